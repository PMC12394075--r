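---
title: "Models and methods behind fretdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretdyn)
```

fretdyn quantifies the conformational dynamics of dimeric membrane
receptors (its defaults are tuned to metabotropic glutamate receptor
sensors) from single-molecule FRET recordings, and ships the surrounding
analyses such experiments lean on: structural reporter metrics on
coordinate frames and differential hydrogen-deuterium exchange. This
vignette explains the models, the numerical choices, and what the synthetic
data generator does and does not emulate.

## The kinetic model and camera averaging

The molecular degree of freedom (a ligand-binding clamshell opening and
closing, or two lobes twisting against each other) is modelled as a
continuous-time Markov chain (CTMC) over 2-4 conformational states. Each
state $i$ emits an apparent FRET efficiency centred on $\epsilon_i$; a
camera frame of duration $\tau$ reports the *time average* of the emission
over the frame plus Gaussian noise of SD $\sigma$:

$$E_t = \sum_i f_{t,i}\,\epsilon_i + \mathcal{N}(0, \sigma^2),$$

where $f_{t,i}$ is the fraction of frame $t$ spent in state $i$.
`simulate_trace()` samples the CTMC path exactly (exponential holding
times, embedded-chain jumps, stationary start) and computes $f_{t,i}$ by
exact interval bookkeeping rather than sub-frame discretization. Donor and
acceptor channels are synthesized from a fixed total intensity (500 a.u.)
so that acceptor/(donor+acceptor) reproduces $E_t$; apparent FRET is
deliberately uncorrected (no gamma or crosstalk factor), because every
quantity downstream is defined in apparent-FRET units.

Two regimes matter. When exchange is slow relative to the frame rate
($\tau(k_1+k_2) \ll 1$), frames are essentially pure states and the pooled
histogram is bimodal at $\epsilon_1, \epsilon_2$ with stationary weights.
When exchange is fast ($\tau(k_1+k_2) \gg 1$), averaging collapses the
histogram into a single peak at the stationary mean — at equal forward and
reverse rates of 100/s with 100 ms frames and means 0.38/0.63, a unimodal
peak at $\approx 0.505$. The simulator's defaults (means 0.38/0.63,
$\sigma = 0.05$, 10 or 50 frames/s) are the study conditions for the
glutamate-sensor regime this package targets; $\sigma = 0.05$ reproduces
realistic single-molecule peak widths and is configurable.

Photobleaching is a single exponential-time event that drops both channels
to unit-SD background noise. That matches the quality-control model
(acceptor < 5, donor < 5, sum < 10 a.u. marks the bleached tail) but is
deliberately simpler than real photophysics: no donor-only blinking, no
partial bleaching steps, no intensity drift. Trace selection effects that
motivate the missed-trace correction are *not* emulated by the generator;
the correction is exercised arithmetically.

## Quality control

`trim_photobleach()` keeps the longest prefix before the first run of at
least `k_persist = 3` consecutive dark frames. The persistence rule exists
because a single noisy frame can dip below an intensity threshold without
any bleach; three frames at 10 fps (0.3 s) is far longer than a noise
excursion and far shorter than typical bleach tails. Traces shorter than
50 frames after trimming (5 s at 10 fps) are excluded from kinetics — too
few frames for meaningful dwell statistics. Both knobs are configurable;
manual curation in the original workflow has no published rule to copy.

## HMM idealization and its resolution limit

`fit_hmm()` is a plain maximum-likelihood Baum-Welch EM over all supplied
traces jointly: shared transition matrix, shared initial distribution, and
per-state Gaussian emissions with free SDs. Ten random restarts (quantile
means jittered under a seeded RNG) and a relative log-likelihood tolerance
of $10^{-6}$ are the defaults. This is a deliberate simplification of
empirical-Bayes HMM engines: the state count is fixed by the experiment
design (2 for single-sensor data, 3-4 with modulators or G protein), so
model selection machinery is unnecessary. States are relabelled ascending
by mean, so "high FRET" is always the last index; Viterbi ties break
toward the lower state index.

Rates come from the off-diagonal per-frame transition probabilities via
$k = -\ln(1 - P)/\tau$. Two biases are worth knowing about:

* even for a perfectly observed two-state CTMC the frame-to-frame
  transition probability is $\pi_j(1 - e^{-(k_1+k_2)\tau})$, not
  $1 - e^{-k\tau}$, so the simple inversion under-estimates rates by
  $\mathcal{O}(k\tau)$ (about 5% at $k\tau = 0.2$);
* idealized dwell times are biased long, because sub-frame excursions to
  the other state are invisible (about 10% of opposite-state dwells are
  shorter than one frame at $k\tau = 0.1$) and dwell lengths are quantized
  to whole frames. The dwell tests assert a 25% band for this reason, and
  the first and last dwell of every trace are censored.

Beyond $k\tau \approx 1$ idealization fails outright — most frames contain
transitions, the fitted states collapse toward the stationary mean and the
inferred rates saturate far below truth (this degradation is asserted in
the test suite). That failure is the motivation for the time-averaged
likelihood below.

## Sub-frame-resolution inference

For a stationary two-state CTMC, the fraction $f$ of a frame spent in
state 1 has a mixed law: atoms at $f = 1$ (no exit from state 1, weight
$\pi_1 e^{-k_1\tau}$) and $f = 0$ (weight $\pi_2 e^{-k_2\tau}$), and a
continuous part — the classical two-state occupation-time density —

$$p(f) = \tau e^{-k_1 f\tau - k_2(1-f)\tau}\Big[(\pi_1 k_1 + \pi_2 k_2)
I_0(z) + \sqrt{k_1 k_2}\big(\pi_1\sqrt{\tfrac{f}{1-f}} +
\pi_2\sqrt{\tfrac{1-f}{f}}\big) I_1(z)\Big],$$

with $z = 2\tau\sqrt{k_1 k_2 f(1-f)}$ and $\pi_1 = k_2/(k_1+k_2)$. The
implementation (`occupancy_fraction_density()`) uses exponentially scaled
Bessel functions, which keeps the evaluation stable to $k = 1000$/s, and
was validated against a brute-force window simulator
(`sample_occupancy_fraction()`) that never shares code with the closed
form. The marginal likelihood of one frame's FRET value integrates the
Gaussian noise model over this law (`frame_loglik()`): atoms analytically,
continuous part by fixed-order Gauss-Legendre quadrature with 101 nodes.
101 nodes resolve the sharpest admissible density (at $k = 1000$/s the
continuous part has SD $\approx 0.05$ in $f$) and the quadrature is
checked against the Monte-Carlo marginal in the tests.

`infer_rates_global()` samples the joint posterior of $(\epsilon_1,
\epsilon_2, \sigma)$ — shared across datasets — and per-dataset rate pairs
with a Goodman-Weare affine-invariant ensemble sampler (stretch move,
$a = 2$), written in-package because no R implementation of this sampler
is available as a dependency. Priors: $\epsilon_1 \sim N(0.44, 0.2^2)$,
$\epsilon_2 \sim N(0.66, 0.2^2)$ (these fix the state labelling),
log-uniform $\sigma \in [0.01, 1]$ and log-uniform rates
$\in [10^{-3}, 10^3]$/s. Rates and $\sigma$ are sampled in log space,
where their priors are flat.

Numerical choices that required a decision:

* **Walker count** defaults to 4x the parameter dimension (no published
  value to copy); results are robust to doubling it.
* **Initialization.** Scattering walkers over the prior is the textbook
  choice but fails reproducibly here: with rates spanning six decades, the
  ensemble collapses into whichever mode the best early walker occupies,
  and the stretch move cannot escape a basin once every walker is inside
  it (the degenerate $\epsilon_1 = \epsilon_2$ ridge is entropically
  attractive and sits ~200 nats below the true mode on fast-regime data).
  The default therefore follows common ensemble-sampler practice: score
  prior draws plus a deterministic grid of symmetric rates across the
  prior decades, polish the best candidates with L-BFGS-B, and start the
  walkers in a small ball around the optimum. `init = "prior"` restores
  the textbook behaviour.
* **Burn-in** runs until the ensemble-mean log-posterior changes by less
  than 0.1 over 100 steps, bounded between 300 and 1700 steps; burn-in is
  discarded and summaries use 100 further production steps thinned every
  10th (median, 16th-84th percentile interval), with the MAP taken over
  the full production chain.
* **Binned likelihood.** Observations are binned at 0.002 FRET units and
  the likelihood weighted by counts; the bin width is at least 5x smaller
  than any admissible $\sigma$, and it makes the per-step cost independent
  of the number of frames.

One caveat on calibration: the likelihood treats frames as independent,
but consecutive frames of one trace are weakly correlated (correlation
$e^{-(k_1+k_2)\tau}$, about 2% at $k\tau = 2$). The posterior is therefore
very slightly overconfident. More practically, a 16th-84th percentile
interval is a 68% credible interval: across repeated synthetic datasets it
covers the generating rate in roughly two runs out of three, which is the
correct calibrated behaviour, not a defect. Identifiability also degrades
toward the static limit — the profile log-likelihood flattens as
$k\tau \to 0$, and the posterior width for $k$ grows without bound (both
are asserted qualitatively in the tests).

## Histograms, occupancy, and the missed-trace correction

Population histograms are computed per movie and averaged with the
standard error across movies (40 bins over $[-0.1, 1.1]$ by default), and
state occupancies come from Gaussian-mixture decompositions
(`fit_mixture()`): unbinned maximum likelihood via mclust by default, with
a binned least-squares mode for histogram-only input. The weight of the
highest-mean component is the "fraction high".

Automated trace selection preferentially loses molecules that dwell only
in the dim low-FRET state. With $c = n/n_\mathrm{ref}$ the ratio of traces
passing selection relative to a saturating reference condition, the
corrected fractions are $f'_A = c f_A$ and $f'_I = 1 - c(1 - f_I)$ —
implemented as the exact complement $1 - f'_A$ so the two sum to 1 to the
last bit — giving $K'_\mathrm{eq} = f'_A / f'_I$ and, when the reverse
rate is taken as completely observed, $k'_f = K'_\mathrm{eq} k_r$. The
correction assumes (i) only inactive-state molecules are missed and
(ii) the reference condition misses none.

Cooperativity enters through two small models: independent per-subunit
closure gives a both-closed probability of $p^2$ (0.25 at $p = 0.5$), and
a linear gating chain of equilibrium constants $K_i$ gives state
occupancies proportional to $\prod_{j<i} K_j$. The gating chain is
parameterized by equilibrium constants only — no kinetics — because that
is the level at which multi-state gating schemes are typically
constrained; the package ships no numeric $K_i$ values, they are user
inputs. FRET-distance conversion uses the Förster relation
$R = R_0((1-E)/E)^{1/6}$ with $R_0$ supplied by the user (51 Å for the
dye pair the defaults target).

## Structural metrics

All metrics operate on plain atom tables (chain, residue number, atom
name, element, xyz) parsed from PDB/mmCIF via bio3d, so multi-model files
map 1:1 onto frame lists. Distances are Euclidean between resolved single
atoms (Cα by default); centers of mass are mass-weighted with standard
atomic masses (unit-mass mode for toys); hydrogen bonds require
donor-acceptor distance ≤ 3.5 Å *and* deviation from D–H···A linearity
≤ 50° — the cutoff is applied to the deviation, i.e. the angle at the
hydrogen must exceed 130°, the convention of the common trajectory
analysis tools, and a residue pair is in contact if any one atom triplet
qualifies. Windowed RMSF superposes each frame onto a two-pass mean
structure using only the flanking alignment residues (Kabsch
least-squares via bio3d), then reports per-residue Cα fluctuations about
the time-averaged positions, so global rigid motion cancels exactly.
Inter-helix angles are measured between first principal components of the
Cα selections, oriented N→C (antiparallel = 180°; an undirected mode
folds onto [0°, 90°]). Note that the principal axis of a *finite* wound
helix tilts slightly away from the geometric axis (the axial coordinate
correlates with winding phase), which bounds the achievable precision at
roughly 2° for a 14-residue helix; the toy tests therefore use collinear
point sets where the axis is exact. Residue numbering is taken as-is from
the input files; mapping between receptor paralogues is the user's
responsibility.

## Differential HDX

Uptake tables are tidy data frames keyed by (start, end, sequence) so
duplicate intervals from different charge states stay distinct. Measured
%D is adjusted for incomplete maximal labelling by dividing by 0.90
(capped at 100 with a warning). For two conditions, `woods_table()`
reports $\Delta\%D = \bar{D}_B - \bar{D}_A$ per peptide and timepoint;
negative means more protected in B. Peptides with $|\Delta\%D| \le 10$
are "unchanged" — the boundary is inclusive by definition of the gray
zone. No significance test is attached to the classification (the
threshold rule stands on its own); replicate SDs are reported so users
can add one. The uptake simulator draws saturating exponentials scaled so
the requested protection is met exactly at the longest timepoint, with
Gaussian replicate noise; it does not emulate EX1 bimodality,
back-exchange kinetics, or peptide-level intrinsic-rate variation, so
passing tests say nothing about those phenomena.

## Problem sizes in the test suite

The suite regenerates everything from seeds. Representative sizes, chosen
to give each estimator enough data for its stated tolerance while keeping
a laptop run comfortable: 300 traces x 900 frames for the fast-exchange
histogram, 100 x 900 for slow-regime HMM recovery (rates recovered within
15%), 50 traces x 500 frames per repetition (10 repetitions) for
fast-regime posterior coverage, $10^6$ windows per rate/frame-period
combination for the occupancy-law Monte-Carlo comparison (KS distance
below 0.01), and $10^4$-dwell samples for exponential dwell checks.

## Known limitations

* The sub-resolution likelihood is strictly two-state; 3-4 state sensors
  are handled only by the HMM layer.
* The generator shares one noise SD across states and channels; real
  traces show intensity-dependent noise.
* No dose-response fitting, no ligand-binding model beyond independent
  closure, and no figure-replication utilities.
* Trajectory input is limited to multi-model PDB/mmCIF and in-memory
  frame lists; binary MD formats are out of scope.
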