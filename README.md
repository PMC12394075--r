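# fretdyn

Kinetic and structural analysis of single-molecule FRET (smFRET)
conformational dynamics, built for the activation pathway of dimeric
membrane receptors such as metabotropic glutamate receptors: a
ligand-binding clamshell that opens and closes, inter-subunit twisting,
and cysteine-rich-domain approach toward the G-protein-bound state.

smFRET reports a dye-pair distance per camera frame as the apparent
efficiency E = acceptor/(donor + acceptor). The package covers the full
quantitative chain around that observable:

* **Simulation** — exact continuous-time Markov chain (CTMC) traces with
  camera time-averaging, per-frame Gaussian noise, and single-step
  photobleaching; plus synthetic HDX uptake tables and toy coordinate
  frames with known geometry, so every stage is testable without
  experimental data.
* **Quality control** — automated photobleach trimming (acceptor < 5,
  donor < 5, sum < 10 a.u., persistent for 3 frames) and the trace-count
  ratio c = n/n_ref feeding the missed-trace correction.
* **Idealization** — pooled Gaussian-emission HMM (Baum-Welch, 10
  restarts, 1e-6 precision), Viterbi paths, censored dwell statistics,
  and rate constants k = −ln(1 − P)/τ from the per-frame transition
  probabilities.
* **Sub-frame-resolution kinetics** — for exchange faster than the frame
  rate, a Bayesian likelihood built on the exact occupancy-fraction law
  of a two-state CTMC observed through a τ-window: point masses
  π₁e^(−k₁τ), π₂e^(−k₂τ) at f = 1, 0 plus a Bessel-form continuous
  density, marginalized over Gaussian noise and sampled with an
  affine-invariant ensemble MCMC (global likelihood: emission means and
  noise shared across datasets, independent rate pairs per dataset;
  posterior summarized by median, 16th–84th percentile interval, MAP).
* **Equilibria** — Gaussian-mixture histogram decomposition,
  the missed-trace occupancy correction f′_A = c·f_A,
  f′_I = 1 − c(1 − f_I), K′_eq = f′_A/f′_I, k′_f = K′_eq·k_r,
  independent-subunit cooperativity (p² both-closed), linear gating-chain
  occupancies, and Förster conversion R = R₀((1−E)/E)^(1/6).
* **Structural metrics** — Cα pair distances, clamshell openness,
  lower-lobe center-of-mass separation, geometric hydrogen bonds
  (3.5 Å / 50° deviation from linearity), windowed RMSF after Kabsch
  superposition, and inter-helix angles, on PDB/mmCIF multi-model files
  or in-memory frames.
* **Differential HDX** — 90% maximal-deuteration adjustment, per-peptide
  Δ%D Woods tables with the inclusive ≤10% gray zone, replicate-averaged
  uptake curves.

## Worked example

Simulate a fast-exchange sensor (both rates 100/s, i.e. well beyond a
50 fps camera), watch the histogram collapse to one peak, then recover
the rates with the sub-frame-resolution likelihood:

```r
library(fretdyn)

model <- two_state_model(k_f = 100, k_r = 100,
                         emission_means = c(0.38, 0.63), noise_sd = 0.05)
set <- simulate_trace_set(model, n_traces = 50, n_frames = 500,
                          frame_period = 0.02, seed = 7)

fit_mixture(pool_fret(set), 1)$means
#> 0.505      # unimodal peak at the stationary mean, not at either state

infer_rates_global(pool_fret(set), tau = 0.02, seed = 3)
#> <subres_posterior> 20 walkers, burn-in 400 steps, acceptance 0.55
#>  parameter   median     lo16      hi84      map
#>       eps1  0.38180  0.37670   0.38850  0.38690
#>       eps2  0.62770  0.62180   0.63350  0.62260
#>      sigma  0.05075  0.04928   0.05281  0.05215
#>       k1_1 95.27000 85.71000 103.50000 86.91000
#>       k2_1 95.04000 85.08000 103.30000 86.31000
```

The histogram alone cannot distinguish fast exchange from a single
intermediate state; the time-averaged likelihood recovers both emission
means (0.38/0.63), the noise level, and the 100/s rates from the same
frames. A standard HMM on these data saturates far below the true rates
(see the vignette for why).

Occupancy correction and distance conversion are closed-form:

```r
correct_occupancy(0.5, count_ratio(600, 1000), k_r = 1)
#> <occupancy_estimate> f_A = 0.5 (observed), c = 0.6
#>   corrected: f'_A = 0.3, f'_I = 0.7, K'_eq = 0.4286
#>   k_r = 1 /s  ->  k'_f = 0.4286 /s

fret_to_distance(0.85, r0 = 51)
#> 38.2       # Angstrom
```

See `vignettes/fretdyn-methods.Rmd` for the models, priors, numerical
choices and known biases, and `run_pipeline()` for a one-call
simulate → QC → idealize → histogram → correction run that writes CSV/JSON
tables with provenance.

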