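Package: fretdyn
Title: Kinetic and Structural Analysis of Single-Molecule FRET Conformational Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying conformational dynamics of membrane receptors from
    single-molecule FRET recordings: exact continuous-time Markov-chain trace simulation
    with camera time-averaging and photobleaching, automated trace quality control,
    hidden Markov model idealization with Viterbi paths and dwell-time statistics,
    Bayesian inference of transition rates faster than the frame rate via the
    time-averaged occupancy-fraction likelihood sampled with an affine-invariant
    ensemble MCMC, Gaussian-mixture decomposition of FRET histograms with a
    missed-trace occupancy correction, multi-state gating-scheme occupancies,
    FRET-distance conversion, structural metrics on coordinate frames (distances,
    centers of mass, hydrogen bonds, inter-helix angles, windowed RMSF), and
    differential hydrogen-deuterium exchange (Woods plot) classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    pracma,
    jsonlite,
    bio3d,
    mclust,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
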