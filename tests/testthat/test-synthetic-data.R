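test_that("kinetic model validates inputs and computes stationary occupancy", {
  m <- two_state_model(3, 1)
  expect_equal(stationary_distribution(m), c(0.25, 0.75))
  expect_error(two_state_model(-1, 1), "non-negative")
  expect_error(kinetic_model(c(0.4, 0.6), matrix(c(0, Inf, 1, 0), 2, 2)),
               "finite")
  expect_error(two_state_model(1, 1, noise_sd = -0.1), "noise_sd")
  # 3-state stationary distribution sums to 1 and solves pi Q = 0
  q3 <- matrix(c(0, 2, 0.5, 1, 0, 1, 0.2, 3, 0), 3, 3, byrow = TRUE)
  m3 <- kinetic_model(c(0.2, 0.5, 0.8), q3)
  pi3 <- stationary_distribution(m3)
  expect_equal(sum(pi3), 1, tolerance = 1e-12)
  expect_lt(max(abs(pi3 %*% m3$rate_matrix)), 1e-10)
})

test_that("a frozen noiseless model emits a constant trace at the state mean", {
  m <- two_state_model(0, 0, emission_means = c(0.38, 0.63), noise_sd = 0)
  sim <- simulate_trace(m, 50, 0.1, seed = 1, start_state = 1)
  expect_equal(sim$trace$apparent_fret, rep(0.38, 50))
  expect_equal(sim$trace$acceptor / (sim$trace$donor + sim$trace$acceptor),
               sim$trace$apparent_fret)
})

test_that("long-run frame occupancy converges to the stationary value", {
  m <- two_state_model(3, 1)
  sim <- simulate_trace(m, 1e5, 0.1, seed = 2)
  expect_close(mean(sim$truth$f_high), 0.75, tol = 0.01)
  expect_true(all(sim$truth$f_high >= 0 & sim$truth$f_high <= 1))
  expect_equal(rowSums(sim$truth$occupancy), rep(1, 1e5), tolerance = 1e-9)
})

test_that("simulation is byte-identical under the same seed", {
  m <- two_state_model(2, 1)
  a <- simulate_trace(m, 200, 0.1, seed = 99, bleach_rate = 0.05)
  b <- simulate_trace(m, 200, 0.1, seed = 99, bleach_rate = 0.05)
  expect_identical(a, b)
  sa <- simulate_trace_set(m, 5, 100, 0.1, seed = 4)
  sb <- simulate_trace_set(m, 5, 100, 0.1, seed = 4)
  expect_identical(sa, sb)
})

test_that("dwell times of the latent path are exponential at the set rates", {
  m <- two_state_model(5, 2, noise_sd = 0)
  sim <- simulate_trace(m, 4e4, 0.1, seed = 7)  # ~4000 s, ~1e4 dwells/state
  jt <- sim$truth$jump_times
  js <- sim$truth$jump_states
  dwell <- diff(jt)
  st <- js[-length(js)]
  # complete dwells only (last is censored by trace end)
  d_low <- dwell[st == 1L]
  d_high <- dwell[st == 2L]
  expect_gt(length(d_low), 5e3)
  expect_gt(stats::ks.test(d_low, "pexp", 5)$p.value, 0.01)
  expect_gt(stats::ks.test(d_high, "pexp", 2)$p.value, 0.01)
})

test_that("camera averaging: fast exchange collapses variance, slow is bimodal", {
  # fast: tau*(k1+k2) = 40 -> switching variance mostly averaged out
  fast <- simulate_trace_set(two_state_model(200, 200), 10, 2000, 0.1,
                             seed = 11)
  e_fast <- pool_fret(fast)
  # residual switching variance at lambda*tau = 40 is ~2/(lambda*tau) of the
  # full bernoulli variance: var ~ sigma^2 + 0.05*0.125^2*... stays < 2*sigma^2
  expect_lt(stats::var(e_fast), 2 * 0.05^2)
  # slow: clearly bimodal at the state means with stationary weights
  slow <- simulate_trace_set(two_state_model(0.05, 0.05), 40, 500, 0.1,
                             seed = 12)
  e_slow <- pool_fret(slow)
  expect_close(mean(e_slow < 0.505), 0.5, tol = 0.08)
  lo <- e_slow[e_slow < 0.505]; hi <- e_slow[e_slow >= 0.505]
  expect_close(mean(lo), 0.38, tol = 0.01)
  expect_close(mean(hi), 0.63, tol = 0.01)
})

test_that("photobleaching drops both channels below the QC thresholds", {
  m <- two_state_model(1, 1)
  found <- FALSE
  for (s in 1:10) {
    sim <- simulate_trace(m, 400, 0.1, seed = s, bleach_rate = 0.1)
    bf <- sim$truth$bleach_frame
    if (!is.na(bf)) {
      found <- TRUE
      dark <- bf:400
      expect_true(all(sim$trace$donor[dark] < 5))
      expect_true(all(sim$trace$acceptor[dark] < 5))
      expect_true(all(sim$trace$donor[dark] + sim$trace$acceptor[dark] < 10))
    }
  }
  expect_true(found)
})

test_that("trace sets round-trip through the plain-text format", {
  set <- simulate_trace_set(two_state_model(1, 2), 3, 50, 0.1, seed = 21,
                            condition = "glu10uM")
  dir <- withr::local_tempdir()
  write_trace_set(set, dir)
  back <- read_trace_set(dir)
  expect_equal(length(back$traces), 3L)
  for (i in 1:3) {
    expect_equal(back$traces[[i]]$donor, set$traces[[i]]$donor,
                 tolerance = 1e-6)
    expect_equal(back$traces[[i]]$apparent_fret,
                 set$traces[[i]]$apparent_fret, tolerance = 1e-6)
  }
  expect_true(file.exists(file.path(dir, "truth.json")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$noise_sd, 0.05)
})

test_that("uptake simulator reproduces the requested protection in expectation", {
  peps <- toy_peptides()
  prot <- data.frame(start = 216, end = 226, condition = "glu", delta = 40)
  # noiseless: condition difference at the longest timepoint is exact
  tab <- simulate_uptake_table(peps, prot, noise_sd = 0, replicates = 1,
                               seed = 5)
  w <- woods_table(tab, "apo", "glu", timepoints = 13200, threshold = 10)
  expect_equal(w$delta_pct_d[w$start == 216], -40, tolerance = 1e-9)
  expect_true(all(abs(w$delta_pct_d[w$start != 216]) < 1e-9))
  # per-replicate noise has the requested SD
  tabn <- simulate_uptake_table(peps, prot, noise_sd = 1, replicates = 200,
                                seed = 6)
  g <- tabn[tabn$start == 55 & tabn$timepoint == 13200 &
              tabn$condition == "apo", ]
  expect_close(stats::sd(g$percent_d), 1, tol = 0.15)
  # mean uptake is monotone in time
  cv <- uptake_curve(tab, 55, 62, "apo")
  expect_false(attr(cv, "nonmonotonic"))
  expect_error(simulate_uptake_table(peps[0, ], NULL), "empty")
  expect_error(simulate_uptake_table(peps, noise_sd = -1), "noise_sd")
})

test_that("toy frame generator realizes requested geometry", {
  at <- toy_dimer()
  fr <- make_toy_frames(at, n_frames = 5, jitter_sd = 0, seed = 1)
  expect_length(fr, 5)
  expect_identical(fr[[1]], fr[[5]])
  expect_equal(pair_distance(fr[[1]], "A", 500, "B", 500), 38.2)
  # jittered frames move atoms by about the requested SD
  frj <- make_toy_frames(at, n_frames = 200, jitter_sd = 0.5, seed = 2)
  dx <- vapply(frj, function(f) f$x[1] - at$x[1], 1)
  expect_close(stats::sd(dx), 0.5, tol = 0.1)
})
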