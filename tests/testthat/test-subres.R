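test_that("occupancy-fraction point masses equal stationary survival weights", {
  d <- occupancy_fraction_density(0.5, 1, 1, 0.1)
  expect_equal(d$point_mass_1, 0.5 * exp(-0.1), tolerance = 1e-12)
  expect_equal(d$point_mass_0, 0.5 * exp(-0.1), tolerance = 1e-12)
  # static limit: almost all mass in the atoms
  ds <- occupancy_fraction_density(0.5, 1e-3, 1e-3, 0.1)
  expect_close(ds$point_mass_0 + ds$point_mass_1, 1, tol = 1e-4)
  # asymmetric rates: atom weights pi1 e^(-k1 tau), pi2 e^(-k2 tau)
  da <- occupancy_fraction_density(0.5, 4, 1, 0.1)
  expect_equal(da$point_mass_1, 0.2 * exp(-0.4), tolerance = 1e-12)
  expect_equal(da$point_mass_0, 0.8 * exp(-0.1), tolerance = 1e-12)
  expect_error(occupancy_fraction_density(0.5, -1, 1, 0.1), "rates")
  expect_error(occupancy_fraction_density(0.5, 1, 1, 0), "tau")
  expect_error(occupancy_fraction_density(1.5, 1, 1, 0.1), "0, 1")
})

test_that("occupancy-fraction law is normalized across rate regimes", {
  for (tau in c(0.02, 0.1)) {
    for (k1 in c(0.01, 1, 100, 1000)) {
      for (k2 in unique(c(k1, 10 * k1))) {
        d <- occupancy_fraction_density(0, k1, k2, tau)
        cont <- stats::integrate(function(f)
          occupancy_fraction_density(f, k1, k2, tau)$density, 0, 1,
          rel.tol = 1e-10, subdivisions = 400L)$value
        expect_close(cont + d$point_mass_0 + d$point_mass_1, 1, tol = 1e-6)
      }
    }
  }
})

test_that("closed-form law matches the brute-force window simulator", {
  # moderate n here; the full 1e6-window sweep runs in the acceptance suite
  for (cfg in list(c(1, 2, 0.1), c(10, 10, 0.1), c(100, 30, 0.02))) {
    k1 <- cfg[1]; k2 <- cfg[2]; tau <- cfg[3]
    f_mc <- sample_occupancy_fraction(1e5, k1, k2, tau, seed = 17)
    grid <- seq(0, 1, length.out = 201)
    f_ana <- occ_cdf(grid, k1, k2, tau)
    f_emp <- stats::ecdf(f_mc)(grid)
    expect_lt(max(abs(f_ana - f_emp)), 0.01)
    # mean occupancy equals the stationary weight of state 1
    expect_close(mean(f_mc), k2 / (k1 + k2), tol = 0.01)
  }
})

test_that("frame likelihood reaches its static and fast analytic limits", {
  e <- seq(0.2, 0.9, by = 0.05)
  # static: two-component mixture with stationary weights; the limit is
  # approached linearly in k*tau, so k*tau = 1e-5 sits inside 1e-4
  ll <- frame_loglik(e, 0.44, 0.66, 0.05, 1e-3, 1e-3, 0.01)
  mix <- log(0.5 * stats::dnorm(e, 0.44, 0.05) +
               0.5 * stats::dnorm(e, 0.66, 0.05))
  expect_close(ll, mix, tol = 1e-4)
  # asymmetric rates weight the mixture by the stationary distribution
  lla <- frame_loglik(e, 0.44, 0.66, 0.05, 1e-3, 3e-3, 0.01)
  mixa <- log(0.75 * stats::dnorm(e, 0.44, 0.05) +
                0.25 * stats::dnorm(e, 0.66, 0.05))
  expect_close(lla, mixa, tol = 5e-4)
  # fast: single Gaussian at the stationary mean (residual switching
  # variance at lambda*tau = 200 shifts log-density by < 5e-3 at sigma 0.2)
  llf <- frame_loglik(e, 0.44, 0.66, 0.2, 1e3, 1e3, 0.1)
  expect_close(llf, stats::dnorm(e, 0.55, 0.2, log = TRUE), tol = 5e-3)
  expect_error(frame_loglik(0.5, 0.44, 0.66, -0.1, 1, 1, 0.1), "sigma")
})

test_that("frame likelihood agrees with a Monte-Carlo marginal", {
  # Rao-Blackwellized MC estimate: average the Gaussian over sampled f
  for (k in c(1, 10, 100)) {
    f <- sample_occupancy_fraction(2e5, k, k, 0.1, seed = 23)
    e_test <- seq(0.25, 0.8, length.out = 10)
    for (ee in e_test) {
      vals <- stats::dnorm(ee, f * 0.44 + (1 - f) * 0.66, 0.05)
      mc <- mean(vals); se <- stats::sd(vals) / sqrt(length(vals))
      ana <- exp(frame_loglik(ee, 0.44, 0.66, 0.05, k, k, 0.1))
      expect_lt(abs(ana - mc), 3 * se + 1e-8)
    }
  }
})

test_that("likelihood is invariant under simultaneous state relabelling", {
  e <- c(0.1, 0.4, 0.55, 0.7, 1.0)
  a <- frame_loglik(e, 0.44, 0.66, 0.07, 3, 40, 0.1)
  b <- frame_loglik(e, 0.66, 0.44, 0.07, 40, 3, 0.1)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("rates become unidentifiable in the static limit", {
  # profile flatness: for data simulated in the static regime the
  # log-likelihood barely distinguishes k = 1e-3 from k = 1e-2, while in the
  # fast regime the same decade step is decisive
  slow <- pool_fret(simulate_trace_set(
    two_state_model(0.01, 0.01, c(0.44, 0.66), 0.05), 10, 500, 0.1, seed = 3))
  d_slow <- abs(sum(frame_loglik(slow, 0.44, 0.66, 0.05, 1e-3, 1e-3, 0.1)) -
                  sum(frame_loglik(slow, 0.44, 0.66, 0.05, 1e-2, 1e-2, 0.1)))
  fast <- pool_fret(simulate_trace_set(
    two_state_model(100, 100, c(0.44, 0.66), 0.05), 10, 500, 0.1, seed = 4))
  d_fast <- abs(sum(frame_loglik(fast, 0.44, 0.66, 0.05, 100, 100, 0.1)) -
                  sum(frame_loglik(fast, 0.44, 0.66, 0.05, 1000, 1000, 0.1)))
  expect_lt(d_slow, 5)
  expect_gt(d_fast, 100)
})

test_that("with no data the posterior reproduces the prior", {
  post <- infer_rates_global(numeric(0), tau = 0.1, n_walkers = 50,
                             n_production = 1000, min_burn = 300,
                             max_burn = 500, seed = 9)
  s <- post$summary
  expect_close(s$median[s$parameter == "eps1"], 0.44, tol = 0.044)
  expect_close(s$median[s$parameter == "eps2"], 0.66, tol = 0.066)
  # log-uniform medians: sigma 0.1, k 1 (wide prior; generous MC tolerance)
  expect_close(log10(s$median[s$parameter == "sigma"]), -1, tol = 0.15)
  expect_close(log10(s$median[s$parameter == "k1_1"]), 0, tol = 0.3)
})

test_that("global fit shares emissions and resolves a 4-fold rate difference", {
  m_slow <- two_state_model(25, 25, c(0.44, 0.66), 0.05)
  m_fast <- two_state_model(100, 100, c(0.44, 0.66), 0.05)
  d1 <- pool_fret(simulate_trace_set(m_slow, 30, 400, 0.02, seed = 51))
  d2 <- pool_fret(simulate_trace_set(m_fast, 30, 400, 0.02, seed = 52))
  post <- infer_rates_global(list(d1, d2), tau = 0.02, seed = 53)
  s <- post$summary
  get <- function(p) s[s$parameter == p, ]
  # shared emissions recovered once
  expect_close(get("eps1")$median, 0.44, tol = 0.02)
  expect_close(get("eps2")$median, 0.66, tol = 0.02)
  # the rate ratio between datasets is ~4x, within the joint intervals
  ratio <- get("k1_2")$median / get("k1_1")$median
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6.5)
  # each interval is ordered and brackets its median
  expect_true(all(s$lo16 <= s$median & s$median <= s$hi84))
})
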