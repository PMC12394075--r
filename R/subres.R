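#' Distribution of the per-frame occupancy fraction of a two-state chain
#'
#' For a stationary two-state continuous-time Markov chain observed through a
#' camera frame of duration tau, the fraction f of the frame spent in state 1
#' (escape rate `k1`; state 2 has escape rate `k2`) has a mixed distribution:
#' point masses at f = 1 (no transition out of state 1, weight
#' pi1 exp(-k1 tau)) and f = 0 (weight pi2 exp(-k2 tau)), plus a continuous
#' part supported on (0, 1),
#' \deqn{p(f) = \tau e^{-k_1 f \tau - k_2 (1-f)\tau}\left[
#'   (\pi_1 k_1 + \pi_2 k_2) I_0(z) + \sqrt{k_1 k_2}\,\big(\pi_1
#'   \sqrt{f/(1-f)} + \pi_2 \sqrt{(1-f)/f}\big) I_1(z)\right]}
#' with \eqn{z = 2\tau\sqrt{k_1 k_2 f (1-f)}}, \eqn{\pi_1 = k_2/(k_1+k_2)},
#' and modified Bessel functions \eqn{I_0, I_1} (the classical occupation-time
#' law of a two-state Markov chain). Exponentially scaled Bessel functions
#' keep the evaluation stable up to rates of 1000/s.
#'
#' @param f Numeric vector of fractions in \[0, 1\] at which to evaluate the
#'   continuous density.
#' @param k1 Escape rate from state 1 (the low-FRET state), 1/s.
#' @param k2 Escape rate from state 2, 1/s.
#' @param tau Frame duration, seconds.
#' @return A list: \code{f}, \code{density} (continuous part at \code{f}),
#'   \code{point_mass_0}, \code{point_mass_1}. The total law integrates to 1.
#' @seealso [sample_occupancy_fraction()] for the brute-force Monte-Carlo
#'   counterpart, [frame_loglik()] for the marginal FRET likelihood built on
#'   this law.
#' @export
occupancy_fraction_density <- function(f, k1, k2, tau) {
  if (!all(is.finite(c(k1, k2))) || k1 <= 0 || k2 <= 0)
    stop("rates must be finite and > 0")
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  p1 <- k2 / (k1 + k2)
  p2 <- k1 / (k1 + k2)
  dens <- occ_density_cont(f, k1, k2, tau, p1, p2)
  list(f = f, density = dens,
       point_mass_0 = p2 * exp(-k2 * tau),
       point_mass_1 = p1 * exp(-k1 * tau))
}

# continuous part only; vectorized in f, endpoints evaluate to limits
occ_density_cont <- function(f, k1, k2, tau, p1, p2) {
  x <- f * tau
  y <- (1 - f) * tau
  z <- 2 * sqrt(k1 * k2 * x * y)
  i0 <- besselI(z, 0, expon.scaled = TRUE)
  i1 <- besselI(z, 1, expon.scaled = TRUE)
  # e^{-k1 x - k2 y} * I_nu(z) = e^{-(k1 x + k2 y - z)} * scaled I_nu; the
  # exponent is <= 0 by AM-GM so this never overflows.
  ex <- exp(-(k1 * x + k2 * y - z))
  c0 <- p1 * k1 + p2 * k2
  ratio <- sqrt(f / (1 - f))
  term1 <- ifelse(f >= 1, Inf, p1 * ratio)        # I1 ~ z/2 tames endpoints
  term2 <- ifelse(f <= 0, Inf, p2 / ratio)
  c1 <- sqrt(k1 * k2) * (term1 + term2)
  d <- tau * ex * (c0 * i0 + c1 * i1)
  # at the endpoints I1(z)->0 like z, giving finite one-sided limits:
  # f -> 0: c1*I1 -> p2*k2*tau*... ; compute limits explicitly
  at0 <- f <= 0
  at1 <- f >= 1
  if (any(at0))
    d[at0] <- tau * exp(-k2 * tau) * (c0 + p2 * k1 * k2 * tau)
  if (any(at1))
    d[at1] <- tau * exp(-k1 * tau) * (c0 + p1 * k1 * k2 * tau)
  d
}

#' Monte-Carlo sampler of the per-frame occupancy fraction
#'
#' Simulates `n` independent stationary two-state chains over one frame of
#' duration tau by explicit exponential dwell sampling and returns the exact
#' fraction of the frame spent in state 1. This brute-force sampler is the
#' independent ground truth against which the closed-form
#' [occupancy_fraction_density()] is validated.
#'
#' @param n Number of windows.
#' @inheritParams occupancy_fraction_density
#' @param seed Integer seed.
#' @return Numeric vector of n occupancy fractions in \[0, 1\].
#' @export
sample_occupancy_fraction <- function(n, k1, k2, tau, seed = NULL) {
  stopifnot(k1 > 0, k2 > 0, tau > 0, n >= 1)
  with_seed(seed, {
    p1 <- k2 / (k1 + k2)
    st <- ifelse(stats::runif(n) < p1, 1L, 2L)
    t1 <- numeric(n)
    elapsed <- numeric(n)
    act <- seq_len(n)
    while (length(act)) {
      k <- ifelse(st[act] == 1L, k1, k2)
      d <- stats::rexp(length(act), k)
      rem <- tau - elapsed[act]
      dt <- pmin(d, rem)
      t1[act] <- t1[act] + ifelse(st[act] == 1L, dt, 0)
      elapsed[act] <- elapsed[act] + dt
      jumped <- d < rem
      st[act[jumped]] <- 3L - st[act[jumped]]
      act <- act[jumped]
    }
    t1 / tau
  })
}

#' Prior specification for sub-resolution rate inference
#'
#' Defaults: Gaussian priors on the two emission means (0.44 and 0.66, both
#' SD 0.2, fixing the state labelling: state 1 is the lower mean), and
#' maximum-entropy log-uniform priors on the shared noise SD (0.01 to 1.0)
#' and on every rate constant (1e-3 to 1e3 per second).
#'
#' @param eps1_mean,eps1_sd,eps2_mean,eps2_sd Normal prior moments of the
#'   low and high emission means.
#' @param sigma_range Support of the log-uniform prior on the noise SD.
#' @param k_range Support of the log-uniform prior on rates (1/s).
#' @return An object of class \code{biasd_priors}.
#' @export
biasd_priors <- function(eps1_mean = 0.44, eps1_sd = 0.2,
                         eps2_mean = 0.66, eps2_sd = 0.2,
                         sigma_range = c(0.01, 1.0),
                         k_range = c(1e-3, 1e3)) {
  stopifnot(all(sigma_range > 0), all(k_range > 0),
            sigma_range[1] < sigma_range[2], k_range[1] < k_range[2])
  structure(list(eps1_mean = eps1_mean, eps1_sd = eps1_sd,
                 eps2_mean = eps2_mean, eps2_sd = eps2_sd,
                 sigma_range = sigma_range, k_range = k_range),
            class = "biasd_priors")
}

#' Marginal log-likelihood of an apparent-FRET observation
#'
#' Log-density of a single camera frame's apparent FRET value E under the
#' time-averaged two-state model: the Gaussian noise model marginalized over
#' the occupancy-fraction law,
#' log Int Normal(E | f eps1 + (1-f) eps2, sigma) dP(f).
#' The two point masses are added analytically; the continuous part uses
#' fixed-order Gauss-Legendre quadrature on (0, 1).
#'
#' @param e Numeric vector of apparent FRET values.
#' @param eps1,eps2 Emission means of state 1 (low) and state 2 (high).
#' @param sigma Shared Gaussian noise SD (> 0).
#' @param k1,k2 Escape rates from states 1 and 2 (1/s).
#' @param tau Frame duration (s).
#' @param n_nodes Gauss-Legendre node count (default 101).
#' @return Numeric vector of log-densities, one per element of `e`.
#' @export
frame_loglik <- function(e, eps1, eps2, sigma, k1, k2, tau, n_nodes = 101L) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (k1 <= 0 || k2 <= 0 || !all(is.finite(c(k1, k2))))
    stop("rates must be finite and > 0")
  gq <- gauss_nodes(n_nodes)
  p1 <- k2 / (k1 + k2); p2 <- k1 / (k1 + k2)
  w_cont <- gq$w * occ_density_cont(gq$x, k1, k2, tau, p1, p2)
  comp_w <- c(w_cont, p1 * exp(-k1 * tau), p2 * exp(-k2 * tau))
  comp_mu <- c(gq$x * eps1 + (1 - gq$x) * eps2, eps1, eps2)
  keep <- comp_w > 0
  lw <- log(comp_w[keep])
  mu <- comp_mu[keep]
  # n_e x n_comp matrix of log(w) + log N(e | mu, sigma), row-logsumexp
  m <- outer(e, mu, function(ee, mm)
    stats::dnorm(ee, mm, sigma, log = TRUE))
  row_logsumexp(sweep(m, 2L, lw, `+`))
}

# cached Gauss-Legendre nodes/weights on (0, 1)
gauss_cache <- new.env(parent = emptyenv())
gauss_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(gauss_cache[[key]])) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    gauss_cache[[key]] <- list(x = gl$x, w = gl$w)
  }
  gauss_cache[[key]]
}

#' Global Bayesian inference of sub-frame-rate transition rates
#'
#' Samples the joint posterior of shared emission parameters (eps1, eps2,
#' sigma) and per-dataset rate pairs (k1, k2) under the time-averaged
#' two-state likelihood ([frame_loglik()]), using an affine-invariant
#' ensemble MCMC sampler (Goodman-Weare stretch move). All datasets share
#' emission means and noise; each contributes an independent rate pair
#' (the "global" likelihood). Burn-in is run until the ensemble-mean
#' log-posterior plateaus (bounded
#' between `min_burn` and `max_burn` steps) and discarded; summaries come
#' from `n_production` further steps thinned every `thin`-th step, and the
#' MAP estimate from the full production chain.
#'
#' For speed the likelihood bins observations on a fine grid (`bin_width`,
#' default 0.002 FRET units, far below any admissible sigma) and weights
#' each bin centre by its count.
#'
#' @param datasets A list of numeric vectors of apparent FRET values (or a
#'   single vector), one entry per dataset.
#' @param tau Frame duration (s).
#' @param priors A [biasd_priors()].
#' @param n_walkers Ensemble size; default 4x the parameter dimension.
#' @param n_production Production steps after burn-in (default 100).
#' @param thin Thinning interval for summary samples (default 10).
#' @param min_burn,max_burn Bounds on the burn-in length.
#' @param plateau_tol Plateau criterion: burn-in ends when the ensemble-mean
#'   log-posterior changes by less than this over 100 steps.
#' @param n_nodes Quadrature nodes for the likelihood.
#' @param bin_width Observation binning resolution (FRET units).
#' @param init Walker initialization: "map" (default) scores prior draws,
#'   polishes the best by L-BFGS-B and starts the ensemble in a small ball
#'   around the optimum; "prior" scatters walkers over the prior (classic,
#'   but an ensemble started across a 6-decade rate prior can collapse into
#'   a minor mode before finding the dominant one).
#' @param seed Integer seed; fixed seed and walker count give reproducible
#'   chains.
#' @return Object of class \code{subres_posterior}: \code{summary}
#'   (data.frame: parameter, median, lo16, hi84, map), \code{samples}
#'   (thinned production draws), \code{map} (named vector),
#'   \code{n_burn}, \code{log_post_trace}, \code{acceptance_rate}.
#' @export
infer_rates_global <- function(datasets, tau, priors = biasd_priors(),
                               n_walkers = NULL, n_production = 100L,
                               thin = 10L, min_burn = 300L, max_burn = 1700L,
                               plateau_tol = 0.1, n_nodes = 101L,
                               bin_width = 0.002, init = c("map", "prior"),
                               seed = 1L) {
  init <- match.arg(init)
  if (is.numeric(datasets)) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L, tau > 0)
  nd <- length(datasets)
  # bin each dataset once: likelihood is evaluated at bin centres x counts
  binned <- lapply(datasets, function(e) {
    e <- e[is.finite(e)]
    if (length(e) == 0L)  # empty likelihood: the posterior is the prior
      return(list(e = numeric(0), n = numeric(0)))
    b <- round(e / bin_width)
    tab <- table(b)
    list(e = as.numeric(names(tab)) * bin_width, n = as.numeric(tab))
  })

  # parameter vector: eps1, eps2, log(sigma), then per dataset log(k1), log(k2)
  dim_theta <- 3L + 2L * nd
  if (is.null(n_walkers)) n_walkers <- 4L * dim_theta
  if (n_walkers < 2L * dim_theta)
    stop("need at least 2x as many walkers as parameters")
  par_names <- c("eps1", "eps2", "sigma",
                 as.vector(t(outer(seq_len(nd), c("k1", "k2"),
                                   function(i, k) sprintf("%s_%d", k, i)))))

  lsr <- log(priors$sigma_range)
  lkr <- log(priors$k_range)
  log_prior <- function(th) {
    if (th[3L] < lsr[1L] || th[3L] > lsr[2L]) return(-Inf)
    ks <- th[4:dim_theta]
    if (any(ks < lkr[1L]) || any(ks > lkr[2L])) return(-Inf)
    stats::dnorm(th[1L], priors$eps1_mean, priors$eps1_sd, log = TRUE) +
      stats::dnorm(th[2L], priors$eps2_mean, priors$eps2_sd, log = TRUE)
    # log-uniform: constant within support (improper-free, normalized)
  }
  log_post <- function(th) {
    lp <- log_prior(th)
    if (!is.finite(lp)) return(-Inf)
    sig <- exp(th[3L])
    ll <- 0
    for (i in seq_len(nd)) {
      if (!length(binned[[i]]$e)) next
      k1 <- exp(th[2L + 2L * i])
      k2 <- exp(th[3L + 2L * i])
      li <- frame_loglik(binned[[i]]$e, th[1L], th[2L], sig, k1, k2, tau,
                         n_nodes = n_nodes)
      ll <- ll + sum(binned[[i]]$n * li)
    }
    lp + ll
  }

  with_seed(seed, {
    draw_prior <- function() {
      c(stats::rnorm(1, priors$eps1_mean, priors$eps1_sd),
        stats::rnorm(1, priors$eps2_mean, priors$eps2_sd),
        stats::runif(1, lsr[1L], lsr[2L]),
        stats::runif(2L * nd, lkr[1L], lkr[2L]))
    }
    if (init == "map") {
      # score a batch of prior draws, polish the best few by L-BFGS-B, and
      # start the ensemble in a small ball around the optimum (the usual
      # ensemble-sampler initialization; avoids trapping the whole ensemble
      # in a minor mode when walkers scattered over the prior collapse)
      cand <- t(vapply(seq_len(64L), function(i) draw_prior(),
                       numeric(dim_theta)))
      # deterministic candidates: emission means at the prior centres, noise
      # at half the pooled data SD, symmetric rates spanning the prior decades
      # (the rate axis is where basins of attraction separate)
      pooled_e <- unlist(lapply(binned, function(b) rep(b$e, b$n)))
      sd_pool <- if (length(pooled_e) > 1L) stats::sd(pooled_e) else 0.1
      s0 <- log(min(max(sd_pool / 2, priors$sigma_range[1L]),
                    priors$sigma_range[2L]))
      k_grid <- log(10^seq(log10(priors$k_range[1L]) + 1,
                           log10(priors$k_range[2L]) - 0.5, by = 1))
      grid <- t(vapply(k_grid, function(lk)
        c(priors$eps1_mean, priors$eps2_mean, s0, rep(lk, 2L * nd)),
        numeric(dim_theta)))
      cand <- rbind(cand, grid)
      cand_lp <- apply(cand, 1L, log_post)
      top <- cand[order(cand_lp, decreasing = TRUE)[1:3], , drop = FALSE]
      lower <- c(-Inf, -Inf, lsr[1L], rep(lkr[1L], 2L * nd))
      upper <- c(Inf, Inf, lsr[2L], rep(lkr[2L], 2L * nd))
      opts <- lapply(seq_len(nrow(top)), function(i)
        try(stats::optim(top[i, ], function(th) -log_post(th),
                         method = "L-BFGS-B", lower = lower, upper = upper,
                         control = list(maxit = 200)), silent = TRUE))
      opts <- Filter(function(o) !inherits(o, "try-error"), opts)
      center <- if (length(opts)) {
        opts[[which.min(vapply(opts, function(o) o$value, 1))]]$par
      } else top[1L, ]
      walkers <- matrix(rep(center, each = n_walkers), n_walkers, dim_theta)
      walkers <- walkers + matrix(stats::rnorm(n_walkers * dim_theta, 0, 0.02),
                                  n_walkers, dim_theta)
      # clamp back inside the prior support
      walkers[, 3L] <- pmin(pmax(walkers[, 3L], lsr[1L]), lsr[2L])
      walkers[, 4:dim_theta] <-
        pmin(pmax(walkers[, 4:dim_theta], lkr[1L]), lkr[2L])
    } else {
      walkers <- t(vapply(seq_len(n_walkers), function(i) draw_prior(),
                          numeric(dim_theta)))
    }
    lp <- apply(walkers, 1L, log_post)
    while (any(!is.finite(lp))) {  # re-draw the rare invalid initializations
      bad <- which(!is.finite(lp))
      for (b in bad) walkers[b, ] <- draw_prior()
      lp[bad] <- apply(walkers[bad, , drop = FALSE], 1L, log_post)
    }

    a_stretch <- 2
    n_acc <- 0L; n_prop <- 0L
    step_ensemble <- function() {
      halves <- list(seq_len(n_walkers %/% 2L),
                     (n_walkers %/% 2L + 1L):n_walkers)
      for (h in 1:2) {
        move <- halves[[h]]; other <- halves[[3L - h]]
        for (i in move) {
          j <- other[sample.int(length(other), 1L)]
          z <- (stats::runif(1) * (sqrt(a_stretch) - 1 / sqrt(a_stretch)) +
                  1 / sqrt(a_stretch))^2
          prop <- walkers[j, ] + z * (walkers[i, ] - walkers[j, ])
          lp_prop <- log_post(prop)
          n_prop <<- n_prop + 1L
          if (is.finite(lp_prop) &&
              log(stats::runif(1)) <
                (dim_theta - 1) * log(z) + lp_prop - lp[i]) {
            walkers[i, ] <<- prop
            lp[i] <<- lp_prop
            n_acc <<- n_acc + 1L
          }
        }
      }
    }

    # burn-in with plateau detection on the ensemble-mean log-posterior
    lp_trace <- numeric(0)
    n_burn <- 0L
    repeat {
      for (s in 1:100) {
        step_ensemble()
        lp_trace <- c(lp_trace, mean(lp[is.finite(lp)]))
      }
      n_burn <- n_burn + 100L
      if (n_burn >= min_burn) {
        m <- length(lp_trace)
        delta <- abs(mean(lp_trace[(m - 99):m]) -
                       mean(lp_trace[(m - 199):(m - 100)]))
        if (delta < plateau_tol || n_burn >= max_burn) break
      }
    }

    # production
    prod_samples <- vector("list", n_production)
    prod_lp <- numeric(n_production * n_walkers)
    best_lp <- -Inf; best_theta <- walkers[1L, ]
    keep_idx <- logical(n_production)
    for (s in seq_len(n_production)) {
      step_ensemble()
      lp_trace <- c(lp_trace, mean(lp))
      if (s %% thin == 0L) {
        prod_samples[[s]] <- walkers
        keep_idx[s] <- TRUE
      }
      w_best <- which.max(lp)
      if (lp[w_best] > best_lp) {
        best_lp <- lp[w_best]
        best_theta <- walkers[w_best, ]
      }
    }
    samples <- do.call(rbind, prod_samples[keep_idx])
    colnames(samples) <- par_names

    # transform to natural scale for reporting
    nat <- samples
    nat[, 3:dim_theta] <- exp(nat[, 3:dim_theta])
    map_nat <- best_theta
    map_nat[3:dim_theta] <- exp(map_nat[3:dim_theta])
    names(map_nat) <- par_names

    qs <- apply(nat, 2L, stats::quantile, probs = c(0.16, 0.5, 0.84),
                names = FALSE)
    summary <- data.frame(parameter = par_names,
                          median = qs[2L, ], lo16 = qs[1L, ], hi84 = qs[3L, ],
                          map = map_nat, row.names = NULL,
                          stringsAsFactors = FALSE)
    structure(list(summary = summary, samples = nat, map = map_nat,
                   n_burn = n_burn, log_post_trace = lp_trace,
                   acceptance_rate = n_acc / n_prop,
                   n_walkers = n_walkers, tau = tau),
              class = "subres_posterior")
  })
}

#' @export
print.subres_posterior <- function(x, ...) {
  cat(sprintf(
    "<subres_posterior> %d walkers, burn-in %d steps, acceptance %.2f\n",
    x$n_walkers, x$n_burn, x$acceptance_rate))
  df <- x$summary
  df[, 2:5] <- signif(df[, 2:5], 4)
  print(df, row.names = FALSE)
  invisible(x)
}
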