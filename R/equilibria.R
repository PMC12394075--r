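#' Gaussian-mixture decomposition of a FRET histogram
#'
#' Decomposes pooled apparent-FRET observations into 1-4 Gaussian
#' components, the standard way state occupancies are read off smFRET
#' histograms. Two modes: maximum-likelihood on the unbinned values
#' (default, via mclust with unequal variances) and least-squares on a
#' binned histogram (sum-of-Gaussians curve fit). Components are reported in
#' ascending order of mean; \code{fraction_high} is the weight of the
#' highest-mean component.
#'
#' @param e Numeric vector of apparent FRET values.
#' @param n_components Number of Gaussian components (1-4).
#' @param method "ml" (unbinned maximum likelihood) or "binned"
#'   (least-squares on the histogram).
#' @param bins Number of histogram bins for the binned mode (default 40).
#' @param range Histogram range (default c(-0.1, 1.1)).
#' @param seed Seed for the binned mode's start-value jitter.
#' @return Object of class \code{mixture_fit}: \code{means}, \code{sds},
#'   \code{weights} (sum to 1), \code{fraction_high}, \code{n_components},
#'   \code{method}, and \code{residual} (binned mode) or \code{loglik}
#'   (ml mode). Flagged with a warning when components collapse.
#' @export
fit_mixture <- function(e, n_components, method = c("ml", "binned"),
                        bins = 40L, range = c(-0.1, 1.1), seed = 1L) {
  method <- match.arg(method)
  e <- e[is.finite(e)]
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > 4L)
    stop("n_components must be in 1..4")
  if (length(e) < 3L * n_components)
    stop("fewer observations than mixture parameters")

  if (n_components == 1L) {
    fit <- list(means = mean(e), sds = stats::sd(e), weights = 1,
                loglik = sum(stats::dnorm(e, mean(e), stats::sd(e),
                                          log = TRUE)))
  } else if (method == "ml") {
    mclustBIC <- mclust::mclustBIC  # Mclust looks this up in the caller
    mc <- mclust::Mclust(e, G = n_components, modelNames = "V",
                         verbose = FALSE)
    if (is.null(mc)) stop("mixture fit failed")
    fit <- list(means = as.numeric(mc$parameters$mean),
                sds = sqrt(as.numeric(mc$parameters$variance$sigmasq)),
                weights = as.numeric(mc$parameters$pro),
                loglik = mc$loglik)
    if (length(fit$sds) == 1L) fit$sds <- rep(fit$sds, n_components)
  } else {
    fit <- fit_mixture_binned(e, n_components, bins, range, seed)
  }

  ord <- order(fit$means)
  out <- structure(list(
    n_components = n_components,
    means = fit$means[ord], sds = fit$sds[ord],
    weights = fit$weights[ord] / sum(fit$weights),
    fraction_high = fit$weights[ord][n_components] / sum(fit$weights),
    method = method, loglik = fit$loglik %||% NA_real_,
    residual = fit$residual %||% NA_real_), class = "mixture_fit")
  gaps <- diff(out$means)
  gap_scale <- pmin(out$sds[-n_components], out$sds[-1L])
  if (n_components > 1L &&
      (any(gaps < 2 * gap_scale) || min(out$weights) < 1e-4))
    warning("mixture components overlap (means closer than twice the ",
            "component SD, or near-zero weight); the data may support ",
            "fewer components")
  out
}

fit_mixture_binned <- function(e, k, bins, range, seed) {
  h <- graphics::hist(e, breaks = seq(range[1], range[2], length.out = bins + 1),
                      plot = FALSE)
  x <- h$mids; d <- h$density
  qs <- stats::quantile(e, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  s0 <- rep(stats::sd(e) / k, k)
  a0 <- rep(max(d) / k, k)
  start <- stats::setNames(c(qs, log(s0), log(a0)),
                           c(paste0("m", 1:k), paste0("ls", 1:k),
                             paste0("la", 1:k)))
  model_fun <- function(p) {
    m <- p[1:k]; s <- exp(p[(k + 1):(2 * k)]); a <- exp(p[(2 * k + 1):(3 * k)])
    rowSums(vapply(1:k, function(j) a[j] * exp(-(x - m[j])^2 / (2 * s[j]^2)),
                   numeric(length(x))))
  }
  fit <- with_seed(seed, minpack.lm::nls.lm(
    par = start, fn = function(p) d - model_fun(p),
    control = minpack.lm::nls.lm.control(maxiter = 500)))
  p <- fit$par
  m <- p[1:k]; s <- exp(p[(k + 1):(2 * k)]); a <- exp(p[(2 * k + 1):(3 * k)])
  w <- a * s  # area of each component, up to sqrt(2*pi)
  list(means = as.numeric(m), sds = as.numeric(s),
       weights = as.numeric(w / sum(w)),
       residual = sqrt(mean((d - model_fun(p))^2)))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d component(s), method %s\n",
              x$n_components, x$method))
  print(data.frame(mean = round(x$means, 4), sd = round(x$sds, 4),
                   weight = round(x$weights, 4)), row.names = FALSE)
  cat("  fraction_high:", round(x$fraction_high, 4), "\n")
  invisible(x)
}

#' Missed-trace correction of an observed active-state fraction
#'
#' Automated trace selection can miss molecules that dwell only in the dim
#' low-FRET (inactive) state, inflating the observed active fraction. Under
#' the assumption that only inactive molecules are missed, the corrected
#' fractions are f'_A = c f_A and f'_I = 1 - c (1 - f_I), where
#' c = n / n_reference is the trace-count ratio against a saturating
#' reference condition ([count_ratio()]). The corrected fractions sum to 1
#' exactly. The corrected equilibrium constant is K'_eq = f'_A / f'_I, and
#' when the measured reverse rate k_r is supplied (assumed complete: every
#' active-to-inactive transition is observed), the corrected forward rate is
#' k'_f = K'_eq k_r.
#'
#' @param f_a Observed active-state fraction in \[0, 1\].
#' @param c_factor Correction factor c in (0, 1\].
#' @param k_r Measured reverse rate (1/s), optional.
#' @return Object of class \code{occupancy_estimate}: \code{f_a_obs},
#'   \code{c}, \code{f_a_corr}, \code{f_i_corr}, \code{k_eq_corr}, and
#'   \code{k_f_corr} (NA without k_r).
#' @examples
#' correct_occupancy(0.5, 0.6)           # K'_eq = 0.3 / 0.7
#' correct_occupancy(0.5, 0.6, k_r = 1)  # k'_f = 0.4286
#' @export
correct_occupancy <- function(f_a, c_factor, k_r = NULL) {
  if (!is.numeric(f_a) || f_a < 0 || f_a > 1) stop("f_a must be in [0, 1]")
  if (!is.numeric(c_factor) || c_factor <= 0 || c_factor > 1)
    stop("c_factor must be in (0, 1]")
  f_a_corr <- c_factor * f_a
  # algebraically 1 - c*(1 - f_I) with f_I = 1 - f_A; written as the exact
  # complement so the corrected fractions sum to 1 to the last bit
  f_i_corr <- 1 - f_a_corr
  if (f_i_corr == 0) stop("corrected inactive fraction is zero: K'_eq infinite")
  k_eq <- f_a_corr / f_i_corr
  structure(list(f_a_obs = f_a, c = c_factor,
                 f_a_corr = f_a_corr, f_i_corr = f_i_corr,
                 k_eq_corr = k_eq,
                 k_r = k_r %||% NA_real_,
                 k_f_corr = if (is.null(k_r)) NA_real_ else k_eq * k_r),
            class = "occupancy_estimate")
}

#' @export
print.occupancy_estimate <- function(x, ...) {
  cat(sprintf("<occupancy_estimate> f_A = %.4g (observed), c = %.4g\n",
              x$f_a_obs, x$c))
  cat(sprintf("  corrected: f'_A = %.4g, f'_I = %.4g, K'_eq = %.4g\n",
              x$f_a_corr, x$f_i_corr, x$k_eq_corr))
  if (!is.na(x$k_f_corr))
    cat(sprintf("  k_r = %.4g /s  ->  k'_f = %.4g /s\n", x$k_r, x$k_f_corr))
  invisible(x)
}

#' Probability that both subunits are closed
#'
#' Under independent closure of the two ligand-binding clamshells, each with
#' probability p, the receptor has both clamshells closed with probability
#' p^2 (0.25 at p = 0.5).
#'
#' @param p Per-subunit closure probability in \[0, 1\].
#' @return p squared.
#' @export
both_closed_probability <- function(p) {
  if (any(!is.numeric(p)) || any(p < 0) || any(p > 1))
    stop("p must be in [0, 1]")
  p^2
}

#' State occupancies of a sequential gating scheme
#'
#' For a linear chain of conformational states connected by equilibrium
#' constants K_i (state i to state i+1), the occupancy of state i is
#' proportional to the product of the K_j for j < i, normalized to sum to 1.
#' Condition-specific K sets give condition-specific occupancy profiles.
#'
#' @param k_chain Numeric vector of equilibrium constants, length
#'   n_states - 1, all > 0.
#' @param state_labels Optional state names.
#' @return Named numeric vector of occupancies summing to 1.
#' @examples
#' gating_occupancies(rep(1, 5))   # six equally occupied states
#' gating_occupancies(0.4286)      # c(0.70, 0.30)
#' @export
gating_occupancies <- function(k_chain, state_labels = NULL) {
  if (any(!is.finite(k_chain)) || any(k_chain <= 0))
    stop("all equilibrium constants must be finite and > 0")
  occ <- cumprod(c(1, k_chain))
  occ <- occ / sum(occ)
  names(occ) <- state_labels %||% paste0("state_", seq_along(occ))
  occ
}

#' Convert FRET efficiency to dye-pair distance (and back)
#'
#' R = R0 ((1 - E) / E)^(1/6), the Foerster relation; at E = 0.5 the
#' distance equals the Foerster radius R0. `distance_to_fret` is the exact
#' inverse, E = 1 / (1 + (R / R0)^6).
#'
#' @param e FRET efficiency, strictly between 0 and 1.
#' @param r0 Foerster radius in Angstrom (> 0).
#' @return Distance in Angstrom.
#' @examples
#' fret_to_distance(0.85, 51)  # ~38.2 Angstrom
#' @export
fret_to_distance <- function(e, r0) {
  if (any(e <= 0) || any(e >= 1))
    stop("E must be strictly between 0 and 1 (distance diverges at the ends)")
  if (any(r0 <= 0)) stop("R0 must be > 0")
  r0 * ((1 - e) / e)^(1 / 6)
}

#' @rdname fret_to_distance
#' @param r Dye-pair distance in Angstrom (> 0).
#' @export
distance_to_fret <- function(r, r0) {
  if (any(r <= 0) || any(r0 <= 0)) stop("distances must be > 0")
  1 / (1 + (r / r0)^6)
}

#' Per-movie averaged FRET histogram
#'
#' Computes a density histogram per group of traces (typically one group per
#' movie) on a common grid and returns the across-group mean density with
#' its standard error, the presentation convention for smFRET population
#' histograms.
#'
#' @param traces A \code{fret_trace_set} or list of \code{fret_trace}.
#' @param groups Factor/vector assigning traces to movies; a single group
#'   pools everything.
#' @param bins Number of bins (default 40).
#' @param range Histogram range (default c(-0.1, 1.1)).
#' @return data.frame: bin_center, density (mean across groups), sem.
#' @export
fret_histogram <- function(traces, groups = NULL, bins = 40L,
                           range = c(-0.1, 1.1)) {
  traces <- as_trace_list(traces)
  if (is.null(groups)) groups <- rep(1L, length(traces))
  stopifnot(length(groups) == length(traces))
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  dens <- sapply(split(traces, groups), function(grp) {
    e <- unlist(lapply(grp, function(tr) tr$apparent_fret))
    e <- e[is.finite(e) & e >= range[1] & e <= range[2]]
    graphics::hist(e, breaks = breaks, plot = FALSE)$density
  })
  dens <- matrix(dens, nrow = bins)
  data.frame(
    bin_center = (breaks[-1] + breaks[-(bins + 1)]) / 2,
    density = rowMeans(dens),
    sem = if (ncol(dens) > 1L)
      apply(dens, 1L, stats::sd) / sqrt(ncol(dens)) else NA_real_)
}
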