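#' Fit a discrete-state hidden Markov model to FRET traces
#'
#' Pooled maximum-likelihood fit (Baum-Welch EM) of a Gaussian-emission HMM
#' shared across all supplied traces: one transition matrix, one initial
#' distribution, and per-state emission means and SDs. The best of
#' `n_restarts` random initializations is returned. States are relabelled in
#' ascending order of emission mean, so the high-FRET state is always the
#' last index.
#'
#' @param traces A \code{fret_trace_set}, list of \code{fret_trace}, or list
#'   of numeric vectors of apparent FRET values.
#' @param n_states Number of states (typically 2-4: 2 for a simple
#'   open/closed sensor, 3-4 when modulators or G protein add states).
#' @param n_restarts Number of random restarts (default 10).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations per restart.
#' @param seed Integer seed controlling restart initializations.
#' @return An object of class \code{hmm_fit}: \code{n_states},
#'   \code{emission_means}, \code{emission_sds} (ascending by mean),
#'   \code{transition_matrix} (row-stochastic per-frame probabilities),
#'   \code{initial_prob}, \code{log_likelihood}, \code{n_restarts},
#'   \code{converged}, \code{ll_trace} (per-iteration log-likelihood of the
#'   winning restart), \code{frame_period}.
#' @export
fit_hmm <- function(traces, n_states, n_restarts = 10L, tol = 1e-6,
                    max_iter = 500L, seed = 1L) {
  obs <- traces_to_matrix(traces)
  y <- obs$y; lens <- obs$lens
  if (any(lens < 2L)) stop("each trace must have at least 2 frames")
  pooled <- y[!is.na(y)]
  if (stats::sd(pooled) == 0)
    stop("degenerate data: pooled FRET signal has zero variance")
  K <- as.integer(n_states)
  if (K < 2L || K > 8L) stop("n_states must be between 2 and 8")

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- hmm_init(pooled, K, jitter = (r > 1L))
      fit <- try(hmm_em(y, lens, init, tol = tol, max_iter = max_iter),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
    }
  })
  if (is.null(best)) stop("all EM restarts failed")

  # relabel states ascending by emission mean
  ord <- order(best$mu)
  fit <- structure(list(
    n_states = K,
    emission_means = best$mu[ord],
    emission_sds = best$sigma[ord],
    transition_matrix = best$P[ord, ord, drop = FALSE],
    initial_prob = best$pi0[ord],
    log_likelihood = best$log_likelihood,
    n_restarts = n_restarts,
    converged = best$converged,
    ll_trace = best$ll_trace,
    frame_period = obs$frame_period), class = "hmm_fit")
  gaps <- diff(fit$emission_means)
  gap_scale <- pmin(fit$emission_sds[-K], fit$emission_sds[-1L])
  if (any(gaps < 2 * gap_scale))
    warning("fitted states overlap (means closer than twice the emission ",
            "SD); the data may support fewer states")
  fit
}

# Convert trace inputs to an NA-padded matrix (n_traces x max_len).
traces_to_matrix <- function(traces) {
  frame_period <- NA_real_
  if (inherits(traces, "fret_trace")) traces <- list(traces)
  if (inherits(traces, "fret_trace_set")) traces <- traces$traces
  stopifnot(is.list(traces), length(traces) >= 1L)
  vecs <- lapply(traces, function(tr) {
    if (inherits(tr, "fret_trace")) tr$apparent_fret else as.numeric(tr)
  })
  fp <- unique(unlist(lapply(traces, function(tr)
    if (inherits(tr, "fret_trace")) tr$frame_period else NULL)))
  if (length(fp) == 1L) frame_period <- fp
  vecs <- lapply(vecs, function(v) v[!is.na(v)])
  lens <- vapply(vecs, length, 1L)
  y <- matrix(NA_real_, length(vecs), max(lens))
  for (i in seq_along(vecs)) y[i, seq_len(lens[i])] <- vecs[[i]]
  list(y = y, lens = lens, frame_period = frame_period)
}

hmm_init <- function(pooled, K, jitter = TRUE) {
  qs <- stats::quantile(pooled, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  if (jitter) qs <- qs + stats::rnorm(K, 0, stats::sd(pooled) / 4)
  P <- matrix(0.1 / (K - 1), K, K)
  diag(P) <- 0.9
  list(mu = qs, sigma = rep(stats::sd(pooled) / 2, K),
       P = P, pi0 = rep(1 / K, K))
}

# Baum-Welch on an NA-padded observation matrix; padded cells use emission
# likelihood 1 so they contribute nothing (beta stays 1, scale stays 1), and
# sufficient statistics are accumulated only over real frames.
hmm_em <- function(y, lens, init, tol, max_iter) {
  n <- nrow(y); Tmax <- ncol(y); K <- length(init$mu)
  mu <- init$mu; sigma <- pmax(init$sigma, 1e-4)
  P <- init$P; pi0 <- init$pi0
  ll_old <- -Inf; ll_trace <- numeric(0)
  converged <- FALSE

  emis <- function(t) {
    e <- matrix(1, n, K)
    obs <- !is.na(y[, t])
    if (any(obs)) {
      yo <- y[obs, t]
      for (k in seq_len(K))
        e[obs, k] <- stats::dnorm(yo, mu[k], sigma[k])
    }
    # guard complete underflow
    bad <- rowSums(e) == 0
    e[bad, ] <- .Machine$double.xmin
    e
  }

  for (iter in seq_len(max_iter)) {
    # E-step: scaled forward-backward, vectorized over traces
    alpha <- array(0, c(n, K, Tmax))
    scales <- matrix(1, n, Tmax)
    B1 <- emis(1L)
    a <- sweep(B1, 2L, pi0, `*`)
    s <- rowSums(a); a <- a / s
    alpha[, , 1L] <- a; scales[, 1L] <- s
    Bs <- vector("list", Tmax); Bs[[1L]] <- B1
    for (t in 2:Tmax) {
      Bt <- emis(t)
      a <- (a %*% P) * Bt
      s <- rowSums(a)
      a <- a / s
      alpha[, , t] <- a; scales[, t] <- s; Bs[[t]] <- Bt
    }
    active <- outer(lens, seq_len(Tmax), `>=`)
    ll <- sum(log(scales)[active])

    beta <- matrix(1, n, K)
    gamma1 <- NULL
    # accumulate sufficient statistics on the backward pass
    xi_sum <- matrix(0, K, K)
    w_sum <- numeric(K); wy_sum <- numeric(K); wy2_sum <- numeric(K)
    g_last <- matrix(alpha[, , Tmax], n, K) * beta
    g_last <- g_last / rowSums(g_last)
    acc <- function(g, t) {
      obs <- active[, t]
      go <- g[obs, , drop = FALSE]; yo <- y[obs, t]
      w_sum <<- w_sum + colSums(go)
      wy_sum <<- wy_sum + colSums(go * yo)
      wy2_sum <<- wy2_sum + colSums(go * yo^2)
    }
    acc(g_last, Tmax)
    for (t in (Tmax - 1L):1L) {
      Bb <- Bs[[t + 1L]] * beta / scales[, t + 1L]  # n x K
      # transitions t -> t+1 counted for traces with len >= t+1
      obs2 <- active[, t + 1L]
      xi_sum <- xi_sum + P *
        (t(matrix(alpha[, , t], n, K)[obs2, , drop = FALSE]) %*%
           Bb[obs2, , drop = FALSE])
      beta <- Bb %*% t(P)  # beta-hat_t under Rabiner scaling (padded rows stay 1)
      g <- matrix(alpha[, , t], n, K) * beta
      g <- g / rowSums(g)
      acc(g, t)
      if (t == 1L) gamma1 <- g
    }
    if (is.null(gamma1)) gamma1 <- g_last

    # M-step
    pi0 <- colMeans(gamma1)
    P <- xi_sum / rowSums(xi_sum)
    P[!is.finite(P)] <- 1 / K
    mu <- wy_sum / w_sum
    sigma <- sqrt(pmax(wy2_sum / w_sum - mu^2, 1e-8))

    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && (ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, P = P, pi0 = pi0,
       log_likelihood = ll, ll_trace = ll_trace, converged = converged)
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> %d states, logLik %.2f, converged: %s\n",
              x$n_states, x$log_likelihood, x$converged))
  cat("  means:", paste(format(round(x$emission_means, 4)), collapse = ", "), "\n")
  cat("  sds:  ", paste(format(round(x$emission_sds, 4)), collapse = ", "), "\n")
  cat("  transition matrix (per frame):\n")
  print(round(x$transition_matrix, 4))
  invisible(x)
}

#' Most probable state path (Viterbi) under an HMM fit
#'
#' Deterministic global decoding of a single trace. Ties are broken toward
#' the lowest state index.
#'
#' @param trace A \code{fret_trace} or numeric vector of apparent FRET.
#' @param fit An \code{hmm_fit}.
#' @return An object of class \code{idealized_path}: \code{states} (per-frame
#'   indices, 1 = lowest mean), \code{dwells} (data.frame: state, start,
#'   n_frames), \code{frame_period}.
#' @export
viterbi <- function(trace, fit) {
  stopifnot(inherits(fit, "hmm_fit"))
  y <- if (inherits(trace, "fret_trace")) trace$apparent_fret else
    as.numeric(trace)
  fp <- if (inherits(trace, "fret_trace")) trace$frame_period else
    fit$frame_period
  y <- y[!is.na(y)]
  n <- length(y); K <- fit$n_states
  if (n == 0L) stop("empty trace")
  if (any(fit$emission_sds <= 0))
    stop("zero emission SD: Viterbi undefined off the emission support")
  logB <- vapply(seq_len(K), function(k)
    stats::dnorm(y, fit$emission_means[k], fit$emission_sds[k], log = TRUE),
    numeric(n))
  logB <- matrix(logB, n, K)
  logP <- log(fit$transition_matrix)
  delta <- matrix(-Inf, n, K)
  psi <- matrix(1L, n, K)
  delta[1L, ] <- log(fit$initial_prob) + logB[1L, ]
  for (t in 2:n) {
    cand <- delta[t - 1L, ] + logP  # K x K: from i (row) to j (col)
    psi[t, ] <- apply(cand, 2L, which.max)  # first max = lowest index
    delta[t, ] <- cand[cbind(psi[t, ], seq_len(K))] + logB[t, ]
  }
  states <- integer(n)
  states[n] <- which.max(delta[n, ])
  if (n > 1L) for (t in (n - 1L):1L) states[t] <- psi[t + 1L, states[t + 1L]]
  r <- rle(states)
  dwells <- data.frame(state = r$values,
                       start = cumsum(c(1L, r$lengths))[seq_along(r$lengths)],
                       n_frames = r$lengths)
  structure(list(states = states, dwells = dwells, frame_period = fp),
            class = "idealized_path")
}

#' Convert a per-frame transition probability to a rate constant
#'
#' Inverts P = 1 - exp(-k tau): k = -log(1 - P) / tau, the standard
#' conversion from an HMM's per-frame transition probability to a first-order
#' rate constant.
#'
#' @param p Transition probability in \[0, 1).
#' @param frame_period Frame duration tau in seconds.
#' @return Rate in 1/s.
#' @examples
#' prob_to_rate(1 - exp(-0.1), 0.1)  # 1
#' @export
prob_to_rate <- function(p, frame_period) {
  if (any(!is.finite(p)) || any(p < 0)) stop("P must be finite and >= 0")
  if (any(p >= 1)) stop("P >= 1 implies an infinite rate")
  if (frame_period <= 0) stop("frame_period must be > 0")
  -log(1 - p) / frame_period
}

#' Rate constants from a fitted HMM transition matrix
#'
#' Applies [prob_to_rate()] to every off-diagonal element.
#'
#' @param fit An \code{hmm_fit}.
#' @param frame_period Frame duration in seconds (defaults to the value
#'   recorded in the fit).
#' @return Matrix of rates (1/s); diagonal NA.
#' @export
hmm_rates <- function(fit, frame_period = fit$frame_period) {
  stopifnot(inherits(fit, "hmm_fit"))
  if (is.na(frame_period)) stop("frame_period unknown; supply it explicitly")
  K <- fit$n_states
  rates <- matrix(NA_real_, K, K)
  off <- row(rates) != col(rates)
  rates[off] <- prob_to_rate(fit$transition_matrix[off], frame_period)
  rates
}

#' Dwell-time statistics from idealized paths
#'
#' Collects dwell durations per state across paths, censoring the first and
#' last dwell of every trace (their true length is unknown), and reports the
#' mean dwell and the maximum-likelihood exponential escape rate 1/mean.
#'
#' @param paths A list of \code{idealized_path} (or a single one).
#' @return A list with \code{dwells} (data.frame: state, duration_s) and
#'   \code{rates} (data.frame: state, n_dwells, mean_dwell_s, rate_per_s).
#'   Empty (with a warning) if no uncensored dwells remain.
#' @export
dwell_statistics <- function(paths) {
  if (inherits(paths, "idealized_path")) paths <- list(paths)
  all_dw <- lapply(paths, function(p) {
    d <- p$dwells
    if (nrow(d) <= 2L) return(NULL)  # only censored dwells
    d <- d[-c(1L, nrow(d)), , drop = FALSE]
    data.frame(state = d$state, duration_s = d$n_frames * p$frame_period)
  })
  dw <- do.call(rbind, all_dw)
  if (is.null(dw) || nrow(dw) == 0L) {
    warning("no uncensored dwells; traces may lack transitions")
    return(list(dwells = data.frame(state = integer(), duration_s = numeric()),
                rates = data.frame(state = integer(), n_dwells = integer(),
                                   mean_dwell_s = numeric(),
                                   rate_per_s = numeric())))
  }
  agg <- stats::aggregate(duration_s ~ state, dw, function(x)
    c(n = length(x), mean = mean(x)))
  rates <- data.frame(state = agg$state,
                      n_dwells = agg$duration_s[, "n"],
                      mean_dwell_s = agg$duration_s[, "mean"],
                      rate_per_s = 1 / agg$duration_s[, "mean"])
  list(dwells = dw, rates = rates)
}
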