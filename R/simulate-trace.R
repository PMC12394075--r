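#' Simulate a camera-averaged single-molecule FRET trace
#'
#' Samples an exact continuous-time Markov chain path (exponential waiting
#' times, embedded-chain jumps) from the stationary distribution of `model`,
#' time-averages it over camera frames of length `frame_period`, and emits the
#' apparent FRET efficiency per frame: the occupancy-weighted mean of the
#' state emission means plus Gaussian noise of SD `model$noise_sd`. Donor and
#' acceptor channels are synthesized from a fixed total intensity so that
#' acceptor / (donor + acceptor) reproduces the apparent FRET exactly.
#'
#' When rates are fast relative to the frame rate (`frame_period * rate >> 1`)
#' the per-frame average collapses toward the stationary mean and the FRET
#' histogram becomes unimodal; when rates are slow it is bimodal at the state
#' means. This camera averaging is the regime distinction that motivates
#' sub-frame-resolution inference (see [infer_rates_global()]).
#'
#' @param model A [kinetic_model()].
#' @param n_frames Number of camera frames (>= 1).
#' @param frame_period Frame integration time tau in seconds.
#' @param seed Integer seed; identical (model, seed) give identical output.
#' @param bleach_rate Single-step photobleaching rate in 1/s, or NULL for no
#'   bleaching. Bleaching zeroes both channels (plus unit-SD background noise)
#'   from the bleach frame onward.
#' @param total_intensity Donor + acceptor intensity before bleaching (a.u.).
#' @param start_state Optional fixed initial state index; default samples the
#'   stationary distribution.
#' @return A list with components \code{trace} (class \code{fret_trace}:
#'   \code{frame_period}, \code{donor}, \code{acceptor}, \code{apparent_fret},
#'   \code{meta}) and \code{truth} (class \code{synthetic_truth}: the model,
#'   jump times/states of the latent path, per-frame per-state occupancy
#'   fraction matrix \code{occupancy}, \code{f_high} = occupancy of the
#'   highest-FRET state, and \code{bleach_frame} or NA).
#' @examples
#' sim <- simulate_trace(two_state_model(1, 1), n_frames = 100,
#'                       frame_period = 0.1, seed = 7)
#' mean(sim$truth$f_high)
#' @export
simulate_trace <- function(model, n_frames, frame_period, seed = NULL,
                           bleach_rate = NULL, total_intensity = 500,
                           start_state = NULL) {
  stopifnot(inherits(model, "kinetic_model"))
  if (!is.numeric(n_frames) || n_frames < 1)
    stop("n_frames must be >= 1")
  if (!is.numeric(frame_period) || frame_period <= 0)
    stop("frame_period must be > 0")
  if (!is.null(bleach_rate) && (!is.finite(bleach_rate) || bleach_rate < 0))
    stop("bleach_rate must be non-negative")
  n_frames <- as.integer(n_frames)

  with_seed(seed, {
    t_end <- n_frames * frame_period
    path <- sample_ctmc_path(model, t_end, start_state)
    occ <- frame_occupancy(path, n_frames, frame_period, model$n_states)
    e_mean <- drop(occ %*% model$emission_means)
    e_obs <- e_mean + stats::rnorm(n_frames, 0, model$noise_sd)

    acceptor <- e_obs * total_intensity
    donor <- total_intensity - acceptor

    bleach_frame <- NA_integer_
    if (!is.null(bleach_rate) && bleach_rate > 0) {
      t_bleach <- stats::rexp(1L, bleach_rate)
      if (t_bleach < t_end) {
        bleach_frame <- as.integer(floor(t_bleach / frame_period)) + 1L
        dark <- bleach_frame:n_frames
        donor[dark] <- stats::rnorm(length(dark), 0, 1)
        acceptor[dark] <- stats::rnorm(length(dark), 0, 1)
      }
    }

    tot <- donor + acceptor
    apparent <- ifelse(tot > 0, acceptor / tot, NA_real_)

    trace <- structure(
      list(frame_period = frame_period, donor = donor, acceptor = acceptor,
           apparent_fret = apparent,
           meta = list(trace_id = NA_character_, condition = NA_character_,
                       seed = seed)),
      class = "fret_trace")
    truth <- structure(
      list(model = model, jump_times = path$times, jump_states = path$states,
           occupancy = occ, f_high = occ[, model$n_states],
           bleach_frame = bleach_frame),
      class = "synthetic_truth")
    list(trace = trace, truth = truth)
  })
}

# Exact CTMC path on [0, t_end]: returns entry times and states, first entry
# at time 0. Uses the embedded jump chain with exponential holding times.
sample_ctmc_path <- function(model, t_end, start_state = NULL) {
  Q <- model$rate_matrix
  n <- model$n_states
  exit_rate <- -diag(Q)
  jump_prob <- Q
  diag(jump_prob) <- 0
  for (i in seq_len(n))
    if (exit_rate[i] > 0) jump_prob[i, ] <- jump_prob[i, ] / exit_rate[i]

  s0 <- if (is.null(start_state)) {
    sample.int(n, 1L, prob = stationary_distribution(model))
  } else as.integer(start_state)

  cap <- max(16L, as.integer(2 * t_end * max(exit_rate) + 10 * sqrt(t_end * max(exit_rate) + 1)))
  times <- numeric(cap); states <- integer(cap)
  times[1L] <- 0; states[1L] <- s0
  m <- 1L; t_cur <- 0; s_cur <- s0
  repeat {
    if (exit_rate[s_cur] <= 0) break  # absorbing
    t_cur <- t_cur + stats::rexp(1L, exit_rate[s_cur])
    if (t_cur >= t_end) break
    s_cur <- if (n == 2L) 3L - s_cur else
      sample.int(n, 1L, prob = jump_prob[s_cur, ])
    m <- m + 1L
    if (m > length(times)) {
      times <- c(times, numeric(length(times)))
      states <- c(states, integer(length(states)))
    }
    times[m] <- t_cur; states[m] <- s_cur
  }
  list(times = times[seq_len(m)], states = states[seq_len(m)])
}

# Fraction of each frame spent in each state, given a jump path.
frame_occupancy <- function(path, n_frames, frame_period, n_states) {
  t_end <- n_frames * frame_period
  bounds <- frame_period * (seq_len(n_frames) - 1L)
  starts <- sort(unique(c(path$times, bounds)))
  ends <- c(starts[-1L], t_end)
  seg_state <- path$states[findInterval(starts, path$times)]
  # frame index via the same boundary values used to split the segments, so
  # floating-point drift cannot push a boundary segment into the wrong frame
  seg_frame <- findInterval(starts, bounds)
  dur <- ends - starts
  occ <- matrix(0, n_frames, n_states)
  occ_acc <- rowsum(dur, group = (seg_frame - 1L) * n_states + seg_state)
  keys <- as.integer(rownames(occ_acc))
  occ[cbind((keys - 1L) %/% n_states + 1L, (keys - 1L) %% n_states + 1L)] <-
    occ_acc[, 1L]
  occ <- occ / frame_period
  occ[occ < 0] <- 0  # guard sub-ulp drift from the duration arithmetic
  occ[occ > 1] <- 1
  occ
}

#' Simulate a reproducible set of FRET traces
#'
#' Generates `n_traces` traces from one model. Per-trace seeds are derived
#' from the master seed by a counter-based scheme, so any subset of the set
#' can be regenerated independently.
#'
#' @inheritParams simulate_trace
#' @param n_traces Number of traces.
#' @param condition Condition label stored in each trace's metadata.
#' @return A list of class \code{fret_trace_set}: elements \code{traces}
#'   (list of \code{fret_trace}), \code{truths}, and \code{manifest}
#'   (data.frame: trace_id, condition, frame_period_s, seed, bleach_frame).
#' @export
simulate_trace_set <- function(model, n_traces, n_frames, frame_period,
                               seed, bleach_rate = NULL,
                               condition = "synthetic",
                               total_intensity = 500) {
  traces <- vector("list", n_traces)
  truths <- vector("list", n_traces)
  ids <- sprintf("trace_%04d", seq_len(n_traces))
  seeds <- vapply(seq_len(n_traces), function(i) derive_seed(seed, i), 1L)
  for (i in seq_len(n_traces)) {
    sim <- simulate_trace(model, n_frames, frame_period, seed = seeds[i],
                          bleach_rate = bleach_rate,
                          total_intensity = total_intensity)
    sim$trace$meta$trace_id <- ids[i]
    sim$trace$meta$condition <- condition
    traces[[i]] <- sim$trace
    truths[[i]] <- sim$truth
  }
  manifest <- data.frame(
    trace_id = ids, condition = condition, frame_period_s = frame_period,
    seed = seeds,
    bleach_frame = vapply(truths, function(tr) tr$bleach_frame, 1L),
    stringsAsFactors = FALSE)
  structure(list(traces = traces, truths = truths, manifest = manifest),
            class = "fret_trace_set")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace> %d frames @ %g s  (id: %s, condition: %s)\n",
              length(x$donor), x$frame_period,
              x$meta$trace_id, x$meta$condition))
  invisible(x)
}

#' @export
length.fret_trace <- function(x) length(x$donor)

#' Pool apparent-FRET values from traces
#'
#' @param traces A \code{fret_trace_set}, list of \code{fret_trace}, or a
#'   single trace.
#' @param drop_na Drop frames with undefined apparent FRET (bleached frames
#'   with non-positive total intensity).
#' @return Numeric vector of pooled per-frame apparent FRET efficiencies.
#' @export
pool_fret <- function(traces, drop_na = TRUE) {
  traces <- as_trace_list(traces)
  e <- unlist(lapply(traces, function(tr) tr$apparent_fret), use.names = FALSE)
  if (drop_na) e <- e[!is.na(e)]
  e
}

as_trace_list <- function(traces) {
  if (inherits(traces, "fret_trace")) return(list(traces))
  if (inherits(traces, "fret_trace_set")) return(traces$traces)
  stopifnot(is.list(traces))
  traces
}
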