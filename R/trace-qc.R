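#' Intensity thresholds for photobleach detection
#'
#' A frame is "dark" when acceptor < `acceptor_min`, or donor < `donor_min`,
#' or donor + acceptor < `total_min`. Defaults follow common practice for
#' camera-based smFRET quality control (5, 5, 10 a.u.).
#'
#' @param acceptor_min,donor_min,total_min Intensity thresholds in a.u.
#' @return An object of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(acceptor_min = 5, donor_min = 5, total_min = 10) {
  stopifnot(is.finite(acceptor_min), is.finite(donor_min), is.finite(total_min))
  structure(list(acceptor_min = acceptor_min, donor_min = donor_min,
                 total_min = total_min), class = "qc_thresholds")
}

#' Truncate a trace at photobleaching
#'
#' Returns the longest prefix of the trace ending before the first frame at
#' which the dark condition (any threshold violated) holds for at least
#' `k_persist` consecutive frames. The persistence requirement prevents
#' truncation at single noisy frames. If the trace is dark from the first
#' frame, an empty trace is returned with attribute \code{rejected = TRUE}
#' and \code{rejected_reason}.
#'
#' @param trace A \code{fret_trace}.
#' @param thr A [qc_thresholds()].
#' @param k_persist Minimum run length of dark frames that counts as a
#'   bleaching event (default 3).
#' @return The trimmed \code{fret_trace}; attribute \code{trimmed_at} gives
#'   the first dark frame index (NA if untrimmed).
#' @export
trim_photobleach <- function(trace, thr = qc_thresholds(), k_persist = 3L) {
  stopifnot(inherits(trace, "fret_trace"), inherits(thr, "qc_thresholds"))
  n <- length(trace$donor)
  if (n == 0L) stop("empty trace")
  dark <- trace$acceptor < thr$acceptor_min |
    trace$donor < thr$donor_min |
    (trace$donor + trace$acceptor) < thr$total_min
  cut_at <- first_run_start(dark, k_persist)
  if (is.na(cut_at)) return(trace)
  keep <- seq_len(cut_at - 1L)
  out <- trace
  out$donor <- trace$donor[keep]
  out$acceptor <- trace$acceptor[keep]
  out$apparent_fret <- trace$apparent_fret[keep]
  attr(out, "trimmed_at") <- cut_at
  if (cut_at == 1L) {
    attr(out, "rejected") <- TRUE
    attr(out, "rejected_reason") <- "all frames below intensity thresholds"
  }
  out
}

# Index of the first element of the first TRUE-run of length >= k, else NA.
first_run_start <- function(flag, k) {
  r <- rle(flag)
  hit <- which(r$values & r$lengths >= k)
  if (!length(hit)) return(NA_integer_)
  idx <- cumsum(c(1L, r$lengths))
  idx[hit[1L]]
}

#' Missed-trace correction factor from trace counts
#'
#' The correction factor c = n / n_reference, where n is the number of traces
#' passing selection in a condition of interest and n_reference the number in
#' the saturating-ligand reference condition, assumed free of excluded traces.
#' Values above 1 are kept but warned about (more traces than reference).
#'
#' @param n_condition Trace count for the condition of interest.
#' @param n_reference Trace count for the reference (saturating) condition.
#' @return The correction factor c (unitless).
#' @seealso [correct_occupancy()] which consumes c.
#' @examples
#' count_ratio(600, 1000)  # 0.6
#' @export
count_ratio <- function(n_condition, n_reference) {
  if (!is.numeric(n_reference) || n_reference <= 0)
    stop("reference trace count must be > 0")
  c_val <- n_condition / n_reference
  if (c_val > 1)
    warning(sprintf("correction factor %.3f > 1; more traces than reference",
                    c_val))
  c_val
}

#' Apply QC to a trace set
#'
#' Trims every trace at photobleaching and drops traces that are rejected or
#' shorter than `min_frames` after trimming (too short for dwell statistics).
#'
#' @param traces A \code{fret_trace_set} or list of \code{fret_trace}.
#' @param thr A [qc_thresholds()].
#' @param k_persist Dark-run persistence, see [trim_photobleach()].
#' @param min_frames Minimum post-trim length to keep a trace (default 50).
#' @return A list with \code{traces} (kept, trimmed) and \code{report}
#'   (data.frame: trace_id, kept_frames, rejected_reason).
#' @export
qc_traces <- function(traces, thr = qc_thresholds(), k_persist = 3L,
                      min_frames = 50L) {
  traces <- as_trace_list(traces)
  trimmed <- lapply(traces, trim_photobleach, thr = thr, k_persist = k_persist)
  kept_frames <- vapply(trimmed, length, 1L)
  reason <- rep(NA_character_, length(trimmed))
  reason[vapply(trimmed, function(x) isTRUE(attr(x, "rejected")), TRUE)] <-
    "below intensity thresholds"
  reason[is.na(reason) & kept_frames < min_frames] <- "too short after trim"
  report <- data.frame(
    trace_id = vapply(traces, function(x) x$meta$trace_id %||% NA_character_,
                      ""),
    kept_frames = kept_frames,
    rejected_reason = reason,
    stringsAsFactors = FALSE)
  list(traces = trimmed[is.na(reason)], report = report)
}
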