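# Differential hydrogen-deuterium exchange analysis. The working table is a
# tidy data.frame with columns: start, end, sequence, timepoint (s),
# condition, replicate, percent_d.

#' Simulate an HDX-MS uptake table with known protection
#'
#' Generates per-peptide, per-condition uptake curves of the saturating form
#' %D(t) = (plateau - protection) * s(t), where s(t) is a normalized
#' exponential approach to 1 at the longest timepoint, so that the
#' between-condition difference at the longest timepoint equals the
#' requested protection exactly (in expectation). Gaussian replicate noise
#' is added on the %D scale.
#'
#' @param peptides data.frame with columns start, end and optionally
#'   sequence, plateau (max %D, default 80) and t50 (time to half
#'   saturation, s; default scales with peptide length).
#' @param protection data.frame with columns start, end, condition, delta
#'   (%D removed at the longest timepoint; 0 rows mean no protection
#'   anywhere).
#' @param conditions Character vector of condition labels.
#' @param timepoints Increasing exchange times in seconds (default a
#'   log-spaced grid ending at 13200 s).
#' @param noise_sd Replicate noise SD in %D.
#' @param replicates Replicates per condition/timepoint.
#' @param seed Integer seed.
#' @return A tidy uptake data.frame as described above.
#' @export
simulate_uptake_table <- function(peptides, protection = NULL,
                                  conditions = c("apo", "glu"),
                                  timepoints = c(30, 120, 600, 3600, 13200),
                                  noise_sd = 1, replicates = 3L, seed = 1L) {
  if (nrow(peptides) == 0L) stop("empty peptide set")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  peptides$sequence <- peptides$sequence %||%
    vapply(peptides$end - peptides$start + 1L,
           function(n) paste(rep("A", n), collapse = ""), "")
  peptides$plateau <- peptides$plateau %||% rep(80, nrow(peptides))
  peptides$t50 <- peptides$t50 %||%
    (60 * (peptides$end - peptides$start + 1L))
  if (any(peptides$plateau < 0 | peptides$plateau > 100))
    stop("plateau %D targets must lie in [0, 100]")
  t_max <- max(timepoints)

  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(peptides))) {
      p <- peptides[i, ]
      k_ex <- log(2) / p$t50
      s_t <- (1 - exp(-k_ex * timepoints)) / (1 - exp(-k_ex * t_max))
      for (cond in conditions) {
        delta <- 0
        if (!is.null(protection) && nrow(protection)) {
          hit <- protection$start == p$start & protection$end == p$end &
            protection$condition == cond
          if (any(hit)) delta <- sum(protection$delta[hit])
        }
        mean_d <- pmax(p$plateau - delta, 0) * s_t
        for (r in seq_len(replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = p$start, end = p$end, sequence = p$sequence,
            timepoint = timepoints, condition = cond, replicate = r,
            percent_d = pmax(mean_d + stats::rnorm(length(timepoints),
                                                   0, noise_sd), 0),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Adjust uptake for incomplete maximal labelling
#'
#' Divides measured %D by the maximal-deuteration fraction of the labelling
#' buffer (default 0.90), the standard back-exchange adjustment. Values
#' exceeding 100 after adjustment are capped at 100 with a warning.
#'
#' @param table Tidy uptake data.frame with a percent_d column.
#' @param max_label_fraction Maximal deuteration fraction in (0, 1].
#' @return The table with adjusted percent_d.
#' @examples
#' df <- data.frame(percent_d = 45)
#' normalize_max_deuteration(df)$percent_d  # 50
#' @export
normalize_max_deuteration <- function(table, max_label_fraction = 0.90) {
  if (!is.numeric(max_label_fraction) || max_label_fraction <= 0 ||
      max_label_fraction > 1)
    stop("max_label_fraction must be in (0, 1]")
  d <- table$percent_d / max_label_fraction
  if (any(d > 100)) {
    warning(sprintf("%d adjusted uptake value(s) exceed 100%%; capped",
                    sum(d > 100)))
    d <- pmin(d, 100)
  }
  table$percent_d <- d
  table
}

#' Woods-plot table of per-peptide deuteration differences
#'
#' For every peptide (keyed by start, end, sequence) and timepoint present
#' in both conditions, computes the replicate-mean difference
#' delta = mean(%D in B) - mean(%D in A). Negative values mean increased
#' protection in condition B. Peptides are classified "unchanged" when
#' |delta| <= threshold (boundary inclusive; default 10 %D), otherwise
#' "protected" (delta < 0) or "deprotected" (delta > 0). Peptides missing
#' one condition are skipped with a message.
#'
#' @param table Tidy uptake data.frame.
#' @param condition_a,condition_b Condition labels (difference is B - A).
#' @param timepoints Timepoints to evaluate (default: all shared ones).
#' @param threshold Gray-zone half-width in %D (default 10).
#' @return data.frame: start, end, sequence, timepoint, delta_pct_d,
#'   classification.
#' @export
woods_table <- function(table, condition_a, condition_b, timepoints = NULL,
                        threshold = 10) {
  need <- c("start", "end", "sequence", "timepoint", "condition", "percent_d")
  if (!all(need %in% names(table)))
    stop("uptake table must have columns ", paste(need, collapse = ", "))
  tp <- timepoints %||% sort(unique(table$timepoint))
  tab <- table[table$timepoint %in% tp &
                 table$condition %in% c(condition_a, condition_b), ]
  key <- interaction(tab$start, tab$end, tab$sequence, tab$timepoint,
                     drop = TRUE)
  out <- lapply(split(tab, key), function(g) {
    a <- g$percent_d[g$condition == condition_a]
    b <- g$percent_d[g$condition == condition_b]
    if (!length(a) || !length(b)) {
      message(sprintf("peptide %d-%d @ %gs missing a condition; skipped",
                      g$start[1L], g$end[1L], g$timepoint[1L]))
      return(NULL)
    }
    delta <- mean(b) - mean(a)
    data.frame(start = g$start[1L], end = g$end[1L],
               sequence = g$sequence[1L], timepoint = g$timepoint[1L],
               delta_pct_d = delta,
               classification = if (abs(delta) <= threshold) "unchanged"
               else if (delta < 0) "protected" else "deprotected",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      sequence = character(), timepoint = numeric(),
                      delta_pct_d = numeric(), classification = character()))
  out <- out[order(out$start, out$end, out$timepoint), ]
  rownames(out) <- NULL
  out
}

#' Replicate-averaged uptake curve for one peptide
#'
#' Mean and SD of %D across replicates per timepoint for a peptide in one
#' condition. A single replicate reports SD as NA. A non-monotonic mean
#' uptake curve (possible EX1 behaviour or back-exchange artifact) sets the
#' \code{nonmonotonic} attribute without altering values.
#'
#' @param table Tidy uptake data.frame.
#' @param start,end Peptide bounds.
#' @param condition Condition label.
#' @return data.frame: timepoint, mean_pct_d, sd_pct_d, n; attribute
#'   \code{nonmonotonic} TRUE/FALSE.
#' @export
uptake_curve <- function(table, start, end, condition) {
  g <- table[table$start == start & table$end == end &
               table$condition == condition, ]
  if (nrow(g) == 0L)
    stop(sprintf("no uptake records for peptide %d-%d in condition %s",
                 start, end, condition))
  sp <- split(g$percent_d, g$timepoint)
  out <- data.frame(
    timepoint = as.numeric(names(sp)),
    mean_pct_d = vapply(sp, mean, 1),
    sd_pct_d = vapply(sp, function(x)
      if (length(x) > 1L) stats::sd(x) else NA_real_, 1),
    n = vapply(sp, length, 1L))
  out <- out[order(out$timepoint), ]
  rownames(out) <- NULL
  attr(out, "nonmonotonic") <- is.unsorted(out$mean_pct_d)
  out
}
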