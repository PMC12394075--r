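# Plain-text persistence for trace sets: one tab-separated file per trace
# (frame_index, donor, acceptor), a manifest CSV, and a ground-truth JSON.

#' Write a trace set to disk
#'
#' @param set A \code{fret_trace_set}.
#' @param dir Output directory (created if needed).
#' @param write_truth Also write the generator ground truth (rates,
#'   emissions, noise, bleach frames) as truth.json.
#' @return Invisibly, the manifest with a `file` column added.
#' @export
write_trace_set <- function(set, dir, write_truth = TRUE) {
  stopifnot(inherits(set, "fret_trace_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, paste0(set$manifest$trace_id, ".tsv"))
  for (i in seq_along(set$traces)) {
    tr <- set$traces[[i]]
    utils::write.table(
      data.frame(frame_index = seq_along(tr$donor),
                 donor = tr$donor, acceptor = tr$acceptor),
      files[i], sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest <- set$manifest
  manifest$file <- basename(files)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (write_truth) {
    truth0 <- set$truths[[1L]]
    truth <- list(
      n_states = truth0$model$n_states,
      emission_means = truth0$model$emission_means,
      noise_sd = truth0$model$noise_sd,
      rate_matrix = truth0$model$rate_matrix,
      bleach_frames = manifest$bleach_frame)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}

#' Read a trace set written by [write_trace_set()]
#'
#' @param dir Directory containing manifest.csv and per-trace TSV files.
#' @return A \code{fret_trace_set} (without ground truth).
#' @export
read_trace_set <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  traces <- lapply(seq_len(nrow(manifest)), function(i) {
    d <- utils::read.table(file.path(dir, manifest$file[i]), header = TRUE,
                           sep = "\t")
    tot <- d$donor + d$acceptor
    structure(
      list(frame_period = manifest$frame_period_s[i],
           donor = d$donor, acceptor = d$acceptor,
           apparent_fret = ifelse(tot > 0, d$acceptor / tot, NA_real_),
           meta = list(trace_id = manifest$trace_id[i],
                       condition = manifest$condition[i],
                       seed = manifest$seed[i])),
      class = "fret_trace")
  })
  structure(list(traces = traces, truths = NULL, manifest = manifest),
            class = "fret_trace_set")
}
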