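# Internal helpers shared across modules.

# Numerically stable log(sum(exp(x))) over matrix rows. max.col is much
# faster than apply(m, 1, max) and this sits in the MCMC hot path.
row_logsumexp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based per-item seed derivation: reproducible regardless of how a
# trace set is partitioned for generation. Kept inside 32-bit signed range.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + as.numeric(counter)) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
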