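#' Continuous-time Markov model of conformational exchange
#'
#' Defines the ground-truth kinetic scheme used by the trace simulator: a
#' continuous-time Markov chain (CTMC) over `n_states` conformations, each
#' emitting an apparent FRET efficiency drawn from a Gaussian centred on the
#' state's emission mean.
#'
#' @param emission_means Numeric vector of per-state apparent-FRET means
#'   (ascending order enforced), each within \[-0.2, 1.2\].
#' @param rate_matrix Square matrix of transition rates in 1/s; off-diagonal
#'   entry \code{[i, j]} is the rate from state i to state j. The diagonal is
#'   ignored and recomputed as minus the row sum.
#' @param noise_sd Per-frame Gaussian noise SD on the apparent FRET signal
#'   (a single shared value, unitless).
#' @return An object of class \code{kinetic_model} with elements
#'   \code{n_states}, \code{emission_means}, \code{noise_sd},
#'   \code{rate_matrix} (generator with proper diagonal).
#' @seealso [two_state_model()] for the common two-state case,
#'   [stationary_distribution()].
#' @export
kinetic_model <- function(emission_means, rate_matrix, noise_sd = 0.05) {
  emission_means <- as.numeric(emission_means)
  n <- length(emission_means)
  if (n < 2L) stop("a kinetic model needs at least 2 states")
  if (any(!is.finite(emission_means)) ||
      any(emission_means < -0.2) || any(emission_means > 1.2))
    stop("emission means must be finite and within [-0.2, 1.2]")
  if (is.unsorted(emission_means, strictly = FALSE))
    stop("emission means must be in ascending order (low-FRET state first)")
  if (!is.matrix(rate_matrix) || any(dim(rate_matrix) != n))
    stop("rate_matrix must be an n_states x n_states matrix")
  off <- rate_matrix[row(rate_matrix) != col(rate_matrix)]
  if (any(!is.finite(off)) || any(off < 0))
    stop("off-diagonal transition rates must be finite and non-negative")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be finite and non-negative")
  Q <- rate_matrix
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(
    list(n_states = n, emission_means = emission_means,
         noise_sd = noise_sd, rate_matrix = Q),
    class = "kinetic_model"
  )
}

#' Two-state exchange model
#'
#' Convenience constructor for the two-state open/closed scheme: `k_f` is the
#' forward rate (low-FRET to high-FRET state) and `k_r` the reverse rate.
#' The stationary occupancy of the high-FRET state is `k_f / (k_f + k_r)`.
#'
#' @param k_f Forward rate, low to high state, 1/s.
#' @param k_r Reverse rate, high to low state, 1/s.
#' @param emission_means Length-2 vector of state FRET means (low, high).
#' @param noise_sd Per-frame Gaussian noise SD.
#' @return A \code{kinetic_model}.
#' @examples
#' m <- two_state_model(k_f = 3, k_r = 1)
#' stationary_distribution(m)  # c(0.25, 0.75)
#' @export
two_state_model <- function(k_f, k_r, emission_means = c(0.38, 0.63),
                            noise_sd = 0.05) {
  kinetic_model(emission_means,
                matrix(c(0, k_f, k_r, 0), 2L, 2L, byrow = TRUE),
                noise_sd)
}

#' Stationary distribution of a kinetic model
#'
#' Solves pi Q = 0 with sum(pi) = 1 for the model's generator. For a two-state
#' model this equals \code{c(k_r, k_f) / (k_f + k_r)} exactly.
#'
#' @param model A \code{kinetic_model}.
#' @return Numeric vector of stationary state occupancies summing to 1.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  Q <- model$rate_matrix
  n <- model$n_states
  if (n == 2L) {
    kf <- Q[1L, 2L]; kr <- Q[2L, 1L]
    if (kf + kr == 0) return(c(0.5, 0.5))
    return(c(kr, kf) / (kf + kr))
  }
  # Solve the augmented system t(Q) pi = 0, 1' pi = 1 by least squares.
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat <- pmax(pi_hat, 0)
  pi_hat / sum(pi_hat)
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> %d states\n", x$n_states))
  cat("  emission means:", paste(format(x$emission_means), collapse = ", "), "\n")
  cat("  noise sd:      ", format(x$noise_sd), "\n")
  cat("  stationary:    ",
      paste(format(round(stationary_distribution(x), 4)), collapse = ", "), "\n")
  invisible(x)
}
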