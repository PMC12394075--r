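# Synthetic coordinate frames with known geometry, for exercising the
# structural metrics without any downloaded structures.

#' Build an atom-record table from explicit coordinates
#'
#' @param chain,resno,elety Vectors (recycled) of chain ids, residue numbers
#'   and atom names.
#' @param xyz n x 3 matrix of coordinates (Angstrom).
#' @param resid Residue name (default "ALA").
#' @param element Element symbols (default guessed from atom name).
#' @return An atom-record data.frame usable by all struct metrics.
#' @export
toy_atoms <- function(chain, resno, elety, xyz, resid = "ALA",
                      element = NULL) {
  xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  data.frame(chain = rep_len(chain, n), resno = rep_len(resno, n),
             resid = rep_len(resid, n), elety = rep_len(elety, n),
             element = rep_len(element %||% guess_element(rep_len(elety, n)), n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Ideal helix Calpha coordinates
#'
#' Generates Calpha positions of an ideal alpha helix (rise 1.5 Angstrom,
#' 100 degrees per residue, radius 2.3 Angstrom) along a given axis. With
#' `radius = 0` the points are collinear along the axis, which makes the
#' principal axis exact (a finite helix always tilts the first principal
#' component slightly, because the axial coordinate correlates with the
#' winding phase).
#'
#' @param n_res Number of residues.
#' @param start First residue number.
#' @param chain Chain id.
#' @param axis Length-3 axis direction (normalized internally).
#' @param origin Length-3 origin.
#' @param radius Helix radius in Angstrom (default 2.3).
#' @param rise Rise per residue in Angstrom (default 1.5).
#' @return An atom-record data.frame of Calpha atoms.
#' @export
toy_helix <- function(n_res, start = 1L, chain = "A",
                      axis = c(0, 0, 1), origin = c(0, 0, 0),
                      radius = 2.3, rise = 1.5) {
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame around the axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  i <- seq_len(n_res) - 1L
  ang <- i * 100 * pi / 180
  xyz <- t(vapply(seq_along(i), function(j)
    origin + rise * i[j] * axis +
      radius * (cos(ang[j]) * u + sin(ang[j]) * v),
    numeric(3)))
  toy_atoms(chain, start + i, "CA", xyz)
}

#' Jittered copies of a base frame
#'
#' Emits `n_frames` copies of a base atom table with isotropic Gaussian
#' coordinate jitter of SD `jitter_sd`; with zero jitter all frames are
#' identical (so every RMSF is zero and all distances are exact).
#'
#' @param atoms Base atom-record data.frame (e.g. from [toy_atoms()]).
#' @param n_frames Number of frames.
#' @param jitter_sd Isotropic per-coordinate Gaussian SD, Angstrom.
#' @param seed Integer seed.
#' @return A list of atom-record data.frames.
#' @export
make_toy_frames <- function(atoms, n_frames = 1L, jitter_sd = 0, seed = NULL) {
  validate_frame(atoms)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      fr <- atoms
      if (jitter_sd > 0) {
        n <- nrow(fr)
        fr$x <- fr$x + stats::rnorm(n, 0, jitter_sd)
        fr$y <- fr$y + stats::rnorm(n, 0, jitter_sd)
        fr$z <- fr$z + stats::rnorm(n, 0, jitter_sd)
      }
      fr
    })
  })
}

#' Apply a rigid-body motion to a frame
#'
#' Rotates (about the origin) then translates all atom coordinates; useful
#' for asserting the rigid-motion invariance of geometric observables.
#'
#' @param frame An atom-record data.frame.
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation Length-3 translation vector (default zero).
#' @return The transformed frame.
#' @export
transform_frame <- function(frame, rotation = diag(3), translation = c(0, 0, 0)) {
  validate_frame(frame)
  co <- as.matrix(frame[, c("x", "y", "z")]) %*% t(rotation)
  frame$x <- co[, 1] + translation[1]
  frame$y <- co[, 2] + translation[2]
  frame$z <- co[, 3] + translation[3]
  frame
}

#' Random rotation matrix
#'
#' Uniform random 3D rotation (QR of a Gaussian matrix with sign fix).
#'
#' @param seed Integer seed.
#' @return A 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  with_seed(seed, {
    qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
    q <- qr.Q(qr_dec)
    d <- sign(diag(qr.R(qr_dec)))
    q <- q %*% diag(d)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}
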