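# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# a toy dimer: two point-cloud "lobes" per chain with known COM separation,
# plus a reporter Calpha pair at a known distance
toy_dimer <- function(com_sep = 57, pair_dist = 38.2) {
  cloud <- function(center) {
    # 4 unit-mass points symmetric about the center: COM = center exactly
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
    sweep(offs, 2L, center, `+`)
  }
  rbind(
    toy_atoms("A", 200:203, "CA", cloud(c(0, 0, 0)), element = "C"),
    toy_atoms("B", 200:203, "CA", cloud(c(com_sep, 0, 0)), element = "C"),
    toy_atoms("A", 500, "CA", matrix(c(0, 20, 0), 1), element = "C"),
    toy_atoms("B", 500, "CA", matrix(c(pair_dist, 20, 0), 1), element = "C")
  )
}

# peptide table for HDX simulations
toy_peptides <- function() {
  data.frame(start = c(55, 147, 216, 290),
             end = c(62, 157, 226, 300))
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("%s within %g of %s",
                              paste(signif(actual, 5), collapse = ","), tol,
                              paste(signif(expected, 5), collapse = ",")))
}

# Analytic CDF of the occupancy-fraction law on a grid (atoms + trapezoid
# integral of the continuous part), used for KS-style comparisons
occ_cdf <- function(x, k1, k2, tau, n_grid = 8001L) {
  g <- seq(0, 1, length.out = n_grid)
  d <- occupancy_fraction_density(g, k1, k2, tau)
  cum <- c(0, cumsum((d$density[-1] + d$density[-n_grid]) / 2 * diff(g)))
  sapply(x, function(xx) {
    d$point_mass_0 + stats::approx(g, cum, xx, rule = 2)$y +
      if (xx >= 1) d$point_mass_1 else 0
  })
}

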