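test_that("pair and clamshell distances reproduce constructed geometry", {
  fr <- toy_dimer()
  expect_equal(pair_distance(fr, "A", 500, "B", 500), 38.2)
  at <- rbind(toy_atoms("A", 144, "CA", matrix(c(0, 0, 0), 1)),
              toy_atoms("A", 272, "CA", matrix(c(0, 0, 12.5), 1)))
  expect_equal(clamshell_distance(at, "A"), 12.5)
  # identical points give zero
  at2 <- rbind(toy_atoms("A", 1, "CA", matrix(0, 1, 3)),
               toy_atoms("B", 1, "CA", matrix(0, 1, 3)))
  expect_equal(pair_distance(at2, "A", 1, "B", 1), 0)
  expect_error(pair_distance(fr, "A", 999, "B", 500), "residue 999")
})

test_that("lobe separation equals the constructed COM distance", {
  fr <- toy_dimer(com_sep = 57)
  expect_equal(lobe_separation(fr, chains = c("A", "B"), residues = 200:203,
                               mass_weighted = FALSE), 57)
  # mass weighting with identical elements gives the same answer
  expect_equal(lobe_separation(fr, chains = c("A", "B"), residues = 200:203,
                               mass_weighted = TRUE), 57)
  # mirror-symmetric dimer: separation is twice the COM-to-axis distance
  expect_equal(lobe_separation(fr, chains = c("A", "B"), residues = 200:203),
               2 * 28.5)
  expect_error(lobe_separation(fr, chains = c("A", "B"), residues = 900:910),
               "empty selection")
})

test_that("all geometric metrics are invariant to rigid motion", {
  fr <- toy_dimer()
  set.seed(13)
  for (s in 1:5) {
    rot <- random_rotation(seed = s)
    shift <- stats::rnorm(3, 0, 50)
    fr2 <- transform_frame(fr, rot, shift)
    expect_equal(pair_distance(fr2, "A", 500, "B", 500),
                 pair_distance(fr, "A", 500, "B", 500), tolerance = 1e-9)
    expect_equal(lobe_separation(fr2, chains = c("A", "B"),
                                 residues = 200:203),
                 lobe_separation(fr, chains = c("A", "B"),
                                 residues = 200:203), tolerance = 1e-9)
  }
  # helix angle too
  hel <- rbind(toy_helix(14, 95, "A", axis = c(0, 0, 1)),
               toy_helix(14, 95, "B", axis = c(0, 1, 1),
                         origin = c(30, 0, 0)))
  a0 <- interhelix_angle(hel, "A", "B")
  rot <- random_rotation(seed = 42)
  expect_equal(interhelix_angle(transform_frame(hel, rot, c(5, -3, 9)),
                                "A", "B"), a0, tolerance = 1e-6)
})

test_that("hydrogen-bond test applies both cutoffs with the stated convention", {
  d <- c(0, 0, 0); h <- c(1, 0, 0)
  # linear D-H...A at 3.0 A donor-acceptor distance
  expect_true(hbond_present(d, h, c(3, 0, 0)))
  # too far
  expect_false(hbond_present(d, h, c(3.6, 0, 0)))
  # deviation from linearity beyond 50 degrees: place A at 60 deg off the
  # D->H direction as seen from H
  ang <- 60 * pi / 180
  a_bent <- h + 2.0 * c(cos(ang), sin(ang), 0)
  expect_lte(sqrt(sum((a_bent - d)^2)), 3.5)
  expect_false(hbond_present(d, h, a_bent))
  # 40 degrees off is accepted
  ang2 <- 40 * pi / 180
  a_ok <- h + 2.0 * c(cos(ang2), sin(ang2), 0)
  expect_true(hbond_present(d, h, a_ok))
  expect_error(hbond_present(d, d, c(3, 0, 0)), "distinct")
  # residue-level OR over triplets
  fr <- rbind(
    toy_atoms("A", 10, "N", matrix(c(0, 0, 0), 1), element = "N"),
    toy_atoms("A", 10, "H", matrix(c(1, 0, 0), 1), element = "H"),
    toy_atoms("B", 20, "O", matrix(c(3, 0, 0), 1), element = "O"),
    toy_atoms("B", 20, "OXT", matrix(c(20, 0, 0), 1), element = "O"))
  trip <- data.frame(d_chain = "A", d_resno = 10, d_elety = "N",
                     h_chain = "A", h_resno = 10, h_elety = "H",
                     a_chain = "B", a_resno = 20,
                     a_elety = c("OXT", "O"))
  expect_true(residue_hbond(fr, trip))
  expect_false(residue_hbond(fr, trip[1, ]))
})

test_that("windowed RMSF is zero for static frames and exact for a known oscillation", {
  base <- toy_atoms("A", 150:190, "CA",
                    cbind(3 * (150:190), sin(150:190), cos(150:190)))
  static <- make_toy_frames(base, n_frames = 6, jitter_sd = 0)
  r0 <- window_rmsf(static, "A")
  expect_equal(r0$rmsf, rep(0, nrow(r0)), tolerance = 1e-9)
  expect_equal(r0$resno, 166:180)
  # one atom oscillating +/-1 A along x about its mean: RMSF exactly 1
  osc <- lapply(1:10, function(i) {
    fr <- base
    fr$x[fr$resno == 170] <- fr$x[fr$resno == 170] + c(1, -1)[i %% 2 + 1]
    fr
  })
  r1 <- window_rmsf(osc, "A")
  expect_equal(r1$rmsf[r1$resno == 170], 1, tolerance = 1e-9)
  expect_lt(max(r1$rmsf[r1$resno != 170]), 0.05)
  # rigid global translation of alternating frames is removed by alignment
  trans <- lapply(1:10, function(i)
    transform_frame(base, diag(3), c(10 * (i %% 2), -5 * (i %% 2), 0)))
  r2 <- window_rmsf(trans, "A")
  expect_equal(r2$rmsf, rep(0, nrow(r2)), tolerance = 1e-6)
})

test_that("inter-helix angle reports constructed angles with N-to-C orientation", {
  # radius-0 "helices" (collinear Calphas) make the principal axis exact;
  # a wound helix of finite length tilts the first principal component
  rr <- 95:112
  h1 <- toy_helix(18, 95, "A", axis = c(0, 0, 1), radius = 0)
  h2 <- toy_helix(18, 95, "B", axis = c(0, 0, 1), origin = c(25, 0, 0),
                  radius = 0)
  expect_close(interhelix_angle(rbind(h1, h2), "A", "B",
                                residues1 = rr, residues2 = rr), 0, tol = 0.5)
  # 30 degrees about a shared perpendicular
  ax30 <- c(0, sin(30 * pi / 180), cos(30 * pi / 180))
  h3 <- toy_helix(18, 95, "B", axis = ax30, origin = c(25, 0, 0), radius = 0)
  expect_close(interhelix_angle(rbind(h1, h3), "A", "B",
                                residues1 = rr, residues2 = rr), 30, tol = 0.5)
  # antiparallel: 180 directed, 0 undirected
  h4 <- toy_helix(18, 95, "B", axis = c(0, 0, -1), origin = c(25, 0, 20),
                  radius = 0)
  expect_close(interhelix_angle(rbind(h1, h4), "A", "B",
                                residues1 = rr, residues2 = rr), 180, tol = 0.5)
  expect_close(interhelix_angle(rbind(h1, h4), "A", "B", residues1 = rr,
                                residues2 = rr, directed = FALSE),
               0, tol = 0.5)
  expect_error(interhelix_angle(rbind(h1[1:3, ], h2), "A", "B"), ">= 4")
})

test_that("multi-model PDB files round-trip into per-model frames", {
  base <- toy_dimer()
  frames <- make_toy_frames(base, n_frames = 3, jitter_sd = 0.2, seed = 5)
  # write a multi-model PDB with bio3d and read it back
  tmp <- withr::local_tempfile(fileext = ".pdb")
  lines <- unlist(lapply(seq_along(frames), function(m) {
    f <- frames[[m]]
    c(sprintf("MODEL     %4d", m),
      sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              seq_len(nrow(f)), f$chain, f$resno, f$x, f$y, f$z),
      "ENDMDL")
  }))
  writeLines(c(lines, "END"), tmp)
  back <- read_structure_frames(tmp)
  expect_length(back, 3L)
  for (m in 1:3)
    expect_equal(pair_distance(back[[m]], "A", 500, "B", 500),
                 pair_distance(frames[[m]], "A", 500, "B", 500),
                 tolerance = 1e-3)
  # tidy batch distances align 1:1 with model indices
  pairs <- data.frame(role = "CRD-CRD", chain_a = "A", resno_a = 500,
                      chain_b = "B", resno_b = 500)
  tab <- pair_distances(back, pairs)
  expect_equal(tab$model, 1:3)
})
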