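# Structural observables on coordinate frames. A "frame" is a data.frame of
# atom records with columns chain, resno, resid, elety (atom name), element
# (optional), x, y, z (Angstrom). Multi-model files become lists of frames.

#' Read structure frames from a PDB/mmCIF file
#'
#' Parses single- or multi-model PDB (and mmCIF) files via bio3d and returns
#' a list of atom-record data.frames, one per model, ready for the geometry
#' operations in this package.
#'
#' @param path Path to a .pdb or .cif file.
#' @param multi Read all models of a multi-model file (default TRUE).
#' @return A list of frames (data.frames with chain, resno, resid, elety,
#'   element, x, y, z).
#' @export
read_structure_frames <- function(path, multi = TRUE) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path) else
    bio3d::read.pdb(path, multi = multi)
  at <- pdb$atom
  base <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                     elety = at$elety,
                     element = at$elesy %||% guess_element(at$elety),
                     stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1L && multi) {
    lapply(seq_len(nrow(xyz)), function(m) {
      co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
      cbind(base, data.frame(x = co[, 1], y = co[, 2], z = co[, 3]))
    })
  } else {
    co <- matrix(as.numeric(xyz), ncol = 3L, byrow = TRUE)
    list(cbind(base, data.frame(x = co[, 1], y = co[, 2], z = co[, 3])))
  }
}

guess_element <- function(elety) {
  sub("^([A-Za-z]).*", "\\1", trimws(elety))
}

# standard atomic masses for mass-weighted centers of mass
atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, SE = 78.971, FE = 55.845,
                   ZN = 65.38, MG = 24.305, CL = 35.45, NA. = 22.990)

atom_mass <- function(element) {
  m <- atomic_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  as.numeric(m)
}

validate_frame <- function(frame) {
  need <- c("chain", "resno", "elety", "x", "y", "z")
  if (!all(need %in% names(frame)))
    stop("frame must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(as.matrix(frame[, c("x", "y", "z")]))))
    stop("frame contains non-finite coordinates")
  invisible(frame)
}

# resolve exactly one atom; informative error naming the selection
atom_xyz <- function(frame, chain, resno, elety = "CA") {
  hit <- frame$chain == chain & frame$resno == resno & frame$elety == elety
  n <- sum(hit)
  if (n == 0L)
    stop(sprintf("no atom %s for residue %s in chain %s", elety, resno, chain))
  if (n > 1L)
    stop(sprintf("ambiguous selection: %d atoms %s for residue %s chain %s",
                 n, elety, resno, chain))
  as.numeric(frame[hit, c("x", "y", "z")])
}

#' Calpha-Calpha distance between two residues
#'
#' Euclidean distance between single atoms (default Calpha) of two residues,
#' the metric used for inter-subunit reporter-site separations (for example
#' LBD-LBD, CRD-CRD or TM6-TM6 distances between equivalent residues of the
#' two protomers).
#'
#' @param frame An atom-record data.frame.
#' @param chain_a,resno_a,chain_b,resno_b Selectors for the two residues.
#' @param elety Atom name (default "CA").
#' @return Distance in Angstrom.
#' @export
pair_distance <- function(frame, chain_a, resno_a, chain_b, resno_b,
                          elety = "CA") {
  validate_frame(frame)
  a <- atom_xyz(frame, chain_a, resno_a, elety)
  b <- atom_xyz(frame, chain_b, resno_b, elety)
  sqrt(sum((a - b)^2))
}

#' Clamshell openness of one ligand-binding domain
#'
#' Distance between the Calpha atoms of an upper-lobe and a lower-lobe
#' residue of the same chain (defaults 144 and 272, the Tyr/Ser pair
#' flanking the mGluR2 clamshell cleft): large when the clamshell is open,
#' small when closed around ligand.
#'
#' @param frame An atom-record data.frame.
#' @param chain Chain identifier.
#' @param res_upper,res_lower Residue numbers of the reporter pair.
#' @return Distance in Angstrom.
#' @export
clamshell_distance <- function(frame, chain, res_upper = 144L,
                               res_lower = 272L) {
  pair_distance(frame, chain, res_upper, chain, res_lower)
}

#' Separation of the two lower-lobe centers of mass
#'
#' Distance between the centers of mass of a residue selection (default
#' residues 188-317 and 452-474, the LBD lower lobe) in each of two chains.
#' Mass-weighted by standard atomic masses by default; unit masses give the
#' plain centroid.
#'
#' @param frame An atom-record data.frame.
#' @param chains Length-2 character vector of chain ids (defaults to the
#'   first two chains present).
#' @param residues Residue numbers of the selection.
#' @param mass_weighted Use atomic masses (default TRUE).
#' @return Distance in Angstrom between the two centers of mass.
#' @export
lobe_separation <- function(frame, chains = NULL,
                            residues = c(188:317, 452:474),
                            mass_weighted = TRUE) {
  validate_frame(frame)
  if (is.null(chains)) chains <- unique(frame$chain)[1:2]
  if (length(chains) != 2L || anyNA(chains))
    stop("need exactly two chains")
  com <- function(ch) {
    sel <- frame[frame$chain == ch & frame$resno %in% residues, , drop = FALSE]
    if (nrow(sel) == 0L)
      stop(sprintf("empty selection: no atoms in chain %s for the residue range",
                   ch))
    w <- if (mass_weighted && "element" %in% names(sel))
      atom_mass(sel$element) else rep(1, nrow(sel))
    colSums(sel[, c("x", "y", "z")] * w) / sum(w)
  }
  sqrt(sum((com(chains[1L]) - com(chains[2L]))^2))
}

#' Geometric hydrogen-bond test
#'
#' A donor-hydrogen...acceptor triplet forms a hydrogen bond when the
#' donor-acceptor distance is at most `dist_cutoff` (default 3.5 Angstrom)
#' and the deviation of the D-H...A arrangement from linearity is at most
#' `angle_cutoff` degrees (default 50; i.e. the D-H...A angle at the
#' hydrogen is at least 130 degrees). Inputs are xyz coordinate vectors or
#' matrices (one triplet per row) for vectorized evaluation.
#'
#' @param donor,hydrogen,acceptor Numeric length-3 vectors or n x 3 matrices.
#' @param dist_cutoff Donor-acceptor distance cutoff, Angstrom.
#' @param angle_cutoff Maximum deviation from linearity, degrees.
#' @return Logical (vector) indicating a qualifying hydrogen bond.
#' @seealso [residue_hbond()] for the any-pair residue-level contact.
#' @export
hbond_present <- function(donor, hydrogen, acceptor, dist_cutoff = 3.5,
                          angle_cutoff = 50) {
  d <- rbind(donor); h <- rbind(hydrogen); a <- rbind(acceptor)
  if (any(rowSums((d - h)^2) == 0) || any(rowSums((a - h)^2) == 0) ||
      any(rowSums((d - a)^2) == 0))
    stop("donor, hydrogen and acceptor must be three distinct positions")
  da <- sqrt(rowSums((d - a)^2))
  v1 <- d - h
  v2 <- a - h
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  theta <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi  # angle at H; 180 = linear
  deviation <- 180 - theta
  da <= dist_cutoff & deviation <= angle_cutoff
}

#' Residue-level hydrogen-bond contact
#'
#' A residue pair is in hydrogen-bond contact when any one of the supplied
#' donor/hydrogen/acceptor atom triplets qualifies under [hbond_present()].
#'
#' @param frame An atom-record data.frame.
#' @param triplets data.frame with columns d_chain, d_resno, d_elety,
#'   h_chain, h_resno, h_elety, a_chain, a_resno, a_elety.
#' @inheritParams hbond_present
#' @return TRUE if at least one triplet forms a hydrogen bond.
#' @export
residue_hbond <- function(frame, triplets, dist_cutoff = 3.5,
                          angle_cutoff = 50) {
  validate_frame(frame)
  stopifnot(nrow(triplets) >= 1L)
  any(vapply(seq_len(nrow(triplets)), function(i) {
    tr <- triplets[i, ]
    hbond_present(
      atom_xyz(frame, tr$d_chain, tr$d_resno, tr$d_elety),
      atom_xyz(frame, tr$h_chain, tr$h_resno, tr$h_elety),
      atom_xyz(frame, tr$a_chain, tr$a_resno, tr$a_elety),
      dist_cutoff, angle_cutoff)
  }, TRUE))
}

#' Windowed root-mean-square fluctuation
#'
#' Superposes every frame onto a reference by rigid-body least squares using
#' only the Calpha atoms of `align_residues` (two flanking segments by
#' default), then computes the per-residue RMSF of the Calpha atoms of
#' `rmsf_residues` about their time-averaged positions. The reference is the
#' mean structure after a first-pass alignment to the initial frame (or a
#' supplied reference frame). Global rigid motion therefore does not
#' contribute to the RMSF.
#'
#' @param frames List of atom-record data.frames (>= 2).
#' @param chain Chain to analyze.
#' @param align_residues Residue numbers used for superposition (default
#'   c(155:166, 180:188), segments flanking the default window).
#' @param rmsf_residues Residue numbers whose fluctuation is reported
#'   (default 166:180).
#' @param reference Optional reference frame (atom data.frame); default is
#'   the two-pass mean structure.
#' @return data.frame: resno, rmsf (Angstrom).
#' @export
window_rmsf <- function(frames, chain,
                        align_residues = c(155:166, 180:188),
                        rmsf_residues = 166:180, reference = NULL) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  resnos <- sort(unique(c(align_residues, rmsf_residues)))
  get_ca <- function(fr) {
    validate_frame(fr)
    sel <- fr[fr$chain == chain & fr$elety == "CA" & fr$resno %in% resnos, ]
    sel <- sel[order(sel$resno), ]
    if (!all(resnos %in% sel$resno))
      stop("alignment/window residues missing Calpha atoms in a frame")
    as.numeric(t(as.matrix(sel[, c("x", "y", "z")])))  # bio3d xyz ordering
  }
  xyz <- t(vapply(frames, get_ca, numeric(3L * length(resnos))))
  fit_idx <- bio3d::atom2xyz(which(resnos %in% align_residues))
  ref <- if (is.null(reference)) {
    pass1 <- bio3d::fit.xyz(fixed = xyz[1L, ], mobile = xyz,
                            fixed.inds = fit_idx, mobile.inds = fit_idx)
    colMeans(pass1)
  } else get_ca(reference)
  aligned <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                            fixed.inds = fit_idx, mobile.inds = fit_idx)
  mean_pos <- colMeans(aligned)
  dev2 <- sweep(aligned, 2L, mean_pos)^2
  n_atoms <- length(resnos)
  msd <- matrix(0, nrow(aligned), n_atoms)
  for (j in seq_len(n_atoms)) {
    cols <- (3L * (j - 1L) + 1L):(3L * j)
    msd[, j] <- rowSums(dev2[, cols, drop = FALSE])
  }
  rmsf_all <- sqrt(colMeans(msd))
  keep <- resnos %in% rmsf_residues
  data.frame(resno = resnos[keep], rmsf = rmsf_all[keep])
}

#' Angle between two helix axes
#'
#' Fits the principal axis (first principal component) of the Calpha
#' coordinates of each selection and reports the angle between the two axes
#' in degrees. Axes are oriented N-terminus to C-terminus, so parallel
#' helices give 0 and antiparallel helices 180 (set `directed = FALSE` to
#' fold onto \[0, 90\]).
#'
#' @param frame An atom-record data.frame.
#' @param chain1,chain2 Chains of the two helices.
#' @param residues1,residues2 Residue ranges (default 95:108, helix B of
#'   each protomer; >= 4 residues required).
#' @param directed Keep the N-to-C orientation (default TRUE).
#' @return Angle in degrees, in \[0, 180\] (directed) or \[0, 90\].
#' @export
interhelix_angle <- function(frame, chain1, chain2,
                             residues1 = 95:108, residues2 = 95:108,
                             directed = TRUE) {
  validate_frame(frame)
  axis_of <- function(chain, residues) {
    sel <- frame[frame$chain == chain & frame$elety == "CA" &
                   frame$resno %in% residues, ]
    sel <- sel[order(sel$resno), ]
    if (nrow(sel) < 4L)
      stop(sprintf("need >= 4 Calpha atoms in chain %s for an axis", chain))
    co <- as.matrix(sel[, c("x", "y", "z")])
    pc <- stats::prcomp(co, center = TRUE)
    if (pc$sdev[1L] < 1e-8) stop("degenerate axis: atoms nearly coincident")
    ax <- pc$rotation[, 1L]
    span <- co[nrow(co), ] - co[1L, ]  # orient N -> C
    if (sum(ax * span) < 0) ax <- -ax
    ax
  }
  a1 <- axis_of(chain1, residues1)
  a2 <- axis_of(chain2, residues2)
  cosang <- sum(a1 * a2)
  if (!directed) cosang <- abs(cosang)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Evaluate reporter-pair distances over many frames
#'
#' Tidy batch interface: computes [pair_distance()] for every row of a pair
#' table in every frame.
#'
#' @param frames List of atom-record data.frames.
#' @param pairs data.frame with columns role, chain_a, resno_a, chain_b,
#'   resno_b and optionally elety.
#' @return data.frame: model, role, distance.
#' @export
pair_distances <- function(frames, pairs) {
  stopifnot(is.list(frames),
            all(c("chain_a", "resno_a", "chain_b", "resno_b") %in%
                  names(pairs)))
  if (is.null(pairs$elety)) pairs$elety <- "CA"
  if (is.null(pairs$role)) pairs$role <- paste0("pair_", seq_len(nrow(pairs)))
  do.call(rbind, lapply(seq_along(frames), function(m) {
    data.frame(model = m, role = pairs$role,
               distance = vapply(seq_len(nrow(pairs)), function(i)
                 pair_distance(frames[[m]], pairs$chain_a[i], pairs$resno_a[i],
                               pairs$chain_b[i], pairs$resno_b[i],
                               pairs$elety[i]), numeric(1)))
  }))
}
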