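#' Ballesteros-Weinstein residue map
#'
#' Maps generic class A GPCR residue codes (helix.position, e.g. `"2.50"`,
#' `"7.53"`) to concrete (chain, residue number) pairs of a structure.
#'
#' @param entries named list: BW code -> `list(chain =, res_num =)` (or
#'   `c(chain, res_num)`).
#' @param receptor receptor name (metadata).
#' @return An object of class `bw_map`.
#' @export
bw_map <- function(entries, receptor = "receptor") {
  if (!length(entries) || is.null(names(entries)) ||
      anyDuplicated(names(entries)))
    stop("bw_map: entries must be uniquely named by BW code")
  entries <- lapply(entries, function(e) {
    e <- as.list(e)
    if (is.null(names(e)) || !all(c("chain", "res_num") %in% names(e)))
      names(e) <- c("chain", "res_num")[seq_along(e)]
    list(chain = as.character(e$chain), res_num = as.integer(e$res_num))
  })
  structure(list(receptor = receptor, entries = entries), class = "bw_map")
}

#' Read a Ballesteros-Weinstein map from YAML
#'
#' Expected layout: `receptor: <name>` and `entries: {"2.50": {chain: A,
#' res_num: 52}, ...}`.
#'
#' @param path YAML file.
#' @return A [bw_map()].
#' @export
read_bw_map <- function(path) {
  y <- yaml::read_yaml(path)
  bw_map(y$entries, receptor = if (is.null(y$receptor)) "receptor"
                               else y$receptor)
}

#' Resolve a BW code to a residue in a frame
#'
#' @param map a [bw_map()].
#' @param frame a [structure_frame()].
#' @param code BW code, e.g. `"2.50"`.
#' @return The residue's atom table (subset of `frame$atoms`).
#' @export
resolve_bw <- function(map, frame, code) {
  stopifnot(inherits(map, "bw_map"), inherits(frame, "structure_frame"))
  e <- map$entries[[code]]
  if (is.null(e)) stop("resolve_bw: code '", code, "' not in map")
  res <- frame$atoms[frame$atoms$chain == e$chain &
                     frame$atoms$res_num == e$res_num, , drop = FALSE]
  if (!nrow(res))
    stop("resolve_bw: residue ", e$chain, "/", e$res_num, " (BW ", code,
         ") absent from frame '", frame$frame_id, "'")
  res
}

atom_xyz <- function(res, name) {
  hit <- res[res$atom_name == name, , drop = FALSE]
  if (nrow(hit) != 1L)
    stop("atom '", name, "' missing (or duplicated) in residue ",
         res$chain[1], "/", res$res_num[1])
  c(hit$x, hit$y, hit$z)
}

#' C-alpha distance between two BW positions
#'
#' Euclidean distance (Angstrom) between the Calpha atoms of two mapped
#' residues — e.g. the TM3-TM6 activation distance between 3.50 and 6.34.
#'
#' @param frame a `structure_frame`.
#' @param code_i,code_j BW codes.
#' @param map a [bw_map()].
#' @return Distance in Angstrom.
#' @export
ca_distance <- function(frame, code_i, code_j, map) {
  a <- atom_xyz(resolve_bw(map, frame, code_i), "CA")
  b <- atom_xyz(resolve_bw(map, frame, code_j), "CA")
  sqrt(sum((a - b)^2))
}

.backbone_names <- c("N", "CA", "C", "O")

#' Side-chain centre of mass
#'
#' Mass-weighted mean position of a residue's heavy side-chain atoms
#' (everything beyond the backbone N/CA/C/O and terminal OXT; hydrogens
#' excluded). Glycine has no heavy side-chain atom and is an error.
#'
#' @param frame a `structure_frame`.
#' @param residue a residue atom table (from [resolve_bw()]).
#' @return Numeric length-3 coordinate (Angstrom).
#' @export
sidechain_com <- function(frame, residue) {
  sc <- residue[!(residue$atom_name %in% c(.backbone_names, "OXT")) &
                residue$element != "H", , drop = FALSE]
  if (!nrow(sc))
    stop("sidechain_com: no heavy side-chain atoms in residue ",
         residue$chain[1], "/", residue$res_num[1],
         " (", residue$res_name[1], ")")
  m <- sc$mass
  c(sum(sc$x * m), sum(sc$y * m), sum(sc$z * m)) / sum(m)
}

#' Triangle area from side lengths (Heron's formula)
#'
#' `s = (a+b+c)/2; area = sqrt(s(s-a)(s-b)(s-c))`. A negative radicand
#' within `tol` (a numerically degenerate triangle) clamps to zero; a
#' triangle-inequality violation beyond `tol` is an error.
#'
#' @param a,b,c side lengths (Angstrom), >= 0.
#' @param tol numerical tolerance (default 1e-9).
#' @return Area in Angstrom^2.
#' @examples
#' heron_area(3, 4, 5)  # 6
#' @export
heron_area <- function(a, b, c, tol = 1e-9) {
  if (any(c(a, b, c) < 0)) stop("heron_area: sides must be >= 0")
  s <- (a + b + c) / 2
  viol <- max(a - (b + c), b - (a + c), c - (a + b))
  if (viol > tol)
    stop("heron_area: triangle inequality violated by ", signif(viol, 3))
  rad <- s * (s - a) * (s - b) * (s - c)
  if (rad < 0) rad <- 0
  sqrt(rad)
}

#' Triangle area spanned by three side-chain centres of mass
#'
#' Area of the triangle whose vertices are the side-chain COMs of three
#' mapped residues — used for the Na+ pocket (2.50/3.39/7.49) and the
#' hydrophobic lock (3.43/6.40/6.41).
#'
#' @param frame a `structure_frame`.
#' @param codes character vector of exactly three BW codes.
#' @param map a [bw_map()].
#' @return Area in Angstrom^2.
#' @export
pocket_area <- function(frame, codes, map) {
  if (length(codes) != 3L) stop("pocket_area: need exactly three BW codes")
  p <- lapply(codes, function(cd)
    sidechain_com(frame, resolve_bw(map, frame, cd)))
  d <- function(u, v) sqrt(sum((u - v)^2))
  heron_area(d(p[[1]], p[[2]]), d(p[[1]], p[[3]]), d(p[[2]], p[[3]]))
}

# Kabsch least-squares superposition: returns X aligned onto Y (n x 3 each)
kabsch_align <- function(X, Y, X_apply = X) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  sv <- svd(crossprod(Xc, Yc))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(X_apply, 2L, cx) %*% t(R), 2L, cy, "+")
}

backbone_coords <- function(frame, map, codes) {
  out <- do.call(rbind, lapply(codes, function(cd) {
    res <- resolve_bw(map, frame, cd)
    t(vapply(.backbone_names, function(nm) atom_xyz(res, nm), numeric(3)))
  }))
  out
}

#' NPxxY motif backbone RMSD after superposition
#'
#' Least-squares superposes the frame onto a reference over the backbone
#' (N, CA, C, O) atoms of `fit_selection`, then reports the RMSD over the
#' NPxxY motif backbone (BW 7.49-7.53) only. The default fit uses every
#' mapped code; fitting on the non-motif codes isolates the motif's own
#' displacement.
#'
#' @param frame,reference `structure_frame` objects (reference = inactive
#'   structure).
#' @param map a [bw_map()] containing the motif codes 7.49..7.53.
#' @param fit_selection BW codes used for the superposition (default: all
#'   codes in the map).
#' @param motif_codes the motif BW codes (default `"7.49"`..`"7.53"`).
#' @return RMSD in Angstrom.
#' @export
npxxy_rmsd <- function(frame, reference, map,
                       fit_selection = names(map$entries),
                       motif_codes = c("7.49", "7.50", "7.51", "7.52",
                                       "7.53")) {
  missing_codes <- setdiff(motif_codes, names(map$entries))
  if (length(missing_codes))
    stop("npxxy_rmsd: motif codes missing from map: ",
         paste(missing_codes, collapse = ", "))
  Xfit <- backbone_coords(frame, map, fit_selection)
  Yfit <- backbone_coords(reference, map, fit_selection)
  Xmot <- backbone_coords(frame, map, motif_codes)
  Ymot <- backbone_coords(reference, map, motif_codes)
  Xmot_aln <- kabsch_align(Xfit, Yfit, X_apply = Xmot)
  sqrt(mean(rowSums((Xmot_aln - Ymot)^2)))
}

#' A100 activation-index configuration
#'
#' The A100 index condenses five interhelical Calpha distances into one
#' activation score: `A = intercept + sum_k coef_k * d_k`. Scores below 0
#' are inactive, 0 to 55 intermediate, above 55 active. The distance pairs
#' and coefficients come from the index's defining publication and are
#' receptor-family level constants; they are configuration here, with the
#' thresholds fixed at the published 0/55 cut points.
#'
#' @param distance_pairs list of exactly five 2-vectors of BW codes.
#' @param coefficients numeric vector of exactly five weights.
#' @param intercept scalar intercept.
#' @param thresholds `c(inactive_below, active_above)`; defaults `c(0, 55)`.
#' @return An object of class `a100_config`.
#' @export
a100_config <- function(distance_pairs, coefficients, intercept = 0,
                        thresholds = c(inactive_below = 0,
                                       active_above = 55)) {
  if (length(distance_pairs) != 5L || length(coefficients) != 5L)
    stop("a100_config: exactly five distance pairs and coefficients")
  if (!all(vapply(distance_pairs, length, 0L) == 2L))
    stop("a100_config: each distance pair needs two BW codes")
  if (thresholds[1] >= thresholds[2])
    stop("a100_config: inactive threshold must be below active threshold")
  structure(list(distance_pairs = distance_pairs,
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept),
                 thresholds = as.numeric(thresholds)),
            class = "a100_config")
}

#' Read an A100 configuration from YAML
#'
#' Layout: `distance_pairs` (list of two-code lists), `coefficients`,
#' `intercept`, optional `thresholds: [0, 55]`.
#'
#' @param path YAML file.
#' @return An [a100_config()].
#' @export
read_a100_config <- function(path) {
  y <- yaml::read_yaml(path)
  a100_config(lapply(y$distance_pairs, unlist),
              unlist(y$coefficients),
              intercept = if (is.null(y$intercept)) 0 else y$intercept,
              thresholds = if (is.null(y$thresholds)) c(0, 55)
                           else unlist(y$thresholds))
}

#' A100 activation index and state label
#'
#' @param frame a `structure_frame`.
#' @param cfg an [a100_config()].
#' @param map a [bw_map()].
#' @return List with `value` and `state` (`"inactive"`, `"intermediate"`,
#'   `"active"`); boundary values sit in `"intermediate"`.
#' @export
a100_index <- function(frame, cfg, map) {
  stopifnot(inherits(cfg, "a100_config"))
  d <- vapply(cfg$distance_pairs, function(p)
    ca_distance(frame, p[1], p[2], map), numeric(1))
  value <- cfg$intercept + sum(cfg$coefficients * d)
  state <- if (value < cfg$thresholds[1]) "inactive"
           else if (value > cfg$thresholds[2]) "active"
           else "intermediate"
  list(value = value, state = state)
}

# signed dihedral (degrees, IUPAC convention) of four points
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.chi2_atoms <- list(
  ASP = c("CA", "CB", "CG", "OD1"), ASN = c("CA", "CB", "CG", "OD1"),
  GLU = c("CA", "CB", "CG", "CD"),  GLN = c("CA", "CB", "CG", "CD"),
  LEU = c("CA", "CB", "CG", "CD1"), PHE = c("CA", "CB", "CG", "CD1"),
  TYR = c("CA", "CB", "CG", "CD1"), TRP = c("CA", "CB", "CG", "CD1"),
  HIS = c("CA", "CB", "CG", "ND1"), MET = c("CA", "CB", "CG", "SD"),
  LYS = c("CA", "CB", "CG", "CD"),  ARG = c("CA", "CB", "CG", "CD"),
  ILE = c("CA", "CB", "CG1", "CD1"), PRO = c("CA", "CB", "CG", "CD"))

#' Chi2 side-chain torsion
#'
#' Signed second side-chain dihedral in degrees, `(-180, 180]`, IUPAC
#' convention (for Asp: CA-CB-CG-OD1). Flips of this torsion reposition a
#' protonated carboxyl oxygen and track conformational substates.
#'
#' @param frame a `structure_frame`.
#' @param residue a residue atom table (from [resolve_bw()]).
#' @return Angle in degrees.
#' @export
chi2_torsion <- function(frame, residue) {
  rn <- residue$res_name[1]
  names4 <- .chi2_atoms[[rn]]
  if (is.null(names4))
    stop("chi2_torsion: no chi2 definition for residue type ", rn)
  p <- lapply(names4, function(nm) atom_xyz(residue, nm))
  dihedral_deg(p[[1]], p[[2]], p[[3]], p[[4]])
}

#' Snapshot count of a sampling protocol
#'
#' Number of trajectory snapshots produced by sampling `duration_ps` at
#' fixed `interval_ps` over `replicates` runs — e.g. 100 ns at 100 ps with
#' the t=0 frame gives 1001 per replicate, 3003 over three replicates.
#'
#' @param duration_ps simulation length per replicate (ps).
#' @param interval_ps snapshot interval (ps); must divide `duration_ps`.
#' @param replicates number of replicates.
#' @param include_t0 count the initial frame (default TRUE).
#' @return Integer snapshot count.
#' @examples
#' frame_count(100000, 100, 3)  # 3003
#' @export
frame_count <- function(duration_ps, interval_ps, replicates = 1L,
                        include_t0 = TRUE) {
  if (interval_ps <= 0) stop("frame_count: interval must be > 0")
  k <- duration_ps / interval_ps
  if (abs(k - round(k)) > 1e-9)
    stop("frame_count: interval does not divide duration")
  as.integer(replicates * (round(k) + as.integer(include_t0)))
}

#' All activation metrics for one frame
#'
#' Computes the full per-frame activation record: TM3-TM6 (Calpha
#' 3.50-6.34) and TM3-TM7 (Calpha 3.50-7.53) distances, NPxxY backbone
#' RMSD vs a reference, the A100 index and state, the transmission-switch
#' distances (3.40-6.48, 5.51-6.44), Na+ pocket (2.50/3.39/7.49) and
#' hydrophobic-lock (3.43/6.40/6.41) side-chain COM triangle areas, the
#' side-chain TM3-TM7 distance (3.43-7.53 COMs) and the chi2 torsion of
#' the target residue (default 2.50).
#'
#' @param frame a `structure_frame`.
#' @param reference reference (inactive) `structure_frame` for the RMSD.
#' @param map a [bw_map()] covering every code used.
#' @param a100 an [a100_config()], or `NULL` to skip the index.
#' @param chi2_code BW code whose chi2 is tracked (default `"2.50"`).
#' @param fit_selection superposition selection for [npxxy_rmsd()].
#' @return A one-row data.frame of class `activation_metrics`.
#' @export
activation_metrics <- function(frame, reference, map, a100 = NULL,
                               chi2_code = "2.50",
                               fit_selection = names(map$entries)) {
  com_d <- function(ci, cj) {
    u <- sidechain_com(frame, resolve_bw(map, frame, ci))
    v <- sidechain_com(frame, resolve_bw(map, frame, cj))
    sqrt(sum((u - v)^2))
  }
  a <- if (is.null(a100)) list(value = NA_real_, state = NA_character_)
       else a100_index(frame, a100, map)
  out <- data.frame(
    frame_id = frame$frame_id,
    time_ps = frame$time_ps,
    tm3_tm6_A = ca_distance(frame, "3.50", "6.34", map),
    tm3_tm7_ca_A = ca_distance(frame, "3.50", "7.53", map),
    npxxy_rmsd_A = npxxy_rmsd(frame, reference, map, fit_selection),
    a100 = a$value,
    state = a$state,
    ts_d1_A = ca_distance(frame, "3.40", "6.48", map),
    ts_d2_A = ca_distance(frame, "5.51", "6.44", map),
    na_pocket_area_A2 = pocket_area(frame, c("2.50", "3.39", "7.49"), map),
    hlock_area_A2 = pocket_area(frame, c("3.43", "6.40", "6.41"), map),
    tm3_tm7_sc_A = com_d("3.43", "7.53"),
    chi2_deg = chi2_torsion(frame, resolve_bw(map, frame, chi2_code)),
    stringsAsFactors = FALSE)
  class(out) <- c("activation_metrics", class(out))
  out
}
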