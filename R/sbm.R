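#' Parameters of the C-alpha structure-based model
#'
#' Energy unit epsilon is 1 (nominally kJ/mol), lengths are nm and
#' temperatures are reported in reduced units epsilon/k_B.  The force
#' constants follow the conventional C-alpha Go-model ratios: stiff
#' harmonic bonds and angles, unit-scale dihedral/contact/excluded-volume
#' strengths.  All values are configurable; the landscape shape, not the
#' absolute scale, carries the conclusions.
#'
#' @param epsilon basic energy unit.
#' @param k_bond bond force constant (epsilon/nm^2).
#' @param k_angle angle force constant (epsilon/rad^2).
#' @param k_dihedral dihedral strength (epsilon).
#' @param contact_strength native-contact well depth (epsilon).
#' @param nc_sigma excluded-volume diameter (nm).
#' @param nc_epsilon excluded-volume strength (epsilon).
#' @param nonbonded_cutoff truncation radius for the generic repulsion (nm).
#' @param exclusion_depth nonbonded pairs within this many bonds are
#'   excluded (covered by the bonded terms).
#' @return An `sbm_parameters` list.
#' @export
sbm_parameters <- function(epsilon = 1.0, k_bond = 20000, k_angle = 40,
                           k_dihedral = 1.0, contact_strength = 1.0,
                           nc_sigma = 0.4, nc_epsilon = 1.0,
                           nonbonded_cutoff = 3.0, exclusion_depth = 3) {
  p <- list(epsilon = epsilon, k_bond = k_bond, k_angle = k_angle,
            k_dihedral = k_dihedral, contact_strength = contact_strength,
            nc_sigma = nc_sigma, nc_epsilon = nc_epsilon,
            nonbonded_cutoff = nonbonded_cutoff,
            exclusion_depth = as.integer(exclusion_depth))
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "sbm_parameters")
}

#' Build the C-alpha model topology from a structure and its contact map
#'
#' Every bonded term (N-1 bonds, N-2 angles, N-3 dihedrals) takes its
#' minimum from the native C-alpha geometry; every contact gets a 10-12
#' well with minimum exactly at the native pair distance d_ij; all other
#' pairs beyond the bonded exclusion depth repel.  The native state is
#' thus the global minimum of the potential by construction.
#'
#' @param s an [rp_structure()] (only C-alpha atoms are used).
#' @param cm an `rp_contact_map` for the same structure.
#' @param params an [sbm_parameters()].
#' @return An `sbm_topology`: native coordinates (nm) plus term tables.
#' @export
build_topology <- function(s, cm, params = sbm_parameters()) {
  xyz <- ca_xyz(s) / 10  # Angstrom -> nm
  n <- nrow(xyz)
  if (!is.null(cm) && cm$n_residues != n) {
    rp_stop("ContactSizeMismatch",
            sprintf("contact map has %d residues, structure %d", cm$n_residues, n))
  }
  bonds_idx <- cbind(1:(n - 1), 2:n)
  bonds_r0 <- sqrt(rowSums((xyz[bonds_idx[, 1], , drop = FALSE] -
                            xyz[bonds_idx[, 2], , drop = FALSE])^2))
  angles_idx <- if (n >= 3) cbind(1:(n - 2), 2:(n - 1), 3:n) else
    matrix(integer(0), 0, 3)
  angles_t0 <- apply(angles_idx, 1, function(r)
    measure_angle(xyz[r[1], ], xyz[r[2], ], xyz[r[3], ]) * pi / 180)
  dihedrals_idx <- if (n >= 4) cbind(1:(n - 3), 2:(n - 2), 3:(n - 1), 4:n) else
    matrix(integer(0), 0, 4)
  dihedrals_p0 <- apply(dihedrals_idx, 1, function(r)
    measure_torsion(xyz[r[1], ], xyz[r[2], ], xyz[r[3], ], xyz[r[4], ]) * pi / 180)
  contacts <- if (is.null(cm)) data.frame(i = integer(0), j = integer(0),
                                          dij = numeric(0)) else cm$contacts
  contacts_idx <- as.matrix(contacts[, c("i", "j"), drop = FALSE])
  storage.mode(contacts_idx) <- "integer"
  # nonbonded list: beyond the bonded exclusion depth and not a contact
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sep <- all_pairs[, 2] - all_pairs[, 1]
  keep <- sep > params$exclusion_depth
  key <- paste(all_pairs[, 1], all_pairs[, 2])
  ckey <- paste(contacts$i, contacts$j)
  keep <- keep & !(key %in% ckey)
  nonbonded_idx <- all_pairs[keep, , drop = FALSE]
  storage.mode(nonbonded_idx) <- "integer"
  colnames(nonbonded_idx) <- NULL
  structure(list(
    n_beads = n,
    native_coords = xyz,
    bonds_idx = bonds_idx, bonds_r0 = bonds_r0,
    angles_idx = angles_idx, angles_t0 = as.numeric(angles_t0),
    dihedrals_idx = dihedrals_idx, dihedrals_p0 = as.numeric(dihedrals_p0),
    contacts_idx = contacts_idx,
    contacts_d = contacts$dij,
    contacts_eps = rep(params$contact_strength, nrow(contacts)),
    nonbonded_idx = nonbonded_idx,
    params = params,
    label = s$label
  ), class = "sbm_topology")
}

#' @export
print.sbm_topology <- function(x, ...) {
  cat(sprintf("<sbm_topology> '%s': %d beads, %d bonds, %d angles, %d dihedrals, %d contacts\n",
              x$label, x$n_beads, nrow(x$bonds_idx), nrow(x$angles_idx),
              nrow(x$dihedrals_idx), nrow(x$contacts_idx)))
  invisible(x)
}

check_coords <- function(t, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != t$n_beads || ncol(coords) != 3) {
    rp_stop("ShapeMismatch",
            sprintf("coords must be %d x 3", t$n_beads))
  }
  coords
}

#' Potential energy of a conformation
#'
#' @param t an `sbm_topology`.
#' @param coords n_beads x 3 matrix (nm).
#' @return list with `total` and `components` (bond, angle, dihedral,
#'   contact, noncontact), all in epsilon.
#' @export
potential_energy <- function(t, coords) {
  e <- cpp_sbm_energy(t, check_coords(t, coords))
  list(total = sum(e), components = as.list(e))
}

#' Forces (-dE/dx) of a conformation
#'
#' @param t an `sbm_topology`.
#' @param coords n_beads x 3 matrix (nm).
#' @return n_beads x 3 force matrix (epsilon/nm).
#' @export
sbm_forces <- function(t, coords) {
  cpp_sbm_forces(t, check_coords(t, coords))
}

#' Export/import a topology in GROMACS dialect
#'
#' Writes a .top/.gro text pair encoding the identical functional forms
#' (bond type 1, angle type 1, the 1+3 cosine dihedral as two type-1
#' entries, contacts as 10-12 pairs, excluded volume via atomtype C12),
#' for interoperability with external structure-based-model engines.
#' `read_topology()` round-trips the exported pair.
#'
#' @param t an `sbm_topology`.
#' @return list of character vectors `top` and `gro`.
#' @export
export_topology <- function(t) {
  p <- t$params
  top <- c(
    "; C-alpha structure-based model (rpfold export)",
    "[ defaults ]",
    "; nbfunc comb-rule gen-pairs",
    "  1 1 no",
    "", "[ atomtypes ]",
    "; name mass charge ptype c6 c12",
    sprintf("  CA 1.0 0.0 A 0.0 %.9e", p$nc_epsilon * p$nc_sigma^12),
    "", "[ moleculetype ]",
    "; name nrexcl",
    sprintf("  Macromolecule %d", p$exclusion_depth),
    "", "[ atoms ]",
    sprintf("  %d CA %d G CA %d 0.0 1.0", 1:t$n_beads, 1:t$n_beads, 1:t$n_beads),
    "", "[ bonds ]")
  top <- c(top, sprintf("  %d %d 1 %.9e %.9e", t$bonds_idx[, 1], t$bonds_idx[, 2],
                        t$bonds_r0, p$k_bond))
  top <- c(top, "", "[ angles ]",
           sprintf("  %d %d %d 1 %.9e %.9e", t$angles_idx[, 1], t$angles_idx[, 2],
                   t$angles_idx[, 3], t$angles_t0 * 180 / pi, p$k_angle))
  top <- c(top, "", "[ dihedrals ]")
  if (nrow(t$dihedrals_idx) > 0) {
    d <- t$dihedrals_idx
    p0 <- t$dihedrals_p0 * 180 / pi
    top <- c(top,
             sprintf("  %d %d %d %d 1 %.9e %.9e 1", d[, 1], d[, 2], d[, 3], d[, 4],
                     p0, p$k_dihedral),
             sprintf("  %d %d %d %d 1 %.9e %.9e 3", d[, 1], d[, 2], d[, 3], d[, 4],
                     3 * p0, 0.5 * p$k_dihedral))
  }
  top <- c(top, "", "[ pairs ]")
  if (nrow(t$contacts_idx) > 0) {
    # 10-12 pair: V = C12/r^12 - C10/r^10 with minimum -eps at d_ij
    top <- c(top, sprintf("  %d %d 1 %.9e %.9e",
                          t$contacts_idx[, 1], t$contacts_idx[, 2],
                          6 * t$contacts_eps * t$contacts_d^10,
                          5 * t$contacts_eps * t$contacts_d^12))
  }
  top <- c(top, "", "[ exclusions ]")
  if (nrow(t$contacts_idx) > 0) {
    top <- c(top, sprintf("  %d %d", t$contacts_idx[, 1], t$contacts_idx[, 2]))
  }
  top <- c(top, "", "[ system ]", "  Macromolecule", "", "[ molecules ]",
           "  Macromolecule 1")
  gro <- c("C-alpha SBM native coordinates",
           sprintf("%5d", t$n_beads),
           sprintf("%5dGLY   CA%5d%8.3f%8.3f%8.3f", 1:t$n_beads, 1:t$n_beads,
                   t$native_coords[, 1], t$native_coords[, 2], t$native_coords[, 3]),
           "  20.00000  20.00000  20.00000")
  list(top = top, gro = gro)
}

#' @rdname export_topology
#' @param top,gro character vectors as produced by [export_topology()].
#' @param params an [sbm_parameters()] (force constants are read from the
#'   files; sigma/cutoff/exclusions from `params`).
#' @export
read_topology <- function(top, gro, params = sbm_parameters()) {
  section <- ""
  bonds <- list(); angles <- list(); dihs <- list(); pairs <- list()
  for (ln in top) {
    ln2 <- trimws(sub(";.*", "", ln))
    if (!nzchar(ln2)) next
    if (grepl("^\\[", ln2)) {
      section <- gsub("\\[|\\]| ", "", ln2)
      next
    }
    f <- strsplit(ln2, "\\s+")[[1]]
    if (section == "bonds") bonds[[length(bonds) + 1]] <- as.numeric(f)
    if (section == "angles") angles[[length(angles) + 1]] <- as.numeric(f)
    if (section == "dihedrals") dihs[[length(dihs) + 1]] <- as.numeric(f)
    if (section == "pairs") pairs[[length(pairs) + 1]] <- as.numeric(f)
  }
  glines <- gro[3:(length(gro) - 1)]
  xyz <- do.call(rbind, lapply(glines, function(l) {
    as.numeric(c(substr(l, 21, 28), substr(l, 29, 36), substr(l, 37, 44)))
  }))
  n <- nrow(xyz)
  b <- do.call(rbind, bonds)
  a <- do.call(rbind, angles)
  d1 <- do.call(rbind, dihs)
  d1 <- d1[d1[, 8] == 1, , drop = FALSE]  # base multiplicity rows carry phi0
  pr <- do.call(rbind, pairs)
  # invert pair coefficients: C10 = 6 eps d^10, C12 = 5 eps d^12
  if (!is.null(pr) && nrow(pr) > 0) {
    dij <- sqrt(6 * pr[, 5] / (5 * pr[, 4]))
    eps <- pr[, 4] / (6 * dij^10)
  } else {
    dij <- numeric(0); eps <- numeric(0)
  }
  params$k_bond <- if (!is.null(b)) b[1, 5] else params$k_bond
  params$k_angle <- if (!is.null(a)) a[1, 6] else params$k_angle
  params$k_dihedral <- if (!is.null(d1) && nrow(d1) > 0) d1[1, 7] else params$k_dihedral
  ci <- if (!is.null(pr) && nrow(pr) > 0)
    cbind(as.integer(pr[, 1]), as.integer(pr[, 2])) else matrix(integer(0), 0, 2)
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- (all_pairs[, 2] - all_pairs[, 1]) > params$exclusion_depth &
    !(paste(all_pairs[, 1], all_pairs[, 2]) %in% paste(ci[, 1], ci[, 2]))
  nbi <- all_pairs[keep, , drop = FALSE]
  storage.mode(nbi) <- "integer"; colnames(nbi) <- NULL
  structure(list(
    n_beads = n, native_coords = xyz,
    bonds_idx = cbind(as.integer(b[, 1]), as.integer(b[, 2])),
    bonds_r0 = b[, 4],
    angles_idx = if (!is.null(a)) cbind(as.integer(a[, 1]), as.integer(a[, 2]),
                                        as.integer(a[, 3])) else matrix(integer(0), 0, 3),
    angles_t0 = if (!is.null(a)) a[, 5] * pi / 180 else numeric(0),
    dihedrals_idx = if (!is.null(d1) && nrow(d1) > 0)
      cbind(as.integer(d1[, 1]), as.integer(d1[, 2]), as.integer(d1[, 3]),
            as.integer(d1[, 4])) else matrix(integer(0), 0, 4),
    dihedrals_p0 = if (!is.null(d1) && nrow(d1) > 0) d1[, 6] * pi / 180 else numeric(0),
    contacts_idx = ci, contacts_d = dij, contacts_eps = eps,
    nonbonded_idx = nbi, params = params, label = "imported"
  ), class = "sbm_topology")
}
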