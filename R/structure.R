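#' Protein structures with backbone and side-chain heavy atoms
#'
#' An `rp_structure` holds an ordered set of residues, each with its heavy
#' atoms, a one-letter sequence and a label.  Residues are renumbered
#' 1..N sequentially on construction; original author numbering is kept as
#' metadata only.  A backbone scaffold (`rp_backbone`) is the restriction
#' to the four backbone atoms N, CA, C, O.
#'
#' @param atoms data frame with columns `resno` (1-based sequential),
#'   `resid` (three-letter residue name), `elety` (atom name), `element`,
#'   `x`, `y`, `z` (Angstrom).
#' @param label identifier string.
#' @param orig_resno optional original author numbering (per residue).
#' @return An object of class `rp_structure`.
#' @export
rp_structure <- function(atoms, label = "structure", orig_resno = NULL) {
  needed <- c("resno", "resid", "elety", "element", "x", "y", "z")
  stopifnot(all(needed %in% names(atoms)))
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    rp_stop("InvalidCoordinates", "non-finite atom coordinates")
  }
  resnos <- unique(atoms$resno)
  if (!identical(as.integer(resnos), seq_along(resnos))) {
    # renumber sequentially in order of appearance
    atoms$resno <- match(atoms$resno, resnos)
  }
  seq3 <- atoms$resid[!duplicated(atoms$resno)]
  structure(list(
    atoms = atoms,
    sequence = aa_three_to_one(seq3),
    label = label,
    orig_resno = orig_resno
  ), class = "rp_structure")
}

#' @export
print.rp_structure <- function(x, ...) {
  cat(sprintf("<%s> '%s': %d residues, %d heavy atoms\n",
              class(x)[1], x$label, n_residues(x), nrow(x$atoms)))
  cat("  sequence:", paste(x$sequence, collapse = ""), "\n")
  invisible(x)
}

#' Number of residues in a structure or contact map
#' @param x an `rp_structure` or `rp_contact_map`.
#' @return integer count.
#' @export
n_residues <- function(x) UseMethod("n_residues")

#' @export
n_residues.rp_structure <- function(x) length(x$sequence)

#' One-letter sequence of a structure
#' @param s an `rp_structure`.
#' @return character scalar.
#' @export
structure_sequence <- function(s) paste(s$sequence, collapse = "")

#' C-alpha coordinates of a structure
#' @param s an `rp_structure`.
#' @return N x 3 matrix in Angstrom.
#' @export
ca_xyz <- function(s) {
  ca <- s$atoms[s$atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) != n_residues(s)) {
    missing <- setdiff(seq_len(n_residues(s)), ca$resno)
    rp_stop("MissingCA", sprintf("residue(s) without CA: %s",
                                 paste(missing, collapse = ", ")))
  }
  as.matrix(ca[order(ca$resno), c("x", "y", "z")])
}

infer_element <- function(elety) {
  # PDB convention: strip leading digits; H/D by leading character;
  # two-character elements for common hetero atoms
  nm <- sub("^[0-9]+", "", elety)
  first <- substr(nm, 1, 1)
  ifelse(substr(nm, 1, 2) %in% c("SE", "FE", "ZN", "MG"), substr(nm, 1, 2),
         ifelse(first %in% c("H", "D"), "H", first))
}

#' Read a protein structure from a PDB file or text
#'
#' Parses ATOM records of a single chain (the first, unless given),
#' resolves alternate locations by highest occupancy (ties broken by the
#' lexicographically first altloc id), drops waters/HETATM records except
#' for common modified residues (e.g. MSE -> MET), and renumbers residues
#' sequentially, flattening insertion codes.
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format lines.
#' @param chain chain identifier; `NULL` selects the first chain.
#' @param label structure label; defaults to the file name.
#' @return An [rp_structure()].
#' @export
read_structure <- function(pdb, chain = NULL, label = NULL) {
  if (length(pdb) > 1 || grepl("\n", pdb[1]) || grepl("^ATOM|^HETATM|^HEADER", pdb[1])) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(if (length(pdb) == 1) strsplit(pdb, "\n")[[1]] else pdb, tmp)
    path <- tmp
    if (is.null(label)) label <- "pdb_text"
  } else {
    path <- pdb
    if (is.null(label)) label <- sub("\\.pdb$", "", basename(path))
  }
  p <- bio3d::read.pdb(path, verbose = FALSE)
  at <- p$atom
  # keep standard ATOM records plus recognised modified residues
  keep <- at$type == "ATOM" | at$resid %in% names(AA_MODIFIED_MAP)
  at <- at[keep & !(at$resid %in% SOLVENT_RESIDUES), , drop = FALSE]
  if (nrow(at) == 0) rp_stop("NoChainFound", "no protein ATOM records found")
  chains <- unique(at$chain)
  sel_chain <- if (is.null(chain)) chains[1] else chain
  if (!sel_chain %in% chains) {
    rp_stop("NoChainFound", sprintf("chain '%s' not present (have: %s)",
                                    sel_chain, paste(chains, collapse = ", ")))
  }
  at <- at[at$chain %in% sel_chain, , drop = FALSE]
  # residue key in order of appearance (flattens insertion codes)
  ins <- if (!is.null(at$insert)) ifelse(is.na(at$insert), "", at$insert) else ""
  key <- paste(at$resno, ins, sep = "_")
  seqno <- match(key, unique(key))
  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # ties -> lexicographically first altloc id
  alt <- if (!is.null(at$alt)) ifelse(is.na(at$alt), "", at$alt) else ""
  occ <- if (!is.null(at$o)) ifelse(is.na(at$o), 1, at$o) else 1
  orig_idx <- seq_len(nrow(at))
  ord <- order(seqno, at$elety, -occ, alt)
  at <- at[ord, , drop = FALSE]; seqno <- seqno[ord]; orig_idx <- orig_idx[ord]
  dup <- duplicated(paste(seqno, at$elety))
  at <- at[!dup, , drop = FALSE]; seqno <- seqno[!dup]; orig_idx <- orig_idx[!dup]
  # restore residue-major ordering with atoms in file order
  ord2 <- order(seqno, orig_idx)
  at <- at[ord2, , drop = FALSE]; seqno <- seqno[ord2]

  resid <- at$resid
  resid <- ifelse(resid %in% names(AA_MODIFIED_MAP), AA_MODIFIED_MAP[resid], resid)
  # element: use file field when present, infer otherwise
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- ifelse(is.na(elem) | elem == "", infer_element(at$elety), toupper(elem))
  orig <- tapply(at$resno, seqno, function(v) v[1])

  s <- rp_structure(
    data.frame(resno = seqno, resid = resid, elety = at$elety, element = elem,
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE),
    label = label, orig_resno = as.integer(orig)
  )
  if (n_residues(s) < 2) rp_stop("NoChainFound", "fewer than 2 standard residues")
  s
}

#' Write a structure as fixed-column PDB
#'
#' @param s an [rp_structure()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(s, file) {
  a <- s$atoms
  n <- nrow(a)
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = rep("A", n), o = rep(1, n), b = rep(0, n))
  invisible(file)
}

#' Remove hydrogen (and deuterium) atoms
#'
#' Detection is element-based; when the element field is missing it is
#' inferred from the atom-name convention (leading digits then H).
#'
#' @param s an [rp_structure()].
#' @return The structure without element-H/D atoms; all other atoms are
#'   preserved in order.
#' @export
strip_hydrogens <- function(s) {
  elem <- s$atoms$element
  elem[is.na(elem) | elem == ""] <- infer_element(s$atoms$elety[is.na(elem) | elem == ""])
  s$atoms <- s$atoms[!(toupper(elem) %in% c("H", "D")), , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Extract the backbone scaffold (N, CA, C, O) of a structure
#'
#' Side-chain atoms and the terminal OXT are deleted; backbone coordinates
#' are untouched.  Every residue must carry exactly one of each backbone
#' atom.
#'
#' @param s an [rp_structure()].
#' @return An object of class `rp_backbone` (also an `rp_structure`).
#' @export
extract_backbone <- function(s) {
  a <- s$atoms
  for (i in seq_len(n_residues(s))) {
    present <- a$elety[a$resno == i]
    for (bb in BACKBONE_ATOMS) {
      if (sum(present == bb) != 1) {
        rp_stop("MissingBackboneAtom",
                sprintf("residue %d lacks backbone atom %s", i, bb))
      }
    }
  }
  s$atoms <- a[a$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  rownames(s$atoms) <- NULL
  class(s) <- unique(c("rp_backbone", class(s)))
  s
}

#' Count heavy atoms missing from the standard residue composition
#'
#' Compares each residue's atoms with the expected backbone plus
#' side-chain heavy-atom set of its amino acid; extra atoms (e.g. OXT)
#' are ignored.
#'
#' @param s an [rp_structure()].
#' @return list with `total` missing-atom count and a per-residue data
#'   frame (`resno`, `aa`, `n_missing`, `missing` names).
#' @export
count_missing_atoms <- function(s) {
  per <- lapply(seq_len(n_residues(s)), function(i) {
    aa3 <- AA_ONE_TO_THREE[s$sequence[i]]
    expected <- c(BACKBONE_ATOMS, aa_sidechain_atoms(aa3))
    present <- s$atoms$elety[s$atoms$resno == i]
    miss <- setdiff(expected, present)
    data.frame(resno = i, aa = s$sequence[i], n_missing = length(miss),
               missing = paste(miss, collapse = ","), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(total = sum(per$n_missing), per_residue = per)
}

#' Complete missing side-chain atoms with the built-in rotamer placer
#'
#' Residues with an incomplete heavy-atom set get their whole side chain
#' rebuilt (constrained to the structure's own sequence) with the
#' clash-minimizing placer; complete residues are left untouched.
#'
#' @param s an [rp_structure()].
#' @param settings a [repack_settings()].
#' @return A completed [rp_structure()].
#' @export
complete_side_chains <- function(s, settings = repack_settings()) {
  miss <- count_missing_atoms(s)
  bad <- miss$per_residue$resno[miss$per_residue$n_missing > 0]
  if (length(bad) == 0) return(s)
  # drop incomplete side chains, rebuild them onto the fixed backbone
  drop <- s$atoms$resno %in% bad & !(s$atoms$elety %in% c(BACKBONE_ATOMS, "OXT"))
  s$atoms <- s$atoms[!drop, , drop = FALSE]
  repack_side_chains(s, structure_sequence(s), settings,
                     rebuild_only = bad)
}
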