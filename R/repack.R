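#' Random sequence permutation
#'
#' Uniformly shuffles an amino-acid sequence with a seeded Fisher-Yates
#' draw.  The permuted sequence has exactly the wild-type composition, so
#' the average side-chain size of the chain is conserved; only the spatial
#' arrangement of side-chain sizes changes once the permutant is repacked.
#'
#' @param seq one-letter amino-acid string (or character vector).
#' @param seed integer seed; the shuffle depends on nothing else.
#' @return A `rp_permutation` record with fields `source_sequence`,
#'   `permuted_sequence`, `seed` and `mapping` (permuted position i holds
#'   source residue `mapping[i]`).
#' @export
permute_sequence <- function(seq, seed) {
  aa <- if (length(seq) == 1) strsplit(seq, "")[[1]] else seq
  if (length(aa) < 1) rp_stop("InvalidAlphabet", "empty sequence")
  if (!all(aa %in% names(AA_ONE_TO_THREE))) {
    bad <- which(!aa %in% names(AA_ONE_TO_THREE))[1]
    rp_stop("InvalidAlphabet",
            sprintf("invalid amino-acid code '%s' at position %d", aa[bad], bad))
  }
  mapping <- with_preserved_seed(seed, sample.int(length(aa)))
  structure(list(
    source_sequence = paste(aa, collapse = ""),
    permuted_sequence = paste(aa[mapping], collapse = ""),
    seed = as.integer(seed),
    mapping = mapping
  ), class = "rp_permutation")
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Settings for the built-in side-chain placer
#'
#' The placer is a deterministic, repulsive-steric-only repacker: side
#' chains are built from ideal internal-coordinate templates, chi1/chi2
#' are sampled from \{-60, 60, 180\} degrees (deeper torsions fixed at
#' 180), residues are placed greedily in descending side-chain size order
#' and each residue takes the rotamer with the fewest steric clashes
#' against the backbone and already-placed atoms.  Attractive
#' physico-chemical terms are deliberately not modelled.
#'
#' @param clash_distance heavy-atom clash threshold in Angstrom.
#' @param max_sweeps refinement passes after the greedy placement.
#' @param pack_shell packing-shell radius in Angstrom: among rotamers with
#'   equally few clashes, the one with the most environment atoms within
#'   this radius is chosen (side chains pack inward, as a rotamer-prior
#'   stand-in); remaining ties fall to the lowest rotamer index.
#' @param external_tool optional path to an external repacker executable
#'   (invoked as `tool -i backbone.pdb -s seq.txt -o out.pdb`); its output
#'   is validated for an unchanged backbone on read-back.
#' @return A `repack_settings` list.
#' @export
repack_settings <- function(clash_distance = 2.5, max_sweeps = 2,
                            pack_shell = 6.0, external_tool = NULL) {
  stopifnot(clash_distance > 0, max_sweeps >= 0, pack_shell >= clash_distance)
  structure(list(clash_distance = clash_distance, max_sweeps = max_sweeps,
                 pack_shell = pack_shell, external_tool = external_tool),
            class = "repack_settings")
}

CHI_CHOICES <- c(-60, 60, 180)

# enumerate rotamers for a residue: chi1-major grid over sampled chis
rotamer_grid <- function(aa3) {
  k <- aa_n_sampled_chis(aa3)
  if (k == 0) return(list(numeric(0)))
  if (k == 1) return(lapply(CHI_CHOICES, function(c1) c(c1)))
  out <- list()
  for (c1 in CHI_CHOICES) for (c2 in CHI_CHOICES) out[[length(out) + 1]] <- c(c1, c2)
  out
}

# build side-chain heavy atoms for one residue from its backbone frame
# and chi values; returns a matrix with rownames = atom names
build_side_chain <- function(aa3, n_xyz, ca_xyz, c_xyz, chi) {
  tmpl <- AA_SIDECHAIN_TEMPLATES[[aa3]]
  if (is.null(tmpl)) return(matrix(numeric(0), 0, 3))
  pos <- list(N = n_xyz, CA = ca_xyz, C = c_xyz)
  for (r in seq_len(nrow(tmpl))) {
    row <- tmpl[r, ]
    tor <- switch(row$tors,
                  fix  = row$off,
                  chi1 = chi[1] + row$off,
                  chi2 = chi[2] + row$off,
                  chi3 = 180 + row$off,
                  chi4 = 180 + row$off)
    pos[[row$atom]] <- place_atom(pos[[row$a]], pos[[row$b]], pos[[row$c]],
                                  row$bond, row$angle, tor)
  }
  sc <- tmpl$atom
  do.call(rbind, setNames(pos[sc], sc))
}

# number of clashes between candidate atoms and an environment block
count_env_clashes <- function(cand, env, threshold) {
  if (nrow(cand) == 0 || nrow(env) == 0) return(0L)
  d2 <- outer(rowSums(cand^2), rowSums(env^2), `+`) - 2 * cand %*% t(env)
  sum(d2 < threshold^2)
}

#' Count steric clashes in a structure
#'
#' Counts unordered heavy-atom pairs closer than `threshold`.  Pairs
#' whose distance is dictated by covalent backbone geometry rather than
#' packing are excluded: pairs within one residue, and pairs between
#' adjacent residues in which both atoms belong to the backbone
#' neighbourhood (N, CA, C, O, OXT or CB).  An ideal-geometry structure
#' therefore scores zero.
#'
#' @param s an [rp_structure()].
#' @param threshold distance threshold in Angstrom.
#' @return integer clash count.
#' @export
count_clashes <- function(s, threshold = 2.5) {
  a <- strip_hydrogens(s)$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pairs <- cpp_close_pairs(xyz, threshold)
  if (nrow(pairs) == 0) return(0L)
  ri <- a$resno[pairs[, 1]]; rj <- a$resno[pairs[, 2]]
  ei <- a$elety[pairs[, 1]]; ej <- a$elety[pairs[, 2]]
  same <- ri == rj
  local_set <- c("N", "CA", "C", "O", "OXT", "CB")
  peptide <- (abs(ri - rj) == 1) & ei %in% local_set & ej %in% local_set
  sum(!same & !peptide)
}

#' Repack side chains onto a fixed backbone
#'
#' Threads `seq` onto the backbone of `b` and rebuilds all side chains
#' with the clash-minimizing rotamer placer (see [repack_settings()]).
#' Backbone coordinates are preserved exactly.
#'
#' @param b an `rp_backbone` (or any [rp_structure()]; only N/CA/C/O and
#'   OXT atoms are kept unless `rebuild_only` is given).
#' @param seq one-letter sequence of the same length as the backbone.
#' @param settings a [repack_settings()].
#' @param rebuild_only optional residue indices: only these side chains
#'   are rebuilt, all other atoms (including existing side chains) are
#'   kept as-is.
#' @return An [rp_structure()] carrying the full heavy-atom set of `seq`.
#' @export
repack_side_chains <- function(b, seq, settings = repack_settings(),
                               rebuild_only = NULL) {
  aa1 <- if (length(seq) == 1) strsplit(seq, "")[[1]] else seq
  n <- n_residues(b)
  if (length(aa1) != n) {
    rp_stop("LengthMismatch",
            sprintf("sequence length %d != backbone length %d", length(aa1), n))
  }
  if (!all(aa1 %in% names(AA_ONE_TO_THREE))) {
    rp_stop("InvalidAlphabet", "sequence contains invalid amino-acid codes")
  }
  if (!is.null(settings$external_tool)) {
    return(repack_external(b, aa1, settings))
  }
  aa3 <- aa_one_to_three(aa1)
  a <- b$atoms
  if (is.null(rebuild_only)) {
    a <- a[a$elety %in% c(BACKBONE_ATOMS, "OXT"), , drop = FALSE]
    rebuild <- seq_len(n)
  } else {
    rebuild <- sort(rebuild_only)
  }
  bb <- lapply(seq_len(n), function(i) {
    ri <- a[a$resno == i, , drop = FALSE]
    get1 <- function(nm) {
      row <- ri[ri$elety == nm, , drop = FALSE]
      if (nrow(row) != 1) rp_stop("MissingBackboneAtom",
                                  sprintf("residue %d lacks backbone atom %s", i, nm))
      as.numeric(row[1, c("x", "y", "z")])
    }
    list(N = get1("N"), CA = get1("CA"), C = get1("C"))
  })
  # environment: all backbone/kept atoms
  env <- as.matrix(a[, c("x", "y", "z")])
  placed <- vector("list", n)      # side-chain matrices for rebuilt residues
  # greedy order: descending side-chain heavy-atom count, then index
  sizes <- vapply(aa3, function(x) length(aa_sidechain_atoms(x)), integer(1))
  order_res <- rebuild[order(-sizes[rebuild], rebuild)]
  # fewest clashes wins; among clash-ties the rotamer packing against the
  # most neighbours (heavy atoms within pack_shell) is taken, then the
  # lowest rotamer index
  choose_rotamer <- function(i, env_i) {
    grid <- rotamer_grid(aa3[i])
    best <- NULL; best_clash <- Inf; best_pack <- -1L
    for (g in grid) {
      sc <- build_side_chain(aa3[i], bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C, g)
      cl <- count_env_clashes(sc, env_i, settings$clash_distance)
      pk <- count_env_clashes(sc, env_i, settings$pack_shell)
      if (cl < best_clash || (cl == best_clash && pk > best_pack)) {
        best_clash <- cl; best_pack <- pk; best <- sc
      }
    }
    best
  }
  for (i in order_res) {
    sc <- choose_rotamer(i, env)
    placed[[i]] <- sc
    if (nrow(sc) > 0) env <- rbind(env, sc)
  }
  if (settings$max_sweeps > 0 && length(order_res) > 1) {
    n_bb <- nrow(a)
    for (sweep in seq_len(settings$max_sweeps)) {
      for (i in order_res) {
        others <- do.call(rbind, c(list(as.matrix(a[, c("x", "y", "z")])),
                                   placed[setdiff(rebuild, i)]))
        placed[[i]] <- choose_rotamer(i, others)
      }
    }
  }
  # assemble: per residue backbone atoms then template-order side chain
  rows <- lapply(seq_len(n), function(i) {
    ri <- a[a$resno == i, , drop = FALSE]
    ri$resid <- aa3[i]
    if (i %in% rebuild) {
      sc <- placed[[i]]
      if (!is.null(sc) && nrow(sc) > 0) {
        ri <- rbind(ri[ri$elety != "OXT", , drop = FALSE],
                    data.frame(resno = i, resid = aa3[i], elety = rownames(sc),
                               element = infer_element(rownames(sc)),
                               x = sc[, 1], y = sc[, 2], z = sc[, 3],
                               stringsAsFactors = FALSE),
                    ri[ri$elety == "OXT", , drop = FALSE])
      }
    }
    ri
  })
  out <- rp_structure(do.call(rbind, rows), label = paste0(b$label, "_repacked"))
  out
}

# external repacker hook: SCWRL-compatible invocation, backbone validated
repack_external <- function(b, aa1, settings) {
  dir <- tempfile("repack"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  bb_pdb <- file.path(dir, "backbone.pdb")
  seq_f <- file.path(dir, "seq.txt")
  out_pdb <- file.path(dir, "out.pdb")
  write_structure(b, bb_pdb)
  writeLines(paste(aa1, collapse = ""), seq_f)
  status <- system2(settings$external_tool,
                    c("-i", bb_pdb, "-s", seq_f, "-o", out_pdb))
  if (!identical(status, 0L) || !file.exists(out_pdb)) {
    rp_stop("ExternalToolFailure",
            sprintf("external repacker exited with status %s", status))
  }
  out <- read_structure(out_pdb, label = paste0(b$label, "_repacked"))
  bb_in <- b$atoms[b$atoms$elety %in% BACKBONE_ATOMS, c("x", "y", "z")]
  bb_out <- out$atoms[out$atoms$elety %in% BACKBONE_ATOMS, c("x", "y", "z")]
  if (nrow(bb_in) != nrow(bb_out) ||
      max(abs(as.matrix(bb_in) - as.matrix(bb_out))) > 1e-2) {
    rp_stop("ExternalToolFailure", "external repacker altered the backbone")
  }
  out
}

#' Homopolymer repacking probe
#'
#' Repacks the backbone with a single residue type.  Poly-alanine probes
#' the minimal backbone-driven contact set, poly-tryptophan (or
#' poly-arginine) an upper bound of achievable contacts, and a
#' medium-sized residue (e.g. leucine) probes homogeneous average-size
#' packing.
#'
#' @param b an `rp_backbone`.
#' @param aa one-letter residue code to thread at every position.
#' @param settings a [repack_settings()].
#' @return An [rp_structure()].
#' @export
probe_homopolymer <- function(b, aa, settings = repack_settings()) {
  if (!aa %in% names(AA_ONE_TO_THREE)) {
    rp_stop("InvalidAlphabet", sprintf("invalid amino-acid code '%s'", aa))
  }
  repack_side_chains(b, strrep(aa, n_residues(b)), settings)
}
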