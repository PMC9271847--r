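#' Specification of a synthetic toy structure
#'
#' A toy spec is an ordered list of secondary-structure segments (helix,
#' strand or loop), each with a length and an optional sequence, plus
#' optional assembly instructions that place non-loop segments as rigid
#' bodies (loops between placed segments are rebuilt as bridges).  With no
#' assembly the chain is grown residue-by-residue from canonical phi/psi
#' torsions (helix -57/-47, strand -139/+135).
#'
#' @param segments list of `list(type, length, seq)`; `type` one of
#'   "helix", "strand", "loop"; `seq` defaults to poly-alanine.
#' @param assembly optional list of placements
#'   `list(segment = k, translate = c(x, y, z), rotate = c(rx, ry, rz))`
#'   (Angstrom / degrees, applied to the segment in its canonical frame:
#'   centred, chain axis along +x).
#' @return An `rp_toy_spec`.
#' @export
toy_spec <- function(segments, assembly = NULL) {
  for (s in segments) {
    if (!s$type %in% c("helix", "strand", "loop")) {
      rp_stop("InvalidSpec", sprintf("unknown segment type '%s'", s$type))
    }
    if (is.null(s$length) || s$length < 1) rp_stop("InvalidSpec", "bad segment length")
    if (!is.null(s$seq) && nchar(s$seq) != s$length) {
      rp_stop("InvalidSpec", "segment sequence length mismatch")
    }
  }
  if (!is.null(assembly)) {
    placed <- vapply(assembly, function(p) p$segment, numeric(1))
    for (k in placed) {
      if (k > length(segments) || segments[[k]]$type == "loop") {
        rp_stop("InvalidSpec", "placements must reference non-loop segments")
      }
    }
  }
  structure(list(segments = segments, assembly = assembly),
            class = "rp_toy_spec")
}

toy_sequence <- function(spec) {
  paste(vapply(spec$segments, function(s) {
    if (is.null(s$seq)) strrep("A", s$length) else s$seq
  }, character(1)), collapse = "")
}

# torsions for every residue of the spec, by segment type
toy_torsions <- function(spec) {
  phi <- psi <- numeric(0)
  for (s in spec$segments) {
    t <- SS_TORSIONS[[s$type]]
    phi <- c(phi, rep(t["phi"], s$length))
    psi <- c(psi, rep(t["psi"], s$length))
  }
  list(phi = unname(phi), psi = unname(psi))
}

# bridge CA positions between two anchors: L interior points on a circular
# arc such that all L+1 consecutive chords equal the virtual CA-CA bond
bridge_ca_positions <- function(p_start, p_end, L, bulge_dir, spacing = 3.8) {
  D <- vnorm(p_end - p_start)
  need <- spacing * (L + 1)
  if (D > need + 1e-9) {
    rp_stop("InvalidSpec",
            sprintf("bridge of %d residues cannot span %.1f A (max %.1f A)", L, D, need))
  }
  u <- vunit(p_end - p_start)
  w <- vunit(bulge_dir - sum(bulge_dir * u) * u)
  if (D > need - 1e-6) {  # essentially collinear
    return(t(vapply(seq_len(L), function(k) p_start + u * D * k / (L + 1),
                    numeric(3))))
  }
  # chord c = 2R sin(a), full chord D = 2R sin((L+1) a): solve for a
  f <- function(a) sin((L + 1) * a) - (D / spacing) * sin(a)
  lo <- 1e-9; hi <- pi / (L + 1) - 1e-9
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  a <- (lo + hi) / 2
  R <- spacing / (2 * sin(a))
  mid_pt <- (p_start + p_end) / 2
  # center such that the arc apex lies on the bulge side
  ctr <- mid_pt - R * cos((L + 1) * a) * w
  # endpoint angles are -(L+1)a and +(L+1)a in the (u, w) basis
  t(vapply(seq_len(L), function(k) {
    ang <- -(L + 1) * a + 2 * a * k
    ctr + R * (sin(ang) * u + cos(ang) * w)
  }, numeric(3)))
}

# approximate N/C placement for a bridge residue from its CA, the local
# chain tangent and an out-of-chain normal (ideal N-CA-C angle preserved)
bridge_backbone_from_ca <- function(ca_prev, ca, ca_next, normal) {
  t <- vunit(ca_next - ca_prev)
  n <- vunit(normal - sum(normal * t) * t)
  a <- (180 - BB_GEOM$ang_n_ca_c) / 2 * pi / 180
  u1 <- -cos(a) * t + sin(a) * n
  u2 <-  cos(a) * t + sin(a) * n
  list(N = ca + BB_GEOM$n_ca * u1, CA = ca, C = ca + BB_GEOM$ca_c * u2)
}

#' Generate a synthetic toy structure
#'
#' Builds an ideal-geometry backbone from the spec (see [toy_spec()]) and
#' threads the spec's sequence onto it with the built-in rotamer placer.
#' Construction is fully deterministic for a fixed (spec, seed).
#'
#' @param spec an [toy_spec()].
#' @param seed integer; reserved for randomized variants, the default
#'   builder is deterministic.
#' @param settings a [repack_settings()] for the side-chain build.
#' @return An [rp_structure()].
#' @export
make_toy_structure <- function(spec, seed = 1, settings = repack_settings()) {
  if (!inherits(spec, "rp_toy_spec")) rp_stop("InvalidSpec", "not an rp_toy_spec")
  segs <- spec$segments
  n_seg <- length(segs)
  seg_len <- vapply(segs, function(s) s$length, numeric(1))
  seg_end <- cumsum(seg_len)
  seg_start <- seg_end - seg_len + 1
  n <- sum(seg_len)
  tor <- toy_torsions(spec)

  if (is.null(spec$assembly)) {
    bb <- build_backbone_from_torsions(tor$phi, tor$psi)
    coords <- lapply(bb, function(m) list(N = m["N", ], CA = m["CA", ], C = m["C", ]))
  } else {
    placements <- setNames(spec$assembly,
                           vapply(spec$assembly, function(p) p$segment, numeric(1)))
    coords <- vector("list", n)
    # rigid-placed segments, each built from its own torsions
    for (k in seq_len(n_seg)) {
      if (segs[[k]]$type == "loop") next
      pk <- placements[[as.character(k)]]
      if (is.null(pk)) rp_stop("InvalidSpec",
                               sprintf("segment %d needs a placement", k))
      t <- SS_TORSIONS[[segs[[k]]$type]]
      bb <- build_backbone_from_torsions(rep(t["phi"], seg_len[k]),
                                         rep(t["psi"], seg_len[k]))
      xyz <- do.call(rbind, bb)
      ca_idx <- seq(2, nrow(xyz), by = 3)
      xyz <- canonical_frame(xyz, ca_idx)
      xyz <- apply_rigid(xyz,
                         rotate = if (is.null(pk$rotate)) c(0, 0, 0) else pk$rotate,
                         translate = if (is.null(pk$translate)) c(0, 0, 0) else pk$translate)
      for (j in seq_len(seg_len[k])) {
        coords[[seg_start[k] + j - 1]] <-
          list(N = xyz[3 * j - 2, ], CA = xyz[3 * j - 1, ], C = xyz[3 * j, ])
      }
    }
    # loops bridge the two flanking placed segments
    for (k in seq_len(n_seg)) {
      if (segs[[k]]$type != "loop") next
      if (k == 1 || k == n_seg) {
        rp_stop("InvalidSpec", "terminal loops are not supported with assembly")
      }
      iA <- seg_end[k - 1]; iB <- seg_end[k] + 1
      caA <- coords[[iA]]$CA; caB <- coords[[iB]]$CA
      centroid <- Reduce(`+`, lapply(coords[!vapply(coords, is.null, logical(1))],
                                     `[[`, "CA")) / sum(!vapply(coords, is.null, logical(1)))
      bulge <- caA + caB - 2 * centroid
      if (vnorm(bulge) < 1e-6) bulge <- c(0, 0, 1)
      cas <- bridge_ca_positions(caA, caB, seg_len[k], vunit(bulge))
      path <- rbind(caA, cas, caB)
      for (j in seq_len(seg_len[k])) {
        coords[[seg_start[k] + j - 1]] <-
          bridge_backbone_from_ca(path[j, ], path[j + 1, ], path[j + 2, ], vunit(bulge))
      }
    }
  }
  # carbonyl oxygens from measured psi (anti to the next amide nitrogen)
  rows <- list()
  for (i in seq_len(n)) {
    psi_i <- if (i < n) measure_torsion(coords[[i]]$N, coords[[i]]$CA,
                                        coords[[i]]$C, coords[[i + 1]]$N) else 180
    O <- place_atom(coords[[i]]$N, coords[[i]]$CA, coords[[i]]$C,
                    BB_GEOM$c_o, BB_GEOM$ang_ca_c_o, psi_i - 180)
    xyz <- rbind(coords[[i]]$N, coords[[i]]$CA, coords[[i]]$C, O)
    rows[[i]] <- data.frame(resno = i, resid = "GLY",
                            elety = c("N", "CA", "C", "O"),
                            element = c("N", "C", "C", "O"),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  bb_struct <- rp_structure(do.call(rbind, rows), label = "toy")
  class(bb_struct) <- unique(c("rp_backbone", class(bb_struct)))
  out <- repack_side_chains(bb_struct, toy_sequence(spec), settings)
  out$label <- "toy"
  out
}

#' Convenience toy structures
#'
#' `toy_helix()` and `toy_strand()` are single ideal segments;
#' `toy_hairpin()` is a two-stranded antiparallel beta-hairpin with
#' geometrically paired strands.
#'
#' @param n,n_strand,n_turn residue counts.
#' @param seq optional sequence (defaults to poly-alanine).
#' @param strand_sep inter-strand C-alpha spacing in Angstrom.
#' @param seed passed to [make_toy_structure()].
#' @return An [rp_structure()].
#' @export
toy_helix <- function(n = 10, seq = NULL, seed = 1) {
  make_toy_structure(toy_spec(list(list(type = "helix", length = n, seq = seq))), seed)
}

#' @rdname toy_helix
#' @export
toy_strand <- function(n = 6, seq = NULL, seed = 1) {
  make_toy_structure(toy_spec(list(list(type = "strand", length = n, seq = seq))), seed)
}

#' @rdname toy_helix
#' @export
toy_hairpin <- function(n_strand = 6, n_turn = 2, seq = NULL,
                        strand_sep = 5.0, seed = 1) {
  segs <- list(list(type = "strand", length = n_strand),
               list(type = "loop", length = n_turn),
               list(type = "strand", length = n_strand))
  if (!is.null(seq)) {
    stopifnot(nchar(seq) == 2 * n_strand + n_turn)
    segs[[1]]$seq <- substr(seq, 1, n_strand)
    segs[[2]]$seq <- substr(seq, n_strand + 1, n_strand + n_turn)
    segs[[3]]$seq <- substr(seq, n_strand + n_turn + 1, 2 * n_strand + n_turn)
  }
  asm <- list(list(segment = 1, translate = c(0, 0, 0)),
              list(segment = 3, rotate = c(0, 0, 180),
                   translate = c(0, strand_sep, 0)))
  make_toy_structure(toy_spec(segs, asm), seed)
}

#' Benchmark beta-sandwich toy scaffolds for robustness studies
#'
#' Builds a 34-residue four-stranded beta-sandwich: two antiparallel
#' hairpins stacked face to face with an 8 Angstrom sheet-sheet gap that
#' only side chains can bridge.  Two sequence variants probe the two
#' phenotypes the RP method distinguishes:
#' \describe{
#'   \item{`balanced`}{medium-sized hydrophobics (V/I/L/T) throughout:
#'     whatever the permutation, medium side chains always line the gap
#'     and the inter-sheet contacts survive.}
#'   \item{`bulky_core`}{the inter-sheet core is held together
#'     exclusively by three tryptophans on the top sheet (every other
#'     residue is A/S/G, too short to bridge); permutation scatters the
#'     tryptophans and the core contacts are lost, mirroring a
#'     tryptophan-packed natural core.}
#' }
#'
#' @param variant `"balanced"` or `"bulky_core"`.
#' @param gap sheet-sheet spacing in Angstrom.
#' @param seed passed to [make_toy_structure()].
#' @return list with `structure` (an [rp_structure()]), `regions` (named
#'   residue-index sets: `core` = the gap-lining face, `periphery`),
#'   `sheet_a`, `sheet_b` and `core_positions` (the tryptophan sites of
#'   the bulky variant).
#' @export
toy_sandwich <- function(variant = c("balanced", "bulky_core"),
                         gap = 8.0, seed = 1) {
  variant <- match.arg(variant)
  ns <- 7
  seqs <- switch(variant,
    balanced = c("TVIVTVI", "VT", "IVTVIVT", "TV", "VTIVTVI", "VT", "IVTVIVT"),
    bulky_core = c("ASASASA", "AG", "SASASAS", "GA", "SAWAWAS", "AG", "ASWASAS"))
  segs <- list(list(type = "strand", length = ns, seq = seqs[1]),
               list(type = "loop", length = 2, seq = seqs[2]),
               list(type = "strand", length = ns, seq = seqs[3]),
               list(type = "loop", length = 2, seq = seqs[4]),
               list(type = "strand", length = ns, seq = seqs[5]),
               list(type = "loop", length = 2, seq = seqs[6]),
               list(type = "strand", length = ns, seq = seqs[7]))
  asm <- list(list(segment = 1, translate = c(0, 0, 0)),
              list(segment = 3, rotate = c(0, 0, 180), translate = c(0, 5, 0)),
              list(segment = 5, rotate = c(180, 0, 0), translate = c(0, 5, gap)),
              list(segment = 7, rotate = c(180, 0, 180), translate = c(0, 0, gap)))
  s <- make_toy_structure(toy_spec(segs, asm), seed)
  s$label <- paste0("toy_", variant)
  sheet_a <- c(1:7, 10:16)
  sheet_b <- c(19:25, 28:34)
  list(structure = s,
       regions = list(core = sheet_b,
                      periphery = setdiff(seq_len(n_residues(s)), sheet_b)),
       sheet_a = sheet_a, sheet_b = sheet_b,
       core_positions = c(21, 23, 30))
}
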