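# shared fixtures, built once per test run

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_helix10 <- function() fx("helix10", function() toy_helix(10))
fx_hairpin <- function() fx("hairpin", function() toy_hairpin(6, 2))
fx_hairpin_cm <- function() fx("hairpin_cm", function() compute_contact_map(fx_hairpin()))
fx_hairpin_top <- function() fx("hairpin_top", function()
  build_topology(fx_hairpin(), fx_hairpin_cm()))

# minimal hand-written PDB text: two alanine residues, backbone + CB
minimal_pdb <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  ALA A   2       3.983   2.843   0.000  1.00  0.00           C",
    "ATOM      8  C   ALA A   2       5.496   2.683   0.000  1.00  0.00           C",
    "ATOM      9  O   ALA A   2       6.009   1.566   0.000  1.00  0.00           O",
    "ATOM     10  CB  ALA A   2       3.528   3.654   1.214  1.00  0.00           C",
    "TER", "END")
}

# brute-force all-pairs contact map (independent oracle for the
# grid-accelerated implementation)
brute_force_contacts <- function(s, cutoff = 4.5, min_sep = 3) {
  s <- strip_hydrogens(s)
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- n_residues(s)
  out <- list()
  for (i in seq_len(n - 1)) {
    ai <- xyz[a$resno == i, , drop = FALSE]
    for (j in (i + min_sep):n) {
      if (j > n) break
      aj <- xyz[a$resno == j, , drop = FALSE]
      d2 <- outer(rowSums(ai^2), rowSums(aj^2), `+`) - 2 * ai %*% t(aj)
      if (min(d2) < cutoff^2) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(data.frame(i = integer(0), j = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("i", "j")
  df[order(df$i, df$j), ]
}

# random heavy-atom cloud packaged as an rp_structure (for clash and
# contact oracles); residues of 3 atoms each
random_cloud_structure <- function(n_atoms = 48, seed = 1, spread = 12) {
  set.seed(seed)
  stopifnot(n_atoms %% 3 == 0)
  n_res <- n_atoms / 3
  atoms <- data.frame(
    resno = rep(seq_len(n_res), each = 3),
    resid = "GLY",
    elety = rep(c("N", "CA", "C"), n_res),
    element = rep(c("N", "C", "C"), n_res),
    x = runif(n_atoms, 0, spread), y = runif(n_atoms, 0, spread),
    z = runif(n_atoms, 0, spread), stringsAsFactors = FALSE)
  # every residue needs an O for rp_structure plausibility; reuse C coords
  o <- atoms[atoms$elety == "C", ]
  o$elety <- "O"; o$element <- "O"; o$x <- o$x + 0.4
  rp_structure(rbind(atoms, o), label = sprintf("cloud%d", seed))
}

# reference hysteresis automaton in plain R (oracle for the C++ one)
r_count_transitions <- function(q, q_unfolded = 0.3, q_folded = 0.8) {
  state <- 0L; n <- 0L
  for (v in q) {
    s <- if (v >= q_folded) 1L else if (v <= q_unfolded) -1L else 0L
    if (s == 0L) next
    if (state != 0L && s != state) n <- n + 1L
    state <- s
  }
  n
}
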