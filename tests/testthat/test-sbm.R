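# a straight 4-bead chain (nm) with no contacts: all bonded terms at their
# native minima, every pair within the bonded exclusion depth
chain4 <- function() {
  atoms <- data.frame(resno = rep(1:4, each = 4), resid = "GLY",
                      elety = rep(c("N", "CA", "C", "O"), 4),
                      element = rep(c("N", "C", "C", "O"), 4),
                      x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  # CA positions roughly 3.8 A apart with a slight kink (well-defined
  # dihedral); other backbone atoms nearby (unused by the C-alpha model)
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(6.5, 2.6, 0), c(9.0, 4.0, 2.2))
  for (r in 1:4) {
    idx <- which(atoms$resno == r)
    atoms[idx, c("x", "y", "z")] <-
      sweep(matrix(c(-1, 0, 0, 0, 0, 0, 1, 0.5, 0, 1.2, 1.6, 0), 4, 3, byrow = TRUE),
            2, ca[r, ], `+`)
  }
  rp_structure(atoms, label = "chain4")
}

empty_map <- function(n) {
  m <- fx_hairpin_cm()
  m$n_residues <- as.integer(n)
  m$contacts <- m$contacts[0, ]
  m$M <- 0L
  m
}

test_that("topology term counts are N-1, N-2, N-3, M", {
  s <- fx_hairpin()                      # N = 14
  cm <- fx_hairpin_cm()
  t <- build_topology(s, cm)
  expect_equal(nrow(t$bonds_idx), 13L)
  expect_equal(nrow(t$angles_idx), 12L)
  expect_equal(nrow(t$dihedrals_idx), 11L)
  expect_equal(nrow(t$contacts_idx), cm$M)
  # every contact pair is excluded from the generic repulsion list
  nb_keys <- paste(t$nonbonded_idx[, 1], t$nonbonded_idx[, 2])
  con_keys <- paste(t$contacts_idx[, 1], t$contacts_idx[, 2])
  expect_length(intersect(nb_keys, con_keys), 0L)
  # contact minima are the native distances from the map
  expect_equal(t$contacts_d, cm$contacts$dij)
})

test_that("native energy of a contact-free 4-bead chain is exactly zero", {
  t <- build_topology(chain4(), empty_map(4))
  e <- potential_energy(t, t$native_coords)
  expect_equal(e$total, 0, tolerance = 1e-12)
  f <- sbm_forces(t, t$native_coords)
  expect_lt(max(abs(f)), 1e-6)
})

test_that("a bond stretched by 0.01 nm costs exactly 1 epsilon", {
  t <- build_topology(chain4(), empty_map(4))
  x <- t$native_coords
  # stretch the last bond along its own axis: only E_bond changes
  axis <- (x[4, ] - x[3, ]) / sqrt(sum((x[4, ] - x[3, ])^2))
  x[4, ] <- x[4, ] + 0.01 * axis
  e <- potential_energy(t, x)
  expect_equal(e$components$bond, 0.5 * 20000 * 1e-4, tolerance = 1e-9)
  # force on the stretched bead: magnitude k * delta along the bond axis
  f <- sbm_forces(t, x)
  expect_equal(sqrt(sum(f[4, ]^2)), 20000 * 0.01, tolerance = 1e-3)
  expect_equal(f[4, ] / sqrt(sum(f[4, ]^2)), unname(-axis), tolerance = 1e-3)
})

test_that("the 10-12 contact term has its minimum -eps exactly at d_ij", {
  t <- fx_hairpin_top()
  e_native <- potential_energy(t, t$native_coords)
  expect_equal(e_native$components$contact, -nrow(t$contacts_idx),
               tolerance = 1e-9)
  # numerical minimum of one pair term: perturbing any contact distance
  # upward or downward raises the contact energy
  s <- 1e-4
  for (dir in c(1 - s, 1 + s)) {
    x <- t$native_coords
    k <- 1
    i <- t$contacts_idx[k, 1]; j <- t$contacts_idx[k, 2]
    mid <- (x[i, ] + x[j, ]) / 2
    x[i, ] <- mid + (x[i, ] - mid) * dir
    x[j, ] <- mid + (x[j, ] - mid) * dir
    e <- potential_energy(t, x)
    expect_gt(e$components$contact, e_native$components$contact)
  }
})

test_that("analytic forces equal central-difference gradients", {
  t <- fx_hairpin_top()
  set.seed(7)
  for (rep in 1:3) {
    x <- t$native_coords + matrix(rnorm(3 * t$n_beads, sd = 0.04), ncol = 3)
    f <- sbm_forces(t, x)
    h <- 1e-6
    num <- matrix(0, t$n_beads, 3)
    for (i in seq_len(t$n_beads)) for (c in 1:3) {
      xp <- x; xp[i, c] <- xp[i, c] + h
      xm <- x; xm[i, c] <- xm[i, c] - h
      num[i, c] <- -(potential_energy(t, xp)$total -
                       potential_energy(t, xm)$total) / (2 * h)
    }
    expect_lt(max(abs(f - num)) / max(abs(f)), 1e-6)
  }
})

test_that("energy is invariant under rigid-body motion", {
  t <- fx_hairpin_top()
  set.seed(3)
  x <- t$native_coords + matrix(rnorm(3 * t$n_beads, sd = 0.05), ncol = 3)
  e0 <- potential_energy(t, x)$total
  for (rep in 1:5) {
    ang <- runif(3, -180, 180)
    R <- rpfold:::rotation_matrix(ang[1], ang[2], ang[3])
    shift <- runif(3, -5, 5)
    x2 <- sweep(t(R %*% t(x)), 2, shift, `+`)
    expect_lt(abs(potential_energy(t, x2)$total - e0), 1e-9)
  }
})

test_that("coordinate shape mismatches are rejected", {
  t <- fx_hairpin_top()
  expect_error(potential_energy(t, t$native_coords[-1, ]),
               class = "ShapeMismatch")
  expect_error(build_topology(fx_helix10(), fx_hairpin_cm()),
               class = "ContactSizeMismatch")
})

test_that("exported topology round-trips through the reader", {
  t <- fx_hairpin_top()
  ex <- export_topology(t)
  t2 <- read_topology(ex$top, ex$gro)
  # identical functional form: evaluate the re-read terms on the exact
  # native coordinates (the .gro file itself is only 1e-3 nm precise)
  e1 <- potential_energy(t, t$native_coords)
  e2 <- potential_energy(t2, t$native_coords)
  expect_equal(e2$total, e1$total, tolerance = 1e-6)
  set.seed(5)
  x <- t$native_coords + matrix(rnorm(3 * t$n_beads, sd = 0.03), ncol = 3)
  expect_equal(potential_energy(t2, x)$total, potential_energy(t, x)$total,
               tolerance = 1e-5)
})

test_that("export formats the expected sections", {
  t4 <- build_topology(chain4(), empty_map(4))
  ex <- export_topology(t4)
  bonds_at <- grep("\\[ bonds \\]", ex$top)
  pairs_at <- grep("\\[ pairs \\]", ex$top)
  excl_at <- grep("\\[ exclusions \\]", ex$top)
  expect_equal(sum(grepl("^  \\d+ \\d+ 1 ", ex$top[(bonds_at + 1):(pairs_at - 1)])), 3L)
  # empty contact list -> empty pairs section
  expect_equal(pairs_at + 2, excl_at)
})
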