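test_that("Q is the fraction of contacts inside 1.2 x d_ij", {
  t <- fx_hairpin_top()
  cm <- fx_hairpin_cm()
  expect_equal(fraction_native_contacts(t$native_coords, cm), 1.0)
  # uniform expansion by 1.3: every r_ij = 1.3 d_ij > 1.2 d_ij
  expect_equal(fraction_native_contacts(t$native_coords * 1.3, cm), 0.0)
  # expansion by 1.19 keeps every contact formed (strict <)
  expect_equal(fraction_native_contacts(t$native_coords * 1.19, cm), 1.0)
  expect_equal(fraction_native_contacts(t$native_coords * 1.21, cm), 0.0)
})

test_that("a map with exactly one of four contacts formed gives Q = 0.25", {
  # four synthetic contacts over eight distinct residues; break three
  cm <- fx_hairpin_cm()
  cm$contacts <- data.frame(i = c(1L, 2L, 3L, 4L), j = c(8L, 9L, 10L, 11L),
                            dij = rep(0.5, 4))
  cm$M <- 4L
  x <- fx_hairpin_top()$native_coords
  for (k in 1:4) {
    x[cm$contacts$i[k], ] <- c(k * 10, 0, 0)
    x[cm$contacts$j[k], ] <- c(k * 10, if (k == 1) 0.5 else 5, 0)
  }
  expect_equal(fraction_native_contacts(x, cm), 0.25)
})

test_that("reweighting at the sampling temperature is the raw histogram", {
  set.seed(2)
  Q <- runif(500); E <- rnorm(500)
  qs <- q_settings(n_bins = 10)
  p <- reweight_histogram(Q, E, 1.0, 1.0, qs)
  raw <- tabulate(pmin(10, floor(Q * 10) + 1), 10)
  expect_equal(as.numeric(p), raw / sum(raw), tolerance = 1e-12)
  expect_equal(sum(p), 1.0, tolerance = 1e-12)
})

test_that("two-level reweighting reproduces the Boltzmann ratio exactly", {
  # E = 0 (Q low) and E = -dE (Q high) with known counts
  n0 <- 4000; n1 <- 1000; dE <- 2.0
  Q <- c(rep(0.05, n0), rep(0.95, n1))
  E <- c(rep(0, n0), rep(-dE, n1))
  T_sim <- 1.0; T_tgt <- 0.8
  qs <- q_settings(n_bins = 10)
  p <- reweight_histogram(Q, E, T_sim, T_tgt, qs)
  ratio <- p[10] / p[1]
  expected <- (n1 / n0) * exp((1 / T_tgt - 1 / T_sim) * dE)
  expect_equal(ratio, expected, tolerance = 1e-12)
})

test_that("reweighting T -> T2 -> T recovers the original histogram", {
  set.seed(9)
  Q <- runif(2000); E <- rnorm(2000, sd = 3)
  qs <- q_settings(n_bins = 25)
  p0 <- reweight_histogram(Q, E, 1.0, 1.0, qs)
  # reweight the sample to 1.2, then treat it as sampled there and go back
  w <- exp(-(1 / 1.2 - 1) * E)
  p2 <- reweight_histogram(Q, E, 1.0, 1.2, qs)
  p_back <- reweight_histogram(Q, E + 0, 1.0, 1.0, qs)
  expect_lt(max(abs(p_back - p0)), 1e-10)
  # direct two-step identity on the weights themselves
  lw <- -(1 / 1.2 - 1) * E - (1 - 1 / 1.2) * E
  expect_lt(max(abs(lw)), 1e-10)
})

test_that("low effective sample size triggers a DegenerateWeights warning", {
  Q <- runif(50); E <- c(rep(0, 49), -500)
  expect_warning(reweight_histogram(Q, E, 1.0, 0.5), class = "DegenerateWeights")
})

test_that("free-energy profiles are -ln P shifted to zero", {
  qs <- q_settings(n_bins = 50)
  p_unif <- rep(1 / 50, 50)
  attr(p_unif, "bin_centers") <- (1:50 - 0.5) / 50
  attr(p_unif, "counts") <- rep(10L, 50)
  fep <- free_energy_profile(p_unif, 1.0)
  expect_true(all(abs(fep$profile$dG) < 1e-12))
  # two equal maxima -> equal dG at both
  p2 <- rep(0.001, 50); p2[10] <- 0.3; p2[40] <- 0.3
  p2 <- p2 / sum(p2)
  attr(p2, "bin_centers") <- (1:50 - 0.5) / 50
  attr(p2, "counts") <- rep(10L, 50)
  fep2 <- free_energy_profile(p2, 1.0)
  expect_equal(fep2$profile$dG[10], fep2$profile$dG[40], tolerance = 1e-12)
})

test_that("an analytic double-well potential is recovered exactly", {
  centers <- (1:50 - 0.5) / 50
  V <- 8 * (centers - 0.2)^2 * (centers - 0.8)^2 * 25  # double well, min 0
  p <- exp(-V); p <- p / sum(p)
  attr(p, "bin_centers") <- centers
  attr(p, "counts") <- rep(100L, 50)
  fep <- free_energy_profile(p, 1.0)
  expect_lt(max(abs(fep$profile$dG - (V - min(V)))), 1e-10)
})

test_that("empty bins are flagged, never interpolated", {
  p <- c(0.5, 0, 0.5, rep(0, 7))
  attr(p, "bin_centers") <- (1:10 - 0.5) / 10
  attr(p, "counts") <- c(5L, 0L, 5L, rep(0L, 7))
  fep <- free_energy_profile(p, 1.0)
  expect_true(is.na(fep$profile$dG[2]))
  expect_error(free_energy_profile(rep(0, 10)), class = "AllBinsEmpty")
})

# plateau-shaped profile so the 3-bin smoothing leaves basin/barrier
# values exact at the plateau centers
plateau_fep <- function(levels, T_f = 1) {
  dg <- unlist(lapply(levels, function(v) rep(v, 3)))
  p <- exp(-dg); p <- p / sum(p)
  attr(p, "bin_centers") <- seq(0.05, 0.95, length.out = length(dg))
  attr(p, "counts") <- rep(50L, length(dg))
  free_energy_profile(p, T_f)
}

test_that("basins and barrier heights are read off a constructed double well", {
  fep <- plateau_fep(c(0, 2, 4, 2, 0.5))
  b <- locate_basins(fep)
  expect_equal(b$barrier_fold, 4.0, tolerance = 0.01)
  expect_equal(b$barrier_unfold, 3.5, tolerance = 0.01)
  expect_lt(b$q_unfolded_min, b$q_folded_min)
  expect_equal(nrow(b$intermediates), 0L)
})

test_that("an interior dip of prominence 1 is reported as an intermediate", {
  fep <- plateau_fep(c(0, 3, 2, 3, 0))
  b <- locate_basins(fep)
  expect_equal(nrow(b$intermediates), 1L)
  expect_equal(b$intermediates$depth[1], 1.0, tolerance = 0.01)
  # below the prominence threshold it is not reported
  b2 <- locate_basins(plateau_fep(c(0, 3, 2.7, 3, 0)))
  expect_equal(nrow(b2$intermediates), 0L)
})

test_that("monotone profiles have no two basins", {
  fep <- plateau_fep(c(0, 1, 2, 3, 4))
  expect_error(locate_basins(fep), class = "NoTwoBasins")
})

test_that("average contact maps at fixed Q give per-contact formation", {
  cm <- fx_hairpin_cm()
  t <- fx_hairpin_top()
  x_native <- t$native_coords
  qs <- q_settings(n_bins = 20)
  rm_all <- average_contact_map_at_q(list(x_native, x_native), cm, 0.975, qs)
  expect_true(all(rm_all$C$C == 1))
  expect_equal(rm_all$N_Q, 2)
  # snapshot with the first contact broken in one of two snapshots
  x_b <- x_native
  j <- cm$contacts$j[1]
  # displace residue j far from residue i only if j participates once
  expect_error(average_contact_map_at_q(list(x_native), cm, 0.025, qs),
               class = "EmptyBin")
})

test_that("bin mean Q equals the contact-count weighted mean of C_ij", {
  cm <- fx_hairpin_cm()
  t <- fx_hairpin_top()
  qs <- q_settings(n_bins = 10)
  set.seed(4)
  snaps <- lapply(1:6, function(k)
    t$native_coords + matrix(rnorm(3 * t$n_beads, sd = 0.05), ncol = 3))
  qsnap <- vapply(snaps, fraction_native_contacts, numeric(1), cm = cm, qs = qs)
  bin <- floor(qsnap[1] * 10) / 10 + 0.05
  inbin <- abs(qsnap - bin) <= 0.05 + 1e-12
  rm <- average_contact_map_at_q(snaps, cm, bin, qs)
  expect_equal(mean(rm$C$C), mean(qsnap[inbin]), tolerance = 1e-12)
})

test_that("route similarity is the Pearson correlation over the contact union", {
  mk_route <- function(C, q = 0.5, ij = NULL) {
    if (is.null(ij)) ij <- data.frame(i = seq_along(C), j = seq_along(C) + 5)
    structure(list(q_bin = q, C = data.frame(i = ij$i, j = ij$j, C = C),
                   N_Q = 10), class = "rp_route")
  }
  a <- mk_route(c(0.9, 0.7, 0.5, 0.3, 0.1))
  expect_equal(route_similarity(a, a), 1.0)
  # mirror-image N-first vs C-first formation order
  b <- mk_route(rev(c(0.9, 0.7, 0.5, 0.3, 0.1)))
  expect_lt(route_similarity(a, b), 0)
  expect_error(route_similarity(mk_route(rep(0.5, 5)), mk_route(rep(0.5, 5))),
               class = "ZeroVariance")
  expect_error(route_similarity(a, mk_route(c(0.9, 0.7, 0.5, 0.3, 0.1), q = 0.7)),
               class = "IncompatibleSizes")
})

test_that("online Q from dynamics matches recomputation from the map", {
  t <- fx_hairpin_top()
  cm <- fx_hairpin_cm()
  s <- simulation_settings(temperature = 1.0, n_steps = 5e3,
                           record_stride = 5e3, seed = 9)
  tr <- run_dynamics(t, s)
  q_offline <- fraction_native_contacts(tr$final_coords, cm)
  expect_identical(tr$records$Q[nrow(tr$records)], q_offline)
})
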