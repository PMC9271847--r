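# single-bead-residue fixture with a controllable closest heavy-atom
# distance: residues 1 and `sep_res` sit exactly `gap` apart, the others
# far away along x
two_residue_fixture <- function(gap, sep_res = 5) {
  n <- max(5, sep_res)
  x <- 100 * seq_len(n)
  z <- rep(0, n)
  x[1] <- 0; x[sep_res] <- 0; z[sep_res] <- -gap
  rp_structure(data.frame(resno = seq_len(n), resid = "GLY", elety = "CA",
                          element = "C", x = x, y = 0, z = z,
                          stringsAsFactors = FALSE),
               label = "pairfix")
}

test_that("cutoff is a strict inequality on the closest heavy-atom pair", {
  near <- compute_contact_map(two_residue_fixture(4.0))
  expect_true(any(near$contacts$i == 1 & near$contacts$j == 5))
  far <- compute_contact_map(two_residue_fixture(4.6))
  expect_false(any(far$contacts$i == 1 & far$contacts$j == 5))
  at <- compute_contact_map(two_residue_fixture(4.5))
  expect_false(any(at$contacts$i == 1 & at$contacts$j == 5))
})

test_that("minimum sequence separation |i-j| >= 3 is enforced", {
  s <- two_residue_fixture(3.0, sep_res = 3)   # |i-j| = 2
  cm <- compute_contact_map(s, min_sep = 3)
  expect_false(any(cm$contacts$i == 1 & cm$contacts$j == 3))
  cm2 <- compute_contact_map(s, min_sep = 2)
  expect_true(any(cm2$contacts$i == 1 & cm2$contacts$j == 3))
})

test_that("grid-accelerated search equals the brute-force oracle", {
  fixtures <- c(list(fx_hairpin(), fx_helix10()),
                lapply(1:6, function(k) random_cloud_structure(36, k, spread = 14)))
  for (s in fixtures) {
    cm <- compute_contact_map(s)
    ref <- brute_force_contacts(s)
    expect_equal(cm$contacts[, c("i", "j")], ref, ignore_attr = TRUE)
  }
})

test_that("contact maps are nested in the cutoff", {
  for (s in list(fx_hairpin(), toy_sandwich("balanced")$structure)) {
    keys <- function(cutoff) {
      cm <- compute_contact_map(s, cutoff)
      paste(cm$contacts$i, cm$contacts$j)
    }
    k45 <- keys(4.5); k55 <- keys(5.5); k60 <- keys(6.0)
    expect_true(all(k45 %in% k55))
    expect_true(all(k55 %in% k60))
    expect_lt(length(k45), length(k60))
  }
})

test_that("d_ij is the native CA-CA distance in nm", {
  hp <- fx_hairpin()
  cm <- fx_hairpin_cm()
  ca <- ca_xyz(hp)
  for (k in seq_len(min(5, cm$M))) {
    i <- cm$contacts$i[k]; j <- cm$contacts$j[k]
    expect_equal(cm$contacts$dij[k],
                 sqrt(sum((ca[i, ] - ca[j, ])^2)) / 10, tolerance = 1e-12)
  }
})

test_that("composite maps count per-contact occupancy and conserve totals", {
  cm <- fx_hairpin_cm()
  comp5 <- composite_map(list(cm, cm, cm, cm, cm))
  expect_true(all(comp5$counts$count == 5L))
  expect_equal(sum(comp5$counts$count), 5L * cm$M)
  # disjoint maps: restrict to two disjoint halves
  a <- cm; a$contacts <- cm$contacts[1:3, ]
  b <- cm; b$contacts <- cm$contacts[4:6, ]
  comp2 <- composite_map(list(a, b))
  expect_true(all(comp2$counts$count == 1L))
  expect_equal(sum(comp2$counts$count), 6L)
})

test_that("difference maps partition exactly", {
  wt <- fx_hairpin_cm()
  dm_same <- difference_map(wt, wt)
  expect_equal(nrow(dm_same$wt_only), 0L)
  expect_equal(nrow(dm_same$rp_only), 0L)
  empty <- wt; empty$contacts <- wt$contacts[0, ]; empty$M <- 0L
  dm_empty <- difference_map(wt, empty)
  expect_equal(nrow(dm_empty$wt_only), wt$M)
  rp <- wt; rp$contacts <- wt$contacts[3:wt$M, ]
  dm <- difference_map(wt, rp)
  expect_equal(nrow(dm$common) + nrow(dm$wt_only), wt$M)
  expect_error(difference_map(wt, compute_contact_map(fx_helix10())),
               class = "IncompatibleSizes")
})

test_that("region gain/loss normalizes by wild-type contacts per region", {
  wt <- fx_hairpin_cm()
  # regions chosen so both hold wild-type contacts (cross-strand pairs)
  regions <- list(CORE = c(1:3, 11:14), periphery = c(4:6, 9:10))
  same <- region_gain_loss(wt, list(wt), regions)
  expect_true(all(same$gained == 0 & same$lost == 0))
  in_core <- wt$contacts$i %in% regions$CORE & wt$contacts$j %in% regions$CORE
  n_core <- sum(in_core)
  expect_gte(n_core, 2)
  # drop 2 CORE contacts, add 1 new periphery contact
  rp <- wt
  rp$contacts <- rbind(wt$contacts[-which(in_core)[1:2], ],
                       data.frame(i = 6L, j = 10L, dij = 0.6))
  rp$M <- nrow(rp$contacts)
  gl <- region_gain_loss(wt, list(rp), regions)
  n_peri <- sum(wt$contacts$i %in% regions$periphery &
                  wt$contacts$j %in% regions$periphery)
  expect_equal(gl$lost[gl$region == "CORE"], 2 / max(1, n_core))
  expect_equal(gl$gained[gl$region == "periphery"], 1 / max(1, n_peri))
  # region without wild-type contacts: gains normalized by max(1, 0)
  empty_reg <- list(void = c(7, 8))
  rp2 <- wt
  rp2$contacts <- rbind(wt$contacts, data.frame(i = 7L, j = 8L, dij = 0.5))
  rp2$M <- nrow(rp2$contacts)
  expect_warning(gl2 <- region_gain_loss(wt, list(rp2),
                                         c(empty_reg, list(x = integer(0)))),
                 class = "EmptyRegion")
  expect_equal(gl2$gained[gl2$region == "void"], 1)
})

test_that("fully conserved composites yield no sensitive regions", {
  cm <- fx_hairpin_cm()
  comp <- composite_map(list(cm, cm, cm, cm, cm))
  expect_equal(nrow(sensitive_regions(comp)), 0L)
})

test_that("an engineered variably-packed block is detected", {
  # 30-residue synthetic composite: conserved lattice everywhere except
  # residues 12-20, whose contacts appear in only 1 of 5 maps
  conserved <- data.frame(i = 1:7, j = 22:28, dij = 0.8)
  variable <- data.frame(i = 12:19, j = c(16:22, 25), dij = 0.8)
  mk <- function(with_var) {
    cc <- if (with_var) rbind(conserved, variable) else conserved
    m <- fx_hairpin_cm()
    m$n_residues <- 30L; m$contacts <- cc; m$M <- nrow(cc)
    m
  }
  comp <- composite_map(list(mk(TRUE), mk(FALSE), mk(FALSE), mk(FALSE), mk(FALSE)))
  seg <- sensitive_regions(comp, low_occupancy = 0.4)
  expect_gte(nrow(seg), 1L)
  covered <- unlist(lapply(seq_len(nrow(seg)), function(k) seg$start[k]:seg$end[k]))
  expect_true(all(12:19 %in% covered))
})

test_that("backbone-mediated contacts survive random permutation", {
  # contacts whose WT minimum distance is between backbone atoms are
  # present in every repacked permutant
  wt <- fx_hairpin()
  cm <- fx_hairpin_cm()
  a <- strip_hydrogens(wt)$atoms
  bbset <- c("N", "CA", "C", "O")
  backbone_driven <- vapply(seq_len(cm$M), function(k) {
    ai <- a[a$resno == cm$contacts$i[k] & a$elety %in% bbset, c("x", "y", "z")]
    aj <- a[a$resno == cm$contacts$j[k] & a$elety %in% bbset, c("x", "y", "z")]
    d2 <- outer(rowSums(ai^2), rowSums(aj^2), `+`) - 2 * as.matrix(ai) %*% t(as.matrix(aj))
    min(d2) < 4.5^2
  }, logical(1))
  b <- extract_backbone(wt)
  for (seed in 1:3) {
    p <- permute_sequence(structure_sequence(wt), seed)
    rp_cm <- compute_contact_map(repack_side_chains(b, p$permuted_sequence))
    rp_keys <- paste(rp_cm$contacts$i, rp_cm$contacts$j)
    wt_keys <- paste(cm$contacts$i, cm$contacts$j)[backbone_driven]
    expect_true(all(wt_keys %in% rp_keys))
  }
})

test_that("contact-map text files round-trip", {
  cm <- fx_hairpin_cm()
  f <- tempfile(fileext = ".cmap")
  write_contact_map(cm, f)
  back <- read_contact_map(f)
  expect_equal(back$n_residues, cm$n_residues)
  expect_equal(back$contacts$i, cm$contacts$i)
  expect_equal(back$contacts$j, cm$contacts$j)
  expect_equal(back$contacts$dij, cm$contacts$dij, tolerance = 1e-6)
  expect_equal(back$cutoff, cm$cutoff)
  expect_equal(back$min_sep, cm$min_sep)
})
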