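# hand-constructed folding metrics (bypassing simulation) for criteria tests
mk_metrics <- function(label = "m", q_u = 0.2, q_f = 0.9, barrier = 4,
                       intermediates = data.frame(q = numeric(0),
                                                  depth = numeric(0)),
                       route_C = c(0.9, 0.7, 0.5, 0.3, 0.1),
                       T_f = 1.0, transitions = 20) {
  qs <- q_settings(n_bins = 20)
  basins <- structure(list(
    q_unfolded_min = q_u, q_folded_min = q_f,
    barrier_fold = barrier, barrier_unfold = barrier - 0.5,
    q_barrier_top = 0.525, intermediates = intermediates,
    smoothed = data.frame(Q = numeric(0), dG = numeric(0))),
    class = "rp_basins")
  n_con <- length(route_C)
  route_counts <- matrix(0, qs$n_bins, n_con)
  bin_counts <- rep(0, qs$n_bins)
  b <- rpfold:::q_bin_index(0.525, qs)
  route_counts[b, ] <- route_C * 10
  bin_counts[b] <- 10
  structure(list(label = label, T_f = T_f, transitions = transitions,
                 fep = NULL, basins = basins,
                 route_counts = route_counts, bin_counts = bin_counts,
                 contacts = data.frame(i = seq_len(n_con),
                                       j = seq_len(n_con) + 5),
                 qs = qs, converged = TRUE),
            class = "rp_folding_metrics")
}

test_that("five permutants identical to the wild type are robust", {
  wt <- mk_metrics("wt")
  rps <- lapply(1:5, function(k) mk_metrics(paste0("rp", k)))
  rep <- assess_robustness(wt, rps)
  expect_equal(rep$verdict, "robust")
  expect_false(any(rep$per_rp$c1_fail | rep$per_rp$c2_fail | rep$per_rp$c3_fail))
  expect_true(all(rep$per_rp$route_similarity > 0.99))
})

test_that("a barrier change beyond 2 k_BT_f flags criterion 2", {
  wt <- mk_metrics("wt", barrier = 4)
  rps <- c(lapply(1:4, function(k) mk_metrics(paste0("rp", k), barrier = 4)),
           list(mk_metrics("rp5", barrier = 7)))
  rep <- assess_robustness(wt, rps)
  expect_equal(rep$verdict, "non_robust")
  expect_true(rep$per_rp$c2_fail[5])
  expect_false(any(rep$per_rp$c1_fail))
  # a 1.5 k_BT_f change stays within tolerance
  rep2 <- assess_robustness(wt, list(mk_metrics("rp", barrier = 5.5)))
  expect_equal(rep2$verdict, "robust")
})

test_that("an incompletely folding permutant flags criterion 1", {
  wt <- mk_metrics("wt", q_f = 0.9)
  rep <- assess_robustness(wt, list(mk_metrics("rp", q_f = 0.55)))
  expect_equal(rep$verdict, "non_robust")
  expect_true(rep$per_rp$c1_fail[1])
})

test_that("a changed intermediate count flags criterion 2", {
  wt <- mk_metrics("wt")
  rp <- mk_metrics("rp", intermediates = data.frame(q = 0.6, depth = 1.2))
  rep <- assess_robustness(wt, list(rp))
  expect_equal(rep$verdict, "non_robust")
  expect_true(rep$per_rp$c2_fail[1])
})

test_that("a route change alone is annotated but does not flip the verdict", {
  wt <- mk_metrics("wt")
  rp <- mk_metrics("rp", route_C = rev(c(0.9, 0.7, 0.5, 0.3, 0.1)))
  rep <- assess_robustness(wt, list(rp))
  expect_equal(rep$verdict, "robust")
  expect_true(rep$per_rp$route_changed[1])
  expect_false(rep$per_rp$c3_fail[1])
  # the same route change plus a basin shift fails criterion 3
  rp2 <- mk_metrics("rp2", q_f = 0.55,
                    route_C = rev(c(0.9, 0.7, 0.5, 0.3, 0.1)))
  rep2 <- assess_robustness(wt, list(rp2))
  expect_equal(rep2$verdict, "non_robust")
  expect_true(rep2$per_rp$c3_fail[1])
})

test_that("verdicts are monotone in the permutant set", {
  wt <- mk_metrics("wt")
  good <- lapply(1:4, function(k) mk_metrics(paste0("rp", k)))
  bad <- mk_metrics("bad", barrier = 8)
  expect_equal(assess_robustness(wt, good)$verdict, "robust")
  expect_equal(assess_robustness(wt, good[1:2])$verdict, "robust")
  expect_equal(assess_robustness(wt, c(good, list(bad)))$verdict, "non_robust")
  # degenerate report: no permutants
  rep0 <- assess_robustness(wt, list())
  expect_equal(rep0$verdict, "robust")
  expect_equal(nrow(rep0$per_rp), 0L)
})

test_that("an unconverged permutant fails criteria 1 and 2", {
  wt <- mk_metrics("wt")
  rp <- mk_metrics("rp")
  rp$basins <- NULL
  rep <- assess_robustness(wt, list(rp))
  expect_equal(rep$verdict, "non_robust")
  expect_true(rep$per_rp$c1_fail[1] && rep$per_rp$c2_fail[1])
})

test_that("rescue contacts are the region-restricted gains of the best RP", {
  wt <- fx_hairpin_cm()
  # rp1: identical map; rp2: gains two contacts in region, one outside
  gains_in <- data.frame(i = c(1L, 2L), j = c(5L, 6L), dij = 0.6)
  gains_out <- data.frame(i = 9L, j = 13L, dij = 0.6)
  rp2 <- wt
  rp2$contacts <- rbind(wt$contacts, gains_in, gains_out)
  rp2$M <- nrow(rp2$contacts)
  region <- 1:7
  out <- identify_rescue_contacts(wt, list(wt, rp2), barriers = c(3.0, 5.0),
                                  wt_barrier = 3.5, region = region)
  expect_equal(nrow(out), 2L)
  expect_true(all(out$i %in% region & out$j %in% region))
  expect_equal(attr(out, "best_rp"), 2L)
  # occupancy ranking comes from the composite of all RP maps
  expect_true(all(diff(out$occupancy) <= 0))
  # no permutant above the wild-type barrier -> error
  expect_error(identify_rescue_contacts(wt, list(wt, rp2), c(3.0, 3.2),
                                        wt_barrier = 3.5),
               class = "NoImprovedRP")
  # identical best map -> empty list
  empty <- identify_rescue_contacts(wt, list(wt), barriers = 4,
                                    wt_barrier = 3.5, region = region)
  expect_equal(nrow(empty), 0L)
})

test_that("a depleted region's rescue contacts come from the removed set", {
  wt_full <- fx_hairpin_cm()
  region <- c(3, 4, 11, 12)   # holds cross-strand wild-type contacts
  in_reg <- wt_full$contacts$i %in% region & wt_full$contacts$j %in% region
  # wild type deliberately depleted in the region; the "best RP" re-adds all
  wt_depleted <- wt_full
  wt_depleted$contacts <- wt_full$contacts[!in_reg, ]
  wt_depleted$M <- nrow(wt_depleted$contacts)
  out <- identify_rescue_contacts(wt_depleted, list(wt_full), barriers = 6,
                                  wt_barrier = 3, region = region)
  removed_keys <- paste(wt_full$contacts$i[in_reg], wt_full$contacts$j[in_reg])
  expect_gt(nrow(out), 0L)
  expect_true(all(paste(out$i, out$j) %in% removed_keys))
})

test_that("permutant generation inside the pipeline is seed-reproducible", {
  toy <- toy_sandwich("bulky_core")
  seqs1 <- vapply(1:5, function(k)
    permute_sequence(structure_sequence(toy$structure), 1 + k)$permuted_sequence,
    character(1))
  seqs2 <- vapply(1:5, function(k)
    permute_sequence(structure_sequence(toy$structure), 1 + k)$permuted_sequence,
    character(1))
  expect_identical(seqs1, seqs2)
  expect_false(any(duplicated(seqs1)))
})
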