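#' Numeric tolerances of the three robustness criteria
#'
#' A robust backbone satisfies, for every permutant: (1) folded and
#' unfolded basins at similar Q as the wild type, (2) folding barriers
#' within `barrier_tolerance` k_BT_f and the same number of populated
#' intermediates, (3) similar folding routes.  A route change alone is
#' only annotated; it contributes to a non-robust verdict when it
#' co-occurs with a criterion 1 or 2 failure.
#'
#' @param barrier_tolerance barrier-difference tolerance (k_BT_f).
#' @param basin_q_tolerance allowed |delta Q| of either basin position.
#' @param route_similarity_min minimum route correlation considered
#'   "similar".
#' @param intermediate_prominence minimum dip depth (k_BT_f) for a local
#'   minimum to count as an intermediate.
#' @param n_rps number of random permutants simulated.
#' @return A `robustness_criteria` list.
#' @export
robustness_criteria <- function(barrier_tolerance = 2.0, basin_q_tolerance = 0.1,
                                route_similarity_min = 0.75,
                                intermediate_prominence = 0.5, n_rps = 5) {
  stopifnot(barrier_tolerance > 0, basin_q_tolerance > 0,
            route_similarity_min > -1, n_rps >= 0)
  structure(list(barrier_tolerance = barrier_tolerance,
                 basin_q_tolerance = basin_q_tolerance,
                 route_similarity_min = route_similarity_min,
                 intermediate_prominence = intermediate_prominence,
                 n_rps = as.integer(n_rps)),
            class = "robustness_criteria")
}

#' Folding metrics of one construct
#'
#' Runs the full single-construct protocol: folding-temperature search,
#' reweighting of the accepted near-T_f run to T_f, free-energy profile,
#' basin/barrier/intermediate analysis and Q-binned route accumulation.
#'
#' @param t the construct's `sbm_topology`.
#' @param protocol a [tf_protocol()].
#' @param qs a [q_settings()].
#' @param prominence intermediate prominence threshold (k_BT_f).
#' @param basin_thresholds optional [transition_thresholds()]: anchor
#'   basin positions to the ensemble windows (see [locate_basins()]);
#'   used for marginally cooperative systems where the two ensembles
#'   overlap in Q.  All constructs of one study should use the same mode.
#' @param label construct label.
#' @return An `rp_folding_metrics` list: `label`, `T_f`, `transitions`,
#'   `fep`, `basins`, `route_counts`/`bin_counts` (for [route_at()]),
#'   `converged`.
#' @export
folding_metrics <- function(t, protocol = tf_protocol(), qs = q_settings(),
                            prominence = 0.5, basin_thresholds = NULL,
                            label = t$label) {
  tf <- find_folding_temperature(t, protocol)
  tr <- tf$trajectory
  p <- reweight_histogram(tr$records$Q, tr$records$E, tr$temperature, tf$T_f, qs)
  fep <- free_energy_profile(p, tf$T_f)
  basins <- tryCatch(locate_basins(fep, prominence = prominence,
                                   thresholds = basin_thresholds),
                     rpfold_error = function(e) NULL)
  structure(list(label = label, T_f = tf$T_f, transitions = tf$transitions,
                 fep = fep, basins = basins,
                 route_counts = tr$route_counts, bin_counts = tr$bin_counts,
                 contacts = data.frame(i = t$contacts_idx[, 1],
                                       j = t$contacts_idx[, 2]),
                 qs = qs,
                 converged = tf$transitions >= protocol$min_transitions &&
                   !is.null(basins)),
            class = "rp_folding_metrics")
}

#' @export
print.rp_folding_metrics <- function(x, ...) {
  cat(sprintf("<rp_folding_metrics> '%s': T_f = %.4f (%d transitions)\n",
              x$label, x$T_f, x$transitions))
  if (!is.null(x$basins)) print(x$basins)
  invisible(x)
}

#' Folding-route map of a construct at a chosen Q bin
#'
#' @param metrics an `rp_folding_metrics` (with route accumulation).
#' @param q_bin Q bin center; defaults to the construct's own barrier top.
#' @return An `rp_route` (see [average_contact_map_at_q()]).
#' @export
route_at <- function(metrics, q_bin = NULL) {
  if (is.null(metrics$route_counts)) {
    rp_stop("EmptyBin", "metrics carry no route accumulation")
  }
  qs <- metrics$qs
  if (is.null(q_bin)) q_bin <- metrics$basins$q_barrier_top
  b <- q_bin_index(q_bin, qs)
  if (metrics$bin_counts[b] < 1) {
    # fall back to the nearest populated bin
    pop <- which(metrics$bin_counts >= 1)
    if (length(pop) == 0) rp_stop("EmptyBin", "no populated route bins")
    b <- pop[which.min(abs(pop - b))]
  }
  Cij <- metrics$route_counts[b, ] / metrics$bin_counts[b]
  structure(list(q_bin = q_bin_centers(qs)[b],
                 C = data.frame(i = metrics$contacts$i, j = metrics$contacts$j,
                                C = Cij),
                 N_Q = metrics$bin_counts[b]),
            class = "rp_route")
}

n_intermediates <- function(metrics, prominence) {
  if (is.null(metrics$basins)) return(NA_integer_)
  sum(metrics$basins$intermediates$depth >= prominence)
}

#' Apply the three robustness criteria
#'
#' Compares every permutant's folding metrics against the wild type.
#' Criterion 1 fails when either basin moves by more than
#' `basin_q_tolerance` in Q; criterion 2 when the folding barrier differs
#' by more than `barrier_tolerance` k_BT_f or the number of populated
#' intermediates changes; criterion 3 when the folding route (compared at
#' the wild-type barrier-top Q bin) correlates below
#' `route_similarity_min` AND a criterion 1 or 2 failure co-occurs: a
#' route change on its own is annotated, not penalized.  A permutant
#' whose landscape lost its two-basin structure entirely fails
#' criteria 1 and 2.
#'
#' @param wt wild-type `rp_folding_metrics`.
#' @param rps list of permutant `rp_folding_metrics`.
#' @param crit a [robustness_criteria()].
#' @return An `rp_robustness_report`: `verdict` ("robust"/"non_robust"),
#'   per-RP table `per_rp` (basin shifts, barrier difference,
#'   intermediates, route similarity, failed criteria), `wt`, `rps`.
#' @export
assess_robustness <- function(wt, rps, crit = robustness_criteria()) {
  if (is.null(wt$basins)) {
    rp_stop("UnconvergedInput", "wild-type metrics have no two-basin landscape")
  }
  wt_route <- tryCatch(route_at(wt, wt$basins$q_barrier_top),
                       rpfold_error = function(e) NULL)
  wt_ni <- n_intermediates(wt, crit$intermediate_prominence)
  rows <- list()
  for (k in seq_along(rps)) {
    m <- rps[[k]]
    if (is.null(m$basins)) {
      rows[[k]] <- data.frame(
        rp = k, label = m$label, d_q_unfolded = NA_real_, d_q_folded = NA_real_,
        d_barrier = NA_real_, n_intermediates = NA_integer_,
        route_similarity = NA_real_, c1_fail = TRUE, c2_fail = TRUE,
        route_changed = NA, c3_fail = FALSE, stringsAsFactors = FALSE)
      next
    }
    dqu <- m$basins$q_unfolded_min - wt$basins$q_unfolded_min
    dqf <- m$basins$q_folded_min - wt$basins$q_folded_min
    dbar <- m$basins$barrier_fold - wt$basins$barrier_fold
    ni <- n_intermediates(m, crit$intermediate_prominence)
    sim <- NA_real_
    if (!is.null(wt_route)) {
      sim <- tryCatch({
        route_similarity(wt_route, route_at(m, wt$basins$q_barrier_top))
      }, rpfold_error = function(e) NA_real_)
    }
    c1 <- abs(dqu) > crit$basin_q_tolerance || abs(dqf) > crit$basin_q_tolerance
    c2 <- abs(dbar) > crit$barrier_tolerance || (!is.na(ni) && ni != wt_ni)
    changed <- !is.na(sim) && sim < crit$route_similarity_min
    c3 <- changed && (c1 || c2)
    rows[[k]] <- data.frame(
      rp = k, label = m$label, d_q_unfolded = dqu, d_q_folded = dqf,
      d_barrier = dbar, n_intermediates = ni, route_similarity = sim,
      c1_fail = c1, c2_fail = c2, route_changed = changed, c3_fail = c3,
      stringsAsFactors = FALSE)
  }
  per_rp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rp = integer(0))
  any_fail <- length(rows) > 0 &&
    any(per_rp$c1_fail | per_rp$c2_fail | per_rp$c3_fail, na.rm = TRUE)
  structure(list(verdict = if (any_fail) "non_robust" else "robust",
                 per_rp = per_rp, wt = wt, rps = rps, criteria = crit),
            class = "rp_robustness_report")
}

#' @export
print.rp_robustness_report <- function(x, ...) {
  cat(sprintf("<rp_robustness_report> verdict: %s (%d RPs)\n",
              x$verdict, nrow(x$per_rp)))
  if (nrow(x$per_rp) > 0) {
    print(x$per_rp[, c("rp", "d_q_unfolded", "d_q_folded", "d_barrier",
                       "n_intermediates", "route_similarity",
                       "c1_fail", "c2_fail", "route_changed")],
          digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Rescue contacts: gains of the best-folding permutant
#'
#' When at least one permutant folds over a higher barrier than the wild
#' type, the contacts that this permutant gained (present in its map but
#' not the wild type's), restricted to a region of interest (typically
#' the region unfolded in the wild-type intermediate), are candidate
#' "rescue" contacts whose addition may suppress the intermediate.
#' Contacts are ranked by their occupancy across all permutant maps.
#'
#' @param wt_cm wild-type `rp_contact_map`.
#' @param rp_cms list of permutant `rp_contact_map`s.
#' @param barriers numeric folding barriers of the permutants (k_BT_f).
#' @param wt_barrier wild-type folding barrier.
#' @param region residue indices to restrict to (both partners inside);
#'   defaults to the whole chain.
#' @return data frame `i`, `j`, `occupancy` sorted by decreasing
#'   occupancy, with attribute `best_rp`.
#' @export
identify_rescue_contacts <- function(wt_cm, rp_cms, barriers, wt_barrier,
                                     region = NULL) {
  stopifnot(length(rp_cms) == length(barriers))
  improved <- which(!is.na(barriers) & barriers > wt_barrier)
  if (length(improved) == 0) {
    rp_stop("NoImprovedRP", "no permutant has a higher folding barrier than the wild type")
  }
  best <- improved[which.max(barriers[improved])]
  dm <- difference_map(wt_cm, rp_cms[[best]])
  gained <- dm$rp_only
  if (!is.null(region)) {
    gained <- gained[gained$i %in% region & gained$j %in% region, , drop = FALSE]
  }
  if (nrow(gained) == 0) {
    out <- data.frame(i = integer(0), j = integer(0), occupancy = numeric(0))
    attr(out, "best_rp") <- best
    return(out)
  }
  comp <- composite_map(rp_cms)
  occ <- setNames(comp$counts$count / comp$n_maps,
                  paste(comp$counts$i, comp$counts$j))
  gained$occupancy <- unname(occ[paste(gained$i, gained$j)])
  gained <- gained[order(-gained$occupancy, gained$i, gained$j),
                   c("i", "j", "occupancy")]
  rownames(gained) <- NULL
  attr(gained, "best_rp") <- best
  gained
}

#' Configuration for the end-to-end pipeline
#'
#' @param n_rps number of random permutants (sequential seeds from
#'   `seed`; no cherry-picking).
#' @param seed master seed; RP k uses seed + k, simulations use offsets
#'   derived from it.
#' @param cutoff,min_sep contact-map parameters (Angstrom / residues).
#' @param params an [sbm_parameters()].
#' @param protocol a [tf_protocol()].
#' @param criteria a [robustness_criteria()].
#' @param qs a [q_settings()].
#' @param repack a [repack_settings()].
#' @param basin_mode `"local_minima"` (free local minima, the default) or
#'   `"ensemble"` (basins anchored to the threshold windows; for
#'   marginally cooperative systems).
#' @param low_occupancy variable-contact threshold for
#'   [sensitive_regions()].
#' @param rescue_region optional residue set for
#'   [identify_rescue_contacts()].
#' @param run_dir optional directory: all intermediate artifacts (PDBs,
#'   contact maps, trajectories, report JSON) are written there with a
#'   manifest.
#' @return An `rp_config` list.
#' @export
rp_config <- function(n_rps = 5, seed = 1, cutoff = 4.5, min_sep = 3,
                      params = sbm_parameters(), protocol = tf_protocol(),
                      criteria = robustness_criteria(n_rps = n_rps),
                      qs = q_settings(), repack = repack_settings(),
                      basin_mode = c("local_minima", "ensemble"),
                      low_occupancy = 0.4, rescue_region = NULL,
                      run_dir = NULL) {
  structure(list(n_rps = as.integer(n_rps), seed = as.integer(seed),
                 cutoff = cutoff, min_sep = as.integer(min_sep),
                 params = params, protocol = protocol, criteria = criteria,
                 qs = qs, repack = repack,
                 basin_mode = match.arg(basin_mode),
                 low_occupancy = low_occupancy,
                 rescue_region = rescue_region, run_dir = run_dir),
            class = "rp_config")
}

#' Run the full random-permutant pipeline
#'
#' permute (x n_rps) -> repack -> contact maps -> C-alpha models ->
#' folding-temperature search -> production -> landscape analysis ->
#' three-criterion robustness assessment, plus composite-map sensitive
#' regions and rescue-contact identification.  Fully reproducible from
#' (structure, config).
#'
#' @param wt an [rp_structure()] or a PDB path.
#' @param config an [rp_config()].
#' @return An `rp_robustness_report` with additional fields
#'   `wt_contact_map`, `rp_contact_maps`, `permutations`, `composite`,
#'   `sensitive_regions`, `rescue_contacts`, `config`.
#' @export
run_rp_pipeline <- function(wt, config = rp_config()) {
  if (is.character(wt)) wt <- read_structure(wt)
  wt <- strip_hydrogens(wt)
  if (count_missing_atoms(wt)$total > 0) {
    wt <- complete_side_chains(wt, config$repack)
  }
  wt_cm <- compute_contact_map(wt, config$cutoff, config$min_sep)
  backbone <- extract_backbone(wt)
  wt_seq <- structure_sequence(wt)

  perms <- list(); rp_structs <- list(); rp_cms <- list()
  for (k in seq_len(config$n_rps)) {
    perms[[k]] <- permute_sequence(wt_seq, config$seed + k)
    rp_structs[[k]] <- repack_side_chains(backbone, perms[[k]]$permuted_sequence,
                                          config$repack)
    rp_structs[[k]]$label <- sprintf("%s_rp%d", wt$label, k)
    rp_cms[[k]] <- compute_contact_map(rp_structs[[k]], config$cutoff,
                                       config$min_sep)
  }

  prot <- config$protocol
  prot$route_bins <- config$qs$n_bins
  prot$seed <- config$seed * 1000L
  bthr <- if (config$basin_mode == "ensemble") prot$thresholds else NULL
  wt_top <- build_topology(wt, wt_cm, config$params)
  wt_metrics <- folding_metrics(wt_top, prot, config$qs,
                                config$criteria$intermediate_prominence,
                                basin_thresholds = bthr,
                                label = wt$label)
  rp_metrics <- list()
  for (k in seq_len(config$n_rps)) {
    prot_k <- prot
    prot_k$seed <- config$seed * 1000L + k * 97L
    top_k <- build_topology(rp_structs[[k]], rp_cms[[k]], config$params)
    rp_metrics[[k]] <- folding_metrics(top_k, prot_k, config$qs,
                                       config$criteria$intermediate_prominence,
                                       basin_thresholds = bthr,
                                       label = rp_structs[[k]]$label)
  }

  report <- assess_robustness(wt_metrics, rp_metrics, config$criteria)
  report$wt_contact_map <- wt_cm
  report$rp_contact_maps <- rp_cms
  report$permutations <- perms
  if (config$n_rps >= 2) {
    report$composite <- composite_map(rp_cms)
    report$sensitive_regions <- sensitive_regions(report$composite,
                                                  config$low_occupancy)
  }
  barriers <- vapply(rp_metrics, function(m)
    if (is.null(m$basins)) NA_real_ else m$basins$barrier_fold, numeric(1))
  report$rescue_contacts <- tryCatch(
    identify_rescue_contacts(wt_cm, rp_cms, barriers,
                             wt_metrics$basins$barrier_fold,
                             config$rescue_region),
    rpfold_error = function(e) NULL)
  report$config <- config
  if (!is.null(config$run_dir)) write_run_artifacts(report, wt, rp_structs, config)
  report
}

# write per-stage artifacts and a manifest to the run directory
write_run_artifacts <- function(report, wt, rp_structs, config) {
  dir.create(config$run_dir, showWarnings = FALSE, recursive = TRUE)
  rd <- config$run_dir
  write_structure(wt, file.path(rd, "wt.pdb"))
  write_contact_map(report$wt_contact_map, file.path(rd, "wt.cmap"))
  for (k in seq_along(rp_structs)) {
    write_structure(rp_structs[[k]], file.path(rd, sprintf("rp%d.pdb", k)))
    write_contact_map(report$rp_contact_maps[[k]],
                      file.path(rd, sprintf("rp%d.cmap", k)))
  }
  summary <- list(
    verdict = report$verdict,
    wt = list(label = report$wt$label, T_f = report$wt$T_f,
              barrier = report$wt$basins$barrier_fold,
              q_unfolded = report$wt$basins$q_unfolded_min,
              q_folded = report$wt$basins$q_folded_min),
    per_rp = report$per_rp,
    seeds = vapply(report$permutations, function(p) p$seed, integer(1)),
    config = list(n_rps = config$n_rps, seed = config$seed,
                  cutoff = config$cutoff, min_sep = config$min_sep)
  )
  jsonlite::write_json(summary, file.path(rd, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- data.frame(file = list.files(rd), stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(rd, "MANIFEST.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(rd)
}
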