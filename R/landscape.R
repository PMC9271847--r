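#' Settings for Q computation and binning
#'
#' A native contact counts as formed in a snapshot when its C-alpha
#' distance is strictly less than `formation_factor` times its native
#' distance d_ij.
#'
#' @param formation_factor contact-formation multiplier (> 1).
#' @param n_bins uniform Q bins over [0, 1].
#' @return A `q_settings` list.
#' @export
q_settings <- function(formation_factor = 1.2, n_bins = 50) {
  stopifnot(formation_factor > 1, n_bins >= 10)
  structure(list(formation_factor = formation_factor,
                 n_bins = as.integer(n_bins)),
            class = "q_settings")
}

q_bin_centers <- function(qs) (seq_len(qs$n_bins) - 0.5) / qs$n_bins

q_bin_index <- function(Q, qs) pmin(qs$n_bins, pmax(1L, floor(Q * qs$n_bins) + 1L))

# per-contact formation indicators for one conformation (coords in nm)
contact_formation <- function(coords, cm, qs = q_settings()) {
  if (cm$M == 0) rp_stop("EmptyContactMap", "contact map has no contacts")
  r <- sqrt(rowSums((coords[cm$contacts$i, , drop = FALSE] -
                     coords[cm$contacts$j, , drop = FALSE])^2))
  as.integer(r < qs$formation_factor * cm$contacts$dij)
}

#' Fraction of native contacts Q of a conformation
#'
#' Q = (number of formed contacts) / M, with a contact formed when its
#' C-alpha distance is below `formation_factor` x d_ij.
#'
#' @param coords n x 3 C-alpha coordinates in nm.
#' @param cm an `rp_contact_map` (d_ij in nm).
#' @param qs a [q_settings()].
#' @return Q in [0, 1].
#' @export
fraction_native_contacts <- function(coords, cm, qs = q_settings()) {
  mean(contact_formation(as.matrix(coords), cm, qs))
}

#' Single-histogram reweighting of a Q histogram
#'
#' Reweights samples collected at `T_sim` to `T_target`:
#' P_target(bin) is proportional to the sum over the bin's samples of
#' exp(-(1/T_target - 1/T_sim) E), normalized over bins.
#'
#' @param Q,E sample vectors (Q in [0,1], E potential energies).
#' @param T_sim,T_target temperatures in reduced units.
#' @param qs a [q_settings()].
#' @return numeric vector of bin probabilities (sums to 1) with
#'   attributes `bin_centers` and `counts` (raw samples per bin).
#' @export
reweight_histogram <- function(Q, E, T_sim, T_target, qs = q_settings()) {
  stopifnot(length(Q) == length(E), length(Q) > 0, T_sim > 0, T_target > 0)
  lw <- -(1 / T_target - 1 / T_sim) * E
  lw <- lw - max(lw)
  w <- exp(lw)
  ess <- sum(w)^2 / sum(w^2)
  if (ess < 10) {
    rp_warn("DegenerateWeights",
            sprintf("effective sample size %.1f < 10 after reweighting", ess))
  }
  bins <- q_bin_index(Q, qs)
  p <- vapply(seq_len(qs$n_bins), function(b) sum(w[bins == b]), numeric(1))
  p <- p / sum(p)
  attr(p, "bin_centers") <- q_bin_centers(qs)
  attr(p, "counts") <- tabulate(bins, nbins = qs$n_bins)
  p
}

#' Free-energy profile from a Q population
#'
#' dG(bin)/k_BT = -ln P(bin), shifted so that the global minimum is zero;
#' empty bins are flagged (NA) rather than silently interpolated.
#'
#' @param p bin probabilities as from [reweight_histogram()] (or any
#'   normalized vector; bin centers default to uniform bins on [0,1]).
#' @param T_f the temperature the profile is scaled at (stored for
#'   reporting; dG is already in units of k_B T).
#' @return An `rp_fep`: data frame `profile` (Q, dG, n_samples) plus `T_f`.
#' @export
free_energy_profile <- function(p, T_f = NA_real_) {
  centers <- attr(p, "bin_centers")
  if (is.null(centers)) centers <- (seq_along(p) - 0.5) / length(p)
  counts <- attr(p, "counts")
  if (is.null(counts)) counts <- ifelse(p > 0, 1L, 0L)
  if (all(p == 0 | !is.finite(p))) rp_stop("AllBinsEmpty", "empty histogram")
  dg <- ifelse(p > 0, -log(p), NA_real_)
  dg <- dg - min(dg, na.rm = TRUE)
  structure(list(profile = data.frame(Q = centers, dG = dg, n_samples = counts),
                 T_f = T_f),
            class = "rp_fep")
}

#' @export
print.rp_fep <- function(x, ...) {
  ok <- !is.na(x$profile$dG)
  cat(sprintf("<rp_fep> %d/%d populated bins, T_f = %.4f, max dG = %.2f k_BT\n",
              sum(ok), nrow(x$profile), x$T_f, max(x$profile$dG, na.rm = TRUE)))
  invisible(x)
}

#' Locate basins, barriers and intermediates in a free-energy profile
#'
#' The profile is smoothed with a 3-bin moving average over populated
#' bins; the unfolded basin is the lowest-Q local minimum, the folded
#' basin the highest-Q one.  The barrier is the maximum dG between the
#' basins minus the basin dG (folding barrier from the unfolded side,
#' unfolding barrier from the folded side).  Interior minima with
#' prominence at least `prominence` are reported as intermediates.
#'
#' @param fep an `rp_fep`.
#' @param prominence minimum depth (k_BT) below the flanking maxima for
#'   an interior minimum to count as an intermediate.
#' @param thresholds optional [transition_thresholds()].  When given, the
#'   basins are anchored to the ensemble windows instead of requiring two
#'   free local minima: the unfolded basin is the deepest bin with
#'   Q <= `q_unfolded`, the folded basin the deepest bin with
#'   Q >= `q_folded`, and local minima between them (including a
#'   dominant compact well that a marginally cooperative system may carry)
#'   are reported as intermediates.  This keeps basin metrics well
#'   defined for landscapes whose folded and unfolded ensembles overlap
#'   in Q; for a genuinely two-state profile both definitions agree.
#' @return An `rp_basins` list: `q_unfolded_min`, `q_folded_min`,
#'   `barrier_fold`, `barrier_unfold`, `intermediates` (data frame
#'   `q`, `depth`), `smoothed` profile.
#' @export
locate_basins <- function(fep, prominence = 0.5, thresholds = NULL) {
  pr <- fep$profile[!is.na(fep$profile$dG), , drop = FALSE]
  n <- nrow(pr)
  if (n < 3) rp_stop("NoTwoBasins", "too few populated bins")
  sm <- vapply(seq_len(n), function(k) {
    lo <- max(1, k - 1); hi <- min(n, k + 1)
    mean(pr$dG[lo:hi])
  }, numeric(1))
  is_min <- vapply(seq_len(n), function(k) {
    # interior bins may tie with a neighbour (flat basin bottoms); edge
    # bins must descend strictly, so a truncated-smoothing plateau at the
    # end of a slope does not masquerade as a basin
    if (k == 1) return(sm[1] < sm[2])
    if (k == n) return(sm[n] < sm[n - 1])
    sm[k] <= sm[k - 1] && sm[k] <= sm[k + 1]
  }, logical(1))
  # suppress plateau duplicates: keep the first bin of equal-value runs
  mins <- which(is_min)
  if (length(mins) > 1) {
    mins <- mins[c(TRUE, diff(mins) > 1 | abs(diff(sm[mins])) > 1e-12)]
  }
  if (is.null(thresholds)) {
    if (length(mins) < 2) rp_stop("NoTwoBasins", "profile has fewer than two basins")
    iu <- mins[1]; if_ <- mins[length(mins)]
  } else {
    lo_set <- which(pr$Q <= thresholds$q_unfolded)
    hi_set <- which(pr$Q >= thresholds$q_folded)
    if (length(lo_set) == 0 || length(hi_set) == 0) {
      rp_stop("NoTwoBasins", "an ensemble window holds no populated bins")
    }
    iu <- lo_set[which.min(sm[lo_set])]
    if_ <- hi_set[which.min(sm[hi_set])]
  }
  seg <- sm[iu:if_]
  barrier_top <- max(seg)
  top_idx <- iu + which.max(seg) - 1
  interior <- mins[mins > iu & mins < if_]
  inter <- data.frame(q = numeric(0), depth = numeric(0))
  for (m in interior) {
    left_max <- max(sm[iu:m])
    right_max <- max(sm[m:if_])
    depth <- min(left_max, right_max) - sm[m]
    if (depth >= prominence) {
      inter <- rbind(inter, data.frame(q = pr$Q[m], depth = depth))
    }
  }
  structure(list(
    q_unfolded_min = pr$Q[iu], q_folded_min = pr$Q[if_],
    barrier_fold = barrier_top - sm[iu],
    barrier_unfold = barrier_top - sm[if_],
    q_barrier_top = pr$Q[top_idx],
    intermediates = inter,
    basin_mode = if (is.null(thresholds)) "local_minima" else "ensemble",
    smoothed = data.frame(Q = pr$Q, dG = sm)
  ), class = "rp_basins")
}

#' @export
print.rp_basins <- function(x, ...) {
  cat(sprintf(paste0("<rp_basins> unfolded at Q = %.2f, folded at Q = %.2f, ",
                     "folding barrier %.2f k_BT, %d intermediate(s)\n"),
              x$q_unfolded_min, x$q_folded_min, x$barrier_fold,
              nrow(x$intermediates)))
  invisible(x)
}

#' Average contact map at a given foldedness Q (folding route)
#'
#' For every native contact, C_ij is the fraction of the bin's snapshots
#' in which the contact is formed; the pattern of partial formation at
#' fixed Q summarizes the folding route.
#'
#' @param snapshots list of n x 3 coordinate matrices (nm), or a single
#'   matrix of per-snapshot Q-formation rows as returned with
#'   `formation = TRUE`.
#' @param cm the construct's `rp_contact_map`.
#' @param q_bin target Q bin center.
#' @param qs a [q_settings()].
#' @return An `rp_route`: `q_bin`, `C` (data frame i, j, C_ij), `N_Q`.
#' @export
average_contact_map_at_q <- function(snapshots, cm, q_bin, qs = q_settings()) {
  if (length(snapshots) == 0) rp_stop("EmptyBin", "no snapshots supplied")
  half <- 0.5 / qs$n_bins
  forms <- list()
  for (s in snapshots) {
    f <- contact_formation(as.matrix(s), cm, qs)
    if (abs(mean(f) - q_bin) <= half + 1e-12) forms[[length(forms) + 1]] <- f
  }
  if (length(forms) == 0) rp_stop("EmptyBin",
                                  sprintf("no snapshots in bin around Q = %.3f", q_bin))
  Cij <- Reduce(`+`, forms) / length(forms)
  structure(list(q_bin = q_bin,
                 C = data.frame(i = cm$contacts$i, j = cm$contacts$j, C = Cij),
                 N_Q = length(forms)),
            class = "rp_route")
}

# route map accumulated on-line from a trajectory re-run (used by the
# pipeline, which does not store snapshot coordinates)
route_from_formation <- function(formation_rows, Q, q_bin, qs = q_settings(), cm) {
  half <- 0.5 / qs$n_bins
  sel <- abs(Q - q_bin) <= half + 1e-12
  if (!any(sel)) rp_stop("EmptyBin",
                         sprintf("no snapshots in bin around Q = %.3f", q_bin))
  Cij <- colMeans(formation_rows[sel, , drop = FALSE])
  structure(list(q_bin = q_bin,
                 C = data.frame(i = cm$contacts$i, j = cm$contacts$j, C = Cij),
                 N_Q = sum(sel)),
            class = "rp_route")
}

#' Similarity of two folding routes
#'
#' Pearson correlation of the per-contact formation probabilities of two
#' route maps taken at the same Q bin, compared over the union of the
#' two contact sets (a contact absent from one map contributes 0 there).
#'
#' @param a,b `rp_route` objects at the same `q_bin`.
#' @return correlation in [-1, 1].
#' @export
route_similarity <- function(a, b) {
  if (!isTRUE(all.equal(a$q_bin, b$q_bin))) {
    rp_stop("IncompatibleSizes", "route maps are at different Q bins")
  }
  keys <- union(paste(a$C$i, a$C$j), paste(b$C$i, b$C$j))
  va <- setNames(rep(0, length(keys)), keys)
  vb <- va
  va[paste(a$C$i, a$C$j)] <- a$C$C
  vb[paste(b$C$i, b$C$j)] <- b$C$C
  if (sd(va) == 0 || sd(vb) == 0) {
    rp_stop("ZeroVariance", "route similarity undefined for constant formation vectors")
  }
  cor(va, vb)
}
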