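#' Settings for Langevin (stochastic) dynamics
#'
#' The integrator is BAOAB splitting with the exact Ornstein-Uhlenbeck
#' substep, chosen for its configurational-sampling accuracy at large
#' time steps.  Bead masses are uniform (1.0): only equilibrium
#' populations are interpreted, not kinetics.  Temperatures are in
#' reduced units epsilon/k_B.
#'
#' @param temperature target temperature (epsilon/k_B).
#' @param dt time step in ps.
#' @param friction friction coefficient in 1/ps.
#' @param n_steps number of integration steps.
#' @param record_stride record (step, Q, E) every this many steps.
#' @param seed integer RNG seed (trajectory is bit-reproducible).
#' @param mass bead mass.
#' @return A `simulation_settings` list.
#' @export
simulation_settings <- function(temperature = 1.0, dt = 0.0005, friction = 1.0,
                                n_steps = 1e6, record_stride = 200, seed = 1,
                                mass = 1.0) {
  stopifnot(dt > 0, n_steps >= 1, temperature >= 0, friction > 0)
  structure(list(temperature = temperature, dt = dt, friction = friction,
                 n_steps = n_steps, record_stride = as.integer(record_stride),
                 seed = as.integer(seed), mass = mass),
            class = "simulation_settings")
}

#' Run Langevin dynamics on a C-alpha model
#'
#' Propagates the model at the target temperature and records the
#' fraction of native contacts Q (formation criterion r < 1.2 d_ij),
#' potential and kinetic energy every `record_stride` steps.
#'
#' @param t an `sbm_topology`.
#' @param settings a [simulation_settings()].
#' @param start_coords starting conformation (defaults to native).
#' @param start_velocities optional starting velocities; drawn from the
#'   Maxwell-Boltzmann distribution when `NULL`.
#' @param q_factor contact-formation factor (contact formed when
#'   r < q_factor * d_ij).
#' @param route_bins if > 0, additionally accumulate per-contact
#'   formation counts in this many Q bins (for folding-route maps).
#' @return An `rp_trajectory`: data frame `records` (step, Q, E, Ekin)
#'   plus settings, final coordinates/velocities and the topology label.
#' @export
run_dynamics <- function(t, settings, start_coords = NULL,
                         start_velocities = NULL, q_factor = 1.2,
                         route_bins = 0) {
  if (is.null(start_coords)) start_coords <- t$native_coords
  start_coords <- check_coords(t, start_coords)
  res <- cpp_run_dynamics(t, start_coords,
                          if (is.null(start_velocities)) NULL else
                            check_coords(t, start_velocities),
                          settings$n_steps, settings$dt, settings$friction,
                          settings$temperature, settings$mass, settings$seed,
                          settings$record_stride, q_factor,
                          as.integer(route_bins))
  rec <- as.data.frame(res$records)
  names(rec) <- c("step", "Q", "E", "Ekin")
  structure(list(records = rec, temperature = settings$temperature,
                 seed = settings$seed, settings = settings,
                 final_coords = res$coords, final_velocities = res$velocities,
                 route_counts = res$route_counts, bin_counts = res$bin_counts,
                 label = t$label),
            class = "rp_trajectory")
}

#' @export
print.rp_trajectory <- function(x, ...) {
  cat(sprintf("<rp_trajectory> '%s': %d records at T = %.4f (seed %d)\n",
              x$label, nrow(x$records), x$temperature, x$seed))
  invisible(x)
}

#' Write/read a trajectory as TSV with a JSON sidecar
#' @param traj an `rp_trajectory`.
#' @param file TSV path; the sidecar is `<file>.json`.
#' @return `file` ([write_trajectory()]) or an `rp_trajectory`.
#' @export
write_trajectory <- function(traj, file) {
  utils::write.table(traj$records, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(temperature = traj$temperature, seed = traj$seed,
               label = traj$label,
               settings = traj$settings[c("dt", "friction", "n_steps",
                                          "record_stride", "mass")])
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  rec <- utils::read.table(file, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  structure(list(records = rec, temperature = meta$temperature,
                 seed = meta$seed, settings = meta$settings,
                 final_coords = NULL, final_velocities = NULL,
                 label = meta$label),
            class = "rp_trajectory")
}

#' Hysteresis thresholds for transition counting
#' @param q_unfolded Q at or below which the chain counts as unfolded.
#' @param q_folded Q at or above which it counts as folded.
#' @return A `transition_thresholds` list.
#' @export
transition_thresholds <- function(q_unfolded = 0.3, q_folded = 0.8) {
  stopifnot(0 < q_unfolded, q_unfolded < q_folded, q_folded < 1)
  structure(list(q_unfolded = q_unfolded, q_folded = q_folded),
            class = "transition_thresholds")
}

#' Count folding/unfolding transitions in a Q series
#'
#' Two-state hysteresis automaton: the state flips to folded when
#' Q >= `q_folded` and to unfolded when Q <= `q_unfolded`; values in
#' between leave the state unchanged.  Returns the number of state flips
#' after the first assignment.
#'
#' @param q numeric Q series (or an `rp_trajectory`).
#' @param thr a [transition_thresholds()].
#' @return integer transition count.
#' @export
count_transitions <- function(q, thr = transition_thresholds()) {
  if (inherits(q, "rp_trajectory")) q <- q$records$Q
  stopifnot(length(q) >= 1)
  cpp_count_transitions(as.numeric(q), thr$q_unfolded, thr$q_folded)
}

#' Solve for the folding temperature from one sampled trajectory
#'
#' Given (Q, E) samples at `T_sim`, single-histogram reweighting gives
#' the folded/unfolded populations at any nearby temperature; the folding
#' temperature is the root of their log-ratio.  Bisection runs until the
#' scaled free energies of the two ensembles agree within `tol` k_BT.
#'
#' @param Q,E sample vectors.
#' @param T_sim sampling temperature (reduced units).
#' @param thr a [transition_thresholds()] defining the two ensembles.
#' @param bracket temperature search interval, relative to `T_sim`.
#' @param tol convergence threshold on |dG_folded - dG_unfolded| (k_BT).
#' @return list `T_f`, `dG_gap` (residual free-energy difference),
#'   `p_folded`, `p_unfolded` at `T_f`.
#' @export
solve_tf_from_samples <- function(Q, E, T_sim, thr = transition_thresholds(),
                                  bracket = c(0.5, 2), tol = 0.2) {
  stopifnot(length(Q) == length(E), length(Q) > 0)
  folded <- Q >= thr$q_folded
  unfolded <- Q <= thr$q_unfolded
  if (!any(folded)) rp_stop("NoFoldingDetected", "no folded samples in trajectory")
  if (!any(unfolded)) rp_stop("NoUnfoldingDetected", "no unfolded samples in trajectory")
  log_ratio <- function(T_target) {
    lw <- -(1 / T_target - 1 / T_sim) * E
    lw <- lw - max(lw)
    w <- exp(lw)
    log(sum(w[folded])) - log(sum(w[unfolded]))
  }
  lo <- bracket[1] * T_sim; hi <- bracket[2] * T_sim
  flo <- log_ratio(lo); fhi <- log_ratio(hi)
  if (flo * fhi > 0) {
    # populations do not cross in the bracket: report the closer end
    T_f <- if (abs(flo) < abs(fhi)) lo else hi
  } else {
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      fm <- log_ratio(mid)
      if (abs(fm) < tol * 1e-3 || (hi - lo) < 1e-12 * T_sim) break
      if (fm * flo <= 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
    }
    T_f <- (lo + hi) / 2
  }
  gap <- log_ratio(T_f)
  lw <- -(1 / T_f - 1 / T_sim) * E; lw <- lw - max(lw); w <- exp(lw)
  list(T_f = T_f, dG_gap = abs(gap),
       p_folded = sum(w[folded]) / sum(w),
       p_unfolded = sum(w[unfolded]) / sum(w))
}

# T at which the unfolded and folded ensemble basins are equally deep:
# root of dG_min(Q >= q_folded) - dG_min(Q <= q_unfolded) over reweighted
# histograms.  The two windows are disjoint, so the root is well defined
# even when the landscape carries additional structure between them; at
# the solution the two basin bins have the same scaled free energy.
solve_tf_equal_basins <- function(Q, E, T_sim, thr = transition_thresholds(),
                                  qs = q_settings(), bracket = c(0.6, 1.6)) {
  centers <- q_bin_centers(qs)
  gap <- function(T_target) {
    lw <- -(1 / T_target - 1 / T_sim) * E
    lw <- lw - max(lw)
    w <- exp(lw)
    bins <- q_bin_index(Q, qs)
    p <- vapply(seq_len(qs$n_bins), function(b) sum(w[bins == b]), numeric(1))
    p <- p / sum(p)
    dg <- ifelse(p > 0, -log(p), NA_real_)
    lo <- suppressWarnings(min(dg[centers <= thr$q_unfolded], na.rm = TRUE))
    hi <- suppressWarnings(min(dg[centers >= thr$q_folded], na.rm = TRUE))
    if (!is.finite(lo) || !is.finite(hi)) return(NA_real_)
    hi - lo
  }
  lo_T <- bracket[1] * T_sim; hi_T <- bracket[2] * T_sim
  g_lo <- gap(lo_T); g_hi <- gap(hi_T)
  if (is.na(g_lo) || is.na(g_hi)) return(list(T_f = T_sim, dG_gap = gap(T_sim)))
  if (g_lo * g_hi > 0) {
    T_f <- if (abs(g_lo) < abs(g_hi)) lo_T else hi_T
    return(list(T_f = T_f, dG_gap = abs(gap(T_f))))
  }
  for (it in 1:100) {
    mid <- (lo_T + hi_T) / 2
    gm <- gap(mid)
    if (is.na(gm) || abs(gm) < 1e-6 || (hi_T - lo_T) < 1e-10 * T_sim) break
    if (gm * g_lo <= 0) hi_T <- mid else { lo_T <- mid; g_lo <- gm }
  }
  T_f <- (lo_T + hi_T) / 2
  list(T_f = T_f, dG_gap = abs(gap(T_f)))
}

#' Protocol settings for the folding-temperature search
#'
#' @param T_lo,T_hi scan bounds (reduced units).
#' @param n_scan temperatures in the coarse scan.
#' @param scan_steps,prod_steps integration steps for scan and production.
#' @param min_transitions transitions a run must show before its
#'   reweighted T_f estimate is accepted (15 mirrors full-scale practice;
#'   5 is the small-system test profile).
#' @param thresholds a [transition_thresholds()].
#' @param record_stride,seed,max_iter see [simulation_settings()].
#' @return A `tf_protocol` list.
#' @export
tf_protocol <- function(T_lo = 0.5, T_hi = 1.6, n_scan = 5,
                        scan_steps = 4e5, prod_steps = 4e6,
                        min_transitions = 5,
                        thresholds = transition_thresholds(),
                        record_stride = 200, seed = 1, max_iter = 8,
                        route_bins = 50) {
  structure(list(T_lo = T_lo, T_hi = T_hi, n_scan = as.integer(n_scan),
                 scan_steps = scan_steps, prod_steps = prod_steps,
                 min_transitions = as.integer(min_transitions),
                 thresholds = thresholds,
                 record_stride = as.integer(record_stride),
                 seed = as.integer(seed), max_iter = as.integer(max_iter),
                 route_bins = as.integer(route_bins)),
            class = "tf_protocol")
}

#' Locate the folding temperature of a model
#'
#' Coarse temperature scan (short runs from the native state) brackets
#' the melting region between the highest mostly-folded and lowest
#' mostly-unfolded temperatures; production runs at the bracket midpoint
#' are then iterated, re-centering on the reweighted T_f estimate, until a
#' run within 2% of its own estimate shows at least `min_transitions`
#' folding/unfolding transitions.  T_f is the temperature at which the
#' folded and unfolded basins of the reweighted profile have equal scaled
#' free energy (bisected to machine tolerance, well under the 0.2 k_BT
#' acceptance band); [solve_tf_from_samples()] offers the
#' ensemble-population variant of the same root finding.
#'
#' @param t an `sbm_topology` with at least one contact.
#' @param protocol a [tf_protocol()].
#' @return list `T_f`, `trajectory` (accepted production run),
#'   `transitions`, `diagnostics` (scan table, iteration log).
#' @export
find_folding_temperature <- function(t, protocol = tf_protocol()) {
  if (nrow(t$contacts_idx) == 0) rp_stop("EmptyContactMap", "topology has no contacts")
  thr <- protocol$thresholds
  temps <- seq(protocol$T_lo, protocol$T_hi, length.out = protocol$n_scan)
  scan <- data.frame(T = temps, mean_Q = NA_real_, min_Q = NA_real_, max_Q = NA_real_)
  for (k in seq_along(temps)) {
    s <- simulation_settings(temperature = temps[k], n_steps = protocol$scan_steps,
                             record_stride = protocol$record_stride,
                             seed = protocol$seed + k)
    tr <- run_dynamics(t, s)
    q <- tr$records$Q
    scan$mean_Q[k] <- mean(q); scan$min_Q[k] <- min(q); scan$max_Q[k] <- max(q)
  }
  folded_at <- scan$T[scan$mean_Q >= thr$q_folded]
  unfolded_at <- scan$T[scan$mean_Q <= thr$q_unfolded]
  if (length(unfolded_at) == 0) {
    rp_stop("NoUnfoldingDetected",
            "chain never unfolds within the scan bounds; raise T_hi")
  }
  if (length(folded_at) == 0) {
    rp_stop("NoFoldingDetected",
            "chain is not folded at any scan temperature; lower T_lo")
  }
  T_cur <- (max(folded_at) + min(unfolded_at)) / 2
  log <- list()
  best <- NULL
  for (it in seq_len(protocol$max_iter)) {
    s <- simulation_settings(temperature = T_cur, n_steps = protocol$prod_steps,
                             record_stride = protocol$record_stride,
                             seed = protocol$seed + 100 + it)
    tr <- run_dynamics(t, s, route_bins = protocol$route_bins)
    q <- tr$records$Q
    ntrans <- count_transitions(q, thr)
    entry <- list(T = T_cur, transitions = ntrans,
                  frac_folded = mean(q >= thr$q_folded),
                  frac_unfolded = mean(q <= thr$q_unfolded))
    log[[it]] <- entry
    if (any(q >= thr$q_folded) && any(q <= thr$q_unfolded)) {
      # T_f: equal scaled free energy of the folded and unfolded basins
      # in the reweighted profile
      sol <- solve_tf_equal_basins(q, tr$records$E, T_cur, thr,
                                   q_settings(n_bins = max(10, protocol$route_bins)))
      # accept only a run close to its own reweighted T_f, so both
      # ensembles are sampled directly, not just through reweighting
      if (ntrans >= protocol$min_transitions &&
          abs(T_cur - sol$T_f) <= 0.02 * T_cur) {
        return(list(T_f = sol$T_f, trajectory = tr, transitions = ntrans,
                    diagnostics = list(scan = scan, iterations = log,
                                       dG_gap = sol$dG_gap)))
      }
      if (is.null(best) || ntrans > best$transitions) {
        # single-histogram reweighting is only trustworthy near the run
        # temperature; keep the fallback estimate within 3%
        best <- list(T_f = max(0.97 * T_cur, min(1.03 * T_cur, sol$T_f)),
                     trajectory = tr, transitions = ntrans)
      }
      # damped re-centering: at most an 8% move per iteration
      T_cur <- max(0.92 * T_cur, min(1.08 * T_cur, sol$T_f))
    } else if (all(q > thr$q_unfolded)) {
      T_cur <- T_cur * 1.08   # too cold: never unfolds
    } else {
      T_cur <- T_cur / 1.08   # too hot: never refolds
    }
  }
  if (!is.null(best)) {
    if (best$transitions < protocol$min_transitions) {
      rp_warn("FewTransitions",
              sprintf("best run has only %d transitions (< %d)",
                      best$transitions, protocol$min_transitions))
    } else {
      rp_warn("TfUnconverged",
              "T_f estimate did not settle within 2% across iterations; using the best run")
    }
    return(list(T_f = best$T_f, trajectory = best$trajectory,
                transitions = best$transitions,
                diagnostics = list(scan = scan, iterations = log)))
  }
  rp_stop("NoFoldingDetected",
          "no run sampled both ensembles within max_iter iterations")
}
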