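#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Cell-list pair search (used by contact maps and clash counting)
// ---------------------------------------------------------------------------

// All unordered atom pairs with distance < cutoff, via a spatial grid with
// cell size = cutoff.  Returns a 2-column matrix of 1-based indices (i < j).
// [[Rcpp::export]]
IntegerMatrix cpp_close_pairs(NumericMatrix xyz, double cutoff) {
  const int n = xyz.nrow();
  const double c2 = cutoff * cutoff;
  std::unordered_map<long long, std::vector<int>> cells;
  std::vector<long long> key(n);
  auto cell_key = [&](int cx, int cy, int cz) -> long long {
    return (static_cast<long long>(cx + 1048576) << 42) |
           (static_cast<long long>(cy + 1048576) << 21) |
           static_cast<long long>(cz + 1048576);
  };
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = static_cast<int>(std::floor(xyz(i, 0) / cutoff));
    cy[i] = static_cast<int>(std::floor(xyz(i, 1) / cutoff));
    cz[i] = static_cast<int>(std::floor(xyz(i, 2) / cutoff));
    cells[cell_key(cx[i], cy[i], cz[i])].push_back(i);
  }
  std::vector<int> out_i, out_j;
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(cell_key(cx[i] + dx, cy[i] + dy, cz[i] + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double ddx = xyz(i, 0) - xyz(j, 0);
            double ddy = xyz(i, 1) - xyz(j, 1);
            double ddz = xyz(i, 2) - xyz(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < c2) {
              out_i.push_back(i + 1);
              out_j.push_back(j + 1);
            }
          }
        }
  }
  IntegerMatrix out(out_i.size(), 2);
  for (size_t k = 0; k < out_i.size(); ++k) {
    out(k, 0) = out_i[k];
    out(k, 1) = out_j[k];
  }
  return out;
}

// Residue-pair contacts: minimum heavy-atom distance < cutoff and
// sequence separation >= min_sep.  Returns data.frame(i, j, dmin).
// [[Rcpp::export]]
DataFrame cpp_residue_contacts(NumericMatrix xyz, IntegerVector resno,
                               double cutoff, int min_sep) {
  IntegerMatrix pairs = cpp_close_pairs(xyz, cutoff);
  std::unordered_map<long long, double> best;
  for (int k = 0; k < pairs.nrow(); ++k) {
    int a = pairs(k, 0) - 1, b = pairs(k, 1) - 1;
    int ri = resno[a], rj = resno[b];
    if (ri == rj) continue;
    int lo = ri < rj ? ri : rj, hi = ri < rj ? rj : ri;
    if (hi - lo < min_sep) continue;
    double dx = xyz(a, 0) - xyz(b, 0);
    double dy = xyz(a, 1) - xyz(b, 1);
    double dz = xyz(a, 2) - xyz(b, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    long long key = static_cast<long long>(lo) * 1000000LL + hi;
    auto it = best.find(key);
    if (it == best.end() || d < it->second) best[key] = d;
  }
  std::vector<long long> keys;
  keys.reserve(best.size());
  for (auto& kv : best) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  IntegerVector vi(keys.size()), vj(keys.size());
  NumericVector vd(keys.size());
  for (size_t k = 0; k < keys.size(); ++k) {
    vi[k] = static_cast<int>(keys[k] / 1000000LL);
    vj[k] = static_cast<int>(keys[k] % 1000000LL);
    vd[k] = best[keys[k]];
  }
  return DataFrame::create(_["i"] = vi, _["j"] = vj, _["dmin"] = vd);
}

// ---------------------------------------------------------------------------
// C-alpha structure-based model: energy, forces, Langevin dynamics
// ---------------------------------------------------------------------------

struct SbmTerms {
  // bonded
  std::vector<int> b_i, b_j;           std::vector<double> b_r0;
  std::vector<int> a_i, a_j, a_k;      std::vector<double> a_t0;
  std::vector<int> d_i, d_j, d_k, d_l; std::vector<double> d_p0;
  // native contacts (10-12) and generic repulsion
  std::vector<int> c_i, c_j;           std::vector<double> c_d, c_e;
  std::vector<int> n_i, n_j;
  double k_bond, k_angle, k_dih, nc_eps, nc_sigma, nb_cutoff;
};

static SbmTerms unpack_terms(List top) {
  SbmTerms t;
  IntegerMatrix b = top["bonds_idx"];
  NumericVector br = top["bonds_r0"];
  for (int k = 0; k < b.nrow(); ++k) {
    t.b_i.push_back(b(k, 0) - 1); t.b_j.push_back(b(k, 1) - 1);
    t.b_r0.push_back(br[k]);
  }
  IntegerMatrix a = top["angles_idx"];
  NumericVector at = top["angles_t0"];
  for (int k = 0; k < a.nrow(); ++k) {
    t.a_i.push_back(a(k, 0) - 1); t.a_j.push_back(a(k, 1) - 1);
    t.a_k.push_back(a(k, 2) - 1); t.a_t0.push_back(at[k]);
  }
  IntegerMatrix d = top["dihedrals_idx"];
  NumericVector dp = top["dihedrals_p0"];
  for (int k = 0; k < d.nrow(); ++k) {
    t.d_i.push_back(d(k, 0) - 1); t.d_j.push_back(d(k, 1) - 1);
    t.d_k.push_back(d(k, 2) - 1); t.d_l.push_back(d(k, 3) - 1);
    t.d_p0.push_back(dp[k]);
  }
  IntegerMatrix c = top["contacts_idx"];
  NumericVector cd = top["contacts_d"];
  NumericVector ce = top["contacts_eps"];
  for (int k = 0; k < c.nrow(); ++k) {
    t.c_i.push_back(c(k, 0) - 1); t.c_j.push_back(c(k, 1) - 1);
    t.c_d.push_back(cd[k]); t.c_e.push_back(ce[k]);
  }
  IntegerMatrix nb = top["nonbonded_idx"];
  for (int k = 0; k < nb.nrow(); ++k) {
    t.n_i.push_back(nb(k, 0) - 1); t.n_j.push_back(nb(k, 1) - 1);
  }
  List par = top["params"];
  t.k_bond = as<double>(par["k_bond"]);
  t.k_angle = as<double>(par["k_angle"]);
  t.k_dih = as<double>(par["k_dihedral"]);
  t.nc_eps = as<double>(par["nc_epsilon"]);
  t.nc_sigma = as<double>(par["nc_sigma"]);
  t.nb_cutoff = as<double>(par["nonbonded_cutoff"]);
  return t;
}

// energy components: 0 bond, 1 angle, 2 dihedral, 3 contact, 4 noncontact.
// If f != nullptr, accumulates forces (-dE/dx) into it.
static void sbm_eval(const SbmTerms& t, const double* x, int n,
                     double* e, double* f) {
  for (int c = 0; c < 5; ++c) e[c] = 0.0;
  if (f) std::fill(f, f + 3 * n, 0.0);

  auto addf = [&](int i, double fx, double fy, double fz) {
    f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
  };

  // bonds: (k/2)(r - r0)^2
  for (size_t k = 0; k < t.b_i.size(); ++k) {
    int i = t.b_i[k], j = t.b_j[k];
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - t.b_r0[k];
    e[0] += 0.5 * t.k_bond * dr * dr;
    if (f) {
      double fac = -t.k_bond * dr / r;
      addf(i, fac * dx, fac * dy, fac * dz);
      addf(j, -fac * dx, -fac * dy, -fac * dz);
    }
  }

  // angles: (k/2)(theta - t0)^2
  for (size_t k = 0; k < t.a_i.size(); ++k) {
    int i = t.a_i[k], j = t.a_j[k], l = t.a_k[k];
    double rij[3] = { x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                      x[3 * i + 2] - x[3 * j + 2] };
    double rkj[3] = { x[3 * l] - x[3 * j], x[3 * l + 1] - x[3 * j + 1],
                      x[3 * l + 2] - x[3 * j + 2] };
    double nij = std::sqrt(rij[0] * rij[0] + rij[1] * rij[1] + rij[2] * rij[2]);
    double nkj = std::sqrt(rkj[0] * rkj[0] + rkj[1] * rkj[1] + rkj[2] * rkj[2]);
    double cost = (rij[0] * rkj[0] + rij[1] * rkj[1] + rij[2] * rkj[2]) / (nij * nkj);
    if (cost > 1.0) cost = 1.0;
    if (cost < -1.0) cost = -1.0;
    double theta = std::acos(cost);
    double dt = theta - t.a_t0[k];
    e[1] += 0.5 * t.k_angle * dt * dt;
    if (f) {
      double sint = std::sqrt(1.0 - cost * cost);
      if (sint < 1e-8) sint = 1e-8;
      double dVdt = t.k_angle * dt;
      double fi[3], fk[3];
      for (int c = 0; c < 3; ++c) {
        double uij = rij[c] / nij, ukj = rkj[c] / nkj;
        fi[c] = -dVdt * (ukj - cost * uij) / (-sint * nij);
        fk[c] = -dVdt * (uij - cost * ukj) / (-sint * nkj);
      }
      addf(i, fi[0], fi[1], fi[2]);
      addf(l, fk[0], fk[1], fk[2]);
      addf(j, -fi[0] - fk[0], -fi[1] - fk[1], -fi[2] - fk[2]);
    }
  }

  // dihedrals: k[(1 - cos(p - p0)) + 0.5 (1 - cos 3(p - p0))]
  for (size_t k = 0; k < t.d_i.size(); ++k) {
    int i = t.d_i[k], j = t.d_j[k], m = t.d_k[k], l = t.d_l[k];
    double b1[3], b2[3], b3[3];
    for (int c = 0; c < 3; ++c) {
      b1[c] = x[3 * j + c] - x[3 * i + c];
      b2[c] = x[3 * m + c] - x[3 * j + c];
      b3[c] = x[3 * l + c] - x[3 * m + c];
    }
    double n1[3] = { b1[1] * b2[2] - b1[2] * b2[1],
                     b1[2] * b2[0] - b1[0] * b2[2],
                     b1[0] * b2[1] - b1[1] * b2[0] };
    double n2[3] = { b2[1] * b3[2] - b2[2] * b3[1],
                     b2[2] * b3[0] - b2[0] * b3[2],
                     b2[0] * b3[1] - b2[1] * b3[0] };
    double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
    double m1[3] = { n1[1] * b2[2] - n1[2] * b2[1],
                     n1[2] * b2[0] - n1[0] * b2[2],
                     n1[0] * b2[1] - n1[1] * b2[0] };
    double xx = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
    double yy = (m1[0] * n2[0] + m1[1] * n2[1] + m1[2] * n2[2]) / nb2;
    double phi = std::atan2(yy, xx);
    double dphi = phi - t.d_p0[k];
    e[2] += t.k_dih * ((1.0 - std::cos(dphi)) + 0.5 * (1.0 - std::cos(3.0 * dphi)));
    if (f) {
      double dVdphi = t.k_dih * (std::sin(dphi) + 1.5 * std::sin(3.0 * dphi));
      double n1sq = n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2];
      double n2sq = n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2];
      double b1b2 = b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2];
      double b3b2 = b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2];
      double dpi[3], dpl[3], dpj[3], dpm[3];
      double c1 = b1b2 / (nb2 * nb2), c3 = b3b2 / (nb2 * nb2);
      for (int c = 0; c < 3; ++c) {
        dpi[c] = nb2 / n1sq * n1[c];
        dpl[c] = -nb2 / n2sq * n2[c];
        dpj[c] = -(1.0 + c1) * dpi[c] + c3 * dpl[c];
        dpm[c] = c1 * dpi[c] - (1.0 + c3) * dpl[c];
      }
      addf(i, -dVdphi * dpi[0], -dVdphi * dpi[1], -dVdphi * dpi[2]);
      addf(j, -dVdphi * dpj[0], -dVdphi * dpj[1], -dVdphi * dpj[2]);
      addf(m, -dVdphi * dpm[0], -dVdphi * dpm[1], -dVdphi * dpm[2]);
      addf(l, -dVdphi * dpl[0], -dVdphi * dpl[1], -dVdphi * dpl[2]);
    }
  }

  // native contacts: eps [5 (d/r)^12 - 6 (d/r)^10]
  for (size_t k = 0; k < t.c_i.size(); ++k) {
    int i = t.c_i[k], j = t.c_j[k];
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    double s2 = t.c_d[k] * t.c_d[k] / r2;
    double s10 = s2 * s2 * s2 * s2 * s2;
    double s12 = s10 * s2;
    e[3] += t.c_e[k] * (5.0 * s12 - 6.0 * s10);
    if (f) {
      // dV/dr = -60 eps (s^12 - s^10)/r ; F = -dV/dr * rhat
      double fac = 60.0 * t.c_e[k] * (s12 - s10) / r2;
      addf(i, fac * dx, fac * dy, fac * dz);
      addf(j, -fac * dx, -fac * dy, -fac * dz);
    }
  }

  // generic excluded volume: eps (sigma/r)^12, truncated at nb_cutoff
  double co2 = t.nb_cutoff * t.nb_cutoff;
  for (size_t k = 0; k < t.n_i.size(); ++k) {
    int i = t.n_i[k], j = t.n_j[k];
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= co2) continue;
    double s2 = t.nc_sigma * t.nc_sigma / r2;
    double s12 = s2 * s2 * s2 * s2 * s2 * s2;
    e[4] += t.nc_eps * s12;
    if (f) {
      double fac = 12.0 * t.nc_eps * s12 / r2;
      addf(i, fac * dx, fac * dy, fac * dz);
      addf(j, -fac * dx, -fac * dy, -fac * dz);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sbm_energy(List top, NumericMatrix coords) {
  int n = coords.nrow();
  SbmTerms t = unpack_terms(top);
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  double e[5];
  sbm_eval(t, x.data(), n, e, nullptr);
  NumericVector out = NumericVector::create(
    _["bond"] = e[0], _["angle"] = e[1], _["dihedral"] = e[2],
    _["contact"] = e[3], _["noncontact"] = e[4]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sbm_forces(List top, NumericMatrix coords) {
  int n = coords.nrow();
  SbmTerms t = unpack_terms(top);
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  double e[5];
  sbm_eval(t, x.data(), n, e, f.data());
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = f[3 * i + c];
  return out;
}

static double compute_q(const SbmTerms& t, const double* x, double qfactor) {
  if (t.c_i.empty()) return NA_REAL;
  int formed = 0;
  for (size_t k = 0; k < t.c_i.size(); ++k) {
    int i = t.c_i[k], j = t.c_j[k];
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < qfactor * t.c_d[k]) ++formed;
  }
  return static_cast<double>(formed) / static_cast<double>(t.c_i.size());
}

// BAOAB Langevin propagation.  Records (step, Q, potential energy) every
// `stride` steps; bit-reproducible for a fixed seed.
// [[Rcpp::export]]
List cpp_run_dynamics(List top, NumericMatrix coords0, Nullable<NumericMatrix> vel0,
                      double n_steps_d, double dt, double gamma, double temperature,
                      double mass, int seed, int stride, double qfactor,
                      int route_bins) {
  long long n_steps = static_cast<long long>(n_steps_d);
  int n = coords0.nrow();
  SbmTerms t = unpack_terms(top);
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords0(i, c);

  RpRng rng(static_cast<uint64_t>(seed));
  if (vel0.isNotNull()) {
    NumericMatrix v0(vel0);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) v[3 * i + c] = v0(i, c);
  } else {
    double sd = std::sqrt(temperature / mass);
    for (int i = 0; i < 3 * n; ++i) v[i] = sd * rng.normal();
  }

  double e[5];
  sbm_eval(t, x.data(), n, e, f.data());
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * temperature / mass);
  const double half_dt = 0.5 * dt;

  long long n_rec = n_steps / stride;
  NumericMatrix records(n_rec, 4);  // step, Q, Epot, Ekin
  long long rec = 0;

  // optional per-Q-bin accumulation of contact-formation counts, used to
  // derive folding-route maps without storing coordinates
  const int n_con = static_cast<int>(t.c_i.size());
  NumericMatrix route_counts(route_bins > 0 ? route_bins : 1,
                             route_bins > 0 ? n_con : 1);
  NumericVector bin_counts(route_bins > 0 ? route_bins : 1);

  for (long long step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * n; ++i) {
      v[i] += half_dt * f[i] / mass;
      x[i] += half_dt * v[i];
    }
    for (int i = 0; i < 3 * n; ++i)
      v[i] = c1 * v[i] + c2 * rng.normal();
    for (int i = 0; i < 3 * n; ++i) x[i] += half_dt * v[i];
    sbm_eval(t, x.data(), n, e, f.data());
    for (int i = 0; i < 3 * n; ++i) v[i] += half_dt * f[i] / mass;

    if (step % stride == 0 && rec < n_rec) {
      double epot = e[0] + e[1] + e[2] + e[3] + e[4];
      if (!std::isfinite(epot) || std::fabs(x[0]) > 1e7) {
        stop("NumericalBlowup: non-finite energy or diverging coordinates at step %lld", step);
      }
      double ekin = 0.0;
      for (int i = 0; i < 3 * n; ++i) ekin += 0.5 * mass * v[i] * v[i];
      records(rec, 0) = static_cast<double>(step);
      records(rec, 1) = compute_q(t, x.data(), qfactor);
      records(rec, 2) = epot;
      records(rec, 3) = ekin;
      if (route_bins > 0 && n_con > 0) {
        double qv = records(rec, 1);
        int b = static_cast<int>(std::floor(qv * route_bins));
        if (b >= route_bins) b = route_bins - 1;
        if (b < 0) b = 0;
        bin_counts[b] += 1.0;
        for (int k = 0; k < n_con; ++k) {
          int i = t.c_i[k], j = t.c_j[k];
          double dx = x[3 * i] - x[3 * j];
          double dy = x[3 * i + 1] - x[3 * j + 1];
          double dz = x[3 * i + 2] - x[3 * j + 2];
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < qfactor * t.c_d[k]) route_counts(b, k) += 1.0;
        }
      }
      ++rec;
    }
  }

  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      xf(i, c) = x[3 * i + c];
      vf(i, c) = v[3 * i + c];
    }
  List out = List::create(_["records"] = records, _["coords"] = xf,
                          _["velocities"] = vf);
  if (route_bins > 0) {
    out["route_counts"] = route_counts;
    out["bin_counts"] = bin_counts;
  }
  return out;
}

// hysteresis two-state transition counter (folded >= qf, unfolded <= qu)
// [[Rcpp::export]]
int cpp_count_transitions(NumericVector q, double q_unfolded, double q_folded) {
  int state = 0;  // 0 unassigned, 1 folded, -1 unfolded
  int transitions = 0;
  for (int i = 0; i < q.size(); ++i) {
    int s = q[i] >= q_folded ? 1 : (q[i] <= q_unfolded ? -1 : 0);
    if (s == 0) continue;
    if (state != 0 && s != state) ++transitions;
    state = s;
  }
  return transitions;
}
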