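// Overdamped explicit-Euler engine for the neuroblast-astrocyte model.
//
// Circle indexing: for n neuroblasts and m astrocytic units the force
// arrays hold 2n + m entries: soma_i -> 2i, tip_i -> 2i + 1, unit_k ->
// 2n + k. All-pairs O(n^2) assembly; the R-level assemble_forces() is the
// independent oracle for this code.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

// Deterministic RNG independent of R's stream: mt19937 (standardised
// sequence) with hand-rolled uniform and Box-Muller normal transforms so
// draws are identical across compilers.
struct Rng {
  std::mt19937 g;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint32_t seed) : g(seed) {}
  double unif() { return (g() + 0.5) * (1.0 / 4294967296.0); }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
  int below(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
  void shuffle(std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = below(i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

struct Pars {
  double side, rS, rT, w, L, A_mid, omega_sal;
  double A_act, omega_act, phi_act, sigma_A;
  int u;
  double amp_lo, amp_hi;
  double mu_low, mu_high, kP, kR;
  double HN_mid, A_H, sigma_H;
  int u_H;
  double HA, Ha, r_max, r_min, rho_A, tau, mu_A, d_slit, mismatch_interval;
  int amp_mode, adh_mode, shrink_mode, law;
};

Pars read_pars(const List& par) {
  Pars p;
  p.side = par["side"]; p.rS = par["r_S"]; p.rT = par["r_T"]; p.w = par["w"];
  p.L = par["L"]; p.A_mid = par["A_mid"]; p.omega_sal = par["omega_sal"];
  p.A_act = par["A_act"]; p.omega_act = par["omega_act"];
  p.phi_act = par["phi_act"]; p.sigma_A = par["sigma_A"];
  p.u = par["u"]; p.amp_lo = par["amp_lo"]; p.amp_hi = par["amp_hi"];
  p.mu_low = par["mu_low"]; p.mu_high = par["mu_high"];
  p.kP = par["k_P"]; p.kR = par["k_R"];
  p.HN_mid = par["H_N"]; p.A_H = par["A_H"]; p.sigma_H = par["sigma_H"];
  p.u_H = par["u_H"];
  p.HA = par["H_A"]; p.Ha = par["H_a"];
  p.r_max = par["r_max"]; p.r_min = par["r_min"]; p.rho_A = par["rho_A"];
  p.tau = par["tau"]; p.mu_A = par["mu_A"]; p.d_slit = par["d_slit"];
  p.mismatch_interval = par["mismatch_interval"];
  p.amp_mode = par["amp_mode"]; p.adh_mode = par["adh_mode"];
  p.shrink_mode = par["shrink_mode"]; p.law = par["law"];
  return p;
}

inline double mim(double d, double side) {
  if (d > 0.5 * side) d -= side;
  else if (d < -0.5 * side) d += side;
  return d;
}

inline double wrap1(double x, double side) {
  x -= side * std::floor(x / side);
  if (x >= side) x = 0.0;
  return x;
}

// Full force assembly at one instant. nb arrays are soma/tip positions,
// lbar the per-cell spring targets. degen (optional) supplies random
// directions for coincident centres; without it the event is an error.
void compute_forces(int n, int m,
                    const std::vector<double>& sx, const std::vector<double>& sy,
                    const std::vector<double>& tx, const std::vector<double>& ty,
                    const std::vector<double>& ax, const std::vector<double>& ay,
                    const std::vector<double>& ar, const std::vector<int>& aown,
                    const std::vector<double>& lbar,
                    const Pars& p, double HN, Rng* degen,
                    std::vector<double>& Fx, std::vector<double>& Fy) {
  const int nc = 2 * n + m;
  const double side = p.side, half = 0.5 * p.side;
  std::fill(Fx.begin(), Fx.end(), 0.0);
  std::fill(Fy.begin(), Fy.end(), 0.0);

  // flat circle arrays
  std::vector<double> cx(nc), cy(nc), cr(nc);
  std::vector<int> owner(nc), isnb(nc);
  for (int i = 0; i < n; ++i) {
    cx[2 * i] = sx[i]; cy[2 * i] = sy[i]; cr[2 * i] = p.rS;
    cx[2 * i + 1] = tx[i]; cy[2 * i + 1] = ty[i]; cr[2 * i + 1] = p.rT;
    owner[2 * i] = owner[2 * i + 1] = i;
    isnb[2 * i] = isnb[2 * i + 1] = 1;
  }
  for (int k = 0; k < m; ++k) {
    cx[2 * n + k] = ax[k]; cy[2 * n + k] = ay[k]; cr[2 * n + k] = ar[k];
    owner[2 * n + k] = aown[k];
    isnb[2 * n + k] = 0;
  }

  // circle-circle pairs
  for (int i = 0; i < nc - 1; ++i) {
    for (int j = i + 1; j < nc; ++j) {
      if (isnb[i] && isnb[j] && owner[i] == owner[j]) continue;  // spring only
      double dx = cx[i] - cx[j];
      if (dx > half) dx -= side; else if (dx < -half) dx += side;
      double rsum = cr[i] + cr[j];
      if (dx > rsum || dx < -rsum) continue;
      double dy = cy[i] - cy[j];
      if (dy > half) dy -= side; else if (dy < -half) dy += side;
      if (dy > rsum || dy < -rsum) continue;
      double d2 = dx * dx + dy * dy;
      if (d2 >= rsum * rsum) continue;
      double dist = std::sqrt(d2);
      double nx, ny, overlap;
      if (dist == 0.0) {
        if (!degen) stop("coincident circle centres (no RNG supplied)");
        double a = 2.0 * M_PI * degen->unif();
        nx = std::cos(a); ny = std::sin(a);
        overlap = rsum;
      } else {
        nx = dx / dist; ny = dy / dist;
        overlap = rsum - dist;
      }
      double H;
      if (isnb[i] && isnb[j]) H = HN;
      else if (!isnb[i] && !isnb[j]) H = (owner[i] == owner[j]) ? p.Ha : p.HA;
      else H = 0.0;
      double mag = (p.law == 0) ? p.kR * overlap - H : (p.kR - H) * overlap;
      Fx[i] += mag * nx; Fy[i] += mag * ny;
      Fx[j] -= mag * nx; Fy[j] -= mag * ny;
    }
  }

  // via-process contacts: each neuroblast's segment vs every foreign circle
  for (int i = 0; i < n; ++i) {
    double abx = mim(tx[i] - sx[i], side);
    double aby = mim(ty[i] - sy[i], side);
    double len2 = abx * abx + aby * aby;
    if (len2 == 0.0) stop("degenerate neuroblast axis");
    double reach = std::sqrt(len2);
    int i_soma = 2 * i, i_tip = 2 * i + 1;
    for (int j = 0; j < nc; ++j) {
      if (isnb[j] && owner[j] == i) continue;
      double acx = mim(cx[j] - sx[i], side);
      double acy = mim(cy[j] - sy[i], side);
      // cheap reject: circle further from both endpoints than w + r + |ab|
      double lim = p.w + cr[j];
      if (acx > reach + lim || acx < -lim - reach) continue;
      if (acy > reach + lim || acy < -lim - reach) continue;
      double s = (acx * abx + acy * aby) / len2;
      if (s <= 0.0 || s >= 1.0) continue;  // endpoint: circle-circle handles it
      double dx = acx - s * abx, dy = acy - s * aby;
      double d2 = dx * dx + dy * dy;
      if (d2 >= lim * lim) continue;
      double dist = std::sqrt(d2);
      double nx, ny, overlap;
      if (dist == 0.0) {
        if (!degen) stop("circle centre on process axis (no RNG supplied)");
        double a = 2.0 * M_PI * degen->unif();
        nx = std::cos(a); ny = std::sin(a);
        overlap = lim;
      } else {
        nx = dx / dist; ny = dy / dist;
        overlap = lim - dist;
      }
      double fxv = p.kR * overlap * nx, fyv = p.kR * overlap * ny;
      Fx[j] += fxv; Fy[j] += fyv;
      Fx[i_soma] -= (1.0 - s) * fxv; Fy[i_soma] -= (1.0 - s) * fyv;
      Fx[i_tip] -= s * fxv; Fy[i_tip] -= s * fyv;
    }
  }

  // process springs
  for (int i = 0; i < n; ++i) {
    double dx = mim(tx[i] - sx[i], side);
    double dy = mim(ty[i] - sy[i], side);
    double l = std::sqrt(dx * dx + dy * dy);
    double f = p.kP * (l - lbar[i]) / l;
    Fx[2 * i] += f * dx; Fy[2 * i] += f * dy;
    Fx[2 * i + 1] -= f * dx; Fy[2 * i + 1] -= f * dy;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix engine_forces(NumericMatrix nb, NumericVector l_target,
                            NumericVector ax, NumericVector ay,
                            NumericVector ar, IntegerVector a_owner,
                            List par, double H_N_t) {
  Pars p = read_pars(par);
  int n = nb.nrow(), m = ax.size();
  std::vector<double> sx(n), sy(n), tx(n), ty(n), lbar(n);
  for (int i = 0; i < n; ++i) {
    sx[i] = nb(i, 0); sy[i] = nb(i, 1); tx[i] = nb(i, 2); ty[i] = nb(i, 3);
    lbar[i] = l_target[i];
  }
  std::vector<double> axv(ax.begin(), ax.end()), ayv(ay.begin(), ay.end()),
      arv(ar.begin(), ar.end());
  std::vector<int> aown(a_owner.begin(), a_owner.end());
  std::vector<double> Fx(2 * n + m), Fy(2 * n + m);
  compute_forces(n, m, sx, sy, tx, ty, axv, ayv, arv, aown, lbar, p, H_N_t,
                 nullptr, Fx, Fy);
  NumericMatrix out(2 * n + m, 2);
  for (int i = 0; i < 2 * n + m; ++i) { out(i, 0) = Fx[i]; out(i, 1) = Fy[i]; }
  return out;
}

// [[Rcpp::export]]
List engine_run(NumericMatrix nb_init, NumericVector ax0, NumericVector ay0,
                NumericVector ar0, IntegerVector a_owner, List par,
                double duration, double dt, double out_every, int seed) {
  Pars p = read_pars(par);
  const int n = nb_init.nrow(), m = ax0.size();
  const long steps = (long)std::lround(duration / dt);
  const long spo = (long)std::lround(out_every / dt);
  if (spo <= 0 || steps % spo != 0)
    stop("output_interval must divide duration and be a multiple of dt");
  const long n_frames = steps / spo + 1;

  std::vector<double> sx(n), sy(n), tx(n), ty(n), phi(n), amp(n),
      udx(n, 0.0), udy(n, 0.0), next_redraw(n);
  for (int i = 0; i < n; ++i) {
    sx[i] = nb_init(i, 0); sy[i] = nb_init(i, 1);
    tx[i] = nb_init(i, 2); ty[i] = nb_init(i, 3);
    phi[i] = nb_init(i, 4);
    amp[i] = p.A_mid;
    next_redraw[i] = 2.0 * M_PI * p.u;  // first crossing of a 2*pi*u multiple
  }
  std::vector<double> ax(ax0.begin(), ax0.end()), ay(ay0.begin(), ay0.end()),
      ar(ar0.begin(), ar0.end());
  std::vector<int> aown(a_owner.begin(), a_owner.end());

  uint32_t base = (uint32_t)seed * 2654435761u;
  Rng rng_amp(base + 101u), rng_adh(base + 202u), rng_perm(base + 303u),
      rng_degen(base + 404u);

  auto clamp = [](double x, double lo, double hi) {
    return x < lo ? lo : (x > hi ? hi : x);
  };
  if (p.amp_mode == 2)
    for (int i = 0; i < n; ++i)
      amp[i] = clamp(p.A_mid + p.sigma_A * rng_amp.norm(), p.amp_lo, p.amp_hi);

  double HN = p.HN_mid;
  double sal_period = 2.0 * M_PI / p.omega_sal;
  double next_HN = p.u_H * sal_period;
  if (p.adh_mode == 2)
    HN = clamp(p.HN_mid + p.sigma_H * rng_adh.norm(), 0.0, 2.0 * p.HN_mid);

  std::vector<int> perm(m);
  for (int k = 0; k < m; ++k) perm[k] = k;
  double next_perm = 0.0;  // initial permutation drawn at t = 0

  std::vector<double> lbar(n), Fx(2 * n + m), Fy(2 * n + m);
  std::vector<int> resting(n), B(m), Beff(m);

  NumericMatrix nb_out(n_frames * n, 10);
  NumericMatrix as_out(n_frames * m, 7);
  NumericVector times(n_frames), hn_out(n_frames);
  long frame = 0;
  double max_disp = 0.0;

  for (long s = 0; s <= steps; ++s) {
    double t = s * dt;

    // schedules
    if (p.adh_mode == 1) {
      HN = p.HN_mid + p.A_H * std::sin(p.omega_act * t + p.phi_act);
      if (HN < 0.0) HN = 0.0;
    } else if (p.adh_mode == 2 && t >= next_HN) {
      HN = clamp(p.HN_mid + p.sigma_H * rng_adh.norm(), 0.0, 2.0 * p.HN_mid);
      next_HN += p.u_H * sal_period;
    }
    for (int i = 0; i < n; ++i) {
      double theta = p.omega_sal * t + phi[i];
      double A;
      if (p.amp_mode == 0) A = p.A_mid;
      else if (p.amp_mode == 1)
        A = p.A_mid + p.A_act * std::sin(p.omega_act * t + p.phi_act);
      else {
        while (theta >= next_redraw[i]) {  // start of a resting phase, every u cycles
          amp[i] = clamp(p.A_mid + p.sigma_A * rng_amp.norm(), p.amp_lo, p.amp_hi);
          next_redraw[i] += 2.0 * M_PI * p.u;
        }
        A = amp[i];
      }
      lbar[i] = p.L + A * std::sin(theta);
      resting[i] = (A == 0.0) || (A * std::cos(theta) >= 0.0);
      if (p.amp_mode != 2) amp[i] = A;  // recorded in the trajectory
    }
    if (p.shrink_mode == 1 && m > 0 && t >= next_perm) {
      rng_perm.shuffle(perm);
      next_perm += p.mismatch_interval;
    }

    // neighbour counts at time t (drive both shrinkage and the record);
    // surface distance <= d_slit compared in squared form (identical
    // booleans, no sqrt)
    for (int k = 0; k < m; ++k) {
      int b = 0;
      double lim_s = ar[k] + p.rS + p.d_slit, lim_s2 = lim_s * lim_s;
      double lim_t = ar[k] + p.rT + p.d_slit, lim_t2 = lim_t * lim_t;
      for (int i = 0; i < n; ++i) {
        double dx = mim(sx[i] - ax[k], p.side), dy = mim(sy[i] - ay[k], p.side);
        if (dx * dx + dy * dy <= lim_s2) { ++b; continue; }
        dx = mim(tx[i] - ax[k], p.side); dy = mim(ty[i] - ay[k], p.side);
        if (dx * dx + dy * dy <= lim_t2) ++b;
      }
      B[k] = b;
    }
    for (int k = 0; k < m; ++k)
      Beff[k] = (p.shrink_mode == 1) ? B[perm[k]] : B[k];

    if (s % spo == 0) {
      times[frame] = t;
      hn_out[frame] = HN;
      for (int i = 0; i < n; ++i) {
        long r = frame * n + i;
        if (!std::isfinite(sx[i]) || !std::isfinite(tx[i]) ||
            !std::isfinite(sy[i]) || !std::isfinite(ty[i]))
          stop("non-finite coordinate at t = %f (cell %d)", t, i + 1);
        nb_out(r, 0) = t; nb_out(r, 1) = i + 1;
        nb_out(r, 2) = sx[i]; nb_out(r, 3) = sy[i];
        nb_out(r, 4) = tx[i]; nb_out(r, 5) = ty[i];
        nb_out(r, 6) = udx[i]; nb_out(r, 7) = udy[i];
        nb_out(r, 8) = amp[i]; nb_out(r, 9) = resting[i];
      }
      for (int k = 0; k < m; ++k) {
        long r = frame * m + k;
        as_out(r, 0) = t; as_out(r, 1) = aown[k]; as_out(r, 2) = k + 1;
        as_out(r, 3) = ax[k]; as_out(r, 4) = ay[k];
        as_out(r, 5) = ar[k]; as_out(r, 6) = Beff[k];
      }
      ++frame;
      Rcpp::checkUserInterrupt();
    }
    if (s == steps) break;

    compute_forces(n, m, sx, sy, tx, ty, ax, ay, ar, aown, lbar, p, HN,
                   &rng_degen, Fx, Fy);

    // Euler update with phase-dependent friction
    for (int i = 0; i < n; ++i) {
      double mu_s = resting[i] ? p.mu_high : p.mu_low;
      double mu_t = resting[i] ? p.mu_low : p.mu_high;
      double dxs = dt * Fx[2 * i] / mu_s, dys = dt * Fy[2 * i] / mu_s;
      double dxt = dt * Fx[2 * i + 1] / mu_t, dyt = dt * Fy[2 * i + 1] / mu_t;
      double d1 = dxs * dxs + dys * dys, d2 = dxt * dxt + dyt * dyt;
      if (d1 > max_disp) max_disp = d1;
      if (d2 > max_disp) max_disp = d2;
      sx[i] = wrap1(sx[i] + dxs, p.side); sy[i] = wrap1(sy[i] + dys, p.side);
      tx[i] = wrap1(tx[i] + dxt, p.side); ty[i] = wrap1(ty[i] + dyt, p.side);
      udx[i] += dxs; udy[i] += dys;
    }
    for (int k = 0; k < m; ++k) {
      double dx = dt * Fx[2 * n + k] / p.mu_A, dy = dt * Fy[2 * n + k] / p.mu_A;
      double d2 = dx * dx + dy * dy;
      if (d2 > max_disp) max_disp = d2;
      ax[k] = wrap1(ax[k] + dx, p.side); ay[k] = wrap1(ay[k] + dy, p.side);
      double rbar = p.r_max - p.rho_A * Beff[k];
      if (rbar < p.r_min) rbar = p.r_min;
      ar[k] += (dt / p.tau) * (rbar - ar[k]);
    }
  }

  return List::create(_["times"] = times, _["h_n"] = hn_out,
                      _["nb"] = nb_out, _["astro"] = as_out,
                      _["max_step_disp"] = std::sqrt(max_disp));
}
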