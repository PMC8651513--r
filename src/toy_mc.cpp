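// Metropolis Monte Carlo for small charged Lennard-Jones systems.
// Minimum-image truncated LJ + Coulomb in an orthorhombic periodic box,
// optional harmonic tether to the box centre. Emits, per stored frame,
// the decomposition of the potential energy in the free charge parameters
//   U(theta) = c0 + b.theta + theta' M theta
// (exact, because charges enter the Coulomb sum bilinearly), the diagonal
// virial pressure at the sampling charges, and configuration-only
// observables used by the reweighting oracle.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static const double F_COUL = 138.935458;   // kJ mol^-1 nm e^-2
static const double KB_KJ = 0.008314462618;
static const double BAR = 16.6054;         // 1 kJ/mol/nm^3 in bar

struct Sys {
  int n;
  double box[3];
  const double* sigma;
  const double* eps;
  const int* group;        // 1-based free-group id, 0 = frozen charge
  const double* q;         // actual charge of each particle (e)
  double rc2;
  double kext;             // harmonic tether (kJ/mol/nm^2), 0 = off
};

static inline double mind(double d, double L) {
  d -= L * std::round(d / L);
  return d;
}

// pair energy; r2 must be <= rc2
static inline double pair_u(const Sys& S, int i, int j, double r2) {
  double sig = 0.5 * (S.sigma[i] + S.sigma[j]);
  double epsij = std::sqrt(S.eps[i] * S.eps[j]);
  double u = 0.0;
  if (epsij > 0.0) {
    double sr2 = sig * sig / r2;
    double sr6 = sr2 * sr2 * sr2;
    u += 4.0 * epsij * (sr6 * sr6 - sr6);
  }
  double qq = S.q[i] * S.q[j];
  if (qq != 0.0) u += F_COUL * qq / std::sqrt(r2);
  return u;
}

// energy of particle i against all others + external
static double part_u(const Sys& S, const std::vector<double>& x, int i) {
  double u = 0.0;
  for (int j = 0; j < S.n; ++j) {
    if (j == i) continue;
    double r2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      double dd = mind(x[3 * i + d] - x[3 * j + d], S.box[d]);
      r2 += dd * dd;
    }
    if (r2 <= S.rc2) u += pair_u(S, i, j, r2);
  }
  if (S.kext > 0.0) {
    double r2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      double dd = x[3 * i + d] - 0.5 * S.box[d];
      r2 += dd * dd;
    }
    u += 0.5 * S.kext * r2;
  }
  return u;
}

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericMatrix pos0, NumericVector box,
                NumericVector sigma, NumericVector eps,
                IntegerVector group, NumericVector charge,
                double temperature, int n_steps, double step_size,
                int stride, int burn_in, double cutoff, double kext,
                int seed, bool store_positions) {
  int n = pos0.nrow();
  int ng = 0;
  for (int i = 0; i < n; ++i) ng = std::max(ng, group[i]);
  Sys S;
  S.n = n;
  for (int d = 0; d < 3; ++d) S.box[d] = box[d];
  S.sigma = sigma.begin();
  S.eps = eps.begin();
  S.group = group.begin();
  S.q = charge.begin();
  S.rc2 = cutoff * cutoff;
  S.kext = kext;

  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos0(i, d);

  // reject overlapping starts (LJ core blow-up)
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double r2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double dd = mind(x[3 * i + d] - x[3 * j + d], S.box[d]);
        r2 += dd * dd;
      }
      double sig = 0.5 * (sigma[i] + sigma[j]);
      if (eps[i] > 0 && eps[j] > 0 && r2 < 0.49 * sig * sig)
        stop("overlapping initial coordinates (pair %d,%d)", i + 1, j + 1);
    }

  double beta = 1.0 / (KB_KJ * temperature);
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> runif(0.0, 1.0);
  std::uniform_int_distribution<int> rpick(0, n - 1);

  int n_frames = 0;
  for (int s = burn_in + 1; s <= n_steps; ++s)
    if ((s - burn_in) % stride == 0) ++n_frames;
  if (n_frames < 2) stop("too few frames: increase n_steps or reduce stride");

  NumericVector c0(n_frames), u_base(n_frames);
  NumericMatrix B(n_frames, ng);
  NumericMatrix M(n_frames, ng * ng);   // row-major flattened symmetric M
  NumericVector pxx(n_frames), pyy(n_frames), pzz(n_frames);
  NumericVector inv_r(n_frames);
  NumericMatrix inv_r_g(n_frames, ng);
  NumericMatrix pos_out = store_positions
    ? NumericMatrix(n_frames * n, 3) : NumericMatrix(1, 1);

  long accepted = 0, attempted = 0;
  int frame = 0;
  double V = S.box[0] * S.box[1] * S.box[2];

  for (int s = 1; s <= n_steps; ++s) {
    int i = rpick(rng);
    double old_u = part_u(S, x, i);
    double xi_old[3];
    for (int d = 0; d < 3; ++d) {
      xi_old[d] = x[3 * i + d];
      double nx = xi_old[d] + step_size * (2.0 * runif(rng) - 1.0);
      nx -= S.box[d] * std::floor(nx / S.box[d]);
      x[3 * i + d] = nx;
    }
    double new_u = part_u(S, x, i);
    ++attempted;
    double dU = new_u - old_u;
    if (dU <= 0.0 || runif(rng) < std::exp(-beta * dU)) {
      ++accepted;
    } else {
      for (int d = 0; d < 3; ++d) x[3 * i + d] = xi_old[d];
    }

    if (s > burn_in && (s - burn_in) % stride == 0) {
      // frame bookkeeping: full pair loop
      double fc0 = 0.0, fir = 0.0;
      std::vector<double> fb(ng, 0.0), fM(ng * ng, 0.0), firg(ng, 0.0);
      double w[3] = {0.0, 0.0, 0.0};
      for (int a = 0; a < n; ++a)
        for (int b2 = a + 1; b2 < n; ++b2) {
          double dr[3], r2 = 0.0;
          for (int d = 0; d < 3; ++d) {
            dr[d] = mind(x[3 * a + d] - x[3 * b2 + d], S.box[d]);
            r2 += dr[d] * dr[d];
          }
          if (r2 > S.rc2) continue;
          double r = std::sqrt(r2);
          double ir = 1.0 / r;
          fir += ir;
          int ga = group[a], gb = group[b2];
          if (ga > 0) firg[ga - 1] += ir;
          if (gb > 0 && gb != ga) firg[gb - 1] += ir;
          // LJ part
          double sig = 0.5 * (sigma[a] + sigma[b2]);
          double epsab = std::sqrt(eps[a] * eps[b2]);
          double dudr_lj = 0.0;
          if (epsab > 0.0) {
            double sr2 = sig * sig / r2;
            double sr6 = sr2 * sr2 * sr2;
            fc0 += 4.0 * epsab * (sr6 * sr6 - sr6);
            dudr_lj = -4.0 * epsab * (12.0 * sr6 * sr6 - 6.0 * sr6) / r;
          }
          // Coulomb decomposition in free parameters
          double fcoul_ir = F_COUL * ir;
          if (ga == 0 && gb == 0) {
            fc0 += fcoul_ir * charge[a] * charge[b2];
          } else if (ga > 0 && gb == 0) {
            fb[ga - 1] += fcoul_ir * charge[b2];
          } else if (ga == 0 && gb > 0) {
            fb[gb - 1] += fcoul_ir * charge[a];
          } else if (ga == gb) {
            fM[(ga - 1) * ng + (ga - 1)] += fcoul_ir;
          } else {
            fM[(ga - 1) * ng + (gb - 1)] += 0.5 * fcoul_ir;
            fM[(gb - 1) * ng + (ga - 1)] += 0.5 * fcoul_ir;
          }
          // virial at the sampling charges: w_dd = -u'(r) * dr_d^2 / r
          double dudr = dudr_lj - fcoul_ir * charge[a] * charge[b2] / r;
          for (int d = 0; d < 3; ++d)
            w[d] += -dudr * dr[d] * dr[d] / r;
        }
      double ext = 0.0;
      if (S.kext > 0.0)
        for (int a = 0; a < n; ++a) {
          double r2 = 0.0;
          for (int d = 0; d < 3; ++d) {
            double dd = x[3 * a + d] - 0.5 * S.box[d];
            r2 += dd * dd;
          }
          ext += 0.5 * S.kext * r2;
        }
      fc0 += ext;
      c0[frame] = fc0;
      inv_r[frame] = fir;
      double ub = fc0;
      for (int g = 0; g < ng; ++g) {
        B(frame, g) = fb[g];
        inv_r_g(frame, g) = firg[g];
      }
      // theta at sampling charges: representative charge per group
      std::vector<double> th(ng, 0.0);
      for (int a = 0; a < n; ++a)
        if (group[a] > 0) th[group[a] - 1] = charge[a];
      for (int g = 0; g < ng; ++g) {
        ub += fb[g] * th[g];
        for (int h = 0; h < ng; ++h) {
          M(frame, g * ng + h) = fM[g * ng + h];
          ub += fM[g * ng + h] * th[g] * th[h];
        }
      }
      u_base[frame] = ub;
      double ideal = n * KB_KJ * temperature;
      pxx[frame] = (ideal + w[0]) / V * BAR;
      pyy[frame] = (ideal + w[1]) / V * BAR;
      pzz[frame] = (ideal + w[2]) / V * BAR;
      if (store_positions)
        for (int a = 0; a < n; ++a)
          for (int d = 0; d < 3; ++d)
            pos_out(frame * n + a, d) = x[3 * a + d];
      ++frame;
    }
  }

  return List::create(
    _["n_frames"] = n_frames, _["n_groups"] = ng,
    _["c0"] = c0, _["B"] = B, _["M"] = M, _["u_base"] = u_base,
    _["pxx"] = pxx, _["pyy"] = pyy, _["pzz"] = pzz,
    _["inv_r"] = inv_r, _["inv_r_g"] = inv_r_g,
    _["acceptance"] = attempted ? (double)accepted / attempted : NA_REAL,
    _["positions"] = pos_out);
}
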