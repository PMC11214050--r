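// Metropolis Monte Carlo relaxation of grown chromatin configurations at
// nucleosome resolution.
//
// Each inter-nucleosome virtual bond (the linker from the DNA exit pose of
// nucleosome j to the entry pose of nucleosome j+1) carries a quadratic
// deformation energy with bend, twist, and stretch terms whose moduli derive
// from the wormlike-chain constants (lp, lt, L1, tau). Nucleosome sterics
// use the shifted Lennard-Jones repulsion: V0 [ (2R/D)^12 - 2 (2R/D)^6 + 1 ]
// for D < 2R, zero otherwise. Moves are crankshaft rotations of internal
// segments, rigid pivots of terminal segments, and single-nucleosome
// perturbations; only the two boundary bonds of a rigidly moved segment and
// the moved-vs-unmoved steric pairs change energy.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double HUGE_E = 1e12;

inline double wrap_angle(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a <= -M_PI) a += 2.0 * M_PI;
  return a;
}

inline void mat_mul(const double *A, const double *B, double *C) {
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += A[3 * r + k] * B[3 * k + c];
      C[3 * r + c] = s;
    }
}

inline void axis_angle_rot(const double *ax, double ang, double *R) {
  double c = std::cos(ang), s = std::sin(ang), t = 1.0 - c;
  double x = ax[0], y = ax[1], z = ax[2];
  R[0] = t * x * x + c;     R[1] = t * x * y - s * z; R[2] = t * x * z + s * y;
  R[3] = t * x * y + s * z; R[4] = t * y * y + c;     R[5] = t * y * z - s * x;
  R[6] = t * x * z - s * y; R[7] = t * y * z + s * x; R[8] = t * z * z + c;
}

inline void random_unit_axis(double *ax) {
  double u = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - u * u));
  ax[0] = s * std::cos(phi);
  ax[1] = s * std::sin(phi);
  ax[2] = u;
}

struct Relaxer {
  int N;
  std::vector<double> pos, tri;      // 3N, 9N
  std::vector<int> lbp;              // N-1 linker lengths (bp)
  double dl[3], Rk[9];
  double lp, lt, L1, tau, stretch_scale, V0, Rnuc;
  std::vector<double> E_el;          // per-bond elastic energy
  // extended precision keeps incremental totals within 1e-8 of a full
  // recomputation even when overlap energies are many orders larger
  long double E_st;                  // total steric energy

  double pair_steric(int i, int j) const {
    double dx = pos[3 * i] - pos[3 * j];
    double dy = pos[3 * i + 1] - pos[3 * j + 1];
    double dz = pos[3 * i + 2] - pos[3 * j + 2];
    double D2 = dx * dx + dy * dy + dz * dz;
    double cut = 2.0 * Rnuc;
    if (D2 >= cut * cut) return 0.0;
    if (D2 < 1e-12) return HUGE_E;
    double x2 = cut * cut / D2;
    double x6 = x2 * x2 * x2;
    return V0 * (x6 * x6 - 2.0 * x6 + 1.0);
  }

  long double full_steric() const {
    long double s = 0.0;
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j) s += pair_steric(i, j);
    return s;
  }

  // steric energy of nucleosomes [a, b] against everything outside [a, b]
  long double cross_steric(int a, int b) const {
    long double s = 0.0;
    for (int i = a; i <= b; ++i) {
      for (int j = 0; j < a; ++j) s += pair_steric(i, j);
      for (int j = b + 1; j < N; ++j) s += pair_steric(i, j);
    }
    return s;
  }

  double elastic_bond(int j) const {
    const double *Qa = &tri[9 * j];
    const double *Qb = &tri[9 * (j + 1)];
    double L = lbp[j] * L1;
    // exit pose of nucleosome j
    double po[3], Fo[9];
    for (int k = 0; k < 3; ++k)
      po[k] = pos[3 * j + k] + Qa[3 * k] * dl[0] + Qa[3 * k + 1] * dl[1] +
              Qa[3 * k + 2] * dl[2];
    mat_mul(Qa, Rk, Fo);
    double r[3];
    for (int k = 0; k < 3; ++k) r[k] = pos[3 * (j + 1) + k] - po[k];
    double rn = std::sqrt(r[0] * r[0] + r[1] * r[1] + r[2] * r[2]);
    double th1 = 0.0, th2 = 0.0;
    if (rn > 1e-9) {
      double u[3] = {r[0] / rn, r[1] / rn, r[2] / rn};
      double c1 = Fo[2] * u[0] + Fo[5] * u[1] + Fo[8] * u[2];
      double c2 = Qb[2] * u[0] + Qb[5] * u[1] + Qb[8] * u[2];
      th1 = std::acos(std::min(1.0, std::max(-1.0, c1)));
      th2 = std::acos(std::min(1.0, std::max(-1.0, c2)));
    }
    // twist from the frame rotation Fo^T Qb
    double m00 = 0.0, m01 = 0.0, m10 = 0.0, m11 = 0.0;
    for (int k = 0; k < 3; ++k) {
      m00 += Fo[3 * k] * Qb[3 * k];
      m01 += Fo[3 * k] * Qb[3 * k + 1];
      m10 += Fo[3 * k + 1] * Qb[3 * k];
      m11 += Fo[3 * k + 1] * Qb[3 * k + 1];
    }
    double tw = std::atan2(m10 - m01, m00 + m11);
    double dev = wrap_angle(tw - tau * lbp[j]); // tau is rad per bp
    double ks = stretch_scale * lp * lp / (L * L * L * L);
    return 0.5 * lp / L * (th1 * th1 + th2 * th2) +
           0.5 * lt / L * dev * dev + 0.5 * ks * (rn - L) * (rn - L);
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".elastic_bonds_cpp")]]
NumericVector elastic_bonds_cpp(NumericMatrix pos0, NumericMatrix tri0,
                                IntegerVector linker_bp, NumericVector d_local,
                                NumericVector R_kink, double lp, double lt,
                                double L1, double tau, double stretch_scale) {
  Relaxer rx;
  rx.N = pos0.nrow();
  rx.pos.resize(3 * rx.N);
  rx.tri.resize(9 * rx.N);
  for (int i = 0; i < rx.N; ++i) {
    for (int k = 0; k < 3; ++k) rx.pos[3 * i + k] = pos0(i, k);
    for (int k = 0; k < 9; ++k) rx.tri[9 * i + k] = tri0(i, k);
  }
  rx.lbp.assign(linker_bp.begin(), linker_bp.end());
  for (int k = 0; k < 3; ++k) rx.dl[k] = d_local[k];
  for (int k = 0; k < 9; ++k) rx.Rk[k] = R_kink[k];
  rx.lp = lp; rx.lt = lt; rx.L1 = L1; rx.tau = tau;
  rx.stretch_scale = stretch_scale;
  NumericVector out(rx.N - 1);
  for (int j = 0; j < rx.N - 1; ++j) out[j] = rx.elastic_bond(j);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".relax_cpp")]]
List relax_cpp(NumericMatrix pos0, NumericMatrix tri0, IntegerVector linker_bp,
               NumericVector d_local, NumericVector R_kink, double lp,
               double lt, double L1, double tau, double stretch_scale,
               double V0, double Rnuc, int n_steps, NumericVector probs,
               double amp_crank, double amp_pivot, double amp_single_t,
               double amp_single_r, int seg_max, int trace_every) {
  Relaxer rx;
  int N = pos0.nrow();
  if (N < 2) stop("need at least 2 nucleosomes");
  if (linker_bp.size() != N - 1) stop("need N - 1 linker lengths");
  rx.N = N;
  rx.pos.resize(3 * N);
  rx.tri.resize(9 * N);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) rx.pos[3 * i + k] = pos0(i, k);
    for (int k = 0; k < 9; ++k) rx.tri[9 * i + k] = tri0(i, k);
  }
  rx.lbp.assign(linker_bp.begin(), linker_bp.end());
  for (int k = 0; k < 3; ++k) rx.dl[k] = d_local[k];
  for (int k = 0; k < 9; ++k) rx.Rk[k] = R_kink[k];
  rx.lp = lp; rx.lt = lt; rx.L1 = L1; rx.tau = tau;
  rx.stretch_scale = stretch_scale;
  rx.V0 = V0; rx.Rnuc = Rnuc;

  rx.E_el.resize(N - 1);
  long double E_el_tot = 0.0;
  for (int j = 0; j < N - 1; ++j) {
    rx.E_el[j] = rx.elastic_bond(j);
    E_el_tot += rx.E_el[j];
  }
  rx.E_st = rx.full_steric();

  double p_crank = probs[0], p_pivot = probs[1];
  int n_trace = trace_every > 0 ? n_steps / trace_every : 0;
  NumericMatrix trace(n_trace, 3);
  int trace_row = 0;
  IntegerVector n_prop(3), n_acc(3);

  std::vector<double> save_pos(3 * N), save_tri(9 * N);

  for (int step = 0; step < n_steps; ++step) {
    double u = unif_rand();
    int type; // 0 crank, 1 pivot, 2 single
    if (u < p_crank && N >= 3) type = 0;
    else if (u < p_crank + p_pivot) type = 1;
    else type = 2;

    int a, b; // moved (contiguous, inclusive) range
    double ax[3], Rm[9], pivot[3];
    bool rotate = true;

    if (type == 0) {
      // crankshaft about the axis joining two anchor nucleosomes p < q
      int pa = (int)(unif_rand() * (N - 2));
      if (pa > N - 3) pa = N - 3;
      int max_m = std::min(seg_max, N - 2 - pa);
      int m = 1 + (int)(unif_rand() * max_m);
      if (m > max_m) m = max_m;
      int qa = pa + m + 1;
      a = pa + 1; b = qa - 1;
      double v[3];
      double nv = 0.0;
      for (int k = 0; k < 3; ++k) {
        v[k] = rx.pos[3 * qa + k] - rx.pos[3 * pa + k];
        nv += v[k] * v[k];
      }
      nv = std::sqrt(nv);
      if (nv > 1e-9) for (int k = 0; k < 3; ++k) ax[k] = v[k] / nv;
      else random_unit_axis(ax);
      double ang = amp_crank * (2.0 * unif_rand() - 1.0);
      axis_angle_rot(ax, ang, Rm);
      for (int k = 0; k < 3; ++k) pivot[k] = rx.pos[3 * pa + k];
    } else if (type == 1) {
      // rigid rotation of a terminal segment about a random axis through
      // the boundary nucleosome
      bool head = unif_rand() < 0.5;
      int max_m = std::min(seg_max, N - 1);
      int m = 1 + (int)(unif_rand() * max_m);
      if (m > max_m) m = max_m;
      int kpiv;
      if (head) { a = 0; b = m - 1; kpiv = m; }
      else { a = N - m; b = N - 1; kpiv = N - m - 1; }
      random_unit_axis(ax);
      double ang = amp_pivot * (2.0 * unif_rand() - 1.0);
      axis_angle_rot(ax, ang, Rm);
      for (int k = 0; k < 3; ++k) pivot[k] = rx.pos[3 * kpiv + k];
    } else {
      // single-nucleosome translation + orientation perturbation
      a = b = (int)(unif_rand() * N);
      if (a > N - 1) a = b = N - 1;
      rotate = false;
    }
    ++n_prop[type];

    // save the moved block
    for (int i = a; i <= b; ++i) {
      for (int k = 0; k < 3; ++k) save_pos[3 * i + k] = rx.pos[3 * i + k];
      for (int k = 0; k < 9; ++k) save_tri[9 * i + k] = rx.tri[9 * i + k];
    }

    // old energies of affected bonds and steric cross terms
    int bond_lo = a - 1, bond_hi = b; // may be out of range; checked below
    double E_old = 0.0;
    if (bond_lo >= 0) E_old += rx.E_el[bond_lo];
    if (bond_hi <= N - 2) E_old += rx.E_el[bond_hi];
    long double st_old = rx.cross_steric(a, b);

    // apply the move
    if (rotate) {
      for (int i = a; i <= b; ++i) {
        double d[3], nd[3];
        for (int k = 0; k < 3; ++k) d[k] = rx.pos[3 * i + k] - pivot[k];
        for (int r = 0; r < 3; ++r)
          nd[r] = Rm[3 * r] * d[0] + Rm[3 * r + 1] * d[1] + Rm[3 * r + 2] * d[2];
        for (int k = 0; k < 3; ++k) rx.pos[3 * i + k] = pivot[k] + nd[k];
        double Q[9];
        mat_mul(Rm, &rx.tri[9 * i], Q);
        for (int k = 0; k < 9; ++k) rx.tri[9 * i + k] = Q[k];
      }
    } else {
      for (int k = 0; k < 3; ++k)
        rx.pos[3 * a + k] += amp_single_t * (2.0 * unif_rand() - 1.0);
      if (amp_single_r > 0.0) {
        random_unit_axis(ax);
        double ang = amp_single_r * (2.0 * unif_rand() - 1.0);
        axis_angle_rot(ax, ang, Rm);
        double Q[9];
        mat_mul(Rm, &rx.tri[9 * a], Q);
        for (int k = 0; k < 9; ++k) rx.tri[9 * a + k] = Q[k];
      }
    }

    double e_lo = bond_lo >= 0 ? rx.elastic_bond(bond_lo) : 0.0;
    double e_hi = bond_hi <= N - 2 ? rx.elastic_bond(bond_hi) : 0.0;
    double E_new = (bond_lo >= 0 ? e_lo : 0.0) + (bond_hi <= N - 2 ? e_hi : 0.0);
    long double st_new = rx.cross_steric(a, b);
    double dE = (E_new - E_old) + (double)(st_new - st_old);

    bool accept = dE <= 0.0 || unif_rand() < std::exp(-dE);
    if (accept) {
      if (bond_lo >= 0) { E_el_tot += (long double)e_lo - rx.E_el[bond_lo]; rx.E_el[bond_lo] = e_lo; }
      if (bond_hi <= N - 2) { E_el_tot += (long double)e_hi - rx.E_el[bond_hi]; rx.E_el[bond_hi] = e_hi; }
      rx.E_st += st_new - st_old;
      ++n_acc[type];
    } else {
      for (int i = a; i <= b; ++i) {
        for (int k = 0; k < 3; ++k) rx.pos[3 * i + k] = save_pos[3 * i + k];
        for (int k = 0; k < 9; ++k) rx.tri[9 * i + k] = save_tri[9 * i + k];
      }
    }

    if (trace_every > 0 && (step + 1) % trace_every == 0 &&
        trace_row < n_trace) {
      trace(trace_row, 0) = step + 1;
      trace(trace_row, 1) = (double)E_el_tot;
      trace(trace_row, 2) = (double)rx.E_st;
      ++trace_row;
    }
  }

  NumericMatrix pos_out(N, 3), tri_out(N, 9);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) pos_out(i, k) = rx.pos[3 * i + k];
    for (int k = 0; k < 9; ++k) tri_out(i, k) = rx.tri[9 * i + k];
  }
  colnames(trace) = CharacterVector::create("step", "elastic", "steric");
  return List::create(
      _["pos"] = pos_out, _["tri"] = tri_out, _["trace"] = trace,
      _["elastic_total"] = (double)E_el_tot,
      _["steric_total"] = (double)rx.E_st,
      _["n_proposed"] = n_prop, _["n_accepted"] = n_acc);
}
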