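// Base-pair-resolved chain growth under the kinked twistable wormlike chain.
//
// Each bp contributes a rotation R = Rz(phi) Ry(theta) Rz(psi - phi): a bend
// of magnitude theta toward azimuth phi plus a twist psi about the local
// tangent, followed by a translation of L1 along the new tangent. theta is
// drawn with density proportional to exp(kappa * cos(theta)) on the sphere
// (kappa = lp / L1), whose mean cosine is the Langevin-type coth(kappa) -
// 1/kappa; psi is Gaussian with mean tau (rad per bp) and variance L1 / lt.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

typedef double Tri[9]; // row-major triad, columns are frame axes

inline double sample_cos_bend(double kappa) {
  // inverse CDF for density prop. to exp(kappa * u), u in [-1, 1]
  double v = unif_rand();
  if (kappa < 1e-12) return 2.0 * v - 1.0;
  // u = 1 + log(v + (1 - v) e^{-2 kappa}) / kappa, computed stably
  double u = 1.0 + std::log(v + (1.0 - v) * std::exp(-2.0 * kappa)) / kappa;
  if (u > 1.0) u = 1.0;
  if (u < -1.0) u = -1.0;
  return u;
}

inline void step_rotation(double cb, double phi, double psi, double *R) {
  // R = Rz(phi) Ry(theta) Rz(psi - phi), cb = cos(theta)
  double sb = std::sqrt(std::max(0.0, 1.0 - cb * cb));
  double cp = std::cos(phi), sp = std::sin(phi);
  double g = psi - phi;
  double cg = std::cos(g), sg = std::sin(g);
  // Ry(theta) Rz(g)
  double a11 = cb * cg, a12 = -cb * sg, a13 = sb;
  double a21 = sg, a22 = cg, a23 = 0.0;
  double a31 = -sb * cg, a32 = sb * sg, a33 = cb;
  R[0] = cp * a11 - sp * a21; R[1] = cp * a12 - sp * a22; R[2] = cp * a13 - sp * a23;
  R[3] = sp * a11 + cp * a21; R[4] = sp * a12 + cp * a22; R[5] = sp * a13 + cp * a23;
  R[6] = a31; R[7] = a32; R[8] = a33;
}

inline void mat_mul(const double *A, const double *B, double *C) {
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += A[3 * r + k] * B[3 * k + c];
      C[3 * r + c] = s;
    }
}

inline void reorthonormalize(double *F) {
  // Gram-Schmidt on columns; guards against slow round-off drift
  double c1[3], c2[3], c3[3];
  for (int k = 0; k < 3; ++k) {
    c1[k] = F[3 * k];
    c2[k] = F[3 * k + 1];
  }
  double n1 = std::sqrt(c1[0] * c1[0] + c1[1] * c1[1] + c1[2] * c1[2]);
  for (int k = 0; k < 3; ++k) c1[k] /= n1;
  double d = c1[0] * c2[0] + c1[1] * c2[1] + c1[2] * c2[2];
  for (int k = 0; k < 3; ++k) c2[k] -= d * c1[k];
  double n2 = std::sqrt(c2[0] * c2[0] + c2[1] * c2[1] + c2[2] * c2[2]);
  for (int k = 0; k < 3; ++k) c2[k] /= n2;
  c3[0] = c1[1] * c2[2] - c1[2] * c2[1];
  c3[1] = c1[2] * c2[0] - c1[0] * c2[2];
  c3[2] = c1[0] * c2[1] - c1[1] * c2[0];
  for (int k = 0; k < 3; ++k) {
    F[3 * k] = c1[k];
    F[3 * k + 1] = c2[k];
    F[3 * k + 2] = c3[k];
  }
}

struct Grower {
  double kappa, sd_twist, mean_twist, L1;
  double p[3];
  double F[9];
  long n_steps;

  Grower(double lp, double lt, double L1_, double tau)
      : kappa(lp / L1_), sd_twist(std::sqrt(L1_ / lt)),
        mean_twist(tau), L1(L1_), n_steps(0) {
    p[0] = p[1] = p[2] = 0.0;
    for (int k = 0; k < 9; ++k) F[k] = 0.0;
    F[0] = F[4] = F[8] = 1.0;
  }

  void bp_step() {
    double cb = sample_cos_bend(kappa);
    double phi = 2.0 * M_PI * unif_rand();
    double psi = norm_rand() * sd_twist + mean_twist;
    double R[9], Fn[9];
    step_rotation(cb, phi, psi, R);
    mat_mul(F, R, Fn);
    for (int k = 0; k < 9; ++k) F[k] = Fn[k];
    if (++n_steps % 500 == 0) reorthonormalize(F);
    p[0] += L1 * F[2];
    p[1] += L1 * F[5];
    p[2] += L1 * F[8];
  }

  void apply_kink(const double *d_local, const double *R_kink) {
    for (int k = 0; k < 3; ++k)
      p[k] += F[3 * k] * d_local[0] + F[3 * k + 1] * d_local[1] +
              F[3 * k + 2] * d_local[2];
    double Fn[9];
    mat_mul(F, R_kink, Fn);
    for (int k = 0; k < 9; ++k) F[k] = Fn[k];
    reorthonormalize(F);
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".sample_bp_angles_cpp")]]
NumericMatrix sample_bp_angles_cpp(int n, double lp, double lt, double L1,
                                   double tau) {
  NumericMatrix out(n, 3);
  double kappa = lp / L1;
  double sd_twist = std::sqrt(L1 / lt);
  double mean_twist = tau;
  for (int i = 0; i < n; ++i) {
    double cb = sample_cos_bend(kappa);
    out(i, 0) = std::acos(cb);
    out(i, 1) = 2.0 * M_PI * unif_rand();
    out(i, 2) = norm_rand() * sd_twist + mean_twist;
  }
  colnames(out) = CharacterVector::create("bend", "azimuth", "twist");
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".grow_dna_cpp")]]
List grow_dna_cpp(int n_bp, double lp, double lt, double L1, double tau) {
  Grower g(lp, lt, L1, tau);
  NumericMatrix pos(n_bp + 1, 3), tri(n_bp + 1, 9);
  for (int k = 0; k < 3; ++k) pos(0, k) = g.p[k];
  for (int k = 0; k < 9; ++k) tri(0, k) = g.F[k];
  for (int i = 1; i <= n_bp; ++i) {
    g.bp_step();
    for (int k = 0; k < 3; ++k) pos(i, k) = g.p[k];
    for (int k = 0; k < 9; ++k) tri(i, k) = g.F[k];
  }
  return List::create(_["pos"] = pos, _["tri"] = tri);
}

//' @noRd
// [[Rcpp::export(name = ".grow_chain_cpp")]]
List grow_chain_cpp(IntegerVector linkers, NumericVector d_local,
                    NumericVector R_kink, double lp, double lt, double L1,
                    double tau, bool record_bp) {
  int M = linkers.size() + 1;
  long n_bp = 0;
  for (int i = 0; i < linkers.size(); ++i) n_bp += linkers[i];

  Grower g(lp, lt, L1, tau);
  NumericMatrix nuc_pos(M, 3), nuc_tri(M, 9);
  NumericMatrix bp_pos(record_bp ? n_bp : 0, 3);
  NumericMatrix bp_tri(record_bp ? n_bp : 0, 9);
  IntegerVector linker_map(record_bp ? n_bp : 0);

  double dl[3] = {d_local[0], d_local[1], d_local[2]};
  double Rk[9];
  for (int k = 0; k < 9; ++k) Rk[k] = R_kink[k];

  long bp = 0;
  for (int m = 0; m < M; ++m) {
    // record the DNA entry pose of nucleosome m
    for (int k = 0; k < 3; ++k) nuc_pos(m, k) = g.p[k];
    for (int k = 0; k < 9; ++k) nuc_tri(m, k) = g.F[k];
    if (m == M - 1) break;
    g.apply_kink(dl, Rk);
    for (int j = 0; j < linkers[m]; ++j) {
      g.bp_step();
      if (record_bp) {
        for (int k = 0; k < 3; ++k) bp_pos(bp, k) = g.p[k];
        for (int k = 0; k < 9; ++k) bp_tri(bp, k) = g.F[k];
        linker_map[bp] = m + 1; // 1-based linker index
      }
      ++bp;
    }
  }
  List out = List::create(_["nuc_pos"] = nuc_pos, _["nuc_tri"] = nuc_tri);
  if (record_bp) {
    out["bp_pos"] = bp_pos;
    out["bp_tri"] = bp_tri;
    out["linker_map"] = linker_map;
  }
  return out;
}
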