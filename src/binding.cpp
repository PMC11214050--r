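// Transfer-matrix evaluation of the grand-canonical HP1 binding model and
// heat-bath Monte Carlo sampling of linker lengths.
//
// Energies are in kBT throughout (beta = 1). Occupancy states sigma in
// {0,1,2} index the 3x3 transfer matrices; bond i couples nucleosomes i and
// i+1 with periodic closure (bond M-1 couples M-1 and 0, 0-based).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Mat3 {
  double m[9]; // row-major
};

inline double phi_bind(int sig, int s, double mu, double eps) {
  // five-branch single-nucleosome binding free energy; the J_int term of the
  // doubly-occupied branch is added by the caller so this helper stays a
  // pure function of (sigma, s, mu, eps).
  switch (sig) {
  case 0: return 0.0;
  case 1:
    if (s == 0) return -mu - std::log(2.0);
    if (s == 1) return -mu - std::log(1.0 + std::exp(-eps));
    return -mu + eps - std::log(2.0);
  default: // sig == 2, J added by caller
    return -2.0 * mu + s * eps;
  }
}

inline double phi_bind_full(int sig, int s, double mu, double eps, double J) {
  double e = phi_bind(sig, s, mu, eps);
  if (sig == 2) e += J;
  return e;
}

inline void fill_T(Mat3 &T, int s_i, int s_j, int gamma, double mu,
                   double eps, double J) {
  double hb_i[3], hb_j[3];
  for (int k = 0; k < 3; ++k) {
    hb_i[k] = -0.5 * phi_bind_full(k, s_i, mu, eps, J);
    hb_j[k] = -0.5 * phi_bind_full(k, s_j, mu, eps, J);
  }
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c)
      T.m[3 * r + c] = std::exp(hb_i[r] + hb_j[c] - J * gamma * r * c);
}

inline void matmul(const Mat3 &A, const Mat3 &B, Mat3 &C) {
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += A.m[3 * r + k] * B.m[3 * k + c];
      C.m[3 * r + c] = s;
    }
}

inline double rescale(Mat3 &A) {
  double mx = 0.0;
  for (int k = 0; k < 9; ++k) if (A.m[k] > mx) mx = A.m[k];
  if (mx <= 0.0) return 0.0;
  for (int k = 0; k < 9; ++k) A.m[k] /= mx;
  return std::log(mx);
}

// rescale without tracking the factor; valid wherever scales cancel in a
// trace ratio
inline void rescale_nolog(Mat3 &A) {
  double mx = 0.0;
  for (int k = 0; k < 9; ++k) if (A.m[k] > mx) mx = A.m[k];
  if (mx > 0.0) for (int k = 0; k < 9; ++k) A.m[k] /= mx;
}

inline double trace3(const Mat3 &A) { return A.m[0] + A.m[4] + A.m[8]; }

inline void set_identity(Mat3 &A) {
  for (int k = 0; k < 9; ++k) A.m[k] = 0.0;
  A.m[0] = A.m[4] = A.m[8] = 1.0;
}

// trace(A * D * B) with D = diag(0, 1, 2)
inline double trace_ADB(const Mat3 &A, const Mat3 &B) {
  double s = 0.0;
  for (int r = 0; r < 3; ++r)
    for (int k = 0; k < 3; ++k)
      s += A.m[3 * r + k] * k * B.m[3 * k + r];
  return s;
}

inline double trace_AB(const Mat3 &A, const Mat3 &B) {
  double s = 0.0;
  for (int r = 0; r < 3; ++r)
    for (int k = 0; k < 3; ++k)
      s += A.m[3 * r + k] * B.m[3 * k + r];
  return s;
}

// Precompute both gamma branches of every bond's transfer matrix.
void build_bond_tables(const IntegerVector &s, double mu, double eps,
                       double J, std::vector<Mat3> &T0, std::vector<Mat3> &T1) {
  int M = s.size();
  T0.resize(M);
  T1.resize(M);
  for (int i = 0; i < M; ++i) {
    int j = (i + 1) % M;
    fill_T(T0[i], s[i], s[j], 0, mu, eps, J);
    fill_T(T1[i], s[i], s[j], 1, mu, eps, J);
  }
}

// Free-energy difference Phi(gamma_i = 1) - Phi(gamma_i = 0) with all other
// bonds frozen at their current state. O(M) matrix multiplies.
double delta_phi_bond(int i, const std::vector<Mat3> &T0,
                      const std::vector<Mat3> &T1, const IntegerVector &gamma) {
  int M = gamma.size();
  Mat3 A, B, tmp;
  set_identity(A);
  set_identity(B);
  for (int k = 0; k < i; ++k) {
    matmul(A, gamma[k] ? T1[k] : T0[k], tmp);
    A = tmp;
    rescale_nolog(A); // scale factors cancel in the trace ratio
  }
  for (int k = M - 1; k > i; --k) {
    matmul(gamma[k] ? T1[k] : T0[k], B, tmp);
    B = tmp;
    rescale_nolog(B);
  }
  Mat3 AT1, AT0;
  matmul(A, T1[i], AT1);
  matmul(A, T0[i], AT0);
  double t1 = trace_AB(AT1, B);
  double t0 = trace_AB(AT0, B);
  return -(std::log(t1) - std::log(t0));
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".tm_evaluate_cpp")]]
List tm_evaluate_cpp(IntegerVector s, IntegerVector gamma, double eps_m,
                     double J_int, double mu) {
  int M = s.size();
  if (gamma.size() != M) stop("length of gamma must equal length of s");
  std::vector<Mat3> T0, T1;
  build_bond_tables(s, mu, eps_m, J_int, T0, T1);

  // prefix products P[i] = T_0 ... T_i, suffix S[i] = T_i ... T_{M-1},
  // each rescaled to unit max-norm with accumulated log scale factors.
  std::vector<Mat3> P(M), S(M);
  double log_scale = 0.0;
  Mat3 tmp;
  P[0] = gamma[0] ? T1[0] : T0[0];
  log_scale += rescale(P[0]);
  for (int i = 1; i < M; ++i) {
    matmul(P[i - 1], gamma[i] ? T1[i] : T0[i], tmp);
    P[i] = tmp;
    log_scale += rescale(P[i]);
  }
  double log_xi = log_scale + std::log(trace3(P[M - 1]));

  S[M - 1] = gamma[M - 1] ? T1[M - 1] : T0[M - 1];
  rescale(S[M - 1]);
  for (int i = M - 2; i >= 0; --i) {
    matmul(gamma[i] ? T1[i] : T0[i], S[i + 1], tmp);
    S[i] = tmp;
    rescale(S[i]);
  }

  // <sigma_i> by inserting diag(0,1,2) at site i; prefix/suffix scale
  // factors are identical in numerator and denominator and cancel.
  NumericVector occ(M);
  // site 0 sits before bond 0: <sigma_0> = tr(D S_0) / tr(S_0)
  occ[0] = (1.0 * S[0].m[4] + 2.0 * S[0].m[8]) / trace3(S[0]);
  for (int i = 1; i < M; ++i) {
    double num = trace_ADB(P[i - 1], S[i]);
    double den = trace_AB(P[i - 1], S[i]);
    occ[i] = num / den;
  }

  return List::create(_["log_xi"] = log_xi, _["occupancy"] = occ);
}

//' @noRd
// [[Rcpp::export(name = ".delta_phi_cpp")]]
double delta_phi_cpp(int i, IntegerVector s, IntegerVector gamma,
                     double eps_m, double J_int, double mu) {
  int M = s.size();
  if (i < 1 || i > M) stop("linker index out of range");
  std::vector<Mat3> T0, T1;
  build_bond_tables(s, mu, eps_m, J_int, T0, T1);
  return delta_phi_bond(i - 1, T0, T1, gamma);
}

namespace {

// draw one linker length from the two-branch conditional law given the
// free-energy difference dphi of enabling its interaction
inline int draw_length(double dphi, int l_c, double z, double log_z,
                       double zlc, double short_geom) {
  double w = std::exp(-dphi); // >= 1 since dphi <= 0
  double p_short = w * short_geom / (w * short_geom + zlc);
  double u = unif_rand();
  if (u < p_short) {
    // inverse CDF of the truncated geometric on {1, ..., l_c}
    double v = unif_rand();
    int l = (int)std::ceil(std::log(1.0 - v * short_geom) / log_z);
    if (l < 1) l = 1;
    if (l > l_c) l = l_c;
    return l;
  }
  // shifted geometric tail on {l_c + 1, ...}
  double v = unif_rand();
  int k = (int)std::ceil(std::log(1.0 - v) / log_z);
  if (k < 1) k = 1;
  return l_c + k;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".linker_sweep_cpp")]]
List linker_sweep_cpp(IntegerVector s, IntegerVector lengths, double eps_m,
                      double J_int, double mu, int l_c, double z,
                      int n_sweeps, bool record_gamma, bool random_scan) {
  int M = s.size();
  if (lengths.size() != M) stop("lengths must have one entry per nucleosome");
  std::vector<Mat3> T0, T1;
  build_bond_tables(s, mu, eps_m, J_int, T0, T1);

  IntegerVector len = clone(lengths);
  IntegerVector gamma(M);
  for (int i = 0; i < M; ++i) gamma[i] = len[i] <= l_c ? 1 : 0;

  double log_z = std::log(z);
  double zlc = std::pow(z, l_c);
  double short_geom = 1.0 - zlc; // truncated-geometric mass factor, l <= l_c

  NumericVector trace(n_sweeps);
  IntegerMatrix gamma_rec = record_gamma ? IntegerMatrix(n_sweeps, M)
                                         : IntegerMatrix(0, 0);

  std::vector<Mat3> S(M + 1); // suffix cache for the in-order scan

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    if (random_scan) {
      // uniformly random linker per update; O(M) matrix products per update
      for (int step = 0; step < M; ++step) {
        int i = (int)(unif_rand() * M);
        if (i >= M) i = M - 1;
        double dphi = delta_phi_bond(i, T0, T1, gamma);
        int l = draw_length(dphi, l_c, z, log_z, zlc, short_geom);
        len[i] = l;
        gamma[i] = l <= l_c ? 1 : 0;
      }
    } else {
      // in-order scan with per-sweep suffix cache and an incrementally
      // updated prefix: O(M) matrix products per sweep in total. Bonds
      // after position i are untouched earlier in the sweep, so the cached
      // suffixes stay exact for every conditional draw.
      set_identity(S[M]);
      for (int k = M - 1; k >= 0; --k) {
        matmul(gamma[k] ? T1[k] : T0[k], S[k + 1], S[k]);
        rescale_nolog(S[k]);
      }
      Mat3 A, tmp, AT;
      set_identity(A);
      for (int i = 0; i < M; ++i) {
        matmul(A, T1[i], AT);
        double t1 = trace_AB(AT, S[i + 1]);
        matmul(A, T0[i], AT);
        double t0 = trace_AB(AT, S[i + 1]);
        double dphi = -(std::log(t1) - std::log(t0));
        int l = draw_length(dphi, l_c, z, log_z, zlc, short_geom);
        len[i] = l;
        gamma[i] = l <= l_c ? 1 : 0;
        matmul(A, gamma[i] ? T1[i] : T0[i], tmp);
        A = tmp;
        rescale_nolog(A);
      }
    }
    int n_short = 0;
    for (int i = 0; i < M; ++i) n_short += gamma[i];
    trace[sweep] = (double)n_short / M;
    if (record_gamma)
      for (int i = 0; i < M; ++i) gamma_rec(sweep, i) = gamma[i];
  }

  List out = List::create(_["lengths"] = len, _["gamma"] = gamma,
                          _["trace"] = trace);
  if (record_gamma) out["gamma_record"] = gamma_rec;
  return out;
}
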