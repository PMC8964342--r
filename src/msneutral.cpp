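// Sampling kernels for the hierarchical-Dirichlet-process multi-site
// neutral model: CRP table counts, stick breaking, Polya-urn site
// simulation, slice samplers for the theta and immigration conditionals,
// the full Gibbs sweep, and a forward Moran (zero-sum birth/death)
// simulator. All randomness goes through R's RNG so set.seed() governs
// every draw.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Chinese restaurant process: customer i (1-based) opens a new table with
// probability conc / (conc + i - 1); returns the table count, distributed
// as Antoniak(conc, n).
// [[Rcpp::export]]
int crp_tables_cpp(int n, double conc) {
  if (n < 0) stop("n must be non-negative");
  if (conc <= 0.0) stop("concentration must be positive");
  int t = 0;
  for (int i = 0; i < n; ++i) {
    if (unif_rand() * (conc + i) < conc) ++t;
  }
  return t;
}

// Stick-breaking weights Stick(theta), truncated when the residual stick
// falls below eps. Returned weights sum to 1 - residual (< eps short of 1).
// [[Rcpp::export]]
NumericVector stick_break_cpp(double theta, double eps) {
  if (theta <= 0.0) stop("theta must be positive");
  std::vector<double> w;
  double rest = 1.0;
  // residual after k sticks has expectation (theta/(1+theta))^k; cap the
  // atom count defensively far beyond the eps horizon
  int cap = (int)std::min(1e7, 64.0 + 16.0 * (theta + 1.0) * std::log(1.0 / eps));
  for (int k = 0; k < cap && rest >= eps; ++k) {
    double v = R::rbeta(1.0, theta);
    w.push_back(rest * v);
    rest *= (1.0 - v);
  }
  return wrap(w);
}

// Polya-urn realization of J draws from DP(I, base) where base is a
// discrete measure over K atoms (weights need not be normalized). `w` is a
// per-atom acceptance weight (all 1 = neutral): each proposed read of atom
// j is accepted with probability w[j]/max(w), otherwise redrawn with the
// urn unchanged. Returns per-atom counts summing exactly to J.
// [[Rcpp::export]]
IntegerVector polya_urn_cpp(int J, double I, NumericVector atoms,
                            NumericVector w) {
  int K = atoms.size();
  if (K == 0) stop("empty base measure");
  if (I <= 0.0) stop("immigration rate must be positive");
  bool weighted = (w.size() == K);
  std::vector<double> cum(K);
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    if (atoms[k] < 0) stop("negative base weight");
    s += atoms[k];
    cum[k] = s;
  }
  if (s <= 0.0) stop("base measure has zero mass");
  double wmax = 1.0;
  if (weighted) {
    wmax = *std::max_element(w.begin(), w.end());
    if (wmax <= 0.0) stop("acceptance weights must include a positive entry");
  }
  IntegerVector counts(K);
  std::vector<int> reads;
  reads.reserve(J);
  int n = 0;
  while (n < J) {
    int j;
    if (unif_rand() * (I + n) < I) {
      double u = unif_rand() * s;
      j = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (j >= K) j = K - 1;
    } else {
      j = reads[(int)(unif_rand() * n)];
    }
    if (weighted && unif_rand() * wmax >= w[j]) continue;
    reads.push_back(j);
    ++counts[j];
    ++n;
  }
  return counts;
}

// --- slice sampling (Neal 2003, stepping out + shrinkage) in log-parameter
// space for the two non-standard 1-D full conditionals ---

// log target for z = log(theta):
//   p(theta) propto theta^S Gamma(theta)/Gamma(theta+T) Gamma(theta|a,r)
// (the Stirling factor s(T,S) is constant in theta); Jacobian adds +z.
static inline double lp_theta(double z, double S, double T, double shape,
                              double rate) {
  double th = std::exp(z);
  if (!R_finite(th)) return R_NegInf;
  return (S + shape) * z - rate * th + R::lgammafn(th) - R::lgammafn(th + T);
}

// log target for z = log(I):
//   p(I) propto Gamma(I)/Gamma(J+I) I^T Gamma(I|a,r)
static inline double lp_immig(double z, double Ti, double Ji, double shape,
                              double rate) {
  double I = std::exp(z);
  if (!R_finite(I)) return R_NegInf;
  return (Ti + shape) * z - rate * I + R::lgammafn(I) - R::lgammafn(I + Ji);
}

template <typename F>
static double slice_step(double x0, F logf, double width, int maxsteps) {
  double y = logf(x0) - R::exp_rand(); // log slice level
  double u = unif_rand();
  double L = x0 - width * u;
  double Rr = L + width;
  int j = (int)(maxsteps * unif_rand());
  int k = maxsteps - 1 - j;
  while (j-- > 0 && y < logf(L)) L -= width;
  while (k-- > 0 && y < logf(Rr)) Rr += width;
  for (int guard = 0; guard < 1000; ++guard) {
    double x1 = L + unif_rand() * (Rr - L);
    if (y < logf(x1)) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0; // unreachable in practice
}

// [[Rcpp::export]]
double slice_theta_cpp(double theta0, double S, double T, double shape,
                       double rate, int nsteps) {
  double z = std::log(theta0);
  auto f = [&](double zz) { return lp_theta(zz, S, T, shape, rate); };
  for (int i = 0; i < nsteps; ++i) z = slice_step(z, f, 1.0, 50);
  return std::exp(z);
}

// [[Rcpp::export]]
double slice_immig_cpp(double I0, double Ti, double Ji, double shape,
                       double rate, int nsteps) {
  double z = std::log(I0);
  auto f = [&](double zz) { return lp_immig(zz, Ti, Ji, shape, rate); };
  for (int i = 0; i < nsteps; ++i) z = slice_step(z, f, 1.0, 50);
  return std::exp(z);
}

// Full Gibbs sweep over (theta, beta, I, T) for an M x S count matrix.
// Steps per sweep: (a) theta | S, T; (b) beta ~ Dir(T.1..T.S, theta);
// (c) I_i | T_i, J_i; (d) T_ij ~ Antoniak(I_i beta_j, x_ij) via CRP.
// Post-burn-in draws of theta and I are returned in full (for medians and
// credible limits); every `thin`-th post-burn-in sweep is additionally
// stored with its beta row for reuse by the neutrality test.
// [[Rcpp::export]]
List gibbs_msn_cpp(IntegerMatrix x, int n_iter, int n_burnin, int thin,
                   double theta_shape, double theta_rate, double immig_shape,
                   double immig_rate, double theta0, NumericVector I0,
                   NumericVector beta0, IntegerMatrix T0) {
  int M = x.nrow(), S = x.ncol();
  NumericVector J(M);
  for (int i = 0; i < M; ++i) {
    double s = 0.0;
    for (int j = 0; j < S; ++j) s += x(i, j);
    J[i] = s;
  }
  double theta = theta0;
  NumericVector I = clone(I0);
  NumericVector beta = clone(beta0); // length S + 1, last = unrepresented
  IntegerMatrix T = clone(T0);

  int n_post = n_iter - n_burnin;
  int n_stored = n_post / thin;
  NumericVector theta_post(n_post);
  NumericMatrix I_post(n_post, M);
  NumericVector theta_st(n_stored);
  NumericMatrix I_st(n_stored, M);
  NumericMatrix beta_st(n_stored, S + 1);

  for (int it = 1; it <= n_iter; ++it) {
    // (a) biodiversity number
    double Ttot = 0.0;
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < S; ++j) Ttot += T(i, j);
    theta = slice_theta_cpp(theta, (double)S, Ttot, theta_shape, theta_rate, 1);

    // (b) metacommunity relative frequencies
    double gsum = 0.0;
    for (int j = 0; j < S; ++j) {
      double Tc = 0.0;
      for (int i = 0; i < M; ++i) Tc += T(i, j);
      double g = R::rgamma(Tc, 1.0);
      if (g < 1e-300) g = 1e-300;
      beta[j] = g;
      gsum += g;
    }
    double gu = R::rgamma(theta, 1.0);
    if (gu < 1e-300) gu = 1e-300;
    beta[S] = gu;
    gsum += gu;
    for (int j = 0; j <= S; ++j) {
      beta[j] /= gsum;
      if (beta[j] < 1e-300) beta[j] = 1e-300;
    }

    // (c) immigration rates
    for (int i = 0; i < M; ++i) {
      double Ti = 0.0;
      for (int j = 0; j < S; ++j) Ti += T(i, j);
      I[i] = slice_immig_cpp(I[i], Ti, J[i], immig_shape, immig_rate, 1);
    }

    // (d) ancestral counts
    for (int i = 0; i < M; ++i) {
      for (int j = 0; j < S; ++j) {
        int xij = x(i, j);
        if (xij == 0) { T(i, j) = 0; continue; }
        double conc = I[i] * beta[j];
        if (!(conc > 0.0) || !R_finite(conc))
          stop("non-finite CRP concentration at site %d, taxon %d", i + 1,
               j + 1);
        T(i, j) = crp_tables_cpp(xij, conc);
      }
    }

    if (it > n_burnin) {
      int p = it - n_burnin - 1;
      theta_post[p] = theta;
      for (int i = 0; i < M; ++i) I_post(p, i) = I[i];
      if ((it - n_burnin) % thin == 0) {
        int q = (it - n_burnin) / thin - 1;
        theta_st[q] = theta;
        for (int i = 0; i < M; ++i) I_st(q, i) = I[i];
        for (int j = 0; j <= S; ++j) beta_st(q, j) = beta[j];
      }
    }
  }

  return List::create(_["theta_post"] = theta_post, _["I_post"] = I_post,
                      _["theta_stored"] = theta_st, _["I_stored"] = I_st,
                      _["beta_stored"] = beta_st, _["T_final"] = T);
}

// Forward Moran dynamic of the local-community neutral model: at each
// event a random individual dies and is replaced by a metacommunity
// immigrant with probability m, otherwise by the offspring of a randomly
// chosen surviving local individual. Community initialized iid from the
// metacommunity SAD; returns per-taxon counts after n_events deaths.
// [[Rcpp::export]]
IntegerVector forward_hubbell_cpp(int N, double m, NumericVector meta,
                                  int n_events) {
  int K = meta.size();
  if (N < 2) stop("N must be at least 2");
  if (m <= 0.0 || m > 1.0) stop("m must lie in (0, 1]");
  std::vector<double> cum(K);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { s += meta[k]; cum[k] = s; }
  if (s <= 0.0) stop("metacommunity SAD has zero mass");
  std::vector<int> comm(N);
  for (int i = 0; i < N; ++i) {
    double u = unif_rand() * s;
    int j = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
    comm[i] = j >= K ? K - 1 : j;
  }
  for (int e = 0; e < n_events; ++e) {
    int d = (int)(unif_rand() * N);
    if (unif_rand() < m) {
      double u = unif_rand() * s;
      int j = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
      comm[d] = j >= K ? K - 1 : j;
    } else {
      int p;
      do { p = (int)(unif_rand() * N); } while (p == d);
      comm[d] = comm[p];
    }
  }
  IntegerVector counts(K);
  for (int i = 0; i < N; ++i) ++counts[comm[i]];
  return counts;
}
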