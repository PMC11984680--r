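// Constrained least-squares machinery for single-shell 3-tissue CSD.
// Per voxel the joint problem min ||A x - s||^2 over x = (FOD SH
// coefficients, w_GM, w_CSF) subject to FOD amplitude >= 0 on a dense
// direction grid and w_GM, w_CSF >= 0 is solved exactly by the Lawson-
// Hanson LSI -> LDP -> NNLS reduction. A tiny ridge on the FOD l = 0
// coefficient acts as the deterministic tie-break for the single-shell
// isotropic degeneracy (a GM unit is exactly mimicked by a non-negative
// WM-FOD pedestal + CSF combination; the ridge selects the
// minimal-pedestal, i.e. maximal-GM, point of the optimal set).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Precomputed LSI reduction for min ||A x - s|| s.t. C x >= 0 with a
// voxel-independent operator A and constraint matrix C (Lawson & Hanson
// LSI -> LDP -> NNLS). Per voxel only the data vector changes.
struct LsiPre {
  mat Qt;    // n x nrow(A): economy Q^T
  mat Rinv;  // n x n
  mat G;     // m x n: C R^{-1}
};

static LsiPre lsi_precompute(const mat& A, const mat& C) {
  LsiPre pre;
  mat Q, R;
  qr_econ(Q, R, A);
  pre.Qt = Q.t();
  if (!inv(pre.Rinv, trimatu(R))) pre.Rinv = pinv(R);
  pre.G = C * pre.Rinv;
  return pre;
}

// NNLS on the implicit LDP matrix E = [G^T; h^T] with target (0,...,0,1)
static vec ldp_nnls(const mat& G, const vec& h, int max_iter) {
  const uword n = G.n_cols, m = G.n_rows;
  vec u = zeros<vec>(m);
  std::vector<char> passive(m, 0);
  vec r = zeros<vec>(n + 1);
  r(n) = 1.0; // residual b - E u, b = e_{n+1}
  std::vector<uword> pidx;
  pidx.reserve(n + 2);
  for (int it = 0; it < max_iter; ++it) {
    // gradient E^T r = G r_head + h r_n
    vec wgrad = G * r.head(n) + h * r(n);
    int best = -1;
    double wmax = 1e-10;
    for (uword j = 0; j < m; ++j)
      if (!passive[j] && wgrad(j) > wmax) { wmax = wgrad(j); best = j; }
    if (best < 0) break;
    passive[best] = 1;
    for (int inner = 0; inner < max_iter; ++inner) {
      pidx.clear();
      for (uword j = 0; j < m; ++j) if (passive[j]) pidx.push_back(j);
      mat Ep(n + 1, pidx.size());
      for (size_t k = 0; k < pidx.size(); ++k) {
        Ep.col(k).head(n) = G.row(pidx[k]).t();
        Ep(n, k) = h(pidx[k]);
      }
      vec b = zeros<vec>(n + 1);
      b(n) = 1.0;
      vec z;
      if (!solve(z, Ep, b, solve_opts::fast + solve_opts::allow_ugly))
        z = pinv(Ep) * b;
      if (z.min() > 0) {
        u.zeros();
        for (size_t k = 0; k < pidx.size(); ++k) u(pidx[k]) = z(k);
        break;
      }
      double alpha = datum::inf;
      for (size_t k = 0; k < pidx.size(); ++k)
        if (z(k) <= 0) {
          double a = u(pidx[k]) / (u(pidx[k]) - z(k));
          if (a < alpha) alpha = a;
        }
      if (!std::isfinite(alpha)) alpha = 0;
      for (size_t k = 0; k < pidx.size(); ++k) {
        double nu = u(pidx[k]) + alpha * (z(k) - u(pidx[k]));
        u(pidx[k]) = nu;
        if (nu <= 1e-12) { passive[pidx[k]] = 0; u(pidx[k]) = 0; }
      }
    }
    // residual r = b - E u
    r.head(n) = -(G.t() * u);
    r(n) = 1.0 - dot(h, u);
    double rn = dot(r, r);
    if (rn < 1e-24) break;
  }
  return u;
}

static vec lsi_solve(const LsiPre& pre, const vec& s, int max_iter) {
  const uword n = pre.Rinv.n_cols;
  vec f = pre.Qt * s;
  vec h = -(pre.G * f);
  vec u = ldp_nnls(pre.G, h, max_iter);
  vec r(n + 1);
  r.head(n) = -(pre.G.t() * u);
  r(n) = 1.0 - dot(h, u);
  double rn1 = -r(n); // E u - b last component = -r(n)... keep sign below
  // w_i = -(Eu - b)_i / (Eu - b)_n ; (Eu - b) = -r
  vec w(n);
  if (std::abs(r(n)) < 1e-14) {
    w.zeros();
    return pre.Rinv * w;
  }
  for (uword i = 0; i < n; ++i) w(i) = -(-r(i)) / (-r(n));
  (void)rn1;
  vec y = w + f;
  return pre.Rinv * y;
}

// generic one-off interface (used for the response template and tests)
static vec solve_nonneg_ls(const mat& A, const vec& s, const mat& Ccon,
                           double eps, int max_iter) {
  (void)eps;
  LsiPre pre = lsi_precompute(A, Ccon);
  return lsi_solve(pre, s, max_iter > 300 ? max_iter : 300);
}

// exact non-negative least squares for <= 3 columns by support enumeration
static vec nnls_enum(const mat& A, const vec& s) {
  const uword p = A.n_cols;
  vec best = zeros<vec>(p);
  double best_rss = dot(s, s);
  const uword nsub = 1u << p;
  for (uword m = 1; m < nsub; ++m) {
    uvec cols;
    for (uword j = 0; j < p; ++j) if (m & (1u << j))
      cols.insert_rows(cols.n_rows, uvec{j});
    mat As = A.cols(cols);
    vec b;
    if (!solve(b, As, s, solve_opts::no_approx)) continue;
    if (b.min() < 0) continue;
    vec r = s - As * b;
    double rss = dot(r, r);
    if (rss < best_rss - 1e-14) {
      best_rss = rss;
      best.zeros();
      for (uword j = 0; j < cols.n_rows; ++j) best(cols(j)) = b(j);
    }
  }
  return best;
}

// exact LSI solve, exported for response-template construction and tests
// [[Rcpp::export]]
arma::vec cpp_solve_lsi(const arma::mat& A, const arma::vec& s,
                        const arma::mat& C, int max_iter = 300) {
  return solve_nonneg_ls(A, s, C, 0.0, max_iter);
}

// real even SH row (matches the R basis); minimal copy for rotations
static void sh_row_even(const double* d, int lmax, double* out);

// rotate a zonal (m = 0) coefficient set onto axis v (addition theorem)
static vec rotate_zonal(const vec& zonal, const double* v, int lmax) {
  const int ncoef = (lmax + 1) * (lmax + 2) / 2;
  std::vector<double> y(ncoef);
  sh_row_even(v, lmax, y.data());
  vec out(ncoef);
  int j = 0, zi = 0;
  for (int l = 0; l <= lmax; l += 2, ++zi) {
    double f = std::sqrt(4.0 * arma::datum::pi / (2.0 * l + 1.0)) * zonal(zi);
    for (int m = -l; m <= l; ++m, ++j) out(j) = f * y[j];
  }
  return out;
}

// Stage 1: joint constrained LS (FOD + w_GM + w_CSF, ridge tie-break),
// which pins the fiber orientation. Stage 2: fit (w_WM, w_GM, w_CSF) by
// exact NNLS against the measured response kernel rotated to the stage-1
// peak (the delta-FOD forward signal) plus the two isotropic columns;
// this keeps the apodized-delta pedestal of the hard-constrained stage-1
// FOD from absorbing the GM compartment. The reported FOD is the
// non-negative single-fiber template FOD scaled so its l = 0 coefficient
// carries exactly w_ICA.
// [[Rcpp::export]]
Rcpp::List cpp_fit_ss3t(const arma::mat& S, const arma::mat& A_wm,
                        const arma::vec& col_gm, const arma::vec& col_csf,
                        const arma::mat& Bcon, double wm_b0, double eps,
                        int max_iter, double f00_ridge,
                        const arma::vec& template_zonal,
                        const arma::mat& Bpeak,
                        const arma::mat& peak_dirs,
                        const arma::vec& shell_zonal,
                        const arma::mat& shell_dirs, int n_b0) {
  const uword nvox = S.n_rows;
  const uword ncoef = A_wm.n_cols;
  const uword nmeas = A_wm.n_rows;
  const double sqrt4pi = std::sqrt(4.0 * arma::datum::pi);
  mat fod(nvox, ncoef, fill::zeros);
  mat w(nvox, 3, fill::zeros); // (w_ICA, w_ICI, w_ECI)

  // joint operator [A_wm | col_gm | col_csf] plus the l = 0 ridge row
  mat A(nmeas + 1, ncoef + 2, fill::zeros);
  A.submat(0, 0, nmeas - 1, ncoef - 1) = A_wm;
  A.col(ncoef).head(nmeas) = col_gm;
  A.col(ncoef + 1).head(nmeas) = col_csf;
  A(nmeas, 0) = f00_ridge * wm_b0 * sqrt4pi;
  // constraints: FOD amplitudes on the dense grid, then w_GM, w_CSF
  mat C(Bcon.n_rows + 2, ncoef + 2, fill::zeros);
  C.submat(0, 0, Bcon.n_rows - 1, ncoef - 1) = Bcon;
  C(Bcon.n_rows, ncoef) = 1.0;
  C(Bcon.n_rows + 1, ncoef + 1) = 1.0;

  LsiPre pre = lsi_precompute(A, C);
  const int lmax = (int)std::round((-3.0 + std::sqrt(1.0 + 8.0 * ncoef)) / 2);
  const int n_zonal = lmax / 2 + 1;
  const uword n_shell = shell_dirs.n_rows;
  // K(l,0) * Z_l factors of the kernel amplitude, even l only
  std::vector<double> zk(n_zonal);
  for (int i = 0; i < n_zonal; ++i)
    zk[i] = std::sqrt((4.0 * (double)i + 1.0) / (4.0 * M_PI)) *
            shell_zonal(i);
  std::vector<double> Pl(2 * n_zonal); // Legendre up to l = lmax
  vec s(nmeas + 1, fill::zeros);
  vec sv(nmeas);
  mat A2(nmeas, 3);
  A2.col(1) = col_gm;
  A2.col(2) = col_csf;
  for (uword v = 0; v < nvox; ++v) {
    sv = S.row(v).t();
    s.head(nmeas) = sv;
    // stage 1: joint constrained fit
    vec x = lsi_solve(pre, s, max_iter > 300 ? max_iter : 300);
    vec f1 = x.subvec(0, ncoef - 1);
    // stage-1 peak on the dense grid
    vec pamp = Bpeak * f1;
    uword ipk = pamp.index_max();
    double vpk[3] = {peak_dirs(ipk, 0), peak_dirs(ipk, 1),
                     peak_dirs(ipk, 2)};
    // stage 2: exact NNLS against the rotated kernel + isotropic columns
    for (int i = 0; i < n_b0; ++i) A2(i, 0) = wm_b0;
    for (uword i = 0; i < n_shell; ++i) {
      double t = shell_dirs(i, 0) * vpk[0] + shell_dirs(i, 1) * vpk[1] +
                 shell_dirs(i, 2) * vpk[2];
      // Legendre recurrence at cos(theta) = t
      Pl[0] = 1.0;
      Pl[1] = t;
      for (int l = 2; l <= lmax; ++l)
        Pl[l] = ((2.0 * l - 1.0) * t * Pl[l - 1] -
                 (l - 1.0) * Pl[l - 2]) / (double)l;
      double val = 0;
      for (int zi = 0; zi < n_zonal; ++zi) val += zk[zi] * Pl[2 * zi];
      A2(n_b0 + i, 0) = val / wm_b0; // normalized: weight in b0 units
    }
    vec x2 = nnls_enum(A2, sv);
    double wica = x2(0);
    // report a non-negative single-fiber FOD carrying w_ICA in its l = 0
    double alpha = (template_zonal(0) > 1e-12)
                       ? wica / (wm_b0 * sqrt4pi * template_zonal(0))
                       : 0.0;
    vec f = alpha * rotate_zonal(template_zonal, vpk, lmax);
    fod.row(v) = f.t();
    w(v, 0) = wica;
    w(v, 1) = x2(1);
    w(v, 2) = x2(2);
  }
  return Rcpp::List::create(Rcpp::Named("fod") = fod, Rcpp::Named("w") = w);
}

// definition for the forward declaration above: same convention as the
// tracking translation unit (duplicated locally; static linkage)
static void sh_row_even(const double* d, int lmax, double* out) {
  const double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  const double ct = d[2] / r;
  const double phi = std::atan2(d[1], d[0]);
  const int np = lmax + 1;
  std::vector<std::vector<double>> P(np, std::vector<double>(np, 0.0));
  P[0][0] = 1.0;
  const double somx2 = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  for (int m = 1; m <= lmax; ++m)
    P[m][m] = P[m - 1][m - 1] * (-(2.0 * m - 1.0)) * somx2;
  for (int m = 0; m < lmax; ++m) {
    P[m + 1][m] = ct * (2.0 * m + 1.0) * P[m][m];
    for (int l = m + 2; l <= lmax; ++l)
      P[l][m] = ((2.0 * l - 1.0) * ct * P[l - 1][m] -
                 (l + m - 1.0) * P[l - 2][m]) / (double)(l - m);
  }
  int j = 0;
  for (int l = 0; l <= lmax; l += 2) {
    for (int m = -l; m <= l; ++m) {
      const int am = std::abs(m);
      double k = std::sqrt((2.0 * l + 1.0) / (4.0 * M_PI) *
                           std::exp(std::lgamma(l - am + 1.0) -
                                    std::lgamma(l + am + 1.0)));
      double val;
      if (m == 0) val = k * P[l][0];
      else if (m > 0) val = std::sqrt(2.0) * k * P[l][am] * std::cos(m * phi);
      else val = std::sqrt(2.0) * k * P[l][am] * std::sin(am * phi);
      out[j++] = val;
    }
  }
}
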