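// Probabilistic streamline propagation on an FOD coefficient field,
// exact segment-voxel traversal, and SIFT-style greedy pruning.
//
// Conventions: the affine maps continuous grid coordinates to world mm,
// voxel i is the half-open box [i, i+1) in grid units (centre i + 0.5).
// All randomness comes from the R RNG, so set.seed() governs everything.

#include <RcppArmadillo.h>
#include <queue>
#include <vector>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------- real SH

#define SH_MAX_L 16

// real even SH row at a unit direction; matches the R basis (Condon-
// Shortley phase inside P_l^m, sqrt(2) on |m| > 0 terms). Stack buffers
// only: this sits in the tracking inner loop.
static void sh_row(double x, double y, double z, int lmax, double* out) {
  const double r = std::sqrt(x * x + y * y + z * z);
  const double ct = z / r;
  const double phi = std::atan2(y, x);
  // associated Legendre table P[l][m]
  double P[SH_MAX_L + 1][SH_MAX_L + 1] = {{0.0}};
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
  // normalization constants, computed once per lmax
  static thread_local double K[SH_MAX_L + 1][SH_MAX_L + 1];
  static thread_local int K_lmax = -1;
  if (K_lmax < lmax) {
    for (int l = 0; l <= lmax; ++l)
      for (int m = 0; m <= l; ++m)
        K[l][m] = std::sqrt((2.0 * l + 1.0) / (4.0 * M_PI) *
                            std::exp(std::lgamma(l - m + 1.0) -
                                     std::lgamma(l + m + 1.0)));
    K_lmax = lmax;
  }
  double cm[SH_MAX_L + 1], sm[SH_MAX_L + 1];
  const double cp = std::cos(phi), sp = std::sin(phi);
  cm[0] = 1.0; sm[0] = 0.0;
  for (int m = 1; m <= lmax; ++m) {
    cm[m] = cm[m - 1] * cp - sm[m - 1] * sp;
    sm[m] = sm[m - 1] * cp + cm[m - 1] * sp;
  }
  const double sq2 = std::sqrt(2.0);
  int j = 0;
  for (int l = 0; l <= lmax; l += 2) {
    for (int m = -l; m <= l; ++m) {
      const int am = std::abs(m);
      double v;
      if (m == 0) v = K[l][0] * P[l][0];
      else if (m > 0) v = sq2 * K[l][am] * P[l][am] * cm[am];
      else v = sq2 * K[l][am] * P[l][am] * sm[am];
      out[j++] = v;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sh_eval(const NumericMatrix& dirs, int lmax) {
  const int n = dirs.nrow();
  const int nc = (lmax + 1) * (lmax + 2) / 2;
  NumericMatrix out(n, nc);
  std::vector<double> row(nc);
  for (int i = 0; i < n; ++i) {
    sh_row(dirs(i, 0), dirs(i, 1), dirs(i, 2), lmax, row.data());
    for (int j = 0; j < nc; ++j) out(i, j) = row[j];
  }
  return out;
}

// ------------------------------------------------------------ field access

struct Field {
  const double* coef; // nvox x ncoef, voxel-major (R array layout)
  const int* mask;
  int nx, ny, nz, ncoef;
  long nvox;
  // world -> grid
  arma::mat33 Minv;
  arma::vec3 tinv;

  inline void world_to_grid(const double* p, double* g) const {
    for (int i = 0; i < 3; ++i)
      g[i] = Minv(i, 0) * (p[0] - tinv(0)) + Minv(i, 1) * (p[1] - tinv(1)) +
             Minv(i, 2) * (p[2] - tinv(2));
  }
  inline bool in_mask(const double* g) const {
    int i = (int)std::floor(g[0]), j = (int)std::floor(g[1]),
        k = (int)std::floor(g[2]);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      return false;
    return mask[(long)i + nx * ((long)j + (long)ny * k)] != 0;
  }
  // trilinear interpolation of coefficients at grid coordinate g
  inline void interp(const double* g, double* out) const {
    double xf = g[0] - 0.5, yf = g[1] - 0.5, zf = g[2] - 0.5;
    int i0 = (int)std::floor(xf), j0 = (int)std::floor(yf),
        k0 = (int)std::floor(zf);
    double fx = xf - i0, fy = yf - j0, fz = zf - k0;
    if (i0 < 0) { i0 = 0; fx = 0; } if (i0 > nx - 2) { i0 = nx - 2; fx = 1; }
    if (j0 < 0) { j0 = 0; fy = 0; } if (j0 > ny - 2) { j0 = ny - 2; fy = 1; }
    if (k0 < 0) { k0 = 0; fz = 0; } if (k0 > nz - 2) { k0 = nz - 2; fz = 1; }
    if (nx == 1) { i0 = 0; fx = 0; }
    if (ny == 1) { j0 = 0; fy = 0; }
    if (nz == 1) { k0 = 0; fz = 0; }
    for (int c = 0; c < ncoef; ++c) out[c] = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          int ii = std::min(i0 + di, nx - 1);
          int jj = std::min(j0 + dj, ny - 1);
          int kk = std::min(k0 + dk, nz - 1);
          double wgt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                       (dk ? fz : 1 - fz);
          if (wgt <= 0) continue;
          const double* base =
              coef + ((long)ii + nx * ((long)jj + (long)ny * kk));
          for (int c = 0; c < ncoef; ++c) out[c] += wgt * base[(long)c * nvox];
        }
  }
};

static inline double dot_n(const double* a, const double* b, int n) {
  double s = 0;
  for (int i = 0; i < n; ++i) s += a[i] * b[i];
  return s;
}

// orthonormal frame perpendicular to d
static inline void make_frame(const double* d, double* e1, double* e2) {
  double ax = std::abs(d[0]), ay = std::abs(d[1]), az = std::abs(d[2]);
  double up[3] = {0, 0, 0};
  if (ax <= ay && ax <= az) up[0] = 1;
  else if (ay <= az) up[1] = 1;
  else up[2] = 1;
  e1[0] = d[1] * up[2] - d[2] * up[1];
  e1[1] = d[2] * up[0] - d[0] * up[2];
  e1[2] = d[0] * up[1] - d[1] * up[0];
  double n1 = std::sqrt(dot_n(e1, e1, 3));
  for (int i = 0; i < 3; ++i) e1[i] /= n1;
  e2[0] = d[1] * e1[2] - d[2] * e1[1];
  e2[1] = d[2] * e1[0] - d[0] * e1[2];
  e2[2] = d[0] * e1[1] - d[1] * e1[0];
}

// draw a direction uniformly within the cone of half-angle alpha around d
static inline void cone_sample(const double* d, double cos_alpha,
                               double* out) {
  double e1[3], e2[3];
  make_frame(d, e1, e2);
  double ct = 1.0 - R::runif(0, 1) * (1.0 - cos_alpha);
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double ph = R::runif(0, 1) * 2.0 * M_PI;
  for (int i = 0; i < 3; ++i)
    out[i] = ct * d[i] + st * (std::cos(ph) * e1[i] + std::sin(ph) * e2[i]);
}

struct TrackParams {
  double step, cos_alpha, cutoff, min_len, max_len;
};

// sample the next direction by rejection sampling proportional to the FOD
// amplitude within the cone; returns false on termination
static bool next_direction(const Field& F, const double* coefs,
                           const double* dir, const TrackParams& P,
                           int lmax, double* out, double* row) {
  const int NPROBE = 12, NTRY = 64;
  double cand[3];
  double amax = 0;
  double probes[NPROBE][3];
  for (int i = 0; i < NPROBE; ++i) {
    cone_sample(dir, P.cos_alpha, probes[i]);
    sh_row(probes[i][0], probes[i][1], probes[i][2], lmax, row);
    double a = dot_n(row, coefs, F.ncoef);
    if (a > amax) amax = a;
  }
  if (amax < P.cutoff) return false;
  double bound = 1.3 * amax;
  for (int t = 0; t < NTRY; ++t) {
    cone_sample(dir, P.cos_alpha, cand);
    sh_row(cand[0], cand[1], cand[2], lmax, row);
    double a = dot_n(row, coefs, F.ncoef);
    if (a >= P.cutoff && R::runif(0, 1) * bound <= a) {
      for (int i = 0; i < 3; ++i) out[i] = cand[i];
      return true;
    }
  }
  return false;
}

// grow one side from `seed` along `dir0`, appending world points to pts
static void grow(const Field& F, const double* seed, const double* dir0,
                 const TrackParams& P, int lmax, int max_steps,
                 std::vector<double>& pts) {
  double p[3] = {seed[0], seed[1], seed[2]};
  double dir[3] = {dir0[0], dir0[1], dir0[2]};
  double g[3], nd[3];
  std::vector<double> coefs(F.ncoef), row(F.ncoef);
  for (int s = 0; s < max_steps; ++s) {
    F.world_to_grid(p, g);
    F.interp(g, coefs.data());
    if (!next_direction(F, coefs.data(), dir, P, lmax, nd, row.data()))
      break;
    double q[3] = {p[0] + P.step * nd[0], p[1] + P.step * nd[1],
                   p[2] + P.step * nd[2]};
    F.world_to_grid(q, g);
    if (!F.in_mask(g)) break;
    pts.insert(pts.end(), q, q + 3);
    for (int i = 0; i < 3; ++i) { p[i] = q[i]; dir[i] = nd[i]; }
  }
}

// [[Rcpp::export]]
List cpp_propagate_batch(NumericVector coef, IntegerVector dims, int ncoef,
                         IntegerVector mask, NumericMatrix affine,
                         NumericMatrix seeds, List params,
                         NumericMatrix B300, NumericMatrix dirs300) {
  Field F;
  F.coef = REAL(coef);
  F.mask = INTEGER(mask);
  F.nx = dims[0]; F.ny = dims[1]; F.nz = dims[2];
  F.ncoef = ncoef;
  F.nvox = (long)F.nx * F.ny * F.nz;
  arma::mat44 A;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) A(i, j) = affine(i, j);
  F.Minv = arma::inv(arma::mat33(A.submat(0, 0, 2, 2)));
  F.tinv = A.submat(0, 3, 2, 3);

  TrackParams P;
  P.step = as<double>(params["step_size"]);
  P.cos_alpha = std::cos(as<double>(params["max_angle"]) * M_PI / 180.0);
  P.cutoff = as<double>(params["cutoff"]);
  P.min_len = as<double>(params["min_length"]);
  P.max_len = as<double>(params["max_length"]);
  const int lmax = (int)std::round((-3.0 + std::sqrt(1.0 + 8.0 * ncoef)) / 2);
  const int max_steps_total = (int)std::floor(P.max_len / P.step);

  const int nseed = seeds.nrow();
  const int n300 = dirs300.nrow();
  std::vector<double> coefs(F.ncoef), amp(n300);
  List out(nseed);
  LogicalVector accepted(nseed);
  RNGScope scope;
  for (int sidx = 0; sidx < nseed; ++sidx) {
    double seed[3] = {seeds(sidx, 0), seeds(sidx, 1), seeds(sidx, 2)};
    double g[3];
    F.world_to_grid(seed, g);
    accepted[sidx] = false;
    if (!F.in_mask(g)) { out[sidx] = R_NilValue; continue; }
    F.interp(g, coefs.data());
    // initial direction ~ FOD amplitude on the dense direction set
    double tot = 0;
    for (int i = 0; i < n300; ++i) {
      double a = 0;
      for (int c = 0; c < F.ncoef; ++c) a += B300(i, c) * coefs[c];
      amp[i] = (a >= P.cutoff) ? a : 0.0;
      tot += amp[i];
    }
    if (tot <= 0) { out[sidx] = R_NilValue; continue; }
    double u = R::runif(0, 1) * tot, acc = 0;
    int pick = n300 - 1;
    for (int i = 0; i < n300; ++i) {
      acc += amp[i];
      if (u <= acc) { pick = i; break; }
    }
    double d0[3] = {dirs300(pick, 0), dirs300(pick, 1), dirs300(pick, 2)};
    std::vector<double> fwd, bwd;
    grow(F, seed, d0, P, lmax, max_steps_total, fwd);
    double d0n[3] = {-d0[0], -d0[1], -d0[2]};
    int remaining = max_steps_total - (int)(fwd.size() / 3);
    grow(F, seed, d0n, P, lmax, remaining, bwd);
    const int nf = fwd.size() / 3, nb = bwd.size() / 3;
    const int npts = nf + nb + 1;
    double len = (npts - 1) * P.step;
    if (len < P.min_len) { out[sidx] = R_NilValue; continue; }
    NumericMatrix pts(npts, 3);
    for (int i = 0; i < nb; ++i)          // backward side, reversed
      for (int j = 0; j < 3; ++j) pts(i, j) = bwd[3 * (nb - 1 - i) + j];
    for (int j = 0; j < 3; ++j) pts(nb, j) = seed[j];
    for (int i = 0; i < nf; ++i)
      for (int j = 0; j < 3; ++j) pts(nb + 1 + i, j) = fwd[3 * i + j];
    out[sidx] = pts;
    accepted[sidx] = true;
  }
  return List::create(Named("streamlines") = out,
                      Named("accepted") = accepted);
}

// -------------------------------------------------- segment-voxel traversal

// exact Amanatides-Woo traversal of one segment in grid coordinates
static void traverse_segment(const double* g0, const double* g1,
                             std::vector<long>& out, int nx, int ny, int nz) {
  double d[3] = {g1[0] - g0[0], g1[1] - g0[1], g1[2] - g0[2]};
  int v[3] = {(int)std::floor(g0[0]), (int)std::floor(g0[1]),
              (int)std::floor(g0[2])};
  const int vend[3] = {(int)std::floor(g1[0]), (int)std::floor(g1[1]),
                       (int)std::floor(g1[2])};
  int stp[3];
  double tMax[3], tDelta[3];
  for (int i = 0; i < 3; ++i) {
    if (d[i] > 0) {
      stp[i] = 1;
      tDelta[i] = 1.0 / d[i];
      tMax[i] = ((std::floor(g0[i]) + 1.0) - g0[i]) / d[i];
    } else if (d[i] < 0) {
      stp[i] = -1;
      tDelta[i] = -1.0 / d[i];
      tMax[i] = (g0[i] - std::floor(g0[i])) / (-d[i]);
      if (g0[i] == std::floor(g0[i])) tMax[i] = 0.0; // on lower face
    } else {
      stp[i] = 0;
      tDelta[i] = std::numeric_limits<double>::infinity();
      tMax[i] = std::numeric_limits<double>::infinity();
    }
  }
  const int dims[3] = {nx, ny, nz};
  auto push = [&](const int* vv) {
    if (vv[0] >= 0 && vv[1] >= 0 && vv[2] >= 0 && vv[0] < nx && vv[1] < ny &&
        vv[2] < nz)
      out.push_back((long)vv[0] + nx * ((long)vv[1] + (long)ny * vv[2]));
  };
  push(v);
  int guard = 4 * (nx + ny + nz) + 12;
  while ((v[0] != vend[0] || v[1] != vend[1] || v[2] != vend[2]) &&
         guard-- > 0) {
    int ax = 0;
    if (tMax[1] < tMax[ax]) ax = 1;
    if (tMax[2] < tMax[ax]) ax = 2;
    if (tMax[ax] > 1.0) break; // remaining crossings beyond the segment end
    v[ax] += stp[ax];
    tMax[ax] += tDelta[ax];
    push(v);
    (void)dims;
  }
}

// [[Rcpp::export]]
List cpp_streamline_voxels(NumericMatrix coords, IntegerVector offsets,
                           NumericMatrix affine, IntegerVector dims) {
  arma::mat44 A;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) A(i, j) = affine(i, j);
  arma::mat33 Minv = arma::inv(arma::mat33(A.submat(0, 0, 2, 2)));
  arma::vec3 t = A.submat(0, 3, 2, 3);
  const int n = offsets.size() - 1;
  List out(n);
  std::vector<long> vox;
  for (int s = 0; s < n; ++s) {
    vox.clear();
    const int a = offsets[s], b = offsets[s + 1];
    double gprev[3], gcur[3];
    for (int i = a; i < b; ++i) {
      double p[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
      for (int k = 0; k < 3; ++k)
        gcur[k] = Minv(k, 0) * (p[0] - t(0)) + Minv(k, 1) * (p[1] - t(1)) +
                  Minv(k, 2) * (p[2] - t(2));
      if (i > a)
        traverse_segment(gprev, gcur, vox, dims[0], dims[1], dims[2]);
      else if (b - a == 1) { // single point: its own voxel
        double tmp[3] = {gcur[0], gcur[1], gcur[2]};
        traverse_segment(tmp, tmp, vox, dims[0], dims[1], dims[2]);
      }
      for (int k = 0; k < 3; ++k) gprev[k] = gcur[k];
    }
    std::sort(vox.begin(), vox.end());
    vox.erase(std::unique(vox.begin(), vox.end()), vox.end());
    IntegerVector iv(vox.size());
    for (size_t i = 0; i < vox.size(); ++i) iv[i] = (int)vox[i];
    out[s] = iv;
  }
  return out;
}

// ----------------------------------------------------------------- SIFT

// greedy removal: cost = sum_v (mu TD(v) - A(v))^2 over voxels visited by
// the input tractogram; each removal deletes the streamline whose removal
// most decreases the cost; mu is refit after each batch of removals
// [[Rcpp::export]]
List cpp_sift(List vox_lists, NumericVector amp_full, int keep,
              int batch = 25) {
  const int n = vox_lists.size();
  std::vector<std::vector<int>> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = as<std::vector<int>>(vox_lists[i]);

  // compact voxel indexing over the union of visited voxels
  std::vector<int> all;
  for (auto& v : sv) all.insert(all.end(), v.begin(), v.end());
  std::sort(all.begin(), all.end());
  all.erase(std::unique(all.begin(), all.end()), all.end());
  const int nv = all.size();
  auto vid = [&](int vox) {
    return (int)(std::lower_bound(all.begin(), all.end(), vox) - all.begin());
  };
  std::vector<double> A(nv);
  for (int i = 0; i < nv; ++i) A[i] = amp_full[all[i]];
  std::vector<int> TD(nv, 0);
  for (auto& v : sv)
    for (auto& x : v) {
      x = vid(x);
      TD[x] += 1;
    }

  auto fit_mu = [&]() {
    double num = 0, den = 0;
    for (int i = 0; i < nv; ++i) {
      num += A[i] * TD[i];
      den += (double)TD[i] * TD[i];
    }
    return den > 0 ? num / den : 0.0;
  };
  double mu = fit_mu();
  std::vector<double> r(nv);
  auto refresh_r = [&]() {
    for (int i = 0; i < nv; ++i) r[i] = mu * TD[i] - A[i];
  };
  refresh_r();
  auto cost_now = [&]() {
    double c = 0;
    for (int i = 0; i < nv; ++i) c += r[i] * r[i];
    return c;
  };
  auto delta_of = [&](int j) {
    double d = 0;
    for (int v : sv[j]) d += mu * mu - 2.0 * mu * r[v];
    return d;
  };

  std::vector<char> alive(n, 1);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> heap;
  auto rebuild = [&]() {
    heap = decltype(heap)();
    for (int j = 0; j < n; ++j)
      if (alive[j]) heap.push({delta_of(j), j});
  };
  rebuild();

  const int n_remove = n - keep;
  NumericVector costs(n_remove + 1);
  costs[0] = cost_now();
  for (int m = 0; m < n_remove; ++m) {
    // lazy best-first: pop until the top's stored key matches a fresh one
    int pick = -1;
    while (!heap.empty()) {
      Node top = heap.top();
      heap.pop();
      if (!alive[top.second]) continue;
      double fresh = delta_of(top.second);
      if (fresh <= top.first + 1e-12) { pick = top.second; break; }
      heap.push({fresh, top.second});
    }
    if (pick < 0) break;
    alive[pick] = 0;
    for (int v : sv[pick]) {
      TD[v] -= 1;
      r[v] -= mu;
    }
    if ((m + 1) % batch == 0) {
      mu = fit_mu();
      refresh_r();
      rebuild();
    }
    costs[m + 1] = cost_now();
  }
  LogicalVector kept(n);
  for (int j = 0; j < n; ++j) kept[j] = alive[j] == 1;
  return List::create(Named("kept") = kept, Named("cost") = costs,
                      Named("mu") = mu);
}
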