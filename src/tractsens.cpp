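// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Marchenko-Pastur PCA denoising core.
//
// For each sliding patch (edge 2r+1, optionally strided; clamped inside the
// grid so every voxel is covered), form the M x N patch matrix X (M voxels,
// N volumes), eigendecompose C = X'X / M, and classify the smallest c
// eigenvalues as noise when their spread fits under the Marchenko-Pastur
// support width:
//     e[c-1] - e[0] < 4 * sqrt(c / M) * mean(e[0..c-1])
// (the MP law for pure noise with aspect ratio gamma = c/M has support width
// 4 sigma^2 sqrt(gamma) and mean sigma^2). The largest c satisfying the
// inequality is taken; sigma^2 is estimated as the mean of the classified
// eigenvalues, and the patch is reconstructed from the remaining (signal)
// components. Overlapping patch estimates are aggregated by averaging.
//
// [[Rcpp::export]]
List mppca_cpp(NumericVector signal, IntegerVector dims, int radius, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nvol = dims[3];
  const int edge = 2 * radius + 1;
  const int M = edge * edge * edge;
  if (nx < edge || ny < edge || nz < edge)
    stop("patch (edge %d) does not fit the %dx%dx%d grid", edge, nx, ny, nz);

  const double *sig = signal.begin();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;

  std::vector<double> acc(nvox * (R_xlen_t)nvol, 0.0);
  std::vector<double> cnt(nvox, 0.0);
  std::vector<double> sig_acc(nvox, 0.0);
  std::vector<double> sig_cnt(nvox, 0.0);

  // patch-center positions per axis (0-based), clamped, last included
  auto centers = [&](int n) {
    std::vector<int> c;
    for (int p = radius; p <= n - 1 - radius; p += stride) c.push_back(p);
    if (c.back() != n - 1 - radius) c.push_back(n - 1 - radius);
    return c;
  };
  std::vector<int> cxs = centers(nx), cys = centers(ny), czs = centers(nz);

  arma::mat X(M, nvol);
  std::vector<R_xlen_t> vidx(M);

  for (int cz : czs) for (int cy : cys) for (int cx : cxs) {
    int m = 0;
    for (int dz = -radius; dz <= radius; ++dz)
      for (int dy = -radius; dy <= radius; ++dy)
        for (int dx = -radius; dx <= radius; ++dx) {
          R_xlen_t v = (R_xlen_t)(cx + dx) + (R_xlen_t)nx * ((cy + dy) + (R_xlen_t)ny * (cz + dz));
          vidx[m++] = v;
        }
    for (int t = 0; t < nvol; ++t) {
      const double *col = sig + (R_xlen_t)t * nvox;
      for (int i = 0; i < M; ++i) X(i, t) = col[vidx[i]];
    }
    arma::mat C = (X.t() * X) / (double)M;
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, C);              // ascending

    int best_c = 0;
    double csum = 0.0;
    for (int c = 1; c <= nvol; ++c) {
      csum += eval[c - 1];
      double mean_e = csum / c;
      double spread = eval[c - 1] - eval[0];
      if (spread < 4.0 * std::sqrt((double)c / M) * mean_e) best_c = c;
    }
    double sigma2 = 0.0;
    if (best_c > 0) {
      double s = 0.0;
      for (int c = 0; c < best_c; ++c) s += eval[c];
      sigma2 = s / best_c;
    }
    double sigma = sigma2 > 0 ? std::sqrt(sigma2) : 0.0;

    arma::mat Xhat;
    if (best_c == 0) {
      Xhat = X;
    } else if (best_c == nvol) {
      Xhat.zeros(M, nvol);
    } else {
      arma::mat Vs = evec.cols(best_c, nvol - 1);
      Xhat = X * Vs * Vs.t();
    }
    for (int t = 0; t < nvol; ++t) {
      double *col = acc.data() + (R_xlen_t)t * nvox;
      for (int i = 0; i < M; ++i) col[vidx[i]] += Xhat(i, t);
    }
    for (int i = 0; i < M; ++i) {
      cnt[vidx[i]] += 1.0;
      sig_acc[vidx[i]] += sigma;
      sig_cnt[vidx[i]] += 1.0;
    }
  }

  NumericVector out((R_xlen_t)nvox * nvol);
  for (int t = 0; t < nvol; ++t) {
    const double *ac = acc.data() + (R_xlen_t)t * nvox;
    double *oc = out.begin() + (R_xlen_t)t * nvox;
    for (R_xlen_t i = 0; i < nvox; ++i) oc[i] = cnt[i] > 0 ? ac[i] / cnt[i] : sig[(R_xlen_t)t * nvox + i];
  }
  NumericVector sigma_map(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i)
    sigma_map[i] = sig_cnt[i] > 0 ? sig_acc[i] / sig_cnt[i] : NA_REAL;

  out.attr("dim") = dims;
  sigma_map.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(_["denoised"] = out, _["sigma"] = sigma_map);
}

// Batched solve of per-voxel weighted normal equations: row v of `lhs`
// holds the p x p matrix (column-major), row v of `rhs` the p-vector.
// Returns the p x nvox coefficient matrix and a success flag per voxel.
// [[Rcpp::export]]
List wlls_solve_cpp(NumericMatrix lhs, NumericMatrix rhs) {
  const int nvox = lhs.nrow();
  const int p = rhs.ncol();
  NumericMatrix coef(p, nvox);
  LogicalVector ok(nvox);
  arma::mat m(p, p);
  arma::vec b(p), x(p);
  for (int v = 0; v < nvox; ++v) {
    for (int j = 0; j < p * p; ++j) m(j % p, j / p) = lhs(v, j);
    for (int j = 0; j < p; ++j) b(j) = rhs(v, j);
    bool good = arma::solve(x, m, b, arma::solve_opts::no_approx);
    ok[v] = good && x.is_finite();
    if (ok[v]) for (int j = 0; j < p; ++j) coef(j, v) = x(j);
  }
  return List::create(_["coef"] = coef, _["ok"] = ok);
}

// Catmull-Rom cubic kernel weights for fractional offset t in [0,1)
static inline void cr_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = -0.5 * t3 + t2 - 0.5 * t;
  w[1] = 1.5 * t3 - 2.5 * t2 + 1.0;
  w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
  w[3] = 0.5 * t3 - 0.5 * t2;
}

// Resample a 3D volume under a pull-back affine in 1-based voxel coordinates:
// value(out) = vol(A %*% out + b); order 3 = tricubic Catmull-Rom (default),
// order 1 = trilinear (used for coarse search stages); edge-clamped
// neighbours, fully outside -> 0.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector vol, NumericMatrix A, NumericVector b,
                                  int order = 3) {
  IntegerVector dims = vol.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *src = vol.begin();
  NumericVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = dims;

  auto clampi = [](int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); };

  for (int k = 1; k <= nz; ++k)
    for (int j = 1; j <= ny; ++j)
      for (int i = 1; i <= nx; ++i) {
        double xi = A(0,0)*i + A(0,1)*j + A(0,2)*k + b[0];
        double yj = A(1,0)*i + A(1,1)*j + A(1,2)*k + b[1];
        double zk = A(2,0)*i + A(2,1)*j + A(2,2)*k + b[2];
        R_xlen_t oidx = (R_xlen_t)(i - 1) + (R_xlen_t)nx * ((j - 1) + (R_xlen_t)ny * (k - 1));
        if (xi < 0.5 || xi > nx + 0.5 || yj < 0.5 || yj > ny + 0.5 ||
            zk < 0.5 || zk > nz + 0.5) {
          out[oidx] = 0.0;
          continue;
        }
        int fx = (int)std::floor(xi), fy = (int)std::floor(yj), fz = (int)std::floor(zk);
        double tx = xi - fx, ty = yj - fy, tz = zk - fz;
        if (order == 1) {
          double val = 0.0;
          for (int dz = 0; dz <= 1; ++dz) {
            int zz = clampi(fz + dz, 1, nz);
            double wzz = dz ? tz : 1.0 - tz;
            for (int dy = 0; dy <= 1; ++dy) {
              int yy = clampi(fy + dy, 1, ny);
              double wyy = (dy ? ty : 1.0 - ty) * wzz;
              for (int dx = 0; dx <= 1; ++dx) {
                int xx = clampi(fx + dx, 1, nx);
                val += (dx ? tx : 1.0 - tx) * wyy *
                  src[(R_xlen_t)(xx - 1) + (R_xlen_t)nx * ((yy - 1) + (R_xlen_t)ny * (zz - 1))];
              }
            }
          }
          out[oidx] = val;
          continue;
        }
        double wx[4], wy[4], wz[4];
        cr_weights(tx, wx); cr_weights(ty, wy); cr_weights(tz, wz);
        double val = 0.0;
        for (int dz = -1; dz <= 2; ++dz) {
          int zz = clampi(fz + dz, 1, nz);
          double wzz = wz[dz + 1];
          if (wzz == 0.0) continue;
          for (int dy = -1; dy <= 2; ++dy) {
            int yy = clampi(fy + dy, 1, ny);
            double wyy = wy[dy + 1] * wzz;
            double row = 0.0;
            for (int dx = -1; dx <= 2; ++dx) {
              int xx = clampi(fx + dx, 1, nx);
              row += wx[dx + 1] * src[(R_xlen_t)(xx - 1) + (R_xlen_t)nx * ((yy - 1) + (R_xlen_t)ny * (zz - 1))];
            }
            val += wyy * row;
          }
        }
        out[oidx] = val;
      }
  return out;
}
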