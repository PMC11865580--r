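#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Deterministic quasi-uniform unit-sphere sampling (golden-section spiral).
// A fixed point set makes occlusion monotone: adding atoms can only remove
// accessible sample points, never add them, so dSASA >= 0 holds exactly.
static void golden_spiral(int n, std::vector<double> &sx,
                          std::vector<double> &sy, std::vector<double> &sz) {
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  sx.resize(n); sy.resize(n); sz.resize(n);
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    sx[k] = r * std::cos(phi);
    sy[k] = r * std::sin(phi);
    sz[k] = z;
  }
}

// Shrake-Rupley SASA. coords: m x 3 heavy-atom coordinates (Angstrom),
// radii: per-atom van der Waals radii. Returns per-atom accessible area.
// [[Rcpp::export(name = ".sasa_kernel")]]
NumericVector sasa_kernel(NumericMatrix coords, NumericVector radii,
                          double probe, int n_points) {
  int m = coords.nrow();
  std::vector<double> sx, sy, sz;
  golden_spiral(n_points, sx, sy, sz);
  NumericVector area(m);
  std::vector<int> nbr;
  nbr.reserve(64);
  for (int i = 0; i < m; ++i) {
    double Ri = radii[i] + probe;
    double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    nbr.clear();
    for (int j = 0; j < m; ++j) {
      if (j == i) continue;
      double Rj = radii[j] + probe;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double cut = Ri + Rj;
      if (d2 < cut * cut) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xi + Ri * sx[k], py = yi + Ri * sy[k], pz = zi + Ri * sz[k];
      bool buried = false;
      for (size_t t = 0; t < nbr.size(); ++t) {
        int j = nbr[t];
        double Rj = radii[j] + probe;
        double dx = px - coords(j, 0), dy = py - coords(j, 1),
               dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)n_points;
  }
  return area;
}

// Exact sphere through 4 points: 2*(p_k - p_0) . c = |p_k|^2 - |p_0|^2.
// Returns false when the points are (near-)coplanar: relative determinant
// below tol, the C++ analogue of rejecting condition numbers > 1e8.
static bool sphere_from_4(const double p[4][3], double c[3], double *radius) {
  double A[3][3], b[3];
  double scale = 0.0;
  for (int k = 1; k < 4; ++k) {
    double n0 = 0.0, nk = 0.0;
    for (int d = 0; d < 3; ++d) {
      A[k - 1][d] = 2.0 * (p[k][d] - p[0][d]);
      scale = std::max(scale, std::fabs(A[k - 1][d]));
      n0 += p[0][d] * p[0][d];
      nk += p[k][d] * p[k][d];
    }
    b[k - 1] = nk - n0;
  }
  double det =
      A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
      A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
      A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (scale <= 0.0 || std::fabs(det) < 1e-8 * scale * scale * scale)
    return false;
  // Cramer's rule
  for (int d = 0; d < 3; ++d) {
    double M[3][3];
    for (int r = 0; r < 3; ++r)
      for (int cc = 0; cc < 3; ++cc)
        M[r][cc] = (cc == d) ? b[r] : A[r][cc];
    double dd =
        M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
        M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
        M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
    c[d] = dd / det;
  }
  double r2 = 0.0;
  for (int d = 0; d < 3; ++d) r2 += (p[0][d] - c[d]) * (p[0][d] - c[d]);
  *radius = std::sqrt(r2);
  return *radius > 0.0;
}

// RANSAC sphere fit: minimal samples of 4, inliers |dist - r| <= threshold.
// Candidate ranking: most inliers, then smaller inlier RMSE, then earlier
// iteration. Early exit when every point is an inlier. Uses R's RNG so
// set.seed() gives bit-for-bit reproducibility.
// [[Rcpp::export(name = ".ransac_sphere_kernel")]]
List ransac_sphere_kernel(NumericMatrix pts, double threshold, int max_iter) {
  int n = pts.nrow();
  if (n < 4) stop("ransac kernel requires >= 4 points");
  RNGScope scope;
  double best_c[3] = {0, 0, 0}, best_r = -1.0, best_rmse = R_PosInf;
  int best_n = -1, best_iter = -1, n_valid = 0;
  std::vector<int> best_in;
  int idx[4];
  double p[4][3], c[3], r;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // 4 distinct indices, uniform without replacement
    for (int k = 0; k < 4; ++k) {
      bool dup;
      do {
        idx[k] = (int)std::floor(unif_rand() * n);
        if (idx[k] >= n) idx[k] = n - 1;
        dup = false;
        for (int t = 0; t < k; ++t) if (idx[t] == idx[k]) { dup = true; break; }
      } while (dup);
    }
    for (int k = 0; k < 4; ++k)
      for (int d = 0; d < 3; ++d) p[k][d] = pts(idx[k], d);
    if (!sphere_from_4(p, c, &r)) continue;  // degenerate sample, still costs an iteration
    ++n_valid;
    int n_in = 0;
    double sse = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = pts(i, 0) - c[0], dy = pts(i, 1) - c[1],
             dz = pts(i, 2) - c[2];
      double resid = std::sqrt(dx * dx + dy * dy + dz * dz) - r;
      if (std::fabs(resid) <= threshold) { ++n_in; sse += resid * resid; }
    }
    if (n_in < 4) continue;
    double rmse = std::sqrt(sse / n_in);
    if (n_in > best_n || (n_in == best_n && rmse < best_rmse)) {
      best_n = n_in; best_rmse = rmse; best_iter = iter;
      for (int d = 0; d < 3; ++d) best_c[d] = c[d];
      best_r = r;
      best_in.clear();
      for (int i = 0; i < n; ++i) {
        double dx = pts(i, 0) - c[0], dy = pts(i, 1) - c[1],
               dz = pts(i, 2) - c[2];
        double resid = std::sqrt(dx * dx + dy * dy + dz * dz) - r;
        if (std::fabs(resid) <= threshold) best_in.push_back(i + 1);
      }
    }
    if (best_n == n) break;  // unanimous consensus
  }
  if (best_n < 0)
    return List::create(Named("found") = false,
                        Named("n_iterations_used") = std::min(iter, max_iter),
                        Named("n_valid_samples") = n_valid);
  return List::create(
      Named("found") = true,
      Named("center") = NumericVector::create(best_c[0], best_c[1], best_c[2]),
      Named("radius") = best_r,
      Named("inlier_indices") = IntegerVector(best_in.begin(), best_in.end()),
      Named("inlier_rmse") = best_rmse,
      Named("n_iterations_used") = std::min(iter, max_iter),
      Named("best_iteration") = best_iter,
      Named("n_valid_samples") = n_valid);
}
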