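#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// reflect index into [0, n-1], edge-inclusive ("symmetric" padding)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Separable 2D correlation with symmetric boundary padding.
// kx runs along columns (x), ky along rows (y). Kernels must be odd-length.
// [[Rcpp::export]]
NumericMatrix conv_sep_reflect(const NumericMatrix& img,
                               const NumericVector& kx,
                               const NumericVector& ky) {
  int H = img.nrow(), W = img.ncol();
  int nx = kx.size(), ny = ky.size();
  if (nx % 2 == 0 || ny % 2 == 0) stop("kernels must have odd length");
  int hx = nx / 2, hy = ny / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // horizontal pass (over columns)
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double s = 0.0;
      for (int t = 0; t < nx; ++t)
        s += kx[t] * img(i, reflect_idx(j - hx + t, W));
      tmp(i, j) = s;
    }
  }
  // vertical pass (over rows)
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int t = 0; t < ny; ++t)
        s += ky[t] * tmp(reflect_idx(i - hy + t, H), j);
      out(i, j) = s;
    }
  }
  return out;
}

// Connected components of a logical mask, 4-connectivity, labels 1..K in
// raster (column-major) discovery order; 0 outside the mask.
// [[Rcpp::export]]
IntegerMatrix label_components4(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int ci = q.front().first, cj = q.front().second; q.pop();
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int ni = ci + di[d], nj = cj + dj[d];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push(std::make_pair(ni, nj));
          }
        }
      }
    }
  }
  return lab;
}

// Rasterize spherocylindrical rods onto a pixel grid.
// Pixel (i,j) (0-based row i, col j) has physical coordinates
//   x = (j + 0.5 - W/2) * px,  y = (H/2 - i - 0.5) * px
// (origin at the image center, y pointing up). A pixel belongs to the rod
// whose axis segment is nearest among those within width/2.
// Returns owner matrix (1-based rod index, 0 = background).
// [[Rcpp::export]]
IntegerMatrix rasterize_rods_cpp(const NumericVector& x, const NumericVector& y,
                                 const NumericVector& theta,
                                 const NumericVector& len,
                                 double width, int H, int W, double px) {
  int n = x.size();
  IntegerMatrix owner(H, W);
  NumericMatrix best(H, W);
  std::fill(owner.begin(), owner.end(), 0);
  std::fill(best.begin(), best.end(), R_PosInf);
  double hw = width / 2.0;
  for (int r = 0; r < n; ++r) {
    double a = std::max((len[r] - width) / 2.0, 0.0);
    double cx = std::cos(theta[r]), cy = std::sin(theta[r]);
    // bounding box in pixel indices
    double reach = a + hw + px;
    int j0 = (int)std::floor((x[r] - reach) / px + W / 2.0 - 0.5);
    int j1 = (int)std::ceil((x[r] + reach) / px + W / 2.0 - 0.5);
    int i0 = (int)std::floor(H / 2.0 - 0.5 - (y[r] + reach) / px);
    int i1 = (int)std::ceil(H / 2.0 - 0.5 - (y[r] - reach) / px);
    j0 = std::max(j0, 0); j1 = std::min(j1, W - 1);
    i0 = std::max(i0, 0); i1 = std::min(i1, H - 1);
    for (int j = j0; j <= j1; ++j) {
      double pxx = (j + 0.5 - W / 2.0) * px;
      for (int i = i0; i <= i1; ++i) {
        double pyy = (H / 2.0 - i - 0.5) * px;
        double dx = pxx - x[r], dy = pyy - y[r];
        // distance to segment [-e, +e] around rod center
        double t = dx * cx + dy * cy;
        if (t > a) t = a; else if (t < -a) t = -a;
        double qx = dx - t * cx, qy = dy - t * cy;
        double d2 = qx * qx + qy * qy;
        if (d2 <= hw * hw && d2 < best(i, j)) {
          best(i, j) = d2;
          owner(i, j) = r + 1;
        }
      }
    }
  }
  return owner;
}

// Hungarian algorithm (Kuhn-Munkres with potentials), square cost matrix,
// minimizes total cost. Returns 1-based column assigned to each row.
// Deterministic for a given cost matrix.
// [[Rcpp::export]]
IntegerVector hungarian_cpp(const NumericMatrix& cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = R_PosInf;
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      if (!R_finite(delta)) stop("infeasible assignment problem");
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
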