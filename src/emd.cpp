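// Empirical mode decomposition core: extrema detection with plateau handling,
// natural cubic spline envelopes with mirror-extended boundary extrema,
// Cauchy-criterion sifting, and the noise-assisted ensemble variant (EEMD).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Run-length compression of equal-value plateaus, then interior runs that
// exceed (maxima) or undercut (minima) both neighbours; plateau midpoint is
// reported as the extremum index. Indices are 0-based.
static void find_extrema(const arma::vec &x,
                         std::vector<int> &maxima,
                         std::vector<int> &minima) {
  maxima.clear();
  minima.clear();
  const int n = (int)x.n_elem;
  if (n < 3) return;
  std::vector<int> rs, re;           // run start/end (inclusive)
  std::vector<double> rv;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[j + 1] == x[i]) ++j;
    rs.push_back(i); re.push_back(j); rv.push_back(x[i]);
    i = j + 1;
  }
  for (size_t k = 1; k + 1 < rv.size(); ++k) {
    const int mid = (rs[k] + re[k]) / 2;
    if (rv[k] > rv[k - 1] && rv[k] > rv[k + 1]) maxima.push_back(mid);
    else if (rv[k] < rv[k - 1] && rv[k] < rv[k + 1]) minima.push_back(mid);
  }
}

// Natural cubic spline through (xs, ys), evaluated at integer grid 0..n-1.
// xs strictly increasing; degenerate knot counts fall back to constant/linear.
static arma::vec spline_eval(const std::vector<double> &xs,
                             const std::vector<double> &ys, int n) {
  const int m = (int)xs.size();
  arma::vec out(n);
  if (m == 0) { out.zeros(); return out; }
  if (m == 1) { out.fill(ys[0]); return out; }
  if (m == 2) {
    const double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int t = 0; t < n; ++t) out[t] = ys[0] + slope * (t - xs[0]);
    return out;
  }
  // Second derivatives by the standard tridiagonal solve (natural ends).
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), c2(m);
  for (int k = 0; k < m - 1; ++k) h[k] = xs[k + 1] - xs[k];
  for (int k = 1; k < m - 1; ++k)
    alpha[k] = 3.0 * ((ys[k + 1] - ys[k]) / h[k] - (ys[k] - ys[k - 1]) / h[k - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int k = 1; k < m - 1; ++k) {
    l[k] = 2.0 * (xs[k + 1] - xs[k - 1]) - h[k - 1] * mu[k - 1];
    mu[k] = h[k] / l[k];
    z[k] = (alpha[k] - h[k - 1] * z[k - 1]) / l[k];
  }
  c2[m - 1] = 0.0;
  for (int k = m - 2; k >= 0; --k) c2[k] = z[k] - mu[k] * c2[k + 1];
  // Evaluate; extrapolate with the boundary cubic where the grid exceeds knots.
  int seg = 0;
  for (int t = 0; t < n; ++t) {
    const double xt = (double)t;
    while (seg < m - 2 && xs[seg + 1] < xt) ++seg;
    const double dx = xs[seg + 1] - xs[seg];
    const double a = ys[seg], b =
      (ys[seg + 1] - ys[seg]) / dx - dx * (2.0 * c2[seg] + c2[seg + 1]) / 3.0;
    const double c = c2[seg], d = (c2[seg + 1] - c2[seg]) / (3.0 * dx);
    const double u = xt - xs[seg];
    out[t] = a + b * u + c * u * u + d * u * u * u;
  }
  return out;
}

// Mirror up to `nmirror` extrema about both record ends before envelope fitting.
static void mirror_extend(const std::vector<int> &idx, const arma::vec &v,
                          int n, int nmirror,
                          std::vector<double> &xs, std::vector<double> &ys) {
  xs.clear(); ys.clear();
  const int m = (int)idx.size();
  std::vector<std::pair<double,double>> pts;
  for (int k = 0; k < std::min(nmirror, m); ++k)
    if (idx[k] > 0) pts.push_back({-(double)idx[k], v[idx[k]]});
  std::sort(pts.begin(), pts.end());
  for (auto &p : pts) { xs.push_back(p.first); ys.push_back(p.second); }
  for (int k = 0; k < m; ++k) { xs.push_back((double)idx[k]); ys.push_back(v[idx[k]]); }
  for (int k = m - 1; k >= std::max(0, m - nmirror); --k) {
    if (idx[k] < n - 1) {
      xs.push_back(2.0 * (n - 1) - idx[k]); ys.push_back(v[idx[k]]);
    }
  }
}

// One sifting pass: mean of upper/lower envelopes subtracted from h.
// Returns false when fewer than 3 interior extrema remain (residual reached).
static bool sift_once(const arma::vec &h, arma::vec &out) {
  std::vector<int> mx, mn;
  find_extrema(h, mx, mn);
  if ((int)(mx.size() + mn.size()) < 3 || mx.empty() || mn.empty()) return false;
  const int n = (int)h.n_elem;
  std::vector<double> xs, ys;
  mirror_extend(mx, h, n, 2, xs, ys);
  arma::vec upper = spline_eval(xs, ys, n);
  mirror_extend(mn, h, n, 2, xs, ys);
  arma::vec lower = spline_eval(xs, ys, n);
  out = h - (upper + lower) / 2.0;
  return true;
}

static void emd_decompose(const arma::vec &x, int max_imfs,
                          double sd_thresh, int max_sift,
                          std::vector<arma::vec> &imfs, arma::vec &residual) {
  imfs.clear();
  arma::vec r = x;
  for (int i = 0; i < max_imfs; ++i) {
    std::vector<int> mx, mn;
    find_extrema(r, mx, mn);
    if ((int)(mx.size() + mn.size()) < 3 || mx.empty() || mn.empty()) break;
    arma::vec h = r, hn;
    for (int it = 0; it < max_sift; ++it) {
      if (!sift_once(h, hn)) break;
      const double denom = arma::dot(h, h);
      const double sd = denom > 0 ? arma::dot(h - hn, h - hn) / denom : 0.0;
      h = hn;
      if (sd < sd_thresh) break;
    }
    imfs.push_back(h);
    r -= h;
  }
  residual = r;
}

// [[Rcpp::export]]
List emd_cpp(const arma::vec &x, int max_imfs,
             double sd_thresh = 0.2, int max_sift = 50) {
  std::vector<arma::vec> imfs;
  arma::vec residual;
  emd_decompose(x, max_imfs, sd_thresh, max_sift, imfs, residual);
  List li(imfs.size());
  for (size_t i = 0; i < imfs.size(); ++i) li[i] = NumericVector(imfs[i].begin(), imfs[i].end());
  return List::create(_["imfs"] = li,
                      _["residual"] = NumericVector(residual.begin(), residual.end()));
}

// [[Rcpp::export]]
List eemd_cpp(const arma::vec &x, int ensemble_size, double noise_width,
              int max_imfs, int seed, double sd_thresh = 0.2, int max_sift = 50) {
  const int n = (int)x.n_elem;
  const double sdx = arma::stddev(x);
  arma::mat acc(max_imfs, n, arma::fill::zeros);
  arma::vec acc_res(n, arma::fill::zeros);
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  int max_count = 0;
  for (int e = 0; e < ensemble_size; ++e) {
    arma::vec xe = x;
    if (noise_width > 0 && sdx > 0)
      for (int t = 0; t < n; ++t) xe[t] += noise_width * sdx * gauss(rng);
    std::vector<arma::vec> imfs;
    arma::vec res;
    emd_decompose(xe, max_imfs, sd_thresh, max_sift, imfs, res);
    max_count = std::max(max_count, (int)imfs.size());
    for (size_t i = 0; i < imfs.size(); ++i) acc.row(i) += imfs[i].t();
    acc_res += res;
  }
  acc /= (double)ensemble_size;
  acc_res /= (double)ensemble_size;
  List li(max_count);
  for (int i = 0; i < max_count; ++i) {
    arma::rowvec r = acc.row(i);
    li[i] = NumericVector(r.begin(), r.end());
  }
  return List::create(_["imfs"] = li,
                      _["residual"] = NumericVector(acc_res.begin(), acc_res.end()));
}
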