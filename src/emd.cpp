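// Empirical mode decomposition core: extrema detection, mirrored natural
// cubic spline envelopes, sifting, classical EMD, and the ICEEMDAN loop.
// Noise realizations are generated on the R side so that all randomness
// goes through R's RNG and seeding scheme.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Interior local extrema. Plateaus count once, at their midpoint.
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& imax, std::vector<int>& imin) {
  imax.clear(); imin.clear();
  const int n = (int)x.size();
  int i = 1;
  while (i < n - 1) {
    if (x[i] > x[i - 1]) {
      int j = i;
      while (j < n - 1 && x[j + 1] == x[j]) ++j;      // plateau end
      if (j < n - 1 && x[j + 1] < x[j]) imax.push_back((i + j) / 2);
      i = j + 1;
    } else if (x[i] < x[i - 1]) {
      int j = i;
      while (j < n - 1 && x[j + 1] == x[j]) ++j;
      if (j < n - 1 && x[j + 1] > x[j]) imin.push_back((i + j) / 2);
      i = j + 1;
    } else {
      ++i;
    }
  }
}

// Natural cubic spline through (t, v), evaluated at 0..n-1.
// Knots must be strictly increasing and bracket [0, n-1].
static void natural_spline_eval(const std::vector<double>& t,
                                const std::vector<double>& v,
                                int n, std::vector<double>& out) {
  const int m = (int)t.size();
  out.assign(n, 0.0);
  if (m == 2) {                                       // straight line
    const double slope = (v[1] - v[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = v[0] + slope * (i - t[0]);
    return;
  }
  // second derivatives M via tridiagonal system (natural: M0 = Mm-1 = 0)
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), M(m);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((v[i + 1] - v[i]) / h[i] - (v[i] - v[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  // evaluate, walking the knot intervals left to right
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = (double)i;
    while (seg < m - 2 && t[seg + 1] < xi) ++seg;
    const double dt = t[seg + 1] - t[seg];
    const double a = (t[seg + 1] - xi) / dt, b = (xi - t[seg]) / dt;
    out[i] = a * v[seg] + b * v[seg + 1] +
      ((a * a * a - a) * M[seg] + (b * b * b - b) * M[seg + 1]) * (dt * dt) / 6.0;
  }
}

// Mirror up to two extrema beyond each end so the spline brackets [0, n-1].
// If the endpoint sample sticks out beyond the nearest extremum value it is
// promoted to a knot itself (standard guard against envelope undershoot).
static void extend_knots(const std::vector<int>& idx,
                         const std::vector<double>& x,
                         int n, bool upper,
                         std::vector<double>& t, std::vector<double>& v) {
  t.clear(); v.clear();
  const int ne = (int)idx.size();
  const double x0 = x[0], xn = x[n - 1];
  // left extension
  const bool end0_knot = upper ? (x0 >= x[idx[0]]) : (x0 <= x[idx[0]]);
  if (end0_knot) {
    // mirror the first interior extremum around t = 0 for support
    t.push_back(-(double)idx[0]); v.push_back(x[idx[0]]);
    t.push_back(0.0); v.push_back(x0);
  } else {
    const int k = std::min(2, ne);
    for (int j = k - 1; j >= 0; --j) {
      t.push_back(-(double)idx[j]); v.push_back(x[idx[j]]);
    }
  }
  for (int j = 0; j < ne; ++j) { t.push_back((double)idx[j]); v.push_back(x[idx[j]]); }
  // right extension
  const bool endn_knot = upper ? (xn >= x[idx[ne - 1]]) : (xn <= x[idx[ne - 1]]);
  if (endn_knot) {
    t.push_back((double)(n - 1)); v.push_back(xn);
    t.push_back((double)(2 * (n - 1) - idx[ne - 1])); v.push_back(x[idx[ne - 1]]);
  } else {
    const int k = std::min(2, ne);
    for (int j = 0; j < k; ++j) {
      t.push_back((double)(2 * (n - 1) - idx[ne - 1 - j])); v.push_back(x[idx[ne - 1 - j]]);
    }
  }
}

// Mean of upper and lower spline envelopes; identity when the signal has no
// interior maximum or no interior minimum (it is then its own trend).
static bool local_mean_vec(const std::vector<double>& x, std::vector<double>& mean) {
  const int n = (int)x.size();
  std::vector<int> imax, imin;
  find_extrema(x, imax, imin);
  if (imax.empty() || imin.empty() || n < 4) { mean = x; return false; }
  std::vector<double> tu, vu, tl, vl, up, lo;
  extend_knots(imax, x, n, true, tu, vu);
  extend_knots(imin, x, n, false, tl, vl);
  natural_spline_eval(tu, vu, n, up);
  natural_spline_eval(tl, vl, n, lo);
  mean.resize(n);
  for (int i = 0; i < n; ++i) mean[i] = 0.5 * (up[i] + lo[i]);
  return true;
}

static int n_extrema(const std::vector<double>& x) {
  std::vector<int> imax, imin;
  find_extrema(x, imax, imin);
  return (int)(imax.size() + imin.size());
}

// One mode by sifting with the Cauchy SD stopping rule.
// Returns false when the input has too few extrema to sift.
static bool sift_mode(const std::vector<double>& r, double tol, int max_sift,
                      std::vector<double>& mode) {
  const int n = (int)r.size();
  if (n_extrema(r) < 3) return false;
  std::vector<double> h(r), m;
  for (int s = 0; s < max_sift; ++s) {
    if (!local_mean_vec(h, m)) break;
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) { num += m[i] * m[i]; den += h[i] * h[i]; }
    for (int i = 0; i < n; ++i) h[i] -= m[i];
    if (den <= 0.0 || num / den < tol) break;
  }
  mode = h;
  return true;
}

static void emd_vec(const std::vector<double>& x, int max_imfs,
                    double tol, int max_sift,
                    std::vector< std::vector<double> >& imfs,
                    std::vector<double>& residue) {
  imfs.clear();
  residue = x;
  std::vector<double> mode;
  for (int k = 0; k < max_imfs; ++k) {
    if (!sift_mode(residue, tol, max_sift, mode)) break;
    imfs.push_back(mode);
    const int n = (int)residue.size();
    for (int i = 0; i < n; ++i) residue[i] -= mode[i];
  }
}

static std::vector<double> as_vec(const NumericVector& x) {
  return std::vector<double>(x.begin(), x.end());
}

static NumericMatrix imfs_to_matrix(const std::vector< std::vector<double> >& imfs, int n) {
  NumericMatrix out((int)imfs.size(), n);
  for (int j = 0; j < (int)imfs.size(); ++j)
    for (int i = 0; i < n; ++i) out(j, i) = imfs[j][i];
  return out;
}

// population-agnostic: sample sd (denominator n-1), matching R's sd()
static double sdev(const std::vector<double>& x) {
  const int n = (int)x.size();
  if (n < 2) return 0.0;
  double mu = 0.0;
  for (double v : x) mu += v;
  mu /= n;
  double ss = 0.0;
  for (double v : x) ss += (v - mu) * (v - mu);
  return std::sqrt(ss / (n - 1));
}

// [[Rcpp::export(name = ".local_mean_cpp")]]
NumericVector local_mean_cpp(NumericVector x) {
  std::vector<double> xv = as_vec(x), m;
  local_mean_vec(xv, m);
  return wrap(m);
}

// [[Rcpp::export(name = ".n_extrema_cpp")]]
int n_extrema_cpp(NumericVector x) {
  std::vector<double> xv = as_vec(x);
  return n_extrema(xv);
}

// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector x, int max_imfs, double tol, int max_sift) {
  std::vector<double> xv = as_vec(x), res;
  std::vector< std::vector<double> > imfs;
  emd_vec(xv, max_imfs, tol, max_sift, imfs, res);
  return List::create(_["imfs"] = imfs_to_matrix(imfs, (int)xv.size()),
                      _["residue"] = wrap(res));
}

// ICEEMDAN. `noise` is an L x n matrix of standard Gaussian sequences.
// Residues are estimated as the average local mean over noise-perturbed
// realizations; the same realizations, passed through the EMD mode operator
// E_j, are reused at every stage.
// [[Rcpp::export(name = ".iceemdan_cpp")]]
List iceemdan_cpp(NumericVector x, NumericMatrix noise, double epsilon0,
                  int max_imfs, double tol, int max_sift) {
  const int n = x.size(), L = noise.nrow();
  std::vector<double> xv = as_vec(x);

  // E_j(w^(i)) for all realizations, computed once
  std::vector< std::vector< std::vector<double> > > emodes(L);
  std::vector<double> res_unused;
  for (int i = 0; i < L; ++i) {
    std::vector<double> w(n);
    for (int k = 0; k < n; ++k) w[k] = noise(i, k);
    emd_vec(w, max_imfs, tol, max_sift, emodes[i], res_unused);
  }

  std::vector< std::vector<double> > imfs;
  std::vector<double> r_prev(n), acc(n, 0.0), pert(n), m;
  const double sx = sdev(xv);

  // stage 1: r1 = mean_i M(x + beta0_i * E1(w^(i))), beta0 per realization
  for (int i = 0; i < L; ++i) {
    double b0 = 0.0;
    if (!emodes[i].empty()) {
      const double sw = sdev(emodes[i][0]);
      if (sw > 0.0) b0 = epsilon0 * sx / sw;
    }
    for (int k = 0; k < n; ++k)
      pert[k] = xv[k] + (emodes[i].empty() ? 0.0 : b0 * emodes[i][0][k]);
    local_mean_vec(pert, m);
    for (int k = 0; k < n; ++k) acc[k] += m[k];
  }
  for (int k = 0; k < n; ++k) r_prev[k] = acc[k] / L;
  {
    std::vector<double> imf1(n);
    for (int k = 0; k < n; ++k) imf1[k] = xv[k] - r_prev[k];
    imfs.push_back(imf1);
  }

  // stages j >= 2: r_j = mean_i M(r_{j-1} + beta_{j-1} E_j(w^(i)))
  for (int j = 2; j <= max_imfs; ++j) {
    if (n_extrema(r_prev) < 3) break;
    const double beta = epsilon0 * sdev(r_prev);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int i = 0; i < L; ++i) {
      const bool has = (int)emodes[i].size() >= j;
      for (int k = 0; k < n; ++k)
        pert[k] = r_prev[k] + (has ? beta * emodes[i][j - 1][k] : 0.0);
      local_mean_vec(pert, m);
      for (int k = 0; k < n; ++k) acc[k] += m[k];
    }
    std::vector<double> r_j(n), imf_j(n);
    for (int k = 0; k < n; ++k) {
      r_j[k] = acc[k] / L;
      imf_j[k] = r_prev[k] - r_j[k];
    }
    imfs.push_back(imf_j);
    r_prev = r_j;
  }

  return List::create(_["imfs"] = imfs_to_matrix(imfs, n),
                      _["residue"] = wrap(r_prev));
}
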