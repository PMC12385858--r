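// SymDIRECT core: weighted WCSS objective over an intensity histogram,
// symmetric-feasibility pruning, potentially-optimal rectangle selection,
// trisection, and the main dividing-rectangles loop with optional Lloyd
// polish.  The exported piece functions (sym_feasible_cpp, po_select_cpp,
// trisect_*_cpp, lloyd_cpp) wrap the same internals the main loop uses.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

const double REL_TOL = 1e-12;

// weighted within-cluster sum of squares: sum_b w_b * min_j (v_b - c_j)^2
double eval_wcss(const std::vector<double>& v, const std::vector<double>& w,
                 const double* c, int k) {
  double s = 0.0;
  const size_t B = v.size();
  for (size_t b = 0; b < B; ++b) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < k; ++j) {
      double d = v[b] - c[j];
      d *= d;
      if (d < best) best = d;
    }
    s += w[b] * best;
  }
  return s;
}

// greedy witness for intersection with the sorted simplex {c1<=...<=ck}:
// x1=a1, x_i=max(x_{i-1},a_i); feasible iff x_i <= b_i for all i.
bool sym_feasible_impl(const double* lo, const double* hi, int k) {
  double x = lo[0];
  if (x > hi[0] + REL_TOL) return false;
  for (int i = 1; i < k; ++i) {
    if (lo[i] > x) x = lo[i];
    if (x > hi[i] + REL_TOL) return false;
  }
  return true;
}

// Potentially-optimal selection over (diameter, f) pairs.
// Returns 0-based positions into the supplied arrays.
std::vector<int> po_select_impl(const std::vector<double>& diam,
                                const std::vector<double>& fval,
                                const std::vector<int>& created,
                                double f_min, double epsilon) {
  const int n = (int)diam.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (diam[a] != diam[b]) return diam[a] < diam[b];
    if (fval[a] != fval[b]) return fval[a] < fval[b];
    return created[a] < created[b];
  });
  // group diameters within relative tolerance; per-group best = min f,
  // earliest created among exact (d, f) ties
  std::vector<int> gbest;     // representative index per group
  std::vector<double> gd, gf; // group diameter, best f
  for (int t = 0; t < n; ++t) {
    int i = ord[t];
    double tol = REL_TOL * std::max(1.0, diam[i]);
    if (gd.empty() || diam[i] - gd.back() > tol) {
      gd.push_back(diam[i]);
      gf.push_back(fval[i]);
      gbest.push_back(i);
    }
    // ord is sorted so the first member of each group already has min f
    // and earliest creation among equal (d, f)
  }
  const int m = (int)gd.size();
  std::vector<int> out;
  const double thresh = f_min - epsilon * std::fabs(f_min);
  for (int t = 0; t < m; ++t) {
    // K range from pairwise Lipschitz conditions
    double k_low = 0.0; // K must be > 0
    double k_high = std::numeric_limits<double>::infinity();
    bool ok = true;
    for (int s = 0; s < m && ok; ++s) {
      if (s == t) continue;
      double dd = gd[t] - gd[s];
      double df = gf[t] - gf[s];
      if (dd > 0) {
        double bound = df / dd;
        if (bound > k_low) k_low = bound;
      } else if (dd < 0) {
        double bound = df / dd; // = (gf[s]-gf[t])/(gd[s]-gd[t])
        if (bound < k_high) k_high = bound;
      } else if (df > 0) {
        ok = false; // dominated at equal diameter
      }
    }
    if (!ok) continue;
    if (k_high <= 0) continue;
    if (k_low > k_high * (1 + REL_TOL) + REL_TOL) continue;
    // epsilon condition at the most favourable admissible K (largest)
    if (std::isfinite(k_high)) {
      if (gf[t] - k_high * gd[t] > thresh + REL_TOL) continue;
    }
    out.push_back(gbest[t]);
  }
  if (out.empty() && m > 0) out.push_back(gbest[m - 1]); // safety: largest rect
  return out;
}

std::vector<int> max_dims_impl(const double* h, int k) {
  double hm = 0.0;
  for (int i = 0; i < k; ++i) hm = std::max(hm, h[i]);
  std::vector<int> dims;
  for (int i = 0; i < k; ++i)
    if (h[i] >= hm * (1.0 - REL_TOL)) dims.push_back(i);
  return dims;
}

// Lloyd iterations over the histogram; centers updated to weighted means of
// nearest-assigned bins (ties to the lower index), empty clusters keep their
// center; returns sorted centers.
void lloyd_impl(const std::vector<double>& v, const std::vector<double>& w,
                std::vector<double>& c, int max_iter, double tol) {
  const int k = (int)c.size();
  const size_t B = v.size();
  std::sort(c.begin(), c.end());
  std::vector<double> sw(k), swv(k), nc(k);
  for (int iter = 0; iter < max_iter; ++iter) {
    std::fill(sw.begin(), sw.end(), 0.0);
    std::fill(swv.begin(), swv.end(), 0.0);
    for (size_t b = 0; b < B; ++b) {
      int best = 0;
      double bd = std::numeric_limits<double>::infinity();
      for (int j = 0; j < k; ++j) {
        double d = v[b] - c[j];
        d *= d;
        if (d < bd) { bd = d; best = j; } // strict < keeps lower index on ties
      }
      sw[best] += w[b];
      swv[best] += w[b] * v[b];
    }
    double shift = 0.0;
    for (int j = 0; j < k; ++j) {
      nc[j] = (sw[j] > 0) ? swv[j] / sw[j] : c[j];
      shift = std::max(shift, std::fabs(nc[j] - c[j]));
    }
    c = nc;
    std::sort(c.begin(), c.end());
    if (shift < tol) break;
  }
}

// Boundary polish for 1-D weighted k-means: optimal clusters of a sorted
// sample are contiguous, so a center vector induces k-1 split points over
// the bins; move each split +/-1 bin while the objective improves.  Fixes
// adjacent-basin Lloyd fixed points (a single bin on the wrong side of a
// boundary).  Returns segment-mean centers.
void boundary_polish(const std::vector<double>& v, const std::vector<double>& w,
                     std::vector<double>& c) {
  const int k = (int)c.size();
  const int B = (int)v.size();
  if (B <= k) return;
  std::sort(c.begin(), c.end());
  // prefix sums over bins
  std::vector<double> cw(B + 1, 0.0), cwv(B + 1, 0.0), cwv2(B + 1, 0.0);
  for (int i = 0; i < B; ++i) {
    cw[i + 1] = cw[i] + w[i];
    cwv[i + 1] = cwv[i] + w[i] * v[i];
    cwv2[i + 1] = cwv2[i] + w[i] * v[i] * v[i];
  }
  // segment cost of bins [i, j) around their weighted mean
  auto seg = [&](int i, int j) -> double {
    double sw = cw[j] - cw[i];
    if (sw <= 0) return 0.0;
    double sv = cwv[j] - cwv[i];
    double s2 = cwv2[j] - cwv2[i];
    double cost = s2 - sv * sv / sw;
    return cost > 0 ? cost : 0.0;
  };
  // splits s[0..k]: cluster j covers bins [s[j], s[j+1])
  std::vector<int> s(k + 1);
  s[0] = 0;
  s[k] = B;
  int b = 0;
  for (int j = 0; j < k - 1; ++j) {
    double mid = (c[j] + c[j + 1]) / 2.0;
    while (b < B && v[b] <= mid) ++b;
    s[j + 1] = b;
  }
  // enforce non-empty segments
  for (int j = 1; j < k; ++j) if (s[j] <= s[j - 1]) s[j] = s[j - 1] + 1;
  for (int j = k - 1; j >= 1; --j) if (s[j] >= s[j + 1]) s[j] = s[j + 1] - 1;
  bool improved = true;
  while (improved) {
    improved = false;
    for (int j = 1; j < k; ++j) {
      double cur = seg(s[j - 1], s[j]) + seg(s[j], s[j + 1]);
      if (s[j] + 1 < s[j + 1]) {
        double alt = seg(s[j - 1], s[j] + 1) + seg(s[j] + 1, s[j + 1]);
        if (alt < cur - 1e-15) { ++s[j]; improved = true; continue; }
      }
      if (s[j] - 1 > s[j - 1]) {
        double alt = seg(s[j - 1], s[j] - 1) + seg(s[j] - 1, s[j + 1]);
        if (alt < cur - 1e-15) { --s[j]; improved = true; }
      }
    }
  }
  for (int j = 0; j < k; ++j) {
    double sw = cw[s[j + 1]] - cw[s[j]];
    c[j] = (sw > 0) ? (cwv[s[j + 1]] - cwv[s[j]]) / sw : c[j];
  }
  std::sort(c.begin(), c.end());
}

struct Pool {
  int k;
  std::vector<double> center, half, fval, diam;
  std::vector<int> created;
  std::vector<char> alive;
  int counter = 0;
  explicit Pool(int k_) : k(k_) {}
  int n() const { return (int)fval.size(); }
  int add(const double* c, const double* h, double f) {
    for (int i = 0; i < k; ++i) {
      center.push_back(c[i]);
      half.push_back(h[i]);
    }
    double d2 = 0.0;
    for (int i = 0; i < k; ++i) d2 += h[i] * h[i];
    fval.push_back(f);
    diam.push_back(std::sqrt(d2));
    created.push_back(counter++);
    alive.push_back(1);
    return n() - 1;
  }
};

} // namespace

// [[Rcpp::export]]
double wcss_cpp(NumericVector values, NumericVector weights, NumericVector centers) {
  std::vector<double> v(values.begin(), values.end());
  std::vector<double> w(weights.begin(), weights.end());
  return eval_wcss(v, w, centers.begin(), centers.size());
}

// [[Rcpp::export]]
NumericVector wcss_batch_cpp(NumericVector values, NumericVector weights,
                             NumericMatrix centers) {
  std::vector<double> v(values.begin(), values.end());
  std::vector<double> w(weights.begin(), weights.end());
  const int n = centers.nrow(), k = centers.ncol();
  NumericVector out(n);
  std::vector<double> c(k);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) c[j] = centers(i, j);
    out[i] = eval_wcss(v, w, c.data(), k);
  }
  return out;
}

// [[Rcpp::export]]
bool sym_feasible_cpp(NumericVector lower, NumericVector upper) {
  return sym_feasible_impl(lower.begin(), upper.begin(), lower.size());
}

// [[Rcpp::export]]
IntegerVector po_select_cpp(NumericVector diam, NumericVector fval,
                            IntegerVector created, double f_min, double epsilon) {
  std::vector<double> d(diam.begin(), diam.end());
  std::vector<double> f(fval.begin(), fval.end());
  std::vector<int> cr(created.begin(), created.end());
  std::vector<int> sel = po_select_impl(d, f, cr, f_min, epsilon);
  IntegerVector out(sel.size());
  for (size_t i = 0; i < sel.size(); ++i) out[i] = sel[i] + 1;
  return out;
}

// [[Rcpp::export]]
List trisect_points_cpp(NumericVector center, NumericVector half) {
  const int k = center.size();
  std::vector<int> dims = max_dims_impl(half.begin(), k);
  const int m = (int)dims.size();
  double hmax = 0.0;
  for (int i = 0; i < k; ++i) hmax = std::max(hmax, half[i]);
  const double delta = 2.0 * hmax / 3.0;
  NumericMatrix pts(2 * m, k);
  IntegerVector dout(m);
  for (int t = 0; t < m; ++t) {
    dout[t] = dims[t] + 1;
    for (int j = 0; j < k; ++j) {
      pts(2 * t, j) = center[j];
      pts(2 * t + 1, j) = center[j];
    }
    pts(2 * t, dims[t]) = center[dims[t]] + delta;
    pts(2 * t + 1, dims[t]) = center[dims[t]] - delta;
  }
  return List::create(_["points"] = pts, _["dims"] = dout, _["delta"] = delta);
}

// [[Rcpp::export]]
List trisect_children_cpp(NumericVector center, NumericVector half,
                          double f_center, IntegerVector dims,
                          NumericVector f_plus, NumericVector f_minus) {
  const int k = center.size();
  const int m = dims.size();
  double hmax = 0.0;
  for (int i = 0; i < k; ++i) hmax = std::max(hmax, half[i]);
  const double delta = 2.0 * hmax / 3.0;
  // order split dimensions by best sampled objective, ascending (stable)
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return std::min(f_plus[a], f_minus[a]) < std::min(f_plus[b], f_minus[b]);
  });
  std::vector<double> ch(center.begin(), center.end());
  std::vector<double> hh(half.begin(), half.end());
  NumericMatrix cc(2 * m + 1, k), chh(2 * m + 1, k);
  NumericVector cf(2 * m + 1);
  int row = 0;
  for (int t = 0; t < m; ++t) {
    int d = dims[ord[t]] - 1;
    hh[d] = half[d] / 3.0;
    // minus child, plus child (with current half-side state)
    for (int side = 0; side < 2; ++side) {
      std::vector<double> c2(ch);
      c2[d] = ch[d] + (side == 0 ? -delta : delta);
      for (int j = 0; j < k; ++j) { cc(row, j) = c2[j]; chh(row, j) = hh[j]; }
      cf[row] = (side == 0) ? f_minus[ord[t]] : f_plus[ord[t]];
      ++row;
    }
  }
  for (int j = 0; j < k; ++j) { cc(row, j) = ch[j]; chh(row, j) = hh[j]; }
  cf[row] = f_center;
  return List::create(_["centers"] = cc, _["halves"] = chh, _["f"] = cf);
}

// [[Rcpp::export]]
List lloyd_cpp(NumericVector values, NumericVector weights,
               NumericVector centers, int max_iter = 200, double tol = 1e-12) {
  std::vector<double> v(values.begin(), values.end());
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<double> c(centers.begin(), centers.end());
  lloyd_impl(v, w, c, max_iter, tol);
  double f = eval_wcss(v, w, c.data(), (int)c.size());
  return List::create(_["centers"] = NumericVector(c.begin(), c.end()),
                      _["wcss"] = f);
}

// [[Rcpp::export]]
List symdirect_cpp(NumericVector values, NumericVector weights, int k,
                   double epsilon, int max_evals, double diameter_tol,
                   bool lloyd_refine, int lloyd_max_iter = 200,
                   double lloyd_tol = 1e-12) {
  std::vector<double> v(values.begin(), values.end());
  std::vector<double> w(weights.begin(), weights.end());
  Pool pool(k);

  std::vector<double> c0(k, 0.5), h0(k, 0.5);
  double f0 = eval_wcss(v, w, c0.data(), k);
  int evals = 1;
  pool.add(c0.data(), h0.data(), f0);
  std::vector<double> inc_pt(c0);
  double inc_f = f0;
  std::vector<double> trace;
  trace.push_back(inc_f);

  std::vector<double> lo(k), hi(k);
  while (evals < max_evals) {
    // collect alive rectangles
    std::vector<int> ids;
    double maxd = 0.0;
    for (int i = 0; i < pool.n(); ++i)
      if (pool.alive[i]) { ids.push_back(i); maxd = std::max(maxd, pool.diam[i]); }
    if (ids.empty() || maxd < diameter_tol) break;

    std::vector<double> ad, af;
    std::vector<int> acr;
    ad.reserve(ids.size()); af.reserve(ids.size()); acr.reserve(ids.size());
    for (int id : ids) {
      ad.push_back(pool.diam[id]);
      af.push_back(pool.fval[id]);
      acr.push_back(pool.created[id]);
    }
    std::vector<int> po = po_select_impl(ad, af, acr, inc_f, epsilon);
    bool any = false;
    for (int p : po) {
      if (evals >= max_evals) break; // allow at most one final trisection batch
      int id = ids[p];
      // copy: pool vectors may reallocate during pool.add below
      std::vector<double> cv(pool.center.begin() + (size_t)id * k,
                             pool.center.begin() + (size_t)(id + 1) * k);
      std::vector<double> hv(pool.half.begin() + (size_t)id * k,
                             pool.half.begin() + (size_t)(id + 1) * k);
      const double f_parent = pool.fval[id];
      const double* c = cv.data();
      const double* h = hv.data();
      std::vector<int> dims = max_dims_impl(h, k);
      const int m = (int)dims.size();
      double hmax = 0.0;
      for (int i = 0; i < k; ++i) hmax = std::max(hmax, h[i]);
      const double delta = 2.0 * hmax / 3.0;
      std::vector<double> fplus(m), fminus(m);
      std::vector<double> pt(c, c + k);
      for (int t = 0; t < m; ++t) {
        int d = dims[t];
        pt[d] = c[d] + delta;
        fplus[t] = eval_wcss(v, w, pt.data(), k);
        pt[d] = c[d] - delta;
        fminus[t] = eval_wcss(v, w, pt.data(), k);
        pt[d] = c[d];
        evals += 2;
        if (fplus[t] < inc_f) {
          inc_f = fplus[t];
          inc_pt.assign(c, c + k);
          inc_pt[d] = c[d] + delta;
        }
        if (fminus[t] < inc_f) {
          inc_f = fminus[t];
          inc_pt.assign(c, c + k);
          inc_pt[d] = c[d] - delta;
        }
      }
      // split order: ascending best sampled objective
      std::vector<int> ord(m);
      for (int i = 0; i < m; ++i) ord[i] = i;
      std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
        return std::min(fplus[a], fminus[a]) < std::min(fplus[b], fminus[b]);
      });
      std::vector<double> ch(c, c + k), hh(h, h + k);
      for (int t = 0; t < m; ++t) {
        int d = dims[ord[t]];
        hh[d] = h[d] / 3.0;
        for (int side = 0; side < 2; ++side) {
          std::vector<double> c2(ch);
          c2[d] = ch[d] + (side == 0 ? -delta : delta);
          for (int j = 0; j < k; ++j) {
            lo[j] = c2[j] - hh[j];
            hi[j] = c2[j] + hh[j];
          }
          if (sym_feasible_impl(lo.data(), hi.data(), k))
            pool.add(c2.data(), hh.data(), side == 0 ? fminus[ord[t]] : fplus[ord[t]]);
        }
      }
      for (int j = 0; j < k; ++j) {
        lo[j] = ch[j] - hh[j];
        hi[j] = ch[j] + hh[j];
      }
      if (sym_feasible_impl(lo.data(), hi.data(), k))
        pool.add(ch.data(), hh.data(), f_parent);
      pool.alive[id] = 0;
      any = true;
    }
    trace.push_back(inc_f);
    if (!any) break;
  }

  std::vector<double> cen(inc_pt);
  std::sort(cen.begin(), cen.end());
  double fbest = inc_f;
  if (lloyd_refine) {
    // polish the incumbent plus a small elite of low-objective rectangle
    // centers: local refinement from several basins, deterministically
    std::vector<int> order(pool.n());
    for (int i = 0; i < pool.n(); ++i) order[i] = i;
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      if (pool.fval[a] != pool.fval[b]) return pool.fval[a] < pool.fval[b];
      return pool.created[a] < pool.created[b];
    });
    // greedy diverse elite: best objective first, keep points whose sorted
    // centers differ from all accepted ones by >= 0.05 in some coordinate
    const int n_elite = 10;
    const double div_tol = 0.05;
    std::vector<std::vector<double>> starts;
    starts.push_back(inc_pt);
    std::sort(starts[0].begin(), starts[0].end());
    for (int t = 0; t < pool.n() && (int)starts.size() < n_elite + 1; ++t) {
      int id = order[t];
      std::vector<double> cand(pool.center.begin() + (size_t)id * k,
                               pool.center.begin() + (size_t)(id + 1) * k);
      std::sort(cand.begin(), cand.end());
      bool novel = true;
      for (const std::vector<double>& s : starts) {
        double dmax = 0.0;
        for (int j = 0; j < k; ++j)
          dmax = std::max(dmax, std::fabs(cand[j] - s[j]));
        if (dmax < div_tol) { novel = false; break; }
      }
      if (novel) starts.push_back(cand);
    }
    for (std::vector<double>& s : starts) {
      lloyd_impl(v, w, s, lloyd_max_iter, lloyd_tol);
      boundary_polish(v, w, s);
      double fl = eval_wcss(v, w, s.data(), k);
      if (fl < fbest) {
        fbest = fl;
        cen = s;
      }
    }
  }
  int n_alive = 0;
  for (int i = 0; i < pool.n(); ++i) n_alive += pool.alive[i];
  return List::create(_["centers"] = NumericVector(cen.begin(), cen.end()),
                      _["wcss"] = fbest, _["eval_count"] = evals,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["n_rect_alive"] = n_alive,
                      _["n_rect_total"] = pool.n());
}
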