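// Permutation and DP kernels for the recombination-detection statistics.
#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

static inline double chi2_2x2(double a, double b, double c, double d) {
  double r1 = a + b, r2 = c + d, c1 = a + c, c2 = b + d;
  if (r1 <= 0 || r2 <= 0 || c1 <= 0 || c2 <= 0) return 0.0;
  double N = r1 + r2;
  double det = a * d - b * c;
  return N * det * det / (r1 * r2 * c1 * c2);
}

// max over internal breakpoints of the (left,right) x (label1,label2)
// Pearson chi-squared; labels coded 1/2. Returns stat and breakpoint
// (number of sites left of the split, 1..k-1).
static double max_chi2_scan(const int* lab, int k, int* arg) {
  int m = 0;
  for (int i = 0; i < k; ++i) if (lab[i] == 1) ++m;
  int n = k - m;
  double best = 0.0;
  int bestt = 1;
  int a = 0; // label-1 count on the left
  for (int t = 1; t < k; ++t) {
    if (lab[t - 1] == 1) ++a;
    double b = t - a;
    double c = m - a, d = n - b;
    double s = chi2_2x2(a, b, c, d);
    if (s > best) { best = s; bestt = t; }
  }
  if (arg) *arg = bestt;
  return best;
}

// [[Rcpp::export]]
List cpp_max_chi2(IntegerVector labels) {
  int k = labels.size();
  if (k < 2) return List::create(_["stat"] = 0.0, _["breakpoint"] = NA_INTEGER);
  int arg = 1;
  double s = max_chi2_scan(INTEGER(labels), k, &arg);
  return List::create(_["stat"] = s, _["breakpoint"] = arg);
}

// Exact permutation p-value of the max-breakpoint chi-squared: the
// probability, over all C(m+n, m) orderings of m label-1 and n label-2
// sites, that some internal breakpoint's 2x2 chi-squared reaches c.
// Computed by forward probability DP over the hypergeometric prefix
// walk (t sites seen, a of them label 1), absorbing mass on first entry
// into the rejection region.
// [[Rcpp::export]]
double cpp_maxchi_scan_pvalue(int m, int n, double c) {
  int w = m + n;
  if (w < 2 || c <= 0) return 1.0;
  std::vector<double> g(m + 1, 0.0), h(m + 1, 0.0);
  g[0] = 1.0;
  double pout = 0.0;
  for (int t = 0; t < w; ++t) {
    std::fill(h.begin(), h.end(), 0.0);
    int alo = std::max(0, t - n), ahi = std::min(t, m);
    double rem = w - t;
    for (int a = alo; a <= ahi; ++a) {
      double mass = g[a];
      if (mass <= 0) continue;
      double pup = (m - a) / rem;
      // advance one site
      if (m - a > 0) h[a + 1] += mass * pup;
      if (n - (t - a) > 0) h[a] += mass * (1.0 - pup);
    }
    // absorb states entering the rejection region at breakpoint t+1
    int tb = t + 1;
    if (tb >= 1 && tb <= w - 1) {
      int blo = std::max(0, tb - n), bhi = std::min(tb, m);
      for (int a = blo; a <= bhi; ++a) {
        if (h[a] <= 0) continue;
        double chi = chi2_2x2(a, tb - a, m - a, n - (tb - a));
        if (chi >= c - 1e-9) { pout += h[a]; h[a] = 0.0; }
      }
    }
    std::swap(g, h);
  }
  return pout;
}

// [[Rcpp::export]]
NumericVector cpp_maxchi_null(int m, int n, int nperm, int seed) {
  int k = m + n;
  std::vector<int> lab(k);
  for (int i = 0; i < k; ++i) lab[i] = (i < m) ? 1 : 2;
  std::mt19937 rng(static_cast<unsigned>(seed));
  NumericVector out(nperm);
  for (int p = 0; p < nperm; ++p) {
    for (int i = k - 1; i > 0; --i) {
      std::uniform_int_distribution<int> u(0, i);
      std::swap(lab[i], lab[u(rng)]);
    }
    out[p] = max_chi2_scan(lab.data(), k, nullptr);
  }
  return out;
}

// best two-breakpoint segmentation: maximize chi-squared of
// (inside [i,j)) vs (outside) x (label1,label2) over all 0<=i<j<=k.
// [[Rcpp::export]]
List cpp_best_segment(IntegerVector labels) {
  int k = labels.size();
  std::vector<int> pre(k + 1, 0); // prefix count of label 1
  for (int i = 0; i < k; ++i) pre[i + 1] = pre[i] + (labels[i] == 1);
  int m = pre[k], n = k - m;
  double best = -1.0;
  int bi = 0, bj = k;
  // a segment and its complement give the same chi-squared; prefer the
  // shorter segment (the anomalous tract rather than its flank)
  for (int i = 0; i < k; ++i) {
    for (int j = i + 1; j <= k; ++j) {
      double a = pre[j] - pre[i];          // label1 inside
      double b = (j - i) - a;              // label2 inside
      double c = m - a, d = n - b;
      double s = chi2_2x2(a, b, c, d);
      if (s > best + 1e-9 ||
          (s > best - 1e-9 && (j - i) < (bj - bi))) {
        best = s; bi = i; bj = j;
      }
    }
  }
  return List::create(_["stat"] = best, _["from"] = bi, _["to"] = bj);
}

// two-breakpoint extraction anchored at the argmax single-breakpoint
// chi-squared: the strongest transition t1 is one tract edge; the other
// edge maximizes the inside-vs-outside chi-squared of the segment bounded
// by t1. Ties prefer the shorter segment.
// [[Rcpp::export]]
List cpp_anchored_segment(IntegerVector labels, int anchor = -1) {
  int k = labels.size();
  std::vector<int> pre(k + 1, 0);
  for (int i = 0; i < k; ++i) pre[i + 1] = pre[i] + (labels[i] == 1);
  int m = pre[k], n = k - m;
  int t1 = 1;
  if (anchor >= 1 && anchor < k) t1 = anchor;
  else max_chi2_scan(INTEGER(labels), k, &t1);
  double best = -1.0;
  int bi = 0, bj = k;
  for (int t2 = 0; t2 <= k; ++t2) {
    if (t2 == t1) continue;
    int i = std::min(t1, t2), j = std::max(t1, t2);
    double a = pre[j] - pre[i];
    double b = (j - i) - a;
    double c = m - a, d = n - b;
    double s = chi2_2x2(a, b, c, d);
    if (s > best + 1e-9 ||
        (s > best - 1e-9 && (j - i) < (bj - bi))) {
      best = s; bi = i; bj = j;
    }
  }
  return List::create(_["stat"] = best, _["from"] = bi, _["to"] = bj,
                      _["anchor"] = t1);
}

// [[Rcpp::export]]
List cpp_max_run(IntegerVector x) {
  int k = x.size(), best = 0, bs = 0, cur = 0, cs = 0;
  for (int i = 0; i < k; ++i) {
    if (x[i] == 1) {
      if (cur == 0) cs = i;
      ++cur;
      if (cur > best) { best = cur; bs = cs; }
    } else cur = 0;
  }
  return List::create(_["len"] = best, _["from"] = bs, _["to"] = bs + best);
}

// null distribution of the max agreement run for a ones among s sites
// [[Rcpp::export]]
IntegerVector cpp_maxrun_null(int a, int s, int nperm, int seed) {
  std::vector<int> x(s);
  for (int i = 0; i < s; ++i) x[i] = (i < a) ? 1 : 0;
  std::mt19937 rng(static_cast<unsigned>(seed));
  IntegerVector out(nperm);
  for (int p = 0; p < nperm; ++p) {
    for (int i = s - 1; i > 0; --i) {
      std::uniform_int_distribution<int> u(0, i);
      std::swap(x[i], x[u(rng)]);
    }
    int best = 0, cur = 0;
    for (int i = 0; i < s; ++i) {
      if (x[i]) { if (++cur > best) best = cur; }
      else cur = 0;
    }
    out[p] = best;
  }
  return out;
}

// maximum descent of a +/-1 walk, with the (from,to] step-index interval
// achieving it (0-based site indices; from = position of the running max).
// [[Rcpp::export]]
List cpp_descent(IntegerVector steps) {
  int k = steps.size();
  double h = 0, runmax = 0;
  int runmaxIdx = -1; // step index after which the running max occurs
  double best = 0;
  int bfrom = 0, bto = 0;
  for (int i = 0; i < k; ++i) {
    h += steps[i];
    if (h > runmax) { runmax = h; runmaxIdx = i; }
    double drop = runmax - h;
    if (drop > best) { best = drop; bfrom = runmaxIdx + 1; bto = i; }
  }
  return List::create(_["stat"] = best, _["from"] = bfrom, _["to"] = bto);
}

// Monte-Carlo exceedance count of the maximum descent over random
// shuffles of m up-steps and n down-steps
// [[Rcpp::export]]
int cpp_descent_mc(int m, int n, int d, int nperm, int seed) {
  int k = m + n;
  std::vector<int> st(k);
  for (int i = 0; i < k; ++i) st[i] = (i < m) ? 1 : -1;
  std::mt19937 rng(static_cast<unsigned>(seed));
  int exc = 0;
  for (int p = 0; p < nperm; ++p) {
    for (int i = k - 1; i > 0; --i) {
      std::uniform_int_distribution<int> u(0, i);
      std::swap(st[i], st[u(rng)]);
    }
    int h = 0, runmax = 0, best = 0;
    for (int i = 0; i < k; ++i) {
      h += st[i];
      if (h > runmax) runmax = h;
      if (runmax - h > best) best = runmax - h;
    }
    if (best >= d) ++exc;
  }
  return exc;
}

// exact P(maximum descent >= d) for a uniformly random arrangement of
// m up-steps and n down-steps, by forward probability DP over prefixes
// with state (ups used, current drop below running max). When the
// projected work m*n*d exceeds maxOps the threshold is lowered, which
// can only increase the returned tail probability (a conservative
// upper bound); the threshold actually used is returned.
// [[Rcpp::export]]
List cpp_descent_pvalue(int m, int n, int d, double maxOps = 2e8) {
  if (d <= 0) return List::create(_["p"] = 1.0, _["d"] = d);
  if (n < d) return List::create(_["p"] = 0.0, _["d"] = d);
  int duse = d;
  double ops = static_cast<double>(m) * n * d;
  if (ops > maxOps) {
    duse = std::max(1, static_cast<int>(maxOps /
      (static_cast<double>(m) * n + 1.0)));
    duse = std::min(duse, d);
  }
  int T = m + n;
  // g[i*duse+c]: probability of a prefix with i ups, (t-i) downs and
  // current drop c that never reached duse
  std::vector<double> g(static_cast<size_t>(m + 1) * duse, 0.0);
  std::vector<double> h(g.size(), 0.0);
  g[0] = 1.0;
  double pout = 0.0;
  for (int t = 0; t < T; ++t) {
    int ilo = std::max(0, t - n), ihi = std::min(t, m);
    std::fill(h.begin() + static_cast<size_t>(ilo) * duse,
              h.begin() + static_cast<size_t>(std::min(ihi + 2, m + 1)) *
                duse, 0.0);
    double rem = T - t;
    for (int i = ilo; i <= ihi; ++i) {
      double pup = (m - i) / rem;
      double pdn = 1.0 - pup;
      double* gi = &g[static_cast<size_t>(i) * duse];
      double* hi = &h[static_cast<size_t>(i) * duse];
      double* hu = (i < m) ? &h[static_cast<size_t>(i + 1) * duse] : nullptr;
      int j = t - i;
      bool canDown = (n - j) > 0;
      for (int c = 0; c < duse; ++c) {
        double mass = gi[c];
        if (mass <= 0) continue;
        if (hu) hu[c > 0 ? c - 1 : 0] += mass * pup;
        if (canDown) {
          if (c + 1 >= duse) pout += mass * pdn;
          else hi[c + 1] += mass * pdn;
        }
      }
    }
    std::swap(g, h);
  }
  return List::create(_["p"] = pout, _["d"] = duse);
}
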