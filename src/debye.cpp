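#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sinc(double x) {
  // sin(x)/x with the x -> 0 limit; |x| below ~1e-8 is indistinguishable
  // from 1 at double precision
  if (std::fabs(x) < 1e-8) return 1.0;
  return std::sin(x) / x;
}

// Direct O(N^2) Debye sum.
// coords: N x 3, fq: N x nq per-atom effective amplitudes, q: length nq.
// [[Rcpp::export(name = ".debye_direct_cpp")]]
NumericVector debye_direct_cpp(NumericMatrix coords, NumericMatrix fq,
                               NumericVector q) {
  const int n = coords.nrow(), nq = q.size();
  NumericVector I(nq);
  // diagonal terms
  for (int k = 0; k < nq; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += fq(i, k) * fq(i, k);
    I[k] = s;
  }
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - coords(j, 0);
      const double dy = yi - coords(j, 1);
      const double dz = zi - coords(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k) {
        I[k] += 2.0 * fq(i, k) * fq(j, k) * sinc(q[k] * r);
      }
    }
  }
  return I;
}

// Histogram-accelerated Debye sum. Atoms are grouped into scattering
// species (identical form-factor profile); each pair's weight is split
// linearly between the two bracketing distance-grid nodes (linear
// binning, second-order accurate in the bin width), and
// I(q) = sum over species pairs of f_a(q) f_b(q) * (hist_ab . sinc(q r)).
// The sinc table over (node, q) is computed once per call.
// species: 0-based species index per atom; fq_s: n_species x nq.
// [[Rcpp::export(name = ".debye_hist_cpp")]]
NumericVector debye_hist_cpp(NumericMatrix coords, IntegerVector species,
                             NumericMatrix fq_s, NumericVector q,
                             double bin) {
  const int n = coords.nrow(), nq = q.size(), ns = fq_s.nrow();
  const int npair = ns * (ns + 1) / 2;
  // max distance -> number of distance-grid nodes r_b = b * bin
  double rmax2 = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = coords(i, 0) - coords(j, 0);
      const double dy = coords(i, 1) - coords(j, 1);
      const double dz = coords(i, 2) - coords(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rmax2) rmax2 = r2;
    }
  const int nb = (int)(std::sqrt(rmax2) / bin) + 3;
  std::vector<double> hist((size_t)npair * nb, 0.0);
  std::vector<double> diag(ns, 0.0);
  for (int i = 0; i < n; ++i) diag[species[i]] += 1.0;
  for (int i = 0; i < n; ++i) {
    const int si = species[i];
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - coords(j, 0);
      const double dy = yi - coords(j, 1);
      const double dz = zi - coords(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double pos = r / bin;
      // quadratic (three-node) assignment about the nearest node: the
      // weights reproduce the 0th, 1st and 2nd moments of the pair
      // distance, making the binned sum third-order accurate in `bin`
      int b = (int)(pos + 0.5);
      if (b < 1) b = 1;
      const double t = pos - b;
      int sa = si, sb = species[j];
      if (sa > sb) std::swap(sa, sb);
      const int pidx = sa * ns - sa * (sa - 1) / 2 + (sb - sa);
      double *h = &hist[(size_t)pidx * nb];
      h[b - 1] += 2.0 * 0.5 * t * (t - 1.0);
      h[b]     += 2.0 * (1.0 - t * t);
      h[b + 1] += 2.0 * 0.5 * t * (t + 1.0);
    }
  }
  // sinc(q * r_b) table, bins fastest
  std::vector<double> st((size_t)nq * nb);
  for (int k = 0; k < nq; ++k) {
    double *col = &st[(size_t)k * nb];
    for (int b = 0; b < nb; ++b) col[b] = sinc(q[k] * b * bin);
  }
  NumericVector I(nq);
  for (int k = 0; k < nq; ++k) {
    double s = 0.0;
    for (int a = 0; a < ns; ++a) s += diag[a] * fq_s(a, k) * fq_s(a, k);
    const double *col = &st[(size_t)k * nb];
    for (int a = 0; a < ns; ++a) {
      for (int b2 = a; b2 < ns; ++b2) {
        const int pidx = a * ns - a * (a - 1) / 2 + (b2 - a);
        const double fab = fq_s(a, k) * fq_s(b2, k);
        const double *h = &hist[(size_t)pidx * nb];
        double dot = 0.0;
        for (int bb = 0; bb < nb; ++bb) dot += h[bb] * col[bb];
        s += fab * dot;
      }
    }
    I[k] = s;
  }
  return I;
}

// Soft-sphere clash penalty between atoms of different rigid bodies.
// Pairs that are natively (in the template) closer than `rmin` are only
// penalised below `slack` times their native separation, so packed
// template contacts carry no cost; all other inter-body pairs are
// penalised quadratically below rmin.
// [[Rcpp::export(name = ".clash_penalty_cpp")]]
double clash_penalty_cpp(NumericMatrix coords, NumericMatrix ref,
                         IntegerVector body, double rmin, double slack) {
  const int n = coords.nrow();
  double pen = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (body[i] == body[j]) continue;
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= rmin * rmin) continue;
      dx = ref(i, 0) - ref(j, 0);
      dy = ref(i, 1) - ref(j, 1);
      dz = ref(i, 2) - ref(j, 2);
      const double d0 = std::sqrt(dx * dx + dy * dy + dz * dz);
      double allowed = rmin < slack * d0 ? rmin : slack * d0;
      const double d = std::sqrt(d2);
      if (d < allowed) {
        const double v = allowed - d;
        pen += v * v;
      }
    }
  }
  return pen;
}
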