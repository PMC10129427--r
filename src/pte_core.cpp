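#include <Rcpp.h>
using namespace Rcpp;

// Phase transfer entropy between all ordered channel pairs from binned
// instantaneous phases.
//
// binmat: nchan x ntime matrix of 1-based phase-bin indices.
// epoch_start / epoch_len: 1-based starts and lengths of the analysis
// segments; the prediction lag never crosses a segment boundary.
// Segment estimates are combined by a length-weighted average.
//
// PTE(x->y) = H(Yp,Xp) + H(Yf,Yp) - H(Yp) - H(Yf,Yp,Xp), with Yf the target
// phase `delay` samples ahead. With mm_correct each plug-in entropy gets the
// Miller-Madow correction (K-1)/(2N), which cancels the first-order
// occupancy bias of the histogram estimator.
// [[Rcpp::export]]
NumericMatrix pte_matrix_core(IntegerMatrix binmat, IntegerVector epoch_start,
                              IntegerVector epoch_len, int delay, int nbins,
                              bool mm_correct) {
  const int nchan = binmat.nrow();
  const int nep = epoch_start.size();
  NumericMatrix out(nchan, nchan);
  const int b = nbins, b2 = b * b;
  std::vector<double> c3((size_t)b2 * b), c2a(b2), c2b(b2), c1(b);
  std::vector<int> t3, t2a, t2b, t1;
  double wtot = 0.0;
  for (int e = 0; e < nep; ++e) {
    const int s0 = epoch_start[e] - 1, L = epoch_len[e];
    const int n = L - delay;
    if (n < 2) continue;
    wtot += n;
    for (int i = 0; i < nchan; ++i) {
      for (int j = 0; j < nchan; ++j) {
        if (i == j) continue;
        t3.clear(); t2a.clear(); t2b.clear(); t1.clear();
        for (int t = 0; t < n; ++t) {
          int xp = binmat(i, s0 + t) - 1;
          int yp = binmat(j, s0 + t) - 1;
          int yf = binmat(j, s0 + t + delay) - 1;
          int i1 = yp, i2a = yp + xp * b, i2b = yf + yp * b, i3 = i2b + xp * b2;
          if (c1[i1] == 0) t1.push_back(i1);
          if (c2a[i2a] == 0) t2a.push_back(i2a);
          if (c2b[i2b] == 0) t2b.push_back(i2b);
          if (c3[i3] == 0) t3.push_back(i3);
          c1[i1]++; c2a[i2a]++; c2b[i2b]++; c3[i3]++;
        }
        double h1 = 0, h2a = 0, h2b = 0, h3 = 0;
        const double invn = 1.0 / n;
        for (size_t k = 0; k < t1.size(); ++k) {
          double p = c1[t1[k]] * invn; h1 -= p * std::log(p); c1[t1[k]] = 0;
        }
        for (size_t k = 0; k < t2a.size(); ++k) {
          double p = c2a[t2a[k]] * invn; h2a -= p * std::log(p); c2a[t2a[k]] = 0;
        }
        for (size_t k = 0; k < t2b.size(); ++k) {
          double p = c2b[t2b[k]] * invn; h2b -= p * std::log(p); c2b[t2b[k]] = 0;
        }
        for (size_t k = 0; k < t3.size(); ++k) {
          double p = c3[t3[k]] * invn; h3 -= p * std::log(p); c3[t3[k]] = 0;
        }
        double v = h2a + h2b - h1 - h3;
        if (mm_correct)
          v += ((double)t2a.size() + (double)t2b.size()
                - (double)t1.size() - (double)t3.size()) / (2.0 * n);
        out(i, j) += v * n;
      }
    }
  }
  if (wtot > 0)
    for (int i = 0; i < nchan; ++i)
      for (int j = 0; j < nchan; ++j) out(i, j) /= wtot;
  return out;
}
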