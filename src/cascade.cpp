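#include <Rcpp.h>
using namespace Rcpp;

// Causal IIR cascade (direct form I) over a multi-channel block with carried
// per-channel, per-stage input/output histories, so signals can be filtered
// sample-stream style in blocks of any size. Stage coefficients must be
// normalised (a[0] == 1). The state layout is, per channel and stage,
// k past inputs followed by k past outputs (k = stage order), newest first.

// [[Rcpp::export]]
List cascade_filter_cpp(NumericMatrix block, List b_list, List a_list,
                        NumericVector state) {
  const int n = block.nrow(), nch = block.ncol(), S = b_list.size();
  NumericMatrix out(n, nch);
  NumericVector st = clone(state);

  std::vector<NumericVector> bv(S), av(S);
  std::vector<int> ord(S);
  int per_ch = 0;
  for (int s = 0; s < S; ++s) {
    bv[s] = as<NumericVector>(b_list[s]);
    av[s] = as<NumericVector>(a_list[s]);
    ord[s] = av[s].size() - 1;
    per_ch += 2 * ord[s];
  }
  if (st.size() != per_ch * nch) stop("filter state has the wrong size");

  std::vector<double> x(n);
  for (int c = 0; c < nch; ++c) {
    for (int i = 0; i < n; ++i) x[i] = block(i, c);
    int so = c * per_ch;
    for (int s = 0; s < S; ++s) {
      const int k = ord[s];
      double *xh = &st[0] + so;      // x_{t-1}, x_{t-2}, ...
      double *yh = xh + k;           // y_{t-1}, y_{t-2}, ...
      const double *b = &bv[s][0];
      const double *a = &av[s][0];
      for (int i = 0; i < n; ++i) {
        const double xi = x[i];
        double acc = b[0] * xi;
        for (int j = 1; j <= k; ++j) acc += b[j] * xh[j - 1] - a[j] * yh[j - 1];
        for (int j = k - 1; j > 0; --j) { xh[j] = xh[j - 1]; yh[j] = yh[j - 1]; }
        if (k > 0) { xh[0] = xi; yh[0] = acc; }
        x[i] = acc;
      }
      so += 2 * k;
    }
    for (int i = 0; i < n; ++i) out(i, c) = x[i];
  }
  return List::create(_["block"] = out, _["state"] = st);
}
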