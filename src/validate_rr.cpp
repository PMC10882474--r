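#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Sequential criterion-beat-difference validation of an RR series.
// A beat is accepted when it lies in the physiologic band and within
// max(expected_frac * m, min_artifact_ms) of the running median m of the
// last 5 accepted beats.
// [[Rcpp::export(name = ".validate_rr_cpp")]]
LogicalVector validate_rr_cpp(NumericVector rr_ms, double band_lo,
                              double band_hi, double expected_frac,
                              double min_artifact_ms) {
  int n = rr_ms.size();
  LogicalVector keep(n);
  double buf[5];
  int cnt = 0, pos = 0;
  for (int i = 0; i < n; ++i) {
    double x = rr_ms[i];
    if (NumericVector::is_na(x) || x < band_lo || x > band_hi) continue;
    if (cnt > 0) {
      double tmp[5];
      std::copy(buf, buf + cnt, tmp);
      std::sort(tmp, tmp + cnt);
      double ref = (cnt % 2 == 1) ? tmp[cnt / 2]
                                  : 0.5 * (tmp[cnt / 2 - 1] + tmp[cnt / 2]);
      double cbd = std::max(expected_frac * ref, min_artifact_ms);
      if (std::abs(x - ref) > cbd) continue;
    }
    keep[i] = true;
    buf[pos] = x;
    pos = (pos + 1) % 5;
    if (cnt < 5) ++cnt;
  }
  return keep;
}
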