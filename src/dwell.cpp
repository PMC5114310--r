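#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double medianOf(std::vector<double> v) {
  size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Sequential scan of the online dwell criterion: at each sample t the
// trailing window [t - threshold, t] must satisfy the dispersion bound on
// both axes (blink samples excluded), must not overlap the previous dwell's
// window, and the candidate click position must not fall within the
// 3 x 3 degree square around any click of the previous `refractoryMs` ms.
// [[Rcpp::export]]
DataFrame cpp_detect_dwells(NumericVector t, NumericVector x, NumericVector y,
                            LogicalVector blink, double thresholdMs,
                            double dispersionDeg, double refractoryMs,
                            double samePosHalfDeg) {
  int n = t.size();
  std::vector<double> clickT, clickX, clickY;
  if (n >= 2) {
    double dt = t[1] - t[0];
    int w = (int)std::round(thresholdMs / dt);
    double lastClick = R_NegInf;
    std::vector<double> wx, wy;
    wx.reserve(w + 1);
    wy.reserve(w + 1);
    for (int i = w; i < n; i++) {
      if (t[i] - thresholdMs < lastClick) continue;  // window overlap rule
      double xmin = R_PosInf, xmax = R_NegInf;
      double ymin = R_PosInf, ymax = R_NegInf;
      int cnt = 0;
      for (int j = i - w; j <= i; j++) {
        if (blink[j]) continue;
        if (x[j] < xmin) xmin = x[j];
        if (x[j] > xmax) xmax = x[j];
        if (y[j] < ymin) ymin = y[j];
        if (y[j] > ymax) ymax = y[j];
        cnt++;
      }
      if (cnt == 0) continue;
      if (xmax - xmin > dispersionDeg || ymax - ymin > dispersionDeg)
        continue;
      wx.clear();
      wy.clear();
      for (int j = i - w; j <= i; j++) {
        if (blink[j]) continue;
        wx.push_back(x[j]);
        wy.push_back(y[j]);
      }
      double cx = medianOf(wx), cy = medianOf(wy);
      bool suppressed = false;
      for (int k = (int)clickT.size() - 1; k >= 0; k--) {
        if (clickT[k] < t[i] - refractoryMs) break;
        if (std::abs(cx - clickX[k]) <= samePosHalfDeg &&
            std::abs(cy - clickY[k]) <= samePosHalfDeg) {
          suppressed = true;
          break;
        }
      }
      if (suppressed) continue;
      clickT.push_back(t[i]);
      clickX.push_back(cx);
      clickY.push_back(cy);
      lastClick = t[i];
    }
  }
  int m = clickT.size();
  NumericVector ct(m), cx(m), cy(m), onset(m);
  for (int k = 0; k < m; k++) {
    ct[k] = clickT[k];
    cx[k] = clickX[k];
    cy[k] = clickY[k];
    onset[k] = clickT[k] - thresholdMs;
  }
  return DataFrame::create(_["click_time_ms"] = ct, _["onset_ms"] = onset,
                           _["click_x_deg"] = cx, _["click_y_deg"] = cy);
}
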