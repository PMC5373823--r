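#include <Rcpp.h>
using namespace Rcpp;

// Brute-force 2D displacement histogram between two pixelized point sets.
// px/py are 1-based pixel indices; the histogram covers displacements
// dx, dy in [-K, K] (dx = px2 - px1). All ordered pairs are counted,
// including coincident ones, matching the FFT image product exactly.
// [[Rcpp::export]]
NumericMatrix pair_disp_hist_cpp(IntegerVector px1, IntegerVector py1,
                                 IntegerVector px2, IntegerVector py2,
                                 int K) {
  const int W = 2 * K + 1;
  NumericMatrix hist(W, W);
  const int n1 = px1.size(), n2 = px2.size();
  for (int i = 0; i < n1; ++i) {
    const int xi = px1[i], yi = py1[i];
    for (int j = 0; j < n2; ++j) {
      const int dx = px2[j] - xi;
      if (dx < -K || dx > K) continue;
      const int dy = py2[j] - yi;
      if (dy < -K || dy > K) continue;
      hist(dx + K, dy + K) += 1.0;
    }
  }
  return hist;
}

// Sequential-frame chain assignment for localization grouping.
// Input is sorted by frame. A localization joins the nearest open chain
// whose last frame is the current or previous frame and whose running mean
// lies within radius; otherwise it opens a new chain. Returns 1-based
// chain ids per localization.
// [[Rcpp::export]]
IntegerVector group_chains_cpp(NumericVector x, NumericVector y,
                               IntegerVector frame, double radius) {
  const int n = x.size();
  IntegerVector cid(n);
  std::vector<double> sx, sy, mx, my;
  std::vector<int> cnt, last, id;
  const double r2 = radius * radius;
  int nchain = 0;
  for (int i = 0; i < n; ++i) {
    const int f = frame[i];
    // prune chains that can no longer be extended
    size_t w = 0;
    for (size_t c = 0; c < id.size(); ++c) {
      if (last[c] >= f - 1) {
        sx[w] = sx[c]; sy[w] = sy[c]; mx[w] = mx[c]; my[w] = my[c];
        cnt[w] = cnt[c]; last[w] = last[c]; id[w] = id[c];
        ++w;
      }
    }
    sx.resize(w); sy.resize(w); mx.resize(w); my.resize(w);
    cnt.resize(w); last.resize(w); id.resize(w);
    // nearest chain last extended in the previous frame, within radius
    int best = -1; double bestd = r2;
    for (size_t c = 0; c < id.size(); ++c) {
      if (last[c] != f - 1) continue;
      const double dx = x[i] - mx[c], dy = y[i] - my[c];
      const double d2 = dx * dx + dy * dy;
      if (d2 <= bestd) { bestd = d2; best = (int)c; }
    }
    if (best >= 0) {
      sx[best] += x[i]; sy[best] += y[i]; cnt[best] += 1; last[best] = f;
      mx[best] = sx[best] / cnt[best]; my[best] = sy[best] / cnt[best];
      cid[i] = id[best];
    } else {
      ++nchain;
      sx.push_back(x[i]); sy.push_back(y[i]);
      mx.push_back(x[i]); my.push_back(y[i]);
      cnt.push_back(1); last.push_back(f); id.push_back(nchain);
      cid[i] = nchain;
    }
  }
  return cid;
}

// Frame-pair displacement histograms for steady-state live correlation.
// Localizations of the two channels, each sorted by frame, are paired for
// frame lags 0..tau_max; pair displacements binned on the pixel grid as in
// pair_disp_hist_cpp, one histogram slab per lag. Also returns, per lag,
// the sum over frame pairs of nA(t) * nB(t + lag) needed for normalization.
// [[Rcpp::export]]
List tau_pair_hist_cpp(IntegerVector pxA, IntegerVector pyA, IntegerVector fA,
                       IntegerVector pxB, IntegerVector pyB, IntegerVector fB,
                       int tau_max, int K) {
  const int W = 2 * K + 1;
  // frame index ranges
  int fmax = 0;
  for (int i = 0; i < fA.size(); ++i) fmax = std::max(fmax, fA[i]);
  for (int i = 0; i < fB.size(); ++i) fmax = std::max(fmax, fB[i]);
  const int nf = fmax + 1;
  std::vector<int> startA(nf + 1, 0), startB(nf + 1, 0);
  for (int i = 0; i < fA.size(); ++i) startA[fA[i] + 1]++;
  for (int i = 0; i < fB.size(); ++i) startB[fB[i] + 1]++;
  for (int f = 0; f < nf; ++f) { startA[f + 1] += startA[f]; startB[f + 1] += startB[f]; }

  List hists(tau_max + 1);
  NumericVector npairs(tau_max + 1);
  for (int tau = 0; tau <= tau_max; ++tau) {
    NumericMatrix h(W, W);
    double np = 0.0;
    for (int t = 0; t + tau < nf; ++t) {
      const int a0 = startA[t], a1 = startA[t + 1];
      const int b0 = startB[t + tau], b1 = startB[t + tau + 1];
      np += (double)(a1 - a0) * (double)(b1 - b0);
      for (int i = a0; i < a1; ++i) {
        const int xi = pxA[i], yi = pyA[i];
        for (int j = b0; j < b1; ++j) {
          const int dx = pxB[j] - xi;
          if (dx < -K || dx > K) continue;
          const int dy = pyB[j] - yi;
          if (dy < -K || dy > K) continue;
          h(dx + K, dy + K) += 1.0;
        }
      }
      if (tau > 0) {  // negative lag: A at t+tau vs B at t
        const int a0n = startA[t + tau], a1n = startA[t + tau + 1];
        const int b0n = startB[t], b1n = startB[t + 1];
        np += (double)(a1n - a0n) * (double)(b1n - b0n);
        for (int i = a0n; i < a1n; ++i) {
          const int xi = pxA[i], yi = pyA[i];
          for (int j = b0n; j < b1n; ++j) {
            const int dx = pxB[j] - xi;
            if (dx < -K || dx > K) continue;
            const int dy = pyB[j] - yi;
            if (dy < -K || dy > K) continue;
            h(dx + K, dy + K) += 1.0;
          }
        }
      }
    }
    hists[tau] = h;
    npairs[tau] = np;
  }
  return List::create(_["hist"] = hists, _["npairs"] = npairs);
}
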