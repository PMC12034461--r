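#include <Rcpp.h>

using namespace Rcpp;

// Pooled co-active counts under circular shuffles. `frames` holds each
// neuron's 0-based active frames; `offsets` is nNeurons x nShuffles of
// 0-based circular shifts (drawn in R so seeding stays on the R side).
// Returns an nFrames x nShuffles matrix of co-active neuron counts.
// [[Rcpp::export]]
IntegerMatrix shuffle_counts_cpp(List frames, int nFrames,
                                 IntegerMatrix offsets) {
  const int nNeurons = frames.size();
  const int nShuffles = offsets.ncol();
  IntegerMatrix out(nFrames, nShuffles);
  for (int s = 0; s < nShuffles; ++s) {
    int* col = &out(0, s);
    for (int i = 0; i < nNeurons; ++i) {
      IntegerVector f = frames[i];
      const int off = offsets(i, s);
      for (int j = 0; j < f.size(); ++j) {
        int pos = f[j] + off;
        if (pos >= nFrames) pos -= nFrames;
        ++col[pos];
      }
    }
  }
  return out;
}
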