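// Inner loop of the word-aligned multitaper spectrogram: gathers the
// sliding-window segments of every trial and channel and applies the
// real-valued taper/DFT operator in one BLAS matrix product per channel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// samples: time x channel matrix (one column per channel)
// trial_start: 0-based first sample of each trial
// win_start: 0-based window offsets within a trial
// op: (2 * n_tapers * nf) x n_win operator (cosine/sine blocks per taper,
//     pre-multiplied by the taper)
// returns taper-averaged magnitudes as an array [n_tr, n_ch, nf, nt]
// [[Rcpp::export]]
NumericVector cpp_trial_asm(const arma::mat& samples,
                            const arma::uvec& trial_start,
                            const arma::uvec& win_start,
                            const arma::mat& op,
                            int nf, int n_tapers, bool power) {
  const int n_win = op.n_cols;
  const int n_tr = trial_start.n_elem;
  const int nt = win_start.n_elem;
  const int n_ch = samples.n_cols;
  NumericVector out((size_t)n_tr * n_ch * nf * nt);
  out.attr("dim") = IntegerVector::create(n_tr, n_ch, nf, nt);
  double* o = out.begin();
  arma::mat seg(n_win, (arma::uword)nt * n_tr);
  for (int ch = 0; ch < n_ch; ++ch) {
    const double* col = samples.colptr(ch);
    arma::uword c = 0;
    for (int tr = 0; tr < n_tr; ++tr)
      for (int w = 0; w < nt; ++w, ++c) {
        const double* src = col + trial_start[tr] + win_start[w];
        std::copy(src, src + n_win, seg.colptr(c));
      }
    arma::mat y = op * seg;
    for (int tr = 0; tr < n_tr; ++tr)
      for (int w = 0; w < nt; ++w) {
        const double* yc = y.colptr((arma::uword)tr * nt + w);
        for (int f = 0; f < nf; ++f) {
          double acc = 0;
          for (int k = 0; k < n_tapers; ++k) {
            const double re = yc[2 * k * nf + f];
            const double im = yc[(2 * k + 1) * nf + f];
            const double m2 = re * re + im * im;
            acc += power ? m2 : std::sqrt(m2);
          }
          o[tr + (size_t)n_tr * (ch + (size_t)n_ch *
                                 (f + (size_t)nf * w))] = acc / n_tapers;
        }
      }
  }
  return out;
}
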