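#include <Rcpp.h>
using namespace Rcpp;

// Double-strand PWM scan of a set of sequences.
//
// lf: W x 4 matrix of log likelihood ratios log(p_pwm/p_bg), columns A,C,G,T,
//     forward orientation. lr: same for the reverse-complemented matrix, so
//     scoring lr on the forward sequence equals scoring lf on the reverse
//     complement of the window.
//
// Per window the score is the larger of the two strand likelihood ratios;
// windows containing a non-ACGT character contribute 0 and are never hits.
// Returns per-sequence TBA (sum of per-window max LR), the log-scale variant
// (sum of per-window max log-LR), and optionally all windows with LR >= min_lr.
// [[Rcpp::export(name = ".scan_pwm_cpp")]]
List scan_pwm_cpp(CharacterVector seqs, NumericMatrix lf, NumericMatrix lr,
                  double min_lr, bool collect_hits) {
  const int W = lf.nrow();
  const int n = seqs.size();
  NumericVector tba(n), tba_log(n);
  std::vector<int> h_seq, h_pos, h_strand;
  std::vector<double> h_lr;

  for (int s = 0; s < n; ++s) {
    SEXP el = STRING_ELT(seqs, s);
    const char *str = CHAR(el);
    const int L = LENGTH(el);
    if (L < W) { tba[s] = 0.0; tba_log[s] = 0.0; continue; }

    std::vector<int> code(L);
    for (int i = 0; i < L; ++i) {
      switch (str[i]) {
        case 'A': case 'a': code[i] = 0; break;
        case 'C': case 'c': code[i] = 1; break;
        case 'G': case 'g': code[i] = 2; break;
        case 'T': case 't': code[i] = 3; break;
        default: code[i] = -1;
      }
    }

    double tot = 0.0, totlog = 0.0;
    for (int i = 0; i + W <= L; ++i) {
      double sf = 0.0, sr = 0.0;
      bool has_n = false;
      for (int j = 0; j < W; ++j) {
        const int b = code[i + j];
        if (b < 0) { has_n = true; break; }
        sf += lf(j, b);
        sr += lr(j, b);
      }
      if (has_n) continue;
      const double m = sf > sr ? sf : sr;
      const double w = std::exp(m);
      tot += w;
      totlog += m;
      if (collect_hits && w >= min_lr) {
        h_seq.push_back(s + 1);
        h_pos.push_back(i);
        h_lr.push_back(w);
        h_strand.push_back(sf >= sr ? 1 : -1);
      }
    }
    tba[s] = tot;
    tba_log[s] = totlog;
  }

  return List::create(
    _["tba"] = tba,
    _["tba_log"] = tba_log,
    _["hit_seq"] = wrap(h_seq),
    _["hit_pos"] = wrap(h_pos),
    _["hit_lr"] = wrap(h_lr),
    _["hit_strand"] = wrap(h_strand));
}
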