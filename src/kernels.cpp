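#include <Rcpp.h>
using namespace Rcpp;

// Score every window of a base-coded sequence against a log10-ratio matrix.
// lr: 5 x L matrix, rows A,C,G,T,N (N row is all zero: neutral base).
// seq: integer codes 0..4. Returns one score per window start (0-based).
// [[Rcpp::export]]
NumericVector cpp_score_windows(NumericMatrix lr, IntegerVector seq) {
  int L = lr.ncol();
  int n = seq.size();
  int nw = n - L + 1;
  if (nw < 1) return NumericVector(0);
  NumericVector out(nw);
  for (int s = 0; s < nw; ++s) {
    double acc = 0.0;
    for (int p = 0; p < L; ++p) acc += lr(seq[s + p], p);
    out[s] = acc;
  }
  return out;
}

// Scan a list of base-coded promoters with one motif. lr scores the forward
// strand; lr_rc is the reverse-complemented matrix, so evaluating it at a
// forward offset scores the reverse-complement of that window — both strands
// come out of a single pass with offsets already on the forward frame.
// Returns parallel vectors (gene index 1-based, 0-based offset,
// strand 0='+' / 1='-', jindex), ordered by gene, offset, then strand.
// [[Rcpp::export]]
List cpp_scan_codes(NumericMatrix lr, NumericMatrix lr_rc, List codes,
                    double threshold, bool both_strands) {
  int L = lr.ncol();
  std::vector<int> gene, offset, strand;
  std::vector<double> score;
  for (int g = 0; g < codes.size(); ++g) {
    IntegerVector seq = codes[g];
    int n = seq.size();
    for (int s = 0; s + L <= n; ++s) {
      double f = 0.0, r = 0.0;
      for (int p = 0; p < L; ++p) {
        int b = seq[s + p];
        f += lr(b, p);
        if (both_strands) r += lr_rc(b, p);
      }
      if (f >= threshold) {
        gene.push_back(g + 1); offset.push_back(s);
        strand.push_back(0); score.push_back(f);
      }
      if (both_strands && r >= threshold) {
        gene.push_back(g + 1); offset.push_back(s);
        strand.push_back(1); score.push_back(r);
      }
    }
  }
  return List::create(_["gene"] = wrap(gene), _["offset"] = wrap(offset),
                      _["strand"] = wrap(strand), _["jindex"] = wrap(score));
}

// Weighted Kendall's tau: 2/D * sum_{i>j} v_i v_j sgn(i-j) sgn(R_i-R_j)
// with D = (sum v)^2 - sum v^2. R is a permutation (any distinct reals work).
// [[Rcpp::export]]
double cpp_tau_w(NumericVector v, NumericVector R) {
  int n = v.size();
  double sv = 0.0, sv2 = 0.0;
  for (int i = 0; i < n; ++i) { sv += v[i]; sv2 += v[i] * v[i]; }
  double D = sv * sv - sv2;
  double acc = 0.0;
  for (int i = 1; i < n; ++i) {
    double vi = v[i], Ri = R[i];
    for (int j = 0; j < i; ++j) {
      double d = Ri - R[j];
      if (d > 0) acc += vi * v[j];
      else if (d < 0) acc -= vi * v[j];
    }
  }
  return 2.0 * acc / D;
}

// tau_w for each column of a matrix of rank vectors (permutations of 1..n).
// [[Rcpp::export]]
NumericVector cpp_tau_w_many(NumericVector v, NumericMatrix Rs) {
  int m = Rs.ncol();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    NumericVector col = Rs(_, k);
    out[k] = cpp_tau_w(v, col);
  }
  return out;
}

// Null permutation sample of tau_w: n_perm random permutations of 1..n,
// drawn with R's RNG (so set.seed() on the R side controls reproducibility).
// [[Rcpp::export]]
NumericVector cpp_perm_taus(NumericVector v, int n_perm) {
  int n = v.size();
  NumericVector out(n_perm);
  NumericVector R(n);
  for (int k = 0; k < n_perm; ++k) {
    for (int i = 0; i < n; ++i) R[i] = i + 1;
    // Fisher-Yates with R's unif_rand
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      double tmp = R[i]; R[i] = R[j]; R[j] = tmp;
    }
    out[k] = cpp_tau_w(v, R);
  }
  return out;
}
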