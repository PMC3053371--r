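#include <Rcpp.h>
using namespace Rcpp;

// Alignment kernels for the profile search engine and the surrogate
// threading backend. Residues arrive as 0-based integer codes; code 20 is
// the mask/unknown token X. Profiles are L x 20 per-position score
// matrices; X against any profile position scores `xscore`.

static inline double prof_score(const NumericMatrix& prof, int i, int a,
                                double xscore) {
  return (a >= 0 && a < 20) ? prof(i, a) : xscore;
}

// Glocal alignment: the profile must be consumed in full (global in the
// profile), the sequence is local (free start/end). Linear gap costs:
// gap_del skips a profile position, gap_ins consumes an unmatched sequence
// residue inside the alignment. Score only.
// [[Rcpp::export(name = ".glocal_score_cpp")]]
double glocal_score_cpp(NumericMatrix prof, IntegerVector seq,
                        double gap_ins, double gap_del, double xscore) {
  const int L = prof.nrow(), n = seq.size();
  const double NEG = -1e30;
  std::vector<double> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = 0.0;  // row i = 0: free start
  for (int i = 1; i <= L; ++i) {
    cur[0] = prev[0] - gap_del;
    for (int j = 1; j <= n; ++j) {
      double m = prev[j - 1] + prof_score(prof, i - 1, seq[j - 1], xscore);
      double d = prev[j] - gap_del;
      double ins = cur[j - 1] - gap_ins;
      double best = m > d ? m : d;
      if (ins > best) best = ins;
      cur[j] = best > NEG ? best : NEG;
    }
    std::swap(prev, cur);
  }
  double best = prev[0];
  for (int j = 1; j <= n; ++j) if (prev[j] > best) best = prev[j];
  return best;
}

// Same DP with traceback. Returns score, the 1-based sequence span of the
// aligned region, and the matched (profile_pos, seq_pos) pairs (1-based).
// Tie-break: match preferred over delete over insert, and the smallest
// ending sequence position among equal-scoring ends (deterministic).
// [[Rcpp::export(name = ".glocal_align_cpp")]]
List glocal_align_cpp(NumericMatrix prof, IntegerVector seq,
                      double gap_ins, double gap_del, double xscore) {
  const int L = prof.nrow(), n = seq.size();
  NumericMatrix V(L + 1, n + 1);
  IntegerMatrix P(L + 1, n + 1);  // 0 start, 1 match, 2 del, 3 ins
  for (int j = 0; j <= n; ++j) { V(0, j) = 0.0; P(0, j) = 0; }
  for (int i = 1; i <= L; ++i) {
    V(i, 0) = V(i - 1, 0) - gap_del; P(i, 0) = 2;
    for (int j = 1; j <= n; ++j) {
      double m = V(i - 1, j - 1) + prof_score(prof, i - 1, seq[j - 1], xscore);
      double d = V(i - 1, j) - gap_del;
      double ins = V(i, j - 1) - gap_ins;
      double best = m; int ptr = 1;
      if (d > best) { best = d; ptr = 2; }
      if (ins > best) { best = ins; ptr = 3; }
      V(i, j) = best; P(i, j) = ptr;
    }
  }
  int jend = 0; double best = V(L, 0);
  for (int j = 1; j <= n; ++j) if (V(L, j) > best) { best = V(L, j); jend = j; }
  // traceback
  std::vector<int> pp, qp;
  int i = L, j = jend;
  int jstart = jend;
  while (i > 0) {
    int ptr = P(i, j);
    if (ptr == 1) { pp.push_back(i); qp.push_back(j); jstart = j; --i; --j; }
    else if (ptr == 2) { --i; }
    else { jstart = j; --j; }
  }
  std::reverse(pp.begin(), pp.end());
  std::reverse(qp.begin(), qp.end());
  if (!qp.empty()) jstart = qp.front();
  return List::create(_["score"] = best,
                      _["qstart"] = jstart,  // 1-based first aligned residue
                      _["qend"] = jend,      // 1-based last aligned residue
                      _["ppos"] = wrap(pp), _["qpos"] = wrap(qp));
}

// Batch glocal scores against a list of integer sequences (calibration).
// [[Rcpp::export(name = ".glocal_scores_batch_cpp")]]
NumericVector glocal_scores_batch_cpp(NumericMatrix prof, List seqs,
                                      double gap_ins, double gap_del,
                                      double xscore) {
  const int k = seqs.size();
  NumericVector out(k);
  for (int s = 0; s < k; ++s) {
    IntegerVector sq = seqs[s];
    out[s] = glocal_score_cpp(prof, sq, gap_ins, gap_del, xscore);
  }
  return out;
}

// Smith-Waterman local alignment, affine gaps (Gotoh), score only.
// submat is a square matrix over the residue code alphabet (21 incl. X).
static double sw_score_one(const IntegerVector& a, const IntegerVector& b,
                           const NumericMatrix& submat,
                           double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double Hdiag = 0.0;  // H[i-1][0]
    double F = NEG;
    H[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - gap_ext, H[j] - gap_open);
      F = std::max(F - gap_ext, H[j - 1] - gap_open);
      double h = Hdiag + submat(a[i - 1], b[j - 1]);
      h = std::max(h, E[j]);
      h = std::max(h, F);
      h = std::max(h, 0.0);
      Hdiag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_scores_batch_cpp")]]
NumericVector sw_scores_batch_cpp(IntegerVector query, List refs,
                                  NumericMatrix submat,
                                  double gap_open, double gap_ext) {
  const int k = refs.size();
  NumericVector out(k);
  for (int s = 0; s < k; ++s) {
    IntegerVector r = refs[s];
    out[s] = sw_score_one(query, r, submat, gap_open, gap_ext);
  }
  return out;
}
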