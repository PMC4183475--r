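// Sequence-comparison inner loops shared by the preclustering, OTU picking
// and chimera detection stages.  All sequences live in reference-alignment
// space: one character per alignment column, '.' = outside read coverage,
// '-' = deletion relative to the reference, A/C/G/T/N otherwise.

#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>
using namespace Rcpp;

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}
static inline bool covered(char c) { return c != '.' && c != 'N'; }
static inline bool is_transition(char a, char b) {
  return (a == 'A' && b == 'G') || (a == 'G' && b == 'A') ||
         (a == 'C' && b == 'T') || (a == 'T' && b == 'C');
}

// identity-mode distance: mismatches / comparable columns, where a column
// is comparable when both sequences cover it (gap vs base counts as a
// mismatch).  K2P mode: Kimura two-parameter distance over columns where
// both carry a plain base; undefined -> +Inf (never within a threshold).
static double pair_dist(const std::string &a, const std::string &b,
                        bool k2p, int min_overlap, int *overlap_out) {
  const size_t L = a.size();
  long comp = 0, mis = 0, ts = 0, tv = 0;
  for (size_t i = 0; i < L; ++i) {
    const char ca = a[i], cb = b[i];
    if (!covered(ca) || !covered(cb)) continue;
    if (k2p) {
      if (!is_base(ca) || !is_base(cb)) continue;
      ++comp;
      if (ca != cb) {
        if (is_transition(ca, cb)) ++ts; else ++tv;
      }
    } else {
      if (ca == '-' && cb == '-') { ++comp; continue; }
      ++comp;
      if (ca != cb) ++mis;
    }
  }
  if (overlap_out) *overlap_out = (int)comp;
  if (comp < min_overlap) return R_PosInf;
  if (!k2p) return (double)mis / (double)comp;
  const double P = (double)ts / comp, Q = (double)tv / comp;
  const double w1 = 1.0 - 2.0 * P - Q, w2 = 1.0 - 2.0 * Q;
  if (w1 <= 0.0 || w2 <= 0.0) return R_PosInf;
  return -0.5 * std::log(w1 * std::sqrt(w2));
}

// [[Rcpp::export(name = ".gp_pair_dist")]]
double gp_pair_dist(std::string a, std::string b, bool k2p = false,
                    int min_overlap = 1) {
  return pair_dist(a, b, k2p, min_overlap, nullptr);
}

// Greedy abundance-sorted centroid clustering.  `order` gives processing
// order (1-based indices; the caller sorts by decreasing abundance with its
// tie-breaks).  Each sequence joins the first centroid, in centroid
// creation order, within `max_dist`; otherwise it founds a new centroid.
// With `extend`, alignment columns the centroid does not cover ('.') are
// filled in from joining members (first member to cover a column wins), so
// centroids grow towards full amplicon coverage.  Returns the per-sequence
// 1-based centroid index and the (possibly extended) centroid sequences.
// [[Rcpp::export(name = ".gp_greedy_cluster")]]
List gp_greedy_cluster(std::vector<std::string> seqs, IntegerVector order,
                       double max_dist, bool k2p = false,
                       int min_overlap = 1, bool extend = false) {
  const int n = seqs.size();
  IntegerVector assign(n, NA_INTEGER);
  std::vector<int> cents;
  std::vector<std::string> cseq;
  cents.reserve(256);
  for (int oi = 0; oi < order.size(); ++oi) {
    const int i = order[oi] - 1;
    int hit = -1;
    for (size_t c = 0; c < cents.size(); ++c) {
      const double d = pair_dist(seqs[i], cseq[c], k2p, min_overlap,
                                 nullptr);
      if (d <= max_dist) {
        hit = cents[c];
        if (extend) {
          std::string &cs = cseq[c];
          const std::string &ms = seqs[i];
          for (size_t p = 0; p < cs.size(); ++p)
            if (cs[p] == '.' && ms[p] != '.') cs[p] = ms[p];
        }
        break;
      }
    }
    if (hit < 0) {
      cents.push_back(i);
      cseq.push_back(seqs[i]);
      hit = i;
    }
    assign[i] = hit + 1;
  }
  CharacterVector out_seq(cents.size());
  IntegerVector out_idx(cents.size());
  for (size_t c = 0; c < cents.size(); ++c) {
    out_seq[c] = cseq[c];
    out_idx[c] = cents[c] + 1;
  }
  return List::create(Named("assign") = assign,
                      Named("centroid_index") = out_idx,
                      Named("centroid_seq") = out_seq);
}

// Two-parent single-crossover chimera scan.  Queries are processed in
// ascending abundance; candidate parents for a query are the sequences
// with abundance >= skew * query abundance.  The model places one
// crossover between consecutive query-covered columns; each parent side
// must span >= min_parent_bases query positions.  A query is flagged when
// the best two-parent model identity is >= min_ident and exceeds the best
// single-parent identity by >= min_margin.
// [[Rcpp::export(name = ".gp_chimera_scan")]]
DataFrame gp_chimera_scan(std::vector<std::string> seqs, NumericVector abund,
                          double skew = 2.0, double min_ident = 0.99,
                          double min_margin = 0.01,
                          int min_parent_bases = 30) {
  const int n = seqs.size();
  LogicalVector flagged(n, false);
  IntegerVector parent_a(n, NA_INTEGER), parent_b(n, NA_INTEGER),
      cross_col(n, NA_INTEGER);
  NumericVector model_id(n, NA_REAL), single_id(n, NA_REAL);

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int x, int y) { return abund[x] < abund[y]; });

  for (int qi = 0; qi < n; ++qi) {
    const int q = ord[qi];
    const std::string &qs = seqs[q];
    // query positions (alignment columns the query covers with a real char)
    std::vector<int> pos;
    pos.reserve(qs.size());
    for (size_t i = 0; i < qs.size(); ++i)
      if (covered(qs[i])) pos.push_back((int)i);
    const int L = (int)pos.size();
    if (L < 2 * min_parent_bases) continue;

    std::vector<int> cand;
    for (int c = 0; c < n; ++c)
      if (c != q && abund[c] >= skew * abund[q]) cand.push_back(c);
    if (cand.size() < 2) continue;

    const int nc = (int)cand.size();
    // cumulative matches along query positions, per candidate
    std::vector<std::vector<int>> cum(nc, std::vector<int>(L + 1, 0));
    double best_single = 0.0;
    for (int c = 0; c < nc; ++c) {
      const std::string &cs = seqs[cand[c]];
      for (int k = 0; k < L; ++k) {
        const char cc = cs[pos[k]];
        cum[c][k + 1] = cum[c][k] +
            ((covered(cc) && cc == qs[pos[k]]) ? 1 : 0);
      }
      const double sid = (double)cum[c][L] / L;
      if (sid > best_single) best_single = sid;
    }

    double best_model = -1.0;
    int ba = -1, bb = -1, bx = -1;
    for (int k = min_parent_bases; k <= L - min_parent_bases; ++k) {
      // top-2 left scores and top-2 right scores to enforce a != b
      int l1 = -1, l2 = -1, r1 = -1, r2 = -1;
      for (int c = 0; c < nc; ++c) {
        const int lv = cum[c][k];
        if (l1 < 0 || lv > cum[l1][k]) { l2 = l1; l1 = c; }
        else if (l2 < 0 || lv > cum[l2][k]) l2 = c;
        const int rv = cum[c][L] - cum[c][k];
        if (r1 < 0 || rv > cum[r1][L] - cum[r1][k]) { r2 = r1; r1 = c; }
        else if (r2 < 0 || rv > cum[r2][L] - cum[r2][k]) r2 = c;
      }
      int a = l1, b = r1;
      if (a == b) {
        const int alt1 = (l2 >= 0) ?
            cum[l2][k] + (cum[r1][L] - cum[r1][k]) : -1;
        const int alt2 = (r2 >= 0) ?
            cum[l1][k] + (cum[r2][L] - cum[r2][k]) : -1;
        if (alt1 < 0 && alt2 < 0) continue;
        if (alt1 >= alt2) { a = l2; b = r1; } else { a = l1; b = r2; }
      }
      const double sc = (double)(cum[a][k] + (cum[b][L] - cum[b][k])) / L;
      if (sc > best_model) {
        best_model = sc; ba = a; bb = b; bx = k;
      }
    }
    if (ba < 0) continue;
    model_id[q] = best_model;
    single_id[q] = best_single;
    parent_a[q] = cand[ba] + 1;
    parent_b[q] = cand[bb] + 1;
    cross_col[q] = pos[bx - 1] + 1;  // last column taken from parent_a
    if (best_model >= min_ident && best_model - best_single >= min_margin)
      flagged[q] = true;
  }
  return DataFrame::create(
      Named("flagged") = flagged, Named("parent_a") = parent_a,
      Named("parent_b") = parent_b, Named("crossover_col") = cross_col,
      Named("model_identity") = model_id,
      Named("single_identity") = single_id);
}
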