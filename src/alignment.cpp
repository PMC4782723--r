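#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment (Gotoh affine-gap) and banded edit distance.
// Conventions shared by every caller:
//   * gap of length k costs gap_open + k * gap_extend (both <= 0);
//   * traceback tie-break is diagonal > up (gap in b) > left (gap in a),
//     and within a gap state the predecessor preference is M > X > Y,
//     so alignments are reproducible;
//   * identity is all-columns: matches / alignment columns, terminal
//     gap columns included.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct AlnResult {
  double score;
  int columns;
  int matches;
  std::string aligned_a;
  std::string aligned_b;
};

// state codes: 0 = M (diagonal), 1 = X (up, consumes a), 2 = Y (left, consumes b)
static AlnResult nw_core(const char* a, int la, const char* b, int lb,
                         double match, double mismatch,
                         double go, double ge, bool traceback) {
  const int W = lb + 1;
  std::vector<double> M((la + 1) * W, NEG_INF), X((la + 1) * W, NEG_INF),
      Y((la + 1) * W, NEG_INF);
  std::vector<unsigned char> tbM, tbX, tbY;
  if (traceback) {
    tbM.assign((la + 1) * W, 0);
    tbX.assign((la + 1) * W, 0);
    tbY.assign((la + 1) * W, 0);
  }
  M[0] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[i * W] = go + i * ge;
    if (traceback) tbX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= lb; ++j) {
    Y[j] = go + j * ge;
    if (traceback) tbY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= la; ++i) {
    const int row = i * W, prow = (i - 1) * W;
    for (int j = 1; j <= lb; ++j) {
      // M: diagonal step, predecessor preference M > X > Y
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double bm = M[prow + j - 1];
      unsigned char st = 0;
      if (X[prow + j - 1] > bm) { bm = X[prow + j - 1]; st = 1; }
      if (Y[prow + j - 1] > bm) { bm = Y[prow + j - 1]; st = 2; }
      M[row + j] = (bm == NEG_INF) ? NEG_INF : bm + s;
      if (traceback) tbM[row + j] = st;
      // X: gap in b (vertical); extending X is cheaper than re-opening
      double vm = M[prow + j] + go + ge;
      st = 0;
      if (X[prow + j] + ge > vm) { vm = X[prow + j] + ge; st = 1; }
      if (Y[prow + j] + go + ge > vm) { vm = Y[prow + j] + go + ge; st = 2; }
      X[row + j] = vm;
      if (traceback) tbX[row + j] = st;
      // Y: gap in a (horizontal)
      double hm = M[row + j - 1] + go + ge;
      st = 0;
      if (X[row + j - 1] + go + ge > hm) { hm = X[row + j - 1] + go + ge; st = 1; }
      if (Y[row + j - 1] + ge > hm) { hm = Y[row + j - 1] + ge; st = 2; }
      Y[row + j] = hm;
      if (traceback) tbY[row + j] = st;
    }
  }
  AlnResult res;
  const int end = la * W + lb;
  unsigned char state = 0;
  res.score = M[end];
  if (X[end] > res.score) { res.score = X[end]; state = 1; }
  if (Y[end] > res.score) { res.score = Y[end]; state = 2; }
  res.columns = 0;
  res.matches = 0;
  if (!traceback) return res;

  std::string ra, rb;
  ra.reserve(la + lb);
  rb.reserve(la + lb);
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char prev = tbM[i * W + j];
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++res.matches;
      --i; --j;
      state = prev;
    } else if (state == 1) {
      unsigned char prev = tbX[i * W + j];
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      state = prev;
    } else {
      unsigned char prev = tbY[i * W + j];
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
      state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  res.aligned_a = ra;
  res.aligned_b = rb;
  res.columns = (int)ra.size();
  return res;
}

// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend) {
  AlnResult r = nw_core(a.c_str(), a.size(), b.c_str(), b.size(),
                        match, mismatch, gap_open, gap_extend, true);
  return List::create(_["aligned_a"] = r.aligned_a, _["aligned_b"] = r.aligned_b,
                      _["score"] = r.score, _["columns"] = r.columns,
                      _["matches"] = r.matches);
}

// Banded Levenshtein; returns -1 when the distance exceeds max_d.
// max_d < 0 computes the unbanded distance.
static int edit_core(const char* a, int la, const char* b, int lb, int max_d) {
  if (la < lb) { std::swap(a, b); std::swap(la, lb); }
  if (max_d >= 0 && la - lb > max_d) return -1;
  const int band = (max_d >= 0) ? max_d : la;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  const int BIG = la + lb + 1;
  for (int j = 0; j <= lb; ++j) prev[j] = (j <= band) ? j : BIG;
  for (int i = 1; i <= la; ++i) {
    int lo = (max_d >= 0) ? std::max(1, i - band) : 1;
    int hi = (max_d >= 0) ? std::min(lb, i + band) : lb;
    cur[lo - 1] = (lo == 1) ? i : BIG;
    int rowmin = cur[lo - 1];
    for (int j = lo; j <= hi; ++j) {
      int d = prev[j - 1] + ((a[i - 1] == b[j - 1]) ? 0 : 1);
      int up = (prev[j] < BIG) ? prev[j] + 1 : BIG;
      int left = (cur[j - 1] < BIG) ? cur[j - 1] + 1 : BIG;
      cur[j] = std::min(d, std::min(up, left));
      if (cur[j] < rowmin) rowmin = cur[j];
    }
    if (hi < lb) cur[hi + 1] = BIG;
    if (max_d >= 0 && rowmin > max_d) return -1;
    std::swap(prev, cur);
  }
  int d = prev[lb];
  if (max_d >= 0 && d > max_d) return -1;
  return d;
}

// [[Rcpp::export]]
IntegerVector cpp_edit_distance(CharacterVector a, CharacterVector b, int max_d) {
  const int n = a.size();
  if (b.size() != n) stop("sequence vectors must have equal length");
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string sa = as<std::string>(a[k]), sb = as<std::string>(b[k]);
    out[k] = edit_core(sa.c_str(), sa.size(), sb.c_str(), sb.size(), max_d);
  }
  return out;
}

// All-columns identity for one pair (helper for matrix/edge builders).
// The pair is canonically oriented (lexicographically smaller sequence
// first) so that identity is exactly symmetric even when co-optimal
// alignments differ in match count.
static double pair_identity(const std::string& a, const std::string& b,
                            double match, double mismatch, double go, double ge) {
  const std::string* p = &a;
  const std::string* q = &b;
  if (b < a) std::swap(p, q);
  AlnResult r = nw_core(p->c_str(), p->size(), q->c_str(), q->size(),
                        match, mismatch, go, ge, true);
  return (double)r.matches / (double)r.columns;
}

// Exact pre-filter: in any global alignment with m matches and L' >= L
// (Levenshtein) non-match columns, identity = m/(m+L') <= m/(m+L)
// <= min(la,lb)/(min(la,lb)+L). So identity >= t forces
// L <= min(la,lb) * (1-t)/t, and pairs failing the banded check at that
// cutoff cannot reach the threshold.
static int prefilter_cutoff(int la, int lb, double t) {
  int mn = std::min(la, lb);
  return (int)std::floor(mn * (1.0 - t) / t + 1e-9);
}

// [[Rcpp::export]]
DataFrame cpp_similarity_edges(CharacterVector seqs, double t, double match,
                               double mismatch, double gap_open, double gap_extend) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  std::vector<int> ia, ja;
  std::vector<double> idv;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int cutoff = prefilter_cutoff(s[i].size(), s[j].size(), t);
      if (edit_core(s[i].c_str(), s[i].size(), s[j].c_str(), s[j].size(),
                    cutoff) < 0)
        continue;
      double id = pair_identity(s[i], s[j], match, mismatch, gap_open, gap_extend);
      if (id >= t - 1e-9) {
        ia.push_back(i + 1);
        ja.push_back(j + 1);
        idv.push_back(id);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["i"] = ia, _["j"] = ja, _["identity"] = idv);
}

// [[Rcpp::export]]
NumericMatrix cpp_identity_matrix(CharacterVector q, CharacterVector r,
                                  double match, double mismatch,
                                  double gap_open, double gap_extend) {
  const int nq = q.size(), nr = r.size();
  std::vector<std::string> sq(nq), sr(nr);
  for (int i = 0; i < nq; ++i) sq[i] = as<std::string>(q[i]);
  for (int j = 0; j < nr; ++j) sr[j] = as<std::string>(r[j]);
  NumericMatrix out(nq, nr);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j)
      out(i, j) = pair_identity(sq[i], sr[j], match, mismatch, gap_open, gap_extend);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_pairs_within_d(CharacterVector seqs, int d) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  std::vector<int> ia, ja, dv;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int dist = edit_core(s[i].c_str(), s[i].size(), s[j].c_str(), s[j].size(), d);
      if (dist >= 0) {
        ia.push_back(i + 1);
        ja.push_back(j + 1);
        dv.push_back(dist);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["i"] = ia, _["j"] = ja, _["dist"] = dv);
}

// Greedy centroid clustering over sequences already sorted by decreasing
// abundance (ties by id). Each sequence joins the existing centroid of
// maximal identity when that identity reaches t (ties -> earliest-created
// centroid), otherwise founds a new OTU.
// [[Rcpp::export]]
List cpp_greedy_cluster(CharacterVector seqs, double t, double match,
                        double mismatch, double gap_open, double gap_extend) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  IntegerVector otu(n);
  LogicalVector is_centroid(n);
  NumericVector cid(n);
  std::vector<int> centroids;
  for (int i = 0; i < n; ++i) {
    int best = -1;
    double best_id = -1.0;
    for (size_t c = 0; c < centroids.size(); ++c) {
      const std::string& sc = s[centroids[c]];
      int cutoff = prefilter_cutoff(s[i].size(), sc.size(), t);
      if (edit_core(s[i].c_str(), s[i].size(), sc.c_str(), sc.size(), cutoff) < 0)
        continue;
      double id = pair_identity(s[i], sc, match, mismatch, gap_open, gap_extend);
      if (id >= t - 1e-9 && id > best_id + 1e-12) {
        best_id = id;
        best = (int)c;
      }
    }
    if (best >= 0) {
      otu[i] = best + 1;
      is_centroid[i] = false;
      cid[i] = best_id;
    } else {
      centroids.push_back(i);
      otu[i] = (int)centroids.size();
      is_centroid[i] = true;
      cid[i] = 1.0;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["otu"] = otu, _["is_centroid"] = is_centroid,
                      _["centroid_identity"] = cid);
}
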