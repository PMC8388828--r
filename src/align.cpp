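#include <Rcpp.h>
#include <climits>
#include <cmath>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) over integer-coded sequences with an
// arbitrary substitution matrix. Gap of length L costs gap_open + L * gap_extend
// (BLAST convention). Multiple HSPs are recovered Waterman-Eggert style by
// masking the subject span of each reported alignment and re-running the DP,
// so reported HSPs never overlap on the subject.

namespace {

struct Hsp {
  int qs, qe, ss, se;       // 0-based inclusive
  double score;
  int length, matches, mismatches, gapopens;
};

const int NEG = INT_MIN / 4;

// traceback byte: bits 0-1 = H origin (0 stop, 1 diag, 2 E, 3 F),
// bit 2 = E extends, bit 3 = F extends
struct Workspace {
  std::vector<int> H, Hrow, F;
  std::vector<unsigned char> tb;
};

// One DP pass + traceback of the single best alignment. Integer scores.
// scol holds subject codes with masked positions redirected to a sentinel
// column of the substitution matrix, keeping the inner loop branch-light.
bool sw_once(const std::vector<int>& q, const std::vector<int>& s,
             const std::vector<int>& sub, int nalpha, int gap_open,
             int gap_extend, const std::vector<int>& scol,
             Workspace& w, Hsp& out) {
  const int m = q.size(), n = s.size();
  if (m == 0 || n == 0) return false;
  const int gof = gap_open + gap_extend;

  w.H.assign(n + 1, 0);
  w.Hrow.assign(n + 1, 0);
  w.F.assign(n + 1, NEG);
  w.tb.assign((size_t)(m + 1) * (n + 1), 0);

  int best = 0;
  int bi = -1, bj = -1;

  for (int i = 1; i <= m; ++i) {
    const int* subrow = &sub[(size_t)q[i - 1] * (nalpha + 1)];
    int Hdiag = 0, Hleft = 0, Ecur = NEG;
    unsigned char* tbi = &w.tb[(size_t)i * (n + 1)];
    const int* Hprev = w.H.data();
    int* Hcur = w.Hrow.data();
    int* Fv = w.F.data();
    const int* sc_ = scol.data();
    for (int j = 1; j <= n; ++j) {
      int e_open = Hleft - gof;
      int e_ext = Ecur - gap_extend;
      unsigned char te = (unsigned char)(e_ext > e_open) << 2;
      Ecur = e_ext > e_open ? e_ext : e_open;
      int f_open = Hprev[j] - gof;
      int f_ext = Fv[j] - gap_extend;
      unsigned char tf = (unsigned char)(f_ext > f_open) << 3;
      int f = f_ext > f_open ? f_ext : f_open;
      Fv[j] = f;
      int sc = Hdiag + subrow[sc_[j - 1]];
      int h = 0;
      unsigned char to = 0;
      if (sc > h) { h = sc; to = 1; }
      if (Ecur > h) { h = Ecur; to = 2; }
      if (f > h) { h = f; to = 3; }
      Hcur[j] = h;
      tbi[j] = (unsigned char)(te | tf | to);
      if (h > best) { best = h; bi = i; bj = j; }
      Hdiag = Hprev[j];
      Hleft = h;
    }
    std::swap(w.H, w.Hrow);
  }

  if (bi < 0 || best <= 0) return false;

  int i = bi, j = bj;
  int matches = 0, mism = 0, gapopens = 0, len = 0;
  int state = 0;
  while (i > 0 && j > 0) {
    unsigned char t = w.tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      unsigned char o = t & 3;
      if (o == 0) break;
      if (o == 1) {
        ++len;
        if (q[i - 1] == s[j - 1]) ++matches; else ++mism;
        --i; --j;
      } else if (o == 2) state = 2;
      else state = 3;
    } else if (state == 2) {  // gap consuming subject
      ++len;
      if (!(t & 4)) { ++gapopens; state = 0; }
      --j;
    } else {                  // gap consuming query
      ++len;
      if (!(t & 8)) { ++gapopens; state = 0; }
      --i;
    }
  }
  out.qs = i; out.qe = bi - 1; out.ss = j; out.se = bj - 1;
  out.score = best; out.length = len;
  out.matches = matches; out.mismatches = mism; out.gapopens = gapopens;
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".sw_hsps")]]
DataFrame sw_hsps(IntegerVector query, IntegerVector subject, NumericMatrix sub,
                  double gap_open, double gap_extend, double min_score,
                  int max_hits) {
  std::vector<int> q(query.begin(), query.end());
  std::vector<int> s(subject.begin(), subject.end());
  if ((double)q.size() * (double)s.size() > 6.4e7)
    stop("sequences too long for exhaustive DP (%d x %d cells); use the seeded search",
         (int)q.size(), (int)s.size());
  const int nalpha = sub.nrow();
  // scores are integral in every supported scheme; the DP runs on ints.
  // An extra sentinel column (index nalpha) carries the masking penalty.
  std::vector<int> subflat((size_t)nalpha * (nalpha + 1));
  for (int a = 0; a < nalpha; ++a) {
    for (int b = 0; b < sub.ncol(); ++b) {
      double v = sub(a, b);
      int iv = (int)std::lround(v);
      if (std::abs(v - iv) > 1e-9) stop("substitution scores must be integers");
      subflat[(size_t)a * (nalpha + 1) + b] = iv;
    }
    subflat[(size_t)a * (nalpha + 1) + nalpha] = -100000;
  }
  for (size_t i = 0; i < q.size(); ++i)
    if (q[i] < 0 || q[i] >= nalpha) stop("query code out of range");
  for (size_t i = 0; i < s.size(); ++i)
    if (s[i] < 0 || s[i] >= nalpha) stop("subject code out of range");
  int igo = (int)std::lround(gap_open), ige = (int)std::lround(gap_extend);
  std::vector<int> scol(s.begin(), s.end());
  Workspace w;
  std::vector<Hsp> hits;
  for (int h = 0; h < max_hits; ++h) {
    Hsp hsp;
    if (!sw_once(q, s, subflat, nalpha, igo, ige, scol, w, hsp))
      break;
    if (hsp.score < min_score) break;
    hits.push_back(hsp);
    for (int p = hsp.ss; p <= hsp.se; ++p) scol[p] = nalpha;
  }
  int k = hits.size();
  IntegerVector qs(k), qe(k), ss(k), se(k), length(k), matches(k), mism(k), go(k);
  NumericVector score(k);
  for (int i = 0; i < k; ++i) {
    qs[i] = hits[i].qs + 1; qe[i] = hits[i].qe + 1;
    ss[i] = hits[i].ss + 1; se[i] = hits[i].se + 1;
    score[i] = hits[i].score; length[i] = hits[i].length;
    matches[i] = hits[i].matches; mism[i] = hits[i].mismatches;
    go[i] = hits[i].gapopens;
  }
  return DataFrame::create(
      _["qstart"] = qs, _["qend"] = qe, _["sstart"] = ss, _["send"] = se,
      _["raw_score"] = score, _["length"] = length, _["matches"] = matches,
      _["mismatches"] = mism, _["gapopen"] = go);
}

// Exact k-mer seed positions shared by query and subject (codes 0..3 only;
// positions containing any other code are skipped). Returns 1-based starts.
// [[Rcpp::export(name = ".kmer_seeds")]]
IntegerMatrix kmer_seeds(IntegerVector query, IntegerVector subject, int k) {
  const int m = query.size(), n = subject.size();
  if (k < 1 || k > 15 || m < k || n < k) return IntegerMatrix(0, 2);
  std::unordered_multimap<uint64_t, int> qmap;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t key = 0;
  int run = 0;
  for (int i = 0; i < m; ++i) {
    int c = query[i];
    if (c < 0 || c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) qmap.insert({key, i - k + 1});
  }
  std::vector<int> qpos, spos;
  key = 0; run = 0;
  for (int j = 0; j < n; ++j) {
    int c = subject[j];
    if (c < 0 || c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      auto range = qmap.equal_range(key);
      for (auto it = range.first; it != range.second; ++it) {
        qpos.push_back(it->second + 1);
        spos.push_back(j - k + 2);
      }
    }
  }
  IntegerMatrix out(qpos.size(), 2);
  for (size_t i = 0; i < qpos.size(); ++i) {
    out(i, 0) = qpos[i];
    out(i, 1) = spos[i];
  }
  return out;
}

// Batch variant: seeds of many queries against one subject, hashing the
// subject once. Returns a list of 2-column matrices (qpos, spos), one per
// query.
// [[Rcpp::export(name = ".kmer_seeds_batch")]]
List kmer_seeds_batch(List queries, IntegerVector subject, int k) {
  const int n = subject.size();
  const int nq = queries.size();
  List out(nq);
  if (k < 1 || k > 15 || n < k) {
    for (int qi = 0; qi < nq; ++qi) out[qi] = IntegerMatrix(0, 2);
    return out;
  }
  std::unordered_multimap<uint64_t, int> smap;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t key = 0;
  int run = 0;
  for (int j = 0; j < n; ++j) {
    int c = subject[j];
    if (c < 0 || c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) smap.insert({key, j - k + 1});
  }
  for (int qi = 0; qi < nq; ++qi) {
    IntegerVector q = queries[qi];
    const int m = q.size();
    std::vector<int> qpos, spos;
    key = 0; run = 0;
    for (int i = 0; i < m; ++i) {
      int c = q[i];
      if (c < 0 || c > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto range = smap.equal_range(key);
        for (auto it = range.first; it != range.second; ++it) {
          qpos.push_back(i - k + 2);
          spos.push_back(it->second + 1);
        }
      }
    }
    IntegerMatrix mat(qpos.size(), 2);
    for (size_t i = 0; i < qpos.size(); ++i) {
      mat(i, 0) = qpos[i];
      mat(i, 1) = spos[i];
    }
    out[qi] = mat;
  }
  return out;
}
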