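// Local-alignment kernels: exact affine-gap Smith-Waterman (the oracle)
// and BLAST-style seed-and-extend search with X-drop extension.
// A gap of length k costs gap_open + k * gap_extend.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int enc(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;  // N or anything else: never matches
  }
}

struct AlnResult {
  int score = 0;
  int qs = 0, qe = -1, ss = 0, se = -1;  // 0-based inclusive, empty if qe<qs
  std::string qa, sa;
};

// exact O(nm) local DP with traceback; three states:
// 1 = H (aligned pair), 2 = X (gap in subject), 3 = Y (gap in query)
static AlnResult sw_core(const std::string& a, const std::string& b,
                         int reward, int penalty, int go, int ge) {
  const int n = (int)a.size(), m = (int)b.size();
  const int NEG = -(1 << 28);
  const int open_cost = go + ge;
  std::vector<int> Hm((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> Xm((size_t)(n + 1) * (m + 1), NEG);
  std::vector<int> Ym((size_t)(n + 1) * (m + 1), NEG);
  std::vector<uint8_t> tH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tX((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tY((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int ea = enc(a[i - 1]);
    size_t r = (size_t)i * (m + 1), rp = (size_t)(i - 1) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      int s = (ea >= 0 && ea == enc(b[j - 1])) ? reward : penalty;
      int x1 = Hm[rp + j] - open_cost, x2 = Xm[rp + j] - ge;
      if (x1 >= x2) { Xm[r + j] = x1; tX[r + j] = 1; }
      else          { Xm[r + j] = x2; tX[r + j] = 2; }
      int y1 = Hm[r + j - 1] - open_cost, y2 = Ym[r + j - 1] - ge;
      if (y1 >= y2) { Ym[r + j] = y1; tY[r + j] = 1; }
      else          { Ym[r + j] = y2; tY[r + j] = 3; }
      int d = Hm[rp + j - 1], from = 1;
      if (Xm[rp + j - 1] > d) { d = Xm[rp + j - 1]; from = 2; }
      if (Ym[rp + j - 1] > d) { d = Ym[rp + j - 1]; from = 3; }
      int h = d + s;
      if (h <= 0) { Hm[r + j] = 0; tH[r + j] = 0; }
      else { Hm[r + j] = h; tH[r + j] = (uint8_t)from; }
      if (Hm[r + j] > best) { best = Hm[r + j]; bi = i; bj = j; }
    }
  }
  AlnResult res;
  res.score = best;
  if (best <= 0) return res;
  int i = bi, j = bj, state = 1;
  std::string qa, sa;
  res.qe = bi - 1; res.se = bj - 1;
  while (i > 0 || j > 0) {
    size_t r = (size_t)i * (m + 1);
    if (state == 1) {
      uint8_t f = tH[r + j];
      if (f == 0) break;
      qa.push_back(a[i - 1]); sa.push_back(b[j - 1]);
      --i; --j; state = f;
      // predecessor H cell may be the zero start; next iteration breaks
      if (state == 1 && tH[(size_t)i * (m + 1) + j] == 0) break;
    } else if (state == 2) {
      qa.push_back(a[i - 1]); sa.push_back('-');
      uint8_t f = tX[r + j];
      --i; state = (f == 1) ? 1 : 2;
    } else {
      qa.push_back('-'); sa.push_back(b[j - 1]);
      uint8_t f = tY[r + j];
      --j; state = (f == 1) ? 1 : 3;
    }
  }
  res.qs = i; res.ss = j;
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  res.qa = qa; res.sa = sa;
  return res;
}

// [[Rcpp::export]]
List cpp_smith_waterman(std::string a, std::string b, int reward, int penalty,
                        int gap_open, int gap_extend) {
  double cells = (double)a.size() * (double)b.size();
  if (cells > 6.4e7)
    stop("sequences too long for exact local DP (%.0f cells)", cells);
  AlnResult r = sw_core(a, b, reward, penalty, gap_open, gap_extend);
  bool empty = r.score <= 0;
  return List::create(
    _["score"] = r.score,
    _["q_start"] = empty ? NA_INTEGER : r.qs + 1,
    _["q_end"] = empty ? NA_INTEGER : r.qe + 1,
    _["s_start"] = empty ? NA_INTEGER : r.ss + 1,
    _["s_end"] = empty ? NA_INTEGER : r.se + 1,
    _["q_aln"] = empty ? "" : r.qa,
    _["s_aln"] = empty ? "" : r.sa);
}

struct Hsp {
  int qs, qe, ss, se, score;
  double pident;
  std::string qa, sa;
};

static double aln_identity(const std::string& qa, const std::string& sa) {
  int match = 0;
  for (size_t k = 0; k < qa.size(); ++k)
    if (qa[k] == sa[k] && qa[k] != '-' && enc(qa[k]) >= 0) ++match;
  return qa.empty() ? 0.0 : 100.0 * match / (double)qa.size();
}

// ungapped X-drop extension from a seed [qi, qi+W) / [sj, sj+W)
static void ungapped_extend(const std::vector<int>& qa,
                            const std::vector<int>& sa,
                            int qi, int sj, int W, int reward, int penalty,
                            int xdrop, int& qs, int& qe, int& ss, int& se,
                            int& score) {
  int base = W * reward;
  int cur = 0, bestr = 0, len = 0, bestlen = 0;
  int i = qi + W, j = sj + W;
  while (i < (int)qa.size() && j < (int)sa.size()) {
    cur += (qa[i] >= 0 && qa[i] == sa[j]) ? reward : penalty;
    ++len;
    if (cur > bestr) { bestr = cur; bestlen = len; }
    if (bestr - cur > xdrop) break;
    ++i; ++j;
  }
  cur = 0; int bestl = 0, lenl = 0, bestlenl = 0;
  i = qi - 1; j = sj - 1;
  while (i >= 0 && j >= 0) {
    cur += (qa[i] >= 0 && qa[i] == sa[j]) ? reward : penalty;
    ++lenl;
    if (cur > bestl) { bestl = cur; bestlenl = lenl; }
    if (bestl - cur > xdrop) break;
    --i; --j;
  }
  score = base + bestr + bestl;
  qs = qi - bestlenl; qe = qi + W - 1 + bestlen;
  ss = sj - bestlenl; se = sj + W - 1 + bestlen;
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string query, std::string subject, int W,
                          int reward, int penalty, int gap_open,
                          int gap_extend, int xdrop, int min_score,
                          double min_pident, int ungapped_trigger, int pad) {
  const int n = (int)query.size(), m = (int)subject.size();
  std::vector<Hsp> hsps;
  if (n >= W && m >= W) {
    std::vector<int> q(n), s(m);
    for (int i = 0; i < n; ++i) q[i] = enc(query[i]);
    for (int j = 0; j < m; ++j) s[j] = enc(subject[j]);
    std::unordered_map<uint64_t, std::vector<int>> index;
    uint64_t code = 0, mask = (W >= 32) ? ~0ULL : ((1ULL << (2 * W)) - 1);
    int run = 0;
    for (int j = 0; j < m; ++j) {
      if (s[j] < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)s[j]) & mask;
      if (++run >= W) index[code].emplace_back(j - W + 1);
    }
    // per-diagonal extent already covered by an ungapped extension
    std::unordered_map<int, int> diag_cover;
    code = 0; run = 0;
    for (int i = 0; i < n; ++i) {
      if (q[i] < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)q[i]) & mask;
      if (++run < W) continue;
      int qi = i - W + 1;
      auto hit = index.find(code);
      if (hit == index.end()) continue;
      for (int sj : hit->second) {
        int diag = qi - sj;
        auto dc = diag_cover.find(diag);
        if (dc != diag_cover.end() && qi + W - 1 <= dc->second) continue;
        int qs, qe, ss, se, usc;
        ungapped_extend(q, s, qi, sj, W, reward, penalty, xdrop,
                        qs, qe, ss, se, usc);
        diag_cover[diag] = qe;
        if (usc < ungapped_trigger) continue;
        bool inside = false;
        for (const Hsp& h : hsps)
          if (qs >= h.qs - 3 && qe <= h.qe + 3 &&
              ss >= h.ss - 3 && se <= h.se + 3) { inside = true; break; }
        if (inside) continue;
        // gapped stage: local DP in a window around the ungapped HSP,
        // re-expanding while the optimum touches the window boundary
        int p = pad;
        for (int iter = 0; iter < 4; ++iter) {
          int wqs = std::max(0, qs - p), wqe = std::min(n - 1, qe + p);
          int wss = std::max(0, ss - p), wse = std::min(m - 1, se + p);
          double cells = (double)(wqe - wqs + 1) * (double)(wse - wss + 1);
          if (cells > 6.4e7) break;
          AlnResult r = sw_core(query.substr(wqs, wqe - wqs + 1),
                                subject.substr(wss, wse - wss + 1),
                                reward, penalty, gap_open, gap_extend);
          if (r.score <= 0) break;
          bool touch =
            ((r.qs <= 2 && wqs > 0) || (r.qe >= wqe - wqs - 2 && wqe < n - 1) ||
             (r.ss <= 2 && wss > 0) || (r.se >= wse - wss - 2 && wse < m - 1));
          if (touch && iter < 3) { p *= 3; continue; }
          Hsp h;
          h.qs = wqs + r.qs; h.qe = wqs + r.qe;
          h.ss = wss + r.ss; h.se = wss + r.se;
          h.score = r.score; h.qa = r.qa; h.sa = r.sa;
          h.pident = aln_identity(r.qa, r.sa);
          if (h.score >= min_score && h.pident >= min_pident)
            hsps.push_back(std::move(h));
          break;
        }
      }
    }
  }
  std::sort(hsps.begin(), hsps.end(),
            [](const Hsp& a, const Hsp& b) { return a.score > b.score; });
  std::vector<Hsp> keep;
  for (const Hsp& h : hsps) {
    bool dup = false;
    for (const Hsp& k : keep)
      if (h.qs >= k.qs - 3 && h.qe <= k.qe + 3 &&
          h.ss >= k.ss - 3 && h.se <= k.se + 3) { dup = true; break; }
    if (!dup) keep.push_back(h);
  }
  int N = (int)keep.size();
  IntegerVector qs(N), qe(N), ss(N), se(N), sc(N);
  NumericVector pid(N);
  CharacterVector qa(N), sa(N);
  for (int k = 0; k < N; ++k) {
    qs[k] = keep[k].qs + 1; qe[k] = keep[k].qe + 1;
    ss[k] = keep[k].ss + 1; se[k] = keep[k].se + 1;
    sc[k] = keep[k].score; pid[k] = keep[k].pident;
    qa[k] = keep[k].qa; sa[k] = keep[k].sa;
  }
  return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                           _["s_start"] = ss, _["s_end"] = se,
                           _["score"] = sc, _["pident"] = pid,
                           _["q_aln"] = qa, _["s_aln"] = sa,
                           _["stringsAsFactors"] = false);
}
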