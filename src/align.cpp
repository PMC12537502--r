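// Seed-and-extend local alignment for short nucleotide sequences.
// Exact word seeds, ungapped X-drop extension, then affine-gap extension
// from both segment ends. Scoring is match/mismatch with affine gap costs
// (positive costs subtracted); ambiguity codes score as mismatches.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct Hit {
  int qstart, qend, sstart, send; // 0-based half-open
  double score;
  int core_len, core_ident;
};

// affine-gap extension score from an anchor, forward over q[0..m) vs
// s[0..n): best score of any alignment of prefixes starting at the anchor.
// Returns score and the prefix lengths attaining it.
static void gapped_extend(const std::vector<int>& q, int q0, int qdir,
                          const std::vector<int>& s, int s0, int sdir,
                          int max_ext, double match, double mismatch,
                          double gap_open, double gap_extend, double xdrop,
                          double& best, int& bq, int& bs) {
  int m = 0, n = 0;
  // collect up to max_ext codes in the given direction
  std::vector<int> qq, ss;
  for (int i = 0; i < max_ext; ++i) {
    int idx = q0 + qdir * i;
    if (idx < 0 || idx >= (int)q.size()) break;
    qq.push_back(q[idx]);
  }
  for (int i = 0; i < max_ext; ++i) {
    int idx = s0 + sdir * i;
    if (idx < 0 || idx >= (int)s.size()) break;
    ss.push_back(s[idx]);
  }
  m = qq.size(); n = ss.size();
  best = 0.0; bq = 0; bs = 0;
  if (m == 0 || n == 0) return;
  const double NEG = -1e18;
  std::vector<double> H(n + 1), E(n + 1), Hprev(n + 1), Eprev(n + 1);
  // row 0: query gap of length j
  Hprev[0] = 0.0; Eprev[0] = NEG;
  for (int j = 1; j <= n; ++j) {
    Hprev[j] = -(gap_open + gap_extend * j);
    Eprev[j] = NEG;
  }
  double F;
  for (int i = 1; i <= m; ++i) {
    H[0] = -(gap_open + gap_extend * i);
    E[0] = NEG;
    F = NEG;
    double row_best = NEG;
    for (int j = 1; j <= n; ++j) {
      double sub = (qq[i - 1] >= 0 && qq[i - 1] == ss[j - 1]) ? match
        : mismatch;
      E[j] = std::max(Eprev[j] - gap_extend, Hprev[j] - gap_open - gap_extend);
      F = std::max(F - gap_extend, H[j - 1] - gap_open - gap_extend);
      H[j] = std::max(Hprev[j - 1] + sub, std::max(E[j], F));
      if (H[j] > best) { best = H[j]; bq = i; bs = j; }
      if (H[j] > row_best) row_best = H[j];
    }
    if (row_best < best - xdrop) break; // X-drop on the whole row
    std::swap(H, Hprev);
    std::swap(E, Eprev);
  }
  if (best < 0) { best = 0; bq = 0; bs = 0; }
}

// [[Rcpp::export(name = ".seed_extend_align_cpp")]]
DataFrame seed_extend_align_cpp(std::string query, std::string subject,
                                int word, double match, double mismatch,
                                double gap_open, double gap_extend,
                                double xdrop, double min_ungapped,
                                int max_ext) {
  int m = query.size(), n = subject.size();
  std::vector<Hit> hits;
  if (m >= word && n >= word) {
    std::vector<int> q(m), s(n);
    for (int i = 0; i < m; ++i) q[i] = base_code(query[i]);
    for (int i = 0; i < n; ++i) s[i] = base_code(subject[i]);

    // index subject words
    std::unordered_map<long, std::vector<int> > index;
    long mask = 1;
    for (int i = 0; i < word; ++i) mask *= 4;
    long key = 0; int valid = 0;
    for (int i = 0; i < n; ++i) {
      if (s[i] < 0) { valid = 0; key = 0; continue; }
      key = (key * 4 + s[i]) % mask;
      if (++valid >= word) index[key].push_back(i - word + 1);
    }
    // per-diagonal furthest extension, to skip covered seeds
    std::unordered_map<long, int> diag_end;
    key = 0; valid = 0;
    for (int i = 0; i < m; ++i) {
      if (q[i] < 0) { valid = 0; key = 0; continue; }
      key = (key * 4 + q[i]) % mask;
      if (++valid < word) continue;
      int qp = i - word + 1;
      auto it = index.find(key);
      if (it == index.end()) continue;
      for (int sp : it->second) {
        long diag = (long)sp - qp + m; // shifted to stay positive
        auto de = diag_end.find(diag);
        if (de != diag_end.end() && qp < de->second) continue;
        // ungapped X-drop extension around the seed
        int lq = qp, ls = sp;            // inclusive left ends
        int rq = qp + word - 1, rs = sp + word - 1; // inclusive right ends
        double score = word * match;     // exact word match
        double bestsc = score;
        int brq = rq, brs = rs;
        // right
        {
          double cur = score;
          int iq = rq + 1, is = rs + 1;
          while (iq < m && is < n) {
            cur += (q[iq] >= 0 && q[iq] == s[is]) ? match : mismatch;
            if (cur > bestsc) { bestsc = cur; brq = iq; brs = is; }
            if (cur < bestsc - xdrop) break;
            ++iq; ++is;
          }
        }
        // left
        double bestsc2 = bestsc;
        int blq = lq, bls = ls;
        {
          double cur = bestsc;
          int iq = lq - 1, is = ls - 1;
          while (iq >= 0 && is >= 0) {
            cur += (q[iq] >= 0 && q[iq] == s[is]) ? match : mismatch;
            if (cur > bestsc2) { bestsc2 = cur; blq = iq; bls = is; }
            if (cur < bestsc2 - xdrop) break;
            --iq; --is;
          }
        }
        diag_end[diag] = brq + 1;
        if (bestsc2 < min_ungapped) continue;
        // count core identity on the ungapped segment
        int core_len = brq - blq + 1, core_ident = 0;
        for (int t = 0; t < core_len; ++t) {
          if (q[blq + t] >= 0 && q[blq + t] == s[bls + t]) ++core_ident;
        }
        // gapped extensions beyond both ends
        double lsc, rsc; int lbq, lbs, rbq, rbs;
        gapped_extend(q, blq - 1, -1, s, bls - 1, -1, max_ext, match,
                      mismatch, gap_open, gap_extend, xdrop, lsc, lbq, lbs);
        gapped_extend(q, brq + 1, +1, s, brs + 1, +1, max_ext, match,
                      mismatch, gap_open, gap_extend, xdrop, rsc, rbq, rbs);
        Hit h;
        h.qstart = blq - lbq;
        h.sstart = bls - lbs;
        h.qend = brq + rbq + 1;
        h.send = brs + rbs + 1;
        h.score = bestsc2 + lsc + rsc;
        h.core_len = core_len;
        h.core_ident = core_ident;
        hits.push_back(h);
      }
    }
  }
  // greedily keep non-overlapping locally optimal hits (by score)
  std::sort(hits.begin(), hits.end(),
            [](const Hit& a, const Hit& b) {
              if (a.score != b.score) return a.score > b.score;
              return a.sstart < b.sstart;
            });
  std::vector<Hit> kept;
  for (const Hit& h : hits) {
    bool clash = false;
    for (const Hit& k : kept) {
      bool qov = h.qstart < k.qend && k.qstart < h.qend;
      bool sov = h.sstart < k.send && k.sstart < h.send;
      if (qov || sov) { clash = true; break; }
    }
    if (!clash) kept.push_back(h);
  }
  int nk = kept.size();
  IntegerVector qs(nk), qe(nk), ssv(nk), se(nk), cl(nk), ci(nk);
  NumericVector sc(nk);
  for (int i = 0; i < nk; ++i) {
    qs[i] = kept[i].qstart; qe[i] = kept[i].qend;
    ssv[i] = kept[i].sstart; se[i] = kept[i].send;
    sc[i] = kept[i].score;
    cl[i] = kept[i].core_len; ci[i] = kept[i].core_ident;
  }
  return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                           _["sstart"] = ssv, _["send"] = se,
                           _["score"] = sc, _["core_len"] = cl,
                           _["core_ident"] = ci);
}
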