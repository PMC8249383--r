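#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Shared helpers ------------------------------------------------------------

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'X': return 'X';   // hard mask: no alignment may cross it
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

// Watson-Crick pair between two genomic bases (N never pairs)
static inline bool wc_pair(char a, char b) {
  return a != 'N' && b != 'N' && b == comp(a);
}

struct Cand {
  int l1, l2, r1, r2;   // 1-based arm coordinates (left arm, right arm)
  int score;
  std::string aln_left, aln_right; // right arm given 3'->5' so columns pair
};

// Inverted-repeat scan ------------------------------------------------------
//
// einverted-style detection: local alignment of a window T against its own
// reverse complement R, with the left arm constrained to precede the right
// arm. Per cell we track the alignment start so the repeat span
// (right arm end - left arm start + 1) is known at acceptance time; ties in
// score prefer the smaller span (larger start-coordinate sum), then the
// leftmost start.

static void scan_window(const std::string &T, int off,
                        int match, int mismatch, int gap,
                        int min_score, int max_span,
                        std::vector<Cand> &out) {
  const int W = (int) T.size();
  const std::string R = revcomp_str(T);
  // matrices: H score, SI/SJ start cell, PTR traceback (0 stop,1 diag,2 up,3 left)
  std::vector<int> H((W + 1) * (W + 1), 0), SI((W + 1) * (W + 1), 0),
    SJ((W + 1) * (W + 1), 0);
  std::vector<unsigned char> PTR((W + 1) * (W + 1), 0);
  auto idx = [W](int i, int j) { return i * (W + 1) + j; };

  for (int i = 1; i <= W; ++i) {
    for (int j = 1; j <= W; ++j) {
      if (T[i - 1] == 'X' || R[j - 1] == 'X') {
        // masked position: no alignment may include or cross this column
        H[idx(i, j)] = 0; SI[idx(i, j)] = 0; SJ[idx(i, j)] = 0;
        PTR[idx(i, j)] = 0;
        continue;
      }
      const int s = (T[i - 1] == R[j - 1] && T[i - 1] != 'N') ? match : mismatch;
      int bh = 0, bsi = 0, bsj = 0;
      unsigned char bp = 0;
      // diagonal
      {
        int prev = H[idx(i - 1, j - 1)];
        int v = prev + s;
        if (v > 0) {
          int si = prev > 0 ? SI[idx(i - 1, j - 1)] : i;
          int sj = prev > 0 ? SJ[idx(i - 1, j - 1)] : j;
          if (v > bh || (v == bh && (si + sj > bsi + bsj ||
                                     (si + sj == bsi + bsj && si < bsi)))) {
            bh = v; bsi = si; bsj = sj; bp = 1;
          }
        }
      }
      // up: gap in R (right arm)
      if (H[idx(i - 1, j)] > 0) {
        int v = H[idx(i - 1, j)] + gap;
        if (v > 0) {
          int si = SI[idx(i - 1, j)], sj = SJ[idx(i - 1, j)];
          if (v > bh || (v == bh && (si + sj > bsi + bsj ||
                                     (si + sj == bsi + bsj && si < bsi)))) {
            bh = v; bsi = si; bsj = sj; bp = 2;
          }
        }
      }
      // left: gap in T (left arm)
      if (H[idx(i, j - 1)] > 0) {
        int v = H[idx(i, j - 1)] + gap;
        if (v > 0) {
          int si = SI[idx(i, j - 1)], sj = SJ[idx(i, j - 1)];
          if (v > bh || (v == bh && (si + sj > bsi + bsj ||
                                     (si + sj == bsi + bsj && si < bsi)))) {
            bh = v; bsi = si; bsj = sj; bp = 3;
          }
        }
      }
      H[idx(i, j)] = bh; SI[idx(i, j)] = bsi; SJ[idx(i, j)] = bsj;
      PTR[idx(i, j)] = bp;
    }
  }

  for (int i = 1; i <= W; ++i) {
    for (int j = 1; j <= W; ++j) {
      const int h = H[idx(i, j)];
      if (h < min_score) continue;
      if (i + j > W) continue;              // arms must not overlap
      const int si = SI[idx(i, j)], sj = SJ[idx(i, j)];
      const int p1 = W + 1 - sj;            // right arm end
      const int p2 = W + 1 - j;             // right arm start
      if (p1 - si + 1 > max_span) continue;
      // traceback to build the arm alignment
      std::string al, ar;
      int ci = i, cj = j;
      while (PTR[idx(ci, cj)] != 0) {
        unsigned char p = PTR[idx(ci, cj)];
        if (p == 1) {
          al.push_back(T[ci - 1]);
          ar.push_back(comp(R[cj - 1]));    // actual right-arm base, 3'->5'
          --ci; --cj;
        } else if (p == 2) {
          al.push_back(T[ci - 1]); ar.push_back('-'); --ci;
        } else {
          al.push_back('-'); ar.push_back(comp(R[cj - 1])); --cj;
        }
      }
      std::reverse(al.begin(), al.end());
      std::reverse(ar.begin(), ar.end());
      Cand c;
      c.l1 = off + si; c.l2 = off + i;
      c.r1 = off + p2; c.r2 = off + p1;
      c.score = h; c.aln_left = al; c.aln_right = ar;
      out.push_back(c);
    }
  }
}

// [[Rcpp::export(name = ".ir_scan_cpp")]]
DataFrame ir_scan_cpp(std::string seq, int match, int mismatch, int gap,
                      int min_score, int max_span) {
  const int n = (int) seq.size();
  std::vector<Cand> cands;
  const int W = std::min(n, 2 * max_span);
  const int step = std::max(1, max_span);
  for (int w0 = 0; w0 < n; w0 += step) {
    int len = std::min(W, n - w0);
    if (len < 2) break;
    scan_window(seq.substr(w0, len), w0, match, mismatch, gap,
                min_score, max_span, cands);
    if (w0 + len >= n) break;
  }
  const int m = (int) cands.size();
  IntegerVector l1(m), l2(m), r1(m), r2(m), sc(m);
  CharacterVector al(m), ar(m);
  for (int k = 0; k < m; ++k) {
    l1[k] = cands[k].l1; l2[k] = cands[k].l2;
    r1[k] = cands[k].r1; r2[k] = cands[k].r2;
    sc[k] = cands[k].score;
    al[k] = cands[k].aln_left; ar[k] = cands[k].aln_right;
  }
  return DataFrame::create(_["left_start"] = l1, _["left_end"] = l2,
                           _["right_start"] = r1, _["right_end"] = r2,
                           _["score"] = sc, _["aln_left"] = al,
                           _["aln_right"] = ar,
                           _["stringsAsFactors"] = false);
}

// Exhaustive arm-pair oracle ------------------------------------------------
//
// Scores every (left arm, right arm) interval pair with a global
// Needleman-Wunsch alignment of the left arm against the reverse complement
// of the right arm, under the same linear scoring. Used as the independent
// reference for the scan above; arm length is capped for tractability.

static int nw_score(const std::string &a, const std::string &b,
                    int match, int mismatch, int gap) {
  const int n = (int) a.size(), m = (int) b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    for (int j = 1; j <= m; ++j) {
      const int s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match : mismatch;
      cur[j] = std::max(prev[j - 1] + s, std::max(prev[j] + gap, cur[j - 1] + gap));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".ir_enumerate_cpp")]]
DataFrame ir_enumerate_cpp(std::string seq, int match, int mismatch, int gap,
                           int min_score, int max_span, int max_arm) {
  const int n = (int) seq.size();
  const int min_arm = (min_score + match - 1) / match; // 4*min(len) >= min_score
  std::vector<int> L1, L2, R1, R2, SC;
  for (int l1 = 1; l1 <= n; ++l1) {
    for (int l2 = l1 + min_arm - 1; l2 <= std::min(n, l1 + max_arm - 1); ++l2) {
      const std::string left = seq.substr(l1 - 1, l2 - l1 + 1);
      for (int r1 = l2 + 1; r1 <= n; ++r1) {
        const int r2hi = std::min(std::min(n, l1 + max_span - 1),
                                  r1 + max_arm - 1);
        for (int r2 = r1 + min_arm - 1; r2 <= r2hi; ++r2) {
          const std::string right = revcomp_str(seq.substr(r1 - 1, r2 - r1 + 1));
          const int sc = nw_score(left, right, match, mismatch, gap);
          if (sc >= min_score) {
            L1.push_back(l1); L2.push_back(l2);
            R1.push_back(r1); R2.push_back(r2); SC.push_back(sc);
          }
        }
      }
    }
  }
  return DataFrame::create(_["left_start"] = wrap(L1), _["left_end"] = wrap(L2),
                           _["right_start"] = wrap(R1), _["right_end"] = wrap(R2),
                           _["score"] = wrap(SC));
}

// Wobble-aware target scan --------------------------------------------------
//
// Local alignment of an sRNA (5'->3') against a transcript read 3'->5',
// with half-unit scores carried as doubled integers. Column classes:
// match = Watson-Crick complement, wobble = G:U (G:T on the T-normalized
// alphabet), otherwise mismatch; N never matches or wobbles.

static inline int duplex_score2(char q, char t, int match2, int wobble2,
                                int mismatch2) {
  if (q == 'N' || t == 'N') return mismatch2;
  if (t == comp(q)) return match2;
  if ((q == 'G' && t == 'T') || (q == 'T' && t == 'G')) return wobble2;
  return mismatch2;
}

static inline char duplex_class(char q, char t) {
  if (q == 'N' || t == 'N') return 'x';
  if (t == comp(q)) return 'm';
  if ((q == 'G' && t == 'T') || (q == 'T' && t == 'G')) return 'w';
  return 'x';
}

// [[Rcpp::export(name = ".target_scan_cpp")]]
DataFrame target_scan_cpp(std::string query, std::string subject,
                          int match2, int wobble2, int mismatch2, int gap2,
                          int cutoff2) {
  const int n = (int) query.size(), m = (int) subject.size();
  std::vector<int> H((n + 1) * (m + 1), 0), G((n + 1) * (m + 1), 0),
    SI((n + 1) * (m + 1), 0), SJ((n + 1) * (m + 1), 0);
  std::vector<unsigned char> PTR((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int bh = 0, bg = 0, bsi = 0, bsj = 0;
      unsigned char bp = 0;
      const int s = duplex_score2(query[i - 1], subject[j - 1],
                                  match2, wobble2, mismatch2);
      {
        int prev = H[idx(i - 1, j - 1)];
        int v = prev + s;
        if (v > 0) {
          int g = prev > 0 ? G[idx(i - 1, j - 1)] : 0;
          int si = prev > 0 ? SI[idx(i - 1, j - 1)] : i;
          int sj = prev > 0 ? SJ[idx(i - 1, j - 1)] : j;
          if (v > bh || (v == bh && g < bg)) {
            bh = v; bg = g; bsi = si; bsj = sj; bp = 1;
          }
        }
      }
      if (H[idx(i - 1, j)] > 0) {
        int v = H[idx(i - 1, j)] + gap2;
        if (v > 0) {
          int g = G[idx(i - 1, j)] + 1;
          if (v > bh || (v == bh && g < bg)) {
            bh = v; bg = g; bsi = SI[idx(i - 1, j)]; bsj = SJ[idx(i - 1, j)];
            bp = 2;
          }
        }
      }
      if (H[idx(i, j - 1)] > 0) {
        int v = H[idx(i, j - 1)] + gap2;
        if (v > 0) {
          int g = G[idx(i, j - 1)] + 1;
          if (v > bh || (v == bh && g < bg)) {
            bh = v; bg = g; bsi = SI[idx(i, j - 1)]; bsj = SJ[idx(i, j - 1)];
            bp = 3;
          }
        }
      }
      H[idx(i, j)] = bh; G[idx(i, j)] = bg;
      SI[idx(i, j)] = bsi; SJ[idx(i, j)] = bsj; PTR[idx(i, j)] = bp;
    }
  }

  std::vector<int> QS, QE, SS, SE, SC2, NG;
  std::vector<std::string> PAIR;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (H[idx(i, j)] < cutoff2) continue;
      std::string pcode;
      int ci = i, cj = j;
      while (PTR[idx(ci, cj)] != 0) {
        unsigned char p = PTR[idx(ci, cj)];
        if (p == 1) {
          pcode.push_back(duplex_class(query[ci - 1], subject[cj - 1]));
          --ci; --cj;
        } else if (p == 2) {
          pcode.push_back('g'); --ci;
        } else {
          pcode.push_back('g'); --cj;
        }
      }
      std::reverse(pcode.begin(), pcode.end());
      QS.push_back(SI[idx(i, j)]); QE.push_back(i);
      SS.push_back(SJ[idx(i, j)]); SE.push_back(j);
      SC2.push_back(H[idx(i, j)]); NG.push_back(G[idx(i, j)]);
      PAIR.push_back(pcode);
    }
  }
  return DataFrame::create(_["q_start"] = wrap(QS), _["q_end"] = wrap(QE),
                           _["s_start"] = wrap(SS), _["s_end"] = wrap(SE),
                           _["score2"] = wrap(SC2), _["n_gaps"] = wrap(NG),
                           _["pairing"] = wrap(PAIR),
                           _["stringsAsFactors"] = false);
}
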