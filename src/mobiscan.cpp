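// Core sequence kernels: affine-gap Smith-Waterman with deterministic
// tie-breaking, and k-mer seeded scanners for junction-read detection,
// unique flank placement and breakpoint-spanning evidence collection.
// Sequences are plain ACGTN strings; N never counts as a match.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1; // N or anything else: no k-mer seed, never a match
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default:  c = 'N';
    }
  }
  return r;
}

struct SWResult {
  int score = 0;
  int a_start = 0, a_end = 0;   // 0-based half-open on a
  int b_start = 0, b_end = 0;   // 0-based half-open on b
  int matches = 0;
  int aligned_len = 0;          // alignment columns incl. gap columns
  int matches_b_left = 0;       // match columns with b-position < b_mark
  int matches_b_right = 0;      // match columns with b-position >= b_mark
};

// Gotoh local alignment. First base of a gap costs gap_open, each further
// base gap_extend (both negative). Tie-break: the optimal cell with the
// lowest (a_end, b_end); traceback prefers diagonal, then vertical, then
// horizontal moves. b_mark splits match counts at a template junction
// column (pass 0 to disable).
static SWResult sw_core(const std::string &a, const std::string &b,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int b_mark) {
  const int n = (int)a.size(), m = (int)b.size();
  const int NEG = -1000000000;
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[idx(i, j - 1)] + gap_open, E[idx(i, j - 1)] + gap_extend);
      int f = std::max(H[idx(i - 1, j)] + gap_open, F[idx(i - 1, j)] + gap_extend);
      bool is_match = a[i - 1] == b[j - 1] && a[i - 1] != 'N';
      int d = H[idx(i - 1, j - 1)] + (is_match ? match : mismatch);
      int h = std::max(0, std::max(d, std::max(e, f)));
      E[idx(i, j)] = e; F[idx(i, j)] = f; H[idx(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  SWResult res;
  res.score = best;
  if (best == 0) return res;

  // Traceback from (bi, bj) in the H layer.
  int i = bi, j = bj, layer = 0; // 0 = H, 1 = E (gap in a), 2 = F (gap in b)
  res.a_end = bi; res.b_end = bj;
  while (i > 0 && j > 0) {
    if (layer == 0) {
      int h = H[idx(i, j)];
      if (h == 0) break;
      bool is_match = a[i - 1] == b[j - 1] && a[i - 1] != 'N';
      int d = H[idx(i - 1, j - 1)] + (is_match ? match : mismatch);
      if (h == d) {
        if (is_match) {
          ++res.matches;
          if (j - 1 < b_mark) ++res.matches_b_left; else ++res.matches_b_right;
        }
        ++res.aligned_len; --i; --j;
      } else if (h == F[idx(i, j)]) {
        layer = 2;
      } else {
        layer = 1;
      }
    } else if (layer == 2) { // vertical: consume a
      ++res.aligned_len;
      if (F[idx(i, j)] == H[idx(i - 1, j)] + gap_open) layer = 0;
      --i;
    } else {                 // horizontal: consume b
      ++res.aligned_len;
      if (E[idx(i, j)] == H[idx(i, j - 1)] + gap_open) layer = 0;
      --j;
    }
  }
  res.a_start = i; res.b_start = j;
  return res;
}

// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_extend) {
  SWResult r = sw_core(a, b, match, mismatch, gap_open, gap_extend, 0);
  return List::create(
      _["score"] = r.score, _["a_start"] = r.a_start, _["a_end"] = r.a_end,
      _["b_start"] = r.b_start, _["b_end"] = r.b_end, _["matches"] = r.matches,
      _["aligned_len"] = r.aligned_len);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  out.names() = seqs.names();
  return out;
}

typedef std::unordered_map<uint64_t, std::vector<int>> KmerSetIndex;
typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> KmerPosIndex;

// Best-scoring ungapped segment (match +1, mismatch -2, N never matches)
// of query q placed on subject s at diagonal d (q[i] ~ s[i+d]).
struct Segment { int q0 = 0, q1 = 0, matches = 0, score = -1000000000; };

static Segment diagonal_segment(const std::string &q, const std::string &s,
                                int d) {
  const int lo = std::max(0, -d);
  const int hi = std::min((int)q.size(), (int)s.size() - d);
  Segment best;
  int cur = 0, cur0 = lo, cur_matches = 0;
  for (int i = lo; i < hi; ++i) {
    bool m = q[i] == s[i + d] && q[i] != 'N';
    cur += m ? 1 : -2;
    cur_matches += m ? 1 : 0;
    if (cur > best.score) {
      best.score = cur; best.q0 = cur0; best.q1 = i + 1;
      best.matches = cur_matches;
    }
    if (cur < 0) { cur = 0; cur_matches = 0; cur0 = i + 1; }
  }
  return best;
}

// Enumerate valid (N-free) k-mers of s; cb(pos, code).
template <typename F>
static void each_kmer(const std::string &s, int k, F cb) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++run >= k) cb(i - k + 1, code);
  }
}

static KmerPosIndex build_pos_index(const std::vector<std::string> &seqs, int k) {
  KmerPosIndex idx;
  for (int t = 0; t < (int)seqs.size(); ++t) {
    each_kmer(seqs[t], k, [&](int pos, uint64_t code) {
      idx[code].push_back({t, pos});
    });
  }
  return idx;
}

// Candidate (subject, diagonal) pairs for query q against a position
// index; deduplicated.
static std::vector<std::pair<int, int>> seed_diagonals(const KmerPosIndex &idx,
                                                       const std::string &q,
                                                       int k) {
  std::unordered_set<int64_t> seen;
  std::vector<std::pair<int, int>> out;
  each_kmer(q, k, [&](int qpos, uint64_t code) {
    auto it = idx.find(code);
    if (it == idx.end()) return;
    for (auto &rp : it->second) {
      int d = rp.second - qpos;
      int64_t key = (int64_t)rp.first * 100000000LL + d + 10000000;
      if (seen.insert(key).second) out.push_back({rp.first, d});
    }
  });
  return out;
}

// Scan reads for TE-junction structure against an end-sequence library
// by exact k-mer seeding and ungapped score-maximising extension along
// each seeded diagonal. sides[e] in {"L","R","whole"}. A read qualifies
// iff its best segment on some end covers >= min_te read bases at
// >= min_ident, reaches the junction-forming terminus of the end
// (within `slack` bases), and leaves >= min_flank unaligned bases on
// exactly the flank side.
// [[Rcpp::export]]
DataFrame cpp_scan_junctions(CharacterVector reads, CharacterVector ends,
                             CharacterVector sides, int k, int min_te,
                             int min_flank, double min_ident, int slack) {
  std::vector<std::string> endv(ends.size());
  for (R_xlen_t i = 0; i < ends.size(); ++i) endv[i] = as<std::string>(ends[i]);
  std::vector<std::string> sidev(sides.size());
  for (R_xlen_t i = 0; i < sides.size(); ++i) sidev[i] = as<std::string>(sides[i]);
  KmerPosIndex idx = build_pos_index(endv, k);

  std::vector<int> o_read, o_end, o_rs, o_re, o_score;
  std::vector<std::string> o_orient, o_side;

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int best_score = 0, best_end = -1, best_rs = 0, best_re = 0, best_o = 0;
    std::string best_side;
    for (int o = 0; o < 2; ++o) {
      std::string oriented = (o == 0) ? fwd : revcomp(fwd);
      const int len = (int)oriented.size();
      for (auto &cand : seed_diagonals(idx, oriented, k)) {
        const int e = cand.first, d = cand.second;
        Segment a = diagonal_segment(oriented, endv[e], d);
        if (a.score <= 0) continue;
        int te_len = a.q1 - a.q0;
        if (te_len < min_te) continue;
        if ((double)a.matches / te_len < min_ident) continue;
        int left_un = a.q0, right_un = len - a.q1;
        bool left_flank = left_un >= min_flank, right_flank = right_un >= min_flank;
        if (left_flank == right_flank) continue; // need exactly one flank side
        const int blen = (int)endv[e].size();
        bool reach_start = a.q0 + d <= slack;
        bool reach_end = a.q1 + d >= blen - slack;
        std::string jside;
        if (sidev[e] == "L") {
          if (!(reach_start && left_flank)) continue;
          jside = "L";
        } else if (sidev[e] == "R") {
          if (!(reach_end && right_flank)) continue;
          jside = "R";
        } else { // whole element
          if (reach_start && left_flank) jside = "L";
          else if (reach_end && right_flank) jside = "R";
          else continue;
        }
        bool better = a.score > best_score;
        if (a.score == best_score && best_end >= 0)
          better = e < best_end || (e == best_end && o < best_o);
        if (better) {
          best_score = a.score; best_end = e; best_o = o;
          best_rs = a.q0; best_re = a.q1;
          best_side = jside;
        }
      }
    }
    if (best_end >= 0) {
      o_read.push_back((int)r + 1); o_end.push_back(best_end + 1);
      o_rs.push_back(best_rs); o_re.push_back(best_re);
      o_score.push_back(best_score);
      o_orient.push_back(best_o == 0 ? "+" : "-"); o_side.push_back(best_side);
    }
  }
  return DataFrame::create(
      _["read"] = o_read, _["end"] = o_end, _["orient"] = o_orient,
      _["side"] = o_side, _["te_start"] = o_rs, _["te_end"] = o_re,
      _["score"] = o_score, _["stringsAsFactors"] = false);
}

// Place flanks on the reference by exact k-mer seeding plus ungapped,
// score-maximizing extension (match +1 / mismatch -2) on both strands.
// A flank maps iff the best segment reaches min_len and min_ident and no
// second seeded location scores within second_frac of the best.
// [[Rcpp::export]]
DataFrame cpp_map_flanks(CharacterVector flanks, CharacterVector refs, int k,
                         int min_len, double min_ident, double second_frac) {
  std::vector<std::string> refv(refs.size());
  for (R_xlen_t i = 0; i < refs.size(); ++i) refv[i] = as<std::string>(refs[i]);
  KmerPosIndex idx;
  for (int t = 0; t < (int)refv.size(); ++t)
    each_kmer(refv[t], k, [&](int pos, uint64_t code) {
      idx[code].push_back({t, pos});
    });

  const R_xlen_t nf = flanks.size();
  IntegerVector o_rid(nf, NA_INTEGER), o_start(nf, NA_INTEGER),
      o_end(nf, NA_INTEGER), o_fstart(nf, NA_INTEGER), o_fend(nf, NA_INTEGER),
      o_score(nf, NA_INTEGER), o_matches(nf, NA_INTEGER);
  CharacterVector o_strand(nf, NA_STRING);
  LogicalVector o_found(nf, false);

  for (R_xlen_t f = 0; f < nf; ++f) {
    std::string fwd = as<std::string>(flanks[f]);
    struct Hit { int rid, strand, d, score, f0, f1, matches; };
    Hit best{-1, 0, 0, -1000000000, 0, 0, 0};
    int second = -1000000000;
    for (int o = 0; o < 2; ++o) {
      std::string q = (o == 0) ? fwd : revcomp(fwd);
      const int flen = (int)q.size();
      std::unordered_set<int64_t> diags; // (rid, diagonal) pairs
      std::vector<std::pair<int, int>> cand;
      each_kmer(q, k, [&](int qpos, uint64_t code) {
        auto it = idx.find(code);
        if (it == idx.end()) return;
        for (auto &rp : it->second) {
          int d = rp.second - qpos;
          int64_t key = (int64_t)rp.first * 100000000LL + d + 10000000;
          if (diags.insert(key).second) cand.push_back({rp.first, d});
        }
      });
      for (auto &c : cand) {
        const std::string &ref = refv[c.first];
        int d = c.second;
        int lo = std::max(0, -d), hi = std::min(flen, (int)ref.size() - d);
        // Kadane over per-base scores for the best contiguous segment
        int cur = 0, cur0 = lo, seg_best = -1, s0 = lo, s1 = lo;
        int cur_matches = 0, seg_matches = 0;
        for (int i = lo; i < hi; ++i) {
          bool m = q[i] == ref[d + i] && q[i] != 'N';
          cur += m ? 1 : -2;
          cur_matches += m ? 1 : 0;
          if (cur > seg_best) { seg_best = cur; s0 = cur0; s1 = i + 1; seg_matches = cur_matches; }
          if (cur < 0) { cur = 0; cur_matches = 0; cur0 = i + 1; }
        }
        if (seg_best <= 0) continue;
        if (seg_best > best.score) {
          second = best.score;
          best = {c.first, o, d, seg_best, s0, s1, seg_matches};
        } else if (seg_best > second) {
          second = seg_best;
        }
      }
    }
    int seg_len = best.f1 - best.f0;
    bool valid = best.rid >= 0 && seg_len >= min_len &&
                 (double)best.matches / seg_len >= min_ident &&
                 (double)second < second_frac * best.score;
    if (valid) {
      o_found[f] = true;
      o_rid[f] = best.rid + 1;
      o_strand[f] = (best.strand == 0) ? "+" : "-";
      o_start[f] = best.d + best.f0;
      o_end[f] = best.d + best.f1;
      o_fstart[f] = best.f0; // coords on the oriented flank
      o_fend[f] = best.f1;
      o_score[f] = best.score;
      o_matches[f] = best.matches;
    }
  }
  return DataFrame::create(
      _["found"] = o_found, _["rid"] = o_rid, _["strand"] = o_strand,
      _["ref_start"] = o_start, _["ref_end"] = o_end, _["f_start"] = o_fstart,
      _["f_end"] = o_fend, _["score"] = o_score, _["matches"] = o_matches,
      _["stringsAsFactors"] = false);
}

// Count reads supporting allele templates. junction[t] is the 0-based
// template offset of the breakpoint; a read supports template t iff the
// best ungapped seeded segment (either orientation) has >= min_overlap
// matched bases on each side of the junction at >= min_ident identity
// over the segment. Returns one row per qualifying (read, template)
// pair.
// [[Rcpp::export]]
DataFrame cpp_collect_evidence(CharacterVector reads, CharacterVector templates,
                               IntegerVector junction, int k, int min_overlap,
                               double min_ident) {
  std::vector<std::string> tv(templates.size());
  for (R_xlen_t i = 0; i < templates.size(); ++i)
    tv[i] = as<std::string>(templates[i]);
  KmerPosIndex idx = build_pos_index(tv, k);

  std::vector<int> o_read, o_tmpl;
  std::unordered_set<int> qualified;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    qualified.clear();
    for (int o = 0; o < 2; ++o) {
      std::string q = (o == 0) ? fwd : revcomp(fwd);
      for (auto &cand : seed_diagonals(idx, q, k)) {
        const int t = cand.first, d = cand.second;
        if (qualified.count(t)) continue;
        Segment a = diagonal_segment(q, tv[t], d);
        if (a.score <= 0) continue;
        if ((double)a.matches / (a.q1 - a.q0) < min_ident) continue;
        // matched bases on each side of the junction column
        const std::string &s = tv[t];
        int ml = 0, mr = 0;
        for (int i = a.q0; i < a.q1; ++i) {
          if (q[i] == s[i + d] && q[i] != 'N') {
            if (i + d < junction[t]) ++ml; else ++mr;
          }
        }
        if (ml >= min_overlap && mr >= min_overlap) qualified.insert(t);
      }
    }
    for (int t : qualified) {
      o_read.push_back((int)r + 1);
      o_tmpl.push_back(t + 1);
    }
  }
  return DataFrame::create(_["read"] = o_read, _["template"] = o_tmpl,
                           _["stringsAsFactors"] = false);
}
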