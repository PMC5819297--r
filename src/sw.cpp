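// Affine-gap local alignment core and k-mer seeded read classification.
//
// Scoring convention: a gap of length L costs gap_open + L * gap_extend
// (both negative), i.e. the first gapped base pays gap_open + gap_extend.
// Only A/C/G/T can match; N and masked ('#') positions always mismatch.

#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Params {
  int match, mismatch, gap_open, gap_extend;
};

inline int subst(char a, char b, const Params& p) {
  switch (a) {
    case 'A': case 'C': case 'G': case 'T':
      return (a == b) ? p.match : p.mismatch;
    default:
      return p.mismatch;
  }
}

inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

struct EndRes { int score, qe, re; };  // 1-based end coordinates, score 0 => none

// Linear-memory forward pass: best local score and its end cell.
// Ties broken toward the first maximal cell in row-major order.
EndRes sw_end(const std::string& a, const std::string& b, const Params& p) {
  const int m = (int)a.size(), n = (int)b.size();
  const int NEG = INT_MIN / 4;
  std::vector<int> H(n + 1, 0), F(n + 1, NEG);
  EndRes best{0, 0, 0};
  for (int i = 1; i <= m; ++i) {
    int diag = 0;        // H[i-1][j-1]
    int E = NEG;         // E[i][0]
    const char ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      E = std::max(H[j - 1] + p.gap_open + p.gap_extend, E + p.gap_extend);
      F[j] = std::max(H[j] + p.gap_open + p.gap_extend, F[j] + p.gap_extend);
      int h = diag + subst(ai, b[j - 1], p);
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      if (h > best.score) best = {h, i, j};
    }
  }
  return best;
}

struct Aln {
  int score, qs, qe, rs, re, matches, aln_len;  // 1-based inclusive; score 0 => none
};

// Traceback over the bounded rectangle [qs..qe] x [rs..re] to count matched
// columns and total alignment columns. Packed byte per cell:
// bits 0-1: H source (0 stop, 1 diag, 2 E/left, 3 F/up); bit 2: E opened here;
// bit 3: F opened here.
void rect_stats(const std::string& a, const std::string& b, const Params& p,
                int qs, int qe, int rs, int re, int& matches, int& aln_len) {
  const int m = qe - qs + 1, n = re - rs + 1;
  const int NEG = INT_MIN / 4;
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> H(n + 1, 0), F(n + 1, NEG);
  for (int i = 1; i <= m; ++i) {
    int diag = 0, E = NEG;
    const char ai = a[qs - 1 + i - 1];
    for (int j = 1; j <= n; ++j) {
      uint8_t cell = 0;
      int e_open = H[j - 1] + p.gap_open + p.gap_extend;
      int e_ext = E + p.gap_extend;
      if (e_open >= e_ext) { E = e_open; cell |= 4; } else { E = e_ext; }
      int f_open = H[j] + p.gap_open + p.gap_extend;
      int f_ext = F[j] + p.gap_extend;
      if (f_open >= f_ext) { F[j] = f_open; cell |= 8; } else { F[j] = f_ext; }
      int d = diag + subst(ai, b[rs - 1 + j - 1], p);
      int h = 0; uint8_t src = 0;
      if (d > h) { h = d; src = 1; }
      if (E > h) { h = E; src = 2; }
      if (F[j] > h) { h = F[j]; src = 3; }
      diag = H[j];
      H[j] = h;
      tb[(size_t)i * (n + 1) + j] = cell | src;
    }
  }
  // Walk back from the rectangle corner (the optimal alignment ends there).
  matches = 0; aln_len = 0;
  int i = m, j = n;
  int state = 0;  // 0 = in H, 2 = in E, 3 = in F
  while (i > 0 && j > 0) {
    uint8_t cell = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      uint8_t src = cell & 3;
      if (src == 0) break;
      if (src == 1) {
        ++aln_len;
        if (subst(a[qs - 1 + i - 1], b[rs - 1 + j - 1], p) == p.match) ++matches;
        --i; --j;
      } else {
        state = src;
      }
    } else if (state == 2) {   // gap consuming reference
      ++aln_len;
      bool opened = (cell & 4) != 0;
      --j;
      if (opened) state = 0;
    } else {                   // gap consuming query
      ++aln_len;
      bool opened = (cell & 8) != 0;
      --i;
      if (opened) state = 0;
    }
  }
}

// Full best local alignment: end by forward pass, start by reverse pass,
// matched-column stats over the bounded rectangle.
Aln sw_full(const std::string& a, const std::string& b, const Params& p,
            bool stats = true) {
  Aln out{0, 0, 0, 0, 0, 0, 0};
  EndRes e = sw_end(a, b, p);
  if (e.score <= 0) return out;
  std::string ra(a.begin(), a.begin() + e.qe); std::reverse(ra.begin(), ra.end());
  std::string rb(b.begin(), b.begin() + e.re); std::reverse(rb.begin(), rb.end());
  EndRes s = sw_end(ra, rb, p);
  out.score = e.score;
  out.qe = e.qe; out.re = e.re;
  out.qs = e.qe - s.qe + 1;
  out.rs = e.re - s.re + 1;
  if (stats) rect_stats(a, b, p, out.qs, out.qe, out.rs, out.re,
                        out.matches, out.aln_len);
  return out;
}

inline bool kmer_code(const std::string& s, int pos, int k, uint64_t& code) {
  code = 0;
  for (int t = 0; t < k; ++t) {
    uint64_t v;
    switch (s[pos + t]) {
      case 'A': v = 0; break;
      case 'C': v = 1; break;
      case 'G': v = 2; break;
      case 'T': v = 3; break;
      default: return false;
    }
    code = (code << 2) | v;
  }
  return true;
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> KmerIndex;

KmerIndex build_index(const std::vector<std::string>& refs, int k) {
  KmerIndex idx;
  for (int r = 0; r < (int)refs.size(); ++r) {
    const std::string& s = refs[r];
    if ((int)s.size() < k) continue;
    for (int pos = 0; pos + k <= (int)s.size(); ++pos) {
      uint64_t code;
      if (kmer_code(s, pos, k, code)) idx[code].push_back({r, pos});
    }
  }
  return idx;
}

}  // namespace

// [[Rcpp::export(name = ".sw_align_cpp")]]
IntegerVector sw_align_cpp(std::string a, std::string b,
                           int match, int mismatch, int gap_open, int gap_extend) {
  Params p{match, mismatch, gap_open, gap_extend};
  Aln r = sw_full(a, b, p);
  return IntegerVector::create(
      _["score"] = r.score, _["q_start"] = r.qs, _["q_end"] = r.qe,
      _["r_start"] = r.rs, _["r_end"] = r.re,
      _["matches"] = r.matches, _["aln_len"] = r.aln_len);
}

// Iterative non-overlapping local hits of `pattern` (both strands) against
// `subject`; hits are taken greedily by descending score, the matched subject
// span is masked after each hit. Coordinates 1-based inclusive on `subject`.
// [[Rcpp::export(name = ".find_hits_cpp")]]
DataFrame find_hits_cpp(std::string pattern, std::string subject,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int stop_score, int max_hits) {
  Params p{match, mismatch, gap_open, gap_extend};
  std::string rc = revcomp(pattern);
  std::vector<int> starts, ends, scores;
  std::vector<int> matchv, alnv;
  std::vector<std::string> strands;
  for (int it = 0; it < max_hits; ++it) {
    Aln f = sw_full(pattern, subject, p);
    Aln r = sw_full(rc, subject, p);
    bool fwd = f.score >= r.score;
    Aln& best = fwd ? f : r;
    if (best.score < stop_score || best.score <= 0) break;
    starts.push_back(best.rs);
    ends.push_back(best.re);
    scores.push_back(best.score);
    matchv.push_back(best.matches);
    alnv.push_back(best.aln_len);
    strands.push_back(fwd ? "+" : "-");
    for (int x = best.rs - 1; x < best.re; ++x) subject[x] = '#';
  }
  return DataFrame::create(
      _["start"] = starts, _["end"] = ends, _["strand"] = strands,
      _["score"] = scores, _["matches"] = matchv, _["aln_len"] = alnv,
      _["stringsAsFactors"] = false);
}

// Classify reads against reference sequences. For every (read, reference)
// pair with at least one shared seed k-mer (k = k1, falling back to k = k2
// for reads with no k1 candidate at all), the best local alignment over both
// read strands is computed inside seed-bounded windows. With
// exhaustive = TRUE, every read is aligned in full against every reference.
// Rows below min_score or min_aln_len are suppressed.
// [[Rcpp::export(name = ".classify_cpp")]]
DataFrame classify_cpp(CharacterVector reads, CharacterVector refs,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int min_score, int min_aln_len,
                       int k1, int k2, bool exhaustive) {
  Params p{match, mismatch, gap_open, gap_extend};
  const int nref = refs.size(), nread = reads.size();
  std::vector<std::string> R(nref);
  for (int i = 0; i < nref; ++i) R[i] = as<std::string>(refs[i]);

  KmerIndex idx1, idx2;
  if (!exhaustive) {
    idx1 = build_index(R, k1);
    idx2 = build_index(R, k2);
  }

  std::vector<int> o_read, o_ref, o_score, o_rs, o_re, o_qs, o_qe, o_match, o_aln;
  std::vector<std::string> o_strand;

  // per-(ref,strand) implied reference start positions of seed hits
  std::vector<std::vector<int>> cand(2 * nref);

  for (int ri = 0; ri < nread; ++ri) {
    std::string q = as<std::string>(reads[ri]);
    const int qlen = (int)q.size();
    if (qlen == 0) continue;
    std::string qr = revcomp(q);
    const std::string* Q[2] = {&q, &qr};

    // best per reference across strands/windows
    std::vector<Aln> best(nref);
    std::vector<int> beststrand(nref, 0);
    std::vector<char> seen(nref, 0);

    if (exhaustive) {
      for (int rf = 0; rf < nref; ++rf) {
        for (int st = 0; st < 2; ++st) {
          Aln a = sw_full(*Q[st], R[rf], p);
          if (!seen[rf] || a.score > best[rf].score) {
            best[rf] = a; beststrand[rf] = st; seen[rf] = 1;
          }
        }
      }
    } else {
      // one seeded pass; rescued with the shorter seed when no reference
      // reaches the reporting floor (divergent reads can lack a clean k1-mer)
      for (int pass = 0; pass < 2; ++pass) {
        const KmerIndex& idx = pass == 0 ? idx1 : idx2;
        const int k = pass == 0 ? k1 : k2;
        if (qlen < k) continue;
        std::vector<int> touched;
        for (int st = 0; st < 2; ++st) {
          const std::string& qq = *Q[st];
          for (int pos = 0; pos + k <= qlen; ++pos) {
            uint64_t code;
            if (!kmer_code(qq, pos, k, code)) continue;
            auto it = idx.find(code);
            if (it == idx.end()) continue;
            for (auto& pr : it->second) {
              int key = 2 * pr.first + st;
              if (cand[key].empty()) touched.push_back(key);
              cand[key].push_back(pr.second - pos);
            }
          }
        }
        for (int key : touched) {
          int rf = key / 2, st = key % 2;
          std::vector<int>& dv = cand[key];
          std::sort(dv.begin(), dv.end());
          const std::string& ref = R[rf];
          const int nlen = (int)ref.size();
          size_t a0 = 0;
          while (a0 < dv.size()) {
            size_t a1 = a0;
            while (a1 + 1 < dv.size() && dv[a1 + 1] - dv[a1] <= 2 * qlen) ++a1;
            int ws = std::max(0, dv[a0] - qlen - 8);
            int we = std::min(nlen, dv[a1] + 2 * qlen + 8);
            if (we > ws) {
              Aln a = sw_full(*Q[st], ref.substr(ws, we - ws), p);
              if (a.score > 0) {
                a.rs += ws; a.re += ws;
                if (!seen[rf] || a.score > best[rf].score) {
                  best[rf] = a; beststrand[rf] = st; seen[rf] = 1;
                }
              }
            }
            a0 = a1 + 1;
          }
          dv.clear();
        }
        int top = 0;
        for (int rf = 0; rf < nref; ++rf) {
          if (seen[rf] && best[rf].score > top) top = best[rf].score;
        }
        if (top >= min_score) break;
      }
    }

    for (int rf = 0; rf < nref; ++rf) {
      if (!seen[rf]) continue;
      const Aln& a = best[rf];
      if (a.score < min_score || a.aln_len < min_aln_len) continue;
      o_read.push_back(ri + 1);
      o_ref.push_back(rf + 1);
      o_score.push_back(a.score);
      o_rs.push_back(a.rs);
      o_re.push_back(a.re);
      o_qs.push_back(a.qs);
      o_qe.push_back(a.qe);
      o_match.push_back(a.matches);
      o_aln.push_back(a.aln_len);
      o_strand.push_back(beststrand[rf] == 0 ? "+" : "-");
    }
    if (ri % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return DataFrame::create(
      _["read_idx"] = o_read, _["ref_idx"] = o_ref, _["score"] = o_score,
      _["ref_start"] = o_rs, _["ref_end"] = o_re,
      _["q_start"] = o_qs, _["q_end"] = o_qe,
      _["matches"] = o_match, _["aln_len"] = o_aln, _["strand"] = o_strand,
      _["stringsAsFactors"] = false);
}
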