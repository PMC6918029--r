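// Nucleotide read mapper: exact k-mer seeding followed by banded local
// alignment around each candidate diagonal (match/mismatch/linear gap).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int nt_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
    }
  }
  return r;
}

struct NtAln {
  int score = 0;
  int qs = 0, qe = 0, rs = 0, re = 0; // 0-based half-open, oriented read coords
};

// Banded local DP restricted to diagonals [diag-band, diag+band], where a
// read position i aligns near reference position i+diag.  Linear gap cost.
static NtAln banded_sw(const std::string &read, const std::string &ref,
                       int diag, int band, int match, int mismatch, int gap) {
  const int L = (int)read.size(), R = (int)ref.size();
  const int W = 2 * band + 1;
  const int NEG = -1000000000;
  std::vector<int> prev(W, 0), cur(W, 0);
  std::vector<unsigned char> trace((L + 1) * W, 0); // 0 stop,1 diag,2 left(ref gap... ref consumed),3 up
  NtAln best;
  int bi = 0, bk = 0;
  for (int i = 1; i <= L; ++i) {
    for (int k = 0; k < W; ++k) {
      int j = i + diag - band + k; // 1-based ref position for this cell
      if (j < 1 || j > R) { cur[k] = NEG; continue; }
      int s = (nt_code(read[i - 1]) >= 0 && nt_code(read[i - 1]) == nt_code(ref[j - 1]))
                  ? match : mismatch;
      int h = 0; unsigned char t = 0;
      int d = prev[k]; // (i-1, j-1) is same k in prev row
      if (d > NEG / 2 && d + s > h) { h = d + s; t = 1; }
      if (k > 0 && cur[k - 1] > NEG / 2 && cur[k - 1] + gap > h) { h = cur[k - 1] + gap; t = 2; } // gap in read (consume ref)
      if (k + 1 < W && prev[k + 1] > NEG / 2 && prev[k + 1] + gap > h) { h = prev[k + 1] + gap; t = 3; } // gap in ref (consume read)
      cur[k] = h; trace[i * W + k] = t;
      if (h > best.score) { best.score = h; bi = i; bk = k; }
    }
    std::swap(prev, cur);
  }
  if (best.score <= 0) return best;
  int i = bi, k = bk;
  best.qe = i; best.re = i + diag - band + k;
  while (i > 0) {
    unsigned char t = trace[i * W + k];
    if (t == 0) break;
    if (t == 1) { --i; }
    else if (t == 2) { --k; }
    else { --i; ++k; }
  }
  best.qs = i; best.rs = i + diag - band + k;
  return best;
}

// [[Rcpp::export]]
DataFrame map_reads_cpp(CharacterVector reads, std::string ref,
                        int match, int mismatch, int gap, int min_score,
                        int k = 12, int band = 8, int max_diags = 50) {
  const int R = (int)ref.size();
  std::unordered_map<uint32_t, std::vector<int>> index;
  if (R >= k) {
    uint32_t code = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1) : 0xFFFFFFFFu;
    int run = 0;
    for (int p = 0; p < R; ++p) {
      int c = nt_code(ref[p]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)c) & mask;
      if (++run >= k) index[code].push_back(p - k + 1);
    }
  }
  const int n = reads.size();
  IntegerVector score(n), qstart(n), qend(n), rstart(n), rend(n);
  CharacterVector strand(n);
  LogicalVector mapped(n);
  std::vector<int> diags;

  for (int ri = 0; ri < n; ++ri) {
    if (ri % 4096 == 0) Rcpp::checkUserInterrupt();
    std::string fwd = as<std::string>(reads[ri]);
    NtAln best; char best_strand = '+';
    for (int st = 0; st < 2; ++st) {
      std::string rd = (st == 0) ? fwd : revcomp(fwd);
      const int L = (int)rd.size();
      if (L < k) continue;
      diags.clear();
      uint32_t code = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1) : 0xFFFFFFFFu;
      int run = 0;
      for (int p = 0; p < L; ++p) {
        int c = nt_code(rd[p]);
        if (c < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint32_t)c) & mask;
        if (++run >= k) {
          auto it = index.find(code);
          if (it != index.end()) {
            int q0 = p - k + 1;
            for (int rp : it->second) diags.push_back(rp - q0);
          }
        }
      }
      if (diags.empty()) continue;
      std::sort(diags.begin(), diags.end());
      diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
      // merge diagonals within the band into representative groups
      std::vector<int> reps;
      int grp_start = diags[0], last = diags[0];
      for (size_t t = 1; t <= diags.size(); ++t) {
        if (t == diags.size() || diags[t] - last > band) {
          reps.push_back((grp_start + last) / 2);
          if (t < diags.size()) { grp_start = diags[t]; last = diags[t]; }
        } else last = diags[t];
      }
      if ((int)reps.size() > max_diags) reps.resize(max_diags);
      for (int d : reps) {
        NtAln a = banded_sw(rd, ref, d, band, match, mismatch, gap);
        if (a.score > best.score) {
          best = a;
          best_strand = (st == 0) ? '+' : '-';
          // convert minus-strand coords back to original read orientation
          if (st == 1) {
            int qs = L - a.qe, qe = L - a.qs;
            best.qs = qs; best.qe = qe;
          }
        }
      }
    }
    if (best.score >= min_score && best.score > 0) {
      mapped[ri] = true; score[ri] = best.score;
      qstart[ri] = best.qs; qend[ri] = best.qe;
      rstart[ri] = best.rs; rend[ri] = best.re;
      strand[ri] = std::string(1, best_strand);
    } else {
      mapped[ri] = false; score[ri] = 0;
      qstart[ri] = NA_INTEGER; qend[ri] = NA_INTEGER;
      rstart[ri] = NA_INTEGER; rend[ri] = NA_INTEGER;
      strand[ri] = NA_STRING;
    }
  }
  return DataFrame::create(
    _["mapped"] = mapped, _["score"] = score, _["strand"] = strand,
    _["qstart0"] = qstart, _["qend0"] = qend,
    _["rstart0"] = rstart, _["rend0"] = rend,
    _["stringsAsFactors"] = false);
}
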