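// Protein local alignment kernels: affine-gap Smith-Waterman with full
// traceback, plus a k-mer two-hit prefiltered many-vs-many search.
#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Alphabet: 20 amino acids + X (any).  Index order below must match B62.
static const char AA_ORDER[] = "ARNDCQEGHILKMFPSTWYVX";
static const int NAA = 21;

// BLOSUM62 (NCBI), restricted to the 20 standard residues; X scores -1
// against everything including itself.
static const int B62[NAA][NAA] = {
  //  A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   X
  {   4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0, -1 }, // A
  {  -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3, -1 }, // R
  {  -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3, -1 }, // N
  {  -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3, -1 }, // D
  {   0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1, -1 }, // C
  {  -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2, -1 }, // Q
  {  -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2, -1 }, // E
  {   0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3, -1 }, // G
  {  -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3, -1 }, // H
  {  -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3, -1 }, // I
  {  -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1, -1 }, // L
  {  -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2, -1 }, // K
  {  -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1, -1 }, // M
  {  -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1, -1 }, // F
  {  -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2, -1 }, // P
  {   1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2, -1 }, // S
  {   0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0, -1 }, // T
  {  -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3, -1 }, // W
  {  -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1, -1 }, // Y
  {   0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4, -1 }, // V
  {  -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1 }  // X
};

static int AA_IDX[256];
static bool aa_idx_ready = false;

static void init_aa_idx() {
  if (aa_idx_ready) return;
  for (int i = 0; i < 256; ++i) AA_IDX[i] = NAA - 1; // default to X
  for (int i = 0; i < NAA; ++i) {
    AA_IDX[(unsigned char)AA_ORDER[i]] = i;
    AA_IDX[(unsigned char)std::tolower(AA_ORDER[i])] = i;
  }
  aa_idx_ready = true;
}

struct Aln {
  int score = 0;
  int qs = 0, qe = 0, ss = 0, se = 0; // 0-based half-open
  int ident = 0, len = 0, gapopen = 0, mism = 0;
};

// Affine-gap local alignment; gap of length k costs gap_open + k*gap_extend.
static Aln sw_affine(const std::string &a, const std::string &b,
                     int gap_open, int gap_extend) {
  init_aa_idx();
  const int n = (int)a.size(), m = (int)b.size();
  Aln best;
  if (n == 0 || m == 0) return best;
  if ((double)(n + 1) * (m + 1) > 6.4e7)
    stop("sequences too long for full dynamic programming");

  const int NEG = -1000000000;
  const int W = m + 1;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  // traces: tH in {0 stop,1 diag,2 E(gap in query),3 F(gap in subject)}
  std::vector<unsigned char> tH((n + 1) * W, 0), tE((n + 1) * W, 0), tF((n + 1) * W, 0);

  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) ai[i] = AA_IDX[(unsigned char)a[i]];
  for (int j = 0; j < m; ++j) bi[j] = AA_IDX[(unsigned char)b[j]];

  int bi_best = 0, bj_best = 0;
  for (int i = 1; i <= n; ++i) {
    const int *row = B62[ai[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      // E: gap consuming subject (move left): query i fixed
      int e_open = H[idx - 1] - gap_open - gap_extend;
      int e_ext = E[idx - 1] - gap_extend;
      if (e_open >= e_ext) { E[idx] = e_open; tE[idx] = 1; }
      else { E[idx] = e_ext; tE[idx] = 0; }
      // F: gap consuming query (move up)
      int f_open = H[idx - W] - gap_open - gap_extend;
      int f_ext = F[idx - W] - gap_extend;
      if (f_open >= f_ext) { F[idx] = f_open; tF[idx] = 1; }
      else { F[idx] = f_ext; tF[idx] = 0; }
      int diag = H[idx - W - 1] + row[bi[j - 1]];
      int h = 0; unsigned char t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (F[idx] > h) { h = F[idx]; t = 3; }
      H[idx] = h; tH[idx] = t;
      if (h > best.score) { best.score = h; bi_best = i; bj_best = j; }
    }
  }
  if (best.score <= 0) return best;

  // traceback
  int i = bi_best, j = bj_best;
  best.qe = i; best.se = j;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (true) {
    const int idx = i * W + j;
    if (state == 0) {
      unsigned char t = tH[idx];
      if (t == 0) break;
      if (t == 1) {
        ++best.len;
        if (ai[i - 1] == bi[j - 1] && ai[i - 1] != NAA - 1) ++best.ident;
        else ++best.mism;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++best.len;
      if (tE[idx] == 1) { state = 0; ++best.gapopen; }
      --j;
    } else {
      ++best.len;
      if (tF[idx] == 1) { state = 0; ++best.gapopen; }
      --i;
    }
    if (i == 0 || j == 0) {
      // ran into matrix edge inside a gap run (cannot happen from H)
      break;
    }
  }
  best.qs = i; best.ss = j;
  return best;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, int gap_open, int gap_extend) {
  Aln r = sw_affine(a, b, gap_open, gap_extend);
  return List::create(
    _["score"] = r.score, _["qstart"] = r.qs, _["qend"] = r.qe,
    _["sstart"] = r.ss, _["send"] = r.se, _["ident"] = r.ident,
    _["length"] = r.len, _["gapopen"] = r.gapopen, _["mismatch"] = r.mism);
}

// Vectorized pairwise scores (oracle-style batch interface).
// [[Rcpp::export]]
IntegerVector sw_score_batch_cpp(CharacterVector a, CharacterVector b,
                                 int gap_open, int gap_extend) {
  int n = a.size();
  if (b.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    Aln r = sw_affine(as<std::string>(a[i]), as<std::string>(b[i]),
                      gap_open, gap_extend);
    out[i] = r.score;
  }
  return out;
}

// k-mer index over subjects for the two-hit prefilter
struct KmerIndex {
  int k;
  std::vector<std::vector<std::pair<int, int>>> pos; // code -> (subject, offset)
  KmerIndex(const std::vector<std::string> &subjects, int k_) : k(k_) {
    init_aa_idx();
    size_t ncode = 1;
    for (int i = 0; i < k; ++i) ncode *= NAA;
    pos.resize(ncode);
    for (int s = 0; s < (int)subjects.size(); ++s) {
      const std::string &seq = subjects[s];
      if ((int)seq.size() < k) continue;
      for (int p = 0; p + k <= (int)seq.size(); ++p) {
        int code = 0; bool ok = true;
        for (int t = 0; t < k; ++t) {
          int c = AA_IDX[(unsigned char)seq[p + t]];
          if (c == NAA - 1) { ok = false; break; } // skip kmers with X
          code = code * NAA + c;
        }
        if (ok) pos[code].emplace_back(s, p);
      }
    }
  }
};

struct SeedHit { int subj, diag, qpos; };

// [[Rcpp::export]]
DataFrame search_cpp(CharacterVector queries, CharacterVector subjects,
                     int gap_open, int gap_extend, bool prefilter,
                     int kmer = 4, int max_diag_sep = 3) {
  init_aa_idx();
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::string> subj(ns);
  for (int s = 0; s < ns; ++s) subj[s] = as<std::string>(subjects[s]);

  KmerIndex *index = nullptr;
  if (prefilter) index = new KmerIndex(subj, kmer);

  std::vector<int> o_q, o_s, o_score, o_qs, o_qe, o_ss, o_se,
      o_id, o_len, o_go, o_mm;
  std::vector<int> cand;
  std::vector<char> is_cand(ns, 0);

  for (int q = 0; q < nq; ++q) {
    if (q % 4096 == 0) Rcpp::checkUserInterrupt();
    std::string qs = as<std::string>(queries[q]);
    cand.clear();
    if (prefilter) {
      std::vector<SeedHit> seeds;
      const int L = (int)qs.size();
      for (int p = 0; p + kmer <= L; ++p) {
        int code = 0; bool ok = true;
        for (int t = 0; t < kmer; ++t) {
          int c = AA_IDX[(unsigned char)qs[p + t]];
          if (c == NAA - 1) { ok = false; break; }
          code = code * NAA + c;
        }
        if (!ok) continue;
        for (auto &sp : index->pos[code])
          seeds.push_back({sp.first, p - sp.second, p});
      }
      std::sort(seeds.begin(), seeds.end(), [](const SeedHit &x, const SeedHit &y) {
        if (x.subj != y.subj) return x.subj < y.subj;
        if (x.diag != y.diag) return x.diag < y.diag;
        return x.qpos < y.qpos;
      });
      // two-hit rule: a subject qualifies when a cluster of seeds on
      // nearby diagonals (within max_diag_sep of the previous seed)
      // spans at least kmer query positions, i.e. contains two
      // non-overlapping seed words.
      int qmin = 0, qmax = 0;
      for (size_t i = 0; i < seeds.size(); ++i) {
        bool fresh = i == 0 || seeds[i].subj != seeds[i - 1].subj ||
                     seeds[i].diag - seeds[i - 1].diag > max_diag_sep;
        if (fresh) {
          qmin = qmax = seeds[i].qpos;
        } else {
          qmin = std::min(qmin, seeds[i].qpos);
          qmax = std::max(qmax, seeds[i].qpos);
        }
        if (qmax - qmin >= kmer && !is_cand[seeds[i].subj]) {
          is_cand[seeds[i].subj] = 1;
          cand.push_back(seeds[i].subj);
        }
      }
    } else {
      for (int s = 0; s < ns; ++s) cand.push_back(s);
    }
    for (int s : cand) {
      if (prefilter) is_cand[s] = 0;
      Aln r = sw_affine(qs, subj[s], gap_open, gap_extend);
      if (r.score <= 0) continue;
      o_q.push_back(q + 1); o_s.push_back(s + 1); o_score.push_back(r.score);
      o_qs.push_back(r.qs); o_qe.push_back(r.qe);
      o_ss.push_back(r.ss); o_se.push_back(r.se);
      o_id.push_back(r.ident); o_len.push_back(r.len);
      o_go.push_back(r.gapopen); o_mm.push_back(r.mism);
    }
  }
  if (index) delete index;
  return DataFrame::create(
    _["q_idx"] = o_q, _["s_idx"] = o_s, _["raw_score"] = o_score,
    _["qstart0"] = o_qs, _["qend0"] = o_qe, _["sstart0"] = o_ss,
    _["send0"] = o_se, _["ident"] = o_id, _["aln_len"] = o_len,
    _["gapopen"] = o_go, _["mismatch"] = o_mm);
}
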