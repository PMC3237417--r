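#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Nucleotide pairing for fold: AU, GC, GU (T treated as U, N never pairs).
static inline bool can_pair(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return true;
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return true;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return true;
  return false;
}

// Maximum base-pairing (Nussinov-style) fold with minimum loop of 3 nt.
// Returns 1-based pair table (0 = unpaired). Traceback is deterministic:
// when several structures attain the maximum, closing pairs are preferred
// over leaving i unpaired, and the outermost admissible partner is taken,
// which favours long stacked helices.
// [[Rcpp::export]]
IntegerVector nussinov_pair_table(std::string seq, int min_loop = 3) {
  int n = seq.size();
  IntegerVector pt(n, 0);
  if (n < 2) return pt;
  std::vector<int> N((size_t)n * n, 0);
  auto idx = [n](int i, int j) { return (size_t)i * n + j; };
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = N[idx(i + 1, j)];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int v = 1 + (k - i >= 2 ? N[idx(i + 1, k - 1)] : 0) +
                (k + 1 <= j ? N[idx(k + 1, j)] : 0);
        if (v > best) best = v;
      }
      N[idx(i, j)] = best;
    }
  }
  // iterative traceback over interval stack
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    int target = N[idx(i, j)];
    if (target == 0) continue;
    // prefer pairing i; outermost partner first
    int chosen = -1;
    for (int k = j; k >= i + min_loop + 1; --k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int v = 1 + (k - i >= 2 ? N[idx(i + 1, k - 1)] : 0) +
              (k + 1 <= j ? N[idx(k + 1, j)] : 0);
      if (v == target) { chosen = k; break; }
    }
    if (chosen >= 0) {
      pt[i] = chosen + 1;
      pt[chosen] = i + 1;
      if (chosen - i >= 2) stack.push_back(std::make_pair(i + 1, chosen - 1));
      if (chosen + 1 <= j) stack.push_back(std::make_pair(chosen + 1, j));
    } else {
      stack.push_back(std::make_pair(i + 1, j));
    }
  }
  return pt;
}

// Affine-gap Smith-Waterman (Gotoh). A gap of length L costs
// -(gap_open + gap_extend * (L - 1)). The wildcard character always
// mismatches ('N' for nucleotides, 'X' for proteins -- for proteins 'N'
// is asparagine and must be allowed to match).
// Traceback ties: diagonal > up (gap in subject) > left (gap in query).
// Returns score, 1-based inclusive spans, matches and aligned columns
// (gap runs counted as one column each, for gap-compressed identity).
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, double match = 1.0,
                  double mismatch = -1.0, double gap_open = 2.0,
                  double gap_extend = 1.0, std::string wildcard = "N") {
  char wc = wildcard.empty() ? 'N' : wildcard[0];
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");
  size_t W = (size_t)m + 1;
  std::vector<double> H((size_t)(n + 1) * W, 0.0), E(H), F(H);
  // trace codes: 0 stop, 1 diag, 2 up(E: gap in b/subject), 3 left(F: gap in a)
  std::vector<unsigned char> TH((size_t)(n + 1) * W, 0), TE(TH), TF(TH);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    char ca = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      char cb = b[j - 1];
      size_t c = (size_t)i * W + j;
      size_t up = c - W, left = c - 1, diag = c - W - 1;
      // E: alignment ending with gap in b (consumes a[i])
      double e_open = H[up] - gap_open, e_ext = E[up] - gap_extend;
      if (e_open >= e_ext) { E[c] = e_open; TE[c] = 1; } else { E[c] = e_ext; TE[c] = 0; }
      double f_open = H[left] - gap_open, f_ext = F[left] - gap_extend;
      if (f_open >= f_ext) { F[c] = f_open; TF[c] = 1; } else { F[c] = f_ext; TF[c] = 0; }
      bool is_match = (ca == cb) && ca != wc;
      double d = H[diag] + (is_match ? match : mismatch);
      double h = d; unsigned char t = 1;
      if (E[c] > h) { h = E[c]; t = 2; }
      if (F[c] > h) { h = F[c]; t = 3; }
      if (h <= 0.0) { h = 0.0; t = 0; }
      H[c] = h; TH[c] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int matches = 0, mismatches = 0, gap_runs = 0;
  int i = bi, j = bj, ai_end = bi, bj_end = bj, ai_start = bi, bj_start = bj;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 && j > 0) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      unsigned char t = TH[c];
      if (t == 0) break;
      if (t == 1) {
        bool is_match = (a[i - 1] == b[j - 1]) && a[i - 1] != wc;
        if (is_match) ++matches; else ++mismatches;
        ai_start = i; bj_start = j;
        --i; --j;
      } else if (t == 2) { state = 1; } else { state = 2; }
    } else if (state == 1) {
      ++gap_runs;
      // walk the whole gap run in E
      while (true) {
        size_t c2 = (size_t)i * W + j;
        unsigned char open_here = TE[c2];
        ai_start = i;
        --i;
        if (open_here) break;
      }
      state = 0;
    } else {
      ++gap_runs;
      while (true) {
        size_t c2 = (size_t)i * W + j;
        unsigned char open_here = TF[c2];
        bj_start = j;
        --j;
        if (open_here) break;
      }
      state = 0;
    }
  }
  int aligned_cols = matches + mismatches + gap_runs;
  return List::create(
      _["score"] = best, _["query_start"] = ai_start, _["query_end"] = ai_end,
      _["subject_start"] = bj_start, _["subject_end"] = bj_end,
      _["matches"] = matches, _["mismatches"] = mismatches,
      _["gap_runs"] = gap_runs, _["aligned_cols"] = aligned_cols);
}

static inline char comp_base(char x) {
  switch (x) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'U': return 'A';
    default: return 'N';
  }
}

// Ungapped complementarity scan of a mature miRNA (5'->3') against a cDNA.
// Mature position k faces window position (L - k + 1). Per position:
// Watson-Crick 0, G:U wobble 0.5, other 1; weight doubled at mature
// positions 2..13. Returns per-offset scores (offset = 1-based window start
// in the cDNA) for windows scoring <= max_score.
// [[Rcpp::export]]
DataFrame scan_target_sites(std::string mature, std::string cdna,
                            double max_score = 4.0) {
  int L = mature.size(), n = cdna.size();
  std::vector<int> starts;
  std::vector<double> scores;
  if (n < L || L == 0) {
    return DataFrame::create(_["site_start"] = IntegerVector(0),
                             _["score"] = NumericVector(0));
  }
  for (int s = 0; s + L <= n; ++s) {
    double sc = 0.0;
    for (int k = 1; k <= L && sc <= max_score; ++k) {
      char mk = mature[k - 1];
      if (mk == 'U') mk = 'T';
      char wk = cdna[s + L - k]; // window position L - k + 1
      double pen;
      if (comp_base(wk) == mk && mk != 'N') pen = 0.0;
      else if ((mk == 'G' && wk == 'T') || (mk == 'T' && wk == 'G')) pen = 0.5;
      else pen = 1.0;
      if (k >= 2 && k <= 13) pen *= 2.0;
      sc += pen;
    }
    if (sc <= max_score) {
      starts.push_back(s + 1);
      scores.push_back(sc);
    }
  }
  return DataFrame::create(_["site_start"] = wrap(starts),
                           _["score"] = wrap(scores));
}

// Monte Carlo intersection sampler: draw an m-subset and an n-subset of
// 1..M without replacement (independently) and count their intersection.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector mc_intersection_sample(int M, int m, int n, int reps) {
  IntegerVector out(reps);
  std::vector<int> perm(M), member(M, 0);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < M; ++i) perm[i] = i;
    // partial Fisher-Yates for set 1
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(unif_rand() * (M - i));
      if (j >= M) j = M - 1;
      std::swap(perm[i], perm[j]);
      member[perm[i]] = 1;
    }
    for (int i = 0; i < M; ++i) perm[i] = i;
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      int j = i + (int)(unif_rand() * (M - i));
      if (j >= M) j = M - 1;
      std::swap(perm[i], perm[j]);
      if (member[perm[i]]) ++cnt;
    }
    out[r] = cnt;
    for (int i = 0; i < M; ++i) member[i] = 0;
  }
  return out;
}
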