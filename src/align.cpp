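#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Shared helpers for the protein alignment kernels.
//
// All aligners use BLAST-style affine gap costs: a gap of length g costs
// gap_open + g * gap_extend (the first gap character pays both penalties).
// Sequences arrive as integer vectors of 0-based indices into the rows of
// the substitution matrix (encoding is done once in R).

static const double NEG_INF = -1e18;

// ---------------------------------------------------------------------------
// Local (Smith-Waterman) alignment with traceback statistics.
// Returns raw score, 0-based half-open intervals on both sequences,
// alignment column count (incl. internal gaps), identical columns and
// gap columns.
// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b, IntegerMatrix mat,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0);
  const double go = gap_open + gap_extend, ge = gap_extend;

  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG_INF);
  std::vector<double> F((n + 1) * (m + 1), NEG_INF);
  // traceback codes: 0 stop, 1 diag, 2 from E (gap in a / left), 3 from F (up)
  std::vector<unsigned char> TB((n + 1) * (m + 1), 0);
  std::vector<unsigned char> TE((n + 1) * (m + 1), 0); // 1 = E extended
  std::vector<unsigned char> TF((n + 1) * (m + 1), 0);

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * (m + 1) + j;
      const int up = (i - 1) * (m + 1) + j, left = idx - 1,
                diag = up - 1;
      double e_open = H[left] - go, e_ext = E[left] - ge;
      E[idx] = std::max(e_open, e_ext);
      TE[idx] = e_ext > e_open ? 1 : 0;
      double f_open = H[up] - go, f_ext = F[up] - ge;
      F[idx] = std::max(f_open, f_ext);
      TF[idx] = f_ext > f_open ? 1 : 0;
      double d = H[diag] + mat(ai, b[j - 1]);
      double h = 0.0; unsigned char tb = 0;
      if (d > h) { h = d; tb = 1; }
      if (E[idx] > h) { h = E[idx]; tb = 2; }
      if (F[idx] > h) { h = F[idx]; tb = 3; }
      H[idx] = h; TB[idx] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback
  int i = bi, j = bj;
  int cols = 0, ident = 0, gaps = 0;
  int state = 0; // 0 = in H
  while (i > 0 && j > 0) {
    const int idx = i * (m + 1) + j;
    if (state == 0) {
      unsigned char tb = TB[idx];
      if (tb == 0) break;
      if (tb == 1) {
        ++cols;
        if (a[i - 1] == b[j - 1]) ++ident;
        --i; --j;
      } else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // gap in a, consume b
      ++cols; ++gaps;
      if (!TE[idx]) state = 0;
      --j;
    } else { // gap in b, consume a
      ++cols; ++gaps;
      if (!TF[idx]) state = 0;
      --i;
    }
  }
  return List::create(
      _["score"] = best,
      _["a_start"] = i, _["a_end"] = bi,
      _["b_start"] = j, _["b_end"] = bj,
      _["aln_len"] = cols, _["n_ident"] = ident, _["n_gap_cols"] = gaps);
}

// ---------------------------------------------------------------------------
// Global alignment with free terminal gaps ("overlap" alignment).
// Identity is reported over alignment columns excluding terminal-gap
// columns (core) and, alternatively, over all columns including terminal
// gaps (full).
// [[Rcpp::export]]
List cpp_overlap_align(IntegerVector a, IntegerVector b, IntegerMatrix mat,
                       double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG_INF);
  std::vector<double> F((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> TB((n + 1) * (m + 1), 0);
  std::vector<unsigned char> TE((n + 1) * (m + 1), 0);
  std::vector<unsigned char> TF((n + 1) * (m + 1), 0);
  // free leading gaps: first row/col scores 0, traceback code 0 ends there
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * (m + 1) + j;
      const int up = (i - 1) * (m + 1) + j, left = idx - 1, diag = up - 1;
      double e_open = H[left] - go, e_ext = E[left] - ge;
      E[idx] = std::max(e_open, e_ext);
      TE[idx] = e_ext > e_open ? 1 : 0;
      double f_open = H[up] - go, f_ext = F[up] - ge;
      F[idx] = std::max(f_open, f_ext);
      TF[idx] = f_ext > f_open ? 1 : 0;
      double d = H[diag] + mat(ai, b[j - 1]);
      double h = d; unsigned char tb = 1;
      if (E[idx] > h) { h = E[idx]; tb = 2; }
      if (F[idx] > h) { h = F[idx]; tb = 3; }
      H[idx] = h; TB[idx] = tb;
    }
  }
  // best over last row and last column (free trailing gaps)
  double best = NEG_INF; int bi = n, bj = m;
  for (int j = 0; j <= m; ++j)
    if (H[n * (m + 1) + j] > best) { best = H[n * (m + 1) + j]; bi = n; bj = j; }
  for (int i = 0; i <= n; ++i)
    if (H[i * (m + 1) + m] > best) { best = H[i * (m + 1) + m]; bi = i; bj = m; }

  int i = bi, j = bj, cols = 0, ident = 0, state = 0;
  while (i > 0 && j > 0) {
    const int idx = i * (m + 1) + j;
    if (state == 0) {
      unsigned char tb = TB[idx];
      if (tb == 1) {
        ++cols;
        if (a[i - 1] == b[j - 1]) ++ident;
        --i; --j;
      } else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ++cols;
      if (!TE[idx]) state = 0;
      --j;
    } else {
      ++cols;
      if (!TF[idx]) state = 0;
      --i;
    }
  }
  // terminal (unaligned) overhangs; the path starts and ends on an
  // edge of the matrix, so one of each pair is zero
  int lead = std::max(i, j);
  int trail = std::max(n - bi, m - bj);
  return List::create(
      _["score"] = best, _["cols_core"] = cols, _["n_ident"] = ident,
      _["lead"] = lead, _["trail"] = trail,
      _["a_start"] = i, _["a_end"] = bi, _["b_start"] = j, _["b_end"] = bj);
}

// ---------------------------------------------------------------------------
// Local alignment score + footprint without traceback (start propagation),
// used for gapped extension inside windows of the seeded search.
struct SwHit { double score; int a0, a1, b0, b1; };

static SwHit sw_footprint(const int* a, int n, const int* b, int m,
                          const IntegerMatrix& mat, double go, double ge) {
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG_INF);
  std::vector<double> Fv(m + 1, NEG_INF);
  std::vector<int> Hsa(m + 1, 0), Hsb(m + 1, 0), Esa(m + 1, 0), Esb(m + 1, 0),
      Fsa(m + 1, 0), Fsb(m + 1, 0);
  SwHit best{0.0, 0, 0, 0, 0};
  std::vector<double> Hprev(m + 1, 0.0);
  std::vector<int> HsaP(m + 1, 0), HsbP(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    Hprev = H; HsaP = Hsa; HsbP = Hsb;
    H[0] = 0; Hsa[0] = i; Hsb[0] = 0;
    for (int j = 1; j <= m; ++j) {
      // E: gap consuming b (horizontal)
      double e_open = H[j - 1] - go, e_ext = E[j - 1] - ge;
      if (e_ext > e_open) { E[j] = e_ext; /* Esa/Esb keep */ }
      else { E[j] = e_open; Esa[j] = Hsa[j - 1]; Esb[j] = Hsb[j - 1]; }
      // F: gap consuming a (vertical), uses previous row state of column j
      double f_open = Hprev[j] - go, f_ext = Fv[j] - ge;
      if (f_ext > f_open) { Fv[j] = f_ext; }
      else { Fv[j] = f_open; Fsa[j] = HsaP[j]; Fsb[j] = HsbP[j]; }
      double d = Hprev[j - 1] + mat(a[i - 1], b[j - 1]);
      int dsa = HsaP[j - 1], dsb = HsbP[j - 1];
      if (Hprev[j - 1] == 0.0 && dsa == 0 && dsb == 0) { dsa = i - 1; dsb = j - 1; }
      double h = 0.0; int sa = i, sb = j;
      if (d > h) { h = d; sa = (Hprev[j-1] <= 0.0) ? i - 1 : dsa; sb = (Hprev[j-1] <= 0.0) ? j - 1 : dsb; }
      if (E[j] > h) { h = E[j]; sa = Esa[j]; sb = Esb[j]; }
      if (Fv[j] > h) { h = Fv[j]; sa = Fsa[j]; sb = Fsb[j]; }
      H[j] = h; Hsa[j] = sa; Hsb[j] = sb;
      if (h > best.score) {
        best.score = h; best.a0 = sa; best.a1 = i; best.b0 = sb; best.b1 = j;
      }
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Seeded translated-search kernel for one (query protein, frame protein)
// pair. Finds exact k-mer seeds over the 20 standard residues, performs
// ungapped X-drop extension on the seed diagonal, and for extensions
// scoring >= gap_trigger runs a windowed Smith-Waterman around the
// ungapped segment. Returns candidate HSPs (0-based half-open intervals,
// raw scores); E-values and deduplication happen in R.
// [[Rcpp::export]]
DataFrame cpp_seed_extend(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                          double gap_open, double gap_extend, int k,
                          double xdrop, double gap_trigger, int pad) {
  const int n = q.size(), m = s.size();
  std::vector<double> sc_q0, sc_q1, sc_s0, sc_s1, sc_sc;
  if (n >= k && m >= k) {
    // index query k-mers (standard residues 0..19 only)
    std::unordered_map<long long, std::vector<int> > qidx;
    long long code = 0; int run = 0;
    const long long B = 20;
    long long powk = 1; for (int t = 0; t < k - 1; ++t) powk *= B;
    for (int i = 0; i < n; ++i) {
      int c = q[i];
      if (c < 0 || c >= 20) { run = 0; code = 0; continue; }
      code = (run >= k ? code % powk : code) * B + c;
      ++run;
      if (run >= k) qidx[code].push_back(i - k + 1);
    }
    if (!qidx.empty()) {
      // per-diagonal coverage: furthest subject position already extended
      std::unordered_map<int, int> diag_cov;
      long long scode = 0; int srun = 0;
      for (int j = 0; j < m; ++j) {
        int c = s[j];
        if (c < 0 || c >= 20) { srun = 0; scode = 0; continue; }
        scode = (srun >= k ? scode % powk : scode) * B + c;
        ++srun;
        if (srun < k) continue;
        auto it = qidx.find(scode);
        if (it == qidx.end()) continue;
        int sj = j - k + 1;
        for (int qi : it->second) {
          int d = sj - qi;
          auto dc = diag_cov.find(d);
          if (dc != diag_cov.end() && sj < dc->second) continue;
          // ungapped X-drop extension from the seed
          double seed_sc = 0;
          for (int t = 0; t < k; ++t) seed_sc += mat(q[qi + t], s[sj + t]);
          double bestsc = seed_sc, cur = seed_sc;
          int qa = qi, qb = qi + k, sa = sj, sb = sj + k;
          int bqa = qa, bqb = qb, bsa = sa, bsb = sb;
          // extend right
          { int qq = qb, ss = sb;
            while (qq < n && ss < m) {
              cur += mat(q[qq], s[ss]); ++qq; ++ss;
              if (cur > bestsc) { bestsc = cur; bqb = qq; bsb = ss; }
              if (cur < bestsc - xdrop) break;
            } }
          // extend left
          cur = bestsc;
          { int qq = qa, ss = sa;
            while (qq > 0 && ss > 0) {
              --qq; --ss; cur += mat(q[qq], s[ss]);
              if (cur > bestsc) { bestsc = cur; bqa = qq; bsa = ss; }
              if (cur < bestsc - xdrop) break;
            } }
          diag_cov[d] = std::max(dc != diag_cov.end() ? dc->second : 0, bsb);
          if (bestsc < gap_trigger) continue;
          // gapped stage: windowed Smith-Waterman around the segment
          int w0 = bsa - (bqa + pad); if (w0 < 0) w0 = 0;
          int w1 = bsb + (n - bqb) + pad; if (w1 > m) w1 = m;
          SwHit h = sw_footprint(&q[0], n, &s[0] + w0, w1 - w0, mat,
                                 gap_open + gap_extend, gap_extend);
          if (h.score <= 0) continue;
          sc_q0.push_back(h.a0); sc_q1.push_back(h.a1);
          sc_s0.push_back(w0 + h.b0); sc_s1.push_back(w0 + h.b1);
          sc_sc.push_back(h.score);
        }
      }
    }
  }
  return DataFrame::create(
      _["q_start"] = sc_q0, _["q_end"] = sc_q1,
      _["s_start"] = sc_s0, _["s_end"] = sc_s1, _["score"] = sc_sc);
}
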