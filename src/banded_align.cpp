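#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Banded affine-gap local (Smith-Waterman) alignment of two nucleotide
// sequences, restricted to diagonals d = j - i with band_lo <= d <= band_hi
// (i indexes the query, j the subject, both 1-based). A gap of length L
// costs gap_open + L * gap_extend. Only unambiguous A/C/G/T characters can
// score (and count) as identities; any pair involving an ambiguity code is
// penalised as a mismatch.
//
// Score recurrences use rolling rows; full traceback matrices are kept as
// bytes. NEG is far enough below zero that "cell outside band" needs no
// explicit branch: subtracting gap costs keeps it hopelessly negative.
//
// Returns c(score, aln_len, n_ident, n_gapcols, qstart, qend, sstart, send);
// all zeros when no positive-scoring local alignment exists in the band.

static inline int encode_base(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4; // ambiguity codes never match anything
  }
}

// [[Rcpp::export]]
IntegerVector banded_local_align(std::string q, std::string s,
                                 int band_lo, int band_hi,
                                 int match, int mismatch,
                                 int gap_open, int gap_extend) {
  const int m = (int)q.size(), n = (int)s.size();
  if (m < 1 || n < 1) stop("empty sequence");
  if (band_lo > band_hi) stop("band_lo must be <= band_hi");
  if (band_lo < 1 - m) band_lo = 1 - m;
  if (band_hi > n - 1) band_hi = n - 1;
  if (band_lo > band_hi) return IntegerVector(8, 0);
  const int W = band_hi - band_lo + 1;
  const int NEG = INT_MIN / 4;
  const int go = gap_open + gap_extend, ge = gap_extend;

  std::vector<int> qe(m), se(n);
  for (int i = 0; i < m; ++i) qe[i] = encode_base(q[i]);
  for (int j = 0; j < n; ++j) se[j] = encode_base(s[j]);

  // rolling score rows (index k in 0..W-1), full traceback byte matrices:
  // tbH 0=local start,1=diag,2=from E,3=from F; tbE/tbF 1=open,2=extend
  std::vector<int> Hprev(W, NEG), Hcur(W, NEG), Fprev(W, NEG), Fcur(W, NEG);
  std::vector<unsigned char> tbH((size_t)(m + 1) * W, 0);
  std::vector<unsigned char> tbE((size_t)(m + 1) * W, 0);
  std::vector<unsigned char> tbF((size_t)(m + 1) * W, 0);

  int best = 0, bi = -1, bk = -1;
  for (int i = 1; i <= m; ++i) {
    const int qc = qe[i - 1];
    const int k0 = std::max(0, 1 - i - band_lo);
    const int k1 = std::min(W - 1, n - i - band_lo);
    if (k0 > k1) { std::swap(Hprev, Hcur); std::swap(Fprev, Fcur); continue; }
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    unsigned char *tH = &tbH[(size_t)i * W];
    unsigned char *tE = &tbE[(size_t)i * W];
    unsigned char *tF = &tbF[(size_t)i * W];
    int h_left = NEG, e_left = NEG;
    const bool first_row = (i == 1);
    for (int k = k0; k <= k1; ++k) {
      const int j = i + band_lo + k;

      const int eopen = h_left - go, eext = e_left - ge;
      const int e = eopen >= eext ? eopen : eext;
      tE[k] = (unsigned char)(eopen >= eext ? 1 : 2);

      int f, hp, fp;
      if (k + 1 < W) { hp = Hprev[k + 1]; fp = Fprev[k + 1]; }
      else { hp = NEG; fp = NEG; }
      const int fopen = hp - go, fext = fp - ge;
      f = fopen >= fext ? fopen : fext;
      tF[k] = (unsigned char)(fopen >= fext ? 1 : 2);

      const int hd = (first_row || j == 1) ? 0 : Hprev[k];
      const int sub = (qc == se[j - 1] && qc < 4) ? match : mismatch;
      const int d = hd + sub;

      int h = 0; unsigned char th = 0;
      if (d > h) { h = d; th = 1; }
      if (e > h) { h = e; th = 2; }
      if (f > h) { h = f; th = 3; }
      Hcur[k] = h; Fcur[k] = f; tH[k] = th;
      if (h > best) { best = h; bi = i; bk = k; }

      h_left = h; e_left = e;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  IntegerVector out(8, 0);
  if (best <= 0) return out;

  // traceback over the stored move matrices
  int i = bi, k = bk;
  int aln_len = 0, n_ident = 0, n_gap = 0;
  const int qend = bi, send = bi + band_lo + bk;
  int qstart = qend + 1, sstart = send + 1;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    const size_t idx = (size_t)i * W + k;
    if (state == 0) {
      const unsigned char t = tbH[idx];
      if (t == 0) break;
      if (t == 1) {
        const int j = i + band_lo + k;
        ++aln_len;
        if (qe[i - 1] == se[j - 1] && qe[i - 1] < 4) ++n_ident;
        qstart = i; sstart = j;
        --i;                       // diagonal keeps k
        if (i == 0 || i + band_lo + k < 1) break;
      } else if (t == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {       // E: consumed s[j], gap in query
      ++aln_len; ++n_gap;
      sstart = i + band_lo + k;
      state = (tbE[idx] == 2) ? 1 : 0;
      --k;                         // move to (i, j-1)
    } else {                       // F: consumed q[i], gap in subject
      ++aln_len; ++n_gap;
      qstart = i;
      state = (tbF[idx] == 2) ? 2 : 0;
      --i; ++k;                    // move to (i-1, j)
    }
  }

  out[0] = best; out[1] = aln_len; out[2] = n_ident; out[3] = n_gap;
  out[4] = qstart; out[5] = qend; out[6] = sstart; out[7] = send;
  return out;
}
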