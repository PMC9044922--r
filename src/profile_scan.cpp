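#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of a protein against a position-specific
// scoring profile with affine gaps.  Rows = protein positions, columns =
// profile columns.  Gap convention: the first gapped position costs
// gap_open, each further position gap_extend.  Masked protein positions can
// never take part in an alignment (used for iterative best-hit extraction).
//
// Returns the single best-scoring local hit and a traceback map giving, for
// every profile column, the residue index aligned to it (0 = gap/unaligned).
// Ties are resolved match > delete > insert and, among equal-scoring end
// cells, the one with the smallest protein position then smallest profile
// column, which makes hits deterministic and leftmost.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".profile_local_align")]]
List profile_local_align(IntegerVector seq,     // 1-based residue index, 0 = unknown
                         NumericMatrix scores,  // L x 20 position-specific scores
                         double gap_open,
                         double gap_extend,
                         LogicalVector mask) {
  const int n = seq.size();
  const int L = scores.nrow();
  if (n == 0 || L == 0)
    return List::create(_["score"] = 0.0, _["found"] = false);

  // DP matrices, (n+1) x (L+1), row-major
  std::vector<double> M((n + 1) * (L + 1), NEG_INF);
  std::vector<double> Ix(M.size(), NEG_INF);  // gap in profile (extra protein residue)
  std::vector<double> Iy(M.size(), NEG_INF);  // gap in protein (deleted profile column)
  // traceback: for M 0=fresh start,1=M,2=Ix,3=Iy; for Ix/Iy 1=from M,2=extend
  std::vector<unsigned char> tM(M.size(), 0), tIx(M.size(), 0), tIy(M.size(), 0);

  const int W = L + 1;
  double best = 0.0;
  int bi = -1, bj = -1;

  for (int i = 1; i <= n; ++i) {
    const bool usable = !mask[i - 1] && seq[i - 1] >= 1 && seq[i - 1] <= 20;
    for (int j = 1; j <= L; ++j) {
      const int idx = i * W + j, dg = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      // match state
      if (usable) {
        double s = scores(j - 1, seq[i - 1] - 1);
        double prev = 0.0; unsigned char t = 0;
        if (M[dg] > prev) { prev = M[dg]; t = 1; }
        if (Ix[dg] > prev) { prev = Ix[dg]; t = 2; }
        if (Iy[dg] > prev) { prev = Iy[dg]; t = 3; }
        M[idx] = s + prev; tM[idx] = t;
      }
      // insertion in protein (consumes residue i, stays on column j);
      // an insertion may not span a masked residue either
      if (!mask[i - 1]) {
        double fromM = M[up] - gap_open, ext = Ix[up] - gap_extend;
        if (fromM >= ext) { Ix[idx] = fromM; tIx[idx] = 1; }
        else              { Ix[idx] = ext;   tIx[idx] = 2; }
      }
      // deletion of profile column j (no residue consumed)
      {
        double fromM = M[lf] - gap_open, ext = Iy[lf] - gap_extend;
        if (fromM >= ext) { Iy[idx] = fromM; tIy[idx] = 1; }
        else              { Iy[idx] = ext;   tIy[idx] = 2; }
      }
      if (M[idx] > best + 1e-12) { best = M[idx]; bi = i; bj = j; }
    }
  }

  if (bi < 0)
    return List::create(_["score"] = 0.0, _["found"] = false);

  // traceback from (bi, bj) in state M
  IntegerVector col_res(L, 0);     // residue index aligned to each profile column
  int i = bi, j = bj, state = 0;   // 0 = M, 1 = Ix, 2 = Iy
  int prot_start = bi, prof_start = bj;
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      col_res[j - 1] = seq[i - 1];
      prot_start = i; prof_start = j;
      const unsigned char t = tM[idx];
      --i; --j;
      if (t == 0) break;
      state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
    } else if (state == 1) {
      const unsigned char t = tIx[idx];
      prot_start = i;
      --i;
      state = (t == 1) ? 0 : 1;
    } else {
      const unsigned char t = tIy[idx];
      --j;
      state = (t == 1) ? 0 : 2;
    }
  }

  return List::create(
    _["score"] = best,
    _["found"] = true,
    _["prot_start"] = prot_start,  // 1-based inclusive
    _["prot_end"] = bi,
    _["prof_start"] = prof_start,
    _["prof_end"] = bj,
    _["col_res"] = col_res);
}
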