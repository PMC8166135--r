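#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -1e18;

// ---------------------------------------------------------------------------
// Affine-gap global alignment over a precomputed column-similarity matrix.
// Used for pairwise protein alignment and for profile-profile merges in the
// progressive MSA.  Returns the operation path: 1 = diagonal (align column of
// A with column of B), 2 = consume A column (gap in B), 3 = consume B column
// (gap in A).  Ties prefer diagonal, then consuming A, keeping leftmost paths
// deterministic.
// [[Rcpp::export]]
List align_profiles_cpp(NumericMatrix C, double gap_open, double gap_ext) {
  const int m = C.nrow(), n = C.ncol();
  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> X((m + 1) * (n + 1), NEG_INF); // gap in B (A consumed)
  std::vector<double> Y((m + 1) * (n + 1), NEG_INF); // gap in A (B consumed)
  std::vector<uint8_t> tbM((m + 1) * (n + 1), 0), tbX((m + 1) * (n + 1), 0),
      tbY((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) {
    X[at(i, 0)] = gap_open + (i - 1) * gap_ext;
    tbX[at(i, 0)] = (i == 1) ? 1 : 2; // from M : from X
  }
  for (int j = 1; j <= n; ++j) {
    Y[at(0, j)] = gap_open + (j - 1) * gap_ext;
    tbY[at(0, j)] = (j == 1) ? 1 : 3;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // M from best of three at (i-1, j-1)
      double bm = M[at(i - 1, j - 1)];
      uint8_t src = 1;
      if (X[at(i - 1, j - 1)] > bm) { bm = X[at(i - 1, j - 1)]; src = 2; }
      if (Y[at(i - 1, j - 1)] > bm) { bm = Y[at(i - 1, j - 1)]; src = 3; }
      M[at(i, j)] = bm + C(i - 1, j - 1);
      tbM[at(i, j)] = src;
      // X: consume A column
      double xo = M[at(i - 1, j)] + gap_open;
      double xe = X[at(i - 1, j)] + gap_ext;
      double yo = Y[at(i - 1, j)] + gap_open;
      if (xo >= xe && xo >= yo) { X[at(i, j)] = xo; tbX[at(i, j)] = 1; }
      else if (xe >= yo)        { X[at(i, j)] = xe; tbX[at(i, j)] = 2; }
      else                      { X[at(i, j)] = yo; tbX[at(i, j)] = 3; }
      // Y: consume B column
      double ym = M[at(i, j - 1)] + gap_open;
      double ye = Y[at(i, j - 1)] + gap_ext;
      double yx = X[at(i, j - 1)] + gap_open;
      if (ym >= ye && ym >= yx) { Y[at(i, j)] = ym; tbY[at(i, j)] = 1; }
      else if (ye >= yx)        { Y[at(i, j)] = ye; tbY[at(i, j)] = 3; }
      else                      { Y[at(i, j)] = yx; tbY[at(i, j)] = 2; }
    }
  }
  double best = M[at(m, n)];
  int state = 1;
  if (X[at(m, n)] > best) { best = X[at(m, n)]; state = 2; }
  if (Y[at(m, n)] > best) { best = Y[at(m, n)]; state = 3; }

  std::vector<int> ops;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 1) {
      uint8_t s = tbM[at(i, j)];
      ops.push_back(1); --i; --j; state = s;
    } else if (state == 2) {
      uint8_t s = tbX[at(i, j)];
      ops.push_back(2); --i; state = s;
    } else {
      uint8_t s = tbY[at(i, j)];
      ops.push_back(3); --j; state = s;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["ops"] = wrap(ops));
}

// ---------------------------------------------------------------------------
// Pairwise identity distances on an integer-coded alignment matrix
// (rows = sequences).  d = 1 - identical/comparable over columns where
// neither row holds the gap code; pairs without comparable columns get
// distance 1 (flagged by count 0 in the returned attribute).
// [[Rcpp::export]]
List identity_dist_cpp(IntegerMatrix msa, int gap_code) {
  const int n = msa.nrow(), L = msa.ncol();
  NumericMatrix d(n, n);
  IntegerMatrix comp(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int comparable = 0, same = 0;
      for (int c = 0; c < L; ++c) {
        int xa = msa(a, c), xb = msa(b, c);
        if (xa != gap_code && xb != gap_code) {
          ++comparable;
          if (xa == xb) ++same;
        }
      }
      double dist = comparable > 0 ?
        1.0 - (double)same / comparable : 1.0;
      d(a, b) = dist; d(b, a) = dist;
      comp(a, b) = comparable; comp(b, a) = comparable;
    }
  }
  return List::create(_["d"] = d, _["comparable"] = comp);
}

// ---------------------------------------------------------------------------
// Frameshift-aware protein-to-DNA alignment in codon space.
//
// Glocal: the DNA flanks are free, the whole protein must be consumed.
// States: M (codon aligned to a residue; includes stop read-through and
// +-1/+-2 frameshift codons), X (protein gap: residue unaligned), Y (DNA
// codon gap, affine per codon), L (long DNA gap: flat opening penalty, free
// 1-nt extension; models large insertions).
//
// prot: 0-based indices into the substitution matrix rows; dna: 0-based
// indices 0..3 = ACGT (4 = N); submat: square substitution matrix;
// codon_aa: length-64 map codon index -> aa index in submat (-1 = stop).
// [[Rcpp::export]]
List frameshift_align_cpp(IntegerVector prot, IntegerVector dna,
                          NumericMatrix submat, IntegerVector codon_aa,
                          double gap_open, double gap_ext, double fs_pen,
                          double stop_pen, double lg_open, bool ends_free) {
  const int m = prot.size(), n = dna.size();
  const bool use_long = R_finite(lg_open);

  // codon index ending at dna position j (1-based j in DP): bases j-3..j-1
  std::vector<int> codon(n + 1, -2); // -2 = invalid (contains N / short)
  for (int j = 3; j <= n; ++j) {
    int b1 = dna[j - 3], b2 = dna[j - 2], b3 = dna[j - 1];
    if (b1 < 4 && b2 < 4 && b3 < 4) codon[j] = 16 * b1 + 4 * b2 + b3;
  }

  const size_t sz = (size_t)(m + 1) * (n + 1);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  std::vector<uint8_t> tbM(sz, 0), tbX(sz, 0), tbY(sz, 0), tbL(sz, 0);
  // rolling rows for scores
  std::vector<double> Mp(n + 1), Xp(n + 1), Yp(n + 1), Lp(n + 1);
  std::vector<double> Mc(n + 1), Xc(n + 1), Yc(n + 1), Lc(n + 1);

  if (ends_free) {
    for (int j = 0; j <= n; ++j) {
      Mp[j] = 0.0; Xp[j] = NEG_INF; Yp[j] = NEG_INF; Lp[j] = NEG_INF;
    }
  } else {
    // global on DNA: the 5' flank must be consumed by gap states
    for (int j = 0; j <= n; ++j) {
      Mp[j] = (j == 0) ? 0.0 : NEG_INF;
      Xp[j] = NEG_INF; Yp[j] = NEG_INF; Lp[j] = NEG_INF;
    }
    for (int j = 3; j <= n; j += 3) {
      if (j == 3) { Yp[j] = gap_open; tbY[at(0, j)] = 1; }
      else        { Yp[j] = Yp[j - 3] + gap_ext; tbY[at(0, j)] = 2; }
    }
    if (use_long) {
      for (int j = 1; j <= n; ++j) {
        double lo = (j == 1) ? lg_open : NEG_INF;
        double le = Lp[j - 1];
        double ly = Yp[j - 1] + lg_open;
        if (lo >= le && lo >= ly) { Lp[j] = lo; tbL[at(0, j)] = 1; }
        else if (le >= ly)        { Lp[j] = le; tbL[at(0, j)] = 2; }
        else                      { Lp[j] = ly; tbL[at(0, j)] = 4; }
      }
    }
  }
  // nt consumed per M-op and its shift: order = preference (codon first)
  const int dsteps[5] = {3, 2, 4, 1, 5};

  for (int i = 1; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      Mc[j] = NEG_INF; Xc[j] = NEG_INF; Yc[j] = NEG_INF; Lc[j] = NEG_INF;
      // ---- M ----
      double bestM = NEG_INF; uint8_t bestMtb = 0;
      for (int di = 0; di < 5; ++di) {
        int d = dsteps[di];
        if (j < d) continue;
        double base = Mp[j - d]; uint8_t src = 0; // 0=M 1=X 2=Y 3=L
        if (Xp[j - d] > base) { base = Xp[j - d]; src = 1; }
        if (Yp[j - d] > base) { base = Yp[j - d]; src = 2; }
        if (Lp[j - d] > base) { base = Lp[j - d]; src = 3; }
        if (base <= NEG_INF / 2) continue;
        double sc;
        if (d == 3) {
          int c = codon[j];
          if (c == -2) continue;
          int aa = codon_aa[c];
          sc = (aa < 0) ? stop_pen : submat(prot[i - 1], aa);
        } else {
          sc = fs_pen;
        }
        double v = base + sc;
        if (v > bestM) { bestM = v; bestMtb = (uint8_t)(d * 4 + src + 1); }
      }
      Mc[j] = bestM; tbM[at(i, j)] = bestMtb;
      // ---- X (protein gap, consume 1 aa, 0 nt) ----
      double xo = Mp[j] + gap_open, xe = Xp[j] + gap_ext;
      double xy = Yp[j] + gap_open, xl = Lp[j] + gap_open;
      double bx = xo; uint8_t tx = 1;
      if (xe > bx) { bx = xe; tx = 2; }
      if (xy > bx) { bx = xy; tx = 3; }
      if (xl > bx) { bx = xl; tx = 4; }
      Xc[j] = bx; tbX[at(i, j)] = tx;
      // ---- Y (codon gap in protein view: consume 3 nt) ----
      if (j >= 3) {
        double yo = Mc[j - 3] + gap_open, ye = Yc[j - 3] + gap_ext;
        double yx = Xc[j - 3] + gap_open;
        double by = yo; uint8_t ty = 1;
        if (ye > by) { by = ye; ty = 2; }
        if (yx > by) { by = yx; ty = 3; }
        Yc[j] = by; tbY[at(i, j)] = ty;
      }
      // ---- L (long DNA gap, 1 nt steps) ----
      if (use_long && j >= 1) {
        double lo = Mc[j - 1] + lg_open, le = Lc[j - 1];
        double lx = Xc[j - 1] + lg_open, ly = Yc[j - 1] + lg_open;
        double bl = lo; uint8_t tl = 1;
        if (le > bl) { bl = le; tl = 2; }
        if (lx > bl) { bl = lx; tl = 3; }
        if (ly > bl) { bl = ly; tl = 4; }
        Lc[j] = bl; tbL[at(i, j)] = tl;
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc);
    std::swap(Yp, Yc); std::swap(Lp, Lc);
  }

  // best end: protein fully consumed; trailing DNA free (glocal) or fully
  // consumed by any state (global)
  double best = NEG_INF; int bj = 0, bstate = 0; // 0=M 1=X 2=Y 3=L
  if (ends_free) {
    for (int j = 0; j <= n; ++j) {
      if (Mp[j] > best) { best = Mp[j]; bj = j; bstate = 0; }
      if (Xp[j] > best) { best = Xp[j]; bj = j; bstate = 1; }
    }
  } else {
    best = Mp[n]; bj = n; bstate = 0;
    if (Xp[n] > best) { best = Xp[n]; bstate = 1; }
    if (Yp[n] > best) { best = Yp[n]; bstate = 2; }
    if (Lp[n] > best) { best = Lp[n]; bstate = 3; }
  }
  if (best <= NEG_INF / 2) stop("no feasible alignment");

  // traceback; op codes: 1 codon, 2 frameshift, 3 protein_gap,
  // 4 dna_gap_3n, 5 long_gap
  std::vector<int> op, shift, aa_idx, d_start, d_end;
  int i = m, j = bj, state = bstate; // 0=M 1=X 2=Y 3=L
  int dna_end = bj;
  while (i > 0 || (!ends_free && j > 0)) {
    if (state == 0) {
      uint8_t tb = tbM[at(i, j)];
      int d = (tb - 1) / 4, src = (tb - 1) % 4;
      if (d == 3) {
        op.push_back(1); shift.push_back(0);
      } else {
        op.push_back(2); shift.push_back(d - 3);
      }
      aa_idx.push_back(i); d_start.push_back(j - d); d_end.push_back(j);
      i -= 1; j -= d; state = src;
    } else if (state == 1) {
      uint8_t tb = tbX[at(i, j)];
      op.push_back(3); shift.push_back(0);
      aa_idx.push_back(i); d_start.push_back(j); d_end.push_back(j);
      i -= 1; state = (tb == 1) ? 0 : (tb == 2) ? 1 : (tb == 3) ? 2 : 3;
    } else if (state == 2) {
      uint8_t tb = tbY[at(i, j)];
      op.push_back(4); shift.push_back(0);
      aa_idx.push_back(NA_INTEGER); d_start.push_back(j - 3); d_end.push_back(j);
      j -= 3; state = (tb == 1) ? 0 : (tb == 2) ? 2 : 1;
    } else {
      uint8_t tb = tbL[at(i, j)];
      op.push_back(5); shift.push_back(0);
      aa_idx.push_back(NA_INTEGER); d_start.push_back(j - 1); d_end.push_back(j);
      j -= 1; state = (tb == 1) ? 0 : (tb == 2) ? 3 : (tb == 3) ? 1 : 2;
    }
  }
  int dna_start = j;
  std::reverse(op.begin(), op.end());
  std::reverse(shift.begin(), shift.end());
  std::reverse(aa_idx.begin(), aa_idx.end());
  std::reverse(d_start.begin(), d_start.end());
  std::reverse(d_end.begin(), d_end.end());
  return List::create(_["score"] = best, _["op"] = wrap(op),
                      _["shift"] = wrap(shift), _["aa_idx"] = wrap(aa_idx),
                      _["dna_start"] = wrap(d_start),
                      _["dna_end"] = wrap(d_end),
                      _["dna_aln_start"] = dna_start,
                      _["dna_aln_end"] = dna_end);
}
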