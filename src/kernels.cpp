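#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Online single-pass clustering of fixed-length subsequences by ungapped
// BLOSUM similarity.  Each subsequence is compared against every existing
// cluster (its founding representative by default, or every member when
// compare_members is true); it joins the best-scoring cluster if that score
// reaches the threshold t, ties going to the earliest-created cluster,
// otherwise it founds a new cluster.  Residue indices are 1-based positions
// in the fixed 20-letter alphabet.
// [[Rcpp::export]]
List cpp_spmap_cluster(IntegerMatrix ss, IntegerMatrix blosum, int t,
                       bool compare_members) {
  const int n = ss.nrow();
  const int l = ss.ncol();
  std::vector<int> rep_row;              // founding row per cluster
  std::vector<std::vector<int> > member_rows;
  std::vector<int> assign(n);

  // row-major copy of subsequences for cache locality
  std::vector<int> s(n * l);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < l; ++j) s[i * l + j] = ss(i, j) - 1;

  const int na = blosum.nrow();
  std::vector<int> B(na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b) B[a * na + b] = blosum(a, b);

  for (int i = 0; i < n; ++i) {
    const int *xi = &s[i * l];
    int best = std::numeric_limits<int>::min();
    int best_c = -1;
    const int nc = (int) rep_row.size();
    for (int c = 0; c < nc; ++c) {
      int sc;
      if (!compare_members) {
        const int *rc = &s[rep_row[c] * l];
        sc = 0;
        for (int j = 0; j < l; ++j) sc += B[xi[j] * na + rc[j]];
      } else {
        sc = std::numeric_limits<int>::min();
        for (size_t m = 0; m < member_rows[c].size(); ++m) {
          const int *rc = &s[member_rows[c][m] * l];
          int v = 0;
          for (int j = 0; j < l; ++j) v += B[xi[j] * na + rc[j]];
          if (v > sc) sc = v;
        }
      }
      if (sc > best) { best = sc; best_c = c; }  // strict: earliest wins ties
    }
    if (best_c >= 0 && best >= t) {
      assign[i] = best_c;
      member_rows[best_c].push_back(i);
    } else {
      assign[i] = (int) rep_row.size();
      rep_row.push_back(i);
      member_rows.push_back(std::vector<int>(1, i));
    }
  }

  const int nc = (int) rep_row.size();
  IntegerVector sizes(nc);
  for (int c = 0; c < nc; ++c) sizes[c] = (int) member_rows[c].size();

  // per-cluster position x residue counts, dim (l, 20, nc)
  IntegerVector counts(l * 20 * nc);
  for (int i = 0; i < n; ++i) {
    const int c = assign[i];
    for (int j = 0; j < l; ++j)
      counts[c * l * 20 + s[i * l + j] * l + j] += 1;
  }
  counts.attr("dim") = IntegerVector::create(l, 20, nc);

  IntegerVector assign_r(n), rep_r(nc);
  for (int i = 0; i < n; ++i) assign_r[i] = assign[i] + 1;
  for (int c = 0; c < nc; ++c) rep_r[c] = rep_row[c] + 1;

  return List::create(_["assignment"] = assign_r,
                      _["representative_row"] = rep_r,
                      _["sizes"] = sizes,
                      _["counts"] = counts);
}

// Gotoh affine-gap alignment, score only, integer arithmetic.  A gap of
// length L costs open + L * ext (the Biostrings convention).  local =
// Smith-Waterman (scores floored at zero), otherwise global
// Needleman-Wunsch with end-gap penalties.  Sequences are 1-based
// indices into the row/column order of sub.
// [[Rcpp::export]]
NumericVector cpp_align_batch(IntegerVector query, List targets,
                              IntegerMatrix sub, int gap_open,
                              int gap_ext, bool local) {
  const int m = query.size();
  const int na = sub.nrow();
  std::vector<int> S(na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b) S[a * na + b] = sub(a, b);
  const int NEG = std::numeric_limits<int>::min() / 4;
  const int nt = targets.size();
  NumericVector out(nt);

  std::vector<int> q(m);
  for (int i = 0; i < m; ++i) q[i] = query[i] - 1;

  std::vector<int> H, E, y;
  for (int tt = 0; tt < nt; ++tt) {
    IntegerVector tv = targets[tt];
    const int n = tv.size();
    y.resize(n);
    for (int j = 0; j < n; ++j) y[j] = tv[j] - 1;

    H.assign(n + 1, 0);
    E.assign(n + 1, NEG);
    int best = 0;
    if (!local)
      for (int j = 1; j <= n; ++j) H[j] = -(gap_open + j * gap_ext);
    int *Hp = H.data();
    int *Ep = E.data();
    const int *yp = y.data();

    for (int i = 1; i <= m; ++i) {
      int Hdiag = Hp[0];
      int F = NEG;
      Hp[0] = local ? 0 : -(gap_open + i * gap_ext);
      int Hleft = Hp[0];               // H(i, j-1)
      const int *Srow = &S[q[i - 1] * na];
      for (int j = 1; j <= n; ++j) {
        const int e = std::max(Ep[j], Hp[j] - gap_open) - gap_ext;
        Ep[j] = e;                                   // gap consuming query row
        F = std::max(F, Hleft - gap_open) - gap_ext; // gap consuming target col
        int h = Hdiag + Srow[yp[j - 1]];
        if (e > h) h = e;
        if (F > h) h = F;
        if (local && h < 0) h = 0;
        Hdiag = Hp[j];
        Hp[j] = h;
        Hleft = h;
        if (local && h > best) best = h;
      }
    }
    out[tt] = local ? best : Hp[n];
  }
  return out;
}

// Global affine-gap alignment that additionally reports the number of
// identical aligned positions and the alignment length (columns, gaps
// included) along one optimal-score path.  Ties are resolved
// deterministically: diagonal, then gap-in-query, then gap-in-target;
// gap opening is preferred over extension at equal score.
// [[Rcpp::export]]
NumericMatrix cpp_global_align_stats(IntegerVector query, List targets,
                                     IntegerMatrix sub, int gap_open,
                                     int gap_ext) {
  const int m = query.size();
  const int na = sub.nrow();
  std::vector<int> S(na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b) S[a * na + b] = sub(a, b);
  const int NEG = std::numeric_limits<int>::min() / 4;
  const int nt = targets.size();
  NumericMatrix out(nt, 3);
  colnames(out) = CharacterVector::create("score", "matches", "alnlen");

  std::vector<int> q(m);
  for (int i = 0; i < m; ++i) q[i] = query[i] - 1;

  for (int tt = 0; tt < nt; ++tt) {
    IntegerVector tv = targets[tt];
    const int n = tv.size();
    std::vector<int> y(n);
    for (int j = 0; j < n; ++j) y[j] = tv[j] - 1;

    // rolling rows; for each DP state keep score + match count + length
    std::vector<int> H(n + 1), E(n + 1);
    std::vector<int> Hm(n + 1), HL(n + 1), Em(n + 1), EL(n + 1);

    H[0] = 0; Hm[0] = 0; HL[0] = 0;
    E[0] = NEG; Em[0] = 0; EL[0] = 0;
    for (int j = 1; j <= n; ++j) {
      H[j] = -(gap_open + j * gap_ext); Hm[j] = 0; HL[j] = j;
      E[j] = NEG; Em[j] = 0; EL[j] = j;
    }

    for (int i = 1; i <= m; ++i) {
      int Hdiag = H[0]; int Hdm = Hm[0], HdL = HL[0];
      int F = NEG; int Fm = 0, FL = 0;
      H[0] = -(gap_open + i * gap_ext); Hm[0] = 0; HL[0] = i;
      int Hup = H[0]; int Hupm = Hm[0], HupL = HL[0];
      const int *Srow = &S[q[i - 1] * na];
      for (int j = 1; j <= n; ++j) {
        // E: gap in query (consumes target column j)
        const int e_open = H[j] - gap_open - gap_ext;
        const int e_ext  = E[j] - gap_ext;
        if (e_open >= e_ext) { E[j] = e_open; Em[j] = Hm[j]; EL[j] = HL[j] + 1; }
        else                 { E[j] = e_ext;  EL[j] = EL[j] + 1; }
        // F: gap in target (consumes query row i)
        const int f_open = Hup - gap_open - gap_ext;
        const int f_ext  = F - gap_ext;
        if (f_open >= f_ext) { F = f_open; Fm = Hupm; FL = HupL + 1; }
        else                 { F = f_ext;  FL = FL + 1; }
        // H: best of diagonal / E / F, diagonal preferred on ties
        const int d = Hdiag + Srow[y[j - 1]];
        const int dm = Hdm + (q[i - 1] == y[j - 1] ? 1 : 0);
        const int dL = HdL + 1;
        int h, hm, hL;
        if (d >= E[j] && d >= F) { h = d; hm = dm; hL = dL; }
        else if (E[j] >= F)      { h = E[j]; hm = Em[j]; hL = EL[j]; }
        else                     { h = F; hm = Fm; hL = FL; }
        Hdiag = H[j]; Hdm = Hm[j]; HdL = HL[j];
        H[j] = h; Hm[j] = hm; HL[j] = hL;
        Hup = h; Hupm = hm; HupL = hL;
      }
    }
    out(tt, 0) = H[n];
    out(tt, 1) = Hm[n];
    out(tt, 2) = HL[n];
  }
  return out;
}
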