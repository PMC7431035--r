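// Affine-gap alignment engine.
//
// Conventions shared with the R layer:
//  * sequences are plain ASCII over {A,C,G,T,N}; N scores as a mismatch
//    against everything (including N);
//  * gap cost: first gap column costs gap_open, each further column in the
//    same gap costs gap_extend;
//  * traceback ties are broken deterministically: diagonal, then gap in b
//    (consuming a), then gap in a;
//  * all reported intervals are 0-based half-open.

#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <vector>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4; // N and anything else: always mismatch
  }
}

static inline int subst(int ca, int cb, int match, int mismatch) {
  if (ca == 4 || cb == 4) return mismatch;
  return (ca == cb) ? match : mismatch;
}

// trace byte layout:
//   bits 0-1 : predecessor of M  (0 = local start, 1 = M, 2 = Ix, 3 = Iy)
//   bit  2   : Ix extends Ix (else opened from M)
//   bit  3   : Iy extends Iy (else opened from M)
struct DPResult {
  int best_score, best_i, best_j; // best M cell (local) / final cell (global)
};

// Fill the DP. Score matrices are kept as rolling rows (previous/current);
// only the packed traceback byte matrix is stored in full. mask (may be
// empty) forbids aligning a[i-1] with b[j-1]. NEG is far enough from
// INT_MIN that subtracting penalties can never wrap.
static DPResult fill_dp(const std::vector<int>& a, const std::vector<int>& b,
                        int match, int mismatch, int go, int ge,
                        bool global,
                        const std::vector<uint8_t>& mask,
                        std::vector<uint8_t>& tr) {
  const size_t m = a.size(), n = b.size(), w = n + 1;
  tr.assign((m + 1) * w, 0);

  std::vector<int> pM(w, NEG), pX(w, NEG), pY(w, NEG);
  std::vector<int> cM(w, NEG), cX(w, NEG), cY(w, NEG);
  pM[0] = 0;
  if (global) {
    for (size_t j = 1; j <= n; ++j) {
      pY[j] = -(go + (int)(j - 1) * ge);
      tr[j] |= (j > 1) ? 8 : 0;
    }
  }

  DPResult res; res.best_score = global ? NEG : 0; res.best_i = 0; res.best_j = 0;
  std::vector<int> srow(n);

  for (size_t i = 1; i <= m; ++i) {
    uint8_t* trow = &tr[i * w];
    cM[0] = NEG; cY[0] = NEG;
    if (global) {
      cX[0] = -(go + (int)(i - 1) * ge);
      trow[0] |= (i > 1) ? 4 : 0;
    } else {
      cX[0] = NEG;
    }
    const int ai = a[i - 1];
    for (size_t j = 0; j < n; ++j)
      srow[j] = (ai == b[j] && ai != 4) ? match : mismatch;
    const uint8_t* mrow = mask.empty() ? NULL : &mask[(i - 1) * n];
    for (size_t j = 1; j <= n; ++j) {
      // Ix: gap in b, consumes a[i-1]; tie prefers opening from M
      int fromM = pM[j] - go, fromI = pX[j] - ge;
      uint8_t t = 0;
      if (fromI > fromM) { cX[j] = fromI; t = 4; } else cX[j] = fromM;
      // Iy: gap in a, consumes b[j-1]
      int oM = cM[j - 1] - go, oY = cY[j - 1] - ge;
      if (oY > oM) { cY[j] = oY; t |= 8; } else cY[j] = oM;
      // M: aligned pair
      if (mrow && mrow[j - 1]) { cM[j] = NEG; trow[j] = t; continue; }
      int dM = pM[j - 1], dX = pX[j - 1], dY = pY[j - 1];
      int best = dM; uint8_t code = 1;            // prefer diagonal
      if (dX > best) { best = dX; code = 2; }     // then gap-in-b
      if (dY > best) { best = dY; code = 3; }     // then gap-in-a
      if (!global && 0 > best) { best = 0; code = 0; } // fresh start last
      cM[j] = best + srow[j - 1];
      trow[j] = t | code;
      if (!global && cM[j] > res.best_score) {
        res.best_score = cM[j]; res.best_i = (int)i; res.best_j = (int)j;
      }
    }
    pM.swap(cM); pX.swap(cX); pY.swap(cY);
  }

  if (global) {
    // after the final swap the last row lives in the p* vectors
    int bm = pM[n], bx = pX[n], by = pY[n];
    res.best_score = bm; res.best_i = 0; // best_i reused as final state: 0=M,1=Ix,2=Iy
    if (bx > res.best_score) { res.best_score = bx; res.best_i = 1; }
    if (by > res.best_score) { res.best_score = by; res.best_i = 2; }
  }
  return res;
}

// Traceback from M-state cell (ei, ej) [local] or from given final state at
// (m, n) [global]. Returns alignment as R list.
static List traceback(const std::string& sa, const std::string& sb,
                      const std::vector<uint8_t>& tr, size_t n,
                      int ei, int ej, int final_state, bool global, int score,
                      std::vector<std::pair<int,int> >* used_pairs) {
  const size_t w = n + 1;
  std::string ga, gb;
  int i = ei, j = ej;
  int state = final_state; // 0=M, 1=Ix, 2=Iy
  while (i > 0 || j > 0) {
    uint8_t t = tr[(size_t)i * w + j];
    if (state == 0) {
      uint8_t pred = t & 3;
      ga.push_back(sa[i - 1]); gb.push_back(sb[j - 1]);
      if (used_pairs) used_pairs->push_back(std::make_pair(i - 1, j - 1));
      --i; --j;
      if (!global && pred == 0) break;   // local alignment starts here
      state = (pred == 2) ? 1 : (pred == 3) ? 2 : 0;
    } else if (state == 1) { // Ix: gap in b, consumes a
      ga.push_back(sa[i - 1]); gb.push_back('-');
      state = (t & 4) ? 1 : 0;
      --i;
    } else {                 // Iy: gap in a, consumes b
      ga.push_back('-'); gb.push_back(sb[j - 1]);
      state = (t & 8) ? 2 : 0;
      --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["score"] = score,
                      _["a_start"] = i, _["a_end"] = ei,
                      _["b_start"] = j, _["b_end"] = ej,
                      _["a_gapped"] = ga, _["b_gapped"] = gb);
}

static void check_size(size_t m, size_t n) {
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  if ((double)m * (double)n > 2.6e8)
    stop("alignment problem too large (%d x %d); cap is 2.6e8 cells", (int)m, (int)n);
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b, int match, int mismatch,
                     int gap_open, int gap_extend, int k_max, int min_score) {
  check_size(a.size(), b.size());
  std::vector<int> ea = encode(a), eb = encode(b);
  const size_t n = b.size();
  std::vector<uint8_t> mask; // grows lazily on first declump
  std::vector<uint8_t> tr;
  List out;
  for (int k = 0; k < k_max; ++k) {
    DPResult r = fill_dp(ea, eb, match, mismatch, gap_open, gap_extend,
                         false, mask, tr);
    if (r.best_score <= 0 || r.best_score < min_score) break;
    std::vector<std::pair<int,int> > used;
    List aln = traceback(a, b, tr, n, r.best_i, r.best_j, 0, false,
                         r.best_score, &used);
    out.push_back(aln);
    if (k + 1 < k_max) {
      if (mask.empty()) mask.assign(a.size() * n, 0);
      for (size_t u = 0; u < used.size(); ++u)
        mask[(size_t)used[u].first * n + used[u].second] = 1;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, int match, int mismatch,
                      int gap_open, int gap_extend) {
  check_size(a.size(), b.size());
  std::vector<int> ea = encode(a), eb = encode(b);
  std::vector<uint8_t> mask;
  std::vector<uint8_t> tr;
  DPResult r = fill_dp(ea, eb, match, mismatch, gap_open, gap_extend,
                       true, mask, tr);
  return traceback(a, b, tr, b.size(), (int)a.size(), (int)b.size(),
                   r.best_i, true, r.best_score, NULL);
}

// Best local score only, O(n) memory: used for null calibration and for
// genome-tiling prescans.
// [[Rcpp::export]]
int cpp_local_best_score(std::string a, std::string b, int match, int mismatch,
                         int gap_open, int gap_extend) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  std::vector<int> ea = encode(a), eb = encode(b);
  const size_t m = ea.size(), n = eb.size();
  std::vector<int> pM(n + 1, NEG), pX(n + 1, NEG), pY(n + 1, NEG);
  std::vector<int> cM(n + 1, NEG), cX(n + 1, NEG), cY(n + 1, NEG);
  pM[0] = 0;
  int best = 0;
  for (size_t i = 1; i <= m; ++i) {
    cM[0] = 0; cX[0] = NEG; cY[0] = NEG;
    for (size_t j = 1; j <= n; ++j) {
      int fromM = (pM[j] == NEG) ? NEG : pM[j] - gap_open;
      int fromX = (pX[j] == NEG) ? NEG : pX[j] - gap_extend;
      cX[j] = fromM > fromX ? fromM : fromX;
      int oM = (cM[j - 1] == NEG) ? NEG : cM[j - 1] - gap_open;
      int oY = (cY[j - 1] == NEG) ? NEG : cY[j - 1] - gap_extend;
      cY[j] = oM > oY ? oM : oY;
      int d = pM[j - 1];
      if (pX[j - 1] > d) d = pX[j - 1];
      if (pY[j - 1] > d) d = pY[j - 1];
      if (0 > d) d = 0;
      cM[j] = d + subst(ea[i - 1], eb[j - 1], match, mismatch);
      if (cM[j] > best) best = cM[j];
    }
    pM.swap(cM); pX.swap(cX); pY.swap(cY);
  }
  return best;
}

// Simulate best local scores of random i.i.d. sequence pairs under base
// frequencies p (length 4). Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
NumericVector cpp_null_best_scores(int n_sims, int len, int match, int mismatch,
                                   int gap_open, int gap_extend,
                                   NumericVector p) {
  if (len < 2) stop("len must be >= 2");
  NumericVector out(n_sims);
  double c1 = p[0], c2 = c1 + p[1], c3 = c2 + p[2];
  const char* bases = "ACGT";
  std::string a(len, 'A'), b(len, 'A');
  for (int s = 0; s < n_sims; ++s) {
    for (int i = 0; i < len; ++i) {
      double u = unif_rand();
      a[i] = bases[u < c1 ? 0 : (u < c2 ? 1 : (u < c3 ? 2 : 3))];
      u = unif_rand();
      b[i] = bases[u < c1 ? 0 : (u < c2 ? 1 : (u < c3 ? 2 : 3))];
    }
    out[s] = cpp_local_best_score(a, b, match, mismatch, gap_open, gap_extend);
  }
  return out;
}
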