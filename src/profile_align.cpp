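#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman with affine gaps of an encoded query (1-based indices into
// the 20-letter alphabet; NA = ambiguous residue, scores 0) against a profile
// given as an L x 20 integer score matrix. A gap of length k costs
// gap_open + k * gap_extend, matching the pairwise aligner. Returns the best
// local score (>= 0).
// [[Rcpp::export(name = ".profile_sw")]]
int profile_sw(IntegerVector query, IntegerMatrix profile,
               int gap_open, int gap_extend) {
  const int m = query.size();
  const int L = profile.nrow();
  const int NEG = -1000000000;
  const int first = gap_open + gap_extend;  // cost of opening a length-1 gap
  std::vector<int> M(L + 1, 0), Ix(L + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int diagM = 0;      // M[i-1][j-1]
    int prevM = 0;      // M[i][0]
    int Iy = NEG;       // gap in profile dimension, current row
    const bool isna = IntegerVector::is_na(query[i - 1]);
    const int aa = isna ? 0 : query[i - 1] - 1;
    for (int j = 1; j <= L; ++j) {
      // Ix: gap consuming query rows (vertical)
      int ix = std::max(M[j] - first, Ix[j] - gap_extend);
      // Iy: gap consuming profile columns (horizontal)
      Iy = std::max(prevM - first, Iy - gap_extend);
      int sub = isna ? 0 : profile(j - 1, aa);
      int mm = diagM + sub;
      if (ix > mm) mm = ix;
      if (Iy > mm) mm = Iy;
      if (mm < 0) mm = 0;
      diagM = M[j];
      M[j] = mm;
      Ix[j] = ix;
      prevM = mm;
      if (mm > best) best = mm;
    }
  }
  return best;
}
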