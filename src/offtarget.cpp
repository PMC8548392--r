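#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
using namespace Rcpp;

// Off-target candidate scoring: layered DP over bulge count. Layer g holds
// the minimum number of mismatches achievable with exactly g alignment gaps
// (bulges) when the spacer is aligned against a genomic window anchored at
// the PAM-proximal end (distal end free). Genomic N never matches.

static const int INF = 1 << 28;

static inline int base_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    default:  return 16; // N / anything else
  }
}

static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    case 'U': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8; case 'S': return 2 | 4;
    case 'W': return 1 | 8; case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 1 | 2 | 4 | 8 | 16; // sequence N matches pattern N only
    default:  return 0;
  }
}

static bool layered_dp(const char* win, int wlen, const char* spacer, int L,
                       int max_mm, int max_b,
                       int& out_g, int& out_mm, int& out_glen) {
  // D[g][i][j]: g gaps used, i spacer bases consumed, j window bases consumed
  const int J = wlen + 1;
  std::vector<int> D((size_t)(max_b + 1) * (L + 1) * J, INF);
  auto at = [&](int g, int i, int j) -> int& {
    return D[((size_t) g * (L + 1) + i) * J + j];
  };
  at(0, 0, 0) = 0;
  for (int g = 0; g <= max_b; ++g)
    for (int i = 0; i <= L; ++i)
      for (int j = 0; j <= wlen; ++j) {
        int cur = at(g, i, j);
        if (cur >= INF) continue;
        if (i < L && j < wlen) {
          bool match = (spacer[i] == win[j]) &&
                       (spacer[i] == 'A' || spacer[i] == 'C' ||
                        spacer[i] == 'G' || spacer[i] == 'T');
          int& d = at(g, i + 1, j + 1);
          int v = cur + (match ? 0 : 1);
          if (v < d) d = v;
        }
        if (g < max_b) {
          if (i < L) { int& d = at(g + 1, i + 1, j); if (cur < d) d = cur; }
          if (j < wlen) { int& d = at(g + 1, i, j + 1); if (cur < d) d = cur; }
        }
      }
  for (int g = 0; g <= max_b; ++g) {
    int best = INF, bestj = -1;
    for (int j = 0; j <= wlen; ++j) {
      int v = at(g, L, j);
      if (v < best) { best = v; bestj = j; }
    }
    if (best <= max_mm) { out_g = g; out_mm = best; out_glen = bestj; return true; }
  }
  return false;
}

// [[Rcpp::export]]
IntegerVector offtarget_dp_cpp(std::string window, std::string spacer,
                               int max_mm, int max_bulges) {
  int g, mm, glen;
  if (layered_dp(window.c_str(), (int) window.size(), spacer.c_str(),
                 (int) spacer.size(), max_mm, max_bulges, g, mm, glen))
    return IntegerVector::create(g, mm, glen);
  return IntegerVector::create(-1, -1, -1);
}

// Scan one strand of a genome: at every PAM occurrence, score the adjacent
// window. Returns a matrix with columns pam_start, n_bulges, n_mismatches,
// footprint length (genome bases paired with the spacer), all 0-based.
// [[Rcpp::export]]
IntegerMatrix scan_offtargets_cpp(std::string genome, std::string spacer,
                                  std::string pam, int max_mm, int max_bulges) {
  const int n = (int) genome.size();
  const int plen = (int) pam.size();
  const int L = (int) spacer.size();
  std::vector<int> pmask(plen);
  for (int k = 0; k < plen; ++k) pmask[k] = iupac_mask(pam[k]);
  std::vector<std::array<int, 4>> hits;
  for (int p = 0; p + plen < n; ++p) {
    bool ok = true;
    for (int k = 0; k < plen; ++k)
      if (!(base_mask(genome[p + k]) & pmask[k])) { ok = false; break; }
    if (!ok) continue;
    int ws = p + plen;
    int wlen = std::min(L + max_bulges, n - ws);
    if (wlen < L - max_bulges) continue;
    int g, mm, glen;
    if (layered_dp(genome.c_str() + ws, wlen, spacer.c_str(), L,
                   max_mm, max_bulges, g, mm, glen))
      hits.push_back({p, g, mm, glen});
  }
  IntegerMatrix out((int) hits.size(), 4);
  for (int r = 0; r < (int) hits.size(); ++r)
    for (int c = 0; c < 4; ++c) out(r, c) = hits[r][c];
  colnames(out) = CharacterVector::create("pam_start", "n_bulges",
                                          "n_mismatches", "footprint");
  return out;
}
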