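#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Semi-global affine-gap alignment: the read is aligned globally, the
// amplicon (reference) has free end gaps. Gap of length k costs
// gap_open + k * gap_ext. Traceback prefers diagonal, then deletion
// (gap in the read, reference base consumed), then insertion.
//
// States: H = best of all, M = diagonal end, X = deletion end (ref
// consumed), Y = insertion end (read consumed).

static const int NEG = std::numeric_limits<int>::min() / 4;

// [[Rcpp::export]]
List align_read_cpp(std::string read, std::string ref,
                    int match = 2, int mismatch = -3,
                    int gap_open = 6, int gap_ext = 1) {
  const int m = (int) read.size();
  const int n = (int) ref.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const char* rd = read.c_str();
  const char* rf = ref.c_str();
  const int gfirst = gap_open + gap_ext;

  std::vector<int> H(m + 1), Hp(m + 1), X(m + 1), Xp(m + 1);
  // traceback, 3 bytes/cell: H choice (0 diag, 1 del, 2 ins, 3 row start),
  // X extends (0/1), Y extends (0/1)
  std::vector<signed char> tb((size_t)(n + 1) * (m + 1) * 3);

  // row i = ref prefix length i; col j = read prefix length j
  Hp[0] = 0; Xp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Hp[j] = -gfirst - (j - 1) * gap_ext;   // leading insertion run
    Xp[j] = NEG;
    tb[(size_t) j * 3] = 2;
    tb[(size_t) j * 3 + 2] = (j > 1);
  }

  int best = Hp[m], best_i = 0;
  for (int i = 1; i <= n; ++i) {
    H[0] = 0;                              // free leading reference
    X[0] = NEG;
    int ycur = NEG;
    const char rc = rf[i - 1];
    signed char* trow = &tb[(size_t) i * (m + 1) * 3];
    trow[0] = 3;
    for (int j = 1; j <= m; ++j) {
      int sub = (rc == rd[j - 1] && rc != 'N') ? match : mismatch;
      int dM = Hp[j - 1] + sub;
      // deletion: consume ref base, gap in read
      int xo = Hp[j] - gfirst, xe = Xp[j] - gap_ext;
      int x = (xe > xo) ? xe : xo;
      // insertion: consume read base, gap in ref
      int yo = H[j - 1] - gfirst, ye = ycur - gap_ext;
      int y = (ye > yo) ? ye : yo;
      // preference on ties: diagonal > deletion > insertion
      int h = dM; signed char t = 0;
      if (x > h) { h = x; t = 1; }
      if (y > h) { h = y; t = 2; }
      H[j] = h; X[j] = x; ycur = y;
      signed char* c = trow + (size_t) j * 3;
      c[0] = t; c[1] = (signed char)(xe > xo); c[2] = (signed char)(ye > yo);
    }
    if (H[m] > best) { best = H[m]; best_i = i; }
    std::swap(H, Hp); std::swap(X, Xp);
  }

  // traceback from (best_i, m); state 0 = H, 1 = X (deletion), 2 = Y (insertion)
  std::string ops; // built reversed
  int i = best_i, j = m, nmatch = 0, state = 0;
  while (true) {
    const signed char* c = &tb[((size_t) i * (m + 1) + j) * 3];
    if (state == 0) {
      if (j == 0) break;
      signed char t = c[0];
      if (t == 3) break;                       // free leading reference
      if (t == 0) {                            // diagonal
        ops.push_back('M');
        if (rf[i - 1] == rd[j - 1] && rf[i - 1] != 'N') ++nmatch;
        --i; --j;
      } else state = t;
    } else if (state == 1) {
      ops.push_back('D'); state = c[1] ? 1 : 0; --i;
    } else {
      ops.push_back('I'); state = c[2] ? 2 : 0; --j;
    }
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(_["score"] = best,
                      _["ref_start"] = i,      // 0-based start on reference
                      _["ref_end"] = best_i,   // 0-based half-open end
                      _["ops"] = ops,          // per-column M/D/I string
                      _["n_match"] = nmatch);
}
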