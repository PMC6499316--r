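#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of a read against its amplicon with
// affine gap costs (a run of k gaps costs gap_open + k * gap_extension) and
// optionally free end gaps (leading/trailing gap runs in either sequence
// cost nothing, so unsequenced flanks are not penalized).
//
// Traceback tie-breaking is deterministic: diagonal (match/mismatch) is
// preferred over a gap in the read (deletion), which is preferred over a
// gap in the amplicon (insertion). Combined with downstream
// left-normalization of indels this fixes event placement completely.
//
// Integer scoring parameters (the default 5/-4/-25/0) run through an integer
// kernel; fractional parameters fall back to a double kernel.

template <typename T>
struct Cell { T m, x, y; };

template <typename T>
static List nw_core(const std::string& read, const std::string& amp,
                    T match, T mismatch, T gap_open, T gap_ext,
                    bool free_end_gaps, T neg_inf) {
  const int m = (int)read.size();
  const int n = (int)amp.size();
  const int W = n + 1;
  std::vector<Cell<T> > dp((size_t)(m + 1) * W);

  dp[0].m = 0; dp[0].x = neg_inf; dp[0].y = neg_inf;
  for (int j = 1; j <= n; ++j) {
    dp[j].m = neg_inf;
    dp[j].x = free_end_gaps ? (T)0 : (T)(gap_open + j * gap_ext);
    dp[j].y = neg_inf;
  }
  for (int i = 1; i <= m; ++i) {
    Cell<T>* cur = &dp[(size_t)i * W];
    const Cell<T>* prev = &dp[(size_t)(i - 1) * W];
    cur[0].m = neg_inf;
    cur[0].x = neg_inf;
    cur[0].y = free_end_gaps ? (T)0 : (T)(gap_open + i * gap_ext);
    const char ri = read[i - 1];
    for (int j = 1; j <= n; ++j) {
      const Cell<T>& d = prev[j - 1];
      const Cell<T>& up = prev[j];
      const Cell<T>& lf = cur[j - 1];
      const T s = (ri == amp[j - 1]) ? match : mismatch;
      T dm = d.m > d.x ? d.m : d.x;
      if (d.y > dm) dm = d.y;
      cur[j].m = (dm <= neg_inf / 2) ? neg_inf : dm + s;
      T xo = lf.m > lf.y ? lf.m : lf.y;
      xo = (xo <= neg_inf / 2) ? neg_inf : xo + gap_open + gap_ext;
      T xe = (lf.x <= neg_inf / 2) ? neg_inf : lf.x + gap_ext;
      cur[j].x = xo > xe ? xo : xe;
      T yo = up.m > up.x ? up.m : up.x;
      yo = (yo <= neg_inf / 2) ? neg_inf : yo + gap_open + gap_ext;
      T ye = (up.y <= neg_inf / 2) ? neg_inf : up.y + gap_ext;
      cur[j].y = yo > ye ? yo : ye;
    }
  }

  auto cellBest = [&](int i, int j) {
    const Cell<T>& c = dp[(size_t)i * W + j];
    T b = c.m > c.x ? c.m : c.x;
    return c.y > b ? c.y : b;
  };

  // With free end gaps the alignment may end anywhere on the last row or
  // column (the remainder is a free trailing run); candidates are scanned in
  // a fixed order preferring fewer end gaps, so ties are deterministic.
  int bi = m, bj = n;
  T best = cellBest(m, n);
  if (free_end_gaps) {
    for (int j = n - 1; j >= 0; --j) {
      T v = cellBest(m, j);
      if (v > best) { best = v; bi = m; bj = j; }
    }
    for (int i = m - 1; i >= 0; --i) {
      T v = cellBest(i, n);
      if (v > best) { best = v; bi = i; bj = n; }
    }
  }

  // state: 0 = M (diagonal), 1 = X (gap in read), 2 = Y (gap in amplicon);
  // preference M > X > Y at every tie.
  const Cell<T>& bc = dp[(size_t)bi * W + bj];
  int state = (bc.m == best) ? 0 : (bc.x == best ? 1 : 2);

  std::string ra, aa;  // built reversed
  ra.reserve(m + n); aa.reserve(m + n);
  for (int j = n; j > bj; --j) { ra += '-'; aa += amp[j - 1]; }
  for (int i = m; i > bi; --i) { ra += read[i - 1]; aa += '-'; }

  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    if (i == 0) { ra += '-'; aa += amp[j - 1]; --j; continue; }
    if (j == 0) { ra += read[i - 1]; aa += '-'; --i; continue; }
    const Cell<T>& c = dp[(size_t)i * W + j];
    const Cell<T>& d = dp[(size_t)(i - 1) * W + (j - 1)];
    const Cell<T>& up = dp[(size_t)(i - 1) * W + j];
    const Cell<T>& lf = dp[(size_t)i * W + (j - 1)];
    if (state == 0) {
      const T s = (read[i - 1] == amp[j - 1]) ? match : mismatch;
      const T target = c.m - s;
      ra += read[i - 1]; aa += amp[j - 1];
      if (d.m == target) state = 0;
      else if (d.x == target) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ra += '-'; aa += amp[j - 1];
      if (lf.m + gap_open + gap_ext == c.x) state = 0;
      else if (lf.x + gap_ext == c.x) state = 1;
      else state = 2;
      --j;
    } else {
      ra += read[i - 1]; aa += '-';
      if (up.m + gap_open + gap_ext == c.y) state = 0;
      else if (up.x + gap_open + gap_ext == c.y) state = 1;
      else state = 2;
      --i;
    }
  }

  std::reverse(ra.begin(), ra.end());
  std::reverse(aa.begin(), aa.end());
  return List::create(_["score"] = (double)best,
                      _["read_aln"] = ra,
                      _["amp_aln"] = aa);
}

static inline bool whole(double x) { return std::floor(x) == x; }

// [[Rcpp::export]]
List nw_align_cpp(std::string read, std::string amp,
                  double match, double mismatch,
                  double gap_open, double gap_ext,
                  bool free_end_gaps) {
  if (read.empty() || amp.empty()) stop("empty sequence");
  if (whole(match) && whole(mismatch) && whole(gap_open) && whole(gap_ext)) {
    return nw_core<long long>(read, amp, (long long)match,
                              (long long)mismatch, (long long)gap_open,
                              (long long)gap_ext, free_end_gaps,
                              (long long)-4e15);
  }
  return nw_core<double>(read, amp, match, mismatch, gap_open, gap_ext,
                         free_end_gaps, -4e15);
}
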