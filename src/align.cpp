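#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Global (end-to-end, terminal gaps penalized) pairwise alignment with affine
// gap costs, Gotoh three-state recursion. A gap of length L costs
// gap_open + L * gap_extend (both <= 0). Substitution score is `match` only
// when both symbols are the same unambiguous A/C/G/T; every other pairing
// (including anything involving N) scores `mismatch`.
//
// Score ties are resolved lexicographically: maximal score, then maximal
// match count, then minimal column count, then state preference M > X > Y
// (diagonal > up > left). The optimal (score, matches, columns) triple is
// therefore unique and symmetric in the two sequences, which makes percent
// identity well-defined and reproducible.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

struct Cell {
  double score;
  int match;
  int col;
};

// strictly better under (score desc, match desc, col asc)
static inline bool better(const Cell& a, const Cell& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.match != b.match) return a.match > b.match;
  return a.col < b.col;
}

struct AlnDP {
  int n, m;
  std::vector<Cell> M, X, Y;          // (n+1) x (m+1), row-major
  std::vector<signed char> pM, pX, pY; // predecessor state: 0=M 1=X 2=Y, -1 none

  inline size_t idx(int i, int j) const { return (size_t)i * (m + 1) + j; }

  AlnDP(const std::string& a, const std::string& b,
        double match, double mismatch, double gap_open, double gap_extend) {
    n = (int)a.size();
    m = (int)b.size();
    size_t sz = (size_t)(n + 1) * (m + 1);
    Cell dead = {NEG_INF, 0, 0};
    M.assign(sz, dead); X.assign(sz, dead); Y.assign(sz, dead);
    pM.assign(sz, -1); pX.assign(sz, -1); pY.assign(sz, -1);
    M[idx(0, 0)] = {0.0, 0, 0};
    for (int i = 1; i <= n; ++i) {
      X[idx(i, 0)] = {gap_open + i * gap_extend, 0, i};
      pX[idx(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Y[idx(0, j)] = {gap_open + j * gap_extend, 0, j};
      pY[idx(0, j)] = (j == 1) ? 0 : 2;
    }
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        char ca = a[i - 1], cb = b[j - 1];
        bool hit = (ca == cb) && is_acgt(ca);
        double s = hit ? match : mismatch;
        // M from the best of M/X/Y at (i-1, j-1)
        {
          const Cell* prev[3] = {&M[idx(i - 1, j - 1)], &X[idx(i - 1, j - 1)],
                                 &Y[idx(i - 1, j - 1)]};
          int bs = 0;
          for (int k = 1; k < 3; ++k) if (better(*prev[k], *prev[bs])) bs = k;
          if (prev[bs]->score != NEG_INF) {
            M[idx(i, j)] = {prev[bs]->score + s, prev[bs]->match + (hit ? 1 : 0),
                            prev[bs]->col + 1};
            pM[idx(i, j)] = (signed char)bs;
          }
        }
        // X: gap in the reference, consumes a[i-1]
        {
          Cell cand[3];
          const Cell& cm = M[idx(i - 1, j)];
          const Cell& cx = X[idx(i - 1, j)];
          const Cell& cy = Y[idx(i - 1, j)];
          cand[0] = {cm.score + gap_open + gap_extend, cm.match, cm.col + 1};
          cand[1] = {cx.score + gap_extend, cx.match, cx.col + 1};
          cand[2] = {cy.score + gap_open + gap_extend, cy.match, cy.col + 1};
          int bs = 0;
          for (int k = 1; k < 3; ++k) if (better(cand[k], cand[bs])) bs = k;
          if (cand[bs].score != NEG_INF) {
            X[idx(i, j)] = cand[bs];
            pX[idx(i, j)] = (signed char)bs;
          }
        }
        // Y: gap in the query, consumes b[j-1]
        {
          Cell cand[3];
          const Cell& cm = M[idx(i, j - 1)];
          const Cell& cx = X[idx(i, j - 1)];
          const Cell& cy = Y[idx(i, j - 1)];
          cand[0] = {cm.score + gap_open + gap_extend, cm.match, cm.col + 1};
          cand[1] = {cx.score + gap_open + gap_extend, cx.match, cx.col + 1};
          cand[2] = {cy.score + gap_extend, cy.match, cy.col + 1};
          int bs = 0;
          for (int k = 1; k < 3; ++k) if (better(cand[k], cand[bs])) bs = k;
          if (cand[bs].score != NEG_INF) {
            Y[idx(i, j)] = cand[bs];
            pY[idx(i, j)] = (signed char)bs;
          }
        }
      }
    }
  }

  int final_state() const {
    const Cell* fin[3] = {&M[idx(n, m)], &X[idx(n, m)], &Y[idx(n, m)]};
    int bs = 0;
    for (int k = 1; k < 3; ++k) if (better(*fin[k], *fin[bs])) bs = k;
    return bs;
  }

  const Cell& final_cell() const {
    int bs = final_state();
    return (bs == 0) ? M[idx(n, m)] : (bs == 1 ? X[idx(n, m)] : Y[idx(n, m)]);
  }

  void traceback_strings(const std::string& a, const std::string& b,
                         std::string& out_a, std::string& out_b) const {
    int i = n, j = m, state = final_state();
    while (i > 0 || j > 0) {
      if (state == 0) {
        out_a.push_back(a[i - 1]);
        out_b.push_back(b[j - 1]);
        state = pM[idx(i, j)];
        --i; --j;
      } else if (state == 1) {
        out_a.push_back(a[i - 1]);
        out_b.push_back('-');
        state = pX[idx(i, j)];
        --i;
      } else {
        out_a.push_back('-');
        out_b.push_back(b[j - 1]);
        state = pY[idx(i, j)];
        --j;
      }
    }
    std::reverse(out_a.begin(), out_a.end());
    std::reverse(out_b.begin(), out_b.end());
  }
};

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string query, std::string ref,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  if (query.empty() || ref.empty())
    stop("sequences must be non-empty");
  AlnDP dp(query, ref, match, mismatch, gap_open, gap_extend);
  std::string aq, ar;
  aq.reserve(query.size() + ref.size());
  ar.reserve(query.size() + ref.size());
  dp.traceback_strings(query, ref, aq, ar);
  const Cell& fin = dp.final_cell();
  return List::create(
    _["aligned_query"] = aq,
    _["aligned_ref"] = ar,
    _["score"] = fin.score,
    _["n_matches"] = fin.match,
    _["n_columns"] = fin.col);
}

// Align one query against many references; one row per reference with the
// optimal score and the (unique) tie-broken match/column counts.
// [[Rcpp::export(name = ".nw_batch_cpp")]]
NumericMatrix nw_batch_cpp(std::string query, CharacterVector refs,
                           double match, double mismatch,
                           double gap_open, double gap_extend) {
  if (query.empty()) stop("query must be non-empty");
  int k = refs.size();
  NumericMatrix out(k, 3);
  colnames(out) = CharacterVector::create("score", "n_matches", "n_columns");
  for (int r = 0; r < k; ++r) {
    std::string ref = as<std::string>(refs[r]);
    if (ref.empty()) stop("reference sequences must be non-empty");
    AlnDP dp(query, ref, match, mismatch, gap_open, gap_extend);
    const Cell& fin = dp.final_cell();
    out(r, 0) = fin.score;
    out(r, 1) = fin.match;
    out(r, 2) = fin.col;
  }
  return out;
}
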