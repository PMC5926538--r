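#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap penalties and free end
// gaps, the scoring convention of EMBOSS needle's defaults for nucleotides:
// match +5, mismatch -4, gap open 10, gap extend 0.5, end gaps unpenalised.
// A gap run of length L costs open + L * extend (the extension is charged for
// every gapped position, including the first, matching Biostrings).
//
// Traceback is deterministic: at every cell ties are resolved preferring the
// diagonal (match/mismatch) state, then the vertical state (gap in target,
// consuming query), then the horizontal state (gap in query).

static const double NEG = -1e30;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string query, std::string target,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int m = (int)query.size(), n = (int)target.size();
  if (m == 0 || n == 0) stop("empty sequence");

  const double open_cost = gap_open + gap_extend;  // first gapped position
  const double ext_cost = gap_extend;

  // state matrices: M diag, X gap-in-target (vertical), Y gap-in-query (horizontal)
  std::vector<double> M((m + 1) * (n + 1), NEG), X((m + 1) * (n + 1), NEG),
      Y((m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) X[at(i, 0)] = 0.0;  // free leading query-consuming gap
  for (int j = 1; j <= n; ++j) Y[at(0, j)] = 0.0;  // free leading target-consuming gap

  for (int i = 1; i <= m; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= n; ++j) {
      const char tc = target[j - 1];
      // N is scored as a mismatch against everything, including N
      const double s = (qc == tc && qc != 'N') ? match : mismatch;
      double dm = M[at(i - 1, j - 1)], dx = X[at(i - 1, j - 1)], dy = Y[at(i - 1, j - 1)];
      double best = dm >= dx ? (dm >= dy ? dm : dy) : (dx >= dy ? dx : dy);
      M[at(i, j)] = best + s;

      double xo = M[at(i - 1, j)] - open_cost;
      double xe = X[at(i - 1, j)] - (j == 0 ? 0.0 : ext_cost);
      double xy = Y[at(i - 1, j)] - open_cost;
      X[at(i, j)] = std::max(xo, std::max(xe, xy));

      double yo = M[at(i, j - 1)] - open_cost;
      double yx = X[at(i, j - 1)] - open_cost;
      double ye = Y[at(i, j - 1)] - ext_cost;
      Y[at(i, j)] = std::max(yo, std::max(yx, ye));
    }
  }

  // terminal cell: free trailing gaps, so take the best cell on the last row
  // or last column. Scan order (deterministic): (m,n) first, then last column
  // top-to-bottom, then last row left-to-right; strict improvement required.
  auto cell_best = [&](int i, int j, int &state) {
    double bm = M[at(i, j)], bx = X[at(i, j)], by = Y[at(i, j)];
    if (bm >= bx && bm >= by) { state = 0; return bm; }
    if (bx >= by) { state = 1; return bx; }
    state = 2; return by;
  };
  int bi = m, bj = n, bstate;
  double bscore = cell_best(m, n, bstate);
  for (int i = 0; i <= m; ++i) {
    int st; double sc = cell_best(i, n, st);
    if (sc > bscore) { bscore = sc; bi = i; bj = n; bstate = st; }
  }
  for (int j = 0; j <= n; ++j) {
    int st; double sc = cell_best(m, j, st);
    if (sc > bscore) { bscore = sc; bi = m; bj = j; bstate = st; }
  }

  // traceback
  std::string aq, atg;
  // trailing free gaps
  for (int j = n; j > bj; --j) { aq.push_back('-'); atg.push_back(target[j - 1]); }
  for (int i = m; i > bi; --i) { aq.push_back(query[i - 1]); atg.push_back('-'); }

  int i = bi, j = bj, state = bstate;
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {  // M
      if (i == 0 && j == 0) break;
      if (i == 0 || j == 0) break;  // M only reachable from (0,0) on edges
      const char qc = query[i - 1], tc = target[j - 1];
      const double s = (qc == tc && qc != 'N') ? match : mismatch;
      aq.push_back(qc); atg.push_back(tc);
      double need = M[at(i, j)] - s;
      --i; --j;
      if (i == 0 && j == 0) { state = 0; continue; }
      if (std::abs(M[at(i, j)] - need) < tol) state = 0;
      else if (std::abs(X[at(i, j)] - need) < tol) state = 1;
      else state = 2;
    } else if (state == 1) {  // X: gap in target, consume query
      aq.push_back(query[i - 1]); atg.push_back('-');
      double cur = X[at(i, j)];
      --i;
      if (j == 0) { state = 1; if (i == 0) break; continue; }  // free leading run
      if (std::abs(M[at(i, j)] - (cur + open_cost)) < tol) state = 0;
      else if (std::abs(X[at(i, j)] - (cur + ext_cost)) < tol) state = 1;
      else state = 2;
    } else {  // Y: gap in query, consume target
      aq.push_back('-'); atg.push_back(target[j - 1]);
      double cur = Y[at(i, j)];
      --j;
      if (i == 0) { state = 2; if (j == 0) break; continue; }  // free leading run
      if (std::abs(M[at(i, j)] - (cur + open_cost)) < tol) state = 0;
      else if (std::abs(X[at(i, j)] - (cur + open_cost)) < tol) state = 1;
      else state = 2;
    }
    if (i == 0 && j == 0) break;
    if (i == 0 && state == 0) state = 2;  // only horizontal moves remain
    if (j == 0 && state == 0) state = 1;
  }
  // leading free gaps
  while (i > 0) { aq.push_back(query[i - 1]); atg.push_back('-'); --i; }
  while (j > 0) { aq.push_back('-'); atg.push_back(target[j - 1]); --j; }

  std::reverse(aq.begin(), aq.end());
  std::reverse(atg.begin(), atg.end());

  return List::create(_["score"] = bscore,
                      _["aligned_query"] = aq,
                      _["aligned_target"] = atg);
}

// Longest run of alignment columns that are exact base matches with no gap in
// either row; 'N' never matches anything, including 'N'.
// [[Rcpp::export(name = ".identity_run_cpp")]]
int identity_run_cpp(std::string aq, std::string atg) {
  if (aq.size() != atg.size()) stop("aligned strings differ in length");
  int best = 0, cur = 0;
  for (size_t k = 0; k < aq.size(); ++k) {
    char a = aq[k], b = atg[k];
    if (a == b && a != '-' && a != 'N') {
      if (++cur > best) best = cur;
    } else {
      cur = 0;
    }
  }
  return best;
}
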