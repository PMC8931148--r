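#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Gotoh global alignment with affine gaps. A gap of length k costs
// gap_open + k * gap_extend. States: M (diagonal), D (gap in read,
// consuming reference), I (gap in reference, consuming read).
// Deterministic traceback: at equal score prefer M > D > I.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List gotoh_align(std::string ref, std::string read, double match,
                 double mismatch, double gap_open, double gap_extend) {
  const int n = ref.size();   // reference length (rows)
  const int m = read.size();  // read length (cols)

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> D((n + 1) * (m + 1), NEG_INF);
  std::vector<double> I((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) D[at(i, 0)] = gap_open + i * gap_extend;
  for (int j = 1; j <= m; ++j) I[at(0, j)] = gap_open + j * gap_extend;

  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i > 0 && j > 0) {
        double s = (ref[i - 1] == read[j - 1]) ? match : mismatch;
        double best = M[at(i - 1, j - 1)];
        if (D[at(i - 1, j - 1)] > best) best = D[at(i - 1, j - 1)];
        if (I[at(i - 1, j - 1)] > best) best = I[at(i - 1, j - 1)];
        M[at(i, j)] = best + s;
      }
      if (i > 0) {
        double open_from = M[at(i - 1, j)];
        if (I[at(i - 1, j)] > open_from) open_from = I[at(i - 1, j)];
        double d = open_from + gap_open + gap_extend;
        double ext = D[at(i - 1, j)] + gap_extend;
        D[at(i, j)] = (d >= ext) ? d : ext;
      }
      if (j > 0) {
        double open_from = M[at(i, j - 1)];
        if (D[at(i, j - 1)] > open_from) open_from = D[at(i, j - 1)];
        double ins = open_from + gap_open + gap_extend;
        double ext = I[at(i, j - 1)] + gap_extend;
        I[at(i, j)] = (ins >= ext) ? ins : ext;
      }
    }
  }

  // final state: prefer M > D > I at equal score
  double score = M[at(n, m)];
  int state = 0; // 0 = M, 1 = D, 2 = I
  if (D[at(n, m)] > score) { score = D[at(n, m)]; state = 1; }
  if (I[at(n, m)] > score) { score = I[at(n, m)]; state = 2; }

  // traceback, collecting per-column ops (0 match, 1 mismatch, 2 ins, 3 del)
  std::vector<int> ops_rev;
  std::vector<int> ref_pos_rev; // 0-based reference offset of each op column
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double s = (ref[i - 1] == read[j - 1]) ? match : mismatch;
      ops_rev.push_back(ref[i - 1] == read[j - 1] ? 0 : 1);
      ref_pos_rev.push_back(i - 1);
      double target = M[at(i, j)] - s;
      int prev;
      if (std::abs(M[at(i - 1, j - 1)] - target) < eps) prev = 0;
      else if (std::abs(D[at(i - 1, j - 1)] - target) < eps) prev = 1;
      else prev = 2;
      --i; --j;
      state = prev;
    } else if (state == 1) { // deletion: consumes ref
      ops_rev.push_back(3);
      ref_pos_rev.push_back(i - 1);
      double ext = D[at(i - 1, j)] + gap_extend;
      int prev;
      if (i - 1 == 0 && j == 0) {
        prev = 1; // leading gap runs to the origin through D inits
        if (std::abs(M[at(0, 0)] + gap_open + gap_extend - D[at(i, j)]) < eps)
          prev = 0;
      } else if (std::abs(M[at(i - 1, j)] + gap_open + gap_extend - D[at(i, j)]) < eps) {
        prev = 0;
      } else if (std::abs(ext - D[at(i, j)]) < eps) {
        prev = 1;
      } else {
        prev = 2;
      }
      --i;
      state = prev;
    } else { // insertion: consumes read
      ops_rev.push_back(2);
      ref_pos_rev.push_back(i);
      double ext = I[at(i, j - 1)] + gap_extend;
      int prev;
      if (i == 0 && j - 1 == 0) {
        prev = 2;
        if (std::abs(M[at(0, 0)] + gap_open + gap_extend - I[at(i, j)]) < eps)
          prev = 0;
      } else if (std::abs(M[at(i, j - 1)] + gap_open + gap_extend - I[at(i, j)]) < eps) {
        prev = 0;
      } else if (std::abs(ext - I[at(i, j)]) < eps) {
        prev = 2;
      } else {
        prev = 1;
      }
      --j;
      state = prev;
    }
  }

  // merge runs (forward order); an op run keeps the ref offset of its start
  std::vector<std::string> op_out;
  std::vector<int> len_out, off_out;
  const char *names[4] = {"match", "mismatch", "insertion", "deletion"};
  for (int k = (int)ops_rev.size() - 1; k >= 0;) {
    int op = ops_rev[k];
    int start_off = ref_pos_rev[k];
    int len = 0;
    while (k >= 0 && ops_rev[k] == op) { ++len; --k; }
    op_out.push_back(names[op]);
    len_out.push_back(len);
    off_out.push_back(start_off);
  }

  return List::create(
    _["score"] = score,
    _["op"] = op_out,
    _["length"] = len_out,
    _["ref_offset"] = off_out
  );
}
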