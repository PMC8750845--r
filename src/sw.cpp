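#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Affine-gap Smith-Waterman with optional banding and deterministic
// traceback. Scoring convention: a gap of length L costs
// gap_open + L * gap_extend (opening the first gap base pays both).
// 'N' mismatches every base, including 'N'.
//
// Tie-breaking (must stay in sync with the pure-R oracle used in tests):
//   - cell origin preference: diagonal > up (gap in target) > left (gap in
//     query); score <= 0 stops the trace;
//   - gap matrices prefer opening from H over extending on exact ties;
//   - the traceback starts at the first maximal cell in row-major order
//     (smallest query position, then smallest target position).

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N and anything else: mismatches everything
  }
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string target,
                  int match, int mismatch, int gap_open, int gap_extend,
                  int band_width = 0, int band_offset = 0) {
  const int m = (int)query.size();
  const int n = (int)target.size();
  if (m == 0 || n == 0) stop("empty sequence");
  if ((double)(m + 1) * (double)(n + 1) > 4e8)
    stop("sequences too long for dense alignment");

  std::vector<int> q(m), t(n);
  for (int i = 0; i < m; ++i) q[i] = base_code(query[i]);
  for (int j = 0; j < n; ++j) t[j] = base_code(target[j]);

  const int NEG = -(1 << 28);
  const int go = gap_open, ge = gap_extend;

  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fcol(n + 1, NEG);
  // tb bits: 0-1 H origin (0 stop, 1 diag, 2 up, 3 left); 2: E extended; 3: F extended
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);

  int best = 0, best_i = 0, best_j = 0;
  const bool banded = band_width > 0;

  for (int i = 1; i <= m; ++i) {
    int jlo = 1, jhi = n;
    if (banded) {
      jlo = std::max(1, i + band_offset - band_width);
      jhi = std::min(n, i + band_offset + band_width);
      if (jlo > n || jhi < 1) { std::fill(Hcur.begin(), Hcur.end(), 0); std::swap(Hprev, Hcur); continue; }
    }
    std::fill(Hcur.begin(), Hcur.end(), 0);
    int e = NEG;
    const int qi = q[i - 1];
    unsigned char *tbrow = &tb[(size_t)i * (n + 1)];
    for (int j = jlo; j <= jhi; ++j) {
      // E: gap in query (left). Uses H/E at (i, j-1).
      int e_open = Hcur[j - 1] - go - ge;
      int e_ext = e - ge;
      unsigned char flags = 0;
      if (e_open >= e_ext) { e = e_open; } else { e = e_ext; flags |= 4; }
      // F: gap in target (up). Uses H/F at (i-1, j).
      int f_open = Hprev[j] - go - ge;
      int f_ext = Fcol[j] - ge;
      int f;
      if (f_open >= f_ext) { f = f_open; } else { f = f_ext; flags |= 8; }
      Fcol[j] = f;
      int s = (qi == t[j - 1] && qi < 4) ? match : mismatch;
      int diag = Hprev[j - 1] + s;
      int h = diag; unsigned char org = 1;
      if (f > h) { h = f; org = 2; }
      if (e > h) { h = e; org = 3; }
      if (h <= 0) { h = 0; org = 0; }
      Hcur[j] = h;
      tbrow[j] = (unsigned char)(org | flags);
      if (h > best) { best = h; best_i = i; best_j = j; }
    }
    std::swap(Hprev, Hcur);
    // reset F outside band for next row
    if (banded) {
      if (jlo - 1 >= 0) Fcol[jlo - 1] = NEG;
    }
  }

  if (best == 0) {
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0,
                        _["qpos"] = IntegerVector(0), _["tpos"] = IntegerVector(0));
  }

  // Traceback from (best_i, best_j), state H.
  std::vector<int> qpos, tpos;
  qpos.reserve(m + n); tpos.reserve(m + n);
  int i = best_i, j = best_j;
  int state = 0; // 0 = H, 1 = E (left/gap-in-query), 2 = F (up/gap-in-target)
  while (i > 0 && j > 0) {
    unsigned char cell = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      int org = cell & 3;
      if (org == 0) break;
      if (org == 1) { qpos.push_back(i); tpos.push_back(j); --i; --j; }
      else if (org == 2) state = 2;
      else state = 1;
    } else if (state == 1) { // E: consume target j, gap in query
      qpos.push_back(0); tpos.push_back(j);
      bool ext = (cell & 4) != 0;
      --j;
      if (!ext) state = 0;
    } else { // F: consume query i, gap in target
      qpos.push_back(i); tpos.push_back(0);
      bool ext = (cell & 8) != 0;
      --i;
      if (!ext) state = 0;
    }
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(tpos.begin(), tpos.end());

  int q_start = 0, t_start = 0;
  for (size_t k = 0; k < qpos.size(); ++k) if (qpos[k] > 0) { q_start = qpos[k]; break; }
  for (size_t k = 0; k < tpos.size(); ++k) if (tpos[k] > 0) { t_start = tpos[k]; break; }

  return List::create(_["score"] = best,
                      _["q_start"] = q_start, _["q_end"] = best_i,
                      _["t_start"] = t_start, _["t_end"] = best_j,
                      _["qpos"] = wrap(qpos), _["tpos"] = wrap(tpos));
}
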