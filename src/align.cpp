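#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// IUPAC nucleotide bitmasks (A=1, C=2, G=4, T=8). 0 = unrecognized.
static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 5;  case 'Y': return 10; case 'S': return 6;
    case 'W': return 9;  case 'K': return 12; case 'M': return 3;
    case 'B': return 14; case 'D': return 13; case 'H': return 11;
    case 'V': return 7;  case 'N': return 15;
    default:  return 0;
  }
}

// Match rule. Strict mode: exact base equality, N never matches (not even N/N).
// IUPAC mode: compatible codes (intersecting masks) count as a match; used for
// degenerate primer positions during demultiplexing only.
static inline bool base_match(char a, char b, bool iupac) {
  if (iupac) return (iupac_mask(a) & iupac_mask(b)) != 0;
  if (a == 'N' || b == 'N') return false;
  return a == b;
}

static const int NEG_INF = INT32_MIN / 4;

// Traceback byte layout: bits 0-1 = H source (0 stop, 1 diag, 2 E, 3 F);
// bit 2 = E extended from E (else opened from H); bit 3 = F extended from F.

struct AlnResult {
  int score, qstart, qend, tstart, tend;
  int n_match, n_mismatch, n_gap, n_gap_cols;
};

static List aln_to_list(const AlnResult &r) {
  return List::create(
    _["score"] = r.score,
    _["qstart"] = r.qstart, _["qend"] = r.qend,
    _["tstart"] = r.tstart, _["tend"] = r.tend,
    _["n_match"] = r.n_match, _["n_mismatch"] = r.n_mismatch,
    _["n_gap"] = r.n_gap, _["n_gap_cols"] = r.n_gap_cols);
}

// Full Smith-Waterman/Gotoh local alignment. A gap of length k costs
// gap_open + k * gap_extend (LAST -a/-b convention).
// [[Rcpp::export]]
List cpp_local_align(std::string q, std::string t,
                     int match, int mismatch, int gap_open, int gap_extend,
                     bool iupac = false) {
  const int m = (int) q.size(), n = (int) t.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  const int go = gap_open + gap_extend, ge = gap_extend;

  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fcol(n + 1, NEG_INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int Erow = NEG_INF;
    Hcur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      uint8_t cell = 0;
      int e_open = Hcur[j - 1] - go, e_ext = Erow - ge;
      int E = e_open;
      if (e_ext > e_open) { E = e_ext; cell |= 4; }
      Erow = E;
      int f_open = Hprev[j] - go, f_ext = Fcol[j] - ge;
      int F = f_open;
      if (f_ext > f_open) { F = f_ext; cell |= 8; }
      Fcol[j] = F;
      int s = base_match(q[i - 1], t[j - 1], iupac) ? match : -mismatch;
      int diag = Hprev[j - 1] + s;
      int H = 0; int dir = 0;
      if (diag > H) { H = diag; dir = 1; }
      if (E > H) { H = E; dir = 2; }
      if (F > H) { H = F; dir = 3; }
      // prefer diagonal on ties with E/F for a canonical traceback
      if (dir != 1 && diag == H && H > 0) dir = 1;
      Hcur[j] = H;
      tb[(size_t) i * (n + 1) + j] = cell | (uint8_t) dir;
      if (H > best) { best = H; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }

  AlnResult r{best, 0, 0, 0, 0, 0, 0, 0, 0};
  if (best > 0) {
    int i = bi, j = bj, state = 0; // 0 = H
    while (true) {
      uint8_t cell = tb[(size_t) i * (n + 1) + j];
      if (state == 0) {
        int dir = cell & 3;
        if (dir == 0) break;
        if (dir == 1) {
          if (base_match(q[i - 1], t[j - 1], iupac)) r.n_match++; else r.n_mismatch++;
          --i; --j;
        } else if (dir == 2) state = 2;
        else state = 3;
      } else if (state == 2) { // E: gap in query, consumes target
        r.n_gap_cols++;
        bool ext = (cell & 4) != 0;
        --j;
        if (!ext) { state = 0; r.n_gap++; }
      } else { // F: gap in target, consumes query
        r.n_gap_cols++;
        bool ext = (cell & 8) != 0;
        --i;
        if (!ext) { state = 0; r.n_gap++; }
      }
    }
    r.qstart = i; r.qend = bi; r.tstart = j; r.tend = bj;
  }
  return aln_to_list(r);
}

static AlnResult banded_core(const std::string &q, const std::string &t,
                             int dlo, int dhi, int match, int mismatch,
                             int gap_open, int gap_extend, bool iupac) {
  const int m = (int) q.size(), n = (int) t.size();
  dlo = std::max(dlo, -m); dhi = std::min(dhi, n);
  const int go = gap_open + gap_extend, ge = gap_extend;
  const int W = dhi - dlo + 1;

  // band storage: row i holds diagonals dlo..dhi => j = i + dlo + w
  std::vector<int> Hprev(W, NEG_INF), Hcur(W, NEG_INF);
  std::vector<int> Fprev(W, NEG_INF), Fcur(W, NEG_INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);

  // row 0: H = 0 wherever j in [0, n]
  for (int w = 0; w < W; ++w) {
    int j = 0 + dlo + w;
    Hprev[w] = (j >= 0 && j <= n) ? 0 : NEG_INF;
  }
  int best = 0, bi = 0, bw = 0;
  for (int i = 1; i <= m; ++i) {
    int Erow = NEG_INF;
    for (int w = 0; w < W; ++w) {
      int j = i + dlo + w;
      if (j < 0 || j > n) { Hcur[w] = NEG_INF; Fcur[w] = NEG_INF; continue; }
      if (j == 0) { Hcur[w] = 0; Fcur[w] = NEG_INF; Erow = NEG_INF; continue; }
      uint8_t cell = 0;
      // horizontal neighbor (i, j-1) is band index w-1 in the same row
      int Hleft = (w >= 1) ? Hcur[w - 1] : NEG_INF;
      int e_open = (Hleft <= NEG_INF / 2) ? NEG_INF : Hleft - go;
      int e_ext = (Erow <= NEG_INF / 2) ? NEG_INF : Erow - ge;
      int E = e_open;
      if (e_ext > e_open) { E = e_ext; cell |= 4; }
      Erow = E;
      // vertical neighbor (i-1, j) is band index w+1 in previous row
      int Hup = (w + 1 < W) ? Hprev[w + 1] : NEG_INF;
      int Fup = (w + 1 < W) ? Fprev[w + 1] : NEG_INF;
      int f_open = (Hup <= NEG_INF / 2) ? NEG_INF : Hup - go;
      int f_ext = (Fup <= NEG_INF / 2) ? NEG_INF : Fup - ge;
      int F = f_open;
      if (f_ext > f_open) { F = f_ext; cell |= 8; }
      Fcur[w] = F;
      // diagonal neighbor (i-1, j-1) is the same band index in previous row
      int Hdiag = Hprev[w];
      int s = base_match(q[i - 1], t[j - 1], iupac) ? match : -mismatch;
      int diag = (Hdiag <= NEG_INF / 2) ? NEG_INF : Hdiag + s;
      int H = 0, dir = 0;
      if (diag > H) { H = diag; dir = 1; }
      if (E > H) { H = E; dir = 2; }
      if (F > H) { H = F; dir = 3; }
      if (dir != 1 && diag == H && H > 0) dir = 1;
      Hcur[w] = H;
      tb[(size_t) i * W + w] = cell | (uint8_t) dir;
      if (H > best) { best = H; bi = i; bw = w; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  AlnResult r{best, 0, 0, 0, 0, 0, 0, 0, 0};
  if (best > 0) {
    int i = bi, w = bw, state = 0;
    while (true) {
      uint8_t cell = tb[(size_t) i * W + w];
      if (state == 0) {
        int dir = cell & 3;
        if (dir == 0) break;
        if (dir == 1) {
          int j = i + dlo + w;
          if (base_match(q[i - 1], t[j - 1], iupac)) r.n_match++; else r.n_mismatch++;
          --i; // diagonal keeps the same band index
        } else if (dir == 2) state = 2;
        else state = 3;
      } else if (state == 2) {
        r.n_gap_cols++;
        bool ext = (cell & 4) != 0;
        --w; // consume target: same row, previous band index
        if (!ext) { state = 0; r.n_gap++; }
      } else {
        r.n_gap_cols++;
        bool ext = (cell & 8) != 0;
        --i; ++w; // consume query: previous row, next band index
        if (!ext) { state = 0; r.n_gap++; }
      }
    }
    r.qstart = i; r.qend = bi;
    r.tstart = i + dlo + w; r.tend = bi + dlo + bw;
  }
  return r;
}

// Score-only banded Gotoh: same recurrences as banded_core without traceback
// bookkeeping, for competitive scoring of many targets.
static int banded_score_core(const std::string &q, const std::string &t,
                             int dlo, int dhi, int match, int mismatch,
                             int gap_open, int gap_extend) {
  const int m = (int) q.size(), n = (int) t.size();
  dlo = std::max(dlo, -m); dhi = std::min(dhi, n);
  if (dlo > dhi) return 0;
  const int go = gap_open + gap_extend, ge = gap_extend;
  const int W = dhi - dlo + 1;
  std::vector<int> Hprev(W), Hcur(W), Fprev(W, NEG_INF), Fcur(W);
  for (int w = 0; w < W; ++w) {
    int j = dlo + w;
    Hprev[w] = (j >= 0 && j <= n) ? 0 : NEG_INF;
  }
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int Erow = NEG_INF;
    const char qi = q[i - 1];
    for (int w = 0; w < W; ++w) {
      int j = i + dlo + w;
      if (j < 0 || j > n) { Hcur[w] = NEG_INF; Fcur[w] = NEG_INF; continue; }
      if (j == 0) { Hcur[w] = 0; Fcur[w] = NEG_INF; Erow = NEG_INF; continue; }
      int Hleft = (w >= 1) ? Hcur[w - 1] : NEG_INF;
      int E = std::max(Hleft - go, Erow - ge);
      Erow = E;
      int Hup = (w + 1 < W) ? Hprev[w + 1] : NEG_INF;
      int Fup = (w + 1 < W) ? Fprev[w + 1] : NEG_INF;
      int F = std::max(Hup - go, Fup - ge);
      Fcur[w] = F;
      int s = base_match(qi, t[j - 1], false) ? match : -mismatch;
      int H = std::max(0, Hprev[w] + s);
      H = std::max(H, std::max(E, F));
      Hcur[w] = H;
      if (H > best) best = H;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  return best;
}

// Banded Gotoh local alignment restricted to diagonals d = j - i in [dlo, dhi].
// [[Rcpp::export]]
List cpp_banded_local_align(std::string q, std::string t, int dlo, int dhi,
                            int match, int mismatch, int gap_open, int gap_extend,
                            bool iupac = false) {
  if (q.empty() || t.empty()) stop("sequences must be non-empty");
  if (dlo > dhi) stop("invalid band");
  return aln_to_list(banded_core(q, t, dlo, dhi, match, mismatch, gap_open,
                                 gap_extend, iupac));
}

// Levenshtein distance; N mismatches everything, including N (same rule as
// alignment scoring).
// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b) {
  const int m = (int) a.size(), n = (int) b.size();
  if (m == 0) return n;
  if (n == 0) return m;
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    const char ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (base_match(ai, b[j - 1], false) ? 0 : 1);
      int del = prev[j] + 1, ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Exact k-mer seeding: returns c(n_seeds, dlo, dhi) where [dlo, dhi] is the
// densest diagonal window of span <= win among seed diagonals (d = tpos - qpos).
// k-mers containing non-ACGT bases, or occurring more than max_occ times in the
// target, are skipped. n_seeds = 0 means no usable seed.
// [[Rcpp::export]]
IntegerVector cpp_seed_band(std::string q, std::string t, int k, int win,
                            int max_occ = 32) {
  const int m = (int) q.size(), n = (int) t.size();
  IntegerVector out = IntegerVector::create(0, 0, 0);
  if (k < 4 || k > 15 || m < k || n < k) return out;

  auto code2 = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);

  std::unordered_map<uint32_t, std::vector<int> > idx;
  idx.reserve((size_t) n * 2);
  {
    uint32_t key = 0; int valid = 0;
    for (int j = 0; j < n; ++j) {
      int c = code2(t[j]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t) c) & mask;
      if (++valid >= k) {
        std::vector<int> &v = idx[key];
        if ((int) v.size() <= max_occ) v.push_back(j - k + 1);
      }
    }
  }
  std::vector<int> diags;
  {
    uint32_t key = 0; int valid = 0;
    for (int i = 0; i < m; ++i) {
      int c = code2(q[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t) c) & mask;
      if (++valid >= k) {
        auto it = idx.find(key);
        if (it != idx.end() && (int) it->second.size() <= max_occ) {
          int qpos = i - k + 1;
          for (int tpos : it->second) diags.push_back(tpos - qpos);
        }
      }
    }
  }
  if (diags.empty()) return out;
  std::sort(diags.begin(), diags.end());
  size_t besti = 0, bestj = 0, bestcnt = 0, lo = 0;
  for (size_t hi = 0; hi < diags.size(); ++hi) {
    while (diags[hi] - diags[lo] > win) ++lo;
    size_t cnt = hi - lo + 1;
    if (cnt > bestcnt) { bestcnt = cnt; besti = lo; bestj = hi; }
  }
  out[0] = (int) bestcnt;
  out[1] = diags[besti];
  out[2] = diags[bestj];
  return out;
}

// Map one read (one orientation) against many targets: the read's k-mers are
// indexed once, each target is scanned for exact seed matches, and targets
// with at least min_seeds seeds in their densest diagonal window (span <= win)
// get a score-only banded alignment over that window padded by win/2. Targets
// without enough seeds score 0. Returns one row per target with the seed
// window, so the caller can recompute the winning alignment with traceback.
// [[Rcpp::export]]
DataFrame cpp_map_read(std::string q, CharacterVector targets, int k, int win,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int max_occ = 32, int min_seeds = 4) {
  const int m = (int) q.size();
  const int nt = targets.size();
  if (k < 4 || k > 15) stop("k must be in 4..15");
  auto code2 = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  const uint32_t kmask = (1u << (2 * k)) - 1;
  std::unordered_map<uint32_t, std::vector<int> > qidx;
  if (m >= k) {
    qidx.reserve((size_t) m * 2);
    uint32_t key = 0; int valid = 0;
    for (int i = 0; i < m; ++i) {
      int c = code2(q[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t) c) & kmask;
      if (++valid >= k) {
        std::vector<int> &v = qidx[key];
        if ((int) v.size() <= max_occ) v.push_back(i - k + 1);
      }
    }
  }
  IntegerVector score(nt), band_lo(nt), band_hi(nt), n_seeds(nt);
  std::vector<int> diags;
  for (int ti = 0; ti < nt; ++ti) {
    std::string t = as<std::string>(targets[ti]);
    diags.clear();
    if (m >= k && (int) t.size() >= k) {
      uint32_t key = 0; int valid = 0;
      for (int j = 0; j < (int) t.size(); ++j) {
        int c = code2(t[j]);
        if (c < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint32_t) c) & kmask;
        if (++valid >= k) {
          auto it = qidx.find(key);
          if (it != qidx.end() && (int) it->second.size() <= max_occ) {
            int tpos = j - k + 1;
            for (int qpos : it->second) diags.push_back(tpos - qpos);
          }
        }
      }
    }
    int cnt = 0, dlo = 0, dhi = 0;
    if (!diags.empty()) {
      std::sort(diags.begin(), diags.end());
      size_t lo = 0, bi = 0, bj = 0, bc = 0;
      for (size_t hi = 0; hi < diags.size(); ++hi) {
        while (diags[hi] - diags[lo] > win) ++lo;
        if (hi - lo + 1 > bc) { bc = hi - lo + 1; bi = lo; bj = hi; }
      }
      cnt = (int) bc; dlo = diags[bi]; dhi = diags[bj];
    }
    n_seeds[ti] = cnt;
    int pad = win / 2;
    int sc = 0;
    if (cnt >= min_seeds) {
      sc = banded_score_core(q, t, dlo - pad, dhi + pad, match, mismatch,
                             gap_open, gap_extend);
    }
    score[ti] = sc;
    band_lo[ti] = dlo - pad;
    band_hi[ti] = dhi + pad;
  }
  return DataFrame::create(
    _["score"] = score, _["band_lo"] = band_lo, _["band_hi"] = band_hi,
    _["n_seeds"] = n_seeds);
}

// Banded Levenshtein distance: exact when the optimal path stays within
// |(j - i) - drift| <= band around the main diagonal (drift up to the length
// difference is always allowed); an upper bound otherwise. band = 0 runs the
// full computation.
// [[Rcpp::export]]
int cpp_banded_edit_distance(std::string a, std::string b, int band = 0) {
  const int m = (int) a.size(), n = (int) b.size();
  if (m == 0) return n;
  if (n == 0) return m;
  if (band <= 0) return cpp_edit_distance(a, b);
  const int big = INT32_MAX / 4;
  const int lo_d = std::min(0, n - m) - band, hi_d = std::max(0, n - m) + band;
  std::vector<int> prev(n + 1, big), cur(n + 1, big);
  for (int j = 0; j <= std::min(n, hi_d); ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    const int jlo = std::max(1, i + lo_d), jhi = std::min(n, i + hi_d);
    if (jlo > jhi) return cpp_edit_distance(a, b);  // degenerate band
    std::fill(cur.begin(), cur.end(), big);
    if (jlo == 1 && i + lo_d <= 0) cur[0] = i;
    const char ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int sub = prev[j - 1] + (base_match(ai, b[j - 1], false) ? 0 : 1);
      int del = prev[j] + 1, ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}
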