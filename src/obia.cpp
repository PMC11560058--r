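// Compiled kernels for the OBIA pipeline: high-pass convolution, Sobel
// gradient, moving-window texture statistics, seeded watershed flooding and
// lambda-schedule region merging. All functions treat NA pixels as nodata.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <cmath>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// High-pass filter: center weight = number of valid neighbour positions in
// the w x w window, each valid neighbour weight -1. With no nodata this is
// the classic sharpen-residual kernel (center w^2-1, others -1); with nodata
// the weights renormalize so a constant region still maps to zero. Border
// neighbours are taken by edge replication (index clamping).
// [[Rcpp::export]]
NumericMatrix cpp_highpass(NumericMatrix px, LogicalMatrix nd, int w) {
  int h = px.nrow(), wd = px.ncol(), r = w / 2;
  NumericMatrix out(h, wd);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < wd; ++j) {
      if (nd(i, j)) { out(i, j) = NA_REAL; continue; }
      double s = 0.0; int nvalid = 0;
      for (int di = -r; di <= r; ++di) {
        for (int dj = -r; dj <= r; ++dj) {
          if (di == 0 && dj == 0) continue;
          int ii = clampi(i + di, 0, h - 1);
          int jj = clampi(j + dj, 0, wd - 1);
          if (!nd(ii, jj)) { s += px(ii, jj); ++nvalid; }
        }
      }
      out(i, j) = nvalid * px(i, j) - s;
    }
  }
  return out;
}

// 3x3 binomial smoothing (weights outer([1,2,1],[1,2,1])/16) with
// replicate-edge padding; weights renormalize over valid pixels so nodata
// neighbourhoods stay unbiased. Nodata centers give NA.
// [[Rcpp::export]]
NumericMatrix cpp_binomial3(NumericMatrix px, LogicalMatrix nd) {
  int h = px.nrow(), wd = px.ncol();
  static const double wgt[3] = {1.0, 2.0, 1.0};
  NumericMatrix out(h, wd);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < wd; ++j) {
      if (nd(i, j)) { out(i, j) = NA_REAL; continue; }
      double s = 0.0, wsum = 0.0;
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          int ii = clampi(i + di, 0, h - 1);
          int jj = clampi(j + dj, 0, wd - 1);
          if (nd(ii, jj)) continue;
          double wv = wgt[di + 1] * wgt[dj + 1];
          s += wv * px(ii, jj);
          wsum += wv;
        }
      out(i, j) = s / wsum;
    }
  }
  return out;
}

// Sobel gradient magnitude with replicate-edge padding. Nodata centers give
// NA; nodata neighbours are replaced by the center value, which keeps land
// boundaries from producing artificial spikes.
// [[Rcpp::export]]
NumericMatrix cpp_sobel(NumericMatrix px, LogicalMatrix nd) {
  int h = px.nrow(), wd = px.ncol();
  NumericMatrix out(h, wd);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < wd; ++j) {
      if (nd(i, j)) { out(i, j) = NA_REAL; continue; }
      double c = px(i, j);
      double v[3][3];
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          int ii = clampi(i + di, 0, h - 1);
          int jj = clampi(j + dj, 0, wd - 1);
          v[di + 1][dj + 1] = nd(ii, jj) ? c : px(ii, jj);
        }
      double gx = (v[0][2] + 2.0 * v[1][2] + v[2][2]) -
                  (v[0][0] + 2.0 * v[1][0] + v[2][0]);
      double gy = (v[2][0] + 2.0 * v[2][1] + v[2][2]) -
                  (v[0][0] + 2.0 * v[0][1] + v[0][2]);
      out(i, j) = std::sqrt(gx * gx + gy * gy);
    }
  }
  return out;
}

// Moving-window texture statistics over the k x k neighbourhood clipped to
// the image: mean, population variance, range, and entropy
// sum_b p_b log2(p_b) over nbins histogram bins scaled to [gmin, gmax]
// (<= 0 by construction). Nodata windows renormalize over valid pixels.
// [[Rcpp::export]]
List cpp_texture(NumericMatrix px, LogicalMatrix nd, int k, int nbins,
                 double gmin, double gmax) {
  int h = px.nrow(), wd = px.ncol(), r = k / 2;
  NumericMatrix m_mean(h, wd), m_var(h, wd), m_ent(h, wd), m_rng(h, wd);
  double span = gmax - gmin;
  std::vector<int> counts(nbins);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < wd; ++j) {
      if (nd(i, j)) {
        m_mean(i, j) = m_var(i, j) = m_ent(i, j) = m_rng(i, j) = NA_REAL;
        continue;
      }
      double s = 0.0, s2 = 0.0, vmin = R_PosInf, vmax = R_NegInf;
      int n = 0;
      std::fill(counts.begin(), counts.end(), 0);
      for (int di = -r; di <= r; ++di) {
        int ii = i + di;
        if (ii < 0 || ii >= h) continue;
        for (int dj = -r; dj <= r; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= wd) continue;
          if (nd(ii, jj)) continue;
          double v = px(ii, jj);
          s += v; s2 += v * v; ++n;
          if (v < vmin) vmin = v;
          if (v > vmax) vmax = v;
          int b = span > 0.0 ? (int)std::floor((v - gmin) / span * nbins) : 0;
          counts[clampi(b, 0, nbins - 1)]++;
        }
      }
      double mu = s / n;
      m_mean(i, j) = mu;
      double var = s2 / n - mu * mu;
      m_var(i, j) = var < 0.0 ? 0.0 : var;
      m_rng(i, j) = vmax - vmin;
      double ent = 0.0;
      for (int b = 0; b < nbins; ++b) {
        if (counts[b] > 0) {
          double p = (double)counts[b] / n;
          ent += p * std::log2(p);
        }
      }
      m_ent(i, j) = ent;
    }
  }
  return List::create(_["mean"] = m_mean, _["variance"] = m_var,
                      _["entropy"] = m_ent, _["range"] = m_rng);
}

struct FloodEntry {
  double value;
  long order;
  int idx;
  int label;
};
struct FloodCmp {
  bool operator()(const FloodEntry& a, const FloodEntry& b) const {
    if (a.value != b.value) return a.value > b.value;
    return a.order > b.order;
  }
};

// Watershed of a suppressed gradient map: gradient values strictly below
// `thresh` are set to 0, seeds are the regional minima (4-connected plateaus
// with no strictly lower valid neighbour, discovered in row-major order),
// and remaining pixels are flooded in order of increasing suppressed value
// with FIFO tie-breaking. Every valid pixel receives a label 1..n; nodata
// (NA) pixels stay 0.
//
// Strong-edge rescue (hysteresis logic): a small bright target one or two
// pixels wide is a pure gradient ridge with no interior minimum, so without
// intervention its edge response dissolves into the surrounding basin and
// the target is lost. Strong-edge components - 4-connected sets of pixels
// whose gradient reaches `strong_ratio` times the suppression threshold
// (the classic strong:weak edge ratio) - spanning at least `min_rescue_px`
// pixels (the Sobel response of a resolvable target; isolated noise
// exceedances are smaller) therefore seed new regions before flooding.
// Rescue only fires when no basin can represent the target: if the
// component touches at least `min_bright_px` suppressed (sub-threshold)
// pixels that are themselves bright, those pixels form a crest-dip plateau
// which already seeds a basin, and the component is left to ordinary
// flooding (fewer than `dip_evidence_px` bright sub-threshold pixels are
// indistinguishable from noise and do not count). Because an edge
// band mixes the bright ridge with its dark reaction halo, only its bright
// side is labelled: each 4-connected piece of the component with intensity
// above `bright_floor` and at least `min_bright_px` pixels becomes one
// closed region; without `intensity` the whole component is taken.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix g, double thresh,
                            Nullable<NumericMatrix> intensity = R_NilValue,
                            double strong_ratio = 2.0,
                            int min_rescue_px = 8, int min_bright_px = 1,
                            double bright_floor = 0.0,
                            int dip_evidence_px = 3) {
  int h = g.nrow(), wd = g.ncol(), npx = h * wd;
  std::vector<double> sv(npx);
  std::vector<int> lab(npx, 0); // 0 unvisited, -1 nodata, -2 visited non-min
  for (int j = 0; j < wd; ++j)
    for (int i = 0; i < h; ++i) {
      int idx = j * h + i;
      if (NumericMatrix::is_na(g(i, j))) { lab[idx] = -1; sv[idx] = NA_REAL; }
      else sv[idx] = g(i, j) < thresh ? 0.0 : g(i, j);
    }
  const int dR[4] = {-1, 1, 0, 0};
  const int dC[4] = {0, 0, -1, 1};
  int nlab = 0;
  int n_basin = 0; // labels above this are strong-edge rescue regions
  std::vector<int> plateau;
  // row-major scan (row fastest within a row: iterate rows outer, cols inner)
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < wd; ++j) {
      int idx0 = j * h + i;
      if (lab[idx0] != 0) continue;
      double v = sv[idx0];
      plateau.clear();
      plateau.push_back(idx0);
      lab[idx0] = -3; // in current plateau
      bool is_min = true;
      for (size_t q = 0; q < plateau.size(); ++q) {
        int idx = plateau[q];
        int pi = idx % h, pj = idx / h;
        for (int d = 0; d < 4; ++d) {
          int ni = pi + dR[d], nj = pj + dC[d];
          if (ni < 0 || ni >= h || nj < 0 || nj >= wd) continue;
          int nidx = nj * h + ni;
          if (lab[nidx] == -1) continue;
          if (sv[nidx] < v) { is_min = false; }
          else if (sv[nidx] == v && lab[nidx] != -3 &&
                   lab[nidx] <= 0) { // unvisited or visited-nonmin plateau mate
            if (lab[nidx] == 0) {
              lab[nidx] = -3;
              plateau.push_back(nidx);
            } else {
              is_min = false; // touches an already-rejected equal plateau
            }
          } else if (sv[nidx] == v && lab[nidx] > 0) {
            // equal-valued pixels already claimed by a seed: same plateau,
            // cannot happen for minima discovered in scan order
            is_min = false;
          }
        }
      }
      int mark = is_min ? ++nlab : -2;
      for (size_t q = 0; q < plateau.size(); ++q) lab[plateau[q]] = mark;
    }
  }
  // strong-edge rescue of wall components
  n_basin = nlab;
  if (thresh > 0.0) {
    bool has_int = intensity.isNotNull();
    NumericMatrix inten;
    if (has_int) inten = NumericMatrix(intensity);
    double strong = strong_ratio * thresh;
    std::vector<char> seen(npx, 0);
    std::vector<char> in_piece(npx, 0);
    std::vector<char> dip_seen(npx, 0);
    std::vector<int> comp, piece, dips;
    for (int i0 = 0; i0 < h; ++i0) {
      for (int j0 = 0; j0 < wd; ++j0) {
        int idx0 = j0 * h + i0;
        if (lab[idx0] != -2 || seen[idx0] || sv[idx0] < strong) continue;
        comp.clear();
        comp.push_back(idx0);
        seen[idx0] = 1;
        dips.clear();
        for (size_t q = 0; q < comp.size(); ++q) {
          int idx = comp[q];
          int pi = idx % h, pj = idx / h;
          for (int d = 0; d < 4; ++d) {
            int ni = pi + dR[d], nj = pj + dC[d];
            if (ni < 0 || ni >= h || nj < 0 || nj >= wd) continue;
            int nidx = nj * h + ni;
            if (lab[nidx] == -1) continue;
            if (lab[nidx] == -2 && !seen[nidx] && sv[nidx] >= strong) {
              seen[nidx] = 1;
              comp.push_back(nidx);
            } else if (has_int && sv[nidx] == 0.0 &&
                       inten[nidx] > bright_floor && !dip_seen[nidx]) {
              dip_seen[nidx] = 1;
              dips.push_back(nidx);
            }
          }
        }
        int n_dip_bright = (int)dips.size();
        for (size_t q = 0; q < dips.size(); ++q) dip_seen[dips[q]] = 0;
        if (n_dip_bright >= dip_evidence_px ||
            (int)comp.size() < min_rescue_px) continue;
        if (!has_int) {
          ++nlab;
          for (size_t q = 0; q < comp.size(); ++q) lab[comp[q]] = nlab;
          continue;
        }
        // label each sufficiently large bright piece of the component
        for (size_t q = 0; q < comp.size(); ++q) {
          int idx = comp[q];
          if (in_piece[idx] || !(inten[idx] > bright_floor)) continue;
          piece.clear();
          piece.push_back(idx);
          in_piece[idx] = 1;
          for (size_t p = 0; p < piece.size(); ++p) {
            int pdx = piece[p];
            int pi = pdx % h, pj = pdx / h;
            for (int d = 0; d < 4; ++d) {
              int ni = pi + dR[d], nj = pj + dC[d];
              if (ni < 0 || ni >= h || nj < 0 || nj >= wd) continue;
              int nidx = nj * h + ni;
              if (lab[nidx] == -2 && !in_piece[nidx] && seen[nidx] &&
                  sv[nidx] >= strong && inten[nidx] > bright_floor) {
                in_piece[nidx] = 1;
                piece.push_back(nidx);
              }
            }
          }
          if ((int)piece.size() >= min_bright_px) {
            ++nlab;
            for (size_t p = 0; p < piece.size(); ++p) lab[piece[p]] = nlab;
          }
        }
      }
    }
  }
  // flood: basins grow in order of increasing suppressed gradient;
  // strong-edge rescue regions are closed objects and only claim pixels no
  // basin can reach (their queue entries carry an infinite value)
  // pixels may be queued by several fronts; the entry popped first (lowest
  // value, then FIFO) assigns the label, later entries are skipped
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCmp> pq;
  long order = 0;
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < wd; ++j) {
      int idx = j * h + i;
      if (lab[idx] <= 0) continue;
      bool rescue = lab[idx] > n_basin;
      for (int d = 0; d < 4; ++d) {
        int ni = i + dR[d], nj = j + dC[d];
        if (ni < 0 || ni >= h || nj < 0 || nj >= wd) continue;
        int nidx = nj * h + ni;
        if (lab[nidx] == -2)
          pq.push({rescue ? R_PosInf : sv[nidx], order++, nidx, lab[idx]});
      }
    }
  while (!pq.empty()) {
    FloodEntry e = pq.top();
    pq.pop();
    if (lab[e.idx] > 0) continue;
    lab[e.idx] = e.label;
    bool rescue = e.label > n_basin;
    int pi = e.idx % h, pj = e.idx / h;
    for (int d = 0; d < 4; ++d) {
      int ni = pi + dR[d], nj = pj + dC[d];
      if (ni < 0 || ni >= h || nj < 0 || nj >= wd) continue;
      int nidx = nj * h + ni;
      if (lab[nidx] == -2)
        pq.push({rescue ? R_PosInf : sv[nidx], order++, nidx, e.label});
    }
  }
  IntegerMatrix out(h, wd);
  for (int j = 0; j < wd; ++j)
    for (int i = 0; i < h; ++i) {
      int v = lab[j * h + i];
      out(i, j) = v > 0 ? v : 0;
    }
  return out;
}

static inline long long pairkey(int a, int b, long long M) {
  return (long long)a * M + b;
}

// Region-adjacency statistics for a label image: per-segment pixel count and
// value sum, and for every 4-adjacent pair of distinct segments the shared
// border length in pixel edges.
// [[Rcpp::export]]
List cpp_rag(IntegerMatrix labels, NumericMatrix px, int nseg) {
  int h = labels.nrow(), wd = labels.ncol();
  std::vector<double> sum(nseg + 1, 0.0);
  std::vector<double> cnt(nseg + 1, 0.0);
  long long M = nseg + 1;
  std::unordered_map<long long, int> border;
  for (int j = 0; j < wd; ++j)
    for (int i = 0; i < h; ++i) {
      int a = labels(i, j);
      if (a == 0) continue;
      sum[a] += px(i, j);
      cnt[a] += 1.0;
      if (i + 1 < h) {
        int b = labels(i + 1, j);
        if (b != 0 && b != a) border[pairkey(std::min(a, b), std::max(a, b), M)]++;
      }
      if (j + 1 < wd) {
        int b = labels(i, j + 1);
        if (b != 0 && b != a) border[pairkey(std::min(a, b), std::max(a, b), M)]++;
      }
    }
  int ne = border.size();
  IntegerVector ei(ne), ej(ne), eb(ne);
  int q = 0;
  for (auto& kv : border) {
    ei[q] = (int)(kv.first / M);
    ej[q] = (int)(kv.first % M);
    eb[q] = kv.second;
    ++q;
  }
  return List::create(_["count"] = NumericVector(cnt.begin() + 1, cnt.end()),
                      _["sum"] = NumericVector(sum.begin() + 1, sum.end()),
                      _["i"] = ei, _["j"] = ej, _["border"] = eb);
}

struct MergeEntry {
  double cost;
  int i, j;
};
struct MergeCmp {
  bool operator()(const MergeEntry& a, const MergeEntry& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    if (a.i != b.i) return a.i > b.i;
    return a.j > b.j;
  }
};

static inline double lambda_cost(double ni, double nj, double mi, double mj,
                                 double border) {
  double d = mi - mj;
  return (ni * nj / (ni + nj)) * d * d / border;
}

// Lambda-schedule region merging: repeatedly merge the globally cheapest
// adjacent pair whose current merge cost is strictly below `lambda`,
// updating means, sizes and borders locally. Ties broken by (smaller id,
// smaller neighbour id). Returns labels relabelled 1..n in row-major order
// of first occurrence.
// [[Rcpp::export]]
IntegerMatrix cpp_lambda_merge(IntegerMatrix labels, NumericMatrix px,
                               int nseg, double lambda) {
  int h = labels.nrow(), wd = labels.ncol();
  std::vector<double> sum(nseg + 1, 0.0), cnt(nseg + 1, 0.0);
  long long M = nseg + 1;
  std::unordered_map<long long, double> border;
  std::vector<std::unordered_set<int>> nbrs(nseg + 1);
  for (int j = 0; j < wd; ++j)
    for (int i = 0; i < h; ++i) {
      int a = labels(i, j);
      if (a == 0) continue;
      sum[a] += px(i, j);
      cnt[a] += 1.0;
      int b;
      if (i + 1 < h && (b = labels(i + 1, j)) != 0 && b != a) {
        border[pairkey(std::min(a, b), std::max(a, b), M)]++;
        nbrs[a].insert(b);
        nbrs[b].insert(a);
      }
      if (j + 1 < wd && (b = labels(i, j + 1)) != 0 && b != a) {
        border[pairkey(std::min(a, b), std::max(a, b), M)]++;
        nbrs[a].insert(b);
        nbrs[b].insert(a);
      }
    }
  std::priority_queue<MergeEntry, std::vector<MergeEntry>, MergeCmp> pq;
  std::unordered_map<long long, double> curcost;
  for (auto& kv : border) {
    int a = (int)(kv.first / M), b = (int)(kv.first % M);
    double t = lambda_cost(cnt[a], cnt[b], sum[a] / cnt[a], sum[b] / cnt[b],
                           kv.second);
    curcost[kv.first] = t;
    pq.push({t, a, b});
  }
  std::vector<char> active(nseg + 1, 1);
  std::vector<int> parent(nseg + 1);
  for (int s = 0; s <= nseg; ++s) parent[s] = s;
  while (!pq.empty()) {
    MergeEntry e = pq.top();
    if (e.cost >= lambda) break;
    pq.pop();
    if (!active[e.i] || !active[e.j]) continue;
    long long key = pairkey(e.i, e.j, M);
    auto it = curcost.find(key);
    if (it == curcost.end() || it->second != e.cost) continue; // stale
    // merge j into i (i < j)
    int i = e.i, j = e.j;
    sum[i] += sum[j];
    cnt[i] += cnt[j];
    active[j] = 0;
    parent[j] = i;
    nbrs[i].erase(j);
    nbrs[j].erase(i);
    border.erase(key);
    curcost.erase(key);
    for (int c : nbrs[j]) {
      nbrs[c].erase(j);
      long long kj = pairkey(std::min(c, j), std::max(c, j), M);
      double b = border[kj];
      border.erase(kj);
      curcost.erase(kj);
      long long ki = pairkey(std::min(c, i), std::max(c, i), M);
      border[ki] += b;
      nbrs[c].insert(i);
      nbrs[i].insert(c);
    }
    nbrs[j].clear();
    for (int c : nbrs[i]) {
      long long ki = pairkey(std::min(c, i), std::max(c, i), M);
      double t = lambda_cost(cnt[i], cnt[c], sum[i] / cnt[i],
                             sum[c] / cnt[c], border[ki]);
      curcost[ki] = t;
      pq.push({t, std::min(c, i), std::max(c, i)});
    }
  }
  // final mapping; the root of a merged group is always its smallest
  // original id, so assigning new ids in ascending root order keeps the
  // no-merge case an identity relabelling
  std::vector<int> final_of(nseg + 1, 0);
  std::vector<int> newid(nseg + 1, 0);
  int next = 0;
  for (int s = 1; s <= nseg; ++s) {
    int r = s;
    while (parent[r] != r) r = parent[r];
    final_of[s] = r;
    if (newid[r] == 0) newid[r] = ++next;
  }
  IntegerMatrix out(h, wd);
  for (int j = 0; j < wd; ++j)
    for (int i = 0; i < h; ++i) {
      int a = labels(i, j);
      out(i, j) = a == 0 ? 0 : newid[final_of[a]];
    }
  return out;
}

// 4-connected components of a logical mask, row-major label order.
// Used for segment-map validation and hole counting.
// [[Rcpp::export]]
IntegerMatrix cpp_label4(LogicalMatrix mask) {
  int h = mask.nrow(), wd = mask.ncol();
  IntegerMatrix lab(h, wd);
  const int dR[4] = {-1, 1, 0, 0};
  const int dC[4] = {0, 0, -1, 1};
  int nlab = 0;
  std::vector<int> stack;
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < wd; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++nlab;
      stack.clear();
      stack.push_back(j * h + i);
      lab(i, j) = nlab;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int pi = idx % h, pj = idx / h;
        for (int d = 0; d < 4; ++d) {
          int ni = pi + dR[d], nj = pj + dC[d];
          if (ni < 0 || ni >= h || nj < 0 || nj >= wd) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = nlab;
            stack.push_back(nj * h + ni);
          }
        }
      }
    }
  return lab;
}
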