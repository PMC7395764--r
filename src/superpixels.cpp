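#include <Rcpp.h>
#include <set>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Local k-means superpixels on a depth map (grid-seeded, SLIC-style):
// distance = (d_depth / depth_scale)^2 + compactness * (d_xy / S)^2,
// followed by a connectivity pass that relabels stray fragments to their
// dominant neighbour. Returns a 1-based label matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_slic_depth(NumericMatrix depth, int n_superpixels,
                             double depth_scale, double compactness,
                             int iters) {
  const int nr = depth.nrow(), nc = depth.ncol();
  const double N = (double)nr * nc;
  double S = std::sqrt(N / std::max(n_superpixels, 1));
  if (S < 2.0) S = 2.0;

  // grid seeds
  std::vector<double> cr, cc, cd;
  for (double r = S / 2; r < nr; r += S)
    for (double c = S / 2; c < nc; c += S) {
      cr.push_back(r);
      cc.push_back(c);
      cd.push_back(depth((int)r, (int)c));
    }
  const int K = cr.size();
  IntegerMatrix label(nr, nc);
  std::fill(label.begin(), label.end(), 0);
  std::vector<double> best(nr * (size_t)nc);

  for (int it = 0; it < iters; ++it) {
    std::fill(best.begin(), best.end(), R_PosInf);
    for (int k = 0; k < K; ++k) {
      int r0 = std::max(0, (int)(cr[k] - 2 * S)), r1 = std::min(nr - 1, (int)(cr[k] + 2 * S));
      int c0 = std::max(0, (int)(cc[k] - 2 * S)), c1 = std::min(nc - 1, (int)(cc[k] + 2 * S));
      for (int c = c0; c <= c1; ++c) {
        for (int r = r0; r <= r1; ++r) {
          double dd = (depth(r, c) - cd[k]) / depth_scale;
          double dr = r - cr[k], dc = c - cc[k];
          double D = dd * dd + compactness * (dr * dr + dc * dc) / (S * S);
          size_t idx = (size_t)c * nr + r;
          if (D < best[idx]) { best[idx] = D; label(r, c) = k + 1; }
        }
      }
    }
    // update centers
    std::vector<double> sr(K, 0), sc(K, 0), sdep(K, 0);
    std::vector<int> cnt(K, 0);
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int k = label(r, c) - 1;
        if (k < 0) continue;
        sr[k] += r; sc[k] += c; sdep[k] += depth(r, c); cnt[k]++;
      }
    for (int k = 0; k < K; ++k)
      if (cnt[k] > 0) {
        cr[k] = sr[k] / cnt[k]; cc[k] = sc[k] / cnt[k]; cd[k] = sdep[k] / cnt[k];
      }
  }

  // connectivity: flood-fill components; attach small fragments to the
  // dominant adjacent component's label
  IntegerMatrix comp(nr, nc);
  std::fill(comp.begin(), comp.end(), 0);
  int ncomp = 0;
  std::vector<int> comp_label, comp_size;
  const int drs[4] = {1, -1, 0, 0}, dcs[4] = {0, 0, 1, -1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (comp(r, c) != 0) continue;
      ++ncomp;
      int lab = label(r, c);
      int sz = 0;
      std::queue<std::pair<int, int> > q;
      q.push(std::make_pair(r, c));
      comp(r, c) = ncomp;
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        ++sz;
        for (int d = 0; d < 4; ++d) {
          int rr = p.first + drs[d], cc2 = p.second + dcs[d];
          if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
          if (comp(rr, cc2) == 0 && label(rr, cc2) == lab) {
            comp(rr, cc2) = ncomp;
            q.push(std::make_pair(rr, cc2));
          }
        }
      }
      comp_label.push_back(lab);
      comp_size.push_back(sz);
    }
  int min_size = (int)(S * S / 4);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int ci = comp(r, c) - 1;
      if (comp_size[ci] >= min_size) continue;
      // adopt the label of the first sufficiently large neighbour component
      for (int d = 0; d < 4; ++d) {
        int rr = r + drs[d], cc2 = c + dcs[d];
        if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
        int cj = comp(rr, cc2) - 1;
        if (cj != ci && comp_size[cj] >= min_size) {
          label(r, c) = comp_label[cj];
          break;
        }
      }
    }

  // compact label ids to 1..K'
  std::vector<int> remap(K + 1, 0);
  int next = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = label(r, c);
      if (remap[l] == 0) remap[l] = ++next;
      label(r, c) = remap[l];
    }
  return label;
}

// Per-superpixel mean depth, centroid and 4-neighbour adjacency pairs,
// in one pass over the label map.
// [[Rcpp::export]]
List cpp_label_stats(IntegerMatrix label, NumericMatrix depth) {
  int nr = label.nrow(), nc = label.ncol();
  int K = 0;
  for (int i = 0; i < nr * nc; ++i) K = std::max(K, label[i]);
  std::vector<double> sd(K, 0), srow(K, 0), scol(K, 0);
  std::vector<int> cnt(K, 0);
  std::set<std::pair<int, int> > adj;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int k = label(r, c) - 1;
      sd[k] += depth(r, c); srow[k] += r + 1; scol[k] += c + 1; cnt[k]++;
      if (r + 1 < nr) {
        int k2 = label(r + 1, c) - 1;
        if (k2 != k) adj.insert(std::make_pair(std::min(k, k2) + 1, std::max(k, k2) + 1));
      }
      if (c + 1 < nc) {
        int k2 = label(r, c + 1) - 1;
        if (k2 != k) adj.insert(std::make_pair(std::min(k, k2) + 1, std::max(k, k2) + 1));
      }
    }
  NumericVector mean_depth(K), mrow(K), mcol(K);
  IntegerVector count(K);
  for (int k = 0; k < K; ++k) {
    mean_depth[k] = cnt[k] ? sd[k] / cnt[k] : NA_REAL;
    mrow[k] = cnt[k] ? srow[k] / cnt[k] : NA_REAL;
    mcol[k] = cnt[k] ? scol[k] / cnt[k] : NA_REAL;
    count[k] = cnt[k];
  }
  IntegerMatrix pairs(adj.size(), 2);
  int i = 0;
  for (std::set<std::pair<int, int> >::iterator it = adj.begin();
       it != adj.end(); ++it, ++i) {
    pairs(i, 0) = it->first;
    pairs(i, 1) = it->second;
  }
  return List::create(_["mean_depth"] = mean_depth, _["row"] = mrow,
                      _["col"] = mcol, _["count"] = count,
                      _["pairs"] = pairs);
}
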