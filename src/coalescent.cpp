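#include <Rcpp.h>
using namespace Rcpp;

// Structured coalescent on the 4-lineage species network
// (((C,D),O),A) with an optional hybrid edge: at time t_h each remaining
// D lineage is routed to the O-side ancestor with probability gamma,
// otherwise to the C-side ancestor.  Populations:
//   0 = C, 1 = D, 2 = O, 3 = A (tip branches),
//   4 = C/O common ancestor  [t_co, t_root),
//   5 = root population      [t_root, inf).
// Time in coalescent units; coalescence rate k(k-1)/2 / ne[pop].
// Node numbering follows the ape "phylo" convention: tips 1..n, internal
// nodes n+1..2n-1 with the root at n+1 (internal ids assigned in reverse
// order of creation, so the last coalescence - the root - gets n+1).

static inline int pick_pop(const std::vector<double> &w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  for (int p = 0; p < (int)w.size(); ++p) {
    acc += w[p];
    if (u <= acc) return p;
  }
  return (int)w.size() - 1;
}

// [[Rcpp::export(name = ".sim_msc_loci")]]
List sim_msc_loci(int n_loci, IntegerVector n_hap, double t_h, double t_co,
                  double t_root, double gamma, NumericVector ne) {
  if (n_hap.size() != 4) stop("n_hap must have length 4");
  if (ne.size() != 6) stop("ne must have length 6");
  const int ntip = n_hap[0] + n_hap[1] + n_hap[2] + n_hap[3];
  if (ntip < 2) stop("need at least two sampled lineages");
  List out(n_loci);
  RNGScope scope;

  std::vector<int> anode(ntip), apop(ntip);
  std::vector<double> atime(ntip);

  for (int rep = 0; rep < n_loci; ++rep) {
    // active lineages
    int n_act = ntip;
    {
      int idx = 0;
      for (int g = 0; g < 4; ++g)
        for (int j = 0; j < n_hap[g]; ++j) {
          anode[idx] = idx + 1;
          apop[idx] = g;
          atime[idx] = 0.0;
          ++idx;
        }
    }
    IntegerMatrix edge(2 * ntip - 2, 2);
    NumericVector elen(2 * ntip - 2);
    int eidx = 0;
    int created = 0;  // internal nodes created so far
    double t = 0.0;
    int phase = 0;  // 0:[0,t_h) 1:[t_h,t_co) 2:[t_co,t_root) 3:beyond
    const double bounds[3] = {t_h, t_co, t_root};
    std::vector<double> w(6);
    std::vector<int> kpop(6);

    while (n_act > 1) {
      std::fill(kpop.begin(), kpop.end(), 0);
      for (int i = 0; i < n_act; ++i) kpop[apop[i]]++;
      double rate = 0.0;
      for (int p = 0; p < 6; ++p) {
        w[p] = 0.5 * kpop[p] * (kpop[p] - 1) / ne[p];
        rate += w[p];
      }
      double tnext = (rate > 0) ? t + exp_rand() / rate : R_PosInf;
      if (phase < 3 && tnext >= bounds[phase]) {
        t = bounds[phase];
        if (phase == 0) {
          for (int i = 0; i < n_act; ++i)
            if (apop[i] == 1) apop[i] = (unif_rand() < gamma) ? 2 : 0;
        } else if (phase == 1) {
          for (int i = 0; i < n_act; ++i)
            if (apop[i] == 0 || apop[i] == 2) apop[i] = 4;
        } else {
          for (int i = 0; i < n_act; ++i) apop[i] = 5;
        }
        ++phase;
        continue;
      }
      // coalescence event
      t = tnext;
      int p = pick_pop(w, rate);
      // choose two distinct lineages uniformly within pop p
      int k = kpop[p];
      int i1 = (int)(unif_rand() * k);
      int i2 = (int)(unif_rand() * (k - 1));
      if (i2 >= i1) ++i2;
      // map within-pop index -> active index
      int a1 = -1, a2 = -1, seen = 0;
      for (int i = 0; i < n_act; ++i) {
        if (apop[i] == p) {
          if (seen == i1) a1 = i;
          if (seen == i2) a2 = i;
          ++seen;
        }
      }
      int parent_tmp = ntip + 1 + created;  // temporary id, remapped below
      ++created;
      edge(eidx, 0) = parent_tmp;
      edge(eidx, 1) = anode[a1];
      elen[eidx] = t - atime[a1];
      ++eidx;
      edge(eidx, 0) = parent_tmp;
      edge(eidx, 1) = anode[a2];
      elen[eidx] = t - atime[a2];
      ++eidx;
      anode[a1] = parent_tmp;
      atime[a1] = t;
      // remove a2 by swapping with the last active lineage
      anode[a2] = anode[n_act - 1];
      apop[a2] = apop[n_act - 1];
      atime[a2] = atime[n_act - 1];
      --n_act;
    }
    // remap temporary internal ids: k-th created (k = 0..ntip-2)
    // becomes 2*ntip - 1 - k, so the root (last created) is ntip + 1
    for (int e = 0; e < 2 * ntip - 2; ++e) {
      for (int c = 0; c < 2; ++c) {
        int v = edge(e, c);
        if (v > ntip) edge(e, c) = 2 * ntip - 1 - (v - ntip - 1);
      }
    }
    out[rep] = List::create(_["edge"] = edge, _["edge.length"] = elen);
  }
  return out;
}

// Drop n_mut infinite-sites mutations on a tree: each mutation falls on an
// edge with probability proportional to its length; the tips below that
// edge carry the derived state.  Returns an ntip x n_mut logical matrix.
// [[Rcpp::export(name = ".drop_mutations")]]
LogicalMatrix drop_mutations(IntegerMatrix edge, NumericVector elen,
                             int ntip, int n_mut) {
  const int n_edge = edge.nrow();
  const int n_node = 2 * ntip - 1;
  // descendant tip sets per node; internal ids decrease with creation time,
  // so scanning internal nodes from 2n-1 down to n+1 sees children first
  std::vector<std::vector<int> > tips(n_node + 1);
  for (int v = 1; v <= ntip; ++v) tips[v].push_back(v);
  std::vector<std::vector<int> > kids(n_node + 1);
  for (int e = 0; e < n_edge; ++e) kids[edge(e, 0)].push_back(edge(e, 1));
  for (int v = n_node; v > ntip; --v) {
    for (size_t j = 0; j < kids[v].size(); ++j) {
      const std::vector<int> &tc = tips[kids[v][j]];
      tips[v].insert(tips[v].end(), tc.begin(), tc.end());
    }
  }
  std::vector<double> cum(n_edge);
  double total = 0.0;
  for (int e = 0; e < n_edge; ++e) {
    total += elen[e];
    cum[e] = total;
  }
  LogicalMatrix out(ntip, n_mut);
  if (total <= 0.0) return out;
  RNGScope scope;
  for (int m = 0; m < n_mut; ++m) {
    double u = unif_rand() * total;
    int lo = 0, hi = n_edge - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    const std::vector<int> &tc = tips[edge(lo, 1)];
    for (size_t j = 0; j < tc.size(); ++j) out(tc[j] - 1, m) = true;
  }
  return out;
}
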