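#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Single-site Gibbs sampler for a pairwise MRF over nStates-valued nodes.
//
// nodePot:   nNodes x nStates matrix of node weights.
// edges:     nEdges x 2 matrix of 0-based node pairs (i < j).
// edgePot:   nStates*nStates*nEdges array, column-major per edge slice;
//            entry [a, b, e] is the weight for (state(i)=a, state(j)=b).
//            Slices may be arbitrarily scaled: the conditional renormalizes.
// nSweeps:   number of full sequential sweeps over all nodes.
// recordSweeps: sorted 1-based sweep numbers after which the state vector
//            is recorded.
// init:      1-based initial states.
//
// The per-direction tables are laid out so that the neighbor-state lookup
// is always a contiguous nStates-long block, which keeps the inner product
// loop vectorizable. Uses R's RNG (set.seed on the R side).
// [[Rcpp::export]]
IntegerMatrix gibbs_chain_cpp(NumericMatrix nodePot, IntegerMatrix edges,
                              NumericVector edgePot, int nSweeps,
                              IntegerVector recordSweeps, IntegerVector init,
                              bool synchronous) {
  const int nNodes = nodePot.nrow();
  const int S = nodePot.ncol();
  const size_t S2 = (size_t)S * S;
  const int nEdges = edges.nrow();

  // node potentials, row-major per node
  std::vector<double> np((size_t)nNodes * S);
  for (int v = 0; v < nNodes; ++v)
    for (int a = 0; a < S; ++a) np[(size_t)v * S + a] = nodePot(v, a);

  // directed edge tables: block d holds, for the receiving node, the
  // weights arranged as [a + S * neighborState]
  std::vector<double> dir(2 * (size_t)nEdges * S2);
  const double *EP = edgePot.begin();
  std::vector<int> deg(nNodes, 0);
  for (int e = 0; e < nEdges; ++e) {
    ++deg[edges(e, 0)];
    ++deg[edges(e, 1)];
  }
  std::vector<size_t> start(nNodes + 1, 0);
  for (int v = 0; v < nNodes; ++v) start[v + 1] = start[v] + deg[v];
  std::vector<int> nbr(start[nNodes]);
  std::vector<size_t> blk(start[nNodes]);
  {
    std::vector<size_t> fill(nNodes, 0);
    for (int e = 0; e < nEdges; ++e) {
      const int i = edges(e, 0), j = edges(e, 1);
      const double *T = EP + S2 * e;
      double *Bi = &dir[(2 * (size_t)e) * S2];      // for node i: [a + S*s_j]
      double *Bj = &dir[(2 * (size_t)e + 1) * S2];  // for node j: [a + S*s_i]
      for (int b = 0; b < S; ++b)
        for (int a = 0; a < S; ++a) {
          Bi[a + S * b] = T[a + S * b];     // pot(a, b)
          Bj[a + S * b] = T[b + S * a];     // pot(b, a): transpose
        }
      size_t ki = start[i] + fill[i]++;
      size_t kj = start[j] + fill[j]++;
      nbr[ki] = j; blk[ki] = (2 * (size_t)e) * S2;
      nbr[kj] = i; blk[kj] = (2 * (size_t)e + 1) * S2;
    }
  }

  std::vector<int> state(nNodes);
  for (int v = 0; v < nNodes; ++v) state[v] = init[v] - 1;

  const int nRec = recordSweeps.size();
  IntegerMatrix out(nRec, nNodes);
  int rec = 0;

  std::vector<double> w(S);
  std::vector<int> prev(nNodes);
  for (int sweep = 1; sweep <= nSweeps; ++sweep) {
    // sequential scan reads the evolving state (true single-site Gibbs);
    // synchronous updating reads the previous sweep's state for all nodes
    const std::vector<int> &src = synchronous ? (prev = state) : state;
    for (int v = 0; v < nNodes; ++v) {
      const double *npv = &np[(size_t)v * S];
      for (int a = 0; a < S; ++a) w[a] = npv[a];
      for (size_t k = start[v]; k < start[v + 1]; ++k) {
        // the column loads are latency-bound (random 168-byte blocks from a
        // table larger than cache); prefetch the next neighbor's column
        if (k + 1 < start[v + 1]) {
          const double *nxt = &dir[blk[k + 1] + (size_t)S * src[nbr[k + 1]]];
#if defined(__GNUC__) || defined(__clang__)
          __builtin_prefetch(nxt, 0, 1);
          __builtin_prefetch(nxt + 8, 0, 1);
          __builtin_prefetch(nxt + 16, 0, 1);
#endif
        }
        const double *col = &dir[blk[k] + (size_t)S * src[nbr[k]]];
        for (int a = 0; a < S; ++a) w[a] *= col[a];
      }
      double tot = 0.0;
      for (int a = 0; a < S; ++a) tot += w[a];
      double u = unif_rand() * tot;
      int a = 0;
      double c = w[0];
      while (u > c && a < S - 1) { ++a; c += w[a]; }
      state[v] = a;
    }
    if (rec < nRec && sweep == recordSweeps[rec]) {
      for (int v = 0; v < nNodes; ++v) out(rec, v) = state[v] + 1;
      ++rec;
    }
  }
  return out;
}
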