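#include <Rcpp.h>
using namespace Rcpp;

// Classify every canonical triple against one gene tree and accumulate
// topology tallies. Classification uses the pairwise-MRCA depth rule: for
// sorted labels (a,b,c) the resolved topology is the pair whose MRCA lies
// strictly below the MRCA of all three; in a tree the two shallower pairwise
// MRCAs always coincide, so either one pair has the unique deepest MRCA or
// all three are equal (a polytomy -> unresolved).
//
// counts  : T x 3 integer matrix, modified in place (+1 per resolved triple)
// mrca    : k x k matrix of MRCA node ids over the tips present in this tree
// depth   : per-node topological depth (edges from root), 1-based node ids
// pos     : length-K map sample index -> row of mrca (0 = sample missing)
// triples : T x 3 matrix of 1-based sample indices, each row sorted
// policy  : 0 = skip unresolved, 1 = assign a uniform random slot (uses the
//           R RNG stream, so seeding is the caller's responsibility)
// [[Rcpp::export(name = ".count_triplets_cpp")]]
void count_triplets_cpp(IntegerMatrix counts, IntegerMatrix mrca,
                        NumericVector depth, IntegerVector pos,
                        IntegerMatrix triples, int policy) {
  const int T = triples.nrow();
  for (int t = 0; t < T; ++t) {
    int a = pos[triples(t, 0) - 1];
    int b = pos[triples(t, 1) - 1];
    int c = pos[triples(t, 2) - 1];
    if (a == 0 || b == 0 || c == 0) continue;  // tip missing at this locus
    --a; --b; --c;
    double dab = depth[mrca(a, b) - 1];
    double dac = depth[mrca(a, c) - 1];
    double dbc = depth[mrca(b, c) - 1];
    int slot = -1;
    if (dab > dac && dab > dbc) slot = 0;
    else if (dac > dab && dac > dbc) slot = 1;
    else if (dbc > dab && dbc > dac) slot = 2;
    if (slot < 0) {  // unresolved (all three MRCAs coincide)
      if (policy == 1) slot = (int)(unif_rand() * 3.0);
      else continue;
      if (slot > 2) slot = 2;
    }
    counts(t, slot) += 1;
  }
}

// For each canonical triple, the node id of the MRCA of its three tips in the
// guide tree: the shallowest of the three pairwise MRCAs.
// [[Rcpp::export(name = ".triple_mrca_cpp")]]
IntegerVector triple_mrca_cpp(IntegerMatrix mrca, NumericVector depth,
                              IntegerVector pos, IntegerMatrix triples) {
  const int T = triples.nrow();
  IntegerVector out(T);
  for (int t = 0; t < T; ++t) {
    int a = pos[triples(t, 0) - 1] - 1;
    int b = pos[triples(t, 1) - 1] - 1;
    int c = pos[triples(t, 2) - 1] - 1;
    int nab = mrca(a, b), nac = mrca(a, c), nbc = mrca(b, c);
    int best = nab;
    if (depth[nac - 1] < depth[best - 1]) best = nac;
    if (depth[nbc - 1] < depth[best - 1]) best = nbc;
    out[t] = best;
  }
  return out;
}
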