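#include <Rcpp.h>
using namespace Rcpp;

// Union-find over a small fixed vertex set.
static int uf_find(std::vector<int>& par, int x) {
  while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
  return x;
}

// Refined pairwise incompatibility matrix for parsimony-informative sites.
//
// `states` is an n_seq x n_site integer matrix; 0 marks missing data and
// positive integers encode character states. For each site pair the score is
// the cycle rank (edges - vertices + components) of the partition
// intersection graph built on the sequences non-missing at both sites:
// vertices are the states observed at either site, edges the distinct joint
// patterns. The rank equals the minimum number of extra (homoplastic)
// changes any tree must spend on the pair beyond (s_i - 1) + (s_j - 1).
// [[Rcpp::export]]
IntegerMatrix incompat_matrix(IntegerMatrix states) {
  const int n = states.nrow(), m = states.ncol();
  IntegerMatrix out(m, m);
  const int MAXS = 64; // states per site are tiny in practice
  std::vector<int> map_i(MAXS), map_j(MAXS);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      std::fill(map_i.begin(), map_i.end(), -1);
      std::fill(map_j.begin(), map_j.end(), -1);
      int si = 0, sj = 0;
      std::vector<std::pair<int, int> > joint;
      joint.reserve(n);
      for (int r = 0; r < n; ++r) {
        int a = states(r, i), b = states(r, j);
        if (a == 0 || b == 0) continue;
        if (map_i[a] < 0) map_i[a] = si++;
        if (map_j[b] < 0) map_j[b] = sj++;
        joint.push_back(std::make_pair(map_i[a], map_j[b]));
      }
      std::sort(joint.begin(), joint.end());
      joint.erase(std::unique(joint.begin(), joint.end()), joint.end());
      const int V = si + sj;
      const int E = (int)joint.size();
      std::vector<int> par(V);
      for (int v = 0; v < V; ++v) par[v] = v;
      int comp = V;
      for (size_t e = 0; e < joint.size(); ++e) {
        int ra = uf_find(par, joint[e].first);
        int rb = uf_find(par, si + joint[e].second);
        if (ra != rb) { par[ra] = rb; --comp; }
      }
      int cyc = E - V + comp;
      if (cyc < 0) cyc = 0;
      out(i, j) = cyc;
      out(j, i) = cyc;
    }
  }
  return out;
}
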