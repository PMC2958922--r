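#include <Rcpp.h>
using namespace Rcpp;

// Parsimony lengths over state-set (bitmask) characters.
//
// States are encoded as bitmasks over at most 4 bits: nucleotides use
// A=1, C=2, G=4, T=8 (IUPAC codes are unions; gap/missing = 15), binary
// indel characters use present=1, absent=2, missing=3.  A mask of 0 is
// invalid and rejected on entry.

static inline int popcount4(int x) {
  return (x & 1) + ((x >> 1) & 1) + ((x >> 2) & 1) + ((x >> 3) & 1);
}

// Per-character parsimony length of a rooted tree in ape edge-matrix form
// (parent in column 1, child in column 2; tips 1..ntip, root = ntip + 1).
// Uses Hartigan's count rule at every node, which reduces to Fitch set
// operations for binary nodes and stays exact at a multifurcating root
// (ape stores unrooted binary trees with a basal trichotomy).
// [[Rcpp::export]]
IntegerVector fitch_per_char_cpp(IntegerMatrix edge, int ntip,
                                 IntegerMatrix states) {
  const int nedge = edge.nrow();
  const int nchar = states.ncol();
  if (states.nrow() != ntip) stop("states must have one row per tip");
  int nnode = 0;
  for (int i = 0; i < nedge; ++i) {
    if (edge(i, 0) > nnode) nnode = edge(i, 0);
    if (edge(i, 1) > nnode) nnode = edge(i, 1);
  }
  // children lists
  std::vector<int> child_count(nnode + 1, 0);
  for (int i = 0; i < nedge; ++i) child_count[edge(i, 0)]++;
  std::vector<int> offset(nnode + 2, 0);
  for (int v = 1; v <= nnode; ++v) offset[v + 1] = offset[v] + child_count[v];
  std::vector<int> children(nedge);
  {
    std::vector<int> fill(nnode + 1, 0);
    for (int i = 0; i < nedge; ++i) {
      int p = edge(i, 0);
      children[offset[p] + fill[p]++] = edge(i, 1);
    }
  }
  const int root = ntip + 1;
  // postorder of internal nodes via iterative DFS
  std::vector<int> order;
  order.reserve(nnode);
  {
    std::vector<int> stack;
    stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      order.push_back(v);
      for (int k = offset[v]; k < offset[v + 1]; ++k)
        if (children[k] > ntip) stack.push_back(children[k]);
    }
    std::reverse(order.begin(), order.end());
  }
  IntegerVector out(nchar);
  std::vector<int> set(nnode + 1);
  for (int c = 0; c < nchar; ++c) {
    for (int t = 1; t <= ntip; ++t) {
      int s = states(t - 1, c);
      if (s <= 0 || s > 15) stop("invalid state mask at tip %d", t);
      set[t] = s;
    }
    int len = 0;
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int v = order[oi];
      int k0 = offset[v], k1 = offset[v + 1];
      int deg = k1 - k0;
      if (deg == 2) {  // Fitch fast path
        int a = set[children[k0]], b = set[children[k0 + 1]];
        int inter = a & b;
        if (inter) set[v] = inter;
        else { set[v] = a | b; ++len; }
      } else {  // Hartigan count rule
        int cnt[4] = {0, 0, 0, 0};
        for (int k = k0; k < k1; ++k) {
          int s = set[children[k]];
          for (int b = 0; b < 4; ++b) if (s & (1 << b)) ++cnt[b];
        }
        int mx = 0;
        for (int b = 0; b < 4; ++b) if (cnt[b] > mx) mx = cnt[b];
        int h = 0;
        for (int b = 0; b < 4; ++b) if (cnt[b] == mx) h |= (1 << b);
        set[v] = h;
        len += deg - mx;
      }
    }
    out[c] = len;
  }
  return out;
}

// Total parsimony length of an unrooted binary tree given as an undirected
// edge list (tip ids <= ntip index rows of `states`; internal ids arbitrary).
// The tree is rooted at its first tip for scoring; Fitch length is
// root-invariant.  Not every tip need be present (partial trees during
// stepwise addition).
// [[Rcpp::export]]
int score_uedge_cpp(IntegerMatrix uedge, int ntip, IntegerMatrix states) {
  const int nedge = uedge.nrow();
  const int nchar = states.ncol();
  int maxid = 0;
  int root_tip = 0;
  for (int i = 0; i < nedge; ++i) {
    for (int k = 0; k < 2; ++k) {
      int v = uedge(i, k);
      if (v > maxid) maxid = v;
      if (v <= ntip && (root_tip == 0 || v < root_tip)) root_tip = v;
    }
  }
  if (root_tip == 0) stop("tree contains no tips");
  // adjacency (each undirected edge appears twice)
  std::vector<int> deg(maxid + 1, 0);
  for (int i = 0; i < nedge; ++i) { deg[uedge(i, 0)]++; deg[uedge(i, 1)]++; }
  std::vector<int> off(maxid + 2, 0);
  for (int v = 1; v <= maxid; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> adj(2 * nedge);
  {
    std::vector<int> fill(maxid + 1, 0);
    for (int i = 0; i < nedge; ++i) {
      int a = uedge(i, 0), b = uedge(i, 1);
      adj[off[a] + fill[a]++] = b;
      adj[off[b] + fill[b]++] = a;
    }
  }
  // orient away from the root tip: DFS producing nodes in postorder
  std::vector<int> parent(maxid + 1, 0), order;
  order.reserve(maxid);
  {
    std::vector<int> stack;
    stack.push_back(root_tip);
    parent[root_tip] = -1;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      order.push_back(v);
      for (int k = off[v]; k < off[v + 1]; ++k) {
        int w = adj[k];
        if (w != parent[v]) { parent[w] = v; stack.push_back(w); }
      }
    }
    std::reverse(order.begin(), order.end());
  }
  std::vector<int> set(maxid + 1, 0);
  int total = 0;
  for (int c = 0; c < nchar; ++c) {
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int v = order[oi];
      if (v <= ntip) {
        set[v] = states(v - 1, c);
        continue;
      }
      int acc = 15;  // intersect children sequentially (binary below tip-1 root)
      bool first = true;
      for (int k = off[v]; k < off[v + 1]; ++k) {
        int w = adj[k];
        if (w == parent[v]) continue;
        if (first) { acc = set[w]; first = false; }
        else {
          int inter = acc & set[w];
          if (inter) acc = inter;
          else { acc |= set[w]; ++total; }
        }
      }
      set[v] = acc;
    }
    // pendant edge to the root tip acts as the root edge
    int child = adj[off[root_tip]];
    if (!(states(root_tip - 1, c) & set[child])) ++total;
  }
  return total;
}

// Batch variant: score many undirected edge lists against one matrix.
// [[Rcpp::export]]
IntegerVector score_uedge_many_cpp(List uedges, int ntip,
                                   IntegerMatrix states) {
  const int n = uedges.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = score_uedge_cpp(as<IntegerMatrix>(uedges[i]), ntip, states);
  return out;
}
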