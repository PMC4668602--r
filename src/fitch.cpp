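// Core parsimony engine: exact unordered-character (Fitch) optimization with
// state sets as bit masks, directional-set machinery for incremental TBR
// rescoring, stepwise addition, and topological constraint checking.
//
// Conventions shared with the R side:
//  * tips are 0..nTip-1 and correspond row-for-row to the mask matrix;
//  * internal nodes of an unrooted binary tree are nTip..2*nTip-3;
//  * ape edge matrices are 1-based with tips 1..nTip; c++ id = ape id - 1;
//  * a state-set mask is an int with bit k set iff state k (0..9) is allowed.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <set>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int MAXST = 10;
static const int BIG = 1 << 28;

// ---------------------------------------------------------------------------
// General scoring on an arbitrary (possibly multifurcating, rooted or
// unrooted-with-basal-polytomy) ape edge matrix.  Exact dynamic program with
// unit change costs: cost(node, s) = sum over children of
// min(cost(child, s), min_t cost(child, t) + 1).  Handles polytomies exactly.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_steps(IntegerMatrix edge, int nTip, IntegerMatrix masks) {
  int nEdge = edge.nrow();
  int nNode = 0;
  for (int i = 0; i < nEdge; ++i)
    nNode = std::max(nNode, std::max(edge(i, 0), edge(i, 1)));
  int nChar = masks.ncol();

  std::vector<std::vector<int>> children(nNode);
  std::vector<bool> isChild(nNode, false);
  for (int i = 0; i < nEdge; ++i) {
    children[edge(i, 0) - 1].push_back(edge(i, 1) - 1);
    isChild[edge(i, 1) - 1] = true;
  }
  int root = -1;
  for (int v = nTip; v < nNode; ++v)
    if (!children[v].empty() && !isChild[v]) { root = v; break; }
  if (root < 0) stop("edge matrix has no root");

  std::vector<int> order; order.reserve(nNode);
  std::vector<int> stack1; stack1.push_back(root);
  while (!stack1.empty()) {
    int v = stack1.back(); stack1.pop_back();
    order.push_back(v);
    for (int c : children[v]) stack1.push_back(c);
  }
  std::reverse(order.begin(), order.end());

  IntegerVector out(nChar);
  std::vector<std::array<int, MAXST>> cost(nNode);
  for (int ch = 0; ch < nChar; ++ch) {
    for (int v : order) {
      auto &cv = cost[v];
      if (v < nTip) {
        int mk = masks(v, ch);
        for (int s = 0; s < MAXST; ++s) cv[s] = (mk >> s & 1) ? 0 : BIG;
      } else {
        cv.fill(0);
        for (int c : children[v]) {
          auto &cc = cost[c];
          int mc = BIG;
          for (int s = 0; s < MAXST; ++s) mc = std::min(mc, cc[s]);
          for (int s = 0; s < MAXST; ++s)
            cv[s] += std::min(cc[s], mc + 1);
        }
      }
    }
    int best = BIG;
    for (int s = 0; s < MAXST; ++s) best = std::min(best, cost[root][s]);
    out[ch] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Unrooted binary tree structure used by the search.
// ---------------------------------------------------------------------------

struct UTree {
  int nTip = 0;
  std::vector<std::array<int, 3>> adj; // -1 padded; tips use slot 0

  int nNode() const { return 2 * nTip - 2; }

  void init(int n) {
    nTip = n;
    adj.assign(2 * n - 2, {-1, -1, -1});
  }
  void link(int a, int b) {
    for (int k = 0; k < 3; ++k) if (adj[a][k] == -1) { adj[a][k] = b; return; }
    stop("node degree overflow");
  }
  void addEdge(int a, int b) { link(a, b); link(b, a); }
  int degree(int a) const {
    int d = 0;
    for (int k = 0; k < 3; ++k) if (adj[a][k] != -1) ++d;
    return d;
  }
};

static UTree fromEdgeMatrix(IntegerMatrix edge, int nTip) {
  UTree t; t.init(nTip);
  if (edge.nrow() != 2 * nTip - 3) stop("tree is not an unrooted binary tree");
  for (int i = 0; i < edge.nrow(); ++i)
    t.addEdge(edge(i, 0) - 1, edge(i, 1) - 1);
  for (int v = nTip; v < t.nNode(); ++v)
    if (t.degree(v) != 3) stop("internal node of degree != 3");
  return t;
}

// Emit an ape-style edge matrix (basal trifurcation at the internal node
// adjacent to tip 0) with internal nodes renumbered in preorder.
static IntegerMatrix toEdgeMatrix(const UTree &t) {
  int n = t.nTip;
  IntegerMatrix edge(2 * n - 3, 2);
  std::vector<int> newId(t.nNode(), -1);
  int root = t.adj[0][0];
  int nextInternal = n + 1;
  int row = 0;
  std::vector<std::pair<int, int>> st; // (node, parent)
  newId[root] = nextInternal++;
  for (int k = 2; k >= 0; --k)
    if (t.adj[root][k] != -1) st.push_back({t.adj[root][k], root});
  while (!st.empty()) {
    auto pr = st.back(); st.pop_back();
    int v = pr.first, p = pr.second;
    newId[v] = (v < n) ? v + 1 : nextInternal++;
    edge(row, 0) = newId[p];
    edge(row, 1) = newId[v];
    ++row;
    for (int k = 2; k >= 0; --k) {
      int u = t.adj[v][k];
      if (u != -1 && u != p) st.push_back({u, v});
    }
  }
  return edge;
}

// [[Rcpp::export]]
IntegerMatrix cpp_canonical_edge(IntegerMatrix edge, int nTip) {
  return toEdgeMatrix(fromEdgeMatrix(edge, nTip));
}

// ---------------------------------------------------------------------------
// Bipartitions as tip bitsets; canonical side excludes tip 0.
// ---------------------------------------------------------------------------

typedef std::vector<uint64_t> Bits;

static void bitsSet(Bits &b, int i) { b[i >> 6] |= (uint64_t(1) << (i & 63)); }

static int bitsPop(const Bits &b) {
  int n = 0;
  for (uint64_t w : b) n += __builtin_popcountll(w);
  return n;
}

// sides (tip set of the block not containing tip 0) of all internal edges
static std::vector<Bits> edgeSides(const UTree &t) {
  int n = t.nTip, W = (n + 63) / 64;
  std::vector<Bits> below(t.nNode());
  std::vector<std::pair<int, int>> order;
  {
    std::vector<std::pair<int, int>> st;
    st.push_back({t.adj[0][0], 0});
    while (!st.empty()) {
      auto pr = st.back(); st.pop_back();
      order.push_back(pr);
      int v = pr.first;
      for (int k = 0; k < 3; ++k) {
        int u = t.adj[v][k];
        if (u != -1 && u != pr.second) st.push_back({u, v});
      }
    }
    std::reverse(order.begin(), order.end());
  }
  for (auto &pr : order) {
    int v = pr.first, p = pr.second;
    below[v].assign(W, 0);
    if (v < n) bitsSet(below[v], v);
    else {
      for (int k = 0; k < 3; ++k) {
        int u = t.adj[v][k];
        if (u != -1 && u != p)
          for (int w = 0; w < W; ++w) below[v][w] |= below[u][w];
      }
    }
  }
  std::vector<Bits> sides;
  for (auto &pr : order) {
    int v = pr.first, p = pr.second;
    if (v >= n && p >= n) sides.push_back(below[v]);
  }
  return sides;
}

static Bits topologyKey(const UTree &t) {
  auto sides = edgeSides(t);
  std::sort(sides.begin(), sides.end());
  Bits key;
  for (auto &s : sides) key.insert(key.end(), s.begin(), s.end());
  return key;
}

// Canonical topology key of an unrooted binary tree as a hex string (tip
// order of the edge matrix defines the bit positions).
// [[Rcpp::export]]
std::string cpp_topology_key(IntegerMatrix edge, int nTip) {
  Bits key = topologyKey(fromEdgeMatrix(edge, nTip));
  char buf[17];
  std::string out;
  out.reserve(16 * key.size());
  for (uint64_t w : key) {
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)w);
    out += buf;
    out += '.';
  }
  return out;
}

// ---------------------------------------------------------------------------
// Constraints.
// ---------------------------------------------------------------------------

struct Constraint {
  std::vector<Bits> pos;  // each must equal (side & scope) for some edge side
  Bits scope;             // union of taxa in positive groups
  std::vector<Bits> conv; // none may equal an exact edge side
  int W = 0;
  bool empty() const { return pos.empty() && conv.empty(); }
};

static bool satisfies(const UTree &t, const Constraint &C) {
  if (C.empty()) return true;
  int n = t.nTip, W = (n + 63) / 64;
  auto sides = edgeSides(t);
  Bits all(W, 0);
  for (int i = 0; i < n; ++i) bitsSet(all, i);
  std::vector<Bits> allSides;
  allSides.reserve(2 * sides.size() + 2 * n);
  for (auto &s : sides) {
    allSides.push_back(s);
    Bits c(W);
    for (int w = 0; w < W; ++w) c[w] = all[w] & ~s[w];
    allSides.push_back(c);
  }
  for (int i = 0; i < n; ++i) {
    Bits s(W, 0); bitsSet(s, i);
    allSides.push_back(s);
    Bits c(W);
    for (int w = 0; w < W; ++w) c[w] = all[w] & ~s[w];
    allSides.push_back(c);
  }
  int scopeSize = bitsPop(C.scope);
  for (auto &g : C.pos) {
    int gs = bitsPop(g);
    if (gs <= 1 || gs == scopeSize) continue; // vacuous
    bool found = false;
    for (auto &s : allSides) {
      bool eq = true;
      for (int w = 0; w < W; ++w)
        if ((s[w] & C.scope[w]) != g[w]) { eq = false; break; }
      if (eq) { found = true; break; }
    }
    if (!found) return false;
  }
  for (auto &g : C.conv) {
    for (auto &s : allSides) {
      bool eq = true;
      for (int w = 0; w < W; ++w) if (s[w] != g[w]) { eq = false; break; }
      if (eq) return false;
    }
  }
  return true;
}

static Constraint buildConstraint(List posGroups, IntegerVector scope,
                                  List convGroups, int nTip) {
  Constraint C;
  C.W = (nTip + 63) / 64;
  C.scope.assign(C.W, 0);
  if (scope.size() == 0) {
    for (int i = 0; i < nTip; ++i) bitsSet(C.scope, i);
  } else {
    for (int i = 0; i < scope.size(); ++i) bitsSet(C.scope, scope[i]);
  }
  for (int i = 0; i < posGroups.size(); ++i) {
    IntegerVector g = posGroups[i];
    Bits b(C.W, 0);
    for (int j = 0; j < g.size(); ++j) bitsSet(b, g[j]);
    C.pos.push_back(b);
  }
  for (int i = 0; i < convGroups.size(); ++i) {
    IntegerVector g = convGroups[i];
    Bits b(C.W, 0);
    for (int j = 0; j < g.size(); ++j) bitsSet(b, g[j]);
    C.conv.push_back(b);
  }
  return C;
}

// [[Rcpp::export]]
bool cpp_satisfies(IntegerMatrix edge, int nTip, List posGroups,
                   IntegerVector scope, List convGroups) {
  UTree t = fromEdgeMatrix(edge, nTip);
  Constraint C = buildConstraint(posGroups, scope, convGroups, nTip);
  return satisfies(t, C);
}

// ---------------------------------------------------------------------------
// Directional Fitch sets on an unrooted binary tree or fragment.
//
// V[x -> y] = downpass state set of the component containing x when edge
// (x, y) is cut, rooted at x.  Midpoint set of edge (u, v) =
// fitchCombine(V[u->v], V[v->u]).  The rooting-invariant fragment length L
// accumulates union events of the downpass plus the root combine.
// ---------------------------------------------------------------------------

struct FragViews {
  std::vector<std::pair<int, int>> edges; // (tip,tip) pseudo-edge if singleton
  std::vector<std::vector<uint16_t>> mid; // [edge][char]
  double L = 0.0;
  bool singleton = false;
};

static void fragmentViews(const std::vector<std::array<int, 3>> &adj,
                          const std::vector<int> &nodes, int nTip,
                          const IntegerMatrix &masks, const NumericVector &w,
                          FragViews &out) {
  int nChar = masks.ncol();
  out.edges.clear(); out.mid.clear(); out.L = 0.0; out.singleton = false;

  if (nodes.size() == 1) {
    int tipId = nodes[0];
    out.singleton = true;
    out.edges.push_back({tipId, tipId});
    out.mid.resize(1);
    out.mid[0].resize(nChar);
    for (int ch = 0; ch < nChar; ++ch) out.mid[0][ch] = (uint16_t)masks(tipId, ch);
    return;
  }

  int root = -1;
  for (int v : nodes) if (v < nTip) { root = v; break; }
  int rootChild = -1;
  for (int k = 0; k < 3; ++k)
    if (adj[root][k] != -1) { rootChild = adj[root][k]; break; }

  // preorder (node, parent) pairs from the root tip
  std::vector<std::pair<int, int>> order;
  {
    std::vector<std::pair<int, int>> st;
    st.push_back({rootChild, root});
    while (!st.empty()) {
      auto pr = st.back(); st.pop_back();
      order.push_back(pr);
      int v = pr.first;
      for (int k = 0; k < 3; ++k) {
        int u = adj[v][k];
        if (u != -1 && u != pr.second) st.push_back({u, v});
      }
    }
  }
  std::vector<std::pair<int, int>> post(order.rbegin(), order.rend());

  int N = (int)adj.size();
  std::vector<std::array<std::vector<uint16_t>, 3>> V(N);
  auto slotOf = [&](int x, int y) {
    for (int k = 0; k < 3; ++k) if (adj[x][k] == y) return k;
    stop("slotOf: edge missing");
    return -1;
  };

  // downpass: V[v -> parent]
  for (auto &pr : post) {
    int v = pr.first, p = pr.second;
    auto &out_v = V[v][slotOf(v, p)];
    out_v.resize(nChar);
    if (v < nTip) {
      for (int ch = 0; ch < nChar; ++ch) out_v[ch] = (uint16_t)masks(v, ch);
    } else {
      int c1 = -1, c2 = -1;
      for (int k = 0; k < 3; ++k) {
        int u = adj[v][k];
        if (u != -1 && u != p) { if (c1 == -1) c1 = u; else c2 = u; }
      }
      auto &a = V[c1][slotOf(c1, v)];
      auto &b = V[c2][slotOf(c2, v)];
      for (int ch = 0; ch < nChar; ++ch) {
        uint16_t is = a[ch] & b[ch];
        if (is) out_v[ch] = is;
        else { out_v[ch] = (uint16_t)(a[ch] | b[ch]); out.L += w[ch]; }
      }
    }
  }
  // root combine with the root tip's own mask
  {
    auto &b = V[rootChild][slotOf(rootChild, root)];
    for (int ch = 0; ch < nChar; ++ch)
      if (!((uint16_t)masks(root, ch) & b[ch])) out.L += w[ch];
    auto &rv = V[root][slotOf(root, rootChild)];
    rv.resize(nChar);
    for (int ch = 0; ch < nChar; ++ch) rv[ch] = (uint16_t)masks(root, ch);
  }
  // uppass in preorder: V[p -> v]
  std::vector<int> parent(N, -1);
  for (auto &pr : order) parent[pr.first] = pr.second;
  for (auto &pr : order) {
    int v = pr.first, p = pr.second;
    if (p == root) continue; // set above
    auto &out_pv = V[p][slotOf(p, v)];
    if (!out_pv.empty()) continue;
    out_pv.resize(nChar);
    int q = parent[p], s = -1;
    for (int k = 0; k < 3; ++k) {
      int u = adj[p][k];
      if (u != -1 && u != v && u != q) s = u;
    }
    auto &up = V[q][slotOf(q, p)];
    auto &sib = V[s][slotOf(s, p)];
    for (int ch = 0; ch < nChar; ++ch) {
      uint16_t is = up[ch] & sib[ch];
      out_pv[ch] = is ? is : (uint16_t)(up[ch] | sib[ch]);
    }
  }

  // midpoint sets per undirected edge
  for (auto &pr : order) out.edges.push_back({pr.second, pr.first});
  out.mid.resize(out.edges.size());
  for (size_t e = 0; e < out.edges.size(); ++e) {
    int p = out.edges[e].first, v = out.edges[e].second;
    auto &a = V[p][slotOf(p, v)];
    auto &b = V[v][slotOf(v, p)];
    out.mid[e].resize(nChar);
    for (int ch = 0; ch < nChar; ++ch) {
      uint16_t is = a[ch] & b[ch];
      out.mid[e][ch] = is ? is : (uint16_t)(a[ch] | b[ch]);
    }
  }
}

static double joinCost(const std::vector<uint16_t> &a, const std::vector<uint16_t> &b,
                       const NumericVector &w, double cap) {
  double c = 0.0;
  int nChar = (int)a.size();
  for (int ch = 0; ch < nChar; ++ch) {
    if (!(a[ch] & b[ch])) {
      c += w[ch];
      if (c > cap) return c;
    }
  }
  return c;
}

static double treeLen(const UTree &t, const IntegerMatrix &masks, const NumericVector &w) {
  std::vector<int> nodes;
  for (int v = 0; v < t.nNode(); ++v) nodes.push_back(v);
  FragViews fv;
  fragmentViews(t.adj, nodes, t.nTip, masks, w, fv);
  return fv.L;
}

// [[Rcpp::export]]
double cpp_tree_length_binary(IntegerMatrix edge, int nTip, IntegerMatrix masks,
                              NumericVector w) {
  UTree t = fromEdgeMatrix(edge, nTip);
  return treeLen(t, masks, w);
}

// ---------------------------------------------------------------------------
// TBR search with first-improvement hill climbing and an equal-length buffer.
// ---------------------------------------------------------------------------

struct Buffer {
  std::vector<UTree> trees;
  std::set<Bits> keys;
  double best = 0.0;
  bool add(const UTree &t) {
    Bits k = topologyKey(t);
    if (keys.count(k)) return false;
    keys.insert(k);
    trees.push_back(t);
    return true;
  }
  void reset(const UTree &t, double len) {
    trees.clear(); keys.clear();
    best = len;
    add(t);
  }
};

struct CutResult {
  std::vector<std::array<int, 3>> adj;
  std::vector<int> nodesA, nodesB;
  int juncA = -1, juncB = -1; // suppressed junction ids; -1 = lone-tip side
};

static void componentNodes(const std::vector<std::array<int, 3>> &adj, int start,
                           std::vector<int> &out) {
  out.clear();
  std::vector<int> st; st.push_back(start);
  std::vector<char> seen(adj.size(), 0);
  seen[start] = 1;
  while (!st.empty()) {
    int v = st.back(); st.pop_back();
    out.push_back(v);
    for (int k = 0; k < 3; ++k) {
      int u = adj[v][k];
      if (u != -1 && !seen[u]) { seen[u] = 1; st.push_back(u); }
    }
  }
}

static CutResult cutEdgeFull(const UTree &t, int a, int b) {
  CutResult R;
  R.adj = t.adj;
  auto unlink = [&](int x, int y) {
    for (int k = 0; k < 3; ++k) if (R.adj[x][k] == y) { R.adj[x][k] = -1; return; }
  };
  unlink(a, b); unlink(b, a);
  int startA = a, startB = b;
  auto suppress = [&](int x, int &start) -> int {
    int n1 = -1, n2 = -1;
    for (int k = 0; k < 3; ++k)
      if (R.adj[x][k] != -1) { if (n1 == -1) n1 = R.adj[x][k]; else n2 = R.adj[x][k]; }
    for (int k = 0; k < 3; ++k) {
      if (R.adj[n1][k] == x) R.adj[n1][k] = n2;
      if (R.adj[n2][k] == x) R.adj[n2][k] = n1;
    }
    R.adj[x] = {-1, -1, -1};
    start = n1;
    return x;
  };
  if (a >= t.nTip) R.juncA = suppress(a, startA);
  if (b >= t.nTip) R.juncB = suppress(b, startB);
  componentNodes(R.adj, startA, R.nodesA);
  componentNodes(R.adj, startB, R.nodesB);
  return R;
}

static UTree reconnect(const UTree &orig, const CutResult &R,
                       std::pair<int, int> eA, std::pair<int, int> eB) {
  UTree t = orig;
  t.adj = R.adj;
  auto attach = [&](std::pair<int, int> e, int junc) -> int {
    if (junc == -1) return e.first; // lone tip
    int u = e.first, v = e.second;
    for (int k = 0; k < 3; ++k) {
      if (t.adj[u][k] == v) t.adj[u][k] = junc;
      if (t.adj[v][k] == u) t.adj[v][k] = junc;
    }
    t.adj[junc] = {u, v, -1};
    return junc;
  };
  int attachA = attach(eA, R.juncA);
  int attachB = attach(eB, R.juncB);
  for (int k = 0; k < 3; ++k)
    if (t.adj[attachA][k] == -1) { t.adj[attachA][k] = attachB; break; }
  for (int k = 0; k < 3; ++k)
    if (t.adj[attachB][k] == -1) { t.adj[attachB][k] = attachA; break; }
  return t;
}

static std::vector<std::pair<int, int>> allEdges(const UTree &t) {
  std::vector<std::pair<int, int>> out;
  for (int v = 0; v < t.nNode(); ++v)
    for (int k = 0; k < 3; ++k) {
      int u = t.adj[v][k];
      if (u > v) out.push_back({v, u});
    }
  return out;
}

// One full TBR scan; returns true on a strict (constraint-satisfying)
// improvement, which resets the buffer.  Equal-length neighbors are
// collected into the buffer up to `hold`.
static bool tbrScan(const UTree &t, const IntegerMatrix &masks, const NumericVector &w,
                    Buffer &buf, int hold, const Constraint &C, double eps) {
  auto edges = allEdges(t);
  FragViews fvA, fvB;
  for (auto &e : edges) {
    CutResult R = cutEdgeFull(t, e.first, e.second);
    fragmentViews(R.adj, R.nodesA, t.nTip, masks, w, fvA);
    fragmentViews(R.adj, R.nodesB, t.nTip, masks, w, fvB);
    double base = fvA.L + fvB.L;
    double cap = buf.best - base + eps;
    if (cap < -eps) continue; // cannot even tie
    for (size_t i = 0; i < fvA.edges.size(); ++i) {
      for (size_t j = 0; j < fvB.edges.size(); ++j) {
        double jc = joinCost(fvA.mid[i], fvB.mid[j], w, cap);
        double len = base + jc;
        if (len < buf.best - eps) {
          UTree cand = reconnect(t, R, fvA.edges[i], fvB.edges[j]);
          if (satisfies(cand, C)) {
            buf.reset(cand, len);
            return true;
          }
        } else if (len < buf.best + eps && (int)buf.trees.size() < hold) {
          UTree cand = reconnect(t, R, fvA.edges[i], fvB.edges[j]);
          if (satisfies(cand, C)) buf.add(cand);
        }
      }
    }
  }
  return false;
}

static List bufferToR(const Buffer &buf) {
  List trees(buf.trees.size());
  for (size_t i = 0; i < buf.trees.size(); ++i)
    trees[i] = toEdgeMatrix(buf.trees[i]);
  return List::create(_["edges"] = trees, _["best_length"] = buf.best);
}

// [[Rcpp::export]]
List cpp_tbr(IntegerMatrix edge, int nTip, IntegerMatrix masks, NumericVector w,
             int hold, List posGroups, IntegerVector scope, List convGroups,
             int maxRounds) {
  UTree start = fromEdgeMatrix(edge, nTip);
  Constraint C = buildConstraint(posGroups, scope, convGroups, nTip);
  if (!satisfies(start, C)) stop("start tree violates constraints");
  const double eps = 1e-9;
  Buffer buf;
  buf.reset(start, treeLen(start, masks, w));
  int rounds = 0;
  size_t i = 0;
  while (i < buf.trees.size()) {
    if (++rounds > maxRounds) break;
    UTree cur = buf.trees[i]; // copy: buffer may be reset during the scan
    if (tbrScan(cur, masks, w, buf, hold, C, eps)) i = 0;
    else ++i;
    Rcpp::checkUserInterrupt();
  }
  return bufferToR(buf);
}

// ---------------------------------------------------------------------------
// Partial constraint check during stepwise addition: each positive group,
// restricted to the placed part of its scope, must be monophyletic (vacuous
// when of size <= 1 or equal to the placed scope).
// ---------------------------------------------------------------------------

static bool satisfiesPartial(const UTree &t, const Constraint &C,
                             const Bits &placed) {
  int n = t.nTip, W = (n + 63) / 64;
  // pick a placed tip as DFS root
  int rootTip = -1;
  for (int i = 0; i < n && rootTip < 0; ++i)
    if (placed[i >> 6] >> (i & 63) & 1) rootTip = i;

  std::vector<Bits> below(t.nNode());
  std::vector<std::pair<int, int>> order;
  {
    std::vector<std::pair<int, int>> st; st.push_back({t.adj[rootTip][0], rootTip});
    while (!st.empty()) {
      auto pr = st.back(); st.pop_back();
      order.push_back(pr);
      int v = pr.first;
      for (int k = 0; k < 3; ++k) {
        int u = t.adj[v][k];
        if (u != -1 && u != pr.second) st.push_back({u, v});
      }
    }
    std::reverse(order.begin(), order.end());
  }
  for (auto &pr : order) {
    int v = pr.first, p = pr.second;
    below[v].assign(W, 0);
    if (v < n) bitsSet(below[v], v);
    else
      for (int k = 0; k < 3; ++k) {
        int u = t.adj[v][k];
        if (u != -1 && u != p)
          for (int w2 = 0; w2 < W; ++w2) below[v][w2] |= below[u][w2];
      }
  }
  std::vector<Bits> sides;
  for (auto &pr : order) sides.push_back(below[pr.first]);
  { Bits s(W, 0); bitsSet(s, rootTip); sides.push_back(s); }
  size_t nS = sides.size();
  for (size_t i2 = 0; i2 < nS; ++i2) {
    Bits c(W);
    for (int w2 = 0; w2 < W; ++w2) c[w2] = placed[w2] & ~sides[i2][w2];
    sides.push_back(c);
  }

  for (auto &g : C.pos) {
    Bits gp(W), scp(W);
    int szg = 0, szs = 0;
    for (int w2 = 0; w2 < W; ++w2) {
      gp[w2] = g[w2] & placed[w2];
      scp[w2] = C.scope[w2] & placed[w2];
      szg += __builtin_popcountll(gp[w2]);
      szs += __builtin_popcountll(scp[w2]);
    }
    if (szg <= 1 || szg == szs) continue;
    bool found = false;
    for (auto &s : sides) {
      bool eq = true;
      for (int w2 = 0; w2 < W; ++w2)
        if ((s[w2] & scp[w2]) != gp[w2]) { eq = false; break; }
      if (eq) { found = true; break; }
    }
    if (!found) return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// Stepwise addition.  The caller supplies the (random) addition order; ties
// among equal-cost feasible attachment edges are broken with R's RNG.
// Converse constraints are not enforced here (repair happens in R).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_stepwise(IntegerMatrix masks, NumericVector w, IntegerVector order0,
                  List posGroups, IntegerVector scope) {
  int n = masks.nrow();
  if (n < 3) stop("need at least 3 taxa");
  Constraint C = buildConstraint(posGroups, scope, List::create(), n);
  int W = (n + 63) / 64;

  UTree t; t.init(n);
  int j0 = n;
  t.adj[j0] = {order0[0], order0[1], order0[2]};
  t.adj[order0[0]][0] = j0;
  t.adj[order0[1]][0] = j0;
  t.adj[order0[2]][0] = j0;

  std::vector<int> nodes = {order0[0], order0[1], order0[2], j0};
  Bits placed(W, 0);
  bitsSet(placed, order0[0]); bitsSet(placed, order0[1]); bitsSet(placed, order0[2]);

  FragViews fv;
  int nChar = masks.ncol();

  for (int k = 3; k < n; ++k) {
    int x = order0[k];
    fragmentViews(t.adj, nodes, n, masks, w, fv);
    int nE = (int)fv.edges.size();
    std::vector<double> cost(nE);
    for (int e = 0; e < nE; ++e) {
      double c = 0.0;
      for (int ch = 0; ch < nChar; ++ch)
        if (!(fv.mid[e][ch] & (uint16_t)masks(x, ch))) c += w[ch];
      cost[e] = c;
    }
    std::vector<double> levels(cost);
    std::sort(levels.begin(), levels.end());
    levels.erase(std::unique(levels.begin(), levels.end(),
                             [](double a, double b) { return std::abs(a - b) < 1e-9; }),
                 levels.end());
    int junc = n + k - 2;
    Bits placedNext = placed;
    bitsSet(placedNext, x);
    int chosen = -1;
    for (double lv : levels) {
      std::vector<int> feas;
      for (int e = 0; e < nE; ++e) {
        if (std::abs(cost[e] - lv) > 1e-9) continue;
        if (!C.pos.empty()) {
          int u = fv.edges[e].first, v = fv.edges[e].second;
          UTree tt = t;
          for (int q = 0; q < 3; ++q) {
            if (tt.adj[u][q] == v) tt.adj[u][q] = junc;
            if (tt.adj[v][q] == u) tt.adj[v][q] = junc;
          }
          tt.adj[junc] = {u, v, x};
          tt.adj[x][0] = junc;
          if (!satisfiesPartial(tt, C, placedNext)) continue;
        }
        feas.push_back(e);
      }
      if (!feas.empty()) {
        chosen = feas[(int)(unif_rand() * feas.size()) % feas.size()];
        break;
      }
    }
    if (chosen < 0) stop("constraints unsatisfiable during stepwise addition");
    int u = fv.edges[chosen].first, v = fv.edges[chosen].second;
    for (int q = 0; q < 3; ++q) {
      if (t.adj[u][q] == v) t.adj[u][q] = junc;
      if (t.adj[v][q] == u) t.adj[v][q] = junc;
    }
    t.adj[junc] = {u, v, x};
    t.adj[x][0] = junc;
    nodes.push_back(x);
    nodes.push_back(junc);
    placed = placedNext;
  }
  double L = treeLen(t, masks, w);
  return List::create(_["edge"] = toEdgeMatrix(t), _["length"] = L);
}

// ---------------------------------------------------------------------------
// Minimum attainable length of each queried internal edge over all
// most-parsimonious reconstructions (for the min-length-zero collapse rule).
// Exact via the directional-set formula around the edge: with the four
// components' downpass sets D_i, a state outside D_i costs that component
// exactly one extra step, so
//   minlen(c) = min_s [cntU(s) + cntV(s)] - min_{su,sv} [cntU(su) + cntV(sv)
//               + (su != sv)].
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_min_branch_lengths(IntegerMatrix edge, int nTip,
                                     IntegerMatrix masks, NumericVector w,
                                     IntegerMatrix internalEdges) {
  UTree t = fromEdgeMatrix(edge, nTip);
  int nChar = masks.ncol();

  NumericVector out(internalEdges.nrow());
  auto downSet = [&](int x, int y, std::vector<uint16_t> &S) {
    std::vector<std::pair<int, int>> order;
    std::vector<std::pair<int, int>> st; st.push_back({x, y});
    while (!st.empty()) {
      auto pr = st.back(); st.pop_back();
      order.push_back(pr);
      int a = pr.first;
      for (int k = 0; k < 3; ++k) {
        int bn = t.adj[a][k];
        if (bn != -1 && bn != pr.second) st.push_back({bn, a});
      }
    }
    std::reverse(order.begin(), order.end());
    std::vector<std::vector<uint16_t>> D(t.nNode());
    for (auto &pr : order) {
      int a = pr.first, p = pr.second;
      D[a].resize(nChar);
      if (a < nTip) {
        for (int ch = 0; ch < nChar; ++ch) D[a][ch] = (uint16_t)masks(a, ch);
      } else {
        int c1 = -1, c2 = -1;
        for (int k = 0; k < 3; ++k) {
          int bb = t.adj[a][k];
          if (bb != -1 && bb != p) { if (c1 == -1) c1 = bb; else c2 = bb; }
        }
        for (int ch = 0; ch < nChar; ++ch) {
          uint16_t is = D[c1][ch] & D[c2][ch];
          D[a][ch] = is ? is : (uint16_t)(D[c1][ch] | D[c2][ch]);
        }
      }
    }
    S = D[x];
  };

  for (int q = 0; q < internalEdges.nrow(); ++q) {
    int u = internalEdges(q, 0) - 1, v = internalEdges(q, 1) - 1;
    if (u < nTip || v < nTip) { out[q] = NA_REAL; continue; }
    int A[2], B[2], ai = 0, bi = 0;
    for (int k = 0; k < 3; ++k) {
      if (t.adj[u][k] != -1 && t.adj[u][k] != v) A[ai++] = t.adj[u][k];
      if (t.adj[v][k] != -1 && t.adj[v][k] != u) B[bi++] = t.adj[v][k];
    }
    std::vector<uint16_t> DA0, DA1, DB0, DB1;
    downSet(A[0], u, DA0);
    downSet(A[1], u, DA1);
    downSet(B[0], v, DB0);
    downSet(B[1], v, DB1);
    double minlen = 0.0;
    for (int ch = 0; ch < nChar; ++ch) {
      uint16_t a0 = DA0[ch], a1 = DA1[ch], b0 = DB0[ch], b1 = DB1[ch];
      int cntU[MAXST], cntV[MAXST];
      for (int s = 0; s < MAXST; ++s) {
        cntU[s] = ((a0 >> s & 1) ? 0 : 1) + ((a1 >> s & 1) ? 0 : 1);
        cntV[s] = ((b0 >> s & 1) ? 0 : 1) + ((b1 >> s & 1) ? 0 : 1);
      }
      int bestEq = BIG, bestNeq = BIG;
      for (int su = 0; su < MAXST; ++su)
        for (int sv = 0; sv < MAXST; ++sv) {
          int c = cntU[su] + cntV[sv];
          if (su == sv) bestEq = std::min(bestEq, c);
          else bestNeq = std::min(bestNeq, c);
        }
      int bestAny = std::min(bestEq, bestNeq + 1);
      minlen += w[ch] * (bestEq - bestAny);
    }
    out[q] = minlen;
  }
  return out;
}
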