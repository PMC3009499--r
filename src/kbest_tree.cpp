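// Memory-efficient k-best decoder.
//
// Maintains, online, a compressed tree of back pointers:
//  - path nodes: one per (position, state, rank) triple still reachable
//    from the current frontier; store parent pointer, owning state node,
//    partial log score, and a child counter;
//  - state nodes: group the <= k path nodes sharing (position, state) and,
//    after merging, a run of consecutive states traversed identically by
//    every surviving path through them.
// After each position the structure is pruned (path nodes unreachable from
// the new frontier are removed transitively) and compressed (a parent and
// child state node are merged whenever each is the other's unique
// partner).  Scores are computed by a heap-merge of the predecessors'
// sorted score lists, scaled by one log transition+emission factor per
// predecessor.  Exact score ties are broken by lexicographic comparison of
// the realized state-index sequences, matching the R reference engines.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <queue>
#include <deque>
#include <algorithm>
#include <limits>
#include <cmath>
#include <cstdio>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct PathNode {
  int parent;       // path-node id; -1 only for the root's own node
  int owner;        // state-node id
  double score;     // log probability of this partial path
  int child_count;
  bool live;
};

struct StateNode {
  std::vector<int> run;           // 1-based HMM state indices
  std::vector<int> paths;         // live path-node ids, rank order
  std::map<int, int> parent_edges; // parent state-node id -> path-level edge count
  std::map<int, int> child_edges;  // child state-node id  -> path-level edge count
  bool live;
};

struct Tree {
  std::vector<PathNode> pn;
  std::vector<StateNode> sn;
  std::vector<int> free_pn, free_sn;
  std::set<int> live_pn, live_sn;
  double merges = 0, prunes = 0;
  double peak_pn = 0, peak_sn = 0;

  int new_pn(int parent, int owner, double score) {
    int id;
    if (!free_pn.empty()) { id = free_pn.back(); free_pn.pop_back(); }
    else { id = (int)pn.size(); pn.push_back(PathNode()); }
    pn[id] = PathNode{parent, owner, score, 0, true};
    live_pn.insert(id);
    return id;
  }
  int new_sn() {
    int id;
    if (!free_sn.empty()) { id = free_sn.back(); free_sn.pop_back(); }
    else { id = (int)sn.size(); sn.push_back(StateNode()); }
    sn[id].run.clear(); sn[id].paths.clear();
    sn[id].parent_edges.clear(); sn[id].child_edges.clear();
    sn[id].live = true;
    live_sn.insert(id);
    return id;
  }
  void free_path(int id) {
    pn[id].live = false;
    live_pn.erase(id);
    free_pn.push_back(id);
  }
  void free_state(int id) {
    sn[id].live = false;
    live_sn.erase(id);
    free_sn.push_back(id);
  }
  void add_edge(int p, int c) {
    sn[c].parent_edges[p]++;
    sn[p].child_edges[c]++;
  }
  void remove_edge_one(int p, int c) {
    std::map<int,int>::iterator it = sn[c].parent_edges.find(p);
    if (it != sn[c].parent_edges.end() && --(it->second) == 0)
      sn[c].parent_edges.erase(it);
    it = sn[p].child_edges.find(c);
    if (it != sn[p].child_edges.end() && --(it->second) == 0)
      sn[p].child_edges.erase(it);
  }

  // full state sequence (1-based indices) of the partial path ending at pnid
  std::vector<int> reconstruct(int pnid) const {
    std::vector<int> out;
    for (int p = pnid; p != 0; p = pn[p].parent) {
      const std::vector<int>& r = sn[pn[p].owner].run;
      for (int t = (int)r.size() - 1; t >= 0; --t) out.push_back(r[t]);
    }
    std::reverse(out.begin(), out.end());
    return out;
  }
};

struct Cand { double score; int c; int r; };

// ---------------------------------------------------------------------------

static void audit_tree(const Tree& T,
                       const std::vector<std::vector<std::pair<double,int> > >& frontier,
                       int pos, int k, std::vector<std::string>& fail) {
  char buf[256];
  // 1. reachability from frontier equals the live path-node set
  std::set<int> reach;
  reach.insert(0);
  for (size_t v = 0; v < frontier.size(); ++v)
    for (size_t r = 0; r < frontier[v].size(); ++r)
      for (int p = frontier[v][r].second; p != -1; p = T.pn[p].parent) {
        if (!reach.insert(p).second) break;
      }
  if (reach != T.live_pn) {
    snprintf(buf, sizeof(buf),
             "position %d: reachable path nodes (%d) != live path nodes (%d)",
             pos, (int)reach.size(), (int)T.live_pn.size());
    fail.push_back(buf);
  }
  // 2. child counters
  std::map<int,int> cc;
  for (std::set<int>::const_iterator it = T.live_pn.begin(); it != T.live_pn.end(); ++it)
    if (*it != 0) cc[T.pn[*it].parent]++;
  for (std::set<int>::const_iterator it = T.live_pn.begin(); it != T.live_pn.end(); ++it) {
    int want = cc.count(*it) ? cc[*it] : 0;
    if (T.pn[*it].child_count != want) {
      snprintf(buf, sizeof(buf), "position %d: path node %d child_count %d, recount %d",
               pos, *it, T.pn[*it].child_count, want);
      fail.push_back(buf);
    }
  }
  // 3. state-node membership and edge maps recomputed from scratch
  std::map<std::pair<int,int>, int> edges;
  for (std::set<int>::const_iterator it = T.live_pn.begin(); it != T.live_pn.end(); ++it) {
    if (*it == 0) continue;
    const PathNode& q = T.pn[*it];
    if (!T.sn[q.owner].live) {
      snprintf(buf, sizeof(buf), "position %d: path node %d owned by dead state node", pos, *it);
      fail.push_back(buf);
    }
    edges[std::make_pair(T.pn[q.parent].owner, q.owner)]++;
  }
  for (std::set<int>::const_iterator it = T.live_sn.begin(); it != T.live_sn.end(); ++it) {
    const StateNode& S = T.sn[*it];
    if (*it != 0 && S.paths.empty()) {
      snprintf(buf, sizeof(buf), "position %d: state node %d live with no path nodes", pos, *it);
      fail.push_back(buf);
    }
    if ((int)S.paths.size() > k) {
      snprintf(buf, sizeof(buf), "position %d: state node %d holds %d > k path nodes",
               pos, *it, (int)S.paths.size());
      fail.push_back(buf);
    }
    for (size_t j = 0; j < S.paths.size(); ++j)
      if (!T.pn[S.paths[j]].live || T.pn[S.paths[j]].owner != *it) {
        snprintf(buf, sizeof(buf), "position %d: state node %d has stale path entry", pos, *it);
        fail.push_back(buf);
        break;
      }
    std::map<int,int> pe, ce;
    for (std::map<std::pair<int,int>,int>::const_iterator e = edges.begin(); e != edges.end(); ++e) {
      if (e->first.second == *it) pe[e->first.first] = e->second;
      if (e->first.first == *it) ce[e->first.second] = e->second;
    }
    if (pe != S.parent_edges || ce != S.child_edges) {
      snprintf(buf, sizeof(buf), "position %d: state node %d edge maps out of date", pos, *it);
      fail.push_back(buf);
    }
  }
  // 4. no mergeable pair remains (the root is virtual and never merged)
  for (std::set<int>::const_iterator it = T.live_sn.begin(); it != T.live_sn.end(); ++it) {
    if (*it == 0) continue;
    const StateNode& S = T.sn[*it];
    if (S.child_edges.size() == 1) {
      int v = S.child_edges.begin()->first;
      if (T.sn[v].parent_edges.size() == 1) {
        snprintf(buf, sizeof(buf), "position %d: mergeable pair (%d,%d) survived compression",
                 pos, *it, v);
        fail.push_back(buf);
      }
    }
  }
  // 5. every frontier path expands to exactly `pos` states
  for (size_t v = 0; v < frontier.size(); ++v)
    for (size_t r = 0; r < frontier[v].size(); ++r) {
      std::vector<int> sq = T.reconstruct(frontier[v][r].second);
      if ((int)sq.size() != pos) {
        snprintf(buf, sizeof(buf),
                 "position %d: frontier path for state %d rank %d has length %d",
                 pos, (int)v + 1, (int)r + 1, (int)sq.size());
        fail.push_back(buf);
      }
    }
}

// merge state nodes u (parent) and v (child); u absorbs v
static void merge_pair(Tree& T, int u, int v) {
  StateNode& U = T.sn[u];
  StateNode& V = T.sn[v];
  std::vector<int> old_parents;
  for (std::map<int,int>::const_iterator it = U.parent_edges.begin();
       it != U.parent_edges.end(); ++it)
    old_parents.push_back(it->first);
  // splice path-node chains: V's nodes skip over U's nodes
  for (size_t j = 0; j < V.paths.size(); ++j) {
    int q = V.paths[j];
    int upn = T.pn[q].parent;
    int gp = T.pn[upn].parent;
    T.pn[q].parent = gp;
    T.pn[gp].child_count++;
  }
  for (size_t j = 0; j < U.paths.size(); ++j) {
    int upn = U.paths[j];
    T.pn[T.pn[upn].parent].child_count--;
    T.free_path(upn);
  }
  // transfer child edges of V to u
  for (std::map<int,int>::const_iterator it = V.child_edges.begin();
       it != V.child_edges.end(); ++it) {
    T.sn[it->first].parent_edges.erase(v);
    T.sn[it->first].parent_edges[u] = it->second;
  }
  U.run.insert(U.run.end(), V.run.begin(), V.run.end());
  U.paths = V.paths;
  for (size_t j = 0; j < U.paths.size(); ++j) T.pn[U.paths[j]].owner = u;
  U.child_edges = V.child_edges;
  // rebuild u's parent edges from its (new) path nodes
  for (size_t t = 0; t < old_parents.size(); ++t)
    T.sn[old_parents[t]].child_edges.erase(u);
  U.parent_edges.clear();
  for (size_t j = 0; j < U.paths.size(); ++j)
    U.parent_edges[T.pn[T.pn[U.paths[j]].parent].owner]++;
  for (std::map<int,int>::const_iterator it = U.parent_edges.begin();
       it != U.parent_edges.end(); ++it)
    T.sn[it->first].child_edges[u] = it->second;
  T.free_state(v);
  T.merges += 1;
}

static void compress(Tree& T) {
  bool changed = true;
  while (changed) {
    changed = false;
    std::vector<int> ids(T.live_sn.begin(), T.live_sn.end());
    for (size_t t = 0; t < ids.size(); ++t) {
      int u = ids[t];
      if (u == 0 || !T.sn[u].live) continue;
      if (T.sn[u].child_edges.size() == 1) {
        int v = T.sn[u].child_edges.begin()->first;
        if (T.sn[v].parent_edges.size() == 1) {
          merge_pair(T, u, v);
          changed = true;
        }
      }
    }
  }
}

static void prune(Tree& T, const std::vector<int>& seeds) {
  std::deque<int> queue;
  for (size_t t = 0; t < seeds.size(); ++t) {
    int q = seeds[t];
    if (q != 0 && T.pn[q].live && T.pn[q].child_count == 0)
      queue.push_back(q);
  }
  while (!queue.empty()) {
    int q = queue.front(); queue.pop_front();
    if (!T.pn[q].live) continue;
    int ow = T.pn[q].owner;
    int par = T.pn[q].parent;
    std::vector<int>& pl = T.sn[ow].paths;
    pl.erase(std::remove(pl.begin(), pl.end(), q), pl.end());
    T.remove_edge_one(T.pn[par].owner, ow);
    if (--T.pn[par].child_count == 0 && par != 0)
      queue.push_back(par);
    T.free_path(q);
    T.prunes += 1;
    if (pl.empty()) T.free_state(ow);
  }
}

// [[Rcpp::export]]
List kbest_tree_cpp(int m, NumericMatrix lt, NumericMatrix le,
                    NumericVector lend, IntegerVector sym, int k,
                    bool audit, bool return_tree, bool complete_ties) {
  int n = sym.size();
  Tree T;
  std::vector<std::string> fail;

  // virtual root: state node 0 (empty run) holding path node 0
  int rs = T.new_sn();                 // id 0
  int rp = T.new_pn(-1, rs, 0.0);      // id 0
  T.sn[rs].paths.push_back(rp);

  // frontier[v]: sorted (score, path-node id) list for state v (0-based)
  std::vector<std::vector<std::pair<double,int> > > frontier(m);

  bool dead = false;
  for (int i = 1; i <= n && !dead; ++i) {
    int s = sym[i - 1] - 1;
    // ---- compute the k best scores per state (heap merge) ----------------
    std::vector<std::vector<double> > nsc(m);
    std::vector<std::vector<int> > nsrc(m);
    for (int v = 0; v < m; ++v) {
      double eb = le(v, s);
      if (eb == NEG_INF) continue;
      if (i == 1) {
        double f = lt(0, v) + eb;
        if (f != NEG_INF && !std::isnan(f)) {
          nsc[v].push_back(f);
          nsrc[v].push_back(0);
        }
        continue;
      }
      std::vector<double> fac(m, NEG_INF);
      bool any = false;
      for (int c = 0; c < m; ++c) {
        if (frontier[c].empty()) continue;
        double f = lt(c + 1, v) + eb;
        if (f == NEG_INF || std::isnan(f)) continue;
        fac[c] = f;
        any = true;
      }
      if (!any) continue;
      struct Cmp {
        const Tree* T;
        const std::vector<std::vector<std::pair<double,int> > >* fr;
        bool operator()(const Cand& a, const Cand& b) const {
          if (a.score != b.score) return a.score < b.score; // max-heap
          std::vector<int> qa = T->reconstruct((*fr)[a.c][a.r].second);
          std::vector<int> qb = T->reconstruct((*fr)[b.c][b.r].second);
          // a has lower priority if its sequence is lex-greater
          return std::lexicographical_compare(qb.begin(), qb.end(),
                                              qa.begin(), qa.end());
        }
      };
      Cmp cmp; cmp.T = &T; cmp.fr = &frontier;
      std::priority_queue<Cand, std::vector<Cand>, Cmp> heap(cmp);
      for (int c = 0; c < m; ++c)
        if (fac[c] != NEG_INF) {
          double sc = frontier[c][0].first + fac[c];
          if (sc != NEG_INF) heap.push(Cand{sc, c, 0});
        }
      // Pop past k through any exact tie with the k-th score: adding the
      // per-predecessor factor can collapse strictly ordered frontier
      // scores into an exact tie, leaving a tied run member hidden behind
      // its sibling in the heap, so the heap's emission order alone does
      // not settle ties. The tied group is lex-ordered below and then
      // truncated to k.
      while (!heap.empty() &&
             ((int)nsc[v].size() < k ||
              heap.top().score == nsc[v][k - 1])) {
        Cand top = heap.top(); heap.pop();
        nsc[v].push_back(top.score);
        nsrc[v].push_back(frontier[top.c][top.r].second);
        int r2 = top.r + 1;
        if (r2 < (int)frontier[top.c].size()) {
          double sc = frontier[top.c][r2].first + fac[top.c];
          if (sc != NEG_INF) heap.push(Cand{sc, top.c, r2});
        }
      }
      // restore the total order (score desc, lex asc) inside equal-score
      // groups, then truncate to k
      size_t g0 = 0;
      while (g0 < nsc[v].size()) {
        size_t g1 = g0 + 1;
        while (g1 < nsc[v].size() && nsc[v][g1] == nsc[v][g0]) ++g1;
        if (g1 - g0 > 1) {
          std::vector<std::pair<std::vector<int>, int> > grp;
          for (size_t t = g0; t < g1; ++t)
            grp.push_back(std::make_pair(T.reconstruct(nsrc[v][t]),
                                         nsrc[v][t]));
          std::sort(grp.begin(), grp.end());
          for (size_t t = g0; t < g1; ++t)
            nsrc[v][t] = grp[t - g0].second;
        }
        g0 = g1;
      }
      if ((int)nsc[v].size() > k) {
        nsc[v].resize(k);
        nsrc[v].resize(k);
      }
    }
    // ---- attach the new level --------------------------------------------
    std::vector<int> old_frontier;
    for (int v = 0; v < m; ++v)
      for (size_t r = 0; r < frontier[v].size(); ++r)
        old_frontier.push_back(frontier[v][r].second);
    if (i == 1) old_frontier.push_back(0); // root pn is the old frontier
    bool empty_level = true;
    std::vector<std::vector<std::pair<double,int> > > nf(m);
    for (int v = 0; v < m; ++v) {
      if (nsc[v].empty()) continue;
      empty_level = false;
      int sid = T.new_sn();
      T.sn[sid].run.push_back(v + 1);
      for (size_t r = 0; r < nsc[v].size(); ++r) {
        int src = nsrc[v][r];
        int pid = T.new_pn(src, sid, nsc[v][r]);
        T.pn[src].child_count++;
        T.add_edge(T.pn[src].owner, sid);
        T.sn[sid].paths.push_back(pid);
        nf[v].push_back(std::make_pair(nsc[v][r], pid));
      }
    }
    frontier.swap(nf);
    if (empty_level) { dead = true; }
    T.peak_pn = std::max(T.peak_pn, (double)T.live_pn.size());
    T.peak_sn = std::max(T.peak_sn, (double)T.live_sn.size());
    // ---- prune and compress ----------------------------------------------
    prune(T, old_frontier);
    compress(T);
    if (audit && !dead) {
      audit_tree(T, frontier, i, k, fail);
      if (!fail.empty()) break;
    }
  }

  List out;
  if (dead || !fail.empty()) {
    out["paths"] = List(0);
    out["scores"] = NumericVector(0);
  } else {
    // ---- recover the k best full paths (m-way merge at the leaves) -------
    std::vector<std::pair<double,int> > cands;
    for (int v = 0; v < m; ++v) {
      if (lend[v] == NEG_INF) continue;
      for (size_t r = 0; r < frontier[v].size(); ++r) {
        double sc = frontier[v][r].first + lend[v];
        if (sc != NEG_INF && !std::isnan(sc))
          cands.push_back(std::make_pair(sc, frontier[v][r].second));
      }
    }
    struct FinCmp {
      const Tree* T;
      bool operator()(const std::pair<double,int>& a,
                      const std::pair<double,int>& b) const {
        if (a.first != b.first) return a.first > b.first;
        std::vector<int> qa = T->reconstruct(a.second);
        std::vector<int> qb = T->reconstruct(b.second);
        return std::lexicographical_compare(qa.begin(), qa.end(),
                                            qb.begin(), qb.end());
      }
    };
    FinCmp fc; fc.T = &T;
    std::sort(cands.begin(), cands.end(), fc);
    int kk = std::min((int)cands.size(), k);
    // With an exact score tie at the cutoff, "the k best" is not a
    // well-defined selection; optionally return the whole boundary tie
    // class rather than splitting it arbitrarily.
    if (complete_ties && kk > 0) {
      double bound = cands[kk - 1].first;
      while (kk < (int)cands.size() && cands[kk].first == bound) ++kk;
    }
    List paths(kk);
    NumericVector scores(kk);
    for (int r = 0; r < kk; ++r) {
      std::vector<int> sq = T.reconstruct(cands[r].second);
      paths[r] = IntegerVector(sq.begin(), sq.end());
      scores[r] = cands[r].first;
    }
    out["paths"] = paths;
    out["scores"] = scores;
  }
  out["peak_path_nodes"] = T.peak_pn;
  out["peak_state_nodes"] = T.peak_sn;
  out["merges"] = T.merges;
  out["prunes"] = T.prunes;
  out["audit_failures"] = wrap(fail);
  if (return_tree) {
    List tl;
    std::vector<int> ids(T.live_sn.begin(), T.live_sn.end());
    for (size_t t = 0; t < ids.size(); ++t) {
      const StateNode& S = T.sn[ids[t]];
      std::vector<int> ch;
      for (std::map<int,int>::const_iterator it = S.child_edges.begin();
           it != S.child_edges.end(); ++it)
        ch.push_back(it->first);
      tl.push_back(List::create(
        _["id"] = ids[t],
        _["run"] = IntegerVector(S.run.begin(), S.run.end()),
        _["n_paths"] = (int)S.paths.size(),
        _["children"] = IntegerVector(ch.begin(), ch.end())));
    }
    out["tree"] = tl;
  }
  return out;
}
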