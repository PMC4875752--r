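#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Event codes: 0 codivergence, 1 duplication, 2 host switch, 3 leaf, -1 infeasible
static const double INF = std::numeric_limits<double>::infinity();
static const double EPS = 1e-9;

struct HTree {
  int nnode, root, log2n;
  std::vector<int> parent, left, right;  // -1 sentinel
  std::vector<int> rnk;                  // internal 1..n-1, leaves n
  std::vector<int> depth, tin, tout;
  std::vector<std::vector<int>> up;      // binary lifting

  void build(const IntegerVector& par, const IntegerVector& lf,
             const IntegerVector& rg, const IntegerVector& rk) {
    nnode = par.size();
    parent.resize(nnode); left.resize(nnode); right.resize(nnode); rnk.resize(nnode);
    root = -1;
    for (int i = 0; i < nnode; ++i) {
      parent[i] = par[i] - 1;           // 0 -> -1 (root)
      left[i] = lf[i] - 1; right[i] = rg[i] - 1;
      rnk[i] = rk[i];
      if (parent[i] < 0) root = i;
    }
    depth.assign(nnode, 0); tin.assign(nnode, 0); tout.assign(nnode, 0);
    // iterative DFS (preorder in/out stamps)
    int timer = 0;
    std::vector<std::pair<int,int>> stack; // node, state
    stack.push_back({root, 0});
    while (!stack.empty()) {
      auto& top = stack.back();
      int v = top.first;
      if (top.second == 0) {
        top.second = 1;
        tin[v] = timer++;
        if (left[v] >= 0) {
          depth[left[v]] = depth[v] + 1;
          depth[right[v]] = depth[v] + 1;
          stack.push_back({right[v], 0});
          stack.push_back({left[v], 0});
        }
      } else {
        tout[v] = timer++;
        stack.pop_back();
      }
    }
    log2n = 1; while ((1 << log2n) < nnode) ++log2n;
    up.assign(log2n + 1, std::vector<int>(nnode));
    for (int i = 0; i < nnode; ++i) up[0][i] = parent[i] < 0 ? i : parent[i];
    for (int k = 1; k <= log2n; ++k)
      for (int i = 0; i < nnode; ++i) up[k][i] = up[k-1][up[k-1][i]];
  }

  inline bool anc_or_eq(int u, int v) const {
    return tin[u] <= tin[v] && tout[v] <= tout[u];
  }
  inline bool comparable(int u, int v) const {
    return anc_or_eq(u, v) || anc_or_eq(v, u);
  }
  inline int open_rank(int v) const { return parent[v] < 0 ? 0 : rnk[parent[v]]; }
  // temporal overlap of the edges above v1 and above v2 (root gets a notional
  // stem opening at rank 0); open intervals, strict overlap
  inline bool coexist(int v1, int v2) const {
    return std::max(open_rank(v1), open_rank(v2)) <
           std::min(rnk[v1], rnk[v2]);
  }
  inline int dist(int anc, int desc) const { return depth[desc] - depth[anc]; }
  int kth_anc(int v, int k) const {
    for (int b = 0; k > 0; ++b, k >>= 1) if (k & 1) v = up[b][v];
    return v;
  }
  // child of h on the path toward strict descendant v
  inline int child_toward(int h, int v) const {
    return kth_anc(v, depth[v] - depth[h] - 1);
  }
  int lca(int u, int v) const {
    if (anc_or_eq(u, v)) return u;
    if (anc_or_eq(v, u)) return v;
    for (int k = log2n; k >= 0; --k)
      if (!anc_or_eq(up[k][u], v)) u = up[k][u];
    return parent[u];
  }
};

struct EventRes {
  int event;    // -1 infeasible
  int losses;
  int landing;  // host node where a switched lineage lands (-1 if n/a)
  int resident; // 1 = first child stays, 2 = second child stays (switch only)
  bool feasible;
};

// One placement semantics shared by the filtered solver and both oracles.
// h: placement of the parasite parent; h1, h2: placements of its children.
// A configuration with both children strictly below different children of h
// admits two explanations: a codivergence (each lineage tracks a daughter,
// costing C + L*(d1 - 1 + d2 - 1)) or an independent duplication at h
// followed by lineage sorting (D + L*(d1 + d2)); the cheaper one is
// reported, codivergence on ties. Under cost schemes with C <= D + 2L
// (e.g. the default) this is always the codivergence.
static EventRes classify(const HTree& H, int h, int h1, int h2,
                         double C, double D, double L) {
  bool d1 = H.anc_or_eq(h, h1), d2 = H.anc_or_eq(h, h2);
  if (d1 && d2) {
    if (h1 != h && h2 != h &&
        H.child_toward(h, h1) != H.child_toward(h, h2) &&
        C <= D + 2 * L + EPS) {
      return {0, (H.dist(h, h1) - 1) + (H.dist(h, h2) - 1), -1, 0, true};
    }
    return {1, H.dist(h, h1) + H.dist(h, h2), -1, 0, true};
  }
  if (d1 && !H.anc_or_eq(h2, h)) {       // second child switches
    int g = H.lca(h, h2);
    for (int a = h2; a != g; a = H.parent[a])
      if (H.coexist(h, a))               // lowest coexisting landing point
        return {2, H.dist(h, h1) + H.dist(a, h2), a, 1, true};
    return {-1, 0, -1, 0, false};
  }
  if (d2 && !H.anc_or_eq(h1, h)) {       // first child switches
    int g = H.lca(h, h1);
    for (int a = h1; a != g; a = H.parent[a])
      if (H.coexist(h, a))
        return {2, H.dist(h, h2) + H.dist(a, h1), a, 2, true};
    return {-1, 0, -1, 0, false};
  }
  return {-1, 0, -1, 0, false};
}

static HTree make_host(const IntegerVector& par, const IntegerVector& lf,
                       const IntegerVector& rg, const IntegerVector& rk) {
  HTree H; H.build(par, lf, rg, rk); return H;
}

// [[Rcpp::export(name = ".classify_event_cpp")]]
List classify_event_cpp(IntegerVector h_parent, IntegerVector h_left,
                        IntegerVector h_right, IntegerVector h_rank,
                        int h, int h1, int h2, NumericVector costs) {
  HTree H = make_host(h_parent, h_left, h_right, h_rank);
  EventRes e = classify(H, h - 1, h1 - 1, h2 - 1,
                        costs[0], costs[1], costs[3]);
  return List::create(_["event"] = e.event, _["losses"] = e.losses,
                      _["landing"] = e.landing + 1,
                      _["resident"] = e.resident,
                      _["feasible"] = e.feasible);
}

struct Site {
  int host;
  double cost;
  int event, losses;
  int li, ri;     // indices into the children's site lists (-1 for leaves)
  int landing;
};

// deterministic per-host minimum: lower cost, then lower event code, then
// lower losses
static void add_site(std::unordered_map<int, Site>& m, const Site& s) {
  auto it = m.find(s.host);
  if (it == m.end()) { m[s.host] = s; return; }
  Site& o = it->second;
  if (s.cost < o.cost - EPS) { o = s; return; }
  if (s.cost <= o.cost + EPS) {
    if (s.event < o.event || (s.event == o.event && s.losses < o.losses)) o = s;
  }
}

typedef std::vector<Site> SiteList;

// retained mapping sites for one internal parasite node
static SiteList node_sites(const HTree& H, const SiteList& SL,
                           const SiteList& SR, double C, double D,
                           double W, double L) {
  std::unordered_map<int, Site> cand;
  const double minCD = std::min(C, D), minDW = std::min(D, W);

  // (ii) codivergence-or-duplication sites: for every host that is a common
  // ancestor of a pair of child sites, price the cheapest such event there,
  // then retain the Pareto frontier under loss-priced descent — a candidate
  // at g is dominated when a kept candidate at a descendant-or-equal host g'
  // satisfies c' + L*dist(g, g') <= c (the deeper site then substitutes in
  // every later use of g's placement, the classifier repricing the event as
  // needed; a site exactly at an ancestor cannot serve a parent codivergence
  // at that ancestor, which is why cheapest-only retention would lose
  // optimality). Each child list is first propagated up the host tree as a
  // descent-priced minimum (cost + L per edge), the upward walk cut as soon
  // as it stops improving.
  {
    typedef std::unordered_map<int, std::pair<double, int>> UpMap;
    UpMap upL, upR;
    auto lift = [&H, L](const SiteList& S, UpMap& up) {
      for (size_t i = 0; i < S.size(); ++i) {
        double val = S[i].cost;
        for (int g = S[i].host; ; g = H.parent[g]) {
          auto it = up.find(g);
          if (it == up.end()) up[g] = {val, (int)i};
          else if (val < it->second.first - EPS) it->second = {val, (int)i};
          else break;                  // no improvement here or above
          if (H.parent[g] < 0) break;
          val += L;
        }
      }
    };
    lift(SL, upL);
    lift(SR, upR);
    const bool codiv_ok = C <= D + 2 * L + EPS;
    std::vector<Site> v;
    const UpMap& small = upL.size() <= upR.size() ? upL : upR;
    for (auto& kv : small) {
      int g = kv.first;
      auto itL = upL.find(g), itR = upR.find(g);
      if (itL == upL.end() || itR == upR.end()) continue;
      // duplication pricing at g (covers children at or anywhere below g)
      double best = D + itL->second.first + itR->second.first;
      int li = itL->second.second, ri = itR->second.second;
      if (codiv_ok && H.left[g] >= 0) {
        int x1 = H.left[g], x2 = H.right[g];
        auto a = upL.find(x1); auto b = upR.find(x2);
        if (a != upL.end() && b != upR.end()) {
          double c = C + a->second.first + b->second.first;
          if (c < best - EPS) { best = c; li = a->second.second;
                                ri = b->second.second; }
        }
        a = upL.find(x2); b = upR.find(x1);
        if (a != upL.end() && b != upR.end()) {
          double c = C + a->second.first + b->second.first;
          if (c < best - EPS) { best = c; li = a->second.second;
                                ri = b->second.second; }
        }
      }
      EventRes e = classify(H, g, SL[li].host, SR[ri].host, C, D, L);
      v.push_back(Site{g, best, e.event, e.losses, li, ri, -1});
    }
    std::sort(v.begin(), v.end(), [&H](const Site& a, const Site& b) {
      if (H.depth[a.host] != H.depth[b.host])
        return H.depth[a.host] > H.depth[b.host];   // deepest first
      return a.host < b.host;
    });
    std::vector<const Site*> kept;
    for (size_t k = 0; k < v.size(); ++k) {
      bool dominated = false;
      for (const Site* m : kept) {                  // survivors are deeper
        if (H.anc_or_eq(v[k].host, m->host) &&
            m->cost + L * H.dist(v[k].host, m->host) <= v[k].cost + EPS) {
          dominated = true;
          break;
        }
      }
      if (!dominated) { kept.push_back(&v[k]); add_site(cand, v[k]); }
    }
  }

  // (i) inherited sites: parent at one child's host, the other child reaches
  // its best feasible site by duplication-descent or host switch
  for (int dir = 0; dir < 2; ++dir) {
    const SiteList& A = dir == 0 ? SL : SR;   // resident child
    const SiteList& B = dir == 0 ? SR : SL;   // moving child
    for (size_t i = 0; i < A.size(); ++i) {
      double best = INF; Site b; bool found = false;
      for (size_t j = 0; j < B.size(); ++j) {
        double base = A[i].cost + B[j].cost;
        if (base + minDW > best + EPS) break;
        int h1 = dir == 0 ? A[i].host : B[j].host;
        int h2 = dir == 0 ? B[j].host : A[i].host;
        EventRes e = classify(H, A[i].host, h1, h2, C, D, L);
        if (!e.feasible) continue;
        double c = base + (e.event == 1 ? D : W) + L * e.losses;
        if (!found || c < best - EPS) {
          best = c;
          int li = dir == 0 ? (int)i : (int)j;
          int ri = dir == 0 ? (int)j : (int)i;
          b = {A[i].host, c, e.event, e.losses, li, ri, e.landing};
          found = true;
        }
      }
      if (found) add_site(cand, b);
    }
  }

  // (iii) the most recent feasible host switch in each direction: among
  // minimum-cost feasible switches maximise the take-off rank (most recent),
  // ties by lowest landing node id
  for (int dir = 0; dir < 2; ++dir) {
    const SiteList& A = dir == 0 ? SL : SR;   // resident child
    const SiteList& B = dir == 0 ? SR : SL;   // switching child
    double best = INF; Site b; bool found = false;
    for (size_t i = 0; i < A.size(); ++i) {
      for (int h = A[i].host; ; h = H.parent[h]) {
        double lift = L * H.dist(h, A[i].host);
        if (A[i].cost + B[0].cost + W + lift > best + EPS) break;
        for (size_t j = 0; j < B.size(); ++j) {
          double base = A[i].cost + B[j].cost + W + lift;
          if (base > best + EPS) break;
          if (H.comparable(h, B[j].host)) continue;
          int h1 = dir == 0 ? A[i].host : B[j].host;
          int h2 = dir == 0 ? B[j].host : A[i].host;
          EventRes e = classify(H, h, h1, h2, C, D, L);
          if (!e.feasible) continue;
          double c = A[i].cost + B[j].cost + W + L * e.losses;
          bool take = !found || c < best - EPS;
          if (!take && c <= best + EPS) {
            if (H.rnk[h] > H.rnk[b.host] ||
                (H.rnk[h] == H.rnk[b.host] && e.landing < b.landing))
              take = true;
          }
          if (take) {
            best = std::min(best, c);
            int li = dir == 0 ? (int)i : (int)j;
            int ri = dir == 0 ? (int)j : (int)i;
            b = {h, c, e.event, e.losses, li, ri, e.landing};
            found = true;
          }
        }
        if (H.parent[h] < 0) break;
      }
    }
    if (found) add_site(cand, b);
  }

  SiteList out; out.reserve(cand.size());
  for (auto& kv : cand) out.push_back(kv.second);
  std::sort(out.begin(), out.end(), [](const Site& a, const Site& b) {
    if (a.cost != b.cost) return a.cost < b.cost;
    return a.host < b.host;
  });
  return out;
}

static std::vector<int> postorder(const HTree& T) {
  std::vector<int> po; po.reserve(T.nnode);
  std::vector<int> stack; stack.push_back(T.root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    po.push_back(v);
    if (T.left[v] >= 0) { stack.push_back(T.left[v]); stack.push_back(T.right[v]); }
  }
  std::reverse(po.begin(), po.end());
  return po;
}

// [[Rcpp::export(name = ".solve_dtr_cpp")]]
List solve_dtr_cpp(IntegerVector h_parent, IntegerVector h_left,
                   IntegerVector h_right, IntegerVector h_rank,
                   IntegerVector p_parent, IntegerVector p_left,
                   IntegerVector p_right, IntegerVector phi,
                   NumericVector costs) {
  HTree H = make_host(h_parent, h_left, h_right, h_rank);
  IntegerVector prk(p_parent.size(), 1);
  HTree P; P.build(p_parent, p_left, p_right, prk);
  double C = costs[0], D = costs[1], W = costs[2], L = costs[3];

  std::vector<SiteList> tab(P.nnode);
  std::vector<int> po = postorder(P);
  for (int p : po) {
    if (P.left[p] < 0) {
      if (phi[p] <= 0) stop("parasite leaf without association");
      tab[p] = {Site{phi[p] - 1, 0.0, 3, 0, -1, -1, -1}};
    } else {
      tab[p] = node_sites(H, tab[P.left[p]], tab[P.right[p]], C, D, W, L);
      if (tab[p].empty()) stop("no feasible mapping site for a parasite node");
    }
  }

  // optimum at the parasite root: minimum cost, ties by lowest host id
  const SiteList& RS = tab[P.root];
  int besti = 0;
  for (size_t k = 1; k < RS.size(); ++k) {
    if (RS[k].cost < RS[besti].cost - EPS) besti = (int)k;
    else if (RS[k].cost <= RS[besti].cost + EPS && RS[k].host < RS[besti].host)
      besti = (int)k;
  }

  // traceback
  IntegerVector placement(P.nnode, NA_INTEGER), ev(P.nnode, NA_INTEGER),
      lo(P.nnode, 0);
  int alpha = 0, beta = 0, gamma = 0, delta = 0;
  std::vector<std::pair<int,int>> st; st.push_back({P.root, besti});
  while (!st.empty()) {
    int p = st.back().first, k = st.back().second; st.pop_back();
    const Site& s = tab[p][k];
    placement[p] = s.host + 1;
    ev[p] = s.event;
    lo[p] = s.losses;
    if (s.event == 0) ++alpha; else if (s.event == 1) ++beta;
    else if (s.event == 2) ++gamma;
    delta += s.losses;
    if (P.left[p] >= 0) {
      st.push_back({P.left[p], s.li});
      st.push_back({P.right[p], s.ri});
    }
  }

  // flatten the site table
  int tot = 0; for (auto& v : tab) tot += (int)v.size();
  IntegerVector t_p(tot), t_h(tot), t_e(tot), t_l(tot);
  NumericVector t_c(tot);
  int ix = 0;
  for (int p = 0; p < P.nnode; ++p)
    for (const Site& s : tab[p]) {
      t_p[ix] = p + 1; t_h[ix] = s.host + 1; t_e[ix] = s.event;
      t_l[ix] = s.losses; t_c[ix] = s.cost; ++ix;
    }

  return List::create(
      _["optimum"] = RS[besti].cost,
      _["placement"] = placement, _["event"] = ev, _["losses"] = lo,
      _["counts"] = IntegerVector::create(alpha, beta, gamma, delta),
      _["site_p"] = t_p, _["site_h"] = t_h, _["site_event"] = t_e,
      _["site_losses"] = t_l, _["site_cost"] = t_c);
}

// Unfiltered full-table dynamic programme: one cell per (parasite node,
// host node), minimising over every child-placement pair.
// [[Rcpp::export(name = ".full_table_cpp")]]
List full_table_cpp(IntegerVector h_parent, IntegerVector h_left,
                    IntegerVector h_right, IntegerVector h_rank,
                    IntegerVector p_parent, IntegerVector p_left,
                    IntegerVector p_right, IntegerVector phi,
                    NumericVector costs) {
  HTree H = make_host(h_parent, h_left, h_right, h_rank);
  IntegerVector prk(p_parent.size(), 1);
  HTree P; P.build(p_parent, p_left, p_right, prk);
  double C = costs[0], D = costs[1], W = costs[2], L = costs[3];
  int nh = H.nnode, np = P.nnode;
  NumericMatrix tabm(np, nh);
  std::fill(tabm.begin(), tabm.end(), INF);
  for (int p : postorder(P)) {
    if (P.left[p] < 0) {
      tabm(p, phi[p] - 1) = 0.0;
    } else {
      int l = P.left[p], r = P.right[p];
      for (int h = 0; h < nh; ++h) {
        double best = INF;
        for (int h1 = 0; h1 < nh; ++h1) {
          if (!std::isfinite(tabm(l, h1))) continue;
          for (int h2 = 0; h2 < nh; ++h2) {
            if (!std::isfinite(tabm(r, h2))) continue;
            EventRes e = classify(H, h, h1, h2, C, D, L);
            if (!e.feasible) continue;
            double evc = e.event == 0 ? C : (e.event == 1 ? D : W);
            double c = tabm(l, h1) + tabm(r, h2) + evc + L * e.losses;
            if (c < best) best = c;
          }
        }
        tabm(p, h) = best;
      }
    }
  }
  double opt = INF;
  int rp = P.root;
  for (int h = 0; h < nh; ++h) opt = std::min(opt, tabm(rp, h));
  int populated = 0;
  for (int i = 0; i < np * nh; ++i) if (std::isfinite(tabm[i])) ++populated;
  return List::create(_["optimum"] = opt, _["table"] = tabm,
                      _["populated"] = populated);
}

// Exhaustive enumeration over assignments of internal parasite nodes to
// host nodes (leaves fixed by phi); events are induced per node.
// [[Rcpp::export(name = ".brute_force_cpp")]]
double brute_force_cpp(IntegerVector h_parent, IntegerVector h_left,
                       IntegerVector h_right, IntegerVector h_rank,
                       IntegerVector p_parent, IntegerVector p_left,
                       IntegerVector p_right, IntegerVector phi,
                       NumericVector costs) {
  HTree H = make_host(h_parent, h_left, h_right, h_rank);
  IntegerVector prk(p_parent.size(), 1);
  HTree P; P.build(p_parent, p_left, p_right, prk);
  double C = costs[0], D = costs[1], W = costs[2], L = costs[3];
  int nh = H.nnode;
  std::vector<int> internals;
  for (int v : postorder(P)) if (P.left[v] >= 0) internals.push_back(v);
  int k = (int)internals.size();
  std::vector<int> sigma(P.nnode, -1);
  for (int v = 0; v < P.nnode; ++v) if (P.left[v] < 0) sigma[v] = phi[v] - 1;
  std::vector<int> odo(k, 0);
  double best = INF;
  bool done = k == 0;
  if (k == 0) return 0.0;
  while (!done) {
    for (int i = 0; i < k; ++i) sigma[internals[i]] = odo[i];
    double tot = 0.0; bool ok = true;
    for (int p : internals) {
      EventRes e = classify(H, sigma[p], sigma[P.left[p]],
                            sigma[P.right[p]], C, D, L);
      if (!e.feasible) { ok = false; break; }
      tot += (e.event == 0 ? C : (e.event == 1 ? D : W)) + L * e.losses;
      if (tot > best) { ok = false; break; }
    }
    if (ok && tot < best) best = tot;
    int i = 0;
    while (i < k && ++odo[i] == nh) { odo[i] = 0; ++i; }
    done = i == k;
  }
  return best;
}
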