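#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Coalescent machinery shared by the synthetic-data generator, the ABC
// demography engine and the fixed-S null distribution of Tajima's D.
//
// Conventions: time is measured backwards from the present in coalescent
// units of 2*N0 generations (N0 = present size).  Exponential growth at rate
// r (per coalescent unit) means N(t) = N0 * exp(-r t) looking backwards, so
// the pairwise coalescence rate at time t is C(k,2) * exp(r t).  For r < 0
// the ancestral population is capped at CAP_FACTOR times the present size so
// genealogies remain finite.

static const double CAP_FACTOR = 1000.0;

struct Genealogy {
  int n;                      // leaves
  std::vector<int> parent;    // 2n-1 nodes; root parent = -1
  std::vector<double> time;   // node times (leaves at 0)
  double tmrca;
};

// Waiting time to the next coalescence among k lineages starting at time s.
static double coal_wait(int k, double s, double r) {
  double C2 = k * (k - 1) / 2.0;
  double E = R::exp_rand();
  if (std::fabs(r) < 1e-12) return E / C2;
  if (r > 0.0) {
    // log1p form avoids overflow of exp(r*s) for strong growth
    return std::log1p(r * E * std::exp(-r * s) / C2) / r;
  }
  // r < 0: exponential shrinkage backwards until the cap, constant after
  double tcap = std::log(CAP_FACTOR) / (-r);
  if (s >= tcap) return E * CAP_FACTOR / C2;
  double E1 = (C2 / r) * (std::exp(r * tcap) - std::exp(r * s));
  if (E <= E1)
    return std::log(std::exp(r * s) + r * E / C2) / r - s;
  return (tcap - s) + (E - E1) * CAP_FACTOR / C2;
}

// Pick an unordered pair of distinct indices from idx, merge them into a new
// node, updating the genealogy in place.  Returns nothing; idx shrinks by 1.
static void merge_pair(std::vector<int>& idx, Genealogy& g, int& next_node,
                       double t) {
  int k = (int)idx.size();
  int a = (int)(R::unif_rand() * k); if (a == k) a = k - 1;
  int b = (int)(R::unif_rand() * (k - 1)); if (b == k - 1) b = k - 2;
  if (b >= a) b++;
  int u = idx[a], v = idx[b];
  g.parent[u] = next_node;
  g.parent[v] = next_node;
  g.time[next_node] = t;
  // replace position min(a,b) with the new node, remove the other
  int lo = std::min(a, b), hi = std::max(a, b);
  idx[lo] = next_node;
  idx.erase(idx.begin() + hi);
  next_node++;
}

// model: r != 0 or tau <= 0 -> single panmictic population with growth r;
// tau > 0 with 0 < n1 < n -> two constant-size demes merging at time tau.
static Genealogy sim_genealogy(int n, double r, double tau, int n1) {
  Genealogy g;
  g.n = n;
  int nnodes = 2 * n - 1;
  g.parent.assign(nnodes, -1);
  g.time.assign(nnodes, 0.0);
  std::vector<int> act;
  act.reserve(n);
  for (int i = 0; i < n; ++i) act.push_back(i);
  int next_node = n;
  double t = 0.0;
  bool structured = (tau > 0.0 && n1 > 0 && n1 < n);

  if (structured) {
    std::vector<int> a0, a1;
    for (int i = 0; i < n; ++i) (i < n1 ? a0 : a1).push_back(i);
    while (t < tau && (a0.size() > 1 || a1.size() > 1)) {
      double r0 = a0.size() * (a0.size() - 1) / 2.0;
      double r1 = a1.size() * (a1.size() - 1) / 2.0;
      double tot = r0 + r1;
      double w = R::exp_rand() / tot;
      if (t + w >= tau) break;
      t += w;
      if (R::unif_rand() * tot < r0)
        merge_pair(a0, g, next_node, t);
      else
        merge_pair(a1, g, next_node, t);
    }
    t = tau;
    act.clear();
    act.insert(act.end(), a0.begin(), a0.end());
    act.insert(act.end(), a1.begin(), a1.end());
    while (act.size() > 1) {
      int k = (int)act.size();
      t += R::exp_rand() / (k * (k - 1) / 2.0);
      merge_pair(act, g, next_node, t);
    }
  } else {
    while (act.size() > 1) {
      int k = (int)act.size();
      t += coal_wait(k, t, r);
      merge_pair(act, g, next_node, t);
    }
  }
  g.tmrca = t;
  return g;
}

struct Mutation {
  int site;
  int node;      // child end of the branch carrying the mutation
  double time;   // time of the event (between node and its parent)
  int offset;    // 0..2: new base = (current + 1 + offset) % 4
};

// cumulative branch lengths (branch v = edge above node v); returns TBL
static double branch_cumsum(const Genealogy& g, std::vector<double>& cum) {
  int nnodes = 2 * g.n - 1;
  cum.resize(nnodes - 1);
  double tbl = 0.0;
  for (int v = 0; v < nnodes - 1; ++v) {
    tbl += g.time[g.parent[v]] - g.time[v];
    cum[v] = tbl;
  }
  return tbl;
}

// nmut mutations placed on branches proportional to length, uniform columns
// (finite sites, Jukes-Cantor)
static std::vector<Mutation> place_mutations(const Genealogy& g, int L,
                                             int nmut,
                                             const std::vector<double>& cum,
                                             double tbl) {
  int nnodes = 2 * g.n - 1;
  std::vector<Mutation> muts(nmut);
  for (int m = 0; m < nmut; ++m) {
    double u = R::unif_rand() * tbl;
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (v >= nnodes - 1) v = nnodes - 2;
    Mutation mu;
    mu.node = v;
    mu.site = (int)(R::unif_rand() * L); if (mu.site == L) mu.site = L - 1;
    double blen = g.time[g.parent[v]] - g.time[v];
    mu.time = g.time[v] + R::unif_rand() * blen;
    mu.offset = (int)(R::unif_rand() * 3.0); if (mu.offset == 3) mu.offset = 2;
    muts[m] = mu;
  }
  return muts;
}

// Resolve leaf states at mutated columns.  Returns a (nhit x n) matrix of
// bases 0..3 together with the list of hit columns and their root bases.
struct HitStates {
  std::vector<int> sites;            // distinct mutated columns, sorted
  std::vector<int> root;             // root base per hit column
  std::vector<std::vector<int>> leaf; // [hit][leaf] base
};

static HitStates resolve_states(const Genealogy& g,
                                const std::vector<Mutation>& muts) {
  HitStates hs;
  int n = g.n, nnodes = 2 * n - 1;
  std::unordered_map<int, int> slot;
  for (const auto& m : muts) {
    if (!slot.count(m.site)) {
      slot[m.site] = (int)hs.sites.size();
      hs.sites.push_back(m.site);
    }
  }
  // keep column order deterministic
  std::vector<int> order(hs.sites.size());
  std::vector<int> sorted_sites = hs.sites;
  std::sort(sorted_sites.begin(), sorted_sites.end());
  std::unordered_map<int, int> newslot;
  for (size_t i = 0; i < sorted_sites.size(); ++i) newslot[sorted_sites[i]] = (int)i;
  hs.sites = sorted_sites;
  int nhit = (int)hs.sites.size();
  hs.root.resize(nhit);
  for (int i = 0; i < nhit; ++i) {
    int b = (int)(R::unif_rand() * 4.0); if (b == 4) b = 3;
    hs.root[i] = b;
  }
  hs.leaf.assign(nhit, std::vector<int>(n, 0));
  if (nhit == 0) return hs;

  // mutations grouped per branch (child node), applied parent -> child,
  // i.e. in order of decreasing event time
  std::vector<std::vector<int>> on_node(nnodes);
  for (size_t m = 0; m < muts.size(); ++m) on_node[muts[m].node].push_back((int)m);
  for (auto& v : on_node)
    std::sort(v.begin(), v.end(), [&](int a, int b) {
      return muts[a].time > muts[b].time;
    });

  std::vector<std::vector<int>> children(nnodes);
  for (int v = 0; v < nnodes - 1; ++v) children[g.parent[v]].push_back(v);
  int root_node = nnodes - 1;

  std::vector<int> state = hs.root;
  // iterative DFS with undo log
  struct Frame { int node; size_t child_i; size_t undo_mark; };
  std::vector<std::pair<int, int>> undo;  // (slot, previous base)
  std::vector<Frame> stack;
  auto enter = [&](int v) -> size_t {
    size_t mark = undo.size();
    for (int mi : on_node[v]) {
      int sl = newslot[muts[mi].site];
      undo.push_back({sl, state[sl]});
      state[sl] = (state[sl] + 1 + muts[mi].offset) % 4;
    }
    if (v < n)
      for (int i = 0; i < nhit; ++i) hs.leaf[i][v] = state[i];
    return mark;
  };
  stack.push_back({root_node, 0, 0});
  while (!stack.empty()) {
    Frame& f = stack.back();
    if (f.child_i == 0 && f.node != root_node) {
      // applied on push below; nothing here
    }
    if (f.child_i < children[f.node].size()) {
      int c = children[f.node][f.child_i++];
      size_t mark = enter(c);
      stack.push_back({c, 0, mark});
    } else {
      // unwind this node's mutations (root has none applied)
      if (f.node != root_node) {
        while (undo.size() > f.undo_mark) {
          state[undo.back().first] = undo.back().second;
          undo.pop_back();
        }
      }
      stack.pop_back();
    }
  }
  return hs;
}

// Per-column allele counts -> S, singleton sites, total/variance of pairwise
// differences, haplotype counts.  d is a reusable buffer of length n*(n-1)/2.
static void summarize_hits(const HitStates& hs, int n, std::vector<int>& d,
                           double out[7]) {
  int npairs = n * (n - 1) / 2;
  std::fill(d.begin(), d.begin() + npairs, 0);
  int S = 0, singletons = 0;
  std::vector<std::vector<int>> groups(4);
  for (size_t col = 0; col < hs.sites.size(); ++col) {
    for (int b = 0; b < 4; ++b) groups[b].clear();
    const std::vector<int>& st = hs.leaf[col];
    for (int i = 0; i < n; ++i) groups[st[i]].push_back(i);
    int nalleles = 0, major = -1, majorcount = -1;
    for (int b = 0; b < 4; ++b) {
      if (!groups[b].empty()) {
        nalleles++;
        if ((int)groups[b].size() > majorcount) {
          majorcount = (int)groups[b].size();
          major = b;
        }
      }
    }
    if (nalleles < 2) continue;
    S++;
    bool single = true;
    for (int b = 0; b < 4; ++b)
      if (b != major && !groups[b].empty() && groups[b].size() != 1) single = false;
    if (single) singletons++;
    for (int a = 0; a < 4; ++a) {
      if (groups[a].empty()) continue;
      for (int b = a + 1; b < 4; ++b) {
        if (groups[b].empty()) continue;
        for (int u : groups[a])
          for (int v : groups[b]) {
            int i = std::min(u, v), j = std::max(u, v);
            d[i * n - i * (i + 1) / 2 + (j - i - 1)]++;
          }
      }
    }
  }
  double tot = 0.0;
  for (int i = 0; i < npairs; ++i) tot += d[i];
  double kbar = tot / npairs;
  double var = 0.0;
  if (npairs > 1) {
    for (int i = 0; i < npairs; ++i) var += (d[i] - kbar) * (d[i] - kbar);
    var /= (npairs - 1);
  }
  out[0] = S;
  out[1] = kbar;
  out[2] = singletons;
  out[3] = var;
  out[4] = tot;
  // haplotype grouping: leaves i, j share a haplotype iff d[i][j] == 0
  std::vector<int> rep(n, -1);
  int nhap = 0, maxhap = 0;
  for (int i = 0; i < n; ++i) {
    if (rep[i] >= 0) continue;
    int cnt = 1;
    rep[i] = i;
    for (int j = i + 1; j < n; ++j) {
      if (rep[j] < 0 && d[i * n - i * (i + 1) / 2 + (j - i - 1)] == 0) {
        rep[j] = i;
        cnt++;
      }
    }
    nhap++;
    if (cnt > maxhap) maxhap = cnt;
  }
  out[5] = nhap;
  out[6] = maxhap;
}

// Tajima's D from n, S, kbar; NaN when undefined (S == 0 or n < 4)
static double tajima_d(int n, double S, double kbar) {
  if (S <= 0 || n < 4) return NA_REAL;
  double a1 = 0, a2 = 0;
  for (int i = 1; i <= n - 1; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  return (kbar - S / a1) / std::sqrt(e1 * S + e2 * S * (S - 1.0));
}

// [[Rcpp::export]]
List cpp_simulate(int n, int L, double theta, double r, double tau, int n1) {
  Genealogy g = sim_genealogy(n, r, tau, n1);
  std::vector<double> cum;
  double tbl = branch_cumsum(g, cum);
  int nmut = (int)R::rpois(theta / 2.0 * tbl);
  std::vector<Mutation> muts = place_mutations(g, L, nmut, cum, tbl);
  HitStates hs = resolve_states(g, muts);

  IntegerMatrix seq(n, L);
  for (int j = 0; j < L; ++j) {
    int b = (int)(R::unif_rand() * 4.0); if (b == 4) b = 3;
    for (int i = 0; i < n; ++i) seq(i, j) = b;
  }
  for (size_t col = 0; col < hs.sites.size(); ++col)
    for (int i = 0; i < n; ++i) seq(i, hs.sites[col]) = hs.leaf[col][i];

  int nnodes = 2 * n - 1;
  IntegerVector parent(nnodes);
  NumericVector ntime(nnodes);
  for (int v = 0; v < nnodes; ++v) {
    parent[v] = g.parent[v] < 0 ? NA_INTEGER : g.parent[v] + 1;  // 1-based
    ntime[v] = g.time[v];
  }
  int nm = (int)muts.size();
  IntegerVector msite(nm), mnode(nm);
  NumericVector mtime(nm);
  for (int m = 0; m < nm; ++m) {
    msite[m] = muts[m].site + 1;  // 1-based column
    mnode[m] = muts[m].node + 1;
    mtime[m] = muts[m].time;
  }
  return List::create(_["seq"] = seq, _["parent"] = parent,
                      _["node_time"] = ntime, _["tmrca"] = g.tmrca,
                      _["mut_site"] = msite, _["mut_node"] = mnode,
                      _["mut_time"] = mtime);
}

// Batched simulation returning summary statistics only:
// columns S, kbar, singletons, D, var_pairwise, tmrca.
// Draws whose Poisson mutation count exceeds mut_cap are abandoned (all-NA
// row): they saturate every column and cannot be close to any observed
// alignment of length L, so resolving their states is wasted work.
// [[Rcpp::export]]
NumericMatrix cpp_abc_sims(int n, int L, NumericVector theta, NumericVector r,
                           int mut_cap) {
  int nsims = theta.size();
  NumericMatrix out(nsims, 8);
  std::vector<int> d(n * (n - 1) / 2);
  double s[7];
  for (int i = 0; i < nsims; ++i) {
    Genealogy g = sim_genealogy(n, r[i], -1.0, 0);
    std::vector<double> cum;
    double tbl = branch_cumsum(g, cum);
    int nmut = (int)R::rpois(theta[i] / 2.0 * tbl);
    if (nmut > mut_cap) {
      for (int j = 0; j < 7; ++j) out(i, j) = NA_REAL;
      out(i, 7) = g.tmrca;
      continue;
    }
    std::vector<Mutation> muts = place_mutations(g, L, nmut, cum, tbl);
    HitStates hs = resolve_states(g, muts);
    summarize_hits(hs, n, d, s);
    out(i, 0) = s[0];
    out(i, 1) = s[1];
    out(i, 2) = s[2];
    out(i, 3) = tajima_d(n, s[0], s[1]);
    out(i, 4) = s[3];
    out(i, 5) = s[5];
    out(i, 6) = s[6];
    out(i, 7) = g.tmrca;
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Null distribution of Tajima's D conditional on the observed number of
// segregating sites: constant-size genealogies, S mutations placed on
// branches proportional to length, infinite-sites accounting.
// [[Rcpp::export]]
NumericVector cpp_fixed_s_D(int n, int S, int reps) {
  NumericVector out(reps);
  int nnodes = 2 * n - 1;
  double npairs = n * (n - 1) / 2.0;
  std::vector<double> cum(nnodes - 1);
  std::vector<int> nl(nnodes);
  for (int rep = 0; rep < reps; ++rep) {
    Genealogy g = sim_genealogy(n, 0.0, -1.0, 0);
    std::fill(nl.begin(), nl.end(), 0);
    for (int v = 0; v < n; ++v) nl[v] = 1;
    for (int v = 0; v < nnodes - 1; ++v) nl[g.parent[v]] += nl[v];  // children precede parents
    double tbl = 0.0;
    for (int v = 0; v < nnodes - 1; ++v) {
      tbl += g.time[g.parent[v]] - g.time[v];
      cum[v] = tbl;
    }
    double tot = 0.0;
    for (int m = 0; m < S; ++m) {
      double u = R::unif_rand() * tbl;
      int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (v >= nnodes - 1) v = nnodes - 2;
      tot += (double)nl[v] * (n - nl[v]);
    }
    out[rep] = tajima_d(n, S, tot / npairs);
    if (rep % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Hamming distance matrix over the columns of an integer-coded alignment
// (rows = sequences).  Any integer coding works; values compared exactly.
// [[Rcpp::export]]
IntegerMatrix cpp_pairwise_diff(IntegerMatrix m) {
  int n = m.nrow(), L = m.ncol();
  IntegerMatrix d(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int c = 0;
      for (int k = 0; k < L; ++k)
        if (m(i, k) != m(j, k)) c++;
      d(i, j) = c;
      d(j, i) = c;
    }
  return d;
}
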