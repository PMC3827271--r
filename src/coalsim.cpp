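// Continuous-time coalescent machinery for a two-population divergence
// model: plain genealogies (no recombination) and an ancestral
// recombination graph (ARG) with infinite-sites mutation.
//
// Conventions:
//  - time is measured in generations, increasing into the past from 0;
//  - a population of K effective chromosomes coalesces any particular
//    pair of lineages at rate 1/K per generation;
//  - tips 0..n1-1 belong to population 1 ("uar"), n1..n1+n2-1 to
//    population 2 ("uma"); the populations merge into an ancestral
//    population of size Kanc at time tdiv;
//  - all randomness comes from R's RNG so set.seed() governs results.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------
// Genealogy sampler (no recombination)
// ---------------------------------------------------------------------

// Samples a coalescent tree. Returns parent pointers (0-based, -1 at the
// root) and node times; nodes 0..n-1 are tips at time 0, internal nodes
// are appended in coalescence order, so node 2n-2 is the grand MRCA.
// [[Rcpp::export]]
List cpp_sim_tree(int n1, int n2, double K1, double K2, double Kanc,
                  double tdiv) {
  const int n = n1 + n2;
  if (n < 1) stop("need at least one sampled chromosome");
  const int n_nodes = 2 * n - 1;
  std::vector<int> parent(n_nodes, -1);
  std::vector<double> node_time(n_nodes, 0.0);

  std::vector<int> pop1, pop2;          // active lineage node ids
  for (int i = 0; i < n1; ++i) pop1.push_back(i);
  for (int i = 0; i < n2; ++i) pop2.push_back(n1 + i);

  double t = 0.0;
  bool merged = !R_finite(tdiv) ? false : (tdiv <= 0.0);
  if (merged) { // degenerate split time: single ancestral population
    for (size_t i = 0; i < pop2.size(); ++i) pop1.push_back(pop2[i]);
    pop2.clear();
  }
  int next_node = n;

  while ((int)(pop1.size() + pop2.size()) > 1) {
    double k1 = (double)pop1.size(), k2 = (double)pop2.size();
    double rate1, rate2;
    if (!merged) {
      rate1 = k1 * (k1 - 1.0) / 2.0 / K1;
      rate2 = k2 * (k2 - 1.0) / 2.0 / K2;
    } else {
      rate1 = k1 * (k1 - 1.0) / 2.0 / Kanc;
      rate2 = 0.0;
    }
    double total = rate1 + rate2;
    if (total <= 0.0) {
      if (merged) stop("internal: zero rate after merge");
      t = tdiv;
      for (size_t i = 0; i < pop2.size(); ++i) pop1.push_back(pop2[i]);
      pop2.clear();
      merged = true;
      continue;
    }
    double dt = R::exp_rand() / total;
    if (!merged && R_finite(tdiv) && t + dt > tdiv) {
      t = tdiv;
      for (size_t i = 0; i < pop2.size(); ++i) pop1.push_back(pop2[i]);
      pop2.clear();
      merged = true;
      continue;
    }
    t += dt;
    std::vector<int> &pop = (unif_rand() * total < rate1 || merged) ? pop1 : pop2;
    if (pop.size() < 2) { // numerical guard; pick the other population
      std::vector<int> &alt = (&pop == &pop1) ? pop2 : pop1;
      if (alt.size() < 2) stop("internal: no coalescible pair");
      int i = (int)(unif_rand() * alt.size());
      int j = (int)(unif_rand() * (alt.size() - 1)); if (j >= i) ++j;
      int a = alt[i], b = alt[j];
      parent[a] = next_node; parent[b] = next_node;
      node_time[next_node] = t;
      if (i < j) { alt.erase(alt.begin() + j); alt.erase(alt.begin() + i); }
      else       { alt.erase(alt.begin() + i); alt.erase(alt.begin() + j); }
      alt.push_back(next_node);
      ++next_node;
      continue;
    }
    int i = (int)(unif_rand() * pop.size());
    int j = (int)(unif_rand() * (pop.size() - 1)); if (j >= i) ++j;
    int a = pop[i], b = pop[j];
    parent[a] = next_node; parent[b] = next_node;
    node_time[next_node] = t;
    if (i < j) { pop.erase(pop.begin() + j); pop.erase(pop.begin() + i); }
    else       { pop.erase(pop.begin() + i); pop.erase(pop.begin() + j); }
    pop.push_back(next_node);
    ++next_node;
  }

  return List::create(_["parent"] = wrap(parent),
                      _["node_time"] = wrap(node_time),
                      _["n_tips"] = n,
                      _["tmrca"] = n > 1 ? node_time[n_nodes - 1] : 0.0);
}

// Leaf sets under every node of a tree given as parent pointers.
static std::vector< std::vector<int> > leaf_sets(const std::vector<int> &parent,
                                                 int n_tips) {
  int n_nodes = (int)parent.size();
  std::vector< std::vector<int> > ls(n_nodes);
  for (int i = 0; i < n_tips; ++i) ls[i].push_back(i);
  // parents are created in increasing index order, so a single pass works
  for (int v = 0; v < n_nodes; ++v) {
    int p = parent[v];
    if (p >= 0) {
      ls[p].insert(ls[p].end(), ls[v].begin(), ls[v].end());
    }
  }
  for (int v = n_tips; v < n_nodes; ++v) std::sort(ls[v].begin(), ls[v].end());
  return ls;
}

// Drops infinite-sites mutations on a genealogy. If s_fixed >= 0 exactly
// that many mutations are placed (multinomially by branch length),
// otherwise the count is Poisson(total branch length * mu_locus).
// Returns a 0/1 matrix (sites x tips) and uniform site positions in (0,1).
// [[Rcpp::export]]
List cpp_mutate_tree(IntegerVector parent_, NumericVector node_time_,
                     int n_tips, double mu_locus, int s_fixed) {
  std::vector<int> parent = as< std::vector<int> >(parent_);
  std::vector<double> node_time = as< std::vector<double> >(node_time_);
  int n_nodes = (int)parent.size();

  std::vector<double> blen(n_nodes, 0.0);
  double total = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] >= 0) {
      blen[v] = node_time[parent[v]] - node_time[v];
      total += blen[v];
    }
  }
  int S;
  if (s_fixed >= 0) S = s_fixed;
  else S = (total > 0.0 && mu_locus > 0.0) ? (int)R::rpois(total * mu_locus) : 0;
  if (S > 0 && total <= 0.0) stop("cannot place mutations on a zero-length tree");

  IntegerMatrix mat(S, n_tips);
  NumericVector pos(S);
  if (S == 0)
    return List::create(_["mat"] = mat, _["pos"] = pos);

  std::vector< std::vector<int> > ls = leaf_sets(parent, n_tips);
  std::vector<double> cum(n_nodes, 0.0);
  double acc = 0.0;
  for (int v = 0; v < n_nodes; ++v) { acc += blen[v]; cum[v] = acc; }

  for (int s = 0; s < S; ++s) {
    double u = unif_rand() * total;
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (v >= n_nodes) v = n_nodes - 1;
    for (size_t k = 0; k < ls[v].size(); ++k) mat(s, ls[v][k]) = 1;
    pos[s] = unif_rand();
  }
  return List::create(_["mat"] = mat, _["pos"] = pos);
}

// ---------------------------------------------------------------------
// ARG simulation with intra-locus recombination
// ---------------------------------------------------------------------

// Descendant-tip sets are bitmasks (MASK_WORDS x 64 tips max), making
// unions and MRCA checks O(1) words.
#define MASK_WORDS 4
struct Mask {
  uint64_t w[MASK_WORDS];
  Mask() { for (int i = 0; i < MASK_WORDS; ++i) w[i] = 0; }
  void set(int b) { w[b >> 6] |= (uint64_t)1 << (b & 63); }
  bool get(int b) const { return (w[b >> 6] >> (b & 63)) & 1; }
  Mask operator|(const Mask &o) const {
    Mask m;
    for (int i = 0; i < MASK_WORDS; ++i) m.w[i] = w[i] | o.w[i];
    return m;
  }
  bool operator==(const Mask &o) const {
    for (int i = 0; i < MASK_WORDS; ++i) if (w[i] != o.w[i]) return false;
    return true;
  }
};

struct Seg {
  double l, r;              // half-open interval on [0,1)
  Mask leaves;              // descendant tips
};

struct Lin {
  std::vector<Seg> segs;    // disjoint, sorted by l
  int pop;
  double material() const {
    double m = 0.0;
    for (size_t i = 0; i < segs.size(); ++i) m += segs[i].r - segs[i].l;
    return m;
  }
  double span() const {
    if (segs.empty()) return 0.0;
    return segs.back().r - segs.front().l;
  }
};

// Merges the ancestral material of two coalescing lineages; segments whose
// union covers all n tips have found their MRCA and are dropped (their
// completion time is the candidate grand TMRCA).
static Lin coalesce_lineages(const Lin &a, const Lin &b, const Mask &full,
                             double t, double &tmrca) {
  Lin out;
  out.pop = a.pop;
  std::vector<double> cuts;
  cuts.reserve(2 * (a.segs.size() + b.segs.size()));
  for (size_t i = 0; i < a.segs.size(); ++i) { cuts.push_back(a.segs[i].l); cuts.push_back(a.segs[i].r); }
  for (size_t i = 0; i < b.segs.size(); ++i) { cuts.push_back(b.segs[i].l); cuts.push_back(b.segs[i].r); }
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());

  size_t ia = 0, ib = 0;
  for (size_t c = 0; c + 1 < cuts.size(); ++c) {
    double l = cuts[c], r = cuts[c + 1];
    double mid = 0.5 * (l + r);
    while (ia < a.segs.size() && a.segs[ia].r <= mid) ++ia;
    while (ib < b.segs.size() && b.segs[ib].r <= mid) ++ib;
    const Mask *la = NULL, *lb = NULL;
    if (ia < a.segs.size() && a.segs[ia].l <= mid && mid < a.segs[ia].r) la = &a.segs[ia].leaves;
    if (ib < b.segs.size() && b.segs[ib].l <= mid && mid < b.segs[ib].r) lb = &b.segs[ib].leaves;
    if (!la && !lb) continue;
    Seg s; s.l = l; s.r = r;
    if (la && lb) s.leaves = *la | *lb;
    else s.leaves = la ? *la : *lb;
    if (s.leaves == full) {
      if (t > tmrca) tmrca = t;
      continue; // reached MRCA at these positions
    }
    if (!out.segs.empty() && out.segs.back().r == s.l &&
        out.segs.back().leaves == s.leaves) {
      out.segs.back().r = s.r; // glue identical neighbours
    } else {
      out.segs.push_back(s);
    }
  }
  return out;
}

// Simulates one locus under the divergence model with infinite-sites
// mutation (total rate mu_locus per lineage per generation spread over the
// locus) and crossover recombination (rate r_locus per lineage per
// generation, uniform breakpoints across the current ancestral span).
// Returns segregating sites as a 0/1 matrix (sites x tips, unsorted
// positions in (0,1)) plus the grand TMRCA over all positions.
// [[Rcpp::export]]
List cpp_sim_locus_arg(int n1, int n2, double K1, double K2, double Kanc,
                       double tdiv, double mu_locus, double r_locus) {
  const int n = n1 + n2;
  if (n < 1) stop("need at least one sampled chromosome");

  if (n > 64 * MASK_WORDS) stop("at most ", 64 * MASK_WORDS, " chromosomes supported");
  Mask full;
  for (int i = 0; i < n; ++i) full.set(i);

  std::vector<Lin> lins;
  for (int i = 0; i < n; ++i) {
    Lin L; L.pop = (i < n1) ? 0 : 1;
    Seg s; s.l = 0.0; s.r = 1.0; s.leaves.set(i);
    if (n > 1) L.segs.push_back(s); // n == 1: everything is already MRCA
    lins.push_back(L);
  }
  bool merged = R_finite(tdiv) ? (tdiv <= 0.0) : false;
  if (merged) for (size_t i = 0; i < lins.size(); ++i) lins[i].pop = 0;

  double t = 0.0, tmrca = 0.0;
  std::vector<double> site_pos;
  std::vector<Mask> site_leaves;

  while (true) {
    // prune finished lineages
    for (int i = (int)lins.size() - 1; i >= 0; --i)
      if (lins[i].segs.empty()) lins.erase(lins.begin() + i);
    if (lins.size() <= 1) break;

    int k1 = 0, k2 = 0;
    double mat_total = 0.0, span_total = 0.0;
    for (size_t i = 0; i < lins.size(); ++i) {
      if (lins[i].pop == 0) ++k1; else ++k2;
      mat_total += lins[i].material();
      span_total += lins[i].span();
    }
    double c1, c2;
    if (!merged) {
      c1 = k1 * (k1 - 1.0) / 2.0 / K1;
      c2 = k2 * (k2 - 1.0) / 2.0 / K2;
    } else {
      c1 = (double)lins.size() * (lins.size() - 1.0) / 2.0 / Kanc;
      c2 = 0.0;
    }
    double rmut = mu_locus * mat_total;
    double rrec = r_locus * span_total;
    double total = c1 + c2 + rmut + rrec;
    if (total <= 0.0) {
      if (merged) stop("internal: stalled ARG");
      t = tdiv;
      for (size_t i = 0; i < lins.size(); ++i) lins[i].pop = 0;
      merged = true;
      continue;
    }
    double dt = R::exp_rand() / total;
    if (!merged && R_finite(tdiv) && t + dt > tdiv) {
      t = tdiv;
      for (size_t i = 0; i < lins.size(); ++i) lins[i].pop = 0;
      merged = true;
      continue;
    }
    t += dt;
    double u = unif_rand() * total;

    if (u < rmut) { // mutation on ancestral material
      double target = unif_rand() * mat_total;
      double acc = 0.0;
      for (size_t i = 0; i < lins.size(); ++i) {
        for (size_t s = 0; s < lins[i].segs.size(); ++s) {
          double len = lins[i].segs[s].r - lins[i].segs[s].l;
          if (target < acc + len) {
            double x = lins[i].segs[s].l + (target - acc);
            site_pos.push_back(x);
            site_leaves.push_back(lins[i].segs[s].leaves);
            goto placed;
          }
          acc += len;
        }
      }
      placed: ;
    } else if (u < rmut + rrec) { // crossover
      double target = unif_rand() * span_total;
      double acc = 0.0;
      int idx = -1;
      double x = 0.0;
      for (size_t i = 0; i < lins.size(); ++i) {
        double sp = lins[i].span();
        if (target < acc + sp) {
          idx = (int)i;
          x = lins[i].segs.front().l + (target - acc);
          break;
        }
        acc += sp;
      }
      if (idx >= 0) {
        Lin &L = lins[idx];
        Lin left, right;
        left.pop = right.pop = L.pop;
        for (size_t s = 0; s < L.segs.size(); ++s) {
          const Seg &sg = L.segs[s];
          if (sg.r <= x) left.segs.push_back(sg);
          else if (sg.l >= x) right.segs.push_back(sg);
          else {
            Seg a = sg, b = sg;
            a.r = x; b.l = x;
            left.segs.push_back(a);
            right.segs.push_back(b);
          }
        }
        if (!left.segs.empty() && !right.segs.empty()) {
          lins[idx] = left;
          lins.push_back(right);
        }
      }
    } else { // coalescence
      bool in_pop1 = merged ? true : (u < rmut + rrec + c1);
      std::vector<int> cand;
      for (size_t i = 0; i < lins.size(); ++i)
        if (merged || lins[i].pop == (in_pop1 ? 0 : 1)) cand.push_back((int)i);
      if (cand.size() < 2) continue; // guard (rounding at rate boundaries)
      int i = (int)(unif_rand() * cand.size());
      int j = (int)(unif_rand() * (cand.size() - 1)); if (j >= i) ++j;
      int a = cand[i], b = cand[j];
      Lin m = coalesce_lineages(lins[a], lins[b], full, t, tmrca);
      if (a < b) { lins.erase(lins.begin() + b); lins.erase(lins.begin() + a); }
      else       { lins.erase(lins.begin() + a); lins.erase(lins.begin() + b); }
      lins.push_back(m);
    }
  }

  int S = (int)site_pos.size();
  IntegerMatrix mat(S, n);
  NumericVector pos(S);
  for (int s = 0; s < S; ++s) {
    pos[s] = site_pos[s];
    for (int k = 0; k < n; ++k)
      if (site_leaves[s].get(k)) mat(s, k) = 1;
  }
  return List::create(_["mat"] = mat, _["pos"] = pos, _["tmrca"] = tmrca);
}

// Time of the most recent common ancestor of a subset of tips (0-based
// ids) on a tree given as parent pointers and node times.
// [[Rcpp::export]]
double cpp_subset_tmrca(IntegerVector parent_, NumericVector node_time_,
                        IntegerVector tips) {
  std::vector<int> parent = as< std::vector<int> >(parent_);
  int n_nodes = (int)parent.size();
  if (tips.size() < 2) return 0.0;
  std::vector<int> count(n_nodes, 0);
  // climb from each tip, counting visits; the first node reached by all
  // tips (lowest index with full count on the ancestral path) is the MRCA
  for (int k = 0; k < tips.size(); ++k) {
    int v = tips[k];
    while (v >= 0) { ++count[v]; v = parent[v]; }
  }
  int m = (int)tips.size();
  for (int v = 0; v < n_nodes; ++v)
    if (count[v] == m) return node_time_[v];
  stop("tips do not share an ancestor");
}

// ---------------------------------------------------------------------
// Summary-statistic helper
// ---------------------------------------------------------------------

// Tallies distinct haplotypes (columns of a sites x chromosomes 0/1
// matrix) into a (n1+1) x (n2+1) table of (count among first n1 columns,
// count among the rest).
// [[Rcpp::export]]
IntegerMatrix cpp_hap_tally(IntegerMatrix mat, int n1) {
  int S = mat.nrow(), n = mat.ncol();
  int n2 = n - n1;
  std::map<std::vector<int>, std::pair<int,int> > tab;
  std::vector<int> key(S);
  for (int c = 0; c < n; ++c) {
    for (int s = 0; s < S; ++s) key[s] = mat(s, c);
    std::pair<int,int> &e = tab[key];
    if (c < n1) ++e.first; else ++e.second;
  }
  IntegerMatrix out(n1 + 1, n2 + 1);
  for (std::map<std::vector<int>, std::pair<int,int> >::iterator it = tab.begin();
       it != tab.end(); ++it)
    ++out(it->second.first, it->second.second);
  return out;
}
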