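#include <Rcpp.h>
#include <algorithm>
#include <cstdio>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Genome-space block mapping against one isoform's segment table.
// Segments are exons (plus an optional virtual poly(A) segment) in ascending
// genome order with positive gaps; cum[j] = transcript bases (in ascending
// genome order) preceding segment j.  Blocks map iff each lies inside one
// segment and consecutive blocks jump exactly across one full gap.
// ---------------------------------------------------------------------------
static bool map_blocks(const int* seg_s, const int* seg_e, const double* cum,
                       int nseg, const int* b_s, const int* b_e, int nb,
                       double L, int strand, double& t0, double& t1) {
  // last segment with start <= first block start
  int j = int(std::upper_bound(seg_s, seg_s + nseg, b_s[0]) - seg_s) - 1;
  if (j < 0) return false;
  if (b_e[0] > seg_e[j]) return false;
  double o_first = cum[j] + (b_s[0] - seg_s[j]);
  double o_last = 0.0;
  int cur = j;
  for (int b = 0; b < nb; ++b) {
    if (b > 0) {
      if (b_e[b - 1] != seg_e[cur]) return false;
      ++cur;
      if (cur >= nseg || b_s[b] != seg_s[cur]) return false;
    }
    if (b_s[b] < seg_s[cur] || b_e[b] > seg_e[cur]) return false;
    o_last = cum[cur] + (b_e[b] - 1 - seg_s[cur]);
  }
  if (strand > 0) { t0 = o_first; t1 = o_last + 1; }
  else           { t0 = L - 1 - o_last; t1 = L - o_first; }
  return true;
}

static inline double cdf_at(double u, int kmin, const NumericVector& cdf) {
  if (u < kmin) return 0.0;
  int idx = int(u) - kmin;
  if (idx >= cdf.size()) return 1.0;
  return cdf[idx];
}

static inline double pmf_at(double k, int kmin, const NumericVector& pmf) {
  if (k < kmin) return 0.0;
  int idx = int(k) - kmin;
  if (idx >= pmf.size()) return 0.0;
  return pmf[idx];
}

// Line sweep over one chromosome.  Alignments sorted by span start, isoforms
// sorted by (segment-)span start.  For each alignment, all isoforms whose
// span has opened and not yet closed are candidates; weight contributions
// Q_a * F_a * O_a are accumulated per (read, isoform).
// [[Rcpp::export]]
List cpp_sweep_weights(IntegerVector aln_read, NumericVector aln_qa,
                       IntegerVector aln_start, IntegerVector aln_end,
                       IntegerVector aln_strand, IntegerVector aln_strand2,
                       LogicalVector aln_paired,
                       IntegerVector blk_start, IntegerVector blk_end,
                       IntegerVector blk_mate, IntegerVector blk_off,
                       IntegerVector iso_idx, IntegerVector iso_span_start,
                       IntegerVector iso_span_end, IntegerVector iso_strand,
                       NumericVector iso_L,
                       IntegerVector seg_start, IntegerVector seg_end,
                       NumericVector seg_cum, IntegerVector seg_off,
                       int kmin, NumericVector pmf, NumericVector cdf,
                       bool directional) {
  int nA = aln_read.size(), nI = iso_idx.size();
  std::unordered_map<uint64_t, double> acc;
  acc.reserve(size_t(nA) * 2);
  std::vector<int> active;
  int ip = 0;
  for (int i = 0; i < nA; ++i) {
    int as = aln_start[i], ae = aln_end[i];
    while (ip < nI && iso_span_start[ip] <= as) active.push_back(ip++);
    // prune closed isoforms
    size_t keep = 0;
    for (size_t t = 0; t < active.size(); ++t)
      if (iso_span_end[active[t]] > as) active[keep++] = active[t];
    active.resize(keep);

    // mate block ranges within this alignment
    int b0 = blk_off[i], b1 = blk_off[i + 1];
    int split = b0;
    while (split < b1 && blk_mate[split] == 1) ++split;

    for (size_t t = 0; t < active.size(); ++t) {
      int j = active[t];
      if (iso_span_end[j] < ae) continue;
      int g = iso_idx[j];  // 1-based global transcript index
      const int* sS = &seg_start[0] + seg_off[g - 1];
      const int* sE = &seg_end[0] + seg_off[g - 1];
      const double* sC = &seg_cum[0] + seg_off[g - 1];
      int nseg = seg_off[g] - seg_off[g - 1];
      double L = iso_L[j];
      double t0a, t1a;
      if (!map_blocks(sS, sE, sC, nseg, &blk_start[0] + b0, &blk_end[0] + b0,
                      split - b0, L, iso_strand[j], t0a, t1a))
        continue;
      double w = 0.0;
      if (!aln_paired[i]) {
        bool sense = aln_strand[i] == iso_strand[j];
        if (directional && !sense) continue;
        double u = sense ? (L - t0a) : t1a;
        double F = cdf_at(u, kmin, cdf);
        w = aln_qa[i] * F;
      } else {
        if (split == b1) continue;  // missing mate blocks
        double t0b, t1b;
        if (!map_blocks(sS, sE, sC, nseg, &blk_start[0] + split,
                        &blk_end[0] + split, b1 - split, L, iso_strand[j],
                        t0b, t1b))
          continue;
        if (aln_strand[i] == aln_strand2[i]) continue;  // same-strand mates
        // leftmost mate (transcript coords) must be sense: pairs point to
        // each other along the transcript
        bool m1_left = t0a <= t0b;
        int left_strand = m1_left ? aln_strand[i] : aln_strand2[i];
        if (left_strand != iso_strand[j]) continue;
        if (directional && aln_strand[i] != iso_strand[j]) continue;
        double k = std::max(t1a, t1b) - std::min(t0a, t0b);
        double F = pmf_at(k, kmin, pmf);
        w = aln_qa[i] * F;
      }
      if (w > 0.0)
        acc[(uint64_t(aln_read[i]) << 32) | uint64_t(g)] += w;
    }
  }
  std::vector<uint64_t> keys;
  keys.reserve(acc.size());
  for (auto& kv : acc) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  int n = keys.size();
  IntegerVector out_read(n), out_iso(n);
  NumericVector out_w(n);
  for (int i = 0; i < n; ++i) {
    out_read[i] = int(keys[i] >> 32);
    out_iso[i] = int(keys[i] & 0xffffffffu);
    out_w[i] = acc[keys[i]];
  }
  return List::create(_["read"] = out_read, _["tx"] = out_iso,
                      _["w"] = out_w);
}

// ---------------------------------------------------------------------------
// Online union-find over the read-isoform compatibility graph with read
// class collapsing.  Trees are united by height (no path compression while
// reads are being added); each read class is stored in a hash table at the
// LCA of its isoforms' nodes, so duplicate classes are always found there.
// ---------------------------------------------------------------------------
struct RClass {
  double m;
  std::vector<int> iso;  // global 1-based transcript indices, sorted
  std::vector<double> w; // max-normalized weights
};

struct Forest {
  std::vector<int> parent, height, node_iso, stamp;
  std::unordered_map<int, int> iso2node;
  std::vector<std::unordered_map<std::string, int> > tabs;
  std::vector<RClass> classes;
  std::vector<int> class_node;
  double total_m = 0.0;
  long n_reads = 0, n_merged = 0;
  int epoch = 0;

  int get_node(int iso) {
    auto it = iso2node.find(iso);
    if (it != iso2node.end()) return it->second;
    int id = parent.size();
    parent.push_back(id);
    height.push_back(0);
    node_iso.push_back(iso);
    stamp.push_back(0);
    tabs.push_back(std::unordered_map<std::string, int>());
    iso2node[iso] = id;
    return id;
  }
  int find(int x) const {          // no path compression
    while (parent[x] != x) x = parent[x];
    return x;
  }
  // LCA of two nodes in the same tree, via root-path marking
  int lca2(int a, int b) {
    ++epoch;
    int x = a;
    while (true) { stamp[x] = epoch; if (parent[x] == x) break; x = parent[x]; }
    int y = b;
    while (stamp[y] != epoch) y = parent[y];
    return y;
  }
};

static std::string class_signature(const std::vector<int>& iso,
                                   const std::vector<double>& w) {
  double wmax = 0.0;
  for (double v : w) if (v > wmax) wmax = v;
  char buf[40];
  std::string sig;
  sig.reserve(iso.size() * 24);
  for (size_t i = 0; i < iso.size(); ++i) {
    std::snprintf(buf, sizeof(buf), "%d:%.8e;", iso[i], w[i] / wmax);
    sig += buf;
  }
  return sig;
}

static void forest_add(Forest& F, std::vector<int> iso, std::vector<double> w,
                       double bw, bool collapse) {
  // sort entries by isoform id
  std::vector<size_t> ord(iso.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return iso[a] < iso[b]; });
  std::vector<int> si(iso.size());
  std::vector<double> sw(w.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    si[i] = iso[ord[i]];
    sw[i] = w[ord[i]];
  }
  F.n_reads++;
  F.total_m += bw;
  std::vector<int> nodes(si.size());
  for (size_t i = 0; i < si.size(); ++i) nodes[i] = F.get_node(si[i]);
  std::vector<int> roots;
  for (int nd : nodes) {
    int r = F.find(nd);
    bool seen = false;
    for (int rr : roots) if (rr == r) { seen = true; break; }
    if (!seen) roots.push_back(r);
  }
  int home;
  if (roots.size() > 1) {
    // unite all trees; taller root wins, ties broken towards the root whose
    // isoform id is smaller (height then grows by one)
    int win = roots[0];
    for (size_t i = 1; i < roots.size(); ++i) {
      int r = roots[i];
      if (F.height[r] > F.height[win]) {
        F.parent[win] = r;
        win = r;
      } else if (F.height[r] < F.height[win]) {
        F.parent[r] = win;
      } else {
        if (F.node_iso[r] < F.node_iso[win]) std::swap(r, win);
        F.parent[r] = win;
        F.height[win]++;
      }
    }
    home = win;  // new tree root is (trivially) the LCA
  } else {
    home = nodes[0];
    for (size_t i = 1; i < nodes.size(); ++i) home = F.lca2(home, nodes[i]);
  }
  std::string sig = class_signature(si, sw);
  if (!collapse) {
    char buf[24];
    std::snprintf(buf, sizeof(buf), "#%ld", F.n_reads);
    sig += buf;
  }
  auto& tab = F.tabs[home];
  auto it = tab.find(sig);
  if (it != tab.end()) {
    F.classes[it->second].m += bw;
    F.n_merged++;
  } else {
    RClass rc;
    rc.m = bw;
    double wmax = *std::max_element(sw.begin(), sw.end());
    for (double& v : sw) v /= wmax;
    rc.iso = si;
    rc.w = sw;
    tab[sig] = F.classes.size();
    F.classes.push_back(std::move(rc));
    F.class_node.push_back(home);
  }
}

// [[Rcpp::export]]
SEXP cpp_forest_new() {
  XPtr<Forest> xp(new Forest(), true);
  return xp;
}

// [[Rcpp::export]]
void cpp_forest_add(SEXP fxp, IntegerVector iso, NumericVector w, double bw,
                    bool collapse) {
  XPtr<Forest> F(fxp);
  if (iso.size() == 0) stop("read with no compatibility entries");
  std::vector<int> vi(iso.begin(), iso.end());
  std::vector<double> vw(w.begin(), w.end());
  forest_add(*F, vi, vw, bw, collapse);
}

// Batch insertion: entries of read r are rows read_off[r] .. read_off[r+1]-1
// [[Rcpp::export]]
void cpp_forest_add_batch(SEXP fxp, IntegerVector ent_iso, NumericVector ent_w,
                          IntegerVector read_off, NumericVector read_m,
                          bool collapse) {
  XPtr<Forest> F(fxp);
  int nr = read_off.size() - 1;
  for (int r = 0; r < nr; ++r) {
    int a = read_off[r], b = read_off[r + 1];
    if (a >= b) continue;
    std::vector<int> vi(ent_iso.begin() + a, ent_iso.begin() + b);
    std::vector<double> vw(ent_w.begin() + a, ent_w.begin() + b);
    forest_add(*F, vi, vw, read_m[r], collapse);
  }
}

// [[Rcpp::export]]
List cpp_forest_stats(SEXP fxp) {
  XPtr<Forest> F(fxp);
  int n = F->parent.size();
  IntegerVector par(n), hei(n), iso(n), root(n);
  for (int i = 0; i < n; ++i) {
    par[i] = F->parent[i] + 1;
    hei[i] = F->height[i];
    iso[i] = F->node_iso[i];
    root[i] = F->find(i) + 1;
  }
  return List::create(_["n_nodes"] = n,
                      _["n_classes"] = int(F->classes.size()),
                      _["n_reads"] = double(F->n_reads),
                      _["n_merged"] = double(F->n_merged),
                      _["total_m"] = F->total_m, _["parent"] = par,
                      _["height"] = hei, _["iso"] = iso, _["root"] = root);
}

// Collect connected components; path compression is safe at this point.
// [[Rcpp::export]]
List cpp_forest_collect(SEXP fxp) {
  XPtr<Forest> F(fxp);
  int n = F->parent.size();
  std::vector<int> root(n);
  for (int i = 0; i < n; ++i) {           // find with path compression
    int r = i;
    while (F->parent[r] != r) r = F->parent[r];
    int x = i;
    while (F->parent[x] != r) { int nx = F->parent[x]; F->parent[x] = r; x = nx; }
    root[i] = r;
  }
  // components ordered by smallest member isoform id for determinism
  std::unordered_map<int, int> comp_of_root;
  std::vector<int> comp_min_iso, comp_root;
  for (int i = 0; i < n; ++i) {
    int r = root[i];
    auto it = comp_of_root.find(r);
    if (it == comp_of_root.end()) {
      comp_of_root[r] = comp_root.size();
      comp_root.push_back(r);
      comp_min_iso.push_back(F->node_iso[i]);
    } else if (F->node_iso[i] < comp_min_iso[it->second])
      comp_min_iso[it->second] = F->node_iso[i];
  }
  int nc = comp_root.size();
  std::vector<int> order(nc);
  for (int c = 0; c < nc; ++c) order[c] = c;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return comp_min_iso[a] < comp_min_iso[b]; });
  std::vector<int> rank(nc);
  for (int c = 0; c < nc; ++c) rank[order[c]] = c;

  // isoforms per component (sorted)
  std::vector<std::vector<int> > comp_iso(nc);
  for (int i = 0; i < n; ++i)
    comp_iso[rank[comp_of_root[root[i]]]].push_back(F->node_iso[i]);
  for (int c = 0; c < nc; ++c)
    std::sort(comp_iso[c].begin(), comp_iso[c].end());

  // classes per component, in insertion order
  int ncls = F->classes.size();
  std::vector<std::vector<int> > comp_cls(nc);
  for (int k = 0; k < ncls; ++k)
    comp_cls[rank[comp_of_root[root[F->class_node[k]]]]].push_back(k);

  IntegerVector iso_off(nc + 1), cls_off(nc + 1);
  int tot_iso = 0, tot_ent = 0, tot_cls = 0;
  for (int c = 0; c < nc; ++c) {
    iso_off[c + 1] = (tot_iso += comp_iso[c].size());
    cls_off[c + 1] = (tot_cls += comp_cls[c].size());
    for (int k : comp_cls[c]) tot_ent += F->classes[k].iso.size();
  }
  IntegerVector iso_flat(tot_iso);
  NumericVector cls_m(tot_cls);
  IntegerVector ent_off(tot_cls + 1), ent_iso(tot_ent);
  NumericVector ent_w(tot_ent);
  int pi = 0, pc = 0, pe = 0;
  for (int c = 0; c < nc; ++c) {
    for (int v : comp_iso[c]) iso_flat[pi++] = v;
    for (int k : comp_cls[c]) {
      const RClass& rc = F->classes[k];
      cls_m[pc] = rc.m;
      for (size_t e = 0; e < rc.iso.size(); ++e) {
        ent_iso[pe] = rc.iso[e];
        ent_w[pe] = rc.w[e];
        ++pe;
      }
      ent_off[pc + 1] = pe;
      ++pc;
    }
  }
  return List::create(_["n_components"] = nc, _["iso"] = iso_flat,
                      _["iso_off"] = iso_off, _["cls_off"] = cls_off,
                      _["cls_m"] = cls_m, _["ent_off"] = ent_off,
                      _["ent_iso"] = ent_iso, _["ent_w"] = ent_w);
}

// ---------------------------------------------------------------------------
// Batched transcript-interval -> genome-blocks projection (simulator and
// SAM parsing hot path).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_genome_blocks(IntegerVector tx, NumericVector t0, NumericVector t1,
                       IntegerVector strand, NumericVector L,
                       IntegerVector seg_start, IntegerVector seg_end,
                       NumericVector seg_cum, IntegerVector seg_off) {
  int n = tx.size();
  std::vector<int> off(1, 0), bs, be;
  bs.reserve(n * 2);
  be.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    int g = tx[i];
    int s0 = seg_off[g - 1], s1 = seg_off[g];
    double o0, o1;
    if (strand[i] > 0) { o0 = t0[i]; o1 = t1[i]; }
    else               { o0 = L[i] - t1[i]; o1 = L[i] - t0[i]; }
    for (int j = s0; j < s1; ++j) {
      double w = seg_end[j] - seg_start[j];
      double a = std::max(o0, seg_cum[j]);
      double b = std::min(o1, seg_cum[j] + w);
      if (b > a) {
        bs.push_back(seg_start[j] + int(a - seg_cum[j]));
        be.push_back(seg_start[j] + int(b - seg_cum[j]));
      }
    }
    off.push_back(bs.size());
  }
  return List::create(_["off"] = IntegerVector(off.begin(), off.end()),
                      _["start"] = IntegerVector(bs.begin(), bs.end()),
                      _["end"] = IntegerVector(be.begin(), be.end()));
}
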