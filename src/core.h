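#pragma once

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <cstdint>
#include <limits>
#include <memory>
#include <queue>
#include <string>
#include <unordered_map>
#include <vector>

namespace pbp {

constexpr double INF = std::numeric_limits<double>::infinity();

// One profile column: probability mass over {A,C,G,T} plus a gap-fraction slot.
struct Col {
  std::array<double, 5> p;
};

// Cluster representative: a position-wise base-probability profile.  Columns
// that carry unit mass on a single base are stored as a 1-byte code; only
// mixed columns (ambiguity codes, merged minority alleles, gap mass) are
// materialized.  Profiles are immutable once created ("frozen" snapshots).
struct Rep {
  int len = 0;
  std::vector<uint8_t> code;  // 0..3 = pure A/C/G/T, 255 = mixed (see mixed_*)
  std::vector<int> mixed_idx;
  std::vector<Col> mixed_col;
  double weight = 1.0;
};

struct AlignParams {
  double mismatch = 1.0;
  double gap = 1.0;
};

struct AlignResult {
  double cost = 0.0;
  long len = 0;          // alignment length of the tie-broken optimal path
  double dist = 0.0;     // cost / len
  bool truncated = false;  // dist is a certified lower bound >= caller cutoff
};

AlignResult align_dist(const Rep& a, const Rep& b, const AlignParams& par,
                       double cutoff);
Rep align_merge(const Rep& a, const Rep& b, const AlignParams& par);
Rep rep_from_string(const std::string& s, double weight);
Rcpp::NumericMatrix rep_to_matrix(const Rep& r);
Rep rep_from_matrix(const Rcpp::NumericMatrix& m, double weight);

// ---------------------------------------------------------------------------
// Abstract item space: items are cluster representatives; dist() is the
// pseudo-metric; merge() builds the representative of a merged cluster.
class Space {
 public:
  virtual ~Space() {}
  // Distance between items i and j.  If the exact value provably exceeds
  // `cutoff`, implementations may return any certified lower bound >= the
  // smaller of (exact value, cutoff).  Every call increments `evals`.
  virtual double dist(int i, int j, double cutoff) = 0;
  virtual int merge(int i, int j) = 0;  // returns new item index
  virtual int n_items() const = 0;
  virtual double weight(int i) const = 0;
  long long evals = 0;
};

class ProfileSpace : public Space {
 public:
  AlignParams par;
  std::vector<Rep> items;
  double dist(int i, int j, double cutoff) override {
    ++evals;
    AlignResult r = align_dist(items[i], items[j], par, cutoff);
    return r.dist;
  }
  int merge(int i, int j) override {
    items.push_back(align_merge(items[i], items[j], par));
    return static_cast<int>(items.size()) - 1;
  }
  int n_items() const override { return static_cast<int>(items.size()); }
  double weight(int i) const override { return items[i].weight; }
};

// Euclidean toy space over point clouds; items are clusters of point indices.
// Used by the oracle tests so the tree and engine run on a true metric.
enum class Linkage { kCentroid = 0, kSingle = 1, kAverage = 2 };

class EuclidSpace : public Space {
 public:
  int dim = 0;
  std::vector<double> pts;  // column-major: pts[d + i*dim]
  Linkage linkage = Linkage::kCentroid;
  struct Item {
    std::vector<int> members;
    std::vector<double> centroid;
    double w;
  };
  std::vector<Item> items;

  double pdist(int a, int b) const {
    double s = 0;
    for (int d = 0; d < dim; ++d) {
      double t = pts[d + a * dim] - pts[d + b * dim];
      s += t * t;
    }
    return std::sqrt(s);
  }
  double dist(int i, int j, double) override {
    ++evals;
    const Item& A = items[i];
    const Item& B = items[j];
    switch (linkage) {
      case Linkage::kCentroid: {
        double s = 0;
        for (int d = 0; d < dim; ++d) {
          double t = A.centroid[d] - B.centroid[d];
          s += t * t;
        }
        return std::sqrt(s);
      }
      case Linkage::kSingle: {
        double best = INF;
        for (int a : A.members)
          for (int b : B.members) best = std::min(best, pdist(a, b));
        return best;
      }
      case Linkage::kAverage: {
        double s = 0;
        for (int a : A.members)
          for (int b : B.members) s += pdist(a, b);
        return s / (static_cast<double>(A.members.size()) * B.members.size());
      }
    }
    return INF;  // unreachable
  }
  int merge(int i, int j) override {
    Item m;
    const Item& A = items[i];
    const Item& B = items[j];
    m.members = A.members;
    m.members.insert(m.members.end(), B.members.begin(), B.members.end());
    m.w = A.w + B.w;
    m.centroid.resize(dim);
    for (int d = 0; d < dim; ++d)
      m.centroid[d] = (A.centroid[d] * A.w + B.centroid[d] * B.w) / m.w;
    items.push_back(std::move(m));
    return static_cast<int>(items.size()) - 1;
  }
  int n_items() const override { return static_cast<int>(items.size()); }
  double weight(int i) const override { return items[i].w; }
};

// ---------------------------------------------------------------------------
// PBP tree: ordered, equal-depth hyper-sphere index.
struct Node {
  int level;    // 0 = root, 1..L internal, L+1 = leaf
  long order;   // creation sequence number within its level
  int item;     // frozen center (space item index); -1 for root
  int parent;   // node index; -1 for root
  int payload;  // cluster id for leaves, -1 otherwise
  bool alive;
  double rcov;  // running max distance from the center to any center ever
                // inserted beneath this node; never shrinks on deletion,
                // so it stays a sound covering radius for the live subtree
  std::vector<int> kids;
};

class Tree {
 public:
  Space* sp = nullptr;
  int L = 0;                  // number of internal levels
  std::vector<double> radii;  // radii[l], l = 1..L; leaf level L+1 has 0
  std::vector<double> tcov;   // tcov[l] = sum_{k=l..L} radii[k] (subtree cover)
  double slack = 0.0;
  std::vector<Node> nodes;  // nodes[0] = root
  std::vector<long> next_order;
  std::unordered_map<int, int> leaf_of;  // cluster id -> leaf node index

  // One center item can sit at several levels (it seeded a node chain), so
  // within a single insert or search the distance to it is computed once
  // and reused.  Cached truncated values remember their cutoff and are only
  // reused when still conclusive; real evaluations alone hit the counter.
  struct Memo {
    struct Entry {
      double v;
      bool trunc;
    };
    std::unordered_map<int, Entry> seen;
    double operator()(Space* sp, int query, int item, double cutoff) {
      auto it = seen.find(item);
      if (it != seen.end() &&
          (!it->second.trunc || it->second.v >= cutoff))
        return it->second.v;
      double d = sp->dist(query, item, cutoff);
      seen[item] = {d, d >= cutoff};
      return d;
    }
  };

  Tree(Space* s, const std::vector<double>& internal_radii, double slk)
      : sp(s), L(static_cast<int>(internal_radii.size())), slack(slk) {
    radii.assign(L + 2, 0.0);
    for (int l = 1; l <= L; ++l) radii[l] = internal_radii[l - 1];
    tcov.assign(L + 2, 0.0);
    for (int l = L; l >= 1; --l) tcov[l] = tcov[l + 1] + radii[l];
    Node root{0, 0, -1, -1, -1, true, 0.0, {}};
    nodes.push_back(root);
    next_order.assign(L + 2, 0);
  }

  int new_node(int level, int item, int parent, int payload) {
    Node nd{level, next_order[level]++, item, parent, payload, true, 0.0, {}};
    nodes.push_back(nd);
    int idx = static_cast<int>(nodes.size()) - 1;
    nodes[parent].kids.push_back(idx);
    return idx;
  }

  // Insert cluster `id` with representative `item`; returns leaf node index.
  int insert(int id, int item) {
    if (leaf_of.count(id))
      Rcpp::stop("cluster id %d already present in tree", id);
    Memo memo;
    std::vector<int> frontier{0};  // node indices at level l-1 worth expanding
    int sel = 0;                   // selected (minimal-order covering) node
    std::vector<int> created;
    for (int l = 1; l <= L; ++l) {
      int best = -1;
      long best_order = 0;
      std::vector<int> next_frontier;
      for (int f : frontier) {
        for (int c : nodes[f].kids) {
          const Node& nd = nodes[c];
          if (!nd.alive || nd.level != l) continue;
          // a covering node at any deeper level has its center within
          // rcov of this node, so the frontier can be cut at the smaller
          // of the schedule bound and the actual subtree radius; the
          // evaluation cutoff must stay above the covering radius so the
          // coverage decision is never made on a truncated bound
          double keep =
              std::min(tcov[l], nd.rcov + radii[l + 1]) + slack;
          double d = memo(sp, item, nd.item,
                          std::max(keep, radii[l]) + 1e-12);
          if (d <= radii[l] && (best < 0 || nd.order < best_order)) {
            best = c;
            best_order = nd.order;
          }
          if (d <= keep) next_frontier.push_back(c);
        }
      }
      if (best < 0) {
        best = new_node(l, item, sel, -1);
        created.push_back(best);
      }
      sel = best;
      // ensure the selected node is expanded at the next level
      bool have = false;
      for (int f : next_frontier)
        if (f == sel) {
          have = true;
          break;
        }
      if (!have) next_frontier.push_back(sel);
      frontier = std::move(next_frontier);
    }
    int leaf = new_node(L + 1, item, sel, id);
    leaf_of[id] = leaf;
    // widen the ACTUAL ancestor chain's covering radii (the per-level
    // selections need not be the leaf's ancestors); covering evaluations
    // during the descent were exact, so the memo serves these for free
    int cur = nodes[leaf].parent;
    while (cur != 0) {
      Node& anc = nodes[cur];
      double d = (anc.item == item) ? 0.0 : memo(sp, item, anc.item, INF);
      if (d > anc.rcov) anc.rcov = d;
      cur = anc.parent;
    }
    // a chain node created at an upper level is abandoned when an existing
    // node intercepted the descent deeper down; prune it (deepest first)
    for (auto it = created.rbegin(); it != created.rend(); ++it) {
      Node& nd = nodes[*it];
      if (nd.alive && nd.kids.empty()) {
        auto& ks = nodes[nd.parent].kids;
        for (size_t i = 0; i < ks.size(); ++i)
          if (ks[i] == *it) {
            ks.erase(ks.begin() + i);
            break;
          }
        nd.alive = false;
      }
    }
    return leaf;
  }

  void erase(int id) {
    auto it = leaf_of.find(id);
    if (it == leaf_of.end()) Rcpp::stop("cluster id %d not in tree", id);
    int cur = it->second;
    leaf_of.erase(it);
    while (cur != 0) {
      Node& nd = nodes[cur];
      nd.alive = false;
      int par = nd.parent;
      auto& ks = nodes[par].kids;
      for (size_t i = 0; i < ks.size(); ++i)
        if (ks[i] == cur) {
          ks.erase(ks.begin() + i);
          break;
        }
      if (par == 0 || !nodes[par].kids.empty()) break;
      cur = par;
    }
  }

  struct NNResult {
    int id = -1;          // nearest non-excluded leaf (< 0: none below dmax)
    double d = INF;       // its distance
    double second = INF;  // certified lower bound on the runner-up distance
  };

  // Branch-and-bound nearest neighbour among leaves whose payload is not in
  // `excl`, restricted to distances < dmax.  Exact for metric distances when
  // slack >= the maximum triangle violation; ties go to the smaller id.
  // Alongside the winner, a certified lower bound on the distance to every
  // OTHER leaf is maintained (runner-up evaluations and the priorities of
  // subtrees never expanded); the engine uses it as a sound stale bound
  // when the winner is later consumed by a merge.
  NNResult nearest(int query_item, const std::vector<int>& excl,
                   double dmax) const {
    auto excluded = [&](int id) {
      for (int e : excl)
        if (e == id) return true;
      return false;
    };
    NNResult res;
    Memo memo;
    double bound = dmax;  // prune iff priority > bound + slack
    typedef std::pair<double, int> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
    pq.push({0.0, 0});
    while (!pq.empty()) {
      QE top = pq.top();
      pq.pop();
      if (top.first > bound + slack) {
        res.second = std::min(res.second, top.first);
        break;
      }
      const Node& nd = nodes[top.second];
      for (int c : nd.kids) {
        const Node& ch = nodes[c];
        if (!ch.alive) continue;
        if (ch.level == L + 1) {
          if (excluded(ch.payload)) continue;
          double d = memo(sp, query_item, ch.item, bound + slack + 1e-12);
          if (d < res.d) {
            res.second = std::min(res.second, res.d);
            res.d = d;
            res.id = ch.payload;
            bound = std::min(dmax, res.d);
          } else {
            res.second = std::min(res.second, d);
            if (d == res.d && res.id >= 0 && ch.payload < res.id)
              res.id = ch.payload;
          }
        } else {
          double eff = std::min(tcov[ch.level], ch.rcov);
          double cut = bound + slack + eff + 1e-12;
          double d = memo(sp, query_item, ch.item, cut);
          double pr = std::max(0.0, d - eff);
          if (pr <= bound + slack) pq.push({pr, c});
          else res.second = std::min(res.second, pr);
        }
      }
    }
    if (res.id < 0 || res.d >= dmax) {
      res.id = -1;
      res.d = INF;
    }
    return res;
  }

  int n_leaves() const { return static_cast<int>(leaf_of.size()); }
};

// ---------------------------------------------------------------------------
// Replica core: a space, a tree over the active clusters, and the id -> item
// map.  Workers hold a Core; the master engine embeds one.
struct Core {
  Space* sp = nullptr;
  std::unique_ptr<Tree> tree;
  std::unordered_map<int, int> item_of;  // cluster id -> item index

  void build(const std::vector<double>& radii, double slack,
             const std::vector<int>& ids, const std::vector<int>& items) {
    tree.reset(new Tree(sp, radii, slack));
    for (size_t i = 0; i < ids.size(); ++i) {
      item_of[ids[i]] = items[i];
      tree->insert(ids[i], items[i]);
    }
  }
  // Apply one master-ordered merge event; returns the new item index.
  int apply_merge(int a, int b, int m) {
    tree->erase(a);
    tree->erase(b);
    int it = sp->merge(item_of.at(a), item_of.at(b));
    item_of[m] = it;
    tree->insert(m, it);
    return it;
  }
  Tree::NNResult query(int id, double dmax) const {
    return tree->nearest(item_of.at(id), {id}, dmax);
  }
};

}  // namespace pbp
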