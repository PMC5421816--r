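// Multi-point hierarchical clustering engine with delayed NN updating.
//
// The master keeps, per active cluster, a nearest-neighbour record that is
// either FRESH (exact NN and distance), STALE (a certified lower bound on
// the NN distance), or RETIRED (NN distance known to be >= d_up).  Two heaps
// order fresh candidate pairs by (distance, min id, max id) and stale
// records by lower bound.  A candidate pair is merged only when its distance
// is strictly below every stale lower bound (and, being the fresh-heap
// minimum, below every other fresh NN distance), which makes it the global
// minimum over all pairwise distances; otherwise a batch of stale records is
// scheduled for re-search.
//
// Why the fresh-heap minimum is the global minimum even though a record
// ignores clusters created after it was computed: every new cluster is
// searched over all active clusters the moment it is created, so for any
// pair {x, y} the endpoint whose record was computed later bounds the pair
// from below by its own record value (or stale bound).  The minimum over
// all record values therefore bounds the global minimum pair distance from
// below, while every fresh value is a real pair distance - so when the
// strict merge condition fires, the candidate is exactly the global
// minimum, without assuming a reducible linkage.

#include "core.h"

namespace pbp {

struct NNRec {
  int nn = -1;
  double d = INF;   // fresh: NN distance; stale: lower bound
  double d2 = INF;  // certified lower bound on the runner-up distance
  uint8_t state = 0;  // 0 pending, 1 fresh, 2 stale, 3 retired
  long stamp = 0;
};

class Engine {
 public:
  Core core;
  double d_up;
  int batch_size;
  int n0 = 0;
  std::vector<NNRec> rec;    // indexed by cluster id (1-based)
  std::vector<char> active_;

  struct FE {
    double d;
    int mn, mx, a;
    long stamp;
    bool operator>(const FE& o) const {
      if (d != o.d) return d > o.d;
      if (mn != o.mn) return mn > o.mn;
      return mx > o.mx;
    }
  };
  struct SE {
    double b;
    int id;
    long stamp;
    bool operator>(const SE& o) const {
      if (b != o.b) return b > o.b;
      return id > o.id;
    }
  };
  std::priority_queue<FE, std::vector<FE>, std::greater<FE>> fresh;
  std::priority_queue<SE, std::vector<SE>, std::greater<SE>> stale;

  std::vector<int> ev_a, ev_b, ev_m;
  std::vector<double> ev_d;

  Engine(Space* sp, const std::vector<double>& radii, double slack,
         double dup, int batch, int n_initial)
      : d_up(dup), batch_size(batch), n0(n_initial) {
    core.sp = sp;
    std::vector<int> ids(n0), items(n0);
    for (int i = 0; i < n0; ++i) {
      ids[i] = i + 1;
      items[i] = i;
    }
    core.build(radii, slack, ids, items);
    rec.resize(2 * n0 + 2);
    active_.assign(2 * n0 + 2, 0);
    for (int i = 1; i <= n0; ++i) active_[i] = 1;
  }

  int next_id() const { return n0 + static_cast<int>(ev_a.size()) + 1; }
  int max_id() const { return next_id() - 1; }

  void push_fresh(int a) {
    const NNRec& r = rec[a];
    fresh.push({r.d, std::min(a, r.nn), std::max(a, r.nn), a, r.stamp});
  }
  void push_stale(int a) { stale.push({rec[a].d, a, rec[a].stamp}); }

  void set_nn(int id, int nn, double d, double d2) {
    NNRec& r = rec[id];
    ++r.stamp;
    r.d2 = d2;
    if (nn < 0 || d >= d_up) {
      r.state = 3;
      r.nn = -1;
      r.d = INF;
    } else {
      r.state = 1;
      r.nn = nn;
      r.d = d;
      push_fresh(id);
    }
  }

  // action: 0 = done, 1 = merge, 2 = update
  Rcpp::List next() {
    while (!fresh.empty()) {
      const FE& t = fresh.top();
      const NNRec& r = rec[t.a];
      if (active_[t.a] && r.state == 1 && r.stamp == t.stamp && active_[r.nn])
        break;
      fresh.pop();
    }
    while (!stale.empty()) {
      const SE& t = stale.top();
      const NNRec& r = rec[t.id];
      if (active_[t.id] && r.state == 2 && r.stamp == t.stamp && r.d == t.b)
        break;
      stale.pop();
    }
    double dstar = fresh.empty() ? INF : fresh.top().d;
    double sbound = stale.empty() ? INF : stale.top().b;
    if (dstar < d_up && dstar < sbound) {
      int a = fresh.top().a;
      return Rcpp::List::create(
          Rcpp::Named("action") = 1, Rcpp::Named("a") = std::min(a, rec[a].nn),
          Rcpp::Named("b") = std::max(a, rec[a].nn),
          Rcpp::Named("distance") = dstar);
    }
    if (sbound < d_up) {
      std::vector<int> ids;
      std::vector<double> bounds;
      while (static_cast<int>(ids.size()) < batch_size && !stale.empty()) {
        SE t = stale.top();
        const NNRec& r = rec[t.id];
        if (active_[t.id] && r.state == 2 && r.stamp == t.stamp &&
            r.d == t.b) {
          ids.push_back(t.id);
          bounds.push_back(t.b);
          NNRec& rw = rec[t.id];
          ++rw.stamp;
          rw.state = 0;  // in flight
        }
        stale.pop();
      }
      return Rcpp::List::create(Rcpp::Named("action") = 2,
                                Rcpp::Named("ids") = ids,
                                Rcpp::Named("bounds") = bounds);
    }
    return Rcpp::List::create(Rcpp::Named("action") = 0);
  }

  // Execute the merge of (a, b); returns the new id and its NN record.
  Rcpp::List do_merge(int a, int b) {
    if (!active_[a] || !active_[b]) Rcpp::stop("merge of inactive cluster");
    NNRec& ra = rec[a];
    double d = (ra.state == 1 && ra.nn == b) ? ra.d : rec[b].d;
    int m = next_id();
    core.apply_merge(a, b, m);
    active_[a] = active_[b] = 0;
    active_[m] = 1;
    ++rec[a].stamp;
    ++rec[b].stamp;
    ev_a.push_back(a);
    ev_b.push_back(b);
    ev_m.push_back(m);
    ev_d.push_back(d);

    pbp::Tree::NNResult q = core.query(m, d_up);
    set_nn(m, q.id, q.d, q.second);

    // Repair records whose NN was consumed by this merge.  One distance
    // evaluation against the new cluster m settles each of them: every
    // surviving cluster the record's search saw is at least the runner-up
    // bound d2 away, so if d(x, m) < d2 then m is the unique new NN and
    // the record is fresh again without a search; otherwise d2 is a sound
    // stale lower bound (for reducible linkages it also bounds every
    // later descendant of the consumed neighbour, since such a cluster
    // can only be d2 or d(x, m) away at best).  Pairs with unrelated new
    // clusters are always covered by those clusters' own records.
    int item_m = core.item_of.at(m);
    for (int x = 1; x < m; ++x) {
      if (!active_[x]) continue;
      NNRec& r = rec[x];
      if (r.state == 1 && (r.nn == a || r.nn == b)) {
        ++r.stamp;
        double lim = std::min(r.d2, d_up);
        double dxm = core.sp->dist(core.item_of.at(x), item_m, lim + 1e-12);
        if (dxm < lim) {
          r.state = 1;
          r.nn = m;
          r.d = dxm;
          push_fresh(x);
        } else if (r.d2 < d_up) {
          r.state = 2;
          r.nn = -1;
          r.d = r.d2;
          push_stale(x);
        } else {
          r.state = 3;
          r.nn = -1;
          r.d = INF;
        }
      }
    }
    return Rcpp::List::create(Rcpp::Named("m") = m, Rcpp::Named("distance") = d,
                              Rcpp::Named("nn") = q.id,
                              Rcpp::Named("nn_distance") = q.d);
  }
};

}  // namespace pbp

using namespace Rcpp;
using pbp::Engine;
using pbp::Space;

// [[Rcpp::export(name = ".eng_new")]]
SEXP eng_new(SEXP sp_, std::vector<double> radii, double slack, double d_up,
             int batch_size, int n) {
  XPtr<Space> sp(sp_);
  XPtr<Engine> eng(new Engine(sp.get(), radii, slack, d_up, batch_size, n),
                   true);
  return eng;
}

// [[Rcpp::export(name = ".eng_pending")]]
IntegerVector eng_pending(SEXP eng_) {
  XPtr<Engine> eng(eng_);
  std::vector<int> out;
  for (int i = 1; i <= eng->max_id(); ++i)
    if (eng->active_[i] && eng->rec[i].state == 0) out.push_back(i);
  return wrap(out);
}

// [[Rcpp::export(name = ".eng_set_nn")]]
void eng_set_nn(SEXP eng_, IntegerVector ids, IntegerVector nns,
                NumericVector ds, NumericVector d2s) {
  XPtr<Engine> eng(eng_);
  for (int i = 0; i < ids.size(); ++i)
    eng->set_nn(ids[i], nns[i], ds[i], d2s[i]);
}

// Run NN searches on the master replica (used when workers == 1 and for
// cross-checks); returns a matrix (id, nn, distance, runner-up bound).
// [[Rcpp::export(name = ".eng_query")]]
NumericMatrix eng_query(SEXP eng_, IntegerVector ids) {
  XPtr<Engine> eng(eng_);
  NumericMatrix out(ids.size(), 4);
  for (int i = 0; i < ids.size(); ++i) {
    pbp::Tree::NNResult q = eng->core.query(ids[i], eng->d_up);
    out(i, 0) = ids[i];
    out(i, 1) = q.id;
    out(i, 2) = q.d;
    out(i, 3) = q.second;
  }
  return out;
}

// [[Rcpp::export(name = ".eng_next")]]
List eng_next(SEXP eng_) {
  XPtr<Engine> eng(eng_);
  return eng->next();
}

// [[Rcpp::export(name = ".eng_do_merge")]]
List eng_do_merge(SEXP eng_, int a, int b) {
  XPtr<Engine> eng(eng_);
  return eng->do_merge(a, b);
}

// Replica-side application of a master-ordered merge batch.
// [[Rcpp::export(name = ".eng_apply")]]
void eng_apply(SEXP eng_, IntegerVector a, IntegerVector b, IntegerVector m) {
  XPtr<Engine> eng(eng_);
  for (int i = 0; i < a.size(); ++i) {
    eng->core.apply_merge(a[i], b[i], m[i]);
    eng->active_[a[i]] = 0;
    eng->active_[b[i]] = 0;
    if (m[i] >= static_cast<int>(eng->active_.size()))
      eng->active_.resize(2 * m[i] + 2, 0);
    eng->active_[m[i]] = 1;
    eng->ev_a.push_back(a[i]);
    eng->ev_b.push_back(b[i]);
    eng->ev_m.push_back(m[i]);
    eng->ev_d.push_back(NA_REAL);
  }
}

// Replica-side NN queries (each id searched with itself excluded).
// [[Rcpp::export(name = ".eng_replica_query")]]
NumericMatrix eng_replica_query(SEXP eng_, IntegerVector ids) {
  return eng_query(eng_, ids);
}

// [[Rcpp::export(name = ".eng_events")]]
DataFrame eng_events(SEXP eng_) {
  XPtr<Engine> eng(eng_);
  return DataFrame::create(Named("a") = eng->ev_a, Named("b") = eng->ev_b,
                           Named("merged") = eng->ev_m,
                           Named("distance") = eng->ev_d);
}

// [[Rcpp::export(name = ".eng_nn_table")]]
DataFrame eng_nn_table(SEXP eng_) {
  XPtr<Engine> eng(eng_);
  std::vector<int> id, nn;
  std::vector<double> d;
  std::vector<std::string> st;
  const char* names[4] = {"pending", "fresh", "stale", "retired"};
  for (int i = 1; i <= eng->max_id(); ++i) {
    if (!eng->active_[i]) continue;
    id.push_back(i);
    nn.push_back(eng->rec[i].nn);
    d.push_back(eng->rec[i].d);
    st.push_back(names[eng->rec[i].state]);
  }
  return DataFrame::create(Named("cluster") = id, Named("nn") = nn,
                           Named("distance") = d, Named("state") = st,
                           Named("stringsAsFactors") = false);
}

// [[Rcpp::export(name = ".eng_n_active")]]
int eng_n_active(SEXP eng_) {
  XPtr<Engine> eng(eng_);
  int n = 0;
  for (int i = 1; i <= eng->max_id(); ++i) n += eng->active_[i];
  return n;
}
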