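#include "core.h"

using namespace Rcpp;
using pbp::AlignParams;
using pbp::AlignResult;
using pbp::EuclidSpace;
using pbp::Linkage;
using pbp::ProfileSpace;
using pbp::Rep;
using pbp::Space;
using pbp::Tree;

// ---------------------------------------------------------------- spaces ---

// [[Rcpp::export(name = ".space_seqs")]]
SEXP space_seqs(CharacterVector seqs, NumericVector weights, double mismatch,
                double gap) {
  ProfileSpace* sp = new ProfileSpace();
  sp->par.mismatch = mismatch;
  sp->par.gap = gap;
  sp->items.reserve(2 * seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    sp->items.push_back(pbp::rep_from_string(as<std::string>(seqs[i]), weights[i]));
  return XPtr<Space>(sp, true);
}

// Points: one row per point.
// [[Rcpp::export(name = ".space_points")]]
SEXP space_points(NumericMatrix pts, std::string linkage) {
  EuclidSpace* sp = new EuclidSpace();
  int n = pts.nrow();
  sp->dim = pts.ncol();
  sp->pts.resize(static_cast<size_t>(n) * sp->dim);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < sp->dim; ++d) sp->pts[d + i * sp->dim] = pts(i, d);
  sp->linkage = (linkage == "single")    ? Linkage::kSingle
                : (linkage == "average") ? Linkage::kAverage
                                         : Linkage::kCentroid;
  sp->items.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    EuclidSpace::Item it;
    it.members = {i};
    it.w = 1.0;
    it.centroid.resize(sp->dim);
    for (int d = 0; d < sp->dim; ++d) it.centroid[d] = pts(i, d);
    sp->items.push_back(std::move(it));
  }
  return XPtr<Space>(sp, true);
}

// [[Rcpp::export(name = ".space_n")]]
int space_n(SEXP sp_) { return XPtr<Space>(sp_)->n_items(); }

// [[Rcpp::export(name = ".space_dist")]]
double space_dist(SEXP sp_, int i, int j, double cutoff) {
  XPtr<Space> sp(sp_);
  return sp->dist(i - 1, j - 1, cutoff);
}

// [[Rcpp::export(name = ".space_dist_many")]]
NumericVector space_dist_many(SEXP sp_, int i, IntegerVector js) {
  XPtr<Space> sp(sp_);
  NumericVector out(js.size());
  for (int k = 0; k < js.size(); ++k)
    out[k] = sp->dist(i - 1, js[k] - 1, pbp::INF);
  return out;
}

// [[Rcpp::export(name = ".space_merge")]]
int space_merge(SEXP sp_, int i, int j) {
  XPtr<Space> sp(sp_);
  return sp->merge(i - 1, j - 1) + 1;
}

// [[Rcpp::export(name = ".space_add_point")]]
int space_add_point(SEXP sp_, NumericVector x) {
  XPtr<Space> sp(sp_);
  EuclidSpace* es = dynamic_cast<EuclidSpace*>(sp.get());
  if (!es) stop("not a point space");
  if (x.size() != es->dim) stop("wrong dimension");
  int pid = static_cast<int>(es->pts.size()) / es->dim;
  for (int d = 0; d < es->dim; ++d) es->pts.push_back(x[d]);
  EuclidSpace::Item it;
  it.members = {pid};
  it.w = 1.0;
  it.centroid.assign(x.begin(), x.end());
  es->items.push_back(std::move(it));
  return es->n_items();
}

// [[Rcpp::export(name = ".space_add_seq")]]
int space_add_seq(SEXP sp_, std::string seq, double weight) {
  XPtr<Space> sp(sp_);
  ProfileSpace* ps = dynamic_cast<ProfileSpace*>(sp.get());
  if (!ps) stop("not a sequence space");
  ps->items.push_back(pbp::rep_from_string(seq, weight));
  return ps->n_items();
}

// [[Rcpp::export(name = ".space_profile")]]
List space_profile(SEXP sp_, int i) {
  XPtr<Space> sp(sp_);
  ProfileSpace* ps = dynamic_cast<ProfileSpace*>(sp.get());
  if (!ps) stop("not a sequence space");
  const Rep& r = ps->items[i - 1];
  return List::create(Named("profile") = pbp::rep_to_matrix(r),
                      Named("weight") = r.weight);
}

// [[Rcpp::export(name = ".space_evals")]]
double space_evals(SEXP sp_) {
  return static_cast<double>(XPtr<Space>(sp_)->evals);
}

// [[Rcpp::export(name = ".space_reset_evals")]]
void space_reset_evals(SEXP sp_) { XPtr<Space>(sp_)->evals = 0; }

// ------------------------------------------------------------- alignment ---

// [[Rcpp::export(name = ".align_pair")]]
List align_pair(NumericMatrix a, double wa, NumericMatrix b, double wb,
                double mismatch, double gap, double cutoff) {
  AlignParams par{mismatch, gap};
  Rep ra = pbp::rep_from_matrix(a, wa);
  Rep rb = pbp::rep_from_matrix(b, wb);
  AlignResult r = pbp::align_dist(ra, rb, par, cutoff);
  return List::create(Named("distance") = r.dist, Named("cost") = r.cost,
                      Named("length") = static_cast<double>(r.len),
                      Named("truncated") = r.truncated);
}

// [[Rcpp::export(name = ".align_merge_pair")]]
List align_merge_pair(NumericMatrix a, double wa, NumericMatrix b, double wb,
                      double mismatch, double gap) {
  AlignParams par{mismatch, gap};
  Rep ra = pbp::rep_from_matrix(a, wa);
  Rep rb = pbp::rep_from_matrix(b, wb);
  Rep m = pbp::align_merge(ra, rb, par);
  return List::create(Named("profile") = pbp::rep_to_matrix(m),
                      Named("weight") = m.weight);
}

// ------------------------------------------------------------------ tree ---

// [[Rcpp::export(name = ".tree_new")]]
SEXP tree_new(SEXP sp_, std::vector<double> radii, double slack) {
  XPtr<Space> sp(sp_);
  return XPtr<Tree>(new Tree(sp.get(), radii, slack), true);
}

// [[Rcpp::export(name = ".tree_insert")]]
void tree_insert(SEXP tr_, int id, int item) {
  XPtr<Tree>(tr_)->insert(id, item - 1);
}

// [[Rcpp::export(name = ".tree_delete")]]
void tree_delete(SEXP tr_, int id) { XPtr<Tree>(tr_)->erase(id); }

// [[Rcpp::export(name = ".tree_nearest")]]
List tree_nearest(SEXP tr_, int item, IntegerVector exclude, double dmax) {
  XPtr<Tree> tr(tr_);
  std::vector<int> excl(exclude.begin(), exclude.end());
  Tree::NNResult q = tr->nearest(item - 1, excl, dmax);
  return List::create(Named("id") = q.id, Named("distance") = q.d,
                      Named("second") = q.second);
}

// [[Rcpp::export(name = ".tree_ids")]]
IntegerVector tree_ids(SEXP tr_) {
  XPtr<Tree> tr(tr_);
  std::vector<int> ids;
  for (auto& kv : tr->leaf_of) ids.push_back(kv.first);
  std::sort(ids.begin(), ids.end());
  return wrap(ids);
}

// [[Rcpp::export(name = ".tree_size")]]
int tree_size(SEXP tr_) { return XPtr<Tree>(tr_)->n_leaves(); }

// [[Rcpp::export(name = ".tree_node_count")]]
int tree_node_count(SEXP tr_) {
  XPtr<Tree> tr(tr_);
  int n = 0;
  for (const auto& nd : tr->nodes) n += nd.alive;
  return n;
}

// Structural audit.  Distance evaluations made by the audit are excluded
// from the space's evaluation counter.
// [[Rcpp::export(name = ".tree_audit")]]
List tree_audit(SEXP tr_, bool check_order) {
  XPtr<Tree> tr(tr_);
  long long saved = tr->sp->evals;
  std::vector<std::string> problems;
  int nlive_leaves = 0;
  for (size_t i = 1; i < tr->nodes.size(); ++i) {
    const pbp::Node& nd = tr->nodes[i];
    if (!nd.alive) continue;
    const pbp::Node& par = tr->nodes[nd.parent];
    if (!par.alive) problems.push_back("dead parent of a live node");
    if (nd.level != par.level + 1)
      problems.push_back("child level is not parent level + 1");
    if (nd.level == tr->L + 1) {
      ++nlive_leaves;
      if (nd.payload < 0) problems.push_back("leaf without payload");
      auto it = tr->leaf_of.find(nd.payload);
      if (it == tr->leaf_of.end() || it->second != static_cast<int>(i))
        problems.push_back("leaf not registered in the leaf map");
      if (!nd.kids.empty()) problems.push_back("leaf with children");
    } else if (nd.kids.empty()) {
      problems.push_back("childless internal node left unpruned");
    }
    // coverage at creation (frozen centers, so this persists)
    if (nd.parent != 0) {
      double d = tr->sp->dist(nd.item, par.item, pbp::INF);
      if (d > tr->radii[par.level] + 1e-9)
        problems.push_back("node center not covered by its parent sphere");
    }
    if (check_order && nd.parent != 0) {
      for (size_t j = 1; j < tr->nodes.size(); ++j) {
        const pbp::Node& other = tr->nodes[j];
        if (!other.alive || other.level != par.level ||
            other.order >= par.order)
          continue;
        double d = tr->sp->dist(nd.item, other.item, pbp::INF);
        if (d <= tr->radii[par.level] - 1e-9)
          problems.push_back("parent is not the minimal-order covering node");
      }
    }
  }
  if (nlive_leaves != static_cast<int>(tr->leaf_of.size()))
    problems.push_back("leaf map size differs from live leaf count");
  for (int l = 1; l <= tr->L; ++l)
    if (!(tr->radii[l] > tr->radii[l + 1]))
      problems.push_back("radius schedule is not strictly decreasing");
  tr->sp->evals = saved;
  return List::create(Named("ok") = problems.empty(),
                      Named("problems") = wrap(problems));
}

// [[Rcpp::export(name = ".tree_radii")]]
NumericVector tree_radii(SEXP tr_) {
  XPtr<Tree> tr(tr_);
  NumericVector out(tr->L + 1);
  for (int l = 1; l <= tr->L; ++l) out[l - 1] = tr->radii[l];
  out[tr->L] = 0.0;
  return out;
}
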