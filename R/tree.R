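#' Pseudo-metric based partitioning (PBP) tree
#'
#' An ordered, equal-depth hierarchy of hyper-spheres over the active cluster
#' representatives.  All nodes at one level share a radius; radii halve from
#' the top level (`d_up`) down, and leaves have radius zero.  Each node's
#' center is a frozen snapshot of the representative that created it, and its
#' parent is the node at the level above whose sphere covered the center and
#' had the minimal creation order among such nodes.  The structure supports
#' near-constant insertion and deletion and sublinear branch-and-bound
#' nearest-neighbour search.
#'
#' Because coverage chains down the levels, the subtree of a level-`l` node
#' lies within `sum(radii[l:L])` (about twice its own radius under halving)
#' of its center; the search prunes with this subtree covering radius, which
#' keeps it exact for metric distances.  The alignment distance is only a
#' pseudo-metric: `slack` widens the pruning threshold so that exactness is
#' retained as long as `slack` is at least the maximum triangle violation.
#'
#' @param space A `pbp_space` providing items and distances.
#' @param d_up Top-level sphere radius; normally the clustering stop
#'   distance, so no search needs to look past it.
#' @param levels Number of internal levels (default 6): radii
#'   `d_up, d_up/2, ..., d_up/2^(levels-1)`, then 0 for the leaves.
#' @param slack Non-negative pruning relaxation for pseudo-metric distances
#'   (default 0; `Inf` forces exhaustive scans).
#' @param radii Optional explicit internal radii (overrides `d_up`/`levels`;
#'   must be strictly decreasing and positive).
#' @return A `pbp_tree` handle (mutable; operations modify it in place).
#' @export
#' @examples
#' sp <- point_space(matrix(c(0, 1, 3, 7), 4, 1))
#' tr <- pbp_tree(sp, d_up = 8, levels = 3)
#' for (i in 1:4) pbp_insert(tr, i, i)
#' pbp_nearest(tr, query = 2, exclude = 2)  # nearest other leaf to point 2
pbp_tree <- function(space, d_up = NULL, levels = 6L, slack = 0,
                     radii = NULL) {
  if (is.null(radii)) {
    stopifnot(is.numeric(d_up), d_up > 0, levels >= 1)
    radii <- d_up / 2^(0:(levels - 1))
  } else {
    stopifnot(all(radii > 0), all(diff(radii) < 0))
  }
  stopifnot(slack >= 0)
  structure(
    list(ptr = .tree_new(space$ptr, radii, slack), space = space,
         radii = c(radii, 0), slack = slack),
    class = "pbp_tree")
}

#' @export
print.pbp_tree <- function(x, ...) {
  cat("<pbp_tree>", .tree_size(x$ptr), "leaves,", .tree_node_count(x$ptr),
      "live nodes; radii:", paste(signif(x$radii, 4), collapse = " "), "\n")
  invisible(x)
}

#' Insert, delete and query clusters in a PBP tree
#'
#' `pbp_insert()` descends the levels top-down, attaching under the
#' minimal-order covering node at each level and creating new nodes (centered
#' at a frozen copy of the representative) where no sphere covers it.
#' `pbp_delete()` removes the leaf and prunes ancestors left childless;
#' frozen centers of surviving nodes are never updated.  `pbp_nearest()` runs
#' a best-first branch-and-bound search; ties in distance go to the smaller
#' cluster id.
#'
#' @param tree A `pbp_tree`.
#' @param id Cluster id (unique among current leaves).
#' @param item Item index in the tree's space (the cluster representative).
#' @return `pbp_insert`/`pbp_delete` return the tree invisibly;
#'   `pbp_nearest` returns a list with `id` and `distance` (`id = -1` and an
#'   infinite distance when nothing qualifies).
#' @export
pbp_insert <- function(tree, id, item) {
  .tree_insert(tree$ptr, as.integer(id), as.integer(item))
  invisible(tree)
}

#' @rdname pbp_insert
#' @export
pbp_delete <- function(tree, id) {
  .tree_delete(tree$ptr, as.integer(id))
  invisible(tree)
}

#' @rdname pbp_insert
#' @param query Item index of the query representative.
#' @param exclude Cluster ids to skip (e.g. the query's own id).
#' @param dmax Only distances strictly below `dmax` qualify; searches capped
#'   at the stop distance prune everything beyond it.
#' @export
pbp_nearest <- function(tree, query, exclude = integer(), dmax = Inf) {
  .tree_nearest(tree$ptr, as.integer(query), as.integer(exclude), dmax)
}

#' @rdname pbp_insert
#' @export
pbp_leaf_ids <- function(tree) .tree_ids(tree$ptr)

#' @rdname pbp_insert
#' @export
pbp_size <- function(tree) .tree_size(tree$ptr)

#' Structural audit of a PBP tree
#'
#' Verifies, over the whole tree: equal depth (every live leaf at the bottom
#' level, child level = parent level + 1), the strictly decreasing radius
#' schedule, coverage at creation (every node center within its parent's
#' sphere; valid forever because centers are frozen), pruning of childless
#' internal nodes, and the bijection between live leaves and the cluster-id
#' map.  With `check_order = TRUE` it additionally verifies the
#' minimal-order parent rule by exhaustive scan (quadratic; for small trees).
#' Audit distance evaluations are excluded from [distance_evals()].
#'
#' @param tree A `pbp_tree`.
#' @param check_order Also check the minimal-order parent rule.
#' @return List with `ok` (logical) and `problems` (character).
#' @export
pbp_audit <- function(tree, check_order = FALSE) {
  .tree_audit(tree$ptr, isTRUE(check_order))
}
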