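#' Item spaces: the distance provider behind the PBP tree and the engines
#'
#' A space owns the cluster representatives ("items") and evaluates the
#' pairwise distance between them.  Two kinds are provided: a sequence space
#' (alignment distance between consensus profiles, the production path) and a
#' Euclidean point space (centroid, single or average linkage between point
#' clusters), which serves as a true metric surrogate in oracle tests while
#' exercising the identical tree and engine code paths.  All distance
#' evaluations made through a space are counted; see [distance_evals()].
#'
#' @param seqs Character vector of DNA sequences.
#' @param abundances Positive integer weights, recycled to `length(seqs)`.
#' @param params A [distance_params()] object.
#' @return A `pbp_space` handle.
#' @export
#' @examples
#' sp <- sequence_space(c("ACGT", "ACGA"))
#' space_distance(sp, 1, 2)
sequence_space <- function(seqs, abundances = 1,
                           params = distance_params()) {
  stopifnot(is.character(seqs), length(seqs) >= 1, all(nchar(seqs) > 0))
  abundances <- rep_len(as.numeric(abundances), length(seqs))
  stopifnot(all(abundances >= 1))
  structure(
    list(ptr = .space_seqs(seqs, abundances, params$mismatch, params$gap),
         kind = "sequence", params = params, n_initial = length(seqs)),
    class = "pbp_space")
}

#' @rdname sequence_space
#' @param points Numeric matrix, one row per point.
#' @param linkage Cluster distance for merged point clusters: `"centroid"`
#'   (weighted centroid distance), `"single"` or `"average"`.
#' @export
point_space <- function(points, linkage = c("centroid", "single", "average")) {
  linkage <- match.arg(linkage)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  structure(
    list(ptr = .space_points(points, linkage), kind = "point",
         linkage = linkage, n_initial = nrow(points)),
    class = "pbp_space")
}

#' @export
print.pbp_space <- function(x, ...) {
  cat("<pbp_space> kind:", x$kind, "-", .space_n(x$ptr), "items,",
      format(distance_evals(x), big.mark = ","), "distance evaluations\n")
  invisible(x)
}

#' Distance between two items of a space
#'
#' @param space A `pbp_space`.
#' @param i,j Item indices (1-based).
#' @param cutoff Optional pruning cutoff: when the exact distance provably
#'   exceeds it, a certified lower bound may be returned instead (used by the
#'   tree's branch-and-bound search; exact callers leave it at `Inf`).
#' @return A numeric distance.
#' @export
space_distance <- function(space, i, j, cutoff = Inf) {
  .space_dist(space$ptr, as.integer(i), as.integer(j), cutoff)
}

#' Merge two items into a new cluster representative
#'
#' @inheritParams space_distance
#' @return The index of the newly created item.
#' @export
space_merge_items <- function(space, i, j) {
  .space_merge(space$ptr, as.integer(i), as.integer(j))
}

#' @rdname space_distance
#' @export
n_items <- function(space) .space_n(space$ptr)

#' Count of pairwise distance evaluations
#'
#' Monotone counter of every distance evaluation made through a space
#' (including evaluations truncated at a pruning cutoff, which still cost a
#' corridor DP pass).  This is the unit of work for the subquadratic-scaling
#' analysis.  Structural tree audits do not count.
#'
#' @param space A `pbp_space` (or an object carrying one, e.g. a clustering
#'   fit's `space` element).
#' @return Number of evaluations since creation or the last reset.
#' @export
distance_evals <- function(space) .space_evals(space$ptr)

#' @rdname distance_evals
#' @export
reset_distance_evals <- function(space) {
  .space_reset_evals(space$ptr)
  invisible(space)
}

#' Extract the consensus profile of an item in a sequence space
#'
#' @inheritParams space_distance
#' @return A `cluster_rep`.
#' @export
space_profile <- function(space, i) {
  stopifnot(space$kind == "sequence")
  out <- .space_profile(space$ptr, as.integer(i))
  new_cluster_rep(out$profile, out$weight)
}

#' Register an extra sequence as a new item
#'
#' @inheritParams space_distance
#' @param seq DNA sequence string.
#' @param weight Abundance weight.
#' @return The new item's index.
#' @export
space_add_sequence <- function(space, seq, weight = 1) {
  stopifnot(space$kind == "sequence")
  .space_add_seq(space$ptr, seq, weight)
}

#' @rdname space_add_sequence
#' @param x Numeric coordinate vector (point spaces).
#' @export
space_add_point <- function(space, x) {
  stopifnot(space$kind == "point")
  .space_add_point(space$ptr, as.numeric(x))
}
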