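#' Alignment distance parameters
#'
#' Costs for the global-alignment pseudo-metric used throughout the package:
#' a mismatch between two aligned columns costs `mismatch` times the expected
#' disagreement between the two base distributions, and every gapped column
#' costs `gap`.  The total cost is divided by the alignment length, so with
#' unit costs the distance lies in `[0, 1]` and `1 - distance` is the usual
#' percent-identity notion of sequence similarity (85% similarity corresponds
#' to a distance of 0.15).
#'
#' @param mismatch Non-negative mismatch cost (default 1).
#' @param gap Non-negative per-column gap cost (default 1).
#' @return A `distance_params` object.
#' @export
#' @examples
#' distance_params()
distance_params <- function(mismatch = 1, gap = 1) {
  stopifnot(is.numeric(mismatch), mismatch >= 0, is.numeric(gap), gap >= 0)
  structure(list(mismatch = as.numeric(mismatch), gap = as.numeric(gap)),
            class = "distance_params")
}

iupac_sets <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Build a cluster representative from a single sequence
#'
#' A cluster representative is a position-wise base-probability profile: one
#' column per position holding probabilities over A, C, G, T plus a
#' gap-fraction slot.  A plain sequence maps to unit-mass columns; IUPAC
#' ambiguity codes map to uniform mass over their base set (N gives 0.25 on
#' each base).
#'
#' @param seq A DNA sequence (string over the IUPAC alphabet).
#' @param abundance Number of identical raw reads this record represents.
#' @return A `cluster_rep`: list with a 5-row `profile` matrix and a `weight`.
#' @export
#' @examples
#' rep_from_sequence("ACGT")
#' rep_from_sequence("N")$profile
rep_from_sequence <- function(seq, abundance = 1) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) > 0,
            abundance >= 1)
  bases <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(bases, names(iupac_sets))
  if (length(bad) > 0)
    stop("invalid base(s) in sequence: ", paste(unique(bad), collapse = ", "))
  prof <- matrix(0, 5, length(bases),
                 dimnames = list(c("A", "C", "G", "T", "gap"), NULL))
  for (i in seq_along(bases)) {
    set <- strsplit(iupac_sets[[bases[i]]], "")[[1]]
    prof[set, i] <- 1 / length(set)
  }
  new_cluster_rep(prof, abundance)
}

#' @rdname rep_from_sequence
#' @param profile A 5-row matrix (rows A, C, G, T, gap) of column
#'   probability vectors.
#' @param weight Total abundance the representative summarizes.
#' @export
new_cluster_rep <- function(profile, weight) {
  structure(list(profile = profile, weight = as.numeric(weight)),
            class = "cluster_rep")
}

#' @export
print.cluster_rep <- function(x, ...) {
  cat("<cluster_rep> ", ncol(x$profile), " columns, weight ", x$weight, "\n",
      sep = "")
  invisible(x)
}

as_cluster_rep <- function(x) {
  if (inherits(x, "cluster_rep")) return(x)
  if (is.character(x)) return(rep_from_sequence(x))
  stop("expected a cluster_rep or a sequence string")
}

#' Alignment distance between sequences or cluster representatives
#'
#' Global (Needleman-Wunsch) alignment minimizing expected mismatch plus gap
#' cost, normalized by the minimal alignment length among the minimum-cost
#' alignments.  The column-against-column cost is the expected disagreement
#' `1 - sum_b p(b) q(b)` between the two base distributions (gap mass in a
#' column contributes the gap cost proportionally); aligning a column against
#' a gap costs the gap cost.  Because the optimal-alignment set is symmetric
#' in the two profiles and the normalization takes its minimal length, the
#' distance is exactly symmetric; residual traceback ties are broken
#' deterministically (diagonal, then consuming the first profile, then the
#' second), so merged profiles are reproducible too.
#'
#' @param a,b Sequences (strings) or `cluster_rep` objects.
#' @param params A [distance_params()] object.
#' @return A single distance in `[0, 1]`.
#' @export
#' @examples
#' align_distance("ACGT", "ACGA")           # 1 mismatch / 4 columns = 0.25
#' align_distance("ACGTACGT", "ACGACGT")    # 1 gap / 8 columns = 0.125
align_distance <- function(a, b, params = distance_params()) {
  a <- as_cluster_rep(a)
  b <- as_cluster_rep(b)
  if (ncol(a$profile) == 0 || ncol(b$profile) == 0)
    stop("cannot align an empty profile")
  .align_pair(a$profile, a$weight, b$profile, b$weight,
              params$mismatch, params$gap, Inf)$distance
}

#' Merge two cluster representatives
#'
#' Aligns the two profiles with the same dynamic program as
#' [align_distance()] and averages the aligned columns weighted by the two
#' cluster weights; a gap in one profile contributes gap mass proportional to
#' that profile's weight.  The merged weight is the sum of the two weights.
#'
#' @inheritParams align_distance
#' @return A `cluster_rep` for the merged cluster.
#' @export
#' @examples
#' m <- merge_reps(rep_from_sequence("AAAA", 3), rep_from_sequence("AAAT", 1))
#' m$profile[, 4]   # A: 0.75, T: 0.25
merge_reps <- function(a, b, params = distance_params()) {
  a <- as_cluster_rep(a)
  b <- as_cluster_rep(b)
  out <- .align_merge_pair(a$profile, a$weight, b$profile, b$weight,
                           params$mismatch, params$gap)
  new_cluster_rep(out$profile, out$weight)
}
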