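#' Alpha-diversity estimators on OTU abundance vectors
#'
#' Nonparametric richness estimators computed from an abundance vector (one
#' positive count per OTU, abundance-expanded so the total equals the number
#' of reads).  `chao1()` uses the classic estimator
#' `S_obs + F1^2 / (2 F2)` when doubletons exist and the bias-corrected form
#' `S_obs + F1 (F1 - 1) / 2` when `F2 = 0` (F1, F2 = numbers of singleton
#' and doubleton OTUs).  `ace()` splits OTUs at `rare_cutoff` (classical
#' cutoff 10): with sample coverage `C = 1 - F1 / N_rare` and coefficient of
#' variation `gamma^2 = max(S_rare/C * sum i(i-1) F_i / (N_rare (N_rare-1))
#' - 1, 0)`, the estimate is `S_abund + S_rare/C + F1/C * gamma^2`; if every
#' rare OTU is a singleton (`C = 0`) it falls back to `chao1()`, and with no
#' rare OTUs it returns `S_obs`.  Both estimators are never below `S_obs`.
#'
#' @param counts Positive integer abundances, one per OTU.
#' @param rare_cutoff Rare/abundant split for ACE (default 10).
#' @return A single richness estimate.
#' @export
#' @examples
#' chao1(c(1, 1, 2, 3))   # 6: S_obs = 4, F1 = 2, F2 = 1
#' ace(c(1, 1, 2, 11))    # 7
chao1 <- function(counts) {
  counts <- check_counts(counts)
  s <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
}

#' @rdname chao1
#' @export
ace <- function(counts, rare_cutoff = 10) {
  counts <- check_counts(counts)
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  if (length(rare) == 0) return(length(counts))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  C <- 1 - f1 / n_rare
  if (C == 0) return(chao1(counts))
  i <- seq_len(rare_cutoff)
  fi <- vapply(i, function(k) sum(rare == k), numeric(1))
  s_rare <- length(rare)
  gamma2 <- if (n_rare > 1)
    max(s_rare / C * sum(i * (i - 1) * fi) / (n_rare * (n_rare - 1)) - 1, 0)
  else 0
  s_abund + s_rare / C + f1 / C * gamma2
}

#' Rarefaction: expected richness in a subsample
#'
#' `E[S_n] = S_obs - sum_i C(N - N_i, n) / C(N, n)` where `N_i` are the OTU
#' abundances and `N` their total, computed with log-binomials for
#' stability.  Monotone non-decreasing in `n`, with `E[S_0] = 0` and
#' `E[S_N] = S_obs`.
#'
#' @inheritParams chao1
#' @param n Subsample sizes, each in `[0, sum(counts)]` (vectorized).
#' @return Expected OTU counts, one per element of `n`.
#' @export
#' @examples
#' rarefaction(c(2, 2), 2)   # 5/3
rarefaction <- function(counts, n) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (any(n < 0 | n > N)) stop("subsample size out of range [0, ", N, "]")
  vapply(n, function(k) {
    miss <- exp(lchoose(N - counts, k) - lchoose(N, k))
    miss[counts > N - k] <- 0  # OTU cannot be entirely absent
    length(counts) - sum(miss)
  }, numeric(1))
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) stop("empty abundance vector")
  if (any(counts < 1 | counts != floor(counts)))
    stop("abundances must be positive integers")
  counts
}

#' Diversity summary across partition thresholds
#'
#' For each threshold in a pipeline result: observed OTU count, Chao1 and
#' ACE estimates, and optionally rarefaction at the requested depths.
#'
#' @param x A `pbp_otu` pipeline result (see [otu_pipeline()]).
#' @param depths Optional rarefaction depths.
#' @param rare_cutoff Passed to [ace()].
#' @return A tibble with one row per threshold (times depths, if given).
#' @export
diversity_table <- function(x, depths = NULL, rare_cutoff = 10) {
  rows <- lapply(x$thresholds, function(t) {
    v <- otu_abundances(x, t)
    base <- tibble(threshold = t, n_reads = sum(v), s_obs = length(v),
                   chao1 = chao1(v), ace = ace(v, rare_cutoff))
    if (is.null(depths)) return(base)
    depths <- depths[depths <= sum(v)]
    merge(base, tibble(threshold = t, depth = depths,
                       rarefied = rarefaction(v, depths)),
          by = "threshold")
  })
  as_tibble(do.call(rbind, rows))
}
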