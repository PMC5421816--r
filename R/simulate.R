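#' Specification for a synthetic amplicon dataset
#'
#' Defines the generative model used for benchmarking: `n_templates` random
#' DNA templates (uniform over ACGT, re-drawn until every pair is at least
#' `min_separation` apart in alignment distance), from which reads are
#' produced by i.i.d. per-base substitutions and indels.  The expected
#' read-to-template distance is about `sub_rate + 2 * indel_rate` (deletions
#' and insertions each occur at `indel_rate` per base and each cost one gap
#' column).  Ground-truth template labels are kept for every read.
#'
#' @param n_templates Number of templates (distinct source taxa).
#' @param template_length Template length in bases (e.g. 250 for a 16S
#'   hypervariable region read).
#' @param min_separation Minimum pairwise template distance; keep it well
#'   above twice the expected read-to-template distance for a cleanly
#'   separated benchmark.
#' @param reads_per_template Reads per template (scalar or vector, the
#'   abundance profile).
#' @param sub_rate,indel_rate Per-base substitution / indel probabilities,
#'   each in `[0, 0.5)`.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_templates = 8, template_length = 250,
                           min_separation = 0.25, reads_per_template = 50,
                           sub_rate = 0.01, indel_rate = 0, seed = 1) {
  stopifnot(n_templates >= 1, template_length >= 1,
            sub_rate >= 0, sub_rate < 0.5, indel_rate >= 0, indel_rate < 0.5,
            min_separation >= 0, all(reads_per_template >= 1))
  reads_per_template <- rep_len(as.integer(reads_per_template), n_templates)
  structure(list(n_templates = as.integer(n_templates),
                 template_length = as.integer(template_length),
                 min_separation = min_separation,
                 reads_per_template = reads_per_template,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic read set with known OTU structure
#'
#' @param spec A [synthetic_spec()].
#' @return List with `reads` (tibble `id`, `seq`, `template`) and
#'   `templates` (tibble `template`, `seq`).
#' @export
#' @examples
#' ds <- make_dataset(synthetic_spec(n_templates = 2, template_length = 40,
#'                                   reads_per_template = 5))
#' head(ds$reads)
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bases <- c("A", "C", "G", "T")
  with_seed(spec$seed, {
    templates <- character(spec$n_templates)
    for (i in seq_len(spec$n_templates)) {
      ok <- FALSE
      for (try in 1:200) {
        cand <- paste(sample(bases, spec$template_length, replace = TRUE),
                      collapse = "")
        sep <- if (i == 1) Inf else
          min(vapply(templates[seq_len(i - 1)], align_distance, numeric(1),
                     b = cand))
        if (sep >= spec$min_separation) {
          templates[i] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place template ", i, " at separation >= ",
             spec$min_separation, " after 200 attempts")
    }
    alts <- lapply(setNames(bases, bases), function(b) setdiff(bases, b))
    total <- sum(spec$reads_per_template)
    ids <- character(total); seqs <- character(total); tlab <- integer(total)
    k <- 0L
    for (t in seq_len(spec$n_templates)) {
      tmpl <- strsplit(templates[t], "")[[1]]
      L <- length(tmpl)
      for (r in seq_len(spec$reads_per_template[t])) {
        del <- if (spec$indel_rate > 0) runif(L) < spec$indel_rate
               else rep(FALSE, L)
        sub <- if (spec$sub_rate > 0) runif(L) < spec$sub_rate
               else rep(FALSE, L)
        ins <- if (spec$indel_rate > 0) runif(L) < spec$indel_rate
               else rep(FALSE, L)
        chars <- tmpl
        hit <- sub & !del
        if (any(hit))
          chars[hit] <- mapply(function(b, k) alts[[b]][k], tmpl[hit],
                               sample.int(3, sum(hit), replace = TRUE))
        slots <- matrix(NA_character_, 2, L)
        slots[1, !del] <- chars[!del]
        if (any(ins)) slots[2, ins] <- sample(bases, sum(ins), replace = TRUE)
        out <- slots[!is.na(slots)]
        k <- k + 1L
        ids[k] <- sprintf("t%02d_r%04d", t, r)
        seqs[k] <- paste(out, collapse = "")
        tlab[k] <- t
      }
    }
    list(reads = tibble(id = ids, seq = seqs, template = tlab),
         templates = tibble(template = seq_len(spec$n_templates),
                            seq = templates))
  })
}

#' Normalized mutual information between two labelings
#'
#' `I(U; V) / sqrt(H(U) H(V))` over the contingency table of the two
#' labelings (logs cancel, so the value is base-invariant).  Degenerate
#' cases: 1 when both labelings are the same single class, 0 when either
#' labeling has zero entropy but the partitions differ.
#'
#' @param truth,pred Label vectors over the same items (any label type).
#' @return NMI in `[0, 1]`.
#' @export
#' @examples
#' nmi(c(1, 1, 2, 2), c("a", "a", "b", "b"))   # 1
#' nmi(c(1, 1, 2, 2), c(1, 2, 2, 2))           # ~0.346
nmi <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("labelings cover different item sets")
  n <- length(truth)
  if (n == 0) stop("empty labelings")
  tab <- table(truth, pred)
  p <- tab / n
  pu <- rowSums(p)
  pv <- colSums(p)
  hu <- -sum(ifelse(pu > 0, pu * log2(pu), 0))
  hv <- -sum(ifelse(pv > 0, pv * log2(pv), 0))
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  mi <- 0
  for (i in seq_along(pu)) for (j in seq_along(pv))
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (pu[i] * pv[j]))
  unname(mi / sqrt(hu * hv))
}

#' Peak NMI over partition thresholds
#'
#' Evaluates the NMI of the flat partition at each threshold against the
#' ground-truth labeling and returns the best (ties go to the smaller
#' threshold) - the standard protocol for scoring a hierarchical clustering
#' against taxonomy labels without committing to one cutoff.
#'
#' @param truth Ground-truth labels: a vector aligned with the clustered
#'   records, or, when `members` is given, a *named* vector over raw read
#'   ids.
#' @param events Tetrad tibble or `pbp_hc` fit.
#' @param thresholds Thresholds to scan (all `<= d_up`).
#' @param n Number of records (taken from the fit if omitted).
#' @param members Optional list (one element per record) of raw read ids,
#'   as produced by [dereplicate()]; scoring is then done at the read level.
#' @return List with `threshold`, `nmi`, and the per-threshold `scores`.
#' @export
peak_nmi <- function(truth, events, thresholds, n = NULL, members = NULL) {
  if (length(thresholds) == 0) stop("no thresholds given")
  if (inherits(events, "pbp_hc")) {
    n <- n %||% events$n
  }
  parts <- cut_partitions(events, n = n, thresholds = thresholds)
  n <- max(parts$id)
  scores <- vapply(thresholds, function(t) {
    part <- parts[parts$threshold == t, ]
    pred <- part$otu[order(part$id)]
    if (is.null(members)) {
      nmi(truth, pred)
    } else {
      reads <- unlist(members)
      pred_reads <- rep(pred, lengths(members))
      nmi(unname(truth[reads]), pred_reads)
    }
  }, numeric(1))
  best <- which.max(scores)  # which.max takes the first maximum: smaller t
  list(threshold = thresholds[best], nmi = scores[best],
       scores = tibble(threshold = thresholds, nmi = scores))
}
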