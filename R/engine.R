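#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# Build the item space for an engine input: a data frame of sequence records
# (columns seq and optionally id, abundance) or a numeric matrix of points.
build_space <- function(x, linkage = NULL, params = distance_params()) {
  if (is.matrix(x)) {
    linkage <- linkage %||% "centroid"
    sp <- point_space(x, linkage)
    list(space = sp, n = nrow(x), ids = as.character(seq_len(nrow(x))),
         linkage = linkage, kind = "point",
         rebuild = list(kind = "point", points = x, linkage = linkage))
  } else {
    x <- as.data.frame(x)
    if (!"seq" %in% names(x)) stop("records need a 'seq' column")
    ab <- if ("abundance" %in% names(x)) x$abundance else rep(1, nrow(x))
    ids <- if ("id" %in% names(x)) as.character(x$id) else
      as.character(seq_len(nrow(x)))
    sp <- sequence_space(x$seq, ab, params)
    list(space = sp, n = nrow(x), ids = ids, linkage = "representative",
         kind = "sequence",
         rebuild = list(kind = "sequence", seqs = x$seq, abundances = ab,
                        params = params))
  }
}

rebuild_space <- function(rb) {
  if (rb$kind == "point") point_space(rb$points, rb$linkage)
  else sequence_space(rb$seqs, rb$abundances, rb$params)
}

# ---------------------------------------------------------------------------

#' Exact sequential hierarchical clustering (reference engine)
#'
#' The quadratic reference: repeatedly merge the globally closest active pair
#' until every inter-cluster distance reaches `d_up` or one cluster remains.
#' Ties are broken lexicographically by (distance, smaller id, larger id).
#' Intended as the correctness oracle for the multi-point engine on small
#' inputs (hundreds of records).
#'
#' Linkage providers: `"representative"` (distance between consensus
#' profiles, the production linkage; merged representatives are rebuilt at
#' every step), `"centroid"` (point input), and exact `"average"` /
#' `"single"` linkage computed by Lance-Williams updates from the initial
#' pairwise matrix (abundance-weighted for sequence records).
#'
#' @param x Data frame of sequence records (`seq`, optional `id`,
#'   `abundance`) or a numeric matrix of points (one row per point).
#' @param d_up Stop distance in (0, 1] for sequences (any positive value for
#'   points); merging halts at the first step whose minimum distance reaches
#'   it.
#' @param linkage Cluster-distance provider (see Details).
#' @param params [distance_params()] for sequence input.
#' @return A tibble of merge events: `a`, `b` (merged cluster ids, `a < b`),
#'   `merged` (the new id, `n + k` for step `k`) and `distance`.
#' @export
#' @examples
#' hc_oracle(matrix(c(0, 1, 3, 7), 4, 1), d_up = 10, linkage = "single")
hc_oracle <- function(x, d_up,
                      linkage = c("representative", "average", "single",
                                  "centroid"),
                      params = distance_params()) {
  linkage <- match.arg(linkage)
  lw <- linkage %in% c("average", "single")
  built <- build_space(x, if (!lw) linkage else "centroid", params)
  space <- built$space
  n <- built$n
  if (n < 1) stop("empty input")
  size <- 2L * n
  D <- matrix(Inf, size, size)
  item <- seq_len(n)
  w <- vapply(seq_len(n), function(i) space_weight(space, i), numeric(1))
  for (i in seq_len(n)) {
    if (i < n) D[i, (i + 1):n] <- D[(i + 1):n, i] <-
        .space_dist_many(space$ptr, i, (i + 1):n)
  }
  active <- seq_len(n)
  ev_a <- integer(); ev_b <- integer(); ev_m <- integer(); ev_d <- numeric()
  k <- 0L
  while (length(active) > 1) {
    Dsub <- D[active, active, drop = FALSE]
    mn <- min(Dsub)
    if (!is.finite(mn) || mn >= d_up) break
    hits <- which(Dsub == mn, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    pa <- active[hits[, 1]]; pb <- active[hits[, 2]]
    ord <- order(pa, pb)[1]
    a <- pa[ord]; b <- pb[ord]
    k <- k + 1L
    m <- n + k
    if (lw) {
      others <- setdiff(active, c(a, b))
      if (length(others) > 0) {
        dm <- if (linkage == "single") pmin(D[a, others], D[b, others])
              else (w[a] * D[a, others] + w[b] * D[b, others]) / (w[a] + w[b])
        D[m, others] <- D[others, m] <- dm
      }
      w[m] <- w[a] + w[b]
    } else {
      item[m] <- space_merge_items(space, item[a], item[b])
      others <- setdiff(active, c(a, b))
      if (length(others) > 0) {
        dm <- .space_dist_many(space$ptr, item[m], item[others])
        D[m, others] <- D[others, m] <- dm
      }
    }
    active <- c(setdiff(active, c(a, b)), m)
    ev_a <- c(ev_a, a); ev_b <- c(ev_b, b); ev_m <- c(ev_m, m)
    ev_d <- c(ev_d, mn)
  }
  tibble(a = ev_a, b = ev_b, merged = ev_m, distance = ev_d)
}

space_weight <- function(space, i) {
  if (space$kind == "sequence") .space_profile(space$ptr, i)$weight else 1
}

# ---------------------------------------------------------------------------

#' Multi-point hierarchical clustering on a PBP tree
#'
#' The production engine.  All records are inserted into a PBP tree, an
#' initial nearest-neighbour (NN) table is built by per-record searches
#' capped at `d_up`, and clusters are then merged until no inter-cluster
#' distance remains below `d_up`.
#'
#' In the default `"event"` mode, NN maintenance is *delayed*: records whose
#' NN was consumed by a merge keep their old distance as a certified lower
#' bound, and a candidate pair is merged as soon as its distance is strictly
#' below every such bound and every other fresh NN distance - making it the
#' global minimum, so the flat partitions equal the sequential reference
#' ([hc_oracle()]) at every threshold.  When no candidate qualifies, a batch
#' of up to `batch_factor * workers` stale records (smallest bounds first) is
#' re-searched, on the worker pool when `workers > 1`.  The `"round"` mode is
#' the literal multi-point formulation: in each round all mutual-NN pairs
#' below `d_up` (after tie-breaking) are merged together; it reproduces the
#' sequential result for reducible linkages and is kept for conformance
#' testing.
#'
#' @inheritParams hc_oracle
#' @param levels,slack,radii PBP tree geometry, see [pbp_tree()].
#' @param batch_factor Stale-record updates dispatched per scheduling round,
#'   per worker (default 20).
#' @param workers Worker processes holding replicated trees (1 = in-process).
#'   The merge-event list is invariant to the worker count.
#' @param mode `"event"` (delayed updating, default) or `"round"`.
#' @return A `pbp_hc` object; its `events` element is the tetrad tibble
#'   (`a`, `b`, `merged`, `distance`).  Use [cut_partitions()] to derive flat
#'   OTU partitions and [distance_evals()] via `$evals` for the work counter.
#' @export
#' @examples
#' reads <- data.frame(seq = c("ACGTACGT", "ACGTACGA", "TTTTGGGG"))
#' fit <- hc_multipoint(reads, d_up = 0.3)
#' fit$events
hc_multipoint <- function(x, d_up, levels = 6L, slack = 0, radii = NULL,
                          batch_factor = 20L, workers = 1L,
                          mode = c("event", "round"),
                          linkage = NULL, params = distance_params()) {
  mode <- match.arg(mode)
  stopifnot(d_up > 0, batch_factor >= 1, workers >= 1)
  built <- build_space(x, linkage, params)
  if (is.null(radii)) radii <- d_up / 2^(0:(levels - 1))
  if (mode == "round") {
    state <- hc_state(built = built, d_up = d_up, radii = radii,
                      slack = slack)
    events <- run_hc_rounds(state)
  } else {
    events <- run_hc_events(built, d_up, radii, slack,
                            as.integer(batch_factor), as.integer(workers))
  }
  structure(
    list(events = events, n = built$n, d_up = d_up, mode = mode,
         workers = as.integer(workers), linkage = built$linkage,
         record_ids = built$ids, space = built$space,
         evals = distance_evals(built$space), levels = levels,
         slack = slack, batch_factor = batch_factor),
    class = "pbp_hc")
}

run_hc_events <- function(built, d_up, radii, slack, batch_factor, workers) {
  space <- built$space
  n <- built$n
  eng <- .eng_new(space$ptr, radii, slack, d_up, batch_factor * workers, n)
  pool <- NULL
  if (workers > 1)
    pool <- spawn_pool(built$rebuild, d_up, radii, slack,
                       batch_factor, workers)
  on.exit(if (!is.null(pool)) halt_workers(pool), add = TRUE)
  query <- function(ids) {
    if (is.null(pool)) .eng_query(eng, as.integer(ids))
    else dispatch_updates(pool, ids, .raw = TRUE)
  }
  ids <- .eng_pending(eng)
  q <- query(ids)
  .eng_set_nn(eng, as.integer(q[, 1]), as.integer(q[, 2]), q[, 3], q[, 4])
  repeat {
    act <- .eng_next(eng)
    if (act$action == 0L) break
    if (act$action == 1L) {
      res <- .eng_do_merge(eng, act$a, act$b)
      if (!is.null(pool)) pool_push_event(pool, act$a, act$b, res$m)
    } else {
      q <- query(act$ids)
      .eng_set_nn(eng, as.integer(q[, 1]), as.integer(q[, 2]), q[, 3], q[, 4])
    }
  }
  as_tibble(.eng_events(eng))
}

#' @export
print.pbp_hc <- function(x, ...) {
  cat("<pbp_hc> ", x$n, " records, ", nrow(x$events), " merges (mode ",
      x$mode, ", linkage ", x$linkage, ", d_up ", x$d_up, ")\n", sep = "")
  cat("  distance evaluations:", format(x$evals, big.mark = ","), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname hc_multipoint
#' @param x,... A fitted `pbp_hc` object (for `tidy`/`glance`).
#' @export
tidy.pbp_hc <- function(x, ...) x$events

#' @rdname hc_multipoint
#' @export
glance.pbp_hc <- function(x, ...) {
  tibble(n = x$n, n_merges = nrow(x$events),
         n_clusters = x$n - nrow(x$events), d_up = x$d_up,
         max_height = if (nrow(x$events)) max(x$events$distance) else NA_real_,
         distance_evals = x$evals, mode = x$mode, workers = x$workers)
}

# ---------------------------------------------------------------------------
# Round-based (literal multi-point) engine, exposed as a small state machine
# so its operations are individually testable.

#' Round-based clustering state
#'
#' Holds the space, the PBP tree over active clusters, and the NN table used
#' by the literal multi-point rounds ([merge_round()]).  Created internally
#' by `hc_multipoint(mode = "round")`; exported for conformance tests.
#'
#' @inheritParams hc_multipoint
#' @param built Internal pre-built space (alternative to `x`).
#' @return An environment-backed `pbp_hc_state`.
#' @keywords internal
#' @export
hc_state <- function(x = NULL, d_up, levels = 6L, slack = 0, radii = NULL,
                     params = distance_params(), linkage = NULL,
                     built = NULL) {
  built <- built %||% build_space(x, linkage, params)
  if (is.null(radii)) radii <- d_up / 2^(0:(levels - 1))
  st <- new.env(parent = emptyenv())
  st$space <- built$space
  st$n <- built$n
  st$d_up <- d_up
  st$tree <- structure(list(ptr = .tree_new(built$space$ptr, radii, slack),
                            space = built$space, radii = c(radii, 0),
                            slack = slack), class = "pbp_tree")
  st$item <- seq_len(built$n)
  st$active <- seq_len(built$n)
  st$next_id <- built$n + 1L
  st$events <- tibble(a = integer(), b = integer(), merged = integer(),
                      distance = numeric())
  for (i in seq_len(built$n)) .tree_insert(st$tree$ptr, i, i)
  st$nn <- state_search_nn(st, st$active)
  class(st) <- c("pbp_hc_state", class(st))
  st
}

state_search_nn <- function(st, ids) {
  res <- lapply(ids, function(id)
    .tree_nearest(st$tree$ptr, st$item[id], id, st$d_up))
  tibble(cluster = as.integer(ids),
         nn = vapply(res, function(r) as.integer(r$id), integer(1)),
         distance = vapply(res, function(r) r$distance, numeric(1)),
         state = "fresh")
}

#' Merge a round of disjoint cluster pairs
#'
#' Applies one multi-point round: pairs are processed in ascending
#' (distance, min id, max id) order; each pair is deleted from the tree,
#' merged into a new cluster with id `n + k`, and the merged representative
#' is inserted back.  NN records pointing at consumed clusters become stale
#' (their old distance is kept as a lower bound) in the state's table.
#'
#' @param st A [hc_state()].
#' @param pairs Tibble with columns `a`, `b`, `distance` (disjoint pairs, as
#'   produced by [mutual_nn_pairs()]).
#' @return The tibble of merge events appended in this round.
#' @export
merge_round <- function(st, pairs) {
  if (nrow(pairs) == 0) return(st$events[0, ])
  stopifnot(all(c(pairs$a, pairs$b) %in% st$active),
            !anyDuplicated(c(pairs$a, pairs$b)))
  pairs <- pairs[order(pairs$distance, pmin(pairs$a, pairs$b),
                       pmax(pairs$a, pairs$b)), ]
  new_events <- pairs[0, ]
  removed <- integer()
  for (i in seq_len(nrow(pairs))) {
    a <- min(pairs$a[i], pairs$b[i]); b <- max(pairs$a[i], pairs$b[i])
    .tree_delete(st$tree$ptr, a)
    .tree_delete(st$tree$ptr, b)
    m <- st$next_id
    st$next_id <- st$next_id + 1L
    st$item[m] <- space_merge_items(st$space, st$item[a], st$item[b])
    .tree_insert(st$tree$ptr, m, st$item[m])
    st$active <- c(setdiff(st$active, c(a, b)), m)
    removed <- c(removed, a, b)
    ev <- tibble(a = as.integer(a), b = as.integer(b),
                 merged = as.integer(m), distance = pairs$distance[i])
    st$events <- rbind(st$events, ev)
  }
  st$nn <- st$nn[!(st$nn$cluster %in% removed), ]
  stale <- st$nn$nn %in% removed
  st$nn$state[stale] <- "stale"
  invisible(utils::tail(st$events, nrow(pairs)))
}

run_hc_rounds <- function(st) {
  repeat {
    if (length(st$active) <= 1) break
    # refresh new clusters and records invalidated by the last round
    todo <- c(setdiff(st$active, st$nn$cluster),
              st$nn$cluster[st$nn$state == "stale"])
    if (length(todo) > 0) {
      st$nn <- st$nn[!(st$nn$cluster %in% todo), ]
      st$nn <- rbind(st$nn, state_search_nn(st, sort(todo)))
      st$nn <- st$nn[order(st$nn$cluster), ]
    }
    cand <- st$nn[is.finite(st$nn$distance), ]
    if (nrow(cand) == 0) break
    cand <- tie_break(cand)
    pairs <- mutual_nn_pairs(cand, st$d_up)
    if (nrow(pairs) == 0) break
    merge_round(st, pairs)
  }
  st$events
}

# ---------------------------------------------------------------------------

#' Mutual nearest-neighbour pairs
#'
#' Extracts from a fresh NN table all unordered pairs `{a, b}` with
#' `NN(a) = b`, `NN(b) = a` and distance below `d_up` - the set merged
#' together in one multi-point round.  The pairs are necessarily disjoint.
#'
#' @param nn Tibble with columns `cluster`, `nn`, `distance` and optionally
#'   `state` (all records must be `"fresh"`; a stale record is a contract
#'   violation).
#' @param d_up Stop distance.
#' @return Tibble with columns `a`, `b` (`a < b`) and `distance`, ordered by
#'   (distance, a, b).
#' @export
#' @examples
#' nn <- tibble::tibble(cluster = 1:4, nn = c(2L, 1L, 2L, 3L),
#'                      distance = c(1, 1, 2, 4))
#' mutual_nn_pairs(nn, d_up = 10)
mutual_nn_pairs <- function(nn, d_up) {
  if ("state" %in% names(nn) && any(nn$state != "fresh"))
    stop("stale NN record encountered; mutual pairs need a fresh table")
  idx <- match(nn$nn, nn$cluster)
  mutual <- !is.na(idx) & nn$nn[idx] == nn$cluster
  keep <- mutual & nn$cluster < nn$nn & nn$distance < d_up
  out <- tibble(a = as.integer(nn$cluster[keep]),
                b = as.integer(nn$nn[keep]),
                distance = nn$distance[keep])
  out[order(out$distance, out$a, out$b), ]
}

#' Tie-breaking pass over an NN table
#'
#' Equal NN distances can chain (`NN(a) = b`, `NN(b) = c`, `NN(c) = a` with
#' equal distances) so that no mutual pair exists and a round would stall.
#' The tie-break scans unpaired clusters in ascending id order; for an
#' unpaired `a` with `b = NN(a)`, if `b` is also unpaired and
#' `D(b, NN(b)) >= D(a, b)`, then `NN(b)` is forced to `a`, creating a
#' mergeable pair.  Records already in mutual pairs are never touched.
#'
#' @param nn Tibble with columns `cluster`, `nn`, `distance`.
#' @param paired Ids currently in mutual pairs (computed from `nn` if NULL).
#' @return The modified NN table.
#' @export
tie_break <- function(nn, paired = NULL) {
  if (is.null(paired)) {
    idx <- match(nn$nn, nn$cluster)
    mutual <- !is.na(idx) & nn$nn[idx] == nn$cluster
    paired <- nn$cluster[mutual]
  }
  rows <- order(nn$cluster)
  for (r in rows) {
    a <- nn$cluster[r]
    if (a %in% paired) next
    b <- nn$nn[r]
    rb <- match(b, nn$cluster)
    if (is.na(rb) || b %in% paired) next
    if (nn$distance[rb] >= nn$distance[r]) {
      nn$nn[rb] <- a
      nn$distance[rb] <- nn$distance[r]
      paired <- c(paired, a, b)
    }
  }
  nn
}

#' Delayed-update scheduling decision
#'
#' The decision rule of the event engine, as a pure function over the two
#' queues: merge the best candidate pair when its distance is strictly below
#' every stale lower bound (it is then the global minimum); otherwise
#' re-search a batch of stale records (smallest bounds first); report
#' completion when neither queue can produce a pair below `d_up`.
#'
#' @param candidates Tibble of fresh candidate pairs (`a`, `b`, `distance`).
#' @param stale Tibble of stale records (`cluster`, `bound`).
#' @param d_up Stop distance.
#' @param batch_size Maximum update batch (typically
#'   `batch_factor * workers`).
#' @return A list with `action` (`"merge"`, `"update"` or `"done"`) and
#'   either the pair (`a`, `b`, `distance`) or the ids to refresh.
#' @export
#' @examples
#' schedule_next(tibble::tibble(a = 1L, b = 2L, distance = 0.02),
#'               tibble::tibble(cluster = 3L, bound = 0.05),
#'               d_up = 0.15, batch_size = 40)
schedule_next <- function(candidates, stale, d_up, batch_size) {
  dstar <- Inf
  if (nrow(candidates) > 0) {
    ord <- order(candidates$distance, pmin(candidates$a, candidates$b),
                 pmax(candidates$a, candidates$b))
    candidates <- candidates[ord, ]
    dstar <- candidates$distance[1]
  }
  sbound <- if (nrow(stale) > 0) min(stale$bound) else Inf
  if (dstar < d_up && dstar < sbound) {
    return(list(action = "merge", a = candidates$a[1], b = candidates$b[1],
                distance = dstar))
  }
  if (sbound < d_up) {
    ids <- stale$cluster[order(stale$bound, stale$cluster)]
    return(list(action = "update",
                ids = ids[seq_len(min(length(ids), batch_size))]))
  }
  list(action = "done")
}

# ---------------------------------------------------------------------------

#' Cut a merge-event list into flat partitions
#'
#' Applies every merge event with distance strictly below each threshold and
#' reports the resulting partition of the original records.  Partition
#' labels are canonical: each OTU is labelled by its smallest member id.
#'
#' @param events Tetrad tibble (`a`, `b`, `merged`, `distance`) or a
#'   `pbp_hc` fit.
#' @param n Number of original records (taken from the fit if omitted).
#' @param thresholds Distance thresholds; must not exceed the `d_up` used to
#'   generate the events (deeper merges were never computed).
#' @param d_up The stop distance of the run (taken from the fit if given).
#' @return Tibble with columns `threshold`, `id` (record index 1..n) and
#'   `otu` (canonical label).
#' @export
#' @examples
#' ev <- tibble::tibble(a = 1L, b = 2L, merged = 4L, distance = 0.01)
#' cut_partitions(ev, n = 3, thresholds = c(0, 0.05))
cut_partitions <- function(events, n = NULL, thresholds, d_up = Inf) {
  if (inherits(events, "pbp_hc")) {
    n <- n %||% events$n
    d_up <- events$d_up
    events <- events$events
  }
  stopifnot(!is.null(n))
  if (any(thresholds > d_up))
    stop("threshold exceeds d_up: partitions beyond the stop distance were ",
         "never computed")
  ev <- events[order(events$distance, events$merged), , drop = FALSE]
  out <- vector("list", length(thresholds))
  for (ti in seq_along(thresholds)) {
    t <- thresholds[ti]
    keep <- ev$distance < t
    parent <- seq_len(n + nrow(ev))
    parent[ev$a[keep]] <- ev$merged[keep]
    parent[ev$b[keep]] <- ev$merged[keep]
    # resolve each leaf to its root with memoization
    root <- integer(n + nrow(ev))
    find_root <- function(i) {
      path <- integer()
      while (parent[i] != i && root[i] == 0L) {
        path <- c(path, i)
        i <- parent[i]
      }
      r <- if (root[i] != 0L) root[i] else i
      root[c(path, i)] <<- r
      r
    }
    lab_root <- vapply(seq_len(n), find_root, integer(1))
    canon <- stats::ave(seq_len(n), lab_root, FUN = min)
    out[[ti]] <- tibble(threshold = t, id = seq_len(n),
                        otu = as.integer(canon))
  }
  do.call(rbind, out)
}
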