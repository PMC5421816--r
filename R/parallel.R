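# Master-worker execution: each worker process holds a full replica of the
# records and an independently built PBP tree (same deterministic insertion
# order, hence identical structure).  The master decides merges; workers only
# answer NN queries.  All coupling flows through three message kinds: APPLY
# (ordered merge-event batches, buffered and flushed lazily before queries),
# QUERY/ANSWER (round-robin batches of cluster ids), and HALT.

worker_state <- new.env(parent = emptyenv())

.worker_init <- function(rebuild, d_up, radii, slack, batch, n) {
  sp <- rebuild_space(rebuild)
  worker_state$space <- sp
  worker_state$eng <- .eng_new(sp$ptr, radii, slack, d_up, batch, n)
  TRUE
}

.worker_apply <- function(a, b, m) {
  .eng_apply(worker_state$eng, as.integer(a), as.integer(b), as.integer(m))
  TRUE
}

.worker_query <- function(ids) {
  .eng_replica_query(worker_state$eng, as.integer(ids))
}

spawn_pool <- function(rebuild, d_up, radii, slack, batch_factor, workers) {
  cl <- tryCatch(
    parallel::makeCluster(workers, type = "FORK"),
    error = function(e) stop("worker startup failed: ", conditionMessage(e),
                             call. = FALSE))
  ok <- tryCatch({
    parallel::clusterCall(cl, .worker_init, rebuild, d_up, radii, slack,
                          as.integer(batch_factor) * as.integer(workers),
                          if (rebuild$kind == "point") nrow(rebuild$points)
                          else length(rebuild$seqs))
    TRUE
  }, error = function(e) {
    parallel::stopCluster(cl)
    stop("worker startup failed: ", conditionMessage(e), call. = FALSE)
  })
  pool <- new.env(parent = emptyenv())
  pool$cl <- cl
  pool$workers <- as.integer(workers)
  pool$buffer <- list(a = integer(), b = integer(), m = integer())
  pool$alive <- TRUE
  class(pool) <- "pbp_pool"
  pool
}

pool_push_event <- function(pool, a, b, m) {
  pool$buffer$a <- c(pool$buffer$a, a)
  pool$buffer$b <- c(pool$buffer$b, b)
  pool$buffer$m <- c(pool$buffer$m, m)
  invisible(pool)
}

pool_flush <- function(pool) {
  if (length(pool$buffer$a) > 0) {
    parallel::clusterCall(pool$cl, .worker_apply, pool$buffer$a,
                          pool$buffer$b, pool$buffer$m)
    pool$buffer <- list(a = integer(), b = integer(), m = integer())
  }
  invisible(pool)
}

#' Worker pool with replicated PBP trees
#'
#' `spawn_workers()` launches `workers` processes, each reading the full
#' record set and building its own PBP tree from the identical insertion
#' order, so every replica answers nearest-neighbour queries exactly as the
#' master would.  `broadcast_apply()` sends an ordered batch of merge events
#' to every replica; `dispatch_updates()` partitions a batch of cluster ids
#' round-robin across workers and collects one answer per id;
#' `halt_workers()` terminates the pool.  With `workers = 1` the clustering
#' engine bypasses the pool and runs in-process; the merge-event list is
#' identical either way.
#'
#' @param records Data frame of sequence records (`seq`, optional
#'   `abundance`) or a numeric point matrix.
#' @param d_up Stop distance (also the top tree radius).
#' @param workers Number of worker processes.
#' @param levels,slack Tree geometry, see [pbp_tree()].
#' @param batch_factor Scheduling batch factor (see [hc_multipoint()]).
#' @param params,linkage Passed to the space construction.
#' @return A `pbp_pool` handle.
#' @export
spawn_workers <- function(records, d_up, workers = 2L, levels = 6L,
                          slack = 0, batch_factor = 20L,
                          params = distance_params(), linkage = NULL) {
  built <- build_space(records, linkage, params)
  radii <- d_up / 2^(0:(levels - 1))
  spawn_pool(built$rebuild, d_up, radii, slack, batch_factor, workers)
}

#' @rdname spawn_workers
#' @param pool A `pbp_pool`.
#' @param ids Active cluster ids whose NN records should be recomputed.
#' @param .raw Return the bare (id, nn, distance) matrix instead of a tibble.
#' @export
dispatch_updates <- function(pool, ids, .raw = FALSE) {
  stopifnot(inherits(pool, "pbp_pool"), isTRUE(pool$alive))
  pool_flush(pool)
  ids <- as.integer(ids)
  if (length(ids) == 0) {
    out <- matrix(numeric(), 0, 4)
  } else {
    shard <- ((seq_along(ids) - 1L) %% pool$workers) + 1L
    parts <- split(ids, shard)
    ans <- parallel::clusterApply(pool$cl, parts, .worker_query)
    out <- do.call(rbind, ans)
    if (nrow(out) != length(ids))
      stop("lost worker answers: expected ", length(ids), " got ", nrow(out))
    out <- out[order(match(out[, 1], ids)), , drop = FALSE]
  }
  if (.raw) return(out)
  tibble(cluster = as.integer(out[, 1]), nn = as.integer(out[, 2]),
         distance = out[, 3])
}

#' @rdname spawn_workers
#' @param events Tetrad tibble of merge events (`a`, `b`, `merged`), applied
#'   on every replica in master order.
#' @export
broadcast_apply <- function(pool, events) {
  stopifnot(inherits(pool, "pbp_pool"), isTRUE(pool$alive))
  if (nrow(events) > 0)
    parallel::clusterCall(pool$cl, .worker_apply, events$a, events$b,
                          events$merged)
  invisible(pool)
}

#' @rdname spawn_workers
#' @export
halt_workers <- function(pool) {
  if (isTRUE(pool$alive)) {
    parallel::stopCluster(pool$cl)
    pool$alive <- FALSE
  }
  invisible(NULL)
}

#' @export
print.pbp_pool <- function(x, ...) {
  cat("<pbp_pool>", x$workers, "workers,",
      if (isTRUE(x$alive)) "alive" else "halted", "\n")
  invisible(x)
}
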