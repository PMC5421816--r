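#' Read a FASTA file of amplicon reads
#'
#' Wrapped sequence lines are joined and bases uppercased.  When
#' `parse_size = TRUE`, a trailing `;size=N` tag on the header (the usual
#' dereplication convention) is stripped and used as the record's abundance.
#'
#' @param path Path to a FASTA file.
#' @param parse_size Parse `;size=N` header tags into the abundance column.
#' @return Tibble with columns `id`, `seq` (and `abundance` when parsed).
#' @export
read_fasta <- function(path, parse_size = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  complain <- function(cond) {
    hdr <- fasta_offender(path)
    stop("malformed FASTA record", if (!is.na(hdr))
      paste0(" '", hdr, "'") else "", ": ", conditionMessage(cond),
      call. = FALSE)
  }
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path), error = complain),
    warning = function(w) {
      if (grepl("invalid", conditionMessage(w))) complain(w)
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(tibble(id = character(), seq = character()))
  }
  out <- tibble(id = names(set), seq = unname(toupper(as.character(set))))
  if (parse_size) {
    m <- regmatches(out$id, regexec(";size=([0-9]+)", out$id))
    out$abundance <- vapply(m, function(x)
      if (length(x) == 2) as.numeric(x[2]) else 1, numeric(1))
    out$id <- sub(";size=[0-9]+;?", "", out$id)
  }
  out
}

# best-effort identification of the record a FASTA parser choked on
fasta_offender <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !startsWith(lines[1], ">"))
    return(if (length(lines)) lines[1] else NA_character_)
  hdr <- NA_character_
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      hdr <- sub("^>", "", ln)
    } else if (grepl("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv-]", ln)) {
      return(hdr)
    }
  }
  NA_character_
}

#' Write sequences to FASTA
#'
#' @param x Tibble with `id` and `seq` (and optionally `abundance`, emitted
#'   as a `;size=N` header tag when `size_tag = TRUE`).
#' @param path Output path.
#' @param size_tag Append `;size=N` abundance tags to headers.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, size_tag = FALSE) {
  ids <- x$id
  if (size_tag && "abundance" %in% names(x))
    ids <- sprintf("%s;size=%d", ids, as.integer(x$abundance))
  set <- Biostrings::DNAStringSet(setNames(x$seq, ids))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Dereplicate identical reads
#'
#' Collapses exact duplicate sequences into one record whose abundance is
#' the duplicate count (summing any existing abundances).  The representative
#' id is the first-seen id and records keep first-occurrence order.  The
#' `members` list-column records the collapsed read ids, so every raw read
#' remains traceable to exactly one record.
#'
#' @param x Tibble with `id` and `seq` (optional `abundance`).
#' @return Tibble with `id`, `seq`, `abundance` and `members`.
#' @export
#' @examples
#' dereplicate(tibble::tibble(id = c("r1", "r2", "r3"),
#'                            seq = c("ACGT", "ACGT", "ACGA")))
dereplicate <- function(x) {
  if (nrow(x) == 0)
    return(tibble(id = character(), seq = character(),
                  abundance = numeric(), members = list()))
  ab <- if ("abundance" %in% names(x)) x$abundance else rep(1, nrow(x))
  first <- !duplicated(x$seq)
  grp <- match(x$seq, x$seq[first])
  tibble(
    id = x$id[first],
    seq = x$seq[first],
    abundance = as.numeric(tapply(ab, grp, sum)[as.character(seq_len(sum(first)))]),
    members = unname(split(x$id, grp))
  )
}

#' Length and primer filters
#'
#' Drops records whose length falls outside
#' `[min_len_frac, max_len_frac] * mean(length)` (mean over the input
#' records, unweighted) and, when a primer is given, records whose prefix
#' has more than `primer_max_mismatch` mismatches against the primer
#' (position-wise comparison over the primer length; IUPAC codes in the
#' primer match their base sets; a read shorter than the primer counts the
#' missing positions as mismatches).
#'
#' @param x Record tibble (`id`, `seq`, ...).
#' @param min_len_frac,max_len_frac Length window relative to the mean read
#'   length (defaults 0.8 and 1.25).
#' @param primer Optional primer sequence.
#' @param primer_max_mismatch Mismatch budget for the primer check.
#' @return List with `kept` (the surviving records) and `rejected`
#'   (tibble `id`, `reason`).
#' @export
filter_reads <- function(x, min_len_frac = 0.8, max_len_frac = 1.25,
                         primer = NULL, primer_max_mismatch = 2L) {
  stopifnot(min_len_frac > 0, min_len_frac <= 1, max_len_frac >= 1)
  if (nrow(x) == 0)
    return(list(kept = x, rejected = tibble(id = character(),
                                            reason = character())))
  len <- nchar(x$seq)
  mu <- mean(len)
  bad_len <- len < min_len_frac * mu | len > max_len_frac * mu
  reason <- ifelse(bad_len, sprintf("length %d outside [%.1f, %.1f]",
                                    len, min_len_frac * mu,
                                    max_len_frac * mu), NA_character_)
  if (!is.null(primer)) {
    mm <- vapply(x$seq, primer_mismatches, numeric(1), primer = primer,
                 USE.NAMES = FALSE)
    bad_primer <- is.na(reason) & mm > primer_max_mismatch
    reason[bad_primer] <- sprintf("primer mismatch %d > %d",
                                  mm[bad_primer], primer_max_mismatch)
  }
  keep <- is.na(reason)
  list(kept = x[keep, , drop = FALSE],
       rejected = tibble(id = x$id[!keep], reason = reason[!keep]))
}

primer_mismatches <- function(seq, primer) {
  p <- strsplit(toupper(primer), "")[[1]]
  s <- strsplit(toupper(seq), "")[[1]]
  mm <- max(0L, length(p) - length(s))
  n <- min(length(p), length(s))
  for (i in seq_len(n)) {
    set <- iupac_sets[[p[i]]]
    if (is.null(set)) stop("invalid primer base: ", p[i])
    base_set <- iupac_sets[[s[i]]] %||% s[i]
    if (!any(strsplit(base_set, "")[[1]] %in% strsplit(set, "")[[1]]))
      mm <- mm + 1L
  }
  mm
}

#' Write clustering outputs
#'
#' `<prefix>.cluster` holds the tetrad table, one merge step per line
#' (`a b merged distance`, distance with 6 decimals).  For each threshold,
#' `<prefix>.otu_<t>` holds one OTU per line: member record ids separated by
#' spaces, largest OTU first (ties by smallest member id).  Output is
#' byte-identical across reruns of the same input.
#'
#' @param events Tetrad tibble (or `pbp_hc` fit).
#' @param partitions Partition tibble from [cut_partitions()].
#' @param prefix Output path prefix.
#' @param ids Optional record id strings (index -> id); defaults to the
#'   fit's record ids or the plain indices.
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(events, partitions, prefix, ids = NULL) {
  if (inherits(events, "pbp_hc")) {
    ids <- ids %||% events$record_ids
    events <- events$events
  }
  files <- character()
  cl_file <- paste0(prefix, ".cluster")
  lines <- sprintf("%d %d %d %.6f", events$a, events$b, events$merged,
                   events$distance)
  writeLines(lines, cl_file)
  files <- c(files, cl_file)
  for (t in unique(partitions$threshold)) {
    part <- partitions[partitions$threshold == t, ]
    groups <- split(part$id, part$otu)
    size <- vapply(groups, length, integer(1))
    first <- vapply(groups, min, numeric(1))
    groups <- groups[order(-size, first)]
    lab <- function(i) if (is.null(ids)) as.character(i) else ids[i]
    lines <- vapply(groups, function(g)
      paste(lab(sort(g)), collapse = " "), character(1))
    f <- sprintf("%s.otu_%g", prefix, t)
    writeLines(unname(lines), f)
    files <- c(files, f)
  }
  invisible(files)
}

#' End-to-end OTU clustering pipeline
#'
#' FASTA (or record tibble) in; dereplication, optional length/primer
#' filtering, multi-point hierarchical clustering to `d_up`, and flat OTU
#' partitions at the requested thresholds out.  Stage counts are logged to
#' stderr.
#'
#' @param input FASTA path or a tibble with `id`/`seq` columns.
#' @param d_up Stop distance (1 - similarity; 0.15 matches the usual 85%
#'   similarity termination).
#' @param thresholds Partition thresholds (all `<= d_up`).
#' @param out_prefix If non-NULL, write the tetrad table and OTU files here.
#' @param filter Apply [filter_reads()] (lengths, and primer when given).
#' @param primer,primer_max_mismatch,min_len_frac,max_len_frac See
#'   [filter_reads()].
#' @param ... Passed to [hc_multipoint()] (workers, levels, slack, ...).
#' @return A `pbp_otu` list: `fit` (the `pbp_hc`), `records` (dereplicated),
#'   `rejected`, `partitions`, and `read_otus` (read-level OTU assignment
#'   per threshold).
#' @export
otu_pipeline <- function(input, d_up = 0.15,
                         thresholds = c(0.03, 0.05, 0.10),
                         out_prefix = NULL, filter = TRUE, primer = NULL,
                         primer_max_mismatch = 2L, min_len_frac = 0.8,
                         max_len_frac = 1.25, ...) {
  stopifnot(all(thresholds <= d_up))
  raw <- if (is.character(input)) read_fasta(input) else as_tibble(input)
  message("reads in: ", nrow(raw))
  rejected <- tibble(id = character(), reason = character())
  if (filter) {
    fl <- filter_reads(raw, min_len_frac, max_len_frac, primer,
                       primer_max_mismatch)
    raw <- fl$kept
    rejected <- fl$rejected
    message("after filters: ", nrow(raw), " kept, ", nrow(rejected),
            " rejected")
  }
  records <- dereplicate(raw)
  message("dereplicated: ", nrow(records), " unique records")
  fit <- hc_multipoint(records[, c("id", "seq", "abundance")], d_up = d_up,
                       ...)
  message("merges: ", nrow(fit$events), " (",
          format(fit$evals, big.mark = ","), " distance evaluations)")
  partitions <- cut_partitions(fit, thresholds = thresholds)
  read_otus <- do.call(rbind, lapply(unique(partitions$threshold),
    function(t) {
      part <- partitions[partitions$threshold == t, ]
      tibble(threshold = t,
             read = unlist(records$members),
             otu = rep(part$otu[match(seq_len(nrow(records)), part$id)],
                       lengths(records$members)))
    }))
  if (!is.null(out_prefix))
    write_outputs(fit, partitions, out_prefix, ids = records$id)
  structure(list(fit = fit, records = records, rejected = rejected,
                 partitions = partitions, read_otus = read_otus,
                 thresholds = thresholds),
            class = "pbp_otu")
}

#' @export
print.pbp_otu <- function(x, ...) {
  cat("<pbp_otu> ", nrow(x$records), " records, ", nrow(x$fit$events),
      " merges\n", sep = "")
  for (t in x$thresholds) {
    part <- x$partitions[x$partitions$threshold == t, ]
    cat(sprintf("  t = %-5g: %d OTUs\n", t, length(unique(part$otu))))
  }
  invisible(x)
}

#' OTU abundance vector at a threshold
#'
#' Abundance-expanded OTU sizes (each record contributes its abundance), the
#' input to the diversity estimators.
#'
#' @param x A `pbp_otu` pipeline result.
#' @param threshold One of the pipeline's thresholds.
#' @return Integer vector of per-OTU read counts.
#' @export
otu_abundances <- function(x, threshold) {
  part <- x$partitions[x$partitions$threshold == threshold, ]
  if (nrow(part) == 0) stop("threshold not in pipeline results")
  ab <- x$records$abundance[part$id]
  as.integer(tapply(ab, part$otu, sum))
}
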