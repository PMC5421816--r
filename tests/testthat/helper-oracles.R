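# Shared fixtures and independent oracles, built in code at test time.

DNA <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

mutate_seq <- function(s, k) {
  b <- strsplit(s, "")[[1]]
  pos <- sample(length(b), k)
  for (i in pos) b[i] <- sample(setdiff(DNA, b[i]), 1)
  paste(b, collapse = "")
}

# A small read set with known template structure (records are dereplicated).
random_instance <- function(n_reads = 30, n_templates = 4, len = 40,
                            sub_rate = 0.1) {
  tmpl <- replicate(n_templates, random_seq(len))
  reads <- vapply(sample(tmpl, n_reads, replace = TRUE), function(s) {
    b <- strsplit(s, "")[[1]]
    mut <- runif(len) < sub_rate
    b[mut] <- vapply(b[mut], function(x) sample(setdiff(DNA, x), 1), "")
    paste(b, collapse = "")
  }, "", USE.NAMES = FALSE)
  dereplicate(tibble::tibble(id = as.character(seq_along(reads)),
                             seq = reads))
}

# Independent full-matrix alignment oracle: plain-R Needleman-Wunsch over
# the complete DP table (no corridor), unit-style costs, normalized by the
# minimal alignment length among minimum-cost paths (lexicographic
# (cost, length) DP), matching the package's symmetric convention.
align_oracle <- function(a, b, mismatch = 1, gap = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  la <- length(A)
  lb <- length(B)
  C <- matrix(Inf, la + 1, lb + 1)
  L <- matrix(0L, la + 1, lb + 1)
  C[1, ] <- (0:lb) * gap
  L[1, ] <- 0:lb
  C[, 1] <- (0:la) * gap
  L[, 1] <- 0:la
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cd <- C[i, j] + if (A[i] == B[j]) 0 else mismatch
      cu <- C[i, j + 1] + gap
      cl <- C[i + 1, j] + gap
      cc <- cd; ll <- L[i, j] + 1L
      if (cu < cc || (cu == cc && L[i, j + 1] + 1L < ll)) {
        cc <- cu; ll <- L[i, j + 1] + 1L
      }
      if (cl < cc || (cl == cc && L[i + 1, j] + 1L < ll)) {
        cc <- cl; ll <- L[i + 1, j] + 1L
      }
      C[i + 1, j + 1] <- cc
      L[i + 1, j + 1] <- ll
    }
  }
  C[la + 1, lb + 1] / L[la + 1, lb + 1]
}

# Linear-scan NN oracle on a Euclidean point matrix.
scan_nn <- function(pts, q, exclude = q) {
  dd <- sqrt(colSums((t(pts) - pts[q, ])^2))
  dd[exclude] <- Inf
  best <- min(dd)
  list(id = which(dd == best)[1], distance = best)
}

# Canonical flat partition labels (cut_partitions labels each OTU by its
# smallest member, so identical labels <=> identical partitions).
partition_at <- function(events, n, t) {
  part <- cut_partitions(events, n, t)
  part$otu[order(part$id)]
}
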