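# Independent brute-force oracles used to validate the fast
# implementations. Kept deliberately naive.

# Exhaustive best-window oracle for the Mott trimmer: maximise the score
# sum over all (i, j); ties resolved toward the smallest end, then the
# smallest start. Returns list(sum, start, end) like mott_segment().
mott_oracle <- function(s) {
  n <- length(s)
  p <- c(0, cumsum(s))
  best <- list(sum = -Inf, start = NA_integer_, end = NA_integer_)
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      v <- p[j + 1] - p[i]
      if (v > best$sum + 1e-12) {
        best <- list(sum = v, start = i, end = j)
      }
    }
  }
  best
}

# Exhaustive SSR oracle: for every position and unit length, count
# maximal perfect repeats by direct string comparison; keep run starts
# with >= min_units complete units and atomic ACGT motifs; resolve
# overlaps leftmost-longest like the scanner.
ssr_oracle <- function(seq, min_units = 5, unit_lens = 2:6) {
  seq <- toupper(seq)
  n <- nchar(seq)
  at <- function(i, L) substr(seq, i, i + L - 1L)
  clean <- function(x) !grepl("[^ACGT]", x)
  cand <- list()
  for (u in unit_lens) {
    for (i in seq_len(max(0L, n - u * min_units + 1L))) {
      motif <- at(i, u)
      if (!clean(motif) || !bessurvey:::is_atomic_motif(motif)) next
      # maximality to the left: the preceding u bases must differ
      if (i > u && at(i - u, u) == motif) next
      if (i > 1 && i <= u) {
        # partial left context: previous base must break the period
        if (substr(seq, i - 1L, i - 1L) == substr(motif, u, u)) next
      }
      r <- 0L
      while (i + (r + 1L) * u - 1L <= n && at(i + r * u, u) == motif &&
             clean(at(i + r * u, u))) {
        r <- r + 1L
      }
      # extend over a partial trailing unit to measure the perfect run,
      # then truncate
      if (r >= min_units) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + r * u, motif = motif,
          unit_len = u, units = r)
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), unit_len = integer(),
                      units = integer()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, -(cand$end - cand$start), cand$unit_len), ]
  kept <- rep(FALSE, nrow(cand))
  iv <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (nrow(iv) == 0 || all(e <= iv[, 1] | s >= iv[, 2])) {
      kept[i] <- TRUE
      iv <- rbind(iv, c(s, e))
    }
  }
  out <- cand[kept, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# Per-base boolean-array union oracle for interval coverage
coverage_oracle <- function(start, end, size) {
  covered <- logical(size)
  for (i in seq_along(start)) {
    if (end[i] > start[i]) covered[(start[i] + 1):end[i]] <- TRUE
  }
  sum(covered)
}

random_reads <- function(n, len_range = c(80, 300), seed = NULL,
                         prefix = "r") {
  gen <- function() {
    lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    bes_reads(sprintf("%s%04d_F", prefix, seq_len(n)),
              vapply(lens, random_dna, character(1)))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# one-row hit tibble helper for classification tests
mk_hit <- function(chrom, sstart, send, strand, query_id = "c1_F",
                   score = 500, evalue = 1e-30) {
  tibble::tibble(query_id = query_id, subject_id = chrom,
                 identity = 99, aligned_columns = send - sstart,
                 identical_columns = send - sstart, mismatches = 0L,
                 gap_opens = 0L, qstart = 0L, qend = send - sstart,
                 sstart = sstart, send = send, strand = strand,
                 evalue = evalue, score = score)
}
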