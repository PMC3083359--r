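#' Quality-trim reads with the modified-Mott algorithm
#'
#' Each base contributes a score `error_threshold - 10^(-Q/10)`; the read
#' is trimmed to the contiguous segment maximising the score sum (ties
#' resolved toward the smallest end position, then the smallest start).
#' Reads whose best segment has non-positive score are emptied (and
#' dropped from the returned table). An `error_threshold` of 0.01
#' corresponds to the usual Q20 cutoff.
#'
#' @param reads A [bes_reads] tibble; all reads must carry qualities.
#' @param error_threshold Error-probability threshold.
#' @return The trimmed [bes_reads] tibble (reads trimmed to nothing are
#'   removed).
#' @export
quality_trim <- function(reads, error_threshold = 0.01) {
  if (nrow(reads) == 0) return(reads)
  if (anyNA(reads$qual)) {
    stop("quality_trim requires per-base qualities; ",
         "use FASTA mode (skip quality trimming) for quality-less reads")
  }
  quals <- string_to_quals(reads$qual)
  seg <- lapply(quals, function(q) {
    mott_segment(error_threshold - 10^(-q / 10))
  })
  keep <- vapply(seg, function(s) s$sum > 0, logical(1))
  out <- reads[keep, , drop = FALSE]
  if (nrow(out) > 0) {
    st <- vapply(seg[keep], `[[`, integer(1), "start")
    en <- vapply(seg[keep], `[[`, integer(1), "end")
    out$seq <- substr(out$seq, st, en)
    out$qual <- substr(out$qual, st, en)
  }
  out
}

# maximal-sum contiguous segment (1-based inclusive bounds);
# ties: smallest end, then smallest start (which, for equal prefix
# minima, is the longest segment ending there)
mott_segment <- function(s) {
  p <- cumsum(s)
  prev <- c(0, p[-length(p)])
  # prefix minimum of c(0, p)[1..j] = best start for segment ending at j
  pm <- cummin(prev)
  best_at <- p - pm
  j <- which.max(best_at)           # first maximal end
  i <- match(pm[j], c(0, p[seq_len(j - 1)]))  # first prefix achieving min
  list(sum = best_at[j], start = i, end = j)
}

#' Trim cloning-vector (or host) sequence from read ends
#'
#' Local alignments of each read against each vector sequence with a
#' score of at least `min_match` (match +1, mismatch -2, affine gaps) at
#' identity at least `min_identity`, touching within `end_window` bp of
#' either read end,
#' are removed; the longest remaining clean interior segment is retained.
#' A read that is entirely vector becomes empty and is dropped.
#'
#' @param reads A [bes_reads] tibble.
#' @param vectors Named character vector (or `DNAStringSet`) of vector /
#'   contaminant sequences.
#' @param min_match Minimum alignment score.
#' @param min_identity Minimum alignment identity (fraction).
#' @param end_window Hit must start/end within this many bp of a read end.
#' @return Trimmed [bes_reads] tibble.
#' @export
vector_trim <- function(reads, vectors, min_match = 16, min_identity = 0.9,
                        end_window = 25) {
  if (is(vectors, "DNAStringSet")) vectors <- as.character(vectors)
  stopifnot(length(vectors) >= 1)
  if (nrow(reads) == 0) return(reads)
  newseq <- reads$seq
  newqual <- reads$qual
  keep <- rep(TRUE, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rlen <- nchar(reads$seq[i])
    hits <- IRanges::IRanges()
    for (v in vectors) {
      probe <- reads$seq[i]
      for (round in 1:3) {  # a read can carry more than one vector patch
        aln <- local_align(c(v, revcomp(v)), Biostrings::DNAString(probe))
        sc <- Biostrings::score(aln)
        b <- which.max(sc)
        if (sc[b] < min_match) break
        pid <- Biostrings::pid(aln[b], type = "PID1")
        rng <- Biostrings::subject(aln[b])
        st <- Biostrings::start(rng); en <- Biostrings::end(rng)
        if (pid >= min_identity * 100) {
          hits <- c(hits, IRanges::IRanges(st, en))
        }
        substr(probe, st, en) <- strrep("N", en - st + 1L)
      }
    }
    if (length(hits) == 0) next
    hits <- IRanges::reduce(hits)
    # keep only hits anchored near a read end, extended to that end
    near_start <- IRanges::start(hits) <= end_window + 1L
    near_end <- IRanges::end(hits) >= rlen - end_window
    anchored <- hits[near_start | near_end]
    if (length(anchored) == 0) next
    IRanges::start(anchored)[IRanges::start(anchored) <= end_window + 1L] <- 1L
    IRanges::end(anchored)[IRanges::end(anchored) >= rlen - end_window] <- rlen
    clean <- IRanges::setdiff(IRanges::IRanges(1L, rlen),
                              IRanges::reduce(anchored))
    if (length(clean) == 0) {
      keep[i] <- FALSE
      next
    }
    best <- clean[which.max(IRanges::width(clean))]
    newseq[i] <- substr(reads$seq[i], IRanges::start(best), IRanges::end(best))
    if (!is.na(newqual[i])) {
      newqual[i] <- substr(reads$qual[i], IRanges::start(best),
                           IRanges::end(best))
    }
  }
  out <- reads[keep, , drop = FALSE]
  out$seq <- newseq[keep]
  out$qual <- newqual[keep]
  out
}

#' Drop reads shorter than a minimum length
#'
#' @param reads A [bes_reads] tibble.
#' @param min_len Minimum retained length (bp); the conventional survey
#'   floor is 50 bp.
#' @return Filtered [bes_reads] tibble.
#' @export
length_filter <- function(reads, min_len = 50) {
  reads[nchar(reads$seq) >= min_len, , drop = FALSE]
}

#' Remove redundant reads
#'
#' A read is redundant when a local alignment against another retained
#' read covers its full length at more than `identity` identity (either
#' strand). Of a mutually covering pair the longer read is kept; at equal
#' length the lexicographically earlier id is kept. Output order is
#' preserved.
#'
#' @param reads A [bes_reads] tibble (already length-filtered).
#' @param identity Identity fraction above which a fully covered read is
#'   dropped (strictly greater).
#' @param k,stride K-mer prefilter parameters (candidate pairs must share
#'   at least one k-mer).
#' @return `list(reads = retained bes_reads, removed = n removed,
#'   removed_ids = character)`.
#' @export
filter_redundant <- function(reads, identity = 0.95, k = 16, stride = 4) {
  n <- nrow(reads)
  if (n <= 1) return(list(reads = reads, removed = 0L,
                          removed_ids = character()))
  # candidate pairs via shared k-mers: stride-sampled (both strands)
  # joined against an every-position table so phase never hides a pair
  st <- rbindlist(lapply(seq_len(n), function(i) {
    s <- reads$seq[i]
    fw <- sample_kmers(s, k, stride)$kmer
    rv <- sample_kmers(revcomp(s), k, stride)$kmer
    data.table(idx = i, kmer = unique(c(fw, rv)))
  }))
  ft <- rbindlist(lapply(seq_len(n), function(i) {
    data.table(idx = i, kmer = sample_kmers(reads$seq[i], k, 1)$kmer)
  }))
  setkey(ft, kmer)
  pairs <- ft[st, on = "kmer", nomatch = 0L,
              allow.cartesian = TRUE][idx != i.idx,
                .N, by = .(a = pmin(idx, i.idx), b = pmax(idx, i.idx))]
  if (nrow(pairs) == 0) return(list(reads = reads, removed = 0L,
                                    removed_ids = character()))
  lens <- nchar(reads$seq)
  # rank: longer first, then id; a read is removed if covered by a
  # higher-ranked read that itself survives
  rnk <- order(-lens, reads$id)
  rank_of <- integer(n); rank_of[rnk] <- seq_len(n)
  removed <- rep(FALSE, n)
  covered_by <- function(a, b) {  # is read a fully covered by read b?
    subj <- Biostrings::DNAString(reads$seq[b])
    aln <- local_align(c(reads$seq[a], revcomp(reads$seq[a])), subj)
    for (j in 1:2) {
      rng <- Biostrings::pattern(aln[j])
      if (Biostrings::start(rng) == 1L &&
          Biostrings::end(rng) == lens[a] &&
          Biostrings::pid(aln[j], type = "PID1") > identity * 100) {
        return(TRUE)
      }
    }
    FALSE
  }
  ord <- pairs[order(pmin(rank_of[pairs$a], rank_of[pairs$b])), ]
  for (r in seq_len(nrow(ord))) {
    a <- ord$a[r]; b <- ord$b[r]
    if (rank_of[a] < rank_of[b]) { hi <- a; lo <- b } else { hi <- b; lo <- a }
    if (removed[hi] || removed[lo]) next
    if (covered_by(lo, hi)) removed[lo] <- TRUE
  }
  list(reads = reads[!removed, , drop = FALSE],
       removed = sum(removed),
       removed_ids = reads$id[removed])
}

#' Survey statistics for a set of cleaned BES
#'
#' @param reads Final [bes_reads] tibble.
#' @param n_input Optional raw read count (before any filtering).
#' @param n_after_trim Optional count surviving trimming.
#' @param n_redundant_removed Optional count removed as redundant.
#' @return A `survey_stats` list: counts, `total_bp`, `mean_len_bp`
#'   (rounded integer; `NA` and flagged when there are no reads),
#'   `min_len`/`max_len`, `gc_percent`/`at_percent` (1 decimal, ambiguity
#'   codes excluded from numerator and denominator), `n_mate_pairs`
#'   (clones with both ends surviving) and a 50-bp `length_histogram`.
#' @export
survey_stats <- function(reads, n_input = NULL, n_after_trim = NULL,
                         n_redundant_removed = NULL) {
  n <- nrow(reads)
  lens <- nchar(reads$seq)
  total_bp <- sum(lens)
  if (n == 0) {
    counts <- c(A = 0, C = 0, G = 0, T = 0)
  } else {
    af <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(reads$seq),
                                        collapse = TRUE)
    counts <- af[c("A", "C", "G", "T")]
  }
  acgt <- sum(counts)
  gc <- if (acgt > 0) round((counts[["C"]] + counts[["G"]]) / acgt * 100, 1)
        else NA_real_
  pairs_tbl <- if (n > 0) table(table(reads$clone_id[!is.na(reads$end)]))
               else NULL
  n_pairs <- if (!is.null(pairs_tbl) && "2" %in% names(pairs_tbl))
    as.integer(pairs_tbl[["2"]]) else 0L
  brk <- seq(0, max(c(lens, 50)) + 50, by = 50)
  hist_tbl <- tibble(
    bin_start = head(brk, -1),
    bin_end = brk[-1],
    n = as.integer(table(cut(lens, brk, right = TRUE, include.lowest = FALSE)))
  )
  structure(list(
    n_reads = n_input %||% n,
    n_after_trim = n_after_trim %||% n,
    n_redundant_removed = n_redundant_removed %||% 0L,
    n_final = n,
    total_bp = total_bp,
    mean_len_bp = if (n > 0) as.integer(round(total_bp / n)) else NA_integer_,
    undefined_mean = n == 0,
    min_len = if (n > 0) min(lens) else NA_integer_,
    max_len = if (n > 0) max(lens) else NA_integer_,
    gc_percent = gc,
    at_percent = if (!is.na(gc)) round(100 - gc, 1) else NA_real_,
    n_mate_pairs = n_pairs,
    length_histogram = hist_tbl
  ), class = "survey_stats")
}

#' @export
print.survey_stats <- function(x, ...) {
  cat("BES survey statistics\n")
  cat(sprintf("  reads in            %10d\n", x$n_reads))
  cat(sprintf("  after trimming      %10d\n", x$n_after_trim))
  cat(sprintf("  redundant removed   %10d\n", x$n_redundant_removed))
  cat(sprintf("  final reads         %10d\n", x$n_final))
  cat(sprintf("  total bp            %10.0f\n", x$total_bp))
  cat(sprintf("  mean length (bp)    %10s\n", x$mean_len_bp))
  cat(sprintf("  GC%% / AT%%           %.1f / %.1f\n",
              x$gc_percent, x$at_percent))
  cat(sprintf("  mate pairs          %10d\n", x$n_mate_pairs))
  invisible(x)
}

#' Survey statistics from published totals
#'
#' Reproduces the survey-table arithmetic (mean read length, trimming
#' success, retained counts) from totals alone, for summarising a survey
#' whose per-read data are not at hand.
#'
#' @param n_reads Raw sequencing read count.
#' @param n_bes Reads passing the minimum-length floor before trimming.
#' @param n_after_trim Reads surviving trimming.
#' @param n_redundant_removed Reads removed as redundant.
#' @param total_bp Total bases over the final read set.
#' @return A `survey_stats`-like list with `n_final`, `mean_len_bp`
#'   (rounded integer) and `trim_success_percent` (1 decimal, relative
#'   to `n_bes`).
#' @export
survey_stats_from_totals <- function(n_reads, n_bes = n_reads,
                                     n_after_trim,
                                     n_redundant_removed = 0,
                                     total_bp) {
  n_final <- n_after_trim - n_redundant_removed
  stopifnot(n_final >= 0, n_after_trim <= n_bes, n_bes <= n_reads)
  structure(list(
    n_reads = n_reads,
    n_bes = n_bes,
    n_after_trim = n_after_trim,
    n_redundant_removed = n_redundant_removed,
    n_final = n_final,
    total_bp = total_bp,
    mean_len_bp = if (n_final > 0) as.integer(round(total_bp / n_final))
                  else NA_integer_,
    undefined_mean = n_final == 0,
    min_len = NA_integer_, max_len = NA_integer_,
    gc_percent = NA_real_, at_percent = NA_real_,
    n_mate_pairs = NA_integer_,
    trim_success_percent = if (n_bes > 0)
      round(n_after_trim / n_bes * 100, 1) else NA_real_,
    length_histogram = NULL
  ), class = "survey_stats")
}

#' Run the full read-cleanup stage
#'
#' Quality trim (when qualities are present), vector trim (when vectors
#' are given), length filter, redundancy filter, and survey statistics.
#'
#' @param reads Raw [bes_reads] tibble.
#' @param vectors Optional vector/contaminant sequences.
#' @param error_threshold Mott threshold (0.01 = Q20).
#' @param min_len Minimum read length (bp).
#' @param identity Redundancy-filter identity.
#' @return `list(reads, stats, n_input, n_bes, n_after_trim,
#'   trim_success_percent)`.
#' @export
clean_reads <- function(reads, vectors = NULL, error_threshold = 0.01,
                        min_len = 50, identity = 0.95) {
  n_input <- nrow(reads)
  n_bes <- sum(nchar(reads$seq) >= min_len)
  r <- reads
  if (n_input > 0 && !anyNA(r$qual)) r <- quality_trim(r, error_threshold)
  if (!is.null(vectors)) r <- vector_trim(r, vectors)
  r <- length_filter(r, min_len)
  n_after_trim <- nrow(r)
  red <- filter_redundant(r, identity = identity)
  stats <- survey_stats(red$reads, n_input = n_input,
                        n_after_trim = n_after_trim,
                        n_redundant_removed = red$removed)
  list(reads = red$reads, stats = stats,
       n_input = n_input, n_bes = n_bes, n_after_trim = n_after_trim,
       trim_success_percent = if (n_bes > 0)
         round(n_after_trim / n_bes * 100, 1) else NA_real_)
}
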