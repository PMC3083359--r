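#' Find perfect microsatellites
#'
#' Scans for maximal perfect tandem repeats of atomic 2-6 bp motifs with
#' at least `min_units` complete units. Runs are broken at non-ACGT
#' characters. Partial trailing units are truncated (a 5.5-unit run is
#' reported as 5 units over exactly `units * unit_len` bp). Overlaps
#' between candidate calls of different unit lengths are resolved
#' leftmost-longest; non-atomic motif calls (e.g. an `ACAC` tetramer call
#' over an `AC` dinucleotide run) are never emitted.
#'
#' @param reads A [bes_reads] tibble, or a named/unnamed character vector
#'   of sequences.
#' @param min_units Minimum number of complete units (default 5).
#' @param unit_lens Motif lengths scanned (default 2:6).
#' @return Tibble of hits: `read_id`, `start`, `end` (0-based half-open),
#'   `motif` (as found), `canonical` (rotation/reverse-complement class
#'   representative), `unit_len`, `units`, `left_flank_bp`,
#'   `right_flank_bp`.
#' @export
find_ssrs <- function(reads, min_units = 5, unit_lens = 2:6) {
  stopifnot(all(unit_lens >= 2), all(unit_lens <= 6), min_units >= 1)
  if (is.character(reads)) {
    ids <- names(reads) %||% paste0("seq", seq_along(reads))
    reads <- tibble(id = ids, seq = unname(reads))
  }
  if (nrow(reads) == 0) return(ssr_hit_skeleton())
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    h <- find_ssrs_one(toupper(reads$seq[i]), min_units, unit_lens)
    if (nrow(h) > 0) h$read_id <- reads$id[i]
    h
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(ssr_hit_skeleton())
  out$canonical <- vapply(out$motif, canonical_motif, character(1))
  out[, c("read_id", "start", "end", "motif", "canonical", "unit_len",
          "units", "left_flank_bp", "right_flank_bp")]
}

ssr_hit_skeleton <- function() {
  tibble(read_id = character(), start = integer(), end = integer(),
         motif = character(), canonical = character(),
         unit_len = integer(), units = integer(),
         left_flank_bp = integer(), right_flank_bp = integer())
}

find_ssrs_one <- function(seq, min_units, unit_lens) {
  n <- nchar(seq)
  empty <- tibble(start = integer(), end = integer(), motif = character(),
                  unit_len = integer(), units = integer(),
                  left_flank_bp = integer(), right_flank_bp = integer())
  if (n < 2 * min(unit_lens)) return(empty)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- v %in% c("A", "C", "G", "T")
  cand <- list()
  for (u in unit_lens) {
    if (n < u * min_units) next
    m <- n - u
    if (m < 1) next
    eq <- (v[seq_len(m)] == v[(u + 1):n]) & ok[seq_len(m)] & ok[(u + 1):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run_len <- r$lengths[j] + u          # perfect-run length in bp
      units <- run_len %/% u
      if (units < min_units) next
      st <- starts[j]                       # 1-based run start
      motif <- substr(seq, st, st + u - 1L)
      if (!is_atomic_motif(motif)) next
      cand[[length(cand) + 1L]] <- tibble(
        start = st - 1L, end = st - 1L + units * u, motif = motif,
        unit_len = u, units = units)
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- bind_rows(cand)
  # leftmost-longest greedy overlap resolution (span desc, then shorter
  # unit first for determinism)
  cand <- cand[order(cand$start, -(cand$end - cand$start), cand$unit_len), ]
  kept <- logical(nrow(cand))
  last_end <- -1L
  # greedy scan: keep a candidate iff it does not overlap any kept one
  kept_iv <- IRanges::IRanges()
  for (i in seq_len(nrow(cand))) {
    iv <- to_iranges(cand$start[i], cand$end[i])
    if (length(IRanges::findOverlaps(iv, kept_iv)) == 0) {
      kept[i] <- TRUE
      kept_iv <- c(kept_iv, iv)
    }
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out$left_flank_bp <- out$start
  out$right_flank_bp <- n - out$end
  out
}

#' Canonical microsatellite motif
#'
#' The representative of a motif's equivalence class: the lexicographic
#' minimum over all rotations of the motif and all rotations of its
#' reverse complement (so `TG`, `GT`, `CA` and `AC` all map to `AC`).
#'
#' @param motif Atomic motif of length 2-6.
#' @return Canonical motif string.
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  L <- nchar(motif)
  stopifnot(L >= 2, L <= 6)
  if (!is_atomic_motif(motif)) {
    stop("motif '", motif, "' is not atomic")
  }
  rots <- function(x) {
    vapply(seq_len(L), function(i)
      paste0(substr(x, i, L), substr(x, 1, i - 1L)), character(1))
  }
  min(c(rots(motif), rots(revcomp(motif))))
}

#' Check flank sufficiency for primer design
#'
#' An SSR is primer-designable when both flanks are at least
#' `min_flank_bp` long and neither flank is repeat-masked (lowercase or
#' `N`) over half or more of its length.
#'
#' @param hits SSR hit tibble from [find_ssrs()].
#' @param reads A [bes_reads] tibble (sequences may be soft-masked).
#' @param min_flank_bp Minimum flank length (bp).
#' @return Logical vector (one element per hit).
#' @export
flank_check <- function(hits, reads, min_flank_bp = 50) {
  if (nrow(hits) == 0) return(logical())
  seqs <- setNames(reads$seq, reads$id)
  vapply(seq_len(nrow(hits)), function(i) {
    s <- seqs[[hits$read_id[i]]]
    n <- nchar(s)
    lf <- hits$start[i]
    rf <- n - hits$end[i]
    if (lf < min_flank_bp || rf < min_flank_bp) return(FALSE)
    masked_frac <- function(x) {
      if (nchar(x) == 0) return(0)
      v <- strsplit(x, "", fixed = TRUE)[[1]]
      mean(v %in% c("a", "c", "g", "t", "n", "N"))
    }
    masked_frac(substr(s, 1, lf)) < 0.5 &&
      masked_frac(substr(s, hits$end[i] + 1L, n)) < 0.5
  }, logical(1))
}

#' Microsatellite census
#'
#' @param hits SSR hit tibble, optionally with a logical `designable`
#'   column (see [flank_check()]).
#' @return An `ssr_census` list: `n_reads_with_ssr`, `n_ssrs`, `by_unit`
#'   tibble (unit length, count, percent to 2 decimals of all SSRs),
#'   `by_motif` tibble (canonical motif, count, descending) and
#'   `n_primer_designable`.
#' @export
ssr_census <- function(hits) {
  n <- nrow(hits)
  by_unit <- tibble(unit_len = 2:6,
                    n = vapply(2:6, function(u) sum(hits$unit_len == u),
                               integer(1)))
  by_unit$percent <- if (n > 0) round(by_unit$n / n * 100, 2) else 0
  by_motif <- if (n > 0) {
    bm <- as_tibble(table(canonical = hits$canonical))
    names(bm)[2] <- "n"
    bm$n <- as.integer(bm$n)
    bm[order(-bm$n, bm$canonical), ]
  } else {
    tibble(canonical = character(), n = integer())
  }
  structure(list(
    n_reads_with_ssr = length(unique(hits$read_id)),
    n_ssrs = n,
    by_unit = by_unit,
    by_motif = by_motif,
    n_primer_designable = if ("designable" %in% names(hits))
      sum(hits$designable) else NA_integer_
  ), class = "ssr_census")
}

#' @export
print.ssr_census <- function(x, ...) {
  cat("SSR census:", x$n_ssrs, "microsatellites in", x$n_reads_with_ssr,
      "reads\n")
  lab <- c("di", "tri", "tetra", "penta", "hexa")
  for (i in seq_len(nrow(x$by_unit))) {
    cat(sprintf("  %-6s %6d (%.2f%%)\n", lab[i], x$by_unit$n[i],
                x$by_unit$percent[i]))
  }
  if (!is.na(x$n_primer_designable)) {
    cat("  primer-designable:", x$n_primer_designable, "\n")
  }
  invisible(x)
}
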