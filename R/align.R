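KA_K <- 0.71
KA_LAMBDA <- 1.37

#' Build an exact k-mer seed index over a reference
#'
#' Positions are indexed on the plus strand only; minus-strand hits are
#' found at query time by reverse-complementing the query. K-mers
#' occurring more than `max_occ` times are dropped from the index
#' (repeat seeds), the usual seeding heuristic.
#'
#' @param reference Named character vector of chromosome sequences (or
#'   `DNAStringSet`, or a `ref_genome` / `sample_genome`).
#' @param k Seed length, in `[10, 20]`.
#' @param max_occ Per-k-mer occurrence cap.
#' @return A `bes_index` object.
#' @export
build_index <- function(reference, k = 14, max_occ = 50) {
  stopifnot(k >= 10, k <= 20)
  if (inherits(reference, "ref_genome") ||
      inherits(reference, "sample_genome")) {
    reference <- reference$seqs
  }
  if (is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  if (length(reference) == 0 || sum(nchar(reference)) == 0) {
    stop("empty reference")
  }
  tabs <- lapply(names(reference), function(cn) {
    s <- toupper(reference[[cn]])
    n <- nchar(s)
    if (n < k) return(NULL)
    st <- seq_len(n - k + 1L)
    data.table(kmer = substring(s, st, st + k - 1L), chrom = cn,
               pos = st - 1L)  # 0-based
  })
  dt <- rbindlist(tabs)
  dt <- dt[!grepl("[^ACGT]", kmer)]
  cnt <- dt[, .N, by = kmer]
  hot <- cnt[N > max_occ, kmer]
  if (length(hot)) dt <- dt[!kmer %in% hot]
  setkey(dt, kmer)
  structure(list(seeds = dt, k = k,
                 seqs = setNames(toupper(reference), names(reference)),
                 chrom_lens = setNames(nchar(reference), names(reference)),
                 total_bp = sum(nchar(reference))),
            class = "bes_index")
}

#' @export
print.bes_index <- function(x, ...) {
  cat("bes_index: k =", x$k, ";", length(x$seqs), "sequence(s),",
      x$total_bp, "bp,", nrow(x$seeds), "indexed seed positions\n")
  invisible(x)
}

#' Align queries to an indexed reference (seed and extend)
#'
#' Exact k-mer seeds (sampled along the query on both strands) are
#' grouped into diagonal bands per chromosome; each band is extended by
#' local alignment (match +1, mismatch -2, gap open 5, gap extend 2) of
#' the query against the banded reference window. An e-value-like
#' expectation `K*m*n*exp(-lambda*S)` (K = 0.71, lambda = 1.37) is
#' attached to every hit; only its cutoff behaviour is meaningful, it is
#' not a calibrated BLAST e-value.
#'
#' @param queries A [bes_reads] tibble or named character vector.
#' @param index A `bes_index` from [build_index()].
#' @param min_score Minimum alignment score to report.
#' @param stride Query seed sampling stride (bp).
#' @param min_seeds Minimum seeds supporting a band.
#' @param max_loci Maximum bands extended per query and strand.
#' @param band_width Diagonal tolerance when grouping seeds (bp).
#' @return Hit tibble (0-based half-open coordinates, `sstart < send`
#'   always, strand explicit): `query_id`, `subject_id`, `identity`,
#'   `aligned_columns`, `identical_columns`, `mismatches`, `gap_opens`,
#'   `qstart`, `qend`, `sstart`, `send`, `strand`, `evalue`, `score`.
#' @export
align_bes <- function(queries, index, min_score = 30, stride = 10,
                      min_seeds = 2, max_loci = 10, band_width = 100) {
  stopifnot(inherits(index, "bes_index"))
  if (is.data.frame(queries)) {
    queries <- setNames(queries$seq, queries$id)
  }
  queries <- toupper(queries)
  k <- index$k
  out <- hit_skeleton()
  if (length(queries) == 0) return(out)
  qlens <- nchar(queries)
  short <- qlens < k
  # seed table over both query orientations
  qk <- rbindlist(lapply(seq_along(queries), function(i) {
    if (short[i]) return(NULL)
    fw <- sample_kmers(queries[[i]], k, stride)
    rv <- sample_kmers(revcomp(queries[[i]]), k, stride)
    rbindlist(list(
      data.table(qid = i, orient = "+", qpos = fw$qpos, kmer = fw$kmer),
      data.table(qid = i, orient = "-", qpos = rv$qpos, kmer = rv$kmer)))
  }))
  if (is.null(qk) || nrow(qk) == 0) return(out)
  seeds <- index$seeds[qk, on = "kmer", nomatch = 0L,
                       allow.cartesian = TRUE]
  if (nrow(seeds) == 0) return(out)
  seeds[, diag := pos - qpos]
  seeds[, band := round(diag / band_width)]
  # merge adjacent bands by also crediting each seed to band+1
  bands <- seeds[, .(nseed = .N, dmin = min(diag), dmax = max(diag)),
                 by = .(qid, orient, chrom, band)]
  bands <- bands[nseed >= min_seeds | vapply(qid, function(i)
    qlens[i] < 3 * k, logical(1))]
  if (nrow(bands) == 0) return(out)
  bands <- bands[order(qid, orient, chrom, -nseed, band)]
  bands <- bands[, head(.SD, max_loci), by = .(qid, orient)]
  rows <- vector("list", nrow(bands))
  for (r in seq_len(nrow(bands))) {
    i <- bands$qid[r]
    orient <- bands$orient[r]
    cn <- bands$chrom[r]
    qseq <- if (orient == "+") queries[[i]] else revcomp(queries[[i]])
    qlen <- qlens[i]
    clen <- index$chrom_lens[[cn]]
    w0 <- max(0L, bands$dmin[r] - band_width)
    w1 <- min(clen, bands$dmax[r] + qlen + band_width)
    if (w1 - w0 < k) next
    win <- substr(index$seqs[[cn]], w0 + 1L, w1)
    aln <- local_align(qseq, Biostrings::DNAString(win))
    sc <- Biostrings::score(aln)
    if (sc < min_score) next
    prng <- Biostrings::pattern(aln)
    srng <- Biostrings::subject(aln)
    nmat <- Biostrings::nmatch(aln)
    nmis <- Biostrings::nmismatch(aln)
    cols <- aln_columns(aln)
    qs <- Biostrings::start(prng) - 1L   # 0-based on oriented query
    qe <- Biostrings::end(prng)
    if (orient == "-") { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
    rows[[r]] <- tibble(
      query_id = names(queries)[i], subject_id = cn,
      identity = round(nmat / cols * 100, 2),
      aligned_columns = cols, identical_columns = nmat,
      mismatches = nmis, gap_opens = aln_gap_opens(aln),
      qstart = qs, qend = qe,
      sstart = w0 + Biostrings::start(srng) - 1L,
      send = w0 + Biostrings::end(srng),
      strand = orient,
      evalue = KA_K * qlen * index$total_bp * exp(-KA_LAMBDA * sc),
      score = sc)
  }
  hits <- bind_rows(rows)
  if (nrow(hits) == 0) return(out)
  dedupe_hits(hits)
}

hit_skeleton <- function() {
  tibble(query_id = character(), subject_id = character(),
         identity = double(), aligned_columns = integer(),
         identical_columns = integer(), mismatches = integer(),
         gap_opens = integer(), qstart = integer(), qend = integer(),
         sstart = integer(), send = integer(), strand = character(),
         evalue = double(), score = double())
}

# drop duplicate hits of the same locus (same query/chrom/strand with
# >=50% subject overlap), keeping the best score
dedupe_hits <- function(hits) {
  hits <- hits[order(hits$query_id, -hits$score, hits$evalue,
                     hits$subject_id, hits$sstart), ]
  keep <- rep(TRUE, nrow(hits))
  grp <- paste(hits$query_id, hits$subject_id, hits$strand)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    kept <- IRanges::IRanges()
    for (i in idx) {
      iv <- to_iranges(hits$sstart[i], hits$send[i])
      ov <- IRanges::intersect(iv, kept)
      if (sum(IRanges::width(ov)) >= 0.5 * IRanges::width(iv)) {
        keep[i] <- FALSE
      } else {
        kept <- IRanges::reduce(c(kept, iv))
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Read / write BLAST-style 12-column tabular alignments
#'
#' The canonical tab-separated dialect: query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send
#' (1-based inclusive; minus strand encoded as sstart > send), e-value,
#' bit score. Internally coordinates are 0-based half-open with an
#' explicit strand column; `identical_columns` is reconstructed as
#' `round(identity * length / 100)`.
#'
#' @param path Tabular file.
#' @return Hit tibble (see [align_bes()]).
#' @export
read_blast_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(hit_skeleton())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad) > 0) {
    stop("malformed tabular line ", bad[1], ": expected 12 columns, got ",
         lengths(parts)[bad[1]])
  }
  m <- do.call(rbind, parts)
  s1 <- as.integer(m[, 9]); s2 <- as.integer(m[, 10])
  strand <- ifelse(s1 <= s2, "+", "-")
  tibble(
    query_id = m[, 1], subject_id = m[, 2],
    identity = as.numeric(m[, 3]),
    aligned_columns = as.integer(m[, 4]),
    identical_columns = as.integer(round(as.numeric(m[, 3]) *
                                           as.integer(m[, 4]) / 100)),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]) - 1L, qend = as.integer(m[, 8]),
    sstart = pmin(s1, s2) - 1L, send = pmax(s1, s2),
    strand = strand,
    evalue = as.numeric(m[, 11]), score = as.numeric(m[, 12]))
}

#' @rdname read_blast_tabular
#' @param hits Hit tibble.
#' @export
write_blast_tabular <- function(hits, path) {
  s1 <- ifelse(hits$strand == "+", hits$sstart + 1L, hits$send)
  s2 <- ifelse(hits$strand == "+", hits$send, hits$sstart + 1L)
  lines <- paste(hits$query_id, hits$subject_id,
                 format_num(hits$identity), hits$aligned_columns,
                 hits$mismatches, hits$gap_opens,
                 hits$qstart + 1L, hits$qend, s1, s2,
                 format_num(hits$evalue), format_num(hits$score),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, trim = TRUE), character(1))
}

#' Select the top hit per query
#'
#' Hits passing the e-value cutoff are ranked per query by score
#' (descending), e-value (ascending), aligned columns (descending), then
#' subject chromosome and start (lexicographic) for full determinism;
#' the best is kept. `n_unique` counts queries with exactly one passing
#' hit before selection.
#'
#' @param hits Hit tibble.
#' @param evalue_cutoff Maximum e-value.
#' @return A `top_hits` list: `hits` (one row per query), `n_queries_hit`,
#'   `n_unique`.
#' @export
select_top_hits <- function(hits, evalue_cutoff = 1e-5) {
  passing <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(passing) == 0) {
    return(structure(list(hits = hit_skeleton(), n_queries_hit = 0L,
                          n_unique = 0L), class = "top_hits"))
  }
  per_query <- table(passing$query_id)
  ord <- order(passing$query_id, -passing$score, passing$evalue,
               -passing$aligned_columns, passing$subject_id,
               passing$sstart)
  passing <- passing[ord, , drop = FALSE]
  best <- passing[!duplicated(passing$query_id), , drop = FALSE]
  structure(list(hits = best,
                 n_queries_hit = length(per_query),
                 n_unique = sum(per_query == 1L)),
            class = "top_hits")
}

#' @export
print.top_hits <- function(x, ...) {
  cat("top_hits:", x$n_queries_hit, "queries with a passing hit (",
      x$n_unique, "unique )\n")
  invisible(x)
}

#' Identity summary of top hits
#'
#' The mean is site-weighted — total identical columns over total aligned
#' columns — which is what a printed count of identical sites implies;
#' the histogram is per-hit over 1%-wide bins spanning 75-100%.
#'
#' @param hits Hit tibble or `top_hits`.
#' @return List: `mean_identity_percent` (1 decimal; `NA` and flagged for
#'   an empty set), `total_aligned`, `total_identical`, `histogram`
#'   tibble (`bin_lo`, `n`).
#' @export
identity_summary <- function(hits) {
  if (inherits(hits, "top_hits")) hits <- hits$hits
  if (nrow(hits) == 0) {
    return(list(mean_identity_percent = NA_real_, undefined = TRUE,
                total_aligned = 0, total_identical = 0,
                histogram = tibble(bin_lo = 75:100, n = 0L)))
  }
  ta <- sum(hits$aligned_columns)
  ti <- sum(hits$identical_columns)
  b <- pmin(pmax(floor(hits$identity), 75), 100)
  hist_tbl <- tibble(bin_lo = 75:100,
                     n = vapply(75:100, function(x) sum(b == x), integer(1)))
  list(mean_identity_percent = round(ti / ta * 100, 1),
       undefined = FALSE,
       total_aligned = ta, total_identical = ti,
       histogram = hist_tbl)
}
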