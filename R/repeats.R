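repeat_families <- c("DNA", "LINE", "SINE", "LTR", "Satellite", "Simple",
                     "LowComplexity", "Unknown")

repeat_library_tbl <- function(id, family, seq) {
  stopifnot(!anyDuplicated(id), all(nchar(seq) > 0),
            all(family %in% repeat_families))
  tibble(id = as.character(id), family = as.character(family),
         seq = toupper(as.character(seq)))
}

#' Merge repeat libraries non-redundantly
#'
#' Combines one or more repeat libraries and drops the shorter member of
#' every pair that aligns at >= `identity` identity over >= `coverage` of
#' the shorter sequence's length (either strand). The result is ordered
#' by descending length, then id.
#'
#' @param libs A repeat-library tibble (`id`, `family`, `seq`) or a list
#'   of them.
#' @param identity Identity fraction (inclusive).
#' @param coverage Fraction of the shorter sequence that must be covered
#'   (inclusive).
#' @return Merged repeat-library tibble.
#' @export
merge_repeat_libraries <- function(libs, identity = 0.95, coverage = 0.95) {
  if (is.data.frame(libs)) libs <- list(libs)
  stopifnot(length(libs) >= 1)
  lib <- bind_rows(libs)
  if (anyDuplicated(lib$id)) {
    lib$id <- make.unique(lib$id, sep = "_dup")
  }
  lib <- lib[order(-nchar(lib$seq), lib$id), , drop = FALSE]
  n <- nrow(lib)
  if (n <= 1) return(lib)
  lens <- nchar(lib$seq)
  kt <- rbindlist(lapply(seq_len(n), function(i) {
    fw <- sample_kmers(lib$seq[i], 16, 4)$kmer
    rv <- sample_kmers(revcomp(lib$seq[i]), 16, 4)$kmer
    data.table(idx = i, kmer = unique(c(fw, rv)))
  }))
  setkey(kt, kmer)
  pairs <- unique(kt[kt, on = "kmer", allow.cartesian = TRUE][idx < i.idx,
                     .(a = idx, b = i.idx)])
  keep <- rep(TRUE, n)
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(pairs$b, pairs$a), ]
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$a[r]; b <- pairs$b[r]  # a ranks higher (longer/earlier)
      if (!keep[a] || !keep[b]) next
      subj <- Biostrings::DNAString(lib$seq[a])
      aln <- local_align(c(lib$seq[b], revcomp(lib$seq[b])), subj)
      for (j in 1:2) {
        rng <- Biostrings::pattern(aln[j])
        cov <- (Biostrings::end(rng) - Biostrings::start(rng) + 1L) / lens[b]
        if (cov >= coverage &&
            Biostrings::pid(aln[j], type = "PID1") >= identity * 100) {
          keep[b] <- FALSE
          break
        }
      }
    }
  }
  lib[keep, , drop = FALSE]
}

#' Mask reads against a repeat library
#'
#' Every local alignment of a library entry against a read (either
#' strand) scoring at least `min_score` becomes a repeat hit. Hit
#' intervals are unioned per read before masking (soft = lowercase,
#' hard = `N`). Divergence is the percentage of substituted columns among
#' aligned non-gap columns, a proxy for repeat age.
#'
#' @param reads A [bes_reads] tibble.
#' @param library Repeat-library tibble (`id`, `family`, `seq`).
#' @param min_score Minimum alignment score (match +1, mismatch -2,
#'   affine gaps). The default keeps false masking of random sequence
#'   effectively at zero.
#' @param soft Lowercase-mask (`TRUE`) or hard-mask with `N` (`FALSE`).
#' @param k,stride K-mer prefilter parameters.
#' @return `list(reads = masked bes_reads, hits = RepeatHit tibble,
#'   summary = repeat_summary)`.
#' @export
mask_repeats <- function(reads, library, min_score = 30, soft = TRUE,
                         k = 12, stride = 4) {
  total_bp <- sum(nchar(reads$seq))
  if (nrow(library) == 0) {
    warning("empty repeat library: nothing masked")
    return(list(reads = reads, hits = repeat_hit_skeleton(),
                summary = repeat_summary(repeat_hit_skeleton(), total_bp)))
  }
  hits <- repeat_hit_skeleton()
  if (nrow(reads) > 0) {
    rt <- rbindlist(lapply(seq_len(nrow(reads)), function(i) {
      km <- sample_kmers(toupper(reads$seq[i]), k, stride)$kmer
      data.table(read_idx = i, kmer = unique(km))
    }))
    lt <- rbindlist(lapply(seq_len(nrow(library)), function(e) {
      fw <- sample_kmers(library$seq[e], k, 1)$kmer
      rv <- sample_kmers(revcomp(library$seq[e]), k, 1)$kmer
      data.table(lib_idx = e, kmer = unique(c(fw, rv)))
    }))
    setkey(lt, kmer)
    cand <- unique(rt[lt, on = "kmer", nomatch = 0L,
                      allow.cartesian = TRUE][, .(read_idx, lib_idx)])
    rows <- list()
    if (nrow(cand) > 0) {
      cand <- cand[order(cand$read_idx, cand$lib_idx), ]
      for (r in seq_len(nrow(cand))) {
        i <- cand$read_idx[r]; e <- cand$lib_idx[r]
        probe <- toupper(reads$seq[i])
        pat <- c(library$seq[e], revcomp(library$seq[e]))
        for (round in 1:3) {
          aln <- local_align(pat, Biostrings::DNAString(probe))
          sc <- Biostrings::score(aln)
          b <- which.max(sc)
          if (sc[b] < min_score) break
          rng <- Biostrings::subject(aln[b])
          st <- Biostrings::start(rng); en <- Biostrings::end(rng)
          nmat <- Biostrings::nmatch(aln[b])
          nmis <- Biostrings::nmismatch(aln[b])
          rows[[length(rows) + 1L]] <- tibble(
            read_id = reads$id[i], read_start = st - 1L, read_end = en,
            library_id = library$id[e], family = library$family[e],
            strand = if (b == 1) "+" else "-",
            divergence = round(nmis / (nmat + nmis) * 100, 2),
            score = sc[b])
          substr(probe, st, en) <- strrep("N", en - st + 1L)
        }
      }
    }
    if (length(rows) > 0) hits <- bind_rows(rows)
  }
  masked <- reads
  if (nrow(hits) > 0) {
    for (rid in unique(hits$read_id)) {
      i <- match(rid, masked$id)
      h <- hits[hits$read_id == rid, ]
      iv <- IRanges::reduce(to_iranges(h$read_start, h$read_end))
      s <- masked$seq[i]
      for (j in seq_along(iv)) {
        a <- IRanges::start(iv)[j]; b <- IRanges::end(iv)[j]
        piece <- substr(s, a, b)
        substr(s, a, b) <- if (soft) tolower(piece)
                           else strrep("N", b - a + 1L)
      }
      masked$seq[i] <- s
    }
  }
  list(reads = masked, hits = hits,
       summary = repeat_summary(hits, total_bp))
}

repeat_hit_skeleton <- function() {
  tibble(read_id = character(), read_start = integer(),
         read_end = integer(), library_id = character(),
         family = character(), strand = character(),
         divergence = double(), score = double())
}

#' Summarise repeat masking
#'
#' Overlapping hits are unioned per read before any bp total, so family
#' totals can never exceed the masked total.
#'
#' @param hits RepeatHit tibble.
#' @param total_bp Total bp of the read set the hits came from.
#' @return A `repeat_summary` list: `masked_bp`, `masked_percent`
#'   (1 decimal), `by_family` (unioned bp and percent per family) and
#'   `divergence_histogram` (2%-wide bins per family).
#' @export
repeat_summary <- function(hits, total_bp) {
  union_bp <- function(h) {
    if (nrow(h) == 0) return(0L)
    sum(vapply(split(h, h$read_id), function(x)
      union_width(x$read_start, x$read_end), integer(1)))
  }
  masked_bp <- union_bp(hits)
  fams <- sort(unique(hits$family))
  by_family <- tibble(
    family = fams,
    bp = vapply(fams, function(f) union_bp(hits[hits$family == f, ]),
                integer(1), USE.NAMES = FALSE))
  by_family$percent <- if (total_bp > 0)
    round(by_family$bp / total_bp * 100, 2) else 0
  bins <- seq(0, 100, by = 2)
  dh <- if (nrow(hits) > 0) {
    b <- pmin(floor(hits$divergence / 2) * 2, 98)
    as_tibble(table(family = hits$family, bin_lo = b))
  } else {
    tibble(family = character(), bin_lo = character(), n = integer())
  }
  names(dh)[3] <- "n"
  dh$bin_lo <- as.numeric(dh$bin_lo)
  dh$n <- as.integer(dh$n)
  dh <- dh[dh$n > 0, ]
  structure(list(masked_bp = masked_bp,
                 masked_percent = if (total_bp > 0)
                   round(masked_bp / total_bp * 100, 1) else 0,
                 total_bp = total_bp,
                 by_family = by_family,
                 divergence_histogram = dh),
            class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("repeat masking: %d / %d bp (%.1f%%)\n", x$masked_bp,
              x$total_bp, x$masked_percent))
  for (i in seq_len(nrow(x$by_family))) {
    cat(sprintf("  %-14s %8d bp (%.2f%%)\n", x$by_family$family[i],
                x$by_family$bp[i], x$by_family$percent[i]))
  }
  invisible(x)
}

#' Scan unmasked reads for transposon-protein homology
#'
#' Reads are translated in all six frames, frames are broken at stop
#' codons into fragments of at least `min_orf_aa` residues, and fragments
#' are locally aligned (BLOSUM62, gap open 11 / extend 1) against a
#' transposon-protein library. The best hit per read with score >=
#' `min_score` is reported.
#'
#' @param reads A [bes_reads] tibble.
#' @param proteins Named character vector (or `AAStringSet`) of
#'   transposon proteins.
#' @param min_score Minimum alignment score.
#' @param min_orf_aa Minimum fragment length (aa).
#' @return Tibble: `read_id`, `protein_id`, `frame` (1-3 plus strand,
#'   4-6 minus), `score`, `fragment_aa`.
#' @export
transposon_protein_scan <- function(reads, proteins, min_score = 60,
                                    min_orf_aa = 20) {
  if (is(proteins, "AAStringSet")) {
    proteins <- setNames(as.character(proteins), names(proteins))
  }
  stopifnot(length(proteins) >= 1, !is.null(names(proteins)))
  out <- tibble(read_id = character(), protein_id = character(),
                frame = integer(), score = double(),
                fragment_aa = integer())
  if (nrow(reads) == 0) return(out)
  frags <- rbindlist(lapply(seq_len(nrow(reads)), function(i) {
    six_frame_fragments(toupper(reads$seq[i]), min_orf_aa, reads$id[i])
  }), fill = TRUE)
  if (nrow(frags) == 0) return(out)
  # 4-mer amino-acid word prefilter
  aa_words <- function(s) {
    n <- nchar(s)
    if (n < 4) return(character())
    unique(substring(s, 1:(n - 3), 4:n))
  }
  ft <- rbindlist(lapply(seq_len(nrow(frags)), function(j)
    data.table(fidx = j, kmer = aa_words(frags$aa[j]))))
  pt <- rbindlist(lapply(seq_along(proteins), function(e)
    data.table(pidx = e, kmer = aa_words(proteins[[e]]))))
  setkey(pt, kmer)
  cand <- unique(ft[pt, on = "kmer", nomatch = 0L,
                    allow.cartesian = TRUE][, .(fidx, pidx)])
  if (nrow(cand) == 0) return(out)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  blosum <- get("BLOSUM62", envir = data_env)
  rows <- lapply(seq_len(nrow(cand)), function(r) {
    j <- cand$fidx[r]; e <- cand$pidx[r]
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(frags$aa[j]),
      subject = Biostrings::AAString(proteins[[e]]),
      type = "local", substitutionMatrix = blosum,
      gapOpening = 11, gapExtension = 1)
    tibble(read_id = frags$read_id[j], protein_id = names(proteins)[e],
           frame = frags$frame[j], score = Biostrings::score(aln),
           fragment_aa = nchar(frags$aa[j]))
  })
  hits <- bind_rows(rows)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  if (nrow(hits) == 0) return(out)
  # best hit per read (ties: protein id, frame)
  hits <- hits[order(hits$read_id, -hits$score, hits$protein_id,
                     hits$frame), ]
  hits[!duplicated(hits$read_id), , drop = FALSE]
}

six_frame_fragments <- function(seq, min_orf_aa, read_id) {
  res <- list()
  for (strand in 1:2) {
    s <- if (strand == 1) seq else revcomp(seq)
    for (f in 1:3) {
      n <- nchar(s) - f + 1L
      if (n < 3 * min_orf_aa) next
      sub <- substr(s, f, f + (n %/% 3L) * 3L - 1L)
      aa <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X")))
      for (p in strsplit(aa, "*", fixed = TRUE)[[1]]) {
        if (nchar(p) >= min_orf_aa) {
          res[[length(res) + 1L]] <- data.table(
            read_id = read_id, frame = (strand - 1L) * 3L + f, aa = p)
        }
      }
    }
  }
  rbindlist(res)
}

#' De novo repeat discovery by frequent k-mer extension
#'
#' A deliberately simple discoverer: the most frequent k-mer with at
#' least `min_copies` occurrences seeds a candidate, which is extended
#' column by column in both directions while the consensus base is
#' supported by at least `min_copies` occurrences. Candidates are emitted
#' as family `Unknown` and made non-redundant with
#' [merge_repeat_libraries()].
#'
#' @param reads A [bes_reads] tibble.
#' @param k Seed k-mer length, in `[12, 32]`.
#' @param min_copies Minimum seed count and consensus support.
#' @param max_candidates Safety cap on emitted candidates.
#' @return Repeat-library tibble of candidates (possibly empty).
#' @export
discover_repeats_kmer <- function(reads, k = 16, min_copies = 10,
                                  max_candidates = 50) {
  stopifnot(k >= 12, k <= 32, min_copies >= 2)
  empty <- repeat_library_tbl(character(), character(), character())
  if (nrow(reads) == 0) return(empty)
  seqs <- toupper(reads$seq)
  dt <- rbindlist(lapply(seq_along(seqs), function(i) {
    n <- nchar(seqs[i])
    if (n < k) return(NULL)
    st <- seq_len(n - k + 1L)
    data.table(read_idx = i, pos = st,
               kmer = substring(seqs[i], st, st + k - 1L))
  }))
  dt <- dt[!grepl("[^ACGT]", kmer)]
  cands <- character()
  while (length(cands) < max_candidates && nrow(dt) > 0) {
    cnt <- dt[, .N, by = kmer][order(-N, kmer)]
    if (cnt$N[1] < min_copies) break
    seed <- cnt$kmer[1]
    occ <- dt[kmer == seed, .(read_idx, pos)]
    ext <- extend_consensus(seqs, occ, k, min_copies)
    cands <- c(cands, ext$consensus)
    # retire k-mers overlapping the extended occurrence spans
    spans <- data.table(read_idx = occ$read_idx,
                        lo = occ$pos - ext$left - k + 1L,
                        hi = occ$pos + k - 1L + ext$right)
    dt <- dt[!spans, on = .(read_idx, pos >= lo, pos <= hi)]
  }
  if (length(cands) == 0) return(empty)
  lib <- repeat_library_tbl(sprintf("denovo%03d", seq_along(cands)),
                            "Unknown", cands)
  merge_repeat_libraries(lib)
}

# greedy consensus extension of seed occurrences in both directions
extend_consensus <- function(seqs, occ, k, min_copies) {
  lens <- nchar(seqs)
  grow <- function(dirn) {
    active <- seq_len(nrow(occ))
    out <- character()
    d <- 0L
    repeat {
      d <- d + 1L
      p <- if (dirn < 0) occ$pos[active] - d
           else occ$pos[active] + k - 1L + d
      inb <- p >= 1L & p <= lens[occ$read_idx[active]]
      if (!any(inb)) break
      b <- substring(seqs[occ$read_idx[active][inb]], p[inb], p[inb])
      tb <- sort(table(b), decreasing = TRUE)
      cons <- names(tb)[1]
      support <- tb[[1]]
      if (support < min_copies || !cons %in% c("A", "C", "G", "T")) break
      out <- c(out, cons)
      active <- active[inb][b == cons]
      if (length(active) < min_copies) break
    }
    out
  }
  left <- grow(-1L)
  right <- grow(+1L)
  seed_seq <- substring(seqs[occ$read_idx[1]], occ$pos[1],
                        occ$pos[1] + k - 1L)
  list(consensus = paste0(paste(rev(left), collapse = ""), seed_seq,
                          paste(right, collapse = "")),
       left = length(left), right = length(right))
}
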