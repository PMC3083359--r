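clone_categories <- c("paired_ends", "long_pair", "mate_reverse",
                      "unmate", "singleton", "unmapped")

#' Classify one clone from its two end hits
#'
#' Decision tree over the top hits of the forward and reverse end: no
#' hits = unmapped; one = singleton; different chromosomes = unmate; same
#' chromosome but orientation-inconsistent = mate_reverse; consistent and
#' facing-end gap <= `max_separation` = paired_ends, else long_pair.
#' Orientation-consistent means the two ends map inward on opposite
#' strands (leftmost hit on plus, rightmost on minus), the physically
#' coherent layout of one insert. The gap is measured between the facing
#' ends of the two hit intervals; the span (present only for
#' paired_ends) runs outermost to outermost.
#'
#' @param fhit,rhit Single-row hit tibbles (or `NULL`/empty for a missing
#'   end). Passing more than one hit per end is an error: select top
#'   hits first.
#' @param clone_id Optional clone id (else derived from the hit query).
#' @param max_separation Maximum facing-end gap (bp) for paired_ends.
#' @return One-row tibble: `clone_id`, `category`, `chrom`,
#'   `span_start`, `span_end`, `gap`, plus the per-end hit coordinates.
#' @export
classify_clone <- function(fhit, rhit, clone_id = NULL,
                           max_separation = 300000) {
  norm <- function(h) {
    if (is.null(h) || (is.data.frame(h) && nrow(h) == 0)) return(NULL)
    stopifnot(is.data.frame(h))
    if (nrow(h) > 1) {
      stop("more than one hit supplied for a single end; ",
           "select top hits first")
    }
    h
  }
  fhit <- norm(fhit); rhit <- norm(rhit)
  if (is.null(clone_id)) {
    qid <- c(fhit$query_id, rhit$query_id)[1]
    clone_id <- if (is.null(qid)) NA_character_ else sub("_[FR]$", "", qid)
  }
  row <- tibble(clone_id = clone_id, category = NA_character_,
                chrom = NA_character_, span_start = NA_integer_,
                span_end = NA_integer_, gap = NA_integer_,
                f_chrom = fhit$subject_id %||% NA_character_,
                f_start = fhit$sstart %||% NA_integer_,
                f_end = fhit$send %||% NA_integer_,
                f_strand = fhit$strand %||% NA_character_,
                r_chrom = rhit$subject_id %||% NA_character_,
                r_start = rhit$sstart %||% NA_integer_,
                r_end = rhit$send %||% NA_integer_,
                r_strand = rhit$strand %||% NA_character_)
  if (is.null(fhit) && is.null(rhit)) {
    row$category <- "unmapped"
  } else if (is.null(fhit) || is.null(rhit)) {
    row$category <- "singleton"
  } else if (fhit$subject_id != rhit$subject_id) {
    row$category <- "unmate"
  } else {
    if (fhit$sstart <= rhit$sstart) { left <- fhit; right <- rhit }
    else { left <- rhit; right <- fhit }
    inward <- left$strand == "+" && right$strand == "-"
    if (!inward) {
      row$category <- "mate_reverse"
    } else {
      gap <- right$sstart - left$send
      row$gap <- as.integer(gap)
      if (gap <= max_separation) {
        row$category <- "paired_ends"
        row$chrom <- fhit$subject_id
        row$span_start <- min(fhit$sstart, rhit$sstart)
        row$span_end <- max(fhit$send, rhit$send)
      } else {
        row$category <- "long_pair"
      }
    }
  }
  row
}

#' Classify all clones from a top-hit set
#'
#' Clone and end identity is taken from the `<clone>_F` / `<clone>_R`
#' query-id convention. Clones listed in `clones` but absent from the
#' hits are reported as unmapped.
#'
#' @param top_hits A `top_hits` object or a one-hit-per-query tibble.
#' @param clones Optional character vector of all sequenced clone ids.
#' @param max_separation Paired-end gap threshold (bp).
#' @return `list(classifications = tibble, summary = mate-pair summary
#'   tibble)`; see [mate_pair_summary()].
#' @export
classify_clones <- function(top_hits, clones = NULL,
                            max_separation = 300000) {
  hits <- if (inherits(top_hits, "top_hits")) top_hits$hits else top_hits
  if (nrow(hits) > 0 && anyDuplicated(hits$query_id)) {
    stop("multiple hits per query; select top hits first")
  }
  ends <- sub("^.*_([FR])$", "\\1", hits$query_id)
  cl <- sub("_[FR]$", "", hits$query_id)
  all_clones <- sort(unique(c(cl, clones)))
  rows <- lapply(all_clones, function(cid) {
    classify_clone(hits[cl == cid & ends == "F", , drop = FALSE],
                   hits[cl == cid & ends == "R", , drop = FALSE],
                   clone_id = cid, max_separation = max_separation)
  })
  classifications <- bind_rows(rows)
  if (nrow(classifications) == 0) {
    classifications <- classify_clone(NULL, NULL, clone_id = "x")[0, ]
  }
  list(classifications = classifications,
       summary = mate_pair_summary(classifications))
}

#' Mate-pair mapping summary
#'
#' Clone and BES counts per category plus mapped/unmapped/total rows.
#' Two-hit categories contribute two BES per clone, singletons one.
#'
#' @param classifications Classification tibble from [classify_clones()].
#' @return Tibble with columns `category`, `n_clones`, `n_bes`.
#' @export
mate_pair_summary <- function(classifications) {
  cnt <- function(cat) sum(classifications$category == cat)
  per <- tibble(category = clone_categories,
                n_clones = vapply(clone_categories, cnt, integer(1),
                                  USE.NAMES = FALSE))
  per$n_bes <- ifelse(per$category %in%
                        c("paired_ends", "long_pair", "mate_reverse",
                          "unmate"),
                      2L * per$n_clones,
                      ifelse(per$category == "singleton", per$n_clones,
                             2L * per$n_clones))
  mapped <- per[per$category != "unmapped", ]
  bind_rows(
    tibble(category = "mapped", n_clones = sum(mapped$n_clones),
           n_bes = sum(mapped$n_bes)),
    per,
    tibble(category = "total", n_clones = sum(per$n_clones),
           n_bes = sum(per$n_bes)))
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom, to_iranges(genes$start, genes$end),
                         gene_id = genes$gene_id, coding = genes$coding)
}

#' Annotate an aligned interval against gene models
#'
#' `coding` if the interval overlaps (by >= 1 bp) any protein-coding gene
#' span, introns included; else `noncoding` if it overlaps a non-coding
#' gene; else `intergenic`. Coding takes precedence when both overlap.
#'
#' @param chrom,start,end Parallel vectors of intervals (0-based
#'   half-open).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `coding`).
#' @return Character vector in `{coding, noncoding, intergenic}`.
#' @export
annotate_interval <- function(chrom, start, end, genes) {
  if (length(chrom) == 0) return(character())
  if (nrow(genes) == 0) return(rep("intergenic", length(chrom)))
  q <- GenomicRanges::GRanges(chrom, to_iranges(start, end))
  g <- genes_to_granges(genes)
  out <- rep("intergenic", length(q))
  ov <- GenomicRanges::findOverlaps(q, g)
  if (length(ov) > 0) {
    hit_coding <- tapply(genes$coding[S4Vectors::subjectHits(ov)],
                         S4Vectors::queryHits(ov), any)
    idx <- as.integer(names(hit_coding))
    out[idx] <- ifelse(hit_coding, "coding", "noncoding")
  }
  out
}

#' Annotate a hit table's subject intervals
#'
#' @param hits Hit tibble (uses `subject_id`, `sstart`, `send`).
#' @param genes Gene tibble.
#' @return Character vector, one annotation per hit.
#' @export
annotate_end <- function(hits, genes) {
  annotate_interval(hits$subject_id, hits$sstart, hits$send, genes)
}

#' Build and type microsyntenies
#'
#' One microsynteny per paired-ends clone: both end hits lie on one
#' chromosome, inward-facing, within the separation threshold. The type
#' follows the unordered pair of end annotations: 1 coding/coding,
#' 2 coding/noncoding, 3 noncoding/noncoding, 4 coding/intergenic,
#' 5 noncoding/intergenic, 6 intergenic/intergenic (the remainder class
#' completing the partition).
#'
#' @param classifications Classification tibble from [classify_clones()].
#' @param genes Gene tibble.
#' @return `list(microsyntenies = tibble, type_counts = tibble)`.
#' @export
build_microsyntenies <- function(classifications, genes) {
  pe <- classifications[classifications$category == "paired_ends", ,
                        drop = FALSE]
  if (nrow(pe) == 0) {
    ms <- tibble(clone_id = character(), chrom = character(),
                 span_start = integer(), span_end = integer(),
                 ann_f = character(), ann_r = character(),
                 type = integer())
    return(list(microsyntenies = ms,
                type_counts = tibble(type = 1:6, n = 0L)))
  }
  ann_f <- annotate_interval(pe$f_chrom, pe$f_start, pe$f_end, genes)
  ann_r <- annotate_interval(pe$r_chrom, pe$r_start, pe$r_end, genes)
  pair_type <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "/")
    switch(key,
           "coding/coding" = 1L,
           "coding/noncoding" = 2L,
           "noncoding/noncoding" = 3L,
           "coding/intergenic" = 4L,
           "intergenic/noncoding" = 5L,
           "intergenic/intergenic" = 6L)
  }
  type <- mapply(pair_type, ann_f, ann_r, USE.NAMES = FALSE)
  ms <- tibble(clone_id = pe$clone_id, chrom = pe$chrom,
               span_start = pe$span_start, span_end = pe$span_end,
               ann_f = ann_f, ann_r = ann_r, type = as.integer(type))
  type_counts <- tibble(type = 1:6,
                        n = vapply(1:6, function(t) sum(ms$type == t),
                                   integer(1)))
  list(microsyntenies = ms, type_counts = type_counts)
}

#' Per-chromosome physical coverage
#'
#' Covered bp is the length of the union of spans per chromosome
#' (overlaps counted once); a Total row sums the columns and recomputes
#' the percentage from the totals.
#'
#' @param spans Tibble with `chrom`, `span_start`, `span_end` (0-based
#'   half-open), e.g. microsyntenies or paired-end spans.
#' @param chrom_sizes Named numeric vector, or two-column data frame
#'   (chromosome, size), covering every chromosome referenced.
#' @return Coverage tibble: `chrom`, `size_bp`, `covered_bp`, `n_clones`,
#'   `coverage_percent` (2 decimals), with a final `Total` row.
#' @export
chromosome_coverage <- function(spans, chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2]]),
                            as.character(chrom_sizes[[1]]))
  }
  unknown <- setdiff(unique(spans$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    stop("span(s) reference unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  }
  per <- lapply(names(chrom_sizes), function(cn) {
    sp <- spans[spans$chrom == cn, , drop = FALSE]
    tibble(chrom = cn, size_bp = chrom_sizes[[cn]],
           covered_bp = as.numeric(union_width(sp$span_start,
                                               sp$span_end)),
           n_clones = nrow(sp))
  })
  tab <- bind_rows(per)
  stopifnot(all(tab$covered_bp <= tab$size_bp))
  tab$coverage_percent <- round(tab$covered_bp / tab$size_bp * 100, 2)
  total <- tibble(chrom = "Total", size_bp = sum(tab$size_bp),
                  covered_bp = sum(tab$covered_bp),
                  n_clones = sum(tab$n_clones))
  total$coverage_percent <- round(total$covered_bp / total$size_bp * 100, 2)
  out <- bind_rows(tab, total)
  class(out) <- c("coverage_table", class(out))
  out
}

#' Genes with a BES hit in an exon
#'
#' A gene is counted once when at least one aligned BES interval overlaps
#' (>= 1 bp) at least one of its exons; intronic-only hits do not count.
#'
#' @param hits Hit tibble (top hits).
#' @param exons Exon tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param genes Optional gene tibble; when given, only protein-coding
#'   genes are considered.
#' @return Sorted character vector of gene ids.
#' @export
exon_gene_hits <- function(hits, exons, genes = NULL) {
  if (nrow(hits) == 0 || nrow(exons) == 0) return(character())
  if (!is.null(genes)) {
    exons <- exons[exons$gene_id %in% genes$gene_id[genes$coding], ,
                   drop = FALSE]
    if (nrow(exons) == 0) return(character())
  }
  q <- GenomicRanges::GRanges(hits$subject_id,
                              to_iranges(hits$sstart, hits$send))
  e <- GenomicRanges::GRanges(exons$chrom,
                              to_iranges(exons$start, exons$end))
  ov <- GenomicRanges::findOverlaps(q, e)
  sort(unique(exons$gene_id[S4Vectors::subjectHits(ov)]))
}
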