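#' Simulate a reference genome with annotation
#'
#' Generates random chromosome sequences (A/T-rich by default) and plants
#' non-overlapping gene models, repeat-family copies and perfect
#' microsatellites, returning both the sequences and a full annotation of
#' what was planted. The object stands in for an annotated reference
#' assembly when exercising the survey pipeline.
#'
#' @param chrom_sizes Named integer vector of chromosome sizes (bp),
#'   each >= 10 kb.
#' @param n_genes Number of gene models to plant.
#' @param coding_fraction Fraction of genes flagged protein-coding.
#' @param gene_len_range,exon_count_range Gene span (bp) and exon count
#'   ranges.
#' @param n_repeat_families Number of repeat-family consensus sequences to
#'   invent (classes drawn from DNA/LINE/SINE/LTR).
#' @param n_repeat_copies Number of repeat copies planted genome-wide.
#' @param repeat_len_range Family consensus length range (bp).
#' @param repeat_divergence Per-site substitution rate applied to each
#'   planted copy relative to its consensus.
#' @param n_ssrs Number of perfect microsatellites planted.
#' @param ssr_motifs Motifs to draw from (2-6 bp, atomic).
#' @param ssr_units_range Repeat-unit count range (>= 5).
#' @param base_comp Background base composition.
#' @param seed Optional integer seed; fixed seed gives byte-identical
#'   output.
#' @param max_tries Placement attempts per feature before giving up.
#' @return A `ref_genome` list: `seqs` (named character), `genes`, `exons`,
#'   `repeats`, `ssrs` tibbles (0-based half-open coordinates) and
#'   `repeat_library`.
#' @export
simulate_reference <- function(chrom_sizes,
                               n_genes = 0,
                               coding_fraction = 0.8,
                               gene_len_range = c(1000, 8000),
                               exon_count_range = c(2, 6),
                               n_repeat_families = 3,
                               n_repeat_copies = 0,
                               repeat_len_range = c(200, 1200),
                               repeat_divergence = 0.1,
                               n_ssrs = 0,
                               ssr_motifs = c("AC", "AT", "AG", "AAT", "AAGT"),
                               ssr_units_range = c(6, 15),
                               base_comp = c(A = 0.316, C = 0.184,
                                             G = 0.184, T = 0.316),
                               seed = NULL,
                               max_tries = 200) {
  stopifnot(length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)),
            !anyDuplicated(names(chrom_sizes)), all(chrom_sizes >= 10000),
            n_genes >= 0, n_repeat_copies >= 0, n_ssrs >= 0,
            ssr_units_range[1] >= 5,
            all(nchar(ssr_motifs) >= 2), all(nchar(ssr_motifs) <= 6))
  if (!all(vapply(ssr_motifs, is_atomic_motif, logical(1)))) {
    stop("ssr_motifs must be atomic (not repetitions of a shorter motif)")
  }
  run <- function() {
    seqs <- vapply(chrom_sizes, random_dna, character(1),
                   base_comp = base_comp)
    names(seqs) <- names(chrom_sizes)
    occupied <- lapply(chrom_sizes, function(x) IRanges::IRanges())

    place <- function(len) {
      for (i in seq_len(max_tries)) {
        chrom <- sample(names(chrom_sizes), 1, prob = chrom_sizes)
        clen <- chrom_sizes[[chrom]]
        if (clen < len + 2) next
        start <- sample.int(clen - len, 1) - 1L  # 0-based
        cand <- to_iranges(start, start + len)
        if (length(IRanges::findOverlaps(cand, occupied[[chrom]])) == 0) {
          occupied[[chrom]] <<- c(occupied[[chrom]], cand)
          return(list(chrom = chrom, start = start, end = start + len))
        }
      }
      stop("could not place a feature of length ", len,
           " without overlap after ", max_tries, " tries")
    }

    genes <- exons <- NULL
    if (n_genes > 0) {
      grows <- vector("list", n_genes)
      erows <- vector("list", n_genes)
      for (g in seq_len(n_genes)) {
        len <- rint(gene_len_range[1], gene_len_range[2])
        loc <- place(len)
        gid <- sprintf("gene%04d", g)
        m <- rint(exon_count_range[1], exon_count_range[2])
        # first exon starts at the gene start, last ends at the gene end
        brk <- sort(sample(seq(20L, len - 20L), 2L * (m - 1L)))
        es <- c(0L, brk[seq(2, length(brk), by = 2)])
        ee <- c(brk[seq(1, length(brk), by = 2)], len)
        grows[[g]] <- tibble(
          gene_id = gid, chrom = loc$chrom, start = loc$start, end = loc$end,
          strand = sample(c("+", "-"), 1),
          coding = runif(1) < coding_fraction)
        erows[[g]] <- tibble(gene_id = gid, chrom = loc$chrom,
                             start = loc$start + es, end = loc$start + ee)
      }
      genes <- bind_rows(grows)
      exons <- bind_rows(erows)
    } else {
      genes <- tibble(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), coding = logical())
      exons <- tibble(gene_id = character(), chrom = character(),
                      start = integer(), end = integer())
    }

    fam_class <- c("DNA", "LINE", "SINE", "LTR")
    lib <- tibble(
      id = sprintf("rfam%02d", seq_len(n_repeat_families)),
      family = fam_class[(seq_len(n_repeat_families) - 1) %% length(fam_class) + 1],
      seq = vapply(seq_len(n_repeat_families), function(i)
        random_dna(rint(repeat_len_range[1], repeat_len_range[2]),
                   base_comp), character(1)))

    reps <- NULL
    if (n_repeat_copies > 0) {
      stopifnot(n_repeat_families > 0)
      rrows <- vector("list", n_repeat_copies)
      for (r in seq_len(n_repeat_copies)) {
        fi <- sample.int(nrow(lib), 1)
        copy <- mutate_sites(lib$seq[fi], repeat_divergence)$seq
        loc <- place(nchar(copy))
        substr(seqs[[loc$chrom]], loc$start + 1L, loc$end) <- copy
        rrows[[r]] <- tibble(chrom = loc$chrom, start = loc$start,
                             end = loc$end, family = lib$family[fi],
                             library_id = lib$id[fi])
      }
      reps <- bind_rows(rrows)
    } else {
      reps <- tibble(chrom = character(), start = integer(), end = integer(),
                     family = character(), library_id = character())
    }

    ssrs <- NULL
    if (n_ssrs > 0) {
      srows <- vector("list", n_ssrs)
      for (s in seq_len(n_ssrs)) {
        motif <- sample(ssr_motifs, 1)
        units <- rint(ssr_units_range[1], ssr_units_range[2])
        run_seq <- strrep(motif, units)
        loc <- place(nchar(run_seq))
        substr(seqs[[loc$chrom]], loc$start + 1L, loc$end) <- run_seq
        srows[[s]] <- tibble(chrom = loc$chrom, start = loc$start,
                             end = loc$end, motif = motif, units = units)
      }
      ssrs <- bind_rows(srows)
    } else {
      ssrs <- tibble(chrom = character(), start = integer(), end = integer(),
                     motif = character(), units = integer())
    }

    structure(list(seqs = seqs, genes = genes, exons = exons,
                   repeats = reps, ssrs = ssrs, repeat_library = lib),
              class = "ref_genome")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome:", length(x$seqs), "chromosome(s),",
      sum(nchar(x$seqs)), "bp;",
      nrow(x$genes), "genes,", nrow(x$repeats), "repeat copies,",
      nrow(x$ssrs), "SSRs\n")
  invisible(x)
}

#' Derive a diverged sample genome from a reference
#'
#' Models the genome a clone library is built from as a copy of the
#' reference with independent per-site substitutions (the divergence knob;
#' no indels unless `indel_rate > 0`) plus optional segmental duplications
#' appended as extra contigs, emulating a recently duplicated genome in
#' which one locus has two or more homologous copies.
#'
#' @param ref A `ref_genome` or named character vector of sequences.
#' @param divergence Per-site substitution probability in `[0, 0.3]`.
#' @param dup_fraction Fraction of the genome duplicated, in `[0, 1]`.
#' @param dup_segment_len Target duplicated-segment length (bp).
#' @param dup_divergence Extra per-site substitution applied to each
#'   duplicated copy (paralog divergence).
#' @param indel_rate Optional per-site indel probability (default 0; when
#'   positive, 1-3 bp insertions/deletions are introduced and reference
#'   coordinates are tracked through an offset map).
#' @param seed Optional integer seed.
#' @return A `sample_genome` list: `seqs` (chromosomes plus `dup*`
#'   contigs), `segments` map of duplicated contigs to their source
#'   (0-based half-open), `indel_events`, and the `divergence` used.
#' @export
derive_sample_genome <- function(ref, divergence = 0.1, dup_fraction = 0,
                                 dup_segment_len = 50000,
                                 dup_divergence = 0.02,
                                 indel_rate = 0, seed = NULL) {
  stopifnot(divergence >= 0, divergence <= 0.3,
            dup_fraction >= 0, dup_fraction <= 1, indel_rate >= 0)
  seqs <- if (inherits(ref, "ref_genome")) ref$seqs else ref
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  run <- function() {
    out <- vapply(seqs, function(s) mutate_sites(s, divergence)$seq,
                  character(1))
    names(out) <- names(seqs)

    indel_events <- tibble(chrom = character(), ref_pos = integer(),
                           shift = integer())
    if (indel_rate > 0) {
      for (cn in names(out)) {
        s <- out[[cn]]
        n <- nchar(s)
        pos <- which(runif(n) < indel_rate)
        if (!length(pos)) next
        sizes <- sample(1:3, length(pos), replace = TRUE) *
          sample(c(1L, -1L), length(pos), replace = TRUE)
        pieces <- character(0)
        prev <- 1L
        for (i in seq_along(pos)) {
          if (sizes[i] > 0) {  # insertion after pos
            pieces <- c(pieces, substr(s, prev, pos[i]),
                        random_dna(sizes[i]))
            prev <- pos[i] + 1L
          } else {             # deletion of |size| bases at pos
            pieces <- c(pieces, substr(s, prev, pos[i] - 1L))
            prev <- min(n + 1L, pos[i] - sizes[i])
          }
        }
        pieces <- c(pieces, substr(s, prev, n))
        out[[cn]] <- paste(pieces, collapse = "")
        indel_events <- bind_rows(indel_events,
          tibble(chrom = cn, ref_pos = pos - 1L, shift = sizes))
      }
    }

    segments <- tibble(contig = character(), src_chrom = character(),
                       src_start = integer(), src_end = integer())
    if (dup_fraction > 0) {
      total <- round(dup_fraction * sum(nchar(out)))
      n_seg <- max(1L, ceiling(total / dup_segment_len))
      lens <- nchar(out)
      srows <- vector("list", n_seg)
      for (i in seq_len(n_seg)) {
        cn <- sample(names(seqs), 1, prob = lens[names(seqs)])
        L <- min(dup_segment_len, lens[[cn]] - 2L)
        st <- sample.int(lens[[cn]] - L, 1) - 1L
        seg <- substr(out[[cn]], st + 1L, st + L)
        seg <- mutate_sites(seg, dup_divergence)$seq
        contig <- sprintf("dup%03d", i)
        out[[contig]] <- seg
        srows[[i]] <- tibble(contig = contig, src_chrom = cn,
                             src_start = st, src_end = st + L)
      }
      segments <- bind_rows(srows)
    }

    structure(list(seqs = out, segments = segments,
                   indel_events = indel_events, divergence = divergence),
              class = "sample_genome")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.sample_genome <- function(x, ...) {
  cat("sample_genome:", length(x$seqs), "contig(s),", sum(nchar(x$seqs)),
      "bp; divergence", x$divergence, ";", nrow(x$segments),
      "duplicated segment(s)\n")
  invisible(x)
}

# map a sample-genome interval back to reference coordinates
# (dup contigs via the segment map, indels via the offset map)
map_to_ref <- function(sample, chrom, start, end) {
  seg <- sample$segments
  if (chrom %in% seg$contig) {
    i <- match(chrom, seg$contig)
    start <- seg$src_start[i] + start
    end <- seg$src_start[i] + end
    chrom <- seg$src_chrom[i]
  }
  ev <- sample$indel_events
  if (nrow(ev) > 0) {
    ev <- ev[ev$chrom == chrom, , drop = FALSE]
    if (nrow(ev) > 0) {
      sh <- function(p) p - sum(ev$shift[ev$ref_pos < p])
      start <- sh(start); end <- sh(end)
    }
  }
  list(chrom = chrom, start = start, end = end)
}

#' Simulate BAC-end reads from a sample genome
#'
#' Draws clone inserts (length ~ Normal, default mean 141 kb, matching a
#' typical BAC library), sequences both termini inward (forward end on the
#' plus strand, reverse end reverse-complemented from the opposite
#' terminus), assigns a two-segment quality model (Q40 core, linear decay
#' to Q8 over the final 15% of each read), introduces sequencing errors
#' according to those qualities, and optionally prepends cloning-vector
#' contamination. A truth table records the error-free origin of every
#' read.
#'
#' @param sample A `sample_genome` (or named character vector).
#' @param n_clones Number of clones; each yields two reads.
#' @param insert_mean,insert_sd Insert-length distribution (bp).
#' @param read_len_mean,read_len_sd,read_len_range Read-length
#'   distribution; range defaults to 50-924 bp.
#' @param vector Cloning-vector sequence (single string); required when
#'   `contamination_rate > 0`.
#' @param contamination_rate Fraction of reads receiving a 20-120 bp
#'   vector prefix.
#' @param quality_model `"two_segment"` (default) or `"none"` (FASTA-style
#'   reads without qualities and without sequencing errors).
#' @param apply_errors Introduce base errors at the per-base rate implied
#'   by the quality string.
#' @param seed Optional integer seed.
#' @param max_tries Resampling attempts for inserts that do not fit.
#' @return `list(reads = bes_reads tibble, truth = tibble)`; truth has one
#'   row per read (2 x `n_clones`).
#' @export
simulate_bac_ends <- function(sample, n_clones,
                              insert_mean = 141000, insert_sd = 20000,
                              read_len_mean = 650, read_len_sd = 120,
                              read_len_range = c(50, 924),
                              vector = NULL, contamination_rate = 0,
                              quality_model = c("two_segment", "none"),
                              apply_errors = TRUE,
                              seed = NULL, max_tries = 100) {
  quality_model <- match.arg(quality_model)
  stopifnot(n_clones >= 0, insert_mean >= 2 * read_len_range[2],
            contamination_rate >= 0, contamination_rate <= 1)
  if (contamination_rate > 0 && is.null(vector)) {
    stop("contamination_rate > 0 requires a vector sequence")
  }
  seqs <- if (inherits(sample, "sample_genome")) sample$seqs else sample
  smp <- if (inherits(sample, "sample_genome")) sample else
    structure(list(seqs = seqs,
                   segments = tibble(contig = character(),
                                     src_chrom = character(),
                                     src_start = integer(),
                                     src_end = integer()),
                   indel_events = tibble(chrom = character(),
                                         ref_pos = integer(),
                                         shift = integer()),
                   divergence = NA_real_), class = "sample_genome")
  lens <- nchar(seqs)
  max_read <- read_len_range[2]

  run <- function() {
    if (n_clones == 0) {
      return(list(reads = empty_reads(),
                  truth = truth_skeleton()))
    }
    rrows <- vector("list", 2L * n_clones)
    trows <- vector("list", 2L * n_clones)
    for (ci in seq_len(n_clones)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cn <- sample(names(seqs), 1, prob = lens)
        ins <- round(rnorm(1, insert_mean, insert_sd))
        if (ins < 2 * max_read || ins > lens[[cn]]) next
        ist <- sample.int(lens[[cn]] - ins + 1L, 1) - 1L  # 0-based
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place insert of ~", insert_mean,
             " bp after ", max_tries, " tries (chromosomes too short?)")
      }
      clone <- sprintf("clone%05d", ci)
      for (endlab in c("F", "R")) {
        rl <- round(rnorm(1, read_len_mean, read_len_sd))
        rl <- max(read_len_range[1], min(read_len_range[2], rl,
                                         floor(ins / 2)))
        if (endlab == "F") {
          rstart <- ist; rend <- ist + rl; strand <- "+"
          rseq <- substr(seqs[[cn]], rstart + 1L, rend)
        } else {
          rend <- ist + ins; rstart <- rend - rl; strand <- "-"
          rseq <- revcomp(substr(seqs[[cn]], rstart + 1L, rend))
        }
        qual <- NA_character_
        if (quality_model == "two_segment") {
          q <- two_segment_quals(rl)
          if (apply_errors) {
            p <- 10^(-q / 10)
            v <- strsplit(rseq, "", fixed = TRUE)[[1]]
            hit <- which(runif(rl) < p)
            if (length(hit)) {
              alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                           G = c("A", "C", "T"), T = c("A", "C", "G"))
              pick <- sample.int(3L, length(hit), replace = TRUE)
              v[hit] <- mapply(function(b, k) alts[[b]][k], v[hit], pick,
                               USE.NAMES = FALSE)
              rseq <- paste(v, collapse = "")
            }
          }
          qual <- quals_to_string(list(q))
        }
        contaminated <- FALSE
        if (contamination_rate > 0 && runif(1) < contamination_rate) {
          plen <- sample(20:120, 1)
          plen <- min(plen, nchar(vector))
          rseq <- paste0(substr(vector, 1, plen), rseq)
          if (!is.na(qual)) {
            qual <- paste0(quals_to_string(list(rep(40L, plen))), qual)
          }
          contaminated <- TRUE
        }
        rid <- paste0(clone, "_", endlab)
        refloc <- map_to_ref(smp, cn, rstart, rend)
        k <- (ci - 1L) * 2L + (endlab == "R") + 1L
        rrows[[k]] <- tibble(id = rid, seq = rseq, qual = qual)
        trows[[k]] <- tibble(
          read_id = rid, clone_id = clone, end = endlab,
          chrom = cn, start = rstart, end_pos = rend, strand = strand,
          ref_chrom = refloc$chrom, ref_start = refloc$start,
          ref_end = refloc$end,
          insert_start = ist, insert_end = ist + ins, insert_len = ins,
          contaminated = contaminated, divergence = smp$divergence)
      }
    }
    r <- bind_rows(rrows)
    list(reads = bes_reads(r$id, r$seq, r$qual), truth = bind_rows(trows))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

truth_skeleton <- function() {
  tibble(read_id = character(), clone_id = character(), end = character(),
         chrom = character(), start = integer(), end_pos = integer(),
         strand = character(), ref_chrom = character(),
         ref_start = integer(), ref_end = integer(),
         insert_start = integer(), insert_end = integer(),
         insert_len = integer(), contaminated = logical(),
         divergence = double())
}

# Q40 core, then linear decay to Q8 over the final 15% of the read
two_segment_quals <- function(len) {
  core <- floor(0.85 * len)
  q <- rep(40L, len)
  tail_len <- len - core
  if (tail_len > 0) {
    q[(core + 1):len] <- as.integer(round(seq(40, 8,
                                              length.out = tail_len + 1)[-1]))
  }
  q
}

#' Write simulated annotation as GFF3 / BED12 / truth TSV
#'
#' @param genome A `ref_genome`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genome, path) {
  g <- genome$genes
  e <- genome$exons
  gr_g <- GenomicRanges::GRanges(
    g$chrom, to_iranges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id,
    biotype = ifelse(g$coding, "protein_coding", "noncoding"))
  if (nrow(e) > 0) {
    st <- g$strand[match(e$gene_id, g$gene_id)]
    gr_e <- GenomicRanges::GRanges(
      e$chrom, to_iranges(e$start, e$end), strand = st,
      type = "exon", ID = paste0(e$gene_id, ".e", seq_len(nrow(e))),
      biotype = NA_character_)
    S4Vectors::mcols(gr_e)$Parent <- e$gene_id
    S4Vectors::mcols(gr_g)$Parent <- NA_character_
    gr <- c(gr_g, gr_e)
  } else {
    gr <- gr_g
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
write_genes_bed12 <- function(genome, path) {
  g <- genome$genes
  rows <- vapply(seq_len(nrow(g)), function(i) {
    e <- genome$exons[genome$exons$gene_id == g$gene_id[i], , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    paste(g$chrom[i], g$start[i], g$end[i], g$gene_id[i], 0, g$strand[i],
          g$start[i], g$end[i], "0",
          nrow(e),
          paste0(paste(e$end - e$start, collapse = ","), ","),
          paste0(paste(e$start - g$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Expects `gene` features carrying a `biotype` attribute
#' (`protein_coding` vs `noncoding`) and optional `exon` children.
#'
#' @param path GFF3 file.
#' @return List with `genes` and `exons` tibbles (0-based half-open).
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  genes <- tibble(
    gene_id = as.character(md$ID[is_gene]),
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    coding = as.character(md$biotype[is_gene]) == "protein_coding")
  is_exon <- md$type == "exon"
  parent <- if ("Parent" %in% names(md)) {
    vapply(md$Parent[is_exon], function(p) as.character(p)[1], character(1))
  } else character(0)
  exons <- tibble(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon])
  list(genes = genes, exons = exons)
}

#' @rdname write_genes_gff3
#' @param truth Truth tibble from [simulate_bac_ends()].
#' @export
write_truth_tsv <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}
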