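test_that("empty feature config yields empty annotation", {
  g <- simulate_reference(c(chr1 = 20000), n_genes = 0,
                          n_repeat_copies = 0, n_ssrs = 0, seed = 1)
  expect_equal(nrow(g$genes), 0)
  expect_equal(nrow(g$repeats), 0)
  expect_equal(nrow(g$ssrs), 0)
  expect_equal(nchar(g$seqs[["chr1"]]), 20000)
})

test_that("same config and seed reproduce byte-identical FASTA", {
  mk <- function() simulate_reference(c(chr1 = 30000, chr2 = 15000),
                                      n_genes = 5, n_repeat_copies = 8,
                                      n_ssrs = 6, seed = 99)
  g1 <- mk(); g2 <- mk()
  expect_identical(g1$seqs, g2$seqs)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta_seqs(g1$seqs, f1)
  write_fasta_seqs(g2$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("feature placement respects invariants and rejects impossible configs", {
  g <- simulate_reference(c(chr1 = 120000), n_genes = 6,
                          n_repeat_copies = 10, n_ssrs = 10, seed = 3)
  feats <- dplyr::bind_rows(
    g$genes[, c("chrom", "start", "end")],
    g$repeats[, c("chrom", "start", "end")],
    g$ssrs[, c("chrom", "start", "end")])
  expect_true(all(feats$start >= 0))
  expect_true(all(feats$end <= nchar(g$seqs[feats$chrom])))
  # pairwise non-overlap
  by_chr <- split(feats, feats$chrom)
  for (f in by_chr) {
    f <- f[order(f$start), ]
    if (nrow(f) > 1) expect_true(all(f$start[-1] >= f$end[-nrow(f)]))
  }
  # exons nested in gene spans
  for (i in seq_len(nrow(g$exons))) {
    gi <- g$genes[g$genes$gene_id == g$exons$gene_id[i], ]
    expect_gte(g$exons$start[i], gi$start)
    expect_lte(g$exons$end[i], gi$end)
  }
  expect_error(
    simulate_reference(c(chr1 = 10000), n_genes = 20,
                       gene_len_range = c(4000, 8000), seed = 1),
    "overlap")
})

test_that("planted SSRs are recovered by the scanner", {
  g <- simulate_reference(c(chr1 = 100000), n_ssrs = 20,
                          ssr_motifs = "AC",
                          ssr_units_range = c(8, 8), seed = 11)
  hits <- find_ssrs(g$seqs)
  ac <- hits[hits$canonical == "AC", ]
  expect_gte(nrow(ac), 20)
  # every planted locus is recovered by an AC hit; flanking context may
  # shift the maximal run by up to one unit (leftmost-longest +
  # partial-unit truncation), so allow one unit of slack at the end
  for (i in seq_len(nrow(g$ssrs))) {
    expect_true(any(ac$start <= g$ssrs$start[i] &
                    ac$end >= g$ssrs$end[i] - 2L))
  }
})

test_that("zero divergence reproduces the reference exactly", {
  g <- simulate_reference(c(chr1 = 20000), seed = 5)
  s <- derive_sample_genome(g, divergence = 0, dup_fraction = 0, seed = 6)
  expect_identical(s$seqs[["chr1"]], g$seqs[["chr1"]])
})

test_that("observed mismatch fraction matches the divergence rate", {
  g <- simulate_reference(c(chr1 = 100000), seed = 7)
  s <- derive_sample_genome(g, divergence = 0.10, seed = 8)
  a <- strsplit(g$seqs[["chr1"]], "")[[1]]
  b <- strsplit(s$seqs[["chr1"]], "")[[1]]
  frac <- mean(a != b)
  expect_lt(abs(frac - 0.10), 0.005)  # binomial n = 100,000
})

test_that("duplicated segments create second homologous loci", {
  g <- simulate_reference(c(chr1 = 100000), seed = 9)
  s <- derive_sample_genome(g, divergence = 0.05, dup_fraction = 0.5,
                            dup_segment_len = 20000, seed = 10)
  expect_gte(nrow(s$segments), 2)
  expect_true(all(s$segments$contig %in% names(s$seqs)))
  # a read from a duplicated source region aligns to >= 2 loci of the
  # sample genome itself (truth-aware rerun)
  seg <- s$segments[1, ]
  probe <- substr(s$seqs[[seg$src_chrom]], seg$src_start + 501,
                  seg$src_start + 1100)
  idx <- build_index(s)
  hits <- align_bes(setNames(probe, "probe_F"), idx)
  expect_gte(nrow(hits), 2)
})

test_that("clone simulation yields inward mate pairs with full truth", {
  g <- simulate_reference(c(chr1 = 120000), seed = 12)
  s <- derive_sample_genome(g, divergence = 0, seed = 13)
  be <- simulate_bac_ends(s, n_clones = 25, insert_mean = 40000,
                          insert_sd = 5000, quality_model = "none",
                          seed = 14)
  expect_equal(nrow(be$truth), 50)
  expect_equal(nrow(be$reads), 50)
  expect_setequal(be$truth$read_id, be$reads$id)
  # reads are exact extracts of the sample genome at their truth locus
  for (i in seq_len(nrow(be$truth))) {
    tr <- be$truth[i, ]
    piece <- substr(s$seqs[[tr$chrom]], tr$start + 1, tr$end_pos)
    expected <- if (tr$strand == "+") piece else revcomp(piece)
    expect_identical(be$reads$seq[be$reads$id == tr$read_id], expected)
  }
  # inward orientation: F at insert start on +, R at insert end on -
  f <- be$truth[be$truth$end == "F", ]
  r <- be$truth[be$truth$end == "R", ]
  expect_true(all(f$strand == "+"))
  expect_true(all(r$strand == "-"))
  expect_true(all(f$start == f$insert_start))
  expect_true(all(r$end_pos == r$insert_end))
})

test_that("empty clone set and insert-length distribution behave", {
  g <- simulate_reference(c(chr1 = 500000), seed = 15)
  s <- derive_sample_genome(g, divergence = 0, seed = 16)
  be0 <- simulate_bac_ends(s, n_clones = 0, seed = 17)
  expect_equal(nrow(be0$reads), 0)
  expect_equal(nrow(be0$truth), 0)
  be <- simulate_bac_ends(s, n_clones = 400, insert_mean = 141000,
                          insert_sd = 20000, quality_model = "none",
                          seed = 18)
  ins <- be$truth$insert_len[be$truth$end == "F"]
  se <- 20000 / sqrt(length(ins))
  expect_lt(abs(mean(ins) - 141000), 4 * se)
  expect_error(simulate_bac_ends(s, 10, insert_mean = 1000),
               "insert_mean")
})

test_that("contaminated reads carry a vector prefix and the flag", {
  g <- simulate_reference(c(chr1 = 60000), seed = 19)
  s <- derive_sample_genome(g, divergence = 0, seed = 20)
  vec <- withr::with_seed(21, random_dna(500))
  be <- simulate_bac_ends(s, n_clones = 30, insert_mean = 20000,
                          insert_sd = 2000, read_len_range = c(50, 600),
                          vector = vec, contamination_rate = 0.5,
                          quality_model = "none", seed = 22)
  cont <- be$truth$contaminated
  expect_gt(sum(cont), 0)
  expect_lt(sum(cont), nrow(be$truth))
  for (rid in be$truth$read_id[cont]) {
    sq <- be$reads$seq[be$reads$id == rid]
    expect_identical(substr(sq, 1, 20), substr(vec, 1, 20))
  }
})

test_that("annotation round-trips through GFF3", {
  g <- simulate_reference(c(chr1 = 50000), n_genes = 6, seed = 23)
  path <- tempfile(fileext = ".gff3")
  write_genes_gff3(g, path)
  back <- read_genes_gff3(path)
  expect_equal(nrow(back$genes), 6)
  ord <- match(g$genes$gene_id, back$genes$gene_id)
  expect_equal(back$genes$start[ord], g$genes$start)
  expect_equal(back$genes$end[ord], g$genes$end)
  expect_equal(back$genes$coding[ord], g$genes$coding)
  expect_equal(nrow(back$exons), nrow(g$exons))
})
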