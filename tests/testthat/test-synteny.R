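test_that("clone classification follows the decision tree", {
  f <- mk_hit("chr1", 100L, 700L, "+", "c1_F")
  r <- mk_hit("chr1", 250000L, 250600L, "-", "c1_R")
  pe <- classify_clone(f, r)
  expect_equal(pe$category, "paired_ends")
  expect_equal(pe$chrom, "chr1")
  expect_equal(pe$span_start, 100L)
  expect_equal(pe$span_end, 250600L)
  expect_equal(pe$clone_id, "c1")

  um <- classify_clone(f, mk_hit("chr2", 100L, 700L, "-", "c1_R"))
  expect_equal(um$category, "unmate")

  mr <- classify_clone(f, mk_hit("chr1", 250000L, 250600L, "+", "c1_R"))
  expect_equal(mr$category, "mate_reverse")

  lp <- classify_clone(f, mk_hit("chr1", 350800L, 351400L, "-", "c1_R"))
  expect_equal(lp$category, "long_pair")     # facing gap 350,100 bp
  # exactly at the threshold it is still paired
  at <- classify_clone(f, mk_hit("chr1", 300700L, 301300L, "-", "c1_R"))
  expect_equal(at$category, "paired_ends")

  expect_equal(classify_clone(f, NULL)$category, "singleton")
  expect_equal(classify_clone(NULL, NULL, clone_id = "c9")$category,
               "unmapped")
  two <- dplyr::bind_rows(f, f)
  expect_error(classify_clone(two, r), "top hits")
})

test_that("inward orientation is judged by position, not end label", {
  # reverse-end hit left of forward-end hit: leftmost must be +
  f <- mk_hit("chr1", 50000L, 50600L, "-", "c1_F")
  r <- mk_hit("chr1", 1000L, 1600L, "+", "c1_R")
  expect_equal(classify_clone(f, r)$category, "paired_ends")
  # both minus: inconsistent
  f2 <- mk_hit("chr1", 1000L, 1600L, "-", "c1_F")
  r2 <- mk_hit("chr1", 50000L, 50600L, "-", "c1_R")
  expect_equal(classify_clone(f2, r2)$category, "mate_reverse")
})

test_that("category counts partition the clones", {
  withr::with_seed(60, {
    hits <- list()
    n <- 0
    add <- function(h) { n <<- n + 1; hits[[n]] <<- h }
    # 5 paired, 3 long, 2 reverse, 4 unmate, 6 singleton
    for (i in 1:5) {
      add(mk_hit("chr1", i * 1000L, i * 1000L + 600L, "+",
                 sprintf("pe%d_F", i)))
      add(mk_hit("chr1", i * 1000L + 100000L, i * 1000L + 100600L, "-",
                 sprintf("pe%d_R", i)))
    }
    for (i in 1:3) {
      add(mk_hit("chr1", i * 1000L, i * 1000L + 600L, "+",
                 sprintf("lp%d_F", i)))
      add(mk_hit("chr1", i * 1000L + 400000L, i * 1000L + 400600L, "-",
                 sprintf("lp%d_R", i)))
    }
    for (i in 1:2) {
      add(mk_hit("chr1", i * 1000L, i * 1000L + 600L, "+",
                 sprintf("mr%d_F", i)))
      add(mk_hit("chr1", i * 1000L + 5000L, i * 1000L + 5600L, "+",
                 sprintf("mr%d_R", i)))
    }
    for (i in 1:4) {
      add(mk_hit("chr1", i * 1000L, i * 1000L + 600L, "+",
                 sprintf("um%d_F", i)))
      add(mk_hit("chr2", i * 1000L, i * 1000L + 600L, "-",
                 sprintf("um%d_R", i)))
    }
    for (i in 1:6) {
      add(mk_hit("chr1", i * 2000L, i * 2000L + 600L, "+",
                 sprintf("sg%d_F", i)))
    }
    all_hits <- dplyr::bind_rows(hits)
    res <- classify_clones(all_hits,
                           clones = c(sprintf("pe%d", 1:5),
                                      sprintf("lp%d", 1:3),
                                      sprintf("mr%d", 1:2),
                                      sprintf("um%d", 1:4),
                                      sprintf("sg%d", 1:6),
                                      "un1", "un2"))
    s <- res$summary
    get <- function(cat, col) s[[col]][s$category == cat]
    expect_equal(get("paired_ends", "n_clones"), 5L)
    expect_equal(get("long_pair", "n_clones"), 3L)
    expect_equal(get("mate_reverse", "n_clones"), 2L)
    expect_equal(get("unmate", "n_clones"), 4L)
    expect_equal(get("singleton", "n_clones"), 6L)
    expect_equal(get("unmapped", "n_clones"), 2L)
    expect_equal(get("mapped", "n_clones"), 20L)
    expect_equal(get("mapped", "n_bes"), 2L * 14L + 6L)
    expect_equal(get("total", "n_clones"),
                 sum(vapply(c("paired_ends", "long_pair", "mate_reverse",
                              "unmate", "singleton", "unmapped"),
                            function(x) get(x, "n_clones"), integer(1))))
  })
})

genes_fixture <- tibble::tibble(
  gene_id = c("g1", "g2"),
  chrom = "chr1",
  start = c(1000L, 9000L), end = c(5000L, 12000L),
  strand = "+",
  coding = c(TRUE, FALSE))

test_that("end annotation honours intron inclusion and coding precedence", {
  # inside g1's span (introns included) -> coding
  expect_equal(annotate_interval("chr1", 2000L, 2400L, genes_fixture),
               "coding")
  # overlapping both a coding and a noncoding gene -> coding
  wide <- annotate_interval("chr1", 4500L, 9500L, genes_fixture)
  expect_equal(wide, "coding")
  # inside the noncoding gene only
  expect_equal(annotate_interval("chr1", 9500L, 9900L, genes_fixture),
               "noncoding")
  # annotation desert
  expect_equal(annotate_interval("chr1", 50000L, 50400L, genes_fixture),
               "intergenic")
})

test_that("microsynteny types partition the paired clones", {
  mkcls <- function(id, fs, fe, rs, re) {
    classify_clone(mk_hit("chr1", fs, fe, "+", paste0(id, "_F")),
                   mk_hit("chr1", rs, re, "-", paste0(id, "_R")))
  }
  cls <- dplyr::bind_rows(
    mkcls("t1", 1100L, 1500L, 9100L, 9500L),    # coding vs noncoding -> 2
    mkcls("t2", 1100L, 1500L, 4000L, 4400L),    # coding vs coding -> 1
    mkcls("t3", 1100L, 1500L, 50000L, 50400L),  # coding vs intergenic -> 4
    mkcls("t4", 9100L, 9500L, 60000L, 60400L),  # noncoding vs intergenic -> 5
    mkcls("t5", 40000L, 40400L, 70000L, 70400L))# intergenic/intergenic -> 6
  ms <- build_microsyntenies(cls, genes_fixture)
  got <- setNames(ms$microsyntenies$type, ms$microsyntenies$clone_id)
  expect_equal(unname(got[c("t1", "t2", "t3", "t4", "t5")]),
               c(2L, 1L, 4L, 5L, 6L))
  expect_equal(sum(ms$type_counts$n), nrow(ms$microsyntenies))
  # unordered pair: the noncoding/coding assignment of the two physical
  # ends does not change the type
  swapped <- classify_clone(mk_hit("chr1", 9100L, 9500L, "-", "t6_F"),
                            mk_hit("chr1", 1100L, 1500L, "+", "t6_R"))
  ms2 <- build_microsyntenies(swapped, genes_fixture)
  expect_equal(ms2$microsyntenies$type, 2L)
})

test_that("coverage union equals the per-base oracle and totals reconcile", {
  withr::with_seed(61, {
    sizes <- c(cA = 100000, cB = 80000)
    spans <- tibble::tibble(
      chrom = sample(names(sizes), 60, TRUE),
      span_start = sample(0:70000, 60, TRUE))
    spans$span_end <- pmin(spans$span_start +
                             sample(2000:30000, 60, TRUE),
                           sizes[spans$chrom])
    spans$clone_id <- sprintf("c%02d", 1:60)
    cov <- chromosome_coverage(spans, sizes)
    for (cn in names(sizes)) {
      sp <- spans[spans$chrom == cn, ]
      expect_equal(cov$covered_bp[cov$chrom == cn],
                   coverage_oracle(sp$span_start, sp$span_end,
                                   sizes[[cn]]))
    }
    tot <- cov[cov$chrom == "Total", ]
    per <- cov[cov$chrom != "Total", ]
    expect_equal(tot$size_bp, sum(per$size_bp))
    expect_equal(tot$covered_bp, sum(per$covered_bp))
    expect_equal(tot$n_clones, sum(per$n_clones))
    expect_equal(tot$coverage_percent,
                 round(tot$covered_bp / tot$size_bp * 100, 2))
    expect_true(all(per$covered_bp <= per$size_bp))
  })
  # duplicate spans count once
  dup <- tibble::tibble(chrom = "cA", span_start = c(10L, 10L),
                        span_end = c(500L, 500L))
  cd <- chromosome_coverage(dup, c(cA = 1000))
  expect_equal(cd$covered_bp[1], 490)
  expect_error(chromosome_coverage(
    tibble::tibble(chrom = "nope", span_start = 0L, span_end = 10L),
    c(cA = 1000)), "unknown")
})

test_that("exon-level gene hits count each gene once and skip introns", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 1000L, end = 9000L, strand = "+",
                          coding = TRUE)
  exons <- tibble::tibble(gene_id = c("g1", "g1"), chrom = "chr1",
                          start = c(1000L, 8000L), end = c(1500L, 9000L))
  hits <- dplyr::bind_rows(
    mk_hit("chr1", 1100L, 1300L, "+", "a_F"),
    mk_hit("chr1", 8100L, 8400L, "+", "b_F"),
    mk_hit("chr1", 3000L, 3500L, "+", "c_F"))   # intron only
  expect_equal(exon_gene_hits(hits, exons, genes), "g1")
  expect_equal(exon_gene_hits(hits[3, ], exons, genes), character())
})

test_that("simulated clones within the separation threshold classify as paired", {
  g <- simulate_reference(c(chr1 = 400000), n_genes = 12, seed = 62)
  s <- derive_sample_genome(g, divergence = 0.10, seed = 63)
  be <- simulate_bac_ends(s, n_clones = 40, insert_mean = 100000,
                          insert_sd = 10000, seed = 64)
  idx <- build_index(g)
  top <- select_top_hits(align_bes(be$reads, idx))
  res <- classify_clones(top)
  # well-mapped clones: both ends with top hits at their truth loci
  m <- merge(top$hits, be$truth, by.x = "query_id", by.y = "read_id")
  ok_read <- m$subject_id == m$ref_chrom & abs(m$sstart - m$ref_start) < 5000
  good_clones <- names(which(table(m$clone_id[ok_read]) == 2))
  cls <- res$classifications
  frac_pe <- mean(cls$category[cls$clone_id %in% good_clones] ==
                  "paired_ends")
  expect_gte(frac_pe, 0.95)
  # a trans-chromosomal chimera classifies as unmate
  chim <- classify_clone(mk_hit("chr1", 0L, 600L, "+", "x_F"),
                         mk_hit("chr9", 0L, 600L, "-", "x_R"))
  expect_equal(chim$category, "unmate")
})
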