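ref_fixture <- function(seed = 50, size = 120000) {
  withr::with_seed(seed, setNames(random_dna(size), "chr1"))
}

test_that("index bounds, empty reference and k range are enforced", {
  r <- ref_fixture(size = 10000)
  small <- setNames(substr(r[["chr1"]], 1, 1000), "c")
  idx <- build_index(small, k = 14)
  expect_lte(nrow(idx$seeds), 1000 - 14 + 1)
  expect_error(build_index(setNames(character(), character())), "empty")
  expect_error(build_index(small, k = 9), "k")
  expect_error(build_index(small, k = 21), "k")
})

test_that("an exact substring aligns at full identity at its locus", {
  r <- ref_fixture()
  idx <- build_index(r)
  q <- setNames(substr(r[["chr1"]], 5001, 5500), "q_F")
  hits <- align_bes(q, idx)
  expect_gte(nrow(hits), 1)
  top <- hits[1, ]
  expect_equal(top$identity, 100)
  expect_equal(top$aligned_columns, 500L)
  expect_equal(top$sstart, 5000L)
  expect_equal(top$send, 5500L)
  expect_equal(top$strand, "+")
})

test_that("a poly-N query yields no hits", {
  idx <- build_index(ref_fixture(size = 20000))
  expect_equal(nrow(align_bes(setNames(strrep("N", 300), "n_F"), idx)), 0)
})

test_that("alignment score is symmetric under query reverse complement", {
  r <- ref_fixture(seed = 51)
  idx <- build_index(r)
  q <- substr(r[["chr1"]], 40001, 40600)
  q <- withr::with_seed(52, bessurvey:::mutate_sites(q, 0.05)$seq)
  fw <- align_bes(setNames(q, "q_F"), idx)[1, ]
  rc <- align_bes(setNames(revcomp(q), "q_F"), idx)[1, ]
  expect_equal(rc$score, fw$score)
  expect_equal(rc$sstart, fw$sstart)
  expect_equal(rc$send, fw$send)
  expect_equal(rc$identity, fw$identity)
  expect_equal(fw$strand, "+")
  expect_equal(rc$strand, "-")
})

test_that("divergent queries align with identity tracking the mutation rate", {
  r <- ref_fixture(seed = 53, size = 200000)
  idx <- build_index(r)
  withr::with_seed(54, {
    ids <- numeric(60)
    for (i in 1:60) {
      st <- sample(1:(200000 - 700), 1)
      q <- bessurvey:::mutate_sites(substr(r[["chr1"]], st, st + 599),
                                    0.10)$seq
      h <- align_bes(setNames(q, paste0("q", i, "_F")), idx)
      ids[i] <- h$identity[1]
    }
  })
  expect_gt(mean(ids), 88)
  expect_lt(mean(ids), 93)
})

test_that("aligner recovers the exact locus of errorless simulated reads", {
  g <- simulate_reference(c(chr1 = 150000, chr2 = 100000), seed = 55)
  s <- derive_sample_genome(g, divergence = 0, seed = 56)
  be <- simulate_bac_ends(s, n_clones = 50, insert_mean = 30000,
                          insert_sd = 3000, quality_model = "none",
                          seed = 57)
  idx <- build_index(g)
  top <- select_top_hits(align_bes(be$reads, idx))
  m <- merge(top$hits, be$truth, by.x = "query_id", by.y = "read_id")
  expect_gte(nrow(m), 99)
  ok <- m$subject_id == m$ref_chrom &
    abs(m$sstart - m$ref_start) <= 5 &
    abs(m$send - m$ref_end) <= 5
  expect_gte(mean(ok), 0.99)
  # strand agrees with the simulated end orientation
  expect_true(all(m$strand.x[ok] == m$strand.y[ok]))
})

test_that("tabular round trip is lossless and strand convention holds", {
  withr::with_seed(58, {
    n <- 100
    len <- sample(100:700, n)
    sstart <- sample(0:1e6, n)
    hits <- tibble::tibble(
      query_id = sprintf("q%03d_F", 1:n),
      subject_id = sample(c("chr1", "chr2"), n, TRUE),
      identity = round(runif(n, 80, 100), 2),
      aligned_columns = len,
      identical_columns = as.integer(round(round(runif(n, 80, 100), 2) *
                                             len / 100)),
      mismatches = sample(0:30, n, TRUE),
      gap_opens = sample(0:3, n, TRUE),
      qstart = sample(0:50, n, TRUE), qend = sample(300:700, n, TRUE),
      sstart = sstart, send = sstart + len,
      strand = sample(c("+", "-"), n, TRUE),
      evalue = signif(10^runif(n, -40, -6), 6),
      score = as.numeric(sample(50:900, n, TRUE)))
    hits$identical_columns <- as.integer(round(hits$identity *
                                                 hits$aligned_columns / 100))
    path <- tempfile(fileext = ".tsv")
    write_blast_tabular(hits, path)
    back <- read_blast_tabular(path)
    expect_equal(as.data.frame(back), as.data.frame(hits),
                 tolerance = 1e-12)
  })
})

test_that("minus strand is encoded by reversed subject coordinates", {
  h <- mk_hit("chr2", 400L, 900L, "-", query_id = "q_R")
  path <- tempfile(fileext = ".tsv")
  write_blast_tabular(h, path)
  f <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(as.integer(f[9]), 900L)
  expect_equal(as.integer(f[10]), 401L)
  back <- read_blast_tabular(path)
  expect_equal(back$strand, "-")
  expect_equal(back$sstart, 400L)
  expect_equal(back$send, 900L)
})

test_that("malformed tabular lines are rejected with the line number", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("q", "s", "99.0", "100", "1", "0", "1", "100",
                       "1", "100", "1e-20", "180"), collapse = "\t"),
               paste(rep("x", 11), collapse = "\t")), path)
  expect_error(read_blast_tabular(path), "line 2")
})

test_that("top-hit selection applies the cutoff and deterministic ties", {
  hits <- dplyr::bind_rows(
    mk_hit("chrB", 50L, 550L, "+", "q1_F", score = 500, evalue = 1e-30),
    mk_hit("chrA", 100L, 600L, "+", "q1_F", score = 500, evalue = 1e-30),
    mk_hit("chrA", 0L, 500L, "+", "q2_F", score = 300, evalue = 1e-2))
  top <- select_top_hits(hits, evalue_cutoff = 1e-5)
  expect_equal(top$n_queries_hit, 1)   # q2 fails the cutoff
  expect_equal(top$hits$subject_id, "chrA")  # lexicographic tie rule
  expect_equal(top$n_unique, 0)        # q1 had two passing hits
  # permutation invariance
  top2 <- select_top_hits(hits[c(3, 1, 2), ], evalue_cutoff = 1e-5)
  expect_equal(top2$hits, top$hits)
})

test_that("identity summary is site-weighted", {
  two <- dplyr::bind_rows(
    tibble::tibble(identity = 50, aligned_columns = 100L,
                   identical_columns = 50L),
    tibble::tibble(identity = 100, aligned_columns = 100L,
                   identical_columns = 100L))
  s <- identity_summary(two)
  expect_equal(s$mean_identity_percent, 75.0)
  all100 <- tibble::tibble(identity = rep(100, 5),
                           aligned_columns = rep(200L, 5),
                           identical_columns = rep(200L, 5))
  expect_equal(identity_summary(all100)$mean_identity_percent, 100.0)
  empty <- identity_summary(all100[0, ])
  expect_true(empty$undefined)
  expect_true(is.na(empty$mean_identity_percent))
})
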