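#' Survey report (key-value summary table)
#'
#' Collates the stage summaries into one key-value table in the shape of
#' a sequencing-survey statistics table: read counts, trimming success,
#' length and composition statistics, repeat fraction, SSR counts,
#' mate-pair mapping counts, genome fraction
#' (`total_bp / genome_size * 100`, 1 decimal) and clonal coverage
#' (`n_clones * mean_insert / genome_size`, 2 decimals).
#'
#' @param stats A `survey_stats` object (or `NULL`).
#' @param repeat_summary Optional `repeat_summary`.
#' @param ssr_census Optional `ssr_census`.
#' @param mate_summary Optional mate-pair summary tibble.
#' @param coverage Optional coverage table.
#' @param type_counts Optional microsynteny type counts.
#' @param identity Optional [identity_summary()] result.
#' @param genome_size Genome size (bp) for the genome-fraction and
#'   clonal-coverage lines.
#' @param n_clones Number of clones in the library.
#' @param mean_insert Mean insert size (bp).
#' @param trim_success_percent Optional trimming success percentage.
#' @return Tibble with columns `key`, `value` (numeric).
#' @export
survey_report <- function(stats = NULL, repeat_summary = NULL,
                          ssr_census = NULL, mate_summary = NULL,
                          coverage = NULL, type_counts = NULL,
                          identity = NULL, genome_size = NULL,
                          n_clones = NULL, mean_insert = NULL,
                          trim_success_percent = NULL) {
  kv <- list()
  put <- function(key, value) {
    kv[[length(kv) + 1L]] <<- tibble(key = key, value = as.numeric(value))
  }
  if (!is.null(stats)) {
    put("n_reads", stats$n_reads)
    put("n_after_trim", stats$n_after_trim)
    if (!is.null(trim_success_percent)) {
      put("trim_success_percent", trim_success_percent)
    } else if (stats$n_reads > 0) {
      put("trim_success_percent",
          round(stats$n_after_trim / stats$n_reads * 100, 1))
    }
    put("n_redundant_removed", stats$n_redundant_removed)
    put("n_final_bes", stats$n_final)
    put("total_bp", stats$total_bp)
    put("mean_read_length_bp", stats$mean_len_bp %||% NA_real_)
    put("gc_percent", stats$gc_percent)
    put("at_percent", stats$at_percent)
    put("n_mate_pairs", stats$n_mate_pairs)
  }
  if (!is.null(repeat_summary)) {
    put("repeat_masked_bp", repeat_summary$masked_bp)
    put("repeat_masked_percent", repeat_summary$masked_percent)
  }
  if (!is.null(ssr_census)) {
    put("n_ssrs", ssr_census$n_ssrs)
    put("n_reads_with_ssr", ssr_census$n_reads_with_ssr)
    di <- ssr_census$by_unit
    put("ssr_di_percent", di$percent[di$unit_len == 2])
    put("ssr_tri_percent", di$percent[di$unit_len == 3])
    if (!is.na(ssr_census$n_primer_designable)) {
      put("n_ssr_primer_designable", ssr_census$n_primer_designable)
    }
  }
  if (!is.null(identity)) {
    put("mean_identity_percent", identity$mean_identity_percent)
  }
  if (!is.null(mate_summary)) {
    put("mapped_clones",
        mate_summary$n_clones[mate_summary$category == "mapped"])
    put("mapped_bes",
        mate_summary$n_bes[mate_summary$category == "mapped"])
    put("paired_ends_clones",
        mate_summary$n_clones[mate_summary$category == "paired_ends"])
  }
  if (!is.null(coverage)) {
    tot <- coverage[coverage$chrom == "Total", ]
    if (nrow(tot) == 1) {
      put("genome_covered_bp", tot$covered_bp)
      put("genome_coverage_percent", tot$coverage_percent)
    }
  }
  if (!is.null(type_counts)) {
    for (t in type_counts$type) {
      put(paste0("microsynteny_type", t),
          type_counts$n[type_counts$type == t])
    }
  }
  if (!is.null(genome_size)) {
    if (!is.null(stats)) {
      put("genome_fraction_percent",
          round(stats$total_bp / genome_size * 100, 1))
    }
    if (!is.null(n_clones) && !is.null(mean_insert)) {
      put("clonal_coverage",
          round(n_clones * mean_insert / genome_size, 2))
    }
  }
  if (length(kv) == 0) return(tibble(key = character(), value = numeric()))
  bind_rows(kv)
}

default_config <- function() {
  list(
    seed = 1L, out_dir = "bes_survey_out",
    simulate = FALSE,
    # simulation block
    sim_chrom_sizes = "chr1=1000000",
    sim_n_clones = 200L, sim_divergence = 0.1, sim_dup_fraction = 0,
    sim_n_genes = 20L, sim_n_repeat_copies = 30L, sim_n_ssrs = 20L,
    sim_contamination_rate = 0.1, sim_insert_mean = 141000,
    sim_insert_sd = 20000, sim_vector = NULL,
    # file inputs (non-simulated runs)
    reads_fastq = NULL, reads_fasta = NULL, ref_fasta = NULL,
    genes_gff3 = NULL, chrom_sizes_tsv = NULL, vectors_fasta = NULL,
    repeat_lib_fasta = NULL, hits_tsv = NULL,
    # thresholds
    min_len = 50L, error_threshold = 0.01, redundancy_identity = 0.95,
    mask_min_score = 30, discover_repeats = TRUE, discover_k = 16L,
    discover_min_copies = 10L, min_flank = 50L, evalue_cutoff = 1e-5,
    max_separation = 300000L, align_min_score = 30,
    run_synteny = TRUE)
}

#' Read a pipeline configuration file
#'
#' A flat key-value YAML file; unknown keys are an error, missing keys
#' take the documented defaults.
#'
#' @param path YAML file (or a named list to validate).
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  def <- default_config()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  cfg <- utils::modifyList(def, cfg)
  stopifnot(cfg$min_len >= 1, cfg$error_threshold > 0,
            cfg$error_threshold < 1, cfg$redundancy_identity > 0,
            cfg$redundancy_identity <= 1, cfg$max_separation > 0,
            cfg$evalue_cutoff > 0)
  cfg
}

parse_chrom_sizes_key <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  setNames(as.integer(vapply(kv, `[`, character(1), 2)),
           vapply(kv, `[`, character(1), 1))
}

#' Run the whole survey pipeline
#'
#' Stages run in order clean, repeats, ssr, align, synteny, report; any
#' stage failure aborts with an error naming the stage. Every output is
#' written under `out_dir` together with a manifest of input checksums,
#' parameters and output checksums; an identical config and seed gives an
#' identical manifest.
#'
#' @param config A config list, or path to a YAML config (see
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with the in-memory stage results and the
#'   report tibble.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inputs <- character()

  sim_truth <- NULL
  if (isTRUE(cfg$simulate)) {
    sim <- stage("simulate", {
      sizes <- parse_chrom_sizes_key(cfg$sim_chrom_sizes)
      ref <- simulate_reference(
        sizes, n_genes = cfg$sim_n_genes,
        n_repeat_copies = cfg$sim_n_repeat_copies,
        n_ssrs = cfg$sim_n_ssrs, seed = cfg$seed)
      smp <- derive_sample_genome(ref, divergence = cfg$sim_divergence,
                                  dup_fraction = cfg$sim_dup_fraction,
                                  seed = cfg$seed + 1L)
      vec <- cfg$sim_vector %||%
        withr::with_seed(cfg$seed + 2L, random_dna(1200))
      be <- simulate_bac_ends(
        smp, n_clones = cfg$sim_n_clones,
        insert_mean = cfg$sim_insert_mean,
        insert_sd = cfg$sim_insert_sd, vector = vec,
        contamination_rate = cfg$sim_contamination_rate,
        seed = cfg$seed + 3L)
      sim_dir <- file.path(out_dir, "sim")
      dir.create(sim_dir, showWarnings = FALSE)
      write_fasta_seqs(ref$seqs, file.path(sim_dir, "ref.fa"))
      write_genes_gff3(ref, file.path(sim_dir, "genes.gff3"))
      write_fasta_seqs(setNames(vec, "vector"),
                       file.path(sim_dir, "vector.fa"))
      write_bes_fastq(be$reads, file.path(sim_dir, "reads.fastq"))
      write_truth_tsv(be$truth, file.path(sim_dir, "truth.tsv"))
      list(ref = ref, reads = be$reads, truth = be$truth, vector = vec,
           sizes = sizes)
    })
    reads <- sim$reads
    ref_seqs <- sim$ref$seqs
    genes <- sim$ref$genes
    exons <- sim$ref$exons
    chrom_sizes <- nchar(sim$ref$seqs)
    vectors <- setNames(sim$vector, "vector")
    repeat_lib <- NULL
    sim_truth <- sim$truth
    inputs <- c(inputs,
                file.path(out_dir, "sim",
                          c("ref.fa", "genes.gff3", "reads.fastq")))
  } else {
    reads <- stage("clean", {
      if (!is.null(cfg$reads_fastq)) read_bes_fastq(cfg$reads_fastq)
      else if (!is.null(cfg$reads_fasta)) read_bes_fasta(cfg$reads_fasta)
      else stop("no reads_fastq or reads_fasta input configured")
    })
    ref_seqs <- if (!is.null(cfg$ref_fasta))
      read_fasta_seqs(cfg$ref_fasta) else NULL
    ann <- if (!is.null(cfg$genes_gff3)) read_genes_gff3(cfg$genes_gff3)
           else NULL
    genes <- ann$genes
    exons <- ann$exons
    chrom_sizes <- if (!is.null(cfg$chrom_sizes_tsv)) {
      sz <- data.table::fread(cfg$chrom_sizes_tsv, header = FALSE)
      setNames(as.numeric(sz[[2]]), as.character(sz[[1]]))
    } else if (!is.null(ref_seqs)) nchar(ref_seqs) else NULL
    vectors <- if (!is.null(cfg$vectors_fasta))
      read_fasta_seqs(cfg$vectors_fasta) else NULL
    repeat_lib <- if (!is.null(cfg$repeat_lib_fasta))
      read_repeat_library_fasta(cfg$repeat_lib_fasta) else NULL
    inputs <- c(inputs, unlist(cfg[c("reads_fastq", "reads_fasta",
                                     "ref_fasta", "genes_gff3",
                                     "chrom_sizes_tsv", "vectors_fasta",
                                     "repeat_lib_fasta")]))
  }

  cleaned <- stage("clean", {
    clean_reads(reads, vectors = vectors,
                error_threshold = cfg$error_threshold,
                min_len = cfg$min_len,
                identity = cfg$redundancy_identity)
  })
  write_bes_fasta(cleaned$reads, file.path(out_dir, "cleaned.fa"))
  write_tsv_file(stats_to_tsv(cleaned$stats),
                 file.path(out_dir, "stats.tsv"))

  rep_res <- stage("repeats", {
    lib <- repeat_lib
    if (isTRUE(cfg$discover_repeats)) {
      found <- discover_repeats_kmer(cleaned$reads, k = cfg$discover_k,
                                     min_copies = cfg$discover_min_copies)
      lib <- if (is.null(lib)) found
             else merge_repeat_libraries(list(lib, found))
    }
    if (is.null(lib) || nrow(lib) == 0) {
      list(reads = cleaned$reads, hits = repeat_hit_skeleton(),
           summary = repeat_summary(repeat_hit_skeleton(),
                                    sum(nchar(cleaned$reads$seq))))
    } else {
      mask_repeats(cleaned$reads, lib, min_score = cfg$mask_min_score)
    }
  })
  write_tsv_file(rep_res$hits, file.path(out_dir, "repeat_hits.tsv"))
  write_tsv_file(rep_res$summary$by_family,
                 file.path(out_dir, "repeat_summary.tsv"))

  ssr_res <- stage("ssr", {
    hits <- find_ssrs(rep_res$reads)
    hits$designable <- flank_check(hits, rep_res$reads,
                                   min_flank_bp = cfg$min_flank)
    list(hits = hits, census = ssr_census(hits))
  })
  write_tsv_file(ssr_res$hits, file.path(out_dir, "ssr_hits.tsv"))
  write_tsv_file(ssr_res$census$by_unit,
                 file.path(out_dir, "ssr_census.tsv"))

  top <- NULL
  idsum <- NULL
  if (!is.null(cfg$hits_tsv) || !is.null(ref_seqs)) {
    top <- stage("align", {
      hits <- if (!is.null(cfg$hits_tsv)) {
        read_blast_tabular(cfg$hits_tsv)
      } else {
        idx <- build_index(ref_seqs)
        align_bes(cleaned$reads, idx, min_score = cfg$align_min_score)
      }
      select_top_hits(hits, evalue_cutoff = cfg$evalue_cutoff)
    })
    idsum <- identity_summary(top)
    write_blast_tabular(top$hits, file.path(out_dir, "tophits.tsv"))
  }

  syn <- NULL
  if (isTRUE(cfg$run_synteny) && !is.null(top)) {
    syn <- stage("synteny", {
      if (is.null(genes)) {
        stop("synteny typing requested but no gene annotation available")
      }
      if (is.null(chrom_sizes)) {
        stop("synteny requested but no chromosome sizes available")
      }
      cls <- classify_clones(top, max_separation = cfg$max_separation)
      ms <- build_microsyntenies(cls$classifications, genes)
      cov <- chromosome_coverage(ms$microsyntenies, chrom_sizes)
      list(cls = cls, ms = ms, coverage = cov)
    })
    write_tsv_file(syn$cls$classifications,
                   file.path(out_dir, "classifications.tsv"))
    write_tsv_file(syn$cls$summary,
                   file.path(out_dir, "mate_pair_summary.tsv"))
    write_microsynteny_bed(syn$ms$microsyntenies,
                           file.path(out_dir, "microsyntenies.bed"))
    write_tsv_file(syn$coverage, file.path(out_dir, "coverage.tsv"))
  }

  report <- stage("report", {
    survey_report(
      stats = cleaned$stats,
      repeat_summary = rep_res$summary,
      ssr_census = ssr_res$census,
      mate_summary = if (!is.null(syn)) syn$cls$summary,
      coverage = if (!is.null(syn)) syn$coverage,
      type_counts = if (!is.null(syn)) syn$ms$type_counts,
      identity = idsum,
      genome_size = if (!is.null(chrom_sizes)) sum(chrom_sizes),
      n_clones = length(unique(cleaned$reads$clone_id)),
      mean_insert = cfg$sim_insert_mean,
      trim_success_percent = cleaned$trim_success_percent)
  })
  write_tsv_file(report, file.path(out_dir, "report.tsv"))

  manifest <- pipeline_manifest(cfg, inputs, out_dir)
  write_tsv_file(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(config = cfg, cleaned = cleaned, repeats = rep_res,
                 ssr = ssr_res, top_hits = top, synteny = syn,
                 report = report, truth = sim_truth,
                 manifest = manifest))
}

write_tsv_file <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

stats_to_tsv <- function(stats) {
  keys <- c("n_reads", "n_after_trim", "n_redundant_removed", "n_final",
            "total_bp", "mean_len_bp", "min_len", "max_len",
            "gc_percent", "at_percent", "n_mate_pairs")
  tibble(key = keys,
         value = vapply(keys, function(k) as.numeric(stats[[k]]),
                        numeric(1)))
}

write_microsynteny_bed <- function(ms, path) {
  lines <- paste(ms$chrom, ms$span_start, ms$span_end, ms$clone_id,
                 ms$type, "+", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

pipeline_manifest <- function(cfg, inputs, out_dir) {
  param_keys <- sort(setdiff(names(cfg), "out_dir"))
  params <- tibble(
    key = paste0("param:", param_keys),
    value = vapply(param_keys, function(k)
      paste(format(cfg[[k]], trim = TRUE), collapse = ","), character(1)))
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  in_md5 <- tibble(
    key = paste0("input_md5:", basename(inputs)),
    value = unname(tools::md5sum(inputs)))
  outs <- sort(setdiff(list.files(out_dir, full.names = TRUE,
                                  recursive = TRUE),
                       file.path(out_dir, "manifest.tsv")))
  outs <- outs[!dir.exists(outs)]
  out_md5 <- tibble(
    key = paste0("output_md5:", sub(paste0("^", out_dir, "/?"), "",
                                    outs)),
    value = unname(tools::md5sum(outs)))
  bind_rows(params, in_md5, out_md5)
}

#' Read a repeat library FASTA (`>id #family` description convention)
#'
#' @param path FASTA file; a `#family` suffix in the description sets the
#'   family class (default `Unknown`).
#' @return Repeat-library tibble.
#' @export
read_repeat_library_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  fam <- ifelse(grepl("#", nm),
                sub("^.*#\\s*", "", nm), "Unknown")
  fam[!fam %in% repeat_families] <- "Unknown"
  repeat_library_tbl(id, fam, as.character(x))
}

#' Write a repeat library FASTA with `#family` descriptions
#'
#' @param lib Repeat-library tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_repeat_library_fasta <- function(lib, path) {
  x <- Biostrings::DNAStringSet(setNames(lib$seq,
                                         paste(lib$id, "", lib$family,
                                               sep = "#")))
  names(x) <- paste0(lib$id, " #", lib$family)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
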