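`%||%` <- function(x, y) if (is.null(x)) y else x

#' Generate random DNA sequence
#'
#' Uniform i.i.d. nucleotides with a given base composition. Teleost
#' genomes are A/T rich; the default composition is ~63% A/T.
#'
#' @param n Sequence length in bp.
#' @param base_comp Named probability vector over A, C, G, T.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, base_comp = c(A = 0.316, C = 0.184, G = 0.184, T = 0.316)) {
  stopifnot(n >= 0)
  if (n == 0) return("")
  paste(sample(names(base_comp), n, replace = TRUE, prob = base_comp),
        collapse = "")
}

#' Reverse complement of character sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitute each site independently with probability `rate`, uniformly
# among the three alternative bases. Non-ACGT characters are left alone.
# Returns list(seq=, n_sub=, positions=) with 1-based substituted positions.
mutate_sites <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) {
    return(list(seq = seq, n_sub = 0L, positions = integer()))
  }
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate & v %in% c("A", "C", "G", "T"))
  if (length(hit)) {
    alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- mapply(function(b, k) alts[[b]][k], v[hit], pick,
                     USE.NAMES = FALSE)
  }
  list(seq = paste(v, collapse = ""), n_sub = length(hit), positions = hit)
}

# Phred helpers: integer scores <-> Phred+33 string
quals_to_string <- function(q) {
  vapply(q, function(x) rawToChar(as.raw(pmin(x, 93L) + 33L)), character(1))
}
string_to_quals <- function(s) {
  lapply(s, function(x) as.integer(charToRaw(x)) - 33L)
}

# 0-based half-open intervals -> IRanges (1-based closed)
to_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)
from_iranges <- function(ir) {
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# union width of 0-based half-open intervals
union_width <- function(start, end) {
  if (length(start) == 0) return(0L)
  sum(IRanges::width(IRanges::reduce(to_iranges(start, end))))
}

# uniform integer in [a, b]; safe when a == b (unlike sample(a:b, 1))
rint <- function(a, b) if (a >= b) as.integer(a) else
  sample.int(b - a + 1L, 1L) + a - 1L

# is `motif` a repetition of a shorter motif?
is_atomic_motif <- function(motif) {
  L <- nchar(motif)
  if (L < 1) return(FALSE)
  for (p in seq_len(L - 1)) {
    if (L %% p == 0) {
      unit <- substr(motif, 1, p)
      if (strrep(unit, L / p) == motif) return(FALSE)
    }
  }
  TRUE
}

# stride-sampled k-mers of a character sequence; always includes the last
# full window. Returns tibble(qpos, kmer) with 0-based qpos.
sample_kmers <- function(seq, k, stride) {
  n <- nchar(seq)
  if (n < k) return(tibble(qpos = integer(), kmer = character()))
  s <- unique(c(seq(1L, n - k + 1L, by = stride), n - k + 1L))
  tibble(qpos = s - 1L, kmer = substring(seq, s, s + k - 1L))
}

nucleotide_scoring <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                    baseOnly = FALSE)
      # ambiguity codes never score as a match
      m[m < 1] <- -2
      diag(m)[rownames(m) != "A" & rownames(m) != "C" &
              rownames(m) != "G" & rownames(m) != "T"] <- -2
      mat <<- m
    }
    mat
  }
})

# Local alignment with the survey's nucleotide scoring
# (match +1, mismatch -2, gap open 5, gap extend 2).
local_align <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = "local",
    substitutionMatrix = nucleotide_scoring(),
    gapOpening = 5, gapExtension = 2)
}

aln_gap_opens <- function(aln) {
  ip <- Biostrings::indel(Biostrings::pattern(aln))
  is <- Biostrings::indel(Biostrings::subject(aln))
  length(ip[[1]]) + length(is[[1]])
}

aln_columns <- function(aln) {
  nchar(as.character(Biostrings::alignedPattern(aln)))
}
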