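#' BES read tables
#'
#' BES are held in a plain tibble with one row per read and columns
#' `id`, `clone_id`, `end` (`"F"`/`"R"`), `seq` and `qual` (Phred+33
#' string, `NA` for FASTA input). Read ids follow the `<clone>_F` /
#' `<clone>_R` convention; ids not matching it get `end = NA` and
#' `clone_id` equal to the full id.
#'
#' @param id Character vector of read ids.
#' @param seq Character vector of sequences.
#' @param qual Optional character vector of Phred+33 quality strings.
#' @return A `bes_reads` tibble.
#' @export
bes_reads <- function(id, seq, qual = NA_character_) {
  stopifnot(length(id) == length(seq))
  qual <- rep_len(qual, length(id))
  ok <- is.na(qual) | nchar(qual) == nchar(seq)
  if (!all(ok)) {
    stop("quality string length differs from sequence length for read(s): ",
         paste(head(id[!ok]), collapse = ", "))
  }
  has_end <- grepl("_[FR]$", id)
  out <- tibble(
    id = as.character(id),
    clone_id = ifelse(has_end, sub("_[FR]$", "", id), id),
    end = ifelse(has_end, sub("^.*_([FR])$", "\\1", id), NA_character_),
    seq = toupper(as.character(seq)),
    qual = as.character(qual)
  )
  class(out) <- c("bes_reads", class(out))
  out
}

empty_reads <- function() bes_reads(character(), character(), character())

#' Read BES from FASTQ or FASTA
#'
#' @param path Input file.
#' @return A [bes_reads] tibble (FASTA input has `qual = NA`).
#' @export
read_bes_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- as.character(S4Vectors::mcols(x)$qualities)
  bes_reads(sub("\\s.*$", "", names(x)), as.character(x), q)
}

#' @rdname read_bes_fastq
#' @export
read_bes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  bes_reads(sub("\\s.*$", "", names(x)), as.character(x))
}

#' Write BES to FASTA / FASTQ
#'
#' @param reads A [bes_reads] tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bes_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' @rdname write_bes_fasta
#' @export
write_bes_fastq <- function(reads, path) {
  if (anyNA(reads$qual)) stop("cannot write FASTQ: some reads lack qualities")
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
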