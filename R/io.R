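#' Read a protein FASTA into a named character vector
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_proteins <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a named character vector of proteins to FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta_proteins <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

phred_to_char <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(as.integer(v) + 33L)), character(1))
}

char_to_phred <- function(s) {
  lapply(s, function(v) as.integer(charToRaw(v)) - 33L)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @return `list(ids, seqs, quals)` with `quals` a list of integer Phred
#'   vectors.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qs <- as.character(S4Vectors::mcols(x)$qualities)
  list(ids = names(x), seqs = as.character(x), quals = char_to_phred(qs))
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param ids,seqs,quals Read ids, sequences and integer Phred quality
#'   vectors (list).
#' @param path Output file.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  dna <- Biostrings::DNAStringSet(setNames(seqs, ids))
  q <- Biostrings::BStringSet(phred_to_char(quals))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = q)
  invisible(path)
}

# Write a TSV with "# key=value" header comment lines (config echo).
write_tsv_commented <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}
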