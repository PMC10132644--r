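# Thin wrappers around Biostrings for the plain-text sequence formats the
# pipeline consumes and emits. Synthetic reads carry a fixed Phred+33
# quality ('I' = Q40); the classifier is quality-agnostic.

#' Read a FASTQ file into a data.frame of id + sequence
#' @param path FASTQ path (4-line records, Phred+33).
#' @return data.frame with columns `id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = FALSE)
  data.frame(id = names(x), seq = as.character(x),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write id + sequence records to FASTQ
#' @param reads data.frame with columns `id`, `seq`.
#' @param path Output path.
#' @param quality_char Fixed per-base quality character (default "I", Q40).
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$id
  quals <- Biostrings::BStringSet(vapply(
    nchar(reads$seq),
    function(n) strrep(quality_char, n),
    character(1)
  ))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
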