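#' Read and write FASTQ (Phred+33)
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that move reads between files and the
#' plain data.frame representation used throughout the pipeline.
#'
#' @param reads A data.frame with columns `read_id`, `bases`, `qualities`.
#' @param path FASTQ file path.
#' @return `read_fastq()` returns a data.frame with columns `read_id`,
#'   `bases`, `qualities`; `write_fastq()` returns `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qualities))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x),
             bases = as.character(x),
             qualities = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Read and write the simulation truth sidecar
#'
#' The sidecar is a TSV with one row per tagged template molecule
#' (`molecule_id`, `allele_id`, `umi`, `n_reads`).
#'
#' @param truth Truth data.frame as produced by [sequence_reads()].
#' @param path TSV path.
#' @return `read_truth()` returns the truth data.frame; `write_truth()`
#'   returns `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(molecule_id = "character", umi = "character"))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
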