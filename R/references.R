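#' Primer architecture constants
#'
#' The barcoding primer pair defines the fixed architecture of every read in
#' this assay. The reverse barcoding primer contributes a constant Illumina
#' tail followed by the 12-nt UMI and a gene-specific segment; the forward
#' primer contributes the gene-specific segment at the far end plus its own
#' Illumina tail, which appears reverse-complemented at the 3' end of a
#' full-length read.
#'
#' @return A single DNA string.
#' @name primer_architecture
NULL

#' @describeIn primer_architecture Constant tail preceding the UMI at the
#'   read's 5' end (from the reverse barcoding primer).
#' @export
umi_constant_prefix <- function() "GGACACTCTTTCCCTACACGACGCTCTTCCGATCT"

#' @describeIn primer_architecture Gene-specific segment immediately 3' of
#'   the UMI; shared 5' flank of all three allele amplicons.
#' @export
flank_5p <- function() "ATGGGAAAGAGTGTCCCTCTGCTGGGAAAGCGG"

#' @describeIn primer_architecture Shared 3' flank of all three amplicons
#'   (reverse complement of the forward primer's gene-specific segment).
#' @export
flank_3p <- function() "GCAGTTGCCACAAAAATACTCA"

#' @describeIn primer_architecture Adapter read-through sequence at the 3'
#'   end of a full-length read (reverse complement of the forward primer's
#'   Illumina tail); the default adapter for trimming.
#' @export
adapter_3p <- function() "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"

#' Generate the three allele reference amplicons
#'
#' The assay distinguishes alleles by amplicon identity and length: wildtype
#' Braf (185 bp), native Braf-CA (308 bp) and activated Braf-CA (335 bp).
#' The actual murine sequences are not required by the pipeline, which is
#' sequence-agnostic: references are built with the published gene-specific
#' primer segments as shared flanks and independent random interiors, which
#' makes the three amplicons mutually far apart in edit distance so that
#' error-free reads are unambiguous.
#'
#' @param seed Integer seed; the same seed always yields byte-identical
#'   references.
#' @param lengths Integer vector of three amplicon lengths in bp, in the
#'   order wt, ca_native, ca_active.
#' @return A named [Biostrings::DNAStringSet] with elements `wt`,
#'   `ca_native`, `ca_active` of exactly the requested lengths.
#' @examples
#' refs <- make_references(seed = 1)
#' Biostrings::width(refs)
#' @export
make_references <- function(seed = 1L, lengths = c(185L, 308L, 335L)) {
  if (length(lengths) != 3L || any(is.na(lengths)))
    stop("lengths must be three amplicon lengths (wt, ca_native, ca_active)",
         call. = FALSE)
  lengths <- as.integer(lengths)
  f5 <- flank_5p(); f3 <- flank_3p()
  min_len <- nchar(f5) + nchar(f3) + 1L
  if (any(lengths < min_len))
    stop("each amplicon length must exceed the combined flank length (",
         nchar(f5) + nchar(f3), " bp); got ",
         paste(lengths, collapse = "/"), call. = FALSE)
  seqs <- with_seed(seed, function() {
    vapply(lengths, function(len) {
      mid <- paste(sample(c("A", "C", "G", "T"),
                          len - nchar(f5) - nchar(f3), replace = TRUE),
                   collapse = "")
      paste0(f5, mid, f3)
    }, character(1))
  })
  refs <- Biostrings::DNAStringSet(seqs)
  names(refs) <- allele_ids()
  refs
}

#' Read or write allele references as FASTA
#'
#' @param refs A named `DNAStringSet` as returned by [make_references()].
#' @param path FASTA file path.
#' @return `read_references()` returns a `DNAStringSet` named by allele;
#'   `write_references()` returns `path` invisibly.
#' @export
write_references <- function(refs, path) {
  Biostrings::writeXStringSet(refs, path)
  invisible(path)
}

#' @rdname write_references
#' @export
read_references <- function(path) {
  refs <- Biostrings::readDNAStringSet(path)
  missing <- setdiff(allele_ids(), names(refs))
  if (length(missing))
    stop("reference FASTA is missing allele(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  refs[allele_ids()]
}
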