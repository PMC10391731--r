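#' Trim a 3' adapter from reads
#'
#' Scans each read for the adapter: at every candidate start offset the
#' overlapping segment (the full adapter inside the read, or the adapter's
#' leading bases hanging off the read's 3' end) is compared against the
#' adapter, and the leftmost offset whose overlap is at least `min_overlap`
#' bases with at most `max_error_rate` mismatches wins; bases and qualities
#' are truncated at that offset (0-based, half-open). Reads without a match
#' are returned unchanged.
#'
#' @param bases Character vector of read sequences.
#' @param qualities Matching character vector of Phred+33 quality strings.
#' @param adapter Adapter sequence to remove (default: the assay's 3'
#'   read-through adapter, [adapter_3p()]).
#' @param min_overlap Minimum adapter overlap in bases (default 3).
#' @param max_error_rate Maximum mismatch fraction of the overlap
#'   (default 0.1).
#' @return A list with trimmed `bases` and `qualities` vectors plus
#'   `trimmed`, a logical vector marking reads that were cut.
#' @examples
#' trim_adapter("ACGTACGTAGATCGGAAGAGC", "IIIIIIIIIIIIIIIIIIIII",
#'              adapter = "AGATCGGAAGAGC")
#' @export
trim_adapter <- function(bases, qualities, adapter = adapter_3p(),
                         min_overlap = 3L, max_error_rate = 0.1) {
  if (!nzchar(adapter)) stop("adapter must be non-empty", call. = FALSE)
  stopifnot(length(bases) == length(qualities))
  cut <- trim_adapter_cpp(bases, adapter, as.integer(min_overlap),
                          max_error_rate)
  hit <- cut >= 0L
  bases[hit] <- substr(bases[hit], 1L, cut[hit])
  qualities[hit] <- substr(qualities[hit], 1L, cut[hit])
  list(bases = bases, qualities = qualities, trimmed = hit)
}

#' All-bases quality filter
#'
#' Reimplements the classic fastq_quality_filter rule `-q 20 -Q33 -p 100`:
#' a read passes only if at least `min_fraction` of its bases have Phred
#' quality at least `min_q` (defaults: every base at Q20 or better,
#' Phred+33 encoding). Malformed quality strings (characters below `!`)
#' fail and are counted in the `malformed` attribute.
#'
#' @param qualities Character vector of Phred+33 quality strings.
#' @param min_q Minimum per-base Phred score (default 20).
#' @param min_fraction Minimum fraction of bases meeting `min_q`
#'   (default 1.0, i.e. all bases).
#' @return Logical vector (pass/fail) with attribute `malformed` giving the
#'   number of records rejected for undecodable qualities.
#' @export
quality_filter <- function(qualities, min_q = 20L, min_fraction = 1.0) {
  res <- quality_filter_cpp(qualities, as.integer(min_q), min_fraction)
  pass <- res$pass
  attr(pass, "malformed") <- res$malformed
  if (res$malformed > 0L)
    warning(res$malformed, " record(s) had malformed quality strings",
            call. = FALSE)
  pass
}

#' Preprocess a read table: trim, length-gate, quality-filter
#'
#' Applies [trim_adapter()] and [quality_filter()] and discards reads too
#' short to carry a classifiable insert (shorter than the UMI constant
#' prefix + UMI + 10 bases after trimming).
#'
#' @param reads Read data.frame (`read_id`, `bases`, `qualities`, optional
#'   truth columns).
#' @param adapter,min_overlap,max_error_rate Passed to [trim_adapter()].
#' @param min_q,min_fraction Passed to [quality_filter()].
#' @param umi_length UMI length used in the minimum-length gate.
#' @return List: `reads` (the surviving, trimmed read table) and `log`, a
#'   one-row data.frame of counters (`n_in`, `n_trimmed`, `n_too_short`,
#'   `n_failed_quality`, `n_out`).
#' @export
preprocess_reads <- function(reads, adapter = adapter_3p(), min_overlap = 3L,
                             max_error_rate = 0.1, min_q = 20L,
                             min_fraction = 1.0, umi_length = 12L) {
  if (!is.data.frame(reads) || nrow(reads) == 0L)
    stop("preprocess: no input reads", call. = FALSE)
  n_in <- nrow(reads)
  tr <- trim_adapter(reads$bases, reads$qualities, adapter,
                     min_overlap, max_error_rate)
  reads$bases <- tr$bases
  reads$qualities <- tr$qualities
  min_len <- nchar(umi_constant_prefix()) + umi_length + 10L
  long_enough <- nchar(reads$bases) >= min_len
  reads <- reads[long_enough, , drop = FALSE]
  pass <- suppressWarnings(quality_filter(reads$qualities, min_q, min_fraction))
  out <- reads[pass, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out,
       log = data.frame(n_in = n_in,
                        n_trimmed = sum(tr$trimmed),
                        n_too_short = sum(!long_enough),
                        n_failed_quality = sum(!pass),
                        n_out = nrow(out)))
}
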