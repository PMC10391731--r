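#' Extract the UMI from reads anchored by the constant prefix
#'
#' The reverse barcoding primer places a constant 35-nt Illumina tail at the
#' read's 5' end, immediately followed by the 12-nt UMI and then the
#' gene-specific insert. The prefix must match the read start with at most
#' `max_mismatch` mismatches; otherwise the read is counted as "no-anchor"
#' and excluded. Reads whose UMI contains a non-ACGT character are dropped
#' (flagged, not returned as classifiable).
#'
#' @param bases,qualities Read sequences and Phred+33 qualities.
#' @param constant_prefix Constant tail preceding the UMI
#'   (default [umi_constant_prefix()]).
#' @param umi_length UMI length (default 12).
#' @param max_mismatch Maximum mismatches tolerated in the prefix
#'   (default 1).
#' @return A list of vectors aligned with the input: `umi`, `insert`,
#'   `insert_qual`, and `status` (one of `"ok"`, `"no_anchor"`,
#'   `"umi_invalid"`).
#' @export
extract_umi <- function(bases, qualities, constant_prefix = umi_constant_prefix(),
                        umi_length = 12L, max_mismatch = 1L) {
  plen <- nchar(constant_prefix)
  mm <- prefix_mismatches_cpp(bases, constant_prefix)
  anchored <- mm <= max_mismatch
  umi <- ifelse(anchored, substr(bases, plen + 1L, plen + umi_length), NA)
  insert <- ifelse(anchored, substr(bases, plen + umi_length + 1L,
                                    nchar(bases)), NA)
  insert_qual <- ifelse(anchored, substr(qualities, plen + umi_length + 1L,
                                         nchar(qualities)), NA)
  status <- ifelse(anchored, "ok", "no_anchor")
  bad_umi <- anchored & (grepl("[^ACGT]", umi) | nchar(umi) < umi_length)
  status[bad_umi] <- "umi_invalid"
  list(umi = umi, insert = insert, insert_qual = insert_qual, status = status)
}

#' Semi-global edit distance
#'
#' Unit-cost Levenshtein distance between `query` and `ref` with free
#' end-gaps on the reference: the query aligns end-to-end against any infix
#' of the reference. This is the metric used for allele assignment.
#'
#' @param query,ref DNA strings.
#' @return Integer edit distance.
#' @examples
#' edit_dist_semiglobal("ACGT", "TTACGTTT")  # 0
#' @export
edit_dist_semiglobal <- function(query, ref) {
  edit_dist_semiglobal_cpp(as.character(query), as.character(ref))
}

#' Assign inserts to alleles by semi-global edit distance
#'
#' Each insert is compared to the three allele references by unit-cost
#' Levenshtein distance with free end-gaps on the reference (the insert must
#' align end-to-end, the reference may overhang). The nearest reference is
#' called only when the best distance is at most `max_dist_fraction` of the
#' insert length *and* the second-best reference is at least `min_margin`
#' edits further away; everything else is `unclassified`. Distances above
#' the decision cap (allowed distance + margin) are reported saturated at
#' cap + 1, since their exact value cannot affect the call.
#'
#' @param inserts Character vector of insert sequences.
#' @param refs Named `DNAStringSet` of the three references.
#' @param max_dist_fraction Maximum best-distance as a fraction of insert
#'   length (default 0.1).
#' @param min_margin Minimum lead of best over second-best in edits
#'   (default 3).
#' @return A data.frame with `allele_call` (`wt`, `ca_native`, `ca_active`
#'   or `unclassified`), `dist_best`, `dist_second`.
#' @examples
#' refs <- make_references()
#' assign_allele(as.character(refs["ca_active"]), refs)
#' @export
assign_allele <- function(inserts, refs, max_dist_fraction = 0.1,
                          min_margin = 3L) {
  ref_names <- names(refs)
  ref_chr <- as.character(refs)
  n <- length(inserts)
  if (n == 0L)
    return(data.frame(allele_call = character(0), dist_best = integer(0),
                      dist_second = integer(0)))
  if (any(!nzchar(inserts) | is.na(inserts)))
    stop("assign_allele: inserts must be non-empty", call. = FALSE)
  len <- nchar(inserts)
  cap <- as.integer(floor(max_dist_fraction * len)) + as.integer(min_margin)

  # distances are computed once per distinct insert; inserts identical to a
  # reference reuse precomputed reference-vs-reference distances
  uq <- unique(inserts)
  map <- match(inserts, uq)
  ulen <- nchar(uq)
  ucap <- as.integer(floor(max_dist_fraction * ulen)) + as.integer(min_margin)
  d <- matrix(NA_integer_, nrow = length(uq), ncol = length(ref_chr))
  exact <- match(uq, ref_chr)
  hit <- which(!is.na(exact))
  if (length(hit)) {
    for (i in hit) {
      for (j in seq_along(ref_chr))
        d[i, j] <- if (j == exact[i]) 0L else
          min(edit_dist_semiglobal_cpp(ref_chr[exact[i]], ref_chr[j]),
              ucap[i] + 1L)
    }
  }
  todo <- which(is.na(exact))
  if (length(todo))
    d[todo, ] <- dist_to_refs_cpp(uq[todo], ref_chr, ucap[todo])

  ord1 <- max.col(-d, ties.method = "first")
  best <- d[cbind(seq_len(nrow(d)), ord1)]
  d2 <- d
  d2[cbind(seq_len(nrow(d)), ord1)] <- NA_integer_
  second <- apply(d2, 1L, min, na.rm = TRUE)
  ok <- best <= floor(max_dist_fraction * ulen) & (second - best) >= min_margin
  call_u <- ifelse(ok, ref_names[ord1], "unclassified")

  data.frame(allele_call = call_u[map],
             dist_best = best[map],
             dist_second = as.integer(second)[map],
             stringsAsFactors = FALSE)
}

#' Classify a preprocessed read table
#'
#' Orientation-normalizes reads (reads whose reverse complement matches the
#' UMI prefix are flipped), extracts UMIs, and assigns alleles. Every input
#' read ends in exactly one category: an allele call, `unclassified`,
#' `no_anchor`, or `umi_invalid`.
#'
#' @param reads Preprocessed read data.frame (`read_id`, `bases`,
#'   `qualities`).
#' @param refs Allele references.
#' @param constant_prefix,umi_length,max_mismatch Passed to [extract_umi()].
#' @param max_dist_fraction,min_margin Passed to [assign_allele()].
#' @return A list with `classified` (data.frame: `read_id`, `umi`,
#'   `allele_call`, `dist_best`, `dist_second`, plus truth columns when
#'   present) and `categories`, a named count vector over all input reads.
#' @export
classify_reads <- function(reads, refs,
                           constant_prefix = umi_constant_prefix(),
                           umi_length = 12L, max_mismatch = 1L,
                           max_dist_fraction = 0.1, min_margin = 3L) {
  stopifnot(is.data.frame(reads))
  bases <- reads$bases
  quals <- reads$qualities
  mm <- prefix_mismatches_cpp(bases, constant_prefix)
  flip <- which(mm > max_mismatch)
  if (length(flip)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(bases[flip])))
    rc_ok <- prefix_mismatches_cpp(rc, constant_prefix) <= max_mismatch
    bases[flip[rc_ok]] <- rc[rc_ok]
    quals[flip[rc_ok]] <- vapply(quals[flip[rc_ok]], function(q)
      paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = ""),
      character(1), USE.NAMES = FALSE)
  }
  ex <- extract_umi(bases, quals, constant_prefix, umi_length, max_mismatch)
  ok <- ex$status == "ok" & nzchar(ex$insert)
  calls <- rep(NA_character_, length(bases))
  db <- ds <- rep(NA_integer_, length(bases))
  if (any(ok)) {
    asg <- assign_allele(ex$insert[ok], refs, max_dist_fraction, min_margin)
    calls[ok] <- asg$allele_call
    db[ok] <- asg$dist_best
    ds[ok] <- asg$dist_second
  }
  category <- ifelse(ex$status != "ok", ex$status,
                     ifelse(nzchar(ex$insert), calls, "unclassified"))
  classified <- data.frame(read_id = reads$read_id, umi = ex$umi,
                           allele_call = calls, dist_best = db,
                           dist_second = ds, stringsAsFactors = FALSE)
  for (col in c("molecule_id", "allele_id"))
    if (col %in% names(reads)) classified[[paste0("truth_", col)]] <- reads[[col]]
  if ("umi" %in% names(reads)) classified$truth_umi <- reads$umi
  keep <- ex$status == "ok" & nzchar(ex$insert)
  list(classified = classified[keep, , drop = FALSE],
       categories = table(factor(category,
         levels = c(allele_ids(), "unclassified", "no_anchor", "umi_invalid"))))
}
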