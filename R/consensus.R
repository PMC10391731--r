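#' Group classified reads into barcode families
#'
#' Reads sharing one UMI (exact string match) form one barcode family.
#' Families with fewer than `family_min_reads` reads are marked `discarded`
#' (PCR-duplicate floor: only UMIs seen in at least 3 reads count as genuine
#' founding molecules by default). Unclassified reads contribute to a
#' family's size but cast no allele vote. An optional Hamming-distance-1
#' merge collapses likely sequencing-error UMIs into their largest neighbor
#' (off by default; grouping is exact-match as the assay prescribes).
#'
#' @param classified Data.frame from [classify_reads()] (`umi`,
#'   `allele_call`).
#' @param family_min_reads Minimum reads per retained family (default 3).
#' @param min_vote_fraction Minimum plurality vote share for a consensus
#'   call (default 0.6); see [consensus_allele()].
#' @param merge_hamming1 If `TRUE`, merge UMIs at Hamming distance 1 into
#'   the larger family before thresholding (default `FALSE`).
#' @return A data.frame with one row per distinct UMI: `umi`, `n_reads`,
#'   per-allele vote counts (`votes_wt`, `votes_ca_native`,
#'   `votes_ca_active`, `votes_unclassified`) and `consensus` (an allele id
#'   or `discarded`).
#' @export
build_families <- function(classified, family_min_reads = 3L,
                           min_vote_fraction = 0.6, merge_hamming1 = FALSE) {
  stopifnot(is.data.frame(classified),
            all(c("umi", "allele_call") %in% names(classified)))
  umi <- classified$umi
  if (merge_hamming1 && length(unique(umi)) > 1L)
    umi <- merge_umis_hamming1(umi)
  lv <- c(allele_ids(), "unclassified")
  votes <- table(umi, factor(classified$allele_call, levels = lv))
  fam <- data.frame(umi = rownames(votes),
                    n_reads = as.integer(rowSums(votes)),
                    stringsAsFactors = FALSE)
  for (a in lv) fam[[paste0("votes_", a)]] <- as.integer(votes[, a])
  v <- matrix(as.integer(votes[, allele_ids()]), ncol = 3L)
  tot <- rowSums(v)
  top <- pmax(v[, 1L], v[, 2L], v[, 3L])
  tied <- rowSums(v == top) > 1L
  cons <- allele_ids()[max.col(v, ties.method = "first")]
  bad <- tot == 0L | tied | (top / pmax(tot, 1L)) < min_vote_fraction
  fam$consensus <- ifelse(bad, "discarded", cons)
  fam$consensus[fam$n_reads < family_min_reads] <- "discarded"
  rownames(fam) <- NULL
  fam
}

#' Consensus allele call within one barcode family
#'
#' The family's consensus is the allele with the plurality of allele votes,
#' provided its share among allele-voting reads (unclassified reads do not
#' vote) is at least `min_vote_fraction`; ties and sub-threshold pluralities
#' are `discarded`.
#'
#' @param votes Integer vector of per-allele vote counts in [allele_ids()]
#'   order, or a named vector containing those names.
#' @param min_vote_fraction Minimum vote share (default 0.6).
#' @return A single string: an allele id or `"discarded"`.
#' @examples
#' consensus_allele(c(wt = 1, ca_native = 0, ca_active = 5))
#' @export
consensus_allele <- function(votes, min_vote_fraction = 0.6) {
  if (!is.null(names(votes))) votes <- votes[allele_ids()]
  votes <- as.integer(votes)
  tot <- sum(votes)
  if (tot == 0L) return("discarded")
  top <- max(votes)
  if (sum(votes == top) > 1L) return("discarded")
  if (top / tot < min_vote_fraction) return("discarded")
  allele_ids()[which.max(votes)]
}

merge_umis_hamming1 <- function(umi) {
  counts <- sort(table(umi), decreasing = TRUE)
  canon <- names(counts)
  remap <- stats::setNames(canon, canon)
  for (i in rev(seq_along(canon))) {
    if (i == 1L) break
    cand <- canon[seq_len(i - 1L)]
    h1 <- cand[hamming1(canon[i], cand)]
    if (length(h1)) remap[canon[i]] <- h1[1L]
  }
  unname(remap[umi])
}

hamming1 <- function(x, ys) {
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  vapply(strsplit(ys, "", fixed = TRUE),
         function(y) length(y) == length(xs) && sum(y != xs) == 1L,
         logical(1))
}

#' Tally consensus families per allele class
#'
#' @param families Data.frame from [build_families()].
#' @param sample_id Sample label carried into the result.
#' @return An `allele_family_counts` object: a list with `sample_id`,
#'   `raw` (named integer vector of retained consensus families per allele)
#'   and placeholders for the noise floor (`floored`, `suppressed`), filled
#'   by [apply_noise_floor()].
#' @export
count_families <- function(families, sample_id = "sample") {
  raw <- vapply(allele_ids(), function(a)
    sum(families$consensus == a), integer(1))
  structure(list(sample_id = sample_id, raw = raw,
                 floored = raw, suppressed = stats::setNames(
                   rep(FALSE, 3L), allele_ids()),
                 max_noise_families = NA_integer_),
            class = "allele_family_counts")
}

#' Apply the background-noise family floor
#'
#' Residual noise survives UMI correction at a low rate, so any allele class
#' observed in at most `max_noise_families` barcode families per sample is
#' treated as background: its floored count is reported as 0 with the
#' suppressed flag set, while the raw count is always preserved.
#'
#' @param counts An `allele_family_counts` object from [count_families()].
#' @param max_noise_families Largest family count still considered
#'   background (default 6: six or fewer families are noise, seven are a
#'   signal).
#' @return The updated `allele_family_counts` object.
#' @examples
#' fam <- data.frame(umi = "AAAA", n_reads = 3, consensus = "ca_active")
#' apply_noise_floor(count_families(fam))
#' @export
apply_noise_floor <- function(counts, max_noise_families = 6L) {
  stopifnot(inherits(counts, "allele_family_counts"))
  supp <- counts$raw <= max_noise_families
  counts$floored <- ifelse(supp, 0L, counts$raw)
  names(counts$floored) <- names(counts$raw)
  counts$suppressed <- supp
  counts$max_noise_families <- as.integer(max_noise_families)
  counts
}

#' @export
print.allele_family_counts <- function(x, ...) {
  cat("allele_family_counts [", x$sample_id, "]\n", sep = "")
  m <- rbind(raw = x$raw, floored = x$floored,
             suppressed = as.integer(x$suppressed))
  print(m)
  invisible(x)
}
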