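# Independent reference implementations used as oracles. These are written
# as direct transcriptions of the definitions (full DP matrices, exhaustive
# scans) and stay independent of the package's optimized code paths.

# Full-matrix unit-cost edit distance with free end-gaps on the reference:
# query rows are global, reference columns are free at both ends.
semiglobal_oracle <- function(query, ref) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  m <- length(q); n <- length(r)
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1L] <- 0:m
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + (q[i] != r[j]),
                               D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L)
    }
  }
  min(D[m + 1L, ])
}

# Exhaustive-offset 3'-adapter scan: leftmost offset whose overlap with the
# adapter start is >= min_overlap bases and has <= floor(err * overlap)
# mismatches; -1 when no offset qualifies.
trim_cut_oracle <- function(read, adapter, min_overlap = 3L,
                            max_error_rate = 0.1) {
  b <- strsplit(read, "", fixed = TRUE)[[1]]
  a <- strsplit(adapter, "", fixed = TRUE)[[1]]
  for (s in seq_len(max(length(b) - min_overlap + 1L, 0L))) {
    ov <- min(length(b) - s + 1L, length(a))
    mm <- sum(b[s:(s + ov - 1L)] != a[seq_len(ov)])
    if (ov >= min_overlap && mm <= floor(max_error_rate * ov)) return(s - 1L)
  }
  -1L
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_umis_for_test <- function(n) {
  umis <- unique(vapply(seq_len(2L * n + 10L), function(i) random_dna(12L),
                        character(1)))
  umis[seq_len(n)]
}

# deterministic substitution: rotates the base one step through ACGT
mutate_bases_at <- function(s, positions) {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  v[positions] <- rot[v[positions]]
  paste(v, collapse = "")
}

mutate_bases <- function(s, positions) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in positions) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[sample.int(3L, 1L)]
  paste(v, collapse = "")
}

# A small, fully noiseless sample used by exact-equality oracles.
zero_error_sim <- function(seed, n_cells = 150L, fraction = 0.2,
                           mean_reads = 10) {
  refs <- make_references()
  m <- sample_model(n_cells = n_cells, activated_cell_fraction = fraction,
                    templates_per_allele_per_cell = 1,
                    mean_reads_per_molecule = mean_reads,
                    pcr_error_rate = 0, seq_error_rate = 0, seed = seed)
  mols <- simulate_sample(refs, m)
  sim <- sequence_reads(mols, refs, m)
  list(refs = refs, model = m, reads = sim$reads, truth = sim$truth)
}

# In-memory pipeline: preprocess -> classify -> quantify with defaults.
run_in_memory <- function(reads, refs, sample_id = "s",
                          thresholds = default_thresholds()) {
  pre <- preprocess_reads(reads, thresholds$adapter, thresholds$min_overlap,
                          thresholds$max_error_rate, thresholds$min_q,
                          thresholds$min_fraction, thresholds$umi_length)
  cls <- classify_reads(pre$reads, refs, thresholds$constant_prefix,
                        thresholds$umi_length, thresholds$max_mismatch,
                        thresholds$max_dist_fraction, thresholds$min_margin)
  qt <- quantify_sample(cls$classified, sample_id, thresholds)
  list(pre = pre, cls = cls, report = qt$report, families = qt$families,
       counts = qt$counts)
}
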