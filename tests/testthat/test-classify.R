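test_that("planted UMIs are extracted at the prefix offset", {
  prefix <- umi_constant_prefix()
  insert <- "ACGGATTACAGGATTACA"
  read <- paste0(prefix, "ACGTACGTACGT", insert)
  qual <- strrep("I", nchar(read))
  ex <- extract_umi(read, qual)
  expect_identical(ex$umi, "ACGTACGTACGT")
  expect_identical(ex$insert, insert)
  expect_identical(ex$status, "ok")
})

test_that("one mismatch in the prefix is tolerated, two are not", {
  prefix <- umi_constant_prefix()
  p1 <- mutate_bases(prefix, 5)
  set.seed(2)
  read1 <- paste0(p1, "ACGTACGTACGT", random_dna(30))
  ex1 <- extract_umi(read1, strrep("I", nchar(read1)))
  expect_identical(ex1$umi, "ACGTACGTACGT")
  p2 <- mutate_bases(prefix, c(5, 9))
  read2 <- paste0(p2, "ACGTACGTACGT", random_dna(30))
  ex2 <- extract_umi(read2, strrep("I", nchar(read2)))
  expect_identical(ex2$status, "no_anchor")
})

test_that("reads with N in the UMI are dropped and counted", {
  prefix <- umi_constant_prefix()
  read <- paste0(prefix, "ACGTNCGTACGT", strrep("A", 30))
  ex <- extract_umi(read, strrep("I", nchar(read)))
  expect_identical(ex$status, "umi_invalid")
})

test_that("zero-error extraction recovers every planted UMI", {
  sim <- zero_error_sim(seed = 23, n_cells = 100, mean_reads = 5)
  pre <- preprocess_reads(sim$reads)
  ex <- extract_umi(pre$reads$bases, pre$reads$qualities)
  expect_true(all(ex$status == "ok"))
  expect_identical(ex$umi, pre$reads$umi)
})

test_that("inserts identical to a reference are called at distance zero", {
  refs <- make_references()
  for (a in allele_ids()) {
    asg <- assign_allele(as.character(refs[[a]]), refs)
    expect_identical(asg$allele_call, a)
    expect_identical(asg$dist_best, 0L)
    expect_gte(asg$dist_second - asg$dist_best, 3L)
  }
})

test_that("equidistant inserts fall to unclassified by the margin rule", {
  set.seed(3)
  r1 <- strrep("ACGT", 10)
  r2 <- mutate_bases(r1, c(5, 15))       # distance 2 from r1
  refs <- Biostrings::DNAStringSet(c(a = r1, b = r2))
  insert <- mutate_bases(r1, 5)          # distance 1 from both
  asg <- assign_allele(insert, refs)
  expect_identical(asg$allele_call, "unclassified")
  expect_identical(asg$dist_best, 1L)
})

test_that("noisy inserts match the full-DP Levenshtein oracle", {
  refs <- make_references()
  wt <- as.character(refs[["wt"]])
  set.seed(31)
  two_off <- mutate_bases(wt, sample(nchar(wt), 2))
  asg <- assign_allele(two_off, refs)
  expect_identical(asg$allele_call, "wt")
  expect_identical(asg$dist_best, 2L)
  expect_identical(asg$dist_best, semiglobal_oracle(two_off, wt))
  # random substitution loads against every reference
  for (i in 1:12) {
    a <- sample(allele_ids(), 1)
    r <- as.character(refs[[a]])
    k <- sample(0:5, 1)
    ins <- if (k > 0) mutate_bases(r, sample(nchar(r), k)) else r
    asg <- assign_allele(ins, refs)
    expect_identical(asg$allele_call, a)
    expect_identical(asg$dist_best, semiglobal_oracle(ins, r))
  }
})

test_that("semi-global distance gives free end-gaps on the reference only", {
  expect_identical(edit_dist_semiglobal("ACGT", "TTTACGTTTT"), 0L)
  expect_identical(edit_dist_semiglobal("TTTACGTTTT", "ACGT"), 6L)
  set.seed(13)
  for (i in 1:10) {
    q <- random_dna(sample(5:25, 1))
    r <- random_dna(sample(5:40, 1))
    expect_identical(edit_dist_semiglobal(q, r), semiglobal_oracle(q, r))
  }
})

test_that("every read lands in exactly one category", {
  refs <- make_references()
  m <- sample_model(n_cells = 300, activated_cell_fraction = 0.1,
                    seq_error_rate = 0.01, seed = 44)
  sim <- sequence_reads(simulate_sample(refs, m), refs, m)
  pre <- preprocess_reads(sim$reads)
  cls <- classify_reads(pre$reads, refs)
  expect_identical(sum(cls$categories), nrow(pre$reads))
  expect_identical(sum(cls$categories[allele_ids()]) +
                     cls$categories[["unclassified"]],
                   nrow(cls$classified))
})

test_that("zero-error reads classify to their truth allele without exception", {
  sim <- zero_error_sim(seed = 29, n_cells = 120)
  pre <- preprocess_reads(sim$reads)
  cls <- classify_reads(pre$reads, refs = make_references())
  expect_identical(cls$classified$allele_call, cls$classified$truth_allele_id)
})

test_that("reverse-complement reads are flipped before extraction", {
  sim <- zero_error_sim(seed = 37, n_cells = 30)
  pre <- preprocess_reads(sim$reads)
  reads <- pre$reads
  flip <- seq_len(nrow(reads)) %% 2 == 0
  reads$bases[flip] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads$bases[flip])))
  cls <- classify_reads(reads, make_references())
  expect_identical(cls$classified$allele_call, cls$classified$truth_allele_id)
  expect_identical(cls$categories[["no_anchor"]], 0L)
})

test_that("native/activated confusion is rare even at 0.5% sequencing error", {
  refs <- make_references()
  m <- sample_model(n_cells = 1500, activated_cell_fraction = 0.5,
                    templates_per_allele_per_cell = 0.5,
                    mean_reads_per_molecule = 3,
                    seq_error_rate = 0.005, seed = 71)
  sim <- sequence_reads(simulate_sample(refs, m), refs, m)
  pre <- preprocess_reads(sim$reads, min_q = 0)  # keep all reads
  cls <- classify_reads(pre$reads, refs)
  d <- cls$classified
  ca <- d$truth_allele_id %in% c("ca_native", "ca_active")
  swapped <- ca & d$allele_call %in% c("ca_native", "ca_active") &
    d$allele_call != d$truth_allele_id
  expect_lt(sum(swapped) / max(sum(ca), 1), 1e-3)
})
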