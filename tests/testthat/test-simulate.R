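test_that("model validation rejects out-of-range parameters", {
  expect_error(sample_model(activated_cell_fraction = -0.1, seed = 1), "\\[0, 1\\]")
  expect_error(sample_model(activated_cell_fraction = 1.2, seed = 1), "\\[0, 1\\]")
  expect_error(sample_model(seed = 1, templates_per_allele_per_cell = 0),
               "positive")
  expect_error(sample_model(n_cells = 100, activated_cell_fraction = 0.5),
               "seed")
})

test_that("boundary fractions produce pure molecule pools", {
  refs <- make_references()
  m0 <- sample_model(n_cells = 500, activated_cell_fraction = 0, seed = 3)
  expect_equal(sum(simulate_sample(refs, m0)$allele_id == "ca_active"), 0)
  m1 <- sample_model(n_cells = 500, activated_cell_fraction = 1, seed = 3)
  mols1 <- simulate_sample(refs, m1)
  expect_equal(sum(mols1$allele_id == "ca_native"), 0)
  expect_gt(sum(mols1$allele_id == "ca_active"), 0)
})

test_that("molecule simulation is reproducible and UMIs are well-formed", {
  refs <- make_references()
  m <- sample_model(n_cells = 300, activated_cell_fraction = 0.1, seed = 9)
  a <- simulate_sample(refs, m)
  b <- simulate_sample(refs, m)
  expect_identical(a, b)
  expect_true(all(nchar(a$umi) == 12L))
  expect_true(all(grepl("^[ACGT]+$", a$umi)))
  expect_false(any(duplicated(a$molecule_id)))
})

test_that("activated molecule share matches the binomial sampling oracle", {
  refs <- make_references()
  ratios <- vapply(1:50, function(s) {
    m <- sample_model(n_cells = 10000, activated_cell_fraction = 0.005,
                      seed = 1000 + s)
    mols <- simulate_sample(refs, m)
    ca <- mols$allele_id != "wt"
    sum(mols$allele_id == "ca_active") / sum(ca)
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.005), 3 * se)
})

test_that("expected molecule count is 2 * n_cells * capture efficiency", {
  refs <- make_references()
  n <- vapply(1:30, function(s) {
    m <- sample_model(n_cells = 2000, activated_cell_fraction = 0.1,
                      templates_per_allele_per_cell = 0.5, seed = 400 + s)
    nrow(simulate_sample(refs, m))
  }, numeric(1))
  # Poisson with mean 2 * 2000 * 0.5 = 2000
  expect_lt(abs(mean(n) - 2000), 3 * stats::sd(n) / sqrt(30))
})

test_that("zero-noise reads are byte-identical to their source template", {
  sim <- zero_error_sim(seed = 21, n_cells = 50)
  refs_chr <- as.character(sim$refs)
  expected <- paste0(umi_constant_prefix(), sim$reads$umi,
                     refs_chr[sim$reads$allele_id], adapter_3p())
  expect_identical(sim$reads$bases, expected)
  expect_identical(nchar(sim$reads$qualities), nchar(sim$reads$bases))
})

test_that("total read count follows the Poisson depth oracle", {
  refs <- make_references()
  m <- sample_model(n_cells = 500, activated_cell_fraction = 0.1,
                    templates_per_allele_per_cell = 1,
                    mean_reads_per_molecule = 10, seed = 77)
  mols <- simulate_sample(refs, m)
  sim <- sequence_reads(mols, refs, m)
  lambda <- nrow(mols) * 10
  expect_lt(abs(nrow(sim$reads) - lambda), 3 * sqrt(lambda))
  expect_identical(sum(sim$truth$n_reads), nrow(sim$reads))
})

test_that("FASTQ output has four lines per record and round-trips", {
  sim <- zero_error_sim(seed = 5, n_cells = 20)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  expect_identical(length(readLines(fq)), 4L * nrow(sim$reads))
  back <- read_fastq(fq)
  expect_identical(back$bases, sim$reads$bases)
  expect_identical(back$qualities, sim$reads$qualities)
  expect_identical(back$read_id, sim$reads$read_id)
})

test_that("every read maps back to exactly one truth record", {
  sim <- zero_error_sim(seed = 6, n_cells = 40)
  mol_of_read <- sub(":.*$", "", sim$reads$read_id)
  expect_true(all(mol_of_read %in% sim$truth$molecule_id))
  expect_identical(mol_of_read, sim$reads$molecule_id)
  counted <- table(factor(sim$reads$molecule_id,
                          levels = sim$truth$molecule_id))
  expect_identical(as.integer(counted), sim$truth$n_reads)
})

test_that("zero-error distinct (UMI, allele) pairs equal the truth table", {
  sim <- zero_error_sim(seed = 8, n_cells = 100)
  obs <- unique(paste(sim$reads$umi, sim$reads$allele_id))
  exp <- paste(sim$truth$umi, sim$truth$allele_id)[sim$truth$n_reads > 0]
  expect_setequal(obs, exp)
})

test_that("UMI collisions stay within 10x the birthday bound", {
  refs <- make_references()
  tot_coll <- 0; tot_bound <- 0
  for (s in 1:5) {
    m <- sample_model(n_cells = 4000, activated_cell_fraction = 0.1,
                      templates_per_allele_per_cell = 1, seed = 600 + s)
    mols <- simulate_sample(refs, m)
    n <- nrow(mols)
    tot_coll <- tot_coll + (n - length(unique(mols$umi)))
    tot_bound <- tot_bound + n * (n - 1) / 2 / 4^12
  }
  expect_lte(tot_coll, 10 * tot_bound)
})

test_that("PCR and sequencing errors appear at roughly the configured rates", {
  refs <- make_references()
  m <- sample_model(n_cells = 300, activated_cell_fraction = 0,
                    templates_per_allele_per_cell = 1,
                    mean_reads_per_molecule = 5,
                    pcr_error_rate = 0, seq_error_rate = 0.01, seed = 55)
  mols <- simulate_sample(refs, m)
  sim <- sequence_reads(mols, refs, m)
  template <- paste0(umi_constant_prefix(), sim$reads$umi,
                     as.character(refs)[sim$reads$allele_id], adapter_3p())
  mism <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 sim$reads$bases, template)
  n_bases <- sum(nchar(template))
  rate <- sum(mism) / n_bases
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 / n_bases))
  # quality string encodes the error rate: Q20 for 1% errors
  expect_true(all(sim$reads$qualities ==
                    strrep(intToUtf8(20 + 33), nchar(sim$reads$bases))))
})
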