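#' Built-in test scenarios mirroring the study arms
#'
#' Three scenarios cover the regimes of the assay: `null` (no recombined
#' cells), `non_induced` (rare spontaneous recombination, 0.5% of cells)
#' and `induced` (tamoxifen-level recombination, 30% of cells). All use the
#' default capture efficiency and depth, which puts the non-induced library
#' in the 5,000-15,000 total-read range with a few tens of activated reads,
#' the scale observed in real non-induced samples.
#'
#' @param seed Integer seed; per-scenario seeds are derived from it.
#' @return Named list of scenario definitions, each with `name`,
#'   `expected_regime` and `model` (a [sample_model()]).
#' @export
scenario_definitions <- function(seed = 1L) {
  base_seed <- as.integer(seed) %% 1000000000L
  list(
    null = list(name = "null", expected_regime = "null",
                model = sample_model(n_cells = 10000L,
                                     activated_cell_fraction = 0,
                                     seed = base_seed + 101L)),
    non_induced = list(name = "non_induced", expected_regime = "non_induced",
                       model = sample_model(n_cells = 10000L,
                                            activated_cell_fraction = 0.005,
                                            seed = base_seed + 202L)),
    induced = list(name = "induced", expected_regime = "induced",
                   model = sample_model(n_cells = 10000L,
                                        activated_cell_fraction = 0.3,
                                        seed = base_seed + 303L))
  )
}

#' Generate the packaged scenario suite on disk
#'
#' Simulates every scenario from [scenario_definitions()] and writes, per
#' scenario, the reads (FASTQ), the references (FASTA), the truth sidecar
#' (TSV) and an expected-summary JSON (model parameters, expected regime,
#' truth molecule counts).
#'
#' @param out_dir Output directory (one subdirectory per scenario).
#' @param seed Integer seed.
#' @return Invisibly, a named list of scenario output directories.
#' @export
make_scenarios <- function(out_dir, seed = 1L) {
  refs <- make_references()
  defs <- scenario_definitions(seed)
  dirs <- list()
  for (sc in defs) {
    d <- file.path(out_dir, sc$name)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    mols <- simulate_sample(refs, sc$model)
    sim <- sequence_reads(mols, refs, sc$model,
                          fastq = file.path(d, "reads.fastq"),
                          truth = file.path(d, "truth.tsv"))
    write_references(refs, file.path(d, "refs.fasta"))
    truth_counts <- as.list(table(factor(sim$truth$allele_id,
                                         levels = allele_ids())))
    jsonlite::write_json(
      list(name = sc$name, expected_regime = sc$expected_regime,
           model = unclass(sc$model), n_molecules = nrow(sim$truth),
           n_reads = nrow(sim$reads), truth_molecules = truth_counts),
      file.path(d, "expected_summary.json"), auto_unbox = TRUE, digits = NA)
    dirs[[sc$name]] <- d
  }
  invisible(dirs)
}

#' Classify a quantification report row into a regime
#'
#' Maps a sample's activation prevalence onto the three study regimes using
#' the raw (pre-floor) family prevalence: exactly 0 is `null`, below 1% is
#' `non_induced`, 10% or more is `induced`, and anything between 1% and 10%
#' is `intermediate`. Raw counts are used because regime typing asks
#' whether activated families were observed at all, which the background
#' floor deliberately hides.
#'
#' @param report_row One row of a pipeline report.
#' @return A single string.
#' @export
classify_regime <- function(report_row) {
  p <- report_row$prevalence_raw
  if (is.na(p) || p == 0) return("null")
  if (p < 0.01) return("non_induced")
  if (p >= 0.10) return("induced")
  "intermediate"
}
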