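#' Describe a simulated sample
#'
#' A `sample_model` captures everything the simulator needs about one tissue
#' sample: the cell population, the capture efficiency of the barcoding PCR,
#' the amplification depth, and the error rates. The cell population is
#' modelled as heterozygous Braf-CA/+ : every cell carries one wildtype Braf
#' template and one Braf-CA template, and the Braf-CA template is the
#' activated (recombined) form with probability `activated_cell_fraction`.
#'
#' Defaults describe the non-induced study condition: ten thousand cells of
#' which 0.5% carry the activated allele, a capture efficiency of 0.18
#' tagged templates per allele per cell, and a sequencing depth of 3.5 reads
#' per tagged molecule. That lands total library sizes in the
#' 5,000-15,000-read range typical of such samples, at the per-molecule
#' depth that maximizes the yield of retained (>= 3 read) barcode families
#' per sequenced read.
#'
#' @param n_cells Number of cells in the sample.
#' @param activated_cell_fraction Probability that a cell's Braf-CA allele is
#'   the activated (recombined) form; in `[0, 1]`.
#' @param templates_per_allele_per_cell Expected number of UMI-tagged template
#'   molecules recovered per allele per cell (capture efficiency; may exceed
#'   1 if input DNA holds several genome copies per cell equivalent).
#' @param umi_length UMI length in nt (12 in this assay).
#' @param barcoding_cycles PCR cycles during UMI attachment (3).
#' @param adapter_cycles PCR cycles of the adapter amplification (28).
#' @param pcr_error_rate Substitution probability per base per PCR cycle
#'   (default 1e-6, proofreading polymerase).
#' @param seq_error_rate Substitution probability per sequenced base
#'   (default 1e-3, i.e. Q30); the emitted quality string encodes this rate.
#' @param indel_rate Per-base sequencing indel probability (default 0).
#' @param mean_reads_per_molecule Mean of the Poisson read count per tagged
#'   molecule.
#' @param seed Mandatory integer seed; all randomness in the simulator flows
#'   from it.
#' @return An object of class `sample_model` (a validated list).
#' @examples
#' m <- sample_model(n_cells = 1000, activated_cell_fraction = 0.01, seed = 7)
#' @export
sample_model <- function(n_cells = 10000L,
                         activated_cell_fraction = 0.005,
                         templates_per_allele_per_cell = 0.18,
                         umi_length = 12L,
                         barcoding_cycles = 3L,
                         adapter_cycles = 28L,
                         pcr_error_rate = 1e-6,
                         seq_error_rate = 1e-3,
                         indel_rate = 0,
                         mean_reads_per_molecule = 3.5,
                         seed) {
  if (missing(seed)) stop("sample_model: seed is mandatory", call. = FALSE)
  m <- list(n_cells = as.integer(n_cells),
            activated_cell_fraction = activated_cell_fraction,
            templates_per_allele_per_cell = templates_per_allele_per_cell,
            umi_length = as.integer(umi_length),
            barcoding_cycles = as.integer(barcoding_cycles),
            adapter_cycles = as.integer(adapter_cycles),
            pcr_error_rate = pcr_error_rate,
            seq_error_rate = seq_error_rate,
            indel_rate = indel_rate,
            mean_reads_per_molecule = mean_reads_per_molecule,
            seed = as.integer(seed))
  validate_sample_model(m)
  class(m) <- "sample_model"
  m
}

validate_sample_model <- function(m) {
  stopifnot(is.list(m))
  if (m$n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  f <- m$activated_cell_fraction
  if (!is.numeric(f) || is.na(f) || f < 0 || f > 1)
    stop("activated_cell_fraction must lie in [0, 1]", call. = FALSE)
  if (m$templates_per_allele_per_cell <= 0)
    stop("templates_per_allele_per_cell must be positive", call. = FALSE)
  if (m$umi_length < 1L) stop("umi_length must be >= 1", call. = FALSE)
  if (m$mean_reads_per_molecule <= 0)
    stop("mean_reads_per_molecule must be positive", call. = FALSE)
  for (r in c("pcr_error_rate", "seq_error_rate", "indel_rate"))
    if (m[[r]] < 0 || m[[r]] > 0.5)
      stop(r, " must lie in [0, 0.5]", call. = FALSE)
  invisible(m)
}

#' @export
print.sample_model <- function(x, ...) {
  cat("sample_model:", x$n_cells, "cells,",
      sprintf("%.4g%%", 100 * x$activated_cell_fraction), "activated;",
      x$templates_per_allele_per_cell, "templates/allele/cell,",
      x$mean_reads_per_molecule, "reads/molecule; seed", x$seed, "\n")
  invisible(x)
}
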