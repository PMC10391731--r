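#' Default analysis thresholds
#'
#' All tunable thresholds of the pipeline in one list: adapter trimming
#' (`adapter`, `min_overlap`, `max_error_rate`), quality filter (`min_q`,
#' `min_fraction` — Q20 on 100% of bases), UMI extraction
#' (`constant_prefix`, `umi_length`, `max_mismatch`), allele matching
#' (`max_dist_fraction`, `min_margin`), family calling (`family_min_reads`,
#' `min_vote_fraction`) and the background floor (`max_noise_families`).
#'
#' @return Named list of defaults.
#' @export
default_thresholds <- function() {
  list(adapter = adapter_3p(), min_overlap = 3L, max_error_rate = 0.1,
       min_q = 20L, min_fraction = 1.0,
       constant_prefix = umi_constant_prefix(), umi_length = 12L,
       max_mismatch = 1L, max_dist_fraction = 0.1, min_margin = 3L,
       family_min_reads = 3L, min_vote_fraction = 0.6,
       max_noise_families = 6L)
}

#' Quantify one sample from preprocessed, classified reads
#'
#' Chains [build_families()], [count_families()], [apply_noise_floor()] and
#' [quant_report()].
#'
#' @param classified Data.frame from [classify_reads()].
#' @param sample_id Sample label.
#' @param thresholds Threshold list (see [default_thresholds()]).
#' @return List: `report` (one-row data.frame), `families`, `counts`.
#' @export
quantify_sample <- function(classified, sample_id = "sample",
                            thresholds = default_thresholds()) {
  fam <- build_families(classified, thresholds$family_min_reads,
                        thresholds$min_vote_fraction)
  counts <- apply_noise_floor(count_families(fam, sample_id),
                              thresholds$max_noise_families)
  read_counts <- vapply(allele_ids(), function(a)
    sum(classified$allele_call == a, na.rm = TRUE), numeric(1))
  list(report = quant_report(counts, read_counts),
       families = fam, counts = counts)
}

#' Run the full pipeline on a configuration
#'
#' Executes preprocess -> classify -> consensus -> quantify for every sample
#' in the configuration and returns one report row per sample. A sample is
#' either a FASTQ file (`fastq:`, optionally `truth:`) or an in-silico
#' sample (`simulate:` holding [sample_model()] arguments). References come
#' from a FASTA (`refs_fasta:`) or are generated (`refs_seed:`,
#' `refs_lengths:`). The run is fully reproducible from the configuration
#' and its seed; identical configurations produce byte-identical outputs.
#'
#' @param config A configuration list, or the path of a YAML file holding
#'   one. Top-level keys: `seed` (mandatory), `samples` (named list),
#'   optional `thresholds` overrides, and a reference source.
#' @param out_dir Optional output directory; when given, per-sample
#'   families/categories TSVs, a preprocessing log, the report TSV and a
#'   report JSON are written there.
#' @return A list: `report` (data.frame, one row per sample), `samples`
#'   (per-sample details: families, counts, categories, preprocess log) and
#'   `thresholds`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config: seed is mandatory", call. = FALSE)
  if (is.null(config$samples) || !length(config$samples))
    stop("config: no samples given", call. = FALSE)
  th <- utils::modifyList(default_thresholds(),
                          config$thresholds %||% list())
  refs <- pipeline_refs(config)
  sample_ids <- names(config$samples)
  if (is.null(sample_ids))
    sample_ids <- paste0("sample", seq_along(config$samples))

  details <- list()
  rows <- vector("list", length(config$samples))
  for (i in seq_along(config$samples)) {
    sid <- sample_ids[i]
    spec <- config$samples[[i]]
    reads <- stage(sid, "input", load_sample_reads(spec, refs, config$seed, i))
    pre <- stage(sid, "preprocess", preprocess_reads(
      reads, th$adapter, th$min_overlap, th$max_error_rate,
      th$min_q, th$min_fraction, th$umi_length))
    cls <- stage(sid, "classify", classify_reads(
      pre$reads, refs, th$constant_prefix, th$umi_length, th$max_mismatch,
      th$max_dist_fraction, th$min_margin))
    qt <- stage(sid, "quantify", quantify_sample(cls$classified, sid, th))
    rows[[i]] <- qt$report
    details[[sid]] <- list(families = qt$families, counts = qt$counts,
                           categories = cls$categories, pre_log = pre$log)
  }
  report <- do.call(rbind, rows)
  out <- list(report = report, samples = details, thresholds = th)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(sample_id, name, expr) {
  tryCatch(force(expr), error = function(e)
    stop(sprintf("[stage %s | sample %s] %s", name, sample_id,
                 conditionMessage(e)), call. = FALSE))
}

pipeline_refs <- function(config) {
  if (!is.null(config$refs_fasta)) return(read_references(config$refs_fasta))
  make_references(config$refs_seed %||% 1L,
                  unlist(config$refs_lengths %||% c(185L, 308L, 335L)))
}

load_sample_reads <- function(spec, refs, run_seed, index) {
  if (!is.null(spec$fastq)) return(read_fastq(spec$fastq))
  if (!is.null(spec$simulate)) {
    args <- spec$simulate
    if (is.null(args$seed)) args$seed <- (run_seed %% 1000000000L) + 13L * index
    model <- do.call(sample_model, args)
    mols <- simulate_sample(refs, model)
    return(sequence_reads(mols, refs, model)$reads)
  }
  stop("sample must provide either fastq: or simulate:", call. = FALSE)
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(out$report, file.path(out_dir, "report.tsv"))
  jsonlite::write_json(
    list(schema = "umiquant-report/1", report = out$report),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  for (sid in names(out$samples)) {
    d <- out$samples[[sid]]
    write_tsv(d$families, file.path(out_dir, paste0(sid, ".families.tsv")))
    write_tsv(data.frame(category = names(d$categories),
                         n = as.integer(d$categories)),
              file.path(out_dir, paste0(sid, ".categories.tsv")))
    write_tsv(cbind(sample_id = sid, d$pre_log),
              file.path(out_dir, paste0(sid, ".preprocess.tsv")))
  }
  invisible(out_dir)
}
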