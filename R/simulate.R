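#' Simulate the tagged template molecules of one sample
#'
#' Draws the UMI-tagged template molecules produced by the barcoding PCR from
#' a heterozygous cell population. Each cell contributes on average
#' `templates_per_allele_per_cell` captured templates of its wildtype allele
#' and of its Braf-CA allele (activated with probability
#' `activated_cell_fraction`, otherwise native). Every captured template
#' receives an independent UMI drawn uniformly from the 4^`umi_length` space.
#'
#' @param refs Allele references from [make_references()] (used only for
#'   validation here; sequences are attached by [sequence_reads()]).
#' @param model A [sample_model()].
#' @return A data.frame of truth records with columns `molecule_id`,
#'   `allele_id`, `umi`.
#' @examples
#' m <- sample_model(n_cells = 100, activated_cell_fraction = 0.2, seed = 1)
#' mols <- simulate_sample(make_references(), m)
#' table(mols$allele_id)
#' @export
simulate_sample <- function(refs, model) {
  validate_sample_model(model)
  stopifnot(all(allele_ids() %in% names(refs)))
  with_seed(model$seed, function() {
    tpc <- model$templates_per_allele_per_cell
    n_active_cells <- rbinom(1L, model$n_cells, model$activated_cell_fraction)
    n_wt  <- rpois(1L, model$n_cells * tpc)
    n_nat <- rpois(1L, (model$n_cells - n_active_cells) * tpc)
    n_act <- rpois(1L, n_active_cells * tpc)
    n <- n_wt + n_nat + n_act
    allele <- rep(allele_ids(), times = c(n_wt, n_nat, n_act))
    data.frame(
      molecule_id = sprintf("M%07d", seq_len(n)),
      allele_id = allele,
      umi = random_umis(n, model$umi_length),
      stringsAsFactors = FALSE
    )
  })
}

random_umis <- function(n, umi_length) {
  if (n == 0L) return(character(0))
  chars <- matrix(sample(c("A", "C", "G", "T"), n * umi_length,
                         replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

#' Simulate sequencing reads from tagged molecules
#'
#' Emits full-amplicon single-end reads (constant tail + UMI + gene-specific
#' amplicon + adapter read-through) for each tagged molecule, with a Poisson
#' read count per molecule. PCR substitution errors are applied along an
#' explicit per-cycle doubling lineage for the barcoding cycles (so early
#' errors are shared by sibling reads of one family) and independently per
#' read for the adapter cycles; sequencing errors are applied per base at
#' `seq_error_rate`, and the constant quality string encodes that rate
#' (Phred+33). With all error rates zero every read is byte-identical to its
#' source template.
#'
#' @param molecules Truth data.frame from [simulate_sample()].
#' @param refs Allele references ([make_references()]).
#' @param model The same [sample_model()] used to draw `molecules`.
#' @param fastq,truth Optional output paths; when given, reads are written as
#'   Phred+33 FASTQ and the truth sidecar as TSV.
#' @return A list with `reads` (data.frame: `read_id`, `bases`, `qualities`,
#'   plus truth annotations `molecule_id`, `allele_id`, `umi`) and `truth`
#'   (the input truth table with an `n_reads` column appended).
#' @export
sequence_reads <- function(molecules, refs, model, fastq = NULL, truth = NULL) {
  validate_sample_model(model)
  stopifnot(is.data.frame(molecules),
            all(c("molecule_id", "allele_id", "umi") %in% names(molecules)))
  read_seed <- (model$seed %% 1000000000L) + 777L
  out <- with_seed(read_seed, function() {
    n_mol <- nrow(molecules)
    template <- paste0(umi_constant_prefix(), molecules$umi,
                       as.character(refs[molecules$allele_id]), adapter_3p())
    tlen <- nchar(template)

    # barcoding-phase lineage: molecules whose 2^c-leaf PCR tree acquired
    # any substitution get the explicit tree; the overwhelming majority do
    # not and keep their template verbatim in every leaf
    cyc <- model$barcoding_cycles
    n_events <- 2L^cyc - 1L
    tree_errs <- rbinom(n_mol, tlen * n_events, model$pcr_error_rate)
    leaves <- vector("list", n_mol)
    for (i in which(tree_errs > 0L))
      leaves[[i]] <- pcr_tree_leaves(template[i], cyc, tree_errs[i])

    n_reads <- rpois(n_mol, model$mean_reads_per_molecule)
    total <- sum(n_reads)
    mol_of_read <- rep.int(seq_len(n_mol), n_reads)
    bases <- template[mol_of_read]
    if (any(tree_errs > 0L)) {
      mutated <- which(tree_errs[mol_of_read] > 0L)
      if (length(mutated)) {
        leaf_pick <- sample.int(2L^cyc, length(mutated), replace = TRUE)
        bases[mutated] <- vapply(seq_along(mutated), function(k)
          leaves[[mol_of_read[mutated[k]]]][leaf_pick[k]], character(1))
      }
    }

    # adapter-phase PCR errors (independent per read lineage) + sequencing
    # substitutions at the rate the quality string encodes
    rlen <- nchar(bases)
    k_pcr <- rbinom(total, rlen * model$adapter_cycles, model$pcr_error_rate)
    k_seq <- rbinom(total, rlen, model$seq_error_rate)
    k <- k_pcr + k_seq
    hit <- which(k > 0L)
    if (length(hit)) {
      idx <- rep.int(hit, k[hit])
      pos <- ceiling(runif(length(idx)) * rlen[idx])
      shift <- sample.int(3L, length(idx), replace = TRUE)
      bases <- substitute_at_cpp(bases, idx, as.integer(pos), shift)
    }
    if (model$indel_rate > 0) {
      k_ind <- rbinom(total, rlen, model$indel_rate)
      for (i in which(k_ind > 0L)) bases[i] <- apply_indels(bases[i], k_ind[i])
    }

    q <- if (model$seq_error_rate <= 0) 40L else
      max(2L, min(40L, as.integer(round(-10 * log10(model$seq_error_rate)))))
    quals <- strrep(intToUtf8(q + 33L), nchar(bases))

    within <- sequence(n_reads)
    reads <- data.frame(
      read_id = paste0(molecules$molecule_id[mol_of_read], ":", within),
      bases = bases, qualities = quals,
      molecule_id = molecules$molecule_id[mol_of_read],
      allele_id = molecules$allele_id[mol_of_read],
      umi = molecules$umi[mol_of_read],
      stringsAsFactors = FALSE
    )
    truth_tab <- molecules
    truth_tab$n_reads <- n_reads
    list(reads = reads, truth = truth_tab)
  })
  if (!is.null(fastq)) write_fastq(out$reads, fastq)
  if (!is.null(truth)) write_truth(out$truth, truth)
  out
}

# Explicit barcoding-PCR doubling tree for one molecule: c cycles create
# 2^c - 1 copy events and 2^c leaf strands; `k` substitutions are assigned
# uniformly over (event, position) and inherited by all descendants.
pcr_tree_leaves <- function(template, cycles, k) {
  n_nodes <- 2L^cycles
  event_of_err <- sample.int(n_nodes - 1L, k, replace = TRUE)
  pos <- sample.int(nchar(template), k, replace = TRUE)
  shift <- sample.int(3L, k, replace = TRUE)
  seqs <- character(n_nodes)
  seqs[1L] <- template
  for (node in seq_len(n_nodes - 1L)) {
    parent <- node - 2L^floor(log2(node))       # 0-based parent id
    s <- seqs[parent + 1L]
    e <- which(event_of_err == node)
    if (length(e))
      s <- substitute_at_cpp(s, rep.int(1L, length(e)), pos[e], shift[e])
    seqs[node + 1L] <- s
  }
  seqs
}

apply_indels <- function(s, k) {
  for (j in seq_len(k)) {
    n <- nchar(s)
    p <- sample.int(n, 1L)
    if (runif(1) < 0.5) {
      s <- paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, n))
    } else {
      s <- paste0(substr(s, 1L, p), sample(c("A", "C", "G", "T"), 1L),
                  substr(s, p + 1L, n))
    }
  }
  s
}
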