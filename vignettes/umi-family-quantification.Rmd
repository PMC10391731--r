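---
title: "Quantifying rare Cre-recombined alleles with UMI barcode families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rare Cre-recombined alleles with UMI barcode families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umiquant)
```

## The measurement problem

A tamoxifen-inducible CreER^T2^ driver is never perfectly silent: in the
absence of tamoxifen a small fraction of cells recombines the conditional
*Braf^CA^* allele anyway and begins expressing oncogenic BRAF^V600E^.
Estimating that fraction means counting roughly one mutant cell per
thousand, which is below the substitution error floor of ordinary amplicon
sequencing. The assay analysed here attaches a random 12-nt unique
molecular identifier (UMI) to every template molecule during a 3-cycle
barcoding PCR, then amplifies (28 cycles) and sequences. Because all reads
descending from one template share its UMI, reads can be collapsed into
*barcode families* and molecules — not reads — become the unit of counting.
Three amplicons are distinguishable by sequence and length: wildtype *Braf*
(185 bp), the unrecombined ("native") *Braf^CA^* allele (308 bp), and the
recombined ("activated") allele (335 bp). Every cell is heterozygous: one
wildtype template plus one *Braf^CA^* template, activated or native.

## The counting model

Let $W$, $N$ and $A$ be the retained barcode-family counts per allele class
in a sample after noise suppression. The two estimators are

$$\hat p = \frac{A}{N + A} \qquad\text{(activation prevalence)}$$

$$\hat f = \frac{A}{W} \qquad\text{(mutant-cell fraction)},$$

the latter because each cell contributes exactly one wildtype template
under the heterozygous model, so $W$ estimates the number of assayed cell
equivalents. Both carry Wilson 95% intervals: $\hat p$ directly on
$(A,\,N+A)$, and $\hat f$ by computing the Wilson bounds of
$p = A/(A+W)$ and mapping them through the monotone odds transform
$p/(1-p)$. We chose the odds-transform propagation because it keeps the
interval inside the parameter space and reduces exactly to the Wilson
interval when $A \ll W$; the assay's design leaves the propagation rule
open. Group contrasts of per-sample estimates use Welch's unequal-variance
$t$ test; when either group has zero variance the comparison degenerates to
an exact-equality report, since the $t$ statistic is undefined or
misleading there.

## Pipeline stages and their tunables

All thresholds live in `default_thresholds()` and can be overridden per
run. Defaults, units, and rationale:

| parameter | default | meaning |
|---|---|---|
| `adapter` | 3' read-through sequence | removed by a leftmost-match scan |
| `max_error_rate` | 0.1 | mismatch fraction tolerated in the adapter overlap (the conventional trimmer default; the assay states only "default parameters") |
| `min_overlap` | 3 bases | shortest adapter suffix overlap considered |
| `min_q`, `min_fraction` | Q20, 1.0 | the all-bases quality rule `-q 20 -Q33 -p 100`: every base ≥ Q20 |
| `max_mismatch` | 1 | mismatches tolerated in the 35-nt constant prefix anchoring the UMI |
| `max_dist_fraction` | 0.1 | best edit distance allowed, as a fraction of insert length |
| `min_margin` | 3 edits | required lead of best over second-best reference |
| `family_min_reads` | 3 reads | families below this are PCR-duplicate noise |
| `min_vote_fraction` | 0.6 | consensus vote share required within a family |
| `max_noise_families` | 6 families | per-class background floor: ≤ 6 families report as 0 |

The family threshold (≥ 3 reads) and the background floor (≤ 6 families)
are the assay's printed rules and sit exactly at their boundaries: a 2-read
family is discarded and a 3-read family kept; 6 activated families are
suppressed and 7 are reported.

Allele matching is a direct banded edit-distance comparison (unit-cost
Levenshtein, free end-gaps on the reference so a trimmed read may align to
an amplicon infix) rather than a general-purpose mapper: with three short
references whose pairwise distances exceed 20 edits, the
best-versus-second-best margin rule makes "matching a read to an allele"
operational and unambiguous, and distances above the decision cap
(allowed distance + margin) are reported saturated because their exact
value cannot change any call. The matching thresholds are configuration,
not claims about the original pipeline, which does not state its
tolerances.

Two scope decisions follow the same logic. UMI grouping is exact-match —
the assay counts reads with "the same" identifier — with an optional
Hamming-distance-1 merge available but off by default. And although the
prevalence figure is described in terms of reads, the deduplication into
barcode families exists precisely to make counts molecular, so the
estimators run on post-floor family counts; a read-based prevalence is
emitted alongside (`prevalence_reads`, plus `prevalence_raw` for pre-floor
families) so either reading of the source material is recoverable.

The background floor is applied per allele class within each sample, and
regime typing (`classify_regime()`: null / non-induced / induced at
prevalence 0, < 1%, ≥ 10%) uses the *raw* family prevalence: a typical
non-induced sample yields about six activated families, which the floor —
by design — hides, so the post-floor value cannot distinguish "nothing
there" from "rare signal correctly suppressed for ultrasensitive claims".
Both values appear in every report.

## What the simulator emulates

`sample_model()` describes one tissue sample; its defaults are the
non-induced study condition: 10,000 cells, 0.5% of them carrying the
activated allele, capture efficiency 0.18 tagged templates per allele per
cell, Poisson sequencing depth with mean 3.5 reads per molecule, PCR
substitution rate $10^{-6}$ per base per cycle (proofreading polymerase)
and sequencing substitution rate $10^{-3}$ (Q30). Those sizes put a sample
at roughly 12,500 total reads with a few tens of activated reads, matching
the library scale reported for real non-induced samples (5,000–15,000
total and 0–67 activated reads), and the per-molecule depth $\mu = 3.5$
maximizes the yield of retained families per sequenced read,
$P(X \ge 3 \mid \mu)/\mu$ for Poisson $X$.

The simulator is explicit where it matters for UMI consensus and
simplified where it does not:

* The 3-cycle barcoding lineage is simulated as an explicit doubling tree
  per molecule, so substitutions acquired early are shared by sibling
  reads of a family — the error mode that could defeat consensus calling.
* The 28 adapter cycles contribute independent per-read substitution
  loads. Shared adapter-phase ancestry is ignored; at $10^{-6}$ per base
  per cycle its effect on family consensus is negligible.
* Reads are full amplicons, single-end, as if mates were already merged;
  the read-length configuration of the real instrument is not modelled.
* Quality strings are constant at the Phred encoding of the configured
  substitution rate, and errors are applied at exactly that rate, so the
  filter semantics are testable; real per-base quality variation,
  position-dependent error, chimeras and index hopping are not modelled.
  Indels are available (`indel_rate`) but default to 0, substitution being
  the dominant error mode for short amplicons.

Consequently, passing tests demonstrate the *counting logic* — trimming,
anchoring, classification margins, family thresholds, floors and
estimators — under realistic error magnitudes. They do not validate
behaviour against instrument-specific artefacts, nor the wet-lab protocol
itself.

The actual murine allele sequences are not required: references are random
interiors of the printed lengths between the printed gene-specific primer
segments, which the pipeline depends on, and independent random interiors
make the three references mutually far apart (minimum pairwise distance
> 20 edits), so classification behaves as in the real assay.

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open; trimming cuts at the match start.
* Adapter matching takes the *leftmost* qualifying offset; candidate
  overlaps shorter than 3 bases are ignored.
* Edit-distance ties between references fail the margin rule and fall to
  `unclassified`; within-family vote ties are `discarded`.
* Zero denominators produce missing estimates with reason codes
  (`zero_denominator`, `zero_wildtype`), never `NaN`.
* An empty FASTQ fails structurally in the preprocess stage with a
  stage-labelled error; every stage error names its stage and sample.
* Every random draw flows from one mandatory integer seed per model (the
  pipeline derives per-sample seeds from the run seed), and simulation is
  byte-reproducible; the package restores the caller's RNG state.

## Problem sizes used by the test-suite

The exact-equality oracles run at 150 cells with full capture and mean
depth 10, where UMI collisions are vanishingly rare (the birthday bound at
300 molecules in a $4^{12}$ space is ~0.003 expected collisions), so
family counts must equal truth-table molecule counts *exactly*. The
headline and null-specificity checks run 20 replicate samples at the
default 10,000-cell condition; estimator-consistency checks run 20 seeds
per true fraction $\{0.001, 0.005, 0.05, 0.5\}$ with full capture and mean
depth 5, scaling the cell count per fraction so that activated families
clear the background floor (e.g. 20,000 cells at 0.1%). These sizes keep
each property statistically meaningful at desk scale.

## Known limitations

* The mutant-cell fraction assumes equal capture efficiency across
  alleles; allele-length-dependent PCR bias would bias $\hat f$ and is not
  modelled or corrected.
* The background floor is a hard threshold, not an error model; samples
  whose true activated-family expectation is near 6 are reported as 0 by
  design, making the estimator conservative at the detection boundary (the
  non-induced condition deliberately sits in this regime).
* The Wilson-odds interval for $\hat f$ treats $W$ and $A$ as one binomial
  split and ignores Poisson variation in the number of assayed cells.
* No multiple-testing correction is applied across group contrasts; each
  comparison is a single planned test.
```{r session}
sessionInfo()
```
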