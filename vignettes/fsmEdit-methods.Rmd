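---
title: "Frameshift neoantigen calling and immunoediting analysis: methods"
author: "fsmEdit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frameshift neoantigen calling and immunoediting analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsmEdit)
```

## Background

Mismatch-repair-deficient (MMR-deficient) tumors accumulate single-nucleotide
deletions in coding mononucleotide repeats. Each such frameshift mutation
(FSM) shifts the reading frame and produces a frameshift peptide (FSP): a
novel protein tail, absent from normal tissue, that runs from the first
altered codon to the first stop codon of the shifted frame. Because the same
repeat loci mutate recurrently across microsatellite-instable (MSI) tumors,
FSP neoantigens are shared between patients, which makes them attractive
targets for off-the-shelf cancer vaccines, particularly in Lynch syndrome,
where carriers develop multiple MSI tumors over a lifetime.

`fsmEdit` implements the computational chain for this setting:

1. **FSM calling** at a fixed catalog of coding mononucleotide-repeat loci
   from per-locus read evidence (a lookup, not de novo variant calling).
2. **MSI scoring** as the percentage of unstable microsatellite loci.
3. A **somatic variant filter cascade** for tumor-only and tumor-normal
   exomes, with per-sample MMR/stability gene-set status and tumor
   mutational burden (TMB).
4. **Frameshift peptide translation** and enumeration of junction-spanning
   MHC class I / class II candidate epitopes, scored by a pluggable binding
   predictor.
5. **Immunoediting analysis**: lost/kept/gained classification of FSMs
   across sequential tumors of one patient and a rank-sum editing-signature
   test.
6. A **seeded synthetic cohort generator** that replaces restricted patient
   data in all tests and power analyses.

## Calling rules and their boundaries

An FSM is called **present** when at least `min_mut_reads = 3`
mutant-supporting reads are observed and the variant allele frequency
strictly exceeds `min_fsm_vaf = 0.10`. Both constants are exposed in
`pipelineConfig()`. The VAF boundary is deliberately strict: a locus at
exactly 10% is absent. Zero-depth loci yield an absent call with VAF 0
rather than an error, and loci with no evidence row are treated as absent
(presence-only lookup); a `low_coverage` audit column flags loci under the
cascade's 20x minimum so that absence at poorly covered loci can be
interpreted with care.

The MSI score is `100 * n_unstable / n_scanned`; samples are MSI when the
score strictly exceeds `msi_threshold_pct = 20`. The published rule pair
(">20% MSI", "<20% MSS") leaves exactly 20% unspecified; we resolve the
boundary as MSS, keeping the MSI rule strict. The per-locus instability
call used with synthetic data is a deliberately simple stand-in for trained
locus-specific models (which are out of scope): a locus is unstable when at
least 3 mutant reads are seen *and* the mutant fraction is at least 0.10.
Note the inclusive boundary (>=), unlike the strict FSM rule; the two rules
are documented separately because only the FSM rule is a published constant.

## The somatic filter cascade

`applyFilterCascade()` applies eleven stages in a fixed order: caller QC;
coverage >= 20x; at least six reads for both alleles; gene-symbol exclusion
(case-sensitive substring match for `orf`, `ENSG`, `ENSM`, `ENST`,
`Unknown`); chromosomes 1-22 and X; the gnomAD population filter (tumor-only
samples only: removal requires AF > 1% in **both** the global and the
Finnish population, and a missing frequency never exceeds the cutoff);
absolute AF >= 0.05; mean-normalized AF ratio (zygosity ratio) <= 5;
mode-normalized AF >= 0.15; coding consequence; and ClinVar P/LP or
predicted loss of function.

Two estimation details were genuinely open and are fixed as follows:

* **Normalizer anchoring.** The mean and mode used by stages 8-9 are
  computed once over the survivors of stages 1-7, not iteratively. The
  survivor set is therefore the conjunction of individual predicates and is
  independent of evaluation order; only the per-stage first-failure counts
  depend on the order. With zero stage-1-7 survivors the two stages are
  documented no-ops.
* **Mode estimation.** The AF mode is the midpoint of the most populated
  half-open histogram bin `[k*0.05, (k+1)*0.05)` over [0, 1], ties broken
  toward the higher-AF bin. This is deterministic and auditable; any other
  convention for a continuous mode would be equally arbitrary.

**TMB** is the count of variants surviving through the coding stage (the
last annotation-neutral stage, before the pathogenicity filter) divided by
the 37 Mb exome territory. Restricting the numerator to pathogenic variants
would be nonstandard for a burden measure; the choice is recorded here
because the upstream definition is not stated.

## Frameshift peptides and epitope enumeration

`translateFsp()` deletes one base of the homopolymer run (the last one;
within a homopolymer every choice yields the same mutant CDS, a property the
test suite checks), re-translates with the standard codon table, and defines
the **junction codon** as the first codon whose nucleotides differ from the
wild-type codon at the same index. The FSP is up to `flank_aa` wild-type
residues before the junction plus the novel residues up to (exclusive) the
first stop of the shifted frame. A frameshift that opens directly on a stop
codon gives an empty novel sequence, and a CDS that ends before any stop
gives `terminated = FALSE` with the novel sequence truncated at the last
complete codon.

Candidate epitopes are all windows of the target length over the FSP that
contain at least one novel residue: 9-mers for class I, 12-16-mers for class
II. `flank_aa = 8` for class I and 15 for class II because a k-mer can
borrow at most k-1 wild-type residues; larger flanks would only add fully
wild-type windows. Identical window sequences arising at different offsets
are emitted once with a multiplicity field, and binder counting is over
unique (peptide, allele) pairs - the conservative reading of "number of
predicted binders"; the multiplicity field preserves the alternative.
Homozygous alleles count once.

Binding prediction is a plug-in contract: any deterministic
`function(peptide, allele) -> IC50 nM` can stand behind
`predictBinding()`, so an adapter for an external tool (write a peptide
FASTA, read back a score table) needs no core changes. Strong binders have
IC50 strictly below 500 nM. The packaged `syntheticAffinityOracle()` is a
hash-driven stand-in: IC50 is log-uniform on [1, 50000) nM as a pure
function of (peptide, allele, seed), and each allele carries a planted
3-residue anchor motif whose carriers receive IC50 in [1, 400), guaranteeing
plantable strong binders. Under this oracle a random (peptide, allele) pair
is "strong" with probability ln(500)/ln(50000) ~ 0.57 - far denser than a
real predictor, which matters for the retention model below.

## Immunoediting analysis

For a pair of sequential tumors, FSMs are **kept** (present in both),
**lost** (present only in the earlier) or **gained** (present only in the
later). For a patient with exactly three sequenced tumors the trio rule
classifies the third tumor against the union of the first two. Pairwise
analyses use adjacent diagnoses.

The **editing-signature test** is a one-sided Wilcoxon rank-sum test of the
per-FSM class I strong-binder counts, alternative "lost > kept". The binder
count is the single pre-registered primary statistic - the hypothesized
mechanism is CD8-driven selection - while FSP length and class II counts are
reported as secondary summaries, avoiding multiplicity. The exact null
distribution is used when both groups have at most 25 untied values, the
normal approximation with tie correction otherwise; fully tied data give
p = 1. An empty lost or kept category yields a defined "undetermined"
result (NA), not an exception. "Clear signs of immunoediting" in the
recurrent-loss analysis is operationalized as `signature_present`, since a
visual assessment is not reproducible; `recurrentLosses()` then reports loci
lost in at least `min_patients` signature-positive carriers of a given
allele that also have at least one strong predicted binder for that allele.

At **cohort level** (parameter recovery), the per-FSM binder counts of lost
and kept FSMs are pooled across the cohort's patient pairs and tested once.
This rule was open: under strong selection a single patient may retain too
few FSMs for a per-patient test, while pooling keeps the comparison
well-defined and pre-registered. Under the null (slope 0) the pooled lost
and kept counts are exchangeable, so the pooled test inherits the nominal
level.

## The synthetic cohort generator

The generator (`simConfig()`, `simulateCohort()` and friends) emulates the
study conditions rather than any particular dataset:

* **Catalog**: 204 coding mononucleotide-repeat loci (the shared-vaccine
  catalog scale), homopolymer lengths 6-12, CDS context constructed so the
  shifted frame always reaches a stop codon; novel FSP lengths are
  geometric-like with mean ~18 residues and deliberate mass at 1-2 residue
  peptides.
* **Recurrence**: one Beta(0.8, 2) draw per locus per cohort (mean 0.29,
  about 57-58 FSMs per tumor, matching the published CRC median of 57);
  sharing the draw across patients creates the locus-level recurrence that
  makes FSMs shared between tumors.
* **Evidence**: depth ~ negative binomial (mean 80, size 8); mutant reads ~
  binomial at a true VAF uniform on [0.15, 0.45] for mutated loci and at a
  noise rate of 0.005 for wild-type loci, so the 3-read/10% rule is
  exercised against a realistic background (observed false-positive rate
  < 1%).
* **Retention model**: an FSM with class-I strong-binder count b is retained
  in the next tumor with probability `plogis(3 - 2 b)`; when the later tumor
  is B2M-negative the slope is forced to 0 (antigen presentation lost, so
  selection is immunogenicity-blind). Absent FSMs are gained independently
  at rate 0.2 (~30 gains per tumor, matching the published median of 32).
  The binder counts b are computed through the package's own epitope module
  with the synthetic oracle - generator and analyzer share one
  immunogenicity definition, so the recovery experiment cannot pass by way
  of a second, private binder definition.
* **MSI profiles**: per-locus instability 0.4 (MSI) / 0.05 (MSS) over 200
  scanned loci, a desk-scale stand-in for a genome-wide panel.
* **Planted variant tables**: exact per-stage compositions for cascade
  testing. Because stages 8-9 share one normalizer pool, a zygosity-ratio
  failure requires a low-AF pool mean while a mode-normalized failure
  requires a high AF mode; a single table therefore cannot plant both, and
  the generator raises a documented generation error for such requests (and
  for population-filter failures in matched-normal samples).

Because the synthetic oracle's strong-binder density is high, per-FSM binder
counts scale with novel length times allele count and reach dozens for long
FSPs. With the retention parameters above this drives long, immunogenic
FSPs to near-certain loss while the short-FSP loci populate the kept
category - an exaggerated but directionally faithful version of the
published pattern, and exactly the regime the recovery experiment needs:
with slope 2 the pooled signature fires in essentially all replicate
cohorts, with slope 0 at about the 5% level.

What the generator does **not** emulate: read-level artifacts (FFPE damage,
mapping ambiguity at repeats), tumor clonality and phylogeny, germline
contamination of tumor-only calls, linkage between FSM burden and MSI score,
and realistic predictor biology (anchor-residue preferences, length
dependence of class II affinity). Passing tests therefore demonstrate
correctness of the analysis chain under its stated model, not performance on
real sequencing data.

Determinism: every `simulate*` output is a pure function of (config, seed,
arguments); per-object RNG streams are derived by hashing the master seed
with a context label, so any single object can be regenerated independently
of call order.

## Cohort statistics

Descriptive tables round percentages half away from zero to one decimal
(matching clinical-table conventions). Group comparisons use the two-sided
Wilcoxon rank-sum test (exact for <= 25 untied observations per group),
categorical associations the Fisher exact test, and CD8-density analyses
the Pearson correlation with a t-based p-value; zero-variance input yields
an undefined correlation (NA), not an error. These are standard, delegated
routines - the package's contribution is the FSM/epitope/editing chain, not
the test machinery. The CD8 correlation analysis is restricted to
B2M-positive samples by a filter flag, not hard-coded.

## Problem sizes and tolerances in the test suite

The suite runs at desk scale, chosen as the smallest sizes at which the
statistical checks have negligible flake probability: 100-500 locus
catalogs for translation and calling properties; 50 random planted variant
tables (~1,300 records) for cascade/audit equivalence; exhaustive FSM-call
boundary enumeration over depths 0-60; 200 random FSPs for enumeration
equivalence; 10 replicate cohorts of 9 patient pairs per arm for the
editing-signature recovery experiment; 200 replicates for rank-sum
calibration (3 binomial standard errors around 0.05); 100 replicates each
for MSI/MSS classification; and exhaustive Fisher enumeration for all 2x2
tables with total <= 30. Monte-Carlo tolerances are set at 3 standard
errors of the relevant binomial or mean throughout.

## Known limitations

* The instability rule behind the MSI score is a simplified stand-in, not a
  trained per-locus model; its agreement with any production MSI caller is
  untested by design.
* The retention model is a formalization device: its logistic form and
  parameters are not estimated from data, and no claim is made that any
  specific lost FSM was immunologically eliminated.
* Binder counts depend on the plugged-in predictor; the synthetic oracle's
  affinity scale is not biological.
* The cascade assumes annotations (consequence, ClinVar class, LoF flags,
  gnomAD frequencies) are inputs; no annotation is computed.
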