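# fsmEdit

Frameshift neoantigen calling and immunoediting analysis for
microsatellite-instable (MSI) tumors.

## The problem

Mismatch-repair-deficient tumors — most prominently in Lynch syndrome —
accumulate single-nucleotide deletions in coding mononucleotide repeats.
Each such frameshift mutation (FSM) produces a frameshift peptide (FSP): a
novel protein tail translated in the −1 frame from the first altered codon
to the first stop codon. Because the same repeat loci mutate recurrently
across MSI tumors, FSP neoantigens are shared between patients and are the
basis of off-the-shelf cancer vaccines. Two questions drive the analysis
this package implements:

* **Coverage** — how many of a fixed catalog of shared FSMs (default scale:
  204 loci) are present in a given tumor, and how does the burden relate to
  MSI status, tumor stage, somatic MMR-gene mutations, TMB and CD8
  infiltration?
* **Immunoediting** — across sequential tumors of one patient, are FSMs
  predicted to encode strongly MHC-binding epitopes preferentially *lost*
  (immune selection), and does the loss pattern disappear when antigen
  presentation is broken (B2M-negative tumors)?

## What the package computes

* `callFsm` / `fsmProfile` — FSM presence per locus from read evidence:
  present iff ≥ 3 mutant reads **and** VAF strictly > 10%.
* `callLocusInstability` / `msiScore` — MSI score = % unstable loci;
  MSI iff score strictly > 20%.
* `applyFilterCascade` — the 11-stage tumor-only / tumor-normal somatic
  variant filter cascade (QC, 20× coverage, 6 reads per allele, symbol and
  chromosome filters, gnomAD ≤ 1% for tumor-only, AF ≥ 0.05, zygosity ratio
  ≤ 5, mode-normalized AF ≥ 0.15, coding, ClinVar P/LP or LoF), with
  first-failure audit, `classifyGeneSet` (MSH3/MSH6/POLD1/POLE/B2M) and
  `computeTmb` (mutations per 37 Mb).
* `translateFsp` / `enumerateClassI` / `enumerateClassII` /
  `predictBinding` — FSP translation and junction-spanning 9-mer and
  12–16-mer enumeration, scored by any plug-in predictor
  `function(peptide, allele) -> IC50 nM`; strong binder iff IC50 < 500 nM.
  A deterministic `syntheticAffinityOracle` is included.
* `classifyPair` / `classifyTrio` / `summarizeEdits` /
  `detectEditingSignature` / `recurrentLosses` — lost/kept/gained
  partition for tumor pairs (and the three-tumor rule), per-category
  immunogenicity summaries, the one-sided rank-sum editing test on per-FSM
  class-I strong-binder counts, and recurrently lost FSMs among HLA-sharing
  patients.
* `simConfig` / `simulateCohort` / `runPipeline` — a fully seeded synthetic
  cohort generator (catalog, recurrence, read evidence, planted variant
  tables, HLA genotypes, logistic immunogenicity-dependent retention model)
  and an end-to-end orchestrator writing a report directory.

See the methods vignette (`vignettes/fsmEdit-methods.Rmd`) for the model,
conventions and design decisions.

## Worked example

```r
library(fsmEdit)

cfg <- simConfig(seed = 1, n_patients = 9)      # study-scale synthetic cohort
co  <- simulateCohort(cfg, b2m_later = "random")
co$catalog
#> LocusCatalog 'synthetic-1' with 204 coding mononucleotide-repeat loci
#>   repeat lengths 6-12; genes: SLC22A9, AIM2, UBR5, TFAM, CASP5, ...

# FSM profile of one patient's sequential tumors
p1 <- fsmProfile("Pt03_T1", co$evidence, co$catalog)
p2 <- fsmProfile("Pt03_T2", co$evidence, co$catalog)
cl <- classifyPair(p1$present, p2$present, patient_id = "Pt03",
                   earlier_sample_id = "Pt03_T1", later_sample_id = "Pt03_T2")
cl
#> PairClassification Pt03 (Pt03_T1 -> Pt03_T2): 2 kept, 50 lost, 34 gained

# immunogenicity through the epitope module and the editing test
pred   <- syntheticAffinityOracle(1)
hla    <- co$hla[co$hla$patient_id == "Pt03", ]
immuno <- immunogenicityTable(co$catalog, hla, pred,
                              class_i_counts = co$binder_counts,
                              include_class_ii = FALSE)
summarizeEdits(cl, immuno)
#> EditSummary
#>  category n_fsm median_fsp_len total_strong_i total_strong_ii
#>      lost    50           20.0           2484               0
#>      kept     2            9.0              3               0
#>    gained    34           23.5           2533               0
detectEditingSignature(cl, immuno, b2m_context = "positive")
#> EditingSignal Pt03: W = 99.5, one-sided p = 0.009824956, signature present (B2M positive)

msiScore("Pt03_T1", simulateMsiProfile("Pt03_T1", TRUE, cfg))
#> MsiResult Pt03_T1: 71/200 unstable (35.50%) -> MSI
```

Reading: of the 52 FSMs in Pt03's first tumor, the 50 lost ones carry far
more predicted class-I strong binders (total 2484, median FSP length 20)
than the 2 kept ones (total 3, median length 9) — the immunoediting
signature (one-sided rank-sum p = 0.0098). The tumor's MSI score of 35.5%
is well above the 20% classification threshold. The gained FSMs are
immunologically comparable to the lost ones, so vaccine-relevant targets
keep (re)appearing in later tumors.

A thin command-line wrapper over these functions is installed at
`inst/scripts/fsmedit-pipeline.R` (subcommands `simulate`, `call-fsm`,
`msi-score`, `filter-variants`, `run`).

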