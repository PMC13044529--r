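#' @import methods
NULL

#' Pipeline thresholds and constants
#'
#' Holds every numeric threshold used by the FSM caller, the MSI scorer, the
#' somatic filter cascade and the epitope machinery, in one validated object.
#' Defaults are the published analysis settings: FSM presence requires at
#' least 3 mutant-supporting reads and a variant allele frequency strictly
#' above 10\%; MSI classification requires a score strictly above 20\%;
#' variant filtering requires 20x coverage, six reads for each allele,
#' gnomAD population AF <= 1\% (tumor-only samples, both global and Finnish),
#' absolute AF >= 0.05, mean-normalized AF ratio (zygosity ratio) <= 5 and
#' mode-normalized AF >= 0.15; strong MHC binders have predicted IC50
#' strictly below 500 nM; class I epitopes are 9-mers and class II epitopes
#' 12- to 16-mers; TMB uses a 37 Mb exome territory.
#'
#' @slot min_mut_reads integer, minimum mutant-supporting reads for FSM presence.
#' @slot min_fsm_vaf numeric, VAF must strictly exceed this for FSM presence.
#' @slot min_depth integer, minimum coverage for variant inclusion.
#' @slot min_allele_reads integer, minimum reads for both ref and alt alleles.
#' @slot popaf_cut numeric, gnomAD AF cutoff (exclusion requires > cut in both
#'   global and Finnish populations; tumor-only samples only).
#' @slot min_abs_af numeric, minimum absolute allele fraction.
#' @slot max_zygosity_ratio numeric, maximum af / mean(af) ratio.
#' @slot min_mode_norm_af numeric, minimum af / mode(af) ratio.
#' @slot msi_threshold_pct numeric, MSI classification requires score strictly
#'   above this percentage.
#' @slot strong_ic50_nm numeric, strong binders have IC50 strictly below this.
#' @slot class_i_len integer, class I epitope length (9).
#' @slot class_ii_lens integer vector, class II epitope lengths (12:16).
#' @slot flank_aa integer, wild-type flank residues retained for class I
#'   epitope enumeration (8, one less than the 9-mer length).
#' @slot class_ii_flank_aa integer, flank residues for class II enumeration
#'   (15, one less than the longest class II window).
#' @slot tmb_territory_mb numeric, sequencing territory in Mb for TMB.
#' @slot excluded_symbol_patterns character, gene-symbol substrings whose
#'   carriers are removed by the cascade.
#' @slot allowed_chroms character, chromosomes retained by the cascade.
#' @export
setClass("PipelineConfig",
  representation(
    min_mut_reads = "integer",
    min_fsm_vaf = "numeric",
    min_depth = "integer",
    min_allele_reads = "integer",
    popaf_cut = "numeric",
    min_abs_af = "numeric",
    max_zygosity_ratio = "numeric",
    min_mode_norm_af = "numeric",
    msi_threshold_pct = "numeric",
    strong_ic50_nm = "numeric",
    class_i_len = "integer",
    class_ii_lens = "integer",
    flank_aa = "integer",
    class_ii_flank_aa = "integer",
    tmb_territory_mb = "numeric",
    excluded_symbol_patterns = "character",
    allowed_chroms = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  num <- c(object@min_mut_reads, object@min_fsm_vaf, object@min_depth,
           object@min_allele_reads, object@popaf_cut, object@min_abs_af,
           object@max_zygosity_ratio, object@min_mode_norm_af,
           object@msi_threshold_pct, object@strong_ic50_nm,
           object@class_i_len, object@class_ii_lens, object@flank_aa,
           object@class_ii_flank_aa, object@tmb_territory_mb)
  if (any(!is.finite(num)) || any(num <= 0)) {
    return("all thresholds must be positive and finite")
  }
  if (length(object@allowed_chroms) < 1) return("allowed_chroms must be non-empty")
  TRUE
})

#' Catalog of coding mononucleotide-repeat loci
#'
#' An ordered collection of repeat loci, each carrying enough CDS context to
#' translate the single-nucleotide-deletion frameshift. Validity enforces,
#' per locus: unique \code{locus_id}; \code{cds_seq} uppercase ACGT with
#' length divisible by 3; a maximal homopolymer run of \code{repeat_base} of
#' length \code{repeat_len} starting at 0-based CDS index
#' \code{repeat_cds_index}; and no in-frame stop codon strictly before the
#' codon containing the repeat start.
#'
#' @slot loci data.frame with columns locus_id, gene_symbol, chrom, pos,
#'   repeat_base, repeat_len, cds_seq, repeat_cds_index.
#' @slot name character scalar, catalog name.
#' @export
setClass("LocusCatalog",
  representation(loci = "data.frame", name = "character"))

.LOCUS_COLS <- c("locus_id", "gene_symbol", "chrom", "pos", "repeat_base",
                 "repeat_len", "cds_seq", "repeat_cds_index")

.validateLocusRow <- function(row) {
  msgs <- character(0)
  bad <- function(m) msgs <<- c(msgs, sprintf("locus %s: %s", row$locus_id, m))
  if (!row$chrom %in% c(as.character(1:22), "X")) bad("chrom outside 1..22, X")
  if (is.na(row$pos) || row$pos < 1) bad("pos must be >= 1")
  if (!row$repeat_base %in% c("A", "C", "G", "T")) bad("repeat_base not in ACGT")
  if (is.na(row$repeat_len) || row$repeat_len < 4) bad("repeat_len must be >= 4")
  cds <- row$cds_seq
  if (nchar(cds) %% 3 != 0 || grepl("[^ACGT]", cds)) {
    bad("cds_seq must be uppercase ACGT with length divisible by 3")
    return(msgs)
  }
  i <- row$repeat_cds_index
  if (is.na(i) || i < 0 || i + row$repeat_len > nchar(cds)) {
    bad("repeat window outside cds_seq")
    return(msgs)
  }
  win <- substr(cds, i + 1, i + row$repeat_len)
  if (win != strrep(row$repeat_base, row$repeat_len)) {
    bad("repeat window is not a uniform run of repeat_base")
  }
  if (i > 0 && substr(cds, i, i) == row$repeat_base) {
    bad("base before repeat window equals repeat_base (run not maximal)")
  }
  after <- i + row$repeat_len + 1
  if (after <= nchar(cds) && substr(cds, after, after) == row$repeat_base) {
    bad("base after repeat window equals repeat_base (run not maximal)")
  }
  repeat_codon <- i %/% 3
  if (repeat_codon > 0) {
    aa <- .translateCodons(.splitCodons(substr(cds, 1, 3 * repeat_codon)))
    if (any(aa == "*")) bad("in-frame stop codon before the repeat codon")
  }
  msgs
}

setValidity("LocusCatalog", function(object) {
  df <- object@loci
  miss <- setdiff(.LOCUS_COLS, names(df))
  if (length(miss) > 0) {
    return(paste("missing locus column(s):", paste(miss, collapse = ", ")))
  }
  if (length(object@name) != 1) return("name must be a single string")
  if (nrow(df) == 0) return(TRUE)
  if (anyDuplicated(df$locus_id)) return("locus_id values must be unique")
  msgs <- character(0)
  for (r in seq_len(nrow(df))) {
    m <- .validateLocusRow(df[r, , drop = FALSE])
    if (length(m) > 0) msgs <- c(msgs, sprintf("row %d: %s", r, m))
  }
  if (length(msgs) > 0) return(paste(msgs, collapse = "; "))
  TRUE
})

#' Synthetic cohort generator configuration
#'
#' All generative parameters of the seeded synthetic cohort: catalog
#' construction, per-locus FSM recurrence (one Beta draw per locus per
#' cohort), read-depth and VAF models, the logistic immunogenicity-dependent
#' retention model for sequential tumors, the FSM gain process, B2M loss in
#' later tumors, and the per-locus microsatellite instability rates used by
#' the MSI scorer.
#'
#' @slot seed integer master seed; every generated object is a pure function
#'   of (config, seed, arguments).
#' @slot n_patients integer number of patients.
#' @slot catalog_size integer number of repeat loci (default 204, encoding
#'   209-peptide-scale neoantigen sets).
#' @slot repeat_len_range integer length-2, homopolymer length range.
#' @slot recurrence_alpha,recurrence_beta numeric Beta prior on the per-locus
#'   FSM probability shared across the cohort.
#' @slot depth_mean,depth_dispersion numeric negative-binomial depth model
#'   (mean and size).
#' @slot true_vaf_range numeric length-2, uniform range of true mutant VAF.
#' @slot loss_intercept,loss_slope numeric retention model: an FSM with
#'   class-I strong-binder count b is retained in the next tumor with
#'   probability plogis(loss_intercept - loss_slope * b); loss_slope is
#'   forced to 0 when the later tumor is B2M-negative.
#' @slot gain_rate numeric per-locus probability that an FSM absent earlier
#'   is gained in the next tumor.
#' @slot p_b2m_negative_second_tumor numeric probability the later tumor has
#'   lost B2M expression.
#' @slot msi_unstable_frac_msi,msi_unstable_frac_mss numeric per-locus
#'   instability probabilities for MSI and MSS samples.
#' @slot n_msi_loci integer number of scanned microsatellite loci (desk-scale
#'   stand-in for a genome-wide panel).
#' @slot noise_vaf numeric sequencing-noise deletion rate at wild-type loci.
#' @slot variant_table_spec list of planted per-stage counts for filter
#'   cascade testing (names: pass, fail_qc, fail_depth, fail_allele_reads,
#'   fail_symbol, fail_chrom, fail_popaf, fail_abs_af, fail_zygosity,
#'   fail_mode_norm, fail_noncoding, fail_not_pathogenic).
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    n_patients = "integer",
    catalog_size = "integer",
    repeat_len_range = "integer",
    recurrence_alpha = "numeric",
    recurrence_beta = "numeric",
    depth_mean = "numeric",
    depth_dispersion = "numeric",
    true_vaf_range = "numeric",
    loss_intercept = "numeric",
    loss_slope = "numeric",
    gain_rate = "numeric",
    p_b2m_negative_second_tumor = "numeric",
    msi_unstable_frac_msi = "numeric",
    msi_unstable_frac_mss = "numeric",
    n_msi_loci = "integer",
    noise_vaf = "numeric",
    variant_table_spec = "list"
  )
)

setValidity("SimConfig", function(object) {
  fr <- c(object@gain_rate, object@p_b2m_negative_second_tumor,
          object@msi_unstable_frac_msi, object@msi_unstable_frac_mss,
          object@noise_vaf)
  if (any(fr < 0 | fr > 1)) return("all rate parameters must lie in [0, 1]")
  if (object@catalog_size < 1) return("catalog_size must be >= 1")
  if (object@n_msi_loci < 1) return("n_msi_loci must be >= 1")
  if (length(object@repeat_len_range) != 2 ||
      object@repeat_len_range[1] < 4 ||
      object@repeat_len_range[1] > object@repeat_len_range[2]) {
    return("repeat_len_range must be [min, max] with min >= 4")
  }
  v <- object@true_vaf_range
  if (length(v) != 2 || v[1] <= 0 || v[2] >= 1 || v[1] > v[2]) {
    return("true_vaf_range must lie strictly inside (0, 1)")
  }
  if (object@recurrence_alpha <= 0 || object@recurrence_beta <= 0) {
    return("Beta recurrence parameters must be positive")
  }
  if (object@loss_slope < 0) return("loss_slope must be >= 0")
  if (object@depth_mean <= 0 || object@depth_dispersion <= 0) {
    return("depth model parameters must be positive")
  }
  TRUE
})

#' MSI scoring result
#'
#' @slot sample_id character.
#' @slot n_scanned integer, number of scanned microsatellite loci.
#' @slot n_unstable integer, loci called unstable.
#' @slot score_pct numeric, 100 * n_unstable / n_scanned.
#' @slot classification character, "MSI" if score strictly exceeds the
#'   threshold (default 20), else "MSS".
#' @export
setClass("MsiResult",
  representation(sample_id = "character", n_scanned = "integer",
                 n_unstable = "integer", score_pct = "numeric",
                 classification = "character"))

setValidity("MsiResult", function(object) {
  if (object@n_scanned < 1) return("n_scanned must be >= 1")
  if (object@n_unstable < 0 || object@n_unstable > object@n_scanned) {
    return("n_unstable must lie in [0, n_scanned]")
  }
  if (abs(object@score_pct - 100 * object@n_unstable / object@n_scanned) > 1e-9) {
    return("score_pct inconsistent with counts")
  }
  if (!object@classification %in% c("MSI", "MSS")) {
    return("classification must be MSI or MSS")
  }
  TRUE
})

#' Somatic filter cascade result
#'
#' @slot kept data.frame of surviving variant records.
#' @slot stage_counts named integer vector of first-failure removal counts,
#'   in cascade order.
#' @slot audit character vector, per input record the first failing stage
#'   name or "pass"; partitions the input.
#' @export
setClass("FilterResult",
  representation(kept = "data.frame", stage_counts = "integer",
                 audit = "character"))

setValidity("FilterResult", function(object) {
  n_in <- length(object@audit)
  if (nrow(object@kept) + sum(object@stage_counts) != n_in) {
    return("|input| must equal |kept| + sum(removals)")
  }
  if (sum(object@audit == "pass") != nrow(object@kept)) {
    return("audit 'pass' labels must match kept records")
  }
  TRUE
})

#' Translated frameshift peptide
#'
#' @slot locus_id character.
#' @slot flank character, wild-type residues preceding the junction (at most
#'   the configured flank length).
#' @slot novel character, residues from the first altered codon to the
#'   residue before the first stop in the shifted frame.
#' @slot full character, flank followed by novel.
#' @slot novel_len integer, nchar(novel).
#' @slot terminated logical, TRUE if a stop codon was reached before the CDS end.
#' @export
setClass("FrameshiftPeptide",
  representation(locus_id = "character", flank = "character",
                 novel = "character", full = "character",
                 novel_len = "integer", terminated = "logical"))

setValidity("FrameshiftPeptide", function(object) {
  if (object@full != paste0(object@flank, object@novel)) {
    return("full must equal flank followed by novel")
  }
  if (grepl("\\*", object@full)) return("no stop symbol allowed in full")
  if (object@novel_len != nchar(object@novel)) {
    return("novel_len inconsistent with novel")
  }
  TRUE
})

#' Lost/kept/gained partition for sequential tumors
#'
#' @slot patient_id character.
#' @slot earlier_sample_id,later_sample_id character sample identifiers.
#' @slot kept,lost,gained character vectors of locus ids; pairwise disjoint,
#'   with kept + lost = earlier present set and kept + gained = later present
#'   set (for the trio rule, "earlier" is the union of the first two tumors).
#' @export
setClass("PairClassification",
  representation(patient_id = "character", earlier_sample_id = "character",
                 later_sample_id = "character", kept = "character",
                 lost = "character", gained = "character"))

setValidity("PairClassification", function(object) {
  k <- object@kept; l <- object@lost; g <- object@gained
  if (length(intersect(k, l)) || length(intersect(k, g)) ||
      length(intersect(l, g))) {
    return("kept, lost and gained must be pairwise disjoint")
  }
  TRUE
})

#' Immunogenicity summary of an FSM partition
#'
#' @slot table data.frame with one row per category (lost, kept, gained):
#'   n_fsm, median_fsp_len (NA when the category is empty), total_strong_i,
#'   total_strong_ii.
#' @slot binders_i,binders_ii,fsp_lens named lists (lost/kept/gained) of the
#'   per-FSM values behind the summary, retained for testing.
#' @export
setClass("EditSummary",
  representation(table = "data.frame", binders_i = "list",
                 binders_ii = "list", fsp_lens = "list"))

#' Immunoediting signature test result
#'
#' @slot patient_id character.
#' @slot statistic numeric rank-sum statistic (NA when undetermined).
#' @slot p_value numeric one-sided p-value (NA when undetermined).
#' @slot signature_present logical; NA when lost or kept is empty
#'   (undetermined), otherwise p_value < alpha.
#' @slot b2m_context character, B2M IHC status of the later tumor.
#' @slot alpha numeric test level.
#' @export
setClass("EditingSignal",
  representation(patient_id = "character", statistic = "numeric",
                 p_value = "numeric", signature_present = "logical",
                 b2m_context = "character", alpha = "numeric"))
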