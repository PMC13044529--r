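# Tumor-only / tumor-normal somatic variant filter cascade.
#
# Stage order (first-failure attribution): qc, depth, allele_reads, symbol,
# chrom, popaf (tumor-only samples only), abs_af, zygosity, mode_norm,
# noncoding, not_pathogenic. The zygosity-ratio and mode-normalized-AF
# normalizers (mean and histogram mode of AF) are anchored once to the
# survivors of stages 1-7; the survivor set is therefore the conjunction of
# the individual predicates and does not depend on evaluation order, while
# the per-stage removal counts do.

.CASCADE_STAGES <- c("qc", "depth", "allele_reads", "symbol", "chrom",
                     "popaf", "abs_af", "zygosity", "mode_norm", "noncoding",
                     "not_pathogenic")

#' Arithmetic mean and histogram mode of allele fractions
#'
#' The mode is estimated as the midpoint of the most populated half-open
#' histogram bin [k*w, (k+1)*w) over [0, 1]; ties are broken toward the
#' higher-AF bin. The estimator is deterministic and auditable; an AF of
#' exactly 1 falls in the final bin.
#'
#' @param afs non-empty numeric vector of allele fractions in [0, 1].
#' @param bin_width histogram bin width (default 0.05).
#' @return a numeric scalar.
#' @examples
#' sampleAfMode(c(0.10, 0.10, 0.10, 0.90))  # 0.125
#' @export
sampleAfMean <- function(afs) {
  if (length(afs) == 0) stop("sampleAfMean: empty AF list", call. = FALSE)
  mean(afs)
}

#' @rdname sampleAfMean
#' @export
sampleAfMode <- function(afs, bin_width = 0.05) {
  if (length(afs) == 0) stop("sampleAfMode: empty AF list", call. = FALSE)
  nbins <- ceiling(1 / bin_width)
  bin <- pmin(floor(afs / bin_width), nbins - 1)  # af = 1 joins the last bin
  counts <- tabulate(bin + 1L, nbins)
  best <- max(which(counts == max(counts)))  # tie -> higher bin
  (best - 1) * bin_width + bin_width / 2
}

#' Apply the somatic variant filter cascade
#'
#' Applies, in order: (1) caller QC pass; (2) coverage >= 20x; (3) at least
#' six reads for both the reference and the variant allele; (4) gene symbol
#' free of the excluded substrings (orf, ENSG, ENSM, ENST, Unknown;
#' case-sensitive); (5) chromosome in 1-22, X; (6) for tumor-only samples
#' only, removal when the gnomAD population AF exceeds 1\% in both the global
#' and the Finnish population (missing values never exceed the cutoff, and
#' such records are flagged for audit); (7) absolute AF >= 0.05; (8)
#' mean-normalized AF ratio (zygosity ratio) <= 5; (9) mode-normalized AF
#' >= 0.15; (10) coding consequence; (11) ClinVar pathogenic/likely
#' pathogenic or predicted loss of function. Stages 8-9 normalize by the
#' mean/mode of AF over survivors of stages 1-7; with zero such survivors
#' those stages are no-ops.
#'
#' @param records variant data.frame from one sample (see
#'   \code{\link{readVariantTable}}).
#' @param sample one row of the samples table; \code{matched_normal}
#'   controls stage 6.
#' @param config a \linkS4class{PipelineConfig}.
#' @return A \linkS4class{FilterResult}.
#' @export
applyFilterCascade <- function(records, sample, config = pipelineConfig()) {
  n <- nrow(records)
  counts <- stats::setNames(integer(length(.CASCADE_STAGES)), .CASCADE_STAGES)
  if (n == 0) {
    return(new("FilterResult", kept = records, stage_counts = counts,
               audit = character(0)))
  }
  .validateVariants(records)
  matched <- isTRUE(sample$matched_normal)

  p <- list()
  p$qc <- records$qc_pass
  p$depth <- records$depth >= config@min_depth
  p$allele_reads <- records$ref_reads >= config@min_allele_reads &
    records$alt_reads >= config@min_allele_reads
  hasPattern <- rep(FALSE, n)
  for (pat in config@excluded_symbol_patterns) {
    hasPattern <- hasPattern | grepl(pat, records$gene_symbol, fixed = TRUE)
  }
  p$symbol <- !hasPattern
  p$chrom <- records$chrom %in% config@allowed_chroms
  if (matched) {
    p$popaf <- rep(TRUE, n)
  } else {
    exceeds <- function(v) !is.na(v) & v > config@popaf_cut
    p$popaf <- !(exceeds(records$gnomad_global_af) &
                   exceeds(records$gnomad_fin_af))
  }
  p$abs_af <- records$af >= config@min_abs_af

  pre <- p$qc & p$depth & p$allele_reads & p$symbol & p$chrom & p$popaf &
    p$abs_af
  if (any(pre)) {
    afm <- sampleAfMean(records$af[pre])
    afmode <- sampleAfMode(records$af[pre])
    p$zygosity <- records$af / afm <= config@max_zygosity_ratio
    p$mode_norm <- records$af / afmode >= config@min_mode_norm_af
  } else {
    p$zygosity <- rep(TRUE, n)  # normalizer undefined: stages are no-ops
    p$mode_norm <- rep(TRUE, n)
  }
  p$noncoding <- records$is_coding
  p$not_pathogenic <- records$clinvar_class %in% c("P", "LP") |
    records$lof_predicted

  audit <- rep("pass", n)
  for (st in rev(.CASCADE_STAGES)) audit[!p[[st]]] <- st
  for (st in .CASCADE_STAGES) counts[st] <- sum(audit == st)
  kept <- records[audit == "pass", , drop = FALSE]
  rownames(kept) <- NULL
  new("FilterResult", kept = kept, stage_counts = counts, audit = audit)
}

#' Per-sample MMR / genomic-stability gene-set mutation status
#'
#' Flags whether the cascade-filtered (pathogenic or LoF) variants of a
#' sample hit MSH3, MSH6, POLD1, POLE or B2M; \code{any_mmr_stability} is the
#' OR of the four non-B2M flags.
#'
#' @param kept cascade-filtered variant data.frame.
#' @param sample_id sample identifier.
#' @return one-row data.frame with the five logical flags and
#'   any_mmr_stability.
#' @export
classifyGeneSet <- function(kept, sample_id) {
  hit <- function(g) g %in% kept$gene_symbol
  out <- data.frame(sample_id = as.character(sample_id),
                    mutated_MSH3 = hit("MSH3"), mutated_MSH6 = hit("MSH6"),
                    mutated_POLD1 = hit("POLD1"), mutated_POLE = hit("POLE"),
                    mutated_B2M = hit("B2M"), stringsAsFactors = FALSE)
  out$any_mmr_stability <- out$mutated_MSH3 | out$mutated_MSH6 |
    out$mutated_POLD1 | out$mutated_POLE
  out
}

#' Tumor mutational burden
#'
#' Mutations per megabase: the count of coding variants surviving the
#' cascade through the coding stage (pre-pathogenicity, the last
#' annotation-neutral stage) divided by the sequencing territory (37 Mb
#' exome by default).
#'
#' @param n_variants variant count (>= 0).
#' @param config a \linkS4class{PipelineConfig}.
#' @return numeric, mutations per Mb.
#' @examples
#' computeTmb(74)  # 2.0
#' @export
computeTmb <- function(n_variants, config = pipelineConfig()) {
  stopifnot(n_variants >= 0)
  n_variants / config@tmb_territory_mb
}

#' Variant count through the coding stage
#'
#' Helper for the TMB numerator: variants whose first failure, if any, is
#' the pathogenicity stage (i.e. they survive stages 1-10).
#'
#' @param result a \linkS4class{FilterResult}.
#' @return integer count.
#' @export
countThroughCoding <- function(result) {
  sum(auditLabels(result) %in% c("pass", "not_pathogenic"))
}
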