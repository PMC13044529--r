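#' Call FSM presence from read evidence
#'
#' A frameshift mutation is called present at a locus when at least
#' \code{min_mut_reads} mutant-supporting reads are observed and the variant
#' allele frequency strictly exceeds \code{min_fsm_vaf} (defaults 3 reads and
#' 10\%). A VAF of exactly 10\% is therefore absent. Zero depth yields an
#' absent call with VAF 0, not an error.
#'
#' @param evidence data.frame with columns sample_id, locus_id, depth,
#'   mut_reads (one or more rows).
#' @param config a \linkS4class{PipelineConfig}.
#' @return data.frame with columns sample_id, locus_id, depth, mut_reads,
#'   vaf, present.
#' @examples
#' ev <- data.frame(sample_id = "S1", locus_id = c("L1", "L2"),
#'                  depth = c(30L, 10L), mut_reads = c(3L, 3L))
#' callFsm(ev, pipelineConfig())  # L1 at exactly 10% is absent; L2 present
#' @export
callFsm <- function(evidence, config = pipelineConfig()) {
  validateEvidence(evidence)
  vaf <- ifelse(evidence$depth > 0, evidence$mut_reads / evidence$depth, 0)
  present <- evidence$mut_reads >= config@min_mut_reads &
    vaf > config@min_fsm_vaf
  out <- evidence
  out$vaf <- vaf
  out$present <- present
  out
}

#' Per-sample FSM profile and burden
#'
#' Looks up FSM presence at every catalog locus for one sample. Loci without
#' an evidence row are reported absent (the lookup reports presence only); a
#' coverage-audit column flags loci whose depth falls below the cascade's
#' minimum coverage, for interpretation.
#'
#' @param sample_id sample identifier.
#' @param evidence evidence data.frame (may cover several samples).
#' @param catalog a \linkS4class{LocusCatalog}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return list with elements \code{present} (character vector of locus ids
#'   called present), \code{burden} (its length), and \code{calls} (per-locus
#'   data.frame with columns locus_id, depth, mut_reads, vaf, present,
#'   low_coverage).
#' @export
fsmProfile <- function(sample_id, evidence, catalog,
                       config = pipelineConfig()) {
  ev <- evidence[evidence$sample_id == sample_id, , drop = FALSE]
  if (anyDuplicated(ev$locus_id)) {
    stop("duplicate evidence rows for sample ", sample_id, " at locus ",
         ev$locus_id[duplicated(ev$locus_id)][1], call. = FALSE)
  }
  ids <- loci(catalog)$locus_id
  calls <- data.frame(locus_id = ids, depth = 0L, mut_reads = 0L,
                      stringsAsFactors = FALSE)
  m <- match(ev$locus_id, ids)
  if (anyNA(m)) {
    stop("evidence refers to loci outside the catalog: ",
         ev$locus_id[is.na(m)][1], call. = FALSE)
  }
  calls$depth[m] <- ev$depth
  calls$mut_reads[m] <- ev$mut_reads
  calls$sample_id <- sample_id
  cc <- callFsm(calls[, c("sample_id", "locus_id", "depth", "mut_reads")],
                config)
  cc$low_coverage <- cc$depth < config@min_depth
  present <- cc$locus_id[cc$present]
  list(present = present, burden = length(present),
       calls = cc[, c("locus_id", "depth", "mut_reads", "vaf", "present",
                      "low_coverage")])
}

#' Simplified per-locus microsatellite instability call
#'
#' A deliberately simple per-locus rule standing in for trained
#' locus-specific instability models: a scanned locus is unstable when at
#' least \code{instab_min_reads} mutant reads are seen and the mutant read
#' fraction is at least \code{instab_min_frac}. Note the fraction boundary is
#' inclusive (>=), unlike the strict (>) VAF rule of \code{\link{callFsm}}.
#'
#' @param evidence data.frame with columns depth, mut_reads.
#' @param instab_min_frac minimum mutant-read fraction (default 0.10,
#'   inclusive).
#' @param instab_min_reads minimum mutant reads (default 3).
#' @return logical vector, TRUE where the locus is unstable.
#' @export
callLocusInstability <- function(evidence, instab_min_frac = 0.10,
                                 instab_min_reads = 3L) {
  validateEvidence(evidence)
  frac <- ifelse(evidence$depth > 0, evidence$mut_reads / evidence$depth, 0)
  evidence$mut_reads >= instab_min_reads & frac >= instab_min_frac
}

#' MSI score and classification
#'
#' The MSI score is the percentage of scanned microsatellite loci called
#' unstable; samples with a score strictly above
#' \code{msi_threshold_pct} (default 20\%) are classified MSI, all others
#' MSS. A score of exactly 20\% is MSS.
#'
#' @param sample_id sample identifier.
#' @param unstable logical vector of per-locus instability calls.
#' @param config a \linkS4class{PipelineConfig}.
#' @return An \linkS4class{MsiResult}.
#' @examples
#' msiScore("S1", c(rep(TRUE, 3), rep(FALSE, 7)))  # 30%, MSI
#' @export
msiScore <- function(sample_id, unstable, config = pipelineConfig()) {
  n <- length(unstable)
  if (n < 1) stop("msiScore requires at least one scanned locus", call. = FALSE)
  if (anyNA(unstable)) stop("instability calls must not contain NA", call. = FALSE)
  u <- sum(unstable)
  pct <- 100 * u / n
  new("MsiResult", sample_id = as.character(sample_id), n_scanned = as.integer(n),
      n_unstable = as.integer(u), score_pct = pct,
      classification = if (pct > config@msi_threshold_pct) "MSI" else "MSS")
}
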