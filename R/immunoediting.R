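# Lost / kept / gained classification across sequential tumors and the
# editing-signature test.

#' Classify FSMs across a pair of sequential tumors
#'
#' Set algebra on the present FSM sets: kept = present in both tumors, lost =
#' present only in the earlier tumor, gained = present only in the later
#' tumor.
#'
#' @param present_earlier,present_later character vectors of locus ids over
#'   one catalog.
#' @param patient_id,earlier_sample_id,later_sample_id identifiers carried
#'   into the result.
#' @return A \linkS4class{PairClassification}.
#' @examples
#' classifyPair(c("a", "b", "c"), c("b", "c", "d"))
#' @export
classifyPair <- function(present_earlier, present_later,
                         patient_id = "", earlier_sample_id = "",
                         later_sample_id = "") {
  e <- unique(as.character(present_earlier))
  l <- unique(as.character(present_later))
  new("PairClassification", patient_id = patient_id,
      earlier_sample_id = earlier_sample_id,
      later_sample_id = later_sample_id,
      kept = intersect(e, l), lost = setdiff(e, l), gained = setdiff(l, e))
}

#' Classify FSMs across three sequential tumors
#'
#' The three-tumor rule: FSMs present in the first or second tumor are lost
#' if absent from the third and kept if detected in the third; FSMs unique to
#' the third tumor are gained. Equivalently,
#' \code{classifyPair(union(P1, P2), P3)}; with an empty first set the rule
#' degenerates to the pair rule on the last two tumors.
#'
#' @param present_1,present_2,present_3 character vectors of locus ids.
#' @param patient_id,earlier_sample_id,later_sample_id identifiers.
#' @return A \linkS4class{PairClassification} describing the third tumor.
#' @export
classifyTrio <- function(present_1, present_2, present_3,
                         patient_id = "", earlier_sample_id = "",
                         later_sample_id = "") {
  classifyPair(union(present_1, present_2), present_3,
               patient_id = patient_id,
               earlier_sample_id = earlier_sample_id,
               later_sample_id = later_sample_id)
}

.lookupImmuno <- function(ids, immuno, col) {
  m <- match(ids, immuno$locus_id)
  if (anyNA(m)) {
    stop("missing immunogenicity row for locus ", ids[is.na(m)][1],
         call. = FALSE)
  }
  immuno[[col]][m]
}

#' Summarize immunogenicity by lost/kept/gained category
#'
#' Per category: FSM count, median frameshift-peptide length (NA, not 0,
#' when the category is empty), and total class I / class II strong-binder
#' counts. The per-FSM vectors behind the summary are retained.
#'
#' @param classification a \linkS4class{PairClassification}.
#' @param immuno immunogenicity table (locus_id, n_strong_i, n_strong_ii,
#'   fsp_len) covering every classified locus.
#' @return An \linkS4class{EditSummary}.
#' @export
summarizeEdits <- function(classification, immuno) {
  cats <- list(lost = classification@lost, kept = classification@kept,
               gained = classification@gained)
  bi <- lapply(cats, .lookupImmuno, immuno = immuno, col = "n_strong_i")
  bii <- lapply(cats, .lookupImmuno, immuno = immuno, col = "n_strong_ii")
  lens <- lapply(cats, .lookupImmuno, immuno = immuno, col = "fsp_len")
  tab <- data.frame(
    category = names(cats),
    n_fsm = vapply(cats, length, 1L),
    median_fsp_len = vapply(lens, function(v) {
      if (length(v) == 0) NA_real_ else stats::median(v)
    }, 1),
    total_strong_i = vapply(bi, function(v) sum(as.integer(v)), 1L),
    total_strong_ii = vapply(bii, function(v) sum(as.integer(v)), 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  new("EditSummary", table = tab, binders_i = bi, binders_ii = bii,
      fsp_lens = lens)
}

#' One-sided rank-sum editing test on raw values
#'
#' Tests whether the lost values stochastically exceed the kept values
#' (Wilcoxon rank-sum, alternative lost > kept). The exact distribution is
#' used when both groups have at most 25 untied observations, the normal
#' approximation with tie correction otherwise. Empty groups give an
#' undetermined result (NA), not an error.
#'
#' @param lost_values,kept_values numeric vectors.
#' @param alpha test level (default 0.05).
#' @return list(statistic, p_value, signature_present).
#' @export
rankSumSignature <- function(lost_values, kept_values, alpha = 0.05) {
  if (length(lost_values) == 0 || length(kept_values) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                signature_present = NA))
  }
  ties <- anyDuplicated(c(lost_values, kept_values)) > 0
  exact <- !ties && length(lost_values) <= 25 && length(kept_values) <= 25
  wt <- suppressWarnings(stats::wilcox.test(lost_values, kept_values,
                                            alternative = "greater",
                                            exact = exact, correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # fully tied data carry no rank evidence
  list(statistic = unname(wt$statistic), p_value = p,
       signature_present = p < alpha)
}

#' Detect the immunoediting signature for one classification
#'
#' The pre-registered primary statistic is the per-FSM class I strong-binder
#' count: immunoediting predicts that lost FSMs carry more predicted strong
#' CD8 epitopes than kept FSMs. Peptide length and class II counts are
#' secondary summaries (see \code{\link{summarizeEdits}}).
#'
#' @param classification a \linkS4class{PairClassification}.
#' @param immuno immunogenicity table covering the classified loci.
#' @param alpha test level (default 0.05).
#' @param b2m_context B2M IHC status of the later tumor, carried into the
#'   result.
#' @return An \linkS4class{EditingSignal}; undetermined (NA) when lost or
#'   kept is empty.
#' @export
detectEditingSignature <- function(classification, immuno, alpha = 0.05,
                                   b2m_context = "unknown") {
  lost <- .lookupImmuno(classification@lost, immuno, "n_strong_i")
  kept <- .lookupImmuno(classification@kept, immuno, "n_strong_i")
  rs <- rankSumSignature(as.numeric(lost), as.numeric(kept), alpha)
  new("EditingSignal", patient_id = classification@patient_id,
      statistic = if (is.na(rs$statistic)) NA_real_ else rs$statistic,
      p_value = if (is.na(rs$p_value)) NA_real_ else rs$p_value,
      signature_present = rs$signature_present,
      b2m_context = b2m_context, alpha = alpha)
}

#' Cohort-level editing signature
#'
#' Pools the per-FSM class I strong-binder counts of lost and kept FSMs
#' across all patient pairs of a cohort and applies the one-sided rank-sum
#' test. Used by the parameter-recovery analysis, where single patients
#' under strong selection can retain too few FSMs for a per-patient test.
#'
#' @param classifications list of \linkS4class{PairClassification}.
#' @param immunos list of per-patient immunogenicity tables, aligned with
#'   \code{classifications}.
#' @param alpha test level.
#' @return list(statistic, p_value, signature_present, n_lost, n_kept).
#' @export
cohortEditingSignal <- function(classifications, immunos, alpha = 0.05) {
  lost <- numeric(0); kept <- numeric(0)
  for (i in seq_along(classifications)) {
    cl <- classifications[[i]]; im <- immunos[[i]]
    lost <- c(lost, .lookupImmuno(cl@lost, im, "n_strong_i"))
    kept <- c(kept, .lookupImmuno(cl@kept, im, "n_strong_i"))
  }
  rs <- rankSumSignature(as.numeric(lost), as.numeric(kept), alpha)
  c(rs, list(n_lost = length(lost), n_kept = length(kept)))
}

#' Recurrently lost FSMs among HLA-sharing patients
#'
#' Among patients with clear signs of immunoediting (signature present) who
#' carry the given class I allele, finds loci lost in at least
#' \code{min_patients} of them that also have at least one strong predicted
#' binder for that allele. Output is sorted by supporting-patient count,
#' then locus id.
#'
#' @param classifications named list of \linkS4class{PairClassification}
#'   (names: patient ids).
#' @param signals named list of \linkS4class{EditingSignal} per patient.
#' @param hla HLA genotype table.
#' @param allele class I allele name (e.g. "A*02:01").
#' @param catalog a \linkS4class{LocusCatalog}.
#' @param predictor affinity predictor.
#' @param min_patients minimum number of supporting patients (default 2).
#' @param config a \linkS4class{PipelineConfig}.
#' @param binder_counts optional precomputed \code{\link{classIBinderCounts}}
#'   matrix including this allele.
#' @return data.frame with locus_id, n_patients, patients
#'   (semicolon-separated), sorted by support then locus id; empty when no
#'   signature-positive carrier loses any qualifying locus.
#' @export
recurrentLosses <- function(classifications, signals, hla, allele, catalog,
                            predictor, min_patients = 2L,
                            config = pipelineConfig(),
                            binder_counts = NULL) {
  carriers <- hla$patient_id[vapply(hla$class_i, function(s) {
    allele %in% .splitAlleles(s)
  }, logical(1))]
  eligible <- intersect(carriers, names(signals)[vapply(signals, function(s) {
    isTRUE(s@signature_present)
  }, logical(1))])
  empty <- data.frame(locus_id = character(0), n_patients = integer(0),
                      patients = character(0), stringsAsFactors = FALSE)
  if (length(eligible) == 0) return(empty)
  lostBy <- lapply(eligible, function(pid) classifications[[pid]]@lost)
  names(lostBy) <- eligible
  tally <- table(unlist(lostBy))
  cand <- names(tally)[tally >= min_patients]
  if (length(cand) == 0) return(empty)
  if (is.null(binder_counts)) {
    sub <- new("LocusCatalog",
               loci = loci(catalog)[loci(catalog)$locus_id %in% cand, ,
                                    drop = FALSE],
               name = catalogName(catalog))
    binder_counts <- classIBinderCounts(sub, allele, predictor, config)
  }
  hasBinder <- cand[binder_counts[cand, allele] >= 1]
  if (length(hasBinder) == 0) return(empty)
  out <- data.frame(
    locus_id = hasBinder,
    n_patients = as.integer(tally[hasBinder]),
    patients = vapply(hasBinder, function(lc) {
      paste(eligible[vapply(lostBy, function(v) lc %in% v, logical(1))],
            collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_patients, out$locus_id), , drop = FALSE]
}

#' Editing-signature parameter-recovery experiment
#'
#' Simulates replicate cohorts of patient pairs and counts how many show the
#' cohort-level editing signature. With the default retention slope the
#' signature should appear in nearly all replicates; with the slope forced to
#' 0 (B2M-negative later tumors) the lost and kept binder counts are
#' exchangeable and the signature should appear at about the test level.
#' Burden calls use noiseless truth-free evidence via the standard FSM
#' caller.
#'
#' @param n_cohorts number of replicate cohorts.
#' @param base_seed integer; cohort r uses a seed derived from
#'   (base_seed, r).
#' @param b2m_later "positive" (selection active) or "negative" (slope
#'   forced to 0).
#' @param sim_args named list of \code{\link{simConfig}} overrides.
#' @param alpha test level.
#' @param pipe_config a \linkS4class{PipelineConfig}.
#' @return list(n_signature, results) where results is a per-cohort
#'   data.frame (seed, p_value, signature, n_lost, n_kept).
#' @export
editingRecoveryExperiment <- function(n_cohorts = 10L, base_seed = 1L,
                                      b2m_later = c("positive", "negative"),
                                      sim_args = list(), alpha = 0.05,
                                      pipe_config = pipelineConfig()) {
  b2m_later <- match.arg(b2m_later)
  res <- vector("list", n_cohorts)
  for (r in seq_len(n_cohorts)) {
    seed <- .deriveSeed(base_seed, paste0("recovery:", b2m_later, ":", r))
    cfg <- do.call(simConfig, c(list(seed = seed), sim_args))
    co <- simulateCohort(cfg, b2m_later = b2m_later,
                         pipe_config = pipe_config)
    pids <- unique(co$samples$patient_id)
    cls <- list(); ims <- list()
    for (pid in pids) {
      s1 <- paste0(pid, "_T1"); s2 <- paste0(pid, "_T2")
      p1 <- fsmProfile(s1, co$evidence, co$catalog, pipe_config)$present
      p2 <- fsmProfile(s2, co$evidence, co$catalog, pipe_config)$present
      cls[[pid]] <- classifyPair(p1, p2, patient_id = pid,
                                 earlier_sample_id = s1,
                                 later_sample_id = s2)
      b <- co$patient_binders[[pid]]
      ims[[pid]] <- data.frame(locus_id = names(b),
                               n_strong_i = as.integer(b),
                               n_strong_ii = 0L, fsp_len = 0L,
                               stringsAsFactors = FALSE)
    }
    sig <- cohortEditingSignal(cls, ims, alpha)
    res[[r]] <- data.frame(seed = seed,
                           p_value = if (is.na(sig$p_value)) NA_real_
                                     else sig$p_value,
                           signature = isTRUE(sig$signature_present),
                           n_lost = sig$n_lost, n_kept = sig$n_kept)
  }
  results <- do.call(rbind, res)
  list(n_signature = sum(results$signature), results = results)
}
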