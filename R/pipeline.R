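#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates the complete chain on a simulated cohort: generation, FSM
#' calling and per-sample burden, MSI scoring, planted-variant filtering with
#' gene-set status and TMB (when \code{variant_table_spec} is non-empty),
#' per-patient immunogenicity, lost/kept/gained classification of each
#' patient's tumor pair, editing-signature tests and the cohort
#' characteristics table. Writes TSV/JSON outputs and a run log (package
#' version, seed, full config echo) into \code{out_dir}.
#'
#' @param sim_config a \linkS4class{SimConfig}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param out_dir output directory; created if needed. NULL skips writing.
#' @param b2m_later passed to \code{\link{simulateCohort}}.
#' @return invisible list with the in-memory results: cohort, burdens, msi,
#'   filters, gene_sets, tmb, classifications, signals, summaries,
#'   cohort_table.
#' @export
runPipeline <- function(sim_config, config = pipelineConfig(),
                        out_dir = NULL, b2m_later = "random") {
  co <- simulateCohort(sim_config, b2m_later = b2m_later,
                       pipe_config = config)
  predictor <- syntheticAffinityOracle(sim_config@seed)

  profiles <- list()
  for (sid in unique(co$evidence$sample_id)) {
    profiles[[sid]] <- fsmProfile(sid, co$evidence, co$catalog, config)
  }
  burdens <- data.frame(
    sample_id = names(profiles),
    burden = vapply(profiles, function(p) p$burden, 1L),
    stringsAsFactors = FALSE, row.names = NULL)

  msi <- lapply(co$samples$sample_id, function(sid) {
    calls <- simulateMsiProfile(sid, is_msi = TRUE, sim_config)
    msiScore(sid, calls, config)
  })
  names(msi) <- co$samples$sample_id

  filters <- list(); gene_sets <- list(); tmb <- list()
  if (length(sim_config@variant_table_spec) > 0) {
    for (r in seq_len(nrow(co$samples))) {
      sm <- co$samples[r, ]
      vt <- simulateVariantTable(sm, sim_config@variant_table_spec,
                                 sim_config)
      fr <- applyFilterCascade(vt$variants, sm, config)
      filters[[sm$sample_id]] <- fr
      gene_sets[[sm$sample_id]] <- classifyGeneSet(keptVariants(fr),
                                                   sm$sample_id)
      tmb[[sm$sample_id]] <- computeTmb(countThroughCoding(fr), config)
    }
  }

  pids <- unique(co$samples$patient_id)
  cls <- list(); sigs <- list(); sums <- list(); immunos <- list()
  for (pid in pids) {
    s1 <- paste0(pid, "_T1"); s2 <- paste0(pid, "_T2")
    hlaRow <- co$hla[co$hla$patient_id == pid, ]
    immuno <- immunogenicityTable(co$catalog, hlaRow, predictor, config,
                                  class_i_counts = co$binder_counts,
                                  include_class_ii = FALSE)
    immunos[[pid]] <- immuno
    cls[[pid]] <- classifyPair(profiles[[s1]]$present,
                               profiles[[s2]]$present,
                               patient_id = pid, earlier_sample_id = s1,
                               later_sample_id = s2)
    b2m <- co$samples$b2m_ihc[co$samples$sample_id == s2]
    sigs[[pid]] <- detectEditingSignature(cls[[pid]], immuno,
                                          b2m_context = b2m)
    sums[[pid]] <- summarizeEdits(cls[[pid]], immuno)
  }
  cohortSig <- cohortEditingSignal(cls, immunos)
  ctab <- buildCohortTable(co$samples)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLocusCatalog(co$catalog, file.path(out_dir, "catalog.tsv"))
    writeEvidence(co$evidence, file.path(out_dir, "evidence.tsv"))
    writeSamples(co$samples, file.path(out_dir, "samples.tsv"))
    writeHla(co$hla, file.path(out_dir, "hla.tsv"))
    .writeTsv(burdens, file.path(out_dir, "fsm_burden.tsv"))
    .writeTsv(data.frame(
      sample_id = names(msi),
      n_scanned = vapply(msi, function(m) m@n_scanned, 1L),
      n_unstable = vapply(msi, function(m) m@n_unstable, 1L),
      score_pct = vapply(msi, function(m) m@score_pct, 1),
      classification = vapply(msi, function(m) m@classification, ""),
      stringsAsFactors = FALSE), file.path(out_dir, "msi.tsv"))
    clsTab <- do.call(rbind, lapply(cls, function(cl) data.frame(
      patient_id = cl@patient_id,
      category = rep(c("kept", "lost", "gained"),
                     c(length(cl@kept), length(cl@lost), length(cl@gained))),
      locus_id = c(cl@kept, cl@lost, cl@gained), stringsAsFactors = FALSE)))
    .writeTsv(clsTab, file.path(out_dir, "classification.tsv"))
    sigTab <- do.call(rbind, lapply(sigs, function(s) data.frame(
      patient_id = s@patient_id, statistic = s@statistic,
      p_value = s@p_value, signature_present = s@signature_present,
      b2m_context = s@b2m_context, stringsAsFactors = FALSE)))
    .writeTsv(sigTab, file.path(out_dir, "editing_signals.tsv"))
    .writeTsv(ctab, file.path(out_dir, "cohort_table.tsv"))
    writeFspFasta(co$catalog, file.path(out_dir, "fsp.fasta"), config)
    log <- list(
      package = "fsmEdit",
      version = as.character(utils::packageVersion("fsmEdit")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = sim_config@seed,
      sim_config = stats::setNames(
        lapply(slotNames(sim_config), function(s) slot(sim_config, s)),
        slotNames(sim_config)),
      pipeline_config = stats::setNames(
        lapply(slotNames(config), function(s) slot(config, s)),
        slotNames(config)),
      cohort_signature = cohortSig[c("p_value", "signature_present",
                                     "n_lost", "n_kept")])
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  invisible(list(cohort = co, profiles = profiles, burdens = burdens,
                 msi = msi, filters = filters, gene_sets = gene_sets,
                 tmb = tmb, classifications = cls, signals = sigs,
                 summaries = sums, immunos = immunos,
                 cohort_signature = cohortSig, cohort_table = ctab))
}
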