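#' Create a pipeline configuration
#'
#' Constructor for \linkS4class{PipelineConfig} with the published defaults.
#' Any threshold can be overridden; overrides are echoed into pipeline run
#' logs by \code{\link{runPipeline}}.
#'
#' @param min_mut_reads minimum mutant-supporting reads for FSM presence (3).
#' @param min_fsm_vaf VAF must strictly exceed this for FSM presence (0.10).
#' @param min_depth minimum coverage for variant inclusion (20).
#' @param min_allele_reads minimum reads required for both alleles (6).
#' @param popaf_cut gnomAD AF cutoff, exclusion requires exceeding it in both
#'   global and Finnish populations; tumor-only samples only (0.01).
#' @param min_abs_af minimum absolute allele fraction (0.05).
#' @param max_zygosity_ratio maximum mean-normalized AF ratio (5).
#' @param min_mode_norm_af minimum mode-normalized AF (0.15).
#' @param msi_threshold_pct MSI requires a score strictly above this (20).
#' @param strong_ic50_nm strong binders have IC50 strictly below this (500).
#' @param class_i_len class I epitope length (9).
#' @param class_ii_lens class II epitope lengths (12:16).
#' @param flank_aa wild-type flank residues for class I enumeration (8).
#' @param class_ii_flank_aa flank residues for class II enumeration (15).
#' @param tmb_territory_mb exome territory in Mb for TMB (37).
#' @param excluded_symbol_patterns gene-symbol substrings removed by the
#'   cascade (case-sensitive substring match).
#' @param allowed_chroms chromosomes retained by the cascade (1..22, X).
#' @return A validated \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig()
#' cfg
#' @export
pipelineConfig <- function(min_mut_reads = 3L,
                           min_fsm_vaf = 0.10,
                           min_depth = 20L,
                           min_allele_reads = 6L,
                           popaf_cut = 0.01,
                           min_abs_af = 0.05,
                           max_zygosity_ratio = 5,
                           min_mode_norm_af = 0.15,
                           msi_threshold_pct = 20,
                           strong_ic50_nm = 500,
                           class_i_len = 9L,
                           class_ii_lens = 12:16,
                           flank_aa = 8L,
                           class_ii_flank_aa = 15L,
                           tmb_territory_mb = 37,
                           excluded_symbol_patterns = c("orf", "ENSG", "ENSM",
                                                        "ENST", "Unknown"),
                           allowed_chroms = c(as.character(1:22), "X")) {
  new("PipelineConfig",
      min_mut_reads = as.integer(min_mut_reads),
      min_fsm_vaf = as.numeric(min_fsm_vaf),
      min_depth = as.integer(min_depth),
      min_allele_reads = as.integer(min_allele_reads),
      popaf_cut = as.numeric(popaf_cut),
      min_abs_af = as.numeric(min_abs_af),
      max_zygosity_ratio = as.numeric(max_zygosity_ratio),
      min_mode_norm_af = as.numeric(min_mode_norm_af),
      msi_threshold_pct = as.numeric(msi_threshold_pct),
      strong_ic50_nm = as.numeric(strong_ic50_nm),
      class_i_len = as.integer(class_i_len),
      class_ii_lens = as.integer(class_ii_lens),
      flank_aa = as.integer(flank_aa),
      class_ii_flank_aa = as.integer(class_ii_flank_aa),
      tmb_territory_mb = as.numeric(tmb_territory_mb),
      excluded_symbol_patterns = excluded_symbol_patterns,
      allowed_chroms = allowed_chroms)
}

#' Serialize and restore a pipeline configuration
#'
#' JSON round-trip for \linkS4class{PipelineConfig}; defaults serialize and
#' deserialize bit-identically, and overridden values survive the round trip.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path file path.
#' @return \code{writePipelineConfig} returns the path invisibly;
#'   \code{readPipelineConfig} returns a \linkS4class{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  sl <- slotNames(config)
  x <- stats::setNames(lapply(sl, function(s) slot(config, s)), sl)
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, x)
}
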