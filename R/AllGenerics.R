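#' Accessors
#'
#' Accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @return \code{loci} returns the locus data.frame of a
#'   \linkS4class{LocusCatalog}; \code{catalogName} its name;
#'   \code{keptVariants}, \code{stageCounts} and \code{auditLabels} the
#'   components of a \linkS4class{FilterResult}; \code{summaryTable} the
#'   per-category table of an \linkS4class{EditSummary}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname accessors
#' @export
setGeneric("catalogName", function(x) standardGeneric("catalogName"))

#' @rdname accessors
#' @export
setGeneric("keptVariants", function(x) standardGeneric("keptVariants"))

#' @rdname accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname accessors
#' @export
setGeneric("auditLabels", function(x) standardGeneric("auditLabels"))

#' @rdname accessors
#' @export
setGeneric("summaryTable", function(x) standardGeneric("summaryTable"))

#' @rdname accessors
#' @export
setMethod("loci", "LocusCatalog", function(x) x@loci)

#' @rdname accessors
#' @export
setMethod("catalogName", "LocusCatalog", function(x) x@name)

#' @describeIn accessors number of loci in the catalog.
#' @export
setMethod("length", "LocusCatalog", function(x) nrow(x@loci))

#' @rdname accessors
#' @export
setMethod("keptVariants", "FilterResult", function(x) x@kept)

#' @rdname accessors
#' @export
setMethod("stageCounts", "FilterResult", function(x) x@stage_counts)

#' @rdname accessors
#' @export
setMethod("auditLabels", "FilterResult", function(x) x@audit)

#' @rdname accessors
#' @export
setMethod("summaryTable", "EditSummary", function(x) x@table)

setMethod("show", "LocusCatalog", function(object) {
  cat(sprintf("LocusCatalog '%s' with %d coding mononucleotide-repeat loci\n",
              object@name, nrow(object@loci)))
  if (nrow(object@loci) > 0) {
    cat(sprintf("  repeat lengths %d-%d; genes: %s%s\n",
                min(object@loci$repeat_len), max(object@loci$repeat_len),
                paste(utils::head(unique(object@loci$gene_symbol), 5),
                      collapse = ", "),
                if (length(unique(object@loci$gene_symbol)) > 5) ", ..." else ""))
  }
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  FSM call: >= %d mutant reads, VAF > %.2f\n",
              object@min_mut_reads, object@min_fsm_vaf))
  cat(sprintf("  MSI: score > %g%% => MSI\n", object@msi_threshold_pct))
  cat(sprintf("  cascade: depth >= %d, allele reads >= %d, popAF > %g (both), AF >= %g,\n",
              object@min_depth, object@min_allele_reads, object@popaf_cut,
              object@min_abs_af))
  cat(sprintf("           zygosity ratio <= %g, mode-normalized AF >= %g\n",
              object@max_zygosity_ratio, object@min_mode_norm_af))
  cat(sprintf("  epitopes: class I %d-mers, class II %s-mers, strong IC50 < %g nM\n",
              object@class_i_len,
              paste(range(object@class_ii_lens), collapse = "-"),
              object@strong_ic50_nm))
  cat(sprintf("  TMB territory: %g Mb\n", object@tmb_territory_mb))
})

setMethod("show", "MsiResult", function(object) {
  cat(sprintf("MsiResult %s: %d/%d unstable (%.2f%%) -> %s\n",
              object@sample_id, object@n_unstable, object@n_scanned,
              object@score_pct, object@classification))
})

setMethod("show", "FilterResult", function(object) {
  cat(sprintf("FilterResult: %d in, %d kept\n", length(object@audit),
              nrow(object@kept)))
  nz <- object@stage_counts[object@stage_counts > 0]
  if (length(nz) > 0) {
    cat("  removed:", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "),
        "\n")
  }
})

setMethod("show", "FrameshiftPeptide", function(object) {
  cat(sprintf("FrameshiftPeptide %s: flank '%s' + novel '%s' (%d aa%s)\n",
              object@locus_id, object@flank, object@novel, object@novel_len,
              if (object@terminated) ", stop reached" else ", runs to CDS end"))
})

setMethod("show", "PairClassification", function(object) {
  cat(sprintf("PairClassification %s (%s -> %s): %d kept, %d lost, %d gained\n",
              object@patient_id, object@earlier_sample_id,
              object@later_sample_id, length(object@kept),
              length(object@lost), length(object@gained)))
})

setMethod("show", "EditSummary", function(object) {
  cat("EditSummary\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "EditingSignal", function(object) {
  cat(sprintf("EditingSignal %s: W = %s, one-sided p = %s, signature %s (B2M %s)\n",
              object@patient_id, format(object@statistic),
              format(object@p_value),
              if (is.na(object@signature_present)) "undetermined"
              else if (object@signature_present) "present" else "absent",
              object@b2m_context))
})
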