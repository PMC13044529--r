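# On-disk formats: tab-separated, UTF-8, "NA" the only missing-value token.

.CLINVAR_LEVELS <- c("P", "LP", "VUS", "LB", "B", "none")
.VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "qc_pass", "depth",
                   "ref_reads", "alt_reads", "af", "gnomad_global_af",
                   "gnomad_fin_af", "gene_symbol", "is_coding",
                   "lof_predicted", "clinvar_class")
.SAMPLE_COLS <- c("sample_id", "patient_id", "tumor_type", "chronology_index",
                  "diagnosis_age", "stage", "matched_normal", "b2m_ihc",
                  "mmr_germline", "cd8_core_density", "cd8_margin_density")
.EVIDENCE_COLS <- c("sample_id", "locus_id", "depth", "mut_reads")
.HLA_COLS <- c("patient_id", "class_i", "class_ii")

#' Read and write a repeat-locus catalog
#'
#' TSV with columns locus_id, gene_symbol, chrom, pos, repeat_base,
#' repeat_len, cds_seq, repeat_cds_index. Genomic positions are 1-based (VCF
#' convention); \code{repeat_cds_index} is a 0-based index into
#' \code{cds_seq}. Rows violating the locus invariants are rejected with
#' row-numbered messages.
#'
#' @param path file path.
#' @param format table format; only "tsv" is supported.
#' @param catalog a \linkS4class{LocusCatalog}.
#' @param name catalog name to attach on read (defaults to the file name).
#' @return \code{readLocusCatalog} returns a \linkS4class{LocusCatalog};
#'   \code{writeLocusCatalog} returns the path invisibly.
#' @export
readLocusCatalog <- function(path, format = "tsv", name = NULL) {
  if (!identical(format, "tsv")) stop("unsupported catalog format: ", format)
  df <- .readTsv(path)
  .requireCols(df, .LOCUS_COLS, "locus catalog")
  df <- df[, .LOCUS_COLS]
  if (nrow(df) > 0) {
    df$pos <- as.integer(df$pos)
    df$repeat_len <- as.integer(df$repeat_len)
    df$repeat_cds_index <- as.integer(df$repeat_cds_index)
    df$chrom <- as.character(df$chrom)
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  new("LocusCatalog", loci = df, name = name)
}

#' @rdname readLocusCatalog
#' @export
writeLocusCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "LocusCatalog"))
  .writeTsv(loci(catalog), path)
}

.validateVariants <- function(df, what = "variant table") {
  if (nrow(df) == 0) return(df)
  for (r in seq_len(nrow(df))) {
    x <- df[r, ]
    fail <- function(m) stop(sprintf("%s row %d: %s", what, r, m), call. = FALSE)
    if (is.na(x$pos) || x$pos < 1) fail("pos must be >= 1")
    if (is.na(x$depth) || x$depth < 0) fail("depth must be >= 0")
    if (is.na(x$ref_reads) || is.na(x$alt_reads) ||
        x$ref_reads < 0 || x$alt_reads < 0) fail("allele read counts must be >= 0")
    if (x$ref_reads + x$alt_reads > x$depth) {
      fail("ref_reads + alt_reads exceeds depth")
    }
    if (is.na(x$af) || x$af < 0 || x$af > 1) fail("af must lie in [0, 1]")
    if (x$depth > 0 && abs(x$af - x$alt_reads / x$depth) > 0.01) {
      fail("af inconsistent with alt_reads/depth (tolerance 0.01)")
    }
    for (col in c("gnomad_global_af", "gnomad_fin_af")) {
      v <- x[[col]]
      if (!is.na(v) && (v < 0 || v > 1)) fail(paste(col, "must lie in [0, 1]"))
    }
    if (!x$clinvar_class %in% .CLINVAR_LEVELS) {
      fail(sprintf("unknown clinvar_class '%s'", x$clinvar_class))
    }
    if (!is.logical(x$qc_pass) || is.na(x$qc_pass)) fail("qc_pass must be TRUE/FALSE")
    if (!is.logical(x$is_coding) || is.na(x$is_coding)) fail("is_coding must be TRUE/FALSE")
    if (!is.logical(x$lof_predicted) || is.na(x$lof_predicted)) {
      fail("lof_predicted must be TRUE/FALSE")
    }
  }
  df
}

#' Read and write annotated somatic variant tables
#'
#' Two dialects are supported. \code{"maf_like_tsv"} is a TSV with the typed
#' columns chrom, pos, ref, alt, qc_pass, depth, ref_reads, alt_reads, af,
#' gnomad_global_af, gnomad_fin_af, gene_symbol, is_coding, lof_predicted,
#' clinvar_class. \code{"vcf"} carries annotations in INFO keys GNOMAD_AF,
#' GNOMAD_FIN_AF, GENE, CODING, LOF, CLNSIG and AF (AF is carried so the
#' allele fraction round-trips exactly rather than being re-derived from
#' AD/DP), with FORMAT fields DP and AD and FILTER PASS encoding qc_pass.
#' Missing gnomAD frequencies are preserved as NA, never as 0.
#'
#' @param path file path.
#' @param dialect "maf_like_tsv" or "vcf".
#' @param variants a validated variant data.frame.
#' @return \code{readVariantTable} returns a validated data.frame of variant
#'   records; \code{writeVariantTable} returns the path invisibly.
#' @export
readVariantTable <- function(path, dialect = c("maf_like_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "maf_like_tsv") {
    df <- .readTsv(path)
    .requireCols(df, .VARIANT_COLS, "variant table")
    df <- df[, .VARIANT_COLS]
    if (nrow(df) == 0) return(.emptyVariantTable())
    df$chrom <- as.character(df$chrom)
    df$pos <- as.integer(df$pos)
    df$depth <- as.integer(df$depth)
    df$ref_reads <- as.integer(df$ref_reads)
    df$alt_reads <- as.integer(df$alt_reads)
    df$gnomad_global_af <- as.numeric(df$gnomad_global_af)
    df$gnomad_fin_af <- as.numeric(df$gnomad_fin_af)
    if (is.character(df$qc_pass)) df$qc_pass <- as.logical(df$qc_pass)
    if (is.character(df$is_coding)) df$is_coding <- as.logical(df$is_coding)
    if (is.character(df$lof_predicted)) df$lof_predicted <- as.logical(df$lof_predicted)
    return(.validateVariants(df))
  }
  .readVariantVcf(path)
}

.emptyVariantTable <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), qc_pass = logical(0), depth = integer(0),
             ref_reads = integer(0), alt_reads = integer(0), af = numeric(0),
             gnomad_global_af = numeric(0), gnomad_fin_af = numeric(0),
             gene_symbol = character(0), is_coding = logical(0),
             lof_predicted = logical(0), clinvar_class = character(0),
             stringsAsFactors = FALSE)
}

#' @rdname readVariantTable
#' @export
writeVariantTable <- function(variants, path,
                              dialect = c("maf_like_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  .requireCols(variants, .VARIANT_COLS, "variant table")
  if (dialect == "maf_like_tsv") {
    return(.writeTsv(variants[, .VARIANT_COLS], path))
  }
  .writeVariantVcf(variants, path)
}

.writeVariantVcf <- function(df, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=GNOMAD_AF,Number=1,Type=Float,Description=\"gnomAD global AF\">",
    "##INFO=<ID=GNOMAD_FIN_AF,Number=1,Type=Float,Description=\"gnomAD Finnish AF\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CODING,Number=1,Type=Integer,Description=\"1 if coding consequence\">",
    "##INFO=<ID=LOF,Number=1,Type=Integer,Description=\"1 if predicted loss of function\">",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"ClinVar class\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths ref,alt\">",
    "##FILTER=<ID=fail_qc,Description=\"Failed caller quality control\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR"
  )
  fmtNum <- function(v) ifelse(is.na(v), NA, sub("\\.?0+$", "",
                                                 format(v, scientific = FALSE,
                                                        trim = TRUE, digits = 15)))
  lines <- hdr
  if (nrow(df) > 0) {
    info <- vapply(seq_len(nrow(df)), function(r) {
      x <- df[r, ]
      parts <- c(sprintf("AF=%s", fmtNum(x$af)),
                 if (!is.na(x$gnomad_global_af))
                   sprintf("GNOMAD_AF=%s", fmtNum(x$gnomad_global_af)),
                 if (!is.na(x$gnomad_fin_af))
                   sprintf("GNOMAD_FIN_AF=%s", fmtNum(x$gnomad_fin_af)),
                 sprintf("GENE=%s", x$gene_symbol),
                 sprintf("CODING=%d", as.integer(x$is_coding)),
                 sprintf("LOF=%d", as.integer(x$lof_predicted)),
                 sprintf("CLNSIG=%s", x$clinvar_class))
      paste(parts, collapse = ";")
    }, character(1))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tDP:AD\t%d:%d,%d",
                    df$chrom, df$pos, df$ref, df$alt,
                    ifelse(df$qc_pass, "PASS", "fail_qc"), info,
                    df$depth, df$ref_reads, df$alt_reads)
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

.readVariantVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) return(.emptyVariantTable())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  infoNum <- function(k) suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = k)))
  infoChr <- function(k) as.character(vcfR::extract.info(vcf, element = k))
  gt <- function(el) {
    m <- vcfR::extract.gt(vcf, element = el)
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    m[, 1]
  }
  dp <- as.integer(gt("DP"))
  ad <- gt("AD")
  adm <- do.call(rbind, strsplit(ad, ",", fixed = TRUE))
  df <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qc_pass = fix$FILTER == "PASS",
    depth = dp,
    ref_reads = as.integer(adm[, 1]),
    alt_reads = as.integer(adm[, 2]),
    af = infoNum("AF"),
    gnomad_global_af = infoNum("GNOMAD_AF"),
    gnomad_fin_af = infoNum("GNOMAD_FIN_AF"),
    gene_symbol = infoChr("GENE"),
    is_coding = infoNum("CODING") == 1,
    lof_predicted = infoNum("LOF") == 1,
    clinvar_class = infoChr("CLNSIG"),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$af))) stop("VCF record missing AF INFO field", call. = FALSE)
  .validateVariants(df, "VCF")
}

#' Read and write per-locus FSM read evidence
#'
#' TSV with columns sample_id, locus_id, depth, mut_reads (reads supporting
#' the single-nucleotide deletion). Rows with mut_reads > depth are rejected.
#'
#' @param path file path.
#' @param evidence an evidence data.frame.
#' @return \code{readEvidence} returns a validated data.frame;
#'   \code{writeEvidence} the path, invisibly.
#' @export
readEvidence <- function(path) {
  df <- .readTsv(path)
  .requireCols(df, .EVIDENCE_COLS, "evidence table")
  df <- df[, .EVIDENCE_COLS]
  if (nrow(df) == 0) return(df)
  df$depth <- as.integer(df$depth)
  df$mut_reads <- as.integer(df$mut_reads)
  validateEvidence(df)
}

#' @rdname readEvidence
#' @export
writeEvidence <- function(evidence, path) {
  .requireCols(evidence, .EVIDENCE_COLS, "evidence table")
  .writeTsv(evidence[, .EVIDENCE_COLS], path)
}

#' Validate an FSM evidence table
#'
#' @param evidence data.frame with sample_id, locus_id, depth, mut_reads.
#' @return The validated data.frame (invisibly usable in pipelines).
#' @export
validateEvidence <- function(evidence) {
  bad <- which(is.na(evidence$depth) | is.na(evidence$mut_reads) |
               evidence$depth < 0 | evidence$mut_reads < 0 |
               evidence$mut_reads > evidence$depth)
  if (length(bad) > 0) {
    stop(sprintf("evidence row %d: mut_reads must lie in [0, depth]", bad[1]),
         call. = FALSE)
  }
  evidence
}

.validateSamples <- function(df) {
  if (nrow(df) == 0) return(df)
  for (r in seq_len(nrow(df))) {
    x <- df[r, ]
    fail <- function(m) stop(sprintf("samples row %d: %s", r, m), call. = FALSE)
    if (!x$tumor_type %in% c("CRC", "UC")) {
      fail(sprintf("unknown tumor_type '%s'", x$tumor_type))
    }
    if (is.na(x$chronology_index) || x$chronology_index < 1) {
      fail("chronology_index must be >= 1")
    }
    okStage <- if (x$tumor_type == "CRC") c("I", "II", "III", "IV", "unknown")
               else c("nonMI", "MI", "unknown")
    if (!x$stage %in% okStage) {
      fail(sprintf("stage '%s' not allowed for tumor_type %s", x$stage,
                   x$tumor_type))
    }
    if (!x$b2m_ihc %in% c("positive", "negative", "heterogeneous", "unknown")) {
      fail(sprintf("unknown b2m_ihc '%s'", x$b2m_ihc))
    }
    if (!x$mmr_germline %in% c("MLH1", "MSH2", "MSH6", "PMS2", "EPCAM",
                               "unknown")) {
      fail(sprintf("unknown mmr_germline '%s'", x$mmr_germline))
    }
    if (!is.logical(x$matched_normal) || is.na(x$matched_normal)) {
      fail("matched_normal must be TRUE/FALSE")
    }
  }
  dup <- duplicated(df[, c("patient_id", "chronology_index")])
  if (any(dup)) {
    stop(sprintf("samples row %d: duplicate chronology_index within patient",
                 which(dup)[1]), call. = FALSE)
  }
  df
}

#' Read and write sample metadata
#'
#' TSV with columns sample_id, patient_id, tumor_type (CRC/UC),
#' chronology_index (order of MSI cancer diagnosis, 1-based), diagnosis_age,
#' stage (I-IV for CRC, nonMI/MI for UC, or unknown), matched_normal,
#' b2m_ihc (positive/negative/heterogeneous/unknown), mmr_germline,
#' cd8_core_density, cd8_margin_density. The stage vocabulary is restricted
#' by tumor type and chronology_index must be unique within a patient.
#'
#' @param path file path.
#' @param samples a sample metadata data.frame.
#' @return \code{readSamples} returns a validated data.frame;
#'   \code{writeSamples} the path, invisibly.
#' @export
readSamples <- function(path) {
  df <- .readTsv(path)
  .requireCols(df, .SAMPLE_COLS, "samples table")
  df <- df[, .SAMPLE_COLS]
  if (nrow(df) == 0) return(df)
  df$chronology_index <- as.integer(df$chronology_index)
  df$diagnosis_age <- as.numeric(df$diagnosis_age)
  df$cd8_core_density <- as.numeric(df$cd8_core_density)
  df$cd8_margin_density <- as.numeric(df$cd8_margin_density)
  if (is.character(df$matched_normal)) df$matched_normal <- as.logical(df$matched_normal)
  .validateSamples(df)
}

#' @rdname readSamples
#' @export
writeSamples <- function(samples, path) {
  .requireCols(samples, .SAMPLE_COLS, "samples table")
  .writeTsv(samples[, .SAMPLE_COLS], path)
}

.HLA_PATTERN <- "^[A-Z]+[0-9]*\\*[0-9]{2,}:[0-9]{2,}$"

.validateHla <- function(df) {
  if (nrow(df) == 0) return(df)
  for (r in seq_len(nrow(df))) {
    ci <- .splitAlleles(df$class_i[r])
    cii <- .splitAlleles(df$class_ii[r])
    fail <- function(m) stop(sprintf("HLA row %d: %s", r, m), call. = FALSE)
    if (length(ci) < 1 || length(ci) > 6) {
      fail("class_i must carry 1-6 alleles")
    }
    bad <- c(ci, cii)[!grepl(.HLA_PATTERN, c(ci, cii))]
    if (length(bad) > 0) {
      fail(sprintf("malformed allele name '%s'", bad[1]))
    }
    if (any(table(ci) > 2) || (length(cii) > 0 && any(table(cii) > 2))) {
      fail("an allele may be listed at most twice (homozygosity)")
    }
  }
  df
}

.splitAlleles <- function(s) {
  if (is.na(s) || s == "") return(character(0))
  strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Read and write patient HLA genotypes
#'
#' TSV with columns patient_id, class_i, class_ii; alleles are
#' semicolon-separated names like "A*02:01". class_i carries 1-6 entries,
#' class_ii may be empty; homozygous alleles may appear twice but no allele
#' more than twice.
#'
#' @param path file path.
#' @param hla an HLA genotype data.frame.
#' @return \code{readHla} returns a validated data.frame; \code{writeHla}
#'   the path, invisibly. \code{hlaAlleles} splits one row's allele string
#'   into a character vector.
#' @export
readHla <- function(path) {
  df <- .readTsv(path)
  .requireCols(df, .HLA_COLS, "HLA table")
  df <- df[, .HLA_COLS]
  df$class_i <- as.character(df$class_i)
  df$class_ii <- ifelse(is.na(df$class_ii), "", as.character(df$class_ii))
  .validateHla(df)
}

#' @rdname readHla
#' @export
writeHla <- function(hla, path) {
  .requireCols(hla, .HLA_COLS, "HLA table")
  .writeTsv(hla[, .HLA_COLS], path)
}

#' @rdname readHla
#' @param allele_string semicolon-separated allele names.
#' @export
hlaAlleles <- function(allele_string) .splitAlleles(allele_string)
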