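# Frameshift peptide translation and MHC epitope enumeration.
#
# Conventions: the single deleted base is the last base of the homopolymer
# run (within a homopolymer the deleted position is immaterial: every choice
# yields the same mutant CDS). The junction codon is the first codon whose
# nucleotides differ from the wild-type in-frame codon at the same index.

#' Translate the deletion frameshift at a repeat locus
#'
#' Deletes one base of the mononucleotide run, re-translates the mutant CDS
#' with the standard codon table, and reports the frameshift peptide: up to
#' \code{flank_aa} wild-type residues preceding the junction codon, followed
#' by the novel residues from the junction codon up to (exclusive) the first
#' stop codon in the shifted frame. If no stop is reached and fewer than 3 nt
#' remain, the novel sequence is truncated at the CDS end and
#' \code{terminated} is FALSE. A frameshift producing an immediate stop at
#' the junction yields an empty novel sequence, not an error.
#'
#' @param locus one locus: a single row of \code{loci(catalog)} (data.frame
#'   or list) with fields locus_id, cds_seq, repeat_cds_index, repeat_len.
#' @param config a \linkS4class{PipelineConfig}.
#' @param flank_aa flank length override; class II enumeration uses the
#'   longer \code{class_ii_flank_aa} so that every junction-spanning window
#'   up to the longest class II length is enumerable.
#' @return A \linkS4class{FrameshiftPeptide}.
#' @examples
#' loc <- list(locus_id = "toy", cds_seq = "ATGCCTAAAAAACTGAGGTAA",
#'             repeat_cds_index = 6L, repeat_len = 6L)
#' translateFsp(loc)  # flank "MPK", novel "N"
#' @export
translateFsp <- function(locus, config = pipelineConfig(),
                         flank_aa = config@flank_aa) {
  wt <- locus$cds_seq
  i <- locus$repeat_cds_index + locus$repeat_len  # 1-based last run base
  mut <- paste0(substr(wt, 1, i - 1), substr(wt, i + 1, nchar(wt)))
  wtC <- .splitCodons(wt)
  mutC <- .splitCodons(mut)  # trailing partial codon (<3 nt) dropped
  nm <- length(mutC)
  diffs <- which(mutC != wtC[seq_len(nm)])
  j <- if (length(diffs) > 0) diffs[1] else nm + 1L

  mutAA <- .translateCodons(mutC)
  stops <- which(mutAA == "*")
  terminated <- FALSE
  if (length(stops) > 0 && stops[1] < j) {
    # shared stop codon at/after the repeat but before any altered codon:
    # translation ends before the frameshift is reached
    novel <- ""
    terminated <- TRUE
    j <- stops[1]  # flank ends before the stop
  } else if (j > nm) {
    novel <- ""
  } else {
    stopAfter <- stops[stops >= j]
    if (length(stopAfter) > 0) {
      terminated <- TRUE
      novel <- paste(mutAA[seq(j, stopAfter[1] - 1L)][seq_len(max(0, stopAfter[1] - j))],
                     collapse = "")
      if (stopAfter[1] == j) novel <- ""
    } else {
      novel <- paste(mutAA[seq(j, nm)], collapse = "")
    }
  }

  wtAA <- .translateCodons(wtC)
  fstart <- max(1L, j - flank_aa)
  flank <- if (j > 1) paste(wtAA[seq(fstart, j - 1L)], collapse = "") else ""

  new("FrameshiftPeptide",
      locus_id = as.character(locus$locus_id),
      flank = flank, novel = novel,
      full = paste0(flank, novel),
      novel_len = nchar(novel),
      terminated = terminated)
}

.enumWindows <- function(full, flank_len, k) {
  L <- nchar(full)
  if (L < k) return(character(0))
  sMin <- max(1L, flank_len + 2L - k)  # window must contain >= 1 novel residue
  sMax <- L - k + 1L
  if (sMin > sMax) return(character(0))
  substring(full, sMin:sMax, (sMin:sMax) + k - 1L)
}

.tabulateWindows <- function(wins) {
  if (length(wins) == 0) {
    return(data.frame(peptide = character(0), multiplicity = integer(0),
                      stringsAsFactors = FALSE))
  }
  tb <- table(wins)
  data.frame(peptide = names(tb), multiplicity = as.integer(tb),
             stringsAsFactors = FALSE)[order(match(names(tb), wins)), ,
                                       drop = FALSE]
}

#' Enumerate junction-spanning candidate epitopes
#'
#' All windows of the target length over the frameshift peptide that contain
#' at least one novel residue. Identical sequences arising from different
#' offsets are reported once with their multiplicity. Windows shorter than
#' the target length are never emitted.
#'
#' @param fsp a \linkS4class{FrameshiftPeptide}.
#' @param config a \linkS4class{PipelineConfig}; class I uses
#'   \code{class_i_len} (9), class II all of \code{class_ii_lens} (12-16).
#' @return data.frame with columns peptide, multiplicity (and length for
#'   class II).
#' @export
enumerateClassI <- function(fsp, config = pipelineConfig()) {
  fl <- nchar(fsp@flank)
  .tabulateWindows(.enumWindows(fsp@full, fl, config@class_i_len))
}

#' @rdname enumerateClassI
#' @export
enumerateClassII <- function(fsp, config = pipelineConfig()) {
  fl <- nchar(fsp@flank)
  out <- lapply(config@class_ii_lens, function(k) {
    df <- .tabulateWindows(.enumWindows(fsp@full, fl, k))
    if (nrow(df) > 0) df$length <- k
    df
  })
  out <- out[vapply(out, nrow, 1L) > 0]
  if (length(out) == 0) {
    return(data.frame(peptide = character(0), multiplicity = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Predict peptide-MHC binding through a pluggable predictor
#'
#' Applies a deterministic affinity predictor to every (peptide, allele)
#' pair and classifies strong binders by the strict IC50 < 500 nM rule. An
#' external prediction tool can be adapted by wrapping it in a function
#' \code{function(peptide, allele) -> IC50 nM}.
#'
#' @param peptides character vector of peptide sequences.
#' @param alleles character vector of allele names.
#' @param predictor function(peptide, allele) returning a positive IC50 in nM.
#' @param config a \linkS4class{PipelineConfig}.
#' @return data.frame with one row per (peptide, allele) pair: peptide,
#'   allele, ic50_nm, strong.
#' @export
predictBinding <- function(peptides, alleles, predictor,
                           config = pipelineConfig()) {
  if (length(peptides) == 0 || length(alleles) == 0) {
    return(data.frame(peptide = character(0), allele = character(0),
                      ic50_nm = numeric(0), strong = logical(0),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(peptide = peptides, allele = alleles,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ic50 <- mapply(function(p, a) predictor(p, a), grid$peptide, grid$allele,
                 USE.NAMES = FALSE)
  bad <- which(!is.finite(ic50) | ic50 <= 0)
  if (length(bad) > 0) {
    stop(sprintf("predictor returned a non-positive or missing IC50 for (%s, %s)",
                 grid$peptide[bad[1]], grid$allele[bad[1]]), call. = FALSE)
  }
  grid$ic50_nm <- as.numeric(ic50)
  grid$strong <- grid$ic50_nm < config@strong_ic50_nm
  grid
}

#' Deterministic synthetic affinity oracle
#'
#' A stand-in for external MHC binding predictors, used by the synthetic
#' cohort and in tests. For a given seed it is a pure function of (peptide,
#' allele): the IC50 is log-uniform on [1, 50000) nM, driven by a hash of
#' (peptide, allele, seed). Each allele additionally carries a planted
#' 3-residue anchor motif (derived from the allele name and seed); peptides
#' containing their allele's motif receive an IC50 log-uniform on [1, 400)
#' nM, guaranteeing plantable strong binders.
#'
#' @param seed integer seed.
#' @return function(peptide, allele) returning IC50 in nM. The planted motif
#'   of an allele is available via \code{oracleMotif}.
#' @export
syntheticAffinityOracle <- function(seed) {
  force(seed)
  motifs <- new.env(parent = emptyenv())
  function(peptide, allele) {
    motif <- get0(allele, envir = motifs)
    if (is.null(motif)) {
      motif <- oracleMotif(allele, seed)
      assign(allele, motif, envir = motifs)
    }
    if (grepl(motif, peptide, fixed = TRUE)) {
      u <- .hashUnif(paste("motif", peptide, allele, seed, sep = "|"))
      exp(u * log(400))
    } else {
      u <- .hashUnif(paste(peptide, allele, seed, sep = "|"))
      exp(u * log(50000))
    }
  }
}

#' @rdname syntheticAffinityOracle
#' @param allele allele name.
#' @export
oracleMotif <- function(allele, seed) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  idx <- vapply(1:3, function(k) {
    1L + as.integer(floor(.hashUnif(paste("anchor", allele, seed, k,
                                          sep = "|")) * 20))
  }, integer(1))
  paste(aas[idx], collapse = "")
}

#' Class I strong-binder counts per locus and allele
#'
#' For every catalog locus, enumerates the junction-spanning class I 9-mers
#' and counts, per allele, the unique peptides predicted to bind strongly
#' (IC50 < 500 nM). Shared across patients carrying the same allele, so the
#' count matrix is computed once per cohort.
#'
#' @param catalog a \linkS4class{LocusCatalog}.
#' @param alleles character vector of class I allele names.
#' @param predictor an affinity predictor function.
#' @param config a \linkS4class{PipelineConfig}.
#' @return integer matrix loci x alleles of strong-binder counts
#'   (dimnames: locus_id, allele).
#' @export
classIBinderCounts <- function(catalog, alleles, predictor,
                               config = pipelineConfig()) {
  df <- loci(catalog)
  alleles <- unique(alleles)
  m <- matrix(0L, nrow = nrow(df), ncol = length(alleles),
              dimnames = list(df$locus_id, alleles))
  for (r in seq_len(nrow(df))) {
    fsp <- translateFsp(df[r, ], config)
    peps <- enumerateClassI(fsp, config)$peptide
    if (length(peps) == 0) next
    for (a in alleles) {
      calls <- predictBinding(peps, a, predictor, config)
      m[r, a] <- sum(calls$strong)
    }
  }
  m
}

#' Per-patient FSM immunogenicity profile
#'
#' Counts strong (peptide, allele) pairs for one locus against one patient's
#' HLA genotype: class I over all junction-spanning 9-mers and the patient's
#' distinct class I alleles, class II over 12- to 16-mers and distinct class
#' II alleles. Duplicate windows contribute once (unique-pair counting);
#' homozygous alleles count once.
#'
#' @param locus one row of \code{loci(catalog)}.
#' @param hla one row of an HLA genotype table (patient_id, class_i,
#'   class_ii with semicolon-separated alleles).
#' @param predictor an affinity predictor function.
#' @param config a \linkS4class{PipelineConfig}.
#' @return data.frame with one row: locus_id, patient_id, n_strong_i,
#'   n_strong_ii, fsp_len (length of flank + novel at the class I flank).
#' @export
immunogenicityProfile <- function(locus, hla, predictor,
                                  config = pipelineConfig()) {
  ci <- unique(.splitAlleles(hla$class_i))
  cii <- unique(.splitAlleles(hla$class_ii))
  fspI <- translateFsp(locus, config)
  pepsI <- enumerateClassI(fspI, config)$peptide
  nI <- if (length(pepsI) > 0 && length(ci) > 0) {
    sum(predictBinding(pepsI, ci, predictor, config)$strong)
  } else 0L
  nII <- 0L
  if (length(cii) > 0) {
    fspII <- translateFsp(locus, config, flank_aa = config@class_ii_flank_aa)
    pepsII <- enumerateClassII(fspII, config)$peptide
    if (length(pepsII) > 0) {
      nII <- sum(predictBinding(pepsII, cii, predictor, config)$strong)
    }
  }
  data.frame(locus_id = as.character(locus$locus_id),
             patient_id = as.character(hla$patient_id),
             n_strong_i = as.integer(nI), n_strong_ii = as.integer(nII),
             fsp_len = nchar(fspI@full), stringsAsFactors = FALSE)
}

#' Immunogenicity table for a whole catalog
#'
#' \code{\link{immunogenicityProfile}} applied to every catalog locus, with
#' the class I work shared through \code{\link{classIBinderCounts}}.
#'
#' @inheritParams immunogenicityProfile
#' @param catalog a \linkS4class{LocusCatalog}.
#' @param class_i_counts optional precomputed matrix from
#'   \code{\link{classIBinderCounts}} covering the patient's alleles.
#' @param include_class_ii compute class II counts (slower); default TRUE.
#' @return data.frame with one row per locus: locus_id, patient_id,
#'   n_strong_i, n_strong_ii, fsp_len.
#' @export
immunogenicityTable <- function(catalog, hla, predictor,
                                config = pipelineConfig(),
                                class_i_counts = NULL,
                                include_class_ii = TRUE) {
  df <- loci(catalog)
  ci <- unique(.splitAlleles(hla$class_i))
  cii <- unique(.splitAlleles(hla$class_ii))
  if (is.null(class_i_counts)) {
    class_i_counts <- classIBinderCounts(catalog, ci, predictor, config)
  }
  nI <- if (length(ci) > 0) {
    as.integer(rowSums(class_i_counts[df$locus_id, ci, drop = FALSE]))
  } else rep(0L, nrow(df))
  lens <- integer(nrow(df))
  nII <- rep(0L, nrow(df))
  for (r in seq_len(nrow(df))) {
    lens[r] <- nchar(translateFsp(df[r, ], config)@full)
    if (include_class_ii && length(cii) > 0) {
      fspII <- translateFsp(df[r, ], config,
                            flank_aa = config@class_ii_flank_aa)
      peps <- enumerateClassII(fspII, config)$peptide
      if (length(peps) > 0) {
        nII[r] <- sum(predictBinding(peps, cii, predictor, config)$strong)
      }
    }
  }
  data.frame(locus_id = df$locus_id,
             patient_id = as.character(hla$patient_id),
             n_strong_i = nI, n_strong_ii = nII, fsp_len = lens,
             stringsAsFactors = FALSE)
}

#' Write frameshift peptides as FASTA
#'
#' Headers follow \code{locus_id|gene|novel_len}.
#'
#' @param catalog a \linkS4class{LocusCatalog}.
#' @param path output file path.
#' @param config a \linkS4class{PipelineConfig}.
#' @return the path, invisibly.
#' @export
writeFspFasta <- function(catalog, path, config = pipelineConfig()) {
  df <- loci(catalog)
  lines <- character(0)
  for (r in seq_len(nrow(df))) {
    fsp <- translateFsp(df[r, ], config)
    lines <- c(lines,
               sprintf(">%s|%s|%d", df$locus_id[r], df$gene_symbol[r],
                       fsp@novel_len),
               fsp@full)
  }
  writeLines(lines, path)
  invisible(path)
}
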