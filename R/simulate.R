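# Seeded synthetic cohort generator. Every simulate* output is a pure
# function of (config, seed, arguments): per-object RNG streams are derived
# from the master seed and a context label, so regenerating any single
# object reproduces it byte-identically regardless of call order.

.GENE_POOL <- c("MSH3", "MSH6", "TTK", "FAHD2B", "TGFBR2", "ACVR2A", "ASTE1",
                "SLC35F5", "TFAM", "BAX", "CASP5", "RNF43", "SEC31A", "AIM2",
                "HPS1", "MBD4", "TCF7L2", "XYLT2", "CHEK1", "SRRT", "MYH11",
                "SLC22A9", "PRRT2", "SPINK5", "OR7E24", "LTN1", "KIAA2018",
                "CNOT1", "DOCK3", "UBR5")

.CLASS_I_POOL <- list(
  A = c("A*01:01", "A*02:01", "A*03:01", "A*11:01", "A*24:02"),
  B = c("B*07:02", "B*08:01", "B*35:01", "B*44:02"),
  C = c("C*04:01", "C*07:01", "C*07:02"))
.CLASS_II_POOL <- c("DRB1*03:01", "DRB1*04:01", "DRB1*07:01", "DRB1*15:01")

#' Create a synthetic-cohort configuration
#'
#' Constructor for \linkS4class{SimConfig}. Defaults emulate the study
#' conditions of a Lynch-syndrome MSI cohort: a 204-locus shared FSM catalog,
#' per-locus recurrence Beta(0.8, 2) giving roughly 57 FSMs per tumor,
#' negative-binomial depth around 80x, mutant VAF uniform on [0.15, 0.45],
#' sequencing-noise deletions at rate 0.005, a logistic retention model
#' (intercept 3, slope 2 per class-I strong binder) for sequential tumors,
#' a gain rate of 0.2 (about 30 gained FSMs per later tumor), and MSI
#' instability fractions 0.4 (MSI) / 0.05 (MSS) over 200 scanned loci.
#'
#' @param seed integer master seed (required).
#' @param n_patients number of patients (default 9, the paired-tumor study
#'   size).
#' @param catalog_size number of catalog loci (default 204).
#' @param repeat_len_range homopolymer length range (default c(6, 12)).
#' @param recurrence_alpha,recurrence_beta Beta prior on per-locus FSM
#'   probability, drawn once per locus per cohort.
#' @param depth_mean,depth_dispersion negative-binomial depth model.
#' @param true_vaf_range uniform range of the true mutant VAF.
#' @param loss_intercept,loss_slope logistic retention model parameters.
#' @param gain_rate per-locus FSM gain probability in the next tumor.
#' @param p_b2m_negative_second_tumor probability of B2M loss in the later
#'   tumor.
#' @param msi_unstable_frac_msi,msi_unstable_frac_mss per-locus instability
#'   rates.
#' @param n_msi_loci scanned microsatellite loci.
#' @param noise_vaf noise deletion rate at wild-type loci.
#' @param variant_table_spec named list of planted per-stage counts (see
#'   \code{\link{simulateVariantTable}}).
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed,
                      n_patients = 9L,
                      catalog_size = 204L,
                      repeat_len_range = c(6L, 12L),
                      recurrence_alpha = 0.8,
                      recurrence_beta = 2,
                      depth_mean = 80,
                      depth_dispersion = 8,
                      true_vaf_range = c(0.15, 0.45),
                      loss_intercept = 3,
                      loss_slope = 2,
                      gain_rate = 0.2,
                      p_b2m_negative_second_tumor = 0.2,
                      msi_unstable_frac_msi = 0.4,
                      msi_unstable_frac_mss = 0.05,
                      n_msi_loci = 200L,
                      noise_vaf = 0.005,
                      variant_table_spec = list()) {
  new("SimConfig", seed = as.integer(seed), n_patients = as.integer(n_patients),
      catalog_size = as.integer(catalog_size),
      repeat_len_range = as.integer(repeat_len_range),
      recurrence_alpha = recurrence_alpha, recurrence_beta = recurrence_beta,
      depth_mean = depth_mean, depth_dispersion = depth_dispersion,
      true_vaf_range = true_vaf_range, loss_intercept = loss_intercept,
      loss_slope = loss_slope, gain_rate = gain_rate,
      p_b2m_negative_second_tumor = p_b2m_negative_second_tumor,
      msi_unstable_frac_msi = msi_unstable_frac_msi,
      msi_unstable_frac_mss = msi_unstable_frac_mss,
      n_msi_loci = as.integer(n_msi_loci), noise_vaf = noise_vaf,
      variant_table_spec = variant_table_spec)
}

.NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# Build one locus: upstream in-frame non-stop codons, a maximal homopolymer
# run starting at a codon boundary, then a downstream region engineered so
# the -1 frame after the deletion reads `novelTarget` non-stop codons and
# then a stop (guaranteeing a finite frameshift peptide).
.buildLocusCds <- function(repeat_base, repeat_len, novelTarget) {
  k <- sample(8:15, 1)
  up <- sample(.NONSTOP_CODONS, k, replace = TRUE)
  lastOk <- .NONSTOP_CODONS[substr(.NONSTOP_CODONS, 3, 3) != repeat_base]
  if (substr(up[k], 3, 3) == repeat_base) up[k] <- sample(lastOk, 1)
  upstream <- paste(up, collapse = "")

  rPrime <- repeat_len - 1L
  q <- rPrime %% 3L
  bases <- c("A", "C", "G", "T")
  # straddle codon of the shifted frame: q run bases + (3-q) downstream bases
  straddle <- NULL
  for (try in 1:100) {
    headLen <- (3L - q) %% 3L
    if (headLen == 0L) headLen <- 3L  # q == 0: straddle entirely downstream
    head <- sample(bases, headLen, replace = TRUE)
    if (head[1] == repeat_base) next  # keep the run maximal
    cod <- paste0(strrep(repeat_base, if (q == 0L) 0L else q),
                  paste(head, collapse = ""))
    if (nchar(cod) != 3) next
    if (!cod %in% .stopCodons) { straddle <- head; break }
  }
  if (is.null(straddle)) {
    stop("locus generation failed: no viable junction codon", call. = FALSE)
  }
  mid <- if (novelTarget > 1) {
    paste(sample(.NONSTOP_CODONS, novelTarget - 1L, replace = TRUE),
          collapse = "")
  } else ""
  stopC <- sample(.stopCodons, 1)
  x <- paste0(paste(straddle, collapse = ""), mid, stopC)
  # pad so the wild-type CDS length is a multiple of 3
  pad <- (3L - (repeat_len + nchar(x)) %% 3L) %% 3L
  extra <- sample(0:2, 1) * 3L + pad
  if (extra > 0) x <- paste0(x, paste(sample(bases, extra, replace = TRUE),
                                      collapse = ""))
  list(cds = paste0(upstream, strrep(repeat_base, repeat_len), x),
       repeat_cds_index = nchar(upstream))
}

#' Simulate a catalog of coding mononucleotide-repeat loci
#'
#' Generates \code{catalog_size} loci satisfying all catalog invariants; each
#' CDS is constructed so that the shifted (-1) frame downstream of the
#' deletion reaches a stop codon, giving a finite frameshift peptide whose
#' novel length is drawn from a geometric-like distribution (mean about 18
#' residues, with mass at 1-2 residue peptides). Gene symbols are drawn from
#' a fixed plausible list including MSH3, MSH6, TTK and FAHD2B.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A validated \linkS4class{LocusCatalog}.
#' @export
simulateCatalog <- function(config) {
  .withSeed(.deriveSeed(config@seed, "catalog"), {
    n <- config@catalog_size
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      base <- sample(c("A", "C", "G", "T"), 1)
      rlen <- sample(seq(config@repeat_len_range[1],
                         config@repeat_len_range[2]), 1)
      novelTarget <- 1L + stats::rgeom(1, 0.055)
      built <- .buildLocusCds(base, rlen, novelTarget)
      rows[[i]] <- data.frame(
        locus_id = sprintf("FSM%04d", i),
        gene_symbol = sample(.GENE_POOL, 1),
        chrom = sample(c(as.character(1:22), "X"), 1),
        pos = sample.int(2e8, 1),
        repeat_base = base, repeat_len = rlen,
        cds_seq = built$cds, repeat_cds_index = built$repeat_cds_index,
        stringsAsFactors = FALSE)
    }
    new("LocusCatalog", loci = do.call(rbind, rows),
        name = sprintf("synthetic-%d", config@seed))
  })
}

#' Simulate patient HLA genotypes
#'
#' Draws two alleles per class I locus (A, B, C) and two class II alleles
#' from fixed pools (homozygosity possible); the small pools create the
#' allele sharing across patients that the recurrent-loss analysis needs.
#'
#' @param patient_ids character vector.
#' @param config a \linkS4class{SimConfig}.
#' @return HLA genotype data.frame (patient_id, class_i, class_ii).
#' @export
simulateHla <- function(patient_ids, config) {
  rows <- lapply(patient_ids, function(pid) {
    .withSeed(.deriveSeed(config@seed, paste0("hla:", pid)), {
      ci <- unlist(lapply(.CLASS_I_POOL, function(pool) {
        sample(pool, 2, replace = TRUE)
      }))
      cii <- sample(.CLASS_II_POOL, 2, replace = TRUE)
      data.frame(patient_id = pid, class_i = paste(ci, collapse = ";"),
                 class_ii = paste(cii, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
  })
  .validateHla(do.call(rbind, rows))
}

#' Per-locus FSM recurrence probabilities
#'
#' One Beta(recurrence_alpha, recurrence_beta) draw per locus per cohort;
#' sharing the draw across patients creates the locus-level recurrence
#' structure under which most FSMs recur across tumors.
#'
#' @param catalog a \linkS4class{LocusCatalog}.
#' @param config a \linkS4class{SimConfig}.
#' @return named numeric vector of per-locus FSM probabilities.
#' @export
drawLocusRecurrence <- function(catalog, config) {
  .withSeed(.deriveSeed(config@seed, "recurrence"), {
    stats::setNames(stats::rbeta(length(catalog), config@recurrence_alpha,
                                 config@recurrence_beta),
                    loci(catalog)$locus_id)
  })
}

.sampleEvidence <- function(sample_id, catalog, config, mutated) {
  ids <- loci(catalog)$locus_id
  n <- length(ids)
  depth <- stats::rnbinom(n, size = config@depth_dispersion,
                          mu = config@depth_mean)
  vaf <- ifelse(mutated,
                stats::runif(n, config@true_vaf_range[1],
                             config@true_vaf_range[2]),
                config@noise_vaf)
  mut <- stats::rbinom(n, depth, vaf)
  list(evidence = data.frame(sample_id = sample_id, locus_id = ids,
                             depth = as.integer(depth),
                             mut_reads = as.integer(mut),
                             stringsAsFactors = FALSE),
       true_vaf = stats::setNames(ifelse(mutated, vaf, NA_real_), ids))
}

#' Simulate the first tumor of a patient
#'
#' Each catalog locus carries an FSM with its cohort-level recurrence
#' probability; depth is negative binomial, mutant reads binomial at the true
#' VAF for mutated loci and at the noise rate for wild-type loci.
#'
#' @param sample_id sample identifier (also the RNG context label).
#' @param catalog a \linkS4class{LocusCatalog}.
#' @param config a \linkS4class{SimConfig}.
#' @param p_locus named per-locus FSM probabilities (defaults to
#'   \code{\link{drawLocusRecurrence}}).
#' @return list(evidence, truth) where truth carries the true FSM set and
#'   per-locus true VAFs.
#' @export
simulateFirstTumor <- function(sample_id, catalog, config,
                               p_locus = drawLocusRecurrence(catalog, config)) {
  .withSeed(.deriveSeed(config@seed, paste0("tumor1:", sample_id)), {
    ids <- loci(catalog)$locus_id
    mutated <- stats::runif(length(ids)) < p_locus[ids]
    sampled <- .sampleEvidence(sample_id, catalog, config, mutated)
    list(evidence = sampled$evidence,
         truth = list(sample_id = sample_id,
                      fsm_set = ids[mutated],
                      true_vaf = sampled$true_vaf))
  })
}

#' Simulate a subsequent tumor under the retention model
#'
#' An FSM present in the previous tumor is retained with probability
#' \code{plogis(loss_intercept - loss_slope * b)} where b is its class-I
#' strong-binder count for the patient; when the later tumor is B2M-negative
#' (antigen presentation lost), the slope is forced to 0 and retention is
#' immunogenicity-blind. FSMs absent before are gained independently with
#' probability \code{gain_rate}. Evidence is sampled as for the first tumor.
#'
#' @param prev_truth truth list of the previous tumor (from
#'   \code{\link{simulateFirstTumor}} or this function).
#' @param immunogenicity named numeric vector of per-locus class-I
#'   strong-binder counts for this patient (or a data.frame with locus_id
#'   and n_strong_i).
#' @param b2m_negative logical.
#' @param catalog a \linkS4class{LocusCatalog}.
#' @param config a \linkS4class{SimConfig}.
#' @param sample_id identifier of the new tumor.
#' @return list(evidence, truth); truth additionally records the retention
#'   probabilities and the gained set.
#' @export
simulateNextTumor <- function(prev_truth, immunogenicity, b2m_negative,
                              catalog, config, sample_id) {
  if (is.data.frame(immunogenicity)) {
    immunogenicity <- stats::setNames(immunogenicity$n_strong_i,
                                      immunogenicity$locus_id)
  }
  ids <- loci(catalog)$locus_id
  prev <- prev_truth$fsm_set
  if (!all(prev %in% ids)) {
    stop("previous truth refers to loci outside this catalog", call. = FALSE)
  }
  .withSeed(.deriveSeed(config@seed, paste0("tumorNext:", sample_id)), {
    slope <- if (b2m_negative) 0 else config@loss_slope
    b <- immunogenicity[prev]
    b[is.na(b)] <- 0
    pKeep <- stats::plogis(config@loss_intercept - slope * b)
    retained <- stats::runif(length(prev)) < pKeep
    absent <- setdiff(ids, prev)
    gained <- absent[stats::runif(length(absent)) < config@gain_rate]
    fsm <- c(prev[retained], gained)
    mutated <- ids %in% fsm
    sampled <- .sampleEvidence(sample_id, catalog, config, mutated)
    list(evidence = sampled$evidence,
         truth = list(sample_id = sample_id, fsm_set = ids[mutated],
                      true_vaf = sampled$true_vaf,
                      retained = stats::setNames(retained, prev),
                      retention_prob = stats::setNames(pKeep, prev),
                      gained = gained,
                      b2m_negative = b2m_negative))
  })
}

#' Simulate per-locus microsatellite instability calls
#'
#' Each scanned locus is unstable independently with probability
#' \code{msi_unstable_frac_msi} (MSI samples) or \code{msi_unstable_frac_mss}
#' (MSS samples).
#'
#' @param sample_id sample identifier.
#' @param is_msi logical.
#' @param config a \linkS4class{SimConfig}.
#' @return logical vector of length \code{n_msi_loci}.
#' @export
simulateMsiProfile <- function(sample_id, is_msi, config) {
  frac <- if (is_msi) config@msi_unstable_frac_msi else config@msi_unstable_frac_mss
  .withSeed(.deriveSeed(config@seed, paste0("msi:", sample_id)), {
    stats::runif(config@n_msi_loci) < frac
  })
}

.CLEAN_SYMBOLS <- setdiff(.GENE_POOL, character(0))
.BAD_SYMBOLS <- c("C9orf72", "ENSG00000123456", "ENST00000335137",
                  "ENSMUSG00000017146", "Unknown")

.plantRecord <- function(stage, design, chrom_pool) {
  # baseline record passing every stage under the given AF design
  if (design == "zygosity") {
    depth <- 100L; alt <- 12L
  } else {
    depth <- 100L; alt <- 40L
  }
  rec <- list(chrom = sample(chrom_pool, 1), pos = sample.int(2e8, 1),
              ref = sample(c("A", "C", "G", "T"), 1), alt = "-",
              qc_pass = TRUE, depth = depth, ref_reads = depth - alt,
              alt_reads = alt, af = alt / depth,
              gnomad_global_af = sample(c(NA, 1e-4, 5e-3), 1),
              gnomad_fin_af = sample(c(NA, 1e-4), 1),
              gene_symbol = sample(.CLEAN_SYMBOLS, 1), is_coding = TRUE,
              lof_predicted = sample(c(TRUE, FALSE), 1),
              clinvar_class = sample(c("P", "LP"), 1))
  if (!rec$lof_predicted && stage != "not_pathogenic") rec$clinvar_class <- "P"
  switch(stage,
    pass = rec,
    qc = { rec$qc_pass <- FALSE; rec },
    depth = { rec$depth <- 10L
              rec$alt_reads <- as.integer(round(rec$af * 10))
              rec$ref_reads <- rec$depth - rec$alt_reads
              rec$af <- rec$alt_reads / rec$depth; rec },
    allele_reads = { rec$alt_reads <- 5L; rec$ref_reads <- 95L
                     rec$af <- 0.05; rec },
    symbol = { rec$gene_symbol <- sample(.BAD_SYMBOLS, 1); rec },
    chrom = { rec$chrom <- sample(c("Y", "MT"), 1); rec },
    popaf = { rec$gnomad_global_af <- 0.05; rec$gnomad_fin_af <- 0.02; rec },
    abs_af = { rec$depth <- 300L; rec$alt_reads <- 9L; rec$ref_reads <- 291L
               rec$af <- 0.03; rec },
    zygosity = { rec$depth <- 100L; rec$alt_reads <- 90L; rec$ref_reads <- 6L
                 rec$af <- 0.90; rec },
    mode_norm = { rec$depth <- 100L; rec$alt_reads <- 6L; rec$ref_reads <- 94L
                  rec$af <- 0.06; rec },
    noncoding = { rec$is_coding <- FALSE; rec },
    not_pathogenic = { rec$clinvar_class <- sample(c("VUS", "LB", "B", "none"), 1)
                       rec$lof_predicted <- FALSE; rec },
    stop("unknown stage: ", stage, call. = FALSE))
}

#' Simulate a planted variant table
#'
#' Emits exactly the requested composition: for every cascade stage, the
#' given number of records whose first failure is that stage (each passing
#' all earlier stages), plus full passers. Stage names: pass, qc, depth,
#' allele_reads, symbol, chrom, popaf, abs_af, zygosity, mode_norm,
#' noncoding, not_pathogenic.
#'
#' Because the zygosity-ratio and mode-normalized-AF stages share a single
#' normalizer pool (survivors of stages 1-7), some compositions are
#' unsatisfiable and raise a generation error: a zygosity failure needs a
#' low-AF pool mean while a mode failure needs a high AF mode, so the two
#' cannot be planted in one table; zygosity failures also must not outnumber
#' one twelfth of the baseline pool, and mode failures must not outnumber the
#' baseline pool. popaf failures require a tumor-only sample.
#'
#' @param sample one row of a samples table (needs sample_id and
#'   matched_normal).
#' @param spec named list/vector of non-negative counts per stage label.
#' @param config a \linkS4class{SimConfig}.
#' @return list(variants, truth) where truth$stage is the planted first-fail
#'   label per record ("pass" for passers), aligned with the rows.
#' @export
simulateVariantTable <- function(sample, spec, config) {
  labels <- c("pass", .CASCADE_STAGES)
  bad <- setdiff(names(spec), labels)
  if (length(bad) > 0) stop("unknown stage label(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  cnt <- stats::setNames(integer(length(labels)), labels)
  for (nm in names(spec)) cnt[nm] <- as.integer(spec[[nm]])
  if (any(cnt < 0)) stop("planted counts must be non-negative", call. = FALSE)
  if (cnt["popaf"] > 0 && isTRUE(sample$matched_normal)) {
    stop("popaf failures require a tumor-only sample (population filter is ",
         "skipped for matched-normal samples)", call. = FALSE)
  }
  if (cnt["zygosity"] > 0 && cnt["mode_norm"] > 0) {
    stop("a single table cannot plant both zygosity and mode-normalized ",
         "failures: the shared normalizer pool cannot satisfy both",
         call. = FALSE)
  }
  baseline <- cnt["pass"] + cnt["noncoding"] + cnt["not_pathogenic"]
  if (cnt["zygosity"] > 0 && cnt["zygosity"] * 12 >= baseline) {
    stop("too many zygosity failures for the baseline pool (need > 12x)",
         call. = FALSE)
  }
  if (cnt["mode_norm"] > 0 && cnt["mode_norm"] > baseline) {
    stop("mode-normalized failures cannot outnumber the baseline pool",
         call. = FALSE)
  }
  design <- if (cnt["zygosity"] > 0) "zygosity" else "mode"
  .withSeed(.deriveSeed(config@seed,
                        paste0("variants:", sample$sample_id)), {
    chrom_pool <- c(as.character(1:22), "X")
    stageOf <- rep(labels, cnt)
    rows <- lapply(stageOf, .plantRecord, design = design,
                   chrom_pool = chrom_pool)
    ord <- sample.int(length(rows))
    df <- do.call(rbind, lapply(rows[ord], as.data.frame,
                                stringsAsFactors = FALSE))
    truth <- stageOf[ord]
    if (length(rows) == 0) {
      df <- .emptyVariantTable()
      truth <- character(0)
    }
    rownames(df) <- NULL
    list(variants = df, truth = list(sample_id = sample$sample_id,
                                     stage = truth))
  })
}

#' Simulate a cohort of sequential tumor pairs
#'
#' The full generative chain for the immunoediting analysis: a catalog,
#' cohort-level locus recurrence, patient HLA genotypes, a first tumor per
#' patient, per-patient class-I strong-binder counts through the epitope
#' module (the generator and the analyzer share one immunogenicity
#' definition), and a second tumor under the retention model.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param predictor affinity predictor; defaults to the synthetic oracle
#'   seeded with the config seed.
#' @param b2m_later "random" draws B2M loss with
#'   \code{p_b2m_negative_second_tumor}; "positive" and "negative" force the
#'   later tumors' B2M status.
#' @param pipe_config a \linkS4class{PipelineConfig} for the epitope module.
#' @return list with catalog, p_locus, hla, samples (metadata for both
#'   tumors of every patient), evidence (all tumors), truths (named by
#'   sample_id), binder_counts (loci x alleles matrix) and patient_binders
#'   (per-patient named vectors used by the retention model).
#' @export
simulateCohort <- function(config, predictor = NULL,
                           b2m_later = c("random", "positive", "negative"),
                           pipe_config = pipelineConfig()) {
  b2m_later <- match.arg(b2m_later)
  if (is.null(predictor)) predictor <- syntheticAffinityOracle(config@seed)
  catalog <- simulateCatalog(config)
  p_locus <- drawLocusRecurrence(catalog, config)
  pids <- sprintf("Pt%02d", seq_len(config@n_patients))
  hla <- simulateHla(pids, config)
  allAlleles <- unique(unlist(lapply(hla$class_i, .splitAlleles)))
  counts <- classIBinderCounts(catalog, allAlleles, predictor, pipe_config)

  samples <- list(); evidence <- list(); truths <- list(); pb <- list()
  for (i in seq_along(pids)) {
    pid <- pids[i]
    s1 <- paste0(pid, "_T1"); s2 <- paste0(pid, "_T2")
    first <- simulateFirstTumor(s1, catalog, config, p_locus)
    ci <- unique(.splitAlleles(hla$class_i[hla$patient_id == pid]))
    b <- stats::setNames(as.integer(rowSums(counts[, ci, drop = FALSE])),
                         rownames(counts))
    pb[[pid]] <- b
    b2mNeg <- switch(b2m_later,
      random = .withSeed(.deriveSeed(config@seed, paste0("b2m:", pid)),
                         stats::runif(1) < config@p_b2m_negative_second_tumor),
      positive = FALSE, negative = TRUE)
    second <- simulateNextTumor(first$truth, b, b2mNeg, catalog, config, s2)
    evidence[[s1]] <- first$evidence
    evidence[[s2]] <- second$evidence
    truths[[s1]] <- first$truth
    truths[[s2]] <- second$truth
    samples[[pid]] <- data.frame(
      sample_id = c(s1, s2), patient_id = pid, tumor_type = "CRC",
      chronology_index = 1:2, diagnosis_age = NA_real_,
      stage = "unknown", matched_normal = FALSE,
      b2m_ihc = c("positive", if (b2mNeg) "negative" else "positive"),
      mmr_germline = "MLH1", cd8_core_density = NA_real_,
      cd8_margin_density = NA_real_, stringsAsFactors = FALSE)
  }
  list(catalog = catalog, p_locus = p_locus, hla = hla,
       samples = do.call(rbind, c(samples, make.row.names = FALSE)),
       evidence = do.call(rbind, c(evidence, make.row.names = FALSE)),
       truths = truths, binder_counts = counts, patient_binders = pb)
}

#' Write a complete synthetic fixture set
#'
#' Writes catalog, evidence, samples, HLA, one planted variant table per
#' sample (when \code{variant_table_spec} is non-empty) and the generator
#' truth (JSON) into a directory.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param out_dir output directory (created if needed).
#' @param ... passed to \code{\link{simulateCohort}}.
#' @return invisible list of written paths.
#' @export
simulateFixtureSet <- function(config, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  co <- simulateCohort(config, ...)
  paths <- list(
    catalog = file.path(out_dir, "catalog.tsv"),
    evidence = file.path(out_dir, "evidence.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    hla = file.path(out_dir, "hla.tsv"),
    truth = file.path(out_dir, "truth.json"))
  writeLocusCatalog(co$catalog, paths$catalog)
  writeEvidence(co$evidence, paths$evidence)
  writeSamples(co$samples, paths$samples)
  writeHla(co$hla, paths$hla)
  if (length(config@variant_table_spec) > 0) {
    for (r in seq_len(nrow(co$samples))) {
      sm <- co$samples[r, ]
      vt <- simulateVariantTable(sm, config@variant_table_spec, config)
      p <- file.path(out_dir, sprintf("variants_%s.tsv", sm$sample_id))
      writeVariantTable(vt$variants, p)
      paths[[paste0("variants_", sm$sample_id)]] <- p
    }
  }
  truthOut <- lapply(co$truths, function(t) {
    list(sample_id = t$sample_id, fsm_set = t$fsm_set,
         gained = t$gained, b2m_negative = t$b2m_negative)
  })
  jsonlite::write_json(truthOut, paths$truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
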