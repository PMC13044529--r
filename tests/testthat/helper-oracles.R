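# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive results through different primitives than the
# package implementation.

# The worked toy locus: M P K K L R *; A-run of 6 at CDS index 6; the
# deletion frameshift yields flank "MPK" and novel "N".
toyLocus <- function() {
  list(locus_id = "toy", gene_symbol = "TOY", chrom = "1", pos = 1000L,
       repeat_base = "A", repeat_len = 6L,
       cds_seq = "ATGCCTAAAAAACTGAGGTAA", repeat_cds_index = 6L)
}

# Brute-force frameshift translation: deletes the FIRST base of the run
# (homopolymer position invariance) and translates via Biostrings.
bruteFsp <- function(locus, flank_aa = 8L) {
  wt <- locus$cds_seq
  i <- locus$repeat_cds_index + 1L
  mut <- paste0(substr(wt, 1, i - 1), substr(wt, i + 1, nchar(wt)))
  mutTrim <- substr(mut, 1, 3L * (nchar(mut) %/% 3L))
  aaOf <- function(s) {
    if (nchar(s) == 0) return(character(0))
    strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(s), no.init.codon = TRUE)), "")[[1]]
  }
  wtAA <- aaOf(substr(wt, 1, 3L * (nchar(wt) %/% 3L)))
  mutAA <- aaOf(mutTrim)
  nm <- length(mutAA)
  codon <- function(s, idx) substr(s, 3 * idx - 2, 3 * idx)
  j <- nm + 1L
  for (cix in seq_len(nm)) {
    if (codon(mutTrim, cix) != codon(wt, cix)) { j <- cix; break }
  }
  stops <- which(mutAA == "*")
  if (length(stops) > 0 && stops[1] < j) {
    novel <- ""
    j <- stops[1]
  } else if (j > nm) {
    novel <- ""
  } else {
    lastNovel <- if (length(stops[stops >= j]) > 0) stops[stops >= j][1] - 1L else nm
    novel <- if (lastNovel >= j) paste(mutAA[j:lastNovel], collapse = "") else ""
  }
  flank <- if (j > 1) {
    paste(wtAA[max(1L, j - flank_aa):(j - 1L)], collapse = "")
  } else ""
  list(flank = flank, novel = novel, full = paste0(flank, novel))
}

# Direct window enumeration: every start position checked against the novel
# residue positions.
bruteWindows <- function(full, flank_len, k) {
  L <- nchar(full)
  if (L < k) return(character(0))
  res <- character(0)
  novelPos <- if (flank_len < L) seq(flank_len + 1L, L) else integer(0)
  for (s in seq_len(L - k + 1L)) {
    if (any(seq(s, s + k - 1L) %in% novelPos)) {
      res <- c(res, substr(full, s, s + k - 1L))
    }
  }
  res
}

# Exhaustive conditional Fisher p for a 2x2 table: sum of hypergeometric
# point probabilities not exceeding the observed one (same rel. tolerance as
# stats::fisher.test).
bruteFisherP <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, r1, n - r1, c1)
  pobs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Random feasible planted-table spec (the zygosity and mode stages cannot
# coexist; zygosity failures need a 12x baseline pool).
randomVariantSpec <- function() {
  spec <- list(pass = sample(5:20, 1))
  for (st in c("qc", "depth", "allele_reads", "symbol", "chrom", "popaf",
               "abs_af", "noncoding", "not_pathogenic")) {
    spec[[st]] <- sample(0:3, 1)
  }
  if (stats::runif(1) < 0.5) {
    spec$zygosity <- sample(0:1, 1)
    baseline <- spec$pass + spec$noncoding + spec$not_pathogenic
    if (spec$zygosity * 12 >= baseline) spec$pass <- spec$zygosity * 12 + 1
  } else {
    spec$mode_norm <- sample(0:3, 1)
    baseline <- spec$pass + spec$noncoding + spec$not_pathogenic
    if (spec$mode_norm > baseline) spec$mode_norm <- baseline
  }
  spec
}

tumorOnlySample <- function(id = "S1") {
  data.frame(sample_id = id, matched_normal = FALSE,
             stringsAsFactors = FALSE)
}

# A minimal fully-passing variant record for cascade edge tests.
passingVariant <- function(...) {
  rec <- data.frame(chrom = "1", pos = 1000L, ref = "A", alt = "-",
                    qc_pass = TRUE, depth = 100L, ref_reads = 60L,
                    alt_reads = 40L, af = 0.40, gnomad_global_af = NA_real_,
                    gnomad_fin_af = NA_real_, gene_symbol = "MSH3",
                    is_coding = TRUE, lof_predicted = TRUE,
                    clinvar_class = "P", stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

baseSamplesFixture <- function() {
  data.frame(
    sample_id = c("S1", "S2", "S3"),
    patient_id = c("P1", "P1", "P2"),
    tumor_type = c("CRC", "CRC", "UC"),
    chronology_index = c(1L, 2L, 1L),
    diagnosis_age = c(45, 52, NA),
    stage = c("I", "II", "MI"),
    matched_normal = c(TRUE, FALSE, TRUE),
    b2m_ihc = c("positive", "negative", "unknown"),
    mmr_germline = c("MLH1", "MLH1", "MSH2"),
    cd8_core_density = c(120.5, NA, 80),
    cd8_margin_density = c(NA, NA, 60),
    stringsAsFactors = FALSE)
}
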