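test_that("the worked toy locus translates to flank MPK, novel N", {
  fsp <- translateFsp(toyLocus())
  expect_equal(fsp@flank, "MPK")
  expect_equal(fsp@novel, "N")
  expect_equal(fsp@full, "MPKN")
  expect_equal(fsp@novel_len, 1L)
  expect_true(fsp@terminated)
})

test_that("a frameshift opening on a stop codon yields an empty novel", {
  # ATG CCT AAAAAAA TGA CA: deleting one A of the 7-run shifts TGA into frame
  loc <- list(locus_id = "stopjx", cds_seq = "ATGCCTAAAAAAATGACA",
              repeat_cds_index = 6L, repeat_len = 7L)
  fsp <- translateFsp(loc)
  expect_equal(fsp@novel, "")
  expect_equal(fsp@full, fsp@flank)
  expect_true(fsp@terminated)
})

test_that("translation agrees with the independent re-translation oracle", {
  catal <- simulateCatalog(simConfig(seed = 91, catalog_size = 100))
  df <- loci(catal)
  for (r in seq_len(nrow(df))) {
    got <- translateFsp(df[r, ])
    want <- bruteFsp(df[r, ])
    expect_equal(got@flank, want$flank, label = df$locus_id[r])
    expect_equal(got@novel, want$novel, label = df$locus_id[r])
    expect_equal(got@full, want$full, label = df$locus_id[r])
  }
})

test_that("deleting any base of the homopolymer yields the same mutant CDS", {
  df <- loci(simulateCatalog(simConfig(seed = 17, catalog_size = 10)))
  for (r in seq_len(nrow(df))) {
    lc <- df[r, ]
    muts <- vapply(seq_len(lc$repeat_len), function(o) {
      i <- lc$repeat_cds_index + o  # 1-based position of the o-th run base
      paste0(substr(lc$cds_seq, 1, i - 1),
             substr(lc$cds_seq, i + 1, nchar(lc$cds_seq)))
    }, character(1))
    expect_length(unique(muts), 1)
  }
})

test_that("wild-type and mutant translations agree before the junction", {
  df <- loci(simulateCatalog(simConfig(seed = 29, catalog_size = 20)))
  for (r in seq_len(nrow(df))) {
    lc <- df[r, ]
    fsp <- translateFsp(lc, flank_aa = 10000L)
    # with an unbounded flank, flank is exactly the wild-type prefix before
    # the junction codon
    wtAA <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(lc$cds_seq), no.init.codon = TRUE)), "")[[1]]
    expect_identical(substr(paste(wtAA, collapse = ""), 1, nchar(fsp@flank)),
                     fsp@flank, info = lc$locus_id)
  }
})

test_that("window enumeration matches combinatorial expectations", {
  cfg <- pipelineConfig()
  mk <- function(flank, novel) {
    new("FrameshiftPeptide", locus_id = "t", flank = flank, novel = novel,
        full = paste0(flank, novel), novel_len = nchar(novel),
        terminated = TRUE)
  }
  # one novel residue behind an 8-residue flank: exactly one 9-mer
  one <- enumerateClassI(mk("MAGICFLK", "N"), cfg)
  expect_equal(nrow(one), 1)
  expect_equal(one$peptide, "MAGICFLKN")
  # ten novel residues: ten 9-mer windows
  ten <- enumerateClassI(mk("MAGICFLK", "NPQRSTVWYA"), cfg)
  expect_equal(sum(ten$multiplicity), 10)
  # full shorter than the window: nothing
  expect_equal(nrow(enumerateClassI(mk("MAGICFL", "N"), cfg)), 0)
})

test_that("enumeration equals direct window enumeration with multiplicity", {
  set.seed(64)
  cfg <- pipelineConfig()
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (r in 1:40) {
    fl <- paste(sample(aas, sample(0:15, 1), replace = TRUE), collapse = "")
    nv <- paste(sample(aas, sample(0:25, 1), replace = TRUE), collapse = "")
    fsp <- new("FrameshiftPeptide", locus_id = "t", flank = fl, novel = nv,
               full = paste0(fl, nv), novel_len = nchar(nv),
               terminated = TRUE)
    for (k in c(9L, 12L, 16L)) {
      want <- bruteWindows(fsp@full, nchar(fl), k)
      got <- if (k == 9) enumerateClassI(fsp, cfg) else {
        e <- enumerateClassII(fsp, cfg); e[e$length == k, , drop = FALSE]
      }
      expect_equal(sum(got$multiplicity), length(want))
      expect_setequal(got$peptide, unique(want))
    }
  }
})

test_that("binding calls apply the strict 500 nM boundary", {
  fixed <- function(p, a) if (p == "AAAAAAAAA") 499.999 else 500
  calls <- predictBinding(c("AAAAAAAAA", "CCCCCCCCC"), "A*02:01", fixed)
  expect_identical(calls$strong, c(TRUE, FALSE))
  expect_equal(nrow(predictBinding(c("AAAA"), character(0), fixed)), 0)
  expect_error(predictBinding("AAAA", "A*02:01", function(p, a) -1),
               "non-positive")
})

test_that("the synthetic oracle is deterministic with plantable motifs", {
  pred <- syntheticAffinityOracle(5)
  expect_identical(pred("MAGICPEPK", "A*02:01"), pred("MAGICPEPK", "A*02:01"))
  motif <- oracleMotif("A*02:01", 5)
  expect_equal(nchar(motif), 3)
  carrier <- paste0("MAG", motif, "PKL")
  expect_lt(pred(carrier, "A*02:01"), 400)
  # a different seed gives a different predictor
  pred2 <- syntheticAffinityOracle(6)
  expect_false(isTRUE(all.equal(pred("MAGICPEPK", "A*02:01"),
                                pred2("MAGICPEPK", "A*02:01"))))
})

test_that("motif-free oracle IC50s are log-uniform on [1, 50000)", {
  pred <- syntheticAffinityOracle(9)
  allele <- "B*07:02"
  motif <- oracleMotif(allele, 9)
  set.seed(12)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  peps <- unique(vapply(1:11000, function(i) {
    paste(sample(aas, 9, replace = TRUE), collapse = "")
  }, character(1)))
  peps <- peps[!grepl(motif, peps, fixed = TRUE)][1:10000]
  ic <- vapply(peps, function(p) pred(p, allele), numeric(1))
  expect_true(all(ic >= 1 & ic < 50000))
  pStrong <- log(500) / log(50000)
  frac <- mean(ic < 500)
  expect_lt(abs(frac - pStrong), 3 * sqrt(pStrong * (1 - pStrong) / 10000))
})

test_that("immunogenicity profiles count unique strong pairs", {
  catal <- simulateCatalog(simConfig(seed = 33, catalog_size = 6))
  df <- loci(catal)
  pred <- syntheticAffinityOracle(33)
  cfg <- pipelineConfig()
  hla <- data.frame(patient_id = "P1",
                    class_i = "A*02:01;A*03:01;B*07:02",
                    class_ii = "DRB1*04:01", stringsAsFactors = FALSE)
  for (r in seq_len(nrow(df))) {
    prof <- immunogenicityProfile(df[r, ], hla, pred, cfg)
    # brute-force double loop over windows x alleles
    fspI <- translateFsp(df[r, ], cfg)
    pepsI <- unique(bruteWindows(fspI@full, nchar(fspI@flank), 9L))
    wantI <- 0L
    for (p in pepsI) for (a in c("A*02:01", "A*03:01", "B*07:02")) {
      if (pred(p, a) < 500) wantI <- wantI + 1L
    }
    expect_equal(prof$n_strong_i, wantI, info = df$locus_id[r])
    fspII <- translateFsp(df[r, ], cfg, flank_aa = 15L)
    pepsII <- unique(unlist(lapply(12:16, function(k) {
      bruteWindows(fspII@full, nchar(fspII@flank), k)
    })))
    wantII <- sum(vapply(pepsII, function(p) pred(p, "DRB1*04:01") < 500,
                         logical(1)))
    expect_equal(prof$n_strong_ii, wantII, info = df$locus_id[r])
  }
  # empty class II genotype and monotonicity in alleles
  noII <- hla; noII$class_ii <- ""
  p0 <- immunogenicityProfile(df[1, ], noII, pred, cfg)
  expect_equal(p0$n_strong_ii, 0L)
  less <- hla; less$class_i <- "A*02:01"
  expect_lte(immunogenicityProfile(df[1, ], less, pred, cfg)$n_strong_i,
             immunogenicityProfile(df[1, ], hla, pred, cfg)$n_strong_i)
})

test_that("an FSP without novel residues yields no epitopes", {
  loc <- list(locus_id = "stopjx", cds_seq = "ATGCCTAAAAAAATGACA",
              repeat_cds_index = 6L, repeat_len = 7L)
  hla <- data.frame(patient_id = "P1", class_i = "A*02:01",
                    class_ii = "DRB1*04:01", stringsAsFactors = FALSE)
  prof <- immunogenicityProfile(loc, hla, syntheticAffinityOracle(1))
  expect_equal(prof$n_strong_i, 0L)
  expect_equal(prof$n_strong_ii, 0L)
})
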