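test_that("catalog generation is deterministic and validator-consistent", {
  cfg <- simConfig(seed = 7, catalog_size = 1)
  expect_identical(loci(simulateCatalog(cfg)), loci(simulateCatalog(cfg)))

  big <- simulateCatalog(simConfig(seed = 42, catalog_size = 60))
  expect_true(validObject(big))
  # wild-type in-frame translation has no stop strictly before the repeat
  for (r in seq_len(length(big))) {
    lc <- loci(big)[r, ]
    upCodons <- substring(lc$cds_seq,
                          seq(1, lc$repeat_cds_index - 2, by = 3),
                          seq(3, lc$repeat_cds_index, by = 3))
    expect_false(any(upCodons %in% c("TAA", "TAG", "TGA")), label = lc$locus_id)
  }
  # round-trip through the validating reader
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLocusCatalog(big, p)
  expect_identical(loci(readLocusCatalog(p)), loci(big))
})

test_that("first-tumor evidence follows the binomial read model", {
  cfg <- simConfig(seed = 11, catalog_size = 500,
                   true_vaf_range = c(0.4, 0.4), depth_mean = 500,
                   depth_dispersion = 50,
                   recurrence_alpha = 1e6, recurrence_beta = 1)
  catal <- simulateCatalog(cfg)
  t1 <- simulateFirstTumor("S1", catal, cfg)
  # recurrence Beta(1e6, 1) ~ 1: every locus mutated in truth
  expect_equal(length(t1$truth$fsm_set), 500)
  vafs <- t1$evidence$mut_reads / t1$evidence$depth
  se <- sqrt(0.4 * 0.6 / mean(t1$evidence$depth)) / sqrt(500)
  expect_lt(abs(mean(vafs) - 0.4), 3 * se)
  # determinism under a fixed seed
  t1b <- simulateFirstTumor("S1", catal, cfg)
  expect_identical(t1b$evidence, t1$evidence)
})

test_that("retention model hits its logistic limit cases", {
  cfg0 <- simConfig(seed = 23, catalog_size = 450,
                    recurrence_alpha = 1e6, recurrence_beta = 1,
                    gain_rate = 0, loss_intercept = 50, loss_slope = 0)
  catal <- simulateCatalog(cfg0)
  t1 <- simulateFirstTumor("S1", catal, cfg0)
  b <- stats::setNames(rep(5, length(catal)), loci(catal)$locus_id)
  # alpha large, beta 0, gain 0: the next truth set equals the previous
  t2 <- simulateNextTumor(t1$truth, b, FALSE, catal, cfg0, "S2")
  expect_setequal(t2$truth$fsm_set, t1$truth$fsm_set)

  # alpha = 0, beta = 0: empirical retention about 1/2
  cfgH <- simConfig(seed = 23, catalog_size = 450,
                    recurrence_alpha = 1e6, recurrence_beta = 1,
                    gain_rate = 0, loss_intercept = 0, loss_slope = 0)
  t2h <- simulateNextTumor(t1$truth, b, FALSE, catal, cfgH, "S2h")
  frac <- mean(t2h$truth$retained)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 450))
})

test_that("with positive slope, lost FSMs carry more binders than kept", {
  lostB <- numeric(0); keptB <- numeric(0)
  for (r in 1:20) {
    cfg <- simConfig(seed = 1000 + r, catalog_size = 100,
                     recurrence_alpha = 1e6, recurrence_beta = 1,
                     gain_rate = 0, loss_intercept = 1, loss_slope = 0.5)
    catal <- simulateCatalog(cfg)
    t1 <- simulateFirstTumor("S1", catal, cfg)
    b <- stats::setNames(stats::rpois(length(catal), 3),
                         loci(catal)$locus_id)
    t2 <- simulateNextTumor(t1$truth, b, FALSE, catal, cfg, "S2")
    ret <- t2$truth$retained
    lostB <- c(lostB, b[names(ret)[!ret]])
    keptB <- c(keptB, b[names(ret)[ret]])
  }
  expect_gt(mean(lostB), mean(keptB))
})

test_that("B2M-negative later tumors ignore immunogenicity", {
  cfg <- simConfig(seed = 31, catalog_size = 300,
                   recurrence_alpha = 1e6, recurrence_beta = 1,
                   gain_rate = 0, loss_intercept = 0, loss_slope = 10)
  catal <- simulateCatalog(cfg)
  t1 <- simulateFirstTumor("S1", catal, cfg)
  b <- stats::setNames(rep(100, length(catal)), loci(catal)$locus_id)
  # slope 10 with b = 100 would lose everything; B2M loss forces slope to 0
  t2 <- simulateNextTumor(t1$truth, b, TRUE, catal, cfg, "S2")
  expect_lt(abs(mean(t2$truth$retained) - 0.5), 3 * sqrt(0.25 / 300))
  expect_true(all(t2$truth$retention_prob == 0.5))
})

test_that("planted variant tables have exactly the requested composition", {
  cfg <- simConfig(seed = 13)
  vt <- simulateVariantTable(tumorOnlySample(),
                             list(pass = 5, depth = 2), cfg)
  expect_equal(nrow(vt$variants), 7)
  expect_equal(sum(vt$variants$depth < 20), 2)
  expect_true(all(vt$variants$depth[vt$truth$stage == "pass"] >= 20))

  empty <- simulateVariantTable(tumorOnlySample(), list(), cfg)
  expect_equal(nrow(empty$variants), 0)
  expect_length(empty$truth$stage, 0)
})

test_that("unsatisfiable planted compositions raise generation errors", {
  cfg <- simConfig(seed = 13)
  expect_error(simulateVariantTable(tumorOnlySample(),
                                    list(pass = 30, zygosity = 1,
                                         mode_norm = 1), cfg),
               "cannot plant both")
  matched <- data.frame(sample_id = "S1", matched_normal = TRUE)
  expect_error(simulateVariantTable(matched, list(pass = 5, popaf = 1), cfg),
               "tumor-only")
  expect_error(simulateVariantTable(tumorOnlySample(),
                                    list(pass = 5, zygosity = 2), cfg),
               "zygosity")
})

test_that("cascade audit recovers planted truth on random specs", {
  set.seed(202)
  cfg <- simConfig(seed = 55)
  for (r in 1:10) {
    spec <- randomVariantSpec()
    sm <- tumorOnlySample(sprintf("S%02d", r))
    vt <- simulateVariantTable(sm, spec, cfg)
    fr <- applyFilterCascade(vt$variants, sm)
    expect_identical(auditLabels(fr), vt$truth$stage)
    expect_equal(nrow(keptVariants(fr)), spec$pass)
  }
})

test_that("MSI profile simulation hits its limits and is deterministic", {
  cfg1 <- simConfig(seed = 9, msi_unstable_frac_msi = 1)
  expect_true(all(simulateMsiProfile("S1", TRUE, cfg1)))
  cfg <- simConfig(seed = 9)
  a <- simulateMsiProfile("S2", TRUE, cfg)
  expect_identical(a, simulateMsiProfile("S2", TRUE, cfg))
  expect_length(a, cfg@n_msi_loci)
})

test_that("cohort simulation is deterministic and validator-consistent", {
  cfg <- simConfig(seed = 19, catalog_size = 15, n_patients = 2)
  co1 <- simulateCohort(cfg)
  co2 <- simulateCohort(cfg)
  expect_identical(co1$evidence, co2$evidence)
  expect_identical(co1$samples, co2$samples)
  expect_identical(co1$binder_counts, co2$binder_counts)
  expect_silent(validateEvidence(co1$evidence))
  # fixture set writes a complete, re-readable directory
  d <- withr::local_tempdir()
  simulateFixtureSet(cfg, d)
  expect_identical(loci(readLocusCatalog(file.path(d, "catalog.tsv"))),
                   loci(co1$catalog))
  expect_identical(readEvidence(file.path(d, "evidence.tsv")), co1$evidence)
  expect_identical(readSamples(file.path(d, "samples.tsv")), co1$samples)
  expect_identical(readHla(file.path(d, "hla.tsv")), co1$hla)
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$Pt01_T1$fsm_set, co1$truths$Pt01_T1$fsm_set)
})
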