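test_that("cascade edge cases: empty input, coverage, population filter", {
  sm <- tumorOnlySample()
  empty <- applyFilterCascade(passingVariant()[0, ], sm)
  expect_equal(nrow(keptVariants(empty)), 0)
  expect_true(all(stageCounts(empty) == 0))

  # depth 19 fails the 20x stage
  r <- applyFilterCascade(passingVariant(depth = 19L, ref_reads = 11L,
                                         alt_reads = 8L, af = 8 / 19), sm)
  expect_identical(auditLabels(r), "depth")

  # a common variant survives in a matched-normal sample ...
  common <- passingVariant(gnomad_global_af = 0.5, gnomad_fin_af = 0.5)
  matched <- data.frame(sample_id = "S1", matched_normal = TRUE)
  expect_identical(auditLabels(applyFilterCascade(common, matched)), "pass")
  # ... but is removed from a tumor-only sample
  expect_identical(auditLabels(applyFilterCascade(common, sm)), "popaf")
  # exceeding the cutoff in only one population is not enough
  oneSided <- passingVariant(gnomad_global_af = 0.5, gnomad_fin_af = 0.002)
  expect_identical(auditLabels(applyFilterCascade(oneSided, sm)), "pass")
})

test_that("AF mean and histogram mode follow the documented conventions", {
  expect_equal(sampleAfMean(c(0.5)), 0.5)
  expect_equal(sampleAfMode(c(0.5)), 0.525)      # midpoint of [0.50, 0.55)
  expect_equal(sampleAfMode(c(0.10, 0.10, 0.10, 0.90)), 0.125)
  # tie between [0.20, 0.25) and [0.40, 0.45): higher bin wins
  expect_equal(sampleAfMode(c(0.21, 0.22, 0.41, 0.42)), 0.425)
  expect_error(sampleAfMean(numeric(0)), "empty")
  expect_error(sampleAfMode(numeric(0)), "empty")
})

test_that("survivors equal the conjunction of predicates regardless of order", {
  set.seed(77)
  cfg <- pipelineConfig()
  sm <- tumorOnlySample()
  simcfg <- simConfig(seed = 14)
  vt <- simulateVariantTable(sm, list(pass = 12, qc = 2, depth = 2,
                                      allele_reads = 2, symbol = 1,
                                      chrom = 1, popaf = 2, abs_af = 2,
                                      mode_norm = 2, noncoding = 2,
                                      not_pathogenic = 2), simcfg)
  df <- vt$variants
  res <- applyFilterCascade(df, sm, cfg)

  # recompute the conjunction directly, anchoring mean/mode to stage-1..7
  # survivors
  pre <- df$qc_pass & df$depth >= 20 & df$ref_reads >= 6 & df$alt_reads >= 6 &
    !grepl("orf|ENSG|ENSM|ENST|Unknown", df$gene_symbol) &
    df$chrom %in% c(as.character(1:22), "X") &
    !(!is.na(df$gnomad_global_af) & df$gnomad_global_af > 0.01 &
        !is.na(df$gnomad_fin_af) & df$gnomad_fin_af > 0.01) &
    df$af >= 0.05
  m <- mean(df$af[pre]); mo <- sampleAfMode(df$af[pre])
  keep <- pre & df$af / m <= 5 & df$af / mo >= 0.15 & df$is_coding &
    (df$clinvar_class %in% c("P", "LP") | df$lof_predicted)
  expect_identical(auditLabels(res) == "pass", keep)
  expect_equal(sum(stageCounts(res)) + nrow(keptVariants(res)), nrow(df))
})

test_that("relaxing a threshold never increases removals", {
  sm <- tumorOnlySample()
  vt <- simulateVariantTable(sm, list(pass = 10, depth = 3, allele_reads = 2,
                                      abs_af = 2), simConfig(seed = 15))
  strict <- applyFilterCascade(vt$variants, sm, pipelineConfig())
  relaxed <- applyFilterCascade(vt$variants, sm,
                                pipelineConfig(min_depth = 5L,
                                               min_abs_af = 0.01))
  expect_lte(sum(stageCounts(relaxed)), sum(stageCounts(strict)))
  expect_lte(stageCounts(relaxed)["depth"], stageCounts(strict)["depth"])
})

test_that("gene-set status flags cascade-surviving drivers", {
  none <- classifyGeneSet(passingVariant()[0, ], "S1")
  expect_false(any(unlist(none[, -1])))

  one <- classifyGeneSet(passingVariant(gene_symbol = "MSH3"), "S1")
  expect_true(one$mutated_MSH3)
  expect_true(one$any_mmr_stability)
  expect_false(one$mutated_B2M)

  set.seed(31)
  genes <- sample(c("MSH3", "MSH6", "POLD1", "POLE", "B2M", "TP53", "APC"),
                  200, replace = TRUE)
  kept <- do.call(rbind, lapply(genes, function(g) passingVariant(gene_symbol = g)))
  st <- classifyGeneSet(kept, "S2")
  for (g in c("MSH3", "MSH6", "POLD1", "POLE", "B2M")) {
    expect_identical(st[[paste0("mutated_", g)]], g %in% genes, info = g)
  }
  expect_identical(st$any_mmr_stability,
                   any(c("MSH3", "MSH6", "POLD1", "POLE") %in% genes))
})

test_that("TMB is variants per megabase over the exome territory", {
  expect_equal(computeTmb(0), 0)
  expect_equal(computeTmb(74), 2)
  expect_equal(computeTmb(37), 1)
  # numerator counts variants surviving through the coding stage
  sm <- tumorOnlySample()
  vt <- simulateVariantTable(sm, list(pass = 4, not_pathogenic = 3,
                                      noncoding = 2), simConfig(seed = 16))
  fr <- applyFilterCascade(vt$variants, sm)
  expect_equal(countThroughCoding(fr), 7)
})

test_that("zero stage-1..7 survivors make the normalizer stages no-ops", {
  sm <- tumorOnlySample()
  df <- passingVariant(qc_pass = FALSE)
  res <- applyFilterCascade(df, sm)
  expect_identical(auditLabels(res), "qc")
  expect_equal(nrow(keptVariants(res)), 0)
})
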