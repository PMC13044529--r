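test_that("pair classification is the documented set algebra", {
  same <- classifyPair(c("a", "b"), c("a", "b"))
  expect_setequal(same@kept, c("a", "b"))
  expect_length(same@lost, 0)
  expect_length(same@gained, 0)

  disj <- classifyPair(c("a", "b"), c("c"))
  expect_length(disj@kept, 0)
  expect_setequal(disj@lost, c("a", "b"))
  expect_setequal(disj@gained, "c")

  mix <- classifyPair(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(mix@kept, c("b", "c"))
  expect_setequal(mix@lost, "a")
  expect_setequal(mix@gained, "d")
})

test_that("pair and trio classifications partition the involved loci", {
  set.seed(55)
  pool <- sprintf("L%03d", 1:60)
  for (r in 1:25) {
    e <- sample(pool, sample(0:40, 1))
    l <- sample(pool, sample(0:40, 1))
    cl <- classifyPair(e, l)
    expect_setequal(c(cl@kept, cl@lost), e)
    expect_setequal(c(cl@kept, cl@gained), l)
    expect_length(intersect(cl@lost, cl@gained), 0)

    p1 <- sample(pool, sample(0:30, 1))
    p2 <- sample(pool, sample(0:30, 1))
    p3 <- sample(pool, sample(0:30, 1))
    tr <- classifyTrio(p1, p2, p3)
    expect_setequal(c(tr@kept, tr@lost, tr@gained), union(union(p1, p2), p3))
  }
})

test_that("the three-tumor rule follows the stated membership logic", {
  tr <- classifyTrio(c("a"), c("b", "c"), c("c", "d"))
  expect_true("a" %in% tr@lost)    # first tumor only, absent from third
  expect_true("c" %in% tr@kept)    # second and third
  expect_true("d" %in% tr@gained)  # unique to the third
  expect_true("b" %in% tr@lost)

  # with an empty first set the trio rule degenerates to the pair rule
  p2 <- c("x", "y"); p3 <- c("y", "z")
  tr2 <- classifyTrio(character(0), p2, p3)
  pr <- classifyPair(p2, p3)
  expect_setequal(tr2@kept, pr@kept)
  expect_setequal(tr2@lost, pr@lost)
  expect_setequal(tr2@gained, pr@gained)
})

immunoFixture <- function(ids, binders = NULL, lens = NULL) {
  n <- length(ids)
  data.frame(locus_id = ids,
             n_strong_i = if (is.null(binders)) stats::rpois(n, 2) else binders,
             n_strong_ii = stats::rpois(n, 1),
             fsp_len = if (is.null(lens)) sample(4:60, n, TRUE) else lens,
             stringsAsFactors = FALSE)
}

test_that("edit summaries report counts, medians and binder totals", {
  emptyCl <- classifyPair(character(0), character(0))
  es <- summarizeEdits(emptyCl, immunoFixture(character(0)))
  tab <- summaryTable(es)
  expect_true(all(tab$n_fsm == 0))
  expect_true(all(is.na(tab$median_fsp_len)))

  cl <- classifyPair(c("x", "y"), c("y"))
  im <- data.frame(locus_id = c("x", "y"), n_strong_i = c(3L, 0L),
                   n_strong_ii = c(1L, 0L), fsp_len = c(10L, 4L))
  tab2 <- summaryTable(summarizeEdits(cl, im))
  expect_equal(tab2$median_fsp_len[tab2$category == "lost"], 10)
  expect_equal(tab2$median_fsp_len[tab2$category == "kept"], 4)
  expect_equal(tab2$total_strong_i[tab2$category == "lost"], 3L)
  expect_equal(tab2$total_strong_i[tab2$category == "kept"], 0L)

  expect_error(summarizeEdits(cl, im[1, ]), "missing immunogenicity")

  set.seed(9)
  ids <- sprintf("L%03d", 1:100)
  big <- classifyPair(sample(ids, 70), sample(ids, 60))
  imb <- immunoFixture(ids)
  tb <- summaryTable(summarizeEdits(big, imb))
  for (cat in c("lost", "kept", "gained")) {
    members <- slot(big, cat)
    expect_equal(tb$total_strong_i[tb$category == cat],
                 sum(imb$n_strong_i[match(members, imb$locus_id)]), info = cat)
    expect_equal(tb$n_fsm[tb$category == cat], length(members))
  }
})

test_that("editing signature fires under maximal separation, not when empty", {
  ids <- sprintf("L%02d", 1:30)
  cl <- classifyPair(ids[1:20], ids[11:30])  # lost 1:10, kept 11:20
  im <- immunoFixture(ids, binders = c(rep(5L, 10), rep(0L, 10), rep(2L, 10)))
  sig <- detectEditingSignature(cl, im)
  expect_true(sig@signature_present)
  expect_lt(sig@p_value, 0.001)

  noLost <- classifyPair(ids[1:10], ids[1:20])
  und <- detectEditingSignature(noLost, im)
  expect_true(is.na(und@signature_present))
  expect_true(is.na(und@p_value))
})

test_that("recurrent losses require shared HLA, signature and a binder", {
  catal <- simulateCatalog(simConfig(seed = 47, catalog_size = 12))
  ids <- loci(catal)$locus_id
  pred <- syntheticAffinityOracle(47)
  allele <- "A*02:01"
  hla <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4", "P5"),
    class_i = c("A*02:01;B*07:02", "A*02:01;B*08:01", "A*02:01;C*07:01",
                "A*03:01;B*07:02", "A*02:01;B*44:02"),
    class_ii = "", stringsAsFactors = FALSE)
  bc <- classIBinderCounts(catal, allele, pred)
  withBinder <- ids[bc[, allele] >= 1]
  skip_if(length(withBinder) < 2, "fixture lacks binder-positive loci")
  shared <- withBinder[1]

  mkSig <- function(pid, present) {
    new("EditingSignal", patient_id = pid, statistic = 1, p_value =
          if (present) 0.01 else 0.5, signature_present = present,
        b2m_context = "positive", alpha = 0.05)
  }
  cls <- list(
    P1 = classifyPair(c(shared, ids[5]), ids[7]),
    P2 = classifyPair(c(shared, ids[6]), ids[8]),
    P3 = classifyPair(shared, shared),          # kept, not lost
    P4 = classifyPair(c(shared, ids[9]), ids[7]),  # non-carrier
    P5 = classifyPair(c(shared, ids[9]), ids[7])   # signature-negative
  )
  sigs <- list(P1 = mkSig("P1", TRUE), P2 = mkSig("P2", TRUE),
               P3 = mkSig("P3", TRUE), P4 = mkSig("P4", TRUE),
               P5 = mkSig("P5", FALSE))
  out <- recurrentLosses(cls, sigs, hla, allele, catal, pred,
                         binder_counts = bc)
  expect_true(shared %in% out$locus_id)
  row <- out[out$locus_id == shared, ]
  expect_equal(row$n_patients, 2L)
  expect_setequal(strsplit(row$patients, ";")[[1]], c("P1", "P2"))

  # brute-force re-derivation: patients x loci x criteria
  eligible <- c("P1", "P2", "P3", "P5")[c(TRUE, TRUE, TRUE, FALSE)]
  want <- character(0)
  for (lc in ids) {
    supp <- eligible[vapply(eligible, function(p) lc %in% cls[[p]]@lost,
                            logical(1))]
    if (length(supp) >= 2 && bc[lc, allele] >= 1) want <- c(want, lc)
  }
  expect_setequal(out$locus_id, want)

  # no signature-positive carriers: empty result
  offSigs <- lapply(sigs, function(s) {
    s@signature_present <- FALSE; s
  })
  expect_equal(nrow(recurrentLosses(cls, offSigs, hla, allele, catal, pred,
                                    binder_counts = bc)), 0)
})

test_that("gained FSMs are immunologically exchangeable with the catalog", {
  # under a constant gain process the binder counts of gained FSMs are a
  # random subsample of the catalog's: a rank test should rarely reject
  rejections <- 0L
  nrep <- 20L
  for (r in seq_len(nrep)) {
    cfg <- simConfig(seed = 3000 + r, catalog_size = 150,
                     recurrence_alpha = 1, recurrence_beta = 1e6,
                     gain_rate = 0.3, loss_intercept = 3, loss_slope = 0)
    catal <- simulateCatalog(cfg)
    ids <- loci(catal)$locus_id
    b <- stats::setNames(stats::rpois(length(ids), 2) +
                           stats::rbinom(length(ids), 1, 0.3) * 10, ids)
    t1 <- simulateFirstTumor("S1", catal, cfg)
    t2 <- simulateNextTumor(t1$truth, b, FALSE, catal, cfg, "S2")
    gained <- t2$truth$gained
    if (length(gained) < 3) next
    p <- suppressWarnings(stats::wilcox.test(b[gained], b,
                                             exact = FALSE)$p.value)
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)  # >= 90% non-significant
})
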