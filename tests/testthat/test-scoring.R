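test_that("database p-value matches identity, linear regime and a frozen high-precision value", {
  expect_equal(databasePValue(0.5, 1), 0.5)
  expect_equal(databasePValue(1e-12, 1000), 1e-9, tolerance = 1e-8)
  # frozen 30-digit evaluation of 1 - (1 - 1e-6)^70625
  expect_equal(databasePValue(1e-6, 70625), 0.06818877706586464,
               tolerance = 1e-12)
  expect_equal(databasePValue(1e-300, 10), 1e-299, tolerance = 1e-12)
  expect_error(databasePValue(0, 10), "spectralProbability")
  expect_error(databasePValue(1.5, 10), "spectralProbability")
  expect_error(databasePValue(0.5, 0), "databaseSize")
})

test_that("database p-value is monotone in both arguments with the right limits", {
  ps <- 10^seq(-12, -3, length.out = 30)
  vals <- databasePValue(ps, 5000)
  expect_true(all(diff(vals) > 0))
  Ns <- c(1, 10, 100, 1e4, 1e6, 1e9)
  valsN <- vapply(Ns, function(N) databasePValue(1e-7, N), numeric(1))
  expect_true(all(diff(valsN) > 0))
  expect_equal(databasePValue(1e-7, 1), 1e-7)
  expect_equal(databasePValue(1e-7, 1e12), 1, tolerance = 1e-6)
})

test_that("PSM FDR filter equals the brute-force prefix oracle and keeps flagged decoys", {
  allT <- makePsms(p = c(1e-9, 1e-8, 1e-7))
  expect_equal(nrow(psmFdrFilter(allT, 0.01)), 3L)
  allD <- makePsms(p = c(1e-9, 1e-8), decoy = c(TRUE, TRUE))
  expect_equal(nrow(psmFdrFilter(allD, 0.01)), 0L)
  expect_equal(nrow(psmFdrFilter(allT[0, ], 0.01)), 0L)

  # 99 targets, then one decoy, then one target: the full 101-record
  # prefix has 1/100 = 1% decoys and qualifies at alpha = 1%
  p <- c(seq(1e-10, 1e-6, length.out = 99), 2e-6, 3e-6)
  d <- c(rep(FALSE, 99), TRUE, FALSE)
  got <- psmFdrFilter(makePsms(p = p, decoy = d), 0.01)
  expect_equal(nrow(got), oraclePrefixTda(p, d, 0.01)$n)
  expect_equal(sum(got$is_decoy), 1L)

  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(5:60, 1)
    p <- runif(n)
    d <- runif(n) < 0.3
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    got <- psmFdrFilter(makePsms(p = p, decoy = d), alpha)
    expect_equal(nrow(got), oraclePrefixTda(p, d, alpha)$n)
  }
})

test_that("under a pure-null score model the accepted decoy fraction stays at the level", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 2000
    psms <- makePsms(p = runif(n), decoy = rep(c(FALSE, TRUE), n / 2))
    acc <- psmFdrFilter(psms, 0.05)
    if (nrow(acc) > 0 && sum(!acc$is_decoy) > 0)
      expect_lte(sum(acc$is_decoy) / sum(!acc$is_decoy), 0.05)
  }
})

test_that("search-space adjustment needs two distinct peptides per protein", {
  # P1 has two distinct target peptides -> eligible; P2 only one -> not
  psms <- makePsms(p = rep(NA_real_, 3), sp = rep(1e-6, 3),
                   peptide = c("AAAAAAK", "CCCCCCK", "DDDDDDK"),
                   scan = 1:3)
  psms$database_p_value <- databasePValue(psms$spectral_probability, 70625)
  protMap <- list(AAAAAAK = "P1", CCCCCCK = "P1", DDDDDDK = "P2")
  out <- adjustSearchSpace(psms, protMap, reducedDatabaseSize = 1500)
  orig <- databasePValue(1e-6, 70625)
  reduced <- databasePValue(1e-6, 1500)
  byPep <- setNames(out$database_p_value, out$peptide)
  expect_equal(unname(byPep["AAAAAAK"]), reduced)
  expect_equal(unname(byPep["CCCCCCK"]), reduced)
  expect_equal(unname(byPep["DDDDDDK"]), orig)   # single-peptide protein
  expect_lt(reduced, orig)
  # spectral probabilities never change; p-values only move down
  expect_equal(sort(out$spectral_probability),
               sort(psms$spectral_probability))
  expect_true(all(out$database_p_value <=
                    psms$database_p_value[match(out$peptide, psms$peptide)]))
  expect_error(adjustSearchSpace(psms, list(AAAAAAK = "P1"), 1500),
               "missing protein mapping")
})

test_that("eligibility pools peptides across a target/decoy protein pair", {
  # 4-PSM fixture: P3 gets one target peptide and its decoy reverse(P3)
  # one decoy peptide -> pooled count 2, both adjusted; P4 stays single
  psms <- makePsms(p = rep(NA_real_, 4), sp = rep(1e-6, 4),
                   peptide = c("FFFFFFK", "GGGGGGK", "HHHHHHK", "MMMMMMK"),
                   decoy = c(FALSE, TRUE, FALSE, FALSE), scan = 1:4)
  psms$database_p_value <- databasePValue(psms$spectral_probability, 70625)
  protMap <- list(FFFFFFK = "P3", GGGGGGK = "XXX_P3",
                  HHHHHHK = "P4", MMMMMMK = "P5")
  out <- adjustSearchSpace(psms, protMap, reducedDatabaseSize = 1500,
                           peptideLevelFdr = 0.6, psmLevelFdr = 0.6)
  reduced <- databasePValue(1e-6, 1500)
  orig <- databasePValue(1e-6, 70625)
  byPep <- setNames(out$database_p_value, out$peptide)
  expect_equal(unname(byPep["FFFFFFK"]), reduced)
  expect_equal(unname(byPep["GGGGGGK"]), reduced)
  expect_equal(unname(byPep["HHHHHHK"]), orig)
  expect_equal(unname(byPep["MMMMMMK"]), orig)
})

test_that("synthetic-pool filter cuts just below the best decoy per length", {
  pool <- c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK")
  psms <- makePsms(p = c(1e-12, 1e-10, 1e-8, 1e-9),
                   peptide = c(pool, "EEEEEEEK"),
                   decoy = c(FALSE, FALSE, FALSE, TRUE),
                   run = "main", scan = 1:4)
  res <- syntheticPoolFilter(psms, backgroundRunIds = "bg1",
                             poolTargetPeptides = pool)
  expect_equal(nrow(res$accepted), 2L)
  expect_setequal(res$accepted$peptide, c("AAAAAAAK", "CCCCCCCK"))
  expect_equal(res$thresholds$max_p_value, 1e-9)

  # no decoys at all -> everything accepted
  clean <- makePsms(p = c(1e-10, 1e-8), peptide = pool[1:2],
                    run = "main", scan = 1:2)
  resClean <- syntheticPoolFilter(clean, "bg1", pool)
  expect_equal(nrow(resClean$accepted), 2L)

  expect_error(syntheticPoolFilter(psms, character(0), pool),
               "background")
})

test_that("background peptides shared with the target pool are not counted as decoys", {
  pool <- c("AAAAAAAK", "CCCCCCCK")
  psms <- makePsms(p = c(1e-12, 1e-10, 1e-6),
                   peptide = c(pool, pool[1]),
                   run = c("main", "main", "bg1"), scan = 1:3)
  # bg1's match to AAAAAAAK (also synthesized in bg1's pool AND in the
  # target pool) must not set the threshold
  res <- syntheticPoolFilter(psms, "bg1", pool,
                             backgroundPoolPeptides = list(bg1 = pool[1]))
  expect_equal(nrow(res$accepted), 3L)
  # without the exclusion it is a decoy and truncates the accepted set
  res2 <- syntheticPoolFilter(psms, "bg1", pool)
  expect_equal(nrow(res2$accepted), 2L)
})

test_that("synthetic-pool output never contains a decoy PSM", {
  for (seed in 1:5) {
    fx <- generatePoolFixture(seed = seed, nTargets = 60,
                              nBackgroundRuns = 3, nDecoyPsms = 10,
                              nBackgroundPsms = 20)
    res <- syntheticPoolFilter(fx$psms, fx$backgroundRunIds,
                               fx$poolTargetPeptides,
                               fx$backgroundPoolPeptides)
    acc <- res$accepted
    expect_false(any(acc$is_decoy))
    expect_false(any(acc$run_id %in% fx$backgroundRunIds &
                       !acc$peptide %in% fx$poolTargetPeptides))
  }
})
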