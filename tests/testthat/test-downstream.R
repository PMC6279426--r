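test_that("greedy proteotypic selection reproduces the worked examples", {
  # one precursor in every search
  out <- selectProteotypic(paste0("s", 1:5),
                           list(A = paste0("s", 1:5)))
  expect_equal(out$precursors, "A")
  expect_equal(out$coverage, 1.0)

  # A covers 1-9 (90%), stop immediately despite B/C existing
  searches <- paste0("s", 1:10)
  ps <- list(A = paste0("s", 1:9), B = "s10", C = paste0("s", 1:5))
  out <- selectProteotypic(searches, ps, targetCoverage = 0.9)
  expect_equal(out$precursors, "A")
  expect_equal(out$coverage, 0.9)

  # 40 precursors, one distinct search each, 200 searches -> capped at 20
  searches <- paste0("s", 1:200)
  ps <- setNames(lapply(1:40, function(i) paste0("s", i)),
                 sprintf("p%02d", 1:40))
  out <- selectProteotypic(searches, ps)
  expect_equal(length(out$precursors), 20L)
  expect_equal(out$coverage, 0.1)

  expect_error(selectProteotypic(character(0), ps), "zero searches")
})

test_that("greedy selection matches an independent greedy implementation", {
  for (seed in 1:40) {
    set.seed(seed)
    nS <- sample(5:20, 1)
    nP <- sample(3:12, 1)
    searches <- paste0("s", seq_len(nS))
    ps <- setNames(lapply(seq_len(nP), function(i)
      sample(searches, sample(1:nS, 1))), sprintf("p%02d", seq_len(nP)))
    got <- selectProteotypic(searches, ps, targetCoverage = 0.9,
                             maxPrecursors = 20)
    want <- oracleGreedyCover(searches, ps, 0.9, 20)
    expect_identical(got$precursors, want)
  }
})

test_that("greedy coverage respects the (1 - 1/e) guarantee against the optimum", {
  for (seed in 1:15) {
    set.seed(seed)
    nS <- sample(6:12, 1)
    nP <- sample(4:9, 1)
    searches <- paste0("s", seq_len(nS))
    ps <- setNames(lapply(seq_len(nP), function(i)
      sample(searches, sample(1:4, 1))), sprintf("p%02d", seq_len(nP)))
    k <- 3L
    got <- selectProteotypic(searches, ps, targetCoverage = 1,
                             maxPrecursors = k)
    greedyCov <- length(unique(unlist(ps[got$precursors]))) / nS
    combos <- utils::combn(names(ps), min(k, nP), simplify = FALSE)
    optCov <- max(vapply(combos, function(cs)
      length(unique(unlist(ps[cs]))) / nS, numeric(1)))
    expect_gte(greedyCov + 1e-12, (1 - 1 / exp(1)) * optCov)
  }
})

test_that("co-observation detectability requires proteotypic precursors in the search", {
  perSearch <- list(s1 = c("P1", "P2"), s2 = c("P1", "P3"))
  sets <- list(P1 = c("a/2"), P2 = c("b/2"), P3 = c("c/2"))
  hits <- list(s1 = c("a/2", "b/2"), s2 = c("a/2"))
  out <- detectInteractions(perSearch, sets, hits)
  r12 <- out[out$proteinA == "P1" & out$proteinB == "P2", ]
  expect_true(r12$detectable)
  r13 <- out[out$proteinA == "P1" & out$proteinB == "P3", ]
  expect_false(r13$detectable)  # P3's proteotypic precursor absent in s2
  none <- detectInteractions(list(s1 = "P1", s2 = "P2"), sets, hits)
  expect_equal(nrow(none), 0L)
})

test_that("single-amino-acid-variant detection matches the exhaustive window scan", {
  pe1 <- c(A = "MKPEPSIDEKLLGW", B = "WWWWYYYYHHHH")
  expect_true(isSaavOfPe1("PEPSIDEK", pe1))   # exact substring
  expect_true(isSaavOfPe1("PEPTIDEK", pe1))   # Hamming distance 1
  expect_false(isSaavOfPe1("PEGGIDEK", pe1))  # distance 2
  expect_false(isSaavOfPe1("PEPTIDEK", character(0)))
  for (seed in 1:20) {
    set.seed(seed)
    aa <- names(speclib:::.RESIDUE_MASS)
    seqs <- vapply(1:3, function(i)
      paste(sample(aa, 40, replace = TRUE), collapse = ""), character(1))
    pep <- paste(sample(aa, 9, replace = TRUE), collapse = "")
    expect_identical(isSaavOfPe1(pep, seqs), oracleSaav(pep, seqs))
  }
})

test_that("novel proteins need two non-overlapping peptides and no SAAV support", {
  novelSeq <- paste0("MKWY", "AGTSEEVVLK", "WYHGW", "TTSSGGHHVK", "WY")
  fasta <- c(PE1A = "MKPEPSIDEKLLGW", NOV1 = novelSeq)
  pe <- c(PE1A = 1L, NOV1 = 2L)
  # spans [5,14] and [20,29]: disjoint -> called
  out <- callNovelProteins(c("AGTSEEVVLK", "TTSSGGHHVK"), fasta, pe)
  expect_equal(out$accession, "NOV1")
  expect_equal(out$pe_level, 2L)

  # overlapping evidence only -> not called
  overlapping <- c("AGTSEEVVLK", substring(novelSeq, 14, 22))
  out2 <- callNovelProteins(overlapping, fasta, pe)
  expect_equal(nrow(out2), 0L)

  # SAAV of a PE1 protein is struck from the evidence
  fasta2 <- c(PE1A = "MKPEPSIDEKLLGW",
              NOV2 = paste0("MK", "PEPTIDEK", "WWW", "AGTSEEVVLK", "H"))
  out3 <- callNovelProteins(c("PEPTIDEK", "AGTSEEVVLK"), fasta2,
                            c(PE1A = 1L, NOV2 = 2L), minLength = 8L)
  expect_equal(nrow(out3), 0L)

  # short peptides are ignored outright
  out4 <- callNovelProteins(c("AGTSEEVV", "TTSSGGHH"), fasta, pe,
                            minLength = 9L)
  expect_equal(nrow(out4), 0L)
})

test_that("fixture SAAV traps are caught by the exclusion rule", {
  cfg <- fixtureConfig(seed = 5, nProteins = 10, nNovelProteins = 2,
                       nSaavTraps = 2)
  uni <- generateUniverse(cfg)
  pe1 <- uni$targets[uni$peLevels == 1L]
  for (trap in uni$saavTraps)
    expect_true(isSaavOfPe1(trap, pe1))
})

test_that("SILAC gold standard applies all four concordance gates", {
  cfg0 <- fixtureConfig(seed = 9, nProteins = 10, silac = TRUE,
                        nSilacPairs = 8)
  uni <- generateUniverse(cfg0)
  sp <- generateSilacPairs(cfg0, uni)
  gold <- buildSilacGold(sp$psmsLight, sp$psmsHeavy, sp$store)
  expect_true(all(gold$pairs$concordant))
  expect_equal(nrow(gold$entries),
               length(unique(paste0(gold$pairs$peptide, "/",
                                    gold$pairs$charge))))
  expect_true(all(gold$pairs$aligned_cosine > 0.999))

  # retention-time jitter of 2 minutes violates the 1-minute gate
  cfgRt <- fixtureConfig(seed = 9, nProteins = 10, silac = TRUE,
                         nSilacPairs = 8, silacRtJitter = 2)
  spRt <- generateSilacPairs(cfgRt, uni)
  goldRt <- buildSilacGold(spRt$psmsLight, spRt$psmsHeavy, spRt$store)
  expect_equal(nrow(goldRt$entries), 0L)
  expect_true(all(goldRt$pairs$rt_delta > 1))
})

test_that("a weakly aligned pair fails the cosine gate", {
  # one shared (shifted) peak with intensity product 0.48 < 0.6
  light <- Spectrum(c(100, 300), c(0.6, 0.8), precursorCharge = 2L,
                    runId = "r1", scan = 1L, retentionTime = 30)
  heavy <- Spectrum(c(100 + 8.0142, 900), c(0.8, 0.6),
                    precursorCharge = 2L, runId = "r1", scan = 2L,
                    retentionTime = 30)
  store <- list("r1::1" = light, "r1::2" = heavy)
  pl <- makePsms(p = 1e-8, peptide = "AAGTSEEVLK", scan = 1L)
  ph <- makePsms(p = 1e-8, peptide = "AAGTSEEVLK(+8.0142)", scan = 2L)
  gold <- buildSilacGold(pl, ph, store)
  expect_equal(nrow(gold$pairs), 1L)
  expect_lt(gold$pairs$aligned_cosine, 0.6)
  expect_false(gold$pairs$concordant)
})

test_that("SILAC pairing is symmetric in input file order", {
  cfg <- fixtureConfig(seed = 23, nProteins = 10, silac = TRUE,
                       nSilacPairs = 10)
  uni <- generateUniverse(cfg)
  sp <- generateSilacPairs(cfg, uni)
  g1 <- buildSilacGold(sp$psmsLight, sp$psmsHeavy, sp$store)
  shuffle <- function(df) df[rev(seq_len(nrow(df))), ]
  g2 <- buildSilacGold(shuffle(sp$psmsLight), shuffle(sp$psmsHeavy),
                       sp$store)
  expect_equal(g1$entries, g2$entries)
  expect_equal(g1$pairs, g2$pairs)
})
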