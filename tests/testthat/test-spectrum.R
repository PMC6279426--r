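test_that("normalization rescales to unit Euclidean norm and is idempotent", {
  s <- Spectrum(c(100, 200), c(3, 4))
  expect_equal(peakIntensity(normalizeSpectrum(s)), c(0.6, 0.8))

  single <- Spectrum(500, 17)
  expect_equal(peakIntensity(normalizeSpectrum(single)), 1.0)

  set.seed(11)
  r <- Spectrum(sort(runif(50, 100, 1500)), runif(50, 0.01, 10))
  n1 <- normalizeSpectrum(r)
  expect_equal(sum(peakIntensity(n1)^2), 1, tolerance = 1e-9)
  expect_equal(peakMz(n1), peakMz(r))
  n2 <- normalizeSpectrum(n1)
  expect_equal(peakIntensity(n2), peakIntensity(n1))

  expect_error(normalizeSpectrum(Spectrum(numeric(0), numeric(0))),
               "invalid-spectrum")
  expect_error(normalizeSpectrum(Spectrum(c(100, 200), c(0, 0))),
               "invalid-spectrum")
})

test_that("spectrum construction sorts peaks and merges duplicate m/z", {
  s <- Spectrum(c(300, 100, 100), c(1, 2, 3))
  expect_equal(peakMz(s), c(100, 300))
  expect_equal(peakIntensity(s), c(5, 1))
  expect_error(Spectrum(c(-1, 100), c(1, 1)))
})

test_that("fragment annotation finds the hand-computed b1 ion of alanine", {
  # b1 of "AG" = residue mass of A + one proton = 71.03711 + 1.00728
  s <- Spectrum(72.04439, 1, precursorCharge = 1L)
  ann <- annotatePeaks(s, "AG", precursorCharge = 1L)
  bRows <- ann[ann$series == "b" & ann$loss == "none" & ann$isotope == 0L, ]
  expect_equal(nrow(bRows), 1L)
  expect_equal(bRows$index, 1L)
  expect_equal(bRows$theoreticalMz, 72.04439, tolerance = 1e-6)
})

test_that("annotation of an empty spectrum is empty and bad residues error", {
  empty <- Spectrum(numeric(0), numeric(0), precursorCharge = 2L)
  expect_equal(nrow(annotatePeaks(empty, "PEPTIDEK")), 0L)
  s <- Spectrum(500, 1)
  expect_error(annotatePeaks(s, "PEPZIDE"), "invalid-peptide")
})

test_that("a spectrum built from the theoretical ion ladder is fully annotated", {
  pep <- "LVDGTSEEK"
  frags <- theoreticalFragments(pep, maxCharge = 1L)
  y <- frags[frags$series == "y" & frags$loss == "none" &
               frags$isotope == 0L, ]
  s <- Spectrum(y$mz, rep(1, nrow(y)), precursorCharge = 1L)
  ann <- annotatePeaks(s, pep, precursorCharge = 1L)
  expect_setequal(unique(ann$peak), seq_along(peakMz(s)))
  yAnn <- ann[ann$label == "y", ]
  expect_setequal(yAnn$index, y$index)
  expect_equal(explainedIntensity(s, ann), 1.0)
})

test_that("explained intensity counts each peak once and ignores scale", {
  s <- Spectrum(c(100, 200, 300), c(0.3, 0.3, 0.4))
  ann <- data.frame(peak = c(1L, 2L, 1L))  # peak 1 annotated twice
  expect_equal(explainedIntensity(s, ann), 0.6)
  expect_equal(explainedIntensity(s, ann[0, , drop = FALSE]), 0)
  s10 <- Spectrum(peakMz(s), peakIntensity(s) * 10)
  expect_equal(explainedIntensity(s10, ann), 0.6)
  allAnn <- data.frame(peak = 1:3)
  expect_equal(explainedIntensity(s, allAnn), 1.0)
  expect_error(explainedIntensity(Spectrum(numeric(0), numeric(0)), ann),
               "invalid-spectrum")
})

test_that("precursor mass filter honors ppm bound and 13C rescue", {
  pep <- "LVDGTSEEK"
  z <- 2L
  theo <- peptideNeutralMass(pep)
  mzExact <- (theo + z * 1.00728) / z
  expect_true(precursorMassFilter(mzExact, z, pep))
  mz100 <- (theo * (1 + 100e-6) + z * 1.00728) / z
  expect_false(precursorMassFilter(mz100, z, pep, allowC13 = FALSE))
  mzC13 <- (theo + 1.00335 + z * 1.00728) / z
  expect_true(precursorMassFilter(mzC13, z, pep, allowC13 = TRUE))
  expect_false(precursorMassFilter(mzC13, z, pep, allowC13 = FALSE))
  expect_error(precursorMassFilter(mzExact, 0L, pep), "charge")
})

test_that("13C-tolerant filtering accepts a superset of strict filtering", {
  pep <- "AGSTVLK"
  z <- 2L
  theo <- peptideNeutralMass(pep)
  set.seed(5)
  obs <- (theo + runif(200, -2, 2) + z * 1.00728) / z
  strict <- vapply(obs, precursorMassFilter, logical(1), charge = z,
                   peptide = pep, allowC13 = FALSE)
  loose <- vapply(obs, precursorMassFilter, logical(1), charge = z,
                  peptide = pep, allowC13 = TRUE)
  expect_true(all(loose[strict]))
})

test_that("cosine handles identity, disjoint peaks and the hand-matched case", {
  a <- Spectrum(c(100, 300), c(0.6, 0.8))
  b <- Spectrum(c(100, 500), c(0.8, 0.6))
  expect_equal(cosineSimilarity(a, a), 1, tolerance = 1e-9)
  disjoint <- Spectrum(c(700, 900), c(0.6, 0.8))
  expect_equal(cosineSimilarity(a, disjoint), 0)
  # single shared peak at 100: 0.6 * 0.8
  expect_equal(cosineSimilarity(a, b), 0.48)
  expect_error(cosineSimilarity(Spectrum(100, 5), a), "normalized")
})

test_that("cosine is symmetric and bounded on random spectra", {
  for (seed in 1:25) {
    a <- normalizeSpectrum(randomSpectrum(12, seed))
    b <- normalizeSpectrum(randomSpectrum(9, seed + 1000))
    ab <- cosineSimilarity(a, b)
    expect_identical(ab, cosineSimilarity(b, a))
    expect_gte(ab, 0); expect_lte(ab, 1)
    expect_gte(alignedCosine(a, b, parentMassDelta = 8.0142), ab)
  }
})

test_that("aligned cosine recovers a perfectly y-shifted heavy copy", {
  pep <- "LVDGTSEEK"
  frags <- theoreticalFragments(pep, maxCharge = 1L)
  plain <- frags[frags$loss == "none" & frags$isotope == 0L &
                   frags$series %in% c("b", "y"), ]
  set.seed(3)
  int <- runif(nrow(plain), 0.2, 1)
  light <- normalizeSpectrum(Spectrum(plain$mz, int, precursorCharge = 1L))
  heavyMz <- ifelse(plain$series == "y", plain$mz + 8.0142, plain$mz)
  heavy <- normalizeSpectrum(Spectrum(heavyMz, int, precursorCharge = 1L))
  expect_equal(alignedCosine(light, heavy, parentMassDelta = 8.0142), 1,
               tolerance = 1e-9)
  far <- normalizeSpectrum(Spectrum(peakMz(light) + 5000, peakIntensity(light),
                                    precursorCharge = 1L))
  expect_equal(alignedCosine(light, far, parentMassDelta = 8.0142), 0)
})

test_that("optimal-mode aligned cosine equals the exhaustive alignment oracle", {
  for (seed in 1:40) {
    set.seed(seed)
    nA <- sample(3:8, 1); nB <- sample(3:8, 1)
    delta <- 8.0142
    a <- normalizeSpectrum(Spectrum(sort(runif(nA, 100, 600)),
                                    runif(nA, 0.1, 1),
                                    precursorCharge = 2L))
    b <- normalizeSpectrum(Spectrum(sort(runif(nB, 100, 620)),
                                    runif(nB, 0.1, 1),
                                    precursorCharge = 2L))
    shifts <- c(0, delta, delta / 2)
    expected <- oracleMatchScore(peakMz(a), peakIntensity(a),
                                 peakMz(b), peakIntensity(b),
                                 tol = 0.25, shifts = shifts)
    got <- alignedCosine(a, b, parentMassDelta = delta,
                         fragmentToleranceDa = 0.25, method = "optimal")
    expect_equal(got, expected, tolerance = 1e-12)
    expect_lte(alignedCosine(a, b, parentMassDelta = delta,
                             fragmentToleranceDa = 0.25), got + 1e-12)
  }
})

test_that("peptide parsing, canonical form and localization grouping", {
  p <- parsePeptide("PEPS(+79.966)TIDE")
  expect_equal(p$sequence, "PEPSTIDE")
  expect_equal(p$positions, 4L)
  expect_equal(p$deltas, 79.966)
  expect_equal(canonicalPeptide("PEPS(+79.966)TIDE"), "PEPS(+79.9660)TIDE")
  expect_equal(unmodifiedSequence("(+42.011)PEPS(+79.966)TIDE"), "PEPSTIDE")
  g <- localizationGroup(c("PEPS(+79.966)TIDE", "PEPST(+79.966)IDE",
                           "PEPS(+79.966)TIDE"), c(2, 2, 3))
  expect_identical(g[1], g[2])
  expect_false(g[1] == g[3])
})
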