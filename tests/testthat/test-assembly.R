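emptyState <- function() newLibraryState(buildConfig())

test_that("merging an empty batch is the identity", {
  st <- emptyState()
  psms <- makePsms(p = c(1e-8, 1e-7))
  st1 <- updateCandidates(st, psms)
  st2 <- updateCandidates(st1, psms[0, ])
  expect_identical(precursorLedger(st1), precursorLedger(st2))
  expect_identical(candidateSets(st1), candidateSets(st2))
})

test_that("candidate caps: 20 per dataset, 100 global", {
  one <- makePsms(p = sort(runif(300, 1e-9, 1e-4)),
                  peptide = "AAAAAAGTSK", scan = 1:300,
                  run = sprintf("r%03d", 1:300), dataset = "D1")
  st <- updateCandidates(emptyState(), one)
  cs <- candidateSets(st)[["AAAAAAGTSK/2"]]
  expect_equal(nrow(cs), 20L)
  # the 20 retained are the globally best under the total order
  expect_equal(sort(cs$database_p_value),
               sort(one$database_p_value)[1:20])

  spread <- makePsms(p = sort(runif(500, 1e-9, 1e-4)),
                     peptide = "CCCCCCGTSK", scan = 1:500,
                     run = sprintf("r%03d", 1:500),
                     dataset = rep(sprintf("D%02d", 1:50), each = 10))
  st2 <- updateCandidates(emptyState(), spread)
  expect_equal(nrow(candidateSets(st2)[["CCCCCCGTSK/2"]]), 100L)
})

test_that("candidate merging is associative, commutative and idempotent", {
  set.seed(21)
  psms <- makePsms(p = runif(120, 1e-9, 1e-3),
                   peptide = rep(c("AAGTSEEK", "GGTTSSEK", "TTEEAAGK"), 40),
                   scan = 1:120, run = sprintf("r%02d", rep(1:12, 10)),
                   dataset = rep(sprintf("D%d", 1:4), 30))
  idx <- sample(nrow(psms))
  b <- split(idx, rep(1:3, length.out = nrow(psms)))
  once <- updateCandidates(emptyState(), psms)
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  for (perm in perms) {
    st <- emptyState()
    for (k in perm) st <- updateCandidates(st, psms[b[[k]], ])
    expect_identical(precursorLedger(st), precursorLedger(once))
    expect_identical(candidateSets(st), candidateSets(once))
  }
  # overlapping batches (duplicate PSMs) collapse to the same state
  twice <- updateCandidates(once, psms)
  expect_identical(candidateSets(twice), candidateSets(once))
})

test_that("a PSM referencing a missing spectrum is reported by run and scan", {
  psms <- makePsms(p = 1e-8, run = "ghost", scan = 99L)
  expect_error(updateCandidates(emptyState(), psms, store = list()),
               "ghost::99")
})

test_that("representative selection maximizes mean pairwise cosine", {
  mk <- function(mz, int, run, scan)
    Spectrum(mz, int, precursorCharge = 2L, runId = run, scan = scan)
  store <- list(
    "r1::1" = mk(c(100, 200, 300), c(1, 2, 3), "r1", 1L),
    "r1::2" = mk(c(100, 200, 300), c(1, 2, 3), "r1", 2L),
    "r1::3" = mk(c(500, 600, 700), c(1, 1, 1), "r1", 3L))
  cand <- makePsms(p = c(1e-9, 1e-8, 1e-7), peptide = "AAGTSEEK",
                   scan = 1:3)
  rep1 <- selectRepresentative(cand, store)
  # the two identical spectra beat the outlier; first under total order
  expect_equal(rep1$psm$scan, 1L)

  single <- selectRepresentative(cand[2, ], store)
  expect_equal(single$psm$scan, 2L)
  expect_error(selectRepresentative(cand, list()), "no retrievable")
})

test_that("representative choice equals exhaustive mean-similarity computation", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(2:6, 1)
    store <- list()
    for (i in seq_len(n))
      store[[paste0("r1::", i)]] <- randomSpectrum(sample(5:12, 1),
                                                   seed * 100 + i,
                                                   scan = i)
    cand <- makePsms(p = sort(runif(n, 1e-9, 1e-4)),
                     peptide = "AAGTSEEK", scan = seq_len(n))
    got <- selectRepresentative(cand, store)
    specs <- lapply(store[paste0("r1::", 1:n)], normalizeSpectrum)
    means <- vapply(1:n, function(i) {
      mean(vapply(setdiff(1:n, i), function(j)
        cosineSimilarity(specs[[i]], specs[[j]]), numeric(1)))
    }, numeric(1))
    expect_equal(got$psm$scan, which(means == max(means))[1])
    # membership: the representative is one of the candidates
    expect_true(got$psm$scan %in% cand$scan)
  }
})

test_that("ambiguity filter collapses localization variants before counting", {
  entries <- data.frame(key = c("e1", "e2", "e3", "e4"),
                        search_id = "S1", length = 8L,
                        stringsAsFactors = FALSE)
  thr <- list(S1 = data.frame(length = 8L, max_p_value = 1e-4))
  ann <- list(
    e1 = data.frame(peptide = "AAGTSEEK", charge = 2L,
                    database_p_value = 1e-6),
    e2 = data.frame(peptide = c("AAGS(+79.9660)EEK", "AAGSE(+79.9660)EK"),
                    charge = 2L, database_p_value = c(1e-7, 1e-6)),
    e3 = data.frame(peptide = c("AAGTSEEK", "GGTTSSEK"), charge = 2L,
                    database_p_value = c(1e-7, 1e-6)),
    e4 = data.frame(peptide = c("AAGTSEEK", "GGTTSSEK"), charge = 2L,
                    database_p_value = c(1e-7, 1e-2)))
  out <- filterAmbiguous(entries, ann, thr)
  expect_true("e1" %in% out$key)   # one passing annotation
  expect_true("e2" %in% out$key)   # two variants of one peptide
  expect_false("e3" %in% out$key)  # two distinct passing sequences
  expect_true("e4" %in% out$key)   # second annotation fails the threshold
  # entry missing from the table is retained with a log message
  e5 <- data.frame(key = "e5", search_id = "S1", length = 8L)
  expect_message(out5 <- filterAmbiguous(e5, ann, thr), "missing")
  expect_equal(out5$key, "e5")
})

test_that("an empty state builds an empty library", {
  lib <- buildLibrary(emptyState(), c(P1 = "MKAAAAAAK"), list())
  expect_s4_class(lib, "SpectralLibrary")
  expect_equal(nrow(libraryEntries(lib)), 0L)
})

test_that("the built library equals the stage-by-stage oracle pipeline", {
  cfg <- fixtureConfig(seed = 31, nProteins = 15, nTruePeptides = 50,
                       nDecoyPeptides = 20)
  uni <- generateUniverse(cfg)
  stream <- generatePsmStream(cfg, uni)
  conf <- buildConfig(window = 50L)
  state <- updateCandidates(newLibraryState(conf), stream$psms,
                            store = stream$store)
  lib <- buildLibrary(state, uni$targets, stream$store)

  # independent composition of the stages
  rec <- precursorRecords(stream$psms)
  lf <- localPrecursorFdr(rec, window = conf$window, alpha = conf$local_fdr)
  rec2 <- collapseSiteVariants(lf$accepted)
  fasta <- c(uni$targets, uni$decoys)
  mapping <- mapPrecursorsToProteins(rec2, fasta)
  prot <- scoreProteins(rec2, mapping)
  accProt <- pickedProteinFdr(prot, conf$protein_fdr)
  keep <- vapply(strsplit(mapping$accessions, ","), function(a)
    any(a %in% accProt$accession), logical(1))
  expect_setequal(libraryEntries(lib)$key, rec2$key[keep])

  # decoy persistence: decoy entries equal decoy precursors surviving FDR
  expect_equal(sum(libraryEntries(lib)$is_decoy), sum(rec2$is_decoy[keep]))
  # every representative is one of its precursor's candidates
  ent <- libraryEntries(lib)
  for (i in seq_len(nrow(ent))) {
    cand <- candidateSets(state)[[ent$key[i]]]
    expect_true(any(cand$run_id == ent$run_id[i] &
                      cand$scan == ent$scan[i]))
  }
})

test_that("batch order never changes the exported library bytes", {
  cfg <- fixtureConfig(seed = 17, nProteins = 12, nTruePeptides = 40,
                       nDecoyPeptides = 15)
  uni <- generateUniverse(cfg)
  stream <- generatePsmStream(cfg, uni)
  conf <- buildConfig(window = 50L)
  set.seed(4)
  idx <- sample(nrow(stream$psms))
  batches <- split(idx, rep(1:3, length.out = length(idx)))
  md5s <- vapply(list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1)), function(perm) {
    st <- newLibraryState(conf)
    for (k in perm)
      st <- updateCandidates(st, stream$psms[batches[[k]], ],
                             store = stream$store)
    lib <- buildLibrary(st, uni$targets, stream$store)
    f <- tempfile(fileext = ".mgf")
    exportLibrary(lib, f, "mgf")
    unname(tools::md5sum(f))
  }, character(1))
  expect_equal(length(unique(md5s)), 1L)
})

test_that("a strictly better PSM never evicts its precursor from the library", {
  cfg <- fixtureConfig(seed = 53, nProteins = 10, nTruePeptides = 30,
                       nDecoyPeptides = 0L)
  uni <- generateUniverse(cfg)
  stream <- generatePsmStream(cfg, uni)
  conf <- buildConfig(window = 50L)
  st <- updateCandidates(newLibraryState(conf), stream$psms,
                         store = stream$store)
  lib1 <- buildLibrary(st, uni$targets, stream$store)
  k <- libraryEntries(lib1)$key[1]
  cand <- candidateSets(st)[[k]]
  better <- cand[1, ]
  better$scan <- 10000L
  better$database_p_value <- better$database_p_value / 10
  better$spectral_probability <- better$spectral_probability / 10
  store2 <- stream$store
  store2[[paste0(better$run_id, "::", better$scan)]] <-
    stream$store[[paste0(better$run_id, "::", cand$scan[1])]]
  st2 <- updateCandidates(st, better, store = store2)
  lib2 <- buildLibrary(st2, uni$targets, store2)
  expect_true(k %in% libraryEntries(lib2)$key)
})

test_that("library state round-trips through its directory layout", {
  cfg <- fixtureConfig(seed = 61, nProteins = 8, nTruePeptides = 20,
                       nDecoyPeptides = 5)
  uni <- generateUniverse(cfg)
  stream <- generatePsmStream(cfg, uni)
  st <- updateCandidates(newLibraryState(buildConfig()), stream$psms)
  dir <- tempfile()
  saveLibraryState(st, dir, store = stream$store)
  st2 <- loadLibraryState(dir)
  expect_equal(precursorLedger(st2)$key, precursorLedger(st)$key)
  expect_equal(precursorLedger(st2)$best_p_value,
               precursorLedger(st)$best_p_value)
  expect_equal(names(candidateSets(st2)), names(candidateSets(st)))
  store2 <- attr(st2, "store")
  expect_equal(length(store2), length(stream$store))
})
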