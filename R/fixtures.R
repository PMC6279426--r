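## Synthetic-data generation: peptide/protein universes, theoretical
## spectra with controllable noise, target/decoy score models, SILAC
## pairs and synthetic-pool layouts. Everything is deterministic given
## the seed: per-entity sub-seeds are derived with a stable string hash
## so regenerated fixtures are byte-identical.

.stableHash <- function(id) {
  codes <- utf8ToInt(id)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483587
  as.integer(h)
}

.subSeed <- function(seed, id) {
  as.integer((as.numeric(seed) * 7919 + .stableHash(id)) %% 2147483587)
}

.logUniform <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Fixture generation configuration
#'
#' Bundles all knobs of the synthetic-data generator. Defaults emulate
#' the study conditions the pipeline targets: separable but overlapping
#' score distributions (true-match spectral probabilities log-uniform on
#' \[1e-15, 1e-9\], random-match on \[1e-8, 1e-2\]), a small effective
#' database (so null database p-values spread over (0,1) instead of
#' saturating), theoretical b/y fragment spectra with optional dropout /
#' spurious-peak / intensity-jitter noise, and a datasets-by-runs layout.
#'
#' @param seed Integer master seed; every generated entity derives its
#'   own sub-seed from it.
#' @param nProteins Number of target proteins.
#' @param peptidesPerProtein Tryptic segments per protein.
#' @param nNovelProteins Planted PE2 proteins (novel-candidate traps).
#' @param nSaavTraps Planted PE1 windows at Hamming distance 1 from a
#'   novel peptide.
#' @param trueScoreRange,nullScoreRange Spectral-probability ranges.
#' @param databaseSize Effective database size N for p-value conversion.
#' @param noise List: `dropout` (per-peak omission probability),
#'   `spurious` (count of unannotatable peaks added), `jitter`
#'   (multiplicative intensity noise sd).
#' @param nDatasets,runsPerDataset Layout of the PSM stream.
#' @param nTruePeptides,nDecoyPeptides Peptides drawn from the target and
#'   decoy digests.
#' @param psmsPerPrecursor Integer range (min, max) of replicate PSMs.
#' @param silac Logical: generate SILAC light/heavy pairs.
#' @param nSilacPairs,silacRtJitter,silacFragPerturb SILAC pair count and
#'   perturbation controls (minutes; fraction of y-peaks scrambled).
#' @return A list of class `"FixtureConfig"`.
#' @export
fixtureConfig <- function(seed = 1L, nProteins = 40L,
                          peptidesPerProtein = 12L,
                          nNovelProteins = 3L, nSaavTraps = 2L,
                          trueScoreRange = c(1e-15, 1e-9),
                          nullScoreRange = c(1e-8, 1e-2),
                          databaseSize = 1000L,
                          noise = list(dropout = 0, spurious = 0L,
                                       jitter = 0),
                          nDatasets = 4L, runsPerDataset = 2L,
                          nTruePeptides = 150L, nDecoyPeptides = 50L,
                          psmsPerPrecursor = c(1L, 5L),
                          silac = FALSE, nSilacPairs = 20L,
                          silacRtJitter = 0, silacFragPerturb = 0) {
  stopifnot(nProteins >= 1L, peptidesPerProtein >= 1L, databaseSize >= 1L)
  cfg <- as.list(environment())
  class(cfg) <- c("FixtureConfig", "list")
  cfg
}

.randomTrypticProtein <- function(nSegments, rng = NULL) {
  letters20 <- names(.RESIDUE_MASS)
  interior <- setdiff(letters20, c("K", "R"))
  segs <- vapply(seq_len(nSegments), function(i) {
    len <- sample(7:14, 1L)
    paste0(paste(sample(interior, len, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1))
  paste(segs, collapse = "")
}

#' Generate a synthetic protein universe
#'
#' Random tryptic-friendly target proteins with reversed decoys, plus
#' planted PE2 "novel" proteins carrying peptides absent from the PE1 set
#' and planted SAAV traps: PE1 windows at Hamming distance 1 from a novel
#' peptide, which the single-amino-acid-variant exclusion must catch.
#'
#' @param config A [fixtureConfig()].
#' @return List: `targets` (named character, PE1 + PE2 proteins),
#'   `decoys`, `peLevels` (named integer), `novelPeptides` (peptides
#'   planted only in PE2 proteins), `saavTraps` (novel peptides that got
#'   a distance-1 PE1 window planted).
#' @export
generateUniverse <- function(config) {
  stopifnot(inherits(config, "FixtureConfig"))
  if (config$nProteins < 1L) stop("degenerate universe size")
  set.seed(.subSeed(config$seed, "universe"))
  n <- config$nProteins
  targets <- vapply(seq_len(n), function(i)
    .randomTrypticProtein(config$peptidesPerProtein), character(1))
  names(targets) <- sprintf("P%04d", seq_len(n))
  pe <- stats::setNames(rep(1L, n), names(targets))

  novelPeptides <- character(0)
  saavTraps <- character(0)
  if (config$nNovelProteins > 0L) {
    for (i in seq_len(config$nNovelProteins)) {
      acc <- sprintf("N%04d", i)
      prot <- .randomTrypticProtein(max(4L, config$peptidesPerProtein %/% 2L))
      targets[[acc]] <- prot
      pe[[acc]] <- 2L
      novelPeptides <- c(novelPeptides,
                         trypticPeptides(prot, missed = 0L,
                                         minLength = 9L, maxLength = 20L))
    }
    novelPeptides <- unique(novelPeptides)
    # plant SAAV traps: insert a distance-1 copy of a novel peptide into
    # a PE1 protein, flanked by K so the reading frame stays tryptic
    nTrap <- min(config$nSaavTraps, length(novelPeptides))
    if (nTrap > 0L) {
      trapPeps <- novelPeptides[seq_len(nTrap)]
      for (k in seq_len(nTrap)) {
        p <- trapPeps[k]
        pos <- sample(nchar(p), 1L)
        orig <- substring(p, pos, pos)
        repl <- sample(setdiff(names(.RESIDUE_MASS), orig), 1L)
        variant <- paste0(substring(p, 1L, pos - 1L), repl,
                          substring(p, pos + 1L))
        host <- sprintf("P%04d", k)
        targets[[host]] <- paste0(targets[[host]], variant, "K")
      }
      saavTraps <- trapPeps
    }
  }
  decoys <- makeDecoyDb(targets)
  list(targets = targets, decoys = decoys, peLevels = pe,
       novelPeptides = novelPeptides, saavTraps = saavTraps)
}

# deterministic theoretical spectrum of a peptide: singly charged b/y
# ions with reproducible pseudo-random intensities, then optional noise
.syntheticSpectrum <- function(peptide, charge, seed, noise,
                               runId, datasetId, scan, rt) {
  set.seed(seed)
  ions <- .plainByIons(peptide)
  mz <- c(ions$b, ions$y)
  int <- stats::runif(length(mz), 0.2, 1)
  if (noise$dropout > 0) {
    keep <- stats::runif(length(mz)) >= noise$dropout
    if (!any(keep)) keep[1L] <- TRUE
    mz <- mz[keep]; int <- int[keep]
  }
  if (noise$jitter > 0)
    int <- int * exp(stats::rnorm(length(int), 0, noise$jitter))
  if (noise$spurious > 0L) {
    smz <- stats::runif(noise$spurious, 200, 1500)
    sint <- stats::runif(noise$spurious, 0.01, 0.1) * max(int)
    mz <- c(mz, smz); int <- c(int, sint)
  }
  Spectrum(mz, int, precursorMz = peptideMz(peptide, charge),
           precursorCharge = charge, retentionTime = rt,
           runId = runId, datasetId = datasetId, scan = scan)
}

#' Generate a synthetic PSM stream with matching spectra
#'
#' True peptides are drawn from the target digest and receive replicate
#' PSMs with spectra synthesized from their theoretical b/y ions (plus
#' the configured noise) and spectral probabilities from the true-match
#' distribution; decoy peptides are drawn from the decoy digest with
#' random-match probabilities. The stream is a plain data.frame and can
#' be partitioned into batches any way whatsoever: the generated content
#' depends only on the seed, never on the partition.
#'
#' @param config A [fixtureConfig()].
#' @param universe Output of [generateUniverse()].
#' @return List: `psms` (PSM data.frame in the documented dialect),
#'   `store` (named spectrum list), `trueKeys` (precursor keys of
#'   planted true precursors), `universe`.
#' @export
generatePsmStream <- function(config, universe) {
  stopifnot(inherits(config, "FixtureConfig"))
  set.seed(.subSeed(config$seed, "stream"))
  targetDigest <- unique(unlist(lapply(universe$targets, trypticPeptides,
                                       missed = 0L, minLength = 7L,
                                       maxLength = 25L)))
  decoyDigest <- unique(unlist(lapply(universe$decoys, trypticPeptides,
                                      missed = 0L, minLength = 7L,
                                      maxLength = 25L)))
  decoyDigest <- setdiff(decoyDigest, targetDigest)
  truePeps <- sample(targetDigest, min(config$nTruePeptides,
                                       length(targetDigest)))
  decoyPeps <- sample(decoyDigest, min(config$nDecoyPeptides,
                                       length(decoyDigest)))
  datasets <- sprintf("D%02d", seq_len(config$nDatasets))
  runs <- unlist(lapply(datasets, function(d)
    sprintf("%s_run%02d", d, seq_len(config$runsPerDataset))))
  runDataset <- rep(datasets, each = config$runsPerDataset)
  names(runDataset) <- runs

  makePsms <- function(peps, isDecoy) {
    rows <- list()
    for (p in peps) {
      set.seed(.subSeed(config$seed, paste0("psm:", p)))
      nP <- sample(config$psmsPerPrecursor[1]:config$psmsPerPrecursor[2], 1L)
      runSel <- sample(runs, nP, replace = TRUE)
      sp <- if (isDecoy) .logUniform(nP, config$nullScoreRange)
        else .logUniform(nP, config$trueScoreRange)
      rt <- stats::runif(1L, 10, 90)
      rows[[p]] <- data.frame(
        run_id = runSel, scan = NA_integer_,
        dataset_id = unname(runDataset[runSel]),
        search_id = unname(runDataset[runSel]),
        peptide = p, charge = 2L, spectral_probability = sp,
        database_p_value = databasePValue(sp, config$databaseSize),
        is_decoy = isDecoy,
        rt_min = rt + stats::runif(nP, -0.2, 0.2),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  psms <- rbind(makePsms(truePeps, FALSE), makePsms(decoyPeps, TRUE))
  # deterministic scan numbering per run, in (peptide, sp) order
  psms <- psms[order(psms$run_id, psms$peptide,
                     psms$spectral_probability, method = "radix"), ,
               drop = FALSE]
  psms$scan <- stats::ave(seq_len(nrow(psms)), psms$run_id,
                          FUN = seq_along)
  rownames(psms) <- NULL

  store <- list()
  for (i in seq_len(nrow(psms))) {
    s <- .syntheticSpectrum(
      psms$peptide[i], psms$charge[i],
      seed = .subSeed(config$seed, paste0("spec:", psms$run_id[i], ":",
                                          psms$scan[i])),
      noise = config$noise, runId = psms$run_id[i],
      datasetId = psms$dataset_id[i], scan = psms$scan[i],
      rt = psms$rt_min[i])
    store[[paste0(psms$run_id[i], "::", psms$scan[i])]] <- s
  }
  list(psms = psms, store = store,
       trueKeys = precursorKey(truePeps, rep(2L, length(truePeps))),
       universe = universe)
}

#' Generate SILAC light/heavy spectrum pairs
#'
#' Picks K/R-terminated peptides from the target digest and emits, per
#' pair, a light spectrum and a heavy spectrum whose y ions are shifted
#' by the lysine (+8.0142) or arginine (+10.0083) label delta. Retention
#' -time jitter and fragmentation perturbation (a fraction of heavy
#' y-peaks displaced) are controllable so known-concordant and
#' known-discordant pairs can be planted.
#'
#' @param config A [fixtureConfig()] with `silac = TRUE`.
#' @param universe Output of [generateUniverse()].
#' @return List: `psmsLight`, `psmsHeavy` (PSM data.frames), `store`
#'   (spectra for both sides), `planted` (data.frame with each pair's
#'   intended concordance).
#' @export
generateSilacPairs <- function(config, universe) {
  stopifnot(inherits(config, "FixtureConfig"), isTRUE(config$silac))
  set.seed(.subSeed(config$seed, "silac"))
  digest <- unique(unlist(lapply(universe$targets, trypticPeptides,
                                 missed = 0L, minLength = 7L,
                                 maxLength = 20L)))
  eligible <- digest[substring(digest, nchar(digest)) %in% c("K", "R")]
  skipped <- setdiff(digest, eligible)
  if (length(skipped))
    message(length(skipped), " peptide(s) ending in neither K nor R skipped")
  peps <- sample(eligible, min(config$nSilacPairs, length(eligible)))
  deltas <- silacDeltas()
  lightRows <- heavyRows <- list()
  store <- list()
  planted <- list()
  for (k in seq_along(peps)) {
    p <- peps[k]
    set.seed(.subSeed(config$seed, paste0("silacpair:", p)))
    lastRes <- substring(p, nchar(p))
    delta <- deltas[[lastRes]]
    heavyPep <- paste0(substring(p, 1L, nchar(p) - 1L), lastRes,
                       sprintf("(%+.4f)", delta))
    run <- sprintf("SILAC_run%02d", (k - 1L) %% 3L + 1L)
    rt <- stats::runif(1L, 10, 90)
    sp <- .logUniform(2L, config$trueScoreRange)
    rtJit <- config$silacRtJitter
    fragPerturb <- config$silacFragPerturb

    ions <- .plainByIons(p)
    fragSeries <- rep(c("b", "y"), c(length(ions$b), length(ions$y)))
    lightMz <- c(ions$b, ions$y)
    int <- stats::runif(length(lightMz), 0.2, 1)
    heavyMz <- ifelse(fragSeries == "y", lightMz + delta, lightMz)
    heavyInt <- int
    if (fragPerturb > 0) {
      yIdx <- which(fragSeries == "y")
      nPert <- ceiling(fragPerturb * length(yIdx))
      pert <- sample(yIdx, nPert)
      heavyMz[pert] <- heavyMz[pert] + stats::runif(nPert, 3, 7)
      heavyInt[pert] <- stats::runif(nPert, 0.2, 1)
    }
    scanL <- 2L * k - 1L; scanH <- 2L * k
    sL <- Spectrum(lightMz, int, precursorMz = peptideMz(p, 2L),
                   precursorCharge = 2L, retentionTime = rt,
                   runId = run, datasetId = "SILAC", scan = scanL)
    sH <- Spectrum(heavyMz, heavyInt,
                   precursorMz = peptideMz(heavyPep, 2L),
                   precursorCharge = 2L, retentionTime = rt + rtJit,
                   runId = run, datasetId = "SILAC", scan = scanH)
    store[[paste0(run, "::", scanL)]] <- sL
    store[[paste0(run, "::", scanH)]] <- sH
    lightRows[[k]] <- data.frame(
      run_id = run, scan = scanL, dataset_id = "SILAC",
      search_id = "SILAC", peptide = p, charge = 2L,
      spectral_probability = sp[1],
      database_p_value = databasePValue(sp[1], config$databaseSize),
      is_decoy = FALSE, rt_min = rt, stringsAsFactors = FALSE)
    heavyRows[[k]] <- data.frame(
      run_id = run, scan = scanH, dataset_id = "SILAC",
      search_id = "SILAC", peptide = heavyPep, charge = 2L,
      spectral_probability = sp[2],
      database_p_value = databasePValue(sp[2], config$databaseSize),
      is_decoy = FALSE, rt_min = rt + rtJit, stringsAsFactors = FALSE)
    planted[[k]] <- data.frame(
      peptide = p,
      concordant = rtJit <= 1 && fragPerturb == 0,
      stringsAsFactors = FALSE)
  }
  list(psmsLight = do.call(rbind, lightRows),
       psmsHeavy = do.call(rbind, heavyRows),
       store = store, planted = do.call(rbind, planted))
}

#' Simulate a null-dominated precursor score ledger
#'
#' Emits precursor records for error-rate simulations: a planted fraction
#' of true target precursors with spectral probabilities from the
#' true-match distribution, and the rest split evenly between target and
#' decoy precursors drawn i.i.d. from the random-match distribution (so
#' decoy counts estimate the false-target count). Used to measure the
#' realized FDR of the local precursor filter.
#'
#' @param n Total number of precursors.
#' @param trueFraction Fraction of planted true targets.
#' @param seed Integer seed.
#' @param config A [fixtureConfig()] supplying score ranges and N.
#' @return Precursor-record data.frame with an extra `planted_true`
#'   column.
#' @export
generateScoreRecords <- function(n, trueFraction = 0.5, seed = 1L,
                                 config = fixtureConfig(seed = seed)) {
  set.seed(.subSeed(seed, "scorerecords"))
  nTrue <- round(n * trueFraction)
  nNull <- n - nTrue
  nNullDecoy <- nNull %/% 2L
  nNullTarget <- nNull - nNullDecoy
  sp <- c(.logUniform(nTrue, config$trueScoreRange),
          .logUniform(nNullTarget + nNullDecoy, config$nullScoreRange))
  isDecoy <- c(rep(FALSE, nTrue + nNullTarget), rep(TRUE, nNullDecoy))
  plantedTrue <- c(rep(TRUE, nTrue), rep(FALSE, nNullTarget + nNullDecoy))
  len <- sample(7:30, n, replace = TRUE)
  key <- sprintf("SIM%06d/2", seq_len(n))
  data.frame(key = key, peptide = key, charge = 2L,
             best_p_value = databasePValue(sp, config$databaseSize),
             is_decoy = isDecoy, length = len,
             planted_true = plantedTrue, stringsAsFactors = FALSE)
}

#' Simulate planted protein universes for protein-level FDR measurement
#'
#' Generates target/decoy protein pairs: a fraction of targets are true
#' (2-10 uniquely mapped precursors from the true-match distribution);
#' the remaining targets and every decoy get 1-3 precursors from the
#' random-match distribution. Protein scores are the sum over precursors
#' of -log10(database p-value).
#'
#' @param nPairs Number of target/decoy protein pairs.
#' @param trueFraction Fraction of targets planted true.
#' @param seed Integer seed.
#' @param config A [fixtureConfig()].
#' @return data.frame `accession`, `is_decoy`, `score`, `n_precursors`,
#'   `planted_true`.
#' @export
generateProteinScoreSim <- function(nPairs = 500L, trueFraction = 0.5,
                                    seed = 1L,
                                    config = fixtureConfig(seed = seed)) {
  set.seed(.subSeed(seed, "proteinsim"))
  rows <- list()
  for (i in seq_len(nPairs)) {
    acc <- sprintf("P%04d", i)
    isTrue <- stats::runif(1) < trueFraction
    nPrec <- if (isTrue) sample(2:10, 1L) else sample(1:3, 1L)
    sp <- if (isTrue) .logUniform(nPrec, config$trueScoreRange)
      else .logUniform(nPrec, config$nullScoreRange)
    nDec <- sample(1:3, 1L)
    spDec <- .logUniform(nDec, config$nullScoreRange)
    rows[[length(rows) + 1L]] <- data.frame(
      accession = c(acc, paste0("XXX_", acc)),
      is_decoy = c(FALSE, TRUE),
      score = c(sum(-log10(databasePValue(sp, config$databaseSize))),
                sum(-log10(databasePValue(spDec, config$databaseSize)))),
      n_precursors = c(nPrec, nDec),
      planted_true = c(isTrue, FALSE), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic-pool search fixture
#'
#' Emulates a synthetic peptide pool searched against its own tiny
#' database with background runs of knowingly absent peptides: main-run
#' PSMs to pool peptides (true scores) and to the decoy database (null
#' scores), plus background-run PSMs (null scores) some of whose peptides
#' are deliberately also present in the target pool (the exclusion rule's
#' test case). Decoy-definition ground truth is returned alongside.
#'
#' @param seed Integer seed.
#' @param nTargets Pool size (default 1000).
#' @param nBackgroundRuns Number of background runs (default 10).
#' @param nDecoyPsms Main-run decoy-database matches planted.
#' @param nBackgroundPsms Background-run matches planted.
#' @param overlapFraction Fraction of background peptides also present in
#'   the target pool.
#' @param config A [fixtureConfig()].
#' @return List: `psms`, `backgroundRunIds`, `poolTargetPeptides`,
#'   `backgroundPoolPeptides`.
#' @export
generatePoolFixture <- function(seed = 1L, nTargets = 1000L,
                                nBackgroundRuns = 10L, nDecoyPsms = 30L,
                                nBackgroundPsms = 100L,
                                overlapFraction = 0.1,
                                config = fixtureConfig(seed = seed)) {
  set.seed(.subSeed(seed, "pool"))
  interior <- setdiff(names(.RESIDUE_MASS), c("K", "R"))
  mkPep <- function(n) vapply(seq_len(n), function(i)
    paste0(paste(sample(interior, sample(7:14, 1L), replace = TRUE),
                 collapse = ""), sample(c("K", "R"), 1L)), character(1))
  pool <- unique(mkPep(nTargets))
  mainRun <- "POOL_main"
  bgRuns <- sprintf("POOL_bg%02d", seq_len(nBackgroundRuns))
  # main-run true matches: scores interleave across the range so the
  # per-length cut is exercised nontrivially
  spMain <- .logUniform(length(pool), c(1e-15, 1e-4))
  main <- data.frame(
    run_id = mainRun, scan = seq_along(pool), dataset_id = "POOL",
    search_id = "POOL", peptide = pool, charge = 2L,
    spectral_probability = spMain,
    database_p_value = databasePValue(spMain, config$databaseSize),
    is_decoy = FALSE, rt_min = stats::runif(length(pool), 10, 90),
    stringsAsFactors = FALSE)
  spDec <- .logUniform(nDecoyPsms, c(1e-9, 1e-2))
  decoyPeps <- mkPep(nDecoyPsms)
  decoy <- data.frame(
    run_id = mainRun, scan = length(pool) + seq_len(nDecoyPsms),
    dataset_id = "POOL", search_id = "POOL", peptide = decoyPeps,
    charge = 2L, spectral_probability = spDec,
    database_p_value = databasePValue(spDec, config$databaseSize),
    is_decoy = TRUE, rt_min = stats::runif(nDecoyPsms, 10, 90),
    stringsAsFactors = FALSE)
  bgPepsByRun <- list()
  bgRows <- list()
  scan0 <- length(pool) + nDecoyPsms
  for (r in bgRuns) {
    nOverlap <- round(overlapFraction * nBackgroundPsms / nBackgroundRuns)
    nOwn <- max(1L, nBackgroundPsms %/% nBackgroundRuns - nOverlap)
    own <- mkPep(nOwn)
    overlap <- if (nOverlap > 0L) sample(pool, nOverlap) else character(0)
    peps <- c(own, overlap)
    bgPepsByRun[[r]] <- peps
    sp <- .logUniform(length(peps), c(1e-9, 1e-2))
    bgRows[[r]] <- data.frame(
      run_id = r, scan = scan0 + seq_along(peps), dataset_id = "POOL",
      search_id = "POOL", peptide = peps, charge = 2L,
      spectral_probability = sp,
      database_p_value = databasePValue(sp, config$databaseSize),
      is_decoy = FALSE, rt_min = stats::runif(length(peps), 10, 90),
      stringsAsFactors = FALSE)
    scan0 <- scan0 + length(peps)
  }
  psms <- rbind(main, decoy, do.call(rbind, bgRows))
  rownames(psms) <- NULL
  list(psms = psms, backgroundRunIds = bgRuns,
       poolTargetPeptides = pool, backgroundPoolPeptides = bgPepsByRun)
}

#' Write a complete fixture input directory
#'
#' Emits FASTA (targets + decoys), PE levels, PSM TSVs (one per dataset),
#' MGFs (one per run) and a config snapshot -- a self-contained input set
#' for the pipeline.
#'
#' @param config A [fixtureConfig()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
writeFixtureDirectory <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  uni <- generateUniverse(config)
  stream <- generatePsmStream(config, uni)
  writeFastaDb(c(uni$targets, uni$decoys), file.path(dir, "proteins.fasta"))
  utils::write.table(
    data.frame(accession = names(uni$peLevels), pe = uni$peLevels),
    file.path(dir, "pe_levels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (d in unique(stream$psms$dataset_id)) {
    writePsmTable(stream$psms[stream$psms$dataset_id == d, ],
                  file.path(dir, paste0("psms_", d, ".tsv")))
  }
  for (r in unique(stream$psms$run_id)) {
    keys <- paste0(stream$psms$run_id, "::", stream$psms$scan)
    sel <- stream$psms$run_id == r
    writeMgf(stream$store[keys[sel]], file.path(dir, paste0(r, ".mgf")))
  }
  yaml::write_yaml(unclass(config[setdiff(names(config), "noise")]),
                   file.path(dir, "fixture_config.yaml"))
  yaml::write_yaml(config$noise, file.path(dir, "fixture_noise.yaml"))
  writeConstantsFile(file.path(dir, "constants.tsv"))
  invisible(dir)
}
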