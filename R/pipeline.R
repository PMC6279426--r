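#' Protein-by-search occurrence matrix
#'
#' For each search, PSMs passing the library's per-length minimum score
#' cutoff determine the peptides observed; a protein is called in a
#' search when at least one unique peptide (mapping to that protein
#' alone) was observed. The matrix drives proteotypic selection and
#' co-observation analysis.
#'
#' @param psms PSM data.frame (all searches pooled; `search_id` column).
#' @param thresholds Per-length threshold data.frame (`length`,
#'   `max_p_value`), e.g. a built library's thresholds.
#' @param fasta Named character vector of proteins (with decoys).
#' @param equateIL I/L handling for mapping.
#' @return List: `presence` (logical matrix, proteins x searches),
#'   `precursorSearches` (named list: precursor key -> searches in which
#'   it passed), `precursorProteins` (named list: key -> accession for
#'   uniquely mapping precursors).
#' @export
occurrenceMatrix <- function(psms, thresholds, fasta, equateIL = FALSE) {
  if (nrow(psms) == 0L)
    return(list(presence = matrix(FALSE, 0, 0),
                precursorSearches = list(), precursorProteins = list()))
  len <- nchar(unmodifiedSequence(psms$peptide))
  cut <- thresholds$max_p_value[match(len, thresholds$length)]
  keep <- !is.na(cut) & psms$database_p_value <= cut & !psms$is_decoy
  psms <- psms[keep, , drop = FALSE]
  if (nrow(psms) == 0L)
    return(list(presence = matrix(FALSE, 0, 0),
                precursorSearches = list(), precursorProteins = list()))
  key <- precursorKey(psms$peptide, psms$charge)
  recs <- data.frame(key = unique(key), stringsAsFactors = FALSE)
  recs$peptide <- sub("/[0-9]+$", "", recs$key)
  mapping <- mapPrecursorsToProteins(recs, fasta, equateIL = equateIL)
  uniq <- !mapping$shared & !mapping$unmapped
  precProt <- stats::setNames(as.list(mapping$accessions[uniq]),
                              mapping$key[uniq])
  precSearch <- lapply(split(psms$search_id, key), function(s)
    sort(unique(s)))
  searches <- sort(unique(psms$search_id))
  prots <- sort(unique(unlist(precProt)))
  presence <- matrix(FALSE, length(prots), length(searches),
                     dimnames = list(prots, searches))
  for (k in names(precProt)) {
    p <- precProt[[k]]
    presence[p, precSearch[[k]]] <- TRUE
  }
  list(presence = presence, precursorSearches = precSearch,
       precursorProteins = precProt)
}

.manifest <- function(command, inputs, config, counts, outDir) {
  files <- unlist(inputs[vapply(inputs, function(x)
    is.character(x) && all(file.exists(x)), logical(1))], use.names = FALSE)
  if (length(files)) files <- files[!dir.exists(files)] else
    files <- character(0)
  manifest <- list(
    command = command,
    inputs = if (length(files))
      data.frame(path = files, md5 = unname(tools::md5sum(files)),
                 stringsAsFactors = FALSE)
    else data.frame(path = character(0), md5 = character(0)),
    counts = counts)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(config), file.path(outDir, "config.yaml"))
  invisible(manifest)
}

.stageLog <- function(stage, n) {
  message(sprintf("[%s] %d records", stage, n))
}

#' Run a pipeline command
#'
#' One entry point tying the modules into the full build: `"build"` (PSM
#' TSVs + MGFs + FASTA -> state + library), `"augment"` (existing state +
#' a new batch), `"export"` (state -> mgf/sptxt), `"report"` (FDR
#' diagnostics including the naive aggregate FDR), `"proteotypic"`,
#' `"novel"`, `"silac-gold"` and `"fixtures"`. Every run writes a frozen
#' config snapshot and a manifest listing each input file with its
#' checksum; stage-by-stage record counts are logged to stderr.
#'
#' @param command One of build, augment, export, proteotypic, novel,
#'   silac-gold, fixtures, report.
#' @param inputs Named list of input paths/values; see Details in the
#'   package vignette.
#' @param config A [buildConfig()] list.
#' @param outDir Output directory (created).
#' @return Invisibly, a list of outputs (varies by command).
#' @export
runPipeline <- function(command, inputs = list(), config = buildConfig(),
                        outDir = "speclib_out") {
  command <- match.arg(command, c("build", "augment", "export",
                                  "proteotypic", "novel", "silac-gold",
                                  "fixtures", "report"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  loadInputs <- function() {
    store <- list()
    for (m in inputs$mgfs) store <- c(store, readMgf(m))
    psms <- do.call(rbind, lapply(inputs$psm_tsvs, readPsmTable))
    list(psms = psms, store = store)
  }
  filterBatch <- function(psms, store) {
    counts$psms_in <<- nrow(psms); .stageLog("psms_in", nrow(psms))
    psms <- spectrumQualityFilter(psms, store, config)
    counts$quality_filtered <<- nrow(psms)
    .stageLog("quality_filtered", nrow(psms))
    psms <- do.call(rbind, lapply(split(psms, psms$search_id),
                                  psmFdrFilter, alpha = config$psm_fdr))
    rownames(psms) <- NULL
    counts$psm_fdr_filtered <<- nrow(psms)
    .stageLog("psm_fdr_filtered", nrow(psms))
    psms
  }
  finishBuild <- function(state, store) {
    fasta <- readFastaDb(inputs$fasta)
    lib <- buildLibrary(state, fasta, store)
    d <- lib@diagnostics
    for (nm in names(d)) counts[[nm]] <<- d[[nm]]
    .stageLog("library_entries", nrow(lib@entries))
    saveLibraryState(state, file.path(outDir, "state"), store = store)
    exportLibrary(lib, file.path(outDir, "library.mgf"), "mgf")
    writeThresholdTable(lib@thresholds,
                        file.path(outDir, "thresholds.tsv"))
    writeConstantsFile(file.path(outDir, "constants.tsv"))
    lib
  }

  out <- switch(command,
    fixtures = {
      cfg <- do.call(fixtureConfig, inputs[intersect(names(inputs),
                                            names(formals(fixtureConfig)))])
      writeFixtureDirectory(cfg, outDir)
      counts$fixture_seed <- cfg$seed
      outDir
    },
    build = {
      li <- loadInputs()
      psms <- filterBatch(li$psms, li$store)
      state <- updateCandidates(newLibraryState(config), psms,
                                store = li$store)
      finishBuild(state, li$store)
    },
    augment = {
      state <- loadLibraryState(inputs$state_dir)
      store <- attr(state, "store")
      if (is.null(store)) store <- list()
      if (!is.null(inputs$psm_tsvs)) {
        li <- loadInputs()
        psms <- filterBatch(li$psms, li$store)
        store <- c(store, li$store[setdiff(names(li$store), names(store))])
        state <- updateCandidates(state, psms, store = store)
      }
      finishBuild(state, store)
    },
    export = {
      state <- loadLibraryState(inputs$state_dir)
      store <- attr(state, "store")
      fasta <- readFastaDb(inputs$fasta)
      lib <- buildLibrary(state, fasta, store)
      fmt <- if (is.null(inputs$format)) "mgf" else inputs$format
      path <- file.path(outDir, paste0("library.", fmt))
      exportLibrary(lib, path, fmt)
      counts$library_entries <- nrow(lib@entries)
      path
    },
    report = {
      state <- loadLibraryState(inputs$state_dir)
      ledger <- state@ledger
      rep <- list(precursors_in_ledger = nrow(ledger),
                  decoy_precursors = sum(ledger$is_decoy),
                  naive_aggregate_fdr = naiveAggregateFdr(ledger))
      jsonlite::write_json(rep, file.path(outDir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      counts <- utils::modifyList(counts, rep)
      rep
    },
    proteotypic = {
      state <- loadLibraryState(inputs$state_dir)
      store <- attr(state, "store")
      fasta <- readFastaDb(inputs$fasta)
      lib <- buildLibrary(state, fasta, store)
      allPsms <- do.call(rbind, state@candidates)
      occ <- occurrenceMatrix(allPsms, lib@thresholds,
                              c(fasta, makeDecoyDb(fasta,
                                                   config$decoy_prefix)),
                              equateIL = config$equate_il)
      rows <- list()
      for (acc in rownames(occ$presence)) {
        searches <- colnames(occ$presence)[occ$presence[acc, ]]
        precs <- names(occ$precursorProteins)[
          unlist(occ$precursorProteins) == acc]
        ps <- occ$precursorSearches[precs]
        sel <- selectProteotypic(searches, ps,
                                 targetCoverage = config$proteotypic_coverage,
                                 maxPrecursors = config$proteotypic_cap)
        if (length(sel$precursors))
          rows[[acc]] <- data.frame(
            accession = acc, rank = seq_along(sel$precursors),
            precursor = sel$precursors,
            cumulative_coverage = sel$cumulativeCoverage,
            stringsAsFactors = FALSE)
      }
      tab <- do.call(rbind, rows)
      utils::write.table(tab, file.path(outDir, "proteotypic.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      counts$proteins_with_proteotypic <- length(rows)
      tab
    },
    novel = {
      state <- loadLibraryState(inputs$state_dir)
      store <- attr(state, "store")
      fasta <- readFastaDb(inputs$fasta)
      lib <- buildLibrary(state, fasta, store)
      peTab <- utils::read.table(inputs$pe_levels, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
      pe <- stats::setNames(peTab$pe, peTab$accession)
      ent <- lib@entries
      peps <- unique(unmodifiedSequence(ent$peptide[!ent$is_decoy]))
      novel <- callNovelProteins(peps, fasta, pe,
                                 minLength = config$min_novel_peptide_length,
                                 equateIL = config$equate_il)
      utils::write.table(novel, file.path(outDir, "novel_proteins.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      counts$novel_proteins <- nrow(novel)
      novel
    },
    `silac-gold` = {
      store <- list()
      for (m in inputs$mgfs) store <- c(store, readMgf(m))
      light <- readPsmTable(inputs$psms_light)
      heavy <- readPsmTable(inputs$psms_heavy)
      gold <- buildSilacGold(light, heavy, store, config)
      counts$silac_pairs_evaluated <- nrow(gold$pairs)
      counts$silac_entries <- nrow(gold$entries)
      if (nrow(gold$entries)) {
        keys <- paste0(gold$entries$light_run, "::", gold$entries$light_scan)
        writeMgf(lapply(store[keys], normalizeSpectrum),
                 file.path(outDir, "silac_gold.mgf"),
                 sequences = paste0(gold$entries$peptide, "/",
                                    gold$entries$charge))
      }
      utils::write.table(gold$pairs, file.path(outDir, "silac_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      gold
    })
  .manifest(command, inputs, config, counts, outDir)
  invisible(out)
}
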