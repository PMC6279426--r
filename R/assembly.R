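#' Create an empty library build state
#'
#' @param config Build configuration from [buildConfig()].
#' @return An empty [LibraryState-class].
#' @export
newLibraryState <- function(config = buildConfig()) {
  new("LibraryState",
      ledger = data.frame(key = character(0), peptide = character(0),
                          charge = integer(0), best_p_value = numeric(0),
                          is_decoy = logical(0), length = integer(0),
                          best_run_id = character(0), best_scan = integer(0),
                          stringsAsFactors = FALSE),
      candidates = list(), config = config)
}

# apply the per-dataset cap, then the global cap, under the total order
.capCandidates <- function(df, topCandidates, perDatasetCap) {
  df <- df[psmOrder(df), , drop = FALSE]
  withinDataset <- stats::ave(seq_len(nrow(df)), df$dataset_id,
                              FUN = seq_along)
  df <- df[withinDataset <= perDatasetCap, , drop = FALSE]
  df <- utils::head(df, topCandidates)
  rownames(df) <- NULL
  df
}

#' Merge new PSMs into the candidate ledger
#'
#' Every precursor ever seen -- including decoys and precursors below any
#' current threshold -- keeps (i) a ledger row with its best PSM and (ii)
#' a candidate set: the best `top_candidates` PSMs under the total order,
#' with at most `per_dataset_cap` from any one dataset (the per-dataset
#' cap is applied first; both caps are prefix operations under the total
#' order, so the merge is associative and commutative). Duplicate PSMs
#' (same run, scan, search, precursor) are merged away, making the update
#' idempotent as well.
#'
#' @param state A [LibraryState-class].
#' @param psms New PSM batch (data.frame), already quality- and per-search
#'   FDR-filtered.
#' @param store Optional spectrum store (named list keyed
#'   `"<run>::<scan>"`); when given, every PSM must reference a stored
#'   spectrum.
#' @return The updated [LibraryState-class].
#' @export
updateCandidates <- function(state, psms, store = NULL) {
  stopifnot(is(state, "LibraryState"))
  if (nrow(psms) == 0L) return(state)
  validatePsms(psms)
  if (!is.null(store)) {
    ref <- paste0(psms$run_id, "::", psms$scan)
    miss <- ref[!ref %in% names(store)]
    if (length(miss))
      stop("PSM(s) reference missing spectra: ",
           paste(utils::head(unique(miss), 5), collapse = ", "))
  }
  cfg <- state@config
  pep <- canonicalPeptide(psms$peptide)
  psms$peptide <- pep
  key <- paste0(pep, "/", as.integer(psms$charge))
  cand <- state@candidates
  for (k in unique(key)) {
    add <- psms[key == k, , drop = FALSE]
    df <- rbind(cand[[k]], add[, .PSM_COLUMNS])
    dup <- duplicated(df[, c("run_id", "scan", "search_id", "peptide",
                             "charge")])
    df <- df[!dup, , drop = FALSE]
    cand[[k]] <- .capCandidates(df, cfg$top_candidates, cfg$per_dataset_cap)
  }
  # the ledger row for a key is its best PSM; the best PSM is rank 1 of the
  # candidate set (both caps are prefix operations under the total order),
  # so rebuilding touched rows from the merged candidates is order invariant
  ledger <- state@ledger
  ledger <- ledger[!ledger$key %in% unique(key), , drop = FALSE]
  newRows <- lapply(unique(key), function(k) {
    best <- cand[[k]][1L, ]
    data.frame(key = k, peptide = best$peptide,
               charge = as.integer(best$charge),
               best_p_value = best$database_p_value,
               is_decoy = best$is_decoy,
               length = nchar(unmodifiedSequence(best$peptide)),
               best_run_id = best$run_id,
               best_scan = as.integer(best$scan),
               stringsAsFactors = FALSE)
  })
  ledger <- rbind(ledger, do.call(rbind, newRows))
  ledger <- ledger[order(ledger$key, method = "radix"), , drop = FALSE]
  rownames(ledger) <- NULL
  new("LibraryState", ledger = ledger, candidates = cand[order(names(cand))],
      config = cfg)
}

#' Select the representative spectrum of a candidate set
#'
#' The representative is the candidate spectrum with the highest average
#' cosine similarity to all other candidate spectra of the same precursor
#' (the consensus-by-exemplar rule). A single candidate represents itself;
#' ties are broken by the total PSM order.
#'
#' @param candidates Candidate data.frame for one precursor (rows in total
#'   order).
#' @param store Named list of [Spectrum-class] keyed `"<run>::<scan>"`.
#' @param fragmentToleranceDa Cosine match tolerance (default 0.1).
#' @return List: `psm` (the chosen candidate row), `spectrum` (normalized
#'   [Spectrum-class]), `meanCosine`.
#' @export
selectRepresentative <- function(candidates, store,
                                 fragmentToleranceDa = 0.1) {
  refs <- paste0(candidates$run_id, "::", candidates$scan)
  have <- refs %in% names(store)
  if (!any(have)) stop("no retrievable spectra for candidate set")
  candidates <- candidates[have, , drop = FALSE]
  refs <- refs[have]
  specs <- lapply(store[refs], normalizeSpectrum)
  n <- length(specs)
  if (n == 1L) {
    return(list(psm = candidates[1L, , drop = FALSE],
                spectrum = specs[[1L]], meanCosine = NA_real_))
  }
  sim <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sim[i, j] <- sim[j, i] <-
      cosineSimilarity(specs[[i]], specs[[j]], fragmentToleranceDa)
  }
  meanSim <- rowSums(sim) / (n - 1L)
  best <- which(meanSim == max(meanSim))[1L]  # rows are in total order
  list(psm = candidates[best, , drop = FALSE],
       spectrum = specs[[best]], meanCosine = meanSim[best])
}

#' Remove ambiguously identified library spectra
#'
#' A representative spectrum is ambiguous when a re-search offers two or
#' more distinct peptide explanations that each pass the PSM threshold of
#' the spectrum's original search. Alternatives differing only by
#' modification site localization are collapsed to the best-scoring
#' variant before counting. Entries absent from the annotation table are
#' retained and logged.
#'
#' @param entries Library entry data.frame (must carry `key`, `search_id`
#'   and `length` columns).
#' @param candidateAnnotations Named list keyed by entry `key`; each
#'   element a data.frame with `peptide`, `charge`, `database_p_value`
#'   (up to 20 alternative explanations from a re-search).
#' @param searchThresholds Named list keyed by `search_id`; each element a
#'   threshold data.frame (`length`, `max_p_value`) for the entry's
#'   original search.
#' @return The retained entry rows.
#' @export
filterAmbiguous <- function(entries, candidateAnnotations,
                            searchThresholds) {
  if (nrow(entries) == 0L) return(entries)
  keep <- logical(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    k <- entries$key[i]
    ann <- candidateAnnotations[[k]]
    if (is.null(ann)) {
      message("entry ", k, " missing from annotation table; retained")
      keep[i] <- TRUE
      next
    }
    thr <- searchThresholds[[entries$search_id[i]]]
    passes <- vapply(seq_len(nrow(ann)), function(j) {
      L <- nchar(unmodifiedSequence(ann$peptide[j]))
      row <- thr[thr$length == L, , drop = FALSE]
      nrow(row) > 0L && ann$database_p_value[j] <= row$max_p_value[1L]
    }, logical(1))
    ann <- ann[passes, , drop = FALSE]
    if (nrow(ann) >= 2L) {
      grp <- localizationGroup(ann$peptide, ann$charge)
      o <- order(ann$database_p_value, method = "radix")
      ann <- ann[o[!duplicated(grp[o])], , drop = FALSE]
    }
    keep[i] <- nrow(ann) < 2L
  }
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the spectral library from the accumulated state
#'
#' Runs the library-level pipeline on the full precursor ledger:
#' length-binned local precursor FDR, site-localization collapse, protein
#' mapping, picked protein FDR (precursors retained iff they map to at
#' least one accepted protein), representative selection by average
#' cosine, and -- when a re-search annotation table is supplied --
#' ambiguity filtering. Decoy precursors surviving the FDR stages become
#' flagged decoy library entries. Because every stage is a deterministic
#' function of the (order-invariantly merged) state, the exported library
#' is identical for any batch order of the input PSM stream.
#'
#' @param state A populated [LibraryState-class].
#' @param fasta Named character vector of target protein sequences (decoy
#'   entries are appended automatically when absent).
#' @param store Named spectrum list keyed `"<run>::<scan>"`.
#' @param candidateAnnotations Optional re-search annotation table for
#'   [filterAmbiguous()].
#' @param searchThresholds Optional per-search threshold tables (required
#'   when `candidateAnnotations` is given).
#' @return A [SpectralLibrary-class].
#' @export
buildLibrary <- function(state, fasta, store,
                         candidateAnnotations = NULL,
                         searchThresholds = NULL) {
  stopifnot(is(state, "LibraryState"))
  cfg <- state@config
  ledger <- state@ledger
  diag <- list(precursors_in_ledger = nrow(ledger),
               naive_aggregate_fdr = if (nrow(ledger))
                 naiveAggregateFdr(ledger) else NA_real_)
  emptyLib <- function() new("SpectralLibrary",
                             entries = data.frame(), spectra = list(),
                             thresholds = data.frame(length = integer(0),
                                                     max_p_value = numeric(0)),
                             diagnostics = diag)
  if (nrow(ledger) == 0L) return(emptyLib())

  seqs <- .asProteinVector(fasta)
  if (!any(startsWith(names(seqs), cfg$decoy_prefix)))
    seqs <- c(seqs, makeDecoyDb(seqs, cfg$decoy_prefix))

  records <- ledger[, c("key", "peptide", "charge", "best_p_value",
                        "is_decoy", "length")]
  lf <- localPrecursorFdr(records, window = cfg$window,
                          alpha = cfg$local_fdr,
                          windowMode = cfg$window_mode)
  records <- lf$accepted
  diag$post_local_fdr <- nrow(records)
  records <- collapseSiteVariants(records)
  diag$post_localization_collapse <- nrow(records)
  if (nrow(records) == 0L) return(emptyLib())

  mapping <- mapPrecursorsToProteins(records, seqs,
                                     equateIL = cfg$equate_il)
  proteins <- scoreProteins(records, mapping,
                            decoyPrefix = cfg$decoy_prefix)
  acceptedProteins <- pickedProteinFdr(proteins, alpha = cfg$protein_fdr,
                                       decoyPrefix = cfg$decoy_prefix)
  diag$accepted_proteins <- nrow(acceptedProteins)
  accSet <- acceptedProteins$accession
  mapsToAccepted <- vapply(strsplit(mapping$accessions, ",", fixed = TRUE),
                           function(a) any(a %in% accSet), logical(1))
  records <- records[mapsToAccepted, , drop = FALSE]
  mapping <- mapping[mapsToAccepted, , drop = FALSE]
  diag$post_protein_fdr <- nrow(records)
  if (nrow(records) == 0L) return(emptyLib())

  entries <- list(); spectra <- list()
  for (i in seq_len(nrow(records))) {
    k <- records$key[i]
    cand <- state@candidates[[k]]
    rep <- selectRepresentative(cand, store,
                                fragmentToleranceDa = cfg$fragment_tolerance_da)
    prov <- paste0(cand$dataset_id, "|", cand$run_id, "|", cand$scan)
    entries[[length(entries) + 1L]] <- data.frame(
      key = k, peptide = records$peptide[i],
      charge = records$charge[i], is_decoy = records$is_decoy[i],
      length = records$length[i],
      best_p_value = records$best_p_value[i],
      representative_p_value = rep$psm$database_p_value,
      run_id = rep$psm$run_id, scan = rep$psm$scan,
      search_id = rep$psm$search_id,
      protein_accessions = mapping$accessions[i],
      n_psms = nrow(cand),
      n_datasets = length(unique(cand$dataset_id)),
      provenance = paste(sort(prov), collapse = ";"),
      stringsAsFactors = FALSE)
    spectra[[k]] <- rep$spectrum
  }
  entries <- do.call(rbind, entries)
  diag$representatives <- nrow(entries)

  if (!is.null(candidateAnnotations)) {
    entries <- filterAmbiguous(entries, candidateAnnotations,
                               searchThresholds)
    spectra <- spectra[entries$key]
    diag$post_ambiguity_filter <- nrow(entries)
  }

  o <- order(entries$peptide, entries$charge, method = "radix")
  entries <- entries[o, , drop = FALSE]
  rownames(entries) <- NULL
  spectra <- spectra[entries$key]
  diag$library_entries <- nrow(entries)
  diag$decoy_entries <- sum(entries$is_decoy)
  diag$final_decoy_fraction <- if (sum(!entries$is_decoy) > 0)
    sum(entries$is_decoy) / sum(!entries$is_decoy) else NA_real_
  new("SpectralLibrary", entries = entries, spectra = spectra,
      thresholds = lf$thresholds, diagnostics = diag)
}

#' Export a spectral library
#'
#' Writes the library as an annotated MGF (with `SEQ=` and provenance
#' comment lines) or as SpectraST text (`sptxt`). Output is canonical:
#' entries are sorted by (peptide, charge) and floats printed at fixed
#' precision, so identical libraries serialize to identical bytes.
#'
#' @param library A [SpectralLibrary-class].
#' @param path Output file path.
#' @param format `"mgf"` or `"sptxt"`.
#' @return Invisibly, the path.
#' @export
exportLibrary <- function(library, path, format = c("mgf", "sptxt")) {
  format <- match.arg(format)
  entries <- library@entries
  if (format == "mgf") {
    writeMgf(library@spectra, path,
             sequences = if (nrow(entries))
               paste0(entries$peptide, "/", entries$charge) else NULL,
             provenance = if (nrow(entries)) entries$provenance else NULL)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(entries))) {
      s <- library@spectra[[entries$key[i]]]
      ann <- annotatePeaks(s, entries$peptide[i],
                           precursorCharge = entries$charge[i])
      labels <- rep("?", length(s@mz))
      if (nrow(ann)) {
        lab <- paste0(ann$label, ann$index,
                      ifelse(ann$charge > 1, paste0("^", ann$charge), ""))
        firstAnn <- !duplicated(ann$peak)
        labels[ann$peak[firstAnn]] <- lab[firstAnn]
      }
      writeLines(sprintf("Name: %s/%d", entries$peptide[i],
                         entries$charge[i]), con)
      writeLines(sprintf("LibID: %d", i), con)
      mzVal <- if (!is.na(s@precursorMz)) s@precursorMz else
        peptideMz(entries$peptide[i], entries$charge[i])
      writeLines(paste0("PrecursorMZ: ", .fmtNum(mzVal)), con)
      writeLines(sprintf(
        "Comment: Protein=%s Decoy=%d Pvalue=%s Provenance=%s",
        entries$protein_accessions[i], as.integer(entries$is_decoy[i]),
        format(entries$representative_p_value[i], digits = 6,
               scientific = TRUE),
        entries$provenance[i]), con)
      writeLines(sprintf("NumPeaks: %d", length(s@mz)), con)
      writeLines(paste0(.fmtNum(s@mz), "\t", .fmtNum(s@intensity), "\t",
                        labels), con)
      writeLines("", con)
    }
    invisible(path)
  }
}

#' Persist a library state to a directory
#'
#' Writes the ledger TSV, one candidate-set TSV, a config snapshot (YAML)
#' and, when a store is given, the spectra as MGF -- a resumable on-disk
#' layout for incremental builds.
#'
#' @param state A [LibraryState-class].
#' @param dir Output directory (created if needed).
#' @param store Optional spectrum store to persist alongside.
#' @return Invisibly, `dir`.
#' @export
saveLibraryState <- function(state, dir, store = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ledger <- state@ledger
  ledger$best_p_value <- format(ledger$best_p_value, digits = 17,
                                scientific = TRUE, trim = TRUE)
  utils::write.table(ledger, file.path(dir, "ledger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cand <- state@candidates
  if (length(cand)) {
    all <- do.call(rbind, lapply(names(cand), function(k) {
      df <- cand[[k]]; df$key <- k; df
    }))
    all$spectral_probability <- format(all$spectral_probability,
                                       digits = 17, scientific = TRUE,
                                       trim = TRUE)
    all$database_p_value <- format(all$database_p_value, digits = 17,
                                   scientific = TRUE, trim = TRUE)
    utils::write.table(all, file.path(dir, "candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(state@config, file.path(dir, "config.yaml"))
  if (!is.null(store)) writeMgf(store, file.path(dir, "spectra.mgf"))
  invisible(dir)
}

#' Load a persisted library state
#'
#' @param dir Directory written by [saveLibraryState()].
#' @return A [LibraryState-class] (and, when present, the spectra are
#'   attached as attribute `"store"`).
#' @export
loadLibraryState <- function(dir) {
  config <- yaml::read_yaml(file.path(dir, "config.yaml"))
  ledger <- utils::read.table(file.path(dir, "ledger.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  candPath <- file.path(dir, "candidates.tsv")
  cand <- list()
  if (file.exists(candPath) && nrow(ledger)) {
    all <- utils::read.table(candPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    cand <- split(all[, .PSM_COLUMNS], all$key)
    cand <- lapply(cand, function(df) { rownames(df) <- NULL; df })
    cand <- cand[order(names(cand))]
  }
  state <- new("LibraryState", ledger = ledger, candidates = cand,
               config = config)
  mgfPath <- file.path(dir, "spectra.mgf")
  if (file.exists(mgfPath)) attr(state, "store") <- readMgf(mgfPath)
  state
}
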