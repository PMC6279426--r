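#' Build the precursor record table from PSMs
#'
#' Groups PSMs by precursor (canonical peptide string + charge) and keeps
#' each precursor's best (lowest) database p-value, decoy flag and peptide
#' length. This is the unfiltered precursor ledger view on which all
#' library-level error control operates.
#'
#' @param psms PSM data.frame.
#' @return data.frame with columns `key`, `peptide`, `charge`,
#'   `best_p_value`, `is_decoy`, `length`.
#' @export
precursorRecords <- function(psms) {
  if (nrow(psms) == 0L)
    return(data.frame(key = character(0), peptide = character(0),
                      charge = integer(0), best_p_value = numeric(0),
                      is_decoy = logical(0), length = integer(0)))
  pep <- canonicalPeptide(psms$peptide)
  key <- paste0(pep, "/", as.integer(psms$charge))
  o <- psmOrder(psms)
  first <- o[!duplicated(key[o])]
  out <- data.frame(key = key[first], peptide = pep[first],
                    charge = as.integer(psms$charge[first]),
                    best_p_value = psms$database_p_value[first],
                    is_decoy = psms$is_decoy[first],
                    stringsAsFactors = FALSE)
  out$length <- nchar(unmodifiedSequence(out$peptide))
  rownames(out) <- NULL
  out
}

# vectorized window decoy/target ratio at every rank of a sorted bin
.windowFdrAll <- function(isDecoy, w, mode) {
  n <- length(isDecoy)
  i <- seq_len(n)
  if (mode == "trailing") {
    lo <- pmax(1L, i - w + 1L); hi <- i
  } else {
    half <- w %/% 2L
    lo <- pmax(1L, i - half); hi <- pmin(n, i + half)
  }
  cd <- cumsum(isDecoy)
  d <- cd[hi] - c(0L, cd)[lo]
  t <- (hi - lo + 1L) - d
  ifelse(t == 0L, ifelse(d == 0L, 0, Inf), d / t)
}

#' Length-binned sliding-window local precursor FDR filter
#'
#' Precursor records are grouped by peptide length and, within each bin,
#' sorted by increasing database p-value. The local FDR at a record is the
#' decoy/target ratio over the window of `window` surrounding records; the
#' per-bin acceptance threshold is the highest p-value whose window has a
#' local FDR strictly below `alpha`, and all records at or below that
#' threshold are accepted (a score prefix of the bin). Bins smaller than
#' the window use the bin size as the window.
#'
#' Two window readings are provided: `"trailing"` (default) takes the
#' `window` records at better ranks, inclusive of the record itself;
#' `"centered"` takes `window/2` records on each side.
#'
#' @param records Precursor records from [precursorRecords()].
#' @param window Window size (default 500; must be >= 2).
#' @param alpha Local FDR level (default 0.01).
#' @param windowMode `"trailing"` or `"centered"`.
#' @return List with `thresholds` (data.frame `length`, `max_p_value`)
#'   and `accepted` (record rows passing their bin's threshold).
#' @export
localPrecursorFdr <- function(records, window = 500L, alpha = 0.01,
                              windowMode = c("trailing", "centered")) {
  windowMode <- match.arg(windowMode)
  stopifnot(window >= 2L, alpha > 0, alpha < 1)
  if (nrow(records) == 0L)
    return(list(thresholds = data.frame(length = integer(0),
                                        max_p_value = numeric(0)),
                accepted = records))
  keep <- logical(nrow(records))
  thr <- list()
  for (L in sort(unique(records$length))) {
    sel <- which(records$length == L)
    bin <- records[sel, , drop = FALSE]
    o <- order(bin$best_p_value, bin$is_decoy, bin$key, method = "radix")
    bin <- bin[o, , drop = FALSE]
    w <- min(window, nrow(bin))
    fdr <- .windowFdrAll(bin$is_decoy, w, windowMode)
    ok <- which(fdr < alpha)
    cut <- if (length(ok)) max(bin$best_p_value[ok]) else -Inf
    thr[[length(thr) + 1L]] <- data.frame(length = L, max_p_value = cut)
    keep[sel[o][bin$best_p_value <= cut]] <- TRUE
  }
  accepted <- records[keep, , drop = FALSE]
  rownames(accepted) <- NULL
  list(thresholds = do.call(rbind, thr), accepted = accepted)
}

#' Collapse site-localization variants of modified precursors
#'
#' Precursors that differ only in the position of their modifications
#' (same unmodified sequence, same multiset of modification deltas, same
#' charge) are redundant; only the best-scoring variant is kept. Ties are
#' broken by the canonical key.
#'
#' @param records Precursor records.
#' @return The deduplicated records.
#' @export
collapseSiteVariants <- function(records) {
  if (nrow(records) <= 1L) return(records)
  grp <- localizationGroup(records$peptide, records$charge)
  o <- order(records$best_p_value, records$is_decoy, records$key,
             method = "radix")
  keep <- o[!duplicated(grp[o])]
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map precursor peptide sequences onto a protein database
#'
#' Exact substring search of each unmodified peptide sequence against
#' every protein (targets and decoys alike). Precursors hitting more than
#' one accession are marked shared and are excluded from protein scoring;
#' precursors hitting none are flagged unmapped.
#'
#' @param records Precursor records.
#' @param fasta Named character vector or `Biostrings::AAStringSet` of
#'   protein sequences (decoy entries carry the decoy accession prefix).
#' @param equateIL Treat I and L as identical (default FALSE).
#' @return data.frame with columns `key`, `accessions` (comma-separated),
#'   `n_proteins`, `shared`, `unmapped`.
#' @export
mapPrecursorsToProteins <- function(records, fasta, equateIL = FALSE) {
  seqs <- .asProteinVector(fasta)
  if (nrow(records) == 0L)
    return(data.frame(key = character(0), accessions = character(0),
                      n_proteins = integer(0), shared = logical(0),
                      unmapped = logical(0)))
  pep <- unmodifiedSequence(records$peptide)
  if (equateIL) {
    pep <- gsub("I", "L", pep, fixed = TRUE)
    seqs[] <- gsub("I", "L", seqs, fixed = TRUE)
  }
  uniquePep <- unique(pep)
  subj <- Biostrings::AAStringSet(seqs)
  hits <- lapply(uniquePep, function(p) {
    cnt <- Biostrings::vcountPattern(p, subj)
    names(seqs)[cnt > 0L]
  })
  names(hits) <- uniquePep
  acc <- hits[pep]
  n <- lengths(acc)
  data.frame(key = records$key,
             accessions = vapply(acc, function(a)
               paste(sort(a), collapse = ","), character(1)),
             n_proteins = as.integer(n),
             shared = n > 1L, unmapped = n == 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}

.asProteinVector <- function(fasta) {
  if (is(fasta, "AAStringSet")) {
    out <- as.character(fasta)
    names(out) <- sub("\\s.*$", "", names(fasta))
    out
  } else if (is.character(fasta)) {
    if (is.null(names(fasta))) stop("protein sequences must be named")
    fasta
  } else stop("fasta must be an AAStringSet or a named character vector")
}

#' Score proteins from uniquely mapped precursors
#'
#' Each protein is scored by the sum over its uniquely mapped precursors
#' of -log10(database p-value) -- equivalently, one minus the product of
#' those p-values: the score grows as the chance that all the evidence
#' arose randomly shrinks. Shared and unmapped precursors contribute to no
#' protein.
#'
#' @param records Precursor records.
#' @param mapping Output of [mapPrecursorsToProteins()].
#' @param decoyPrefix Accession prefix marking decoys (default `"XXX_"`).
#' @return data.frame `accession`, `is_decoy`, `score`, `n_precursors`.
#' @export
scoreProteins <- function(records, mapping, decoyPrefix = "XXX_") {
  stopifnot(identical(records$key, mapping$key))
  uniq <- !mapping$shared & !mapping$unmapped
  if (!any(uniq))
    return(data.frame(accession = character(0), is_decoy = logical(0),
                      score = numeric(0), n_precursors = integer(0)))
  acc <- mapping$accessions[uniq]
  contrib <- -log10(records$best_p_value[uniq])
  agg <- rowsum(contrib, group = acc, reorder = TRUE)
  cnt <- as.integer(table(acc)[rownames(agg)])
  data.frame(accession = rownames(agg),
             is_decoy = startsWith(rownames(agg), decoyPrefix),
             score = as.numeric(agg[, 1]), n_precursors = cnt,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Picked protein-level FDR
#'
#' Protein-level target-decoy competition: each target accession is paired
#' with its decoy counterpart (`<decoyPrefix><accession>`) and only the
#' higher-scoring member of each pair stays in the ranking (target wins
#' ties); unpaired proteins compete alone. Competitors are sorted by
#' decreasing score and the largest prefix with decoy/target ratio at or
#' below `alpha` is accepted. Accepted accessions include decoy winners in
#' the prefix, flagged, so that decoy precursors can be carried into the
#' library.
#'
#' @param proteins data.frame from [scoreProteins()].
#' @param alpha Protein-level FDR (default 0.01).
#' @param decoyPrefix Decoy accession prefix (default `"XXX_"`).
#' @return data.frame of accepted rows (`accession`, `is_decoy`, `score`).
#' @export
pickedProteinFdr <- function(proteins, alpha = 0.01, decoyPrefix = "XXX_") {
  stopifnot(alpha > 0, alpha < 1)
  if (nrow(proteins) == 0L) return(proteins)
  pairId <- ifelse(proteins$is_decoy,
                   sub(paste0("^", decoyPrefix), "", proteins$accession),
                   proteins$accession)
  o <- order(-proteins$score, proteins$is_decoy, proteins$accession,
             method = "radix")
  picked <- o[!duplicated(pairId[o])]
  comp <- proteins[sort(picked), , drop = FALSE]
  o2 <- order(-comp$score, comp$is_decoy, comp$accession, method = "radix")
  comp <- comp[o2, , drop = FALSE]
  decoys <- cumsum(comp$is_decoy)
  targets <- cumsum(!comp$is_decoy)
  ratio <- ifelse(targets == 0, ifelse(decoys == 0, 0, Inf), decoys / targets)
  ok <- which(ratio <= alpha)
  if (length(ok) == 0L) return(comp[0, , drop = FALSE])
  out <- comp[seq_len(max(ok)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Naive aggregate precursor FDR
#'
#' The decoy/target ratio over the full unfiltered precursor ledger: the
#' error rate one would incur by simply pooling every per-search-filtered
#' PSM without library-level controls. Reported as a diagnostic alongside
#' every build.
#'
#' @param records Precursor records (must carry `is_decoy`).
#' @return Fraction (decoys/targets), or `NA` with a message when there
#'   are no targets.
#' @export
naiveAggregateFdr <- function(records) {
  d <- sum(records$is_decoy)
  t <- sum(!records$is_decoy)
  if (t == 0L) {
    message("naive aggregate FDR undefined: zero target precursors")
    return(NA_real_)
  }
  d / t
}
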