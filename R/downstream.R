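#' Greedy proteotypic precursor selection for one protein
#'
#' Builds the smallest practical set of precursors that covers a protein's
#' observations: repeatedly add the precursor covering the greatest number
#' of the protein's searches not already covered, until the target
#' coverage fraction is reached or the cap is hit. Each added precursor
#' strictly increases coverage. Ties are broken by the supplied precursor
#' ranking (best p-value first), then by precursor key.
#'
#' @param proteinSearches Character vector: searches in which the protein
#'   was observed.
#' @param precursorSearches Named list: precursor key -> character vector
#'   of searches in which that precursor passed the library score cutoff
#'   (each a subset of `proteinSearches`).
#' @param targetCoverage Stop once this fraction of the protein's searches
#'   is covered (default 0.9).
#' @param maxPrecursors Cap on the set size (default 20).
#' @param precursorRank Optional named numeric (e.g. best p-values) used
#'   to break coverage ties; lower is better.
#' @return List with `precursors` (ordered keys), `coverage` (fraction)
#'   and `cumulativeCoverage` (per added precursor).
#' @export
selectProteotypic <- function(proteinSearches, precursorSearches,
                              targetCoverage = 0.9, maxPrecursors = 20L,
                              precursorRank = NULL) {
  if (length(proteinSearches) == 0L)
    stop("protein with zero searches: proteotypic selection undefined")
  proteinSearches <- unique(proteinSearches)
  uncovered <- proteinSearches
  total <- length(proteinSearches)
  keys <- names(precursorSearches)
  if (is.null(precursorRank))
    precursorRank <- stats::setNames(rep(0, length(keys)), keys)
  chosen <- character(0)
  cumCov <- numeric(0)
  while ((total - length(uncovered)) / total < targetCoverage - 1e-12 &&
         length(chosen) < maxPrecursors) {
    gain <- vapply(keys, function(k)
      length(intersect(precursorSearches[[k]], uncovered)), integer(1))
    if (!length(gain) || max(gain) == 0L) break
    o <- order(-gain, precursorRank[keys], keys, method = "radix")
    pick <- keys[o[1L]]
    chosen <- c(chosen, pick)
    uncovered <- setdiff(uncovered, precursorSearches[[pick]])
    cumCov <- c(cumCov, 1 - length(uncovered) / total)
    keys <- setdiff(keys, pick)
  }
  list(precursors = chosen,
       coverage = if (length(cumCov)) cumCov[length(cumCov)] else 0,
       cumulativeCoverage = cumCov)
}

#' Co-observed protein pairs and their proteotypic detectability
#'
#' In affinity-purification pulldowns, two proteins accepted in the same
#' search are co-observed (a possible interaction). A co-observation is
#' detectable by proteotypic precursors if each of the two proteins has at
#' least one of its proteotypic precursors among that search's accepted
#' precursors.
#'
#' @param perSearchProteins Named list: search id -> accepted accessions.
#' @param proteotypicSets Named list: accession -> precursor keys (from
#'   [selectProteotypic()]).
#' @param precursorHits Named list: search id -> accepted precursor keys.
#' @return data.frame `search`, `proteinA`, `proteinB`, `detectable`
#'   (one row per unordered co-observed pair per search).
#' @export
detectInteractions <- function(perSearchProteins, proteotypicSets,
                               precursorHits) {
  rows <- list()
  for (srch in names(perSearchProteins)) {
    prots <- sort(unique(perSearchProteins[[srch]]))
    if (length(prots) < 2L) next
    hits <- precursorHits[[srch]]
    protDetect <- vapply(prots, function(p)
      length(intersect(proteotypicSets[[p]], hits)) > 0L, logical(1))
    idx <- utils::combn(length(prots), 2L)
    rows[[length(rows) + 1L]] <- data.frame(
      search = srch, proteinA = prots[idx[1L, ]],
      proteinB = prots[idx[2L, ]],
      detectable = protDetect[idx[1L, ]] & protDetect[idx[2L, ]],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(search = character(0), proteinA = character(0),
                      proteinB = character(0), detectable = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Is a peptide a single-amino-acid variant of a known protein?
#'
#' TRUE when some protein with established evidence (PE1) contains a
#' substring of equal length at Hamming distance at most 1 from the
#' peptide (distance 0 means the peptide maps to a PE1 protein outright).
#' Such peptides are excluded from novel-protein evidence.
#'
#' @param peptide Plain peptide sequence.
#' @param pe1Sequences Character vector (or `AAStringSet`) of PE1 protein
#'   sequences.
#' @param equateIL Treat I and L as identical (default FALSE).
#' @return Logical.
#' @export
isSaavOfPe1 <- function(peptide, pe1Sequences, equateIL = FALSE) {
  if (length(pe1Sequences) == 0L) return(FALSE)
  seqs <- if (is(pe1Sequences, "AAStringSet"))
    as.character(pe1Sequences) else as.character(pe1Sequences)
  if (equateIL) {
    peptide <- gsub("I", "L", peptide, fixed = TRUE)
    seqs <- gsub("I", "L", seqs, fixed = TRUE)
  }
  subj <- Biostrings::AAStringSet(unname(seqs))
  any(Biostrings::vcountPattern(peptide, subj, max.mismatch = 1L) > 0L)
}

#' Call novel proteins from accepted peptide evidence
#'
#' Applies the reporting guideline for proteins lacking prior protein
#' -level evidence (protein-existence classes PE2-PE5): peptides must be
#' at least `minLength` residues, peptides that are an exact substring of
#' -- or a single-amino-acid variant of -- any PE1 protein are excluded,
#' and a PE2-5 protein is called only when at least two of its remaining
#' peptides occupy non-overlapping (disjoint) coordinate spans in the
#' protein. Accessions missing a PE annotation are conservatively treated
#' as PE1 and logged.
#'
#' @param peptides Character vector of accepted (unmodified) peptide
#'   sequences.
#' @param fasta Named character vector of target protein sequences.
#' @param peLevels Named integer/character vector: accession -> PE level
#'   (1..5, `"PE2"` style accepted).
#' @param minLength Minimum peptide length (default 9).
#' @param equateIL I/L handling for the SAAV scan (default FALSE).
#' @return data.frame `accession`, `pe_level`, `n_peptides`, `peptides`
#'   (semicolon list with spans), one row per called protein.
#' @export
callNovelProteins <- function(peptides, fasta, peLevels, minLength = 9L,
                              equateIL = FALSE) {
  seqs <- .asProteinVector(fasta)
  pe <- .normalizePeLevels(peLevels, names(seqs))
  pe1 <- seqs[pe == 1L]
  novelProt <- seqs[pe >= 2L]
  peptides <- unique(peptides[nchar(peptides) >= minLength])
  if (!length(peptides) || !length(novelProt))
    return(data.frame(accession = character(0), pe_level = integer(0),
                      n_peptides = integer(0), peptides = character(0)))
  saav <- vapply(peptides, isSaavOfPe1, logical(1),
                 pe1Sequences = pe1, equateIL = equateIL)
  peptides <- peptides[!saav]
  rows <- list()
  for (acc in names(novelProt)) {
    spans <- list()
    for (p in peptides) {
      m <- Biostrings::matchPattern(p, Biostrings::AAString(novelProt[[acc]]))
      if (length(m))
        spans[[p]] <- cbind(start = Biostrings::start(m),
                            end = Biostrings::end(m))
    }
    if (length(spans) < 2L) next
    if (!.hasDisjointPair(spans)) next
    desc <- vapply(names(spans), function(p)
      sprintf("%s[%d,%d]", p, spans[[p]][1, "start"], spans[[p]][1, "end"]),
      character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      accession = acc, pe_level = pe[[acc]],
      n_peptides = length(spans),
      peptides = paste(sort(desc), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(accession = character(0), pe_level = integer(0),
                      n_peptides = integer(0), peptides = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.normalizePeLevels <- function(peLevels, accessions) {
  lv <- rep(1L, length(accessions))
  names(lv) <- accessions
  if (length(peLevels)) {
    vals <- as.integer(gsub("PE", "", as.character(peLevels), fixed = TRUE))
    known <- intersect(names(peLevels), accessions)
    lv[known] <- vals[match(known, names(peLevels))]
  }
  missing <- setdiff(accessions, names(peLevels))
  if (length(peLevels) && length(missing))
    message(length(missing), " accession(s) missing PE annotation; treated as PE1")
  lv
}

# do >=2 peptides admit disjoint placements? spans: named list of matrices
.hasDisjointPair <- function(spans) {
  peps <- names(spans)
  for (i in seq_len(length(peps) - 1L)) for (j in (i + 1L):length(peps)) {
    a <- spans[[i]]; b <- spans[[j]]
    for (ra in seq_len(nrow(a))) for (rb in seq_len(nrow(b))) {
      if (a[ra, "end"] < b[rb, "start"] || b[rb, "end"] < a[ra, "start"])
        return(TRUE)
    }
  }
  FALSE
}

#' Build a SILAC light/heavy gold-standard library
#'
#' Metabolic labelling produces light and heavy versions of the same
#' peptide that co-elute and fragment identically up to a fixed y-ion mass
#' shift (+8.0142 Da on K, +10.0083 Da on R). Concordant pairs -- same
#' sequence modulo the label, shift-aligned cosine above the gate,
#' explained intensity above the gate in both spectra, retention times
#' within one minute -- give a high-confidence reference library: the
#' light member of each concordant pair is eligible and the lowest
#' database p-value spectrum per precursor becomes its representative.
#' Pairing is done within the same run (co-elution), and the output is
#' independent of the order of the light/heavy input tables.
#'
#' @param psmsLight,psmsHeavy PSM data.frames at <= 1% FDR; heavy peptides
#'   carry the SILAC deltas as inline modifications.
#' @param store Spectrum store keyed `"<run>::<scan>"`.
#' @param config A [buildConfig()] list supplying the three gates.
#' @return List with `entries` (data.frame of representative light PSMs
#'   per precursor) and `pairs` (every evaluated pair with its gate
#'   values and concordance flag).
#' @export
buildSilacGold <- function(psmsLight, psmsHeavy, store,
                           config = buildConfig()) {
  deltas <- silacDeltas()
  stripSilac <- function(pep) {
    p <- parsePeptide(pep)
    if (!length(p$positions)) return(canonicalPeptide(pep))
    res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
    keep <- !vapply(seq_along(p$positions), function(k) {
      pos <- p$positions[k]
      pos >= 1L && res[pos] %in% names(deltas) &&
        abs(p$deltas[k] - deltas[[res[pos]]]) < 1e-3
    }, logical(1))
    .formatPeptide(p$sequence, p$positions[keep], p$deltas[keep])
  }
  pairRows <- list()
  baseHeavy <- vapply(psmsHeavy$peptide, stripSilac, character(1))
  baseLight <- canonicalPeptide(psmsLight$peptide)
  oL <- psmOrder(psmsLight); oH <- psmOrder(psmsHeavy)
  psmsLight <- psmsLight[oL, , drop = FALSE]; baseLight <- baseLight[oL]
  psmsHeavy <- psmsHeavy[oH, , drop = FALSE]; baseHeavy <- baseHeavy[oH]
  for (i in seq_len(nrow(psmsLight))) {
    candidates <- which(baseHeavy == baseLight[i] &
                          psmsHeavy$run_id == psmsLight$run_id[i])
    for (j in candidates) {
      if (psmsHeavy$charge[j] != psmsLight$charge[i]) {
        message("charge mismatch for ", baseLight[i], "; pair skipped")
        next
      }
      sL <- store[[paste0(psmsLight$run_id[i], "::", psmsLight$scan[i])]]
      sH <- store[[paste0(psmsHeavy$run_id[j], "::", psmsHeavy$scan[j])]]
      if (is.null(sL) || is.null(sH)) next
      sLn <- normalizeSpectrum(sL); sHn <- normalizeSpectrum(sH)
      z <- psmsLight$charge[i]
      delta <- peptideNeutralMass(psmsHeavy$peptide[j]) -
        peptideNeutralMass(psmsLight$peptide[i])
      ac <- alignedCosine(sLn, sHn, parentMassDelta = delta,
                          fragmentToleranceDa = config$fragment_tolerance_da)
      eiL <- explainedIntensity(sLn, annotatePeaks(
        sLn, psmsLight$peptide[i], precursorCharge = z,
        fragmentToleranceDa = config$fragment_tolerance_da))
      eiH <- explainedIntensity(sHn, annotatePeaks(
        sHn, psmsHeavy$peptide[j], precursorCharge = z,
        fragmentToleranceDa = config$fragment_tolerance_da))
      rtd <- abs(psmsLight$rt_min[i] - psmsHeavy$rt_min[j])
      concordant <- ac > config$silac_min_cosine &&
        eiL > config$silac_min_explained &&
        eiH > config$silac_min_explained &&
        rtd <= config$silac_max_rt_delta
      pairRows[[length(pairRows) + 1L]] <- data.frame(
        light_run = psmsLight$run_id[i], light_scan = psmsLight$scan[i],
        heavy_run = psmsHeavy$run_id[j], heavy_scan = psmsHeavy$scan[j],
        peptide = baseLight[i], charge = z,
        aligned_cosine = ac, explained_light = eiL, explained_heavy = eiH,
        rt_delta = rtd, concordant = concordant,
        light_p_value = psmsLight$database_p_value[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pairRows))
    return(list(entries = data.frame(), pairs = data.frame()))
  pairs <- do.call(rbind, pairRows)
  o <- order(pairs$peptide, pairs$charge, pairs$light_run,
             pairs$light_scan, pairs$heavy_run, pairs$heavy_scan,
             method = "radix")
  pairs <- pairs[o, , drop = FALSE]
  rownames(pairs) <- NULL
  conc <- pairs[pairs$concordant, , drop = FALSE]
  if (nrow(conc) == 0L) return(list(entries = conc, pairs = pairs))
  key <- paste0(conc$peptide, "/", conc$charge)
  o2 <- order(conc$light_p_value, conc$light_run, conc$light_scan,
              method = "radix")
  entries <- conc[o2[!duplicated(key[o2])], , drop = FALSE]
  entries <- entries[order(entries$peptide, entries$charge,
                           method = "radix"), , drop = FALSE]
  rownames(entries) <- NULL
  list(entries = entries, pairs = pairs)
}
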