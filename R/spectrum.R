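#' Rescale a spectrum to unit Euclidean norm
#'
#' Fragment intensities are rescaled so that the sum of squared intensities
#' equals 1; m/z values and peak order are untouched. Idempotent.
#'
#' @param spectrum A [Spectrum-class].
#' @return The normalized [Spectrum-class].
#' @export
#' @examples
#' s <- Spectrum(c(100, 200), c(3, 4))
#' peakIntensity(normalizeSpectrum(s))  # 0.6 0.8
normalizeSpectrum <- function(spectrum) {
  stopifnot(is(spectrum, "Spectrum"))
  nrm <- sqrt(sum(spectrum@intensity^2))
  if (length(spectrum@mz) == 0L || nrm == 0)
    stop("invalid-spectrum: cannot normalize an empty or all-zero spectrum")
  spectrum@intensity <- spectrum@intensity / nrm
  spectrum
}

.isNormalized <- function(spectrum, tol = 1e-6) {
  abs(sum(spectrum@intensity^2) - 1) <= tol
}

#' Theoretical fragment ions of a peptide
#'
#' Enumerates the standard ion ladder for a peptide: b and y ions (plain,
#' first isotope, H2O loss, NH3 loss) and plain a ions, at every fragment
#' charge from 1 up to `maxCharge`. Masses are monoisotopic; modification
#' deltas are added to the fragments containing the modified residue
#' (N-terminal modifications ride on b/a ions).
#'
#' @param peptide Modified peptide string.
#' @param maxCharge Highest fragment charge to enumerate (usually the
#'   precursor charge).
#' @return data.frame with columns `series` ("b","y","a"), `index`
#'   (fragment ordinal), `charge`, `isotope` (0/1), `loss`
#'   ("none","H2O","NH3"), `label` and `mz`.
#' @export
theoreticalFragments <- function(peptide, maxCharge = 1L) {
  parsed <- parsePeptide(peptide)
  res <- strsplit(parsed$sequence, "", fixed = TRUE)[[1]]
  L <- length(res)
  if (L < 2L) {
    return(data.frame(series = character(0), index = integer(0),
                      charge = integer(0), isotope = integer(0),
                      loss = character(0), label = character(0),
                      mz = numeric(0)))
  }
  ladder <- .fragmentLadder(parsed)
  bNeutral <- ladder$b; yNeutral <- ladder$y
  idx <- seq_len(L - 1L)
  m <- L - 1L

  vIso <- c(0L, 1L, 0L, 0L)
  vLoss <- c("none", "none", "H2O", "NH3")
  vLossMass <- c(0, 0, .H2O_MASS, .NH3_MASS)
  vSuffix <- c("", "-isotope", "-H2O", "-NH3")
  nz <- max(1L, as.integer(maxCharge))
  perZ <- 9L * m  # 4 b-variants + 4 y-variants + a
  n <- nz * perZ
  series <- character(n); label <- character(n); loss <- character(n)
  index <- integer(n); charge <- integer(n); isotope <- integer(n)
  mz <- numeric(n)
  at <- 0L
  for (z in seq_len(nz)) {
    for (v in 1:4) {
      sl <- at + seq_len(m)
      series[sl] <- "b"; index[sl] <- idx; charge[sl] <- z
      isotope[sl] <- vIso[v]; loss[sl] <- vLoss[v]
      label[sl] <- paste0("b", vSuffix[v])
      mz[sl] <- (bNeutral - vLossMass[v] + z * .PROTON_MASS +
                   vIso[v] * .C13_DELTA) / z
      at <- at + m
      sl <- at + seq_len(m)
      series[sl] <- "y"; index[sl] <- idx; charge[sl] <- z
      isotope[sl] <- vIso[v]; loss[sl] <- vLoss[v]
      label[sl] <- paste0("y", vSuffix[v])
      mz[sl] <- (yNeutral - vLossMass[v] + z * .PROTON_MASS +
                   vIso[v] * .C13_DELTA) / z
      at <- at + m
    }
    sl <- at + seq_len(m)
    series[sl] <- "a"; index[sl] <- idx; charge[sl] <- z
    isotope[sl] <- 0L; loss[sl] <- "none"; label[sl] <- "a"
    mz[sl] <- (bNeutral - .CO_MASS + z * .PROTON_MASS) / z
    at <- at + m
  }
  data.frame(series = series, index = index, charge = charge,
             isotope = isotope, loss = loss, label = label, mz = mz,
             stringsAsFactors = FALSE)
}

# neutral b/y fragment ladders of a parsed peptide
.fragmentLadder <- function(parsed) {
  res <- strsplit(parsed$sequence, "", fixed = TRUE)[[1]]
  L <- length(res)
  rmass <- unname(.RESIDUE_MASS[res])
  if (length(parsed$positions)) {
    pos <- pmax(parsed$positions, 1L)  # N-term rides on residue 1
    for (k in seq_along(pos)) rmass[pos[k]] <- rmass[pos[k]] + parsed$deltas[k]
  }
  prefix <- cumsum(rmass)
  idx <- seq_len(L - 1L)
  list(b = prefix[idx],
       y = rev(prefix[L] - prefix[idx] + .H2O_MASS))
}

# singly-charged plain b/y m/z values (fast path for spectrum synthesis)
.plainByIons <- function(peptide) {
  ladder <- .fragmentLadder(parsePeptide(peptide))
  list(b = ladder$b + .PROTON_MASS, y = ladder$y + .PROTON_MASS)
}

#' Annotate observed peaks with theoretical fragment ions
#'
#' Every theoretical b/y/a ion (including first isotopes and H2O/NH3
#' losses for b/y, at fragment charges 1..`precursorCharge`) lying within
#' the fragment tolerance of an observed peak yields one annotation,
#' matched to the closest such peak. One observed peak may carry several
#' annotations.
#'
#' @param spectrum A [Spectrum-class].
#' @param peptide Modified peptide string.
#' @param precursorCharge Maximum fragment charge considered; defaults to
#'   the spectrum's precursor charge.
#' @param fragmentToleranceDa Match tolerance in Da (default 0.1).
#' @return data.frame with one row per annotation: `series`, `index`,
#'   `charge`, `isotope`, `loss`, `label`, `theoreticalMz`, `peak`
#'   (index into the spectrum's peaks), `observedMz`.
#' @export
annotatePeaks <- function(spectrum, peptide,
                          precursorCharge = NULL,
                          fragmentToleranceDa = 0.1) {
  stopifnot(is(spectrum, "Spectrum"), fragmentToleranceDa > 0)
  if (is.null(precursorCharge)) precursorCharge <- spectrum@precursorCharge
  frags <- theoreticalFragments(peptide, maxCharge = precursorCharge)
  empty <- data.frame(series = character(0), index = integer(0),
                      charge = integer(0), isotope = integer(0),
                      loss = character(0), label = character(0),
                      theoreticalMz = numeric(0), peak = integer(0),
                      observedMz = numeric(0))
  if (length(spectrum@mz) == 0L || nrow(frags) == 0L) return(empty)
  mz <- spectrum@mz
  # nearest observed peak to each theoretical mass
  pos <- findInterval(frags$mz, mz)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(mz))
  dLo <- abs(frags$mz - mz[lo])
  dHi <- abs(frags$mz - mz[hi])
  nearest <- ifelse(dLo <= dHi, lo, hi)
  dist <- pmin(dLo, dHi)
  hit <- dist <= fragmentToleranceDa
  if (!any(hit)) return(empty)
  out <- frags[hit, , drop = FALSE]
  out$theoreticalMz <- out$mz
  out$mz <- NULL
  out$peak <- nearest[hit]
  out$observedMz <- mz[out$peak]
  rownames(out) <- NULL
  out
}

#' Fraction of fragment intensity explained by annotated peaks
#'
#' The sum of intensities of peaks carrying at least one annotation,
#' divided by the total intensity. Each peak counts once however many
#' annotations it carries; the value is invariant under global intensity
#' rescaling.
#'
#' @param spectrum A [Spectrum-class].
#' @param annotations Annotation data.frame from [annotatePeaks()].
#' @return Fraction in \[0, 1\].
#' @export
explainedIntensity <- function(spectrum, annotations) {
  stopifnot(is(spectrum, "Spectrum"))
  total <- sum(spectrum@intensity)
  if (length(spectrum@mz) == 0L || total == 0)
    stop("invalid-spectrum: explained intensity undefined for an empty spectrum")
  if (NROW(annotations) == 0L) return(0)
  sum(spectrum@intensity[unique(annotations$peak)]) / total
}

#' Precursor mass-accuracy filter
#'
#' Keeps a PSM if the observed neutral precursor mass is within `maxPpm`
#' parts per million of the peptide's theoretical neutral mass, optionally
#' after subtracting one 13C isotope spacing (1.00335 Da) from the observed
#' neutral mass. Neutral mass convention: `mz * z - z * proton`; ppm is
#' computed on neutral masses.
#'
#' @param observedMz Observed precursor m/z (Da).
#' @param charge Precursor charge (positive integer).
#' @param peptide Modified peptide string.
#' @param maxPpm Tolerance in ppm (default 50).
#' @param allowC13 Permit a one-isotope correction (default TRUE).
#' @return Logical: `TRUE` to keep, `FALSE` to discard.
#' @export
precursorMassFilter <- function(observedMz, charge, peptide,
                                maxPpm = 50, allowC13 = TRUE) {
  stopifnot(maxPpm > 0)
  if (any(charge <= 0)) stop("charge must be positive")
  theo <- peptideNeutralMass(peptide)
  obs <- observedMz * charge - charge * .PROTON_MASS
  shifts <- if (allowC13) c(0, .C13_DELTA) else 0
  dev <- vapply(shifts, function(s) abs((obs - s - theo) / theo) * 1e6,
                numeric(length(obs)))
  dev <- matrix(dev, nrow = length(obs))
  apply(dev, 1L, min) <= maxPpm
}

# Greedy / exact one-to-one matching over candidate peak pairs.
# pairs: data.frame(i, j, w). Returns the selected rows.
.matchPairs <- function(pairs, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (nrow(pairs) == 0L) return(pairs[0, , drop = FALSE])
  if (method == "greedy") {
    o <- order(-pairs$w, pairs$i, pairs$j)
    pairs <- pairs[o, , drop = FALSE]
    usedI <- logical(max(pairs$i)); usedJ <- logical(max(pairs$j))
    keep <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (!usedI[i] && !usedJ[j]) {
        keep[k] <- TRUE; usedI[i] <- TRUE; usedJ[j] <- TRUE
      }
    }
    pairs[keep, , drop = FALSE]
  } else {
    # exact maximum-weight matching by branch and bound over pairs sorted
    # by weight; intended for small instances (oracle/verification use)
    o <- order(-pairs$w, pairs$i, pairs$j)
    pairs <- pairs[o, , drop = FALSE]
    n <- nrow(pairs)
    best <- list(score = -Inf, sel = logical(n))
    suffixMax <- rev(cumsum(rev(pairs$w)))
    recurse <- function(k, usedI, usedJ, score, sel) {
      if (score + (if (k <= n) suffixMax[k] else 0) <= best$score) return()
      if (k > n) {
        if (score > best$score) best <<- list(score = score, sel = sel)
        return()
      }
      i <- pairs$i[k]; j <- pairs$j[k]
      if (!(i %in% usedI) && !(j %in% usedJ)) {
        sel[k] <- TRUE
        recurse(k + 1L, c(usedI, i), c(usedJ, j), score + pairs$w[k], sel)
        sel[k] <- FALSE
      }
      recurse(k + 1L, usedI, usedJ, score, sel)
    }
    recurse(1L, integer(0), integer(0), 0, logical(n))
    pairs[best$sel, , drop = FALSE]
  }
}

.candidatePairs <- function(mzA, intA, mzB, intB, tol, shift = 0) {
  # pairs (i, j) with |mzB[j] - mzA[i] - shift| <= tol
  if (!length(mzA) || !length(mzB))
    return(data.frame(i = integer(0), j = integer(0), w = numeric(0)))
  target <- mzA + shift
  loIdx <- findInterval(target - tol, mzB)          # last B below window
  hiIdx <- findInterval(target + tol + 1e-12, mzB)  # last B inside window
  counts <- hiIdx - loIdx
  if (all(counts <= 0))
    return(data.frame(i = integer(0), j = integer(0), w = numeric(0)))
  i <- rep.int(seq_along(mzA), pmax(counts, 0L))
  j <- unlist(lapply(seq_along(mzA), function(k)
    if (counts[k] > 0L) (loIdx[k] + 1L):hiIdx[k] else integer(0)))
  keep <- abs(mzB[j] - target[i]) <= tol
  data.frame(i = i[keep], j = j[keep], w = intA[i[keep]] * intB[j[keep]])
}

#' Cosine similarity between two normalized spectra
#'
#' Peaks are matched one-to-one within the fragment tolerance; the
#' similarity is the sum of products of matched intensities. The default
#' matching is greedy by descending intensity product (deterministic and
#' symmetric); an exact maximum-weight matching mode is provided for
#' verification on small spectra.
#'
#' @param a,b Normalized [Spectrum-class] objects.
#' @param fragmentToleranceDa Match tolerance in Da (default 0.1).
#' @param method "greedy" (default) or "optimal" (exact assignment,
#'   small spectra only).
#' @param normalize If `TRUE`, normalize inputs first; if `FALSE`
#'   (default), unnormalized input is an error.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' a <- normalizeSpectrum(Spectrum(c(100, 200, 300), c(1, 2, 3)))
#' cosineSimilarity(a, a)
cosineSimilarity <- function(a, b, fragmentToleranceDa = 0.1,
                             method = c("greedy", "optimal"),
                             normalize = FALSE) {
  stopifnot(is(a, "Spectrum"), is(b, "Spectrum"))
  if (normalize) { a <- normalizeSpectrum(a); b <- normalizeSpectrum(b) }
  if (!.isNormalized(a) || !.isNormalized(b))
    stop("spectra must be normalized to unit Euclidean norm (see normalizeSpectrum)")
  pairs <- .candidatePairs(a@mz, a@intensity, b@mz, b@intensity,
                           fragmentToleranceDa)
  sel <- .matchPairs(pairs, method = match.arg(method))
  min(1, sum(sel$w))
}

#' Shift-aligned cosine similarity between light and heavy spectra
#'
#' For isotopically labelled pairs, each light peak may match a heavy peak
#' at the same mass or offset by `parentMassDelta / z` for any fragment
#' charge z up to the precursor charge; the alignment maximizing the
#' cosine score is used. Because a zero shift is always admissible,
#' `alignedCosine(a, b) >= cosineSimilarity(a, b)`.
#'
#' @param light,heavy Normalized [Spectrum-class] objects.
#' @param parentMassDelta Neutral precursor mass difference (Da). If
#'   `NULL`, derived from the two spectra's precursor m/z and charges.
#' @param fragmentToleranceDa Match tolerance in Da (default 0.1).
#' @param method Matching mode as in [cosineSimilarity()].
#' @param normalize Normalize inputs first (default FALSE).
#' @return Similarity in \[0, 1\].
#' @export
alignedCosine <- function(light, heavy, parentMassDelta = NULL,
                          fragmentToleranceDa = 0.1,
                          method = c("greedy", "optimal"),
                          normalize = FALSE) {
  stopifnot(is(light, "Spectrum"), is(heavy, "Spectrum"))
  if (normalize) { light <- normalizeSpectrum(light); heavy <- normalizeSpectrum(heavy) }
  if (!.isNormalized(light) || !.isNormalized(heavy))
    stop("spectra must be normalized to unit Euclidean norm (see normalizeSpectrum)")
  if (is.null(parentMassDelta)) {
    if (is.na(light@precursorMz) || is.na(heavy@precursorMz))
      stop("parentMassDelta not given and precursor m/z unavailable")
    parentMassDelta <-
      (heavy@precursorMz * heavy@precursorCharge -
         heavy@precursorCharge * .PROTON_MASS) -
      (light@precursorMz * light@precursorCharge -
         light@precursorCharge * .PROTON_MASS)
  }
  zmax <- max(1L, light@precursorCharge)
  shifts <- unique(c(0, parentMassDelta / seq_len(zmax)))
  pairs <- do.call(rbind, lapply(shifts, function(s)
    .candidatePairs(light@mz, light@intensity, heavy@mz, heavy@intensity,
                    fragmentToleranceDa, shift = s)))
  pairs <- unique(pairs)
  sel <- .matchPairs(pairs, method = match.arg(method))
  min(1, sum(sel$w))
}
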