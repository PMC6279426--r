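#' Parse a modified peptide string
#'
#' Peptides are written with inline, parenthesised mass deltas following the
#' modified residue, e.g. `"PEPS(+79.9660)TIDE"`. An N-terminal modification
#' is written as a leading delta before the first residue, e.g.
#' `"(+42.0110)PEPTIDE"`. Positions are 1-based residue indices; position 0
#' denotes the N-terminus.
#'
#' @param peptide Character scalar, the modified peptide string.
#' @return A list with components `sequence` (plain residue string),
#'   `positions` (integer vector, 0 = N-term) and `deltas` (numeric, Da).
#' @export
#' @examples
#' parsePeptide("PEPS(+79.9660)TIDE")
parsePeptide <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L, !is.na(peptide))
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  seq <- character(0)
  positions <- integer(0)
  deltas <- numeric(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i
      while (j <= n && chars[j] != ")") j <- j + 1L
      if (j > n) stop("unbalanced '(' in peptide string: ", peptide)
      num <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      delta <- suppressWarnings(as.numeric(num))
      if (is.na(delta)) stop("invalid modification delta '", num, "' in ", peptide)
      positions <- c(positions, length(seq))  # 0 if before first residue
      deltas <- c(deltas, delta)
      i <- j + 1L
    } else {
      if (!ch %in% names(.RESIDUE_MASS))
        stop("invalid-peptide: residue '", ch, "' outside amino-acid alphabet in ", peptide)
      seq <- c(seq, ch)
      i <- i + 1L
    }
  }
  list(sequence = paste(seq, collapse = ""),
       positions = positions, deltas = deltas)
}

#' Canonical text form of a modified peptide
#'
#' Reformats all modification deltas to a fixed four-decimal signed form so
#' that precursor equality is plain string equality.
#'
#' @param peptide Character vector of peptide strings.
#' @return Character vector of canonicalised peptide strings.
#' @export
#' @examples
#' canonicalPeptide("PEPS(+79.966)TIDE")
canonicalPeptide <- function(peptide) {
  vapply(peptide, function(p) {
    parsed <- parsePeptide(p)
    .formatPeptide(parsed$sequence, parsed$positions, parsed$deltas)
  }, character(1), USE.NAMES = FALSE)
}

.formatPeptide <- function(sequence, positions, deltas) {
  if (length(positions) == 0L) return(sequence)
  ord <- order(positions, deltas)
  positions <- positions[ord]; deltas <- deltas[ord]
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- character(length(res) + 1L)
  out[1L] <- ""
  for (k in seq_along(res)) out[k + 1L] <- res[k]
  for (k in seq_along(positions)) {
    idx <- positions[k] + 1L
    out[idx] <- paste0(out[idx], sprintf("(%+.4f)", deltas[k]))
  }
  paste(out, collapse = "")
}

#' Strip modifications from a peptide string
#'
#' @param peptide Character vector of (possibly modified) peptide strings.
#' @return Character vector of plain residue sequences.
#' @export
unmodifiedSequence <- function(peptide) {
  gsub("\\([^)]*\\)", "", peptide)
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus modification deltas plus one water.
#'
#' @param peptide Modified peptide string.
#' @return Neutral mass in Da.
#' @export
#' @examples
#' peptideNeutralMass("AG")
peptideNeutralMass <- function(peptide) {
  parsed <- parsePeptide(peptide)
  res <- strsplit(parsed$sequence, "", fixed = TRUE)[[1]]
  sum(.RESIDUE_MASS[res]) + sum(parsed$deltas) + .H2O_MASS
}

#' Theoretical precursor m/z for a peptide at a charge
#'
#' @param peptide Modified peptide string.
#' @param charge Positive integer charge state.
#' @return m/z in Da.
#' @export
peptideMz <- function(peptide, charge) {
  stopifnot(charge >= 1)
  (peptideNeutralMass(peptide) + charge * .PROTON_MASS) / charge
}

#' Precursor key (peptide/charge) in canonical form
#'
#' A precursor is the combination of modified peptide sequence and charge
#' state; it is the unit of a spectral-library entry.
#'
#' @param peptide Character vector of peptide strings.
#' @param charge Integer vector of charges.
#' @return Character vector `"<canonical peptide>/<charge>"`.
#' @export
precursorKey <- function(peptide, charge) {
  paste0(canonicalPeptide(peptide), "/", as.integer(charge))
}

#' Site-localization group of a precursor
#'
#' Precursors that differ only in where (not which) modifications sit share
#' a group id: the unmodified sequence, the sorted multiset of modification
#' deltas, and the charge.
#'
#' @param peptide Character vector of peptide strings.
#' @param charge Integer vector of charges.
#' @return Character vector of group identifiers.
#' @export
#' @examples
#' localizationGroup(c("PEPS(+79.966)TIDE", "PEPST(+79.966)IDE"), c(2, 2))
localizationGroup <- function(peptide, charge) {
  mapply(function(p, z) {
    parsed <- parsePeptide(p)
    ds <- sort(round(parsed$deltas, 4))
    paste0(parsed$sequence, "|",
           paste(sprintf("%+.4f", ds), collapse = ","), "|", as.integer(z))
  }, peptide, charge, USE.NAMES = FALSE)
}

#' Fully tryptic digest of a protein sequence
#'
#' Cleaves after K and R, allowing up to `missed` missed cleavage sites.
#'
#' @param sequence Protein sequence (character scalar).
#' @param missed Maximum missed cleavages (default 1).
#' @param minLength,maxLength Peptide length bounds retained.
#' @return Character vector of peptide sequences (unique, in order of
#'   first occurrence).
#' @export
trypticPeptides <- function(sequence, missed = 1L, minLength = 6L, maxLength = 40L) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n == 0L) return(character(0))
  cut <- which(res %in% c("K", "R"))
  bounds <- unique(c(0L, cut, n))  # peptide i spans (bounds[i]+1):bounds[i+1]
  nb <- length(bounds) - 1L
  out <- character(0)
  for (i in seq_len(nb)) {
    for (m in 0:missed) {
      j <- i + m
      if (j > nb) break
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      len <- end - start + 1L
      if (len >= minLength && len <= maxLength)
        out <- c(out, paste(res[start:end], collapse = ""))
    }
  }
  unique(out)
}
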