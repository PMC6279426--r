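#' Database p-value from a spectral probability
#'
#' Converts the spectral probability P(S|T) of a peptide-spectrum match --
#' the probability that a random peptide matches spectrum S with a score
#' better than T -- into the probability that at least one of N candidate
#' peptides in the searched database produces a match at least that good:
#' `1 - (1 - p)^N`. Computed via `expm1(N * log1p(-p))` so that tiny
#' probabilities keep full relative precision.
#'
#' The value is strictly increasing in both `p` and `N`, equals `p` at
#' `N = 1`, and tends to 1 as `N` grows for fixed `p > 0`. A smaller
#' search space therefore yields a smaller (better) database p-value for
#' the same match quality, which is what the dynamic search-space
#' adjustment for purification data exploits.
#'
#' @param spectralProbability Numeric in (0, 1], vectorized.
#' @param databaseSize Positive integer N, the number of candidate
#'   peptides eligible to match the spectrum.
#' @return Database p-value in (0, 1].
#' @export
#' @examples
#' databasePValue(0.5, 1)          # 0.5
#' databasePValue(1e-12, 1000)     # ~1e-9
databasePValue <- function(spectralProbability, databaseSize) {
  p <- spectralProbability
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("spectralProbability must be in (0, 1]")
  if (any(databaseSize < 1)) stop("databaseSize must be >= 1")
  ifelse(p == 1, 1, -expm1(databaseSize * log1p(-p)))
}

#' Total PSM ordering used throughout the pipeline
#'
#' All sorts in the pipeline use one lexicographic total order:
#' (database p-value, targets before decoys, run id, scan). A total order
#' is what makes candidate-set merging and every FDR cut deterministic and
#' order invariant.
#'
#' @param psms data.frame with columns `database_p_value`, `is_decoy`,
#'   `run_id`, `scan`.
#' @return Integer permutation (as from [order()]).
#' @export
psmOrder <- function(psms) {
  order(psms$database_p_value, psms$is_decoy, psms$run_id, psms$scan,
        method = "radix")
}

#' Filter PSMs to a target-decoy FDR level
#'
#' Standard target-decoy filtering: PSMs are sorted by increasing database
#' p-value (total order) and the largest prefix whose decoy/target ratio
#' does not exceed `alpha` is accepted. Decoys inside the accepted prefix
#' are retained in the output, flagged, so that library-level error rates
#' can be estimated empirically downstream.
#'
#' @param psms PSM data.frame (see [readPsmTable()] for the dialect).
#' @param alpha FDR level in (0, 1), default 0.01.
#' @return The accepted PSM rows (targets and flagged decoys).
#' @export
psmFdrFilter <- function(psms, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  if (nrow(psms) == 0L) return(psms)
  psms <- psms[psmOrder(psms), , drop = FALSE]
  decoys <- cumsum(psms$is_decoy)
  targets <- cumsum(!psms$is_decoy)
  ratio <- ifelse(targets == 0, ifelse(decoys == 0, 0, Inf), decoys / targets)
  ok <- which(ratio <= alpha)
  if (length(ok) == 0L) return(psms[0, , drop = FALSE])
  out <- psms[seq_len(max(ok)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# peptide-level TDA: score each distinct peptide sequence by its best PSM
# p-value, then target-decoy filter at alpha. Returns accepted peptides.
.peptideFdrFilter <- function(psms, alpha = 0.01) {
  if (nrow(psms) == 0L)
    return(data.frame(peptide = character(0), is_decoy = logical(0),
                      database_p_value = numeric(0)))
  key <- canonicalPeptide(psms$peptide)
  o <- psmOrder(psms)
  first <- o[!duplicated(key[o])]
  pep <- data.frame(peptide = key[first],
                    is_decoy = psms$is_decoy[first],
                    database_p_value = psms$database_p_value[first],
                    run_id = psms$run_id[first], scan = psms$scan[first],
                    stringsAsFactors = FALSE)
  psmFdrFilter(pep, alpha)[, c("peptide", "is_decoy", "database_p_value")]
}

#' Dynamic search-space adjustment for purification data
#'
#' In affinity-purification samples far fewer proteins are present than in
#' the full proteome database, so match significance can be re-assessed
#' against a reduced candidate set. A protein is eligible for the reduced
#' search space if, at the stated peptide-level FDR, a total of two or more
#' distinct peptide sequences map to the target protein P or to its decoy
#' counterpart reverse(P) (pooled counting, so the decoy side of the
#' competition models true/false and false/false peptide pairs). PSMs whose
#' peptide maps to an eligible protein get their database p-value
#' recomputed with the reduced database size; PSMs to proteins with only
#' one identified peptide keep their original p-values. The adjusted set is
#' re-sorted and re-filtered at the PSM-level FDR.
#'
#' @param psms PSM data.frame from one search.
#' @param proteinMap Named character vector or list mapping each distinct
#'   (unmodified) peptide sequence to its protein accession (decoy
#'   peptides map to the decoy accession, `"<decoyPrefix><target>"`).
#' @param reducedDatabaseSize Positive integer: candidate count of the
#'   reduced search space.
#' @param peptideLevelFdr Peptide-level FDR used for eligibility
#'   (default 0.01).
#' @param psmLevelFdr Final PSM-level FDR re-filter (default 0.01).
#' @param decoyPrefix Accession prefix marking decoy proteins
#'   (default `"XXX_"`).
#' @return The adjusted, re-filtered PSM data.frame.
#' @export
adjustSearchSpace <- function(psms, proteinMap, reducedDatabaseSize,
                              peptideLevelFdr = 0.01, psmLevelFdr = 0.01,
                              decoyPrefix = "XXX_") {
  if (nrow(psms) == 0L) return(psms)
  pepSeq <- unmodifiedSequence(psms$peptide)
  missing <- setdiff(unique(pepSeq), names(proteinMap))
  if (length(missing))
    stop("missing protein mapping for peptide(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  prot <- unlist(proteinMap[pepSeq], use.names = FALSE)
  # pooled eligibility on the target/decoy pair id
  pairId <- sub(paste0("^", decoyPrefix), "", prot)
  accepted <- .peptideFdrFilter(psms, peptideLevelFdr)
  accSeq <- unmodifiedSequence(accepted$peptide)
  accPair <- sub(paste0("^", decoyPrefix), "",
                 unlist(proteinMap[accSeq], use.names = FALSE))
  counts <- table(accPair[!duplicated(paste0(accPair, "\r", accSeq))])
  eligible <- names(counts)[counts >= 2L]
  adjust <- pairId %in% eligible
  psms$database_p_value[adjust] <-
    databasePValue(psms$spectral_probability[adjust], reducedDatabaseSize)
  psmFdrFilter(psms, psmLevelFdr)
}

#' Empirical zero-FDR filtering for synthetic peptide pools
#'
#' Synthetic pools are searched against a tiny known database, too small
#' for the usual decoy statistics, so background runs of knowingly absent
#' peptides supply the false matches. A decoy PSM is (a) a main-pool
#' spectrum matched to the decoy database, or (b) a background-run
#' spectrum matched to the target or decoy database -- except that
#' background peptides that also occur in the target pool are excluded
#' from being counted as decoys. Within each peptide length, PSMs are
#' sorted by increasing database p-value and the acceptance threshold is
#' set just below the best decoy, so that zero decoy PSMs survive.
#'
#' @param psms PSM data.frame; `run_id` distinguishes main from
#'   background runs.
#' @param backgroundRunIds Character vector of background run ids
#'   (must be non-empty; the empirical FDR is undefined without them).
#' @param poolTargetPeptides Character vector: peptide sequences in the
#'   target pool.
#' @param backgroundPoolPeptides Named list: run id -> peptide sequences
#'   synthesized in that background pool (used for the exclusion rule).
#' @return List with `thresholds` (data.frame `length`, `max_p_value`)
#'   and `accepted` (PSM rows; contains no decoy PSMs by construction).
#' @export
syntheticPoolFilter <- function(psms, backgroundRunIds,
                                poolTargetPeptides,
                                backgroundPoolPeptides = list()) {
  if (length(backgroundRunIds) == 0L)
    stop("empirical FDR undefined: no background runs configured")
  if (nrow(psms) == 0L)
    return(list(thresholds = data.frame(length = integer(0),
                                        max_p_value = numeric(0)),
                accepted = psms))
  pepSeq <- unmodifiedSequence(psms$peptide)
  fromBackground <- psms$run_id %in% backgroundRunIds
  # background peptides also present in the target pool are not decoys
  inOwnPool <- rep(FALSE, nrow(psms))
  for (rid in intersect(names(backgroundPoolPeptides), backgroundRunIds)) {
    sel <- psms$run_id == rid &
      pepSeq %in% intersect(backgroundPoolPeptides[[rid]], poolTargetPeptides)
    inOwnPool <- inOwnPool | sel
  }
  isDecoyPsm <- (!fromBackground & psms$is_decoy) |
    (fromBackground & !inOwnPool)
  len <- nchar(pepSeq)
  keep <- logical(nrow(psms))
  thr <- list()
  for (L in sort(unique(len))) {
    sel <- which(len == L)
    dec <- sel[isDecoyPsm[sel]]
    cut <- if (length(dec)) min(psms$database_p_value[dec]) else Inf
    ok <- sel[psms$database_p_value[sel] < cut & !isDecoyPsm[sel]]
    keep[ok] <- TRUE
    thr[[length(thr) + 1L]] <- data.frame(length = L, max_p_value = cut)
  }
  accepted <- psms[keep, , drop = FALSE]
  accepted <- accepted[psmOrder(accepted), , drop = FALSE]
  rownames(accepted) <- NULL
  list(thresholds = do.call(rbind, thr), accepted = accepted)
}
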