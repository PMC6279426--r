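# Independent brute-force oracles and small fixture constructors used
# across the suite. Oracles deliberately avoid the package's own code
# paths (plain loops, exhaustive enumeration).

makePsms <- function(p, decoy = rep(FALSE, length(p)),
                     peptide = "AAGTSEEVLK",
                     charge = 2L, run = "r1", scan = seq_along(p),
                     dataset = "D1", search = "S1",
                     sp = p, rt = 30) {
  data.frame(run_id = rep_len(run, length(p)), scan = scan,
             dataset_id = rep_len(dataset, length(p)),
             search_id = rep_len(search, length(p)),
             peptide = rep_len(peptide, length(p)),
             charge = rep_len(as.integer(charge), length(p)),
             spectral_probability = pmin(sp, 1),
             database_p_value = p, is_decoy = decoy,
             rt_min = rep_len(rt, length(p)), stringsAsFactors = FALSE)
}

# largest prefix of (sorted) records with decoy/target ratio <= alpha
oraclePrefixTda <- function(p, decoy, alpha) {
  o <- order(p, decoy)
  p <- p[o]; decoy <- decoy[o]
  best <- 0L
  for (i in seq_along(p)) {
    d <- sum(decoy[seq_len(i)]); t <- i - d
    r <- if (t == 0L) { if (d == 0L) 0 else Inf } else d / t
    if (r <= alpha) best <- i
  }
  list(n = best, idx = o[seq_len(best)])
}

# exhaustive local-FDR threshold: scan every rank, compute the window
# ratio by explicit summation, keep the highest qualifying p-value
oracleLocalFdr <- function(p, decoy, window, alpha,
                           mode = c("trailing", "centered")) {
  mode <- match.arg(mode)
  o <- order(p, decoy)
  p <- p[o]; decoy <- decoy[o]
  n <- length(p)
  w <- min(window, n)
  cut <- -Inf
  for (i in seq_len(n)) {
    if (mode == "trailing") { lo <- max(1, i - w + 1); hi <- i }
    else { half <- w %/% 2; lo <- max(1, i - half); hi <- min(n, i + half) }
    d <- sum(decoy[lo:hi]); t <- (hi - lo + 1) - d
    r <- if (t == 0) { if (d == 0) 0 else Inf } else d / t
    if (r < alpha && p[i] > cut) cut <- p[i]
  }
  cut
}

# pick-then-prefix protein TDA by explicit enumeration
oraclePickedProtein <- function(proteins, alpha, decoyPrefix = "XXX_") {
  pairId <- ifelse(proteins$is_decoy,
                   sub(paste0("^", decoyPrefix), "", proteins$accession),
                   proteins$accession)
  winners <- do.call(rbind, lapply(unique(pairId), function(pid) {
    grp <- proteins[pairId == pid, , drop = FALSE]
    grp <- grp[order(-grp$score, grp$is_decoy, grp$accession), , drop = FALSE]
    grp[1, , drop = FALSE]
  }))
  winners <- winners[order(-winners$score, winners$is_decoy,
                           winners$accession), , drop = FALSE]
  best <- 0L
  for (i in seq_len(nrow(winners))) {
    d <- sum(winners$is_decoy[seq_len(i)]); t <- i - d
    r <- if (t == 0L) { if (d == 0L) 0 else Inf } else d / t
    if (r <= alpha) best <- i
  }
  if (best == 0L) winners[0, , drop = FALSE] else
    winners[seq_len(best), , drop = FALSE]
}

# exhaustive maximum-weight one-to-one matching over candidate pairs;
# pairs admissible at any of the given shifts
oracleMatchScore <- function(mzA, intA, mzB, intB, tol, shifts = 0) {
  pairs <- list()
  for (i in seq_along(mzA)) for (j in seq_along(mzB)) {
    if (any(abs(mzB[j] - mzA[i] - shifts) <= tol))
      pairs[[length(pairs) + 1L]] <- c(i, j, intA[i] * intB[j])
  }
  if (!length(pairs)) return(0)
  P <- do.call(rbind, pairs)
  best <- 0
  recurse <- function(k, usedI, usedJ, score) {
    if (score > best) best <<- score
    if (k > nrow(P)) return()
    recurse(k + 1L, usedI, usedJ, score)
    if (!(P[k, 1] %in% usedI) && !(P[k, 2] %in% usedJ))
      recurse(k + 1L, c(usedI, P[k, 1]), c(usedJ, P[k, 2]),
              score + P[k, 3])
  }
  recurse(1L, integer(0), integer(0), 0)
  min(1, best)
}

# independent re-implementation of greedy set cover for proteotypic sets
oracleGreedyCover <- function(searches, precSearches, target, cap,
                              rank = NULL) {
  if (is.null(rank))
    rank <- stats::setNames(rep(0, length(precSearches)),
                            names(precSearches))
  uncovered <- unique(searches)
  total <- length(uncovered)
  chosen <- character(0)
  repeat {
    if ((total - length(uncovered)) / total >= target - 1e-12) break
    if (length(chosen) >= cap) break
    remaining <- setdiff(names(precSearches), chosen)
    if (!length(remaining)) break
    gains <- sapply(remaining, function(k)
      length(intersect(precSearches[[k]], uncovered)))
    if (max(gains) == 0) break
    cand <- remaining[gains == max(gains)]
    cand <- cand[order(rank[cand], cand)]
    chosen <- c(chosen, cand[1])
    uncovered <- setdiff(uncovered, precSearches[[cand[1]]])
  }
  chosen
}

# exhaustive Hamming-distance-<=1 window scan
oracleSaav <- function(peptide, seqs) {
  L <- nchar(peptide)
  pep <- strsplit(peptide, "")[[1]]
  for (s in seqs) {
    if (nchar(s) < L) next
    for (start in seq_len(nchar(s) - L + 1L)) {
      win <- strsplit(substring(s, start, start + L - 1L), "")[[1]]
      if (sum(win != pep) <= 1L) return(TRUE)
    }
  }
  FALSE
}

randomSpectrum <- function(n, seed, charge = 2L, run = "r", scan = 1L) {
  set.seed(seed)
  Spectrum(sort(runif(n, 100, 1500)), runif(n, 0.1, 1),
           precursorMz = runif(1, 300, 900), precursorCharge = charge,
           runId = run, scan = scan)
}
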