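#' Read a Mascot generic format (MGF) peak-list file
#'
#' Honors TITLE, PEPMASS, CHARGE, RTINSECONDS and SCANS headers; SEQ and
#' `#` comment lines written by [writeMgf()] are tolerated. Run and
#' dataset ids are parsed from a `TITLE=run:<run>;dataset:<dataset>` form
#' when present, else taken from the arguments.
#'
#' @param path MGF file path.
#' @param runId,datasetId Fallback provenance ids for entries whose TITLE
#'   does not carry them.
#' @return Named list of [Spectrum-class] objects, keyed `"<run>::<scan>"`.
#' @export
readMgf <- function(path, runId = NA_character_, datasetId = NA_character_) {
  lines <- readLines(path)
  out <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (lines[i] == "BEGIN IONS") {
      pepmass <- NA_real_; charge <- 1L; rt <- NA_real_
      scan <- NA_integer_; run <- runId; ds <- datasetId
      mz <- numeric(0); int <- numeric(0)
      i <- i + 1L
      while (i <= n && lines[i] != "END IONS") {
        ln <- lines[i]
        if (startsWith(ln, "#")) {
          # provenance comment, ignore
        } else if (startsWith(ln, "TITLE=")) {
          tt <- substring(ln, 7L)
          m <- regmatches(tt, regexec("run:([^;]+);dataset:([^;]+)", tt))[[1]]
          if (length(m) == 3L) { run <- m[2]; ds <- m[3] }
        } else if (startsWith(ln, "PEPMASS=")) {
          pepmass <- as.numeric(strsplit(substring(ln, 9L), "[ \t]")[[1]][1])
        } else if (startsWith(ln, "CHARGE=")) {
          charge <- as.integer(gsub("[^0-9]", "", substring(ln, 8L)))
        } else if (startsWith(ln, "RTINSECONDS=")) {
          rt <- as.numeric(substring(ln, 13L)) / 60
        } else if (startsWith(ln, "SCANS=")) {
          scan <- as.integer(substring(ln, 7L))
        } else if (grepl("^[0-9]", ln)) {
          xy <- as.numeric(strsplit(ln, "[ \t]+")[[1]][1:2])
          mz <- c(mz, xy[1]); int <- c(int, xy[2])
        }
        i <- i + 1L
      }
      sp <- Spectrum(mz, int, precursorMz = pepmass,
                     precursorCharge = charge, retentionTime = rt,
                     runId = run, datasetId = ds, scan = scan)
      out[[paste0(run, "::", scan)]] <- sp
    }
    i <- i + 1L
  }
  out
}

.fmtNum <- function(x, digits = 6L) {
  # fixed-precision, locale-independent float printing for canonical output
  sprintf(paste0("%.", digits, "f"), x)
}

#' Write spectra to an MGF file
#'
#' Fixed-precision peak formatting makes the output canonical: the same
#' spectra always serialize to the same bytes. When `sequences` are given,
#' a `SEQ=` line and a `#PROVENANCE` comment line are written per entry
#' (the annotated library MGF dialect).
#'
#' @param spectra List of [Spectrum-class] objects.
#' @param path Output path.
#' @param sequences Optional character vector of peptide strings, parallel
#'   to `spectra`.
#' @param provenance Optional character vector of provenance strings,
#'   parallel to `spectra`.
#' @return Invisibly, the path.
#' @export
writeMgf <- function(spectra, path, sequences = NULL, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=run:%s;dataset:%s;scan:%d",
                       s@runId, s@datasetId, s@scan), con)
    if (!is.na(s@precursorMz))
      writeLines(paste0("PEPMASS=", .fmtNum(s@precursorMz)), con)
    writeLines(sprintf("CHARGE=%d+", s@precursorCharge), con)
    if (!is.na(s@retentionTime))
      writeLines(paste0("RTINSECONDS=", .fmtNum(s@retentionTime * 60, 3L)), con)
    if (!is.na(s@scan)) writeLines(sprintf("SCANS=%d", s@scan), con)
    if (!is.null(sequences)) writeLines(paste0("SEQ=", sequences[k]), con)
    if (!is.null(provenance)) writeLines(paste0("#PROVENANCE ", provenance[k]), con)
    writeLines(paste(.fmtNum(s@mz), .fmtNum(s@intensity)), con)
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}

.PSM_COLUMNS <- c("run_id", "scan", "dataset_id", "search_id", "peptide",
                  "charge", "spectral_probability", "database_p_value",
                  "is_decoy", "rt_min")

#' Read a PSM table
#'
#' Tab-separated, one row per peptide-spectrum match, with the documented
#' header: `run_id`, `scan`, `dataset_id`, `search_id`, `peptide`,
#' `charge`, `spectral_probability`, `database_p_value` (optional;
#' recomputed from `spectral_probability` when absent), `is_decoy`,
#' `rt_min`. Ranges are validated on read.
#'
#' @param path TSV file path.
#' @param databaseSize Database size N used to recompute missing
#'   `database_p_value` columns (required in that case).
#' @return Validated PSM data.frame.
#' @export
readPsmTable <- function(path, databaseSize = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  required <- setdiff(.PSM_COLUMNS, "database_p_value")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("PSM table missing column(s): ", paste(missing, collapse = ", "))
  if (!"database_p_value" %in% names(df)) {
    if (is.null(databaseSize))
      stop("database_p_value absent and no databaseSize given to recompute it")
    df$database_p_value <- databasePValue(df$spectral_probability, databaseSize)
  }
  df$is_decoy <- as.logical(df$is_decoy)
  df$charge <- as.integer(df$charge)
  df$scan <- as.integer(df$scan)
  validatePsms(df)
  df[, .PSM_COLUMNS]
}

#' Validate a PSM data.frame
#'
#' @param psms PSM data.frame.
#' @return Invisibly `TRUE`; stops naming the first offending record
#'   otherwise.
#' @export
validatePsms <- function(psms) {
  bad <- which(!is.finite(psms$spectral_probability) |
                 psms$spectral_probability <= 0 |
                 psms$spectral_probability > 1)
  if (length(bad))
    stop("record ", bad[1], ": spectral_probability out of (0,1]")
  bad <- which(!is.finite(psms$database_p_value) |
                 psms$database_p_value <= 0 | psms$database_p_value > 1)
  if (length(bad))
    stop("record ", bad[1], ": database_p_value out of (0,1]")
  bad <- which(is.na(psms$charge) | psms$charge < 1L)
  if (length(bad)) stop("record ", bad[1], ": charge must be >= 1")
  bad <- which(is.na(psms$is_decoy))
  if (length(bad)) stop("record ", bad[1], ": is_decoy must be TRUE/FALSE")
  invisible(TRUE)
}

#' Write a PSM table
#'
#' Lossless round-trip counterpart of [readPsmTable()]: probabilities are
#' written with full precision.
#'
#' @param psms PSM data.frame.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writePsmTable <- function(psms, path) {
  df <- psms[, .PSM_COLUMNS]
  df$spectral_probability <- format(df$spectral_probability, digits = 17,
                                    scientific = TRUE, trim = TRUE)
  df$database_p_value <- format(df$database_p_value, digits = 17,
                                scientific = TRUE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of protein sequences (accession = first
#'   whitespace-delimited token of the header).
#' @export
readFastaDb <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

#' Generate a reversed-decoy protein database
#'
#' Whole-protein reversal with a configurable accession prefix, the
#' standard decoy construction for target-decoy error estimation.
#'
#' @param targets Named character vector of target protein sequences.
#' @param decoyPrefix Accession prefix for decoys (default `"XXX_"`).
#' @return Named character vector of reversed sequences.
#' @export
makeDecoyDb <- function(targets, decoyPrefix = "XXX_") {
  rev1 <- vapply(strsplit(targets, "", fixed = TRUE), function(ch)
    paste(rev(ch), collapse = ""), character(1))
  names(rev1) <- paste0(decoyPrefix, names(targets))
  rev1
}

#' Write protein sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeFastaDb <- function(seqs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(seqs[[i]], con)
  }
  invisible(path)
}

#' Write a per-length threshold table as TSV
#'
#' @param thresholds data.frame with `length`, `max_p_value`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeThresholdTable <- function(thresholds, path) {
  df <- thresholds
  df$max_p_value <- format(df$max_p_value, digits = 17, scientific = TRUE,
                           trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
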