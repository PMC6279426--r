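#' @import methods
NULL

#' Spectrum: a centroided MS/MS peak list with provenance
#'
#' Peaks are stored as parallel `mz`/`intensity` vectors, sorted by
#' ascending m/z with no duplicated m/z values (duplicates are merged by
#' summing intensity at construction). Precursor information and
#' run/dataset/scan provenance travel with the peaks.
#'
#' @slot mz Numeric, ascending fragment m/z values (Da), all > 0.
#' @slot intensity Numeric, nonnegative intensities (arbitrary units).
#' @slot precursorMz Numeric scalar, precursor m/z (Da); may be `NA`.
#' @slot precursorCharge Integer scalar >= 1.
#' @slot retentionTime Numeric scalar, minutes; may be `NA`.
#' @slot runId,datasetId Character scalars, opaque provenance ids.
#' @slot scan Integer scan number.
#'
#' @export
setClass("Spectrum", representation(
  mz = "numeric", intensity = "numeric",
  precursorMz = "numeric", precursorCharge = "integer",
  retentionTime = "numeric", runId = "character",
  datasetId = "character", scan = "integer"
))

setValidity("Spectrum", function(object) {
  msg <- character(0)
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity lengths differ")
  if (any(object@mz <= 0)) msg <- c(msg, "all mz must be > 0")
  if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (is.unsorted(object@mz, strictly = TRUE) && length(object@mz) > 1)
    msg <- c(msg, "mz must be strictly ascending (no duplicate mz)")
  if (length(object@precursorCharge) != 1L || is.na(object@precursorCharge) ||
      object@precursorCharge < 1L)
    msg <- c(msg, "precursorCharge must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' Peaks are sorted by m/z; peaks whose m/z coincide after rounding to
#' `mergeDigits` decimals are merged by summing intensity, so that
#' one-to-one peak matching is well defined.
#'
#' @param mz,intensity Numeric vectors of equal length.
#' @param precursorMz Precursor m/z (Da), `NA` if unknown.
#' @param precursorCharge Integer >= 1.
#' @param retentionTime Retention time in minutes, `NA` if unknown.
#' @param runId,datasetId Provenance identifiers.
#' @param scan Integer scan number.
#' @param mergeDigits Decimals used when merging coincident m/z (default 4).
#' @return A [Spectrum-class] object.
#' @export
#' @examples
#' Spectrum(c(100, 200), c(3, 4), precursorCharge = 2)
Spectrum <- function(mz, intensity, precursorMz = NA_real_,
                     precursorCharge = 1L, retentionTime = NA_real_,
                     runId = NA_character_, datasetId = NA_character_,
                     scan = NA_integer_, mergeDigits = 4L) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz)) {
    key <- round(mz, mergeDigits)
    if (anyDuplicated(key)) {
      agg <- rowsum(intensity, group = key, reorder = TRUE)
      mz <- as.numeric(rownames(agg))
      intensity <- as.numeric(agg[, 1])
    } else {
      o <- order(mz)
      mz <- mz[o]; intensity <- intensity[o]
    }
  }
  new("Spectrum", mz = as.numeric(mz), intensity = as.numeric(intensity),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      retentionTime = as.numeric(retentionTime),
      runId = as.character(runId), datasetId = as.character(datasetId),
      scan = as.integer(scan))
}

#' @describeIn Spectrum-class number of peaks
#' @param x,object A `Spectrum`.
#' @export
setMethod("length", "Spectrum", function(x) length(x@mz))

#' @rdname Spectrum-class
#' @export
setGeneric("peakMz", function(x) standardGeneric("peakMz"))
#' @rdname Spectrum-class
#' @export
setMethod("peakMz", "Spectrum", function(x) x@mz)

#' @rdname Spectrum-class
#' @export
setGeneric("peakIntensity", function(x) standardGeneric("peakIntensity"))
#' @rdname Spectrum-class
#' @export
setMethod("peakIntensity", "Spectrum", function(x) x@intensity)

#' @rdname Spectrum-class
#' @export
setGeneric("precursorCharge", function(x) standardGeneric("precursorCharge"))
#' @rdname Spectrum-class
#' @export
setMethod("precursorCharge", "Spectrum", function(x) x@precursorCharge)

#' @rdname Spectrum-class
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))
#' @rdname Spectrum-class
#' @export
setMethod("precursorMz", "Spectrum", function(x) x@precursorMz)

#' @rdname Spectrum-class
#' @export
setGeneric("retentionTime", function(x) standardGeneric("retentionTime"))
#' @rdname Spectrum-class
#' @export
setMethod("retentionTime", "Spectrum", function(x) x@retentionTime)

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum:", length(object@mz), "peaks;",
      "precursor m/z", format(object@precursorMz, digits = 8),
      paste0("(", object@precursorCharge, "+);"),
      "run", object@runId, "scan", object@scan, "\n")
})

#' LibraryState: the order-invariant accumulation state of a library build
#'
#' Holds (i) the full precursor ledger -- every precursor ever observed,
#' unfiltered and including decoys, with the best-scoring PSM recorded --
#' and (ii) the bounded candidate set per precursor (top candidates under
#' the total PSM order, with a per-dataset cap). Merging new PSM batches
#' into the state is associative and commutative, which is what makes
#' incremental library builds independent of the order in which data
#' arrive.
#'
#' @slot ledger data.frame: one row per precursor key with best PSM fields.
#' @slot candidates named list of data.frames (one per precursor key).
#' @slot config list of build thresholds (see [buildConfig()]).
#' @export
setClass("LibraryState", representation(
  ledger = "data.frame", candidates = "list", config = "ANY"
))

setValidity("LibraryState", function(object) {
  msg <- character(0)
  if (nrow(object@ledger) &&
      !all(names(object@candidates) %in% object@ledger$key))
    msg <- c(msg, "candidate-set keys must be a subset of the ledger")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LibraryState", function(object) {
  nl <- nrow(object@ledger)
  nd <- if (nl) sum(object@ledger$is_decoy) else 0L
  cat("LibraryState:", nl, "precursors in ledger (", nd, "decoy );",
      length(object@candidates), "candidate sets\n")
})

#' @rdname LibraryState-class
#' @param x,object A `LibraryState`.
#' @export
setGeneric("precursorLedger", function(x) standardGeneric("precursorLedger"))
#' @rdname LibraryState-class
#' @export
setMethod("precursorLedger", "LibraryState", function(x) x@ledger)

#' @rdname LibraryState-class
#' @export
setGeneric("candidateSets", function(x) standardGeneric("candidateSets"))
#' @rdname LibraryState-class
#' @export
setMethod("candidateSets", "LibraryState", function(x) x@candidates)

#' SpectralLibrary: an assembled, error-controlled spectral library
#'
#' @slot entries data.frame: one row per library entry (precursor key,
#'   peptide, charge, decoy flag, representative provenance, protein
#'   accessions, representative p-value, contributing dataset/PSM counts).
#' @slot spectra named list of [Spectrum-class] representatives, parallel
#'   to `entries$key`.
#' @slot thresholds data.frame of per-length local-FDR thresholds.
#' @slot diagnostics list of stage-by-stage counts and error-rate
#'   diagnostics (including the naive aggregate FDR).
#' @export
setClass("SpectralLibrary", representation(
  entries = "data.frame", spectra = "list",
  thresholds = "data.frame", diagnostics = "list"
))

setValidity("SpectralLibrary", function(object) {
  if (nrow(object@entries) &&
      !identical(object@entries$key, names(object@spectra)))
    "entries$key must match names(spectra)" else TRUE
})

setMethod("show", "SpectralLibrary", function(object) {
  n <- nrow(object@entries)
  nd <- if (n) sum(object@entries$is_decoy) else 0L
  cat("SpectralLibrary:", n, "entries (", nd, "decoy )\n")
  if (!is.null(object@diagnostics$naive_aggregate_fdr))
    cat("  naive aggregate precursor FDR:",
        format(object@diagnostics$naive_aggregate_fdr, digits = 3), "\n")
})

#' @rdname SpectralLibrary-class
#' @param x,object A `SpectralLibrary`.
#' @export
setGeneric("libraryEntries", function(x) standardGeneric("libraryEntries"))
#' @rdname SpectralLibrary-class
#' @export
setMethod("libraryEntries", "SpectralLibrary", function(x) x@entries)

#' @rdname SpectralLibrary-class
#' @export
setGeneric("librarySpectra", function(x) standardGeneric("librarySpectra"))
#' @rdname SpectralLibrary-class
#' @export
setMethod("librarySpectra", "SpectralLibrary", function(x) x@spectra)

#' @rdname SpectralLibrary-class
#' @export
setGeneric("libraryDiagnostics", function(x) standardGeneric("libraryDiagnostics"))
#' @rdname SpectralLibrary-class
#' @export
setMethod("libraryDiagnostics", "SpectralLibrary", function(x) x@diagnostics)
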