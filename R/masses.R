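#' Monoisotopic mass constants
#'
#' Internal table of monoisotopic amino-acid residue masses (Da), the proton
#' mass and small-molecule deltas used for fragment mass calculation. Values
#' are documented to five decimals and fixed inside the package so that
#' libraries are reproducible independently of any external mass table. The
#' same constants can be emitted as a provenance file next to an exported
#' library with [writeConstantsFile()].
#'
#' @format Named numeric vectors.
#' @keywords internal
#' @name mass-constants
NULL

.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.PROTON_MASS  <- 1.00728   # mass of a proton, Da
.H2O_MASS     <- 18.01056  # water loss / peptide C-terminus
.NH3_MASS     <- 17.02655  # ammonia loss
.CO_MASS      <- 27.99491  # b -> a conversion
.C13_DELTA    <- 1.00335   # 13C - 12C isotope spacing

#' SILAC label mass deltas
#'
#' Heavy-label deltas for stable-isotope labelling by amino acids in cell
#' culture: +8.0142 Da on lysine (K) and +10.0083 Da on arginine (R).
#'
#' @return Named numeric vector of label deltas in Da.
#' @export
#' @examples
#' silacDeltas()
silacDeltas <- function() c(K = 8.0142, R = 10.0083)

#' Write the mass-constant provenance file
#'
#' Emits the residue masses, proton mass and modification-relevant constants
#' used by the package as a plain-text table, intended to accompany any
#' exported spectral library so downstream users can verify the mass scale.
#'
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
writeConstantsFile <- function(path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# speclib mass constants (monoisotopic, Da)", con)
  writeLines(sprintf("proton\t%.5f", .PROTON_MASS), con)
  writeLines(sprintf("H2O\t%.5f", .H2O_MASS), con)
  writeLines(sprintf("NH3\t%.5f", .NH3_MASS), con)
  writeLines(sprintf("CO\t%.5f", .CO_MASS), con)
  writeLines(sprintf("C13\t%.5f", .C13_DELTA), con)
  for (aa in names(.RESIDUE_MASS))
    writeLines(sprintf("residue_%s\t%.5f", aa, .RESIDUE_MASS[[aa]]), con)
  sd <- silacDeltas()
  for (aa in names(sd))
    writeLines(sprintf("silac_%s\t%.4f", aa, sd[[aa]]), con)
  invisible(path)
}
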