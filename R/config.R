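#' Build configuration with the pipeline's default thresholds
#'
#' Collects every tunable threshold of the library build in one list, with
#' the defaults the pipeline was designed around: 1% PSM-level FDR per
#' search, 1% local precursor FDR over a 500-record sliding window, 1%
#' picked protein FDR, candidate caps of 100 spectra per precursor and 20
#' per dataset, spectrum quality gates of 40% minimum explained fragment
#' intensity and 50 ppm maximum precursor mass deviation, 0.1 Da fragment
#' tolerance, minimum novel-peptide length 9, proteotypic selection to 90%
#' coverage with a cap of 20 precursors, and SILAC concordance gates
#' (aligned cosine > 0.6, explained intensity > 0.5 in both spectra,
#' retention-time difference of at most one minute).
#'
#' Every pipeline run freezes its configuration into the output directory
#' as a YAML snapshot for provenance.
#'
#' @param psm_fdr PSM-level FDR per search.
#' @param local_fdr Local precursor FDR level.
#' @param window Sliding-window size for the local FDR.
#' @param window_mode `"trailing"` or `"centered"` window semantics.
#' @param protein_fdr Picked protein FDR level.
#' @param top_candidates Global candidate cap per precursor.
#' @param per_dataset_cap Per-dataset candidate cap.
#' @param explained_intensity_min Minimum explained-intensity fraction.
#' @param precursor_ppm_max Maximum precursor mass deviation (ppm).
#' @param fragment_tolerance_da Fragment match tolerance (Da).
#' @param min_novel_peptide_length Minimum peptide length for
#'   novel-protein evidence.
#' @param proteotypic_coverage Target coverage for proteotypic selection.
#' @param proteotypic_cap Maximum proteotypic precursors per protein.
#' @param silac_min_cosine Minimum aligned cosine for SILAC concordance.
#' @param silac_min_explained Minimum explained intensity (both spectra).
#' @param silac_max_rt_delta Maximum light/heavy RT difference (minutes).
#' @param decoy_prefix Decoy accession prefix.
#' @param equate_il Treat I and L as identical in protein mapping.
#' @return A named list of class `"BuildConfig"`.
#' @export
buildConfig <- function(psm_fdr = 0.01, local_fdr = 0.01, window = 500L,
                        window_mode = "trailing", protein_fdr = 0.01,
                        top_candidates = 100L, per_dataset_cap = 20L,
                        explained_intensity_min = 0.40,
                        precursor_ppm_max = 50,
                        fragment_tolerance_da = 0.1,
                        min_novel_peptide_length = 9L,
                        proteotypic_coverage = 0.90,
                        proteotypic_cap = 20L,
                        silac_min_cosine = 0.6,
                        silac_min_explained = 0.5,
                        silac_max_rt_delta = 1,
                        decoy_prefix = "XXX_",
                        equate_il = FALSE) {
  cfg <- list(psm_fdr = psm_fdr, local_fdr = local_fdr,
              window = as.integer(window), window_mode = window_mode,
              protein_fdr = protein_fdr,
              top_candidates = as.integer(top_candidates),
              per_dataset_cap = as.integer(per_dataset_cap),
              explained_intensity_min = explained_intensity_min,
              precursor_ppm_max = precursor_ppm_max,
              fragment_tolerance_da = fragment_tolerance_da,
              min_novel_peptide_length = as.integer(min_novel_peptide_length),
              proteotypic_coverage = proteotypic_coverage,
              proteotypic_cap = as.integer(proteotypic_cap),
              silac_min_cosine = silac_min_cosine,
              silac_min_explained = silac_min_explained,
              silac_max_rt_delta = silac_max_rt_delta,
              decoy_prefix = decoy_prefix,
              equate_il = equate_il)
  stopifnot(cfg$psm_fdr > 0, cfg$psm_fdr < 1, cfg$local_fdr > 0,
            cfg$local_fdr < 1, cfg$window >= 2L, cfg$protein_fdr > 0,
            cfg$protein_fdr < 1, cfg$top_candidates >= 1L,
            cfg$per_dataset_cap >= 1L,
            cfg$explained_intensity_min >= 0,
            cfg$explained_intensity_min <= 1,
            cfg$precursor_ppm_max > 0, cfg$fragment_tolerance_da > 0,
            cfg$window_mode %in% c("trailing", "centered"))
  class(cfg) <- c("BuildConfig", "list")
  cfg
}

#' Read a configuration file (YAML key/value), with full defaulting
#'
#' Keys absent from the file take the [buildConfig()] defaults; unknown
#' keys are an error.
#'
#' @param path YAML file path.
#' @return A `"BuildConfig"` list.
#' @export
readBuildConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(buildConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(buildConfig, vals)
}

#' Apply the spectrum quality gates to PSMs
#'
#' Keeps PSMs whose spectra (i) have at least the minimum fraction of
#' fragment intensity explained by annotated b/y/a peaks and (ii) whose
#' observed precursor mass is within the ppm tolerance of the peptide's
#' theoretical neutral mass (one 13C isotope allowed).
#'
#' @param psms PSM data.frame.
#' @param store Spectrum store keyed `"<run>::<scan>"`.
#' @param config A [buildConfig()] list.
#' @return The quality-passing PSM rows.
#' @export
spectrumQualityFilter <- function(psms, store, config = buildConfig()) {
  if (nrow(psms) == 0L) return(psms)
  keep <- vapply(seq_len(nrow(psms)), function(i) {
    s <- store[[paste0(psms$run_id[i], "::", psms$scan[i])]]
    if (is.null(s)) return(FALSE)
    ann <- annotatePeaks(s, psms$peptide[i],
                         precursorCharge = psms$charge[i],
                         fragmentToleranceDa = config$fragment_tolerance_da)
    frac <- explainedIntensity(s, ann)
    if (frac < config$explained_intensity_min) return(FALSE)
    obs <- if (!is.na(s@precursorMz)) s@precursorMz else
      peptideMz(psms$peptide[i], psms$charge[i])
    precursorMassFilter(obs, psms$charge[i], psms$peptide[i],
                        maxPpm = config$precursor_ppm_max, allowC13 = TRUE)
  }, logical(1))
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
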