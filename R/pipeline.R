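## Orchestration helpers tying the layers together: turning annotated
## spectra into a training set, and fitting per-site glycome models from a
## confident first-pass results table for the smoothing re-search.

#' Build a fragmentation-model training set from annotated spectra
#'
#' @param spectra list of annotated [spectrum()] objects (labelled peaks and
#'   an `assignment`), e.g. from [read_mgf()] on an annotated MGF or from
#'   [simulate_spectra()].
#' @return list of training GPSMs for [train_fragmentation_model()].
#' @export
annotated_training_set <- function(spectra) {
  lapply(spectra, function(sp) {
    if (is.null(sp$assignment))
      stop("spectrum ", sp$scan_id, " carries no glycopeptide assignment")
    list(spectrum = sp,
         peptide = sp$assignment$peptide,
         peptide_mass = peptide_mass(sp$assignment$peptide),
         glycan = parse_composition(sp$assignment$glycan),
         charge = sp$precursor_charge)
  })
}

#' Fit site-glycome smoothing models from a results table
#'
#' Restricts to confident target identifications (joint FDR at or below
#' `fdr_threshold`, both moieties target), groups them by glycosite, takes
#' each glycan's best glycan score as the observation, and fits one
#' smoothing model per site over the searchable glycome.
#'
#' @param results a [search_run()] results data.frame.
#' @param glycans list of searchable [glycan_composition()] objects.
#' @param fdr_threshold joint FDR cut for observations.
#' @param neighborhoods neighborhood rules.
#' @return named list of site models keyed by site id.
#' @export
fit_site_models_from_results <- function(results, glycans,
                                         fdr_threshold = 0.01,
                                         neighborhoods = default_neighborhoods()) {
  graph <- build_graph(glycans)
  conf <- results[!results$is_decoy_peptide & !results$is_decoy_glycan &
                    results$fdr_joint <= fdr_threshold &
                    results$score_glycan > 0, , drop = FALSE]
  models <- list()
  for (site in unique(conf$site)) {
    sub <- conf[conf$site == site, , drop = FALSE]
    obs <- tapply(sub$score_glycan, sub$glycan, max)
    models[[site]] <- fit_site_model(
      stats::setNames(as.numeric(obs), names(obs)), graph,
      neighborhoods = neighborhoods, site = site)
  }
  models
}
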