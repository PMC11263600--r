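## Glycan-first search: a sorted glycan mass index is scanned per precursor
## mass shift, surviving (peptide, glycan) pairs are cheaply pre-ranked and
## capped at k per shift, then fully scored through whichever scoring layers
## are enabled. Target and decoy candidates flow through identical code.

#' Search configuration
#'
#' @param precursor_tol,fragment_tol fractional mass tolerances.
#' @param max_nh3 maximum number of ammonium adducts considered (mass shifts
#'   0..max_nh3 x 17.0265 Da).
#' @param k candidate cap per mass shift after pre-ranking.
#' @param layers character subset of `c("model", "smoothing")`; empty = base
#'   scoring only.
#' @param params scoring parameters.
#' @param seed base seed for decoy ladder draws.
#' @return a `search_config` list.
#' @export
search_config <- function(precursor_tol = 5e-6, fragment_tol = 20e-6,
                          max_nh3 = 2L, k = 70L, layers = character(0),
                          params = default_params(), seed = 1L) {
  stopifnot(k >= 1L, precursor_tol > 0, fragment_tol > 0)
  params$tol <- fragment_tol
  params$precursor_tol <- precursor_tol
  list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
       max_nh3 = as.integer(max_nh3), k = as.integer(k), layers = layers,
       params = params, seed = as.integer(seed))
}

#' Build the glycopeptide search space from proteins and a glycan list
#'
#' Targets: tryptic sequon-bearing peptides, one candidate per (peptide,
#' site). Decoys: whole-protein reversals retaining glycosites at mirrored
#' positions; decoy peptides are those spanning a mirrored site. Glycan
#' compositions serve as their own decoys through shifted peptide+Y ladders
#' at scoring time.
#'
#' @param proteins named character vector of protein sequences.
#' @param glycans list of [glycan_composition()] objects.
#' @param max_missed missed cleavages.
#' @return a `search_space` list with `peptides` (data.frame), `glycans`
#'   (data.frame + ladder list), `decoy_site_map`.
#' @export
build_search_space <- function(proteins, glycans, max_missed = 2L) {
  pep_rows <- list()
  decoy_site_map <- character(0)
  for (pn in names(proteins)) {
    seq_ <- proteins[[pn]]
    dg <- digest(seq_, max_missed = max_missed, sequon_only = TRUE)
    for (i in seq_len(nrow(dg))) {
      for (s in as.integer(strsplit(dg$sequons[i], ",")[[1]])) {
        abs_site <- dg$start[i] + s - 1L
        pep_rows[[length(pep_rows) + 1L]] <- data.frame(
          sequence = dg$sequence[i], protein = pn, site_local = s,
          site_id = sprintf("%s:%d", pn, abs_site),
          mass = peptide_mass(dg$sequence[i]), is_decoy = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    ## decoy: reversed protein, sites at mirrored positions
    dec <- reverse_decoy(seq_)
    if (length(dec$decoy_sites)) {
      ddg <- digest(dec$sequence, max_missed = max_missed)
      for (i in seq_len(nrow(ddg))) {
        span <- ddg$start[i]:ddg$end[i]
        for (k in seq_along(dec$decoy_sites)) {
          ds <- dec$decoy_sites[k]
          if (!(ds %in% span)) next
          d_id <- sprintf("DECOY_%s:%d", pn, ds)
          decoy_site_map[d_id] <- sprintf("%s:%d", pn, dec$target_sites[k])
          pep_rows[[length(pep_rows) + 1L]] <- data.frame(
            sequence = ddg$sequence[i], protein = paste0("DECOY_", pn),
            site_local = ds - ddg$start[i] + 1L, site_id = d_id,
            mass = peptide_mass(ddg$sequence[i]), is_decoy = TRUE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  peptides <- unique(do.call(rbind, pep_rows))
  rownames(peptides) <- NULL
  gly <- data.frame(
    id = seq_along(glycans),
    text = vapply(glycans, format, character(1)),
    mass = vapply(glycans, function(g) g$mass, numeric(1)),
    cardinality = vapply(glycans, function(g) g$cardinality, integer(1)),
    n_g = vapply(glycans, approx_size, integer(1)),
    stringsAsFactors = FALSE)
  ord <- order(gly$mass)
  gly <- gly[ord, , drop = FALSE]
  ladders <- lapply(glycans[ord], generate_y_ladder)
  list(peptides = peptides, glycans = gly, glycan_objects = glycans[ord],
       ladders = ladders, decoy_site_map = decoy_site_map)
}

## Cheap pre-score for top-k truncation: matched core peptide+Y masses plus
## matched high-intensity backbone peaks.
prescore_candidate <- function(sp, pep_mass, sequence, ladder, tol) {
  core <- ladder$mass_delta[ladder$is_core]
  n_core <- sum(!is.na(vapply(pep_mass + core, function(m)
    match_mass(sp$peaks$neutral_mass, m, tol), integer(1))))
  frags <- backbone_fragments(sequence)
  top <- sp$peaks$neutral_mass[sp$peaks$rank <= 10L]
  n_top <- sum(!is.na(vapply(frags$mass, function(m)
    match_mass(sort(top), m, tol), integer(1))))
  n_core + n_top
}

#' Generate candidate (peptide, glycan, mass shift) triples for a spectrum
#'
#' For each ammonium mass shift, scans the glycan mass index for compositions
#' whose complement (precursor - shift - glycan mass) hits a peptide mass at
#' the precursor tolerance, pre-ranks the pairs by a cheap matched-fragment
#' count and truncates to the top k per shift. Decoy channels are expanded
#' afterwards: target peptide x decoy glycan and decoy peptide x target
#' glycan.
#'
#' @param sp a [spectrum()].
#' @param space a [build_search_space()] result.
#' @param config a [search_config()].
#' @return data.frame(pep_idx, gly_idx, n_nh3, channel) with channel in
#'   TT/TD/DT.
#' @export
candidates_for <- function(sp, space, config) {
  out <- list()
  tol_abs <- config$precursor_tol * sp$precursor_mass
  pm <- space$peptides$mass
  for (a in 0:config$max_nh3) {
    resid <- sp$precursor_mass - a * NH3_MASS
    rows <- list()
    for (gi in seq_len(nrow(space$glycans))) {
      need <- resid - space$glycans$mass[gi]
      if (need <= 0) next
      hits <- which(abs(pm - need) <= tol_abs)
      for (pi in hits)
        rows[[length(rows) + 1L]] <- c(pi, gi)
    }
    if (!length(rows)) next
    pairs <- unique(do.call(rbind, rows))
    ps <- vapply(seq_len(nrow(pairs)), function(r) {
      pi <- pairs[r, 1]; gi <- pairs[r, 2]
      prescore_candidate(sp, pm[pi], space$peptides$sequence[pi],
                         space$ladders[[gi]], config$fragment_tol)
    }, numeric(1))
    keep <- order(ps, decreasing = TRUE)[seq_len(min(config$k, nrow(pairs)))]
    pairs <- pairs[keep, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      pi <- pairs[r, 1]; gi <- pairs[r, 2]
      if (space$peptides$is_decoy[pi]) {
        out[[length(out) + 1L]] <- data.frame(pep_idx = pi, gly_idx = gi,
                                              n_nh3 = a, channel = "DT")
      } else {
        out[[length(out) + 1L]] <- data.frame(pep_idx = pi, gly_idx = gi,
                                              n_nh3 = a, channel = "TT")
        out[[length(out) + 1L]] <- data.frame(pep_idx = pi, gly_idx = gi,
                                              n_nh3 = a, channel = "TD")
      }
    }
  }
  if (!length(out))
    return(data.frame(pep_idx = integer(0), gly_idx = integer(0),
                      n_nh3 = integer(0), channel = character(0)))
  do.call(rbind, out)
}

## Fully score one candidate; returns a one-row data.frame.
score_candidate <- function(sp, space, pi, gi, n_nh3, channel, config,
                            frag_model = NULL, site_models = NULL) {
  pep <- space$peptides[pi, ]
  gly_obj <- space$glycan_objects[[gi]]
  decoy_glycan <- channel == "TD"
  ladder <- if (decoy_glycan) {
    make_decoy_ladder(gly_obj, key_seed(paste(pep$sequence,
                                              space$glycans$text[gi]),
                                        config$seed))
  } else space$ladders[[gi]]
  tol <- config$fragment_tol
  masses <- sp$peaks$neutral_mass

  y_theor <- pep$mass + ladder$mass_delta
  y_hit <- vapply(y_theor, function(m) match_mass(masses, m, tol), integer(1))
  hitG <- !is.na(y_hit)
  matched_G <- data.frame(
    intensity = sp$peaks$intensity[y_hit[hitG]],
    ppm = ppm_error(masses[y_hit[hitG]], y_theor[hitG]),
    phi = rep(0, sum(hitG)), glycan_size = ladder$glycan_size[hitG])

  frags <- backbone_fragments(pep$sequence, occupied = pep$site_local)
  b_hit <- vapply(frags$mass, function(m) match_mass(masses, m, tol),
                  integer(1))
  hitP <- !is.na(b_hit)
  matched_P <- data.frame(
    intensity = sp$peaks$intensity[b_hit[hitP]],
    ppm = ppm_error(masses[b_hit[hitP]], frags$mass[hitP]),
    phi = rep(0, sum(hitP)))
  n <- nchar(pep$sequence)
  bond <- ifelse(frags$series == "y", n - frags$index, frags$index)
  coverage_P <- length(unique(bond[hitP])) / (n - 1)

  covs <- glycan_coverage(ladder$mass_delta[hitG], gly_obj, ladder = ladder)
  theo_pre <- pep$mass + gly_obj$mass + n_nh3 * NH3_MASS
  g <- gpsm(matched_P, matched_G, coverage_P, covs$coverage_G,
            covs$coverage_G_core,
            ppm_pre = ppm_error(sp$precursor_mass, theo_pre),
            glycan = gly_obj, oxonium = observed_oxonium(sp, tol))

  u_g <- 0
  if (!is.null(site_models) && "smoothing" %in% config$layers) {
    ## decoy parity by construction: decoy glycans and decoy-peptide sites
    ## resolve to the same u_g as their target counterparts
    u_g <- u_for(site_models, pep$site_id, space$glycans$text[gi],
                 decoy_site_map = space$decoy_site_map)
  }

  if (!is.null(frag_model) && "model" %in% config$layers) {
    key <- partition_key(n, approx_size(gly_obj), sp$precursor_charge,
                         proton_mobility(pep$sequence, sp$precursor_charge),
                         gly_obj$glycan_type)$key
    if (nrow(matched_P)) {
      matched_P$phi <- vapply(which(hitP), function(k)
        predict_reliability(frag_model$reliability,
          extract_pair_features(sp, b_hit[k], "backbone", pep$mass, tol),
          key), numeric(1))
    }
    if (nrow(matched_G)) {
      matched_G$phi <- vapply(which(hitG), function(k)
        predict_reliability(frag_model$reliability,
          extract_pair_features(sp, y_hit[k], "Y", pep$mass, tol),
          key), numeric(1))
    }
    g$matched_P <- matched_P
    g$matched_G <- matched_G
    pred <- predict_intensity(
      frag_model, pep$sequence,
      backbone_frags = frags[hitP, c("series", "index"), drop = FALSE],
      y_ladder = ladder[hitG, , drop = FALSE],
      y_intensities = matched_G$intensity, key = key)
    cors <- cor_terms(g, predicted_P = pred$backbone, predicted_G = pred$y)
    sc_p <- score_peptide_model(g, config$params, cors)
    sc_g <- score_glycan_model(g, config$params, cors, u_g = u_g)
    total <- score_total_model(g, config$params, cors, u_g = u_g)
    cor_prime <- cors$CorPrime_P
  } else {
    sc_p <- score_peptide_base(g, config$params)
    sc_g <- score_glycan_base(g, config$params, u_g = u_g)
    total <- score_total_base(g, config$params, u_g = u_g)
    cor_prime <- 0
  }

  data.frame(
    scan_id = sp$scan_id, peptide = pep$sequence, protein = pep$protein,
    site = pep$site_id, glycan = space$glycans$text[gi],
    mass_shift = n_nh3 * NH3_MASS,
    is_decoy_peptide = channel == "DT", is_decoy_glycan = decoy_glycan,
    score_peptide = sc_p, score_glycan = sc_g, score_total = total,
    coverage_P = coverage_P, coverage_G = covs$coverage_G,
    coverage_G_core = covs$coverage_G_core,
    cor_prime_P = cor_prime, cardinality = gly_obj$cardinality,
    rt = sp$rt, u_g = u_g, stringsAsFactors = FALSE)
}

#' Run a search over a set of spectra
#'
#' Scores every candidate of every spectrum through the enabled layers,
#' keeps the single best assignment per spectrum (the decoy channels compete
#' with the targets), and estimates peptide, glycan and joint q-values.
#'
#' @param spectra list of [spectrum()] objects.
#' @param space a [build_search_space()] result.
#' @param config a [search_config()].
#' @param frag_model optional [train_fragmentation_model()] model (used when
#'   `"model"` is in `config$layers`).
#' @param site_models optional named list of site-glycome models (used when
#'   `"smoothing"` is in `config$layers`).
#' @return results data.frame, one row per identified spectrum, with
#'   `fdr_peptide`, `fdr_glycan`, `fdr_joint` columns.
#' @export
search_run <- function(spectra, space, config = search_config(),
                       frag_model = NULL, site_models = NULL) {
  best <- list()
  for (sp in spectra) {
    cand <- candidates_for(sp, space, config)
    if (nrow(cand) == 0L) next
    scored <- lapply(seq_len(nrow(cand)), function(r)
      score_candidate(sp, space, cand$pep_idx[r], cand$gly_idx[r],
                      cand$n_nh3[r], cand$channel[r], config,
                      frag_model, site_models))
    scored <- do.call(rbind, scored)
    best[[length(best) + 1L]] <- scored[which.max(scored$score_total), ]
  }
  if (!length(best)) {
    return(data.frame(scan_id = character(0)))
  }
  res <- do.call(rbind, best)
  rownames(res) <- NULL
  pf <- peptide_fdr(res[, c("score_peptide", "coverage_P", "cor_prime_P")],
                    res$is_decoy_peptide, seed = config$seed)
  gf <- glycan_fdr(res$score_glycan, res$is_decoy_glycan, res$cardinality)
  res$fdr_peptide <- pf$q
  res$fdr_glycan <- gf$q
  res$glycan_fdr_defined <- gf$glycan_fdr_defined
  res$fdr_joint <- joint_fdr(res$fdr_peptide, res$fdr_glycan,
                             res$glycan_fdr_defined)
  res
}
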