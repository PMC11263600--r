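## Closed-form GPSM scores: the base peptide/glycan mixture, the
## precursor-accuracy and signature-ion bias terms, the fragmentation-model
## enhanced scores, and site-glycome smoothing. Target and decoy candidates
## run through these same functions; there is no decoy-specific path.

#' Default scoring parameters
#'
#' alpha/beta weight the whole-glycan and core coverages, gamma the peptide
#' coverage, w the peptide/glycan mixture; tolerances are fractional (20e-6 =
#' 20 ppm fragments, 5e-6 = 5 ppm precursor).
#'
#' @return list of parameters.
#' @export
default_params <- function() {
  list(alpha = 0.5, beta = 0.4, gamma = 1, w = 0.65,
       tol = 20e-6, precursor_tol = 5e-6,
       mu_pre = 0, sigma_pre = 5e-6)
}

#' Assemble a glycopeptide-spectrum match for scoring
#'
#' @param matched_P data.frame(intensity, ppm, phi) of matched backbone
#'   fragments (phi optional, defaults 0).
#' @param matched_G data.frame(intensity, ppm, phi, glycan_size) of matched
#'   peptide+Y fragments.
#' @param coverage_P fraction of backbone bonds with a matched b or y ion.
#' @param coverage_G,coverage_G_core glycan coverages from
#'   [glycan_coverage()].
#' @param ppm_pre fractional precursor mass error.
#' @param glycan the candidate [glycan_composition()].
#' @param oxonium named relative intensities (fraction of base peak) of
#'   observed signature oxonium ions, e.g. `c(NeuAc = 0.4)`.
#' @param ... extra fields carried through (spectrum/peptide refs etc.).
#' @return a `gpsm` list.
#' @export
gpsm <- function(matched_P, matched_G, coverage_P, coverage_G,
                 coverage_G_core, ppm_pre = 0, glycan = NULL,
                 oxonium = numeric(0), ...) {
  fix <- function(df, y = FALSE) {
    if (is.null(df) || nrow(df) == 0L) {
      df <- data.frame(intensity = numeric(0), ppm = numeric(0),
                       phi = numeric(0))
      if (y) df$glycan_size <- integer(0)
      return(df)
    }
    if (is.null(df$phi)) df$phi <- 0
    df
  }
  structure(
    c(list(matched_P = fix(matched_P), matched_G = fix(matched_G, TRUE),
           coverage_P = coverage_P, coverage_G = coverage_G,
           coverage_G_core = coverage_G_core, ppm_pre = ppm_pre,
           glycan = glycan, oxonium = oxonium),
      list(...)),
    class = "gpsm")
}

## Mass-accuracy down-weight of a matched fragment: 1 - |ppm/tol|^4.
match_weight <- function(ppm, tol) 1 - abs(ppm / tol)^4

## Weighted log-intensity evidence sum shared by all score variants.
evidence_sum <- function(matched, tol, phi_weight = FALSE) {
  if (nrow(matched) == 0L) return(0)
  ok <- matched$intensity > 0
  if (any(!ok)) warning("skipping matched fragment(s) with intensity <= 0")
  m <- matched[ok, , drop = FALSE]
  if (nrow(m) == 0L) return(0)
  base <- log10(m$intensity) * match_weight(m$ppm, tol)
  if (phi_weight) sum(base * (m$phi + 1) + m$phi) else sum(base)
}

#' Base peptide score (coverage-weighted log-intensity sum)
#' @param g a [gpsm()]. @param params scoring parameters.
#' @return nonnegative score when all matched intensities >= 1.
#' @export
score_peptide_base <- function(g, params = default_params()) {
  evidence_sum(g$matched_P, params$tol) * g$coverage_P^params$gamma
}

#' Base glycan score (dual-coverage-weighted log-intensity sum)
#'
#' Optionally smoothed: `u_g` (site-glycome prior credit) is added to the
#' evidence bracket before the coverage scaling, so unsupported glycans
#' (coverage 0) gain nothing from a site model.
#'
#' @param g a [gpsm()]. @param params scoring parameters.
#' @param u_g site-specific glycome smoothing credit (0 = no site model).
#' @export
score_glycan_base <- function(g, params = default_params(), u_g = 0) {
  (evidence_sum(g$matched_G, params$tol) + u_g) *
    g$coverage_G^params$alpha * g$coverage_G_core^params$beta
}

#' Precursor mass-accuracy bias
#'
#' `-10 log10(1 - exp(-(ppm - mu)^2 / (2 sigma^2)))`, a bonus that favors
#' candidates whose precursor mass error sits near mu. The log argument is
#' floored at 1e-3, capping the bonus at 30 for a perfect precursor match.
#'
#' @param ppm_pre fractional precursor error. @param mu_pre,sigma_pre center
#'   and scale (fractional; default 0 and 5e-6).
#' @export
mass_accuracy_bias <- function(ppm_pre, mu_pre = 0, sigma_pre = 5e-6) {
  stopifnot(sigma_pre > 0)
  v <- 1 - exp(-(ppm_pre - mu_pre)^2 / (2 * sigma_pre^2))
  min(-10 * log10(max(v, 1e-3)), 30)
}

#' Signature (oxonium) ion consistency term
#'
#' For each sialic acid (NeuAc, NeuGc): an observed diagnostic oxonium with no
#' corresponding residue in the composition is penalized in proportion to its
#' relative intensity; an expected oxonium absent (<= 1% base peak) is
#' penalized harder the more residues are expected.
#'
#' @param g a [gpsm()] (uses `g$glycan` counts and `g$oxonium`).
#' @return a nonpositive penalty in score units.
#' @export
signature_ion_term <- function(g) {
  total <- 0
  for (m in c("NeuAc", "NeuGc")) {
    o <- if (!is.null(g$glycan)) count_of(g$glycan, m) else 0L
    rel <- if (m %in% names(g$oxonium)) g$oxonium[[m]] else 0
    if (o == 0) {
      total <- total + 10 * log10(1 - min(rel, 0.999))
    } else if (rel <= 0.01) {
      total <- total + 10 * log10(1 - min(o / 2, 0.99))
    }
  }
  total
}

#' Total base GPSM score (mixture + bias terms)
#' @inheritParams score_glycan_base
#' @export
score_total_base <- function(g, params = default_params(), u_g = 0) {
  params$w * score_peptide_base(g, params) +
    (1 - params$w) * score_glycan_base(g, params, u_g = u_g) +
    signature_ion_term(g) +
    mass_accuracy_bias(g$ppm_pre, params$mu_pre, params$sigma_pre)
}

#' Correlation terms between observed and model-predicted intensities
#'
#' @param g a [gpsm()].
#' @param predicted_P,predicted_G predicted intensity vectors aligned to
#'   `matched_P` / `matched_G` rows.
#' @return list(Cor_P, CorPrime_P, Cor_G, Rel_G); all 0 when nothing matched.
#' @export
cor_terms <- function(g, predicted_P = NULL, predicted_G = NULL) {
  m_p <- nrow(g$matched_P)
  m_g <- nrow(g$matched_G)
  if (m_p == 0L && m_g == 0L)
    return(list(Cor_P = 0, CorPrime_P = 0, Cor_G = 0, Rel_G = 0))
  rho_p <- if (m_p > 0L && !is.null(predicted_P))
    safe_cor(g$matched_P$intensity, predicted_P) else 0
  rho_g <- if (m_g > 0L && !is.null(predicted_G))
    safe_cor(g$matched_G$intensity, predicted_G) else 0
  Cor_P <- if (m_p > 0L) (rho_p + 1) * log10(m_p) else 0
  CorPrime_P <- if (m_p > 0L) (rho_p + 1) * m_p * g$coverage_P else 0
  Cor_G <- if (m_g > 0L) (rho_g + 1) / 2 else 0
  pad <- function(x) 0.5 * x + 0.5
  Rel_G <- if (m_g > 0L)
    sum(pad(g$matched_G$phi)) * max(rho_g, 0.25) else 0
  list(Cor_P = Cor_P, CorPrime_P = CorPrime_P, Cor_G = Cor_G, Rel_G = Rel_G)
}

#' Model-enhanced peptide score
#'
#' Reliability phi reweights each peak's evidence (low-confidence peaks are
#' discounted toward the base weight, confident ones doubled plus a flat phi
#' bonus) and the shifted intensity correlation Cor_P rewards matching more
#' fragments that still agree with the predicted pattern.
#'
#' @param g a [gpsm()] with `phi` filled on `matched_P`.
#' @param params scoring parameters.
#' @param cors precomputed [cor_terms()] list.
#' @export
score_peptide_model <- function(g, params = default_params(),
                                cors = cor_terms(g)) {
  (evidence_sum(g$matched_P, params$tol, phi_weight = TRUE) + cors$Cor_P) *
    g$coverage_P^params$gamma
}

#' Count of non-trivial matched peptide+Y fragments
#'
#' Fragments retaining more than one residue; Y0/Y1 match too easily to count
#' as model-significant evidence.
#' @param g a [gpsm()].
#' @export
sigfrag <- function(g) {
  if (nrow(g$matched_G) == 0L) return(0L)
  sum(g$matched_G$glycan_size > 1L)
}

#' Peptide-coverage gate for the glycan model terms
#'
#' `s(x) = min(exp(3x - 1), 1)`: glycan-model credit is attenuated when the
#' peptide backbone itself is poorly covered, since Y-ion evidence presumes
#' the backbone is right.
#' @param x peptide coverage in `[0, 1]`.
#' @export
coverage_gate <- function(x) pmin(exp(3 * x - 1), 1)

#' Model-enhanced glycan score (optionally smoothed)
#'
#' @inheritParams score_peptide_model
#' @param u_g site-glycome smoothing credit added inside the bracket.
#' @export
score_glycan_model <- function(g, params = default_params(),
                               cors = cor_terms(g), u_g = 0) {
  model_term <- (cors$Rel_G + cors$Cor_G) * sigfrag(g) *
    coverage_gate(g$coverage_P)
  (evidence_sum(g$matched_G, params$tol) + model_term + u_g) *
    g$coverage_G^params$alpha * g$coverage_G_core^params$beta
}

#' Total model-enhanced GPSM score
#' @inheritParams score_glycan_model
#' @export
score_total_model <- function(g, params = default_params(),
                              cors = cor_terms(g), u_g = 0) {
  params$w * score_peptide_model(g, params, cors) +
    (1 - params$w) * score_glycan_model(g, params, cors, u_g = u_g) +
    signature_ion_term(g) +
    mass_accuracy_bias(g$ppm_pre, params$mu_pre, params$sigma_pre)
}

## Neutral-mass references for the sialic-acid diagnostic oxonium ions:
## the intact residue and the residue minus water (the singly protonated
## m/z equivalents are residue + proton, e.g. NeuAc 292.1027 / 274.0921).
oxonium_reference <- function() {
  res <- c(NeuAc = residue_mass("NeuAc"), NeuGc = residue_mass("NeuGc"))
  data.frame(
    monosaccharide = rep(names(res), each = 2L),
    neutral_mass = as.numeric(rbind(res, res - WATER_MASS)),
    stringsAsFactors = FALSE)
}

#' Extract observed signature-oxonium relative intensities from a spectrum
#'
#' @param sp a [spectrum()].
#' @param tol fractional mass tolerance.
#' @return named numeric (NeuAc, NeuGc) of max relative intensity (fraction
#'   of base peak) over each residue's diagnostic masses.
#' @export
observed_oxonium <- function(sp, tol = 20e-6) {
  ref <- oxonium_reference()
  base <- max(sp$peaks$intensity, 0)
  out <- c(NeuAc = 0, NeuGc = 0)
  if (base <= 0 || nrow(sp$peaks) == 0L) return(out)
  for (i in seq_len(nrow(ref))) {
    j <- match_mass(sp$peaks$neutral_mass, ref$neutral_mass[i], tol)
    if (!is.na(j)) {
      m <- ref$monosaccharide[i]
      out[m] <- max(out[m], sp$peaks$intensity[j] / base)
    }
  }
  out
}
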