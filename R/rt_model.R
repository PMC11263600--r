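## Relative retention-time modeling over glycoforms of shared peptide
## backbones, the RT agreement score, quasi-isobaric composition/adduct
## revision, and adduct-assignment parsimony.

.RT_MONOS <- c("Hex", "HexNAc", "dHex", "NeuAc", "NeuGc", "Pent")

#' Default quasi-isobaric revision rules
#'
#' The NeuAc+NH3 <-> Hex+dHex family: swapping one sialic acid plus an
#' ammonium adduct for a hexose plus a fucose changes the precursor mass by
#' only ~0.0112 Da, within 5 ppm for precursors above ~2.25 kDa. Both
#' directions are registered. Rule registration asserts mass closure at a
#' stated reference mass.
#'
#' @param precursor_tol fractional precursor tolerance.
#' @param reference_mass reference precursor mass (Da) for the closure check.
#' @return list of revision rules (delta_composition, delta_adducts,
#'   net_mass).
#' @export
default_revision_rules <- function(precursor_tol = 5e-6,
                                   reference_mass = 2250) {
  fwd <- list(delta_composition = c(NeuAc = -1, Hex = 1, dHex = 1),
              delta_adducts = c(NH3 = -1))
  rules <- list(fwd,
                list(delta_composition = -fwd$delta_composition,
                     delta_adducts = -fwd$delta_adducts))
  lapply(rules, function(r) {
    net <- sum(residue_mass(names(r$delta_composition)) * r$delta_composition) +
      sum(NH3_MASS * r$delta_adducts)
    if (abs(net) > precursor_tol * reference_mass)
      stop("revision rule is not mass-closed at the reference mass")
    r$net_mass <- net
    r
  })
}

#' Construct an eluted identification table
#'
#' @param backbone peptide backbone key (sequence or sequence+site).
#' @param glycan canonical composition strings.
#' @param adduct_nh3 ammonium adduct counts.
#' @param apex_rt apex retention times, minutes.
#' @param abundance MS1 feature abundances (> 0).
#' @param ms2_score MS2 identification scores.
#' @param neuac_oxonium relative intensity of the NeuAc diagnostic ion
#'   observed for the ID's spectra (0 when absent).
#' @return data.frame of eluted IDs.
#' @export
eluted_ids <- function(backbone, glycan, adduct_nh3 = 0L, apex_rt,
                       abundance = 1, ms2_score = 1,
                       neuac_oxonium = 0) {
  data.frame(backbone = backbone, glycan = glycan,
             adduct_nh3 = adduct_nh3, apex_rt = apex_rt,
             abundance = abundance, ms2_score = ms2_score,
             neuac_oxonium = neuac_oxonium, stringsAsFactors = FALSE)
}

id_count_matrix <- function(glycan_strings) {
  t(vapply(glycan_strings, function(s) {
    g <- parse_composition(s)
    v <- stats::setNames(numeric(length(.RT_MONOS)), .RT_MONOS)
    v[names(g$counts)] <- g$counts
    v
  }, numeric(length(.RT_MONOS))))
}

make_bins <- function(rt_min, rt_max, n_bins = 8L) {
  span <- max(rt_max - rt_min, 1e-6)
  ## overlapping bins: centers evenly spaced, width twice the spacing
  ## (50% overlap between adjacent bins)
  centers <- seq(rt_min, rt_max, length.out = n_bins)
  width <- if (n_bins > 1L) 2 * diff(centers[1:2]) else span
  data.frame(center = centers, lo = centers - width / 2,
             hi = centers + width / 2)
}

fit_bin_coefficients <- function(delta_rt, X, rt, bins, weights) {
  coefs <- matrix(NA_real_, nrow(bins), ncol(X),
                  dimnames = list(NULL, colnames(X)))
  resid_scale <- rep(NA_real_, nrow(bins))
  for (b in seq_len(nrow(bins))) {
    in_bin <- rt >= bins$lo[b] & rt <= bins$hi[b]
    if (sum(in_bin) < ncol(X) + 1L) next
    Xb <- X[in_bin, , drop = FALSE]
    keep <- colSums(Xb != 0) > 0
    if (!any(keep)) next
    ## robust refit: misassigned glycoforms sit far off the elution model, so
    ## trim gross outliers after an initial fit and refit on the consensus
    w <- weights[in_bin]
    yb <- delta_rt[in_bin]
    fit <- stats::lm.wfit(Xb[, keep, drop = FALSE], yb, w = w)
    w_r <- w
    for (rnd in 1:2) {
      s <- max(stats::mad(fit$residuals[w_r > 0], center = 0), 1e-3)
      w_new <- w * as.numeric(abs(fit$residuals) <= 3 * s)
      if (sum(w_new > 0) < ncol(Xb) + 1L) break
      w_r <- w_new
      fit <- stats::lm.wfit(Xb[, keep, drop = FALSE], yb, w = w_r)
    }
    cf <- stats::setNames(rep(0, ncol(X)), colnames(X))
    cf[names(fit$coefficients)] <- ifelse(is.na(fit$coefficients), 0,
                                          fit$coefficients)
    coefs[b, ] <- cf
    ## scale from the consensus rows only: masked outliers must not widen it
    resid_scale[b] <- max(stats::mad(fit$residuals[w_r > 0], center = 0),
                          1e-3)
  }
  list(coefs = coefs, resid_scale = resid_scale)
}

#' Fit the relative retention-time model
#'
#' For every peptide backbone with at least `min_glycoforms` identified
#' glycoforms, the abundance-weighted mean apex defines a reference RT and
#' the abundance-weighted mean composition a reference glycan. Within
#' overlapping RT bins, apex deviations are regressed on signed
#' monosaccharide-count differences and ammonium adduct counts, giving
#' time-local minutes-per-residue coefficients. The fit then iterates:
#' backbones not yet covered whose glycan compositions lie within L1
#' distance 2 of a covered composition are anchored with model-predicted
#' references and the model refit, until coverage stops growing (max 10
#' rounds). The per-bin residual scale is 1.4826 x median absolute residual.
#'
#' @param ids an [eluted_ids()] table.
#' @param min_glycoforms minimum glycoforms per eligible backbone.
#' @param n_bins number of overlapping RT bins.
#' @return an `rt_model` or NULL when no backbone is eligible; carries the
#'   coverage fraction of backbones.
#' @export
fit_rt_model <- function(ids, min_glycoforms = 2L, n_bins = 8L) {
  tab <- table(ids$backbone)
  eligible <- names(tab)[tab >= min_glycoforms]
  if (length(eligible) == 0L) return(NULL)
  run_span <- c(min(ids$apex_rt), max(ids$apex_rt))
  bins <- make_bins(run_span[1], run_span[2], n_bins)
  Xc <- id_count_matrix(ids$glycan)
  wt <- log1p(ids$abundance)
  mask <- rep(1, nrow(ids))  # quasi-isobaric misassignments get masked out

  backbone_refs <- function(covered) {
    refs <- list()
    for (bb in covered) {
      sel <- ids$backbone == bb
      w <- wt[sel] * mask[sel]
      if (sum(w) <= 0) w <- wt[sel]
      refs[[bb]] <- list(
        rt = sum(ids$apex_rt[sel] * w) / sum(w),
        comp = colSums(Xc[sel, , drop = FALSE] * w) / sum(w),
        adduct = sum(ids$adduct_nh3[sel] * w) / sum(w))
    }
    refs
  }

  fit_once <- function(refs) {
    covered <- names(refs)
    sel <- ids$backbone %in% covered
    ref_rt <- vapply(ids$backbone[sel], function(b) refs[[b]]$rt, numeric(1))
    ref_comp <- t(vapply(ids$backbone[sel], function(b) refs[[b]]$comp,
                         numeric(length(.RT_MONOS))))
    ref_add <- vapply(ids$backbone[sel], function(b) refs[[b]]$adduct,
                      numeric(1))
    X <- cbind(Xc[sel, , drop = FALSE] - ref_comp,
               NH3 = ids$adduct_nh3[sel] - ref_add)
    fit_bin_coefficients(ids$apex_rt[sel] - ref_rt, X, ids$apex_rt[sel],
                         bins, weights = (wt * mask)[sel])
  }

  covered <- eligible
  refs <- backbone_refs(covered)
  fit <- fit_once(refs)
  ## mask IDs whose apex sits far off the consensus model (e.g. swapped
  ## composition/adduct assignments), recompute references and refit: the
  ## model should describe the consistent majority
  for (robust_round in 1:3) {
    model_tmp <- structure(list(bins = bins, coefs = fit$coefs,
                                resid_scale = fit$resid_scale,
                                refs = refs, run_span = run_span),
                           class = "rt_model")
    new_mask <- mask
    for (i in which(ids$backbone %in% covered)) {
      ## leave-one-out reference: a misassigned ID must not pull its own
      ## backbone reference toward itself before being judged
      pred <- predict_rt(model_tmp, ids[i, , drop = FALSE],
                         ref = loo_reference(
                           ids, i,
                           exclude_keys = id_key(ids[mask == 0, ,
                                                     drop = FALSE])))
      if (is.na(pred)) next
      s <- local_resid_scale(model_tmp, ids$apex_rt[i])
      new_mask[i] <- as.numeric(abs(ids$apex_rt[i] - pred) <= 2.5 * s)
    }
    if (all(new_mask == mask)) break
    mask <- new_mask
    refs <- backbone_refs(covered)
    fit <- fit_once(refs)
  }
  all_bb <- unique(ids$backbone)
  for (round in seq_len(10L)) {
    uncovered <- setdiff(all_bb, covered)
    if (length(uncovered) == 0L) break
    cov_comp <- Xc[ids$backbone %in% covered, , drop = FALSE]
    newly <- character(0)
    for (bb in uncovered) {
      comp_bb <- Xc[ids$backbone == bb, , drop = FALSE]
      d <- apply(cov_comp, 1, function(cc)
        min(rowSums(abs(sweep(comp_bb, 2, cc)))))
      if (min(d) <= 2) newly <- c(newly, bb)
    }
    if (length(newly) == 0L) break
    ## anchor new backbones with model-predicted composition deltas
    model_tmp <- structure(list(bins = bins, coefs = fit$coefs,
                                resid_scale = fit$resid_scale,
                                refs = refs, run_span = run_span),
                           class = "rt_model")
    for (bb in newly) {
      sel <- which(ids$backbone == bb)
      w <- log1p(ids$abundance[sel])
      mean_comp <- colSums(Xc[sel, , drop = FALSE] * w) / sum(w)
      mean_add <- sum(ids$adduct_nh3[sel] * w) / sum(w)
      deltas <- vapply(sel, function(i) {
        blend_coefs(model_tmp, ids$apex_rt[i]) %*%
          c(Xc[i, ] - mean_comp, ids$adduct_nh3[i] - mean_add)
      }, numeric(1))
      refs[[bb]] <- list(rt = sum((ids$apex_rt[sel] - deltas) * w) / sum(w),
                         comp = mean_comp, adduct = mean_add)
    }
    covered <- c(covered, newly)
    fit <- fit_once(refs)
  }
  structure(list(bins = bins, coefs = fit$coefs,
                 resid_scale = fit$resid_scale, refs = refs,
                 run_span = run_span,
                 coverage = length(covered) / length(all_bb),
                 masked_keys = id_key(ids[mask == 0, , drop = FALSE])),
            class = "rt_model")
}

## Overlap-weighted blend of per-bin coefficient rows at a time point:
## triangular weights peaking at each bin center, so adjacent overlapping
## bins interpolate smoothly.
blend_coefs <- function(model, rt) {
  bins <- model$bins
  halfw <- (bins$hi - bins$lo) / 2
  w <- pmax(1 - abs(rt - bins$center) / halfw, 0)
  ok <- !is.na(model$coefs[, 1]) & w > 0
  if (!any(ok)) {
    ok <- !is.na(model$coefs[, 1])
    if (!any(ok)) return(rep(0, ncol(model$coefs)))
    nearest <- which(ok)[which.min(abs(bins$center[ok] - rt))]
    return(model$coefs[nearest, ])
  }
  drop(crossprod(model$coefs[ok, , drop = FALSE], w[ok]) / sum(w[ok]))
}

local_resid_scale <- function(model, rt) {
  ok <- !is.na(model$resid_scale)
  if (!any(ok)) return(Inf)
  nearest <- which(ok)[which.min(abs(model$bins$center[ok] - rt))]
  model$resid_scale[nearest]
}

#' Predict the apex RT of an eluted identification
#'
#' @param model an [fit_rt_model()] model.
#' @param id one-row [eluted_ids()] data.frame.
#' @param ref optional reference override (list with `rt`, `comp`,
#'   `adduct`), e.g. a leave-one-out reference during revision.
#' @return predicted minutes, or NA when the backbone is not covered (the
#'   consumer must skip such IDs).
#' @export
predict_rt <- function(model, id, ref = NULL) {
  if (is.null(ref)) ref <- model$refs[[id$backbone]]
  if (is.null(ref)) return(NA_real_)
  delta <- c(id_count_matrix(id$glycan)[1, ] - ref$comp,
             NH3 = id$adduct_nh3 - ref$adduct)
  ref$rt + drop(blend_coefs(model, ref$rt) %*% delta)
}

id_key <- function(ids) {
  sprintf("%s|%s|%d|%.4f", ids$backbone, ids$glycan, ids$adduct_nh3,
          ids$apex_rt)
}

## Backbone reference from the other identifications of the same backbone:
## excluding the ID under scrutiny (and any ID the model flagged as an
## elution outlier) stops misassigned compositions from dragging the
## reference toward themselves.
loo_reference <- function(ids, i, exclude_keys = character(0)) {
  sel <- which(ids$backbone == ids$backbone[i])
  sel <- setdiff(sel, i)
  if (length(exclude_keys)) {
    clean <- sel[!(id_key(ids[sel, , drop = FALSE]) %in% exclude_keys)]
    if (length(clean)) sel <- clean
  }
  if (!length(sel)) return(NULL)
  w <- log1p(ids$abundance[sel])
  Xc <- id_count_matrix(ids$glycan[sel])
  list(rt = sum(ids$apex_rt[sel] * w) / sum(w),
       comp = colSums(Xc * w) / sum(w),
       adduct = sum(ids$adduct_nh3[sel] * w) / sum(w))
}

#' RT agreement score
#'
#' `max(0, 1 - 2|residual|/span)`: one minus the probability that a uniformly
#' random time point lands within the observed residual of the prediction, so
#' 0.75 corresponds to a 25% chance match by random elution.
#'
#' @param model an rt model. @param id one-row eluted ID.
#' @return score in `[0, 1]` (NA when uncovered).
#' @export
rt_score <- function(model, id) {
  pred <- predict_rt(model, id)
  if (is.na(pred)) return(NA_real_)
  span <- max(model$run_span[2] - model$run_span[1], 1e-6)
  max(0, 1 - 2 * abs(id$apex_rt - pred) / span)
}

apply_rule <- function(id, rule, glycan_space) {
  g <- parse_composition(id$glycan)
  counts <- stats::setNames(numeric(length(.RT_MONOS)), .RT_MONOS)
  counts[names(g$counts)] <- g$counts
  for (m in names(rule$delta_composition))
    counts[m] <- counts[m] + rule$delta_composition[[m]]
  nh3 <- id$adduct_nh3 + if ("NH3" %in% names(rule$delta_adducts))
    rule$delta_adducts[["NH3"]] else 0
  if (any(counts < 0) || nh3 < 0) return(NULL)
  new_g <- format(glycan_composition(
    stats::setNames(as.integer(counts[counts > 0]),
                    names(counts)[counts > 0]),
    g$glycan_type))
  if (!is.null(glycan_space) && !(new_g %in% glycan_space)) return(NULL)
  out <- id
  out$glycan <- new_g
  out$adduct_nh3 <- nh3
  out
}

#' Revise quasi-isobaric composition/adduct assignments by retention time
#'
#' For each covered ID, the identity assignment competes with every
#' applicable revision rule; the candidate minimizing the absolute RT
#' residual wins if it improves on the identity by more than twice the local
#' residual scale, diagnostic-ion evidence does not contradict it (a revision
#' removing the last NeuAc is vetoed when the NeuAc oxonium is present above
#' 1% of base peak, and adding the first NeuAc is vetoed when it is absent),
#' and the optional guard accepts. Provenance is recorded in `revised_from`.
#' Revision is idempotent: re-running on its own output changes nothing.
#'
#' @param model an [fit_rt_model()] model.
#' @param ids an [eluted_ids()] table.
#' @param rules revision rules ([default_revision_rules()]).
#' @param glycan_space canonical strings of the searchable compositions
#'   (candidates outside it are never proposed).
#' @param fdr_guard optional function(old_id, new_id) -> logical.
#' @return `ids` with possibly revised glycan/adduct columns and a
#'   `revised_from` provenance column.
#' @export
revise <- function(model, ids, rules = default_revision_rules(),
                   glycan_space = NULL, fdr_guard = NULL) {
  ids$revised_from <- ids$revised_from %||% NA_character_
  for (i in seq_len(nrow(ids))) {
    id <- ids[i, , drop = FALSE]
    if (!is.na(id$revised_from)) next  # idempotence: already revised
    ref <- loo_reference(ids, i, exclude_keys = model$masked_keys %||%
                           character(0))
    pred0 <- predict_rt(model, id, ref = ref)
    if (is.na(pred0)) next
    resid0 <- abs(id$apex_rt - pred0)
    scale <- local_resid_scale(model, id$apex_rt)
    best <- NULL; best_resid <- resid0
    for (rule in rules) {
      cand <- apply_rule(id, rule, glycan_space)
      if (is.null(cand)) next
      ## diagnostic-ion veto on sialic-acid changes
      dNeuAc <- if ("NeuAc" %in% names(rule$delta_composition))
        rule$delta_composition[["NeuAc"]] else 0
      had <- count_of(parse_composition(id$glycan), "NeuAc")
      if (dNeuAc < 0 && had + dNeuAc == 0 && id$neuac_oxonium > 0.01) next
      if (dNeuAc > 0 && had == 0 && id$neuac_oxonium <= 0.01) next
      pred <- predict_rt(model, cand, ref = ref)
      if (is.na(pred)) next
      r <- abs(cand$apex_rt - pred)
      if (r < best_resid) { best <- cand; best_resid <- r }
    }
    if (!is.null(best) && (resid0 - best_resid) > 2 * scale &&
        (is.null(fdr_guard) || isTRUE(fdr_guard(id, best)))) {
      best$revised_from <- sprintf("%s+%dNH3", id$glycan, id$adduct_nh3)
      ids[i, ] <- best
    }
  }
  ids
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parsimony reassignment of adducted identifications
#'
#' Within groups of identifications explaining the same MS1 feature, a
#' mass-shifted (adducted) assignment with no RT-overlapping unshifted
#' glycoform of the same glycopeptide is replaced by a rule-mapped unshifted
#' alternative when one exists in the candidate glycan space; unshifted
#' assignments are never touched.
#'
#' @param ids an [eluted_ids()] table with `rt_start`/`rt_end` columns (the
#'   feature's elution window).
#' @param rules revision rules.
#' @param glycan_space canonical strings of searchable compositions.
#' @return the table with reassigned rows flagged in `reassigned`.
#' @export
parsimony_reassign <- function(ids, rules = default_revision_rules(),
                               glycan_space = NULL) {
  ids$reassigned <- FALSE
  if (is.null(ids$rt_start)) ids$rt_start <- ids$apex_rt - 0.5
  if (is.null(ids$rt_end)) ids$rt_end <- ids$apex_rt + 0.5
  for (i in seq_len(nrow(ids))) {
    if (ids$adduct_nh3[i] == 0L) next
    same <- ids$backbone == ids$backbone[i] & ids$glycan == ids$glycan[i] &
      ids$adduct_nh3 == 0L
    overlap <- same & ids$rt_start <= ids$rt_end[i] &
      ids$rt_end >= ids$rt_start[i]
    if (any(overlap)) next  # an unshifted version co-elutes: keep as is
    for (rule in rules) {
      cand <- apply_rule(ids[i, , drop = FALSE], rule, glycan_space)
      if (!is.null(cand) && cand$adduct_nh3 == 0L) {
        keep_flag <- ids$reassigned
        cand$reassigned <- TRUE
        ids[i, ] <- cand
        ids$reassigned[-i] <- keep_flag[-i]
        break
      }
    }
  }
  ids
}
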