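## Partitioned fragmentation learning: a peak-relation reliability model
## (naive-Bayes likelihood ratios over inter-peak mass-offset features) and a
## weighted multinomial relative-intensity model fit by Newton/IRLS, split by
## whether the dominant peptide+Y series ascends or descends with glycan size.

.LEN_BIN_EDGES <- c(10, 15, 20, 27)    # peptide length bins: <=10, 11-15, 16-20, 21-27, >=28
.GLYCAN_SIZE_EDGE <- 9                 # n_g <= 9 vs >= 10
.CHARGE_BINS <- 5L                     # 1,2,3,4,>=5
.MOBILITY_LEVELS <- c("mobile", "partial", "immobile")

#' Fragmentation-model partition key
#'
#' Spectra are partitioned by peptide length, approximate glycan size,
#' precursor charge and proton mobility (5 x 2 x 5 x 3 = 150 cells per
#' glycosylation type) because fragmentation behavior shifts along each axis.
#'
#' @param peptide_len peptide length (residues).
#' @param n_g approximate glycan size from [approx_size()].
#' @param charge precursor charge.
#' @param mobility proton mobility class from [proton_mobility()].
#' @param glyco_type `"N"` or `"O"`.
#' @return list with the bin indices and a canonical `key` string.
#' @export
partition_key <- function(peptide_len, n_g, charge, mobility,
                          glyco_type = "N") {
  len_bin <- findInterval(peptide_len, .LEN_BIN_EDGES + 1L) + 1L
  size_bin <- if (n_g <= .GLYCAN_SIZE_EDGE) 1L else 2L
  charge_bin <- min(max(charge, 1L), .CHARGE_BINS)
  mobility <- match.arg(mobility, .MOBILITY_LEVELS)
  key <- sprintf("%s|L%d|G%d|Z%d|%s", glyco_type, len_bin, size_bin,
                 charge_bin, mobility)
  list(len_bin = len_bin, size_bin = size_bin, charge_bin = charge_bin,
       mobility = mobility, glyco_type = glyco_type, key = key)
}

#' Number of partition cells per glycosylation type
#' @export
partition_grid_size <- function() {
  (length(.LEN_BIN_EDGES) + 1L) * 2L * .CHARGE_BINS * length(.MOBILITY_LEVELS)
}

parse_partition_key <- function(key) {
  p <- strsplit(key, "\\|")[[1]]
  list(glyco_type = p[1],
       len_bin = as.integer(sub("L", "", p[2])),
       size_bin = as.integer(sub("G", "", p[3])),
       charge_bin = as.integer(sub("Z", "", p[4])),
       mobility = p[5])
}

## Manhattan distance between two partition keys (mobility: 1 per class step;
## different glyco_type is infinitely far).
partition_distance <- function(a, b) {
  ka <- parse_partition_key(a); kb <- parse_partition_key(b)
  if (ka$glyco_type != kb$glyco_type) return(Inf)
  abs(ka$len_bin - kb$len_bin) + abs(ka$size_bin - kb$size_bin) +
    abs(ka$charge_bin - kb$charge_bin) +
    abs(match(ka$mobility, .MOBILITY_LEVELS) -
        match(kb$mobility, .MOBILITY_LEVELS))
}

## ---- peak-relation features ----------------------------------------------

#' Inter-peak relationship features of one peak
#'
#' Binary features describing whether another peak sits at a diagnostic mass
#' offset: each amino-acid residue mass and the HexNAc offset for backbone
#' series; HexNAc/Hex/dHex offsets for peptide+Y series; and the b/y
#' complement pair when the candidate peptide mass is known. All offsets are
#' checked both directions at the fragment tolerance.
#'
#' @param sp a [spectrum()].
#' @param peak_index index into `sp$peaks`.
#' @param series `"all"` (default), `"backbone"` or `"Y"` to restrict the
#'   feature family.
#' @param peptide_mass candidate peptide neutral mass for the complement
#'   feature (skipped when NULL).
#' @param tol fractional mass tolerance.
#' @return character vector of fired feature names.
#' @export
extract_pair_features <- function(sp, peak_index, series = "all",
                                  peptide_mass = NULL, tol = 20e-6) {
  masses <- sp$peaks$neutral_mass
  if (length(masses) < 2L) return(character(0))
  m0 <- masses[peak_index]
  others <- masses[-peak_index]
  has_partner <- function(offset) {
    target_up <- m0 + offset
    target_dn <- m0 - offset
    !is.na(match_mass(others, target_up, tol)) ||
      (target_dn > 0 && !is.na(match_mass(others, target_dn, tol)))
  }
  fired <- character(0)
  if (series %in% c("all", "backbone")) {
    for (aa in names(.AA_RESIDUE_MASS)) {
      if (aa == "I") next  # isobaric with L
      if (has_partner(.AA_RESIDUE_MASS[[aa]]))
        fired <- c(fired, paste0("aa:", aa))
    }
    if (has_partner(residue_mass("HexNAc"))) fired <- c(fired, "b.hexnac")
    if (!is.null(peptide_mass)) {
      comp <- peptide_mass - m0
      if (comp > 0 && !is.na(match_mass(others, comp, tol)))
        fired <- c(fired, "complement")
    }
  }
  if (series %in% c("all", "Y")) {
    if (has_partner(residue_mass("HexNAc"))) fired <- c(fired, "Y.hexnac")
    if (has_partner(residue_mass("Hex"))) fired <- c(fired, "Y.hex")
    if (has_partner(residue_mass("dHex"))) fired <- c(fired, "Y.dhex")
  }
  unique(fired)
}

## Peaks entering reliability training: all annotated peaks plus unannotated
## peaks at or above a relative-intensity floor (0.1% of base peak) - a noise
## gate standing in for the intensity-rank rule; inference is unrestricted.
.TRAIN_INTENSITY_FLOOR <- 0.001

training_peak_table <- function(asp, tol) {
  pk <- asp$spectrum$peaks
  base <- max(pk$intensity)
  annotated <- nzchar(pk$label) & pk$label != "noise"
  keep <- annotated | pk$intensity >= .TRAIN_INTENSITY_FLOOR * base
  idx <- which(keep)
  feats <- lapply(idx, function(i)
    extract_pair_features(asp$spectrum, i, "all",
                          peptide_mass = asp$peptide_mass, tol = tol))
  list(annotated = annotated[idx], features = feats)
}

#' Fit the peak-relation reliability model
#'
#' Per partition: each feature's likelihood ratio
#' `P(feature | annotated) / P(feature | unannotated)` with add-one
#' smoothing, plus the annotated-fraction prior. Partitions with fewer than
#' `min_spectra` training spectra borrow their adjacent charge bins; a global
#' model backs everything.
#'
#' @param training list of annotated training GPSMs, each a list with
#'   `spectrum` (labelled peaks), `peptide` (sequence), `peptide_mass`,
#'   `glycan`, `charge`.
#' @param tol fractional fragment tolerance.
#' @param min_spectra minimum spectra per partition before borrowing.
#' @return a `reliability_model`: list(partitions, global).
#' @export
fit_reliability <- function(training, tol = 20e-6, min_spectra = 50L) {
  keys <- vapply(training, function(x)
    partition_key(nchar(x$peptide), approx_size(x$glycan), x$charge,
                  proton_mobility(x$peptide, x$charge),
                  x$glycan$glycan_type)$key, character(1))
  tables <- lapply(training, training_peak_table, tol = tol)

  estimate <- function(tab_list) {
    ann_feats <- unlist(lapply(tab_list, function(t) unlist(t$features[t$annotated])))
    un_feats <- unlist(lapply(tab_list, function(t) unlist(t$features[!t$annotated])))
    n_ann <- sum(vapply(tab_list, function(t) sum(t$annotated), integer(1)))
    n_un <- sum(vapply(tab_list, function(t) sum(!t$annotated), integer(1)))
    if (n_ann + n_un == 0L) return(NULL)
    all_feats <- unique(c(ann_feats, un_feats))
    ca <- table(factor(ann_feats, levels = all_feats))
    cu <- table(factor(un_feats, levels = all_feats))
    lr <- ((as.numeric(ca) + 1) / (n_ann + 2)) /
      ((as.numeric(cu) + 1) / (n_un + 2))
    names(lr) <- all_feats
    list(prior = (n_ann + 1) / (n_ann + n_un + 2), lr = lr,
         n_spectra = length(tab_list))
  }

  partitions <- list()
  for (k in unique(keys)) {
    members <- which(keys == k)
    if (length(members) < min_spectra) {
      ## borrow adjacent charge bins
      pk <- parse_partition_key(k)
      for (dz in c(-1L, 1L)) {
        zb <- pk$charge_bin + dz
        if (zb >= 1L && zb <= .CHARGE_BINS) {
          k2 <- sprintf("%s|L%d|G%d|Z%d|%s", pk$glyco_type, pk$len_bin,
                        pk$size_bin, zb, pk$mobility)
          members <- union(members, which(keys == k2))
        }
      }
    }
    est <- estimate(tables[members])
    if (!is.null(est)) partitions[[k]] <- est
  }
  structure(list(partitions = partitions, global = estimate(tables)),
            class = "reliability_model")
}

#' Posterior reliability of a matched peak
#'
#' Naive-Bayes combination of the fired features' likelihood ratios with the
#' partition prior: `phi = prior * prod(LR) / (prior * prod(LR) + 1 - prior)`.
#'
#' @param model a [fit_reliability()] model.
#' @param features fired feature names (from [extract_pair_features()]).
#' @param key partition key string (nearest fitted partition used if absent;
#'   global model as last resort).
#' @return phi in `[0, 1]`.
#' @export
predict_reliability <- function(model, features, key = NULL) {
  part <- NULL
  if (!is.null(key)) {
    part <- model$partitions[[key]]
    if (is.null(part) && length(model$partitions)) {
      d <- vapply(names(model$partitions), partition_distance, numeric(1),
                  a = key)
      if (any(is.finite(d)))
        part <- model$partitions[[names(which.min(d))]]
    }
  }
  if (is.null(part)) part <- model$global
  if (is.null(part)) return(0)
  lrs <- part$lr[features]
  lrs <- lrs[!is.na(lrs)]
  odds <- part$prior / (1 - part$prior) * prod(lrs)
  odds / (1 + odds)
}

## ---- ladder direction -----------------------------------------------------

#' Classify a peptide+Y ladder as ascending or descending
#'
#' Sign of the rank correlation between attached glycan size and matched
#' intensity; ties and sparse ladders (< 2 distinct sizes) default to
#' descending, the majority class under stepped collision energy.
#'
#' @param glycan_sizes,intensities matched Y fragment sizes and intensities.
#' @return `"ascending"` or `"descending"`.
#' @export
ladder_direction <- function(glycan_sizes, intensities) {
  if (length(glycan_sizes) < 2L || length(unique(glycan_sizes)) < 2L)
    return("descending")
  rho <- safe_cor(rank(glycan_sizes), rank(intensities))
  if (length(glycan_sizes) == 2L)  # safe_cor needs >= 3 points
    rho <- sign(diff(intensities[order(glycan_sizes)]))
  if (rho > 0) "ascending" else "descending"
}

## ---- intensity model ------------------------------------------------------

#' Feature matrix for backbone fragment intensity prediction
#'
#' @param sequence peptide string.
#' @param frags data.frame(series, index) of b/y fragments.
#' @return numeric matrix, one row per fragment.
#' @export
backbone_feature_matrix <- function(sequence, frags) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  rows <- matrix(0, nrow(frags), 11,
                 dimnames = list(NULL, c(
                   "is_y", "relpos", "relpos2", "basic_frac",
                   "nflank_K", "nflank_R", "nflank_H", "nflank_P",
                   "nflank_DE", "cflank_P", "cflank_G")))
  for (i in seq_len(nrow(frags))) {
    is_y <- frags$series[i] == "y"
    idx <- frags$index[i]
    bond <- if (is_y) n - idx else idx       # cleavage after position `bond`
    span <- if (is_y) (bond + 1L):n else 1L:bond
    left <- chars[bond]; right <- chars[bond + 1L]
    rows[i, ] <- c(
      as.numeric(is_y), bond / (n - 1), (bond / (n - 1))^2,
      sum(chars[span] %in% c("K", "R", "H")) / length(span),
      as.numeric(left == "K"), as.numeric(left == "R"),
      as.numeric(left == "H"), as.numeric(left == "P"),
      as.numeric(left %in% c("D", "E")), as.numeric(right == "P"),
      as.numeric(right == "G"))
  }
  rows
}

#' Feature matrix for peptide+Y fragment intensity prediction
#'
#' @param ladder data.frame(composition, glycan_size, is_core) ladder rows.
#' @return numeric matrix, one row per fragment.
#' @export
y_feature_matrix <- function(ladder) {
  size <- ladder$glycan_size
  hexnac <- vapply(ladder$composition, function(cc) {
    count_of(parse_composition(cc), "HexNAc")
  }, integer(1))
  dhex <- vapply(ladder$composition, function(cc) {
    count_of(parse_composition(cc), "dHex")
  }, integer(1))
  cbind(size = size / 10, size2 = (size / 10)^2,
        is_core = as.numeric(ladder$is_core),
        log_size = log1p(size),
        hexnac_frac = ifelse(size > 0, hexnac / size, 0),
        has_dhex = as.numeric(dhex > 0))
}

softmax <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Fit a weighted multinomial intensity model by Newton/IRLS
#'
#' Maximizes the weighted multinomial log-likelihood where each training
#' spectrum's observed relative intensities (normalized over its fragment
#' group) act as outcome proportions under a softmax of fragment features.
#' Spectra are weighted by their total matched signal and individual peaks by
#' their reliability (or 1 when the reliability weighting destabilizes the
#' fit).
#'
#' @param units list of training units: each `list(X, y, w_spectrum, w_peaks)`
#'   with `X` a fragment feature matrix and `y` observed proportions.
#' @param ridge ridge added to the Hessian on singularity.
#' @param penalty L2 penalty on theta, keeping sparse partitions bounded.
#' @param max_iter,tol Newton iteration controls.
#' @return list(theta, converged, iterations, ll_trace, uniform_fallback).
#' @export
fit_intensity <- function(units, ridge = 1e-4, penalty = 1e-3,
                          max_iter = 100L, tol = 1e-6) {
  units <- Filter(function(u) nrow(u$X) >= 2L && sum(u$y) > 0, units)
  p <- if (length(units)) ncol(units[[1]]$X) else 0L
  if (length(units) == 0L || p == 0L) {
    return(list(theta = numeric(p), converged = FALSE, iterations = 0L,
                ll_trace = numeric(0), uniform_fallback = TRUE))
  }
  for (k in seq_along(units)) {
    u <- units[[k]]
    if (is.null(u$w_peaks)) u$w_peaks <- rep(1, nrow(u$X))
    if (is.null(u$w_spectrum)) u$w_spectrum <- 1
    u$c <- u$w_spectrum * u$w_peaks * (u$y / sum(u$y))
    units[[k]] <- u
  }
  loglik <- function(theta) {
    sum(vapply(units, function(u) {
      pr <- softmax(drop(u$X %*% theta))
      sum(u$c * log(pmax(pr, 1e-300)))
    }, numeric(1))) - 0.5 * penalty * sum(theta^2)
  }
  theta <- numeric(p)
  ll <- loglik(theta)
  trace <- ll
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    grad <- -penalty * theta
    hess <- diag(penalty, p)
    for (u in units) {
      pr <- softmax(drop(u$X %*% theta))
      C <- sum(u$c)
      xbar <- drop(crossprod(pr, u$X))
      grad <- grad + drop(crossprod(u$c, u$X)) - C * xbar
      hess <- hess + C * (crossprod(u$X * pr, u$X) - tcrossprod(xbar))
    }
    step <- tryCatch(solve(hess + diag(1e-10, p), grad),
                     error = function(e) solve(hess + diag(ridge, p), grad))
    ## damped Newton: halve until the objective improves
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-6 && ll_new < ll) break
    delta <- ll_new - ll
    theta <- cand
    ll <- ll_new
    trace <- c(trace, ll)
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  list(theta = unname(theta), converged = converged, iterations = it,
       ll_trace = trace, uniform_fallback = FALSE)
}

#' Predict relative fragment intensities from a fitted theta
#' @param theta coefficient vector.
#' @param X fragment feature matrix.
#' @return probability vector over the rows of `X` (sums to 1).
#' @export
predict_intensity_theta <- function(theta, X) {
  if (length(theta) == 0L || all(theta == 0)) return(rep(1 / nrow(X), nrow(X)))
  softmax(drop(X %*% theta))
}

## ---- full fragmentation model --------------------------------------------

annotated_to_units <- function(training, reliability = NULL, tol = 20e-6) {
  backbone <- list(); y_asc <- list(); y_desc <- list()
  for (asp in training) {
    pk <- asp$spectrum$peaks
    lab <- pk$label
    key <- partition_key(nchar(asp$peptide), approx_size(asp$glycan),
                         asp$charge, proton_mobility(asp$peptide, asp$charge),
                         asp$glycan$glycan_type)$key
    ## backbone unit
    is_b <- grepl("^[by][0-9]+$", lab)
    if (sum(is_b) >= 2L) {
      frags <- data.frame(series = substr(lab[is_b], 1, 1),
                          index = as.integer(sub("^[by]", "", lab[is_b])))
      X <- backbone_feature_matrix(asp$peptide, frags)
      inten <- pk$intensity[is_b]
      w_pk <- if (is.null(reliability)) rep(1, sum(is_b)) else
        vapply(which(is_b), function(i)
          predict_reliability(reliability,
                              extract_pair_features(asp$spectrum, i, "backbone",
                                                    asp$peptide_mass, tol),
                              key), numeric(1))
      backbone[[length(backbone) + 1L]] <- list(
        X = X, y = inten / sum(inten), w_spectrum = log1p(sum(inten)),
        w_peaks = w_pk, key = key)
    }
    ## peptide+Y unit
    is_Y <- grepl("^Y:", lab)
    if (sum(is_Y) >= 2L) {
      comps <- sub("^Y:", "", lab[is_Y])
      sizes <- vapply(comps, function(cc) {
        if (cc == "0") 0L else parse_composition(cc)$cardinality
      }, integer(1))
      is_core <- rep(TRUE, sum(is_Y))
      ladder <- data.frame(composition = ifelse(comps == "0", "{}", comps),
                           glycan_size = sizes, is_core = is_core,
                           stringsAsFactors = FALSE)
      X <- y_feature_matrix(ladder)
      inten <- pk$intensity[is_Y]
      dir <- ladder_direction(sizes, inten)
      unit <- list(X = X, y = inten / sum(inten),
                   w_spectrum = log1p(sum(inten)),
                   w_peaks = rep(1, sum(is_Y)), key = key)
      if (dir == "ascending") y_asc[[length(y_asc) + 1L]] <- unit
      else y_desc[[length(y_desc) + 1L]] <- unit
    }
  }
  list(backbone = backbone, y_ascending = y_asc, y_descending = y_desc)
}

#' Train the full fragmentation model from annotated spectra
#'
#' Fits the reliability model, then per-partition intensity models for the
#' backbone series and the ascending/descending peptide+Y series (no
#' adjacent-charge borrowing for intensity fits). Partitions too sparse to
#' fit fall through to a global model at prediction time.
#'
#' @param training list of annotated GPSMs (see [fit_reliability()]).
#' @param tol fractional fragment tolerance.
#' @param min_spectra minimum spectra for a per-partition intensity fit.
#' @return a `fragmentation_model`.
#' @export
train_fragmentation_model <- function(training, tol = 20e-6,
                                      min_spectra = 20L) {
  reliability <- fit_reliability(training, tol = tol)
  units <- annotated_to_units(training, reliability, tol)
  fit_group <- function(us) {
    keys <- vapply(us, `[[`, character(1), "key")
    parts <- list()
    for (k in unique(keys)) {
      sub <- us[keys == k]
      if (length(sub) >= min_spectra) parts[[k]] <- fit_intensity(sub)
    }
    list(partitions = parts, global = fit_intensity(us))
  }
  structure(
    list(reliability = reliability,
         backbone = fit_group(units$backbone),
         y_ascending = fit_group(units$y_ascending),
         y_descending = fit_group(units$y_descending),
         tol = tol),
    class = "fragmentation_model")
}

lookup_theta <- function(group, key) {
  fit <- group$partitions[[key]]
  if (is.null(fit) && length(group$partitions)) {
    d <- vapply(names(group$partitions), partition_distance, numeric(1),
                a = key)
    if (any(is.finite(d))) fit <- group$partitions[[names(which.min(d))]]
  }
  if (is.null(fit)) fit <- group$global
  fit$theta
}

#' Predict fragment intensity patterns for a candidate glycopeptide
#'
#' @param model a [train_fragmentation_model()] model.
#' @param sequence peptide string.
#' @param backbone_frags data.frame(series, index) of matched backbone
#'   fragments (NULL to skip).
#' @param y_ladder matched peptide+Y ladder rows (composition, glycan_size,
#'   is_core; NULL to skip).
#' @param y_intensities observed Y intensities (chooses the direction model).
#' @param key partition key string.
#' @return list(backbone, y): probability vectors (each sums to 1).
#' @export
predict_intensity <- function(model, sequence, backbone_frags = NULL,
                              y_ladder = NULL, y_intensities = NULL,
                              key) {
  out <- list(backbone = NULL, y = NULL)
  if (!is.null(backbone_frags) && nrow(backbone_frags) > 0L) {
    X <- backbone_feature_matrix(sequence, backbone_frags)
    out$backbone <- predict_intensity_theta(lookup_theta(model$backbone, key), X)
  }
  if (!is.null(y_ladder) && nrow(y_ladder) > 0L) {
    dir <- if (!is.null(y_intensities))
      ladder_direction(y_ladder$glycan_size, y_intensities) else "descending"
    grp <- if (dir == "ascending") model$y_ascending else model$y_descending
    X <- y_feature_matrix(y_ladder)
    out$y <- predict_intensity_theta(lookup_theta(grp, key), X)
  }
  out
}

#' Serialize a fragmentation model to JSON
#' @param model a `fragmentation_model`. @param path output file.
#' @export
write_fragmentation_model <- function(model, path) {
  ## named numeric vectors must go out as JSON objects, not bare arrays
  rel_part <- function(p) list(prior = p$prior, lr = as.list(p$lr),
                               n_spectra = p$n_spectra)
  rel <- list(partitions = lapply(model$reliability$partitions, rel_part),
              global = rel_part(model$reliability$global))
  jsonlite::write_json(
    list(schema = "glycosearch-frag-model/1", reliability = rel,
         backbone = model$backbone, y_ascending = model$y_ascending,
         y_descending = model$y_descending, tol = model$tol),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fragmentation model from JSON
#' @param path model JSON file.
#' @export
read_fragmentation_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_group <- function(g) {
    g$partitions <- lapply(g$partitions, function(p) {
      p$theta <- as.numeric(p$theta); p
    })
    g$global$theta <- as.numeric(g$global$theta)
    g
  }
  rel <- raw$reliability
  rel$partitions <- lapply(rel$partitions, function(p) {
    p$lr <- unlist(p$lr); p
  })
  rel$global$lr <- unlist(rel$global$lr)
  structure(list(reliability = structure(rel, class = "reliability_model"),
                 backbone = fix_group(raw$backbone),
                 y_ascending = fix_group(raw$y_ascending),
                 y_descending = fix_group(raw$y_descending),
                 tol = raw$tol),
            class = "fragmentation_model")
}
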