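## Target-decoy FDR control: counting q-values with monotonization, a
## Percolator-style semi-supervised linear-margin rescorer for the peptide
## channel, decoy counting (optionally Gamma-tail smoothed) for the glycan
## channel, and the inclusion-exclusion joint FDR.

#' Target-decoy counting q-values
#'
#' At each score threshold, FDR is estimated as (#decoys above + 1) /
#' (#targets above), then monotonized from the bottom of the score range so
#' q-values never increase with score.
#'
#' @param scores numeric scores (higher = better).
#' @param is_decoy logical decoy flags.
#' @return q-values aligned to `scores` (decoys receive q-values too).
#' @export
tdc_qvalues <- function(scores, is_decoy) {
  n <- length(scores)
  if (n == 0L) return(numeric(0))
  ord <- order(scores, decreasing = TRUE)
  dec <- cumsum(is_decoy[ord])
  tar <- cumsum(!is_decoy[ord])
  fdr <- (dec + 1) / pmax(tar, 1)
  q <- rev(cummin(rev(pmin(fdr, 1))))
  out <- numeric(n)
  out[ord] <- q
  out
}

#' Peptide FDR via semi-supervised linear-margin rescoring
#'
#' Percolator-style: the initial direction is the peptide score; for three
#' rounds, targets passing q <= 0.01 are taken as positives against all
#' decoys and a linear max-margin classifier (C = 1) is trained on the
#' feature matrix (peptide score, peptide coverage, and the linear
#' correlation term when a fragmentation model is in play); decision values
#' rescore all PSMs. Falls back to score-only counting with a warning when
#' decoys are too few to train against.
#'
#' @param features data.frame/matrix with at least `score_peptide`,
#'   `coverage_P` and optionally `cor_prime_P` columns.
#' @param is_decoy logical decoy-peptide flags.
#' @param n_iter rescoring rounds.
#' @param seed RNG seed (classifier training is deterministic but the seed
#'   also pins any tie-breaking).
#' @return list(q = q-values, score = final rescored values, used_svm).
#' @export
peptide_fdr <- function(features, is_decoy, n_iter = 3L, seed = 1L) {
  features <- as.data.frame(features)
  base_score <- features$score_peptide
  if (sum(is_decoy) < 20L) {
    warning("fewer than 20 decoys: falling back to score-only counting")
    return(list(q = tdc_qvalues(base_score, is_decoy), score = base_score,
                used_svm = FALSE))
  }
  cols <- intersect(c("score_peptide", "coverage_P", "cor_prime_P"),
                    names(features))
  X <- as.matrix(features[, cols, drop = FALSE])
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  score <- base_score
  used_svm <- FALSE
  for (it in seq_len(n_iter)) {
    q <- tdc_qvalues(score, is_decoy)
    pos <- which(!is_decoy & q <= 0.01)
    if (length(pos) < 5L)  # too few confident positives: take top targets
      pos <- order(ifelse(is_decoy, -Inf, score),
                   decreasing = TRUE)[seq_len(max(5L, sum(!is_decoy) %/% 10L))]
    neg <- which(is_decoy)
    idx <- c(pos, neg)
    y <- factor(c(rep("target", length(pos)), rep("decoy", length(neg))),
                levels = c("decoy", "target"))
    fit <- with_local_seed(seed + it, tryCatch(
      e1071::svm(X[idx, , drop = FALSE], y, kernel = "linear", cost = 1,
                 scale = TRUE),
      error = function(e) NULL))
    if (is.null(fit)) break
    dv <- drop(attr(stats::predict(fit, X, decision.values = TRUE),
                    "decision.values"))
    ## orient: targets should score higher
    if (stats::median(dv[!is_decoy]) < stats::median(dv[is_decoy])) dv <- -dv
    score <- dv
    used_svm <- TRUE
  }
  list(q = tdc_qvalues(score, is_decoy), score = score, used_svm = used_svm)
}

#' Glycan FDR via decoy-glycan counting
#'
#' Counting q-values over the glycan score with decoy-glycan flags.
#' Compositions with three or fewer residues produce too few peptide+Y ions
#' for the estimate to be meaningful: their `glycan_fdr_defined` flag is
#' FALSE and they are excluded from glycan-FDR-thresholded lists. An optional
#' Gamma fit to the decoy score distribution smooths the estimate in the
#' sparse high-score tail.
#'
#' @param score_glycan glycan scores.
#' @param is_decoy_glycan logical decoy-glycan flags.
#' @param cardinality glycan residue counts (|g|).
#' @param gamma_tail fit a Gamma tail model to the decoy scores.
#' @return data.frame(q, glycan_fdr_defined).
#' @export
glycan_fdr <- function(score_glycan, is_decoy_glycan, cardinality,
                       gamma_tail = FALSE) {
  defined <- cardinality > 3L
  q <- rep(NA_real_, length(score_glycan))
  sel <- defined
  if (any(sel)) {
    s <- score_glycan[sel]
    d <- is_decoy_glycan[sel]
    if (!any(d)) {
      warning("too few decoy glycan matches to estimate the glycan FDR ",
              "accurately")
      q[sel] <- pmin(1 / (sum(!d) + 1), 1)
    } else if (gamma_tail && sum(d) >= 20L && all(s[d] > 0)) {
      fitg <- tryCatch(
        suppressWarnings(MASS::fitdistr(s[d], "gamma")),
        error = function(e) NULL)
      qc <- tdc_qvalues(s, d)
      if (!is.null(fitg)) {
        n_d <- sum(d); n_t <- sum(!d)
        surv <- stats::pgamma(s, fitg$estimate["shape"],
                              fitg$estimate["rate"], lower.tail = FALSE)
        exp_dec <- surv * n_d
        tar_above <- vapply(s, function(x) sum(s[!d] >= x), numeric(1))
        q_gamma <- pmin((exp_dec + 1) / pmax(tar_above, 1), 1)
        ## smooth only where counting is sparse (few decoys above)
        dec_above <- vapply(s, function(x) sum(s[d] >= x), numeric(1))
        qc <- ifelse(dec_above < 5, pmin(qc, q_gamma), qc)
        ord <- order(s, decreasing = TRUE)
        qc[ord] <- rev(cummin(rev(qc[ord])))
      }
      q[sel] <- qc
    } else {
      q[sel] <- tdc_qvalues(s, d)
    }
  }
  data.frame(q = q, glycan_fdr_defined = defined)
}

#' Joint peptide+glycan FDR
#'
#' Inclusion-exclusion combination: a glycopeptide is wrong when either
#' moiety is wrong. When the glycan FDR is undefined (tiny composition) the
#' joint FDR falls back to the peptide FDR with the flag propagated.
#'
#' @param fdr_p,fdr_g component FDRs in `[0, 1]` (`fdr_g` may be NA).
#' @param glycan_fdr_defined logical flags.
#' @return joint FDR vector.
#' @export
joint_fdr <- function(fdr_p, fdr_g, glycan_fdr_defined = !is.na(fdr_g)) {
  ifelse(glycan_fdr_defined & !is.na(fdr_g),
         fdr_p + fdr_g - fdr_p * fdr_g,
         fdr_p)
}
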