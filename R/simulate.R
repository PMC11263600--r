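## Seeded synthetic-data generators emulating the structures the engine
## consumes: stepped-collision-energy glycopeptide spectra (b/y + peptide+Y
## ladders + oxonium peaks with multiplicative log-normal noise and random
## noise peaks), LC runs with composition-dependent elution, and planted
## quasi-isobaric misassignments. Truth tables record every peak's origin.

#' A representative N-glycan composition list
#'
#' High-mannose (Hex4-9 HexNAc2), paucimannose, and complex bi/tri-antennary
#' compositions with optional core fucose and sialylation: the composition
#' classes mammalian glycoproteomes are dominated by.
#'
#' @return list of [glycan_composition()] objects.
#' @export
default_glycans <- function() {
  out <- list()
  for (h in 4:9)
    out <- c(out, list(glycan_composition(c(Hex = h, HexNAc = 2))))
  out <- c(out, list(glycan_composition(c(Hex = 3, HexNAc = 2))))
  for (hn in c(4L, 5L)) {
    for (s in 0:2) {
      for (f in 0:1) {
        cnt <- c(Hex = 3L + hn - 2L, HexNAc = hn, NeuAc = s, dHex = f)
        out <- c(out, list(glycan_composition(cnt[cnt > 0])))
      }
    }
  }
  out
}

#' Random plausible N-glycan compositions
#'
#' Draws compositions over the core plus random antenna/fucose/sialic-acid
#' counts, for stress-testing ladder and decoy machinery.
#'
#' @param n number of compositions.
#' @param seed RNG seed.
#' @return list of [glycan_composition()] objects.
#' @export
random_compositions <- function(n, seed) {
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      cnt <- c(HexNAc = 2L + sample(0:4, 1), Hex = 3L + sample(0:6, 1),
               dHex = sample(0:2, 1), NeuAc = sample(0:3, 1))
      glycan_composition(cnt[cnt > 0])
    })
  })
}

#' Simulation configuration
#'
#' @param n_backbones number of peptide backbones.
#' @param glycoforms_per_backbone glycoforms sampled per backbone.
#' @param theta_backbone,theta_y true intensity-model coefficient vectors
#'   (dims matching [backbone_feature_matrix()] / [y_feature_matrix()]).
#' @param rt_coefficients minutes-per-residue elution coefficients.
#' @param rt_adduct_coef minutes per ammonium adduct.
#' @param rt_noise_sd apex RT noise, minutes.
#' @param noise_sd log-normal peak intensity noise (sdlog).
#' @param n_noise_peaks Poisson mean of random noise peaks per spectrum.
#' @param adduct_rate probability an ID carries one ammonium adduct.
#' @param swap_rate fraction of eligible IDs recorded under the
#'   NeuAc+NH3 -> Hex+dHex misassignment.
#' @param run_span LC run length, minutes.
#' @param seed mandatory RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_backbones = 20L, glycoforms_per_backbone = 5L,
                       theta_backbone = NULL, theta_y = NULL,
                       rt_coefficients = c(Hex = 0.5, HexNAc = 0.3,
                                           dHex = -0.3, NeuAc = 2.0,
                                           NeuGc = 2.0, Pent = 0.2),
                       rt_adduct_coef = -0.8, rt_noise_sd = 0.1,
                       noise_sd = 0.3, n_noise_peaks = 30,
                       adduct_rate = 0.3, swap_rate = 0,
                       run_span = 120, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(theta_backbone))
    theta_backbone <- c(0.6, 1.2, -1.0, -0.8, 0.9, 0.7, 0.4, -1.2, 0.5,
                        -0.9, 0.3)
  if (is.null(theta_y))
    theta_y <- c(-2.5, 0.8, 0.6, 0.4, 0.5, 0.3)
  stopifnot(swap_rate >= 0, swap_rate <= 1, adduct_rate >= 0,
            adduct_rate <= 1)
  list(n_backbones = n_backbones,
       glycoforms_per_backbone = glycoforms_per_backbone,
       theta_backbone = theta_backbone, theta_y = theta_y,
       rt_coefficients = rt_coefficients, rt_adduct_coef = rt_adduct_coef,
       rt_noise_sd = rt_noise_sd, noise_sd = noise_sd,
       n_noise_peaks = n_noise_peaks, adduct_rate = adduct_rate,
       swap_rate = swap_rate, run_span = run_span, seed = as.integer(seed))
}

## Random tryptic glycopeptide backbone: a sequon planted away from the
## termini, C-terminal K/R, occasional internal proline and missed-cleavage
## K/R so every cleavage-context feature of the intensity model can occur.
random_glycopeptide_backbone <- function(len = NULL) {
  pool <- c("A", "G", "S", "T", "V", "L", "E", "D", "F", "Y", "Q", "H", "M",
            "W", "I", "P")
  if (is.null(len)) len <- sample(9:16, 1)
  chars <- sample(pool, len - 1L, replace = TRUE)
  pos <- sample(2:(len - 4L), 1)
  chars[pos] <- "N"
  chars[pos + 1L] <- sample(setdiff(pool, "P"), 1)
  chars[pos + 2L] <- sample(c("S", "T"), 1)
  free <- setdiff(seq(2L, len - 2L), c(pos, pos + 1L, pos + 2L))
  if (length(free) && stats::runif(1) < 0.5)  # missed-cleavage site
    chars[sample(free, 1)] <- sample(c("K", "R"), 1)
  if (chars[1] == "P") chars[1] <- "A"
  paste(c(chars, sample(c("K", "R"), 1)), collapse = "")
}

#' Simulate synthetic proteins carrying glycopeptide backbones
#'
#' @param n number of backbones.
#' @param peptides_per_protein backbones concatenated per protein.
#' @param seed RNG seed.
#' @return list(proteins = named vector, backbones = character).
#' @export
simulate_proteins <- function(n, peptides_per_protein = 5L, seed = 1L) {
  with_local_seed(seed, {
    backbones <- unique(replicate(n, random_glycopeptide_backbone()))
    while (length(backbones) < n)
      backbones <- unique(c(backbones, random_glycopeptide_backbone()))
    backbones <- backbones[seq_len(n)]
    groups <- split(backbones,
                    ceiling(seq_along(backbones) / peptides_per_protein))
    proteins <- vapply(groups, paste, character(1), collapse = "")
    names(proteins) <- sprintf("SYNPROT%02d", seq_along(proteins))
    list(proteins = proteins, backbones = backbones)
  })
}

simulate_one_spectrum <- function(scan_id, sequence, glycan, charge, n_nh3,
                                  cfg, rt = NA_real_, total_signal = 1e5) {
  frags <- backbone_fragments(sequence)
  ladder <- generate_y_ladder(glycan)
  pmass <- peptide_mass(sequence)
  Xb <- backbone_feature_matrix(sequence, frags)
  Xy <- y_feature_matrix(ladder)
  p_b <- predict_intensity_theta(cfg$theta_backbone, Xb)
  p_y <- predict_intensity_theta(cfg$theta_y, Xy)
  sial <- count_of(glycan, "NeuAc") > 0L
  w_ox <- if (sial) 0.08 else 0
  int_b <- p_b * total_signal * 0.5 * (1 - w_ox)
  int_y <- p_y * total_signal * 0.5 * (1 - w_ox)
  masses <- c(frags$mass, pmass + ladder$mass_delta)
  intens <- c(int_b, int_y)
  labels <- c(paste0(frags$series, frags$index),
              ifelse(ladder$glycan_size == 0L, "Y:0",
                     paste0("Y:", ladder$composition)))
  if (sial) {
    ox <- oxonium_reference()
    ox <- ox[ox$monosaccharide == "NeuAc", ]
    masses <- c(masses, ox$neutral_mass)
    intens <- c(intens, rep(w_ox * total_signal / 2, nrow(ox)))
    labels <- c(labels, paste0("oxonium:", ox$monosaccharide))
  }
  intens <- intens * exp(stats::rnorm(length(intens), 0, cfg$noise_sd))
  keep <- intens >= 10
  masses <- masses[keep]; intens <- intens[keep]; labels <- labels[keep]
  n_noise <- stats::rpois(1, cfg$n_noise_peaks)
  if (n_noise > 0) {
    nm <- stats::runif(n_noise, 150, pmass + glycan$mass)
    ni <- exp(stats::runif(n_noise, log(10), log(stats::quantile(intens, 0.2))))
    masses <- c(masses, nm); intens <- c(intens, ni)
    labels <- c(labels, rep("", n_noise))
  }
  ## fragment masses observed with ppm-scale error
  obs <- masses * (1 + stats::rnorm(length(masses), 0, 2e-6))
  theo_pre <- pmass + glycan$mass + n_nh3 * NH3_MASS
  sp <- spectrum(scan_id,
                 precursor_mass = theo_pre * (1 + stats::rnorm(1, 0, 0.5e-6)),
                 precursor_charge = charge, rt = rt,
                 peaks = data.frame(neutral_mass = obs, intensity = intens,
                                    charge = 1L, label = labels,
                                    stringsAsFactors = FALSE))
  sp$assignment <- list(peptide = sequence, glycan = format(glycan))
  sp
}

#' Simulate a set of annotated glycopeptide spectra
#'
#' Each glycopeptide emits its b/y series, its peptide+Y ladder with
#' intensities drawn from the configured multinomial models, and diagnostic
#' oxonium ions when sialylated; multiplicative log-normal noise and random
#' noise peaks are layered on top. The truth table records each spectrum's
#' generating glycopeptide; peak labels record each peak's origin.
#'
#' @param cfg a [sim_config()].
#' @param backbones peptide backbone sequences (generated if NULL).
#' @param glycans list of compositions (default [default_glycans()]).
#' @return list(spectra, truth, backbones, glycans).
#' @export
simulate_spectra <- function(cfg, backbones = NULL,
                             glycans = default_glycans()) {
  with_local_seed(cfg$seed, {
    if (is.null(backbones)) {
      backbones <- simulate_proteins(cfg$n_backbones,
                                     seed = cfg$seed + 1L)$backbones
    }
    rows <- list(); spectra <- list()
    scan <- 0L
    for (bb in backbones) {
      gs <- sample(seq_along(glycans),
                   min(cfg$glycoforms_per_backbone, length(glycans)))
      for (gi in gs) {
        scan <- scan + 1L
        g <- glycans[[gi]]
        charge <- sample(2:4, 1)
        n_nh3 <- stats::rbinom(1, 1, cfg$adduct_rate)
        rt <- stats::runif(1, 5, cfg$run_span - 5)
        id <- sprintf("synth.%04d", scan)
        spectra[[scan]] <- simulate_one_spectrum(id, bb, g, charge, n_nh3,
                                                 cfg, rt = rt)
        rows[[scan]] <- data.frame(scan_id = id, peptide = bb,
                                   glycan = format(g), charge = charge,
                                   n_nh3 = n_nh3, rt = rt,
                                   stringsAsFactors = FALSE)
      }
    }
    list(spectra = spectra, truth = do.call(rbind, rows),
         backbones = backbones, glycans = glycans)
  })
}

#' Simulate an LC run of eluted identifications with planted swaps
#'
#' Apex RTs follow a linear composition model (per-monosaccharide and adduct
#' coefficients, optionally drifting linearly over the run) plus Gaussian
#' noise. A configured fraction of sialylated+adducted IDs is recorded under
#' the quasi-isobaric NeuAc+NH3 -> Hex+dHex swap, with truth labels.
#'
#' @param cfg a [sim_config()] (set `swap_rate` to plant misassignments).
#' @param glycans list of compositions.
#' @param drift per-minute linear drift multiplier on the Hex/NeuAc
#'   coefficients (0 = stationary).
#' @return list(ids = [eluted_ids()] table with truth columns
#'   (`true_glycan`, `true_adduct`, `swapped`), glycans).
#' @export
simulate_run <- function(cfg, glycans = default_glycans(), drift = 0) {
  with_local_seed(cfg$seed, {
    backbones <- simulate_proteins(cfg$n_backbones,
                                   seed = cfg$seed + 1L)$backbones
    coef <- cfg$rt_coefficients
    rows <- list()
    for (bb in backbones) {
      base_rt <- stats::runif(1, 10, cfg$run_span - 10)
      gs <- sample(seq_along(glycans),
                   min(cfg$glycoforms_per_backbone, length(glycans)))
      for (gi in gs) {
        g <- glycans[[gi]]
        cnt <- stats::setNames(numeric(length(coef)), names(coef))
        cnt[names(g$counts)] <- g$counts
        n_nh3 <- stats::rbinom(1, 1, cfg$adduct_rate)
        local_coef <- coef * (1 + drift * (base_rt - cfg$run_span / 2))
        apex <- base_rt + sum(local_coef * cnt) +
          cfg$rt_adduct_coef * n_nh3 + stats::rnorm(1, 0, cfg$rt_noise_sd)
        sial <- count_of(g, "NeuAc") > 0L
        rows[[length(rows) + 1L]] <- data.frame(
          backbone = bb, glycan = format(g), adduct_nh3 = n_nh3,
          apex_rt = apex, abundance = stats::rlnorm(1, 10, 1),
          ms2_score = stats::runif(1, 5, 40),
          neuac_oxonium = if (sial) stats::runif(1, 0.05, 0.5) else 0,
          stringsAsFactors = FALSE)
      }
    }
    ids <- do.call(rbind, rows)
    ids$true_glycan <- ids$glycan
    ids$true_adduct <- ids$adduct_nh3
    ids$swapped <- FALSE
    eligible <- which(vapply(ids$glycan, function(s)
      count_of(parse_composition(s), "NeuAc") > 0L, logical(1)) &
      ids$adduct_nh3 >= 1L)
    if (cfg$swap_rate > 0 && length(eligible)) {
      n_swap <- round(cfg$swap_rate * nrow(ids))
      swap <- sample(eligible, min(n_swap, length(eligible)))
      rule <- default_revision_rules()[[1]]  # NeuAc+NH3 -> Hex+dHex
      for (i in swap) {
        cand <- apply_rule(ids[i, , drop = FALSE], rule, NULL)
        if (is.null(cand)) next
        ids$glycan[i] <- cand$glycan
        ids$adduct_nh3[i] <- cand$adduct_nh3
        ids$swapped[i] <- TRUE
        ## the recorded (wrong) composition lost its sialic acid, but the
        ## spectra still show the diagnostic ion of the true glycan
      }
    }
    rownames(ids) <- NULL
    list(ids = ids, glycans = glycans)
  })
}
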