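params <- default_params()

test_that("base peptide score weighs log intensity by accuracy and coverage", {
  g <- gpsm(matched_P = data.frame(intensity = c(1000, 1000), ppm = c(0, 0)),
            matched_G = NULL, coverage_P = 0.5, coverage_G = 0,
            coverage_G_core = 0)
  expect_equal(score_peptide_base(g, params), (3 + 3) * 0.5, tolerance = 1e-9)

  # a peak at exactly the tolerance contributes nothing
  g2 <- gpsm(matched_P = data.frame(intensity = 1000, ppm = params$tol),
             matched_G = NULL, coverage_P = 1, coverage_G = 0,
             coverage_G_core = 0)
  expect_equal(score_peptide_base(g2, params), 0, tolerance = 1e-12)

  g3 <- gpsm(matched_P = NULL, matched_G = NULL, coverage_P = 1,
             coverage_G = 0, coverage_G_core = 0)
  expect_equal(score_peptide_base(g3, params), 0)

  # non-positive intensities are skipped with a warning
  g4 <- gpsm(matched_P = data.frame(intensity = c(100, 0), ppm = c(0, 0)),
             matched_G = NULL, coverage_P = 1, coverage_G = 0,
             coverage_G_core = 0)
  expect_warning(s4 <- score_peptide_base(g4, params), "intensity")
  expect_equal(s4, 2)
})

test_that("base glycan score applies both coverage exponents", {
  g <- gpsm(matched_P = NULL,
            matched_G = data.frame(intensity = rep(100, 5), ppm = rep(0, 5),
                                   glycan_size = 1:5),
            coverage_P = 0, coverage_G = 5 / 7, coverage_G_core = 1)
  expect_equal(score_glycan_base(g, params), 10 * (5 / 7)^0.5,
               tolerance = 1e-6)
  expect_equal(10 * (5 / 7)^0.5, 8.452, tolerance = 1e-3)

  g$coverage_G <- 0
  expect_equal(score_glycan_base(g, params), 0)

  # doubling intensities adds m_g*log10(2) inside the bracket
  g$coverage_G <- 5 / 7
  g2 <- g
  g2$matched_G$intensity <- g2$matched_G$intensity * 2
  expect_equal(score_glycan_base(g2, params) - score_glycan_base(g, params),
               5 * log10(2) * (5 / 7)^0.5, tolerance = 1e-9)
})

test_that("precursor mass-accuracy bias has the stated floor, cap and decay", {
  expect_equal(mass_accuracy_bias(0), 30)
  expect_equal(mass_accuracy_bias(5e-6),
               -10 * log10(1 - exp(-0.5)), tolerance = 1e-9)
  expect_equal(mass_accuracy_bias(5e-6), 4.051, tolerance = 1e-3)
  expect_lt(mass_accuracy_bias(100e-6), 1e-6)
  expect_true(is.finite(mass_accuracy_bias(0)))
})

test_that("signature-ion term penalizes inconsistent sialic acid evidence", {
  mk <- function(neuac, rel) {
    gl <- if (neuac > 0) glycan_composition(c(Hex = 5, HexNAc = 4,
                                              NeuAc = neuac))
      else glycan_composition(c(Hex = 5, HexNAc = 4))
    gpsm(NULL, NULL, 0, 0, 0, glycan = gl,
         oxonium = if (rel > 0) c(NeuAc = rel) else numeric(0))
  }
  expect_equal(signature_ion_term(mk(0, 0.5)), 10 * log10(0.5),
               tolerance = 1e-9)  # -3.0103: unexpected ion observed
  expect_equal(signature_ion_term(mk(1, 0)), 10 * log10(1 - 0.5),
               tolerance = 1e-9)  # expected ion missing
  expect_equal(signature_ion_term(mk(2, 0)), -20, tolerance = 1e-9)
  expect_equal(signature_ion_term(mk(1, 0.3)), 0)
  expect_equal(signature_ion_term(mk(0, 0)), 0)
  # base-peak oxonium stays finite through the 0.999 cap
  expect_true(is.finite(signature_ion_term(mk(0, 1.0))))
})

test_that("total score is the stated linear mixture plus separable biases", {
  set.seed(42)
  g <- random_gpsm()
  g$oxonium <- numeric(0)
  g$glycan <- glycan_composition(c(Hex = 5, HexNAc = 4))
  p1 <- params; p1$w <- 1
  expect_equal(score_total_base(g, p1),
               score_peptide_base(g, p1) + signature_ion_term(g) +
                 mass_accuracy_bias(g$ppm_pre), tolerance = 1e-9)
  # w = 0.65, components 10 and 8, biases zeroed
  expect_equal(0.65 * 10 + 0.35 * 8, 9.3)
  # shifting ppm_pre changes the total by the bias delta only
  g2 <- g
  g2$ppm_pre <- 20e-6
  expect_equal(score_total_base(g, params) - score_total_base(g2, params),
               mass_accuracy_bias(g$ppm_pre) - mass_accuracy_bias(20e-6),
               tolerance = 1e-9)
})

test_that("correlation terms follow the shifted-Pearson closed forms", {
  g <- gpsm(matched_P = data.frame(intensity = (1:10)^2, ppm = rep(0, 10)),
            matched_G = NULL, coverage_P = 0.8, coverage_G = 0,
            coverage_G_core = 0)
  # perfectly correlated prediction: rho = 1
  ct <- cor_terms(g, predicted_P = (1:10)^2)
  expect_equal(ct$Cor_P, 2 * log10(10), tolerance = 1e-9)
  expect_equal(ct$CorPrime_P, 2 * 10 * 0.8, tolerance = 1e-9)
  # anti-correlated: both shifted terms hit zero
  ct2 <- cor_terms(g, predicted_P = -(1:10)^2)
  expect_equal(ct2$Cor_P, 0, tolerance = 1e-9)

  gg <- gpsm(matched_P = NULL,
             matched_G = data.frame(intensity = c(4, 3, 2, 1),
                                    ppm = rep(0, 4), phi = c(1, 1, 1, 1),
                                    glycan_size = 1:4),
             coverage_P = 0, coverage_G = 0.5, coverage_G_core = 0.5)
  # rho floor at 0.25 inside Rel_G: pad(1) = 1 per fragment
  pred <- c(1, 2, 4, 3)  # weakly anti-correlated with observed
  rho <- cor(c(4, 3, 2, 1), pred)
  ct3 <- cor_terms(gg, predicted_G = pred)
  expect_equal(ct3$Rel_G, 4 * max(rho, 0.25), tolerance = 1e-9)
  expect_equal(ct3$Cor_G, (rho + 1) / 2, tolerance = 1e-9)

  # phi = (1, 1) with only 2 fragments: rho degenerates to 0, floor applies
  gg2 <- gpsm(matched_P = NULL,
              matched_G = data.frame(intensity = c(4, 3), ppm = c(0, 0),
                                     phi = c(1, 1), glycan_size = 1:2),
              coverage_P = 0, coverage_G = 0.5, coverage_G_core = 0.5)
  expect_equal(cor_terms(gg2, predicted_G = c(1, 2))$Rel_G, 2 * 0.25)

  expect_equal(cor_terms(gpsm(NULL, NULL, 0, 0, 0)),
               list(Cor_P = 0, CorPrime_P = 0, Cor_G = 0, Rel_G = 0))
})

test_that("model peptide score rewards reliability as stated", {
  g <- gpsm(matched_P = data.frame(intensity = 1000, ppm = 0, phi = 1),
            matched_G = NULL, coverage_P = 1, coverage_G = 0,
            coverage_G_core = 0)
  expect_equal(score_peptide_model(g, params), 3 * 2 + 1, tolerance = 1e-9)

  # increasing phi never decreases the score
  set.seed(7)
  g2 <- random_gpsm()
  s_lo <- score_peptide_model(g2, params)
  g2$matched_P$phi <- pmin(g2$matched_P$phi + 0.3, 1)
  expect_gte(score_peptide_model(g2, params), s_lo)
})

test_that("glycan model terms gate on peptide coverage and fragment count", {
  expect_equal(coverage_gate(1 / 3), 1, tolerance = 1e-12)
  expect_equal(coverage_gate(0), exp(-1), tolerance = 1e-9)
  expect_equal(coverage_gate(1), 1)

  g <- gpsm(matched_P = NULL,
            matched_G = data.frame(intensity = rep(100, 4), ppm = rep(0, 4),
                                   phi = rep(0.5, 4),
                                   glycan_size = c(0L, 1L, 2L, 5L)),
            coverage_P = 0.5, coverage_G = 0.5, coverage_G_core = 0.5)
  expect_equal(sigfrag(g), 2L)

  # sigfrag = 0 reduces the model glycan score to the base form
  g0 <- g
  g0$matched_G$glycan_size <- c(0L, 1L, 0L, 1L)
  cors <- cor_terms(g0, predicted_G = c(1, 2, 3, 4))
  expect_equal(score_glycan_model(g0, params, cors),
               score_glycan_base(g0, params), tolerance = 1e-9)
})

test_that("score reductions hold algebraically on randomized matches", {
  set.seed(123)
  for (i in 1:25) {
    g <- random_gpsm(m_p = sample(2:8, 1), m_g = sample(2:6, 1))
    # phi = 0 and zero correlation terms reduce the model score to the base
    g0 <- g
    g0$matched_P$phi <- 0
    zero_cors <- list(Cor_P = 0, CorPrime_P = 0, Cor_G = 0, Rel_G = 0)
    expect_equal(score_peptide_model(g0, params, zero_cors),
                 score_peptide_base(g0, params), tolerance = 1e-9)
    # u_g = 0 leaves both glycan scores untouched
    cors <- cor_terms(g, predicted_G = runif(nrow(g$matched_G)))
    expect_equal(score_glycan_base(g, params, u_g = 0),
                 score_glycan_base(g, params), tolerance = 1e-12)
    expect_equal(score_glycan_model(g, params, cors, u_g = 0),
                 score_glycan_model(g, params, cors), tolerance = 1e-12)
    # mixture endpoints
    pw <- params; pw$w <- 1
    expect_equal(score_total_model(g, pw, cors),
                 score_peptide_model(g, pw, cors) + signature_ion_term(g) +
                   mass_accuracy_bias(g$ppm_pre), tolerance = 1e-9)
    pw$w <- 0
    expect_equal(score_total_model(g, pw, cors),
                 score_glycan_model(g, pw, cors) + signature_ion_term(g) +
                   mass_accuracy_bias(g$ppm_pre), tolerance = 1e-9)
    # all scores finite
    expect_true(is.finite(score_total_base(g, params)))
    expect_true(is.finite(score_total_model(g, params, cors)))
  }
})

test_that("smoothing credit enters inside the coverage-gated bracket", {
  g <- gpsm(matched_P = NULL,
            matched_G = data.frame(intensity = rep(100, 5), ppm = rep(0, 5),
                                   glycan_size = 1:5),
            coverage_P = 0, coverage_G = 5 / 7, coverage_G_core = 1)
  inner_factor <- (5 / 7)^params$alpha * 1^params$beta
  expect_equal(score_glycan_base(g, params, u_g = 2) -
                 score_glycan_base(g, params),
               2 * inner_factor, tolerance = 1e-9)
  # worked numbers: inner 10, u 2, coverage factor 0.8 gives 9.6 vs 8.0
  expect_equal((10 + 2) * 0.8, 9.6)
  expect_equal(10 * 0.8, 8.0)
  # zero coverage gates the credit off entirely
  g$coverage_G <- 0
  expect_equal(score_glycan_base(g, params, u_g = 50), 0)
})

test_that("oxonium references match the protonated literature values", {
  ref <- oxonium_reference()
  proton <- 1.00727646677
  mz <- sort(ref$neutral_mass[ref$monosaccharide == "NeuAc"] + proton)
  expect_equal(mz, c(274.0921, 292.1027), tolerance = 1e-4)
  mzg <- sort(ref$neutral_mass[ref$monosaccharide == "NeuGc"] + proton)
  expect_equal(mzg, c(290.0870, 308.0976), tolerance = 1e-4)
})
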