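# Shared fixtures: random GPSMs for algebraic scoring identities, and a
# compact simulate-train wrapper used by several suites.

random_gpsm <- function(m_p = 5L, m_g = 4L, glycan = NULL, tol = 20e-6) {
  if (is.null(glycan))
    glycan <- glycan_composition(c(Hex = 5, HexNAc = 4, NeuAc = 1))
  gpsm(
    matched_P = data.frame(intensity = exp(runif(m_p, log(50), log(5000))),
                           ppm = runif(m_p, -tol / 2, tol / 2),
                           phi = runif(m_p)),
    matched_G = data.frame(intensity = exp(runif(m_g, log(50), log(5000))),
                           ppm = runif(m_g, -tol / 2, tol / 2),
                           phi = runif(m_g),
                           glycan_size = sample(0:8, m_g, replace = TRUE)),
    coverage_P = runif(1, 0.2, 1), coverage_G = runif(1, 0.1, 1),
    coverage_G_core = runif(1, 0.1, 1),
    ppm_pre = runif(1, -4e-6, 4e-6), glycan = glycan,
    oxonium = c(NeuAc = runif(1, 0.05, 0.6)))
}

sim_training_set <- function(n_backbones, seed, glycoforms = 4L, ...) {
  cfg <- sim_config(n_backbones = n_backbones,
                    glycoforms_per_backbone = glycoforms, seed = seed, ...)
  sim <- simulate_spectra(cfg)
  list(cfg = cfg, sim = sim, training = annotated_training_set(sim$spectra))
}
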