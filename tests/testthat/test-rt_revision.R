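test_that("the default revision rule family is mass-closed", {
  rules <- default_revision_rules()
  expect_length(rules, 2L)
  expect_lt(abs(abs(rules[[1]]$net_mass) - 0.0112), 1e-4)
  expect_equal(rules[[1]]$net_mass, -rules[[2]]$net_mass)
  # 5 ppm closure holds at the reference mass
  expect_lte(abs(rules[[1]]$net_mass), 5e-6 * 2250)
  expect_error(default_revision_rules(precursor_tol = 1e-6),
               "not mass-closed")
})

test_that("rt model recovers the generating elution coefficients", {
  cfg <- sim_config(n_backbones = 40L, glycoforms_per_backbone = 6L,
                    rt_noise_sd = 0.1, seed = 5L)
  run <- simulate_run(cfg)
  model <- fit_rt_model(run$ids)
  expect_equal(model$coverage, 1)
  cf <- glycosearch:::blend_coefs(model, 60)
  truth <- c(cfg$rt_coefficients, NH3 = cfg$rt_adduct_coef)
  for (m in c("Hex", "HexNAc", "dHex", "NeuAc", "NH3"))
    expect_equal(unname(cf[m]), unname(truth[m]), tolerance = 0.1,
                 label = paste("coefficient", m))
})

test_that("single-glycoform backbones yield no model", {
  ids <- eluted_ids(backbone = c("A", "B"),
                    glycan = c("{Hex:5; HexNAc:2}", "{Hex:6; HexNAc:2}"),
                    apex_rt = c(10, 20))
  expect_null(fit_rt_model(ids))
})

test_that("per-bin coefficients track a drifting generator", {
  cfg <- sim_config(n_backbones = 60L, glycoforms_per_backbone = 6L,
                    rt_noise_sd = 0.05, seed = 15L)
  run <- simulate_run(cfg, drift = 0.004)
  model <- fit_rt_model(run$ids)
  hex_early <- glycosearch:::blend_coefs(model, 25)["Hex"]
  hex_late <- glycosearch:::blend_coefs(model, 95)["Hex"]
  # drift multiplies coefficients by (1 + 0.004*(t - 60)): late > early
  expect_gt(unname(hex_late - hex_early), 0.05)
})

test_that("rt predictions and scores follow the stated closed forms", {
  cfg <- sim_config(n_backbones = 20L, glycoforms_per_backbone = 5L,
                    rt_noise_sd = 0.05, seed = 25L)
  run <- simulate_run(cfg)
  model <- fit_rt_model(run$ids)
  id <- run$ids[1, , drop = FALSE]
  # removing the composition delta leaves exactly the reference RT
  ref <- model$refs[[id$backbone]]
  expect_equal(predict_rt(model, id) -
                 drop(glycosearch:::blend_coefs(model, ref$rt) %*%
                        c(glycosearch:::id_count_matrix(id$glycan)[1, ] -
                            ref$comp, NH3 = id$adduct_nh3 - ref$adduct)),
               ref$rt, tolerance = 1e-9)

  # +1 NeuAc moves the prediction by the NeuAc coefficient
  id2 <- id
  g2 <- parse_composition(id$glycan)
  id2$glycan <- format(glycan_composition(c(g2$counts, NeuAc = 1)))
  cf <- glycosearch:::blend_coefs(model, ref$rt)
  expect_equal(predict_rt(model, id2) - predict_rt(model, id),
               unname(cf["NeuAc"]), tolerance = 1e-9)

  # uncovered backbone signals NA
  id3 <- id
  id3$backbone <- "NOTAPEPTIDE"
  expect_true(is.na(predict_rt(model, id3)))
  expect_true(is.na(rt_score(model, id3)))

  # score closed form: 1 at zero residual, 0.75 at span/8, 0 beyond span/2
  span <- model$run_span[2] - model$run_span[1]
  mk <- function(resid) {
    x <- id
    x$apex_rt <- predict_rt(model, id) + resid
    rt_score(model, x)
  }
  expect_equal(mk(0), 1, tolerance = 1e-9)
  expect_equal(mk(span / 8), 0.75, tolerance = 1e-9)
  expect_equal(mk(span / 2), 0, tolerance = 1e-9)
  expect_equal(mk(span), 0)
  # strictly decreasing in |residual| inside the support
  expect_true(all(diff(vapply(c(0, 1, 2, 5, 10),
                              mk, numeric(1))) < 0))
})

test_that("revision corrects planted quasi-isobaric swaps without touching clean ids", {
  cfg <- sim_config(n_backbones = 60L, glycoforms_per_backbone = 6L,
                    swap_rate = 0.1, adduct_rate = 0.4, seed = 3L)
  run <- simulate_run(cfg)
  model <- fit_rt_model(run$ids)
  space <- vapply(run$glycans, format, character(1))
  rev <- revise(model, run$ids, glycan_space = space)
  changed <- !is.na(rev$revised_from)
  corrected <- changed & run$ids$swapped &
    rev$glycan == run$ids$true_glycan &
    rev$adduct_nh3 == run$ids$true_adduct
  expect_gte(sum(corrected) / sum(run$ids$swapped), 0.6)
  expect_lte(sum(changed & !run$ids$swapped) / sum(!run$ids$swapped), 0.02)

  # idempotence: a second pass changes nothing
  rev2 <- revise(model, rev, glycan_space = space)
  expect_identical(rev2$glycan, rev$glycan)
  expect_identical(rev2$adduct_nh3, rev$adduct_nh3)

  # swap rate 0 leaves everything untouched
  cfg0 <- sim_config(n_backbones = 30L, glycoforms_per_backbone = 5L,
                     swap_rate = 0, adduct_rate = 0.4, seed = 7L)
  run0 <- simulate_run(cfg0)
  rev0 <- revise(fit_rt_model(run0$ids), run0$ids,
                 glycan_space = vapply(run0$glycans, format, character(1)))
  expect_lte(mean(!is.na(rev0$revised_from)), 0.02)
})

test_that("diagnostic-ion evidence vetoes contradictory revisions", {
  cfg <- sim_config(n_backbones = 40L, glycoforms_per_backbone = 6L,
                    swap_rate = 0.15, adduct_rate = 0.5, seed = 13L)
  run <- simulate_run(cfg)
  model <- fit_rt_model(run$ids)
  space <- vapply(run$glycans, format, character(1))
  ids_no_ox <- run$ids
  ids_no_ox$neuac_oxonium <- 0  # no sialic-acid evidence anywhere
  rev <- revise(model, ids_no_ox, glycan_space = space)
  # swaps whose recorded composition lost its only NeuAc can only be fixed
  # by adding the first NeuAc back: without the diagnostic ion, all vetoed
  first_neuac <- ids_no_ox$swapped & vapply(ids_no_ox$glycan, function(s)
    glycosearch:::count_of(parse_composition(s), "NeuAc") == 0L, logical(1))
  changed_comp <- rev$glycan != ids_no_ox$glycan
  expect_equal(sum(changed_comp & first_neuac), 0)
  # with the diagnostic ion present, some of the same swaps are corrected
  rev_ox <- revise(model, run$ids, glycan_space = space)
  expect_gt(sum(rev_ox$glycan != run$ids$glycan & first_neuac), 0)
})

test_that("parsimony reassigns stranded adducted identifications only", {
  space <- c("{Hex:5; HexNAc:4; NeuAc:1}", "{Hex:6; HexNAc:4; dHex:1}")
  ids <- eluted_ids(
    backbone = c("PEPA", "PEPA", "PEPB"),
    glycan = c("{Hex:5; HexNAc:4; NeuAc:1}", "{Hex:5; HexNAc:4; NeuAc:1}",
               "{Hex:5; HexNAc:4; NeuAc:1}"),
    adduct_nh3 = c(1L, 0L, 1L),
    apex_rt = c(50, 50.2, 80))
  out <- parsimony_reassign(ids, glycan_space = space)
  # PEPA's shifted id co-elutes with an unshifted twin: untouched
  expect_false(out$reassigned[1])
  expect_equal(out$glycan[1], ids$glycan[1])
  # PEPB's shifted id is stranded: mapped to the unshifted alternative
  expect_true(out$reassigned[3])
  expect_equal(out$adduct_nh3[3], 0L)
  expect_equal(out$glycan[3], "{Hex:6; HexNAc:4; dHex:1}")
  # unshifted ids are never touched
  expect_false(out$reassigned[2])
})
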