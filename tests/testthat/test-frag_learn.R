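test_that("partition keys bin the four fragmentation axes into a 150 grid", {
  k <- partition_key(12, 10, 3, "mobile", "N")
  expect_equal(k$len_bin, 2L)
  expect_equal(k$size_bin, 2L)
  expect_equal(k$charge_bin, 3L)
  expect_equal(partition_grid_size(), 150L)
  expect_equal(partition_key(30, 5, 7, "partial")$charge_bin, 5L)
  expect_equal(partition_key(10, 9, 1, "immobile")$len_bin, 1L)
  expect_equal(partition_key(28, 9, 1, "immobile")$len_bin, 5L)
  # distance is Manhattan over bins with mobility steps
  expect_equal(glycosearch:::partition_distance("N|L2|G1|Z2|mobile",
                                                "N|L3|G2|Z2|immobile"), 4)
  expect_equal(glycosearch:::partition_distance("N|L1|G1|Z1|mobile",
                                                "O|L1|G1|Z1|mobile"), Inf)
})

test_that("pair features fire on residue-mass offsets within tolerance", {
  mk_sp <- function(masses) spectrum("t", 3000, 2, 1,
                                     data.frame(neutral_mass = masses,
                                                intensity = rep(100,
                                                                length(masses))))
  hn <- residue_mass("HexNAc")
  sp <- mk_sp(c(1000, 1000 + hn))
  expect_true("Y.hexnac" %in% extract_pair_features(sp, 1, "Y"))
  expect_true("Y.hexnac" %in% extract_pair_features(sp, 2, "Y"))
  expect_true("b.hexnac" %in% extract_pair_features(sp, 1, "backbone"))

  # singleton spectrum fires nothing
  expect_length(extract_pair_features(mk_sp(1500), 1), 0L)

  # partner displaced 3 match-windows from the offset is not a partner
  # (the window is tol x the partner mass, ~0.024 Da here)
  off <- hn + 3 * 20e-6 * (1000 + hn)
  expect_false("Y.hexnac" %in%
                 extract_pair_features(mk_sp(c(1000, 1000 + off)), 1, "Y"))

  # complement to the peptide mass
  sp2 <- mk_sp(c(400, 1600))
  expect_true("complement" %in%
                extract_pair_features(sp2, 1, "backbone", peptide_mass = 2000))
  expect_false("complement" %in%
                 extract_pair_features(sp2, 1, "backbone", peptide_mass = 2500))
})

test_that("reliability posteriors follow the naive-Bayes closed form", {
  model <- structure(list(
    partitions = list(), global = list(prior = 0.5,
                                       lr = c(f1 = 5, f2 = 0.2))),
    class = "reliability_model")
  expect_equal(predict_reliability(model, "f1"), 5 / 6, tolerance = 1e-9)
  expect_equal(predict_reliability(model, character(0)), 0.5)
  expect_equal(predict_reliability(model, c("f1", "f2")), 0.5,
               tolerance = 1e-9)  # LRs cancel
  # unknown features are ignored
  expect_equal(predict_reliability(model, "f9"), 0.5)
})

test_that("fitted reliability separates true fragment peaks from noise", {
  tr <- sim_training_set(25L, seed = 31L)
  model <- fit_reliability(tr$training)
  # a feature that marks annotated peaks gets LR > 1
  expect_true(any(model$global$lr[grep("hexnac|aa:", names(model$global$lr))] > 1))

  # AUROC of phi against annotation truth on held-out spectra
  te <- sim_training_set(10L, seed = 77L)
  phis <- c(); truth <- c()
  for (asp in te$training[1:20]) {
    tab <- glycosearch:::training_peak_table(asp, 20e-6)
    key <- partition_key(nchar(asp$peptide), approx_size(asp$glycan),
                         asp$charge,
                         proton_mobility(asp$peptide, asp$charge))$key
    phis <- c(phis, vapply(tab$features, function(f)
      predict_reliability(model, f, key), numeric(1)))
    truth <- c(truth, tab$annotated)
  }
  pos <- phis[truth]; neg <- phis[!truth]
  auroc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_gt(auroc, 0.8)
})

test_that("ladder direction is the sign of the size-intensity rank correlation", {
  expect_equal(ladder_direction(1:5, c(10, 20, 30, 40, 50)), "ascending")
  expect_equal(ladder_direction(1:5, c(50, 40, 30, 20, 10)), "descending")
  expect_equal(ladder_direction(1:5, rep(10, 5)), "descending")
  expect_equal(ladder_direction(3L, 10), "descending")
  expect_equal(ladder_direction(c(2L, 5L), c(1, 9)), "ascending")
})

test_that("intensity model is a proper multinomial and recovers parameters", {
  set.seed(21)
  theta <- c(0.6, 1.2, -1.0, -0.8, 0.9, 0.7, 0.4, -1.2, 0.5, -0.9, 0.3)
  units <- lapply(1:120, function(i) {
    bb <- glycosearch:::random_glycopeptide_backbone()
    X <- backbone_feature_matrix(bb, backbone_fragments(bb))
    y <- predict_intensity_theta(theta, X)
    y <- y * exp(rnorm(length(y), 0, 0.2))
    list(X = X, y = y / sum(y), w_spectrum = 1, w_peaks = rep(1, nrow(X)))
  })
  fit <- fit_intensity(units)
  expect_true(fit$converged)
  expect_gt(cor(fit$theta, theta), 0.95)
  # objective is non-decreasing across iterations
  expect_true(all(diff(fit$ll_trace) >= -1e-8))
  # predictions sum to one over each fragment set
  p <- predict_intensity_theta(fit$theta, units[[1]]$X)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # identical-feature fragments share probability; theta = 0 is uniform
  Xeq <- rbind(units[[1]]$X[1, ], units[[1]]$X[1, ])
  peq <- predict_intensity_theta(fit$theta, Xeq)
  expect_equal(peq[1], peq[2])
  expect_equal(predict_intensity_theta(numeric(11), Xeq), c(0.5, 0.5))
})

test_that("degenerate training falls back to a uniform model", {
  # single-fragment spectra carry no contrast
  units <- lapply(1:5, function(i)
    list(X = matrix(1, 1, 3), y = 1, w_spectrum = 1, w_peaks = 1))
  fit <- fit_intensity(units)
  expect_true(fit$uniform_fallback)
  expect_equal(predict_intensity_theta(fit$theta, matrix(rnorm(6), 2, 3)),
               c(0.5, 0.5))
  expect_false(fit_intensity(list())$converged)
})

test_that("trained model resolves every partition key to predictions", {
  tr <- sim_training_set(20L, seed = 41L)
  fm <- train_fragmentation_model(tr$training, min_spectra = 10L)
  bb <- "ANDSTLLKGGK"
  frags <- backbone_fragments(bb)[1:6, ]
  lad <- generate_y_ladder(parse_composition("{Hex:5; HexNAc:2}"))
  # a key no partition was fitted for still predicts via nearest/global
  pred <- predict_intensity(fm, bb, backbone_frags = frags,
                            y_ladder = lad, y_intensities = rev(seq_len(nrow(lad))),
                            key = "N|L5|G2|Z5|immobile")
  expect_equal(sum(pred$backbone), 1, tolerance = 1e-9)
  expect_equal(sum(pred$y), 1, tolerance = 1e-9)
})

test_that("fragmentation models survive a JSON round trip", {
  tr <- sim_training_set(12L, seed = 51L)
  fm <- train_fragmentation_model(tr$training, min_spectra = 6L)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_fragmentation_model(fm, tmp)
  back <- read_fragmentation_model(tmp)
  expect_equal(back$backbone$global$theta, fm$backbone$global$theta,
               tolerance = 1e-9)
  expect_equal(back$reliability$global$prior, fm$reliability$global$prior,
               tolerance = 1e-9)
  expect_equal(sort(names(back$reliability$global$lr)),
               sort(names(fm$reliability$global$lr)))
})
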