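test_that("residue masses derive from elemental compositions", {
  expect_equal(residue_mass("HexNAc"), 203.0794, tolerance = 1e-4)
  expect_equal(residue_mass("Hex"), 162.0528, tolerance = 1e-4)
  expect_equal(residue_mass("dHex"), 146.0579, tolerance = 1e-4)
  # independent oracle: sum the element masses by hand for Hex (C6H10O5)
  expect_equal(residue_mass("Hex"),
               6 * 12 + 10 * 1.0078250319 + 5 * 15.9949146221,
               tolerance = 1e-9)
  expect_error(residue_mass("Xyl2"), "unknown monosaccharide")
})

test_that("composition parsing handles both dialects and rejects bad input", {
  g <- parse_composition("{Hex:5; HexNAc:2}")
  expect_equal(unname(g$counts[c("Hex", "HexNAc")]), c(5L, 2L))
  expect_equal(g$cardinality, 7L)
  expect_equal(parse_composition("{HexNAc:1}")$mass, 203.0794,
               tolerance = 1e-4)
  expect_equal(parse_composition("{Hex:1; dHex:1}")$mass,
               residue_mass("Hex") + residue_mass("dHex"), tolerance = 1e-9)
  expect_equal(parse_composition("{Hex:1; dHex:1}")$mass, 308.1107,
               tolerance = 1e-4)
  # concatenated dialect agrees with canonical
  expect_equal(parse_composition("HexNAc(2)Hex(5)")$mass,
               parse_composition("{Hex:5; HexNAc:2}")$mass)
  expect_error(parse_composition("{Foo:1}"), "Foo")
  expect_error(parse_composition("{Hex:-2}"), "negative")
})

test_that("approximate glycan size discounts labile and second fucose", {
  sz <- function(txt) approx_size(parse_composition(txt))
  expect_equal(sz("{Hex:5; HexNAc:2}"), 7L)
  expect_equal(sz("{Hex:5; HexNAc:4; dHex:1; NeuAc:2}"), 10L)
  expect_equal(sz("{HexNAc:2; Hex:3; dHex:2; NeuAc:1}"), 6L)
  expect_equal(approx_size(glycan_composition(c(NeuAc = 2))), 0L)
})

test_that("coverage normalizer follows the fucosylation-split log rule", {
  expect_equal(coverage_normalizer(7, 0), 7)
  expect_equal(coverage_normalizer(10, 2), 10 * log(10), tolerance = 1e-4)
  expect_equal(coverage_normalizer(8, 0), max(4 * log(8), 8),
               tolerance = 1e-4)
  # d_g >= n_g and monotone in n_g on both branches
  for (dhex in c(0, 1)) {
    d <- vapply(1:25, coverage_normalizer, numeric(1), dhex = dhex)
    expect_true(all(d >= pmax(1:25, 1)))
    expect_true(all(diff(d) >= 0))
  }
  # degenerate tiny compositions stay defined
  expect_equal(coverage_normalizer(0, 0), 1)
  expect_equal(coverage_normalizer(1, 0), 1)
})

test_that("peptide+Y ladders enumerate core subtrees plus residue combinations", {
  lad <- generate_y_ladder(parse_composition("{Hex:3; HexNAc:2}"))
  expect_equal(nrow(lad), 6L)
  expect_equal(lad$mass_delta[1], 0)                      # Y0 present
  expect_equal(lad$glycan_size[1], 0L)
  expect_true(all(lad$is_core))
  # oracle: expected masses from the core tree by direct summation
  hn <- residue_mass("HexNAc"); hx <- residue_mass("Hex")
  expect_equal(sort(lad$mass_delta),
               sort(c(0, hn, 2 * hn, 2 * hn + hx, 2 * hn + 2 * hx,
                      2 * hn + 3 * hx)), tolerance = 1e-9)

  # fucosylated: every non-Y0 core mass reappears +dHex
  lad_f <- generate_y_ladder(parse_composition("{Hex:3; HexNAc:2; dHex:1}"))
  base <- lad$mass_delta[lad$mass_delta > 0]
  for (m in base)
    expect_true(any(abs(lad_f$mass_delta - (m + residue_mass("dHex"))) < 1e-6))

  # sialic acids are labile: never appended to any fragment
  lad_s <- generate_y_ladder(parse_composition("{NeuAc:2; Hex:5; HexNAc:4}"))
  expect_false(any(grepl("Neu", lad_s$composition)))

  # ladder determinism
  expect_identical(generate_y_ladder(parse_composition("{Hex:5; HexNAc:4}")),
                   generate_y_ladder(parse_composition("{Hex:5; HexNAc:4}")))

  # composition without the core falls back to combination-only mode
  lad_o <- generate_y_ladder(glycan_composition(c(HexNAc = 2, Hex = 1),
                                                glycan_type = "O"))
  expect_equal(nrow(lad_o), 6L)  # (2+1)*(1+1) combinations incl. Y0
  expect_equal(sum(lad_o$is_core), 1L)
})

test_that("decoy ladders shift only fragments beyond Y1, reproducibly", {
  g <- parse_composition("{Hex:5; HexNAc:4; dHex:1}")
  d1 <- make_decoy_ladder(g, seed = 99L)
  d2 <- make_decoy_ladder(g, seed = 99L)
  expect_identical(d1$mass_delta, d2$mass_delta)
  expect_true(all(d1$shift[d1$glycan_size <= 1L] == 0))
  expect_true(all(d1$shift[d1$glycan_size >= 2L] >= 1.0))
  expect_true(all(d1$shift[d1$glycan_size >= 2L] <= 30.0))
  d3 <- make_decoy_ladder(g, seed = 100L)
  expect_false(identical(d1$shift, d3$shift))

  # uniform moments over many draws
  shifts <- unlist(lapply(1:400, function(s) {
    d <- make_decoy_ladder(g, seed = s)
    d$shift[d$glycan_size >= 2L]
  }))
  expect_gte(length(shifts), 10000)
  expect_gte(min(shifts), 1.0)
  expect_lte(max(shifts), 30.0)
  expect_equal(mean(shifts), 15.5, tolerance = 0.2 / 15.5)
})

test_that("glycan coverage divides distinct matches by the normalizer", {
  g <- parse_composition("{Hex:5; HexNAc:2}")
  lad <- generate_y_ladder(g)
  cov <- glycan_coverage(lad$mass_delta[1:5], g, ladder = lad)
  expect_equal(cov$coverage_G, 5 / 7, tolerance = 1e-9)
  expect_equal(glycan_coverage(numeric(0), g, ladder = lad),
               list(coverage_G = 0, coverage_G_core = 0))
  cov_all <- glycan_coverage(lad$mass_delta[lad$is_core], g, ladder = lad)
  expect_equal(cov_all$coverage_G_core, 1)

  # monotone: adding a matched fragment never decreases either coverage
  prev <- c(0, 0)
  for (k in seq_len(nrow(lad))) {
    cc <- glycan_coverage(lad$mass_delta[seq_len(k)], g, ladder = lad)
    expect_gte(cc$coverage_G, prev[1])
    expect_gte(cc$coverage_G_core, prev[2])
    prev <- c(cc$coverage_G, cc$coverage_G_core)
  }
  expect_lte(cov_all$coverage_G, 1)
})
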