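test_that("replicate averaging applies the repeat-QC rule", {
  expect_equal(average_replicates(c(28.0, 28.0)),
               list(cp_mean = 28.0, qc_repeat_flag = FALSE))
  r <- average_replicates(c(28.0, 28.6), max_dev = 0.5)
  expect_equal(r$cp_mean, 28.3)
  expect_true(r$qc_repeat_flag)                  # spread 0.6 > 0.5
  expect_equal(average_replicates(c(30.1, 29.9, 30.0)),
               list(cp_mean = 30.0, qc_repeat_flag = FALSE))
  expect_error(average_replicates(numeric(0)), "at least one")
  expect_error(average_replicates(c(NA_real_)), "at least one")
})

test_that("detection-limit call is inclusive at the limit", {
  expect_true(call_negative(35.0))
  expect_false(call_negative(34.99))
  expect_true(call_negative(41.2))
  expect_false(call_negative(34.99, detection_limit = 34.99 + 1e-9))
})

test_that("reference geometric mean matches the closed form and AM-GM", {
  expect_equal(reference_geomean(c(24, 24, 24)), 24)
  expect_equal(reference_geomean(c(24, 25, 26)), 15600^(1 / 3),
               tolerance = 1e-12)
  expect_equal(round_half_up(reference_geomean(c(24, 25, 26)), 4), 24.9867)
  set.seed(41)
  for (i in 1:25) {
    cps <- runif(3, 18, 34)
    g <- reference_geomean(cps)
    expect_equal(g, reference_geomean(rev(cps)))       # permutation-invariant
    expect_lte(g, mean(cps))                           # AM-GM
  }
  expect_error(reference_geomean(c(24, 25)), "three")
})

test_that("relative expression is exact base-2 and halves per cycle", {
  expect_equal(relative_expression(24, 24), 1.0)
  expect_equal(relative_expression(25, 24), 0.5)
  expect_equal(relative_expression(28.0, 24.9866), 2^-3.0134,
               tolerance = 1e-12)
  expect_equal(round_half_up(relative_expression(28.0, 24.9866), 4), 0.1238)
  set.seed(7)
  for (i in 1:25) {
    cp <- runif(1, 20, 34); g <- runif(1, 22, 27)
    expect_equal(relative_expression(cp + 1, g),
                 relative_expression(cp, g) / 2, tolerance = 1e-12)
    expect_lt(relative_expression(cp + 0.1, g), relative_expression(cp, g))
  }
})

test_that("fold change follows the reciprocal down-regulation convention", {
  up <- fold_change(c(1.3, 1.4, 1.5), c(0.9, 1.0, 1.1))
  expect_equal(up$fold, 1.4)
  expect_equal(up$direction, "up")
  dn <- fold_change(c(0.9, 1.0, 1.1), c(1.4, 1.5, 1.6))
  expect_equal(dn$fold, 1.5)
  expect_equal(dn$direction, "down")
  expect_true(fold_change(c(1, 2), c(0, 0))$undefined)
  expect_error(fold_change(numeric(0), 1), "non-empty")
})

test_that("planted fold is recovered from a large two-group simulation", {
  # Monte-Carlo oracle: log-normal groups with a planted 1.4-fold shift
  set.seed(2024)
  n <- 10000
  stable <- 0.15 * 2^rnorm(n, 0, 0.9)
  recl <- 1.4 * 0.15 * 2^rnorm(n, 0, 0.9)
  fc <- fold_change(recl, stable)
  expect_gt(fc$ratio, 1.33)
  expect_lt(fc$ratio, 1.47)
})

test_that("quantification normalizes to the reference geoM with QC rules", {
  expr <- quantify_expression(tiny_cp_table())
  # S1: geoM = (24*25*26)^(1/3); AMACR = 2^-(28 - geoM)
  g1 <- 15600^(1 / 3)
  expect_equal(expr["S1", "AMACR"], 2^-(28 - g1), tolerance = 1e-12)
  expect_equal(expr["S1", "MALAT1"], 2^-(30 - g1), tolerance = 1e-12)
  # S2: MALAT1 mean CP 36.1 >= 35 -> negative -> missing by default
  expect_true(is.na(expr["S2", "MALAT1"]))
  expect_equal(expr["S2", "AMACR"], 2^-(25 - 24), tolerance = 1e-12)
  # imputation at the detection limit as config alternative
  expr_imp <- quantify_expression(tiny_cp_table(),
                                  negative_handling = "impute")
  expect_equal(expr_imp["S2", "MALAT1"], 2^-(35 - 24), tolerance = 1e-12)
})

test_that("flagged measurements are excluded unless kept by override", {
  cp <- tiny_cp_table()
  cp$cp_rep2[cp$sample_id == "S1" & cp$assay == "AMACR"] <- 28.6  # spread 0.6
  expr <- quantify_expression(cp)
  expect_true(is.na(expr["S1", "AMACR"]))
  expr_keep <- quantify_expression(cp, keep_flagged = TRUE)
  expect_equal(expr_keep["S1", "AMACR"], 2^-(28.3 - 15600^(1 / 3)),
               tolerance = 1e-12)
})

test_that("a failed reference voids the patient's values with a warning", {
  cp <- tiny_cp_table()
  cp$cp_rep1[cp$sample_id == "S2" & cp$assay == "TBP"] <- 36.0
  cp$cp_rep2[cp$sample_id == "S2" & cp$assay == "TBP"] <- 36.0
  expect_warning(expr <- quantify_expression(cp), "S2")
  expect_true(all(is.na(expr["S2", ])))
  expect_false(anyNA(expr["S1", ]))
})

test_that("quantification is idempotent and normalization mode matters", {
  cp <- tiny_cp_table()
  expect_identical(quantify_expression(cp), quantify_expression(cp))
  ga <- quantify_expression(cp, normalization = "arithmetic")
  gg <- quantify_expression(cp)
  # arithmetic reference mean >= geometric mean -> larger expression values
  expect_true(all(ga["S1", ] >= gg["S1", ], na.rm = TRUE))
})
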