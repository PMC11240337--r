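counts_to_vectors <- function(tp, fp, fn, tn) {
  list(ind = rep(c(TRUE, TRUE, FALSE, FALSE), c(tp, fp, fn, tn)),
       lab = rep(c(TRUE, FALSE, TRUE, FALSE), c(tp, fp, fn, tn)))
}

test_that("single-binary-predictor fits reproduce the contingency OR", {
  v <- counts_to_vectors(10, 3, 21, 38)            # PSA > 10 vs outcome
  f <- fit_logistic(data.frame(PSA = v$ind), v$lab)
  expect_equal(round(f$coefficients$or, 2), 6.03)
  expect_equal(round(f$coefficients$ci_low, 2), 1.49)
  expect_equal(round(f$coefficients$ci_high, 2), 24.36)
  v2 <- counts_to_vectors(11, 3, 20, 38)           # PSAD > 0.2
  f2 <- fit_logistic(data.frame(PSAD = v2$ind), v2$lab)
  expect_equal(round(f2$coefficients$or, 2), 6.97)
  expect_equal(round(f2$coefficients$ci_low, 2), 1.74)
  expect_equal(round(f2$coefficients$ci_high, 2), 27.88)
  # cross-product identity to at least 6 decimals
  or <- odds_ratio(confusion(v$ind, v$lab))
  expect_equal(f$coefficients$or, or$or, tolerance = 1e-6)
  expect_equal(f$coefficients$ci_low, or$ci_low, tolerance = 1e-6)
  expect_lt(f$loglik, 0)
})

test_that("a predictor orthogonal to the outcome has OR exactly 1", {
  # balanced design: every (x, y) cell equally filled
  x <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 25)
  y <- rep(c(TRUE, TRUE, FALSE, FALSE), each = 25)
  f <- fit_logistic(data.frame(x = x), y)
  expect_equal(f$coefficients$or, 1.0, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected or flagged", {
  y <- rep(c(TRUE, FALSE), 20)
  expect_error(fit_logistic(data.frame(x = rep(TRUE, 40)), y), "constant")
  expect_error(fit_logistic(data.frame(x = TRUE, z = FALSE)[0, ],
                            logical(0)), "more predictors")
  # perfect separation: coefficient diverges and is flagged
  x <- c(rnorm(30), rnorm(30) + 50)
  ysep <- rep(c(FALSE, TRUE), each = 30)
  f <- suppressWarnings(fit_logistic(data.frame(x = x), ysep))
  expect_true(f$separation_flag)
  expect_true(is.na(f$coefficients$p_value))
})

test_that("univariate screen keeps marker order and skips constants", {
  set.seed(9)
  labs <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  m <- data.frame(a = rbinom(60, 1, .5) == 1,
                  b = rbinom(60, 1, .5) == 1,
                  c = rep(TRUE, 60))
  expect_warning(tab <- univariate_screen(m, labs), "without variation")
  expect_equal(tab$term, c("a", "b"))
  expect_identical(nrow(univariate_screen(m[0], labs)), NULL)
})

test_that("univariate screen under permuted labels keeps ~5% type I error", {
  set.seed(31)
  n <- 200
  m <- data.frame(x1 = rbinom(n, 1, .5) == 1, x2 = rbinom(n, 1, .5) == 1)
  labs <- rep(c(TRUE, FALSE), each = n / 2)
  hits <- replicate(500, {
    tab <- univariate_screen(m, sample(labs))
    tab$p_value < 0.05
  })
  rate <- mean(hits)
  expect_gt(rate, 0.025); expect_lt(rate, 0.075)
})

test_that("stepwise enters the label-copy first and respects entry alpha", {
  set.seed(13)
  labs <- sample(c(TRUE, FALSE), 80, replace = TRUE)
  cand <- data.frame(noise = rbinom(80, 1, .5) == 1, copy = labs)
  fs <- suppressWarnings(forward_stepwise(cand, labs))
  expect_gte(nrow(fs$trace), 1)
  expect_equal(fs$trace$term[1], "copy")
  expect_true("copy" %in% fs$selected)
  # a lone candidate failing the entry test yields the empty model
  weak <- data.frame(w = c(rep(TRUE, 40), rep(FALSE, 40)))
  ybal <- rep(c(TRUE, FALSE), 40)
  fs2 <- forward_stepwise(weak, ybal, entry_alpha = 0.05)
  expect_equal(fs2$selected, character(0))
  expect_null(fs2$fit)
  expect_equal(nrow(fs2$trace), 0)
})

test_that("every entered term passed the entry test and the trace replays", {
  set.seed(99)
  n <- 300
  cand <- data.frame(a = rbinom(n, 1, .4) == 1, b = rbinom(n, 1, .5) == 1,
                     c = rbinom(n, 1, .5) == 1)
  labs <- rbinom(n, 1, plogis(-1 + 1.2 * cand$a + 0.9 * cand$b)) == 1
  fs1 <- forward_stepwise(cand, labs)
  fs2 <- forward_stepwise(cand, labs)
  expect_identical(fs1$trace, fs2$trace)           # deterministic replay
  entered <- fs1$trace[fs1$trace$action == "enter", ]
  expect_true(all(entered$p_value < 0.05))
  # log-likelihood is non-decreasing along the entry path
  expect_true(all(diff(entered$loglik) > -1e-10))
})

test_that("stepwise log-likelihood never decreases when terms enter", {
  set.seed(121)
  for (i in 1:5) {
    n <- 150
    cand <- data.frame(a = rbinom(n, 1, .5) == 1, b = rbinom(n, 1, .5) == 1,
                       c = rbinom(n, 1, .5) == 1, d = rbinom(n, 1, .5) == 1)
    labs <- rbinom(n, 1, plogis(-0.5 + 1.5 * cand$a)) == 1
    fs <- forward_stepwise(cand, labs)
    ll <- fs$trace$loglik[fs$trace$action == "enter"]
    if (length(ll) > 1) expect_true(all(diff(ll) > -1e-10))
  }
})
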