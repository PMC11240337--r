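test_that("AUC is 1/0 under perfect separation and flips with direction", {
  r <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE), "greater")
  expect_equal(r$auc, 1.0)
  r2 <- roc_curve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE), "greater")
  expect_equal(r2$auc, 0.0)
  r3 <- roc_curve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE), "less")
  expect_equal(r3$auc, 1.0)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both outcome classes")
})

test_that("AUC equals the all-pairs Mann-Whitney count on random instances", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(6:200, 1)
    vals <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
    labs <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(labs) == 0 || sum(!labs) == 0) next
    r <- roc_curve(vals, labs, "greater")
    expect_equal(r$auc, auc_bruteforce(vals, labs), tolerance = 1e-12)
    # cross-module identity: AUC = U / (n1 n0) from the rank-sum statistic
    w <- suppressWarnings(stats::wilcox.test(vals[labs], vals[!labs]))
    expect_equal(r$auc, unname(w$statistic) / (sum(labs) * sum(!labs)),
                 tolerance = 1e-12)
  }
})

test_that("auto orientation never yields AUC below one half", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    vals <- rnorm(n)
    labs <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(labs) == 0 || sum(!labs) == 0) next
    expect_gte(roc_curve(vals, labs, "auto")$auc, 0.5)
  }
})

test_that("null markers give AUC near one half at large n", {
  set.seed(2000)
  vals <- rnorm(2000)
  labs <- sample(rep(c(TRUE, FALSE), 1000))
  a <- roc_curve(vals, labs, "greater")$auc
  expect_gt(a, 0.47); expect_lt(a, 0.53)
})

test_that("DeLong inference matches pROC and is well calibrated", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (i in 1:10) {
    n <- sample(40:120, 1)
    labs <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.45, .55))
    if (sum(labs) < 2 || sum(!labs) < 2) next
    vals <- rnorm(n) + labs
    r <- roc_curve(vals, labs, "greater")
    inf <- auc_inference(r)
    pr <- pROC::roc(labs, vals, direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(inf$auc_ci, ci[c(1, 3)], tolerance = 1e-8)
  }
})

test_that("perfect separation yields vanishing p and CI capped at 1", {
  vals <- c(rnorm(300), rnorm(300) + 10)
  labs <- rep(c(FALSE, TRUE), each = 300)
  inf <- auc_inference(roc_curve(vals, labs, "greater"))
  # all placements tied at 1 -> zero DeLong variance, flagged degenerate
  expect_true(inf$degenerate)
  vals[1] <- 11  # one crossing pair restores a positive variance
  inf2 <- auc_inference(roc_curve(vals, labs, "greater"))
  expect_lt(inf2$p_value, 1e-10)
  expect_lte(inf2$auc_ci[2], 1.0)
})

test_that("AUC estimator is nearly unbiased under a binormal model", {
  # true AUC = pnorm(1/sqrt(2) * qnorm(0.75)...) -- direct: mu=qnorm(.75)*sqrt(2)
  mu <- sqrt(2) * qnorm(0.75)  # separation giving true AUC 0.75
  set.seed(303)
  est <- replicate(40, {
    labs <- rep(c(TRUE, FALSE), c(2500, 2500))
    vals <- rnorm(5000) + mu * labs
    roc_curve(vals, labs, "greater")$auc
  })
  expect_lt(abs(mean(est) - 0.75), 0.01)
})

test_that("DeLong confidence interval has near-nominal coverage at n=72", {
  mu <- sqrt(2) * qnorm(0.75)
  set.seed(404)
  hits <- replicate(400, {
    labs <- rep(c(TRUE, FALSE), c(31, 41))
    vals <- rnorm(72) + mu * labs
    ci <- auc_inference(roc_curve(vals, labs, "greater"))$auc_ci
    ci[1] <= 0.75 && 0.75 <= ci[2]
  })
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.985)
})

test_that("Youden cutoff equals exhaustive maximization with tie-breaks", {
  # pinned four-point instance: J is maximized at cutoff 1 (sns 1, spc .5)
  r <- youden_cutoff(roc_curve(c(1, 2, 3, 10), c(FALSE, TRUE, FALSE, TRUE),
                               "greater"))
  o <- youden_bruteforce(c(1, 2, 3, 10), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(r$cutoff, o$cutoff)
  expect_equal(r$youden_j, o$j)
  set.seed(55)
  for (i in 1:40) {
    n <- sample(6:150, 1)
    vals <- sample(round(rnorm(n), sample(0:2, 1)))
    labs <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(labs) == 0 || sum(!labs) == 0) next
    dir <- sample(c("greater", "less"), 1)
    r <- youden_cutoff(roc_curve(vals, labs, dir))
    o <- youden_bruteforce(vals, labs, dir)
    expect_equal(r$cutoff, o$cutoff)
    expect_equal(r$youden_j, o$j, tolerance = 1e-12)
    expect_equal(r$youden_j, r$sns + r$spc - 1, tolerance = 1e-12)
  }
})

test_that("Youden J is invariant under strictly monotone transforms", {
  set.seed(66)
  vals <- rnorm(50)
  labs <- sample(c(TRUE, FALSE), 50, replace = TRUE, prob = c(.4, .6))
  j1 <- youden_cutoff(roc_curve(vals, labs, "greater"))$youden_j
  j2 <- youden_cutoff(roc_curve(exp(vals), labs, "greater"))$youden_j
  expect_equal(j1, j2, tolerance = 1e-12)
})

test_that("dichotomization is strict on both sides", {
  expect_equal(dichotomize(c(9, 10, 11), 10, "greater"),
               c(FALSE, FALSE, TRUE))
  expect_equal(dichotomize(c(0.04, 0.0457, 0.05), 0.0457, "less"),
               c(TRUE, FALSE, FALSE))
  expect_true(all(!dichotomize(c(1, 2, 3), 5, "greater")))
  expect_true(is.na(dichotomize(NA_real_, 1, "greater")))
})

test_that("a binary marker's AUC is (SNS + SPC) / 2", {
  set.seed(88)
  for (i in 1:15) {
    n <- 80
    ind <- sample(c(TRUE, FALSE), n, replace = TRUE)
    labs <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(ind)) < 2 || sum(labs) == 0 || sum(!labs) == 0) next
    r <- roc_curve(as.numeric(ind), labs, "greater")
    s <- diagnostic_summary(confusion(ind, labs))
    expect_equal(r$auc, (s$sns + s$spc) / 2, tolerance = 1e-12)
  }
})
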