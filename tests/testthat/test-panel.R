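test_that("sum scores count positive components", {
  m <- rbind(c(TRUE, TRUE, TRUE, FALSE, FALSE),
             c(FALSE, FALSE, FALSE, FALSE, FALSE),
             c(TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(sum_score(m), c(3L, 0L, 5L))
  # permutation of components leaves scores unchanged
  expect_equal(sum_score(m[, c(4, 2, 5, 1, 3)]), sum_score(m))
  set.seed(3)
  r <- matrix(runif(200) > 0.5, 40, 5)
  expect_equal(sum(sum_score(r)), sum(r))          # counting oracle
  r[3, 2] <- NA
  expect_warning(s <- sum_score(r), "missing component")
  expect_true(is.na(s[3]))
})

test_that("panel definitions validate and apply frozen cutoffs", {
  p <- panel_definition(c("PSAD", "MALAT1"), c("greater", "less"),
                        c(0.2, 0.0457), threshold = 1, name = "demo")
  d <- data.frame(PSAD = c(0.25, 0.1), MALAT1 = c(0.05, 0.02))
  ind <- panel_indicators(d, p)
  expect_equal(ind[, "PSAD"], c(TRUE, FALSE))
  expect_equal(ind[, "MALAT1"], c(FALSE, TRUE))
  expect_error(panel_definition("a", "greater", 1, threshold = 2), "1..1")
  expect_error(panel_indicators(d[, 1, drop = FALSE], p), "lacks component")
})

test_that("planted confusion counts are reproduced exactly by evaluation", {
  pl <- plant_panel(tp = 27, fp = 7, fn = 4, tn = 34,
                    n_components = 5, threshold = 3)
  pe <- evaluate_panel(sum_score(pl$indicators), pl$labels, threshold = 3,
                       name = "2C-3T")
  expect_equal(pe$confusion$tp, 27L)
  expect_equal(pe$confusion$fp, 7L)
  expect_equal(pe$confusion$fn, 4L)
  expect_equal(pe$confusion$tn, 34L)
  expect_equal(round(pe$odds_ratio$or, 2), 32.79)
  expect_equal(round(100 * pe$summary$sns, 1), 87.1)
  expect_equal(round(100 * pe$summary$spc, 1), 82.9)
  expect_equal(round(100 * pe$summary$acc, 1), 84.7)
  expect_equal(round(pe$avoidance$avoided_pct), 47)
  expect_equal(round(pe$avoidance$missed_pct), 6)
  expect_equal(round(pe$avoidance$overcalled_pct), 10)
})

test_that("random feasible planted counts reproduce exactly", {
  set.seed(12)
  for (i in 1:20) {
    k <- sample(0:30, 4, replace = TRUE)
    if (k[1] + k[3] == 0 || k[2] + k[4] == 0) next   # need both classes
    y <- sample(2:6, 1)
    x <- sample(seq_len(y), 1)
    pl <- plant_panel(k[1], k[2], k[3], k[4], n_components = y, threshold = x)
    pe <- evaluate_panel(sum_score(pl$indicators), pl$labels, threshold = x)
    expect_equal(unlist(pe$confusion[c("tp", "fp", "fn", "tn")]),
                 c(tp = k[1], fp = k[2], fn = k[3], tn = k[4]))
  }
  expect_error(plant_panel(1, 1, 1, 1, n_components = 3, threshold = 4),
               "infeasible")
})

test_that("a score identical to the label separates perfectly", {
  labs <- rep(c(TRUE, FALSE), c(12, 18))
  scores <- ifelse(labs, 5L, 0L)
  pe <- evaluate_panel(scores, labs, threshold = "youden")
  expect_equal(pe$roc$auc, 1.0)
  expect_equal(pe$summary$acc, 1.0)
  expect_equal(pe$avoidance$missed_pct, 0)
})

test_that("raising the positivity threshold trades sensitivity for specificity", {
  set.seed(21)
  for (i in 1:10) {
    n <- 60
    m <- matrix(runif(n * 5) > 0.45, n, 5)
    labs <- runif(n) > 0.55
    if (sum(labs) == 0 || sum(!labs) == 0) next
    s <- sum_score(m)
    prev <- NULL
    for (x in 1:5) {
      cur <- diagnostic_summary(confusion(s >= x, labs))
      if (!is.null(prev)) {
        expect_lte(cur$sns, prev$sns + 1e-12)
        expect_gte(cur$spc, prev$spc - 1e-12)
      }
      prev <- cur
    }
  }
})

test_that("score AUC dominates the binary split and avoidance sums to 100%", {
  set.seed(34)
  n <- 80
  m <- matrix(runif(n * 5) > 0.5, n, 5)
  labs <- runif(n) > 0.5
  s <- sum_score(m)
  pe <- evaluate_panel(s, labs, threshold = 3)
  expect_gte(pe$roc$auc + 1e-12, (pe$summary$sns + pe$summary$spc) / 2)
  av <- pe$avoidance
  hit_pct <- 100 * mean(labs & pe$positivity)
  expect_equal(av$avoided_pct + av$missed_pct + av$overcalled_pct + hit_pct,
               100, tolerance = 1e-9)
})

test_that("published 2C avoidance percentages follow from its counts", {
  av <- biopsy_avoidance(rep(c(TRUE, TRUE, FALSE, FALSE), c(23, 13, 8, 28)),
                         rep(c(TRUE, FALSE, TRUE, FALSE), c(23, 13, 8, 28)))
  expect_equal(round(av$avoided_pct), 39)
  expect_equal(round(av$missed_pct), 11)
  av_all_pos <- biopsy_avoidance(rep(TRUE, 30),
                                 rep(c(TRUE, FALSE), 15))
  expect_equal(av_all_pos$avoided_pct, 0)
  expect_equal(av_all_pos$missed_pct, 0)
})
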