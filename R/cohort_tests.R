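#' Two-group comparison with the study's test-choice rule
#'
#' Continuous variables are compared by the two-sided Mann-Whitney U test
#' (exact when the product of the group sizes is at most 400 and there are
#' no ties, otherwise the normal approximation with tie correction);
#' categorical 2x2 tables by Fisher's exact test, two-sided by the
#' probability-mass method (summing all tables as or less probable than the
#' observed one).
#'
#' @param values For `variable_kind = "continuous"`, a list of two numeric
#'   vectors (one per group). For `"categorical"`, either a 2x2 count
#'   matrix or a list of two factor/character vectors.
#' @param variable_kind `"continuous"` or `"categorical"`.
#' @param variable Name used in reports.
#' @return A list of class `"uev_group_comparison"` with `variable`,
#'   `test`, `statistic`, `p_value`, and `summaries` (per-group medians and
#'   ranges, or counts).
#' @export
compare_two_groups <- function(values,
                               variable_kind = c("continuous", "categorical"),
                               variable = "variable") {
  variable_kind <- match.arg(variable_kind)
  if (variable_kind == "continuous") {
    if (!is.list(values) || length(values) != 2L)
      stop("continuous comparison needs a list of two numeric vectors")
    x <- values[[1]][!is.na(values[[1]])]
    y <- values[[2]][!is.na(values[[2]])]
    if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- !ties && length(x) * length(y) <= 400
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact))
    summaries <- lapply(list(x, y), function(v)
      list(median = stats::median(v), range = range(v), n = length(v)))
    structure(list(variable = variable, test = "Mann-Whitney U",
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   summaries = summaries),
              class = "uev_group_comparison")
  } else {
    tab <- if (is.matrix(values) || is.table(values)) as.matrix(values)
           else table(factor(rep(c(1, 2), vapply(values, length, 1L))),
                      unlist(values))
    if (any(dim(tab) != c(2L, 2L)))
      stop("Fisher comparison needs a 2x2 table")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("both groups must be non-empty")
    ft <- stats::fisher.test(tab)
    structure(list(variable = variable, test = "Fisher exact",
                   statistic = unname(ft$estimate), p_value = ft$p.value,
                   summaries = list(counts = tab)),
              class = "uev_group_comparison")
  }
}

#' Multi-group comparison with the study's test-choice rule
#'
#' Continuous variables across three or more groups are compared by the
#' Kruskal-Wallis test (with tie correction); categorical r x c tables by
#' the Pearson chi-square test without continuity correction, with
#' (r-1)(c-1) degrees of freedom.
#'
#' @param values For `"continuous"`, a list of three or more numeric
#'   vectors. For `"categorical"`, an r x c count matrix.
#' @param variable_kind `"continuous"` or `"categorical"`.
#' @param variable Name used in reports.
#' @return A `"uev_group_comparison"` object (see [compare_two_groups()]).
#' @export
compare_multi_groups <- function(values,
                                 variable_kind = c("continuous", "categorical"),
                                 variable = "variable") {
  variable_kind <- match.arg(variable_kind)
  if (variable_kind == "continuous") {
    if (!is.list(values) || length(values) < 3L)
      stop("continuous comparison needs a list of three or more groups")
    values <- lapply(values, function(v) v[!is.na(v)])
    if (any(vapply(values, length, 1L) == 0L))
      stop("all groups must be non-empty")
    kt <- stats::kruskal.test(values)
    summaries <- lapply(values, function(v)
      list(median = stats::median(v), range = range(v), n = length(v)))
    structure(list(variable = variable, test = "Kruskal-Wallis",
                   statistic = unname(kt$statistic), p_value = kt$p.value,
                   summaries = summaries),
              class = "uev_group_comparison")
  } else {
    tab <- as.matrix(values)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("all groups must be non-empty")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    structure(list(variable = variable, test = "chi-square",
                   statistic = unname(ct$statistic), p_value = ct$p.value,
                   summaries = list(counts = tab)),
              class = "uev_group_comparison")
  }
}

#' @export
print.uev_group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s, p = %.4g\n", x$variable, x$test, x$p_value))
  invisible(x)
}

#' Cohort characteristics table with group comparisons
#'
#' Builds a demographics-style table: per-group medians with ranges for
#' continuous variables and counts for categorical ones, each with the
#' p-value from the test-choice rule (two groups: Mann-Whitney U or Fisher;
#' three or more: Kruskal-Wallis or chi-square).
#'
#' @param data Data frame with one row per patient.
#' @param group Name of the grouping column in `data` (e.g. the outcome
#'   label, or an ISUP stratum).
#' @param continuous Character vector of continuous variable columns.
#' @param categorical Character vector of categorical variable columns.
#' @return A list of `"uev_group_comparison"` objects, one per variable,
#'   plus a `table` data frame (variable, test, p_value, one summary column
#'   per group).
#' @export
cohort_table <- function(data, group, continuous = character(0),
                         categorical = character(0)) {
  g <- data[[group]]
  if (is.null(g)) stop("grouping column not found: ", group)
  g <- factor(g)
  if (anyNA(g)) {
    data <- data[!is.na(g), , drop = FALSE]
    g <- droplevels(g[!is.na(g)])
  }
  levs <- levels(g)
  if (length(levs) < 2L || any(table(g) == 0L))
    stop("grouping must define at least two non-empty groups")
  two <- length(levs) == 2L
  comparisons <- list()
  rows <- list()
  for (v in continuous) {
    by_group <- split(data[[v]], g)
    cmp <- if (two) compare_two_groups(by_group, "continuous", v)
           else compare_multi_groups(by_group, "continuous", v)
    comparisons[[v]] <- cmp
    summ <- vapply(by_group, function(x) {
      x <- x[!is.na(x)]
      sprintf("%.3g (%.3g to %.3g)", stats::median(x), min(x), max(x))
    }, character(1))
    rows[[v]] <- data.frame(variable = v, test = cmp$test,
                            p_value = cmp$p_value, t(summ),
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  for (v in categorical) {
    tab <- table(factor(data[[v]]), g)
    cmp <- if (two && all(dim(tab) == 2L))
      compare_two_groups(t(tab), "categorical", v)
    else compare_multi_groups(t(tab), "categorical", v)
    comparisons[[v]] <- cmp
    summ <- vapply(levs, function(l)
      paste(sprintf("%s:%d", rownames(tab), tab[, l]), collapse = " "),
      character(1))
    rows[[v]] <- data.frame(variable = v, test = cmp$test,
                            p_value = cmp$p_value, t(summ),
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(comparisons = comparisons, table = tab)
}
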