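#' Maximum-likelihood logistic regression fit
#'
#' Thin wrapper around [stats::glm()] (iteratively reweighted least squares)
#' returning the quantities the reports need: coefficients, Wald standard
#' errors, odds ratios with Wald confidence intervals, Wald p-values, the
#' model log-likelihood, and convergence/separation flags. Coefficients with
#' absolute value above 15 together with non-convergence signal (quasi-)
#' complete separation; Wald inference is then unreliable and flagged.
#'
#' @param predictors Data frame (or matrix) of predictors, one column per
#'   term; logical columns are treated as 0/1 indicators.
#' @param labels Logical outcome labels.
#' @param conf_level Confidence level for the odds-ratio intervals.
#' @return An object of class `"uev_logit"`: a list with `coefficients`
#'   (data frame: term, estimate, se, or, ci_low, ci_high, p_value),
#'   `loglik`, `converged`, `separation_flag`, and the underlying `glm`
#'   object as `fit`.
#' @export
fit_logistic <- function(predictors, labels, conf_level = 0.95) {
  predictors <- as.data.frame(predictors)
  labels <- as.logical(labels)
  if (nrow(predictors) != length(labels))
    stop("`predictors` and `labels` must have the same number of rows")
  if (nrow(predictors) <= ncol(predictors))
    stop("more predictors than observations")
  const <- vapply(predictors, function(x) length(unique(x[!is.na(x)])) < 2L,
                  logical(1))
  if (any(const))
    stop("constant predictor(s): ",
         paste(names(predictors)[const], collapse = ", "))
  dat <- data.frame(.y = labels, lapply(predictors, as.numeric),
                    check.names = FALSE)
  form <- stats::reformulate(sprintf("`%s`", names(predictors)),
                             response = ".y")
  fit <- stats::glm(form, family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # a slope beyond +/-15 on the log-odds scale (odds ratios outside
  # ~3e-7..3e6) only arises under (quasi-)complete separation
  sep <- any(abs(est) > 15)
  keep <- names(est) != "(Intercept)"
  terms <- gsub("`", "", names(est)[keep])
  coefs <- data.frame(term = terms,
                      estimate = unname(est[keep]),
                      se = unname(se[keep]),
                      or = exp(unname(est[keep])),
                      ci_low = exp(unname(est[keep] - z * se[keep])),
                      ci_high = exp(unname(est[keep] + z * se[keep])),
                      p_value = 2 * stats::pnorm(-abs(unname(est[keep] /
                                                               se[keep]))),
                      stringsAsFactors = FALSE)
  if (sep) coefs[c("se", "ci_low", "ci_high", "p_value")] <- NA_real_
  structure(list(coefficients = coefs,
                 intercept = unname(est["(Intercept)"]),
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = fit$converged,
                 separation_flag = sep,
                 fit = fit),
            class = "uev_logit")
}

#' @export
print.uev_logit <- function(x, ...) {
  cat(sprintf("Logistic fit (logLik %.3f%s)\n", x$loglik,
              if (x$separation_flag) ", SEPARATION" else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Univariate logistic screen of dichotomized markers
#'
#' One single-predictor logistic regression per marker, mirroring the
#' univariate column of the selection table: odds ratio, Wald confidence
#' interval, and Wald p-value. Markers without variation are skipped with a
#' warning. Input order is preserved.
#'
#' @param markers Data frame of logical indicator columns (one per marker).
#' @param labels Logical outcome labels.
#' @param conf_level Confidence level for the intervals.
#' @return Data frame with one row per screened marker: `term`, `or`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
univariate_screen <- function(markers, labels, conf_level = 0.95) {
  markers <- as.data.frame(markers)
  out <- vector("list", ncol(markers))
  for (i in seq_along(markers)) {
    x <- markers[[i]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning("marker without variation skipped: ", names(markers)[i])
      next
    }
    f <- fit_logistic(markers[i], labels, conf_level = conf_level)
    out[[i]] <- f$coefficients[c("term", "or", "ci_low", "ci_high", "p_value")]
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Forward-stepwise logistic predictor selection
#'
#' At each step the unentered candidate with the smallest Rao score-test
#' p-value enters the model if that p-value is below `entry_alpha`; after
#' every entry, entered terms whose likelihood-ratio removal p-value exceeds
#' `removal_alpha` are removed (worst first). The procedure stops when no
#' entry or removal changes the model. Ties are resolved by candidate input
#' order, so the trace is deterministic.
#'
#' @param candidates Data frame of candidate predictor columns (typically
#'   dichotomized indicators).
#' @param labels Logical outcome labels.
#' @param entry_alpha Score-test entry threshold, default 0.05.
#' @param removal_alpha Likelihood-ratio removal threshold, default 0.10.
#' @param conf_level Confidence level for the final fit's intervals.
#' @return A list with `selected` (character vector, possibly empty), `fit`
#'   (a [fit_logistic()] object for the selected terms, or `NULL` for the
#'   intercept-only model), and `trace` (data frame: step, action, term,
#'   statistic, p_value, loglik).
#' @export
forward_stepwise <- function(candidates, labels,
                             entry_alpha = 0.05, removal_alpha = 0.10,
                             conf_level = 0.95) {
  candidates <- as.data.frame(candidates)
  labels <- as.logical(labels)
  cc <- stats::complete.cases(candidates) & !is.na(labels)
  candidates <- candidates[cc, , drop = FALSE]
  labels <- labels[cc]
  dat <- data.frame(.y = labels, lapply(candidates, as.numeric),
                    check.names = FALSE)
  nm <- names(candidates)
  bt <- function(x) sprintf("`%s`", x)
  model_formula <- function(sel) {
    stats::reformulate(if (length(sel)) bt(sel) else "1", response = ".y")
  }
  selected <- character(0)
  trace <- list()
  step_no <- 0L
  repeat {
    remaining <- setdiff(nm, selected)
    changed <- FALSE
    if (length(remaining) > 0L) {
      f0 <- stats::glm(model_formula(selected), family = stats::binomial(),
                       data = dat)
      a1 <- stats::add1(f0, scope = model_formula(c(selected, remaining)),
                        test = "Rao")
      # row labels carry backticks only for non-syntactic names
      idx <- match(remaining, gsub("`", "", rownames(a1)))
      stat <- a1[idx, "Rao score"]
      p <- a1[idx, "Pr(>Chi)"]
      ok <- which(!is.na(p) & p < entry_alpha)
      if (length(ok) > 0L) {
        pick <- ok[which.min(p[ok])]       # first index wins ties
        step_no <- step_no + 1L
        selected <- c(selected, remaining[pick])
        f1 <- stats::glm(model_formula(selected), family = stats::binomial(),
                         data = dat)
        trace[[length(trace) + 1L]] <-
          data.frame(step = step_no, action = "enter",
                     term = remaining[pick], statistic = stat[pick],
                     p_value = p[pick],
                     loglik = as.numeric(stats::logLik(f1)),
                     stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    # removal pass (only meaningful once >= 2 terms are in)
    while (length(selected) > 0L) {
      f1 <- stats::glm(model_formula(selected), family = stats::binomial(),
                       data = dat)
      d1 <- stats::drop1(f1, test = "LRT")
      pr <- d1[match(selected, gsub("`", "", rownames(d1))), "Pr(>Chi)"]
      worst <- which.max(pr)
      if (is.na(pr[worst]) || pr[worst] <= removal_alpha) break
      step_no <- step_no + 1L
      removed <- selected[worst]
      selected <- setdiff(selected, removed)
      f2 <- stats::glm(model_formula(selected), family = stats::binomial(),
                       data = dat)
      trace[[length(trace) + 1L]] <-
        data.frame(step = step_no, action = "remove", term = removed,
                   statistic = d1[match(removed, gsub("`", "",
                                                      rownames(d1))), "LRT"],
                   p_value = pr[worst],
                   loglik = as.numeric(stats::logLik(f2)),
                   stringsAsFactors = FALSE)
      changed <- TRUE
    }
    if (!changed) break
  }
  fit <- if (length(selected) > 0L)
    fit_logistic(candidates[selected], labels, conf_level = conf_level)
  else NULL
  trace <- if (length(trace)) do.call(rbind, trace)
  else data.frame(step = integer(0), action = character(0),
                  term = character(0), statistic = numeric(0),
                  p_value = numeric(0), loglik = numeric(0))
  list(selected = selected, fit = fit, trace = trace)
}
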