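#' Construct an association result
#'
#' Light container for one effect estimate (odds ratio, relative risk
#' ratio, or hazard ratio) with its Wald 95% confidence interval on the log
#' scale, p-value, sample size, and model metadata.
#'
#' @param measure `"OR"`, `"RRR"` or `"HR"`.
#' @param term Name of the predictor the estimate belongs to.
#' @param estimate Point estimate (ratio scale, > 0).
#' @param ci_low,ci_high 95% confidence bounds.
#' @param p_value Two-sided p-value.
#' @param n_used Number of observations the model used.
#' @param model Named list of model metadata (outcome, reference level,
#'   covariates, ...).
#' @param flags Character vector of quality flags (e.g.
#'   `"haldane_correction"`, `"separation"`, `"dropped_collinear:x"`).
#' @return An object of class `assoc_result`.
#' @export
assoc_result <- function(measure, term, estimate, ci_low, ci_high, p_value,
                         n_used, model = list(), flags = character(0)) {
  stopifnot(measure %in% c("OR", "RRR", "HR"))
  structure(list(measure = measure, term = term, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high, p_value = p_value,
                 n_used = n_used, model = model, flags = flags),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s [%s] = %.3f (95%% CI %.3f-%.3f), p = %.4g, n = %d%s\n",
              x$measure, x$term, x$estimate, x$ci_low, x$ci_high,
              x$p_value, x$n_used,
              if (length(x$flags)) paste0(" [",
                paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.assoc_result <- function(x, ...) {
  data.frame(measure = x$measure, term = x$term, estimate = x$estimate,
             ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
             n_used = x$n_used,
             outcome = if (!is.null(x$model$outcome)) x$model$outcome
                       else NA_character_,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Bind association results into one data.frame
#' @param results A list of `assoc_result` objects.
#' @return A data.frame with one row per result.
#' @export
assoc_results_table <- function(results) {
  do.call(rbind, lapply(results, as.data.frame))
}

#' Odds ratio from a 2x2 burden-by-outcome contingency table
#'
#' Computes the odds ratio for the high- versus low-burden category with
#' the low-burden / no-event cell as reference: `OR = (yes_high * no_low) /
#' (no_high * yes_low)`, with a Wald confidence interval from
#' `SE(log OR) = sqrt(sum(1/cell))`. Any zero cell triggers the
#' Haldane-Anscombe 0.5 continuity correction (applied to all four cells
#' and flagged). The chi-square test without continuity correction is
#' reported in the model metadata, with Fisher's exact test alongside
#' whenever an expected cell is below 5 (never silently substituted).
#'
#' @param tab A 2x2 matrix of counts: rows low/high burden, columns
#'   no/yes outcome (in that order; dimnames are respected when present).
#' @return An `assoc_result` with measure `"OR"`.
#' @examples
#' tab <- matrix(c(348, 187, 239, 138), nrow = 2,
#'               dimnames = list(burden = c("low", "high"),
#'                               outcome = c("no", "yes")))
#' contingency_or(tab)
#' @export
contingency_or <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (!is.null(dimnames(tab))) {
    rn <- rownames(tab); cn <- colnames(tab)
    if (all(c("low", "high") %in% rn)) tab <- tab[c("low", "high"), ]
    if (all(c("no", "yes") %in% cn)) tab <- tab[, c("no", "yes")]
  }
  flags <- character(0)
  work <- tab
  if (any(tab == 0)) {
    work <- tab + 0.5
    flags <- "haldane_correction"
  }
  or <- (work[2, 2] * work[1, 1]) / (work[2, 1] * work[1, 2])
  se <- sqrt(sum(1 / work))
  z <- log(or) / se
  p <- 2 * pnorm(-abs(z))
  meta <- list(outcome = "composite", reference = "low burden, no event",
               counts = tab)
  if (sum(tab) > 0) {
    suppressWarnings(meta$chisq_p <- chisq.test(tab, correct = FALSE)$p.value)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      meta$fisher_p <- fisher.test(tab)$p.value
      flags <- c(flags, "expected_cell_lt_5")
    }
  }
  assoc_result("OR", "burden_high", or, exp(log(or) - qnorm(0.975) * se),
               exp(log(or) + qnorm(0.975) * se), p, sum(tab),
               model = meta, flags = flags)
}

# shared extraction of one coefficient from a glm/coxph-style fit
wald_from <- function(est_log, se, measure, term, n_used, model,
                      flags = character(0)) {
  if (!is.finite(se) || se > 15) {
    flags <- c(flags, "separation")
    return(assoc_result(measure, term, exp(est_log), 0, Inf, NA_real_,
                        n_used, model, flags))
  }
  z <- est_log / se
  assoc_result(measure, term, exp(est_log),
               exp(est_log - qnorm(0.975) * se),
               exp(est_log + qnorm(0.975) * se),
               2 * pnorm(-abs(z)), n_used, model, flags)
}

#' Multivariable logistic regression for statin intolerance
#'
#' Fits `intolerance ~ burden_category + covariates` by maximum-likelihood
#' logistic regression (complete cases) and reports the adjusted odds ratio
#' for high versus low burden. Covariates dropped for collinearity are
#' reported explicitly; separation is flagged with infinite CI bounds
#' rather than silently penalized. With no covariates the estimate equals
#' the 2x2 contingency odds ratio exactly.
#'
#' @param data A data.frame with logical `intolerance`, factor
#'   `burden_category` (levels low/high) and any covariate columns.
#' @param covariates Character vector of covariate column names (default
#'   none: unadjusted).
#' @return An `assoc_result` with measure `"OR"`.
#' @export
fit_intolerance_logistic <- function(data, covariates = character(0)) {
  need <- c("intolerance", "burden_category", covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[, need, drop = FALSE]), need, drop = FALSE]
  if (length(unique(d$intolerance)) < 2)
    stop("degenerate outcome: intolerance does not vary")
  f <- as.formula(paste("intolerance ~ burden_category",
                        if (length(covariates))
                          paste("+", paste(covariates, collapse = " + "))
                        else ""))
  fit <- glm(f, data = d, family = binomial())
  flags <- character(0)
  dropped <- names(coef(fit))[is.na(coef(fit))]
  if (length(dropped))
    flags <- paste0("dropped_collinear:", dropped)
  cf <- summary(fit)$coefficients
  term <- "burden_categoryhigh"
  wald_from(cf[term, "Estimate"], cf[term, "Std. Error"], "OR",
            "burden_high", nrow(d),
            model = list(outcome = "intolerance", reference = "low burden",
                         covariates = covariates),
            flags = flags)
}

#' Multinomial logistic regression for regimen modification
#'
#' Fits the three-level regimen-modification outcome (reference: no change)
#' against burden category and covariates with [nnet::multinom()], and
#' returns one relative risk ratio per predictor and contrast
#' (escalation vs no change, de-escalation vs no change), with Wald
#' confidence intervals on the log scale.
#'
#' @param data A data.frame with factor `modification` (levels `no_change`,
#'   `escalation`, `de_escalation`), factor `burden_category`, and
#'   covariates.
#' @param covariates Character vector of covariate column names.
#' @param predictors Predictors entering the model besides covariates
#'   (default burden category; add e.g. `"myopathy"` to probe the
#'   myopathy -> de-escalation effect).
#' @param allow_collapsed Permit a two-class outcome (e.g. escalation
#'   merged into no-change), in which case the single remaining contrast is
#'   equivalent to a binary logistic fit. By default an empty class is an
#'   error naming the class.
#' @return A list of `assoc_result` objects (measure `"RRR"`), one per
#'   contrast x coefficient.
#' @export
fit_modification_multinomial <- function(data, covariates = character(0),
                                         predictors = "burden_category",
                                         allow_collapsed = FALSE) {
  need <- c("modification", predictors, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[, need, drop = FALSE]), need, drop = FALSE]
  d$modification <- droplevels(factor(d$modification,
                                      levels = c("no_change", "escalation",
                                                 "de_escalation")))
  absent <- setdiff(c("no_change", "escalation", "de_escalation"),
                    levels(d$modification)[table(d$modification) > 0])
  if (length(absent) && !allow_collapsed)
    stop("empty modification class: ", paste(absent, collapse = ", "))
  rhs <- paste(c(predictors, covariates), collapse = " + ")
  f <- as.formula(paste("modification ~", rhs))
  fit <- nnet::multinom(f, data = d, trace = FALSE, maxit = 500,
                        abstol = 1e-12, reltol = 1e-12)
  sm <- summary(fit)
  est <- sm$coefficients; se <- sm$standard.errors
  if (is.null(dim(est))) {   # two-class edge: coerce to matrix
    est <- matrix(est, nrow = 1, dimnames = list(fit$lev[2], names(est)))
    se <- matrix(se, nrow = 1, dimnames = dimnames(est))
  }
  results <- list()
  for (lev in rownames(est)) {
    for (term in setdiff(colnames(est), "(Intercept)")) {
      results[[paste(lev, term, sep = ".")]] <- wald_from(
        est[lev, term], se[lev, term], "RRR", term, nrow(d),
        model = list(outcome = lev, reference = "no_change",
                     covariates = covariates))
    }
  }
  results
}

#' Cox proportional hazards and Kaplan-Meier persistence analysis
#'
#' Models the time to first statin regimen change with a Cox proportional
#' hazards model (Efron tie handling) for high versus low PGx burden,
#' Kaplan-Meier curves per burden category, and the log-rank test.
#' Subjects without a change are censored at the end of follow-up.
#'
#' @param data A data.frame with `time_to_first_change` (days, >= 0),
#'   logical or 0/1 `event`, and factor `burden_category`.
#' @param covariates Optional covariate columns added to the Cox model.
#' @return A list of class `persistence_fit`: `result` (an `assoc_result`
#'   with measure `"HR"`), `km` (a data.frame of survival-curve
#'   coordinates: time, surv, lower, upper, strata), `logrank_p`, and the
#'   fitted `survival::coxph` object as `cox`.
#' @export
fit_persistence_cox <- function(data, covariates = character(0)) {
  need <- c("time_to_first_change", "event", "burden_category", covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[, need, drop = FALSE]), need, drop = FALSE]
  if (any(d$time_to_first_change < 0)) stop("negative event times")
  d$event <- as.integer(d$event)

  km_fit <- survival::survfit(
    survival::Surv(time_to_first_change, event) ~ burden_category, data = d)
  km <- data.frame(time = km_fit$time, surv = km_fit$surv,
                   lower = km_fit$lower, upper = km_fit$upper,
                   strata = rep(names(km_fit$strata),
                                times = km_fit$strata))

  if (sum(d$event) == 0) {
    res <- assoc_result("HR", "burden_high", NA_real_, NA_real_, NA_real_,
                        NA_real_, nrow(d),
                        model = list(outcome = "time to regimen change",
                                     reference = "low burden"),
                        flags = "no_events")
    return(structure(list(result = res, km = km, logrank_p = NA_real_,
                          cox = NULL), class = "persistence_fit"))
  }
  rhs <- paste(c("burden_category", covariates), collapse = " + ")
  cox <- survival::coxph(
    as.formula(paste("survival::Surv(time_to_first_change, event) ~", rhs)),
    data = d, ties = "efron")
  cf <- summary(cox)$coefficients
  term <- "burden_categoryhigh"
  res <- wald_from(cf[term, "coef"], cf[term, "se(coef)"], "HR",
                   "burden_high", nrow(d),
                   model = list(outcome = "time to regimen change",
                                reference = "low burden",
                                covariates = covariates,
                                ties = "efron"))
  lr <- survival::survdiff(
    survival::Surv(time_to_first_change, event) ~ burden_category, data = d)
  logrank_p <- pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)
  structure(list(result = res, km = km, logrank_p = logrank_p, cox = cox),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  print(x$result)
  cat(sprintf("log-rank p = %.4g\n", x$logrank_p))
  invisible(x)
}

#' Descriptive group-comparison tables
#'
#' Summarizes variables across the regimen-change (or any other) groups the
#' way cohort baseline tables are reported: mean +/- SD with one-way ANOVA
#' for approximately normal variables, median (Q1-Q3) with Kruskal-Wallis
#' for skewed ones, and counts (%) with the chi-square test (no continuity
#' correction) for categorical ones. When any expected cell is below 5,
#' Fisher's exact p is reported alongside the chi-square p, never
#' substituted. Empty groups are dropped with a note.
#'
#' @param data A data.frame.
#' @param group Name of the grouping column.
#' @param variables Named character vector mapping variable names to their
#'   declared scale: `"normal"`, `"skewed"` or `"categorical"`.
#' @return A data.frame with one row per variable (several per level for
#'   categorical variables): the per-group summary strings, the test used
#'   and its p-value (plus `fisher_p` where computed).
#' @export
group_comparison_tables <- function(data, group, variables) {
  stopifnot(group %in% names(data))
  g <- factor(data[[group]])
  empty <- levels(g)[table(g) == 0]
  if (length(empty)) {
    message("omitting empty group(s): ", paste(empty, collapse = ", "))
    g <- droplevels(g)
    data <- data[!is.na(g), , drop = FALSE]
  }
  rows <- list()
  for (v in names(variables)) {
    type <- variables[[v]]
    x <- data[[v]]
    if (type == "normal") {
      smry <- tapply(x, g, function(z)
        sprintf("%.2f ± %.2f", mean(z, na.rm = TRUE),
                sd(z, na.rm = TRUE)))
      p <- summary(aov(x ~ g))[[1]][["Pr(>F)"]][1]
      rows[[v]] <- data.frame(variable = v, level = "", type = type,
                              t(smry), test = "anova", p_value = p,
                              fisher_p = NA_real_, check.names = FALSE)
    } else if (type == "skewed") {
      smry <- tapply(x, g, function(z) {
        q <- quantile(z, c(0.25, 0.5, 0.75), na.rm = TRUE)
        sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
      })
      p <- kruskal.test(x ~ g)$p.value
      rows[[v]] <- data.frame(variable = v, level = "", type = type,
                              t(smry), test = "kruskal-wallis", p_value = p,
                              fisher_p = NA_real_, check.names = FALSE)
    } else if (type == "categorical") {
      tab <- table(factor(x), g)
      degenerate <- nrow(tab) < 2 || ncol(tab) < 2
      p <- if (degenerate) NA_real_ else
        suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      fp <- if (!degenerate && any(expected < 5)) {
        exact_ok <- nrow(tab) == 2 && ncol(tab) == 2
        tryCatch(
          fisher.test(tab, simulate.p.value = !exact_ok, B = 1e4)$p.value,
          error = function(e)
            fisher.test(tab, simulate.p.value = TRUE, B = 1e4)$p.value)
      } else NA_real_
      pct <- prop.table(tab, margin = 2) * 100
      for (lev in rownames(tab)) {
        smry <- sprintf("%d (%.2f%%)", tab[lev, ], pct[lev, ])
        names(smry) <- colnames(tab)
        rows[[paste(v, lev)]] <- data.frame(
          variable = v, level = lev, type = type, t(smry),
          test = "chi-square", p_value = p, fisher_p = fp,
          check.names = FALSE)
      }
    } else stop("unknown variable type: ", type)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
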