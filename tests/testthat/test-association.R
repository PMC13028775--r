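test_that("contingency odds ratio matches hand arithmetic on published counts", {
  tab <- reference_cohort_counts()$burden_composite
  res <- contingency_or(tab)
  expect_equal(res$estimate, (138 * 348) / (187 * 239), tolerance = 1e-12)
  se <- sqrt(1 / 348 + 1 / 239 + 1 / 187 + 1 / 138)
  expect_equal(res$ci_low, exp(log(res$estimate) - qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(res$ci_high, exp(log(res$estimate) + qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_identical(res$n_used, sum(tab))

  # symmetric table: OR exactly 1
  sym <- matrix(c(10, 10, 10, 10), 2,
                dimnames = list(c("low", "high"), c("no", "yes")))
  expect_equal(contingency_or(sym)$estimate, 1)
})

test_that("zero cells trigger the Haldane-Anscombe correction with a flag", {
  tab <- matrix(c(0, 5, 5, 5), 2, byrow = TRUE,
                dimnames = list(c("low", "high"), c("no", "yes")))
  res <- contingency_or(tab)
  expect_true("haldane_correction" %in% res$flags)
  # hand calculation with 0.5 added to every cell
  expect_equal(res$estimate, (5.5 * 0.5) / (5.5 * 5.5), tolerance = 1e-12)
  expect_true(is.finite(res$estimate))
  expect_true(is.finite(res$ci_low) && is.finite(res$ci_high))
})

test_that("unadjusted logistic OR equals the contingency OR to 1e-6", {
  tab <- reference_cohort_counts()$burden_composite
  d <- data.frame(
    burden_category = factor(rep(rep(c("low", "high"), 2),
                                 times = c(t(tab))[c(1, 3, 2, 4)]),
                             levels = c("low", "high")),
    intolerance = rep(c(FALSE, FALSE, TRUE, TRUE),
                      times = c(t(tab))[c(1, 3, 2, 4)]))
  # cross-check the expansion reproduces the table
  expect_identical(unname(as.vector(table(d$burden_category,
                                          d$intolerance))),
                   as.vector(tab))
  lg <- fit_intolerance_logistic(d)
  ct <- contingency_or(tab)
  expect_equal(lg$estimate, ct$estimate, tolerance = 1e-6)
  expect_equal(lg$ci_low, ct$ci_low, tolerance = 1e-4)
})

test_that("degenerate or missing outcome classes raise informative errors", {
  d <- data.frame(burden_category = factor(c("low", "high"),
                                           levels = c("low", "high")),
                  intolerance = c(FALSE, FALSE))
  expect_error(fit_intolerance_logistic(d), "degenerate")

  d <- data.frame(
    modification = factor(rep(c("no_change", "escalation"), 50),
                          levels = c("no_change", "escalation",
                                     "de_escalation")),
    burden_category = factor(rep(c("low", "high"), 50),
                             levels = c("low", "high")))
  expect_error(fit_modification_multinomial(d), "de_escalation")
})

test_that("two-class collapse matches a binary logistic fit to 1e-6", {
  set.seed(77)
  n <- 600
  d <- data.frame(
    burden_category = factor(sample(c("low", "high"), n, TRUE),
                             levels = c("low", "high")))
  p <- plogis(-1.2 + 0.5 * (d$burden_category == "high"))
  d$modification <- factor(ifelse(runif(n) < p, "de_escalation",
                                  "no_change"),
                           levels = c("no_change", "escalation",
                                      "de_escalation"))
  mm <- fit_modification_multinomial(d, allow_collapsed = TRUE)
  bg <- glm(modification == "de_escalation" ~ burden_category, data = d,
            family = binomial())
  expect_equal(log(mm[["de_escalation.burden_categoryhigh"]]$estimate),
               unname(coef(bg)["burden_categoryhigh"]), tolerance = 1e-6)
})

test_that("deterministic de-escalation under myopathy is flagged as separation", {
  d <- data.frame(
    myopathy = rep(c(TRUE, FALSE), c(60, 240)),
    burden_category = factor(rep(c("low", "high"), 150),
                             levels = c("low", "high")))
  d$modification <- factor(
    c(rep("de_escalation", 60),
      rep(c("no_change", "escalation"), c(200, 40))),
    levels = c("no_change", "escalation", "de_escalation"))
  mm <- fit_modification_multinomial(d, predictors = c("burden_category",
                                                       "myopathy"))
  de_myo <- mm[["de_escalation.myopathyTRUE"]]
  expect_true("separation" %in% de_myo$flags || de_myo$estimate > 100)
})

test_that("reversing the reference category inverts estimates exactly", {
  d <- sim_dataset(1500, seed = 42,
                   effects = null_effects(or_intolerance_high_burden = 2))
  a <- fit_intolerance_logistic(d)
  d2 <- d
  d2$burden_category <- factor(as.character(d2$burden_category),
                               levels = c("high", "low"))
  b <- glm(intolerance ~ burden_category, data = d2, family = binomial())
  expect_equal(log(a$estimate),
               -unname(coef(b)["burden_categorylow"]), tolerance = 1e-9)

  cx <- fit_persistence_cox(d)
  cx2 <- survival::coxph(survival::Surv(time_to_first_change, event) ~
                           burden_category, data = d2, ties = "efron")
  expect_equal(log(cx$result$estimate),
               -unname(coef(cx2)["burden_categorylow"]), tolerance = 1e-9)
})

test_that("confidence intervals are symmetric on the log scale", {
  d <- sim_dataset(1200, seed = 55)
  res <- list(fit_intolerance_logistic(d),
              fit_modification_multinomial(d)[[1]],
              fit_persistence_cox(d)$result)
  for (r in res)
    expect_equal(log(r$estimate) - log(r$ci_low),
                 log(r$ci_high) - log(r$estimate), tolerance = 1e-9)
})

test_that("Kaplan-Meier survival matches the closed form without censoring", {
  # k changers among n subjects, all others administratively censored at 365
  n <- 200; k <- 57
  d <- data.frame(
    time_to_first_change = c(sort(sample(1:364, k, replace = TRUE)),
                             rep(365, n - k)),
    event = rep(c(TRUE, FALSE), c(k, n - k)),
    burden_category = factor("low", levels = c("low", "high")))
  km <- survival::survfit(survival::Surv(time_to_first_change, event) ~ 1,
                          data = d)
  s_end <- min(km$surv)
  expect_equal(s_end, 1 - k / n, tolerance = 1e-12)
})

test_that("identical groups give a null log-rank test and HR near 1", {
  base <- data.frame(time_to_first_change = c(30, 90, 180, 365, 365),
                     event = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  d <- rbind(cbind(base, burden_category = "low"),
             cbind(base, burden_category = "high"))
  d$burden_category <- factor(d$burden_category, levels = c("low", "high"))
  fit <- fit_persistence_cox(d)
  expect_equal(fit$logrank_p, 1, tolerance = 1e-9)
  expect_equal(fit$result$estimate, 1, tolerance = 1e-9)
  # and an event-free cohort reports the HR as undefined
  d$event <- FALSE
  fit0 <- fit_persistence_cox(d)
  expect_true("no_events" %in% fit0$result$flags)
  expect_true(is.na(fit0$result$estimate))
})

test_that("group comparison tables report the declared summaries and tests", {
  set.seed(99)
  d <- data.frame(
    grp = factor(rep(c("a", "b", "c"), each = 40)),
    x = rnorm(120, 10, 2),
    y = exp(rnorm(120)),
    flag = rep(rep(c("yes", "no"), c(10, 30)), 3))
  tab <- group_comparison_tables(d, "grp",
                                 c(x = "normal", y = "skewed",
                                   flag = "categorical"))
  expect_setequal(unique(tab$variable), c("x", "y", "flag"))
  expect_true(all(c("a", "b", "c") %in% names(tab)))
  # identical group compositions: chi-square statistic 0, p = 1
  expect_equal(tab$p_value[tab$variable == "flag"][1], 1, tolerance = 1e-9)
  # three identical groups for a continuous variable: F = 0, p = 1
  d2 <- data.frame(grp = factor(rep(c("a", "b", "c"), each = 5)),
                   x = rep(c(1, 2, 3, 4, 5), 3))
  t2 <- group_comparison_tables(d2, "grp", c(x = "normal"))
  expect_equal(t2$p_value, 1, tolerance = 1e-9)
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  set.seed(321)
  ps <- replicate(200, {
    d <- data.frame(g = factor(rep(1:3, each = 20)), x = rnorm(60))
    kruskal.test(x ~ g, data = d)$p.value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
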