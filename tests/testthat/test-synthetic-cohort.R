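test_that("identical configurations produce identical cohorts", {
  cfg <- sim_config(n_subjects = 200, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$dispensing, b$dispensing)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$labs, b$labs)
  expect_identical(a$truth, b$truth)
  # and a different seed does not
  c <- simulate_cohort(sim_config(n_subjects = 200, seed = 124))
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("component generators agree when called separately", {
  cfg <- sim_config(n_subjects = 150, seed = 31)
  coh <- simulate_cohort(cfg)
  g <- simulate_genotypes(cfg)
  expect_identical(coh$genotypes, g)
  expect_identical(coh$dispensing[], simulate_dispensing(cfg, g)[])
  lo <- simulate_labs_outcomes(cfg, g)
  expect_identical(coh$clinical, lo$clinical)
  expect_identical(coh$labs, lo$labs)
})

test_that("configuration validation catches inconsistent inputs", {
  expect_error(sim_config(allele_freqs = c(rs4149056 = 0.2)),
               "rs2306283")
  expect_error(sim_config(statin_mix = c(atorvastatin = 0.7,
                                         rosuvastatin = 0.2)),
               "sum to 1")
  expect_error(sim_config(intensity_mix = c(low = 0.5, moderate = 0.5,
                                            high = 0.2)), "sum to 1")
  expect_error(sim_config(followup_days = 0), "followup_days")
  expect_error(sim_config(effect_sizes = c(or_intolerance_high_burden = 1)),
               "effect_sizes")
  expect_error(sim_config(baseline_rates = c(myopathy = 2, liver_injury = 0,
                                             nonadherence = 0, escalation = 0,
                                             deescalation = 0,
                                             intolerance = 0)),
               "baseline_rates|\\[0, 1\\]")
})

test_that("genotypes follow Hardy-Weinberg proportions", {
  # heterozygote fraction at the published 521C frequency
  q <- 0.2322
  af <- c(rs4149056 = q, rs2306283 = 0.485, rs2231142 = 0.062,
          rs1799853 = 0.11, rs4986893 = 0.045)
  g <- simulate_genotypes(sim_config(n_subjects = 10000, seed = 1,
                                     allele_freqs = af))
  het <- mean(g$rs4149056 == 1)
  p_het <- 2 * q * (1 - q)
  expect_lt(abs(het - p_het), 3 * sqrt(p_het * (1 - p_het) / 10000))

  # chi-square HWE test at alpha = 0.001 passes for >= 95% of seeds x loci
  hwe_p <- function(counts) {
    n <- sum(counts)
    qhat <- (counts[2] + 2 * counts[3]) / (2 * n)
    expd <- n * c((1 - qhat)^2, 2 * qhat * (1 - qhat), qhat^2)
    keep <- expd > 0
    stat <- sum((counts[keep] - expd[keep])^2 / expd[keep])
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  pass <- 0; total <- 0
  for (s in 1:20) {
    g <- simulate_genotypes(sim_config(n_subjects = 5000, seed = s))
    for (rs in names(af)) {
      counts <- tabulate(g[[rs]] + 1, nbins = 3)
      total <- total + 1
      pass <- pass + (hwe_p(counts) > 0.001)
    }
  }
  expect_gte(pass / total, 0.95)
})

test_that("degenerate allele frequencies behave as fixed genotypes", {
  af0 <- c(rs4149056 = 0, rs2306283 = 0, rs2231142 = 0, rs1799853 = 0,
           rs4986893 = 0)
  g <- simulate_genotypes(sim_config(n_subjects = 50, seed = 2,
                                     allele_freqs = af0))
  expect_true(all(as.matrix(g[, -1]) == 0))
  p <- pgx_profiles(g)
  expect_true(all(p$burden_score == 0))
  expect_true(all(p$burden_category == "low"))

  af1 <- af0; af1["rs4149056"] <- 1
  g <- simulate_genotypes(sim_config(n_subjects = 50, seed = 2,
                                     allele_freqs = af1))
  expect_true(all(g$rs4149056 == 2))
  expect_true(all(pgx_profiles(g)$phenotype == "poor"))
})

test_that("unphased emission hides the generated haplotypes but stays consistent", {
  g <- simulate_genotypes(sim_config(n_subjects = 500, seed = 8))
  haps <- attr(g, "haplotypes")
  expect_identical(nrow(haps), 500L)
  implied521 <- (haps$hap1 %in% c("*5", "*15")) +
    (haps$hap2 %in% c("*5", "*15"))
  implied388 <- (haps$hap1 %in% c("*37", "*15")) +
    (haps$hap2 %in% c("*37", "*15"))
  expect_identical(as.integer(implied521), g$rs4149056)
  expect_identical(as.integer(implied388), g$rs2306283)
  # the true diplotype is always among the caller's candidates
  for (i in sample(500, 20)) {
    call <- call_slco1b1_diplotype(g$rs4149056[i], g$rs2306283[i])
    truth <- call_slco1b1_diplotype(
      g$rs4149056[i], g$rs2306283[i],
      phased_haplotypes = c(haps$hap1[i], haps$hap2[i]))
    expect_true(truth$candidate_diplotypes %in% call$candidate_diplotypes)
  }
})

test_that("baseline non-adherence rate is recovered without effect modifiers", {
  br <- sim_config()$baseline_rates
  br["nonadherence"] <- 0.33
  d <- sim_dataset(5000, seed = 4, baseline_rates = br)
  se <- sqrt(0.33 * 0.67 / 5000)
  expect_lt(abs(mean(!d$adherent) - 0.33), 3 * se)
  # derived adherence equals the latent label by construction
  expect_true(all(d$mpr[!d$adherent] < 0.8))
})

test_that("derived courses reproduce the latent regimen truth", {
  coh <- simulate_cohort(sim_config(n_subjects = 1000, seed = 21))
  courses <- derive_courses(coh$dispensing)
  m <- match(coh$truth$subject_id, courses$subject_id)
  expect_identical(as.character(courses$modification[m]),
                   as.character(coh$truth$modification))
  ch <- !is.na(coh$truth$change_day)
  expect_equal(courses$time_to_first_change[m][ch],
               coh$truth$change_day[ch])
})

test_that("a null hazard effect leaves the burden groups' persistence indistinguishable", {
  d <- sim_dataset(2000, seed = 6)
  fit <- fit_persistence_cox(d)
  expect_gt(fit$logrank_p, 0.05)
  expect_true(fit$result$ci_low <= 1 && 1 <= fit$result$ci_high)
})

test_that("a strong de-escalation effect is recovered by the multinomial fit", {
  # recovery interval frozen from a pre-build sampling oracle (20 seeds)
  for (s in 1:5) {
    r <- recovery_fit("RRR", 3, seed = s)
    expect_gt(r[["est"]], 2.4)
    expect_lt(r[["est"]], 3.7)
  }
})

test_that("zero CK variance collapses routine draws to exp(mu)", {
  ckp <- list(male = c(mu = log(150), sigma = 0),
              female = c(mu = log(90), sigma = 0))
  coh <- simulate_cohort(sim_config(n_subjects = 200, seed = 13,
                                    ck_lognormal_params = ckp))
  ck <- coh$labs[coh$labs$lab == "ck", ]
  routine <- ck$value[ck$value < 300]   # peaks for designated are >= 3x ULN
  sexes <- coh$clinical$sex[match(ck$subject_id[ck$value < 300],
                                  coh$clinical$subject_id)]
  expect_true(all(abs(routine - ifelse(sexes == "male", 150, 90)) < 1e-9))
})

test_that("total CK missingness disables the biochemical intolerance route", {
  coh <- simulate_cohort(sim_config(n_subjects = 300, seed = 14,
                                    missingness = c(ck = 1, alt = 0,
                                                    ast = 0)))
  expect_false(any(coh$labs$lab == "ck"))
  courses <- derive_courses(coh$dispensing)
  flags <- suppressMessages(outcome_flags(coh$clinical, coh$labs, courses))
  # generator injects at most one regimen change, so the switch route
  # cannot fire either: nobody can be called intolerant
  expect_false(any(flags$intolerance))
})
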