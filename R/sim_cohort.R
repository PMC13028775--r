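#' Simulate panel genotypes under Hardy-Weinberg equilibrium
#'
#' Draws genotypes at the five panel variants independently per locus at the
#' configured minor-allele frequencies. The two SLCO1B1 sites are generated
#' as phased haplotypes internally - so true star-allele diplotypes exist
#' for the truth labels - but are emitted as unphased dosages, exercising
#' the diplotype caller's ambiguity handling. Loci are simulated unlinked
#' (they lie on three different chromosomes).
#'
#' @param config A [sim_config()].
#' @return A data.frame with `subject_id` and one dosage column (0/1/2) per
#'   panel rsID. The true SLCO1B1 haplotype pair is attached as attribute
#'   `"haplotypes"`; the variant panel as attribute `"panel"`.
#' @examples
#' g <- simulate_genotypes(sim_config(n_subjects = 100, seed = 1))
#' table(g$rs4149056)
#' @export
simulate_genotypes <- function(config) {
  config <- validate_sim_config(config)
  panel <- pgx_panel()
  af <- config$allele_freqs
  n <- config$n_subjects
  set.seed(stream_seed(config$seed, "genotypes"))

  q388 <- af[[panel$rsid[panel$locus == "SLCO1B1_388"]]]
  q521 <- af[[panel$rsid[panel$locus == "SLCO1B1_521"]]]
  h1_388 <- rbinom(n, 1, q388); h2_388 <- rbinom(n, 1, q388)
  h1_521 <- rbinom(n, 1, q521); h2_521 <- rbinom(n, 1, q521)

  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  out[[panel$rsid[panel$locus == "SLCO1B1_521"]]] <- h1_521 + h2_521
  out[[panel$rsid[panel$locus == "SLCO1B1_388"]]] <- h1_388 + h2_388
  for (locus in c("ABCG2_421", "CYP2C9_star2", "CYP2C9_star3")) {
    rsid <- panel$rsid[panel$locus == locus]
    out[[rsid]] <- rbinom(n, 2, af[[rsid]])
  }
  attr(out, "haplotypes") <- data.frame(
    subject_id = out$subject_id,
    hap1 = star_from_alleles(h1_388, h1_521),
    hap2 = star_from_alleles(h2_388, h2_521),
    stringsAsFactors = FALSE
  )
  attr(out, "panel") <- panel
  out
}

# Latent per-subject outcome assignment shared by the dispensing and lab
# generators (both derive it deterministically from the config's "latent"
# stream, so calling them separately or together yields the same cohort).
#
# Generative model:
#  * burden category: scored from the true genotypes under config$scheme;
#  * latent intolerance designation: Bernoulli on the logit scale with
#    log-OR effect of high burden (or_intolerance_high_burden);
#  * myopathy: baseline Bernoulli, forced TRUE for designated-intolerant
#    subjects (so the CK-based intolerance rule recovers them);
#  * regimen modification: multinomial logit over no-change / escalation /
#    de-escalation with RRR effects of high burden and myopathy, combined
#    with an exponential time-to-change whose hazard is the multinomial
#    no-change hazard scaled by hr_regimen_change_high_burden^high. Each
#    effect is exactly recoverable by its fitting model when the other
#    effects are at 1.
latent_outcomes <- function(config, genotypes) {
  n <- config$n_subjects
  stopifnot(nrow(genotypes) == n)
  profiles <- pgx_profiles(genotypes, config$scheme)
  high <- as.integer(profiles$burden_category == "high")

  r <- config$baseline_rates
  eff <- config$effect_sizes
  tau <- config$followup_days
  set.seed(stream_seed(config$seed, "latent"))

  p_int <- plogis(qlogis(r[["intolerance"]]) +
                    log(eff[["or_intolerance_high_burden"]]) * high)
  designated <- rbinom(n, 1, p_int) == 1
  myopathy <- (rbinom(n, 1, r[["myopathy"]]) == 1) | designated

  p_nc0 <- 1 - r[["escalation"]] - r[["deescalation"]]
  eta_e <- log(r[["escalation"]] / p_nc0) +
    log(eff[["rrr_escalation_high_burden"]]) * high
  eta_d <- log(r[["deescalation"]] / p_nc0) +
    log(eff[["rrr_deescalation_high_burden"]]) * high +
    log(eff[["rrr_deescalation_myopathy"]]) * myopathy
  p_nc <- 1 / (1 + exp(eta_e) + exp(eta_d))

  lambda <- (-log(p_nc) / tau) *
    eff[["hr_regimen_change_high_burden"]]^high
  t_raw <- rexp(n) / lambda          # Inf when lambda == 0 (never changes)
  u_type <- runif(n)
  event <- is.finite(t_raw) & t_raw < tau
  change_day <- ifelse(event, pmin(pmax(round(t_raw), 1), tau - 1), NA_real_)
  p_de <- ifelse(exp(eta_e) + exp(eta_d) > 0,
                 exp(eta_d) / (exp(eta_e) + exp(eta_d)), 0.5)
  modification <- ifelse(!event, "no_change",
                         ifelse(u_type < p_de, "de_escalation", "escalation"))

  nonadherent <- rbinom(n, 1, r[["nonadherence"]]) == 1
  liver <- rbinom(n, 1, r[["liver_injury"]]) == 1

  data.frame(
    subject_id = genotypes$subject_id,
    burden_score = profiles$burden_score,
    burden_category = profiles$burden_category,
    designated_intolerant = designated,
    myopathy = myopathy,
    liver_injury = liver,
    nonadherent = nonadherent,
    modification = factor(modification,
                          levels = c("no_change", "escalation",
                                     "de_escalation")),
    change_day = change_day,
    stringsAsFactors = FALSE
  )
}

# sample one value per row from a per-group choice set, looping over the
# (small, fixed-order) set of groups so the RNG stream is reproducible
sample_by_group <- function(group, choices_for, weights_for = NULL) {
  out <- rep(NA_character_, length(group))
  for (g in sort(unique(group))) {
    idx <- which(group == g)
    ch <- choices_for(g)
    if (length(ch) == 0) stop("no feasible choice for group ", g)
    if (length(ch) == 1) { out[idx] <- ch; next }
    w <- if (is.null(weights_for)) NULL else weights_for(g, ch)
    if (!is.null(w) && sum(w) <= 0) w <- NULL
    out[idx] <- sample(ch, length(idx), replace = TRUE, prob = w)
  }
  out
}

#' Simulate statin dispensing records
#'
#' Generates a 12-month (by default) sequence of 30-day pharmacy fills per
#' subject. Drugs follow the configured statin mix and baseline intensity
#' follows the configured intensity mix, restricted to doses the intensity
#' table lists for the drug. Regimen-change events (escalation /
#' de-escalation, switching drug when the target intensity is not available
#' for the current drug) are injected at the latent change day, where the
#' running fill is truncated and the new regimen starts; non-adherent
#' subjects stop refilling partway through follow-up so their MPR falls
#' below 0.8.
#'
#' @param config A [sim_config()].
#' @param genotypes Genotypes from [simulate_genotypes()] under the same
#'   config (the latent burden category modulates change probabilities).
#' @return A data.frame of dispensing events (`subject_id`, `date`, `drug`,
#'   `dose_mg`, `days_supplied`) with the per-subject regimen truth attached
#'   as attribute `"truth"`.
#' @export
simulate_dispensing <- function(config, genotypes) {
  config <- validate_sim_config(config)
  if (is.null(genotypes) || nrow(genotypes) == 0)
    stop("genotypes must be non-empty")
  lat <- latent_outcomes(config, genotypes)
  simulate_dispensing_impl(config, genotypes, lat)
}

simulate_dispensing_impl <- function(config, genotypes, lat) {
  force(lat)   # must be evaluated before this component's stream is seeded
  n <- config$n_subjects
  tau <- config$followup_days
  opts <- statin_dose_options()
  imix <- config$intensity_mix
  smix <- config$statin_mix
  lvl <- intensity_levels()
  set.seed(stream_seed(config$seed, "dispensing"))

  drug <- sample(names(smix), n, replace = TRUE, prob = smix)
  cls <- as.character(lat$modification)

  # feasible baseline levels: no-change keeps any listed level; escalators
  # must start below high; de-escalators must start above low
  base_group <- paste(drug, cls)
  baseline_level <- sample_by_group(
    base_group,
    choices_for = function(g) {
      parts <- strsplit(g, " ")[[1]]
      avail <- names(opts[[parts[1]]])
      switch(parts[2],
             escalation = intersect(avail, c("low", "moderate")),
             de_escalation = intersect(avail, c("moderate", "high")),
             avail)
    },
    weights_for = function(g, ch) unname(imix[ch])
  )

  dose_group <- paste(drug, baseline_level)
  baseline_dose <- as.numeric(sample_by_group(
    dose_group,
    choices_for = function(g) {
      parts <- strsplit(g, " ")[[1]]
      as.character(opts[[parts[1]]][[parts[2]]])
    }
  ))

  # target regimen for changers: adjacent intensity level, same drug when it
  # offers that level, otherwise switch to a statin that does
  changer <- cls != "no_change"
  target_level <- rep(NA_character_, n)
  shift <- ifelse(cls == "escalation", 1L, -1L)
  target_level[changer] <-
    lvl[match(baseline_level[changer], lvl) + shift[changer]]
  target_drug <- rep(NA_character_, n)
  tg <- paste(drug, target_level)[changer]
  target_drug[changer] <- sample_by_group(
    tg,
    choices_for = function(g) {
      parts <- strsplit(g, " ")[[1]]
      if (parts[2] %in% names(opts[[parts[1]]])) return(parts[1])
      names(opts)[vapply(opts, function(o) parts[2] %in% names(o), TRUE)]
    },
    weights_for = function(g, ch) unname(smix[ch])
  )
  target_dose <- rep(NA_real_, n)
  tdg <- paste(target_drug, target_level)[changer]
  target_dose[changer] <- as.numeric(sample_by_group(
    tdg,
    choices_for = function(g) {
      parts <- strsplit(g, " ")[[1]]
      as.character(opts[[parts[1]]][[parts[2]]])
    }
  ))

  u_stop <- runif(n)
  stop_day <- ifelse(lat$nonadherent, (0.3 + 0.4 * u_stop) * tau, tau)
  change_day <- lat$change_day

  # old-regimen fills every 30 days before min(change, stop); the fill
  # running at a change is truncated at the change day
  limit_old <- ifelse(changer, pmin(change_day, stop_day), stop_day)
  n_old <- as.integer(pmax(ceiling(limit_old / 30), 1))
  old <- data.frame(
    subject_id = rep(genotypes$subject_id, n_old),
    date = 30 * (sequence(n_old) - 1),
    drug = rep(drug, n_old),
    dose_mg = rep(baseline_dose, n_old),
    changer = rep(changer, n_old),
    change_day = rep(change_day, n_old),
    stringsAsFactors = FALSE
  )
  old$days_supplied <- ifelse(old$changer,
                              pmin(30, old$change_day - old$date), 30)
  old <- old[, c("subject_id", "date", "drug", "dose_mg", "days_supplied")]

  # new-regimen fills from the change day; a change after the stop day is a
  # single short fill (the non-adherent patient returning once)
  if (any(changer)) {
    c_day <- change_day[changer]
    s_day <- stop_day[changer]
    late <- c_day >= s_day
    n_new <- as.integer(ifelse(late, 1L, ceiling((s_day - c_day) / 30)))
    new <- data.frame(
      subject_id = rep(genotypes$subject_id[changer], n_new),
      date = rep(c_day, n_new) + 30 * (sequence(n_new) - 1),
      drug = rep(target_drug[changer], n_new),
      dose_mg = rep(target_dose[changer], n_new),
      days_supplied = ifelse(rep(late, n_new), 15, 30),
      stringsAsFactors = FALSE
    )
    out <- rbind(old, new)
  } else out <- old
  out <- out[order(out$subject_id, out$date), ]
  rownames(out) <- NULL

  attr(out, "truth") <- data.frame(
    subject_id = genotypes$subject_id,
    baseline_drug = drug, baseline_dose = baseline_dose,
    baseline_intensity = baseline_level,
    target_drug = target_drug, target_dose = target_dose,
    target_intensity = target_level,
    stop_day = stop_day,
    stringsAsFactors = FALSE
  )
  out
}

# fixed demographic parameters of the emulated CAD statin-user population
sim_demographics <- function() {
  list(p_male = 0.7212, age_mean = 60.33, age_sd = 10.71,
       ldl_mean = 2.48, ldl_sd = 0.99, p_diabetes = 0.8209,
       p_inhibitor = 0.1679,
       alt_mu = log(19), alt_sigma = 0.40,
       ast_mu = log(17), ast_sigma = 0.35)
}

#' Simulate the clinical table, laboratory series and truth labels
#'
#' Draws demographics and baseline covariates, a dated creatine kinase (CK)
#' series per subject (lognormal with sex-specific parameters), ALT/AST
#' values, and the EHR-style myopathy / liver-injury diagnosis flags.
#' Subjects latently designated intolerant additionally receive a CK peak of
#' at least three times their sex-specific upper limit of normal, so the
#' rule-based intolerance phenotype recovers the designation. Lab
#' missingness is applied last.
#'
#' @param config A [sim_config()].
#' @param genotypes Genotypes from [simulate_genotypes()] (same config).
#' @param dispensings Dispensing events from [simulate_dispensing()]
#'   (accepted for interface completeness; the latent assignment shared with
#'   the dispensing generator already carries the regimen truth).
#' @return A list with `clinical` (one row per subject: sex, age, diabetes,
#'   LDL, interacting-drug flag, myopathy and liver-injury flags), `labs`
#'   (long dated series: `subject_id`, `lab`, `date`, `value`), and `truth`
#'   (latent labels with the configured effect sizes as attribute
#'   `"effect_sizes"`).
#' @export
simulate_labs_outcomes <- function(config, genotypes, dispensings = NULL) {
  config <- validate_sim_config(config)
  lat <- latent_outcomes(config, genotypes)
  simulate_labs_impl(config, genotypes, lat)
}

simulate_labs_impl <- function(config, genotypes, lat) {
  force(lat)   # must be evaluated before this component's stream is seeded
  n <- config$n_subjects
  tau <- config$followup_days
  dem <- sim_demographics()
  ckp <- config$ck_lognormal_params
  set.seed(stream_seed(config$seed, "labs"))

  sex <- ifelse(rbinom(n, 1, dem$p_male) == 1, "male", "female")
  age <- rnorm(n, dem$age_mean, dem$age_sd)
  ldl <- pmax(rnorm(n, dem$ldl_mean, dem$ldl_sd), 0.1)
  diabetes <- rbinom(n, 1, dem$p_diabetes) == 1
  inhibitor <- rbinom(n, 1, dem$p_inhibitor) == 1

  mu <- ifelse(sex == "male", ckp$male[["mu"]], ckp$female[["mu"]])
  sigma <- ifelse(sex == "male", ckp$male[["sigma"]], ckp$female[["sigma"]])
  k_ck <- 2L
  ck_val <- exp(rep(mu, each = k_ck) + rep(sigma, each = k_ck) *
                  rnorm(n * k_ck))
  ck_date <- sample(0:(tau - 1), n * k_ck, replace = TRUE)
  peak_val <- ck_uln(sex) * 3 * runif(n, 1, 3)
  peak_date <- sample(0:(tau - 1), n, replace = TRUE)
  alt_val <- exp(rnorm(n, dem$alt_mu, dem$alt_sigma))
  ast_val <- exp(rnorm(n, dem$ast_mu, dem$ast_sigma))
  lab_date <- sample(0:(tau - 1), 2 * n, replace = TRUE)

  labs <- rbind(
    data.frame(subject_id = rep(genotypes$subject_id, each = k_ck),
               lab = "ck", date = ck_date, value = ck_val,
               stringsAsFactors = FALSE),
    data.frame(subject_id = genotypes$subject_id[lat$designated_intolerant],
               lab = "ck", date = peak_date[lat$designated_intolerant],
               value = peak_val[lat$designated_intolerant],
               stringsAsFactors = FALSE),
    data.frame(subject_id = genotypes$subject_id, lab = "alt",
               date = lab_date[seq_len(n)], value = alt_val,
               stringsAsFactors = FALSE),
    data.frame(subject_id = genotypes$subject_id, lab = "ast",
               date = lab_date[n + seq_len(n)], value = ast_val,
               stringsAsFactors = FALSE)
  )
  # missingness last: each observed value is dropped independently
  p_miss <- config$missingness
  u <- runif(nrow(labs))
  keep <- u >= ifelse(is.na(p_miss[labs$lab]), 0, p_miss[labs$lab])
  labs <- labs[keep, ]
  labs <- labs[order(labs$subject_id, labs$lab, labs$date), ]
  rownames(labs) <- NULL

  clinical <- data.frame(
    subject_id = genotypes$subject_id,
    sex = sex, age = age, diabetes = diabetes, ldl = ldl,
    inhibitor = inhibitor,
    myopathy = lat$myopathy, liver_injury = lat$liver_injury,
    stringsAsFactors = FALSE
  )
  truth <- lat
  attr(truth, "effect_sizes") <- config$effect_sizes
  list(clinical = clinical, labs = labs, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the genotype, dispensing and laboratory generators under one master
#' seed and bundles the result with the latent truth labels. Identical
#' configurations (including the seed) produce identical cohorts.
#'
#' @param config A [sim_config()].
#' @return An object of class `pgx_cohort`: a list with `config`,
#'   `genotypes`, `dispensing`, `clinical`, `labs` and `truth`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_subjects = 100, seed = 7))
#' coh
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  genotypes <- simulate_genotypes(config)
  lat <- latent_outcomes(config, genotypes)
  dispensing <- simulate_dispensing_impl(config, genotypes, lat)
  lo <- simulate_labs_impl(config, genotypes, lat)
  truth <- lo$truth
  attr(truth, "dispensing_truth") <- attr(dispensing, "truth")
  structure(list(config = config,
                 genotypes = genotypes,
                 dispensing = dispensing,
                 clinical = lo$clinical,
                 labs = lo$labs,
                 truth = truth),
            class = "pgx_cohort")
}

#' @export
print.pgx_cohort <- function(x, ...) {
  cat("<pgx_cohort>", nrow(x$genotypes), "subjects,",
      nrow(x$dispensing), "dispensing events,",
      nrow(x$labs), "lab values (seed", x$config$seed, ")\n")
  cat("  true burden:",
      paste(names(table(x$truth$burden_category)),
            table(x$truth$burden_category), sep = "=", collapse = " "), "\n")
  cat("  true modification:",
      paste(names(table(x$truth$modification)),
            table(x$truth$modification), sep = "=", collapse = " "), "\n")
  invisible(x)
}
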