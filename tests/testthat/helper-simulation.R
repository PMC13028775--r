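# Shared simulation helpers for the test suite. All seeds are fixed.

null_effects <- function(...) {
  eff <- c(or_intolerance_high_burden = 1,
           rrr_deescalation_high_burden = 1,
           rrr_escalation_high_burden = 1,
           rrr_deescalation_myopathy = 1,
           hr_regimen_change_high_burden = 1)
  mods <- c(...)
  eff[names(mods)] <- mods
  eff
}

sim_dataset <- function(n, seed, effects = null_effects(), ...) {
  coh <- simulate_cohort(sim_config(n_subjects = n, seed = seed,
                                    effect_sizes = effects, ...))
  cohort_analysis_dataset(coh)
}

# one parameter-recovery replicate: simulate with a single non-null effect
# and fit the model that targets it; returns c(estimate, ci_low, ci_high)
recovery_fit <- function(measure, value, seed, n = 5000) {
  eff <- switch(measure,
                OR = null_effects(or_intolerance_high_burden = value),
                RRR = null_effects(rrr_deescalation_high_burden = value),
                HR = null_effects(hr_regimen_change_high_burden = value))
  d <- sim_dataset(n, seed, eff)
  res <- switch(measure,
                OR = fit_intolerance_logistic(d),
                RRR = fit_modification_multinomial(d)[[
                  "de_escalation.burden_categoryhigh"]],
                HR = fit_persistence_cox(d)$result)
  c(est = res$estimate, lo = res$ci_low, hi = res$ci_high)
}

# cached matrix of null-simulation p-values (all effects 1), one row per
# replicate, one column per fitted contrast; computed once per test run
.null_cache <- new.env(parent = emptyenv())
null_pvalues <- function(n_reps = 200, n = 2000) {
  key <- paste0("p", n_reps, "_", n)
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  out <- matrix(NA_real_, n_reps, 4,
                dimnames = list(NULL, c("or", "rrr_esc", "rrr_de", "hr")))
  for (s in seq_len(n_reps)) {
    d <- sim_dataset(n, seed = s)
    out[s, "or"] <- fit_intolerance_logistic(d)$p_value
    mm <- fit_modification_multinomial(d)
    out[s, "rrr_esc"] <- mm[["escalation.burden_categoryhigh"]]$p_value
    out[s, "rrr_de"] <- mm[["de_escalation.burden_categoryhigh"]]$p_value
    out[s, "hr"] <- fit_persistence_cox(d)$result$p_value
  }
  .null_cache[[key]] <- out
  out
}

# dispensing-event builder for course tests
make_events <- function(dates, drugs, doses, supplied = 30, id = "S1") {
  data.frame(subject_id = rep_len(id, length(dates)), date = dates,
             drug = rep_len(drugs, length(dates)),
             dose_mg = rep_len(doses, length(dates)),
             days_supplied = rep_len(supplied, length(dates)),
             stringsAsFactors = FALSE)
}
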