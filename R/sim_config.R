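#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic-cohort simulator with defaults that
#' emulate a 12-month statin-user cohort of coronary artery disease patients:
#' allele frequencies close to the reference cohort's genotype marginals,
#' a dispensing mix dominated by atorvastatin and rosuvastatin, mostly
#' moderate/high baseline intensity, lognormal creatine kinase with
#' sex-specific upper limits of normal, and regimen-change / outcome rates
#' matching the reference cohort's printed shares (10.21% escalation,
#' 11.42% de-escalation, 29.5% non-adherence, 14.5% myopathy, 2.5% liver
#' injury). Effect sizes default to the reference cohort's point estimates
#' and are expressed on the scale of the model that consumes them
#' (odds ratio, relative risk ratio, hazard ratio).
#'
#' @param n_subjects Number of subjects to simulate.
#' @param seed Integer master seed; each generator component (genotypes,
#'   latent outcome assignment, dispensing, labs) draws from its own stream
#'   derived from it, so adding draws to one component never perturbs the
#'   others.
#' @param allele_freqs Named numeric vector of minor-allele frequencies,
#'   keyed by the panel rsIDs; all five panel variants must be present.
#' @param statin_mix Named probabilities over the five statins (must sum
#'   to 1).
#' @param intensity_mix Named probabilities over baseline intensity levels
#'   `low`, `moderate`, `high` (must sum to 1).
#' @param followup_days Length of follow-up in days (day 0 is the first
#'   fill).
#' @param effect_sizes Named positive reals:
#'   `or_intolerance_high_burden` (odds ratio of latent intolerance for the
#'   high- vs low-burden category), `rrr_deescalation_high_burden` and
#'   `rrr_escalation_high_burden` (multinomial relative risk ratios vs
#'   no-change), `rrr_deescalation_myopathy` (myopathy -> de-escalation),
#'   and `hr_regimen_change_high_burden` (hazard ratio of time to first
#'   regimen change).
#' @param baseline_rates Named probabilities for the low-burden,
#'   no-myopathy stratum: `myopathy`, `liver_injury`, `nonadherence`,
#'   `escalation`, `deescalation`, and `intolerance` (the latent
#'   intolerance designation rate the odds-ratio effect acts on).
#' @param ck_lognormal_params List with elements `male` and `female`, each
#'   `c(mu, sigma)` on the log IU/L scale.
#' @param missingness Named probabilities that an observed lab value is
#'   dropped, keyed by lab (`ck`, `alt`, `ast`).
#' @param scheme Burden scoring scheme used for the latent (truth) burden
#'   category; see [phenotype_points()].
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_subjects = 50, seed = 1)
#' cfg$allele_freqs
#' @export
sim_config <- function(n_subjects = 911,
                       seed = 1L,
                       allele_freqs = c(rs4149056 = 0.20,
                                        rs2306283 = 0.485,
                                        rs2231142 = 0.062,
                                        rs1799853 = 0.110,
                                        rs4986893 = 0.045),
                       statin_mix = c(atorvastatin = 0.6136,
                                      rosuvastatin = 0.3370,
                                      pravastatin  = 0.0241,
                                      simvastatin  = 0.0220,
                                      fluvastatin  = 0.0033),
                       intensity_mix = c(low = 0.016,
                                         moderate = 0.446,
                                         high = 0.538),
                       followup_days = 365L,
                       effect_sizes = c(or_intolerance_high_burden = 1.14,
                                        rrr_deescalation_high_burden = 1.18,
                                        rrr_escalation_high_burden = 0.93,
                                        rrr_deescalation_myopathy = 1.91,
                                        hr_regimen_change_high_burden = 1.02),
                       baseline_rates = c(myopathy = 0.145,
                                          liver_injury = 0.025,
                                          nonadherence = 0.295,
                                          escalation = 0.1021,
                                          deescalation = 0.1142,
                                          intolerance = 0.10),
                       ck_lognormal_params = list(male = c(mu = log(120),
                                                          sigma = 0.45),
                                                  female = c(mu = log(80),
                                                             sigma = 0.45)),
                       missingness = c(ck = 0, alt = 0, ast = 0),
                       scheme = c("table8_weighted", "text_ordinal")) {
  scheme <- match.arg(scheme)
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects),
         seed = as.integer(seed),
         allele_freqs = allele_freqs,
         statin_mix = statin_mix,
         intensity_mix = intensity_mix,
         followup_days = as.integer(followup_days),
         effect_sizes = effect_sizes,
         baseline_rates = baseline_rates,
         ck_lognormal_params = ck_lognormal_params,
         missingness = missingness,
         scheme = scheme),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.finite(cfg$n_subjects) || cfg$n_subjects < 1)
    stop("n_subjects must be a positive integer", call. = FALSE)
  if (cfg$followup_days <= 0)
    stop("followup_days must be > 0", call. = FALSE)

  need <- panel_rsids()
  missing_freq <- setdiff(need, names(cfg$allele_freqs))
  if (length(missing_freq))
    stop("allele_freqs is missing panel variant(s): ",
         paste(missing_freq, collapse = ", "), call. = FALSE)
  if (any(cfg$allele_freqs < 0 | cfg$allele_freqs > 1))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)

  check_simplex <- function(x, what) {
    if (any(x < 0 | x > 1))
      stop(what, " probabilities must lie in [0, 1]", call. = FALSE)
    if (abs(sum(x) - 1) > 1e-9)
      stop(what, " must sum to 1 (got ", format(sum(x)), ")", call. = FALSE)
  }
  check_simplex(cfg$statin_mix, "statin_mix")
  if (!all(names(cfg$statin_mix) %in% statin_drugs()))
    stop("statin_mix names must be statins in the panel: ",
         paste(statin_drugs(), collapse = ", "), call. = FALSE)
  check_simplex(cfg$intensity_mix, "intensity_mix")
  if (!setequal(names(cfg$intensity_mix), c("low", "moderate", "high")))
    stop("intensity_mix must be named low/moderate/high", call. = FALSE)

  need_eff <- c("or_intolerance_high_burden", "rrr_deescalation_high_burden",
                "rrr_escalation_high_burden", "rrr_deescalation_myopathy",
                "hr_regimen_change_high_burden")
  miss <- setdiff(need_eff, names(cfg$effect_sizes))
  if (length(miss))
    stop("effect_sizes is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(cfg$effect_sizes <= 0))
    stop("effect sizes must be positive", call. = FALSE)

  need_rate <- c("myopathy", "liver_injury", "nonadherence", "escalation",
                 "deescalation", "intolerance")
  miss <- setdiff(need_rate, names(cfg$baseline_rates))
  if (length(miss))
    stop("baseline_rates is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(cfg$baseline_rates < 0 | cfg$baseline_rates > 1))
    stop("baseline_rates must lie in [0, 1]", call. = FALSE)
  if (sum(cfg$baseline_rates[c("escalation", "deescalation")]) >= 1)
    stop("escalation + deescalation baseline rates must be < 1",
         call. = FALSE)
  if (any(cfg$missingness < 0 | cfg$missingness > 1))
    stop("missingness must lie in [0, 1]", call. = FALSE)
  sapply(cfg$ck_lognormal_params[c("male", "female")], function(p) {
    if (length(p) < 2 || p[2] < 0)
      stop("ck_lognormal_params must give (mu, sigma >= 0) per sex",
           call. = FALSE)
  })
  cfg
}

#' Read a simulation configuration from YAML or JSON
#'
#' The document mirrors the arguments of [sim_config()]; omitted fields keep
#' their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  doc <- read_config_document(path)
  args <- doc[intersect(names(doc), names(formals(sim_config)))]
  args <- lapply(args, function(x) if (is.list(x) &&
    all(vapply(x, is.numeric, TRUE)) &&
    all(lengths(x) == 1)) unlist(x) else x)
  do.call(sim_config, args)
}

read_config_document <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

# Independent RNG streams per generator component, derived from the master
# seed. Offsets are fixed so adding a component never perturbs the others.
stream_seed <- function(seed, stream) {
  idx <- match(stream, c("genotypes", "latent", "dispensing", "labs"))
  if (is.na(idx)) stop("unknown RNG stream: ", stream)
  as.integer((abs(as.numeric(seed)) %% 599999) * 2017 + idx * 104729) %% .Machine$integer.max
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_subjects, "subjects, seed", x$seed,
      ",", x$followup_days, "days follow-up, scheme", x$scheme, "\n")
  cat("  allele freqs:",
      paste(names(x$allele_freqs), signif(x$allele_freqs, 3),
            sep = "=", collapse = " "), "\n")
  cat("  effects:",
      paste(names(x$effect_sizes), signif(x$effect_sizes, 3),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}
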