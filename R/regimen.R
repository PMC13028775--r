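#' @name statin_intensity
#' @title ACC/AHA statin intensity categories
#' @description
#' Drug-dose ranges defining low, moderate and high intensity (expected
#' LDL-C reduction < 30%, 30-49%, and >= 50% respectively). Ranges are
#' closed intervals in mg/day; doses outside every listed range are
#' unclassifiable. Not every drug offers every level: atorvastatin and
#' rosuvastatin have no low-intensity dose, while simvastatin, pravastatin
#' and fluvastatin have no high-intensity dose.
NULL

statin_drugs <- function() {
  c("atorvastatin", "rosuvastatin", "simvastatin", "pravastatin",
    "fluvastatin")
}

intensity_levels <- function() c("low", "moderate", "high")

statin_intensity_ranges <- function() {
  data.frame(
    drug = c("atorvastatin", "atorvastatin",
             "rosuvastatin", "rosuvastatin",
             "simvastatin", "simvastatin",
             "pravastatin", "pravastatin",
             "fluvastatin", "fluvastatin"),
    level = c("moderate", "high", "moderate", "high",
              "low", "moderate", "low", "moderate", "low", "moderate"),
    dose_min = c(10, 40, 5, 20, 10, 20, 10, 40, 20, 80),
    dose_max = c(20, 80, 10, 40, 10, 40, 20, 80, 40, 80),
    stringsAsFactors = FALSE
  )
}

# listed doses per (drug, level), used by the synthetic dispensing generator
statin_dose_options <- function() {
  list(
    atorvastatin = list(moderate = c(10, 20), high = c(40, 80)),
    rosuvastatin = list(moderate = c(5, 10), high = c(20, 40)),
    simvastatin  = list(low = 10, moderate = c(20, 40)),
    pravastatin  = list(low = c(10, 20), moderate = c(40, 80)),
    fluvastatin  = list(low = c(20, 40), moderate = 80)
  )
}

#' Classify a statin dose into an intensity level
#'
#' Looks up the (drug, dose) pair in the intensity dose ranges, treating the
#' printed ranges as closed intervals. Doses covered by no listed range
#' (e.g. atorvastatin 5 mg, or atorvastatin 30 mg which falls between the
#' moderate and high ranges) return `"unclassifiable"`.
#'
#' @param drug Character vector of lowercase generic statin names.
#' @param dose_mg Positive numeric vector of daily doses in mg.
#' @return Factor with levels low/moderate/high/unclassifiable.
#' @examples
#' classify_intensity("atorvastatin", 40)  # high
#' classify_intensity("rosuvastatin", 5)   # moderate
#' classify_intensity("atorvastatin", 5)   # unclassifiable
#' @export
classify_intensity <- function(drug, dose_mg) {
  n <- max(length(drug), length(dose_mg))
  drug <- rep_len(drug, n); dose_mg <- rep_len(dose_mg, n)
  unknown <- !(drug %in% statin_drugs())
  if (any(unknown))
    stop("unknown drug: ", paste(unique(drug[unknown]), collapse = ", "))
  if (any(!is.na(dose_mg) & dose_mg <= 0))
    stop("dose_mg must be positive")
  rng <- statin_intensity_ranges()
  out <- rep("unclassifiable", n)
  for (i in seq_len(nrow(rng))) {
    hit <- drug == rng$drug[i] & !is.na(dose_mg) &
      dose_mg >= rng$dose_min[i] & dose_mg <= rng$dose_max[i]
    out[hit] <- rng$level[i]
  }
  factor(out, levels = c(intensity_levels(), "unclassifiable"))
}

#' Derive regimen courses for a cohort of dispensing records
#'
#' Turns longitudinal dispensing events into one intensity-labelled course
#' per subject: the three-level regimen-modification class, the switch
#' count, the time to first intensity change, and MPR adherence.
#'
#' The modification class is the class of the *first* intensity-level
#' transition within follow-up: escalation if the level rises,
#' de-escalation if it falls, otherwise no change. Same-intensity drug or
#' dose switches leave the class at no-change but increment `switch_count`
#' (the intolerance rule consumes that count). Unclassifiable intensities
#' are skipped for transition detection but still count as switches when
#' drug or dose differ. Subjects without an intensity transition are
#' censored at `followup_days`.
#'
#' MPR is the sum of dispensed days of supply (each fill truncated at the
#' follow-up end), divided by `followup_days` and capped at 1; adherence is
#' MPR >= 0.80.
#'
#' @param events A data.frame of dispensing events: `subject_id`, `date`
#'   (day index from the subject's first fill), `drug`, `dose_mg`,
#'   `days_supplied`.
#' @param followup_days Length of the follow-up window in days.
#' @return A data.frame with one row per subject: `modification`,
#'   `switch_count`, `time_to_first_change`, `event` (indicator of an
#'   intensity change), `mpr`, `adherent`, the baseline drug/dose/intensity
#'   and `n_events`.
#' @seealso [derive_course()] for a single subject, [compute_mpr()].
#' @export
derive_courses <- function(events, followup_days = 365L) {
  stopifnot(followup_days > 0)
  need <- c("subject_id", "date", "drug", "dose_mg", "days_supplied")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("dispensing table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(events) == 0) stop("no dispensing events supplied")
  if (any(events$date < 0)) stop("dispensing dates must be >= 0")

  dt <- data.table::as.data.table(events)[, need, with = FALSE]
  n_late <- sum(dt$date > followup_days)
  if (n_late)
    message(n_late, " dispensing event(s) beyond follow-up ignored")
  dt <- dt[date <= followup_days]
  if (nrow(dt) == 0) stop("no dispensing events within follow-up")
  data.table::setorder(dt, subject_id, date)

  dt[, intensity := classify_intensity(drug, dose_mg)]
  dt[, level_num := match(as.character(intensity), intensity_levels())]

  course_one <- function(sd) {
    k <- nrow(sd)
    sw <- if (k > 1)
      sum(sd$drug[-1] != sd$drug[-k] | sd$dose_mg[-1] != sd$dose_mg[-k])
    else 0L
    lv <- sd$level_num[!is.na(sd$level_num)]
    lv_dates <- sd$date[!is.na(sd$level_num)]
    modif <- "no_change"; t_change <- as.numeric(followup_days); ev <- FALSE
    if (length(lv) > 1) {
      diffs <- which(lv[-1] != lv[-length(lv)])
      if (length(diffs)) {
        i <- diffs[1]
        modif <- if (lv[i + 1] > lv[i]) "escalation" else "de_escalation"
        t_change <- as.numeric(lv_dates[i + 1])
        ev <- TRUE
      }
    }
    mpr <- min(sum(pmin(sd$days_supplied,
                        pmax(followup_days - sd$date, 0))) / followup_days, 1)
    list(modification = modif, switch_count = as.integer(sw),
         time_to_first_change = t_change, event = ev,
         mpr = mpr, adherent = mpr >= 0.80,
         baseline_drug = sd$drug[1], baseline_dose = sd$dose_mg[1],
         baseline_intensity = as.character(sd$intensity[1]),
         n_events = k)
  }
  out <- dt[, course_one(.SD), by = subject_id]
  out <- as.data.frame(out)
  out$modification <- factor(out$modification,
                             levels = c("no_change", "escalation",
                                        "de_escalation"))
  out$baseline_intensity <- factor(out$baseline_intensity,
                                   levels = c(intensity_levels(),
                                              "unclassifiable"))
  out
}

#' Derive the regimen course for a single subject
#'
#' @inheritParams derive_courses
#' @return A one-row data.frame; see [derive_courses()].
#' @examples
#' ev <- data.frame(subject_id = "S1", date = c(0, 90),
#'                  drug = "atorvastatin", dose_mg = c(20, 40),
#'                  days_supplied = 90)
#' derive_course(ev)  # escalation at day 90
#' @export
derive_course <- function(events, followup_days = 365L) {
  if (nrow(events) == 0) stop("no dispensing events supplied")
  if (length(unique(events$subject_id)) != 1)
    stop("derive_course expects events for a single subject")
  derive_courses(events, followup_days)
}

#' Medication possession ratio over the follow-up window
#'
#' MPR = cumulative days of medication supplied within follow-up divided by
#' the total days of follow-up, capped at 1. Supplies extending past the
#' follow-up end are truncated. Adherence is MPR >= 0.80 (inclusive).
#'
#' @param events Dispensing events for one subject (may be empty: MPR 0).
#' @param followup_days Length of follow-up in days.
#' @return A list with `mpr` and `adherent`.
#' @examples
#' ev <- data.frame(subject_id = "S1", date = 0, drug = "atorvastatin",
#'                  dose_mg = 20, days_supplied = 292)
#' compute_mpr(ev, 365)  # exactly 0.8, adherent
#' @export
compute_mpr <- function(events, followup_days = 365L) {
  stopifnot(followup_days > 0)
  if (is.null(events) || nrow(events) == 0)
    return(list(mpr = 0, adherent = FALSE))
  ev <- events[events$date <= followup_days, , drop = FALSE]
  mpr <- min(sum(pmin(ev$days_supplied,
                      pmax(followup_days - ev$date, 0))) / followup_days, 1)
  list(mpr = mpr, adherent = mpr >= 0.80)
}
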