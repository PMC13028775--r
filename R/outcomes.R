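#' Sex-specific upper limit of normal for creatine kinase
#'
#' @param sex Character vector (`"male"`/`"female"`; `NA` allowed).
#' @return Numeric IU/L: 120 for women, 180 for men, `NA` when sex is
#'   missing (CK rules are then unevaluable and flagged downstream).
#' @examples
#' ck_uln(c("female", "male"))
#' @export
ck_uln <- function(sex) {
  bad <- !is.na(sex) & !(sex %in% c("male", "female"))
  if (any(bad)) stop("sex must be 'male', 'female' or NA")
  ifelse(is.na(sex), NA_real_, ifelse(sex == "female", 120, 180))
}

#' Rule-based statin intolerance flag
#'
#' Biochemical statin intolerance requires a 3-fold CK elevation over the
#' sex-specific upper limit of normal, accompanied by myopathy findings or
#' regimen de-escalation; changing statin more than 3 times is an
#' alternative behavioural route. Two readings of the rule are offered:
#'
#' * `"extended"` (default): `(max CK >= 3 x ULN AND (myopathy OR
#'   de-escalation)) OR switch_count > 3` - the switch route stands alone
#'   and needs no CK data;
#' * `"strict"`: the 3-fold CK elevation is required for all three
#'   sub-clauses: `max CK >= 3 x ULN AND (myopathy OR de-escalation OR
#'   switch_count > 3)`.
#'
#' Missing inputs degrade the affected clause to FALSE (an empty CK series
#' or missing sex never asserts intolerance).
#'
#' @param max_ck Numeric vector: each subject's maximum observed CK (IU/L);
#'   `NA` for an empty series.
#' @param sex `"male"`/`"female"`/`NA` per subject.
#' @param modification Regimen modification class per subject (from
#'   [derive_courses()]).
#' @param switch_count Integer switch count per subject.
#' @param myopathy Logical myopathy diagnosis flag per subject.
#' @param rule `"extended"` or `"strict"`.
#' @return Logical vector.
#' @examples
#' intolerance_flag(600, "male", "de_escalation", 0, FALSE)   # TRUE
#' intolerance_flag(NA, "male", "no_change", 4, FALSE)        # TRUE
#' @export
intolerance_flag <- function(max_ck, sex, modification, switch_count,
                             myopathy, rule = c("extended", "strict")) {
  rule <- match.arg(rule)
  ck3 <- !is.na(max_ck) & !is.na(sex) & max_ck >= 3 * ck_uln(sex)
  myo <- !is.na(myopathy) & myopathy
  deesc <- !is.na(modification) & modification == "de_escalation"
  many_switches <- !is.na(switch_count) & switch_count > 3
  if (rule == "extended")
    (ck3 & (myo | deesc)) | many_switches
  else
    ck3 & (myo | deesc | many_switches)
}

#' Composite adverse outcome flag
#'
#' The composite adverse outcome is the occurrence of any of statin-related
#' myopathy, liver injury, or poor medication adherence; one event suffices.
#'
#' @param myopathy,liver_injury,nonadherent Logical vectors.
#' @return Logical vector: the elementwise OR.
#' @examples
#' composite_flag(FALSE, FALSE, TRUE)  # TRUE
#' @export
composite_flag <- function(myopathy, liver_injury, nonadherent) {
  myopathy | liver_injury | nonadherent
}

#' Rule-based outcome phenotyping for a cohort
#'
#' Applies all outcome definitions to the clinical table, laboratory series
#' and derived regimen courses: CK elevation (1 x ULN, reported separately
#' from the 3 x ULN intolerance criterion), statin intolerance, the
#' EHR-style myopathy and liver-injury flags, MPR-based non-adherence, and
#' the composite adverse outcome.
#'
#' @param clinical Per-subject table with `subject_id`, `sex`, `myopathy`,
#'   `liver_injury` (see [simulate_labs_outcomes()]).
#' @param labs Long lab series with `subject_id`, `lab`, `value` (`"ck"`
#'   rows are used).
#' @param courses Output of [derive_courses()].
#' @param rule Intolerance rule variant; see [intolerance_flag()].
#' @return A data.frame keyed by subject: `ck_max`, `ck_elevated`,
#'   `intolerance`, `myopathy`, `liver_injury`, `nonadherent`, `composite`,
#'   and `ck_unevaluable` (TRUE when missing sex or an empty CK series made
#'   the CK rules unevaluable).
#' @export
outcome_flags <- function(clinical, labs, courses,
                          rule = c("extended", "strict")) {
  rule <- match.arg(rule)
  ck <- labs[labs$lab == "ck" & !is.na(labs$value), , drop = FALSE]
  ck_max <- tapply(ck$value, ck$subject_id, max)
  out <- data.frame(subject_id = clinical$subject_id,
                    stringsAsFactors = FALSE)
  out$ck_max <- as.numeric(ck_max[out$subject_id])
  out$sex <- clinical$sex[match(out$subject_id, clinical$subject_id)]

  m <- match(out$subject_id, courses$subject_id)
  modification <- courses$modification[m]
  switch_count <- courses$switch_count[m]
  adherent <- courses$adherent[m]

  out$ck_unevaluable <- is.na(out$ck_max) | is.na(out$sex)
  if (any(out$ck_unevaluable))
    message(sum(out$ck_unevaluable),
            " subject(s) with unevaluable CK rules (missing sex or CK)")
  out$ck_elevated <- ifelse(out$ck_unevaluable, NA,
                            out$ck_max >= ck_uln(out$sex))
  out$myopathy <- clinical$myopathy
  out$liver_injury <- clinical$liver_injury
  out$intolerance <- intolerance_flag(out$ck_max, out$sex, modification,
                                      switch_count, out$myopathy, rule)
  out$nonadherent <- !adherent
  out$composite <- composite_flag(out$myopathy, out$liver_injury,
                                  out$nonadherent)
  out$sex <- NULL
  out
}
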