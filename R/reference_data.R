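#' Published reference-cohort summary counts
#'
#' Printed summary counts from a published retrospective cohort of 911
#' statin-treated coronary artery disease patients, bundled as inputs for
#' worked examples and validation: the regimen-change group sizes, the
#' SLCO1B1 function-phenotype distribution (889 of the 911 subjects were
#' phenotyped), and the burden-by-composite-outcome contingency table.
#'
#' The contingency table's count-derived odds ratio is 1.074; the source
#' publication rounds it to 1.08, and its two row totals sum to 912 rather
#' than 911 - both printed-table quirks that the count-derived analyses in
#' this package intentionally do not "correct".
#'
#' @return A list with components `regimen` (named counts: escalation,
#'   de_escalation, no_change), `slco1b1_phenotype` (named counts: normal,
#'   decreased, poor) and `burden_composite` (2x2 matrix: rows low/high
#'   burden, columns no/yes composite outcome).
#' @examples
#' ref <- reference_cohort_counts()
#' pct_shares(ref$regimen)
#' contingency_or(ref$burden_composite)
#' @export
reference_cohort_counts <- function() {
  list(
    regimen = c(escalation = 93L, de_escalation = 104L, no_change = 714L),
    slco1b1_phenotype = c(normal = 578L, decreased = 272L, poor = 39L),
    burden_composite = matrix(
      c(348L, 187L, 239L, 138L), nrow = 2,
      dimnames = list(burden = c("low", "high"), outcome = c("no", "yes")))
  )
}

#' Percentage shares of a count vector
#'
#' @param counts Non-negative counts.
#' @param digits Rounding for the returned percentages.
#' @return Named numeric percentages summing to ~100.
#' @examples
#' pct_shares(c(a = 93, b = 104, c = 714))
#' @export
pct_shares <- function(counts, digits = 2) {
  round(100 * counts / sum(counts), digits)
}
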