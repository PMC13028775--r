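#' @name slco1b1
#' @title SLCO1B1 star-allele haplotypes and function phenotypes
#' @description
#' The four SLCO1B1 haplotypes the burden score distinguishes are defined by
#' the two panel sites: `*1` = 388A-521T, `*37` = 388G-521T,
#' `*5` = 388A-521C, `*15` = 388G-521C. Transporter function phenotypes
#' follow the diplotype grouping used in CPIC-style translation tables:
#' normal = {*1/*1, *1/*37, *37/*37}; decreased = {*1/*5, *1/*15, *37/*5,
#' *37/*15}; poor = {*5/*5, *5/*15, *15/*15}. Because every haplotype
#' carrying 521C is reduced-function, the phenotype depends only on the
#' 521C dosage; phase ambiguity never changes it.
NULL

star_allele_order <- c("*1", "*37", "*5", "*15")

# haplotype from per-haplotype alt-allele indicators (388G, 521C)
star_from_alleles <- function(a388, a521) {
  ifelse(a521 == 1L,
         ifelse(a388 == 1L, "*15", "*5"),
         ifelse(a388 == 1L, "*37", "*1"))
}

# diplotype string with haplotypes in canonical order, e.g. "*1/*15"
format_diplotype <- function(h1, h2) {
  o1 <- match(h1, star_allele_order)
  o2 <- match(h2, star_allele_order)
  ifelse(o1 <= o2, paste0(h1, "/", h2), paste0(h2, "/", h1))
}

slco1b1_phenotype_table <- function() {
  c("*1/*1" = "normal", "*1/*37" = "normal", "*37/*37" = "normal",
    "*1/*5" = "decreased", "*1/*15" = "decreased",
    "*37/*5" = "decreased", "*37/*15" = "decreased",
    "*5/*5" = "poor", "*5/*15" = "poor", "*15/*15" = "poor")
}

#' Call the SLCO1B1 diplotype and function phenotype for one subject
#'
#' Enumerates every unordered star-allele pair consistent with the unphased
#' dosages at c.521T>C (rs4149056) and c.388A>G (rs2306283), and assigns the
#' transporter function phenotype from the diplotype grouping. When both
#' sites are heterozygous the candidate set contains two diplotypes
#' (`*1/*15` and `*37/*5`); both belong to the decreased-function group, so
#' the phenotype is reported without resolving phase. Supplying phased
#' haplotypes collapses the candidate set to a singleton.
#'
#' A missing dosage at either site yields phenotype `"unknown"` and an empty
#' candidate set; no imputation is attempted.
#'
#' @param d521 Dosage (0, 1, 2 or `NA`) of the 521C allele (rs4149056).
#' @param d388 Dosage (0, 1, 2 or `NA`) of the 388G allele (rs2306283).
#' @param phased_haplotypes Optional character vector of two star alleles
#'   (e.g. `c("*1", "*15")`); must be consistent with the dosages.
#' @return A list of class `slco_diplotype` with elements
#'   `candidate_diplotypes` (character), `phenotype` (one of `"normal"`,
#'   `"decreased"`, `"poor"`, `"unknown"`) and `phased` (logical).
#' @examples
#' call_slco1b1_diplotype(1, 1)   # double heterozygote: two candidates
#' call_slco1b1_diplotype(2, 0)   # *5/*5, poor function
#' @export
call_slco1b1_diplotype <- function(d521, d388, phased_haplotypes = NULL) {
  if (!is.null(phased_haplotypes)) {
    stopifnot(length(phased_haplotypes) == 2,
              all(phased_haplotypes %in% star_allele_order))
    implied521 <- sum(phased_haplotypes %in% c("*5", "*15"))
    implied388 <- sum(phased_haplotypes %in% c("*37", "*15"))
    if ((!is.na(d521) && implied521 != d521) ||
        (!is.na(d388) && implied388 != d388))
      stop("phased haplotypes are inconsistent with the supplied dosages")
    dip <- format_diplotype(phased_haplotypes[1], phased_haplotypes[2])
    return(structure(list(candidate_diplotypes = dip,
                          phenotype = unname(slco1b1_phenotype_table()[dip]),
                          phased = TRUE),
                     class = "slco_diplotype"))
  }
  if (is.na(d521) || is.na(d388)) {
    return(structure(list(candidate_diplotypes = character(0),
                          phenotype = "unknown", phased = FALSE),
                     class = "slco_diplotype"))
  }
  stopifnot(d521 %in% 0:2, d388 %in% 0:2)
  splits <- function(d) if (d == 1L) list(c(0L, 1L), c(1L, 0L)) else
    list(c(as.integer(d / 2), as.integer(d / 2)))
  dips <- character(0)
  for (s5 in splits(d521)) for (s3 in splits(d388)) {
    h1 <- star_from_alleles(s3[1], s5[1])
    h2 <- star_from_alleles(s3[2], s5[2])
    dips <- c(dips, format_diplotype(h1, h2))
  }
  dips <- unique(dips)
  phen <- unique(unname(slco1b1_phenotype_table()[dips]))
  # provable invariant: all phasings of the same dosages share one phenotype
  stopifnot(length(phen) == 1)
  structure(list(candidate_diplotypes = dips, phenotype = phen,
                 phased = FALSE),
            class = "slco_diplotype")
}

#' @export
print.slco_diplotype <- function(x, ...) {
  cat("<slco_diplotype> ",
      if (length(x$candidate_diplotypes))
        paste(x$candidate_diplotypes, collapse = " | ") else "(unresolved)",
      " -> ", x$phenotype,
      if (x$phased) " [phased]" else "", "\n", sep = "")
  invisible(x)
}

#' Points contributed by the SLCO1B1 phenotype to the burden score
#'
#' Two scoring schemes are supported. `table8_weighted` (the score's
#' defining table) collapses decreased and poor function to 2 points;
#' `text_ordinal` keeps the ordinal 0/1/2 coding (normal/decreased/poor).
#' The two schemes differ only for decreased-function subjects, where the
#' difference is exactly 1 point - which can move a subject across the
#' low/high dichotomization boundary.
#'
#' @param phenotype Character vector of phenotypes (`"normal"`,
#'   `"decreased"`, `"poor"`, `"unknown"`), or a `slco_diplotype`.
#' @param scheme `"table8_weighted"` (default) or `"text_ordinal"`.
#' @return Integer points (0, 1 or 2); `NA` for unknown phenotypes.
#' @examples
#' phenotype_points("decreased", "text_ordinal")     # 1
#' phenotype_points("decreased", "table8_weighted")  # 2
#' @export
phenotype_points <- function(phenotype,
                             scheme = c("table8_weighted", "text_ordinal")) {
  scheme <- match.arg(scheme)
  if (inherits(phenotype, "slco_diplotype")) phenotype <- phenotype$phenotype
  map <- if (scheme == "text_ordinal")
    c(normal = 0L, decreased = 1L, poor = 2L)
  else
    c(normal = 0L, decreased = 2L, poor = 2L)
  unname(map[phenotype])
}

#' Dominant-model carrier code for a variant dosage
#'
#' Codes a dosage under the dominant framework used for ABCG2 and CYP2C9:
#' 0 for non-carriers, 1 for any variant-allele carrier (heterozygous or
#' homozygous). Missing dosages return `NA`; downstream scoring excludes
#' such subjects rather than imputing.
#'
#' @param dosage Integer vector of alt-allele dosages (0, 1, 2 or `NA`).
#' @return Integer vector of 0/1 carrier codes.
#' @examples
#' carrier_code(c(0, 1, 2, NA))
#' @export
carrier_code <- function(dosage) {
  out <- ifelse(is.na(dosage), NA_integer_, as.integer(dosage > 0))
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  out
}

#' Gene-level CYP2C9 carrier flag
#'
#' CYP2C9 contributes a single dominant carrier flag covering both
#' reduced-function alleles: 1 if either the *2 or the *3 dosage carries a
#' variant allele, 0 if both are reference. A known variant allele
#' overrides a missing co-allele; an all-reference call requires both
#' dosages to be observed (otherwise `NA`).
#'
#' @param d_star2,d_star3 Dosages (0/1/2/`NA`) of the CYP2C9*2 and *3
#'   alleles.
#' @return Integer vector of 0/1 carrier codes (`NA` when unresolvable).
#' @examples
#' cyp2c9_carrier(c(0, 1, NA, NA), c(0, 0, 2, 0))
#' @export
cyp2c9_carrier <- function(d_star2, d_star3) {
  c2 <- carrier_code(d_star2)
  c3 <- carrier_code(d_star3)
  out <- ifelse((!is.na(c2) & c2 == 1L) | (!is.na(c3) & c3 == 1L), 1L,
                ifelse(!is.na(c2) & !is.na(c3), 0L, NA_integer_))
  out
}

#' Cumulative PGx burden score and low/high category
#'
#' Sums the three components - SLCO1B1 phenotype points, the ABCG2 carrier
#' code and the CYP2C9 gene-level carrier code - into the 0-4 burden score,
#' and dichotomizes it as low (0-1) versus high (2-4). Any unresolved
#' component leaves the subject unscored (`NA` score and category).
#'
#' @param slco1b1_points Integer 0-2 (see [phenotype_points()]).
#' @param abcg2_carrier Integer 0/1 (see [carrier_code()]).
#' @param cyp2c9_carrier Integer 0/1 gene-level carrier flag.
#' @return A data.frame with `burden_score` (integer 0-4) and
#'   `burden_category` (factor low/high).
#' @examples
#' burden_score(2, 1, 1)  # maximum: 4, high
#' burden_score(0, 0, 0)  # 0, low
#' @export
burden_score <- function(slco1b1_points, abcg2_carrier, cyp2c9_carrier) {
  score <- slco1b1_points + abcg2_carrier + cyp2c9_carrier
  stopifnot(all(is.na(score) | (score >= 0 & score <= 4)))
  category <- factor(ifelse(is.na(score), NA_character_,
                            ifelse(score <= 1, "low", "high")),
                     levels = c("low", "high"))
  data.frame(burden_score = as.integer(score), burden_category = category)
}

#' Per-subject PGx profiles for a genotype table
#'
#' Applies the full genotype-to-burden pipeline to a wide genotype table:
#' SLCO1B1 diplotype calling and phenotype assignment, ABCG2 and CYP2C9
#' dominant carrier coding, the burden score under the requested scheme,
#' and the low/high category. Subjects with any unresolved component are
#' flagged unscored with an explicit exclusion reason (no imputation).
#'
#' @param genotypes A data.frame with `subject_id` and one dosage column per
#'   panel rsID (as produced by [simulate_genotypes()] or
#'   [read_genotype_vcf()]).
#' @param scheme Burden scoring scheme; see [phenotype_points()].
#' @param panel Variant panel mapping rsIDs to loci; see [pgx_panel()].
#' @return A data.frame with one row per subject: diplotype candidates,
#'   phenotype, component points, `burden_score`, `burden_category`,
#'   `scored` and `exclusion_reason`.
#' @examples
#' g <- data.frame(subject_id = "S1", rs4149056 = 1, rs2306283 = 1,
#'                 rs2231142 = 0, rs1799853 = 0, rs4986893 = 0)
#' pgx_profiles(g)
#' @export
pgx_profiles <- function(genotypes,
                         scheme = c("table8_weighted", "text_ordinal"),
                         panel = pgx_panel()) {
  scheme <- match.arg(scheme)
  need <- c("subject_id", panel$rsid)
  miss <- setdiff(need, names(genotypes))
  if (length(miss))
    stop("genotype table is missing column(s): ",
         paste(miss, collapse = ", "))
  rs <- function(locus) genotypes[[panel$rsid[panel$locus == locus]]]
  d521 <- rs("SLCO1B1_521"); d388 <- rs("SLCO1B1_388")

  # precompute the 9 dosage combinations once via the diplotype caller
  combos <- expand.grid(d521 = 0:2, d388 = 0:2)
  calls <- lapply(seq_len(nrow(combos)), function(i)
    call_slco1b1_diplotype(combos$d521[i], combos$d388[i]))
  combo_key <- paste(combos$d521, combos$d388)
  dip_str <- vapply(calls, function(x)
    paste(x$candidate_diplotypes, collapse = "|"), character(1))
  phen <- vapply(calls, `[[`, character(1), "phenotype")

  key <- paste(d521, d388)
  idx <- match(key, combo_key)   # NA when either dosage is missing
  phenotype <- ifelse(is.na(idx), "unknown", phen[idx])
  diplotypes <- ifelse(is.na(idx), "", dip_str[idx])

  slco_pts <- phenotype_points(phenotype, scheme)
  abcg2 <- carrier_code(rs("ABCG2_421"))
  cyp <- cyp2c9_carrier(rs("CYP2C9_star2"), rs("CYP2C9_star3"))
  bs <- burden_score(slco_pts, abcg2, cyp)

  reason <- character(nrow(genotypes))
  reason[is.na(slco_pts)] <- "missing SLCO1B1 genotype"
  reason[is.na(abcg2)] <- trimws(paste(reason[is.na(abcg2)],
                                       "missing ABCG2 genotype"))
  reason[is.na(cyp)] <- trimws(paste(reason[is.na(cyp)],
                                     "missing CYP2C9 genotype"))
  out <- data.frame(
    subject_id = genotypes$subject_id,
    diplotypes = diplotypes,
    phenotype = factor(phenotype,
                       levels = c("normal", "decreased", "poor", "unknown")),
    slco1b1_points = slco_pts,
    abcg2_carrier = abcg2,
    cyp2c9_carrier = cyp,
    burden_score = bs$burden_score,
    burden_category = bs$burden_category,
    scheme = scheme,
    scored = !is.na(bs$burden_score),
    exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
  n_excl <- sum(!out$scored)
  if (n_excl)
    message(n_excl, " subject(s) excluded from scoring (missing genotypes)")
  out
}
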