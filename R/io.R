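#' Write genotypes as a minimal VCF 4.2
#'
#' Emits a plain-text VCF with the GT field only and unphased `/`
#' separators, one sample column per subject, sites taken from the variant
#' panel. Dosage `NA` becomes `./.`.
#'
#' @param genotypes Wide genotype table (see [simulate_genotypes()]).
#' @param path Output file path.
#' @param panel Variant panel; see [pgx_panel()].
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(genotypes, path, panel = pgx_panel()) {
  gt_of <- function(d) ifelse(is.na(d), "./.",
                              c("0/0", "0/1", "1/1")[d + 1])
  header <- c("##fileformat=VCFv4.2",
              "##source=pgxburden",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", genotypes$subject_id),
                    collapse = "\t"))
  body <- vapply(seq_len(nrow(panel)), function(i) {
    paste(c(panel$chrom[i], panel$pos[i], panel$rsid[i], panel$ref[i],
            panel$alt[i], ".", "PASS", ".", "GT",
            gt_of(genotypes[[panel$rsid[i]]])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read panel genotypes from a VCF
#'
#' Parses a VCF with `vcfR` and extracts alt-allele dosages at the panel
#' variants. Sites are matched by rsID first, then by chrom:pos:ref:alt for
#' records whose ID column does not carry the rsID. Phased (`|`) and
#' unphased (`/`) GT values are both accepted; anything unparseable becomes
#' `NA`.
#'
#' @param path Path to a VCF file.
#' @param panel Variant panel; see [pgx_panel()].
#' @return A wide genotype data.frame (`subject_id` + one column per panel
#'   rsID).
#' @export
read_genotype_vcf <- function(path, panel = pgx_panel()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  key_file <- paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":")
  key_panel <- paste(panel$chrom, panel$pos, panel$ref, panel$alt, sep = ":")
  idx <- match(panel$rsid, fix$ID)
  idx[is.na(idx)] <- match(key_panel[is.na(idx)], key_file)
  samples <- colnames(gt)
  out <- data.frame(subject_id = samples, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(panel))) {
    if (is.na(idx[i])) {
      out[[panel$rsid[i]]] <- NA_integer_
      next
    }
    g <- gt[idx[i], ]
    alleles <- strsplit(gsub("\\|", "/", g), "/")
    out[[panel$rsid[i]]] <- vapply(alleles, function(a) {
      a <- suppressWarnings(as.integer(a))
      if (length(a) != 2 || any(is.na(a))) NA_integer_ else sum(a > 0)
    }, integer(1))
  }
  out
}

#' @rdname genotype_csv
#' @export
write_genotype_csv <- function(genotypes, path, panel = pgx_panel()) {
  long <- do.call(rbind, lapply(panel$rsid, function(rs)
    data.frame(subject_id = genotypes$subject_id, variant_id = rs,
               dosage = genotypes[[rs]], stringsAsFactors = FALSE)))
  long <- long[order(long$subject_id, long$variant_id), ]
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Genotype CSV interchange
#'
#' The long genotype CSV dialect has columns `subject_id`, `variant_id`
#' (rsID) and `dosage` (0/1/2, empty for missing).
#'
#' @param genotypes Wide genotype table.
#' @param path File path.
#' @param panel Variant panel; see [pgx_panel()].
#' @return The wide genotype data.frame (reader) or `path` (writer).
#' @name genotype_csv
#' @export
read_genotype_csv <- function(path, panel = pgx_panel()) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "variant_id", "dosage")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("genotype CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  subjects <- unique(long$subject_id)
  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (rs in panel$rsid) {
    rows <- long[long$variant_id == rs, ]
    out[[rs]] <- rows$dosage[match(subjects, rows$subject_id)]
  }
  out
}

#' Read a dispensing CSV
#'
#' Columns: `subject_id`, `date` (either an integer day index from each
#' subject's first fill, or an ISO-8601 date converted to a day index per
#' subject), `drug` (lowercase generic), `dose_mg`, `days_supplied`.
#'
#' @param path File path.
#' @return A dispensing data.frame with day-index dates.
#' @export
read_dispensing_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "date", "drug", "dose_mg", "days_supplied")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("dispensing CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(d$date)) {
    dates <- as.Date(d$date)
    if (any(is.na(dates))) stop("unparseable dispensing dates")
    first <- tapply(dates, d$subject_id, min)
    d$date <- as.numeric(dates - first[d$subject_id])
  }
  d$date <- as.numeric(d$date)
  d
}

#' Write a cohort to plain-text files
#'
#' Writes the genotypes (minimal VCF and long CSV), dispensing and clinical
#' tables (CSV), the lab series (CSV) and the truth labels (JSON) of a
#' synthetic cohort into a directory.
#'
#' @param cohort A `pgx_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pgx_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_genotype_csv(cohort$genotypes, file.path(dir, "genotypes.csv"))
  write.csv(cohort$dispensing, file.path(dir, "dispensing.csv"),
            row.names = FALSE)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  write.csv(cohort$labs, file.path(dir, "labs.csv"), row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         effect_sizes = as.list(attr(truth, "effect_sizes")),
         subjects = truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
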