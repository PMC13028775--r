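#' Configuration for an end-to-end pipeline run
#'
#' A pipeline run consumes either a simulate block (a [sim_config()]) or a
#' set of input file paths - exactly one of the two - plus the analysis
#' options: burden scoring scheme, follow-up window, and the intolerance
#' rule variant.
#'
#' @param simulate Optional [sim_config()] describing a synthetic cohort.
#' @param paths Optional named list of input files: `genotypes_vcf` or
#'   `genotypes_csv`, `dispensing_csv`, `clinical_csv`, `labs_csv`.
#' @param scheme Burden scoring scheme; see [phenotype_points()].
#' @param followup_days Follow-up window in days.
#' @param intolerance_rule `"extended"` or `"strict"`; see
#'   [intolerance_flag()].
#' @param out_dir Optional output directory; when given, every stage's
#'   table plus the association results and the run manifest are written
#'   there.
#' @param seed Integer seed recorded in the manifest (defaults to the
#'   simulate block's seed).
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            scheme = c("table8_weighted", "text_ordinal"),
                            followup_days = 365L,
                            intolerance_rule = c("extended", "strict"),
                            out_dir = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  intolerance_rule <- match.arg(intolerance_rule)
  if (is.null(simulate) && is.null(paths))
    stop("pipeline config needs either a simulate block or input paths",
         call. = FALSE)
  if (!is.null(simulate) && !is.null(paths))
    stop("supply either a simulate block or input paths, not both",
         call. = FALSE)
  if (!is.null(simulate)) {
    simulate <- validate_sim_config(simulate)
    if (is.null(seed)) seed <- simulate$seed
  }
  if (!is.null(paths)) {
    if (is.null(paths$genotypes_vcf) && is.null(paths$genotypes_csv))
      stop("paths must include genotypes_vcf or genotypes_csv",
           call. = FALSE)
    need <- c("dispensing_csv", "clinical_csv", "labs_csv")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop("paths is missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (is.null(seed)) seed <- 0L
  }
  structure(list(simulate = simulate, paths = paths, scheme = scheme,
                 followup_days = as.integer(followup_days),
                 intolerance_rule = intolerance_rule,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror [pipeline_config()]; a `simulate` mapping is
#' passed through [sim_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` document.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  doc <- read_config_document(path)
  simulate <- NULL
  if (!is.null(doc$simulate)) {
    args <- doc$simulate[intersect(names(doc$simulate),
                                   names(formals(sim_config)))]
    args <- lapply(args, function(x)
      if (is.list(x) && all(vapply(x, is.numeric, TRUE)) &&
          all(lengths(x) == 1)) unlist(x) else x)
    simulate <- do.call(sim_config, args)
  }
  pipeline_config(simulate = simulate, paths = doc$paths,
                  scheme = doc$scheme %||% "table8_weighted",
                  followup_days = doc$followup_days %||% 365L,
                  intolerance_rule = doc$intolerance_rule %||% "extended",
                  out_dir = doc$out_dir, seed = doc$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analysis dataset for a simulated cohort
#'
#' Convenience wrapper running the profiling, course-derivation and
#' outcome-phenotyping stages on a `pgx_cohort` and merging them into the
#' one-row-per-scored-subject analysis dataset, without fitting any model.
#' Useful for simulation studies that need many replicates of a single
#' fit.
#'
#' @param cohort A `pgx_cohort` from [simulate_cohort()].
#' @param scheme Burden scoring scheme.
#' @param intolerance_rule Intolerance rule variant.
#' @return The merged analysis data.frame.
#' @export
cohort_analysis_dataset <- function(cohort,
                                    scheme = c("table8_weighted",
                                               "text_ordinal"),
                                    intolerance_rule = c("extended",
                                                         "strict")) {
  stopifnot(inherits(cohort, "pgx_cohort"))
  scheme <- match.arg(scheme)
  profiles <- suppressMessages(pgx_profiles(cohort$genotypes, scheme))
  courses <- suppressMessages(derive_courses(cohort$dispensing,
                                             cohort$config$followup_days))
  flags <- suppressMessages(outcome_flags(cohort$clinical, cohort$labs,
                                          courses,
                                          match.arg(intolerance_rule)))
  build_analysis_dataset(profiles, courses, flags, cohort$clinical)
}

# merged one-row-per-scored-subject analysis dataset
build_analysis_dataset <- function(profiles, courses, flags, clinical) {
  d <- profiles[profiles$scored,
                c("subject_id", "phenotype", "burden_score",
                  "burden_category")]
  m <- match(d$subject_id, courses$subject_id)
  for (col in c("modification", "switch_count", "time_to_first_change",
                "event", "mpr", "adherent", "baseline_intensity"))
    d[[col]] <- courses[[col]][m]
  m <- match(d$subject_id, flags$subject_id)
  for (col in c("ck_max", "ck_elevated", "intolerance", "myopathy",
                "liver_injury", "nonadherent", "composite"))
    d[[col]] <- flags[[col]][m]
  m <- match(d$subject_id, clinical$subject_id)
  for (col in intersect(c("sex", "age", "diabetes", "ldl", "inhibitor"),
                        names(clinical)))
    d[[col]] <- clinical[[col]][m]
  d$baseline_intensity <- droplevels(d$baseline_intensity)
  d
}

#' Run the full burden-analysis pipeline
#'
#' Executes the stages in order - cohort acquisition (simulation or file
#' input), PGx profiling, regimen-course derivation, outcome phenotyping,
#' analysis-dataset assembly, and the association layer - and assembles a
#' reproducibility manifest (config hash, seed, per-stage row counts,
#' exclusions with reasons, number of hypothesis tests run). Any stage
#' error aborts with the stage name.
#'
#' The association layer fits: the burden-by-composite contingency odds
#' ratio, the adjusted intolerance logistic model, the adjusted
#' regimen-modification multinomial model (burden and myopathy as
#' predictors), the Cox/Kaplan-Meier persistence analysis, and descriptive
#' group-comparison tables. Adjustment covariates are age, sex, LDL,
#' diabetes, baseline statin intensity and the interacting-drug flag,
#' as available in the data.
#'
#' @param config A [pipeline_config()] (or a [sim_config()], which is
#'   wrapped automatically).
#' @return A list of class `pgx_run` with every stage's table, the
#'   association results, and `manifest`.
#' @examples
#' run <- run_pipeline(pipeline_config(simulate =
#'   sim_config(n_subjects = 300, seed = 11)))
#' run$associations$contingency
#' @export
run_pipeline <- function(config) {
  if (inherits(config, "sim_config"))
    config <- pipeline_config(simulate = config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    cohort <- stage("simulate", simulate_cohort(config$simulate))
    genotypes <- cohort$genotypes
    dispensing <- cohort$dispensing
    clinical <- cohort$clinical
    labs <- cohort$labs
    truth <- cohort$truth
  } else {
    cohort <- NULL; truth <- NULL
    genotypes <- stage("read_genotypes",
      if (!is.null(config$paths$genotypes_vcf))
        read_genotype_vcf(config$paths$genotypes_vcf)
      else read_genotype_csv(config$paths$genotypes_csv))
    dispensing <- stage("read_dispensing",
                        read_dispensing_csv(config$paths$dispensing_csv))
    clinical <- stage("read_clinical",
                      read.csv(config$paths$clinical_csv,
                               stringsAsFactors = FALSE))
    labs <- stage("read_labs",
                  read.csv(config$paths$labs_csv, stringsAsFactors = FALSE))
  }

  profiles <- stage("pgx_profiles",
                    suppressMessages(pgx_profiles(genotypes,
                                                  config$scheme)))
  courses <- stage("derive_courses",
                   suppressMessages(derive_courses(dispensing,
                                                   config$followup_days)))
  flags <- stage("outcome_flags",
                 suppressMessages(outcome_flags(clinical, labs, courses,
                                                config$intolerance_rule)))
  dataset <- stage("analysis_dataset",
                   build_analysis_dataset(profiles, courses, flags,
                                          clinical))

  covs <- intersect(c("age", "sex", "ldl", "diabetes",
                      "baseline_intensity", "inhibitor"), names(dataset))
  associations <- stage("associations", {
    tab <- table(dataset$burden_category,
                 factor(ifelse(dataset$composite, "yes", "no"),
                        levels = c("no", "yes")))
    list(
      contingency = contingency_or(as.matrix(unclass(tab))),
      logistic = fit_intolerance_logistic(dataset, covariates = covs),
      multinomial = fit_modification_multinomial(
        dataset, covariates = covs,
        predictors = c("burden_category", "myopathy")),
      persistence = fit_persistence_cox(dataset),
      group_tables = group_comparison_tables(
        dataset, "modification",
        c(age = "normal", ldl = "normal", sex = "categorical",
          phenotype = "categorical", burden_category = "categorical",
          myopathy = "categorical", liver_injury = "categorical",
          nonadherent = "categorical"))
    )
  })

  n_tests <- 4 + length(associations$multinomial) +
    length(unique(associations$group_tables$variable))
  manifest <- list(
    package = as.character(utils::packageVersion("pgxburden")),
    seed = config$seed,
    scheme = config$scheme,
    intolerance_rule = config$intolerance_rule,
    followup_days = config$followup_days,
    config_hash = hash_config(config),
    counts = list(
      subjects = nrow(genotypes),
      genotyped = nrow(genotypes),
      scored = sum(profiles$scored),
      excluded_unscored = sum(!profiles$scored),
      courses = nrow(courses),
      flagged = nrow(flags),
      analysis_rows = nrow(dataset)),
    exclusions = list(
      unscored_subjects = profiles$subject_id[!profiles$scored],
      unscored_reasons = profiles$exclusion_reason[!profiles$scored]),
    n_hypothesis_tests = n_tests
  )

  run <- structure(list(config = config, genotypes = genotypes,
                        dispensing = dispensing, clinical = clinical,
                        labs = labs, truth = truth, profiles = profiles,
                        courses = courses, flags = flags, dataset = dataset,
                        associations = associations, manifest = manifest),
                   class = "pgx_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

hash_config <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL
  jsonlite::write_json(serialize_config(cfg), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

serialize_config <- function(x) {
  if (inherits(x, "pipeline_config") || inherits(x, "sim_config"))
    x <- unclass(x)
  if (is.list(x)) lapply(x, serialize_config)
  else if (is.numeric(x) || is.character(x) || is.logical(x)) as.list(x)
  else as.character(x)
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# pgxburden seed=%d config=%s", run$manifest$seed,
                   run$manifest$config_hash)
  put <- function(df, name) {
    path <- file.path(dir, name)
    writeLines(stamp, path)
    suppressWarnings(write.table(df, path, append = TRUE, sep = ",",
                                 row.names = FALSE, qmethod = "double"))
  }
  put(run$profiles, "profiles.csv")
  put(run$courses, "courses.csv")
  put(run$flags, "outcomes.csv")
  put(run$dataset, "analysis_dataset.csv")
  put(run$associations$persistence$km, "km_curves.csv")
  put(run$associations$group_tables, "group_tables.csv")
  assoc <- c(list(run$associations$contingency, run$associations$logistic),
             run$associations$multinomial,
             list(run$associations$persistence$result))
  jsonlite::write_json(
    list(seed = run$manifest$seed,
         results = assoc_results_table(assoc),
         logrank_p = run$associations$persistence$logrank_p),
    file.path(dir, "associations.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @export
print.pgx_run <- function(x, ...) {
  cat("<pgx_run>", x$manifest$counts$subjects, "subjects;",
      x$manifest$counts$scored, "scored;",
      x$manifest$counts$analysis_rows, "analysis rows\n")
  print(x$associations$contingency)
  print(x$associations$logistic)
  print(x$associations$persistence$result)
  invisible(x)
}
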