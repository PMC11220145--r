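#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end pipeline: the locus definition, the
#' expansion-counting window, the eligibility guard, the baseline source,
#' the full-penetrance regression mode and the seed recorded in output
#' provenance headers.
#'
#' @param locus A [htt_locus()] (or arguments for it as a list).
#' @param window Expansion-counting window (>= 1).
#' @param guard Eligibility guard in CAG units (>= 0); see
#'   [allele_eligibility()].
#' @param baseline `"simulator"` (stutter baseline derived from
#'   [stutter_params()] at each allele's length) or a path to a baseline
#'   JSON ([read_baseline_json()]).
#' @param regression_mode `"table1"` or `"results_text"`; see
#'   [fit_all_categories()].
#' @param stutter [stutter_params()] used for simulator baselines.
#' @param seed Seed recorded in provenance and used for any simulation the
#'   pipeline performs.
#' @return A list of class `"cag_pipeline_config"`.
#' @export
pipeline_config <- function(locus = htt_locus(), window = 10L, guard = 2L,
                            baseline = "simulator",
                            regression_mode = c("table1", "results_text"),
                            stutter = stutter_params(), seed = 1L) {
  if (is.list(locus) && !inherits(locus, "cag_locus"))
    locus <- do.call(htt_locus, locus)
  regression_mode <- match.arg(regression_mode)
  if (window < 1) cag_error("invalid_params", "window must be >= 1")
  if (guard < 0) cag_error("invalid_params", "guard must be >= 0")
  if (is.character(baseline) && baseline != "simulator" &&
      !file.exists(baseline))
    cag_error("missing_file", sprintf("baseline file not found: %s", baseline))
  structure(list(locus = locus, window = as.integer(window),
                 guard = as.integer(guard), baseline = baseline,
                 regression_mode = regression_mode, stutter = stutter,
                 seed = as.integer(seed)),
            class = "cag_pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file; top-level keys match [pipeline_config()]
#'   arguments, with `locus` and `stutter` given as nested maps.
#' @return A `"cag_pipeline_config"`.
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!file.exists(path))
    cag_error("missing_file", sprintf("pipeline config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$stutter)) cfg$stutter <- do.call(stutter_params, cfg$stutter)
  do.call(pipeline_config, cfg)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)[setdiff(names(config), "stutter")]), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_provenance <- function(config) {
  c(config_hash = config_hash(config), seed = as.character(config$seed))
}

sample_baseline <- function(config, cag) {
  if (is.character(config$baseline) && config$baseline == "simulator")
    stutter_baseline(cag, config$stutter, window = config$window)
  else if (inherits(config$baseline, "baseline_model")) config$baseline
  else read_baseline_json(config$baseline)
}

#' Run the full analysis pipeline
#'
#' Executes genotype -> eligibility -> expansion ratio -> cohort models on
#' a set of FASTQ files. `metadata` must have columns `sample_id`, `fastq`,
#' `age_at_sampling` and `group` (plus optional `tissue`); schema
#' violations are reported naming the offending column. Outputs
#' (`profiles.tsv`, `cohort.tsv`, `regression.json`) carry `#` provenance
#' headers with the configuration hash and seed; on failure, partially
#' written outputs are removed.
#'
#' The regression report always contains all four allele-category blocks;
#' categories without enough records are marked unfitted. When exactly two
#' groups (other than `"unknown"`) are present among the intermediate-
#' allele records, the covariate-adjusted group comparison is included.
#'
#' @param metadata Sample metadata data.frame (see Details).
#' @param config A [pipeline_config()].
#' @param output_dir Directory for the output files (created if needed).
#' @return Invisibly, a list with `profiles` (data.frame), `cohort`
#'   (data.frame), `fits`, `comparison` (or NULL) and the output paths.
#' @export
run_pipeline <- function(metadata, config = pipeline_config(), output_dir) {
  required <- c("sample_id", "fastq", "age_at_sampling", "group")
  missing <- setdiff(required, names(metadata))
  if (length(missing))
    cag_error("schema", sprintf("metadata missing required column(s): %s",
                                paste(missing, collapse = ", ")))
  for (col in required) {
    bad <- which(is.na(metadata[[col]]))
    if (length(bad))
      cag_error("schema",
                sprintf("metadata column `%s` has missing values (row %d)",
                        col, bad[1]))
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  paths <- file.path(output_dir, c("profiles.tsv", "cohort.tsv",
                                   "regression.json"))
  names(paths) <- c("profiles", "cohort", "regression")
  ok <- FALSE
  on.exit(if (!ok) unlink(paths))

  prov <- pipeline_provenance(config)
  if (is.null(metadata$tissue)) metadata$tissue <- NA_character_
  profile_rows <- list()
  cohort_rows <- list()
  for (i in seq_len(nrow(metadata))) {
    sm <- metadata[i, ]
    calls <- read_fastq_calls(sm$fastq, config$locus)
    gt <- genotype_sample(calls, config$locus)
    elig <- allele_eligibility(gt, window = config$window,
                               guard = config$guard)
    roles <- if (gt$homozygous) "long" else c("short", "long")
    for (role in roles) {
      allele <- if (role == "short") gt$allele_short else gt$allele_long
      e <- elig[elig$allele_role == role, ]
      prof <- tryCatch(
        compute_expansion_ratio(gt, allele, window = config$window,
                                sample_id = sm$sample_id, tissue = sm$tissue,
                                allele_role = role),
        cagmosaic_error_undefined_ratio = function(e) NULL)
      if (is.null(prof)) next
      genuine <- is_genuine_expansion(
        prof, sample_baseline(config, allele$cag))$genuine
      profile_rows[[length(profile_rows) + 1]] <-
        profiles_table(list(prof), eligible = e$eligible, genuine = genuine)
      if (e$eligible)
        cohort_rows[[length(cohort_rows) + 1]] <- data.frame(
          sample_id = sm$sample_id, inherited_cag = allele$cag,
          age_at_sampling = sm$age_at_sampling, group = sm$group,
          category = assign_category(allele$cag), ratio = prof$ratio,
          stringsAsFactors = FALSE)
    }
  }
  profiles <- do.call(rbind, profile_rows)
  cohort <- do.call(rbind, cohort_rows)
  write_profiles_tsv(profiles, paths["profiles"], provenance = prov)
  write_cohort_tsv(cohort, paths["cohort"], provenance = prov)
  result <- fit_cohort_report(cohort, config, paths["regression"], prov)
  ok <- TRUE
  invisible(c(list(profiles = profiles, cohort = cohort, paths = paths),
              result))
}

#' Fit the cohort models of the pipeline on an existing cohort table
#'
#' The regression stage of [run_pipeline()], usable on its own against a
#' cohort TSV produced earlier (or by [simulate_scenario()]).
#'
#' @param cohort Cohort data.frame or path to a cohort TSV.
#' @param config A [pipeline_config()].
#' @param json_path Optional path for the regression report JSON.
#' @return A list with `fits` (four category blocks) and `comparison`
#'   (NULL unless exactly two non-unknown groups are present).
#' @export
run_cohort_models <- function(cohort, config = pipeline_config(),
                              json_path = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_tsv(cohort)
  fit_cohort_report(cohort, config, json_path, pipeline_provenance(config))
}

fit_cohort_report <- function(cohort, config, json_path = NULL,
                              provenance = NULL) {
  fits <- fit_all_categories(cohort, fp_mode = config$regression_mode)
  comparison <- NULL
  ia <- cohort[assign_category(cohort$inherited_cag) == "intermediate" &
                 cohort$group != "unknown", , drop = FALSE]
  if (length(unique(ia$group)) == 2 && all(table(ia$group) >= 2)) {
    comparison <- adjusted_group_comparison(ia)
    comparison$model <- NULL
  }
  if (!is.null(json_path))
    write_regression_json(fits, json_path,
                          extra = list(comparison = comparison,
                                       provenance = as.list(provenance)))
  list(fits = fits, comparison = comparison)
}
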