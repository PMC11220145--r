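category_levels <- c("normal", "intermediate", "reduced_penetrance",
                     "full_penetrance")

#' Clinical allele category from inherited CAG length
#'
#' `<= 26` normal, `27-35` intermediate, `36-39` reduced penetrance,
#' `>= 40` full penetrance. A CAG of exactly 27 is intermediate, per the
#' definition of the intermediate range.
#'
#' @param inherited_cag Integer vector of inherited pure-CAG lengths (>= 1).
#' @return A character vector of categories.
#' @examples
#' assign_category(c(26, 27, 35, 36, 39, 40))
#' @export
assign_category <- function(inherited_cag) {
  if (any(inherited_cag < 1))
    cag_error("invalid_cag", "inherited CAG lengths must be >= 1")
  as.character(cut(inherited_cag, breaks = c(0, 26.5, 35.5, 39.5, Inf),
                   labels = category_levels))
}

check_cohort_columns <- function(records, required = c("inherited_cag",
                                                       "age_at_sampling",
                                                       "ratio")) {
  missing <- setdiff(required, names(records))
  if (length(missing))
    cag_error("schema",
              sprintf("cohort records missing required column(s): %s",
                      paste(missing, collapse = ", ")))
  for (col in required) {
    if (any(is.na(records[[col]])))
      cag_error("schema", sprintf("missing values in column `%s`", col))
  }
  invisible(records)
}

#' Per-category regression of expansion ratio on CAG and age
#'
#' Ordinary least squares of the expansion ratio on inherited CAG length and
#' age at sampling (raw covariates, not centred). Main effects, their Wald
#' 95% confidence intervals, two-sided p values and R-squared are reported
#' from the main-effects model; the CAG-by-age interaction p value comes
#' from a second model augmented with the product term.
#'
#' @param records Cohort data.frame with columns `inherited_cag`,
#'   `age_at_sampling`, `ratio` (and optionally `category`).
#' @param category Optional category to subset to (records are assigned via
#'   [assign_category()] when no `category` column is present).
#' @param with_interaction Fit the augmented model for the interaction p
#'   (default `TRUE`).
#' @param min_n Minimum records required (default 10).
#' @param cag_range Optional length-2 vector restricting the CAG window
#'   (e.g. `c(40, 50)` for the full-penetrance table window).
#'
#' @return An object of class `"regression_result"`: `category`, `n`,
#'   `beta_cag`, `beta_age`, `ci95_cag`, `ci95_age`, `p_cag`, `p_age`,
#'   `r2`, `interaction_p`, and the fitted `model`.
#' @export
fit_category_regression <- function(records, category = NULL,
                                    with_interaction = TRUE, min_n = 10,
                                    cag_range = NULL) {
  check_cohort_columns(records)
  if (!is.null(category)) {
    cats <- records$category %||% assign_category(records$inherited_cag)
    records <- records[cats == category, , drop = FALSE]
  }
  if (!is.null(cag_range))
    records <- records[records$inherited_cag >= cag_range[1] &
                         records$inherited_cag <= cag_range[2], , drop = FALSE]
  n <- nrow(records)
  if (n < min_n)
    cag_error("insufficient_records",
              sprintf("%d records (%d required) for category %s", n, min_n,
                      category %||% "<all>"))
  for (term in c("inherited_cag", "age_at_sampling")) {
    if (length(unique(records[[term]])) < 2)
      cag_error("rank_deficient",
                sprintf("design is rank deficient: `%s` is constant", term))
  }
  fit <- lm(ratio ~ inherited_cag + age_at_sampling, data = records)
  if (anyNA(coef(fit)))
    cag_error("rank_deficient",
              sprintf("design is rank deficient: collinear term(s) %s",
                      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  ci <- confint(fit, level = 0.95)
  sm <- summary(fit)$coefficients
  interaction_p <- NA_real_
  if (with_interaction) {
    fit2 <- lm(ratio ~ inherited_cag * age_at_sampling, data = records)
    sm2 <- summary(fit2)$coefficients
    term <- "inherited_cag:age_at_sampling"
    if (term %in% rownames(sm2)) interaction_p <- sm2[term, "Pr(>|t|)"]
  }
  structure(
    list(category = category %||% "all", n = n,
         beta_cag = unname(coef(fit)["inherited_cag"]),
         beta_age = unname(coef(fit)["age_at_sampling"]),
         ci95_cag = unname(ci["inherited_cag", ]),
         ci95_age = unname(ci["age_at_sampling", ]),
         p_cag = unname(sm["inherited_cag", "Pr(>|t|)"]),
         p_age = unname(sm["age_at_sampling", "Pr(>|t|)"]),
         r2 = summary(fit)$r.squared,
         interaction_p = interaction_p,
         model = fit),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s (n=%d)\n", x$category, x$n))
  cat(sprintf("  CAG: beta=%.5g [%.5g, %.5g], p=%.3g\n", x$beta_cag,
              x$ci95_cag[1], x$ci95_cag[2], x$p_cag))
  cat(sprintf("  age: beta=%.5g [%.5g, %.5g], p=%.3g\n", x$beta_age,
              x$ci95_age[1], x$ci95_age[2], x$p_age))
  cat(sprintf("  R2=%.3f, interaction p=%.3g\n", x$r2, x$interaction_p))
  invisible(x)
}

#' Fit all four allele-category regressions
#'
#' Runs [fit_category_regression()] for the normal, intermediate,
#' reduced-penetrance and full-penetrance categories. The full-penetrance
#' window is configurable: `fp_mode = "table1"` restricts to 40-50 CAG (the
#' tabulated range), `fp_mode = "results_text"` uses all records >= 40 CAG.
#' Categories with too few records are reported unfitted rather than
#' dropped, so the report always carries four blocks.
#'
#' @inheritParams fit_category_regression
#' @param fp_mode `"table1"` or `"results_text"` (see Details).
#' @return A named list of `"regression_result"` objects or unfitted
#'   placeholders (`fitted = FALSE`, `reason`).
#' @export
fit_all_categories <- function(records, fp_mode = c("table1", "results_text"),
                               with_interaction = TRUE, min_n = 10) {
  fp_mode <- match.arg(fp_mode)
  check_cohort_columns(records)
  out <- lapply(category_levels, function(cat) {
    cag_range <- if (cat == "full_penetrance" && fp_mode == "table1")
      c(40, 50) else NULL
    tryCatch({
      r <- fit_category_regression(records, cat, with_interaction, min_n,
                                   cag_range)
      r$fitted <- TRUE
      r
    }, cagmosaic_error = function(e) {
      cats <- records$category %||% assign_category(records$inherited_cag)
      list(category = cat, n = sum(cats == cat), fitted = FALSE,
           reason = conditionMessage(e))
    })
  })
  setNames(out, category_levels)
}

#' Per-CAG scan of the age effect
#'
#' For each CAG length in `[min_cag, max_cag]`, fits OLS of ratio on age at
#' sampling and reports the slope and its two-sided p value. `mode =
#' "per_cag"` uses the records at exactly that length; `mode = "cumulative"`
#' uses all records with at least that length (both stratifications are
#' offered because either could underlie a "significant from CAG >= x"
#' statement). Strata with fewer than `min_n` records are marked
#' not estimable.
#'
#' @param records Cohort data.frame (see [fit_category_regression()]).
#' @param min_cag,max_cag CAG range to scan.
#' @param mode `"per_cag"` or `"cumulative"`.
#' @param min_n Minimum records per stratum (default 3).
#' @return A data.frame with columns `cag`, `mode`, `n`, `beta_age`,
#'   `p_age`, `estimable`.
#' @export
age_effect_scan <- function(records, min_cag, max_cag,
                            mode = c("per_cag", "cumulative"), min_n = 3) {
  mode <- match.arg(mode)
  check_cohort_columns(records)
  rows <- lapply(seq(min_cag, max_cag), function(L) {
    sub <- if (mode == "per_cag")
      records[records$inherited_cag == L, , drop = FALSE]
    else records[records$inherited_cag >= L, , drop = FALSE]
    n <- nrow(sub)
    if (n < min_n || length(unique(sub$age_at_sampling)) < 2)
      return(data.frame(cag = L, mode = mode, n = n, beta_age = NA_real_,
                        p_age = NA_real_, estimable = FALSE))
    fit <- lm(ratio ~ age_at_sampling, data = sub)
    sm <- summary(fit)$coefficients
    data.frame(cag = L, mode = mode, n = n,
               beta_age = unname(coef(fit)["age_at_sampling"]),
               p_age = unname(sm["age_at_sampling", "Pr(>|t|)"]),
               estimable = TRUE)
  })
  do.call(rbind, rows)
}

#' Covariate-adjusted comparison of two groups
#'
#' ANCOVA of the expansion ratio on a group indicator plus inherited CAG
#' and age at sampling. Adjusted group means are the model predictions at
#' the covariate grand means; the group p value is the two-sided Wald test
#' of the indicator.
#'
#' @param records Cohort data.frame with a `group` column containing exactly
#'   two distinct groups (records labelled `"unknown"` are dropped first).
#' @return A list with `groups`, `n` (per group), `adjusted_means` (named),
#'   `difference`, `p_group`, and the fitted `model`.
#' @export
adjusted_group_comparison <- function(records) {
  check_cohort_columns(records, c("inherited_cag", "age_at_sampling",
                                  "ratio", "group"))
  records <- records[records$group != "unknown", , drop = FALSE]
  groups <- sort(unique(records$group))
  if (length(groups) != 2)
    cag_error("schema", sprintf("exactly two groups required, found: %s",
                                paste(groups, collapse = ", ")))
  n_per <- table(factor(records$group, levels = groups))
  if (any(n_per < 2))
    cag_error("insufficient_records",
              sprintf("group %s has fewer than 2 records",
                      names(n_per)[n_per < 2]))
  records$group <- factor(records$group, levels = groups)
  fit <- lm(ratio ~ group + inherited_cag + age_at_sampling, data = records)
  at <- data.frame(group = factor(groups, levels = groups),
                   inherited_cag = mean(records$inherited_cag),
                   age_at_sampling = mean(records$age_at_sampling))
  means <- setNames(predict(fit, newdata = at), groups)
  sm <- summary(fit)$coefficients
  term <- paste0("group", groups[2])
  list(groups = groups, n = as.integer(n_per), adjusted_means = means,
       difference = unname(means[2] - means[1]),
       p_group = unname(sm[term, "Pr(>|t|)"]), model = fit)
}

#' Read / write cohort record tables
#'
#' Cohort TSVs have columns `sample_id`, `inherited_cag`,
#' `age_at_sampling`, `group`, `ratio` (plus optional `category`), with
#' `#`-prefixed provenance headers.
#'
#' @param path TSV path.
#' @return A cohort data.frame (with `category` filled in when absent).
#' @export
read_cohort_tsv <- function(path) {
  if (!file.exists(path))
    cag_error("missing_file", sprintf("cohort table not found: %s", path))
  rec <- read_tsv_with_header(path)
  check_cohort_columns(rec)
  if (is.null(rec$category)) rec$category <- assign_category(rec$inherited_cag)
  rec
}

#' @rdname read_cohort_tsv
#' @param records Cohort data.frame.
#' @param provenance Named character vector for the `#` header.
#' @export
write_cohort_tsv <- function(records, path, provenance = NULL) {
  write_tsv_with_header(records, path, provenance)
}

#' Serialise a category regression report as JSON
#'
#' @param fits Named list from [fit_all_categories()].
#' @param path Output JSON path.
#' @param extra Optional named list merged into the report (e.g. a group
#'   comparison).
#' @return `path`, invisibly.
#' @export
write_regression_json <- function(fits, path, extra = NULL) {
  blocks <- lapply(fits, function(f) {
    f$model <- NULL
    unclass(f)
  })
  report <- c(list(schema = "cagmosaic-regression/1",
                   categories = blocks), extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
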