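#' Assign the half-year season of a measurement
#'
#' Measurements are dichotomised into a summer half-year and a winter
#' half-year: May-October is the summer half in the northern hemisphere,
#' November-April in the southern (the months are inverted south of the
#' equator).
#'
#' @param month Integer month 1-12 (vectorised).
#' @param hemisphere `"north"` or `"south"` (recycled if scalar).
#' @return Factor with levels `summer_half`, `winter_half`.
#' @examples
#' assign_season(7, "north") # summer_half
#' assign_season(7, "south") # winter_half
#' @export
assign_season <- function(month, hemisphere) {
  n <- max(length(month), length(hemisphere))
  month <- rep_len(month, n)
  hemisphere <- rep_len(as.character(hemisphere), n)
  if (anyNA(month) || any(month != round(month)) || any(month < 1) ||
      any(month > 12)) {
    stop("month must be an integer in 1..12", call. = FALSE)
  }
  if (!all(hemisphere %in% c("north", "south"))) {
    stop("hemisphere must be 'north' or 'south'", call. = FALSE)
  }
  may_oct <- month >= 5 & month <= 10
  summer <- (may_oct & hemisphere == "north") |
            (!may_oct & hemisphere == "south")
  factor(ifelse(summer, "summer_half", "winter_half"),
         levels = c("summer_half", "winter_half"))
}

#' Two-year age bands
#'
#' Bands used for descriptive tables and the age-group regressions:
#' 2-4 (merged), then 5-6, 7-8, ..., 17-18.
#'
#' @param age_years Decimal ages.
#' @return Factor of band labels; ages outside \[2, 19) map to `NA`.
#' @export
age_group_bands <- function(age_years) {
  cut(age_years, breaks = c(2, 5, 7, 9, 11, 13, 15, 17, 19),
      right = FALSE,
      labels = c("2-4", "5-6", "7-8", "9-10", "11-12", "13-14", "15-16",
                 "17-18"))
}

#' Assemble participant-timepoint analysis records
#'
#' Joins reduced activity summaries to demographics and derives the analysis
#' covariates: 2-year age band, weight status (IOTF category and
#' sex-by-ageband standardised BMI) and half-year season. Only timepoints
#' meeting the valid-day inclusion rule are kept, and the participant id is
#' carried as the cluster id (all measurement waves of one child form one
#' cluster).
#'
#' @param timepoints Timepoint summary tibble (from [reduce_cohort()] or
#'   [summarize_timepoint()]).
#' @param demographics One row per participant-timepoint with columns
#'   `participant_id`, `timepoint_id`, `sex`, `age_years`, `height_m`,
#'   `weight_kg`, `study_id`, `country`, `hemisphere`, `measurement_month`.
#' @param classify_weight Compute BMI/IOTF columns (needs valid
#'   height/weight/age); set `FALSE` for outcomes-only analyses.
#' @return Tibble of analysis records, one row per included
#'   participant-timepoint.
#' @export
build_analysis_records <- function(timepoints, demographics,
                                   classify_weight = TRUE) {
  need <- c("participant_id", "timepoint_id", "sex", "age_years", "study_id",
            "country", "hemisphere", "measurement_month")
  miss <- setdiff(need, names(demographics))
  if (length(miss)) {
    stop("demographics lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tp <- timepoints[timepoints$included, , drop = FALSE]
  rec <- merge(tp, demographics, by = c("participant_id", "timepoint_id"))
  rec <- tibble::as_tibble(rec)
  rec$age_group <- age_group_bands(rec$age_years)
  rec$season <- assign_season(rec$measurement_month, rec$hemisphere)
  rec$cluster_id <- rec$participant_id
  if (classify_weight) {
    rec$bmi <- compute_bmi(rec$weight_kg, rec$height_m)
    rec$weight_category <- classify_iotf(rec$bmi, rec$age_years, rec$sex)
    rec$overweight_obese <- rec$weight_category != "normal"
    rec$bmi_z <- standardize_bmi(rec$bmi, rec$sex, rec$age_years)
  }
  rec
}

#' Standardise an outcome within each country
#'
#' Replaces the outcome by its within-country z-score (population SD), so
#' relative within-country effects can be compared across countries with
#' different absolute activity levels. Appends a column `<outcome>_z`.
#'
#' @param records Analysis record tibble with a `country` column.
#' @param outcome Name of the outcome column, default `"mean_cpm"`.
#' @return `records` with the added z-scored column.
#' @export
standardize_within_country <- function(records, outcome = "mean_cpm") {
  if (!outcome %in% names(records)) {
    stop("no column '", outcome, "' in records", call. = FALSE)
  }
  x <- records[[outcome]]
  z <- numeric(length(x))
  for (ctry in unique(records$country)) {
    idx <- records$country == ctry
    if (sum(idx) < 2L) {
      stop("country '", ctry, "' has fewer than 2 records; cannot ",
           "standardise", call. = FALSE)
    }
    m <- mean(x[idx])
    s <- sqrt(mean((x[idx] - m)^2))
    if (s == 0) stop("country '", ctry, "' has zero outcome SD",
                     call. = FALSE)
    z[idx] <- (x[idx] - m) / s
  }
  records[[paste0(outcome, "_z")]] <- z
  records
}

# Build the model formula for fit_adjusted_model. Terms whose covariate has
# fewer than 2 observed levels are dropped (a constant regressor is
# inestimable); study and season enter as adjustment factors whenever they
# vary.
build_model_formula <- function(records, outcome, formula_spec) {
  nlev <- function(v) length(unique(v[!is.na(v)]))
  has_sex <- nlev(records$sex) >= 2L
  has_age <- nlev(records$age_group) >= 2L
  has_wt2 <- "overweight_obese" %in% names(records) &&
    nlev(records$overweight_obese) >= 2L
  has_wt3 <- "weight_category" %in% names(records) &&
    nlev(records$weight_category) >= 2L

  terms <- switch(formula_spec,
    main = c(if (has_sex) "sex", if (has_age) "age_group"),
    age_sex_interaction =
      if (has_sex && has_age) "age_group * sex"
      else c(if (has_sex) "sex", if (has_age) "age_group"),
    age_sex_weight_interaction = {
      if (!has_wt2) stop("weight status does not vary; cannot fit the ",
                         "three-way interaction model", call. = FALSE)
      base <- if (has_sex && has_age) "age_group * sex * overweight_obese"
              else paste(c(if (has_sex) "sex", if (has_age) "age_group",
                           "overweight_obese"), collapse = " + ")
      base
    },
    weight_dose_response = {
      if (!has_wt3) stop("weight category does not vary; cannot fit the ",
                         "dose-response model", call. = FALSE)
      c(if (has_sex) "sex", if (has_age) "age_group", "weight_category")
    },
    stop("unknown formula_spec: ", formula_spec, call. = FALSE))

  adj <- c(if (nlev(records$study_id) >= 2L) "study_id",
           if (nlev(records$season) >= 2L) "season")
  rhs <- paste(c(terms, adj), collapse = " + ")
  if (rhs == "") rhs <- "1"
  stats::as.formula(paste(outcome, "~", rhs))
}

#' Fit an adjusted linear model with cluster-robust standard errors
#'
#' Ordinary least squares with study and season as adjustment factors
#' (included whenever they vary in the sample) and sandwich cluster-robust
#' standard errors, clustering all measurement waves of a participant
#' (`cluster_id`). The small-sample correction is the CR1 convention with
#' cluster-count factor G/(G-1) and residual factor (n-1)/(n-k); with
#' singleton clusters this reduces to the classical HC1
#' heteroskedasticity-robust estimator.
#'
#' `formula_spec` selects the model structure:
#' * `"main"`: additive sex and age-group effects;
#' * `"age_sex_interaction"`: full age-by-sex cross, so every age-sex cell is
#'   expressed relative to the reference cell (default boys aged 5-6);
#' * `"age_sex_weight_interaction"`: three-way cross of age, sex and the
#'   binary normal vs overweight/obese indicator;
#' * `"weight_dose_response"`: additive model with the 3-level weight
#'   category.
#'
#' @param records Analysis record tibble (see [build_analysis_records()]).
#' @param outcome Outcome column name, default `"mean_cpm"`.
#' @param formula_spec Model structure, see Details.
#' @param reference Named list giving the reference levels, default
#'   `list(sex = "male", age_group = "5-6")`.
#' @return An object of class `regression_result`: `coefficients` tibble
#'   (`term`, `estimate`, `se`, `ci_low`, `ci_high`) with 95% CIs as
#'   estimate +/- 1.96 SE, `n`, `n_clusters`, the fitted `model` and the
#'   robust `vcov`.
#' @export
fit_adjusted_model <- function(records, outcome = "mean_cpm",
                               formula_spec = c("main",
                                                "age_sex_interaction",
                                                "age_sex_weight_interaction",
                                                "weight_dose_response"),
                               reference = list(sex = "male",
                                                age_group = "5-6")) {
  formula_spec <- match.arg(formula_spec)
  if (anyNA(records[[outcome]])) {
    stop("outcome '", outcome, "' contains missing values", call. = FALSE)
  }
  records <- as.data.frame(records)
  for (v in c("sex", "age_group", "study_id", "season", "weight_category")) {
    if (v %in% names(records)) records[[v]] <- droplevels(factor(records[[v]]))
  }
  for (v in names(reference)) {
    if (v %in% names(records) && reference[[v]] %in% levels(records[[v]])) {
      records[[v]] <- stats::relevel(records[[v]], ref = reference[[v]])
    }
  }
  clusters <- records$cluster_id
  n_clusters <- length(unique(clusters))
  if (n_clusters < 2L) {
    stop("need at least 2 clusters for cluster-robust inference",
         call. = FALSE)
  }

  fml <- build_model_formula(records, outcome, formula_spec)
  fit <- stats::lm(fml, data = records)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular design; aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  V <- sandwich::vcovCL(fit, cluster = clusters, type = "HC1")
  se <- sqrt(diag(V))
  structure(
    list(coefficients = tibble::tibble(
           term = names(cf), estimate = unname(cf), se = unname(se),
           ci_low = unname(cf - 1.96 * se), ci_high = unname(cf + 1.96 * se)),
         n = stats::nobs(fit),
         n_clusters = n_clusters,
         formula = deparse(fml),
         formula_spec = formula_spec,
         model = fit,
         vcov = V),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, digits = 3, ...) {
  cat(sprintf("<regression_result> %s  (n = %d, clusters = %d)\n",
              x$formula, x$n, x$n_clusters))
  print(as.data.frame(lapply(x$coefficients, function(c)
    if (is.numeric(c)) round(c, digits) else c)), row.names = FALSE)
  invisible(x)
}

#' Extract the male-female contrast from a regression result
#'
#' Returns the boys-minus-girls difference in the outcome with its SE,
#' regardless of which sex was the reference level.
#'
#' @param result A `regression_result` from [fit_adjusted_model()].
#' @return Named list `estimate`, `se`.
#' @export
sex_gap <- function(result) {
  cf <- result$coefficients
  if ("sexmale" %in% cf$term) {
    i <- match("sexmale", cf$term)
    list(estimate = cf$estimate[i], se = cf$se[i])
  } else if ("sexfemale" %in% cf$term) {
    i <- match("sexfemale", cf$term)
    list(estimate = -cf$estimate[i], se = cf$se[i])
  } else {
    stop("no sex term in the fitted model", call. = FALSE)
  }
}

#' Fit a linear age trend in activity with clustered errors
#'
#' Regresses the outcome on continuous age (plus study and season adjusters
#' when they vary), with participant-clustered robust SEs. Used to express
#' the average per-year difference in activity, either absolutely (cpm per
#' year) or relative to the model-predicted level at a reference age via
#' [annual_pct_change()].
#'
#' @inheritParams fit_adjusted_model
#' @return A `regression_result` whose `age_years` term is the per-year
#'   difference in the outcome.
#' @export
fit_age_trend <- function(records, outcome = "mean_cpm") {
  if (anyNA(records[[outcome]])) {
    stop("outcome '", outcome, "' contains missing values", call. = FALSE)
  }
  records <- as.data.frame(records)
  for (v in c("study_id", "season")) {
    if (v %in% names(records)) records[[v]] <- droplevels(factor(records[[v]]))
  }
  clusters <- records$cluster_id
  if (length(unique(clusters)) < 2L) {
    stop("need at least 2 clusters", call. = FALSE)
  }
  nlev <- function(v) length(unique(v[!is.na(v)]))
  adj <- c("age_years",
           if ("study_id" %in% names(records) &&
               nlev(records$study_id) >= 2L) "study_id",
           if ("season" %in% names(records) &&
               nlev(records$season) >= 2L) "season")
  fml <- stats::as.formula(paste(outcome, "~", paste(adj, collapse = " + ")))
  fit <- stats::lm(fml, data = records)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular design; aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  V <- sandwich::vcovCL(fit, cluster = clusters, type = "HC1")
  se <- sqrt(diag(V))
  structure(
    list(coefficients = tibble::tibble(
           term = names(cf), estimate = unname(cf), se = unname(se),
           ci_low = unname(cf - 1.96 * se), ci_high = unname(cf + 1.96 * se)),
         n = stats::nobs(fit),
         n_clusters = length(unique(clusters)),
         formula = deparse(fml),
         formula_spec = "age_trend",
         model = fit,
         vcov = V),
    class = "regression_result")
}

#' Annual percentage change in activity relative to a reference age
#'
#' Converts the per-year coefficient of an age-trend fit into a percentage of
#' the model-predicted outcome at `reference_age` (the youngest modelled age
#' by convention, so "percent per year relative to the age-5 level"; any
#' reference age, e.g. 12, can be requested). Positive values denote decline.
#'
#' @param trend A `regression_result` from [fit_age_trend()].
#' @param reference_age Age at which the reference level is predicted.
#' @return Named list: `pct_per_year` (decline positive), `cpm_per_year`
#'   (signed coefficient) and `reference_level`.
#' @export
annual_pct_change <- function(trend, reference_age = 5) {
  cf <- trend$coefficients
  slope <- cf$estimate[match("age_years", cf$term)]
  if (is.na(slope)) stop("no age_years term in fit", call. = FALSE)
  # predicted outcome at the reference age, other covariates at reference
  nd <- data.frame(age_years = reference_age)
  mf <- trend$model$model
  for (v in setdiff(names(mf)[-1L], "age_years")) {
    nd[[v]] <- factor(levels(mf[[v]])[1L], levels = levels(mf[[v]]))
  }
  ref_level <- as.numeric(stats::predict(trend$model, newdata = nd))
  list(pct_per_year = -100 * slope / ref_level,
       cpm_per_year = slope,
       reference_level = ref_level)
}

#' Per-country longitudinal age slopes of standardised activity
#'
#' Restricts the records to participants measured at two or more timepoints
#' spanning at least `min_span_years`, and to countries whose retained
#' longitudinal data cover an age range of at least `min_country_span_years`.
#' Within each such country, fits the standardised outcome on continuous age
#' (adjusted for sex, and season where it varies) with participant-clustered
#' robust SEs. The per-country slopes are suitable input for
#' [meta_analyze()].
#'
#' @param records Analysis records carrying a standardised outcome column
#'   (see [standardize_within_country()]).
#' @param outcome Standardised outcome column, default `"mean_cpm_z"`.
#' @param min_span_years Minimum within-participant age span, default 1.
#' @param min_country_span_years Minimum within-country age span of the
#'   retained data, default 4.
#' @return Tibble with one row per country: `country`, `estimate` (SD per
#'   year), `se`, `n`, `n_participants`.
#' @export
longitudinal_age_slope <- function(records, outcome = "mean_cpm_z",
                                   min_span_years = 1,
                                   min_country_span_years = 4) {
  sp <- tapply(records$age_years, records$participant_id,
               function(a) max(a) - min(a))
  ntp <- tapply(records$timepoint_id, records$participant_id,
                function(t) length(unique(t)))
  keep_ids <- names(sp)[sp >= min_span_years & ntp >= 2L]
  rec <- records[records$participant_id %in% keep_ids, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop("no participants with repeated measurements spanning >= ",
         min_span_years, " year(s)", call. = FALSE)
  }
  rows <- list()
  for (ctry in unique(rec$country)) {
    rc <- rec[rec$country == ctry, , drop = FALSE]
    if (max(rc$age_years) - min(rc$age_years) < min_country_span_years) next
    rc <- as.data.frame(rc)
    nlev <- function(v) length(unique(v))
    adj <- c("age_years", if (nlev(rc$sex) >= 2L) "sex",
             if (nlev(rc$season) >= 2L) "season")
    fml <- stats::as.formula(paste(outcome, "~",
                                   paste(adj, collapse = " + ")))
    fit <- stats::lm(fml, data = rc)
    V <- sandwich::vcovCL(fit, cluster = rc$cluster_id, type = "HC1")
    i <- match("age_years", names(stats::coef(fit)))
    rows[[ctry]] <- tibble::tibble(
      country = ctry,
      estimate = unname(stats::coef(fit)[i]),
      se = sqrt(diag(V))[i],
      n = stats::nobs(fit),
      n_participants = length(unique(rc$participant_id)))
  }
  if (!length(rows)) {
    stop("no country retains >= ", min_country_span_years,
         " years of longitudinal age span", call. = FALSE)
  }
  tibble::as_tibble(data.table::rbindlist(rows))
}
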