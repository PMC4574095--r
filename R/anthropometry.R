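#' Body mass index
#'
#' @param weight_kg Weight in kilograms, positive.
#' @param height_m Height in metres, positive.
#' @return `weight_kg / height_m^2` (kg/m^2).
#' @examples
#' compute_bmi(50, 1.60)
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (anyNA(weight_kg) || anyNA(height_m) || any(weight_kg <= 0) ||
      any(height_m <= 0)) {
    stop("weight and height must be positive and non-missing", call. = FALSE)
  }
  weight_kg / height_m^2
}

the_iotf_env <- new.env(parent = emptyenv())

#' IOTF-convention BMI cut-off table
#'
#' Age- and sex-specific BMI thresholds for child overweight and obesity in
#' the IOTF convention: half-year rows from age 2 to 18, with the age-18 row
#' anchored at the adult equivalents of BMI 25 (overweight) and 30 (obese).
#' The table bundled with the package (`extdata/iotf_cutoffs.csv`) is this
#' package's transcription of the published cut-offs; ship your own CSV with
#' the same columns (`sex`, `age_years`, `bmi_overweight`, `bmi_obese`) to
#' use a different reference.
#'
#' @param path Optional path to an alternative cut-off CSV.
#' @return A data frame with columns `sex`, `age_years`, `bmi_overweight`,
#'   `bmi_obese`.
#' @export
iotf_cutoffs <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the_iotf_env$table)) return(the_iotf_env$table)
    path <- system.file("extdata", "iotf_cutoffs.csv",
                        package = "accelcohort", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    the_iotf_env$table <- tab
    return(tab)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Classify weight status with IOTF cut-offs
#'
#' A participant is obese when BMI is at or above the obesity cut-off for
#' their sex and age, otherwise overweight when at or above the overweight
#' cut-off, otherwise normal weight (categories are mutually exclusive).
#' Cut-offs are linearly interpolated between the half-year table rows; ages
#' above the top row (18) use the adult-equivalent 25/30 row. Classification
#' is supported for ages 2 to 19.
#'
#' @param bmi BMI in kg/m^2.
#' @param age_years Decimal age, within \[2, 19\].
#' @param sex `"male"` or `"female"` (recycled if scalar).
#' @param cutoffs Cut-off table, see [iotf_cutoffs()].
#' @return Factor with levels `normal`, `overweight`, `obese`.
#' @export
classify_iotf <- function(bmi, age_years, sex, cutoffs = iotf_cutoffs()) {
  n <- max(length(bmi), length(age_years), length(sex))
  bmi <- rep_len(bmi, n)
  age_years <- rep_len(age_years, n)
  sex <- rep_len(as.character(sex), n)
  if (anyNA(age_years) || any(age_years < 2) || any(age_years > 19)) {
    stop("age_years must lie within [2, 19] for IOTF classification",
         call. = FALSE)
  }
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  a <- pmin(age_years, max(cutoffs$age_years))
  ow <- ob <- numeric(n)
  for (s in c("male", "female")) {
    idx <- sex == s
    if (!any(idx)) next
    tab <- cutoffs[cutoffs$sex == s, ]
    tab <- tab[order(tab$age_years), ]
    ow[idx] <- stats::approx(tab$age_years, tab$bmi_overweight, a[idx],
                             rule = 2)$y
    ob[idx] <- stats::approx(tab$age_years, tab$bmi_obese, a[idx],
                             rule = 2)$y
  }
  cat3 <- ifelse(bmi >= ob, "obese", ifelse(bmi >= ow, "overweight", "normal"))
  factor(cat3, levels = c("normal", "overweight", "obese"))
}

#' Standardise BMI within sex by 1-year age band
#'
#' Computes a z-score of BMI within each sex-by-ageband cell of the analysis
#' sample, where bands are `floor(age_years)`. The cell SD is the population
#' (divide-by-n) standard deviation, so a two-member cell maps to exactly
#' (-1, +1). Cells with fewer than 2 members or zero spread cannot be
#' standardised and yield `0` with a warning.
#'
#' @param bmi BMI values.
#' @param sex `"male"`/`"female"` per observation.
#' @param age_years Decimal ages per observation.
#' @return Numeric vector of z-scores, aligned with the input.
#' @export
standardize_bmi <- function(bmi, sex, age_years) {
  n <- length(bmi)
  if (n == 0L) stop("empty sample", call. = FALSE)
  stopifnot(length(sex) == n, length(age_years) == n)
  band <- floor(age_years)
  key <- paste(sex, band, sep = "|")
  z <- numeric(n)
  degenerate <- character(0)
  for (k in unique(key)) {
    idx <- key == k
    x <- bmi[idx]
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (length(x) < 2L || s == 0) {
      z[idx] <- 0
      degenerate <- c(degenerate, k)
    } else {
      z[idx] <- (x - m) / s
    }
  }
  if (length(degenerate)) {
    warning("cells with < 2 members or zero SD set to z = 0: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  z
}
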