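test_that("season assignment inverts between hemispheres", {
  expect_equal(as.character(assign_season(7, "north")), "summer_half")
  expect_equal(as.character(assign_season(7, "south")), "winter_half")
  expect_equal(as.character(assign_season(11, "north")), "winter_half")
  expect_equal(as.character(assign_season(c(5, 10, 4), "north")),
               c("summer_half", "summer_half", "winter_half"))
  expect_equal(as.character(assign_season(c(5, 10, 4), "south")),
               c("winter_half", "winter_half", "summer_half"))
  expect_error(assign_season(13, "north"), "1..12")
  expect_error(assign_season(6, "equator"), "hemisphere")
})

test_that("age bands follow the 2-year descriptive grouping", {
  expect_equal(as.character(age_group_bands(c(2.8, 5, 6.9, 9.5, 18.4))),
               c("2-4", "5-6", "5-6", "9-10", "17-18"))
  expect_true(is.na(age_group_bands(1.5)))
})

test_that("within-country standardisation is exact and shift-invariant", {
  rec <- tibble::tibble(country = c("a", "a"), mean_cpm = c(600, 800))
  z <- standardize_within_country(rec)$mean_cpm_z
  expect_equal(z, c(-1, 1))

  set.seed(44)
  rec2 <- tibble::tibble(country = rep(c("a", "b"), each = 30),
                         mean_cpm = c(rnorm(30, 700, 90), rnorm(30, 500, 40)))
  z2 <- standardize_within_country(rec2)$mean_cpm_z
  for (ctry in c("a", "b")) {
    zs <- z2[rec2$country == ctry]
    expect_equal(mean(zs), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(zs^2)), 1, tolerance = 1e-9)
  }
  # shifting one country's raw outcome leaves all z-scores unchanged
  rec3 <- rec2
  rec3$mean_cpm[rec3$country == "a"] <- rec3$mean_cpm[rec3$country == "a"] + 100
  expect_equal(standardize_within_country(rec3)$mean_cpm_z, z2)

  expect_error(standardize_within_country(
    tibble::tibble(country = c("a", "b", "b"), mean_cpm = 1:3)),
    "fewer than 2")
})

test_that("an additive sex effect is recovered with near-classical SEs", {
  rec <- make_records(n_per_cell = 60, sex_effect = 25, noise_sd = 10)
  fit <- fit_adjusted_model(rec, formula_spec = "main")
  sg <- sex_gap(fit)
  expect_equal(sg$estimate, 25, tolerance = 0.15) # ~3 MC SEs
  # independent records: cluster-robust equals classical HC1 exactly
  se_hc1 <- sqrt(diag(sandwich::vcovHC(fit$model, type = "HC1")))
  expect_equal(sqrt(diag(fit$vcov)), se_hc1, tolerance = 1e-8)
})

test_that("cluster-robust SEs match the longhand CR1 oracle", {
  rec <- make_records(n_per_cell = 20, sex_effect = 10, noise_sd = 15)
  # fold records into 40 clusters so clusters really repeat
  rec$cluster_id <- rep_len(sprintf("c%02d", 1:40), nrow(rec))
  fit <- fit_adjusted_model(rec, formula_spec = "main")
  want <- cr1_se_oracle(fit$model, rec$cluster_id)
  expect_equal(sqrt(diag(fit$vcov)), want, tolerance = 1e-10)
  expect_equal(fit$n_clusters, 40L)
  # confidence intervals are estimate +/- 1.96 SE
  cf <- fit$coefficients
  expect_equal(cf$ci_high - cf$estimate, 1.96 * cf$se)
})

test_that("duplicating records within clusters does not shrink robust SEs", {
  rec <- make_records(n_per_cell = 30, sex_effect = 12, noise_sd = 8)
  fit1 <- fit_adjusted_model(rec, formula_spec = "main")
  dup <- rbind(rec, rec) # same cluster ids, twice the rows
  fit2 <- fit_adjusted_model(dup, formula_spec = "main")
  i <- match(fit1$coefficients$term, fit2$coefficients$term)
  expect_equal(fit2$coefficients$estimate[i], fit1$coefficients$estimate,
               tolerance = 1e-10)
  # naive iid errors would shrink by sqrt(2); clustered ones must not
  ratio <- fit2$coefficients$se[i] / fit1$coefficients$se
  expect_true(all(ratio > 0.95))
})

test_that("zero-noise records recover injected effects exactly", {
  rec <- make_records(n_per_cell = 10, sex_effect = 40, noise_sd = 0)
  rec$mean_cpm <- 500 + 40 * (rec$sex == "male") - 15 * (rec$age_group == "7-8")
  fit <- fit_adjusted_model(rec, formula_spec = "main",
                            reference = list(sex = "female",
                                             age_group = "5-6"))
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "sexmale"], 40, tolerance = 1e-9)
  expect_equal(cf$estimate[cf$term == "age_group7-8"], -15, tolerance = 1e-9)
})

test_that("degenerate designs fail loudly", {
  rec <- make_records(n_per_cell = 10)
  rec$cluster_id <- "only_one"
  expect_error(fit_adjusted_model(rec), "at least 2 clusters")

  rec2 <- make_records(n_per_cell = 10)
  # a covariate perfectly collinear with sex produces an aliased term
  rec2$study_id <- ifelse(rec2$sex == "male", "s1", "s2")
  expect_error(fit_adjusted_model(rec2, formula_spec = "main"), "aliased")
})

test_that("the age-sex interaction model is relative to the reference cell", {
  rec <- make_records(n_per_cell = 15, sex_effect = 0, noise_sd = 0)
  rec$mean_cpm <- 700 - 30 * (rec$age_group == "7-8") -
    50 * (rec$sex == "female") -
    20 * (rec$age_group == "7-8" & rec$sex == "female")
  fit <- fit_adjusted_model(rec, formula_spec = "age_sex_interaction")
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "(Intercept)"], 700, tolerance = 1e-9)
  expect_equal(cf$estimate[cf$term == "sexfemale"], -50, tolerance = 1e-9)
  expect_equal(cf$estimate[cf$term == "age_group7-8:sexfemale"], -20,
               tolerance = 1e-9)
})

test_that("sex_gap reads the contrast under either reference coding", {
  rec <- make_records(n_per_cell = 20, sex_effect = 18, noise_sd = 0)
  f1 <- fit_adjusted_model(rec, formula_spec = "main",
                           reference = list(sex = "male"))
  f2 <- fit_adjusted_model(rec, formula_spec = "main",
                           reference = list(sex = "female"))
  expect_equal(sex_gap(f1)$estimate, 18, tolerance = 1e-9)
  expect_equal(sex_gap(f2)$estimate, 18, tolerance = 1e-9)
})

test_that("the age trend converts to percent per year at a reference age", {
  # deterministic linear decline: 31 cpm/yr from 738 at age 5
  ages <- rep(seq(5, 15, by = 0.5), each = 4)
  rec <- tibble::tibble(
    participant_id = sprintf("p%03d", seq_along(ages)),
    mean_cpm = 738 - 31 * (ages - 5),
    age_years = ages,
    study_id = "s1",
    season = factor("summer_half"),
    cluster_id = sprintf("p%03d", seq_along(ages)))
  trend <- fit_age_trend(rec)
  pc5 <- annual_pct_change(trend, 5)
  expect_equal(pc5$cpm_per_year, -31, tolerance = 1e-9)
  expect_equal(pc5$pct_per_year, 100 * 31 / 738, tolerance = 1e-9)
  # relative to age 12 the same decrement is a larger percentage
  pc12 <- annual_pct_change(trend, 12)
  expect_equal(pc12$pct_per_year, 100 * 31 / (738 - 31 * 7), tolerance = 1e-9)
})

test_that("longitudinal slopes are estimated per country and pooled", {
  set.seed(66)
  # two countries, each with repeated measures declining 0.1 SD/yr
  mk <- function(ctry, n = 200, slope = -0.1) {
    age1 <- runif(n, 6, 12)
    tibble::tibble(
      participant_id = paste0(ctry, sprintf("p%03d", rep(seq_len(n), 2))),
      timepoint_id = rep(c("t1", "t2"), each = n),
      mean_cpm_z = slope * (c(age1, age1 + 3) - 9) +
        rep(rnorm(n, 0, 0.3), 2) + rnorm(2 * n, 0, 0.1),
      age_years = c(age1, age1 + 3),
      sex = rep(sample(c("male", "female"), n, TRUE), 2),
      season = factor(rep("summer_half", 2 * n)),
      country = ctry,
      cluster_id = paste0(ctry, sprintf("p%03d", rep(seq_len(n), 2))))
  }
  rec <- rbind(mk("A"), mk("B"))
  sl <- longitudinal_age_slope(rec)
  expect_equal(nrow(sl), 2L)
  expect_true(all(abs(sl$estimate + 0.1) < 0.03)) # ~4 MC SEs
  pooled <- meta_analyze(sl$estimate, sl$se, sl$country)
  expect_lt(pooled$ci_high, 0) # decline clearly detected

  # a country whose retained data span < 4 years of age is dropped even
  # though every participant spans >= 1 year
  shrt <- mk("C")
  a1 <- runif(200, 8, 8.5)
  shrt$age_years <- c(a1, a1 + 3)
  expect_error(longitudinal_age_slope(shrt), "4 years")

  # participants measured once cannot contribute
  once <- mk("A")[1:100, ]
  once$timepoint_id <- "t1"
  expect_error(longitudinal_age_slope(once), "repeated")
})
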