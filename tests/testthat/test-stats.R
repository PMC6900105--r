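sim_season_rows <- function(n_ind = 60, effect = 5, sd_ind = 2, sd_res = 2,
                            seed = 1) {
  set.seed(seed)
  b <- rnorm(n_ind, 0, sd_ind)
  data.frame(individual = rep(sprintf("I%02d", 1:n_ind), each = 2),
             season = rep(c("southward", "northward"), n_ind),
             flight_time_h = 30 + rep(b, each = 2) +
               effect * rep(c(0, 1), n_ind) + rnorm(2 * n_ind, 0, sd_res))
}

test_that("parametric bootstrap p-values are reproducible and guarded", {
  rows <- sim_season_rows(n_ind = 20, effect = 3, seed = 2)
  rows$individual <- factor(rows$individual)
  rows$season <- factor(rows$season, levels = c("southward", "northward"))
  full <- lme4::lmer(flight_time_h ~ season + (1 | individual), rows,
                     REML = FALSE)
  null <- lme4::lmer(flight_time_h ~ 1 + (1 | individual), rows, REML = FALSE)

  expect_error(parametric_bootstrap_p(full, null, B = 0), "B must be >= 1")
  expect_error(parametric_bootstrap_p(null, full, B = 19), "not nested")

  p1 <- parametric_bootstrap_p(full, null, B = 49, seed = 11)
  p2 <- parametric_bootstrap_p(full, null, B = 49, seed = 11)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_gt(as.numeric(p1), 0)
  expect_lte(as.numeric(p1), 1)

  # invariant to relabelling of individuals
  rows2 <- rows
  rows2$individual <- factor(rows$individual,
                             labels = sample(levels(rows$individual)))
  full2 <- lme4::lmer(flight_time_h ~ season + (1 | individual), rows2,
                      REML = FALSE)
  null2 <- lme4::lmer(flight_time_h ~ 1 + (1 | individual), rows2,
                      REML = FALSE)
  p3 <- parametric_bootstrap_p(full2, null2, B = 49, seed = 11)
  expect_equal(as.numeric(p1), as.numeric(p3))
})

test_that("the seasonal LMM recovers a known contrast", {
  rows <- sim_season_rows(n_ind = 60, effect = 5, seed = 1)
  fit <- fit_season_lmm(rows, B = 99, seed = 1)
  est <- fit$coefficients[fit$coefficients$term == "seasonnorthward", ]
  expect_lt(abs(est$estimate - 5), 3 * est$se)
  expect_lt(fit$boot$p, 0.05)

  # null effect: estimate within 3 SE of zero
  rows0 <- sim_season_rows(n_ind = 60, effect = 0, seed = 4)
  fit0 <- fit_season_lmm(rows0, B = 19, seed = 1)
  est0 <- fit0$coefficients[fit0$coefficients$term == "seasonnorthward", ]
  expect_lt(abs(est0$estimate), 3 * est0$se)

  expect_error(fit_season_lmm(rows[rows$season == "northward", ], B = 9),
               "both seasons")
})

test_that("with one observation per individual the LMM contrast equals the OLS group difference", {
  set.seed(5)
  rows <- data.frame(individual = sprintf("I%02d", 1:40),
                     season = rep(c("southward", "northward"), 20),
                     flight_time_h = rnorm(40, 32, 3))
  fit <- suppressMessages(fit_season_lmm(rows, B = 9, seed = 1))
  ols <- mean(rows$flight_time_h[rows$season == "northward"]) -
    mean(rows$flight_time_h[rows$season == "southward"])
  est <- fit$coefficients$estimate[fit$coefficients$term == "seasonnorthward"]
  expect_equal(est, ols, tolerance = 1e-6)
})

test_that("the mortality GLMM recovers the flight-time slope and reports covariates", {
  rows <- generate_mortality_cohort(n_crossings = 400, slope = 0.25, seed = 1)
  fit <- fit_mortality_glmm(rows, B = 19, seed = 1, test = "flight_time_h")
  est <- fit$coefficients[fit$coefficients$term == "flight_time_h", ]
  expect_lt(abs(est$estimate - 0.25), 3 * est$se)
  expect_false(is.na(est$estimate_std))        # standardized scale reported
  expect_true(all(c("flight_time_h", "relative_departure_days") %in%
                    fit$coefficients$term))

  all_surv <- rows[rows$died == 0, ]
  expect_error(fit_mortality_glmm(all_surv, B = 9), "both outcomes")
})

test_that("informed/uninformed comparison reports percentage shortening and enforces the invariant", {
  base <- data.frame(individual = rep(sprintf("I%02d", 1:30), 2),
                     time_informed = rep(seq(30, 40, length.out = 30), 2))

  same <- base; same$time_uninformed <- same$time_informed
  fit_same <- suppressWarnings(suppressMessages(
    compare_informed_uninformed(same, B = 9, seed = 1)))
  expect_equal(fit_same$pct_shorter, 0)
  est <- fit_same$coefficients$estimate[
    fit_same$coefficients$term == "variantuninformed"]
  expect_equal(est, 0, tolerance = 1e-8)

  short <- base; short$time_uninformed <- 0.9 * short$time_informed
  fit_short <- suppressMessages(compare_informed_uninformed(short, B = 9, seed = 1))
  expect_equal(fit_short$pct_shorter, 10, tolerance = 1e-9)

  bad <- base; bad$time_uninformed <- base$time_informed + 1
  expect_error(compare_informed_uninformed(bad, B = 9), "invariant breach")
})
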