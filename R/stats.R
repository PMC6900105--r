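# Inferential models: seasonal contrast in minimal flight time, in-flight
# mortality on the northward crossing, and the informed-vs-uninformed
# robustness comparison. All models carry an individual random intercept
# and fixed effects are tested by parametric bootstrap.

new_fit_result <- function(model, coefs, ranef_var, boot, nobs, ngroups,
                           B, seed, notes = character(0)) {
  structure(list(model = model, coefficients = coefs,
                 ranef_var = ranef_var, boot = boot,
                 nobs = nobs, ngroups = ngroups,
                 n_boot = B, seed = seed, notes = notes),
            class = "windcross_fit")
}

#' @export
print.windcross_fit <- function(x, ...) {
  cat("<windcross_fit> ", x$nobs, " obs, ", x$ngroups,
      " individuals; random-intercept SD = ", signif(sqrt(x$ranef_var), 4),
      "\n", sep = "")
  df <- x$coefficients
  if (!is.null(x$boot)) {
    df$boot_p <- x$boot$p[match(df$term, x$boot$term)]
  }
  print(df, row.names = FALSE)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

fixef_table <- function(model) {
  est <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  data.frame(term = names(est), estimate = unname(est), se = unname(se))
}

ranef_variance <- function(model) {
  vc <- lme4::VarCorr(model)
  as.numeric(vc[[1]][1, 1])
}

#' Parametric-bootstrap p-value for nested mixed models
#'
#' Simulates `B` response vectors from the fitted null model, refits both
#' the null and the full model to each, and compares the observed
#' likelihood-ratio statistic with the bootstrap distribution:
#' `p = (1 + #{LRT_boot >= LRT_obs}) / (B + 1)`. Deterministic under a
#' fixed seed and invariant to relabelling of individuals.
#'
#' @param full,null Fitted `merMod` objects (ML fits); `null` must be
#'   nested in `full` (same response, fewer parameters).
#' @param B Number of bootstrap replicates, >= 1.
#' @param seed Integer RNG seed.
#' @return Numeric p-value in (0, 1], with attributes `lrt_obs` and
#'   `n_failed` (replicates dropped for refit failure).
#' @export
parametric_bootstrap_p <- function(full, null, B = 1000, seed = 1L) {
  if (B < 1) stop("B must be >= 1 (the p-value denominator is B + 1)")
  if (!inherits(full, "merMod") || !inherits(null, "merMod")) {
    stop("full and null must be lme4 fits")
  }
  df_full <- attr(stats::logLik(full), "df")
  df_null <- attr(stats::logLik(null), "df")
  if (df_full <= df_null || stats::nobs(full) != stats::nobs(null)) {
    stop("models are not nested (null must have fewer parameters, same data)")
  }
  if (!all(names(lme4::fixef(null)) %in% names(lme4::fixef(full)))) {
    stop("models are not nested: null has terms absent from full")
  }
  lrt_obs <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                         as.numeric(stats::logLik(null))))
  sims <- stats::simulate(null, nsim = B, seed = seed)
  stat <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    stat[b] <- tryCatch({
      f2 <- suppressMessages(suppressWarnings(lme4::refit(full, sims[[b]])))
      n2 <- suppressMessages(suppressWarnings(lme4::refit(null, sims[[b]])))
      max(0, 2 * (as.numeric(stats::logLik(f2)) - as.numeric(stats::logLik(n2))))
    }, error = function(e) NA_real_)
  }
  ok <- !is.na(stat)
  p <- (1 + sum(stat[ok] >= lrt_obs - 1e-8)) / (sum(ok) + 1)
  attr(p, "lrt_obs") <- lrt_obs
  attr(p, "n_failed") <- sum(!ok)
  p
}

#' Seasonal contrast in minimal flight time
#'
#' Linear mixed model `flight_time_h ~ season + (1 | individual)`, fitted
#' by maximum likelihood, with the season contrast tested by parametric
#' bootstrap. The season factor is ordered (southward, northward) so the
#' reported contrast is northward minus southward hours.
#'
#' @param rows Data frame with `flight_time_h`, `season`
#'   (southward/northward), `individual`.
#' @param B Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return A `windcross_fit`. Singular fits are reported in `$notes`, not
#'   hidden.
#' @export
fit_season_lmm <- function(rows, B = 1000, seed = 1L) {
  if (length(unique(rows$season)) < 2L) {
    stop("need both seasons to estimate a seasonal contrast")
  }
  rows$season <- factor(rows$season, levels = c("southward", "northward"))
  rows$individual <- factor(rows$individual)
  # allow the degenerate one-observation-per-individual design, where the
  # fit collapses to the OLS group contrast
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  full <- lme4::lmer(flight_time_h ~ season + (1 | individual), data = rows,
                     REML = FALSE, control = ctrl)
  null <- lme4::lmer(flight_time_h ~ 1 + (1 | individual), data = rows,
                     REML = FALSE, control = ctrl)
  p <- parametric_bootstrap_p(full, null, B = B, seed = seed)
  notes <- character(0)
  if (lme4::isSingular(full)) notes <- c(notes, "singular fit (random-intercept variance at boundary)")
  new_fit_result(full, fixef_table(full), ranef_variance(full),
                 data.frame(term = "seasonnorthward", p = as.numeric(p)),
                 nobs = nrow(rows), ngroups = nlevels(rows$individual),
                 B = B, seed = seed, notes = notes)
}

#' In-flight mortality model for northward crossings
#'
#' Logistic mixed model
#' `died ~ flight_time_h + relative_departure_days + tag_type +
#' (1 | individual)`, ML fit via Laplace approximation. Each fixed effect
#' is tested by dropping it from the full model and computing a
#' parametric-bootstrap p-value. Coefficients are reported on the raw
#' scale (log-odds per hour / per day) and, for the continuous
#' predictors, per SD (`estimate_std`).
#'
#' @param rows Data frame with `died` (0/1), `flight_time_h`,
#'   `relative_departure_days`, `tag_type`, `individual`.
#' @param B Bootstrap replicates per tested effect.
#' @param seed RNG seed.
#' @param test Character vector of fixed effects to bootstrap-test
#'   (default all three).
#' @param nAGQ Integrand approximation passed to [lme4::glmer()]: 1
#'   (Laplace, the default) or 0 (faster penalized-likelihood step,
#'   appropriate for large simulation studies).
#' @return A `windcross_fit`; complete separation is detected and
#'   reported in `$notes`.
#' @export
fit_mortality_glmm <- function(rows, B = 1000, seed = 1L,
                               test = c("flight_time_h",
                                        "relative_departure_days",
                                        "tag_type"),
                               nAGQ = 1L) {
  if (length(unique(rows$died)) < 2L) {
    stop("both outcomes (died and survived) must be present")
  }
  rows$individual <- factor(rows$individual)
  rows$tag_type <- factor(rows$tag_type)
  one_tag <- nlevels(rows$tag_type) < 2L
  rhs <- c("flight_time_h", "relative_departure_days",
           if (!one_tag) "tag_type")
  fml <- stats::reformulate(c(rhs, "(1 | individual)"), response = "died")
  full <- lme4::glmer(fml, data = rows, family = stats::binomial, nAGQ = nAGQ)

  notes <- character(0)
  if (one_tag) notes <- c(notes, "single tag type present; tag_type dropped")
  mu <- stats::fitted(full)
  beta <- lme4::fixef(full)
  if (all(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(beta) > 15)) {
    notes <- c(notes, "possible complete separation (fitted probabilities degenerate)")
  }
  if (lme4::isSingular(full)) {
    notes <- c(notes, "singular fit (random-intercept variance at boundary)")
  }

  test <- intersect(test, rhs)
  boot <- data.frame(term = character(0), p = numeric(0))
  for (tm in test) {
    rhs0 <- setdiff(rhs, tm)
    fml0 <- stats::reformulate(c(if (length(rhs0)) rhs0 else "1",
                                 "(1 | individual)"), response = "died")
    null <- lme4::glmer(fml0, data = rows, family = stats::binomial,
                        nAGQ = nAGQ)
    p <- parametric_bootstrap_p(full, null, B = B, seed = seed)
    boot <- rbind(boot, data.frame(term = tm, p = as.numeric(p)))
  }

  coefs <- fixef_table(full)
  coefs$estimate_std <- NA_real_
  for (v in c("flight_time_h", "relative_departure_days")) {
    i <- match(v, coefs$term)
    if (!is.na(i)) coefs$estimate_std[i] <- coefs$estimate[i] * stats::sd(rows[[v]])
  }
  new_fit_result(full, coefs, ranef_variance(full), boot,
                 nobs = nrow(rows), ngroups = nlevels(rows$individual),
                 B = B, seed = seed, notes = notes)
}

#' Compare informed and uninformed minimal flight times
#'
#' Paired comparison of the two simulation variants: a linear mixed model
#' of flight time on variant with an individual random intercept, plus the
#' mean percentage shortening
#' `mean((informed - uninformed) / informed) * 100`. The uninformed route
#' is, by definition, of equal or shorter duration; any pair violating
#' this is an invariant breach upstream and raises an error.
#'
#' @param rows Data frame with `time_informed`, `time_uninformed` (hours)
#'   and `individual`, one row per crossing.
#' @param B Bootstrap replicates for the variant effect.
#' @param seed RNG seed.
#' @return A `windcross_fit` with extra element `pct_shorter`.
#' @export
compare_informed_uninformed <- function(rows, B = 1000, seed = 1L) {
  stopifnot(all(c("time_informed", "time_uninformed", "individual") %in% names(rows)))
  viol <- rows$time_uninformed > rows$time_informed + 1e-6
  if (any(viol)) {
    stop("invariant breach: ", sum(viol),
         " pair(s) have uninformed time > informed time")
  }
  pct <- mean((rows$time_informed - rows$time_uninformed) /
                rows$time_informed) * 100
  long <- data.frame(
    flight_time_h = c(rows$time_informed, rows$time_uninformed),
    variant = factor(rep(c("informed", "uninformed"), each = nrow(rows)),
                     levels = c("informed", "uninformed")),
    individual = factor(rep(rows$individual, 2)))
  full <- lme4::lmer(flight_time_h ~ variant + (1 | individual), data = long,
                     REML = FALSE)
  null <- lme4::lmer(flight_time_h ~ 1 + (1 | individual), data = long,
                     REML = FALSE)
  p <- parametric_bootstrap_p(full, null, B = B, seed = seed)
  out <- new_fit_result(full, fixef_table(full), ranef_variance(full),
                        data.frame(term = "variantuninformed",
                                   p = as.numeric(p)),
                        nobs = nrow(long), ngroups = nlevels(long$individual),
                        B = B, seed = seed)
  out$pct_shorter <- pct
  out
}
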