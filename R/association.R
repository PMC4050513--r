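#' Default adjustment covariates
#'
#' The covariate set of the adjusted models: sex, age (continuous),
#' nationality, parents' education (4 levels), parental smoking, smoking at
#' home, average air-refreshing time (3 levels), residential traffic,
#' orthodontic appliance, DMFT score (>= 1 vs 0) and the person who
#' collected the cell sample (3 levels).
#'
#' @return character vector of column names.
#' @export
default_model_covariates <- function() {
  c("sex", "age", "nationality", "educ", "smoking_parents", "smoke_home",
    "air_refresh", "traffic", "ortho", "dmft", "collector")
}

p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

assoc_row <- function(outcome, pollutant, specification, family, est, lo, hi,
                      p, n, converged = TRUE, dispersion = NA_real_) {
  data.frame(outcome = outcome, pollutant = pollutant,
             specification = specification, family = family,
             estimate = est, conf_low = lo, conf_high = hi, p_value = p,
             stars = p_stars(p), n = n, converged = converged,
             dispersion = dispersion, stringsAsFactors = FALSE)
}

#' Weighted linear association model
#'
#' Weighted least squares of a (approximately) normally distributed marker
#' on a standardized exposure plus covariates. Weights (typically the
#' number of comet cells examined) are normalized to mean 1 so the
#' effective n matches the nominal n; with equal weights the fit reduces to
#' OLS. Complete-case analysis; Wald 95\% CI with the t reference.
#'
#' @param data cohort data frame with exposure z-scores and outcomes.
#' @param outcome outcome column name.
#' @param exposure exposure column name (z-scored).
#' @param covariates character vector of adjustment covariates (empty =
#'   crude).
#' @param weights_var optional weight column (e.g. `"cells_examined"`).
#' @return one-row data frame (class `association_estimate`): per-1-SD
#'   slope, 95\% CI, p, complete-case n.
#' @export
fit_weighted_linear <- function(data, outcome, exposure,
                                covariates = character(), weights_var = NULL) {
  vars <- c(outcome, exposure, covariates, weights_var)
  cc <- complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  n <- nrow(d)
  if (n < length(covariates) + 12)
    stop("too few complete cases for the requested model")
  w <- if (is.null(weights_var)) rep(1, n) else d[[weights_var]]
  w <- w / mean(w)
  f <- as.formula(paste(outcome, "~",
                        paste(c(exposure, covariates), collapse = " + ")))
  fit <- lm(f, data = d, weights = w)
  a <- tryCatch(coef(summary(fit))[exposure, ], error = function(e)
    stop("rank-deficient design; aliased: ",
         paste(names(which(is.na(coef(fit)))), collapse = ", ")))
  if (anyNA(coef(fit)))
    stop("rank-deficient design; aliased: ",
         paste(names(which(is.na(coef(fit)))), collapse = ", "))
  tq <- qt(0.975, fit$df.residual)
  out <- assoc_row(outcome, exposure,
                   if (length(covariates)) "adjusted" else "crude",
                   "gaussian", a["Estimate"], a["Estimate"] - tq * a["Std. Error"],
                   a["Estimate"] + tq * a["Std. Error"], a["Pr(>|t|)"], n)
  class(out) <- c("association_estimate", "data.frame")
  out
}

#' Negative-binomial association model
#'
#' NB2 (log link, ML dispersion) regression of an overdispersed count
#' marker on a standardized exposure plus covariates; the association is
#' reported as a rate ratio \eqn{e^{\hat\beta}} per 1-SD with a Wald CI
#' exponentiated from the log scale. If the NB fit fails or the dispersion
#' runs to the Poisson boundary, a Poisson fit is used with a warning.
#'
#' @inheritParams fit_weighted_linear
#' @return one-row `association_estimate` with the RR scale.
#' @export
fit_negative_binomial <- function(data, outcome, exposure,
                                  covariates = character()) {
  vars <- c(outcome, exposure, covariates)
  cc <- complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  n <- nrow(d)
  y <- d[[outcome]]
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("outcome must be nonnegative integer counts")
  if (all(y == 0)) stop("all-zero count outcome")
  f <- as.formula(paste(outcome, "~",
                        paste(c(exposure, covariates), collapse = " + ")))
  theta <- NA_real_
  fam <- "negative-binomial"
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(f, data = d)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || fit$theta > 1e4) {
    if (!is.null(fit) && fit$theta > 1e4)
      warning("dispersion at the Poisson boundary; falling back to Poisson")
    else warning("negative-binomial fit failed; falling back to Poisson")
    fit <- glm(f, data = d, family = poisson())
    fam <- "poisson"
  } else theta <- fit$theta
  a <- coef(summary(fit))[exposure, ]
  zq <- qnorm(0.975)
  est <- exp(a["Estimate"])
  out <- assoc_row(outcome, exposure,
                   if (length(covariates)) "adjusted" else "crude",
                   fam, est, exp(a["Estimate"] - zq * a["Std. Error"]),
                   exp(a["Estimate"] + zq * a["Std. Error"]),
                   a[4], n, converged = fit$converged, dispersion = theta)
  class(out) <- c("association_estimate", "data.frame")
  out
}

#' Full crude/adjusted association battery
#'
#' Runs the 24 main models: six markers (tail intensity, tail length, tail
#' moment as weighted linear; binucleated-cell percent as linear; micro-
#' nucleus and nuclear-bud counts as negative binomial) by two pollutants
#' by crude/adjusted. Individual model failures are recorded and the
#' battery continues.
#'
#' @param cohort cohort with outcomes and `z_hcho`, `z_no2`.
#' @param covariates adjustment set, see [default_model_covariates()].
#' @param exposures named exposure columns.
#' @return data frame of `association_estimate` rows (one per model), with
#'   `error` messages for failed fits.
#' @export
association_battery <- function(cohort, covariates = default_model_covariates(),
                                exposures = c(hcho = "z_hcho", no2 = "z_no2")) {
  outcomes <- list(
    ti = list(family = "gaussian", weights = "cells_examined"),
    tl = list(family = "gaussian", weights = "cells_examined"),
    tm = list(family = "gaussian", weights = "cells_examined"),
    bn = list(family = "gaussian", weights = NULL),
    mn_count = list(family = "nb"),
    bud_count = list(family = "nb"))
  rows <- list()
  for (o in names(outcomes)) for (pol in names(exposures))
    for (spec in c("crude", "adjusted")) {
      cv <- if (spec == "adjusted") covariates else character()
      res <- tryCatch({
        if (outcomes[[o]]$family == "gaussian")
          fit_weighted_linear(cohort, o, exposures[[pol]], cv,
                              weights_var = outcomes[[o]]$weights)
        else
          fit_negative_binomial(cohort, o, exposures[[pol]], cv)
      }, error = function(e) {
        r <- assoc_row(o, exposures[[pol]], spec, outcomes[[o]]$family,
                       NA_real_, NA_real_, NA_real_, NA_real_, NA_integer_,
                       converged = FALSE)
        r$error <- conditionMessage(e)
        r
      })
      res$pollutant <- pol
      if (is.null(res$error)) res$error <- NA_character_
      rows[[length(rows) + 1]] <- res
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity analyses
#'
#' (a) `indoor`: the main adjusted battery with three extra indicators of
#' indoor air quality (age of the house, age of nonwooden bedroom
#' furniture, double-glazed windows), restricted to non-movers because the
#' indicators refer to the baseline address. (b) `near_industry`: the main
#' adjusted battery restricted to children living within `radius_km`
#' (default 4) of a chipboard industry.
#'
#' @param cohort cohort with outcomes, exposures, `mover`,
#'   `d_chipboard_km` and the indoor-indicator columns.
#' @param covariates main adjustment set.
#' @param radius_km chipboard-distance cut for analysis (b).
#' @return list with elements `indoor` and `near_industry`, each an
#'   association battery data frame; `near_industry` carries attribute `n`.
#' @export
sensitivity_analyses <- function(cohort, covariates = default_model_covariates(),
                                 radius_km = 4) {
  stopifnot(all(c("mover", "house_new", "furniture", "double_glazing",
                  "d_chipboard_km") %in% names(cohort)))
  indoor_cov <- c(covariates, "house_new", "furniture", "double_glazing")
  a <- association_battery(cohort[!cohort$mover, , drop = FALSE],
                           covariates = indoor_cov)
  a <- a[a$specification == "adjusted", , drop = FALSE]
  near <- cohort[cohort$d_chipboard_km < radius_km, , drop = FALSE]
  b <- association_battery(near, covariates = covariates)
  b <- b[b$specification == "adjusted", , drop = FALSE]
  attr(b, "n") <- nrow(near)
  list(indoor = a, near_industry = b)
}

#' Participation rate
#'
#' Percent of invited families that took part.
#'
#' @param n_participated,n_invited counts.
#' @return percentage (0-100).
#' @export
participation_rate <- function(n_participated, n_invited) {
  stopifnot(n_invited > 0, n_participated >= 0, n_participated <= n_invited)
  100 * n_participated / n_invited
}
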