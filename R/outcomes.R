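#' Outcome generative specification
#'
#' Marginal distributions of the six genotoxicity markers and the per-1-SD
#' exposure effects used as generative truth. Defaults match the observed
#' marker distributions (tail intensity 3.25 +/- 0.88 \%, tail length
#' 11.69 +/- 2.11 um, tail moment 0.20 +/- 0.05, binucleated cells
#' 1.83 +/- 0.64 \%, micronuclei 0.12 \% and nuclear buds 0.23 \% of 2,000
#' scored cells) and the adjusted association estimates (TI +0.13 \%/SD
#' formaldehyde, TM +0.007/SD formaldehyde, BN +0.13 \%/SD NO2, bud rate
#' ratios 1.12/SD formaldehyde and 1.16/SD NO2; null effects elsewhere).
#'
#' The negative-binomial size (theta) defaults are back-computed from the
#' marker coefficients of variation: buds theta = 1.2 reproduces CV near
#' 1.0 at a mean count of 4.6 per 2,000 cells; micronuclei theta = 7
#' reproduces CV near 0.75 at a mean count of 2.4.
#'
#' @param effects named list per outcome: for gaussian outcomes, additive
#'   slopes per 1-SD of `hcho`/`no2`; for count outcomes, rate ratios.
#' @param covariate_effects list with `gaussian` (fractions of the outcome
#'   SD per unit covariate) and `count` (log-rate per unit covariate).
#' @return an object of class `outcome_spec`.
#' @export
outcome_spec <- function(effects = NULL, covariate_effects = NULL) {
  gaussian <- list(
    ti = list(mean = 3.25, sd = 0.88, comet = TRUE),
    tl = list(mean = 11.69, sd = 2.11, comet = TRUE),
    tm = list(mean = 0.20, sd = 0.05, comet = TRUE),
    bn = list(mean = 1.83, sd = 0.64, comet = FALSE))
  counts <- list(
    mn = list(freq_pct = 0.12, theta = 7),
    buds = list(freq_pct = 0.23, theta = 1.2))
  eff <- list(
    ti = c(hcho = 0.13, no2 = 0),
    tl = c(hcho = 0, no2 = 0),
    tm = c(hcho = 0.007, no2 = 0),
    bn = c(hcho = 0, no2 = 0.13),
    mn = c(hcho = 1, no2 = 1),
    buds = c(hcho = 1.12, no2 = 1.16))
  if (!is.null(effects)) eff[names(effects)] <- effects
  cov_eff <- list(
    gaussian = c(age = 0.03, smoking_parents = 0.15, traffic = 0.10,
                 dmft = 0.10),
    count = c(age = 0.015, smoking_parents = 0.08, traffic = 0.05,
              dmft = 0.05))
  if (!is.null(covariate_effects)) cov_eff[names(covariate_effects)] <-
    covariate_effects
  for (o in names(gaussian)) stopifnot(gaussian[[o]]$sd > 0)
  stopifnot(all(unlist(eff[c("mn", "buds")]) > 0))
  structure(list(gaussian = gaussian, counts = counts, effects = eff,
                 covariate_effects = cov_eff, cells_ref = 50,
                 scored_cells = 2000),
            class = "outcome_spec")
}

# Centered covariate design used by the generative model (age in years
# centred at 9; binary indicators centred at their sample mean so the
# marginal outcome mean is not shifted).
covariate_design <- function(cohort) {
  X <- cbind(age = cohort$age - 9,
             smoking_parents = cohort$smoking_parents,
             traffic = cohort$traffic,
             dmft = cohort$dmft)
  sweep(X, 2, colMeans(X), "-")
}

#' Simulate genotoxicity outcomes for a cohort
#'
#' Gaussian markers are intercept + (effect per SD) x standardized exposure
#' + covariate terms + residual, with the residual SD chosen so the
#' marginal SD matches the specification; comet markers get a
#' heteroscedastic residual SD proportional to \eqn{\sqrt{50/cells}},
#' which is what justifies weighting those models by the number of cells
#' examined. Micronucleus and bud counts are negative binomial with log
#' mean = log(baseline count per 2,000 cells) + log(RR) x standardized
#' exposure + covariate terms. Values are truncated to valid ranges
#' (nonnegative; counts at most 2,000).
#'
#' @param cohort data frame from [generate_cohort()].
#' @param z matrix or data frame with standardized exposures `hcho`, `no2`
#'   (each mean 0, SD 1 over the cohort).
#' @param spec an [outcome_spec()].
#' @param seed integer seed.
#' @return `cohort` with outcome columns `ti`, `tl`, `tm`, `bn` (percent /
#'   um units) and counts `mn_count`, `bud_count` plus frequencies
#'   `mn_pct`, `bud_pct`, `bn_pct` alias.
#' @export
simulate_outcomes <- function(cohort, z, spec = outcome_spec(), seed) {
  if (missing(seed)) stop("a seed is required")
  z <- as.matrix(as.data.frame(z)[, c("hcho", "no2")])
  stopifnot(nrow(z) == nrow(cohort))
  ms <- colMeans(z); sds <- apply(z, 2, sd)
  if (any(abs(ms) > 1e-6) || any(abs(sds - 1) > 1e-6))
    stop("exposures must be standardized (mean 0, SD 1)")
  set.seed(seed)
  n <- nrow(cohort)
  X <- covariate_design(cohort)
  cb <- spec$covariate_effects

  for (o in names(spec$gaussian)) {
    g <- spec$gaussian[[o]]
    eff <- spec$effects[[o]]
    s <- drop(z %*% eff[c("hcho", "no2")]) +
      drop(X %*% (cb$gaussian[colnames(X)] * g$sd))
    v_sys <- var(s)
    if (v_sys >= g$sd^2)
      stop(sprintf("inconsistent OutcomeSpec: systematic SD exceeds marginal SD for '%s'", o))
    base_sd <- sqrt(g$sd^2 - v_sys)
    if (g$comet) {
      infl <- spec$cells_ref / cohort$cells_examined
      base_sd <- base_sd / sqrt(mean(infl))
      sd_i <- base_sd * sqrt(infl)
    } else sd_i <- rep(base_sd, n)
    y <- (g$mean - mean(s)) + s + rnorm(n, sd = sd_i)
    y <- pmax(y, 0)
    if (o %in% c("ti", "bn")) y <- pmin(y, 100)
    cohort[[o]] <- y
  }

  for (o in names(spec$counts)) {
    ct <- spec$counts[[o]]
    base_count <- ct$freq_pct / 100 * spec$scored_cells
    lrr <- log(spec$effects[[o]][c("hcho", "no2")])
    eta <- drop(z %*% lrr) + drop(X %*% cb$count[colnames(X)])
    mu <- base_count * exp(eta - mean(eta))
    y <- rnbinom(n, size = ct$theta, mu = mu)
    y <- pmin(y, spec$scored_cells)
    cohort[[paste0(sub("s$", "", o), "_count")]] <- as.integer(y)
    cohort[[paste0(sub("s$", "", o), "_pct")]] <- 100 * y / spec$scored_cells
  }
  cohort
}
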