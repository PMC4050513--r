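test_that("a noiseless linear signal is recovered exactly", {
  co <- fake_exposed_cohort(80, seed = 1)
  co$y <- 1 + 2 * co$z_hcho
  # lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fit_weighted_linear(co, "y", "z_hcho"))
  expect_equal(fit$estimate, 2, tolerance = 1e-10)
  expect_lt(fit$conf_high - fit$conf_low, 1e-6)
  expect_equal(fit$n, 80L)
  expect_equal(fit$specification, "crude")
})

test_that("equal weights reproduce the unweighted fit", {
  co <- fake_exposed_cohort(150, seed = 2)
  set.seed(3)
  co$y <- 1 + 0.4 * co$z_hcho + rnorm(150)
  co$wconst <- 7
  f1 <- fit_weighted_linear(co, "y", "z_hcho", c("sex", "age"))
  f2 <- fit_weighted_linear(co, "y", "z_hcho", c("sex", "age"),
                            weights_var = "wconst")
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-12)
  expect_equal(f1$conf_low, f2$conf_low, tolerance = 1e-12)
})

test_that("weighting matters under heteroscedasticity tied to cells examined", {
  co <- fake_exposed_cohort(4000, seed = 4)
  set.seed(5)
  co$y <- 3 + 0.2 * co$z_hcho + rnorm(4000, sd = sqrt(50 / co$cells_examined))
  fw <- fit_weighted_linear(co, "y", "z_hcho", weights_var = "cells_examined")
  fu <- fit_weighted_linear(co, "y", "z_hcho")
  # weighted fit is more precise (narrower CI) under the generative model
  expect_lte(fw$conf_high - fw$conf_low, fu$conf_high - fu$conf_low + 1e-9)
})

test_that("rank-deficient designs fail with the aliased column named", {
  co <- fake_exposed_cohort(60, seed = 6)
  co$dup <- co$age
  co$y <- rnorm(60)
  expect_error(fit_weighted_linear(co, "y", "z_hcho", c("age", "dup")),
               "aliased")
})

test_that("Poisson-null counts give RR near 1 with covering CI", {
  co <- fake_exposed_cohort(400, seed = 7)
  set.seed(8)
  co$cnt <- rpois(400, 4)
  fit <- suppressWarnings(fit_negative_binomial(co, "cnt", "z_hcho"))
  expect_gt(fit$estimate, 0.9)
  expect_lt(fit$estimate, 1.1)
  expect_true(fit$conf_low < 1 && fit$conf_high > 1)
})

test_that("NB intervals widen relative to Poisson on overdispersed counts", {
  co <- fake_exposed_cohort(500, seed = 9)
  set.seed(10)
  co$cnt <- rnbinom(500, size = 1, mu = 5)
  nb <- fit_negative_binomial(co, "cnt", "z_hcho")
  po <- glm(cnt ~ z_hcho, data = co, family = poisson())
  se_po <- coef(summary(po))["z_hcho", "Std. Error"]
  width_po <- 2 * qnorm(0.975) * se_po
  width_nb <- log(nb$conf_high) - log(nb$conf_low)
  expect_gt(width_nb, width_po)
  expect_gt(nb$dispersion, 0.5)
  expect_lt(nb$dispersion, 2.5)
})

test_that("NB estimates approach Poisson when data are not overdispersed", {
  co <- fake_exposed_cohort(800, seed = 11)
  set.seed(12)
  co$cnt <- rpois(800, exp(1 + 0.2 * co$z_no2))
  nb <- suppressWarnings(fit_negative_binomial(co, "cnt", "z_no2"))
  po <- glm(cnt ~ z_no2, data = co, family = poisson())
  expect_equal(log(nb$estimate), coef(po)["z_no2"], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("count-model input validation", {
  co <- fake_exposed_cohort(50, seed = 13)
  co$bad <- rnorm(50)
  expect_error(fit_negative_binomial(co, "bad", "z_hcho"), "integer")
  co$zero <- 0L
  expect_error(fit_negative_binomial(co, "zero", "z_hcho"), "all-zero")
})

test_that("the battery runs 24 models and distinguishes crude from adjusted", {
  cc <- simulate_study_cohort(374, seed = 14)
  bat <- suppressWarnings(association_battery(cc))
  expect_equal(nrow(bat), 24)
  expect_equal(sum(bat$specification == "crude"), 12)
  expect_setequal(unique(bat$pollutant), c("hcho", "no2"))
  expect_true(all(is.na(bat$error)))
  # confounding by stratum-linked traffic: crude and adjusted differ
  cr <- bat[bat$outcome == "ti" & bat$pollutant == "hcho", ]
  expect_false(isTRUE(all.equal(cr$estimate[cr$specification == "crude"],
                                cr$estimate[cr$specification == "adjusted"])))
  # CI contains the point estimate everywhere
  ok <- !is.na(bat$estimate)
  expect_true(all(bat$conf_low[ok] <= bat$estimate[ok] &
                  bat$estimate[ok] <= bat$conf_high[ok]))
})

test_that("sensitivity analyses subset and augment as designed", {
  cc <- simulate_study_cohort(374, seed = 15)
  sens <- suppressWarnings(sensitivity_analyses(cc))
  expect_named(sens, c("indoor", "near_industry"))
  expect_equal(attr(sens$near_industry, "n"),
               sum(cc$d_chipboard_km < 4))
  expect_true(all(sens$indoor$specification == "adjusted"))
  # indoor battery excludes movers
  expect_true(all(sens$indoor$n <= sum(!cc$mover)))
})

test_that("participation arithmetic", {
  expect_equal(round(participation_rate(413, 656)), 63)
  expect_error(participation_rate(10, 0))
})
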