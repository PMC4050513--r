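zero_effect_spec <- function() {
  outcome_spec(
    effects = list(ti = c(hcho = 0, no2 = 0), tl = c(hcho = 0, no2 = 0),
                   tm = c(hcho = 0, no2 = 0), bn = c(hcho = 0, no2 = 0),
                   mn = c(hcho = 1, no2 = 1), buds = c(hcho = 1, no2 = 1)),
    covariate_effects = list(gaussian = c(age = 0, smoking_parents = 0,
                                          traffic = 0, dmft = 0),
                             count = c(age = 0, smoking_parents = 0,
                                       traffic = 0, dmft = 0)))
}

test_that("all effects zero and tight SD puts every TI at the intercept", {
  co <- fake_exposed_cohort(60, seed = 1)
  sp <- zero_effect_spec()
  sp$gaussian$ti$sd <- 1e-9
  out <- simulate_outcomes(co, data.frame(hcho = co$z_hcho, no2 = co$z_no2),
                           sp, seed = 2)
  expect_true(all(abs(out$ti - 3.25) < 1e-6))
})

test_that("marginal moments match the marker distribution targets", {
  co <- fake_exposed_cohort(6000, seed = 3)
  out <- simulate_outcomes(co, data.frame(hcho = co$z_hcho, no2 = co$z_no2),
                           outcome_spec(), seed = 4)
  expect_equal(mean(out$ti), 3.25, tolerance = 0.02)
  expect_equal(sd(out$ti), 0.88, tolerance = 0.05)
  expect_equal(mean(out$bn), 1.83, tolerance = 0.02)
  expect_equal(mean(out$tm), 0.20, tolerance = 0.01)
  # bud frequency ~0.23% of 2,000 cells with CV near 1
  expect_equal(mean(out$bud_pct), 0.23, tolerance = 0.025)
  expect_equal(sd(out$bud_count) / mean(out$bud_count), 1.01,
               tolerance = 0.15)
  # micronuclei ~0.12%
  expect_equal(mean(out$mn_pct), 0.12, tolerance = 0.015)
  # validity ranges
  expect_true(all(out$mn_count >= 0 & out$mn_count <= 2000))
  expect_true(all(out$bud_count == round(out$bud_count)))
  expect_true(all(out$ti >= 0 & out$ti <= 100 & out$bn >= 0 & out$bn <= 100))
})

test_that("comet residuals are heteroscedastic in cells examined", {
  co <- fake_exposed_cohort(8000, seed = 5)
  sp <- zero_effect_spec()
  out <- simulate_outcomes(co, data.frame(hcho = co$z_hcho, no2 = co$z_no2),
                           sp, seed = 6)
  v_full <- var(out$ti[out$cells_examined == 50])
  v_part <- var(out$ti[out$cells_examined < 50])
  expect_gt(v_part, v_full)
  # ratio close to the mean 50/cells inflation of the partial group
  infl <- mean(50 / out$cells_examined[out$cells_examined < 50])
  expect_equal(v_part / v_full, infl, tolerance = 0.25)
})

test_that("an unattainable marginal SD is rejected", {
  co <- fake_exposed_cohort(100, seed = 7)
  sp <- outcome_spec(effects = list(ti = c(hcho = 5, no2 = 0)))
  expect_error(simulate_outcomes(co, data.frame(hcho = co$z_hcho,
                                                no2 = co$z_no2),
                                 sp, seed = 8), "inconsistent OutcomeSpec")
})

test_that("unstandardized exposures are rejected", {
  co <- fake_exposed_cohort(50, seed = 9)
  z <- data.frame(hcho = co$z_hcho * 2, no2 = co$z_no2)
  expect_error(simulate_outcomes(co, z, outcome_spec(), seed = 1),
               "standardized")
})

test_that("fixing the seed fixes every generated value", {
  co <- fake_exposed_cohort(100, seed = 10)
  z <- data.frame(hcho = co$z_hcho, no2 = co$z_no2)
  a <- simulate_outcomes(co, z, outcome_spec(), seed = 11)
  b <- simulate_outcomes(co, z, outcome_spec(), seed = 11)
  expect_identical(a, b)
})
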