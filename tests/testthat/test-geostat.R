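test_that("empirical variogram reproduces hand arithmetic on collinear sites", {
  df <- data.frame(x_km = c(0, 1, 2), y_km = 0, value = c(0, 1, 2))
  emp <- empirical_variogram(df, n_bins = 2, max_lag = 2, min_pairs = 1)
  # pairs at lag 1: gamma = 0.5 (twice); at lag 2: gamma = 2
  expect_equal(emp$gamma, c(0.5, 2))
  expect_equal(emp$npairs, c(2L, 1L))
})

test_that("constant field has zero semivariance everywhere", {
  set.seed(1)
  df <- data.frame(x_km = runif(30, 0, 10), y_km = runif(30, 0, 10),
                   value = 5)
  emp <- empirical_variogram(df)
  expect_true(all(emp$gamma[!is.na(emp$gamma)] == 0))
})

test_that("white noise yields a flat variogram near the field variance", {
  set.seed(42)
  n <- 400
  df <- data.frame(x_km = runif(n, 0, 20), y_km = runif(n, 0, 30),
                   value = rnorm(n, sd = 2))
  emp <- empirical_variogram(df, n_bins = 8)
  ok <- !emp$flagged
  expect_true(all(abs(emp$gamma[ok] - 4) / 4 < 0.25))
})

test_that("fitting recovers an exactly exponential empirical variogram", {
  truth <- vgm_model("exponential", nugget = 0.01, psill = 0.12, range = 3.5)
  h <- seq(0.5, 8, by = 0.5)
  emp <- structure(
    data.frame(lag = h, center = h, gamma = semivariance(truth, h),
               npairs = 100L, flagged = FALSE),
    class = c("empirical_variogram", "data.frame"),
    max_lag = 8, theta = 0, ratio = 1)
  fit <- fit_variogram(emp, "exponential")
  expect_equal(fit$nugget, 0.01, tolerance = 1e-3)
  expect_equal(fit$psill, 0.12, tolerance = 1e-3)
  expect_equal(fit$range, 3.5, tolerance = 1e-3)
})

test_that("pure-nugget data fit a negligible partial sill", {
  set.seed(3)
  df <- data.frame(x_km = runif(120, 0, 20), y_km = runif(120, 0, 30),
                   value = rnorm(120))
  fit <- fit_variogram(empirical_variogram(df), "exponential")
  expect_lt(fit$psill, 0.35 * (fit$nugget + fit$psill))
})

test_that("kriging is exact at data sites with zero nugget", {
  set.seed(6)
  sites <- data.frame(x_km = runif(12, 0, 10), y_km = runif(12, 0, 10),
                      value = runif(12, 2, 4))
  m <- vgm_model("exponential", nugget = 0, psill = 1, range = 3)
  kr <- krige(sites, m, sites)
  expect_equal(kr$pred_ugm3, sites$value, tolerance = 1e-8)
  expect_true(all(kr$kvar < 1e-8))
})

test_that("pure-nugget kriging returns the arithmetic mean with uniform weights", {
  set.seed(7)
  sites <- data.frame(x_km = runif(8, 0, 10), y_km = runif(8, 0, 10),
                      value = rnorm(8, 10))
  m <- vgm_model("nugget", nugget = 2, psill = 0, range = 1)
  kr <- krige(sites, m, data.frame(x_km = 5, y_km = 5), keep_weights = TRUE)
  expect_equal(kr$pred_ugm3, mean(sites$value), tolerance = 1e-10)
  expect_equal(as.vector(attr(kr, "weights")), rep(1 / 8, 8),
               tolerance = 1e-10)
})

test_that("kriging weights sum to one and variances are nonnegative", {
  set.seed(8)
  for (i in 1:5) {
    n <- sample(5:25, 1)
    sites <- data.frame(x_km = runif(n, 0, 20), y_km = runif(n, 0, 30),
                        value = rnorm(n))
    m <- vgm_model(sample(c("exponential", "spherical", "gaussian"), 1),
                   nugget = runif(1, 0, 0.5), psill = runif(1, 0.5, 2),
                   range = runif(1, 1, 6),
                   angle = runif(1, 0, 180), ratio = runif(1, 0.4, 1))
    q <- data.frame(x_km = runif(100, 0, 20), y_km = runif(100, 0, 30))
    kr <- krige(sites, m, q, keep_weights = TRUE)
    expect_equal(colSums(attr(kr, "weights")), rep(1, 100), tolerance = 1e-8)
    expect_true(all(kr$kvar >= 0))
  }
})

test_that("system-solved weights match brute-force variance minimization", {
  set.seed(9)
  for (i in 1:8) {
    n <- sample(3:5, 1)
    xy <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    m <- vgm_model("exponential", nugget = runif(1, 0, 0.3),
                   psill = runif(1, 0.5, 2), range = runif(1, 1, 5))
    q <- c(runif(1, 0, 10), runif(1, 0, 10))
    sites <- data.frame(x_km = xy[, 1], y_km = xy[, 2], value = rnorm(n))
    kr <- krige(sites, m, data.frame(x_km = q[1], y_km = q[2]),
                keep_weights = TRUE)
    w_sys <- as.vector(attr(kr, "weights"))
    w_bf <- ok_weights_bruteforce(xy, m, q)
    expect_equal(w_sys, w_bf, tolerance = 1e-6)
  }
})

test_that("coincident sites are averaged and all-coincident input fails", {
  sites <- data.frame(x_km = c(1, 1, 4), y_km = c(2, 2, 5),
                      value = c(2, 4, 6))
  m <- vgm_model("exponential", nugget = 0, psill = 1, range = 2)
  expect_message(kr <- krige(sites, m, data.frame(x_km = 1, y_km = 2)),
                 "averaged")
  expect_equal(kr$pred_ugm3, 3, tolerance = 1e-8)
})

test_that("LOOCV RMSE matches hand arithmetic under a pure-nugget model", {
  sites <- data.frame(x_km = c(0, 1, 2), y_km = 0, value = c(0, 1, 2))
  m <- vgm_model("nugget", nugget = 1, psill = 0, range = 1)
  r <- loocv_rmse(sites, m)
  expect_equal(as.numeric(r), sqrt((1.5^2 + 0 + 1.5^2) / 3),
               tolerance = 1e-10)
  # constant data -> RMSE 0
  sites$value <- 2
  expect_equal(as.numeric(loocv_rmse(sites, m)), 0)
})

test_that("select_model returns a sorted leaderboard with the winner first", {
  set.seed(12)
  d <- tiny_district()
  co <- generate_cohort(d, 40, seed = 12)
  pts <- genokrig:::as_xy(co)[1:50, ]
  z <- genokrig:::grf_simulate(vgm_model("exponential", nugget = 0.01,
                                         psill = 0.12, range = 3.5), pts)
  df <- data.frame(x_km = pts[, 1], y_km = pts[, 2], value = 2.5 + z)
  sel <- select_model(df)
  expect_true(all(diff(sel$leaderboard$loocv_rmse) >= 0))
  expect_equal(sel$leaderboard$loocv_rmse[1], sel$rmse)
  expect_s3_class(sel$model, "vgm_model")
  # single candidate returns it
  one <- select_model(df, families = "spherical")
  expect_equal(one$model$family, "spherical")
})
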