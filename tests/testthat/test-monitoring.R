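make_surface <- function(fs, sites) {
  generate_pollution_field(fs, tiny_district(), grid_resolution = 2,
                           seed = 5, at_points = sites)
}

test_sites <- function(n = 15, seed = 3) {
  set.seed(seed)
  data.frame(site_id = sprintf("S%02d", 1:n),
             x_km = runif(n, 0.5, 19.5), y_km = runif(n, 0.5, 29.5))
}

test_that("no noise, no offsets, no missingness reproduces the true field", {
  fs <- pollutant_field_spec(
    "p", mu = 3, variogram = vgm_model("exponential", psill = 0.1, range = 2),
    season_means = c(warm = 3, cold = 3), bump_amplitude = 0, noise_sd = 0)
  sites <- test_sites()
  surf <- make_surface(fs, sites)
  meas <- simulate_campaign_measurements(surf, sites, fs, missing_rate = 0,
                                         seed = 1)
  expect_equal(nrow(meas), 4 * nrow(sites))
  truth <- surface_value(surf, sites)
  for (cmp in 1:4) {
    mm <- meas[meas$campaign == cmp, ]
    expect_equal(mm$conc_ugm3, truth, tolerance = 1e-12)
  }
})

test_that("seasonal signs: formaldehyde warm > cold, NO2 cold > warm", {
  sites <- test_sites()
  for (rep_seed in 1:5) {
    fs <- formaldehyde_spec()
    surf <- make_surface(fs, sites)
    meas <- simulate_campaign_measurements(surf, sites, fs,
                                           missing_rate = 0.1,
                                           seed = rep_seed)
    warm <- mean(meas$conc_ugm3[meas$season == "warm"])
    cold <- mean(meas$conc_ugm3[meas$season == "cold"])
    expect_gt(warm, cold)
    ns <- no2_spec()
    surf2 <- make_surface(ns, sites)
    meas2 <- simulate_campaign_measurements(surf2, sites, ns,
                                            missing_rate = 0.1,
                                            seed = rep_seed)
    expect_gt(mean(meas2$conc_ugm3[meas2$season == "cold"]),
              mean(meas2$conc_ugm3[meas2$season == "warm"]))
  }
})

test_that("missingness never removes a whole site and leaves a complete site", {
  fs <- formaldehyde_spec()
  sites <- test_sites(20)
  surf <- make_surface(fs, sites)
  for (s in 1:10) {
    meas <- simulate_campaign_measurements(surf, sites, fs,
                                           missing_rate = 0.35, seed = s)
    tab <- table(meas$site_id)
    expect_true(all(sites$site_id %in% names(tab)))
    expect_true(any(tab == 4))
    expect_true(all(meas$conc_ugm3 > 0))
  }
})

test_that("campaign corrections follow the difference method", {
  # two complete sites with campaign means (3, 3, 1, 1) -> Delta (+1,+1,-1,-1)
  meas <- data.frame(
    site_id = rep(c("a", "b"), each = 4),
    x_km = rep(c(1, 2), each = 4), y_km = rep(c(1, 2), each = 4),
    campaign = rep(1:4, 2),
    conc_ugm3 = c(3.5, 3.5, 1.5, 1.5, 2.5, 2.5, 0.5, 0.5))
  delta <- campaign_corrections(meas)
  expect_equal(unname(delta), c(1, 1, -1, -1), ignore_attr = TRUE)
  expect_equal(sum(delta), 0)
  # identical campaigns -> zero corrections
  meas0 <- meas; meas0$conc_ugm3 <- rep(c(2, 3), each = 4)
  expect_equal(unname(campaign_corrections(meas0)), rep(0, 4),
               ignore_attr = TRUE)
  # incomplete-only data cannot be anchored
  expect_error(campaign_corrections(meas[meas$campaign < 4, ]),
               "cannot anchor")
})

test_that("annual means: identity on complete sites, correction on partial ones", {
  meas <- data.frame(
    site_id = rep(c("a", "b"), each = 4),
    x_km = rep(c(1, 2), each = 4), y_km = rep(c(1, 2), each = 4),
    campaign = rep(1:4, 2),
    conc_ugm3 = c(3.5, 3.5, 1.5, 1.5, 2.5, 2.5, 0.5, 0.5))
  delta <- campaign_corrections(meas)
  # a site observed only in the two warm campaigns with raw values (5, 5)
  part <- rbind(meas, data.frame(site_id = "c", x_km = 3, y_km = 3,
                                 campaign = 1:2, conc_ugm3 = c(5, 5)))
  ann <- annual_site_means(part, delta)
  expect_equal(ann$annual_ugm3[ann$site_id == "c"], 4)
  # complete sites: adjusted annual mean == raw mean, corrections or not
  raw_a <- mean(meas$conc_ugm3[meas$site_id == "a"])
  expect_equal(ann$annual_ugm3[ann$site_id == "a"], raw_a,
               tolerance = 1e-12)
  expect_equal(ann$n_campaigns_used, c(4L, 4L, 2L))
})

test_that("adjustment reduces annual-mean error under seasonal imbalance", {
  # small paired simulation; the full 100-replicate version runs in the
  # acceptance suite
  fs <- no2_spec()
  sites <- test_sites(20, seed = 9)
  surf <- make_surface(fs, sites)
  truth <- surface_value(surf, sites)
  better <- logical(20)
  for (s in seq_len(20)) {
    meas <- simulate_campaign_measurements(surf, sites, fs,
                                           missing_rate = 0.3, seed = 100 + s)
    ann <- suppressWarnings(annual_site_means(meas))
    raw <- tapply(meas$conc_ugm3, factor(meas$site_id, unique(meas$site_id)),
                  mean)
    mae_adj <- mean(abs(ann$annual_ugm3 - truth[match(ann$site_id,
                                                      sites$site_id)]))
    mae_raw <- mean(abs(as.numeric(raw) - truth[match(names(raw),
                                                      sites$site_id)]))
    better[s] <- mae_adj < mae_raw
  }
  expect_gt(mean(better), 0.8)
})
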