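#' Default covariate category frequencies
#'
#' Marginal frequencies for the questionnaire covariates of the simulated
#' cohort, matched to the observed characteristics of the study children.
#' Residential traffic is stratum-specific (children near the industries
#' report more traffic), which induces mild confounding between exposure
#' and traffic; all other covariates are drawn independently of location.
#'
#' @return a named list of frequency specifications; every categorical
#'   entry sums to 1.
#' @export
default_covariate_freqs <- function() {
  list(
    female = 0.44,
    foreign = 0.09,
    educ = c(primary = 0.027, secondary = 0.277, high = 0.533,
             university = 0.163),
    smoking_parents = 0.29,
    smoke_home = 0.11,
    traffic_high = c(ge4km = 0.556, small_factory_lt4km = 0.554,
                     chipboard_lt2km = 0.688),
    ortho = 0.196,
    dmft = 0.45,
    collector = c(unassisted = 0.141, assisted = 0.637, health = 0.222),
    air_refresh = c(lt15min = 0.245, about30min = 0.301, ge1h = 0.454),
    house_new = 0.152,
    furniture = c(none = 0.219, lt3y = 0.317, ge3y = 0.464),
    double_glazing = 0.66,
    mover = 0.09,
    age_range = c(6, 12),
    cells_full_prob = 0.85,
    cells_range = c(20, 49))
}

check_freqs <- function(freqs) {
  for (nm in c("educ", "collector", "air_refresh", "furniture")) {
    if (abs(sum(freqs[[nm]]) - 1) > 1e-8)
      stop(sprintf("covariate frequencies for '%s' must sum to 1", nm))
  }
  invisible(TRUE)
}

draw_cat <- function(n, freqs) {
  factor(sample(names(freqs), n, replace = TRUE, prob = freqs),
         levels = names(freqs))
}

#' Generate a cohort of children (no outcomes yet)
#'
#' Residences are placed uniformly inside each distance stratum's region
#' (rejection sampling inside the district extent); covariates are drawn
#' with the given frequencies; age is uniform on the configured range.
#'
#' @param district a [district_spec()].
#' @param n_per_stratum children sampled per stratum (default 250, as in
#'   the study design).
#' @param covariate_freqs see [default_covariate_freqs()].
#' @param seed integer seed.
#' @return data frame, one row per child: `child_id`, `x_km`, `y_km`,
#'   `stratum`, distances to factories, covariates, `cells_examined`,
#'   `mover`.
#' @export
generate_cohort <- function(district, n_per_stratum = 250,
                            covariate_freqs = default_covariate_freqs(),
                            seed) {
  stopifnot(n_per_stratum >= 1)
  if (missing(seed)) stop("a seed is required")
  check_freqs(covariate_freqs)
  set.seed(seed)
  e <- district$extent
  strata <- c("chipboard_lt2km", "small_factory_lt4km", "ge4km")
  res <- vector("list", 3)
  for (s in seq_along(strata)) {
    got <- matrix(numeric(0), 0, 2)
    for (tries in 1:200) {
      m <- max(4 * n_per_stratum, 400)
      cand <- cbind(runif(m, e["xmin"], e["xmax"]),
                    runif(m, e["ymin"], e["ymax"]))
      lab <- distance_strata(cand, district)
      got <- rbind(got, cand[lab == strata[s], , drop = FALSE])
      if (nrow(got) >= n_per_stratum) break
    }
    if (nrow(got) < n_per_stratum)
      stop(sprintf(paste0("stratum '%s' region appears empty or tiny: only ",
                          "%d of %d residences placed (check distance ",
                          "thresholds against the extent)"),
                   strata[s], nrow(got), n_per_stratum))
    res[[s]] <- got[seq_len(n_per_stratum), , drop = FALSE]
  }
  xy <- do.call(rbind, res)
  n <- nrow(xy)
  f <- covariate_freqs
  cohort <- data.frame(
    child_id = sprintf("C%04d", seq_len(n)),
    x_km = xy[, 1], y_km = xy[, 2],
    stratum = factor(rep(strata, each = n_per_stratum), levels = strata),
    sex = factor(ifelse(runif(n) < f$female, "female", "male"),
                 levels = c("male", "female")),
    age = runif(n, f$age_range[1], f$age_range[2]),
    nationality = factor(ifelse(runif(n) < f$foreign, "foreign", "italian"),
                         levels = c("italian", "foreign")),
    educ = draw_cat(n, f$educ),
    smoking_parents = rbinom(n, 1, f$smoking_parents),
    smoke_home = rbinom(n, 1, f$smoke_home),
    air_refresh = draw_cat(n, f$air_refresh),
    ortho = rbinom(n, 1, f$ortho),
    dmft = rbinom(n, 1, f$dmft),
    collector = draw_cat(n, f$collector),
    house_new = rbinom(n, 1, f$house_new),
    furniture = draw_cat(n, f$furniture),
    double_glazing = rbinom(n, 1, f$double_glazing),
    mover = rbinom(n, 1, f$mover) == 1)
  cohort$traffic <- rbinom(n, 1, f$traffic_high[as.character(cohort$stratum)])
  cohort$d_chipboard_km <- min_dist_to(xy, district$chipboard)
  cohort$d_small_km <- min_dist_to(xy, district$small_factories)
  full <- runif(n) < f$cells_full_prob
  cohort$cells_examined <- ifelse(
    full, 50L, as.integer(round(runif(n, f$cells_range[1], f$cells_range[2]))))
  cohort
}
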