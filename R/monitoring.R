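#' Simulate passive-sampler campaign measurements
#'
#' Four one-week campaigns (two warm, two cold) at the monitoring sites. A
#' measurement is the latent annual surface value at the site, plus the
#' campaign's seasonal offset (the campaign-mean level minus the average of
#' the four campaign-mean levels, so offsets sum to zero), plus sampler
#' noise. Missingness is applied independently by site x campaign; a draw
#' that would remove all four campaigns of a site, or leave no fully
#' complete site, is redrawn.
#'
#' @param surface an `exposure_surface` from [generate_pollution_field()].
#' @param sites data frame with `site_id`, `x_km`, `y_km`.
#' @param spec the [pollutant_field_spec()] (seasonal means, noise SD).
#' @param missing_rate probability a site x campaign measurement is lost.
#' @param seed integer seed.
#' @param max_redraws bound on missingness redraws.
#' @return data frame of observed measurements: `site_id`, `x_km`, `y_km`,
#'   `campaign` (1-4), `season` ("warm"/"cold"), `pollutant`, `conc_ugm3`.
#' @export
simulate_campaign_measurements <- function(surface, sites, spec,
                                           missing_rate = 0.1, seed,
                                           max_redraws = 100) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (missing(seed)) stop("a seed is required")
  ns <- nrow(sites)
  truth <- surface_value(surface, sites)
  seasons <- c("warm", "warm", "cold", "cold")
  camp_mean <- spec$season_means[seasons]
  offsets <- camp_mean - mean(camp_mean)

  set.seed(seed)
  noise <- matrix(rnorm(ns * 4, sd = spec$noise_sd), ns, 4)
  conc <- outer(truth, rep(1, 4)) + outer(rep(1, ns), offsets) + noise
  # keep concentrations positive by redrawing the sampler noise
  for (i in 1:50) {
    bad <- conc <= 0
    if (!any(bad)) break
    conc[bad] <- (outer(truth, rep(1, 4)) + outer(rep(1, ns), offsets))[bad] +
      rnorm(sum(bad), sd = spec$noise_sd)
  }
  conc[conc <= 0] <- 1e-6

  obs <- matrix(TRUE, ns, 4)
  if (missing_rate > 0) {
    ok <- FALSE
    for (i in seq_len(max_redraws)) {
      obs <- matrix(runif(ns * 4) >= missing_rate, ns, 4)
      if (all(rowSums(obs) >= 1) && any(rowSums(obs) == 4)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not draw a missingness pattern leaving every site ",
                  "with >= 1 campaign and >= 1 site complete")
  }

  out <- data.frame(
    site_id = rep(sites$site_id, 4),
    x_km = rep(sites$x_km, 4),
    y_km = rep(sites$y_km, 4),
    campaign = rep(1:4, each = ns),
    season = rep(seasons, each = ns),
    pollutant = spec$pollutant,
    conc_ugm3 = as.vector(conc))
  out[as.vector(obs), , drop = FALSE]
}

#' Campaign correction terms for temporal adjustment
#'
#' Difference-method temporal adjustment for multi-campaign passive-sampler
#' data: over the sites with all four campaigns observed, compute each
#' campaign's mean concentration \eqn{A_c} and the grand mean
#' \eqn{\bar A = \mathrm{mean}(A_1,\dots,A_4)}; the correction is
#' \eqn{\Delta_c = A_c - \bar A}, to be subtracted from every measurement in
#' campaign \eqn{c}. The corrections sum to zero, so a complete site's
#' adjusted annual mean equals its raw four-campaign mean.
#'
#' @param measurements data frame with `site_id`, `campaign`, `conc_ugm3`.
#' @return named numeric vector `Delta` of length 4 with attributes
#'   `complete_sites` (site ids used) and `campaign_means`.
#' @export
campaign_corrections <- function(measurements) {
  stopifnot(all(c("site_id", "campaign", "conc_ugm3") %in% names(measurements)))
  tab <- table(measurements$site_id, measurements$campaign)
  complete <- rownames(tab)[rowSums(tab > 0) == 4]
  if (!length(complete))
    stop("cannot anchor temporal adjustment: no site has all 4 campaigns")
  m <- measurements[measurements$site_id %in% complete, ]
  A <- as.numeric(tapply(m$conc_ugm3, factor(m$campaign, levels = 1:4), mean))
  delta <- A - mean(A)
  names(delta) <- as.character(1:4)
  attr(delta, "complete_sites") <- complete
  attr(delta, "campaign_means") <- A
  delta
}

#' Adjusted annual site means
#'
#' Subtract the campaign corrections from each measurement and average the
#' available adjusted measurements per site. Negative adjusted
#' concentrations are clipped to zero (count reported via attribute and a
#' warning).
#'
#' @param measurements data frame with `site_id`, `x_km`, `y_km`,
#'   `campaign`, `conc_ugm3`.
#' @param corrections result of [campaign_corrections()]; computed from
#'   `measurements` when omitted.
#' @return data frame `site_id`, `x_km`, `y_km`, `annual_ugm3`,
#'   `n_campaigns_used`, with attributes `corrections` and `n_clipped`.
#' @export
annual_site_means <- function(measurements, corrections = NULL) {
  if (is.null(corrections)) corrections <- campaign_corrections(measurements)
  adj <- measurements$conc_ugm3 -
    corrections[as.character(measurements$campaign)]
  n_clip <- sum(adj < 0)
  if (n_clip > 0) {
    warning(sprintf("%d adjusted concentrations were negative; clipped to 0",
                    n_clip))
    adj[adj < 0] <- 0
  }
  sid <- factor(measurements$site_id, levels = unique(measurements$site_id))
  out <- data.frame(
    site_id = levels(sid),
    x_km = tapply(measurements$x_km, sid, `[`, 1),
    y_km = tapply(measurements$y_km, sid, `[`, 1),
    annual_ugm3 = as.numeric(tapply(adj, sid, mean)),
    n_campaigns_used = as.integer(tapply(adj, sid, length)),
    row.names = NULL)
  attr(out, "corrections") <- corrections
  attr(out, "n_clipped") <- n_clip
  out
}
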