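#!/usr/bin/env Rscript
# Stage 3 — simulate the four 1-week campaigns and compute adjusted annual
# site means.
#
# Two warm and two cold campaigns with pollutant-specific seasonal levels
# (formaldehyde higher in the warm season, NO2 in the cold one), sampler
# noise and 10% site-by-campaign missingness. Annual means use the
# difference-method temporal adjustment: campaign corrections computed over
# the complete sites are subtracted from every measurement before
# averaging.

library(genokrig)

seed <- 20251001
district <- district_spec()
cohort <- read.csv("results/cohort.csv")
sites <- read.csv("results/sites.csv")

all_meas <- list()
for (pol in c("hcho", "no2")) {
  spec <- if (pol == "hcho") formaldehyde_spec() else no2_spec()
  surf <- generate_pollution_field(spec, district, grid_resolution = 0.5,
                                   seed = seed + match(pol, c("hcho", "no2")),
                                   at_points = rbind(as.matrix(sites[, c("x_km", "y_km")]),
                                                     as.matrix(cohort[, c("x_km", "y_km")])))
  meas <- simulate_campaign_measurements(surf, sites, spec,
                                         missing_rate = 0.1,
                                         seed = seed + 10 + match(pol, c("hcho", "no2")))
  all_meas[[pol]] <- meas
  ann <- annual_site_means(meas)
  write.csv(ann, sprintf("results/annual_%s.csv", pol), row.names = FALSE)
  wm <- mean(meas$conc_ugm3[meas$season == "warm"])
  cm <- mean(meas$conc_ugm3[meas$season == "cold"])
  delta <- attr(ann, "corrections")
  cat(sprintf("%s: warm %.2f vs cold %.2f ug/m3; annual %.2f +/- %.2f over %d sites\n",
              pol, wm, cm, mean(ann$annual_ugm3), sd(ann$annual_ugm3),
              nrow(ann)))
  cat(sprintf("   campaign corrections: %s (sum %.2g)\n",
              paste(sprintf("%+.2f", delta), collapse = ", "), sum(delta)))
}
write.csv(do.call(rbind, all_meas), "results/monitoring.csv",
          row.names = FALSE)
cat("formaldehyde is higher in the warm season and NO2 in the cold season,\n")
cat("as the seasonal level specification dictates.\n")
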