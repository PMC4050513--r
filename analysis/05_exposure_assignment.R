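#!/usr/bin/env Rscript
# Stage 5 — assign standardized residential exposures.
#
# Each child's exposure is the ordinary-kriging prediction at the residence
# (direct point kriging from the annual site means with the selected
# variogram model), standardized over the cohort (sample SD). The stage
# also reports the stratum exposure contrast. For NO2 the industry kernel
# is strong relative to the stochastic field, so children near the
# chipboard industries come out the most exposed; for formaldehyde the two
# components are of comparable scale and the ordering of the (small)
# stratum contrast varies between realizations.

library(genokrig)

cohort <- read.csv("results/cohort.csv")

sources <- list()
for (pol in c("hcho", "no2")) {
  ann <- read.csv(sprintf("results/annual_%s.csv", pol))
  lb <- read.csv(sprintf("results/variogram_leaderboard_%s.csv", pol))
  b <- lb[1, ]
  sources[[pol]] <- list(sites = ann,
                         model = vgm_model(b$family, nugget = b$nugget,
                                           psill = b$psill, range = b$range,
                                           angle = b$theta, ratio = b$ratio))
}
cohort <- assign_exposure(sources, cohort)
write.csv(cohort, "results/exposed_cohort.csv", row.names = FALSE)

std <- attr(cohort, "standardization")
for (pol in c("hcho", "no2")) {
  cat(sprintf("%s: assigned exposure %.2f +/- %.2f ug/m3 (1 SD = %.2f)\n",
              pol, std[[pol]]["mean"], std[[pol]]["sd"], std[[pol]]["sd"]))
  mu <- tapply(cohort[[paste0(pol, "_ugm3")]], cohort$stratum, mean)
  cat(sprintf("   stratum means: chipboard %.2f / small factory %.2f / far %.2f\n",
              mu["chipboard_lt2km"], mu["small_factory_lt4km"], mu["ge4km"]))
  p <- anova(lm(cohort[[paste0(pol, "_ugm3")]] ~ cohort$stratum))$`Pr(>F)`[1]
  cat(sprintf("   stratum contrast p = %.2g\n", p))
}
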