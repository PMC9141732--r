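#!/usr/bin/env Rscript
# Quantity stage: estimate the Markov transition matrix from the synthetic
# pair and derive the three 2030 demand vectors — natural development from
# the Markov projection, ecological-priority and balanced from the
# constrained LP (optimal shares rescaled to the landscape total).

suppressPackageStartupMessages(library(esvland))
dir.create("results", showWarnings = FALSE)
stopifnot(file.exists("results/02_lulc_t1.asc"))  # run 02 first

t1 <- read_asc("results/02_lulc_t1.asc", integer = TRUE)
t2 <- read_asc("results/02_lulc_t2.asc", integer = TRUE)

P <- estimate_transition_matrix(t1, t2)
write.csv(data.frame(from = rownames(P), round(P, 6), check.names = FALSE),
          "results/03_transition_matrix.csv", row.names = FALSE)

total_ha <- sum(raster_area_table(t2)$area_ha)
nd <- project_areas(raster_area_table(t2), P, steps = 2)
epd_sol <- solve_epd()
eed_sol <- solve_eed(w = 0.5)
epd <- area_table(epd_sol$x / sum(epd_sol$x) * total_ha, label = "epd")
eed <- area_table(eed_sol$x / sum(eed_sol$x) * total_ha, label = "eed")

dem <- rbind(cbind(scenario = "nd", nd),
             cbind(scenario = "epd", epd),
             cbind(scenario = "eed", eed))
write.csv(dem, "results/03_demand.csv", row.names = FALSE)

# the basin-scale LP solutions themselves, in km^2 at reporting precision
sols <- rbind(
  data.frame(scenario = "epd", class = names(epd_sol$x),
             area_km2 = format_area_km2(epd_sol$x)),
  data.frame(scenario = "eed", class = names(eed_sol$x),
             area_km2 = format_area_km2(eed_sol$x)))
write.csv(sols, "results/03_lp_solutions_km2.csv", row.names = FALSE)

cat("Transition matrix (rounded):\n"); print(round(P, 3))
cat("\nDemand (ha):\n"); print(dem)
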