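#!/usr/bin/env Rscript
# Generate the synthetic basin used by the spatial stages: a two-date
# land-use pair with the published class composition, an elevation model,
# and the nine driver layers. Everything is written as ESRI ASCII grids plus
# the YAML generator config, so later stages (and readers) can reload them.

suppressPackageStartupMessages(library(esvland))
dir.create("results", showWarnings = FALSE)

cfg <- landscape_config(seed = 20240101)
write_landscape_config(cfg, "results/02_landscape_config.yaml")

pair <- generate_lulc_pair(cfg)
dem <- generate_dem(cfg)
drivers <- generate_drivers(dem, pair$t1, cfg)

write_asc(pair$t1, "results/02_lulc_t1.asc")
write_asc(pair$t2, "results/02_lulc_t2.asc")
write_asc(dem, "results/02_dem.asc")
for (nm in names(drivers))
  write_asc(drivers[[nm]], sprintf("results/02_driver_%s.asc", nm))

areas <- rbind(cbind(date = "t1", pair$areas_t1),
               cbind(date = "t2", pair$areas_t2))
write.csv(areas, "results/02_areas.csv", row.names = FALSE)

cat("Grid:", cfg$n_rows, "x", cfg$n_cols, "cells at", cfg$cell_size, "m\n")
cat("Class shares at t2:\n")
print(data.frame(class = pair$areas_t2$class_name,
                 share = round(pair$areas_t2$area_ha /
                                 sum(pair$areas_t2$area_ha), 4)))
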