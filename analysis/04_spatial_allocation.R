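#!/usr/bin/env Rscript
# Spatial stage: fit per-class suitability surfaces from the observed
# expansion (random forests over the driver stack), validate the CA by
# hindcasting t2 from t1, then allocate each 2030 demand vector with the
# patch-generating CA.

suppressPackageStartupMessages(library(esvland))
dir.create("results", showWarnings = FALSE)
stopifnot(file.exists("results/03_demand.csv"))   # run 02 and 03 first

t1 <- read_asc("results/02_lulc_t1.asc", integer = TRUE)
t2 <- read_asc("results/02_lulc_t2.asc", integer = TRUE)
driver_files <- Sys.glob("results/02_driver_*.asc")
drivers <- lapply(driver_files, read_asc)
names(drivers) <- sub("^02_driver_(.*)\\.asc$", "\\1", basename(driver_files))

samples <- extract_expansion_samples(t1, t2, drivers, seed = 11)
suit <- fit_suitability(samples, drivers, n_trees = 50, seed = 11)

# hindcast validation: allocate the observed t2 demand starting from t1
hind <- run_cars(t1, suit, raster_area_table(t2),
                 params = ca_params(seed = 12))
val <- validate_maps(hind$raster, t2)
write.csv(data.frame(metric = c("overall_accuracy", "kappa"),
                     value = c(val$overall_accuracy, val$kappa)),
          "results/04_validation.csv", row.names = FALSE)
cat(sprintf("Hindcast: OA %.4f, kappa %.4f, converged %s\n",
            val$overall_accuracy, val$kappa, hind$converged))

dem <- read.csv("results/03_demand.csv")
for (sc in c("nd", "epd", "eed")) {
  d <- dem[dem$scenario == sc, ]
  res <- run_cars(t2, suit, d[order(d$class_code), "area_ha"],
                  params = ca_params(seed = 13, max_iter = 1000))
  write_asc(res$raster, sprintf("results/04_alloc_%s.asc", sc))
  write.csv(res$log, sprintf("results/04_log_%s.csv", sc), row.names = FALSE)
  cat(sprintf("%s: converged %s in %d iterations\n", sc, res$converged,
              nrow(res$log)))
}
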