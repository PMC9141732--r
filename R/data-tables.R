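# Packaged study constants: the published per-hectare ESV coefficient table,
# the per-date/per-scenario class area tables, and the scenario correlation
# table used as a ranking fixture.

#' ESV coefficient table for the study basin
#'
#' Per-hectare annual ecosystem-service values (CNY ha^-1 a^-1) for nine
#' secondary services across the six land-use classes, derived from the
#' Chinese terrestrial-ecosystem equivalent table revised by regional grain
#' price (the farmland base value) and a biomass factor. Row attribute
#' `category` maps each service to its primary category (supplying,
#' regulating, supporting, cultural).
#'
#' @return a 9 x 6 numeric matrix with service rownames, class colnames and a
#'   `category` attribute (length-9 character).
#' @export
esv_coefficients <- function() {
  V <- rbind(
    food_production      = c(650.35,  112.13,  257.90,   224.26,  0,    11.21),
    raw_material         = c(100.92, 2915.37,  381.24,    44.85,  0,    16.82),
    gas_conditioning     = c(1244.64, 3924.53, 1356.77,  1009.17, 0,    11.21),
    climate_regulation   = c(571.86, 3027.50, 3576.93,  9844.97,  0,    78.49),
    water_conservation   = c(672.78, 3588.14,  897.04, 20116.02,  0,    33.64),
    waste_disposal       = c(1838.92, 1468.90, 1468.90, 20385.13, 0,    11.21),
    soil_formation       = c(11.21,  4373.05, 1513.75,   964.31,  0,    22.43),
    biodiversity         = c(235.47, 3655.42, 1502.53,  2803.24,  0,   381.24),
    aesthetic_landscape  = c(100.92, 1435.26,  661.56,  5550.41, 11.21, 11.21))
  colnames(V) <- lulc_classes()
  attr(V, "category") <- c("supplying", "supplying",
                           "regulating", "regulating", "regulating", "regulating",
                           "supporting", "supporting",
                           "cultural")
  V
}

#' Primary service categories
#' @export
esv_categories <- function() c("supplying", "regulating", "supporting", "cultural")

#' Published basin area tables, 1980-2020 and the three 2030 scenarios
#'
#' Class areas (converted from the published km2 values to hectares) for the
#' observed dates 1980-2020 and the three 2030 scenarios: `nd` (natural
#' development, Markov projection), `epd` (ecological priority), `eed`
#' (balanced ecological-economic).
#'
#' @param which a label among `"1980","1990","2000","2010","2020","nd","epd","eed"`,
#'   or `NULL` for the full named list.
#' @return an [area_table] (or a named list of them).
#' @export
basin_areas <- function(which = NULL) {
  km2 <- rbind(
    `1980` = c(5786.59, 536.29, 11281.16,  867.08, 288.43, 15291.96),
    `1990` = c(5919.35, 551.09, 11271.38,  907.11, 365.42, 15037.16),
    `2000` = c(6557.07, 473.64, 10601.43,  916.78, 410.77, 15091.80),
    `2010` = c(7328.37, 460.77, 10162.20,  933.06, 444.59, 14722.51),
    `2020` = c(7804.49, 455.52,  9663.77, 1048.93, 542.70, 14536.10),
    nd     = c(7807.49, 433.20,  9666.02, 1295.35, 568.94, 14280.50),
    epd    = c(7700.22, 493.29,  9679.65, 1322.70, 569.96, 14285.70),
    eed    = c(7550.26, 455.68,  9807.96, 1301.60, 607.71, 14328.29))
  tabs <- lapply(rownames(km2), function(lbl) area_table(km2[lbl, ] * 100, label = lbl))
  names(tabs) <- rownames(km2)
  if (is.null(which)) return(tabs)
  if (!which %in% names(tabs)) stop("unknown area table label: ", which)
  tabs[[which]]
}

#' Published scenario correlation table (ranking fixture)
#'
#' Pearson correlation coefficients and bivariate global Moran's I between the
#' four primary service categories under the three 2030 scenarios, as
#' published for the real basin rasters. Shipped only to exercise
#' [synergy_ranking()]; these values cannot be recomputed without the real
#' GIS layers.
#'
#' @return data.frame with columns `pair`, `pearson_nd`, `pearson_epd`,
#'   `pearson_eed`, `moran_nd`, `moran_epd`, `moran_eed`.
#' @export
scenario_correlations <- function() {
  data.frame(
    pair = c("supplying-regulating", "supplying-supporting",
             "supplying-cultural", "regulating-supporting",
             "regulating-cultural", "supporting-cultural"),
    pearson_nd  = c(0.243, 0.606, 0.142, 0.550, 0.987, 0.563),
    pearson_epd = c(0.256, 0.597, 0.150, 0.547, 0.986, 0.562),
    pearson_eed = c(0.261, 0.609, 0.157, 0.551, 0.986, 0.563),
    moran_nd    = c(0.190, 0.466, 0.097, 0.385, 0.637, 0.395),
    moran_epd   = c(0.206, 0.468, 0.110, 0.380, 0.621, 0.394),
    moran_eed   = c(0.214, 0.474, 0.119, 0.380, 0.614, 0.389))
}
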