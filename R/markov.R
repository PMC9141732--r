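# Markov-chain land-use demand: transition-probability estimation from a
# raster pair and area projection (the natural-development scenario and the
# quantity input to the cellular automaton).

#' Estimate a transition-probability matrix from two land-use rasters
#'
#' Cross-tabulates aligned categorical rasters: `P[k, c]` is the fraction of
#' class-`k` cells at the first date observed as class `c` at the second.
#' Classes absent at the first date get identity rows.
#'
#' @param t1,t2 aligned categorical [land_raster]s (same nodata mask).
#' @return 6 x 6 row-stochastic matrix with class dimnames and attribute
#'   `counts` (the raw cross-tabulation).
#' @export
estimate_transition_matrix <- function(t1, t2) {
  check_aligned(t1, t2)
  v1 <- raster_values(t1); v2 <- raster_values(t2)
  ok <- !is.na(v1) & !is.na(v2)
  if (!identical(which(is.na(v1)), which(is.na(v2))))
    stop("rasters have different nodata masks")
  counts <- matrix(0, 6, 6, dimnames = list(lulc_classes(), lulc_classes()))
  tab <- table(factor(v1[ok], levels = 1:6), factor(v2[ok], levels = 1:6))
  counts[] <- as.numeric(tab)
  P <- counts / pmax(rowSums(counts), 1)
  absent <- rowSums(counts) == 0
  P[absent, ] <- 0
  diag(P)[absent] <- 1
  attr(P, "counts") <- counts
  P
}

#' Project class areas through a transition matrix
#'
#' `areas' = areas %*% P^steps`; total area is conserved exactly (row
#' stochasticity).
#'
#' @param areas an [area_table] (or length-6 ha vector).
#' @param P 6 x 6 row-stochastic matrix.
#' @param steps number of transition periods (>= 0).
#' @return an [area_table] of projected areas.
#' @export
project_areas <- function(areas, P, steps = 2) {
  if (steps < 0) stop("steps must be >= 0")
  if (any(abs(rowSums(P) - 1) > 1e-9)) stop("P rows must sum to 1")
  a <- if (is.data.frame(areas)) areas$area_ha else as.numeric(areas)
  for (i in seq_len(steps)) a <- drop(a %*% P)
  area_table(a, label = sprintf("projected+%d", steps))
}
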