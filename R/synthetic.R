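# Synthetic desk-scale basins: a south-high/north-low elevation surface, six
# spatially autocorrelated land-use classes zoned mountain -> oasis -> desert,
# controlled patchy between-date transitions, and aligned continuous driver
# layers. Everything is deterministic for a fixed config seed.

#' Landscape generator configuration
#'
#' @param n_rows,n_cols grid dimensions (>= 8 each). Row 1 is the northern
#'   edge; elevation rises southwards (mountain-oasis-desert zonation).
#' @param cell_size cell edge in metres (default 100).
#' @param class_fractions target share per class, summing to 1. The default
#'   is the published 2020 basin composition.
#' @param autocorr_range Gaussian smoothing length of the latent fields, in
#'   cells.
#' @param transition_rates 6 x 6 row-stochastic per-step change matrix
#'   applied between the two generated dates.
#' @param dem_noise sd of the smoothed elevation noise, metres.
#' @param elev_range min/max elevation of the south-north ramp, metres.
#' @param seed RNG seed.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(n_rows = 200, n_cols = 200, cell_size = 100,
                             class_fractions = default_class_fractions(),
                             autocorr_range = 8,
                             transition_rates = default_transition_rates(),
                             dem_noise = 300,
                             elev_range = c(250, 5200),
                             seed = 42) {
  stopifnot(n_rows >= 8, n_cols >= 8, cell_size > 0)
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  if (length(class_fractions) != 6 || any(class_fractions < 0))
    stop("class_fractions must be 6 non-negative shares")
  if (any(transition_rates < 0) || any(transition_rates > 1) ||
      any(abs(rowSums(transition_rates) - 1) > 1e-9))
    stop("transition_rates must be row-stochastic with entries in [0,1]")
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 class_fractions = class_fractions,
                 autocorr_range = autocorr_range,
                 transition_rates = transition_rates,
                 dem_noise = dem_noise, elev_range = elev_range, seed = seed),
            class = "landscape_config")
}

#' @rdname landscape_config
#' @export
default_class_fractions <- function() {
  a <- basin_areas("2020")$area_ha
  stats::setNames(a / sum(a), lulc_classes())
}

#' @rdname landscape_config
#' @export
default_transition_rates <- function() {
  # diag-dominant flows mirroring the basin's observed direction of change:
  # grassland/unused -> farmland, unused -> construction/water, plus small
  # afforestation/revegetation flows so that every class that can grow under
  # the planning scenarios also shows historical expansion (the suitability
  # model learns only from observed expansion).
  P <- diag(6)
  dimnames(P) <- list(lulc_classes(), lulc_classes())
  P["grassland", "farmland"] <- 0.03
  P["grassland", "woodland"] <- 0.005
  P["grassland", "unused"] <- 0.003
  P["unused", "farmland"] <- 0.01
  P["unused", "grassland"] <- 0.01
  P["unused", "construction"] <- 0.005
  P["unused", "water"] <- 0.005
  P["farmland", "construction"] <- 0.01
  P["farmland", "grassland"] <- 0.005
  P["farmland", "woodland"] <- 0.002
  diag(P) <- 1 - (rowSums(P) - diag(P))
  P
}

#' Read / write a landscape config as YAML
#' @param path file path.
#' @export
read_landscape_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$class_fractions <- unlist(y$class_fractions)
  y$transition_rates <- matrix(unlist(y$transition_rates), 6, 6, byrow = TRUE,
                               dimnames = list(lulc_classes(), lulc_classes()))
  do.call(landscape_config, y)
}

#' @rdname read_landscape_config
#' @param config a `landscape_config`.
#' @export
write_landscape_config <- function(config, path) {
  y <- unclass(config)
  y$class_fractions <- as.list(y$class_fractions)
  y$transition_rates <- lapply(seq_len(nrow(y$transition_rates)),
                               function(i) as.numeric(y$transition_rates[i, ]))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

# Gaussian-smoothed standard-normal field (approximately unit variance after
# renormalization); the smoothing sd in cells sets the autocorrelation range.
smooth_field <- function(n_rows, n_cols, range) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range <= 0) return(z)
  r <- max(1L, ceiling(2 * range))
  k <- stats::dnorm(seq(-r, r), sd = range)
  k <- k / sum(k)
  z <- conv_sep(z, k)
  z / stats::sd(z)
}

# Separable convolution with reflected edges.
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  pad_conv <- function(mm) {
    top <- mm[rev(seq_len(min(r, nrow(mm)))), , drop = FALSE]
    bot <- mm[nrow(mm) + 1 - rev(seq_len(min(r, nrow(mm)))), , drop = FALSE]
    padded <- rbind(top, mm, bot)
    out <- matrix(0, nrow(mm), ncol(mm))
    for (i in seq_along(k))
      out <- out + k[i] * padded[(i - 1) + seq_len(nrow(mm)), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(m))))
}

#' Synthetic elevation surface
#'
#' Monotone south-to-north ramp (southern rows high) plus Gaussian-smoothed
#' noise; deterministic for a fixed config seed.
#'
#' @param config a [landscape_config()].
#' @return a continuous [land_raster] of elevation in metres.
#' @export
generate_dem <- function(config) {
  set.seed(config$seed + 101L)
  nr <- config$n_rows; nc <- config$n_cols
  ramp <- config$elev_range[1] +
    (config$elev_range[2] - config$elev_range[1]) *
    (row(matrix(0, nr, nc)) - 1) / (nr - 1)
  noise <- if (config$dem_noise > 0)
    smooth_field(nr, nc, config$autocorr_range) * config$dem_noise
  else matrix(0, nr, nc)
  land_raster(ramp + noise, cellsize = config$cell_size)
}

# Class preference bumps along the normalized south(1) -> north(0) elevation
# axis: mountains host woodland/water, the mid-basin oasis hosts farmland and
# construction, the north is desert (unused).
class_preference <- function(elev_norm) {
  bump <- function(center, width) exp(-((elev_norm - center) / width)^2)
  list(farmland     = bump(0.45, 0.15),
       woodland     = bump(0.78, 0.10),
       grassland    = 0.7 * bump(0.60, 0.25) + 0.3 * bump(0.25, 0.2),
       water        = bump(0.90, 0.08) + 0.3 * bump(0.5, 0.05),
       construction = bump(0.40, 0.08),
       unused       = bump(0.05, 0.18) + 0.5 * bump(1.0, 0.06))
}

#' Synthetic land-use raster pair with controlled transitions
#'
#' Builds the first-date map by ranking per-class suitability scores
#' (elevation-zone preference plus a smoothed class-specific noise field) and
#' filling exact target cell counts from the configured class fractions; the
#' second date applies `transition_rates` cellwise, selecting for each
#' source-target pair the top scoring cells of a smoothed pair-specific
#' change field, so change arrives in patches.
#'
#' @param config a [landscape_config()].
#' @return list with `t1`, `t2` (categorical [land_raster]s) and `areas_t1`,
#'   `areas_t2` ([area_table]s).
#' @export
generate_lulc_pair <- function(config) {
  set.seed(config$seed + 202L)
  nr <- config$n_rows; nc <- config$n_cols
  n <- nr * nc
  dem <- generate_dem(config)
  e <- raster_values(dem)
  elev_norm <- (e - min(e)) / (max(e) - min(e))
  pref <- class_preference(elev_norm)
  scores <- lapply(seq_len(6), function(k)
    2 * pref[[k]] + smooth_field(nr, nc, config$autocorr_range))
  # exact target counts (largest-remainder rounding)
  tgt <- config$class_fractions * n
  cnt <- floor(tgt)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(tgt - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  t1 <- integer(n)
  unassigned <- rep(TRUE, n)
  for (k in order(cnt)) {              # scarcest classes choose first
    if (cnt[k] == 0) next
    s <- as.numeric(scores[[k]])
    s[!unassigned] <- -Inf
    pick <- order(s, decreasing = TRUE)[seq_len(cnt[k])]
    t1[pick] <- k
    unassigned[pick] <- FALSE
  }
  m1 <- matrix(t1, nr, nc)
  # patchy transitions on top of t1
  m2 <- m1
  P <- config$transition_rates
  for (k in 1:6) {
    src <- which(m1 == k)
    if (length(src) == 0) next
    avail <- rep(TRUE, length(src))
    for (cc in setdiff(order(P[k, ], decreasing = TRUE), k)) {
      r <- P[k, cc]
      if (r <= 0) next
      n_change <- round(r * length(src))
      if (n_change == 0) next
      fld <- as.numeric(smooth_field(nr, nc, config$autocorr_range))[src]
      fld[!avail] <- -Inf
      n_change <- min(n_change, sum(avail))
      pick <- order(fld, decreasing = TRUE)[seq_len(n_change)]
      m2[src[pick]] <- cc
      avail[pick] <- FALSE
    }
  }
  r1 <- land_raster(m1, cellsize = config$cell_size, nodata = 0L)
  r2 <- land_raster(m2, cellsize = config$cell_size, nodata = 0L)
  list(t1 = r1, t2 = r2,
       areas_t1 = raster_area_table(r1, "t1"),
       areas_t2 = raster_area_table(r2, "t2"))
}

# Chamfer 3-4 two-pass distance transform; returns distances in metres
# (exact zero on feature cells, ~5 % worst-case error off-feature).
distance_transform <- function(mask, cellsize) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- 3 * (nr + nc)
  d <- ifelse(mask, 0, big)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- d[i, j]
    if (i > 1) v <- min(v, d[i - 1, j] + 3)
    if (j > 1) v <- min(v, d[i, j - 1] + 3)
    if (i > 1 && j > 1) v <- min(v, d[i - 1, j - 1] + 4)
    if (i > 1 && j < nc) v <- min(v, d[i - 1, j + 1] + 4)
    d[i, j] <- v
  }
  for (i in rev(seq_len(nr))) for (j in rev(seq_len(nc))) {
    v <- d[i, j]
    if (i < nr) v <- min(v, d[i + 1, j] + 3)
    if (j < nc) v <- min(v, d[i, j + 1] + 3)
    if (i < nr && j < nc) v <- min(v, d[i + 1, j + 1] + 4)
    if (i < nr && j > 1) v <- min(v, d[i + 1, j - 1] + 4)
    d[i, j] <- v
  }
  d / 3 * cellsize
}

# Rasterize a random straight line crossing the grid.
line_mask <- function(nr, nc) {
  side <- sample(1:2, 1)
  if (side == 1) {   # left-right
    p0 <- c(stats::runif(1, 1, nr), 1); p1 <- c(stats::runif(1, 1, nr), nc)
  } else {           # top-bottom
    p0 <- c(1, stats::runif(1, 1, nc)); p1 <- c(nr, stats::runif(1, 1, nc))
  }
  t <- seq(0, 1, length.out = 4 * max(nr, nc))
  ri <- pmin(nr, pmax(1, round(p0[1] + t * (p1[1] - p0[1]))))
  ci <- pmin(nc, pmax(1, round(p0[2] + t * (p1[2] - p0[2]))))
  m <- matrix(FALSE, nr, nc)
  m[cbind(ri, ci)] <- TRUE
  m
}

#' Synthetic driver stack
#'
#' Continuous layers aligned to the land-use raster: slope (finite-difference
#' gradient magnitude of the elevation surface, m/m), lapse-rate temperature
#' (decreasing in elevation) and orographic precipitation (increasing),
#' GDP/population densities decaying with distance from construction cells,
#' and chamfer distance transforms from seeded road/rail lines and the water
#' cells.
#'
#' @param dem elevation [land_raster] from [generate_dem()].
#' @param lulc categorical [land_raster] (first date).
#' @param config a [landscape_config()].
#' @return named list of [land_raster]s: `elevation`, `slope`, `temperature`,
#'   `precipitation`, `gdp_density`, `pop_density`, `dist_road`, `dist_rail`,
#'   `dist_water`.
#' @export
generate_drivers <- function(dem, lulc, config) {
  check_aligned(dem, lulc)
  set.seed(config$seed + 303L)
  nr <- config$n_rows; nc <- config$n_cols
  e <- raster_values(dem)
  cs <- config$cell_size
  dzdx <- (e[, c(2:nc, nc)] - e[, c(1, 1:(nc - 1))]) / (2 * cs)
  dzdy <- (e[c(2:nr, nr), ] - e[c(1, 1:(nr - 1)), ]) / (2 * cs)
  slope <- sqrt(dzdx^2 + dzdy^2)
  temp <- 25 - 0.0065 * e + 0.5 * smooth_field(nr, nc, config$autocorr_range)
  prec <- pmax(60 + 0.035 * e + 5 * smooth_field(nr, nc, config$autocorr_range), 0)
  v <- raster_values(lulc)
  constr <- !is.na(v) & v == 5
  d_constr <- if (any(constr)) distance_transform(constr, cs) else
    matrix(5e4, nr, nc)
  gdp <- 5000 * exp(-d_constr / 2000) +
    50 * abs(smooth_field(nr, nc, config$autocorr_range))
  pop <- 800 * exp(-d_constr / 2500) +
    10 * abs(smooth_field(nr, nc, config$autocorr_range))
  road <- line_mask(nr, nc) | line_mask(nr, nc)
  rail <- line_mask(nr, nc)
  water <- !is.na(v) & v == 4
  if (!any(water)) water <- line_mask(nr, nc)
  mk <- function(m) land_raster(m, cellsize = cs)
  list(elevation = mk(e), slope = mk(slope), temperature = mk(temp),
       precipitation = mk(prec), gdp_density = mk(gdp), pop_density = mk(pop),
       dist_road = mk(distance_transform(road, cs)),
       dist_rail = mk(distance_transform(rail, cs)),
       dist_water = mk(distance_transform(water, cs)))
}
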