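# Equivalent-factor ecosystem-service valuation: farmland base-value revision,
# coefficient scaling, total/decomposed ESV, 2-km grid aggregation, Jenks
# level classification and coefficient sensitivity.

#' Farmland base value from grain statistics
#'
#' The regional base value of one equivalent factor is 1/7 of the per-hectare
#' economic value of grain production (no-labour-input assumption):
#' `E_a = (1/7) * sum(m_i * p_i * q_i) / M` with sown areas `m_i` (ha), unit
#' prices `p_i` (CNY/kg), yields `q_i` (kg/ha) and total cultivated area `M`.
#'
#' @param m sown area per crop, ha.
#' @param p unit price per crop, CNY/kg.
#' @param q yield per crop, kg/ha.
#' @param M total cultivated area, ha.
#' @return base value `E_a` in CNY/ha.
#' @export
revise_farmland_value <- function(m, p, q, M) {
  stopifnot(length(m) == length(p), length(p) == length(q))
  if (length(m) == 0) return(0)
  if (!is.finite(M) || M <= 0) stop("total cultivated area M must be positive")
  if (any(c(m, p, q) < 0)) stop("crop records must be non-negative")
  if (M < max(m)) stop("M must be at least the largest sown area")
  sum(m * p * q) / M / 7
}

#' Scale a dimensionless equivalent table to monetary coefficients
#'
#' Multiplies a table of dimensionless service equivalents by the regional
#' base value `E_a`, applying a biomass correction factor. Users working from
#' the published monetary coefficient table ([esv_coefficients()]) bypass
#' this step.
#'
#' @param equivalents 9 x 6 matrix of dimensionless equivalents.
#' @param E_a base value in CNY/ha (from [revise_farmland_value()]).
#' @param biomass_factor regional biomass correction (default 0.58).
#' @return monetary coefficient matrix in CNY ha^-1 a^-1.
#' @export
scale_equivalent_table <- function(equivalents, E_a, biomass_factor = 0.58) {
  if (!is.finite(E_a) || E_a <= 0) stop("E_a must be positive")
  out <- equivalents * E_a * biomass_factor
  attr(out, "category") <- attr(equivalents, "category")
  out
}

#' Total and decomposed ecosystem-service value
#'
#' `ESV = sum_i A_i * V_i`: areas (ha) times per-hectare coefficients, with
#' per-service (9), per-category (4) and per-class (6) decompositions.
#' Reporting is in 10^8 CNY at two decimals via [format_esv()].
#'
#' @param areas an [area_table] (or length-6 numeric vector of ha).
#' @param coeffs coefficient matrix from [esv_coefficients()].
#' @return an `esv_result`: list with `total` (CNY), `by_service`,
#'   `by_category`, `by_class` (all CNY).
#' @export
compute_esv <- function(areas, coeffs = esv_coefficients()) {
  a <- if (inherits(areas, "area_table") || is.data.frame(areas)) areas$area_ha else as.numeric(areas)
  stopifnot(length(a) == 6)
  if (any(a < 0)) stop("areas must be non-negative")
  contrib <- coeffs %*% a                       # per service
  by_class <- drop(a * colSums(coeffs))
  names(by_class) <- lulc_classes()
  by_service <- drop(contrib)
  cat_map <- attr(coeffs, "category")
  by_category <- vapply(esv_categories(),
                        function(g) sum(by_service[cat_map == g]), numeric(1))
  structure(list(total = sum(by_service), by_service = by_service,
                 by_category = by_category, by_class = by_class,
                 label = attr(areas, "label")),
            class = "esv_result")
}

#' @export
print.esv_result <- function(x, ...) {
  cat(sprintf("ESV%s: %s x10^8 CNY\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              format_esv(x$total)))
  cat("by category (10^8 CNY):\n")
  print(round(x$by_category / 1e8, 2))
  invisible(x)
}

#' Format a CNY value in 10^8 CNY at two decimals
#' @param cny value in CNY.
#' @return numeric, 10^8 CNY rounded to 2 decimals.
#' @export
format_esv <- function(cny) round(cny / 1e8, 2)

#' Change between two ESV results
#'
#' @param a,b `esv_result` objects on the same coefficient table.
#' @return list with `delta` (CNY), `delta_1e8` (10^8 CNY, 2 dp) and
#'   `percent` ((b-a)/a * 100, 2 dp), computed from unrounded totals.
#' @export
esv_change <- function(a, b) {
  if (a$total == 0) stop("baseline total is zero; percent change undefined")
  d <- b$total - a$total
  list(delta = d, delta_1e8 = format_esv(d),
       percent = round(d / a$total * 100, 2))
}

#' Per-grid-cell ESV aggregation
#'
#' Overlays a square evaluation grid (default 2 km) on a categorical land-use
#' raster and sums, per grid cell, raster-cell area times the per-class
#' coefficient. Grid cells wholly nodata are dropped (mask `FALSE`); partial
#' cells are valued by their valid area.
#'
#' @param lulc a categorical [land_raster].
#' @param coeffs coefficient matrix.
#' @param grid_size_m evaluation-grid edge in metres (default 2000).
#' @return a `service_grid`: list with matrices `total` and one per category
#'   (CNY per grid cell), logical `mask`, `grid_size_m`, and grid dims.
#' @export
esv_raster <- function(lulc, coeffs = esv_coefficients(), grid_size_m = 2000) {
  if (grid_size_m < lulc$cellsize) stop("evaluation grid smaller than raster cell")
  v <- raster_values(lulc)
  fac <- grid_size_m / lulc$cellsize
  gr <- ceiling(nrow(v) / fac)
  gc <- ceiling(ncol(v) / fac)
  row_bin <- ceiling(row(v) / fac)
  col_bin <- ceiling(col(v) / fac)
  bin <- (col_bin - 1) * gr + row_bin
  area <- cell_area_ha(lulc)
  cat_map <- attr(coeffs, "category")
  per_class_total <- colSums(coeffs)
  layers <- list(total = per_class_total)
  for (g in esv_categories())
    layers[[g]] <- colSums(coeffs[cat_map == g, , drop = FALSE])
  valid <- !is.na(v)
  out <- lapply(layers, function(cf) {
    cellval <- ifelse(valid, cf[ifelse(valid, v, 1L)] * area, 0)
    m <- matrix(0, gr, gc)
    s <- tapply(cellval, bin, sum)
    m[as.integer(names(s))] <- s
    m
  })
  nvalid <- matrix(0, gr, gc)
  s <- tapply(as.numeric(valid), bin, sum)
  nvalid[as.integer(names(s))] <- s
  mask <- nvalid > 0
  structure(c(out, list(mask = mask, grid_size_m = grid_size_m,
                        nrow = gr, ncol = gc)),
            class = "service_grid")
}

#' Jenks natural-breaks classification
#'
#' Exact Fisher dynamic-programming partition of one-dimensional values into
#' `k` classes minimizing within-class sum of squared deviations; levels are
#' ordered low to high (level 1 = I ... level k = VII for the default
#' seven-level ESV map). Inputs with more than `max_bins` distinct values are
#' first binned to `max_bins` quantile bins (weighted DP stays exact on the
#' binned representation).
#'
#' @param values numeric vector (NAs allowed, returned as NA).
#' @param k number of classes (default 7).
#' @param max_bins cap on distinct values entering the exact DP.
#' @return integer vector of levels 1..k with attribute `breaks` (upper class
#'   bounds).
#' @export
classify_levels <- function(values, k = 7, max_bins = 1024) {
  ok <- !is.na(values)
  x <- values[ok]
  ux <- sort(unique(x))
  if (length(ux) < k) {
    warning("fewer distinct values than classes; reducing k to ", length(ux))
    k <- length(ux)
  }
  if (length(ux) > max_bins) {
    qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = max_bins + 1),
                                 type = 1))
    bin_of <- findInterval(x, qs, rightmost.closed = TRUE, all.inside = TRUE)
    centers <- tapply(x, bin_of, mean)
    w <- tabulate(bin_of, nbins = length(qs) - 1)
    keep <- w > 0
    ux <- as.numeric(centers)
    wts <- w[keep]
  } else {
    wts <- tabulate(match(x, ux), nbins = length(ux))
  }
  breaks <- fisher_jenks_breaks(ux, wts, k)
  lev <- rep(NA_integer_, length(values))
  lev[ok] <- findInterval(x, breaks$upper, left.open = TRUE) + 1L
  lev[ok] <- pmin(lev[ok], k)
  attr(lev, "breaks") <- breaks$upper
  lev
}

# Weighted Fisher-Jenks DP over sorted distinct values xs with weights w.
# Returns the k-1 upper boundaries (last value of each class except the top).
fisher_jenks_breaks <- function(xs, w, k) {
  n <- length(xs)
  cw  <- c(0, cumsum(w))
  cwx <- c(0, cumsum(w * xs))
  cwx2 <- c(0, cumsum(w * xs^2))
  # ssd of segment (i..j], 1-based inclusive i..j
  ssd <- function(i, j) {
    W <- cw[j + 1] - cw[i]
    S <- cwx[j + 1] - cwx[i]
    (cwx2[j + 1] - cwx2[i]) - S^2 / W
  }
  cost <- matrix(Inf, k, n)     # cost[c, j] = best ssd for xs[1..j] in c classes
  back <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- ssd(1, j)
  if (k > 1) for (cc in 2:k) {
    for (j in cc:n) {
      i <- cc:j                  # last class starts at xs[i]
      cand <- cost[cc - 1, i - 1] + vapply(i, function(s) ssd(s, j), numeric(1))
      best <- which.min(cand)
      cost[cc, j] <- cand[best]
      back[cc, j] <- i[best]
    }
  }
  upper <- numeric(k - 1)
  j <- n
  if (k > 1) for (cc in k:2) {
    s <- back[cc, j]
    upper[cc - 1] <- xs[s - 1]
    j <- s - 1
  }
  list(upper = upper, ssd = cost[k, n])
}

#' Coefficient sensitivity of the total ESV
#'
#' Elasticity of the total ESV to a +/-`delta` perturbation of one class's
#' value coefficient: `CS_k = |dESV/ESV| / |dVC_k/VC_k|`. Under the additive
#' valuation model this equals class k's share of the total, so CS values lie
#' in [0,1], sum to 1, and are invariant to the perturbation sign.
#'
#' @param areas an [area_table].
#' @param coeffs coefficient matrix.
#' @param delta perturbation fraction (default 0.5, i.e. +/-50 %).
#' @return list with `cs` (named length-6), `delta` and the class `ordering`
#'   (most to least sensitive).
#' @export
sensitivity_cs <- function(areas, coeffs = esv_coefficients(), delta = 0.5) {
  base <- compute_esv(areas, coeffs)
  if (base$total <= 0) stop("total ESV must be positive")
  cs <- vapply(1:6, function(k) {
    pert <- coeffs
    pert[, k] <- pert[, k] * (1 + delta)
    d <- compute_esv(areas, pert)$total - base$total
    abs(d / base$total) / abs(delta)
  }, numeric(1))
  names(cs) <- lulc_classes()
  list(cs = cs, delta = delta,
       ordering = names(sort(cs, decreasing = TRUE)))
}
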