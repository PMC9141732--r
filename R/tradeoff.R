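# Grid-level trade-off/synergy statistics among the four primary service
# categories: Pearson correlations, bivariate global Moran's I, bivariate
# local Moran (LISA) with conditional-permutation inference and cluster
# labels, and ranking of service pairs.

#' Contiguity weights for a regular grid
#'
#' Sparse neighbour lists under queen (8-cell) or rook (4-cell) contiguity,
#' row-standardized by default. Cells masked out or isolated (no valid
#' neighbour) are dropped with a warning.
#'
#' @param nrow,ncol grid dimensions.
#' @param mask optional logical matrix of valid cells.
#' @param scheme `"queen"` or `"rook"`.
#' @param row_standardize divide each cell's weights by its neighbour count.
#' @return a `spatial_weights`: list with `neighbors` (list of integer
#'   vectors indexing `cells`), `weights`, `cells` (linear indices into the
#'   grid), `n`.
#' @export
grid_weights <- function(nrow, ncol, mask = NULL,
                         scheme = c("queen", "rook"),
                         row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  if (is.null(mask)) mask <- matrix(TRUE, nrow, ncol)
  stopifnot(dim(mask) == c(nrow, ncol))
  cells <- which(mask)
  idx <- matrix(NA_integer_, nrow, ncol)
  idx[cells] <- seq_along(cells)
  offs <- if (scheme == "rook") {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1)[-5, ])
  }
  ri <- ((cells - 1) %% nrow) + 1
  ci <- ((cells - 1) %/% nrow) + 1
  nbs <- vector("list", length(cells))
  for (o in seq_len(nrow(offs))) {
    rr <- ri + offs[o, 1]; cc <- ci + offs[o, 2]
    okn <- rr >= 1 & rr <= nrow & cc >= 1 & cc <= ncol
    j <- rep(NA_integer_, length(cells))
    j[okn] <- idx[cbind(rr[okn], cc[okn])]
    hit <- which(!is.na(j))
    for (i in hit) nbs[[i]] <- c(nbs[[i]], j[i])
  }
  iso <- lengths(nbs) == 0
  if (any(iso)) {
    warning(sum(iso), " isolated cell(s) dropped from the weights")
    keep <- which(!iso)
    remap <- rep(NA_integer_, length(cells))
    remap[keep] <- seq_along(keep)
    nbs <- lapply(nbs[keep], function(v) remap[v][!is.na(remap[v])])
    cells <- cells[keep]
  }
  w <- lapply(nbs, function(v) {
    if (row_standardize) rep(1 / length(v), length(v)) else rep(1, length(v))
  })
  structure(list(neighbors = nbs, weights = w, cells = cells,
                 n = length(cells), scheme = scheme,
                 row_standardized = row_standardize),
            class = "spatial_weights")
}

# z-score with the population (1/n) variance, the Moran's I convention.
zscore_pop <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zero variance; Moran's I undefined")
  (x - mean(x)) / s
}

# Spatial lag under a weights object.
spatial_lag <- function(z, W) {
  vapply(seq_len(W$n),
         function(i) sum(W$weights[[i]] * z[W$neighbors[[i]]]), numeric(1))
}

#' Bivariate global Moran's I
#'
#' `I = (1/n) * sum_i z_x[i] * sum_j w_ij z_y[j]` with z-scored variables
#' and row-standardized weights; `x = y` gives the univariate statistic.
#'
#' @param x,y numeric vectors over the weight object's cells.
#' @param W a [grid_weights()] object.
#' @return scalar Moran's I.
#' @export
bivariate_global_moran <- function(x, y, W) {
  stopifnot(length(x) == W$n, length(y) == W$n)
  zx <- zscore_pop(x); zy <- zscore_pop(y)
  mean(zx * spatial_lag(zy, W))
}

#' Bivariate local Moran (LISA) with permutation inference
#'
#' Local statistics `I_i = z_x[i] * sum_j w_ij z_y[j]`; their mean equals the
#' global statistic under row-standardized weights. Pseudo p-values come from
#' conditional permutation (cell `i` held fixed, neighbour values of `y`
#' drawn from the remaining cells), two-sided as twice the smaller tail with
#' the `(count + 1) / (n_perm + 1)` convention. Cluster labels combine the
#' signs of `z_x` and the lag of `z_y` (`high-high`, `low-low`, `high-low`,
#' `low-high`), reported only at `p <= alpha`.
#'
#' @inheritParams bivariate_global_moran
#' @param n_perm number of conditional permutations.
#' @param alpha significance level for labelling.
#' @param seed RNG seed.
#' @return data.frame with `local_i`, `p_value`, `cluster`.
#' @export
bivariate_local_moran <- function(x, y, W, n_perm = 999, alpha = 0.05,
                                  seed = 1) {
  stopifnot(length(x) == W$n, length(y) == W$n)
  set.seed(seed)
  zx <- zscore_pop(x); zy <- zscore_pop(y)
  lag <- spatial_lag(zy, W)
  obs <- zx * lag
  n <- W$n
  p <- numeric(n)
  for (i in seq_len(n)) {
    k <- length(W$neighbors[[i]])
    pool <- zy[-i]
    draws <- matrix(pool[sample.int(n - 1, k * n_perm, replace = TRUE)],
                    n_perm, k)
    perm <- zx[i] * drop(draws %*% W$weights[[i]])
    hi <- (sum(perm >= obs[i]) + 1) / (n_perm + 1)
    lo <- (sum(perm <= obs[i]) + 1) / (n_perm + 1)
    p[i] <- min(1, 2 * min(hi, lo))
  }
  quad <- ifelse(zx >= 0 & lag >= 0, "high-high",
          ifelse(zx < 0 & lag < 0, "low-low",
          ifelse(zx >= 0, "high-low", "low-high")))
  cluster <- ifelse(p <= alpha, quad, "not significant")
  data.frame(local_i = obs, p_value = p, cluster = cluster,
             stringsAsFactors = FALSE)
}

#' Pearson correlation matrix of the four service categories
#'
#' @param grid a `service_grid` from [esv_raster()] (or a data.frame/matrix
#'   with one column per category).
#' @return 4 x 4 correlation matrix; zero-variance services give NA with a
#'   warning.
#' @export
pearson_matrix <- function(grid) {
  M <- service_matrix(grid)
  if (nrow(M) < 3) stop("need at least 3 valid cells")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) warning("zero-variance service; correlations undefined")
  suppressWarnings(stats::cor(M))
}

# Valid-cell matrix (cells x 4 categories) from a service_grid.
service_matrix <- function(grid) {
  if (inherits(grid, "service_grid")) {
    ok <- grid$mask
    M <- sapply(esv_categories(), function(g) grid[[g]][ok])
  } else {
    M <- as.matrix(grid)
  }
  M
}

#' Trade-off/synergy statistics for all service pairs
#'
#' Pearson correlation and bivariate global Moran's I for the six unordered
#' pairs of primary categories on a service grid.
#'
#' @param grid a `service_grid`.
#' @param scheme contiguity scheme for the weights.
#' @return data.frame with `pair`, `pearson`, `moran_i`.
#' @export
tradeoff_statistics <- function(grid, scheme = "queen") {
  M <- service_matrix(grid)
  W <- grid_weights(grid$nrow, grid$ncol, mask = grid$mask, scheme = scheme)
  keep <- match(W$cells, which(grid$mask))
  cats <- esv_categories()
  prs <- utils::combn(4, 2)
  out <- lapply(seq_len(ncol(prs)), function(ci) {
    a <- prs[1, ci]; b <- prs[2, ci]
    data.frame(pair = paste(cats[a], cats[b], sep = "-"),
               pearson = stats::cor(M[, a], M[, b]),
               moran_i = bivariate_global_moran(M[keep, a], M[keep, b], W))
  })
  do.call(rbind, out)
}

#' Rank service pairs by association strength
#'
#' @param values named numeric vector (or data.frame with `pair` and a value
#'   column) of per-pair statistics.
#' @return data.frame ordered descending with `pair`, `value`, `tied`.
#' @export
synergy_ranking <- function(values) {
  if (is.data.frame(values)) {
    v <- stats::setNames(values[[2]], values[[1]])
  } else v <- values
  ord <- order(v, decreasing = TRUE)
  v <- v[ord]
  tied <- duplicated(v) | duplicated(v, fromLast = TRUE)
  data.frame(pair = names(v), value = as.numeric(v), tied = tied,
             row.names = NULL)
}
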