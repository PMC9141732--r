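# Patch-generating land-use simulation: land-expansion analysis (random-forest
# suitability surfaces), and a multi-class random-patch-seed CA with
# neighbourhood effect, adaptive inertia, threshold-decreasing spontaneous
# seeding, a binary conversion-rule matrix, and accuracy/kappa validation.

#' CA parameter set
#'
#' @param neighborhood_weights class expansion-ability weights `w_k` in
#'   `[0, 1]` (defaults: the published basin calibration).
#' @param window neighbourhood window edge (3 = the 8-cell Moore
#'   neighbourhood).
#' @param patch_thresholds per-class new-patch generation thresholds `u_k`.
#' @param decay decay factor `delta` of the decreasing seed threshold
#'   `tau = delta^l * r1`.
#' @param step demand-approach step: when the aggregate demand-gap
#'   improvement of an iteration falls below `step` (cells), the decay level
#'   `l` increments. Default 0.1 % of the grid, set at run time when `NULL`.
#' @param candidate_frac fraction of cells considered per iteration.
#' @param max_iter iteration cap.
#' @param tol_cells per-class demand tolerance in cells.
#' @param argmax select the target class by maximum probability instead of
#'   roulette.
#' @param seed RNG seed.
#' @export
ca_params <- function(neighborhood_weights = c(0.4084, 0.4851, 0.4671, 1, 0.5501, 0.1),
                      window = 3,
                      patch_thresholds = rep(0.5, 6),
                      decay = 0.9,
                      step = NULL,
                      candidate_frac = 0.05,
                      max_iter = 400,
                      tol_cells = 1,
                      argmax = FALSE,
                      seed = 1) {
  stopifnot(all(neighborhood_weights >= 0), all(neighborhood_weights <= 1),
            decay > 0, decay < 1, window == 3,
            candidate_frac > 0, candidate_frac <= 1)
  list(w = neighborhood_weights, window = window, u = patch_thresholds,
       delta = decay, step = step, candidate_frac = candidate_frac,
       max_iter = max_iter, tol_cells = tol_cells, argmax = argmax,
       seed = seed)
}

#' Default conversion-rule matrix
#'
#' Binary allow/forbid matrix for class conversions; diagonal always 1.
#' @param forbid optional 2-column matrix/data.frame of (from, to) codes to
#'   forbid.
#' @export
transition_rules <- function(forbid = NULL) {
  TM <- matrix(1L, 6, 6, dimnames = list(lulc_classes(), lulc_classes()))
  if (!is.null(forbid))
    for (i in seq_len(nrow(forbid))) TM[forbid[i, 1], forbid[i, 2]] <- 0L
  diag(TM) <- 1L
  TM
}

#' Expansion samples for suitability modelling
#'
#' For each class `k`, labels cells that newly became `k` between the two
#' dates (1) against cells that did not (0), over the universe of cells not
#' already `k` at the first date, with the driver values as predictors;
#' a seeded random subsample reduces the training size.
#'
#' @param t1,t2 aligned categorical [land_raster]s.
#' @param drivers named list of aligned continuous [land_raster]s.
#' @param sample_rate fraction of the universe sampled per class.
#' @param seed RNG seed.
#' @return list per class: `data` (data.frame with `label` and drivers) and
#'   `static` (TRUE when the class shows no expansion).
#' @export
extract_expansion_samples <- function(t1, t2, drivers, sample_rate = 0.2,
                                      seed = 1) {
  check_aligned(t1, t2)
  for (d in drivers) check_aligned(t1, d)
  set.seed(seed)
  v1 <- as.numeric(raster_values(t1)); v2 <- as.numeric(raster_values(t2))
  X <- as.data.frame(lapply(drivers, function(d) as.numeric(raster_values(d))))
  ok <- !is.na(v1) & !is.na(v2) & stats::complete.cases(X)
  out <- vector("list", 6)
  names(out) <- lulc_classes()
  for (k in 1:6) {
    uni <- which(ok & v1 != k)
    lab <- as.integer(v2[uni] == k)
    take <- sort(sample(seq_along(uni), max(1, round(sample_rate * length(uni)))))
    df <- cbind(label = lab[take], X[uni[take], , drop = FALSE])
    out[[k]] <- list(data = df, static = sum(lab) == 0)
  }
  out
}

#' Per-class suitability surfaces
#'
#' Fits one random-forest classifier per class on the expansion samples; the
#' per-cell development probability is the fraction of trees voting for
#' expansion. A user-supplied `oracle` (list of six `[0,1]` matrices) passes
#' through unchanged, replacing the classifier — useful for deterministic
#' tests. Static classes (no observed expansion) get a zero surface.
#'
#' @param samples output of [extract_expansion_samples()] (ignored when
#'   `oracle` given).
#' @param drivers named list of driver [land_raster]s (prediction grid).
#' @param n_trees number of trees per forest.
#' @param oracle optional list of six probability matrices.
#' @param seed RNG seed.
#' @return list of six probability matrices in `[0, 1]`, plus attribute
#'   `importance` (per-driver importance by class, classifier path only).
#' @export
fit_suitability <- function(samples = NULL, drivers = NULL, n_trees = 50,
                            oracle = NULL, seed = 1) {
  if (!is.null(oracle)) {
    stopifnot(length(oracle) == 6)
    for (m in oracle) stopifnot(all(m >= 0 & m <= 1, na.rm = TRUE))
    return(oracle)
  }
  set.seed(seed)
  Xfull <- as.data.frame(lapply(drivers, function(d) as.numeric(raster_values(d))))
  dims <- dim(raster_values(drivers[[1]]))
  out <- vector("list", 6)
  imp <- list()
  for (k in 1:6) {
    s <- samples[[k]]
    if (s$static || length(unique(s$data$label)) < 2) {
      out[[k]] <- matrix(0, dims[1], dims[2])
      next
    }
    fit <- randomForest::randomForest(
      x = s$data[, -1, drop = FALSE], y = factor(s$data$label, levels = 0:1),
      ntree = n_trees)
    p <- stats::predict(fit, Xfull, type = "prob")[, "1"]
    # a zero vote fraction means "below one vote in n_trees", not an exact
    # zero; floor at half a vote so no allowed conversion is impossible
    p <- pmax(p, 0.5 / n_trees)
    out[[k]] <- matrix(p, dims[1], dims[2])
    imp[[lulc_classes()[k]]] <- randomForest::importance(fit)[, 1]
  }
  names(out) <- lulc_classes()
  attr(out, "importance") <- imp
  out
}

#' Tree-vote expansion probability
#'
#' The suitability probability of a cell is the fraction of decision trees
#' voting for expansion: `votes / n_trees`.
#' @param votes trees voting for expansion.
#' @param n_trees total trees.
#' @export
tree_vote_probability <- function(votes, n_trees) {
  stopifnot(n_trees > 0, votes >= 0, votes <= n_trees)
  votes / n_trees
}

#' Neighbourhood effect
#'
#' Fraction of the 8 surrounding cells holding class `k`, scaled by the class
#' weight: `count / (n*n - 1) * w_k`. Border cells keep denominator 8
#' (absent neighbours count as non-`k`).
#'
#' @param state integer class matrix.
#' @param k class code.
#' @param w_k class neighbourhood weight.
#' @return matrix of neighbourhood effects in `[0, w_k]`.
#' @export
neighborhood_effect <- function(state, k, w_k) {
  neighbor_counts(state == k) / 8 * w_k
}

# Count of TRUE values among the 8 neighbours of every cell.
neighbor_counts <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- mask
  out <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out + p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  out
}

#' Adaptive-inertia update
#'
#' Three-case multiplier steering each class toward its demand: unchanged
#' when the absolute gap did not grow; scaled by `G2/G1` when both gaps are
#' negative and worsening; scaled by `G1/G2` when both positive and
#' worsening. Zero gaps in a denominator retain the previous coefficient.
#'
#' @param D per-class inertia coefficients (> 0).
#' @param G1 demand gap at the last iteration.
#' @param G2 demand gap two iterations back.
#' @return updated `D`.
#' @export
update_inertia <- function(D, G1, G2) {
  out <- D
  for (k in seq_along(D)) {
    if (abs(G1[k]) <= abs(G2[k])) next
    if (G2[k] < 0 && G2[k] > G1[k] && G1[k] != 0) {
      out[k] <- D[k] * G2[k] / G1[k]
    } else if (G1[k] > G2[k] && G2[k] > 0) {
      out[k] <- D[k] * G1[k] / G2[k]
    }
  }
  out
}

#' Combined and seeded transition probabilities
#'
#' `combined_probability` is the product `P * Omega * D`;
#' `seeded_probability` adds the random-patch branch: where the
#' neighbourhood effect is zero and a uniform draw `r` falls below the
#' suitability, the cell may seed a new patch with probability
#' `P * (r * u_k) * D`, otherwise the combined probability applies.
#'
#' @param P suitability probability.
#' @param omega neighbourhood effect.
#' @param D inertia coefficient.
#' @param r uniform draw(s) in `[0, 1]`.
#' @param u_k patch-generation threshold.
#' @export
combined_probability <- function(P, omega, D) P * omega * D

#' @rdname combined_probability
#' @export
seeded_probability <- function(P, omega, D, r, u_k) {
  ifelse(omega == 0 & r < P, P * (r * u_k) * D, P * omega * D)
}

#' Patch-generating CA allocation
#'
#' Iterative spatial allocation of class demand. Each round a seeded random
#' subset of cells is considered; a candidate converts from its current class
#' `cur` (over demand) to a target `c` (under demand) drawn by roulette over
#' the per-class transition probabilities — the combined probability where
#' class `c` is present in the neighbourhood, or the random-seed branch
#' (additionally gated by suitability above the decreasing threshold
#' `tau = delta^l * r1`, `r1` a positive draw around 1) where it is absent.
#' Conversions respect the rule matrix, never overshoot a class demand within
#' a round, and only changes reducing the aggregate gap are accepted, so
#' `sum(|G|)` is non-increasing. The decay level `l` increments whenever a
#' round improves the aggregate gap by less than `step`. Fully reproducible
#' for a fixed seed.
#'
#' @param t_start starting categorical [land_raster].
#' @param suitability list of six probability matrices ([fit_suitability()]).
#' @param demand an [area_table] of target areas (ha); its total must match
#'   the raster's valid area.
#' @param rules 6 x 6 binary conversion matrix ([transition_rules()]).
#' @param params a [ca_params()].
#' @return list with `raster` (final map), `log` (per-iteration data.frame:
#'   iteration, per-class gap, `l`, `tau`, total absolute gap), `converged`.
#' @export
run_cars <- function(t_start, suitability, demand,
                     rules = transition_rules(), params = ca_params()) {
  set.seed(params$seed)
  v <- raster_values(t_start)
  valid <- which(!is.na(v))
  n <- length(valid)
  area <- cell_area_ha(t_start)
  dem_ha <- if (is.data.frame(demand)) demand$area_ha else as.numeric(demand)
  if (abs(sum(dem_ha) - n * area) > 0.005 * n * area)
    stop("demand total does not match raster area")
  # largest-remainder rounding to whole cells summing exactly to n
  tgt <- dem_ha / area
  dem_cells <- floor(tgt)
  remn <- n - sum(dem_cells)
  ord <- order(tgt - dem_cells, decreasing = TRUE)
  if (remn > 0) dem_cells[ord[seq_len(remn)]] <- dem_cells[ord[seq_len(remn)]] + 1
  state <- v
  counts <- tabulate(state[valid], nbins = 6)
  G <- dem_cells - counts
  # reachability: a growing class must be allowed from some shrinking class
  for (cc in which(G > params$tol_cells)) {
    if (!any(rules[setdiff(1:6, cc), cc] == 1 & G[setdiff(1:6, cc)] < 0))
      stop("demand for class '", lulc_classes()[cc],
           "' unreachable under the conversion rules")
  }
  step <- if (is.null(params$step)) max(1, round(0.001 * n)) else params$step
  D <- rep(1, 6)
  G1 <- G; G2 <- G
  l <- 0
  tau <- params$delta^l * truncated_normal_1()
  logs <- list()
  converged <- all(abs(G) <= params$tol_cells)
  it <- 0
  while (!converged && it < params$max_iter) {
    it <- it + 1
    if (it > 2) D <- update_inertia(D, G1, G2)
    omega <- lapply(1:6, function(k) neighborhood_effect(state, k, params$w[k]))
    cand <- sample(valid, max(1, round(params$candidate_frac * n)))
    cur <- state[cand]
    shrink <- G[cur] < 0                   # only over-demand cells may flip
    cand <- cand[shrink]; cur <- cur[shrink]
    if (length(cand)) {
      TP <- matrix(0, length(cand), 6)
      for (cc in which(G > 0)) {
        allowed <- rules[cbind(cur, cc)] == 1 & cur != cc
        if (!any(allowed)) next
        P <- suitability[[cc]][cand]
        om <- omega[[cc]][cand]
        r <- stats::runif(length(cand))
        tp <- seeded_probability(P, om, D[cc], r, params$u[cc])
        # spontaneous seeds additionally gated by the decreasing threshold
        tp[om == 0 & P <= tau] <- 0
        tp[!allowed] <- 0
        TP[, cc] <- tp
      }
      rs <- rowSums(TP)
      sel <- which(rs > 0)
      if (length(sel)) {
        pick <- integer(length(sel))
        if (params$argmax) {
          pick <- max.col(TP[sel, , drop = FALSE], ties.method = "first")
        } else {
          u <- stats::runif(length(sel)) * rs[sel]
          cum <- TP[sel, , drop = FALSE]
          for (j in 2:6) cum[, j] <- cum[, j] + cum[, j - 1]
          pick <- max.col(cum >= u, ties.method = "first")
        }
        # apply sequentially, capping at the demand of both classes
        for (m in seq_along(sel)) {
          i <- sel[m]; cc <- pick[m]; k <- cur[i]
          if (G[cc] > 0 && G[k] < 0) {
            state[cand[i]] <- cc
            G[cc] <- G[cc] - 1
            G[k] <- G[k] + 1
          }
        }
      }
    }
    improvement <- sum(abs(G1)) - sum(abs(G))
    if (improvement < step) l <- l + 1
    tau <- params$delta^l * truncated_normal_1()
    G2 <- G1; G1 <- G
    logs[[it]] <- data.frame(iteration = it, l = l, tau = tau,
                             total_gap = sum(abs(G)),
                             t(stats::setNames(G, lulc_classes())))
    converged <- all(abs(G) <= params$tol_cells)
  }
  out <- land_raster(state, cellsize = t_start$cellsize, xll = t_start$xll,
                     yll = t_start$yll, nodata = t_start$nodata)
  out$values[is.na(state)] <- if (is.na(t_start$nodata)) NA else t_start$nodata
  list(raster = out,
       log = if (length(logs)) do.call(rbind, logs) else
         data.frame(iteration = integer(), l = integer(), tau = numeric(),
                    total_gap = numeric()),
       converged = converged)
}

truncated_normal_1 <- function() {
  repeat {
    r <- stats::rnorm(1, mean = 1, sd = 0.1)
    if (r > 0) return(r)
  }
}

#' Map-comparison validation
#'
#' Confusion matrix, overall accuracy (trace / total) and Cohen's kappa
#' (`(OA - p_e) / (1 - p_e)` with `p_e` the marginal chance agreement)
#' between a simulated and an observed categorical raster.
#'
#' @param simulated,observed aligned categorical [land_raster]s.
#' @return list with `confusion` (6 x 6), `overall_accuracy`, `kappa`.
#' @export
validate_maps <- function(simulated, observed) {
  check_aligned(simulated, observed)
  v1 <- raster_values(simulated); v2 <- raster_values(observed)
  ok <- !is.na(v1) & !is.na(v2)
  if (!any(ok)) stop("no overlapping valid cells")
  cm <- matrix(0, 6, 6, dimnames = list(lulc_classes(), lulc_classes()))
  tab <- table(factor(v1[ok], levels = 1:6), factor(v2[ok], levels = 1:6))
  cm[] <- as.numeric(tab)
  kappa_from_confusion(cm)
}

#' @rdname validate_maps
#' @param confusion a square cell-count confusion matrix.
#' @export
kappa_from_confusion <- function(confusion) {
  n <- sum(confusion)
  oa <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  list(confusion = confusion, overall_accuracy = oa,
       kappa = (oa - pe) / (1 - pe))
}
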