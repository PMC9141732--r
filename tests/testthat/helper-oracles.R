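# Independent oracles and shared fixtures for the test suite.

# Small, fast landscape configuration.
small_config <- function(seed = 7, n = 64, ...) {
  landscape_config(n_rows = n, n_cols = n, seed = seed, ...)
}

# Exhaustive Jenks oracle: enumerate all contiguous partitions of the sorted
# values into k groups and minimize the within-group sum of squared
# deviations. Returns the group index per (sorted) value.
jenks_oracle <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- NULL; best_cost <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (ci in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, ci], n)
    cost <- 0
    for (g in seq_len(k)) cost <- cost + ssd(xs[(cuts[g] + 1):cuts[g + 1]])
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- rep(seq_len(k), diff(cuts))
    }
  }
  list(groups = best, cost = best_cost, sorted = xs)
}

# Brute-force double-loop bivariate Moran's I.
moran_brute_force <- function(x, y, W) {
  zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  zy <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  acc <- 0
  for (i in seq_len(W$n))
    for (j in seq_along(W$neighbors[[i]]))
      acc <- acc + zx[i] * W$weights[[i]][j] * zy[W$neighbors[[i]][j]]
  acc / W$n
}

# Forward cellwise simulation of a transition matrix on an area vector.
markov_forward_oracle <- function(areas, P, steps = 1) {
  a <- areas
  for (s in seq_len(steps)) {
    out <- numeric(6)
    for (k in 1:6) for (cc in 1:6) out[cc] <- out[cc] + a[k] * P[k, cc]
    a <- out
  }
  a
}

# Deterministic oracle suitability: uniform mid-range probability per class.
flat_suitability <- function(nr, nc, p = 0.6) {
  lapply(1:6, function(k) matrix(p, nr, nc))
}

# Mean patch size of changed cells (4-connectivity flood fill).
mean_patch_size <- function(changed) {
  nr <- nrow(changed); nc <- ncol(changed)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  sizes <- integer(0)
  for (start in which(changed & lab == 0)) {
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    sz <- 0L
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      sz <- sz + 1L
      i <- ((cell - 1) %% nr) + 1; j <- ((cell - 1) %/% nr) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          nxt <- (jj - 1) * nr + ii
          if (changed[nxt] && lab[nxt] == 0L) {
            lab[nxt] <- cur
            queue <- c(queue, nxt)
          }
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  if (length(sizes) == 0) return(0)
  mean(sizes)
}

# boot::simplex cross-check of the constrained LP, in kha for conditioning.
simplex_oracle <- function(obj_coef, cons) {
  sc <- 1e3
  ub_rows <- which(is.finite(cons$upper))
  A1 <- rbind(diag(6)[ub_rows, , drop = FALSE], c(0, 0, 0, 0, cons$pop$M, 0))
  b1 <- c(cons$upper[ub_rows], cons$pop$P) / sc
  sv <- t(sapply(cons$service, function(s) s$coef))
  A2 <- rbind(diag(6), sv)
  b2 <- c(cons$lower, sapply(cons$service, function(s) s$rhs)) / sc
  s <- boot::simplex(a = obj_coef, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                     A3 = matrix(1, 1, 6), b3 = cons$total / sc,
                     maxi = TRUE, n.iter = 500)
  list(solved = s$solved, x = s$soln * sc, value = unname(s$value) * sc)
}
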