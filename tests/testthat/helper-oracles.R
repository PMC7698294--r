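# Independent oracles used across the suite.  These deliberately avoid the
# package's own C++ routines: flood fill is plain recursive-queue R, the
# drape oracle is exhaustive fixed-point relaxation on dense matrices, and
# porosity counts come from direct sums.

# flood-fill component areas of `mask` (TRUE pixels), given connectivity
oracle_flood_areas <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    dij <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    dij <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  areas <- integer(0)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    stack <- matrix(c(i, j), ncol = 2)
    seen[i, j] <- TRUE
    size <- 0L
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      size <- size + 1L
      for (k in seq_len(nrow(dij))) {
        ni <- p[1] + dij[k, 1]; nj <- p[2] + dij[k, 2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          stack <- rbind(stack, c(ni, nj))
        }
      }
    }
    areas <- c(areas, size)
  }
  areas
}

# minimal F-Lipschitz surface >= h over footprint cells (TRUE in `foot`),
# by naive relaxation to the fixed point
oracle_drape <- function(foot, h, F) {
  b <- ifelse(foot, h, -Inf)
  nr <- nrow(foot); nc <- ncol(foot)
  repeat {
    changed <- FALSE
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      if (!foot[i, j]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- i + d[1]; nj <- j + d[2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc && foot[ni, nj] &&
            b[ni, nj] - F > b[i, j]) {
          b[i, j] <- b[ni, nj] - F
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  b
}

# exhaustive best single split minimizing within-child SSE; returns the
# midpoint threshold (ties: first feature, lowest threshold)
oracle_best_split <- function(X, y, min_leaf = 1) {
  best <- NULL
  for (j in seq_along(X)) {
    x <- X[[j]]
    xs <- sort(unique(x))
    if (length(xs) < 2) next
    for (thr in (head(xs, -1) + xs[-1]) / 2) {
      L <- y[x <= thr]; R <- y[x > thr]
      if (length(L) < min_leaf || length(R) < min_leaf) next
      sse <- sum((L - mean(L))^2) + sum((R - mean(R))^2)
      if (is.null(best) || sse < best$sse - 1e-12) {
        best <- list(var = names(X)[j], threshold = thr, sse = sse)
      }
    }
  }
  best
}

# random binary matrix fixture
random_binary <- function(nr, nc, p_solid, seed) {
  set.seed(seed)
  matrix(as.integer(runif(nr * nc) < p_solid), nr, nc)
}
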