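# Independent oracles, written against the mathematical definitions rather
# than the package implementations. Shared by the unit and acceptance
# suites.

# --- at-sea distance: O(V^2) Dijkstra over the 16-neighbour sea lattice.
# A step is blocked when its centre-to-centre segment crosses land: a
# knight move needs both cells its segment traverses to be sea; a diagonal
# is blocked only when both orthogonal neighbours are land (corner pinch).
oracleStepOK <- function(grid, r, c, dr, dc) {
  landAt <- function(rr, cc) grid@land[(cc - 1) * grid@nrow + rr]
  if (abs(dr) + abs(dc) == 1) return(TRUE)
  if (abs(dr) == 1 && abs(dc) == 1)
    return(!(landAt(r + dr, c) && landAt(r, c + dc)))
  # knight: the segment passes the cell one step along the long axis and
  # the cell diagonally adjacent on the same side
  if (abs(dr) == 2) {
    a <- c(r + sign(dr), c); b <- c(r + sign(dr), c + dc)
  } else {
    a <- c(r, c + sign(dc)); b <- c(r + dr, c + sign(dc))
  }
  !landAt(a[1], a[2]) && !landAt(b[1], b[2])
}

oracleDistance <- function(grid, sources) {
  n <- grid@nrow * grid@ncol
  dist <- rep(Inf, n)
  dist[sources] <- 0
  visited <- rep(FALSE, n)
  visited[grid@land] <- TRUE         # land never enters the frontier
  visited[sources] <- FALSE
  off <- sealusage:::neighbourOffsets(16)
  step <- sqrt(off[, 1]^2 + off[, 2]^2) * grid@cellsize
  repeat {
    u <- which(!visited & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    visited[u] <- TRUE
    r <- (u - 1) %% grid@nrow + 1; c <- (u - 1) %/% grid@nrow + 1
    for (k in seq_len(nrow(off))) {
      r2 <- r + off[k, 1]; c2 <- c + off[k, 2]
      if (r2 < 1 || r2 > grid@nrow || c2 < 1 || c2 > grid@ncol) next
      v <- (c2 - 1) * grid@nrow + r2
      if (grid@land[v]) next
      if (!oracleStepOK(grid, r, c, off[k, 1], off[k, 2])) next
      if (dist[u] + step[k] < dist[v]) dist[v] <- dist[u] + step[k]
    }
  }
  m <- matrix(dist, grid@nrow, grid@ncol)
  m[grid@land] <- NA_real_
  m
}

# --- KDE: brute-force double loop over kernels and sea-cell centres.
oracleKde <- function(points, H, grid) {
  Hinv <- solve(H)
  detH <- det(H)
  sea <- which(!grid@land)
  xy <- cellCenter(grid, sea)
  dens <- numeric(length(sea))
  for (i in seq_along(sea)) {
    for (j in seq_len(nrow(points))) {
      d <- c(xy[i, "x"] - points[j, 1], xy[i, "y"] - points[j, 2])
      q <- d %*% Hinv %*% d
      dens[i] <- dens[i] + exp(-0.5 * q)
    }
  }
  dens <- dens / (2 * pi * sqrt(detH) * nrow(points))
  mass <- dens * grid@cellsize^2
  vals <- matrix(0, grid@nrow, grid@ncol)
  vals[sea] <- mass / sum(mass)
  vals
}

# --- logistic MLE: Newton-Raphson on an explicit model matrix.
oracleLogistic <- function(X, y, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in 1:100) {
    mu <- plogis(as.numeric(X %*% beta))
    W <- mu * (1 - mu)
    step <- solve(crossprod(X, X * W), crossprod(X, y - mu))
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# --- cubic B-spline basis: Cox-de Boor recursion on a clamped knot vector.
oracleDeBoor <- function(x, knots, i, p) {
  if (p == 0) {
    hi <- knots[i + 1]
    as.numeric(x >= knots[i] & (x < hi | (hi == max(knots) & x <= hi)))
  } else {
    d1 <- knots[i + p] - knots[i]
    d2 <- knots[i + p + 1] - knots[i + 1]
    a <- if (d1 > 0) (x - knots[i]) / d1 * oracleDeBoor(x, knots, i, p - 1) else 0
    b <- if (d2 > 0) (knots[i + p + 1] - x) / d2 *
           oracleDeBoor(x, knots, i + 1, p - 1) else 0
    a + b
  }
}

# --- change point: exhaustive single-break least squares.
oracleChangepoint <- function(y) {
  sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  costs <- sapply(seq_len(length(y) - 1),
                  function(tau) sse(y[1:tau]) + sse(y[-(1:tau)]))
  which.min(costs)
}
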