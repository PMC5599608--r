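#' Cell indexing helpers
#'
#' Cells are indexed column-major (R matrix order): id
#' `k = (col - 1) * nrow + row`, with row 1 the bottom (southern) row.
#' `cellCenter()` returns projected x/y of cell centres; `xyToCell()` maps
#' projected coordinates to cell ids using half-open intervals
#' `[x, x + cellsize)`; points outside the grid get `NA`.
#'
#' @param grid a [GridSpec-class].
#' @param cells integer cell ids.
#' @param x,y numeric projected coordinates (m).
#' @return `cellCenter()`: a two-column matrix `x`, `y`; `cellRowCol()`: a
#'   two-column matrix `row`, `col`; `xyToCell()`: integer cell ids.
#' @export
cellCenter <- function(grid, cells) {
  rc <- cellRowCol(grid, cells)
  cs <- grid@cellsize
  cbind(x = grid@origin[1] + (rc[, "col"] - 0.5) * cs,
        y = grid@origin[2] + (rc[, "row"] - 0.5) * cs)
}

#' @rdname cellCenter
#' @export
cellRowCol <- function(grid, cells) {
  cells <- as.integer(cells)
  cbind(row = (cells - 1L) %% grid@nrow + 1L,
        col = (cells - 1L) %/% grid@nrow + 1L)
}

#' @rdname cellCenter
#' @export
xyToCell <- function(grid, x, y) {
  cs <- grid@cellsize
  col <- floor((x - grid@origin[1]) / cs) + 1
  row <- floor((y - grid@origin[2]) / cs) + 1
  ok <- row >= 1 & row <= grid@nrow & col >= 1 & col <= grid@ncol
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer((col[ok] - 1) * grid@nrow + row[ok])
  out
}

# Offsets of the 16-neighbourhood (8 queen + 8 knight moves), with
# centre-to-centre step lengths in units of the cell size.
neighbourOffsets <- function(connectivity = 16) {
  queen <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  if (connectivity == 8) return(queen)
  knight <- cbind(dr = c(-2, -2, -1, -1, 1, 1, 2, 2),
                  dc = c(-1, 1, -2, 2, -2, 2, -1, 1))
  rbind(queen, knight)
}

# Neighbours of given cells under an offset set; returns a data.frame of
# (from, to, steplen) pairs staying inside the grid.
cellNeighbours <- function(grid, cells, connectivity = 16) {
  off <- neighbourOffsets(connectivity)
  rc <- cellRowCol(grid, cells)
  from <- rep(as.integer(cells), each = nrow(off))
  nr <- rep(rc[, "row"], each = nrow(off)) + off[, "dr"]
  nc <- rep(rc[, "col"], each = nrow(off)) + off[, "dc"]
  len <- rep(sqrt(off[, "dr"]^2 + off[, "dc"]^2), times = length(cells))
  ok <- nr >= 1 & nr <= grid@nrow & nc >= 1 & nc <= grid@ncol
  data.frame(from = from[ok],
             to = as.integer((nc[ok] - 1) * grid@nrow + nr[ok]),
             steplen = len[ok] * grid@cellsize)
}

# Connected components of a logical mask under 8-adjacency (flood fill).
maskComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  stack <- integer(length(idx))
  for (start in idx) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    comp[start] <- cur
    while (top > 0L) {
      k <- stack[top]; top <- top - 1L
      r <- (k - 1L) %% nr + 1L; c <- (k - 1L) %/% nr + 1L
      for (c2 in max(1L, c - 1L):min(nc, c + 1L)) {
        base <- (c2 - 1L) * nr
        for (r2 in max(1L, r - 1L):min(nr, r + 1L)) {
          k2 <- base + r2
          if (mask[k2] && comp[k2] == 0L) {
            comp[k2] <- cur
            top <- top + 1L
            stack[top] <- k2
          }
        }
      }
    }
  }
  comp
}

# Gaussian-smoothed white noise field via FFT convolution (circular
# boundary), standardised to zero mean / unit variance.
smoothNoiseField <- function(nrow, ncol, sigma_cells) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (sigma_cells <= 0) return(z)
  gk <- function(n) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    stats::dnorm(d, sd = sigma_cells)
  }
  kr <- gk(nrow); kc <- gk(ncol)
  K <- outer(kr, kc)
  K <- K / sum(K)
  f <- Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE)) / (nrow * ncol)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic analysis grid with a connected sea region
#'
#' Builds a 600 m raster whose land mask is a smoothed Gaussian random
#' field thresholded at the requested land fraction. Only the largest
#' connected sea component (8-adjacency) is kept as sea; smaller detached
#' sea pockets are converted to land so that every sea cell is reachable
#' from every other. Deterministic for a fixed seed.
#'
#' @param nrows,ncols grid dimensions (10--2000).
#' @param land_fraction target fraction of land cells in `[0, 0.9)`.
#' @param seed integer seed.
#' @param cellsize cell edge length in metres (default 600).
#' @param smooth_cells smoothing length of the mask field, in cells.
#' @return a [GridSpec-class].
#' @export
genGrid <- function(nrows, ncols, land_fraction, seed, cellsize = 600,
                    smooth_cells = 3) {
  stopifnot(nrows >= 10, nrows <= 2000, ncols >= 10, ncols <= 2000,
            land_fraction >= 0, land_fraction < 0.9)
  set.seed(seed)
  if (land_fraction == 0) {
    land <- matrix(FALSE, nrows, ncols)
  } else {
    f <- smoothNoiseField(nrows, ncols, smooth_cells)
    land <- f > stats::quantile(f, 1 - land_fraction)
    comp <- maskComponents(!land)
    if (max(comp) == 0L)
      stop("grid generation produced no sea cells; lower land_fraction")
    if (max(comp) > 1L) {
      sizes <- tabulate(comp[comp > 0L])
      keep <- which.max(sizes)
      land[comp > 0L & comp != keep] <- TRUE
    }
  }
  new("GridSpec", nrow = as.integer(nrows), ncol = as.integer(ncols),
      cellsize = cellsize, origin = c(0, 0), land = land)
}

#' Coastal cells of a grid
#'
#' Land cells 8-adjacent to at least one sea cell (`coastalLandCells`), and
#' sea cells 8-adjacent to a given land cell (`adjacentSeaCells`, the
#' "waterline" of a haul-out).
#'
#' @param grid a [GridSpec-class].
#' @param cell a land cell id.
#' @return integer cell ids.
#' @export
coastalLandCells <- function(grid) {
  land_cells <- which(grid@land)
  if (!length(land_cells)) return(integer())
  nb <- cellNeighbours(grid, land_cells, connectivity = 8)
  touch_sea <- !grid@land[nb$to]
  sort(unique(nb$from[touch_sea]))
}

#' @rdname coastalLandCells
#' @export
adjacentSeaCells <- function(grid, cell) {
  nb <- cellNeighbours(grid, cell, connectivity = 8)
  sort(unique(nb$to[!grid@land[nb$to]]))
}
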