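#' Cleanse raw telemetry fixes
#'
#' Drops rows with any missing required field, reduces exact duplicate
#' `(animal_id, timestamp)` records to their first occurrence, sorts each
#' animal's fixes by time, and excludes animals left with fewer than
#' `min_fixes` records. Excluded animals are reported in the `"excluded"`
#' attribute of the result (`animal_id`, `n_fixes`, `reason`), mirroring
#' the exclusion of sparse animals in the field protocol.
#'
#' @param fixes data.frame with `animal_id`, `timestamp`, `x_m`, `y_m`,
#'   `at_haulout` (further columns are carried through).
#' @param min_fixes minimum number of surviving fixes per animal.
#' @return cleansed data.frame with attribute `excluded`.
#' @export
cleanseFixes <- function(fixes, min_fixes = 10) {
  req <- c("animal_id", "timestamp", "x_m", "y_m", "at_haulout")
  stopifnot(all(req %in% names(fixes)))
  keep <- stats::complete.cases(fixes[req])
  out <- fixes[keep, , drop = FALSE]
  out <- out[order(out$animal_id, out$timestamp), , drop = FALSE]
  dup <- duplicated(out[c("animal_id", "timestamp")])
  out <- out[!dup, , drop = FALSE]
  n <- table(out$animal_id)
  bad <- names(n)[n < min_fixes]
  gone <- setdiff(unique(fixes$animal_id), unique(out$animal_id))
  excluded <- data.frame(
    animal_id = c(bad, gone),
    n_fixes = c(as.integer(n[bad]), rep(0L, length(gone))),
    reason = c(rep(sprintf("fewer than %d fixes after cleansing", min_fixes),
                   length(bad)),
               rep("no valid fixes", length(gone))))
  if (nrow(excluded))
    message(sprintf("cleanse: excluded %d animal(s): %s", nrow(excluded),
                    paste(excluded$animal_id, collapse = ", ")))
  out <- out[!out$animal_id %in% excluded$animal_id, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Regularise fixes to a uniform clock
#'
#' Straight-line interpolates each animal's positions onto a uniform
#' `interval_h` clock anchored at the first fix. Gaps longer than
#' `max_gap_h` split the track into segments; the clock restarts at each
#' segment's first fix and nothing is interpolated across a gap. No
#' extrapolation occurs beyond the last fix. An interpolated fix is flagged
#' hauled-out only when both bracketing observed fixes are hauled out at
#' the same position; fixes that fall exactly on an observed time keep that
#' record's position and flag. Already-regular tracks come back unchanged
#' (plus a `segment` column).
#'
#' @param fixes cleansed fixes data.frame (see [cleanseFixes()]).
#' @param interval_h clock interval in hours (default 2).
#' @param max_gap_h largest gap to interpolate across (default 24).
#' @return data.frame `animal_id`, `timestamp`, `x_m`, `y_m`,
#'   `at_haulout`, `segment` (plus `tag_type` if present).
#' @export
regulariseTrack <- function(fixes, interval_h = 2, max_gap_h = 24) {
  stopifnot(interval_h > 0)
  out <- lapply(split(fixes, fixes$animal_id), function(a) {
    a <- a[order(a$timestamp), , drop = FALSE]
    if (nrow(a) < 2) return(NULL)
    tsec <- as.numeric(a$timestamp)
    seg <- cumsum(c(0, diff(tsec) > max_gap_h * 3600)) + 1L
    res <- lapply(split(seq_len(nrow(a)), seg), function(ii) {
      s <- a[ii, , drop = FALSE]
      if (nrow(s) < 2) return(NULL)
      ts <- as.numeric(s$timestamp)
      grid_t <- seq(ts[1], ts[length(ts)], by = interval_h * 3600)
      x <- stats::approx(ts, s$x_m, xout = grid_t)$y
      y <- stats::approx(ts, s$y_m, xout = grid_t)$y
      # bracketing indices
      lo <- findInterval(grid_t, ts)
      hi <- pmin(lo + 1L, length(ts))
      exact <- grid_t %in% ts
      lo_e <- findInterval(grid_t, ts)  # at exact times lo points to the fix
      haul <- s$at_haulout[lo] & s$at_haulout[hi] &
        s$x_m[lo] == s$x_m[hi] & s$y_m[lo] == s$y_m[hi]
      haul[exact] <- s$at_haulout[lo_e[exact]]
      x[exact] <- s$x_m[lo_e[exact]]
      y[exact] <- s$y_m[lo_e[exact]]
      d <- data.frame(animal_id = s$animal_id[1],
                      timestamp = as.POSIXct(grid_t, tz = "UTC",
                                             origin = "1970-01-01"),
                      x_m = x, y_m = y, at_haulout = haul,
                      segment = seg[ii[1]])
      if ("tag_type" %in% names(s)) d$tag_type <- s$tag_type[1]
      d
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Median step distance of regularised tracks
#'
#' Pools consecutive-fix distances within animal and segment and returns
#' the median (m). Diagnostic for choosing a grid resolution; the default
#' pipeline fixes 600 m cells regardless.
#'
#' @param tracks regularised tracks (see [regulariseTrack()]).
#' @return median step distance in metres.
#' @export
detectResolution <- function(tracks) {
  key <- paste(tracks$animal_id, tracks$segment)
  steps <- unlist(lapply(split(tracks, key), function(s) {
    if (nrow(s) < 2) return(numeric())
    sqrt(diff(s$x_m)^2 + diff(s$y_m)^2)
  }), use.names = FALSE)
  stats::median(steps)
}

# Snap a cell to the nearest land cell (expanding square search).
snapToLand <- function(grid, cell) {
  if (grid@land[cell]) return(as.integer(cell))
  rc <- cellRowCol(grid, cell)
  for (rad in 1:max(grid@nrow, grid@ncol)) {
    rr <- max(1L, rc[1] - rad):min(grid@nrow, rc[1] + rad)
    cc <- max(1L, rc[2] - rad):min(grid@ncol, rc[2] + rad)
    sub <- as.matrix(expand.grid(row = rr, col = cc))
    ids <- (sub[, "col"] - 1L) * grid@nrow + sub[, "row"]
    landers <- ids[grid@land[ids]]
    if (length(landers)) {
      d2 <- (sub[grid@land[ids], "row"] - rc[1])^2 +
            (sub[grid@land[ids], "col"] - rc[2])^2
      return(as.integer(landers[which.min(d2)]))
    }
  }
  stop("no land cell found to snap to")
}

#' Segment regularised tracks into trips and associate haul-outs
#'
#' Maximal runs of at-sea fixes bounded by haul-out events become trips.
#' Each at-sea fix is associated with one haul-out cell: fixes at or
#' before the trip's temporal midpoint go to the departure haul-out, later
#' fixes to the destination (ties to departure). Trips truncated by the
#' start or end of a track segment associate wholly with their single
#' bounding haul-out. Haul-out fixes are mapped to their containing grid
#' cell, snapped to the nearest land cell when the flagged position falls
#' on sea. Animals with no haul-out fixes at all are excluded and reported
#' in the `"excluded"` attribute.
#'
#' @param tracks regularised tracks (see [regulariseTrack()]).
#' @param grid a [GridSpec-class].
#' @return data.frame of at-sea fixes with `animal_id`, `timestamp`,
#'   `x_m`, `y_m`, `cell`, `trip_id`, `assoc_cell`, `departure_cell`,
#'   `destination_cell` (plus `tag_type` if present), and attribute
#'   `excluded`.
#' @export
segmentTrips <- function(tracks, grid) {
  excluded <- character()
  res <- list()
  for (aid in unique(tracks$animal_id)) {
    a <- tracks[tracks$animal_id == aid, , drop = FALSE]
    if (!any(a$at_haulout)) {
      excluded <- c(excluded, aid)
      next
    }
    for (sg in unique(a$segment)) {
      s <- a[a$segment == sg, , drop = FALSE]
      n <- nrow(s)
      haul_idx <- which(s$at_haulout)
      if (!length(haul_idx)) next   # segment-level: no haul-out, skip runs
      haul_cell <- vapply(haul_idx, function(i) {
        snapToLand(grid, xyToCell(grid, s$x_m[i], s$y_m[i]))
      }, integer(1))
      at_sea <- which(!s$at_haulout)
      if (!length(at_sea)) next
      runs <- split(at_sea, cumsum(c(1, diff(at_sea) != 1)))
      for (ri in seq_along(runs)) {
        run <- runs[[ri]]
        before <- haul_idx[haul_idx < run[1]]
        after <- haul_idx[haul_idx > run[length(run)]]
        dep <- if (length(before)) haul_cell[match(max(before), haul_idx)] else NA_integer_
        dst <- if (length(after)) haul_cell[match(min(after), haul_idx)] else NA_integer_
        tt <- as.numeric(s$timestamp[run])
        if (is.na(dep) && is.na(dst)) next
        if (is.na(dep)) assoc <- rep(dst, length(run))
        else if (is.na(dst)) assoc <- rep(dep, length(run))
        else {
          mid <- (tt[1] + tt[length(tt)]) / 2
          assoc <- ifelse(tt <= mid, dep, dst)
        }
        d <- s[run, intersect(c("animal_id", "timestamp", "x_m", "y_m", "tag_type"),
                              names(s)), drop = FALSE]
        d$cell <- xyToCell(grid, d$x_m, d$y_m)
        d$trip_id <- sprintf("%s_s%d_t%d", aid, sg, ri)
        d$assoc_cell <- as.integer(assoc)
        d$departure_cell <- dep
        d$destination_cell <- dst
        res[[length(res) + 1L]] <- d
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(animal_id = character(), timestamp = as.POSIXct(character()),
               x_m = numeric(), y_m = numeric(), cell = integer(),
               trip_id = character(), assoc_cell = integer(),
               departure_cell = integer(), destination_cell = integer())
  rownames(out) <- NULL
  if (length(excluded))
    message(sprintf("segmentTrips: excluded %d animal(s) with no haul-out records: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  attr(out, "excluded") <- excluded
  out
}

#' Haul-out fix cells per animal
#'
#' Cells (snapped to land) where each animal was recorded hauled out.
#'
#' @param tracks regularised tracks.
#' @param grid a [GridSpec-class].
#' @return data.frame `animal_id`, `cell` (unique pairs).
#' @export
hauloutFixCells <- function(tracks, grid) {
  h <- tracks[tracks$at_haulout, , drop = FALSE]
  if (!nrow(h)) return(data.frame(animal_id = character(), cell = integer()))
  cells <- vapply(seq_len(nrow(h)), function(i)
    snapToLand(grid, xyToCell(grid, h$x_m[i], h$y_m[i])), integer(1))
  unique(data.frame(animal_id = h$animal_id, cell = cells))
}
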