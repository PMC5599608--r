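#' Build the at-sea adjacency graph
#'
#' Nodes are sea cells; edges join cells adjacent under 16-connectivity
#' (queen + knight moves; 8-connectivity via `connectivity = 8`), weighted
#' by centre-to-centre Euclidean distance (600, 600\eqn{\sqrt{2}},
#' 600\eqn{\sqrt{5}} m at the default cell size). Land acts as a barrier
#' simply by owning no node.
#'
#' @param grid a [GridSpec-class].
#' @param connectivity 16 (default) or 8.
#' @return an undirected weighted [igraph][igraph::graph_from_data_frame]
#'   graph whose vertex names are sea-cell ids.
#' @export
buildSeaGraph <- function(grid, connectivity = 16) {
  sea <- which(!grid@land)
  g <- igraph::make_empty_graph(n = length(sea), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(sea))
  if (length(sea) < 2) return(g)
  nb <- cellNeighbours(grid, sea, connectivity)
  nb <- nb[!grid@land[nb$to] & nb$from < nb$to, , drop = FALSE]
  nb <- nb[passableSteps(grid, nb$from, nb$to), , drop = FALSE]
  if (nrow(nb)) {
    idx <- match(c(rbind(nb$from, nb$to)), sea)
    g <- igraph::add_edges(g, idx, weight = nb$steplen)
  }
  g
}

# A diagonal or knight step must not cut a corner through land: the
# centre-to-centre segment passes through intermediate cells (two for a
# knight move, the two orthogonal neighbours for a diagonal), and the step
# is passable only when none of the sea-to-sea intermediates it crosses is
# land. Rook steps are always passable (endpoints are already sea).
passableSteps <- function(grid, from, to) {
  nr <- grid@nrow
  r1 <- (from - 1L) %% nr + 1L; c1 <- (from - 1L) %/% nr + 1L
  r2 <- (to - 1L) %% nr + 1L;   c2 <- (to - 1L) %/% nr + 1L
  dr <- r2 - r1; dc <- c2 - c1
  ok <- rep(TRUE, length(from))
  landAt <- function(r, c) grid@land[(c - 1L) * nr + r]
  diag1 <- abs(dr) == 1L & abs(dc) == 1L
  if (any(diag1)) {
    # both orthogonal intermediates land -> the corner point is land-locked
    ok[diag1] <- !(landAt(r1[diag1] + dr[diag1], c1[diag1]) &
                   landAt(r1[diag1], c1[diag1] + dc[diag1]))
  }
  knight <- abs(dr) + abs(dc) == 3L
  if (any(knight)) {
    # the segment crosses the two cells adjacent to its midpoint
    mr <- dr[knight]; mc <- dc[knight]
    a_r <- r1[knight] + ifelse(abs(mr) == 2L, sign(mr), 0L)
    a_c <- c1[knight] + ifelse(abs(mc) == 2L, sign(mc), 0L)
    b_r <- r1[knight] + ifelse(abs(mr) == 2L, sign(mr), mr)
    b_c <- c1[knight] + ifelse(abs(mc) == 2L, sign(mc), mc)
    ok[knight] <- !landAt(a_r, a_c) & !landAt(b_r, b_c)
  }
  ok
}

# Map a set of source cells (land or sea) to the sea cells where distance
# accumulation starts. Land sources are projected to their 8-adjacent sea
# cells with zero initial cost (haul-outs are onshore; trips start at the
# waterline). Errors if a source touches no sea.
sourceSeaCells <- function(grid, source_cells) {
  out <- integer()
  for (cell in source_cells) {
    if (grid@land[cell]) {
      adj <- adjacentSeaCells(grid, cell)
      if (!length(adj))
        stop(sprintf("source cell %d is on land with no adjacent sea cell", cell))
      out <- c(out, adj)
    } else {
      out <- c(out, as.integer(cell))
    }
  }
  sort(unique(out))
}

#' Shortest at-sea distance surface
#'
#' Multi-source shortest-path (Dijkstra) distance from `source_cells` to
#' every sea cell over the 16-neighbour sea graph, respecting land
#' barriers. Land sources (haul-out cells) are projected to their adjacent
#' sea cells with zero initial cost, so the surface is 0 at the waterline.
#'
#' @param grid a [GridSpec-class].
#' @param source_cells integer cell ids (land cells must be sea-adjacent).
#' @param graph optional precomputed [buildSeaGraph()] result.
#' @param connectivity passed to [buildSeaGraph()] when `graph` is `NULL`.
#' @return numeric matrix (m): distance at sea cells, `Inf` where
#'   unreachable, `NA` on land.
#' @export
atseaDistance <- function(grid, source_cells, graph = NULL, connectivity = 16) {
  if (is.null(graph)) graph <- buildSeaGraph(grid, connectivity)
  src <- sourceSeaCells(grid, source_cells)
  vnames <- igraph::V(graph)$name
  vsrc <- match(as.character(src), vnames)
  if (anyNA(vsrc)) stop("internal: source sea cell missing from graph")
  d <- igraph::distances(graph, v = vsrc, algorithm = "dijkstra")
  dmin <- if (length(vsrc) > 1) apply(d, 2, min) else as.numeric(d)
  out <- matrix(NA_real_, grid@nrow, grid@ncol)
  out[as.integer(vnames)] <- dmin
  out
}

#' Pairwise at-sea distances between haul-out cells
#'
#' Centre-to-centre least-cost distance between onshore haul-out cells,
#' computed on the sea graph augmented with the haul-out cells themselves,
#' each linked to the sea cells in its 16-neighbourhood. Any path between
#' two haul-outs therefore enters the sea immediately (land-land edges do
#' not exist), so distinct haul-out cells are never closer than two entry
#' steps. Unreachable pairs get `Inf`.
#'
#' @param grid a [GridSpec-class].
#' @param cells integer haul-out cell ids (land or sea).
#' @param graph optional precomputed [buildSeaGraph()] result.
#' @return symmetric numeric matrix of distances (m), zero diagonal,
#'   dimnames = cell ids.
#' @export
hauloutPairDistances <- function(grid, cells, graph = NULL) {
  cells <- as.integer(cells)
  if (is.null(graph)) graph <- buildSeaGraph(grid)
  g <- graph
  land_cells <- cells[grid@land[cells]]
  if (length(land_cells)) {
    g <- igraph::add_vertices(g, length(land_cells),
                              name = as.character(land_cells))
    nb <- cellNeighbours(grid, land_cells, connectivity = 16)
    nb <- nb[!grid@land[nb$to], , drop = FALSE]
    # shore entry: any 8-adjacent sea cell is accessible from the shore
    # (consistent with the waterline projection); knight entries must not
    # cross land
    knight <- abs((nb$to - 1) %% grid@nrow - (nb$from - 1) %% grid@nrow) +
      abs((nb$to - 1) %/% grid@nrow - (nb$from - 1) %/% grid@nrow) == 3
    nb <- nb[!knight | passableSteps(grid, nb$from, nb$to), , drop = FALSE]
    if (nrow(nb)) {
      vn <- igraph::V(g)$name
      idx <- match(as.character(c(rbind(nb$from, nb$to))), vn)
      g <- igraph::add_edges(g, idx, weight = nb$steplen)
    }
  }
  vn <- igraph::V(g)$name
  v <- match(as.character(cells), vn)
  if (anyNA(v)) stop("haul-out cell missing from augmented sea graph")
  d <- igraph::distances(g, v = v, to = v, algorithm = "dijkstra")
  dimnames(d) <- list(cells, cells)
  d
}
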