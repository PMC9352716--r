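#' Street graphs for the detour navigation test
#'
#' A minimal undirected street network: nodes with planar coordinates and an
#' intersection flag (a decision point: degree >= 3, or flagged explicitly),
#' and edges with lengths in km. This is the substrate on which walks are
#' recorded and wrong turns detected.
#'
#' @param nodes data frame with columns `id` (character), `x`, `y`, and
#'   optionally `intersection` (logical; defaults to degree >= 3).
#' @param edges data frame with columns `from`, `to`, `length_km` (> 0).
#' @return object of class `street_graph` (list of tibbles `nodes`, `edges`),
#'   validated to be connected with positive edge lengths.
#' @export
street_graph <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("from", "to", "length_km") %in% names(edges)))
  nodes$id <- as.character(nodes$id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (anyDuplicated(nodes$id)) stop_navdis("duplicate node ids")
  if (any(edges$length_km <= 0)) stop_navdis("edge lengths must be > 0")
  unknown <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(unknown)) {
    stop_navdis("edge endpoint not in nodes: %s", paste(unknown, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE, vertices = nodes$id)
  if (!igraph::is_connected(g)) stop_navdis("street graph must be connected")
  deg <- igraph::degree(g)
  if (!"intersection" %in% names(nodes)) {
    nodes$intersection <- deg[nodes$id] >= 3
  }
  out <- list(nodes = nodes, edges = edges)
  class(out) <- "street_graph"
  out
}

#' @export
print.street_graph <- function(x, ...) {
  cat(sprintf("street_graph: %d nodes (%d intersections), %d edges, %.2f km total\n",
              nrow(x$nodes), sum(x$nodes$intersection), nrow(x$edges),
              sum(x$edges$length_km)))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    cbind(graph$edges[, c("from", "to")], weight = graph$edges$length_km),
    directed = FALSE, vertices = graph$nodes$id)
}

# canonical undirected edge key
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

path_edge_keys <- function(path) {
  if (length(path) < 2) return(character())
  edge_key(path[-length(path)], path[-1])
}

graph_edge_keys <- function(graph) edge_key(graph$edges$from, graph$edges$to)

#' Total length of a node path, in km
#' @param graph a [street_graph()].
#' @param path character vector of node ids forming a walkable path.
#' @export
path_length_km <- function(graph, path) {
  keys <- path_edge_keys(path)
  lookup <- setNames(graph$edges$length_km, graph_edge_keys(graph))
  if (any(!keys %in% names(lookup))) {
    stop_navdis("path uses edge absent from graph: %s",
                paste(setdiff(keys, names(lookup)), collapse = ", "))
  }
  sum(lookup[keys])
}

#' Number of intersection nodes along a path
#' @inheritParams path_length_km
#' @export
path_intersections <- function(graph, path) {
  flag <- setNames(graph$nodes$intersection, graph$nodes$id)
  sum(flag[unique(path)])
}

#' Rectangular-grid street graph
#'
#' Convenience generator for simulations: an `nx` by `ny` grid of streets
#' with uniform block length. Interior nodes have degree 4 and are
#' intersections.
#'
#' @param nx,ny grid dimensions (>= 2).
#' @param block_km block edge length in km.
#' @export
make_grid_street_graph <- function(nx = 5, ny = 5, block_km = 0.1) {
  stopifnot(nx >= 2, ny >= 2, block_km > 0)
  idx <- function(i, j) sprintf("n%d_%d", i, j)
  nodes <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  nodes <- tibble::tibble(id = idx(nodes$i, nodes$j),
                          x = (nodes$i - 1) * block_km,
                          y = (nodes$j - 1) * block_km)
  e <- list()
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (i < nx) e[[length(e) + 1]] <- c(idx(i, j), idx(i + 1, j))
    if (j < ny) e[[length(e) + 1]] <- c(idx(i, j), idx(i, j + 1))
  }
  em <- do.call(rbind, e)
  street_graph(nodes, tibble::tibble(from = em[, 1], to = em[, 2],
                                     length_km = block_km))
}

#' Write / read a street graph as GeoJSON
#'
#' Nodes become `Point` features (properties `id`, `intersection`), edges
#' become `LineString` features (properties `from`, `to`, `length_km`).
#'
#' @param graph a [street_graph()].
#' @param path output file.
#' @export
write_street_graph_geojson <- function(graph, path) {
  xy <- setNames(split(cbind(graph$nodes$x, graph$nodes$y),
                       seq_len(nrow(graph$nodes))), graph$nodes$id)
  pts <- lapply(seq_len(nrow(graph$nodes)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(graph$nodes$x[i], graph$nodes$y[i])),
         properties = list(id = graph$nodes$id[i],
                           intersection = graph$nodes$intersection[i]))
  })
  lns <- lapply(seq_len(nrow(graph$edges)), function(i) {
    f <- graph$edges$from[i]; t <- graph$edges$to[i]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(xy[[f]], xy[[t]])),
         properties = list(from = f, to = t,
                           length_km = graph$edges$length_km[i]))
  })
  fc <- list(type = "FeatureCollection", features = c(pts, lns))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_street_graph_geojson
#' @export
read_street_graph_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop_navdis("file %s is not a GeoJSON FeatureCollection", path)
  }
  nodes <- list(); edges <- list()
  for (f in fc$features) {
    if (identical(f$geometry$type, "Point")) {
      nodes[[length(nodes) + 1]] <- tibble::tibble(
        id = f$properties$id,
        x = as.numeric(f$geometry$coordinates[[1]]),
        y = as.numeric(f$geometry$coordinates[[2]]),
        intersection = isTRUE(f$properties$intersection))
    } else if (identical(f$geometry$type, "LineString")) {
      edges[[length(edges) + 1]] <- tibble::tibble(
        from = f$properties$from, to = f$properties$to,
        length_km = as.numeric(f$properties$length_km))
    }
  }
  street_graph(dplyr::bind_rows(nodes), dplyr::bind_rows(edges))
}

#' Write a route as a GeoJSON LineString
#'
#' @param graph a [street_graph()].
#' @param path node sequence of the route.
#' @param route_type `"original"` or `"detour"`.
#' @param file output file.
#' @export
write_route_geojson <- function(graph, path, route_type, file) {
  stopifnot(route_type %in% c("original", "detour"))
  xy <- graph$nodes[match(path, graph$nodes$id), c("x", "y")]
  if (anyNA(xy$x)) stop_navdis("route node not in graph")
  feat <- list(type = "Feature",
               geometry = list(type = "LineString",
                               coordinates = lapply(seq_len(nrow(xy)),
                                 function(i) c(xy$x[i], xy$y[i]))),
               properties = list(route_type = route_type,
                                 nodes = as.list(path)))
  fc <- list(type = "FeatureCollection", features = list(feat))
  jsonlite::write_json(fc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_route_geojson
#' @export
read_route_geojson <- function(file) {
  fc <- jsonlite::read_json(file)
  f <- fc$features[[1]]
  list(route_type = f$properties$route_type,
       path = vapply(f$properties$nodes, as.character, character(1)))
}
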