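#' Semantic connectivity map (minimum spanning tree)
#'
#' Builds the semantic connectivity map: the minimum spanning tree of the
#' complete graph whose edge lengths are the association distances
#' `d = 1 - strength`. Adjacent nodes in the tree have the highest mutual
#' affinity. Kruskal's algorithm with deterministic tie-breaking: edges are
#' ordered by (distance, label_i, label_j) lexicographically. Hub statistics
#' (degree and summed incident strength) are attached, and the central node is
#' the one with maximal degree (ties by summed strength).
#'
#' @param distances Square symmetric matrix of finite distances (e.g.
#'   [strengths_to_distances()]), or a `link_strength_matrix` (converted
#'   automatically).
#' @param labels Node labels; default taken from the matrix dimnames.
#' @return An object of class `semantic_map`: `nodes`, `edges` (tibble with
#'   `from`, `to`, `distance`, `strength`), `hub_scores` (tibble with `node`,
#'   `degree`, `summed_strength`), `central_node`.
#' @examples
#' s <- matrix(c(1, .9, .5, .9, 1, .8, .5, .8, 1), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' semantic_map(strengths_to_distances(link_strengths(s)))
#' @export
semantic_map <- function(distances, labels = NULL) {
  if (inherits(distances, "link_strength_matrix")) {
    distances <- strengths_to_distances(distances)
  }
  d <- as.matrix(unclass(distances))
  n <- nrow(d)
  if (n != ncol(d)) {
    abort_autocmap("Distance matrix must be square.", "autocmap_invalid_argument")
  }
  if (any(!is.finite(d)) || any(abs(d - t(d)) > 1e-12)) {
    abort_autocmap("Distance matrix must be finite and symmetric.",
                   "autocmap_invalid_argument")
  }
  labels <- labels %||% rownames(d) %||% paste0("V", seq_len(n))

  # all edges, ordered by (distance, label_i, label_j)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  a <- pmin(labels[idx[, 1]], labels[idx[, 2]])
  b <- pmax(labels[idx[, 1]], labels[idx[, 2]])
  ord <- order(d[idx], a, b, method = "radix")
  ei <- idx[ord, 1]; ej <- idx[ord, 2]

  # Kruskal with union-find
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  keep <- logical(length(ei))
  taken <- 0L
  for (k in seq_along(ei)) {
    ri <- find(ei[k]); rj <- find(ej[k])
    if (ri != rj) {
      parent[ri] <- rj
      keep[k] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  edges <- tibble::tibble(
    from = pmin(labels[ei[keep]], labels[ej[keep]]),
    to = pmax(labels[ei[keep]], labels[ej[keep]]),
    distance = d[cbind(ei[keep], ej[keep])],
    strength = 1 - d[cbind(ei[keep], ej[keep])]
  ) |> dplyr::arrange(.data$distance, .data$from, .data$to)

  hub <- tibble::tibble(node = c(edges$from, edges$to),
                        strength = rep(edges$strength, 2)) |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(degree = dplyr::n(),
                     summed_strength = sum(.data$strength), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$degree), dplyr::desc(.data$summed_strength),
                   .data$node)
  structure(list(nodes = labels, edges = edges, hub_scores = hub,
                 central_node = hub$node[1]),
            class = "semantic_map")
}

#' @export
print.semantic_map <- function(x, ...) {
  cat("<semantic_map> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges; central node: ", x$central_node, "\n", sep = "")
  print(utils::head(x$edges, 10))
  invisible(x)
}

#' @rdname semantic_map
#' @param x A `semantic_map`.
#' @param ... Unused.
#' @export
tidy.semantic_map <- function(x, ...) x$edges

#' @rdname semantic_map
#' @export
glance.semantic_map <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                 total_distance = sum(x$edges$distance),
                 central_node = x$central_node,
                 central_degree = x$hub_scores$degree[1])
}

map_to_igraph <- function(map) {
  g <- igraph::graph_from_data_frame(
    map$edges[, c("from", "to", "strength", "distance")],
    directed = FALSE,
    vertices = tibble::tibble(name = map$nodes,
                              central = map$nodes == map$central_node))
  g
}

#' Export a semantic map
#'
#' Writes the map to GraphML (via igraph, with `strength`/`distance` edge
#' attributes and a `central` node flag), Graphviz DOT (edge labels formatted
#' to 2 decimals) or a flat edge-list CSV.
#'
#' @param map A [semantic_map()].
#' @param path Output file path.
#' @param format `"graphml"`, `"dot"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_map <- function(map, path, format = c("graphml", "dot", "csv")) {
  if (!inherits(map, "semantic_map")) {
    abort_autocmap("`map` must be a semantic_map.", "autocmap_invalid_argument")
  }
  format <- tryCatch(match.arg(format),
                     error = function(e) abort_autocmap(
                       paste0("Unknown export format: ", format[1]),
                       "autocmap_invalid_argument"))
  if (format == "graphml") {
    igraph::write_graph(map_to_igraph(map), path, format = "graphml")
  } else if (format == "csv") {
    readr::write_csv(map$edges, path)
  } else {
    quote_id <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
    lines <- c("graph semantic_map {",
               paste0("  ", quote_id(map$central_node),
                      " [color=red, style=filled];"),
               sprintf('  %s -- %s [label="%.2f", weight=%.6f];',
                       quote_id(map$edges$from), quote_id(map$edges$to),
                       map$edges$strength, map$edges$strength),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a semantic map back from GraphML
#'
#' @param path A GraphML file written by [export_map()].
#' @return A `semantic_map`.
#' @export
import_map_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  d <- 1 - ed$strength
  edges <- tibble::tibble(from = pmin(ed$from, ed$to),
                          to = pmax(ed$from, ed$to),
                          distance = ed$distance, strength = ed$strength) |>
    dplyr::arrange(.data$distance, .data$from, .data$to)
  hub <- tibble::tibble(node = c(edges$from, edges$to),
                        strength = rep(edges$strength, 2)) |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(degree = dplyr::n(),
                     summed_strength = sum(.data$strength), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$degree), dplyr::desc(.data$summed_strength),
                   .data$node)
  structure(list(nodes = igraph::V(g)$name, edges = edges, hub_scores = hub,
                 central_node = hub$node[1]),
            class = "semantic_map")
}

#' Plot a semantic connectivity map
#'
#' Tree layout with edge widths proportional to link strength and the central
#' node highlighted.
#'
#' @param object A [semantic_map()].
#' @param label_edges Show 2-decimal strength labels on edges.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.semantic_map <- function(object, label_edges = TRUE, ...) {
  g <- map_to_igraph(object)
  xy <- igraph::layout_with_kk(g, weights = igraph::E(g)$distance + 0.05)
  nodes <- tibble::tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                          central = igraph::V(g)$central)
  ed <- object$edges |>
    dplyr::left_join(nodes[, c("name", "x", "y")], by = c(from = "name")) |>
    dplyr::left_join(nodes[, c("name", "x", "y")], by = c(to = "name"),
                     suffix = c("", "end"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$strength),
                          colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, colour = .data$central),
                        size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "red"), guide = "none") +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::theme_void()
  if (label_edges) {
    p <- p + ggplot2::geom_text(
      data = ed,
      ggplot2::aes((.data$x + .data$xend) / 2, (.data$y + .data$yend) / 2,
                   label = sprintf("%.2f", .data$strength)),
      size = 2.5, colour = "grey30")
  }
  p
}
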