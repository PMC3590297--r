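# Biological networks: Cytoscape XGMML import, radius-driven z-depth
# layout, and conversion to the sphere-and-link quadric scene the
# renderer consumes.

#' Network graph container
#'
#' @param nodes data.frame with columns id, label, x, y, radius, r, g, b
#'   and z (layout depth, default 0). Ids must be unique, radii positive.
#' @param edges data.frame with columns source and target (node ids).
#' @return Object of class \code{"network_graph"}.
#' @export
network_graph <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (anyDuplicated(nodes$id)) stop("duplicate node id")
  if (any(nodes$radius <= 0)) stop("node radii must be positive")
  if (is.null(nodes$z)) nodes$z <- 0
  if (nrow(edges)) {
    missing_src <- setdiff(edges$source, nodes$id)
    missing_tgt <- setdiff(edges$target, nodes$id)
    if (length(missing_src) || length(missing_tgt)) {
      bad <- c(missing_src, missing_tgt)[1]
      stop(sprintf("edge references unknown node id '%s'", bad))
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("network_graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

hex_to_rgb <- function(hex) {
  ok <- grepl("^#[0-9a-fA-F]{6}$", hex)
  out <- matrix(0.5, length(hex), 3)
  if (any(ok)) {
    h <- hex[ok]
    out[ok, ] <- cbind(strtoi(substr(h, 2, 3), 16L),
                       strtoi(substr(h, 4, 5), 16L),
                       strtoi(substr(h, 6, 7), 16L)) / 255
  }
  out
}

rgb_to_hex <- function(rgb) {
  rgb <- matrix(rgb, ncol = 3)
  sprintf("#%02x%02x%02x", as.integer(round(rgb[, 1] * 255)),
          as.integer(round(rgb[, 2] * 255)),
          as.integer(round(rgb[, 3] * 255)))
}

#' Parse a Cytoscape XGMML network
#'
#' Extracts node ids, labels, 2D positions, sizes and fill colors plus the
#' edge list. The node radius is half the graphics width (falling back to
#' half the height, then 1.0); fill colors come from the hex fill
#' attribute (neutral gray when absent). The Cytoscape y axis grows
#' downward, so imported y is negated to keep the rendered layout in the
#' orientation of the Cytoscape picture. Nodes without coordinates sit at
#' (0, 0) and are reported via a warning.
#'
#' @param text XGMML document text.
#' @return A [network_graph()]; node order is document order.
#' @export
parse_xgmml <- function(text) {
  doc <- xml2::read_xml(text)
  node_els <- xml2::xml_find_all(doc, ".//*[local-name()='node']")
  if (length(node_els) == 0L) stop("XGMML document contains no nodes")
  get_attr <- function(els, a) xml2::xml_attr(els, a)
  gr <- lapply(node_els, function(nd)
    xml2::xml_find_first(nd, "./*[local-name()='graphics']"))
  gattr <- function(a) vapply(gr, function(g)
    if (inherits(g, "xml_missing")) NA_character_ else xml2::xml_attr(g, a), "")
  id <- get_attr(node_els, "id")
  if (anyDuplicated(id)) stop("duplicate node id in XGMML document")
  label <- get_attr(node_els, "label")
  label[is.na(label)] <- id[is.na(label)]
  x <- suppressWarnings(as.numeric(gattr("x")))
  y <- suppressWarnings(as.numeric(gattr("y")))
  w <- suppressWarnings(as.numeric(gattr("w")))
  h <- suppressWarnings(as.numeric(gattr("h")))
  fill <- gattr("fill")
  no_xy <- !is.finite(x) | !is.finite(y)
  if (any(no_xy))
    warning(sprintf("%d node(s) without coordinates placed at (0, 0)",
                    sum(no_xy)))
  x[!is.finite(x)] <- 0; y[!is.finite(y)] <- 0
  radius <- ifelse(is.finite(w) & w > 0, w / 2,
                   ifelse(is.finite(h) & h > 0, h / 2, 1.0))
  col <- hex_to_rgb(ifelse(is.na(fill), "", fill))
  nodes <- data.frame(id = id, label = label, x = x, y = -y, radius = radius,
                      r = col[, 1], g = col[, 2], b = col[, 3], z = 0,
                      stringsAsFactors = FALSE)
  edge_els <- xml2::xml_find_all(doc, ".//*[local-name()='edge']")
  edges <- data.frame(source = xml2::xml_attr(edge_els, "source"),
                      target = xml2::xml_attr(edge_els, "target"),
                      stringsAsFactors = FALSE)
  network_graph(nodes, edges)
}

#' Serialize a network to XGMML
#'
#' Writes the Cytoscape-dialect document [parse_xgmml()] reads (the y
#' axis is negated back on output, so write-then-parse round-trips).
#'
#' @param graph a [network_graph()].
#' @param label document label.
#' @return XGMML text.
#' @export
write_xgmml <- function(graph, label = "hyperview network") {
  stopifnot(inherits(graph, "network_graph"))
  n <- graph$nodes
  node_lines <- sprintf(
    paste0("  <node id=\"%s\" label=\"%s\">\n",
           "    <graphics type=\"ELLIPSE\" x=\"%.9g\" y=\"%.9g\" w=\"%.9g\" h=\"%.9g\" fill=\"%s\"/>\n",
           "  </node>"),
    n$id, n$label, n$x, -n$y, 2 * n$radius, 2 * n$radius,
    rgb_to_hex(cbind(n$r, n$g, n$b)))
  e <- graph$edges
  edge_lines <- if (nrow(e))
    sprintf("  <edge source=\"%s\" target=\"%s\"/>", e$source, e$target)
  else character(0)
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
         sprintf("<graph label=\"%s\" xmlns=\"http://www.cs.rpi.edu/XGMML\">\n", label),
         paste(c(node_lines, edge_lines), collapse = "\n"),
         "\n</graph>\n")
}

#' Distribute nodes along z by radius
#'
#' Assigns \code{z = depth_factor * (r - r_min) / (r_max - r_min)}: a
#' linear min-max normalization of node radius, so the largest node sits
#' at exactly \code{|depth_factor|} and the smallest at 0. With the
#' package camera convention (the network camera sits on the negative z
#' side), positive \code{depth_factor} pushes bigger nodes into the
#' background and negative pulls them to the foreground. Equal radii
#' leave all z at 0. xy positions are untouched; the rule is idempotent
#' and unchanged under rescaling all radii.
#'
#' @param graph a [network_graph()].
#' @param depth_factor depth scale (layout units; sign picks
#'   background/foreground).
#' @return The graph with its nodes' \code{z} column filled.
#' @export
depth_layout <- function(graph, depth_factor = 1) {
  stopifnot(inherits(graph, "network_graph"))
  r <- graph$nodes$radius
  rng <- range(r)
  graph$nodes$z <- if (rng[1] == rng[2]) rep(0, length(r))
                   else depth_factor * (r - rng[1]) / (rng[2] - rng[1])
  graph
}

#' Convert a network to a renderable quadric scene
#'
#' One sphere per node at (x, y, z) with the node's radius and color; one
#' low-shrink bond hyperboloid per edge between the node centers, built
#' with the same constructors the molecular representation uses.
#'
#' @param graph a [network_graph()] (layout applied).
#' @param link_radius radius of the link hyperboloids at their ends.
#' @param shrink shrink factor for links in [0, 1).
#' @param link_color RGB for links.
#' @return list of [quadric()] objects: all node spheres (document
#'   order), then one hyperboloid per edge.
#' @export
network_to_scene <- function(graph, link_radius = 0.3, shrink = 0.1,
                             link_color = c(0.6, 0.6, 0.6)) {
  stopifnot(inherits(graph, "network_graph"), link_radius > 0)
  n <- graph$nodes
  pos <- cbind(n$x, n$y, n$z)
  spheres <- lapply(seq_len(nrow(n)), function(i)
    sphere_quadric(pos[i, ], n$radius[i], c(n$r[i], n$g[i], n$b[i])))
  idx <- match(graph$edges$source, n$id)
  jdx <- match(graph$edges$target, n$id)
  links <- lapply(seq_len(nrow(graph$edges)), function(e) {
    hb <- tryCatch(
      bond_hyperboloid(pos[idx[e], ], link_radius, pos[jdx[e], ], link_radius,
                       shrink = shrink, color = link_color),
      error = function(err) stop(sprintf("edge %s -> %s: %s",
                                         graph$edges$source[e],
                                         graph$edges$target[e],
                                         conditionMessage(err)), call. = FALSE))
    hb$quadric
  })
  c(spheres, links)
}
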