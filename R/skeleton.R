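#' Ground-truth skeleton of a simulated fiber forest
#'
#' Dense polyline representation: every node stores its parent (0 for tree
#' roots), so edges are the parent–child pairs. Positions are physical µm in
#' the stack frame (z = 0 at the skin surface).
#'
#' @param nodes Data frame with columns `id, x, y, z, radius, parent,
#'   tree_id, caliber, epidermal`.
#' @param boundary_z Depth (µm) of the dermal–epidermal boundary; nodes with
#'   `z < boundary_z` are epidermal.
#' @param extent Physical extent (µm) of the simulated volume.
#' @return A `skin_skeleton` object.
#' @export
skin_skeleton <- function(nodes, boundary_z, extent) {
  need <- c("id", "x", "y", "z", "radius", "parent", "tree_id", "caliber",
            "epidermal")
  if (!all(need %in% names(nodes))) stopf("skeleton nodes missing columns")
  if (nrow(nodes) > 0) {
    if (any(nodes$radius <= 0)) stopf("skeleton radii must be positive")
    if (any(nodes$x < 0 | nodes$y < 0 | nodes$z < 0) ||
        any(nodes$x > extent[1] | nodes$y > extent[2] | nodes$z > extent[3]))
      stopf("skeleton nodes outside the simulated volume")
  }
  structure(list(nodes = nodes, boundary_z = boundary_z,
                 extent = as.numeric(extent)),
            class = "skin_skeleton")
}

empty_skeleton_nodes <- function() {
  data.frame(id = integer(), x = numeric(), y = numeric(), z = numeric(),
             radius = numeric(), parent = integer(), tree_id = integer(),
             caliber = character(), epidermal = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.skin_skeleton <- function(x, ...) {
  cat(sprintf("<skin_skeleton> %d nodes, %d trees, total length %.1f um\n",
              nrow(x$nodes), length(unique(x$nodes$tree_id)),
              skeleton_total_length(x)))
  invisible(x)
}

#' Total centerline length of a skeleton
#'
#' Sum of Euclidean lengths of all parent–child segments.
#'
#' @param skeleton A `skin_skeleton`.
#' @return Length in µm.
#' @export
skeleton_total_length <- function(skeleton) {
  nd <- skeleton$nodes
  if (nrow(nd) == 0) return(0)
  ch <- nd[nd$parent > 0, ]
  if (nrow(ch) == 0) return(0)
  pa <- nd[match(ch$parent, nd$id), ]
  sum(sqrt((ch$x - pa$x)^2 + (ch$y - pa$y)^2 + (ch$z - pa$z)^2))
}

#' Geometric fiber graph
#'
#' Nodes are branch points, endpoints and isolated loop anchors; edges carry
#' full polyline geometry and arc length in µm. Components carry an optional
#' caliber class (`"thin"`/`"thick"`) filled by [classify_fiber_caliber()].
#'
#' @param nodes Data frame `id, x, y, z, radius`.
#' @param edges Data frame `from, to` (+ optional `length`).
#' @param paths List, one polyline matrix (k x 3, µm) per edge, endpoints
#'   equal to the node coordinates.
#' @return A `fiber_graph` with `degree` and `component` columns filled and
#'   edge lengths computed from the polylines.
#' @export
fiber_graph <- function(nodes, edges, paths) {
  if (nrow(edges) != length(paths)) stopf("one polyline per edge required")
  if (nrow(edges) > 0 && any(edges$from == edges$to &
      vapply(paths, nrow, 0L) <= 2))
    stopf("self-loop without geometry not allowed")
  len <- vapply(paths, polyline_length, 0)
  if (nrow(edges) > 0 && any(len <= 0)) stopf("edge lengths must be positive")
  edges$length <- len
  deg <- rep(0L, nrow(nodes))
  if (nrow(edges) > 0) {
    tb <- table(factor(c(edges$from, edges$to), levels = nodes$id))
    deg <- as.integer(tb)
  }
  nodes$degree <- deg
  comp <- rep(NA_integer_, nrow(nodes))
  if (nrow(nodes) > 0) {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(edges)) data.frame(from = as.character(edges$from),
                                      to = as.character(edges$to))
          else data.frame(from = character(), to = character()),
      directed = FALSE,
      vertices = data.frame(name = as.character(nodes$id)))
    comp <- as.integer(igraph::components(g)$membership[
      as.character(nodes$id)])
  }
  nodes$component <- comp
  if (nrow(edges) > 0)
    edges$component <- nodes$component[match(edges$from, nodes$id)]
  else edges$component <- integer()
  comps <- sort(unique(stats::na.omit(nodes$component)))
  structure(list(nodes = nodes, edges = edges, paths = paths,
                 components = data.frame(
                   component = comps,
                   caliber = rep(NA_character_, length(comps)))),
            class = "fiber_graph")
}

#' @export
print.fiber_graph <- function(x, ...) {
  cat(sprintf("<fiber_graph> %d nodes, %d edges, %d components, total length %.1f um\n",
              nrow(x$nodes), nrow(x$edges),
              nrow(x$components), sum(x$edges$length)))
  invisible(x)
}

#' An empty fiber graph (flagged)
#' @return A `fiber_graph` with zero nodes and attribute `empty = TRUE`.
#' @export
empty_fiber_graph <- function() {
  g <- fiber_graph(data.frame(id = integer(), x = numeric(), y = numeric(),
                              z = numeric(), radius = numeric()),
                   data.frame(from = integer(), to = integer()),
                   list())
  attr(g, "empty") <- TRUE
  g
}

polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                    p[-nrow(p), , drop = FALSE])^2)))
}

#' Convert a ground-truth skeleton to a fiber graph
#'
#' Branch points, endpoints and roots become graph nodes; maximal
#' degree-2 chains become edges with the dense polyline as geometry. Useful
#' as the reference graph when validating tracing and quantification.
#'
#' @param skeleton A `skin_skeleton`.
#' @return A `fiber_graph`; component caliber is taken from the skeleton's
#'   per-tree class, and node epidermal flags are carried over as column
#'   `epidermal`.
#' @export
skeleton_to_graph <- function(skeleton) {
  nd <- skeleton$nodes
  if (nrow(nd) == 0) return(empty_fiber_graph())
  idx <- match(nd$parent, nd$id)          # NA for roots
  nchild <- tabulate(idx[!is.na(idx)], nbins = nrow(nd))
  deg <- nchild + as.integer(!is.na(idx))
  is_gnode <- deg != 2
  children <- split(seq_len(nrow(nd)), factor(idx, levels = seq_len(nrow(nd))))
  gnode_rows <- which(is_gnode)
  gid <- match(seq_len(nrow(nd)), gnode_rows)  # NA for pass-through nodes
  nodes <- data.frame(id = seq_along(gnode_rows),
                      x = nd$x[gnode_rows], y = nd$y[gnode_rows],
                      z = nd$z[gnode_rows], radius = nd$radius[gnode_rows])
  edges_from <- integer(); edges_to <- integer(); paths <- list()
  for (gr in gnode_rows) {
    for (ch in children[[gr]]) {
      pts <- list(c(nd$x[gr], nd$y[gr], nd$z[gr]))
      cur <- ch
      while (!is_gnode[cur]) {
        pts[[length(pts) + 1]] <- c(nd$x[cur], nd$y[cur], nd$z[cur])
        cur <- children[[cur]][1]
      }
      pts[[length(pts) + 1]] <- c(nd$x[cur], nd$y[cur], nd$z[cur])
      edges_from <- c(edges_from, gid[gr])
      edges_to <- c(edges_to, gid[cur])
      paths[[length(paths) + 1]] <- do.call(rbind, pts)
    }
  }
  g <- fiber_graph(nodes, data.frame(from = edges_from, to = edges_to), paths)
  g$nodes$epidermal <- nd$epidermal[gnode_rows]
  # carry caliber per component via the tree each component came from
  tree_of_comp <- tapply(nd$tree_id[gnode_rows], g$nodes$component,
                         function(v) v[1])
  cal <- nd$caliber[match(tree_of_comp, nd$tree_id)]
  g$components$caliber <- as.character(cal[match(g$components$component,
                                                 as.integer(names(tree_of_comp)))])
  g
}

#' Write a skeleton (or tree-structured graph) as SWC
#'
#' Standard seven-column SWC, one tree per root; the type column encodes
#' caliber class (3 = thin, 4 = thick). Epidermal flags are written to a
#' companion CSV `<path>.epidermal.csv` keyed by node id rather than as a
#' non-standard extra column.
#'
#' @param skeleton A `skin_skeleton`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skeleton, path) {
  nd <- skeleton$nodes
  type <- ifelse(nd$caliber == "thick", 4L, 3L)
  df <- data.frame(id = nd$id, type = type, x = nd$x, y = nd$y, z = nd$z,
                   radius = nd$radius,
                   parent = ifelse(nd$parent > 0, nd$parent, -1L))
  con <- file(path, "w")
  writeLines("# SWC skin innervation skeleton; type 3 = thin, 4 = thick",
             con)
  write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
  write.csv(data.frame(id = nd$id, epidermal = nd$epidermal),
            paste0(path, ".epidermal.csv"), row.names = FALSE)
  invisible(path)
}

#' Read an SWC skeleton written by [write_swc()]
#'
#' @param path SWC file.
#' @param boundary_z,extent Metadata to restore (µm); defaults infer extent
#'   from the node bounding box.
#' @return A `skin_skeleton`.
#' @export
read_swc <- function(path, boundary_z = NA_real_, extent = NULL) {
  raw <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "radius",
                                  "parent"))
  epi_path <- paste0(path, ".epidermal.csv")
  epid <- if (file.exists(epi_path)) {
    e <- read.csv(epi_path)
    e$epidermal[match(raw$id, e$id)]
  } else rep(FALSE, nrow(raw))
  # assign tree ids by following parents to roots
  parent <- ifelse(raw$parent < 0, 0L, raw$parent)
  tree <- integer(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    j <- i
    while (parent[j] > 0) j <- match(parent[j], raw$id)
    tree[i] <- j
  }
  tree <- match(tree, sort(unique(tree)))
  nodes <- data.frame(id = raw$id, x = raw$x, y = raw$y, z = raw$z,
                      radius = raw$radius, parent = parent,
                      tree_id = tree,
                      caliber = ifelse(raw$type == 4, "thick", "thin"),
                      epidermal = as.logical(epid),
                      stringsAsFactors = FALSE)
  if (is.null(extent))
    extent <- c(max(nodes$x, 0), max(nodes$y, 0), max(nodes$z, 0))
  skin_skeleton(nodes, boundary_z = boundary_z, extent = extent)
}

#' Export a fiber graph as SWC plus an edge-list CSV
#'
#' Tree components are written to `<prefix>.swc` by expanding each edge
#' polyline into an SWC sample chain (interior radii linearly interpolated);
#' components containing cycles go to `<prefix>.edges.csv` with full
#' polyline geometry, so the round trip through [read_fiber_graph()] is
#' lossless for positions, radii and topology.
#'
#' @param graph A `fiber_graph`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_fiber_graph <- function(graph, prefix) {
  nodes_csv <- paste0(prefix, ".nodes.csv")
  edges_csv <- paste0(prefix, ".edges.csv")
  nd <- graph$nodes
  ed <- graph$edges
  write.csv(nd, nodes_csv, row.names = FALSE)
  if (nrow(ed) > 0) {
    geom <- vapply(graph$paths, function(p)
      paste(apply(p, 1, function(r) paste(signif(r, 10), collapse = " ")),
            collapse = ";"), "")
    ed$geometry <- geom
  } else ed$geometry <- character()
  write.csv(ed, edges_csv, row.names = FALSE)
  invisible(prefix)
}

#' Read a fiber graph written by [write_fiber_graph()]
#' @param prefix Path prefix used at write time.
#' @return A `fiber_graph`.
#' @export
read_fiber_graph <- function(prefix) {
  nd <- read.csv(paste0(prefix, ".nodes.csv"))
  ed <- read.csv(paste0(prefix, ".edges.csv"),
                 colClasses = c(geometry = "character"))
  paths <- lapply(ed$geometry, function(s) {
    do.call(rbind, lapply(strsplit(s, ";")[[1]], function(r)
      as.numeric(strsplit(r, " ")[[1]])))
  })
  keep <- c("id", "x", "y", "z", "radius")
  extra <- setdiff(names(nd), c(keep, "degree", "component"))
  g <- fiber_graph(nd[keep], ed[c("from", "to")], paths)
  for (cn in extra) g$nodes[[cn]] <- nd[[cn]]
  g
}
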