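#' Total fiber length within a region of interest
#'
#' Sum of edge arc lengths, with polylines clipped exactly to the
#' axis-aligned `roi` box (Liang–Barsky segment clipping).
#'
#' @param graph A `fiber_graph`.
#' @param roi Optional 2x3 matrix `rbind(lo, hi)` in µm; `NULL` = whole
#'   graph.
#' @return Length in µm.
#' @export
total_fiber_length <- function(graph, roi = NULL) {
  if (nrow(graph$edges) == 0) return(0)
  if (is.null(roi)) return(sum(graph$edges$length))
  sum(vapply(graph$paths, clipped_polyline_length, 0, roi = roi))
}

clipped_polyline_length <- function(p, roi) {
  if (nrow(p) < 2) return(0)
  a <- p[-nrow(p), , drop = FALSE]
  b <- p[-1, , drop = FALSE]
  d <- b - a
  t0 <- rep(0, nrow(a)); t1 <- rep(1, nrow(a))
  for (k in 1:3) {
    # slab [lo, hi] along axis k
    lo <- roi[1, k]; hi <- roi[2, k]
    dk <- d[, k]
    par <- abs(dk) < 1e-12
    inside_par <- a[, k] >= lo & a[, k] <= hi
    tl <- ifelse(par, ifelse(inside_par, 0, 1), (lo - a[, k]) / dk)
    th <- ifelse(par, ifelse(inside_par, 1, 0), (hi - a[, k]) / dk)
    tmin <- pmin(tl, th); tmax <- pmax(tl, th)
    t0 <- pmax(t0, tmin); t1 <- pmin(t1, tmax)
  }
  frac <- pmax(0, t1 - t0)
  sum(frac * sqrt(rowSums(d^2)))
}

#' Count true fiber endings
#'
#' Degree-1 nodes farther than `boundary_margin` from every face of the
#' analysis box are counted as biological endings; endpoints created by
#' clipping at the volume border are excluded.
#'
#' @param graph A `fiber_graph`.
#' @param boundary_margin Exclusion margin from the box faces (µm).
#' @param box 2x3 matrix `rbind(lo, hi)` µm; `NULL` counts every degree-1
#'   node.
#' @return List: `count`, `positions` (data frame of the ending nodes).
#' @export
count_endings <- function(graph, boundary_margin = 3, box = NULL) {
  if (boundary_margin < 0) stopf("boundary_margin must be >= 0")
  nd <- graph$nodes
  ends <- nd[nd$degree == 1, , drop = FALSE]
  if (!is.null(box) && nrow(ends) > 0) {
    ok <- ends$x > box[1, 1] + boundary_margin &
      ends$x < box[2, 1] - boundary_margin &
      ends$y > box[1, 2] + boundary_margin &
      ends$y < box[2, 2] - boundary_margin &
      ends$z > box[1, 3] + boundary_margin &
      ends$z < box[2, 3] - boundary_margin
    ends <- ends[ok, , drop = FALSE]
  }
  list(count = nrow(ends), positions = ends)
}

#' Estimate the dermal–epidermal boundary surface
#'
#' Per lateral position, the deepest extent (largest z) of the epidermal
#' autofluorescence band in a label volume, median-filtered into a smooth
#' height map. Simulator metadata (a constant depth or a full height map)
#' may override for testing.
#'
#' @param labels 3D label array (class 2 = epidermal autofluorescence).
#' @param voxel_size µm per voxel.
#' @param metadata_z Optional known boundary: scalar depth (µm) or an
#'   `nx x ny` matrix.
#' @param median_k Odd lateral median-filter size.
#' @return An `epidermal_surface`: `z` (nx x ny matrix, µm),
#'   `voxel_size`.
#' @export
estimate_epidermal_boundary <- function(labels = NULL,
                                        voxel_size = c(0.427, 0.427, 1),
                                        metadata_z = NULL, median_k = 5L) {
  if (!is.null(metadata_z)) {
    if (is.null(labels) && length(metadata_z) == 1)
      stopf("labels needed to size a constant metadata surface")
    d <- if (!is.null(labels)) dim(labels) else c(nrow(metadata_z),
                                                  ncol(metadata_z), 1)
    zmat <- if (length(metadata_z) == 1)
      matrix(metadata_z, d[1], d[2]) else as.matrix(metadata_z)
    return(structure(list(z = zmat, voxel_size = voxel_size),
                     class = "epidermal_surface"))
  }
  if (is.null(labels)) stopf("boundary estimation error: no input")
  d <- dim(labels)
  af <- labels == 2L
  if (!any(af))
    stopf("boundary estimation error: no epidermal autofluorescence signal and no metadata")
  # deepest af voxel per lateral column
  zidx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  zidx[!af] <- NA
  deepest <- apply(zidx, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  zmap <- (deepest - 1) * voxel_size[3] + 0.5 * voxel_size[3]
  # columns blocked by appendages or band gaps yield spurious shallow
  # plateaus wider than the median filter; reject outliers against a
  # coarse block-median reference surface
  dmap <- dim(zmap)
  bs <- 16L
  bx <- (seq_len(dmap[1]) - 1L) %/% bs
  by <- (seq_len(dmap[2]) - 1L) %/% bs
  ref <- tapply(as.numeric(zmap),
                list(bx[row(zmap)], by[col(zmap)]),
                function(v) if (all(is.na(v))) NA_real_
                            else median(v, na.rm = TRUE))
  ref[is.na(ref)] <- median(ref, na.rm = TRUE)
  refmap <- ref[cbind(bx[row(zmap)] + 1L, by[col(zmap)] + 1L)]
  dim(refmap) <- dmap
  bad <- !is.na(zmap) & abs(zmap - refmap) > 4
  zmap[bad] <- NA
  zmap <- median_filter2d_na(zmap, median_k)
  zmap[is.na(zmap)] <- refmap[is.na(zmap)]
  structure(list(z = zmap, voxel_size = voxel_size),
            class = "epidermal_surface")
}

median_filter2d_na <- function(m, k) {
  if (k <= 1) return(m)
  half <- k %/% 2
  d <- dim(m)
  stackv <- array(NA_real_, c(d[1], d[2], k * k))
  l <- 0
  for (dx in -half:half) for (dy in -half:half) {
    l <- l + 1
    xs <- clamp(seq_len(d[1]) + dx, 1, d[1])
    ys <- clamp(seq_len(d[2]) + dy, 1, d[2])
    stackv[, , l] <- m[xs, ys]
  }
  apply(stackv, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
}

surface_z_at <- function(surface, x, y) {
  d <- dim(surface$z)
  ix <- clamp(round(x / surface$voxel_size[1]) + 1, 1, d[1])
  iy <- clamp(round(y / surface$voxel_size[2]) + 1, 1, d[2])
  surface$z[cbind(ix, iy)]
}

#' Segment intra-epidermal free endings
#'
#' Terminal branches (path from the last branch point to a degree-1 node)
#' whose end node lies above the dermal–epidermal surface (shallower z) are
#' labelled intra-epidermal free endings.
#'
#' @param graph A `fiber_graph` in the same frame as `surface`.
#' @param surface An `epidermal_surface`.
#' @param depth_margin Extra depth (µm) an ending must rise above the
#'   surface before it counts; absorbs the registration and
#'   boundary-estimation error budget in longitudinal comparisons.
#' @param box,boundary_margin Optional lateral analysis box (2x3
#'   `rbind(lo, hi)`, µm): endings within `boundary_margin` of its x/y
#'   faces are ignored (registration warps extrapolate poorly at the
#'   volume border).
#' @return List: `count`, `ending_nodes` (node ids), `edge_ids` (their
#'   terminal-branch edges), `subgraph` (a `fiber_graph` of those
#'   branches).
#' @export
segment_epidermal_endings <- function(graph, surface, depth_margin = 0,
                                      box = NULL, boundary_margin = 3) {
  nd <- graph$nodes
  ends <- which(nd$degree == 1)
  if (!is.null(box) && length(ends) > 0) {
    keep <- nd$x[ends] > box[1, 1] + boundary_margin &
      nd$x[ends] < box[2, 1] - boundary_margin &
      nd$y[ends] > box[1, 2] + boundary_margin &
      nd$y[ends] < box[2, 2] - boundary_margin
    ends <- ends[keep]
  }
  if (length(ends) == 0)
    return(list(count = 0L, ending_nodes = integer(), edge_ids = integer(),
                subgraph = empty_fiber_graph()))
  zs <- surface_z_at(surface, nd$x[ends], nd$y[ends])
  epi <- ends[nd$z[ends] < zs - depth_margin]
  edge_ids <- integer()
  for (nid in nd$id[epi]) {
    edge_ids <- c(edge_ids,
                  which(graph$edges$from == nid | graph$edges$to == nid)[1])
  }
  edge_ids <- unique(edge_ids)
  sub <- if (length(edge_ids) > 0) {
    keep <- rep(FALSE, nrow(graph$edges))
    keep[edge_ids] <- TRUE
    rebuild_graph(graph, keep)
  } else empty_fiber_graph()
  list(count = length(epi), ending_nodes = nd$id[epi], edge_ids = edge_ids,
       subgraph = sub)
}

#' Longitudinal structural-plasticity metrics
#'
#' Per-session total fiber length, ending count and intra-epidermal ending
#' count within the common registered region of interest, each also as a
#' percentage of the baseline session. Per-caliber lengths are reported
#' when components are classified.
#'
#' @param graphs List of registered `fiber_graph`s (one per session).
#' @param baseline_index Index of the baseline session (default 1).
#' @param common_roi 2x3 `rbind(lo, hi)` box (µm) common to all sessions;
#'   `NULL` = no clipping.
#' @param surface Optional `epidermal_surface` in the common frame for
#'   intra-epidermal ending counts.
#' @param boundary_margin Ending-exclusion margin (µm).
#' @param epi_depth_margin Depth margin for intra-epidermal classification
#'   (see [segment_epidermal_endings()]).
#' @return Data frame, one row per session: metrics plus
#'   `pct_*` percent-of-baseline columns (`NA` when the baseline value is
#'   zero).
#' @export
longitudinal_metrics <- function(graphs, baseline_index = 1,
                                 common_roi = NULL, surface = NULL,
                                 boundary_margin = 3,
                                 epi_depth_margin = 2) {
  rows <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    tl <- total_fiber_length(g, common_roi)
    by_cal <- c(thin = 0, thick = 0)
    if (nrow(g$edges) > 0 && !all(is.na(g$components$caliber))) {
      for (cal in c("thin", "thick")) {
        comps <- g$components$component[g$components$caliber %in% cal]
        keep <- g$edges$component %in% comps
        if (any(keep)) {
          sub <- g
          sub$edges <- g$edges[keep, , drop = FALSE]
          sub$paths <- g$paths[keep]
          by_cal[cal] <- total_fiber_length(sub, common_roi)
        }
      }
    }
    ne <- count_endings(g, boundary_margin, common_roi)$count
    nepi <- if (!is.null(surface))
      segment_epidermal_endings(g, surface,
                                depth_margin = epi_depth_margin,
                                box = common_roi,
                                boundary_margin = 0.5)$count
      else NA_integer_
    data.frame(session = i, total_length = tl,
               length_thin = by_cal["thin"], length_thick = by_cal["thick"],
               n_endings = ne, n_epidermal_endings = nepi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  base <- out[baseline_index, ]
  pct <- function(v, b) ifelse(rep(is.na(b) || b == 0, length(v)),
                               NA_real_, 100 * v / b)
  out$pct_total_length <- pct(out$total_length, base$total_length)
  out$pct_length_thin <- pct(out$length_thin, base$length_thin)
  out$pct_length_thick <- pct(out$length_thick, base$length_thick)
  out$pct_endings <- pct(out$n_endings, base$n_endings)
  out$pct_epidermal_endings <- pct(out$n_epidermal_endings,
                                   base$n_epidermal_endings)
  out
}

sample_polyline <- function(p, spacing = 1) {
  if (nrow(p) < 2) return(p)
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  at <- unique(c(seq(0, total, by = spacing), total))
  t(vapply(at, function(a) {
    i <- findInterval(a, s, rightmost.closed = TRUE)
    i <- clamp(i, 1, nrow(p) - 1)
    f <- if (seg[i] < 1e-12) 0 else (a - s[i]) / seg[i]
    p[i, ] + f * (p[i + 1, ] - p[i, ])
  }, numeric(3)))
}

#' Localize gained, lost and stable fiber segments between two sessions
#'
#' Edges are matched by bidirectional polyline proximity: an edge whose
#' sampled points lie (median) within `match_tol` of the other session's
#' curves is stable; unmatched reference edges are lost, unmatched new
#' edges gained.
#'
#' @param graph_ref,graph_new Registered `fiber_graph`s in one frame.
#' @param match_tol Median point-to-curve tolerance (µm).
#' @return A `change_map`: data frame `session` ("reference"/"new"),
#'   `edge_id`, `status` (stable/lost/gained), `match_dist`, plus the three
#'   id sets as attributes-free list columns via `summary` components
#'   `stable_edges`, `lost_edges`, `gained_edges`.
#' @export
diff_fiber_graphs <- function(graph_ref, graph_new, match_tol = 3) {
  samp <- function(g) lapply(g$paths, sample_polyline)
  sr <- samp(graph_ref)
  sn <- samp(graph_new)
  pool_r <- if (length(sr)) do.call(rbind, sr) else matrix(0, 0, 3)
  pool_n <- if (length(sn)) do.call(rbind, sn) else matrix(0, 0, 3)
  med_dist <- function(samples, pool) {
    if (nrow(pool) == 0)
      return(rep(Inf, length(samples)))
    vapply(samples, function(pts) {
      nn <- cpp_grid_nn(pool, pts, cell = max(match_tol, 1))
      median(nn$dist)
    }, 0)
  }
  dr <- med_dist(sr, pool_n)
  dn <- med_dist(sn, pool_r)
  ref_stable <- which(dr <= match_tol)
  new_stable <- which(dn <= match_tol)
  tab <- rbind(
    if (length(sr)) data.frame(session = "reference",
                               edge_id = seq_along(sr),
                               status = ifelse(seq_along(sr) %in% ref_stable,
                                               "stable", "lost"),
                               match_dist = dr),
    if (length(sn)) data.frame(session = "new",
                               edge_id = seq_along(sn),
                               status = ifelse(seq_along(sn) %in% new_stable,
                                               "stable", "gained"),
                               match_dist = dn))
  structure(list(table = tab,
                 stable_edges = list(reference = ref_stable,
                                     new = new_stable),
                 lost_edges = setdiff(seq_along(sr), ref_stable),
                 gained_edges = setdiff(seq_along(sn), new_stable)),
            class = "change_map")
}

#' Write longitudinal metrics as tidy CSV
#'
#' One row per session x metric, suitable for downstream plotting.
#'
#' @param metrics Data frame from [longitudinal_metrics()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  long <- do.call(rbind, lapply(setdiff(names(metrics), "session"),
                                function(m)
    data.frame(session = metrics$session, metric = m,
               value = metrics[[m]])))
  write.csv(long[order(long$session, long$metric), ], path,
            row.names = FALSE)
  invisible(path)
}
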