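#' Parameters for 3D fiber tracing
#'
#' @param threshold Explicit foreground threshold; `NULL` (default) uses
#'   the adaptive local-peak mask (`fg_k`, `core_frac`).
#' @param min_component_voxels Components smaller than this are dropped as
#'   noise specks.
#' @param spur_min Spur-pruning length (µm): leaf edges shorter than this
#'   attached to a junction are thinning artefacts and removed. Trade-off:
#'   real filopodia-like free endings are ~5–10 µm, so the default stays
#'   below them.
#' @param g_max Gap-bridging reach (µm): end-node pairs closer than this
#'   and compatible in direction are joined.
#' @param cone_half_angle Collinearity cone half-angle (degrees) for
#'   bridging.
#' @param smooth_window Odd moving-average window (polyline points) applied
#'   to edge geometry before measuring arc length. The default 1 keeps the
#'   raw voxel chain: its mild digitization inflation roughly offsets the
#'   tip erosion of the thresholded mask, and arc lengths stay equal to the
#'   voxel-step sum; larger windows suppress voxel zigzag but also shorten
#'   genuinely tortuous paths.
#' @param fg_k,core_frac Foreground mask when no explicit `threshold` is
#'   given: voxels above the per-slice noise floor (`fg_k` robust sigmas)
#'   and above `core_frac` of the local structure peak, which keeps the
#'   mask width close to the physical tube regardless of per-structure
#'   brightness.
#' @param psf_fwhm Lateral PSF full width at half maximum (µm), removed in
#'   quadrature from measured profile widths when estimating radii.
#' @return A `trace_params` list.
#' @export
trace_params <- function(threshold = NULL, min_component_voxels = 30L,
                         spur_min = 3, g_max = 5, cone_half_angle = 30,
                         smooth_window = 1L, fg_k = 4, core_frac = 0.5,
                         psf_fwhm = 0.7) {
  structure(list(threshold = threshold,
                 min_component_voxels = as.integer(min_component_voxels),
                 spur_min = spur_min, g_max = g_max,
                 cone_half_angle = cone_half_angle,
                 smooth_window = as.integer(smooth_window),
                 fg_k = fg_k, core_frac = core_frac, psf_fwhm = psf_fwhm),
            class = "trace_params")
}

# local-peak-relative foreground mask (see segmentation core criterion)
trace_foreground_mask <- function(v, dims) {
  # v already lightly smoothed; per-slice floor + local-peak fraction
  sn <- dims[1] * dims[2]
  med <- numeric(dims[3]); madv <- numeric(dims[3])
  for (z in seq_len(dims[3])) {
    sl <- v[(z - 1) * sn + seq_len(sn)]
    med[z] <- median(sl); madv[z] <- stats::mad(sl)
  }
  # absolute floor: noise-based, but never below a small fraction of the
  # global signal ceiling (keeps blur tails out of noiseless data, where
  # the background deviation is zero)
  sig <- rquant(v, 0.999) - median(med)
  floor_z <- rep(med + pmax(4 * madv, 0.04 * sig), each = sn)
  localmax <- cpp_box_max(v, dims, c(7L, 7L, 3L))
  medrep <- rep(med, each = sn)
  v > pmax(floor_z, medrep + 2 * rep(madv, each = sn) +
             0.5 * (localmax - medrep))
}

#' Trace fibers in a cleaned stack into a geometric graph
#'
#' Thresholds the (autofluorescence-removed) stack into a foreground mask,
#' removes speck components, thins the mask to a 3D voxel skeleton, builds
#' a graph with junction/end voxels as nodes and voxel paths as edges,
#' prunes short spurs, and bridges signal gaps: pairs of end nodes within
#' `g_max` µm whose outgoing tangents lie inside the collinearity cone are
#' joined by a straight bridge edge. Per-edge radii come from the
#' half-width at half maximum of the intensity profile normal to the
#' centerline (distance-transform fallback when only a mask is given).
#' Fully deterministic.
#'
#' @param stack8 An `image_stack`, or a 3D logical/integer mask array
#'   (then `voxel_size` must be given).
#' @param params A [trace_params()].
#' @param voxel_size Voxel pitch (µm) when a bare mask is passed.
#' @param mask Optional precomputed foreground mask (e.g. the fiber class
#'   of the semi-supervised segmentation); the stack then only supplies
#'   intensities for radius estimation.
#' @return A `fiber_graph` (edges carry `radius`); empty graph with
#'   attribute `empty = TRUE` if no foreground survives.
#' @export
trace_fibers <- function(stack8, params = trace_params(),
                         voxel_size = NULL, mask = NULL) {
  if (inherits(stack8, "image_stack")) {
    vox <- stack8$voxel_size
    v <- as.numeric(stack8$data)
    dims <- dim(stack8$data)
    intensity <- v
    if (!is.null(mask)) {
      mask <- as.integer(as.logical(mask))
    } else {
      vsm <- cpp_gauss_blur3d(v, dims, c(0.25, 0.25, 0.15))
      if (is.null(params$threshold)) {
        mask <- as.integer(trace_foreground_mask(vsm, dims))
      } else {
        mask <- as.integer(vsm > params$threshold)
      }
    }
  } else {
    if (is.null(voxel_size)) stopf("voxel_size required for a bare mask")
    vox <- voxel_size
    dims <- dim(stack8)
    mask <- as.integer(as.logical(stack8))
    intensity <- NULL
  }
  if (sum(mask) == 0) return(empty_fiber_graph())
  # morphological closing re-attaches fragmented faint stretches (e.g.
  # fiber crossings of the autofluorescence band) before the speck filter
  closed <- cpp_box_max(as.numeric(mask), dims, c(3L, 3L, 3L))
  closed <- -cpp_box_max(-closed, dims, c(3L, 3L, 3L))
  mask <- as.integer(mask | closed > 0.5)
  cc <- cpp_label_cc26(mask, dims)
  sizes <- tabulate(cc[cc > 0])
  keep <- which(sizes >= params$min_component_voxels)
  mask <- as.integer(cc %in% keep)
  if (sum(mask) == 0) return(empty_fiber_graph())
  dist_um <- cpp_chamfer3d(mask, dims, vox)
  skel <- cpp_thin3d(mask, dims)
  g <- skeleton_voxels_to_graph(which(skel == 1L) - 1L, dims, vox,
                                params$smooth_window)
  if (is.null(g)) return(empty_fiber_graph())
  g <- prune_spurs(g, params$spur_min)
  if (nrow(g$nodes) == 0) return(empty_fiber_graph())
  g <- bridge_gaps(g, params$g_max, params$cone_half_angle)
  g <- estimate_edge_radii(g, intensity, dist_um, dims, vox,
                           psf_fwhm = params$psf_fwhm)
  g
}

# Convert 0-based linear indices of skeleton voxels into a fiber graph.
skeleton_voxels_to_graph <- function(idx0, dims, vox, smooth_window) {
  n <- length(idx0)
  if (n == 0) return(NULL)
  nx <- dims[1]; ny <- dims[2]
  x <- idx0 %% nx
  y <- (idx0 %/% nx) %% ny
  z <- idx0 %/% (nx * ny)
  key <- idx0
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  nb <- matrix(NA_integer_, n, nrow(off))
  for (k in seq_len(nrow(off))) {
    xx <- x + off[k, 1]; yy <- y + off[k, 2]; zz <- z + off[k, 3]
    okm <- xx >= 0 & yy >= 0 & zz >= 0 &
      xx < nx & yy < ny & zz < dims[3]
    nk <- rep(NA_real_, n)
    nk[okm] <- xx[okm] + nx * (yy[okm] + ny * zz[okm])
    nb[, k] <- match(nk, key)
  }
  deg <- rowSums(!is.na(nb))
  is_node <- deg != 2
  # cycles with no junction: anchor at the lowest-index voxel
  if (any(!is_node)) {
    compv <- integer(n)
    cur <- 0L
    for (i in seq_len(n)) {
      if (compv[i] > 0) next
      cur <- cur + 1L
      q <- i
      compv[i] <- cur
      while (length(q) > 0) {
        v0 <- q[[1]]; q <- q[-1]
        for (w in nb[v0, ]) {
          if (!is.na(w) && compv[w] == 0) { compv[w] <- cur; q <- c(q, w) }
        }
      }
    }
    for (cid in seq_len(max(compv))) {
      members <- which(compv == cid)
      if (!any(is_node[members])) is_node[members[1]] <- TRUE
    }
  }
  node_rows <- which(is_node)
  if (length(node_rows) == 0) return(NULL)
  gid <- match(seq_len(n), node_rows)
  used <- matrix(FALSE, n, nrow(off))
  back <- match(seq_len(nrow(off)),
                vapply(seq_len(nrow(off)), function(k) {
                  which(off[, 1] == -off[k, 1] & off[, 2] == -off[k, 2] &
                          off[, 3] == -off[k, 3])
                }, 0L))
  back_of <- vapply(seq_len(nrow(off)), function(k)
    which(off[, 1] == -off[k, 1] & off[, 2] == -off[k, 2] &
            off[, 3] == -off[k, 3]), 0L)
  ef <- integer(); et <- integer(); paths <- list()
  for (i in node_rows) {
    for (k in seq_len(nrow(off))) {
      j <- nb[i, k]
      if (is.na(j) || used[i, k]) next
      # walk from node i through degree-2 voxels to the next node
      pts <- list(c(x[i], y[i], z[i]))
      used[i, k] <- TRUE
      prev <- i; cur <- j; kin <- back_of[k]
      used[cur, kin] <- TRUE
      while (!is_node[cur]) {
        pts[[length(pts) + 1]] <- c(x[cur], y[cur], z[cur])
        ks <- which(!is.na(nb[cur, ]) & nb[cur, ] != prev)
        if (length(ks) == 0) break
        k2 <- ks[1]
        used[cur, k2] <- TRUE
        nxt <- nb[cur, k2]
        used[nxt, back_of[k2]] <- TRUE
        prev <- cur; cur <- nxt
      }
      pts[[length(pts) + 1]] <- c(x[cur], y[cur], z[cur])
      poly <- sweep(do.call(rbind, pts), 2, vox, "*")
      if (gid[i] == gid[cur] && nrow(poly) <= 2) next  # degenerate loop
      ef <- c(ef, gid[i]); et <- c(et, gid[cur])
      paths[[length(paths) + 1]] <- smooth_polyline(poly, smooth_window)
    }
  }
  nodes <- data.frame(id = seq_along(node_rows),
                      x = x[node_rows] * vox[1],
                      y = y[node_rows] * vox[2],
                      z = z[node_rows] * vox[3],
                      radius = NA_real_)
  if (length(ef) == 0) {
    # isolated voxels only
    return(fiber_graph(nodes[integer(0), ],
                       data.frame(from = integer(), to = integer()),
                       list()))
  }
  fiber_graph(nodes, data.frame(from = ef, to = et), paths)
}

# moving-average smoothing of a polyline, endpoints pinned
smooth_polyline <- function(p, win) {
  np <- nrow(p)
  if (win <= 1 || np <= 2) return(p)
  half <- win %/% 2
  out <- p
  for (i in 2:(np - 1)) {
    lo <- max(1, i - half); hi <- min(np, i + half)
    out[i, ] <- colMeans(p[lo:hi, , drop = FALSE])
  }
  out
}

# remove leaf edges shorter than spur_min that hang off a junction
prune_spurs <- function(g, spur_min) {
  repeat {
    deg <- g$nodes$degree
    short_leaf <- g$edges$length < spur_min &
      ((deg[match(g$edges$from, g$nodes$id)] == 1 &
          deg[match(g$edges$to, g$nodes$id)] > 2) |
         (deg[match(g$edges$to, g$nodes$id)] == 1 &
            deg[match(g$edges$from, g$nodes$id)] > 2))
    if (!any(short_leaf)) break
    g <- rebuild_graph(g, !short_leaf)
    g <- merge_degree2(g)
  }
  g
}

rebuild_graph <- function(g, keep_edges) {
  ed <- g$edges[keep_edges, , drop = FALSE]
  paths <- g$paths[keep_edges]
  used <- sort(unique(c(ed$from, ed$to)))
  nd <- g$nodes[g$nodes$id %in% used, , drop = FALSE]
  remap <- match(seq_len(max(g$nodes$id, 1)), nd$id)
  if (nrow(ed) > 0) {
    ed$from <- match(ed$from, nd$id)
    ed$to <- match(ed$to, nd$id)
  }
  nd$id <- seq_len(nrow(nd))
  keep_cols <- setdiff(names(nd), c("degree", "component"))
  fiber_graph(nd[keep_cols], ed[c("from", "to")], paths)
}

# merge chains through degree-2 nodes into single edges
merge_degree2 <- function(g) {
  repeat {
    deg2 <- which(g$nodes$degree == 2)
    merged <- FALSE
    for (nid in deg2) {
      inc <- which(g$edges$from == nid | g$edges$to == nid)
      if (length(inc) != 2) next            # loop through this node
      e1 <- inc[1]; e2 <- inc[2]
      p1 <- g$paths[[e1]]; p2 <- g$paths[[e2]]
      if (g$edges$to[e1] != nid) { p1 <- p1[nrow(p1):1, ]; }
      o1 <- if (g$edges$to[e1] != nid) g$edges$to[e1] else g$edges$from[e1]
      if (g$edges$from[e2] != nid) { p2 <- p2[nrow(p2):1, ]; }
      o2 <- if (g$edges$from[e2] != nid) g$edges$from[e2] else g$edges$to[e2]
      if (o1 == nid || o2 == nid) next
      newpath <- rbind(p1, p2[-1, , drop = FALSE])
      keep <- setdiff(seq_len(nrow(g$edges)), c(e1, e2))
      ed <- g$edges[keep, , drop = FALSE]
      paths <- g$paths[keep]
      ed <- rbind(ed[, c("from", "to"), drop = FALSE],
                  data.frame(from = o1, to = o2))
      paths[[length(paths) + 1]] <- newpath
      nd <- g$nodes
      keep_cols <- setdiff(names(nd), c("degree", "component"))
      g <- fiber_graph(nd[keep_cols], ed, paths)
      g <- drop_isolated(g)
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  g
}

drop_isolated <- function(g) {
  if (!any(g$nodes$degree == 0)) return(g)
  rebuild_graph(g, rep(TRUE, nrow(g$edges)))
}

# join end-node pairs within g_max whose tangents face each other
bridge_gaps <- function(g, g_max, cone_half_angle) {
  ends <- which(g$nodes$degree == 1)
  if (length(ends) < 2) return(g)
  cosmin <- cos(cone_half_angle * pi / 180)
  tangent <- function(nid) {
    e <- which(g$edges$from == nid | g$edges$to == nid)[1]
    p <- g$paths[[e]]
    endpt <- c(g$nodes$x[nid], g$nodes$y[nid], g$nodes$z[nid])
    if (sum((p[1, ] - endpt)^2) > sum((p[nrow(p), ] - endpt)^2))
      p <- p[nrow(p):1, ]
    # direction pointing out of the fiber at the end node
    s <- cumsum(c(0, sqrt(rowSums(diff(p)^2))))
    take <- which(s <= 2.5)
    inner <- p[max(take), ]
    d <- endpt - inner
    nd <- sqrt(sum(d^2))
    if (nd < 1e-9) c(0, 0, 0) else d / nd
  }
  tg <- t(vapply(ends, tangent, numeric(3)))
  P <- as.matrix(g$nodes[ends, c("x", "y", "z")])
  cand <- NULL
  for (i in seq_along(ends)) {
    for (j in seq_along(ends)) {
      if (j <= i) next
      if (g$nodes$component[ends[i]] == g$nodes$component[ends[j]]) next
      d <- P[j, ] - P[i, ]
      dist <- sqrt(sum(d^2))
      if (dist > g_max || dist < 1e-9) next
      u <- d / dist
      if (sum(tg[i, ] * u) < cosmin) next
      if (sum(tg[j, ] * (-u)) < cosmin) next
      cand <- rbind(cand, c(i, j, dist))
    }
  }
  if (is.null(cand)) return(g)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  usedend <- rep(FALSE, length(ends))
  ed <- g$edges[, c("from", "to")]
  paths <- g$paths
  bridges <- integer()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (usedend[i] || usedend[j]) next
    usedend[i] <- usedend[j] <- TRUE
    ed <- rbind(ed, data.frame(from = g$nodes$id[ends[i]],
                               to = g$nodes$id[ends[j]]))
    paths[[length(paths) + 1]] <- rbind(P[i, ], P[j, ])
    bridges <- c(bridges, nrow(ed))
  }
  keep_cols <- setdiff(names(g$nodes), c("degree", "component"))
  out <- fiber_graph(g$nodes[keep_cols], ed, paths)
  attr(out, "bridges") <- bridges
  out
}

# per-edge radius: FWHM/2 of the intensity profile normal to the
# centerline when intensity is available, else the distance transform
estimate_edge_radii <- function(g, intensity, dist_um, dims, vox,
                                psf_fwhm = 0.7) {
  ne <- nrow(g$edges)
  if (ne == 0) return(g)
  rad <- numeric(ne)
  bgref <- if (!is.null(intensity)) median(intensity) else NA
  for (e in seq_len(ne)) {
    p <- g$paths[[e]]
    s <- cumsum(c(0, sqrt(rowSums(diff(p)^2))))
    total <- s[length(s)]
    at <- seq(0.15, 0.85, length.out = min(7, max(3, round(total / 5))))
    samp <- vapply(at, function(f) {
      ti <- which.min(abs(s - f * total))
      pt <- p[ti, ]
      tgt <- if (ti < nrow(p)) p[min(nrow(p), ti + 1), ] - p[max(1, ti - 1), ]
             else p[ti, ] - p[ti - 1, ]
      tn <- sqrt(sum(tgt^2))
      tgt <- if (tn < 1e-9) c(0, 0, 1) else tgt / tn
      if (!is.null(intensity))
        profile_radius(intensity, dims, vox, pt, tgt, bgref,
                       psf_fwhm = psf_fwhm)
      else {
        vc <- matrix(pt / vox, 1)
        max(cpp_trilinear(dist_um, dims, vc, 0), 0.25 * min(vox))
      }
    }, 0)
    rad[e] <- median(samp, na.rm = TRUE)
  }
  g$edges$radius <- rad
  inc <- lapply(g$nodes$id, function(nid)
    which(g$edges$from == nid | g$edges$to == nid))
  g$nodes$radius <- vapply(inc, function(ix)
    if (length(ix)) mean(rad[ix]) else NA_real_, 0)
  g
}

profile_radius <- function(intensity, dims, vox, pt, tgt, bgref,
                           psf_fwhm = 0.7) {
  # lateral (horizontal) normals only: the axial point spread is too
  # elongated to carry caliber information at 1 µm slice spacing
  if (abs(tgt[3]) > 0.95) {
    dirs <- list(c(1, 0, 0), c(0, 1, 0))
  } else {
    u <- c(tgt[2], -tgt[1], 0)
    dirs <- list(u / sqrt(sum(u^2)))
  }
  step <- 0.2
  offs <- seq(-3, 3, by = step)
  fw <- vapply(dirs, function(dirv) {
    pts <- sweep(outer(offs, dirv), 2, pt, "+")
    prof <- cpp_trilinear(intensity, dims, sweep(pts, 2, vox, "/"), bgref)
    pk <- max(prof)
    if (pk <= bgref) return(NA_real_)
    half <- bgref + 0.5 * (pk - bgref)
    above <- prof >= half
    ctr <- which.max(prof)
    lo <- ctr; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- ctr; while (hi < length(offs) && above[hi + 1]) hi <- hi + 1
    offs[hi] - offs[lo] + step
  }, 0)
  fwhm <- median(fw, na.rm = TRUE)
  if (is.na(fwhm)) return(NA_real_)
  sqrt(max(fwhm^2 - psf_fwhm^2, 0.1)) / 2
}

#' Classify fiber-graph components into thin and thick caliber
#'
#' Per-component median radius (per-edge radii weighted by edge length)
#' compared to `radius_threshold`; components at or above the threshold are
#' labelled `"thick"` (documented tie-break), below it `"thin"`.
#'
#' @param graph A `fiber_graph` whose edges carry `radius`.
#' @param radius_threshold Caliber cut (µm).
#' @return The graph with `components$caliber` filled.
#' @export
classify_fiber_caliber <- function(graph, radius_threshold = 0.8) {
  if (nrow(graph$edges) == 0) return(graph)
  if (is.null(graph$edges$radius) || all(is.na(graph$edges$radius)))
    stopf("edge radii missing; trace with an intensity stack or mask first")
  for (i in seq_len(nrow(graph$components))) {
    cid <- graph$components$component[i]
    ed <- graph$edges[graph$edges$component == cid, ]
    w <- pmax(1L, round(ed$length))
    r <- median(rep(ed$radius, times = w), na.rm = TRUE)
    graph$components$caliber[i] <-
      if (!is.na(r) && r >= radius_threshold) "thick" else "thin"
  }
  graph
}
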