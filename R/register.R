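#' Rigid transform (rotation + translation) in µm coordinates
#'
#' @param rotation 3x3 orthonormal matrix, det +1.
#' @param translation Length-3 µm vector.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-8)
    stopf("rotation must be orthonormal")
  if (det(rotation) < 0) stopf("rotation must have determinant +1")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$R)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.2f, %.2f, %.2f) um\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#' @param transform A `rigid_transform`.
#' @param points n x 3 matrix (µm).
#' @return Transformed n x 3 matrix.
#' @export
rigid_apply <- function(transform, points) {
  sweep(points %*% t(transform$R), 2, transform$t, "+")
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b `rigid_transform`s.
#' @return `rigid_transform` equal to `x -> a(b(x))`.
#' @export
rigid_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param transform A `rigid_transform`.
#' @return Its inverse.
#' @export
rigid_invert <- function(transform) {
  rigid_transform(t(transform$R), -as.numeric(t(transform$R) %*% transform$t))
}

#' Rotation angle of a rotation matrix in degrees
#' @param R 3x3 rotation matrix.
#' @return Angle (degrees).
#' @export
rotation_angle_deg <- function(R) {
  acos(clamp((sum(diag(R)) - 1) / 2, -1, 1)) * 180 / pi
}

#' Extract a 3D point cloud of fiber voxels from a cleaned stack
#'
#' Suprathreshold voxels are converted to physical µm coordinates (voxel
#' index times voxel size, 0-based) and uniformly subsampled.
#'
#' @param stack8 A cleaned (autofluorescence-removed) `image_stack`.
#' @param threshold Intensity threshold; `NULL` = Otsu.
#' @param max_points Subsample ceiling.
#' @param seed Seed for the subsample.
#' @param mask Optional logical/integer array restricting the cloud (e.g.
#'   the fiber class of the segmentation, so clouds contain nerve fibers
#'   only).
#' @return A `point_cloud`: `points` (n x 3 µm), `weights` (intensities),
#'   `empty` flag.
#' @export
extract_point_cloud <- function(stack8, threshold = NULL,
                                max_points = 20000L, seed = 1L,
                                mask = NULL) {
  v <- as.numeric(stack8$data)
  if (is.null(threshold))
    threshold <- if (max(v) > min(v)) otsu_threshold(v) else Inf
  idx <- which(v > threshold)
  if (!is.null(mask)) idx <- intersect(idx, which(as.logical(mask)))
  if (length(idx) == 0) {
    return(structure(list(points = matrix(0, 0, 3), weights = numeric(),
                          empty = TRUE, voxel_size = stack8$voxel_size),
                     class = "point_cloud"))
  }
  if (length(idx) > max_points)
    idx <- with_seed(seed, sort(sample(idx, max_points)))
  d <- dim(stack8$data)
  i0 <- idx - 1
  xyz <- cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
  pts <- sweep(xyz, 2, stack8$voxel_size, "*")
  structure(list(points = pts, weights = v[idx], empty = FALSE,
                 voxel_size = stack8$voxel_size),
            class = "point_cloud")
}

kabsch <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- t(sweep(src, 2, cs)) %*% sweep(dst, 2, cd)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cd - as.numeric(R %*% cs), sing = sv$d)
}

#' Trimmed iterative-closest-point rigid registration
#'
#' Alternates nearest-neighbour correspondence and a closed-form
#' least-squares rigid update, keeping only the best `trim` fraction of
#' correspondences each iteration so partially overlapping clouds (e.g.
#' denervated sessions) register on their shared structures. A coarse
#' random subsample initializes the fine stage. The recorded residual
#' history (trimmed mean distance) is non-increasing: an update that would
#' increase it is rejected and iteration stops.
#'
#' @param source,target `point_cloud`s (or n x 3 matrices), non-empty.
#' @param opts List: `trim` (kept fraction, default 0.7), `max_iter`,
#'   `tol` (µm change for convergence), `coarse_n` (subsample size of the
#'   initialization stage), `seed`.
#' @return An `icp_result`: `transform` (`rigid_transform` mapping source
#'   into the target frame), `correspondence` (target index per source
#'   point), `residual` (J = sum of kept correspondence distances, µm),
#'   `residual_history`, `iterations`, `trimmed_fraction`.
#' @export
icp_rigid <- function(source, target, opts = list()) {
  src <- if (inherits(source, "point_cloud")) source$points else source
  dst <- if (inherits(target, "point_cloud")) target$points else target
  if (nrow(src) == 0 || nrow(dst) == 0) stopf("point clouds must be non-empty")
  trim <- opts$trim %||% 0.7
  max_iter <- opts$max_iter %||% 40L
  tol <- opts$tol %||% 1e-4
  coarse_n <- opts$coarse_n %||% 1500L
  seed <- opts$seed %||% 1L
  cell <- max(1e-6, 2 * mean(apply(dst, 2, function(c) diff(range(c)))) /
                max(10, nrow(dst)^(1 / 3)))
  degenerate <- FALSE
  run_stage <- function(s_pts, Tcur, iters) {
    hist <- numeric()
    Tprev <- Tcur
    for (it in seq_len(iters)) {
      moved <- rigid_apply(Tcur, s_pts)
      nn <- cpp_grid_nn(dst, moved, cell)
      keep_n <- max(3L, floor(trim * nrow(moved)))
      ord <- order(nn$dist)[seq_len(keep_n)]
      obj <- mean(nn$dist[ord])
      if (length(hist) > 0 && obj > tail(hist, 1) + 1e-12) {
        Tcur <- Tprev   # reject the update that increased the objective
        break
      }
      hist <- c(hist, obj)
      Tprev <- Tcur
      fit <- kabsch(s_pts[ord, , drop = FALSE],
                    dst[nn$idx[ord], , drop = FALSE])
      if (fit$sing[2] < 1e-8 * max(fit$sing[1], 1e-12)) {
        degenerate <<- TRUE
        Tnew <- rigid_transform(Tcur$R,
                                Tcur$t + colMeans(dst[nn$idx[ord], ,
                                                      drop = FALSE]) -
                                  colMeans(moved[ord, , drop = FALSE]))
      } else {
        Tnew <- rigid_transform(fit$R, fit$t)
      }
      converged <- length(hist) > 1 &&
        abs(hist[length(hist) - 1] - obj) < tol
      Tcur <- Tnew
      if (converged) break
    }
    list(transform = Tcur, history = hist)
  }
  # coarse initialization on a subsample, then full-resolution refinement
  Tcur <- rigid_transform()
  if (nrow(src) > coarse_n) {
    sub <- with_seed(seed, sample(nrow(src), coarse_n))
    Tcur <- run_stage(src[sub, , drop = FALSE], Tcur, 15L)$transform
  }
  fine <- run_stage(src, Tcur, max_iter)
  Tfin <- fine$transform
  moved <- rigid_apply(Tfin, src)
  nn <- cpp_grid_nn(dst, moved, cell)
  keep_n <- max(3L, floor(trim * nrow(moved)))
  ord <- order(nn$dist)[seq_len(keep_n)]
  if (degenerate)
    warning("degenerate point-cloud geometry; translation-only fit used")
  structure(list(transform = Tfin, correspondence = nn$idx,
                 correspondence_dist = nn$dist,
                 residual = sum(nn$dist[ord]),
                 residual_history = fine$history,
                 iterations = length(fine$history),
                 trimmed_fraction = trim),
            class = "icp_result")
}

#' Fit a 3D thin-plate-spline warp to landmark pairs
#'
#' Solves the standard TPS system with kernel `U(r) = r` (the 3D
#' biharmonic spline) and bending-energy regularization `lambda`. At
#' `lambda = 0` the warp interpolates the landmarks; as `lambda` grows it
#' approaches the least-squares affine fit.
#'
#' @param src_landmarks,dst_landmarks n x 3 matrices (µm), n >= 4,
#'   non-coplanar.
#' @param lambda Regularization weight (>= 0).
#' @return A `tps_transform` (landmarks, warp coefficients, lambda).
#' @export
tps_fit <- function(src_landmarks, dst_landmarks, lambda = 0) {
  src <- as.matrix(src_landmarks)
  dst <- as.matrix(dst_landmarks)
  n <- nrow(src)
  if (n < 4) stopf("need at least 4 landmark pairs")
  if (lambda < 0) stopf("lambda must be >= 0")
  P <- cbind(1, src)
  if (qr(P)$rank < 4)
    stopf("rank deficiency: landmarks are coplanar")
  K <- as.matrix(stats::dist(src))
  A <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(dst, matrix(0, 4, 3))
  sol <- solve(A, rhs)
  structure(list(src = src, dst = dst, w = sol[1:n, , drop = FALSE],
                 a = sol[(n + 1):(n + 4), , drop = FALSE],
                 lambda = lambda),
            class = "tps_transform")
}

#' Apply a thin-plate-spline transform to points
#' @param transform A `tps_transform`.
#' @param points m x 3 matrix (µm).
#' @return Warped m x 3 matrix.
#' @export
tps_apply <- function(transform, points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  src2 <- rowSums(transform$src^2)
  out <- matrix(0, n, 3)
  # kernel matrix is n x n_landmarks: process in blocks to bound memory
  block <- 100000L
  for (s in seq(1, n, by = block)) {
    e <- min(n, s + block - 1L)
    p <- pts[s:e, , drop = FALSE]
    D2 <- outer(rowSums(p^2), rep(1, nrow(transform$src))) +
      outer(rep(1, nrow(p)), src2) - 2 * p %*% t(transform$src)
    U <- sqrt(pmax(D2, 0))
    out[s:e, ] <- cbind(1, p) %*% transform$a + U %*% transform$w
  }
  out
}

#' Composite session transform: rigid pose then thin-plate-spline warp
#'
#' @param rigid A `rigid_transform` (may be identity).
#' @param tps Optional `tps_transform` applied after the rigid part.
#' @param inverse_tps Optional reverse-direction `tps_transform` used to
#'   pull stack voxels back through the warp when resampling.
#' @return A `session_transform`.
#' @export
session_transform <- function(rigid = rigid_transform(), tps = NULL,
                              inverse_tps = NULL, tps_domain = NULL,
                              tps_domain_inv = NULL) {
  structure(list(rigid = rigid, tps = tps, inverse_tps = inverse_tps,
                 tps_domain = tps_domain, tps_domain_inv = tps_domain_inv),
            class = "session_transform")
}

# weight 1 inside the landmark hull, fading linearly to 0 over a `shell`
# µm band outside it: thin-plate splines extrapolate poorly, so beyond the
# data support the warp falls back to the rigid part
tps_domain_weight <- function(points, domain, shell = 8) {
  if (is.null(domain)) return(rep(1, nrow(points)))
  w <- rep(1, nrow(points))
  for (k in 1:3) {
    d_out <- pmax(domain[1, k] - points[, k], points[, k] - domain[2, k], 0)
    w <- w * clamp(1 - d_out / shell, 0, 1)
  }
  w
}

#' Apply a session transform (rigid, then TPS) to points
#' @param transform A `session_transform` (or `rigid_transform`).
#' @param points n x 3 matrix.
#' @return Transformed matrix.
#' @export
transform_points <- function(transform, points) {
  if (inherits(transform, "rigid_transform"))
    return(rigid_apply(transform, points))
  out <- rigid_apply(transform$rigid, points)
  if (!is.null(transform$tps)) {
    full <- tps_apply(transform$tps, out)
    affine <- cbind(1, out) %*% transform$tps$a
    # the affine part of the spline is globally fitted and bounded; only
    # the kernel (bending) part is unsafe to extrapolate
    w <- tps_domain_weight(out, transform$tps_domain)
    out <- affine + (full - affine) * w
  }
  out
}

# Pull points in the reference frame back into the source frame.
transform_points_inverse <- function(transform, points) {
  if (inherits(transform, "rigid_transform"))
    return(rigid_apply(rigid_invert(transform), points))
  out <- points
  if (!is.null(transform$tps)) {
    if (!is.null(transform$inverse_tps)) {
      full <- tps_apply(transform$inverse_tps, out)
      affine <- cbind(1, out) %*% transform$inverse_tps$a
      w <- tps_domain_weight(out, transform$tps_domain_inv)
      out <- affine + (full - affine) * w
    } else {
      stopf("session transform lacks an inverse TPS for resampling")
    }
  }
  rigid_apply(rigid_invert(transform$rigid), out)
}

#' Register a moving session to a fixed (baseline) session
#'
#' Point-cloud pyramid: trimmed rigid ICP, then a thin-plate-spline warp
#' fitted on mutually-nearest ICP correspondences averaged over spatial
#' blocks (`tps_block` µm) and capped at `n_landmarks` control points. The reverse-direction TPS is fitted too so
#' stacks can be resampled through the warp.
#'
#' @param moving,fixed `point_cloud`s (fiber voxels, physical µm).
#' @param opts ICP options (see [icp_rigid()]); plus `n_landmarks`
#'   (default 200), `lambda` (TPS regularization, default 1), and the
#'   sanity gate `max_residual` (µm, trimmed mean), `max_shift` (µm),
#'   `max_angle` (degrees) beyond which the registration is rejected and
#'   the identity returned (attribute `rejected`).
#' @return A `session_transform` mapping moving into the fixed frame, with
#'   the `icp_result` attached as attribute `icp`.
#' @export
register_session <- function(moving, fixed, opts = list()) {
  icp <- icp_rigid(moving, fixed, opts)
  n_land <- opts$n_landmarks %||% 200L
  lambda <- opts$lambda %||% 1
  # sanity gate: sessions are acquisitions of the same digit in similar
  # poses, so a huge motion or a poor trimmed fit marks a failed
  # registration (e.g. a denervated session with no shared structure);
  # fall back to the identity rather than poison the common volume
  max_res <- opts$max_residual %||% 3
  max_shift <- opts$max_shift %||% 25
  max_angle <- opts$max_angle %||% 10
  trim_mean <- tail(icp$residual_history, 1)
  if (length(trim_mean) == 0) trim_mean <- Inf
  if (trim_mean > max_res ||
      sqrt(sum(icp$transform$t^2)) > max_shift ||
      rotation_angle_deg(icp$transform$R) > max_angle) {
    out <- session_transform()
    attr(out, "icp") <- icp
    attr(out, "rejected") <- TRUE
    warning("registration rejected (poor fit or implausible motion); identity used")
    return(out)
  }
  src <- if (inherits(moving, "point_cloud")) moving$points else moving
  dst <- if (inherits(fixed, "point_cloud")) fixed$points else fixed
  moved <- rigid_apply(icp$transform, src)
  cell <- max(1e-6, 2 * mean(apply(dst, 2, function(c) diff(range(c)))) /
                max(10, nrow(dst)^(1 / 3)))
  fwd <- cpp_grid_nn(dst, moved, cell)
  bwd <- cpp_grid_nn(moved, dst, cell)
  mutual <- which(bwd$idx[fwd$idx] == seq_len(nrow(moved)))
  out <- session_transform(icp$transform)
  if (length(mutual) >= 8) {
    # correspondences slide along fibers; average them over spatial blocks
    # so the landmarks carry the local displacement field, not the slide
    sl0 <- moved[mutual, , drop = FALSE]
    disp <- dst[fwd$idx[mutual], , drop = FALSE] - sl0
    block <- opts$tps_block %||% 15
    key <- paste(floor(sl0[, 1] / block), floor(sl0[, 2] / block),
                 floor(sl0[, 3] / block))
    keep <- names(which(table(key) >= 10))
    sl <- NULL; dl <- NULL
    for (k in keep) {
      m <- key == k
      sl <- rbind(sl, colMeans(sl0[m, , drop = FALSE]))
      dl <- rbind(dl, colMeans(sl0[m, , drop = FALSE]) +
                    colMeans(disp[m, , drop = FALSE]))
    }
    if (!is.null(sl) && nrow(sl) > n_land) {
      pick <- round(seq(1, nrow(sl), length.out = n_land))
      sl <- sl[pick, , drop = FALSE]
      dl <- dl[pick, , drop = FALSE]
    }
    if (!is.null(sl) && nrow(sl) >= 8 && qr(cbind(1, sl))$rank == 4) {
      tps <- tps_fit(sl, dl, lambda)
      itps <- tps_fit(dl, sl, lambda)
      out <- session_transform(icp$transform, tps, itps,
                               tps_domain = apply(sl, 2, range),
                               tps_domain_inv = apply(dl, 2, range))
    }
  }
  attr(out, "icp") <- icp
  out
}

#' Crop registered sessions to their largest common volume
#'
#' Transforms each stack's physical bounding box into the shared reference
#' frame, intersects the boxes, and resamples every stack onto a common
#' voxel grid spanning the intersection (trilinear for intensities,
#' nearest-neighbour for label volumes).
#'
#' @param stacks List of `image_stack`s.
#' @param transforms One transform per stack (`rigid_transform` or
#'   `session_transform`) mapping it into the reference frame.
#' @param labels Optional list of label arrays resampled alongside.
#' @return List: `stacks` (aligned, identical dims), `box` (common physical
#'   box, µm), `labels` when supplied.
#' @export
crop_common_volume <- function(stacks, transforms, labels = NULL) {
  if (length(stacks) != length(transforms))
    stopf("one transform per stack required")
  boxes <- lapply(seq_along(stacks), function(i) {
    ext <- stack_extent(stacks[[i]])
    corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]),
                                     c(0, ext[3])))
    tc <- transform_points(transforms[[i]], corners)
    rbind(apply(tc, 2, min), apply(tc, 2, max))
  })
  lo <- apply(do.call(rbind, lapply(boxes, function(b) b[1, ])), 2, max)
  hi <- apply(do.call(rbind, lapply(boxes, function(b) b[2, ])), 2, min)
  if (any(hi - lo <= 0)) {
    bad <- which(vapply(seq_along(boxes), function(i) {
      any(boxes[[i]][1, ] >= hi) || any(boxes[[i]][2, ] <= lo)
    }, TRUE))
    stopf("empty common volume; session %s does not intersect the others",
          paste(bad, collapse = ", "))
  }
  vox <- stacks[[1]]$voxel_size
  odims <- pmax(2L, as.integer(floor((hi - lo) / vox)) + 1L)
  gx <- lo[1] + (seq_len(odims[1]) - 1) * vox[1]
  gy <- lo[2] + (seq_len(odims[2]) - 1) * vox[2]
  gz <- lo[3] + (seq_len(odims[3]) - 1) * vox[3]
  grid <- cbind(rep(gx, times = odims[2] * odims[3]),
                rep(rep(gy, each = odims[1]), times = odims[3]),
                rep(gz, each = odims[1] * odims[2]))
  out_stacks <- vector("list", length(stacks))
  out_labels <- if (!is.null(labels)) vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    src_pts <- transform_points_inverse(transforms[[i]], grid)
    vc <- sweep(src_pts, 2, stacks[[i]]$voxel_size, "/")
    vals <- cpp_trilinear(as.numeric(stacks[[i]]$data),
                          dim(stacks[[i]]$data), vc, 0)
    out_stacks[[i]] <- image_stack(array(vals, odims),
                                   voxel_size = vox,
                                   bit_depth = stacks[[i]]$bit_depth,
                                   session = stacks[[i]]$session)
    if (!is.null(labels)) {
      vcn <- round(vc)
      dlab <- dim(labels[[i]])
      inside <- vcn[, 1] >= 0 & vcn[, 2] >= 0 & vcn[, 3] >= 0 &
        vcn[, 1] < dlab[1] & vcn[, 2] < dlab[2] & vcn[, 3] < dlab[3]
      lv <- integer(nrow(vcn))
      lidx <- vcn[inside, 1] + dlab[1] * (vcn[inside, 2] +
                                            dlab[2] * vcn[inside, 3]) + 1
      lv[inside] <- as.integer(labels[[i]])[lidx]
      out_labels[[i]] <- array(lv, odims)
    }
  }
  out <- list(stacks = out_stacks, box = rbind(lo = lo, hi = hi))
  if (!is.null(labels)) out$labels <- out_labels
  out
}

#' Serialize a session transform to JSON
#' @param transform A `session_transform` or `rigid_transform`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  if (inherits(transform, "rigid_transform"))
    transform <- session_transform(transform)
  obj <- list(rotation = transform$rigid$R, translation = transform$rigid$t)
  if (!is.null(transform$tps)) {
    obj$tps <- list(src = transform$tps$src, dst = transform$tps$dst,
                    lambda = transform$tps$lambda)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a session transform written by [write_transform()]
#' @param path JSON path.
#' @return A `session_transform`.
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rig <- rigid_transform(matrix(unlist(obj$rotation), 3, 3),
                         unlist(obj$translation))
  if (is.null(obj$tps)) return(session_transform(rig))
  src <- matrix(unlist(obj$tps$src), ncol = 3)
  dst <- matrix(unlist(obj$tps$dst), ncol = 3)
  session_transform(rig, tps_fit(src, dst, obj$tps$lambda),
                    tps_fit(dst, src, obj$tps$lambda))
}
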