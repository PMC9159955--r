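#' Maximum-intensity projection of a stack along z
#' @param stack An `image_stack` or 3D array.
#' @return Matrix `[x, y]`.
#' @export
stack_mip <- function(stack) {
  arr <- if (inherits(stack, "image_stack")) stack$data else stack
  apply(arr, c(1, 2), max)
}

blur2d <- function(m, sigma) {
  d <- dim(m)
  array(cpp_gauss_blur3d(as.numeric(m), c(d, 1L), c(sigma, sigma, 0)), d)
}

# Difference-of-Gaussian blob keypoints inside a sub-window of a MIP.
# Returns data.frame(x, y, score) in full-MIP coordinates, strongest first.
dog_keypoints <- function(mip, xr, yr, max_kp = 250, patch = 5) {
  sub <- mip[xr, yr, drop = FALSE]
  if (nrow(sub) < 2 * patch + 3 || ncol(sub) < 2 * patch + 3)
    return(data.frame(x = integer(), y = integer(), score = numeric()))
  g1 <- blur2d(sub, 1.2)
  g2 <- blur2d(sub, 1.2 * 1.8)
  dog <- g1 - g2
  a <- abs(dog)
  d <- dim(a)
  inner_x <- (patch + 2):(d[1] - patch - 1)
  inner_y <- (patch + 2):(d[2] - patch - 1)
  if (length(inner_x) < 1 || length(inner_y) < 1)
    return(data.frame(x = integer(), y = integer(), score = numeric()))
  ctr <- a[inner_x, inner_y, drop = FALSE]
  ismax <- ctr > 0
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    ismax <- ismax & (ctr >= a[inner_x + dx, inner_y + dy, drop = FALSE])
  }
  thr <- max(1e-9, 3 * stats::mad(dog, center = 0))
  ismax <- ismax & (ctr > thr)
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x = integer(), y = integer(), score = numeric()))
  kp <- data.frame(x = inner_x[idx[, 1]] + xr[1] - 1L,
                   y = inner_y[idx[, 2]] + yr[1] - 1L,
                   score = ctr[ismax])
  kp <- kp[order(-kp$score), ]
  head(kp, max_kp)
}

# Normalized patch descriptors around keypoints (rows = keypoints).
patch_descriptors <- function(mip, kp, patch = 5) {
  sm <- blur2d(mip, 1.0)
  n <- nrow(kp)
  w <- 2 * patch + 1
  out <- matrix(0, n, w * w)
  for (i in seq_len(n)) {
    p <- sm[kp$x[i] + (-patch:patch), kp$y[i] + (-patch:patch)]
    p <- p - mean(p)
    nrm <- sqrt(sum(p^2))
    out[i, ] <- if (nrm > 1e-9) as.numeric(p) / nrm else 0
  }
  out
}

match_consensus <- function(kpA, dA, kpB, dB, min_corr = 0.7) {
  if (nrow(kpA) == 0 || nrow(kpB) == 0) return(NULL)
  cc <- dA %*% t(dB)
  bestB <- max.col(cc)
  bestA <- max.col(t(cc))
  mutual <- which(bestA[bestB] == seq_len(nrow(kpA)))
  keep <- mutual[cc[cbind(mutual, bestB[mutual])] >= min_corr]
  if (length(keep) == 0) return(NULL)
  # candidate displacement of B's origin relative to A's origin
  dx <- kpA$x[keep] - kpB$x[bestB[keep]]
  dy <- kpA$y[keep] - kpB$y[bestB[keep]]
  key <- paste(dx, dy)
  mode_key <- names(which.max(table(key)))
  mv <- as.integer(strsplit(mode_key, " ")[[1]])
  resid <- sqrt((dx - mv[1])^2 + (dy - mv[2])^2)
  inl <- resid <= 1.5
  list(displacement = c(round(median(dx[inl])), round(median(dy[inl]))),
       n_inliers = sum(inl), score = median(resid[inl]))
}

#' Estimate the offset between two adjacent tiles from MIP features
#'
#' Computes the z-maximum-intensity projection of each tile, restricts to
#' strips around the nominal overlap (plus a search margin), detects
#' difference-of-Gaussian blob keypoints, matches normalized patch
#' descriptors and takes the translation consensus. If the strips carry too
#' few features the whole MIPs are tried before giving up.
#'
#' @param tileA,tileB `image_stack` tiles of equal dims. For
#'   `"horizontal"`, B sits to the right (+x) of A; for `"vertical"`, below
#'   (+y).
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param nominal_overlap_frac Nominal overlap as a fraction of tile width.
#' @param min_inliers Minimum consensus matches for a valid offset.
#' @param search_margin Widens the strips beyond the nominal overlap.
#' @return A `tile_offset`: `displacement` (x, y) of tile B's origin in tile
#'   A's pixel frame, `n_inliers`, `score` (median residual, px).
#' @export
estimate_tile_offset <- function(tileA, tileB,
                                 orientation = c("horizontal", "vertical"),
                                 nominal_overlap_frac = 0.1,
                                 min_inliers = 4, search_margin = 0.5) {
  orientation <- match.arg(orientation)
  if (!all(dim(tileA$data) == dim(tileB$data)))
    stopf("tiles must share dimensions")
  mipA <- stack_mip(tileA)
  mipB <- stack_mip(tileB)
  d <- dim(mipA)
  along <- if (orientation == "horizontal") 1L else 2L
  W <- d[along]
  w <- min(W, ceiling(nominal_overlap_frac * (1 + search_margin) * W) + 4L)
  if (orientation == "horizontal") {
    strips <- list(A = list(xr = (W - w + 1):W, yr = seq_len(d[2])),
                   B = list(xr = 1:w, yr = seq_len(d[2])))
  } else {
    strips <- list(A = list(xr = seq_len(d[1]), yr = (W - w + 1):W),
                   B = list(xr = seq_len(d[1]), yr = 1:w))
  }
  try_region <- function(regA, regB) {
    kpA <- dog_keypoints(mipA, regA$xr, regA$yr)
    kpB <- dog_keypoints(mipB, regB$xr, regB$yr)
    if (nrow(kpA) == 0 || nrow(kpB) == 0) return(NULL)
    match_consensus(kpA, patch_descriptors(mipA, kpA),
                    kpB, patch_descriptors(mipB, kpB))
  }
  res <- try_region(strips$A, strips$B)
  if (is.null(res) || res$n_inliers < min_inliers) {
    full <- list(xr = seq_len(d[1]), yr = seq_len(d[2]))
    res2 <- try_region(full, full)
    if (!is.null(res2) && res2$n_inliers >= min_inliers &&
        (is.null(res) || res2$n_inliers > res$n_inliers)) res <- res2
  }
  if (is.null(res) || res$n_inliers < min_inliers)
    stop(structure(class = c("skintrace_insufficient_features", "error",
                             "condition"),
                   list(message = sprintf(
                     "insufficient features to estimate the %s tile offset",
                     orientation), call = NULL)))
  structure(c(res, list(orientation = orientation, method = "features")),
            class = "tile_offset")
}

#' Normalized cross-correlation fallback offset
#'
#' Scans overlap widths in a window of +/- `search` around the nominal
#' overlap (and small transverse shifts) and picks the maximum Pearson
#' correlation between the overlap strips of the two MIPs. Deterministic;
#' used when feature matching finds too few inliers (sparse scenes).
#'
#' @inheritParams estimate_tile_offset
#' @param search Fractional search window around the nominal overlap.
#' @param max_shift Max transverse shift searched (px).
#' @return A `tile_offset` with `method = "ncc"`.
#' @export
ncc_tile_offset <- function(tileA, tileB,
                            orientation = c("horizontal", "vertical"),
                            nominal_overlap_frac = 0.1, search = 0.25,
                            max_shift = 8L) {
  orientation <- match.arg(orientation)
  mipA <- stack_mip(tileA)
  mipB <- stack_mip(tileB)
  if (orientation == "vertical") {
    mipA <- t(mipA)
    mipB <- t(mipB)
  }
  W <- nrow(mipA)
  ov0 <- nominal_overlap_frac * W
  ovs <- max(2, floor(ov0 * (1 - search))):min(W, ceiling(ov0 * (1 + search)))
  best <- c(-Inf, NA, NA)
  H <- ncol(mipA)
  for (ov in ovs) {
    sa <- mipA[(W - ov + 1):W, , drop = FALSE]
    for (sh in (-max_shift):max_shift) {
      ya <- max(1, 1 + sh):min(H, H + sh)
      yb <- ya - sh
      a <- as.numeric(sa[, ya])
      b <- as.numeric(mipB[1:ov, yb])
      if (sd(a) < 1e-9 || sd(b) < 1e-9) next
      cc <- stats::cor(a, b)
      if (cc > best[1]) best <- c(cc, ov, sh)
    }
  }
  if (!is.finite(best[1])) stopf("cross-correlation fallback failed")
  disp <- if (orientation == "horizontal")
    c(W - best[2], best[3]) else c(best[3], W - best[2])
  structure(list(displacement = as.integer(disp), n_inliers = NA_integer_,
                 score = 1 - best[1], orientation = orientation,
                 method = "ncc"),
            class = "tile_offset")
}

seam_offset <- function(tileA, tileB, orientation, nominal_overlap_frac,
                        min_inliers, fallback, seam_name) {
  res <- tryCatch(
    estimate_tile_offset(tileA, tileB, orientation,
                         nominal_overlap_frac, min_inliers),
    skintrace_insufficient_features = function(e) NULL)
  if (is.null(res) && fallback)
    res <- tryCatch(ncc_tile_offset(tileA, tileB, orientation,
                                    nominal_overlap_frac),
                    error = function(e) NULL)
  if (is.null(res))
    stopf("stitching failed at seam %s: offset estimation found too few features",
          seam_name)
  res
}

#' Stitch four quadrant tiles into one superstack
#'
#' Offsets are estimated per seam (left–right pairs first, then
#' top–bottom) unless supplied. Outside overlap strips voxels are copied
#' bit-exactly from the unique source tile; inside overlaps a linear blend
#' ramp as wide as the overlap mixes the contributing tiles. All z planes
#' share the lateral offsets.
#'
#' @param tiles A `tile_set` or named list `t00, t01, t10, t11` of
#'   `image_stack`s (2x2 grid, second digit = column/x).
#' @param offsets Optional 4x2 integer matrix of (x, y) tile origins; when
#'   `NULL` they are estimated from MIP features.
#' @param nominal_overlap_frac Nominal overlap fraction (default the 10%
#'   acquisition setting).
#' @param min_inliers,fallback Passed to the seam estimator; `fallback`
#'   enables the normalized cross-correlation backup.
#' @return An `image_stack` with attribute `provenance` (per-tile offsets,
#'   blend ramp width, estimation method per seam).
#' @export
stitch_quadrants <- function(tiles, offsets = NULL,
                             nominal_overlap_frac = 0.1,
                             min_inliers = 4, fallback = TRUE) {
  if (inherits(tiles, "tile_set")) tiles <- tiles$tiles
  need <- c("t00", "t01", "t10", "t11")
  if (!all(need %in% names(tiles))) stopf("need tiles t00, t01, t10, t11")
  tiles <- tiles[need]
  d <- dim(tiles$t00$data)
  seam_info <- NULL
  if (is.null(offsets)) {
    s_h0 <- seam_offset(tiles$t00, tiles$t01, "horizontal",
                        nominal_overlap_frac, min_inliers, fallback,
                        "t00|t01")
    s_h1 <- seam_offset(tiles$t10, tiles$t11, "horizontal",
                        nominal_overlap_frac, min_inliers, fallback,
                        "t10|t11")
    s_v0 <- seam_offset(tiles$t00, tiles$t10, "vertical",
                        nominal_overlap_frac, min_inliers, fallback,
                        "t00|t10")
    offsets <- rbind(t00 = c(0L, 0L),
                     t01 = s_h0$displacement,
                     t10 = s_v0$displacement,
                     t11 = s_v0$displacement + s_h1$displacement)
    colnames(offsets) <- c("x", "y")
    seam_info <- list(`t00|t01` = s_h0, `t10|t11` = s_h1,
                      `t00|t10` = s_v0)
  }
  offsets <- round(offsets)
  offsets <- sweep(offsets, 2, apply(offsets, 2, min))  # anchor at zero
  nx <- max(offsets[, 1]) + d[1]
  ny <- max(offsets[, 2]) + d[2]
  ramp_x <- max(1L, d[1] - (max(offsets[, 1]) - min(offsets[, 1])))
  ramp_y <- max(1L, d[2] - (max(offsets[, 2]) - min(offsets[, 2])))
  wx <- pmin(1, pmin(seq_len(d[1]), d[1] + 1 - seq_len(d[1])) / ramp_x)
  wy <- pmin(1, pmin(seq_len(d[2]), d[2] + 1 - seq_len(d[2])) / ramp_y)
  wtile <- outer(wx, wy)
  num <- array(0, c(nx, ny, d[3]))
  den <- array(0, c(nx, ny, d[3]))
  for (nm in need) {
    o <- offsets[nm, ]
    ix <- o[1] + seq_len(d[1])
    iy <- o[2] + seq_len(d[2])
    for (z in seq_len(d[3])) {
      num[ix, iy, z] <- num[ix, iy, z] + wtile * tiles[[nm]]$data[, , z]
      den[ix, iy, z] <- den[ix, iy, z] + wtile
    }
  }
  out <- round(num / pmax(den, 1e-12))
  super <- image_stack(out, voxel_size = tiles$t00$voxel_size,
                       bit_depth = tiles$t00$bit_depth,
                       session = tiles$t00$session)
  attr(super, "provenance") <- list(offsets = offsets,
                                    blend_ramp = c(ramp_x, ramp_y),
                                    seams = seam_info)
  super
}
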