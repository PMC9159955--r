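#' Render a skeleton into a 16-bit image stack with ground-truth labels
#'
#' Fibers are rasterized as hard tubes of their node radii, composited with
#' an epidermal autofluorescence band (with lateral texture and gaps) and
#' hair-like appendages, convolved with an anisotropic Gaussian PSF, scaled
#' by the linear depth gain (emulating laser power rising with depth), and
#' finally corrupted with Poisson shot noise plus Gaussian read noise. The
#' returned `labels` volume is the pre-blur ground truth with class priority
#' fiber > appendage > autofluorescence.
#'
#' @param skeleton A `skin_skeleton` fitting the configured volume.
#' @param config A [simulation_config()].
#' @param seed Integer seed (noise, texture, appendage placement).
#' @return List with `stack` (16-bit `image_stack`) and `labels` (3D integer
#'   array; 0 background, 1 fiber, 2 epidermal autofluorescence,
#'   3 appendage).
#' @export
render_stack <- function(skeleton, config, seed = config$seed) {
  dims <- config$volume_dims
  vox <- config$voxel_size
  ext <- config_extent(config)
  nd <- skeleton$nodes
  if (nrow(nd) > 0 &&
      (any(nd$x > ext[1]) || any(nd$y > ext[2]) || any(nd$z > ext[3]) ||
       any(nd$x < 0) || any(nd$y < 0) || any(nd$z < 0)))
    stopf("skeleton does not fit the configured volume")
  n <- prod(dims)
  vol <- numeric(n)
  labels <- integer(n)
  if (nrow(nd) > 0) {
    ch <- nd[nd$parent > 0, , drop = FALSE]
    if (nrow(ch) > 0) {
      pa <- nd[match(ch$parent, nd$id), ]
      val <- config$fiber_intensity[ch$caliber]
      # effective radius floored at half the coarsest voxel pitch so
      # sub-voxel tubes rasterize as connected lines (partial volume)
      r_eff <- pmax(pmax(ch$radius, pa$radius), 0.5 * max(vox))
      cpp_paint_capsules(vol, labels, dims, vox,
                         as.matrix(pa[, c("x", "y", "z")]),
                         as.matrix(ch[, c("x", "y", "z")]),
                         r_eff, as.numeric(val),
                         rep(1L, nrow(ch)))
    }
  }
  with_seed(seed, {
    af <- render_af_band(dims, vox, config)
    vol <- pmax(vol, 0) + af$intensity
    labels[labels == 0L & af$mask] <- 2L
    hairs <- render_appendages(dims, vox, config)
    if (!is.null(hairs)) {
      cpp_paint_capsules(vol, labels, dims, vox, hairs$a, hairs$b,
                         hairs$radius, hairs$value,
                         rep(3L, nrow(hairs$a)))
    }
    sig <- c(config$psf_sigma[["lateral"]] / vox[1],
             config$psf_sigma[["lateral"]] / vox[2],
             config$psf_sigma[["axial"]] / vox[3])
    vol <- cpp_gauss_blur3d(vol, dims, sig)
    gain <- depth_gain_profile(dims[3], config$depth_gain)
    vol <- vol * rep(gain, each = dims[1] * dims[2])
    vol <- vol + config$noise$offset
    if (config$noise$poisson_scale > 0) {
      lam <- vol * config$noise$poisson_scale
      vol <- rpois(n, lam) / config$noise$poisson_scale
    }
    if (config$noise$gauss_sd > 0)
      vol <- vol + rnorm(n, 0, config$noise$gauss_sd)
    vol <- round(clamp(vol, 0, 65535))
    list(stack = image_stack(array(vol, dims), voxel_size = vox,
                             bit_depth = 16L),
         labels = array(labels, dims))
  })
}

#' Per-slice excitation gain profile (linear ramp, surface = 1)
#' @param nz Number of z planes.
#' @param depth_gain Bottom/surface multiplier.
#' @return Numeric vector of length `nz`.
#' @export
depth_gain_profile <- function(nz, depth_gain) {
  if (nz == 1) return(1)
  1 + (depth_gain - 1) * (seq_len(nz) - 1) / (nz - 1)
}

render_af_band <- function(dims, vox, config) {
  band <- config$epidermal_band
  zr <- band$z_range
  inten <- band$intensity
  z_um <- (seq_len(dims[3]) - 1) * vox[3]
  inband <- z_um >= zr[1] & z_um <= zr[2]
  n <- prod(dims)
  if (inten <= 0 || !any(inband))
    return(list(intensity = numeric(n), mask = logical(n)))
  # coarse lateral texture field -> smooth multiplicative factor with gaps
  cf <- 16L
  cd <- c(max(2L, ceiling(dims[1] / cf)), max(2L, ceiling(dims[2] / cf)), 1L)
  tex <- runif(prod(cd))
  tex <- cpp_gauss_blur3d(tex, cd, c(1.2, 1.2, 0))
  tex <- (tex - mean(tex)) / max(sd(tex), 1e-9)
  ix <- pmin(cd[1] - 1, (seq_len(dims[1]) - 1) / cf)
  iy <- pmin(cd[2] - 1, (seq_len(dims[2]) - 1) / cf)
  pts <- cbind(rep(ix, times = dims[2]), rep(iy, each = dims[1]), 0)
  texf <- cpp_trilinear(tex, cd, pts, 0)
  factor_xy <- ifelse(texf < -1.35, 0, 1 + 0.3 * texf)   # ~9% gap area
  slice_n <- dims[1] * dims[2]
  intensity <- numeric(n)
  mask <- logical(n)
  for (z in which(inband)) {
    idx <- (z - 1) * slice_n + seq_len(slice_n)
    intensity[idx] <- inten * factor_xy
    mask[idx] <- factor_xy > 0.25
  }
  list(intensity = intensity, mask = mask)
}

render_appendages <- function(dims, vox, config) {
  area_mm2 <- prod((dims[1:2] - 1) * vox[1:2]) / 1e6
  k <- rpois(1, config$appendage_density * area_mm2)
  if (k == 0) return(NULL)
  ext <- (dims - 1) * vox
  a <- matrix(0, k, 3); b <- matrix(0, k, 3)
  for (i in seq_len(k)) {
    x0 <- runif(1, 0.05, 0.95) * ext[1]
    y0 <- runif(1, 0.05, 0.95) * ext[2]
    len <- runif(1, min(20, 0.7 * ext[3]), min(40, ext[3]))
    tilt <- runif(2, -0.4, 0.4)
    a[i, ] <- c(x0, y0, 0)
    b[i, ] <- c(clamp(x0 + tilt[1] * len, 0, ext[1]),
                clamp(y0 + tilt[2] * len, 0, ext[2]),
                min(len, ext[3]))
  }
  list(a = a, b = b, radius = runif(k, 2.5, 4.5),
       value = rep(0.8 * config$epidermal_band$intensity, k))
}

#' Cut a stack into four quadrant tiles with a shared overlap
#'
#' Emulates the sequential four-tile acquisition: a 2x2 grid of tiles whose
#' adjacent members share `overlap_px` columns/rows copied from the parent
#' stack. True tile offsets are recorded as ground truth for stitching
#' validation.
#'
#' @param stack An `image_stack` whose lateral dims equal `2*W - overlap_px`
#'   for integer tile width `W` (both axes).
#' @param overlap_px Shared overlap in pixels.
#' @return A `tile_set`: tiles named `t00, t01, t10, t11` (row-major: second
#'   digit is the x/column position), a 4x2 matrix of true 0-based (x, y)
#'   offsets, and the overlap.
#' @export
make_quadrant_tiles <- function(stack, overlap_px) {
  d <- dim(stack$data)
  wx2 <- d[1] + overlap_px
  wy2 <- d[2] + overlap_px
  if (wx2 %% 2 != 0 || wy2 %% 2 != 0)
    stopf("lateral dims must equal 2*W - overlap_px for integer W")
  Wx <- wx2 %/% 2L
  Wy <- wy2 %/% 2L
  ox <- Wx - overlap_px
  oy <- Wy - overlap_px
  cut <- function(x0, y0) {
    image_stack(stack$data[x0 + seq_len(Wx), y0 + seq_len(Wy), , drop = FALSE],
                voxel_size = stack$voxel_size, bit_depth = stack$bit_depth,
                session = stack$session)
  }
  tiles <- list(t00 = cut(0L, 0L), t01 = cut(ox, 0L),
                t10 = cut(0L, oy), t11 = cut(ox, oy))
  offsets <- rbind(t00 = c(0L, 0L), t01 = c(ox, 0L),
                   t10 = c(0L, oy), t11 = c(ox, oy))
  colnames(offsets) <- c("x", "y")
  structure(list(tiles = tiles, offsets = offsets,
                 overlap_px = as.integer(overlap_px),
                 tile_dims = c(Wx, Wy, d[3])),
            class = "tile_set")
}
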