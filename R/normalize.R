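#' Parameters for depth-adaptive 16-to-8-bit conversion
#'
#' @param low,high Robust percentiles (0–100) anchoring the output range:
#'   `low` maps to 0, `high` to 255.
#' @param depth_model `"linear"` (per-slice gain fitted linearly in z) or
#'   `"none"`.
#' @param local_weight Convex blend weight of the depth-local gain
#'   correction against the global (flat) transfer; the default 1 divides
#'   the fitted per-slice gain out completely, which makes the conversion
#'   idempotent and depth-uniform (values below 1 apply partial
#'   correction).
#' @param anchor_percentiles Percentile pair of fiber-foreground intensities
#'   used as the cross-session anchor.
#' @return A `conversion_params` list.
#' @export
conversion_params <- function(low = 1.0, high = 99.5,
                              depth_model = c("linear", "none"),
                              local_weight = 1,
                              anchor_percentiles = c(50, 99)) {
  if (!(low >= 0 && low < high && high <= 100))
    stopf("need 0 <= low < high <= 100")
  structure(list(low = low, high = high,
                 depth_model = match.arg(depth_model),
                 local_weight = local_weight,
                 anchor_percentiles = anchor_percentiles),
            class = "conversion_params")
}

# Fit a smooth per-slice gain curve from robust slice spreads; returns a
# multiplicative gain per slice, normalized to mean 1, so that dividing by
# it flattens the depth-dependent excitation ramp. Scale-invariant. Ramps
# shallower than 1.3x are left alone (content-driven residuals, not
# excitation ramps) which keeps the conversion idempotent.
fit_depth_gain <- function(vol, dims, params) {
  nz <- dims[3]
  if (params$depth_model == "none" || nz < 3) return(rep(1, nz))
  sn <- dims[1] * dims[2]
  spread <- numeric(nz)
  for (z in seq_len(nz)) {
    sl <- vol[(z - 1) * sn + seq_len(sn)]
    qs <- quantile(sl, c(0.5, 0.995), names = FALSE)
    spread[z] <- qs[2] - qs[1]
  }
  ok <- spread > 1e-9
  if (sum(ok) < 3) return(rep(1, nz))
  # iterated linear fit in z until the fitted ramp is flat: makes the
  # conversion a fixed point (re-converting a converted stack fits a flat
  # gain), hence idempotent to within a grey level
  zz <- seq_len(nz)
  g <- rep(1, nz)
  s <- spread
  for (it in 1:6) {
    fit <- stats::lsfit(zz[ok], s[ok])
    f <- fit$coefficients[1] + fit$coefficients[2] * zz
    f <- pmax(f, 0.05 * max(f))
    f <- f / mean(f[ok])
    if (it == 1 && max(f[ok]) / min(f[ok]) < 1.3) return(g)
    g <- g * f
    s <- s / f
    if (max(abs(f - 1)) < 0.005) break
  }
  g <- pmax(g, 1e-3)
  g / mean(g)
}

#' Depth-adaptive conversion of a 16-bit stack to 8 bits
#'
#' Fits a per-slice gain curve (linear in z) to robust slice spreads,
#' divides out a `local_weight`-blend of it, then maps intensities linearly
#' between the global robust percentiles `low` -> 0 and `high` -> 255 with
#' clipping. The mapping is monotone non-decreasing within every slice, is
#' invariant to a global multiplicative gain, and is idempotent to within
#' one grey level.
#'
#' @param stack16 A 16-bit `image_stack`.
#' @param params A [conversion_params()].
#' @return An 8-bit `image_stack`; the fitted gain and anchors are attached
#'   as attribute `conversion`.
#' @export
depth_adaptive_convert <- function(stack16, params = conversion_params()) {
  if (stack16$bit_depth != 16L) stopf("input must be a 16-bit stack")
  dims <- dim(stack16$data)
  vol <- as.numeric(stack16$data)
  g <- fit_depth_gain(vol, dims, params)
  g_eff <- (1 - params$local_weight) + params$local_weight * g
  vol <- vol / rep(g_eff, each = dims[1] * dims[2])
  qs <- quantile(vol, c(params$low, params$high) / 100, names = FALSE)
  if (qs[2] - qs[1] < 1e-9) {
    out <- array(if (max(vol) > 0) 128 else 0, dims)
  } else {
    out <- array(round(clamp((vol - qs[1]) / (qs[2] - qs[1]), 0, 1) * 255),
                 dims)
  }
  res <- image_stack(out, voxel_size = stack16$voxel_size, bit_depth = 8L,
                     session = stack16$session)
  attr(res, "conversion") <- list(gain = g, anchors = qs, params = params)
  res
}

#' Convert and normalize a set of sessions for longitudinal comparison
#'
#' Each 16-bit stack is depth-corrected and converted with its own robust
#' percentile anchors, which maps every session's anchor pair onto the same
#' fixed 8-bit targets — so excitation drift (a per-session global gain)
#' cancels. Foreground medians are then aligned to the first (baseline)
#' session via the fiber-foreground anchor percentiles.
#'
#' @param stacks List of 16-bit `image_stack`s (first = baseline).
#' @param params A [conversion_params()].
#' @return List of 8-bit `image_stack`s.
#' @export
cross_session_normalize <- function(stacks, params = conversion_params()) {
  if (length(stacks) < 1) stopf("need at least one stack")
  out <- lapply(stacks, depth_adaptive_convert, params = params)
  if (length(out) == 1) return(out)
  fg_anchor <- function(s) {
    v <- as.numeric(s$data)
    thr <- if (max(v) > min(v)) otsu_threshold(v) else max(v)
    fg <- v[v > thr]
    if (length(fg) < 10) return(NA_real_)
    median(fg)
  }
  a0 <- fg_anchor(out[[1]])
  if (is.na(a0) || a0 <= 0) return(out)
  for (i in seq_along(out)[-1]) {
    ai <- fg_anchor(out[[i]])
    if (is.na(ai) || ai <= 0) next
    sc <- a0 / ai
    if (abs(sc - 1) < 0.02) next
    out[[i]]$data <- round(clamp(out[[i]]$data * sc, 0, 255))
  }
  out
}
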