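#' Configuration for the synthetic skin-innervation simulator
#'
#' Defaults emulate the acquisition the pipeline targets: 427 nm lateral /
#' 1 µm axial voxels, excitation rising linearly 3-fold from surface to
#' bottom (5% to 15% laser power), an epidermal autofluorescence band under
#' the surface with hair-like appendage clutter, and two caliber classes of
#' fiber tree (thin nociceptor-like ending as intra-epidermal free endings,
#' thick A-beta-like ending in coiled sub-epidermal terminals).
#'
#' @param volume_dims Voxel counts (x, y, z). Default `c(256, 256, 64)`, the
#'   desk-scale scene used throughout the test-suite; the full-canvas
#'   preset [acquisition_geometry_config()] exists for stitching checks.
#' @param voxel_size µm per voxel (x, y, z).
#' @param n_trees Named counts per caliber class, `c(thin =, thick =)`.
#' @param branching List: `mean_branches` (mean bifurcations per tree),
#'   `angle_sd` (branch-angle spread, degrees), `tortuosity` (per-step
#'   direction jitter, radians), `step` (polyline step, µm),
#'   `branch_len` (range of inter-branch segment lengths, µm).
#' @param radii List with `thin` and `thick` radius ranges (µm); the thin
#'   range must lie strictly below the thick range.
#' @param epidermal_band List: `z_range` depth interval (µm) of the
#'   autofluorescence band (its deep edge is the dermal–epidermal boundary)
#'   and `intensity` (16-bit counts).
#' @param appendage_density Hair-like clutter per mm² of surface.
#' @param depth_gain Surface-to-bottom excitation multiplier (linear ramp).
#' @param noise List: `poisson_scale` (expected photons per intensity
#'   count; 0 disables shot noise), `gauss_sd` (additive read noise, counts),
#'   `offset` (detector baseline, counts).
#' @param fiber_intensity Peak fluorescence per class, 16-bit counts.
#' @param psf_sigma Gaussian PSF sigma (µm), lateral and axial.
#' @param seed Default seed for operations that are not given one.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(volume_dims = c(256L, 256L, 64L),
                              voxel_size = c(0.427, 0.427, 1),
                              n_trees = c(thin = 6L, thick = 3L),
                              branching = list(mean_branches = 4,
                                               angle_sd = 25,
                                               tortuosity = 0.12,
                                               step = 1.5,
                                               branch_len = c(20, 45)),
                              radii = list(thin = c(0.3, 0.45),
                                           thick = c(1.2, 1.8)),
                              epidermal_band = list(z_range = c(0, 15),
                                                    intensity = 9000),
                              appendage_density = 150,
                              depth_gain = 3,
                              noise = list(poisson_scale = 0.02,
                                           gauss_sd = 150, offset = 800),
                              fiber_intensity = c(thin = 15000,
                                                  thick = 19000),
                              psf_sigma = c(lateral = 0.3, axial = 1.0),
                              seed = 1L) {
  if (any(volume_dims <= 0)) stopf("volume_dims must be positive")
  if (any(voxel_size <= 0)) stopf("voxel sizes must be positive")
  if (max(radii$thin) >= min(radii$thick))
    stopf("thin radius range must lie strictly below the thick range")
  zext <- (volume_dims[3] - 1) * voxel_size[3]
  if (epidermal_band$z_range[1] < 0 || epidermal_band$z_range[2] > zext)
    stopf("epidermal band must lie within the z extent")
  structure(list(volume_dims = as.integer(volume_dims),
                 voxel_size = as.numeric(voxel_size),
                 n_trees = n_trees, branching = branching, radii = radii,
                 epidermal_band = epidermal_band,
                 appendage_density = appendage_density,
                 depth_gain = depth_gain, noise = noise,
                 fiber_intensity = fiber_intensity, psf_sigma = psf_sigma,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Full-canvas acquisition preset
#'
#' A simulation configuration on the full acquisition canvas: four
#' 1050 x 1050-px quadrant tiles with a 100-px shared overlap merge into a
#' 2000 x 2000-px superstack at 427-nm lateral pitch (854 µm span). The z
#' extent is kept shallow so the preset stays desk-computable; it exists
#' for validating the stitching geometry, not for full-depth simulations.
#'
#' @param nz Number of z planes.
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
acquisition_geometry_config <- function(nz = 8L, ...) {
  simulation_config(volume_dims = c(2000L, 2000L, nz),
                    n_trees = c(thin = 40L, thick = 20L),
                    epidermal_band = list(z_range = c(0, 2),
                                          intensity = 7000),
                    appendage_density = 50,
                    ...)
}

config_extent <- function(config) {
  (config$volume_dims - 1) * config$voxel_size
}

#' Generate a ground-truthed fiber forest
#'
#' Grows branching tubular centerlines from deep dermal roots toward the
#' surface. Thin-class trees send terminal branches across the
#' dermal–epidermal boundary as short filopodia-like free endings; thick
#' trees stop below the boundary in coiled Meissner-like terminals. Output
#' is deterministic given `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `skin_skeleton`.
#' @export
generate_fiber_tree <- function(config, seed = config$seed) {
  if (!inherits(config, "simulation_config")) stopf("invalid config")
  ext <- config_extent(config)
  z_epi <- config$epidermal_band$z_range[2]
  with_seed(seed, {
    nodes <- empty_skeleton_nodes()
    tree_id <- 0L
    next_id <- 1L
    for (class in c("thin", "thick")) {
      n <- config$n_trees[[class]]
      if (is.null(n) || n <= 0) next
      for (t in seq_len(n)) {
        tree_id <- tree_id + 1L
        tr <- grow_tree(config, class, tree_id, ext, z_epi, next_id)
        next_id <- next_id + nrow(tr)
        nodes <- rbind(nodes, tr)
      }
    }
    if (nrow(nodes) > 0) nodes$epidermal <- nodes$z < z_epi
    skin_skeleton(nodes, boundary_z = z_epi, extent = ext)
  })
}

# Grow one tree as a set of polyline branches; returns skeleton node rows.
grow_tree <- function(config, class, tree_id, ext, z_epi, id0) {
  br <- config$branching
  rr <- config$radii[[class]]
  base_r <- runif(1, rr[1], rr[2])
  margin <- 0.06 * ext[1:2]
  root <- c(runif(1, margin[1], ext[1] - margin[1]),
            runif(1, margin[2], ext[2] - margin[2]),
            runif(1, 0.75 * ext[3], 0.92 * ext[3]))
  # initial direction: mostly upward (toward surface, -z)
  rows <- list()
  nid <- id0
  add_node <- function(p, r, parent) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = nid, x = p[1], y = p[2], z = p[3], radius = r,
      parent = parent, tree_id = tree_id, caliber = class,
      epidermal = FALSE, stringsAsFactors = FALSE)
    id_here <- nid
    nid <<- nid + 1L
    id_here
  }
  root_id <- add_node(root, base_r, 0L)
  n_branch_events <- max(1L, rpois(1, br$mean_branches))
  # queue of growing tips: list(pos, dir, parent_id, depth, ascending)
  d0 <- normalize(c(rnorm(2, 0, 1), runif(1, -0.6, -0.2)))
  tips <- list(list(pos = root, dir = d0, parent = root_id, depth = 0L,
                    ascending = FALSE))
  budget <- n_branch_events
  stop_z <- if (class == "thin") z_epi + 4 else z_epi + 6
  guard <- 0L
  while (length(tips) > 0 && guard < 200L) {
    guard <- guard + 1L
    tip <- tips[[1]]; tips <- tips[-1]
    seg_len <- runif(1, br$branch_len[1], br$branch_len[2])
    nstep <- if (tip$ascending) 80L else max(2L, round(seg_len / br$step))
    pos <- tip$pos; dir <- tip$dir; parent <- tip$parent
    bias <- if (tip$ascending) c(0, 0, -0.3) else c(0, 0, -0.02)
    tort <- if (tip$ascending) 0.5 * br$tortuosity else br$tortuosity
    reached <- FALSE
    for (s in seq_len(nstep)) {
      dir <- normalize(dir + rnorm(3, 0, tort) + bias)
      pos2 <- pos + dir * br$step
      # reflect at lateral walls, clamp z
      for (d in 1:2) {
        if (pos2[d] < 1 || pos2[d] > ext[d] - 1) {
          dir[d] <- -dir[d]
          pos2[d] <- clamp(pos2[d], 1, ext[d] - 1)
        }
      }
      pos2[3] <- clamp(pos2[3], 0, ext[3] - 0.5)
      taper <- max(0.8, 1 - 0.02 * tip$depth)
      parent <- add_node(pos2, max(rr[1], base_r * taper), parent)
      pos <- pos2
      if (pos[3] <= stop_z) { reached <- TRUE; break }
    }
    if (reached) {
      if (class == "thin") {
        # filopodia-like free ending crossing into the epidermis
        end_len <- runif(1, 5, 9)
        nfe <- max(2L, round(end_len / br$step))
        edir <- normalize(c(rnorm(2, 0, 0.15), -1))
        for (s in seq_len(nfe)) {
          pos2 <- pos + edir * br$step
          pos2[1:2] <- clamp(pos2[1:2], 1, ext[1:2] - 1)
          pos2[3] <- max(pos2[3], 1.0)
          parent <- add_node(pos2, rr[1], parent)
          pos <- pos2
          if (pos[3] <= 1.0) break
        }
      } else {
        # coiled Meissner-like terminal below the boundary
        coil_r <- runif(1, 2.5, 3.5)
        phih <- runif(1, 0, 2 * pi)
        nturn <- seq(0, 1.5 * 2 * pi, length.out = 14)
        for (a in nturn[-1]) {
          pos2 <- c(pos[1] + coil_r * (cos(a + phih) - cos(phih)),
                    pos[2] + coil_r * (sin(a + phih) - sin(phih)),
                    pos[3] - 0.25 * a / (2 * pi))
          pos2[1:2] <- clamp(pos2[1:2], 1, ext[1:2] - 1)
          pos2[3] <- max(pos2[3], z_epi + 2)
          parent <- add_node(pos2, base_r, parent)
        }
      }
    } else if (!tip$ascending && budget > 0) {
      budget <- budget - 1L
      sd_a <- br$angle_sd * pi / 180
      for (k in 1:2) {
        ndir <- normalize(dir + rnorm(3, 0, sd_a))
        tips[[length(tips) + 1]] <- list(pos = pos, dir = ndir,
                                         parent = parent,
                                         depth = tip$depth + 1L,
                                         ascending = FALSE)
      }
    } else if (!tip$ascending) {
      # branch budget spent: this tip becomes an ascending terminal branch
      tips[[length(tips) + 1]] <- list(pos = pos,
                                       dir = normalize(dir + c(0, 0, -0.5)),
                                       parent = parent, depth = tip$depth,
                                       ascending = TRUE)
    }
  }
  do.call(rbind, rows)
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, -1) else v / n
}

#' Baseline scene time point
#'
#' Bundles a freshly generated skeleton with an identity deformation and an
#' empty change record.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A `scene_timepoint`.
#' @export
scene_baseline <- function(config, seed = config$seed) {
  skel <- generate_fiber_tree(config, seed)
  structure(list(skeleton = skel, baseline_skeleton = skel,
                 config = config,
                 deformation = NULL, session_label = 1L,
                 change_record = list(removed_trees = integer(),
                                      regrown_trees = integer(),
                                      epidermal_entry = TRUE)),
            class = "scene_timepoint")
}

#' Apply denervation / reinnervation change to a scene
#'
#' Removes a fraction of trees per caliber class; regrowth re-adds removed
#' trees using their stored baseline centerlines with bounded jitter, so
#' sprouting retraces the original trajectories. With `epidermal_entry =
#' FALSE`, regrown thin-class trees are truncated at the dermal–epidermal
#' boundary (no intra-epidermal free endings re-form). A smooth elastic
#' deformation plus a small rigid motion is composed onto the scene to
#' emulate repositioning between imaging sessions.
#'
#' @param scene A `scene_timepoint`.
#' @param change_spec List: `removal_frac` named per class
#'   (`c(thin =, thick =)`), `regrowth_frac` (fraction of removed thin trees
#'   that regrow), `epidermal_entry` flag, `deformation_amplitude` (µm, peak
#'   smooth displacement), `jitter` (µm, max centerline deviation of regrown
#'   trees).
#' @param seed Integer seed.
#' @return A new `scene_timepoint` with incremented `session_label`.
#' @export
apply_longitudinal_change <- function(scene, change_spec, seed = 1L) {
  rem <- change_spec$removal_frac %||% c(thin = 0, thick = 0)
  reg <- change_spec$regrowth_frac %||% 0
  if (any(rem < 0 | rem > 1) || reg < 0 || reg > 1)
    stopf("removal and regrowth fractions must lie in [0, 1]")
  epi_entry <- isTRUE(change_spec$epidermal_entry %||% TRUE)
  amp <- change_spec$deformation_amplitude %||% 0
  jit <- change_spec$jitter %||% 0.5
  skel <- scene$skeleton
  base <- scene$baseline_skeleton
  with_seed(seed, {
    nd <- skel$nodes
    removed <- integer()
    for (class in names(rem)) {
      tr <- unique(nd$tree_id[nd$caliber == class])
      k <- round(rem[[class]] * length(tr))
      if (k > 0) removed <- c(removed, sample(tr, k))
    }
    nd <- nd[!(nd$tree_id %in% removed), ]
    all_removed <- union(scene$change_record$removed_trees, removed)
    # regrowth retraces baseline trajectories of removed thin trees
    regrown <- integer()
    cand <- intersect(all_removed,
                      unique(base$nodes$tree_id[base$nodes$caliber == "thin"]))
    cand <- setdiff(cand, unique(nd$tree_id))
    k <- round(reg * length(cand))
    if (k > 0) {
      regrown <- sort(sample(cand, k))
      for (tid in regrown) {
        tr <- base$nodes[base$nodes$tree_id == tid, ]
        tr <- jitter_tree(tr, jit, skel$extent)
        if (!epi_entry) tr <- truncate_at_boundary(tr, skel$boundary_z)
        if (nrow(tr) > 0) nd <- rbind(nd, tr)
      }
    }
    if (nrow(nd) > 0) nd$epidermal <- nd$z < skel$boundary_z
    new_skel <- skin_skeleton(nd, skel$boundary_z, skel$extent)
    # each session gets its own independent acquisition deformation:
    # repositioning error does not accumulate across imaging days
    deform <- if (amp > 0) make_deformation(amp, skel$extent, seed) else NULL
    structure(list(skeleton = new_skel, baseline_skeleton = base,
                   config = scene$config,
                   deformation = deform,
                   session_label = scene$session_label + 1L,
                   change_record = list(
                     removed_trees = sort(setdiff(all_removed, regrown)),
                     regrown_trees = regrown,
                     epidermal_entry = epi_entry)),
              class = "scene_timepoint")
  })
}

# bounded smooth jitter: constant per-tree offset plus low-frequency
# per-node noise (smoothed along the node chain so the regrown centerline
# stays smooth at the micrometre scale and does not fatten its apparent
# caliber)
jitter_tree <- function(tree_nodes, jit, ext) {
  if (jit <= 0 || nrow(tree_nodes) == 0) return(tree_nodes)
  off <- normalize(rnorm(3)) * runif(1, 0, 0.6 * jit)
  n <- nrow(tree_nodes)
  noise <- matrix(rnorm(3 * n, 0, 0.3 * jit), ncol = 3)
  if (n > 5) {
    k <- rep(1 / 9, 9)
    for (d in 1:3)
      noise[, d] <- stats::filter(c(rep(noise[1, d], 4), noise[, d],
                                    rep(noise[n, d], 4)), k)[5:(n + 4)]
  }
  noise <- clamp(noise, -0.4 * jit, 0.4 * jit)
  tree_nodes$x <- clamp(tree_nodes$x + off[1] + noise[, 1], 0, ext[1])
  tree_nodes$y <- clamp(tree_nodes$y + off[2] + noise[, 2], 0, ext[2])
  tree_nodes$z <- clamp(tree_nodes$z + off[3] + noise[, 3], 0, ext[3])
  tree_nodes
}

# drop nodes above (shallower than) the boundary together with their
# descendants; a small stand-off models regrown endings stalling under the
# basal membrane rather than touching it
truncate_at_boundary <- function(tree_nodes, boundary_z, standoff = 2) {
  if (nrow(tree_nodes) == 0) return(tree_nodes)
  drop <- tree_nodes$z < boundary_z + standoff
  repeat {
    parent_dropped <- tree_nodes$parent %in% tree_nodes$id[drop]
    newdrop <- drop | parent_dropped
    if (all(newdrop == drop)) break
    drop <- newdrop
  }
  out <- tree_nodes[!drop, ]
  out$epidermal <- FALSE
  out
}

# Smooth invertible deformation: small rigid motion + low-order sinusoidal
# displacement field with the requested peak amplitude.
make_deformation <- function(amplitude, ext, seed) {
  ang <- runif(1, -1.5, 1.5) * pi / 180
  shift <- runif(3, -0.5, 0.5) * c(4, 4, 2)
  ph <- runif(6, 0, 2 * pi)
  a <- amplitude * runif(3, 0.5, 1)
  freq <- 2 * pi / (ext + 1e-9)
  # cap the local strain (amplitude x spatial frequency) at ~10%: live
  # tissue repositioned between sessions deforms smoothly, it does not
  # fold or compress at the scale of the fiber spacing
  a <- pmin(a, 0.1 / freq)
  list(angle = ang, shift = shift, phases = ph, amps = a, freq = freq,
       centre = ext / 2, amplitude = amplitude)
}

compose_deformations <- function(d1, d2) {
  if (is.null(d1)) return(d2)
  if (is.null(d2)) return(d1)
  list(chain = c(deformation_chain(d1), deformation_chain(d2)))
}

deformation_chain <- function(d) {
  if (is.null(d)) return(list())
  if (!is.null(d$chain)) d$chain else list(d)
}

#' Apply a scene's deformation to point coordinates
#'
#' @param points n x 3 matrix (µm).
#' @param deformation Deformation descriptor from a `scene_timepoint`
#'   (`NULL` = identity).
#' @return Deformed n x 3 matrix.
#' @export
apply_deformation <- function(points, deformation) {
  for (d in deformation_chain(deformation)) {
    cs <- cos(d$angle); sn <- sin(d$angle)
    R <- matrix(c(cs, sn, 0, -sn, cs, 0, 0, 0, 1), 3, 3)
    pc <- sweep(points, 2, d$centre)
    points <- sweep(pc %*% t(R), 2, d$centre + d$shift, "+")
    f <- d$freq
    disp <- cbind(
      d$amps[1] * sin(f[2] * points[, 2] + d$phases[1]) *
        cos(f[3] * points[, 3] + d$phases[2]),
      d$amps[2] * sin(f[1] * points[, 1] + d$phases[3]) *
        cos(f[3] * points[, 3] + d$phases[4]),
      d$amps[3] * sin(f[1] * points[, 1] + d$phases[5]) *
        sin(f[2] * points[, 2] + d$phases[6]))
    points <- points + disp
  }
  points
}

#' Skeleton of a scene with its session deformation applied
#'
#' @param scene A `scene_timepoint`.
#' @return A `skin_skeleton` in the deformed (acquisition) frame; positions
#'   are clamped to the volume.
#' @export
deformed_skeleton <- function(scene) {
  skel <- scene$skeleton
  if (is.null(scene$deformation) || nrow(skel$nodes) == 0) return(skel)
  p <- apply_deformation(as.matrix(skel$nodes[, c("x", "y", "z")]),
                         scene$deformation)
  nd <- skel$nodes
  nd$x <- clamp(p[, 1], 0, skel$extent[1])
  nd$y <- clamp(p[, 2], 0, skel$extent[2])
  nd$z <- clamp(p[, 3], 0, skel$extent[3])
  nd$epidermal <- nd$z < skel$boundary_z
  skin_skeleton(nd, skel$boundary_z, skel$extent)
}
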