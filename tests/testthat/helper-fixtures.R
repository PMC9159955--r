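# Shared fixtures, generated in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# desk-scale default scene with ground truth
desk_config <- function(...) simulation_config(...)

desk_scene <- function() fixture("desk_scene", function() {
  cfg <- desk_config()
  sk <- generate_fiber_tree(cfg, 42)
  r <- render_stack(sk, cfg, 142)
  list(config = cfg, skeleton = sk, stack = r$stack, labels = r$labels)
})

# noiseless, autofluorescence-free scene for tracer checks
clean_scene <- function() fixture("clean_scene", function() {
  cfg <- desk_config(noise = list(poisson_scale = 0, gauss_sd = 0,
                                  offset = 800),
                     epidermal_band = list(z_range = c(0, 15),
                                           intensity = 0),
                     appendage_density = 0)
  sk <- generate_fiber_tree(cfg, 42)
  r <- render_stack(sk, cfg, 1)
  list(config = cfg, skeleton = sk, stack = r$stack, labels = r$labels)
})

# single straight horizontal tube skeleton in a small volume
straight_tube_scene <- function(radius = 0.4, caliber = "thin",
                                y_um = 13, n = 101L) {
  cfg <- simulation_config(
    volume_dims = c(256L, 64L, 32L), n_trees = c(thin = 0L, thick = 0L),
    epidermal_band = list(z_range = c(0, 5), intensity = 0),
    appendage_density = 0,
    noise = list(poisson_scale = 0, gauss_sd = 0, offset = 100),
    depth_gain = 1)
  nd <- data.frame(id = seq_len(n),
                   x = seq(4, 104, length.out = n), y = y_um, z = 20,
                   radius = radius, parent = c(0L, seq_len(n - 1)),
                   tree_id = 1L, caliber = caliber, epidermal = FALSE,
                   stringsAsFactors = FALSE)
  sk <- skin_skeleton(nd, boundary_z = 5,
                      extent = (c(256, 64, 32) - 1) * cfg$voxel_size)
  list(config = cfg, skeleton = sk)
}

# independent oracle: sum of Euclidean segment lengths of a skeleton
oracle_skeleton_length <- function(sk) {
  nd <- sk$nodes
  if (nrow(nd) == 0) return(0)
  ch <- nd[nd$parent > 0, ]
  pa <- nd[match(ch$parent, nd$id), ]
  sum(sqrt((ch$x - pa$x)^2 + (ch$y - pa$y)^2 + (ch$z - pa$z)^2))
}

# independent oracle: brute-force point-in-capsule voxel test
oracle_tube_voxels <- function(sk, dims, vox, r_floor = 0.5 * max(vox)) {
  nd <- sk$nodes
  centers <- expand.grid(x = (seq_len(dims[1]) - 1) * vox[1],
                         y = (seq_len(dims[2]) - 1) * vox[2],
                         z = (seq_len(dims[3]) - 1) * vox[3])
  inside <- rep(FALSE, nrow(centers))
  ch <- nd[nd$parent > 0, ]
  pa <- nd[match(ch$parent, nd$id), ]
  for (s in seq_len(nrow(ch))) {
    a <- c(pa$x[s], pa$y[s], pa$z[s])
    b <- c(ch$x[s], ch$y[s], ch$z[s])
    r <- max(ch$radius[s], pa$radius[s], r_floor)
    d <- b - a
    len2 <- sum(d^2)
    pm <- as.matrix(centers)
    t <- if (len2 > 0)
      pmin(1, pmax(0, ((pm[, 1] - a[1]) * d[1] + (pm[, 2] - a[2]) * d[2] +
                         (pm[, 3] - a[3]) * d[3]) / len2))
    else 0
    q <- cbind(a[1] + t * d[1] - pm[, 1], a[2] + t * d[2] - pm[, 2],
               a[3] + t * d[3] - pm[, 3])
    inside <- inside | rowSums(q^2) <= r^2
  }
  sum(inside)
}

# cached segmentation of the desk scene (used by several files)
desk_labels <- function() fixture("desk_labels", function() {
  semi_supervised_segment(desk_scene()$stack)
})

# the 5-session denervation/regrowth timeline used for end-to-end checks
sni_timeline_config <- function(seed = 11L) {
  ch_den <- list(removal_frac = c(thin = 1, thick = 1), regrowth_frac = 0,
                 epidermal_entry = FALSE, deformation_amplitude = 3)
  ch_half <- list(removal_frac = c(thin = 0, thick = 0),
                  regrowth_frac = 0.5, epidermal_entry = FALSE,
                  deformation_amplitude = 3, jitter = 1)
  ch_full <- list(removal_frac = c(thin = 0, thick = 0),
                  regrowth_frac = 1, epidermal_entry = FALSE,
                  deformation_amplitude = 3, jitter = 1)
  ch_hold <- list(removal_frac = c(thin = 0, thick = 0),
                  regrowth_frac = 0, epidermal_entry = FALSE,
                  deformation_amplitude = 3)
  pipeline_config(
    sessions = list(list(type = "simulate"),
                    list(type = "simulate", change = ch_den),
                    list(type = "simulate", change = ch_half),
                    list(type = "simulate", change = ch_full),
                    list(type = "simulate", change = ch_hold)),
    seed = seed)
}

# cached end-to-end result of the 5-session timeline
sni_result <- function() fixture("sni_result", function() {
  suppressWarnings(run_pipeline(sni_timeline_config(11L)))
})
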