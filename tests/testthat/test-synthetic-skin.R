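test_that("fiber forest generation is deterministic and well-formed", {
  cfg <- desk_config()
  sk1 <- generate_fiber_tree(cfg, 42)
  sk2 <- generate_fiber_tree(cfg, 42)
  expect_identical(sk1, sk2)
  sk3 <- generate_fiber_tree(cfg, 43)
  expect_false(identical(sk1$nodes, sk3$nodes))

  nd <- sk1$nodes
  expect_true(all(nd$radius > 0))
  ext <- (cfg$volume_dims - 1) * cfg$voxel_size
  expect_true(all(nd$x >= 0 & nd$x <= ext[1]))
  expect_true(all(nd$z >= 0 & nd$z <= ext[3]))
  expect_identical(nd$epidermal, nd$z < sk1$boundary_z)
  # forest: every non-root parent exists, no cycles (parents precede kids)
  ch <- nd[nd$parent > 0, ]
  expect_true(all(ch$parent %in% nd$id))
  expect_true(all(ch$parent < ch$id))
  # thin trees reach the epidermis, thick trees stay below the boundary
  expect_gt(sum(nd$epidermal & nd$caliber == "thin"), 0)
  expect_equal(sum(nd$epidermal & nd$caliber == "thick"), 0)
})

test_that("empty configuration produces an empty skeleton", {
  cfg <- desk_config(n_trees = c(thin = 0L, thick = 0L))
  sk <- generate_fiber_tree(cfg, 1)
  expect_equal(nrow(sk$nodes), 0)
  expect_equal(skeleton_total_length(sk), 0)
})

test_that("total centerline length matches the brute-force segment sum", {
  sk <- desk_scene()$skeleton
  expect_equal(skeleton_total_length(sk), oracle_skeleton_length(sk))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(radii = list(thin = c(0.5, 1.3),
                                              thick = c(1.2, 1.8))),
               "thin radius")
  expect_error(simulation_config(volume_dims = c(0, 10, 10)), "positive")
  expect_error(simulation_config(
    epidermal_band = list(z_range = c(0, 500), intensity = 1)), "z extent")
})

test_that("rendering composes fibers, band, gain and noise as specified", {
  # empty skeleton + no autofluorescence + no noise -> uniform background
  cfg0 <- desk_config(volume_dims = c(48L, 48L, 16L),
                      n_trees = c(thin = 0L, thick = 0L),
                      epidermal_band = list(z_range = c(0, 5), intensity = 0),
                      appendage_density = 0,
                      noise = list(poisson_scale = 0, gauss_sd = 0,
                                   offset = 300),
                      depth_gain = 1)
  sk0 <- generate_fiber_tree(cfg0, 1)
  r0 <- render_stack(sk0, cfg0, 1)
  expect_equal(unique(as.numeric(r0$stack$data)), 300)
  expect_true(all(r0$labels == 0L))

  # centerline voxels are brighter than voxels far from every fiber
  sc <- straight_tube_scene()
  r <- render_stack(sc$skeleton, sc$config, 1)
  nd <- sc$skeleton$nodes
  ctr_idx <- cbind(round(nd$x / 0.427) + 1, round(nd$y / 0.427) + 1,
                   round(nd$z / 1) + 1)
  far <- r$stack$data[, 40:60, 25:30]   # >3 radii from the tube
  expect_gt(min(r$stack$data[ctr_idx]), max(far))
})

test_that("depth gain follows the configured linear ramp", {
  cfg <- simulation_config(
    volume_dims = c(128L, 32L, 40L), n_trees = c(thin = 0L, thick = 0L),
    epidermal_band = list(z_range = c(0, 5), intensity = 0),
    appendage_density = 0,
    noise = list(poisson_scale = 0, gauss_sd = 0, offset = 0),
    depth_gain = 3)
  ext <- (cfg$volume_dims - 1) * cfg$voxel_size
  mk <- function(z) data.frame(id = 1:60, x = seq(5, 45, length.out = 60),
                               y = 6.8, z = z, radius = 0.8,
                               parent = c(0L, 1:59), tree_id = 1L,
                               caliber = "thin", epidermal = FALSE)
  shallow_z <- 8; deep_z <- 32
  sk <- skin_skeleton(rbind(mk(shallow_z),
                            transform(mk(deep_z), id = id + 100,
                                      parent = ifelse(parent == 0, 0,
                                                      parent + 100),
                                      tree_id = 2)),
                      boundary_z = 5, extent = ext)
  r <- render_stack(sk, cfg, 1)
  v <- r$stack$data
  shallow_mean <- mean(v[30:90, 17, shallow_z + 1])
  deep_mean <- mean(v[30:90, 17, deep_z + 1])
  gain <- depth_gain_profile(cfg$volume_dims[3], 3)
  expected <- gain[deep_z + 1] / gain[shallow_z + 1]
  expect_lt(abs(deep_mean / shallow_mean - expected) / expected, 0.05)
})

test_that("rasterized fiber voxels match the brute-force point-in-tube count", {
  cfg <- simulation_config(
    volume_dims = c(48L, 48L, 24L), n_trees = c(thin = 1L, thick = 1L),
    branching = list(mean_branches = 1, angle_sd = 20, tortuosity = 0.1,
                     step = 1.5, branch_len = c(8, 15)),
    epidermal_band = list(z_range = c(0, 4), intensity = 0),
    appendage_density = 0,
    noise = list(poisson_scale = 0, gauss_sd = 0, offset = 100))
  sk <- generate_fiber_tree(cfg, 3)
  r <- render_stack(sk, cfg, 3)
  expect_equal(sum(r$labels == 1L),
               oracle_tube_voxels(sk, cfg$volume_dims, cfg$voxel_size))
})

test_that("quadrant tiles share the overlap and recompose the parent exactly", {
  sc <- desk_scene()
  ts <- make_quadrant_tiles(sc$stack, 24L)
  expect_equal(unname(ts$tile_dims[1:2]), c(140, 140))
  # geometry [PAPER]: 2000-px canvas with 100-px overlap gives 1050-px tiles
  big <- image_stack(array(0, c(2000, 2000, 1)))
  tb <- make_quadrant_tiles(big, 100L)
  expect_equal(unname(tb$tile_dims[1:2]), c(1050, 1050))
  tb0 <- make_quadrant_tiles(big, 0L)
  expect_equal(unname(tb0$tile_dims[1:2]), c(1000, 1000))
  expect_error(make_quadrant_tiles(image_stack(array(0, c(101, 101, 1))),
                                   24L), "2\\*W")

  # recomposition at true offsets is bit-exact; overlap coverage is 1 or 2
  d <- dim(sc$stack$data)
  canvas <- array(NA_real_, d)
  cover <- array(0L, d[1:2])
  for (nm in rownames(ts$offsets)) {
    o <- ts$offsets[nm, ]
    ix <- o[1] + seq_len(ts$tile_dims[1])
    iy <- o[2] + seq_len(ts$tile_dims[2])
    canvas[ix, iy, ] <- ts$tiles[[nm]]$data
    cover[ix, iy] <- cover[ix, iy] + 1L
  }
  expect_identical(canvas, sc$stack$data)
  expect_true(all(cover >= 1L & cover <= 4L))
  # strictly one outside all overlap strips
  expect_equal(cover[1, 1], 1L)
  expect_equal(max(cover), 4L)  # centre corner overlap
})

test_that("longitudinal change removes, regrows and truncates as requested", {
  cfg <- desk_config()
  sc0 <- scene_baseline(cfg, 42)
  base_len <- skeleton_total_length(sc0$skeleton)

  # full removal, no regrowth -> empty skeleton
  den <- apply_longitudinal_change(sc0, list(
    removal_frac = c(thin = 1, thick = 1), regrowth_frac = 0), seed = 2)
  expect_equal(nrow(den$skeleton$nodes), 0)
  expect_equal(den$session_label, 2L)

  # fractions outside [0, 1] rejected
  expect_error(apply_longitudinal_change(sc0, list(
    removal_frac = c(thin = 1.2, thick = 0))), "\\[0, 1\\]")

  # regrowth without epidermal entry leaves no epidermal nodes
  reg <- apply_longitudinal_change(den, list(
    removal_frac = c(thin = 0, thick = 0), regrowth_frac = 1,
    epidermal_entry = FALSE, jitter = 1), seed = 3)
  expect_gt(nrow(reg$skeleton$nodes), 0)
  expect_equal(sum(reg$skeleton$nodes$epidermal), 0)
  expect_true(all(reg$skeleton$nodes$caliber == "thin"))

  # regrown centerlines retrace baseline trajectories within the jitter
  nd <- reg$skeleton$nodes
  base_nd <- sc0$skeleton$nodes
  for (tid in unique(nd$tree_id)) {
    p <- as.matrix(nd[nd$tree_id == tid, c("x", "y", "z")])
    q <- as.matrix(base_nd[base_nd$tree_id == tid, c("x", "y", "z")])
    nn <- apply(p, 1, function(pt)
      min(sqrt(colSums((t(q) - pt)^2))))
    expect_lt(max(nn), 1 + 1e-9)   # jitter bound: 0.6 + 0.4 of 1 um
  }
})

test_that("scene deformation is smooth, bounded and composable", {
  cfg <- desk_config()
  sc0 <- scene_baseline(cfg, 7)
  sc1 <- apply_longitudinal_change(sc0, list(
    removal_frac = c(thin = 0, thick = 0), regrowth_frac = 0,
    deformation_amplitude = 3), seed = 5)
  p <- as.matrix(sc1$skeleton$nodes[, c("x", "y", "z")])
  q <- apply_deformation(p, sc1$deformation)
  disp <- sqrt(rowSums((q - p)^2))
  expect_gt(max(disp), 0.5)      # deformation actually moves the scene
  expect_lt(max(disp), 25)       # small rigid + 3 um elastic stays bounded
  dsk <- deformed_skeleton(sc1)
  expect_equal(nrow(dsk$nodes), nrow(sc1$skeleton$nodes))
})

test_that("stack and skeleton I/O round-trip through TIFF, SWC and CSV", {
  dir <- withr::local_tempdir()
  sc <- desk_scene()
  p <- file.path(dir, "stack.tif")
  write_stack(sc$stack, p, meta = list(seed = 42))
  back <- read_stack(p)
  expect_equal(back$data, sc$stack$data)
  expect_equal(back$voxel_size, sc$stack$voxel_size)

  lp <- file.path(dir, "labels.tif")
  write_label_volume(sc$labels, lp)
  expect_identical(read_label_volume(lp), sc$labels + 0L)

  sp <- file.path(dir, "skel.swc")
  write_swc(sc$skeleton, sp)
  sk2 <- read_swc(sp, boundary_z = sc$skeleton$boundary_z,
                  extent = sc$skeleton$extent)
  expect_equal(sk2$nodes$x, sc$skeleton$nodes$x, tolerance = 1e-6)
  expect_equal(sk2$nodes$caliber, sc$skeleton$nodes$caliber)
  expect_equal(sk2$nodes$epidermal, sc$skeleton$nodes$epidermal)
  expect_equal(skeleton_total_length(sk2), skeleton_total_length(sc$skeleton),
               tolerance = 1e-6)

  g <- skeleton_to_graph(sc$skeleton)
  gp <- file.path(dir, "graph")
  write_fiber_graph(g, gp)
  g2 <- read_fiber_graph(gp)
  expect_equal(g2$nodes$x, g$nodes$x, tolerance = 1e-6)
  expect_equal(g2$edges$from, g$edges$from)
  expect_equal(g2$edges$to, g$edges$to)
  expect_equal(sum(g2$edges$length), sum(g$edges$length), tolerance = 1e-6)
})
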