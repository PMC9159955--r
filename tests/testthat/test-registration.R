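fiber_cloud <- function(seed = 42) {
  sk <- generate_fiber_tree(desk_config(), seed)
  as.matrix(sk$nodes[, c("x", "y", "z")])
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

test_that("point clouds use the physical coordinate convention", {
  st <- image_stack(array(0, c(16, 16, 8)))
  st$data[5, 9, 3] <- 255
  pc <- extract_point_cloud(st, threshold = 10)
  expect_false(pc$empty)
  expect_equal(unname(pc$points[1, ]), c(4 * 0.427, 8 * 0.427, 2))

  empty <- extract_point_cloud(image_stack(array(0, c(8, 8, 4))),
                               threshold = 10)
  expect_true(empty$empty)
  expect_equal(nrow(empty$points), 0)
})

test_that("cloud from a noiseless render stays within one voxel of the tubes", {
  sc <- straight_tube_scene()
  r <- render_stack(sc$skeleton, sc$config, 1)
  pc <- extract_point_cloud(image_stack(r$stack$data,
                                        voxel_size = sc$config$voxel_size),
                            threshold = 4000)
  nd <- sc$skeleton$nodes
  # distance of each cloud point to the tube centerline (axis-aligned tube
  # along x at fixed y, z)
  d <- sqrt((pc$points[, 2] - nd$y[1])^2 + (pc$points[, 3] - nd$z[1])^2)
  r_eff <- 0.5  # effective raster radius floor
  expect_lt(max(d), r_eff + sqrt(sum((c(0.427, 0.427, 1))^2)))
})

test_that("trimmed ICP recovers known rigid motions", {
  pts <- fiber_cloud()
  # identity
  res0 <- icp_rigid(pts, pts)
  expect_lt(res0$residual, 1e-6)
  expect_lt(rotation_angle_deg(res0$transform$R), 1e-3)

  # 5 degree / 10 um motion recovered to 0.1 deg / 0.1 um
  Tt <- rigid_transform(rot_z(5), c(10, 4, -3))
  res <- icp_rigid(pts, rigid_apply(Tt, pts))
  expect_lt(rotation_angle_deg(t(res$transform$R) %*% Tt$R), 0.1)
  expect_lt(sqrt(sum((res$transform$t - Tt$t)^2)), 0.1)

  # recorded residual history is non-increasing
  expect_true(all(diff(res$residual_history) <= 1e-9))

  # collinear cloud: translation-only fallback with a warning
  # (shift perpendicular to the line; motion along it is unobservable)
  line <- cbind(seq(0, 50, by = 0.5), 0, 0)
  expect_warning(res_l <- icp_rigid(line, line + rep(c(0, 2, 0), each = nrow(line))),
                 "degenerate")
  expect_lt(abs(res_l$transform$t[2] - 2), 0.5)
})

test_that("rigid recovery tolerates jitter and missing points", {
  pts <- fiber_cloud()
  errs_rot <- c(); errs_t <- c()
  for (sd in 1:20) {
    Tt <- with_seed(sd, rigid_transform(rot_z(runif(1, -4, 4)),
                                        runif(3, -8, 8)))
    moved <- rigid_apply(Tt, pts)
    moved <- with_seed(sd + 100, {
      keep <- sample(nrow(moved), round(0.8 * nrow(moved)))
      moved[keep, ] + matrix(rnorm(3 * length(keep), 0,
                                   0.427 / sqrt(3)), ncol = 3)
    })
    res <- icp_rigid(moved, pts)   # align jittered subset back
    inv <- rigid_invert(res$transform)
    errs_rot <- c(errs_rot, rotation_angle_deg(t(inv$R) %*% Tt$R))
    errs_t <- c(errs_t, sqrt(sum((inv$t - Tt$t)^2)))
  }
  expect_lt(median(errs_rot), 1)
  expect_lt(median(errs_t), 1)
})

test_that("registering A to B and B to A gives mutually inverse transforms", {
  pts <- fiber_cloud()
  Tt <- rigid_transform(rot_z(3), c(5, -2, 1))
  moved <- rigid_apply(Tt, pts)
  ab <- icp_rigid(pts, moved)$transform
  ba <- icp_rigid(moved, pts)$transform
  comp <- rigid_compose(ab, ba)
  expect_lt(rotation_angle_deg(comp$R), 0.2)
  expect_lt(sqrt(sum(comp$t^2)), 0.3)
})

test_that("thin-plate splines interpolate, reproduce affine maps and shrink to affine", {
  set.seed(5)
  src <- matrix(runif(45, 0, 100), 15, 3)
  dst <- src + matrix(rnorm(45, 0, 3), 15, 3)
  tw <- tps_fit(src, dst, 0)
  expect_lt(max(abs(tps_apply(tw, src) - dst)), 1e-6)

  A <- matrix(c(1.1, .1, 0, -.05, .95, .02, 0, .03, 1.02), 3, 3)
  b <- c(3, -2, 1)
  dstA <- src %*% A + rep(1, 15) %o% b
  twA <- tps_fit(src, dstA, 0)
  grid <- matrix(runif(60, 10, 90), 20, 3)
  expect_lt(max(abs(tps_apply(twA, grid) - (grid %*% A + rep(1, 20) %o% b))),
            1e-6)

  # lambda -> large approaches the least-squares affine fit
  twL <- tps_fit(src, dst, 1e6)
  aff <- lm.fit(cbind(1, src), dst)
  expect_lt(max(abs(tps_apply(twL, grid) - cbind(1, grid) %*% aff$coefficients)),
            0.01)

  # coplanar landmarks are rejected
  flat <- cbind(src[, 1:2], 5)
  expect_error(tps_fit(flat, flat + 1, 0), "coplanar")
  expect_error(tps_fit(src[1:3, ], dst[1:3, ], 0), "at least 4")
})

test_that("composed ICP+TPS recovers simulated deformations", {
  cfg <- desk_config()
  sc1 <- scene_baseline(cfg, derive_seed(11, "simulate1"))
  r1 <- render_stack(deformed_skeleton(sc1), cfg, derive_seed(11, "render1"))
  lab1 <- semi_supervised_segment(r1$stack)
  s8a <- depth_adaptive_convert(remove_autofluorescence(r1$stack, lab1))
  pca <- extract_point_cloud(s8a, mask = lab1 == 1L)
  ch <- list(removal_frac = c(thin = 0.3, thick = 0.3), regrowth_frac = 0,
             deformation_amplitude = 3)
  sc2 <- apply_longitudinal_change(sc1, ch, derive_seed(11, "simulate2"))
  r2 <- render_stack(deformed_skeleton(sc2), cfg, derive_seed(11, "render2"))
  lab2 <- semi_supervised_segment(r2$stack)
  s8b <- depth_adaptive_convert(remove_autofluorescence(r2$stack, lab2))
  pcb <- extract_point_cloud(s8b, mask = lab2 == 1L)
  tr <- register_session(pcb, pca)
  expect_false(isTRUE(attr(tr, "rejected")))
  nd2 <- deformed_skeleton(sc2)$nodes
  nd1 <- deformed_skeleton(sc1)$nodes
  common <- intersect(nd2$id, nd1$id)
  p2 <- as.matrix(nd2[match(common, nd2$id), c("x", "y", "z")])
  p1 <- as.matrix(nd1[match(common, nd1$id), c("x", "y", "z")])
  err <- sqrt(rowSums((transform_points(tr, p2) - p1)^2))
  expect_lt(median(err), 2)
})

test_that("common-volume cropping follows box arithmetic", {
  st <- image_stack(array(runif(32 * 32 * 8), c(32, 32, 8)),
                    voxel_size = c(1, 1, 1))
  # identity transforms: common box is the full volume
  cr <- crop_common_volume(list(st, st),
                           list(rigid_transform(), rigid_transform()))
  expect_equal(unname(cr$box["hi", ] - cr$box["lo", ]), c(31, 31, 7))
  expect_equal(dim(cr$stacks[[1]]$data), dim(cr$stacks[[2]]$data))

  # a d-um x translation shrinks the common x extent by exactly d
  d <- 5
  cr2 <- crop_common_volume(list(st, st),
                            list(rigid_transform(),
                                 rigid_transform(diag(3), c(d, 0, 0))))
  expect_equal(unname(cr2$box["hi", 1] - cr2$box["lo", 1]), 31 - d)
  expect_equal(dim(cr2$stacks[[1]]$data), dim(cr2$stacks[[2]]$data))

  # disjoint volumes error naming the session
  expect_error(crop_common_volume(list(st, st),
                                  list(rigid_transform(),
                                       rigid_transform(diag(3), c(500, 0, 0)))),
               "session")
})

test_that("transforms serialize to JSON and back", {
  dir <- withr::local_tempdir()
  src <- matrix(runif(45, 0, 100), 15, 3)
  dst <- src + matrix(rnorm(45, 0, 2), 15, 3)
  tr <- session_transform(rigid_transform(rot_z(2), c(1, 2, 3)),
                          tps_fit(src, dst, 0.5), tps_fit(dst, src, 0.5))
  p <- file.path(dir, "xform.json")
  write_transform(tr, p)
  back <- read_transform(p)
  pts <- matrix(runif(30, 0, 100), 10, 3)
  expect_equal(transform_points(back, pts), transform_points(tr, pts),
               tolerance = 1e-6)
})
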