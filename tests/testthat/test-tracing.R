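test_that("a straight tube traces to one component with correct length and endings", {
  sc <- straight_tube_scene()
  r <- render_stack(sc$skeleton, sc$config, 1)
  g <- trace_fibers(r$stack)
  expect_equal(nrow(g$components), 1)
  expect_lt(abs(sum(g$edges$length) - 100) / 100, 0.05)
  expect_equal(sum(g$nodes$degree == 1), 2)
})

test_that("a dark gap within bridging reach is closed into one component", {
  sc <- straight_tube_scene()
  r <- render_stack(sc$skeleton, sc$config, 1)
  gap <- r$stack
  gx <- round(c(50, 53) / 0.427)
  gap$data[gx[1]:gx[2], , ] <- 100
  g <- trace_fibers(gap)
  expect_equal(length(unique(g$nodes$component)), 1)
  br <- attr(g, "bridges")
  expect_gte(length(br), 1)
})

test_that("bridges obey the distance and collinearity limits", {
  sc <- straight_tube_scene()
  r <- render_stack(sc$skeleton, sc$config, 1)
  gap <- r$stack
  gx <- round(c(50, 53) / 0.427)
  gap$data[gx[1]:gx[2], , ] <- 100
  pars <- trace_params(g_max = 5, cone_half_angle = 30)
  g <- trace_fibers(gap, pars)
  for (b in attr(g, "bridges")) {
    p <- g$paths[[b]]
    expect_lte(polyline_length(p), pars$g_max + 1e-9)
  }
  # a gap wider than g_max stays open
  wide <- r$stack
  wx <- round(c(45, 53) / 0.427)
  wide$data[wx[1]:wx[2], , ] <- 100
  g2 <- trace_fibers(wide, trace_params(g_max = 2))
  expect_gt(length(unique(g2$nodes$component)), 1)
})

test_that("empty stacks give empty graphs", {
  st <- image_stack(array(100, c(32, 32, 8)))
  g <- trace_fibers(st)
  expect_equal(nrow(g$nodes), 0)
  expect_true(isTRUE(attr(g, "empty")))
})

test_that("tracing is deterministic", {
  sc <- desk_scene()
  lab <- semi_supervised_segment(sc$stack)
  st <- remove_autofluorescence(sc$stack, lab)
  g1 <- trace_fibers(st, mask = lab == 1L)
  g2 <- trace_fibers(st, mask = lab == 1L)
  expect_identical(g1, g2)
})

test_that("traced total length matches ground truth on noiseless renders", {
  cfg <- clean_scene()$config
  sk <- clean_scene()$skeleton
  r <- clean_scene()
  g <- trace_fibers(depth_adaptive_convert(r$stack))
  gt <- skeleton_total_length(sk)
  expect_lt(abs(sum(g$edges$length) - gt) / gt, 0.05)
})

test_that("graph length equals the voxel-step sum without smoothing", {
  sc <- straight_tube_scene()
  r <- render_stack(sc$skeleton, sc$config, 1)
  g <- trace_fibers(r$stack, trace_params(smooth_window = 1L))
  step_sum <- sum(vapply(g$paths, function(p)
    sum(sqrt(rowSums(diff(p)^2))), 0))
  expect_lt(abs(sum(g$edges$length) - step_sum) / step_sum, 0.02)
  # arc length always bounds the chord
  for (i in seq_len(nrow(g$edges))) {
    p <- g$paths[[i]]
    chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    expect_gte(g$edges$length[i] + 1e-9, chord)
  }
})

test_that("caliber classification separates thin and thick tubes", {
  sc <- straight_tube_scene(radius = 0.3, caliber = "thin", y_um = 13)
  nd2 <- sc$skeleton$nodes
  nd2$radius <- 1.5
  nd2$caliber <- "thick"
  nd2$y <- 20
  nd2$tree_id <- 2L
  nd2$id <- nd2$id + 200L
  nd2$parent <- ifelse(nd2$parent == 0, 0L, nd2$parent + 200L)
  sk <- skin_skeleton(rbind(sc$skeleton$nodes, nd2), 5,
                      sc$skeleton$extent)
  r <- render_stack(sk, sc$config, 1)
  g <- classify_fiber_caliber(trace_fibers(r$stack), radius_threshold = 0.8)
  expect_equal(nrow(g$components), 2)
  # identify by mean y of each component
  ys <- vapply(g$components$component, function(cid)
    mean(do.call(rbind, g$paths[g$edges$component == cid])[, 2]), 0)
  expect_equal(g$components$caliber[order(ys)], c("thin", "thick"))

  # documented tie-break: radius exactly at the threshold is thick
  gg <- g
  gg$edges$radius <- 0.8
  gg <- classify_fiber_caliber(gg, radius_threshold = 0.8)
  expect_true(all(gg$components$caliber == "thick"))
  # all radii below -> all thin
  gg$edges$radius <- 0.2
  gg <- classify_fiber_caliber(gg, radius_threshold = 0.8)
  expect_true(all(gg$components$caliber == "thin"))
})

test_that("mask-only tracing estimates radii from the distance transform", {
  sc <- straight_tube_scene(radius = 1.5, caliber = "thick")
  r <- render_stack(sc$skeleton, sc$config, 1)
  mask <- r$labels == 1L
  g <- trace_fibers(mask, voxel_size = sc$config$voxel_size)
  expect_gt(nrow(g$edges), 0)
  expect_true(all(is.finite(g$edges$radius)))
  expect_gt(median(g$edges$radius), 0.8)
})
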