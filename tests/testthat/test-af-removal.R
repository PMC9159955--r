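blob_volume <- function() {
  # two homogeneous bright blobs on dark background, well separated
  d <- c(40L, 40L, 16L)
  v <- array(200, d)
  v[6:16, 6:16, 4:10] <- 12000
  v[24:36, 24:36, 6:12] <- 9000
  image_stack(v, voxel_size = c(0.427, 0.427, 1))
}

test_that("seed labels propagate across homogeneous blobs", {
  st <- blob_volume()
  seeds <- array(-1L, dim(st$data))
  seeds[10, 10, 6] <- 1L     # fiber seed in blob 1
  seeds[30, 30, 8] <- 2L     # autofluorescence seed in blob 2
  seeds[2, 2, 2] <- 0L       # background seed
  lab <- semi_supervised_segment(st, seeds,
                                 segmentation_params(downsample = c(1L, 1L, 1L)))
  expect_true(all(lab[7:15, 7:15, 5:9] == 1L))
  expect_true(all(lab[25:35, 25:35, 7:11] == 2L))
})

test_that("fully seeded volumes are returned unchanged and seeds are kept", {
  st <- blob_volume()
  seeds <- array(0L, dim(st$data))
  seeds[6:16, 6:16, 4:10] <- 3L
  lab <- semi_supervised_segment(st, seeds,
                                 segmentation_params(downsample = c(1L, 1L, 1L)))
  expect_identical(lab + 0L, seeds + 0L)

  # sparse seeds always keep their label
  seeds2 <- array(-1L, dim(st$data))
  seeds2[10, 10, 6] <- 2L
  seeds2[2, 2, 2] <- 0L
  lab2 <- semi_supervised_segment(st, seeds2,
                                  segmentation_params(downsample = c(1L, 1L, 1L)))
  expect_equal(lab2[10, 10, 6], 2L)
  expect_equal(lab2[2, 2, 2], 0L)
})

test_that("seed validation rejects empty or out-of-range label sets", {
  st <- blob_volume()
  empty <- array(-1L, dim(st$data))
  expect_error(semi_supervised_segment(st, empty), "seeding error")
  bad <- empty; bad[1, 1, 1] <- 7L
  expect_error(semi_supervised_segment(st, bad), "label error")
})

test_that("every voxel receives exactly one class", {
  sc <- desk_scene()
  lab <- semi_supervised_segment(sc$stack)
  expect_true(all(lab %in% 0:3))
  expect_equal(sum(table(factor(lab, 0:3))), prod(dim(sc$stack$data)))
})

test_that("fiber segmentation reaches the target quality on simulated scenes", {
  sc <- desk_scene()
  lab <- semi_supervised_segment(sc$stack)
  gt <- sc$labels
  pred_f <- lab == 1L
  gt_f <- gt == 1L
  precision <- sum(pred_f & gt_f) / sum(pred_f)
  recall <- sum(pred_f & gt_f) / sum(gt_f)
  expect_gte(precision, 0.90)
  expect_gte(recall, 0.90)
})

test_that("diffusion smoothing is edge-preserving and total-variation monotone", {
  # identity cases
  v <- array(runif(6 * 6 * 4), c(6, 6, 4))
  expect_identical(diffusion_smooth(v, list(conductance = 0.2, step = 0.15,
                                            iterations = 0L)), v)
  cv <- array(0.4, c(6, 6, 4))
  expect_equal(diffusion_smooth(cv, list(conductance = 0.2, step = 0.15,
                                         iterations = 25L)), cv,
               tolerance = 1e-12)

  # noisy step edge: variance drops, edge stays put
  set.seed(4)
  d <- c(40L, 20L, 8L)
  step_v <- array(0, d)
  step_v[21:40, , ] <- 1
  noisy <- step_v + array(rnorm(prod(d), 0, 0.12), d)
  sm <- diffusion_smooth(noisy, list(conductance = 0.35, step = 0.15,
                                     iterations = 15L))
  expect_lt(var(as.numeric(sm[1:16, , ])), var(as.numeric(noisy[1:16, , ])))
  expect_lt(var(as.numeric(sm[25:40, , ])), var(as.numeric(noisy[25:40, , ])))
  prof_n <- rowMeans(noisy[, , 4])
  prof_s <- rowMeans(sm[, , 4])
  cross <- function(p) which(p >= 0.5)[1]
  expect_lt(abs(cross(prof_s) - cross(prof_n)), 2)

  # total variation never increases
  tv <- function(a) {
    sum(abs(diff(a))) + sum(abs(apply(a, c(1, 3), diff))) +
      sum(abs(apply(a, c(1, 2), diff)))
  }
  cur <- noisy
  for (it in 1:4) {
    nxt <- diffusion_smooth(cur, list(conductance = 0.35, step = 0.15,
                                      iterations = 3L))
    expect_lte(tv(nxt), tv(cur) + 1e-9)
    cur <- nxt
  }
})

test_that("autofluorescence removal clears the band but spares fibers", {
  sc <- desk_scene()
  st <- sc$stack

  # labels all fiber -> untouched; labels all autofluorescence -> flattened
  all_fiber <- array(1L, dim(st$data))
  expect_identical(remove_autofluorescence(st, all_fiber)$data, st$data)
  all_af <- array(2L, dim(st$data))
  flat <- remove_autofluorescence(st, all_af)
  expect_equal(length(unique(round(apply(flat$data, 3, mean)))),
               length(unique(round(apply(flat$data, 3, median)))))
  expect_error(remove_autofluorescence(st, array(0L, c(2, 2, 2))),
               "dims")

  # simulator scene: band removed, fiber intensities retained
  lab <- semi_supervised_segment(st)
  cleaned <- remove_autofluorescence(st, lab)
  gt <- sc$labels
  af_gt <- gt == 2L | gt == 3L
  removed <- cleaned$data != st$data
  expect_gte(sum(af_gt & removed) / sum(af_gt), 0.95)
  fib_gt <- gt == 1L
  expect_gte(sum(fib_gt & !removed) / sum(fib_gt), 0.95)
})
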