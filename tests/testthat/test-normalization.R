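test_that("conversion handles degenerate and scaled inputs", {
  cs <- image_stack(array(500, c(8, 8, 4)), bit_depth = 16L)
  out <- depth_adaptive_convert(cs)
  expect_equal(length(unique(as.numeric(out$data))), 1)
  expect_equal(out$bit_depth, 8L)
  zs <- image_stack(array(0, c(8, 8, 4)), bit_depth = 16L)
  expect_true(all(depth_adaptive_convert(zs)$data == 0))
  expect_error(depth_adaptive_convert(
    image_stack(array(1, c(4, 4, 2)), bit_depth = 8L)), "16-bit")

  # two stacks identical up to one global multiplicative gain convert
  # identically
  sc <- desk_scene()
  s8 <- depth_adaptive_convert(sc$stack)
  gained <- sc$stack
  gained$data <- gained$data * 1.7
  s8b <- depth_adaptive_convert(gained)
  expect_identical(s8$data, s8b$data)
})

test_that("conversion output spans [0, 255], is monotone within slices and idempotent", {
  sc <- desk_scene()
  s8 <- depth_adaptive_convert(sc$stack)
  expect_equal(range(s8$data), c(0, 255))

  # monotone: per slice, order of any two voxels is preserved
  for (z in c(1, 20, 50)) {
    a <- as.numeric(sc$stack$data[, , z])
    b <- as.numeric(s8$data[, , z])
    ord <- order(a)
    expect_true(all(diff(b[ord]) >= 0))
  }

  # idempotence: re-expressed as 16-bit and re-converted, within 1 grey
  re16 <- image_stack(s8$data * 257, voxel_size = s8$voxel_size,
                      bit_depth = 16L)
  s8c <- depth_adaptive_convert(re16)
  expect_lte(max(abs(s8c$data - s8$data)), 1)
})

test_that("depth gain fitting flattens the excitation ramp", {
  sc <- desk_scene()
  # clean the band first: gain fit is designed for cleaned stacks
  lab <- semi_supervised_segment(sc$stack)
  cl <- remove_autofluorescence(sc$stack, lab)
  s8 <- depth_adaptive_convert(cl)
  conv <- attr(s8, "conversion")
  # the simulator ramps 1 -> 3; the fitted gain must rise substantially
  expect_gt(max(conv$gain) / min(conv$gain), 1.8)
})

test_that("cross-session normalization aligns foreground intensities", {
  sc <- desk_scene()
  single <- cross_session_normalize(list(sc$stack))
  expect_length(single, 1)
  dup <- cross_session_normalize(list(sc$stack, sc$stack))
  expect_identical(dup[[1]]$data, dup[[2]]$data)

  gained <- sc$stack
  gained$data <- gained$data * 2
  out <- cross_session_normalize(list(sc$stack, gained))
  med_fg <- vapply(out, function(s) {
    v <- as.numeric(s$data)
    thr <- skintrace:::otsu_threshold(v)
    median(v[v > thr])
  }, 0)
  expect_lt(abs(med_fg[2] - med_fg[1]) / med_fg[1], 0.05)
})
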