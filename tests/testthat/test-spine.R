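# shared small phantom + stack (straight spine, edges at columns 68/124)
spine_fix <- function() cached("spine_fix", {
  truth <- phantom_generate(small_phantom_spec(seed = 3L))
  stack <- apply_bank(truth$image, build_bank())
  list(truth = truth, stack = stack, g = compute_spine_gfi(stack))
})

test_that("banded_cumulative matches hand-computed prefix sums", {
  g <- matrix(1:25, 5, 5)          # column-major: col j holds 5j-4..5j
  # p = 3 -> central rows 2..4 of each column
  want <- cumsum(sapply(1:5, function(j) sum(g[2:4, j])))
  expect_equal(banded_cumulative(g, 3L), want)
  # full-band prefix ends at the total sum
  expect_equal(banded_cumulative(g, 5L)[5], sum(g))
  # all-zero input -> all-zero output
  expect_equal(banded_cumulative(matrix(0, 4, 6), 2L), rep(0, 6))
  expect_error(banded_cumulative(g, 9L), "out of range")
})

test_that("banded_cumulative is nondecreasing for nonnegative inputs", {
  set.seed(77)
  for (rep in 1:100) {
    g <- matrix(rexp(12 * 8), 12, 8)
    p <- sample(1:12, 1)
    expect_true(all(diff(banded_cumulative(g, p)) >= -1e-12))
  }
})

test_that("find_centers locates the spine center and edge crossings", {
  fx <- spine_fix()
  cen <- find_centers(fx$g)
  lt <- fx$truth$spine_left[fx$truth$spec$image_size[1] %/% 2]
  rt <- fx$truth$spine_right[fx$truth$spec$image_size[1] %/% 2]
  expect_gte(cen$center_col, lt)
  expect_lte(cen$center_col, rt)
  expect_lt(abs(cen$left_center[["col"]] - lt), 4)
  expect_lt(abs(cen$right_center[["col"]] - rt), 4)
  expect_true(all(diff(cen$G_cum) >= 0))
})

test_that("find_centers respects symmetry and rejects blank input", {
  # synthetic symmetric feature image: two vertical ridges at 30 and 70
  g <- matrix(0, 90, 101)
  g[, 30] <- 5; g[, 70] <- 5
  g[, 31] <- 2; g[, 69] <- 2
  cen <- find_centers(g, p = 30L)
  expect_equal(cen$center_col, 50, tolerance = 1)
  expect_equal(unname(cen$left_center["col"]), 30)
  expect_equal(unname(cen$right_center["col"]), 70)
  expect_error(find_centers(matrix(0, 50, 50)),
               class = "discgabor_detection_error")
})

test_that("trace_curves recovers straight edges", {
  fx <- spine_fix()
  cen <- find_centers(fx$g)
  cur <- trace_curves(fx$g, cen)
  vr <- cur$valid_rows[1]:cur$valid_rows[2]
  expect_gt(length(vr), 0.7 * nrow(fx$g))
  rmsL <- sqrt(mean((cur$left[vr] - fx$truth$spine_left[vr])^2))
  rmsR <- sqrt(mean((cur$right[vr] - fx$truth$spine_right[vr])^2))
  expect_lte(rmsL, 2)
  expect_lte(rmsR, 2)
  expect_true(all(cur$left[vr] < cur$right[vr]))
})

test_that("trace_curves tracks a sinusoidally curved spine", {
  truth <- phantom_generate(small_phantom_spec(seed = 9L, curvature_amp = 10))
  stack <- apply_bank(truth$image, build_bank())
  sp <- detect_spine(stack)
  vr <- sp$curves$valid_rows[1]:sp$curves$valid_rows[2]
  rmsL <- sqrt(mean((sp$curves$left[vr] - truth$spine_left[vr])^2))
  rmsR <- sqrt(mean((sp$curves$right[vr] - truth$spine_right[vr])^2))
  expect_lte(rmsL, 3)
  expect_lte(rmsR, 3)
  expect_true(all(sp$curves$left[vr] < sp$curves$right[vr]))
})

test_that("detected curves shift with a translated phantom", {
  base <- phantom_generate(small_phantom_spec(seed = 3L))
  shifted <- phantom_generate(small_phantom_spec(seed = 3L,
                                                 center_col = 96 + 5))
  sp1 <- detect_spine(apply_bank(base$image, build_bank()))
  sp2 <- detect_spine(apply_bank(shifted$image, build_bank()))
  vr <- max(sp1$curves$valid_rows[1], sp2$curves$valid_rows[1]):
    min(sp1$curves$valid_rows[2], sp2$curves$valid_rows[2])
  dL <- mean(sp2$curves$left[vr] - sp1$curves$left[vr])
  dR <- mean(sp2$curves$right[vr] - sp1$curves$right[vr])
  expect_lt(abs(dL - 5), 1)
  expect_lt(abs(dR - 5), 1)
})

test_that("compute_spine_gfi demands 16 directions and is nonnegative", {
  fx <- spine_fix()
  expect_true(all(fx$g >= 0))
  small <- array(runif(4 * 2 * 8 * 8), dim = c(4, 2, 8, 8))
  expect_error(compute_spine_gfi(small), "16-direction")
})
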