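# shared localization fixture on the small phantom
loc_fix <- function() cached("loc_fix", {
  truth <- phantom_generate(small_phantom_spec(seed = 3L))
  stack <- apply_bank(truth$image, build_bank())
  sp <- detect_spine(stack)
  list(truth = truth, stack = stack, curves = sp$curves)
})

test_that("elliptical_median equals the brute-force neighborhood median", {
  set.seed(21)
  img <- matrix(runif(32 * 32), 32, 32)
  la <- 11L; mi <- 5L
  got <- elliptical_median(img, la, mi)
  a <- la / 2; b <- mi / 2
  refl <- function(i, n) { if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i; i }
  for (r in c(1, 2, 7, 16, 32)) for (c in c(1, 9, 20, 32)) {
    vals <- c()
    for (dy in -floor(b):floor(b)) for (dx in -floor(a):floor(a)) {
      if ((dx / a)^2 + (dy / b)^2 <= 1)
        vals <- c(vals, img[refl(r + dy, 32), refl(c + dx, 32)])
    }
    expect_equal(got[r, c], median(vals), tolerance = 1e-12)
  }
  # constant image unchanged; parameter validation
  expect_equal(elliptical_median(matrix(3, 20, 20), 9L, 5L),
               matrix(3, 20, 20))
  expect_error(elliptical_median(img, 5L, 9L), "long_axis")
})

test_that("row_profile sums the band columns per row", {
  g <- matrix(1, 4, 6)
  curves <- structure(list(left = c(2L, 2L, 3L, NA), right = c(5L, 4L, 6L, NA),
                           valid_rows = c(1L, 3L)), class = "spinal_curves")
  expect_equal(row_profile(g, curves), c(4, 3, 4, 0))
  g2 <- matrix(seq_len(24), 4, 6)
  expect_equal(row_profile(g2, curves)[2], g2[2, 2] + g2[2, 3] + g2[2, 4])
  expect_equal(row_profile(matrix(0, 4, 6), curves), rep(0, 4))
})

test_that("candidate_rows finds, merges and filters peaks", {
  # five Gaussian bumps spaced 40 px
  x <- 1:260
  centers <- c(40, 80, 120, 160, 200)
  gh <- rowSums(sapply(centers, function(c0) exp(-(x - c0)^2 / 50)))
  y <- candidate_rows(gh, disc_priors())
  expect_length(y, 5L)
  expect_true(all(abs(sort(y) - centers) <= 1))

  # two bumps 10 px apart merge into one at the weighted mean
  gh2 <- exp(-(x - 100)^2 / 18) + 2 * exp(-(x - 110)^2 / 18)
  y2 <- candidate_rows(gh2, disc_priors())
  expect_length(y2, 1L)
  expect_gt(y2, 100); expect_lt(y2, 110)
  # weighted toward the taller bump
  expect_gt(y2, 105)

  # single bump -> its argmax
  gh3 <- exp(-(x - 77)^2 / 30)
  expect_equal(candidate_rows(gh3, disc_priors()), 77, tolerance = 1)

  expect_error(candidate_rows(rep(0, 100), disc_priors()),
               class = "discgabor_detection_error")
  expect_error(candidate_rows(rep(-1, 100)), "nonnegative")
})

test_that("disc_priors validates and converts mm to px", {
  p <- disc_priors()
  expect_equal(p$min_dy, 25); expect_equal(p$max_dy, 60)
  p2 <- disc_priors(pixel_spacing = 0.8)
  expect_equal(p2$min_dy, 20 / 0.8)
  expect_equal(p2$max_dy, 50 / 0.8)
  expect_error(disc_priors(min_dy = 50, max_dy = 40), "min_dy")
})

test_that("candidate_cols recovers aligned disc abscissae", {
  fx <- loc_fix()
  g_mdisc <- cached("loc_gmdisc", elliptical_median(compute_disc_gfi(fx$stack)))
  gh <- row_profile(g_mdisc, fx$curves)
  y <- candidate_rows(gh, disc_priors())
  cc <- candidate_cols(g_mdisc, y, fx$curves, disc_priors())
  true_cols <- fx$truth$centers[, "col"]
  # most discs lie on the common vertical line (the last two may lean)
  n <- length(cc$x)
  expect_true(all(abs(cc$x[seq_len(max(1, n - 2))] -
                        true_cols[seq_len(max(1, n - 2))]) <= 3))
  # single disc: argmax of its band profile
  cc1 <- candidate_cols(g_mdisc, y[1], fx$curves, disc_priors())
  expect_equal(cc1$x[1], which.max(cc1$gv[[1]]))
})

test_that("compute_boxes brackets unimodal peaks and drops degenerate ones", {
  x <- 1:200
  gh <- numeric(200)
  gh[60:100] <- sin(seq(0, pi, length.out = 41))    # support exactly 60..100
  cols <- list(x = 50L, bands = cbind(top = 1L, bottom = 200L),
               gv = list(c(rep(0, 30), sin(seq(0, pi, length.out = 41)),
                           rep(0, 129))))
  bx <- compute_boxes(gh, cols, y_list = 80, smooth_width = 1L)
  expect_equal(nrow(bx$boxes), 1L)
  expect_lte(abs(bx$boxes[1, "top"] - 60), 2)
  expect_lte(abs(bx$boxes[1, "bottom"] - 100), 2)
  expect_lte(abs(bx$boxes[1, "left"] - 31), 2)
  expect_lte(abs(bx$boxes[1, "right"] - 71), 2)
  # box contains its candidate center
  expect_true(bx$boxes[1, "top"] <= 80 && bx$boxes[1, "bottom"] >= 80)

  # degenerate: flat zero profiles -> dropped with warning
  cols0 <- list(x = 5L, bands = cbind(top = 1L, bottom = 20L),
                gv = list(rep(0, 20)))
  expect_warning(bx0 <- compute_boxes(rep(0, 20), cols0, y_list = 10,
                                      smooth_width = 1L), "degenerate")
  expect_equal(nrow(bx0$boxes), 0L)
})

test_that("estimate_angle lands within one direction bin of the truth", {
  truth <- phantom_generate(small_phantom_spec(
    seed = 5L, angles = c(0, 15, -30, 25), angle_deg = c(-30, 30)))
  stack <- apply_bank(truth$image, build_bank())
  binw <- 180 / 16
  for (i in seq_len(4)) {
    cy <- truth$centers[i, "row"]; cx <- truth$centers[i, "col"]
    box <- c(round(cy - 14), round(cy + 14), round(cx - 26), round(cx + 26))
    est <- estimate_angle(stack, box)
    expect_lte(abs(est - truth$angles[i]), binw + 1e-9,
               label = sprintf("disc %d (true %g, est %g)", i,
                               truth$angles[i], est))
  }
})

test_that("refine_centers equals the brute-force centroid", {
  set.seed(9)
  g <- matrix(runif(40 * 40), 40, 40)
  boxes <- rbind(c(top = 5L, bottom = 20L, left = 8L, right = 30L))
  out <- refine_centers(g, boxes, cbind(row = 12, col = 19))
  thr <- otsu_threshold(g[5:20, 8:30])
  idx <- which(g[5:20, 8:30] > thr, arr.ind = TRUE)
  expect_equal(unname(out[1, "row"]), mean(idx[, 1] + 4))
  expect_equal(unname(out[1, "col"]), mean(idx[, 2] + 7))

  # symmetric binary ellipse -> exact geometric center
  m <- matrix(0, 41, 41)
  m[outer((-20:20)^2 / 100, (-20:20)^2 / 225, "+") <= 1] <- 1
  out2 <- refine_centers(m, rbind(c(top = 1L, bottom = 41L,
                                    left = 1L, right = 41L)),
                         cbind(row = 1, col = 1))
  expect_equal(unname(out2[1, ]), c(21, 21))

  # constant patch falls back to the coarse center
  out3 <- refine_centers(matrix(1, 10, 10),
                         rbind(c(top = 2L, bottom = 9L, left = 2L, right = 9L)),
                         cbind(row = 5, col = 6))
  expect_equal(unname(out3[1, ]), c(5, 6))
})

test_that("localize_discs recovers the small phantom's discs end to end", {
  fx <- loc_fix()
  loc <- localize_discs(fx$stack, fx$curves)
  det <- loc$detections
  expect_equal(nrow(det), 4L)
  cd <- center_distances(cbind(det$row, det$col), fx$truth$centers)
  expect_equal(nrow(cd$pairs), 4L)
  expect_lte(mean(cd$pairs$dist_px), 3)
  # detected spacing satisfies the prior window
  expect_true(all(diff(sort(det$row)) >= 25 & diff(sort(det$row)) <= 60))
  # every center inside its true disc
  for (i in seq_len(4)) {
    r <- round(det$row[i]); c <- round(det$col[i])
    expect_true(any(vapply(fx$truth$disc_masks, function(m) m[r, c],
                           logical(1))))
  }
})
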