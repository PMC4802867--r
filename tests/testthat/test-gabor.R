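test_that("make_kernel matches the scalar formula and its symmetries", {
  set.seed(11)
  sx <- 3 * sqrt(2 * log(2)) / (pi / 2)
  ker <- make_kernel(theta = 0.7, omega = pi / 3, sigma_x = sx,
                     sigma_y = 2 * sx, window = 31L)
  expect_equal(dim(ker$real), c(31L, 31L))
  expect_equal(dim(ker$imag), c(31L, 31L))

  # center value: real = amplitude, imaginary = 0
  expect_equal(ker$real[16, 16], 1 / (2 * pi * sx * 2 * sx), tolerance = 1e-14)
  expect_equal(ker$imag[16, 16], 0)

  # random offsets against independent scalar evaluation
  for (k in 1:5) {
    x <- sample(-15:15, 1); y <- sample(-15:15, 1)
    want <- gabor_scalar(x, y, 0.7, pi / 3, sx, 2 * sx)
    got <- ker$real[16 + y, 16 + x] + 1i * ker$imag[16 + y, 16 + x]
    expect_equal(got, want, tolerance = 1e-12)
  }

  # even real part, odd imaginary part under point reflection
  flip <- function(m) m[nrow(m):1, ncol(m):1]
  expect_lt(max(abs(ker$real - flip(ker$real))), 1e-12)
  expect_lt(max(abs(ker$imag + flip(ker$imag))), 1e-12)

  expect_error(make_kernel(0, pi / 4, 3, 6, 30L), "odd")
  expect_error(make_kernel(0, -1, 3, 6, 31L), "positive")
})

test_that("build_bank produces the published parameterization", {
  p <- gabor_bank_params()
  bank <- build_bank(p)
  expect_length(bank, 80L)            # 16 directions x 5 scales
  expect_s3_class(bank, "gabor_bank")

  k00 <- bank[[1L]]
  expect_identical(attr(k00, "mu"), 0L)
  expect_equal(k00$theta, 0)

  # omega_4 = omega_max / f^4 = pi/4 with f = 2^(1/4)
  expect_equal(p$omega[5], pi / 4, tolerance = 1e-12)
  expect_true(all(diff(p$omega) < 0))
  # sigma_y = 2 sigma_x at every scale
  expect_equal(p$sigma_y, 2 * p$sigma_x, tolerance = 1e-12)
  k_const <- sqrt(2 * log(2))
  expect_equal(p$sigma_x, 3 * k_const / p$omega, tolerance = 1e-12)

  for (mu in c(3L, 15L)) for (v in c(0L, 4L)) {
    k <- bank[[mu * p$K + v + 1L]]
    expect_equal(k$theta, mu * pi / 16)
    expect_equal(k$omega, (pi / 2) / (2^(1 / 4))^v)
  }
  expect_error(gabor_bank_params(S = 1), "S")
  expect_error(gabor_bank_params(window = 4), "odd")
})

test_that("kernel symmetry holds across the whole bank", {
  bank <- build_bank(gabor_bank_params(S = 16L, K = 5L))
  flip <- function(m) m[nrow(m):1, ncol(m):1]
  for (k in bank) {
    expect_lt(max(abs(k$real - flip(k$real))), 1e-12)
    expect_lt(max(abs(k$imag + flip(k$imag))), 1e-12)
  }
})

test_that("apply_bank agrees with brute-force spatial convolution", {
  set.seed(42)
  p <- gabor_bank_params(S = 2L, K = 2L)
  bank <- build_bank(p)
  img <- matrix(runif(64 * 64), 64, 64)
  stack <- apply_bank(img, bank)
  expect_equal(dim(stack), c(2L, 2L, 64L, 64L))
  for (mu in 0:1) for (v in 0:1) {
    k <- bank[[mu * 2L + v + 1L]]
    want <- Mod(brute_conv(img, k$real + 1i * k$imag))
    expect_equal(stack[mu + 1L, v + 1L, , ], want, tolerance = 1e-9)
  }
})

test_that("apply_bank impulse response is the point-reflected kernel modulus", {
  p <- gabor_bank_params(S = 2L, K = 1L)
  bank <- build_bank(p)
  img <- matrix(0, 64, 64)
  img[32, 32] <- 1
  stack <- apply_bank(img, bank)
  k <- bank[[2L]]                       # mu = 1
  kc <- k$real + 1i * k$imag
  # conv(impulse at (32,32)) places K(o) at (32 + o); kernel index
  # (i, j) holds offset (i - 16, j - 16)
  got <- stack[2L, 1L, 17:47, 17:47]
  expect_equal(got, Mod(kc), tolerance = 1e-9)

  # zero image -> zero stack; shape contract
  z <- apply_bank(matrix(0, 64, 64), bank)
  expect_true(all(z == 0))
  expect_error(apply_bank(matrix(0, 16, 16), bank), "smaller")
  expect_error(apply_bank(matrix(NA_real_, 64, 64), bank), "finite")
})

test_that("directional_feature matches hand arithmetic and clips at zero", {
  # hand-built (S=2, K=2, 3x3) stack
  stack <- array(0, dim = c(2, 2, 3, 3))
  stack[1, 1, , ] <- matrix(1:9, 3, 3)
  stack[1, 2, , ] <- matrix(9:1, 3, 3)
  stack[2, 1, , ] <- 2
  stack[2, 2, , ] <- 4
  # U1 = {0}: mean = (stack[1,1]+stack[1,2])/2 = 5 everywhere
  # U2 = {1}: mean = 3 everywhere -> difference = 2
  out <- directional_feature(stack, 0L, 1L)
  expect_equal(out, matrix(2, 3, 3))
  # reversed subsets -> negative difference clipped to 0
  expect_equal(directional_feature(stack, 1L, 0L), matrix(0, 3, 3))
  # U1 = U2 cancels exactly
  expect_equal(directional_feature(stack, 0L, 0L), matrix(0, 3, 3))
  expect_error(directional_feature(stack, 0L, 5L), "out of range")
  expect_error(directional_feature(stack, integer(0), 1L), "nonempty")
})

test_that("constant image gives spatially constant per-direction responses", {
  bank <- build_bank(gabor_bank_params(S = 4L, K = 2L))
  img <- matrix(7, 48, 48)
  stack <- apply_bank(img, bank)
  for (mu in 0:3) for (v in 0:1) {
    slice <- stack[mu + 1L, v + 1L, , ]
    expect_lt(diff(range(slice)), 1e-9 * (1 + max(slice)))
  }
})

test_that("directional_feature output is nonnegative for random stacks", {
  set.seed(5)
  for (rep in 1:5) {
    stack <- array(runif(4 * 2 * 6 * 6), dim = c(4, 2, 6, 6))
    U1 <- sample(0:3, 2)
    U2 <- sample(0:3, 2)
    expect_true(all(directional_feature(stack, U1, U2) >= 0))
  }
})

test_that("mean_direction_gfi averages over scales", {
  stack <- array(0, dim = c(2, 2, 2, 2))
  stack[1, 1, , ] <- matrix(c(1, 2, 3, 4), 2, 2)
  stack[1, 2, , ] <- matrix(c(5, 6, 7, 8), 2, 2)
  expect_equal(mean_direction_gfi(stack, 0L), matrix(c(3, 4, 5, 6), 2, 2))
  # constant across scales -> unchanged
  stack[2, 1, , ] <- 3; stack[2, 2, , ] <- 3
  expect_equal(mean_direction_gfi(stack, 1L), matrix(3, 2, 2))
  expect_error(mean_direction_gfi(stack, 2L), "out of range")
})
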