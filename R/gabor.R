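#' Parameters of the Gabor filter bank
#'
#' Constructs and validates the parameter set of the 2-D Gabor filter bank
#' used throughout the pipeline.  The bank has `S` directions and `K`
#' scales; direction `mu` (0-based) has angle `theta = mu * pi / S` and
#' scale `v` (0-based) has center angular frequency
#' `omega_v = omega_max / f^v`, so the frequency ladder descends
#' geometrically by the spacing factor `f`.  The anisotropic Gaussian
#' envelope has `sigma_x = sigma_x_factor * k / omega_v` along the
#' sinusoidal variation axis and `sigma_y = sigma_y_factor * k / omega_v`
#' across it, with `k = sqrt(2 * log(2))`, so the envelope is twice as
#' long across the wave as along it and disc-like elongated structures are
#' matched.
#'
#' Direction convention: `theta` is the orientation of the sinusoidal
#' variation axis in image coordinates (x = column, increasing rightward;
#' y = row, increasing downward).  A kernel with `theta = 0` varies
#' horizontally and therefore responds maximally to *vertical* elongated
#' structures such as the spinal edges; `theta = pi/2` (direction index
#' `S/2`) responds to horizontal structures such as an untilted disc.
#'
#' @param S number of directions (default 16).
#' @param K number of scales (default 5).
#' @param omega_max upper angular frequency in radians/pixel (default
#'   `pi/2`).
#' @param f frequency spacing factor (default `2^(1/4)`).
#' @param window odd kernel side length in pixels (default 31).
#' @param sigma_x_factor,sigma_y_factor envelope factors (defaults 3 and
#'   6): `sigma = factor * k / omega_v`.
#' @param response `"magnitude"` (default) to take the modulus of the
#'   complex filter response as the Gabor feature image, or `"real"` for
#'   the real part.
#' @return An object of class `gabor_bank_params`.
#' @examples
#' p <- gabor_bank_params()
#' p$omega[5] # = omega_max / f^4 = pi/4
#' @export
gabor_bank_params <- function(S = 16L, K = 5L, omega_max = pi / 2,
                              f = 2^(1 / 4), window = 31L,
                              sigma_x_factor = 3, sigma_y_factor = 6,
                              response = c("magnitude", "real")) {
  response <- match.arg(response)
  S <- as.integer(S); K <- as.integer(K); window <- as.integer(window)
  if (S < 2L) stop("S must be >= 2", call. = FALSE)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3", call. = FALSE)
  if (!is.finite(omega_max) || omega_max <= 0)
    stop("omega_max must be positive", call. = FALSE)
  if (!is.finite(f) || f <= 1)
    stop("f must be > 1 so that frequencies strictly decrease", call. = FALSE)
  if (sigma_x_factor <= 0 || sigma_y_factor <= 0)
    stop("sigma factors must be positive", call. = FALSE)
  k_const <- sqrt(2 * log(2))
  omega <- omega_max / f^(0:(K - 1L))
  structure(list(
    S = S, K = K, omega_max = omega_max, f = f, window = window,
    k_const = k_const,
    sigma_x_factor = sigma_x_factor, sigma_y_factor = sigma_y_factor,
    theta = (0:(S - 1L)) * pi / S,
    omega = omega,
    sigma_x = sigma_x_factor * k_const / omega,
    sigma_y = sigma_y_factor * k_const / omega,
    response = response
  ), class = "gabor_bank_params")
}

#' @export
print.gabor_bank_params <- function(x, ...) {
  cat(sprintf(
    "Gabor bank: S = %d directions, K = %d scales, window %d x %d\n",
    x$S, x$K, x$window, x$window))
  cat(sprintf("  omega_max = %.4f rad/px, f = %.4f, response = %s\n",
              x$omega_max, x$f, x$response))
  cat(sprintf("  omega_v: %s\n", paste(sprintf("%.4f", x$omega), collapse = " ")))
  invisible(x)
}

#' Build a single complex 2-D Gabor kernel
#'
#' Evaluates, on an integer offset grid centered at the window midpoint,
#' \deqn{\psi(x, y) = \frac{1}{2\pi\sigma_x\sigma_y}
#'   \exp\{-\tfrac12[(x'/\sigma_x)^2 + (y'/\sigma_y)^2] + i\,\omega x'\}}
#' with rotated coordinates `x' = x cos(theta) + y sin(theta)` and
#' `y' = -x sin(theta) + y cos(theta)`, where `x` is the column offset and
#' `y` the row offset.  The real part is even and the imaginary part odd
#' under point reflection about the center.
#'
#' @param theta direction angle in radians.
#' @param omega center angular frequency, radians/pixel (> 0).
#' @param sigma_x,sigma_y Gaussian envelope standard deviations in pixels
#'   (> 0).
#' @param window odd kernel side length in pixels.
#' @return An object of class `gabor_kernel` with fields `real`, `imag`
#'   (window x window matrices), `theta`, `omega`, `sigma_x`, `sigma_y`,
#'   `window`.
#' @export
make_kernel <- function(theta, omega, sigma_x, sigma_y, window) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3", call. = FALSE)
  if (any(c(omega, sigma_x, sigma_y) <= 0) ||
      !all(is.finite(c(theta, omega, sigma_x, sigma_y))))
    stop("omega, sigma_x and sigma_y must be positive and finite",
         call. = FALSE)
  h <- (window - 1L) %/% 2L
  off <- -h:h
  X <- matrix(off, window, window, byrow = TRUE)  # column offset
  Y <- matrix(off, window, window)                # row offset
  xp <- X * cos(theta) + Y * sin(theta)
  yp <- -X * sin(theta) + Y * cos(theta)
  env <- exp(-0.5 * ((xp / sigma_x)^2 + (yp / sigma_y)^2)) /
    (2 * pi * sigma_x * sigma_y)
  structure(list(
    real = env * cos(omega * xp),
    imag = env * sin(omega * xp),
    theta = theta, omega = omega,
    sigma_x = sigma_x, sigma_y = sigma_y, window = window
  ), class = "gabor_kernel")
}

#' Build the full Gabor kernel bank
#'
#' Returns the `S * K` kernels of the bank as a flat list ordered with
#' scale fastest: element `mu * K + v + 1` is the kernel for (0-based)
#' direction `mu` and scale `v`.
#'
#' @param params a [gabor_bank_params()] object.
#' @return A list of class `gabor_bank`; each element is a `gabor_kernel`
#'   carrying attributes `mu` and `v`.
#' @export
build_bank <- function(params = gabor_bank_params()) {
  stopifnot(inherits(params, "gabor_bank_params"))
  kernels <- vector("list", params$S * params$K)
  for (mu in 0:(params$S - 1L)) {
    for (v in 0:(params$K - 1L)) {
      ker <- make_kernel(params$theta[mu + 1L], params$omega[v + 1L],
                         params$sigma_x[v + 1L], params$sigma_y[v + 1L],
                         params$window)
      attr(ker, "mu") <- mu
      attr(ker, "v") <- v
      kernels[[mu * params$K + v + 1L]] <- ker
    }
  }
  structure(kernels, class = "gabor_bank", params = params)
}

# symmetric reflection padding (edge pixel included on both axes)
pad_reflect <- function(image, pad) {
  M <- nrow(image); N <- ncol(image)
  if (pad >= M || pad >= N)
    stop("reflection pad exceeds image size", call. = FALSE)
  ri <- c(pad:1, 1:M, M:(M - pad + 1L))
  ci <- c(pad:1, 1:N, N:(N - pad + 1L))
  image[ri, ci, drop = FALSE]
}

#' Filter an image with the Gabor bank
#'
#' Convolves the image with every kernel in the bank (linear convolution,
#' symmetric-reflection boundary padding, same-size output, computed in
#' the frequency domain) and returns the stack of Gabor feature responses.
#' By default the modulus of the complex response is taken, so entries are
#' nonnegative energies comparable across directions.
#'
#' @param image a numeric matrix (rows x columns), finite-valued, with
#'   both dimensions at least the kernel window.
#' @param bank a [build_bank()] object.
#' @return A 4-D array of class `gabor_feature_stack` with dimensions
#'   `(S, K, M, N)` indexed (direction, scale, row, column).
#' @export
apply_bank <- function(image, bank = build_bank()) {
  stopifnot(inherits(bank, "gabor_bank"))
  params <- attr(bank, "params")
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("image must be finite-valued", call. = FALSE)
  w <- params$window
  if (nrow(image) < w || ncol(image) < w)
    stop(sprintf("image (%d x %d) smaller than kernel window (%d)",
                 nrow(image), ncol(image), w), call. = FALSE)
  M <- nrow(image); N <- ncol(image)
  pad <- (w - 1L) %/% 2L
  padded <- pad_reflect(image, pad)
  kers <- lapply(unclass(bank), function(k) k$real + 1i * k$imag)
  cube <- gabor_convolve_cpp(padded, kers, M, N, w,
                             params$response == "magnitude")
  # cube slices are ordered scale-fastest -> (M, N, K, S) -> (S, K, M, N)
  stack <- aperm(array(cube, dim = c(M, N, params$K, params$S)),
                 c(4L, 3L, 1L, 2L))
  structure(stack, class = "gabor_feature_stack",
            S = params$S, K = params$K, response = params$response)
}

stack_dims <- function(stack) {
  d <- dim(stack)
  if (length(d) != 4L) stop("not a (S, K, M, N) feature stack", call. = FALSE)
  list(S = d[1L], K = d[2L], M = d[3L], N = d[4L])
}

#' Direction-subset difference feature (clipped)
#'
#' Computes the Gabor feature image obtained by subtracting the mean
#' response over directions `U2` from the mean over directions `U1`, both
#' averaged over all scales, and clipping negative values to zero.  With
#' `U1` near the target orientation and `U2` near the orthogonal one this
#' isolates elongated structures of the target orientation.
#'
#' @param stack a feature stack from [apply_bank()].
#' @param U1,U2 nonempty sets of 0-based direction indices in
#'   `0..S-1`.
#' @return A nonnegative `M x N` matrix.
#' @export
directional_feature <- function(stack, U1, U2) {
  d <- stack_dims(stack)
  U1 <- as.integer(U1); U2 <- as.integer(U2)
  if (length(U1) == 0L || length(U2) == 0L)
    stop("direction subsets must be nonempty", call. = FALSE)
  if (any(U1 < 0L | U1 >= d$S) || any(U2 < 0L | U2 >= d$S))
    stop("direction index out of range 0..S-1", call. = FALSE)
  mean_over <- function(U) {
    sub <- stack[U + 1L, , , , drop = FALSE]
    dim(sub) <- c(length(U) * d$K, d$M * d$N)
    colMeans(sub)
  }
  g <- mean_over(U1) - mean_over(U2)
  g[g < 0] <- 0
  matrix(g, d$M, d$N)
}

#' Scale-averaged response map of one direction
#'
#' Pixelwise mean over all scales of the responses at direction `mu`.
#' The maximum of these maps over directions reflects the boundary of an
#' elongated structure and seeds the segmentation candidate region.
#'
#' @param stack a feature stack from [apply_bank()].
#' @param mu 0-based direction index.
#' @return An `M x N` matrix.
#' @export
mean_direction_gfi <- function(stack, mu) {
  d <- stack_dims(stack)
  mu <- as.integer(mu)
  if (length(mu) != 1L || mu < 0L || mu >= d$S)
    stop("mu out of range 0..S-1", call. = FALSE)
  sub <- stack[mu + 1L, , , , drop = FALSE]
  dim(sub) <- c(d$K, d$M * d$N)
  matrix(colMeans(sub), d$M, d$N)
}
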