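# Independent oracles used across test files.  These deliberately avoid
# the code paths they check: the Gabor formula is evaluated per scalar
# offset, convolution is a nested loop in the spatial domain, medians and
# centroids are computed by brute force.

# scalar evaluation of the Gabor kernel at one (x, y) offset
gabor_scalar <- function(x, y, theta, omega, sigma_x, sigma_y) {
  xp <- x * cos(theta) + y * sin(theta)
  yp <- -x * sin(theta) + y * cos(theta)
  (1 / (2 * pi * sigma_x * sigma_y)) *
    exp(-0.5 * ((xp / sigma_x)^2 + (yp / sigma_y)^2)) *
    exp(1i * omega * xp)
}

# symmetric reflection padding identical in definition to the package's
# boundary convention, written independently
pad_sym <- function(img, p) {
  M <- nrow(img); N <- ncol(img)
  out <- matrix(0, M + 2 * p, N + 2 * p)
  for (r in seq_len(M + 2 * p)) {
    rr <- r - p
    if (rr < 1) rr <- 1 - rr
    if (rr > M) rr <- 2 * M + 1 - rr
    for (c in seq_len(N + 2 * p)) {
      cc <- c - p
      if (cc < 1) cc <- 1 - cc
      if (cc > N) cc <- 2 * N + 1 - cc
      out[r, c] <- img[rr, cc]
    }
  }
  out
}

# brute-force spatial-domain convolution with a complex kernel,
# symmetric boundary, same-size output: out(p) = sum_o img(p - o) K(o).
# Loops over every output pixel; the sum over kernel offsets is a direct
# elementwise patch product with the 180-degree-rotated kernel.
brute_conv <- function(img, ker_complex) {
  w <- nrow(ker_complex)
  h <- (w - 1L) %/% 2L
  M <- nrow(img); N <- ncol(img)
  padded <- pad_sym(img, h)
  kf <- ker_complex[w:1, w:1]       # img(p - o) pairs with K(o)
  out <- matrix(0i, M, N)
  for (r in seq_len(M)) {
    for (c in seq_len(N)) {
      out[r, c] <- sum(padded[r:(r + 2L * h), c:(c + 2L * h)] * kf)
    }
  }
  out
}

# exhaustive Otsu search over all 256 integer cuts of an 8-bit sample:
# maximize between-class variance of classes {<= t} and {> t}
otsu_exhaustive_8bit <- function(values) {
  values <- as.integer(values)
  best_t <- NA_integer_
  best_v <- -Inf
  n <- length(values)
  for (t in 0:255) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / n
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# small phantom spec used by mid-weight tests (fast to filter);
# any default below can be overridden through ...
small_phantom_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(image_size = c(320L, 192L), n_discs = 4L, center_col = 96,
         band_halfwidth = 28, top_margin = 50, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

# cache expensive shared fixtures (stacks) across tests in one session
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
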