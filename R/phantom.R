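#' Specification of a synthetic spine phantom
#'
#' Describes a synthetic mid-sagittal T2-weighted spine image: a
#' near-vertical bright spinal column band (two roughly parallel edges,
#' optionally bowed), `n_discs` bright elliptical discs stacked along the
#' band with darker vertebral bodies between them, plus optional additive
#' Gaussian noise and a smooth multiplicative intensity inhomogeneity.
#' Disc tilts follow the lumbar anatomy the method targets: close to
#' horizontal superiorly and fanning progressively toward the configured
#' maximum tilt inferiorly, with the two most inferior discs also leaning
#' slightly to the right of the common vertical line.
#'
#' @param image_size `c(M, N)` rows and columns (default `c(512, 256)`).
#' @param n_discs number of discs (default 8).
#' @param disc_width long-axis range in pixels (default `c(30, 55)`,
#'   must be >= 25).
#' @param thickness_ratio disc thickness as a fraction of width
#'   (default 0.5).
#' @param angle_deg allowed tilt range in degrees (default
#'   `c(-30, 30)`); positive tilts the right end of the disc downward.
#' @param angles optional explicit per-disc tilts (overrides the
#'   anatomical progression; must lie inside `angle_deg`).
#' @param spacing_px adjacent-center vertical spacing range in pixels
#'   (default `c(30, 55)`; must stay inside the 25--60 px prior window).
#' @param curvature_amp amplitude in pixels of a sinusoidal bow of the
#'   spinal band (default 0).
#' @param center_col column of the band center (default `N/2`).
#' @param band_halfwidth half-width of the spinal band in pixels
#'   (default 30).
#' @param intensities named list of gray levels on a 0--255 scale
#'   (defaults: background 30, canal 50, vertebra 80, annulus 120,
#'   disc 200; the vertebral level is 40% of the disc level, emulating
#'   T2 contrast).  Each disc is rendered as a darker annulus fibrosus
#'   rim enclosing a bright nucleus pulposus core (a concentric ellipse
#'   scaled by `nucleus_scale`) crossed by a thin annulus-level
#'   intranuclear cleft, the hallmark appearance of a hydrated adult
#'   disc on T2.  Degenerated discs lose the cleft and 40% of the
#'   nucleus signal.
#' @param nucleus_scale axis ratio of the nucleus ellipse relative to
#'   the whole disc (default 0.65).
#' @param noise_sigma additive Gaussian noise standard deviation as a
#'   fraction of the 255 dynamic range (default 0).
#' @param bias_amp amplitude of the smooth multiplicative inhomogeneity
#'   (default 0).
#' @param lean_px rightward lean of the most inferior disc in pixels
#'   (default 6; the second most inferior leans half as much).
#' @param top_margin rows above the first disc center (default 55).
#' @param degenerate optional indices of degenerated discs (intensity
#'   reduced to 60%, thickness to 70%).
#' @param seed RNG seed making the phantom fully deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(512L, 256L), n_discs = 8L,
                         disc_width = c(30, 55), thickness_ratio = 0.5,
                         angle_deg = c(-30, 30), angles = NULL,
                         spacing_px = c(30, 55), curvature_amp = 0,
                         center_col = NULL, band_halfwidth = 30,
                         intensities = list(background = 30, canal = 50,
                                            vertebra = 80, annulus = 120,
                                            disc = 200),
                         nucleus_scale = 0.65,
                         noise_sigma = 0, bias_amp = 0, lean_px = 6,
                         top_margin = 55, degenerate = integer(0),
                         seed = 1L) {
  if (disc_width[1] < 25)
    stop("disc width must be at least 25 px", call. = FALSE)
  if (spacing_px[1] < 25 || spacing_px[2] > 60)
    stop("spacing range must lie inside the 25..60 px prior window",
         call. = FALSE)
  if (n_discs < 1L) stop("need at least one disc", call. = FALSE)
  if (!is.null(angles)) {
    if (length(angles) != n_discs)
      stop("angles must have one entry per disc", call. = FALSE)
    if (any(angles < angle_deg[1] | angles > angle_deg[2]))
      stop("explicit angles outside angle_deg range", call. = FALSE)
  }
  if (is.null(center_col)) center_col <- image_size[2] / 2
  structure(list(image_size = as.integer(image_size), n_discs = as.integer(n_discs),
                 disc_width = disc_width, thickness_ratio = thickness_ratio,
                 angle_deg = angle_deg, angles = angles,
                 spacing_px = spacing_px, curvature_amp = curvature_amp,
                 center_col = center_col, band_halfwidth = band_halfwidth,
                 intensities = intensities, nucleus_scale = nucleus_scale,
                 noise_sigma = noise_sigma,
                 bias_amp = bias_amp, lean_px = lean_px,
                 top_margin = top_margin, degenerate = as.integer(degenerate),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# rotated ellipse coordinates; phi in degrees, positive = right end down
ellipse_coords <- function(M, N, cy, cx, phi) {
  t <- phi * pi / 180
  dr <- matrix(seq_len(M) - cy, M, N)
  dc <- matrix(seq_len(N) - cx, M, N, byrow = TRUE)
  list(u = dc * cos(t) + dr * sin(t),    # along the long axis
       v = -dc * sin(t) + dr * cos(t))   # across it
}

# filled rotated ellipse mask
ellipse_mask <- function(M, N, cy, cx, a, b, phi) {
  ec <- ellipse_coords(M, N, cy, cx, phi)
  (ec$u / a)^2 + (ec$v / b)^2 <= 1
}

# rounded rectangle mask with corner radius cr
rounded_rect_mask <- function(M, N, r1, r2, c1, c2, cr = 4) {
  if (r2 < r1 || c2 < c1) return(matrix(FALSE, M, N))
  cr <- min(cr, (r2 - r1) / 2, (c2 - c1) / 2)
  R <- matrix(seq_len(M), M, N)
  C <- matrix(seq_len(N), M, N, byrow = TRUE)
  dx <- pmax(0, (r1 + cr) - R, R - (r2 - cr))
  dy <- pmax(0, (c1 + cr) - C, C - (c2 - cr))
  dx * dx + dy * dy <= cr * cr
}

#' Generate a synthetic spine phantom with ground truth
#'
#' Renders the phantom described by a [phantom_spec()] and returns the
#' image along with exact ground truth: per-disc binary masks, centers,
#' tilt angles and the left/right spinal band edges per row.  Generation
#' is fully deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()] object.
#' @return An object of class `phantom_truth`: list with `image`
#'   (`M x N` matrix on a 0--255 scale), `disc_masks` (list of logical
#'   matrices, pairwise disjoint), `centers` (matrix row/col), `angles`,
#'   `widths`, `thicknesses`, `spine_left`, `spine_right` and `spec`.
#' @export
phantom_generate <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    M <- spec$image_size[1L]; N <- spec$image_size[2L]
    n <- spec$n_discs
    lev <- spec$intensities

    widths <- stats::runif(n, spec$disc_width[1], spec$disc_width[2])
    thick <- widths * spec$thickness_ratio
    if (!is.null(spec$angles)) {
      angles <- as.numeric(spec$angles)
    } else {
      # anatomical fan: near-horizontal superiorly, tilting toward the
      # upper end of the configured range inferiorly
      target <- min(25, spec$angle_deg[2])
      angles <- seq(0, target, length.out = n) + stats::rnorm(n, 0, 3)
      angles <- pmin(spec$angle_deg[2], pmax(spec$angle_deg[1], angles))
    }
    deg <- seq_len(n) %in% spec$degenerate
    thick[deg] <- thick[deg] * 0.7
    a <- widths / 2; b <- thick / 2
    vext <- sqrt((a * sin(angles * pi / 180))^2 +
                 (b * cos(angles * pi / 180))^2)

    gaps <- numeric(max(0L, n - 1L))
    for (i in seq_len(n - 1L)) {
      lo <- max(spec$spacing_px[1], vext[i] + vext[i + 1L] + 4)
      hi <- spec$spacing_px[2]
      if (lo > hi)
        stop("infeasible packing: disc extents exceed the spacing window",
             call. = FALSE)
      gaps[i] <- stats::runif(1L, lo, hi)
    }
    cy <- spec$top_margin + vext[1L] + c(0, cumsum(gaps))
    if (n >= 1L && cy[n] + vext[n] + 5 > M)
      stop("infeasible packing: discs exceed the image height", call. = FALSE)

    rows <- seq_len(M)
    cc <- spec$center_col +
      spec$curvature_amp * sin(2 * pi * (rows - 1) / (M - 1))
    spine_left <- as.integer(round(cc - spec$band_halfwidth))
    spine_right <- as.integer(round(cc + spec$band_halfwidth))
    spine_left <- pmax(1L, spine_left); spine_right <- pmin(N, spine_right)

    cx <- cc[pmin(M, pmax(1L, as.integer(round(cy))))]
    if (n >= 2L) {
      cx[n] <- cx[n] + spec$lean_px
      cx[n - 1L] <- cx[n - 1L] + spec$lean_px / 2
    }

    img <- matrix(lev$background, M, N)
    band <- matrix(FALSE, M, N)
    for (r in rows) band[r, spine_left[r]:spine_right[r]] <- TRUE
    img[band] <- lev$canal

    # vertebral bodies: rounded rectangles filling the gaps between discs
    vb_halfwidth <- spec$band_halfwidth - 4
    vb_gap <- 3
    seg_tops <- c(max(1, cy[1L] - vext[1L] - spec$spacing_px[2] / 2),
                  cy + vext + vb_gap)
    seg_bots <- c(cy - vext - vb_gap,
                  min(M, cy[n] + vext[n] + spec$spacing_px[2] / 2))
    for (s in seq_along(seg_tops)) {
      r1 <- as.integer(round(seg_tops[s])); r2 <- as.integer(round(seg_bots[s]))
      if (r2 - r1 < 4L) next
      rc <- as.integer(round(cc[pmin(M, pmax(1L, (r1 + r2) %/% 2L))]))
      vb <- rounded_rect_mask(M, N, max(1L, r1), min(M, r2),
                              max(1L, rc - vb_halfwidth),
                              min(N, rc + vb_halfwidth), cr = 5)
      img[vb] <- lev$vertebra
    }

    disc_masks <- vector("list", n)
    centers <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("row", "col")))
    for (i in seq_len(n)) {
      ec <- ellipse_coords(M, N, cy[i], cx[i], angles[i])
      rad2 <- (ec$u / a[i])^2 + (ec$v / b[i])^2
      m <- rad2 <= 1
      disc_masks[[i]] <- m
      centers[i, ] <- c(cy[i], cx[i])
      nuc_lev <- if (deg[i]) lev$disc * 0.6 else lev$disc
      img[m] <- lev$annulus
      img[rad2 <= spec$nucleus_scale^2] <- nuc_lev
      if (!deg[i]) {
        # intranuclear cleft: thin band of annulus-level signal across
        # the middle of the nucleus, the typical adult T2 appearance
        cleft <- m & abs(ec$v) <= 1.5 & abs(ec$u) <= 0.8 * a[i]
        img[cleft] <- lev$annulus
      }
    }

    if (spec$bias_amp > 0) {
      p1 <- stats::runif(1L, 0, pi); p2 <- stats::runif(1L, 0, pi)
      s <- outer(sin(pi * rows / M + p1), sin(pi * seq_len(N) / N + p2))
      img <- img * (1 + spec$bias_amp * (s - mean(s)))
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(M * N, 0, spec$noise_sigma * 255), M, N)
    img <- pmin(pmax(img, 0), 255)

    structure(list(image = img, disc_masks = disc_masks, centers = centers,
                   angles = angles, widths = widths, thicknesses = thick,
                   spine_left = spine_left, spine_right = spine_right,
                   spec = spec),
              class = "phantom_truth")
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Spine phantom %d x %d, %d discs, noise sigma %.3f, seed %d\n",
              nrow(x$image), ncol(x$image), length(x$disc_masks),
              x$spec$noise_sigma, x$spec$seed))
  invisible(x)
}
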