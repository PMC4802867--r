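#' Anatomical priors for disc localization
#'
#' Two pieces of prior knowledge constrain the search: (I) the abscissae
#' of most discs lie roughly on one vertical line, except the most
#' inferior ones which lean slightly to the right; (II) the vertical
#' offset between adjacent disc centers ranges from 20 to 50 mm.  When a
#' pixel spacing is supplied the millimetre window is converted to
#' pixels; otherwise the pixel defaults 25--60 px apply (about
#' 0.8 mm/px).
#'
#' @param min_dy,max_dy adjacent-disc vertical offset window in pixels
#'   (defaults 25 and 60).
#' @param x_alignment_tol maximum deviation of disc abscissae from the
#'   common vertical line, pixels (default 15).
#' @param angle_range maximum disc tilt from horizontal, degrees
#'   (default 30).
#' @param spacing_mm the millimetre offset window (default `c(20, 50)`),
#'   used when `pixel_spacing` is given.
#' @param pixel_spacing mm per pixel, or `NULL` to use pixel defaults.
#' @return An object of class `disc_priors`.
#' @export
disc_priors <- function(min_dy = 25, max_dy = 60, x_alignment_tol = 15,
                        angle_range = 30, spacing_mm = c(20, 50),
                        pixel_spacing = NULL) {
  if (!is.null(pixel_spacing)) {
    if (pixel_spacing <= 0) stop("pixel_spacing must be positive", call. = FALSE)
    min_dy <- spacing_mm[1] / pixel_spacing
    max_dy <- spacing_mm[2] / pixel_spacing
  }
  if (!(min_dy > 0 && min_dy < max_dy))
    stop("need 0 < min_dy < max_dy", call. = FALSE)
  structure(list(min_dy = min_dy, max_dy = max_dy,
                 x_alignment_tol = x_alignment_tol,
                 angle_range = angle_range, spacing_mm = spacing_mm,
                 pixel_spacing = pixel_spacing),
            class = "disc_priors")
}

#' Disc Gabor feature image
#'
#' Clipped difference between the mean response over directions close to
#' the long axis of the discs, `U1 = {7,8,9,10,11}`, and directions close
#' to vertical, `U2 = {1,2,3,4,5}` (0-based, 16-direction bank).
#'
#' @param stack a feature stack from [apply_bank()] with `S = 16`.
#' @return A nonnegative `M x N` matrix.
#' @export
compute_disc_gfi <- function(stack) {
  d <- stack_dims(stack)
  if (d$S != 16L)
    stop("disc feature image requires a 16-direction bank", call. = FALSE)
  directional_feature(stack, 7:11, 1:5)
}

#' Elliptical median filter
#'
#' Replaces every pixel by the median of its neighborhood under an
#' axis-aligned elliptical template (long axis horizontal).  The default
#' 44 x 17 px template matches the typical disc footprint, so isolated
#' ridge responses merge into one compact blob per disc while thin
#' spurious responses are suppressed.  Boundaries are handled by
#' symmetric reflection.
#'
#' @param g a numeric matrix (typically from [compute_disc_gfi()]).
#' @param long_axis,minor_axis template axes in pixels (defaults 44, 17).
#' @return A matrix of the same size.
#' @export
elliptical_median <- function(g, long_axis = 44L, minor_axis = 17L) {
  long_axis <- as.integer(long_axis); minor_axis <- as.integer(minor_axis)
  if (long_axis < 1L || minor_axis < 1L || long_axis < minor_axis)
    stop("need long_axis >= minor_axis >= 1", call. = FALSE)
  median_filter_ellipse_cpp(as.matrix(g), long_axis, minor_axis)
}

#' Row profile of the disc feature image within the spine band
#'
#' `G_h(n)` sums the median-filtered disc feature image over the columns
#' enclosed by the spinal curves at row `n`; rows outside the curves'
#' valid range contribute zero.  Disc centers appear as local maxima of
#' this profile.
#'
#' @param g_mdisc matrix from [elliptical_median()].
#' @param curves a `spinal_curves` object.
#' @return Numeric vector of length `M`.
#' @export
row_profile <- function(g_mdisc, curves) {
  M <- nrow(g_mdisc)
  gh <- numeric(M)
  for (r in curves$valid_rows[1]:curves$valid_rows[2]) {
    l <- curves$left[r]; rr <- curves$right[r]
    if (!is.na(l) && !is.na(rr))
      gh[r] <- sum(g_mdisc[r, l:rr])
  }
  gh
}

# centered moving average, ends padded by edge replication
smooth_ma <- function(x, width = 5L) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1L], h), x, rep(x[n], width - 1L - h))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2L))[(h + 1L):(h + n)]
}

# indices of local maxima of x with topographic prominence >= min_prom
local_peaks <- function(x, min_prom = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  keep <- vapply(cand, function(i) {
    lv <- x[i]
    # walk outward until terrain higher than the peak (or the edge);
    # base on each side is the minimum along the walk
    lbase <- lv; j <- i - 1L
    while (j >= 1L && x[j] <= lv) { lbase <- min(lbase, x[j]); j <- j - 1L }
    rbase <- lv; j <- i + 1L
    while (j <= n && x[j] <= lv) { rbase <- min(rbase, x[j]); j <- j + 1L }
    (lv - max(lbase, rbase)) >= min_prom
  }, logical(1L))
  cand[keep]
}

#' Candidate disc rows from the row profile
#'
#' Local maxima of the smoothed row profile are candidate vertical disc
#' coordinates.  Maxima closer than `min_dy` are merged to their
#' profile-weighted mean row; candidates whose spacing to every neighbor
#' falls outside the `[min_dy, max_dy]` window are dropped as spurious.
#'
#' @param gh row profile from [row_profile()].
#' @param priors a [disc_priors()] object.
#' @param smooth_width moving-average width before peak picking
#'   (default 5).
#' @param prom_frac minimum peak prominence as a fraction of the profile
#'   maximum (default 0.05).
#' @return Sorted numeric vector of candidate rows.
#' @export
candidate_rows <- function(gh, priors = disc_priors(), smooth_width = 5L,
                           prom_frac = 0.05) {
  if (any(gh < 0)) stop("row profile must be nonnegative", call. = FALSE)
  ghs <- smooth_ma(gh, smooth_width)
  peaks <- local_peaks(ghs, min_prom = prom_frac * max(ghs))
  if (length(peaks) == 0L)
    stop_detection("no candidate disc rows found in the row profile")
  # discs are the dominant repeated structure along the column; much
  # weaker peaks (vertebral end-plate artifacts at the column ends) are
  # discarded relative to the median peak height
  peaks <- peaks[ghs[peaks] >= 0.3 * stats::median(ghs[peaks])]
  if (length(peaks) == 0L)
    stop_detection("no candidate disc rows above the height floor")
  y <- as.numeric(peaks)
  wts <- ghs[peaks]
  # merge close pairs, closest first, to the weight-averaged row
  while (length(y) > 1L) {
    gaps <- diff(y)
    i <- which.min(gaps)
    if (gaps[i] >= priors$min_dy) break
    ym <- (y[i] * wts[i] + y[i + 1L] * wts[i + 1L]) / (wts[i] + wts[i + 1L])
    wm <- wts[i] + wts[i + 1L]
    y <- c(y[seq_len(i - 1L)], ym, y[-seq_len(i + 1L)])
    wts <- c(wts[seq_len(i - 1L)], wm, wts[-seq_len(i + 1L)])
  }
  if (length(y) > 1L) {
    gaps <- diff(y)
    okgap <- gaps >= priors$min_dy & gaps <= priors$max_dy
    keep <- vapply(seq_along(y), function(i) {
      (i > 1L && okgap[i - 1L]) || (i < length(y) && okgap[i])
    }, logical(1L))
    if (any(keep)) y <- y[keep]
  }
  if (length(y) == 0L)
    stop_detection("all candidate rows violated the spacing prior")
  sort(y)
}

# per-disc row bands delimited by midpoints between adjacent candidates
disc_bands <- function(y_list, M, priors) {
  n <- length(y_list)
  half_default <- priors$max_dy / 2
  tops <- bots <- numeric(n)
  for (i in seq_len(n)) {
    tops[i] <- if (i == 1L) y_list[1L] - min(half_default,
      if (n > 1L) (y_list[2L] - y_list[1L]) / 2 else half_default)
      else (y_list[i - 1L] + y_list[i]) / 2
    bots[i] <- if (i == n) y_list[n] + min(half_default,
      if (n > 1L) (y_list[n] - y_list[n - 1L]) / 2 else half_default)
      else (y_list[i] + y_list[i + 1L]) / 2
  }
  cbind(top = pmax(1L, as.integer(floor(tops))),
        bottom = pmin(M, as.integer(ceiling(bots))))
}

# column profile of one disc band, masked by the spinal curves
band_col_profile <- function(g_mdisc, rows, curves) {
  N <- ncol(g_mdisc)
  gv <- numeric(N)
  for (r in rows) {
    l <- curves$left[r]; rr <- curves$right[r]
    if (!is.na(l) && !is.na(rr))
      gv[l:rr] <- gv[l:rr] + g_mdisc[r, l:rr]
  }
  gv
}

#' Candidate disc columns
#'
#' For every candidate row the midpoints between adjacent rows delimit a
#' horizontal band; the column profile of the median-filtered disc
#' feature image, restricted to the band and the spinal curves, peaks at
#' the disc abscissa.  Abscissae deviating from the cohort median by more
#' than the alignment tolerance are snapped to the constrained argmax
#' within the tolerance window, except the two most inferior discs which
#' are allowed to lean.
#'
#' @param g_mdisc matrix from [elliptical_median()].
#' @param y_list sorted candidate rows from [candidate_rows()].
#' @param curves a `spinal_curves` object.
#' @param priors a [disc_priors()] object.
#' @return A list with `x` (candidate columns), `bands` (row bounds per
#'   disc) and `gv` (per-disc column profiles).
#' @export
candidate_cols <- function(g_mdisc, y_list, curves, priors = disc_priors()) {
  stopifnot(length(y_list) >= 1L, !is.unsorted(y_list))
  M <- nrow(g_mdisc)
  bands <- disc_bands(y_list, M, priors)
  n <- length(y_list)
  gv <- vector("list", n)
  x <- integer(n)
  for (i in seq_len(n)) {
    gv[[i]] <- band_col_profile(g_mdisc, bands[i, 1L]:bands[i, 2L], curves)
    if (max(gv[[i]]) <= 0)
      stop_detection(sprintf("empty column profile for disc band %d", i))
    x[i] <- which.max(gv[[i]])
  }
  if (n >= 3L) {
    med <- stats::median(x)
    tol <- priors$x_alignment_tol
    for (i in seq_len(n - 2L)) {   # most inferior two discs are exempt
      if (abs(x[i] - med) > tol) {
        lo <- max(1L, as.integer(round(med - tol)))
        hi <- min(ncol(g_mdisc), as.integer(round(med + tol)))
        x[i] <- lo + which.max(gv[[i]][lo:hi]) - 1L
      }
    }
  }
  list(x = x, bands = bands, gv = gv)
}

# walk outward from pos: first ascend to the local peak in this
# direction (merged candidates may start on a slope or between lobes),
# then descend until a local minimum or a (near-)zero; returns the bound
profile_support <- function(profile, pos, dir, eps) {
  n <- length(profile)
  r <- as.integer(round(pos))
  repeat {
    nxt <- r + dir
    if (nxt < 1L || nxt > n || profile[nxt] <= profile[r]) break
    r <- nxt
  }
  repeat {
    nxt <- r + dir
    if (nxt < 1L || nxt > n) break
    if (profile[r] <= eps) break
    if (profile[nxt] > profile[r]) break   # valley at r
    r <- nxt
  }
  r
}

#' Bounding boxes of the candidate discs
#'
#' Per disc, the top and bottom box edges are the nearest
#' local-minimum-or-zero of the (smoothed) row profile above and below
#' the candidate row; the left and right edges come analogously from the
#' disc band's column profile around the candidate column.  Degenerate
#' boxes are dropped with a warning.
#'
#' @param gh row profile from [row_profile()].
#' @param cols result of [candidate_cols()] (`x`, `bands`, `gv`).
#' @param y_list candidate rows matching `cols`.
#' @param smooth_width moving-average width applied to profiles before
#'   the boundary scan (default 5).
#' @return A list with `boxes` (matrix with columns top, bottom, left,
#'   right), and the retained `y`, `x`, `gv` entries.
#' @export
compute_boxes <- function(gh, cols, y_list, smooth_width = 5L) {
  ghs <- smooth_ma(gh, smooth_width)
  eps_h <- 1e-9 * max(ghs)
  n <- length(y_list)
  boxes <- matrix(NA_integer_, n, 4L,
                  dimnames = list(NULL, c("top", "bottom", "left", "right")))
  keep <- logical(n)
  for (i in seq_len(n)) {
    top <- profile_support(ghs, y_list[i], -1L, eps_h)
    bottom <- profile_support(ghs, y_list[i], 1L, eps_h)
    top <- max(top, cols$bands[i, "top"])
    bottom <- min(bottom, cols$bands[i, "bottom"])
    gvs <- smooth_ma(cols$gv[[i]], smooth_width)
    eps_v <- 1e-9 * max(gvs)
    left <- profile_support(gvs, cols$x[i], -1L, eps_v)
    right <- profile_support(gvs, cols$x[i], 1L, eps_v)
    if (bottom > top && right > left) {
      boxes[i, ] <- c(top, bottom, left, right)
      keep[i] <- TRUE
    } else {
      warning(sprintf("disc candidate %d dropped: degenerate box", i),
              call. = FALSE)
    }
  }
  list(boxes = boxes[keep, , drop = FALSE], y = y_list[keep],
       x = cols$x[keep], gv = cols$gv[keep])
}

#' Estimate the tilt of a disc from the feature stack
#'
#' The direction whose scale-summed response energy inside the box is
#' maximal gives the orientation of the sinusoidal variation axis; the
#' structure's long axis is perpendicular, so the tilt from horizontal is
#' `mu * 180 / S - 90` degrees, clamped to +/- 45.  Positive angles tilt
#' the right end of the disc downward in image coordinates (row
#' increasing downward).
#'
#' @param stack a feature stack from [apply_bank()].
#' @param box integer vector `c(top, bottom, left, right)`.
#' @return Tilt in degrees.
#' @export
estimate_angle <- function(stack, box) {
  d <- stack_dims(stack)
  rows <- box[1L]:box[2L]; cls <- box[3L]:box[4L]
  sub <- stack[, , rows, cls, drop = FALSE]
  dim(sub) <- c(d$S, d$K * length(rows) * length(cls))
  mu_star <- which.max(rowMeans(sub)) - 1L
  ang <- mu_star * 180 / d$S - 90
  max(-45, min(45, ang))
}

#' Centroid correction of the coarse disc centers
#'
#' Within each box the median-filtered disc feature image is binarized by
#' Otsu's threshold and the coarse center is replaced by the area
#' centroid of the foreground.  If the foreground is empty (or the box is
#' constant) the coarse center is kept.
#'
#' @param g_mdisc matrix from [elliptical_median()].
#' @param boxes box matrix as returned by [compute_boxes()].
#' @param coarse_centers matrix with columns (row, col), one per box.
#' @return Matrix of refined centers (columns row, col).
#' @export
refine_centers <- function(g_mdisc, boxes, coarse_centers) {
  n <- nrow(boxes)
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(n)) {
    rows <- boxes[i, "top"]:boxes[i, "bottom"]
    cls <- boxes[i, "left"]:boxes[i, "right"]
    patch <- g_mdisc[rows, cls, drop = FALSE]
    thr <- tryCatch(otsu_threshold(patch), error = function(e) NA_real_)
    fg <- if (is.na(thr)) matrix(FALSE, nrow(patch), ncol(patch))
          else patch > thr
    if (any(fg)) {
      idx <- which(fg, arr.ind = TRUE)
      out[i, ] <- c(mean(rows[idx[, 1L]]), mean(cls[idx[, 2L]]))
    } else {
      out[i, ] <- coarse_centers[i, ]
    }
  }
  out
}

#' Localize the intervertebral discs
#'
#' Full localization stage: disc feature image, elliptical median
#' filtering, row/column cumulative profiles with anatomical priors,
#' bounding boxes, tilt estimation and centroid correction.
#'
#' @param stack a feature stack from [apply_bank()] with `S = 16`.
#' @param curves a `spinal_curves` object from [detect_spine()].
#' @param priors a [disc_priors()] object.
#' @param median_axes template axes of the elliptical median filter
#'   (default `c(44, 17)`).
#' @return An object of class `disc_detections`: a list with
#'   `detections` (a data frame with columns disc_id, row, col,
#'   coarse_row, coarse_col, angle_deg, top, bottom, left, right),
#'   `g_disc`, `g_mdisc`, `gh` and `gv`.
#' @export
localize_discs <- function(stack, curves, priors = disc_priors(),
                           median_axes = c(44L, 17L)) {
  g_disc <- compute_disc_gfi(stack)
  g_mdisc <- elliptical_median(g_disc, median_axes[1L], median_axes[2L])
  gh <- row_profile(g_mdisc, curves)
  y <- candidate_rows(gh, priors)
  cc <- candidate_cols(g_mdisc, y, curves, priors)
  bx <- compute_boxes(gh, cc, y)
  n <- nrow(bx$boxes)
  if (n == 0L) stop_detection("all disc candidates were degenerate")
  coarse <- cbind(row = bx$y, col = as.numeric(bx$x))
  refined <- refine_centers(g_mdisc, bx$boxes, coarse)
  angles <- vapply(seq_len(n),
                   function(i) estimate_angle(stack, bx$boxes[i, ]),
                   numeric(1L))
  det <- data.frame(disc_id = seq_len(n),
                    row = refined[, "row"], col = refined[, "col"],
                    coarse_row = coarse[, "row"], coarse_col = coarse[, "col"],
                    angle_deg = angles,
                    top = bx$boxes[, "top"], bottom = bx$boxes[, "bottom"],
                    left = bx$boxes[, "left"], right = bx$boxes[, "right"])
  structure(list(detections = det, g_disc = g_disc, g_mdisc = g_mdisc,
                 gh = gh, gv = bx$gv),
            class = "disc_detections")
}

#' @export
print.disc_detections <- function(x, ...) {
  cat(sprintf("%d disc detections\n", nrow(x$detections)))
  print(round(x$detections[, c("disc_id", "row", "col", "angle_deg")], 1))
  invisible(x)
}
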