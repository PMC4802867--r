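#' Otsu's threshold
#'
#' Exhaustively maximizes the between-class variance of the two classes
#' `{x <= t}` and `{x > t}` over candidate cuts `t`.  For inputs with at
#' most 256 distinct values every observed level is a candidate cut (so
#' 8-bit images are thresholded exactly); otherwise the range is divided
#' into 256 equal bins and cuts are placed at bin upper edges.  Ties take
#' the lowest cut.
#'
#' @param values numeric vector, matrix or array of grayscale values with
#'   at least two distinct finite values.
#' @return The threshold `t`; foreground is conventionally `values > t`.
#' @export
otsu_threshold <- function(values) {
  x <- as.numeric(values)
  x <- x[is.finite(x)]
  ux <- sort(unique(x))
  if (length(ux) < 2L)
    stop("Otsu threshold undefined for constant input", call. = FALSE)
  if (length(ux) <= 256L) {
    levels <- ux
    counts <- tabulate(match(x, ux), nbins = length(ux))
  } else {
    brk <- seq(min(x), max(x), length.out = 257L)
    counts <- as.integer(table(cut(x, brk, include.lowest = TRUE)))
    levels <- brk[-1L]   # cut at bin upper edges
  }
  n <- sum(counts)
  w0 <- cumsum(counts) / n
  m <- cumsum(counts * levels) / n
  mt <- m[length(m)]
  # between-class variance for cut after level i (classes <=, >)
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, length(levels))
  sigma_b[valid] <- (mt * w0[valid] - m[valid])^2 / (w0[valid] * (1 - w0[valid]))
  levels[which.max(sigma_b)]
}

#' Build the per-disc segmentation candidate region
#'
#' The initial region is the disc's bounding box clipped to the spinal
#' curves.  Within the box, the direction with maximal scale-averaged
#' response is found; its response map is binarized by Otsu's threshold,
#' and quadratic curves fitted to the outermost foreground column on each
#' row become the left and right region boundaries (the top and bottom
#' remain the box rows, the columns stay clipped to the spinal curves).
#' If the binary map is empty or spans fewer than three rows the region
#' falls back to box intersected with the spine band.
#'
#' @param detection one row of the `detections` data frame from
#'   [localize_discs()] (needs top, bottom, left, right).
#' @param curves a `spinal_curves` object.
#' @param stack the feature stack of the image.
#' @param mode `"gfi"` (default) for the fitted feature-bounded region,
#'   `"box"` for the raw box-and-band region (used as the comparison
#'   baseline).
#' @param margin outward expansion of the fitted flank curves in pixels
#'   (default 8), compensating the spatial support of the filter
#'   envelope at the thresholded boundary's lateral tips.
#' @return An object of class `candidate_region`: list with logical
#'   `mask` (M x N), `box`, `mu_star`, `binary_area` (foreground pixel
#'   count of the thresholded direction map inside the box),
#'   `initial_area` (pixel count of box clipped to the spine band) and
#'   `boundary_fit` (quadratic coefficients, or NULL on fallback).
#' @export
build_candidate_region <- function(detection, curves, stack,
                                   mode = c("gfi", "box"), margin = 8L) {
  mode <- match.arg(mode)
  d <- stack_dims(stack)
  M <- d$M; N <- d$N
  box <- c(top = detection$top, bottom = detection$bottom,
           left = detection$left, right = detection$right)
  rows <- box["top"]:box["bottom"]
  cls <- box["left"]:box["right"]

  # direction of maximal scale-averaged energy inside the box
  sub <- stack[, , rows, cls, drop = FALSE]
  dim(sub) <- c(d$S, d$K, length(rows) * length(cls))
  energy <- apply(sub, 1L, mean)
  mu_star <- which.max(energy) - 1L
  map <- mean_direction_gfi(stack, mu_star)

  # binarize the whole direction map by Otsu (background-dominated, so
  # the cut stays low enough to keep the full boundary response), then
  # restrict to the box
  thr <- tryCatch(otsu_threshold(map), error = function(e) NA_real_)
  patch <- map[rows, cls, drop = FALSE]
  fg <- if (is.na(thr)) matrix(FALSE, length(rows), length(cls)) else patch > thr
  binary_area <- sum(fg)

  band_cols <- function(r) {
    l <- curves$left[r]; rr <- curves$right[r]
    if (is.na(l) || is.na(rr)) c(box["left"], box["right"]) else c(l, rr)
  }

  mask <- matrix(FALSE, M, N)
  boundary_fit <- NULL
  widths <- rowSums(fg)
  # fit the flank curves on the shoulder rows only (foreground width at
  # least half the maximum): the tapered tips of the boundary response
  # would otherwise pull the fitted curves inside the disc and collapse
  # the candidate region onto the disc itself
  fg_rows <- which(widths >= 0.5 * max(widths) & widths > 0L)
  if (mode == "gfi" && length(fg_rows) >= 3L) {
    lo <- apply(fg[fg_rows, , drop = FALSE], 1L, function(z) which(z)[1L])
    hi <- apply(fg[fg_rows, , drop = FALSE], 1L, function(z) max(which(z)))
    rf <- rows[fg_rows]
    fit_l <- stats::lm(y ~ x + I(x^2), data = data.frame(x = rf, y = cls[lo]))
    fit_r <- stats::lm(y ~ x + I(x^2), data = data.frame(x = rf, y = cls[hi]))
    pl <- stats::predict(fit_l, data.frame(x = rows))
    pr <- stats::predict(fit_r, data.frame(x = rows))
    # extrapolating a quadratic fitted on few rows can pinch the region
    # shut; never let the fitted flanks cut inside the foreground's
    # column span.  The span itself underestimates the structure's
    # lateral extent (the boundary response fades where the disc tip
    # turns vertical), so the flanks are pushed outward by `margin`
    # pixels, on the order of the bank's envelope support.
    pl <- pmin(pl, min(cls[lo])) - margin
    pr <- pmax(pr, max(cls[hi])) + margin
    for (i in seq_along(rows)) {
      r <- rows[i]
      bc <- band_cols(r)
      a <- max(box["left"], bc[1L], floor(pl[i]))
      b <- min(box["right"], bc[2L], ceiling(pr[i]))
      if (a <= b) mask[r, a:b] <- TRUE
    }
    boundary_fit <- list(left = stats::coef(fit_l), right = stats::coef(fit_r))
  } else {
    if (mode == "gfi")
      warning("empty feature map in box; falling back to box-and-band region",
              call. = FALSE)
    for (r in rows) {
      bc <- band_cols(r)
      a <- max(box["left"], bc[1L]); b <- min(box["right"], bc[2L])
      if (a <= b) mask[r, a:b] <- TRUE
    }
  }
  if (!any(mask)) {                 # last resort: the raw box
    for (r in rows) mask[r, cls] <- TRUE
  }
  # initial candidate region (box clipped to the spine band): the
  # reference for the area window A1 and for the initial Otsu threshold
  initial_mask <- matrix(FALSE, M, N)
  for (r in rows) {
    bc <- band_cols(r)
    a <- max(box["left"], bc[1L]); b <- min(box["right"], bc[2L])
    if (a <= b) initial_mask[r, a:b] <- TRUE
  }
  structure(list(mask = mask, box = box, mu_star = mu_star,
                 binary_area = binary_area,
                 initial_mask = initial_mask,
                 initial_area = sum(initial_mask),
                 boundary_fit = boundary_fit),
            class = "candidate_region")
}

#' Adaptive local threshold for one disc
#'
#' Starting from the Otsu threshold of the grayscale values inside the
#' initial candidate region, the threshold is adjusted by bisection until the
#' foreground area (pixels `>= T` inside the region) falls within the
#' area window `[T1, T2]`, where `A1` = initial candidate-region area
#' (box clipped to the spine band) minus the binary feature-map area,
#' `A2` = half the binary feature-map area,
#' `T1 = min(A1, A2)` and `T2 = max(A1, A2)`.  If the area is too large
#' the threshold is raised, if too small it is lowered; each step halves.
#' At most 30 iterations are performed, which guarantees termination.
#'
#' @param image the grayscale image matrix.
#' @param region a [build_candidate_region()] object.
#' @param max_iter iteration cap (default 30).
#' @return A list of class `threshold_state` with `T` (final threshold),
#'   `T_init`, `T1`, `T2`, `area` (final foreground area) and `iter`.
#' @export
adaptive_threshold <- function(image, region, max_iter = 30L) {
  vals <- image[region$mask]
  init_vals <- if (!is.null(region$initial_mask)) image[region$initial_mask]
               else vals
  area_region <- if (!is.null(region$initial_area)) region$initial_area
                 else sum(region$mask)
  # Otsu cut over the initial candidate region; the cut's classes are
  # {<= t} and {> t}, so the >=-convention threshold is the smallest
  # value strictly above the cut
  cut <- tryCatch(otsu_threshold(init_vals), error = function(e) init_vals[1L])
  above <- init_vals[init_vals > cut]
  T_init <- if (length(above) > 0L) min(above) else cut
  A_bin <- region$binary_area
  A1 <- area_region - A_bin
  if (A1 <= 0) {
    warning("candidate region not larger than the binary feature map; ",
            "clamping A1 to 10% of the region area", call. = FALSE)
    A1 <- 0.1 * area_region
  }
  A2 <- A_bin / 2
  T1 <- min(A1, A2); T2 <- max(A1, A2)
  # the adaptive threshold refines within the bright (disc) class: it
  # may never descend below the Otsu cut into the dark class, which
  # would flood the region with vertebra/background
  lo <- cut; hi <- max(vals)
  T <- T_init
  step <- (hi - lo) / 2
  iter <- 0L
  best_T <- T
  best_dist <- Inf
  repeat {
    area <- sum(vals >= T)
    dist <- max(T1 - area, area - T2, 0)
    if (dist < best_dist) { best_dist <- dist; best_T <- T }
    if (dist == 0 || iter >= max_iter) break
    iter <- iter + 1L
    T <- if (area > T2) T + step else T - step
    T <- max(lo, min(hi + .Machine$double.eps * abs(hi), T))
    step <- step / 2
  }
  # on cap exit with no attainable area in [T1, T2] (quantized images
  # can jump across the window), keep the visited threshold whose
  # foreground area came closest to the window
  T <- best_T
  structure(list(T = T, T_init = T_init, T1 = T1, T2 = T2,
                 area = sum(vals >= T), iter = iter),
            class = "threshold_state")
}

#' Coarse disc segmentation
#'
#' Thresholds the grayscale image at the adaptive threshold inside the
#' candidate region.
#'
#' @param image grayscale matrix.
#' @param region_mask logical matrix (the candidate region).
#' @param T_IVD threshold.
#' @return Logical mask.
#' @export
coarse_segment <- function(image, region_mask, T_IVD) {
  stopifnot(is.finite(T_IVD))
  (image >= T_IVD) & region_mask
}

shift_mat <- function(m, dr, dc, fill = FALSE) {
  M <- nrow(m); N <- ncol(m)
  out <- matrix(fill, M, N)
  rs <- max(1L, 1L + dr):min(M, M + dr)
  cs <- max(1L, 1L + dc):min(N, N + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

neighbor_count <- function(mask) {
  cnt <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    cnt <- cnt + shift_mat(mask, dr, dc)
  }
  cnt
}

#' Binary erosion with the 3 x 3 disc (cross) element
#' @param mask logical matrix.
#' @return Logical matrix.
#' @export
binary_erode <- function(mask) {
  mask & shift_mat(mask, 1L, 0L) & shift_mat(mask, -1L, 0L) &
    shift_mat(mask, 0L, 1L) & shift_mat(mask, 0L, -1L)
}

#' Binary dilation with the 3 x 3 disc (cross) element
#' @param mask logical matrix.
#' @return Logical matrix.
#' @export
binary_dilate <- function(mask) {
  mask | shift_mat(mask, 1L, 0L) | shift_mat(mask, -1L, 0L) |
    shift_mat(mask, 0L, 1L) | shift_mat(mask, 0L, -1L)
}

#' Fill interior holes of a binary mask
#'
#' Background components (4-connectivity) that do not touch the image
#' border are interior holes and become foreground.
#'
#' @param mask logical matrix.
#' @return Logical matrix.
#' @export
binary_fill_holes <- function(mask) {
  lab <- label_components_cpp(!mask, 4L)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

#' One-pass 8-neighbor majority promotion
#'
#' Background pixels with at least `k` foreground 8-neighbors (counted on
#' the input mask) become foreground.
#'
#' @param mask logical matrix.
#' @param k neighbor count threshold (default 5).
#' @return Logical matrix.
#' @export
majority_filter <- function(mask, k = 5L) {
  mask | (!mask & neighbor_count(mask) >= k)
}

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels, 0 = background, components numbered
#'   from 1 in column-major first-encounter order.
#' @export
label_components <- function(mask, connectivity = 8L) {
  label_components_cpp(mask, as.integer(connectivity))
}

#' Keep the largest 8-connected component
#' @param mask logical matrix.
#' @return Logical matrix (all FALSE if the input is empty).
#' @export
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label_components_cpp(mask, 8L)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Morphological post-processing of a coarse disc mask
#'
#' Applies, in order: hole filling, erosion and dilation with a 3 x 3
#' disc element, one-pass promotion of background pixels with at least
#' five foreground 8-neighbors, and retention of the largest 8-connected
#' component.
#'
#' @param mask logical matrix (coarse segmentation).
#' @return Logical matrix that is a single connected component, or empty
#'   (with a warning) if the input was empty.
#' @export
postprocess_mask <- function(mask) {
  if (!any(mask)) {
    warning("empty coarse mask: nothing to post-process", call. = FALSE)
    return(mask)
  }
  m <- binary_fill_holes(mask)
  m <- binary_erode(m)
  m <- binary_dilate(m)
  m <- majority_filter(m, 5L)
  if (!any(m)) {
    warning("mask vanished during post-processing", call. = FALSE)
    return(m)
  }
  largest_component(m)
}

#' Segment all localized discs
#'
#' For each detection: build the candidate region, compute the adaptive
#' local threshold, take the coarse segmentation and post-process it.
#'
#' @param image grayscale matrix.
#' @param stack the feature stack of the image.
#' @param curves a `spinal_curves` object.
#' @param detections a `disc_detections` object (or its `detections`
#'   data frame).
#' @param region_mode `"gfi"` (default) or `"box"`, see
#'   [build_candidate_region()].
#' @return A list of class `disc_segmentation`; one element per disc with
#'   `mask`, `coarse_mask`, `region`, `threshold` (a `threshold_state`)
#'   and `disc_id`.
#' @export
segment_discs <- function(image, stack, curves, detections,
                          region_mode = c("gfi", "box")) {
  region_mode <- match.arg(region_mode)
  det <- if (inherits(detections, "disc_detections")) detections$detections
         else detections
  out <- vector("list", nrow(det))
  for (i in seq_len(nrow(det))) {
    region <- build_candidate_region(det[i, ], curves, stack,
                                     mode = region_mode)
    st <- adaptive_threshold(image, region)
    coarse <- coarse_segment(image, region$mask, st$T)
    final <- suppressWarnings(postprocess_mask(coarse))
    out[[i]] <- list(mask = final, coarse_mask = coarse, region = region,
                     threshold = st, disc_id = det$disc_id[i])
  }
  structure(out, class = "disc_segmentation")
}
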