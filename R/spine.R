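#' Spine-edge Gabor feature image
#'
#' The spinal edges are nearly vertical, so the spine feature image is the
#' clipped difference between the mean response of near-vertical
#' directions `U1 = {0,1,2,3,4,5,14,15}` and near-horizontal directions
#' `U2 = {7,8,9,10,11}` (0-based, 16-direction bank).
#'
#' @param stack a feature stack from [apply_bank()] with `S = 16`.
#' @return A nonnegative `M x N` matrix.
#' @export
compute_spine_gfi <- function(stack) {
  d <- stack_dims(stack)
  if (d$S != 16L)
    stop("spine feature image requires a 16-direction bank", call. = FALSE)
  directional_feature(stack, c(0:5, 14:15), 7:11)
}

# rows of the central horizontal band of height p
band_rows <- function(M, p) {
  p <- as.integer(p)
  if (p < 1L || p > M) stop("band height p out of range", call. = FALSE)
  r0 <- (M - p) %/% 2L + 1L
  r0:(r0 + p - 1L)
}

#' Banded cumulative column sum
#'
#' `G_cum(n)` is the sum of the spine feature image over the first `n`
#' columns, restricted to the central band of `p` rows (the middle of the
#' spine is nearly straight, so this band isolates the two edge ridges).
#' The result is nondecreasing because the feature image is nonnegative;
#' its slope is flat over background and over the spine interior, and
#' steep where an edge ridge crosses the band.
#'
#' @param g_spine nonnegative matrix from [compute_spine_gfi()].
#' @param p band height in rows, `1 <= p <= M`.
#' @return Numeric vector of length `N`.
#' @export
banded_cumulative <- function(g_spine, p) {
  rows <- band_rows(nrow(g_spine), p)
  cumsum(colSums(g_spine[rows, , drop = FALSE]))
}

#' Locate the spine center and the edge crossing points
#'
#' The per-column band energy (the discrete slope of `G_cum`) is flat
#' both over background and between the two edge ridges; the spine
#' interior is identified as the longest low-slope plateau that does not
#' touch the image borders (border-touching plateaus are background).
#' The spine center column is the plateau midpoint.  The left/right edge
#' centers are then found from the band-averaged column profile of the
#' feature image: moving outward from the center on each side, the
#' outermost local maximum above the profile's Otsu threshold marks the
#' edge-ridge crest (disc ends shed energy just inside the true edge, so
#' the outermost crest, not the first above-threshold column, is the
#' edge).
#'
#' @param g_spine nonnegative matrix from [compute_spine_gfi()].
#' @param p band height in rows (default `floor(M/3)`).
#' @param plateau_frac slope-threshold fraction of the mean slope
#'   (default 0.25).
#' @return A list of class `spine_centers` with `center_col`,
#'   `left_center`, `right_center` (each center a `c(row, col)` pair),
#'   `mid_row`, `G_cum`, `p` and the `edge_threshold` used.
#' @export
find_centers <- function(g_spine, p = max(1L, nrow(g_spine) %/% 3L),
                         plateau_frac = 0.25) {
  M <- nrow(g_spine); N <- ncol(g_spine)
  rows <- band_rows(M, p)
  G_cum <- banded_cumulative(g_spine, p)
  slope <- diff(c(0, G_cum))      # per-column band energy
  if (max(slope) <= 0)
    stop_detection("blank band: no spine-edge energy in the central band")
  low <- slope < plateau_frac * mean(slope)
  runs <- rle(low)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  interior <- runs$values & starts > 1L & ends < N
  if (!any(interior))
    stop_detection("no interior low-slope plateau found in G_cum")
  best <- which(interior)[which.max(runs$lengths[interior])]
  center_col <- as.integer(round((starts[best] + ends[best]) / 2))

  profile <- colMeans(g_spine[rows, , drop = FALSE])
  thr <- tryCatch(otsu_threshold(profile),
                  error = function(e) stop_detection(
                    "band column profile is constant; cannot threshold edges"))
  mid_row <- rows[(length(rows) + 1L) %/% 2L]

  peaks <- local_peaks(profile)
  peaks <- peaks[profile[peaks] > thr]
  # above-threshold runs; the ridge is the run nearest the center on
  # each side, its outermost crest is the edge
  ab <- profile > thr
  runs2 <- rle(ab)
  e2 <- cumsum(runs2$lengths)
  s2 <- e2 - runs2$lengths + 1L
  s2 <- s2[runs2$values]; e2 <- e2[runs2$values]
  ridge_cross <- function(side) {
    if (side < 0) { idx <- which(s2 < center_col) } else { idx <- which(e2 > center_col) }
    if (length(idx) == 0L) return(NA_integer_)
    run <- if (side < 0) idx[length(idx)] else idx[1L]
    lo <- s2[run]; hi <- min(e2[run], N)
    pk <- peaks[peaks >= lo & peaks <= hi]
    if (side < 0) {
      if (length(pk) > 0L) min(pk) else lo
    } else {
      if (length(pk) > 0L) max(pk) else hi
    }
  }
  left_col <- ridge_cross(-1L)
  right_col <- ridge_cross(1L)
  if (is.na(left_col) || is.na(right_col) || left_col >= right_col)
    stop_detection("no spine-edge crossings found on the band midline")
  structure(list(center_col = center_col,
                 left_center = c(row = mid_row, col = left_col),
                 right_center = c(row = mid_row, col = right_col),
                 mid_row = mid_row, G_cum = G_cum, p = as.integer(p),
                 edge_threshold = thr),
            class = "spine_centers")
}

# trace one edge ridge up and down from (row0, col0); returns a length-M
# vector of columns with NA where the track was lost, plus last good rows
trace_one <- function(g_spine, row0, col0, w, patience, floor_val) {
  M <- nrow(g_spine); N <- ncol(g_spine)
  cols <- rep(NA_integer_, M)
  cols[row0] <- col0
  for (dir in c(-1L, 1L)) {
    pos <- col0
    miss <- 0L
    r <- row0 + dir
    while (r >= 1L && r <= M) {
      # widen the window while the track is lost so the ridge can be
      # re-acquired once an occluding structure has passed
      wr <- w * (1L + miss)
      lo <- max(1L, pos - wr); hi <- min(N, pos + wr)
      win <- g_spine[r, lo:hi]
      # among near-tied responses prefer the column closest to the
      # previous position, so the track does not drift onto disc ends
      near <- which(win >= 0.9 * max(win))
      j <- near[which.min(abs(lo + near - 1L - pos))]
      if (win[j] > floor_val) {
        pos <- lo + j - 1L
        miss <- 0L
        cols[r] <- pos
      } else {
        miss <- miss + 1L
        if (miss > patience) break
        cols[r] <- pos        # hold position while patience lasts
      }
      r <- r + dir
    }
    if (miss > 0L) {
      # wipe the held tail so valid rows end at the last confident row
      bad <- if (dir < 0L) (r + 1L):(r + miss) else (r - miss):(r - 1L)
      bad <- bad[bad >= 1L & bad <= M]
      cols[bad] <- NA_integer_
    }
  }
  cols
}

#' Trace the left and right spinal edge curves
#'
#' Starting from the edge centers found on the band midline, each edge is
#' tracked row by row upward and downward: at every row the feature-image
#' local maximum within a `+/- w` column window around the previous row's
#' position is taken.  If no response above a floor is seen for more than
#' `patience` consecutive rows the track is truncated there.
#'
#' @param g_spine nonnegative matrix from [compute_spine_gfi()].
#' @param centers a `spine_centers` object from [find_centers()], or a
#'   list with `left_center` and `right_center` `c(row, col)` pairs.
#' @param w half-width of the column search window (default 3).
#' @param patience consecutive low-response rows tolerated before the
#'   track is truncated (default 10).
#' @param floor_frac response floor as a fraction of `max(g_spine)`
#'   (default 0.02).
#' @return An object of class `spinal_curves`: `left` and `right`
#'   length-`M` column vectors (NA outside `valid_rows`) and
#'   `valid_rows = c(first, last)`.
#' @export
trace_curves <- function(g_spine, centers, w = 3L, patience = 10L,
                         floor_frac = 0.02) {
  floor_val <- floor_frac * max(g_spine)
  lc <- centers$left_center; rc <- centers$right_center
  left <- trace_one(g_spine, lc[["row"]], lc[["col"]], w, patience, floor_val)
  right <- trace_one(g_spine, rc[["row"]], rc[["col"]], w, patience, floor_val)
  ok <- which(!is.na(left) & !is.na(right) & left < right)
  if (length(ok) == 0L)
    stop_detection("spinal curve tracking lost on every row")
  # largest contiguous run of jointly valid rows containing the midline
  runs <- split(ok, cumsum(c(1L, diff(ok) != 1L)))
  lens <- vapply(runs, length, 1L)
  keep <- runs[[which.max(lens)]]
  left[setdiff(seq_along(left), keep)] <- NA_integer_
  right[setdiff(seq_along(right), keep)] <- NA_integer_
  if (length(keep) < length(ok))
    warning("spinal curves truncated to rows ",
            min(keep), "..", max(keep), call. = FALSE)
  structure(list(left = left, right = right,
                 valid_rows = c(min(keep), max(keep))),
            class = "spinal_curves")
}

#' Detect the spinal curves from a feature stack
#'
#' Convenience wrapper running [compute_spine_gfi()], [find_centers()]
#' and [trace_curves()].
#'
#' @param stack a feature stack from [apply_bank()] with `S = 16`.
#' @param p band height in rows (default `floor(M/3)`).
#' @param ... passed on to [find_centers()] and [trace_curves()]
#'   (`plateau_frac`, `w`, `patience`, `floor_frac`).
#' @return A list with `g_spine`, `centers` and `curves`.
#' @export
detect_spine <- function(stack, p = NULL, ...) {
  g_spine <- compute_spine_gfi(stack)
  if (is.null(p)) p <- max(1L, nrow(g_spine) %/% 3L)
  dots <- list(...)
  fc_args <- dots[names(dots) %in% "plateau_frac"]
  tc_args <- dots[names(dots) %in% c("w", "patience", "floor_frac")]
  centers <- do.call(find_centers, c(list(g_spine, p = p), fc_args))
  curves <- do.call(trace_curves, c(list(g_spine, centers), tc_args))
  list(g_spine = g_spine, centers = centers, curves = curves)
}

# condition class for detection failures so callers can distinguish them
stop_detection <- function(msg) {
  stop(structure(class = c("discgabor_detection_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}
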