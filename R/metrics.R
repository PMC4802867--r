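#' Localization accuracy
#'
#' Percentage of automatically localized disc centers that lie inside the
#' reference disc: `100 * n_correct / n_detected`.
#'
#' @param n_correct number of correct detections.
#' @param n_detected total number of detections (>= 1).
#' @return Percentage in `[0, 100]`.
#' @export
localization_accuracy <- function(n_correct, n_detected) {
  if (n_detected < 1L)
    stop("accuracy undefined with zero detections", call. = FALSE)
  if (n_correct > n_detected || n_correct < 0L)
    stop("need 0 <= n_correct <= n_detected", call. = FALSE)
  100 * n_correct / n_detected
}

as_mask <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "logical"
  m
}

#' Segmentation sensitivity
#'
#' `|M intersect A| / |M|` for reference mask `M` and automatic mask `A`.
#'
#' @param M_mask,A_mask logical matrices of equal size.
#' @return Ratio in `[0, 1]`.
#' @export
sensitivity <- function(M_mask, A_mask) {
  M <- as_mask(M_mask); A <- as_mask(A_mask)
  stopifnot(all(dim(M) == dim(A)))
  nM <- sum(M)
  if (nM == 0L) stop("sensitivity undefined for empty reference mask",
                     call. = FALSE)
  sum(M & A) / nM
}

#' Segmentation specificity
#'
#' `(|I| - |M union A|) / (|I| - |M|)` where `I` is the image extent.
#'
#' @param M_mask,A_mask logical matrices of equal size.
#' @param image_extent total pixel count `|I|`; defaults to the mask
#'   size.
#' @return Ratio in `[0, 1]`.
#' @export
specificity <- function(M_mask, A_mask, image_extent = length(M_mask)) {
  M <- as_mask(M_mask); A <- as_mask(A_mask)
  stopifnot(all(dim(M) == dim(A)))
  nI <- image_extent
  nM <- sum(M)
  if (nI <= nM) stop("specificity undefined when the reference fills the image",
                     call. = FALSE)
  (nI - sum(M | A)) / (nI - nM)
}

#' Dice similarity index
#'
#' `2 |M intersect A| / (|M| + |A|)`.
#'
#' @param M_mask,A_mask logical matrices of equal size.
#' @return Ratio in `[0, 1]`.
#' @export
dice <- function(M_mask, A_mask) {
  M <- as_mask(M_mask); A <- as_mask(A_mask)
  stopifnot(all(dim(M) == dim(A)))
  s <- sum(M) + sum(A)
  if (s == 0L) stop("Dice undefined for two empty masks", call. = FALSE)
  2 * sum(M & A) / s
}

#' Euclidean center-distance statistics
#'
#' Matches detected centers to reference centers by greedy global
#' nearest-neighbor assignment (each reference used at most once) within
#' a gate, and summarizes the matched Euclidean distances in pixels and,
#' when a pixel spacing is given, millimetres.  Unmatched detections and
#' references are reported, never silently dropped.
#'
#' @param detected,reference two-column matrices (row, col).
#' @param pixel_spacing mm per pixel or `NULL`.
#' @param gate maximum matching distance in pixels (default 30).
#' @return A list with `pairs` (data frame det, ref, dist_px, dist_mm),
#'   `unmatched_detected`, `unmatched_reference`, and `summary`
#'   (mean/sd/median/max/min of distances, px and mm).
#' @export
center_distances <- function(detected, reference, pixel_spacing = NULL,
                             gate = 30) {
  det <- matrix(as.numeric(detected), ncol = 2L)
  ref <- matrix(as.numeric(reference), ncol = 2L)
  nd <- nrow(det); nr <- nrow(ref)
  D <- outer(seq_len(nd), seq_len(nr), function(i, j)
    sqrt((det[i, 1L] - ref[j, 1L])^2 + (det[i, 2L] - ref[j, 2L])^2))
  D <- matrix(D, nd, nr)
  pairs <- data.frame(det = integer(0), ref = integer(0),
                      dist_px = numeric(0))
  free_d <- rep(TRUE, nd); free_r <- rep(TRUE, nr)
  repeat {
    W <- D
    W[!free_d, ] <- Inf
    W[, !free_r] <- Inf
    if (all(!is.finite(W)) || min(W) > gate) break
    ij <- arrayInd(which.min(W), dim(W))
    pairs <- rbind(pairs, data.frame(det = ij[1L], ref = ij[2L],
                                     dist_px = D[ij[1L], ij[2L]]))
    free_d[ij[1L]] <- FALSE
    free_r[ij[2L]] <- FALSE
  }
  pairs$dist_mm <- if (is.null(pixel_spacing)) NA_real_
                   else pairs$dist_px * pixel_spacing
  summarize <- function(x) if (length(x) == 0L || all(is.na(x)))
    c(mean = NA_real_, sd = NA_real_, median = NA_real_,
      max = NA_real_, min = NA_real_)
    else c(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
           max = max(x), min = min(x))
  list(pairs = pairs,
       unmatched_detected = which(free_d),
       unmatched_reference = which(free_r),
       summary = list(px = summarize(pairs$dist_px),
                      mm = summarize(pairs$dist_mm)))
}

# is a point inside the (rotated-ellipse) ground-truth mask of any disc?
center_inside_mask <- function(center, mask) {
  r <- as.integer(round(center[1L])); c <- as.integer(round(center[2L]))
  r >= 1L && r <= nrow(mask) && c >= 1L && c <= ncol(mask) && mask[r, c]
}

#' Evaluate detections and segmentations against phantom ground truth
#'
#' Matches detected centers to true centers, scores the localization
#' accuracy (a center is correct when it lies inside the true disc
#' mask), and computes per-disc Dice, sensitivity, specificity and
#' center distances for the matched pairs.
#'
#' @param detections a `disc_detections` object (or its data frame).
#' @param segmentation optional `disc_segmentation` object aligned with
#'   the detections.
#' @param truth a `phantom_truth` object from [phantom_generate()].
#' @param pixel_spacing mm per pixel or `NULL`.
#' @param gate matching gate in pixels (default 30).
#' @return A list of class `eval_report` with `acc`, `per_disc` (data
#'   frame), `distances` (from [center_distances()]), `n_detected`,
#'   `n_true`.
#' @export
evaluate_phantom <- function(detections, segmentation = NULL, truth,
                             pixel_spacing = NULL, gate = 30) {
  det <- if (inherits(detections, "disc_detections")) detections$detections
         else detections
  centers <- cbind(det$row, det$col)
  true_centers <- truth$centers
  cd <- center_distances(centers, true_centers, pixel_spacing, gate)
  n_det <- nrow(centers)
  correct <- logical(n_det)
  for (i in seq_len(n_det)) {
    inside <- vapply(truth$disc_masks,
                     function(m) center_inside_mask(centers[i, ], m),
                     logical(1L))
    correct[i] <- any(inside)
  }
  acc <- localization_accuracy(sum(correct), n_det)

  per <- data.frame(det = cd$pairs$det, ref = cd$pairs$ref,
                    dist_px = cd$pairs$dist_px, dist_mm = cd$pairs$dist_mm,
                    sen = NA_real_, spe = NA_real_, dsi = NA_real_)
  if (!is.null(segmentation)) {
    for (k in seq_len(nrow(per))) {
      A <- segmentation[[per$det[k]]]$mask
      M <- truth$disc_masks[[per$ref[k]]]
      if (any(A)) {
        per$sen[k] <- sensitivity(M, A)
        per$spe[k] <- specificity(M, A)
        per$dsi[k] <- dice(M, A)
      } else {
        per$sen[k] <- 0; per$dsi[k] <- 0
        per$spe[k] <- specificity(M, A)
      }
    }
  }
  structure(list(acc = acc, per_disc = per, distances = cd,
                 n_detected = n_det, n_true = nrow(true_centers)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Detections: %d of %d true discs; Acc = %.2f%%\n",
              x$n_detected, x$n_true, x$acc))
  s <- x$distances$summary$px
  cat(sprintf("Center distance (px): mean %.2f, sd %.2f, median %.2f, max %.2f\n",
              s["mean"], s["sd"], s["median"], s["max"]))
  if (!all(is.na(x$per_disc$dsi)))
    cat(sprintf("Mean DSI %.4f, Sen %.4f, Spe %.4f\n",
                mean(x$per_disc$dsi, na.rm = TRUE),
                mean(x$per_disc$sen, na.rm = TRUE),
                mean(x$per_disc$spe, na.rm = TRUE)))
  invisible(x)
}
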