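#' Default pipeline configuration
#'
#' Flat list of every tunable parameter with the published defaults:
#' 16 directions, 5 scales, `omega_max = pi/2`, `f = 2^(1/4)`, 31 x 31
#' kernels, 44 x 17 median template, 25--60 px spacing prior, 30
#' threshold iterations.
#'
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    S = 16L, K = 5L, omega_max = pi / 2, f = 2^(1 / 4), window = 31L,
    response = "magnitude",
    band_p_frac = 1 / 3, plateau_frac = 0.25,
    track_w = 3L, track_patience = 10L, floor_frac = 0.02,
    min_dy = 25, max_dy = 60, x_alignment_tol = 15, angle_range = 30,
    median_long = 44L, median_minor = 17L,
    max_iter = 30L, region_mode = "gfi",
    pixel_spacing = NA_real_
  ), class = "pipeline_config")
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored.  Values are coerced to the type of the default entry;
#' unknown keys are an error.
#'
#' @param path configuration file.
#' @param base configuration to override (default [default_config()]).
#' @return A `pipeline_config` list.
#' @export
read_config <- function(path, base = default_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(base)) stop("unknown config key: ", key, call. = FALSE)
    base[[key]] <- if (is.character(base[[key]])) val
      else if (is.integer(base[[key]])) as.integer(val)
      else as.numeric(val)
  }
  validate_config(base)
}

validate_config <- function(config) {
  stopifnot(config$S >= 2L, config$K >= 1L, config$window %% 2L == 1L,
            config$omega_max > 0, config$f > 1,
            config$min_dy > 0, config$min_dy < config$max_dy,
            config$max_iter >= 1L,
            config$region_mode %in% c("gfi", "box"),
            config$response %in% c("magnitude", "real"))
  config
}

config_priors <- function(config) {
  ps <- config$pixel_spacing
  if (!is.null(ps) && is.finite(ps) && ps > 0)
    disc_priors(x_alignment_tol = config$x_alignment_tol,
                angle_range = config$angle_range, pixel_spacing = ps)
  else
    disc_priors(min_dy = config$min_dy, max_dy = config$max_dy,
                x_alignment_tol = config$x_alignment_tol,
                angle_range = config$angle_range)
}

#' Run the full localization and segmentation pipeline
#'
#' Executes, in order: Gabor filter bank, spinal curve detection, disc
#' localization and disc segmentation, plus evaluation when ground truth
#' is available.
#'
#' @param image a grayscale matrix or a path readable by [read_image()].
#' @param config a `pipeline_config` list.
#' @param truth optional `phantom_truth` for evaluation.
#' @param pixel_spacing mm per pixel, overriding the config / file
#'   metadata.
#' @param keep_stack keep the (large) feature stack in the result
#'   (default `FALSE`).
#' @return A list of class `pipeline_result` with `image`, `spine`,
#'   `localization`, `segmentation`, `report` (or `NULL`), `config` and
#'   `pixel_spacing`.
#' @export
run_pipeline <- function(image, config = default_config(), truth = NULL,
                         pixel_spacing = NULL, keep_stack = FALSE) {
  config <- validate_config(config)
  if (is.character(image)) image <- read_image(image)
  if (is.null(pixel_spacing)) {
    ps <- attr(image, "pixel_spacing")
    pixel_spacing <- if (!is.null(ps) && is.finite(ps)) ps
      else if (is.finite(config$pixel_spacing)) config$pixel_spacing
      else NULL
  }
  params <- gabor_bank_params(S = config$S, K = config$K,
                              omega_max = config$omega_max, f = config$f,
                              window = config$window,
                              response = config$response)
  stack <- apply_bank(image, build_bank(params))
  spine <- detect_spine(stack,
                        p = max(1L, as.integer(nrow(image) * config$band_p_frac)),
                        plateau_frac = config$plateau_frac,
                        w = config$track_w, patience = config$track_patience,
                        floor_frac = config$floor_frac)
  loc <- localize_discs(stack, spine$curves, config_priors(config),
                        median_axes = c(config$median_long, config$median_minor))
  seg <- segment_discs(image, stack, spine$curves, loc,
                       region_mode = config$region_mode)
  report <- if (!is.null(truth))
    evaluate_phantom(loc, seg, truth, pixel_spacing) else NULL
  out <- list(image = image, spine = spine, localization = loc,
              segmentation = seg, report = report, config = config,
              pixel_spacing = pixel_spacing)
  if (keep_stack) out$stack <- stack
  structure(out, class = "pipeline_result")
}

#' Combined 16-bit label mask of a segmentation
#'
#' @param segmentation a `disc_segmentation` object.
#' @param dims image dimensions `c(M, N)`.
#' @return Integer matrix; pixel value `k` marks disc `k`, 0 background.
#' @export
label_mask <- function(segmentation, dims) {
  lab <- matrix(0L, dims[1L], dims[2L])
  for (s in segmentation) lab[s$mask] <- s$disc_id
  lab
}

#' Write the pipeline output files
#'
#' Writes `centers.csv` (disc_id, row, col, angle_deg), `labels.pgm`
#' (16-bit label mask, label k = disc k), `overlay.ppm` (image with
#' segmentation contours and centers in green/red) and, when a report is
#' present, `report.json`.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- result$localization$detections
  utils::write.csv(det[, c("disc_id", "row", "col", "angle_deg")],
                   file.path(dir, "centers.csv"), row.names = FALSE)
  dims <- dim(result$image)
  lab <- label_mask(result$segmentation, dims)
  write_pgm(lab, file.path(dir, "labels.pgm"), maxval = 65535L)

  img <- result$image
  rng <- range(img)
  g8 <- if (diff(rng) > 0) (img - rng[1L]) / diff(rng) * 255 else img * 0
  r <- g8; g <- g8; b <- g8
  edge <- (lab > 0L) & !(binary_erode(lab > 0L))
  r[edge] <- 0; g[edge] <- 255; b[edge] <- 0
  for (i in seq_len(nrow(det))) {
    rr <- as.integer(round(det$row[i])); cc <- as.integer(round(det$col[i]))
    rs <- max(1L, rr - 2L):min(dims[1L], rr + 2L)
    cs <- max(1L, cc - 2L):min(dims[2L], cc + 2L)
    r[rs, cc] <- 255; g[rs, cc] <- 0; b[rs, cc] <- 0
    r[rr, cs] <- 255; g[rr, cs] <- 0; b[rr, cs] <- 0
  }
  write_ppm(r, g, b, file.path(dir, "overlay.ppm"))

  if (!is.null(result$report)) {
    rep <- result$report
    jsonlite::write_json(list(
      acc = rep$acc, n_detected = rep$n_detected, n_true = rep$n_true,
      per_disc = rep$per_disc,
      distance_summary_px = as.list(rep$distances$summary$px),
      distance_summary_mm = as.list(rep$distances$summary$mm)),
      file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  invisible(dir)
}

#' Run the pipeline over a suite of phantoms
#'
#' Generates `n` phantoms with seeds derived from `seed`, runs the full
#' pipeline on each, and aggregates localization accuracy, center
#' distances, Dice/sensitivity/specificity and (optionally) the paired
#' comparison of Dice with the feature-bounded candidate region versus
#' the raw box-and-band region.
#'
#' @param n number of phantoms (default 20).
#' @param seed base seed; phantom `i` uses `seed * 1000 + i`.
#' @param noise_sigma phantom noise level (fraction of dynamic range).
#' @param spec_args extra arguments passed to [phantom_spec()].
#' @param config a `pipeline_config` list.
#' @param compare_box also segment with `region_mode = "box"` and record
#'   the paired Dice (default `TRUE`).
#' @return A list of class `suite_report` with `per_phantom` (data
#'   frame), `acc` (pooled accuracy, percent), `mean_dsi`, `mean_sen`,
#'   `mean_spe`, `mean_dsi_box`, `distance_px` (pooled summary),
#'   `single_component` (fraction of final masks that are one connected
#'   component) and `max_threshold_iter`.
#' @export
run_suite <- function(n = 20L, seed = 1L, noise_sigma = 0,
                      spec_args = list(), config = default_config(),
                      compare_box = TRUE) {
  stopifnot(n >= 1L)
  rows <- vector("list", n)
  all_d <- numeric(0); all_dsi <- numeric(0); all_sen <- numeric(0)
  all_spe <- numeric(0); all_dsi_box <- numeric(0)
  n_correct <- 0L; n_detected <- 0L
  comp_ok <- 0L; comp_n <- 0L; max_iter_seen <- 0L
  for (i in seq_len(n)) {
    sargs <- utils::modifyList(list(noise_sigma = noise_sigma,
                                    seed = (seed %% 1000000L) * 1000L + i),
                               spec_args)
    truth <- phantom_generate(do.call(phantom_spec, sargs))
    res <- run_pipeline(truth$image, config, truth = truth, keep_stack = TRUE)
    rep <- res$report
    centers <- cbind(res$localization$detections$row,
                     res$localization$detections$col)
    inside <- vapply(seq_len(nrow(centers)), function(k)
      any(vapply(truth$disc_masks, function(m)
        center_inside_mask(centers[k, ], m), logical(1L))), logical(1L))
    n_correct <- n_correct + sum(inside)
    n_detected <- n_detected + length(inside)
    all_d <- c(all_d, rep$per_disc$dist_px)
    all_dsi <- c(all_dsi, rep$per_disc$dsi)
    all_sen <- c(all_sen, rep$per_disc$sen)
    all_spe <- c(all_spe, rep$per_disc$spe)
    for (s in res$segmentation) {
      comp_n <- comp_n + 1L
      if (any(s$mask)) {
        lab <- label_components_cpp(s$mask, 8L)
        if (max(lab) == 1L) comp_ok <- comp_ok + 1L
      }
      max_iter_seen <- max(max_iter_seen, s$threshold$iter)
    }
    dsi_box_i <- NA_real_
    if (compare_box) {
      seg_box <- segment_discs(truth$image, res$stack, res$spine$curves,
                               res$localization, region_mode = "box")
      rep_box <- evaluate_phantom(res$localization, seg_box, truth)
      dsi_box_i <- mean(rep_box$per_disc$dsi, na.rm = TRUE)
      all_dsi_box <- c(all_dsi_box, rep_box$per_disc$dsi)
    }
    rows[[i]] <- data.frame(
      phantom = i, seed = sargs$seed, n_true = rep$n_true,
      n_detected = rep$n_detected, n_inside = sum(inside),
      mean_dist_px = mean(rep$per_disc$dist_px),
      mean_dsi = mean(rep$per_disc$dsi, na.rm = TRUE),
      mean_sen = mean(rep$per_disc$sen, na.rm = TRUE),
      mean_spe = mean(rep$per_disc$spe, na.rm = TRUE),
      mean_dsi_box = dsi_box_i)
  }
  per <- do.call(rbind, rows)
  structure(list(
    per_phantom = per,
    acc = localization_accuracy(n_correct, n_detected),
    mean_dsi = mean(all_dsi, na.rm = TRUE),
    mean_sen = mean(all_sen, na.rm = TRUE),
    mean_spe = mean(all_spe, na.rm = TRUE),
    mean_dsi_box = if (compare_box) mean(all_dsi_box, na.rm = TRUE)
                   else NA_real_,
    distance_px = c(mean = mean(all_d), sd = stats::sd(all_d),
                    median = stats::median(all_d), max = max(all_d),
                    min = min(all_d)),
    single_component = comp_ok / comp_n,
    max_threshold_iter = max_iter_seen,
    n = n, seed = seed, noise_sigma = noise_sigma
  ), class = "suite_report")
}

#' @export
print.suite_report <- function(x, ...) {
  cat(sprintf("Phantom suite: n = %d, noise sigma = %.3f, seed = %d\n",
              x$n, x$noise_sigma, x$seed))
  cat(sprintf("  Localization Acc = %.2f%%, mean center error = %.2f px\n",
              x$acc, x$distance_px["mean"]))
  cat(sprintf("  Mean DSI = %.4f (box-only region: %.4f), Sen = %.4f, Spe = %.4f\n",
              x$mean_dsi, x$mean_dsi_box, x$mean_sen, x$mean_spe))
  cat(sprintf("  Single-component masks: %.1f%%, max threshold iterations: %d\n",
              100 * x$single_component, x$max_threshold_iter))
  invisible(x)
}
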