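#' Measurement pipeline configuration
#'
#' Bundles the tunable parameters of the measurement and counting
#' pipelines. The two threshold specifications reflect the two tasks:
#' a 140/255 cutoff segments whole seeds for length/width, and a stricter
#' 170/255 cutoff is used for projected area and counting, where faint
#' background noise must not register.
#'
#' @param size_threshold [threshold_spec()] for the length/width mask
#'   (default `threshold_spec(140, 255)`).
#' @param area_threshold [threshold_spec()] for the projected-area and
#'   counting mask (default `threshold_spec(170, 255)`).
#' @param n_seeds Expected number of seeds per image (`>= 1`); the `n_seeds`
#'   largest contours are measured, everything smaller is treated as noise.
#' @param morphology [morphology_spec()] used where dilation is enabled.
#' @param min_contour_area_px Noise floor in pixels: contours below this
#'   area are never counted or measured (default 25, well below any
#'   plausible seed at a sane calibration).
#' @param dilate_for_measure Apply dilation before the measurement
#'   thresholds? Default `FALSE` (the measurement chain thresholds the raw
#'   grayscale image).
#' @param dilate_for_count Apply dilation before the counting threshold?
#'   Default `TRUE` (the counting chain dilates first).
#' @param rect_method [bounding_rectangle()] convention: `"rotated"`
#'   (principal-axes rectangle, default), `"minarea"` (strict minimum-area
#'   rectangle), or `"axis"` (axis-aligned box).
#' @return A `measure_config` object.
#' @export
measure_config <- function(size_threshold = threshold_spec(140L, 255L),
                           area_threshold = threshold_spec(170L, 255L),
                           n_seeds = 1L,
                           morphology = morphology_spec(3L, 1L),
                           min_contour_area_px = 25L,
                           dilate_for_measure = FALSE,
                           dilate_for_count = TRUE,
                           rect_method = c("rotated", "minarea", "axis")) {
  n_seeds <- as.integer(n_seeds)
  min_contour_area_px <- as.integer(min_contour_area_px)
  if (is.na(n_seeds) || n_seeds < 1L) stop("n_seeds must be >= 1", call. = FALSE)
  if (is.na(min_contour_area_px) || min_contour_area_px < 0L)
    stop("min_contour_area_px must be >= 0", call. = FALSE)
  stopifnot(inherits(size_threshold, "threshold_spec"),
            inherits(area_threshold, "threshold_spec"),
            inherits(morphology, "morphology_spec"))
  structure(
    list(size_threshold = size_threshold, area_threshold = area_threshold,
         n_seeds = n_seeds, morphology = morphology,
         min_contour_area_px = min_contour_area_px,
         dilate_for_measure = isTRUE(dilate_for_measure),
         dilate_for_count = isTRUE(dilate_for_count),
         rect_method = match.arg(rect_method)),
    class = "measure_config"
  )
}

#' Measure seeds in an image
#'
#' Runs the full measurement chain: grayscale conversion, optional
#' dilation, thresholding with the size threshold, contour extraction,
#' selection of the `n_seeds` largest contours (which silently discards
#' noise specks), and a bounding rectangle per seed. Each seed's projected
#' area is the count of its pixels that survive the stricter area
#' threshold. With a calibration, pixel values are converted to mm
#' (lengths) and mm^2 (areas).
#'
#' @param img A [raster_image()] (RGB or grayscale).
#' @param cfg A [measure_config()].
#' @param cal A `calibration`, or `NULL` for pixel-only output (mm columns
#'   are `NA`).
#' @return A data frame of class `seed_measurements`, one row per seed in
#'   descending area order, with columns `seed_index`, `length_px`,
#'   `width_px`, `area_px`, `length_mm`, `width_mm`, `area_mm2`,
#'   `aspect_ratio`, plus the seed centroid `center_row`/`center_col`
#'   (pixel coordinates, useful for pairing seeds against known layouts).
#' @export
measure_seeds <- function(img, cfg = measure_config(), cal = NULL) {
  stopifnot(inherits(cfg, "measure_config"))
  if (!is.null(cal) && !inherits(cal, "calibration"))
    stop("cal must be a calibration or NULL", call. = FALSE)
  g <- to_grayscale(img)
  if (cfg$dilate_for_measure) g <- dilate(g, cfg$morphology)
  size_mask <- threshold(g, cfg$size_threshold)
  contours <- find_contours(size_mask)
  labels <- attr(contours, "labels")
  keep <- vapply(contours, function(ct) ct$area_px >= cfg$min_contour_area_px,
                 logical(1))
  contours <- contours[keep]
  if (length(contours) == 0L)
    stop("no seed found: no contour at or above the noise floor of ",
         cfg$min_contour_area_px, " px", call. = FALSE)
  sel <- select_top_n_contours(contours, cfg$n_seeds)
  area_fg <- threshold(g, cfg$area_threshold)$pixels > 0L

  n <- length(sel)
  length_px <- width_px <- center_row <- center_col <- numeric(n)
  area_px <- integer(n)
  for (i in seq_len(n)) {
    ct <- sel[[i]]
    sides <- bounding_rectangle(ct, method = cfg$rect_method)
    length_px[i] <- sides[1]
    width_px[i] <- sides[2]
    idx <- which(labels == ct$label, arr.ind = TRUE)
    center_row[i] <- mean(idx[, 1])
    center_col[i] <- mean(idx[, 2])
    area_px[i] <- sum(area_fg & labels == ct$label)
  }
  if (any(area_px == 0L))
    warning("seed(s) with zero projected area at the area threshold (",
            cfg$area_threshold$lower, "); image may be underexposed",
            call. = FALSE)
  out <- data.frame(
    seed_index = seq_len(n),
    length_px = length_px,
    width_px = width_px,
    area_px = area_px,
    length_mm = if (is.null(cal)) NA_real_ else px_to_mm(length_px, cal),
    width_mm = if (is.null(cal)) NA_real_ else px_to_mm(width_px, cal),
    area_mm2 = if (is.null(cal)) NA_real_ else px2_to_mm2(area_px, cal),
    aspect_ratio = length_px / width_px,
    center_row = center_row,
    center_col = center_col
  )
  class(out) <- c("seed_measurements", "data.frame")
  out
}
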