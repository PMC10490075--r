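#' Euclidean distance between two pixel coordinates
#'
#' @param p1,p2 Numeric `(row, col)` pairs; sub-pixel coordinates allowed.
#' @return Distance in pixels.
#' @examples
#' pixel_distance(c(0, 0), c(3, 4))  # 5
#' @export
pixel_distance <- function(p1, p2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2L || length(p2) != 2L)
    stop("points must be (row, col) pairs", call. = FALSE)
  sqrt(sum((p1 - p2)^2))
}

#' Pixel-to-millimetre calibration
#'
#' Derives a pixels-per-mm scale from two points a known physical distance
#' apart — in practice two ruler graduations in a photograph taken at the
#' same camera geometry as the seed images (the classical procedure marks
#' points 10 mm apart). One calibration serves a whole imaging session as
#' long as the camera position and settings do not change.
#'
#' @param p1,p2 `(row, col)` pixel coordinates of the two reference points.
#' @param known_mm Physical distance between them in millimetres (`> 0`).
#' @return A `calibration` object with fields `px_per_mm`, `source_points`,
#'   `known_distance_mm`.
#' @examples
#' cal <- make_calibration(c(10, 10), c(10, 260), known_mm = 10)
#' cal$px_per_mm  # 25
#' @export
make_calibration <- function(p1, p2, known_mm) {
  d <- pixel_distance(p1, p2)
  if (!is.numeric(known_mm) || length(known_mm) != 1L || is.na(known_mm) ||
      known_mm <= 0)
    stop("invalid calibration: known_mm must be a positive number", call. = FALSE)
  if (d == 0)
    stop("invalid calibration: reference points coincide", call. = FALSE)
  structure(
    list(px_per_mm = d / known_mm,
         source_points = rbind(as.numeric(p1), as.numeric(p2)),
         known_distance_mm = as.numeric(known_mm)),
    class = "calibration"
  )
}

#' Construct a calibration directly from a known scale
#'
#' @param px_per_mm Pixels per millimetre (`> 0`).
#' @return A `calibration` object.
#' @export
calibration_from_scale <- function(px_per_mm) {
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L || is.na(px_per_mm) ||
      px_per_mm <= 0)
    stop("px_per_mm must be a positive number", call. = FALSE)
  structure(list(px_per_mm = as.numeric(px_per_mm), source_points = NULL,
                 known_distance_mm = NA_real_),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.4f px/mm", x$px_per_mm))
  if (!is.null(x$source_points))
    cat(sprintf(" (from points %.1f px apart spanning %g mm)",
                pixel_distance(x$source_points[1, ], x$source_points[2, ]),
                x$known_distance_mm))
  cat("\n")
  invisible(x)
}

#' Convert a pixel length to millimetres
#'
#' @param v_px Length(s) in pixels.
#' @param cal A `calibration`.
#' @return `v_px / px_per_mm`, in mm.
#' @export
px_to_mm <- function(v_px, cal) {
  stopifnot(inherits(cal, "calibration"))
  v_px / cal$px_per_mm
}

#' Convert a pixel area to square millimetres
#'
#' @param a_px Area(s) in pixels.
#' @param cal A `calibration`.
#' @return `a_px / px_per_mm^2`, in mm^2.
#' @export
px2_to_mm2 <- function(a_px, cal) {
  stopifnot(inherits(cal, "calibration"))
  a_px / cal$px_per_mm^2
}

#' Persist a calibration to a key-value file
#'
#' The file is a flat `key = value` text format holding the scale and, when
#' derived from reference points, its provenance. [read_calibration()]
#' restores it.
#'
#' @param cal A `calibration`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration"))
  lines <- c(sprintf("px_per_mm = %.12g", cal$px_per_mm))
  if (!is.null(cal$source_points)) {
    lines <- c(lines,
      sprintf("p1 = %.12g,%.12g", cal$source_points[1, 1], cal$source_points[1, 2]),
      sprintf("p2 = %.12g,%.12g", cal$source_points[2, 1], cal$source_points[2, 2]),
      sprintf("known_mm = %.12g", cal$known_distance_mm))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a calibration written by [write_calibration()]
#'
#' @param path Calibration file path.
#' @return A `calibration` object.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path, call. = FALSE)
  kv <- parse_keyvalue_file(path)
  if (is.null(kv$px_per_mm)) stop("calibration file lacks px_per_mm: ", path, call. = FALSE)
  if (!is.null(kv$p1) && !is.null(kv$p2) && !is.null(kv$known_mm)) {
    p1 <- as.numeric(strsplit(kv$p1, ",")[[1]])
    p2 <- as.numeric(strsplit(kv$p2, ",")[[1]])
    make_calibration(p1, p2, as.numeric(kv$known_mm))
  } else {
    calibration_from_scale(as.numeric(kv$px_per_mm))
  }
}

# flat `key = value` parser shared with the CLI config reader
parse_keyvalue_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed key-value line: ", ln, call. = FALSE)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    kv[[key]] <- val
  }
  kv
}
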