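#' Extract contours of foreground regions
#'
#' Finds every 8-connected foreground region of a binary mask and returns
#' one contour per region: the ordered outer boundary (Moore tracing,
#' clockwise) plus the region's enclosed pixel count. Holes are ignored —
#' only outer boundaries are traced.
#'
#' The returned list carries the full label matrix as attribute `"labels"`
#' (regions numbered in row-major scan order), which downstream per-seed
#' area computations reuse.
#'
#' @param mask A [binary_mask()].
#' @return A list of `contour` objects, each with fields `boundary`
#'   (n x 2 matrix of 1-based `(row, col)` coordinates), `area_px`
#'   (region pixel count), and `label` (id in the label matrix). The empty
#'   mask yields an empty list.
#' @export
find_contours <- function(mask) {
  if (!inherits(mask, "binary_mask")) stop("find_contours expects a binary_mask", call. = FALSE)
  lab <- .cpp_label_components(mask$pixels > 0L)
  n <- max(lab)
  out <- vector("list", n)
  if (n > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    for (i in seq_len(n)) {
      boundary <- .cpp_trace_boundary(lab, i)
      # a closed loop of >1 pixels is represented by >= 3 vertices
      if (areas[i] > 1L && nrow(boundary) < 3L)
        boundary <- rbind(boundary, boundary[1L, , drop = FALSE])
      out[[i]] <- structure(
        list(boundary = boundary, area_px = areas[i], label = i),
        class = "contour"
      )
    }
  }
  attr(out, "labels") <- lab
  out
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> area %d px, %d boundary points\n",
              x$area_px, nrow(x$boundary)))
  invisible(x)
}

#' Select the largest contour
#'
#' Keeps only the contour with the maximum enclosed area. This is the
#' pipeline's implicit noise filter: small bright specks produce small
#' contours that are discarded without any explicit size rule. Ties are
#' broken by first position in the list.
#'
#' @param contours A non-empty list of contours from [find_contours()].
#' @return The largest `contour`.
#' @export
select_max_area_contour <- function(contours) {
  if (length(contours) == 0L)
    stop("no seed found: contour list is empty", call. = FALSE)
  areas <- vapply(contours, function(ct) ct$area_px, numeric(1))
  contours[[which.max(areas)]]
}

#' Select the n largest contours
#'
#' Returns the `n` contours with the largest areas, in descending area
#' order (ties broken by original list position). If fewer than `n`
#' contours exist, all are returned and a warning is signalled.
#'
#' @param contours A list of contours from [find_contours()].
#' @param n Number of contours to keep (`>= 1`), typically the number of
#'   seeds placed in the photograph.
#' @return A list of at most `n` contours, area-descending.
#' @export
select_top_n_contours <- function(contours, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (length(contours) < n)
    warning(sprintf("requested %d contours but only %d found", n, length(contours)),
            call. = FALSE)
  areas <- vapply(contours, function(ct) ct$area_px, numeric(1))
  ord <- order(-areas)          # stable: ties keep list order
  contours[ord[seq_len(min(n, length(contours)))]]
}

# Minimum-area enclosing rectangle of a set of pixel centres by rotating
# calipers over the convex hull: the optimal rectangle has one side
# collinear with a hull edge.
#
# Orientation selection must compensate a lattice artefact: spans of pixel
# centres fall short of the continuous shape by up to |ux| + |uy| px (the
# unit pixel square's projected footprint), which is 1 px for axis-aligned
# directions but sqrt(2) px at 45 degrees. Scoring raw spans therefore
# systematically favours tilted rectangles and, for near-circular shapes,
# can snap the orientation ~45 degrees away from the true axes. Candidate
# orientations are scored with the footprint added (the area of the pixels
# treated as unit squares), while the returned sides are the plain centre
# spans of the winning orientation — the familiar contour-library
# convention, reading up to 1 px short of the continuous pre-image, never
# long. Returns c(long side, short side), clamped to >= 1.
min_area_rect <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1L) return(c(1, 1))
  hull <- grDevices::chull(pts[, 2], pts[, 1])   # x = col, y = row
  hp <- pts[hull, , drop = FALSE]
  m <- nrow(hp)
  if (m == 1L) return(c(1, 1))
  if (m == 2L) {
    d <- sqrt(sum((hp[1, ] - hp[2, ])^2))
    return(c(max(d, 1), 1))
  }
  x <- hp[, 2]; y <- hp[, 1]
  best <- c(Inf, 0, 0)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    ex <- x[j] - x[i]; ey <- y[j] - y[i]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    ux <- ex / len; uy <- ey / len          # edge direction
    foot <- abs(ux) + abs(uy)               # unit-square footprint width
    p <- x * ux + y * uy                    # projection onto edge
    q <- -x * uy + y * ux                   # projection onto normal
    s1 <- max(p) - min(p)
    s2 <- max(q) - min(q)
    score <- (s1 + foot) * (s2 + foot)      # area as union of unit squares
    if (score < best[1]) best <- c(score, s1, s2)
  }
  pmax(sort(best[2:3], decreasing = TRUE), 1)
}

# Rotated bounding rectangle oriented along the principal axes of the
# boundary point set (eigenvectors of its 2x2 covariance). For convex
# seed-like shapes the principal axes coincide with the symmetry axes, and
# the estimate is self-stabilising: orientation noise grows only as the
# shape approaches a disk, where orientation no longer affects the spans.
# Sides are centre spans, clamped to >= 1.
principal_axes_rect <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1L) return(c(1, 1))
  y <- pts[, 1] - mean(pts[, 1])   # row
  x <- pts[, 2] - mean(pts[, 2])   # col
  sxx <- mean(x * x); syy <- mean(y * y); sxy <- mean(x * y)
  # major-axis direction: eigenvector of the largest eigenvalue
  if (abs(sxy) < 1e-12 && abs(sxx - syy) < 1e-12) {
    ux <- 1; uy <- 0                       # isotropic: orientation arbitrary
  } else {
    lam <- (sxx + syy) / 2 + sqrt(((sxx - syy) / 2)^2 + sxy^2)
    # (sxy, lam - sxx) and (lam - syy, sxy) are parallel; keep the larger
    if (sxy^2 + (lam - sxx)^2 >= (lam - syy)^2 + sxy^2) {
      ux <- sxy; uy <- lam - sxx
    } else {
      ux <- lam - syy; uy <- sxy
    }
    nrm <- sqrt(ux^2 + uy^2)
    ux <- ux / nrm; uy <- uy / nrm
  }
  p <- x * ux + y * uy
  q <- -x * uy + y * ux
  pmax(sort(c(diff(range(p)), diff(range(q))), decreasing = TRUE), 1)
}

#' Bounding rectangle of a contour
#'
#' Fits a freely rotated rectangle around the contour boundary and returns
#' its sides as `(length_px, width_px)` with `length >= width`. Sides
#' follow the pixel-centre span convention of the classical contour
#' libraries' rotated rectangle: they can read up to one pixel short of
#' the continuous shape that was rasterised, never long; sides are clamped
#' to a minimum of 1 px.
#'
#' The default `"rotated"` method orients the rectangle along the
#' principal axes of the boundary (second-order moments). For convex
#' seed silhouettes this coincides with the symmetry axes and is robust to
#' rasterisation noise, unlike the strict minimum-area rectangle, whose
#' orientation snaps unpredictably between near-tied candidates on
#' low-eccentricity shapes and can mis-state length and width by several
#' percent. The strict minimum-area fit (rotating calipers) remains
#' available as `method = "minarea"`; `method = "axis"` gives the
#' axis-aligned box (integer pixel extent: an axis-aligned `h x w` block
#' measures exactly `(h, w)`).
#'
#' @param contour A `contour` from [find_contours()].
#' @param method `"rotated"` (default, principal-axes rectangle),
#'   `"minarea"` (strict minimum-area rectangle), or `"axis"`.
#' @return Numeric `c(length_px, width_px)`, both `> 0`; a single-pixel
#'   contour reports `c(1, 1)`.
#' @export
bounding_rectangle <- function(contour, method = c("rotated", "minarea", "axis")) {
  method <- match.arg(method)
  if (!inherits(contour, "contour")) stop("expected a contour object", call. = FALSE)
  b <- contour$boundary
  if (nrow(b) == 0L) stop("contour has an empty boundary", call. = FALSE)
  switch(method,
    axis = {
      sides <- c(diff(range(b[, 1])), diff(range(b[, 2]))) + 1  # pixel extent
      sort(sides, decreasing = TRUE)
    },
    minarea = min_area_rect(b),
    rotated = principal_axes_rect(b)
  )
}

#' Count foreground pixels of a mask
#'
#' The projected area in pixels: the exact number of foreground pixels.
#'
#' @param mask A [binary_mask()].
#' @return Integer pixel count (`0` for an empty mask).
#' @export
projected_area_px <- function(mask) {
  if (!inherits(mask, "binary_mask")) stop("projected_area_px expects a binary_mask", call. = FALSE)
  sum(mask$pixels > 0L)
}
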