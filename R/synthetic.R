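# Ground-truth scene generator: bright convex seed silhouettes on a
# near-black background, rendered at a known px/mm so the measurement
# pipeline can be validated against closed-form geometry with no real
# photographs.

#' Specify one synthetic seed shape
#'
#' @param kind `"disk"`, `"ellipse"`, or `"rectangle"`.
#' @param center `(row, col)` centre in pixels (sub-pixel allowed).
#' @param axes_mm `(major, minor)` full axis lengths in mm,
#'   `major >= minor > 0`. For a disk pass one value or two equal values.
#' @param rotation_deg Orientation of the major axis, degrees
#'   counter-clockwise from the column (x) axis.
#' @param intensity Foreground intensity, default 220 — comfortably above
#'   both the 140 and 170 thresholds, like a pale seed on black.
#' @return A `shape_spec` object.
#' @export
shape_spec <- function(kind = c("disk", "ellipse", "rectangle"), center,
                       axes_mm, rotation_deg = 0, intensity = 220L) {
  kind <- match.arg(kind)
  center <- as.numeric(center)
  axes_mm <- as.numeric(axes_mm)
  if (kind == "disk" && length(axes_mm) == 1L) axes_mm <- c(axes_mm, axes_mm)
  if (length(center) != 2L || length(axes_mm) != 2L)
    stop("center must be (row, col); axes_mm must be (major, minor)", call. = FALSE)
  if (axes_mm[1] < axes_mm[2] || axes_mm[2] <= 0)
    stop("axes must satisfy major >= minor > 0", call. = FALSE)
  if (kind == "disk" && axes_mm[1] != axes_mm[2])
    stop("a disk needs equal axes", call. = FALSE)
  intensity <- as.integer(intensity)
  if (intensity < 1L || intensity > 255L)
    stop("intensity must be in [1, 255]", call. = FALSE)
  structure(list(kind = kind, center = center, axes_mm = axes_mm,
                 rotation_deg = as.numeric(rotation_deg), intensity = intensity),
            class = "shape_spec")
}

#' Assemble a synthetic scene
#'
#' @param shapes List of [shape_spec()] objects.
#' @param px_per_mm Render scale in pixels per millimetre.
#' @param image_size `(rows, cols)` of the rendered image.
#' @param background_intensity Background value, default 10 (near-black).
#' @param n_speckles Number of small bright noise speckles to add.
#' @param speckle_radius_px Speckle radius in pixels. The default 1 yields
#'   5 px blobs that stay below the default 25 px noise floor even after
#'   one 3x3 dilation pass (5 px grows to 21 px); raise it deliberately to
#'   build "hostile" scenes whose noise survives the floor.
#' @param rng_seed Seed for speckle placement; rendering is fully
#'   deterministic given the scene.
#' @param allow_overlap If `FALSE` (default), shapes must lie fully inside
#'   the frame and be pairwise separated (circumscribed-circle check with a
#'   3 px margin, enough to survive one 3x3 dilation pass); violations are
#'   scene-construction errors. Set `TRUE` for deliberate overlap tests.
#' @return A `synthetic_scene` object.
#' @export
synthetic_scene <- function(shapes, px_per_mm, image_size,
                            background_intensity = 10L,
                            n_speckles = 0L, speckle_radius_px = 1,
                            rng_seed = 1L, allow_overlap = FALSE) {
  if (inherits(shapes, "shape_spec")) shapes <- list(shapes)
  stopifnot(all(vapply(shapes, inherits, logical(1), "shape_spec")),
            px_per_mm > 0, length(image_size) == 2L)
  image_size <- as.integer(image_size)
  if (!allow_overlap) {
    for (sh in shapes) {
      half <- sh$axes_mm[1] / 2 * px_per_mm
      if (sh$center[1] - half < 0.5 || sh$center[1] + half > image_size[1] + 0.5 ||
          sh$center[2] - half < 0.5 || sh$center[2] + half > image_size[2] + 0.5)
        stop("scene construction: shape extends outside the frame ",
             "(set allow_overlap = TRUE to permit)", call. = FALSE)
    }
    if (length(shapes) > 1L) {
      for (i in seq_len(length(shapes) - 1L)) {
        for (j in seq((i + 1L), length(shapes))) {
          d <- pixel_distance(shapes[[i]]$center, shapes[[j]]$center)
          rsum <- (shapes[[i]]$axes_mm[1] + shapes[[j]]$axes_mm[1]) / 2 * px_per_mm
          if (d < rsum + 3)
            stop("scene construction: shapes ", i, " and ", j,
                 " may overlap or touch (set allow_overlap = TRUE to permit)",
                 call. = FALSE)
        }
      }
    }
  }
  structure(
    list(shapes = shapes, px_per_mm = as.numeric(px_per_mm),
         image_size = image_size,
         background_intensity = as.integer(background_intensity),
         n_speckles = as.integer(n_speckles),
         speckle_radius_px = as.numeric(speckle_radius_px),
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_scene"
  )
}

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# logical mask of one shape over a bounding window of the full grid
shape_window_mask <- function(sh, px_per_mm, image_size) {
  a <- sh$axes_mm[1] / 2 * px_per_mm   # semi-major, px
  b <- sh$axes_mm[2] / 2 * px_per_mm
  half <- a + 1
  r0 <- max(1L, floor(sh$center[1] - half))
  r1 <- min(image_size[1], ceiling(sh$center[1] + half))
  c0 <- max(1L, floor(sh$center[2] - half))
  c1 <- min(image_size[2], ceiling(sh$center[2] + half))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  dr <- matrix(rows - sh$center[1], length(rows), length(cols))
  dc <- matrix(cols - sh$center[2], length(rows), length(cols), byrow = TRUE)
  th <- sh$rotation_deg * pi / 180
  u <- cos(th) * dc + sin(th) * dr     # along major axis
  v <- -sin(th) * dc + cos(th) * dr    # along minor axis
  inside <- if (sh$kind == "rectangle") {
    abs(u) <= a & abs(v) <= b
  } else {
    (u / a)^2 + (v / b)^2 <= 1
  }
  list(rows = rows, cols = cols, inside = inside)
}

#' Render a synthetic scene to a raster image
#'
#' Hard-edged rasterisation: a pixel belongs to a shape iff its centre
#' satisfies the shape's inequality, so pixel-count oracles are exact
#' up to boundary discretisation. Speckle noise is drawn from the scene's
#' seeded generator and placed at least 3 px clear of every shape, so
#' default speckles can never merge with a seed. Deterministic: the same
#' scene always renders to the identical image.
#'
#' @param scene A [synthetic_scene()].
#' @return A 1-channel [raster_image()].
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  px <- matrix(scene$background_intensity, scene$image_size[1], scene$image_size[2])
  shape_fg <- matrix(FALSE, scene$image_size[1], scene$image_size[2])
  for (sh in scene$shapes) {
    wm <- shape_window_mask(sh, scene$px_per_mm, scene$image_size)
    if (is.null(wm)) next
    block <- px[wm$rows, wm$cols, drop = FALSE]
    block[wm$inside] <- sh$intensity
    px[wm$rows, wm$cols] <- block
    fg <- shape_fg[wm$rows, wm$cols, drop = FALSE]
    shape_fg[wm$rows, wm$cols] <- fg | wm$inside
  }
  if (scene$n_speckles > 0L) {
    rad <- scene$speckle_radius_px
    margin <- ceiling(rad) + 3L
    nr <- scene$image_size[1]; nc <- scene$image_size[2]
    with_seed(scene$rng_seed, {
      placed <- 0L; tries <- 0L
      while (placed < scene$n_speckles && tries < 1000L * scene$n_speckles) {
        tries <- tries + 1L
        cr <- runif(1, 1 + rad, nr - rad)
        cc <- runif(1, 1 + rad, nc - rad)
        rr <- max(1L, floor(cr - margin)):min(nr, ceiling(cr + margin))
        cs <- max(1L, floor(cc - margin)):min(nc, ceiling(cc + margin))
        if (any(shape_fg[rr, cs])) next   # keep speckles clear of seeds
        srows <- max(1L, floor(cr - rad)):min(nr, ceiling(cr + rad))
        scols <- max(1L, floor(cc - rad)):min(nc, ceiling(cc + rad))
        dr <- matrix(srows - cr, length(srows), length(scols))
        dc <- matrix(scols - cc, length(srows), length(scols), byrow = TRUE)
        hit <- dr^2 + dc^2 <= rad^2
        block <- px[srows, scols, drop = FALSE]
        block[hit] <- 220L
        px[srows, scols] <- block
        shape_fg[srows, scols] <- shape_fg[srows, scols] | hit
        placed <- placed + 1L
      }
      if (placed < scene$n_speckles)
        warning("placed only ", placed, " of ", scene$n_speckles, " speckles",
                call. = FALSE)
    })
  }
  raster_image(px)
}

#' Analytic ground truth of a synthetic scene
#'
#' Closed-form length, width, aspect ratio, and area per shape (ellipse and
#' disk area `pi * major * minor / 4`, rectangle `major * minor`), in both
#' mm and pixels, ordered area-descending to match the measurement module's
#' output convention.
#'
#' @param scene A [synthetic_scene()].
#' @return A data frame with one row per shape: `kind`, `length_mm`,
#'   `width_mm`, `area_mm2`, `aspect_ratio`, `length_px`, `width_px`,
#'   `area_px`, `center_row`, `center_col`.
#' @export
ground_truth <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  rows <- lapply(scene$shapes, function(sh) {
    maj <- sh$axes_mm[1]; min_ <- sh$axes_mm[2]
    area <- if (sh$kind == "rectangle") maj * min_ else pi * maj * min_ / 4
    data.frame(kind = sh$kind, length_mm = maj, width_mm = min_,
               area_mm2 = area, aspect_ratio = maj / min_,
               length_px = maj * scene$px_per_mm,
               width_px = min_ * scene$px_per_mm,
               area_px = area * scene$px_per_mm^2,
               center_row = sh$center[1], center_col = sh$center[2])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$area_px), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a reproducible batch of measurement scenes
#'
#' Emulates the validation material of a seed-phenotyping trial: each scene
#' holds `shapes_per_scene` elliptical "seeds" with major and minor axes
#' drawn uniformly from `sizes_mm_range` (major >= minor by sorting the
#' draw) at random orientations, laid out on a non-touching grid.
#'
#' @param n_scenes Number of scenes (`>= 1`).
#' @param sizes_mm_range `(min, max)` axis range in mm; default `c(4, 9)`,
#'   the size span of typical soybean seed lots.
#' @param px_per_mm Render scale; default 25.
#' @param shapes_per_scene Seeds per scene; default 5, a typical number of
#'   seeds photographed per cultivar.
#' @param rng_seed Batch seed; the batch is a pure function of its
#'   arguments.
#' @return A list of [synthetic_scene()] objects.
#' @export
make_trial_grid <- function(n_scenes, sizes_mm_range = c(4, 9), px_per_mm = 25,
                            shapes_per_scene = 5L, rng_seed = 1L) {
  n_scenes <- as.integer(n_scenes)
  if (is.na(n_scenes) || n_scenes < 1L) stop("n_scenes must be >= 1", call. = FALSE)
  shapes_per_scene <- as.integer(shapes_per_scene)
  cell <- ceiling((sizes_mm_range[2] + 2) * px_per_mm)   # 1 mm margin per side
  ncol_grid <- ceiling(sqrt(shapes_per_scene))
  nrow_grid <- ceiling(shapes_per_scene / ncol_grid)
  image_size <- c(nrow_grid * cell, ncol_grid * cell)
  jitter_max <- px_per_mm / 2                            # +/- 0.5 mm placement jitter
  with_seed(rng_seed, {
    lapply(seq_len(n_scenes), function(i) {
      shapes <- lapply(seq_len(shapes_per_scene), function(k) {
        ax <- sort(runif(2, sizes_mm_range[1], sizes_mm_range[2]),
                   decreasing = TRUE)
        gr <- (k - 1L) %/% ncol_grid; gc <- (k - 1L) %% ncol_grid
        center <- c(gr * cell + cell / 2, gc * cell + cell / 2) +
          runif(2, -jitter_max, jitter_max)
        shape_spec("ellipse", center = center, axes_mm = ax,
                   rotation_deg = runif(1, 0, 180))
      })
      synthetic_scene(shapes, px_per_mm = px_per_mm, image_size = image_size,
                      rng_seed = rng_seed + i)
    })
  })
}
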