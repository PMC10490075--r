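test_that("find_contours labels match brute-force 8-connected labelling", {
  set.seed(21)
  for (i in 1:20) {
    m <- random_mask(sample(8:32, 1), sample(8:32, 1), p = runif(1, 0.1, 0.5))
    mask <- mask_from_logical(m)
    contours <- find_contours(mask)
    expect_equal(length(contours), bf_component_count(m))
    areas <- vapply(contours, function(ct) ct$area_px, numeric(1))
    expect_equal(sum(areas), sum(m))       # outer regions partition foreground
    expect_true(all(areas >= 1))
  }
})

test_that("find_contours on canonical masks", {
  expect_length(find_contours(mask_from_logical(matrix(FALSE, 8, 8))), 0L)
  m <- matrix(FALSE, 14, 14); m[3:12, 3:12] <- TRUE
  cts <- find_contours(mask_from_logical(m))
  expect_length(cts, 1L)
  expect_equal(cts[[1]]$area_px, 100)
  expect_gte(nrow(cts[[1]]$boundary), 3L)
  # two disks separated by >= 2 background pixels
  two <- render_scene(synthetic_scene(
    list(shape_spec("disk", c(20, 20), 2), shape_spec("disk", c(20, 60), 2)),
    px_per_mm = 5, image_size = c(40, 80)))
  cts2 <- find_contours(threshold(two, threshold_spec(170)))
  expect_length(cts2, 2L)
})

test_that("contour boundaries are closed loops of adjacent pixels", {
  set.seed(22)
  m <- random_mask(20, 20, 0.4)
  cts <- find_contours(mask_from_logical(m))
  for (ct in cts) {
    b <- ct$boundary
    if (nrow(b) < 2L) next
    steps <- abs(diff(b))
    expect_true(all(steps <= 1))           # Moore-adjacent consecutive points
    wrap <- abs(b[1, ] - b[nrow(b), ])
    expect_true(all(wrap <= 1))            # loop closes
  }
})

test_that("select_max_area_contour picks the largest, eliminating noise", {
  m <- matrix(FALSE, 40, 40)
  m[5:24, 5:24] <- TRUE       # area 400
  m[30:32, 30:32] <- TRUE     # area 9
  m[36, 36:38] <- TRUE        # area 3
  cts <- find_contours(mask_from_logical(m))
  expect_length(cts, 3L)
  expect_equal(select_max_area_contour(cts)$area_px, 400)
  expect_error(select_max_area_contour(list()), "no seed found")
})

test_that("select_max_area_contour is permutation-stable up to ties", {
  m <- matrix(FALSE, 30, 30)
  m[2:9, 2:9] <- TRUE; m[12:19, 12:19] <- TRUE; m[22:26, 22:28] <- TRUE
  m[28, 2:4] <- TRUE
  cts <- find_contours(mask_from_logical(m))
  expect_gte(length(cts), 3L)
  set.seed(23)
  best <- select_max_area_contour(cts)$area_px
  for (i in 1:5) {
    perm <- sample(cts)
    expect_equal(select_max_area_contour(perm)$area_px, best)
  }
})

test_that("select_top_n_contours sorts by area and warns on short lists", {
  m <- matrix(FALSE, 40, 60)
  m[5:24, 5:24] <- TRUE       # 400
  m[5:23, 30:49] <- TRUE      # 380
  m[30:32, 30:32] <- TRUE     # 9
  cts <- find_contours(mask_from_logical(m))
  top2 <- select_top_n_contours(cts, 2)
  expect_equal(vapply(top2, function(ct) ct$area_px, numeric(1)), c(400, 380))
  all3 <- select_top_n_contours(cts, 3)
  expect_equal(vapply(all3, function(ct) ct$area_px, numeric(1)), c(400, 380, 9))
  expect_warning(short <- select_top_n_contours(cts[1], 3), "only 1")
  expect_length(short, 1L)
  expect_error(select_top_n_contours(cts, 0), ">= 1")
})

test_that("bounding_rectangle recovers axis-aligned block dimensions", {
  img <- block_image(80, 80, 11, 60, 21, 50)  # 50 x 30 block
  cts <- find_contours(threshold(to_grayscale(img), threshold_spec(140)))
  sides <- bounding_rectangle(cts[[1]])
  expect_lte(abs(sides[1] - 50), 1)   # centre-span convention: <= 1 px short
  expect_lte(abs(sides[2] - 30), 1)
  axis <- bounding_rectangle(cts[[1]], method = "axis")
  expect_equal(axis, c(50, 30))              # exact for axis-aligned boxes
})

test_that("bounding_rectangle is rotation-invariant within 2%", {
  # 50 x 30 px rectangle (2.0 x 1.2 mm at 25 px/mm) rotated 37 degrees
  sc <- synthetic_scene(
    shape_spec("rectangle", c(60, 60), c(2.0, 1.2), rotation_deg = 37),
    px_per_mm = 25, image_size = c(120, 120))
  cts <- find_contours(threshold(render_scene(sc), threshold_spec(140)))
  sides <- bounding_rectangle(select_max_area_contour(cts))
  expect_equal(sides[1], 50, tolerance = 0.02)
  expect_equal(sides[2], 30, tolerance = 0.02)
})

test_that("bounding_rectangle of a disk is square within 2%", {
  sc <- synthetic_scene(shape_spec("disk", c(100, 100), 4), px_per_mm = 20,
                        image_size = c(200, 200))  # radius 40 px
  cts <- find_contours(threshold(render_scene(sc), threshold_spec(140)))
  sides <- bounding_rectangle(cts[[1]])
  expect_equal(sides[1], 80, tolerance = 0.02)
  expect_equal(sides[2], 80, tolerance = 0.02)
  expect_lte(sides[1] / sides[2], 1.02)
})

test_that("degenerate single-pixel contour reports sides (1, 1)", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  cts <- find_contours(mask_from_logical(m))
  expect_equal(bounding_rectangle(cts[[1]]), c(1, 1))
})

test_that("projected_area_px equals the brute-force foreground count", {
  set.seed(24)
  for (i in 1:25) {
    m <- random_mask(sample(4:40, 1), sample(4:40, 1), runif(1, 0, 1))
    expect_identical(projected_area_px(mask_from_logical(m)), sum(m))
  }
  expect_identical(projected_area_px(mask_from_logical(matrix(FALSE, 6, 6))), 0L)
  m <- matrix(FALSE, 30, 30); m[6:25, 6:25] <- TRUE
  expect_identical(projected_area_px(mask_from_logical(m)), 400L)
})

test_that("rasterized disk area approaches pi r^2", {
  sc <- synthetic_scene(shape_spec("disk", c(120, 120), 4), px_per_mm = 25,
                        image_size = c(240, 240))  # radius 50 px
  a <- projected_area_px(threshold(render_scene(sc), threshold_spec(170)))
  expect_equal(a, pi * 50^2, tolerance = 0.01)
})

test_that("measure_seeds recovers known geometry and applies calibration", {
  sc <- synthetic_scene(
    shape_spec("ellipse", c(120, 120), c(6, 4), rotation_deg = 25),
    px_per_mm = 25, image_size = c(240, 240))   # 150 x 100 px axes
  cal <- make_calibration(c(10, 10), c(10, 260), 10)   # 25 px/mm
  m <- measure_seeds(render_scene(sc), measure_config(), cal)
  expect_equal(nrow(m), 1L)
  expect_equal(m$length_mm, 6, tolerance = 0.02)
  expect_equal(m$width_mm, 4, tolerance = 0.02)
  expect_equal(m$aspect_ratio, 1.5, tolerance = 0.02)
  expect_equal(m$area_mm2, pi * 6 * 4 / 4, tolerance = 0.02)
  expect_equal(m$length_px / m$width_px, m$aspect_ratio)
})

test_that("measure_seeds invariants hold across a seeded batch", {
  scenes <- make_trial_grid(5, rng_seed = 99L)
  cal <- calibration_from_scale(25)
  for (sc in scenes) {
    m <- measure_seeds(render_scene(sc), measure_config(n_seeds = 5), cal)
    expect_equal(nrow(m), 5L)
    expect_true(all(m$length_px >= m$width_px))
    expect_true(all(m$aspect_ratio >= 1))
    expect_true(all(m$area_px > 0))
    expect_true(all(diff(m$area_px) <= 0))   # area-descending order
  }
})

test_that("for one clean seed, contour-restricted PA equals whole-mask PA", {
  sc <- synthetic_scene(shape_spec("ellipse", c(80, 80), c(5, 4)),
                        px_per_mm = 20, image_size = c(160, 160))
  img <- render_scene(sc)
  m <- measure_seeds(img, measure_config())
  whole <- projected_area_px(threshold(to_grayscale(img), threshold_spec(170)))
  expect_identical(as.integer(m$area_px), whole)
})

test_that("measure_seeds without calibration leaves mm columns NA", {
  sc <- synthetic_scene(shape_spec("disk", c(50, 50), 4), px_per_mm = 10,
                        image_size = c(100, 100))
  m <- measure_seeds(render_scene(sc), measure_config())
  expect_true(is.na(m$length_mm) && is.na(m$area_mm2))
  expect_false(is.na(m$length_px))
})

test_that("measure_seeds errors when nothing clears the noise floor", {
  img <- raster_image(matrix(10L, 50, 50))
  expect_error(measure_seeds(img, measure_config()), "no seed found")
  tiny <- block_image(50, 50, 20, 21, 20, 21)  # 4 px, below floor of 25
  expect_error(measure_seeds(tiny, measure_config()), "noise floor")
})
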