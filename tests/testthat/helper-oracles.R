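# Independent brute-force oracles and fixture builders. These deliberately
# use naive algorithms (sliding-window maxima, queue-based flood fill)
# so they share no code path with the implementations they check.

# sliding-window maximum dilation, one pass
bf_dilate_once <- function(m, k) {
  h <- k %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rs <- max(1, r - h):min(nr, r + h)
      cs <- max(1, c - h):min(nc, c + h)
      out[r, c] <- max(m[rs, cs])
    }
  }
  out
}

bf_dilate <- function(m, k, iters) {
  for (i in seq_len(iters)) m <- bf_dilate_once(m, k)
  m
}

# 8-connected component labelling by queue-based flood fill
bf_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0L) {
      idx <- queue[1L]; queue <- queue[-1L]
      r <- (idx - 1L) %% nr + 1L
      c <- (idx - 1L) %/% nr + 1L
      for (i in seq_len(nrow(offs))) {
        rr <- r + offs$dr[i]; cc <- c + offs$dc[i]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          j <- (cc - 1L) * nr + rr
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- nxt
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}

bf_component_count <- function(mask) max(bf_label(mask), 0L)

# random binary mask with a mix of isolated pixels and blobs
random_mask <- function(nr, nc, p = 0.2) {
  matrix(runif(nr * nc) < p, nr, nc)
}

mask_from_logical <- function(m, maxval = 255L) {
  binary_mask(matrix(ifelse(m, maxval, 0L), nrow(m), ncol(m)), maxval)
}

# grayscale image with a filled axis-aligned block
block_image <- function(nr, nc, r0, r1, c0, c1, fg = 220L, bg = 10L) {
  px <- matrix(bg, nr, nc)
  px[r0:r1, c0:c1] <- fg
  raster_image(px)
}

# scene of n disjoint disks on a grid; used by counting tests
make_count_scene <- function(n, rng_seed = 1L, px_per_mm = 10,
                             diam_range = c(4, 9), n_speckles = 0L,
                             speckle_radius_px = 1) {
  cell <- ceiling((diam_range[2] + 2) * px_per_mm)
  ncol_grid <- 6L
  nrow_grid <- max(1L, ceiling(max(n, 1L) / ncol_grid))
  image_size <- c(nrow_grid * cell, ncol_grid * cell)
  shapes <- if (n == 0L) list() else with_seed2(rng_seed, {
    lapply(seq_len(n), function(k) {
      d <- runif(1, diam_range[1], diam_range[2])
      gr <- (k - 1L) %/% ncol_grid; gc <- (k - 1L) %% ncol_grid
      center <- c(gr * cell + cell / 2, gc * cell + cell / 2) +
        runif(2, -px_per_mm / 2, px_per_mm / 2)
      shape_spec("disk", center = center, axes_mm = d)
    })
  })
  synthetic_scene(shapes, px_per_mm = px_per_mm, image_size = image_size,
                  n_speckles = n_speckles,
                  speckle_radius_px = speckle_radius_px, rng_seed = rng_seed)
}

# reorder ground-truth rows to match measured rows by nearest centroid
# (pairing by area rank can swap near-equal seeds; position cannot)
match_to_truth <- function(m, gt) {
  idx <- vapply(seq_len(nrow(m)), function(i) {
    which.min((gt$center_row - m$center_row[i])^2 +
              (gt$center_col - m$center_col[i])^2)
  }, integer(1))
  stopifnot(!anyDuplicated(idx))
  gt[idx, , drop = FALSE]
}

# local copy of the seeded-evaluation helper (kept out of the package API)
with_seed2 <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
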