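test_that("grid aggregation covers the field and conserves counts", {
  counts <- rbind(c(3L, 0L), c(1L, 2L), c(0L, 4L))
  colnames(counts) <- c("gA", "gB")
  tab <- make_tiny_table(counts, x = c(5, 95, 50), y = c(5, 95, 50))
  grid <- build_grid(tab, s = 10, origin = c(0, 0))
  expect_equal(c(grid$nx, grid$ny), c(10L, 10L))
  # cell at (5,5) maps to grid (1,1): half-open bins
  expect_equal(as.numeric(grid$counts[1, "gA"]), 3)
  expect_equal(sum(grid$counts), sum(counts))
  expect_error(build_grid(tab, s = 0), "spacing")
})

test_that("tumour mask applies the positive/negative marker rule per grid", {
  panel <- c("CDH1", "SFTPB", "SFTPC", "SFTPD")
  counts <- rbind(c(3L, 2L, 2L, 0L),   # all positives, negative absent -> true
                  c(9L, 9L, 9L, 2L),   # negative marker present -> false
                  c(0L, 0L, 0L, 0L))   # all-zero -> false
  colnames(counts) <- panel
  tab <- make_tiny_table(counts, x = c(5, 25, 45), y = rep(5, 3))
  grid <- build_grid(tab, s = 10, origin = c(0, 0))
  rule <- list(positive = c("CDH1", "SFTPB", "SFTPC"), negative = "SFTPD")
  mask <- tumour_mask(grid, rule)
  expect_equal(as.logical(mask[c(1, 3, 5), 1]), c(TRUE, FALSE, FALSE))
})

test_that("mask smoothing matches a naive filter oracle and the hand trace", {
  # naive double-loop median+mean with replicate padding
  naive_smooth <- function(mask) {
    nx <- nrow(mask); ny <- ncol(mask)
    at <- function(m, i, j) m[min(max(i, 1), nx), min(max(j, 1), ny)]
    step <- function(m, f) {
      out <- matrix(FALSE, nx, ny)
      for (i in seq_len(nx)) for (j in seq_len(ny)) {
        v <- numeric(0)
        for (di in -1:1) for (dj in -1:1) v <- c(v, at(m, i + di, j + dj))
        out[i, j] <- f(v)
      }
      out
    }
    med <- step(mask, function(v) sort(v)[5] > 0)     # median of 9
    step(med, function(v) mean(v) >= 0.5)             # mean, re-binarized
  }

  # 5x5 with a 3x3 true block: median clips the corners to a plus,
  # the blur then resolves everything but the centre below 0.5
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  sm <- smooth_mask(m)
  expect_equal(sm, naive_smooth(m))
  expect_true(sm[3, 3])
  expect_equal(sum(sm), 1)

  # constants are preserved; isolated speckle is removed
  expect_equal(smooth_mask(matrix(TRUE, 4, 6)), matrix(TRUE, 4, 6))
  expect_equal(smooth_mask(matrix(FALSE, 4, 6)), matrix(FALSE, 4, 6))
  sp <- matrix(FALSE, 7, 7); sp[4, 4] <- TRUE
  expect_equal(sum(smooth_mask(sp)), 0)

  set.seed(12)
  for (i in 1:10) {
    r <- matrix(runif(100) < 0.5, 10, 10)
    expect_equal(smooth_mask(r), naive_smooth(r))
  }
})

test_that("contour extraction: single cell, block perimeter, blob choice", {
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  c1 <- extract_contour(m1)
  expect_equal(nrow(c1), 1)
  expect_equal(unlist(c1), c(ix = 3, iy = 3))

  m2 <- matrix(FALSE, 5, 5); m2[2:4, 2:4] <- TRUE
  c2 <- extract_contour(m2)
  expect_equal(nrow(c2), 8)                  # perimeter, centre excluded
  expect_false(any(c2$ix == 3 & c2$iy == 3))
  # every contour cell is mask-true with a false 8-neighbour
  for (k in seq_len(nrow(c2))) {
    expect_true(m2[c2$ix[k], c2$iy[k]])
    nb <- expand.grid(dx = -1:1, dy = -1:1)
    has_false <- any(apply(nb, 1, function(o) {
      qx <- c2$ix[k] + o[1]; qy <- c2$iy[k] + o[2]
      qx < 1 || qy < 1 || qx > 5 || qy > 5 || !m2[qx, qy]
    }))
    expect_true(has_false)
  }

  # two disjoint blobs: "first" takes the raster-order component,
  # "largest" the maximal-area one
  m3 <- matrix(FALSE, 10, 10)
  m3[2:3, 2:3] <- TRUE       # small blob, first in raster order
  m3[6:9, 6:9] <- TRUE       # large blob
  cf <- extract_contour(m3, "first")
  expect_true(all(cf$ix <= 3 & cf$iy <= 3))
  cl <- extract_contour(m3, "largest")
  expect_true(all(cl$ix >= 6 & cl$iy >= 6))

  expect_error(extract_contour(matrix(FALSE, 3, 3)), "empty")
})

test_that("distance field single-edge cases and the interior corridor", {
  # full 5x5 mask: contour is the 16-cell perimeter, centre lies two
  # orthogonal steps inside -> signed distance -20
  m <- matrix(TRUE, 5, 5)
  ctr <- extract_contour(m)
  expect_equal(nrow(ctr), 16)
  df <- distance_field(m, ctr, s = 10)
  expect_equal(df$d[1, 1], 0)                       # contour cell
  expect_equal(df$d[3, 3], -20)                     # corridor interior
  expect_equal(df$d[2, 3], -10)

  # single-cell tumour: orthogonal neighbour +10, diagonal +10*sqrt(2)
  m2 <- matrix(FALSE, 3, 3); m2[2, 2] <- TRUE
  df2 <- distance_field(m2, extract_contour(m2), s = 10)
  expect_equal(df2$d[2, 2], 0)
  expect_equal(df2$d[1, 2], 10)
  expect_equal(df2$d[1, 1], 10 * sqrt(2), tolerance = 1e-12)

  # 4-connectivity: diagonal costs two orthogonal steps
  df4 <- distance_field(m2, extract_contour(m2), s = 10, connectivity = 4)
  expect_equal(df4$d[1, 1], 20)
})

test_that("distance field equals Dijkstra on an explicit edge list", {
  set.seed(33)
  for (i in 1:10) {
    nx <- sample(8:20, 1); ny <- sample(8:20, 1)
    mask <- random_blob_mask(nx, ny)
    if (!any(mask)) next
    ctr <- extract_contour(mask)
    df <- distance_field(mask, ctr, s = 10)
    oracle <- oracle_grid_distance(mask, ctr, s = 10)
    expect_lt(max(abs(abs(df$d) - oracle)), 1e-9)
  }
})

test_that("distance field satisfies metric bound and source monotonicity", {
  set.seed(44)
  mask <- random_blob_mask(15, 15)
  ctr <- extract_contour(mask)
  df <- distance_field(mask, ctr, s = 10)
  # |d| >= straight-line distance to the nearest contour centre
  for (ix in seq_len(15)) for (iy in seq_len(15)) {
    chord <- min(sqrt((ctr$ix - ix)^2 + (ctr$iy - iy)^2)) * 10
    expect_gte(abs(df$d[ix, iy]) + 1e-9, chord)
  }
  # adding a source never increases any distance magnitude
  extra <- data.table::data.table(ix = c(ctr$ix, 15), iy = c(ctr$iy, 15))
  df2 <- distance_field(mask, extra, s = 10)
  expect_true(all(abs(df2$d) <= abs(df$d) + 1e-9))
})

test_that("band assignment uses half-open intervals with the stated edges", {
  # craft a 1-D field: cells along x, distances set directly
  counts <- matrix(1L, 6, 1, dimnames = list(NULL, "g"))
  tab <- make_tiny_table(counts, x = c(5, 15, 25, 35, 45, 55),
                         y = rep(5, 6))
  grid <- build_grid(tab, s = 10, origin = c(0, 0))
  d <- matrix(NA_real_, grid$nx, grid$ny)
  d[, 1] <- c(15, 20, 50, 70, 119.9, -30)
  dfield <- structure(list(d = d, s = 10, connectivity = 8,
                           contour = data.table::data.table(ix = 1, iy = 1),
                           unreachable = matrix(FALSE, grid$nx, grid$ny)),
                      class = "distance_field")
  ab <- assign_bands(tab, grid, dfield)
  expect_equal(ab$labels$band,
               c("peri", "mid", "mid", "distal", "distal", "beyond"))

  # uniform 30 um bands from -60 to 150: -30 falls in [-30,0)
  ab2 <- assign_bands(tab, grid, dfield, uniform_bands(-60, 150, 30))
  expect_equal(ab2$labels$band[6], "[-30,0)")
  expect_equal(ab2$labels$band[1], "[0,30)")

  # band areas: s^2 per grid cell in band
  expect_equal(as.numeric(ab$band_area["peri"]), 100)
  expect_error(band_partition(c(0, 10), c(20, 30), c("a", "b")),
               "overlapping")
})

test_that("band profile densities pool counts over band area", {
  counts <- matrix(c(4L, 6L), 2, 1, dimnames = list(NULL, "g"))
  tab <- make_tiny_table(counts, x = c(5, 15), y = c(5, 5))
  grid <- build_grid(tab, s = 10, origin = c(0, 0))
  d <- matrix(10, grid$nx, grid$ny)   # both grid cells in peri
  dfield <- structure(list(d = d, s = 10, connectivity = 8,
                           contour = data.table::data.table(ix = 1, iy = 1),
                           unreachable = matrix(FALSE, grid$nx, grid$ny)),
                      class = "distance_field")
  ab <- assign_bands(tab, grid, dfield)
  peri <- ab$profile[ab$profile$band == "peri", ]
  expect_equal(peri$density, 10 / ab$band_area["peri"], ignore_attr = TRUE)
})

test_that("band class proportions sum to one within each band", {
  bands <- c("peri", "peri", "peri", "mid", "mid")
  cls <- c("CXCL13+CD8+", "CXCL13-CD8+", "CXCL13+CD8+", "CXCL13-CD8+", NA)
  bp <- band_proportions(bands, cls)
  expect_equal(bp[bp$band == "peri" & bp$class == "CXCL13+CD8+", ]$proportion,
               2 / 3)
  sums <- tapply(bp$proportion, bp$band, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("UPGMC clustering reproduces hand-traced centroid linkage", {
  # identical profiles merge at height zero
  two <- rbind(a = c(1, 2), b = c(1, 2))
  res <- upgmc_cluster(two)
  expect_equal(res$hclust$height, 0)

  # {0}, {1}, {10}: merge {0,1} at 1, then centroid 0.5 vs 10 at 9.5
  three <- matrix(c(0, 1, 10), ncol = 1,
                  dimnames = list(c("p0", "p1", "p10"), "g"))
  res3 <- upgmc_cluster(three)
  expect_equal(res3$hclust$height, c(1, 9.5))
  expect_match(res3$newick, "p10")

  # duplicates merge before any non-duplicate pair
  four <- rbind(a = c(0, 0), b = c(5, 5), c = c(5, 5), d = c(9, 0))
  res4 <- upgmc_cluster(four)
  first <- sort(res4$hclust$merge[1, ])
  expect_equal(res4$hclust$height[1], 0)
  expect_equal(first, c(-3, -2))

  # random profiles match the naive centroid-linkage trace
  set.seed(17)
  for (i in 1:10) {
    profs <- matrix(rnorm(8 * 3, sd = 5), 8, 3)
    res <- upgmc_cluster(profs)
    expect_equal(res$hclust$height, oracle_upgmc_heights(profs),
                 tolerance = 1e-9)
  }

  expect_error(upgmc_cluster(matrix(1, 1, 2)), "at least 2")
})

test_that("full zonation tracks the analytic nest geometry on tissue", {
  sim <- get_default_sim(seed = 1)
  z <- run_zonation(sim$table)
  grid <- z$grid
  xc <- grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$s
  yc <- grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$s
  gx <- matrix(xc, grid$nx, grid$ny)
  gy <- matrix(yc, grid$nx, grid$ny, byrow = TRUE)
  ana <- sqrt((gx - 400)^2 + (gy - 400)^2) - 300
  err <- abs(abs(z$dfield$d) - abs(ana))
  # marker sampling at the nest edge leaves a little mask noise on top of
  # the grid metric, so the tissue-path bound is slightly looser than the
  # rasterized-geometry check
  expect_gt(mean(err <= 10 * sqrt(2), na.rm = TRUE), 0.98)
  # signs agree with the analytic side for all but boundary-adjacent cells
  away <- abs(ana) > 20
  expect_gt(mean(sign(z$dfield$d[away]) == sign(ana[away])), 0.99)
})
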