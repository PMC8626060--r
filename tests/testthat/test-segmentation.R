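# Organ masking and five-region partitioning.

test_that("a bright ellipse on dark background is masked exactly", {
  f <- make_ellipse_cube()
  m <- segment_organ(f$cube)
  expect_identical(m$mask, f$mask)
})

test_that("an all-background cube raises 'no organ found' with the threshold", {
  f <- make_ellipse_cube(fg = 0.05)  # nothing above threshold
  expect_error(segment_organ(f$cube), "no organ found.*0\\.25")
})

test_that("small specks are removed, keeping only the largest component", {
  f <- make_ellipse_cube()
  v <- f$cube$values
  # 10-pixel speck detached from the ellipse
  v[1:2, 1:5, ] <- 0.6
  cube <- hyper_cube(v, f$cube$wavelengths, value_kind = "reflectance")
  m <- segment_organ(cube)
  expect_identical(m$mask, f$mask)
})

test_that("interior holes are filled", {
  f <- make_ellipse_cube()
  v <- f$cube$values
  v[20, 15, ] <- 0.05  # dark pixel inside the organ
  cube <- hyper_cube(v, f$cube$wavelengths, value_kind = "reflectance")
  m <- segment_organ(cube)
  expect_true(m$mask[20, 15])
  expect_identical(m$mask, f$mask)
})

test_that("masking is 8-connected: a diagonal chain stays attached", {
  g <- default_wavelength_grid()
  vals <- array(0.05, c(30, 30, length(g)))
  vals[10:25, 2:4, ] <- 0.6                       # 48-px block
  for (i in 0:15) vals[11 + i, 5 + i, ] <- 0.6    # diagonal tail off its corner
  cube <- hyper_cube(vals, g, value_kind = "reflectance")
  m <- segment_organ(cube, min_organ_pixels = 20)
  # 4-connected labeling would keep only the 48-px block
  expect_identical(sum(m$mask), 48L + 16L)
  expect_true(m$mask[26, 20])
})

test_that("axis-aligned rectangle splits into five exactly equal regions", {
  m <- matrix(FALSE, 120, 40)
  m[11:110, 11:30] <- TRUE  # 100 x 20 = 2000 px
  lab <- partition_regions(m, apex_end = "low_projection")
  expect_identical(as.integer(table(lab$labels[lab$labels > 0])), rep(400L, 5))
  # regions are ordered along the long axis
  centro <- region_table(structure(c(list(labels = lab$labels), lab[-1]),
                                   class = "region_labels"))
  expect_true(all(diff(centro$centroid_line) > 0))
})

test_that("a 101-pixel line puts the extra pixel in the apex region", {
  m <- matrix(FALSE, 3, 105)
  m[2, 3:103] <- TRUE
  lab <- partition_regions(m, apex_end = "low_projection")
  counts <- as.integer(table(lab$labels[lab$labels > 0]))
  # brute-force rank partition of 101 ordered pixels: 21 + 4 * 20
  expect_identical(counts, c(21L, 20L, 20L, 20L, 20L))
  expect_identical(lab$labels[2, 3], 1L)
  expect_identical(lab$labels[2, 103], 5L)
})

test_that("rotated ellipse regions are balanced and ordered along the axis", {
  m <- make_ellipse_mask(theta = 30)
  n <- sum(m)
  lab <- partition_regions(m, apex_end = "low_projection")
  counts <- as.integer(table(lab$labels[lab$labels > 0]))
  expect_true(all(abs(counts - n / 5) <= 1))
  # oracle: sort pixels by projection on the principal axis, split into 5
  # rank blocks, and compare block means of the projection by region
  coords <- which(m, arr.ind = TRUE)
  cc <- sweep(coords, 2, colMeans(coords))
  v <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  proj <- as.numeric(cc %*% v)
  mean_proj <- sapply(1:5, function(r) mean(proj[lab$labels[coords] == r]))
  expect_true(all(diff(mean_proj) > 0) || all(diff(mean_proj) < 0))
})

test_that("region sizes stay within 1 px of area/5 on random blobs", {
  set.seed(42)
  for (i in 1:30) {
    m <- make_blob_mask(n_px = sample(60:400, 1))
    lab <- partition_regions(m, apex_end = "low_projection")
    counts <- tabulate(lab$labels[lab$labels > 0], nbins = 5)
    expect_true(all(abs(counts - sum(m) / 5) <= 1))
  }
})

test_that("swapping the apex end reverses the region order", {
  # exact on a 100-px line (area divisible by 5, no projection ties)
  m <- matrix(FALSE, 3, 104)
  m[2, 3:102] <- TRUE
  lo <- partition_regions(m, apex_end = "low_projection")
  hi <- partition_regions(m, apex_end = "high_projection")
  sel <- lo$labels > 0
  expect_identical(hi$labels[sel], 6L - lo$labels[sel])
  # near-exact on a rotated ellipse (boundary pixels may swap blocks when
  # the area is not divisible by 5)
  e <- make_ellipse_mask(theta = 20)
  lo2 <- partition_regions(e, apex_end = "low_projection")
  hi2 <- partition_regions(e, apex_end = "high_projection")
  sel2 <- lo2$labels > 0
  expect_gt(mean(hi2$labels[sel2] == 6L - lo2$labels[sel2]), 0.98)
})

test_that("partition is equivariant under 90-degree rotation", {
  set.seed(7)
  m <- make_blob_mask(n_px = 250)
  lab <- partition_regions(m, apex_end = "low_projection")$labels
  # rotate image by 90 degrees (transpose + reverse rows)
  m90 <- t(m)[rev(seq_len(ncol(m))), ]
  lab90 <- partition_regions(m90, apex_end = "low_projection")$labels
  back <- t(lab90[rev(seq_len(nrow(lab90))), ])
  sel <- lab > 0
  agree <- mean(back[sel] == lab[sel])
  rev_agree <- mean(back[sel] == (6L - lab[sel]))
  # same partition up to the axis-direction convention
  expect_gt(max(agree, rev_agree), 0.99)
})

test_that("mirroring with apex_end swapped reproduces the partition", {
  m <- make_ellipse_mask(theta = 0, a = 24, b = 7)
  lab <- partition_regions(m, apex_end = "low_projection")$labels
  mm <- m[rev(seq_len(nrow(m))), ]
  labm <- partition_regions(mm, apex_end = "high_projection")$labels
  back <- labm[rev(seq_len(nrow(labm))), ]
  sel <- lab > 0
  expect_gt(mean(back[sel] == lab[sel]), 0.99)
})

test_that("auto apex detection picks the narrow end of a tapered organ", {
  sim <- make_sim(seed = 5)
  m <- segment_organ(sim$cube)
  lab <- partition_regions(m, apex_end = "auto")
  truth <- sim$labels$labels
  sel <- truth > 0 & lab$labels > 0
  expect_gt(mean(lab$labels[sel] == truth[sel]), 0.97)
})

test_that("degenerate masks are rejected", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE
  expect_error(partition_regions(m), "fewer than 2")
})

test_that("equal-length mode matches equal-area on a uniform rectangle", {
  m <- matrix(FALSE, 110, 30)
  m[6:105, 6:25] <- TRUE
  a <- partition_regions(m, apex_end = "low_projection", partition = "equal_area")
  b <- partition_regions(m, apex_end = "low_projection", partition = "equal_length")
  expect_identical(a$labels, b$labels)
})
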