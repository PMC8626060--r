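# ENVI cube I/O, wavelength grid, and reflectance calibration.

test_that("default wavelength grid spans 400-1000 nm in 204 uniform steps", {
  g <- default_wavelength_grid()
  expect_length(g, 204)
  expect_equal(g[1], 400)
  expect_equal(g[204], 1000)
  expect_equal(unique(round(diff(g), 10)), round(600 / 203, 10))
})

test_that("nearest_band matches exhaustive argmin and handles edges", {
  g <- default_wavelength_grid()
  expect_identical(nearest_band(g, 400), 1L)
  # frozen from brute-force argmin over all 204 centers
  expect_identical(nearest_band(g, 550), 52L)
  expect_equal(g[52], 550.7389, tolerance = 1e-4)
  expect_identical(nearest_band(g, 670), 92L)
  expect_equal(g[92], 668.9655, tolerance = 1e-4)
  # exhaustive-argmin property on random targets
  set.seed(11)
  targets <- runif(1000, 399, 1001)
  for (t in targets) {
    expect_identical(nearest_band(g, t), which.min(abs(g - t)))
  }
  # ties break toward the lower wavelength
  expect_identical(nearest_band(c(100, 200), 150), 1L)
  expect_error(nearest_band(g, 4000), "outside the grid")
})

test_that("write/read round-trips values, grid, and metadata for all interleaves", {
  set.seed(2)
  g <- default_wavelength_grid()
  v <- array(round(runif(4 * 4 * 204), 4), c(4, 4, 204))
  cube <- hyper_cube(v, g, organ = "flag_leaf", angle = 105, regime = "N2",
                     plant_id = "N2_p01", value_kind = "reflectance")
  for (il in c("bil", "bip", "bsq")) {
    path <- file.path(withr::local_tempdir(), paste0("c_", il))
    write_envi_cube(cube, path, il, data_type = 5)
    back <- read_envi_cube(path)
    expect_identical(back$values, v)
    expect_equal(back$wavelengths, g, tolerance = 1e-4)
    expect_identical(back$organ, "flag_leaf")
    expect_identical(back$angle, 105)
    expect_identical(back$regime, "N2")
    expect_identical(back$plant_id, "N2_p01")
    expect_identical(back$value_kind, "reflectance")
  }
})

test_that("on-disk interleave does not change in-memory values", {
  set.seed(3)
  v <- array(runif(3 * 5 * 204), c(3, 5, 204))
  cube <- hyper_cube(v, default_wavelength_grid())
  d <- withr::local_tempdir()
  write_envi_cube(cube, file.path(d, "a"), "bsq", data_type = 5)
  write_envi_cube(cube, file.path(d, "b"), "bil", data_type = 5)
  expect_identical(read_envi_cube(file.path(d, "a"))$values,
                   read_envi_cube(file.path(d, "b"))$values)
})

test_that("header records the grid endpoints with decimals", {
  cube <- hyper_cube(array(0.1, c(2, 2, 204)), default_wavelength_grid())
  path <- file.path(withr::local_tempdir(), "g")
  write_envi_cube(cube, path)
  hdr <- paste(readLines(paste0(path, ".hdr")), collapse = " ")
  expect_match(hdr, "400\\.0000")
  expect_match(hdr, "1000\\.0000")
})

test_that("band-count mismatch between header and binary is a loud error", {
  cube <- hyper_cube(array(0.2, c(4, 4, 204)), default_wavelength_grid())
  path <- file.path(withr::local_tempdir(), "bad")
  write_envi_cube(cube, path, "bil")
  # truncate the binary to 203 bands' worth of data
  sz <- file.size(paste0(path, ".dat"))
  con <- file(paste0(path, ".dat"), "r+b")
  truncate(con, sz * 203 / 204)
  close(con)
  expect_error(read_envi_cube(path), "mismatch.*204")
})

test_that("a header without a wavelength list is rejected", {
  path <- file.path(withr::local_tempdir(), "nw")
  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 2",
               "data type = 4", "interleave = bil", "byte order = 0"),
             paste0(path, ".hdr"))
  writeBin(numeric(8), paste0(path, ".dat"), size = 4)
  expect_error(read_envi_cube(path), "wavelength")
})

test_that("unknown interleave is rejected on write", {
  cube <- hyper_cube(array(0.2, c(2, 2, 204)), default_wavelength_grid())
  expect_error(write_envi_cube(cube, tempfile(), "bif"))
})

test_that("reflectance conversion implements (raw-dark)/(white-dark)", {
  g <- default_wavelength_grid()
  white <- seq(1000, 4000, length.out = 204)
  dark <- rep(100, 204)
  mk <- function(spec) hyper_cube(
    aperm(array(spec, c(204, 2, 2)), c(2, 3, 1)), g, value_kind = "raw")
  refs <- reference_set(white, dark)
  expect_true(all(to_reflectance(mk(white), refs)$values == 1))
  expect_true(all(to_reflectance(mk(dark), refs)$values == 0))
  mid <- to_reflectance(mk(dark + 0.5 * (white - dark)), refs)$values
  expect_equal(unique(as.vector(round(mid, 12))), 0.5)
  expect_error(reference_set(white, white), "exceed")
})

test_that("calibration is invariant under joint per-band rescaling", {
  set.seed(4)
  g <- default_wavelength_grid()
  raw <- array(runif(2 * 3 * 204, 100, 900), c(2, 3, 204))
  white <- runif(204, 1000, 2000)
  dark <- runif(204, 0, 50)
  scale <- runif(204, 0.5, 3)
  r1 <- to_reflectance(hyper_cube(raw, g), reference_set(white, dark))
  r2 <- to_reflectance(hyper_cube(sweep(raw, 3, scale, "*"), g),
                       reference_set(white * scale, dark * scale))
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
})

test_that("reflectance is clipped to [0, 1.5] and flagged specular pixels survive", {
  g <- default_wavelength_grid()
  raw <- array(5000, c(1, 1, 204))  # far above white
  r <- to_reflectance(hyper_cube(raw, g), reference_set(rep(1000, 204)))
  expect_true(all(r$values == 1.5))
  expect_identical(r$value_kind, "reflectance")
})
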