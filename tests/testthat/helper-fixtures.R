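# Fixtures are built in code: small cubes, shaped masks, and spectra with
# exact values at the index bands.

# reflectance cube with a constant-spectrum ellipse on a dark background
make_ellipse_cube <- function(nl = 40, nc = 30, nb = 204, fg = 0.5, bg = 0.05,
                              a = 15, b = 8, grid = default_wavelength_grid()) {
  stopifnot(length(grid) == nb)
  rows <- matrix(seq_len(nl), nl, nc)
  cols <- matrix(seq_len(nc), nl, nc, byrow = TRUE)
  ell <- ((rows - (nl + 1) / 2) / a)^2 + ((cols - (nc + 1) / 2) / b)^2 <= 1
  vals <- array(bg, c(nl, nc, nb))
  for (k in seq_len(nb)) vals[, , k][ell] <- fg
  list(cube = hyper_cube(vals, grid, value_kind = "reflectance"), mask = ell)
}

# logical ellipse mask, optionally rotated (degrees)
make_ellipse_mask <- function(nl = 60, nc = 60, a = 24, b = 8, theta = 0) {
  rows <- matrix(seq_len(nl), nl, nc) - (nl + 1) / 2
  cols <- matrix(seq_len(nc), nl, nc, byrow = TRUE) - (nc + 1) / 2
  th <- theta * pi / 180
  u <- rows * cos(th) + cols * sin(th)
  v <- -rows * sin(th) + cols * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# random connected blob mask grown from a seed pixel
make_blob_mask <- function(nl = 40, nc = 40, n_px = 300) {
  m <- matrix(FALSE, nl, nc)
  r <- nl %/% 2; c <- nc %/% 2
  m[r, c] <- TRUE
  frontier <- matrix(c(r, c), ncol = 2)
  while (sum(m) < n_px && nrow(frontier) > 0) {
    i <- sample.int(nrow(frontier), 1)
    p <- frontier[i, ]
    nb <- cbind(p[1] + c(-1, 1, 0, 0), p[2] + c(0, 0, -1, 1))
    ok <- nb[, 1] >= 1 & nb[, 1] <= nl & nb[, 2] >= 1 & nb[, 2] <= nc
    nb <- nb[ok, , drop = FALSE]
    new <- nb[!m[nb], , drop = FALSE]
    if (nrow(new)) {
      j <- sample.int(nrow(new), 1)
      m[new[j, 1], new[j, 2]] <- TRUE
      frontier <- rbind(frontier, new[j, ])
    } else {
      frontier <- frontier[-i, , drop = FALSE]
    }
  }
  m
}

# spectrum object with given reflectance values at the nearest bands to
# `at` (nm), `base` elsewhere
make_spectrum <- function(at = numeric(0), values = numeric(0), base = 0.3,
                          grid = default_wavelength_grid()) {
  refl <- rep(base, length(grid))
  for (i in seq_along(at)) refl[nearest_band(grid, at[i])] <- values[i]
  structure(
    list(reflectance = refl, wavelengths = grid, organ = "flag_leaf",
         region = "central", angle = 105, regime = "N3",
         plant_id = "p1", n_pixels = 10L),
    class = "spectrum"
  )
}

# small simulated organ ready for the segmentation/index stages
make_sim <- function(regime = "N3", organ = "second_leaf", angle = 105,
                     seed = 1, cube_size = c(48, 48), ...) {
  p <- sim_params(cube_size = cube_size, ...)
  simulate_leaf_cube(p, regime, organ, angle, seed = seed,
                     plant_id = paste0(regime, "_t"))
}
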