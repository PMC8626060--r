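# Synthetic hyperspectral cubes and growth records with the regime
# structure of a six-level nitrogen trial.
#
# The reflectance surrogate is a Beer-Lambert style pigment model:
#   R(lambda) = floor + R_struct(lambda) * exp(-A(lambda))
# with a logistic red-edge structural term and Gaussian absorption bands for
# chlorophyll (a blue-green shoulder plus the red band), carotenoids and
# water. It is not a radiative-transfer model; it exists to give the
# analysis stack a recoverable, regime-dependent truth.

# run expr with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation parameters for the synthetic organ generator
#'
#' Defaults encode the study conditions the generator emulates: pigment
#' content decreasing from N1 (160 % of the recommended N rate) to N6 (40 %),
#' a within-leaf nitrogen-sensitivity gradient pointing to the apex in the
#' flag leaf and to the base in the second uppermost leaf, a regime-dependent
#' NIR plateau in the second leaf only, a spike whose pigments do not depend
#' on regime at all, and stronger specular glint at the 125 degree shooting
#' angle than at 105 degrees.
#'
#' @param cab_n1,cab_n6 per-organ chlorophyll absorbance anchors at the N1
#'   and N6 regimes (arbitrary absorbance units); intermediate regimes are
#'   linear in total applied N.
#' @param deficit_scale per-organ amplification of pigment loss in the
#'   nitrogen-sensitive end of the organ (0 = no within-organ gradient).
#' @param pnir_n1,pnir_n6 per-organ NIR plateau anchors (reflectance units).
#' @param ccar_slope,ccar_base carotenoid absorbance as an affine function of
#'   the chlorophyll absorbance.
#' @param cw water absorbance (constant across regimes).
#' @param abs_bands absorption band table: per pigment a matrix of
#'   (center nm, sigma nm, weight) rows defining unit-height Gaussians.
#' @param floor additive reflectance floor.
#' @param struct_base visible-range structural reflectance amplitude.
#' @param re_center,re_width red-edge logistic center and width (nm).
#' @param glint_sigma named per-angle sigma of the half-normal, spectrally
#'   flat specular glint component `|N(0, sigma)|` added to the reflectance
#'   (surface reflection carries the source spectrum, not the leaf's, which
#'   is what blurs ratio indices at the unfavourable angle).
#' @param pixel_noise_sd additive per-pixel-per-band noise sd.
#' @param plant_cv log-scale sd of the per-plant chlorophyll multiplier
#'   (biological plant-to-plant variation, shared across organs and angles
#'   of one plant).
#' @param background reflectance range of the black paper background.
#' @param cube_size cube height and width in pixels.
#' @param visible_ratio_target per-organ calibration target for the
#'   N1/N6 mean visible (500--700 nm) reflectance ratio.
#' @param growth_cv default coefficient of variation of growth records.
#' @param grid wavelength grid (nm).
#' @param design a [regime_design()] table.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(cab_n1 = c(flag_leaf = 4.0, second_leaf = 4.0, spike = 2.8),
                       cab_n6 = c(flag_leaf = 2.0, second_leaf = 2.0, spike = 2.8),
                       deficit_scale = c(flag_leaf = 0.25, second_leaf = 0.45, spike = 0),
                       pnir_n1 = c(flag_leaf = 0.75, second_leaf = 0.80, spike = 0.72),
                       pnir_n6 = c(flag_leaf = 0.75, second_leaf = 0.70, spike = 0.72),
                       ccar_slope = 0.25, ccar_base = 0.5, cw = 0.35,
                       abs_bands = list(
                         cab = rbind(c(430, 80, 1.0), c(670, 25, 0.9)),
                         ccar = rbind(c(470, 25, 1.0)),
                         cw = rbind(c(970, 40, 1.0))
                       ),
                       floor = 0.03, struct_base = 0.08,
                       re_center = 715, re_width = 12,
                       glint_sigma = c(`105` = 0.004, `125` = 0.08),
                       pixel_noise_sd = 0.01, plant_cv = 0.04,
                       background = c(0.03, 0.06),
                       cube_size = c(128, 128),
                       visible_ratio_target = c(flag_leaf = 0.808, second_leaf = 0.753),
                       growth_cv = 0.06,
                       grid = default_wavelength_grid(),
                       design = regime_design()) {
  stopifnot(all(cab_n1 >= 0), all(cab_n6 >= 0), all(deficit_scale >= 0),
            all(pnir_n1 > 0 & pnir_n1 < 1), all(pnir_n6 > 0 & pnir_n6 < 1),
            cw >= 0, floor >= 0, pixel_noise_sd >= 0, plant_cv >= 0,
            length(cube_size) == 2L, all(cube_size >= 16L))
  check_wavelength_grid(grid)
  p <- list(cab_n1 = cab_n1, cab_n6 = cab_n6, deficit_scale = deficit_scale,
            pnir_n1 = pnir_n1, pnir_n6 = pnir_n6,
            ccar_slope = ccar_slope, ccar_base = ccar_base, cw = cw,
            abs_bands = abs_bands, floor = floor, struct_base = struct_base,
            re_center = re_center, re_width = re_width,
            glint_sigma = glint_sigma, pixel_noise_sd = pixel_noise_sd,
            plant_cv = plant_cv, background = background,
            cube_size = as.integer(cube_size),
            visible_ratio_target = visible_ratio_target,
            growth_cv = growth_cv, grid = grid, design = design,
            growth_means = .default_growth_means())
  class(p) <- "sim_params"
  p
}

# default regime mean table for the growth-record generator; see the methods
# vignette for the anchoring of the N1/N6 endpoints and the interpolation
.default_growth_means <- function() {
  seed_n3 <- 4.49 / 0.54  # fixed by the N6/N3 and N6/N1 seed-weight ratios
  data.frame(
    regime = paste0("N", 1:6),
    height = seq(100, 85.6, length.out = 6),
    spad = seq(50, 32.45, length.out = 6),
    lai = seq(5, 2.205, length.out = 6),
    leaf_n = c(2.1, 2.1, 1.9, 1.7, 1.5, 1.2),
    seed_weight = c(10, (10 + seed_n3) / 2, seed_n3,
                    seed_n3 - (seed_n3 - 4.49) / 3,
                    seed_n3 - 2 * (seed_n3 - 4.49) / 3, 4.49),
    stringsAsFactors = FALSE
  )
}

.regime_frac <- function(params, regime) {
  ix <- match(regime, params$design$regime)
  if (is.na(ix)) stop("unknown regime: ", regime, call. = FALSE)
  tot <- params$design$total
  (tot[ix] - min(tot)) / (max(tot) - min(tot))  # 0 at N6, 1 at N1
}

# per-organ, per-regime chlorophyll absorbance (before the axis gradient)
.cab_regime <- function(params, organ, regime) {
  f <- .regime_frac(params, regime)
  params$cab_n6[[organ]] + f * (params$cab_n1[[organ]] - params$cab_n6[[organ]])
}

.pnir_regime <- function(params, organ, regime) {
  f <- .regime_frac(params, regime)
  params$pnir_n6[[organ]] + f * (params$pnir_n1[[organ]] - params$pnir_n6[[organ]])
}

# nitrogen-deficit severity, 0 at N1 down to -(1 - 36.4/145.6) at N6
.deficit <- function(params, regime) {
  ix <- match(regime, params$design$regime)
  -(1 - params$design$total[ix] / max(params$design$total))
}

# axis-position sensitivity weight w(s), s = 0 at apex, 1 at base; quadratic
# so the sensitive end stands out from its neighbouring region
.gradient_weight <- function(organ, s) {
  switch(organ,
    flag_leaf = (1 - s)^4,   # apex most nitrogen-sensitive
    second_leaf = s^4,       # base most nitrogen-sensitive
    spike = rep(0, length(s)),
    stop("unknown organ: ", organ, call. = FALSE)
  )
}

# relative half-width of the organ outline at axis position s (apex at s=0
# tapers harder than the base, so the narrow-end heuristic can find the apex)
organ_width_profile <- function(s, organ = c("flag_leaf", "second_leaf", "spike")) {
  organ <- match.arg(organ)
  h <- if (organ == "spike") s^0.5 * (1 - s)^0.35 else s^0.7 * (1 - s)^0.25
  h / max(h[h > 0], 1e-12)
}

#' Noise-free synthetic leaf/spike reflectance spectrum
#'
#' Evaluates the pigment surrogate at one or more axis positions `s`
#' (0 = apex, 1 = base). The effective chlorophyll absorbance is
#' `Cab(regime) * (1 + deficit_scale * w(s) * deficit(regime))`, so nitrogen
#' deficiency removes extra pigment from the organ's sensitive end.
#'
#' @param params a [sim_params()] object.
#' @param regime regime id (`"N1"`..`"N6"`).
#' @param s axis position(s) in `[0, 1]`.
#' @param organ organ name.
#' @param grid wavelength grid; defaults to the one in `params`.
#' @return Numeric matrix `length(s) x length(grid)` of reflectances
#'   (a vector if `length(s) == 1`).
#' @export
leaf_reflectance_model <- function(params, regime, s, organ = "flag_leaf",
                                   grid = params$grid) {
  stopifnot(inherits(params, "sim_params"), all(s >= 0 & s <= 1))
  organ <- match.arg(organ, c("flag_leaf", "second_leaf", "spike"))
  cab0 <- .cab_regime(params, organ, regime)
  cab_eff <- cab0 * (1 + params$deficit_scale[[organ]] *
                       .gradient_weight(organ, s) * .deficit(params, regime))
  cab_eff <- pmax(cab_eff, 0)
  ccar <- params$ccar_slope * cab0 + params$ccar_base
  pnir <- .pnir_regime(params, organ, regime)

  gsum <- function(bands) {
    out <- numeric(length(grid))
    for (r in seq_len(nrow(bands))) {
      out <- out + bands[r, 3] * exp(-(grid - bands[r, 1])^2 / (2 * bands[r, 2]^2))
    }
    out
  }
  g_cab <- gsum(params$abs_bands$cab)
  g_ccar <- gsum(params$abs_bands$ccar)
  g_cw <- gsum(params$abs_bands$cw)

  r_struct <- params$struct_base + (pnir - params$struct_base) *
    stats::plogis((grid - params$re_center) / params$re_width)

  # absorbance: outer over (s, lambda) for the gradient-dependent term
  A <- outer(cab_eff, g_cab) +
    matrix(ccar * g_ccar + params$cw * g_cw, nrow = length(s),
           ncol = length(grid), byrow = TRUE)
  R <- params$floor + sweep(exp(-A), 2, r_struct, "*")
  if (length(s) == 1L) as.numeric(R) else R
}

#' Area-weighted mean noise-free spectrum of a synthetic organ
#'
#' Averages [leaf_reflectance_model()] over the organ axis, weighting each
#' axis position by the organ's outline width (so it matches the pixel mean
#' over a rendered mask up to discretization).
#'
#' @inheritParams leaf_reflectance_model
#' @param n_s number of axis quadrature points.
#' @return A `spectrum` object.
#' @export
mean_leaf_spectrum <- function(params, regime, organ = "flag_leaf", n_s = 201L) {
  s <- (seq_len(n_s) - 0.5) / n_s
  w <- organ_width_profile(s, organ)
  R <- leaf_reflectance_model(params, regime, s, organ)
  refl <- as.numeric(crossprod(w / sum(w), R))
  structure(
    list(reflectance = refl, wavelengths = params$grid, organ = organ,
         region = "all", angle = NA_real_, regime = regime,
         plant_id = NA_character_, n_pixels = NA_integer_),
    class = "spectrum"
  )
}

#' Visible-range mean reflectance ratio N1/N6
#'
#' Mean noise-free reflectance over all bands with centers in
#' `[500, 700]` nm, N1 relative to N6, for one organ's generator.
#'
#' @inheritParams leaf_reflectance_model
#' @return The ratio (dimensionless, < 1 when N1 is darker).
#' @export
measure_visible_ratio <- function(params, organ = "flag_leaf") {
  sel <- params$grid >= 500 & params$grid <= 700
  m1 <- mean(mean_leaf_spectrum(params, "N1", organ)$reflectance[sel])
  m6 <- mean(mean_leaf_spectrum(params, "N6", organ)$reflectance[sel])
  m1 / m6
}

#' Calibrate the generator to a target visible-reflectance ratio
#'
#' Holds the N6 pigment content fixed and rescales the organ's N1
#' chlorophyll anchor by bisection until the noise-free 500--700 nm mean
#' reflectance ratio N1/N6 ([measure_visible_ratio()]) matches
#' `target_ratio` to within `tol`. Intermediate regimes re-interpolate
#' between the calibrated N1 and fixed N6 anchors.
#'
#' @inheritParams leaf_reflectance_model
#' @param target_ratio target ratio in (0, 1); defaults to the organ's
#'   entry in `params$visible_ratio_target`.
#' @param tol ratio tolerance for bisection.
#' @return The adjusted [sim_params()] object.
#' @export
calibrate_visible_ratio <- function(params, organ = "flag_leaf",
                                    target_ratio = NULL, tol = 1e-4) {
  organ <- match.arg(organ, c("flag_leaf", "second_leaf", "spike"))
  if (is.null(target_ratio)) target_ratio <- params$visible_ratio_target[[organ]]
  stopifnot(target_ratio > 0, target_ratio < 1)
  ratio_at <- function(cab1) {
    p <- params
    p$cab_n1[[organ]] <- cab1
    measure_visible_ratio(p, organ)
  }
  lo <- params$cab_n6[[organ]] * 1.0001  # N1 at least as pigmented as N6
  hi <- 60
  r_lo <- ratio_at(lo); r_hi <- ratio_at(hi)  # ratio decreases in cab_n1
  if (target_ratio > r_lo || target_ratio < r_hi) {
    stop(sprintf(
      "target ratio %.4f unreachable; achievable range is [%.4f, %.4f]",
      target_ratio, r_hi, r_lo), call. = FALSE)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    r_mid <- ratio_at(mid)
    if (abs(r_mid - target_ratio) < tol) break
    if (r_mid > target_ratio) lo <- mid else hi <- mid
  }
  params$cab_n1[[organ]] <- mid
  params
}

#' Render a synthetic organ cube
#'
#' Draws the organ outline (tapered blade for leaves, lanceolate with
#' pigment texture for spikes) on a dark background, fills each foreground
#' pixel with the model spectrum at its axis position, then applies
#' plant-level pigment variation, angle-dependent additive specular glint
#' patches (`|N(0, glint_sigma[angle])|`, spectrally flat) and additive
#' pixel noise. Deterministic for a fixed `seed`.
#'
#' @inheritParams leaf_reflectance_model
#' @param angle shooting angle, 105 or 125 degrees.
#' @param seed RNG seed for this plant/acquisition.
#' @param plant_id identifier stored in the cube metadata.
#' @param plant_seed optional separate seed for the plant-level biology
#'   (pigment multiplier), so the same plant can be rendered at several
#'   angles with the same biological state; defaults to `seed`.
#' @return List with elements `cube` (a reflectance [hyper_cube()]) and
#'   `labels` (ground-truth [partition_regions()]-style `region_labels`
#'   built from the true axis positions).
#' @export
simulate_leaf_cube <- function(params, regime, organ, angle = 105, seed = 1L,
                               plant_id = NA_character_, plant_seed = seed) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.character(organ) || length(organ) != 1L ||
      !organ %in% c("spike", "flag_leaf", "second_leaf")) {
    stop("unknown organ: ", organ, call. = FALSE)
  }
  angle_key <- as.character(angle)
  if (!angle_key %in% names(params$glint_sigma)) {
    stop("no glint sigma configured for angle ", angle, call. = FALSE)
  }
  nl <- params$cube_size[1]; ns <- params$cube_size[2]
  nb <- length(params$grid)

  # plant-level biology (shared across angles via plant_seed)
  cab_mult <- with_seed(plant_seed, exp(stats::rnorm(1, 0, params$plant_cv)))

  with_seed(seed + 1664525L, {
    # organ outline along the line axis
    r0 <- 0.08 * nl; r1 <- 0.92 * nl
    rows <- seq_len(nl)
    s_row <- (rows - r0) / (r1 - r0)
    inside_row <- s_row >= 0 & s_row <= 1
    hw_max <- 0.16 * ns
    half_w <- numeric(nl)
    half_w[inside_row] <- pmax(
      organ_width_profile(pmin(pmax(s_row[inside_row], 1e-6), 1 - 1e-6), organ) * hw_max,
      0)
    col_c <- (ns + 1) / 2
    mask <- outer(half_w, abs(seq_len(ns) - col_c), function(h, d) d <= h & h > 0.5)

    values <- array(0, dim = c(nl, ns, nb))
    # background: flat dark paper with slight pixel-to-pixel variation
    bg <- which(!mask)
    bg_level <- stats::runif(length(bg), params$background[1], params$background[2])
    for (b in seq_len(nb)) values[bg + (b - 1L) * nl * ns] <- bg_level

    # foreground: one model spectrum per occupied row (equal s within a row)
    p_plant <- params
    p_plant$cab_n1 <- params$cab_n1 * cab_mult
    p_plant$cab_n6 <- params$cab_n6 * cab_mult
    occ <- which(inside_row & half_w > 0.5)
    spectra <- leaf_reflectance_model(p_plant, regime,
                                      pmin(pmax(s_row[occ], 0), 1), organ)
    if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)

    fg <- which(mask, arr.ind = TRUE)
    row_of <- match(fg[, 1], occ)
    npx <- nrow(fg)
    pix <- spectra[row_of, , drop = FALSE]

    if (organ == "spike") {
      # spikelet texture: per-pixel multiplicative reflectance variation
      pix <- pix * (1 + stats::rnorm(npx, 0, 0.05))
    }
    # glint: surface-reflected (specular) light bypasses the leaf pigments,
    # so it adds a spectrally flat component. An acquisition-level offset
    # (the organ's overall pose relative to the sun) dominates, with smaller
    # row-coherent patches on top; neither averages out within a region.
    gs <- params$glint_sigma[[angle_key]]
    g_cube <- abs(stats::rnorm(1, 0, gs))
    g_row <- abs(stats::rnorm(length(occ), 0, gs / 3))
    pix <- pix + g_cube + g_row[row_of]
    pix <- pix + matrix(stats::rnorm(npx * nb, 0, params$pixel_noise_sd), npx, nb)
    pix[pix < 0] <- 0
    pix[pix > 1.5] <- 1.5

    flat <- fg[, 1] + (fg[, 2] - 1L) * nl
    for (b in seq_len(nb)) values[flat + (b - 1L) * nl * ns] <- pix[, b]

    cube <- hyper_cube(values, params$grid, organ = organ, angle = angle,
                       regime = regime, plant_id = plant_id,
                       value_kind = "reflectance")

    # ground-truth labels: equal-area quintiles of the true axis position
    s_px <- s_row[fg[, 1]]
    ord <- order(s_px, fg[, 1], fg[, 2])
    q <- npx %/% 5L; rmd <- npx %% 5L
    sizes <- q + as.integer(seq_len(5L) <= rmd)
    lab <- matrix(0L, nl, ns)
    lab[fg[ord, , drop = FALSE]] <- rep.int(1:5, sizes)
    labels <- structure(
      list(labels = lab, apex_end = "low_projection", partition = "equal_area",
           organ = organ, angle = angle, regime = regime, plant_id = plant_id),
      class = "region_labels")

    list(cube = cube, labels = labels)
  })
}

#' Simulate per-plant growth records
#'
#' Draws plant height (cm), SPAD, LAI, leaf nitrogen (% dry mass) and seed
#' weight (g/plant) from normal distributions around the regime mean table
#' (sd = `cv * mean`, truncated at zero). At `cv = 0` every record equals
#' its regime mean exactly.
#'
#' @param params a [sim_params()] object.
#' @param n_per_regime plants per regime (>= 2).
#' @param cv coefficient of variation; defaults to `params$growth_cv`.
#' @param seed RNG seed.
#' @return data.frame with one row per plant: `plant_id`, `regime`,
#'   `height`, `spad`, `lai`, `leaf_n`, `seed_weight`.
#' @export
simulate_growth_records <- function(params, n_per_regime = 10L,
                                    cv = params$growth_cv, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  if (n_per_regime < 2L) stop("n_per_regime must be >= 2", call. = FALSE)
  if (!is.numeric(cv) || length(cv) != 1L || cv < 0) {
    stop("cv must be a single non-negative number", call. = FALSE)
  }
  gm <- params$growth_means
  traits <- c("height", "spad", "lai", "leaf_n", "seed_weight")
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(gm)), function(i) {
      rec <- data.frame(
        plant_id = sprintf("%s_p%02d", gm$regime[i], seq_len(n_per_regime)),
        regime = gm$regime[i], stringsAsFactors = FALSE)
      for (tr in traits) {
        m <- gm[[tr]][i]
        if (cv == 0) {
          rec[[tr]] <- rep(m, n_per_regime)
        } else {
          x <- stats::rnorm(n_per_regime, m, cv * m)
          while (any(x <= 0)) {  # truncate at zero by redraw
            bad <- x <= 0
            x[bad] <- stats::rnorm(sum(bad), m, cv * m)
          }
          rec[[tr]] <- x
        }
      }
      rec
    }))
    rownames(out) <- NULL
    out
  })
}
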