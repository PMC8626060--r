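# Region-mean spectra and vegetation indices.

VI_NAMES <- c("NDVI", "MRE_NDVI", "GNDVI", "PSSRc")

#' Default vegetation-index wavelengths (nm)
#'
#' The four indices use standard literature band positions: NDVI
#' `(R800-R670)/(R800+R670)`, GNDVI `(R800-R550)/(R800+R550)`, MRE-NDVI in its
#' mND705 form `(R750-R705)/(R750+R705-2*R445)`, and PSSRc `R800/R470`.
#' Actual bands are chosen by [nearest_band()] on the cube's grid; every
#' position can be overridden.
#'
#' @return Named list of wavelengths in nm.
#' @export
vi_wavelengths <- function() {
  list(nir = 800, red = 670, green = 550, blue = 445, re_low = 705,
       re_high = 750, violet = 470)
}

#' Mean spectrum of one labeled region
#'
#' Arithmetic per-band mean over the pixels of a region (an ENVI-style ROI
#' mean). Index values downstream are computed from this mean spectrum, not
#' averaged per-pixel, which damps specular glint.
#'
#' @param cube a reflectance [hyper_cube()].
#' @param labels a [partition_regions()] result (or integer matrix 0..5).
#' @param region region name (`"apex"`, `"distal"`, `"central"`, `"proximal"`,
#'   `"base"`), integer 1..5, or `"all"` for the whole mask.
#' @return Object of class `spectrum`: `reflectance`, `wavelengths`,
#'   provenance fields and `n_pixels`.
#' @export
region_mean_spectrum <- function(cube, labels, region = "all") {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  .region_mean_spectrum_flat(cube, matrix(cube$values, d[1] * d[2], d[3]),
                             labels, region)
}

# workhorse taking the cube already flattened to (pixel, band); lets a batch
# pay the flattening copy once per cube instead of once per region
.region_mean_spectrum_flat <- function(cube, vmat, labels, region) {
  lab <- if (inherits(labels, "region_labels")) labels$labels else labels
  if (!identical(dim(lab), dim(cube$values)[1:2])) {
    stop("label image dimensions do not match cube", call. = FALSE)
  }
  if (identical(region, "all")) {
    sel <- lab > 0L
    region_name <- "all"
  } else {
    rid <- if (is.character(region)) match(region, REGION_NAMES) else as.integer(region)
    if (is.na(rid) || rid < 1L || rid > 5L) stop("unknown region: ", region, call. = FALSE)
    sel <- lab == rid
    region_name <- REGION_NAMES[rid]
  }
  npx <- sum(sel)
  if (npx == 0L) stop("region '", region_name, "' has no pixels", call. = FALSE)
  refl <- colMeans(vmat[as.vector(sel), , drop = FALSE])
  structure(
    list(reflectance = refl, wavelengths = cube$wavelengths,
         organ = cube$organ, region = region_name, angle = cube$angle,
         regime = cube$regime, plant_id = cube$plant_id, n_pixels = npx),
    class = "spectrum"
  )
}

.r_at <- function(spectrum, nm) {
  spectrum$reflectance[nearest_band(spectrum$wavelengths, nm)]
}

#' Compute one vegetation index from a spectrum
#'
#' @param spectrum a [region_mean_spectrum()] result.
#' @param index_name one of `"NDVI"`, `"MRE_NDVI"`, `"GNDVI"`, `"PSSRc"`.
#' @param bands named list of wavelengths, see [vi_wavelengths()].
#' @return One-row data.frame (a VI record): `plant_id`, `regime`, `organ`,
#'   `angle`, `region`, `index`, `value`, `n_pixels`.
#' @export
compute_index <- function(spectrum, index_name = VI_NAMES, bands = vi_wavelengths()) {
  stopifnot(inherits(spectrum, "spectrum"))
  index_name <- match.arg(index_name)
  used <- switch(index_name,
    NDVI = c(bands$nir, bands$red),
    GNDVI = c(bands$nir, bands$green),
    MRE_NDVI = c(bands$re_high, bands$re_low, bands$blue),
    PSSRc = c(bands$nir, bands$violet)
  )
  r <- vapply(used, function(nm) .r_at(spectrum, nm), numeric(1))
  if (any(r < 0)) {
    stop(sprintf("negative reflectance at band(s) %s nm",
                 paste(used[r < 0], collapse = ", ")), call. = FALSE)
  }
  val <- switch(index_name,
    NDVI = {
      if (r[1] + r[2] == 0) stop("NDVI denominator zero (bands 800+670 nm)", call. = FALSE)
      (r[1] - r[2]) / (r[1] + r[2])
    },
    GNDVI = {
      if (r[1] + r[2] == 0) stop("GNDVI denominator zero (bands 800+550 nm)", call. = FALSE)
      (r[1] - r[2]) / (r[1] + r[2])
    },
    MRE_NDVI = {
      den <- r[1] + r[2] - 2 * r[3]
      if (den == 0) stop("MRE-NDVI denominator zero (750+705-2*445 nm)", call. = FALSE)
      (r[1] - r[2]) / den
    },
    PSSRc = {
      if (r[2] == 0) stop("PSSRc denominator zero (band 470 nm)", call. = FALSE)
      r[1] / r[2]
    }
  )
  data.frame(plant_id = spectrum$plant_id, regime = spectrum$regime,
             organ = spectrum$organ, angle = spectrum$angle,
             region = spectrum$region, index = index_name, value = val,
             n_pixels = spectrum$n_pixels, stringsAsFactors = FALSE)
}

#' Vegetation indices for a batch of labeled cubes
#'
#' One record per (cube, region, index). Failures of individual cubes are
#' caught, logged, and reported in the `failures` attribute; the batch
#' continues.
#'
#' @param cubes list of reflectance cubes.
#' @param labels list of [partition_regions()] results, parallel to `cubes`.
#' @param regions regions to evaluate (names or 1..5).
#' @param indices subset of [VI_NAMES].
#' @param bands index wavelengths, see [vi_wavelengths()].
#' @return Long-format data.frame of VI records, with attribute `failures`
#'   (data.frame cube/message, zero rows when all cubes succeeded).
#' @export
batch_indices <- function(cubes, labels, regions = 1:5, indices = VI_NAMES,
                          bands = vi_wavelengths()) {
  stopifnot(length(cubes) == length(labels))
  recs <- list(); fails <- list()
  for (i in seq_along(cubes)) {
    cube_id <- if (!is.na(cubes[[i]]$plant_id)) cubes[[i]]$plant_id else as.character(i)
    res <- tryCatch({
      d <- dim(cubes[[i]]$values)
      vmat <- matrix(cubes[[i]]$values, d[1] * d[2], d[3])
      do.call(rbind, lapply(regions, function(rg) {
        sp <- .region_mean_spectrum_flat(cubes[[i]], vmat, labels[[i]], rg)
        do.call(rbind, lapply(indices, function(ix) compute_index(sp, ix, bands)))
      }))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(cube = cube_id,
                                                message = conditionMessage(res),
                                                stringsAsFactors = FALSE)
    } else {
      recs[[length(recs) + 1L]] <- res
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(plant_id = character(), regime = character(), organ = character(),
               angle = numeric(), region = character(), index = character(),
               value = numeric(), n_pixels = integer(), stringsAsFactors = FALSE)
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(cube = character(), message = character(), stringsAsFactors = FALSE)
  if (nrow(failures)) {
    message(sprintf("batch_indices: %d of %d cubes failed (see attr(,'failures'))",
                    nrow(failures), length(cubes)))
  }
  attr(out, "failures") <- failures
  out
}
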