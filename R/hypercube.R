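#' Construct a hyperspectral cube
#'
#' A `hyper_cube` bundles a 3-D array of values indexed `(line, sample, band)`
#' with its wavelength grid and acquisition metadata. Values are either raw
#' sensor counts (`value_kind = "raw"`) or reflectance in `[0, 1.5]`
#' (`value_kind = "reflectance"`; the ceiling above 1 keeps specular glint
#' pixels representable).
#'
#' @param values numeric 3-D array, dimensions `(lines, samples, bands)`.
#' @param wavelengths numeric vector of band centers (nm), one per band.
#' @param organ one of `"spike"`, `"flag_leaf"`, `"second_leaf"`, or `NA`.
#' @param angle shooting angle in degrees (105 or 125), or `NA`.
#' @param regime nitrogen regime id (`"N1"`..`"N6"`), or `NA`.
#' @param plant_id free-form plant identifier, or `NA`.
#' @param value_kind `"raw"` or `"reflectance"`.
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(values, wavelengths,
                       organ = NA_character_, angle = NA_real_,
                       regime = NA_character_, plant_id = NA_character_,
                       value_kind = c("raw", "reflectance")) {
  value_kind <- match.arg(value_kind)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a 3-D array (line, sample, band)", call. = FALSE)
  }
  check_wavelength_grid(wavelengths)
  if (dim(values)[3] != length(wavelengths)) {
    stop(sprintf("band dimension (%d) does not match wavelength grid length (%d)",
                 dim(values)[3], length(wavelengths)), call. = FALSE)
  }
  if (!is.na(organ)) organ <- match.arg(organ, c("spike", "flag_leaf", "second_leaf"))
  if (value_kind == "reflectance") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1.5) {
      stop("reflectance values must lie in [0, 1.5]", call. = FALSE)
    }
  }
  structure(
    list(values = values, wavelengths = as.numeric(wavelengths),
         organ = organ, angle = angle, regime = regime,
         plant_id = plant_id, value_kind = value_kind),
    class = "hyper_cube"
  )
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.2f-%.2f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$value_kind))
  cat(sprintf("  organ=%s angle=%s regime=%s plant=%s\n",
              x$organ, format(x$angle), x$regime, x$plant_id))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

#' White/dark reference pair for reflectance calibration
#'
#' @param white per-band reference counts measured on the reference plate
#'   (numeric vector, one per band), or a full `(line, sample, band)` array.
#' @param dark per-band dark-current counts; defaults to all zeros (the
#'   acquisition protocol modelled here does not record a dark frame).
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(white, dark = NULL) {
  if (is.null(dark)) {
    dark <- if (is.array(white)) array(0, dim(white)) else numeric(length(white))
  }
  if (!identical(dim(white), dim(dark)) &&
      !(is.null(dim(white)) && is.null(dim(dark)) && length(white) == length(dark))) {
    stop("white and dark references must have identical shape", call. = FALSE)
  }
  if (any(white <= dark)) {
    stop("white reference must exceed dark reference at every band", call. = FALSE)
  }
  structure(list(white = white, dark = dark), class = "reference_set")
}

#' Convert raw counts to reflectance
#'
#' Applies the flat-field calibration `(raw - dark) / (white - dark)` per
#' band, treating the reference plate as 100 % reflectance (a `plate_reflectance`
#' factor can impose e.g. the plate's nominal 0.99). Results are clipped to
#' `[0, 1.5]`: negative values arise only from noise, and values above 1 are
#' kept up to 1.5 so specular glint remains visible to downstream analyses.
#'
#' @param raw a `hyper_cube` with `value_kind = "raw"`.
#' @param refs a [reference_set()].
#' @param plate_reflectance true reflectance of the white plate (default 1.0).
#' @return A `hyper_cube` with `value_kind = "reflectance"`.
#' @export
to_reflectance <- function(raw, refs, plate_reflectance = 1.0) {
  stopifnot(inherits(raw, "hyper_cube"), inherits(refs, "reference_set"))
  if (raw$value_kind != "raw") {
    stop("cube is already calibrated (value_kind != 'raw')", call. = FALSE)
  }
  d <- dim(raw$values)
  nb <- d[3]
  if (is.null(dim(refs$white))) {
    if (length(refs$white) != nb) {
      stop(sprintf("reference has %d bands but cube has %d", length(refs$white), nb),
           call. = FALSE)
    }
    denom <- refs$white - refs$dark
    # broadcast per-band references across pixels
    refl <- sweep(sweep(raw$values, 3, refs$dark, "-"), 3, denom, "/")
  } else {
    if (!identical(dim(refs$white), d)) {
      stop("per-pixel reference dimensions do not match cube", call. = FALSE)
    }
    refl <- (raw$values - refs$dark) / (refs$white - refs$dark)
  }
  refl <- refl * plate_reflectance
  refl[refl < 0] <- 0
  refl[refl > 1.5] <- 1.5
  out <- raw
  out$values <- refl
  out$value_kind <- "reflectance"
  out
}
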