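#' Default camera wavelength grid
#'
#' Band centers of the 204-band visible/NIR hyperspectral camera emulated by
#' this package: uniform spacing over 400--1000 nm (sampling interval
#' 600/203 nm, about 2.96 nm). The camera's optical bandwidth (FWHM, nominally
#' 7 nm) is wider than the sampling interval and is not modelled; only band
#' centers matter for band selection.
#'
#' @return Numeric vector of 204 strictly increasing band centers in nm.
#' @export
#' @examples
#' g <- default_wavelength_grid()
#' range(g)  # 400 1000
default_wavelength_grid <- function() {
  400 + (0:203) * (600 / 203)
}

check_wavelength_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2L) {
    stop("wavelength grid must be a numeric vector with at least 2 centers", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("wavelength grid centers must be strictly increasing", call. = FALSE)
  }
  invisible(grid)
}

#' Index of the band nearest a target wavelength
#'
#' Returns the (1-based) index of the band center minimizing the absolute
#' distance to `target_nm`. Ties are broken toward the lower wavelength.
#' Targets farther than one grid spacing outside the grid are an error, so a
#' typo (e.g. 67 for 670) fails loudly rather than silently snapping to an
#' endpoint.
#'
#' @param grid numeric vector of strictly increasing band centers (nm).
#' @param target_nm target wavelength in nm.
#' @return Integer band index into `grid`.
#' @export
#' @examples
#' nearest_band(default_wavelength_grid(), 670)
nearest_band <- function(grid, target_nm) {
  check_wavelength_grid(grid)
  if (!is.numeric(target_nm) || length(target_nm) != 1L || is.na(target_nm)) {
    stop("target_nm must be a single number", call. = FALSE)
  }
  spacing <- stats::median(diff(grid))
  if (target_nm < min(grid) - spacing || target_nm > max(grid) + spacing) {
    stop(sprintf(
      "target wavelength %.2f nm is outside the grid [%.2f, %.2f] nm (+/- one spacing)",
      target_nm, min(grid), max(grid)
    ), call. = FALSE)
  }
  # which.min returns the first minimizer; centers increase, so ties resolve
  # toward the lower wavelength
  which.min(abs(grid - target_nm))
}
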