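# ENVI flat-binary cube + text header I/O.
#
# Layout conventions (band interleave):
#   bsq: sample fastest, then line, then band
#   bil: sample fastest, then band, then line
#   bip: band fastest, then sample, then line
# In memory the cube is always (line, sample, band).

.envi_dtypes <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `3`  = list(what = "integer", size = 4L, signed = TRUE),
  `4`  = list(what = "numeric", size = 4L, signed = TRUE),
  `5`  = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.envi_paths <- function(path) {
  base <- sub("\\.(hdr|dat)$", "", path)
  list(hdr = paste0(base, ".hdr"), dat = paste0(base, ".dat"))
}

#' Write a hyperspectral cube in ENVI format
#'
#' Writes `<path>.hdr` (text header with dimensions, interleave, data type,
#' wavelength list and acquisition metadata) and `<path>.dat` (flat binary,
#' little-endian). Wavelengths are recorded with 4 decimal places.
#'
#' @param cube a [hyper_cube()].
#' @param path output path; a trailing `.hdr`/`.dat` extension is stripped.
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @param data_type ENVI data-type code: 4 (float32, default) or 5 (float64).
#' @return `path`, invisibly.
#' @export
write_envi_cube <- function(cube, path, interleave = c("bil", "bip", "bsq"),
                            data_type = 4L) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  dt <- .envi_dtypes[[as.character(data_type)]]
  if (is.null(dt) || dt$what != "numeric") {
    stop("data_type must be 4 (float32) or 5 (float64) on write", call. = FALSE)
  }
  d <- dim(cube$values)
  p <- .envi_paths(path)

  hdr <- c(
    "ENVI",
    "description = {leafspec hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("value kind = %s", cube$value_kind),
    if (!is.na(cube$organ)) sprintf("organ = %s", cube$organ),
    if (!is.na(cube$angle)) sprintf("angle = %g", cube$angle),
    if (!is.na(cube$regime)) sprintf("regime = %s", cube$regime),
    if (!is.na(cube$plant_id)) sprintf("plant id = %s", cube$plant_id),
    "wavelength = {",
    paste0(" ", paste(sprintf("%.4f", cube$wavelengths), collapse = ", ")),
    "}"
  )
  writeLines(hdr, p$hdr)

  perm <- switch(interleave,
    bsq = c(2L, 1L, 3L),
    bil = c(2L, 3L, 1L),
    bip = c(3L, 2L, 1L)
  )
  con <- file(p$dat, "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(cube$values, perm)), con,
           size = dt$size, endian = "little")
  invisible(path)
}

.parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  txt <- paste(txt, collapse = "\n")
  # fold brace-delimited blocks onto one logical line
  fields <- list()
  pat <- "([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("not a parseable ENVI header: ", hdr_path, call. = FALSE)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- tolower(trimws(sub("=.*$", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    val <- trimws(gsub("[{}]", " ", val))
    fields[[key]] <- val
  }
  fields
}

#' Read an ENVI-format hyperspectral cube
#'
#' Parses the text header, validates that the companion binary has exactly
#' `samples * lines * bands` elements of the declared data type, and returns
#' the cube in `(line, sample, band)` memory order regardless of the on-disk
#' interleave. The header must carry a wavelength list.
#'
#' @param header_path path to the `.hdr` file (or the common basename).
#' @return A [hyper_cube()].
#' @export
read_envi_cube <- function(header_path) {
  p <- .envi_paths(header_path)
  if (!file.exists(p$hdr)) stop("header file not found: ", p$hdr, call. = FALSE)
  if (!file.exists(p$dat)) stop("binary file not found: ", p$dat, call. = FALSE)
  f <- .parse_envi_header(p$hdr)

  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop("ENVI header missing field(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (is.null(f[["wavelength"]])) {
    stop("ENVI header has no wavelength list; cannot build the band grid", call. = FALSE)
  }
  ns <- as.integer(f[["samples"]]); nl <- as.integer(f[["lines"]])
  nb <- as.integer(f[["bands"]])
  interleave <- tolower(f[["interleave"]])
  if (!interleave %in% c("bil", "bip", "bsq")) {
    stop("unsupported interleave: ", interleave, call. = FALSE)
  }
  dt <- .envi_dtypes[[f[["data type"]]]]
  if (is.null(dt)) stop("unsupported ENVI data type code: ", f[["data type"]], call. = FALSE)
  endian <- if (!is.null(f[["byte order"]]) && as.integer(f[["byte order"]]) == 1L)
    "big" else "little"

  wl <- as.numeric(strsplit(f[["wavelength"]], ",")[[1]])
  wl <- wl[!is.na(wl)]
  if (length(wl) != nb) {
    stop(sprintf("header declares %d bands but lists %d wavelengths", nb, length(wl)),
         call. = FALSE)
  }

  n_expected <- as.numeric(ns) * nl * nb
  n_on_disk <- file.size(p$dat) / dt$size
  if (n_on_disk != n_expected) {
    stop(sprintf(
      "binary size mismatch: header implies %d values (%d bands) but file holds %g",
      n_expected, nb, n_on_disk), call. = FALSE)
  }

  con <- file(p$dat, "rb")
  on.exit(close(con))
  v <- readBin(con, what = dt$what, n = n_expected, size = dt$size,
               signed = dt$signed, endian = endian)

  dims <- switch(interleave,
    bsq = c(ns, nl, nb),
    bil = c(ns, nb, nl),
    bip = c(nb, ns, nl)
  )
  perm <- switch(interleave,  # inverse of the write-side permutation
    bsq = c(2L, 1L, 3L),
    bil = c(3L, 1L, 2L),
    bip = c(3L, 2L, 1L)
  )
  arr <- aperm(array(v, dims), perm)

  hyper_cube(arr, wl,
             organ = if (!is.null(f[["organ"]])) f[["organ"]] else NA_character_,
             angle = if (!is.null(f[["angle"]])) as.numeric(f[["angle"]]) else NA_real_,
             regime = if (!is.null(f[["regime"]])) f[["regime"]] else NA_character_,
             plant_id = if (!is.null(f[["plant id"]])) f[["plant id"]] else NA_character_,
             value_kind = if (!is.null(f[["value kind"]])) f[["value kind"]] else "raw")
}
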