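#' Hyperspectral reflectance cube
#'
#' A single time frame of line-scan hyperspectral imaging: a `(y, x, lambda)`
#' array of reflectance with its wavelength axis and acquisition metadata.
#'
#' @param data Numeric array `(ny, nx, n_lambda)`.
#' @param wavelengths_nm Strictly increasing wavelength axis (nm), length
#'   matching `dim(data)[3]`.
#' @param pixel_pitch_um Lateral pixel pitch (micrometres); default 0.6, the
#'   instrument pixel size.
#' @param timestamp_s Acquisition time of this frame (seconds).
#' @param frame_index Integer frame counter (1-based).
#' @return An object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(data, wavelengths_nm, pixel_pitch_um = 0.6,
                               timestamp_s = 0, frame_index = 1L) {
  if (length(dim(data)) != 3) stop("data must be a (y, x, lambda) array",
                                   call. = FALSE)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (dim(data)[3] != length(wavelengths_nm)) {
    stop("third array dimension must match the wavelength axis", call. = FALSE)
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (!(pixel_pitch_um > 0)) stop("pixel pitch must be positive", call. = FALSE)
  structure(list(data = data, wavelengths_nm = wavelengths_nm,
                 pixel_pitch_um = pixel_pitch_um,
                 timestamp_s = timestamp_s,
                 frame_index = as.integer(frame_index)),
            class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hyperspectral_cube> %d x %d px, %d wavelengths (%.1f-%.1f nm), pitch %.2f um, t = %.0f s\n",
    d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
    x$pixel_pitch_um, x$timestamp_s))
  invisible(x)
}

#' Extract one pixel's spectrum from a cube
#'
#' @param cube A [hyperspectral_cube()].
#' @param y,x 1-based pixel indices (row, column).
#' @return A [reflection_spectrum()].
#' @export
pixel_spectrum <- function(cube, y, x) {
  reflection_spectrum(cube$wavelengths_nm, cube$data[y, x, ],
                      metadata = list(y = y, x = x,
                                      frame_index = cube$frame_index))
}
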