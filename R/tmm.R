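#' Thin-film reflectance by the characteristic-matrix method
#'
#' Closed-form transfer-matrix reflectance of an unpatterned multilayer at
#' normal incidence. Serves as the independent oracle for the coupled-wave
#' solver in its uniform-layer limit (duty cycle driven to 0 or 1) and as a
#' quick design aid for planar reference structures.
#'
#' @param wavelengths_nm Wavelength grid (nm).
#' @param n_layers Refractive indices of the finite layers, ordered from the
#'   incidence side downward. May be empty for a bare interface.
#' @param d_layers_nm Thicknesses (nm) matching `n_layers`.
#' @param n_in Index of the semi-infinite incidence medium.
#' @param n_out Index of the semi-infinite exit medium.
#' @return Numeric vector of reflectance values, one per wavelength.
#' @export
#' @examples
#' # quarter-wave TiO2 film on glass in water
#' thin_film_reflectance(550, 2.4, 550 / 4 / 2.4, n_in = 1.333, n_out = 1.52)
thin_film_reflectance <- function(wavelengths_nm, n_layers, d_layers_nm,
                                  n_in, n_out) {
  n_layers <- as.numeric(n_layers)
  d_layers_nm <- as.numeric(d_layers_nm)
  if (length(n_layers) != length(d_layers_nm)) {
    stop("n_layers and d_layers_nm must have equal length", call. = FALSE)
  }
  vapply(wavelengths_nm, function(lambda) {
    k0 <- 2 * pi / lambda
    Mtot <- diag(2) + 0i
    for (j in seq_along(n_layers)) {
      delta <- k0 * n_layers[j] * d_layers_nm[j]
      eta <- n_layers[j]
      Mj <- matrix(c(cos(delta), 1i * eta * sin(delta),
                     1i * sin(delta) / eta, cos(delta)), 2, 2)
      Mtot <- Mtot %*% Mj
    }
    BC <- Mtot %*% c(1, n_out)
    r <- (n_in * BC[1] - BC[2]) / (n_in * BC[1] + BC[2])
    Mod(r)^2
  }, numeric(1))
}
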