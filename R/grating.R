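#' Photonic-crystal grating stack description
#'
#' Constructs the geometric/optical description of a one-dimensional
#' photonic-crystal (PC) biosensor: a replica-molded polymer grating with
#' trapezoidal ridges, conformally coated with a high-index TiO2 film that
#' forms the guided-mode-resonance waveguide. Defaults are the fabricated
#' sensor design used throughout this package: a 400 nm period polymer grating
#' (n = 1.46, depth 120 nm, duty 41.6%, sidewall 85 deg) with a 61 nm TiO2
#' coating (n = 2.4, duty 50%, sidewall 82 deg) on a glass substrate,
#' resonant near 626 nm under water.
#'
#' Duty cycles are the ridge fill fractions at trapezoid mid-height; sidewall
#' angles are measured from the horizontal, so 90 degrees is a rectangular
#' ridge and smaller angles make the ridge base wider than its top.
#'
#' @param period_nm Grating period (nm).
#' @param polymer_index Refractive index of the polymer grating ridges.
#' @param grating_depth_nm Polymer ridge height (nm).
#' @param grating_duty Polymer ridge mid-height fill fraction, in (0, 1).
#' @param grating_sidewall_deg Polymer ridge sidewall angle (degrees, (0, 90]).
#' @param tio2_index Refractive index of the TiO2 coating.
#' @param tio2_thickness_nm TiO2 film thickness (nm).
#' @param tio2_duty TiO2 ridge mid-height fill fraction, in (0, 1).
#' @param tio2_sidewall_deg TiO2 ridge sidewall angle (degrees, (0, 90]).
#' @param substrate_index Refractive index of the semi-infinite substrate.
#' @param staircase_layers Number of horizontal slabs used to discretize each
#'   trapezoid for the coupled-wave solver.
#' @return An object of class `grating_stack`.
#' @seealso [build_staircase()], [simulate_spectrum()]
#' @export
#' @examples
#' stack <- grating_stack()
#' stack
grating_stack <- function(period_nm = 400,
                          polymer_index = 1.46,
                          grating_depth_nm = 120,
                          grating_duty = 0.416,
                          grating_sidewall_deg = 85,
                          tio2_index = 2.4,
                          tio2_thickness_nm = 61,
                          tio2_duty = 0.50,
                          tio2_sidewall_deg = 82,
                          substrate_index = 1.52,
                          staircase_layers = 8L) {
  stopifnot(is.numeric(period_nm), length(period_nm) == 1, period_nm > 0)
  for (d in list(grating_duty, tio2_duty)) {
    if (!(is.numeric(d) && length(d) == 1 && d > 0 && d < 1)) {
      stop("duty cycles must lie strictly between 0 and 1", call. = FALSE)
    }
  }
  for (a in list(grating_sidewall_deg, tio2_sidewall_deg)) {
    if (!(is.numeric(a) && length(a) == 1 && a > 0 && a <= 90)) {
      stop("sidewall angles must lie in (0, 90] degrees", call. = FALSE)
    }
  }
  if (grating_depth_nm < 0 || tio2_thickness_nm < 0) {
    stop("layer thicknesses must be >= 0", call. = FALSE)
  }
  for (n in list(polymer_index, tio2_index, substrate_index)) {
    if (!(is.numeric(n) && length(n) == 1 && n >= 1)) {
      stop("refractive indices must be >= 1", call. = FALSE)
    }
  }
  staircase_layers <- as.integer(staircase_layers)
  if (staircase_layers < 1L) stop("staircase_layers must be >= 1", call. = FALSE)
  structure(
    list(
      period_nm = period_nm,
      polymer_index = polymer_index,
      grating_depth_nm = grating_depth_nm,
      grating_duty = grating_duty,
      grating_sidewall_deg = grating_sidewall_deg,
      tio2_index = tio2_index,
      tio2_thickness_nm = tio2_thickness_nm,
      tio2_duty = tio2_duty,
      tio2_sidewall_deg = tio2_sidewall_deg,
      substrate_index = substrate_index,
      staircase_layers = staircase_layers
    ),
    class = "grating_stack"
  )
}

#' @export
print.grating_stack <- function(x, ...) {
  cat("<grating_stack>\n")
  cat(sprintf("  period        : %g nm\n", x$period_nm))
  cat(sprintf("  polymer ridge : n = %g, depth %g nm, duty %.3f, sidewall %g deg\n",
              x$polymer_index, x$grating_depth_nm, x$grating_duty,
              x$grating_sidewall_deg))
  cat(sprintf("  TiO2 coating  : n = %g, thickness %g nm, duty %.3f, sidewall %g deg\n",
              x$tio2_index, x$tio2_thickness_nm, x$tio2_duty, x$tio2_sidewall_deg))
  cat(sprintf("  substrate     : n = %g\n", x$substrate_index))
  cat(sprintf("  staircase     : %d slabs per trapezoid\n", x$staircase_layers))
  invisible(x)
}

#' Superstrate medium
#'
#' The medium above the sensor surface (cell culture medium or water).
#' Indices are treated as dispersion-free over the 600-650 nm working band.
#'
#' @param superstrate_index Real refractive index (>= 1). Default 1.333 (water).
#' @return An object of class `medium`.
#' @export
medium <- function(superstrate_index = 1.333) {
  if (!(is.numeric(superstrate_index) && length(superstrate_index) == 1 &&
        superstrate_index >= 1)) {
    stop("superstrate index must be a single number >= 1", call. = FALSE)
  }
  structure(list(superstrate_index = superstrate_index), class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> superstrate n = %g\n", x$superstrate_index))
  invisible(x)
}

# fill fraction of a trapezoidal ridge at height z above its base.
# duty is the mid-height fill; sidewall angle theta from horizontal.
trapezoid_fill <- function(z, height, duty, sidewall_deg, period) {
  half_delta <- (height / 2 - z) / tan(sidewall_deg * pi / 180)
  duty + 2 * half_delta / period
}

#' Discretize the trapezoidal grating stack into a staircase of slabs
#'
#' Converts the trapezoidal polymer and TiO2 cross-sections into a sequence of
#' horizontal slabs, each with a single ridge fill fraction, suitable for a
#' layer-by-layer coupled-wave solution. Each trapezoid is cut into
#' `staircase_layers` slabs of equal thickness and the slab takes the fill
#' fraction at its own mid-height, so the thickness-weighted mean fill equals
#' the mid-height duty cycle exactly and total thicknesses are preserved.
#'
#' The physical stack modelled here follows the conformal TiO2 sputter
#' coating: the lowest `tio2_thickness_nm` of the grating grooves is filled
#' with TiO2 deposited at the groove floor; above that level the polymer
#' sidewalls carry lateral TiO2 strips whose combined width is the excess of
#' the TiO2 duty over the polymer duty (the TiO2 ridge is wider than the
#' polymer ridge precisely because the coating wraps the sidewalls); the
#' remaining groove volume is superstrate medium; and a patterned TiO2 ridge
#' layer rides on top of the polymer ridges. Groove/background indices that
#' depend on the superstrate are left as `NA` unless a [medium()] is supplied.
#'
#' @param stack A [grating_stack()].
#' @param medium Optional [medium()]; when supplied, groove regions open to the
#'   superstrate take its index, otherwise they are `NA` placeholders resolved
#'   by the solver.
#' @return A data frame with one row per slab, ordered from the top of the
#'   stack downward, and columns `thickness_nm`, `fill` (ridge fill fraction),
#'   `n_ridge`, `n_groove`, `sidewall_fill` (period fraction occupied by the
#'   lateral TiO2 sidewall coating, split evenly between the two ridge
#'   flanks), and `region` ("tio2_ridge", "grating_upper", "grating_lower").
#' @export
#' @examples
#' build_staircase(grating_stack(staircase_layers = 4), medium())
build_staircase <- function(stack, medium = NULL) {
  stopifnot(inherits(stack, "grating_stack"))
  n_sup <- if (is.null(medium)) NA_real_ else medium$superstrate_index
  K <- stack$staircase_layers
  L <- stack$period_nm

  slab_fills <- function(height, duty, sidewall_deg) {
    dz <- height / K
    zmid <- (seq_len(K) - 0.5) * dz
    f <- trapezoid_fill(zmid, height, duty, sidewall_deg, L)
    if (any(f <= 0 | f >= 1)) {
      stop("sidewall geometry drives a slab fill fraction outside (0, 1)",
           call. = FALSE)
    }
    list(fill = f, z_lo = (seq_len(K) - 1) * dz, z_hi = seq_len(K) * dz)
  }

  sidewall_fill <- max(0, stack$tio2_duty - stack$grating_duty)

  rows <- list()
  # TiO2 ridge layer on top of the polymer ridges (grooves open to medium).
  if (stack$tio2_thickness_nm > 0) {
    s <- slab_fills(stack$tio2_thickness_nm, stack$tio2_duty,
                    stack$tio2_sidewall_deg)
    rows[[length(rows) + 1L]] <- data.frame(
      thickness_nm = stack$tio2_thickness_nm / K,
      fill = rev(s$fill),                       # top slab first
      n_ridge = stack$tio2_index,
      n_groove = n_sup,
      sidewall_fill = 0,
      region = "tio2_ridge"
    )
  }
  # Polymer grating region: ridge is polymer throughout; grooves hold TiO2 up
  # to the coating thickness (conformal deposition at the groove floor), then
  # superstrate medium above.
  if (stack$grating_depth_nm > 0) {
    s <- slab_fills(stack$grating_depth_nm, stack$grating_duty,
                    stack$grating_sidewall_deg)
    if (any(s$fill + sidewall_fill >= 1)) {
      stop("sidewall geometry drives a slab fill fraction outside (0, 1)",
           call. = FALSE)
    }
    split_z <- min(stack$tio2_thickness_nm, stack$grating_depth_nm)
    sub <- list()
    for (i in rev(seq_len(K))) {               # top slab first
      z_lo <- s$z_lo[i]; z_hi <- s$z_hi[i]; f <- s$fill[i]
      if (z_lo >= split_z) {                   # groove open to medium
        sub[[length(sub) + 1L]] <- data.frame(
          thickness_nm = z_hi - z_lo, fill = f,
          n_ridge = stack$polymer_index, n_groove = n_sup,
          sidewall_fill = sidewall_fill, region = "grating_upper")
      } else if (z_hi <= split_z) {            # groove filled with TiO2
        sub[[length(sub) + 1L]] <- data.frame(
          thickness_nm = z_hi - z_lo, fill = f,
          n_ridge = stack$polymer_index, n_groove = stack$tio2_index,
          sidewall_fill = 0, region = "grating_lower")
      } else {                                 # slab straddles the fill level
        sub[[length(sub) + 1L]] <- data.frame(
          thickness_nm = z_hi - split_z, fill = f,
          n_ridge = stack$polymer_index, n_groove = n_sup,
          sidewall_fill = sidewall_fill, region = "grating_upper")
        sub[[length(sub) + 1L]] <- data.frame(
          thickness_nm = split_z - z_lo, fill = f,
          n_ridge = stack$polymer_index, n_groove = stack$tio2_index,
          sidewall_fill = 0, region = "grating_lower")
      }
    }
    rows[[length(rows) + 1L]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "period_nm") <- stack$period_nm
  attr(out, "substrate_index") <- stack$substrate_index
  out
}
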