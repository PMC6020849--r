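# Rigorous coupled-wave analysis (RCWA / Fourier modal method) for 1D
# gratings at normal or planar oblique incidence, following the stable
# enhanced-transmittance-matrix recursion with the correct inverse-rule
# Fourier factorization for TM polarization.
#
# Conventions: harmonics m = -M..M; kx_m = k0*(n_inc*sin(theta) - m*lambda/P);
# "TM" means the magnetic field parallel to the grating lines, i.e. the
# electric field perpendicular to the grating lines -- the polarization used
# by the line-scan instrument. All wavevectors are in units of k0.

#' Sampled reflectance spectrum
#'
#' Container pairing a strictly increasing wavelength grid with reflectance
#' samples. Normalized data are expected to lie in `[0, 1]` up to noise.
#'
#' @param wavelengths_nm Strictly increasing numeric vector (nm).
#' @param reflectance Numeric vector of the same length.
#' @param polarization Polarization tag, `"TM"` (E-field perpendicular to the
#'   grating lines, the instrument default) or `"TE"`.
#' @param metadata Optional named list carried along.
#' @return An object of class `reflection_spectrum`.
#' @export
reflection_spectrum <- function(wavelengths_nm, reflectance,
                                polarization = "TM", metadata = list()) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths_nm) != length(reflectance)) {
    stop("wavelength and reflectance grids must have the same length",
         call. = FALSE)
  }
  if (length(wavelengths_nm) < 2 || any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  structure(list(wavelengths_nm = wavelengths_nm, reflectance = reflectance,
                 polarization = polarization, metadata = metadata),
            class = "reflection_spectrum")
}

#' @export
print.reflection_spectrum <- function(x, ...) {
  cat(sprintf("<reflection_spectrum> %d samples, %.2f-%.2f nm, %s, max R = %.4f\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), x$polarization, max(x$reflectance)))
  invisible(x)
}

# Toeplitz matrices of the permittivity and inverse-permittivity Fourier
# coefficients for a piecewise-constant layer profile: rectangular strips
# (fractional center, fractional width, index) on a uniform background.
# N = 2M+1 harmonics; strips must not overlap.
strip_toeplitz <- function(centers_frac, widths_frac, indices, n_bg, M) {
  p <- seq(-2 * M, 2 * M)
  eps_p <- ifelse(p == 0, n_bg^2, 0) + 0i
  inv_p <- ifelse(p == 0, 1 / n_bg^2, 0) + 0i
  for (j in seq_along(widths_frac)) {
    f <- widths_frac[j]
    s <- ifelse(p == 0, f, sin(pi * p * f) / (pi * p)) *
      exp(-2i * pi * p * centers_frac[j])
    eps_p <- eps_p + (indices[j]^2 - n_bg^2) * s
    inv_p <- inv_p + (1 / indices[j]^2 - 1 / n_bg^2) * s
  }
  N <- 2 * M + 1
  idx <- outer(seq_len(N), seq_len(N), function(i, j) (i - j) + 2 * M + 1)
  list(E = matrix(eps_p[idx], N, N), Einv = matrix(inv_p[idx], N, N))
}

# binary (centered ridge/groove) special case
layer_toeplitz <- function(fill, n_ridge, n_groove, M) {
  strip_toeplitz(0, fill, n_ridge, n_groove, M)
}

# Precompute wavelength-independent layer operators from a staircase table.
# A TiO2 sidewall coating (sidewall_fill > 0) adds one lateral TiO2 strip on
# each flank of the centered ridge.
rcwa_prepare_layers <- function(slabs, n_sup, M, n_sidewall = NULL) {
  lapply(seq_len(nrow(slabs)), function(i) {
    f <- slabs$fill[i]
    nr <- slabs$n_ridge[i]
    ng <- slabs$n_groove[i]
    if (is.na(ng)) ng <- n_sup
    sw <- if (!is.null(slabs$sidewall_fill)) slabs$sidewall_fill[i] else 0
    uniform <- (f <= 0 || f >= 1 || (isTRUE(all.equal(nr, ng)) && sw == 0))
    if (uniform) {
      n_eff <- if (f >= 1) nr else if (f <= 0) ng else nr
      return(list(uniform = TRUE, eps = n_eff^2, d = slabs$thickness_nm[i]))
    }
    if (sw > 0) {
      nsw <- if (is.null(n_sidewall)) stop("sidewall index required") else n_sidewall
      off <- f / 2 + sw / 4                 # strip centers flank the ridge
      tp <- strip_toeplitz(c(0, -off, off), c(f, sw / 2, sw / 2),
                           c(nr, nsw, nsw), ng, M)
    } else {
      tp <- layer_toeplitz(f, nr, ng, M)
    }
    list(uniform = FALSE, E = tp$E, Ei = solve(tp$E), Einvt = tp$Einv,
         EinvInv = solve(tp$Einv), d = slabs$thickness_nm[i])
  })
}

# principal square root with Re >= 0 (ties resolved to +i for evanescent).
# Used for layer eigenmode exponents q (fields e^{-k0 q z}).
mode_sqrt <- function(v) {
  q <- sqrt(as.complex(v))
  flip <- Re(q) < 0 | (abs(Re(q)) < 1e-12 & Im(q) < 0)
  q[flip] <- -q[flip]
  q
}

# Branch for the open-region longitudinal wavevectors kz: positive real for
# propagating orders, negative imaginary for evanescent orders, so that
# transmitted/reflected evanescent orders decay away from the stack under the
# sign conventions of the boundary equations used below.
region_kz <- function(v) {
  q <- sqrt(as.complex(v))
  evan <- abs(Re(q)) < 1e-12 * (1 + Mod(q))
  q[evan & Im(q) > 0] <- -q[evan & Im(q) > 0]
  q[!evan & Re(q) < 0] <- -q[!evan & Re(q) < 0]
  q
}

# Solve one wavelength. Returns reflected/transmitted order amplitudes and
# diffraction efficiencies. Incidence from the superstrate (index n_inc).
rcwa_solve <- function(lambda, period, layers, n_inc, n_out, pol = "TM",
                       M = 10L, theta_deg = 0) {
  N <- 2L * M + 1L
  m <- seq(-M, M)
  sin_t <- sin(theta_deg * pi / 180)
  kx <- n_inc * sin_t - m * lambda / period        # units of k0
  kzI <- region_kz(n_inc^2 - kx^2)
  kzII <- region_kz(n_out^2 - kx^2)
  I_N <- diag(1 + 0i, N)
  delta <- as.complex(m == 0)

  if (pol == "TE") {
    YI <- kzI; YII <- kzII
  } else if (pol == "TM") {
    YI <- kzI / n_inc^2; YII <- kzII / n_out^2
  } else stop("polarization must be 'TE' or 'TM'", call. = FALSE)

  fG <- I_N
  gG <- diag(1i * YII, N)
  Tacc <- I_N
  k0 <- 2 * pi / lambda

  for (ly in rev(layers)) {
    if (ly$uniform) {
      q <- mode_sqrt(kx^2 - ly$eps)
      W <- I_N
      V <- if (pol == "TE") diag(q, N) else diag(q / ly$eps, N)
    } else {
      if (pol == "TE") {
        A <- diag(as.complex(kx^2), N) - ly$E
        eg <- eigen(A, symmetric = FALSE)
        q <- mode_sqrt(eg$values)
        W <- eg$vectors
        V <- W %*% diag(q, N)
      } else {
        KEiK <- ly$Ei * outer(kx, kx)
        A <- ly$EinvInv %*% (KEiK - diag(1, N))
        eg <- eigen(A, symmetric = FALSE)
        q <- mode_sqrt(eg$values)
        W <- eg$vectors
        V <- ly$Einvt %*% W %*% diag(q, N)
      }
    }
    X <- diag(exp(-k0 * q * ly$d), N)
    MM <- rbind(cbind(W, W), cbind(V, -V))
    AB <- solve(MM, rbind(fG, gG))
    a <- AB[1:N, , drop = FALSE]
    b <- AB[(N + 1):(2 * N), , drop = FALSE]
    a_inv <- solve(a)
    XbaX <- X %*% b %*% a_inv %*% X
    fG <- W %*% (I_N + XbaX)
    gG <- V %*% (I_N - XbaX)
    Tacc <- Tacc %*% a_inv %*% X
  }

  cos_t <- sqrt(1 - sin_t^2)
  inc_adm <- if (pol == "TE") n_inc * cos_t else cos_t / n_inc
  rhs <- 1i * (inc_adm * delta + YI * delta)
  c1 <- solve(gG + diag(1i * YI, N) %*% fG, rhs)
  r <- as.vector(fG %*% c1) - delta
  t <- as.vector(Tacc %*% c1)

  if (pol == "TE") {
    DEr <- Mod(r)^2 * Re(kzI) / (n_inc * cos_t)
    DEt <- Mod(t)^2 * Re(kzII) / (n_inc * cos_t)
  } else {
    DEr <- Mod(r)^2 * Re(kzI / n_inc^2) / (cos_t / n_inc)
    DEt <- Mod(t)^2 * Re(kzII / n_out^2) / (cos_t / n_inc)
  }
  list(r = r, t = t, kx = kx, kzI = kzI, kzII = kzII, m = m,
       DEr = DEr, DEt = DEt, R = sum(DEr), T = sum(DEt),
       R0 = DEr[M + 1L], lambda = lambda)
}

#' Simulate the zeroth-order reflectance spectrum of a grating stack
#'
#' Runs the rigorous coupled-wave solver at normal incidence for each
#' wavelength on the grid and returns the zeroth-order reflectance. Incidence
#' is from the superstrate; for a lossless, subwavelength stack the resonance
#' position is side-independent by reciprocity and total reflected plus
#' transmitted efficiency is 1 at every wavelength.
#'
#' @param stack A [grating_stack()].
#' @param medium A [medium()] describing the superstrate.
#' @param wavelengths_nm Wavelength grid (nm), strictly increasing. Default
#'   600-650 nm at 0.05 nm, the design-study grid.
#' @param polarization `"TM"` (E perpendicular to the grating lines; default)
#'   or `"TE"`.
#' @param harmonics Truncation half-order M; 2M+1 Fourier harmonics are
#'   retained. Default 12 (25 harmonics).
#' @param check_energy If `TRUE`, verify R + T = 1 within `1e-6` at every
#'   wavelength and error otherwise.
#' @return A [reflection_spectrum()] with total efficiencies stored in
#'   `metadata` (`R_total`, `T_total`).
#' @export
#' @examples
#' sp <- simulate_spectrum(grating_stack(), medium(),
#'                         wavelengths_nm = seq(620, 632, by = 0.5))
simulate_spectrum <- function(stack, medium,
                              wavelengths_nm = seq(600, 650, by = 0.05),
                              polarization = "TM", harmonics = 12L,
                              check_energy = FALSE) {
  stopifnot(inherits(stack, "grating_stack"), inherits(medium, "medium"))
  M <- as.integer(harmonics)
  slabs <- build_staircase(stack, medium)
  layers <- rcwa_prepare_layers(slabs, medium$superstrate_index, M, stack$tio2_index)
  R0 <- Rtot <- Ttot <- numeric(length(wavelengths_nm))
  for (i in seq_along(wavelengths_nm)) {
    sol <- rcwa_solve(wavelengths_nm[i], stack$period_nm, layers,
                      n_inc = medium$superstrate_index,
                      n_out = stack$substrate_index,
                      pol = polarization, M = M)
    R0[i] <- sol$R0; Rtot[i] <- sol$R; Ttot[i] <- sol$T
  }
  if (check_energy && any(abs(Rtot + Ttot - 1) > 1e-6)) {
    stop(sprintf(
      "energy conservation violated (max |R+T-1| = %.2e); increase harmonics",
      max(abs(Rtot + Ttot - 1))), call. = FALSE)
  }
  reflection_spectrum(wavelengths_nm, R0, polarization,
                      metadata = list(R_total = Rtot, T_total = Ttot,
                                      harmonics = M))
}

# Maximize zeroth-order reflectance over wavelength: coarse grid scan then
# golden-section refinement of the continuous solver response.
rcwa_peak <- function(stack, medium, lower = 600, upper = 650,
                      coarse_step = 0.1, polarization = "TM",
                      harmonics = 12L, tol = 1e-3) {
  M <- as.integer(harmonics)
  slabs <- build_staircase(stack, medium)
  layers <- rcwa_prepare_layers(slabs, medium$superstrate_index, M, stack$tio2_index)
  f <- function(l) rcwa_solve(l, stack$period_nm, layers,
                              medium$superstrate_index, stack$substrate_index,
                              pol = polarization, M = M)$R0
  grid <- seq(lower, upper, by = coarse_step)
  Rg <- vapply(grid, f, numeric(1))
  i0 <- which.max(Rg)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = tol)
  list(pwv_nm = opt$maximum, piv = opt$objective)
}

#' Resonance wavelength and peak intensity versus superstrate index
#'
#' Sweeps the superstrate refractive index, relocating the guided-mode
#' resonance for each value. The peak wavelength shift (PWS) column is
#' referenced to the first index in the sweep. For a lossless sensor without
#' a surface scatterer the peak intensity stays at its near-unity value while
#' the resonance red-shifts with increasing index: bulk refractive-index
#' changes move PWV but not PIV.
#'
#' @param stack A [grating_stack()].
#' @param n2_values Superstrate indices to sweep (each >= 1).
#' @param lower,upper Wavelength search window (nm).
#' @param polarization,harmonics Passed to the solver.
#' @return A data frame with columns `n2`, `pwv_nm`, `piv`, `pws_nm`.
#' @export
resonance_vs_index <- function(stack, n2_values, lower = 600, upper = 650,
                               polarization = "TM", harmonics = 12L) {
  if (any(n2_values < 1)) stop("superstrate indices must be >= 1", call. = FALSE)
  rows <- lapply(n2_values, function(n2) {
    pk <- rcwa_peak(stack, medium(n2), lower, upper,
                    polarization = polarization, harmonics = harmonics)
    data.frame(n2 = n2, pwv_nm = pk$pwv_nm, piv = pk$piv)
  })
  out <- do.call(rbind, rows)
  out$pws_nm <- out$pwv_nm - out$pwv_nm[1]
  out
}

#' Laterally averaged near-field intensity profile above the sensor surface
#'
#' Reconstructs the laterally averaged electric-field intensity enhancement
#' `|E|^2 / |E_incident|^2` of the surface-confined mode in the superstrate,
#' as a function of height above the top of the TiO2 ridges. Only the
#' evanescent diffracted orders are included: the propagating zeroth order
#' forms an ordinary standing wave that is present with or without the
#' resonance and is not part of the confined sensing field. On resonance the
#' profile is dominated by the +/-1 orders carrying the guided mode,
#' decaying with the analytic constant
#' `kappa = (2*pi/lambda) * sqrt(n_eff^2 - n2^2)` (amplitude), with
#' `n_eff = lambda / period` for first-order coupling at normal incidence.
#'
#' @param stack A [grating_stack()].
#' @param medium A [medium()].
#' @param wavelength_nm Wavelength at which to evaluate (use the resonance
#'   wavelength for the enhanced mode profile).
#' @param z_max_nm,z_step_nm Height grid above the TiO2 top surface (nm).
#' @param polarization,harmonics Passed to the solver.
#' @return An object of class `field_profile`: list with `z_nm`,
#'   `intensity_enhancement`, `wavelength_nm`, and the per-order reflected
#'   amplitudes in `metadata`.
#' @export
field_profile <- function(stack, medium, wavelength_nm,
                          z_max_nm = 600, z_step_nm = 2,
                          polarization = "TM", harmonics = 12L) {
  M <- as.integer(harmonics)
  slabs <- build_staircase(stack, medium)
  layers <- rcwa_prepare_layers(slabs, medium$superstrate_index, M, stack$tio2_index)
  sol <- rcwa_solve(wavelength_nm, stack$period_nm, layers,
                    medium$superstrate_index, stack$substrate_index,
                    pol = polarization, M = M)
  z <- seq(0, z_max_nm, by = z_step_nm)
  k0 <- 2 * pi / wavelength_nm
  n1 <- medium$superstrate_index
  kz <- sol$kzI
  r <- sol$r
  m0 <- M + 1L

  evan <- abs(Im(kz)) > 1e-12
  enh <- numeric(length(z))
  if (polarization == "TE") {
    # Ey only; incident |Ey|^2 = 1; evanescent orders add incoherently
    # after lateral averaging.
    for (j in which(evan)) {
      enh <- enh + Mod(r[j])^2 * exp(-2 * k0 * abs(Im(kz[j])) * z)
    }
  } else {
    # From Hy amplitudes: |E_m|^2 = |h_m|^2 (|kx_m|^2 + |kz_m|^2) / n1^4,
    # incident |E|^2 = 1/n1^2 at normal incidence.
    for (j in which(evan)) {
      w2 <- (Mod(sol$kx[j])^2 + Mod(kz[j])^2) / n1^2
      enh <- enh + Mod(r[j])^2 * w2 * exp(-2 * k0 * abs(Im(kz[j])) * z)
    }
  }
  structure(list(z_nm = z, intensity_enhancement = enh,
                 wavelength_nm = wavelength_nm,
                 metadata = list(r = r, kz = kz, kx = sol$kx,
                                 n2 = n1, period_nm = stack$period_nm)),
            class = "field_profile")
}

#' @export
print.field_profile <- function(x, ...) {
  cat(sprintf(
    "<field_profile> lambda = %.2f nm, z = 0-%g nm, surface enhancement %.1fx\n",
    x$wavelength_nm, max(x$z_nm), x$intensity_enhancement[1]))
  invisible(x)
}

#' Fit the exponential tail of a near-field profile
#'
#' Log-linear fit of the intensity enhancement over a height window,
#' returning the amplitude decay constant `kappa` (intensity decays as
#' `exp(-2*kappa*z)`) and the R-squared of the fit.
#'
#' @param profile A [field_profile()].
#' @param z_range_nm Two-element window (nm), default 50-400 nm, past the
#'   near-surface oscillation region.
#' @return List with `kappa_per_nm`, `decay_length_nm` (1/kappa), `r_squared`.
#' @export
fit_field_decay <- function(profile, z_range_nm = c(50, 400)) {
  sel <- profile$z_nm >= z_range_nm[1] & profile$z_nm <= z_range_nm[2] &
    profile$intensity_enhancement > 0
  z <- profile$z_nm[sel]
  y <- log(profile$intensity_enhancement[sel])
  fit <- stats::lm(y ~ z)
  kappa <- -unname(stats::coef(fit)[2]) / 2
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(kappa_per_nm = kappa, decay_length_nm = 1 / kappa, r_squared = r2)
}
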