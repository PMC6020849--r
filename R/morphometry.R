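# Cell morphometry on shift images: segmentation, sub-pixel boundary
# extraction with outward normals, frame-to-frame boundary tracking along
# local normals, band kymographs, edge-versus-center statistics, line
# profiles and temporal curves.
#
# Coordinate conventions: 0-based pixel coordinates, pixel centers at
# integer positions, x = column, y = row increasing downward; physical
# positions are pixel index times the pixel pitch in micrometres.

#' Segment the cell footprint from a shift image
#'
#' Gaussian smoothing, Otsu thresholding, morphological closing, selection of
#' the largest connected component, and hole filling. The PIS channel is the
#' usual segmentation input (the scattering ring gives the strongest boundary
#' contrast); any single-channel matrix works. Invalid (`NA`) pixels are
#' replaced by the finite median before smoothing.
#'
#' @param image Numeric matrix (e.g. `shift$pis_image`).
#' @param smooth_sigma Gaussian sigma in pixels (default 1).
#' @param close_radius Closing radius in pixels (default 2).
#' @return Logical mask matrix.
#' @export
segment_cell <- function(image, smooth_sigma = 1, close_radius = 2) {
  stopifnot(is.matrix(image))
  img <- image
  med <- stats::median(img[is.finite(img)])
  if (!is.finite(med)) stop("image has no finite pixels", call. = FALSE)
  img[!is.finite(img)] <- med
  sm <- gaussian_blur(img, smooth_sigma)
  thr <- otsu_threshold(sm)
  fg <- sm > thr
  if (!any(fg) || stats::sd(sm) == 0) {
    stop("no cell found: empty foreground after thresholding", call. = FALSE)
  }
  fg <- binary_close(fg, close_radius)
  fg <- largest_component(fg)
  if (!any(fg)) stop("no cell found: empty foreground", call. = FALSE)
  fill_holes(fg)
}

#' Ordered sub-pixel cell boundary with outward normals
#'
#' Extracts the 0.5-level iso-contour of the (lightly smoothed) binary mask,
#' resamples it to `n_points` equally spaced arclength positions, and
#' attaches outward unit normals obtained by rotating the local tangent.
#'
#' @param mask Logical matrix with a single foreground component.
#' @param n_points Number of arclength samples (default 360).
#' @param smooth_sigma Gaussian sigma (pixels) applied to the mask before
#'   contouring; sub-pixel accuracy of the 0.5 level relies on it.
#' @param frame_index Frame metadata carried on the object.
#' @return An object of class `cell_boundary`: `xy` (n x 2 matrix of 0-based
#'   (x, y) pixel coordinates), `normals` (n x 2 outward unit vectors),
#'   `s_px` (arclength, pixels), `length_px` (perimeter), `frame_index`.
#' @export
extract_boundary <- function(mask, n_points = 360L, smooth_sigma = 1,
                             frame_index = 1L) {
  stopifnot(is.matrix(mask))
  if (sum(mask) < 4) stop("degenerate contour: mask too small", call. = FALSE)
  sm <- gaussian_blur(mask * 1.0, smooth_sigma)
  ny <- nrow(mask); nx <- ncol(mask)
  if (any(mask[1, ]) || any(mask[ny, ]) || any(mask[, 1]) || any(mask[, nx])) {
    warning("mask touches the frame edge; contour clipped", call. = FALSE)
  }
  # Topology from the raw binary 0.5-contour (exact on straight edges,
  # preserves corners), de-staircased by light circular smoothing of the
  # coordinates, then re-anchored on a sub-pixel 0.5 level by a crossing
  # search along the local normal. High-curvature (corner) stretches are
  # anchored on the bilinear level of the raw mask so corners survive;
  # elsewhere the Gaussian-smoothed level removes digitization wiggle.
  cl <- grDevices::contourLines(x = 0:(ny - 1), y = 0:(nx - 1), z = mask * 1.0,
                                levels = 0.5)
  if (!length(cl)) stop("degenerate contour: no 0.5 level found", call. = FALSE)
  lens <- vapply(cl, function(cc) {
    dx <- diff(c(cc$y, cc$y[1])); dy <- diff(c(cc$x, cc$x[1]))
    sum(sqrt(dx^2 + dy^2))
  }, numeric(1))
  cc <- cl[[which.max(lens)]]
  # contourLines x follows our rows (y), y follows our columns (x)
  px <- cc$y; py <- cc$x
  if (length(px) > 1 && px[1] == px[length(px)] && py[1] == py[length(py)]) {
    px <- px[-length(px)]; py <- py[-length(py)]
  }
  if (length(px) < 4) stop("degenerate contour", call. = FALSE)
  xy <- resample_closed(cbind(px, py), n_points)
  xy[, 1] <- circular_smooth(xy[, 1], 2)
  xy[, 2] <- circular_smooth(xy[, 2], 2)
  corner <- corner_zones(xy)
  raw <- mask * 1.0
  nrm <- boundary_normals(xy, 3L)
  svals <- seq(-2, 2, by = 0.05)
  for (i in seq_len(n_points)) {
    fld <- if (corner[i]) raw else sm
    v <- bilinear_sample(fld, xy[i, 1] + svals * nrm[i, 1],
                         xy[i, 2] + svals * nrm[i, 2]) - 0.5
    ok <- is.finite(v)
    if (sum(ok) < 2) next
    vv <- v[ok]; ss <- svals[ok]
    cr <- which(vv[-length(vv)] * vv[-1] <= 0 & (vv[-length(vv)] != 0 | vv[-1] != 0))
    if (!length(cr)) next
    s_at <- vapply(cr, function(j) {
      if (vv[j + 1] == vv[j]) return(ss[j])
      ss[j] - vv[j] / (vv[j + 1] - vv[j]) * (ss[j + 1] - ss[j])
    }, numeric(1))
    s_best <- s_at[which.min(abs(s_at))]
    xy[i, ] <- xy[i, ] + s_best * nrm[i, ]
  }
  smoothed <- cbind(circular_smooth(xy[, 1], 2), circular_smooth(xy[, 2], 2))
  xy[!corner, ] <- smoothed[!corner, ]
  xy <- resample_closed(xy, n_points)
  colnames(xy) <- c("x", "y")
  L <- polygon_length(xy)
  s_new <- seq(0, L, length.out = n_points + 1L)[-(n_points + 1L)]
  normals <- smooth_normals(xy)
  xs <- xy[, 1]; ys <- xy[, 2]
  # orient outward: the smoothed mask value must drop along the normal
  probe_out <- bilinear_sample(sm, xs + 1.5 * normals[, 1],
                               ys + 1.5 * normals[, 2])
  probe_in <- bilinear_sample(sm, xs - 1.5 * normals[, 1],
                              ys - 1.5 * normals[, 2])
  flip <- mean(probe_out - probe_in, na.rm = TRUE) > 0
  if (isTRUE(flip)) normals <- -normals
  structure(list(xy = xy, normals = normals, s_px = s_new, length_px = L,
                 frame_index = as.integer(frame_index)),
            class = "cell_boundary")
}

# flag boundary samples inside high-curvature (corner) zones: tangent angle
# turning more than 35 degrees over a +/-6-sample stencil, zone widened by
# +/-5 samples
corner_zones <- function(xy, k = 6L, turn_deg = 35, widen = 5L) {
  n <- nrow(xy)
  ip <- ((seq_len(n) - 1 + k) %% n) + 1
  im <- ((seq_len(n) - 1 - k) %% n) + 1
  th <- atan2(xy[ip, 2] - xy[im, 2], xy[ip, 1] - xy[im, 1])
  dth <- abs(atan2(sin(th[ip] - th[im]), cos(th[ip] - th[im]))) * 180 / pi
  corner <- dth > turn_deg
  out <- corner
  for (o in seq(-widen, widen)) {
    out <- out | corner[((seq_len(n) - 1 + o) %% n) + 1]
  }
  out
}

# normals with circularly smoothed tangent angles: unbiased on circles (the
# tangent angle is linear in arclength) while suppressing digitization jitter
smooth_normals <- function(xy, sigma_s = 15) {
  n <- nrow(xy)
  raw <- boundary_normals(xy, 2L)
  th <- atan2(raw[, 1], -raw[, 2])          # recover tangent angle
  cs <- circular_smooth(cos(th), sigma_s)
  sn <- circular_smooth(sin(th), sigma_s)
  l <- sqrt(cs^2 + sn^2)
  cbind(sn / l, -cs / l)
}

# resample a closed polygon to n equally spaced arclength points
resample_closed <- function(P, n) {
  if (nrow(P) > 1 && all(P[1, ] == P[nrow(P), ])) P <- P[-nrow(P), , drop = FALSE]
  seg <- sqrt(diff(c(P[, 1], P[1, 1]))^2 + diff(c(P[, 2], P[1, 2]))^2)
  s_cum <- c(0, cumsum(seg))
  L <- s_cum[length(s_cum)]
  s_new <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  cbind(stats::approx(s_cum, c(P[, 1], P[1, 1]), xout = s_new)$y,
        stats::approx(s_cum, c(P[, 2], P[1, 2]), xout = s_new)$y)
}

# circular Gaussian smoothing of a periodic coordinate series
circular_smooth <- function(v, sigma_s) {
  n <- length(v)
  r <- ceiling(3 * sigma_s)
  k <- exp(-(-r:r)^2 / (2 * sigma_s^2))
  k <- k / sum(k)
  out <- numeric(n)
  for (o in -r:r) out <- out + k[o + r + 1] * v[((seq_len(n) - 1 + o) %% n) + 1]
  out
}

# unit normals from central-difference tangents of a closed polygon,
# tangent rotated -90 degrees (so counterclockwise screen contours give
# outward normals; orientation is checked against the mask by the caller)
boundary_normals <- function(xy, k = 2L) {
  n <- nrow(xy)
  nxt <- ((seq_len(n) - 1 + k) %% n) + 1
  prv <- ((seq_len(n) - 1 - k) %% n) + 1
  tx <- xy[nxt, 1] - xy[prv, 1]
  ty <- xy[nxt, 2] - xy[prv, 2]
  len <- sqrt(tx^2 + ty^2)
  cbind(ty, -tx) / len
}

#' @export
print.cell_boundary <- function(x, ...) {
  cat(sprintf("<cell_boundary> %d samples, perimeter %.1f px, frame %d\n",
              nrow(x$xy), x$length_px, x$frame_index))
  invisible(x)
}

#' Track a boundary into the next frame along local normals
#'
#' For each arclength sample of the previous boundary, casts a ray along its
#' outward normal and places the corresponding point at the 0.5-level
#' crossing of the (smoothed) next mask, keeping the previous sample
#' indexing so kymograph rows stay coherent across time. Of multiple
#' crossings, the one nearest the previous boundary wins. Samples without a
#' crossing inside the search range are interpolated from their neighbours
#' (and counted in the `n_interpolated` attribute).
#'
#' @param prev A [cell_boundary()] from the previous frame.
#' @param next_mask Logical mask of the next frame.
#' @param search_range_um Half-length of the search ray (micrometres).
#' @param pixel_pitch_um Pixel pitch (micrometres).
#' @param smooth_sigma Mask smoothing before the sub-pixel crossing search.
#' @param step_px Ray sampling step (pixels).
#' @return A [cell_boundary()] for the next frame with attributes
#'   `displacement_px` (signed normal displacement per sample, positive =
#'   outward growth) and `n_interpolated`.
#' @export
track_boundary <- function(prev, next_mask, search_range_um = 10,
                           pixel_pitch_um = 0.6, smooth_sigma = 1,
                           step_px = 0.1) {
  stopifnot(inherits(prev, "cell_boundary"), is.matrix(next_mask))
  sm <- gaussian_blur(next_mask * 1.0, smooth_sigma)
  n <- nrow(prev$xy)
  range_px <- search_range_um / pixel_pitch_um
  svals <- seq(-range_px, range_px, by = step_px)
  disp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    px <- prev$xy[i, 1] + svals * prev$normals[i, 1]
    py <- prev$xy[i, 2] + svals * prev$normals[i, 2]
    v <- bilinear_sample(sm, px, py) - 0.5
    ok <- is.finite(v)
    if (sum(ok) < 2) next
    vv <- v[ok]; ss <- svals[ok]
    cross <- which(vv[-length(vv)] * vv[-1] <= 0 &
                     (vv[-length(vv)] != 0 | vv[-1] != 0))
    if (!length(cross)) next
    s_at <- vapply(cross, function(j) {
      if (vv[j + 1] == vv[j]) return(ss[j])
      ss[j] + (0 - vv[j]) / (vv[j + 1] - vv[j]) * (ss[j + 1] - ss[j])
    }, numeric(1))
    disp[i] <- s_at[which.min(abs(s_at))]
  }
  bad <- !is.finite(disp)
  if (all(bad)) stop("no boundary crossings found; masks may not overlap",
                     call. = FALSE)
  if (any(bad)) {
    idx <- seq_len(n)
    good <- idx[!bad]
    # circular linear interpolation over arclength index
    ext_i <- c(good - n, good, good + n)
    ext_v <- rep(disp[good], 3)
    disp[bad] <- stats::approx(ext_i, ext_v, xout = idx[bad])$y
  }
  xy <- prev$xy + disp * prev$normals
  out <- structure(list(xy = xy, normals = smooth_normals(xy),
                        s_px = prev$s_px, length_px = polygon_length(xy),
                        frame_index = prev$frame_index + 1L),
                   class = "cell_boundary")
  # keep outward orientation consistent with the new mask
  probe_out <- bilinear_sample(sm, xy[, 1] + 1.5 * out$normals[, 1],
                               xy[, 2] + 1.5 * out$normals[, 2])
  probe_in <- bilinear_sample(sm, xy[, 1] - 1.5 * out$normals[, 1],
                              xy[, 2] - 1.5 * out$normals[, 2])
  if (isTRUE(mean(probe_out - probe_in, na.rm = TRUE) > 0)) {
    out$normals <- -out$normals
  }
  attr(out, "displacement_px") <- disp
  attr(out, "n_interpolated") <- sum(bad)
  out
}

polygon_length <- function(xy) {
  sum(sqrt(diff(c(xy[, 1], xy[1, 1]))^2 + diff(c(xy[, 2], xy[1, 2]))^2))
}

#' Spatiotemporal band kymograph along the cell boundary
#'
#' Samples an image sequence in a band at a fixed inward offset from the
#' (tracked) cell boundary: entry `(i, t)` is the mean of frame `t` over the
#' segment of the inward normal ray at boundary sample `i` covering
#' `[offset, offset + width]` micrometres inside the boundary, by bilinear
#' interpolation. Band 1 (near the boundary, default offset 0, width 3 um)
#' captures the focal-adhesion ring; band 2 (e.g. offset 6, width 6 um)
#' captures the inner region. `NA` pixels are excluded; entries whose band
#' has no valid sample (or exits the optional mask) are `NA`.
#'
#' @param images List of numeric matrices, one per frame.
#' @param boundaries List of [cell_boundary()] objects corresponded across
#'   frames (same sample indexing).
#' @param offset_um,width_um Band geometry, micrometres inward from the
#'   boundary. `width_um = 0` gives a single-sample line profile.
#' @param pixel_pitch_um Pixel pitch.
#' @param masks Optional list of logical masks; band samples outside the
#'   frame's mask are excluded.
#' @param step_um Sampling step along the ray.
#' @return An object of class `kymograph`: `values` (samples x frames
#'   matrix), `band` specification, `s_px` arclength coordinates.
#' @export
band_kymograph <- function(images, boundaries, offset_um = 0, width_um = 3,
                           pixel_pitch_um = 0.6, masks = NULL,
                           step_um = NULL) {
  stopifnot(length(images) == length(boundaries))
  if (is.null(step_um)) step_um <- pixel_pitch_um / 2
  n_s <- nrow(boundaries[[1]]$xy)
  nfr <- length(images)
  vals <- matrix(NA_real_, n_s, nfr)
  offs_um <- if (width_um > 0) seq(offset_um, offset_um + width_um,
                                   by = step_um) else offset_um
  offs_px <- offs_um / pixel_pitch_um
  for (t in seq_len(nfr)) {
    bd <- boundaries[[t]]
    if (nrow(bd$xy) != n_s) stop("boundaries have inconsistent sampling",
                                 call. = FALSE)
    img <- images[[t]]
    msk <- if (!is.null(masks)) masks[[t]] else NULL
    for (i in seq_len(n_s)) {
      px <- bd$xy[i, 1] - offs_px * bd$normals[i, 1]
      py <- bd$xy[i, 2] - offs_px * bd$normals[i, 2]
      v <- bilinear_sample(img, px, py)
      if (!is.null(msk)) {
        inm <- bilinear_sample(msk * 1.0, px, py)
        v[!is.finite(inm) | inm < 0.5] <- NA_real_
      }
      vals[i, t] <- if (any(is.finite(v))) mean(v, na.rm = TRUE) else NA_real_
    }
  }
  structure(list(values = vals,
                 band = list(offset_um = offset_um, width_um = width_um),
                 s_px = boundaries[[1]]$s_px, n_samples = n_s),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "<kymograph> %d boundary samples x %d frames, band [%g, %g] um inward\n",
    nrow(x$values), ncol(x$values), x$band$offset_um,
    x$band$offset_um + x$band$width_um))
  invisible(x)
}

#' Edge-versus-center statistics of a shift image
#'
#' Splits the cell footprint into an edge region (within `edge_depth_um` of
#' the boundary) and a center region (farther than `center_margin_um`) and
#' reports mean, SD and pixel count of the image over each, per cell and
#' pooled. The two regions are disjoint subsets of the mask.
#'
#' @param image Numeric matrix.
#' @param mask Logical mask or list of masks (one per cell).
#' @param edge_depth_um Edge band depth (default 3 um).
#' @param center_margin_um Minimum boundary distance of the center region
#'   (default 6 um).
#' @param pixel_pitch_um Pixel pitch.
#' @return Data frame with columns `cell`, `region`, `mean`, `sd`,
#'   `n_pixels`; a `pooled` row pair is appended when several cells are
#'   given.
#' @export
edge_center_stats <- function(image, mask, edge_depth_um = 3,
                              center_margin_um = 6, pixel_pitch_um = 0.6) {
  masks <- if (is.list(mask)) mask else list(mask)
  rows <- list()
  pooled <- list(edge = numeric(0), center = numeric(0))
  for (k in seq_along(masks)) {
    mk <- masks[[k]]
    if (!any(mk)) stop("empty cell mask", call. = FALSE)
    dist_um <- distance_to_edge(mk) * pixel_pitch_um
    edge <- mk & dist_um <= edge_depth_um
    center <- mk & dist_um > center_margin_um
    if (!any(edge)) stop("edge region empty", call. = FALSE)
    if (!any(center)) {
      stop("center region empty: mask smaller than the margins", call. = FALSE)
    }
    for (rg in c("edge", "center")) {
      sel <- if (rg == "edge") edge else center
      v <- image[sel]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        cell = k, region = rg, mean = mean(v), sd = stats::sd(v),
        n_pixels = length(v))
      pooled[[rg]] <- c(pooled[[rg]], v)
    }
  }
  out <- do.call(rbind, rows)
  if (length(masks) > 1) {
    for (rg in c("edge", "center")) {
      v <- pooled[[rg]]
      out <- rbind(out, data.frame(cell = NA_integer_, region = rg,
                                   mean = mean(v), sd = stats::sd(v),
                                   n_pixels = length(v)))
    }
  }
  out
}

#' Cross-section profile between two points
#'
#' Bilinear line profile of an image between two pixel positions, with
#' physical positions along the section.
#'
#' @param image Numeric matrix.
#' @param p0,p1 Endpoints as `c(x, y)` in 0-based pixel coordinates.
#' @param n_samples Number of equally spaced samples.
#' @param pixel_pitch_um Pixel pitch.
#' @return Data frame with `position_um`, `x_px`, `y_px`, `value`.
#' @export
cross_section_profile <- function(image, p0, p1, n_samples = 200L,
                                  pixel_pitch_um = 0.6) {
  ny <- nrow(image); nx <- ncol(image)
  for (p in list(p0, p1)) {
    if (p[1] < 0 || p[1] > nx - 1 || p[2] < 0 || p[2] > ny - 1) {
      stop("cross-section endpoint outside the frame", call. = FALSE)
    }
  }
  tt <- seq(0, 1, length.out = n_samples)
  xs <- p0[1] + tt * (p1[1] - p0[1])
  ys <- p0[2] + tt * (p1[2] - p0[2])
  dist_px <- sqrt((p1[1] - p0[1])^2 + (p1[2] - p0[2])^2)
  data.frame(position_um = tt * dist_px * pixel_pitch_um,
             x_px = xs, y_px = ys,
             value = bilinear_sample(image, xs, ys))
}

#' Temporal mean/SD curves of PWS and PIS over a cell
#'
#' In-mask mean and standard deviation per frame for both shift channels,
#' optionally adding a min-max-normalized PIS column for cross-channel
#' comparison of adhesion dynamics.
#'
#' @param shifts List of [shift_images()], one per frame.
#' @param masks Optional list of logical masks (default: each frame's
#'   validity mask).
#' @param normalize_pis If `TRUE`, append a `pis_norm` channel from
#'   [normalize_series()] applied to the PIS means.
#' @return Data frame with columns `frame_index`, `t_s`, `channel`, `mean`,
#'   `sd`, `n_pixels`, `flagged` (TRUE where the mask was empty).
#' @export
temporal_curves <- function(shifts, masks = NULL, normalize_pis = FALSE) {
  if (!length(shifts)) stop("need at least one frame", call. = FALSE)
  rows <- list()
  for (t in seq_along(shifts)) {
    sh <- shifts[[t]]
    mk <- if (!is.null(masks)) masks[[t]] else sh$valid_mask
    for (ch in c("pws", "pis")) {
      img <- if (ch == "pws") sh$pws_image else sh$pis_image
      v <- img[mk]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        frame_index = sh$frame_index, t_s = sh$timestamp_s, channel = ch,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n_pixels = length(v), flagged = length(v) == 0)
    }
  }
  out <- do.call(rbind, rows)
  if (normalize_pis) {
    pis_means <- out$mean[out$channel == "pis"]
    nv <- normalize_series(pis_means, "minmax")
    extra <- out[out$channel == "pis", ]
    extra$channel <- "pis_norm"
    extra$mean <- nv
    extra$sd <- NA_real_
    out <- rbind(out, extra)
  }
  rownames(out) <- NULL
  out
}
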