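# Assembly of peak-wavelength-shift (PWS) and peak-intensity-shift (PIS)
# images from per-pixel resonance maps, with fixed sign conventions:
# PWS = PWV_frame - PWV_background  (positive = red shift, cell attachment)
# PIS = PIV_background - PIV_frame  (positive = reflection efficiency loss,
#                                    i.e. stronger scattering outcoupling)

#' Shift images for one frame against a background
#'
#' Computes the PWS and PIS images of a frame relative to a background
#' (pre-attachment) frame. A pixel whose resonance moved 626 -> 628 nm has
#' PWS = +2 nm; a pixel whose normalized peak intensity fell 0.90 -> 0.80 has
#' PIS = +0.10. Validity masks are intersected; invalid pixels are `NA`.
#'
#' @param frame,background [resonance_maps()] objects of identical shape.
#' @return An object of class `shift_images`: `pws_image` (nm), `pis_image`
#'   (normalized units), `valid_mask`, and frame metadata.
#' @export
shift_images <- function(frame, background) {
  stopifnot(inherits(frame, "resonance_maps"),
            inherits(background, "resonance_maps"))
  if (!all(dim(frame$pwv_map) == dim(background$pwv_map))) {
    stop("frame and background maps have different shapes", call. = FALSE)
  }
  mask <- frame$valid_mask & background$valid_mask
  pws <- frame$pwv_map - background$pwv_map
  pis <- background$piv_map - frame$piv_map
  pws[!mask] <- NA_real_
  pis[!mask] <- NA_real_
  structure(list(pws_image = pws, pis_image = pis, valid_mask = mask,
                 pixel_pitch_um = frame$pixel_pitch_um,
                 timestamp_s = frame$timestamp_s,
                 frame_index = frame$frame_index),
            class = "shift_images")
}

#' @export
print.shift_images <- function(x, ...) {
  cat(sprintf(
    "<shift_images> %d x %d px, %.1f%% valid, PWS in [%.3f, %.3f] nm, PIS in [%.3f, %.3f]\n",
    nrow(x$pws_image), ncol(x$pws_image), 100 * mean(x$valid_mask),
    min(x$pws_image, na.rm = TRUE), max(x$pws_image, na.rm = TRUE),
    min(x$pis_image, na.rm = TRUE), max(x$pis_image, na.rm = TRUE)))
  invisible(x)
}

#' Background reference maps from a frame sequence
#'
#' Builds the per-pixel background reference used for shift images. The
#' default strategy takes the first frame of the sequence (the pre-attachment
#' scan). `"cell_free_median"` takes the per-pixel median over frames,
#' restricted at each frame to pixels flagged cell-free in `cell_free_masks`;
#' with a drift-free background this recovers the true background even while
#' a cell grows over part of the field.
#'
#' @param maps_list List of [resonance_maps()], one per frame, in time order.
#' @param strategy `"first_frame"` or `"cell_free_median"`.
#' @param cell_free_masks For `"cell_free_median"`: list of logical matrices
#'   (TRUE = cell-free) matching the maps; defaults to each frame's validity
#'   mask.
#' @return A [resonance_maps()] background reference.
#' @export
background_from_sequence <- function(maps_list,
                                     strategy = c("first_frame",
                                                  "cell_free_median"),
                                     cell_free_masks = NULL) {
  strategy <- match.arg(strategy)
  if (length(maps_list) < 1) stop("empty frame sequence", call. = FALSE)
  if (strategy == "first_frame") return(maps_list[[1]])
  d <- dim(maps_list[[1]]$pwv_map)
  nfr <- length(maps_list)
  if (is.null(cell_free_masks)) {
    cell_free_masks <- lapply(maps_list, function(m) m$valid_mask)
  }
  pwv_stack <- array(NA_real_, c(d, nfr))
  piv_stack <- array(NA_real_, c(d, nfr))
  for (i in seq_len(nfr)) {
    keep <- maps_list[[i]]$valid_mask & cell_free_masks[[i]]
    pw <- maps_list[[i]]$pwv_map; pw[!keep] <- NA_real_
    pv <- maps_list[[i]]$piv_map; pv[!keep] <- NA_real_
    pwv_stack[, , i] <- pw
    piv_stack[, , i] <- pv
  }
  pwv_med <- apply(pwv_stack, c(1, 2), stats::median, na.rm = TRUE)
  piv_med <- apply(piv_stack, c(1, 2), stats::median, na.rm = TRUE)
  valid <- is.finite(pwv_med) & is.finite(piv_med)
  pwv_med[!valid] <- NA_real_
  piv_med[!valid] <- NA_real_
  resonance_maps(pwv_med, piv_med, valid,
                 maps_list[[1]]$pixel_pitch_um,
                 maps_list[[1]]$timestamp_s,
                 maps_list[[1]]$frame_index)
}

#' Min-max normalization of a per-frame series
#'
#' Maps a series of values to `[0, 1]` by `(v - min) / (max - min)`; used for
#' plotting PIS dynamics on a common axis with PWS. `mode = "none"` is the
#' identity.
#'
#' @param values Numeric vector (one value per frame).
#' @param mode `"minmax"` or `"none"`.
#' @return Normalized numeric vector.
#' @export
normalize_series <- function(values, mode = c("minmax", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(values)
  if (length(values) < 2) stop("minmax normalization needs >= 2 frames",
                               call. = FALSE)
  rng <- range(values, na.rm = TRUE)
  if (rng[2] <= rng[1]) {
    stop("degenerate range: all values equal, cannot minmax-normalize",
         call. = FALSE)
  }
  (values - rng[1]) / (rng[2] - rng[1])
}
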