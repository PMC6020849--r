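# File formats and run configuration. Hyperspectral cubes are exchanged as
# ENVI pairs (text .hdr + flat binary 32-bit float .dat, band-sequential) or
# as native .rds; images and tables are exported as single-band ENVI rasters
# and CSV. (No HDF5 or TIFF bindings are available in the supported R
# stack, so those container formats are not offered.)

envi_header_text <- function(samples, lines, bands, wavelengths = NULL,
                             description = "") {
  txt <- c("ENVI",
           sprintf("description = {%s}", description),
           sprintf("samples = %d", samples),
           sprintf("lines = %d", lines),
           sprintf("bands = %d", bands),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           "interleave = bsq",
           "byte order = 0")
  if (!is.null(wavelengths)) {
    txt <- c(txt, "wavelength units = Nanometers",
             sprintf("wavelength = {%s}",
                     paste(format(wavelengths, trim = TRUE), collapse = ", ")))
  }
  txt
}

parse_envi_header <- function(path) {
  raw <- readLines(path, warn = FALSE)
  txt <- paste(raw, collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexpr(sprintf("(?mi)^%s\\s*=\\s*([^\\n{]+)$", key),
                                 txt, perl = TRUE))
    if (!length(m)) return(NULL)
    trimws(sub(".*=", "", m))
  }
  get_block <- function(key) {
    m <- regmatches(txt, regexpr(sprintf("(?si)%s\\s*=\\s*\\{(.*?)\\}", key),
                                 txt, perl = TRUE))
    if (!length(m)) return(NULL)
    gsub("^.*?\\{|\\}$", "", m)
  }
  list(samples = as.integer(get_scalar("samples")),
       lines = as.integer(get_scalar("lines")),
       bands = as.integer(get_scalar("bands")),
       data_type = as.integer(get_scalar("data type")),
       interleave = tolower(get_scalar("interleave")),
       byte_order = as.integer(get_scalar("byte order")),
       wavelength = get_block("wavelength"),
       description = get_block("description"))
}

#' Write a hyperspectral cube to disk
#'
#' `"envi"` writes a classic ENVI pair: `<path>.hdr` text header (with the
#' wavelength axis in nm and the pixel pitch recorded in the description)
#' plus `<path>.dat` 32-bit little-endian floats in band-sequential order.
#' `"rds"` writes the cube object natively.
#'
#' @param cube A [hyperspectral_cube()].
#' @param path Output path without extension (ENVI) or with `.rds`.
#' @param format `"envi"` or `"rds"`.
#' @return The main file path, invisibly.
#' @export
write_cube <- function(cube, path, format = c("envi", "rds")) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(cube, path)
    return(invisible(path))
  }
  d <- dim(cube$data)
  desc <- sprintf("pixel pitch um = %g; timestamp s = %g; frame index = %d",
                  cube$pixel_pitch_um, cube$timestamp_s, cube$frame_index)
  writeLines(envi_header_text(d[2], d[1], d[3], cube$wavelengths_nm, desc),
             paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  for (b in seq_len(d[3])) {
    writeBin(as.numeric(t(cube$data[, , b])), con, size = 4, endian = "little")
  }
  invisible(paste0(path, ".dat"))
}

#' Read a hyperspectral cube
#'
#' Reads an ENVI pair or a native `.rds` cube. The wavelength axis must be
#' present in the header; a descending axis is reversed together with the
#' data (with a message). A missing pixel pitch falls back to 0.6 um (with
#' a message).
#'
#' @param path Path without extension (ENVI) or to the `.rds` file.
#' @param format `"envi"` or `"rds"`.
#' @return A [hyperspectral_cube()].
#' @export
read_cube <- function(path, format = c("envi", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    cube <- readRDS(path)
    stopifnot(inherits(cube, "hyperspectral_cube"))
    return(cube)
  }
  hdr_path <- paste0(path, ".hdr")
  dat_path <- paste0(path, ".dat")
  if (!file.exists(hdr_path) || !file.exists(dat_path)) {
    stop("ENVI pair not found: ", path, ".{hdr,dat}", call. = FALSE)
  }
  h <- parse_envi_header(hdr_path)
  if (is.null(h$wavelength)) {
    stop("ENVI header has no wavelength axis", call. = FALSE)
  }
  wl <- as.numeric(strsplit(h$wavelength, ",")[[1]])
  if (length(wl) != h$bands) {
    stop("wavelength list length does not match band count", call. = FALSE)
  }
  n_expect <- h$samples * h$lines * h$bands
  vals <- readBin(dat_path, numeric(), n = n_expect + 1L, size = 4,
                  endian = "little")
  if (length(vals) != n_expect) {
    stop(sprintf("payload size mismatch: expected %d values, found %d",
                 n_expect, length(vals)), call. = FALSE)
  }
  arr <- array(NA_real_, c(h$lines, h$samples, h$bands))
  for (b in seq_len(h$bands)) {
    arr[, , b] <- matrix(vals[((b - 1) * h$samples * h$lines + 1):
                                (b * h$samples * h$lines)],
                         h$lines, h$samples, byrow = TRUE)
  }
  if (all(diff(wl) < 0)) {
    message("descending wavelength axis: reversing axis and data")
    wl <- rev(wl)
    arr <- arr[, , rev(seq_len(h$bands)), drop = FALSE]
  }
  pitch <- 0.6
  ts <- 0; fi <- 1L
  if (!is.null(h$description)) {
    mp <- regmatches(h$description,
                     regexpr("pixel pitch um = ([0-9.eE+-]+)", h$description))
    if (length(mp)) pitch <- as.numeric(sub(".*= ", "", mp)) else
      message("no pixel pitch in header; defaulting to 0.6 um")
    mt <- regmatches(h$description,
                     regexpr("timestamp s = ([0-9.eE+-]+)", h$description))
    if (length(mt)) ts <- as.numeric(sub(".*= ", "", mt))
    mf <- regmatches(h$description,
                     regexpr("frame index = ([0-9]+)", h$description))
    if (length(mf)) fi <- as.integer(sub(".*= ", "", mf))
  } else {
    message("no pixel pitch in header; defaulting to 0.6 um")
  }
  hyperspectral_cube(arr, wl, pitch, ts, fi)
}

write_envi_raster <- function(m, path, description = "") {
  writeLines(envi_header_text(ncol(m), nrow(m), 1L, NULL, description),
             paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  close(con)
  paste0(path, ".dat")
}

#' Write a set of analysis artifacts with a manifest
#'
#' Writes matrices as 32-bit float single-band ENVI rasters (physical units,
#' never rescaled), data frames as CSV, and cubes as ENVI pairs, then
#' finalizes a `manifest.json` listing every artifact with its MD5 checksum,
#' the seed, a hash of the effective configuration, and the package version.
#' The manifest is written last: a failed run leaves no manifest.
#'
#' @param artifacts Named list of matrices, data frames and/or
#'   [hyperspectral_cube()] objects. May be empty.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed to record.
#' @param config Configuration list to hash into the manifest.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(artifacts, out_dir, seed = NA_integer_,
                          config = NULL) {
  stopifnot(is.list(artifacts))
  if (length(artifacts) && is.null(names(artifacts))) {
    stop("artifacts must be named", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(artifacts)) {
    a <- artifacts[[nm]]
    base <- file.path(out_dir, nm)
    if (inherits(a, "hyperspectral_cube")) {
      write_cube(a, base, "envi")
      files <- c(files, paste0(base, c(".hdr", ".dat")))
    } else if (is.matrix(a)) {
      write_envi_raster(a, base)
      files <- c(files, paste0(base, c(".hdr", ".dat")))
    } else if (is.data.frame(a)) {
      utils::write.csv(a, paste0(base, ".csv"), row.names = FALSE)
      files <- c(files, paste0(base, ".csv"))
    } else {
      stop("unsupported artifact class for '", nm, "'", call. = FALSE)
    }
  }
  if (length(files)) {
    checksums <- as.list(unname(tools::md5sum(files)))
    names(checksums) <- basename(files)
  } else {
    checksums <- stats::setNames(list(), character(0))
  }
  manifest <- list(
    artifacts = checksums,
    seed = seed,
    config_hash = if (is.null(config)) NA_character_ else
      unname(tools::md5sum(local({
        tf <- tempfile(); jsonlite::write_json(config, tf, auto_unbox = TRUE)
        tf
      }))),
    package = "promscope",
    version = as.character(utils::packageVersion("promscope")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

run_config_keys <- c("grating", "medium", "instrument", "fitting",
                     "morphometry", "scene", "paths", "seed", "log_level")

#' Read and validate a JSON run configuration
#'
#' A run configuration is a single JSON object with blocks `grating`
#' (fields of [grating_stack()], nm and degrees), `medium`, `instrument`,
#' `fitting`, `morphometry`, `scene`, `paths`, and scalars `seed`,
#' `log_level`. Unknown top-level keys or unknown keys inside the `grating`
#' block are rejected.
#'
#' @param path Path to the JSON file.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$grating)) {
    bad <- setdiff(names(cfg$grating), names(formals(grating_stack)))
    if (length(bad)) {
      stop("unknown grating keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg
}

#' Instantiate model objects from a run configuration
#'
#' @param cfg A configuration list from [read_run_config()].
#' @return List with `stack`, `medium`, and `instrument` built from the
#'   respective blocks (package defaults fill anything omitted).
#' @export
config_objects <- function(cfg) {
  stack <- do.call(grating_stack, as.list(cfg$grating %||% list()))
  med <- do.call(medium, as.list(cfg$medium %||% list()))
  inst_args <- as.list(cfg$instrument %||% list())
  if (!is.null(inst_args$wavelength_min_nm)) {
    inst_args$wavelengths_nm <- seq(inst_args$wavelength_min_nm,
                                    inst_args$wavelength_max_nm,
                                    by = inst_args$wavelength_step_nm %||% 0.2)
    inst_args$wavelength_min_nm <- NULL
    inst_args$wavelength_max_nm <- NULL
    inst_args$wavelength_step_nm <- NULL
  }
  inst <- do.call(instrument_model, inst_args)
  list(stack = stack, medium = med, instrument = inst)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
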