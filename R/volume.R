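#' AO-OCT volume container
#'
#' An `ao_volume` bundles a 3D single-precision-valued intensity grid with its
#' acquisition metadata. The array is stored with dimensions `(z, x, y)`:
#' `intensity[, , i]` is fast B-scan `i` (a depth-by-fast-axis image), and
#' B-scans are stacked along the slow scan axis y. Pixel pitches are in
#' micrometers per pixel and the B-scan rate in Hz.
#'
#' @param intensity numeric 3D array, dimensions `(z, x, y)`; values must be
#'   finite.
#' @param pitch named numeric vector `c(x=, y=, z=)`, micrometers per pixel.
#' @param bscan_rate fast B-scan acquisition rate in Hz.
#' @param id optional identifier list, e.g. `list(video = 1, volume = 3)`.
#' @return an object of class `ao_volume`.
#' @export
ao_volume <- function(intensity, pitch = c(x = 1, y = 1, z = 1),
                      bscan_rate = 1100, id = NULL) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stopf("intensity must be a 3D array (z, x, y)")
  if (!all(is.finite(intensity)))
    stopf("intensity must be finite everywhere")
  pitch <- pitch[c("x", "y", "z")]
  if (any(is.na(pitch)) || any(pitch <= 0))
    stopf("pitch must supply positive x, y, z values")
  if (bscan_rate <= 0) stopf("bscan_rate must be > 0")
  structure(list(intensity = intensity, pitch = pitch,
                 bscan_rate = bscan_rate, id = id),
            class = "ao_volume")
}

#' @export
print.ao_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "ao_volume: %d B-scans of %d (z) x %d (x) px; pitch %.3g/%.3g/%.3g um; %g B-scans/s\n",
    d[3], d[1], d[2], x$pitch["x"], x$pitch["y"], x$pitch["z"], x$bscan_rate))
  invisible(x)
}

#' @export
dim.ao_volume <- function(x) dim(x$intensity)

n_bscans <- function(v) dim(v$intensity)[3]

#' Number of B-scans, depth pixels and A-lines of a volume
#' @param v an [ao_volume()].
#' @return named integer vector `c(z=, x=, y=)`.
#' @export
volume_shape <- function(v) {
  d <- dim(v$intensity)
  c(z = d[1], x = d[2], y = d[3])
}

#' Read an AO-OCT volume from disk
#'
#' HDF5 files must carry a dataset `intensity` laid out `(z, x, y)` plus
#' attributes `pitch_x`, `pitch_y`, `pitch_z` (um/px) and `bscan_rate` (Hz).
#' Multi-page TIFF files are read with pages as B-scans (page = z-by-x image);
#' TIFF carries no pitch metadata, so missing values default to 1 um/px and
#' 1100 Hz with a warning.
#'
#' @param path file path ending in `.h5`/`.hdf5` or `.tif`/`.tiff`.
#' @return an [ao_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("no such volume file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) {
    ls <- rhdf5::h5ls(path)
    if (!"intensity" %in% ls$name)
      stopf("HDF5 file %s has no 'intensity' dataset", path)
    arr <- rhdf5::h5read(path, "intensity")
    att <- rhdf5::h5readAttributes(path, "intensity")
    need <- c("pitch_x", "pitch_y", "pitch_z", "bscan_rate")
    if (!all(need %in% names(att)))
      stopf("HDF5 file %s is missing axis metadata (%s)", path,
            paste(setdiff(need, names(att)), collapse = ", "))
    ao_volume(arr,
              pitch = c(x = as.numeric(att$pitch_x),
                        y = as.numeric(att$pitch_y),
                        z = as.numeric(att$pitch_z)),
              bscan_rate = as.numeric(att$bscan_rate))
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    arr <- array(0, dim = c(d[1], d[2], length(pages)))
    for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
    scale <- attr(pages, "aoreg_scale")
    sidecar <- paste0(path, ".json")
    pitch <- c(x = 1, y = 1, z = 1); rate <- 1100
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (!is.null(meta$scale)) arr <- arr * meta$scale
      if (!is.null(meta$pitch)) pitch <- c(x = meta$pitch[["x"]],
                                           y = meta$pitch[["y"]],
                                           z = meta$pitch[["z"]])
      if (!is.null(meta$bscan_rate)) rate <- meta$bscan_rate
    } else {
      warnf("TIFF %s has no .json sidecar; assuming 1 um/px and 1100 Hz", path)
    }
    ao_volume(arr, pitch = pitch, bscan_rate = rate)
  } else {
    stopf("unknown volume format '%s' for %s (use .h5 or .tif)", ext, path)
  }
}

#' Write an AO-OCT volume to disk
#'
#' HDF5 output round-trips values bit-exactly at single precision and stores
#' pitch and B-scan rate as dataset attributes. TIFF output stores one 32-bit
#' float page per B-scan; because TIFF storage is defined on `[0, 1]`, values
#' are divided by their maximum and the scale is recorded in a `.json` sidecar
#' together with the axis metadata.
#'
#' @param volume an [ao_volume()].
#' @param path destination; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ao_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(volume$intensity, path, "intensity")
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, "intensity")
    rhdf5::h5writeAttribute(unname(volume$pitch["x"]), did, "pitch_x")
    rhdf5::h5writeAttribute(unname(volume$pitch["y"]), did, "pitch_y")
    rhdf5::h5writeAttribute(unname(volume$pitch["z"]), did, "pitch_z")
    rhdf5::h5writeAttribute(volume$bscan_rate, did, "bscan_rate")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  } else if (ext %in% c("tif", "tiff")) {
    mx <- max(volume$intensity, 1e-30)
    pages <- lapply(seq_len(n_bscans(volume)),
                    function(i) volume$intensity[, , i] / mx)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    jsonlite::write_json(
      list(scale = mx,
           pitch = as.list(volume$pitch),
           bscan_rate = volume$bscan_rate,
           axis_order = "z,x,y"),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    stopf("unknown volume format '%s' for %s (use .h5 or .tif)", ext, path)
  }
  invisible(path)
}

#' Write a motion trace as CSV (plus per-volume JSON)
#'
#' The CSV columns are `bscan_index` (0-based), `t_ms`, and ground-truth
#' displacements `dx_px`, `dy_px`, `dz_px` in the registration sign convention
#' (target-minus-reference for a motion-free reference; see
#' [simulate_motion()]). Per-volume torsion and scale go to a JSON sidecar.
#'
#' @param trace a `motion_trace` from [simulate_motion()].
#' @param path CSV destination; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_motion_trace <- function(trace, path) {
  df <- data.frame(bscan_index = trace$bscan_index - 1L,
                   t_ms = trace$t_ms,
                   dx_px = trace$dx_px, dy_px = trace$dy_px,
                   dz_px = trace$dz_px)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(torsion_deg = trace$torsion_deg, scale = trace$scale),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}
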