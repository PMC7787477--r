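#' Pipeline configuration
#'
#' Collects every tunable of the registration cascade with its default.
#' Ranges are validated on construction; the resolved configuration is
#' serialized alongside every pipeline run for provenance.
#'
#' @param s coarse sampling interval, B-scans (5-30).
#' @param d coarse sample half-width, B-scans (2d in 8-16).
#' @param w_y fine-search half-width, B-scans.
#' @param ncc_min minimum NCC coefficient for inclusion.
#' @param sigma_max_px local displacement-SD exclusion threshold, px (3-5).
#' @param window_ms outlier window, ms.
#' @param min_overlap NCC overlap floor (fraction of B-scan area).
#' @param vitreous_fraction depth fraction treated as vitreous for the noise
#'   offset.
#' @param m_db_above_n dynamic range between noise offset and saturation, dB.
#' @param crop_cap maximum B-scan size `c(z, x)`, px.
#' @param min_frac fraction of included B-scans for a volume to count as
#'   registered to a reference.
#' @param target_frac registrable fraction the automatic reference search
#'   aims for.
#' @param tilt tilt correction: 0, a slope, or `"auto"`.
#' @param affine_model `"similarity"` or `"affine"`.
#' @param affine_metric `"ncc"` or `"mi"`.
#' @param seed master seed for any stochastic steps.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(s = 15, d = 6, w_y = 8, ncc_min = 0.3,
                            sigma_max_px = 4, window_ms = 20,
                            min_overlap = 0.5, vitreous_fraction = 0.1,
                            m_db_above_n = 37.5, crop_cap = c(512, 512),
                            min_frac = 0.5, target_frac = 0.8, tilt = 0,
                            affine_model = "similarity", affine_metric = "ncc",
                            seed = 1) {
  cfg <- list(s = s, d = d, w_y = w_y, ncc_min = ncc_min,
              sigma_max_px = sigma_max_px, window_ms = window_ms,
              min_overlap = min_overlap,
              vitreous_fraction = vitreous_fraction,
              m_db_above_n = m_db_above_n, crop_cap = crop_cap,
              min_frac = min_frac, target_frac = target_frac, tilt = tilt,
              affine_model = affine_model, affine_metric = affine_metric,
              seed = seed)
  if (s <= 0 || d <= 0) stopf("config: s and d must be > 0")
  if (w_y < 1) stopf("config: w_y must be >= 1")
  if (ncc_min < -1 || ncc_min > 1) stopf("config: ncc_min must be in [-1, 1]")
  if (sigma_max_px <= 0) stopf("config: sigma_max_px must be > 0")
  if (min_frac <= 0 || min_frac > 1 || target_frac <= 0 || target_frac > 1)
    stopf("config: fractions must be in (0, 1]")
  if (vitreous_fraction <= 0 || vitreous_fraction >= 1)
    stopf("config: vitreous_fraction must be in (0, 1)")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else stopf("config must be JSON or YAML: %s", path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Load all volumes from a directory
#'
#' Reads every `.h5`/`.hdf5`/`.tif`/`.tiff` file (sorted by name). Video
#' membership is parsed from file names of the form `video<V>_vol<W>.*` when
#' present, else every volume forms its own video.
#'
#' @param dir input directory.
#' @return list with `volumes` and `video`.
#' @export
load_volumes <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(h5|hdf5|tif|tiff)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(files)) stopf("no volume files found in %s", dir)
  volumes <- lapply(files, read_volume)
  m <- regmatches(basename(files),
                  regexec("video([0-9]+)_", basename(files)))
  video <- vapply(seq_along(m), function(k)
    if (length(m[[k]]) == 2) as.integer(m[[k]][2]) else k, integer(1))
  for (k in seq_along(volumes))
    volumes[[k]]$id <- list(video = video[k], volume = k)
  list(volumes = volumes, video = video, files = files)
}

#' Run the full registration pipeline
#'
#' Pre-processing (optional fast-axis rectification and tilt removal,
#' intensity normalization, batch cropping), reference selection, 3D B-scan
#' registration of every volume to every reference, the multi-reference
#' global solve for B-scan coordinates tau, en-face affine estimation per
#' video, A-line coordinates chi, global rendering, and image-quality
#' metrics. Fully deterministic given inputs and configuration.
#'
#' @param volumes list of [ao_volume()]s (or use [load_volumes()]).
#' @param video integer video id per volume.
#' @param config a [pipeline_config()].
#' @param scan_pattern optional monotone fast-axis lookup for rectification.
#' @param cone_period mosaic period (um) used by the spectral metrics;
#'   `NULL` skips metrics.
#' @param out_dir optional directory: writes displacement tables, tau/chi
#'   tables, affines, rendered volume, count map, metric report and the
#'   resolved config.
#' @return list with `reference`, `single` (per-volume displacement sets and
#'   registered volumes vs the primary reference), `average` (single-
#'   reference average), `multi` (multi-reference object), `tau`, `affine`,
#'   `chi`, `render`, `metrics`, `config`.
#' @export
run_pipeline <- function(volumes, video = rep(1L, length(volumes)),
                         config = pipeline_config(), scan_pattern = NULL,
                         cone_period = NULL, out_dir = NULL) {
  if (!length(volumes)) stopf("pipeline: no input volumes")
  stage <- "preprocess"
  res <- tryCatch({
    volumes <- lapply(volumes, function(v)
      rectify_fast_axis(v, scan_pattern = scan_pattern, tilt = config$tilt))
    volumes <- lapply(volumes, normalize_intensity,
                      vitreous_fraction = config$vitreous_fraction,
                      m_db_above_n = config$m_db_above_n)
    volumes <- crop_batch(volumes, max_bscan = config$crop_cap)

    stage <- "bscan_registration"
    ref_idx <- select_reference(volumes)
    single <- lapply(seq_along(volumes), function(T)
      register_bscans(volumes[[T]], volumes[[ref_idx]], s = config$s,
                      d = config$d, w_y = config$w_y,
                      window_ms = config$window_ms,
                      sigma_max_px = config$sigma_max_px,
                      ncc_min = config$ncc_min,
                      min_overlap = config$min_overlap))
    registered <- lapply(seq_along(volumes), function(T) {
      if (inherits(single[[T]], "registration_failure")) NULL
      else construct_registered(volumes[[T]], single[[T]])
    })
    avg <- average_registered(Filter(Negate(is.null), registered))

    stage <- "global_registration"
    mrd <- multi_reference_register(volumes, video, references = "auto",
                                    min_frac = config$min_frac,
                                    target_frac = config$target_frac,
                                    s = config$s, d = config$d,
                                    w_y = config$w_y,
                                    window_ms = config$window_ms,
                                    sigma_max_px = config$sigma_max_px,
                                    ncc_min = config$ncc_min,
                                    min_overlap = config$min_overlap)
    p <- compute_p(mrd)
    sol <- solve_reference_offsets(p, mrd$references)
    tau <- global_bscan_coords(p, sol$eps, n_t = length(volumes),
                               n_y = mrd$n_y)

    stage <- "affine"
    aff <- estimate_video_affines(volumes, tau, video,
                                  model = config$affine_model,
                                  metric = config$affine_metric)
    chi <- aline_global_coords(tau, aff$affines, n_x = mrd$n_x)

    stage <- "render"
    rnd <- render_global(volumes, chi)

    stage <- "metrics"
    metrics <- NULL
    if (!is.null(cone_period)) {
      ef_ref <- enface_projection(volumes[[ref_idx]])
      ef_unreg <- Reduce(`+`, lapply(volumes, enface_projection)) /
        length(volumes)
      ef_single <- enface_projection(avg$volume)
      ef_global <- render_enface(rnd)
      ef_global[is.na(ef_global)] <- mean(ef_global, na.rm = TRUE)
      common <- common_extent(ef_ref, ef_global)
      metrics <- list(
        relative_contrast_db = relative_spectral_contrast(
          crop_center(ef_single, common), crop_center(ef_ref, common),
          cone_period),
        isr = isr(crop_center(ef_single, common), crop_center(ef_ref, common)),
        mse = mse(crop_center(ef_single, common), crop_center(ef_ref, common)),
        snr_unregistered_db = mosaic_snr(crop_center(ef_unreg, common),
                                         cone_period),
        snr_single_db = mosaic_snr(crop_center(ef_single, common), cone_period),
        snr_global_db = mosaic_snr(crop_center(ef_global, common), cone_period))
    }

    list(reference = ref_idx, single = list(displacements = single,
                                            registered = registered),
         average = avg, multi = mrd, p = p, offsets = sol, tau = tau,
         affine = aff, chi = chi, render = rnd, metrics = metrics,
         config = config)
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  if (!is.null(out_dir)) write_pipeline_outputs(res, volumes, out_dir)
  res
}

common_extent <- function(a, b) pmin(dim(a), dim(b))

crop_center <- function(img, ext) {
  d <- dim(img)
  r0 <- (d[1] - ext[1]) %/% 2
  c0 <- (d[2] - ext[2]) %/% 2
  out <- unclass(img)[r0 + seq_len(ext[1]), c0 + seq_len(ext[2])]
  attr(out, "pitch") <- attr(img, "pitch")
  out
}

write_pipeline_outputs <- function(res, volumes, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(res$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (T in seq_along(res$single$displacements)) {
    d <- res$single$displacements[[T]]
    if (inherits(d, "registration_failure")) next
    df <- d$displacements
    out <- data.frame(i = df$i - 1L, dx = df$dx, dy = df$dy, dz = df$dz,
                      ncc = df$ncc, included = df$included,
                      y_pred = df$y_pred - 1)
    utils::write.csv(out, file.path(out_dir, sprintf("disp_vol%03d.csv", T)),
                     row.names = FALSE)
  }
  tau <- res$tau
  tau_out <- data.frame(T = tau$T - 1L, i = tau$i - 1L, x = tau$x, y = tau$y,
                        z = tau$z, defined = tau$defined)
  utils::write.csv(tau_out, file.path(out_dir, "tau.csv"), row.names = FALSE)
  chi <- res$chi
  chi_out <- data.frame(T = chi$T - 1L, i = chi$i - 1L, alpha = chi$alpha - 1L,
                        x = chi$x, y = chi$y, z = chi$z)
  utils::write.csv(chi_out, file.path(out_dir, "chi.csv"), row.names = FALSE)
  affs <- lapply(res$affine$affines, function(A) {
    A4 <- diag(4)
    if (!is.null(A)) { A4[1:2, 1:2] <- A[1:2, 1:2]; A4[1:2, 4] <- A[1:2, 3] }
    as.numeric(t(A4))  # row-major
  })
  jsonlite::write_json(affs, file.path(out_dir, "affines.json"), digits = NA)
  write_volume(res$render$volume, file.path(out_dir, "global_average.h5"))
  if (!is.null(res$metrics))
    jsonlite::write_json(res$metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
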