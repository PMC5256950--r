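# File interchange: calibrated TIFF stacks with JSON sidecars, a plain-text
# decay-cube container, and trace CSVs.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a calibrated image stack
#'
#' The pixel data go to a multi-page 32-bit float TIFF; calibration metadata
#' (pixel size, frame interval, free-form metadata and the intensity scale
#' used to map data into the TIFF's unit range) go to a JSON sidecar
#' `<path>.json`. Integer-valued data (photon counts, camera ADUs) round
#' trip exactly; other data at 32-bit quantization of the stack range.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  # TIFF samples are 32-bit unsigned integers: the library truncates
  # x * (2^32 - 1) on write and returns k / 2^32 on read. Integer-valued
  # data (photon counts, camera ADUs) are stored bit-exactly by dividing by
  # 2^32 - 1 so the stored integer IS the count ("uint32" storage, decoded
  # as k = v * 2^32); other data quantize at ~2e-10 of the stack maximum.
  offset <- min(0, min(stack$data))
  d <- stack$data - offset
  m32 <- 2^32 - 1
  exact <- all(d == round(d)) && max(d) <= m32
  scale <- if (exact) m32 else 2^ceiling(log2(max(d, 1)))
  pages <- lapply(seq_len(dim(d)[3]), function(f) d[, , f] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_nm = stack$pixel_size_nm,
               frame_interval_ms = stack$frame_interval_ms,
               storage = if (exact) "uint32" else "scaled",
               intensity_scale = scale, intensity_offset = offset,
               meta = stack$meta)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_frame_stack
#' @param pixel_size_nm Pixel size in nm, required when no sidecar exists.
#' @param frame_interval_ms Frame interval fallback when no sidecar exists.
#' @export
read_frame_stack <- function(path, pixel_size_nm = NULL, frame_interval_ms = 100) {
  pages <- try(tiff::readTIFF(path, all = TRUE), silent = TRUE)
  if (inherits(pages, "try-error"))
    stopf("'%s' is not a readable TIFF image", path)
  if (!is.list(pages)) pages <- list(pages)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    pixel_size_nm <- pixel_size_nm %||% meta$pixel_size_nm
    frame_interval_ms <- meta$frame_interval_ms %||% frame_interval_ms
    scale <- meta$intensity_scale %||% 1
    offset <- meta$intensity_offset %||% 0
    storage <- meta$storage %||% "scaled"
    extra <- meta$meta %||% list()
  } else {
    assert_that(!is.null(pixel_size_nm),
                "no calibration sidecar found: supply pixel_size_nm")
    scale <- 1
    offset <- 0
    storage <- "scaled"
    extra <- list()
  }
  data <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) {
    v <- if (storage == "uint32") round(pages[[f]] * 2^32) else pages[[f]] * scale
    data[, , f] <- v + offset
  }
  frame_stack(data, pixel_size_nm, frame_interval_ms, meta = extra)
}

#' Write / read a decay cube
#'
#' Plain-text container: per-pixel channel counts as a headerless
#' tab-separated table (one row per pixel, raster order, `n_channels`
#' columns) at `path`, and a JSON header `<path>.json` holding the
#' dimensions, channel width, repetition rate and IRF descriptor.
#'
#' @param cube A [decay_cube()].
#' @param path Output path for the counts table.
#' @return `path`, invisibly.
#' @export
write_decay_cube <- function(cube, path) {
  stopifnot(inherits(cube, "decay_cube"))
  d <- dim(cube$counts)
  counts <- cube$counts
  dim(counts) <- c(d[1] * d[2], d[3])
  data.table::fwrite(data.table::as.data.table(counts), path, sep = "\t",
                     col.names = FALSE)
  irf <- cube$irf
  hdr <- list(dim = d, channel_width_ps = cube$channel_width_ps,
              rep_rate_mhz = cube$rep_rate_mhz,
              irf = if (is.null(irf)) NULL else unclass(irf))
  jsonlite::write_json(hdr, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_decay_cube
#' @export
read_decay_cube <- function(path) {
  hdr <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  counts <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
  d <- as.integer(hdr$dim)
  assert_that(nrow(counts) == d[1] * d[2] && ncol(counts) == d[3],
              "counts table does not match header dimensions")
  counts <- array(as.integer(counts), dim = d)
  irf <- hdr$irf
  if (!is.null(irf)) {
    irf <- if (identical(irf$type, "gaussian"))
      irf_gaussian(irf$center_ps, irf$fwhm_ps)
    else irf_measured(unlist(irf$counts))
  }
  decay_cube(counts, hdr$channel_width_ps, hdr$rep_rate_mhz, irf)
}

#' Write / read a FRAP (or bleaching) trace CSV
#'
#' Header row `time_s, bleach, reference, background`. On read, the bleach
#' frame is either supplied or auto-detected as the largest single-frame drop
#' of the background-corrected bleach-ROI signal.
#'
#' @param trace A [frap_trace()].
#' @param path CSV path.
#' @return `path` (write), a [frap_trace()] (read).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  utils::write.csv(trace$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param bleach_index Bleach frame index, or `"auto"` to detect it.
#' @export
read_trace_csv <- function(path, bleach_index = "auto") {
  d <- utils::read.csv(path)
  need <- c("time_s", "bleach", "reference", "background")
  assert_that(all(need %in% names(d)),
              "trace CSV must have columns time_s, bleach, reference, background")
  if (identical(bleach_index, "auto"))
    bleach_index <- which.min(diff(d$bleach - d$background)) + 1L
  frap_trace(d$time_s, d$bleach, d$reference, d$background, bleach_index)
}

#' Write a fitted lifetime image
#'
#' Lifetime map (ps; rejected pixels 0) and acceptance mask as 32-bit float
#' TIFFs, plus a JSON summary (mean lifetime, SEM, pixel counts, filters).
#'
#' @param image A `lifetime_image` from [apply_filters()].
#' @param path Base path; writes `<path>_tau.tif`, `<path>_mask.tif`,
#'   `<path>.json`.
#' @return Base `path`, invisibly.
#' @export
write_lifetime_image <- function(image, path) {
  stopifnot(inherits(image, "lifetime_image"))
  tau <- image$tau
  tau[!is.finite(tau)] <- 0
  scale <- max(tau, 1)
  tiff::writeTIFF(tau / scale, paste0(path, "_tau.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(image$accepted * 1, paste0(path, "_mask.tif"),
                  bits.per.sample = 32L)
  jsonlite::write_json(list(mean_tau_ps = image$mean_tau_ps,
                            sem_tau_ps = image$sem_tau_ps,
                            n_accepted = image$n_accepted,
                            n_pixels = image$n_pixels,
                            tau_scale_ps = scale,
                            filters = image$filters),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
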