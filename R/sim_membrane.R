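# Synthetic VAEM/TIRF membrane images: clustered point emitters rendered
# through a Gaussian PSF with Poisson shot noise and a linear camera model.

#' Parameters for the synthetic membrane-image generator
#'
#' Defines a static plasma-membrane snapshot populated with receptor
#' nanoclusters. Clusters are placed by a homogeneous spatial Poisson process
#' with intensity `density_um2`; each cluster contains `receptors` point
#' emitters that all render as a shared diffraction-limited Gaussian spot.
#'
#' @param field_px Image size in pixels, length-1 or length-2 (width, height).
#' @param pixel_size_nm Pixel pitch in nm (camera plane). Default 130.
#' @param density_um2 Expected cluster density, clusters per square micron.
#' @param receptors Fluorescent receptors per cluster (integer >= 1).
#' @param brightness Photons emitted per receptor per frame.
#' @param psf_sigma_nm Gaussian PSF standard deviation in nm. Default 110,
#'   the 0.21 lambda/NA approximation for GFP emission at NA 1.49.
#' @param background Background level, photons per pixel per frame.
#' @param gain Linear camera gain applied after photon detection.
#' @param read_noise Gaussian read noise sd in output units (a.u.).
#' @param frames Number of frames in the stack.
#' @param maturation Fluorophore maturation probability; each receptor is
#'   fluorescent with this probability. Default 1 (perfect maturation).
#' @param shot_noise If `FALSE`, the noiseless expected image is returned
#'   (useful for photon-conservation checks).
#' @param seed Optional integer seed; fixing it makes the output reproducible.
#' @return An object of class `membrane_sim_params`.
#' @export
membrane_sim_params <- function(field_px = c(128L, 128L),
                                pixel_size_nm = 130,
                                density_um2 = 0.55,
                                receptors = 6L,
                                brightness = 200,
                                psf_sigma_nm = 110,
                                background = 50,
                                gain = 1,
                                read_noise = 0,
                                frames = 1L,
                                maturation = 1,
                                shot_noise = TRUE,
                                seed = NULL) {
  if (length(field_px) == 1L) field_px <- rep(field_px, 2L)
  assert_that(all(field_px >= 1), "field_px must be positive")
  assert_that(pixel_size_nm > 0, "pixel_size_nm must be > 0")
  assert_that(density_um2 >= 0, "density_um2 must be >= 0")
  assert_that(receptors >= 1, "receptors must be >= 1")
  assert_that(brightness >= 0, "brightness must be >= 0")
  assert_that(psf_sigma_nm > 0, "psf_sigma_nm must be > 0")
  assert_that(maturation >= 0 && maturation <= 1, "maturation must be in [0,1]")
  structure(list(field_px = as.integer(field_px), pixel_size_nm = pixel_size_nm,
                 density_um2 = density_um2, receptors = as.integer(receptors),
                 brightness = brightness, psf_sigma_nm = psf_sigma_nm,
                 background = background, gain = gain, read_noise = read_noise,
                 frames = as.integer(frames), maturation = maturation,
                 shot_noise = isTRUE(shot_noise), seed = seed),
            class = "membrane_sim_params")
}

#' Calibrated image stack container
#'
#' @param data Numeric array, `[x, y]` or `[x, y, frame]`.
#' @param pixel_size_nm Pixel pitch in nm.
#' @param frame_interval_ms Frame interval in ms.
#' @param meta Optional list of free-form metadata.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(data, pixel_size_nm, frame_interval_ms = 100, meta = list()) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  assert_that(length(dim(data)) == 3L, "data must be a 2-D or 3-D array")
  assert_that(pixel_size_nm > 0, "pixel_size_nm must be > 0")
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 frame_interval_ms = frame_interval_ms, meta = meta),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<frame_stack> %d x %d px, %d frame(s), %.0f nm/px, %.0f ms/frame\n",
              d[1], d[2], d[3], x$pixel_size_nm, x$frame_interval_ms))
  invisible(x)
}

# Pixel-integrated Gaussian PSF rendered into a local window around
# (x0, y0) (continuous pixel coordinates, centre of pixel i at i - 0.5).
render_spot <- function(img, x0, y0, sigma_px, photons) {
  r <- ceiling(5 * sigma_px)
  nx <- nrow(img); ny <- ncol(img)
  ix <- max(1L, floor(x0) - r):min(nx, ceiling(x0) + r)
  iy <- max(1L, floor(y0) - r):min(ny, ceiling(y0) + r)
  if (!length(ix) || !length(iy)) return(img)
  fx <- pnorm(ix, mean = x0, sd = sigma_px) - pnorm(ix - 1, mean = x0, sd = sigma_px)
  fy <- pnorm(iy, mean = y0, sd = sigma_px) - pnorm(iy - 1, mean = y0, sd = sigma_px)
  img[ix, iy] <- img[ix, iy] + photons * (fx %o% fy)
  img
}

#' Simulate a nanocluster membrane image stack
#'
#' Places nanoclusters by a homogeneous spatial Poisson process, renders each
#' cluster as the summed pixel-integrated Gaussian PSF of its fluorescent
#' receptors, adds a flat background, applies Poisson shot noise and a linear
#' camera model (gain, Gaussian read noise). The snapshot is static: every
#' frame shares the same expected image, as appropriate for the immobile
#' clusters this generator emulates.
#'
#' @param params A [membrane_sim_params()] object.
#' @return A list with elements `stack` (a [frame_stack()]) and `truth`
#'   (list: `n_clusters`, `centers` data frame with pixel and micron
#'   coordinates, receptors and expected spot photons per cluster, and the
#'   field area in square microns).
#' @export
simulate_membrane_stack <- function(params) {
  stopifnot(inherits(params, "membrane_sim_params"))
  p <- params
  sigma_px <- p$psf_sigma_nm / p$pixel_size_nm
  if (min(p$field_px) < 2 * ceiling(3 * sigma_px) + 1)
    stopf("field (%d x %d px) too small to hold one PSF (sigma = %.2f px)",
          p$field_px[1], p$field_px[2], sigma_px)
  if (!is.null(p$seed)) set.seed(p$seed)
  nx <- p$field_px[1]; ny <- p$field_px[2]
  area_um2 <- nx * ny * (p$pixel_size_nm / 1000)^2
  n <- rpois(1L, p$density_um2 * area_um2)
  cx <- runif(n, 0, nx); cy <- runif(n, 0, ny)
  fluor <- if (p$maturation < 1) rbinom(n, p$receptors, p$maturation)
           else rep(p$receptors, n)
  expected <- matrix(p$background, nx, ny)
  if (n > 0) {
    for (i in seq_len(n)) {
      if (fluor[i] == 0) next
      expected <- render_spot(expected, cx[i], cy[i], sigma_px,
                              fluor[i] * p$brightness)
    }
  }
  data <- array(0, dim = c(nx, ny, p$frames))
  for (f in seq_len(p$frames)) {
    frame <- if (p$shot_noise) {
      matrix(rpois(nx * ny, expected), nx, ny)
    } else expected
    frame <- frame * p$gain
    if (p$read_noise > 0) frame <- frame + matrix(rnorm(nx * ny, 0, p$read_noise), nx, ny)
    data[, , f] <- frame
  }
  truth <- list(
    n_clusters = n,
    centers = data.frame(x_px = cx, y_px = cy,
                         x_um = cx * p$pixel_size_nm / 1000,
                         y_um = cy * p$pixel_size_nm / 1000,
                         receptors = fluor,
                         photons = fluor * p$brightness),
    area_um2 = area_um2,
    density_um2 = p$density_um2)
  list(stack = frame_stack(data, p$pixel_size_nm, meta = list(sim = unclass(p))),
       truth = truth)
}
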