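# Nanocluster detection in surface-illumination (VAEM/TIRF) images:
# background removal, band-pass filtering, thresholding and particle
# analysis, plus the receptors-per-cluster bookkeeping.

get_frame <- function(image, frame = 1L) {
  if (inherits(image, "frame_stack")) image$data[, , frame] else as.matrix(image)
}

#' Rolling-ball background subtraction
#'
#' Removes smooth background by grayscale morphological opening with a disc
#' structuring element of the given radius (the classical rolling-ball
#' estimate for a flat ball) and subtracts it from the image.
#'
#' @param image A numeric matrix or a [frame_stack()] (then `frame` selects
#'   the frame).
#' @param radius Ball/disc radius in pixels (>= 1). Default 50.
#' @param frame Frame index when `image` is a stack.
#' @return A numeric matrix, everywhere >= 0.
#' @export
rolling_ball_subtract <- function(image, radius = 50, frame = 1L) {
  assert_that(radius >= 1, "radius must be >= 1")
  img <- get_frame(image, frame)
  lo <- min(img); hi <- max(img)
  if (2 * radius + 1 > min(dim(img)) || hi == lo) {
    bg <- lo
  } else {
    # EBImage grayscale morphology clamps at [0, 1]: normalize first
    brush <- EBImage::makeBrush(2 * floor(radius) + 1, shape = "disc")
    bg <- EBImage::opening((img - lo) / (hi - lo), brush) * (hi - lo) + lo
  }
  pmax(img - bg, 0)
}

#' Gaussian band-pass (blur-and-subtract) filter
#'
#' Subtracts a heavily blurred copy of the image from the image itself,
#' suppressing structure larger than the blur scale. The blur sigma is given
#' in microns and converted to pixels with the pixel size (2 um at 130 nm
#' pixels is ~15.4 px).
#'
#' @param image Numeric matrix or [frame_stack()].
#' @param sigma_um Gaussian blur sigma in microns. Default 2.
#' @param pixel_size_nm Pixel size in nm; taken from the stack when `image`
#'   is a [frame_stack()].
#' @param frame Frame index when `image` is a stack.
#' @return A numeric matrix; may contain negative values (they are clipped to
#'   zero before thresholding in [threshold_label()]).
#' @export
bandpass_subtract <- function(image, sigma_um = 2, pixel_size_nm = NULL, frame = 1L) {
  assert_that(sigma_um > 0, "sigma_um must be > 0")
  if (inherits(image, "frame_stack") && is.null(pixel_size_nm))
    pixel_size_nm <- image$pixel_size_nm
  assert_that(!is.null(pixel_size_nm) && pixel_size_nm > 0,
              "pixel_size_nm is required for a plain matrix input")
  img <- get_frame(image, frame)
  sigma_px <- sigma_um * 1000 / pixel_size_nm
  # pad by the kernel radius (replicated edges) so the blur is defined for
  # images smaller than the kernel and free of wrap-around artefacts
  r <- ceiling(3 * sigma_px) + 1L
  nx <- nrow(img); ny <- ncol(img)
  ix <- pmin(pmax(seq(1 - r, nx + r), 1L), nx)
  iy <- pmin(pmax(seq(1 - r, ny + r), 1L), ny)
  padded <- img[ix, iy]
  blurred <- EBImage::gblur(padded, sigma = sigma_px, boundary = "replicate")
  img - blurred[r + seq_len(nx), r + seq_len(ny)]
}

#' Label connected components of a binary mask
#'
#' 8-neighbour (default) or 4-neighbour connected-component labelling by
#' iterative minimum-label propagation. Labels are consecutive integers in
#' raster order of each component's smallest pixel index; background is 0.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of component labels.
#' @export
label_components <- function(mask, connectivity = 8) {
  assert_that(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  mask <- mask != 0
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx + 2L, ny + 2L)
  lab[2:(nx + 1L), 2:(ny + 1L)][mask] <- which(mask)
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  core_x <- 2:(nx + 1L); core_y <- 2:(ny + 1L)
  repeat {
    cur <- lab
    for (s in shifts) {
      nb <- lab[core_x + s[1L], core_y + s[2L], drop = FALSE]
      core <- lab[core_x, core_y, drop = FALSE]
      take <- nb > 0L & core > 0L & nb < core
      if (any(take)) {
        core[take] <- nb[take]
        lab[core_x, core_y] <- core
      }
    }
    if (identical(cur, lab)) break
  }
  out <- lab[core_x, core_y, drop = FALSE]
  # relabel to consecutive integers
  ids <- sort(unique(out[out > 0L]))
  if (length(ids)) out[] <- match(out, ids, nomatch = 0L) * (out > 0L)
  matrix(as.integer(out), nx, ny)
}

#' Rasterize a region-of-interest polygon to a pixel mask
#'
#' Even-odd rule point-in-polygon test on pixel centres. Vertices are in
#' pixel coordinates (pixel i spans \[i-1, i\], centre i - 0.5).
#'
#' @param vertices Two-column matrix or data frame of polygon vertices (x, y).
#' @param dim Image dimensions, `c(nx, ny)`.
#' @return Logical matrix mask.
#' @export
roi_polygon_mask <- function(vertices, dim) {
  v <- as.matrix(vertices)
  assert_that(ncol(v) == 2 && nrow(v) >= 3, "polygon needs >= 3 (x, y) vertices")
  nx <- dim[1]; ny <- dim[2]
  px <- rep(seq_len(nx) - 0.5, times = ny)
  py <- rep(seq_len(ny) - 0.5, each = nx)
  inside <- rep(FALSE, nx * ny)
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nx, ny)
}

#' Threshold a band-pass image and label nanoclusters
#'
#' Applies an intensity threshold to the (zero-clipped) band-pass image,
#' restricts the suprathreshold mask to an optional within-cell ROI, labels
#' connected components and removes particles smaller than `min_area` px
#' (single, non-connected pixels at the default of 2 px, as produced by
#' spatially uncorrelated noise).
#'
#' @param frame Numeric matrix on the acquisition intensity scale (band-pass
#'   output).
#' @param threshold Intensity threshold in a.u. Default 80.
#' @param min_area Minimum particle area in pixels. Default 2.
#' @param connectivity Component connectivity, 8 (default) or 4.
#' @param roi Optional ROI: logical mask matrix or polygon vertices
#'   (two-column, pixel coordinates).
#' @param pixel_size_nm Pixel size in nm used for areas and diameters.
#' @return An object of class `cluster_set`: list with `records` (data frame:
#'   `label`, `area_px`, `area_um2`, `x_px`, `y_px`, `diameter_nm`,
#'   `intensity`), `labels` (label matrix), `roi_area_um2`, `n`.
#' @export
threshold_label <- function(frame, threshold = 80, min_area = 2,
                            connectivity = 8, roi = NULL,
                            pixel_size_nm = 130) {
  img <- pmax(get_frame(frame), 0)
  nx <- nrow(img); ny <- ncol(img)
  if (is.null(roi)) {
    roi_mask <- matrix(TRUE, nx, ny)
  } else if (is.matrix(roi) && is.logical(roi) && all(dim(roi) == dim(img))) {
    roi_mask <- roi
  } else {
    roi_mask <- roi_polygon_mask(roi, dim(img))
  }
  px_area_um2 <- (pixel_size_nm / 1000)^2
  roi_area_um2 <- sum(roi_mask) * px_area_um2
  mask <- (img > threshold) & roi_mask
  lab <- label_components(mask, connectivity)
  n0 <- max(lab)
  if (n0 == 0 || roi_area_um2 == 0) {
    return(structure(list(records = data.frame(label = integer(0),
                                               area_px = integer(0),
                                               area_um2 = numeric(0),
                                               x_px = numeric(0), y_px = numeric(0),
                                               diameter_nm = numeric(0),
                                               intensity = numeric(0)),
                          labels = lab, roi_area_um2 = roi_area_um2, n = 0L),
                     class = "cluster_set"))
  }
  areas <- tabulate(lab[lab > 0L], nbins = n0)
  keep <- which(areas >= min_area)
  relab <- integer(n0)
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  n <- length(keep)
  if (n == 0) {
    return(structure(list(records = data.frame(label = integer(0),
                                               area_px = integer(0),
                                               area_um2 = numeric(0),
                                               x_px = numeric(0), y_px = numeric(0),
                                               diameter_nm = numeric(0),
                                               intensity = numeric(0)),
                          labels = lab, roi_area_um2 = roi_area_um2, n = 0L),
                     class = "cluster_set"))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  xs <- (idx - 1L) %% nx + 1L
  ys <- (idx - 1L) %/% nx + 1L
  area_px <- tabulate(l, nbins = n)
  cx <- as.vector(rowsum(xs - 0.5, l)) / area_px
  cy <- as.vector(rowsum(ys - 0.5, l)) / area_px
  intens <- as.vector(rowsum(img[idx], l))
  area_um2 <- area_px * px_area_um2
  records <- data.frame(label = seq_len(n), area_px = area_px,
                        area_um2 = area_um2, x_px = cx, y_px = cy,
                        diameter_nm = 2 * sqrt(area_um2 / pi) * 1000,
                        intensity = intens)
  structure(list(records = records, labels = lab,
                 roi_area_um2 = roi_area_um2, n = n),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters in %.2f um^2 (%.3f /um^2)\n",
              x$n, x$roi_area_um2,
              if (x$roi_area_um2 > 0) x$n / x$roi_area_um2 else NA_real_))
  invisible(x)
}

#' Run the full nanocluster detection pipeline on one frame
#'
#' Rolling-ball background subtraction, Gaussian band-pass, threshold and
#' particle analysis, each stage individually disableable.
#'
#' @param image Numeric matrix or [frame_stack()].
#' @param pixel_size_nm Pixel size in nm (taken from the stack if available).
#' @param rollball Rolling-ball radius in px, or `NULL` to skip. Default 50.
#' @param sigma_um Band-pass blur sigma in microns, or `NULL` to skip.
#'   Default 2.
#' @param threshold Intensity threshold (a.u.). Default 80.
#' @param min_area Minimum particle area (px). Default 2.
#' @param connectivity 8 (default) or 4.
#' @param roi Optional ROI mask or polygon, see [threshold_label()].
#' @param frame Frame index for stacks.
#' @return A `cluster_set`, see [threshold_label()].
#' @export
detect_clusters <- function(image, pixel_size_nm = NULL, rollball = 50,
                            sigma_um = 2, threshold = 80, min_area = 2,
                            connectivity = 8, roi = NULL, frame = 1L) {
  if (inherits(image, "frame_stack") && is.null(pixel_size_nm))
    pixel_size_nm <- image$pixel_size_nm
  assert_that(!is.null(pixel_size_nm), "pixel_size_nm is required")
  img <- get_frame(image, frame)
  if (!is.null(rollball)) img <- rolling_ball_subtract(img, rollball)
  if (!is.null(sigma_um)) img <- bandpass_subtract(img, sigma_um, pixel_size_nm)
  threshold_label(img, threshold = threshold, min_area = min_area,
                  connectivity = connectivity, roi = roi,
                  pixel_size_nm = pixel_size_nm)
}

#' Summarize cluster sets into density and size statistics
#'
#' For a single `cluster_set`, the density is `n / roi_area_um2` and size
#' statistics are over clusters. For a list of sets (one per image), per-image
#' densities and mean sizes are averaged and their SEM over images reported,
#' matching per-treatment pooling over replicate images.
#'
#' @param sets A `cluster_set` or a list of them.
#' @param roi_area_um2 Optional override of the analysed area (per image).
#' @return An object of class `cluster_summary`: list with `n_clusters`,
#'   `n_images`, `area_um2`, `density_um2`, `density_sem`, `mean_size_um2`,
#'   `size_sem`, `mean_diameter_nm`.
#' @export
summarize_clusters <- function(sets, roi_area_um2 = NULL) {
  if (inherits(sets, "cluster_set")) sets <- list(sets)
  assert_that(length(sets) >= 1, "need at least one cluster_set")
  areas <- vapply(sets, function(s) roi_area_um2 %||% s$roi_area_um2, numeric(1))
  assert_that(all(areas > 0), "ROI area must be > 0")
  ns <- vapply(sets, function(s) s$n, integer(1))
  dens <- ns / areas
  sizes <- lapply(sets, function(s) s$records$area_um2)
  mean_sizes <- vapply(sizes, function(x) if (length(x)) mean(x) else NA_real_, numeric(1))
  all_sizes <- unlist(sizes)
  if (length(sets) > 1L) {
    density <- mean(dens); density_sem <- sem(dens)
    mean_size <- mean(mean_sizes, na.rm = TRUE); size_sem <- sem(mean_sizes)
  } else {
    density <- dens; density_sem <- NA_real_
    mean_size <- if (length(all_sizes)) mean(all_sizes) else NA_real_
    size_sem <- sem(all_sizes)
  }
  structure(list(n_clusters = sum(ns), n_images = length(sets),
                 area_um2 = sum(areas), density_um2 = density,
                 density_sem = density_sem, mean_size_um2 = mean_size,
                 size_sem = size_sem,
                 mean_diameter_nm = if (length(all_sizes))
                   mean(2 * sqrt(all_sizes / pi) * 1000) else NA_real_),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("<cluster_summary> %d clusters / %d image(s): %.2f +/- %.2f per um^2, size %.3f +/- %.3f um^2\n",
              x$n_clusters, x$n_images, x$density_um2, x$density_sem,
              x$mean_size_um2, x$size_sem))
  invisible(x)
}

#' Average number of receptors per nanocluster
#'
#' Divides the receptor surface density by the nanocluster density and rounds
#' to the nearest integer; the SEM is propagated to first order from the two
#' input SEMs.
#'
#' @param receptor_density Receptors per square micron at the membrane.
#' @param cluster_density Nanoclusters per square micron.
#' @param receptor_sem,cluster_sem Optional SEMs of the two densities.
#' @return List with `receptors` (integer), `ratio` (unrounded), `sem`.
#'   If `cluster_density` is 0 the result is flagged undefined (`NA` with a
#'   warning).
#' @export
receptors_per_cluster <- function(receptor_density, cluster_density,
                                  receptor_sem = NULL, cluster_sem = NULL) {
  if (cluster_density <= 0) {
    warning("cluster density is zero: receptors per cluster undefined")
    return(list(receptors = NA_integer_, ratio = NA_real_, sem = NA_real_))
  }
  ratio <- receptor_density / cluster_density
  s <- NA_real_
  if (!is.null(receptor_sem) && !is.null(cluster_sem) && receptor_density > 0) {
    s <- ratio * sqrt((receptor_sem / receptor_density)^2 +
                      (cluster_sem / cluster_density)^2)
  }
  list(receptors = as.integer(round(ratio)), ratio = ratio, sem = s)
}

#' Mean-intensity bleaching trace of a 5 x 5 pixel region of interest
#'
#' @param stack A [frame_stack()].
#' @param center Integer vector `c(x, y)`: centre pixel of the 5 x 5 window.
#' @param size ROI side length in pixels (odd). Default 5.
#' @return Numeric vector of per-frame mean intensities (length = frames).
#' @export
roi_bleach_trace <- function(stack, center, size = 5L) {
  stopifnot(inherits(stack, "frame_stack"))
  assert_that(size %% 2 == 1, "size must be odd")
  h <- (size - 1L) %/% 2L
  d <- dim(stack$data)
  x <- as.integer(center[1]); y <- as.integer(center[2])
  if (x - h < 1L || y - h < 1L || x + h > d[1] || y + h > d[2])
    stopf("ROI window clipped at the image edge (center %d,%d)", x, y)
  apply(stack$data[(x - h):(x + h), (y - h):(y + h), , drop = FALSE], 3, mean)
}
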