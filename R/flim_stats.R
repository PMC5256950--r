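# FRET efficiency and interacting-pixel (IPS) statistics derived from
# fitted lifetime images.

#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tau_da / tau_d`, the fraction of donor excitations transferred to
#' the acceptor, computed from the donor lifetime in presence (`tau_da`) and
#' absence (`tau_d`) of the acceptor.
#'
#' @param tau_da Donor lifetime with acceptor, ps.
#' @param tau_d Donor-only lifetime, ps (> 0).
#' @param percent If `TRUE`, return the integer percentage used in summary
#'   tables (`round(100 * E)`).
#' @return FRET efficiency as a fraction (or integer percent). A negative
#'   efficiency (`tau_da > tau_d`) is returned as-is with a no-FRET warning.
#' @export
fret_efficiency <- function(tau_da, tau_d, percent = FALSE) {
  assert_that(all(tau_d > 0), "tau_d must be > 0")
  e <- 1 - tau_da / tau_d
  if (any(e < 0)) warning("tau_da > tau_d: negative efficiency, no FRET")
  if (percent) round(100 * e) else e
}

#' Interacting-pixel statistic (IPS)
#'
#' Converts a FRET-efficiency threshold into a lifetime threshold
#' `tau_thr = tau_d_ref * (1 - e_threshold)` and reports the percentage of
#' quality-filtered pixels whose fitted mean lifetime falls strictly below
#' it. The denominator is the accepted pixels by default; `denominator =
#' "all"` uses every pixel in the image instead.
#'
#' @param image A `lifetime_image` from [apply_filters()].
#' @param tau_d_ref Donor-only reference lifetime in ps (from a matched
#'   donor-only dataset).
#' @param e_threshold FRET-efficiency threshold. Default 0.13.
#' @param denominator `"accepted"` (default) or `"all"`.
#' @return An object of class `ips_result`: list with `tau_d_ref_ps`,
#'   `e_threshold`, `tau_threshold_ps`, `n_interacting`, `n_evaluated`,
#'   `ips_percent`. With zero accepted pixels the IPS is `NA` (flagged with
#'   a warning).
#' @export
ips_fraction <- function(image, tau_d_ref, e_threshold = 0.13,
                         denominator = c("accepted", "all")) {
  stopifnot(inherits(image, "lifetime_image"))
  denominator <- match.arg(denominator)
  assert_that(tau_d_ref > 0, "tau_d_ref must be > 0")
  assert_that(e_threshold > 0 && e_threshold < 1, "e_threshold must be in (0,1)")
  tau_thr <- tau_d_ref * (1 - e_threshold)
  acc <- image$accepted
  n_int <- sum(image$tau[acc] < tau_thr, na.rm = TRUE)
  n_eval <- if (denominator == "accepted") sum(acc) else image$n_pixels
  ips <- if (n_eval > 0) 100 * n_int / n_eval else NA_real_
  if (n_eval == 0) warning("no accepted pixels: IPS undefined")
  structure(list(tau_d_ref_ps = tau_d_ref, e_threshold = e_threshold,
                 tau_threshold_ps = tau_thr, n_interacting = n_int,
                 n_evaluated = n_eval, ips_percent = ips),
            class = "ips_result")
}

#' @export
print.ips_result <- function(x, ...) {
  cat(sprintf("<ips_result> IPS %.1f%% (%d/%d px below %.0f ps; E_thr %.0f%%)\n",
              x$ips_percent, x$n_interacting, x$n_evaluated,
              x$tau_threshold_ps, 100 * x$e_threshold))
  invisible(x)
}

#' Per-nanocluster lifetime distribution
#'
#' Pools the fitted lifetimes of bright nanoclusters: clusters are connected
#' suprathreshold regions of the photon-count image (or a supplied label
#' mask), qualify when their brightest pixel reaches `min_photons`, and
#' contribute the mean accepted lifetime over their pixels.
#'
#' @param image A `lifetime_image` from [apply_filters()].
#' @param intensity Photon-count matrix (defaults to the image's own per-pixel
#'   photon counts).
#' @param labels Optional integer label matrix from [threshold_label()] /
#'   [label_components()]; if `NULL`, clusters are the 8-connected components
#'   of `intensity >= min_photons`.
#' @param min_photons Peak-intensity qualification threshold, photons per
#'   pixel. Default 2000.
#' @return Data frame with one row per qualifying cluster: `label`,
#'   `area_px`, `peak_photons`, `tau_mean_ps`, `n_accepted_px`.
#' @export
cluster_lifetime_distribution <- function(image, intensity = NULL,
                                          labels = NULL, min_photons = 2000) {
  stopifnot(inherits(image, "lifetime_image"))
  intensity <- intensity %||% image$photons
  if (is.null(labels)) labels <- label_components(intensity >= min_photons)
  n <- max(labels)
  out <- data.frame(label = integer(0), area_px = integer(0),
                    peak_photons = numeric(0), tau_mean_ps = numeric(0),
                    n_accepted_px = integer(0))
  if (n == 0) return(out)
  for (l in seq_len(n)) {
    idx <- which(labels == l)
    if (max(intensity[idx]) < min_photons) next
    tau <- image$tau[idx]
    tau <- tau[is.finite(tau)]
    out <- rbind(out, data.frame(label = l, area_px = length(idx),
                                 peak_photons = max(intensity[idx]),
                                 tau_mean_ps = if (length(tau)) mean(tau) else NA_real_,
                                 n_accepted_px = length(tau)))
  }
  out
}

#' Welch two-sample comparison of lifetime images
#'
#' Convenience comparison of accepted-pixel lifetimes between two images
#' (e.g. donor-only vs double-labelled). The underlying test is Welch's
#' t-test; treat the p-value as an interpretation aid, not a calibrated
#' experiment-level test (pixels within an image are not independent).
#'
#' @param image_a,image_b `lifetime_image` objects.
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_lifetimes <- function(image_a, image_b) {
  stopifnot(inherits(image_a, "lifetime_image"), inherits(image_b, "lifetime_image"))
  stats::t.test(image_a$tau[image_a$accepted], image_b$tau[image_b$accepted])
}
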