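# Synthetic TCSPC FLIM data: per-pixel photon arrival-time histograms for a
# two-population (donor-only / FRET) lifetime image.

#' Instrument response function descriptors
#'
#' TCSPC decay models convolve the ideal exponential decay with the
#' instrument response function (IRF). The IRF may be parametric
#' (`irf_gaussian`) or a measured per-channel histogram (`irf_measured`).
#'
#' @param center_ps Temporal position of the IRF peak in ps.
#' @param fwhm_ps Full width at half maximum in ps. Default 300 ps, typical
#'   of a hybrid detector with ~100 ps single-photon timing resolution.
#' @return An object of class `nm_irf`.
#' @export
irf_gaussian <- function(center_ps = 976.5625, fwhm_ps = 300) {
  assert_that(fwhm_ps > 0, "fwhm_ps must be > 0")
  structure(list(type = "gaussian", center_ps = center_ps, fwhm_ps = fwhm_ps,
                 sigma_ps = fwhm_ps / (2 * sqrt(2 * log(2)))),
            class = "nm_irf")
}

#' @rdname irf_gaussian
#' @param counts Non-negative per-channel IRF histogram (length = number of
#'   time channels); normalized internally.
#' @export
irf_measured <- function(counts) {
  assert_that(all(counts >= 0) && sum(counts) > 0, "IRF counts must be non-negative, not all zero")
  structure(list(type = "measured", counts = counts / sum(counts)),
            class = "nm_irf")
}

#' Parameters for the synthetic TCSPC decay-cube generator
#'
#' Each pixel is labelled interacting with probability `f_int`. Photons in
#' non-interacting pixels decay with the donor lifetime `tau_d_ps`; photons in
#' interacting pixels decay with `tau_da_ps` (by default derived from the
#' interacting-state FRET efficiency `fret_int` as `tau_d_ps * (1 - fret_int)`).
#' Arrival times are IRF-delayed exponential draws wrapped at the laser
#' repetition period and histogrammed into `n_channels` time channels.
#'
#' @param dim_px Image size in pixels, length-1 or length-2.
#' @param tau_d_ps Donor-only fluorescence lifetime, ps.
#' @param tau_da_ps Lifetime of interacting (FRET) pixels, ps; overrides
#'   `fret_int` when given.
#' @param fret_int FRET efficiency of the interacting state, used to derive
#'   `tau_da_ps` when that is `NULL`. Default 0.25, a typical value for a
#'   directly interacting GFP--mCherry pair and comfortably above the ~13 %
#'   detection threshold of the IPS statistic.
#' @param f_int Fraction of pixels in the interacting state, in \[0, 1\].
#' @param photons_mean Mean photons per pixel (per-pixel totals are Poisson).
#' @param photons_min Lower clamp on per-pixel photon totals (default 0: pure
#'   Poisson totals).
#' @param n_channels Number of TCSPC time channels. Default 256.
#' @param rep_rate_mhz Laser repetition rate, MHz. Default 40 (25 ns period);
#'   channel width is `1e6 / rep_rate_mhz / n_channels` ps (~97.7 ps).
#' @param irf An `nm_irf` IRF descriptor, default [irf_gaussian()].
#' @param bg_fraction Fraction of photons that are uncorrelated background,
#'   uniform over the repetition period.
#' @param seed Optional integer seed.
#' @return An object of class `flim_sim_params`.
#' @export
flim_sim_params <- function(dim_px = c(64L, 64L),
                            tau_d_ps = 2402,
                            tau_da_ps = NULL,
                            fret_int = 0.25,
                            f_int = 0,
                            photons_mean = 3000,
                            photons_min = 0,
                            n_channels = 256L,
                            rep_rate_mhz = 40,
                            irf = irf_gaussian(),
                            bg_fraction = 0,
                            seed = NULL) {
  if (length(dim_px) == 1L) dim_px <- rep(dim_px, 2L)
  assert_that(f_int >= 0 && f_int <= 1, "f_int must be in [0,1]")
  assert_that(tau_d_ps > 0, "tau_d_ps must be > 0")
  if (is.null(tau_da_ps)) {
    assert_that(fret_int >= 0 && fret_int < 1, "fret_int must be in [0,1)")
    tau_da_ps <- tau_d_ps * (1 - fret_int)
  }
  assert_that(tau_da_ps > 0 && tau_da_ps <= tau_d_ps,
              "tau_da_ps must satisfy 0 < tau_da <= tau_d")
  assert_that(bg_fraction >= 0 && bg_fraction < 1, "bg_fraction must be in [0,1)")
  period <- 1e6 / rep_rate_mhz
  if (n_channels * period / n_channels < 3 * tau_d_ps)
    warning("measurement window shorter than 3 * tau_d; lifetime estimates will degrade")
  structure(list(dim_px = as.integer(dim_px), tau_d_ps = tau_d_ps,
                 tau_da_ps = tau_da_ps, f_int = f_int,
                 photons_mean = photons_mean, photons_min = photons_min,
                 n_channels = as.integer(n_channels), rep_rate_mhz = rep_rate_mhz,
                 irf = irf, bg_fraction = bg_fraction, seed = seed),
            class = "flim_sim_params")
}

#' Per-pixel photon arrival-time histogram cube
#'
#' @param counts Integer array `[x, y, channel]` of photon counts.
#' @param channel_width_ps Width of one time channel in ps.
#' @param rep_rate_mhz Laser repetition rate in MHz.
#' @param irf An `nm_irf` descriptor (or `NULL` if unknown).
#' @param meta Optional metadata list.
#' @return An object of class `decay_cube`.
#' @export
decay_cube <- function(counts, channel_width_ps, rep_rate_mhz = 40,
                       irf = NULL, meta = list()) {
  assert_that(length(dim(counts)) == 3L, "counts must be a 3-D array [x, y, channel]")
  assert_that(channel_width_ps > 0, "channel_width_ps must be > 0")
  structure(list(counts = counts, channel_width_ps = channel_width_ps,
                 rep_rate_mhz = rep_rate_mhz, irf = irf, meta = meta),
            class = "decay_cube")
}

#' @export
print.decay_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<decay_cube> %d x %d px, %d channels x %.2f ps (%.0f MHz), %d photons total\n",
              d[1], d[2], d[3], x$channel_width_ps, x$rep_rate_mhz, sum(x$counts)))
  invisible(x)
}

#' Simulate a TCSPC decay cube
#'
#' Draws each photon's arrival time as IRF delay + exponential decay time,
#' wraps it at the repetition period (photons emitted after the next laser
#' pulse appear early in the histogram) and bins it into time channels.
#' Per-pixel photon totals are Poisson around `photons_mean`; background
#' photons are uniform over the period.
#'
#' @param params A [flim_sim_params()] object.
#' @return A list with `cube` (a [decay_cube()]) and `truth` (list:
#'   `interacting` logical matrix, `tau_map` ps matrix, `photons` matrix,
#'   `f_int_realized`, and the generating lifetimes).
#' @export
simulate_decay_cube <- function(params) {
  stopifnot(inherits(params, "flim_sim_params"))
  p <- params
  period <- 1e6 / p$rep_rate_mhz
  width <- period / p$n_channels
  if (max(p$tau_d_ps, p$tau_da_ps) >= period / 2)
    warning("lifetime >= half the repetition period: wrap-around dominates the histogram")
  if (p$irf$type == "measured" && length(p$irf$counts) != p$n_channels)
    stopf("measured IRF has %d channels, cube has %d", length(p$irf$counts), p$n_channels)
  if (!is.null(p$seed)) set.seed(p$seed)
  nx <- p$dim_px[1]; ny <- p$dim_px[2]; npx <- nx * ny
  interacting <- matrix(rbinom(npx, 1L, p$f_int) == 1L, nx, ny)
  nphot <- matrix(pmax(rpois(npx, p$photons_mean), p$photons_min), nx, ny)
  tau_map <- matrix(ifelse(interacting, p$tau_da_ps, p$tau_d_ps), nx, ny)

  counts <- array(0L, dim = c(nx, ny, p$n_channels))
  dim(counts) <- c(npx, p$n_channels)
  draw_irf_delay <- function(m) {
    if (p$irf$type == "gaussian") {
      rnorm(m, p$irf$center_ps, p$irf$sigma_ps)
    } else {
      # sample a channel from the measured IRF, uniform within the channel
      ch <- sample.int(p$n_channels, m, replace = TRUE, prob = p$irf$counts)
      (ch - runif(m)) * width
    }
  }
  # chunk pixels so the photon vectors stay modest
  chunk <- max(1L, floor(2e6 / max(1, p$photons_mean)))
  for (start in seq(1L, npx, by = chunk)) {
    idx <- start:min(npx, start + chunk - 1L)
    n_i <- nphot[idx]
    m <- sum(n_i)
    if (m == 0) next
    pix <- rep(seq_along(idx), n_i)
    tau_i <- rep(tau_map[idx], n_i)
    t_arr <- draw_irf_delay(m) + rexp(m, rate = 1) * tau_i
    if (p$bg_fraction > 0) {
      is_bg <- runif(m) < p$bg_fraction
      t_arr[is_bg] <- runif(sum(is_bg), 0, period)
    }
    t_arr <- t_arr %% period
    ch <- pmin(p$n_channels, floor(t_arr / width) + 1L)
    counts[idx, ] <- counts[idx, ] +
      matrix(tabulate(ch + (pix - 1L) * p$n_channels, nbins = length(idx) * p$n_channels),
             nrow = length(idx), byrow = TRUE)
  }
  dim(counts) <- c(nx, ny, p$n_channels)
  list(cube = decay_cube(counts, width, p$rep_rate_mhz, p$irf,
                         meta = list(sim = unclass(p))),
       truth = list(interacting = interacting, tau_map = tau_map,
                    photons = nphot, f_int_realized = mean(interacting),
                    tau_d_ps = p$tau_d_ps, tau_da_ps = p$tau_da_ps))
}
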