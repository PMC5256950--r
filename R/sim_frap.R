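# Synthetic FRAP traces: partial exponential recovery with scan bleaching.

#' Parameters for the synthetic FRAP-trace generator
#'
#' The bleach-ROI intensity follows
#' `F(t) = F_pre * [(1 - depth) + depth * Mf * R(t)] * S(t)` after the bleach
#' pulse, where `R(t) = 1 - exp(-t / tau_rec)` is a single-exponential
#' recovery whose half-time satisfies `t_half = 0.224 * w^2 / D`, and
#' `S(t) = exp(-k_scan * t)` is the scan-bleach factor that also attenuates
#' the reference ROI. Gaussian noise is added to both ROIs.
#'
#' @param mf Mobile fraction, in \[0, 1\].
#' @param d_um2_s Lateral diffusion coefficient, square microns per second.
#' @param w_um Bleach-spot radius in microns.
#' @param depth Bleach depth in (0, 1\]: fraction of pre-bleach intensity
#'   removed by the bleach pulse.
#' @param k_scan Scan-bleach rate per second (applied to every scan frame).
#' @param noise_sd Gaussian noise sd as a fraction of the pre-bleach level.
#' @param times Sampling times in seconds. Default: 1 s sampling with 10
#'   pre-bleach frames and ~500 s of recovery, mirroring typical confocal
#'   FRAP acquisitions of slowly diffusing membrane receptors.
#' @param bleach_index Index of the first post-bleach frame.
#' @param f_pre Pre-bleach plateau intensity (a.u.).
#' @param f_ref Reference-ROI intensity (a.u.).
#' @param f_bg Background intensity (a.u.).
#' @param seed Optional integer seed.
#' @return An object of class `frap_sim_params`.
#' @export
frap_sim_params <- function(mf = 0.28,
                            d_um2_s = 0.003,
                            w_um = 1,
                            depth = 0.8,
                            k_scan = 0.001,
                            noise_sd = 0.02,
                            times = seq(0, 510, by = 1),
                            bleach_index = 11L,
                            f_pre = 1000,
                            f_ref = 800,
                            f_bg = 50,
                            seed = NULL) {
  assert_that(mf >= 0 && mf <= 1, "mf must be in [0,1]")
  assert_that(d_um2_s >= 0, "d_um2_s must be >= 0")
  assert_that(w_um > 0, "w_um must be > 0")
  assert_that(depth > 0 && depth <= 1, "depth must be in (0,1]")
  assert_that(all(diff(times) > 0), "times must be strictly increasing")
  assert_that(bleach_index > 1 && bleach_index <= length(times),
              "bleach_index out of range")
  structure(list(mf = mf, d_um2_s = d_um2_s, w_um = w_um, depth = depth,
                 k_scan = k_scan, noise_sd = noise_sd, times = times,
                 bleach_index = as.integer(bleach_index), f_pre = f_pre,
                 f_ref = f_ref, f_bg = f_bg, seed = seed),
            class = "frap_sim_params")
}

#' FRAP trace container
#'
#' @param time_s Sampling times (s), strictly increasing.
#' @param bleach Bleach-ROI intensity.
#' @param reference Reference-ROI intensity (scan-bleach control).
#' @param background Background-ROI intensity.
#' @param bleach_index Index of the first post-bleach frame.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(time_s, bleach, reference, background, bleach_index) {
  assert_that(all(diff(time_s) > 0), "time_s must be strictly increasing")
  n <- length(time_s)
  assert_that(length(bleach) == n && length(reference) == n && length(background) == n,
              "trace columns must have equal length")
  assert_that(bleach_index > 1 && bleach_index <= n, "bleach_index out of range")
  structure(list(data = data.frame(time_s = time_s, bleach = bleach,
                                   reference = reference, background = background),
                 bleach_index = as.integer(bleach_index)),
            class = "frap_trace")
}

#' Recovery half-time implied by spot radius and diffusion coefficient
#'
#' Uses the Axelrod-style relation `t_half = 0.224 * w^2 / D` for a Gaussian
#' bleach spot of radius `w`.
#'
#' @param w_um Bleach-spot radius (microns).
#' @param d_um2_s Diffusion coefficient (square microns per second).
#' @return Half-time of recovery in seconds.
#' @export
frap_half_time <- function(w_um, d_um2_s) 0.224 * w_um^2 / d_um2_s

#' Simulate a FRAP trace
#'
#' @param params A [frap_sim_params()] object.
#' @return A list with `trace` (a [frap_trace()]) and `truth` (list: `mf`,
#'   `d_um2_s`, `t_half_s`, `tau_rec_s`, `k_scan`, `depth`).
#' @export
simulate_frap_trace <- function(params) {
  stopifnot(inherits(params, "frap_sim_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  t <- p$times
  n <- length(t)
  t0 <- t[p$bleach_index]
  t_half <- if (p$d_um2_s > 0) frap_half_time(p$w_um, p$d_um2_s) else Inf
  tau_rec <- t_half / log(2)
  scan <- exp(-p$k_scan * t)
  rec <- ifelse(t >= t0, 1 - exp(-(t - t0) / tau_rec), NA_real_)
  f <- ifelse(t < t0,
              p$f_pre,
              p$f_pre * ((1 - p$depth) + p$depth * p$mf * rec)) * scan
  ref <- p$f_ref * scan
  noise <- p$noise_sd * p$f_pre
  bleach <- f + p$f_bg + rnorm(n, 0, noise)
  reference <- ref + p$f_bg + rnorm(n, 0, noise * p$f_ref / p$f_pre)
  background <- p$f_bg + rnorm(n, 0, noise / 4)
  list(trace = frap_trace(t, bleach, reference, background, p$bleach_index),
       truth = list(mf = p$mf, d_um2_s = p$d_um2_s, t_half_s = t_half,
                    tau_rec_s = tau_rec, k_scan = p$k_scan, depth = p$depth))
}
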