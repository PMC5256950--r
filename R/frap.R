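# FRAP analysis: normalization with scan-bleach correction, exponential
# recovery fitting (mobile fraction, half-time, diffusion coefficient), and
# the Gaussian membrane cross-section fit.

#' Normalize a FRAP trace
#'
#' Subtracts the background-ROI signal from the bleach and reference ROIs,
#' divides by the reference to correct scan bleaching (or by a fitted
#' exponential of the pre-bleach frames when no reference exists), then
#' rescales so the pre-bleach mean is 1 and the first post-bleach point is 0.
#'
#' @param trace A [frap_trace()] with at least 3 pre-bleach frames.
#' @param correction `"reference"` (default), `"expfit"` or `"none"`.
#' @return An object of class `frap_norm`: list with `data` (data frame
#'   `time_s`, `value`), `bleach_index`, `correction`.
#' @export
normalize_trace <- function(trace, correction = c("reference", "expfit", "none")) {
  stopifnot(inherits(trace, "frap_trace"))
  correction <- match.arg(correction)
  d <- trace$data
  bi <- trace$bleach_index
  assert_that(bi > 3, "need at least 3 pre-bleach frames")
  x <- d$bleach - d$background
  t <- d$time_s
  if (correction == "reference") {
    ref <- d$reference - d$background
    if (any(ref <= 0))
      stopf("reference ROI reaches the background level; cannot correct scan bleaching")
    x <- x / (ref / mean(ref[seq_len(bi - 1L)]))
  } else if (correction == "expfit") {
    pre <- seq_len(bi - 1L)
    k <- -stats::coef(stats::lm(log(pmax(x[pre], 1e-9)) ~ t[pre]))[[2]]
    x <- x / exp(-k * (t - t[1]))
  }
  pre_mean <- mean(x[seq_len(bi - 1L)])
  post0 <- x[bi]
  assert_that(pre_mean > post0, "no bleach detected: pre-bleach level <= first post-bleach point")
  val <- (x - post0) / (pre_mean - post0)
  structure(list(data = data.frame(time_s = t, value = val),
                 bleach_index = bi, correction = correction),
            class = "frap_norm")
}

#' Fit an exponential recovery to a normalized FRAP trace
#'
#' Fits `F(t) = c + a * (1 - exp(-(t - t0) / tau_rec))` to the post-bleach
#' points of a normalized trace and reports the mobile fraction
#' `Mf = a / (1 - c)`. The floor `c` is a nuisance parameter: the
#' normalization anchors the first post-bleach point at exactly zero, so its
#' shot noise would otherwise propagate one-for-one into `Mf`; fitting the
#' floor from all post-bleach points removes that variance (for a noiseless
#' trace `c = 0` and `Mf = a`). The half-time is `t_half = tau_rec * ln 2`
#' and the diffusion coefficient follows from the Axelrod-style relation
#' `D = 0.224 * w^2 / t_half` for a bleach spot of radius `w`.
#'
#' @param norm A `frap_norm` from [normalize_trace()] with >= 10 post-bleach
#'   points.
#' @param w_um Bleach-spot radius in microns.
#' @return An object of class `frap_fit`: list with `mf` (fraction),
#'   `mf_percent`, `tau_rec_s`, `t_half_s`, `d_um2_s`, `w_um`, `vcov`,
#'   `converged`.
#' @export
fit_recovery <- function(norm, w_um) {
  stopifnot(inherits(norm, "frap_norm"))
  assert_that(w_um > 0, "w_um must be > 0")
  d <- norm$data
  bi <- norm$bleach_index
  post <- bi:nrow(d)
  assert_that(length(post) >= 10, "need at least 10 post-bleach points")
  tt <- d$time_s[post] - d$time_s[bi]
  yy <- d$value[post]
  plateau <- mean(tail(yy, max(3L, length(yy) %/% 10L)))
  mf0 <- min(max(plateau, 0.01), 1.2)
  i_half <- which(yy >= plateau / 2)[1]
  tau0 <- max(tt[i_half] / log(2), diff(range(tt)) / 50, 1e-6)
  fit <- try(minpack.lm::nlsLM(yy ~ cc + a * (1 - exp(-tt / tau)),
                               start = list(cc = 0, a = mf0, tau = tau0),
                               lower = c(-0.5, 0, 1e-9),
                               upper = c(0.9, 1.5, Inf),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (!inherits(fit, "try-error")) {
    cf <- stats::coef(fit)
    c_hat <- cf[["cc"]]; a_hat <- cf[["a"]]; tau_hat <- cf[["tau"]]
    vc <- stats::vcov(fit)
  } else {
    # near-singular when the recovery is faster than the sampling interval
    # (tau barely identifiable): profile (c, a) out (closed-form linear
    # least squares for fixed tau) and Brent-search log tau
    dt_min <- min(diff(tt))
    prof <- function(ltau) {
      g <- 1 - exp(-tt / exp(ltau))
      co <- stats::lm.fit(cbind(1, g), yy)$coefficients
      list(c = co[1], a = max(co[2], 0),
           rss = sum((yy - co[1] - max(co[2], 0) * g)^2))
    }
    op <- stats::optimize(function(l) prof(l)$rss,
                          interval = log(c(dt_min / 10, 10 * diff(range(tt)))))
    tau_hat <- exp(op$minimum)
    pr <- prof(op$minimum)
    c_hat <- min(pr$c, 0.9); a_hat <- pr$a
    vc <- NULL
  }
  mf_hat <- min(max(a_hat / (1 - c_hat), 0), 1.5)
  t_half <- tau_hat * log(2)
  structure(list(mf = mf_hat, mf_percent = 100 * mf_hat,
                 tau_rec_s = tau_hat, t_half_s = t_half,
                 d_um2_s = 0.224 * w_um^2 / t_half, w_um = w_um,
                 vcov = vc, converged = TRUE),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> Mf %.1f%%, t_half %.1f s, D %.2e um^2/s (w = %.2f um)\n",
              x$mf_percent, x$t_half_s, x$d_um2_s, x$w_um))
  invisible(x)
}

#' Gaussian fit of a membrane cross-section profile
#'
#' Fits `I(x) = A * exp(-(x - c)^2 / (2 s^2)) + o` to an intensity profile
#' across the membrane. Comparing the fitted amplitudes of a bleached and a
#' non-bleached section quantifies replenishment versus scan bleaching.
#'
#' @param distance_um Position along the profile, microns (should span both
#'   sides of the membrane peak).
#' @param intensity Intensity values, same length.
#' @return An object of class `cross_section_fit`: list with `amplitude`,
#'   `center_um`, `width_um`, `offset`, `converged`.
#' @export
fit_cross_section <- function(distance_um, intensity) {
  assert_that(length(distance_um) == length(intensity), "lengths differ")
  assert_that(length(distance_um) >= 5, "need at least 5 profile points")
  if (stats::sd(intensity) < 1e-12 * max(1, abs(mean(intensity))))
    stopf("flat profile: no peak to fit")
  o0 <- min(intensity)
  a0 <- max(intensity) - o0
  c0 <- distance_um[which.max(intensity)]
  # moment-based width estimate of the background-subtracted peak
  w <- pmax(intensity - o0, 0)
  s_mom <- sqrt(sum(w * (distance_um - c0)^2) / sum(w))
  s_mom <- min(max(s_mom, 1e-3), diff(range(distance_um)))
  fit <- NULL
  for (fac in c(1, 0.5, 2, 0.25, 4)) {
    fit <- try(minpack.lm::nlsLM(
      intensity ~ a * exp(-(distance_um - cc)^2 / (2 * s^2)) + o,
      start = list(a = a0, cc = c0, s = fac * s_mom, o = o0),
      lower = c(0, -Inf, 1e-9, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(fit, "try-error")) break
  }
  if (inherits(fit, "try-error")) stopf("cross-section fit did not converge")
  cf <- stats::coef(fit)
  structure(list(amplitude = cf[["a"]], center_um = cf[["cc"]],
                 width_um = abs(cf[["s"]]), offset = cf[["o"]],
                 converged = TRUE),
            class = "cross_section_fit")
}

#' Amplitude ratio of two cross-section fits
#'
#' @param fit_num,fit_den `cross_section_fit` objects (e.g. post- and
#'   pre-bleach).
#' @return `fit_num$amplitude / fit_den$amplitude`.
#' @export
cross_section_ratio <- function(fit_num, fit_den) {
  stopifnot(inherits(fit_num, "cross_section_fit"),
            inherits(fit_den, "cross_section_fit"))
  fit_num$amplitude / fit_den$amplitude
}
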