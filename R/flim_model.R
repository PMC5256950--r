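# TCSPC decay model: exponential decays convolved with the IRF and wrapped
# at the laser repetition period.

#' Exponential decay model description
#'
#' @param kind `"mono"` or `"bi"`.
#' @param tau_ps Lifetime(s) in ps; for `"bi"`, `tau_ps[1] < tau_ps[2]`.
#' @param amp Decay amplitude(s), same length as `tau_ps`, >= 0 (counts per
#'   channel at time zero).
#' @param baseline Constant baseline, counts per channel.
#' @param shift_ps Temporal shift of the IRF in ps.
#' @return An object of class `decay_model`.
#' @export
decay_model <- function(kind = c("mono", "bi"), tau_ps, amp, baseline = 0,
                        shift_ps = 0) {
  kind <- match.arg(kind)
  k <- if (kind == "mono") 1L else 2L
  assert_that(length(tau_ps) == k && length(amp) == k,
              "%s model needs %d lifetime(s) and amplitude(s)", kind, k)
  assert_that(all(tau_ps > 0), "lifetimes must be > 0")
  assert_that(all(amp >= 0), "amplitudes must be >= 0")
  if (kind == "bi") assert_that(tau_ps[1] < tau_ps[2], "bi model requires tau1 < tau2")
  structure(list(kind = kind, tau_ps = tau_ps, amp = amp, baseline = baseline,
                 shift_ps = shift_ps),
            class = "decay_model")
}

#' Amplitude-weighted mean lifetime of a decay model
#'
#' @param model A [decay_model()].
#' @return `sum(amp * tau) / sum(amp)` in ps.
#' @export
mean_lifetime <- function(model) {
  sum(model$amp * model$tau_ps) / sum(model$amp)
}

# Periodic steady-state decay profile: probability per channel of a photon
# with lifetime tau, excited by an IRF-shaped pulse train with period
# n_channels * width. Returns a normalized (sum 1) length-n_channels vector.
#
# Gaussian IRF: closed-form wrapped exponentially-modified Gaussian.
# Measured IRF: circular convolution (FFT) of the wrapped exponential with
# the normalized IRF histogram. A delta IRF (irf = NULL) gives the bare
# wrapped exponential.
decay_profile <- function(tau, irf, n_channels, width, shift_ps = 0) {
  tmid <- (seq_len(n_channels) - 0.5) * width
  period <- n_channels * width
  if (is.null(irf)) {
    p <- exp(-tmid / tau)                     # wrapped factor is constant
  } else if (inherits(irf, "nm_irf") && irf$type == "gaussian") {
    mu <- irf$center_ps + shift_ps
    sig <- irf$sigma_ps
    p <- numeric(n_channels)
    kmin <- if (mu - 6 * sig < 0) -1L else 0L   # IRF tail before time zero
    for (k in kmin:ceiling(6 * tau / period)) {
      dt <- tmid + k * period - mu
      z <- (sig / tau - dt / sig) / sqrt(2)
      # EMG density up to a constant: exp(sig^2/(2 tau^2) - dt/tau) erfc(z)
      arg <- sig^2 / (2 * tau^2) - dt / tau
      p <- p + exp(pmin(arg, 700)) * erfc(z)
    }
  } else {
    h <- if (inherits(irf, "nm_irf")) irf$counts else irf / sum(irf)
    assert_that(length(h) == n_channels,
                "measured IRF length (%d) must equal n_channels (%d)",
                length(h), n_channels)
    e <- exp(-tmid / tau)
    p <- Re(stats::fft(stats::fft(e) * stats::fft(h), inverse = TRUE)) / n_channels
    # fractional-channel shift via Fourier phase ramp; the constant +0.5
    # realigns the circular-convolution output (defined on the channel grid)
    # with the midpoint sampling convention of the analytic path
    s <- shift_ps / width + 0.5
    n <- n_channels
    freq <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    p <- Re(stats::fft(stats::fft(p) * exp(-2i * pi * freq * s), inverse = TRUE)) / n
    p <- pmax(p, 0)
  }
  p / sum(p)
}

#' Expected TCSPC histogram for a decay model
#'
#' Convolves the model's exponential component(s) with the IRF, wraps at the
#' repetition period (periodic steady state) and adds the baseline. Component
#' photon totals follow from the decay amplitudes as `amp * tau / width`.
#'
#' @param model A [decay_model()].
#' @param irf An `nm_irf` descriptor, a numeric IRF histogram, or `NULL` for
#'   an ideal delta IRF.
#' @param n_channels Number of time channels.
#' @param channel_width_ps Channel width in ps.
#' @return Numeric vector of expected counts per channel.
#' @export
model_decay <- function(model, irf, n_channels, channel_width_ps) {
  stopifnot(inherits(model, "decay_model"))
  m <- rep(model$baseline, n_channels)
  for (i in seq_along(model$tau_ps)) {
    if (model$amp[i] == 0) next
    ni <- model$amp[i] * model$tau_ps[i] / channel_width_ps
    m <- m + ni * decay_profile(model$tau_ps[i], irf, n_channels,
                                channel_width_ps, model$shift_ps)
  }
  m
}
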