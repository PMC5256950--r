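# Per-pixel TCSPC decay fitting by Poisson maximum likelihood (default) or
# Neyman-weighted least squares, with the quality filters used for lifetime
# imaging.

poisson_deviance <- function(y, m) {
  m <- pmax(m, 1e-12)
  t1 <- ifelse(y > 0, y * log(y / m), 0)
  2 * sum(m - y + t1)
}

neyman_chisq <- function(y, m) sum((y - m)^2 / pmax(y, 1))

# Reduced chi-square of a fitted histogram. Pearson (default) has per-channel
# expectation exactly 1 for Poisson counts; channels with fitted expectation
# below `min_expected` are excluded so the statistic is not dominated by
# empty tail channels. Neyman ((y-m)^2 / max(y,1)) is available for parity
# with common TCSPC acquisition software.
reduced_chisq <- function(y, m, n_par, convention = c("pearson", "neyman"),
                          min_expected = 1) {
  convention <- match.arg(convention)
  use <- m >= min_expected
  dof <- sum(use) - n_par
  if (dof < 1) return(NA_real_)
  if (convention == "pearson") {
    sum((y[use] - m[use])^2 / m[use]) / dof
  } else {
    sum((y[use] - m[use])^2 / pmax(y[use], 1)) / dof
  }
}

# Profiled Poisson log-likelihood pieces for m = nn * p + b: for fixed decay
# profile p (sum 1), the MLE over the photon total nn and baseline b is a
# concave 2-parameter problem solved by a damped Newton iteration (b is
# clamped at 0; with b fixed at 0 the MLE is nn = sum(y) exactly).
profile_amplitude <- function(y, p, fit_baseline, b0 = 0.01) {
  n <- sum(y)
  nch <- length(y)
  pos <- y > 0
  yp <- y[pos]; pp <- p[pos]
  if (!fit_baseline) {
    m <- n * p
    return(list(nn = n, b = 0, m = m,
                loglik = sum(yp * log(m[pos])) - n))
  }
  b <- b0
  nn <- max(n - b * nch, 1e-6)
  for (it in 1:40) {
    m <- nn * pp + b
    r <- yp / m
    g1 <- sum(r * pp) - 1
    g2 <- sum(r) - nch
    w <- yp / m^2
    h11 <- -sum(w * pp^2)
    h12 <- -sum(w * pp)
    h22 <- -sum(w)
    det <- h11 * h22 - h12^2
    if (!is.finite(det) || abs(det) < 1e-300) break
    d1 <- -( h22 * g1 - h12 * g2) / det
    d2 <- -(-h12 * g1 + h11 * g2) / det
    step <- 1
    while (nn + step * d1 <= 0) step <- step / 2
    nn <- nn + step * d1
    b <- max(b + step * d2, 0)
    if (b == 0 && g2 < 0) { nn <- n; break }   # baseline pinned at zero
    if (max(abs(g1), abs(g2) / nch) < 1e-10) break
  }
  m <- nn * p + b
  list(nn = nn, b = b, m = m,
       loglik = sum(yp * log(m[pos])) - nn - b * nch)
}

# Moment-based lifetime initialisation: mean arrival time past the IRF
# centre, clamped to a sane range.
tau_moment_init <- function(y, n_channels, width, irf) {
  tmid <- (seq_len(n_channels) - 0.5) * width
  mu <- if (inherits(irf, "nm_irf") && irf$type == "gaussian") irf$center_ps
        else if (!is.null(irf)) {
          h <- if (inherits(irf, "nm_irf")) irf$counts else irf
          sum(tmid * h) / sum(h)
        } else 0
  tbar <- sum(y * tmid) / sum(y) - mu
  min(max(tbar, 0.1 * width), 0.8 * n_channels * width)
}

fit_objective <- function(y, profile_fun, objective) {
  force(y)
  function(m) {
    if (objective == "poisson") poisson_deviance(y, m) else neyman_chisq(y, m)
  }
}

#' Fit one TCSPC pixel histogram
#'
#' Fits a mono- or bi-exponential decay (IRF-convolved, period-wrapped) to a
#' photon arrival-time histogram. The default objective is the Poisson
#' deviance (maximum likelihood for TCSPC counts); Neyman-weighted least
#' squares is available to mirror conventional TCSPC fitting software. No
#' parameter is fixed: lifetimes, amplitudes and baseline are all free (the
#' IRF shift optionally so). With `model = "auto"`, a bi-exponential fit is
#' attempted when the mono fit's reduced chi-square is `>= chi2_max` and kept
#' if it improves it.
#'
#' @param y Integer vector of per-channel counts.
#' @param irf IRF descriptor (see [model_decay()]).
#' @param channel_width_ps Channel width in ps.
#' @param model `"mono"`, `"bi"` or `"auto"`.
#' @param objective `"poisson"` (default) or `"neyman"`.
#' @param fit_baseline Fit a constant baseline (default `TRUE`).
#' @param fit_shift Fit the IRF shift (default `FALSE`).
#' @param chi2_convention Convention for the reported reduced chi-square:
#'   `"pearson"` (default) or `"neyman"`.
#' @param chi2_max Threshold used by the `"auto"` model-selection rule.
#' @return An object of class `pixel_fit`: list with `kind`, `tau_ps`, `amp`,
#'   `baseline`, `shift_ps`, `tau_mean_ps` (amplitude-weighted), `photons`
#'   (total counts), `chi2` (reduced), `objective_value`, `converged`.
#' @export
fit_pixel <- function(y, irf, channel_width_ps, model = "auto",
                      objective = c("poisson", "neyman"),
                      fit_baseline = TRUE, fit_shift = FALSE,
                      chi2_convention = "pearson", chi2_max = 2) {
  objective <- match.arg(objective)
  n_channels <- length(y)
  ntot <- sum(y)
  assert_that(ntot >= 1, "histogram must contain at least one photon")
  fit1 <- fit_decay_kind(y, irf, channel_width_ps, "mono", objective,
                         fit_baseline, fit_shift, chi2_convention)
  out <- fit1
  if (model == "bi" || (model == "auto" && is.finite(fit1$chi2) && fit1$chi2 >= chi2_max)) {
    fit2 <- try(fit_decay_kind(y, irf, channel_width_ps, "bi", objective,
                               fit_baseline, fit_shift, chi2_convention,
                               init_tau = fit1$tau_ps), silent = TRUE)
    if (!inherits(fit2, "try-error") &&
        (model == "bi" || (is.finite(fit2$chi2) && fit2$chi2 < fit1$chi2)))
      out <- fit2
  }
  out
}

# Shared fitting core for one model kind.
fit_decay_kind <- function(y, irf, width, kind, objective, fit_baseline,
                           fit_shift, chi2_convention, init_tau = NULL) {
  n_channels <- length(y)
  ntot <- sum(y)
  tau0 <- init_tau[1] %||% tau_moment_init(y, n_channels, width, irf)
  b0 <- if (fit_baseline) max(mean(sort(y)[seq_len(max(3L, n_channels %/% 20L))]), 1e-3)
        else 0
  a0 <- max(ntot - b0 * n_channels, 1)
  obj_val <- function(m) {
    if (objective == "poisson") poisson_deviance(y, m) else neyman_chisq(y, m)
  }
  if (kind == "mono" && objective == "poisson" && !fit_shift) {
    # fast path: Brent search on log tau with amplitude and baseline
    # profiled out of the Poisson likelihood
    period <- n_channels * width
    nll <- function(ltau) {
      p <- decay_profile(exp(ltau), irf, n_channels, width, 0)
      -profile_amplitude(y, p, fit_baseline, b0)$loglik
    }
    opt <- stats::optimize(nll, interval = log(c(0.5 * width, 1.2 * period)),
                           tol = 1e-5)
    tau <- exp(opt$minimum)
    p <- decay_profile(tau, irf, n_channels, width, 0)
    prof <- profile_amplitude(y, p, fit_baseline, b0)
    m <- prof$m
    n_par <- if (fit_baseline) 3L else 2L
    fit <- list(kind = "mono", tau_ps = tau, amp = prof$nn * width / tau,
                baseline = prof$b, shift_ps = 0, tau_mean_ps = tau,
                photons = ntot,
                chi2 = reduced_chisq(y, m, n_par, chi2_convention),
                objective_value = poisson_deviance(y, m),
                converged = TRUE)
  } else if (kind == "mono") {
    # theta: log tau, log N (decay photons), [log baseline], [shift]
    make_model <- function(theta) {
      tau <- exp(theta[1]); nn <- exp(theta[2])
      b <- if (fit_baseline) exp(theta[3]) else 0
      s <- if (fit_shift) theta[length(theta)] else 0
      nn * decay_profile(tau, irf, n_channels, width, s) + b
    }
    theta0 <- c(log(tau0), log(a0))
    if (fit_baseline) theta0 <- c(theta0, log(b0))
    if (fit_shift) theta0 <- c(theta0, 0)
    n_par <- length(theta0)
    opt <- optim(theta0, function(th) obj_val(make_model(th)),
                 method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
    m <- make_model(opt$par)
    tau <- exp(opt$par[1]); nn <- exp(opt$par[2])
    b <- if (fit_baseline) exp(opt$par[3]) else 0
    s <- if (fit_shift) opt$par[n_par] else 0
    amp <- nn * width / tau
    fit <- list(kind = "mono", tau_ps = tau, amp = amp, baseline = b,
                shift_ps = s, tau_mean_ps = tau, photons = ntot,
                chi2 = reduced_chisq(y, m, n_par, chi2_convention),
                objective_value = opt$value,
                converged = opt$convergence == 0)
  } else {
    # theta: log tau1, log(tau2/tau1 - 1), qlogis(photon fraction tau1),
    #        log N, [log baseline], [shift]
    make_model <- function(theta) {
      tau1 <- exp(theta[1]); tau2 <- tau1 * (1 + exp(theta[2]))
      g <- stats::plogis(theta[3]); nn <- exp(theta[4])
      b <- if (fit_baseline) exp(theta[5]) else 0
      s <- if (fit_shift) theta[length(theta)] else 0
      nn * (g * decay_profile(tau1, irf, n_channels, width, s) +
            (1 - g) * decay_profile(tau2, irf, n_channels, width, s)) + b
    }
    t1 <- tau0 * 0.5; t2 <- tau0 * 1.6
    theta0 <- c(log(t1), log(t2 / t1 - 1), 0, log(a0))
    if (fit_baseline) theta0 <- c(theta0, log(b0))
    if (fit_shift) theta0 <- c(theta0, 0)
    n_par <- length(theta0)
    opt <- optim(theta0, function(th) obj_val(make_model(th)),
                 method = "Nelder-Mead",
                 control = list(maxit = 1500, reltol = 1e-10))
    m <- make_model(opt$par)
    tau1 <- exp(opt$par[1]); tau2 <- tau1 * (1 + exp(opt$par[2]))
    g <- stats::plogis(opt$par[3]); nn <- exp(opt$par[4])
    b <- if (fit_baseline) exp(opt$par[5]) else 0
    s <- if (fit_shift) opt$par[n_par] else 0
    n1 <- g * nn; n2 <- (1 - g) * nn
    amp <- c(n1 * width / tau1, n2 * width / tau2)
    tau_mean <- sum(amp * c(tau1, tau2)) / sum(amp)
    fit <- list(kind = "bi", tau_ps = c(tau1, tau2), amp = amp, baseline = b,
                shift_ps = s, tau_mean_ps = tau_mean, photons = ntot,
                chi2 = reduced_chisq(y, m, n_par, chi2_convention),
                objective_value = opt$value,
                converged = opt$convergence == 0)
  }
  class(fit) <- "pixel_fit"
  fit
}

#' Fit every pixel of a decay cube
#'
#' Applies [fit_pixel()] to each pixel histogram of a [decay_cube()]. Pixels
#' with zero photons are recorded as non-converged with `NA` lifetimes.
#'
#' @param cube A [decay_cube()].
#' @param irf IRF; defaults to the cube's own descriptor.
#' @param ... Passed to [fit_pixel()].
#' @return An object of class `pixel_fits`: list with `fits` (data frame, one
#'   row per pixel: `x`, `y`, `kind`, `tau_mean_ps`, `tau1_ps`, `tau2_ps`,
#'   `photons`, `chi2`, `baseline`, `converged`), `dim`, `channel_width_ps`.
#' @export
fit_cube <- function(cube, irf = NULL, ...) {
  stopifnot(inherits(cube, "decay_cube"))
  irf <- irf %||% cube$irf
  d <- dim(cube$counts)
  nx <- d[1]; ny <- d[2]; nch <- d[3]
  npx <- nx * ny
  counts <- cube$counts
  dim(counts) <- c(npx, nch)
  res <- data.frame(x = rep(seq_len(nx), times = ny),
                    y = rep(seq_len(ny), each = nx),
                    kind = NA_character_, tau_mean_ps = NA_real_,
                    tau1_ps = NA_real_, tau2_ps = NA_real_,
                    photons = as.integer(rowSums(counts)),
                    chi2 = NA_real_, baseline = NA_real_, converged = FALSE)
  for (i in seq_len(npx)) {
    if (res$photons[i] == 0L) next
    f <- try(fit_pixel(counts[i, ], irf, cube$channel_width_ps, ...), silent = TRUE)
    if (inherits(f, "try-error")) next
    res$kind[i] <- f$kind
    res$tau_mean_ps[i] <- f$tau_mean_ps
    res$tau1_ps[i] <- f$tau_ps[1]
    res$tau2_ps[i] <- if (f$kind == "bi") f$tau_ps[2] else NA_real_
    res$chi2[i] <- f$chi2
    res$baseline[i] <- f$baseline
    res$converged[i] <- f$converged
  }
  structure(list(fits = res, dim = c(nx, ny),
                 channel_width_ps = cube$channel_width_ps),
            class = "pixel_fits")
}

#' Apply lifetime-imaging quality filters
#'
#' A pixel is accepted when it converged, has at least `min_photons` photons,
#' reduced chi-square strictly below `chi2_max`, and amplitude-weighted mean
#' lifetime inside `tau_range` (inclusive). The image mean lifetime and its
#' SEM are computed over accepted pixels only.
#'
#' @param fits A `pixel_fits` object from [fit_cube()].
#' @param min_photons Minimum photons per pixel. Default 1200.
#' @param chi2_max Upper bound (strict) on reduced chi-square. Default 2.
#' @param tau_range Accepted lifetime range in ps. Default `c(1500, 2500)`.
#' @return An object of class `lifetime_image`: list with `tau` (matrix, ps;
#'   `NA` where rejected), `accepted` (logical matrix), `photons`, `chi2`
#'   matrices, `mean_tau_ps`, `sem_tau_ps`, `n_accepted`, `n_pixels`, and the
#'   filter settings. If no pixel is accepted the means are `NA` and a
#'   warning is raised.
#' @export
apply_filters <- function(fits, min_photons = 1200, chi2_max = 2,
                          tau_range = c(1500, 2500)) {
  stopifnot(inherits(fits, "pixel_fits"))
  f <- fits$fits
  ok <- f$converged & f$photons >= min_photons &
    is.finite(f$chi2) & f$chi2 < chi2_max &
    is.finite(f$tau_mean_ps) &
    f$tau_mean_ps >= tau_range[1] & f$tau_mean_ps <= tau_range[2]
  nx <- fits$dim[1]; ny <- fits$dim[2]
  tau <- matrix(ifelse(ok, f$tau_mean_ps, NA_real_), nx, ny)
  acc <- matrix(ok, nx, ny)
  photons <- matrix(f$photons, nx, ny)
  chi2 <- matrix(f$chi2, nx, ny)
  n_acc <- sum(ok)
  if (n_acc == 0) warning("no pixel passed the quality filters")
  structure(list(tau = tau, accepted = acc, photons = photons, chi2 = chi2,
                 mean_tau_ps = if (n_acc) mean(tau[acc]) else NA_real_,
                 sem_tau_ps = if (n_acc > 1) sem(tau[acc]) else NA_real_,
                 n_accepted = n_acc, n_pixels = nx * ny,
                 filters = list(min_photons = min_photons, chi2_max = chi2_max,
                                tau_range = tau_range)),
            class = "lifetime_image")
}

#' @export
print.lifetime_image <- function(x, ...) {
  cat(sprintf("<lifetime_image> %d/%d pixels accepted; mean tau %.0f +/- %.1f ps\n",
              x$n_accepted, x$n_pixels, x$mean_tau_ps, x$sem_tau_ps))
  invisible(x)
}
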