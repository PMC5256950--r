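test_that("normalization pins the pre-bleach mean at 1 and first post-bleach at 0", {
  sim <- simulate_frap_trace(frap_sim_params(seed = 1))
  nt <- normalize_trace(sim$trace)
  pre <- seq_len(nt$bleach_index - 1)
  expect_equal(mean(nt$data$value[pre]), 1, tolerance = 1e-12)
  expect_equal(nt$data$value[nt$bleach_index], 0, tolerance = 1e-12)
})

test_that("a bleach ROI sharing the reference's decay normalizes to a flat pre-bleach level", {
  t <- seq(0, 100, by = 1)
  ref <- 800 * exp(-0.002 * t)
  bleach <- ref * c(rep(1, 10), rep(0.3, 91))   # same scan bleach, then a dip
  tr <- frap_trace(t, bleach, ref, rep(0, length(t)), bleach_index = 11L)
  nt <- normalize_trace(tr)
  expect_equal(nt$data$value[1:10], rep(1, 10), tolerance = 1e-9)
  expect_equal(nt$data$value[11:101], rep(0, 91), tolerance = 1e-9)
})

test_that("reference division removes a known scan-bleach decay", {
  sim <- simulate_frap_trace(frap_sim_params(mf = 0, k_scan = 0.004,
                                             noise_sd = 0, seed = 2))
  nt <- normalize_trace(sim$trace)
  post <- nt$bleach_index:nrow(nt$data)
  # an immobile pool: after perfect correction the trace is flat at zero
  slope <- stats::coef(stats::lm(nt$data$value[post] ~ nt$data$time_s[post]))[[2]]
  expect_lt(abs(slope), 1e-3)
})

test_that("normalization is idempotent given a flat reference", {
  sim <- simulate_frap_trace(frap_sim_params(k_scan = 0, noise_sd = 0.01, seed = 3))
  nt <- normalize_trace(sim$trace, correction = "none")
  tr2 <- frap_trace(nt$data$time_s, nt$data$value,
                    rep(1, nrow(nt$data)), rep(0, nrow(nt$data)),
                    nt$bleach_index)
  nt2 <- normalize_trace(tr2, correction = "none")
  expect_equal(nt2$data$value, nt$data$value, tolerance = 1e-12)
})

test_that("a reference that hits the background level aborts with a diagnostic", {
  t <- 0:50
  tr <- frap_trace(t, rep(100, 51), c(rep(50, 40), rep(0, 11)), rep(0, 51), 11L)
  expect_error(normalize_trace(tr), "reference")
})

test_that("a noiseless recovery is fitted to its generating parameters", {
  p <- frap_sim_params(mf = 0.28, d_um2_s = 0.003, w_um = 1, noise_sd = 0,
                       k_scan = 0, seed = 1)
  fit <- fit_recovery(normalize_trace(simulate_frap_trace(p)$trace), w_um = 1)
  expect_equal(fit$mf_percent, 28, tolerance = 0.01)
  expect_equal(fit$d_um2_s, 0.003, tolerance = 0.02)
})

test_that("degenerate recoveries land at the mobile-fraction extremes", {
  p0 <- frap_sim_params(mf = 0, noise_sd = 0.005, seed = 4)
  f0 <- fit_recovery(normalize_trace(simulate_frap_trace(p0)$trace), w_um = 1)
  expect_lt(f0$mf_percent, 3)
  p1 <- frap_sim_params(mf = 1, d_um2_s = 0.05, noise_sd = 0.005, seed = 5)
  f1 <- fit_recovery(normalize_trace(simulate_frap_trace(p1)$trace), w_um = 1)
  expect_equal(f1$mf_percent, 100, tolerance = 0.03)
})

test_that("mobile fraction is recovered across the parameter grid", {
  for (mf in seq(0.1, 0.9, by = 0.2)) {
    for (d in c(0.001, 0.01, 0.1)) {
      errs <- vapply(1:50, function(s) {
        p <- frap_sim_params(mf = mf, d_um2_s = d, noise_sd = 0.02,
                             times = seq(0, 1200, by = 2), bleach_index = 6L,
                             seed = 10000 + 100 * round(1000 * mf) + s)
        fit <- fit_recovery(normalize_trace(simulate_frap_trace(p)$trace),
                            w_um = 1)
        abs(fit$mf - mf)
      }, numeric(1))
      expect_lt(stats::median(errs), 0.03)
    }
  }
})

test_that("the diffusion estimate scales exactly as the spot radius squared", {
  sim <- simulate_frap_trace(frap_sim_params(seed = 6))
  nt <- normalize_trace(sim$trace)
  f1 <- fit_recovery(nt, w_um = 1)
  f2 <- fit_recovery(nt, w_um = 2)
  expect_equal(f2$d_um2_s / f1$d_um2_s, 4, tolerance = 1e-12)
  expect_equal(f1$t_half_s, f2$t_half_s, tolerance = 1e-12)
})

test_that("an exact Gaussian cross-section is recovered to machine precision", {
  x <- seq(-2, 2, by = 0.05)
  y <- 120 * exp(-(x - 0.1)^2 / (2 * 0.3^2)) + 15
  fit <- fit_cross_section(x, y)
  expect_equal(fit$amplitude, 120, tolerance = 1e-8)
  expect_equal(fit$center_um, 0.1, tolerance = 1e-8)
  expect_equal(fit$width_um, 0.3, tolerance = 1e-8)
  expect_equal(fit$offset, 15, tolerance = 1e-8)
})

test_that("cross-section amplitude ratios quantify bleaching", {
  x <- seq(-2, 2, by = 0.05)
  f_pre <- fit_cross_section(x, 100 * exp(-x^2 / 0.18))
  f_post <- fit_cross_section(x, 50 * exp(-x^2 / 0.18))
  expect_equal(cross_section_ratio(f_post, f_pre), 0.5, tolerance = 1e-9)
  expect_error(fit_cross_section(x, rep(3, length(x))), "flat")
})

test_that("noisy cross-section amplitudes are recovered within a few percent", {
  x <- seq(-2, 2, by = 0.04)
  amps <- vapply(1:100, function(s) {
    set.seed(400 + s)
    y <- 100 * exp(-(x + 0.05)^2 / (2 * 0.35^2)) + 10 + rnorm(length(x), 0, 5)
    fit_cross_section(x, y)$amplitude
  }, numeric(1))
  expect_lt(abs(mean(amps) - 100) / 100, 0.03)
})
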