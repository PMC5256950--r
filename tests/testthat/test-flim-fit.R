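w256 <- 25000 / 256

test_that("a noise-free mono histogram is fitted to its generating lifetime", {
  irf <- irf_gaussian()
  mdl <- decay_model("mono", tau_ps = 2000, amp = 1e5 * w256 / 2000)
  m <- model_decay(mdl, irf, 256, w256)
  fit <- fit_pixel(round(m), irf, w256, model = "mono")
  expect_equal(fit$tau_ps, 2000, tolerance = 5e-3)
  expect_true(fit$converged)
  expect_lt(fit$chi2, 0.2)      # essentially no residual on noise-free data
})

test_that("the Poisson-deviance fit is nearly unbiased at high and low counts", {
  tau_hat <- function(photons, reps, seed0) {
    vapply(seq_len(reps), function(s) {
      sim <- simulate_decay_cube(flim_sim_params(dim_px = 1, tau_d_ps = 2402,
                                                 photons_mean = photons,
                                                 photons_min = photons %/% 2,
                                                 seed = seed0 + s))
      fit_pixel(sim$cube$counts[1, 1, ], sim$cube$irf, w256,
                model = "mono")$tau_ps
    }, numeric(1))
  }
  hi <- tau_hat(1e4, 100, 300)
  expect_lt(abs(mean(hi) - 2402) / 2402, 0.01)
  lo <- tau_hat(1200, 100, 700)
  expect_lt(abs(mean(lo) - 2402) / 2402, 0.05)
})

test_that("reduced chi-square of correctly specified fits averages one", {
  sim <- simulate_decay_cube(flim_sim_params(dim_px = c(20, 10), tau_d_ps = 2200,
                                             photons_mean = 3000, seed = 55))
  fits <- fit_cube(sim$cube, model = "mono")
  chi2 <- fits$fits$chi2
  expect_length(chi2, 200)
  expect_lt(abs(mean(chi2) - 1), 0.1)
})

test_that("neyman least squares recovers lifetimes comparably", {
  sim <- simulate_decay_cube(flim_sim_params(dim_px = 2, photons_mean = 5000,
                                             seed = 17))
  # Neyman weighting is biased low at finite counts (its 1/max(y,1) weights
  # overweight the low-count tail); a 10 % envelope covers that known bias
  f <- fit_pixel(sim$cube$counts[1, 1, ], sim$cube$irf, w256,
                 model = "mono", objective = "neyman")
  expect_equal(f$tau_ps, 2402, tolerance = 0.10)
  fn <- fit_pixel(sim$cube$counts[1, 1, ], sim$cube$irf, w256,
                  model = "mono", chi2_convention = "neyman")
  expect_true(is.finite(fn$chi2))
})

test_that("a bi-exponential fit separates two well-spaced lifetimes", {
  p1 <- flim_sim_params(dim_px = 1, tau_d_ps = 1100, photons_mean = 6e4, seed = 5)
  p2 <- flim_sim_params(dim_px = 1, tau_d_ps = 2800, photons_mean = 6e4, seed = 6)
  y <- simulate_decay_cube(p1)$cube$counts[1, 1, ] +
       simulate_decay_cube(p2)$cube$counts[1, 1, ]
  fit <- fit_pixel(y, irf_gaussian(), w256, model = "bi")
  expect_equal(fit$kind, "bi")
  expect_equal(fit$tau_ps[1], 1100, tolerance = 0.10)
  expect_equal(fit$tau_ps[2], 2800, tolerance = 0.10)
  # amplitude-weighted mean lifetime sits between the components
  expect_true(fit$tau_mean_ps > 1100 && fit$tau_mean_ps < 2800)
})

test_that("the baseline is recovered when background photons are present", {
  sim <- simulate_decay_cube(flim_sim_params(dim_px = 1, photons_mean = 2e4,
                                             bg_fraction = 0.2, seed = 23))
  fit <- fit_pixel(sim$cube$counts[1, 1, ], sim$cube$irf, w256, model = "mono")
  # 20 % of 2e4 photons spread over 256 channels ~ 15.6 counts/channel
  expect_equal(fit$baseline, 0.2 * 2e4 / 256, tolerance = 0.15)
  expect_equal(fit$tau_ps, 2402, tolerance = 0.03)
})

test_that("quality filters implement the acceptance boundaries strictly", {
  base <- data.frame(x = 1:4, y = 1L, kind = "mono",
                     tau_mean_ps = c(2000, 2000, 1499.9, 2500),
                     tau1_ps = 2000, tau2_ps = NA_real_,
                     photons = c(1199L, 1200L, 5000L, 5000L),
                     chi2 = c(1, 2, 1, 1.9), baseline = 0, converged = TRUE)
  fits <- structure(list(fits = base, dim = c(4L, 1L), channel_width_ps = w256),
                    class = "pixel_fits")
  img <- apply_filters(fits)
  # 1199 photons: rejected; chi2 == 2 exactly: rejected (strict);
  # tau below 1500: rejected; tau == 2500 exactly: accepted (inclusive range)
  expect_identical(as.vector(img$accepted), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(img$mean_tau_ps, 2500)
})

test_that("donor-only images pass the filters at high rate", {
  sim <- simulate_decay_cube(flim_sim_params(dim_px = 20, tau_d_ps = 2402,
                                             photons_mean = 3000, seed = 41))
  img <- apply_filters(fit_cube(sim$cube, model = "mono"))
  expect_gte(img$n_accepted / img$n_pixels, 0.95)
})

test_that("a pure-baseline histogram is not accepted", {
  set.seed(3)
  y <- rpois(256, 10)
  fit <- fit_pixel(y, irf_gaussian(), w256, model = "mono")
  base <- data.frame(x = 1L, y = 1L, kind = fit$kind,
                     tau_mean_ps = fit$tau_mean_ps, tau1_ps = fit$tau_ps[1],
                     tau2_ps = NA_real_, photons = fit$photons,
                     chi2 = fit$chi2, baseline = fit$baseline,
                     converged = fit$converged)
  fits <- structure(list(fits = base, dim = c(1L, 1L), channel_width_ps = w256),
                    class = "pixel_fits")
  expect_warning(img <- apply_filters(fits), "no pixel passed")
  expect_equal(img$n_accepted, 0)
  expect_true(is.na(img$mean_tau_ps))
})

test_that("fitting a cube returns one row per pixel and flags empty pixels", {
  sim <- simulate_decay_cube(flim_sim_params(dim_px = 4, photons_mean = 500,
                                             seed = 2))
  cube <- sim$cube
  cube$counts[1, 1, ] <- 0L
  fits <- fit_cube(cube, model = "mono")
  expect_equal(nrow(fits$fits), 16)
  expect_false(fits$fits$converged[1])
  expect_true(all(fits$fits$converged[-1]))
})
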