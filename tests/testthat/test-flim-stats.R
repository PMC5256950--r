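make_image <- function(tau, accepted = NULL, photons = NULL) {
  nx <- nrow(tau); ny <- ncol(tau)
  accepted <- accepted %||% is.finite(tau)
  photons <- photons %||% matrix(3000, nx, ny)
  tau_m <- ifelse(accepted, tau, NA_real_)
  structure(list(tau = tau_m, accepted = accepted, photons = photons,
                 chi2 = matrix(1, nx, ny),
                 mean_tau_ps = mean(tau_m[accepted]),
                 sem_tau_ps = NA_real_,
                 n_accepted = sum(accepted), n_pixels = nx * ny,
                 filters = list()),
            class = "lifetime_image")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("FRET efficiency reproduces the published values", {
  # donor+acceptor 2227 ps vs donor-only 2402 ps: 7 %
  expect_equal(fret_efficiency(2227, 2402), 1 - 2227 / 2402)
  expect_equal(fret_efficiency(2227, 2402, percent = TRUE), 7)
  expect_equal(fret_efficiency(2241, 2402, percent = TRUE), 7)
  expect_equal(fret_efficiency(2402, 2402), 0)
  expect_equal(fret_efficiency(1201, 2402), 0.5)
  expect_warning(e <- fret_efficiency(2500, 2402), "no FRET")
  expect_lt(e, 0)
})

test_that("FRET efficiency increases strictly as the quenched lifetime drops", {
  taus <- seq(2400, 200, by = -100)
  e <- fret_efficiency(taus, 2402)
  expect_true(all(diff(e) > 0))
})

test_that("IPS hits its trivial extremes", {
  img_d <- make_image(matrix(2402, 10, 10))
  expect_equal(ips_fraction(img_d, 2402)$ips_percent, 0)
  img_half <- make_image(matrix(1201, 10, 10))
  expect_equal(ips_fraction(img_half, 2402)$ips_percent, 100)
  r <- ips_fraction(img_d, 2402)
  expect_equal(r$tau_threshold_ps, 2402 * 0.87)
})

test_that("IPS is invariant to pixel permutation and photon-preserving rescaling", {
  set.seed(9)
  tau <- matrix(sample(c(1900, 2402), 144, replace = TRUE, prob = c(0.2, 0.8)),
                12, 12)
  img <- make_image(tau)
  ips0 <- ips_fraction(img, 2402)$ips_percent
  perm <- sample(144)
  img_p <- make_image(matrix(tau[perm], 12, 12))
  expect_equal(ips_fraction(img_p, 2402)$ips_percent, ips0)
  # intensity rescaling that preserves photon counts: lifetime map unchanged
  img_r <- img
  img_r$photons <- img$photons     # photon counts preserved by construction
  expect_equal(ips_fraction(img_r, 2402)$ips_percent, ips0)
})

test_that("IPS denominator switch and empty images are handled", {
  tau <- matrix(NA_real_, 4, 4)
  tau[1:2, 1] <- 1900
  tau[3:4, 1] <- 2402
  acc <- is.finite(tau)
  img <- make_image(tau, accepted = acc)
  expect_equal(ips_fraction(img, 2402)$ips_percent, 50)
  expect_equal(ips_fraction(img, 2402, denominator = "all")$ips_percent,
               100 * 2 / 16)
  none <- make_image(matrix(NA_real_, 3, 3), accepted = matrix(FALSE, 3, 3))
  expect_warning(r <- ips_fraction(none, 2402), "undefined")
  expect_true(is.na(r$ips_percent))
})

test_that("cluster lifetime distributions pool bright clusters only", {
  tau <- matrix(2400, 16, 16)
  photons <- matrix(500, 16, 16)
  # two bright clusters with distinct lifetimes, one dim cluster
  tau[3:4, 3:4] <- 2000; photons[3:4, 3:4] <- 2500
  tau[10:12, 10:11] <- 2350; photons[10:12, 10:11] <- 3000
  tau[14:15, 2:3] <- 1700; photons[14:15, 2:3] <- 1500   # below threshold
  img <- make_image(tau, photons = photons)
  d <- cluster_lifetime_distribution(img, photons, min_photons = 2000)
  expect_equal(nrow(d), 2)
  expect_setequal(round(d$tau_mean_ps), c(2000, 2350))
  # nothing above threshold: empty result
  d0 <- cluster_lifetime_distribution(img, matrix(100, 16, 16),
                                      min_photons = 2000)
  expect_equal(nrow(d0), 0)
})

test_that("a mixture image produces a bimodal per-cluster lifetime distribution", {
  sim <- simulate_decay_cube(flim_sim_params(dim_px = 24, f_int = 0.5,
                                             fret_int = 0.25,
                                             photons_mean = 4000, seed = 61))
  img <- apply_filters(fit_cube(sim$cube, model = "mono"))
  # every pixel is its own "cluster": distribution separates the two states
  taus <- img$tau[img$accepted]
  lab <- sim$truth$interacting[img$accepted]
  expect_gt(mean(taus[!lab]) - mean(taus[lab]), 400)
  expect_lt(abs(mean(taus[lab]) - 2402 * 0.75), 60)
  expect_lt(abs(mean(taus[!lab]) - 2402), 40)
})

test_that("lifetime images of two conditions can be compared", {
  a <- make_image(matrix(2402 + rnorm(100, 0, 30), 10, 10))
  b <- make_image(matrix(2200 + rnorm(100, 0, 30), 10, 10))
  ht <- compare_lifetimes(a, b)
  expect_lt(ht$p.value, 1e-6)
})
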