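test_that("normalization makes the spectrum a unit-mass log-tau density", {
  g <- lifetime_grid(100, 1000, 10)
  a <- numeric(10); a[4] <- 7
  n1 <- normalize_spectrum(amplitude_spectrum(g, a))
  expect_equal(n1$alphas[4], 1 / g$delta)
  set.seed(2)
  n2 <- normalize_spectrum(amplitude_spectrum(g, runif(10)))
  expect_equal(sum(n2$alphas) * g$delta, 1, tolerance = 1e-12)
  n3 <- normalize_spectrum(amplitude_spectrum(g, rep(3, 10)))
  expect_equal(n3$alphas, rep(1 / (10 * g$delta), 10))
  expect_error(normalize_spectrum(amplitude_spectrum(g, numeric(10))),
               "mass")
})

test_that("peak segmentation splits well-separated bumps", {
  g <- lifetime_grid(10, 1e5, 300)
  expect_identical(segment_peaks(amplitude_spectrum(g, numeric(300))),
                   list())
  a <- exp(-(g$taus - 100)^2 / (2 * 15^2)) +
    0.5 * exp(-(g$taus - 2000)^2 / (2 * 300^2)) +
    0.2 * exp(-(g$taus - 30000)^2 / (2 * 4000^2))
  regions <- segment_peaks(amplitude_spectrum(g, a))
  expect_length(regions, 3)
  # regions are ordered and disjoint
  for (i in seq_len(2))
    expect_lt(regions[[i]]$k_end, regions[[i + 1]]$k_start)
  expect_error(segment_peaks(amplitude_spectrum(g, a), 2), "0, 1")
})

test_that("peak moments reproduce point-mass and two-point fixtures", {
  g <- lifetime_grid(100, 1000, 10)
  a <- numeric(10); a[6] <- 4
  m <- peak_moments(amplitude_spectrum(g, a),
                    list(k_start = 1, k_end = 10))
  expect_equal(m$mean_tau, g$taus[6])
  expect_equal(m$width, 0)
  expect_equal(m$amp_fraction, 1)

  g2 <- lifetime_grid(100, 200, 2)
  m2 <- peak_moments(amplitude_spectrum(g2, c(1, 1)),
                     list(k_start = 1, k_end = 2))
  expect_equal(m2$mean_tau, 150)
  expect_equal(m2$width, 50)
  expect_equal(m2$rel_width, 1 / 3)

  expect_error(peak_moments(amplitude_spectrum(g, a),
                            list(k_start = 1, k_end = 3)), "mass")
  expect_error(peak_moments(amplitude_spectrum(g, a),
                            list(k_start = 0, k_end = 3)), "region")
})

test_that("a known component count escalates the threshold until it splits", {
  g <- lifetime_grid(10, 1e5, 300)
  # two bumps riding on a plateau higher than the default threshold
  a <- exp(-(log(g$taus) - log(100))^2 / 0.02) +
    0.8 * exp(-(log(g$taus) - log(10000))^2 / 0.02) + 0.005
  sp <- amplitude_spectrum(g, a)
  expect_equal(nrow(peak_table(sp)), 1)           # merged at 1e-3
  tb <- peak_table(sp, n_peaks = 2)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$mean_tau, c(100, 10000), tolerance = 0.05)
  expect_error(peak_table(sp, n_peaks = 7), "segment")
})

test_that("moments are invariant to amplitude rescaling and sum to one", {
  g <- lifetime_grid(10, 1e4, 150)
  set.seed(8)
  a <- exp(-(log(g$taus) - log(100))^2 / 0.05) +
    0.3 * exp(-(log(g$taus) - log(3000))^2 / 0.02)
  sp1 <- amplitude_spectrum(g, a)
  sp2 <- amplitude_spectrum(g, 137.5 * a)
  t1 <- peak_table(sp1)
  t2 <- peak_table(sp2)
  expect_equal(t1$mean_tau, t2$mean_tau)
  expect_equal(t1$amp_fraction, t2$amp_fraction)
  expect_equal(t1$width, t2$width)
  # regions jointly carry all mass above threshold ~ fractions sum to 1
  expect_equal(sum(t1$amp_fraction), 1, tolerance = 1e-3)
})

test_that("weighted width tracks the Gaussian sigma on a fine grid", {
  g <- lifetime_grid(40, 1e5, 400)
  # the Eq.-19 weights live on a log grid, so the moment width of a
  # Gaussian band carries an O((sigma/center)^2) inflation from the
  # 1/tau point-density tilt: exact for narrow bands, ~10% at
  # sigma/center = 0.3 (which is why band widths are estimated by
  # profile fitting, not moments)
  tol <- c(`500` = 0.02, `1000` = 0.035, `1500` = 0.12)
  for (w in c(500, 1000, 1500)) {
    sp <- gaussian_alpha_spectrum(5000, w, g)
    m <- peak_table(sp)
    m <- m[which.max(m$amp_fraction), ]
    expect_equal(m$width, w, tolerance = tol[[as.character(w)]])
  }
})

test_that("replicate dispersion matches hand-computed standard deviations", {
  tb <- function(mt, af, w) data.frame(k_start = 1, k_end = 2, n = 2,
                                       mean_tau = mt, amp_fraction = af,
                                       width = w, rel_width = w / mt)
  same <- replicate_dispersion(list(tb(100, 0.5, 10), tb(100, 0.5, 10)))
  expect_equal(same$amp_fraction_sd, 0)
  expect_equal(same$mean_tau_sd, 0)
  two <- replicate_dispersion(list(tb(100, 0.3, 10), tb(100, 0.4, 10)))
  expect_equal(two$amp_fraction_sd, sd(c(0.3, 0.4)))
  expect_equal(two$amp_fraction_sd, 0.0707, tolerance = 1e-3)
  bad <- list(tb(100, 0.5, 10), rbind(tb(100, 0.4, 10), tb(900, 0.1, 5)))
  expect_error(replicate_dispersion(bad), "disagree")
})

test_that("Gaussian profile fits recover noiseless self-generated curves", {
  g <- lifetime_grid(40, 1e5, 400)
  sp <- gaussian_alpha_spectrum(5000, 500, g, height = 2)
  f1 <- fit_gaussian_profile(sp, 1)
  expect_equal(f1$components$center, 5000, tolerance = 1e-6)
  expect_equal(f1$components$width, 500, tolerance = 1e-6)
  expect_equal(f1$components$amplitude, 2, tolerance = 1e-6)

  # 1:4 height bi-Gaussian mixture, both recovered within 1%
  a2 <- exp(-(g$taus - 1000)^2 / (2 * 300^2)) +
    4 * exp(-(g$taus - 6000)^2 / (2 * 1200^2))
  f2 <- fit_gaussian_profile(amplitude_spectrum(g, a2), 2)
  expect_equal(f2$components$center, c(1000, 6000), tolerance = 0.01)
  expect_equal(f2$components$width, c(300, 1200), tolerance = 0.01)
  expect_equal(f2$components$amplitude, c(1, 4), tolerance = 0.01)

  # idempotence: refitting the fitted curve returns the same parameters
  refit <- fit_gaussian_profile(
    amplitude_spectrum(g, f2$fitted), 2)
  expect_equal(refit$components, f2$components, tolerance = 1e-4)
  expect_error(fit_gaussian_profile(sp, 3), "1 or 2")
})
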