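test_that("Gaussian IRF has the stated width and unit sum", {
  ax <- time_axis(1000, 1000)   # 1 ps channels: half-maximum points on-grid
  irf <- gaussian_irf(ax, fwhm = 120, t0 = 500)
  expect_equal(sum(irf$values), 1, tolerance = 1e-12)
  peak <- irf$values[ax$times == 500]
  expect_equal(irf$values[ax$times == 560], peak / 2, tolerance = 1e-9)
  expect_equal(irf$values[ax$times == 440], peak / 2, tolerance = 1e-9)
  # sigma = fwhm / (2 sqrt(2 log 2)) ~ 51 ps governs the curvature
  sig <- 120 / (2 * sqrt(2 * log(2)))
  expect_equal(sig, 50.96, tolerance = 1e-4)
  expect_error(gaussian_irf(ax, 120, t0 = 2000), "inside")
  expect_error(gaussian_irf(ax, -5), "positive")
})

test_that("distributions are realized on the grid with conserved weight", {
  g <- lifetime_grid(100, 10000, 200)
  # discrete line sitting exactly on a grid lifetime
  d1 <- distribution_spec(1, g$taus[57])
  r1 <- realize_distribution(d1, g)
  expect_equal(sum(r1$alphas > 0), 1)
  expect_equal(which(r1$alphas > 0), 57L)
  expect_equal(sum(r1$alphas), 1)
  # two discrete lines keep their 10:1 weight ratio
  d2 <- distribution_spec(c(10, 1), c(300, 3000))
  r2 <- realize_distribution(d2, g)
  w <- sort(r2$alphas[r2$alphas > 0], decreasing = TRUE)
  expect_equal(w[1] / w[2], 10)
  # Gaussian band: realized mean lifetime near the center
  d3 <- distribution_spec(1, 3000, 300)
  r3 <- realize_distribution(d3, g)
  m <- sum(r3$alphas * g$taus) / sum(r3$alphas)
  expect_lt(abs(m - 3000), g$delta * 3000 + 3000 * 0.011)
  expect_error(realize_distribution(distribution_spec(1, 5), g), "range")
})

test_that("simulation is seed-reproducible and leaves the RNG alone", {
  spec <- simulation_spec(distribution_spec(1, 3000), M = 256,
                          total_span = 10000, peak_counts = 1000,
                          seed = 77)
  s1 <- simulate_decay(spec)
  s2 <- simulate_decay(spec)
  expect_identical(s1$trace$counts, s2$trace$counts)
  spec$seed <- 78L
  expect_false(identical(simulate_decay(spec)$trace$counts,
                         s1$trace$counts))
  set.seed(123); u1 <- runif(1)
  set.seed(123); invisible(simulate_decay(spec)); u2 <- runif(1)
  expect_identical(u1, u2)
})

test_that("the noiseless curve is deterministic and scales with peak counts", {
  d <- distribution_spec(c(0.5, 0.5), c(500, 3000))
  s1 <- simulate_decay(simulation_spec(d, M = 256, total_span = 10000,
                                       peak_counts = 1000, seed = 1))
  s2 <- simulate_decay(simulation_spec(d, M = 256, total_span = 10000,
                                       peak_counts = 1000, seed = 9))
  expect_identical(s1$noiseless, s2$noiseless)
  s3 <- simulate_decay(simulation_spec(d, M = 256, total_span = 10000,
                                       peak_counts = 2000, seed = 1))
  expect_equal(s3$noiseless, 2 * s1$noiseless, tolerance = 1e-12)
  expect_equal(max(s1$noiseless), 1000)
  # realized peak count is close to the target
  expect_lt(abs(max(s1$trace$counts) - 1000), 4 * sqrt(1000))
})

test_that("channel counts behave like Poisson draws across replicates", {
  spec <- simulation_spec(distribution_spec(1, 2000), M = 64,
                          total_span = 6000, peak_counts = 400, seed = 5)
  reps <- replicate_decays(spec, 200)
  counts <- sapply(reps, function(s) s$trace$counts)
  mu <- reps[[1]]$noiseless
  informative <- which(mu > 20)
  vm <- apply(counts[informative, ], 1, var) / mu[informative]
  # variance/mean ~ 1 within sampling error of 200 replicates
  expect_true(all(abs(vm - 1) < 4 * sqrt(2 / 199)))
  # replicate mean tracks the noiseless model within 3 standard errors
  se <- sqrt(mu[informative] / 200)
  dev <- abs(rowMeans(counts[informative, ]) - mu[informative])
  expect_lt(mean(dev > 3 * se), 0.02)
})

test_that("replicate sets use consecutive seeds", {
  spec <- simulation_spec(distribution_spec(1, 2000), M = 64,
                          total_span = 6000, peak_counts = 300, seed = 30)
  reps <- replicate_decays(spec, 3)
  expect_identical(reps[[1]]$trace$counts, simulate_decay(spec)$trace$counts)
  spec$seed <- 31L
  expect_identical(reps[[2]]$trace$counts, simulate_decay(spec)$trace$counts)
  expect_false(identical(reps[[2]]$trace$counts, reps[[3]]$trace$counts))
  expect_error(replicate_decays(spec, 0), ">= 1")
})

test_that("distribution and simulation specs validate", {
  expect_error(distribution_spec(numeric(0), numeric(0)), "length")
  expect_error(distribution_spec(-1, 100), "positive")
  expect_error(distribution_spec(1, -100), "positive")
  expect_error(distribution_spec(1, 100, -5), "nonnegative")
  expect_error(simulation_spec(distribution_spec(1, 100), peak_counts = 0),
               "peak_counts")
  expect_identical(distribution_spec(1, 100)$kind, "discrete")
  expect_identical(distribution_spec(1, 100, 10)$kind, "gaussian-mixture")
})
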