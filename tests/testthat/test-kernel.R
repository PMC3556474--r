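test_that("delta-flash IRF reduces the kernel to pure exponentials", {
  ax <- time_axis(1000, 64)
  irf <- instrument_response(ax, c(1, rep(0, 63)))
  g <- lifetime_grid(50, 500, 5)
  K <- convolution_kernel(irf, g)
  for (k in seq_len(5))
    expect_equal(K$matrix[, k], exp(-ax$times / g$taus[k]),
                 tolerance = 1e-12)
})

test_that("very long lifetimes make kernel columns the IRF running sum", {
  ax <- time_axis(500, 32)
  set.seed(4)
  irf <- instrument_response(ax, runif(32))
  g <- lifetime_grid(10, 1e9, 3)
  K <- convolution_kernel(irf, g)
  expect_equal(K$matrix[, 3], cumsum(irf$values), tolerance = 1e-6)
})

test_that("recursive kernel equals the brute-force double sum", {
  ax <- time_axis(400, 8)
  set.seed(11)
  irf <- instrument_response(ax, runif(8))
  g <- lifetime_grid(30, 300, 3)
  K <- convolution_kernel(irf, g)
  expect_equal(K$matrix, brute_force_kernel(irf, g), tolerance = 1e-12)
})

test_that("kernel is causal: entries never exceed the IRF running sum", {
  p <- tiny_problem(seed = 3, M = 48)
  bound <- cumsum(p$irf$values)
  for (k in seq_len(p$grid$N))
    expect_true(all(p$kernel$matrix[, k] <= bound * (1 + 1e-12)))
  expect_true(all(p$kernel$matrix >= 0))
})

test_that("model counts are exactly linear in the amplitudes", {
  p <- tiny_problem(seed = 5)
  expect_equal(model_counts(p$kernel, numeric(p$grid$N)),
               numeric(p$axis$M))
  a1 <- runif(p$grid$N)
  a2 <- runif(p$grid$N)
  expect_equal(model_counts(p$kernel, 2.5 * a1 - 0.5 * a2),
               2.5 * model_counts(p$kernel, a1) -
                 0.5 * model_counts(p$kernel, a2),
               tolerance = 1e-14)
  # against the direct double sum over channels and lifetimes
  direct <- sapply(seq_len(p$axis$M), function(m)
    sum(sapply(seq_len(p$grid$N), function(k)
      a1[k] * sum(p$irf$values[1:m] *
                    exp(-(p$axis$times[m] - p$axis$times[1:m]) /
                          p$grid$taus[k])))))
  expect_equal(model_counts(p$kernel, a1), direct, tolerance = 1e-12)
  expect_error(model_counts(p$kernel, a1[-1]), "grid")
})

test_that("decay traces validate and default to Poisson variances", {
  ax <- time_axis(100, 4)
  tr <- decay_trace(ax, c(0, 5, 2, 0))
  expect_equal(tr$variances, c(1, 5, 2, 1))
  tr2 <- decay_trace(ax, c(0, 5, 2, 0), variances = c(2, 2, 2, 2))
  expect_equal(tr2$variances, rep(2, 4))
  expect_error(decay_trace(ax, c(1, 2, 3)), "length")
  expect_error(decay_trace(ax, c(-1, 2, 3, 4)), "nonnegative")
  expect_error(decay_trace(ax, c(1, 2, 3, 4), variances = c(0, 1, 1, 1)),
               "positive")
})

test_that("instrument responses validate", {
  ax <- time_axis(100, 4)
  expect_error(instrument_response(ax, c(1, 2, 3)), "length")
  expect_error(instrument_response(ax, c(-1, 2, 3, 4)), "nonnegative")
  expect_error(instrument_response(ax, numeric(4)), "zero")
})
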