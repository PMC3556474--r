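test_that("the flat start matches the total intensity by construction", {
  p <- tiny_problem(seed = 9)
  flat <- sum(p$trace$counts) / sum(p$kernel$matrix)
  expect_equal(sum(model_counts(p$kernel, rep(flat, p$grid$N))),
               sum(p$trace$counts))
})

test_that("noiseless single-exponential data is recovered on the grid", {
  ax <- time_axis(12000, 256)
  irf <- instrument_response(ax, c(1, rep(0, 255)))
  g <- lifetime_grid(300, 8000, 40)
  K <- convolution_kernel(irf, g)
  counts <- 2000 * exp(-ax$times / 3000)
  tr <- decay_trace(ax, counts, variances = pmax(counts, 1))
  fit <- mem_fit(tr, kernel = K)
  s <- summary(fit)
  peak <- s$peaks[which.max(s$peaks$amp_fraction), ]
  # mean lifetime within one grid step of the truth
  expect_lt(abs(log(peak$mean_tau / 3000)), g$delta)
  expect_true(all(fit$alphas > 0))
})

test_that("a noisy fit converges into the chi-squared band", {
  p <- tiny_problem(seed = 21, M = 256, span = 8000, N = 24,
                    tau_min = 100, tau_max = 3000, peak = 2000)
  fit <- mem_fit(p$trace, kernel = p$kernel)
  expect_true(fit$converged)
  expect_lt(abs(fit$chi2 - 1), 0.02 + 1e-9)
  expect_true(all(fit$alphas > 0))
  # weighted residuals are consistent with the reported chi2
  expect_equal(mean(residuals(fit)^2), fit$chi2)
  expect_equal(fitted(fit), model_counts(p$kernel, fit$alphas))
  expect_equal(predict(fit), fitted(fit))
  expect_s3_class(summary(fit), "summary.mem_fit")
  expect_named(coef(fit))
  expect_gt(nrow(fit$history), 0)
})

test_that("the solution is invariant under consistent count rescaling", {
  p <- tiny_problem(seed = 33, M = 256, span = 8000, N = 20,
                    tau_min = 100, tau_max = 3000, peak = 3000)
  c0 <- 4
  scaled <- decay_trace(p$axis, c0 * p$trace$counts,
                        variances = c0^2 * p$trace$variances)
  f1 <- mem_fit(p$trace, kernel = p$kernel)
  f2 <- mem_fit(scaled, kernel = p$kernel)
  expect_equal(f2$chi2, f1$chi2, tolerance = 0.02)
  m1 <- peak_table(amplitude_spectrum(p$grid, f1$alphas))
  m2 <- peak_table(amplitude_spectrum(p$grid, f2$alphas))
  t1 <- m1$mean_tau[which.max(m1$amp_fraction)]
  t2 <- m2$mean_tau[which.max(m2$amp_fraction)]
  expect_lt(abs(log(t2 / t1)), p$grid$delta)
})

test_that("an exhausted iteration budget is reported, not hidden", {
  p <- tiny_problem(seed = 40, M = 128, N = 12, peak = 1500)
  fit <- mem_fit(p$trace, kernel = p$kernel,
                 control = mem_control(max_iters = 2L, max_outer = 1L))
  expect_false(fit$converged)
  expect_true(all(fit$alphas > 0))
})

test_that("solver inputs are validated", {
  p <- tiny_problem()
  expect_error(mem_fit(p$trace, p$irf, control = list()), "mem_control")
  other <- time_axis(100, 8)
  tr <- decay_trace(other, rep(1, 8))
  expect_error(mem_fit(tr, kernel = p$kernel), "axis")
  expect_error(mem_control(chi2_tol = -1), "positive")
  expect_error(mem_control(positivity_fraction = 1), "0, 1")
})
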