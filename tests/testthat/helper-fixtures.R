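# small in-code fixtures shared across the suite

# report every expectation, even after several accuracy-study failures
options(testthat.progress.max_fails = 100L)

# tiny random reconvolution problem: M channels, N lifetimes, a smooth
# IRF and a Poisson-noised trace from known amplitudes
tiny_problem <- function(seed = 1, M = 32L, span = 1600, N = 5L,
                         tau_min = 60, tau_max = 900, peak = 400) {
  set.seed(seed)
  axis <- time_axis(span, M)
  irf <- instrument_response(axis, dnorm(axis$times, span / 8, span / 20))
  grid <- lifetime_grid(tau_min, tau_max, N)
  kernel <- convolution_kernel(irf, grid)
  alphas <- runif(N, 0.2, 1)
  model <- model_counts(kernel, alphas)
  model <- model * peak / max(model)
  counts <- rpois(M, model)
  list(axis = axis, irf = irf, grid = grid, kernel = kernel,
       alphas_true = alphas * peak / max(model_counts(kernel, alphas)),
       model = model,
       trace = decay_trace(axis, counts, variances = pmax(model, 1)))
}

# direct O(M^2 N) evaluation of the causal reconvolution sum, the
# brute-force oracle for the kernel recursion
brute_force_kernel <- function(irf, grid) {
  t <- irf$axis$times
  M <- irf$axis$M
  C <- matrix(0, M, grid$N)
  for (k in seq_len(grid$N))
    for (m in seq_len(M))
      C[m, k] <- sum(irf$values[1:m] * exp(-(t[m] - t[1:m]) / grid$taus[k]))
  C
}

# spectrum whose amplitude profile is an exact Gaussian in tau
gaussian_alpha_spectrum <- function(center, width, grid, height = 1) {
  amplitude_spectrum(grid, height * exp(-(grid$taus - center)^2 /
                                          (2 * width^2)))
}
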