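lagrangian_value <- function(x, trace, kernel) {
  N <- kernel$grid$N
  a <- x[seq_len(N)]
  -skilling_entropy(a) +
    x[N + 1] * (reduced_chi2(trace, model_counts(kernel, a)) - 1)
}

test_that("gradient components vanish where they must", {
  p <- tiny_problem(seed = 2)
  N <- p$grid$N
  # unit amplitudes, zero multiplier: entropy gradient log(1) = 0
  Fv <- mem_gradient(c(rep(1, N), 0), p$trace, p$kernel)
  expect_equal(Fv[seq_len(N)], rep(0, N))
  # perfect fit: the constraint row reads chi2 - 1 = -1
  a <- runif(N, 0.5, 2)
  perfect <- decay_trace(p$axis, model_counts(p$kernel, a),
                         variances = rep(2, p$axis$M))
  expect_equal(mem_gradient(c(a, 0.3), perfect, p$kernel)[N + 1], -1)
})

test_that("gradient matches central finite differences of the Lagrangian", {
  for (seed in 1:3) {
    p <- tiny_problem(seed = seed)
    N <- p$grid$N
    set.seed(seed + 100)
    x <- c(runif(N, 10, 60), runif(1, 0.2, 2))
    Fv <- mem_gradient(x, p$trace, p$kernel)
    fd <- vapply(seq_len(N + 1), function(i) {
      h <- 1e-6 * max(1, abs(x[i]))
      e <- numeric(N + 1); e[i] <- h
      (lagrangian_value(x + e, p$trace, p$kernel) -
         lagrangian_value(x - e, p$trace, p$kernel)) / (2 * h)
    }, numeric(1))
    expect_equal(Fv, fd, tolerance = 1e-6)
  }
})

test_that("Hessian matches finite differences of the gradient", {
  for (seed in 1:3) {
    p <- tiny_problem(seed = seed)
    N <- p$grid$N
    set.seed(seed + 200)
    x <- c(runif(N, 10, 60), runif(1, 0.2, 2))
    H <- mem_hessian(x, p$trace, p$kernel)
    Hfd <- matrix(0, N + 1, N + 1)
    for (j in seq_len(N + 1)) {
      h <- 1e-5 * max(1, abs(x[j]))
      e <- numeric(N + 1); e[j] <- h
      Hfd[, j] <- (mem_gradient(x + e, p$trace, p$kernel) -
                     mem_gradient(x - e, p$trace, p$kernel)) / (2 * h)
    }
    expect_equal(H, Hfd, tolerance = 1e-5)
  }
})

test_that("Hessian is symmetric with a structural zero corner", {
  for (seed in 4:6) {
    p <- tiny_problem(seed = seed)
    N <- p$grid$N
    set.seed(seed)
    x <- c(runif(N, 5, 80), runif(1, -1, 3))
    H <- mem_hessian(x, p$trace, p$kernel)
    expect_identical(H, t(H))
    expect_identical(H[N + 1, N + 1], 0)
  }
})

test_that("derivatives reject nonpositive amplitudes", {
  p <- tiny_problem()
  x <- c(rep(1, p$grid$N), 1)
  x[2] <- -1
  expect_error(mem_gradient(x, p$trace, p$kernel), "positive")
  expect_error(mem_hessian(x, p$trace, p$kernel), "positive")
})
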