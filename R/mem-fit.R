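#' Fit a lifetime distribution to a decay trace by maximum entropy
#'
#' Recovers the amplitude spectrum \eqn{\alpha(\tau)} that maximizes the
#' Skilling entropy subject to reduced chi-squared ~ 1, given a measured
#' (or simulated) TCSPC decay trace and the instrument response
#' function.  The constrained problem is solved as a root-finding
#' problem on the gradient of the Lagrangian
#' \eqn{\Lambda = -S + \lambda(\chi^2 - 1)} in the augmented variable
#' \eqn{(\alpha_1, ..., \alpha_N, \lambda)} by Newton-Raphson iterations:
#' bordered Hessian assembly, LU solve for the correction, positivity
#' cap, and golden-section backtracking on the merit
#' \eqn{f = \frac12 \|\nabla\Lambda\|^2}.  The iteration starts from the
#' flat spectrum whose model curve carries the same total intensity as
#' the data.
#'
#' @param trace A \code{\link{decay_trace}}.
#' @param irf An \code{\link{instrument_response}} on the same axis
#'   (ignored when \code{kernel} is supplied).
#' @param grid A \code{\link{lifetime_grid}}; default 400 lifetimes
#'   log-spaced on 20 ps - 10 ns, a typical choice for nanosecond-scale
#'   fluorescence.
#' @param control A \code{\link{mem_control}} list of solver options.
#' @param kernel Optionally a precomputed
#'   \code{\link{convolution_kernel}} (reused across replicate fits of
#'   the same IRF and grid).
#' @return An object of class \code{"mem_fit"} with components
#'   \code{alphas} (recovered amplitudes, counts scale), \code{grid},
#'   \code{lambda} (final Lagrange multiplier), \code{chi2} (final
#'   reduced chi-squared), \code{entropy}, \code{converged},
#'   \code{iterations}, \code{history} (per-iteration chi-squared,
#'   merit norm, step length), \code{fitted} (model counts) and
#'   \code{trace}.  Methods: \code{print}, \code{summary} (peak table),
#'   \code{coef}, \code{fitted}, \code{residuals}, \code{predict},
#'   \code{plot}.
#' @examples
#' sim <- simulate_decay(simulation_spec(
#'   distribution = distribution_spec(1, 3000),
#'   M = 512, peak_counts = 5e4, seed = 7))
#' fit <- mem_fit(sim$trace, sim$irf, lifetime_grid(200, 10000, 60))
#' fit$chi2
#' summary(fit)
#' @export
mem_fit <- function(trace, irf, grid = lifetime_grid(20, 1e4, 400),
                    control = mem_control(), kernel = NULL) {
  if (!inherits(trace, "decay_trace"))
    stop("'trace' must be a 'decay_trace'", call. = FALSE)
  if (is.null(kernel)) {
    if (!inherits(irf, "instrument_response"))
      stop("'irf' must be an 'instrument_response'", call. = FALSE)
    if (irf$axis$M != trace$axis$M ||
        abs(irf$axis$channel_width - trace$axis$channel_width) >
          1e-9 * trace$axis$channel_width)
      stop("trace and IRF must share the same time axis", call. = FALSE)
    kernel <- convolution_kernel(irf, grid)
  } else {
    if (!inherits(kernel, "convolution_kernel"))
      stop("'kernel' must be a 'convolution_kernel'", call. = FALSE)
    if (kernel$axis$M != trace$axis$M)
      stop("kernel and trace must share the same time axis", call. = FALSE)
    grid <- kernel$grid
  }
  if (!inherits(control, "mem_control"))
    stop("'control' must come from mem_control()", call. = FALSE)

  sol <- mem_engine(trace, kernel, control)
  structure(list(alphas = sol$alphas, grid = grid, lambda = sol$lambda,
                 chi2 = sol$chi2, entropy = sol$entropy,
                 converged = sol$converged, attainable = sol$attainable,
                 grad_rms = sol$grad_rms, iterations = sol$iterations,
                 history = sol$history, fitted = sol$fitted,
                 trace = trace, control = control, call = match.call()),
            class = "mem_fit")
}

#' @export
print.mem_fit <- function(x, ...) {
  cat("Maximum-entropy lifetime distribution fit\n")
  cat(sprintf("  %d channels, %d lifetimes on [%.3g, %.3g] ps\n",
              x$trace$axis$M, x$grid$N, x$grid$taus[1L],
              x$grid$taus[x$grid$N]))
  cat(sprintf("  reduced chi-squared = %.4f, lambda = %.4g, %d iterations (%s)\n",
              x$chi2, x$lambda, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.mem_fit <- function(object, ...) {
  stats::setNames(object$alphas, sprintf("tau=%.4g", object$grid$taus))
}

#' @export
fitted.mem_fit <- function(object, ...) object$fitted

#' Residuals of a maximum-entropy decay fit
#'
#' @param object A \code{"mem_fit"}.
#' @param type \code{"weighted"} (default): \eqn{(E_m - T_m)/\sigma_m},
#'   the residuals whose mean square is the reduced chi-squared;
#'   \code{"response"}: raw count differences.
#' @param ... Unused.
#' @export
residuals.mem_fit <- function(object, type = c("weighted", "response"), ...) {
  type <- match.arg(type)
  r <- object$trace$counts - object$fitted
  if (type == "weighted") r / sqrt(object$trace$variances) else r
}

#' Predicted model counts from a fitted spectrum
#'
#' Reconvolves the fitted amplitude spectrum with an instrument
#' response.  With no new IRF this returns the fitted counts.
#'
#' @param object A \code{"mem_fit"}.
#' @param irf Optional \code{\link{instrument_response}} on which to
#'   predict the decay.
#' @param ... Unused.
#' @export
predict.mem_fit <- function(object, irf = NULL, ...) {
  if (is.null(irf)) return(object$fitted)
  model_counts(convolution_kernel(irf, object$grid), object$alphas)
}

#' Summarize a maximum-entropy fit as a peak table
#'
#' Normalizes the recovered spectrum, segments it into peaks and
#' reports the moment summaries of each peak: amplitude-weighted mean
#' lifetime, amplitude fraction, width (weighted standard deviation of
#' tau) and relative width r = width / mean.
#'
#' @param object A \code{"mem_fit"}.
#' @param valley_threshold Peak segmentation threshold as a fraction of
#'   the spectrum maximum (see \code{\link{segment_peaks}}).
#' @param ... Unused.
#' @return An object of class \code{"summary.mem_fit"}: list with the
#'   fit's convergence diagnostics and the \code{peaks} data frame.
#' @export
summary.mem_fit <- function(object, valley_threshold = 1e-3, ...) {
  spec <- amplitude_spectrum(object$grid, object$alphas)
  peaks <- peak_table(spec, valley_threshold = valley_threshold)
  structure(list(chi2 = object$chi2, lambda = object$lambda,
                 entropy = object$entropy, converged = object$converged,
                 iterations = object$iterations, peaks = peaks),
            class = "summary.mem_fit")
}

#' @export
print.summary.mem_fit <- function(x, ...) {
  cat(sprintf("MEM fit: chi2 = %.4f, lambda = %.4g, %d iterations (%s)\n",
              x$chi2, x$lambda, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("%d peak(s):\n", nrow(x$peaks)))
  print(format(x$peaks, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Plot a maximum-entropy fit
#'
#' @param x A \code{"mem_fit"}.
#' @param which \code{"spectrum"} for the normalized lifetime
#'   distribution on a log-tau axis, \code{"decay"} for data plus fitted
#'   curve (log counts), \code{"residuals"} for weighted residuals.
#' @param ... Passed to the underlying plot call.
#' @export
plot.mem_fit <- function(x, which = c("spectrum", "decay", "residuals"), ...) {
  which <- match.arg(which)
  if (which == "spectrum") {
    spec <- normalize_spectrum(amplitude_spectrum(x$grid, x$alphas))
    graphics::plot(spec$grid$taus, spec$alphas, type = "l", log = "x",
                   xlab = "lifetime (ps)",
                   ylab = "normalized amplitude density", ...)
  } else if (which == "decay") {
    t <- x$trace$axis$times
    graphics::plot(t, pmax(x$trace$counts, 0.5), type = "p", pch = 16,
                   cex = 0.3, log = "y", xlab = "time (ps)",
                   ylab = "counts", ...)
    graphics::lines(t, pmax(x$fitted, 0.5), col = 2)
  } else {
    graphics::plot(x$trace$axis$times, residuals(x), type = "h",
                   xlab = "time (ps)", ylab = "weighted residual", ...)
    graphics::abline(h = 0, col = 2)
  }
  invisible(x)
}
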