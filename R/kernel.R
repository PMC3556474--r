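#' Instrument response function on a time axis
#'
#' Wraps a vector of nonnegative IRF weights sampled on the channel
#' centers of a \code{\link{time_axis}}.  The IRF enters the forward
#' model only through the causal convolution kernel, so its absolute
#' scale is arbitrary; it is not renormalized here.
#'
#' @param axis A \code{\link{time_axis}}.
#' @param values Nonnegative weights, one per channel; not all zero.
#' @return An object of class \code{"instrument_response"}.
#' @seealso \code{\link{gaussian_irf}} for the synthetic Gaussian IRF.
#' @export
instrument_response <- function(axis, values) {
  stopifnot_time_axis(axis)
  values <- as.numeric(values)
  if (length(values) != axis$M)
    stop("IRF length does not match the time axis", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("IRF values must be finite and nonnegative", call. = FALSE)
  if (all(values == 0))
    stop("IRF must not be identically zero", call. = FALSE)
  structure(list(axis = axis, values = values), class = "instrument_response")
}

#' @export
print.instrument_response <- function(x, ...) {
  cat(sprintf("Instrument response on %d channels; sum = %.6g, peak at %.1f ps\n",
              x$axis$M, sum(x$values), x$axis$times[which.max(x$values)]))
  invisible(x)
}

#' Causal reconvolution kernel
#'
#' Builds the dense M x N matrix C with
#' \deqn{C_{m,k} = \sum_{i \le m} R(t_i)\, e^{-(t_m - t_i)/\tau_k},}
#' the discrete convolution of the instrument response with a unit
#' exponential of lifetime \eqn{\tau_k}, truncated causally (only
#' channels at or before \eqn{t_m} contribute).  The model decay is then
#' the linear map \code{T = C \%*\% alpha}.
#'
#' On a uniform axis the exponential factor depends only on the channel
#' lag, so each column obeys the first-order recursion
#' \code{C[m, k] = q_k * C[m - 1, k] + R[m]} with
#' \code{q_k = exp(-width / tau_k)}; the kernel is built in O(M N) by
#' recursive filtering rather than the O(M^2 N) double sum.
#'
#' @param irf An \code{\link{instrument_response}}.
#' @param grid A \code{\link{lifetime_grid}}.
#' @return An object of class \code{"convolution_kernel"}: list with the
#'   \code{matrix} (M x N), the \code{axis} and the \code{grid}.
#' @examples
#' ax  <- time_axis(1000, 64)
#' irf <- instrument_response(ax, c(1, rep(0, 63)))   # delta flash
#' K   <- convolution_kernel(irf, lifetime_grid(50, 500, 5))
#' # delta IRF: columns are pure exponentials exp(-t / tau_k)
#' max(abs(K$matrix[, 3] - exp(-ax$times / K$grid$taus[3])))
#' @export
convolution_kernel <- function(irf, grid) {
  if (!inherits(irf, "instrument_response"))
    stop("expected an 'instrument_response' object", call. = FALSE)
  stopifnot_lifetime_grid(grid)
  R <- irf$values
  M <- irf$axis$M
  q <- exp(-irf$axis$channel_width / grid$taus)
  C <- matrix(0, M, grid$N)
  for (k in seq_len(grid$N))
    C[, k] <- stats::filter(R, q[k], method = "recursive")
  structure(list(matrix = C, axis = irf$axis, grid = grid),
            class = "convolution_kernel")
}

#' @export
print.convolution_kernel <- function(x, ...) {
  cat(sprintf("Reconvolution kernel: %d channels x %d lifetimes\n",
              x$axis$M, x$grid$N))
  invisible(x)
}

#' Model decay counts from an amplitude spectrum
#'
#' The forward model \code{T_m = sum_k C[m, k] alpha_k}: exactly linear
#' in the amplitudes.
#'
#' @param kernel A \code{\link{convolution_kernel}}.
#' @param alphas Amplitude vector on the kernel's lifetime grid.
#' @return Numeric vector of model counts, length M.
#' @export
model_counts <- function(kernel, alphas) {
  if (!inherits(kernel, "convolution_kernel"))
    stop("expected a 'convolution_kernel' object", call. = FALSE)
  alphas <- as.numeric(alphas)
  if (length(alphas) != kernel$grid$N)
    stop("amplitude vector does not match the kernel's lifetime grid",
         call. = FALSE)
  drop(kernel$matrix %*% alphas)
}

#' Measured decay trace with Poisson variances
#'
#' Packages per-channel photon counts with their variances.  TCSPC
#' counts are Poisson distributed, so by default the variance of a
#' channel is its count, floored at 1 so empty channels keep the
#' chi-squared finite.
#'
#' @param axis A \code{\link{time_axis}}.
#' @param counts Nonnegative counts per channel.
#' @param variances Optional per-channel variances (must be strictly
#'   positive); default \code{pmax(counts, 1)}.
#' @return An object of class \code{"decay_trace"}.
#' @export
decay_trace <- function(axis, counts, variances = NULL) {
  stopifnot_time_axis(axis)
  counts <- as.numeric(counts)
  if (length(counts) != axis$M)
    stop("counts length does not match the time axis", call. = FALSE)
  if (anyNA(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative", call. = FALSE)
  if (is.null(variances)) variances <- pmax(counts, 1)
  variances <- as.numeric(variances)
  if (length(variances) != axis$M || any(!is.finite(variances)) ||
      any(variances <= 0))
    stop("variances must be strictly positive, one per channel", call. = FALSE)
  structure(list(axis = axis, counts = counts, variances = variances),
            class = "decay_trace")
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf("Decay trace: %d channels, %.0f total counts, %.0f at peak (t = %.1f ps)\n",
              x$axis$M, sum(x$counts), max(x$counts),
              x$axis$times[which.max(x$counts)]))
  invisible(x)
}
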