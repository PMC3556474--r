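#' Uniform time axis for a TCSPC record
#'
#' Builds the axis of channel centers on which decay traces, instrument
#' response functions and model curves live.  The origin is the first
#' channel, so the centers are \code{0, w, 2w, ...} with channel width
#' \code{w = total_span / M}; the axis covers \code{[0, total_span)}.
#'
#' @param total_span Total record length in picoseconds (e.g. 25000 for a
#'   25 ns record).
#' @param M Number of channels (at least 2).
#' @return An object of class \code{"time_axis"}: a list with elements
#'   \code{times} (channel centers, ps), \code{channel_width} (ps) and
#'   \code{M}.
#' @examples
#' ax <- time_axis(25000, 4096)
#' ax$channel_width    # 25000 / 4096 ~ 6.1 ps
#' @export
time_axis <- function(total_span, M) {
  if (!is.numeric(total_span) || length(total_span) != 1L || !is.finite(total_span) ||
      total_span <= 0)
    stop("'total_span' must be a single positive number (ps)", call. = FALSE)
  M <- as.integer(M)
  if (length(M) != 1L || is.na(M) || M < 2L)
    stop("'M' must be an integer >= 2", call. = FALSE)
  w <- total_span / M
  structure(list(times = w * (seq_len(M) - 1), channel_width = w, M = M),
            class = "time_axis")
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf("Time axis: %d channels of %.4f ps covering [0, %.1f) ps\n",
              x$M, x$channel_width, x$M * x$channel_width))
  invisible(x)
}

is_time_axis <- function(x) inherits(x, "time_axis")

stopifnot_time_axis <- function(x) {
  if (!is_time_axis(x)) stop("expected a 'time_axis' object", call. = FALSE)
  invisible(x)
}

#' Logarithmically spaced lifetime grid
#'
#' The lifetime axis of the amplitude spectrum: \code{N} lifetimes with a
#' constant ratio between neighbours, i.e. equally spaced in log(tau).
#' The log step \code{delta} (natural log) multiplies the amplitudes in
#' all spectral integrals and moments; being uniform, it cancels in
#' amplitude fractions and mean lifetimes but is kept explicit so
#' normalized spectra have a well defined density scale.
#'
#' @param tau_min,tau_max Grid endpoints in ps, \code{0 < tau_min < tau_max}.
#' @param N Number of grid lifetimes (at least 2).
#' @return An object of class \code{"lifetime_grid"}: list with
#'   \code{taus} (ps), \code{delta} (uniform step in natural log tau)
#'   and \code{N}.
#' @examples
#' g <- lifetime_grid(20, 1e4, 400)
#' range(g$taus)
#' @export
lifetime_grid <- function(tau_min, tau_max, N) {
  if (!is.numeric(tau_min) || !is.numeric(tau_max) ||
      length(tau_min) != 1L || length(tau_max) != 1L ||
      !is.finite(tau_min) || !is.finite(tau_max) ||
      tau_min <= 0 || tau_max <= tau_min)
    stop("need 0 < tau_min < tau_max", call. = FALSE)
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 2L)
    stop("'N' must be an integer >= 2", call. = FALSE)
  lt <- seq(log(tau_min), log(tau_max), length.out = N)
  structure(list(taus = exp(lt), delta = (log(tau_max) - log(tau_min)) / (N - 1),
                 N = N),
            class = "lifetime_grid")
}

#' @export
print.lifetime_grid <- function(x, ...) {
  cat(sprintf("Lifetime grid: %d lifetimes log-spaced on [%.3g, %.3g] ps (dlog = %.5f)\n",
              x$N, x$taus[1L], x$taus[x$N], x$delta))
  invisible(x)
}

is_lifetime_grid <- function(x) inherits(x, "lifetime_grid")

stopifnot_lifetime_grid <- function(x) {
  if (!is_lifetime_grid(x)) stop("expected a 'lifetime_grid' object", call. = FALSE)
  invisible(x)
}
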