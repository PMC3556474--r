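#' Lifetime distribution specification for simulation
#'
#' Describes the ground-truth lifetime distribution of a simulated
#' sample as a mixture of components: discrete exponential lines
#' (width 0) and/or Gaussian bands in tau.  A Gaussian band is defined
#' on the amplitude profile \eqn{\alpha(\tau)} — the log-grid amplitude
#' function in which recovered spectra are plotted and profile-fitted —
#' so component amplitudes are peak heights of that profile: a "10 %
#' secondary peak" has one tenth the height of the main band
#' regardless of its width.
#'
#' @param amplitudes Positive relative peak heights (discrete lines:
#'   the line weights).
#' @param centers Component lifetimes / band centers, ps, positive.
#' @param widths Band standard deviations in ps; 0 for discrete lines
#'   (the default for all components).
#' @return An object of class \code{"distribution_spec"}.
#' @examples
#' distribution_spec(c(0.33, 0.33, 0.33), c(100, 1000, 4000))  # 3 lines
#' distribution_spec(1, 5000, 500)                             # one band
#' @export
distribution_spec <- function(amplitudes, centers, widths = 0) {
  amplitudes <- as.numeric(amplitudes)
  centers <- as.numeric(centers)
  widths <- rep_len(as.numeric(widths), length(amplitudes))
  if (length(amplitudes) == 0L || length(centers) != length(amplitudes))
    stop("'amplitudes' and 'centers' must have equal positive length",
         call. = FALSE)
  if (any(!is.finite(amplitudes)) || any(amplitudes <= 0))
    stop("amplitudes must be positive", call. = FALSE)
  if (any(!is.finite(centers)) || any(centers <= 0))
    stop("centers must be positive lifetimes (ps)", call. = FALSE)
  if (any(!is.finite(widths)) || any(widths < 0))
    stop("widths must be nonnegative (ps)", call. = FALSE)
  structure(list(amplitudes = amplitudes, centers = centers,
                 widths = widths,
                 kind = if (all(widths == 0)) "discrete"
                        else "gaussian-mixture"),
            class = "distribution_spec")
}

#' @export
print.distribution_spec <- function(x, ...) {
  cat(sprintf("Lifetime distribution (%s), %d component(s):\n", x$kind,
              length(x$amplitudes)))
  print(data.frame(amplitude = x$amplitudes, center_ps = x$centers,
                   width_ps = x$widths), row.names = FALSE)
  invisible(x)
}

#' Simulation specification for a synthetic TCSPC measurement
#'
#' Bundles everything that defines one simulated decay: the record
#' geometry, the Gaussian instrument response, the ground-truth lifetime
#' distribution, the target peak count (the noise level of a TCSPC
#' histogram) and the random seed.  Defaults emulate a typical TCSPC
#' setup: 4096 channels over 25 ns and a 120 ps FWHM instrument
#' response placed 500 ps into the record so the full rising edge is
#' recorded.
#'
#' @param distribution A \code{\link{distribution_spec}}.
#' @param total_span Record length, ps.
#' @param M Number of channels.
#' @param fwhm Instrument response full width at half maximum, ps.
#' @param t0 Instrument response center, ps (inside the record).
#' @param peak_counts Target counts in the peak channel (>= 1).
#' @param seed Integer seed for the Poisson noise.
#' @return An object of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(distribution, total_span = 25000, M = 4096,
                            fwhm = 120, t0 = 500, peak_counts = 1e4,
                            seed = 1L) {
  if (!inherits(distribution, "distribution_spec"))
    stop("'distribution' must be a 'distribution_spec'", call. = FALSE)
  if (peak_counts < 1) stop("'peak_counts' must be >= 1", call. = FALSE)
  if (fwhm <= 0) stop("'fwhm' must be positive", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer", call. = FALSE)
  structure(list(distribution = distribution, total_span = total_span,
                 M = as.integer(M), fwhm = fwhm, t0 = t0,
                 peak_counts = peak_counts, seed = seed),
            class = "simulation_spec")
}

#' Gaussian instrument response function
#'
#' \eqn{R(t) \propto \exp\{-(t - t_0)^2 / (2\sigma^2)\}} with
#' \eqn{\sigma = FWHM / (2\sqrt{2\ln 2})}, normalized to unit sum.
#'
#' @param axis A \code{\link{time_axis}}.
#' @param fwhm Full width at half maximum, ps.
#' @param t0 Center, ps; must lie inside the axis span.
#' @return An \code{\link{instrument_response}}.
#' @export
gaussian_irf <- function(axis, fwhm = 120, t0 = 500) {
  stopifnot_time_axis(axis)
  if (fwhm <= 0) stop("'fwhm' must be positive", call. = FALSE)
  span <- axis$M * axis$channel_width
  if (t0 < 0 || t0 >= span)
    stop("'t0' must lie inside the record [0, total_span)", call. = FALSE)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  v <- exp(-(axis$times - t0)^2 / (2 * sig^2))
  instrument_response(axis, v / sum(v))
}

#' Realize a distribution specification on an analysis grid
#'
#' Maps the ground-truth mixture onto a log-spaced
#' \code{\link{lifetime_grid}}: a discrete line puts its weight on the
#' nearest grid lifetime; a Gaussian band contributes
#' \eqn{A_j \exp\{-(\tau_k - c_j)^2/(2\Delta\tau_j^2)\}} at every grid
#' point.  The result is normalized to unit total weight.
#'
#' @param dist A \code{\link{distribution_spec}}.
#' @param grid A \code{\link{lifetime_grid}} covering all component
#'   centers.
#' @return An \code{\link{amplitude_spectrum}} whose amplitudes sum
#'   to 1.
#' @export
realize_distribution <- function(dist, grid) {
  if (!inherits(dist, "distribution_spec"))
    stop("expected a 'distribution_spec'", call. = FALSE)
  stopifnot_lifetime_grid(grid)
  taus <- grid$taus
  if (any(dist$centers < taus[1L] | dist$centers > taus[grid$N]))
    stop("component center outside the lifetime grid range", call. = FALSE)
  a <- numeric(grid$N)
  for (j in seq_along(dist$amplitudes)) {
    if (dist$widths[j] == 0) {
      k <- which.min(abs(log(taus) - log(dist$centers[j])))
      if (abs(log(taus[k]) - log(dist$centers[j])) > grid$delta)
        stop("discrete component not representable on this grid",
             call. = FALSE)
      a[k] <- a[k] + dist$amplitudes[j]
    } else {
      a <- a + dist$amplitudes[j] *
        exp(-(taus - dist$centers[j])^2 / (2 * dist$widths[j]^2))
    }
  }
  amplitude_spectrum(grid, a / sum(a))
}

# Noiseless model decay of a distribution spec on a time axis: each
# generation lifetime contributes its causal IRF reconvolution, built
# by the same first-order recursion as the analysis kernel.  Gaussian
# bands are realized on their own fine linear tau grids (2000 points
# over center +/- 5 sd, truncated at positive tau), deliberately
# distinct from any log-spaced analysis grid.
noiseless_decay <- function(dist, irf) {
  axis <- irf$axis
  taus <- numeric(0)
  wts <- numeric(0)
  for (j in seq_along(dist$amplitudes)) {
    if (dist$widths[j] == 0) {
      taus <- c(taus, dist$centers[j])
      wts <- c(wts, dist$amplitudes[j])
    } else {
      lo <- max(dist$centers[j] - 5 * dist$widths[j],
                dist$widths[j] * 1e-3)
      hi <- dist$centers[j] + 5 * dist$widths[j]
      tg <- seq(lo, hi, length.out = 2000L)
      dt <- tg[2L] - tg[1L]
      taus <- c(taus, tg)
      # the Gaussian band describes the amplitude profile alpha(tau) in
      # which spectra are plotted and fitted (amplitude per log-tau
      # bin); the weight of a linear-grid lifetime carries the 1/tau
      # Jacobian of that convention
      wts <- c(wts, dist$amplitudes[j] * dt *
                 exp(-(tg - dist$centers[j])^2 / (2 * dist$widths[j]^2)) /
                 tg)
    }
  }
  q <- exp(-axis$channel_width / taus)
  T <- numeric(axis$M)
  for (i in seq_along(taus))
    T <- T + wts[i] * as.numeric(stats::filter(irf$values, q[i],
                                               method = "recursive"))
  list(model = T, taus = taus, weights = wts)
}

#' Simulate one synthetic TCSPC decay
#'
#' Builds the Gaussian instrument response, forms the noiseless decay
#' by causal reconvolution of the ground-truth lifetime distribution,
#' rescales it so the peak channel has the target mean count, and draws
#' every channel from a Poisson law with that mean (counts in a TCSPC
#' histogram are Poisson distributed; each channel's count is its
#' variance).  The noiseless curve is deterministic; only the Poisson
#' draw consumes randomness, and the seed makes it reproducible.  The
#' caller's random-number state is preserved.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @return A list of class \code{"tcspc_simulation"}: \code{trace}
#'   (the noisy \code{\link{decay_trace}} with Poisson variances),
#'   \code{irf}, \code{noiseless} (mean counts per channel),
#'   \code{truth} (data frame \code{tau}, \code{weight}: the realized
#'   ground-truth distribution, unit total weight) and the \code{spec}.
#' @export
simulate_decay <- function(spec) {
  if (!inherits(spec, "simulation_spec"))
    stop("expected a 'simulation_spec'", call. = FALSE)
  axis <- time_axis(spec$total_span, spec$M)
  irf <- gaussian_irf(axis, spec$fwhm, spec$t0)
  nl <- noiseless_decay(spec$distribution, irf)
  scale <- spec$peak_counts / max(nl$model)
  mean_counts <- pmax(nl$model * scale, 0)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  counts <- stats::rpois(axis$M, mean_counts)

  # Poisson variance = mean; in a simulation the model mean is known
  # exactly, so it is the variance attached to the trace (floored at 1
  # for empty channels).  Measured data, where only the realized count
  # is available, defaults to var = max(counts, 1) via decay_trace().
  structure(list(trace = decay_trace(axis, counts,
                                     variances = pmax(mean_counts, 1)),
                 irf = irf,
                 noiseless = mean_counts,
                 truth = data.frame(tau = nl$taus,
                                    weight = nl$weights / sum(nl$weights)),
                 spec = spec),
            class = "tcspc_simulation")
}

#' @export
print.tcspc_simulation <- function(x, ...) {
  cat(sprintf("Simulated TCSPC decay (seed %d):\n", x$spec$seed))
  print(x$trace)
  invisible(x)
}

#' Simulate a replicate set of decays
#'
#' n independent noise realizations of the same simulation, with seeds
#' \code{seed, seed + 1, ..., seed + n - 1}: the protocol behind
#' replicate accuracy studies.
#'
#' @param spec A \code{\link{simulation_spec}}; its seed starts the
#'   sequence.
#' @param n_replicates Number of replicates (>= 1).
#' @return A list of \code{"tcspc_simulation"} objects.
#' @export
replicate_decays <- function(spec, n_replicates) {
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("'n_replicates' must be >= 1", call. = FALSE)
  lapply(seq_len(n_replicates) - 1L, function(i) {
    s <- spec
    s$seed <- spec$seed + i
    simulate_decay(s)
  })
}
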