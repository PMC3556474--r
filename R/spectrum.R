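#' Amplitude spectrum on a lifetime grid
#'
#' Pairs a \code{\link{lifetime_grid}} with nonnegative amplitudes; the
#' container passed between the solver and the summary functions.
#'
#' @param grid A \code{\link{lifetime_grid}}.
#' @param alphas Nonnegative amplitudes, one per grid lifetime.
#' @param normalized Logical flag: TRUE when the amplitudes are a
#'   density in log tau integrating to one.
#' @return An object of class \code{"amplitude_spectrum"}.
#' @export
amplitude_spectrum <- function(grid, alphas, normalized = FALSE) {
  stopifnot_lifetime_grid(grid)
  alphas <- as.numeric(alphas)
  if (length(alphas) != grid$N)
    stop("amplitudes do not match the lifetime grid", call. = FALSE)
  if (anyNA(alphas) || any(!is.finite(alphas)) || any(alphas < 0))
    stop("amplitudes must be finite and nonnegative", call. = FALSE)
  structure(list(grid = grid, alphas = alphas, normalized = normalized),
            class = "amplitude_spectrum")
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf("%s amplitude spectrum: %d lifetimes on [%.3g, %.3g] ps, peak at %.4g ps\n",
              if (x$normalized) "Normalized" else "Raw",
              x$grid$N, x$grid$taus[1L], x$grid$taus[x$grid$N],
              x$grid$taus[which.max(x$alphas)]))
  invisible(x)
}

#' @export
as.data.frame.amplitude_spectrum <- function(x, ...) {
  data.frame(tau = x$grid$taus, alpha = x$alphas)
}

#' Normalize a spectrum to unit mass in log tau
#'
#' Divides the amplitudes by \eqn{\sum_k \alpha_k \Delta_k} (with
#' \eqn{\Delta_k} the uniform log-tau step), so the spectrum becomes a
#' density whose integral over log tau is one.
#'
#' @param spectrum An \code{\link{amplitude_spectrum}}.
#' @return The normalized \code{"amplitude_spectrum"}.
#' @export
normalize_spectrum <- function(spectrum) {
  if (!inherits(spectrum, "amplitude_spectrum"))
    stop("expected an 'amplitude_spectrum'", call. = FALSE)
  mass <- sum(spectrum$alphas) * spectrum$grid$delta
  if (mass <= 0)
    stop("cannot normalize a spectrum with no mass", call. = FALSE)
  amplitude_spectrum(spectrum$grid, spectrum$alphas / mass, normalized = TRUE)
}

#' Segment a spectrum into peaks
#'
#' Peaks are maximal contiguous index runs where the amplitude exceeds
#' \code{valley_threshold} times the spectrum maximum; runs are
#' separated by sub-threshold valleys and returned in order of
#' increasing lifetime.  The default threshold (1e-3 of the maximum)
#' separates well-resolved lifetime peaks while ignoring the low-level
#' baseline ripple typical of maximum-entropy spectra.
#'
#' @param spectrum An \code{\link{amplitude_spectrum}}.
#' @param valley_threshold Fraction of the spectrum maximum below which
#'   a grid point is valley, in (0, 1).
#' @return A list of peak regions, each a list with \code{k_start},
#'   \code{k_end} and the member count \code{n}; empty when the
#'   spectrum has no mass.
#' @export
segment_peaks <- function(spectrum, valley_threshold = 1e-3) {
  if (!inherits(spectrum, "amplitude_spectrum"))
    stop("expected an 'amplitude_spectrum'", call. = FALSE)
  if (valley_threshold <= 0 || valley_threshold >= 1)
    stop("'valley_threshold' must lie in (0, 1)", call. = FALSE)
  a <- spectrum$alphas
  top <- max(a)
  if (top <= 0) return(list())
  above <- a > valley_threshold * top
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  lapply(keep, function(i)
    list(k_start = starts[i], k_end = ends[i],
         n = ends[i] - starts[i] + 1L))
}

#' Moment summary of one spectral peak
#'
#' Computes the amplitude-weighted moments of a peak region: mean
#' lifetime \eqn{\langle\tau\rangle = \sum \alpha_k \tau_k \Delta_k /
#' \sum \alpha_k \Delta_k}, amplitude fraction \eqn{\langle\alpha\rangle
#' = \sum_{peak} \alpha_k \Delta_k / \sum_{all} \alpha_k \Delta_k},
#' width \eqn{\Delta\tau} (the amplitude-weighted standard deviation of
#' tau over the region, in linear tau) and relative width
#' \eqn{r = \Delta\tau / \langle\tau\rangle}.
#'
#' @param spectrum An \code{\link{amplitude_spectrum}}.
#' @param region One region from \code{\link{segment_peaks}}, or any
#'   list with \code{k_start} and \code{k_end}.
#' @return A one-row data frame: \code{k_start}, \code{k_end}, \code{n},
#'   \code{mean_tau}, \code{amp_fraction}, \code{width},
#'   \code{rel_width}.
#' @export
peak_moments <- function(spectrum, region) {
  if (!inherits(spectrum, "amplitude_spectrum"))
    stop("expected an 'amplitude_spectrum'", call. = FALSE)
  ks <- as.integer(region$k_start)
  ke <- as.integer(region$k_end)
  if (is.na(ks) || is.na(ke) || ks < 1L || ke > spectrum$grid$N || ks > ke)
    stop("invalid peak region", call. = FALSE)
  idx <- ks:ke
  w <- spectrum$alphas[idx]           # uniform log step cancels in ratios
  tot <- sum(spectrum$alphas)
  if (sum(w) <= 0 || tot <= 0)
    stop("peak region carries no spectral mass", call. = FALSE)
  tau <- spectrum$grid$taus[idx]
  m <- sum(w * tau) / sum(w)
  v <- sum(w * (tau - m)^2) / sum(w)
  width <- sqrt(max(v, 0))
  data.frame(k_start = ks, k_end = ke, n = ke - ks + 1L,
             mean_tau = m, amp_fraction = sum(w) / tot,
             width = width, rel_width = width / m)
}

#' Peak table of a spectrum
#'
#' Convenience wrapper: segments the spectrum and stacks the
#' \code{\link{peak_moments}} of every peak, ordered by lifetime.
#'
#' When the number of components is known by design (a simulated
#' three-exponential decay is read as three peaks), supply
#' \code{n_peaks}: the valley threshold is then escalated geometrically
#' from \code{valley_threshold} until the spectrum segments into
#' exactly that many peaks, which makes the summary robust to the
#' height of the shallow inter-peak plateau left by the entropy
#' regularization.
#'
#' @inheritParams segment_peaks
#' @param n_peaks Optional known number of peaks.
#' @return A data frame with one row per peak (zero rows for an empty
#'   spectrum).
#' @export
peak_table <- function(spectrum, valley_threshold = 1e-3, n_peaks = NULL) {
  if (!is.null(n_peaks)) {
    th <- valley_threshold
    while (th < 0.5) {
      tb <- peak_table(spectrum, th)
      if (nrow(tb) == n_peaks) return(tb)
      th <- th * 1.5
    }
    stop(sprintf("spectrum does not segment into %d peaks at any threshold",
                 n_peaks), call. = FALSE)
  }
  regions <- segment_peaks(spectrum, valley_threshold)
  if (length(regions) == 0L)
    return(data.frame(k_start = integer(0), k_end = integer(0),
                      n = integer(0), mean_tau = numeric(0),
                      amp_fraction = numeric(0), width = numeric(0),
                      rel_width = numeric(0)))
  do.call(rbind, lapply(regions, peak_moments, spectrum = spectrum))
}

#' Across-replicate dispersion of peak summaries
#'
#' Given peak tables from repeated fits of independently simulated
#' decays, matches peaks across replicates (by rank of mean lifetime,
#' which for equal peak counts equals nearest-in-log-tau matching of
#' well separated peaks) and reports the across-replicate mean and
#' sample standard deviation of the mean lifetime, amplitude fraction
#' and width of each peak.
#'
#' @param tables List (length >= 2) of peak tables from
#'   \code{\link{peak_table}}, one per replicate, all with the same
#'   number of peaks.
#' @return A data frame with one row per peak: means and standard
#'   deviations of \code{mean_tau}, \code{amp_fraction} and
#'   \code{width}, plus the replicate count.
#' @export
replicate_dispersion <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need at least two replicate peak tables", call. = FALSE)
  counts <- vapply(tables, nrow, integer(1))
  if (length(unique(counts)) != 1L)
    stop(sprintf(
      "replicates disagree on the number of peaks (counts: %s); cannot align",
      paste(counts, collapse = ", ")), call. = FALSE)
  tables <- lapply(tables, function(tb) tb[order(tb$mean_tau), , drop = FALSE])
  npk <- counts[1L]
  out <- lapply(seq_len(npk), function(j) {
    mt <- vapply(tables, function(tb) tb$mean_tau[j], numeric(1))
    af <- vapply(tables, function(tb) tb$amp_fraction[j], numeric(1))
    wd <- vapply(tables, function(tb) tb$width[j], numeric(1))
    data.frame(peak = j,
               mean_tau = mean(mt), mean_tau_sd = stats::sd(mt),
               amp_fraction = mean(af), amp_fraction_sd = stats::sd(af),
               width = mean(wd), width_sd = stats::sd(wd),
               n_replicates = length(tables))
  })
  do.call(rbind, out)
}

#' Fit a Gaussian (or bi-Gaussian) profile to a spectrum
#'
#' Least-squares fit of a sum of one or two Gaussians in tau,
#' \deqn{\alpha(\tau) = \sum_j A_j \exp\{-(\tau - c_j)^2 / (2 \Delta\tau_j^2)\},}
#' to the values of a (normally normalized) spectrum: the estimator of
#' the center and width of a broad lifetime distribution recovered by
#' MEM.  The fit is performed on the amplitude profile \eqn{\alpha(\tau)}
#' exactly as spectra are plotted, the same convention in which
#' Gaussian bands of \code{\link{distribution_spec}} are defined, so a
#' recovered band is directly comparable with the simulated one.
#' Initial guesses come from the shape of the curve (ranked local
#' maxima, with residual-based placement for shoulder components)
#' unless supplied; the fit is bounded (centers inside the grid, widths
#' between the smallest tau spacing and the grid span) to prevent
#' component collapse, and uses Levenberg-Marquardt least squares.
#'
#' @param spectrum An \code{\link{amplitude_spectrum}}, normally
#'   normalized first (see \code{\link{normalize_spectrum}}).
#' @param n_components 1 or 2 Gaussian components.
#' @param init Optional initialization: data frame with columns
#'   \code{amplitude}, \code{center}, \code{width} and
#'   \code{n_components} rows.
#' @return A list of class \code{"gaussian_profile_fit"}:
#'   \code{components} (data frame, ordered by center, with
#'   \code{amplitude}, \code{center}, \code{width}), \code{rss},
#'   \code{fitted} values and the \code{init} used.
#' @export
fit_gaussian_profile <- function(spectrum, n_components = 1L, init = NULL) {
  if (!inherits(spectrum, "amplitude_spectrum"))
    stop("expected an 'amplitude_spectrum'", call. = FALSE)
  n_components <- as.integer(n_components)
  if (!n_components %in% c(1L, 2L))
    stop("'n_components' must be 1 or 2", call. = FALSE)
  tau <- spectrum$grid$taus
  y <- spectrum$alphas

  if (is.null(init)) init <- init_gaussian_components(tau, y, n_components)
  if (nrow(init) != n_components)
    stop("'init' must have one row per component", call. = FALSE)

  dat <- data.frame(tau = tau, y = y)
  w_lo <- min(diff(tau))
  w_hi <- tau[length(tau)] - tau[1L]
  lower <- rep(c(0, tau[1L], w_lo), each = n_components)
  upper <- rep(c(Inf, tau[length(tau)], w_hi), each = n_components)
  if (n_components == 1L) {
    form <- y ~ A1 * exp(-(tau - c1)^2 / (2 * w1^2))
    start <- list(A1 = init$amplitude[1L], c1 = init$center[1L],
                  w1 = init$width[1L])
  } else {
    form <- y ~ A1 * exp(-(tau - c1)^2 / (2 * w1^2)) +
      A2 * exp(-(tau - c2)^2 / (2 * w2^2))
    start <- list(A1 = init$amplitude[1L], A2 = init$amplitude[2L],
                  c1 = init$center[1L], c2 = init$center[2L],
                  w1 = init$width[1L], w2 = init$width[2L])
    lower <- c(0, 0, tau[1L], tau[1L], w_lo, w_lo)
    upper <- c(Inf, Inf, tau[length(tau)], tau[length(tau)], w_hi, w_hi)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(
        "Gaussian profile fit failed (%s); init: %s; residual norm at init: %.4g",
        conditionMessage(e),
        paste(sprintf("%s=%.4g", names(unlist(start)), unlist(start)),
              collapse = ", "),
        sqrt(sum((y - gaussian_mixture_curve(tau, init))^2))),
        call. = FALSE))
  cf <- stats::coef(fit)
  comp <- data.frame(
    amplitude = cf[grep("^A", names(cf))],
    center = cf[grep("^c", names(cf))],
    width = abs(cf[grep("^w", names(cf))]))
  comp <- comp[order(comp$center), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(components = comp,
                 rss = sum(stats::residuals(fit)^2),
                 fitted = as.numeric(stats::fitted(fit)),
                 init = init),
            class = "gaussian_profile_fit")
}

# Initial Gaussian components from the shape of the density curve:
# local maxima (after light 3-point smoothing) ranked by height, kept
# only if separated from stronger ones by more than a half-width, with
# widths from the half-maximum crossings around each maximum.
init_gaussian_components <- function(tau, y, n_components) {
  if (all(y <= 0))
    stop("cannot initialize Gaussian fit on an empty spectrum",
         call. = FALSE)
  n <- length(y)
  ys <- y
  if (n >= 3L)
    ys <- c(y[1L], (y[-c(1L, 2L)] + y[-c(1L, n)] + y[-c(n - 1L, n)]) / 3,
            y[n])
  is_max <- which(ys >= c(-Inf, ys[-n]) & ys >= c(ys[-1L], Inf) & ys > 0)
  is_max <- is_max[order(ys[is_max], decreasing = TRUE)]

  half_width_at <- function(k) {
    half <- ys[k] / 2
    i <- k
    while (i > 1L && ys[i] > half) i <- i - 1L
    j <- k
    while (j < n && ys[j] > half) j <- j + 1L
    # half width at half maximum -> Gaussian sigma
    max((tau[j] - tau[i]) / 2, min(diff(tau))) / sqrt(2 * log(2))
  }

  picked <- integer(0)
  widths <- numeric(0)
  for (k in is_max) {
    wk <- half_width_at(k)
    if (all(abs(tau[k] - tau[picked]) > pmax(widths, wk))) {
      picked <- c(picked, k)
      widths <- c(widths, wk)
    }
    if (length(picked) == n_components) break
  }
  while (length(picked) < n_components) {
    # shoulder without its own maximum: place the extra component at
    # the largest positive residual left by the ones picked so far
    comp <- data.frame(amplitude = y[picked], center = tau[picked],
                       width = widths)
    res <- y - gaussian_mixture_curve(tau, comp)
    res[picked] <- 0
    k <- which.max(res)
    picked <- c(picked, k)
    widths <- c(widths, half_width_at(k))
  }
  data.frame(amplitude = y[picked], center = tau[picked], width = widths)
}

gaussian_mixture_curve <- function(tau, comp) {
  y <- 0
  for (j in seq_len(nrow(comp)))
    y <- y + comp$amplitude[j] *
      exp(-(tau - comp$center[j])^2 / (2 * comp$width[j]^2))
  y
}

#' @export
print.gaussian_profile_fit <- function(x, ...) {
  cat(sprintf("Gaussian profile fit, %d component(s), rss = %.4g\n",
              nrow(x$components), x$rss))
  print(format(x$components, digits = 4), row.names = FALSE)
  invisible(x)
}
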