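#' Replicate accuracy study: simulate, fit, aggregate
#'
#' The protocol behind replicate accuracy tables: simulate
#' \code{n_replicates} independent Poisson realizations of the same
#' ground-truth lifetime distribution, invert each with
#' \code{\link{mem_fit}} (the reconvolution kernel is built once and
#' shared), summarize each recovered spectrum as a peak table and
#' optionally a Gaussian profile fit, and aggregate means and standard
#' deviations across replicates.  Replicates whose solver does not
#' converge are excluded from the aggregates and counted.
#'
#' @param spec A \code{\link{simulation_spec}}; its seed starts the
#'   replicate seed sequence.
#' @param grid Analysis \code{\link{lifetime_grid}}.
#' @param n_replicates Number of replicates (>= 1).
#' @param control \code{\link{mem_control}} solver options.
#' @param valley_threshold Peak segmentation threshold.
#' @param gaussian_components 0 (skip profile fitting), 1 or 2 Gaussian
#'   components to fit to each normalized spectrum.  The fits are
#'   initialized at the simulated ground-truth component positions and
#'   widths (with heights read off each recovered spectrum), the usual
#'   protocol when benchmarking recovery accuracy against known truth;
#'   supply \code{gaussian_init} to override.
#' @param gaussian_init Optional explicit initialization data frame
#'   (columns \code{amplitude}, \code{center}, \code{width}) passed to
#'   \code{\link{fit_gaussian_profile}} for every replicate.
#' @return An object of class \code{"mem_study"}: list with
#'   \code{fits} (per-replicate \code{"mem_fit"} objects),
#'   \code{peak_tables}, \code{aggregate} (peak-moment means/sds across
#'   converged replicates; NULL if fewer than 2 or peak counts
#'   disagree, with the reason in \code{aggregate_note}),
#'   \code{gaussian} (per-replicate component tables) and
#'   \code{gaussian_aggregate}, \code{n_converged},
#'   \code{n_replicates}, \code{seeds} and the \code{spec} echo.
#' @examples
#' \donttest{
#' spec <- simulation_spec(distribution_spec(1, 3000), M = 1024,
#'                         peak_counts = 5e4, seed = 11)
#' st <- mem_study(spec, lifetime_grid(20, 1e4, 100), n_replicates = 3)
#' st$aggregate
#' }
#' @export
mem_study <- function(spec, grid, n_replicates = 20L,
                      control = mem_control(), valley_threshold = 1e-3,
                      gaussian_components = 0L, gaussian_init = NULL) {
  if (!inherits(spec, "simulation_spec"))
    stop("expected a 'simulation_spec'", call. = FALSE)
  stopifnot_lifetime_grid(grid)
  gaussian_components <- as.integer(gaussian_components)
  if (!gaussian_components %in% 0:2)
    stop("'gaussian_components' must be 0, 1 or 2", call. = FALSE)

  sims <- replicate_decays(spec, n_replicates)
  kernel <- convolution_kernel(sims[[1L]]$irf, grid)
  fits <- lapply(sims, function(s)
    mem_fit(s$trace, kernel = kernel, control = control))
  conv <- vapply(fits, function(f) f$converged, logical(1))

  peak_tables <- lapply(fits, function(f)
    peak_table(amplitude_spectrum(grid, f$alphas), valley_threshold))

  aggregate <- NULL
  note <- NULL
  ok <- which(conv)
  if (length(ok) >= 2L) {
    aggregate <- tryCatch(replicate_dispersion(peak_tables[ok]),
                          error = function(e) {
                            note <<- conditionMessage(e)
                            NULL
                          })
  } else note <- "fewer than two converged replicates"

  gaussian <- NULL
  gaussian_aggregate <- NULL
  if (gaussian_components > 0L) {
    d <- spec$distribution
    truth_init <- is.null(gaussian_init) &&
      length(d$amplitudes) == gaussian_components && all(d$widths > 0)
    gaussian <- lapply(fits, function(f) {
      sp <- normalize_spectrum(amplitude_spectrum(grid, f$alphas))
      init <- gaussian_init
      if (truth_init) {
        heights <- vapply(seq_along(d$centers), function(j)
          max(sp$alphas[abs(grid$taus - d$centers[j]) <=
                          pmax(d$widths[j], 4 * grid$delta * d$centers[j])]),
          numeric(1))
        init <- data.frame(amplitude = pmax(heights, 1e-12),
                           center = d$centers, width = d$widths)
      }
      tryCatch(fit_gaussian_profile(sp, gaussian_components,
                                    init = init)$components,
               error = function(e) NULL)
    })
    good <- which(conv & !vapply(gaussian, is.null, logical(1)))
    if (length(good) >= 2L) {
      comp <- seq_len(gaussian_components)
      gaussian_aggregate <- do.call(rbind, lapply(comp, function(j) {
        A <- vapply(gaussian[good], function(g) g$amplitude[j], numeric(1))
        cc <- vapply(gaussian[good], function(g) g$center[j], numeric(1))
        w <- vapply(gaussian[good], function(g) g$width[j], numeric(1))
        data.frame(component = j,
                   amplitude = mean(A), amplitude_sd = stats::sd(A),
                   center = mean(cc), center_sd = stats::sd(cc),
                   width = mean(w), width_sd = stats::sd(w),
                   n_replicates = length(good))
      }))
    }
  }

  structure(list(fits = fits, peak_tables = peak_tables,
                 aggregate = aggregate, aggregate_note = note,
                 gaussian = gaussian,
                 gaussian_aggregate = gaussian_aggregate,
                 n_converged = sum(conv),
                 n_replicates = length(fits),
                 seeds = spec$seed + seq_len(n_replicates) - 1L,
                 spec = spec, grid = grid),
            class = "mem_study")
}

#' @export
print.mem_study <- function(x, ...) {
  cat(sprintf("MEM replicate study: %d/%d replicates converged (seeds %d..%d)\n",
              x$n_converged, x$n_replicates, x$seeds[1L],
              x$seeds[length(x$seeds)]))
  if (!is.null(x$aggregate)) {
    cat("Peak moments across converged replicates (mean +/- sd):\n")
    print(format(x$aggregate, digits = 4), row.names = FALSE)
  } else if (!is.null(x$aggregate_note)) {
    cat("No peak aggregate:", x$aggregate_note, "\n")
  }
  if (!is.null(x$gaussian_aggregate)) {
    cat("Gaussian profile parameters (mean +/- sd):\n")
    print(format(x$gaussian_aggregate, digits = 4), row.names = FALSE)
  }
  invisible(x)
}
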