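# Plain-text I/O: whitespace/comma-delimited columns, '#' comments, an
# optional header line.  No binary vendor formats.

read_columns <- function(file, expected) {
  if (!file.exists(file))
    stop(sprintf("file not found: %s", file), call. = FALSE)
  dat <- tryCatch(
    utils::read.table(file, header = FALSE, comment.char = "#",
                      sep = "", stringsAsFactors = FALSE),
    error = function(e)
      stop(sprintf("cannot parse %s: %s", file, conditionMessage(e)),
           call. = FALSE))
  # header row of column names?
  if (nrow(dat) > 0 && any(is.na(suppressWarnings(as.numeric(dat[1L, ]))))) {
    nms <- as.character(unlist(dat[1L, ]))
    dat <- dat[-1L, , drop = FALSE]
    names(dat) <- nms
  } else {
    names(dat) <- expected[seq_len(ncol(dat))]
  }
  if (ncol(dat) < length(expected))
    stop(sprintf("%s: expected at least %d columns (%s)", file,
                 length(expected), paste(expected, collapse = ", ")),
         call. = FALSE)
  dat[] <- lapply(dat, function(col) as.numeric(as.character(col)))
  if (anyNA(dat[seq_along(expected)]))
    stop(sprintf("%s: non-numeric values in data columns", file),
         call. = FALSE)
  dat
}

axis_from_times <- function(times, file) {
  M <- length(times)
  if (M < 2L) stop(sprintf("%s: need at least 2 channels", file),
                   call. = FALSE)
  w <- diff(times)
  if (any(w <= 0) || max(abs(w - w[1L])) > 1e-6 * w[1L])
    stop(sprintf("%s: time channels must be uniform and increasing", file),
         call. = FALSE)
  time_axis(mean(w) * M, M)
}

#' Read / write a decay trace file
#'
#' Delimited text with columns \code{time_ps}, \code{counts} and an
#' optional third column \code{sigma} (per-channel standard deviation);
#' without it, variances follow the Poisson rule \code{max(counts, 1)}.
#' Lines starting with \code{#} are comments.
#'
#' @param file Path to the trace file.
#' @return \code{read_decay}: a \code{\link{decay_trace}}.
#' @export
read_decay <- function(file) {
  dat <- read_columns(file, c("time_ps", "counts"))
  axis <- axis_from_times(dat[[1L]], file)
  v <- if (ncol(dat) >= 3L && !anyNA(dat[[3L]])) dat[[3L]]^2 else NULL
  decay_trace(axis, dat[[2L]], v)
}

#' @rdname read_decay
#' @param trace A \code{\link{decay_trace}} to write.
#' @export
write_decay <- function(trace, file) {
  if (!inherits(trace, "decay_trace"))
    stop("expected a 'decay_trace'", call. = FALSE)
  writeLines(c("# TCSPC decay trace", "time_ps counts sigma"), file)
  utils::write.table(
    data.frame(time_ps = trace$axis$times, counts = trace$counts,
               sigma = sqrt(trace$variances)),
    file, append = TRUE, quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(file)
}

#' Read / write an instrument response file
#'
#' Delimited text with columns \code{time_ps}, \code{value}; \code{#}
#' comments and an optional header are accepted.
#'
#' @param file Path to the IRF file.
#' @return \code{read_irf}: an \code{\link{instrument_response}}.
#' @export
read_irf <- function(file) {
  dat <- read_columns(file, c("time_ps", "value"))
  instrument_response(axis_from_times(dat[[1L]], file), dat[[2L]])
}

#' @rdname read_irf
#' @param irf An \code{\link{instrument_response}} to write.
#' @export
write_irf <- function(irf, file) {
  if (!inherits(irf, "instrument_response"))
    stop("expected an 'instrument_response'", call. = FALSE)
  writeLines(c("# instrument response function", "time_ps value"), file)
  utils::write.table(
    data.frame(time_ps = irf$axis$times, value = irf$values),
    file, append = TRUE, quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(file)
}

#' Read / write an amplitude spectrum file
#'
#' Columns \code{tau_ps}, \code{alpha}, \code{alpha_normalized} (the
#' log-tau density of \code{\link{normalize_spectrum}}).
#'
#' @param file Path to the spectrum file.
#' @return \code{read_spectrum}: an \code{\link{amplitude_spectrum}}
#'   (raw amplitudes; the normalized column is recomputable).
#' @export
read_spectrum <- function(file) {
  dat <- read_columns(file, c("tau_ps", "alpha"))
  taus <- dat[[1L]]
  N <- length(taus)
  if (N < 2L) stop(sprintf("%s: need at least 2 lifetimes", file),
                   call. = FALSE)
  lr <- diff(log(taus))
  if (any(lr <= 0) || max(abs(lr - lr[1L])) > 1e-6 * lr[1L])
    stop(sprintf("%s: lifetimes must be log-uniformly increasing", file),
         call. = FALSE)
  amplitude_spectrum(lifetime_grid(taus[1L], taus[N], N), dat[[2L]])
}

#' @rdname read_spectrum
#' @param spectrum An \code{\link{amplitude_spectrum}} to write.
#' @export
write_spectrum <- function(spectrum, file) {
  if (!inherits(spectrum, "amplitude_spectrum"))
    stop("expected an 'amplitude_spectrum'", call. = FALSE)
  norm <- normalize_spectrum(spectrum)
  writeLines(c("# lifetime amplitude spectrum",
               "tau_ps alpha alpha_normalized"), file)
  utils::write.table(
    data.frame(tau_ps = spectrum$grid$taus, alpha = spectrum$alphas,
               alpha_normalized = norm$alphas),
    file, append = TRUE, quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(file)
}

#' Write a structured-text results report for a fit
#'
#' Key/value lines (chi-squared, Lagrange multiplier, iteration count,
#' convergence flag) followed by the per-peak summary table.
#'
#' @param fit A \code{"mem_fit"}.
#' @param file Output path.
#' @param extra Optional named character vector of extra provenance
#'   lines (e.g. seeds, config hash).
#' @export
write_fit_report <- function(fit, file, extra = NULL) {
  if (!inherits(fit, "mem_fit")) stop("expected a 'mem_fit'", call. = FALSE)
  s <- summary(fit)
  lines <- c("# MEM fit report",
             sprintf("chi2: %.6f", fit$chi2),
             sprintf("lambda: %.6g", fit$lambda),
             sprintf("entropy: %.6g", fit$entropy),
             sprintf("iterations: %d", fit$iterations),
             sprintf("converged: %s", fit$converged))
  if (!is.null(extra))
    lines <- c(lines, sprintf("%s: %s", names(extra), extra))
  lines <- c(lines, "", "peak mean_tau_ps amp_fraction width_ps rel_width")
  if (nrow(s$peaks))
    lines <- c(lines, sprintf("%d %.6g %.6g %.6g %.6g",
                              seq_len(nrow(s$peaks)), s$peaks$mean_tau,
                              s$peaks$amp_fraction, s$peaks$width,
                              s$peaks$rel_width))
  writeLines(lines, file)
  invisible(file)
}
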