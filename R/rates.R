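#' Bin a spike raster into population rate series
#'
#' Counts spikes of each population in consecutive time bins and divides by
#' the bin width, giving population rates in spikes/ms (kHz at the population
#' level: R_i = N_i * r_i). The two competing populations become \code{X1} and
#' \code{X2}; the shared population of the opposite type becomes \code{Y}.
#'
#' @param raster a \code{\link{simulate_lif}} result.
#' @param bin_ms bin width, ms.
#' @return An object of class \code{pop_rates}: data frame with \code{time}
#'   (bin start, ms) and \code{X1}, \code{X2}, \code{Y} (spikes/ms), plus
#'   attributes \code{bin_ms} and \code{populations}.
#' @export
bin_rates <- function(raster, bin_ms = 10) {
  stopifnot(inherits(raster, "spike_raster"), bin_ms > 0)
  n_bins <- floor(raster$T / bin_ms)
  if (n_bins < 1) stop("duration shorter than one bin")
  pops <- levels(raster$membership)
  out <- data.frame(time = (seq_len(n_bins) - 1) * bin_ms)
  if (length(raster$times) == 0) {
    warning("empty raster: returning all-zero rate series")
    counts <- matrix(0, n_bins, 3)
  } else {
    bin <- pmin(floor(raster$times / bin_ms) + 1L, n_bins)
    pop <- raster$membership[raster$ids]
    counts <- vapply(pops, function(p)
      tabulate(bin[pop == p], nbins = n_bins), numeric(n_bins))
  }
  out$X1 <- counts[, 1] / bin_ms
  out$X2 <- counts[, 2] / bin_ms
  out$Y <- counts[, 3] / bin_ms
  structure(out, bin_ms = bin_ms, populations = pops,
            class = c("pop_rates", "data.frame"))
}

#' Savitzky-Golay smoothing of a rate series
#'
#' Least-squares polynomial smoothing with a window of \code{2n+1} samples
#' and polynomial order \code{m} (defaults 21 and 4). Output length equals
#' input length; near the boundaries the window polynomial is fitted to the
#' available transient window (the filter's own startup/ending rows), which
#' is deterministic.
#'
#' @param x numeric series (or a \code{pop_rates} object, see
#'   \code{\link{smooth_rates}}).
#' @param n half-width of the filter window (window length \code{2n+1}).
#' @param m polynomial order.
#' @return Smoothed numeric series of the same length.
#' @export
savgol_smooth <- function(x, n = 10, m = 4) {
  stopifnot(m < 2 * n + 1)
  if (length(x) <= 2 * n + 1)
    stop("series too short for a Savitzky-Golay window of ", 2 * n + 1)
  as.numeric(signal::sgolayfilt(x, p = m, n = 2 * n + 1))
}

#' Add smoothed population rates E1, E2, I
#'
#' Applies \code{\link{savgol_smooth}} to each rate column; the smoothed
#' competing rates are stored as \code{E1}, \code{E2} and the smoothed shared
#' rate as \code{I} (the naming follows the two-excitatory scenario, but the
#' same columns hold the smoothed inhibitory pair in the EII scenario).
#'
#' @param rates a \code{\link{bin_rates}} result.
#' @param n,m Savitzky-Golay parameters.
#' @return The input with columns \code{E1}, \code{E2}, \code{I} added.
#' @export
smooth_rates <- function(rates, n = 10, m = 4) {
  stopifnot(inherits(rates, "pop_rates"))
  rates$E1 <- savgol_smooth(rates$X1, n, m)
  rates$E2 <- savgol_smooth(rates$X2, n, m)
  rates$I <- savgol_smooth(rates$Y, n, m)
  rates
}

#' Sum/difference coordinates of the competing rates
#'
#' \code{C = (X1 + X2)/2} is the mean rate of the two competing populations
#' and \code{D = (X1 - X2)/2} half their difference; the transform is exactly
#' invertible (\code{X1 = C + D}, \code{X2 = C - D}).
#'
#' @param x1,x2 competing-population rate series (kHz), or a single
#'   \code{pop_rates} object in \code{x1} (smoothed columns are used if
#'   present).
#' @return A data frame with columns \code{C} and \code{D} (class
#'   \code{cd_series}); when a \code{pop_rates} is given, \code{time} and the
#'   (smoothed, if available) shared rate \code{Y} are carried along.
#' @export
to_cd <- function(x1, x2 = NULL) {
  if (inherits(x1, "pop_rates")) {
    r <- x1
    sm <- all(c("E1", "E2", "I") %in% names(r))
    a <- if (sm) r$E1 else r$X1
    b <- if (sm) r$E2 else r$X2
    out <- data.frame(time = r$time, C = (a + b) / 2, D = (a - b) / 2,
                      Y = if (sm) r$I else r$Y)
  } else {
    stopifnot(length(x1) == length(x2))
    out <- data.frame(C = (x1 + x2) / 2, D = (x1 - x2) / 2)
  }
  class(out) <- c("cd_series", "data.frame")
  out
}

#' Invert the sum/difference transform
#'
#' @param cd a \code{\link{to_cd}} result.
#' @return Data frame with \code{X1 = C + D} and \code{X2 = C - D}.
#' @export
from_cd <- function(cd) {
  data.frame(X1 = cd$C + cd$D, X2 = cd$C - cd$D)
}

#' Write a rate series as a tab-separated table
#'
#' @param rates a \code{pop_rates} (optionally smoothed).
#' @param file output path.
#' @export
write_rates <- function(rates, file) {
  utils::write.table(as.data.frame(rates), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
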