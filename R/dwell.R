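#' Detect switches in the rate-difference series
#'
#' Hysteresis rule: starting from the first time the half-difference D leaves
#' the band \code{[-h, +h]}, a switch is recorded whenever D, having exceeded
#' \code{+h}, next falls below \code{-h} (or vice versa). Chatter inside the
#' band produces no events. Dwell times are the intervals between
#' consecutive switches; the epochs before the first and after the last
#' switch are censored and excluded from the dwell statistics.
#'
#' @param D half-difference series, kHz (smoothed).
#' @param hysteresis half-width h of the dead band, kHz.
#' @param time optional sample times, ms (defaults to the sample index).
#' @return An object of class \code{dwell_record}: \code{switch_times},
#'   \code{durations} (uncensored dwell times, ms), \code{winner} (which
#'   population was active during each dwell), \code{n_switches}, and the
#'   censored first/last epoch lengths.
#' @export
detect_switches <- function(D, hysteresis = 0.5, time = NULL) {
  stopifnot(hysteresis > 0)
  if (is.null(time)) time <- seq_along(D)
  state <- 0L
  sw_t <- numeric(0); sw_to <- integer(0)
  for (i in seq_along(D)) {
    if (state == 0L) {
      if (D[i] > hysteresis) state <- 1L
      else if (D[i] < -hysteresis) state <- -1L
    } else if (state == 1L && D[i] < -hysteresis) {
      state <- -1L
      sw_t <- c(sw_t, time[i]); sw_to <- c(sw_to, -1L)
    } else if (state == -1L && D[i] > hysteresis) {
      state <- 1L
      sw_t <- c(sw_t, time[i]); sw_to <- c(sw_to, 1L)
    }
  }
  n_sw <- length(sw_t)
  durations <- if (n_sw >= 2) diff(sw_t) else numeric(0)
  winner <- if (n_sw >= 2) ifelse(sw_to[-n_sw] == 1L, "pop1", "pop2") else character(0)
  structure(list(switch_times = sw_t, durations = durations, winner = winner,
                 n_switches = n_sw,
                 censored_first = if (n_sw) sw_t[1] - time[1] else NA_real_,
                 censored_last = if (n_sw) time[length(time)] - sw_t[n_sw] else NA_real_,
                 hysteresis = hysteresis, T = time[length(time)] - time[1]),
            class = "dwell_record")
}

#' @export
print.dwell_record <- function(x, ...) {
  cat(sprintf("dwell_record: %d switches over %g ms", x$n_switches, x$T))
  if (length(x$durations))
    cat(sprintf(", mean dwell %.1f ms (n = %d uncensored)",
                mean(x$durations), length(x$durations)))
  cat("\n")
  invisible(x)
}

#' Empirical survivor function of dwell times
#'
#' \code{S(t) = #\{tau_i > t\} / n}, the probability that an active state
#' survives beyond t; a right-continuous step function.
#'
#' @param durations uncensored dwell times.
#' @return A function \code{S(t)} (vectorized), with the sorted durations in
#'   attribute \code{"knots"}.
#' @export
survivor <- function(durations) {
  stopifnot(length(durations) >= 1)
  n <- length(durations)
  srt <- sort(durations)
  f <- function(t) vapply(t, function(ti) sum(srt > ti) / n, numeric(1))
  attr(f, "knots") <- srt
  f
}

#' Exponential fit of the dwell-time distribution
#'
#' Maximum-likelihood exponential fit (rate = 1/sample mean) together with
#' the slope and R-squared of a straight-line regression on the logarithm of
#' the empirical survivor function; an R-squared near 1 indicates
#' exponentially distributed (Poisson-like, memoryless) switching.
#'
#' @param durations uncensored dwell times (at least 10).
#' @return List with \code{mean}, \code{rate}, \code{log_surv_slope},
#'   \code{r_squared}, \code{n}.
#' @export
fit_exponential <- function(durations) {
  n <- length(durations)
  if (n < 10) stop("need at least 10 uncensored dwell times")
  m <- mean(durations)
  S <- survivor(durations)
  t <- sort(unique(durations))
  t <- t[-length(t)]               # S = 0 at the largest duration
  y <- log(S(t))
  fit <- stats::lm(y ~ t)
  list(mean = m, rate = 1 / m,
       log_surv_slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared, n = n)
}

#' Classify the competition regime of a run
#'
#' Equal rate (ER): the half-difference D never leaves the hysteresis band.
#' Winner-take-all (WTA): D leaves the band but no switch occurs within the
#' run. Winnerless competition (WLC): at least one switch. The label is
#' duration-dependent (a WLC run shorter than one dwell time looks like
#' WTA), so the observation time is reported alongside.
#'
#' @param D half-difference series, kHz (smoothed).
#' @param hysteresis dead-band half-width, kHz.
#' @param time optional sample times, ms.
#' @return List with \code{regime} (\code{"ER"}, \code{"WLC"} or
#'   \code{"WTA"}), the \code{dwell_record}, and the observation time
#'   \code{T}.
#' @export
classify_regime <- function(D, hysteresis = 0.5, time = NULL) {
  rec <- detect_switches(D, hysteresis, time)
  regime <- if (all(abs(D) <= hysteresis)) "ER"
  else if (rec$n_switches == 0) "WTA"
  else "WLC"
  list(regime = regime, record = rec, T = rec$T)
}

#' Regime map and mean life time across the bifurcation parameter
#'
#' Runs the full spiking pipeline (network build, LIF simulation, rate
#' binning and smoothing, switch detection) for each value of \code{w} and
#' reports the regime label, the number of switches and the mean dwell time
#' (undefined for ER/WTA runs).
#'
#' @param w_values values of the within-population weight factor.
#' @param scenario \code{"EEI"} or \code{"EII"}.
#' @param T simulated duration per run, ms.
#' @param seeds one or more seeds per w; with several seeds the majority
#'   regime is reported.
#' @param hysteresis switch-detection band, kHz.
#' @param bin_ms analysis bin, ms.
#' @param burn_in_ms initial transient to discard, ms.
#' @param ... further arguments to \code{\link{network_spec}}.
#' @return Data frame with one row per w: \code{w}, \code{regime},
#'   \code{mean_dwell}, \code{n_switches} (summed over seeds).
#' @export
sweep_w <- function(w_values, scenario = "EEI", T = 20000, seeds = 1L,
                    hysteresis = 0.5, bin_ms = 10, burn_in_ms = 1000, ...) {
  rows <- lapply(w_values, function(wv) {
    labels <- character(0); all_dur <- numeric(0); n_sw <- 0L
    for (s in seeds) {
      spec <- network_spec(scenario, w = wv, ...)
      net <- assemble_network(spec, seed = s)
      ras <- simulate_lif(net, T = T, seed = s + 1000L)
      rt <- smooth_rates(bin_rates(ras, bin_ms))
      cd <- to_cd(rt)
      cd <- cd[cd$time >= burn_in_ms, , drop = FALSE]
      cls <- classify_regime(cd$D, hysteresis, time = cd$time)
      labels <- c(labels, cls$regime)
      all_dur <- c(all_dur, cls$record$durations)
      n_sw <- n_sw + cls$record$n_switches
    }
    tab <- sort(table(labels), decreasing = TRUE)
    data.frame(w = wv, regime = names(tab)[1],
               mean_dwell = if (length(all_dur)) mean(all_dur) else NA_real_,
               n_switches = n_sw, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
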