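#' Fit the Lotka-Volterra competition reduction to rate series
#'
#' The central model fit of the package. Starting from binned population
#' rates of the two competing subnetworks and the shared subnetwork (a
#' \code{\link{bin_rates}} result, or any data frame with columns
#' \code{time}, \code{X1}, \code{X2}, \code{Y} such as a surrogate), it
#' \enumerate{
#'   \item smooths the three series with a Savitzky-Golay filter,
#'   \item forms the sum/difference coordinates \code{C = (X1+X2)/2},
#'     \code{D = (X1-X2)/2},
#'   \item fits the slaved-rate relation \code{Y = a + b C + f D^2} by least
#'     squares,
#'   \item estimates the empirical flow field and its nullclines in the
#'     \code{(E1, E2)} plane from normalized first-order differences,
#'   \item estimates the state-dependent residual (noise) variance with
#'     near-saddle exclusion,
#'   \item detects switches by hysteresis and summarizes the dwell-time
#'     distribution,
#'   \item classifies the regime (ER / WLC / WTA) and reports the
#'     excitation-inhibition balance correlation \code{cor(X1+X2, Y)}.
#' }
#'
#' @param rates a \code{pop_rates} data frame (binned spiking rates or a
#'   surrogate series).
#' @param sg_n,sg_m Savitzky-Golay half-width and polynomial order.
#' @param hysteresis switch-detection band on D, kHz.
#' @param grid_n flow-field grid resolution per axis.
#' @param min_count minimum samples per usable flow bin.
#' @param exclusion near-saddle exclusion threshold on |D|, kHz, for the
#'   noise-variance field.
#' @param smooth logical; set \code{FALSE} if \code{rates} is already
#'   smooth (e.g. a noise-free surrogate).
#' @param burn_in_ms initial stretch to discard before any analysis, ms.
#'   Spiking runs start from random membrane potentials whose partial
#'   synchrony produces a population transient; \code{\link{run_pipeline}}
#'   discards the first second by default. Surrogates started at a planted
#'   state need no burn-in (default 0).
#' @return An object of class \code{competition_fit} with components
#'   \code{yfit} (coefficients a, b, f and GOF), \code{flow},
#'   \code{nullclines}, \code{noise}, \code{dwell}, \code{regime},
#'   \code{balance_correlation}, and the processed series \code{cd}.
#' @seealso \code{\link{coef.competition_fit}},
#'   \code{\link{predict.competition_fit}},
#'   \code{\link{simulate.competition_fit}}, \code{\link{fit_Y}}
#' @export
fit_competition <- function(rates, sg_n = 10, sg_m = 4, hysteresis = 0.5,
                            grid_n = 30, min_count = 5, exclusion = 0.5,
                            smooth = TRUE, burn_in_ms = 0) {
  stopifnot(is.data.frame(rates),
            all(c("time", "X1", "X2", "Y") %in% names(rates)))
  bin_ms <- attr(rates, "bin_ms")
  if (is.null(bin_ms)) bin_ms <- diff(rates$time[1:2])
  if (burn_in_ms > 0)
    rates <- rates[rates$time >= rates$time[1] + burn_in_ms, , drop = FALSE]

  if (smooth) {
    E1 <- savgol_smooth(rates$X1, sg_n, sg_m)
    E2 <- savgol_smooth(rates$X2, sg_n, sg_m)
    I <- savgol_smooth(rates$Y, sg_n, sg_m)
  } else {
    E1 <- rates$X1; E2 <- rates$X2; I <- rates$Y
  }
  cd <- data.frame(time = rates$time, C = (E1 + E2) / 2, D = (E1 - E2) / 2,
                   Y = I)

  yf <- fit_Y(cd$C, cd$D, cd$Y)

  d1 <- estimate_derivatives(E1, bin_ms)
  d2 <- estimate_derivatives(E2, bin_ms)
  x <- E1[d1$idx]; y <- E2[d2$idx]
  flow <- estimate_flow(x, y, d1$d, d2$d, nx = grid_n, ny = grid_n,
                        min_count = min_count)
  nulls <- empirical_nullclines(flow)
  noise <- noise_variance(x, y, d1$d, d2$d, flow, exclusion = exclusion)

  cls <- classify_regime(cd$D, hysteresis, time = cd$time)
  dw <- cls$record
  expfit <- if (length(dw$durations) >= 10) fit_exponential(dw$durations) else NULL

  structure(list(yfit = yf, flow = flow, nullclines = nulls, noise = noise,
                 dwell = dw, exp_fit = expfit, regime = cls$regime,
                 balance_correlation = stats::cor(E1 + E2, I),
                 cd = cd, bin_ms = bin_ms, hysteresis = hysteresis,
                 call = match.call()),
            class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("Lotka-Volterra competition fit\n")
  cat(sprintf("  regime: %s (%d switches, %d uncensored dwells)\n",
              x$regime, x$dwell$n_switches, length(x$dwell$durations)))
  cat(sprintf("  Y = a + b C + f D^2: a = %.3f kHz, b = %.3f, f = %s ms\n",
              x$yfit$a, x$yfit$b,
              if (is.na(x$yfit$f)) "undetermined" else sprintf("%.4f", x$yfit$f)))
  cat(sprintf("  E/I balance correlation: %.3f\n", x$balance_correlation))
  invisible(x)
}

#' @export
summary.competition_fit <- function(object, ...) {
  x <- object
  cat("Lotka-Volterra competition fit\n")
  cat(sprintf("  samples: %d bins of %g ms (%.1f s)\n",
              nrow(x$cd), x$bin_ms, nrow(x$cd) * x$bin_ms / 1000))
  print(x$yfit)
  cat(sprintf("  regime: %s; switches: %d; E/I balance corr: %.3f\n",
              x$regime, x$dwell$n_switches, x$balance_correlation))
  if (!is.null(x$exp_fit))
    cat(sprintf("  dwell times: mean %.0f ms, log-survivor R^2 = %.3f (n = %d)\n",
                x$exp_fit$mean, x$exp_fit$r_squared, x$exp_fit$n))
  rho <- noise_state_correlation(x$noise, "x")
  cat(sprintf("  noise state dependence (Spearman rho, var(dE1) vs E1): %.3f\n", rho))
  invisible(x)
}

#' Extract the slaved-rate coefficients
#'
#' @param object a \code{\link{fit_competition}} result.
#' @param ... unused.
#' @return Named vector \code{c(a, b, f)}.
#' @export
coef.competition_fit <- function(object, ...) {
  c(a = object$yfit$a, b = object$yfit$b, f = object$yfit$f)
}

#' Predict the shared-population rate from (C, D)
#'
#' @param object a \code{\link{fit_competition}} result.
#' @param newdata data frame with columns \code{C} and \code{D}; defaults to
#'   the fitted series.
#' @param ... unused.
#' @return Predicted Y, kHz.
#' @export
predict.competition_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$cd
  f <- if (is.na(object$yfit$f)) 0 else object$yfit$f
  object$yfit$a + object$yfit$b * newdata$C + f * newdata$D^2
}

#' @export
residuals.competition_fit <- function(object, ...) {
  object$cd$Y - stats::predict(object)
}

#' Simulate from the fitted reduction
#'
#' Integrates the stochastic Lotka-Volterra surrogate using the fitted
#' slaved-rate coefficients (and a given or default deterministic parameter
#' set), returning a rate series comparable to the data the model was
#' fitted on.
#'
#' @param object a \code{\link{fit_competition}} result.
#' @param nsim number of series to simulate.
#' @param seed integer seed.
#' @param params an \code{\link{lv_params}} for the deterministic skeleton.
#' @param noise,eta,T,... passed to \code{\link{surrogate_config}}.
#' @return A \code{pop_rates} data frame (or a list of them for
#'   \code{nsim > 1}).
#' @export
simulate.competition_fit <- function(object, nsim = 1, seed = 1L,
                                     params = lv_params(),
                                     noise = "multiplicative", eta = 0.42,
                                     T = NULL, ...) {
  yf <- yfit_params(object$yfit$a, object$yfit$b,
                    if (is.na(object$yfit$f)) 0 else object$yfit$f)
  if (is.null(T)) T <- nrow(object$cd) * object$bin_ms
  cfg <- surrogate_config(params, yf, model = "lv", noise = noise, eta = eta,
                          T = T, output_dt = object$bin_ms, ...)
  sims <- lapply(seq_len(nsim), function(i) integrate_sde(cfg, seed + i - 1L))
  if (nsim == 1) sims[[1]] else sims
}

#' Plot a competition fit
#'
#' Four base-graphics panels: the smoothed rate traces, the Y(C, D) fit
#' against the data, the empirical flow field with its nullclines, and the
#' dwell-time log-survivor with its exponential fit (when available).
#'
#' @param x a \code{\link{fit_competition}} result.
#' @param which subset of panels 1:4.
#' @param ... unused.
#' @export
plot.competition_fit <- function(x, which = 1:4, ...) {
  op <- graphics::par(mfrow = c(length(which) > 2, 2) + c(1, 0),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    graphics::matplot(x$cd$time / 1000, cbind(x$cd$C + x$cd$D, x$cd$C - x$cd$D,
                                              x$cd$Y),
                      type = "l", lty = 1, col = c("firebrick", "steelblue", "gray40"),
                      xlab = "time (s)", ylab = "rate (kHz)",
                      main = "population rates")
    graphics::legend("topright", c("E1", "E2", "shared"), lty = 1, cex = 0.7,
                     col = c("firebrick", "steelblue", "gray40"))
  }
  if (2 %in% which) {
    graphics::plot(x$cd$Y, stats::predict(x), pch = 16, cex = 0.3,
                   xlab = "observed Y (kHz)", ylab = "fitted a + bC + fD^2",
                   main = "slaved-rate fit")
    graphics::abline(0, 1, col = "red")
  }
  if (3 %in% which) {
    graphics::plot(NA, xlim = range(x$flow$x_edges), ylim = range(x$flow$y_edges),
                   xlab = "E1 (kHz)", ylab = "E2 (kHz)", main = "empirical flow")
    xc <- x$flow$x_centers; yc <- x$flow$y_centers
    sc <- 0.4 * diff(xc[1:2]) / max(abs(x$flow$mean_dx), na.rm = TRUE)
    for (i in seq_along(yc)) for (j in seq_along(xc))
      if (isTRUE(x$flow$usable[i, j]))
        graphics::arrows(xc[j], yc[i], xc[j] + sc * x$flow$mean_dx[i, j],
                         yc[i] + sc * x$flow$mean_dy[i, j],
                         length = 0.02, col = "gray50")
    for (co in x$nullclines$dx) graphics::lines(co, col = "firebrick", lwd = 2)
    for (co in x$nullclines$dy) graphics::lines(co, col = "steelblue", lwd = 2)
  }
  if (4 %in% which && length(x$dwell$durations) >= 10) {
    S <- survivor(x$dwell$durations)
    t <- sort(unique(x$dwell$durations))
    t <- t[-length(t)]
    graphics::plot(t, log(S(t)), pch = 16, cex = 0.5,
                   xlab = "dwell time (ms)", ylab = "log survivor",
                   main = "dwell-time distribution")
    if (!is.null(x$exp_fit))
      graphics::abline(0, -x$exp_fit$rate, col = "red")
  }
  invisible(x)
}
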