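#' Configuration of the stochastic Lotka-Volterra surrogate generator
#'
#' The surrogate generator integrates the competition dynamics as a
#' stochastic differential equation with planted parameters, producing rate
#' time series with known ground truth for validating every analysis stage
#' without a spiking simulation. The shared rate is slaved to the competing
#' pair through \code{Y = a + b C + f D^2}. Noise is independent per
#' dimension, either additive (\code{sigma = eta}) or multiplicative
#' (\code{sigma = eta * X}), the latter being the state-dependent noise
#' hypothesis for balanced networks; rates are kept nonnegative by
#' reflection at zero.
#'
#' @param params an \code{\link{lv_params}} (the planted deterministic
#'   field).
#' @param yfit a \code{\link{yfit_params}} (the planted slaved-rate
#'   relation).
#' @param model \code{"lv"} (state X1, X2 with slaved Y), \code{"cd"} (state
#'   stepped in sum/difference coordinates) or \code{"simplified2d"}
#'   (\code{h0} and \code{f} forced to 0).
#' @param noise \code{"none"}, \code{"additive"} or \code{"multiplicative"}.
#' @param eta noise amplitude: kHz/sqrt(ms) (additive) or 1/sqrt(ms)
#'   (multiplicative).
#' @param dt integration step, ms.
#' @param T duration, ms.
#' @param output_dt output sampling interval, ms (multiple of \code{dt});
#'   default matches the 10-ms analysis grid.
#' @param init initial state \code{c(X1, X2)}, kHz.
#' @return An object of class \code{surrogate_config}.
#' @export
surrogate_config <- function(params = lv_params(), yfit = yfit_params(1.112, 0.356, 0.014),
                             model = c("lv", "cd", "simplified2d"),
                             noise = c("multiplicative", "additive", "none"),
                             eta = 0.1, dt = 0.1, T = 10000, output_dt = 10,
                             init = c(2.5, 0.3)) {
  model <- match.arg(model)
  noise <- match.arg(noise)
  stopifnot(dt > 0, eta >= 0, T > 0, all(init >= 0))
  sub <- round(output_dt / dt)
  if (abs(sub * dt - output_dt) > 1e-9 || sub < 1)
    stop("output_dt must be a positive integer multiple of dt")
  structure(list(params = params, yfit = yfit, model = model, noise = noise,
                 eta = eta, dt = dt, T = T, output_dt = output_dt,
                 init = init),
            class = "surrogate_config")
}

#' Integrate the stochastic surrogate
#'
#' Euler-Maruyama integration of the configured system:
#' \code{X <- X + rhs dt + sigma(X) sqrt(dt) N(0,1)}, reflected at zero,
#' subsampled to the output grid. The ground truth (parameters, fixed-point
#' structure, noise model) is attached for downstream checks.
#'
#' @param config a \code{\link{surrogate_config}}.
#' @param seed integer seed.
#' @return A \code{pop_rates}-compatible data frame with columns
#'   \code{time}, \code{X1}, \code{X2}, \code{Y}; attributes \code{truth}
#'   (the config plus the planted fixed points) and \code{bin_ms}.
#' @export
integrate_sde <- function(config, seed = 1L) {
  stopifnot(inherits(config, "surrogate_config"))
  p <- config$params; yf <- config$yfit
  h0 <- p$h0; f <- yf$f
  if (config$model == "simplified2d") { h0 <- 0; f <- 0 }
  noise_type <- match(config$noise, c("none", "additive", "multiplicative")) - 1L
  set.seed(seed)
  m <- cpp_lv_sde(config$init[1], config$init[2], p$k, p$w, p$k1, p$k0, h0,
                  yf$a, yf$b, f,
                  model = if (config$model == "cd") 1L else 0L,
                  noise_type = noise_type, eta = config$eta,
                  dt = config$dt, n_steps = round(config$T / config$dt),
                  sub = round(config$output_dt / config$dt))
  out <- data.frame(time = m[, 1], X1 = m[, 2], X2 = m[, 3], Y = m[, 4])
  truth <- list(config = config,
                fixed_points = fixed_points(p, yf),
                noise = config$noise, eta = config$eta, seed = seed)
  structure(out, bin_ms = config$output_dt, populations = c("X1", "X2", "Y"),
            truth = truth, class = c("pop_rates", "data.frame"))
}

#' Generate a labelled surrogate dataset for a requested regime
#'
#' Chooses planted parameters that place the deterministic skeleton in the
#' requested regime and integrates the stochastic system:
#' \describe{
#'   \item{WLC}{the EEI operating point (\code{w = 2.5}, two axis attractors
#'     separated by a saddle) with multiplicative noise strong enough to
#'     drive attractor switching;}
#'   \item{ER}{\code{w = 0.8}: a single symmetric attractor on the diagonal
#'     (within-coupling weaker than across, no competition) with weak
#'     noise;}
#'   \item{WTA}{\code{w = 3.0} with weak noise: the attractors and the
#'     saddle exist but the barrier is too high for the noise, so the
#'     initial winner persists.}
#' }
#'
#' @param regime \code{"ER"}, \code{"WLC"} or \code{"WTA"}.
#' @param seed integer seed.
#' @param T duration, ms.
#' @param eta noise amplitude override (one per regime by default).
#' @param sigma_Y standard deviation of the observation noise added to the
#'   (otherwise exactly slaved) shared rate, kHz; small relative to the
#'   kilohertz rate scale.
#' @return As \code{\link{integrate_sde}}, with the truth record describing
#'   the planted regime and fixed-point structure.
#' @export
generate_dataset <- function(regime = c("WLC", "ER", "WTA"), seed = 1L,
                             T = 20000, eta = NULL, sigma_Y = 0.01) {
  regime <- match.arg(regime)
  w <- switch(regime, WLC = 2.5, ER = 0.8, WTA = 3.0)
  # WLC amplitude chosen so the surrogate dwell-time scale (~1 s) matches the
  # spiking network at the same operating point; ER/WTA use weak noise that
  # cannot cross the barrier
  if (is.null(eta)) eta <- switch(regime, WLC = 0.42, ER = 0.05, WTA = 0.05)
  params <- lv_params(w = w)
  yfit <- yfit_params(1.112, 0.356, 0.014)
  fp <- fixed_points(params, yfit)
  n_att <- sum(fp$type == "attractor")
  n_sad <- sum(fp$type == "saddle" & fp$X1 > 0 & fp$X2 > 0)
  if (regime == "WLC" || regime == "WTA") {
    if (n_att != 2 || n_sad != 1)
      stop("planted parameters do not yield the two-attractor/one-saddle structure; found: ",
           paste(fp$type, collapse = ", "))
    init <- c(fp$X2[fp$type == "attractor"][1], 0.1)
  } else {
    if (n_att != 1)
      stop("planted ER parameters do not yield a single attractor; found: ",
           paste(fp$type, collapse = ", "))
    diag_fp <- fp[fp$type == "attractor", ]
    init <- c(diag_fp$X1[1], diag_fp$X2[1])
  }
  cfg <- surrogate_config(params, yfit, model = "lv",
                          noise = "multiplicative", eta = eta, T = T,
                          init = init)
  out <- integrate_sde(cfg, seed)
  if (sigma_Y > 0) out$Y <- out$Y + stats::rnorm(nrow(out), 0, sigma_Y)
  tr <- attr(out, "truth")
  tr$regime <- regime
  tr$sigma_Y <- sigma_Y
  attr(out, "truth") <- tr
  out
}
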