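#' Lyapunov (energy) function of the simplified competition system
#'
#' For the closed 2-D system (shared rate replaced by its linear part,
#' \code{f = 0}, \code{h0 = 0}) an energy-like Lyapunov function is
#' \deqn{V(X_1,X_2) = (pga - k_0)(X_1 + X_2)
#'   + \tfrac{1}{2}\left(\tfrac{pgb}{2} - w\right)(X_1^2 + X_2^2)
#'   + \left(\tfrac{pgb}{2} - 1\right) X_1 X_2}
#' with \code{pg = -k1}. Its derivative along the flow is exactly
#' \deqn{\dot V = -k X_1 B_1^2 - k X_2 B_2^2 \le 0}
#' where \code{B_i} are the bracket terms of the field, so V never increases
#' (for \code{k > 0}) and is constant only at equilibria. The constructor
#' refuses parameter sets with nonzero \code{h0} or \code{f}: the energy
#' analysis is defined for the pure Lotka-Volterra form only.
#'
#' @param params an \code{\link{lv_params}} with \code{h0 = 0}.
#' @param yfit a \code{\link{yfit_params}} with \code{f = 0}.
#' @return An object of class \code{lyapunov_spec}.
#' @export
lyapunov_spec <- function(params, yfit) {
  if (!isTRUE(all.equal(params$h0, 0)))
    stop("the Lyapunov analysis requires h0 = 0; refusing to ignore a nonzero floor drive")
  if (!isTRUE(all.equal(yfit$f, 0)))
    stop("the Lyapunov analysis requires f = 0; refusing to ignore the quadratic Y term")
  pg <- -params$k1
  structure(list(
    L = pg * yfit$a - params$k0,      # linear coefficient
    Q = pg * yfit$b / 2 - params$w,   # diagonal quadratic coefficient (x 1/2)
    S = pg * yfit$b / 2 - 1,          # cross coefficient
    k = params$k, params = params, yfit = yfit),
    class = "lyapunov_spec")
}

#' @rdname lyapunov_spec
#' @param X1,X2 state, kHz (vectorized).
#' @param spec a \code{lyapunov_spec}.
#' @return \code{V}: energy values (arbitrary units).
#' @export
V <- function(X1, X2, spec) {
  stopifnot(inherits(spec, "lyapunov_spec"))
  spec$L * (X1 + X2) + spec$Q * (X1^2 + X2^2) / 2 + spec$S * X1 * X2
}

#' @rdname lyapunov_spec
#' @return \code{Vdot}: the time derivative of V along the flow
#'   (negative semidefinite on the positive quadrant).
#' @export
Vdot <- function(X1, X2, spec) {
  stopifnot(inherits(spec, "lyapunov_spec"))
  B1 <- -(spec$L + spec$Q * X1 + spec$S * X2)
  B2 <- -(spec$L + spec$Q * X2 + spec$S * X1)
  -spec$k * X1 * B1^2 - spec$k * X2 * B2^2
}

#' Attractor-saddle energy barrier as a function of w
#'
#' For each value of the bifurcation parameter \code{w}, locates the fixed
#' points of the simplified 2-D system and returns the energy difference
#' \code{V(saddle) - V(attractor)} (the two axis attractors have equal energy
#' by symmetry). The larger the barrier, the harder it is for intrinsic
#' fluctuations to drive the trajectory over the saddle, hence the longer the
#' dwell times. When the two-attractor/one-saddle configuration does not
#' exist (e.g. \code{w = 1}), the barrier is reported as \code{NA}
#' (undefined), never as zero.
#'
#' @param w_values numeric vector of w values.
#' @param yfit a \code{\link{yfit_params}}; its \code{(a, b)} are held fixed
#'   across the sweep (its \code{f} is set to 0).
#' @param params template \code{\link{lv_params}} (its \code{w} and
#'   \code{h0} are overridden per point).
#' @return Data frame with columns \code{w} and \code{barrier}.
#' @export
energy_barrier <- function(w_values, yfit, params = lv_params()) {
  yf0 <- yfit_params(yfit$a, yfit$b, 0)
  res <- vapply(w_values, function(wv) {
    p <- params; p$w <- wv; p$h0 <- 0
    fp <- fixed_points(p, yf0)
    att <- fp[fp$type == "attractor", , drop = FALSE]
    sad <- fp[fp$type == "saddle" & fp$X1 > 0 & fp$X2 > 0, , drop = FALSE]
    if (nrow(att) != 2 || nrow(sad) != 1) return(NA_real_)
    spec <- lyapunov_spec(p, yf0)
    vs <- V(sad$X1[1], sad$X2[1], spec)
    va <- V(att$X1[1], att$X2[1], spec)
    vs - va
  }, numeric(1))
  data.frame(w = w_values, barrier = res)
}
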