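#' Mean-field coupling matrix
#'
#' The 3x3 matrix (mV*ms per unit population rate) that maps the population
#' rates (R1, R2, R3) onto the mean membrane drive of a neuron in each
#' population. For the EEI scenario it is
#' \code{tau*eps*J * [[w,1,-pg],[1,w,-pg],[p,p,-pg]]}; for the EII scenario
#' \code{tau*eps*J * [[-pwg,-pg,p],[-pg,-pwg,p],[-pg,-pg,1]]}.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param tau membrane time constant, ms.
#' @return 3x3 numeric matrix with population dimnames.
#' @export
coupling_matrix <- function(spec, tau = 20) {
  stopifnot(inherits(spec, "network_spec"))
  w <- spec$w; g <- spec$g; p <- spec$p
  base <- tau * spec$eps * spec$J
  M <- if (spec$scenario == "EEI") {
    base * matrix(c(w, 1, -p * g,
                    1, w, -p * g,
                    p, p, -p * g), 3, 3, byrow = TRUE)
  } else {
    base * matrix(c(-p * w * g, -p * g, p,
                    -p * g, -p * w * g, p,
                    -p * g, -p * g, 1), 3, 3, byrow = TRUE)
  }
  dimnames(M) <- rep(list(names(population_sizes(spec))), 2)
  M
}

#' First and second moments of the synaptic input
#'
#' Mean \code{mu_k} (mV) and standard deviation \code{sigma_k} (mV) of the
#' summed synaptic input to a neuron of population k, given the population
#' rates. Both are computed from the exact per-block in-degrees and weights:
#' \code{mu_k = tau * (sum_j indeg_jk * J_jk * r_j + J * r0)} and
#' \code{sigma_k^2 = tau * sum_j indeg_jk * J_jk^2 * r_j}, with per-neuron
#' rates \code{r_j = R_j / N_j}. The external rate \code{r0} enters the mean
#' only (the DC drive is noiseless).
#'
#' @param R1,R2,R3 population rates, kHz (spikes/ms summed over the
#'   population).
#' @param spec a \code{\link{network_spec}}.
#' @param r0 equivalent external Poisson rate, spikes/ms.
#' @param tau membrane time constant, ms.
#' @return List with numeric vectors \code{mu} and \code{sigma} (length 3).
#' @export
input_moments <- function(R1, R2, R3, spec, r0 = 0, tau = 20) {
  stopifnot(R1 >= 0, R2 >= 0, R3 >= 0)
  bd <- block_degrees(spec)
  sizes <- population_sizes(spec)
  pops <- names(sizes)
  R <- c(R1, R2, R3)
  r <- R / sizes  # per-neuron rates, spikes/ms
  mu <- sigma2 <- numeric(3)
  for (k in 1:3) {
    blk <- bd[bd$to == pops[k], ]
    j <- match(blk$from, pops)
    mu[k] <- tau * (sum(blk$in_deg * blk$weight * r[j]) + spec$J * r0)
    sigma2[k] <- tau * sum(blk$in_deg * blk$weight^2 * r[j])
  }
  list(mu = mu, sigma = sqrt(sigma2))
}

#' Stationary firing rate in the low-rate regime
#'
#' The low-frequency stationary rate of a leaky integrate-and-fire neuron
#' with mean input \code{mu} and input deviation \code{sigma}:
#' \deqn{r = \frac{\theta-\mu}{\sigma\tau\sqrt\pi}\exp\left(-\frac{(\theta-\mu)^2}{\sigma^2}\right)}
#' valid for \code{mu < theta} (fluctuation-driven regime). The
#' \code{"diffusion"} variant uses the standard exponent
#' \code{(theta-mu)^2/(2 sigma^2)} for sensitivity checks.
#'
#' @param mu mean input, mV.
#' @param sigma input standard deviation, mV (> 0).
#' @param theta threshold, mV.
#' @param tau membrane time constant, ms.
#' @param variant exponent convention.
#' @return Firing rate in spikes/ms.
#' @export
stationary_rate <- function(mu, sigma, theta = 20, tau = 20,
                            variant = c("as-printed", "diffusion")) {
  variant <- match.arg(variant)
  stopifnot(sigma > 0)
  if (any(mu >= theta))
    stop("stationary rate formula requires mu < theta (subthreshold mean input)")
  u <- (theta - mu) / sigma
  denom <- if (variant == "as-printed") 1 else 2
  u / (tau * sqrt(pi)) * exp(-u^2 / denom)
}

#' Lotka-Volterra mean-field parameters
#'
#' Coefficients of the competition dynamics
#' \deqn{\dot X_1 = k X_1 (w X_1 + X_2 + k_1 Y + k_0) + h_0}
#' (and symmetrically for X2). Defaults are the EEI operating point:
#' \code{k0 = 22 kHz}, \code{h0 = 0.5 kHz}, \code{k = 1 ms},
#' \code{k1 = -p*g = -18}, \code{w = 2.5}. \code{k} is positive for the EEI
#' network and negative for the EII network. \code{k_prime} and \code{k2}
#' (the Y-dynamics coefficients) are never assigned: the shared rate Y is
#' replaced by its fitted quadratic \code{Y = a + b C + f D^2} throughout.
#'
#' @param k rate-equation gain, ms.
#' @param k0 effective coupling + drive constant, kHz.
#' @param k1 coupling of the shared population, dimensionless (\code{-p*g}
#'   for EEI).
#' @param h0 floor drive keeping extinct populations recoverable, kHz.
#' @param w within-population coupling factor.
#' @param iota time constant of the single-neuron rate dynamics, ms
#'   (documentation of the derivation; not used by the reduced system).
#' @param k_prime,k2 Y-dynamics coefficients, unassigned (\code{NA}).
#' @return An object of class \code{lv_params}.
#' @export
lv_params <- function(k = 1, k0 = 22, k1 = -18, h0 = 0.5, w = 2.5,
                      iota = 1, k_prime = NA, k2 = NA) {
  structure(list(k = k, k0 = k0, k1 = k1, h0 = h0, w = w,
                 iota = iota, k_prime = k_prime, k2 = k2),
            class = "lv_params")
}

#' @export
print.lv_params <- function(x, ...) {
  cat(sprintf("lv_params: k = %g ms, k0 = %g kHz, k1 = %g, h0 = %g kHz, w = %g\n",
              x$k, x$k0, x$k1, x$h0, x$w))
  invisible(x)
}

#' Planted / fitted coefficients of the slaved-rate relation
#'
#' Container for the quadratic relation \code{Y = a + b C + f D^2} between
#' the shared-population rate and the sum/difference coordinates of the
#' competing rates.
#'
#' @param a offset, kHz.
#' @param b linear coefficient, dimensionless.
#' @param f quadratic coefficient, ms.
#' @return An object of class \code{yfit_params}.
#' @export
yfit_params <- function(a, b, f = 0) {
  structure(list(a = a, b = b, f = f), class = "yfit_params")
}

#' Right-hand sides of the competition dynamics
#'
#' \code{lv_rhs} evaluates the three-population reduction with an explicit
#' shared rate Y; \code{cd_rhs} the exactly equivalent sum/difference form
#' (note the quadratic \code{k (w-1) D^2} term in dC); and
#' \code{simplified2d_rhs} the closed two-dimensional system in which Y is
#' replaced by its linear part \code{a + (b/2)(X1+X2)} (\code{f} and
#' \code{h0} set to zero, as in the Lyapunov analysis).
#'
#' @param X1,X2,Y,C,D state variables, kHz (vectorized).
#' @param params an \code{\link{lv_params}}.
#' @param yfit a \code{\link{yfit_params}} (its \code{f} is ignored by
#'   \code{simplified2d_rhs}).
#' @return List with the component time derivatives (kHz/ms).
#' @export
lv_rhs <- function(X1, X2, Y, params) {
  with(params, list(
    dX1 = k * X1 * (w * X1 + X2 + k1 * Y + k0) + h0,
    dX2 = k * X2 * (X1 + w * X2 + k1 * Y + k0) + h0))
}

#' @rdname lv_rhs
#' @export
cd_rhs <- function(C, D, Y, params) {
  with(params, list(
    dC = k * C * ((w + 1) * C + k1 * Y + k0) + k * (w - 1) * D^2 + h0,
    dD = k * D * (2 * w * C + k1 * Y + k0)))
}

#' @rdname lv_rhs
#' @export
simplified2d_rhs <- function(X1, X2, yfit, params) {
  Y <- yfit$a + (yfit$b / 2) * (X1 + X2)
  with(params, list(
    dX1 = k * X1 * (w * X1 + X2 + k1 * Y + k0),
    dX2 = k * X2 * (X1 + w * X2 + k1 * Y + k0)))
}

# Jacobian of the simplified 2-D field at (x1, x2)
simplified2d_jacobian <- function(x1, x2, yfit, params) {
  k <- params$k; w <- params$w; k1 <- params$k1; k0 <- params$k0
  a <- yfit$a; b <- yfit$b
  B1 <- w * x1 + x2 + k1 * (a + b / 2 * (x1 + x2)) + k0
  B2 <- x1 + w * x2 + k1 * (a + b / 2 * (x1 + x2)) + k0
  matrix(c(k * (B1 + x1 * (w + k1 * b / 2)), k * x1 * (1 + k1 * b / 2),
           k * x2 * (1 + k1 * b / 2), k * (B2 + x2 * (w + k1 * b / 2))),
         2, 2, byrow = TRUE)
}

.classify_eigen <- function(J, tol = 1e-9) {
  ev <- Re(eigen(J, only.values = TRUE)$values)
  if (any(abs(ev) < tol)) return(list(type = "marginal", ev = ev))
  if (all(ev < 0)) return(list(type = "attractor", ev = ev))
  if (all(ev > 0)) return(list(type = "unstable", ev = ev))
  list(type = "saddle", ev = ev)
}

# one Newton refinement pass on the simplified 2-D field
.newton_refine <- function(x, yfit, params, iter = 30, tol = 1e-12) {
  for (i in seq_len(iter)) {
    F <- simplified2d_rhs(x[1], x[2], yfit, params)
    F <- c(F$dX1, F$dX2)
    if (max(abs(F)) < tol) break
    J <- simplified2d_jacobian(x[1], x[2], yfit, params)
    step <- tryCatch(solve(J, F), error = function(e) NULL)
    if (is.null(step)) break
    x <- x - step
  }
  x
}

#' Fixed points of the simplified two-dimensional competition system
#'
#' Closed-form equilibria of the 2-D reduction with
#' \code{Y = a + (b/2)(X1+X2)}, verified by Newton root-finding and
#' classified by the eigenvalues of the analytic Jacobian: the origin, the
#' symmetric interior point \code{((pga-k0)/(w+1-pgb)) * (1,1)}
#' (the saddle in the switching regime) and the two axis points
#' \code{(0, (pga-k0)/(w-pgb/2))} and its mirror (the attractors). Here
#' \code{pg = -k1}. For \code{w = 1} the field degenerates to a whole line of
#' equilibria \code{(1 - pgb/2)(X1+X2) = pga - k0}; the single diagonal
#' representative is returned, labelled \code{"marginal"}.
#'
#' @param params an \code{\link{lv_params}} (its \code{h0} is ignored: the
#'   fixed-point analysis is for the \code{h0 = 0} system).
#' @param yfit a \code{\link{yfit_params}} (its \code{f} is ignored).
#' @param tol eigenvalue magnitude below which a point is labelled marginal.
#' @return Data frame of class \code{fixed_points}: \code{X1}, \code{X2}
#'   (kHz), \code{type} (attractor / saddle / unstable / marginal),
#'   \code{lambda1}, \code{lambda2}; attribute \code{degenerate} flags the
#'   \code{w = 1} line-of-equilibria case.
#' @export
fixed_points <- function(params, yfit, tol = 1e-9) {
  p0 <- params; p0$h0 <- 0
  a <- yfit$a; b <- yfit$b
  k0 <- p0$k0; k1 <- p0$k1; w <- p0$w
  num <- -(k1 * a + k0)             # = pg*a - k0 when k1 = -pg
  den_int <- w + 1 + k1 * b         # = w + 1 - pg*b
  den_ax <- w + k1 * b / 2          # = w - pg*b/2

  degenerate <- abs(w - 1) < 1e-12
  cand <- list(c(0, 0))
  if (degenerate) {
    if (abs(den_int) > 1e-12) cand <- c(cand, list(rep(num / den_int, 2)))
  } else {
    if (abs(den_int) < 1e-12 || abs(den_ax) < 1e-12)
      stop("degenerate denominator: the fixed-point formulas are at a bifurcation")
    cand <- c(cand, list(rep(num / den_int, 2),
                         c(0, num / den_ax), c(num / den_ax, 0)))
  }
  rows <- lapply(cand, function(x) {
    x <- .newton_refine(x, yfit, p0)
    cl <- .classify_eigen(simplified2d_jacobian(x[1], x[2], yfit, p0), tol)
    data.frame(X1 = x[1], X2 = x[2], type = cl$type,
               lambda1 = cl$ev[1], lambda2 = cl$ev[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "degenerate") <- degenerate
  class(out) <- c("fixed_points", class(out))
  out
}

#' Analytic nullclines of the competition dynamics
#'
#' Zero-level sets of the simplified 2-D field in the (X1, X2) plane and of
#' the equivalent sum/difference form in the (C, D) plane (with
#' \code{Y = a + bC}, \code{f = h0 = 0}). In (X1, X2), each component's
#' nullcline has the axis branch \code{Xi = 0} and a straight line; in
#' (C, D), \code{D = 0} is always one branch of the dD nullcline, the other
#' being the vertical line \code{C = -(k1 a + k0)/(2w + k1 b)}, while the dC
#' nullcline is the parabola-like curve \code{k C ((w+1)C + k1(a+bC) + k0)
#' + k(w-1) D^2 = 0}.
#'
#' @param params an \code{\link{lv_params}}.
#' @param yfit a \code{\link{yfit_params}}.
#' @param xmax upper end of the evaluation range, kHz.
#' @param n points per curve.
#' @return List with elements \code{x1} and \code{x2} (each a list of
#'   data frames with columns \code{X1}, \code{X2}) and \code{cd} (branches
#'   of the dC and dD nullclines in columns \code{C}, \code{D}).
#' @export
nullclines_analytic <- function(params, yfit, xmax = 4, n = 201) {
  a <- yfit$a; b <- yfit$b
  k0 <- params$k0; k1 <- params$k1; w <- params$w; k <- params$k
  s <- seq(0, xmax, length.out = n)
  # dX1 = 0: X1 = 0 or (w + k1 b/2) X1 + (1 + k1 b/2) X2 + k1 a + k0 = 0
  lin <- function(swap) {
    A <- w + k1 * b / 2; B <- 1 + k1 * b / 2; Cc <- k1 * a + k0
    x2 <- -(A * s + Cc) / B
    d <- data.frame(X1 = s, X2 = x2)
    if (swap) d <- data.frame(X1 = d$X2, X2 = d$X1)
    d[d$X2 >= 0 & d$X1 >= 0, , drop = FALSE]
  }
  x1_br <- list(axis = data.frame(X1 = 0, X2 = s), interior = lin(FALSE))
  x2_br <- list(axis = data.frame(X1 = s, X2 = 0), interior = lin(TRUE))
  # (C, D) plane
  c_star <- -(k1 * a + k0) / (2 * w + k1 * b)
  dgrid <- seq(-xmax / 2, xmax / 2, length.out = n)
  dd_br <- list(D0 = data.frame(C = s, D = 0),
                vertical = data.frame(C = c_star, D = dgrid))
  cc <- s
  q <- -cc * ((w + 1) * cc + k1 * (a + b * cc) + k0) / (w - 1)
  dC_br <- if (abs(w - 1) < 1e-12) {
    cstar2 <- -(k1 * a + k0) / (w + 1 + k1 * b)
    list(vertical = data.frame(C = cstar2, D = dgrid))
  } else {
    ok <- q >= 0
    list(upper = data.frame(C = cc[ok], D = sqrt(q[ok])),
         lower = data.frame(C = cc[ok], D = -sqrt(q[ok])))
  }
  list(x1 = x1_br, x2 = x2_br, cd = list(dC = dC_br, dD = dd_br))
}

#' Read / write model parameter sets as key-value text
#'
#' Plain \code{key<TAB>value} serialization for \code{\link{lv_params}} and
#' \code{\link{yfit_params}} objects.
#'
#' @param x an \code{lv_params} or \code{yfit_params}.
#' @param file path.
#' @export
write_params <- function(x, file) {
  stopifnot(inherits(x, "lv_params") || inherits(x, "yfit_params"))
  vals <- unlist(x)
  lines <- c(paste0("class\t", class(x)[1]),
             paste0(names(vals), "\t", format(vals, digits = 17)))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  kv <- utils::read.table(file, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("key", "value"))
  cls <- kv$value[kv$key == "class"]
  kv <- kv[kv$key != "class", ]
  vals <- as.list(suppressWarnings(as.numeric(kv$value)))
  names(vals) <- kv$key
  structure(vals, class = cls)
}
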