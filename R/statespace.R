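#' Finite-difference derivative of a rate series
#'
#' Normalized first-order differences: forward difference divided by the
#' sampling interval (a centered variant is available). The returned series
#' is aligned with the first \code{n-1} (forward) or interior (centered)
#' samples of the input.
#'
#' @param x numeric series.
#' @param bin_ms sampling interval, ms.
#' @param method \code{"forward"} (default) or \code{"centered"}.
#' @return List with \code{d} (derivative, units of x per ms) and \code{idx}
#'   (indices of x to which each derivative sample belongs).
#' @export
estimate_derivatives <- function(x, bin_ms, method = c("forward", "centered")) {
  method <- match.arg(method)
  n <- length(x)
  if (method == "forward") {
    list(d = diff(x) / bin_ms, idx = seq_len(n - 1))
  } else {
    list(d = (x[-(1:2)] - x[1:(n - 2)]) / (2 * bin_ms), idx = 2:(n - 1))
  }
}

#' Empirical flow field over a two-dimensional rate state space
#'
#' Bins the sampled states on a regular grid and averages the observed
#' time derivatives within each bin, giving the empirical deterministic
#' drift. Bins with fewer than \code{min_count} samples are flagged
#' unusable (\code{NA}), never interpolated.
#'
#' @param x,y state coordinates (equal length).
#' @param dx,dy derivative samples at those states.
#' @param nx,ny grid resolution.
#' @param xlim,ylim grid extent; defaults to the occupied range.
#' @param min_count minimum samples for a usable bin.
#' @return An object of class \code{flow_field}: bin edges/centers, matrices
#'   \code{mean_dx}, \code{mean_dy}, \code{count}, and logical \code{usable}.
#' @export
estimate_flow <- function(x, y, dx, dy, nx = 30, ny = 30,
                          xlim = range(x), ylim = range(y), min_count = 5) {
  stopifnot(length(x) == length(y), length(x) == length(dx),
            length(x) == length(dy))
  # a constant series (e.g. the silent loser population of a WTA run)
  # gives a zero-width range; widen so the grid stays valid
  if (diff(xlim) <= 0) xlim <- xlim + c(-0.5, 0.5)
  if (diff(ylim) <= 0) ylim <- ylim + c(-0.5, 0.5)
  xe <- seq(xlim[1], xlim[2], length.out = nx + 1)
  ye <- seq(ylim[1], ylim[2], length.out = ny + 1)
  ix <- findInterval(x, xe, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, ye, rightmost.closed = TRUE, all.inside = TRUE)
  inside <- x >= xlim[1] & x <= xlim[2] & y >= ylim[1] & y <= ylim[2]
  cell <- (iy - 1L) * nx + ix
  cnt <- mdx <- mdy <- matrix(0, ny, nx)
  tc <- tapply(rep(1, sum(inside)), cell[inside], sum)
  idx <- as.integer(names(tc))
  cnt[cbind((idx - 1L) %/% nx + 1L, (idx - 1L) %% nx + 1L)] <- tc
  sdx <- tapply(dx[inside], cell[inside], sum)
  sdy <- tapply(dy[inside], cell[inside], sum)
  mdx[cbind((idx - 1L) %/% nx + 1L, (idx - 1L) %% nx + 1L)] <- sdx
  mdy[cbind((idx - 1L) %/% nx + 1L, (idx - 1L) %% nx + 1L)] <- sdy
  usable <- cnt >= min_count
  mdx <- ifelse(usable, mdx / cnt, NA_real_)
  mdy <- ifelse(usable, mdy / cnt, NA_real_)
  structure(list(x_edges = xe, y_edges = ye,
                 x_centers = (xe[-1] + xe[-(nx + 1)]) / 2,
                 y_centers = (ye[-1] + ye[-(ny + 1)]) / 2,
                 mean_dx = mdx, mean_dy = mdy, count = cnt, usable = usable,
                 cell_ix = ix, cell_iy = iy, inside = inside,
                 min_count = min_count),
            class = "flow_field")
}

#' Zero-level contours of an empirical flow field
#'
#' Extracts the empirical nullclines (marching-squares zero contours of the
#' binned mean derivatives) for each flow component, over usable bins only.
#'
#' @param flow a \code{\link{estimate_flow}} result.
#' @return List with \code{dx} and \code{dy}, each a list of contour curves
#'   (data frames with the grid coordinates \code{x}, \code{y}). Empty with
#'   a warning if a component never changes sign.
#' @export
empirical_nullclines <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  one <- function(z, label) {
    cl <- grDevices::contourLines(flow$x_centers, flow$y_centers,
                                  t(z), levels = 0)
    if (length(cl) == 0)
      warning("no zero-level contour found for ", label)
    lapply(cl, function(co) data.frame(x = co$x, y = co$y))
  }
  list(dx = one(flow$mean_dx, "d/dt of the first coordinate"),
       dy = one(flow$mean_dy, "d/dt of the second coordinate"))
}

#' Fit the slaved-rate relation Y = a + b C + f D^2
#'
#' Ordinary least squares fit of the shared-population rate on the mean and
#' squared half-difference of the competing rates, with a chi-square
#' goodness-of-fit test on the standardized residuals (20 equal-probability
#' normal bins). If \code{D} carries (numerically) no variance the quadratic
#' coefficient is unidentifiable and \code{f} is reported as \code{NA}.
#'
#' @param C,D,Y rate series, kHz (or a \code{\link{to_cd}} data frame as
#'   first argument).
#' @return An object of class \code{yfit} (extends
#'   \code{\link{yfit_params}}): coefficients \code{a}, \code{b}, \code{f},
#'   their standard errors, \code{chisq}, \code{p_value}, \code{n} and the
#'   underlying \code{lm} fit.
#' @export
fit_Y <- function(C, D = NULL, Y = NULL) {
  if (is.data.frame(C)) { Y <- C$Y; D <- C$D; C <- C$C }
  stopifnot(length(C) == length(D), length(C) == length(Y))
  if (length(C) < 100)
    stop("fit_Y requires at least 100 samples")
  D2 <- D^2
  rank_def <- stats::var(D2) < 1e-14 * max(stats::var(Y), 1e-300)
  if (rank_def) {
    fit <- stats::lm(Y ~ C)
    co <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
    a <- co[[1]]; b <- co[[2]]; f <- NA_real_
    se <- c(se, NA_real_)
  } else {
    fit <- stats::lm(Y ~ C + D2)
    co <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
    a <- co[[1]]; b <- co[[2]]; f <- co[[3]]
  }
  res <- stats::residuals(fit)
  gof <- .chisq_gof(res)
  structure(list(a = a, b = b, f = f, se = unname(se),
                 chisq = gof$stat, p_value = gof$p, n = length(C),
                 lm = fit),
            class = c("yfit", "yfit_params"))
}

# chi-square GOF: standardized residuals vs 20 equal-probability normal bins
.chisq_gof <- function(res, n_bins = 20) {
  z <- res / stats::sd(res)
  edges <- stats::qnorm(seq(0, 1, length.out = n_bins + 1))
  obs <- table(cut(z, edges))
  expd <- length(z) / n_bins
  stat <- sum((as.numeric(obs) - expd)^2 / expd)
  df <- n_bins - 1 - 2
  list(stat = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' @export
print.yfit <- function(x, ...) {
  cat(sprintf("Y = a + b C + f D^2: a = %.4f kHz, b = %.4f, f = %s ms  (n = %d)\n",
              x$a, x$b, if (is.na(x$f)) "undetermined" else sprintf("%.4f", x$f),
              x$n))
  cat(sprintf("  chi-square GOF: X2 = %.1f, p = %.3g\n", x$chisq, x$p_value))
  invisible(x)
}

#' State-dependent variance of the derivative residuals
#'
#' Per-bin variance of the difference between observed derivatives and the
#' local mean drift: flat for additive noise, increasing with the rate for
#' multiplicative noise. Samples near the saddle (absolute rate difference
#' \code{|x - y|} at most \code{2 * exclusion}) are excluded, because the
#' near-instantaneous switch transits inflate the local variance.
#'
#' @param x,y,dx,dy state and derivative samples, as in
#'   \code{\link{estimate_flow}}.
#' @param flow the \code{\link{estimate_flow}} field on the same samples.
#' @param exclusion saddle exclusion threshold on \code{|x - y|/2}, kHz.
#' @return An object of class \code{noise_field}: matrices \code{var_dx},
#'   \code{var_dy} (kHz^2/ms^2; \code{NA} where fewer than 2 residuals) and
#'   \code{count}.
#' @export
noise_variance <- function(x, y, dx, dy, flow, exclusion = 0.5) {
  stopifnot(inherits(flow, "flow_field"))
  nx <- length(flow$x_centers); ny <- length(flow$y_centers)
  keep <- flow$inside & abs(x - y) > 2 * exclusion
  ix <- flow$cell_ix[keep]; iy <- flow$cell_iy[keep]
  rx <- dx[keep] - flow$mean_dx[cbind(iy, ix)]
  ry <- dy[keep] - flow$mean_dy[cbind(iy, ix)]
  cell <- (iy - 1L) * nx + ix
  vfun <- function(r) {
    v <- tapply(r, cell, function(u) if (sum(!is.na(u)) >= 2)
      stats::var(u[!is.na(u)]) else NA_real_)
    m <- matrix(NA_real_, ny, nx)
    idx <- as.integer(names(v))
    m[cbind((idx - 1L) %/% nx + 1L, (idx - 1L) %% nx + 1L)] <- as.numeric(v)
    m
  }
  cnt <- matrix(0, ny, nx)
  tc <- tapply(rep(1, length(cell)), cell, sum)
  idx <- as.integer(names(tc))
  cnt[cbind((idx - 1L) %/% nx + 1L, (idx - 1L) %% nx + 1L)] <- tc
  structure(list(var_dx = vfun(rx), var_dy = vfun(ry), count = cnt,
                 x_centers = flow$x_centers, y_centers = flow$y_centers,
                 exclusion = exclusion),
            class = "noise_field")
}

#' Spearman correlation between bin rate and residual variance
#'
#' Summary of the state dependence of the noise: rank correlation between a
#' bin's coordinate (the rate whose derivative the variance belongs to) and
#' the per-bin residual variance, across usable bins. Positive values
#' indicate multiplicative (state-dependent) noise; values near zero,
#' additive noise.
#'
#' @param nf a \code{\link{noise_variance}} result.
#' @param component \code{"x"} (variance of the first coordinate's
#'   derivative vs its rate) or \code{"y"}.
#' @return Spearman's rho.
#' @export
noise_state_correlation <- function(nf, component = c("x", "y")) {
  component <- match.arg(component)
  if (component == "x") {
    v <- nf$var_dx
    coord <- matrix(nf$x_centers, nrow = length(nf$y_centers),
                    ncol = length(nf$x_centers), byrow = TRUE)
  } else {
    v <- nf$var_dy
    coord <- matrix(nf$y_centers, nrow = length(nf$y_centers),
                    ncol = length(nf$x_centers))
  }
  ok <- !is.na(v)
  stats::cor(coord[ok], v[ok], method = "spearman")
}

#' Joint histogram and correlation of two rate series
#'
#' @param a,b equal-length series.
#' @param nbins grid resolution.
#' @return List with the normalized 2-D histogram (\code{density}, summing
#'   to 1), bin edges, and the Pearson \code{correlation}.
#' @export
joint_hist <- function(a, b, nbins = 30) {
  stopifnot(length(a) == length(b))
  ae <- seq(min(a), max(a), length.out = nbins + 1)
  be <- seq(min(b), max(b), length.out = nbins + 1)
  ia <- findInterval(a, ae, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(b, be, rightmost.closed = TRUE, all.inside = TRUE)
  h <- matrix(0, nbins, nbins)
  tc <- tapply(rep(1, length(a)), (ib - 1L) * nbins + ia, sum)
  idx <- as.integer(names(tc))
  h[cbind((idx - 1L) %% nbins + 1L, (idx - 1L) %/% nbins + 1L)] <- tc
  list(density = h / length(a), a_edges = ae, b_edges = be,
       correlation = stats::cor(a, b))
}

#' Long-format export of flow and noise fields
#'
#' One row per grid bin: bin indices, bin-center coordinates, the per-bin
#' statistics and the sample count — ready for \code{write.table}.
#'
#' @param x a \code{flow_field} or \code{noise_field}.
#' @param ... unused.
#' @export
as.data.frame.flow_field <- function(x, ...) {
  nx <- length(x$x_centers); ny <- length(x$y_centers)
  data.frame(ix = rep(seq_len(nx), each = ny), iy = rep(seq_len(ny), nx),
             x = rep(x$x_centers, each = ny), y = rep(x$y_centers, nx),
             mean_dx = as.vector(x$mean_dx), mean_dy = as.vector(x$mean_dy),
             count = as.vector(x$count))
}

#' @rdname as.data.frame.flow_field
#' @export
as.data.frame.noise_field <- function(x, ...) {
  nx <- length(x$x_centers); ny <- length(x$y_centers)
  data.frame(ix = rep(seq_len(nx), each = ny), iy = rep(seq_len(ny), nx),
             x = rep(x$x_centers, each = ny), y = rep(x$y_centers, nx),
             var_dx = as.vector(x$var_dx), var_dy = as.vector(x$var_dy),
             count = as.vector(x$count))
}
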