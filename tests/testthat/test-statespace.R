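test_that("finite differences recover slopes exactly", {
  t <- seq(0, 100, by = 10)
  d <- estimate_derivatives(3 + 0.25 * t, 10)
  expect_equal(d$d, rep(0.25, 10))
  expect_equal(estimate_derivatives(rep(2, 8), 10)$d, rep(0, 7))
  # quadratic: forward difference of t^2 gives 2t + bin
  q <- estimate_derivatives(t^2, 10)
  expect_equal(q$d, 2 * t[-length(t)] + 10)
  # centered variant drops both ends
  ce <- estimate_derivatives(t^2, 10, method = "centered")
  expect_equal(ce$d, 2 * t[2:10])
})

test_that("flow binning averages a planted linear field within CLT error", {
  set.seed(20)
  n <- 60000
  x <- runif(n, 0, 4); y <- runif(n, 0, 4)
  dx <- (1.5 - x) + rnorm(n, 0, 0.3)
  dy <- (0.5 * y - 1) + rnorm(n, 0, 0.3)
  fl <- estimate_flow(x, y, dx, dy, nx = 10, ny = 10,
                      xlim = c(0, 4), ylim = c(0, 4))
  expect_equal(sum(fl$count), n)
  # per-bin means close to the field at bin centers (CLT: se ~ 0.3/sqrt(600))
  truth <- matrix(1.5 - fl$x_centers, 10, 10, byrow = TRUE)
  expect_lt(max(abs(fl$mean_dx - truth)), 0.12)
  # single point occupies exactly one bin and is below min_count
  f1 <- estimate_flow(1, 1, 0, 0, nx = 5, ny = 5, xlim = c(0, 4), ylim = c(0, 4))
  expect_equal(sum(f1$count), 1)
  expect_true(all(is.na(f1$mean_dx)))
})

test_that("empirical nullclines locate a planted zero line", {
  set.seed(21)
  n <- 80000
  x <- runif(n, 0, 4); y <- runif(n, 0, 4)
  dx <- (1.5 - x) + rnorm(n, 0, 0.2)
  dy <- (y - x) + rnorm(n, 0, 0.2)
  fl <- estimate_flow(x, y, dx, dy, nx = 20, ny = 20,
                      xlim = c(0, 4), ylim = c(0, 4))
  nc <- empirical_nullclines(fl)
  pts <- do.call(rbind, nc$dx)
  expect_gt(nrow(pts), 5)
  # vertical contour at x = 1.5 within one cell width
  expect_true(all(abs(pts$x - 1.5) <= 0.2 + 1e-9))
  # antisymmetric field: contour along the diagonal
  pts2 <- do.call(rbind, nc$dy)
  expect_lt(stats::median(abs(pts2$x - pts2$y)), 0.3)
  # a sign-definite field has no zero contour
  expect_warning(empirical_nullclines(
    estimate_flow(x, y, x + 1, dy, nx = 10, ny = 10)), "no zero-level")
})

test_that("the quadratic rate relation is recovered from planted data", {
  set.seed(22)
  n <- 5000
  C <- runif(n, 0.3, 1.5); D <- runif(n, -1.2, 1.2)
  Y <- 1.0 + 0.3 * C + 0.02 * D^2
  f0 <- suppressWarnings(fit_Y(C, D, Y))  # noiseless: summary.lm warns
  expect_equal(c(f0$a, f0$b, f0$f), c(1.0, 0.3, 0.02), tolerance = 1e-10)

  # unbiased under additive noise: recovery within 3 standard errors
  Yn <- Y + rnorm(n, 0, 0.05)
  fn <- fit_Y(C, D, Yn)
  expect_lt(abs(fn$a - 1.0), 3 * fn$se[1])
  expect_lt(abs(fn$b - 0.3), 3 * fn$se[2])
  expect_lt(abs(fn$f - 0.02), 3 * fn$se[3])
  expect_gt(fn$p_value, 1e-4)  # Gaussian residuals pass the GOF check

  # D identically zero: f is unidentifiable, reported as undetermined
  fd <- fit_Y(C, rep(0, n), 1 + 0.3 * C + rnorm(n, 0, 0.01))
  expect_true(is.na(fd$f))
  expect_equal(fd$b, 0.3, tolerance = 0.05)
  expect_error(fit_Y(1:10, 1:10, 1:10), "100 samples")
})

test_that("noise fields separate additive from multiplicative noise", {
  set.seed(23)
  n <- 200000
  x <- runif(n, 0.2, 4); y <- runif(n, 0.2, 4)
  drift_x <- 1.5 - x; drift_y <- 1.5 - y
  mk_nf <- function(dx, dy) {
    fl <- estimate_flow(x, y, dx, dy, nx = 40, ny = 40,
                        xlim = c(0, 4), ylim = c(0, 4), min_count = 50)
    noise_variance(x, y, dx, dy, fl, exclusion = 0)
  }
  nf_add <- mk_nf(drift_x + rnorm(n, 0, 0.3), drift_y + rnorm(n, 0, 0.3))
  nf_mul <- mk_nf(drift_x + x * rnorm(n, 0, 0.3), drift_y + y * rnorm(n, 0, 0.3))
  expect_lt(abs(noise_state_correlation(nf_add, "x")), 0.1)
  expect_gt(noise_state_correlation(nf_mul, "x"), 0.5)
  expect_gt(noise_state_correlation(nf_mul, "y"), 0.5)
  # zero-noise input gives (numerically) zero variance
  nf0 <- mk_nf(drift_x, drift_y)
  expect_lt(max(nf0$var_dx, na.rm = TRUE), 0.02)
  # saddle exclusion drops the |x - y| band
  nfex <- {
    fl <- estimate_flow(x, y, drift_x, drift_y, nx = 40, ny = 40,
                        xlim = c(0, 4), ylim = c(0, 4), min_count = 50)
    noise_variance(x, y, drift_x, drift_y, fl, exclusion = 0.5)
  }
  expect_equal(sum(nfex$count), sum(abs(x - y) > 1))
})

test_that("joint histograms normalize and report correlation", {
  set.seed(24)
  a <- rnorm(5000)
  jh <- joint_hist(a, a, nbins = 10)
  expect_equal(jh$correlation, 1)
  expect_equal(sum(jh$density), 1)
  b <- rnorm(5000)
  expect_lt(abs(joint_hist(a, b)$correlation), 0.05)
})

test_that("fields export as long-format tables", {
  set.seed(25)
  x <- runif(1000, 0, 2); y <- runif(1000, 0, 2)
  fl <- estimate_flow(x, y, 1 - x, 1 - y, nx = 4, ny = 5,
                      xlim = c(0, 2), ylim = c(0, 2))
  df <- as.data.frame(fl)
  expect_equal(nrow(df), 20)
  expect_equal(sum(df$count), 1000)
  nf <- noise_variance(x, y, 1 - x, 1 - y, fl, exclusion = 0)
  dn <- as.data.frame(nf)
  expect_named(dn, c("ix", "iy", "x", "y", "var_dx", "var_dy", "count"))
})
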