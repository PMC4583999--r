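printed_yfit <- function() yfit_params(1.112, 0.356, 0.014)

test_that("coupling matrices match their closed forms and the block table", {
  spec <- network_spec("EEI", w = 2.5)
  M <- coupling_matrix(spec)
  expect_equal(unname(M),
               0.2 * matrix(c(2.5, 1, -18, 1, 2.5, -18, 3, 3, -18), 3, 3,
                            byrow = TRUE))
  # the same matrix from the exact per-block degrees and weights
  bd <- block_degrees(spec)
  sizes <- c(E1 = 2000, E2 = 2000, I = 1000)
  M2 <- matrix(0, 3, 3)
  for (b in seq_len(nrow(bd))) {
    i <- match(bd$to[b], names(sizes)); j <- match(bd$from[b], names(sizes))
    M2[i, j] <- 20 * bd$in_deg[b] * bd$weight[b] / sizes[[bd$from[b]]]
  }
  expect_equal(unname(M), M2, tolerance = 1e-12)

  # EII: third row is tau*eps*J * (-pg, -pg, 1)
  M3 <- coupling_matrix(network_spec("EII", w = 0.7))
  expect_equal(unname(M3[3, ]), 0.2 * c(-18, -18, 1))
  expect_equal(unname(M3[1, 1]), 0.2 * (-3 * 0.7 * 6))
})

test_that("input moments follow the mean-field equations", {
  spec <- network_spec("EEI", w = 2.5)
  # zero rates: mean tau*J*r0, zero variance
  im0 <- input_moments(0, 0, 0, spec, r0 = 10.8)
  expect_equal(im0$mu, rep(20 * 0.1 * 10.8, 3))
  expect_equal(im0$sigma, rep(0, 3))
  # symmetry under swapping the competing populations
  im <- input_moments(0.9, 0.9, 1.3, spec, r0 = 10.8)
  expect_equal(im$mu[1], im$mu[2])
  expect_equal(im$sigma[1], im$sigma[2])
  # term-by-term hand expansion at the operating point (rates in kHz)
  r1 <- 0.9 / 2000; r2 <- 0.9 / 2000; r3 <- 1.3 / 1000
  mu1 <- 20 * (2000 * 0.1 * 2.5 * 0.1 * r1 + 2000 * 0.1 * 0.1 * r2 -
                 1000 * 3 * 0.1 * 6 * 0.1 * r3 + 0.1 * 10.8)
  sg1 <- sqrt(20 * 0.1 * (2000 * 0.1 * 2.5^2 * 0.1 * r1 +
                            2000 * 0.1 * 0.1 * r2 +
                            1000 * 3 * 0.1 * 6^2 * 0.1 * r3))
  expect_equal(im$mu[1], mu1, tolerance = 1e-12)
  expect_equal(im$sigma[1], sg1, tolerance = 1e-12)
})

test_that("the stationary low-rate formula evaluates as printed", {
  # direct evaluation oracle
  expect_equal(stationary_rate(15, 5, 20, 20),
               1 / (20 * sqrt(pi)) * exp(-1), tolerance = 1e-14)
  # r depends on (mu, sigma) only through u = (theta - mu)/sigma
  expect_equal(stationary_rate(10, 10, 20, 20), stationary_rate(15, 5, 20, 20))
  # vanishes as mu approaches threshold
  expect_lt(stationary_rate(20 - 1e-9, 2), 1e-10)
  expect_error(stationary_rate(21, 2), "mu < theta")
  # the diffusion variant halves the exponent
  expect_equal(stationary_rate(15, 5, variant = "diffusion"),
               1 / (20 * sqrt(pi)) * exp(-0.5), tolerance = 1e-14)
})

test_that("lv, cd and simplified forms are algebraically equivalent", {
  p <- lv_params()
  yf <- printed_yfit()
  # boundary behavior and symmetry of the full form
  expect_equal(lv_rhs(0, 1, 1, p)$dX1, p$h0)
  r <- lv_rhs(1.3, 0.4, 1.1, p); rs <- lv_rhs(0.4, 1.3, 1.1, p)
  expect_equal(r$dX1, rs$dX2)
  # D = 0 is invariant
  expect_equal(cd_rhs(1.2, 0, 0.9, p)$dD, 0)
  # w = 1 removes the D dependence of dC
  p1 <- lv_params(w = 1)
  expect_equal(cd_rhs(1, 0.5, 1, p1)$dC, cd_rhs(1, -0.2, 1, p1)$dC)

  # randomized equivalence property, 1000 positive states
  set.seed(10)
  X1 <- runif(1000, 0, 4); X2 <- runif(1000, 0, 4); Y <- runif(1000, 0, 3)
  lv <- lv_rhs(X1, X2, Y, p)
  cd <- cd_rhs((X1 + X2) / 2, (X1 - X2) / 2, Y, p)
  expect_lt(max(abs((lv$dX1 + lv$dX2) / 2 - cd$dC)), 1e-12)
  expect_lt(max(abs((lv$dX1 - lv$dX2) / 2 - cd$dD)), 1e-12)

  p0 <- p; p0$h0 <- 0
  Ylin <- yf$a + yf$b / 2 * (X1 + X2)
  lv0 <- lv_rhs(X1, X2, Ylin, p0)
  s2 <- simplified2d_rhs(X1, X2, yf, p)
  expect_lt(max(abs(lv0$dX1 - s2$dX1)), 1e-12)
  expect_lt(max(abs(lv0$dX2 - s2$dX2)), 1e-12)
})

test_that("fixed points match the printed formulas and classification", {
  p <- lv_params()  # w = 2.5 operating point
  yf <- printed_yfit()
  fp <- fixed_points(p, yf)
  att <- fp[fp$type == "attractor", ]
  sad <- fp[fp$type == "saddle", ]
  expect_equal(nrow(att), 2)
  expect_equal(nrow(sad), 1)
  # printed-formula values: axis (0, (pga - k0)/(w - pgb/2)), interior on the
  # diagonal at (pga - k0)/(w + 1 - pgb)
  pg <- 18
  ax <- (pg * yf$a - 22) / (2.5 - 0.5 * pg * yf$b)
  expect_equal(sort(att$X2), sort(c(0, ax)), tolerance = 1e-9)
  expect_equal(ax, 2.818, tolerance = 1e-3)
  expect_equal(sad$X1, (pg * yf$a - 22) / (3.5 - pg * yf$b), tolerance = 1e-9)
  expect_equal(sad$X1, sad$X2)
  expect_equal(sad$X1, 0.682, tolerance = 1e-3)
  # every returned point zeroes the field
  for (i in seq_len(nrow(fp))) {
    d <- simplified2d_rhs(fp$X1[i], fp$X2[i], yf, p)
    expect_lt(max(abs(c(d$dX1, d$dX2))), 1e-8)
  }
})

test_that("w = 1 degenerates to a single diagonal equilibrium", {
  fp <- fixed_points(lv_params(w = 1), yfit_params(1.12, 0.27, 0))
  expect_true(attr(fp, "degenerate"))
  nontrivial <- fp[!(fp$X1 == 0 & fp$X2 == 0), ]
  expect_equal(nrow(nontrivial), 1)
  expect_equal(nontrivial$X1, nontrivial$X2)
  expect_equal(nontrivial$type, "marginal")
  expect_false(any(fp$type == "saddle"))
})

test_that("analytic nullclines contain D = 0 and intersect at fixed points", {
  p <- lv_params(); yf <- printed_yfit()
  nc <- nullclines_analytic(p, yf)
  expect_true(all(nc$cd$dD$D0$D == 0))
  # the interior branches of the X1 and X2 nullclines cross at the saddle
  fp <- fixed_points(p, yf)
  sad <- fp[fp$type == "saddle", ]
  l1 <- nc$x1$interior
  # saddle lies on the dX1 = 0 interior line
  pred <- approx(l1$X1, l1$X2, xout = sad$X1)$y
  expect_equal(pred, sad$X2, tolerance = 1e-6)
  # w = 1: the nonzero C and D nullclines are parallel (both vertical lines)
  nc1 <- nullclines_analytic(lv_params(w = 1), yfit_params(1.12, 0.27, 0))
  expect_true(all(diff(nc1$cd$dC$vertical$C) == 0))
  expect_true(all(diff(nc1$cd$dD$vertical$C) == 0))
})

test_that("parameter sets round-trip through key-value text", {
  p <- lv_params(w = 2.75, k0 = 21)
  f <- file.path(tempdir(), "params.tsv")
  write_params(p, f)
  back <- read_params(f)
  expect_s3_class(back, "lv_params")
  expect_equal(back$w, 2.75)
  expect_equal(back$k0, 21)
  expect_true(is.na(back$k2))
  write_params(yfit_params(1.1, 0.3, 0.01), f)
  yb <- read_params(f)
  expect_equal(yb$f, 0.01)
})
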