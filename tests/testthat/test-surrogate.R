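test_that("deterministic integration matches a reference ODE solver", {
  p <- lv_params(); yf <- yfit_params(1.112, 0.356, 0.014)
  cfg <- surrogate_config(p, yf, noise = "none", T = 20, dt = 0.01,
                          output_dt = 0.1, init = c(2.0, 0.6))
  s <- integrate_sde(cfg, seed = 1)
  rhs <- function(t, y, parms) {
    Yv <- yf$a + yf$b * (y[1] + y[2]) / 2 + yf$f * ((y[1] - y[2]) / 2)^2
    d <- lv_rhs(y[1], y[2], Yv, p)
    list(c(d$dX1, d$dX2))
  }
  ref <- deSolve::ode(c(2.0, 0.6), seq(0, 20, by = 0.1), rhs, NULL,
                      rtol = 1e-12, atol = 1e-12)
  expect_lt(max(abs(s$X1 - ref[, 2])), 1e-6)
  expect_lt(max(abs(s$X2 - ref[, 3])), 1e-6)

  # long noiseless run of the pure competition system (h0 = 0, f = 0)
  # converges to one of its attractors
  p0 <- lv_params(h0 = 0)
  yf0 <- yfit_params(yf$a, yf$b, 0)
  cfg2 <- surrogate_config(p0, yf0, model = "simplified2d", noise = "none",
                           T = 500, dt = 0.01, init = c(2.0, 0.6))
  s2 <- integrate_sde(cfg2, seed = 1)
  fp <- fixed_points(p0, yf0)
  att <- fp[fp$type == "attractor", ]
  end <- c(tail(s2$X1, 1), tail(s2$X2, 1))
  dists <- apply(att[, c("X1", "X2")], 1, function(z) sqrt(sum((z - end)^2)))
  expect_lt(min(dists), 0.05)
})

test_that("D = 0 is an invariant manifold of the sum/difference form", {
  p <- lv_params(); yf <- yfit_params(1.112, 0.356, 0.014)
  cfg <- surrogate_config(p, yf, model = "cd", noise = "none", T = 100,
                          dt = 0.01, init = c(1.0, 1.0))  # X1 = X2 -> D = 0
  s <- integrate_sde(cfg, seed = 1)
  expect_true(all(abs(s$X1 - s$X2) < 1e-12))
})

test_that("identical seeds give identical surrogate series", {
  a <- generate_dataset("WLC", seed = 9, T = 2000)
  b <- generate_dataset("WLC", seed = 9, T = 2000)
  expect_identical(a$X1, b$X1)
  expect_identical(a$Y, b$Y)
  c2 <- generate_dataset("WLC", seed = 10, T = 2000)
  expect_false(identical(a$X1, c2$X1))
})

test_that("planted regimes carry the advertised fixed-point structure", {
  wlc <- attr(generate_dataset("WLC", seed = 1, T = 1000), "truth")
  expect_equal(sum(wlc$fixed_points$type == "attractor"), 2)
  expect_equal(sum(wlc$fixed_points$type == "saddle"), 1)
  er <- attr(generate_dataset("ER", seed = 1, T = 1000), "truth")
  expect_equal(sum(er$fixed_points$type == "attractor"), 1)
  # multiplicative WLC surrogates actually alternate between the attractors
  s <- generate_dataset("WLC", seed = 2, T = 60000)
  rec <- detect_switches(savgol_smooth((s$X1 - s$X2) / 2), 0.5, s$time)
  expect_gt(rec$n_switches, 5)
})

test_that("step-size instability aborts with a diagnostic", {
  p <- lv_params(k = 50)  # absurd gain makes Euler blow up
  cfg <- surrogate_config(p, yfit_params(1, 0.3, 0), noise = "additive",
                          eta = 2, dt = 0.5, T = 500, output_dt = 0.5,
                          init = c(3, 0.1))
  expect_error(integrate_sde(cfg, seed = 1), "instability|diverged")
})
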