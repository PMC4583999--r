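test_that("DC current converts to drive and equivalent Poisson rate", {
  expect_equal(dc_to_drive(0)$drive, 0)
  expect_equal(dc_to_drive(0)$r0, 0)
  # 270 pA through 20 ms / 250 pF = 21.6 mV; r0 = drive / (tau J)
  conv <- dc_to_drive(270, neuron_params(tau = 20, C_m = 250), J = 0.1)
  expect_equal(conv$drive, 21.6)
  expect_equal(conv$r0, 10.8)
})

test_that("subthreshold dynamics follow the exact exponential solution", {
  g <- lone_neuron_graph()
  np <- neuron_params(t_ref = 0)
  ras <- simulate_lif(g, T = 50, params = np, drive = 0, t_d = 0.1,
                      v_init = 15)
  expect_length(ras$times, 0)
  expect_equal(ras$v_final, 15 * exp(-50 / 20), tolerance = 1e-12)

  # with subthreshold drive, still no spikes, exact relaxation toward drive
  ras2 <- simulate_lif(g, T = 200, params = np, drive = 18, v_init = 2)
  expect_length(ras2$times, 0)
  expect_equal(ras2$v_final, 18 + (2 - 18) * exp(-200 / 20), tolerance = 1e-10)
})

test_that("suprathreshold drive reproduces the closed-form ISI", {
  g <- lone_neuron_graph()
  np <- neuron_params(t_ref = 0)
  ras <- simulate_lif(g, T = 2000, params = np, drive = 21.6, v_init = 10)
  isi <- diff(ras$times)
  isi_theory <- 20 * log((21.6 - 10) / (21.6 - 20))  # ~39.6 ms
  expect_true(all(abs(isi - isi_theory) <= 0.1 + 1e-9))
  # spike times live on the grid, in [0, T)
  expect_true(all(ras$times >= 0 & ras$times < 2000))
  expect_true(all(diff(ras$times) > 0))
})

test_that("delta synapses deliver exactly their weight after one delay step", {
  # A drives B: A spikes (initialized above threshold), B passive, no drive
  g <- lone_neuron_graph(2, edges = list(i = 1, j = 2, x = 0.1))
  np <- neuron_params(t_ref = 0)
  # T = 0.2 ms = 2 steps: A fires in step 0, B receives 0.1 mV in step 1
  ras <- simulate_lif(g, T = 0.2, params = np, drive = 0, v_init = c(25, 0))
  expect_equal(ras$times, 0)
  expect_equal(ras$ids, 1L)
  expect_equal(ras$v_final[2], 0.1, tolerance = 1e-12)
  # one more step: the pulse then decays
  ras3 <- simulate_lif(g, T = 0.3, params = np, drive = 0, v_init = c(25, 0))
  expect_equal(ras3$v_final[2], 0.1 * exp(-0.1 / 20), tolerance = 1e-12)
})

test_that("refractory period enforces a minimum inter-spike interval", {
  g <- lone_neuron_graph()
  np <- neuron_params(t_ref = 2)
  ras <- simulate_lif(g, T = 2000, params = np, drive = 30, v_init = 10)
  expect_true(all(diff(ras$times) >= 2))
})

test_that("rasters round-trip through the text format", {
  g <- lone_neuron_graph()
  ras <- simulate_lif(g, T = 300, params = neuron_params(t_ref = 0),
                      drive = 21.6, v_init = 10)
  base <- file.path(tempdir(), "rastest")
  write_raster(ras, base)
  back <- read_raster(base, T = 300)
  expect_equal(back$times, ras$times)
  expect_equal(back$ids, ras$ids)
})

test_that("the full network operates below threshold on average", {
  run <- eei_w25_run()
  # fluctuation-driven regime: mean membrane potential below threshold
  expect_lt(mean(run$raster$v_final), 20)
})
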