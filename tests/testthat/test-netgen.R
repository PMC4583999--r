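test_that("block degree tables encode the stated connection fractions", {
  bd <- block_degrees(network_spec("EEI", w = 2.5))
  get <- function(from, to) bd[bd$from == from & bd$to == to, ]

  # within-E and across-E blocks: 10% of 2000
  expect_equal(get("E1", "E1")$in_deg, 200)
  expect_equal(get("E1", "E2")$in_deg, 200)
  expect_equal(get("E1", "E1")$weight, 2.5 * 0.1)
  expect_equal(get("E1", "E2")$weight, 0.1)
  # every excitatory neuron receives 300 inhibitory inputs -> out-degree 600
  expect_equal(get("I", "E1")$in_deg, 300)
  expect_equal(get("I", "E1")$out_deg, 600)
  expect_equal(get("I", "E1")$weight, -0.6)
  # total in-degrees implied by the fractions
  in_E <- sum(bd$in_deg[bd$to == "E1"])
  in_I <- sum(bd$in_deg[bd$to == "I"])
  expect_equal(in_E, 700)
  expect_equal(in_I, 1500)
  # edge-count consistency of every block
  expect_true(all(bd$n_from * bd$out_deg == bd$n_to * bd$in_deg))

  bd2 <- block_degrees(network_spec("EII", w = 0.7))
  g2 <- function(from, to) bd2[bd2$from == from & bd2$to == to, ]
  # E projects to 150 neurons in each inhibitory population -> in-degree 1200
  expect_equal(g2("E", "I1")$out_deg, 150)
  expect_equal(g2("E", "I1")$in_deg, 1200)
  # within-I weight is -w*g*J
  expect_equal(g2("I1", "I1")$weight, -0.7 * 6 * 0.1)
  expect_equal(g2("I1", "I2")$weight, -0.6)
})

test_that("fractional degrees are a hard error naming the block", {
  spec <- network_spec("EEI", w = 2.5, N_E = 1995, N_I = 1000)
  expect_error(block_degrees(spec), "E1")
})

test_that("invalid scenario/weight combinations are rejected", {
  expect_error(network_spec("EEI", w = 0.5), "w >= 1")
  expect_error(network_spec("EII", w = 1.5), "w <= 1")
})

test_that("sample_block meets margins exactly, including forced cases", {
  # (2,2,1,1) without self-edges: the antidiagonal is the only derangement
  b <- suppressWarnings(sample_block(2, 2, 1, 1, forbid_diagonal = TRUE, seed = 5))
  expect_equal(as.matrix(b), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)

  b4 <- suppressWarnings(sample_block(4, 4, 2, 2, forbid_diagonal = TRUE, seed = 7))
  expect_equal(unname(Matrix::rowSums(b4)), rep(2, 4))
  expect_equal(unname(Matrix::colSums(b4)), rep(2, 4))
  expect_equal(sum(Matrix::diag(b4)), 0)

  # rectangular block with distinct margins
  br <- suppressWarnings(sample_block(20, 10, 3, 6, seed = 11))
  expect_equal(unname(Matrix::rowSums(br)), rep(3, 20))
  expect_equal(unname(Matrix::colSums(br)), rep(6, 10))

  expect_error(sample_block(3, 3, 2, 1), "infeasible")
})

test_that("swap randomization approximates uniform edge frequencies", {
  # downscaled Monte-Carlo uniformity oracle: in a (40, 40, 4, 4) block every
  # off-diagonal entry should appear with frequency ~ density 0.1
  n <- 40; deg <- 4
  acc <- matrix(0, n, n)
  for (s in 1:300)
    acc <- acc + as.matrix(sample_block(n, n, deg, deg, TRUE, seed = s))
  freq <- acc / 300
  off <- freq[row(freq) != col(freq)]
  expect_equal(mean(off), deg / (n - 1), tolerance = 0.02)
  # no entry is frozen in or out
  expect_lt(max(off), 0.35)
  expect_equal(sum(diag(acc)), 0)
})

test_that("assembled networks have exact margins, Dale signs, zero trace", {
  spec <- network_spec("EEI", w = 2.5, N_E = 200, N_I = 100, I_DC = 270)
  net <- assemble_network(spec, seed = 3)
  bd <- block_degrees(spec)
  m <- net$membership
  for (b in seq_len(nrow(bd))) {
    blk <- bd[b, ]
    sub <- net$W[m == blk$from, m == blk$to, drop = FALSE]
    expect_true(all(Matrix::rowSums(sub != 0) == blk$out_deg),
                label = paste("row sums", blk$from, blk$to))
    expect_true(all(Matrix::colSums(sub != 0) == blk$in_deg),
                label = paste("col sums", blk$from, blk$to))
    expect_true(all(sub@x == blk$weight))
  }
  expect_equal(sum(Matrix::diag(net$W)), 0)
  # Dale's principle on rows
  exc <- which(m %in% c("E1", "E2"))
  expect_true(all(net$W[exc, ] >= 0))
  expect_true(all(net$W[-exc, ] <= 0))
  # reproducibility from the master seed
  net2 <- assemble_network(spec, seed = 3)
  expect_identical(Matrix::summary(net$W), Matrix::summary(net2$W))
})

test_that("networks round-trip through the triplet text format", {
  spec <- network_spec("EEI", w = 1.5, N_E = 40, N_I = 20)
  net <- assemble_network(spec, seed = 2)
  base <- file.path(tempdir(), "nettest")
  write_network(net, base)
  back <- read_network(base)
  expect_equal(as.matrix(back$W), as.matrix(net$W), ignore_attr = TRUE)
  expect_equal(as.character(back$membership), as.character(net$membership))
})
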