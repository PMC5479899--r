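test_that("input normalization matches the closed form and conserves A", {
  # hand evaluation: D=4, A=8, ytilde=[1,1,2,0] -> y=[2,2,3,1]
  expect_equal(normalize_input(c(1, 1, 2, 0), A = 8), c(2, 2, 3, 1))

  # uniform input: every y_d = (A-D)/D + 1, sum = A
  y <- normalize_input(rep(7, 10), A = 50)
  expect_equal(y, rep(5, 10))

  set.seed(1)
  for (i in 1:20) {
    v <- runif(16, 0, 255); v[sample(16, 3)] <- 0
    y <- normalize_input(v, A = 132)
    expect_equal(sum(y), 132, tolerance = 1e-12)
    expect_true(all(y >= 1))
  }
})

test_that("normalization is invariant to positive rescaling (contrast)", {
  v <- c(3, 0, 10, 250, 1, 1)
  expect_identical(normalize_input(2 * v, A = 20),
                   normalize_input(v, A = 20))       # exact for power of 2
  expect_equal(normalize_input(3 * v, A = 20), normalize_input(v, A = 20),
               tolerance = 1e-14)
  # matrix form agrees with row-wise application
  m <- rbind(v, 5 * v)
  Y <- normalize_input(m, A = 20)
  expect_equal(Y[1, ], Y[2, ], tolerance = 1e-14)
})

test_that("normalization rejects degenerate input", {
  expect_error(normalize_input(rep(0, 5), A = 10), "zero total")
  expect_error(normalize_input(c(-1, 2), A = 10), "non-negative")
  expect_error(normalize_input(1:5, A = 3), "exceed")
})

test_that("linearised-log transfer is continuous, monotone and pinned", {
  expect_equal(transfer_fn(1), 1)
  expect_equal(transfer_fn(0), 0)
  expect_equal(transfer_fn(exp(1)), 2)
  # continuity at the branch point
  expect_equal(transfer_fn(1 - 1e-9), transfer_fn(1 + 1e-9),
               tolerance = 1e-8)
  # non-decreasing on a fine grid
  g <- transfer_fn(seq(0, 5, by = 0.01))
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0))
  expect_error(transfer_fn(-0.1), "non-negative")
})

test_that("integration is the transfer-weighted sum", {
  expect_equal(integrate_input(c(1, 2), matrix(c(1, exp(1)), 1)), 5)
  W0 <- matrix(0, 3, 4)
  expect_equal(integrate_input(rep(2, 4), W0), rep(0, 3))
  # identical rows give identical integrated inputs
  W <- matrix(rep(runif(5, 0.5, 3), each = 3), 3, 5)
  I <- integrate_input(runif(5, 1, 4), W)
  expect_equal(max(I) - min(I), 0)
  expect_error(integrate_input(1:3, matrix(1, 2, 4)), "mismatch")
})

test_that("lateral inhibition is a stable softmax on the simplex", {
  expect_equal(lateral_inhibition(rep(2, 7)), rep(1 / 7, 7))
  expect_equal(lateral_inhibition(c(0, log(3))), c(0.25, 0.75))
  # shift invariance
  I <- c(1.3, -0.2, 5)
  expect_equal(lateral_inhibition(I + 100), lateral_inhibition(I))
  # extreme magnitudes do not overflow
  s <- lateral_inhibition(c(1e4, 0, -1e4))
  expect_equal(sum(s), 1)
  expect_false(anyNA(s))
  # tau -> 0 approaches one-hot at the argmax
  s0 <- lateral_inhibition(c(1, 2, 1.99), tau = 1e-4)
  expect_equal(s0[2], 1, tolerance = 1e-6)
  # tau = 1 default equals explicit
  expect_equal(lateral_inhibition(I, 1), lateral_inhibition(I))
})

test_that("exploration noise has the declared distribution", {
  I <- c(1, 2, 3)
  expect_identical(inject_noise(I, 0), I)
  set.seed(7)
  draws <- replicate(4e4, inject_noise(I, 2.5)[1] - I[1])
  expect_equal(var(draws), 2.5, tolerance = 0.03 * 2.5)
  expect_equal(mean(draws), 0, tolerance = 0.05)
  set.seed(11); a <- inject_noise(I, 1)
  set.seed(11); b <- inject_noise(I, 1)
  expect_identical(a, b)
})

test_that("the Hebbian update has the stated fixed point and scaling", {
  y <- c(2, 2, 3, 1)
  W <- rbind(y, c(1, 1, 1, 1))
  s <- c(0.6, 0.4)
  W2 <- hebbian_update(W, s, y, epsilon = 0.1)
  expect_equal(W2[1, ], y)                       # row at y is a fixed point
  # the other row moves by epsilon * s_c * (y - W) exactly
  expect_equal(W2[2, ] - W[2, ], 0.1 * 0.4 * (y - W[2, ]))

  # scalar hand example: 2 + 0.5 * (4 - 2) = 3
  expect_equal(hebbian_update(matrix(2), 1, 4, 0.5)[1, 1], 3)

  # modulator 0 is a no-op
  expect_identical(hebbian_update(W, s, y, 0.1, modulator = 0), W)
  expect_error(hebbian_update(W, s, y, 0.1, modulator = NaN), "finite")
})

test_that("weights stay above the floor under negative modulation", {
  set.seed(3)
  W <- matrix(runif(20, 0.5, 2), 4, 5)
  y <- runif(5, 1, 3)
  for (i in 1:50)
    W <- hebbian_update(W, rep(0.25, 4), y, epsilon = 0.5, modulator = -2,
                        weight_floor = 1e-8)
  expect_true(all(W >= 1e-8))
})

test_that("weight initialization is scaled to A and reproducible", {
  cfg <- network_config(D = 64, C = 8, K = 4, A = 180, seed = 5)
  W <- init_weights(cfg)
  expect_true(all(abs(rowSums(W) - 180) / 180 < 0.05))
  expect_true(all(W >= cfg$weight_floor))
  expect_identical(init_weights(cfg), W)
  cfg2 <- cfg; cfg2$seed <- 6L
  expect_false(identical(init_weights(cfg2), W))
})

test_that("network_config validates its constraints", {
  expect_error(network_config(D = 100, A = 90), "A > D")
  expect_error(network_config(D = 10, epsilon = 0), "epsilon")
  expect_error(network_config(D = 10, tau = -1), "tau")
  cfg <- network_config(D = 784)
  expect_equal(cfg$A, 900)   # A - D = 116 regardless of size
})
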