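test_that("preferred classes come from B columns with low-index ties", {
  B <- diag(4)
  expect_equal(preferred_class(B), 0:3)
  expect_equal(preferred_class(matrix(1, 3, 5)), rep(0L, 5))
  expect_equal(preferred_class(matrix(c(0.4, 0.6), 2, 1)), 1L)
})

test_that("a frequency prior reweights preferences toward exposure", {
  # the unit responds slightly more to the rare class 1...
  B <- matrix(c(0.4, 0.6), 2, 1)
  expect_equal(preferred_class(B), 1L)
  # ...but under a 10:1 exposure prior its modal class is 0
  expect_equal(preferred_class(B, prior = c(10, 1)), 0L)
})

test_that("preference histograms conserve the neuron count", {
  set.seed(9)
  for (i in 1:10) {
    B <- matrix(runif(5 * 12), 5, 12)
    h <- preference_histogram(preferred_class(B), 5)
    expect_equal(sum(h), 12)
  }
})

test_that("selectivity matches its defining ratio and bounds", {
  # equal responses: zeta = 0 ; exclusive responses: zeta = 1
  mr <- rbind(c(0.5, 0.5, 0.5), c(0.9, 0, 0), c(0.8, 0.2, 0.2))
  z <- selectivity(mr, min_response = 0)
  expect_equal(z$zeta_per_neuron, c(0, 1, 0.75))
  expect_equal(z$zeta_mean, mean(c(0, 1, 0.75)))
  # zeta is invariant to scaling a neuron's responses
  z2 <- selectivity(mr * 3, min_response = 0)
  expect_equal(z2$zeta_per_neuron, z$zeta_per_neuron)
  # values stay in [0, 1] when preferences are the response argmax
  set.seed(10)
  mrr <- matrix(runif(40), 8, 5)
  zr <- selectivity(mrr, min_response = 0)$zeta_per_neuron
  expect_true(all(zr >= 0 & zr <= 1))
})

test_that("per-class selectivity sums over preferring neurons", {
  mr <- rbind(c(0.9, 0.1), c(0.8, 0.4), c(0.1, 0.5))
  z <- selectivity(mr, min_response = 0)
  expect_equal(z$zeta_per_class[1],
               sum(z$zeta_per_neuron[1:2]))
  expect_equal(z$zeta_per_class[2], z$zeta_per_neuron[3])
})

test_that("the responsiveness floor excludes dormant units", {
  mr <- rbind(c(0.9, 0.1, 0.1), c(0.01, 0.005, 0.004))
  z <- selectivity(mr)          # default floor 1/C = 1/2 here
  expect_false(is.na(z$zeta_per_neuron[1]))
  expect_true(is.na(z$zeta_per_neuron[2]))
  expect_equal(z$zeta_mean, z$zeta_per_neuron[1])
})

test_that("per-class accuracy aggregates exactly to the overall rate", {
  out <- per_class_accuracy(c(0L, 1L, 1L), c(0L, 0L, 1L), K = 2)
  expect_equal(out$per_class, c(0.5, 1))
  expect_equal(out$overall, 2 / 3)
  # frequency-weighted identity on random data
  set.seed(11)
  labels <- sample(0:3, 200, replace = TRUE)
  dec <- sample(0:3, 200, replace = TRUE)
  pc <- per_class_accuracy(dec, labels, 4)
  freq <- tabulate(labels + 1, 4) / 200
  expect_equal(sum(pc$per_class * freq), pc$overall)
  # absent class is reported missing
  expect_true(is.na(per_class_accuracy(0L, 0L, K = 3)$per_class[3]))
})

test_that("confidence-accuracy binning recovers a built-in monotone relation", {
  K <- 5
  centers <- seq(1 / K + 0.01, 0.99, by = 0.02)
  kappas <- rep(centers, each = 50)
  # per-bin accuracy constructed to equal the bin centre
  flags <- unlist(lapply(centers, function(c) {
    n1 <- round(50 * c); c(rep(1, n1), rep(0, 50 - n1))
  }))
  rel <- confidence_accuracy_relation(kappas, flags, K)
  expect_gt(rel$r, 0.999)
  # all-correct flags leave no variance: correlation undefined
  rel2 <- confidence_accuracy_relation(kappas, rep(1, length(kappas)), K)
  expect_true(is.na(rel2$r))
  # fewer than two occupied bins: undefined
  rel3 <- confidence_accuracy_relation(rep(0.5, 10), rep(1, 10), K)
  expect_true(is.na(rel3$r))
})

test_that("count-performance correlation matches the closed form", {
  expect_equal(count_performance_correlation(c(1, 2, 3), c(0.5, 0.5, 0.8)),
               0.8660254, tolerance = 1e-6)
  expect_equal(count_performance_correlation(1:4, c(0.1, 0.2, 0.3, 0.4)), 1)
  expect_equal(count_performance_correlation(1:4, c(0.4, 0.3, 0.2, 0.1)), -1)
  expect_true(is.na(count_performance_correlation(c(2, 2, 2), c(0.1, 0.5, 0.9))))
})

test_that("class distance ordering starts at the reference and is stable", {
  # three classes at known 1-D positions 0, 3, 4 (constant images)
  imgs <- rbind(matrix(c(10, 0), 2, 2, byrow = TRUE),
                matrix(c(10, 30), 2, 2, byrow = TRUE),
                matrix(c(10, 40), 2, 2, byrow = TRUE))
  d <- hebb_dataset(imgs, rep(0:2, each = 2))
  ord <- class_distance_order(d, 0L)
  expect_equal(ord$order, c(0L, 1L, 2L))
  expect_equal(ord$distance[1], 0)
  expect_equal(ord$distance, c(0, 30, 40))
  # ties keep class-index order
  d2 <- hebb_dataset(rbind(c(1, 5), c(1, 5), c(2, 9)), c(0L, 1L, 2L))
  expect_equal(class_distance_order(d2, 1L)$order[1:2], c(1L, 0L))
})

test_that("representation reports are internally consistent", {
  d <- tiny_dataset(200, seed = 3)
  te <- tiny_dataset(100, seed = 14)
  fit <- hebbnet(d, test = te, C = 6, pretrain_epochs = 4, epochs = 0,
                 seed = 3)
  rep <- representation_report(fit, te)
  expect_equal(sum(rep$histogram), 6)
  expect_equal(rep$overall_accuracy,
               per_class_accuracy(predict(fit, te), te$labels, 3)$overall)
  z <- rep$zeta_per_neuron
  expect_true(all(is.na(z) | (z >= 0 & z <= 1)))
})
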