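test_that("generation is deterministic given the spec seed", {
  a <- tiny_dataset(50, seed = 9)
  b <- tiny_dataset(50, seed = 9)
  expect_identical(a, b)
  c <- tiny_dataset(50, seed = 10)
  expect_false(identical(a$images, c$images))
})

test_that("noise-free generation reproduces the class prototypes exactly", {
  spec <- tiny_spec(within_class_noise_sd = 0)
  d <- generate_synthetic_digits(spec, 30)
  protos <- neurohebb:::effective_prototypes(spec)
  for (i in seq_len(30))
    expect_equal(d$images[i, ], protos[d$labels[i] + 1L, ])
})

test_that("prototype_overlap spans disjoint support to identical classes", {
  # overlap 0: class supports are pairwise disjoint
  spec0 <- tiny_spec(prototype_overlap = 0)
  p0 <- neurohebb:::effective_prototypes(spec0)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(sum(p0[i, ] > 0 & p0[j, ] > 0), 0)

  # overlap 1: all prototypes identical, between-class mean distance 0
  spec1 <- tiny_spec(prototype_overlap = 1, within_class_noise_sd = 0)
  d1 <- generate_synthetic_digits(spec1, 60)
  m <- sapply(0:2, function(k) colMeans(d1$images[d1$labels == k, , drop = FALSE]))
  expect_equal(max(dist(t(m))), 0)
})

test_that("hard pair collocates two classes without touching the others", {
  spec <- tiny_spec(n_classes = 4L, image_side = 8L,
                    hard_pair = list(classes = c(2L, 3L), mix = 0.9))
  base <- tiny_spec(n_classes = 4L, image_side = 8L)
  p <- neurohebb:::effective_prototypes(spec)
  pb <- neurohebb:::effective_prototypes(base)
  expect_equal(p[1:3, ], pb[1:3, ])          # classes 0-2 unchanged
  d <- as.matrix(dist(p))
  expect_lt(d[3, 4], min(d[1, 2], d[1, 3], d[2, 4]))  # pair is the closest
})

test_that("empirical class frequencies follow class_probs", {
  probs <- c(0.5, 0.3, 0.2)
  d <- generate_synthetic_digits(tiny_spec(class_probs = probs, seed = 3), 1e4)
  counts <- tabulate(d$labels + 1L, 3L)
  expect_gt(stats::chisq.test(counts, p = probs)$p.value, 0.001)
})

test_that("translation jitter moves mass without leaving the frame", {
  d <- tiny_dataset(40, translation_jitter = 2L, within_class_noise_sd = 0)
  expect_true(all(d$images >= 0 & d$images <= 255))
  expect_true(all(rowSums(d$images) > 0))
})

test_that("non-uniform construction hits the requested count ratio", {
  base <- tiny_dataset(1830, seed = 5)  # roughly 600 per class
  nu <- build_nonuniform_dataset(base, kept_classes = 0:2,
                                 overrepresented = 0L, factor = 60)
  counts <- tabulate(nu$labels + 1L, 3L)
  expect_equal(counts[1] / counts[2], 60)
  expect_equal(counts[2], counts[3])

  # factor 1 balances all kept classes
  eq <- build_nonuniform_dataset(base, 0:2, 0:2, factor = 1)
  expect_equal(length(unique(tabulate(eq$labels + 1L, 3L))), 1L)

  # unachievable ratio errors out
  expect_error(build_nonuniform_dataset(base, 0:2, 0L, factor = 1e6),
               "achievable")
})

test_that("non-uniform construction can subsample to exact integer counts", {
  base <- tiny_dataset(1830, seed = 7)
  n0 <- min(tabulate(base$labels + 1L, 3L)[1])
  nu <- build_nonuniform_dataset(base, 0:2, 0L, factor = 60)
  expect_equal(sum(nu$labels == 1L), floor(n0 / 60))
})

test_that("balance_test_dataset keeps classes uniform", {
  base <- tiny_dataset(700, seed = 11)
  bt <- balance_test_dataset(base, 0:2)
  expect_equal(length(unique(tabulate(bt$labels + 1L, 3L))), 1L)
})

test_that("label masking is stratified and seed-stable", {
  d <- tiny_dataset(200, seed = 2)
  m <- mask_labels(d, 0.1, seed = 4)
  expect_equal(sum(m$label_available), round(0.1 * 200))
  # every class keeps at least one label
  for (k in 0:2)
    expect_gte(sum(m$label_available[m$labels == k]), 1L)
  expect_identical(mask_labels(d, 0.1, seed = 4)$label_available,
                   m$label_available)
  # full fraction is a no-op on the flags
  expect_true(all(mask_labels(d, 1)$label_available))
  # budget below the class count warns
  d30 <- tiny_dataset(30, seed = 2)
  expect_warning(mask_labels(d30, 0.05, seed = 1), "label budget")
})
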