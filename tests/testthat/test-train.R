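test_that("zero presentations leave the state untouched", {
  d <- tiny_dataset(60)
  net <- tiny_net(d)
  out <- train_hebbian(net, d, 0)
  expect_identical(out$W, net$W)
  expect_identical(out$clf$B, net$clf$B)
  expect_equal(out$images_seen, 0L)
})

test_that("a flat ACh schedule reproduces the Hebbian trajectory bit for bit", {
  d <- tiny_dataset(150)
  net <- tiny_net(d)
  # alpha = 2, beta = 0 makes ACh identically 1
  heb <- train_hebbian(net, d, 450, seed = 31)
  ach <- train_with_ach(net, d, 450, ach = ach_params(alpha = 2, beta = 0),
                        seed = 31)
  expect_identical(ach$W, heb$W)
  expect_identical(ach$clf$B, heb$clf$B)
})

test_that("a unit DA schedule without noise reproduces the Hebbian trajectory", {
  d <- tiny_dataset(150)
  net <- tiny_net(d)
  heb <- train_hebbian(net, d, 450, seed = 32)
  da1 <- train_with_da(net, d, 450,
                       da = da_params(delta_pp = 1, delta_pm = 1,
                                      delta_mp = 1, delta_mm = 1,
                                      upsilon = 0),
                       seed = 32)
  expect_identical(da1$W, heb$W)
  expect_identical(da1$clf$B, heb$clf$B)
})

test_that("an all-zero DA profile freezes W while B keeps refreshing", {
  d <- tiny_dataset(150)
  net <- tiny_net(d)
  out <- train_with_da(net, d, 300,
                       da = da_params(delta_pp = 0, delta_pm = 0,
                                      delta_mp = 0, delta_mm = 0),
                       seed = 33)
  expect_identical(out$W, net$W)
  expect_false(identical(out$clf$B, net$clf$B))
})

test_that("greedy DA never explores and only sees predicted scenarios", {
  d <- tiny_dataset(200)
  net <- tiny_net(d)
  out <- train_with_da(net, d, 400, da = da_params(greedy = TRUE),
                       test = d, seed = 34)
  expect_true(all(out$log$exploration_rate == 0))
  expect_true(all(out$log$n_mp == 0))
  expect_true(all(out$log$n_mm == 0))
  expect_true(all(out$log$n_pp + out$log$n_pm == 100))
})

test_that("scenario counts account for every reward-evaluated trial", {
  d <- tiny_dataset(200)
  d <- mask_labels(d, 0.5, seed = 2)
  net <- tiny_net(d)
  out <- train_with_da(net, d, 400, seed = 35)
  evaluated <- with(out$log, n_pp + n_pm + n_mp + n_mm)
  # only labeled stimuli are reward-evaluated; refresh window is 100 images
  expect_true(all(evaluated <= 100))
  expect_gt(sum(evaluated), 0)
})

test_that("Hebbian learning is label-blind", {
  d <- tiny_dataset(150)
  d2 <- d
  set.seed(8); d2$labels <- sample(d2$labels)
  net <- tiny_net(d)
  a <- train_hebbian(net, d, 300, seed = 36)
  b <- train_hebbian(net, d2, 300, seed = 36)
  expect_identical(a$W, b$W)
  expect_false(identical(a$clf$B, b$clf$B))
})

test_that("repeated presentation of one stimulus drives the winner to y", {
  img <- tiny_dataset(1, seed = 4)
  net <- tiny_net(img, epsilon = 0.05)
  out <- train_hebbian(net, img, ceiling(10 / 0.05), seed = 37)
  y <- normalize_input(img$images[1, ], net$config$A)
  I <- integrate_input(y, out$W)
  winner <- which.max(I)
  expect_lt(max(abs(out$W[winner, ] - y)), 1e-3)
})

test_that("training is reproducible given config, seed and data", {
  d <- tiny_dataset(150)
  net <- tiny_net(d)
  a <- train_hebbian(net, d, 350, test = d, seed = 38)
  b <- train_hebbian(net, d, 350, test = d, seed = 38)
  expect_identical(a$W, b$W)
  expect_identical(a$log, b$log)
  expect_true(all(diff(a$log$images_seen) > 0))
})

test_that("unlabeled stimuli produce no representation update under DA", {
  d <- tiny_dataset(150)
  d$label_available[] <- FALSE
  net <- tiny_net(d)
  out <- train_with_da(net, d, 300, seed = 39)
  expect_identical(out$W, net$W)
  # the Hebbian fallback flag restores learning
  out2 <- train_with_da(net, d, 300, seed = 39, unlabeled_hebbian = TRUE)
  expect_false(identical(out2$W, net$W))
  # full reinforcement uses the labels for reward despite the mask
  out3 <- train_with_da(net, d, 300, seed = 39, full_reinforcement = TRUE)
  expect_false(identical(out3$W, net$W))
})

test_that("an infinite plateau tolerance stops at the first comparison", {
  d <- tiny_dataset(300)
  net <- tiny_net(d)
  out <- pretrain_critical_period(net, d, test = d, max_epochs = 50,
                                  plateau_window = 2, plateau_tol = Inf,
                                  seed = 40)
  expect_equal(out$images_seen, 400L)   # 2 windows of 2 refreshes x 100
  expect_equal(out$plateau_at, 400L)
})

test_that("pairing experiment reports before and after histograms", {
  d <- tiny_dataset(200)
  net <- tiny_net(d)
  net <- train_hebbian(net, d, 600, seed = 41)
  out <- run_pairing_experiment(net, d, target_class = 1L, rho = 5,
                                n_images = 200, seed = 42)
  expect_equal(sum(out$before), net$config$C)
  expect_equal(sum(out$after), net$config$C)
  expect_equal(length(out$before), d$n_classes)
})

test_that("grid search returns the argmax cell and a complete table", {
  grid <- data.frame(x = c(1, 2, 3))
  gs <- grid_search(grid, function(p, seed) p$x + 0.01 * seed,
                    eval_fn = identity, n_seeds = 3)
  expect_equal(gs$best_params$x, 3)
  expect_equal(nrow(gs$table), 3)
  expect_equal(dim(gs$scores), c(3L, 3L))
  expect_true(gs$table$not_worse[3])
  expect_false(gs$table$not_worse[1])
  # single-cell grid returns that cell
  g1 <- grid_search(data.frame(x = 7), function(p, s) 1,
                    eval_fn = identity, n_seeds = 2)
  expect_equal(g1$best_params$x, 7)
})

test_that("the fitting interface returns a classed model with methods", {
  d <- tiny_dataset(200, seed = 6)
  te <- tiny_dataset(100, seed = 7)
  fit <- hebbnet(d, test = te, C = 6, pretrain_epochs = 3, epochs = 1,
                 seed = 2)
  expect_s3_class(fit, "hebbnet")
  expect_true(is.numeric(fit$test_accuracy))
  expect_named(coef(fit), c("W", "B"))
  expect_equal(dim(coef(fit)$W), c(6L, 36L))
  pred <- predict(fit, te)
  expect_equal(length(pred), 100L)
  post <- predict(fit, te, type = "posterior")
  expect_equal(rowSums(post), rep(1, 100), tolerance = 1e-9)
  expect_output(print(fit), "Hebbian")
  expect_output(print(summary(fit)), "summary")
  # well-separated 3-class problem is learned to high accuracy
  expect_gt(fit$test_accuracy, 0.9)
})
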