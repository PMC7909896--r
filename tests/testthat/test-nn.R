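test_that("initialization is seeded, shaped per the layer contract, and scaled by fan-in", {
  a <- init_model(c(4, 3, 1), seed = 5)
  b <- init_model(c(4, 3, 1), seed = 5)
  expect_identical(a, b)
  expect_equal(dim(a$weights[[1]]), c(4L, 3L))
  expect_equal(dim(a$weights[[2]]), c(3L, 1L))
  expect_equal(lengths(a$biases), c(3L, 1L))
  expect_true(all(vapply(a$biases, function(x) all(x == 0), TRUE)))

  m <- init_model(c(1000, 64, 32, 1), seed = 0)
  expect_lt(abs(sd(m$weights[[1]]) - 1 / sqrt(1000)) / (1 / sqrt(1000)), 0.2)
  expect_error(init_model(c(4)), "layer_sizes")
  expect_error(init_model(c(4, 0, 1)), "layer_sizes")
})

test_that("forward pass: zero model scores 0.5, eval ignores dropout, hand value checks out", {
  m <- init_model(c(3, 2, 1), seed = 1)
  m$weights <- lapply(m$weights, function(w) w * 0)
  x <- matrix(rbinom(15, 1, 0.5), 5)
  expect_equal(nn_forward(m, x)$scores, rep(0.5, 5))

  m2 <- init_model(c(4, 3, 3, 1), seed = 2)
  x2 <- matrix(runif(8), 2)
  expect_equal(
    nn_forward(m2, x2, mode = "eval", dropout_rate = 0.9)$scores,
    nn_forward(m2, x2, mode = "eval", dropout_rate = 0)$scores
  )

  m1 <- init_model(c(2, 1), seed = 0)
  m1$weights[[1]] <- matrix(c(1, 1), 2)
  m1$biases[[1]] <- 0
  expect_equal(nn_forward(m1, matrix(c(1, 1), 1))$scores, plogis(2), tolerance = 1e-12)
  expect_error(nn_forward(m1, matrix(0, 1, 3)), "width")
})

test_that("zero learning rate leaves the model untouched and the gradient all-zero", {
  m <- init_model(c(6, 4, 1), seed = 3)
  sh <- small_cohort()
  fit <- train_local(m, sh, train_config(learning_rate = 0, seed = 1))
  expect_identical(fit$model$weights, m$weights)
  expect_true(all(vapply(fit$gradient$deltas, function(d) all(d == 0), TRUE)))
})

test_that("training is deterministic under a fixed seed and preserves the input model", {
  m <- init_model(c(6, 4, 3, 1), seed = 4)
  m_copy <- m
  sh <- small_cohort()
  cfg <- train_config(seed = 11)
  a <- train_local(m, sh, cfg)
  b <- train_local(m, sh, cfg)
  expect_identical(a$model, b$model)
  expect_identical(m, m_copy)
  c2 <- train_local(m, sh, train_config(seed = 12))
  expect_false(identical(a$model$weights, c2$model$weights))
})

test_that("one full-batch step equals -lr times the analytic BCE gradient", {
  set.seed(101)
  m <- init_model(c(2, 3, 1), seed = 6)
  x <- matrix(c(1, 0, 1, 0, 0, 1, 1, 1), 4)
  y <- c(0, 1, 1, 0)
  shard <- new_cohort(x, y)
  lr <- 0.05
  fit <- train_local(m, shard, train_config(
    learning_rate = lr, batch_size = 4, epochs_per_loop = 1,
    dropout_rate = 0, seed = 1
  ))
  num <- numeric_bce_gradient(m, x, y)
  for (l in seq_along(m$weights)) {
    expect_equal(
      fit$gradient$deltas[[l]],
      -lr * num$weights[[l]],
      tolerance = 1e-5
    )
  }
})

test_that("backprop matches central finite differences on every parameter", {
  set.seed(7)
  m <- init_model(c(3, 3, 1), seed = 8)
  # every row has at least one active feature: with continuous random
  # weights no pre-activation sits exactly on the ReLU kink, where central
  # differences and the subgradient legitimately disagree
  x <- cbind(1, matrix(rbinom(12, 1, 0.5), 6))
  y <- c(1, 0, 1, 1, 0, 0)
  shard <- new_cohort(x, y)
  lr <- 0.01
  fit <- train_local(m, shard, train_config(
    learning_rate = lr, batch_size = 6, epochs_per_loop = 1,
    dropout_rate = 0, seed = 2
  ))
  num <- numeric_bce_gradient(m, x, y)
  for (l in seq_along(m$weights)) {
    ana_w <- -fit$gradient$deltas[[l]] / lr
    rel <- abs(ana_w - num$weights[[l]]) /
      pmax(abs(ana_w) + abs(num$weights[[l]]), 1e-8)
    expect_lt(max(rel), 1e-4)
    ana_b <- -(fit$model$biases[[l]] - m$biases[[l]]) / lr
    rel_b <- abs(ana_b - num$biases[[l]]) /
      pmax(abs(ana_b) + abs(num$biases[[l]]), 1e-8)
    expect_lt(max(rel_b), 1e-4)
  }
})

test_that("five epochs of SGD reduce the full-cohort cross-entropy", {
  for (s in 1:5) {
    coh <- generate_cohort(300, 30, 10, effect_scale = 2, seed = s)
    m <- init_model(c(30, 16, 8, 1), seed = s)
    before <- bce_loss(evaluate_scores(m, coh), coh$labels)
    fit <- train_local(m, coh, train_config(learning_rate = 0.01, seed = s))
    after <- bce_loss(evaluate_scores(fit$model, coh), coh$labels)
    expect_lt(after, before)
  }
})

test_that("inverted dropout conserves the layer's expected activation", {
  m <- init_model(c(5, 4, 4, 1), seed = 9)
  x <- matrix(rbinom(10, 1, 0.5), 2)
  eval_h2 <- nn_forward(m, x, mode = "eval")$hidden[[2]]
  n_draws <- 10000
  acc <- matrix(0, nrow(eval_h2), ncol(eval_h2))
  for (i in seq_len(n_draws)) {
    acc <- acc + nn_forward(m, x, mode = "train", dropout_rate = 0.5, seed = i)$hidden[[2]]
  }
  avg <- acc / n_draws
  active <- eval_h2 > 0
  expect_lt(max(abs(avg[active] - eval_h2[active]) / eval_h2[active]), 0.02)
})

test_that("evaluate_scores is row-wise, order-equivariant, and definitionally the eval forward", {
  m <- init_model(c(6, 4, 1), seed = 10)
  coh <- small_cohort()
  s <- evaluate_scores(m, coh)
  expect_identical(s, nn_forward(m, coh$features)$scores)
  perm <- sample(nrow(coh$features))
  expect_identical(evaluate_scores(m, cohort_subset_for_test(coh, perm)), s[perm])

  mz <- m
  mz$weights <- lapply(mz$weights, function(w) w * 0)
  mz$biases <- lapply(mz$biases, function(b) b * 0)
  expect_equal(evaluate_scores(mz, coh), rep(0.5, nrow(coh$features)))
})

test_that("models round-trip through JSON serialization", {
  m <- init_model(c(5, 3, 2, 1), seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(back$layer_sizes, m$layer_sizes)
  expect_equal(back$weights, m$weights, tolerance = 1e-14)
  expect_equal(back$biases, m$biases, tolerance = 1e-14)
})
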