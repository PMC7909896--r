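# Hand-build a processed_gradient with explicit support, for aggregation
# oracles.
manual_upload <- function(deltas, support, layer_sizes) {
  structure(
    list(
      deltas = deltas, support = support,
      selected_channels = matrix(integer(0), 0, length(layer_sizes) - 1),
      channel_fraction = NA_real_,
      parameter_fraction = NA_real_,
      n_support = sum(vapply(support, sum, 1)),
      n_nonzero = sum(vapply(deltas, function(d) sum(d != 0), 1)),
      n_total = sum(vapply(deltas, length, 1L)),
      alpha = NA_real_, mode = "positive", threshold = NA_real_,
      layer_sizes = layer_sizes
    ),
    class = "processed_gradient"
  )
}

test_that("server update: single full upload at decay 1 adds the gradient verbatim", {
  srv <- init_model(c(2, 2, 1), seed = 1)
  g <- fixture_gradient_5_12()
  up <- process_gradients(g, 1.0)
  out <- server_update(srv, list(up), decay = 1)
  expect_equal(out$weights[[1]], srv$weights[[1]] + g$deltas[[1]])
  expect_equal(out$weights[[2]], srv$weights[[2]] + g$deltas[[2]])
  expect_identical(out$biases, srv$biases) # biases never uploaded
})

test_that("server update averages only over the clients that selected a position", {
  srv <- init_model(c(1, 2, 1), seed = 2)
  sizes <- c(1L, 2L, 1L)
  # both clients select position (1,1,1): values +2 and +4 -> mean 3
  # only client 1 selects position (1,1,2): value 2 -> +2
  u1 <- manual_upload(
    list(matrix(c(2, 2), 1), matrix(c(0, 0), 2)),
    list(matrix(c(TRUE, TRUE), 1), matrix(c(FALSE, FALSE), 2)),
    sizes
  )
  u2 <- manual_upload(
    list(matrix(c(4, 0), 1), matrix(c(0, 0), 2)),
    list(matrix(c(TRUE, FALSE), 1), matrix(c(FALSE, FALSE), 2)),
    sizes
  )
  out <- server_update(srv, list(u1, u2), decay = 1)
  expect_equal(out$weights[[1]][1, 1], srv$weights[[1]][1, 1] + 3)
  expect_equal(out$weights[[1]][1, 2], srv$weights[[1]][1, 2] + 2)
  expect_equal(out$weights[[2]], srv$weights[[2]]) # selected by no client

  expect_identical(server_update(srv, list(), decay = 1), srv)
  zero <- manual_upload(
    list(matrix(0, 1, 2), matrix(0, 2, 1)),
    list(matrix(FALSE, 1, 2), matrix(FALSE, 2, 1)),
    sizes
  )
  expect_equal(server_update(srv, list(zero), decay = 0.8), srv)
})

test_that("decay scales the aggregated update", {
  srv <- init_model(c(2, 2, 1), seed = 3)
  up <- process_gradients(fixture_gradient_5_12(), 1.0)
  out <- server_update(srv, list(up), decay = 0.8)
  expect_equal(out$weights[[2]], srv$weights[[2]] + 0.8 * matrix(c(0, 12), 2))
})

test_that("fedavg_average is the exact arithmetic mean of hand-set client weights", {
  a <- init_model(c(3, 2, 1), seed = 1)
  b <- init_model(c(3, 2, 1), seed = 2)
  a$weights <- lapply(a$weights, function(w) w * 0 + 2)
  b$weights <- lapply(b$weights, function(w) w * 0 + 4)
  avg <- fedavg_average(list(a, b))
  expect_true(all(vapply(avg, function(w) all(w == 3), TRUE)))
})

test_that("client_sync copies weights bit-exactly but leaves client biases alone", {
  srv <- init_model(c(4, 3, 1), seed = 4)
  cl <- init_model(c(4, 3, 1), seed = 5)
  cl$biases <- lapply(cl$biases, function(b) b + 0.7)
  synced <- client_sync(cl, srv)
  expect_identical(synced$weights, srv$weights)
  expect_identical(synced$biases, cl$biases)
  cl2 <- client_sync(init_model(c(4, 3, 1), seed = 6), srv)
  expect_identical(cl2$weights, synced$weights)

  small <- init_model(c(4, 2, 1), seed = 7)
  expect_error(client_sync(small, srv), "layer sizes")
})

test_that("zero global loops returns the initial server and an empty log", {
  coh <- generate_cohort(60, 8, 2, seed = 1)
  sp <- split_federation(coh, 2, seed = 1)
  cfg <- federation_config(
    n_clients = 2, global_loops = 0, hidden_sizes = c(4, 3), master_seed = 9
  )
  run <- run_scbfl(sp, cfg)
  expect_identical(run$server, init_model(c(8, 4, 3, 1), seed = 9))
  expect_equal(nrow(run$log), 0)
})

test_that("with one client, full upload and no decay, SCBFL is centralized SGD", {
  coh <- generate_cohort(120, 10, 3, effect_scale = 2, seed = 2)
  sp <- split_federation(coh, 1, seed = 2)
  n_loops <- 3
  cfg <- federation_config(
    n_clients = 1, global_loops = n_loops, hidden_sizes = c(5, 3),
    alpha = 1.0, decay = 1.0,
    train = train_config(dropout_rate = 0), master_seed = 3
  )
  run <- run_scbfl(sp, cfg)

  chain <- init_model(c(10, 5, 3, 1), seed = 3)
  for (loop in seq_len(n_loops)) {
    tc <- train_config(dropout_rate = 0, seed = client_loop_seed(3, 1, loop, 1))
    chain <- train_local(chain, sp$client_shards[[1]], tc)$model
  }
  for (l in seq_along(chain$weights)) {
    expect_lt(max(abs(run$server$weights[[l]] - chain$weights[[l]])), 1e-10)
  }
})

test_that("zero learning rate freezes the server in both algorithms", {
  coh <- generate_cohort(80, 6, 2, seed = 4)
  sp <- split_federation(coh, 2, seed = 4)
  for (alg in c("scbfl", "fedavg")) {
    cfg <- federation_config(
      n_clients = 2, global_loops = 2, hidden_sizes = c(4, 3),
      algorithm = alg, train = train_config(learning_rate = 0), master_seed = 5
    )
    run <- run_federation(sp, cfg)
    expect_equal(run$server$weights, init_model(c(6, 4, 3, 1), seed = 5)$weights)
  }
})

test_that("identical split and config reproduce the run log exactly", {
  coh <- generate_cohort(150, 10, 3, effect_scale = 2, seed = 6)
  sp <- split_federation(coh, 3, seed = 6)
  cfg <- federation_config(
    n_clients = 3, global_loops = 3, hidden_sizes = c(6, 4),
    alpha = 0.3, master_seed = 7
  )
  a <- run_scbfl(sp, cfg)
  b <- run_scbfl(sp, cfg)
  expect_identical(a$log, b$log)
  expect_identical(a$server, b$server)
})

test_that("pruning keeps server and clients shape-congruent every loop", {
  coh <- generate_cohort(200, 12, 4, effect_scale = 2, seed = 8)
  sp <- split_federation(coh, 2, seed = 8)
  cfg <- federation_config(
    n_clients = 2, global_loops = 6, hidden_sizes = c(8, 6),
    pruning_enabled = TRUE, prune_rate = 0.2, prune_total = 0.4,
    master_seed = 8
  )
  run <- run_scbfl(sp, cfg)
  expect_equal(run$prune_state$pruned_total, floor(0.4 * 14))
  for (cl in run$clients) {
    expect_identical(as.integer(cl$layer_sizes), as.integer(run$server$layer_sizes))
  }
  expect_true(all(diff(run$log$neurons_remaining) <= 0))
})

test_that("channel upload transmits strictly fewer entries than federated averaging", {
  coh <- generate_cohort(150, 10, 3, effect_scale = 2, seed = 9)
  sp <- split_federation(coh, 2, seed = 9)
  base <- list(
    n_clients = 2, global_loops = 3, hidden_sizes = c(6, 4), master_seed = 10
  )
  scbfl <- run_scbfl(sp, do.call(federation_config, c(base, alpha = 0.3)))
  fa <- run_fedavg(sp, do.call(federation_config, base))
  expect_lt(
    dplyr::last(scbfl$log$cum_uploaded_entries),
    dplyr::last(fa$log$cum_uploaded_entries)
  )
  expect_true(all(scbfl$log$mean_upload_fraction > 0 &
    scbfl$log$mean_upload_fraction <= 1))
})

test_that("test AUC trends upward on separable data", {
  coh <- generate_cohort(400, 12, 12, base_log_odds = 0, effect_scale = 3, seed = 12)
  sp <- split_federation(coh, 2, seed = 12)
  cfg <- federation_config(
    n_clients = 2, global_loops = 15, hidden_sizes = c(8, 4),
    alpha = 0.3, master_seed = 12
  )
  run <- run_scbfl(sp, cfg)
  expect_gte(run$log$auc_roc[15], run$log$auc_roc[5])
})

test_that("tidy, glance and autoplot expose the run in tabular and graphical form", {
  coh <- generate_cohort(100, 8, 2, seed = 13)
  sp <- split_federation(coh, 2, seed = 13)
  run <- run_scbfl(sp, federation_config(
    n_clients = 2, global_loops = 2, hidden_sizes = c(4, 3), master_seed = 13
  ))
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  gl <- glance(run)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$auc_roc, td$auc_roc[2])
  expect_s3_class(autoplot(run), "ggplot")
  cp <- curve_points(evaluate_scores(run$server, sp$test), sp$test$labels)
  expect_s3_class(autoplot(cp, "roc"), "ggplot")
  expect_s3_class(plot_trans_information(scbfl = run), "ggplot")
})
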