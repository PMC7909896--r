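#' Federation configuration
#'
#' Defaults mirror the reference distributed clinical setting: 5 clients,
#' hidden layers of 64 and 32 neurons, update rate (alpha) 0.30, decay 0.8
#' applied to the aggregated upload, full (100%) download of server weights,
#' 100 global loops of 5 local epochs each, and — when pruning is enabled —
#' 10% of remaining neurons per loop until 47% of the original hidden
#' neurons are gone.
#'
#' @param n_clients number of clients (default 5).
#' @param global_loops number of federation rounds (default 100).
#' @param hidden_sizes hidden-layer widths (default `c(64, 32)`; the output
#'   layer is always a single sigmoid neuron).
#' @param alpha channel update rate in `(0, 1]` (default 0.30).
#' @param decay scalar factor applied to the aggregated upload at the
#'   server (default 0.8).
#' @param download_rate fraction of server weights downloaded; only the
#'   full download (1.0) is implemented, the field is reserved.
#' @param selection_mode `"positive"` or `"negative"` channel selection.
#' @param algorithm `"scbfl"` (stochastic channel-based federated learning)
#'   or `"fedavg"` (federated averaging baseline).
#' @param pruning_enabled run APoZ pruning during the first loops?
#' @param prune_rate,prune_total per-loop and total pruning fractions.
#' @param train a [train_config()] (its `seed` field is overridden by the
#'   per-client, per-loop derived seeds).
#' @param master_seed integer seed controlling model init and all derived
#'   client seeds.
#' @export
federation_config <- function(n_clients = 5L, global_loops = 100L,
                              hidden_sizes = c(64L, 32L),
                              alpha = 0.30, decay = 0.8,
                              download_rate = 1.0,
                              selection_mode = c("positive", "negative"),
                              algorithm = c("scbfl", "fedavg"),
                              pruning_enabled = FALSE,
                              prune_rate = 0.10, prune_total = 0.47,
                              train = train_config(),
                              master_seed = 0L) {
  selection_mode <- match.arg(selection_mode)
  algorithm <- match.arg(algorithm)
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1]")
  if (decay <= 0 || decay > 1) abort("decay must lie in (0, 1]")
  if (download_rate != 1.0) abort("only download_rate = 1.0 is implemented")
  structure(
    list(
      n_clients = as.integer(n_clients),
      global_loops = as.integer(global_loops),
      hidden_sizes = as.integer(hidden_sizes),
      alpha = alpha, decay = decay, download_rate = download_rate,
      selection_mode = selection_mode, algorithm = algorithm,
      pruning_enabled = isTRUE(pruning_enabled),
      prune_rate = prune_rate, prune_total = prune_total,
      train = train, master_seed = as.integer(master_seed)
    ),
    class = "federation_config"
  )
}

#' Deterministic per-client, per-loop training seed
#'
#' @param master_seed federation master seed.
#' @param client client index (1-based).
#' @param loop global-loop index (1-based).
#' @param n_clients number of clients.
#' @export
client_loop_seed <- function(master_seed, client, loop, n_clients) {
  as.integer(master_seed + client + loop * n_clients)
}

#' Aggregate sparse client uploads into the server model
#'
#' Each weight position is updated by `decay` times the mean of the uploaded
#' values of the clients that *selected* that position; positions selected
#' by no client are left unchanged. Biases are never uploaded and are
#' untouched. With a single client, full selection (alpha = 1) and decay 1
#' this reduces to literally adding the client's gradient to the server
#' weights.
#'
#' @param server the server [init_model()] parameters.
#' @param uploads list of [process_gradients()] results, one per uploading
#'   client (may be empty).
#' @param decay scalar in `(0, 1]`.
#' @export
server_update <- function(server, uploads, decay) {
  if (length(uploads) == 0L) return(server)
  for (up in uploads) {
    if (!identical(
      vapply(up$deltas, dim, integer(2)),
      vapply(server$weights, dim, integer(2))
    )) {
      abort("upload shape does not match the server model (missed prune mask?)")
    }
  }
  for (l in seq_along(server$weights)) {
    num <- Reduce(`+`, lapply(uploads, function(u) u$deltas[[l]]))
    cnt <- Reduce(`+`, lapply(uploads, function(u) u$support[[l]] * 1))
    sel <- cnt > 0
    if (any(sel)) {
      server$weights[[l]][sel] <- server$weights[[l]][sel] +
        decay * num[sel] / cnt[sel]
    }
  }
  server
}

#' Federated-averaging aggregation of client weights
#'
#' The unweighted arithmetic mean, per weight position, of the clients'
#' weight matrices (shards are equal-sized by construction, so sample-size
#' weighting is moot). This is the full-disclosure baseline: every client
#' reveals all of its weights.
#'
#' @param models list of shape-congruent [init_model()] objects.
#' @return list of per-layer mean weight matrices.
#' @export
fedavg_average <- function(models) {
  k <- length(models)
  if (k == 0L) abort("no models to average")
  lapply(seq_along(models[[1]]$weights), function(l) {
    Reduce(`+`, lapply(models, function(m) m$weights[[l]])) / k
  })
}

#' Download server weights into a client model
#'
#' Weight matrices are replaced by the server's; the client's biases are
#' retained — biases are never uploaded, so the server's biases carry no
#' learned signal and overwriting local biases would discard learning.
#'
#' @param client,server [init_model()] objects of identical layer sizes.
#' @export
client_sync <- function(client, server) {
  if (!identical(
    as.integer(client$layer_sizes),
    as.integer(server$layer_sizes)
  )) {
    abort("client/server layer sizes differ; apply the prune masks first")
  }
  client$weights <- server$weights
  client
}

#' Run a federated training experiment
#'
#' Orchestrates the synchronous client-server protocol for
#' `cfg$global_loops` rounds. Each round: every client downloads the server
#' weights ([client_sync()]), trains locally ([train_local()]), and —
#' depending on the algorithm — uploads either a channel-sparsified
#' gradient ([process_gradients()], aggregated by [server_update()] with
#' decay) or its full weights (federated averaging: the server takes the
#' arithmetic mean). If pruning is enabled the server then computes APoZ on
#' the validation cohort, removes the scheduled neurons, and all clients
#' shrink identically. Finally the server is scored on the test cohort and
#' a log record appended.
#'
#' The run is fully deterministic given `(split, cfg)`: per-client training
#' seeds are derived as `master_seed + client + loop * n_clients`.
#'
#' @param split a [split_federation()] layout.
#' @param cfg a [federation_config()].
#' @return object of class `fed_run`: list with `server` (final model),
#'   `log` (tibble, one row per global loop), `config`, `prune_state`
#'   (or NULL), and `clients` (final client models).
#' @export
run_federation <- function(split, cfg = federation_config()) {
  k <- cfg$n_clients
  if (length(split$client_shards) != k) {
    abort(sprintf(
      "split has %d shards but cfg$n_clients = %d",
      length(split$client_shards), k
    ))
  }
  if (any(vapply(split$client_shards, function(s) nrow(s$features), 1L) == 0L)) {
    abort("every client shard must be non-empty")
  }
  n_features <- ncol(split$client_shards[[1]]$features)
  sizes <- c(n_features, cfg$hidden_sizes, 1L)
  server <- init_model(sizes, seed = cfg$master_seed)
  clients <- rep(list(server), k)
  pstate <- if (cfg$pruning_enabled) {
    new_prune_state(sizes, cfg$prune_rate, cfg$prune_total)
  } else {
    NULL
  }
  has_test <- nrow(split$test$features) > 0L
  full_entries <- n_weight_params(server)
  cum_entries <- 0
  log <- vector("list", cfg$global_loops)

  for (loop in seq_len(cfg$global_loops)) {
    seeds <- vapply(
      seq_len(k),
      function(ci) client_loop_seed(cfg$master_seed, ci, loop, k),
      1L
    )
    uploads <- vector("list", k)
    for (ci in seq_len(k)) {
      clients[[ci]] <- client_sync(clients[[ci]], server)
      tc <- cfg$train
      tc$seed <- seeds[ci]
      fit <- train_local(clients[[ci]], split$client_shards[[ci]], tc)
      clients[[ci]] <- fit$model
      if (cfg$algorithm == "scbfl") {
        uploads[[ci]] <- process_gradients(
          fit$gradient, cfg$alpha, cfg$selection_mode
        )
      }
    }
    if (cfg$algorithm == "scbfl") {
      server <- server_update(server, uploads, cfg$decay)
      upload_frac <- mean(vapply(uploads, function(u) u$parameter_fraction, 1))
      cum_entries <- cum_entries + sum(vapply(uploads, function(u) u$n_support, 1))
    } else {
      server$weights <- fedavg_average(clients)
      upload_frac <- 1.0
      cum_entries <- cum_entries + k * full_entries
    }

    if (!is.null(pstate) && pstate$pruned_total < prune_target(pstate) &&
        nrow(split$validation$features) > 0L) {
      ap <- compute_apoz(server, split$validation)
      ps <- prune_step(server, pstate, ap)
      server <- ps$model
      pstate <- ps$state
      if (ps$pruned > 0L) {
        clients <- lapply(clients, drop_neurons, removed_current = ps$removed_current)
      }
      full_entries <- n_weight_params(server)
    }

    if (has_test) {
      scores <- evaluate_scores(server, split$test)
      cp <- curve_points(scores, split$test$labels)
      auc_roc <- auc(cp, "roc")
      auc_pr <- auc(cp, "pr")
    } else {
      auc_roc <- NA_real_
      auc_pr <- NA_real_
    }
    log[[loop]] <- tibble::tibble(
      loop = loop,
      auc_roc = auc_roc,
      auc_pr = auc_pr,
      mean_upload_fraction = upload_frac,
      cum_uploaded_entries = cum_entries,
      neurons_remaining = sum(server$layer_sizes[-c(1, length(server$layer_sizes))]),
      client_seeds = list(seeds)
    )
  }

  structure(
    list(
      server = server,
      log = dplyr::bind_rows(log),
      config = cfg,
      prune_state = pstate,
      clients = clients
    ),
    class = "fed_run"
  )
}

#' @rdname run_federation
#' @export
run_scbfl <- function(split, cfg = federation_config()) {
  cfg$algorithm <- "scbfl"
  run_federation(split, cfg)
}

#' @rdname run_federation
#' @export
run_fedavg <- function(split, cfg = federation_config()) {
  cfg$algorithm <- "fedavg"
  run_federation(split, cfg)
}

#' @export
print.fed_run <- function(x, ...) {
  n <- nrow(x$log)
  if (n > 0) {
    cat(sprintf(
      "<fed_run> %s, %d loops: final AUC-ROC %.4f, AUC-PR %.4f\n",
      x$config$algorithm, n, x$log$auc_roc[n], x$log$auc_pr[n]
    ))
  } else {
    cat(sprintf("<fed_run> %s, 0 loops (init only)\n", x$config$algorithm))
  }
  invisible(x)
}
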