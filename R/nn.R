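#' Dense feed-forward model parameters
#'
#' The learner underneath both federation algorithms is a plain multilayer
#' perceptron: ReLU hidden layers, a sigmoid output neuron, trained by
#' mini-batch SGD on binary cross-entropy. Weights for layer `l` form an
#' `m_{l-1} x m_l` matrix so that a row vector of activations is propagated
#' as `a_l = act(a_{l-1} W_l + b_l)`.
#'
#' @param layer_sizes integer vector `(m_0, m_1, ..., m_L)`: input width
#'   followed by the width of every layer (the reference clinical model is
#'   `c(n_features, 64, 32, 1)`).
#' @param seed integer seed for the weight draw.
#' @return An object of class `model_params`: list with `layer_sizes`,
#'   `weights` (list of `L` matrices) and `biases` (list of `L` vectors).
#'   Weights are drawn from `N(0, 1/fan_in)`; biases start at zero.
#' @export
init_model <- function(layer_sizes, seed = 0L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || any(layer_sizes < 1)) {
    abort("layer_sizes needs >= 2 positive entries (input plus >= 1 layer)")
  }
  L <- length(layer_sizes) - 1L
  run_seeded(seed, {
    weights <- vector("list", L)
    biases <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- layer_sizes[l]
      weights[[l]] <- matrix(
        rnorm(fan_in * layer_sizes[l + 1], sd = 1 / sqrt(fan_in)),
        nrow = fan_in
      )
      biases[[l]] <- numeric(layer_sizes[l + 1])
    }
    structure(
      list(layer_sizes = layer_sizes, weights = weights, biases = biases),
      class = "model_params"
    )
  })
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> layers %s; %d weight parameters\n",
    paste(x$layer_sizes, collapse = "-"), n_weight_params(x)
  ))
  invisible(x)
}

#' Total number of weight entries of a model (biases excluded)
#' @param model a [init_model()] object.
#' @export
n_weight_params <- function(model) {
  sum(vapply(model$weights, length, 1L))
}

n_layers <- function(model) length(model$weights)

# Index of the hidden layer carrying dropout: the second hidden layer when
# the network has at least two, otherwise none (NA).
dropout_layer_of <- function(model) {
  if (n_layers(model) >= 3L) 2L else NA_integer_
}

relu <- function(z) pmax(z, 0)

sigmoid <- function(z) plogis(z)

# Full forward pass keeping pre-activations; uses the *current* RNG stream
# for dropout masks so train_local can interleave shuffling and masking
# deterministically under one seed.
forward_internal <- function(model, x, train = FALSE, dropout_rate = 0) {
  L <- n_layers(model)
  drop_l <- dropout_layer_of(model)
  a <- x
  activations <- vector("list", L - 1L)
  pre <- vector("list", L)
  mask <- NULL
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$weights[[l]], 2, model$biases[[l]], "+")
    pre[[l]] <- z
    if (l < L) {
      a <- relu(z)
      if (train && !is.na(drop_l) && l == drop_l && dropout_rate > 0) {
        mask <- matrix(
          runif(length(a)) >= dropout_rate,
          nrow = nrow(a)
        ) / (1 - dropout_rate)
        a <- a * mask
      }
      activations[[l]] <- a
    } else {
      a <- sigmoid(z)
    }
  }
  list(scores = drop(a), hidden = activations, pre = pre, mask = mask)
}

#' Forward pass of a dense model
#'
#' Hidden layers apply ReLU; the output layer applies a sigmoid, so scores
#' are probabilities in `(0, 1)`. In `"train"` mode an inverted-scaling
#' dropout mask (`/(1 - rate)`) is applied to the second hidden layer; in
#' `"eval"` mode dropout is a no-op.
#'
#' @param model a [init_model()] object.
#' @param features numeric matrix with `m_0` columns.
#' @param mode `"eval"` (default) or `"train"`.
#' @param dropout_rate dropout probability in `[0, 1)`; only used in train
#'   mode.
#' @param seed optional seed for the dropout mask (train mode).
#' @return list with `scores` (vector) and `hidden` (list of post-activation
#'   matrices for each hidden layer, as needed by [compute_apoz()]).
#' @export
nn_forward <- function(model, features, mode = c("eval", "train"),
                       dropout_rate = 0, seed = NULL) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  if (ncol(features) != model$layer_sizes[1]) {
    abort(sprintf(
      "feature width %d does not match model input width %d",
      ncol(features), model$layer_sizes[1]
    ))
  }
  run <- function() {
    forward_internal(model, features,
      train = (mode == "train"), dropout_rate = dropout_rate
    )
  }
  out <- if (!is.null(seed)) run_seeded(seed, run()) else run()
  out[c("scores", "hidden")]
}

#' Mean binary cross-entropy
#'
#' Scores are clipped to `[1e-12, 1 - 1e-12]` inside the loss only.
#' @param scores predicted probabilities.
#' @param labels 0/1 outcomes.
#' @export
bce_loss <- function(scores, labels) {
  p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Local training configuration
#'
#' Defaults follow the reference clinical setting: learning rate 0.01,
#' batch size 32, 5 epochs per global loop, dropout 0.5.
#'
#' @param learning_rate SGD step size (> 0).
#' @param batch_size mini-batch size (>= 1).
#' @param epochs_per_loop local epochs per global loop.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param seed integer seed controlling shuffling and dropout masks.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 32L,
                         epochs_per_loop = 5L, dropout_rate = 0.5,
                         seed = 0L) {
  if (learning_rate < 0) abort("learning_rate must be >= 0")
  if (batch_size < 1) abort("batch_size must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must lie in [0, 1)")
  structure(
    list(
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      epochs_per_loop = as.integer(epochs_per_loop),
      dropout_rate = dropout_rate, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

# Backward pass for mean BCE over one mini-batch. Returns per-layer weight
# and bias gradients. `fw` is the output of forward_internal(train = TRUE).
backward_internal <- function(model, x, y, fw, dropout_rate) {
  L <- n_layers(model)
  drop_l <- dropout_layer_of(model)
  nb <- nrow(x)
  gw <- vector("list", L)
  gb <- vector("list", L)
  # sigmoid + BCE: dL/dz_L = (p - y) / nb
  dz <- matrix(fw$scores - y, ncol = 1) / nb
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1L) x else fw$hidden[[l - 1L]]
    gw[[l]] <- crossprod(a_prev, dz)
    gb[[l]] <- colSums(dz)
    if (l > 1L) {
      da <- dz %*% t(model$weights[[l]])
      if (!is.na(drop_l) && (l - 1L) == drop_l && !is.null(fw$mask)) {
        da <- da * fw$mask
      }
      dz <- da * (fw$pre[[l - 1L]] > 0)
    }
  }
  list(weights = gw, biases = gb)
}

#' Train a model locally on one client shard
#'
#' Runs `epochs_per_loop` epochs of mini-batch SGD on binary cross-entropy,
#' reshuffling each epoch with the seeded RNG. The input model is left
#' unmodified; the returned `gradient` records the total weight change of
#' the loop (`updated - original`), which is the quantity a client offers
#' for upload.
#'
#' @param model starting [init_model()] parameters.
#' @param shard a non-empty [new_cohort()] with matching feature width.
#' @param cfg a [train_config()].
#' @return list with `model` (updated parameters) and `gradient` (class
#'   `gradient_set`: per-layer weight deltas).
#' @export
train_local <- function(model, shard, cfg = train_config()) {
  n <- nrow(shard$features)
  if (n == 0L) abort("cannot train on an empty shard")
  if (ncol(shard$features) != model$layer_sizes[1]) {
    abort("shard feature width does not match the model")
  }
  x_all <- shard$features
  y_all <- shard$labels
  w0 <- model$weights
  upd <- model
  run_seeded(cfg$seed, {
    for (ep in seq_len(cfg$epochs_per_loop)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- x_all[idx, , drop = FALSE]
        yb <- y_all[idx]
        fw <- forward_internal(upd, xb,
          train = TRUE, dropout_rate = cfg$dropout_rate
        )
        if (!all(is.finite(fw$scores))) {
          abort(sprintf("non-finite scores during epoch %d", ep))
        }
        gr <- backward_internal(upd, xb, yb, fw, cfg$dropout_rate)
        for (l in seq_along(upd$weights)) {
          upd$weights[[l]] <- upd$weights[[l]] - cfg$learning_rate * gr$weights[[l]]
          upd$biases[[l]] <- upd$biases[[l]] - cfg$learning_rate * gr$biases[[l]]
        }
      }
    }
  })
  deltas <- purrr::map2(upd$weights, w0, `-`)
  list(
    model = upd,
    gradient = structure(
      list(deltas = deltas, layer_sizes = model$layer_sizes),
      class = "gradient_set"
    )
  )
}

#' Score a cohort with a model
#'
#' Eval-mode forward pass; returns one probability per cohort row, in row
#' order.
#' @param model a [init_model()] object.
#' @param cohort a [new_cohort()] object.
#' @export
evaluate_scores <- function(model, cohort) {
  nn_forward(model, cohort$features, mode = "eval")$scores
}

#' Serialize / restore model parameters as JSON
#'
#' @param model a [init_model()] object.
#' @param path file path.
#' @return `read_model_json()` returns a `model_params` object.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    format_version = 1L,
    layer_sizes = model$layer_sizes,
    # column-major flat storage; shapes are implied by layer_sizes
    weights = lapply(model$weights, as.vector),
    biases = model$biases
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(obj$layer_sizes)
  weights <- lapply(seq_len(length(sizes) - 1L), function(l) {
    matrix(as.numeric(obj$weights[[l]]), nrow = sizes[l])
  })
  structure(
    list(
      layer_sizes = sizes, weights = weights,
      biases = lapply(obj$biases, as.numeric)
    ),
    class = "model_params"
  )
}
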