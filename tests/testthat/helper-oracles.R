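# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check (channel_entry_set
# is itself pinned against hand enumerations before being used here).

make_gradient <- function(deltas, layer_sizes) {
  structure(
    list(deltas = deltas, layer_sizes = as.integer(layer_sizes)),
    class = "gradient_set"
  )
}

# 5/12 worked fixture: sizes (2,2,1), channel (1,1) norm 5, channel (2,1)
# norm 12.
fixture_gradient_5_12 <- function() {
  make_gradient(
    list(matrix(c(3, 4, 0, 0), 2), matrix(c(0, 12), 2)),
    c(2L, 2L, 1L)
  )
}

random_gradient <- function(layer_sizes) {
  L <- length(layer_sizes) - 1L
  make_gradient(
    lapply(seq_len(L), function(l) {
      matrix(rnorm(layer_sizes[l] * layer_sizes[l + 1]), layer_sizes[l])
    }),
    layer_sizes
  )
}

# Norm of every channel by explicit enumeration over entry sets.
oracle_channel_norms <- function(gradient) {
  sizes <- gradient$layer_sizes
  L <- length(sizes) - 1L
  dims <- sizes[-1]
  tuples <- as.matrix(expand.grid(lapply(dims, seq_len)))
  out <- array(NA_real_, dim = dims)
  for (i in seq_len(nrow(tuples))) {
    entries <- channel_entry_set(tuples[i, ], sizes)
    ss <- 0
    for (j in seq_len(nrow(entries))) {
      ss <- ss + gradient$deltas[[entries[j, 1]]][entries[j, 2], entries[j, 3]]^2
    }
    out[matrix(tuples[i, ], 1)] <- sqrt(ss)
  }
  out
}

# Exhaustive Mann-Whitney AUC: (concordant + 0.5 * tied) / (P * N).
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + (p > n) + 0.5 * (p == n)
    }
  }
  tot / (length(pos) * length(neg))
}

# Manual eval-mode forward pass (loops + pmax), independent of nn_forward.
oracle_forward <- function(model, x) {
  a <- as.matrix(x)
  hidden <- list()
  L <- length(model$weights)
  for (l in seq_len(L)) {
    z <- a %*% model$weights[[l]]
    for (j in seq_len(ncol(z))) z[, j] <- z[, j] + model$biases[[l]][j]
    if (l < L) {
      a <- pmax(z, 0)
      hidden[[l]] <- a
    } else {
      a <- 1 / (1 + exp(-z))
    }
  }
  list(scores = drop(a), hidden = hidden)
}

# Eval-mode forward with the activations of the given hidden neurons forced
# to 0; `removed` is a per-hidden-layer list of neuron indices (possibly
# empty), as returned by prune_step()$removed_current.
oracle_forward_masked <- function(model, x, removed) {
  a <- as.matrix(x)
  L <- length(model$weights)
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$weights[[l]], 2, model$biases[[l]], "+")
    if (l < L) {
      a <- pmax(z, 0)
      if (l <= length(removed) && length(removed[[l]])) a[, removed[[l]]] <- 0
    } else {
      a <- plogis(z)
    }
  }
  drop(a)
}

# Central finite differences of the full-batch mean BCE at `model`.
numeric_bce_gradient <- function(model, x, y, eps = 1e-6) {
  loss_at <- function(m) bce_loss(nn_forward(m, x)$scores, y)
  gw <- lapply(model$weights, function(w) array(0, dim = dim(w)))
  gb <- lapply(model$biases, function(b) numeric(length(b)))
  for (l in seq_along(model$weights)) {
    for (i in seq_along(model$weights[[l]])) {
      mp <- model; mp$weights[[l]][i] <- mp$weights[[l]][i] + eps
      mm <- model; mm$weights[[l]][i] <- mm$weights[[l]][i] - eps
      gw[[l]][i] <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    }
    for (i in seq_along(model$biases[[l]])) {
      mp <- model; mp$biases[[l]][i] <- mp$biases[[l]][i] + eps
      mm <- model; mm$biases[[l]][i] <- mm$biases[[l]][i] - eps
      gb[[l]][i] <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    }
  }
  list(weights = gw, biases = gb)
}

small_cohort <- function(n = 60, p = 6, seed = 42, informative = 3) {
  generate_cohort(n, p, informative, effect_scale = 2, seed = seed)
}

# Row-subset of a cohort without touching package internals.
cohort_subset_for_test <- function(cohort, idx) {
  new_cohort(cohort$features[idx, , drop = FALSE], cohort$labels[idx])
}
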