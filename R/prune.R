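#' Structured neuron pruning by average percentage of zeros
#'
#' APoZ measures how often a ReLU neuron is silent: the fraction of
#' validation examples on which its post-activation output is exactly zero.
#' Neurons that are almost always silent contribute little to downstream
#' layers, so the server periodically removes the globally highest-APoZ
#' hidden neurons — a fixed fraction of those remaining per global loop —
#' until a target fraction of the original hidden neurons is gone. The
#' server decides on its central validation set and every client applies
#' the identical masks, keeping all models shape-congruent.
#'
#' @name pruning
NULL

#' Create pruning bookkeeping for a model
#'
#' @param layer_sizes original `(m_0, ..., m_L)` of the unpruned model.
#' @param rate_per_loop fraction of *remaining* hidden neurons to remove per
#'   pruning step (default 0.10).
#' @param total_fraction target fraction of *original* hidden neurons to
#'   remove overall (default 0.47).
#' @return object of class `prune_state`: per-hidden-layer keep masks over
#'   original neuron indices, counts, and the schedule.
#' @export
new_prune_state <- function(layer_sizes, rate_per_loop = 0.10,
                            total_fraction = 0.47) {
  L <- length(layer_sizes) - 1L
  if (L < 2L) abort("pruning needs at least one hidden layer")
  if (rate_per_loop <= 0 || rate_per_loop > 1) abort("rate_per_loop must lie in (0, 1]")
  if (total_fraction < 0 || total_fraction >= 1) abort("total_fraction must lie in [0, 1)")
  hidden <- layer_sizes[2:L]
  structure(
    list(
      original_sizes = as.integer(layer_sizes),
      keep_masks = lapply(hidden, function(m) rep(TRUE, m)),
      pruned_total = 0L,
      original_total = as.integer(sum(hidden)),
      schedule = list(
        rate_per_loop = rate_per_loop,
        total_fraction = total_fraction
      )
    ),
    class = "prune_state"
  )
}

#' @export
print.prune_state <- function(x, ...) {
  cat(sprintf(
    "<prune_state> %d/%d hidden neurons pruned (target %.0f%%, %.0f%%/loop)\n",
    x$pruned_total, x$original_total,
    100 * x$schedule$total_fraction, 100 * x$schedule$rate_per_loop
  ))
  invisible(x)
}

prune_target <- function(state) {
  floor(state$schedule$total_fraction * state$original_total)
}

#' Average percentage of zeros of every hidden neuron
#'
#' Runs an eval-mode forward pass over the whole validation cohort and, for
#' each hidden neuron, reports the fraction of examples whose post-ReLU
#' activation is exactly zero (scalar dense activations, so the output
#' dimension M is 1; the output layer is excluded). Zero is tested exactly —
#' ReLU emits exact zeros.
#'
#' @param model a [init_model()] object.
#' @param validation a non-empty [new_cohort()].
#' @return object of class `apoz_table`: list with `values` (one numeric
#'   vector per hidden layer, entries in `[0, 1]`), `n_examples`, and
#'   `output_dim`.
#' @export
compute_apoz <- function(model, validation) {
  n <- nrow(validation$features)
  if (n == 0L) abort("validation cohort is empty")
  fw <- nn_forward(model, validation$features, mode = "eval")
  values <- lapply(fw$hidden, function(a) colMeans(a == 0))
  structure(
    list(values = values, n_examples = n, output_dim = 1L),
    class = "apoz_table"
  )
}

#' Remove the highest-APoZ neurons (one pruning step)
#'
#' Ranks all current hidden neurons by APoZ jointly across layers and
#' removes the top `k`, where
#' `k = min(max(1, floor(rate_per_loop * remaining)), left_to_target)`.
#' A layer is never emptied: its last neuron is skipped and the next-ranked
#' neuron taken instead. Removing a neuron deletes its incoming weight
#' column and bias entry and its outgoing weight row. When the target has
#' already been reached the step is a signalled no-op (`pruned = 0`), not an
#' error.
#'
#' @param model the current (possibly already shrunken) server model.
#' @param state the matching [new_prune_state()].
#' @param apoz an [compute_apoz()] table for `model`.
#' @return list with `model` (shrunk), `state` (updated), `pruned` (number
#'   removed this step), and `removed_current` (per-hidden-layer integer
#'   vectors of removed current positions, for shrinking other congruent
#'   models).
#' @export
prune_step <- function(model, state, apoz) {
  n_hidden_layers <- length(state$keep_masks)
  left <- prune_target(state) - state$pruned_total
  if (left <= 0L) {
    return(list(
      model = model, state = state, pruned = 0L,
      removed_current = rep(list(integer(0)), n_hidden_layers)
    ))
  }
  remaining_per_layer <- vapply(state$keep_masks, sum, 1L)
  remaining <- sum(remaining_per_layer)
  k <- min(max(1L, floor(state$schedule$rate_per_loop * remaining)), left)

  # Candidate table: (hidden layer, current position, original index, apoz),
  # ranked by apoz descending with deterministic tie-breaks.
  cand <- purrr::imap(apoz$values, function(v, l) {
    tibble::tibble(
      layer = as.integer(l),
      pos = seq_along(v),
      orig = which(state$keep_masks[[l]]),
      apoz = v
    )
  })
  cand <- dplyr::bind_rows(cand)
  cand <- cand[order(-cand$apoz, cand$layer, cand$pos), , drop = FALSE]

  removed_current <- rep(list(integer(0)), n_hidden_layers)
  taken <- 0L
  for (i in seq_len(nrow(cand))) {
    if (taken == k) break
    l <- cand$layer[i]
    if (remaining_per_layer[l] <= 1L) next # never empty a layer
    removed_current[[l]] <- c(removed_current[[l]], cand$pos[i])
    state$keep_masks[[l]][cand$orig[i]] <- FALSE
    remaining_per_layer[l] <- remaining_per_layer[l] - 1L
    taken <- taken + 1L
  }
  state$pruned_total <- state$pruned_total + taken
  list(
    model = drop_neurons(model, removed_current),
    state = state,
    pruned = taken,
    removed_current = removed_current
  )
}

# Structurally remove hidden neurons given per-hidden-layer current
# positions: drop incoming columns + bias entries of layer l and incoming
# rows of layer l + 1.
drop_neurons <- function(model, removed_current) {
  for (l in seq_along(removed_current)) {
    rm_pos <- removed_current[[l]]
    if (length(rm_pos) == 0L) next
    keep <- setdiff(seq_len(ncol(model$weights[[l]])), rm_pos)
    model$weights[[l]] <- model$weights[[l]][, keep, drop = FALSE]
    model$biases[[l]] <- model$biases[[l]][keep]
    model$weights[[l + 1L]] <- model$weights[[l + 1L]][keep, , drop = FALSE]
    model$layer_sizes[l + 1L] <- length(keep)
  }
  model
}

current_sizes <- function(state) {
  sizes <- state$original_sizes
  L <- length(sizes) - 1L
  sizes[2:L] <- vapply(state$keep_masks, sum, 1L)
  sizes
}

#' Shrink a model to the pruned architecture
#'
#' Accepts a model at the ORIGINAL layer sizes (shrinks it per the keep
#' masks) or at the current pruned sizes (returned unchanged, so the
#' operation is idempotent).
#'
#' @param model_any a [init_model()] object at original or current sizes.
#' @param state a [new_prune_state()].
#' @export
apply_mask <- function(model_any, state) {
  if (identical(as.integer(model_any$layer_sizes), current_sizes(state))) {
    return(model_any)
  }
  if (!identical(as.integer(model_any$layer_sizes), state$original_sizes)) {
    abort("model is at neither the original nor the current pruned sizes")
  }
  removed <- lapply(state$keep_masks, function(m) which(!m))
  drop_neurons(model_any, removed)
}
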