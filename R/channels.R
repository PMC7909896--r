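#' Weight positions carried by a neural channel
#'
#' A *channel* is a path through the network identified by one neuron per
#' layer, `(t_1, ..., t_L)`. It carries the full input column into its
#' first-layer neuron — positions `(layer 1, i, t_1)` for every input `i` —
#' plus one inter-layer edge `(layer l, t_{l-1}, t_l)` for each subsequent
#' layer, so the entry set has `m_0 + (L - 1)` positions. Distinct channels
#' may share positions (all channels with the same `t_1` share that input
#' column), which is why uploading a fraction alpha of channels generally
#' uploads more than alpha of the parameters.
#'
#' @param channel integer vector `(t_1, ..., t_L)`, 1-based.
#' @param layer_sizes `(m_0, m_1, ..., m_L)` as in [init_model()].
#' @return integer matrix with columns `layer`, `row`, `col`, one weight
#'   position per row.
#' @export
channel_entry_set <- function(channel, layer_sizes) {
  L <- length(layer_sizes) - 1L
  if (length(channel) != L) abort("channel must have one index per layer")
  if (any(channel < 1) || any(channel > layer_sizes[-1])) {
    abort("channel index out of range")
  }
  m0 <- layer_sizes[1]
  first <- cbind(layer = 1L, row = seq_len(m0), col = channel[1])
  if (L == 1L) return(first)
  rest <- cbind(
    layer = 2:L,
    row = channel[seq_len(L - 1L)],
    col = channel[2:L]
  )
  rbind(first, rest)
}

#' Euclidean norms of every gradient channel
#'
#' For each channel `(t_1, ..., t_L)` the Euclidean norm of the gradient
#' entries on its entry set is stored in an L-dimensional tensor of shape
#' `m_1 x ... x m_L`. Computed by accumulating squared contributions layer
#' by layer, which is algebraically identical to — but much faster than —
#' enumerating every channel's entry set.
#'
#' @param gradient a `gradient_set` from [train_local()] (or any congruent
#'   list of per-layer weight-delta matrices with a `layer_sizes` element).
#' @return object of class `channel_norm_tensor`: list with `norms`
#'   (L-dimensional array) and `layer_sizes`.
#' @export
channel_norms <- function(gradient) {
  g <- gradient$deltas
  L <- length(g)
  sq <- lapply(g, function(m) m^2)
  acc <- colSums(sq[[1]]) # indexed by t_1
  if (L > 1L) {
    for (l in 2:L) {
      dims_prev <- if (l == 2L) length(acc) else dim(acc)
      m_l <- ncol(g[[l]])
      acc <- array(rep(acc, times = m_l), dim = c(dims_prev, m_l))
      nd <- length(dim(acc))
      i_prev <- as.vector(slice.index(acc, nd - 1L))
      i_new <- as.vector(slice.index(acc, nd))
      acc <- acc + array(sq[[l]][cbind(i_prev, i_new)], dim = dim(acc))
    }
  } else {
    acc <- array(acc, dim = length(acc))
  }
  structure(
    list(norms = sqrt(acc), layer_sizes = gradient$layer_sizes),
    class = "channel_norm_tensor"
  )
}

#' @export
print.channel_norm_tensor <- function(x, ...) {
  cat(sprintf(
    "<channel_norm_tensor> shape %s (%d channels)\n",
    paste(dim(x$norms), collapse = " x "), length(x$norms)
  ))
  invisible(x)
}

#' Norm cutoff for channel selection
#'
#' Flattens the norm tensor, sorts it in descending order, and returns the
#' value at rank `ceiling(alpha * K)` (`K` = number of channels), so that
#' channels with norm `>=` the threshold number at least `ceiling(alpha*K)`
#' and — with all-distinct norms — exactly that many. Ties are inclusive.
#'
#' @param norm_tensor a [channel_norms()] result.
#' @param alpha update rate in `(0, 1]`: the fraction of channels to upload.
#' @return the threshold norm (scalar).
#' @export
selection_threshold <- function(norm_tensor, alpha) {
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1]")
  v <- sort(as.vector(norm_tensor$norms), decreasing = TRUE)
  v[rank_count(alpha, length(v))]
}

# ceiling(alpha * K) with a guard against floating-point overshoot when
# alpha was itself derived as a ratio k/K.
rank_count <- function(alpha, K) {
  max(1L, min(K, as.integer(ceiling(alpha * K - 1e-9))))
}

#' Sparsify a gradient by channel selection
#'
#' The core upload step: channels are ranked by Euclidean norm and only the
#' gradient entries lying on selected channels survive; everything else is
#' set to exactly zero. With *positive* selection the top
#' `ceiling(alpha * K)` channels (norm `>=` the [selection_threshold()]) are
#' kept. With *negative* selection the bottom `K - ceiling(alpha * K)`
#' channels are discarded and the remainder kept; the two coincide for
#' distinct norms and differ only in how ties are resolved. Biases are never
#' part of the upload.
#'
#' @param gradient a `gradient_set` from [train_local()].
#' @param alpha update rate in `(0, 1]`.
#' @param mode `"positive"` (default) or `"negative"`.
#' @return object of class `processed_gradient`: list with
#'   \describe{
#'     \item{deltas}{sparsified per-layer matrices (the uploaded update)}
#'     \item{support}{per-layer logical masks of uploaded positions}
#'     \item{selected_channels}{matrix of selected channel index tuples}
#'     \item{channel_fraction}{selected / total channels}
#'     \item{parameter_fraction}{nonzero entries / total weight entries}
#'     \item{n_support}{number of uploaded positions (zeros on selected
#'       channels are transmitted as zeros, so this is the wire size)}
#'     \item{n_nonzero, n_total, alpha, mode, threshold}{accounting}
#'   }
#' @export
process_gradients <- function(gradient, alpha, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  nt <- channel_norms(gradient)
  norms <- nt$norms
  K <- length(norms)
  k_keep <- rank_count(alpha, K)
  thr <- selection_threshold(nt, alpha)
  if (mode == "positive") {
    selected <- norms >= thr
  } else {
    k_drop <- K - k_keep
    if (k_drop == 0L) {
      selected <- array(TRUE, dim = dim(norms))
    } else {
      cutoff <- sort(as.vector(norms))[k_drop]
      selected <- norms > cutoff
      if (!any(selected)) selected <- norms >= max(norms) # total-tie fallback
    }
  }

  support <- support_masks(selected, gradient$layer_sizes)
  deltas <- purrr::map2(gradient$deltas, support, function(g, m) g * m)
  n_total <- sum(vapply(gradient$deltas, length, 1L))
  structure(
    list(
      deltas = deltas,
      support = support,
      selected_channels = which_tuples(selected),
      channel_fraction = sum(selected) / K,
      parameter_fraction = sum(vapply(deltas, function(d) sum(d != 0), 1)) / n_total,
      n_support = sum(vapply(support, sum, 1)),
      n_nonzero = sum(vapply(deltas, function(d) sum(d != 0), 1)),
      n_total = n_total,
      alpha = alpha,
      mode = mode,
      threshold = thr,
      layer_sizes = gradient$layer_sizes
    ),
    class = "processed_gradient"
  )
}

# Per-layer logical masks of the weight positions covered by >= 1 selected
# channel. Layer 1: whole input columns of selected t_1; layer l >= 2: the
# (t_{l-1}, t_l) margin of the selection tensor.
support_masks <- function(selected, layer_sizes) {
  L <- length(layer_sizes) - 1L
  m0 <- layer_sizes[1]
  dims <- layer_sizes[-1]
  masks <- vector("list", L)
  sel_arr <- if (is.null(dim(selected))) array(selected, dim = length(selected)) else selected
  first_cols <- if (L == 1L) as.vector(sel_arr) else apply(sel_arr, 1, any)
  masks[[1]] <- matrix(rep(first_cols, each = m0), nrow = m0)
  if (L > 1L) {
    for (l in 2:L) {
      masks[[l]] <- matrix(
        apply(sel_arr, c(l - 1L, l), any),
        nrow = dims[l - 1L]
      )
    }
  }
  masks
}

which_tuples <- function(selected) {
  if (is.null(dim(selected)) || length(dim(selected)) == 1L) {
    matrix(which(as.vector(selected)), ncol = 1)
  } else {
    which(selected, arr.ind = TRUE)
  }
}

#' @export
print.processed_gradient <- function(x, ...) {
  cat(sprintf(
    "<processed_gradient> alpha %.2f (%s): %d/%d channels, %.1f%% of parameters nonzero\n",
    x$alpha, x$mode, nrow(x$selected_channels),
    prod(x$layer_sizes[-1]), 100 * x$parameter_fraction
  ))
  invisible(x)
}

#' Serialize a processed gradient as a sparse triplet list
#'
#' This is the simulated wire format of an upload: one `(layer, row, col,
#' value)` record per position on a selected channel (exact zeros included),
#' plus metadata. The record count is the trans-information size of the
#' upload.
#'
#' @param upload a [process_gradients()] result.
#' @return a tibble with columns `layer`, `row`, `col`, `value`.
#' @export
upload_triplets <- function(upload) {
  recs <- purrr::imap(upload$support, function(m, l) {
    pos <- which(m, arr.ind = TRUE)
    if (nrow(pos) == 0L) return(NULL)
    tibble::tibble(
      layer = as.integer(l), row = pos[, 1], col = pos[, 2],
      value = upload$deltas[[l]][pos]
    )
  })
  dplyr::bind_rows(recs)
}

#' @rdname upload_triplets
#' @param path file path for the JSON wire message.
#' @export
write_upload_json <- function(upload, path) {
  jsonlite::write_json(
    list(
      alpha = upload$alpha, mode = upload$mode,
      channel_fraction = upload$channel_fraction,
      parameter_fraction = upload$parameter_fraction,
      layer_sizes = upload$layer_sizes,
      triplets = upload_triplets(upload)
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
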