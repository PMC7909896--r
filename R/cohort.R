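#' Synthetic medication-exposure cohorts
#'
#' A *cohort* is a sample-by-feature binary exposure matrix (one indicator per
#' medication) together with a binary mortality label per sample. Real
#' hospital-admission data of this shape are rarely shareable, so the
#' generator below emulates their statistical structure: most medications are
#' rare (right-skewed per-feature prevalence) and the outcome depends
#' log-linearly on a subset of informative exposures.
#'
#' @param features integer/numeric matrix with entries in `{0, 1}`,
#'   `n_samples x n_features`.
#' @param labels vector of `0`/`1` outcomes (1 = died), length `n_samples`.
#' @param feature_prevalence per-feature Bernoulli rates in `(0, 1)`, or
#'   `NULL` when unknown (e.g. for user-supplied data).
#' @param truth generating coefficients (`intercept`, `beta`) kept for
#'   diagnostics, or `NULL`.
#' @return An object of class `cohort`.
#' @seealso [generate_cohort()], [split_federation()], [as_cohort()]
#' @export
new_cohort <- function(features, labels, feature_prevalence = NULL, truth = NULL) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (nrow(features) == 0L) abort("a cohort needs at least one sample")
  if (nrow(features) != length(labels)) {
    abort("`features` rows and `labels` length differ")
  }
  if (!all(features %in% c(0, 1))) abort("feature entries must be 0 or 1")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  if (!is.null(feature_prevalence) &&
      (any(feature_prevalence <= 0) || any(feature_prevalence >= 1))) {
    abort("feature_prevalence entries must lie in (0, 1)")
  }
  structure(
    list(
      features = features,
      labels = labels,
      feature_prevalence = feature_prevalence,
      truth = truth
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d samples x %d features; outcome prevalence %.3f\n",
    nrow(x$features), ncol(x$features), mean(x$labels)
  ))
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$features)

#' Generate a synthetic cohort
#'
#' Draws per-feature prevalences from a right-skewed Beta distribution
#' (clipped away from 0 and 0.5, so every exposure is possible but most are
#' rare), samples binary exposures independently, and draws the mortality
#' label from a logistic model
#' `P(death) = sigmoid(base_log_odds + x . beta)` where `beta` has
#' `n_informative` nonzero entries of magnitude `effect_scale` with random
#' signs.
#'
#' @param n_samples,n_features cohort dimensions (both >= 1).
#' @param n_informative number of features with nonzero effect
#'   (`<= n_features`).
#' @param base_log_odds intercept of the outcome model; the default `-1.5`
#'   gives roughly 18% mortality when effects cancel.
#' @param effect_scale absolute log-odds effect of each informative feature.
#' @param prevalence_shape `c(a, b)` shape parameters of the Beta prevalence
#'   distribution; the default `c(0.3, 3)` concentrates mass near zero.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return A [new_cohort()] object whose `truth` element records the
#'   generating intercept and coefficient vector.
#' @examples
#' coh <- generate_cohort(200, 20, n_informative = 5, seed = 1)
#' mean(coh$labels)
#' @export
generate_cohort <- function(n_samples, n_features, n_informative,
                            base_log_odds = -1.5, effect_scale = 1,
                            prevalence_shape = c(0.3, 3), seed = 0L) {
  if (n_samples < 1 || n_features < 1) abort("cohort dimensions must be positive")
  if (n_informative > n_features) abort("n_informative cannot exceed n_features")
  if (n_informative < 0) abort("n_informative must be >= 0")
  run_seeded(seed, {
    prev <- rbeta(n_features, prevalence_shape[1], prevalence_shape[2])
    prev <- pmin(pmax(prev, 0.001), 0.5)
    x <- matrix(
      rbinom(n_samples * n_features, 1L, rep(prev, each = n_samples)),
      nrow = n_samples
    )
    beta <- numeric(n_features)
    if (n_informative > 0) {
      idx <- sample.int(n_features, n_informative)
      beta[idx] <- effect_scale * sample(c(-1, 1), n_informative, replace = TRUE)
    }
    p <- plogis(base_log_odds + drop(x %*% beta))
    y <- rbinom(n_samples, 1L, p)
    new_cohort(x, y,
      feature_prevalence = prev,
      truth = list(intercept = base_log_odds, beta = beta)
    )
  })
}

#' Build a cohort from a data frame
#'
#' Data-frame-first entry point for user-supplied cohorts: all columns other
#' than `label_col` are taken as binary exposure features.
#'
#' @param data a data frame with 0/1 feature columns and a 0/1 label column.
#' @param label_col name of the outcome column (default `"label"`).
#' @return A [new_cohort()] object.
#' @export
as_cohort <- function(data, label_col = "label") {
  data <- as.data.frame(data)
  if (!label_col %in% names(data)) {
    abort(sprintf("column '%s' not found", label_col))
  }
  feats <- as.matrix(data[setdiff(names(data), label_col)])
  new_cohort(feats, data[[label_col]])
}

#' @export
#' @importFrom tibble as_tibble
as_tibble.cohort <- function(x, ...) {
  feats <- x$features
  colnames(feats) <- colnames(feats) %||% paste0("f", seq_len(ncol(feats)))
  out <- as_tibble(as.data.frame(feats))
  out$label <- x$labels
  out
}

# Row-subset view of a cohort (prevalence/truth metadata carried along).
# Unlike new_cohort(), an empty view is allowed: degenerate splits such as
# fractions = c(1, 0, 0) legitimately produce empty validation/test parts.
cohort_subset <- function(cohort, idx) {
  structure(
    list(
      features = cohort$features[idx, , drop = FALSE],
      labels = cohort$labels[idx],
      feature_prevalence = cohort$feature_prevalence,
      truth = cohort$truth
    ),
    class = "cohort"
  )
}

#' Partition a cohort into a federation layout
#'
#' Splits a cohort into train/validation/test by the given fractions, then
#' divides the training partition into `n_clients` near-equal client shards.
#' Validation and test sizes are floored; the remainder goes to training, and
#' the training remainder is distributed one row each to the first shards, so
#' shard sizes never differ by more than one.
#'
#' `shard_skew` interpolates between IID shards (0) and label-sorted
#' contiguous shards (1): rows are ordered by a convex blend of a uniform
#' random key and the normalised label-sorted rank, then cut into equal
#' blocks, which preserves exact shard sizes at every skew.
#'
#' @param cohort a [new_cohort()] object.
#' @param n_clients number of client shards (>= 1; the default 5 matches a
#'   five-hospital federation).
#' @param fractions `c(train, validation, test)` summing to 1.
#' @param shard_skew label skew in `[0, 1]`; 0 = IID.
#' @param seed integer seed for the row permutation.
#' @return An object of class `federation_split`: list with `client_shards`
#'   (list of cohorts), `validation`, `test`, `split_fractions`, and the
#'   row-index bookkeeping in `indices`.
#' @export
split_federation <- function(cohort, n_clients = 5, fractions = c(0.6, 0.1, 0.3),
                             shard_skew = 0, seed = 0L) {
  if (n_clients < 1) abort("n_clients must be >= 1")
  if (abs(sum(fractions) - 1) > 1e-9) abort("fractions must sum to 1")
  if (shard_skew < 0 || shard_skew > 1) abort("shard_skew must lie in [0, 1]")
  n <- nrow(cohort$features)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < n_clients) abort("training partition smaller than the number of clients")

  run_seeded(seed, {
    perm <- sample.int(n)
    train_idx <- perm[seq_len(n_train)]
    val_idx <- if (n_val > 0) perm[n_train + seq_len(n_val)] else integer(0)
    test_idx <- if (n_test > 0) perm[n_train + n_val + seq_len(n_test)] else integer(0)

    # Blend a random key with the label-sorted rank, then cut equal blocks.
    u <- runif(n_train)
    sorted_rank <- rank(cohort$labels[train_idx], ties.method = "first") / n_train
    key <- (1 - shard_skew) * u + shard_skew * sorted_rank
    train_idx <- train_idx[order(key)]

    base <- n_train %/% n_clients
    extra <- n_train %% n_clients
    sizes <- rep(base, n_clients) + c(rep(1L, extra), rep(0L, n_clients - extra))
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1) + 1L)
    shard_idx <- lapply(seq_len(n_clients), function(k) train_idx[starts[k]:ends[k]])

    structure(
      list(
        client_shards = lapply(shard_idx, function(i) cohort_subset(cohort, i)),
        validation = cohort_subset(cohort, val_idx),
        test = cohort_subset(cohort, test_idx),
        split_fractions = fractions,
        indices = list(shards = shard_idx, validation = val_idx, test = test_idx)
      ),
      class = "federation_split"
    )
  })
}

#' @export
print.federation_split <- function(x, ...) {
  cat(sprintf(
    "<federation_split> %d client shards (%s rows), validation %d, test %d\n",
    length(x$client_shards),
    paste(vapply(x$indices$shards, length, 1L), collapse = "/"),
    length(x$indices$validation), length(x$indices$test)
  ))
  invisible(x)
}
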