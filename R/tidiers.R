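#' Tidy the per-loop log of a federation run
#'
#' @param x a `fed_run` from [run_federation()].
#' @param ... unused.
#' @return the run log as a tibble, one row per global loop (the
#'   `client_seeds` list-column dropped).
#' @export
tidy.fed_run <- function(x, ...) {
  dplyr::select(x$log, -"client_seeds")
}

#' One-row summary of a federation run
#'
#' @inheritParams tidy.fed_run
#' @return tibble with the algorithm, loop count, final test AUC-ROC and
#'   AUC-PR, mean upload fraction, cumulative uploaded entries, remaining
#'   hidden neurons, pruned count and remaining weight parameters.
#' @export
glance.fed_run <- function(x, ...) {
  n <- nrow(x$log)
  tibble::tibble(
    algorithm = x$config$algorithm,
    global_loops = n,
    auc_roc = if (n > 0) x$log$auc_roc[n] else NA_real_,
    auc_pr = if (n > 0) x$log$auc_pr[n] else NA_real_,
    mean_upload_fraction = if (n > 0) mean(x$log$mean_upload_fraction) else NA_real_,
    cum_uploaded_entries = if (n > 0) x$log$cum_uploaded_entries[n] else 0,
    neurons_remaining = sum(x$server$layer_sizes[-c(1, length(x$server$layer_sizes))]),
    neurons_pruned = if (is.null(x$prune_state)) 0L else x$prune_state$pruned_total,
    weight_params = n_weight_params(x$server)
  )
}

#' Plot the learning trajectory of a federation run
#'
#' Test-set AUC-ROC and AUC-PR against the global loop.
#'
#' @param object a `fed_run`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fed_run <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(
      c("auc_roc", "auc_pr"),
      names_to = "metric", values_to = "value"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$loop, .data$value, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "global loop", y = "area under curve",
      title = sprintf("%s run", object$config$algorithm)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ROC or precision-recall curve
#'
#' @param object a [curve_points()] tibble.
#' @param which `"roc"` or `"pr"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.curve_points <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    p <- ggplot2::ggplot(object, ggplot2::aes(.data$fpr, .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
      ggplot2::labs(x = "false positive rate", y = "true positive rate")
  } else {
    p <- ggplot2::ggplot(object, ggplot2::aes(.data$recall, .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "recall", y = "precision")
  }
  p + ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Compare upload volume between runs
#'
#' Cumulative uploaded weight entries (the trans-information proxy) per
#' global loop for one or more runs.
#'
#' @param ... named `fed_run` objects.
#' @return a ggplot object.
#' @export
plot_trans_information <- function(...) {
  runs <- list(...)
  if (is.null(names(runs)) || any(names(runs) == "")) {
    names(runs) <- vapply(runs, function(r) r$config$algorithm, "")
  }
  df <- purrr::imap(runs, function(r, nm) {
    dplyr::mutate(tidy(r), run = nm)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$loop, .data$cum_uploaded_entries, colour = .data$run)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "global loop", y = "cumulative uploaded entries") +
    ggplot2::theme_minimal()
}
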