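#' Write / read a cohort as CSV
#'
#' Plain-text interchange format: header `f1..fN,label`, one 0/1 row per
#' sample. `write_cohort_csv()` optionally writes a JSON sidecar
#' (`<path>.json`) recording the generator configuration and seed so a
#' cohort file is self-describing.
#'
#' @param cohort a [new_cohort()] object.
#' @param path CSV file path.
#' @param config optional named list echoed into the sidecar.
#' @param sidecar write the JSON sidecar? (default: only when `config` is
#'   supplied)
#' @return the path, invisibly; `read_cohort_csv()` returns a cohort.
#' @export
write_cohort_csv <- function(cohort, path, config = NULL,
                             sidecar = !is.null(config)) {
  df <- tibble::as_tibble(cohort)
  names(df) <- c(paste0("f", seq_len(ncol(cohort$features))), "label")
  readr::write_csv(df, path)
  if (sidecar) {
    jsonlite::write_json(
      list(
        config = config,
        n_samples = nrow(cohort$features),
        n_features = ncol(cohort$features)
      ),
      paste0(path, ".json"),
      digits = NA, auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  as_cohort(df, label_col = "label")
}

default_experiment_config <- function() {
  list(
    data = list(
      n_samples = 2000L, n_features = 200L, n_informative = 20L,
      base_log_odds = -1.5, effect_scale = 3, prevalence_shape = c(0.3, 3),
      csv = NULL
    ),
    federation = list(
      n_clients = 5L, global_loops = 100L, hidden_sizes = c(64L, 32L),
      alpha = 0.30, decay = 0.8, download_rate = 1.0,
      selection_mode = "positive", algorithm = "scbfl",
      pruning_enabled = FALSE, prune_rate = 0.10, prune_total = 0.47,
      learning_rate = 0.01, batch_size = 32L, epochs_per_loop = 5L,
      dropout_rate = 0.5,
      fractions = c(0.6, 0.1, 0.3), shard_skew = 0
    ),
    sweep = list(alphas = NULL, prune_rates = NULL, prune_totals = NULL,
                 seeds = NULL),
    output_dir = ".",
    master_seed = 0L,
    schema_version = 1L
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read an experiment configuration
#'
#' Experiments are described by a small YAML file with `data`,
#' `federation`, `sweep` and `output_dir` sections; unspecified fields take
#' the package defaults (which mirror the reference distributed setting).
#' The `data` section must describe exactly one source: either generator
#' parameters or a cohort `csv` path.
#'
#' @param path YAML file, or `NULL` for the full default configuration.
#' @param overrides optional named list merged over the file values.
#' @return a validated `experiment_config` list.
#' @export
read_experiment_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_experiment_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  validate_experiment_config(cfg)
}

validate_experiment_config <- function(cfg) {
  d <- cfg$data
  if (!is.null(d$csv)) {
    cfg$data <- list(csv = d$csv) # CSV wins; generator params ignored
  } else if (is.null(d$n_samples) || is.null(d$n_features)) {
    abort("data: supply either a `csv` path or generator parameters (n_samples, n_features)")
  }
  f <- cfg$federation
  if (!f$algorithm %in% c("scbfl", "fedavg")) {
    abort("federation.algorithm: must be 'scbfl' or 'fedavg'")
  }
  if (f$alpha <= 0 || f$alpha > 1) abort("federation.alpha: must lie in (0, 1]")
  if (abs(sum(f$fractions) - 1) > 1e-9) abort("federation.fractions: must sum to 1")
  structure(cfg, class = "experiment_config")
}

fed_config_of <- function(cfg, master_seed = NULL, ...) {
  f <- cfg$federation
  dots <- list(...)
  args <- list(
    n_clients = f$n_clients, global_loops = f$global_loops,
    hidden_sizes = f$hidden_sizes, alpha = f$alpha, decay = f$decay,
    download_rate = f$download_rate, selection_mode = f$selection_mode,
    algorithm = f$algorithm, pruning_enabled = f$pruning_enabled,
    prune_rate = f$prune_rate, prune_total = f$prune_total,
    train = train_config(
      learning_rate = f$learning_rate, batch_size = f$batch_size,
      epochs_per_loop = f$epochs_per_loop, dropout_rate = f$dropout_rate
    ),
    master_seed = master_seed %||% cfg$master_seed
  )
  args[names(dots)] <- dots
  do.call(federation_config, args)
}

load_cohort <- function(cfg) {
  d <- cfg$data
  if (!is.null(d$csv)) {
    read_cohort_csv(d$csv)
  } else {
    generate_cohort(
      n_samples = d$n_samples, n_features = d$n_features,
      n_informative = d$n_informative %||% 0L,
      base_log_odds = d$base_log_odds %||% -1.5,
      effect_scale = d$effect_scale %||% 1,
      prevalence_shape = d$prevalence_shape %||% c(0.3, 3),
      seed = cfg$master_seed
    )
  }
}

#' Generate a cohort and write it to disk
#'
#' Writes `cohort.csv` (plus its JSON sidecar) into `output_dir`.
#'
#' @param config an `experiment_config` from [read_experiment_config()].
#' @return the CSV path, invisibly.
#' @export
cmd_generate <- function(config = read_experiment_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- load_cohort(config)
  path <- file.path(config$output_dir, "cohort.csv")
  write_cohort_csv(cohort, path,
    config = list(data = config$data, master_seed = config$master_seed)
  )
  invisible(path)
}

#' Run one configured federation experiment
#'
#' Loads or generates the cohort, builds the federation split, runs the
#' configured algorithm, and writes `runlog.csv`, `summary.json` and
#' `model.json` into `output_dir`. The summary echoes the fully resolved
#' configuration, so a run can be reproduced bit-for-bit from its summary
#' alone.
#'
#' @param config an `experiment_config`.
#' @return the `fed_run` object, invisibly.
#' @export
cmd_run <- function(config = read_experiment_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- load_cohort(config)
  f <- config$federation
  split <- split_federation(
    cohort,
    n_clients = f$n_clients, fractions = f$fractions,
    shard_skew = f$shard_skew, seed = config$master_seed
  )
  run <- run_federation(split, fed_config_of(config))
  readr::write_csv(
    dplyr::select(run$log, -"client_seeds"),
    file.path(config$output_dir, "runlog.csv")
  )
  write_model_json(run$server, file.path(config$output_dir, "model.json"))
  jsonlite::write_json(
    list(
      final = as.list(glance(run)),
      config = unclass(config)
    ),
    file.path(config$output_dir, "summary.json"),
    digits = NA, auto_unbox = TRUE, null = "null"
  )
  invisible(run)
}

#' Sweep update-rate and pruning settings
#'
#' Runs the configured algorithm once per combination of the listed sweep
#' values and master seed, and writes a long-format `sweep.csv` with one
#' row per `(setting, seed)`: final AUC-ROC, AUC-PR, mean upload fraction
#' and pruned-neuron count.
#'
#' @param config an `experiment_config` whose `sweep` section lists at
#'   least one of `alphas`, `prune_rates`, `prune_totals` (and optionally
#'   `seeds`, defaulting to the master seed).
#' @return the results tibble, invisibly.
#' @export
cmd_sweep <- function(config = read_experiment_config()) {
  sw <- config$sweep
  if (is.null(sw$alphas) && is.null(sw$prune_rates) && is.null(sw$prune_totals)) {
    abort("sweep: at least one of alphas / prune_rates / prune_totals must be non-empty")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- load_cohort(config)
  f <- config$federation
  seeds <- sw$seeds %||% config$master_seed
  grid <- expand.grid(
    alpha = sw$alphas %||% f$alpha,
    prune_rate = sw$prune_rates %||% f$prune_rate,
    prune_total = sw$prune_totals %||% f$prune_total,
    seed = seeds,
    KEEP.OUT.ATTRS = FALSE
  )
  rows <- purrr::pmap(grid, function(alpha, prune_rate, prune_total, seed) {
    split <- split_federation(
      cohort,
      n_clients = f$n_clients, fractions = f$fractions,
      shard_skew = f$shard_skew, seed = seed
    )
    run <- run_federation(split, fed_config_of(
      config,
      master_seed = as.integer(seed),
      alpha = alpha, prune_rate = prune_rate, prune_total = prune_total,
      pruning_enabled = f$pruning_enabled ||
        !is.null(sw$prune_rates) || !is.null(sw$prune_totals)
    ))
    dplyr::bind_cols(
      tibble::tibble(
        alpha = alpha, prune_rate = prune_rate,
        prune_total = prune_total, seed = seed
      ),
      glance(run)
    )
  })
  out <- dplyr::bind_rows(rows)
  readr::write_csv(out, file.path(config$output_dir, "sweep.csv"))
  invisible(out)
}
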