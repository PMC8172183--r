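#' Run the full classifier benchmark over raw and latent feature sets
#'
#' For every feature set, every classifier is cross-validated twice: on the
#' raw features and on autoencoder latent representations. Latent features are
#' produced fold-safely by default — one autoencoder per training fold — so no
#' test-fold row ever influences the representation it is evaluated in.
#'
#' @param feature_sets Named list of feature tibbles (typically `power`, `rg`,
#'   `bli` from [extract_features()]).
#' @param classifiers List of [classifier_spec()]s; defaults to the six
#'   deterministic classifiers of [default_classifiers()].
#' @param n_folds Number of CV folds.
#' @param seed Integer seed.
#' @param group_filters Character vector drawn from `"all"`, `"nurse"`,
#'   `"control"`.
#' @param ae_arch Optional [ae_architecture()] shared by all latent runs
#'   (defaults per feature set to the 50-50-50 stack on its dimensionality).
#' @param ae_hyper Hyperparameter list for the fold autoencoders.
#' @param ae_global Train one autoencoder on all rows instead of per fold (the
#'   optimistic variant).
#' @param representations Which representations to run: `"raw"`, `"latent"` or
#'   both (default).
#' @return An `eeg_benchmark` tibble with one row per (feature set,
#'   representation, classifier, group filter, fold).
#' @export
run_benchmark <- function(feature_sets, classifiers = default_classifiers(),
                          n_folds = 5, seed = 1L, group_filters = "all",
                          ae_arch = NULL, ae_hyper = list(), ae_global = FALSE,
                          representations = c("raw", "latent")) {
  if (is.null(names(feature_sets))) {
    names(feature_sets) <- map_chr(feature_sets, function(f) {
      attr(f, "feature_set") %||% "features"
    })
  }
  grid <- tidyr::expand_grid(
    set = names(feature_sets),
    representation = representations,
    clf = seq_along(classifiers),
    grp = group_filters
  )
  res <- pmap(grid, function(set, representation, clf, grp) {
    feats <- feature_sets[[set]]
    attr(feats, "feature_set") <- set # list names label the benchmark cells
    crossvalidate(
      feats, classifiers[[clf]], n_folds = n_folds, seed = seed,
      group_filter = grp, ae_latent = representation == "latent",
      ae_arch = ae_arch, ae_hyper = ae_hyper, ae_global = ae_global
    )
  }) |> list_rbind()
  class(res) <- c("eeg_benchmark", class(res))
  res
}

#' Summarise a benchmark into one row per configuration
#'
#' Averages accuracy over folds and per-class precision/F1 over folds and
#' classes, flags the best classifier per (feature set, representation), and
#' sorts by feature set then descending accuracy.
#'
#' @param results An `eeg_benchmark` tibble from [run_benchmark()] or
#'   [crossvalidate()].
#' @param path Optional CSV output path.
#' @return A summary tibble.
#' @export
report_benchmark <- function(results, path = NULL) {
  if (is.null(results) || nrow(results) == 0) abort("empty benchmark results")
  per_class <- results |>
    select("feature_set", "representation", "classifier", "group_filter", "per_class") |>
    tidyr::unnest("per_class")
  if (!all(is.finite(results$accuracy)) || !all(is.finite(per_class$precision)) ||
      !all(is.finite(per_class$f1))) {
    abort("benchmark results contain non-finite metrics")
  }
  keys <- c("feature_set", "representation", "classifier", "group_filter")
  summary <- results |>
    group_by(across(all_of(keys))) |>
    summarise(
      n_folds = n(), mean_accuracy = mean(.data$accuracy),
      sd_accuracy = sd(.data$accuracy), .groups = "drop"
    ) |>
    left_join(
      per_class |>
        group_by(across(all_of(keys))) |>
        summarise(mean_precision = mean(.data$precision),
                  mean_f1 = mean(.data$f1), .groups = "drop"),
      by = keys
    ) |>
    group_by(.data$feature_set, .data$representation, .data$group_filter) |>
    mutate(best = .data$mean_accuracy == max(.data$mean_accuracy)) |>
    ungroup() |>
    arrange(.data$feature_set, .data$representation, desc(.data$mean_accuracy))
  if (!is.null(path)) utils::write.csv(summary, path, row.names = FALSE)
  summary
}

#' @export
print.eeg_benchmark <- function(x, ...) {
  cat(sprintf("<eeg_benchmark> %d fold-level results\n", nrow(x)))
  NextMethod()
}

#' Per-fold accuracies of a benchmark, tidy form
#' @param x An `eeg_benchmark`.
#' @param ... Unused.
#' @export
tidy.eeg_benchmark <- function(x, ...) {
  as_tibble(x) |>
    select(any_of(c("feature_set", "representation", "classifier",
                    "group_filter", "fold", "accuracy")))
}

#' One-row-per-configuration summary of a benchmark
#' @inheritParams tidy.eeg_benchmark
#' @export
glance.eeg_benchmark <- function(x, ...) report_benchmark(x)
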