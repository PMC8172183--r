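#' t-SNE embedding of a feature space
#'
#' Exact (non-approximate) t-SNE of the feature rows to two dimensions, used
#' to inspect how separable the four conditions are in a raw or latent feature
#' space. Defaults mirror the pipeline's diagnostic protocol: perplexity 10,
#' 5000 iterations, learning rate 1000. Deterministic given the seed.
#'
#' @param features A feature tibble (or numeric matrix).
#' @param perplexity t-SNE perplexity. Alternatively set `perplexity_frac` to
#'   use a fraction of the row count (the literal "10%" reading).
#' @param n_iter Number of gradient iterations.
#' @param learning_rate t-SNE learning rate (eta).
#' @param seed Integer seed.
#' @param perplexity_frac If non-`NULL`, overrides `perplexity` with
#'   `perplexity_frac * n` rows.
#' @return A tibble of class `eeg_embedding` with columns `dim1`, `dim2` and
#'   the metadata columns of the input; attributes record perplexity,
#'   iteration count, learning rate, seed and the final KL divergence.
#' @export
tsne_embed <- function(features, perplexity = 10, n_iter = 5000,
                       learning_rate = 1000, seed = 1L,
                       perplexity_frac = NULL) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  n <- nrow(X)
  if (!is.null(perplexity_frac)) perplexity <- floor(perplexity_frac * n)
  if (n - 1 < 3 * perplexity) {
    abort(sprintf("perplexity %g needs more than %g rows, got %d",
                  perplexity, 3 * perplexity + 1, n))
  }
  # canonical row ordering makes the embedding invariant to input row order:
  # the seeded initialization is tied to sorted rows, then unpermuted
  ord <- do.call(order, as.data.frame(X))
  fit <- with_seed(seed, Rtsne::Rtsne(
    X[ord, , drop = FALSE], dims = 2, perplexity = perplexity,
    max_iter = n_iter, eta = learning_rate, theta = 0, pca = FALSE,
    check_duplicates = FALSE, verbose = FALSE
  ))
  coords <- fit$Y[order(ord), , drop = FALSE]
  if (!all(is.finite(coords))) abort("embedding produced non-finite coordinates")
  meta <- if (is.matrix(features)) tibble(.rows = n) else
    features[intersect(.meta_cols, names(features))]
  out <- bind_cols(meta, tibble(dim1 = coords[, 1], dim2 = coords[, 2]))
  attr(out, "perplexity") <- perplexity
  attr(out, "n_iter") <- n_iter
  attr(out, "learning_rate") <- learning_rate
  attr(out, "seed") <- as.integer(seed)
  attr(out, "kl_divergence_final") <- tail(fit$itercosts, 1)
  class(out) <- c("eeg_embedding", class(out))
  out
}

#' Per-condition mean and standard deviation of each feature
#'
#' Standard deviation uses the population convention (divide by n), matching
#' how the feature summaries are reported.
#'
#' @param features A feature tibble.
#' @param path Optional CSV output path.
#' @return A tibble with columns `condition`, `feature`, `mean`, `sd`.
#' @export
feature_summary <- function(features, path = NULL) {
  if (is.null(features) || nrow(features) == 0) abort("empty feature table")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- features |>
    as_tibble() |>
    tidyr::pivot_longer(all_of(feature_cols(features)),
                        names_to = "feature", values_to = "value") |>
    group_by(.data$condition, .data$feature) |>
    summarise(mean = mean(.data$value), sd = pop_sd(.data$value), .groups = "drop")
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
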