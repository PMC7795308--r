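#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an error PCA into one row per feature
#'
#' @param x an [build_error_pca()] result.
#' @param ... unused.
#' @return tibble with `feature` (0-based index), `feature_name`, `mean_error`,
#'   one column per kept component and `dist`.
#' @exportS3Method generics::tidy
tidy.error_pca <- function(x, ...) {
  out <- tibble::tibble(
    feature = fp_feature_index(x$feature_names),
    feature_name = x$feature_names,
    mean_error = unname(x$mu)
  )
  dplyr::bind_cols(out, tibble::as_tibble(x$coords),
                   tibble::tibble(dist = unname(x$dist)))
}

#' @rdname tidy.error_pca
#' @exportS3Method generics::glance
glance.error_pca <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$dist), k = x$k,
    var_explained = sum(x$values[seq_len(x$k)]) / max(sum(x$values), .Machine$double.eps),
    median_dist = stats::median(x$dist)
  )
}

#' Tidy a reconstruction into per-feature error summaries
#'
#' @param x a [dbn_reconstruct()] result.
#' @param ... unused.
#' @return tibble with `feature`, `feature_name` and `mean_error` (column mean
#'   of the absolute error matrix).
#' @exportS3Method generics::tidy
tidy.dbn_reconstruction <- function(x, ...) {
  fn <- x$feature_names %||% feature_names(ncol(x$E))
  tibble::tibble(
    feature = fp_feature_index(fn), feature_name = fn,
    mean_error = unname(colMeans(x$E))
  )
}

#' @rdname tidy.dbn_reconstruction
#' @exportS3Method generics::glance
glance.dbn_reconstruction <- function(x, ...) {
  tibble::tibble(
    n_molecules = nrow(x$E), n_features = ncol(x$E),
    mean_error = mean(x$E),
    mean_molecule_error = mean(x$per_molecule_error)
  )
}

#' Tidy a trained network
#'
#' @param x a [dbn_pretrain()] result.
#' @param ... unused.
#' @return tibble with one row per RBM layer: sizes and final training error.
#' @exportS3Method generics::tidy
tidy.dbn <- function(x, ...) {
  tibble::tibble(
    layer = seq_along(x$layers),
    n_visible = x$layer_sizes[-length(x$layer_sizes)],
    n_hidden = x$layer_sizes[-1],
    final_error = x$training_log
  )
}

#' @rdname tidy.dbn
#' @exportS3Method generics::glance
glance.dbn <- function(x, ...) {
  tibble::tibble(
    n_layers = length(x$layers), fine_tuned = x$fine_tuned,
    input_width = x$layer_sizes[1],
    bottleneck = x$layer_sizes[length(x$layer_sizes)]
  )
}

#' Tidy a recall table into long form
#'
#' @param x a [build_recall_table()] result.
#' @param ... unused.
#' @return tibble with `class`, `method`, `recall`.
#' @exportS3Method generics::tidy
tidy.recall_table <- function(x, ...) {
  tidyr::pivot_longer(x$table, -"class", names_to = "method",
                      values_to = "recall")
}

#' @rdname tidy.recall_table
#' @exportS3Method generics::glance
glance.recall_table <- function(x, ...) {
  tibble::tibble(
    method = names(x$column_means),
    mean_recall = unname(x$column_means),
    best_in_class = unname(x$best_counts)
  )
}

#' Tidy a concordance result
#'
#' @param x a [kendall_w()] result.
#' @param ... unused.
#' @return tibble with one row per ranked object: `method`, `total_rank`,
#'   `mean_rank`.
#' @exportS3Method generics::tidy
tidy.kendall_w <- function(x, ...) {
  tibble::tibble(
    method = names(x$totals) %||% as.character(seq_len(x$n)),
    total_rank = unname(x$totals),
    mean_rank = unname(x$mean_ranks)
  )
}

#' @rdname tidy.kendall_w
#' @exportS3Method generics::glance
glance.kendall_w <- function(x, ...) {
  tibble::tibble(W = x$W, chisq = x$chisq, df = x$n - 1,
                 p_value = x$p_value, m = x$m, n = x$n)
}
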