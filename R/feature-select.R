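#' Principal component analysis of a reconstruction-error matrix
#'
#' Turns the per-entry reconstruction error matrix `E` (molecules x features)
#' into per-feature coordinates: the transpose `T = E'` puts one feature per
#' row; each row is centered across molecules to give the deviation matrix
#' `D`; the covariance `C = D D'` (unnormalized -- scaling changes neither
#' eigenvectors nor relative distances) is eigendecomposed; and each feature's
#' deviation row is projected onto the leading principal directions. The
#' projection of feature `i` onto component `j` equals
#' `sqrt(lambda_j) * u_j[i]`, where `u_j` are the orthonormal eigenvectors of
#' `C` with eigenvalues in nonincreasing order. A feature's distance to the
#' origin, `sqrt(x_i^2 + y_i^2 + z_i^2)` for `k = 3`, measures how much its
#' error varies across molecules: re-constructible features sit near the
#' origin.
#'
#' Eigenvector signs are fixed by flipping each component so its
#' largest-magnitude entry is positive, making results reproducible under
#' degenerate eigenvalues.
#'
#' @param E numeric `N x M` error matrix (or a `dbn_reconstruction`, whose
#'   `$E` is used), `N >= 2`.
#' @param k number of principal components to keep (default 3, giving the
#'   PCA1/PCA2/PCA3 coordinates).
#' @return object of class `error_pca`: list with `mu` (per-feature mean
#'   error), `D` (`M x N` deviation matrix), `C` (`M x M` covariance),
#'   `values` (all eigenvalues, nonincreasing), `components` (`M x k`
#'   orthonormal), `coords` (`M x k`), `dist` (length `M`), `k` and
#'   `feature_names`.
#' @export
build_error_pca <- function(E, k = 3) {
  if (inherits(E, "dbn_reconstruction")) E <- E$E
  E <- as.matrix(E)
  n <- nrow(E); m <- ncol(E)
  if (n < 2) stop("need at least 2 molecules.", call. = FALSE)
  if (k > m) stop("k cannot exceed the number of features.", call. = FALSE)
  fn <- colnames(E) %||% feature_names(m)
  tE <- t(E)
  mu <- rowMeans(tE)
  D <- tE - mu
  C <- D %*% t(D)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # sign convention: largest-magnitude entry of each component positive
  for (j in seq_len(ncol(vecs))) {
    piv <- which.max(abs(vecs[, j]))
    if (vecs[piv, j] < 0) vecs[, j] <- -vecs[, j]
  }
  comp <- vecs[, seq_len(k), drop = FALSE]
  coords <- sweep(comp, 2, sqrt(vals[seq_len(k)]), `*`)
  rownames(coords) <- rownames(comp) <- fn
  colnames(coords) <- colnames(comp) <- paste0("PCA", seq_len(k))
  structure(
    list(mu = mu, D = D, C = C, values = vals, components = comp,
         coords = coords, dist = sqrt(rowSums(coords^2)), k = k,
         feature_names = fn),
    class = "error_pca"
  )
}

#' @export
print.error_pca <- function(x, ...) {
  cat(sprintf("# error PCA: %d features, k = %d, top eigenvalues: %s\n",
              length(x$dist), x$k,
              paste(signif(x$values[seq_len(min(3, x$k))], 4), collapse = ", ")))
  invisible(x)
}

#' Select low-error features from an error PCA
#'
#' Keeps the features closest to the origin of the principal-component space:
#' those with distance at most `threshold`, sorted by ascending distance (ties
#' broken by ascending feature index) and truncated to the `top_k` best. The
#' fixed `top_k` cap (300 per fingerprint at full scale) is the primary
#' selector; the distance threshold (default 3) is a secondary filter whose
#' scale depends on the data.
#'
#' @param pca an [build_error_pca()] result.
#' @param threshold maximum distance to the origin (default 3; `Inf` disables).
#' @param top_k maximum number of features to keep (default 300).
#' @param descriptor optional descriptor label recorded on the selection.
#' @return object of class `selected_features`: tibble with columns `feature`
#'   (0-based original index), `feature_name` and `score` (distance), plus
#'   `descriptor`, `threshold` and `top_k` attributes.
#' @export
select_features <- function(pca, threshold = 3, top_k = 300,
                            descriptor = "FP") {
  stopifnot(inherits(pca, "error_pca"), top_k >= 1)
  idx <- fp_feature_index(pca$feature_names)
  keep <- which(pca$dist <= threshold)
  if (!length(keep)) {
    warning("no features fall below the distance threshold; empty selection.")
  }
  # ties compared at 10 significant digits so numerically identical features
  # (e.g. duplicated columns) respect the ascending-index tie rule
  ord <- keep[order(signif(pca$dist[keep], 10), idx[keep])]
  ord <- ord[seq_len(min(top_k, length(ord)))]
  out <- tibble::tibble(
    feature = idx[ord],
    feature_name = pca$feature_names[ord],
    score = unname(pca$dist[ord])
  )
  attr(out, "descriptor") <- descriptor
  attr(out, "threshold") <- threshold
  attr(out, "top_k") <- top_k
  class(out) <- c("selected_features", class(tibble::tibble()))
  out
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("# selected features: %s, %d kept (threshold %s, top_k %d)\n",
              attr(x, "descriptor"), nrow(x),
              format(attr(x, "threshold")), attr(x, "top_k")))
  NextMethod()
}

#' Fuse selected features from several descriptors into one representation
#'
#' Column-binds each descriptor's selected feature columns, in the order the
#' selections are given, into a combined fingerprint table. All inputs must
#' share molecule ids in the same order. A provenance table maps every
#' combined column back to its descriptor and original feature index.
#'
#' @param selections list of [select_features()] results (or plain tibbles
#'   with a `feature_name` column), one per descriptor.
#' @param matrices matching list of [fp_tbl] (original bits, or reconstructed
#'   values wrapped with [reconstructed_fp()]).
#' @return list with `combined` (a [fp_tbl] named by provenance, descriptor
#'   `"combined"`) and `provenance` (tibble: `column` 0-based combined index,
#'   `descriptor`, `feature` original 0-based index).
#' @export
combine_descriptors <- function(selections, matrices) {
  stopifnot(length(selections) == length(matrices), length(selections) >= 1)
  ids <- fp_ids(matrices[[1]])
  act <- matrices[[1]]$activity
  blocks <- list(); prov <- list()
  for (i in seq_along(selections)) {
    if (!identical(fp_ids(matrices[[i]]), ids)) {
      stop("molecule ids differ across descriptors.", call. = FALSE)
    }
    sel <- selections[[i]]
    desc <- attr(sel, "descriptor") %||% fp_descriptor(matrices[[i]])
    x <- fp_values(matrices[[i]])[, sel$feature_name, drop = FALSE]
    colnames(x) <- paste0(desc, ".", sel$feature_name)
    blocks[[i]] <- x
    prov[[i]] <- tibble::tibble(descriptor = desc, feature = sel$feature)
  }
  combined <- do.call(cbind, blocks)
  prov <- dplyr::bind_rows(prov)
  prov$column <- seq_len(nrow(prov)) - 1L
  prov <- prov[, c("column", "descriptor", "feature")]
  out <- tibble::tibble(molecule_id = ids, activity = act)
  out <- dplyr::bind_cols(out, tibble::as_tibble(combined,
                                                 .name_repair = "minimal"))
  attr(out, "descriptor") <- "combined"
  class(out) <- c("fp_tbl", class(tibble::tibble()))
  list(combined = out, provenance = prov)
}

#' Wrap reconstructed values as a fingerprint table
#'
#' Puts a [dbn_reconstruct()] value matrix `Y` back into [fp_tbl] form (same
#' molecules, activities and feature names as the source table) so it can be
#' fused and searched like any fingerprint.
#'
#' @param fp the source [fp_tbl].
#' @param recon a `dbn_reconstruction` computed from `fp`.
#' @return a [fp_tbl] of continuous values in \[0, 1\].
#' @export
reconstructed_fp <- function(fp, recon) {
  stopifnot(inherits(recon, "dbn_reconstruction"),
            nrow(recon$Y) == nrow(fp))
  y <- recon$Y
  colnames(y) <- recon$feature_names
  fp_tbl(y, fp_ids(fp), fp$activity,
         paste0(fp_descriptor(fp), " (reconstructed)"))
}

#' Enumerate descriptor combinations
#'
#' All subsets of two or more descriptor names, ordered by size and then
#' lexicographically; the search over combinations proceeds pairs first, then
#' triples, and so on up to the full set.
#'
#' @param descriptor_names character vector of at least two names.
#' @return list of character vectors.
#' @examples
#' length(enumerate_combinations(c("ECFC4", "ECFP4", "EPFP4", "GOFP", "CDKFP")))
#' @export
enumerate_combinations <- function(descriptor_names) {
  if (length(descriptor_names) < 2) {
    stop("need at least 2 descriptor names.", call. = FALSE)
  }
  out <- list()
  for (size in 2:length(descriptor_names)) {
    subs <- utils::combn(sort(descriptor_names), size, simplify = FALSE)
    ord <- order(vapply(subs, paste, "", collapse = "\r"))
    out <- c(out, subs[ord])
  }
  out
}
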