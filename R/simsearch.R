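#' Tanimoto similarity coefficients
#'
#' `tanimoto_binary()` is the classic set form `|a AND b| / |a OR b|` for bit
#' vectors; `tanimoto_continuous()` is its continuous generalization
#' `sum(a b) / (sum(a^2) + sum(b^2) - sum(a b))` for non-negative vectors.
#' Both return 0 when both vectors are all-zero (convention) and reduce to the
#' same value on binary input.
#'
#' @param a,b numeric vectors of equal length (binary for
#'   `tanimoto_binary()`).
#' @return similarity in \[0, 1\].
#' @examples
#' tanimoto_binary(c(1, 1, 0, 1), c(1, 0, 1, 1)) # 2 common of 4 in union
#' tanimoto_continuous(c(2, 0), c(1, 1))
#' @export
tanimoto_binary <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch.", call. = FALSE)
  common <- sum(a * b)
  denom <- sum(a) + sum(b) - common
  if (denom == 0) 0 else common / denom
}

#' @rdname tanimoto_binary
#' @export
tanimoto_continuous <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch.", call. = FALSE)
  num <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - num
  if (denom == 0) 0 else num / denom
}

#' Rank a database against a reference structure
#'
#' Scores every database molecule against the query by Tanimoto similarity on
#' the given representation and returns the list sorted by decreasing score,
#' ties broken by ascending molecule id. The reference structure is excluded
#' from its own ranked list by default (including it would inflate recall
#' uniformly).
#'
#' @param fp a [fp_tbl] (binary bits or continuous reconstructed values)
#'   containing the query.
#' @param query_id molecule id of the reference structure.
#' @param mode `"continuous"` (default; exact for binary data too) or
#'   `"binary"`.
#' @param include_query keep the query in its own list (default `FALSE`).
#' @return object of class `ranked_list`: tibble with columns `rank`,
#'   `molecule_id`, `score`, and attribute `query_id`.
#' @export
rank_database <- function(fp, query_id, mode = c("continuous", "binary"),
                          include_query = FALSE) {
  mode <- match.arg(mode)
  x <- fp_values(fp)
  if (!query_id %in% rownames(x)) {
    stop("unknown query_id: ", query_id, call. = FALSE)
  }
  q <- x[query_id, ]
  db <- if (include_query) x else x[rownames(x) != query_id, , drop = FALSE]
  num <- drop(db %*% q)
  denom <- if (mode == "binary") {
    rowSums(db) + sum(q) - num
  } else {
    rowSums(db^2) + sum(q^2) - num
  }
  score <- ifelse(denom == 0, 0, num / denom)
  ord <- order(-score, rownames(db))
  out <- tibble::tibble(
    rank = seq_along(ord),
    molecule_id = rownames(db)[ord],
    score = unname(score[ord])
  )
  attr(out, "query_id") <- query_id
  class(out) <- c("ranked_list", class(tibble::tibble()))
  out
}

#' Retrieve the top fraction of a ranked list
#'
#' Takes the first `ceiling(fraction * nrow(ranked))` molecules -- the top 1%
#' and 5% cutoffs of the screening protocol.
#'
#' @param ranked a [rank_database()] result.
#' @param fraction cutoff fraction in (0, 1].
#' @return character vector of retrieved molecule ids, in rank order.
#' @export
apply_cutoff <- function(ranked, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  utils::head(ranked$molecule_id, ceiling(fraction * nrow(ranked)))
}
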