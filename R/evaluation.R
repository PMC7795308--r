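#' Recall of a retrieval result
#'
#' Percentage of the query's same-class actives found among the retrieved
#' molecules: `100 * true positives / (class size - 1)`. The query itself is
#' excluded from both the retrieved list and the denominator.
#'
#' @param retrieved_ids character vector of retrieved molecule ids (query
#'   excluded).
#' @param query_id the reference structure's id.
#' @param activity named character vector mapping molecule id to activity
#'   class (as from [fp_activity()]), or a data frame with `molecule_id` and
#'   `activity` columns.
#' @return recall percentage in \[0, 100\].
#' @export
recall_percent <- function(retrieved_ids, query_id, activity) {
  if (is.data.frame(activity)) {
    activity <- stats::setNames(activity$activity, activity$molecule_id)
  }
  if (!query_id %in% names(activity)) {
    stop("unknown query_id: ", query_id, call. = FALSE)
  }
  cls <- activity[[query_id]]
  denom <- sum(activity == cls) - 1
  if (denom < 1) {
    stop("activity class of the query has a single member; recall undefined.",
         call. = FALSE)
  }
  100 * sum(activity[retrieved_ids] == cls, na.rm = TRUE) / denom
}

#' Mean recall of an activity class
#'
#' Implements the per-class screening protocol: sample `n_refs` reference
#' structures from the class without replacement (seeded; if the class is
#' smaller than `n_refs` all members are used, with a warning), rank the
#' database against each reference, apply the cutoff, and average the per-query
#' recalls.
#'
#' @param fp a [fp_tbl] representation to search.
#' @param class_id the activity class evaluated.
#' @param cutoff cutoff fraction (e.g. `0.01` or `0.05`).
#' @param n_refs number of reference structures (default 10).
#' @param seed integer seed for the reference sample.
#' @param mode similarity mode passed to [rank_database()].
#' @return mean recall percentage.
#' @export
class_recall <- function(fp, class_id, cutoff, n_refs = 10, seed,
                         mode = c("continuous", "binary")) {
  mode <- match.arg(mode)
  act <- fp_activity(fp)
  members <- names(act)[act == class_id]
  if (!length(members)) stop("unknown class: ", class_id, call. = FALSE)
  if (length(members) < n_refs) {
    warning("class ", class_id, " has fewer than ", n_refs,
            " members; using all of them as references.")
    refs <- members
  } else {
    refs <- withr::with_seed(seed, sample(members, n_refs))
  }
  recalls <- vapply(refs, function(q) {
    retrieved <- apply_cutoff(rank_database(fp, q, mode = mode), cutoff)
    recall_percent(retrieved, q, act)
  }, numeric(1))
  mean(recalls)
}

#' Build a recall table over activity classes and methods
#'
#' Assembles per-class mean recalls into the standard benchmark layout: one
#' row per activity class, one column per method, a column-mean row, and a
#' best-in-class count per method (all methods tied at a row maximum are
#' credited).
#'
#' @param recalls tidy tibble/data frame with columns `class`, `method` and
#'   `recall` (percentages in \[0, 100\]); every method must cover every class.
#' @param dataset,cutoff optional labels stored on the result.
#' @return object of class `recall_table`: list with `table` (wide tibble,
#'   first column `class`), `column_means` and `best_counts` (named numeric
#'   vectors), `dataset` and `cutoff`.
#' @export
build_recall_table <- function(recalls, dataset = NULL, cutoff = NULL) {
  stopifnot(all(c("class", "method", "recall") %in% names(recalls)))
  if (any(recalls$recall < 0 | recalls$recall > 100)) {
    stop("recall values must lie in [0, 100].", call. = FALSE)
  }
  methods <- unique(recalls$method)
  wide <- tidyr::pivot_wider(
    dplyr::as_tibble(recalls[, c("class", "method", "recall")]),
    names_from = "method", values_from = "recall"
  )
  if (anyNA(wide)) stop("missing class/method cell.", call. = FALSE)
  vals <- as.matrix(wide[, methods, drop = FALSE])
  best <- apply(vals, 1, function(r) methods[r == max(r)])
  best_counts <- vapply(methods, function(m) {
    sum(vapply(best, function(b) m %in% b, logical(1)))
  }, numeric(1))
  structure(
    list(table = wide, column_means = colMeans(vals),
         best_counts = best_counts, dataset = dataset, cutoff = cutoff),
    class = "recall_table"
  )
}

#' @export
print.recall_table <- function(x, ...) {
  cat(sprintf("# recall table%s%s: %d classes x %d methods\n",
              if (!is.null(x$dataset)) paste0(" ", x$dataset) else "",
              if (!is.null(x$cutoff)) sprintf(" (top %g%%)", 100 * x$cutoff) else "",
              nrow(x$table), length(x$column_means)))
  print(x$table)
  cat("means:", paste(names(x$column_means),
                      sprintf("%.2f", x$column_means)), "\n")
  cat("best in class:", paste(names(x$best_counts), x$best_counts), "\n")
  invisible(x)
}

#' Gains of a reference method over the others
#'
#' Differences of column-mean recalls, `mean(reference) - mean(method)`, with
#' the column means rounded to two decimals first (matching the precision at
#' which benchmark tables are reported).
#'
#' @param table a [build_recall_table()] result.
#' @param reference method name the gains are computed for.
#' @return tibble with columns `method` and `gain` (positive when the
#'   reference method is better).
#' @export
recall_gains <- function(table, reference) {
  stopifnot(inherits(table, "recall_table"))
  means <- round(table$column_means, 2)
  if (!reference %in% names(means)) {
    stop("reference method not in table: ", reference, call. = FALSE)
  }
  tibble::tibble(
    method = names(means),
    gain = round(means[[reference]] - unname(means), 2)
  )
}

#' Kendall's coefficient of concordance W
#'
#' Measures agreement among `m` judges ranking `n` objects. In the screening
#' benchmark each activity class acts as a judge and each similarity method as
#' an object: within a judge, the method with the highest recall receives rank
#' `n` (mid-ranks on ties). With total ranks `R_i = sum_j r_ij`, grand mean
#' `Rbar = m (n + 1) / 2` and `S = sum_i (R_i - Rbar)^2`, the coefficient is
#' `W = 12 S / (m^2 (n^3 - n))`, ranging from 0 (no agreement) to 1 (complete
#' agreement). The p-value uses the chi-square approximation
#' `chi^2 = m (n - 1) W` on `n - 1` degrees of freedom.
#'
#' @param x numeric matrix or data frame of recall values, judges in rows and
#'   objects (methods) in columns; or a [build_recall_table()] result.
#' @return object of class `kendall_w`: list with `rank_matrix`, `totals`
#'   `R_i`, `grand_mean`, `S`, `W`, `m`, `n`, `chisq`, `p_value` and
#'   `mean_ranks` (`R_i / m`).
#' @examples
#' kendall_w(rbind(c(10, 20, 30), c(11, 22, 33)))$W # identical rankings: 1
#' @export
kendall_w <- function(x) {
  if (inherits(x, "recall_table")) x <- x$table[, -1]
  x <- as.matrix(x)
  m <- nrow(x); n <- ncol(x)
  if (m < 2 || n < 2) stop("need at least 2 judges and 2 objects.",
                           call. = FALSE)
  ranks <- t(apply(x, 1, rank))  # highest value gets rank n; mid-ranks on ties
  totals <- colSums(ranks)
  grand_mean <- m * (n + 1) / 2
  S <- sum((totals - grand_mean)^2)
  W <- 12 * S / (m^2 * (n^3 - n))
  chisq <- m * (n - 1) * W
  structure(
    list(rank_matrix = ranks, totals = totals, grand_mean = grand_mean,
         S = S, W = W, m = m, n = n, chisq = chisq,
         p_value = stats::pchisq(chisq, df = n - 1, lower.tail = FALSE),
         mean_ranks = totals / m),
    class = "kendall_w"
  )
}

#' @export
print.kendall_w <- function(x, ...) {
  cat(sprintf("# Kendall's W = %.3f (m = %d judges, n = %d objects, p = %.4g)\n",
              x$W, x$m, x$n, x$p_value))
  cat("mean ranks:", paste(names(x$mean_ranks) %||% seq_len(x$n),
                           sprintf("%.3f", x$mean_ranks)), "\n")
  invisible(x)
}

#' Published MDDR benchmark recall tables
#'
#' Per-class mean recall percentages of the five similarity methods (SDBN,
#' BIN, SQB, ASMTP, TAN; the heterogeneous DS3 set was benchmarked without
#' ASMTP) on the three MDDR activity-class benchmark datasets, at the top-1%
#' and top-5% cutoffs, as published. Bundled so the evaluation arithmetic
#' (column means, gains, best-in-class counts, concordance) can be recomputed
#' and checked without the licensed MDDR data.
#'
#' @param dataset `"ds1"`, `"ds2"` or `"ds3"`.
#' @param cutoff 1 or 5 (percent).
#' @return tidy tibble with columns `class` (activity index), `method` and
#'   `recall`, ready for [build_recall_table()].
#' @export
mddr_recall_values <- function(dataset = c("ds1", "ds2", "ds3"), cutoff = c(1, 5)) {
  dataset <- match.arg(dataset)
  cutoff <- match.arg(as.character(cutoff), c("1", "5"))
  path <- system.file("extdata", sprintf("mddr_%s_top%s.csv", dataset, cutoff),
                      package = "sdbn", mustWork = TRUE)
  wide <- utils::read.csv(path, check.names = FALSE,
                          colClasses = c(class = "character"))
  tidyr::pivot_longer(tibble::as_tibble(wide), -"class",
                      names_to = "method", values_to = "recall")
}
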