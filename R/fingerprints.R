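#' Fingerprint tables
#'
#' A fingerprint table is a tibble with one row per molecule: a `molecule_id`
#' column, an `activity` column giving the molecule's activity class, and one
#' numeric column per fingerprint feature. Feature columns are named `f<index>`
#' with 0-based, zero-padded indices (`f000`, `f001`, ...), so positional
#' bookkeeping survives subsetting and descriptor fusion. The descriptor name
#' (e.g. `"ECFC4"`) is carried as an attribute and shown when printing.
#'
#' @param values numeric matrix, molecules in rows, features in columns.
#'   Entries must be non-negative and finite.
#' @param molecule_ids character vector of unique molecule identifiers, one
#'   per row of `values`.
#' @param activity character vector of activity-class labels, one per molecule.
#' @param descriptor descriptor name used as a label (default `"FP"`).
#'
#' @return A `fp_tbl`: a tibble of `length(molecule_ids)` rows and
#'   `ncol(values) + 2` columns.
#' @examples
#' fp <- fp_tbl(matrix(c(1, 0, 0, 1), 2, 2), c("m1", "m2"), c("A", "B"))
#' fp_values(fp)
#' @export
fp_tbl <- function(values, molecule_ids, activity, descriptor = "FP") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  molecule_ids <- as.character(molecule_ids)
  activity <- as.character(activity)
  if (nrow(values) != length(molecule_ids)) {
    stop("`molecule_ids` must have one entry per row of `values`.", call. = FALSE)
  }
  if (length(activity) != length(molecule_ids)) {
    stop("every molecule_id must have exactly one activity label.", call. = FALSE)
  }
  if (anyDuplicated(molecule_ids)) {
    dup <- molecule_ids[duplicated(molecule_ids)][1]
    stop("duplicate molecule_id: ", dup, call. = FALSE)
  }
  if (length(values) && (any(!is.finite(values)) || any(values < 0))) {
    stop("fingerprint values must be finite and non-negative.", call. = FALSE)
  }
  # preserve positional feature names on subset matrices (original coordinates)
  cn <- colnames(values)
  if (is.null(cn) || !all(grepl("^f[0-9]+$", cn)) || anyDuplicated(cn)) {
    colnames(values) <- feature_names(ncol(values))
  }
  out <- tibble::tibble(molecule_id = molecule_ids, activity = activity)
  out <- dplyr::bind_cols(out, tibble::as_tibble(values, .name_repair = "minimal"))
  attr(out, "descriptor") <- descriptor
  class(out) <- c("fp_tbl", class(tibble::tibble()))
  out
}

#' @export
print.fp_tbl <- function(x, ...) {
  cat(sprintf(
    "# fingerprint table: %s (%d molecules x %d features)\n",
    fp_descriptor(x), nrow(x), fp_n_features(x)
  ))
  NextMethod()
}

feature_names <- function(m) {
  if (m == 0) return(character(0))
  sprintf(paste0("f%0", max(3L, nchar(as.character(m - 1L))), "d"), seq_len(m) - 1L)
}

#' Accessors for fingerprint tables
#'
#' `fp_values()` returns the feature block as a numeric matrix (row names are
#' molecule ids, column names the `f<index>` feature labels); `fp_ids()`,
#' `fp_activity()` and `fp_descriptor()` return the identifier column, the
#' named activity vector and the descriptor label; `fp_n_features()` the
#' feature count; `fp_feature_index()` maps feature column names back to their
#' 0-based indices.
#'
#' @param fp a fingerprint table (any data frame with `molecule_id`,
#'   `activity` and feature columns).
#' @return See individual descriptions.
#' @export
fp_values <- function(fp) {
  keep <- setdiff(names(fp), c("molecule_id", "activity"))
  x <- as.matrix(as.data.frame(fp)[, keep, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- fp$molecule_id
  x
}

#' @rdname fp_values
#' @export
fp_ids <- function(fp) fp$molecule_id

#' @rdname fp_values
#' @export
fp_activity <- function(fp) stats::setNames(fp$activity, fp$molecule_id)

#' @rdname fp_values
#' @export
fp_descriptor <- function(fp) attr(fp, "descriptor") %||% "FP"

#' @rdname fp_values
#' @export
fp_n_features <- function(fp) length(setdiff(names(fp), c("molecule_id", "activity")))

#' @rdname fp_values
#' @param feature_cols character vector of feature column names (`f<index>`).
#' @export
fp_feature_index <- function(feature_cols) as.integer(sub("^f", "", feature_cols))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a fingerprint matrix from a delimited text file
#'
#' Two lossless plain-text layouts are supported. `"dense"`: a header line
#' `molecule_id,activity,f000,...` followed by one CSV row per molecule.
#' `"sparse"`: no header; each line is `molecule_id<TAB>activity<TAB>idx ...`
#' where the third field lists the 0-based indices of the set bits, separated
#' by spaces (empty for an all-zero molecule). Sparse files require
#' `n_features` to fix the width.
#'
#' @param path file to read.
#' @param format `"dense"` or `"sparse"`.
#' @param n_features total feature count `M` (required for sparse files).
#' @param descriptor descriptor label; defaults to the file name without
#'   extension.
#' @return A [fp_tbl] with rows in file order.
#' @seealso [write_fingerprints()] for the inverse operation.
#' @export
read_fingerprints <- function(path, format = c("dense", "sparse"),
                              n_features = NULL, descriptor = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  descriptor <- descriptor %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  if (format == "dense") {
    if (!length(lines)) stop("empty file: ", path, call. = FALSE)
    header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    m <- length(header) - 2L
    if (m < 0L || header[1] != "molecule_id") {
      stop("malformed header at line 1 of ", path, call. = FALSE)
    }
    body <- lines[-1]
    parsed <- strsplit(body, ",", fixed = TRUE)
    widths <- lengths(parsed)
    bad <- which(widths != m + 2L)
    if (length(bad)) {
      stop(sprintf("parse error at line %d of %s: expected %d fields, found %d",
                   bad[1] + 1L, path, m + 2L, widths[bad[1]]), call. = FALSE)
    }
    ids <- vapply(parsed, `[[`, "", 1L)
    act <- vapply(parsed, `[[`, "", 2L)
    vals <- matrix(0, length(parsed), m)
    if (length(parsed) && m > 0) {
      num <- suppressWarnings(
        vapply(parsed, function(p) as.numeric(p[-(1:2)]), numeric(m))
      )
      vals <- t(matrix(num, nrow = m))
      bad <- which(apply(is.na(vals), 1, any))
      if (length(bad)) {
        stop(sprintf("parse error at line %d of %s: non-numeric feature value",
                     bad[1] + 1L, path), call. = FALSE)
      }
    }
    fp_tbl(vals, ids, act, descriptor)
  } else {
    if (is.null(n_features)) {
      stop("`n_features` is required for sparse files.", call. = FALSE)
    }
    parsed <- strsplit(lines, "\t", fixed = TRUE)
    widths <- lengths(parsed)
    bad <- which(widths < 2L | widths > 3L)
    if (length(bad)) {
      stop(sprintf("parse error at line %d of %s: expected 2-3 tab-separated fields",
                   bad[1], path), call. = FALSE)
    }
    ids <- vapply(parsed, `[[`, "", 1L)
    act <- vapply(parsed, `[[`, "", 2L)
    vals <- matrix(0, length(parsed), n_features)
    for (i in seq_along(parsed)) {
      if (widths[i] == 2L) next
      bits <- parsed[[i]][3]
      if (!nzchar(trimws(bits))) next
      idx <- suppressWarnings(as.integer(strsplit(trimws(bits), "\\s+")[[1]]))
      if (any(is.na(idx)) || any(idx < 0) || any(idx >= n_features)) {
        stop(sprintf("parse error at line %d of %s: bad bit index", i, path),
             call. = FALSE)
      }
      vals[i, idx + 1L] <- 1
    }
    fp_tbl(vals, ids, act, descriptor)
  }
}

#' Write a fingerprint matrix to a delimited text file
#'
#' Inverse of [read_fingerprints()]: `read_fingerprints(write_fingerprints(fp))`
#' reproduces `fp` exactly for binary data and to printed precision otherwise.
#' Sparse output requires a binary matrix.
#'
#' @param fp a [fp_tbl].
#' @inheritParams read_fingerprints
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fp, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  x <- fp_values(fp)
  if (format == "dense") {
    header <- paste(c("molecule_id", "activity", colnames(x)), collapse = ",")
    rows <- if (nrow(x)) {
      vals <- apply(x, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                            collapse = ","))
      if (ncol(x) == 0) {
        paste(fp_ids(fp), fp$activity, sep = ",")
      } else {
        paste(fp_ids(fp), fp$activity, vals, sep = ",")
      }
    } else character(0)
    writeLines(c(header, rows), path)
  } else {
    if (length(x) && !all(x %in% c(0, 1))) {
      stop("sparse format requires a binary matrix; call binarize() first.",
           call. = FALSE)
    }
    rows <- vapply(seq_len(nrow(x)), function(i) {
      paste(fp_ids(fp)[i], fp$activity[i],
            paste(which(x[i, ] == 1) - 1L, collapse = " "), sep = "\t")
    }, "")
    writeLines(rows, path)
  }
  invisible(path)
}

#' Binarize a count fingerprint
#'
#' Restricted Boltzmann machine units are Bernoulli, so count fingerprints
#' (e.g. ECFC4) are mapped to presence/absence before training: an entry
#' becomes 1 iff it exceeds `threshold` (strict inequality). Idempotent on
#' binary matrices at the default threshold.
#'
#' @param fp a [fp_tbl] with non-negative entries.
#' @param threshold count above which a feature is considered present
#'   (default 0).
#' @return A [fp_tbl] with entries in \{0, 1\}; the descriptor label is
#'   annotated with `"binarized"` (once).
#' @examples
#' fp <- fp_tbl(matrix(c(0, 1, 5, 0), 1), "m1", "A")
#' fp_values(binarize(fp))
#' @export
binarize <- function(fp, threshold = 0) {
  x <- fp_values(fp)
  desc <- fp_descriptor(fp)
  if (!grepl(" (binarized)", desc, fixed = TRUE)) {
    desc <- paste0(desc, " (binarized)")
  }
  fp_tbl((x > threshold) * 1, fp_ids(fp), fp$activity, desc)
}
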