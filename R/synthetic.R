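#' Specification for a synthetic multi-descriptor fingerprint dataset
#'
#' Describes an MDDR-like benchmark dataset: several activity classes of given
#' sizes, binary fingerprints in which each class has a disjoint set of
#' "signal" bits switched on with high probability for its own members, a low
#' background on-rate for every bit, and a set of outlier features flipped on
#' with probability 0.5 independently of class. Outlier bits are pure
#' class-independent coin flips, which makes them maximally non-reconstructible
#' for any model of the class structure; they play the role of the
#' large-reconstruction-error feature outliers the training loop removes.
#' Descriptors share molecules and labels but draw independent signal and
#' outlier positions, so different descriptors carry complementary information.
#'
#' Defaults are desk-scale study conditions: 2 classes x 100 molecules, 64
#' features, 3 descriptors, 8 signal bits per class at on-rate 0.9 over a 0.05
#' background, and 8 outlier features.
#'
#' @param class_sizes named integer vector: activity class -> number of active
#'   molecules (all sizes >= 1).
#' @param n_features features per descriptor, `M`.
#' @param n_descriptors number of descriptors to generate.
#' @param signal_bits_per_class number of class-specific informative bits.
#' @param p_signal_on probability a signal bit is on in its own class.
#' @param p_background_on probability any bit is on regardless of class;
#'   must satisfy `0 <= p_background_on < p_signal_on <= 1`.
#' @param n_outlier_features number of class-independent noisy features per
#'   descriptor (disjoint from all signal bits).
#' @param seed integer seed; generation has no implicit global randomness.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_fingerprints()]
#' @export
synthetic_spec <- function(class_sizes = c(A = 100, B = 100),
                           n_features = 64,
                           n_descriptors = 3,
                           signal_bits_per_class = 8,
                           p_signal_on = 0.9,
                           p_background_on = 0.05,
                           n_outlier_features = 8,
                           seed) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  if (is.null(names(class_sizes))) {
    names(class_sizes) <- paste0("C", seq_along(class_sizes))
  }
  if (any(class_sizes < 1)) stop("class sizes must be >= 1.", call. = FALSE)
  if (!(p_background_on >= 0 && p_background_on < p_signal_on && p_signal_on <= 1)) {
    stop("need 0 <= p_background_on < p_signal_on <= 1.", call. = FALSE)
  }
  needed <- signal_bits_per_class * length(class_sizes) + n_outlier_features
  if (needed > n_features) {
    stop("signal and outlier bits must fit disjointly into n_features.",
         call. = FALSE)
  }
  structure(
    list(
      class_sizes = class_sizes, n_features = n_features,
      n_descriptors = n_descriptors,
      signal_bits_per_class = signal_bits_per_class,
      p_signal_on = p_signal_on, p_background_on = p_background_on,
      n_outlier_features = n_outlier_features, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic multi-descriptor fingerprint dataset
#'
#' Samples one binary fingerprint table per descriptor according to a
#' [synthetic_spec()]. Every bit is drawn independently: signal bits of a
#' molecule's own class are Bernoulli(`p_signal_on`), outlier bits are
#' Bernoulli(0.5), and everything else is Bernoulli(`p_background_on`).
#' Deterministic under the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements:
#' \describe{
#'   \item{descriptors}{named list of [fp_tbl] (descriptors `D1`, `D2`, ...),
#'     all sharing molecule ids and activity labels.}
#'   \item{manifest}{tibble of the planted ground truth with columns
#'     `descriptor`, `feature` (0-based index), `role`
#'     (`"signal"`/`"outlier"`) and `class` (`NA` for outliers).}
#' }
#' @examples
#' d <- generate_fingerprints(synthetic_spec(c(A = 5, B = 5), seed = 1))
#' names(d$descriptors)
#' @export
generate_fingerprints <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- names(spec$class_sizes)
  n <- sum(spec$class_sizes)
  labels <- rep(classes, spec$class_sizes)
  ids <- sprintf("mol%04d", seq_len(n))
  withr::with_seed(spec$seed, {
    descs <- list()
    manifest <- list()
    for (d in seq_len(spec$n_descriptors)) {
      dname <- paste0("D", d)
      pool <- sample.int(spec$n_features) - 1L  # 0-based positions
      sig <- list()
      used <- 0L
      for (cl in classes) {
        sig[[cl]] <- sort(pool[used + seq_len(spec$signal_bits_per_class)])
        used <- used + spec$signal_bits_per_class
      }
      outliers <- sort(pool[used + seq_len(spec$n_outlier_features)])
      p <- matrix(spec$p_background_on, n, spec$n_features)
      for (cl in classes) {
        p[labels == cl, sig[[cl]] + 1L] <- spec$p_signal_on
      }
      p[, outliers + 1L] <- 0.5
      x <- (matrix(stats::runif(n * spec$n_features), n) < p) * 1
      descs[[dname]] <- fp_tbl(x, ids, labels, dname)
      sig_tbl <- purrr::imap(sig, function(idx, cl) {
        tibble::tibble(descriptor = dname, feature = idx,
                       role = "signal", class = cl)
      })
      manifest[[dname]] <- dplyr::bind_rows(c(
        unname(sig_tbl),
        list(tibble::tibble(descriptor = dname, feature = outliers,
                            role = "outlier", class = NA_character_))
      ))
    }
    list(descriptors = descs, manifest = dplyr::bind_rows(manifest))
  })
}
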