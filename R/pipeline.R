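#' Configuration for an end-to-end screening run
#'
#' Bundles everything [sdbn_run()] needs: the data source (a
#' [synthetic_spec()] or a list of fingerprint files), the network
#' architecture and training settings, the feature-selection parameters and
#' the evaluation protocol. A single root `seed` deterministically derives
#' every per-stage and per-descriptor seed, so changing one stage's settings
#' does not perturb another stage's randomness.
#'
#' @param spec a [synthetic_spec()] (its seed is re-derived from `seed`), or
#'   `NULL` when `files` is given.
#' @param files optional named character vector of dense fingerprint files,
#'   one per descriptor.
#' @param layer_sizes hidden layer widths (the input width is prepended
#'   automatically).
#' @param train_args list of [train_config()] arguments except `seed`
#'   (desk-scale defaults: lr 0.1, 30 epochs, batch 32, CD-1).
#' @param outlier_fraction per-round removal fraction for
#'   [iterative_feature_learning()].
#' @param fine_tune_epochs autoencoder fine-tuning epochs after outlier
#'   removal (0 disables fine-tuning).
#' @param threshold,top_k feature-selection parameters ([select_features()]).
#' @param combine character vector of descriptor names to fuse (default: all).
#' @param cutoffs retrieval cutoff fractions (default `c(0.01, 0.05)`).
#' @param n_refs reference structures per class (default 10).
#' @param mode similarity mode for the fused representation (default
#'   continuous values on the reconstructed features).
#' @param seed root integer seed (mandatory).
#' @param outdir optional directory; when given, [sdbn_run()] writes matrices,
#'   manifests, selections, the recall table and the concordance report there.
#' @return list of class `sdbn_config`.
#' @export
sdbn_config <- function(spec = NULL, files = NULL,
                        layer_sizes = c(48, 24),
                        train_args = list(learning_rate = 0.1, epochs = 30,
                                          batch_size = 32, gibbs_steps = 1,
                                          init = "gaussian"),
                        outlier_fraction = 0.125,
                        fine_tune_epochs = 150,
                        threshold = Inf, top_k = 16,
                        combine = NULL, cutoffs = c(0.01, 0.05),
                        n_refs = 10, mode = c("continuous", "binary"),
                        seed, outdir = NULL) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  if (is.null(spec) && is.null(files)) {
    stop("either `spec` or `files` must be given.", call. = FALSE)
  }
  if (!is.null(files) && !all(file.exists(files))) {
    stop("missing fingerprint file(s): ",
         paste(files[!file.exists(files)], collapse = ", "), call. = FALSE)
  }
  structure(
    list(spec = spec, files = files, layer_sizes = layer_sizes,
         train_args = train_args, outlier_fraction = outlier_fraction,
         fine_tune_epochs = fine_tune_epochs, threshold = threshold,
         top_k = top_k, combine = combine, cutoffs = cutoffs, n_refs = n_refs,
         mode = match.arg(mode), seed = as.integer(seed), outdir = outdir),
    class = "sdbn_config"
  )
}

#' Run the full screening pipeline
#'
#' Orchestrates generate/load -> per-descriptor training with iterative
#' outlier removal -> autoencoder fine-tuning -> error PCA and feature
#' selection -> multi-descriptor fusion -> Tanimoto search -> recall table and
#' Kendall-W concordance. Every stage draws its randomness from a seed derived
#' from the root seed, so a run is reproducible bit-for-bit from its config.
#'
#' The evaluated methods are the fused representation (`"SDBN"`), each single
#' descriptor's SDBN representation (reconstructed values on its selected
#' features) and plain binary Tanimoto on each original descriptor
#' (`"TAN-<descriptor>"`).
#'
#' @param config an [sdbn_config()].
#' @return object of class `sdbn_run`: list with `descriptors`, `manifest`
#'   (synthetic runs only), `models`, `selections`, `provenance`, `combined`,
#'   `recall_tables` (one [build_recall_table()] per cutoff), `concordance`
#'   (one [kendall_w()] per cutoff) and `log` (per-stage timing tibble).
#' @export
sdbn_run <- function(config) {
  stopifnot(inherits(config, "sdbn_config"))
  log <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    value <- force(expr)
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    value
  }

  manifest <- NULL
  descs <- tick("generate", {
    if (!is.null(config$spec)) {
      spec <- config$spec
      spec$seed <- derive_seed(config$seed, "generate")
      gen <- generate_fingerprints(spec)
      manifest <- gen$manifest
      gen$descriptors
    } else {
      out <- lapply(config$files, read_fingerprints)
      names(out) <- names(config$files) %||%
        vapply(out, fp_descriptor, "")
      out
    }
  })

  models <- list(); recons <- list(); selections <- list(); recon_fps <- list()
  for (d in names(descs)) {
    fp <- binarize(descs[[d]])
    res <- tick(paste0("train:", d), {
      cfg <- do.call(train_config, c(config$train_args,
                                     list(seed = derive_seed(config$seed, "train", d))))
      ifl <- iterative_feature_learning(
        fp, c(fp_n_features(fp), config$layer_sizes), cfg,
        outlier_fraction = config$outlier_fraction
      )
      kept <- fp_values(fp)[, ifl$kept_features + 1L, drop = FALSE]
      model <- ifl$model
      if (config$fine_tune_epochs > 0) {
        ft_cfg <- cfg
        ft_cfg$epochs <- as.integer(config$fine_tune_epochs)
        model <- dbn_fine_tune(model, kept, ft_cfg)
      }
      recon <- dbn_reconstruct(model, kept)
      list(ifl = ifl, model = model, recon = recon, kept = kept)
    })
    models[[d]] <- res$model
    recons[[d]] <- res$recon
    selections[[d]] <- tick(paste0("select:", d), {
      pca <- build_error_pca(res$recon$E)
      select_features(pca, threshold = config$threshold,
                      top_k = config$top_k, descriptor = d)
    })
    recon_fps[[d]] <- reconstructed_fp(
      fp_tbl(res$kept, fp_ids(fp), fp$activity, d), res$recon
    )
  }

  use <- config$combine %||% names(descs)
  comb <- tick("combine",
               combine_descriptors(selections[use], recon_fps[use]))

  classes <- unique(descs[[1]]$activity)
  recall_tables <- list(); concordance <- list()
  for (cutoff in config$cutoffs) {
    rows <- tick(sprintf("evaluate:%g", cutoff), {
      per_method <- list()
      reps <- c(list(SDBN = comb$combined),
                stats::setNames(recon_fps[use], paste0("SDBN-", use)),
                stats::setNames(lapply(descs[use], binarize),
                                paste0("TAN-", use)))
      modes <- c("SDBN" = config$mode,
                 stats::setNames(rep(config$mode, length(use)),
                                 paste0("SDBN-", use)),
                 stats::setNames(rep("binary", length(use)),
                                 paste0("TAN-", use)))
      for (mth in names(reps)) {
        per_method[[mth]] <- tibble::tibble(
          class = classes, method = mth,
          recall = vapply(classes, function(cl) {
            class_recall(reps[[mth]], cl, cutoff, n_refs = config$n_refs,
                         seed = derive_seed(config$seed, "refs", cl, cutoff),
                         mode = modes[[mth]])
          }, numeric(1))
        )
      }
      dplyr::bind_rows(per_method)
    })
    key <- sprintf("top%g", 100 * cutoff)
    recall_tables[[key]] <- build_recall_table(rows, cutoff = cutoff)
    concordance[[key]] <- kendall_w(recall_tables[[key]])
  }

  run <- structure(
    list(descriptors = descs, manifest = manifest, models = models,
         selections = selections, provenance = comb$provenance,
         combined = comb$combined, recall_tables = recall_tables,
         concordance = concordance, config = config,
         log = dplyr::bind_rows(log)),
    class = "sdbn_run"
  )
  if (!is.null(config$outdir)) sdbn_write_run(run, config$outdir)
  run
}

#' @export
print.sdbn_run <- function(x, ...) {
  cat(sprintf("# SDBN run: %d descriptors, seed %d\n",
              length(x$descriptors), x$config$seed))
  for (key in names(x$recall_tables)) {
    print(x$recall_tables[[key]])
  }
  invisible(x)
}

sdbn_write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(run$descriptors)) {
    write_fingerprints(run$descriptors[[d]],
                       file.path(outdir, paste0(d, ".csv")))
    utils::write.csv(run$selections[[d]],
                     file.path(outdir, paste0("selection_", d, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(run$manifest)) {
    jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"))
  }
  write_fingerprints(run$combined, file.path(outdir, "combined.csv"))
  utils::write.csv(run$provenance, file.path(outdir, "provenance.csv"),
                   row.names = FALSE)
  for (key in names(run$recall_tables)) {
    utils::write.csv(run$recall_tables[[key]]$table,
                     file.path(outdir, paste0("recall_", key, ".csv")),
                     row.names = FALSE)
    w <- run$concordance[[key]]
    jsonlite::write_json(
      list(W = w$W, p_value = w$p_value, mean_ranks = as.list(w$mean_ranks)),
      file.path(outdir, paste0("concordance_", key, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  utils::write.csv(run$log, file.path(outdir, "log.csv"), row.names = FALSE)
  invisible(outdir)
}
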