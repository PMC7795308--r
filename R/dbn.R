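#' Greedy layer-wise pretraining of a deep belief network
#'
#' Trains a stack of Bernoulli RBMs: the first on the (binary) input matrix,
#' each subsequent one on the mean-field hidden activations of the layer
#' below. `layer_sizes` gives the full chain starting at the input width,
#' e.g. `c(1024, 2000, 1800, 1300, 800, 300)` for the full-scale
#' configuration, or something like `c(64, 48, 24)` at desk scale.
#'
#' @param data [fp_tbl] or numeric matrix (molecules x features) with entries
#'   in \[0, 1\].
#' @param layer_sizes integer vector of layer widths; `layer_sizes[1]` must
#'   equal the input feature count and at least one hidden layer is required.
#' @param config a [train_config()].
#' @return An object of class `dbn`: list with `layers` (list of [rbm]),
#'   `layer_sizes`, `fine_tuned` flag, `decoder` (populated by
#'   [dbn_fine_tune()]) and `training_log` (per-layer final reconstruction
#'   errors).
#' @export
dbn_pretrain <- function(data, layer_sizes, config) {
  x <- if (inherits(data, "data.frame")) fp_values(data) else as.matrix(data)
  if (!nrow(x)) stop("empty data.", call. = FALSE)
  if (length(layer_sizes) < 2) {
    stop("at least one RBM (two layer sizes) is required.", call. = FALSE)
  }
  if (layer_sizes[1] != ncol(x)) {
    stop("layer_sizes[1] must equal the input feature count (",
         ncol(x), ").", call. = FALSE)
  }
  layers <- vector("list", length(layer_sizes) - 1)
  log <- numeric(length(layers))
  input <- x
  for (l in seq_along(layers)) {
    cfg_l <- config
    cfg_l$seed <- derive_seed(config$seed, "layer", l)
    layers[[l]] <- rbm_train(input, layer_sizes[l + 1], cfg_l)
    tl <- attr(layers[[l]], "training_log")
    log[l] <- if (length(tl)) {
      utils::tail(tl, 1)
    } else {
      # zero-epoch training: report the error of the initialized layer
      mean(abs(input - visible_conditional(layers[[l]],
                                           hidden_conditional(layers[[l]], input))))
    }
    input <- hidden_conditional(layers[[l]], input)
  }
  structure(
    list(layers = layers, layer_sizes = as.integer(layer_sizes),
         fine_tuned = FALSE, decoder = NULL, training_log = log),
    class = "dbn"
  )
}

#' @export
print.dbn <- function(x, ...) {
  cat(sprintf("# DBN: %s%s\n", paste(x$layer_sizes, collapse = " -> "),
              if (x$fine_tuned) " (fine-tuned)" else " (pretrained)"))
  invisible(x)
}

# ---- unrolled autoencoder used for fine-tuning ------------------------------

# params: list(enc = list of (W, b)), dec = list of (W, b)); all layers sigmoid.
dbn_unroll <- function(model) {
  enc <- lapply(model$layers, function(r) list(W = r$W, b = r$b))
  dec <- lapply(rev(model$layers), function(r) list(W = t(r$W), b = r$a))
  list(enc = enc, dec = dec)
}

ae_forward <- function(net, x) {
  acts <- list(x)
  cur <- x
  for (lay in c(net$enc, net$dec)) {
    cur <- sigmoid(sweep(cur %*% lay$W, 2, lay$b, `+`))
    acts[[length(acts) + 1]] <- cur
  }
  acts
}

# Squared-error loss 0.5 * mean over rows of ||x - y||^2 and its gradient
# w.r.t. every weight and bias, by standard backpropagation.
ae_loss_grad <- function(net, x) {
  acts <- ae_forward(net, x)
  layers <- c(net$enc, net$dec)
  nl <- length(layers)
  y <- acts[[nl + 1]]
  n <- nrow(x)
  loss <- 0.5 * sum((y - x)^2) / n
  grads <- vector("list", nl)
  delta <- (y - x) / n * y * (1 - y)
  for (l in rev(seq_len(nl))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta), b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(layers[[l]]$W)) * acts[[l]] * (1 - acts[[l]])
    }
  }
  list(loss = loss, grads = grads)
}

ae_apply_grads <- function(net, grads, lr) {
  nl <- length(net$enc)
  all <- c(net$enc, net$dec)
  for (l in seq_along(all)) {
    all[[l]]$W <- all[[l]]$W - lr * grads[[l]]$W
    all[[l]]$b <- all[[l]]$b - lr * grads[[l]]$b
  }
  list(enc = all[seq_len(nl)], dec = all[nl + seq_len(length(all) - nl)])
}

#' Fine-tune a pretrained network as an autoencoder
#'
#' Unrolls the RBM stack into an encoder-decoder network (decoder initialized
#' with the transposed encoder weights and the RBMs' visible biases, then
#' untied) and minimizes the squared reconstruction error by mini-batch
#' gradient descent for `config$epochs` passes. No labels are involved.
#'
#' @param model a pretrained [dbn_pretrain()] model.
#' @param data the matrix or [fp_tbl] the model was trained on.
#' @param config a [train_config()]; `epochs = 0` leaves the weights unchanged
#'   and only marks the model fine-tuned.
#' @return the model with `fine_tuned = TRUE`, decoder weights stored in
#'   `$decoder`, and a `fine_tune_log` of per-epoch losses.
#' @export
dbn_fine_tune <- function(model, data, config) {
  if (!inherits(model, "dbn")) stop("`model` must be a pretrained dbn.",
                                    call. = FALSE)
  x <- if (inherits(data, "data.frame")) fp_values(data) else as.matrix(data)
  net <- dbn_unroll(model)
  log <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- withr::with_seed(derive_seed(config$seed, "ft-shuffle", ep),
                            sample.int(nrow(x)))
    starts <- seq(1, nrow(x), by = config$batch_size)
    tot <- 0
    for (bi in seq_along(starts)) {
      rows <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1, nrow(x))]
      lg <- ae_loss_grad(net, x[rows, , drop = FALSE])
      net <- ae_apply_grads(net, lg$grads, config$learning_rate)
      tot <- tot + lg$loss * length(rows)
    }
    log[ep] <- tot / nrow(x)
  }
  for (l in seq_along(model$layers)) {
    model$layers[[l]]$W <- net$enc[[l]]$W
    model$layers[[l]]$b <- net$enc[[l]]$b
  }
  model$decoder <- net$dec
  model$fine_tuned <- TRUE
  model$fine_tune_log <- log
  model
}

#' Reconstruct inputs through a deep belief network
#'
#' Deterministic mean-field pass: encode to the deepest layer with each RBM's
#' hidden conditional, decode back with the (fine-tuned or transposed)
#' decoder. Returns the reconstructed value matrix `Y` in \[0,1\], the
#' per-entry absolute error matrix `E = |X - Y|` and the per-molecule error
#' `e_i = ||x_i - y_i||` (L2 by default, L1 switchable).
#'
#' @param model a [dbn_pretrain()] (optionally fine-tuned) model.
#' @param data matrix or [fp_tbl] with the model's input width.
#' @param norm `"l2"` or `"l1"` row norm for the per-molecule error.
#' @return object of class `dbn_reconstruction`: list with `Y`, `E`,
#'   `per_molecule_error`, `molecule_ids` and `feature_names`.
#' @export
dbn_reconstruct <- function(model, data, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  x <- if (inherits(data, "data.frame")) fp_values(data) else as.matrix(data)
  if (ncol(x) != model$layer_sizes[1]) {
    stop("data has ", ncol(x), " features; model expects ",
         model$layer_sizes[1], ".", call. = FALSE)
  }
  cur <- x
  for (r in model$layers) cur <- hidden_conditional(r, cur)
  if (model$fine_tuned && !is.null(model$decoder)) {
    for (lay in model$decoder) cur <- sigmoid(sweep(cur %*% lay$W, 2, lay$b, `+`))
  } else {
    for (r in rev(model$layers)) cur <- visible_conditional(r, cur)
  }
  E <- abs(x - cur)
  e_i <- if (norm == "l2") sqrt(rowSums(E^2)) else rowSums(E)
  structure(
    list(Y = cur, E = E, per_molecule_error = e_i,
         molecule_ids = rownames(x), feature_names = colnames(x)),
    class = "dbn_reconstruction"
  )
}

#' @export
print.dbn_reconstruction <- function(x, ...) {
  cat(sprintf("# reconstruction: %d molecules x %d features, mean error %.4f\n",
              nrow(x$E), ncol(x$E), mean(x$E)))
  invisible(x)
}

#' Iterative feature learning with outlier removal
#'
#' Alternates training and feature pruning: train a fresh network (weights
#' re-initialized from a round-derived seed), reconstruct, and remove the
#' `outlier_fraction` of current features with the largest mean column
#' reconstruction error, until the change in mean per-molecule error between
#' successive rounds drops to `config$tolerance` or `max_rounds` is reached.
#' Removed features are reported as 0-based indices in the coordinates of the
#' original matrix, and never shift as other features are removed.
#'
#' @param data matrix or [fp_tbl].
#' @param layer_sizes layer widths for the first round;
#'   the input width shrinks with the feature set in later rounds.
#' @param config a [train_config()]; its `tolerance` is the convergence
#'   criterion `e`.
#' @param outlier_fraction fraction of current features removed per round
#'   (`0 <= outlier_fraction < 0.5`; 0 trains a single round and removes
#'   nothing).
#' @param max_rounds hard cap on rounds (default 10).
#' @param fine_tune apply [dbn_fine_tune()] each round before measuring errors
#'   (default `FALSE`: outlier screening uses the generatively trained stack,
#'   whose reconstruction cannot chase class-independent noise bits).
#' @return list with the final `model`, its `reconstruction` (on the reduced
#'   matrix), `kept_features` and `removed_features` (0-based original
#'   indices, in removal order), and a per-round `history` tibble.
#' @export
iterative_feature_learning <- function(data, layer_sizes, config,
                                       outlier_fraction, max_rounds = 10,
                                       fine_tune = FALSE) {
  if (outlier_fraction < 0 || outlier_fraction >= 0.5) {
    stop("need 0 <= outlier_fraction < 0.5.", call. = FALSE)
  }
  x <- if (inherits(data, "data.frame")) fp_values(data) else as.matrix(data)
  orig <- seq_len(ncol(x)) - 1L  # 0-based bookkeeping
  keep <- rep(TRUE, ncol(x))
  removed <- integer(0)
  prev_err <- Inf
  history <- list()
  model <- NULL; recon <- NULL
  for (round in seq_len(max_rounds)) {
    if (!any(keep)) stop("all features removed.", call. = FALSE)
    cur <- x[, keep, drop = FALSE]
    sizes <- c(ncol(cur), layer_sizes[-1])
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "round", round)
    model <- dbn_pretrain(cur, sizes, cfg)
    if (fine_tune) model <- dbn_fine_tune(model, cur, cfg)
    recon <- dbn_reconstruct(model, cur)
    # mean per-molecule error, normalized by sqrt(feature count) so the
    # convergence statistic is comparable across rounds as the matrix shrinks
    err <- mean(recon$per_molecule_error) / sqrt(ncol(cur))
    n_remove <- ceiling(outlier_fraction * ncol(cur))
    history[[round]] <- tibble::tibble(
      round = round, n_features = ncol(cur), mean_error = err,
      change = abs(err - prev_err), n_removed = 0L
    )
    if (abs(err - prev_err) <= config$tolerance || n_remove == 0 ||
        round == max_rounds) {
      break
    }
    col_err <- colMeans(recon$E)
    worst <- order(col_err, decreasing = TRUE)[seq_len(n_remove)]
    removed <- c(removed, orig[keep][worst])
    keep[match(orig[keep][worst], orig)] <- FALSE
    history[[round]]$n_removed <- as.integer(n_remove)
    prev_err <- err
  }
  list(model = model, reconstruction = recon,
       kept_features = orig[keep], removed_features = removed,
       history = dplyr::bind_rows(history))
}
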