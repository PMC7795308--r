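#' Logistic sigmoid
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, computed in a form that saturates to 0/1
#' at extreme arguments without overflow.
#'
#' @param x numeric vector or matrix.
#' @return values in (0, 1) with the shape of `x`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Restricted Boltzmann machine parameters
#'
#' A Bernoulli RBM over `V` visible and `H` hidden binary units with energy
#' `E(v, h) = -a'v - b'h - v'Wh`. `W` is the `V x H` symmetric connection
#' weight matrix, `a` the visible bias and `b` the hidden bias.
#'
#' @param W numeric `V x H` weight matrix.
#' @param a numeric visible bias, length `V`.
#' @param b numeric hidden bias, length `H`.
#' @return An object of class `rbm`.
#' @export
rbm <- function(W, a, b) {
  W <- as.matrix(W)
  if (nrow(W) != length(a) || ncol(W) != length(b)) {
    stop("dimension mismatch: rows(W) must equal length(a), cols(W) length(b).",
         call. = FALSE)
  }
  if (any(!is.finite(W)) || any(!is.finite(a)) || any(!is.finite(b))) {
    stop("RBM parameters must be finite.", call. = FALSE)
  }
  structure(list(W = W, a = as.numeric(a), b = as.numeric(b)), class = "rbm")
}

#' @export
print.rbm <- function(x, ...) {
  cat(sprintf("# RBM: %d visible x %d hidden units\n", nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' Initialize RBM parameters
#'
#' Weights default to uniform draws on \[0, 1) (the scheme used for the
#' reference training runs); a small-Gaussian alternative (`sd = 0.01`) is
#' provided because uniform-positive initialization is atypical and can slow
#' mixing. Biases start at 0.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param seed integer seed.
#' @param init `"uniform"` (on \[0,1)) or `"gaussian"` (mean 0, sd 0.01).
#' @return An [rbm].
#' @export
rbm_init <- function(n_visible, n_hidden, seed, init = c("uniform", "gaussian")) {
  init <- match.arg(init)
  withr::with_seed(seed, {
    W <- if (init == "uniform") {
      matrix(stats::runif(n_visible * n_hidden), n_visible, n_hidden)
    } else {
      matrix(stats::rnorm(n_visible * n_hidden, sd = 0.01), n_visible, n_hidden)
    }
    rbm(W, numeric(n_visible), numeric(n_hidden))
  })
}

#' RBM conditional distributions
#'
#' Because an RBM has no intra-layer connections the conditionals factorize
#' over units: `p(h_j = 1 | v) = sigmoid(b_j + sum_i v_i w_ij)` and
#' `p(v_i = 1 | h) = sigmoid(a_i + sum_j h_j w_ij)`. Both accept a single
#' configuration (vector) or a matrix with one configuration per row.
#'
#' @param params an [rbm].
#' @param v,h binary (or mean-field, in \[0,1\]) configuration vector, or a
#'   matrix of row configurations.
#' @return vector (or matrix) of per-unit activation probabilities.
#' @export
hidden_conditional <- function(params, v) {
  vec <- is.null(dim(v))
  v <- rbind(v)
  if (ncol(v) != nrow(params$W)) {
    stop("dimension mismatch: v has ", ncol(v), " units, expected ",
         nrow(params$W), ".", call. = FALSE)
  }
  p <- sigmoid(sweep(v %*% params$W, 2, params$b, `+`))
  if (vec) p[1, ] else p
}

#' @rdname hidden_conditional
#' @export
visible_conditional <- function(params, h) {
  vec <- is.null(dim(h))
  h <- rbind(h)
  if (ncol(h) != ncol(params$W)) {
    stop("dimension mismatch: h has ", ncol(h), " units, expected ",
         ncol(params$W), ".", call. = FALSE)
  }
  p <- sigmoid(sweep(h %*% t(params$W), 2, params$a, `+`))
  if (vec) p[1, ] else p
}

bernoulli_sample <- function(p) (matrix(stats::runif(length(p)), nrow(p)) < p) * 1

#' Alternating Gibbs sampling
#'
#' Runs `k` rounds of blocked Gibbs updates from a starting visible
#' configuration: all hidden units are sampled in parallel from
#' `p(h | v)`, then all visible units from `p(v | h)`. Deterministic under
#' `seed`.
#'
#' @param params an [rbm].
#' @param v0 starting visible configuration (vector, or matrix of rows).
#' @param k number of Gibbs rounds (>= 1).
#' @param seed integer seed.
#' @return list with binary samples `v`, `h` after round `k` and the
#'   mean-field probabilities `pv`, `ph` used at the final round.
#' @export
gibbs_chain <- function(params, v0, k, seed) {
  stopifnot(k >= 1)
  vec <- is.null(dim(v0))
  v <- rbind(v0)
  withr::with_seed(seed, {
    for (t in seq_len(k)) {
      ph <- hidden_conditional(params, v)
      h <- bernoulli_sample(ph)
      pv <- visible_conditional(params, h)
      v <- bernoulli_sample(pv)
    }
    if (vec) {
      list(v = v[1, ], h = h[1, ], pv = pv[1, ], ph = ph[1, ])
    } else {
      list(v = v, h = h, pv = pv, ph = ph)
    }
  })
}

#' One contrastive-divergence parameter update
#'
#' CD-k stochastic ascent on the training log-likelihood:
#' `dW = eps * (<v h>_data - <v h>_model)`, and likewise for the biases, with
#' the model expectation estimated by a `k`-step Gibbs chain started at each
#' data vector. The positive phase uses hidden probabilities (mean-field); the
#' negative chain samples binary states but uses probabilities at the final
#' step, the usual variance-reduction choice.
#'
#' @param params an [rbm].
#' @param batch matrix of visible configurations, one per row (entries in
#'   \[0,1\]).
#' @param learning_rate step size `eps` (0 leaves parameters unchanged).
#' @param k Gibbs steps for the negative phase.
#' @param seed integer seed.
#' @return the updated [rbm].
#' @export
cd_update <- function(params, batch, learning_rate, k = 1, seed) {
  batch <- rbind(batch)
  if (!nrow(batch)) stop("empty batch.", call. = FALSE)
  if (learning_rate == 0) return(params)
  n <- nrow(batch)
  ph0 <- hidden_conditional(params, batch)
  withr::with_seed(seed, {
    v <- batch
    for (t in seq_len(k)) {
      ph <- if (t == 1) ph0 else hidden_conditional(params, v)
      h <- bernoulli_sample(ph)
      pv <- visible_conditional(params, h)
      v <- if (t < k) bernoulli_sample(pv) else pv
    }
  })
  phk <- hidden_conditional(params, v)
  dW <- (crossprod(batch, ph0) - crossprod(v, phk)) / n
  da <- colMeans(batch) - colMeans(v)
  db <- colMeans(ph0) - colMeans(phk)
  rbm(params$W + learning_rate * dW,
      params$a + learning_rate * da,
      params$b + learning_rate * db)
}

#' Training configuration
#'
#' Bundles the hyperparameters shared by RBM and network training. Defaults
#' are the full-scale settings used for the reference experiments (70 epochs,
#' 50 Gibbs steps, batch 128, learning rate 0.05); desk-scale work passes
#' smaller values explicitly.
#'
#' @param learning_rate positive step size `eps`.
#' @param epochs positive number of passes over the data.
#' @param batch_size positive mini-batch size.
#' @param gibbs_steps CD chain length `k`.
#' @param seed integer seed (required; all randomness derives from it).
#' @param tolerance convergence tolerance `e` on the change in mean
#'   reconstruction error between training rounds.
#' @param init weight initialization passed to [rbm_init()].
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.05, epochs = 70, batch_size = 128,
                         gibbs_steps = 50, seed, tolerance = 0.08,
                         init = c("uniform", "gaussian")) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1, gibbs_steps >= 1,
            tolerance > 0)
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         gibbs_steps = as.integer(gibbs_steps), seed = as.integer(seed),
         tolerance = tolerance, init = match.arg(init)),
    class = "train_config"
  )
}

# Deterministic derived seeds: one root seed fans out to independent
# per-stage/per-round streams, kept below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(paste(x, collapse = "")) else as.numeric(x)
  })))
  h <- 0
  for (p in parts) h <- (h * 1103515245 + p + 12345) %% 2147483647
  as.integer(h)
}

#' Train one RBM by contrastive divergence
#'
#' Runs `epochs` passes over the data; each epoch shuffles the rows once
#' (seeded) and applies [cd_update()] to contiguous mini-batches. The
#' training log records the mean-field reconstruction error
#' `mean(|x - p(v | p(h | x))|)` after each epoch.
#'
#' @param data matrix of visible configurations (rows) or a [fp_tbl].
#' @param n_hidden hidden layer size.
#' @param config a [train_config()].
#' @return an [rbm] with a `training_log` attribute (numeric vector).
#' @export
rbm_train <- function(data, n_hidden, config) {
  x <- if (inherits(data, "data.frame")) fp_values(data) else as.matrix(data)
  if (!nrow(x)) stop("empty data.", call. = FALSE)
  params <- rbm_init(ncol(x), n_hidden, derive_seed(config$seed, "init"),
                     config$init)
  log <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- withr::with_seed(derive_seed(config$seed, "shuffle", ep),
                            sample.int(nrow(x)))
    starts <- seq(1, nrow(x), by = config$batch_size)
    for (bi in seq_along(starts)) {
      rows <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1, nrow(x))]
      params <- cd_update(params, x[rows, , drop = FALSE],
                          config$learning_rate, config$gibbs_steps,
                          derive_seed(config$seed, "cd", ep, bi))
    }
    log[ep] <- mean(abs(x - visible_conditional(params,
                                                hidden_conditional(params, x))))
  }
  attr(params, "training_log") <- log
  params
}

#' Exact model moments by state enumeration
#'
#' Computes `<v_i h_j>`, `<v_i>` and `<h_j>` under the Boltzmann distribution
#' `p(v, h) = exp(a'v + b'h + v'Wh) / Z` by summing over all `2^(V+H)` joint
#' states. Intended as ground truth for small models; refuses `V + H > 20`.
#'
#' @param params an [rbm].
#' @return list with matrix `vh` (`V x H`), vectors `v` and `h`, and the log
#'   partition function `log_z`.
#' @export
exact_moments <- function(params) {
  V <- nrow(params$W); H <- ncol(params$W)
  if (V + H > 20) stop("model too large for enumeration (V + H > 20).",
                       call. = FALSE)
  vs <- as.matrix(expand.grid(rep(list(0:1), V)))[, seq_len(V), drop = FALSE]
  hs <- as.matrix(expand.grid(rep(list(0:1), H)))[, seq_len(H), drop = FALSE]
  # unnormalized log-weights over the joint grid (2^V x 2^H)
  lw <- outer(drop(vs %*% params$a), drop(hs %*% params$b), `+`) +
    vs %*% params$W %*% t(hs)
  w <- exp(lw - max(lw))
  z <- sum(w)
  p <- w / z
  list(
    vh = unname(crossprod(vs, p %*% hs)),
    v = unname(drop(crossprod(vs, rowSums(p)))),
    h = unname(drop(crossprod(hs, colSums(p)))),
    log_z = log(z) + max(lw)
  )
}

#' Exact log-likelihood of visible data under a small RBM
#'
#' Sums out the hidden layer analytically and normalizes with the enumerated
#' partition function; used to verify that contrastive-divergence updates
#' ascend the data log-likelihood on tiny models.
#'
#' @param params an [rbm] with `V + H <= 20`.
#' @param data matrix of binary visible rows.
#' @return total log-likelihood of the rows of `data`.
#' @export
rbm_log_likelihood <- function(params, data) {
  data <- rbind(data)
  lz <- exact_moments(params)$log_z
  act <- sweep(data %*% params$W, 2, params$b, `+`)
  softplus <- pmax(act, 0) + log1p(exp(-abs(act)))
  free <- drop(data %*% params$a) + rowSums(softplus)
  sum(free - lz)
}
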