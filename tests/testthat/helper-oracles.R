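# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# p(h_j = 1 | v) by enumerating all hidden states of the joint Boltzmann
# distribution p(v, h) proportional to exp(a'v + b'h + v'Wh).
enum_hidden_conditional <- function(W, a, b, v) {
  H <- ncol(W)
  hs <- as.matrix(expand.grid(rep(list(0:1), H)))[, seq_len(H), drop = FALSE]
  logw <- sum(a * v) + drop(hs %*% b) + drop((v %*% W) %*% t(hs))
  p <- exp(logw - max(logw)); p <- p / sum(p)
  unname(drop(crossprod(hs, p)))
}

# Exact joint moments by looping over every (v, h) state, scalar arithmetic.
enum_moments <- function(W, a, b) {
  V <- nrow(W); H <- ncol(W)
  vs <- as.matrix(expand.grid(rep(list(0:1), V)))[, seq_len(V), drop = FALSE]
  hs <- as.matrix(expand.grid(rep(list(0:1), H)))[, seq_len(H), drop = FALSE]
  vh <- matrix(0, V, H); mv <- numeric(V); mh <- numeric(H); z <- 0
  for (i in seq_len(nrow(vs))) for (j in seq_len(nrow(hs))) {
    v <- vs[i, ]; h <- hs[j, ]
    w <- exp(sum(a * v) + sum(b * h) + drop(v %*% W %*% h))
    z <- z + w
    vh <- vh + w * outer(v, h)
    mv <- mv + w * v
    mh <- mh + w * h
  }
  list(vh = unname(vh / z), v = unname(mv / z), h = unname(mh / z))
}

# Brute-force Tanimoto ranking: scalar pairwise scores, plain sort.
brute_rank <- function(x, query_id, mode = "continuous") {
  q <- x[query_id, ]
  db <- x[setdiff(rownames(x), query_id), , drop = FALSE]
  scores <- vapply(seq_len(nrow(db)), function(i) {
    b <- db[i, ]
    num <- sum(q * b)
    den <- if (mode == "binary") sum(q) + sum(b) - num else sum(q^2) + sum(b^2) - num
    if (den == 0) 0 else num / den
  }, numeric(1))
  names(scores) <- rownames(db)
  ord <- order(-scores, names(scores))
  data.frame(molecule_id = names(scores)[ord], score = unname(scores[ord]),
             stringsAsFactors = FALSE)
}

# Direct transcription of the concordance formulas: total ranks, grand mean
# m(n+1)/2, squared deviations, W = 12 S / (m^2 (n^3 - n)).
brute_kendall_w <- function(x) {
  m <- nrow(x); n <- ncol(x)
  r <- matrix(0, m, n)
  for (j in seq_len(m)) r[j, ] <- rank(x[j, ])
  R <- colSums(r)
  Rbar <- m * (n + 1) / 2
  S <- sum((R - Rbar)^2)
  12 * S / (m^2 * (n^3 - n))
}

# small random RBM with weights big enough that gradients are well-scaled
random_rbm <- function(V, H, seed, sd = 0.5) {
  withr::with_seed(seed, {
    rbm(matrix(stats::rnorm(V * H, sd = sd), V, H),
        stats::rnorm(V, sd = sd / 2), stats::rnorm(H, sd = sd / 2))
  })
}

# desk-scale training settings used across tests
desk_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(learning_rate = 0.1, epochs = 30, batch_size = 32,
                   gibbs_steps = 1, seed = seed, init = "gaussian")
  defaults[names(args)] <- args
  do.call(train_config, defaults)
}

# one synthetic descriptor plus its ground-truth index sets
synth_case <- function(seed, ...) {
  spec <- synthetic_spec(seed = seed, ...)
  gen <- generate_fingerprints(spec)
  man <- gen$manifest[gen$manifest$descriptor == "D1", ]
  list(
    fp = binarize(gen$descriptors$D1),
    all = gen,
    signal = man$feature[man$role == "signal"],
    outlier = man$feature[man$role == "outlier"]
  )
}
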