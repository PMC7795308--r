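test_that("pretraining validates its contract", {
  x <- matrix(rbinom(100, 1, 0.5), 10, 10)
  cfg <- desk_config(1, epochs = 1)
  expect_error(dbn_pretrain(x, 10, cfg), "at least one RBM")
  expect_error(dbn_pretrain(x, c(8, 4), cfg), "input feature count")
  expect_error(dbn_pretrain(x[0, ], c(10, 4), cfg), "empty")
})

test_that("pretraining reduces reconstruction error and is reproducible", {
  wins <- 0
  for (seed in 1:5) {
    case <- synth_case(seed * 11, class_sizes = c(A = 50, B = 50))
    x <- fp_values(case$fp)
    trained <- dbn_pretrain(x, c(64, 32, 16), desk_config(seed, epochs = 15))
    init <- dbn_pretrain(x, c(64, 32, 16), desk_config(seed, epochs = 0))
    err_t <- mean(dbn_reconstruct(trained, x)$E)
    err_0 <- mean(dbn_reconstruct(init, x)$E)
    if (err_t < err_0) wins <- wins + 1
  }
  expect_gte(wins, 3)

  case <- synth_case(4, class_sizes = c(A = 30, B = 30))
  cfg <- desk_config(2, epochs = 3)
  m1 <- dbn_pretrain(case$fp, c(64, 16), cfg)
  m2 <- dbn_pretrain(case$fp, c(64, 16), cfg)
  expect_identical(m1$layers, m2$layers)
})

test_that("fine-tuning with zero epochs only flags the model", {
  x <- matrix(rbinom(80, 1, 0.4), 10, 8)
  m <- dbn_pretrain(x, c(8, 4), desk_config(3, epochs = 2))
  ft <- dbn_fine_tune(m, x, desk_config(3, epochs = 0))
  expect_true(ft$fine_tuned)
  expect_identical(ft$layers, m$layers)
  # decoder initialized as the transposed stack: same reconstruction
  expect_equal(dbn_reconstruct(ft, x)$Y, dbn_reconstruct(m, x)$Y)
  expect_error(dbn_fine_tune(list(), x, desk_config(1)), "pretrained")
})

test_that("fine-tuning reduces the autoencoder loss", {
  wins <- 0
  for (seed in 1:5) {
    case <- synth_case(seed * 13, class_sizes = c(A = 40, B = 40))
    x <- fp_values(case$fp)
    m <- dbn_pretrain(x, c(64, 32, 16), desk_config(seed, epochs = 10))
    ft <- dbn_fine_tune(m, x, desk_config(seed, epochs = 60, learning_rate = 1))
    e0 <- mean(dbn_reconstruct(m, x)$E)
    e1 <- mean(dbn_reconstruct(ft, x)$E)
    if (e1 <= e0) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("backpropagation gradient matches finite differences", {
  # 6-4-3 stack with well-scaled random weights
  model <- structure(list(
    layers = list(random_rbm(6, 4, 71), random_rbm(4, 3, 72)),
    layer_sizes = c(6L, 4L, 3L), fine_tuned = FALSE, decoder = NULL,
    training_log = c(0, 0)
  ), class = "dbn")
  x <- withr::with_seed(7, matrix(rbinom(48, 1, 0.5), 8, 6))
  net <- sdbn:::dbn_unroll(model)
  analytic <- sdbn:::ae_loss_grad(net, x)
  reassemble <- function(all) list(enc = all[1:2], dec = all[3:4])
  numeric_grad <- function(l, what, i, j = NULL, eps = 1e-5) {
    shift <- function(s) {
      all <- c(net$enc, net$dec)
      if (what == "W") all[[l]]$W[i, j] <- all[[l]]$W[i, j] + s
      else all[[l]]$b[i] <- all[[l]]$b[i] + s
      sdbn:::ae_loss_grad(reassemble(all), x)$loss
    }
    (shift(eps) - shift(-eps)) / (2 * eps)
  }
  worst <- 0
  for (l in 1:4) {
    lay <- c(net$enc, net$dec)[[l]]
    for (i in seq_len(nrow(lay$W))) for (j in seq_len(ncol(lay$W))) {
      an <- analytic$grads[[l]]$W[i, j]
      nu <- numeric_grad(l, "W", i, j)
      worst <- max(worst, abs(an - nu) / max(abs(an) + abs(nu), 1e-4))
    }
    for (i in seq_along(lay$b)) {
      an <- analytic$grads[[l]]$b[i]
      nu <- numeric_grad(l, "b", i)
      worst <- max(worst, abs(an - nu) / max(abs(an) + abs(nu), 1e-4))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("reconstruction is deterministic with consistent error norms", {
  case <- synth_case(6, class_sizes = c(A = 20, B = 20))
  m <- dbn_pretrain(case$fp, c(64, 16), desk_config(6, epochs = 5))
  r1 <- dbn_reconstruct(m, case$fp)
  r2 <- dbn_reconstruct(m, case$fp)
  expect_identical(r1, r2)
  expect_true(all(r1$Y >= 0 & r1$Y <= 1))
  expect_true(all(r1$E >= 0))
  expect_equal(r1$per_molecule_error^2, rowSums(r1$E^2), ignore_attr = TRUE)
  l1 <- dbn_reconstruct(m, case$fp, norm = "l1")
  expect_equal(l1$per_molecule_error, rowSums(l1$E), ignore_attr = TRUE)
  expect_error(dbn_reconstruct(m, matrix(0, 2, 5)), "features")
})

test_that("a saturated identity stack reconstructs binary input exactly", {
  V <- 5
  ident <- structure(list(
    layers = list(rbm(40 * diag(V), rep(-20, V), rep(-20, V))),
    layer_sizes = c(V, V), fine_tuned = FALSE, decoder = NULL,
    training_log = 0
  ), class = "dbn")
  x <- rbind(c(1, 0, 1, 1, 0), c(0, 0, 0, 1, 1))
  rec <- dbn_reconstruct(ident, x)
  expect_equal(rec$Y, x, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(rec$E), 1e-6)
  expect_lt(max(rec$per_molecule_error), 1e-5)
})

test_that("planted outlier features earn the largest column errors", {
  wins <- 0
  for (seed in 1:5) {
    case <- synth_case(seed * 101)
    m <- dbn_pretrain(case$fp, c(64, 48, 24), desk_config(seed))
    ce <- colMeans(dbn_reconstruct(m, case$fp)$E)
    if (mean(ce[case$outlier + 1]) > mean(ce[case$signal + 1])) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("iterative feature learning terminates per its contract", {
  case <- synth_case(8, class_sizes = c(A = 30, B = 30))
  cfg <- desk_config(8, epochs = 5)
  # no removals requested: single round
  r0 <- iterative_feature_learning(case$fp, c(64, 16), cfg,
                                   outlier_fraction = 0)
  expect_equal(nrow(r0$history), 1)
  expect_length(r0$removed_features, 0)
  # infinite tolerance: vacuous criterion, stops after round 1
  cfg_inf <- cfg; cfg_inf$tolerance <- Inf
  r1 <- iterative_feature_learning(case$fp, c(64, 16), cfg_inf,
                                   outlier_fraction = 0.1)
  expect_equal(nrow(r1$history), 1)
  expect_length(r1$removed_features, 0)
  expect_error(iterative_feature_learning(case$fp, c(64, 16), cfg, 0.6),
               "outlier_fraction")
})

test_that("iterative learning recovers planted outliers in original coordinates", {
  wins <- 0
  for (seed in 1:5) {
    case <- synth_case(seed * 101)
    res <- iterative_feature_learning(case$fp, c(64, 48, 24),
                                      desk_config(seed),
                                      outlier_fraction = 0.125)
    expect_setequal(c(res$kept_features, res$removed_features), 0:63)
    expect_false(anyDuplicated(res$removed_features) > 0)
    if (sum(case$outlier %in% res$removed_features) >= 6) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("the trained pipeline is bit-reproducible under one seed", {
  case <- synth_case(12, class_sizes = c(A = 25, B = 25))
  run_once <- function() {
    cfg <- desk_config(9, epochs = 4)
    m <- dbn_pretrain(case$fp, c(64, 24, 12), cfg)
    ft <- dbn_fine_tune(m, case$fp, cfg)
    dbn_reconstruct(ft, case$fp)$Y
  }
  expect_identical(run_once(), run_once())
})
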