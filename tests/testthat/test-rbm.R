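test_that("sigmoid is the logistic function and saturates safely", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(2), 0.8807971, tolerance = 1e-7)
  x <- seq(-30, 30, by = 2.5)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_equal(sigmoid(1000), 1)
  expect_equal(sigmoid(-1000), 0)
})

test_that("conditionals factorize and match enumeration of the joint", {
  # zero parameters: everything 0.5; bias-only: sigmoid of the bias
  z <- rbm(matrix(0, 3, 2), numeric(3), numeric(2))
  expect_equal(hidden_conditional(z, c(1, 0, 1)), rep(0.5, 2))
  expect_equal(visible_conditional(z, c(1, 1)), rep(0.5, 3))
  bz <- rbm(matrix(0, 3, 2), c(-1, 0, 2), c(0.5, -0.5))
  expect_equal(hidden_conditional(bz, numeric(3)), sigmoid(c(0.5, -0.5)))
  expect_equal(visible_conditional(bz, numeric(2)), sigmoid(c(-1, 0, 2)))

  # agreement with the brute-force joint enumeration on random tiny models
  for (seed in 1:5) {
    r <- random_rbm(3, 2, seed)
    for (v in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1))) {
      expect_equal(hidden_conditional(r, v),
                   enum_hidden_conditional(r$W, r$a, r$b, v),
                   tolerance = 1e-12)
    }
  }
  expect_error(hidden_conditional(z, c(1, 0)), "dimension")
  expect_error(rbm(matrix(0, 2, 2), numeric(3), numeric(2)), "dimension")
})

test_that("exact moments match closed forms and the scalar oracle", {
  # zero parameters: uniform over all states
  z <- rbm(matrix(0, 2, 2), numeric(2), numeric(2))
  em <- exact_moments(z)
  expect_equal(unname(em$vh), matrix(0.25, 2, 2))
  expect_equal(em$v, rep(0.5, 2))
  expect_equal(em$h, rep(0.5, 2))
  # 1x1 model, a = b = 0: <vh> = e^w / (3 + e^w) from the 4-state sum
  for (w in c(-1, 0.5, 1.5, 3)) {
    expect_equal(drop(exact_moments(rbm(matrix(w), 0, 0))$vh),
                 exp(w) / (3 + exp(w)), tolerance = 1e-12)
  }
  # random tiny model vs the double-loop oracle
  r <- random_rbm(3, 2, 21)
  em <- exact_moments(r)
  or <- enum_moments(r$W, r$a, r$b)
  expect_equal(unname(em$vh), or$vh, tolerance = 1e-12)
  expect_equal(em$v, or$v, tolerance = 1e-12)
  expect_equal(em$h, or$h, tolerance = 1e-12)
  expect_error(exact_moments(rbm(matrix(0, 15, 15), numeric(15), numeric(15))),
               "too large")
})

test_that("gibbs sampling is deterministic and mixes to the fair coin", {
  r <- random_rbm(4, 3, 31)
  c1 <- gibbs_chain(r, c(1, 0, 1, 0), k = 7, seed = 99)
  c2 <- gibbs_chain(r, c(1, 0, 1, 0), k = 7, seed = 99)
  expect_identical(c1, c2)
  expect_true(all(c1$pv >= 0 & c1$pv <= 1))
  expect_true(all(c1$v %in% c(0, 1)))

  # zero parameters: each unit an i.i.d. fair coin; long-run mean 0.5 +- 3 se
  z <- rbm(matrix(0, 2, 2), numeric(2), numeric(2))
  draws <- gibbs_chain(z, matrix(0, 5000, 2), k = 2, seed = 4)
  expect_lt(abs(mean(draws$v) - 0.5), 3 * sqrt(0.25 / length(draws$v)))

  # strong positive single weight: (v1 = 1, h1 = 1) co-occurs above chance
  s <- rbm(matrix(3), 0, 0)
  expect_gt(drop(exact_moments(s)$vh), 0.25)
  chains <- gibbs_chain(s, matrix(rbinom(400, 1, 0.5), 400, 1), k = 10, seed = 8)
  expect_gt(mean(chains$v * chains$h), 0.25)
})

test_that("contrastive divergence follows the update equations", {
  r <- random_rbm(3, 2, 41)
  # zero learning rate leaves parameters untouched
  expect_identical(cd_update(r, matrix(1, 4, 3), 0, 1, seed = 1), r)
  expect_error(cd_update(r, matrix(1, 0, 3), 0.1, 1, seed = 1), "empty")

  # all-ones batch, W = 0, a = b = 0, k = 1: the negative visible state is
  # exactly 0.5 (sigmoid of 0) whatever h is sampled, so the update is
  # deterministic: da = eps * (1 - 0.5), dW = eps * (1 * 0.5 - 0.5 * 0.5)
  z <- rbm(matrix(0, 3, 2), numeric(3), numeric(2))
  up <- cd_update(z, matrix(1, 6, 3), learning_rate = 0.2, k = 1, seed = 77)
  expect_equal(up$a, rep(0.2 * 0.5, 3))
  expect_equal(unname(up$W), matrix(0.2 * 0.25, 3, 2))
  expect_equal(up$b, rep(0, 2), tolerance = 1e-12)
})

test_that("CD is approximately at a fixed point on model-distributed data", {
  r <- random_rbm(3, 2, 51)
  em <- enum_moments(r$W, r$a, r$b)
  # sample visible vectors from the exact marginal p(v)
  vs <- as.matrix(expand.grid(rep(list(0:1), 3)))
  act <- sweep(vs %*% r$W, 2, r$b, `+`)
  lw <- drop(vs %*% r$a) + rowSums(pmax(act, 0) + log1p(exp(-abs(act))))
  pv <- exp(lw - max(lw)); pv <- pv / sum(pv)
  batch <- vs[withr::with_seed(99, sample(8, 4000, replace = TRUE, prob = pv)), ]
  up <- cd_update(r, batch, learning_rate = 1, k = 25, seed = 123)
  at_fixed_point <- mean(abs(up$W - r$W))
  # contrast: the same update on clearly off-model data moves much more
  up2 <- cd_update(r, matrix(1, 4000, 3), learning_rate = 1, k = 25, seed = 123)
  off_model <- mean(abs(up2$W - r$W))
  expect_lt(at_fixed_point, 0.05)
  expect_gt(off_model, 3 * at_fixed_point)
})

test_that("updates with exact model moments ascend the log-likelihood", {
  r <- random_rbm(3, 2, 61, sd = 0.1)
  data <- withr::with_seed(11, matrix(rbinom(60, 1, rep(c(0.8, 0.2, 0.6), each = 20)), 20, 3))
  ll <- rbm_log_likelihood(r, data)
  for (it in 1:30) {
    em <- exact_moments(r)
    ph <- hidden_conditional(r, data)
    r <- rbm(r$W + 0.05 * (crossprod(data, ph) / nrow(data) - em$vh),
             r$a + 0.05 * (colMeans(data) - em$v),
             r$b + 0.05 * (colMeans(ph) - em$h))
  }
  expect_gt(rbm_log_likelihood(r, data), ll)
})

test_that("rbm_train is deterministic and logs finite errors", {
  x <- withr::with_seed(3, matrix(rbinom(200, 1, 0.3), 20, 10))
  cfg <- desk_config(5, epochs = 4, batch_size = 8)
  m1 <- rbm_train(x, 6, cfg)
  m2 <- rbm_train(x, 6, cfg)
  expect_identical(m1, m2)
  expect_true(all(is.finite(attr(m1, "training_log"))))
  expect_length(attr(m1, "training_log"), 4)
})
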