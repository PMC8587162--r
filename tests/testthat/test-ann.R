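identity_scaler <- function(p) list(min = rep(-1, p), range = rep(2, p))

hand_net <- function(W1, b1, W2, b2) {
  structure(
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
         input_scaler = identity_scaler(ncol(W1)),
         target_scaler = identity_scaler(nrow(W2)),
         config = network_config(ncol(W1), nrow(W1), nrow(W2))),
    class = "ann_network"
  )
}

test_that("forward pass matches hand arithmetic", {
  # zero weights and biases: scaled output 0 -> target-range midpoint
  net0 <- hand_net(matrix(0, 3, 2), rep(0, 3), matrix(0, 1, 3), 0)
  net0$target_scaler <- list(min = 10, range = 20)  # targets in [10, 30]
  expect_equal(as.numeric(predict(net0, matrix(rnorm(10), 5))), rep(20, 5))

  # 1-1-1 identity-scaler net: y = tanh(x)
  net1 <- hand_net(matrix(1, 1, 1), 0, matrix(1, 1, 1), 0)
  expect_equal(as.numeric(predict(net1, matrix(0))), 0)

  # random hand-set net against brute-force loops
  set.seed(13)
  W1 <- matrix(rnorm(6), 3, 2); b1 <- rnorm(3)
  W2 <- matrix(rnorm(6), 2, 3); b2 <- rnorm(2)
  net <- hand_net(W1, b1, W2, b2)
  X <- matrix(runif(10, -1, 1), 5)
  got <- predict(net, X)
  for (i in 1:5) {
    a <- tanh(W1 %*% X[i, ] + b1)
    expect_equal(as.numeric(got[i, ]), as.numeric(W2 %*% a + b2),
                 tolerance = 1e-12)
  }
  expect_error(predict(net, matrix(0, 2, 5)), "expects")
})

test_that("analytic jacobian matches central finite differences", {
  for (seed in 1:3) {
    cfg <- network_config(4, 3, 2, seed = seed)
    net <- grapevit:::init_network(cfg, identity_scaler(4), identity_scaler(2))
    set.seed(seed)
    Xs <- matrix(runif(4 * 6, -1, 1), 6)
    J <- grapevit:::ann_jacobian(net, Xs)
    w <- grapevit:::pack_weights(net)
    h <- 1e-6
    num <- vapply(seq_along(w), function(k) {
      wp <- w; wm <- w
      wp[k] <- wp[k] + h; wm[k] <- wm[k] - h
      fp <- as.vector(grapevit:::forward_scaled(
        grapevit:::unpack_weights(net, wp), Xs)$Ys)
      fm <- as.vector(grapevit:::forward_scaled(
        grapevit:::unpack_weights(net, wm), Xs)$Ys)
      (fp - fm) / (2 * h)
    }, numeric(nrow(J)))
    expect_lt(max(abs(J - num)) / max(abs(num)), 1e-5)
  }
})

test_that("an lm step with vanishing damping solves the normal equations", {
  set.seed(3)
  J <- matrix(rnorm(50 * 6), 50)
  e <- rnorm(50)
  delta <- lm_step(J, e, mu = 1e-12)
  oracle <- solve(crossprod(J), -crossprod(J, e))
  expect_equal(delta, as.numeric(oracle), tolerance = 1e-8)
})

test_that("splits reproduce the published stage counts and are deterministic", {
  s1 <- split_dataset(432, c(0.75, 0, 0.25), seed = 1)
  expect_equal(sum(s1$assignment == "training"), 324L)
  expect_equal(sum(s1$assignment == "testing"), 108L)
  s2 <- split_dataset(432, c(0.60, 0.20, 0.20), seed = 1)
  expect_equal(unname(table(s2$assignment)[c("training", "validation", "testing")]),
               c(260L, 86L, 86L), ignore_attr = TRUE)
  expect_identical(split_dataset(432, c(0.6, 0.2, 0.2), 7)$assignment,
                   split_dataset(432, c(0.6, 0.2, 0.2), 7)$assignment)
  expect_error(split_dataset(5, c(0.9, 0.05, 0.05)), "no samples")
  # validation/testing within 1 of fraction * n; training absorbs the
  # rounding remainder of both (at most 2)
  for (n in c(50, 101, 433)) {
    s <- split_dataset(n, c(0.6, 0.2, 0.2), 3)
    counts <- as.integer(table(factor(s$assignment,
                                      c("training", "validation", "testing"))))
    expect_true(all(abs(counts[2:3] - 0.2 * n) <= 1))
    expect_lte(abs(counts[1] - 0.6 * n), 2)
  }
})

test_that("lm drives a realizable linear target to machine-level training error", {
  set.seed(1)
  x <- matrix(runif(50, -1, 1), 50)
  y <- matrix(3 * x - 1, 50)
  sp <- split_dataset(50, c(0.6, 0.2, 0.2), 2)
  fit <- train_network(x, y, sp, network_config(1, 3, 1, max_epochs = 200, seed = 2))
  expect_lt(fit$diagnostics$mse[fit$diagnostics$stage == "training"], 1e-5)
})

test_that("lm training objective is monotone over accepted steps", {
  td <- make_teacher_dataset(120, 4, 5, 1, noise_sd = 0.05, rng_seed = 3)
  sp <- split_dataset(120, c(0.6, 0.2, 0.2), 3)
  fit <- train_network(td$X, td$Y, sp,
                       network_config(4, 5, 1, max_epochs = 100, seed = 3))
  expect_true(all(diff(fit$result$objective) <= 1e-12))
})

test_that("teacher-student recovery succeeds for both training algorithms", {
  td <- make_teacher_dataset(300, 6, 10, 2, noise_sd = 0.05, rng_seed = 7)
  sp_lm <- split_dataset(300, c(0.6, 0.2, 0.2), 11)
  fit_lm <- train_network(td$X, td$Y, sp_lm,
                          network_config(6, 10, 2, "levenberg_marquardt",
                                         max_epochs = 300, seed = 11))
  d <- fit_lm$diagnostics
  expect_gte(d$r[d$stage == "testing"], 0.95)

  sp_br <- split_dataset(300, c(0.75, 0, 0.25), 11)
  fit_br <- train_network(td$X, td$Y, sp_br,
                          network_config(6, 10, 2, "bayesian_regularization",
                                         max_epochs = 300, seed = 11))
  db <- fit_br$diagnostics
  expect_gte(db$r[db$stage == "testing"], 0.95)
  expect_lte(db$mse[db$stage == "testing"], 2 * db$mse[db$stage == "training"])
})

test_that("bayesian regularization shrinks weights on pure-noise targets", {
  set.seed(9)
  X <- matrix(runif(20 * 3, -1, 1), 20)
  Y <- matrix(rnorm(20), 20, 1)
  sp <- split_dataset(20, c(0.75, 0, 0.25), 2)
  fit <- train_network(X, Y, sp,
                       network_config(3, 5, 1, "bayesian_regularization",
                                      max_epochs = 200, seed = 2))
  expect_lt(fit$result$gamma, 0.2 * fit$result$n_weights)
  expect_lt(max(abs(grapevit:::pack_weights(fit$network))), 1e-3)
})

test_that("with hyperparameters frozen at alpha = 0, br follows the lm trajectory", {
  td <- make_teacher_dataset(60, 3, 3, 1, noise_sd = 0.05, rng_seed = 5)
  sp <- split_dataset(60, c(0.75, 0, 0.25), 4)
  f_lm <- train_network(td$X, td$Y, sp,
                        network_config(3, 3, 1, "levenberg_marquardt",
                                       max_epochs = 40, seed = 8))
  f_b0 <- train_network(td$X, td$Y, sp,
                        network_config(3, 3, 1, "bayesian_regularization",
                                       max_epochs = 40, seed = 8),
                        update_hyper = FALSE)
  n <- min(length(f_lm$result$objective), length(f_b0$result$objective))
  expect_equal(f_lm$result$objective[1:n], f_b0$result$objective[1:n],
               tolerance = 1e-9)
})

test_that("training is seeded-deterministic and invariant to input rescaling", {
  td <- make_teacher_dataset(150, 4, 5, 2, noise_sd = 0.05, rng_seed = 6)
  sp <- split_dataset(150, c(0.6, 0.2, 0.2), 5)
  cfg <- network_config(4, 5, 2, max_epochs = 80, seed = 5)
  f1 <- train_network(td$X, td$Y, sp, cfg)
  f2 <- train_network(td$X, td$Y, sp, cfg)
  expect_equal(f1$diagnostics$r, f2$diagnostics$r, tolerance = 1e-9)
  expect_equal(f1$diagnostics$mse, f2$diagnostics$mse, tolerance = 1e-9)
  # positive affine rescaling of the raw inputs changes nothing after min-max
  X2 <- sweep(td$X * 37, 2, c(1, -2, 5, 100), "+")
  f3 <- train_network(X2, td$Y, sp, cfg)
  expect_equal(f3$diagnostics$r, f1$diagnostics$r, tolerance = 1e-8)
})

test_that("scaling round-trips exactly", {
  set.seed(4)
  X <- matrix(rnorm(60, 5, 3), 20)
  sc <- grapevit:::minmax_scaler(X)
  Xs <- grapevit:::scale_apply(sc, X)
  expect_true(all(Xs >= -1 & Xs <= 1))
  expect_equal(grapevit:::scale_invert(sc, Xs), X, tolerance = 1e-12)
})

test_that("neuron trimming selects the parsimonious admissible network", {
  td <- make_teacher_dataset(200, 4, 3, 1, noise_sd = 0.02, rng_seed = 10)
  sp <- split_dataset(200, c(0.6, 0.2, 0.2), 10)
  cfg <- network_config(4, 3, 1, max_epochs = 120, seed = 10)
  rep3 <- neuron_trimming(td$X, td$Y, sp, cfg, candidates = c(3L, 5L, 7L, 10L))
  expect_true(rep3$selected %in% c(3L, 5L, 7L, 10L))
  expect_equal(nrow(rep3$candidates), 4L)
  # a teacher this small is matched by few neurons; ties go to the smallest
  expect_lte(rep3$selected, 5L)

  single <- neuron_trimming(td$X, td$Y, sp, cfg, candidates = 3L)
  expect_equal(single$selected, 3L)

  # pure noise: flexible candidates show the overfitting signature
  set.seed(20)
  Xn <- matrix(runif(40 * 3, -1, 1), 40)
  Yn <- matrix(rnorm(40), 40, 1)
  spn <- split_dataset(40, c(0.6, 0.2, 0.2), 20)
  repn <- neuron_trimming(Xn, Yn, spn,
                          network_config(3, 3, 1, max_epochs = 60, seed = 20),
                          candidates = c(3L, 10L))
  expect_true(any(!repn$candidates$admissible))
})

test_that("network serialization round-trips predictions", {
  td <- make_teacher_dataset(80, 3, 4, 2, noise_sd = 0.05, rng_seed = 12)
  sp <- split_dataset(80, c(0.6, 0.2, 0.2), 12)
  fit <- train_network(td$X, td$Y, sp,
                       network_config(3, 4, 2, max_epochs = 50, seed = 12))
  path <- withr::local_tempfile(fileext = ".json")
  network_to_json(fit, path)
  back <- network_from_json(path)
  expect_equal(predict(back, td$X), predict(fit$network, td$X),
               tolerance = 1e-12)
})

test_that("br rejects a validation stage", {
  td <- make_teacher_dataset(60, 3, 3, 1, rng_seed = 1)
  sp <- split_dataset(60, c(0.6, 0.2, 0.2), 1)
  expect_error(
    train_network(td$X, td$Y, sp,
                  network_config(3, 3, 1, "bayesian_regularization", seed = 1)),
    "no validation"
  )
})
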