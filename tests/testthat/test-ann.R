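# The optimizer is checked on a convex problem, then the full classifier
# on constructed cluster data where the expected outcome is known.

test_that("scaled conjugate gradient minimizes a quadratic", {
  A <- crossprod(matrix(c(2, 0.5, 0, 0.5, 3, 1, 0, 1, 4), 3, 3))
  b <- c(1, -2, 0.5)
  fn <- function(w) 0.5 * sum(w * (A %*% w)) - sum(b * w)
  gr <- function(w) as.numeric(A %*% w) - b
  res <- scg_minimize(rep(0, 3), fn, gr, max_iters = 200)
  expect_equal(res$w, as.numeric(solve(A, b)), tolerance = 1e-5)
})

test_that("separable clusters are fit perfectly and deterministically", {
  fs <- make_cluster_features(n_per_class = 20, sep = 10)
  cfg <- net_config(seed = 5)
  net <- train_workload_net(fs, cfg)
  expect_equal(accuracy(predict(net, fs), fs$labels), 1.0)
  net2 <- train_workload_net(fs, cfg)
  expect_identical(net$weights, net2$weights)
  expect_identical(net$training_meta, net2$training_meta)
  net3 <- train_workload_net(fs, net_config(seed = 6))
  expect_false(identical(net$weights, net3$weights))
})

test_that("shuffled labels give chance-level held-out accuracy", {
  # null simulation: random labels, independent held-out rows; the mean
  # held-out accuracy over 20 replicates stays within 50% +/- 10%
  cfg <- net_config(hidden_layers = c(5, 5), max_iters = 60,
                    n_restarts = 2, seed = 1)
  accs <- vapply(1:20, function(rep) {
    set.seed(rep + 400)
    fs <- make_cluster_features(n_per_class = 20, sep = 0, p = 8,
                                seed = rep)
    fs$labels <- sample(fs$labels)
    te <- make_cluster_features(n_per_class = 25, sep = 0, p = 8,
                                seed = rep + 1000)
    te$labels <- sample(te$labels)
    net <- train_workload_net(fs, cfg)
    accuracy(predict(net, te), te$labels)
  }, numeric(1))
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.60)
})

test_that("degenerate training inputs are rejected", {
  fs <- make_cluster_features(n_per_class = 20, sep = 5)
  one_class <- fs
  one_class$labels <- rep("high", length(fs$labels))
  expect_error(train_workload_net(one_class), "both",
               class = "workloadbci_invalid")
  few <- make_cluster_features(n_per_class = 6, sep = 5)
  expect_error(train_workload_net(few), "at least 10",
               class = "workloadbci_invalid")
})

test_that("prediction is rowwise: duplication and permutation behave", {
  fs <- make_cluster_features(n_per_class = 20, sep = 10)
  net <- train_workload_net(fs, net_config(n_restarts = 2, seed = 3))
  preds <- predict(net, fs)
  dup <- fs
  dup$matrix <- fs$matrix[c(1:5, 1:5), ]
  dup$labels <- fs$labels[c(1:5, 1:5)]
  expect_equal(predict(net, dup), rep(preds[1:5], 2))
  perm <- sample(nrow(fs$matrix))
  pf <- fs
  pf$matrix <- fs$matrix[perm, ]
  expect_equal(predict(net, pf), preds[perm])
  narrow <- fs
  narrow$matrix <- fs$matrix[, 1:5]
  expect_error(predict(net, narrow), "width",
               class = "workloadbci_invalid")
})

test_that("training is equivariant to feature permutation given matched inits", {
  fs <- make_cluster_features(n_per_class = 15, sep = 4, p = 10)
  cfg <- net_config(hidden_layers = c(6, 6), max_iters = 25,
                    early_stop_patience = 50, n_restarts = 1, seed = 2)
  dims <- c(10, 6, 6, 2)
  set.seed(77)
  init <- workloadbci:::init_weights(dims)
  net_a <- train_workload_net(fs, cfg, inits = list(init))

  perm <- c(4, 1, 10, 2, 7, 3, 9, 5, 8, 6)
  fs_p <- fs
  fs_p$matrix <- fs$matrix[, perm]
  colnames(fs_p$matrix) <- colnames(fs$matrix)[perm]
  fs_p$feature_names <- fs$feature_names[perm]
  init_p <- init
  init_p[[1]]$W <- init[[1]]$W[perm, ]
  net_b <- train_workload_net(fs_p, cfg, inits = list(init_p))
  expect_lt(abs(net_b$training_meta$validation_loss -
                  net_a$training_meta$validation_loss), 1e-9)
  expect_equal(predict(net_b, fs_p), predict(net_a, fs))
})

test_that("accuracy is the fraction of matching epochs", {
  expect_equal(accuracy(c("high", "low"), c("high", "low")), 1.0)
  expect_equal(accuracy(c("high", "low"), c("low", "high")), 0.0)
  truth <- c(rep("high", 6), rep("low", 4))
  pred <- truth
  pred[c(1, 3, 8, 10)] <- ifelse(truth[c(1, 3, 8, 10)] == "high",
                                 "low", "high")
  expect_equal(accuracy(pred, truth), 0.6)   # 6 agreements of 10
  expect_error(accuracy(character(0), character(0)),
               class = "workloadbci_invalid")
  expect_error(accuracy("high", c("high", "low")),
               class = "workloadbci_invalid")
})
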