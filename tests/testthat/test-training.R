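test_that("pair labels encode same-class relations", {
  expect_equal(make_pair_labels(c(1, 1, 2)),
               matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3))
  expect_equal(make_pair_labels(c(4, 4, 4)), matrix(1, 3, 3))
  expect_equal(make_pair_labels(c(1, 2, 3)), diag(3))
  expect_equal(make_pair_labels(c("a", "b", "a"))[1, ], c(1, 0, 1))
})

test_that("the learning-rate schedule is the exact step decay", {
  cfg <- train_config(epochs = 100, lr = 0.1, lr_decay_factor = 0.1,
                      lr_decay_every = 30)
  expect_equal(lr_at_epoch(cfg, 1), 0.1)
  expect_equal(lr_at_epoch(cfg, 30), 0.1)
  expect_equal(lr_at_epoch(cfg, 31), 0.01)
  expect_equal(lr_at_epoch(cfg, 61), 0.001)
  cfg2 <- train_config(epochs = 50, lr = 0.2, lr_decay_factor = 1,
                       lr_decay_every = 10)
  expect_true(all(lr_at_epoch(cfg2, 1:50) == 0.2))
  expect_error(lr_at_epoch(cfg, 0), class = "leafhash_config_error")
  expect_error(lr_at_epoch(cfg, 101), class = "leafhash_config_error")
})

test_that("training reduces the combined loss on separable data", {
  fit <- quick_fit()$model
  h <- fit$history
  expect_equal(nrow(h), 20L)
  expect_lt(h$l3[nrow(h)], h$l3[1])
  expect_lt(h$l2[nrow(h)], h$l2[1])
  # recorded learning rates follow the schedule exactly
  expect_equal(h$lr, lr_at_epoch(fit$config, h$epoch))
  expect_true(all(is.finite(unlist(h))))
})

test_that("at eta 0 the recorded combined loss equals the classification loss", {
  m <- tiny_dataset(n_classes = 2, per = 8, size = 16, seed = 401)
  set.seed(401)
  sp <- stratified_split(m, 0.75)
  fit <- dhcnn(sp$train, K = 8,
               backbone = backbone_config("tiny", input_size = 16),
               config = tiny_train_config(epochs = 3, eta = 0, batch_size = 6,
                                          eta_warmup_epochs = 0, seed = 11))
  expect_equal(fit$history$l3, fit$history$l2, tolerance = 1e-12)
})

test_that("two runs with identical configuration produce identical histories", {
  m <- tiny_dataset(n_classes = 2, per = 8, size = 16, seed = 402)
  set.seed(402)
  sp <- stratified_split(m, 0.75)
  cfg <- tiny_train_config(epochs = 3, batch_size = 6, seed = 9)
  bb <- backbone_config("tiny", input_size = 16)
  f1 <- dhcnn(sp$train, K = 8, backbone = bb, config = cfg)
  f2 <- dhcnn(sp$train, K = 8, backbone = bb, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$hash$W, f2$net$hash$W)
})

test_that("backpropagation matches finite differences through the whole network", {
  set.seed(3)
  bb <- backbone_config("tiny", input_size = 8)
  bb$conv_blocks <- list(
    list(filters = 4L, kernel = 3L, stride = 1L, pad = 1L, pool = TRUE, lrn = TRUE),
    list(filters = 6L, kernel = 3L, stride = 1L, pad = 1L, pool = TRUE, lrn = FALSE))
  bb$fc_dims <- 10L
  net <- build_model(bb, K = 4, C = 3, seed = 5)
  B <- 3
  X <- array(rnorm(8 * 8 * 3 * B), c(8, 8, 3, B))
  y <- c(1L, 2L, 1L)
  S <- make_pair_labels(y)
  eta <- 0.6; beta <- 0.7
  loss_fn <- function(net) {
    fw <- leafhash:::forward_net(net, X)
    l1 <- pairwise_likelihood_loss(fw$u, binarize(fw$u), S, beta)$loss
    l2 <- classification_loss(fw$u, y, net$cls$W, net$cls$b)
    combined_loss(l1, l2, eta)
  }
  fw <- leafhash:::forward_net(net, X, keep = TRUE)
  dU <- eta * leafhash:::grad_pairwise(fw$u, binarize(fw$u), S, beta)
  gc <- leafhash:::grad_classification(fw$u, y, net$cls$W, net$cls$b)
  g <- leafhash:::backward_net(net, fw$cache, dU, (1 - eta) * gc$dZ)
  check <- function(get, set, gmat, n_coords = 5) {
    for (i in sample(length(get(net)), n_coords)) {
      h <- 1e-5
      n1 <- net; v <- get(n1); v[i] <- v[i] + h; n1 <- set(n1, v)
      n2 <- net; v <- get(n2); v[i] <- v[i] - h; n2 <- set(n2, v)
      fd <- (loss_fn(n1) - loss_fn(n2)) / (2 * h)
      expect_lt(abs(fd - gmat[i]) / max(abs(fd) + abs(gmat[i]), 1e-8), 1e-4)
    }
  }
  check(function(n) n$conv[[1]]$W, function(n, v) { n$conv[[1]]$W <- v; n }, g$conv[[1]]$W)
  check(function(n) n$conv[[2]]$W, function(n, v) { n$conv[[2]]$W <- v; n }, g$conv[[2]]$W)
  check(function(n) n$fc[[1]]$W, function(n, v) { n$fc[[1]]$W <- v; n }, g$fc[[1]]$W)
  check(function(n) n$hash$W, function(n, v) { n$hash$W <- v; n }, g$hash$W)
  check(function(n) n$cls$W, function(n, v) { n$cls$W <- v; n }, g$cls$W)
})

test_that("the fitted model exposes the standard S3 interface", {
  fit <- quick_fit()
  model <- fit$model
  expect_s3_class(model, "dhcnn")
  expect_output(print(model), "DHCNN")
  s <- summary(model)
  expect_output(print(s), "parameters")
  cf <- coef(model)
  expect_equal(dim(cf$W_h), c(16L, 128L))
  expect_equal(dim(cf$W_s), c(3L, 16L))
  preds <- predict(model, fit$split$test, type = "class")
  expect_length(preds, nrow(fit$split$test))
  expect_true(all(preds %in% model$classes))
  probs <- predict(model, fit$split$test, type = "prob")
  expect_equal(colSums(probs), rep(1, nrow(fit$split$test)), tolerance = 1e-9)
  codes <- predict(model, fit$split$test, type = "code")
  expect_true(all(codes %in% c(-1, 1)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(model))
})
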