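# Paired-input SGD training of the DHCNN, and the user-facing dhcnn() fitting
# function with its S3 methods.

#' Training configuration
#'
#' Defaults follow the reference schedule: SGD with momentum 0.9, batch size
#' 32, initial learning rate 0.1 decayed by a factor of 0.1 every 30 epochs,
#' 200 epochs, 64-bit codes trained with the combined loss at `beta = 1`,
#' `eta = 0.5`. `tiny_train_config()` is the desk-scale preset used
#' throughout the package's own experiments: 30 epochs, learning rate 0.04
#' halved every 15 epochs, eta warmed up over 5 epochs, and pair-count
#' normalization of L1
#' (`l1_mean_pairs = TRUE`) so the loss scale is independent of the batch
#' size.
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param batch_size Minibatch size.
#' @param lr Initial learning rate (> 0).
#' @param lr_decay_factor Multiplicative decay factor in (0, 1].
#' @param lr_decay_every Epoch interval between decays.
#' @param momentum SGD momentum coefficient.
#' @param beta Quantization weight of the pairwise loss.
#' @param eta Balance between pairwise (L1) and classification (L2) losses.
#' @param l1_mean_pairs Normalize L1 by pair / sample counts.
#' @param loss_mode `"L3"` (combined), `"L1"` (pairwise only; the classifier
#'   head is built but receives no gradient) or `"L2"` (cross-entropy only).
#' @param grad_clip Maximum global L2 norm of the per-batch gradient; larger
#'   gradients are rescaled (set `Inf` to disable). Keeps the summed pairwise
#'   loss from destabilizing early epochs.
#' @param eta_warmup_epochs In `"L3"` mode, ramp the pairwise-loss weight
#'   linearly from 0 to `eta` over this many initial epochs (0 = off). A
#'   stand-in for the warm start a pretrained backbone provides: features
#'   become discriminative before the codes harden under the quantization
#'   pull.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(epochs = 200L, batch_size = 32L, lr = 0.1,
                         lr_decay_factor = 0.1, lr_decay_every = 30L,
                         momentum = 0.9, beta = 1, eta = 0.5,
                         l1_mean_pairs = FALSE,
                         loss_mode = c("L3", "L1", "L2"), grad_clip = 5,
                         eta_warmup_epochs = 0L, seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  if (epochs < 1) stop_config("epochs must be >= 1")
  if (lr <= 0) stop_config("lr must be positive")
  if (lr_decay_factor <= 0 || lr_decay_factor > 1)
    stop_config("lr_decay_factor must lie in (0, 1]")
  if (batch_size < 2) stop_config("batch_size must be >= 2")
  if (beta < 0) stop_config("beta must be >= 0")
  if (eta < 0 || eta > 1) stop_config("eta must lie in [0, 1]")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 momentum = momentum, beta = beta, eta = eta,
                 l1_mean_pairs = l1_mean_pairs, loss_mode = loss_mode,
                 grad_clip = grad_clip,
                 eta_warmup_epochs = as.integer(eta_warmup_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param ... Overrides passed to [train_config()].
#' @export
tiny_train_config <- function(...) {
  base <- list(epochs = 30L, batch_size = 32L, lr = 0.04,
               lr_decay_factor = 0.5, lr_decay_every = 15L,
               l1_mean_pairs = TRUE, eta_warmup_epochs = 5L)
  do.call(train_config, utils::modifyList(base, list(...)))
}

#' Pairwise similarity labels from class labels
#'
#' `s_ij = 1` when labels `i` and `j` agree, else 0; symmetric with unit
#' diagonal.
#'
#' @param batch_labels Vector of class labels (any comparable type).
#' @return An `n x n` 0/1 matrix.
#' @export
make_pair_labels <- function(batch_labels) {
  if (!length(batch_labels)) stop_config("batch_labels must be non-empty")
  outer(batch_labels, batch_labels, "==") * 1
}

#' Learning rate at a given epoch
#'
#' Step decay: `lr * factor^floor((epoch - 1) / every)`.
#'
#' @param cfg A [train_config()].
#' @param epoch Epoch number in `1..cfg$epochs`.
#' @return The learning rate in force during that epoch.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (any(epoch < 1) || any(epoch > cfg$epochs))
    stop_config("epoch out of range")
  cfg$lr * cfg$lr_decay_factor^floor((epoch - 1) / cfg$lr_decay_every)
}

# momentum-SGD update of one parameter set; velocities kept in a parallel list
sgd_step <- function(params, grads, vel, lr, mom) {
  for (nm in c("W", "b")) {
    vel[[nm]] <- mom * vel[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + vel[[nm]]
  }
  list(params = params, vel = vel)
}

zero_like <- function(p) list(W = p$W * 0, b = p$b * 0)

# rescale the whole gradient so its global L2 norm is at most `clip`
clip_grads <- function(g, clip) {
  if (!is.finite(clip) || clip <= 0) return(g)
  flat <- c(lapply(g$conv, `[[`, "W"), lapply(g$conv, `[[`, "b"),
            lapply(g$fc, `[[`, "W"), lapply(g$fc, `[[`, "b"),
            list(g$hash$W, g$hash$b, g$cls$W, g$cls$b))
  nrm <- sqrt(sum(vapply(flat, function(x) sum(x^2), 0)))
  if (!is.finite(nrm)) stop_numerical("non-finite gradient")
  if (nrm <= clip) return(g)
  s <- clip / nrm
  g$conv <- lapply(g$conv, function(p) list(W = p$W * s, b = p$b * s))
  g$fc <- lapply(g$fc, function(p) list(W = p$W * s, b = p$b * s))
  g$hash <- list(W = g$hash$W * s, b = g$hash$b * s)
  g$cls <- list(W = g$cls$W * s, b = g$cls$b * s)
  g
}

# core SGD loop over preloaded image batches
train_net <- function(net, images, y, cfg, verbose = FALSE) {
  n <- length(images)
  if (!n) stop_data("empty training split")
  set.seed(cfg$seed)
  # per-channel standardization statistics from the training images
  Xall <- prepare_stack(net, images)
  for (ch in 1:3) {
    v <- Xall[, , ch, ]
    net$norm$mean[ch] <- mean(v)
    net$norm$sd[ch] <- max(stats::sd(v), 1e-6)
    Xall[, , ch, ] <- (v - net$norm$mean[ch]) / net$norm$sd[ch]
  }
  vel <- list(conv = lapply(net$conv, zero_like),
              fc = lapply(net$fc, zero_like),
              hash = zero_like(net$hash), cls = zero_like(net$cls))
  warmup <- if (cfg$loss_mode == "L3") cfg$eta_warmup_epochs else 0L
  hist <- data.frame(epoch = integer(), l1 = numeric(), l2 = numeric(),
                     l3 = numeric(), lr = numeric())
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, ep)
    eta_ep <- if (warmup > 0L && ep <= warmup)
      cfg$eta * (ep - 1) / warmup else cfg$eta
    wu <- switch(cfg$loss_mode, L3 = eta_ep, L1 = 1, L2 = 0)
    wz <- switch(cfg$loss_mode, L3 = 1 - eta_ep, L1 = 0, L2 = 1)
    ord <- sample(n)
    sums <- c(l1 = 0, l2 = 0, l3 = 0); nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      if (length(idx) < 2L) next     # pair loss needs at least two samples
      X <- Xall[, , , idx, drop = FALSE]
      yb <- y[idx]
      fw <- forward_net(net, X, train = TRUE, keep = TRUE)
      Bc <- binarize(fw$u)
      S <- make_pair_labels(yb)
      l1c <- pairwise_likelihood_loss(fw$u, Bc, S, cfg$beta, cfg$l1_mean_pairs)
      gc <- grad_classification(fw$u, yb, net$cls$W, net$cls$b)
      l3 <- combined_loss(l1c$loss, gc$loss, eta_ep)
      if (!is.finite(l3))
        stop_numerical(sprintf("non-finite loss at epoch %d, batch %d", ep, nb + 1L))
      dU <- if (wu > 0)
        wu * grad_pairwise(fw$u, Bc, S, cfg$beta, cfg$l1_mean_pairs)
      else matrix(0, net$K, length(idx))
      dZ <- wz * gc$dZ
      g <- backward_net(net, fw$cache, dU, dZ)
      g <- clip_grads(g, cfg$grad_clip)
      for (i in seq_along(net$conv)) {
        st <- sgd_step(net$conv[[i]][c("W", "b")], g$conv[[i]], vel$conv[[i]], lr, cfg$momentum)
        net$conv[[i]]$W <- st$params$W; net$conv[[i]]$b <- st$params$b
        vel$conv[[i]] <- st$vel
      }
      for (i in seq_along(net$fc)) {
        st <- sgd_step(net$fc[[i]], g$fc[[i]], vel$fc[[i]], lr, cfg$momentum)
        net$fc[[i]] <- st$params; vel$fc[[i]] <- st$vel
      }
      st <- sgd_step(net$hash, g$hash, vel$hash, lr, cfg$momentum)
      net$hash <- st$params; vel$hash <- st$vel
      if (wz > 0) {
        st <- sgd_step(net$cls, g$cls, vel$cls, lr, cfg$momentum)
        net$cls <- st$params; vel$cls <- st$vel
      }
      sums <- sums + c(l1c$loss, gc$loss, l3); nb <- nb + 1L
    }
    hist <- rbind(hist, data.frame(epoch = ep, l1 = sums[["l1"]] / nb,
                                   l2 = sums[["l2"]] / nb,
                                   l3 = sums[["l3"]] / nb, lr = lr))
    if (verbose) message(sprintf("epoch %3d  L1 %.4f  L2 %.4f  L3 %.4f  lr %.4g",
                                 ep, hist$l1[ep], hist$l2[ep], hist$l3[ep], lr))
  }
  list(net = net, history = hist)
}

# resize + stack without standardization (stats computed afterwards)
prepare_stack <- function(net, images) {
  s <- net$backbone$input_size
  X <- array(0, c(s, s, 3L, length(images)))
  for (i in seq_along(images)) X[, , , i] <- resize_image(images[[i]], s, s)
  X
}

load_images <- function(records, size = NULL) {
  lapply(seq_len(nrow(records)), function(i)
    load_record_image(records[i, ], size))
}

#' Fit a DHCNN retrieval model
#'
#' Trains the network on the training records of a manifest by minibatch SGD
#' on the combined objective: the pairwise-likelihood/quantization loss on the
#' relaxed codes, the softmax cross-entropy of the classifier head, weighted
#' by `eta`. Per batch, binary targets are recomputed as `binarize(u)` and
#' treated as constants (the sign function has zero gradient; training
#' backpropagates through the relaxed codes only).
#'
#' @param records Manifest data frame (see [generate_dataset()]); if a
#'   `split` column marks `"train"` rows only those are used, otherwise all.
#' @param K Hash code length in bits.
#' @param backbone A [backbone_config()] or its name.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `"dhcnn"`: the trained network, the class-name
#'   vector, the per-epoch `history` (`epoch,l1,l2,l3,lr`), and the
#'   configuration. Methods: `print`, `summary`, `coef`, `predict`, `plot`.
#' @export
dhcnn <- function(records, K = 16L, backbone = backbone_config("tiny"),
                  config = tiny_train_config(), verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  records <- ensure_record_cols(records)
  if ("train" %in% records$split) records <- records[records$split == "train", ]
  if (!nrow(records)) stop_data("no training records")
  classes <- sort(unique(records$label))
  if (length(classes) < 2) stop_data("training data must contain >= 2 classes")
  if (is.character(backbone)) backbone <- backbone_config(backbone)
  net <- build_model(backbone, K = K, C = length(classes), seed = config$seed)
  images <- load_images(records, backbone$input_size)
  y <- match(records$label, classes)
  fit <- train_net(net, images, y, config, verbose = verbose)
  structure(list(net = fit$net, classes = classes, history = fit$history,
                 config = config, K = as.integer(K), C = length(classes),
                 n_train = nrow(records), call = match.call()),
            class = "dhcnn")
}

#' @export
print.dhcnn <- function(x, ...) {
  cat("DHCNN retrieval model\n")
  cat("  backbone:", x$net$backbone$name, " K:", x$K, "bits  classes:", x$C, "\n")
  cat("  trained on", x$n_train, "images for", nrow(x$history), "epochs\n")
  h <- x$history
  cat(sprintf("  final losses: L1 %.4f  L2 %.4f  L3 %.4f\n",
              h$l1[nrow(h)], h$l2[nrow(h)], h$l3[nrow(h)]))
  invisible(x)
}

#' @export
summary.dhcnn <- function(object, ...) {
  h <- object$history
  s <- list(backbone = object$net$backbone$name, K = object$K, C = object$C,
            n_train = object$n_train, epochs = nrow(h),
            first_l3 = h$l3[1], final_l3 = h$l3[nrow(h)],
            final_lr = h$lr[nrow(h)],
            n_params = sum(vapply(c(object$net$conv, object$net$fc,
                                    list(object$net$hash, object$net$cls)),
                                  function(p) length(p$W) + length(p$b), 0)))
  class(s) <- "summary.dhcnn"
  s
}

#' @export
print.summary.dhcnn <- function(x, ...) {
  cat("DHCNN model summary\n")
  cat("  backbone:", x$backbone, " hash bits:", x$K, " classes:", x$C, "\n")
  cat("  parameters:", format(x$n_params, big.mark = ","), "\n")
  cat(sprintf("  trained %d epochs on %d images; L3 %.4f -> %.4f (lr end %.4g)\n",
              x$epochs, x$n_train, x$first_l3, x$final_l3, x$final_lr))
  invisible(x)
}

#' @export
coef.dhcnn <- function(object, ...) {
  list(W_h = object$net$hash$W, V_h = object$net$hash$b,
       W_s = object$net$cls$W, v_s = object$net$cls$b)
}

#' @export
plot.dhcnn <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$l3, type = "l", xlab = "epoch", ylab = "loss",
       main = "DHCNN training losses", ylim = range(c(h$l1, h$l2, h$l3)), ...)
  graphics::lines(h$epoch, h$l1, lty = 2)
  graphics::lines(h$epoch, h$l2, lty = 3)
  graphics::legend("topright", legend = c("L3", "L1", "L2"), lty = 1:3, bty = "n")
  invisible(x)
}

#' Predict from a fitted DHCNN
#'
#' @param object A fitted [dhcnn()] model.
#' @param newdata A manifest data frame, a list of RGB arrays, or a single
#'   RGB array.
#' @param type `"class"` (predicted class names), `"index"` (1-based class
#'   indices), `"prob"` (`C x n` class distributions), `"code"` (`K x n`
#'   binary hash codes), `"relaxed"` (`K x n` relaxed codes) or `"feature"`
#'   (deep features).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @export
predict.dhcnn <- function(object, newdata,
                          type = c("class", "index", "prob", "code",
                                   "relaxed", "feature"),
                          batch_size = 64L, ...) {
  type <- match.arg(type)
  images <- if (is.data.frame(newdata)) {
    load_images(newdata, object$net$backbone$input_size)
  } else if (is.list(newdata)) newdata
  else list(newdata)
  out <- NULL
  for (start in seq(1, length(images), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(images))
    X <- prepare_batch(object$net, images[idx])
    fw <- forward_net(object$net, X, train = FALSE, keep = FALSE)
    piece <- switch(type,
      class = , index = predict_class(fw$p),
      prob = fw$p, code = binarize(fw$u), relaxed = fw$u, feature = fw$f)
    out <- if (is.null(out)) piece
    else if (is.matrix(piece)) cbind(out, piece) else c(out, piece)
  }
  if (type == "class") object$classes[out] else out
}
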