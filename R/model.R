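# The DHCNN network: convolutional backbone -> feature head -> hash layer ->
# sign binarization, plus a softmax classifier head on the relaxed codes.
# Forward and backward passes are implemented here directly (im2col/GEMM
# convolutions with compiled gather/scatter kernels); stride-1 convolutions
# and 2x2 max pooling cover both registered backbones.

#' Backbone configurations
#'
#' `"paper_vgg11"` is the full VGG-11-style layout: eight stride-1 3x3
#' convolution blocks (64, 128, 256, 256, 512, 512, 512, 512 filters; local
#' response normalization after the first; 2x2 max pooling after blocks 1, 2,
#' 4, 6, 8), two 4096-unit fully connected layers with dropout, 224x224 RGB
#' input. `"tiny"` is a three-block desk-scale variant (16, 32, 64 filters,
#' pooling after each, one 128-unit feature layer, 32x32 input, no dropout).
#'
#' @param name `"tiny"` or `"paper_vgg11"`.
#' @param input_size Input side length override.
#' @param dropout_rate Dropout rate on the fully connected feature layers.
#' @return An object of class `"backbone_config"` with elements
#'   `conv_blocks` (list of `filters`, `kernel`, `stride`, `pad`, `pool`,
#'   `lrn`), `fc_dims`, `dropout_rate`, `input_size`.
#' @export
backbone_config <- function(name = c("tiny", "paper_vgg11"),
                            input_size = NULL, dropout_rate = NULL) {
  name <- match.arg(name)
  blk <- function(f, pool, lrn = FALSE)
    list(filters = f, kernel = 3L, stride = 1L, pad = 1L, pool = pool, lrn = lrn)
  cfg <- if (name == "tiny") {
    list(name = name,
         conv_blocks = list(blk(16L, TRUE), blk(32L, TRUE), blk(64L, TRUE)),
         fc_dims = 128L, dropout_rate = 0, input_size = 32L)
  } else {
    list(name = name,
         conv_blocks = list(blk(64L, TRUE, lrn = TRUE), blk(128L, TRUE),
                            blk(256L, FALSE), blk(256L, TRUE),
                            blk(512L, FALSE), blk(512L, TRUE),
                            blk(512L, FALSE), blk(512L, TRUE)),
         fc_dims = c(4096L, 4096L), dropout_rate = 0.5, input_size = 224L)
  }
  if (!is.null(input_size)) cfg$input_size <- as.integer(input_size)
  if (!is.null(dropout_rate)) {
    if (dropout_rate < 0 || dropout_rate >= 1)
      stop_config("dropout_rate must lie in [0, 1)")
    cfg$dropout_rate <- dropout_rate
  }
  cfg$lrn <- list(n = 5L, alpha = 1e-4, beta = 0.75, k = 2)
  structure(cfg, class = "backbone_config")
}

# spatial size after the conv stack; validates pooling divisibility
conv_out_size <- function(backbone) {
  s <- backbone$input_size
  for (b in backbone$conv_blocks) {
    if (b$stride != 1L) stop_config("only stride-1 convolutions are supported")
    s <- s + 2L * b$pad - b$kernel + 1L
    if (b$pool) {
      if (s %% 2L != 0L) stop_config("feature map size must be even before pooling")
      s <- s %/% 2L
    }
  }
  if (s < 1L) stop_config("input_size too small for this conv stack")
  s
}

#' Build an untrained DHCNN network
#'
#' Allocates and initializes all parameters (He initialization for the
#' convolution and feature layers; small sd-0.01 Gaussians for the hash and
#' classifier heads so relaxed codes start near zero). Initialization is
#' deterministic given `seed`.
#'
#' @param backbone A [backbone_config()] (or a name passed to it).
#' @param K Hash code length in bits.
#' @param C Number of classes (>= 2).
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `"dhcnn_net"` whose forward pass produces the
#'   deep feature, the relaxed code and the class distribution for a batch.
#' @export
build_model <- function(backbone = backbone_config("tiny"), K = 16L, C,
                        seed = 1L) {
  if (is.character(backbone)) backbone <- backbone_config(backbone)
  stopifnot(inherits(backbone, "backbone_config"))
  if (K < 1) stop_config("K must be a positive integer")
  if (missing(C) || C < 2) stop_config("C must be >= 2")
  set.seed(as.integer(seed))
  cin <- 3L
  conv <- lapply(backbone$conv_blocks, function(b) {
    fan <- b$kernel^2 * cin
    W <- matrix(rnorm(b$filters * fan, 0, sqrt(2 / fan)), b$filters, fan)
    cin <<- b$filters
    list(W = W, b = numeric(b$filters), k = b$kernel, pad = b$pad,
         pool = b$pool, lrn = b$lrn)
  })
  s <- conv_out_size(backbone)
  din <- s * s * cin
  fc <- lapply(backbone$fc_dims, function(dout) {
    W <- matrix(rnorm(dout * din, 0, sqrt(2 / din)), dout, din)
    l <- list(W = W, b = numeric(dout))
    din <<- dout
    l
  })
  feat_dim <- din
  # heads start small so relaxed codes begin near zero and grow under the
  # quantization pull rather than saturating the pairwise likelihood at once
  hash <- list(W = matrix(rnorm(K * feat_dim, 0, 0.01), K, feat_dim),
               b = numeric(K))
  cls <- list(W = matrix(rnorm(C * K, 0, 0.01), as.integer(C), K),
              b = numeric(C))
  structure(list(backbone = backbone, K = as.integer(K), C = as.integer(C),
                 conv = conv, fc = fc, hash = hash, cls = cls,
                 feat_dim = feat_dim,
                 norm = list(mean = rep(0.5, 3), sd = rep(0.25, 3)),
                 env = new.env(parent = emptyenv())),
            class = "dhcnn_net")
}

#' @export
print.dhcnn_net <- function(x, ...) {
  cat("DHCNN network (", x$backbone$name, " backbone)\n", sep = "")
  cat("  conv blocks:", paste(vapply(x$conv, function(b) nrow(b$W), 0L),
                              collapse = "-"), "\n")
  cat("  feature dim:", x$feat_dim, " hash bits:", x$K, " classes:", x$C, "\n")
  invisible(x)
}

# ---- layer primitives ------------------------------------------------------

# cached im2col gather indices for (layer geometry, batch size)
conv_indices <- function(env, key, H, W, Cin, k, pad, B) {
  hit <- env[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- H + 2L * pad - k + 1L; Wo <- W + 2L * pad - k + 1L
  off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+"))
  off <- as.vector(outer(off, (0:(Cin - 1L)) * Hp * Wp, "+"))
  base <- as.vector(outer(1:Ho, (0:(Wo - 1L)) * Hp, "+"))
  idx <- outer(off, base, "+")
  npix <- Hp * Wp * Cin
  bigidx <- as.integer(outer(as.vector(idx), (0:(B - 1L)) * npix, "+"))
  res <- list(bigidx = bigidx, rows = k * k * Cin, Ho = Ho, Wo = Wo,
              Hp = Hp, Wp = Wp, npix = npix)
  env[[key]] <- res
  res
}

pad_batch <- function(X, pad) {
  if (pad == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  Xp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), , ] <- X
  Xp
}

mp_forward <- function(X) {
  d <- dim(X); h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  dim(X) <- c(2L, h2, 2L, w2, d[3], d[4])
  sl <- function(i, j) {
    z <- X[i, , j, , , , drop = FALSE]
    dim(z) <- c(h2, w2, d[3], d[4])
    z
  }
  s1 <- sl(1L, 1L); s2 <- sl(2L, 1L); s3 <- sl(1L, 2L); s4 <- sl(2L, 2L)
  y <- pmax(s1, s2, s3, s4)
  m1 <- s1 == y
  m2 <- s2 == y & !m1
  m3 <- s3 == y & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(y = y, masks = list(m1, m2, m3, m4), d = d)
}

mp_backward <- function(dY, cache) {
  d <- cache$d; h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  dX <- array(0, c(2L, h2, 2L, w2, d[3], d[4]))
  dX[1L, , 1L, , , ] <- dY * cache$masks[[1]]
  dX[2L, , 1L, , , ] <- dY * cache$masks[[2]]
  dX[1L, , 2L, , , ] <- dY * cache$masks[[3]]
  dX[2L, , 2L, , , ] <- dY * cache$masks[[4]]
  dim(dX) <- d
  dX
}

# local response normalization across channels
lrn_forward <- function(X, p) {
  d <- dim(X); C <- d[3]
  half <- p$n %/% 2L
  S <- array(0, d)
  X2 <- X * X
  for (o in (-half):half) {
    src <- intersect(seq_len(C), seq_len(C) - o)
    S[, , src + o, ] <- S[, , src + o, , drop = FALSE] + X2[, , src, , drop = FALSE]
  }
  den <- p$k + (p$alpha / p$n) * S
  y <- X * den^(-p$beta)
  list(y = y, den = den)
}

lrn_backward <- function(dY, X, cache, p) {
  den <- cache$den
  d <- dim(X); C <- d[3]; half <- p$n %/% 2L
  G <- dY * X * den^(-p$beta - 1)
  T <- array(0, d)
  for (o in (-half):half) {
    src <- intersect(seq_len(C), seq_len(C) - o)
    T[, , src + o, ] <- T[, , src + o, , drop = FALSE] + G[, , src, , drop = FALSE]
  }
  dY * den^(-p$beta) - (2 * p$alpha * p$beta / p$n) * X * T
}

# ---- forward / backward ----------------------------------------------------

# X: input batch array (H, W, 3, B), already standardized.
forward_net <- function(net, X, train = FALSE, keep = FALSE) {
  B <- dim(X)[4]
  caches <- if (keep) vector("list", length(net$conv))
  for (i in seq_along(net$conv)) {
    ly <- net$conv[[i]]
    d <- dim(X)
    key <- sprintf("c%d_%d", i, B)
    ci <- conv_indices(net$env, key, d[1], d[2], d[3], ly$k, ly$pad, B)
    Xp <- pad_batch(X, ly$pad)
    Xcol <- matrix(lh_gather(as.vector(Xp), ci$bigidx), nrow = ci$rows)
    Y <- ly$W %*% Xcol + ly$b
    dim(Y) <- c(nrow(ly$W), ci$Ho, ci$Wo, B)
    Y <- aperm(Y, c(2, 3, 1, 4))
    relu_mask <- Y > 0
    Y <- Y * relu_mask
    lrn_c <- NULL
    if (ly$lrn) {
      pre_lrn <- Y
      lrn_c <- lrn_forward(Y, net$backbone$lrn)
      Y <- lrn_c$y
    }
    pool_c <- NULL
    if (ly$pool) {
      pool_c <- mp_forward(Y)
      Y <- pool_c$y
    }
    if (keep) {
      caches[[i]] <- list(Xcol = Xcol, relu_mask = relu_mask,
                          lrn = lrn_c, pre_lrn = if (ly$lrn) pre_lrn,
                          pool = pool_c, in_dim = d, ci = ci)
    }
    X <- Y
  }
  conv_out_dim <- dim(X)
  dim(X) <- c(prod(conv_out_dim[1:3]), B)
  fc_caches <- if (keep) vector("list", length(net$fc))
  p_drop <- net$backbone$dropout_rate
  for (i in seq_along(net$fc)) {
    ly <- net$fc[[i]]
    H <- ly$W %*% X + ly$b
    mask <- H > 0
    A <- H * mask
    dmask <- NULL
    if (train && p_drop > 0) {
      dmask <- matrix(runif(length(A)) >= p_drop, nrow(A), ncol(A)) / (1 - p_drop)
      A <- A * dmask
    }
    if (keep) fc_caches[[i]] <- list(X = X, relu_mask = mask, dmask = dmask)
    X <- A
  }
  f <- X
  u <- net$hash$W %*% f + net$hash$b
  z <- net$cls$W %*% u + net$cls$b
  p <- softmax_cols(z)
  list(f = f, u = u, z = z, p = p,
       cache = if (keep) list(conv = caches, fc = fc_caches,
                              conv_out_dim = conv_out_dim, f = f, u = u))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# dU: gradient on the relaxed codes (K x B); dZ: gradient on the classifier
# logits (C x B). Returns parameter gradients mirroring the net structure.
backward_net <- function(net, cache, dU, dZ) {
  u <- cache$u; f <- cache$f
  g_cls <- list(W = dZ %*% t(u), b = rowSums(dZ))
  dU_all <- dU + t(net$cls$W) %*% dZ
  g_hash <- list(W = dU_all %*% t(f), b = rowSums(dU_all))
  dX <- t(net$hash$W) %*% dU_all
  g_fc <- vector("list", length(net$fc))
  for (i in rev(seq_along(net$fc))) {
    cc <- cache$fc[[i]]
    if (!is.null(cc$dmask)) dX <- dX * cc$dmask
    dH <- dX * cc$relu_mask
    g_fc[[i]] <- list(W = dH %*% t(cc$X), b = rowSums(dH))
    dX <- t(net$fc[[i]]$W) %*% dH
  }
  d4 <- cache$conv_out_dim
  dim(dX) <- d4
  g_conv <- vector("list", length(net$conv))
  for (i in rev(seq_along(net$conv))) {
    ly <- net$conv[[i]]; cc <- cache$conv[[i]]
    if (!is.null(cc$pool)) dX <- mp_backward(dX, cc$pool)
    if (!is.null(cc$lrn)) dX <- lrn_backward(dX, cc$pre_lrn, cc$lrn, net$backbone$lrn)
    dX <- dX * cc$relu_mask
    B <- dim(dX)[4]
    dYm <- aperm(dX, c(3, 1, 2, 4))
    dim(dYm) <- c(nrow(ly$W), cc$ci$Ho * cc$ci$Wo * B)
    g_conv[[i]] <- list(W = tcrossprod(dYm, cc$Xcol), b = rowSums(dYm))
    if (i > 1L) {
      dXcol <- crossprod(ly$W, dYm)
      dXp <- lh_scatter_add(cc$ci$npix * B, cc$ci$bigidx, as.vector(dXcol))
      dim(dXp) <- c(cc$ci$Hp, cc$ci$Wp, cc$in_dim[3], B)
      pad <- ly$pad
      dX <- if (pad > 0L)
        dXp[(pad + 1L):(pad + cc$in_dim[1]), (pad + 1L):(pad + cc$in_dim[2]), , ,
            drop = FALSE]
      else dXp
    }
  }
  list(conv = g_conv, fc = g_fc, hash = g_hash, cls = g_cls)
}

# stack records into a standardized input batch
prepare_batch <- function(net, images) {
  s <- net$backbone$input_size
  B <- length(images)
  X <- array(0, c(s, s, 3L, B))
  for (i in seq_len(B)) X[, , , i] <- resize_image(images[[i]], s, s)
  for (ch in 1:3)
    X[, , ch, ] <- (X[, , ch, ] - net$norm$mean[ch]) / net$norm$sd[ch]
  X
}

# ---- exported operations on codes ------------------------------------------

#' Hash layer: affine map from deep features to relaxed codes
#'
#' Computes `u = W_h f + V_h`.
#'
#' @param f Deep feature vector, or matrix with one feature per column.
#' @param W_h `K x feature_dim` weight matrix.
#' @param V_h Length-`K` bias vector.
#' @return The relaxed code(s), same shape convention as `f`.
#' @export
hash_features <- function(f, W_h, V_h) {
  f <- as.matrix(f)
  if (nrow(f) != ncol(W_h))
    stop_config("feature dimension does not match hash layer weights")
  if (length(V_h) != nrow(W_h))
    stop_config("bias length does not match hash layer weights")
  u <- W_h %*% f + V_h
  if (ncol(u) == 1L) drop(u) else u
}

#' Sign binarization of relaxed codes
#'
#' Elementwise sign with the convention `sign(0) = +1`, mapping relaxed codes
#' to \{-1, +1\} hash codes. (Many sign implementations return 0 at 0; the
#' boundary here is deliberately assigned to +1.)
#'
#' @param u Numeric vector, matrix or array of relaxed code values.
#' @return Same shape as `u`, entries in \{-1, +1\}.
#' @export
binarize <- function(u) {
  if (any(!is.finite(u))) stop_numerical("non-finite values in relaxed code")
  out <- ifelse(u >= 0, 1, -1)
  if (!is.null(dim(u))) dim(out) <- dim(u)
  out
}

#' Predicted class from a class distribution
#'
#' Index of the maximal probability; ties break to the lowest index.
#'
#' @param t Probability vector, or matrix with one distribution per column.
#' @return Integer class index (1-based), or a vector of them.
#' @export
predict_class <- function(t) {
  if (is.matrix(t)) return(apply(t, 2, which.max))
  which.max(t)
}
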