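# The training objective: L1 (pairwise likelihood over relaxed-code inner
# products plus a quantization penalty), L2 (softmax cross-entropy on the
# relaxed codes) and their convex combination L3, which is the minimized
# objective. The pairwise term uses psi_ij = 0.5 * u_i' u_j over all
# unordered within-batch pairs i < j (diagonal excluded).

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

as_code_matrix <- function(U) {
  if (is.list(U)) U <- do.call(cbind, U)
  if (is.vector(U)) U <- matrix(U, ncol = 1)
  U
}

#' Pairwise likelihood + quantization loss (L1)
#'
#' For relaxed codes `u_i` and pair labels `s_ij` (1 = same class), the
#' likelihood term is `sum_{i<j} softplus(psi_ij) - s_ij * psi_ij` with
#' `psi_ij = 0.5 * u_i' u_j`, i.e. the negative log-likelihood of the
#' observed pair labels under a logistic model of code inner products. The
#' quantization term `sum_i ||u_i - b_i||^2` pulls each relaxed code toward
#' its binary target `b_i`. The softplus form is numerically stable for
#' `|psi|` up to at least 1e4.
#'
#' @param U Relaxed codes: `K x N` matrix, a list of length-`K` vectors, or a
#'   single vector.
#' @param B Binary codes (same layout); defaults to `binarize(U)`.
#' @param S `N x N` 0/1 similarity matrix (see [make_pair_labels()]).
#' @param beta Weight of the quantization term (>= 0).
#' @param mean_pairs If `TRUE`, the whole loss (likelihood and quantization
#'   terms alike) is divided by the number of pairs, decoupling the loss
#'   scale from the batch size while preserving the summed form's internal
#'   balance. Off by default (plain sums, the form as printed).
#' @return List with `loss`, `likelihood_term`, `quantization_term`
#'   (`loss = likelihood_term + beta * quantization_term` after any
#'   normalization).
#' @export
pairwise_likelihood_loss <- function(U, B = NULL, S = NULL, beta = 1,
                                     mean_pairs = FALSE) {
  U <- as_code_matrix(U)
  if (is.null(B)) B <- binarize(U) else B <- as_code_matrix(B)
  n <- ncol(U)
  if (!identical(dim(U), dim(B)))
    stop_config("U and B must have identical dimensions")
  if (is.null(S)) S <- diag(n)
  S <- as.matrix(S)
  if (nrow(S) != n || ncol(S) != n)
    stop_config("similarity matrix does not match the number of codes")
  lik <- 0
  npairs <- n * (n - 1) / 2
  if (n >= 2) {
    Psi <- crossprod(U) / 2
    up <- upper.tri(Psi)
    lik <- sum(softplus(Psi[up]) - S[up] * Psi[up])
  }
  quant <- sum((U - B)^2)
  scl <- if (mean_pairs && npairs > 0) npairs else 1
  list(loss = (lik + beta * quant) / scl, likelihood_term = lik / scl,
       quantization_term = quant / scl)
}

# gradient of L1 w.r.t. U; b treated as a constant target (stop-gradient
# through the sign function)
grad_pairwise <- function(U, B, S, beta, mean_pairs = FALSE) {
  n <- ncol(U)
  scl <- if (mean_pairs && n >= 2) n * (n - 1) / 2 else 1
  dU <- 2 * beta * (U - B) / scl
  if (n >= 2) {
    Psi <- crossprod(U) / 2
    A <- 1 / (1 + exp(-Psi)) - S
    diag(A) <- 0
    dU <- dU + (U %*% A) / (2 * scl)
  }
  dU
}

#' Cross-entropy classification loss (L2)
#'
#' Mean negative log-likelihood of the true classes under
#' `softmax(W_s u + v_s)` applied to the relaxed codes.
#'
#' @param U Relaxed codes (`K x N` matrix, list, or vector).
#' @param labels Integer class indices of length `N`, or a one-hot `C x N`
#'   matrix.
#' @param W_s `C x K` classifier weights.
#' @param v_s Length-`C` classifier bias.
#' @return The scalar loss.
#' @export
classification_loss <- function(U, labels, W_s, v_s) {
  U <- as_code_matrix(U)
  n <- ncol(U)
  y <- labels_to_indices(labels, nrow(W_s), n)
  z <- W_s %*% U + v_s
  z <- sweep(z, 2, apply(z, 2, max))
  logp <- sweep(z, 2, log(colSums(exp(z))))
  -mean(logp[cbind(y, seq_len(n))])
}

labels_to_indices <- function(labels, C, n) {
  if (is.matrix(labels)) {
    if (ncol(labels) != n || nrow(labels) != C)
      stop_data("one-hot label matrix has wrong shape")
    ok <- apply(labels, 2, function(col)
      sum(col == 1) == 1 && all(col %in% c(0, 1)))
    if (!all(ok)) stop_data("labels must be one-hot vectors")
    return(apply(labels, 2, which.max))
  }
  y <- as.integer(labels)
  if (length(y) != n || any(y < 1) || any(y > C))
    stop_data("label indices out of range")
  y
}

# gradient of L2 w.r.t. logits and the classifier parameters
grad_classification <- function(U, y, W_s, v_s) {
  n <- ncol(U)
  z <- W_s %*% U + v_s
  P <- softmax_cols(z)
  Y <- matrix(0, nrow(W_s), n)
  Y[cbind(y, seq_len(n))] <- 1
  dZ <- (P - Y) / n
  loss <- -mean(log(pmax(P[cbind(y, seq_len(n))], 1e-300)))
  list(dZ = dZ, probs = P, loss = loss)
}

#' Combined loss (L3)
#'
#' The convex combination `L3 = eta * L1 + (1 - eta) * L2`; `eta = 0` keeps
#' only the label information, `eta = 1` only the pairwise similarity
#' information.
#'
#' @param l1,l2 Component loss values.
#' @param eta Balance weight in `[0, 1]`.
#' @return The combined scalar loss.
#' @export
combined_loss <- function(l1, l2, eta) {
  if (!is.numeric(eta) || eta < 0 || eta > 1)
    stop_config("eta must lie in [0, 1]")
  eta * l1 + (1 - eta) * l2
}
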