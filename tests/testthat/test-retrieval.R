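test_that("hamming_distance counts differing positions", {
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)
  expect_equal(hamming_distance(a, a), 0L)
  expect_equal(hamming_distance(a, b), 2L)
  expect_equal(hamming_distance(rep(1, 16), rep(-1, 16)), 16L)
  # (K - a.b)/2 identity for +/-1 codes
  expect_equal(hamming_distance(a, b), (length(a) - sum(a * b)) / 2)
  expect_error(hamming_distance(a, b[1:3]), class = "leafhash_config_error")
})

test_that("Hamming distance satisfies the metric axioms on all 4-bit codes", {
  codes <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  D <- hamming_distances(t(codes), t(codes))
  expect_true(all(diag(D) == 0))
  expect_identical(D, t(D))
  n <- nrow(codes)
  for (i in seq_len(n)) for (k in seq_len(n))
    expect_true(all(D[i, ] + D[, k] >= D[i, k]))
})

test_that("the packed popcount path equals the naive positionwise oracle", {
  set.seed(17)
  for (K in c(16, 31, 33, 64)) {
    db <- binarize(matrix(rnorm(K * 200), K, 200))
    q <- binarize(matrix(rnorm(K * 40), K, 40))
    packed <- hamming_distances(q, db, method = "packed")
    naive <- hamming_distances(q, db, method = "naive")
    expect_identical(packed, naive)
    # identical rankings, not just distances
    expect_identical(apply(packed, 1, order), apply(naive, 1, order))
  }
})

test_that("encoding a database yields one coherent entry per record", {
  fit <- quick_fit()
  db <- encode_database(fit$model, fit$split$train)
  n <- nrow(fit$split$train)
  expect_equal(length(db$ids), n)
  expect_equal(dim(db$codes), c(16L, n))
  expect_true(all(db$codes %in% c(-1, 1)))
  expect_equal(dim(db$distributions), c(3L, n))
  expect_equal(colSums(db$distributions), rep(1, n), tolerance = 1e-9)
  # deterministic re-encoding
  db2 <- encode_database(fit$model, fit$split$train)
  expect_identical(db$codes, db2$codes)
  # code equals sign of the hash layer output (checked via the affine map)
  f <- predict(fit$model, fit$split$train[1, ], type = "feature")
  u <- hash_features(f, coef(fit$model)$W_h, coef(fit$model)$V_h)
  expect_equal(unname(db$codes[, 1]), unname(binarize(u)))
})

test_that("a fabricated feature encodes by sign of the affine map", {
  u <- hash_features(c(0.2, -0.1), diag(2), c(0, 0))
  expect_equal(binarize(u), c(1, -1))
})

test_that("retrieve ranks by distance with ascending-id tie-breaks", {
  # hand-set codes with distances (0, 1, 1, 3, 2) from the query
  q <- rep(1, 4)
  codes <- cbind(c(1, 1, 1, 1), c(-1, 1, 1, 1), c(1, -1, 1, 1),
                 c(-1, -1, -1, 1), c(-1, -1, 1, 1))
  db <- hand_db(codes, predicted = rep(1L, 5), true_labels = rep(1L, 5))
  res <- retrieve(list(code = q, predicted = 1L, label = 1L), db = db, k = 5,
                  mode = "hash_only")
  expect_equal(res$ranked_ids, c(1L, 2L, 3L, 5L, 4L))
  expect_equal(res$distances, c(0L, 1L, 1L, 2L, 3L))
  expect_true(all(res$relevant_flags))
  expect_error(retrieve(list(code = q, predicted = 1L), db = db, k = 9),
               class = "leafhash_config_error")
})

test_that("class_then_hash ranks the predicted-class stratum first", {
  q <- rep(1, 4)
  codes <- cbind(c(-1, -1, -1, 1),   # distance 3, same predicted class
                 c(-1, 1, 1, 1))     # distance 1, other class
  db <- hand_db(codes, predicted = c(1L, 2L), true_labels = c(1L, 2L))
  res <- retrieve(list(code = q, predicted = 1L, label = 1L), db = db, k = 2,
                  mode = "class_then_hash")
  expect_equal(res$ranked_ids, c(1L, 2L))
  res2 <- retrieve(list(code = q, predicted = 1L, label = 1L), db = db, k = 2,
                   mode = "hash_only")
  expect_equal(res2$ranked_ids, c(2L, 1L))
})

test_that("both modes agree when the classifier is perfect and classes code-separated", {
  # class 1 near (+1,+1,+1,+1), class 2 near the antipode; queries classified
  # correctly -> stratification cannot change the distance ordering
  codes <- cbind(c(1, 1, 1, 1), c(1, 1, 1, -1), c(-1, -1, -1, -1),
                 c(-1, -1, -1, 1))
  truth <- c(1L, 1L, 2L, 2L)
  db <- hand_db(codes, predicted = truth, true_labels = truth)
  for (qi in 1:4) {
    q <- list(code = codes[, qi], predicted = truth[qi], label = truth[qi])
    r1 <- retrieve(q, db = db, k = 4, mode = "hash_only")
    r2 <- retrieve(q, db = db, k = 4, mode = "class_then_hash")
    expect_identical(r1$ranked_ids, r2$ranked_ids)
  }
})

test_that("code databases round-trip through the binary and CSV formats", {
  fit <- quick_fit()
  db <- encode_database(fit$model, fit$split$test)
  bin <- file.path(tempdir(), "codes_test.bin")
  write_code_db(db, bin)
  back <- read_code_db(bin)
  expect_identical(back$codes, db$codes)
  expect_identical(back$predicted, db$predicted)
  expect_identical(back$true_labels, db$true_labels)
  expect_equal(back$distributions, db$distributions, tolerance = 1e-12)
  expect_identical(back$classes, db$classes)
  csv <- file.path(tempdir(), "codes_test.csv")
  export_code_db_csv(db, csv)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), length(db$ids))
  expect_equal(names(tab), c("id", "label_pred", "label_true", "code_hex"))
})
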