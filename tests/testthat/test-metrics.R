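test_that("confusion-count metrics follow their definitions", {
  expect_equal(precision(confusion_counts(9, 1, 0)), 0.9)
  expect_equal(precision(confusion_counts(5, 0, 2)), 1)
  expect_equal(precision(confusion_counts(398, 2, 0)), 0.995)
  expect_equal(recall(confusion_counts(797, 0, 3)), 0.99625)
  expect_equal(recall(confusion_counts(10, 3, 0)), 1)
  c1 <- confusion_counts(9966, 0, 34)
  expect_equal(recall(c1), 0.9966)
  expect_equal(fnr(c1), 0.0034, tolerance = 1e-12)
  expect_equal(fnr(c1) + recall(c1), 1)
  expect_error(precision(confusion_counts(0, 0, 5)),
               class = "leafhash_undefined_metric")
  expect_error(recall(confusion_counts(0, 5, 0)),
               class = "leafhash_undefined_metric")
})

test_that("f_score is the harmonic mean", {
  expect_equal(round(f_score(0.9950, 0.9966), 5), 0.99580)
  expect_equal(f_score(0.8, 0.8), 0.8)
  expect_equal(f_score(1, 0.5), 2 / 3)
  expect_error(f_score(0, 0), class = "leafhash_undefined_metric")
})

test_that("average precision matches enumerated cases", {
  expect_equal(average_precision(c(TRUE, TRUE, TRUE)), 1)
  expect_equal(average_precision(c(FALSE, TRUE)), 0.5)
  expect_equal(average_precision(c(TRUE, FALSE, TRUE)), (1 + 2 / 3) / 2)
  expect_equal(average_precision(c(FALSE, FALSE)), 0)
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), cutoff = 2), 1)
})

test_that("average precision agrees with a brute-force oracle on all 6-flag vectors", {
  brute_ap <- function(flags) {
    # explicit loop over ranks, no vectorized shortcuts
    hits <- 0; total <- 0
    for (r in seq_along(flags)) {
      if (flags[r]) {
        hits <- hits + 1
        total <- total + hits / r
      }
    }
    if (hits == 0) 0 else total / hits
  }
  grids <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  for (i in seq_len(nrow(grids))) {
    flags <- unlist(grids[i, ])
    expect_equal(average_precision(flags), brute_ap(flags))
  }
})

test_that("MAP averages over queries or classes as requested", {
  flags <- list(c(TRUE, TRUE), c(FALSE, TRUE), c(FALSE, TRUE))
  expect_equal(mean_average_precision(flags[1:2]), 0.75)
  expect_equal(mean_average_precision(list(c(TRUE), c(TRUE))), 1)
  # 2 classes: APs {1} and {0.5, 0.5}
  expect_equal(mean_average_precision(flags, mode = "class",
                                      query_classes = c(1, 2, 2)), 0.75)
  expect_equal(mean_average_precision(flags, mode = "query"), 2 / 3)
  # the two modes coincide under equal per-class query counts and equal APs
  fl <- list(c(TRUE), c(TRUE), c(FALSE, TRUE), c(FALSE, TRUE))
  expect_equal(mean_average_precision(fl, mode = "query"),
               mean_average_precision(fl, mode = "class",
                                      query_classes = c(1, 2, 1, 2)))
})

test_that("precision@k and recall@k curves match direct counting", {
  cv <- topk_curves(list(c(TRUE, FALSE, TRUE, FALSE)), max_k = 4,
                    total_relevant = 2)
  expect_equal(cv$precision, c(1, 0.5, 2 / 3, 0.5))
  expect_equal(cv$recall, c(0.5, 0.5, 1, 1))
  # recall@k is non-decreasing; with every relevant item retrievable it ends at 1
  set.seed(23)
  for (i in 1:5) {
    flags <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    flags[1] <- TRUE
    cv <- topk_curves(list(flags), total_relevant = sum(flags))
    expect_true(all(diff(cv$recall) >= -1e-12))
    expect_equal(cv$recall[20], 1)
  }
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting", {
  mw_auc <- function(scores, pos) {
    s1 <- scores[pos]; s0 <- scores[!pos]
    cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  expect_equal(roc_auc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))$auc, 0.5)
  expect_equal(roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  set.seed(29)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    scores <- sample(0:15, n, replace = TRUE)   # heavy ties, like Hamming
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(roc_auc(scores, pos)$auc, mw_auc(scores, pos),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)),
               class = "leafhash_undefined_metric")
})

test_that("evaluate_retrieval populates a coherent report on a constructed fixture", {
  # two separable classes; every query code sits on its class corner
  K <- 8
  c1 <- rep(1, K); c2 <- rep(-1, K)
  flip <- function(v, i) { v[i] <- -v[i]; v }
  db <- hand_db(cbind(c1, flip(c1, 1), flip(c1, 2), c2, flip(c2, 1), flip(c2, 2)),
                predicted = c(1L, 1L, 1L, 2L, 2L, 2L),
                true_labels = c(1L, 1L, 1L, 2L, 2L, 2L))
  qs <- hand_db(cbind(c1, c2), predicted = c(1L, 2L), true_labels = c(1L, 2L))
  rep <- evaluate_retrieval(db, qs, cutoffs = c(3L))
  expect_equal(rep$map, 1)
  expect_equal(rep$map_at$map_at_3, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall_tpr, 1)
  expect_equal(rep$fnr, 0)
  expect_equal(rep$fscore, 1)
  expect_equal(rep$auc, 1)
  expect_equal(rep$r_precision, c(1, 1))
  d <- file.path(tempdir(), "report_out")
  write_metrics_report(rep, d)
  expect_true(file.exists(file.path(d, "metrics.json")))
  js <- jsonlite::read_json(file.path(d, "metrics.json"))
  expect_equal(js$map, 1)
  expect_true(file.exists(file.path(d, "curves.csv")))
})
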