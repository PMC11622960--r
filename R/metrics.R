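# Retrieval evaluation: confusion-count metrics, average precision and MAP,
# precision/recall-at-k curves, and ROC/AUC over (query, database item)
# decisions scored by negative Hamming distance. Undefined metrics raise a
# structured error rather than silently returning zero.

#' Confusion counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `"confusion_counts"`.
#' @export
confusion_counts <- function(tp, fp, fn, tn = 0) {
  if (any(c(tp, fp, fn, tn) < 0)) stop_data("confusion counts must be >= 0")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' Precision, recall/TPR, FNR and F-score
#'
#' `precision = TP/(TP+FP)`, `recall = TPR = TP/(TP+FN)`,
#' `FNR = 1 - TPR`, `f_score = 2 P R / (P + R)`. Degenerate denominators
#' raise a `leafhash_undefined_metric` error.
#'
#' @param c A [confusion_counts()].
#' @param p,r Precision and recall values for `f_score()`.
#' @return A numeric scalar in `[0, 1]`.
#' @export
precision <- function(c) {
  if (c$tp + c$fp == 0) stop_undefined_metric("precision undefined: TP + FP = 0")
  c$tp / (c$tp + c$fp)
}

#' @rdname precision
#' @export
recall <- function(c) {
  if (c$tp + c$fn == 0) stop_undefined_metric("recall undefined: TP + FN = 0")
  c$tp / (c$tp + c$fn)
}

#' @rdname precision
#' @export
fnr <- function(c) 1 - recall(c)

#' @rdname precision
#' @export
f_score <- function(p, r) {
  if (p + r == 0) stop_undefined_metric("F-score undefined: precision + recall = 0")
  2 * p * r / (p + r)
}

#' Average precision of one ranked result
#'
#' Mean, over the relevant ranks `r` within the cutoff, of the precision at
#' `r` (`relevant-in-top-r / r`). A result with no relevant item within the
#' cutoff has AP 0 by convention.
#'
#' @param flags Logical relevance flags in rank order (or a
#'   `"retrieval_result"`).
#' @param cutoff Truncation rank (default: full list).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(flags, cutoff = Inf) {
  if (inherits(flags, "retrieval_result")) flags <- flags$relevant_flags
  flags <- as.logical(flags)
  if (!length(flags)) stop_data("empty result")
  flags <- flags[seq_len(min(length(flags), cutoff))]
  rel <- which(flags)
  if (!length(rel)) return(0)
  mean(cumsum(flags)[rel] / rel)
}

#' Mean average precision over queries or classes
#'
#' Query mode (default, the retrieval-literature convention behind MAP@k)
#' averages AP over queries; class mode first averages AP within each query
#' class and then across classes.
#'
#' @param flag_list List of per-query relevance flag vectors (or
#'   `"retrieval_result"`s).
#' @param cutoff Truncation rank.
#' @param mode `"query"` or `"class"`.
#' @param query_classes Class label per query (required for class mode).
#' @return MAP in `[0, 1]`.
#' @export
mean_average_precision <- function(flag_list, cutoff = Inf,
                                   mode = c("query", "class"),
                                   query_classes = NULL) {
  mode <- match.arg(mode)
  if (!length(flag_list)) stop_data("no queries")
  aps <- vapply(flag_list, average_precision, 0, cutoff = cutoff)
  if (mode == "query") return(mean(aps))
  if (is.null(query_classes)) stop_config("class mode needs query_classes")
  mean(vapply(split(aps, query_classes), mean, 0))
}

#' Precision@k and recall@k curves
#'
#' `precision@k` is the mean over queries of relevant-in-top-k / k;
#' `recall@k` divides by each query's total number of relevant database
#' items.
#'
#' @param flag_list List of per-query relevance flags over the full ranking.
#' @param max_k Largest k of the curve.
#' @param total_relevant Per-query totals of relevant items (default: counted
#'   from the full flags).
#' @return Data frame `k, precision, recall`.
#' @export
topk_curves <- function(flag_list, max_k = NULL, total_relevant = NULL) {
  if (!length(flag_list)) stop_data("no queries")
  nmin <- min(lengths(flag_list))
  max_k <- min(max_k %||% nmin, nmin)
  if (is.null(total_relevant))
    total_relevant <- vapply(flag_list, sum, 0)
  cums <- vapply(flag_list, function(f) cumsum(f)[seq_len(max_k)],
                 numeric(max_k))
  cums <- matrix(cums, nrow = max_k)
  prec <- rowMeans(cums / seq_len(max_k))
  rec <- rowMeans(sweep(cums, 2, pmax(total_relevant, 1), "/"))
  data.frame(k = seq_len(max_k), precision = prec, recall = rec)
}

#' ROC curve and AUC from scored binary decisions
#'
#' Sweeps thresholds over all distinct scores, plots TPR against FPR and
#' integrates by the trapezoidal rule (equivalent to Mann-Whitney pair
#' counting with ties scored 1/2).
#'
#' @param scores Numeric decision scores (higher = more positive).
#' @param positive Logical truth per score.
#' @return List with `curve` (data frame `fpr, tpr`) and `auc`.
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  P <- sum(positive); N <- sum(!positive)
  if (P == 0 || N == 0)
    stop_undefined_metric("ROC needs at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  grp_end <- c(which(diff(s) != 0), length(s))   # last index of each tie group
  tp <- cumsum(y)[grp_end]; fp <- cumsum(!y)[grp_end]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate retrieval quality of a model on encoded query / database sets
#'
#' Ranks every query against the database (see [retrieve()] for the ranking
#' modes), then reports: MAP (query mode) and MAP@`cutoffs`; precision@k /
#' recall@k curves; ROC/AUC over all (query, item) pairs scored by negative
#' Hamming distance; and scalar precision / recall / FNR / F-score taken at
#' the R-precision operating point — each query's ranking truncated at its
#' own number of relevant database items, where precision and recall
#' coincide — averaged over queries.
#'
#' @param db Database [encode_database()] result.
#' @param queries Query-set [encode_database()] result (true labels needed).
#' @param mode Ranking mode, `"class_then_hash"` or `"hash_only"`.
#' @param cutoffs Integer vector of MAP@k cutoffs.
#' @param max_k Largest k of the precision/recall curves (default: database
#'   size).
#' @return An object of class `"metrics_report"`.
#' @export
evaluate_retrieval <- function(db, queries, mode = c("class_then_hash", "hash_only"),
                               cutoffs = c(5L, 10L), max_k = NULL) {
  mode <- match.arg(mode)
  if (any(is.na(queries$true_labels)))
    stop_data("query records need ground-truth labels for evaluation")
  rk <- rank_all(queries, db, mode)
  nq <- length(queries$ids)
  flags <- lapply(seq_len(nq), function(i)
    db$true_labels[rk$orders[[i]]] == queries$true_labels[i])
  total_rel <- vapply(seq_len(nq), function(i)
    sum(db$true_labels == queries$true_labels[i]), 0)
  map <- mean_average_precision(flags)
  map_at <- setNames(vapply(cutoffs, function(k)
    mean_average_precision(flags, cutoff = k), 0), paste0("map_at_", cutoffs))
  curves <- topk_curves(flags, max_k = max_k %||% length(db$ids),
                        total_relevant = total_rel)
  pos <- as.vector(outer(queries$true_labels, db$true_labels, "=="))
  roc <- roc_auc(-as.vector(rk$D), pos)
  # R-precision operating point: truncate each ranking at the query's own
  # relevant count, where precision and recall coincide
  rprec <- vapply(seq_len(nq), function(i) {
    R <- max(1, total_rel[i])
    sum(flags[[i]][seq_len(min(R, length(flags[[i]])))]) / R
  }, 0)
  prec <- mean(rprec)
  rec <- prec
  structure(list(precision = prec, recall_tpr = rec, fnr = 1 - rec,
                 fscore = f_score(prec, rec), map = map, map_at = as.list(map_at),
                 auc = roc$auc,
                 precision_at_k = curves$precision, recall_at_k = curves$recall,
                 pr_curve = curves[, c("precision", "recall")],
                 roc_curve = roc$curve, curves = curves,
                 r_precision = rprec,
                 n_queries = nq, n_db = length(db$ids), mode = mode),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Retrieval metrics (", x$n_queries, " queries vs ", x$n_db,
      " database items, mode ", x$mode, ")\n", sep = "")
  cat(sprintf("  precision %.4f  recall/TPR %.4f  FNR %.4f  F-score %.4f\n",
              x$precision, x$recall_tpr, x$fnr, x$fscore))
  cat(sprintf("  MAP %.4f  %s  AUC %.4f\n", x$map,
              paste(names(x$map_at), sprintf("%.4f", unlist(x$map_at)),
                    collapse = "  "), x$auc))
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Scalar metrics go to `metrics.json`; the @k curves to `curves.csv`
#' (`k,precision,recall`); the ROC curve to `roc.csv`.
#'
#' @param report A `"metrics_report"`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scal <- list(precision = report$precision, recall_tpr = report$recall_tpr,
               fnr = report$fnr, fscore = report$fscore, map = report$map,
               map_at = report$map_at, auc = report$auc,
               n_queries = report$n_queries, n_db = report$n_db,
               mode = report$mode)
  jsonlite::write_json(scal, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$curves, file.path(dir, "curves.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roc_curve, file.path(dir, "roc.csv"),
                   row.names = FALSE)
  invisible(dir)
}
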