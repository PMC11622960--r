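# Database encoding and Hamming-ranked retrieval. Codes are stored packed 31
# bits per integer word (R reserves the sign-bit pattern INT_MIN as NA, so
# the sign bit is never used) and compared with a popcount kernel; the packed
# fast path is bit-exact against the naive positionwise count.

#' Pack / compare binary hash codes
#'
#' `pack_codes()` packs a `K x n` matrix over \{-1,+1\} into integer words
#' (31 bits per word, +1 mapping to a set bit). `hamming_distance()` counts
#' differing positions of two codes; `hamming_distances()` returns the full
#' query-by-database distance matrix, by default through the packed popcount
#' kernel (`method = "naive"` is the positionwise reference oracle).
#'
#' @param codes,a,b,query_codes,db_codes Codes over \{-1,+1\}; matrices hold
#'   one code per column.
#' @param method `"packed"` or `"naive"`.
#' @return `hamming_distance()`: integer; `hamming_distances()`: integer
#'   matrix `n_query x n_db`.
#' @export
pack_codes <- function(codes) {
  codes <- as_code_matrix(codes)
  K <- nrow(codes)
  words <- (K + 30L) %/% 31L
  out <- matrix(0L, words, ncol(codes))
  pow <- 2^(0:30)
  for (w in seq_len(words)) {
    lo <- (w - 1L) * 31L + 1L
    hi <- min(w * 31L, K)
    bits <- codes[lo:hi, , drop = FALSE] > 0
    out[w, ] <- as.integer(colSums(bits * pow[seq_len(hi - lo + 1L)]))
  }
  out
}

#' @rdname pack_codes
#' @export
hamming_distance <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (length(a) != length(b)) stop_config("codes must have equal length")
  sum(a != b)
}

#' @rdname pack_codes
#' @export
hamming_distances <- function(query_codes, db_codes,
                              method = c("packed", "naive")) {
  method <- match.arg(method)
  Q <- as_code_matrix(query_codes); D <- as_code_matrix(db_codes)
  if (nrow(Q) != nrow(D)) stop_config("codes must have equal length")
  if (method == "naive") {
    out <- matrix(0L, ncol(Q), ncol(D))
    for (i in seq_len(ncol(Q)))
      out[i, ] <- as.integer(colSums(D != Q[, i]))
    return(out)
  }
  lh_hamming_packed(pack_codes(Q), pack_codes(D))
}

#' Encode an image database for retrieval
#'
#' Runs every record through the trained model and stores, per record, the
#' binary hash code `b = sign(W_h f + V_h)`, the predicted class
#' `argmax_k t^k`, the full class distribution and the ground-truth label
#' (kept for evaluation only).
#'
#' @param model A fitted [dhcnn()].
#' @param records Manifest data frame of database images.
#' @param ids Optional stable integer identifiers (default `1:n`).
#' @param batch_size Forward-pass batch size.
#' @return An object of class `"code_db"`: list with `ids`, `codes`
#'   (`K x n`), `packed`, `predicted` (class indices), `distributions`
#'   (`C x n`), `true_labels` (class indices or `NA`), `K`, `C`, `classes`.
#' @export
encode_database <- function(model, records, ids = NULL, batch_size = 64L) {
  stopifnot(inherits(model, "dhcnn"))
  if (!nrow(records)) stop_data("no records to encode")
  probs <- predict(model, records, type = "prob", batch_size = batch_size)
  u <- predict(model, records, type = "relaxed", batch_size = batch_size)
  codes <- binarize(u)
  n <- ncol(codes)
  ids <- if (is.null(ids)) seq_len(n) else as.integer(ids)
  if (length(ids) != n) stop_config("ids length does not match record count")
  true <- if (!is.null(records$label)) match(records$label, model$classes)
  else rep(NA_integer_, n)
  structure(list(ids = ids, codes = codes, packed = pack_codes(codes),
                 predicted = as.integer(predict_class(probs)),
                 distributions = probs, true_labels = true,
                 K = model$K, C = model$C, classes = model$classes),
            class = "code_db")
}

#' @export
print.code_db <- function(x, ...) {
  cat("Hash code database:", length(x$ids), "items,", x$K, "bits,",
      x$C, "classes\n")
  invisible(x)
}

# build a code_db from parts (used by tests and the no-hash-layer ablation)
code_db_from_parts <- function(codes, predicted, true_labels,
                               distributions = NULL, classes = NULL,
                               ids = NULL) {
  codes <- as_code_matrix(codes)
  n <- ncol(codes)
  C <- max(c(predicted, true_labels), na.rm = TRUE)
  if (is.null(distributions)) {
    distributions <- matrix(0, C, n)
    distributions[cbind(predicted, seq_len(n))] <- 1
  }
  structure(list(ids = ids %||% seq_len(n), codes = codes,
                 packed = pack_codes(codes), predicted = as.integer(predicted),
                 distributions = distributions,
                 true_labels = as.integer(true_labels),
                 K = nrow(codes), C = C,
                 classes = classes %||% paste0("class", seq_len(C))),
            class = "code_db")
}

# ranking order for one query given its distances/predicted class:
# class_then_hash puts entries whose predicted label matches the query's
# predicted label first, then sorts by distance, then by ascending id.
rank_one <- function(dist, db, q_pred, mode) {
  if (mode == "class_then_hash") {
    mismatch <- as.integer(db$predicted != q_pred)
    order(mismatch, dist, db$ids)
  } else {
    order(dist, db$ids)
  }
}

#' Retrieve the top-k database images for a query
#'
#' Encodes the query with the same deterministic preprocessing as the
#' database, ranks all database entries, and returns the top `k`. In
#' `"hash_only"` mode ranking is by Hamming distance ascending; in
#' `"class_then_hash"` (the default) entries whose predicted class equals the
#' query's predicted class are ranked first (each stratum sorted by
#' distance). Ties break by ascending database id.
#'
#' @param query One manifest row, an RGB array, or a list
#'   `list(code =, predicted =, label =)` of a pre-encoded query.
#' @param model A fitted [dhcnn()] (unused when `query` is pre-encoded).
#' @param db A [encode_database()] result.
#' @param k Number of results, `1 <= k <=` database size.
#' @param mode `"class_then_hash"` or `"hash_only"`.
#' @return An object of class `"retrieval_result"`: `ranked_ids`,
#'   `distances`, `relevant_flags` (same true label as the query, when
#'   known), `query_label`, `query_pred`.
#' @export
retrieve <- function(query, model = NULL, db, k = 10L,
                     mode = c("class_then_hash", "hash_only")) {
  mode <- match.arg(mode)
  n <- length(db$ids)
  if (k < 1 || k > n) stop_config("k must lie between 1 and the database size")
  if (is.list(query) && !is.data.frame(query) && !is.null(query$code)) {
    q_code <- query$code; q_pred <- query$predicted
    q_label <- query$label %||% NA_integer_
  } else {
    if (is.null(model)) stop_config("model required to encode the query")
    nd <- if (is.data.frame(query)) query else list(query)
    q_code <- binarize(predict(model, nd, type = "relaxed"))
    q_pred <- as.integer(predict_class(predict(model, nd, type = "prob")))
    q_label <- if (is.data.frame(query) && !is.null(query$label))
      match(query$label, model$classes) else NA_integer_
  }
  dist <- as.integer(hamming_distances(q_code, db$codes))
  ord <- rank_one(dist, db, q_pred, mode)[seq_len(k)]
  structure(list(ranked_ids = db$ids[ord], distances = dist[ord],
                 relevant_flags = if (!is.na(q_label))
                   db$true_labels[ord] == q_label else rep(NA, k),
                 query_label = q_label, query_pred = q_pred, mode = mode),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat("Retrieval result: top", length(x$ranked_ids), "ids:",
      paste(utils::head(x$ranked_ids, 10), collapse = ", "),
      if (length(x$ranked_ids) > 10) "..." else "", "\n")
  invisible(x)
}

# rank every query of a query code_db against a database; returns the list of
# full ranking permutations plus the distance matrix (queries x db)
rank_all <- function(qdb, db, mode = "class_then_hash") {
  D <- hamming_distances(qdb$codes, db$codes)
  orders <- lapply(seq_len(nrow(D)), function(i)
    rank_one(D[i, ], db, qdb$predicted[i], mode))
  list(orders = orders, D = D)
}

# ---- serialization ---------------------------------------------------------

#' Save / load a code database
#'
#' Binary format: magic `"LHDB"`, version, K, n, C, then packed codes,
#' predicted labels, true labels (`NA` as -1), class distributions and class
#' names. `export_code_db_csv()` writes the human-readable
#' `id,label_pred,label_true,code_hex` form.
#'
#' @param db A `"code_db"`.
#' @param path Output file.
#' @return `read_code_db()` returns the `"code_db"`.
#' @export
write_code_db <- function(db, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("LHDB"), con)
  writeBin(c(1L, db$K, length(db$ids), db$C), con, size = 4L)
  writeBin(as.integer(db$packed), con, size = 4L)
  writeBin(as.integer(db$ids), con, size = 4L)
  writeBin(as.integer(db$predicted), con, size = 4L)
  tl <- db$true_labels; tl[is.na(tl)] <- -1L
  writeBin(as.integer(tl), con, size = 4L)
  writeBin(as.numeric(db$distributions), con, size = 8L)
  writeBin(paste(db$classes, collapse = "\n"), con)
  invisible(path)
}

#' @rdname write_code_db
#' @export
read_code_db <- function(path) {
  if (!file.exists(path)) stop_io(paste0("code database not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "LHDB")) stop_io("not a code database file")
  hdr <- readBin(con, "integer", 4L, size = 4L)
  K <- hdr[2]; n <- hdr[3]; C <- hdr[4]
  words <- (K + 30L) %/% 31L
  packed <- matrix(readBin(con, "integer", words * n, size = 4L), words, n)
  ids <- readBin(con, "integer", n, size = 4L)
  predicted <- readBin(con, "integer", n, size = 4L)
  true <- readBin(con, "integer", n, size = 4L)
  true[true == -1L] <- NA_integer_
  dists <- matrix(readBin(con, "numeric", C * n, size = 8L), C, n)
  classes <- strsplit(readBin(con, "character", 1L), "\n")[[1]]
  codes <- unpack_codes(packed, K)
  structure(list(ids = ids, codes = codes, packed = packed,
                 predicted = predicted, distributions = dists,
                 true_labels = true, K = K, C = C, classes = classes),
            class = "code_db")
}

unpack_codes <- function(packed, K) {
  n <- ncol(packed)
  out <- matrix(-1, K, n)
  for (bit in seq_len(K)) {
    w <- (bit - 1L) %/% 31L + 1L
    pos <- (bit - 1L) %% 31L
    set <- bitwAnd(bitwShiftR(packed[w, ], pos), 1L) == 1L
    out[bit, set] <- 1
  }
  out
}

#' @rdname write_code_db
#' @export
export_code_db_csv <- function(db, path) {
  hex <- apply(db$packed, 2, function(w) paste(sprintf("%08x", w), collapse = ""))
  utils::write.csv(data.frame(id = db$ids, label_pred = db$predicted,
                              label_true = db$true_labels, code_hex = hex),
                   path, row.names = FALSE)
  invisible(path)
}
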