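# Label-preserving augmentation operators and the class-balancing + splitting
# strategy. Balancing is bookkeeping over manifest records: augmented copies
# store their source path and a serialized operator chain, and pixels are
# materialized lazily by load_record_image().

AUG_OPS <- c("flip", "gamma", "noise", "pca_color", "rotate", "scale")

#' Augmentation operators
#'
#' `augmentation_op()` builds a fully parameterized operator;
#' `sample_augmentation_op()` draws parameters (and optionally the operator
#' name) from the package's standard label-preserving ranges using the current
#' RNG state:
#' flip axis in \{horizontal, vertical\}; gamma exponent in \[0.7, 1.5\];
#' zero-mean Gaussian noise with sd in \[2, 10\] on the 0-255 scale; PCA colour
#' shifts along the per-image RGB covariance eigenvectors with coefficients
#' `N(0, 0.1)`; rotation in \[-30, 30\] degrees with reflection padding; scale
#' factor in \[0.8, 1.2\] about the centre (crop / reflect-pad).
#'
#' @param name One of `"flip"`, `"gamma"`, `"noise"`, `"pca_color"`,
#'   `"rotate"`, `"scale"`, or `NULL` to sample one uniformly.
#' @param params Named list of operator parameters (`axis`, `exponent`, `sd`,
#'   `alpha`, `angle`, `factor` respectively).
#' @return An object of class `"augmentation_op"`.
#' @export
augmentation_op <- function(name, params = list()) {
  if (!is.character(name) || !(name %in% AUG_OPS))
    stop_config(paste0("unknown augmentation op: ", paste(name, collapse = ",")))
  defaults <- switch(name,
    flip = list(axis = "horizontal"),
    gamma = list(exponent = 1),
    noise = list(sd = 5),
    pca_color = list(alpha = c(0, 0, 0)),
    rotate = list(angle = 0),
    scale = list(factor = 1))
  structure(list(name = name, params = utils::modifyList(defaults, params)),
            class = "augmentation_op")
}

#' @rdname augmentation_op
#' @export
sample_augmentation_op <- function(name = NULL) {
  if (is.null(name)) name <- sample(AUG_OPS, 1)
  params <- switch(name,
    flip = list(axis = sample(c("horizontal", "vertical"), 1)),
    gamma = list(exponent = runif(1, 0.7, 1.5)),
    noise = list(sd = runif(1, 2, 10)),
    pca_color = list(alpha = rnorm(3, 0, 0.1)),
    rotate = list(angle = runif(1, -30, 30)),
    scale = list(factor = runif(1, 0.8, 1.2)))
  augmentation_op(name, params)
}

#' Apply one augmentation operator
#'
#' Deterministic given the operator's parameters; every operator maps an RGB
#' image in `[0,1]` to one of the same size and range.
#'
#' @param image RGB array `h x w x 3`.
#' @param op An [augmentation_op()].
#' @return The transformed image.
#' @export
apply_augmentation <- function(image, op) {
  if (!inherits(op, "augmentation_op")) {
    if (is.character(op)) op <- augmentation_op(op)
    else stop_config("op must be an augmentation_op")
  }
  p <- op$params
  out <- switch(op$name,
    flip = if (identical(p$axis, "vertical"))
      image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
    else image[, rev(seq_len(dim(image)[2])), , drop = FALSE],
    gamma = clip01(image)^p$exponent,
    noise = image + array(rnorm(length(image), 0, p$sd / 255), dim(image)),
    pca_color = {
      px <- matrix(image, ncol = 3)
      e <- eigen(stats::cov(px), symmetric = TRUE)
      shift <- as.numeric(e$vectors %*% (p$alpha * e$values))
      sweep(image, 3, shift, "+")
    },
    rotate = rotate_image(image, p$angle),
    scale = scale_image(image, p$factor))
  clip01(out)
}

# serialize / parse operator chains for manifest storage
ops_to_string <- function(ops) {
  paste(vapply(ops, function(op) {
    vals <- unlist(op$params)
    if (is.numeric(vals)) vals <- signif(vals, 8)
    paste0(op$name, "=", paste(vals, collapse = ","))
  }, ""), collapse = ";")
}

string_to_ops <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  lapply(strsplit(s, ";", fixed = TRUE)[[1]], function(tok) {
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    name <- kv[1]
    val <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
    params <- switch(name,
      flip = list(axis = val),
      gamma = list(exponent = as.numeric(val)),
      noise = list(sd = as.numeric(val)),
      pca_color = list(alpha = as.numeric(val)),
      rotate = list(angle = as.numeric(val)),
      scale = list(factor = as.numeric(val)))
    augmentation_op(name, params)
  })
}

# ensure manifest has the bookkeeping columns
ensure_record_cols <- function(records) {
  n <- nrow(records)
  if (is.null(records$split)) records$split <- rep("", n)
  if (is.null(records$source)) records$source <- rep("", n)
  if (is.null(records$ops)) records$ops <- rep("", n)
  if (is.null(records$augmented)) records$augmented <- rep(FALSE, n)
  records
}

#' Load the pixels of one manifest record
#'
#' Reads the record's image (or, for an augmented record, its source image,
#' to which the stored operator chain is applied) and resizes to `size` if
#' requested. Stochastic operators (noise) are replayed with a seed derived
#' from the record's stored chain, so materialization is deterministic.
#'
#' @param record One manifest row (data frame or list).
#' @param size Optional output side length.
#' @return RGB array in `[0,1]`.
#' @export
load_record_image <- function(record, size = NULL) {
  record <- as.list(record)
  aug <- isTRUE(record$augmented) || isTRUE(record$augmented == "TRUE")
  src <- if (aug && nzchar(record$source %||% "")) record$source else record$path
  img <- read_image(src)
  if (aug) {
    ops <- string_to_ops(record$ops %||% "")
    if (length(ops)) {
      # fixed replay seed so noise injection is reproducible per record
      set.seed(lh_child_seed(sum(utf8ToInt(record$ops)) %% 1000003L, 1L, 1L))
      for (op in ops) img <- apply_augmentation(img, op)
    }
  }
  if (!is.null(size)) img <- resize_image(img, size, size)
  img
}

#' Balance every class to a fixed image count
#'
#' Classes below `target_per_class` are topped up with augmented copies (a
#' uniformly chosen source record plus a random chain of 1-2 distinct
#' operators per copy); classes at or above the target are subsampled
#' uniformly without replacement, originals being preferred before any
#' augmented records already present. Pure bookkeeping: no pixels are touched
#' (see [load_record_image()]).
#'
#' @param records Manifest data frame with at least `path` and `label`.
#' @param target_per_class Desired per-class count (>= 1).
#' @return A manifest data frame with exactly `target_per_class` rows per
#'   class; augmented rows carry `source` and `ops`.
#' @export
balance_classes <- function(records, target_per_class) {
  if (target_per_class < 1) stop_config("target_per_class must be >= 1")
  records <- ensure_record_cols(records)
  if (any(is.na(records$label)) || !nrow(records))
    stop_data("records must be non-empty with labels")
  out <- lapply(split(records, records$label), function(cls) {
    n <- nrow(cls)
    if (n == 0L) stop_data("empty class in records")
    if (n == target_per_class) return(cls)
    if (n > target_per_class) {
      ord <- order(cls$augmented)          # originals first
      keep_pool <- cls[ord, ]
      n_orig <- sum(!cls$augmented)
      if (n_orig >= target_per_class)
        return(keep_pool[sort(sample(seq_len(n_orig), target_per_class)), ])
      extra <- sample(seq(n_orig + 1L, n), target_per_class - n_orig)
      return(keep_pool[c(seq_len(n_orig), sort(extra)), ])
    }
    deficit <- target_per_class - n
    src_idx <- sample(seq_len(n), deficit, replace = TRUE)
    aug <- cls[src_idx, ]
    aug$source <- ifelse(aug$augmented & nzchar(aug$source), aug$source, aug$path)
    aug$ops <- vapply(seq_len(deficit), function(i) {
      nops <- sample(1:2, 1)
      ops_to_string(lapply(sample(AUG_OPS, nops), sample_augmentation_op))
    }, "")
    aug$augmented <- TRUE
    aug$path <- sprintf("%s#aug%04d", aug$source, seq_len(deficit))
    rbind(cls, aug)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stratified train/test split
#'
#' Assigns each class's records to train/test with exactly
#' `floor(n_class * train_fraction)` training records per class, sampled
#' uniformly; no record appears in both splits.
#'
#' @param records Manifest data frame.
#' @param train_fraction Fraction of each class assigned to training, in (0,1).
#' @return An object of class `"balanced_split"`: list with `train`, `test`
#'   (manifest subsets), `per_class_counts` (data frame `label`, `n_train`,
#'   `n_test`) and `records` (full manifest with the `split` column filled).
#' @export
stratified_split <- function(records, train_fraction = 0.8) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction must lie in (0, 1)")
  records <- ensure_record_cols(records)
  sizes <- table(records$label)
  if (any(sizes < 2)) stop_data("every class needs at least 2 records to split")
  records$split <- ""
  for (lab in names(sizes)) {
    idx <- which(records$label == lab)
    n_tr <- floor(length(idx) * train_fraction)
    tr <- sample(idx, n_tr)
    records$split[tr] <- "train"
    records$split[setdiff(idx, tr)] <- "test"
  }
  counts <- aggregate(split ~ label, records,
                      function(s) c(sum(s == "train"), sum(s == "test")))
  per_class <- data.frame(label = counts$label,
                          n_train = counts$split[, 1],
                          n_test = counts$split[, 2],
                          stringsAsFactors = FALSE)
  structure(list(train = records[records$split == "train", ],
                 test = records[records$split == "test", ],
                 per_class_counts = per_class,
                 records = records),
            class = "balanced_split")
}

#' @export
print.balanced_split <- function(x, ...) {
  cat("Stratified split:", nrow(x$train), "train /", nrow(x$test), "test over",
      nrow(x$per_class_counts), "classes\n")
  invisible(x)
}

#' Balance-then-split pipeline
#'
#' Default protocol: top every class up to `target_per_class` on the full
#' pool, then split each class `train_fraction` / `1 - train_fraction`.
#' Because augmentation precedes splitting, augmented variants of one source
#' image may land in both splits; set `split_before_balance = TRUE` for the
#' leakage-free alternative, which splits the originals first and then
#' balances each side separately (train to `floor(target * fraction)`, test
#' to the remainder).
#'
#' @param records Manifest data frame of original records.
#' @param target_per_class Per-class count after balancing.
#' @param train_fraction Training fraction in (0, 1).
#' @param split_before_balance Use the leakage-free ordering.
#' @return A `"balanced_split"` (see [stratified_split()]).
#' @export
balance_and_split <- function(records, target_per_class = 1000,
                              train_fraction = 0.8,
                              split_before_balance = FALSE) {
  if (!split_before_balance) {
    return(stratified_split(balance_classes(records, target_per_class),
                            train_fraction))
  }
  sp <- stratified_split(records, train_fraction)
  n_tr <- floor(target_per_class * train_fraction)
  tr <- balance_classes(sp$train, n_tr)
  te <- balance_classes(sp$test, target_per_class - n_tr)
  tr$split <- "train"; te$split <- "test"
  all <- rbind(tr, te)
  counts <- aggregate(split ~ label, all,
                      function(s) c(sum(s == "train"), sum(s == "test")))
  structure(list(train = tr, test = te,
                 per_class_counts = data.frame(label = counts$label,
                                               n_train = counts$split[, 1],
                                               n_test = counts$split[, 2],
                                               stringsAsFactors = FALSE),
                 records = all),
            class = "balanced_split")
}
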