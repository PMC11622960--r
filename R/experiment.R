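# End-to-end experiment glue: dataset -> balance/split -> fit -> encode ->
# evaluate, plus the ablation grid over loss variants / hash layer / code
# lengths and the similarity stress sweep.

resolve_manifest <- function(dataset, data_dir = NULL) {
  if (inherits(dataset, "synth_config")) {
    dir <- data_dir %||% file.path(tempdir(),
                                   sprintf("lh_data_%d_%d", dataset$seed,
                                           dataset$n_classes))
    if (!file.exists(file.path(dir, "manifest.csv")))
      generate_dataset(dataset, dir)
    return(read_manifest(file.path(dir, "manifest.csv")))
  }
  if (is.character(dataset)) {
    p <- if (dir.exists(dataset)) file.path(dataset, "manifest.csv") else dataset
    return(read_manifest(p))
  }
  if (is.data.frame(dataset)) return(dataset)
  stop_config("dataset must be a synth_config, a manifest data frame, or a path")
}

#' Run one full retrieval experiment
#'
#' Generates or loads a dataset, balances and splits it, fits a [dhcnn()]
#' model on the training split, encodes the training split as the retrieval
#' database and the test split as queries, and evaluates. With `out_dir`
#' set, artifacts are written: `history.csv`, `run_config.yaml`, `codes.bin`
#' / `codes.csv`, and the metrics report.
#'
#' @param dataset A [synth_config()], a manifest data frame, or a path to a
#'   dataset directory / manifest CSV.
#' @param K Hash code length.
#' @param backbone [backbone_config()] or name.
#' @param config [train_config()].
#' @param target_per_class Balancing target (`NULL` = no balancing).
#' @param train_fraction Train share of each class.
#' @param split_before_balance Leakage-free ordering (see
#'   [balance_and_split()]).
#' @param mode Retrieval ranking mode.
#' @param cutoffs MAP@k cutoffs.
#' @param out_dir Optional artifact directory.
#' @param seed Seed for balancing/splitting (training uses `config$seed`).
#' @return List with `model`, `db`, `queries`, `report`, `split`, `manifest`.
#' @export
run_experiment <- function(dataset, K = 16L, backbone = backbone_config("tiny"),
                           config = tiny_train_config(),
                           target_per_class = NULL, train_fraction = 0.8,
                           split_before_balance = FALSE,
                           mode = c("class_then_hash", "hash_only"),
                           cutoffs = c(5L, 10L),
                           out_dir = NULL, seed = config$seed) {
  mode <- match.arg(mode)
  manifest <- resolve_manifest(dataset)
  set.seed(seed)
  split <- if (!is.null(target_per_class)) {
    balance_and_split(manifest, target_per_class, train_fraction,
                      split_before_balance)
  } else if (all(c("train", "test") %in% manifest$split)) {
    structure(list(train = manifest[manifest$split == "train", ],
                   test = manifest[manifest$split == "test", ],
                   per_class_counts = NULL, records = manifest),
              class = "balanced_split")
  } else {
    stratified_split(manifest, train_fraction)
  }
  model <- dhcnn(split$train, K = K, backbone = backbone, config = config)
  db <- encode_database(model, split$train)
  queries <- encode_database(model, split$test)
  report <- evaluate_retrieval(db, queries, mode = mode, cutoffs = cutoffs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(K = K, backbone = model$net$backbone$name,
                          config = unclass(config), mode = mode,
                          cutoffs = cutoffs, seed = seed),
                     file.path(out_dir, "run_config.yaml"))
    write_code_db(db, file.path(out_dir, "codes.bin"))
    export_code_db_csv(db, file.path(out_dir, "codes.csv"))
    write_metrics_report(report, out_dir)
    write_manifest(split$records, file.path(out_dir, "manifest_split.csv"))
  }
  list(model = model, db = db, queries = queries, report = report,
       split = split, manifest = manifest)
}

#' Ablation grid over backbone, hash layer, code length and loss
#'
#' Runs every grid cell on the same dataset and split (fixed by `seed`) and
#' tabulates the retrieval metrics. The "without hash layer" condition keeps
#' the trained backbone but replaces the learned codes by the sign of a
#' fixed Gaussian random projection of the deep features to `K` bits, ranked
#' in `hash_only` mode — isolating the learned hash layer's contribution at
#' comparable code length.
#'
#' @param grid Data frame with columns `backbone`, `hash_layer` (logical),
#'   `K`, `loss` (`"L1"`, `"L2"`, `"L3"`).
#' @param dataset As in [run_experiment()].
#' @param config Base [train_config()]; each cell overrides `loss_mode`.
#' @param mode Ranking mode for cells with a hash layer.
#' @param seed Split seed shared by all cells.
#' @param out_csv Optional path of the results CSV.
#' @return Data frame: one row per cell with `precision`, `recall`,
#'   `fscore`, `map`, `failed`.
#' @export
run_ablation <- function(grid, dataset, config = tiny_train_config(),
                         mode = "class_then_hash",
                         seed = config$seed, out_csv = NULL) {
  manifest <- resolve_manifest(dataset)
  set.seed(seed)
  split <- stratified_split(manifest, 0.8)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    res <- tryCatch({
      cfg <- do.call(train_config,
                     utils::modifyList(unclass(config),
                                       list(loss_mode = as.character(cell$loss))))
      model <- dhcnn(split$train, K = cell$K,
                     backbone = as.character(cell$backbone), config = cfg)
      if (isTRUE(cell$hash_layer)) {
        db <- encode_database(model, split$train)
        qdb <- encode_database(model, split$test)
        use_mode <- mode
      } else {
        fd <- predict(model, split$train, type = "feature")
        fq <- predict(model, split$test, type = "feature")
        proj_seed <- seed + malus_hash(cell$K)
        db <- code_db_from_parts(random_projection_codes(t(fd), cell$K, proj_seed),
                                 predicted = rep(1L, ncol(fd)),
                                 true_labels = match(split$train$label, model$classes),
                                 classes = model$classes)
        qdb <- code_db_from_parts(random_projection_codes(t(fq), cell$K, proj_seed),
                                  predicted = rep(1L, ncol(fq)),
                                  true_labels = match(split$test$label, model$classes),
                                  classes = model$classes)
        use_mode <- "hash_only"
      }
      rep <- evaluate_retrieval(db, qdb, mode = use_mode)
      data.frame(backbone = cell$backbone, hash_layer = cell$hash_layer,
                 K = cell$K, loss = cell$loss,
                 precision = rep$precision, recall = rep$recall_tpr,
                 fscore = rep$fscore, map = rep$map, failed = FALSE)
    }, error = function(e) {
      message("ablation cell ", i, " failed: ", conditionMessage(e))
      data.frame(backbone = cell$backbone, hash_layer = cell$hash_layer,
                 K = cell$K, loss = cell$loss,
                 precision = NA_real_, recall = NA_real_, fscore = NA_real_,
                 map = NA_real_, failed = TRUE)
    })
    res
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

# tiny deterministic offset so different-K projections differ
malus_hash <- function(k) as.integer(k) * 7L

#' Similarity stress sweep
#'
#' Measures how retrieval MAP degrades as the generator's inter-class
#' similarity dial rises: for each level, `n_runs` independent datasets are
#' generated (seeds `seed + run`), a model is trained on each, and the MAP
#' of test-split queries against the training database is recorded.
#'
#' @param levels Similarity levels in `[0, 1]`.
#' @param n_runs Replicate datasets per level.
#' @param n_classes,images_per_class,image_size Generator settings.
#' @param K Code length.
#' @param backbone [backbone_config()].
#' @param config [train_config()] template (its seed is replaced per run).
#' @param mode Ranking mode.
#' @param seed Base seed.
#' @return List with `runs` (level, run, map) and `means` (level, mean map).
#' @export
similarity_stress <- function(levels = c(0, 0.45, 0.9), n_runs = 10L,
                              n_classes = 4L, images_per_class = 36L,
                              image_size = 24L, K = 16L,
                              backbone = backbone_config("tiny", input_size = 24L),
                              config = tiny_train_config(epochs = 12L),
                              mode = "class_then_hash", seed = 1L) {
  rows <- list()
  for (lv in levels) {
    for (r in seq_len(n_runs)) {
      run_seed <- (seed + 131L * r + round(1000 * lv)) %% 2147483629L
      cfgd <- synth_config(n_classes, images_per_class, image_size,
                           similarity_level = lv, seed = run_seed)
      dir <- file.path(tempdir(), sprintf("lh_stress_%d_%d", round(100 * lv), r))
      on.exit(unlink(dir, recursive = TRUE), add = TRUE)
      manifest <- generate_dataset(cfgd, dir)
      cfg <- do.call(train_config,
                     utils::modifyList(unclass(config), list(seed = run_seed)))
      res <- run_experiment(manifest, K = K, backbone = backbone, config = cfg,
                            mode = mode, seed = run_seed)
      rows[[length(rows) + 1L]] <- data.frame(level = lv, run = r,
                                              map = res$report$map)
      unlink(dir, recursive = TRUE)
    }
  }
  runs <- do.call(rbind, rows)
  means <- aggregate(map ~ level, runs, mean)
  list(runs = runs, means = means)
}
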