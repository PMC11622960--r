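test_that("the simulate command writes a reproducible dataset", {
  out1 <- file.path(tempdir(), "cli_sim1")
  out2 <- file.path(tempdir(), "cli_sim2")
  unlink(c(out1, out2), recursive = TRUE)
  args <- c("simulate", "--classes", "2", "--per-class", "3", "--size", "16",
            "--seed", "4")
  expect_equal(dhcnn_cli(c(args, "--out", out1)), 0L)
  expect_equal(dhcnn_cli(c(args, "--out", out2)), 0L)
  m1 <- read_manifest(file.path(out1, "manifest.csv"))
  expect_equal(nrow(m1), 6L)
  expect_true("similarity_group" %in% names(m1))
  expect_identical(unname(tools::md5sum(sort(m1$path))),
                   unname(tools::md5sum(sort(read_manifest(
                     file.path(out2, "manifest.csv"))$path))))
})

test_that("the train/encode/query/evaluate pipeline runs end to end", {
  data_dir <- file.path(tempdir(), "cli_data")
  run_dir <- file.path(tempdir(), "cli_run")
  unlink(c(data_dir, run_dir), recursive = TRUE)
  expect_equal(dhcnn_cli(c("simulate", "--classes", "2", "--per-class", "12",
                           "--size", "24", "--seed", "6", "--out", data_dir)), 0L)
  expect_equal(dhcnn_cli(c("train", "--data", data_dir, "--out", run_dir,
                           "--k", "8", "--epochs", "3", "--batch", "8",
                           "--seed", "6")), 0L)
  expect_true(file.exists(file.path(run_dir, "model.rds")))
  expect_true(file.exists(file.path(run_dir, "history.csv")))
  expect_true(file.exists(file.path(run_dir, "run_config.yaml")))
  hist <- read.csv(file.path(run_dir, "history.csv"))
  expect_equal(names(hist), c("epoch", "l1", "l2", "l3", "lr"))
  expect_equal(nrow(hist), 3L)

  model_f <- file.path(run_dir, "model.rds")
  split_f <- file.path(run_dir, "manifest_split.csv")
  db_f <- file.path(run_dir, "train.db")
  q_f <- file.path(run_dir, "test.db")
  expect_equal(dhcnn_cli(c("encode", "--model", model_f, "--data", split_f,
                           "--split", "train", "--out", db_f)), 0L)
  expect_equal(dhcnn_cli(c("encode", "--model", model_f, "--data", split_f,
                           "--split", "test", "--out", q_f)), 0L)
  expect_true(file.exists(db_f))

  # query returns exactly k ids
  split <- read_manifest(split_f)
  qimg <- split$path[split$split == "test"][1]
  out <- capture.output(code <- dhcnn_cli(c("query", "--model", model_f,
                                            "--db", db_f, "--image", qimg,
                                            "--k", "10")))
  expect_equal(code, 0L)
  expect_equal(length(out) - 1L, 10L)   # header + 10 rows

  eval_dir <- file.path(run_dir, "eval")
  out2 <- capture.output(code2 <- dhcnn_cli(c("evaluate", "--db", db_f,
                                              "--queries", q_f,
                                              "--cutoffs", "5,10",
                                              "--out", eval_dir)))
  expect_equal(code2, 0L)
  js <- jsonlite::read_json(file.path(eval_dir, "metrics.json"))
  expect_named(js$map_at, c("map_at_5", "map_at_10"))
})

test_that("missing upstream artifacts give the documented exit codes", {
  expect_equal(suppressMessages(
    dhcnn_cli(c("train", "--data", "/nonexistent", "--out", tempdir()))), 5L)
  expect_equal(suppressMessages(
    dhcnn_cli(c("encode", "--model", "/nonexistent.rds", "--data", "x",
                "--out", "y"))), 5L)
  expect_equal(suppressMessages(dhcnn_cli("frobnicate")), 2L)
  expect_equal(suppressMessages(
    dhcnn_cli(c("simulate", "--classes", "1", "--out", tempdir()))), 2L)
})

test_that("a single-cell ablation grid yields one data row", {
  m <- tiny_dataset(n_classes = 2, per = 10, size = 24, seed = 601)
  grid <- data.frame(backbone = "tiny", hash_layer = TRUE, K = 8, loss = "L3",
                     stringsAsFactors = FALSE)
  csv <- file.path(tempdir(), "ablate_one.csv")
  res <- run_ablation(grid, m,
                      config = tiny_train_config(epochs = 2, batch_size = 8,
                                                 seed = 601),
                      seed = 601, out_csv = csv)
  expect_equal(nrow(res), 1L)
  expect_false(res$failed)
  tab <- read.csv(csv)
  expect_equal(names(tab), c("backbone", "hash_layer", "K", "loss",
                             "precision", "recall", "fscore", "map", "failed"))
})

test_that("run_experiment returns a populated report on a micro dataset", {
  m <- tiny_dataset(n_classes = 2, per = 10, size = 24, seed = 602)
  res <- run_experiment(m, K = 8,
                        backbone = backbone_config("tiny", input_size = 24),
                        config = tiny_train_config(epochs = 2, batch_size = 8,
                                                   seed = 602),
                        cutoffs = c(3L, 5L), seed = 602)
  r <- res$report
  for (field in c("precision", "recall_tpr", "fnr", "fscore", "map", "auc"))
    expect_true(is.finite(r[[field]]))
  expect_named(r$map_at, c("map_at_3", "map_at_5"))
  expect_s3_class(res$model, "dhcnn")
  expect_equal(length(res$db$ids), nrow(res$split$train))
})
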