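# Shared fixtures, generated in code and cached for the whole test run.

lh_test_cache <- new.env()

# small synthetic dataset on disk; cached by parameters
tiny_dataset <- function(n_classes = 3, per = 12, size = 24, sim = 0,
                         seed = 101) {
  key <- paste("ds", n_classes, per, size, sim * 100, seed, sep = "_")
  if (!is.null(lh_test_cache[[key]])) return(lh_test_cache[[key]])
  dir <- file.path(tempdir(), paste0("lhfix_", key))
  unlink(dir, recursive = TRUE)
  m <- generate_dataset(synth_config(n_classes, per, size, sim, seed), dir)
  lh_test_cache[[key]] <- m
  m
}

# a small fitted model shared by training/retrieval tests: three
# well-separated classes x 40 images, K = 16, 20 epochs
quick_fit <- function() {
  if (!is.null(lh_test_cache$fit)) return(lh_test_cache$fit)
  m <- tiny_dataset(n_classes = 3, per = 40, size = 24, sim = 0, seed = 301)
  set.seed(301)
  sp <- stratified_split(m, 0.8)
  model <- dhcnn(sp$train, K = 16,
                 backbone = backbone_config("tiny", input_size = 24),
                 config = tiny_train_config(epochs = 20, eta_warmup_epochs = 0,
                                            seed = 301))
  lh_test_cache$fit <- list(model = model, split = sp)
  lh_test_cache$fit
}

# smooth low-frequency test images (interpolation-error measurements)
smooth_test_image <- function(seed, size = 32) {
  set.seed(seed)
  g <- outer(seq(0, 1, length.out = size), seq(0, 1, length.out = size),
             function(x, y) 0.5 + 0.3 * sin(2 * pi * (runif(1) + x * runif(1, 0.5, 1.5))) *
               cos(2 * pi * y * runif(1, 0.5, 1.5)))
  array(c(g, 0.8 * g, 0.6 * g), c(size, size, 3))
}

# block-mean RGB features of a manifest's images (training-free encoder input)
block_features <- function(manifest, nb = 4) {
  t(sapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image(manifest$path[i])
    bs <- dim(img)[1] %/% nb
    as.vector(sapply(1:3, function(ch)
      sapply(0:(nb - 1), function(bi)
        sapply(0:(nb - 1), function(bj)
          mean(img[bi * bs + 1:bs, bj * bs + 1:bs, ch])))))
  }))
}

# hand-built code database from explicit parts
hand_db <- function(codes, predicted, true_labels, ...) {
  leafhash:::code_db_from_parts(codes, predicted, true_labels, ...)
}
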