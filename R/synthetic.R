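# Procedural leaf-disease image generator. Classes come in similarity groups:
# the two members of a group share lesion parameters up to a perturbation
# whose magnitude shrinks as similarity_level rises, which gives a
# controllable stand-in for visually confusable disease pairs.

#' Configuration for a synthetic leaf-disease dataset
#'
#' @param n_classes Number of classes (>= 2).
#' @param images_per_class Images generated per class (>= 1).
#' @param image_size Side length in pixels of the square RGB images.
#' @param similarity_level Real in `[0, 1]`: 0 gives well-separated classes,
#'   values near 1 make the two classes of each similarity group nearly
#'   identical (lesion shape, density and hue differ only marginally).
#' @param seed Integer seed; the dataset is a pure function of
#'   (configuration, seed) and regeneration is byte-identical.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(n_classes, images_per_class, image_size = 32,
                         similarity_level = 0, seed = 1L) {
  if (!is.numeric(n_classes) || n_classes < 2)
    stop_config("n_classes must be an integer >= 2")
  if (!is.numeric(images_per_class) || images_per_class < 1)
    stop_config("images_per_class must be >= 1")
  if (!is.numeric(similarity_level) || similarity_level < 0 || similarity_level > 1)
    stop_config("similarity_level must lie in [0, 1]")
  if (image_size < 8) stop_config("image_size must be at least 8 pixels")
  structure(list(n_classes = as.integer(n_classes),
                 images_per_class = as.integer(images_per_class),
                 image_size = as.integer(image_size),
                 similarity_level = as.numeric(similarity_level),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Per-class drawing specifications
#'
#' Expands a [synth_config()] into one specification row per class: leaf hue,
#' lesion shape/density/hue and the similarity group the class belongs to.
#' Classes are paired into groups; within a group the second class is a
#' perturbation of the first with magnitude proportional to
#' `1 - similarity_level`.
#'
#' @param config A [synth_config()].
#' @return A data frame with columns `class_id`, `name`, `base_hue`,
#'   `lesion_shape`, `lesion_density`, `lesion_hue`, `similarity_group`.
#' @export
class_specs <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_classes
  shapes <- c("spot", "blotch", "streak", "curl")
  d <- 1 - config$similarity_level        # perturbation magnitude
  # Per-class "target" parameters are evenly spread (the fully separated
  # layout); each class is interpolated between its group anchor (the
  # parameters of the group's first member) and its own target with weight
  # d. At similarity 0 the classes sit at the spread-out targets; as the
  # level rises, the two members of each group collapse onto the anchor.
  # Twins never stray more than half the inter-group spacing from their
  # anchor, so distinct groups stay separated at every level. Raising the
  # level also mildly compresses the overall hue spread (groups drift a
  # little closer together), so mean inter-class separation decreases
  # strictly with the dial rather than only within groups.
  squeeze <- 1 - 0.35 * config$similarity_level
  tgt_lhue <- (seq_len(n) - 1) * squeeze * 360 / n + 15 + runif(1, -5, 5)
  tgt_bhue <- 70 + (seq_len(n) - 1) * squeeze * 100 / n + runif(1, -4, 4)
  tgt_dens <- 3L + (seq_len(n) - 1L) %% 4L
  tgt_shape <- shapes[(seq_len(n) - 1L) %% 4L + 1L]
  specs <- lapply(seq_len(n), function(i) {
    g <- ceiling(i / 2)
    a <- 2L * g - 1L                     # anchor class of the group
    shape <- if (i != a && d <= 0.5) tgt_shape[a] else tgt_shape[i]
    data.frame(class_id = i,
               name = sprintf("class%02d", i),
               base_hue = (tgt_bhue[a] + d * (tgt_bhue[i] - tgt_bhue[a])) %% 360,
               lesion_shape = shape,
               lesion_density = as.integer(round(tgt_dens[a] +
                                                   d * (tgt_dens[i] - tgt_dens[a]))),
               lesion_hue = (tgt_lhue[a] + d * (tgt_lhue[i] - tgt_lhue[a])) %% 360,
               similarity_group = g,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, specs)
}

#' Draw one procedural leaf image
#'
#' Renders a leaf silhouette of the spec's base hue on a soil-like background
#' and stamps `lesion_density` lesion marks of the spec's shape and hue inside
#' it. Spot lesions are placed with a minimum-separation rejection rule so
#' that, before any residual overlap, each drawn primitive is a distinct
#' connected component. The result carries attributes `lesion_mask` (logical
#' matrix) and `n_lesions` (primitives drawn). Uses the current RNG state;
#' seed beforehand for reproducibility.
#'
#' @param spec One row of [class_specs()] (data frame or list with fields
#'   `base_hue`, `lesion_shape`, `lesion_density`, `lesion_hue`).
#' @param size Image side length in pixels.
#' @return An RGB array `size x size x 3` in `[0, 1]`.
#' @export
generate_leaf_image <- function(spec, size = 32) {
  spec <- as.list(spec)
  if (is.null(spec$lesion_density) || spec$lesion_density < 0)
    stop_config("lesion_density must be >= 0")
  h <- w <- as.integer(size)
  yg <- matrix(rep(seq_len(h) / h, w), h, w)
  xg <- matrix(rep(seq_len(w) / w, each = h), h, w)

  # background: mottled soil
  bg <- hue_rgb(30 + runif(1, -8, 8), 0.35, 0.25)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch] + matrix(rnorm(h * w, 0, 0.03), h, w)

  # leaf silhouette: rotated ellipse with jittered centre/radii
  ang <- runif(1, -25, 25) * pi / 180
  cx <- 0.5 + runif(1, -0.03, 0.03); cy <- 0.5 + runif(1, -0.03, 0.03)
  rx <- 0.40 + runif(1, -0.03, 0.03); ry <- 0.26 + runif(1, -0.03, 0.03)
  dx <- xg - cx; dy <- yg - cy
  ex <- (dx * cos(ang) + dy * sin(ang)) / rx
  ey <- (-dx * sin(ang) + dy * cos(ang)) / ry
  re <- sqrt(ex^2 + ey^2)
  leaf <- re <= 1

  leaf_col <- hue_rgb(spec$base_hue + runif(1, -8, 8),
                      0.60 + runif(1, 0, 0.12), 0.52 + runif(1, -0.06, 0.06))
  shade <- 1 - 0.3 * pmin(re, 1)          # darker toward the rim
  vein <- abs(ey) < 0.045 & abs(ex) < 0.92 # central vein
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[leaf] <- (leaf_col[ch] * shade)[leaf]
    plane[leaf & vein] <- plane[leaf & vein] * 0.75
    img[, , ch] <- plane
  }

  # lesions
  n_lesions <- as.integer(spec$lesion_density)
  mask <- matrix(FALSE, h, w)
  if (n_lesions > 0) {
    shape <- match.arg(spec$lesion_shape, c("spot", "blotch", "streak", "curl"))
    centers <- matrix(NA_real_, n_lesions, 2)
    placed <- 0L
    min_sep <- 0.13
    for (i in seq_len(n_lesions)) {
      for (try in 1:200) {
        t <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * 0.72
        if (shape == "curl") rr <- runif(1, 0.82, 0.95)
        px <- cx + (rr * cos(t) * rx) * cos(ang) - (rr * sin(t) * ry) * sin(ang)
        py <- cy + (rr * cos(t) * rx) * sin(ang) + (rr * sin(t) * ry) * cos(ang)
        ok <- placed == 0L || shape != "spot" ||
          all(sqrt((centers[seq_len(placed), 1] - px)^2 +
                   (centers[seq_len(placed), 2] - py)^2) >= min_sep)
        if (ok) break
      }
      placed <- placed + 1L
      centers[placed, ] <- c(px, py)
      ldx <- xg - px; ldy <- yg - py
      m <- switch(shape,
        spot = {
          r0 <- 0.035 + runif(1, 0, 0.012)
          ldx^2 + ldy^2 <= r0^2
        },
        blotch = {
          a2 <- runif(1, 0, pi)
          ra <- 0.065 + runif(1, 0, 0.03); rb <- 0.04 + runif(1, 0, 0.02)
          u <- ldx * cos(a2) + ldy * sin(a2); v <- -ldx * sin(a2) + ldy * cos(a2)
          (u / ra)^2 + (v / rb)^2 <= 1
        },
        streak = {
          a2 <- ang + runif(1, -0.3, 0.3)
          ra <- 0.10 + runif(1, 0, 0.05); rb <- 0.013 + runif(1, 0, 0.006)
          u <- ldx * cos(a2) + ldy * sin(a2); v <- -ldx * sin(a2) + ldy * cos(a2)
          (u / ra)^2 + (v / rb)^2 <= 1
        },
        curl = {
          # band hugging the rim around the chosen boundary point
          t0 <- atan2(ey[which.min((xg - px)^2 + (yg - py)^2)],
                      ex[which.min((xg - px)^2 + (yg - py)^2)])
          wid <- runif(1, 0.45, 0.8)
          dth <- atan2(sin(atan2(ey, ex) - t0), cos(atan2(ey, ex) - t0))
          re >= 0.8 & re <= 1 & abs(dth) <= wid
        })
      mask <- mask | (m & leaf)
    }
    lcol <- hue_rgb(spec$lesion_hue + runif(1, -6, 6), 0.55,
                    0.30 + runif(1, 0, 0.1))
    alpha <- 0.85
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- (1 - alpha) * plane[mask] + alpha * lcol[ch]
      img[, , ch] <- plane
    }
  }

  for (ch in 1:3) img[, , ch] <- img[, , ch] + matrix(rnorm(h * w, 0, 0.02), h, w)
  img <- clip01(img)
  attr(img, "lesion_mask") <- mask
  attr(img, "n_lesions") <- n_lesions
  img
}

#' Generate a directory-per-class synthetic dataset
#'
#' Writes `n_classes * images_per_class` PNG images under
#' `<out_dir>/<class_name>/<index>.png` plus a `manifest.csv` with columns
#' `path,label,split` (split initially empty) and the class's
#' `similarity_group`. Each image is drawn under a seed derived from
#' (dataset seed, class id, image index), so the dataset is byte-identical
#' across regenerations and independent of generation order.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest data frame, invisibly also written to
#'   `<out_dir>/manifest.csv`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop_io(paste0("output directory not writable: ", out_dir))
  specs <- class_specs(config)
  rows <- vector("list", nrow(specs) * config$images_per_class)
  n <- 0L
  for (ci in seq_len(nrow(specs))) {
    spec <- specs[ci, ]
    cdir <- file.path(out_dir, spec$name)
    dir.create(cdir, showWarnings = FALSE)
    for (ii in seq_len(config$images_per_class)) {
      set.seed(lh_child_seed(config$seed, spec$class_id, ii))
      img <- generate_leaf_image(spec, config$image_size)
      p <- file.path(cdir, sprintf("%03d.png", ii))
      write_image(img, p)
      n <- n + 1L
      rows[[n]] <- data.frame(path = p, label = spec$name, split = "",
                              class_id = spec$class_id,
                              similarity_group = spec$similarity_group,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Read / write a dataset manifest
#'
#' The manifest is a CSV with one row per image record: `path`, `label`,
#' `split` (`"train"`, `"test"` or empty) and, for augmented records, `source`
#' and `ops` describing how to materialize the image from its source.
#'
#' @param manifest A manifest data frame.
#' @param path CSV file path.
#' @return `read_manifest()` returns the data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io(paste0("manifest not found: ", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  m$split[is.na(m$split)] <- ""
  m
}

#' Fixed random-projection hash codes
#'
#' Encodes row vectors by the sign of a fixed Gaussian random projection.
#' Used as a training-free reference encoder: for checking that the
#' similarity dial of the generator moves inter-class Hamming distances, and
#' as the "no hash layer" condition of the ablation harness.
#'
#' @param X Numeric matrix, one item per row.
#' @param K Number of code bits.
#' @param seed Seed for the projection matrix (the projection is a pure
#'   function of `ncol(X)`, `K` and `seed`).
#' @return A `K x nrow(X)` matrix over \{-1, +1\}.
#' @export
random_projection_codes <- function(X, K, seed = 1L) {
  X <- as.matrix(X)
  set.seed(as.integer(seed))
  P <- matrix(rnorm(ncol(X) * K), ncol(X), K)
  binarize(t(X %*% P))
}
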