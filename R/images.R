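# Image utilities. Images are numeric arrays h x w x 3 with values in [0, 1]
# (the png package convention); helpers here never change that contract.

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# scalar HSV (h in degrees) -> length-3 RGB in [0,1]
hue_rgb <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv((h %% 360) / 360, s, v))) / 255
}

#' Read / write an RGB image
#'
#' Thin wrappers around [png::readPNG()] / [png::writePNG()] that enforce the
#' package's h x w x 3 array-in-\[0,1\] convention (grayscale and RGBA inputs
#' are promoted/stripped to RGB).
#'
#' @param path File path of a PNG image.
#' @param image Numeric array `h x w x 3` with values in `[0, 1]`.
#' @return `read_image()` returns the image array; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_io(paste0("cannot read image: ", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  ok <- tryCatch({ png::writePNG(clip01(image), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_io(paste0("cannot write image: ", path))
  invisible(path)
}

# Reflect a (possibly fractional) coordinate into [1, n]; used for
# reflection-padded geometric transforms.
reflect_coord <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  p <- (x - 1) %% (2 * n - 2)
  ifelse(p > n - 1, 2 * n - 2 - p, p) + 1
}

# Inverse-mapped bilinear sampler: for every output pixel (r, c) the source
# location is  A %*% (r - cr_out, c - cc_out) + (cr_in, cc_in),  reflected at
# the input borders. A is the 2x2 inverse transform on centre offsets;
# out_dim allows an output canvas larger than the input.
affine_sample <- function(image, A, out_dim = NULL) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  ho <- if (is.null(out_dim)) h else out_dim[1]
  wo <- if (is.null(out_dim)) w else out_dim[2]
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  cro <- (ho + 1) / 2; cco <- (wo + 1) / 2
  r <- rep(seq_len(ho), times = wo) - cro
  c <- rep(seq_len(wo), each = ho) - cco
  sr <- reflect_coord(A[1, 1] * r + A[1, 2] * c + cr, h)
  sc <- reflect_coord(A[2, 1] * r + A[2, 2] * c + cc, w)
  r0 <- pmin(floor(sr), h - 1L); c0 <- pmin(floor(sc), w - 1L)
  fr <- sr - r0; fc <- sc - c0
  out <- array(0, c(ho, wo, d[3]))
  for (ch in seq_len(d[3])) {
    plane <- image[, , ch]
    i00 <- plane[cbind(r0, c0)]
    i10 <- plane[cbind(r0 + 1L, c0)]
    i01 <- plane[cbind(r0, c0 + 1L)]
    i11 <- plane[cbind(r0 + 1L, c0 + 1L)]
    v <- i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
      i01 * (1 - fr) * fc + i11 * fr * fc
    out[, , ch] <- v
  }
  out
}

# Rotation by `angle` degrees about the image centre, reflection padded.
# With expand = TRUE the canvas grows to contain the whole rotated image
# (no crop), so a rotation and its inverse followed by a centre crop lose
# only interpolation accuracy.
rotate_image <- function(image, angle, expand = FALSE) {
  th <- angle * pi / 180
  # inverse rotation
  A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  out_dim <- NULL
  if (expand) {
    d <- dim(image)
    need <- c(abs(d[1] * cos(th)) + abs(d[2] * sin(th)),
              abs(d[1] * sin(th)) + abs(d[2] * cos(th)))
    # symmetric padding keeps the centre on the pixel grid, so a rotation
    # and its inverse compose without a net half-pixel shift
    out_dim <- d[1:2] + 2 * pmax(ceiling((need - d[1:2]) / 2), 0)
  }
  affine_sample(image, A, out_dim)
}

# centre crop to h x w
center_crop <- function(image, h, w) {
  d <- dim(image)
  r0 <- floor((d[1] - h) / 2); c0 <- floor((d[2] - w) / 2)
  image[r0 + seq_len(h), c0 + seq_len(w), , drop = FALSE]
}

# Scale about the centre by `factor`; > 1 zooms in (centre crop), < 1 zooms
# out with reflection padding, output size unchanged.
scale_image <- function(image, factor) {
  if (factor <= 0) stop_config("scale factor must be positive")
  A <- diag(2) / factor
  affine_sample(image, A)
}

# Plain bilinear resize (edge clamped) to `h x w`.
resize_image <- function(image, h, w) {
  d <- dim(image)
  if (d[1] == h && d[2] == w) return(image)
  sr <- (seq_len(h) - 0.5) * d[1] / h + 0.5
  sc <- (seq_len(w) - 0.5) * d[2] / w + 0.5
  sr <- pmin(pmax(sr, 1), d[1]); sc <- pmin(pmax(sc, 1), d[2])
  r0 <- pmin(floor(sr), d[1] - 1L); c0 <- pmin(floor(sc), d[2] - 1L)
  if (d[1] == 1L) r0 <- rep(1L, h)
  if (d[2] == 1L) c0 <- rep(1L, w)
  fr <- sr - r0; fc <- sc - c0
  out <- array(0, c(h, w, d[3]))
  for (ch in seq_len(d[3])) {
    plane <- image[, , ch]
    p00 <- plane[r0, c0, drop = FALSE]; p10 <- plane[r0 + 1L, c0, drop = FALSE]
    p01 <- plane[r0, c0 + 1L, drop = FALSE]; p11 <- plane[r0 + 1L, c0 + 1L, drop = FALSE]
    out[, , ch] <- p00 * outer(1 - fr, 1 - fc) + p10 * outer(fr, 1 - fc) +
      p01 * outer(1 - fr, fc) + p11 * outer(fr, fc)
  }
  out
}

rgb_to_gray <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# 4-connected component labelling of a logical mask (iterative flood fill).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      r <- (p - 1L) %% h + 1L; c <- (p - 1L) %/% h + 1L
      if (r > 1L) stack <- c(stack, p - 1L)
      if (r < h)  stack <- c(stack, p + 1L)
      if (c > 1L) stack <- c(stack, p - h)
      if (c < w)  stack <- c(stack, p + h)
    }
  }
  lab
}

# Global structural-similarity index of two equal-size grayscale images
# (standard constants, single window).
ssim_global <- function(x, y) {
  c1 <- (0.01)^2; c2 <- (0.03)^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}
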