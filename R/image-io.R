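#' Grayscale image and binary mask I/O
#'
#' Images are plain numeric matrices with intensities in `[0, 1]`
#' (row = image row, column = image column). Binary masks are integer
#' matrices in `{0, 1}` with 1 marking lesion pixels. On disk both are
#' 8-bit grayscale PNG; masks are stored as `{0, 255}` and read back as
#' `{0, 1}`, so mask round trips are lossless while image round trips are
#' exact up to 8-bit quantization.
#'
#' @param path Path to a PNG file.
#' @param img Numeric matrix in `[0, 1]`.
#' @param mask Integer/numeric matrix in `{0, 1}`.
#' @return `read_gray_image()` a numeric matrix in `[0, 1]`;
#'   `read_mask()` an integer matrix in `{0, 1}`; the writers return
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_gray_image(matrix(runif(64), 8, 8), f)
#' img <- read_gray_image(f)
#' @name image_io
NULL

#' @rdname image_io
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L] # collapse RGB(A) written by other tools
  x
}

#' @rdname image_io
#' @export
write_gray_image <- function(img, path) {
  stopifnot(is.matrix(img))
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_mask <- function(path) {
  x <- read_gray_image(path)
  m <- matrix(as.integer(x > 0.5), nrow(x), ncol(x))
  m
}

#' @rdname image_io
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

assert_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) abort(paste0(arg, " must be a matrix"))
  if (!all(mask %in% c(0, 1))) abort(paste0(arg, " must be binary (values in {0, 1})"))
  invisible(mask)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("%s have mismatched dimensions: %s vs %s", what,
                  paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  invisible(NULL)
}

#' Resize a grayscale image or a binary mask
#'
#' Bilinear interpolation for continuous images, nearest neighbour for
#' masks (so resized masks stay binary). Coordinates are aligned so the
#' corner pixel centres map onto each other.
#'
#' @param img,mask Matrix to resize.
#' @param height,width Target dimensions in pixels.
#' @return Matrix of dimension `height` x `width`.
#' @export
resize_image <- function(img, height, width) {
  stopifnot(is.matrix(img), height >= 1, width >= 1)
  H <- nrow(img); W <- ncol(img)
  ry <- seq(1, H, length.out = height)
  rx <- seq(1, W, length.out = width)
  if (H == 1L) { y0 <- rep(1L, height); wy <- rep(0, height) } else {
    y0 <- pmin(floor(ry), H - 1L); wy <- ry - y0
  }
  if (W == 1L) { x0 <- rep(1L, width); wx <- rep(0, width) } else {
    x0 <- pmin(floor(rx), W - 1L); wx <- rx - x0
  }
  y1 <- pmin(y0 + 1L, H); x1 <- pmin(x0 + 1L, W)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  WY <- matrix(wy, height, width); WX <- matrix(wx, height, width, byrow = TRUE)
  (1 - WY) * ((1 - WX) * a + WX * b) + WY * ((1 - WX) * c_ + WX * d)
}

#' @rdname resize_image
#' @export
resize_mask <- function(mask, height, width) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  ry <- round(if (height == 1L) 1 else seq(1, H, length.out = height))
  rx <- round(if (width == 1L) 1 else seq(1, W, length.out = width))
  m <- mask[ry, rx, drop = FALSE]
  matrix(as.integer(m != 0), height, width)
}

#' Gaussian blur with replicate border handling
#'
#' Separable Gaussian smoothing used as the phantom point-spread model.
#' The kernel radius is `ceiling(3 * sigma)`; the border is padded by
#' edge replication so flat fields stay exactly flat.
#'
#' @param img Numeric matrix.
#' @param sigma Standard deviation in pixels; `0` returns the input.
#' @return Blurred matrix with the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma >= 0)
  if (sigma == 0) return(img)
  r <- as.integer(ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g <- g / sum(g)
  H <- nrow(img); W <- ncol(img)
  # replicate-pad, then separable 1-D passes via matrix products
  pad_rows <- img[c(rep(1L, r), seq_len(H), rep(H, r)), , drop = FALSE]
  Krow <- band_matrix(H, r, g)
  tmp <- Krow %*% pad_rows
  pad_cols <- tmp[, c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
  Kcol <- band_matrix(W, r, g)
  tmp2 <- pad_cols %*% t(Kcol)
  tmp2
}

# dense band matrix mapping a length (n + 2r) padded vector to length n
band_matrix <- function(n, r, g) {
  K <- matrix(0, n, n + 2L * r)
  for (k in seq_along(g)) {
    K[cbind(seq_len(n), seq_len(n) + k - 1L)] <- g[k]
  }
  K
}
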