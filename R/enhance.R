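#' Parameters for contrast-limited adaptive histogram equalization
#'
#' The image is divided into `tiles_per_side` x `tiles_per_side`
#' subregions; each tile's gray-level histogram is clipped where the
#' slope of the equalization mapping would exceed `clip_threshold`
#' (expressed as a multiple of the uniform tile-histogram height, so a
#' threshold of 1 forces the identity-slope mapping and `Inf` disables
#' clipping), the clipped excess is redistributed uniformly over all
#' bins in a single pass, and per-pixel output is the bilinear blend of
#' the four surrounding tile mappings.
#'
#' @param tiles_per_side Tile grid side N (N >= 1).
#' @param clip_threshold Slope threshold T > 0 (may be `Inf`).
#' @param n_bins Number of histogram bins (>= 2).
#' @return An object of class `clahe_params`.
#' @export
clahe_params <- function(tiles_per_side = 8, clip_threshold = 2.0, n_bins = 256) {
  stopifnot(tiles_per_side >= 1, clip_threshold > 0, n_bins >= 2)
  structure(list(tiles_per_side = as.integer(tiles_per_side),
                 clip_threshold = clip_threshold, n_bins = as.integer(n_bins)),
            class = "clahe_params")
}

#' Contrast-limited adaptive histogram equalization
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param params A [clahe_params()].
#' @return Enhanced image in `[0, 1]`.
#' @examples
#' img <- matrix(runif(64 * 64)^2, 64, 64)
#' out <- clahe(img, clahe_params(tiles_per_side = 4))
#' @export
clahe <- function(img, params = clahe_params()) {
  stopifnot(is.matrix(img), length(img) > 0, inherits(params, "clahe_params"))
  H <- nrow(img); W <- ncol(img)
  N <- params$tiles_per_side; B <- params$n_bins
  if (N > H || N > W) abort("tile grid is larger than the image")
  bin <- pmin(floor(pmin(pmax(img, 0), 1) * B) + 1L, B)
  # tile edges and per-pixel tile index
  row_tile <- pmin(floor((seq_len(H) - 1L) * N / H) + 1L, N)
  col_tile <- pmin(floor((seq_len(W) - 1L) * N / W) + 1L, N)
  # mapping[ti, tj, ] = clipped-histogram CDF of tile (ti, tj)
  mapping <- array(0, dim = c(N, N, B))
  centers_r <- numeric(N); centers_c <- numeric(N)
  for (ti in seq_len(N)) {
    rows <- which(row_tile == ti)
    centers_r[ti] <- mean(range(rows))
    for (tj in seq_len(N)) {
      cols_ <- which(col_tile == tj)
      if (ti == 1L) centers_c[tj] <- mean(range(cols_))
      hist_i <- tabulate(bin[rows, cols_], nbins = B)
      mapping[ti, tj, ] <- clipped_cdf(hist_i, params$clip_threshold, B)
    }
  }
  if (N == 1L) {
    out <- matrix(mapping[1, 1, ][bin], H, W)
    return(pmin(pmax(out, 0), 1))
  }
  # bilinear blend of the four surrounding tile mappings (clamped at edges)
  ri <- pmin(pmax(findInterval(seq_len(H), centers_r), 1L), N - 1L)
  ci <- pmin(pmax(findInterval(seq_len(W), centers_c), 1L), N - 1L)
  wr <- (seq_len(H) - centers_r[ri]) / (centers_r[ri + 1L] - centers_r[ri])
  wc <- (seq_len(W) - centers_c[ci]) / (centers_c[ci + 1L] - centers_c[ci])
  wr <- pmin(pmax(wr, 0), 1); wc <- pmin(pmax(wc, 0), 1)
  RI <- matrix(ri, H, W); CI <- matrix(ci, H, W, byrow = TRUE)
  WR <- matrix(wr, H, W); WC <- matrix(wc, H, W, byrow = TRUE)
  look <- function(dy, dx) {
    mapping[cbind(as.vector(RI + dy), as.vector(CI + dx), as.vector(bin))]
  }
  out <- (1 - WR) * (1 - WC) * matrix(look(0L, 0L), H, W) +
    (1 - WR) * WC * matrix(look(0L, 1L), H, W) +
    WR * (1 - WC) * matrix(look(1L, 0L), H, W) +
    WR * WC * matrix(look(1L, 1L), H, W)
  pmin(pmax(out, 0), 1)
}

# clip histogram at T x uniform height, redistribute excess uniformly
# (single pass), return the normalized CDF used as the tile mapping
clipped_cdf <- function(hist_i, clip_threshold, n_bins) {
  n_pix <- sum(hist_i)
  if (n_pix == 0) return(seq_len(n_bins) / n_bins)
  if (is.finite(clip_threshold)) {
    limit <- clip_threshold * n_pix / n_bins
    excess <- sum(pmax(hist_i - limit, 0))
    hist_i <- pmin(hist_i, limit) + excess / n_bins
  }
  cumsum(hist_i) / sum(hist_i)
}

#' Parameters for anisotropic diffusion
#'
#' Edge-preserving iterative denoising on the 4-neighbourhood (north,
#' south, east, west) with replicate (Neumann) borders, which makes each
#' iteration exactly intensity conserving. Stability requires
#' `0 < strength <= 4` (the neighbourhood size).
#'
#' @param n_iterations Number of iterations n (>= 0).
#' @param gradient_threshold Gradient threshold k > 0 of the conduction
#'   function.
#' @param strength Diffusion strength lambda, `0 < lambda <= 4`.
#' @param as_printed If `TRUE`, use the sharpening sign convention in
#'   which each pixel gains flux proportional to (center - neighbor);
#'   the default `FALSE` uses the standard Perona-Malik smoothing sign
#'   (neighbor - center). See the methods vignette.
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(n_iterations = 20, gradient_threshold = 0.1,
                             strength = 1.0, as_printed = FALSE) {
  stopifnot(n_iterations >= 0, gradient_threshold > 0,
            strength > 0, strength <= 4)
  structure(list(n_iterations = as.integer(n_iterations),
                 gradient_threshold = gradient_threshold,
                 strength = strength, as_printed = isTRUE(as_printed)),
            class = "diffusion_params")
}

#' Conduction coefficient of anisotropic diffusion
#'
#' `exp(-(diff / k)^2)`: close to 1 across flat regions (strong
#' smoothing), decaying to 0 across strong edges (edges preserved).
#'
#' @param diff Intensity difference(s).
#' @param k Gradient threshold, > 0.
#' @return Value(s) in (0, 1].
#' @export
conduction_coefficient <- function(diff, k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) abort("gradient threshold k must be a positive scalar")
  exp(-(diff / k)^2)
}

#' One anisotropic diffusion step
#'
#' Updates each pixel by `strength / 4` times the sum over its four
#' neighbours of `c(d) * d`, with `d` the neighbour-minus-center
#' difference and `c` the conduction coefficient. Replicate borders
#' make the pairwise fluxes antisymmetric, so the total image intensity
#' is conserved exactly.
#'
#' @param img Numeric matrix.
#' @param params A [diffusion_params()] (its `n_iterations` is ignored
#'   here; one step is applied).
#' @return Matrix of the same dimensions.
#' @export
diffusion_step <- function(img, params = diffusion_params()) {
  stopifnot(is.matrix(img), length(img) > 0, inherits(params, "diffusion_params"))
  H <- nrow(img); W <- ncol(img)
  k <- params$gradient_threshold
  shift_n <- img[c(1L, seq_len(H - 1L)), , drop = FALSE]
  shift_s <- img[c(seq_len(H - 1L) + 1L, H), , drop = FALSE]
  shift_w <- img[, c(1L, seq_len(W - 1L)), drop = FALSE]
  shift_e <- img[, c(seq_len(W - 1L) + 1L, W), drop = FALSE]
  flux <- 0
  for (d in list(shift_n - img, shift_s - img, shift_w - img, shift_e - img)) {
    flux <- flux + conduction_coefficient(d, k) * d
  }
  if (params$as_printed) flux <- -flux
  img + (params$strength / 4) * flux
}

#' Iterated anisotropic diffusion
#'
#' Applies [diffusion_step()] `n_iterations` times; `n_iterations = 0`
#' returns the input unchanged.
#'
#' @inheritParams diffusion_step
#' @return Matrix of the same dimensions.
#' @examples
#' noisy <- matrix(runif(32 * 32), 32, 32)
#' smooth <- anisotropic_diffusion(noisy, diffusion_params(n_iterations = 10))
#' @export
anisotropic_diffusion <- function(img, params = diffusion_params()) {
  stopifnot(inherits(params, "diffusion_params"))
  for (i in seq_len(params$n_iterations)) img <- diffusion_step(img, params)
  img
}

#' Parameters for segmentation-based enhancement
#'
#' @param lesion_weight Weight applied where the mask is 1 (default 1).
#' @param background_weight Weight applied where the mask is 0
#'   (default 0.6); must satisfy
#'   `0 < background_weight <= lesion_weight <= 1`.
#' @return An object of class `sbe_params`.
#' @export
sbe_params <- function(lesion_weight = 1.0, background_weight = 0.6) {
  stopifnot(background_weight > 0, background_weight <= lesion_weight,
            lesion_weight <= 1)
  structure(list(lesion_weight = lesion_weight, background_weight = background_weight),
            class = "sbe_params")
}

#' Segmentation-based enhancement
#'
#' Multiplies the image by a weight map that equals `lesion_weight`
#' inside the segmented lesion and `background_weight` outside,
#' dimming the background and thereby boosting the lesion-to-background
#' contrast by a factor `1 / background_weight` (5/3 at the default
#' 0.6 floor).
#'
#' @param img Numeric matrix.
#' @param mask Binary segmentation mask of the same dimensions.
#' @param params An [sbe_params()].
#' @return Weighted image, same dimensions.
#' @export
sbe_apply <- function(img, mask, params = sbe_params()) {
  stopifnot(is.matrix(img), inherits(params, "sbe_params"))
  assert_binary_mask(mask)
  assert_same_shape(img, mask, "image and mask")
  weights <- params$background_weight +
    (params$lesion_weight - params$background_weight) * mask
  img * weights
}

#' Two-stage contrast preprocessing
#'
#' CLAHE contrast enhancement followed by anisotropic-diffusion
#' denoising, the first two steps of the enhancement chain (the third,
#' [sbe_apply()], needs a segmentation mask).
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param clahe_params A [clahe_params()].
#' @param diff_params A [diffusion_params()].
#' @return Preprocessed image in `[0, 1]`.
#' @export
preprocess <- function(img, clahe_params = buslesion::clahe_params(),
                       diff_params = diffusion_params()) {
  out <- clahe(img, clahe_params)
  out <- anisotropic_diffusion(out, diff_params)
  pmin(pmax(out, 0), 1)
}
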