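#' Specify a synthetic ultrasound phantom
#'
#' Describes one synthetic breast-ultrasound-like image: a speckled,
#' low-contrast field containing `n_lesions` hypoechoic (darker than
#' background) lesions. Benign lesions are smooth ellipses; malignant
#' lesions perturb the ellipse boundary with a lobed radial sinusoid
#' plus a smooth random periodic component, emulating the irregular
#' margins of malignant tumours. A `(spec, seed)` pair fully determines
#' the sample.
#'
#' Default intensities place the background at mid-gray (0.5) with
#' lesions at half that level (`lesion_contrast = 0.5`), multiplicative
#' unit-mean Gamma speckle with dispersion 0.3, and a 1.5 px Gaussian
#' point-spread blur — a deliberately simple emulation of the high
#' noise / low contrast regime of clinical breast ultrasound.
#'
#' @param height,width Image size in pixels.
#' @param n_lesions Number of lesions (>= 0).
#' @param lesion_class `"benign"` or `"malignant"`.
#' @param background_level Mean background echo intensity in (0, 1).
#' @param lesion_contrast Multiplicative intensity factor inside the
#'   lesion, in (0, 1]; values < 1 give hypoechoic lesions.
#' @param speckle_scale Dispersion (standard deviation) of the unit-mean
#'   multiplicative speckle; `0` disables noise.
#' @param spiculation_amplitude Relative radial boundary perturbation in
#'   `[0, 1)`; must be 0 for benign specs and > 0 for malignant ones.
#' @param spiculation_lobes Number of boundary lobes of the sinusoidal
#'   perturbation.
#' @param blur_sigma Gaussian point-spread smoothing in pixels.
#' @param seed RNG seed; identical `(spec, seed)` pairs give
#'   bit-identical samples.
#' @return An object of class `phantom_spec` (a named list).
#' @examples
#' spec <- phantom_spec(seed = 7)
#' sample <- generate_phantom(spec)
#' str(sample$boxes)
#' @export
phantom_spec <- function(height = 128, width = 128, n_lesions = 1,
                         lesion_class = c("benign", "malignant"),
                         background_level = 0.5, lesion_contrast = 0.5,
                         speckle_scale = 0.3,
                         spiculation_amplitude = NULL, spiculation_lobes = 7,
                         blur_sigma = 1.5, seed = 1L) {
  lesion_class <- match.arg(lesion_class)
  if (is.null(spiculation_amplitude)) {
    spiculation_amplitude <- if (lesion_class == "malignant") 0.25 else 0
  }
  stopifnot(height >= 8, width >= 8, n_lesions >= 0,
            background_level > 0, background_level < 1,
            lesion_contrast > 0, lesion_contrast <= 1,
            speckle_scale >= 0, blur_sigma >= 0,
            spiculation_amplitude >= 0, spiculation_amplitude < 1,
            spiculation_lobes >= 1)
  if (lesion_class == "benign" && spiculation_amplitude != 0) {
    abort("benign specs must have spiculation_amplitude = 0")
  }
  if (lesion_class == "malignant" && spiculation_amplitude <= 0) {
    abort("malignant specs must have spiculation_amplitude > 0")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_lesions = as.integer(n_lesions), lesion_class = lesion_class,
                 background_level = background_level, lesion_contrast = lesion_contrast,
                 speckle_scale = speckle_scale,
                 spiculation_amplitude = spiculation_amplitude,
                 spiculation_lobes = as.integer(spiculation_lobes),
                 blur_sigma = blur_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the lesion mask of a phantom
#'
#' Places `n_lesions` disjoint filled ellipses (radially perturbed when
#' `spiculation_amplitude > 0`) that keep clear of the image border and
#' of each other. Placement is retried a bounded number of times; a
#' geometrically infeasible spec raises a placement error.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional seed; defaults to `spec$seed`. Use `NULL` to
#'   draw from the current RNG state.
#' @return Integer binary matrix (`height` x `width`) with exactly
#'   `n_lesions` 8-connected components.
#' @export
generate_lesion_mask <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  H <- spec$height; W <- spec$width
  mask <- matrix(0L, H, W)
  if (spec$n_lesions == 0L) return(mask)
  # pixel-centre grids, 0-based
  ys <- matrix(seq_len(H) - 1L, H, W)
  xs <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
  A <- spec$spiculation_amplitude
  margin <- 3
  max_tries <- 60L * spec$n_lesions
  placed <- 0L
  tries <- 0L
  while (placed < spec$n_lesions) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf("could not place %d disjoint lesions in a %dx%d frame after %d tries",
                    spec$n_lesions, H, W, max_tries))
    }
    smin <- min(H, W)
    a <- runif(1, 0.09, 0.16) * smin
    b <- runif(1, 0.09, 0.16) * smin
    theta <- runif(1, 0, pi)
    phase <- runif(1, 0, 2 * pi)
    # smooth random periodic component (low-order Fourier terms)
    cf <- rnorm(2); sf <- rnorm(2)
    rmax <- max(a, b) * (1 + A) + margin
    if (2 * rmax + 2 > min(H, W)) next
    cy <- runif(1, rmax + 1, H - 2 - rmax)
    cx <- runif(1, rmax + 1, W - 2 - rmax)
    dy <- ys - cy; dx <- xs - cx
    u <- cos(theta) * dx + sin(theta) * dy
    v <- -sin(theta) * dx + cos(theta) * dy
    if (A > 0) {
      phi <- atan2(v, u)
      rough <- cf[1] * cos(2 * phi) + sf[1] * sin(2 * phi) +
        cf[2] * cos(3 * phi) + sf[2] * sin(3 * phi)
      rough <- rough / max(1e-9, max(abs(rough)))
      pert <- A * (0.75 * sin(spec$spiculation_lobes * phi + phase) + 0.25 * rough)
    } else {
      pert <- 0
    }
    inside <- (u / a)^2 + (v / b)^2 <= (1 + pert)^2
    cand <- matrix(as.integer(inside), H, W)
    if (!any(cand == 1L)) next
    # reject if the candidate touches (8-neighbourhood) an existing lesion
    if (placed > 0L && any(dilate1(cand) & mask)) next
    mask <- mask | cand
    placed <- placed + 1L
  }
  matrix(as.integer(mask), H, W)
}

# one-pixel 8-neighbourhood dilation by shifted OR
dilate1 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m > 0
  sh <- function(mm, dr, dc) {
    r <- seq_len(H) - dr; c_ <- seq_len(W) - dc
    r <- pmin(pmax(r, 1L), H); c_ <- pmin(pmax(c_, 1L), W)
    ok <- outer(seq_len(H) - dr >= 1 & seq_len(H) - dr <= H,
                seq_len(W) - dc >= 1 & seq_len(W) - dc <= W, "&")
    res <- mm[r, c_, drop = FALSE] > 0
    res & ok
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | sh(m, dr, dc)
  }
  out
}

#' Render a phantom image from its lesion mask
#'
#' The clean echo field equals `background_level` outside the mask and
#' `background_level * lesion_contrast` inside, smoothed by a Gaussian
#' point-spread of `blur_sigma` pixels, then multiplied by unit-mean
#' Gamma speckle with standard deviation `speckle_scale` and clipped to
#' `[0, 1]`.
#'
#' @param mask Binary matrix matching the spec dimensions.
#' @param spec A [phantom_spec()].
#' @param seed Optional seed (default `spec$seed + 1`); `NULL` draws
#'   from the current RNG state.
#' @return Numeric matrix in `[0, 1]`.
#' @export
render_phantom <- function(mask, spec, seed = if (is.null(spec$seed)) NULL else spec$seed + 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  assert_binary_mask(mask)
  if (nrow(mask) != spec$height || ncol(mask) != spec$width) {
    abort("mask dimensions do not match the phantom spec")
  }
  if (!is.null(seed)) set.seed(seed)
  clean <- spec$background_level * (1 - (1 - spec$lesion_contrast) * mask)
  clean <- gaussian_blur(clean, spec$blur_sigma)
  if (spec$speckle_scale > 0) {
    s2 <- spec$speckle_scale^2
    noise <- matrix(rgamma(length(clean), shape = 1 / s2, scale = s2),
                    nrow(clean), ncol(clean))
    clean <- clean * noise
  }
  pmin(pmax(clean, 0), 1)
}

#' Generate one complete phantom sample
#'
#' Draws the lesion mask and the speckled image from a single RNG
#' stream seeded with `spec$seed`, and derives per-component detection
#' boxes from the mask.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_sample` with elements `image`
#'   (matrix in `[0, 1]`), `mask` (binary matrix), `lesion_class`, and
#'   `boxes` (tibble from [mask_to_labels()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  mask <- generate_lesion_mask(spec, seed = NULL)
  image <- render_phantom(mask, spec, seed = NULL)
  structure(list(image = image, mask = mask,
                 lesion_class = spec$lesion_class,
                 boxes = mask_to_labels(mask, spec$lesion_class, per_component = TRUE)),
            class = "phantom_sample")
}

#' Write a phantom dataset to disk
#'
#' Emulates the file layout of public breast-ultrasound collections:
#' one grayscale image PNG per case plus a same-stem `_mask.png` binary
#' mask, with a dataset-level annotation file in both CSV and
#' COCO-style JSON. Each sample gets its own RNG stream derived from
#' `(seed, index)`, so the dataset is reproducible and order
#' independent.
#'
#' @param spec_list List of [phantom_spec()] objects (their `seed`
#'   fields are overridden by the derived per-sample seeds).
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @return A manifest tibble with one row per sample: `stem`, `image`,
#'   `mask` (paths), `class`, `seed`, `n_boxes`. The annotation files
#'   are written as `annotations.csv` and `annotations.json`, the
#'   manifest as `manifest.csv`.
#' @export
generate_dataset <- function(spec_list, out_dir, seed = 1L) {
  stopifnot(length(spec_list) >= 1)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) abort(paste0("cannot create output directory: ", out_dir))
  }
  rows <- vector("list", length(spec_list))
  all_labels <- vector("list", length(spec_list))
  sizes <- list()
  for (i in seq_along(spec_list)) {
    spec <- spec_list[[i]]
    stopifnot(inherits(spec, "phantom_spec"))
    spec$seed <- sample_seed(seed, i)
    smp <- generate_phantom(spec)
    stem <- sprintf("phantom_%04d", i)
    img_path <- file.path(out_dir, paste0(stem, ".png"))
    mask_path <- file.path(out_dir, paste0(stem, "_mask.png"))
    write_gray_image(smp$image, img_path)
    write_mask(smp$mask, mask_path)
    labs <- smp$boxes
    if (nrow(labs) > 0) labs <- dplyr::bind_cols(tibble(file = paste0(stem, ".png")), labs)
    all_labels[[i]] <- labs
    sizes[[paste0(stem, ".png")]] <- c(spec$height, spec$width)
    rows[[i]] <- tibble(stem = stem, image = img_path, mask = mask_path,
                        class = spec$lesion_class, seed = spec$seed,
                        n_boxes = nrow(smp$boxes))
  }
  labels <- dplyr::bind_rows(all_labels)
  if (nrow(labels) == 0L) {
    labels <- tibble(file = character(), class = character(),
                     x_min = integer(), y_min = integer(),
                     x_max = integer(), y_max = integer(),
                     w = integer(), h = integer())
  }
  write_annotations(labels, file.path(out_dir, "annotations.csv"))
  write_annotations(labels, file.path(out_dir, "annotations.json"), image_sizes = sizes)
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

# per-sample stream: deterministic, order-independent, < 2^31
sample_seed <- function(master, i) {
  as.integer((as.double(master) + 7919 * as.double(i)) %% 2147483647)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d, %d %s lesion(s), bg %.2f, contrast %.2f, speckle %.2f, seed %d\n",
              x$height, x$width, x$n_lesions, x$lesion_class,
              x$background_level, x$lesion_contrast, x$speckle_scale, x$seed))
  invisible(x)
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d %s, %d box(es)\n",
              nrow(x$image), ncol(x$image), x$lesion_class, nrow(x$boxes)))
  invisible(x)
}
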