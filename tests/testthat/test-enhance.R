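test_that("conduction coefficient matches its closed form", {
  expect_equal(conduction_coefficient(0, 0.1), 1)
  expect_equal(conduction_coefficient(0.1, 0.1), exp(-1))
  expect_equal(conduction_coefficient(0.2, 0.1), exp(-4))
  expect_equal(conduction_coefficient(-0.1, 0.1), exp(-1)) # even function
  expect_error(conduction_coefficient(0.1, 0), "positive")
})

test_that("one diffusion step matches a direct pixel-by-pixel evaluation", {
  set.seed(101)
  # the printed center-impulse case
  img <- matrix(0, 3, 3); img[2, 2] <- 1
  p <- diffusion_params(gradient_threshold = 10, strength = 1)
  expect_lt(max(abs(diffusion_step(img, p) - oracle_diffusion_direct(img, 10, 1))), 1e-12)

  for (rep in 1:20) {
    H <- sample(3:16, 1); W <- sample(3:16, 1)
    img <- matrix(runif(H * W), H, W)
    k <- runif(1, 0.05, 0.5); lam <- runif(1, 0.1, 4)
    out <- diffusion_step(img, diffusion_params(gradient_threshold = k, strength = lam))
    expect_lt(max(abs(out - oracle_diffusion_direct(img, k, lam))), 1e-12)
    # intensity conservation (pairwise flux antisymmetry with replicate borders)
    expect_lt(abs(sum(out) - sum(img)) / sum(img), 1e-9)
  }
})

test_that("diffusion fixes constants, stays in range, and composes over iterations", {
  cst <- matrix(0.42, 7, 9)
  p <- diffusion_params(n_iterations = 5)
  expect_equal(diffusion_step(cst, p), cst)
  expect_equal(anisotropic_diffusion(cst, p), cst)

  # range non-expansion: each update is a convex combination of the pixel
  # and its neighbours whenever strength <= 1 (per-neighbour weight
  # strength/4 <= 1/4, the classic discrete stability bound)
  set.seed(7)
  for (rep in 1:100) {
    img <- matrix(runif(12 * 12), 12, 12)
    lam <- runif(1, 0.1, 1)
    out <- anisotropic_diffusion(img, diffusion_params(n_iterations = 3,
                                                       gradient_threshold = 0.3,
                                                       strength = lam))
    expect_gte(min(out), min(img) - 1e-12)
    expect_lte(max(out), max(img) + 1e-12)
  }

  img <- matrix(runif(20 * 20), 20, 20)
  p0 <- diffusion_params(n_iterations = 0)
  expect_identical(anisotropic_diffusion(img, p0), img)
  pa <- diffusion_params(n_iterations = 3, gradient_threshold = 0.2)
  pb <- diffusion_params(n_iterations = 4, gradient_threshold = 0.2)
  pab <- diffusion_params(n_iterations = 7, gradient_threshold = 0.2)
  expect_equal(anisotropic_diffusion(anisotropic_diffusion(img, pa), pb),
               anisotropic_diffusion(img, pab))
})

test_that("diffusion smooths speckle; the as-printed sign sharpens instead", {
  smp <- generate_phantom(phantom_spec(seed = 31))
  p <- diffusion_params(n_iterations = 50, gradient_threshold = 0.3)
  out <- anisotropic_diffusion(smp$image, p)
  expect_lt(stats::var(as.vector(out)), stats::var(as.vector(smp$image)))

  img <- matrix(runif(64), 8, 8)
  std <- diffusion_step(img, diffusion_params(gradient_threshold = 0.2))
  lit <- diffusion_step(img, diffusion_params(gradient_threshold = 0.2, as_printed = TRUE))
  # as-printed flips the update: center gains what it would have lost
  expect_equal(lit, 2 * img - std)
})

test_that("CLAHE fixes constant images and reduces to global HE for one tile", {
  cst <- clahe(matrix(0.3, 24, 24), clahe_params(tiles_per_side = 3))
  expect_lt(diff(range(cst)), 1e-12)

  set.seed(55)
  for (rep in 1:50) {
    img <- matrix(runif(40 * 40)^sample(c(0.5, 1, 2), 1), 40, 40)
    n_bins <- sample(c(32, 64, 256), 1)
    out <- clahe(img, clahe_params(tiles_per_side = 1, clip_threshold = Inf,
                                   n_bins = n_bins))
    expect_lte(max(abs(out - oracle_global_he(img, n_bins))), 1 / n_bins)
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
  }

  expect_error(clahe(matrix(runif(9), 3, 3), clahe_params(tiles_per_side = 8)),
               "larger than the image")
})

test_that("CLAHE clipping bounds the mapping slope", {
  set.seed(66)
  # heavily peaked image: unclipped HE would have a huge slope at the peak
  img <- matrix(rbeta(64 * 64, 8, 8) * 0.2 + 0.4, 64, 64)
  n_bins <- 64
  tight <- clahe(img, clahe_params(tiles_per_side = 1, clip_threshold = 1.5,
                                   n_bins = n_bins))
  loose <- clahe(img, clahe_params(tiles_per_side = 1, clip_threshold = Inf,
                                   n_bins = n_bins))
  slope_of <- function(out) {
    bin <- pmin(floor(img * n_bins) + 1L, n_bins)
    m <- tapply(as.vector(out), as.vector(bin), max)
    bins <- as.integer(names(m))
    diff(m) / (diff(bins) / n_bins)
  }
  # clipped mapping slope <= T (+ one-bin discretization); unclipped exceeds it
  expect_lte(max(slope_of(tight)), 1.5 + 1)
  expect_gt(max(slope_of(loose)), 1.5 + 1)
})

test_that("SBE is the stated piecewise multiplication", {
  set.seed(8)
  img <- matrix(runif(30 * 20), 30, 20)
  ones <- matrix(1L, 30, 20); zeros <- matrix(0L, 30, 20)
  expect_identical(sbe_apply(img, ones), img)
  expect_equal(sbe_apply(img, zeros), 0.6 * img)
  expect_error(sbe_apply(img, matrix(0L, 5, 5)), "mismatch")

  # linearity in the image
  m <- random_mask(30, 20, 0.3)
  expect_equal(sbe_apply(2.5 * img, m), 2.5 * sbe_apply(img, m))

  # contrast-ratio gain of exactly 1/background_weight on a noiseless phantom
  spec <- phantom_spec(height = 48, width = 48, speckle_scale = 0, blur_sigma = 0,
                       seed = 17)
  mask <- generate_lesion_mask(spec)
  img <- render_phantom(mask, spec)
  r_before <- mean(img[mask == 1]) / mean(img[mask == 0])
  sbe <- sbe_apply(img, mask)
  r_after <- mean(sbe[mask == 1]) / mean(sbe[mask == 0])
  expect_equal(r_after, r_before / 0.6)
})

test_that("preprocess is the CLAHE-then-diffusion composition", {
  set.seed(9)
  img <- matrix(runif(32 * 32), 32, 32)
  cp <- clahe_params(tiles_per_side = 4)
  dp <- diffusion_params(n_iterations = 5, gradient_threshold = 0.2)
  expect_equal(preprocess(img, cp, dp),
               anisotropic_diffusion(clahe(img, cp), dp))
  cst <- preprocess(matrix(0.7, 32, 32), cp, dp)
  expect_lt(diff(range(cst)), 1e-12)
  out <- preprocess(img, cp, dp)
  expect_gte(min(out), 0); expect_lte(max(out), 1)
})
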