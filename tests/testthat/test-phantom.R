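test_that("lesion masks have the requested component count and stay off the border", {
  spec0 <- phantom_spec(n_lesions = 0, seed = 1)
  expect_identical(generate_lesion_mask(spec0), matrix(0L, 128, 128))

  for (seed in c(2, 11, 23)) {
    spec2 <- phantom_spec(n_lesions = 2, seed = seed)
    mask <- generate_lesion_mask(spec2)
    expect_identical(max(oracle_flood_fill(mask)), 2L)
    expect_true(all(mask[1, ] == 0) && all(mask[nrow(mask), ] == 0))
    expect_true(all(mask[, 1] == 0) && all(mask[, ncol(mask)] == 0))
  }

  spec3 <- phantom_spec(n_lesions = 3, lesion_class = "malignant", seed = 5)
  expect_identical(max(oracle_flood_fill(generate_lesion_mask(spec3))), 3L)

  # geometrically infeasible: too many lesions for a tiny frame
  cramped <- phantom_spec(height = 24, width = 24, n_lesions = 30, seed = 1)
  expect_error(generate_lesion_mask(cramped), "place")
})

test_that("unspiculated lesions are exact ellipses up to one pixel", {
  # moment-based ellipse recovery: for a filled ellipse the covariance
  # eigenvalues are a^2/4 and b^2/4, so the recovered quadratic form
  # rasterizes back to the component (within a 1-pixel dilation band)
  spec <- phantom_spec(n_lesions = 2, seed = 9)
  mask <- generate_lesion_mask(spec)
  lab <- oracle_flood_fill(mask)
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    pts <- which(comp, arr.ind = TRUE)
    ctr <- colMeans(pts)
    S <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
    ev <- eigen(S)
    dy <- sweep(which(comp | !comp, arr.ind = TRUE), 2, ctr)[, 1]
    dx <- sweep(which(comp | !comp, arr.ind = TRUE), 2, ctr)[, 2]
    u <- ev$vectors[1, 1] * dy + ev$vectors[2, 1] * dx
    v <- ev$vectors[1, 2] * dy + ev$vectors[2, 2] * dx
    q <- u^2 / (4 * ev$values[1]) + v^2 / (4 * ev$values[2])
    ell <- matrix(q <= 1, nrow(mask), ncol(mask))
    # any disagreement lies within a 1-pixel band around the ellipse boundary
    band <- dilate_test(ell) & !erode_test(ell)
    disagree <- xor(comp, ell)
    expect_true(all(band[disagree]))
  }
})

test_that("rendering obeys the noiseless limit and is deterministic", {
  spec <- phantom_spec(height = 32, width = 32, background_level = 0.8,
                       lesion_contrast = 0.5, speckle_scale = 0,
                       blur_sigma = 0, seed = 4)
  mask <- generate_lesion_mask(spec)
  img <- render_phantom(mask, spec)
  expect_equal(unique(img[mask == 0]), 0.8)
  expect_equal(unique(img[mask == 1]), 0.4)

  noisy_spec <- phantom_spec(seed = 4)
  m2 <- generate_lesion_mask(noisy_spec)
  expect_identical(render_phantom(m2, noisy_spec), render_phantom(m2, noisy_spec))
  expect_identical(generate_phantom(noisy_spec), generate_phantom(noisy_spec))
})

test_that("speckle is unit-mean: background average within 3 standard errors", {
  spec <- phantom_spec(height = 128, width = 128, n_lesions = 1, seed = 12)
  smp <- generate_phantom(spec)
  bg <- smp$image[smp$mask == 0]
  # keep away from the blurred lesion rim
  rim <- dilate_test(smp$mask == 1, times = 6)
  bg <- smp$image[!rim & smp$mask == 0]
  expect_gt(length(bg), 1e4)
  se <- stats::sd(bg) / sqrt(length(bg))
  expect_lt(abs(mean(bg) - spec$background_level), 3 * se)
})

test_that("hypoechoic lesions are darker than background at any tested speckle", {
  for (s in c(0.1, 0.3, 0.5)) {
    spec <- phantom_spec(height = 128, width = 128, n_lesions = 2,
                         speckle_scale = s, seed = 21)
    smp <- generate_phantom(spec)
    expect_gte(sum(smp$mask), 1e3)
    tt <- stats::t.test(smp$image[smp$mask == 1], smp$image[smp$mask == 0],
                        alternative = "less")
    expect_lt(tt$p.value, 0.001)
  }
})

test_that("phantom boxes are exactly the per-component mask boxes", {
  for (seed in c(3, 14)) {
    smp <- generate_phantom(phantom_spec(n_lesions = 2, seed = seed))
    expect_identical(smp$boxes,
                     mask_to_labels(smp$mask, smp$lesion_class, per_component = TRUE))
  }
})

test_that("written datasets round-trip and are bit-reproducible", {
  specs <- c(lapply(1:2, function(i) phantom_spec(height = 48, width = 48, seed = i)),
             lapply(3:4, function(i) phantom_spec(height = 48, width = 48,
                                                  lesion_class = "malignant", seed = i)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(specs, d1, seed = 99)
  m2 <- generate_dataset(specs, d2, seed = 99)

  expect_identical(nrow(m1), 4L)
  expect_length(list.files(d1, pattern = "_mask\\.png$"), 4)
  expect_length(setdiff(list.files(d1, pattern = "\\.png$"),
                        list.files(d1, pattern = "_mask\\.png$")), 4)

  # bit-reproducibility across runs
  for (f in list.files(d1, pattern = "\\.png$")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_identical(readLines(file.path(d1, "annotations.csv")),
                   readLines(file.path(d2, "annotations.csv")))

  # masks round-trip losslessly; annotations match recomputed labels
  ann <- read_annotations(file.path(d1, "annotations.csv"))
  annj <- read_annotations(file.path(d1, "annotations.json"))
  expect_identical(ann, annj[names(ann)])
  for (i in seq_len(nrow(m1))) {
    spec <- specs[[i]]
    spec$seed <- m1$seed[i]
    smp <- generate_phantom(spec)
    stored <- read_mask(m1$mask[i])
    expect_identical(stored, smp$mask)
    labs <- mask_to_labels(stored, m1$class[i], per_component = TRUE)
    got <- ann[ann$file == paste0(m1$stem[i], ".png"), names(labs)]
    expect_identical(as.data.frame(got), as.data.frame(labs))
    # image round-trips up to 8-bit quantization
    expect_lt(max(abs(read_gray_image(m1$image[i]) - smp$image)), 1 / 255 + 1e-12)
  }
})
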