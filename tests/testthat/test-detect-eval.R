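box <- function(x0, y0, x1, y1) {
  tibble::tibble(x_min = x0, y_min = y0, x_max = x1, y_max = y1)
}

gt_row <- function(x0, y0, x1, y1, class = "benign", file = "a.png") {
  dplyr::bind_cols(tibble::tibble(file = file, class = class), box(x0, y0, x1, y1))
}

pred_row <- function(x0, y0, x1, y1, class = "benign", conf = 1, file = "a.png") {
  dplyr::mutate(gt_row(x0, y0, x1, y1, class, file), confidence = conf)
}

test_that("IoU matches the pixel-rasterization oracle", {
  a <- box(0, 0, 9, 9)
  expect_identical(iou(a, a), 1)
  expect_identical(iou(a, box(20, 20, 25, 25)), 0)

  set.seed(50)
  for (rep in 1:500) {
    a <- random_box(); b <- random_box()
    v <- iou(a, b)
    expect_lt(abs(v - oracle_iou_raster(a, b)), 1e-12)
    expect_identical(v, iou(b, a)) # symmetry
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("matching reproduces the stated examples in both modes", {
  gts <- dplyr::bind_rows(gt_row(0, 0, 10, 10), gt_row(30, 30, 40, 42))
  perfect <- dplyr::bind_rows(pred_row(0, 0, 10, 10), pred_row(30, 30, 40, 42))
  for (mode in c("standard", "paper_literal")) {
    m <- match_image(perfect, gts, mode = mode)
    b <- m[m$class == "benign", ]
    expect_identical(c(b$tp, b$fp, b$fn), c(2L, 0L, 0L))
  }

  one_hit <- pred_row(0, 0, 10, 10)
  m <- match_image(one_hit, gts, mode = "standard")
  b <- m[m$class == "benign", ]
  expect_identical(c(b$tp, b$fp, b$fn), c(1L, 0L, 1L))

  # paper-literal: a GT overlapped at 0 < IoU <= 0.5 is not a FN
  graze <- dplyr::bind_rows(pred_row(0, 0, 10, 10), pred_row(38, 40, 48, 52))
  std <- match_image(graze, gts, mode = "standard")
  lit <- match_image(graze, gts, mode = "paper_literal")
  expect_identical(std$fn[std$class == "benign"], 1L)
  expect_identical(lit$fn[lit$class == "benign"], 0L)

  # IoU exactly 0.5 is not a TP (strict inequality)
  half <- pred_row(0, 0, 9, 4) # 50 px vs 100 px of (0,0,9,9): IoU = 0.5
  expect_identical(iou(half, box(0, 0, 9, 9)), 0.5)
  m <- match_image(half, gt_row(0, 0, 9, 9))
  expect_identical(m$tp[m$class == "benign"], 0L)

  # class-wise matching only
  cross <- pred_row(0, 0, 10, 10, class = "malignant")
  m <- match_image(cross, gts)
  expect_identical(m$tp[m$class == "malignant"], 0L)
  expect_identical(m$fp[m$class == "malignant"], 1L)

  # duplicates of an already-matched GT are FP
  dup <- dplyr::bind_rows(pred_row(0, 0, 10, 10, conf = 0.9),
                          pred_row(0, 1, 10, 11, conf = 0.8))
  m <- match_image(dup, gt_row(0, 0, 10, 10))
  b <- m[m$class == "benign", ]
  expect_identical(c(b$tp, b$fp), c(1L, 1L))

  # confidence threshold discards predictions
  m <- match_image(dup, gt_row(0, 0, 10, 10), conf_threshold = 0.95)
  b <- m[m$class == "benign", ]
  expect_identical(c(b$tp, b$fp, b$fn), c(0L, 0L, 1L))
})

test_that("match counts equal the brute-force assignment oracle on random scenes", {
  # ground-truth boxes are placed on a coarse grid so they never overlap
  # each other (disjoint lesions), the regime where greedy
  # confidence-ordered matching provably attains the maximum TP count
  set.seed(51)
  for (rep in 1:60) {
    ng <- sample(1:3, 1); np <- sample(0:3, 1)
    cells <- sample(0:3, ng) # distinct 25-px cells in a 100-px row
    gts <- dplyr::bind_rows(lapply(seq_len(ng), function(i) {
      x0 <- cells[i] * 25 + sample(0:3, 1)
      gt_row(x0, 0, x0 + sample(10:18, 1), sample(10:18, 1),
             class = sample(c("benign", "malignant"), 1))
    }))
    preds <- if (np == 0) pred_row(0, 0, 1, 1)[0, ] else
      dplyr::bind_rows(lapply(seq_len(np), function(i) {
        g <- gts[sample(ng, 1), ]
        j <- sample(-8:8, 4, replace = TRUE) # jitter corners
        pred_row(g$x_min + j[1], g$y_min + j[2],
                 max(g$x_min + j[1], g$x_max + j[3]),
                 max(g$y_min + j[2], g$y_max + j[4]),
                 class = sample(c("benign", "malignant"), 1),
                 conf = stats::runif(1))
      }))
    got <- match_image(preds, gts, iou_threshold = 0.5)
    for (cl in c("benign", "malignant")) {
      p <- preds[preds$class == cl, ]; g <- gts[gts$class == cl, ]
      want_tp <- oracle_max_tp(p, g, 0.5)
      row <- got[got$class == cl, ]
      expect_identical(row$tp, as.integer(want_tp))
      expect_identical(row$fp, nrow(p) - as.integer(want_tp))
      expect_identical(row$tp + row$fn, nrow(g)) # standard-mode accounting
    }
  }
})

test_that("precision and recall follow the defining ratios and conventions", {
  m <- tibble::tibble(class = "benign", tp = 1L, fp = 0L, fn = 1L)
  pr <- precision_recall(m)
  expect_identical(c(pr$precision, pr$recall), c(1, 0.5))
  expect_identical(precision_recall(tibble::tibble(tp = 0L, fp = 3L, fn = 0L))$precision, 0)
  pr <- precision_recall(tibble::tibble(tp = 2L, fp = 1L, fn = 0L))
  expect_equal(c(pr$precision, pr$recall), c(2 / 3, 1))
  # 0/0 conventions
  pr <- precision_recall(tibble::tibble(tp = 0L, fp = 0L, fn = 0L))
  expect_identical(c(pr$precision, pr$recall), c(1, 1))
})

test_that("PR curves sweep the confidences and match per-threshold recomputation", {
  gts <- gt_row(0, 0, 10, 10)
  curve <- pr_curve(pred_row(0, 0, 10, 10, conf = 0.7), gts, class = "benign")
  expect_identical(c(curve$precision, curve$recall), c(1, 1))

  wrong <- dplyr::bind_rows(pred_row(50, 50, 60, 60, conf = 0.9),
                            pred_row(70, 70, 80, 80, conf = 0.4))
  curve <- pr_curve(wrong, gts, class = "benign")
  expect_true(all(curve$precision == 0))

  set.seed(52)
  gts2 <- dplyr::bind_rows(gt_row(0, 0, 12, 12), gt_row(40, 40, 60, 55),
                           gt_row(0, 40, 15, 60, class = "malignant"))
  preds2 <- dplyr::bind_rows(lapply(1:6, function(i) {
    g <- gts2[sample(3, 1), ]
    pred_row(g$x_min + sample(-4:4, 1), g$y_min + sample(-4:4, 1),
             g$x_max + sample(-4:4, 1), g$y_max + sample(-4:4, 1),
             class = g$class, conf = round(stats::runif(1), 3))
  }))
  curve <- pr_curve(preds2, gts2)
  for (r in seq_len(nrow(curve))) {
    again <- precision_recall(match_image(preds2, gts2, iou_threshold = 0.5,
                                          conf_threshold = curve$threshold[r]))
    again <- again[again$class == curve$class[r], ]
    expect_equal(curve$precision[r], again$precision)
    expect_equal(curve$recall[r], again$recall)
  }
  # recall non-decreasing as the threshold drops
  for (cl in unique(curve$class)) {
    cc <- curve[curve$class == cl, ]
    expect_true(all(diff(cc$recall) >= 0))
  }
})

test_that("average precision reproduces the hand-derived ranked scenario", {
  # 2 GT; ranked predictions [correct, wrong, correct]:
  # points P=1@R=0.5, P=1/2@R=0.5, P=2/3@R=1; all-points AP = 5/6
  gts <- dplyr::bind_rows(gt_row(0, 0, 10, 10), gt_row(40, 40, 52, 50))
  preds <- dplyr::bind_rows(pred_row(0, 0, 10, 10, conf = 0.9),
                            pred_row(80, 80, 90, 90, conf = 0.8),
                            pred_row(40, 40, 52, 50, conf = 0.7))
  curve <- pr_curve(preds, gts, class = "benign")
  expect_equal(curve$precision, c(1, 1 / 2, 2 / 3))
  expect_equal(curve$recall, c(0.5, 0.5, 1))
  expect_equal(average_precision(curve)$ap, 5 / 6)

  # perfect detector
  p <- pr_curve(pred_row(0, 0, 10, 10), gt_row(0, 0, 10, 10), class = "benign")
  expect_identical(average_precision(p)$ap, 1)
  # no TP at any threshold
  z <- pr_curve(pred_row(90, 90, 95, 95), gt_row(0, 0, 10, 10), class = "benign")
  expect_identical(average_precision(z)$ap, 0)
  expect_error(average_precision(z[0, ]), "empty")
})

test_that("all-points AP dominates the trapezoidal AP on random scenes", {
  set.seed(53)
  for (rep in 1:30) {
    ng <- sample(2:4, 1)
    gts <- dplyr::bind_rows(lapply(seq_len(ng), function(i) {
      x0 <- (i - 1) * 30
      gt_row(x0, 0, x0 + 15, 15)
    }))
    preds <- dplyr::bind_rows(lapply(seq_len(sample(2:6, 1)), function(i) {
      g <- gts[sample(ng, 1), ]
      pred_row(g$x_min + sample(-6:6, 1), g$y_min + sample(-6:6, 1),
               g$x_max + sample(-6:6, 1), g$y_max + sample(-6:6, 1),
               conf = stats::runif(1))
    }))
    curve <- pr_curve(preds, gts, class = "benign")
    expect_gte(average_precision(curve, "all_points")$ap,
               average_precision(curve, "trapezoid")$ap - 1e-12)
  }
})

test_that("mAP is the unweighted class mean and ground truth scores 1", {
  expect_identical(mean_ap(tibble::tibble(class = c("benign", "malignant"),
                                          ap = c(1, 0))), 0.5)
  expect_identical(mean_ap(tibble::tibble(class = "benign", ap = 0.7)), 0.7)
  expect_identical(mean_ap(c(0.4, 0.4)), 0.4)
  expect_error(mean_ap(numeric(0)), "AP")

  # feeding ground truth as predictions is a perfect detector
  set.seed(54)
  gts <- dplyr::bind_rows(lapply(1:8, function(i) {
    x0 <- sample(0:60, 1); y0 <- sample(0:60, 1)
    gt_row(x0, y0, x0 + sample(8:20, 1), y0 + sample(8:20, 1),
           class = if (i %% 2) "benign" else "malignant",
           file = sprintf("img%d.png", (i %% 3) + 1))
  }))
  ev <- evaluate_detections(oracle_predictions(gts), gts)
  expect_identical(ev$map, 1)
  expect_true(all(ev$summary$precision == 1))
  expect_true(all(ev$summary$recall == 1))
  expect_identical(glance(ev)$map, 1)
  expect_identical(tidy(ev), ev$summary)
})

test_that("prediction files round-trip in CSV and COCO-results JSON", {
  set.seed(55)
  preds <- dplyr::bind_rows(lapply(1:5, function(i) {
    b <- random_box(60)
    pred_row(b$x_min, b$y_min, b$x_max, b$y_max,
             class = sample(c("benign", "malignant"), 1),
             conf = round(stats::runif(1), 4),
             file = sprintf("img%d.png", sample(1:2, 1)))
  }))
  preds$w <- preds$x_max - preds$x_min
  preds$h <- preds$y_max - preds$y_min
  preds <- preds[, c("file", "class", "x_min", "y_min", "x_max", "y_max",
                     "w", "h", "confidence")]
  fc <- withr::local_tempfile(fileext = ".csv")
  fj <- withr::local_tempfile(fileext = ".json")
  write_predictions(preds, fc)
  write_predictions(preds, fj)
  expect_identical(as.data.frame(read_predictions(fc)), as.data.frame(preds))
  expect_identical(as.data.frame(read_predictions(fj)), as.data.frame(preds))
})
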