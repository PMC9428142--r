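#' Intersection over union of bounding boxes
#'
#' Boxes use 0-based inclusive corner coordinates, so a box covers
#' `(w + 1) * (h + 1)` pixels; IoU is overlap pixels over union pixels
#' (the Jaccard index), 0 for disjoint boxes.
#'
#' @param a,b Data frames (or one-row tibbles) with columns `x_min`,
#'   `y_min`, `x_max`, `y_max`; recycled elementwise like vectors.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' a <- tibble::tibble(x_min = 0, y_min = 0, x_max = 9, y_max = 9)
#' iou(a, a)
#' @export
iou <- function(a, b) {
  ix0 <- pmax(a$x_min, b$x_min); iy0 <- pmax(a$y_min, b$y_min)
  ix1 <- pmin(a$x_max, b$x_max); iy1 <- pmin(a$y_max, b$y_max)
  iw <- ix1 - ix0 + 1; ih <- iy1 - iy0 + 1
  inter <- ifelse(iw > 0 & ih > 0, iw * ih, 0)
  area <- function(z) (z$x_max - z$x_min + 1) * (z$y_max - z$y_min + 1)
  un <- area(a) + area(b) - inter
  as.numeric(inter / un)
}

eval_classes <- c("benign", "malignant")

#' Match predictions to ground truth on one image
#'
#' Predictions below `conf_threshold` are discarded; the rest are
#' processed per class in descending confidence, each greedily matched
#' to the still-unmatched same-class ground-truth box of highest IoU. A
#' match with IoU strictly greater than `iou_threshold` is a true
#' positive, otherwise the prediction is a false positive. In
#' `"standard"` mode every ground-truth box without a true-positive
#' match counts as a false negative (so TP + FN equals the number of
#' ground-truth boxes per class); `"paper_literal"` mode instead counts
#' as false negatives only the ground-truth boxes with zero IoU against
#' every retained same-class prediction, the published reading under
#' which ground truth overlapped at 0 < IoU <= 0.5 is unaccounted.
#'
#' @param preds Tibble of predictions: `class`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `confidence` (plus an optional `file` column,
#'   ignored here — matching is within one image).
#' @param gts Tibble of ground-truth labels with the same box columns.
#' @param iou_threshold IoU above which a match is a TP (default 0.5).
#' @param conf_threshold Minimum confidence for a prediction to be
#'   retained (default 0).
#' @param mode `"standard"` or `"paper_literal"`.
#' @return Tibble with one row per class: `class`, `tp`, `fp`, `fn`.
#' @export
match_image <- function(preds, gts, iou_threshold = 0.5, conf_threshold = 0,
                        mode = c("standard", "paper_literal")) {
  mode <- match.arg(mode)
  preds <- as_tibble(preds); gts <- as_tibble(gts)
  if (nrow(preds) > 0) preds <- preds[preds$confidence >= conf_threshold, , drop = FALSE]
  purrr::map_dfr(eval_classes, function(cl) {
    p <- preds[preds$class == cl, , drop = FALSE]
    g <- gts[gts$class == cl, , drop = FALSE]
    if (nrow(p) > 0) p <- p[order(-p$confidence), , drop = FALSE]
    matched <- rep(FALSE, nrow(g))
    tp <- 0L; fp <- 0L
    for (i in seq_len(nrow(p))) {
      if (nrow(g) == 0) { fp <- fp + 1L; next }
      ious <- iou(p[i, ], g)
      ious[matched] <- -1
      j <- which.max(ious)
      if (length(j) && ious[j] > iou_threshold) {
        tp <- tp + 1L
        matched[j] <- TRUE
      } else {
        fp <- fp + 1L
      }
    }
    fn <- if (mode == "standard") {
      sum(!matched)
    } else {
      # ground truth with zero IoU against every retained same-class prediction
      if (nrow(g) == 0) 0L else sum(vapply(seq_len(nrow(g)), function(j) {
        nrow(p) == 0 || all(iou(g[j, ], p) == 0)
      }, logical(1)))
    }
    tibble(class = cl, tp = tp, fp = fp, fn = as.integer(fn))
  })
}

#' Precision and recall from match counts
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`. The
#' empty cases use the convention 0/0 = 1 (no ground truth and no
#' predictions is a perfect score); a zero numerator with a non-zero
#' denominator gives 0.
#'
#' @param m Tibble as returned by [match_image()] (columns `tp`, `fp`,
#'   `fn`, optionally `class`).
#' @return The input with `precision` and `recall` columns appended.
#' @export
precision_recall <- function(m) {
  m <- as_tibble(m)
  stopifnot(all(c("tp", "fp", "fn") %in% names(m)), all(m$tp >= 0), all(m$fp >= 0), all(m$fn >= 0))
  m$precision <- ifelse(m$tp + m$fp == 0, 1, m$tp / (m$tp + m$fp))
  m$recall <- ifelse(m$tp + m$fn == 0, 1, m$tp / (m$tp + m$fn))
  m
}

# pool match counts over images at one confidence threshold
match_dataset <- function(preds, gts, iou_threshold = 0.5, conf_threshold = 0,
                          mode = "standard") {
  files <- unique(c(preds$file, gts$file))
  counts <- purrr::map_dfr(files, function(f) {
    match_image(preds[preds$file == f, , drop = FALSE],
                gts[gts$file == f, , drop = FALSE],
                iou_threshold, conf_threshold, mode)
  })
  dplyr::summarise(dplyr::group_by(counts, .data$class),
                   tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
                   .groups = "drop")
}

#' Precision-recall curve over a confidence sweep
#'
#' Sweeps the confidence threshold over every distinct prediction
#' confidence (descending) and records pooled precision and recall per
#' class at each threshold; recall is non-decreasing as the threshold
#' decreases.
#'
#' @param preds Predictions tibble (`file`, `class`, box corners,
#'   `confidence`), possibly spanning many images.
#' @param gts Ground-truth tibble (`file`, `class`, box corners).
#' @param class Optional single class to restrict to; default both.
#' @param iou_threshold,mode Passed to [match_image()].
#' @return A tibble of class `pr_curve`: `class`, `threshold`,
#'   `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
pr_curve <- function(preds, gts, class = NULL, iou_threshold = 0.5,
                     mode = c("standard", "paper_literal")) {
  mode <- match.arg(mode)
  preds <- as_tibble(preds); gts <- as_tibble(gts)
  if (!"file" %in% names(preds)) preds$file <- "image"
  if (!"file" %in% names(gts)) gts$file <- "image"
  classes <- class %||% eval_classes
  thresholds <- sort(unique(preds$confidence), decreasing = TRUE)
  if (length(thresholds) == 0) thresholds <- 1
  out <- purrr::map_dfr(thresholds, function(thr) {
    counts <- match_dataset(preds, gts, iou_threshold, thr, mode)
    counts$threshold <- thr
    counts
  })
  out <- precision_recall(out[out$class %in% classes, , drop = FALSE])
  out <- out[order(out$class, -out$threshold), c("class", "threshold", "precision",
                                                 "recall", "tp", "fp", "fn")]
  class(out) <- c("pr_curve", class(out))
  out
}

#' Average precision (area under the PR curve)
#'
#' `"all_points"` (default) integrates the monotone precision envelope
#' over the recall increments (the all-points interpolation used in
#' modern detection benchmarks); `"trapezoid"` integrates the raw curve
#' by the trapezoidal rule.
#'
#' @param curve A [pr_curve()] tibble (one or more classes).
#' @param method `"all_points"` or `"trapezoid"`.
#' @return Tibble with `class` and `ap`.
#' @export
average_precision <- function(curve, method = c("all_points", "trapezoid")) {
  method <- match.arg(method)
  curve <- as_tibble(curve)
  if (nrow(curve) == 0) abort("empty PR curve")
  purrr::map_dfr(unique(curve$class), function(cl) {
    cc <- curve[curve$class == cl, , drop = FALSE]
    # recall ascending; ties in natural sweep order (precision descending)
    # so the raw curve never crosses above its monotone envelope
    cc <- cc[order(cc$recall, -cc$precision), , drop = FALSE]
    r <- c(0, cc$recall)
    p <- c(cc$precision[1], cc$precision)
    ap <- if (method == "all_points") {
      # monotone envelope: precision at recall r is the max precision
      # attained at any recall >= r
      env <- rev(cummax(rev(p)))
      sum(diff(r) * env[-1])
    } else {
      sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
    }
    tibble(class = cl, ap = min(max(ap, 0), 1))
  })
}

#' Mean average precision over classes
#'
#' The unweighted mean of the per-class average precisions.
#'
#' @param ap_by_class Tibble with columns `class` and `ap` (from
#'   [average_precision()]), or a numeric vector of APs.
#' @return Single numeric mAP.
#' @export
mean_ap <- function(ap_by_class) {
  ap <- if (is.data.frame(ap_by_class)) ap_by_class$ap else as.numeric(ap_by_class)
  if (length(ap) == 0) abort("no per-class AP values")
  mean(ap)
}

#' Evaluate detections against ground truth
#'
#' End-to-end evaluation: per-class precision and recall at a chosen
#' confidence threshold, the PR curve over the full confidence sweep,
#' per-class AP and the mAP.
#'
#' @inheritParams pr_curve
#' @param conf_threshold Confidence threshold for the single
#'   precision/recall operating point (default 0: all predictions).
#' @param ap_method Passed to [average_precision()].
#' @return An object of class `detection_eval`: list with
#'   `summary` (per-class tibble: tp, fp, fn, precision, recall, ap),
#'   `map`, `curve`, and the evaluation settings.
#' @examples
#' gt <- tibble::tibble(file = "a.png", class = "benign",
#'                      x_min = 10L, y_min = 10L, x_max = 40L, y_max = 30L)
#' pred <- dplyr::mutate(gt, confidence = 0.9)
#' ev <- evaluate_detections(pred, gt)
#' glance(ev)
#' @export
evaluate_detections <- function(preds, gts, iou_threshold = 0.5,
                                conf_threshold = 0,
                                mode = c("standard", "paper_literal"),
                                ap_method = c("all_points", "trapezoid")) {
  mode <- match.arg(mode); ap_method <- match.arg(ap_method)
  preds <- as_tibble(preds); gts <- as_tibble(gts)
  if (!"file" %in% names(preds)) preds$file <- "image"
  if (!"file" %in% names(gts)) gts$file <- "image"
  # only classes that occur in the ground truth or the predictions enter
  # the mAP average; an entirely absent class carries no information
  present <- intersect(eval_classes, union(unique(gts$class), unique(preds$class)))
  if (length(present) == 0) abort("no benign/malignant boxes in ground truth or predictions")
  curve <- pr_curve(preds, gts, class = present, iou_threshold = iou_threshold,
                    mode = mode)
  ap <- average_precision(curve, ap_method)
  point <- precision_recall(match_dataset(preds, gts, iou_threshold,
                                          conf_threshold, mode))
  point <- point[point$class %in% present, , drop = FALSE]
  summary <- dplyr::left_join(point, ap, by = "class")
  structure(list(summary = summary, map = mean_ap(ap), curve = curve,
                 iou_threshold = iou_threshold, conf_threshold = conf_threshold,
                 mode = mode, ap_method = ap_method),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("<detection_eval> IoU > %.2f, mode %s, mAP = %.3f\n",
              x$iou_threshold, x$mode, x$map))
  print(x$summary)
  invisible(x)
}

#' Tidy a detection evaluation
#' @param x A `detection_eval`.
#' @param ... Unused.
#' @return The per-class summary tibble.
#' @export
tidy.detection_eval <- function(x, ...) x$summary

#' One-row summary of a detection evaluation
#' @param x A `detection_eval`.
#' @param ... Unused.
#' @return Tibble with `map`, `n_classes`, `iou_threshold`, `mode`.
#' @export
glance.detection_eval <- function(x, ...) {
  tibble(map = x$map, n_classes = length(unique(x$summary$class)),
         iou_threshold = x$iou_threshold, mode = x$mode)
}

#' Read and write detection predictions
#'
#' Predictions are annotations plus a `confidence` column. Supported
#' dialects: flat CSV and COCO-results-style JSON (an array of
#' `{image_id, category_id, bbox, score}` records; `image_id` may be a
#' file name or an integer id resolvable through a companion
#' annotations JSON).
#'
#' @param preds Prediction tibble (`file`, `class`, box corners,
#'   `confidence`).
#' @param path File path; format inferred from the extension.
#' @param format `"csv"` or `"coco_json"`.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` the prediction tibble.
#' @export
write_predictions <- function(preds, path, format = NULL) {
  format <- format %||% guess_annotation_format(path)
  preds <- as_tibble(preds)
  preds$w <- preds$x_max - preds$x_min
  preds$h <- preds$y_max - preds$y_min
  if (format == "csv") {
    write.csv(preds[c(annotation_cols, "confidence")], path, row.names = FALSE)
  } else {
    recs <- purrr::pmap(list(preds$file, preds$class, preds$x_min, preds$y_min,
                             preds$w, preds$h, preds$confidence),
                        function(f, cl, x, y, w, h, s) {
                          list(image_id = f,
                               category_id = unname(coco_category_ids[[cl]]),
                               bbox = c(x, y, w, h), score = s)
                        })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path, format = NULL) {
  format <- format %||% guess_annotation_format(path)
  if (!file.exists(path)) abort(paste0("predictions file not found: ", path))
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(c(annotation_cols, "confidence"), names(df))
    if (length(missing)) abort(paste0("prediction CSV ", path, " lacks fields: ", paste(missing, collapse = ", ")))
    out <- as_tibble(df[c(annotation_cols, "confidence")])
  } else {
    recs <- jsonlite::read_json(path)
    class_by_id <- setNames(names(coco_category_ids), coco_category_ids)
    out <- purrr::map_dfr(recs, function(a) {
      b <- as.numeric(unlist(a$bbox))
      tibble(file = as.character(a$image_id),
             class = unname(class_by_id[[as.character(a$category_id)]]),
             x_min = as.integer(b[1]), y_min = as.integer(b[2]),
             x_max = as.integer(b[1] + b[3]), y_max = as.integer(b[2] + b[4]),
             w = as.integer(b[3]), h = as.integer(b[4]),
             confidence = as.numeric(a$score))
    })
  }
  out
}

#' Build oracle predictions from ground-truth annotations
#'
#' Turns each ground-truth box into a prediction with the given
#' confidence, optionally jittered: each corner is shifted by a uniform
#' offset up to `jitter` pixels (clamped to stay a valid box), which
#' drives the IoU against the source box below the matching threshold
#' once the jitter is large relative to the box size. Used to exercise
#' the evaluation chain without an external detector.
#'
#' @param gts Ground-truth annotation tibble.
#' @param confidence Confidence assigned to every prediction.
#' @param jitter Maximum absolute per-corner shift in pixels.
#' @param seed RNG seed used when `jitter > 0`.
#' @return Prediction tibble.
#' @export
oracle_predictions <- function(gts, confidence = 1, jitter = 0, seed = 1L) {
  preds <- as_tibble(gts)
  preds$confidence <- confidence
  if (jitter > 0) {
    set.seed(seed)
    n <- nrow(preds)
    sh <- function() as.integer(round(runif(n, -jitter, jitter)))
    preds$x_min <- preds$x_min + sh(); preds$x_max <- preds$x_max + sh()
    preds$y_min <- preds$y_min + sh(); preds$y_max <- preds$y_max + sh()
    preds$x_max <- pmax(preds$x_max, preds$x_min)
    preds$y_max <- pmax(preds$y_max, preds$y_min)
    preds$w <- preds$x_max - preds$x_min
    preds$h <- preds$y_max - preds$y_min
  }
  preds
}
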