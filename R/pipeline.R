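#' Split a dataset into train / validation / test
#'
#' Random, seed-reproducible partition with sizes proportional to
#' `ratios` (largest-remainder rounding), following the 8:1:1 recipe
#' used for the real breast-ultrasound collections. With
#' `stratify_by_class` the split is computed per class and combined, so
#' each part's class mix deviates from the global one by at most one
#' item per class.
#'
#' @param item_ids Character or integer vector of item identifiers.
#' @param ratios Length-3 positive vector (train, validation, test);
#'   normalized internally. Default `c(8, 1, 1)`.
#' @param seed RNG seed.
#' @param stratify_by_class Optional vector of class labels aligned
#'   with `item_ids`; `NULL` disables stratification.
#' @return A tibble with columns `id` and `split`
#'   (`train`/`validation`/`test`), one row per input id.
#' @examples
#' split_dataset(sprintf("img%02d", 1:10), seed = 1)
#' @export
split_dataset <- function(item_ids, ratios = c(8, 1, 1), seed = 1L,
                          stratify_by_class = NULL) {
  if (length(item_ids) == 0) abort("cannot split an empty id set")
  stopifnot(length(ratios) == 3, all(ratios > 0))
  if (!is.null(stratify_by_class)) {
    stopifnot(length(stratify_by_class) == length(item_ids))
    set.seed(seed)
    parts <- lapply(split(item_ids, stratify_by_class), function(ids) {
      split_ids(ids, ratios)
    })
    out <- dplyr::bind_rows(parts)
    return(out[match(item_ids, out$id), ])
  }
  set.seed(seed)
  out <- split_ids(item_ids, ratios)
  out[match(item_ids, out$id), ]
}

# largest-remainder apportionment of n items to 3 parts, then a
# seeded shuffle assigns ids to parts
split_ids <- function(ids, ratios) {
  n <- length(ids)
  p <- ratios / sum(ratios)
  base <- floor(n * p)
  rem <- n * p - base
  left <- n - sum(base)
  if (left > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[give] <- base[give] + 1
  }
  shuffled <- if (n == 1) ids else sample(ids)
  split_names <- c("train", "validation", "test")
  tibble(id = shuffled,
         split = rep(split_names, times = base))
}

#' Rescale a bounding box between image sizes
#'
#' Maps detection boxes produced on a resized image back to
#' original-image coordinates (or any size-to-size rescale): corners
#' are scaled by the per-axis size ratio, rounded to the nearest
#' integer and clamped into the target frame. A remap followed by the
#' inverse remap moves each corner by at most one pixel.
#'
#' @param boxes Tibble with `x_min`, `y_min`, `x_max`, `y_max` (extra
#'   columns pass through; `w`, `h` are recomputed).
#' @param from_size,to_size Length-2 `(height, width)` vectors.
#' @return The rescaled boxes tibble.
#' @export
remap_box <- function(boxes, from_size, to_size) {
  stopifnot(length(from_size) == 2, length(to_size) == 2,
            all(from_size > 0), all(to_size > 0))
  boxes <- as_tibble(boxes)
  sy <- to_size[1] / from_size[1]
  sx <- to_size[2] / from_size[2]
  clamp <- function(v, hi) pmin(pmax(as.integer(round(v)), 0L), as.integer(hi) - 1L)
  out <- boxes
  out$x_min <- clamp(boxes$x_min * sx, to_size[2])
  out$x_max <- clamp(boxes$x_max * sx, to_size[2])
  out$y_min <- clamp(boxes$y_min * sy, to_size[1])
  out$y_max <- clamp(boxes$y_max * sy, to_size[1])
  if ("w" %in% names(out)) out$w <- out$x_max - out$x_min
  if ("h" %in% names(out)) out$h <- out$y_max - out$y_min
  out
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end chain: phantom generation (or
#' an existing dataset directory), the 8:1:1 split, CLAHE + diffusion
#' enhancement, segmenter training, segmentation-based enhancement, and
#' detection evaluation against an external predictions file.
#'
#' @param out_dir Output directory for all artifacts.
#' @param data_dir Existing dataset directory (images + `_mask.png`
#'   masks + `annotations.csv`); `NULL` to generate phantoms.
#' @param n_phantoms Number of phantoms to generate when `data_dir` is
#'   `NULL`.
#' @param phantom_size Phantom image side in pixels.
#' @param split_ratios Train/validation/test ratios.
#' @param image_size Working (resized) image side for the segmenter.
#' @param clahe A [clahe_params()].
#' @param diffusion A [diffusion_params()].
#' @param sbe An [sbe_params()].
#' @param segmenter `"train"` to train the R2AttU-Net on the training
#'   split, `"oracle"` to use the ground-truth masks (isolates the
#'   evaluation chain from segmentation quality).
#' @param seg A [seg_config()]; its `input_size` must equal
#'   `image_size`.
#' @param seg_train A [train_config()].
#' @param sbe_on `"preprocessed"` (default) multiplies the SBE weight
#'   map with the CLAHE+diffused image; `"original"` multiplies the
#'   original image.
#' @param predictions Path to a predictions file (CSV or COCO-results
#'   JSON), or a prediction tibble, or `"oracle"` to evaluate
#'   ground-truth-derived perfect predictions; `NULL` skips evaluation.
#' @param iou_threshold,conf_threshold,eval_mode,ap_method Evaluation
#'   settings (see [evaluate_detections()]).
#' @param seed Master seed for every random stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            data_dir = NULL,
                            n_phantoms = 50,
                            phantom_size = 128,
                            split_ratios = c(8, 1, 1),
                            image_size = 64,
                            clahe = clahe_params(tiles_per_side = 4),
                            diffusion = diffusion_params(n_iterations = 10),
                            sbe = sbe_params(),
                            segmenter = c("train", "oracle"),
                            seg = seg_config(input_size = 64),
                            seg_train = train_config(epochs = 30),
                            sbe_on = c("preprocessed", "original"),
                            predictions = "oracle",
                            iou_threshold = 0.5,
                            conf_threshold = 0,
                            eval_mode = "standard",
                            ap_method = "all_points",
                            seed = 1L) {
  segmenter <- match.arg(segmenter)
  sbe_on <- match.arg(sbe_on)
  if (segmenter == "train" && seg$input_size != image_size) {
    abort("seg_config input_size must equal the pipeline image_size")
  }
  structure(list(out_dir = out_dir, data_dir = data_dir,
                 n_phantoms = as.integer(n_phantoms),
                 phantom_size = as.integer(phantom_size),
                 split_ratios = split_ratios, image_size = as.integer(image_size),
                 clahe = clahe, diffusion = diffusion, sbe = sbe,
                 segmenter = segmenter, seg = seg, seg_train = seg_train,
                 sbe_on = sbe_on, predictions = predictions,
                 iou_threshold = iou_threshold, conf_threshold = conf_threshold,
                 eval_mode = eval_mode, ap_method = ap_method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments;
#' nested blocks `clahe`, `diffusion`, `sbe`, `seg`, `seg_train` map
#' onto the corresponding parameter constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("clahe", "diffusion", "sbe", "seg", "seg_train"))]
  # [[ ]] avoids partial matching (e.g. "seg" must not pick up "segmenter")
  if (!is.null(y[["clahe"]])) args$clahe <- do.call(clahe_params, y[["clahe"]])
  if (!is.null(y[["diffusion"]])) args$diffusion <- do.call(diffusion_params, y[["diffusion"]])
  if (!is.null(y[["sbe"]])) args$sbe <- do.call(sbe_params, y[["sbe"]])
  if (!is.null(y[["seg"]])) args$seg <- do.call(seg_config, y[["seg"]])
  if (!is.null(y[["seg_train"]])) args$seg_train <- do.call(train_config, y[["seg_train"]])
  do.call(pipeline_config, args)
}

#' Run the full detection pipeline
#'
#' Stages: (1) generate phantoms or load an existing dataset; (2)
#' 8:1:1-style split; (3) CLAHE + anisotropic diffusion on every image;
#' (4) lesion segmentation (trained R2AttU-Net or oracle masks); (5)
#' segmentation-based enhancement; (6) detection labels from the
#' ground-truth masks; (7) evaluation of external (or oracle)
#' predictions in original-image coordinates. Every stage appends a
#' record (stage, parameters, seed, output hashes) to
#' `<out_dir>/pipeline_log.json`; the evaluation report is written to
#' `<out_dir>/report.json` with the PR curve as `pr_curve.csv`. Reports
#' contain no timestamps, so a rerun with the same configuration and
#' seed is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `manifest`, `splits`,
#'   `labels`, `evaluation` (a `detection_eval` or `NULL`), `report`
#'   (path), and `fit` (the `seg_fit` when the segmenter was trained).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  for (d in file.path(out_dir, c("", "enhanced", "masks", "sbe"))) {
    if (!dir.exists(d)) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  log_path <- file.path(out_dir, "pipeline_log.json")
  if (file.exists(log_path)) unlink(log_path)
  log_stage <- function(stage, params, outputs = character()) {
    rec <- list(stage = stage, seed = config$seed, params = params,
                outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  }

  # stage 1: data
  if (is.null(config$data_dir)) {
    specs <- lapply(seq_len(config$n_phantoms), function(i) {
      phantom_spec(height = config$phantom_size, width = config$phantom_size,
                   lesion_class = if (i %% 2 == 0) "malignant" else "benign",
                   n_lesions = 1L + (i %% 5 == 0), seed = i)
    })
    manifest <- generate_dataset(specs, out_dir = file.path(out_dir, "data"),
                                 seed = config$seed)
    data_dir <- file.path(out_dir, "data")
  } else {
    data_dir <- config$data_dir
    manifest <- as_tibble(read.csv(file.path(data_dir, "manifest.csv"),
                                   stringsAsFactors = FALSE))
  }
  log_stage("data", list(n = nrow(manifest), dir = data_dir),
            file.path(data_dir, "annotations.csv"))

  # stage 2: split
  splits <- split_dataset(manifest$stem, config$split_ratios, seed = config$seed,
                          stratify_by_class = manifest$class)
  write.csv(splits, file.path(out_dir, "splits.csv"), row.names = FALSE)
  log_stage("split", list(ratios = config$split_ratios),
            file.path(out_dir, "splits.csv"))

  # stage 3: enhancement (CLAHE + diffusion)
  enhanced <- list()
  for (i in seq_len(nrow(manifest))) {
    img <- read_gray_image(manifest$image[i])
    enh <- preprocess(img, config$clahe, config$diffusion)
    enhanced[[manifest$stem[i]]] <- enh
    write_gray_image(enh, file.path(out_dir, "enhanced", paste0(manifest$stem[i], ".png")))
  }
  log_stage("enhance",
            list(clahe = unclass(config$clahe), diffusion = unclass(config$diffusion)),
            file.path(out_dir, "enhanced", paste0(manifest$stem, ".png")))

  # stage 4: segmentation masks
  fit <- NULL
  pred_masks <- list()
  if (config$segmenter == "train") {
    train_stems <- splits$id[splits$split == "train"]
    train_samples <- lapply(train_stems, function(stem) {
      i <- match(stem, manifest$stem)
      list(image = enhanced[[stem]], mask = read_mask(manifest$mask[i]))
    })
    fit <- train_segmentation(train_samples, config$seg, config$seg_train)
    for (stem in manifest$stem) {
      pred_masks[[stem]] <- predict_mask(fit$model, enhanced[[stem]])
    }
  } else {
    for (i in seq_len(nrow(manifest))) {
      pred_masks[[manifest$stem[i]]] <- read_mask(manifest$mask[i])
    }
  }
  for (stem in manifest$stem) {
    write_mask(pred_masks[[stem]], file.path(out_dir, "masks", paste0(stem, ".png")))
  }
  log_stage("segment", list(segmenter = config$segmenter,
                            seg = unclass(config$seg)),
            file.path(out_dir, "masks", paste0(manifest$stem, ".png")))

  # stage 5: SBE
  for (i in seq_len(nrow(manifest))) {
    stem <- manifest$stem[i]
    base <- if (config$sbe_on == "preprocessed") enhanced[[stem]] else read_gray_image(manifest$image[i])
    out <- sbe_apply(base, pred_masks[[stem]], config$sbe)
    write_gray_image(out, file.path(out_dir, "sbe", paste0(stem, ".png")))
  }
  log_stage("sbe", list(params = unclass(config$sbe), on = config$sbe_on),
            file.path(out_dir, "sbe", paste0(manifest$stem, ".png")))

  # stage 6: detection labels from ground-truth masks (original coordinates)
  labels <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    mask <- read_mask(manifest$mask[i])
    labs <- mask_to_labels(mask, manifest$class[i], per_component = TRUE)
    if (nrow(labs) > 0) labs <- dplyr::bind_cols(tibble(file = paste0(manifest$stem[i], ".png")), labs)
    labs
  })
  write_annotations(labels, file.path(out_dir, "labels.csv"))
  log_stage("labels", list(per_component = TRUE), file.path(out_dir, "labels.csv"))

  # stage 7: evaluation
  evaluation <- NULL
  report_path <- NULL
  if (!is.null(config$predictions)) {
    preds <- if (is.data.frame(config$predictions)) {
      as_tibble(config$predictions)
    } else if (identical(config$predictions, "oracle")) {
      oracle_predictions(labels, confidence = 1)
    } else {
      if (!file.exists(config$predictions)) {
        abort(paste0("evaluation stage: predictions file not found: ", config$predictions))
      }
      read_predictions(config$predictions)
    }
    evaluation <- evaluate_detections(preds, labels,
                                      iou_threshold = config$iou_threshold,
                                      conf_threshold = config$conf_threshold,
                                      mode = config$eval_mode,
                                      ap_method = config$ap_method)
    report_path <- file.path(out_dir, "report.json")
    report <- list(map = evaluation$map,
                   per_class = evaluation$summary,
                   settings = list(iou_threshold = config$iou_threshold,
                                   conf_threshold = config$conf_threshold,
                                   mode = config$eval_mode,
                                   ap_method = config$ap_method,
                                   seed = config$seed))
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    write.csv(evaluation$curve, file.path(out_dir, "pr_curve.csv"), row.names = FALSE)
    log_stage("evaluate", report$settings,
              c(report_path, file.path(out_dir, "pr_curve.csv")))
  }

  structure(list(manifest = manifest, splits = splits, labels = labels,
                 evaluation = evaluation, report = report_path, fit = fit),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d image(s), %d label(s)%s\n",
              nrow(x$manifest), nrow(x$labels),
              if (is.null(x$evaluation)) "" else sprintf(", mAP = %.3f", x$evaluation$map)))
  invisible(x)
}
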