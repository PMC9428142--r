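#' Bounding boxes from lesion masks
#'
#' A detection label is the tight axis-aligned bounding box of the
#' non-zero pixels of a binary lesion mask plus the lesion class. Boxes
#' use 0-based inclusive pixel coordinates with `x` = column and
#' `y` = row; following the field's labelling convention for these
#' boxes, width and height are stored as `w = x_max - x_min` and
#' `h = y_max - y_min` (no `+ 1`). Overlap areas for IoU are computed
#' internally on the inclusive pixel grid, i.e. `(w + 1) * (h + 1)`.
#'
#' `mask_to_bbox()` scans all non-zero pixels and returns the extreme
#' coordinates as a one-row tibble (`x_min`, `y_min`, `x_max`, `y_max`,
#' `w`, `h`), or `NULL` for an all-zero mask (a segmenter can miss the
#' lesion entirely). `mask_to_labels()` adds the class column and,
#' with `per_component = TRUE`, boxes each 8-connected component
#' independently (multi-lesion images).
#'
#' @param mask Binary matrix in `{0, 1}`.
#' @param lesion_class `"benign"` or `"malignant"`.
#' @param per_component If `TRUE`, one label per 8-connected component;
#'   if `FALSE`, a single label spanning all non-zero pixels.
#' @return `mask_to_bbox()`: a one-row tibble or `NULL`.
#'   `mask_to_labels()`: a tibble with columns `class`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `w`, `h` (zero rows for an empty mask).
#' @examples
#' m <- matrix(0L, 16, 16); m[5:8, 3:6] <- 1L
#' mask_to_bbox(m)
#' mask_to_labels(m, "benign")
#' @export
mask_to_bbox <- function(mask) {
  assert_binary_mask(mask)
  nz <- which(mask != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(NULL)
  x <- nz[, 2L] - 1L # 0-based column
  y <- nz[, 1L] - 1L # 0-based row
  bbox_tbl(min(x), min(y), max(x), max(y))
}

bbox_tbl <- function(x_min, y_min, x_max, y_max) {
  tibble(x_min = as.integer(x_min), y_min = as.integer(y_min),
         x_max = as.integer(x_max), y_max = as.integer(y_max),
         w = as.integer(x_max - x_min), h = as.integer(y_max - y_min))
}

#' @rdname mask_to_bbox
#' @export
mask_to_labels <- function(mask, lesion_class, per_component = TRUE) {
  assert_binary_mask(mask)
  lesion_class <- match.arg(lesion_class, c("benign", "malignant"))
  empty <- tibble(class = character(),
                  x_min = integer(), y_min = integer(),
                  x_max = integer(), y_max = integer(),
                  w = integer(), h = integer())
  if (!any(mask != 0)) return(empty)
  if (!per_component) {
    b <- mask_to_bbox(mask)
    return(dplyr::bind_cols(tibble(class = lesion_class), b))
  }
  lab <- label_components(mask)
  purrr::map_dfr(seq_len(max(lab)), function(k) {
    b <- mask_to_bbox(matrix(as.integer(lab == k), nrow(mask), ncol(mask)))
    dplyr::bind_cols(tibble(class = lesion_class), b)
  })
}

#' Label connected components of a binary mask
#'
#' 8-connectivity labelling (diagonal neighbours belong to the same
#' component), as used to separate multiple lesions in one image.
#'
#' @param mask Binary matrix in `{0, 1}`.
#' @return Integer matrix of labels `0` (background), `1..n`.
#' @export
label_components <- function(mask) {
  assert_binary_mask(mask)
  label_components_cpp(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
}

annotation_cols <- c("file", "class", "x_min", "y_min", "x_max", "y_max", "w", "h")

coco_category_ids <- c(benign = 1L, malignant = 2L)

#' Read and write detection annotations
#'
#' Annotations are a tibble with one row per box: `file` (image file
#' name), `class` (`benign`/`malignant`), corner coordinates `x_min`,
#' `y_min`, `x_max`, `y_max` and the derived `w`, `h`. Two dialects are
#' supported: a flat CSV and a COCO-style JSON document with `images`,
#' `annotations` and `categories` tables (categories: benign = 1,
#' malignant = 2; boxes encoded `[x_min, y_min, w, h]`, losslessly
#' convertible back to corners). `read_annotations(write_annotations(x))`
#' reproduces `x`.
#'
#' @param labels Annotation tibble as above. For JSON, an optional
#'   `height`/`width` column pair per image is stored in `images`.
#' @param path Output/input file; format inferred from the extension
#'   (`.csv` or `.json`) unless `format` is given.
#' @param format `"csv"` or `"coco_json"`.
#' @param image_sizes Optional named list `file -> c(height, width)`
#'   recorded in the COCO `images` table (defaults to 0 when unknown).
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` returns the annotation tibble (images listed
#'   in a COCO file but carrying no boxes contribute zero rows).
#' @export
write_annotations <- function(labels, path, format = NULL, image_sizes = NULL) {
  format <- format %||% guess_annotation_format(path)
  labels <- as_tibble(labels)
  missing <- setdiff(setdiff(annotation_cols, c("w", "h")), names(labels))
  if (length(missing)) abort(paste0("annotations lack columns: ", paste(missing, collapse = ", ")))
  labels$w <- labels$x_max - labels$x_min
  labels$h <- labels$y_max - labels$y_min
  if (format == "csv") {
    write.csv(labels[annotation_cols], path, row.names = FALSE)
  } else {
    files <- unique(labels$file)
    if (!is.null(image_sizes)) files <- unique(c(files, names(image_sizes)))
    size_of <- function(f) {
      s <- image_sizes[[f]]
      if (is.null(s)) c(0L, 0L) else as.integer(s)
    }
    images <- purrr::imap(files, function(f, i) {
      s <- size_of(f)
      list(id = i, file_name = f, height = s[[1]], width = s[[2]])
    })
    ann <- purrr::pmap(list(seq_len(nrow(labels)), labels$file, labels$class,
                            labels$x_min, labels$y_min, labels$w, labels$h),
                       function(i, f, cl, x, y, w, h) {
                         list(id = i, image_id = match(f, files),
                              category_id = unname(coco_category_ids[[cl]]),
                              bbox = c(x, y, w, h), iscrowd = 0L, area = (w + 1) * (h + 1))
                       })
    cats <- purrr::imap(names(coco_category_ids), function(nm, i) {
      list(id = unname(coco_category_ids[[nm]]), name = nm, supercategory = "lesion")
    })
    jsonlite::write_json(list(images = images, annotations = ann, categories = cats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, format = NULL) {
  format <- format %||% guess_annotation_format(path)
  if (format == "csv") {
    df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) abort(paste0("cannot parse annotation CSV ", path, ": ", conditionMessage(e))))
    missing <- setdiff(annotation_cols, names(df))
    if (length(missing)) abort(paste0("annotation CSV ", path, " lacks fields: ", paste(missing, collapse = ", ")))
    out <- as_tibble(df[annotation_cols])
  } else {
    doc <- tryCatch(jsonlite::read_json(path),
                    error = function(e) abort(paste0("cannot parse annotation JSON ", path, ": ", conditionMessage(e))))
    for (field in c("images", "annotations", "categories")) {
      if (is.null(doc[[field]])) abort(paste0("annotation JSON ", path, " lacks field '", field, "'"))
    }
    file_by_id <- setNames(purrr::map_chr(doc$images, "file_name"),
                           purrr::map_int(doc$images, "id"))
    class_by_id <- setNames(purrr::map_chr(doc$categories, "name"),
                            purrr::map_int(doc$categories, "id"))
    out <- purrr::map_dfr(doc$annotations, function(a) {
      b <- as.numeric(unlist(a$bbox))
      tibble(file = unname(file_by_id[[as.character(a$image_id)]]),
             class = unname(class_by_id[[as.character(a$category_id)]]),
             x_min = as.integer(b[1]), y_min = as.integer(b[2]),
             x_max = as.integer(b[1] + b[3]), y_max = as.integer(b[2] + b[4]),
             w = as.integer(b[3]), h = as.integer(b[4]))
    })
    if (nrow(out) == 0L) {
      out <- tibble(file = character(), class = character(),
                    x_min = integer(), y_min = integer(),
                    x_max = integer(), y_max = integer(),
                    w = integer(), h = integer())
    }
  }
  out$class <- as.character(out$class)
  for (cc in c("x_min", "y_min", "x_max", "y_max", "w", "h")) out[[cc]] <- as.integer(out[[cc]])
  out
}

guess_annotation_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         csv = "csv",
         json = "coco_json",
         abort(paste0("cannot infer annotation format from extension of ", path)))
}
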