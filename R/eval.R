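#' Write a label mask as an 8-bit grayscale PNG
#'
#' Label values 0..K (0 = background) and the ignore sentinel 255 are stored
#' verbatim in the 8-bit channel, so round trips are lossless.
#'
#' @param mask integer matrix with values in 0..255.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  v <- as.vector(mask)
  if (any(is.na(v)) || any(v != round(v)) || any(v < 0) || any(v > 255))
    stop("mask values must be integers in 0..255")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param path PNG file. Must be single-channel grayscale; an RGB mask
#'   without a palette mapping is rejected.
#' @param n_classes optional class count K; when given, values outside
#'   \{0..K, 255\} raise a validation error.
#' @return integer matrix of label values.
#' @export
read_mask <- function(path, n_classes = NULL) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L)
    stop("mask PNG must be single-channel grayscale, got ", dim(x)[3],
         " channels (RGB masks without a palette mapping are not supported)")
  m <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  if (!is.null(n_classes)) {
    bad <- setdiff(unique(as.vector(m)), c(0:n_classes, 255L))
    if (length(bad))
      stop("mask contains values outside {0..", n_classes, ", 255}: ",
           paste(bad, collapse = ", "))
  }
  m
}

#' Per-class confusion counts with ignore and background exclusion
#'
#' Pixels whose ground truth is 255 or belongs to \code{excluded} (by default
#' the background class 0) are removed from scoring entirely: they produce
#' neither true/false positives nor false negatives for any class. This is
#' the evaluation protocol in which the background region is not part of the
#' calculation area.
#'
#' @param pred,gt integer label matrices of equal shape, values in
#'   \{0..K, 255\}.
#' @param n_classes foreground class count K.
#' @param excluded integer vector of ground-truth labels removed from scoring
#'   (default 0; use \code{integer(0)} to score the background too).
#' @return list with per-class \code{tp}, \code{fp}, \code{fn} (named by
#'   class id) and \code{valid_pixel_count}.
#' @export
confusion <- function(pred, gt, n_classes, excluded = 0L) {
  if (!all(dim(pred) == dim(gt))) stop("pred and gt shapes differ")
  classes <- setdiff(0:n_classes, excluded)
  keep <- gt != 255L & !(gt %in% excluded)
  p <- pred[keep]; g <- gt[keep]
  tp <- fp <- fn <- stats::setNames(integer(length(classes)),
                                    as.character(classes))
  for (k in classes) {
    kk <- as.character(k)
    tp[kk] <- sum(p == k & g == k)
    fp[kk] <- sum(p == k & g != k)
    fn[kk] <- sum(p != k & g == k)
  }
  list(tp = tp, fp = fp, fn = fn, valid_pixel_count = sum(keep))
}

# merge confusion counts across images
confusion_add <- function(a, b) {
  if (is.null(a)) return(b)
  list(tp = a$tp + b$tp, fp = a$fp + b$fp, fn = a$fn + b$fn,
       valid_pixel_count = a$valid_pixel_count + b$valid_pixel_count)
}

#' Mean intersection-over-union from confusion counts
#'
#' IoU_k = TP / (TP + FP + FN) per class; classes never seen in either the
#' prediction or the ground truth (TP + FP + FN = 0) are dropped from the
#' mean with a message rather than scored as zero.
#'
#' @param counts output of [confusion()].
#' @return list of class \code{camseg_eval} with \code{per_class_iou},
#'   \code{miou} and \code{classes_scored}.
#' @export
miou <- function(counts) {
  denom <- counts$tp + counts$fp + counts$fn
  scor <- denom > 0
  if (!any(scor)) stop("no class has any scorable pixel (all TP+FP+FN are 0)")
  if (any(!scor))
    message("classes dropped from mIoU (no pixels in pred or gt): ",
            paste(names(denom)[!scor], collapse = ", "))
  iou <- counts$tp[scor] / denom[scor]
  structure(list(per_class_iou = iou, miou = mean(iou),
                 classes_scored = as.integer(names(denom)[scor])),
            class = "camseg_eval")
}

#' @export
print.camseg_eval <- function(x, ...) {
  cat("mIoU:", format(x$miou, digits = 4), "over classes",
      paste(x$classes_scored, collapse = ", "), "\n")
  for (i in seq_along(x$per_class_iou))
    cat(sprintf("  class %s IoU: %.4f\n", names(x$per_class_iou)[i],
                x$per_class_iou[i]))
  invisible(x)
}

#' Alpha-blend a label map over an image for inspection
#'
#' @param image H x W x 3 integer array (0..255).
#' @param labels H x W integer label matrix; 255 pixels stay transparent.
#' @param palette (K+1) x 3 RGB matrix, row 1 = label 0.
#' @param alpha blend weight of the palette colour (default 0.5).
#' @return H x W x 3 integer array.
#' @export
render_overlay <- function(image, labels, palette, alpha = 0.5) {
  if (!all(dim(image)[1:2] == dim(labels))) stop("image/labels shapes differ")
  out <- array(0L, dim(image))
  vis <- labels != 255L
  for (ch in 1:3) {
    plane <- image[, , ch]
    col <- matrix(0, nrow(labels), ncol(labels))
    col[vis] <- palette[labels[vis] + 1L, ch]
    plane[vis] <- round(alpha * col[vis] + (1 - alpha) * plane[vis])
    out[, , ch] <- as.integer(plane)
  }
  out
}

#' Evaluate a directory of predicted masks against ground truth
#'
#' File names are matched between the two directories. Aggregation pools
#' confusion counts over all pixels by default; \code{per_image = TRUE}
#' averages per-image mIoU instead.
#'
#' @param pred_dir,gt_dir directories of grayscale PNG masks with matching
#'   file names.
#' @param n_classes foreground class count K.
#' @param out_json,out_csv optional output paths for the summary JSON and a
#'   per-image CSV breakdown.
#' @param excluded ground-truth labels excluded from scoring (default 0).
#' @param per_image average per-image mIoU instead of pooling pixels.
#' @return \code{camseg_eval} for the pooled (or averaged) result.
#' @export
evaluate_predictions <- function(pred_dir, gt_dir, n_classes,
                                 out_json = NULL, out_csv = NULL,
                                 excluded = 0L, per_image = FALSE) {
  files <- intersect(list.files(pred_dir, pattern = "\\.png$"),
                     list.files(gt_dir, pattern = "\\.png$"))
  if (!length(files)) stop("no matching mask files between directories")
  pooled <- NULL
  rows <- list()
  per_image_miou <- numeric(0)
  for (f in files) {
    pred <- read_mask(file.path(pred_dir, f))
    gt <- read_mask(file.path(gt_dir, f))
    cc <- confusion(pred, gt, n_classes, excluded)
    pooled <- confusion_add(pooled, cc)
    mi <- tryCatch(suppressMessages(miou(cc)$miou), error = function(e) NA_real_)
    per_image_miou <- c(per_image_miou, mi)
    rows[[f]] <- data.frame(filename = f, miou = mi,
                            valid_pixels = cc$valid_pixel_count)
  }
  res <- suppressMessages(miou(pooled))
  if (per_image) res$miou <- mean(per_image_miou, na.rm = TRUE)
  if (!is.null(out_csv))
    utils::write.csv(do.call(rbind, rows), out_csv, row.names = FALSE)
  if (!is.null(out_json))
    jsonlite::write_json(list(per_class_iou = as.list(res$per_class_iou),
                              miou = res$miou, n_images = length(files),
                              excluded_labels = as.integer(excluded)),
                         out_json, auto_unbox = TRUE, digits = NA)
  res
}
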