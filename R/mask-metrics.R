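#' Threshold a probability map into a binary segmentation mask
#'
#' A probability map assigns each pixel a vessel likelihood in \[0, 1\].
#' Thresholding labels every pixel whose value is greater than or equal to
#' `t` as vessel (1) and every other pixel as background (0). The inclusive
#' rule means that on an 8-bit grayscale source (values `v / 255`) the
#' default threshold of 0.5 keeps pixels with raw intensity 128 and above.
#'
#' @param map Numeric matrix with all values in \[0, 1\] (rows = image rows).
#' @param t Threshold in \[0, 1\]. Default 0.5.
#' @return Integer matrix of the same dimensions with values in \{0, 1\}.
#' @examples
#' threshold_map(matrix(c(0.49, 0, 0.5, 1), 2, 2))
#' @export
threshold_map <- function(map, t = 0.5) {
  map <- as_probability_map(map)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stop("`t` must be a single number in [0, 1]", call. = FALSE)
  out <- matrix(as.integer(map >= t), nrow = nrow(map), ncol = ncol(map))
  out
}

# Validate and coerce a probability map; tolerates integer matrices of 0/1.
as_probability_map <- function(map) {
  if (!is.matrix(map) || !is.numeric(map))
    stop("a probability map must be a numeric matrix", call. = FALSE)
  if (length(map) == 0L)
    stop("empty probability map", call. = FALSE)
  if (anyNA(map) || any(map < 0) || any(map > 1))
    stop("probability-map values must lie in [0, 1]", call. = FALSE)
  storage.mode(map) <- "double"
  map
}

# Validate a binary mask (0/1 matrix).
as_binary_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (length(mask) == 0L)
    stop(what, " is empty", call. = FALSE)
  if (anyNA(mask) || !all(mask %in% c(0, 1)))
    stop(what, " must contain only 0 (background) and 1 (vessel)", call. = FALSE)
  storage.mode(mask) <- "integer"
  mask
}

#' Per-pixel confusion counts between a predicted and a ground-truth mask
#'
#' Tallies true/false positives and negatives over the whole image, or over
#' an optional region-of-interest mask (pixels where `roi == 1`). The vessel
#' class (1) is the positive class.
#'
#' @param pred,truth Binary (0/1) matrices of identical dimensions.
#' @param roi Optional binary matrix of the same dimensions; pixels outside
#'   the ROI are excluded from every count.
#' @return A list of class `confusion_counts` with integer fields
#'   `tp`, `fp`, `tn`, `fn` and `n` (pixels evaluated).
#' @export
confusion_counts <- function(pred, truth, roi = NULL) {
  pred  <- as_binary_mask(pred, "pred")
  truth <- as_binary_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth dimensions differ", call. = FALSE)
  if (!is.null(roi)) {
    roi <- as_binary_mask(roi, "roi")
    if (!identical(dim(roi), dim(pred)))
      stop("roi dimensions differ from pred/truth", call. = FALSE)
    keep <- roi == 1L
    pred <- pred[keep]
    truth <- truth[keep]
  }
  out <- list(
    tp = sum(pred == 1L & truth == 1L),
    fp = sum(pred == 1L & truth == 0L),
    tn = sum(pred == 0L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L)
  )
  out$n <- out$tp + out$fp + out$tn + out$fn
  class(out) <- "confusion_counts"
  out
}

#' Objective segmentation metrics from confusion counts
#'
#' Computes the standard full-reference, pixel-wise metrics used to evaluate
#' vessel segmentation: accuracy, sensitivity (recall), specificity,
#' precision, F1 score, and the Matthews correlation coefficient (MCC).
#' Ratio metrics with a zero denominator are reported as `NA` and flagged in
#' `undefined`; the MCC is reported as 0 whenever any factor of its
#' denominator is zero (the usual convention), also with a flag.
#'
#' @param counts A `confusion_counts` object, or a list/vector with fields
#'   `tp`, `fp`, `tn`, `fn`.
#' @return A list of class `metric_set` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1`, `mcc`, and a logical
#'   vector `undefined` naming the metrics whose denominator vanished.
#' @examples
#' # class imbalance: an all-background prediction on 10% vessel pixels
#' compute_metrics(list(tp = 0, fp = 0, tn = 90, fn = 10))
#' @export
compute_metrics <- function(counts) {
  cc <- lapply(counts[c("tp", "fp", "tn", "fn")], as.numeric)
  if (anyNA(unlist(cc)) || any(unlist(cc) < 0))
    stop("confusion counts must be non-negative numbers", call. = FALSE)
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop("all confusion counts are zero", call. = FALSE)

  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    accuracy    = (tp + tn) / n,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision   = ratio(tp, tp + fp),
    f1          = ratio(2 * tp, 2 * tp + fp + fn)
  )
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  out$mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else 0
  out$undefined <- c(
    accuracy = FALSE,
    sensitivity = is.na(out$sensitivity),
    specificity = is.na(out$specificity),
    precision = is.na(out$precision),
    f1 = is.na(out$f1),
    mcc = mcc_den == 0
  )
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, ...) {
  vals <- unlist(x[c("accuracy", "sensitivity", "specificity",
                     "precision", "f1", "mcc")])
  print(round(vals, 4))
  if (any(x$undefined))
    cat("undefined (zero denominator):",
        paste(names(x$undefined)[x$undefined], collapse = ", "), "\n")
  invisible(x)
}

#' Read a grayscale PNG as a probability map
#'
#' Integer PNG intensities of bit depth d are mapped onto \[0, 1\] as
#' `v / (2^d - 1)`. Multi-channel images are reduced to their first channel.
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_probability_map <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  as_probability_map(img)
}

#' Read a binary mask from a PNG file
#'
#' The image is thresholded at 0.5 so that near-white pixels map to vessel.
#'
#' @param path Path to a PNG file.
#' @return Integer 0/1 matrix.
#' @export
read_binary_mask <- function(path) {
  threshold_map(read_probability_map(path), 0.5)
}

#' Write a probability map or binary mask as a grayscale PNG
#'
#' @param x Numeric matrix in \[0, 1\].
#' @param path Output path.
#' @export
write_mask_png <- function(x, path) {
  png::writePNG(matrix(as.double(x), nrow(x), ncol(x)), path)
  invisible(path)
}

#' Batch metric evaluation over a dataset manifest
#'
#' For each manifest row, reads the predicted probability map and the
#' ground-truth mask, thresholds the map, and computes the objective
#' metrics. This is the tabular backbone behind objective-vs-subjective
#' comparisons.
#'
#' @param manifest Data frame with columns `image_id`, `dataset`, `model`,
#'   `pred_path`, `truth_path`, and optionally `roi_path`.
#' @param threshold Probability threshold applied to every map. Default 0.5.
#' @return Data frame with one row per manifest entry: identifiers, the raw
#'   confusion counts, and all metrics (`NA` where undefined).
#' @export
evaluate_manifest <- function(manifest, threshold = 0.5) {
  stopifnot(is.data.frame(manifest),
            all(c("image_id", "dataset", "model", "pred_path", "truth_path")
                %in% names(manifest)))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    pred <- threshold_map(read_probability_map(manifest$pred_path[i]), threshold)
    truth <- read_binary_mask(manifest$truth_path[i])
    roi <- NULL
    if ("roi_path" %in% names(manifest) && !is.na(manifest$roi_path[i]) &&
        nzchar(manifest$roi_path[i]))
      roi <- read_binary_mask(manifest$roi_path[i])
    cc <- confusion_counts(pred, truth, roi)
    m <- compute_metrics(cc)
    data.frame(image_id = manifest$image_id[i], dataset = manifest$dataset[i],
               model = manifest$model[i],
               tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, precision = m$precision,
               f1 = m$f1, mcc = m$mcc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
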