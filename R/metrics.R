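#' Pixelwise confusion counts between two binary masks
#'
#' @param pred,truth Binary rasters (logical or 0/1 numeric) of identical
#'   dimensions; nonzero = foreground.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn` summing to the pixel count.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth dimensions differ", call. = FALSE)
  p <- pred != 0; t <- truth != 0
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# ratio with the empty-vs-empty convention 0/0 = 1
safe_ratio <- function(num, den) if (den == 0) 1 else num / den

#' Dice coefficient from confusion counts
#'
#' `2 tp / (2 tp + fp + fn)`, with 0/0 defined as 1 (two empty masks agree).
#' @param c A [confusion()] result.
#' @return Fraction in `[0, 1]`.
#' @export
dice <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  safe_ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn)
}

#' Per-class intersection-over-union from confusion counts
#'
#' @param c A [confusion()] result.
#' @return Named vector with `foreground` and `background` IoU.
#' @export
iou_per_class <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  c(foreground = safe_ratio(c$tp, c$tp + c$fp + c$fn),
    background = safe_ratio(c$tn, c$tn + c$fp + c$fn))
}

#' Mean intersection-over-union from confusion counts
#'
#' Unweighted mean of the foreground and background IoU; the foreground-only
#' IoU is available via [iou_per_class()] for the alternative convention.
#' @param c A [confusion()] result.
#' @return Fraction in `[0, 1]`.
#' @export
miou <- function(c) mean(iou_per_class(c))

#' Pixel accuracy from confusion counts
#'
#' @param c A [confusion()] result.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$fp + c$fn + c$tn
  safe_ratio(c$tp + c$tn, total)
}

#' Evaluate predicted masks against reference masks
#'
#' Pairs mask files by file name between two directories, converts each to
#' a binary boundary raster (label masks via [boundary_from_labels()];
#' 0/255 rasters used as-is) and reports Dice, accuracy, mean IoU and
#' per-class IoU per pair plus a `summary` row of means.
#'
#' @param pred_dir,truth_dir Directories holding masks with matching names.
#' @param out_csv Optional path for a CSV copy of the table.
#' @return Data frame, one row per pair plus a summary row.
#' @export
evaluate_pairs <- function(pred_dir, truth_dir, out_csv = NULL) {
  preds <- sort(list.files(pred_dir, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE))
  common <- preds[file.exists(file.path(truth_dir, preds))]
  if (length(common) == 0) stop("no matching mask files", call. = FALSE)
  as_boundary <- function(path) {
    m <- read_mask_int(path)
    vals <- sort(unique(as.vector(m)))
    if (identical(vals, c(0L, 255L)) || all(vals %in% c(0L, 1L))) m != 0
    else boundary_from_labels(m)
  }
  rows <- lapply(common, function(f) {
    cc <- confusion(as_boundary(file.path(pred_dir, f)),
                    as_boundary(file.path(truth_dir, f)))
    iou <- iou_per_class(cc)
    data.frame(file = f, dice = dice(cc), accuracy = accuracy(cc),
               miou = miou(cc), iou_foreground = iou[["foreground"]],
               iou_background = iou[["background"]])
  })
  tab <- do.call(rbind, rows)
  summary_row <- data.frame(file = "summary", dice = mean(tab$dice),
                            accuracy = mean(tab$accuracy),
                            miou = mean(tab$miou),
                            iou_foreground = mean(tab$iou_foreground),
                            iou_background = mean(tab$iou_background))
  tab <- rbind(tab, summary_row)
  if (!is.null(out_csv)) write.csv(tab, out_csv, row.names = FALSE)
  tab
}
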