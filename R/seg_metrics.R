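#' Per-class segmentation agreement metrics
#'
#' Evaluates a predicted label mask against a reference mask, one row per
#' non-background class (one-vs-rest binarisation): Dice `2TP/(2TP+FP+FN)`,
#' IoU `TP/(TP+FP+FN)`, pixel accuracy, F1 (identical to Dice for binary
#' masks), and a ROC AUC column. With hard masks the AUC degenerates to
#' `(sensitivity + specificity)/2`, which is flagged in the `auc_degenerate`
#' column; supply per-class probability maps to [pixel_roc_auc()] for the
#' non-degenerate form. The `mean` row is the unweighted mean over classes
#' present in the reference; classes absent from both masks are reported as
#' missing and excluded from the mean.
#'
#' @param pred,ref [labeled_bscan()] objects (or bare label matrices) of
#'   identical shape.
#' @return Data frame of per-class metrics plus a `mean` row.
#' @export
per_class_metrics <- function(pred, ref) {
  pg <- if (inherits(pred, "labeled_bscan")) pred$grid else pred
  rg <- if (inherits(ref, "labeled_bscan")) ref$grid else ref
  if (!identical(dim(pg), dim(rg))) {
    stop("prediction and reference grids differ in shape")
  }
  schema <- label_schema()
  classes <- names(schema)[schema != 0L]
  rows <- lapply(classes, function(cl) {
    code <- schema[[cl]]
    p <- pg == code
    r <- rg == code
    tp <- sum(p & r); fp <- sum(p & !r); fn <- sum(!p & r)
    tn <- sum(!p & !r)
    if (tp + fp + fn == 0) {
      return(data.frame(class = cl, dice = NA_real_, iou = NA_real_,
                        accuracy = NA_real_, f1 = NA_real_,
                        roc_auc = NA_real_, tp = tp, fp = fp, fn = fn,
                        tn = tn, in_reference = FALSE,
                        stringsAsFactors = FALSE))
    }
    dice <- 2 * tp / (2 * tp + fp + fn)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    data.frame(class = cl, dice = dice, iou = tp / (tp + fp + fn),
               accuracy = (tp + tn) / length(p), f1 = dice,
               roc_auc = (sens + spec) / 2,
               tp = tp, fp = fp, fn = fn, tn = tn,
               in_reference = tp + fn > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  present <- out[out$in_reference, , drop = FALSE]
  mean_row <- data.frame(
    class = "mean", dice = mean(present$dice), iou = mean(present$iou),
    accuracy = mean(present$accuracy), f1 = mean(present$f1),
    roc_auc = mean(present$roc_auc, na.rm = TRUE),
    tp = NA_integer_, fp = NA_integer_, fn = NA_integer_, tn = NA_integer_,
    in_reference = NA, stringsAsFactors = FALSE)
  out <- rbind(out, mean_row)
  attr(out, "auc_degenerate") <- TRUE
  out
}

#' Pixel-wise ROC AUC of a probability map
#'
#' Rank-based (Mann-Whitney, midrank ties) AUC of a per-pixel probability
#' map against a binary reference mask. If the supplied map is hard
#' (values only 0/1) the result is the degenerate
#' `(sensitivity + specificity)/2` and the output is flagged accordingly.
#'
#' @param prob_map Numeric matrix of scores in \[0, 1\].
#' @param ref_binary Logical (or 0/1) matrix of the same shape.
#' @return List `auc`, `degenerate`, and `reason` when undefined.
#' @export
pixel_roc_auc <- function(prob_map, ref_binary) {
  stopifnot(identical(dim(prob_map), dim(ref_binary)))
  p <- as.vector(prob_map)
  r <- as.numeric(as.vector(ref_binary))
  if (any(p < 0 | p > 1)) stop("probability map values must lie in [0, 1]")
  if (length(unique(r)) < 2L) {
    return(list(auc = NA_real_, degenerate = NA,
                reason = "reference contains a single class"))
  }
  list(auc = auc_rank(p, r), degenerate = all(p %in% c(0, 1)))
}
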