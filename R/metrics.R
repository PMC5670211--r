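# Overlap and contour metrics for binary segmentations.

#' Pixelwise confusion counts between two masks
#'
#' Counts true positives (`G & S`), true negatives (`!G & !S`), false
#' positives (`!G & S`) and false negatives (`G & !S`) between a
#' ground-truth mask `G` and a computed mask `S` of equal shape.
#'
#' @param G,S Logical arrays of identical dimensions (ground truth and
#'   segmentation).
#' @return An object of class `confusion_counts` with integer elements
#'   `tp`, `tn`, `fp`, `fn`; their sum equals the number of pixels.
#' @export
confusion <- function(G, S) {
  if (!is.logical(G) || !is.logical(S)) {
    stop("`G` and `S` must be logical arrays", call. = FALSE)
  }
  if (!identical(dim(G), dim(S))) {
    stop("`G` and `S` must have identical dimensions", call. = FALSE)
  }
  if (any(is.na(G)) || any(is.na(S))) stop("masks contain NA", call. = FALSE)
  structure(
    list(
      tp = sum(G & S), tn = sum(!G & !S),
      fp = sum(!G & S), fn = sum(G & !S)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp %d  tn %d  fp %d  fn %d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

.as_confusion <- function(x, S = NULL) {
  if (inherits(x, "confusion_counts")) {
    if (!is.null(S)) stop("`S` must be NULL when counts are supplied", call. = FALSE)
    x
  } else {
    confusion(x, S)
  }
}

#' Set-similarity metrics: Jaccard, Dice, Matthews correlation
#'
#' * `jaccard()`: \eqn{JI = TP / (TP + FP + FN)}, in \[0, 1\].
#' * `dice()`: \eqn{DSC = TP / (\frac12(TP + FN + TP + FP))}, in \[0, 1\];
#'   algebraically `2 JI / (1 + JI)`.
#' * `mcc()`: \eqn{(TP\,TN - FP\,FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},
#'   in \[-1, 1\]; defined as 0 whenever a denominator factor vanishes.
#'
#' All three equal 1 for a perfect segmentation. `jaccard()` and `dice()`
#' error when both masks are empty (`TP + FP + FN = 0`).
#'
#' @param x A `confusion_counts` object, or the ground-truth logical mask
#'   (in which case `S` must be the computed mask).
#' @param S Optional computed mask when `x` is a mask.
#' @return A single number.
#' @examples
#' G <- matrix(FALSE, 10, 10); G[3:6, 3:6] <- TRUE
#' S <- matrix(FALSE, 10, 10); S[4:7, 3:6] <- TRUE
#' jaccard(G, S); dice(G, S); mcc(G, S)
#' @export
jaccard <- function(x, S = NULL) {
  cc <- .as_confusion(x, S)
  denom <- cc$tp + cc$fp + cc$fn
  if (denom == 0) stop("both masks are empty: Jaccard index undefined", call. = FALSE)
  cc$tp / denom
}

#' @rdname jaccard
#' @export
dice <- function(x, S = NULL) {
  cc <- .as_confusion(x, S)
  denom <- (cc$tp + cc$fn + cc$tp + cc$fp) / 2
  if (denom == 0) stop("both masks are empty: Dice coefficient undefined", call. = FALSE)
  cc$tp / denom
}

#' @rdname jaccard
#' @export
mcc <- function(x, S = NULL) {
  cc <- .as_confusion(x, S)
  # doubles: products of pixel counts overflow 32-bit integers
  tp <- as.numeric(cc$tp); tn <- as.numeric(cc$tn)
  fp <- as.numeric(cc$fp); fn <- as.numeric(cc$fn)
  f1 <- tp + fp; f2 <- tp + fn; f3 <- tn + fp; f4 <- tn + fn
  if (f1 == 0 || f2 == 0 || f3 == 0 || f4 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(f1 * f2 * f3 * f4)
}

#' Boundary pixels of a mask
#'
#' A pixel is a boundary pixel if it belongs to the mask and is 4-adjacent
#' to a pixel outside the mask (neighbors beyond the frame do not count).
#'
#' @param mask Logical matrix.
#' @return Logical matrix marking boundary pixels.
#' @export
boundary_pixels <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  r <- nrow(mask); k <- ncol(mask)
  nb <- mask[c(2:r, r), ] & mask[c(1, 1:(r - 1)), ] &
    mask[, c(2:k, k)] & mask[, c(1, 1:(k - 1))]
  mask & !nb
}

.as_points <- function(x, arg) {
  if (is.logical(x) && is.matrix(x)) {
    pts <- which(boundary_pixels(x), arr.ind = TRUE)
  } else if (is.matrix(x) && is.numeric(x) && ncol(x) == 2L) {
    pts <- x
  } else {
    stop(sprintf("`%s` must be a logical mask or an n x 2 coordinate matrix", arg),
         call. = FALSE)
  }
  if (nrow(pts) == 0L) stop(sprintf("`%s` yields an empty point set", arg), call. = FALSE)
  pts
}

# largest nearest-neighbor distance from each point of A to the set B,
# chunked so the cross-distance block stays within a modest memory footprint
.directed_hausdorff <- function(A, B) {
  chunk <- max(1L, floor(4e7 / nrow(B)))
  worst <- 0
  for (s in seq(1L, nrow(A), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(A))
    d2 <- outer(A[idx, 1], B[, 1], "-")^2 + outer(A[idx, 2], B[, 2], "-")^2
    worst <- max(worst, sqrt(max(apply(d2, 1, min))))
  }
  worst
}

#' Hausdorff distance between two contours
#'
#' The symmetric worst-case discrepancy
#' \deqn{HD(G, S) = \max\{\max_{g \in G}\min_{s \in S} d(g,s),\;
#'   \max_{s \in S}\min_{g \in G} d(g,s)\}}
#' with Euclidean pixel distances. Logical masks are first reduced to their
#' boundary-pixel sets via [boundary_pixels()]; alternatively pass n x 2
#' (row, col) coordinate matrices directly. Zero if and only if the two
#' point sets coincide.
#'
#' @param G,S Logical masks or n x 2 coordinate matrices; both non-empty.
#' @return A single non-negative number.
#' @export
hausdorff <- function(G, S) {
  A <- .as_points(G, "G")
  B <- .as_points(S, "S")
  max(.directed_hausdorff(A, B), .directed_hausdorff(B, A))
}

#' All segmentation scores at once
#'
#' Convenience wrapper returning the four metrics between a computed mask
#' and its ground truth. `accuracy_pct` is the Jaccard index scaled to a
#' percentage, the convention used when reporting tissue-segmentation
#' accuracy.
#'
#' @param truth,pred Logical masks of identical shape.
#' @param metrics Character subset of `c("ji", "dsc", "mcc", "hd")`.
#' @return A one-row data frame.
#' @export
segmentation_scores <- function(truth, pred,
                                metrics = c("ji", "dsc", "mcc", "hd")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  cc <- confusion(truth, pred)
  out <- list()
  if ("ji" %in% metrics) {
    out$ji <- jaccard(cc)
    out$accuracy_pct <- 100 * out$ji
  }
  if ("dsc" %in% metrics) out$dsc <- dice(cc)
  if ("mcc" %in% metrics) out$mcc <- mcc(cc)
  if ("hd" %in% metrics) {
    out$hd <- if (any(truth) && any(pred)) hausdorff(truth, pred) else NA_real_
  }
  as.data.frame(out)
}
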