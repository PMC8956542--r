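# Evaluation metrics: Dice similarity coefficient, 95th-percentile
# Hausdorff distance in mm, volume ratio, Cohen's kappa, accuracy, F1, and
# median/IQR report tables.

#' Slice-classification confusion matrix
#'
#' @param tn,fp,fn,tp Non-negative slice counts (true negative, false
#'   positive, false negative, true positive; positive = slice contains
#'   heart).
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  stopifnot(tn >= 0, fp >= 0, fn >= 0, tp >= 0)
  structure(list(tn = tn, fp = fp, fn = fn, tp = tp),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(truth = c("without heart", "with heart"),
                              prediction = c("without heart", "with heart")))
  print(m)
  invisible(x)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_e` from the
#' row/column marginals; defined as 1 when expected agreement is perfect and
#' observed agreement is too.
#'
#' @param cm A [confusion_matrix()].
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(cm) {
  n <- cm$tn + cm$fp + cm$fn + cm$tp
  if (n == 0) stop("empty confusion matrix")
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tn + cm$fp) * (cm$tn + cm$fn) +
           (cm$fn + cm$tp) * (cm$fp + cm$tp)) / n^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Accuracy, F1 and counts from a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return List with `accuracy`, `f1` (positive class = heart; `NA` when
#'   undefined, i.e. no positives in truth or prediction), and the counts.
#' @export
classification_report <- function(cm) {
  n <- cm$tn + cm$fp + cm$fn + cm$tp
  if (n == 0) stop("empty confusion matrix")
  f1 <- if (cm$tp + cm$fp + cm$fn == 0) NA_real_ else
    2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn)
  list(accuracy = (cm$tp + cm$tn) / n, f1 = f1,
       tn = cm$tn, fp = cm$fp, fn = cm$fn, tp = cm$tp, n = n)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 when both masks are empty (documented
#' convention), 0 when exactly one is empty.
#'
#' @param a,b Binary (logical or 0/1) arrays on the same grid.
#' @return Dice in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim_or_len(a), dim_or_len(b))) stop("mask grids differ")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Boundary voxels of a 3D mask
#'
#' A mask voxel is boundary if at least one of its six face neighbours is
#' background; voxels on the array edge count as boundary (the outside is
#' background).
#'
#' @param mask Binary 3D array.
#' @return Logical array of the same shape.
#' @export
mask_boundary <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  interior <- array(TRUE, dim = d)
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    dest <- src <- lapply(d, seq_len)
    keep <- seq_len(d[ax] - 1L)
    dest[[ax]] <- if (by > 0L) keep else keep + 1L
    src[[ax]] <- if (by > 0L) keep + 1L else keep
    nb <- array(FALSE, dim = d)   # neighbour value in direction `by`
    nb[dest[[1]], dest[[2]], dest[[3]]] <-
      m[src[[1]], src[[2]], src[[3]], drop = FALSE]
    interior <- interior & nb
  }
  m & !interior
}

nearest_rank_percentile <- function(x, p) {
  sort(x)[ceiling(p * length(x))]
}

#' 95th-percentile Hausdorff distance in mm
#'
#' Boundary voxels of each mask are extracted (six-neighbour face
#' adjacency); directed distances from every boundary voxel of one mask to
#' the nearest boundary voxel of the other are computed in physical mm; the
#' symmetric HD95 is the maximum of the two directed 95th percentiles
#' (nearest-rank). 0 for identical masks; `NA` when either mask is empty.
#'
#' @param a,b Binary 3D arrays on the same grid.
#' @param spacing (z, y, x) voxel spacing, mm.
#' @param percentile Percentile of the directed boundary distances
#'   (default 0.95).
#' @return Distance in mm, or `NA_real_` for an empty mask.
#' @export
hausdorff95 <- function(a, b, spacing, percentile = 0.95) {
  if (!identical(dim(a), dim(b))) stop("mask grids differ")
  if (sum(a != 0) == 0 || sum(b != 0) == 0) return(NA_real_)
  pa <- boundary_coords(a, spacing)
  pb <- boundary_coords(b, spacing)
  d_ab <- cpp_nn_distances(pa, pb)
  d_ba <- cpp_nn_distances(pb, pa)
  max(nearest_rank_percentile(d_ab, percentile),
      nearest_rank_percentile(d_ba, percentile))
}

boundary_coords <- function(mask, spacing) {
  idx <- which(mask_boundary(mask), arr.ind = TRUE)
  cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2], idx[, 3] * spacing[3])
}

#' Predicted-to-manual volume ratio
#'
#' Voxel spacing cancels on a shared grid, but is applied so masks on
#' different grids with the same physical coverage compare correctly.
#'
#' @param predicted,manual Binary masks.
#' @param spacing (z, y, x) voxel spacing, mm.
#' @return `predicted volume / manual volume`; `NA` when manual is empty.
#' @export
volume_ratio <- function(predicted, manual, spacing) {
  vm <- sum(manual != 0) * prod(spacing)
  if (vm == 0) return(NA_real_)
  sum(predicted != 0) * prod(spacing) / vm
}

#' Structure volume in ml
#' @param mask Binary mask.
#' @param spacing (z, y, x) voxel spacing, mm.
#' @export
volume_ml <- function(mask, spacing) {
  sum(mask != 0) * prod(spacing) / 1000
}

#' Per-structure metrics for one segmented volume
#'
#' @param predicted Named list of binary masks (per structure).
#' @param manual Named list of reference masks.
#' @param spacing (z, y, x) voxel spacing, mm.
#' @param structures Structures to evaluate.
#' @return Data frame with one row per structure: dice, hd95 (mm),
#'   volume_ratio, predicted_volume and manual_volume (ml).
#' @export
structure_metrics <- function(predicted, manual, spacing,
                              structures = STRUCTURES) {
  rows <- lapply(structures, function(s) {
    data.frame(structure = s,
               dice = dice_coefficient(predicted[[s]], manual[[s]]),
               hd95 = hausdorff95(predicted[[s]], manual[[s]], spacing),
               volume_ratio = volume_ratio(predicted[[s]], manual[[s]],
                                           spacing),
               predicted_volume = volume_ml(predicted[[s]], spacing),
               manual_volume = volume_ml(manual[[s]], spacing),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Median / quartile summary over a validation set
#'
#' Per-structure median and (Q1, Q3) of each metric, using the
#' linear-interpolation quantile (R type 7).
#'
#' @param metrics Data frame of per-volume [structure_metrics()] rows
#'   (stacked).
#' @return Data frame with one row per structure and metric: median, q1, q3.
#' @export
summarize_metrics <- function(metrics) {
  if (nrow(metrics) == 0) stop("no metric rows to summarize")
  vars <- intersect(c("dice", "hd95", "volume_ratio"), names(metrics))
  rows <- list()
  for (s in unique(metrics$structure)) {
    sub <- metrics[metrics$structure == s, , drop = FALSE]
    for (v in vars) {
      x <- sub[[v]][!is.na(sub[[v]])]
      if (length(x) == 0) next
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(structure = s, metric = v, median = q[2],
                   q1 = q[1], q3 = q[3], n = length(x),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
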