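# End-to-end inference: gate axial slices with the stage-1 classifier,
# segment the gated slab in three planes with the stage-2 networks, fuse by
# multiplication (conjunction) of the binary masks.

#' Slab decisions from per-slice probabilities
#'
#' Probabilities at or above `threshold` are positive; single-slice gaps
#' inside positive runs are closed; the longest contiguous positive run is
#' selected (ties: the most cranial run).
#'
#' @param probs Per-slice probabilities, cranio-caudal order.
#' @param threshold Decision threshold.
#' @return A `slab_selection` (0-based half-open `z_start`/`z_end`).
#' @export
slab_from_probs <- function(probs, threshold = 0.5) {
  nz <- length(probs)
  pos <- probs >= threshold
  if (nz >= 3L) {
    gap <- which(!pos[2:(nz - 1L)] & pos[1:(nz - 2L)] & pos[3:nz]) + 1L
    pos[gap] <- TRUE
  }
  if (!any(pos)) {
    return(structure(list(probabilities = probs, decisions = pos,
                          z_start = NA_integer_, z_end = NA_integer_,
                          empty = TRUE, threshold = threshold),
                     class = "slab_selection"))
  }
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  structure(list(probabilities = probs, decisions = pos,
                 z_start = starts[best] - 1L, z_end = ends[best],
                 empty = FALSE, threshold = threshold),
            class = "slab_selection")
}

#' Select the heart-containing axial slab
#'
#' Each axial slice is classified with the stage-1 network and the decisions
#' are smoothed by [slab_from_probs()].
#'
#' @param volume A `ct_volume`.
#' @param classifier A trained `slice_classifier`.
#' @param threshold Decision threshold (default 0.5).
#' @param window A [window_setting()] applied before classification.
#' @return A `slab_selection`: list with `probabilities`, `decisions`,
#'   `z_start`, `z_end` (0-based, half-open) and `empty` flag.
#' @export
select_heart_slab <- function(volume, classifier, threshold = 0.5,
                              window = window_setting()) {
  img <- window_intensity(volume$intensities, window)
  nz <- dim(img)[1]
  probs <- vapply(seq_len(nz), function(z) {
    predict_slice(classifier, img[z, , ])
  }, 0)
  slab_from_probs(probs, threshold)
}

#' @export
print.slab_selection <- function(x, ...) {
  if (x$empty) {
    cat("slab selection: no heart-containing slices found\n")
  } else {
    cat(sprintf("slab selection: slices [%d, %d) of %d (threshold %.2f)\n",
                x$z_start, x$z_end, length(x$probabilities), x$threshold))
  }
  invisible(x)
}

#' Apply the three stage-2 networks over the gated slab
#'
#' The axial network runs on every slab slice (slices outside the slab are
#' implicitly zero); the coronal and sagittal networks run on the
#' slab-cropped, z-resampled volume and their whole-heart probabilities are
#' mapped back to the input grid (nearest-neighbour along z).
#'
#' @param volume A `ct_volume`.
#' @param slab A `slab_selection`.
#' @param models Named list with `axial`, `coronal`, `sagittal` trained
#'   `unet3plus` networks.
#' @param window A [window_setting()].
#' @return List of probability arrays on the input grid: `axial` (4D,
#'   z,y,x,structure), `coronal` and `sagittal` (3D whole-heart).
#' @export
segment_views <- function(volume, slab, models, window = window_setting()) {
  d <- dim(volume$intensities)
  S <- models$axial$config$structures
  ax <- array(0, dim = c(d, length(S)), dimnames = list(NULL, NULL, NULL, S))
  cor <- array(0, dim = d)
  sag <- array(0, dim = d)
  if (isTRUE(slab$empty)) {
    warning("empty slab: returning all-zero probabilities")
    return(list(axial = ax, coronal = cor, sagittal = sag))
  }
  img <- window_intensity(volume$intensities, window)
  zsel <- (slab$z_start + 1L):slab$z_end
  for (z in zsel) {
    pr <- predict_segmenter(models$axial, img[z, , ])
    ax[z, , , ] <- pr
  }
  wv <- volume; wv$intensities <- img
  for (pl in c("coronal", "sagittal")) {
    rs <- reslice(wv, labels = NULL, plane = pl, window = NULL,
                  z_range = range(zsel))
    probs <- lapply(rs$samples, function(s) {
      predict_segmenter(models[[pl]], s$image)[, , 1L]
    })
    back <- map_plane_to_volume(probs, rs$mapping)
    if (pl == "coronal") cor <- back else sag <- back
  }
  list(axial = ax, coronal = cor, sagittal = sag)
}

#' Fuse the three views into the final segmentation
#'
#' Each view is binarised at `threshold`; the final whole heart is the
#' voxel-wise conjunction of the three WH masks. Substructures are gated by
#' the coronal and sagittal WH masks (and optionally also by the axial WH
#' mask, `gate_substructures_by_axial_wh`), matching the fusion by
#' multiplication of binary masks.
#'
#' @param views List from [segment_views()].
#' @param spacing (z, y, x) voxel spacing, mm.
#' @param threshold Binarisation threshold (default 0.5).
#' @param gate_substructures_by_axial_wh Also intersect substructures with
#'   the axial WH mask (default `FALSE`).
#' @param provenance Optional list recorded in the result.
#' @return A `segmentation_result`: named list of binary masks, per-structure
#'   volumes in ml, and provenance.
#' @export
fuse_masks <- function(views, spacing, threshold = 0.5,
                       gate_substructures_by_axial_wh = FALSE,
                       provenance = list()) {
  d <- dim(views$coronal)
  if (!identical(dim(views$axial)[1:3], d) ||
      !identical(dim(views$sagittal), d)) {
    stop("view grids differ")
  }
  S <- dimnames(views$axial)[[4]]
  corb <- views$coronal >= threshold
  sagb <- views$sagittal >= threshold
  gate <- corb & sagb
  masks <- list()
  axwh <- views$axial[, , , "WH"] >= threshold
  masks$WH <- axwh & gate
  for (s in setdiff(S, "WH")) {
    m <- (views$axial[, , , s] >= threshold) & gate
    if (gate_substructures_by_axial_wh) m <- m & axwh
    masks[[s]] <- m
  }
  volumes <- vapply(masks, volume_ml, 0, spacing = spacing)
  structure(list(masks = masks, volumes_ml = volumes, spacing = spacing,
                 threshold = threshold, provenance = provenance),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("segmentation result; structure volumes (ml):\n")
  print(round(x$volumes_ml, 1))
  if (isTRUE(x$provenance$empty_slab)) cat("(empty slab: no heart found)\n")
  invisible(x)
}

#' Run the full two-stage pipeline on one volume
#'
#' Composition of [select_heart_slab()], [segment_views()] and
#' [fuse_masks()].
#'
#' @param volume A `ct_volume`.
#' @param bundle Named list with `classifier` and `axial`, `coronal`,
#'   `sagittal` segmenters (see [train_stage1()], [train_stage2()]).
#' @param stage1_threshold Slice-classifier decision threshold.
#' @param fusion_threshold Mask binarisation threshold.
#' @param window A [window_setting()].
#' @param gate_substructures_by_axial_wh See [fuse_masks()].
#' @return A `segmentation_result`; the gated slab is attached as
#'   `$provenance$slab`.
#' @export
run_pipeline <- function(volume, bundle, stage1_threshold = 0.5,
                         fusion_threshold = 0.5,
                         window = window_setting(),
                         gate_substructures_by_axial_wh = FALSE) {
  for (part in c("classifier", "axial", "coronal", "sagittal")) {
    if (is.null(bundle[[part]])) stop("model bundle is missing '", part, "'")
  }
  t0 <- Sys.time()
  slab <- select_heart_slab(volume, bundle$classifier,
                            threshold = stage1_threshold, window = window)
  t1 <- Sys.time()
  views <- segment_views(volume, slab,
                         bundle[c("axial", "coronal", "sagittal")],
                         window = window)
  t2 <- Sys.time()
  prov <- list(volume = volume$identifier, slab = slab,
               empty_slab = slab$empty,
               stage1_threshold = stage1_threshold,
               fusion_threshold = fusion_threshold,
               timings_s = c(stage1 = as.numeric(t1 - t0, units = "secs"),
                             stage2 = as.numeric(t2 - t1, units = "secs")))
  fuse_masks(views, volume$spacing, threshold = fusion_threshold,
             gate_substructures_by_axial_wh = gate_substructures_by_axial_wh,
             provenance = prov)
}
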