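# Intensity windowing, slice extraction for the three anatomical planes,
# and the z-resampling that makes coronal/sagittal slices near-isotropic.
#
# Conventions (used everywhere): arrays are indexed (z, y, x), z increasing
# caudally; slice indices reported to users are 0-based; windowed images are
# in [0, 1].

#' Intensity window setting
#'
#' @param width Window width in HU (> 0); default 350 (mediastinum).
#' @param level Window level (centre) in HU; default 50.
#' @return A `window_setting` list.
#' @export
window_setting <- function(width = 350, level = 50) {
  stopifnot(width > 0)
  structure(list(width = width, level = level), class = "window_setting")
}

#' Window HU intensities to \[0, 1\]
#'
#' Affine map `(HU - (level - width/2)) / width` clamped to \[0, 1\]; the
#' window level maps to 0.5 and the map is monotone non-decreasing in HU.
#'
#' @param x A `ct_volume`, or a numeric array/matrix of HU values.
#' @param setting A [window_setting()].
#' @return Same shape as the input, values in \[0, 1\]; a `ct_volume` input
#'   returns a `ct_volume` with windowed intensities.
#' @export
window_intensity <- function(x, setting = window_setting()) {
  if (inherits(x, "ct_volume")) {
    x$intensities <- window_intensity(x$intensities, setting)
    return(x)
  }
  lo <- setting$level - setting$width / 2
  pmin(pmax((x - lo) / setting$width, 0), 1)
}

new_slice_sample <- function(image, plane, source_volume, index,
                             heart_present = NA, masks = NULL) {
  stopifnot(all(image >= 0 & image <= 1))
  if (!is.null(masks)) {
    for (m in masks) stopifnot(identical(dim(m), dim(image)))
  }
  structure(list(image = image, plane = plane,
                 source_volume = source_volume, index = as.integer(index),
                 heart_present = heart_present, masks = masks),
            class = "slice_sample")
}

#' Extract axial slice samples for one stage
#'
#' Stage 1 extracts every axial slice with a heart-present label (any WH
#' voxel in the slice). Stage 2 extracts only heart-present slices, each
#' carrying the five per-structure 2D masks, plus `n_liver_only` slices
#' immediately caudal to the heart (liver present, all masks empty) that
#' teach the networks to ignore liver.
#'
#' @param volume A `ct_volume` (already windowed or raw; set `window` to
#'   apply windowing here).
#' @param labels Matching `label_volume`.
#' @param stage 1 or 2.
#' @param n_liver_only Stage-2 extra liver-only slices (default 0).
#' @param window A [window_setting()] applied to the intensities, or `NULL`
#'   if `volume` is already windowed.
#' @return List of `slice_sample`s (0-based `index`).
#' @export
extract_axial_samples <- function(volume, labels, stage = 1,
                                  n_liver_only = 0L,
                                  window = window_setting()) {
  if (!identical(dim(volume$intensities), dim(labels$masks$WH))) {
    stop("volume and label grids differ")
  }
  img <- if (is.null(window)) volume$intensities else
    window_intensity(volume$intensities, window)
  nz <- dim(img)[1]
  heart <- apply(labels$masks$WH, 1, any)
  if (stage == 1) {
    return(lapply(seq_len(nz), function(z) {
      new_slice_sample(img[z, , ], "axial", volume$identifier, z - 1L,
                       heart_present = heart[z])
    }))
  }
  zs <- which(heart)
  samples <- lapply(zs, function(z) {
    masks <- lapply(labels$masks, function(m) m[z, , ])
    new_slice_sample(img[z, , ], "axial", volume$identifier, z - 1L,
                     heart_present = TRUE, masks = masks)
  })
  if (n_liver_only > 0L && length(zs) > 0L) {
    extra <- setdiff(seq(max(zs) + 1L, length.out = n_liver_only), 0L)
    extra <- extra[extra <= nz]
    empty <- lapply(labels$masks, function(m) {
      array(FALSE, dim = dim(m)[2:3])
    })
    samples <- c(samples, lapply(extra, function(z) {
      new_slice_sample(img[z, , ], "axial", volume$identifier, z - 1L,
                       heart_present = FALSE, masks = empty)
    }))
  }
  samples
}

# nearest / linear index maps between an nz-slice grid (thickness dz) and
# its z-resampled version at spacing s
z_resample_maps <- function(nz, dz, s) {
  nz2 <- round(nz * dz / s)
  z2 <- (seq_len(nz2) - 0.5) * s      # resampled voxel centres, mm
  pos <- z2 / dz + 0.5                # fractional source slice position
  i0 <- pmin(pmax(floor(pos), 1L), nz)
  i1 <- pmin(i0 + 1L, nz)
  w1 <- pmin(pmax(pos - i0, 0), 1)
  nearest_src <- ifelse(w1 > 0.5, i1, i0)
  # inverse: for each source slice, nearest resampled slice
  zsrc <- (seq_len(nz) - 0.5) * dz
  inv <- pmin(pmax(round(zsrc / s + 0.5), 1L), nz2)
  list(nz2 = nz2, i0 = i0, i1 = i1, w1 = w1,
       nearest_src = as.integer(nearest_src), inv = as.integer(inv))
}

#' Reslice a volume into coronal or sagittal samples
#'
#' The volume is first resampled along z to the in-plane resolution (linear
#' interpolation for intensities, nearest neighbour for masks) so the
#' resliced images are near-isotropic; the number of resampled slices is
#' `round(nz * slice_thickness / in_plane_spacing)`. Coronal slices are
#' (z', x) images indexed by y; sagittal slices are (z', y) images indexed
#' by x. The z mapping is retained so predictions can be mapped back to the
#' volume grid (nearest neighbour).
#'
#' @param volume A `ct_volume`.
#' @param labels Optional `label_volume`; resliced WH masks are attached.
#' @param plane `"coronal"` or `"sagittal"`.
#' @param window A [window_setting()] or `NULL` if already windowed.
#' @param z_range Optional 1-based (first, last) axial slice range to crop
#'   before reslicing (the gated slab).
#' @return List with `samples` (list of `slice_sample`s) and `mapping`
#'   (resampling bookkeeping for [map_plane_to_volume()]).
#' @export
reslice <- function(volume, labels = NULL, plane = c("coronal", "sagittal"),
                    window = window_setting(), z_range = NULL) {
  plane <- match.arg(plane)
  img <- if (is.null(window)) volume$intensities else
    window_intensity(volume$intensities, window)
  d <- dim(img)
  if (is.null(z_range)) z_range <- c(1L, d[1])
  zs <- z_range[1]:z_range[2]
  img <- img[zs, , , drop = FALSE]
  wh <- if (!is.null(labels)) {
    labels$masks$WH[zs, , , drop = FALSE]
  }
  nz <- length(zs)
  maps <- z_resample_maps(nz, volume$spacing[1], volume$spacing[2])
  # linear interpolation along z, vectorized over (y, x)
  flat <- matrix(img, nz, d[2] * d[3])
  res <- flat[maps$i0, , drop = FALSE] * (1 - maps$w1) +
    flat[maps$i1, , drop = FALSE] * maps$w1
  res <- array(res, dim = c(maps$nz2, d[2], d[3]))
  wh_res <- if (!is.null(wh)) {
    array(matrix(wh, nz, d[2] * d[3])[maps$nearest_src, , drop = FALSE],
          dim = c(maps$nz2, d[2], d[3]))
  }
  n_slices <- if (plane == "coronal") d[2] else d[3]
  samples <- lapply(seq_len(n_slices), function(i) {
    if (plane == "coronal") {
      im <- res[, i, ]
      mk <- if (!is.null(wh_res)) list(WH = wh_res[, i, ] > 0)
    } else {
      im <- res[, , i]
      mk <- if (!is.null(wh_res)) list(WH = wh_res[, , i] > 0)
    }
    new_slice_sample(im, plane, volume$identifier, i - 1L,
                     heart_present = if (!is.null(mk)) any(mk$WH) else NA,
                     masks = mk)
  })
  mapping <- list(plane = plane, z_offset = z_range[1] - 1L, nz = nz,
                  nz2 = maps$nz2, nearest_src = maps$nearest_src,
                  inv = maps$inv, dim = d)
  list(samples = samples, mapping = mapping)
}

#' Map per-slice plane predictions back to the volume grid
#'
#' Inverse of [reslice()]: stacks per-slice 2D arrays (z' as rows) into the
#' resampled grid and maps each original axial slice to its nearest
#' resampled slice. Values outside the resliced z-range are zero.
#'
#' @param slices List of 2D arrays (probabilities or binary masks), one per
#'   coronal/sagittal slice, in slice order.
#' @param mapping The `mapping` element returned by [reslice()].
#' @return 3D array on the original (z, y, x) grid.
#' @export
map_plane_to_volume <- function(slices, mapping) {
  d <- mapping$dim
  out <- array(0, dim = d)
  n <- length(slices)
  zsel <- mapping$z_offset + seq_len(mapping$nz)
  for (i in seq_len(n)) {
    sl <- slices[[i]][mapping$inv, , drop = FALSE]   # nz x (other axis)
    if (mapping$plane == "coronal") {
      out[zsel, i, ] <- sl
    } else {
      out[zsel, , i] <- sl
    }
  }
  out
}

#' Write a PNG preview of a slice sample
#'
#' Grey-scale windowed slice, with the WH mask outline overlaid in red when
#' masks are present. Debugging aid.
#'
#' @param sample A `slice_sample`.
#' @param path Output PNG path.
#' @export
write_slice_preview <- function(sample, path) {
  img <- sample$image
  rgb <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (!is.null(sample$masks$WH)) {
    m <- sample$masks$WH
    edge <- m & !(rbind(m[-1, ], FALSE) & rbind(FALSE, m[-nrow(m), ]) &
                    cbind(m[, -1], FALSE) & cbind(FALSE, m[, -ncol(m)]))
    r <- rgb[, , 1L]; g <- rgb[, , 2L]; b <- rgb[, , 3L]
    r[edge] <- 1; g[edge] <- 0; b[edge] <- 0
    rgb[, , 1L] <- r; rgb[, , 2L] <- g; rgb[, , 3L] <- b
  }
  png::writePNG(rgb, path)
  invisible(path)
}
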