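# Synthetic thoracic CT phantom generator.
#
# Each phantom is an HU-valued torso volume containing a heart modelled as a
# tilted ellipsoid partitioned into four chamber sub-ellipsoids (atria
# cranial to and smaller than the ventricles), flanked by low-HU lungs, with
# a liver region of near-heart HU abutting the caudal heart boundary, plus
# per-voxel Gaussian noise. Ground truth is the five binary masks
# (WH, LV, RV, LA, RA). Axis order is (z, y, x) with z increasing caudally;
# slice indices are 0-based throughout the package.

STRUCTURES <- c("WH", "LV", "RV", "LA", "RA")

#' Phantom generator configuration
#'
#' Defaults define the desk-scale study conditions: a 64 x 96 x 96 grid at
#' 1 mm in-plane with 3 or 5 mm slices, heart and liver mean HU inside the
#' mediastinum window pass band (level 50, width 350: \[-125, 225\] HU) and
#' within 30 HU of each other so the low-contrast heart/liver boundary of
#' non-contrast CT is reproduced, and lung HU far below the window floor.
#'
#' @param grid_shape Integer (nz, ny, nx) voxel counts.
#' @param in_plane_spacing In-plane voxel size, mm.
#' @param slice_thickness Slice thickness, mm; 3 or 5.
#' @param noise_sd Gaussian noise standard deviation, HU.
#' @param heart_center_jitter Uniform jitter half-range of the heart centre,
#'   mm, per axis.
#' @param structure_hu Named mean HU per structure (`WH` is myocardium).
#' @param lung_hu,liver_hu,body_hu Mean HU of lung, liver, and other soft
#'   tissue.
#' @param include_liver_only_slices Number of caudal slices that must
#'   contain liver but no heart (checked after generation).
#' @param seed Integer seed; identical configs generate bit-identical
#'   phantoms.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64L, 96L, 96L),
                           in_plane_spacing = 1,
                           slice_thickness = 3,
                           noise_sd = 20,
                           heart_center_jitter = 4,
                           structure_hu = c(WH = 45, LV = 50, RV = 40,
                                            LA = 48, RA = 42),
                           lung_hu = -780,
                           liver_hu = 60,
                           body_hu = 0,
                           include_liver_only_slices = 3L,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            in_plane_spacing > 0, slice_thickness > 0, noise_sd >= 0,
            heart_center_jitter >= 0,
            all(STRUCTURES %in% names(structure_hu)))
  win_lo <- 50 - 350 / 2
  win_hi <- 50 + 350 / 2
  if (any(structure_hu < win_lo | structure_hu > win_hi) ||
      liver_hu < win_lo || liver_hu > win_hi) {
    stop("heart and liver HU must lie inside the mediastinum window ",
         sprintf("pass band [%g, %g] HU", win_lo, win_hi))
  }
  if (lung_hu >= win_lo) stop("lung HU must lie below the window floor")
  structure(list(grid_shape = as.integer(grid_shape),
                 in_plane_spacing = in_plane_spacing,
                 slice_thickness = slice_thickness,
                 noise_sd = noise_sd,
                 heart_center_jitter = heart_center_jitter,
                 structure_hu = structure_hu,
                 lung_hu = lung_hu, liver_hu = liver_hu, body_hu = body_hu,
                 include_liver_only_slices =
                   as.integer(include_liver_only_slices),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Clinical-scale phantom geometry preset
#'
#' A 512 x 512 in-plane grid at 500/512 mm spacing, the acquisition geometry
#' of the clinical planning CTs the pipeline targets. Heavy: intended for
#' geometry checks, not for CPU training.
#'
#' @param nz Number of axial slices.
#' @param ... Passed to [phantom_config()].
#' @export
phantom_config_clinical <- function(nz = 110L, ...) {
  phantom_config(grid_shape = c(as.integer(nz), 512L, 512L),
                 in_plane_spacing = 500 / 512, ...)
}

new_ct_volume <- function(intensities, spacing, identifier) {
  stopifnot(length(dim(intensities)) == 3L, all(spacing > 0),
            all(is.finite(intensities)))
  structure(list(intensities = intensities, spacing = as.numeric(spacing),
                 identifier = identifier),
            class = "ct_volume")
}

new_label_volume <- function(masks, spacing, identifier) {
  stopifnot(all(STRUCTURES %in% names(masks)))
  structure(list(masks = masks, spacing = as.numeric(spacing),
                 identifier = identifier),
            class = "label_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("CT volume '%s': %d x %d x %d voxels (z,y,x), spacing %s mm\n",
              x$identifier, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  counts <- vapply(x$masks, sum, 0)
  cat(sprintf("label volume '%s': voxels per structure: %s\n", x$identifier,
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  invisible(x)
}

# inside-ellipsoid test in normalized local heart coordinates
ellipsoid_mask <- function(w1, w2, w3, center, semi) {
  ((w1 - center[1]) / semi[1])^2 + ((w2 - center[2]) / semi[2])^2 +
    ((w3 - center[3]) / semi[3])^2 <= 1
}

# relative chamber geometry in normalized heart coordinates
# (long axis first, +1 = caudal); atria cranial and smaller than ventricles
CHAMBER_GEOMETRY <- list(
  LV = list(center = c(0.35, 0.05, 0.28), semi = c(0.42, 0.45, 0.34)),
  RV = list(center = c(0.35, 0.00, -0.38), semi = c(0.40, 0.45, 0.30)),
  LA = list(center = c(-0.45, 0.05, 0.25), semi = c(0.30, 0.38, 0.26)),
  RA = list(center = c(-0.45, 0.00, -0.32), semi = c(0.28, 0.36, 0.25)))

#' Generate one synthetic thoracic phantom
#'
#' @param config A [phantom_config()].
#' @param identifier Volume identifier string.
#' @return List with elements `volume` (a `ct_volume`) and `labels`
#'   (a `label_volume`).
#' @export
generate_phantom <- function(config = phantom_config(),
                             identifier = "phantom") {
  set.seed(config$seed)
  nz <- config$grid_shape[1]; ny <- config$grid_shape[2]
  nx <- config$grid_shape[3]
  dz <- config$slice_thickness; s <- config$in_plane_spacing
  zex <- nz * dz; yex <- ny * s; xex <- nx * s

  # voxel-centre physical coordinates, mm
  zc <- (seq_len(nz) - 0.5) * dz
  yc <- (seq_len(ny) - 0.5) * s
  xc <- (seq_len(nx) - 0.5) * s
  Z <- array(rep(zc, times = ny * nx), dim = c(nz, ny, nx))
  Y <- array(rep(rep(yc, each = nz), times = nx), dim = c(nz, ny, nx))
  X <- array(rep(xc, each = nz * ny), dim = c(nz, ny, nx))

  size <- stats::runif(1, 0.9, 1.1)
  semi <- size * c(40, 26, 28)                       # (z, y, x) mm
  jit <- stats::runif(3, -1, 1) * config$heart_center_jitter
  center <- c(0.45 * zex, 0.50 * yex, 0.52 * xex) + jit
  if (any(center - semi < 0) || any(center + semi > c(zex, yex, xex))) {
    stop("grid too small to contain the heart at the requested spacing")
  }

  # local heart frame: rotate about x (sagittal tilt) then z (axial rotation)
  th <- 20 * pi / 180; ph <- -25 * pi / 180
  Rx <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rz <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  R <- Rz %*% Rx
  p1 <- Z - center[1]; p2 <- Y - center[2]; p3 <- X - center[3]
  u1 <- R[1, 1] * p1 + R[2, 1] * p2 + R[3, 1] * p3
  u2 <- R[1, 2] * p1 + R[2, 2] * p2 + R[3, 2] * p3
  u3 <- R[1, 3] * p1 + R[2, 3] * p2 + R[3, 3] * p3
  w1 <- u1 / semi[1]; w2 <- u2 / semi[2]; w3 <- u3 / semi[3]

  wh <- w1^2 + w2^2 + w3^2 <= 1
  masks <- list(WH = wh)
  taken <- array(FALSE, dim = dim(wh))
  for (ch in c("LV", "RV", "LA", "RA")) {
    g <- CHAMBER_GEOMETRY[[ch]]
    m <- ellipsoid_mask(w1, w2, w3, g$center, g$semi) & wh & !taken
    masks[[ch]] <- m
    taken <- taken | m
  }

  body <- (p2 / (0.42 * yex))^2 + (p3 / (0.46 * xex))^2 <= 1
  lungs <- array(FALSE, dim = dim(wh))
  for (side in c(-1, 1)) {
    lcz <- 0.50 * zex; lcy <- center[2] - 2
    lcx <- center[3] + side * 0.30 * xex
    lungs <- lungs | (((Z - lcz) / (0.46 * zex))^2 + ((Y - lcy) / 30)^2 +
                        ((X - lcx) / 20)^2 <= 1)
  }
  lungs <- lungs & body & !wh

  heart_z <- which(apply(wh, 1, any))
  z_heart_end_mm <- max(heart_z) * dz                 # caudal heart boundary
  liver_semi <- c(36, 30, 32)
  liver_center <- c(z_heart_end_mm, center[2] + 4, center[3] - 10)
  liver <- (((Z - liver_center[1]) / liver_semi[1])^2 +
            ((Y - liver_center[2]) / liver_semi[2])^2 +
            ((X - liver_center[3]) / liver_semi[3])^2 <= 1) & body & !wh
  liver <- liver & !lungs

  n_caudal <- sum(apply(liver, 1, any) & !apply(wh, 1, any) &
                    seq_len(nz) > max(heart_z))
  if (n_caudal < config$include_liver_only_slices) {
    stop("grid too small: only ", n_caudal, " liver-only slices caudal to ",
         "the heart; ", config$include_liver_only_slices, " requested")
  }

  hu <- array(-1000, dim = c(nz, ny, nx))
  hu[body] <- config$body_hu
  hu[lungs] <- config$lung_hu
  hu[liver] <- config$liver_hu
  hu[wh] <- config$structure_hu[["WH"]]
  for (ch in c("LV", "RV", "LA", "RA")) {
    hu[masks[[ch]]] <- config$structure_hu[[ch]]
  }
  if (config$noise_sd > 0) {
    hu <- hu + stats::rnorm(length(hu), 0, config$noise_sd)
  }

  spacing <- c(dz, s, s)
  list(volume = new_ct_volume(hu, spacing, identifier),
       labels = new_label_volume(masks, spacing, identifier))
}

# two fixed rounds of the MINSTD linear congruential map; gives each volume
# an independent reproducible stream from the single global seed
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- ((seed %% m) * 48271 + index) %% m
  s <- (s * 48271 + 11) %% m
  as.integer(max(1, s))
}

#' Generate a partitioned phantom dataset
#'
#' Volumes are partitioned by volume (never by slice) into train / tune /
#' validation, mixing 3 mm and 5 mm slice thickness in the 29:21 proportion
#' of the emulated acquisition protocol.
#'
#' @param n_volumes Number of phantoms.
#' @param config Base [phantom_config()]; per-volume seeds are derived from
#'   `config$seed` so the dataset is reproducible as a whole.
#' @param split_sizes Integer (train, tune, validation); must sum to
#'   `n_volumes`.
#' @param thicknesses Optional explicit per-volume slice thickness vector.
#' @param materialize Generate the voxel data (`TRUE`, default); `FALSE`
#'   builds only the manifest (for split bookkeeping).
#' @return A `phantom_dataset`: list with `phantoms` (named list of
#'   volume/label pairs; empty when not materialized) and `manifest`
#'   (data frame with id, seed, slice_thickness, partition).
#' @export
generate_dataset <- function(n_volumes, config = phantom_config(),
                             split_sizes = c(train = 1, tune = 1,
                                             validation = 1),
                             thicknesses = NULL, materialize = TRUE) {
  if (sum(split_sizes) != n_volumes) {
    stop("split sizes (", paste(split_sizes, collapse = ", "),
         ") do not sum to n_volumes = ", n_volumes)
  }
  if (is.null(thicknesses)) {
    n3 <- round(n_volumes * 29 / 50)
    thicknesses <- c(rep(3, n3), rep(5, n_volumes - n3))
    set.seed(derive_seed(config$seed, 0L))
    thicknesses <- sample(thicknesses)
  }
  stopifnot(length(thicknesses) == n_volumes)
  partition <- rep(c("train", "tune", "validation"), times = split_sizes)
  ids <- sprintf("phantom%03d", seq_len(n_volumes))
  phantoms <- vector("list", n_volumes)
  seeds <- integer(n_volumes)
  for (i in seq_len(n_volumes)) {
    cfg_i <- config
    cfg_i$slice_thickness <- thicknesses[i]
    cfg_i$seed <- derive_seed(config$seed, i)
    seeds[i] <- cfg_i$seed
    if (materialize) {
      phantoms[[i]] <- generate_phantom(cfg_i, identifier = ids[i])
    }
  }
  names(phantoms) <- ids
  manifest <- data.frame(id = ids, seed = seeds,
                         slice_thickness = thicknesses,
                         partition = partition,
                         stringsAsFactors = FALSE)
  structure(list(phantoms = phantoms, manifest = manifest, config = config),
            class = "phantom_dataset")
}

#' Re-split a dataset manifest for stage 2
#'
#' Moves volumes from the training to the validation partition (the tuning
#' partition is untouched), preferring thinner-slice volumes so the
#' validation set balances slice thicknesses — the published protocol moved
#' three 3-mm volumes to go from a 44/3/3 to a 41/3/6 split.
#'
#' @param manifest Manifest data frame from [generate_dataset()].
#' @param new_split Integer (train, tune, validation).
#' @return The transformed manifest.
#' @export
resplit_manifest <- function(manifest, new_split) {
  old <- table(factor(manifest$partition,
                      levels = c("train", "tune", "validation")))
  if (new_split[2] != old[["tune"]]) {
    stop("re-split must keep the tuning partition unchanged")
  }
  k <- old[["train"]] - new_split[1]
  if (k < 0 || new_split[3] - old[["validation"]] != k) {
    stop("inconsistent re-split sizes")
  }
  if (k == 0) return(manifest)
  tr <- which(manifest$partition == "train")
  movable <- tr[order(manifest$slice_thickness[tr],
                      -seq_along(tr))]  # thin slices first, later ids first
  move <- utils::head(movable, k)
  manifest$partition[move] <- "validation"
  manifest
}
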