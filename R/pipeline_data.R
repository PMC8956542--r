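# Assembly of stage-1 and stage-2 training sample sets from a phantom
# dataset, and the desk-scale training presets.
#
# Stage 1 sees every axial slice of every training/tuning volume. Stage 2
# sees only heart-containing axial slices (plus liver-only additions), and
# for the coronal/sagittal networks the slab-cropped, z-resampled volumes
# — the same crop the classifier provides at inference, here taken from the
# ground-truth labels.

partition_ids <- function(dataset, part) {
  dataset$manifest$id[dataset$manifest$partition == part]
}

#' Stage-1 training samples from a phantom dataset
#'
#' Slices near the cranial and caudal heart boundaries are the classifier's
#' hardest cases (the heart appears as a small low-contrast cap);
#' `oversample_boundary` replicates the slices within `boundary_margin` of
#' each heart z-extreme (and the adjacent negatives) that many extra times
#' in the training partition, the same class-imbalance device as adding
#' liver-only slices for stage 2.
#'
#' @param dataset A `phantom_dataset`.
#' @param window A [window_setting()].
#' @param stride Keep every `stride`-th axial slice (1 = all).
#' @param oversample_boundary Extra copies of boundary-adjacent training
#'   slices (0 = off).
#' @param boundary_margin Slices on each side of a heart z-extreme counted
#'   as boundary.
#' @return List with `train` and `tune` lists of slice samples.
#' @export
stage1_samples <- function(dataset, window = window_setting(), stride = 1L,
                           oversample_boundary = 0L, boundary_margin = 1L) {
  get <- function(part) {
    out <- list()
    for (id in partition_ids(dataset, part)) {
      ph <- dataset$phantoms[[id]]
      ss <- extract_axial_samples(ph$volume, ph$labels, stage = 1,
                                  window = window)
      ss <- ss[seq(1L, length(ss), by = stride)]
      if (part == "train" && oversample_boundary > 0L) {
        z <- vapply(ss, function(s) s$index, 0L)
        hp <- vapply(ss, function(s) s$heart_present, NA)
        if (any(hp)) {
          zmin <- min(z[hp]); zmax <- max(z[hp])
          near <- abs(z - zmin) <= boundary_margin |
            abs(z - zmax) <= boundary_margin
          ss <- c(ss, rep(ss[near], oversample_boundary))
        }
      }
      out <- c(out, ss)
    }
    out
  }
  list(train = get("train"), tune = get("tune"))
}

pad_sample_to <- function(sample, div) {
  H0 <- nrow(sample$image); W0 <- ncol(sample$image)
  H <- ceiling(H0 / div) * div; W <- ceiling(W0 / div) * div
  if (H == H0 && W == W0) return(sample)
  img <- matrix(0, H, W); img[seq_len(H0), seq_len(W0)] <- sample$image
  sample$image <- img
  if (!is.null(sample$masks)) {
    sample$masks <- lapply(sample$masks, function(m) {
      mm <- matrix(FALSE, H, W); mm[seq_len(H0), seq_len(W0)] <- m; mm
    })
  }
  sample
}

#' Stage-2 training samples (three planes) from a phantom dataset
#'
#' Axial: heart-containing slices with the five structure masks, plus
#' `n_liver_only` caudal liver-only slices per volume. Coronal/sagittal:
#' slices of the slab-cropped, z-resampled volume with the whole-heart
#' mask (the slab is the ground-truth heart z-range; at inference the
#' classifier provides it). Slices are subsampled by the given strides and
#' zero-padded to a multiple of `2^(depth-1)`.
#'
#' @param dataset A `phantom_dataset`.
#' @param window A [window_setting()].
#' @param stride_axial,stride_plane Subsampling strides.
#' @param n_liver_only Liver-only axial slices added per volume.
#' @param depth Segmenter depth (controls padding divisibility).
#' @return Nested list `[[plane]][[train|tune]]` of slice samples.
#' @export
stage2_samples <- function(dataset, window = window_setting(),
                           stride_axial = 2L, stride_plane = 4L,
                           n_liver_only = 3L, depth = 3L) {
  div <- 2L^(depth - 1L)
  get_axial <- function(part) {
    out <- list()
    for (id in partition_ids(dataset, part)) {
      ph <- dataset$phantoms[[id]]
      ss <- extract_axial_samples(ph$volume, ph$labels, stage = 2,
                                  n_liver_only = n_liver_only,
                                  window = window)
      out <- c(out, ss[seq(1L, length(ss), by = stride_axial)])
    }
    lapply(out, pad_sample_to, div = div)
  }
  get_plane <- function(part, plane) {
    out <- list()
    for (id in partition_ids(dataset, part)) {
      ph <- dataset$phantoms[[id]]
      hz <- range(which(apply(ph$labels$masks$WH, 1, any)))
      rs <- reslice(ph$volume, ph$labels, plane = plane, window = window,
                    z_range = hz)
      out <- c(out, rs$samples[seq(1L, length(rs$samples),
                                   by = stride_plane)])
    }
    lapply(out, pad_sample_to, div = div)
  }
  planes <- list(axial = list(train = get_axial("train"),
                              tune = get_axial("tune")))
  for (pl in c("coronal", "sagittal")) {
    planes[[pl]] <- list(train = get_plane("train", pl),
                         tune = get_plane("tune", pl))
  }
  planes
}

#' Desk-scale training presets
#'
#' Training settings sized for minutes-scale CPU training on the default
#' phantom grid: a shorter epoch budget and a larger learning rate than the
#' clinical-scale defaults (which assume a pretrained backbone and thousands
#' of clinical slices). The classifier runs without normalisation — the
#' absolute windowed intensity level is itself a cue for heart presence —
#' while the segmenters keep instance normalisation, without which the
#' small low-contrast chamber channels saturate and never train.
#'
#' @param seed Integer seed.
#' @return List with `classifier` and per-plane segmenter configs.
#' @export
desk_training_configs <- function(seed = 1L) {
  list(
    classifier = classifier_config(input_size = 48L, base_channels = 8L,
                                   batch_size = 15L, learning_rate = 1e-2,
                                   max_epochs = 14L, patience = 7L,
                                   normalization = "none", lr_decay = 0.8,
                                   seed = seed),
    axial = segmenter_config(structures = c("WH", "LV", "RV", "LA", "RA"),
                             base_channels = 8L, fuse_channels = 16L,
                             learning_rate = 2e-3, max_epochs = 16L,
                             patience = 8L, seed = seed + 1L),
    coronal = segmenter_config(structures = "WH", base_channels = 6L,
                               fuse_channels = 12L, learning_rate = 2e-3,
                               max_epochs = 8L, patience = 4L,
                               seed = seed + 2L),
    sagittal = segmenter_config(structures = "WH", base_channels = 6L,
                                fuse_channels = 12L, learning_rate = 2e-3,
                                max_epochs = 8L, patience = 4L,
                                seed = seed + 3L))
}

#' Run the reference desk-scale recovery study
#'
#' Generates a 16-phantom dataset (10 training / 3 tuning / 3 validation),
#' trains the stage-1 classifier on all training volumes (with boundary
#' oversampling) and the three stage-2 networks on the first five, then
#' evaluates: slice-classification Cohen's kappa over every validation
#' slice, and end-to-end per-structure metrics on `n_eval_volumes` held-out
#' validation phantoms.
#'
#' @param seed Integer seed driving phantom generation and training.
#' @param n_volumes,split_sizes Dataset size (defaults 16 as 10/3/3).
#' @param stage2_train_volumes Training volumes used by stage 2.
#' @param n_eval_volumes Validation volumes run end-to-end.
#' @param verbose Print training progress.
#' @return List with `stage1` (tuning F1, validation confusion matrix,
#'   kappa, accuracy), `metrics` (per-volume per-structure data frame),
#'   `summary` (median/IQR table), `bundle`, and `histories`.
#' @export
run_desk_study <- function(seed = 1L, n_volumes = 16L,
                           split_sizes = c(train = 10L, tune = 3L,
                                           validation = 3L),
                           stage2_train_volumes = 5L,
                           n_eval_volumes = 2L,
                           verbose = FALSE) {
  configs <- desk_training_configs(seed)
  ds <- generate_dataset(n_volumes, phantom_config(seed = seed),
                         split_sizes = split_sizes)
  s1 <- stage1_samples(ds, oversample_boundary = 3L, boundary_margin = 2L)
  r1 <- train_stage1(s1, configs$classifier, verbose = verbose)

  val_ids <- partition_ids(ds, "validation")
  tp <- fp <- tn <- fn <- 0L
  for (id in val_ids) {
    ph <- ds$phantoms[[id]]
    for (s in extract_axial_samples(ph$volume, ph$labels, stage = 1)) {
      pred <- predict_slice(r1$model, s$image) >= 0.5
      if (pred && s$heart_present) tp <- tp + 1L
      else if (pred) fp <- fp + 1L
      else if (s$heart_present) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  cm <- confusion_matrix(tn, fp, fn, tp)

  ds2 <- ds
  tr <- which(ds2$manifest$partition == "train")
  if (length(tr) > stage2_train_volumes) {
    ds2$manifest$partition[tr[-seq_len(stage2_train_volumes)]] <- "unused"
  }
  s2 <- stage2_samples(ds2, stride_axial = 2L, stride_plane = 4L,
                       depth = configs$axial$depth)
  r2 <- train_stage2(s2, configs[c("axial", "coronal", "sagittal")],
                     verbose = verbose)
  bundle <- list(classifier = r1$model, axial = r2$axial$model,
                 coronal = r2$coronal$model, sagittal = r2$sagittal$model)
  metrics <- NULL
  for (id in utils::head(val_ids, n_eval_volumes)) {
    ph <- ds$phantoms[[id]]
    res <- run_pipeline(ph$volume, bundle)
    m <- structure_metrics(res$masks, ph$labels$masks, ph$volume$spacing)
    m$volume <- id
    metrics <- rbind(metrics, m)
  }
  list(stage1 = list(tuning_f1 = max(r1$history$tune_metric, na.rm = TRUE),
                     tuning_slices = length(s1$tune),
                     confusion = cm,
                     kappa = cohens_kappa(cm),
                     accuracy = classification_report(cm)$accuracy),
       metrics = metrics,
       summary = summarize_metrics(metrics),
       bundle = bundle,
       histories = list(stage1 = r1$history, axial = r2$axial$history,
                        coronal = r2$coronal$history,
                        sagittal = r2$sagittal$history))
}

#' Train the full desk-scale model bundle on a phantom dataset
#'
#' Convenience wrapper: stage-1 samples -> [train_stage1()]; stage-2
#' samples -> [train_stage2()]; returns the bundle [run_pipeline()]
#' expects.
#'
#' @param dataset A `phantom_dataset` with train and tune partitions.
#' @param configs From [desk_training_configs()].
#' @param window A [window_setting()].
#' @param verbose Print epoch progress.
#' @return List with `classifier`, `axial`, `coronal`, `sagittal` models
#'   and `histories`.
#' @export
train_bundle <- function(dataset, configs = desk_training_configs(),
                         window = window_setting(), verbose = FALSE) {
  s1 <- stage1_samples(dataset, window = window)
  r1 <- train_stage1(s1, configs$classifier, verbose = verbose)
  s2 <- stage2_samples(dataset, window = window,
                       depth = configs$axial$depth)
  r2 <- train_stage2(s2, configs[c("axial", "coronal", "sagittal")],
                     verbose = verbose)
  list(classifier = r1$model,
       axial = r2$axial$model,
       coronal = r2$coronal$model,
       sagittal = r2$sagittal$model,
       histories = list(stage1 = r1$history,
                        axial = r2$axial$history,
                        coronal = r2$coronal$history,
                        sagittal = r2$sagittal$history))
}
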