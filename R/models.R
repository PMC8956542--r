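# Model contracts and training loops for the two stages.
#
# Stage 1 is a slice-level binary classifier (heart present / absent) over
# axial slices. Stage 2 is three fully convolutional segmentation networks
# with full-scale skip connections: one producing the five structure channels
# on axial slices, two producing a single whole-heart channel on coronal and
# sagittal slices. Both stages are optimised with Adamax, stage 1 under
# binary cross-entropy and stage 2 under the hybrid focal+dice objective.

#' Configuration for the stage-1 slice classifier
#'
#' Defaults follow the published training protocol: mini-batches of 15
#' slices, Adamax with learning rate 1e-4, at most 50 epochs, early stopping
#' on the F1 score of the tuning set (positive class = slice contains heart).
#' The `compact_residual` backbone is a small residual convolutional network
#' trainable on one CPU; `inception_resnet_v2` names the full-scale backbone,
#' which is not bundled and raises an informative error when selected.
#'
#' @param backbone `"compact_residual"` or `"inception_resnet_v2"`.
#' @param input_size Side length in pixels the slice is mean-pooled to before
#'   entering the network (the pooling factor is the integer ratio of the
#'   slice side to `input_size`).
#' @param base_channels Channel width of the first convolution.
#' @param batch_size Slices per optimiser step.
#' @param learning_rate Adamax step size.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Epochs without tuning-F1 improvement before stopping.
#' @param normalization `"instance"` (per-slice channel standardisation
#'   after each convolution) or `"none"`.
#' @param lr_decay Multiplicative learning-rate decay applied after each
#'   epoch (1 = constant).
#' @param stem_native Run the stem convolution at the native slice
#'   resolution before pooling to `input_size` (preserves few-pixel heart
#'   caps on boundary slices) instead of pooling the raw input first.
#' @param seed Integer seed governing initialisation and batch shuffling.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(backbone = c("compact_residual",
                                           "inception_resnet_v2"),
                              input_size = 48L,
                              base_channels = 8L,
                              batch_size = 15L,
                              learning_rate = 1e-4,
                              max_epochs = 50L,
                              patience = 5L,
                              normalization = c("instance", "none"),
                              lr_decay = 1,
                              stem_native = FALSE,
                              seed = 1L) {
  normalization <- match.arg(normalization)
  stopifnot(lr_decay > 0, lr_decay <= 1)
  backbone <- match.arg(backbone)
  stopifnot(batch_size >= 1, learning_rate > 0, base_channels >= 1,
            max_epochs >= 1)
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 normalization = normalization,
                 lr_decay = lr_decay,
                 stem_native = isTRUE(stem_native),
                 optimizer = "adamax",
                 early_stopping_metric = "f1",
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Configuration for a stage-2 segmentation network
#'
#' Defaults follow the published protocol: batches of 5 slices, Adamax with
#' learning rate 1e-3, beta1 0.9, beta2 0.999, epsilon 1e-7, and the hybrid
#' focal+dice loss. Early stopping monitors mean Dice on the tuning set.
#'
#' @param structures Character vector of output channels; the axial network
#'   uses all five (`WH`, `LV`, `RV`, `LA`, `RA`), the coronal and sagittal
#'   networks only `WH`.
#' @param depth Number of encoder levels (>= 2).
#' @param base_channels Channel width of the first encoder level; level `e`
#'   has `base_channels * 2^(e-1)` channels.
#' @param fuse_channels Channels after the full-scale aggregation convolution
#'   at each decoder level.
#' @param batch_size,learning_rate,beta1,beta2,epsilon Adamax settings.
#' @param loss A [loss_config()].
#' @param deep_supervision Attach auxiliary output heads to the coarser
#'   decoder levels (default off).
#' @param max_epochs,patience Early-stopping control.
#' @param normalization `"instance"` (per-slice channel standardisation
#'   after each convolution; keeps small low-contrast structures trainable)
#'   or `"none"`.
#' @param seed Integer seed for initialisation and shuffling.
#' @return A `segmenter_config` list.
#' @export
segmenter_config <- function(structures = c("WH", "LV", "RV", "LA", "RA"),
                             depth = 3L,
                             base_channels = 8L,
                             fuse_channels = 2L * base_channels,
                             batch_size = 5L,
                             learning_rate = 1e-3,
                             beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                             loss = loss_config(),
                             deep_supervision = FALSE,
                             max_epochs = 30L,
                             patience = 10L,
                             normalization = c("instance", "none"),
                             seed = 1L) {
  normalization <- match.arg(normalization)
  stopifnot(depth >= 2, length(structures) >= 1, batch_size >= 1,
            learning_rate > 0)
  structure(list(structures = structures, depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 fuse_channels = as.integer(fuse_channels),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, loss = loss,
                 deep_supervision = isTRUE(deep_supervision),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 normalization = normalization,
                 optimizer = "adamax",
                 seed = as.integer(seed)),
            class = "segmenter_config")
}

## ---- stage-1 classifier --------------------------------------------------

#' Build the stage-1 slice classifier
#'
#' Maps one windowed 2D slice (values in \[0,1\]) to the probability that it
#' contains the heart. The desk-scale `compact_residual` backbone is a
#' three-block residual convolutional network (stem convolution, one identity
#' residual block, two projection residual blocks with 2x2 max-pooling
#' between, concatenated global average + max pooling, and a sigmoid output
#' unit).
#'
#' @param config A [classifier_config()].
#' @return A `slice_classifier` object; apply it with [predict_slice()].
#' @export
build_slice_classifier <- function(config = classifier_config()) {
  if (config$backbone == "inception_resnet_v2") {
    stop("the 'inception_resnet_v2' backbone requires externally supplied ",
         "pretrained weights and is not bundled; use 'compact_residual'")
  }
  set.seed(config$seed)
  C <- config$base_channels
  use_norm <- identical(config$normalization, "instance")
  cn <- function(k, cin, cout, name) {
    list(conv = conv_param(k, cin, cout, name),
         norm = if (use_norm) norm_param(cout, paste0(name, ".in")))
  }
  params <- list(
    stem  = cn(3L, 1L, C, "stem"),
    res1a = cn(3L, C, C, "res1a"),
    res1b = cn(3L, C, C, "res1b"),
    res2a = cn(3L, C, 2L * C, "res2a"),
    res2b = cn(3L, 2L * C, 2L * C, "res2b"),
    skip2 = cn(1L, C, 2L * C, "skip2"),
    res3a = cn(3L, 2L * C, 4L * C, "res3a"),
    res3b = cn(3L, 4L * C, 4L * C, "res3b"),
    skip3 = cn(1L, 2L * C, 4L * C, "skip3"),
    dense = list(w = nn_param(init_weight(8L * C, 1L), "dense.w"),
                 b = nn_param(numeric(1L), "dense.b"))
  )
  structure(list(params = params, config = config),
            class = c("slice_classifier", "hc_model"))
}

fwd_classifier <- function(net, image, tape) {
  cfg <- net$config
  p <- net$params
  H <- nrow(image); W <- ncol(image)
  x <- matrix(as.vector(image), H * W, 1L)
  f <- max(1L, H %/% cfg$input_size)
  if (f > 1L && !isTRUE(cfg$stem_native)) {
    stopifnot(H %% f == 0L, W %% f == 0L)
    x <- op_meanpool(tape, x, H, W, f)
    H <- H %/% f; W <- W %/% f
    f <- 1L
  }
  conv_n <- function(x, blk, H, W, k = 3L) {
    h <- if (k == 1L) {
      op_conv1x1(tape, x, blk$conv$w, blk$conv$b)
    } else {
      op_conv(tape, x, blk$conv$w, blk$conv$b, H, W, k)
    }
    if (!is.null(blk$norm)) {
      h <- op_instnorm(tape, h, blk$norm$g, blk$norm$b)
    }
    h
  }
  res_block <- function(x, a, b, skip, H, W) {
    h <- op_relu(tape, conv_n(x, a, H, W))
    h <- conv_n(h, b, H, W)
    s <- if (is.null(skip)) x else conv_n(x, skip, H, W, 1L)
    op_relu(tape, op_add(tape, h, s))
  }
  h <- op_relu(tape, conv_n(x, p$stem, H, W))
  if (f > 1L) {           # native-resolution stem: pool after the stem
    stopifnot(H %% f == 0L, W %% f == 0L)
    h <- op_maxpool_f(tape, h, H, W, f)
    H <- H %/% f; W <- W %/% f
  }
  h <- res_block(h, p$res1a, p$res1b, NULL, H, W)
  h <- op_maxpool2(tape, h, H, W); H <- H %/% 2L; W <- W %/% 2L
  h <- res_block(h, p$res2a, p$res2b, p$skip2, H, W)
  h <- op_maxpool2(tape, h, H, W); H <- H %/% 2L; W <- W %/% 2L
  h <- res_block(h, p$res3a, p$res3b, p$skip3, H, W)
  # average pooling summarises extent; log-sum-exp pooling preserves small
  # caps of the heart on boundary slices that averaging would dilute
  h <- op_cbind(tape, list(op_gap(tape, h), op_lsepool(tape, h)))
  lw <- leaf(tape, p$dense$w); lb <- leaf(tape, p$dense$b)
  op_sigmoid(tape, op_addbias(tape, op_matmul(tape, h, lw), lb))
}

#' Classify one slice
#'
#' @param net A `slice_classifier`.
#' @param image 2D matrix of windowed intensities in \[0,1\].
#' @return Probability in \[0,1\] that the slice contains the heart.
#' @export
predict_slice <- function(net, image) UseMethod("predict_slice")

#' @export
predict_slice.slice_classifier <- function(net, image) {
  as.numeric(node_value(fwd_classifier(net, image, nn_tape())))
}

#' Number of trainable parameters of a model
#' @param net A `slice_classifier` or `unet3plus` object.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) param_count(net$params)

## ---- stage-2 UNet3+ ------------------------------------------------------

#' Build a full-scale-skip segmentation network (UNet3+ style)
#'
#' An encoder-decoder in which every decoder level aggregates feature maps
#' from all encoder levels at the same or finer scale (mean-pooled down) and
#' from all coarser decoder levels including the bottleneck (nearest-neighbour
#' upsampled), so each decoder level receives exactly `depth` incoming
#' streams. Each stream passes through a 3x3 convolution to
#' `base_channels` channels; the concatenated streams are fused by a 3x3
#' convolution to `fuse_channels` channels. A 1x1 convolution with a
#' per-channel sigmoid produces one probability map per structure at full
#' resolution.
#'
#' Input side lengths must be divisible by `2^(depth-1)`; [predict_segmenter()]
#' zero-pads and crops automatically.
#'
#' @param config A [segmenter_config()].
#' @return A `unet3plus` object.
#' @export
build_unet3plus <- function(config = segmenter_config()) {
  set.seed(config$seed)
  D <- config$depth
  F0 <- config$base_channels
  Fc <- config$fuse_channels
  S <- length(config$structures)
  use_norm <- identical(config$normalization, "instance")
  cn <- function(k, cin, cout, name) {
    list(conv = conv_param(k, cin, cout, name),
         norm = if (use_norm) norm_param(cout, paste0(name, ".in")))
  }
  ch <- F0 * 2L^(seq_len(D) - 1L)
  enc <- vector("list", D)
  cin <- 1L
  for (e in seq_len(D)) {
    enc[[e]] <- list(a = cn(3L, cin, ch[e], sprintf("enc%da", e)),
                     b = cn(3L, ch[e], ch[e], sprintf("enc%db", e)))
    cin <- ch[e]
  }
  dec <- vector("list", D)   # dec[[d]] used for d in (D-1)..1
  for (d in rev(seq_len(D - 1L))) {
    streams <- vector("list", D)
    for (e in seq_len(d)) {
      streams[[e]] <- cn(3L, ch[e], F0, sprintf("dec%d.enc%d", d, e))
    }
    for (j in (d + 1L):D) {
      src_ch <- if (j == D) ch[D] else Fc
      streams[[j]] <- cn(3L, src_ch, F0, sprintf("dec%d.dec%d", d, j))
    }
    dec[[d]] <- list(streams = streams,
                     fuse = cn(3L, D * F0, Fc, sprintf("dec%d.fuse", d)))
  }
  head <- conv_param(1L, Fc, S, "head")
  aux <- NULL
  if (config$deep_supervision && D >= 3L) {
    aux <- lapply(2:(D - 1L), function(d) conv_param(1L, Fc, S,
                                                     sprintf("aux%d", d)))
  }
  structure(list(params = list(enc = enc, dec = dec, head = head, aux = aux),
                 config = config),
            class = c("unet3plus", "hc_model"))
}

#' Incoming feature streams at a decoder level
#'
#' Under the full-scale skip design every decoder level receives one stream
#' per network level: all encoders at the same or finer scale plus all
#' coarser decoders and the bottleneck.
#'
#' @param net A `unet3plus` object.
#' @param d Decoder level (1 = finest; valid up to `depth - 1`).
#' @return Integer number of incoming streams.
#' @export
n_decoder_streams <- function(net, d) {
  stopifnot(d >= 1, d <= net$config$depth - 1L)
  length(net$params$dec[[d]]$streams)
}

fwd_unet <- function(net, image, tape) {
  cfg <- net$config
  D <- cfg$depth
  H <- nrow(image); W <- ncol(image)
  div <- 2L^(D - 1L)
  stopifnot(H %% div == 0L, W %% div == 0L)
  Hs <- H %/% 2L^(seq_len(D) - 1L)
  Ws <- W %/% 2L^(seq_len(D) - 1L)
  x <- matrix(as.vector(image), H * W, 1L)
  cnr <- function(x, blk, H, W) {
    h <- op_conv(tape, x, blk$conv$w, blk$conv$b, H, W)
    if (!is.null(blk$norm)) {
      h <- op_instnorm(tape, h, blk$norm$g, blk$norm$b)
    }
    op_relu(tape, h)
  }
  encv <- vector("list", D)
  h <- x
  for (e in seq_len(D)) {
    if (e > 1L) h <- op_maxpool2(tape, h, Hs[e - 1L], Ws[e - 1L])
    pe <- net$params$enc[[e]]
    h <- cnr(h, pe$a, Hs[e], Ws[e])
    h <- cnr(h, pe$b, Hs[e], Ws[e])
    encv[[e]] <- h
  }
  decv <- vector("list", D)
  decv[[D]] <- encv[[D]]          # bottleneck acts as the coarsest decoder
  for (d in rev(seq_len(D - 1L))) {
    pd <- net$params$dec[[d]]
    streams <- vector("list", D)
    for (e in seq_len(d)) {
      src <- encv[[e]]
      f <- 2L^(d - e)
      if (f > 1L) src <- op_meanpool(tape, src, Hs[e], Ws[e], f)
      streams[[e]] <- cnr(src, pd$streams[[e]], Hs[d], Ws[d])
    }
    for (j in (d + 1L):D) {
      src <- op_upnn(tape, decv[[j]], Hs[j], Ws[j], 2L^(j - d))
      streams[[j]] <- cnr(src, pd$streams[[j]], Hs[d], Ws[d])
    }
    cat <- op_cbind(tape, streams)
    decv[[d]] <- cnr(cat, pd$fuse, Hs[d], Ws[d])
  }
  out <- op_sigmoid(tape, op_conv1x1(tape, decv[[1L]], net$params$head$w,
                                     net$params$head$b))
  if (cfg$deep_supervision && !is.null(net$params$aux)) {
    auxs <- lapply(seq_along(net$params$aux), function(i) {
      d <- i + 1L
      a <- net$params$aux[[i]]
      up <- op_upnn(tape, decv[[d]], Hs[d], Ws[d], 2L^(d - 1L))
      op_sigmoid(tape, op_conv1x1(tape, up, a$w, a$b))
    })
    attr(out, "aux") <- auxs
  }
  out
}

#' Segment one slice
#'
#' Pads the slice with zeros to a multiple of `2^(depth-1)`, runs the
#' network, and crops back.
#'
#' @param net A `unet3plus` object.
#' @param image 2D matrix of windowed intensities in \[0,1\].
#' @return H x W x S array of per-structure probabilities, S following
#'   `net$config$structures`.
#' @export
predict_segmenter <- function(net, image) UseMethod("predict_segmenter")

#' @export
predict_segmenter.unet3plus <- function(net, image) {
  div <- 2L^(net$config$depth - 1L)
  H0 <- nrow(image); W0 <- ncol(image)
  H <- ceiling(H0 / div) * div
  W <- ceiling(W0 / div) * div
  if (H != H0 || W != W0) {
    padded <- matrix(0, H, W)
    padded[seq_len(H0), seq_len(W0)] <- image
    image <- padded
  }
  out <- node_value(fwd_unet(net, image, nn_tape()))
  arr <- array(out, dim = c(H, W, ncol(out)),
               dimnames = list(NULL, NULL, net$config$structures))
  arr[seq_len(H0), seq_len(W0), , drop = FALSE]
}

## ---- training loops ------------------------------------------------------

f1_from_preds <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  if (tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Train the stage-1 slice classifier
#'
#' Minimises binary cross-entropy with Adamax; after each epoch the F1 score
#' (positive class = heart) on the tuning partition is evaluated, the best
#' epoch is checkpointed, and training stops after `patience` epochs without
#' improvement.
#'
#' @param samples List with elements `train` and `tune`, each a list of
#'   stage-1 slice samples (see [extract_axial_samples()]).
#' @param config A [classifier_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` (the trained classifier, best-epoch weights
#'   restored) and `history` (a `training_history` data frame).
#' @export
train_stage1 <- function(samples, config = classifier_config(),
                         verbose = FALSE) {
  train <- samples$train; tune <- samples$tune
  if (length(train) == 0L || length(tune) == 0L) {
    stop("train and tune partitions must both be non-empty")
  }
  tune_y <- vapply(tune, function(s) isTRUE(s$heart_present), NA)
  if (length(unique(tune_y)) < 2L) {
    stop("tuning set contains a single class; F1 early stopping undefined")
  }
  net <- build_slice_classifier(config)
  params <- flatten_params(net$params)
  opt <- adamax_state(params, lr = config$learning_rate)
  best_f1 <- -Inf; best_snap <- params_snapshot(params); best_epoch <- 0L
  wait <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     tune_metric = numeric())
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(train))
    total_loss <- 0
    nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      nn_zero_grad(params)
      batch_loss <- 0
      for (i in idx) {
        tp <- nn_tape()
        prob <- fwd_classifier(net, train[[i]]$image, tp)
        loss <- op_bce(tp, prob, as.numeric(isTRUE(train[[i]]$heart_present)))
        nn_backward(tp, loss)
        batch_loss <- batch_loss + node_value(loss)
      }
      adamax_step(opt, scale = 1 / length(idx))
      total_loss <- total_loss + batch_loss / length(idx)
      nb <- nb + 1L
    }
    opt$lr <- opt$lr * (config$lr_decay %||% 1)
    probs <- vapply(tune, function(s) predict_slice(net, s$image), 0)
    f1 <- f1_from_preds(probs >= 0.5, tune_y)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = total_loss / nb,
                                   tune_metric = f1))
    if (verbose) message(sprintf("epoch %d loss %.4f tune F1 %.4f",
                                 epoch, total_loss / nb, f1))
    if (!is.na(f1) && f1 > best_f1 + 1e-12) {
      best_f1 <- f1; best_snap <- params_snapshot(params)
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$patience) break
    }
  }
  params_restore(params, best_snap)
  history <- structure(hist, class = c("training_history", "data.frame"),
                       stopping_epoch = epoch, best_epoch = best_epoch,
                       metric = "f1", seed = config$seed)
  list(model = net, history = history)
}

mask_matrix <- function(sample, structures) {
  H <- nrow(sample$image); W <- ncol(sample$image)
  m <- matrix(0, H * W, length(structures))
  colnames(m) <- structures
  if (!is.null(sample$masks)) {
    for (i in seq_along(structures)) {
      ms <- sample$masks[[structures[i]]]
      if (!is.null(ms)) m[, i] <- as.numeric(as.vector(ms))
    }
  }
  m
}

hard_dice_mean <- function(prob, target, thr = 0.5) {
  vals <- vapply(seq_len(ncol(target)), function(ch) {
    a <- prob[, ch] >= thr; b <- target[, ch] >= 0.5
    if (!any(a) && !any(b)) return(1)
    2 * sum(a & b) / (sum(a) + sum(b))
  }, 0)
  mean(vals)
}

train_one_segmenter <- function(train, tune, config, plane, verbose = FALSE) {
  if (length(train) == 0L) stop("empty training set for plane '", plane, "'")
  if (length(tune) == 0L) stop("empty tuning set for plane '", plane, "'")
  net <- build_unet3plus(config)
  params <- flatten_params(net$params)
  opt <- adamax_state(params, lr = config$learning_rate, beta1 = config$beta1,
                      beta2 = config$beta2, eps = config$epsilon)
  S <- config$structures
  tr_masks <- lapply(train, mask_matrix, structures = S)
  tu_masks <- lapply(tune, mask_matrix, structures = S)
  best <- -Inf; best_snap <- params_snapshot(params); best_epoch <- 0L
  wait <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     tune_metric = numeric())
  set.seed(config$seed + 2L)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(train))
    total_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      nn_zero_grad(params)
      batch_loss <- 0
      for (i in idx) {
        tp <- nn_tape()
        out <- fwd_unet(net, train[[i]]$image, tp)
        loss <- op_hybrid_loss(tp, out, tr_masks[[i]], config$loss)
        aux <- attr(out, "aux")
        if (!is.null(aux)) {
          for (a in aux) {
            loss <- op_add(tp, loss,
                           op_scale(tp, op_hybrid_loss(tp, a, tr_masks[[i]],
                                                       config$loss),
                                    1 / length(aux)))
          }
        }
        nn_backward(tp, loss)
        batch_loss <- batch_loss + node_value(loss)
      }
      adamax_step(opt, scale = 1 / length(idx))
      total_loss <- total_loss + batch_loss / length(idx)
      nb <- nb + 1L
    }
    dice <- mean(vapply(seq_along(tune), function(i) {
      pr <- node_value(fwd_unet(net, tune[[i]]$image, nn_tape()))
      hard_dice_mean(pr, tu_masks[[i]])
    }, 0))
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = total_loss / nb,
                                   tune_metric = dice))
    if (verbose) message(sprintf("[%s] epoch %d loss %.4f tune Dice %.4f",
                                 plane, epoch, total_loss / nb, dice))
    if (dice > best + 1e-12) {
      best <- dice; best_snap <- params_snapshot(params)
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$patience) break
    }
  }
  params_restore(params, best_snap)
  history <- structure(hist, class = c("training_history", "data.frame"),
                       stopping_epoch = epoch, best_epoch = best_epoch,
                       metric = "dice", seed = config$seed)
  list(model = net, history = history)
}

#' Train the three stage-2 segmentation networks
#'
#' Each plane's network is trained independently under the hybrid focal+dice
#' loss, with early stopping on the mean binarised Dice of its tuning set.
#'
#' @param samples Named list with elements `axial`, `coronal`, `sagittal`;
#'   each a list with `train` and `tune` lists of slice samples carrying
#'   per-structure masks (five for axial, WH only for coronal/sagittal).
#' @param configs Named list of [segmenter_config()]s per plane.
#' @param verbose Print per-epoch progress.
#' @return Named list per plane, each with `model` and `history`.
#' @export
train_stage2 <- function(samples, configs = NULL, verbose = FALSE) {
  planes <- c("axial", "coronal", "sagittal")
  if (is.null(configs)) {
    configs <- list(
      axial = segmenter_config(structures = c("WH", "LV", "RV", "LA", "RA")),
      coronal = segmenter_config(structures = "WH"),
      sagittal = segmenter_config(structures = "WH"))
  }
  out <- list()
  for (pl in planes) {
    sp <- samples[[pl]]
    if (is.null(sp) || length(sp$train) == 0L) {
      stop("no training samples for plane '", pl, "'")
    }
    out[[pl]] <- train_one_segmenter(sp$train, sp$tune, configs[[pl]], pl,
                                     verbose = verbose)
  }
  out
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("training history: %d epochs, best %s %.4f at epoch %d\n",
              nrow(x), attr(x, "metric"),
              max(x$tune_metric, na.rm = TRUE), attr(x, "best_epoch")))
  invisible(x)
}

## ---- model persistence ---------------------------------------------------

#' Save a trained model bundle
#'
#' Writes a self-describing archive (RDS) holding parameter values, the
#' config, and the training seed.
#'
#' @param model A `slice_classifier` or `unet3plus`.
#' @param path Destination file.
#' @export
save_model <- function(model, path) {
  obj <- list(class = class(model)[1L],
              config = model$config,
              values = params_snapshot(model$params))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model bundle written by [save_model()]
#' @param path File written by [save_model()].
#' @return The reconstructed model.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  net <- switch(obj$class,
                slice_classifier = build_slice_classifier(obj$config),
                unet3plus = build_unet3plus(obj$config),
                stop("unknown model class in archive: ", obj$class))
  params_restore(flatten_params(net$params), obj$values)
  net
}
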