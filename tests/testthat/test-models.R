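# Training loop contracts for both stages (tiny synthetic slice sets).

make_cls_samples <- function(n_pos, n_neg, size = 16L, seed = 1L) {
  set.seed(seed)
  mk <- function(pos) {
    img <- matrix(runif(size * size, 0, 0.25), size, size)
    if (pos) img[5:12, 5:12] <- img[5:12, 5:12] + 0.6
    list(image = pmin(img, 1), heart_present = pos)
  }
  c(lapply(seq_len(n_pos), function(i) mk(TRUE)),
    lapply(seq_len(n_neg), function(i) mk(FALSE)))
}

tiny_cls_config <- function(...) {
  classifier_config(input_size = 16L, base_channels = 2L, batch_size = 4L,
                    learning_rate = 5e-3, max_epochs = 3L, patience = 1L,
                    seed = 1L, ...)
}

test_that("stage-1 training respects history and early-stopping contracts", {
  samples <- list(train = make_cls_samples(8, 8),
                  tune = make_cls_samples(3, 3, seed = 2))
  r <- train_stage1(samples, tiny_cls_config())
  expect_lte(nrow(r$history), 3)
  expect_lte(attr(r$history, "stopping_epoch"), 3)
  expect_gte(attr(r$history, "best_epoch"), 1)
  expect_true(all(c("epoch", "train_loss", "tune_metric") %in%
                    names(r$history)))
  # reproducibility: same config trains to identical weights
  r2 <- train_stage1(samples, tiny_cls_config())
  ns <- asNamespace("heartcascade")
  expect_identical(ns$params_snapshot(r$model$params),
                   ns$params_snapshot(r2$model$params))
  expect_identical(r$history$train_loss, r2$history$train_loss)
})

test_that("patience 0 stops at the first non-improving epoch", {
  samples <- list(train = make_cls_samples(6, 6),
                  tune = make_cls_samples(2, 2, seed = 3))
  cfg <- tiny_cls_config()
  cfg$patience <- 0L
  cfg$max_epochs <- 10L
  r <- train_stage1(samples, cfg)
  h <- r$history
  stop_ep <- attr(h, "stopping_epoch")
  if (stop_ep < 10L) {
    # the stopping epoch itself is the first non-improving one
    expect_equal(stop_ep, attr(h, "best_epoch") + 1L)
  }
})

test_that("a single-class tuning set is rejected", {
  samples <- list(train = make_cls_samples(4, 4),
                  tune = make_cls_samples(3, 0, seed = 4))
  expect_error(train_stage1(samples, tiny_cls_config()), "single class")
  expect_error(train_stage1(list(train = list(), tune = list()),
                            tiny_cls_config()), "non-empty")
})

make_seg_samples <- function(n, size = 16L, structures = "WH", seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    img <- matrix(runif(size * size, 0, 0.2), size, size)
    m <- matrix(FALSE, size, size)
    m[4:11, 4:11] <- TRUE
    img[m] <- img[m] + 0.6
    masks <- stats::setNames(rep(list(m), length(structures)), structures)
    list(image = pmin(img, 1), masks = masks)
  })
}

tiny_seg_config <- function(structures = "WH") {
  segmenter_config(structures = structures, depth = 2L, base_channels = 2L,
                   fuse_channels = 3L, batch_size = 4L, learning_rate = 5e-3,
                   max_epochs = 2L, patience = 1L, seed = 1L)
}

test_that("stage-2 trains all three planes with the stated channel counts", {
  samples <- list(
    axial = list(train = make_seg_samples(4, structures =
                                            c("WH", "LV", "RV", "LA", "RA")),
                 tune = make_seg_samples(2, seed = 2, structures =
                                           c("WH", "LV", "RV", "LA", "RA"))),
    coronal = list(train = make_seg_samples(4), tune = make_seg_samples(2)),
    sagittal = list(train = make_seg_samples(4), tune = make_seg_samples(2)))
  configs <- list(
    axial = tiny_seg_config(c("WH", "LV", "RV", "LA", "RA")),
    coronal = tiny_seg_config(), sagittal = tiny_seg_config())
  r <- train_stage2(samples, configs)
  expect_named(r, c("axial", "coronal", "sagittal"))
  out <- predict_segmenter(r$axial$model, samples$axial$tune[[1]]$image)
  expect_equal(dim(out)[3], 5L)
  out1 <- predict_segmenter(r$coronal$model, samples$coronal$tune[[1]]$image)
  expect_equal(dim(out1)[3], 1L)
  for (pl in names(r)) expect_lte(nrow(r[[pl]]$history), 2)
})

test_that("an empty plane dataset raises an error naming the plane", {
  samples <- list(axial = list(train = list(), tune = list()),
                  coronal = list(train = make_seg_samples(2),
                                 tune = make_seg_samples(1)),
                  sagittal = list(train = make_seg_samples(2),
                                  tune = make_seg_samples(1)))
  expect_error(train_stage2(samples), "axial")
})

test_that("batch loss in the training loop equals the standalone loss", {
  ns <- asNamespace("heartcascade")
  cfg <- tiny_seg_config()
  net <- build_unet3plus(cfg)
  s <- make_seg_samples(1)[[1]]
  tp <- ns$nn_tape()
  out <- ns$fwd_unet(net, s$image, tp)
  tape_loss <- ns$node_value(
    ns$op_hybrid_loss(tp, out, ns$mask_matrix(s, cfg$structures), cfg$loss))
  ref <- hybrid_loss(ns$node_value(out),
                     ns$mask_matrix(s, cfg$structures), cfg$loss)
  expect_equal(tape_loss, ref, tolerance = 1e-12)
})

test_that("models save and load with identical predictions", {
  net <- build_unet3plus(tiny_seg_config())
  img <- matrix(runif(256), 16, 16)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(net, f)
  back <- load_model(f)
  expect_equal(predict_segmenter(back, img), predict_segmenter(net, img))
  cls <- build_slice_classifier(tiny_cls_config())
  f2 <- withr::local_tempfile(fileext = ".rds")
  save_model(cls, f2)
  expect_equal(predict_slice(load_model(f2), img), predict_slice(cls, img))
})
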