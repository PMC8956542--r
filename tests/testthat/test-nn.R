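# The autodiff engine and network architecture contracts.

test_that("im2col and col2im are exact adjoints", {
  set.seed(1)
  H <- 5L; W <- 7L; Cin <- 3L; k <- 3L
  x <- matrix(rnorm(H * W * Cin), H * W, Cin)
  dA <- matrix(rnorm(H * W * k * k * Cin), H * W, k * k * Cin)
  A <- heartcascade:::cpp_im2col(x, H, W, k)
  expect_equal(sum(A * dA),
               sum(x * heartcascade:::cpp_col2im(dA, H, W, k, Cin)),
               tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  ns <- asNamespace("heartcascade")
  set.seed(42)
  cfg <- segmenter_config(structures = c("WH", "LV"), depth = 3,
                          base_channels = 2, fuse_channels = 3, seed = 7)
  net <- build_unet3plus(cfg)
  img <- matrix(runif(64), 8, 8)
  tgt <- matrix(rbinom(128, 1, 0.4), 64, 2)
  lc <- loss_config()
  params <- ns$flatten_params(net$params)
  # jitter away from exact ReLU kinks / pooling ties at zero-bias init
  set.seed(5)
  for (p in params) p$value <- p$value + rnorm(length(p$value)) * 0.05
  loss_at <- function() {
    tp <- ns$nn_tape()
    as.numeric(ns$node_value(
      ns$op_hybrid_loss(tp, ns$fwd_unet(net, img, tp), tgt, lc)))
  }
  ns$nn_zero_grad(params)
  tp <- ns$nn_tape()
  L <- ns$op_hybrid_loss(tp, ns$fwd_unet(net, img, tp), tgt, lc)
  ns$nn_backward(tp, L)
  set.seed(8)
  for (pi in seq_along(params)) {
    p <- params[[pi]]
    for (k in sample(length(p$value), min(2L, length(p$value)))) {
      eps <- 1e-6
      old <- p$value[k]
      p$value[k] <- old + eps; lp <- loss_at()
      p$value[k] <- old - eps; lm <- loss_at()
      p$value[k] <- old
      num <- (lp - lm) / (2 * eps)
      expect_equal(p$grad[k], num, tolerance = 5e-3)
    }
  }
})

test_that("tape losses agree with the reference loss implementations", {
  ns <- asNamespace("heartcascade")
  set.seed(2)
  p <- matrix(runif(96, 0.02, 0.98), 32, 3)
  tg <- matrix(rbinom(96, 1, 0.3), 32, 3)
  lc <- loss_config()
  tp <- ns$nn_tape()
  expect_equal(ns$node_value(ns$op_dice_loss(tp, p, tg, lc$dice_smooth)),
               dice_loss(p, tg, lc$dice_smooth, channels = TRUE),
               tolerance = 1e-12)
  expect_equal(ns$node_value(ns$op_focal_loss(tp, p, tg, lc$focal_gamma,
                                              lc$focal_alpha)),
               focal_loss(p, tg, lc$focal_gamma, lc$focal_alpha),
               tolerance = 1e-12)
  expect_equal(ns$node_value(ns$op_hybrid_loss(tp, p, tg, lc)),
               hybrid_loss(p, tg, lc, channels = TRUE), tolerance = 1e-12)
  expect_equal(ns$node_value(ns$op_bce(tp, p, tg)), bce_loss(p, tg),
               tolerance = 1e-12)
})

test_that("classifier parameter count matches a layer-walk oracle", {
  C <- 8L
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  convs <- conv_n(3, 1, C) +
    2 * conv_n(3, C, C) +                        # identity residual block
    conv_n(3, C, 2 * C) + conv_n(3, 2 * C, 2 * C) + conv_n(1, C, 2 * C) +
    conv_n(3, 2 * C, 4 * C) + conv_n(3, 4 * C, 4 * C) +
    conv_n(1, 2 * C, 4 * C)
  head <- 8 * C * 1 + 1                          # avg+lse pooled head
  bare <- build_slice_classifier(classifier_config(base_channels = C,
                                                   normalization = "none"))
  expect_equal(n_parameters(bare), convs + head)
  # instance norm adds a gain and shift per normalised channel
  norm_ch <- C + C + C + 2 * C + 2 * C + 2 * C + 4 * C + 4 * C + 4 * C
  net <- build_slice_classifier(classifier_config(base_channels = C))
  expect_equal(n_parameters(net), convs + head + 2 * norm_ch)
})

test_that("unet parameter count and connectivity match the full-scale-skip
           definition", {
  F0 <- 4L; D <- 3L; Fc <- 8L; S <- 5L
  cfg <- segmenter_config(structures = paste0("s", 1:S), depth = D,
                          base_channels = F0, fuse_channels = Fc,
                          normalization = "none")
  net <- build_unet3plus(cfg)
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  ch <- F0 * 2L^(0:(D - 1L))
  expected <- conv_n(3, 1, ch[1]) + conv_n(3, ch[1], ch[1]) +
    conv_n(3, ch[1], ch[2]) + conv_n(3, ch[2], ch[2]) +
    conv_n(3, ch[2], ch[3]) + conv_n(3, ch[3], ch[3]) +
    # decoder 2: enc1 (pooled), enc2, bottleneck (up); fuse
    conv_n(3, ch[1], F0) + conv_n(3, ch[2], F0) + conv_n(3, ch[3], F0) +
    conv_n(3, D * F0, Fc) +
    # decoder 1: enc1, dec2 (up), bottleneck (up); fuse
    conv_n(3, ch[1], F0) + conv_n(3, Fc, F0) + conv_n(3, ch[3], F0) +
    conv_n(3, D * F0, Fc) +
    conv_n(1, Fc, S)
  expect_equal(n_parameters(net), expected)
  # instance norm adds a gain and a shift per normalised conv channel
  norm_channels <- 2 * sum(ch) +              # two convs per encoder level
    (D - 1) * D * F0 +                        # stream convs per decoder
    (D - 1) * Fc                              # fuse conv per decoder
  withn <- build_unet3plus(segmenter_config(structures = paste0("s", 1:S),
                                            depth = D, base_channels = F0,
                                            fuse_channels = Fc))
  expect_equal(n_parameters(withn), expected + 2 * norm_channels)
  # every decoder level receives exactly `depth` incoming streams
  for (d in seq_len(D - 1L)) expect_equal(n_decoder_streams(net, d), D)
})

test_that("forward passes respect shape and range contracts", {
  cfg <- segmenter_config(structures = c("WH", "LV", "RV", "LA", "RA"),
                          depth = 3, base_channels = 2, fuse_channels = 4,
                          seed = 3)
  net <- build_unet3plus(cfg)
  img <- matrix(runif(64 * 64), 64, 64)
  out <- predict_segmenter(net, img)
  expect_equal(dim(out), c(64L, 64L, 5L))
  expect_true(all(out >= 0 & out <= 1))
  # non-divisible input is padded and cropped back
  img2 <- matrix(runif(30 * 42), 30, 42)
  out2 <- predict_segmenter(net, img2)
  expect_equal(dim(out2), c(30L, 42L, 5L))
  # all-zero input gives a constant map per channel (bias-only init path)
  outz <- predict_segmenter(net, matrix(0, 32, 32))
  for (s in 1:5) expect_lt(diff(range(outz[, , s])), 1e-12)
  cls <- build_slice_classifier(classifier_config(input_size = 16, seed = 2))
  pr <- predict_slice(cls, matrix(runif(32 * 32), 32, 32))
  expect_true(is.finite(pr) && pr >= 0 && pr <= 1)
})

test_that("initialisation is deterministic in the seed", {
  ns <- asNamespace("heartcascade")
  a <- build_slice_classifier(classifier_config(seed = 11))
  b <- build_slice_classifier(classifier_config(seed = 11))
  expect_identical(ns$params_snapshot(a$params), ns$params_snapshot(b$params))
  c2 <- build_slice_classifier(classifier_config(seed = 12))
  expect_false(identical(ns$params_snapshot(a$params),
                         ns$params_snapshot(c2$params)))
  u1 <- build_unet3plus(segmenter_config(seed = 11))
  u2 <- build_unet3plus(segmenter_config(seed = 11))
  expect_identical(ns$params_snapshot(u1$params),
                   ns$params_snapshot(u2$params))
})

test_that("the clinical-scale backbone name is rejected without weights", {
  expect_error(
    build_slice_classifier(classifier_config(backbone =
                                               "inception_resnet_v2")),
    "pretrained")
})
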