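# Slab gating, view fusion algebra, and the end-to-end pipeline with
# oracle models (no training needed).

test_that("slab selection follows the documented smoothing rule", {
  p <- numeric(50)
  p[11:41] <- 1                      # 0-based slices 10..40
  s <- slab_from_probs(p)
  expect_equal(c(s$z_start, s$z_end), c(10L, 41L))
  # two runs with a multi-slice gap: longest run wins, gap stays open
  p2 <- numeric(50)
  p2[11:21] <- 1; p2[26:41] <- 1     # 0-based 10..20 and 25..40
  s2 <- slab_from_probs(p2)
  expect_equal(c(s2$z_start, s2$z_end), c(25L, 41L))
  # a single-slice gap is closed
  p3 <- numeric(20)
  p3[6:10] <- 1; p3[12:16] <- 1      # 0-based 5..9 and 11..15, gap at 10
  s3 <- slab_from_probs(p3)
  expect_equal(c(s3$z_start, s3$z_end), c(5L, 16L))
  # no positive slice: explicit empty signal, not an error
  s4 <- slab_from_probs(numeric(30))
  expect_true(s4$empty)
  expect_true(is.na(s4$z_start))
})

random_views <- function(d3, seed) {
  set.seed(seed)
  S <- c("WH", "LV", "RV", "LA", "RA")
  ax <- array(runif(prod(d3) * 5), dim = c(d3, 5),
              dimnames = list(NULL, NULL, NULL, S))
  list(axial = ax, coronal = array(runif(prod(d3)), d3),
       sagittal = array(runif(prod(d3)), d3))
}

test_that("fusion equals the voxel-wise conjunction oracle", {
  d3 <- c(8L, 8L, 8L)
  for (seed in 1:5) {
    v <- random_views(d3, seed)
    res <- fuse_masks(v, spacing = c(1, 1, 1))
    gate <- (v$coronal >= 0.5) & (v$sagittal >= 0.5)
    expect_equal(res$masks$WH, (v$axial[, , , "WH"] >= 0.5) & gate)
    for (s in c("LV", "RV", "LA", "RA")) {
      expect_equal(res$masks[[s]], (v$axial[, , , s] >= 0.5) & gate)
      # substructures confined to the coronal-sagittal WH gate
      expect_true(all(!res$masks[[s]] | gate))
    }
    # optional axial-WH gating is a further conjunction
    res2 <- fuse_masks(v, spacing = c(1, 1, 1),
                       gate_substructures_by_axial_wh = TRUE)
    for (s in c("LV", "RV", "LA", "RA")) {
      expect_equal(res2$masks[[s]], res$masks[[s]] & res$masks$WH)
    }
  }
})

test_that("fusion identity, annihilator and monotonicity", {
  d3 <- c(6L, 6L, 6L)
  v <- random_views(d3, 9)
  ones <- array(1, d3)
  res <- fuse_masks(list(axial = v$axial, coronal = ones, sagittal = ones),
                    spacing = c(1, 1, 1))
  for (s in dimnames(v$axial)[[4]]) {
    expect_equal(res$masks[[s]], v$axial[, , , s] >= 0.5)
  }
  zeros <- array(0, d3)
  res0 <- fuse_masks(list(axial = v$axial, coronal = zeros,
                          sagittal = ones), spacing = c(1, 1, 1))
  expect_true(all(!unlist(res0$masks)))
  # monotonicity: raising any view's probabilities never removes voxels
  v2 <- v
  set.seed(31)
  v2$coronal <- pmin(v2$coronal + runif(prod(d3)) * 0.5, 1)
  r1 <- fuse_masks(v, spacing = c(1, 1, 1))
  r2 <- fuse_masks(v2, spacing = c(1, 1, 1))
  for (s in names(r1$masks)) expect_true(all(!r1$masks[[s]] | r2$masks[[s]]))
  # grid mismatch is an error
  bad <- v; bad$coronal <- array(0.2, c(5L, 6L, 6L))
  expect_error(fuse_masks(bad, spacing = c(1, 1, 1)), "grids")
})

test_that("pipeline with ground-truth-replaying models recovers all masks
           exactly", {
  cfg <- small_phantom_config(seed = 4, noise_sd = 0)
  ph <- generate_phantom(cfg, "p")
  register_oracles()
  bundle <- make_oracle_bundle(cfg)
  res <- run_pipeline(ph$volume, bundle)
  expect_false(res$provenance$empty_slab)
  for (s in c("WH", "LV", "RV", "LA", "RA")) {
    expect_equal(dice_coefficient(res$masks[[s]], ph$labels$masks[[s]]), 1)
  }
  # predicted volumes match voxel count times voxel volume
  expect_equal(res$volumes_ml[["WH"]],
               volume_ml(ph$labels$masks$WH, ph$volume$spacing))
})

test_that("no positive voxel escapes the selected slab (gating guarantee)", {
  cfg <- small_phantom_config(seed = 6, noise_sd = 0)
  ph <- generate_phantom(cfg, "p")
  register_oracles()
  bundle <- make_oracle_bundle(cfg)
  heart_z <- which(apply(ph$labels$masks$WH, 1, any))
  # restrict the slab artificially to the middle third of the heart
  sub <- heart_z[seq(ceiling(length(heart_z) / 3),
                     floor(2 * length(heart_z) / 3))]
  slab <- slab_from_probs(replace(numeric(dim(ph$volume$intensities)[1]),
                                  sub, 1))
  views <- segment_views(ph$volume, slab, bundle[c("axial", "coronal",
                                                   "sagittal")])
  expect_equal(dim(views$coronal), dim(ph$volume$intensities))
  res <- fuse_masks(views, ph$volume$spacing)
  outside <- setdiff(seq_len(dim(ph$volume$intensities)[1]), sub)
  for (s in names(res$masks)) {
    expect_true(all(!res$masks[[s]][outside, , ]))
  }
})

test_that("an empty slab propagates as an explicit empty result", {
  cfg <- small_phantom_config(seed = 7, noise_sd = 0)
  ph <- generate_phantom(cfg, "p")
  register_oracles()
  bundle <- make_oracle_bundle(cfg)
  bundle$classifier <- structure(list(heart_vals = -1),
                                 class = "hc_oracle_cls")  # never matches
  expect_warning(res <- run_pipeline(ph$volume, bundle), "empty slab")
  expect_true(res$provenance$empty_slab)
  expect_true(all(!unlist(res$masks)))
  expect_true(all(res$volumes_ml == 0))
})

test_that("a missing bundle part is reported by name", {
  ph <- generate_phantom(small_phantom_config(seed = 8), "p")
  expect_error(run_pipeline(ph$volume, list(classifier = NULL)),
               "classifier")
})
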