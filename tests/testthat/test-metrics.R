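# Evaluation metrics against independent brute-force oracles.

test_that("Cohen's kappa matches an agreement-definition oracle on all small
           confusion matrices", {
  for (n in 1:6) {
    parts <- expand.grid(tn = 0:n, fp = 0:n, fn = 0:n, tp = 0:n)
    parts <- parts[rowSums(parts) == n, , drop = FALSE]
    for (i in seq_len(nrow(parts))) {
      cm <- confusion_matrix(parts$tn[i], parts$fp[i], parts$fn[i],
                             parts$tp[i])
      expect_equal(cohens_kappa(cm),
                   kappa_oracle(parts$tn[i], parts$fp[i], parts$fn[i],
                                parts$tp[i]),
                   tolerance = 1e-12)
    }
  }
})

test_that("kappa limiting cases", {
  expect_equal(cohens_kappa(confusion_matrix(5, 0, 0, 7)), 1)
  # constant predictor agrees only by chance
  expect_equal(cohens_kappa(confusion_matrix(8, 0, 4, 0)), 0)
  expect_error(cohens_kappa(confusion_matrix(0, 0, 0, 0)), "empty")
  # kappa never exceeds observed agreement when chance agreement >= 0
  set.seed(3)
  for (r in 1:25) {
    v <- rmultinom(1, 40, runif(4, 0.05, 1))
    cm <- confusion_matrix(v[1], v[2], v[3], v[4])
    rep <- classification_report(cm)
    expect_lte(cohens_kappa(cm), rep$accuracy + 1e-12)
  }
})

test_that("classification report on the published validation counts", {
  cm <- confusion_matrix(tn = 268, fp = 1, fn = 2, tp = 90)
  rep <- classification_report(cm)
  expect_equal(round(100 * rep$accuracy), 99)
  expect_equal(rep$f1, 180 / 183, tolerance = 1e-12)
  expect_equal(round(cohens_kappa(cm), 2), 0.98)
  # all-correct classifier
  rep2 <- classification_report(confusion_matrix(10, 0, 0, 5))
  expect_equal(rep2$accuracy, 1)
  expect_equal(rep2$f1, 1)
  # F1 undefined without any positive in truth or prediction
  expect_true(is.na(classification_report(confusion_matrix(9, 0, 0, 0))$f1))
})

test_that("dice coefficient: identity, disjoint, hand count, conventions", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE; a[1:2, 2, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[1:2, 2, 1] <- TRUE; b[1:2, 3, 1] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, b), 0.5)      # |a|=4, |b|=4, overlap 2
  disj <- array(FALSE, c(4, 4, 4)); disj[4, 4, 4] <- TRUE
  expect_equal(dice_coefficient(a, disj), 0)
  empty <- array(FALSE, c(4, 4, 4))
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_equal(dice_coefficient(a, empty), 0)
  expect_error(dice_coefficient(a, array(FALSE, c(3, 3, 3))), "grids")
})

test_that("dice is symmetric and 1 only for identical non-empty masks", {
  set.seed(7)
  for (r in 1:10) {
    a <- random_mask(c(6, 6, 6), 0.3)
    b <- random_mask(c(6, 6, 6), 0.3)
    expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
    if (!identical(a, b)) expect_lt(dice_coefficient(a, b), 1)
  }
})

test_that("mask boundary is face-adjacency against a direct definition", {
  set.seed(9)
  m <- random_mask(c(7, 8, 6), 0.4)
  bd <- mask_boundary(m)
  d <- dim(m)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) { expect_false(bd[i, j, k]); next }
    nb <- c(
      if (i > 1) m[i - 1, j, k] else FALSE,
      if (i < d[1]) m[i + 1, j, k] else FALSE,
      if (j > 1) m[i, j - 1, k] else FALSE,
      if (j < d[2]) m[i, j + 1, k] else FALSE,
      if (k > 1) m[i, j, k - 1] else FALSE,
      if (k < d[3]) m[i, j, k + 1] else FALSE)
    expect_equal(bd[i, j, k], !all(nb))
  }
})

test_that("hausdorff95: identity, two points, oracle equivalence", {
  a <- array(FALSE, c(9, 9, 9)); a[2, 3, 3] <- TRUE
  b <- array(FALSE, c(9, 9, 9)); b[2, 3, 8] <- TRUE
  sp <- c(3, 1, 1)
  expect_equal(hausdorff95(a, a, sp), 0)
  expect_equal(hausdorff95(a, b, sp), 5)   # 5 voxels * 1 mm apart
  expect_true(is.na(hausdorff95(a, array(FALSE, c(9, 9, 9)), sp)))

  # oracle: all-pairs distances on random masks, nearest-rank percentile
  set.seed(13)
  for (r in 1:6) {
    ma <- random_mask(c(12, 12, 12), 0.2)
    mb <- random_mask(c(12, 12, 12), 0.2)
    if (sum(ma) == 0 || sum(mb) == 0) next
    spc <- c(sample(c(1, 3, 5), 1), 1, 1)
    pa <- which(mask_boundary(ma), arr.ind = TRUE) %*% diag(spc)
    pb <- which(mask_boundary(mb), arr.ind = TRUE) %*% diag(spc)
    dab <- brute_nn_distances(pa, pb)
    dba <- brute_nn_distances(pb, pa)
    p95 <- function(x) sort(x)[ceiling(0.95 * length(x))]
    expect_equal(hausdorff95(ma, mb, spc), max(p95(dab), p95(dba)),
                 tolerance = 1e-10)
  }
})

test_that("hausdorff95 is symmetric and scales with uniform spacing", {
  set.seed(17)
  a <- random_mask(c(10, 10, 10), 0.25)
  b <- random_mask(c(10, 10, 10), 0.25)
  expect_equal(hausdorff95(a, b, c(1, 1, 1)), hausdorff95(b, a, c(1, 1, 1)))
  expect_equal(hausdorff95(a, b, c(2, 2, 2)),
               2 * hausdorff95(a, b, c(1, 1, 1)), tolerance = 1e-10)
  expect_gte(hausdorff95(a, b, c(1, 1, 1)), 0)
})

test_that("volume ratio: identity, proportionality, spacing cancellation", {
  m <- array(FALSE, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- TRUE
  expect_equal(volume_ratio(m, m, c(1, 1, 1)), 1)
  half <- m; half[2:3, , ] <- FALSE   # removes half of the 4x4x4 cube
  expect_equal(volume_ratio(half, m, c(1, 1, 1)), 0.5)
  # anisotropic spacing cancels: 100 vs 80 voxels -> 1.25
  p100 <- array(FALSE, c(10, 10, 10)); p100[seq_len(100)] <- TRUE
  p80 <- array(FALSE, c(10, 10, 10)); p80[seq_len(80)] <- TRUE
  expect_equal(volume_ratio(p100, p80, c(1, 1, 3)), 1.25)
  expect_equal(volume_ratio(p100, p80, c(1, 1, 1)), 1.25)
  expect_true(is.na(volume_ratio(m, array(FALSE, c(6, 6, 6)), c(1, 1, 1))))
})

test_that("summary table matches a sort-based quantile oracle", {
  one <- data.frame(structure = "WH", dice = 0.9, hd95 = 2,
                    volume_ratio = 1.1)
  s1 <- summarize_metrics(one)
  expect_true(all(s1$median == s1$q1 & s1$median == s1$q3))
  vals <- c(1, 2, 3, 4, 5)
  df <- data.frame(structure = "LV", dice = vals, hd95 = vals,
                   volume_ratio = vals)
  s2 <- summarize_metrics(df)
  expect_true(all(s2$median == 3))
  # linear-interpolation quartiles of {0.80, 0.82, 0.84, 0.90}
  v <- c(0.80, 0.82, 0.84, 0.90)
  df3 <- data.frame(structure = "RA", dice = v, hd95 = v, volume_ratio = v)
  s3 <- summarize_metrics(df3)
  srt <- sort(v)
  lin_q <- function(p) {
    h <- (length(srt) - 1) * p
    srt[floor(h) + 1] + (h - floor(h)) * (srt[min(floor(h) + 2,
                                                  length(srt))] -
                                          srt[floor(h) + 1])
  }
  expect_equal(unique(s3$q1), lin_q(0.25), tolerance = 1e-12)
  expect_equal(unique(s3$median), lin_q(0.5), tolerance = 1e-12)
  expect_equal(unique(s3$q3), lin_q(0.75), tolerance = 1e-12)
  expect_true(all(s3$q1 <= s3$median & s3$median <= s3$q3))
  expect_error(summarize_metrics(one[0, ]), "no metric rows")
})
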