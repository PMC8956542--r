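# Shared fixtures: small phantom configurations and deterministic helpers.

# compact phantom grid that still contains the full heart + liver geometry
small_phantom_config <- function(seed = 1L, ...) {
  phantom_config(grid_shape = c(48L, 80L, 80L), heart_center_jitter = 2,
                 seed = seed, ...)
}

# brute-force directed nearest-neighbour distances between two point sets
brute_nn_distances <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sqrt(min(colSums((t(b) - a[i, ])^2)))
  }, 0)
}

# independent kappa oracle built from the agreement definition on label
# vectors (chance agreement from empirical marginal frequencies)
kappa_oracle <- function(tn, fp, fn, tp) {
  truth <- c(rep(0, tn + fp), rep(1, fn + tp))
  pred <- c(rep(0, tn), rep(1, fp), rep(0, fn), rep(1, tp))
  po <- mean(truth == pred)
  pe <- mean(truth == 0) * mean(pred == 0) + mean(truth == 1) * mean(pred == 1)
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

random_mask <- function(dim3, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::runif(prod(dim3)) < p, dim = dim3)
}
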