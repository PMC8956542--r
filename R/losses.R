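# Training objectives: soft dice loss, focal loss, and their hybrid
# combination L_hybrid = w * L_focal + L_dice (default weight w = 2), plus
# the binary cross-entropy used by the stage-1 classifier.
#
# These are the reference (plain numeric) implementations; the training
# loops rebuild the same quantities on the autodiff tape, and the test suite
# checks the two routes agree.

#' Loss configuration for the hybrid segmentation objective
#'
#' The hybrid loss is `focal_weight * focal + dice`, with the focal term
#' weighted twice by default. The focal exponent `gamma` and balance `alpha`
#' follow the standard focal-loss settings (gamma 2, alpha 0.25).
#'
#' @param focal_weight Non-negative weight on the focal term (default 2).
#' @param focal_gamma Focusing exponent (>= 0).
#' @param focal_alpha Balance factor in (0, 1].
#' @param dice_smooth Smoothing constant added to the dice numerator and
#'   denominator (> 0).
#' @return A `loss_config` list.
#' @export
loss_config <- function(focal_weight = 2, focal_gamma = 2,
                        focal_alpha = 0.25, dice_smooth = 1e-6) {
  stopifnot(focal_weight >= 0, focal_gamma >= 0, dice_smooth > 0,
            focal_alpha > 0)
  structure(list(focal_weight = focal_weight, focal_gamma = focal_gamma,
                 focal_alpha = focal_alpha, dice_smooth = dice_smooth),
            class = "loss_config")
}

check_loss_shapes <- function(p, t) {
  if (!identical(dim_or_len(p), dim_or_len(t))) {
    stop("prediction and target shapes differ")
  }
}

#' Soft dice loss
#'
#' `1 - (2*sum(p*t) + s) / (sum(p) + sum(t) + s)`. Multi-structure
#' predictions are matrices with one named column per structure channel
#' (`channels = TRUE`, or autodetected from column names): the per-channel
#' losses are averaged (unweighted). Anything else — including a plain 2D
#' image matrix — is a single channel.
#'
#' @param p Predicted probabilities in \[0,1\].
#' @param t Binary target of the same shape.
#' @param smooth Smoothing constant `s` (> 0).
#' @param channels Treat matrix columns as structure channels; `NULL`
#'   (default) autodetects from column names.
#' @return Scalar loss in \[0, 1\].
#' @export
dice_loss <- function(p, t, smooth = 1e-6, channels = NULL) {
  check_loss_shapes(p, t)
  if (is.null(channels)) {
    channels <- is.matrix(p) && ncol(p) > 1L && !is.null(colnames(p))
  }
  if (channels && is.matrix(p) && ncol(p) > 1L) {
    return(mean(vapply(seq_len(ncol(p)), function(ch) {
      dice_loss(p[, ch], t[, ch], smooth, channels = FALSE)
    }, 0)))
  }
  1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
}

#' Focal loss
#'
#' Mean over pixels of `-alpha * (1 - p_t)^gamma * log(p_t)` where
#' `p_t = p` for target 1 and `1 - p` for target 0. Probabilities are
#' clipped to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param p Predicted probabilities.
#' @param t Binary target of the same shape.
#' @param gamma Focusing exponent.
#' @param alpha Balance factor.
#' @return Scalar loss >= 0.
#' @export
focal_loss <- function(p, t, gamma = 2, alpha = 0.25) {
  check_loss_shapes(p, t)
  pc <- pmin(pmax(p, .nn_eps), 1 - .nn_eps)
  pt <- pc * t + (1 - pc) * (1 - t)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' Hybrid focal + dice loss
#'
#' Exactly `focal_weight * focal_loss + dice_loss`, the stage-2 training
#' objective.
#'
#' @param p Predicted probabilities.
#' @param t Binary target of the same shape.
#' @param config A [loss_config()].
#' @param channels Passed to [dice_loss()].
#' @return Scalar loss >= 0.
#' @export
hybrid_loss <- function(p, t, config = loss_config(), channels = NULL) {
  config$focal_weight * focal_loss(p, t, gamma = config$focal_gamma,
                                   alpha = config$focal_alpha) +
    dice_loss(p, t, smooth = config$dice_smooth, channels = channels)
}

#' Binary cross-entropy
#'
#' Mean over entries of `-[t log p + (1-t) log(1-p)]` with probability
#' clipping; the stage-1 training objective.
#'
#' @param p Predicted probabilities.
#' @param t Binary target of the same shape.
#' @return Scalar loss >= 0.
#' @export
bce_loss <- function(p, t) {
  check_loss_shapes(p, t)
  pc <- pmin(pmax(p, .nn_eps), 1 - .nn_eps)
  mean(-(t * log(pc) + (1 - t) * log(1 - pc)))
}
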