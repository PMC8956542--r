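# Minimal reverse-mode automatic differentiation engine for small 2D
# convolutional networks on one CPU.
#
# Feature maps are stored as dense (H*W) x C matrices, pixels in column-major
# (y fastest) order, so convolutions reduce to an im2col gather followed by a
# single BLAS matrix multiplication. One image is processed per forward pass;
# mini-batches accumulate parameter gradients before an optimizer step.
#
# A "tape" records every operation; nn_backward() replays it in reverse.
# Parameters are leaf environments whose $grad fields accumulate across
# forward passes until nn_zero_grad() is called.

## ---- tape core ----------------------------------------------------------

nn_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

node_new <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

node_value <- function(x) if (is.environment(x)) x$value else x

accum_grad <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

#' @keywords internal
nn_param <- function(value, name = NULL) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$is_param <- TRUE
  p$name <- name
  class(p) <- "nn_param"
  p
}

# Wrap a parameter as a tape leaf so gradients flow into it.
leaf <- function(tape, p) {
  node_new(tape, p$value, parents = list(p), backward = function(nd) {
    accum_grad(p, nd$grad)
  })
}

nn_backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

nn_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- primitive ops ------------------------------------------------------

op_matmul <- function(tape, a, b) {
  av <- node_value(a); bv <- node_value(b)
  node_new(tape, av %*% bv, parents = list(a, b), backward = function(nd) {
    g <- nd$grad
    if (is.environment(a)) accum_grad(a, g %*% t(bv))
    if (is.environment(b)) accum_grad(b, crossprod(av, g))
  })
}

# add a bias row-vector to every row of an (n x C) matrix
op_addbias <- function(tape, x, b) {
  xv <- node_value(x); bv <- node_value(b)
  node_new(tape, sweep(xv, 2L, bv, "+"), parents = list(x, b),
           backward = function(nd) {
    g <- nd$grad
    if (is.environment(x)) accum_grad(x, g)
    if (is.environment(b)) accum_grad(b, colSums(g))
  })
}

op_add <- function(tape, a, b) {
  node_new(tape, node_value(a) + node_value(b), parents = list(a, b),
           backward = function(nd) {
    if (is.environment(a)) accum_grad(a, nd$grad)
    if (is.environment(b)) accum_grad(b, nd$grad)
  })
}

op_sub <- function(tape, a, b) {
  node_new(tape, node_value(a) - node_value(b), parents = list(a, b),
           backward = function(nd) {
    if (is.environment(a)) accum_grad(a, nd$grad)
    if (is.environment(b)) accum_grad(b, -nd$grad)
  })
}

op_ewmul <- function(tape, a, b) {
  av <- node_value(a); bv <- node_value(b)
  node_new(tape, av * bv, parents = list(a, b), backward = function(nd) {
    if (is.environment(a)) accum_grad(a, nd$grad * bv)
    if (is.environment(b)) accum_grad(b, nd$grad * av)
  })
}

op_scale <- function(tape, a, s) {
  node_new(tape, node_value(a) * s, parents = list(a), backward = function(nd) {
    if (is.environment(a)) accum_grad(a, nd$grad * s)
  })
}

op_relu <- function(tape, x) {
  xv <- node_value(x)
  mask <- xv > 0
  node_new(tape, xv * mask, parents = list(x), backward = function(nd) {
    if (is.environment(x)) accum_grad(x, nd$grad * mask)
  })
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-node_value(x)))
  node_new(tape, s, parents = list(x), backward = function(nd) {
    if (is.environment(x)) accum_grad(x, nd$grad * s * (1 - s))
  })
}

op_log <- function(tape, x) {
  xv <- node_value(x)
  node_new(tape, log(xv), parents = list(x), backward = function(nd) {
    if (is.environment(x)) accum_grad(x, nd$grad / xv)
  })
}

op_pow <- function(tape, x, e) {
  xv <- node_value(x)
  node_new(tape, xv^e, parents = list(x), backward = function(nd) {
    if (is.environment(x)) accum_grad(x, nd$grad * e * xv^(e - 1))
  })
}

# clamp with zero gradient outside [lo, hi]
op_clip <- function(tape, x, lo, hi) {
  xv <- node_value(x)
  inside <- xv >= lo & xv <= hi
  node_new(tape, pmin(pmax(xv, lo), hi), parents = list(x),
           backward = function(nd) {
    if (is.environment(x)) accum_grad(x, nd$grad * inside)
  })
}

op_sum <- function(tape, x) {
  xv <- node_value(x)
  node_new(tape, sum(xv), parents = list(x), backward = function(nd) {
    if (is.environment(x)) accum_grad(x, array(nd$grad, dim = dim_or_len(xv)))
  })
}

op_mean <- function(tape, x) {
  xv <- node_value(x)
  n <- length(xv)
  node_new(tape, sum(xv) / n, parents = list(x), backward = function(nd) {
    if (is.environment(x)) accum_grad(x, array(nd$grad / n, dim = dim_or_len(xv)))
  })
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

op_cbind <- function(tape, xs) {
  vals <- lapply(xs, node_value)
  ncols <- vapply(vals, ncol, 0L)
  stops <- cumsum(ncols)
  starts <- c(1L, head(stops, -1L) + 1L)
  node_new(tape, do.call(cbind, vals), parents = xs, backward = function(nd) {
    g <- nd$grad
    for (i in seq_along(xs)) {
      if (is.environment(xs[[i]])) {
        accum_grad(xs[[i]], g[, starts[i]:stops[i], drop = FALSE])
      }
    }
  })
}

## ---- spatial ops --------------------------------------------------------

.nn_cache <- new.env(parent = emptyenv())

# k x k same-padding convolution; x: (H*W) x Cin node, w: nn_param of dim
# (k^2*Cin) x Cout (rows in cpp_im2col's offset-major layout), b: length Cout.
# The im2col gather and its adjoint scatter run in compiled code; the
# contraction itself is one BLAS matrix product.
op_conv <- function(tape, x, w, b, H, W, k = 3L) {
  xv <- node_value(x)
  Cin <- ncol(xv)
  A <- cpp_im2col(xv, H, W, k)
  wl <- leaf(tape, w)
  out <- A %*% wl$value
  out <- sweep(out, 2L, b$value, "+")
  bl <- leaf(tape, b)
  node_new(tape, out, parents = list(x, wl, bl), backward = function(nd) {
    g <- nd$grad
    accum_grad(wl, crossprod(A, g))
    accum_grad(bl, colSums(g))
    if (is.environment(x)) {
      dA <- g %*% t(wl$value)
      accum_grad(x, cpp_col2im(dA, H, W, k, Cin))
    }
  })
}

# 1x1 convolution (pointwise linear map over channels)
op_conv1x1 <- function(tape, x, w, b) {
  wl <- leaf(tape, w); bl <- leaf(tape, b)
  op_addbias(tape, op_matmul(tape, x, wl), bl)
}

pool_groups <- function(H, W, f) {
  key <- paste0("p", H, "x", W, "f", f)
  g <- .nn_cache[[key]]
  if (!is.null(g)) return(g)
  ys <- rep.int(seq_len(H), W)
  xs <- rep(seq_len(W), each = H)
  H2 <- H %/% f
  g <- ((ys - 1L) %/% f + 1L) + (((xs - 1L) %/% f)) * H2
  .nn_cache[[key]] <- g
  g
}

# mean pooling by integer factor f (used to rescale full-scale skips)
op_meanpool <- function(tape, x, H, W, f) {
  xv <- node_value(x)
  grp <- pool_groups(H, W, f)
  out <- rowsum(xv, group = grp, reorder = TRUE) / (f * f)
  node_new(tape, out, parents = list(x), backward = function(nd) {
    if (is.environment(x)) {
      accum_grad(x, nd$grad[grp, , drop = FALSE] / (f * f))
    }
  })
}

# 2x2 max pooling, stride 2
op_maxpool2 <- function(tape, x, H, W) {
  xv <- node_value(x)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  C <- ncol(xv)
  key <- paste0("m", H, "x", W)
  cand <- .nn_cache[[key]]
  if (is.null(cand)) {
    ys2 <- rep.int(seq_len(H2), W2)
    xs2 <- rep(seq_len(W2), each = H2)
    y0 <- 2L * ys2 - 1L; x0 <- 2L * xs2 - 1L
    cand <- cbind(y0 + (x0 - 1L) * H, y0 + 1L + (x0 - 1L) * H,
                  y0 + x0 * H, y0 + 1L + x0 * H)
    .nn_cache[[key]] <- cand
  }
  best <- xv[cand[, 1L], , drop = FALSE]
  argi <- matrix(1L, H2 * W2, C)
  for (j in 2:4) {
    v <- xv[cand[, j], , drop = FALSE]
    upd <- v > best
    best[upd] <- v[upd]
    argi[upd] <- j
  }
  node_new(tape, best, parents = list(x), backward = function(nd) {
    if (is.environment(x)) {
      g <- nd$grad
      dx <- matrix(0, H * W, C)
      rows <- cand[cbind(rep.int(seq_len(H2 * W2), C), as.vector(argi))]
      ix <- cbind(rows, rep(seq_len(C), each = H2 * W2))
      # duplicate winners cannot occur within one output cell, but the same
      # input pixel wins in different channels; accumulate per channel
      dx[ix] <- dx[ix] + as.vector(g)
      accum_grad(x, dx)
    }
  })
}

# max pooling by integer factor f (argmax routing), built on groups
op_maxpool_f <- function(tape, x, H, W, f) {
  if (f == 2L) return(op_maxpool2(tape, x, H, W))
  xv <- node_value(x)
  grp <- pool_groups(H, W, f)
  C <- ncol(xv)
  n2 <- (H %/% f) * (W %/% f)
  # rows grouped by output cell, f^2 members each
  key <- paste0("mf", H, "x", W, "f", f)
  cand <- .nn_cache[[key]]
  if (is.null(cand)) {
    cand <- do.call(cbind, split(seq_len(H * W), grp))
    .nn_cache[[key]] <- cand
  }
  best <- xv[cand[1L, ], , drop = FALSE]
  argi <- matrix(1L, n2, C)
  for (j in 2:(f * f)) {
    v <- xv[cand[j, ], , drop = FALSE]
    upd <- v > best
    best[upd] <- v[upd]
    argi[upd] <- j
  }
  node_new(tape, best, parents = list(x), backward = function(nd) {
    if (is.environment(x)) {
      g <- nd$grad
      dx <- matrix(0, H * W, C)
      rows <- cand[cbind(as.vector(argi), rep.int(seq_len(n2), C))]
      ix <- cbind(rows, rep(seq_len(C), each = n2))
      dx[ix] <- dx[ix] + as.vector(g)
      accum_grad(x, dx)
    }
  })
}

up_index <- function(H, W, f) {
  key <- paste0("u", H, "x", W, "f", f)
  idx <- .nn_cache[[key]]
  if (!is.null(idx)) return(idx)
  Hf <- H * f
  ys <- rep.int(seq_len(Hf), W * f)
  xs <- rep(seq_len(W * f), each = Hf)
  idx <- ((ys - 1L) %/% f + 1L) + ((xs - 1L) %/% f) * H
  .nn_cache[[key]] <- idx
  idx
}

# nearest-neighbour upsampling by integer factor f
op_upnn <- function(tape, x, H, W, f) {
  xv <- node_value(x)
  idx <- up_index(H, W, f)
  node_new(tape, xv[idx, , drop = FALSE], parents = list(x),
           backward = function(nd) {
    if (is.environment(x)) {
      accum_grad(x, rowsum(nd$grad, group = idx, reorder = TRUE))
    }
  })
}

# global max pool: (H*W) x C -> 1 x C (argmax routing in backward)
op_gmax <- function(tape, x) {
  xv <- node_value(x)
  n <- nrow(xv); C <- ncol(xv)
  arg <- max.col(t(xv), ties.method = "first")
  out <- matrix(xv[cbind(arg, seq_len(C))], 1L)
  node_new(tape, out, parents = list(x), backward = function(nd) {
    if (is.environment(x)) {
      dx <- matrix(0, n, C)
      dx[cbind(arg, seq_len(C))] <- nd$grad
      accum_grad(x, dx)
    }
  })
}

# log-sum-exp ("soft max") pool: (H*W) x C -> 1 x C; smooth, noise-robust
# alternative to a hard spatial max
op_lsepool <- function(tape, x, beta = 12) {
  xv <- node_value(x)
  n <- nrow(xv)
  mx <- apply(xv, 2L, max)
  ex <- exp(beta * sweep(xv, 2L, mx, "-"))
  se <- colSums(ex)
  out <- matrix(mx + (log(se) - log(n)) / beta, 1L)
  node_new(tape, out, parents = list(x), backward = function(nd) {
    if (is.environment(x)) {
      wgt <- sweep(ex, 2L, se, "/")       # softmax weights per column
      accum_grad(x, sweep(wgt, 2L, as.vector(nd$grad), "*"))
    }
  })
}

# global average pool: (H*W) x C -> 1 x C
op_gap <- function(tape, x) {
  xv <- node_value(x)
  n <- nrow(xv)
  node_new(tape, matrix(colMeans(xv), 1L), parents = list(x),
           backward = function(nd) {
    if (is.environment(x)) {
      accum_grad(x, matrix(rep(nd$grad / n, each = n), n))
    }
  })
}

# instance normalisation: each channel (column) is standardised over the
# spatial dimension, then scaled/shifted by learned gamma/beta. Works at
# batch size one and needs no running statistics at inference.
op_instnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- node_value(x)
  n <- nrow(xv)
  mu <- colMeans(xv)
  xc <- sweep(xv, 2L, mu, "-")
  v <- colSums(xc * xc) / n
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv_sd, "*")
  gl <- leaf(tape, gamma); bl <- leaf(tape, beta)
  out <- sweep(sweep(xhat, 2L, gl$value, "*"), 2L, bl$value, "+")
  node_new(tape, out, parents = list(x, gl, bl), backward = function(nd) {
    g <- nd$grad
    accum_grad(gl, colSums(g * xhat))
    accum_grad(bl, colSums(g))
    if (is.environment(x)) {
      dxhat <- sweep(g, 2L, gl$value, "*")
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * xhat)
      dx <- sweep(sweep(dxhat, 2L, m1, "-") -
                    sweep(xhat, 2L, m2, "*"), 2L, inv_sd, "*")
      accum_grad(x, dx)
    }
  })
}

## ---- tape losses --------------------------------------------------------

# numerically safe log-probability clip used by all probabilistic losses
.nn_eps <- 1e-7

op_bce <- function(tape, p, target) {
  pc <- op_clip(tape, p, .nn_eps, 1 - .nn_eps)
  tv <- as.numeric(target)
  # -[t log p + (1-t) log(1-p)], mean over entries
  lp <- op_log(tape, pc)
  lq <- op_log(tape, op_sub(tape, 1, pc))
  s <- op_add(tape, op_ewmul(tape, lp, tv), op_ewmul(tape, lq, 1 - tv))
  op_scale(tape, op_mean(tape, s), -1)
}

op_dice_loss <- function(tape, p, target, smooth = 1e-6) {
  # per-channel soft dice, averaged over channels; p and target (n x C)
  tv <- node_value(target)
  C <- ncol(node_value(p))
  total <- NULL
  for (ch in seq_len(C)) {
    pc <- node_new(tape, node_value(p)[, ch, drop = FALSE], parents = list(p),
                   backward = local({
                     ch0 <- ch
                     function(nd) {
                       if (is.environment(p)) {
                         g <- matrix(0, nrow(node_value(p)), C)
                         g[, ch0] <- nd$grad
                         accum_grad(p, g)
                       }
                     }
                   }))
    tch <- tv[, ch, drop = FALSE]
    num <- op_scale(tape, op_sum(tape, op_ewmul(tape, pc, tch)), 2)
    den <- op_add(tape, op_sum(tape, pc), sum(tch))
    frac <- op_ewmul(tape, op_add(tape, num, smooth),
                     op_pow(tape, op_add(tape, den, smooth), -1))
    term <- op_sub(tape, 1, frac)
    total <- if (is.null(total)) term else op_add(tape, total, term)
  }
  op_scale(tape, total, 1 / C)
}

op_focal_loss <- function(tape, p, target, gamma = 2, alpha = 0.25) {
  pc <- op_clip(tape, p, .nn_eps, 1 - .nn_eps)
  tv <- node_value(target)
  # p_t = p*t + (1-p)*(1-t)
  pt <- op_add(tape, op_ewmul(tape, pc, tv),
               op_ewmul(tape, op_sub(tape, 1, pc), 1 - tv))
  w <- op_pow(tape, op_sub(tape, 1, pt), gamma)
  term <- op_ewmul(tape, w, op_log(tape, pt))
  op_scale(tape, op_mean(tape, term), -alpha)
}

op_hybrid_loss <- function(tape, p, target, cfg) {
  f <- op_focal_loss(tape, p, target, gamma = cfg$focal_gamma,
                     alpha = cfg$focal_alpha)
  d <- op_dice_loss(tape, p, target, smooth = cfg$dice_smooth)
  op_add(tape, op_scale(tape, f, cfg$focal_weight), d)
}

## ---- initialisation & optimiser -----------------------------------------

# He-uniform initialisation for a fan_in x fan_out weight matrix
init_weight <- function(fan_in, fan_out) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

conv_param <- function(k, cin, cout, name) {
  list(w = nn_param(init_weight(k * k * cin, cout), paste0(name, ".w")),
       b = nn_param(numeric(cout), paste0(name, ".b")))
}

norm_param <- function(c, name) {
  list(g = nn_param(rep(1, c), paste0(name, ".g")),
       b = nn_param(numeric(c), paste0(name, ".b")))
}

#' @keywords internal
adamax_state <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-7) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0)
  st$u <- lapply(params, function(p) p$value * 0)
  st$params <- params
  st
}

adamax_step <- function(st, scale = 1) {
  st$t <- st$t + 1L
  b1 <- st$beta1
  corr <- 1 - b1^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    g <- g * scale
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$u[[i]] <- pmax(st$beta2 * st$u[[i]], abs(g))
    p$value <- p$value - (st$lr / corr) * st$m[[i]] / (st$u[[i]] + st$eps)
  }
  invisible(NULL)
}

# flatten a nested parameter list (named lists of nn_param / conv_param pairs)
flatten_params <- function(x) {
  if (inherits(x, "nn_param")) return(list(x))
  if (is.list(x)) return(unlist(lapply(x, flatten_params), use.names = FALSE))
  list()
}

param_count <- function(params) {
  sum(vapply(flatten_params(params), function(p) length(p$value), 0))
}

# deep copy of parameter values (for checkpointing the best epoch)
params_snapshot <- function(params) {
  lapply(flatten_params(params), function(p) p$value)
}

params_restore <- function(params, snap) {
  fl <- flatten_params(params)
  for (i in seq_along(fl)) fl[[i]]$value <- snap[[i]]
  invisible(NULL)
}
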