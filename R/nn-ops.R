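# Differentiable operations over (H, W, C, N) arrays.
#
# Every op takes and returns a node (list(v, id)); with tape = NULL it is a
# plain eager computation.  Per-channel broadcasts exploit the column-major
# layout: a length-C vector repeated each = H*W (times N) lines up with the
# (H, W, C, N) element order.

bc_channel <- function(vec, HW, N) rep(rep(vec, each = HW), times = N)

bc_cn <- function(mat, HW) rep(as.vector(mat), each = HW)

# Per-channel sum over spatial and batch axes -> length-C vector.
chan_sum <- function(a, HW, C, N) {
  dim(a) <- c(HW, C, N)
  s <- colSums(a)
  if (N == 1L) as.vector(s) else rowSums(s)
}

# Per-(channel, sample) sum over spatial axes -> (C, N) matrix.
cn_sum <- function(a, HW, C, N) {
  dim(a) <- c(HW, C, N)
  s <- colSums(a)
  matrix(s, C, N)
}

op_input <- function(tape, v) tp_node(tape, v)

op_conv <- function(tape, x, store, name, dilation = 1L, need_dx = TRUE) {
  W <- store$params[[paste0(name, ".W")]]
  bname <- paste0(name, ".b")
  b <- store$params[[bname]]
  y <- nn_conv_fwd(x$v, W, b, dilation)
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  xv <- x$v
  has_b <- !is.null(b)
  tp_node(tape, y, parents = x$id, backward = function(g) {
    r <- nn_conv_bwd(xv, W, g, dilation, need_dx, has_b)
    acc_pgrad(tape, paste0(name, ".W"), r$dw)
    if (has_b) acc_pgrad(tape, bname, r$db)
    list(if (need_dx) r$dx else NULL)
  })
}

op_bn <- function(tape, x, store, name, training, momentum = 0.1, eps = 1e-5) {
  gname <- paste0(name, ".gamma"); bname <- paste0(name, ".beta")
  gamma <- store$params[[gname]]; beta <- store$params[[bname]]
  xv <- x$v
  C <- dim(xv)[3]
  if (training) {
    st <- nn_bn_stats(xv)
    m <- st$mean; v <- st$var
    rk <- paste0(name, ".rm"); vk <- paste0(name, ".rv")
    rm0 <- store$state[[rk]]; rv0 <- store$state[[vk]]
    if (is.null(rm0)) { rm0 <- numeric(C); rv0 <- rep(1, C) }
    store$state[[rk]] <- (1 - momentum) * rm0 + momentum * m
    store$state[[vk]] <- (1 - momentum) * rv0 + momentum * v
  } else {
    m <- store$state[[paste0(name, ".rm")]]
    v <- store$state[[paste0(name, ".rv")]]
    if (is.null(m)) { m <- numeric(C); v <- rep(1, C) }
  }
  invstd <- 1 / sqrt(v + eps)
  y <- nn_bn_apply(xv, m, invstd, gamma, beta)
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  tp_node(tape, y, parents = x$id, backward = function(g) {
    if (training) {
      r <- nn_bn_bwd(xv, g, m, invstd, gamma)
      acc_pgrad(tape, gname, r$dgamma)
      acc_pgrad(tape, bname, r$dbeta)
      list(r$dx)
    } else {
      HW <- dim(xv)[1] * dim(xv)[2]; N <- dim(xv)[4]
      xhat <- nn_bn_apply(xv, m, invstd, rep(1, C), numeric(C))
      acc_pgrad(tape, gname, chan_sum(g * xhat, HW, C, N))
      acc_pgrad(tape, bname, chan_sum(g, HW, C, N))
      list(nn_chan_scale_vec(g, gamma * invstd))
    }
  })
}

# Batch norm over the sample axis of a (d, N) matrix (KSM bottleneck).
# Degenerate at N = 1 in training mode (documented): variance is zero and the
# output collapses to beta, so training uses batches of at least 2.
op_bn1d <- function(tape, x, store, name, training, momentum = 0.1,
                    eps = 1e-5) {
  gname <- paste0(name, ".gamma"); bname <- paste0(name, ".beta")
  gamma <- store$params[[gname]]; beta <- store$params[[bname]]
  xv <- x$v
  dd <- nrow(xv); N <- ncol(xv)
  if (training) {
    m <- rowMeans(xv)
    v <- rowMeans(xv * xv) - m * m
    v[v < 0] <- 0
    rk <- paste0(name, ".rm"); vk <- paste0(name, ".rv")
    rm0 <- store$state[[rk]]; rv0 <- store$state[[vk]]
    if (is.null(rm0)) { rm0 <- numeric(dd); rv0 <- rep(1, dd) }
    store$state[[rk]] <- (1 - momentum) * rm0 + momentum * m
    store$state[[vk]] <- (1 - momentum) * rv0 + momentum * v
  } else {
    m <- store$state[[paste0(name, ".rm")]]
    v <- store$state[[paste0(name, ".rv")]]
    if (is.null(m)) { m <- numeric(dd); v <- rep(1, dd) }
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xv - m) * invstd
  y <- gamma * xhat + beta
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  tp_node(tape, y, parents = x$id, backward = function(g) {
    dgamma <- rowSums(g * xhat)
    dbeta <- rowSums(g)
    acc_pgrad(tape, gname, dgamma)
    acc_pgrad(tape, bname, dbeta)
    dx <- if (training) {
      (gamma * invstd) * (g - dbeta / N - xhat * (dgamma / N))
    } else {
      g * (gamma * invstd)
    }
    list(dx)
  })
}

op_relu <- function(tape, x) {
  y <- nn_relu_fwd(x$v)
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  tp_node(tape, y, parents = x$id,
          backward = function(g) list(nn_relu_bwd(y, g)))
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$v))
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  tp_node(tape, y, parents = x$id,
          backward = function(g) list(g * y * (1 - y)))
}

op_add3 <- function(tape, a, b, c) {
  y <- a$v + b$v + c$v
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  tp_node(tape, y, parents = c(a$id, b$id, c$id),
          backward = function(g) list(g, g, g))
}

op_wsum2 <- function(tape, a, b, wa, wb) {
  y <- wa * a$v + wb * b$v
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  tp_node(tape, y, parents = c(a$id, b$id),
          backward = function(g) list(wa * g, wb * g))
}

op_concat <- function(tape, xs) {
  vs <- lapply(xs, `[[`, "v")
  d1 <- dim(vs[[1]])
  chs <- vapply(vs, function(v) dim(v)[3], numeric(1))
  for (v in vs) {
    dv <- dim(v)
    if (any(dv[c(1, 2, 4)] != d1[c(1, 2, 4)])) {
      stop(sprintf(
        "concat: spatial/batch mismatch (%dx%d vs %dx%d)",
        dv[1], dv[2], d1[1], d1[2]))
    }
  }
  y <- array(0, c(d1[1], d1[2], sum(chs), d1[4]))
  off <- 0
  for (v in vs) {
    y[, , off + seq_len(dim(v)[3]), ] <- v
    off <- off + dim(v)[3]
  }
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  ids <- vapply(xs, `[[`, numeric(1), "id")
  tp_node(tape, y, parents = ids, backward = function(g) {
    out <- vector("list", length(chs))
    off <- 0
    for (j in seq_along(chs)) {
      out[[j]] <- g[, , off + seq_len(chs[j]), , drop = FALSE]
      off <- off + chs[j]
    }
    out
  })
}

op_maxpool <- function(tape, x) {
  r <- nn_maxpool_fwd(x$v)
  if (is.null(tape)) return(list(v = r$y, id = NA_integer_))
  xd <- dim(x$v)
  tp_node(tape, r$y, parents = x$id,
          backward = function(g) list(nn_maxpool_bwd(r$idx, g, xd)))
}

op_avgpool <- function(tape, x) {
  y <- nn_avgpool2_fwd(x$v)
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  xd <- dim(x$v)
  tp_node(tape, y, parents = x$id,
          backward = function(g) list(nn_avgpool2_bwd(g, xd)))
}

op_upsample2 <- function(tape, x) {
  y <- nn_upsample2_fwd(x$v)
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  xd <- dim(x$v)
  tp_node(tape, y, parents = x$id,
          backward = function(g) list(nn_upsample2_bwd(g, xd)))
}

# Global average pooling -> (C, N) matrix.
op_gap <- function(tape, x) {
  d <- dim(x$v); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  y <- cn_sum(x$v, HW, C, N) / HW
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  tp_node(tape, y, parents = x$id, backward = function(g) {
    dx <- rep(as.vector(g) / HW, each = HW)
    dim(dx) <- d
    list(dx)
  })
}

op_fc <- function(tape, x, store, name) {
  W <- store$params[[paste0(name, ".W")]]
  bname <- paste0(name, ".b")
  b <- store$params[[bname]]
  y <- W %*% x$v
  if (!is.null(b)) y <- y + as.vector(b)
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  xv <- x$v
  tp_node(tape, y, parents = x$id, backward = function(g) {
    acc_pgrad(tape, paste0(name, ".W"), tcrossprod(g, xv))
    if (!is.null(b)) acc_pgrad(tape, bname, rowSums(g))
    list(crossprod(W, g))
  })
}

# y[h,w,c,n] = x[h,w,c,n] * s[c,n]  (squeeze-excitation style gating)
op_channel_scale <- function(tape, x, s) {
  d <- dim(x$v); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  srep <- bc_cn(s$v, HW)
  y <- x$v * srep
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  xv <- x$v
  tp_node(tape, y, parents = c(x$id, s$id), backward = function(g) {
    dx <- g * srep
    dim(dx) <- d
    list(dx, cn_sum(g * xv, HW, C, N))
  })
}

# Gate a C-channel image by a 1-channel mask (broadcast over channels).
op_gate <- function(tape, x, m) {
  d <- dim(x$v); C <- d[3]
  mrep <- m$v[, , rep(1L, C), , drop = FALSE]
  y <- x$v * mrep
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  xv <- x$v
  tp_node(tape, y, parents = c(x$id, m$id), backward = function(g) {
    dx <- g * mrep
    tmp <- g * xv
    dim(tmp) <- c(d[1] * d[2], C, d[4])
    dm <- rowSums(aperm(tmp, c(1, 3, 2)), dims = 2)
    dim(dm) <- c(d[1], d[2], 1L, d[4])
    list(dx, dm)
  })
}

# Broadcast a (C, N) vector to every spatial position (ASPP pooled branch).
op_broadcast_hw <- function(tape, s, H, W) {
  C <- nrow(s$v); N <- ncol(s$v); HW <- H * W
  y <- rep(as.vector(s$v), each = HW)
  dim(y) <- c(H, W, C, N)
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  tp_node(tape, y, parents = s$id,
          backward = function(g) list(cn_sum(g, HW, C, N)))
}

# Softmax attention over three branches (per channel, per sample) followed by
# the convex fusion V = alpha.U' + beta.U'' + gamma.U'''.
op_ksm_fuse <- function(tape, u1, u2, u3, la, lb, lc) {
  att <- ksm_softmax3(la$v, lb$v, lc$v)
  d <- dim(u1$v); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  y <- u1$v * bc_cn(att$alpha, HW) + u2$v * bc_cn(att$beta, HW) +
    u3$v * bc_cn(att$gamma, HW)
  if (is.null(tape)) return(list(v = y, id = NA_integer_))
  us <- list(u1$v, u2$v, u3$v)
  aa <- list(att$alpha, att$beta, att$gamma)
  tp_node(tape, y,
          parents = c(u1$id, u2$id, u3$id, la$id, lb$id, lc$id),
          backward = function(g) {
    du <- lapply(aa, function(a) {
      dx <- g * bc_cn(a, HW)
      dim(dx) <- d
      dx
    })
    datt <- lapply(us, function(u) cn_sum(g * u, HW, C, N))
    tot <- aa[[1]] * datt[[1]] + aa[[2]] * datt[[2]] + aa[[3]] * datt[[3]]
    dl <- lapply(1:3, function(j) aa[[j]] * (datt[[j]] - tot))
    c(du, dl)
  })
}

# Stable three-way softmax on (C, N) logit matrices.
ksm_softmax3 <- function(la, lb, lc) {
  mx <- pmax(la, lb, lc)
  ea <- exp(la - mx); eb <- exp(lb - mx); ec <- exp(lc - mx)
  s <- ea + eb + ec
  list(alpha = ea / s, beta = eb / s, gamma = ec / s)
}

# Soft Dice loss, averaged over the batch.
op_dice_loss <- function(tape, p, target, smooth = 1e-6) {
  d <- dim(p$v)
  if (!identical(dim(target), d)) {
    stop("prediction and target shapes differ")
  }
  P <- prod(d[1:3]); N <- d[4]
  pm <- p$v; dim(pm) <- c(P, N)
  tm <- target; dim(tm) <- c(P, N)
  num <- 2 * colSums(pm * tm) + smooth
  den <- colSums(pm) + colSums(tm) + smooth
  loss <- mean(1 - num / den)
  if (is.null(tape)) return(list(v = loss, id = NA_integer_))
  tp_node(tape, loss, parents = p$id, backward = function(g) {
    dp <- (rep(num / den^2, each = P) - 2 * as.vector(tm) *
             rep(1 / den, each = P)) * (g / N)
    dim(dp) <- d
    list(dp)
  })
}
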