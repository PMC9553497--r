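# Independent oracles and fixtures, deliberately written with different
# algorithms than the implementation they check.

# Direct (quadruple-loop) same-padding convolution.
conv_oracle <- function(x, w, b = NULL, dilation = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; Co <- dim(w)[4]; off <- (k - 1) / 2
  if (is.null(b)) b <- numeric(Co)
  y <- array(0, c(H, W, Co, N))
  for (n in 1:N) for (co in 1:Co) for (wi in 1:W) for (hi in 1:H) {
    s <- b[co]
    for (ci in 1:C) for (kw in 1:k) for (kh in 1:k) {
      hh <- hi + dilation * (kh - 1 - off)
      ww <- wi + dilation * (kw - 1 - off)
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W) {
        s <- s + x[hh, ww, ci, n] * w[kh, kw, ci, co]
      }
    }
    y[hi, wi, co, n] <- s
  }
  y
}

# Central finite differences of a scalar function of an array.
numgrad <- function(f, a, eps = 1e-3) {
  da <- a * 0
  for (i in seq_along(a)) {
    a1 <- a; a1[i] <- a[i] + eps
    a2 <- a; a2[i] <- a[i] - eps
    da[i] <- (f(a1) - f(a2)) / (2 * eps)
  }
  da
}

rel_err <- function(got, want) {
  max(abs(got - want)) / max(max(abs(want)), 1e-8)
}

# Queue-based flood fill, 8-connected, independent of the C++ labelling.
flood_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] != 0 && lab[ni, nj] == 0) {
          lab[ni, nj] <- cur
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

bwareaopen_oracle <- function(mask, min_area) {
  lab <- flood_components(mask)
  out <- matrix(0, nrow(mask), ncol(mask))
  if (max(lab) > 0) {
    for (l in seq_len(max(lab))) {
      px <- lab == l
      if (sum(px) >= min_area) out[px] <- 1
    }
  }
  out
}

# Set-arithmetic segmentation metrics, independent of compute_metrics.
metrics_oracle <- function(pred, target) {
  p <- which(pred == 1); t <- which(target == 1)
  inter <- length(intersect(p, t))
  uni <- length(union(p, t))
  list(
    tp = inter,
    fp = length(setdiff(p, t)),
    fn = length(setdiff(t, p)),
    tn = length(pred) - uni,
    dice = if (length(p) + length(t) == 0) 1 else
      2 * inter / (length(p) + length(t)),
    iou = if (uni == 0) 1 else inter / uni
  )
}

# Scanline rasterisation of an axis-aligned ellipse: per pixel row, count
# integer columns within the analytic extent.
ellipse_area_oracle <- function(center, a, b, size) {
  total <- 0
  for (r in seq_len(size)) {
    dy <- (r - center[1]) / a
    if (abs(dy) > 1) next
    half <- b * sqrt(1 - dy^2)
    lo <- ceiling(center[2] - half)
    hi <- floor(center[2] + half)
    lo <- max(lo, 1); hi <- min(hi, size)
    if (hi >= lo) total <- total + (hi - lo + 1)
  }
  total
}

# Small-image synthetic profile for fast training tests.
tiny_synth_params <- function(size = 32L) {
  synthetic_params(
    image_size = size, tubule_count_range = c(1L, 2L),
    semi_axis_range = c(4, 7), ring_thickness_range = c(2, 3),
    distractor_cleft_range = c(0L, 1L))
}

make_pairs <- function(n, seed0, params = tiny_synth_params()) {
  lapply(seq_len(n), function(i) {
    s <- generate_sample(params, seed0 + i)
    list(image = s$image, mask = s$mask)
  })
}

tiny_model_config <- function(input = 32L, wm = 0.125, seed = 5L) {
  model_config(input_size = input, width_multiplier = wm, seed = seed)
}

# Independent layer-by-layer parameter accumulation from a model config,
# written directly from the architecture description (not via dks_plan).
param_count_oracle <- function(cfg) {
  sc <- function(v) pmax(1, round(v * cfg$width_multiplier))
  conv_p <- function(k, cin, cout, bias = FALSE) {
    k * k * cin * cout + if (bias) cout else 0
  }
  bn_p <- function(c) 2 * c
  cu_p <- function(cin, cout) {
    conv_p(3, cin, cout) + bn_p(cout) + conv_p(3, cout, cout) + bn_p(cout)
  }
  se_p <- function(c, r) {
    d <- max(c %/% r, 1)
    (c * d + d) + (d * c + c)
  }
  aspp_p <- function(cin, cout, rates) {
    s <- 0
    for (r in rates) {
      k <- if (r == 1) 1 else 3
      s <- s + conv_p(k, cin, cout) + bn_p(cout)
    }
    s + (cin * cout) + bn_p(cout) +
      conv_p(1, cout * (length(rates) + 1), cout) + bn_p(cout)
  }
  ksm_p <- function(C) {
    d <- max(ceiling(C / cfg$ksm_reduction), cfg$ksm_min_width)
    sum(sapply(c(3, 5, 7), function(k) conv_p(k, C, C, bias = TRUE))) +
      (C * d) + bn_p(d) + 3 * (d * C + C)
  }

  total <- 0
  vggc <- sc(c(64, 128, 256, 512, 512)); convs <- c(2, 2, 4, 4, 4)
  cin <- 3
  for (s in 1:5) for (j in seq_len(convs[s])) {
    total <- total + conv_p(3, cin, vggc[s]) + bn_p(vggc[s])
    cin <- vggc[s]
  }
  aspp_ch <- sc(cfg$aspp_channels); decw <- sc(cfg$decoder_widths)
  total <- total + aspp_p(vggc[5], aspp_ch, cfg$aspp_rates)
  cprev <- aspp_ch
  for (i in 1:4) {
    total <- total + cu_p(cprev + vggc[5 - i], decw[i]) +
      se_p(decw[i], cfg$se_reduction)
    cprev <- decw[i]
  }
  total <- total + ksm_p(decw[4]) + conv_p(1, decw[4], 1, bias = TRUE)

  g <- sc(cfg$growth_rate); stem <- sc(2 * cfg$growth_rate)
  total <- total + cu_p(3, stem)
  c_run <- stem
  dch <- stem
  for (i in 1:4) {
    ct <- floor(cfg$dense_compression * c_run)
    total <- total + bn_p(c_run) + conv_p(1, c_run, ct)
    c_run <- ct
    for (l in seq_len(cfg$dense_block_lengths[i])) {
      total <- total + bn_p(c_run) + conv_p(1, c_run, 4 * g) +
        bn_p(4 * g) + conv_p(3, 4 * g, g)
      c_run <- c_run + g
    }
    dch <- c(dch, c_run)
  }
  total <- total + aspp_p(c_run, aspp_ch, cfg$aspp_rates)
  cprev <- aspp_ch
  for (i in 1:4) {
    total <- total + cu_p(cprev + vggc[5 - i] + dch[5 - i], decw[i]) +
      se_p(decw[i], cfg$se_reduction)
    cprev <- decw[i]
  }
  total + ksm_p(decw[4]) + conv_p(1, decw[4], 1, bias = TRUE)
}

# Full KSM parameter list with the documented names, built from explicit
# shapes so tests can share one parameter set across ksm_* calls.
mk_ksm_param_list <- function(C, seed = 1, reduction = 8, min_width = 32,
                              value = NULL) {
  d <- max(ceiling(C / reduction), min_width)
  set.seed(seed)
  rnd <- function(dims) {
    v <- if (is.null(value)) rnorm(prod(dims)) * 0.3 else
      rep(value, prod(dims))
    if (length(dims) == 1) v else array(v, dim = dims)
  }
  p <- list()
  for (k in c(3, 5, 7)) {
    p[[sprintf("ksm.k%d.W", k)]] <- rnd(c(k, k, C, C))
    p[[sprintf("ksm.k%d.b", k)]] <- rnd(C)
  }
  p[["ksm.fc1.W"]] <- rnd(c(d, C))
  p[["ksm.bn1.gamma"]] <- rep(1, d)
  p[["ksm.bn1.beta"]] <- numeric(d)
  for (br in c("a", "b", "c")) {
    p[[sprintf("ksm.fc2%s.W", br)]] <- rnd(c(C, d))
    p[[sprintf("ksm.fc2%s.b", br)]] <- rnd(C)
  }
  p
}
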