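# The numerical engine: convolution against a direct oracle, and every
# differentiable op against central finite differences.

test_that("convolution matches the direct-convolution oracle", {
  set.seed(42)
  x <- array(rnorm(7 * 6 * 3 * 2), c(7, 6, 3, 2))
  for (k in c(1, 3, 5)) {
    w <- array(rnorm(k * k * 3 * 4), c(k, k, 3, 4))
    b <- rnorm(4)
    got <- dksunet:::nn_conv_fwd(x, w, b, 1L)
    expect_lt(max(abs(got - conv_oracle(x, w, b))), 1e-5)
  }
  # dilated, including dilation larger than the input itself (only the
  # centre tap can land inside; the rest is zero padding)
  w <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  for (d in c(2, 6, 18)) {
    got <- dksunet:::nn_conv_fwd(x, w, NULL, as.integer(d))
    expect_lt(max(abs(got - conv_oracle(x, w, NULL, dilation = d))), 1e-5)
  }
})

test_that("convolution gradients match finite differences", {
  set.seed(7)
  x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.5, c(3, 3, 2, 3))
  b <- rnorm(3)
  r <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  g <- dksunet:::nn_conv_bwd(x, w, r, 1L, TRUE, TRUE)
  expect_lt(rel_err(g$dx, numgrad(function(a)
    sum(dksunet:::nn_conv_fwd(a, w, b, 1L) * r), x)), 1e-3)
  expect_lt(rel_err(g$dw, numgrad(function(a)
    sum(dksunet:::nn_conv_fwd(x, a, b, 1L) * r), w)), 1e-3)
  expect_lt(rel_err(g$db, numgrad(function(a)
    sum(dksunet:::nn_conv_fwd(x, w, a, 1L) * r), b)), 1e-3)
})

# Check the tape gradient of a single op against finite differences on
# f(x) = sum(op(x) * r).
check_op_grad <- function(fwd, x, tol = 1e-4) {
  tape <- dksunet:::new_tape()
  xn <- dksunet:::op_input_tracked(tape, x, "x")
  y <- fwd(tape, xn)
  r <- array(seq_along(y$v) %% 5 - 2, dim = if (is.null(dim(y$v)))
    length(y$v) else dim(y$v))
  dksunet:::tape_backward(tape, y$id, seed = r)
  got <- tape$igrads[["x"]]
  want <- numgrad(function(a) {
    ya <- fwd(NULL, dksunet:::op_input(NULL, a))
    sum(ya$v * r)
  }, x)
  expect_lt(rel_err(got, want), tol)
}

test_that("pooling, upsampling, gating and pooling-path ops backpropagate correctly", {
  set.seed(11)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  check_op_grad(function(tp, xn) dksunet:::op_maxpool(tp, xn), x)
  check_op_grad(function(tp, xn) dksunet:::op_avgpool(tp, xn), x)
  check_op_grad(function(tp, xn) dksunet:::op_upsample2(tp, xn), x)
  check_op_grad(function(tp, xn) dksunet:::op_gap(tp, xn), x)
  check_op_grad(function(tp, xn) dksunet:::op_sigmoid(tp, xn), x)

  m <- array(runif(4 * 4 * 1 * 2), c(4, 4, 1, 2))
  check_op_grad(function(tp, xn) {
    dksunet:::op_gate(tp, xn, dksunet:::op_input(tp, m))
  }, x)
  # and gradient with respect to the mask itself
  check_op_grad(function(tp, mn) {
    dksunet:::op_gate(tp, dksunet:::op_input(tp, x), mn)
  }, m)

  s <- matrix(runif(3 * 2), 3, 2)
  check_op_grad(function(tp, xn) {
    dksunet:::op_channel_scale(tp, xn, dksunet:::op_input(tp, s))
  }, x)
  check_op_grad(function(tp, sn) {
    dksunet:::op_channel_scale(tp, dksunet:::op_input(tp, x), sn)
  }, s)
  check_op_grad(function(tp, sn) dksunet:::op_broadcast_hw(tp, sn, 4, 4), s)
})

test_that("batch norm training-mode forward and backward are correct", {
  set.seed(3)
  store <- dksunet:::new_store()
  dksunet:::mk_bn(store, "bn", 3L)
  store$params[["bn.gamma"]] <- c(1.5, 0.7, 1.1)
  store$params[["bn.beta"]] <- c(0.2, -0.1, 0)
  x <- array(rnorm(4 * 4 * 3 * 2, sd = 2), c(4, 4, 3, 2))

  y <- dksunet:::op_bn(NULL, dksunet:::op_input(NULL, x), store, "bn",
                       training = TRUE)$v
  # normalised activations: per-channel mean beta, sd ~ gamma
  for (c in 1:3) {
    expect_equal(mean(y[, , c, ]), store$params[["bn.beta"]][c],
                 tolerance = 1e-8)
    expect_equal(stats::sd(as.vector(y[, , c, ])) *
                   sqrt(31 / 32),  # population sd
                 abs(store$params[["bn.gamma"]][c]), tolerance = 1e-3)
  }

  check_op_grad(function(tp, xn) {
    dksunet:::op_bn(tp, xn, store, "bn", training = TRUE)
  }, x, tol = 1e-3)

  # parameter gradients
  tape <- dksunet:::new_tape()
  yn <- dksunet:::op_bn(tape, dksunet:::op_input(tape, x), store, "bn",
                        training = TRUE)
  r <- array(rnorm(length(yn$v)), dim(yn$v))
  dksunet:::tape_backward(tape, yn$id, seed = r)
  for (pn in c("bn.gamma", "bn.beta")) {
    want <- numgrad(function(a) {
      st2 <- dksunet:::new_store()
      st2$params[["bn.gamma"]] <- store$params[["bn.gamma"]]
      st2$params[["bn.beta"]] <- store$params[["bn.beta"]]
      st2$params[[pn]] <- a
      sum(dksunet:::op_bn(NULL, dksunet:::op_input(NULL, x), st2, "bn",
                          training = TRUE)$v * r)
    }, store$params[[pn]])
    expect_lt(rel_err(tape$pgrads[[pn]], want), 1e-3)
  }
})

test_that("fully connected and 1-d batch norm ops backpropagate correctly", {
  set.seed(5)
  store <- dksunet:::new_store()
  dksunet:::mk_fc(store, "fc", 3L, 4L)
  dksunet:::mk_bn1d(store, "bnv", 4L)
  x <- matrix(rnorm(3 * 5), 3, 5)
  check_op_grad(function(tp, xn) dksunet:::op_fc(tp, xn, store, "fc"), x)
  x4 <- matrix(rnorm(4 * 5), 4, 5)
  check_op_grad(function(tp, xn) {
    dksunet:::op_bn1d(tp, xn, store, "bnv", training = TRUE)
  }, x4, tol = 1e-3)
})

test_that("softmax fusion op backpropagates to branches and logits", {
  set.seed(9)
  d <- c(3, 3, 2, 2)
  us <- lapply(1:3, function(i) array(rnorm(prod(d)), d))
  ls <- lapply(1:3, function(i) matrix(rnorm(2 * 2), 2, 2))
  mk <- function(tp, repl, which) {
    args <- c(lapply(us, function(u) dksunet:::op_input(tp, u)),
              lapply(ls, function(l) dksunet:::op_input(tp, l)))
    args[[which]] <- repl
    do.call(dksunet:::op_ksm_fuse, c(list(tp), args))
  }
  check_op_grad(function(tp, xn) mk(tp, xn, 1), us[[1]])
  check_op_grad(function(tp, xn) mk(tp, xn, 4), ls[[1]])
  check_op_grad(function(tp, xn) mk(tp, xn, 5), ls[[2]])
})

test_that("dice loss node gradient matches finite differences", {
  set.seed(13)
  p <- array(runif(4 * 4 * 1 * 2, 0.05, 0.95), c(4, 4, 1, 2))
  t <- array((runif(4 * 4 * 2) > 0.5) * 1, c(4, 4, 1, 2))
  tape <- dksunet:::new_tape()
  pn <- dksunet:::op_input_tracked(tape, p, "p")
  l <- dksunet:::op_dice_loss(tape, pn, t, 1e-6)
  dksunet:::tape_backward(tape, l$id)
  want <- numgrad(function(a) {
    dksunet:::op_dice_loss(NULL, dksunet:::op_input(NULL, a), t, 1e-6)$v
  }, p, eps = 1e-5)
  expect_lt(rel_err(tape$igrads[["p"]], want), 1e-3)
})
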