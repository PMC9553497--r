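test_that("dice loss hits its analytic anchor points", {
  m <- matrix(0, 8, 8); m[2:4, 2:4] <- 1
  expect_lt(dice_loss(m, m), 1e-6)              # perfect overlap

  a <- matrix(0, 8, 8); a[1:2, 1:2] <- 1
  b <- matrix(0, 8, 8); b[6:8, 6:8] <- 1
  expect_gt(dice_loss(a, b), 1 - 1e-5)          # disjoint

  # |X| = |Y| = 4 with overlap 2: Dice = 2*2/8 = 0.5
  x <- matrix(0, 4, 4); x[1, 1:4] <- 1
  y <- matrix(0, 4, 4); y[1, 3:4] <- 1; y[2, 1:2] <- 1
  expect_equal(dice_loss(x, y), 0.5, tolerance = 1e-6)

  expect_error(dice_loss(matrix(0, 4, 4), matrix(0, 5, 5)), "differ")
  expect_error(dice_loss(m, m, smooth = 0), "smooth")
})

test_that("dice loss is bounded, symmetric for binary inputs, and batch-averaged", {
  set.seed(17)
  for (i in 1:25) {
    p <- matrix(runif(36), 6, 6)
    t <- matrix((runif(36) > 0.5) * 1, 6, 6)
    l <- dice_loss(p, t)
    expect_gte(l, 0); expect_lte(l, 1)
    pb <- (p > 0.5) * 1
    expect_equal(dice_loss(pb, t), dice_loss(t, pb), tolerance = 1e-12)
  }
  # batch average equals mean of per-sample losses
  p <- array(runif(4 * 4 * 1 * 3), c(4, 4, 1, 3))
  t <- array((runif(4 * 4 * 3) > 0.5) * 1, c(4, 4, 1, 3))
  per <- vapply(1:3, function(j) dice_loss(p[, , , j], t[, , , j]),
                numeric(1))
  expect_equal(dice_loss(p, t), mean(per), tolerance = 1e-12)
})

test_that("dice loss falls monotonically as overlap grows at fixed sizes", {
  t <- matrix(0, 6, 6); t[1, 1:4] <- 1
  losses <- vapply(0:4, function(ov) {
    p <- matrix(0, 6, 6)
    if (ov > 0) p[1, seq_len(ov)] <- 1
    if (ov < 4) p[6, seq_len(4 - ov)] <- 1   # keep |prediction| = 4
    dice_loss(p, t)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("confusion counts match a per-pixel loop oracle", {
  p <- matrix(0, 4, 4); p[1, 1:5 %% 5] <- 0  # keep p zero
  t <- p
  t[c(1, 3, 6, 9, 12)] <- 1
  p2 <- t
  cc <- confusion_counts(p2, t)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 5L, fp = 0L, fn = 0L, tn = 11L))

  cc2 <- confusion_counts(matrix(1, 4, 4), matrix(0, 4, 4))
  expect_equal(cc2$fp, 16L); expect_equal(cc2$tp, 0L)

  set.seed(23)
  for (i in 1:20) {
    pr <- matrix((runif(32 * 32) > 0.5) * 1, 32, 32)
    tg <- matrix((runif(32 * 32) > 0.7) * 1, 32, 32)
    got <- confusion_counts(pr, tg)
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (j in seq_along(pr)) {
      if (pr[j] == 1 && tg[j] == 1) tp <- tp + 1
      else if (pr[j] == 1) fp <- fp + 1
      else if (tg[j] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(unclass(got)[c("tp", "fp", "fn", "tn")],
                 list(tp = tp, fp = fp, fn = fn, tn = tn))
    expect_equal(got$tp + got$fp + got$fn + got$tn, length(pr))
  }
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               "binary")
})

test_that("compute_metrics reproduces hand arithmetic and conventions", {
  r <- compute_metrics(list(tp = 3, fp = 1, fn = 1, tn = 11))
  expect_equal(r$dice, 0.75)
  expect_equal(r$miou_paper, 0.6)
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.75)
  expect_equal(r$f1, 0.75)

  perfect <- compute_metrics(list(tp = 10, fp = 0, fn = 0, tn = 6))
  expect_true(all(unlist(perfect) == 1))

  empty_pred <- compute_metrics(list(tp = 0, fp = 0, fn = 5, tn = 11))
  expect_equal(empty_pred$dice, 0)
  expect_equal(empty_pred$recall, 0)

  both_empty <- compute_metrics(list(tp = 0, fp = 0, fn = 0, tn = 16))
  expect_equal(both_empty$dice, 1)
  expect_equal(both_empty$f1, 1)

  # the printed-precision audit variant duplicates recall
  audit <- compute_metrics(list(tp = 3, fp = 2, fn = 1, tn = 10),
                           printed_precision = TRUE)
  expect_equal(audit$precision, audit$recall)
})

test_that("Dice equals F1 for any confusion counts", {
  set.seed(29)
  for (i in 1:1000) {
    cc <- list(tp = sample(0:50, 1), fp = sample(0:50, 1),
               fn = sample(0:50, 1), tn = sample(0:50, 1))
    r <- compute_metrics(cc)
    expect_equal(r$dice, r$f1, tolerance = 1e-12)
  }
})

test_that("metrics agree with an independent set-arithmetic oracle", {
  set.seed(31)
  for (i in 1:25) {
    pr <- matrix((runif(24 * 24) > runif(1)) * 1, 24, 24)
    tg <- matrix((runif(24 * 24) > runif(1)) * 1, 24, 24)
    o <- metrics_oracle(pr, tg)
    r <- compute_metrics(confusion_counts(pr, tg))
    expect_equal(r$dice, o$dice, tolerance = 1e-12)
    expect_equal(r$miou_paper, o$iou, tolerance = 1e-12)
  }
})

test_that("aggregate_metrics returns both conventions correctly", {
  c1 <- list(tp = 3, fp = 1, fn = 1, tn = 11)
  r1 <- compute_metrics(c1)
  single <- aggregate_metrics(list(r1), list(c1))
  expect_equal(single$mean$dice, r1$dice)
  expect_equal(single$pooled$dice, r1$dice)

  two <- aggregate_metrics(list(r1, r1), list(c1, c1))
  expect_equal(two$mean$dice, two$pooled$dice, tolerance = 1e-12)

  # empty-mask image: mean and pooled diverge, both match hand arithmetic
  c2 <- list(tp = 0, fp = 2, fn = 0, tn = 14)   # empty target, 2 FP
  r2 <- compute_metrics(c2)
  agg <- aggregate_metrics(list(r1, r2), list(c1, c2))
  expect_equal(agg$mean$dice, (0.75 + 0) / 2)
  expect_equal(agg$pooled$dice, 2 * 3 / (2 * 3 + 3 + 1))
  expect_false(isTRUE(all.equal(agg$mean$dice, agg$pooled$dice)))

  expect_error(aggregate_metrics(list(), list()), "non-empty")
})
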