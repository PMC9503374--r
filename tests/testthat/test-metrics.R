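test_that("confusion counts partition the pixels", {
  g <- matrix(c(1, 0, 1, 0), 2)
  expect_mapequal(unclass(confusion_from_masks(g, g))[c("fp", "fn")],
                  list(fp = 0, fn = 0))
  inv <- confusion_from_masks(1 - g, g)
  expect_equal(inv$tp + inv$tn, 0)
  cc <- confusion_from_masks(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_error(confusion_from_masks(matrix(0, 2, 2), matrix(0, 3, 3)),
               "identical shapes")
  expect_error(confusion_from_masks(c(1, 0), c(0.5, 0)), "binary")
  # thresholding: >= is positive
  cc2 <- confusion_from_masks(c(0.5, 0.49), c(1, 1))
  expect_equal(cc2$tp, 1)
})

test_that("worked metric examples match hand arithmetic exactly", {
  perfect <- confusion_counts(tp = 5, fp = 0, fn = 0, tn = 95)
  for (f in list(dice, iou, recall, precision, f2, accuracy))
    expect_equal(f(perfect), 1)
  cc <- confusion_counts(tp = 3, fp = 1, fn = 2, tn = 4)
  expect_equal(dice(cc), 6 / 9, tolerance = 1e-12)
  expect_equal(iou(cc), 0.5, tolerance = 1e-12)
  expect_equal(recall(cc), 0.6, tolerance = 1e-12)
  expect_equal(precision(cc), 0.75, tolerance = 1e-12)
  expect_equal(accuracy(cc), 0.7, tolerance = 1e-12)
  # p = 0.5, r = 1 -> F2 = 2.5/3
  cc2 <- confusion_counts(tp = 3, fp = 3, fn = 0, tn = 1)
  expect_equal(f2(cc2), 2.5 / 3, tolerance = 1e-12)
})

test_that("zero-denominator convention scores empty-vs-empty as ideal", {
  empty <- confusion_counts(tp = 0, fp = 0, fn = 0, tn = 64)
  for (f in list(dice, iou, recall, precision, f2, accuracy))
    expect_equal(f(empty), 1)
  # empty prediction, non-empty truth
  miss <- confusion_counts(tp = 0, fp = 0, fn = 5, tn = 59)
  expect_equal(precision(miss), 0)
  expect_equal(recall(miss), 0)
  # non-empty prediction, empty truth
  false_alarm <- confusion_counts(tp = 0, fp = 5, fn = 0, tn = 59)
  expect_equal(recall(false_alarm), 0)
  expect_equal(dice(false_alarm), 0)
})

test_that("metrics are bounded, monotone in tp, and F2 sits between p and r", {
  set.seed(20)
  for (i in 1:200) {
    cc <- confusion_counts(tp = rpois(1, 20), fp = rpois(1, 10),
                           fn = rpois(1, 10), tn = rpois(1, 50))
    vals <- c(dice(cc), iou(cc), recall(cc), precision(cc), f2(cc),
              accuracy(cc))
    expect_true(all(vals >= 0 & vals <= 1))
    p <- precision(cc); r <- recall(cc)
    expect_gte(f2(cc) + 1e-12, min(p, r))
    expect_lte(f2(cc) - 1e-12, max(p, r))
    up <- confusion_counts(cc$tp + 5, cc$fp, cc$fn, cc$tn)
    vals_up <- c(dice(up), iou(up), recall(up), precision(up), f2(up),
                 accuracy(up))
    expect_true(all(vals_up >= vals - 1e-12))
  }
})

test_that("set evaluation averages per image and pools globally", {
  g <- matrix(c(1, 1, 0, 0), 2)
  rep1 <- evaluate_set(list(g, g), list(g, g))
  expect_true(all(abs(rep1$per_image_mean - 1) < 1e-15))
  expect_true(all(abs(rep1$global_counts - 1) < 1e-15))
  # per-image dice {1, 0.5} -> mean 0.75
  half <- matrix(c(1, 0, 0, 0), 2)  # dice vs g: 2*1/(2+1) ... build exact
  gt <- matrix(c(1, 1, 0, 0), 2)
  pred_half <- matrix(c(1, 0, 1, 0), 2)  # tp=1, fp=1, fn=1 -> dice 0.5
  rep2 <- evaluate_set(list(gt, pred_half), list(gt, gt))
  expect_equal(rep2$per_image_mean[["mdice"]], 0.75, tolerance = 1e-12)
  expect_error(evaluate_set(list(), list()), "empty")
  expect_error(evaluate_set(list(g), list(g, g)), "equal length")
})

test_that("global aggregation equals the pooled-pixel oracle on random sets", {
  set.seed(21)
  for (rep_i in 1:5) {
    n <- 6
    preds <- lapply(1:n, function(i) matrix(runif(64), 8, 8))
    gts <- lapply(1:n, function(i) matrix(rbinom(64, 1, 0.4), 8, 8))
    got <- evaluate_set(preds, gts, threshold = 0.5)$global_counts
    want <- oracle_pooled_metrics(unlist(preds), unlist(gts), 0.5)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the Dice-IoU identity holds under pooled counts", {
  set.seed(22)
  for (i in 1:1000) {
    cc <- confusion_counts(tp = sample(0:100, 1), fp = sample(0:50, 1),
                           fn = sample(0:50, 1), tn = sample(0:200, 1))
    expect_equal(dice(cc), 2 * iou(cc) / (1 + iou(cc)), tolerance = 1e-12)
  }
})
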