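# Evaluation suite: worked examples, brute-force oracle equivalence on
# random small instances, and metric/loss duality.

test_that("confusion counts match enumeration", {
  gt <- matrix(0, 4, 4); gt[2:3, 2:3] <- 1
  pred <- gt; pred[2, 2] <- 0; pred[4, 4] <- 1   # miss one, add a stray
  ct <- confusion_counts(pred, gt)
  expect_equal(ct, list(TP = 3L, FP = 1L, TN = 11L, FN = 1L))
  expect_equal(confusion_counts(gt, gt)[c("FP", "FN")],
               list(FP = 0L, FN = 0L))
  expect_equal(confusion_counts(1 - gt, gt)[c("TP", "TN")],
               list(TP = 0L, TN = 0L))
  expect_error(confusion_counts(gt * 0.5, gt), "binary")
})

test_that("scalar metrics follow the per-image-then-mean form", {
  ct <- list(TP = 3L, FP = 1L, TN = 11L, FN = 1L)
  sc <- scalar_metrics(list(ct))
  expect_equal(sc$accuracy, 14 / 16)
  expect_equal(sc$sensitivity, 3 / 4)
  expect_equal(sc$dice, 6 / 8)
  perfect <- list(TP = 5L, FP = 0L, TN = 11L, FN = 0L)
  sc2 <- scalar_metrics(list(perfect, perfect))
  expect_equal(c(sc2$accuracy, sc2$sensitivity, sc2$dice), c(1, 1, 1))
  # mean of per-image Dice values 1.0 and 0.5
  half <- list(TP = 2L, FP = 2L, TN = 10L, FN = 2L)
  expect_equal(scalar_metrics(list(perfect, half))$dice, 0.75)
  expect_error(scalar_metrics(list()), "no images")
  expect_warning(scalar_metrics(list(list(TP = 0L, FP = 1L, TN = 15L,
                                          FN = 0L))), "excluded")
})

test_that("AUC reproduces analytic cases", {
  gt <- c(1, 1, 0, 1, 0, 0)
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2), gt), 8 / 9)
  expect_equal(auc_score(gt + runif(6, 0, 0.4), gt), 1)  # perfect separation
  expect_equal(auc_score(rep(0.3, 6), gt), 0.5)          # all ties
  expect_true(is.na(auc_score(runif(4), rep(1, 4))))     # one-class gt
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(51)
  for (k in 1:10) {
    s <- runif(20); g <- rbinom(20, 1, 0.4)
    if (sum(g) %in% c(0, 20)) g[1:2] <- c(0, 1)
    a <- auc_score(s, g)
    expect_equal(auc_score(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), g), a)
    expect_equal(auc_score(s^3 + 2, g), a)
  }
})

test_that("BF score handles agreement, disjoint objects and 1-px shifts", {
  gt <- matrix(0, 8, 8); gt[3:6, 3:6] <- 1
  cfg2 <- boundary_match_config(tolerance = 2)
  expect_equal(bf_score(gt, gt, cfg2), 1)
  pred <- matrix(0, 8, 8); pred[3:6, 4:7] <- 1      # shifted 1 px
  expect_equal(bf_score(pred, gt, cfg2), 1)
  far_a <- matrix(0, 12, 12); far_a[1:2, 1:2] <- 1
  far_b <- matrix(0, 12, 12); far_b[11:12, 11:12] <- 1
  expect_equal(bf_score(far_a, far_b, boundary_match_config(tolerance = 2)),
               0)
  empty <- matrix(0, 8, 8)
  expect_equal(bf_score(empty, empty, cfg2), 1)
  expect_equal(bf_score(empty, gt, cfg2), 0)
})

test_that("BF score is monotone non-decreasing in the tolerance", {
  set.seed(52)
  for (k in 1:5) {
    a <- matrix(rbinom(36, 1, 0.4), 6)
    b <- matrix(rbinom(36, 1, 0.4), 6)
    vals <- vapply(c(0, 1, 2, 4, 8), function(th)
      bf_score(a, b, boundary_match_config(tolerance = th)), 1)
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("all metrics equal brute-force oracles on random 6x6 instances", {
  set.seed(53)
  for (k in 1:60) {
    gt <- matrix(rbinom(36, 1, runif(1, 0.2, 0.8)), 6)
    prob <- matrix(runif(36), 6)
    pred <- (prob >= 0.5) * 1
    ct <- confusion_counts(pred, gt)
    expect_identical(ct, oracle_confusion(pred, gt))
    if (sum(gt) > 0) {
      sc <- suppressWarnings(scalar_metrics(list(ct)))
      oc <- oracle_confusion(pred, gt)
      expect_equal(sc$accuracy, (oc$TP + oc$TN) / 36)
      expect_equal(sc$sensitivity, oc$TP / (oc$TP + oc$FN))
      expect_equal(auc_score(prob, gt), oracle_auc(prob, gt),
                   tolerance = 1e-12)
    }
    th <- runif(1, 0.5, 3)
    expect_equal(bf_score(pred, gt, boundary_match_config(tolerance = th)),
                 oracle_bf(pred, gt, th), tolerance = 1e-12)
  }
})

test_that("Dice metric is the complement of the Dice loss on binary maps", {
  set.seed(54)
  for (k in 1:20) {
    p <- matrix(rbinom(36, 1, 0.5), 6)
    g <- matrix(rbinom(36, 1, 0.5), 6)
    if (sum(p) + sum(g) == 0) p[1] <- 1
    ct <- confusion_counts(p, g)
    dice_metric <- 2 * ct$TP / (2 * ct$TP + ct$FP + ct$FN)
    expect_equal(dice_metric, 1 - dice_loss(p, g, smooth_eps = 0),
                 tolerance = 1e-12)
  }
})

test_that("batch evaluation aggregates and recomputes consistently", {
  gt <- matrix(0, 8, 8); gt[3:6, 3:6] <- 1
  prob <- 0.1 + 0.8 * gt
  one <- list(prob = prob, gt = gt, id = "a")
  rep1 <- evaluate_batch(list(one))
  expect_true(all(abs(rep1$aggregate$mean - 1) < 1e-12))
  expect_true(all(rep1$aggregate$sd == 0))

  noisy <- list(prob = pmin(pmax(prob + matrix(rnorm(64, 0, 0.3), 8), 0), 1),
                gt = gt, id = "b")
  rep2 <- evaluate_batch(list(one, noisy, one, noisy))
  # duplicated samples: sd equals the two-value sd, means the two-value mean
  for (m in c("accuracy", "dice", "auc", "bf")) {
    v <- rep2$per_image[[m]]
    expect_equal(mean(v), rep2$aggregate$mean[rep2$aggregate$metric == m])
    expect_equal(v[1], v[3])
    expect_equal(v[2], v[4])
  }
  expect_error(evaluate_batch(list()), "empty")

  tmp_csv <- tempfile(fileext = ".csv"); tmp_json <- tempfile(fileext = ".json")
  write_report(rep2, csv = tmp_csv, json = tmp_json)
  back <- utils::read.csv(tmp_csv)
  expect_equal(nrow(back), 4 + 2)      # images + mean/sd rows
  js <- jsonlite::read_json(tmp_json, simplifyVector = TRUE)
  expect_equal(js$aggregate$mean, rep2$aggregate$mean, tolerance = 1e-9)
})
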