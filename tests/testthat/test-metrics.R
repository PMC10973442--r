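test_that("confusion counting follows the malignant-positive convention", {
  yt <- c("malignant", "malignant", "malignant", "benign", "benign")
  cm <- confusion_matrix(yt, yt)
  expect_equal(unlist(cm[c("tp", "fn", "tn", "fp")]),
               c(tp = 3, fn = 0, tn = 2, fp = 0))
  # inverting predictions swaps tp<->fn and tn<->fp
  inv <- ifelse(yt == "malignant", "benign", "malignant")
  cmi <- confusion_matrix(yt, inv)
  expect_equal(unlist(cmi[c("tp", "fn", "tn", "fp")]),
               c(tp = 0, fn = 3, tn = 0, fp = 2))
  # mixed case tallied by hand
  yt2 <- c("malignant", "malignant", "benign", "benign", "malignant", "benign")
  yp2 <- c("malignant", "benign", "benign", "malignant", "malignant", "benign")
  cm2 <- confusion_matrix(yt2, yp2)
  expect_equal(unlist(cm2[c("tp", "fn", "tn", "fp")]),
               c(tp = 2, fn = 1, tn = 2, fp = 1))
  expect_error(confusion_matrix("benign", c("benign", "benign")), "length")
  expect_error(confusion_matrix(c("benign", "weird"), c("benign", "odd")),
               "labels")
})

test_that("rates reproduce their defining ratios and degenerate errors", {
  cm <- confusion_counts(tp = 90, fn = 10, tn = 93, fp = 7)
  expect_equal(accuracy(cm), 100 * 183 / 200)
  expect_equal(sensitivity(cm), 90)
  expect_equal(precision_rate(cm), 100 * 90 / 97)
  expect_equal(specificity(cm), 93)
  expect_equal(f1_score(cm),
               2 * precision_rate(cm) * 90 / (precision_rate(cm) + 90))
  # perfect classifier
  pc <- confusion_counts(tp = 5, fn = 0, tn = 5, fp = 0)
  r <- metrics_report(pc)
  expect_true(all(unlist(r) == 100))
  # never-positive classifier: precision undefined, accuracy still 50
  np <- confusion_counts(tp = 0, fn = 10, tn = 10, fp = 0)
  expect_error(precision_rate(np), class = "bcicm_undefined_metric")
  expect_equal(accuracy(np), 50)
  ws <- capture_warnings(rn <- metrics_report(np))
  expect_true(any(grepl("PRE", ws)))
  expect_true(is.na(rn$pre) && is.na(rn$f1))
  expect_equal(rn$acc, 50)
})

test_that("F1 lies between precision and sensitivity; balanced ACC identity", {
  set.seed(31)
  for (rep in 1:25) {
    cm <- confusion_counts(tp = sample(1:50, 1), fn = sample(0:50, 1),
                           tn = sample(1:50, 1), fp = sample(0:50, 1))
    p <- precision_rate(cm); s <- sensitivity(cm)
    f <- f1_score(cm)
    expect_gte(f, min(p, s) - 1e-12)
    expect_lte(f, max(p, s) + 1e-12)
  }
  # balanced classes: ACC = (SEN+SPE)/2 exactly
  cm <- confusion_counts(tp = 37, fn = 13, tn = 41, fp = 9)
  expect_equal(accuracy(cm), (sensitivity(cm) + specificity(cm)) / 2)
})

test_that("class-label swap exchanges the class-conditional rates", {
  yt <- rep(c("malignant", "benign"), times = c(30, 20))
  set.seed(17)
  yp <- ifelse(runif(50) < 0.8, yt,
               ifelse(yt == "malignant", "benign", "malignant"))
  cm <- confusion_matrix(yt, yp)
  swap <- function(v) ifelse(v == "malignant", "benign", "malignant")
  cms <- confusion_matrix(swap(yt), swap(yp))
  expect_equal(accuracy(cm), accuracy(cms))
  expect_equal(sensitivity(cm), specificity(cms))
  expect_equal(specificity(cm), sensitivity(cms))
})

test_that("margin scores order points by relative center proximity", {
  b <- c(0, 0); m <- c(4, 0)
  expect_gt(margin_score(rbind(m), b, m), 0)
  expect_equal(margin_score(rbind(c(2, 3)), b, m), 0)
  bl <- make_feature_blobs(blob_gen_spec(n_per_class = 25, seed = 6))
  sc <- margin_score(bl$points, bl$centers[1, ], bl$centers[2, ])
  oracle <- apply(bl$points, 1, function(p)
    sqrt(sum((p - bl$centers[1, ])^2)) - sqrt(sum((p - bl$centers[2, ])^2)))
  expect_equal(order(sc), order(oracle))
  # thresholding the margin at zero is the nearest-center assignment
  expect_identical(as.integer(sc > 0),
                   assign_labels(bl$points, bl$centers))
})

test_that("ROC sweep handles perfect, chance, and hard classifiers", {
  y <- rep(c("malignant", "benign"), each = 4)
  # perfectly separating scores
  expect_equal(roc_curve(c(4, 3, 2, 1, -1, -2, -3, -4), y)$auc, 100)
  # constant scores: the chance diagonal
  expect_equal(roc_curve(rep(0.5, 8), y)$auc, 50)
  # hard classifier at SEN 90 / SPE 93: trapezoid gives 91.5
  yt <- rep(c("malignant", "benign"), times = c(100, 100))
  yp <- c(rep(1, 90), rep(0, 10), rep(0, 93), rep(1, 7))
  rc <- roc_curve(yp, yt)
  expect_equal(rc$auc, 91.5)
  expect_equal(length(rc$fpr), length(rc$tpr))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(rev(rc$fpr)[1], rev(rc$tpr)[1]), c(1, 1))
  expect_error(roc_curve(1:4, rep("malignant", 4)),
               class = "bcicm_undefined_metric")
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  y <- sample(c("benign", "malignant"), 60, replace = TRUE)
  sc <- rnorm(60) + (y == "malignant")
  ours <- roc_curve(sc, y)$auc
  ref <- 100 * as.numeric(pROC::auc(pROC::roc(
    response = factor(y, levels = c("benign", "malignant")),
    predictor = sc, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("cluster-class alignment maximizes accuracy with identity ties", {
  y <- rep(c("benign", "malignant"), each = 5)
  cl_id <- rep(c(0L, 1L), each = 5)
  expect_equal(align_clusters(cl_id, y),
               c("0" = "benign", "1" = "malignant"))
  expect_equal(align_clusters(1L - cl_id, y),
               c("0" = "malignant", "1" = "benign"))
  # 60/40 mixed case against exhaustive two-permutation search
  set.seed(12)
  y2 <- sample(rep(c("benign", "malignant"), times = c(12, 8)))
  cl2 <- sample(c(0L, 1L), 20, replace = TRUE)
  maps <- list(c("0" = "benign", "1" = "malignant"),
               c("0" = "malignant", "1" = "benign"))
  best <- maps[[which.max(vapply(maps, function(m)
    mean(m[as.character(cl2)] == y2), 0))]]
  expect_equal(align_clusters(cl2, y2), best)
  # perfect tie (both mappings 50% accurate) keeps the identity mapping
  tie <- align_clusters(c(0L, 0L, 1L, 1L),
                        c("benign", "malignant", "benign", "malignant"))
  expect_equal(tie, c("0" = "benign", "1" = "malignant"))
  expect_error(align_clusters(c(0L, 2L), c("benign", "benign")), "0 and 1")
})
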