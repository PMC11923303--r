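randomConfusion <- function() {
  matrix(sample(0:40, 9, replace = TRUE), 3, 3,
         dimnames = list(truth = 0:2, predicted = 0:2))
}

# Expand a confusion matrix back into label vectors.
labelsFromConfusion <- function(cm) {
  truth <- integer()
  pred <- integer()
  for (i in 1:3) for (j in 1:3) {
    truth <- c(truth, rep(i - 1L, cm[i, j]))
    pred <- c(pred, rep(j - 1L, cm[i, j]))
  }
  list(truth = truth, pred = pred)
}

test_that("perfect predictions score 1 everywhere", {
  truth <- rep(0:2, times = c(5, 7, 4))
  probs <- diag(3)[truth + 1, ]
  r <- evaluatePredictions(truth, truth, probs)
  expect_equal(r@accuracy, 1)
  expect_equal(r@kappa, 1)
  expect_equal(r@auc, 1)
  expect_equal(unname(r@micro[c("precision", "recall", "f1")]), rep(1, 3))
})

test_that("kappa matches the hand-evaluated chance-corrected form", {
  # 10 class-1 items predicted as class 0 out of 50/30/20
  cm <- matrix(c(50, 10, 0,  0, 20, 0,  0, 0, 20), 3, 3)
  lp <- labelsFromConfusion(cm)
  r <- suppressWarnings(evaluatePredictions(lp$truth, lp$pred))
  # p_o = 0.9; p_e = (50*60 + 30*20 + 20*20) / 100^2 = 0.4
  expect_equal(r@accuracy, 0.9)
  expect_equal(r@kappa, (0.9 - 0.4) / (1 - 0.4))
})

test_that("micro precision = micro recall = accuracy; kappa equals brute force", {
  set.seed(99)
  for (rep in 1:100) {
    cm <- randomConfusion()
    if (sum(cm) == 0) next
    lp <- labelsFromConfusion(cm)
    r <- suppressWarnings(evaluatePredictions(lp$truth, lp$pred))
    expect_identical(unname(confusionCounts(r)), unname(cm) * 1)
    expect_equal(unname(r@micro["precision"]), r@accuracy)
    expect_equal(unname(r@micro["recall"]), r@accuracy)
    n <- sum(cm)
    po <- sum(diag(cm)) / n
    pe <- sum(rowSums(cm) * colSums(cm)) / n^2
    expect_equal(r@kappa, if (pe == 1) 1 else (po - pe) / (1 - pe))
  }
})

test_that("metrics agree with an independent reference implementation", {
  skip_if_not_installed("caret")
  set.seed(7)
  truth <- sample(0:2, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.7, truth, sample(0:2, 200, replace = TRUE))
  r <- suppressWarnings(evaluatePredictions(truth, pred))
  ref <- caret::confusionMatrix(factor(pred, levels = 0:2),
                                factor(truth, levels = 0:2))
  expect_equal(r@accuracy, unname(ref$overall["Accuracy"]))
  expect_equal(r@kappa, unname(ref$overall["Kappa"]))
  expect_equal(unname(r@perClass$recall),
               unname(ref$byClass[, "Sensitivity"]))
  expect_equal(unname(r@perClass$specificity),
               unname(ref$byClass[, "Specificity"]))
})

test_that("chance-level predictions give near-zero kappa", {
  set.seed(11)
  truth <- rep(0:2, each = 400)
  pred <- sample(0:2, 1200, replace = TRUE)
  r <- suppressWarnings(evaluatePredictions(truth, pred))
  expect_lt(abs(r@kappa), 0.08)
})

test_that("AUC handling: omitted without probabilities, class-dropped when absent", {
  expect_warning(r <- evaluatePredictions(c(0, 1, 2), c(0, 1, 2)),
                 "AUC omitted")
  expect_true(is.na(r@auc))
  probs <- matrix(c(0.8, 0.1, 0.1,  0.2, 0.7, 0.1,  0.3, 0.6, 0.1),
                  3, 3, byrow = TRUE)
  expect_warning(r2 <- evaluatePredictions(c(0, 1, 1), c(0, 1, 1), probs),
                 "absent")
  expect_false(is.na(r2@auc))
  expect_error(evaluatePredictions(c(0, 3), c(0, 1)), "labels")
})

test_that("cross-validation of the rule backend is perfect and reproducible", {
  ds <- generateLabeledDataset(40, noiseSd = 0, seed = 14)
  cv <- suppressWarnings(crossValidate(ds$patches, ds$labels,
                                       function(p, l) ruleBackend(),
                                       nFolds = 10, seed = 15))
  accs <- vapply(cv$perFold, function(r) r@accuracy, numeric(1))
  expect_true(all(accs == 1))
  expect_equal(cv$meanAccuracy, 1)
  expect_equal(cv$bestFold, 1L)   # ties resolve to the lowest fold index
  cv2 <- suppressWarnings(crossValidate(ds$patches, ds$labels,
                                        function(p, l) ruleBackend(),
                                        nFolds = 10, seed = 15))
  expect_identical(cv$folds, cv2$folds)
  expect_equal(vapply(cv2$perFold, function(r) r@accuracy, numeric(1)), accs)
})
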