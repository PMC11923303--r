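# Multi-class evaluation: confusion matrix, accuracy, Cohen's kappa,
# one-vs-rest AUC, per-class precision/recall/specificity/F1 with micro and
# macro averages, and k-fold cross-validation of a backend.

#' Evaluate three-class predictions
#'
#' @param truth integer true labels (0/1/2).
#' @param predicted integer predicted labels (0/1/2).
#' @param probabilities optional n x 3 matrix of class probabilities;
#'   required for AUC (AUC is NA with a warning otherwise). A class absent
#'   from the truth is excluded from the AUC average with a warning.
#' @return A [MetricsReport-class].
#' @examples
#' r <- evaluatePredictions(c(0, 1, 2, 0), c(0, 1, 2, 0))
#' confusionCounts(r)
#' @export
evaluatePredictions <- function(truth, predicted, probabilities = NULL) {
  if (length(truth) != length(predicted) || !length(truth))
    stop("truth and predicted must be equal-length and non-empty")
  if (!all(truth %in% 0:2) || !all(predicted %in% 0:2))
    stop("labels must be in {0, 1, 2}")
  cm <- table(factor(truth, levels = 0:2), factor(predicted, levels = 0:2))
  cm <- matrix(as.numeric(cm), 3, 3,
               dimnames = list(truth = 0:2, predicted = 0:2))
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kap <- if (abs(1 - pe) < 1e-12) 1 else (acc - pe) / (1 - pe)

  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  safeDiv <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  prec <- safeDiv(tp, tp + fp)
  rec <- safeDiv(tp, tp + fn)
  spec <- safeDiv(tn, tn + fp)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec), NA_real_)
  perClass <- data.frame(class = 0:2, precision = prec, recall = rec,
                         specificity = spec, f1 = f1)
  micro <- c(precision = sum(tp) / sum(tp + fp),
             recall = sum(tp) / sum(tp + fn),
             specificity = sum(tn) / sum(tn + fp),
             f1 = sum(tp) / sum(tp + (fp + fn) / 2))
  macro <- c(precision = mean(prec, na.rm = TRUE),
             recall = mean(rec, na.rm = TRUE),
             specificity = mean(spec, na.rm = TRUE),
             f1 = mean(f1, na.rm = TRUE))

  auc <- NA_real_
  if (is.null(probabilities)) {
    warning("no probabilities supplied; AUC omitted")
  } else {
    probabilities <- as.matrix(probabilities)
    stopifnot(nrow(probabilities) == length(truth),
              ncol(probabilities) == 3)
    aucs <- vapply(0:2, function(k) {
      resp <- as.integer(truth == k)
      if (length(unique(resp)) < 2) {
        warning(sprintf("class %d absent from truth; excluded from AUC", k))
        return(NA_real_)
      }
      as.numeric(pROC::auc(pROC::roc(resp, probabilities[, k + 1],
                                     quiet = TRUE, direction = "<")))
    }, numeric(1))
    auc <- mean(aucs, na.rm = TRUE)
  }
  new("MetricsReport", confusion = cm, accuracy = acc, kappa = kap,
      auc = auc, perClass = perClass, micro = micro, macro = macro)
}

#' Write a MetricsReport as JSON (confusion matrix also as TSV)
#'
#' @param report a [MetricsReport-class].
#' @param path JSON output path; the confusion matrix is additionally
#'   written next to it with suffix `_confusion.tsv`.
#' @return `path`, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  jsonlite::write_json(metricsAsList(report), path, digits = NA,
                       auto_unbox = TRUE, dataframe = "rows")
  tsv <- sub("\\.json$", "", path)
  write.table(confusionCounts(report), paste0(tsv, "_confusion.tsv"),
              sep = "\t", quote = FALSE)
  invisible(path)
}

#' Cross-validate a classifier backend
#'
#' Stratified k-fold assignment via [splitDataset()]; for each fold the
#' backend factory is trained on the remaining folds and evaluated on the
#' held-out fold.
#'
#' @param patches list of pixel arrays.
#' @param labels integer labels (0/1/2).
#' @param backendFactory `function(trainPatches, trainLabels)` returning a
#'   backend. A factory that ignores its arguments (e.g. the rule backend)
#'   performs no training.
#' @param nFolds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return List: `perFold` (list of [MetricsReport-class]), `meanAccuracy`,
#'   `sdAccuracy`, `bestFold` (highest held-out accuracy, ties to the lowest
#'   fold index), and `folds` (the assignment).
#' @export
crossValidate <- function(patches, labels, backendFactory, nFolds = 10,
                          seed = 1) {
  folds <- splitDataset(labels, nFolds = nFolds, seed = seed)
  reports <- lapply(seq_len(nFolds), function(f) {
    tr <- folds != f
    backend <- backendFactory(patches[tr], labels[tr])
    preds <- lapply(patches[!tr], classifyPatch, backend = backend)
    evaluatePredictions(labels[!tr],
                        vapply(preds, `[[`, 0L, "label"),
                        do.call(rbind, lapply(preds, `[[`, "probabilities")))
  })
  accs <- vapply(reports, function(r) r@accuracy, numeric(1))
  list(perFold = reports, meanAccuracy = mean(accs), sdAccuracy = sd(accs),
       bestFold = which.max(accs), folds = folds)
}
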