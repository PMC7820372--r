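# Performance evaluation: confusion-count metrics (Sn, Sp, Acc, MCC),
# ROC/AUC, and stratified k-fold cross-validation of a full
# encode -> select -> train pipeline with pooled (micro-averaged) metrics.

#' Binary classification metrics from confusion counts
#'
#' Sensitivity `Sn = TP / (TP + FN)`, specificity `Sp = TN / (TN + FP)`,
#' accuracy `Acc = (TP + TN) / (TP + TN + FP + FN)` and the Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' When any factor of the MCC denominator is zero, MCC is defined as 0.
#'
#' @param tp,tn,fp,fn Non-negative integer confusion counts.
#' @return Named numeric vector `c(sn, sp, acc, mcc)`.
#' @export
binary_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop_apofam("confusion counts must be non-negative")
  if (sum(counts) == 0) stop_apofam("all confusion counts are zero")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / sum(counts)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  } else 0
  c(sn = sn, sp = sp, acc = acc, mcc = mcc)
}

#' ROC curve and AUC from decision scores
#'
#' The ROC curve is traced by sweeping a threshold over all distinct score
#' values (ties grouped, one vertex per distinct score), from (0, 0) to
#' (1, 1); the AUC is computed by trapezoidal integration, which makes it
#' equal to the normalized Mann-Whitney U statistic (ties counted 1/2).
#'
#' @param scores Numeric decision values; larger means more positive.
#' @param truth Logical vector (TRUE = positive), or labels combined with
#'   `positive`.
#' @param positive When `truth` is not logical, the label counted as
#'   positive (default `"apo"` if present, else the first sorted label).
#' @return List with `roc_points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive = NULL) {
  if (!is.logical(truth)) {
    truth <- as.character(truth)
    positive <- positive %||% (if ("apo" %in% truth) "apo"
                               else sort(unique(truth))[1L])
    truth <- truth == positive
  }
  stopifnot(length(scores) == length(truth))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop_apofam("both classes must be present to trace a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  # one vertex per distinct score: cumulative counts at the end of each tie
  # group
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(t)[last_of_group]
  fp <- cumsum(!t)[last_of_group]
  tpr <- c(0, tp / n_pos, 1)
  fpr <- c(0, fp / n_neg, 1)
  keep <- !duplicated(data.frame(fpr, tpr))
  roc <- data.frame(fpr = fpr[keep], tpr = tpr[keep])
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc_points = roc, auc = auc)
}

#' Build the default encode -> rank -> select -> train pipeline
#'
#' Returns the pipeline contract consumed by [kfold_cv()]: a function that,
#' given a labelled training [apo_dataset], fits the pipeline (ANOVA ranking
#' and feature selection happen inside the training data only) and returns a
#' prediction function for held-out records.
#'
#' @param encoder An [encoder_config()].
#' @param select_top Number of top-ranked ANOVA features kept (`Inf` or
#'   `NULL` keeps all).
#' @param cost,kernel_width Fixed SVM hyperparameters for the per-fold fits
#'   (defaults: mid-grid cost 32, kernel width 1/d).
#' @param positive Positive label for score orientation (binary tiers).
#' @return A function `(train_dataset) -> function(test_dataset) ->
#'   list(labels, scores)`.
#' @export
svm_pipeline <- function(encoder, select_top = 100L, cost = 32,
                         kernel_width = NULL, positive = NULL) {
  force(encoder); force(select_top); force(cost); force(kernel_width)
  function(train) {
    X <- encode_dataset(train, encoder)
    feats <- colnames(X)
    if (!is.null(select_top) && is.finite(select_top) &&
        select_top < ncol(X)) {
      ranked <- anova_rank(X, train$labels)
      feats <- ranked$feature_names[seq_len(select_top)]
    }
    model <- fixed_train(X[, feats, drop = FALSE], train$labels,
                         cost = cost, kernel_width = kernel_width,
                         encoder = encoder, positive = positive)
    function(test) predict(model, encode_dataset(test, encoder))
  }
}

#' Stratified k-fold cross-validation of a pipeline
#'
#' The dataset is split into stratified folds; for each fold the pipeline is
#' fit on the training split only (including any feature ranking/selection it
#' performs) and applied to the held-out split. Metrics are pooled
#' (micro-averaged) over all held-out predictions: confusion counts are
#' totalled first and the metric formulas applied once to the totals.
#'
#' @param dataset A labelled [apo_dataset]; every class must have at least
#'   `folds` samples.
#' @param pipeline A pipeline contract as returned by [svm_pipeline()].
#' @param folds Number of folds (default 10).
#' @param seed Fold-assignment seed (default 1).
#' @return An object of class `apo_eval`: for two classes, `sn`, `sp`,
#'   `acc`, `mcc`, `auc`, `roc_points` and a 2x2 `confusion`; for more,
#'   `acc`, `per_class_sensitivity` and the k x k `confusion`
#'   (rows = truth). Provenance fields `folds`, `seed`; pooled predictions
#'   in `predictions`.
#' @export
kfold_cv <- function(dataset, pipeline, folds = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "apo_dataset"))
  if (is.null(dataset$labels)) stop_apofam("dataset must be labelled")
  if (folds < 2L) stop_apofam("folds must be >= 2")
  tab <- table(dataset$labels)
  if (any(tab < folds)) {
    stop_apofam("class(es) smaller than the fold count: ",
                paste(names(tab)[tab < folds], collapse = ", "))
  }
  fold_id <- stratified_folds(dataset$labels, folds, seed)
  n <- length(dataset)
  pred_label <- character(n)
  pred_score <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    predictor <- pipeline(dataset[!te])
    p <- predictor(dataset[te])
    pred_label[te] <- p$labels
    if (is.numeric(p$scores) && !is.matrix(p$scores)) {
      pred_score[te] <- p$scores
    }
  }
  classes <- sort(unique(dataset$labels))
  confusion <- table(truth = factor(dataset$labels, classes),
                     predicted = factor(pred_label, classes))
  out <- list(confusion = confusion, folds = folds, seed = seed,
              predictions = data.frame(id = dataset$ids,
                                       truth = dataset$labels,
                                       predicted = pred_label,
                                       score = pred_score,
                                       fold = fold_id,
                                       stringsAsFactors = FALSE))
  if (length(classes) == 2L) {
    pos <- if ("apo" %in% classes) "apo" else classes[1L]
    neg <- setdiff(classes, pos)
    tp <- confusion[pos, pos]; fn <- confusion[pos, neg]
    fp <- confusion[neg, pos]; tn <- confusion[neg, neg]
    m <- binary_metrics(tp, tn, fp, fn)
    out <- c(out, as.list(m), list(positive = pos))
    if (!anyNA(pred_score)) {
      r <- roc_auc(pred_score, dataset$labels == pos)
      out$auc <- r$auc
      out$roc_points <- r$roc_points
    }
  } else {
    out$acc <- sum(diag(confusion)) / n
    out$per_class_sensitivity <-
      stats::setNames(diag(confusion) / rowSums(confusion), classes)
  }
  structure(out, class = "apo_eval")
}

#' @export
print.apo_eval <- function(x, ...) {
  cat("apo_eval:", x$folds, "-fold stratified CV, seed ", x$seed,
      "\n", sep = "")
  if (!is.null(x$sn)) {
    cat(sprintf("  Sn %.4f  Sp %.4f  Acc %.4f  MCC %.4f",
                x$sn, x$sp, x$acc, x$mcc))
    if (!is.null(x$auc)) cat(sprintf("  AUC %.4f", x$auc))
    cat("\n")
  } else {
    cat(sprintf("  overall Acc %.4f\n", x$acc))
    cat("  per-class sensitivity:\n")
    print(round(x$per_class_sensitivity, 4))
  }
  invisible(x)
}

#' Plot the pooled ROC curve of a binary evaluation
#' @param x An `apo_eval` with ROC points.
#' @param ... Passed to [graphics::plot].
#' @export
#' @method plot apo_eval
plot.apo_eval <- function(x, ...) {
  if (is.null(x$roc_points)) stop_apofam("no ROC points in this report")
  graphics::plot(x$roc_points$fpr, x$roc_points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Serialize an evaluation report
#'
#' JSON for the full report; optionally the ROC points as two-column TSV.
#'
#' @param x An `apo_eval`.
#' @param path Output JSON path.
#' @param roc_tsv Optional TSV path for the ROC points.
#' @export
write_eval <- function(x, path, roc_tsv = NULL) {
  rep <- list(folds = x$folds, seed = x$seed,
              confusion = as.data.frame.matrix(unclass(x$confusion)))
  for (f in c("sn", "sp", "acc", "mcc", "auc", "positive")) {
    if (!is.null(x[[f]])) rep[[f]] <- x[[f]]
  }
  if (!is.null(x$per_class_sensitivity)) {
    rep$per_class_sensitivity <- as.list(x$per_class_sensitivity)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(roc_tsv) && !is.null(x$roc_points)) {
    utils::write.table(x$roc_points, roc_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
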