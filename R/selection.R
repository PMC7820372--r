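# Feature selection: one-way ANOVA F-value ranking and incremental feature
# selection (IFS) driven by stratified cross-validated accuracy.

#' Rank features by the one-way ANOVA F-value
#'
#' For each feature, F = MS_between / MS_within of a standard one-way ANOVA
#' across the label groups (df k - 1 and n - k). Large F means the feature
#' separates the classes well relative to its within-class spread. A feature
#' constant across all samples takes F = 0 (0/0 convention); a feature with
#' zero within-group variance but distinct group means separates perfectly
#' and takes F = Inf. Ties are broken by original column order.
#'
#' @param X Numeric feature matrix, samples x features, with column names.
#' @param y Class labels, one per row of `X`; at least two classes, each
#'   with at least two samples.
#' @return An object of class `ranked_features`: list with `feature_names`
#'   (descending F), `f_values` (parallel, non-increasing) and `order`
#'   (column indices into `X`).
#' @export
anova_rank <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(y) != nrow(X)) stop_apofam("y must have one label per row of X")
  tab <- table(y)
  if (length(tab) < 2L) stop_apofam("need at least 2 classes")
  if (any(tab < 2L)) {
    stop_apofam("every class needs >= 2 samples; too small: ",
                paste(names(tab)[tab < 2L], collapse = ", "))
  }
  n <- nrow(X)
  k <- length(tab)
  groups <- split(seq_len(n), y)
  grand <- colMeans(X)
  ssb <- numeric(ncol(X))
  ssw <- numeric(ncol(X))
  for (idx in groups) {
    gm <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + length(idx) * (gm - grand)^2
    ssw <- ssw + colSums((X[idx, , drop = FALSE] -
                            rep(gm, each = length(idx)))^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  # msw = 0: a feature constant within every group separates perfectly
  # (F = Inf) unless it is constant overall too (0/0, defined as 0)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  # guard tiny negative round-off
  f[f < 0] <- 0
  ord <- order(-f, seq_along(f))
  structure(list(feature_names = colnames(X)[ord], f_values = f[ord],
                 order = ord),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, n = 10L, ...) {
  cat("ranked_features:", length(x$feature_names), "features\n")
  top <- utils::head(data.frame(feature = x$feature_names,
                                F = x$f_values), n)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Write a feature ranking as TSV
#' @param ranked A `ranked_features` object.
#' @param path Output TSV path (columns `feature`, `F`).
#' @export
write_ranking <- function(ranked, path) {
  utils::write.table(
    data.frame(feature = ranked$feature_names, F = ranked$f_values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Default subset trainer used by IFS: an RBF-SVM at fixed mid-grid
# hyperparameters. Returns a function(Xtr, ytr) -> function(Xte) -> labels.
default_ifs_trainer <- function(cost = 1, kernel_width = NULL) {
  function(Xtr, ytr) {
    fit <- svm_fit(Xtr, ytr, cost = cost,
                   kernel_width = kernel_width %||% 1 / ncol(Xtr))
    function(Xte) svm_predict_labels(fit, Xte)
  }
}

#' Incremental feature selection (IFS)
#'
#' Features are added to the working subset in ranked order; for each subset
#' size the classifier is evaluated by stratified cross-validated accuracy,
#' and the smallest subset attaining the maximum accuracy is selected.
#'
#' To keep the accuracy curve free of selection bias, each training fold
#' re-ranks the features on its own samples and uses the top n of its own
#' ranking (set `refold_rank = FALSE` to rank once on the full data, which
#' is optimistic on noise). The returned `optimal_features` are always the
#' top `optimal_size` names of the supplied full-data ranking — the subset
#' a final model trained on all data would use.
#'
#' @param ranked A [anova_rank()] result consistent with `X`'s columns.
#' @param X Feature matrix, samples x features.
#' @param y Class labels parallel to rows of `X`.
#' @param cv_folds Number of stratified folds (default 5).
#' @param trainer A function `(X_train, y_train)` returning a prediction
#'   function `(X_test) -> labels`. Defaults to an RBF-SVM at fixed mid-grid
#'   hyperparameters.
#' @param stride Evaluate subset sizes `1, 1 + stride, 1 + 2*stride, ...`
#'   (default 1, i.e. every size). The full feature count is always
#'   included.
#' @param max_size Largest subset size to consider (default: all features).
#' @param refold_rank Re-rank features within each training fold
#'   (default `TRUE`).
#' @param seed Seed for the fold assignment (default 1).
#' @return An object of class `ifs_result`: list with `curve` (data.frame
#'   `size`, `accuracy`), `optimal_size`, `optimal_features`,
#'   `optimal_accuracy`, and provenance (`cv_folds`, `seed`, `stride`).
#' @export
incremental_feature_selection <- function(ranked, X, y, cv_folds = 5L,
                                          trainer = default_ifs_trainer(),
                                          stride = 1L, max_size = NULL,
                                          refold_rank = TRUE, seed = 1L) {
  stopifnot(inherits(ranked, "ranked_features"))
  X <- as.matrix(X)
  y <- as.character(y)
  if (!all(ranked$feature_names %in% colnames(X))) {
    stop_apofam("ranking is not consistent with X's columns")
  }
  if (cv_folds < 2L) stop_apofam("cv_folds must be >= 2")
  p <- length(ranked$feature_names)
  max_size <- min(max_size %||% p, p)
  sizes <- unique(c(seq(1L, max_size, by = stride), max_size))
  folds <- stratified_folds(y, cv_folds, seed)
  fold_order <- lapply(seq_len(cv_folds), function(f) {
    if (refold_rank) {
      anova_rank(X[folds != f, , drop = FALSE], y[folds != f])$feature_names
    } else {
      ranked$feature_names
    }
  })
  acc <- numeric(length(sizes))
  for (s in seq_along(sizes)) {
    correct <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      feats <- fold_order[[f]][seq_len(sizes[s])]
      pred_fun <- tryCatch(
        trainer(X[tr, feats, drop = FALSE], y[tr]),
        error = function(e) {
          stop_apofam("trainer failed at subset size ", sizes[s], ": ",
                      conditionMessage(e))
        })
      pred <- pred_fun(X[!tr, feats, drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    acc[s] <- correct / length(y)
  }
  best <- which.max(acc)  # first maximum = smallest size at the max
  structure(list(curve = data.frame(size = sizes, accuracy = acc),
                 optimal_size = sizes[best],
                 optimal_features = ranked$feature_names[seq_len(sizes[best])],
                 optimal_accuracy = acc[best],
                 cv_folds = cv_folds, seed = seed, stride = stride),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("ifs_result:", nrow(x$curve), "subset sizes evaluated (stride ",
      x$stride, ")\n", sep = "")
  cat("  optimal subset:", x$optimal_size, "features, CV accuracy",
      sprintf("%.4f", x$optimal_accuracy), "\n")
  invisible(x)
}

#' Plot the IFS accuracy curve
#' @param x An `ifs_result`.
#' @param ... Passed to [graphics::plot].
#' @export
#' @method plot ifs_result
plot.ifs_result <- function(x, ...) {
  graphics::plot(x$curve$size, x$curve$accuracy, type = "b",
                 xlab = "Number of top-ranked features",
                 ylab = "Cross-validated accuracy", ...)
  graphics::abline(v = x$optimal_size, lty = 2, col = "grey40")
  invisible(x)
}

#' Serialize an IFS result to JSON
#' @param x An `ifs_result`.
#' @param path Output JSON path.
#' @export
write_ifs <- function(x, path) {
  jsonlite::write_json(
    list(curve = x$curve, optimal_size = x$optimal_size,
         optimal_features = x$optimal_features,
         optimal_accuracy = x$optimal_accuracy,
         cv_folds = x$cv_folds, seed = x$seed, stride = x$stride),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
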