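# RBF-kernel SVM classifiers (e1071 / libsvm backend) with grid search, and
# the two-tier model: tier 1 separates apolipoproteins from
# non-apolipoproteins, tier 2 assigns tier-1 positives to one of seven
# subfamilies. Features are standardized with training-set mean/sd before
# the kernel; the scaling is stored in the model.

DEFAULT_C_GRID <- 2^seq(-5, 15, by = 2)
DEFAULT_WIDTH_GRID <- 2^seq(-15, 3, by = 2)

# Standardize columns by train-set mean/sd; constant columns get scale 1 so
# they map to exact zeros rather than NaN.
.fit_scaling <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale)
}

.apply_scaling <- function(X, scaling) {
  sweep(sweep(X, 2L, scaling$center), 2L, scaling$scale, "/")
}

# Low-level RBF-SVM fit on an already-selected feature matrix.
svm_fit <- function(X, y, cost, kernel_width) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop_apofam("need at least 2 classes to train")
  scaling <- .fit_scaling(X)
  fit <- e1071::svm(.apply_scaling(X, scaling), y, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = kernel_width,
                    scale = FALSE)
  list(fit = fit, scaling = scaling, features = colnames(X),
       levels = levels(y), cost = cost, kernel_width = kernel_width)
}

svm_predict_labels <- function(model, X) {
  X <- .align_features(as.matrix(X), model$features)
  as.character(stats::predict(model$fit, .apply_scaling(X, model$scaling)))
}

# Align a feature matrix's columns to a model's feature list by name.
.align_features <- function(X, features) {
  missing <- setdiff(features, colnames(X))
  if (length(missing)) {
    stop_apofam("missing required feature(s): ",
                paste(utils::head(missing, 5), collapse = ", "))
  }
  X[, features, drop = FALSE]
}

#' Train an RBF-SVM tier with grid search over cost and kernel width
#'
#' Exhaustive grid evaluation by stratified cross-validated accuracy; the
#' best (cost, width) pair is refit on all data. Ties are broken towards
#' smaller cost, then smaller width. The SVM's kernel-width parameter is the
#' RBF gamma of libsvm, named `kernel_width` throughout to avoid collision
#' with the PseAAC tier count.
#'
#' @param X Feature matrix (samples x features, named columns).
#' @param y Class labels (at least two classes).
#' @param c_grid,width_grid Positive hyperparameter grids. Defaults are the
#'   standard libsvm practice grids `2^(-5, -3, ..., 15)` and
#'   `2^(-15, -13, ..., 3)`.
#' @param cv_folds Stratified folds for the grid evaluation (default 5).
#' @param seed Fold-assignment seed (default 1).
#' @param encoder An optional [encoder_config()] recorded in the model so
#'   query sequences can be encoded identically at prediction time.
#' @param label_set Optional declared label set.
#' @param positive For binary problems, the label treated as positive when
#'   orienting decision scores (default `"apo"` when present).
#' @return An object of class `apofam_tier`.
#' @export
grid_search_train <- function(X, y, c_grid = DEFAULT_C_GRID,
                              width_grid = DEFAULT_WIDTH_GRID,
                              cv_folds = 5L, seed = 1L, encoder = NULL,
                              label_set = NULL, positive = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop_apofam("need at least 2 classes")
  if (!length(c_grid) || !length(width_grid)) {
    stop_apofam("hyperparameter grids must be non-empty")
  }
  if (any(c_grid <= 0) || any(width_grid <= 0)) {
    stop_apofam("grid values must be positive")
  }
  c_grid <- sort(c_grid)
  width_grid <- sort(width_grid)
  folds <- stratified_folds(y, cv_folds, seed)
  best <- list(acc = -1, cost = NA_real_, width = NA_real_)
  for (cost in c_grid) {
    for (width in width_grid) {
      correct <- 0L
      for (f in seq_len(cv_folds)) {
        tr <- folds != f
        m <- svm_fit(X[tr, , drop = FALSE], y[tr], cost, width)
        correct <- correct + sum(svm_predict_labels(
          m, X[!tr, , drop = FALSE]) == y[!tr])
      }
      acc <- correct / length(y)
      if (acc > best$acc) best <- list(acc = acc, cost = cost, width = width)
    }
  }
  final <- svm_fit(X, y, best$cost, best$width)
  structure(list(encoder = encoder,
                 selected_features = colnames(X),
                 cost = best$cost, kernel_width = best$width,
                 cv_accuracy = best$acc,
                 label_set = label_set %||% sort(unique(y)),
                 positive = positive %||%
                   (if ("apo" %in% y) "apo" else sort(unique(y))[1L]),
                 fit = final,
                 provenance = list(seed = seed, cv_folds = cv_folds,
                                   c_grid = c_grid,
                                   width_grid = width_grid)),
            class = "apofam_tier")
}

# Train a tier at fixed hyperparameters (no grid search); used inside IFS
# and cross-validation pipelines where a per-subset grid search would be
# disproportionate.
fixed_train <- function(X, y, cost = 32, kernel_width = NULL,
                        encoder = NULL, label_set = NULL, positive = NULL) {
  X <- as.matrix(X)
  kernel_width <- kernel_width %||% 1 / ncol(X)
  final <- svm_fit(X, y, cost, kernel_width)
  structure(list(encoder = encoder, selected_features = colnames(X),
                 cost = cost, kernel_width = kernel_width,
                 cv_accuracy = NA_real_,
                 label_set = label_set %||% sort(unique(as.character(y))),
                 positive = positive %||%
                   (if ("apo" %in% y) "apo" else sort(unique(y))[1L]),
                 fit = final,
                 provenance = list(seed = NA_integer_, cv_folds = NA_integer_,
                                   c_grid = cost, width_grid = kernel_width)),
            class = "apofam_tier")
}

#' Predict with a trained tier
#'
#' Columns of `newdata` are restricted and reordered to the model's selected
#' features by name, then standardized with the stored training scaling.
#'
#' @param object An `apofam_tier`.
#' @param newdata Feature matrix containing at least the model's selected
#'   features, or an [apo_dataset] (encoded with the model's stored encoder
#'   config).
#' @param ... Unused.
#' @return A list with `labels` (character) and `scores`: for a binary tier
#'   a numeric vector of signed decision values oriented so positive means
#'   the model's positive class; for a multiclass tier a samples x classes
#'   matrix of one-vs-one vote counts.
#' @export
predict.apofam_tier <- function(object, newdata, ...) {
  if (inherits(newdata, "apo_dataset")) {
    if (is.null(object$encoder)) {
      stop_apofam("model has no encoder config; supply a feature matrix")
    }
    newdata <- encode_dataset(newdata, object$encoder)
  }
  X <- .align_features(as.matrix(newdata), object$selected_features)
  Xs <- .apply_scaling(X, object$fit$scaling)
  pred <- stats::predict(object$fit$fit, Xs, decision.values = TRUE)
  labels <- as.character(pred)
  dv <- attr(pred, "decision.values")
  lev <- object$fit$levels
  if (length(lev) == 2L) {
    # single pairwise column "A/B": positive sign favours A
    scores <- as.numeric(dv[, 1L])
    first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1]][1L]
    if (!identical(first, object$positive)) scores <- -scores
  } else {
    votes <- matrix(0, nrow(X), length(lev),
                    dimnames = list(rownames(X), lev))
    for (col in colnames(dv)) {
      pair <- strsplit(col, "/", fixed = TRUE)[[1]]
      win <- ifelse(dv[, col] > 0, pair[1L], pair[2L])
      votes[cbind(seq_len(nrow(X)), match(win, lev))] <-
        votes[cbind(seq_len(nrow(X)), match(win, lev))] + 1
    }
    scores <- votes
  }
  list(labels = labels, scores = scores)
}

#' @export
print.apofam_tier <- function(x, ...) {
  cat("apofam_tier:", length(x$label_set), "classes (",
      paste(x$label_set, collapse = ", "), ")\n")
  if (!is.null(x$encoder)) {
    cat("  encoder: "); print(x$encoder)
  }
  cat("  features:", length(x$selected_features),
      "| cost:", format(x$cost), "| kernel width:",
      format(x$kernel_width), "\n")
  if (!is.na(x$cv_accuracy)) {
    cat("  grid-search CV accuracy:", sprintf("%.4f", x$cv_accuracy), "\n")
  }
  invisible(x)
}

#' Fit the two-tier apolipoprotein classifier
#'
#' The main fitting function of the package. Tier 1 is a binary RBF-SVM
#' separating apolipoproteins (`apo`) from non-apolipoproteins (`non-apo`),
#' trained on pseudo-amino-acid composition features by default; tier 2 is a
#' 7-class subfamily RBF-SVM trained on k-spaced amino-acid pair features of
#' the positives. For each tier the features are ranked by ANOVA F-value,
#' optionally pruned by incremental feature selection, and the classifier's
#' cost and kernel width are tuned by grid search.
#'
#' @param binary_data Labelled [apo_dataset] with labels `apo` / `non-apo`.
#' @param subfamily_data Labelled [apo_dataset] of apolipoproteins with
#'   subfamily labels.
#' @param tier1_encoder,tier2_encoder [encoder_config()]s; defaults follow
#'   the method's selected representations: PseAAC (gamma = 10) for tier 1
#'   and CKSAAP (k_max = 3) for tier 2.
#' @param selection `"ifs"` (ANOVA ranking + incremental feature selection,
#'   the full method), `"topn"` (ANOVA ranking, keep the top `n_features`),
#'   or `"none"` (all features).
#' @param n_features Subset size per tier for `selection = "topn"`
#'   (length-2 vector or single value; default 100, capped at the feature
#'   count).
#' @param ifs_stride Stride of the IFS subset-size sweep; `NULL` (default)
#'   picks a stride so that about 60 sizes are evaluated.
#' @param grid_search Tune (cost, kernel width) by grid search on the
#'   selected subset (default `TRUE`); otherwise fixed mid-grid values are
#'   used.
#' @param c_grid,width_grid Hyperparameter grids for the grid search.
#' @param cv_folds Folds for IFS and grid-search evaluation (default 5).
#' @param seed Seed governing all fold assignments (default 1).
#' @return An object of class `apofam`: list with `tier1` and `tier2`
#'   (`apofam_tier`s), the per-tier `ifs` results (when run), and `call`.
#' @examples
#' \donttest{
#' sets <- generate_two_tier(synthetic_spec(n_per_class = 12, seed = 7),
#'                           synthetic_spec(n_classes = 1, n_per_class = 40,
#'                                          seed = 8))
#' fit <- apofam(sets$binary, sets$subfamily, selection = "topn",
#'               n_features = 40, grid_search = FALSE)
#' print(fit)
#' }
#' @export
apofam <- function(binary_data, subfamily_data,
                   tier1_encoder = encoder_config("PseAAC", gamma = 10),
                   tier2_encoder = encoder_config("CKSAAP", k_max = 3),
                   selection = c("ifs", "topn", "none"),
                   n_features = 100L, ifs_stride = NULL,
                   grid_search = TRUE,
                   c_grid = DEFAULT_C_GRID, width_grid = DEFAULT_WIDTH_GRID,
                   cv_folds = 5L, seed = 1L) {
  selection <- match.arg(selection)
  stopifnot(inherits(binary_data, "apo_dataset"),
            inherits(subfamily_data, "apo_dataset"))
  if (is.null(binary_data$labels) || is.null(subfamily_data$labels)) {
    stop_apofam("both datasets must be labelled")
  }
  n_features <- rep_len(n_features, 2L)
  tiers <- list()
  ifs <- list()
  specs <- list(
    tier1 = list(data = binary_data, encoder = tier1_encoder,
                 n_feat = n_features[1L], positive = "apo"),
    tier2 = list(data = subfamily_data, encoder = tier2_encoder,
                 n_feat = n_features[2L], positive = NULL))
  for (tn in names(specs)) {
    sp <- specs[[tn]]
    X <- encode_dataset(sp$data, sp$encoder)
    y <- sp$data$labels
    ranked <- anova_rank(X, y)
    feats <- colnames(X)
    if (selection == "topn") {
      feats <- ranked$feature_names[seq_len(min(sp$n_feat, ncol(X)))]
    } else if (selection == "ifs") {
      stride <- ifs_stride %||% max(1L, ceiling(ncol(X) / 60))
      res <- incremental_feature_selection(ranked, X, y,
                                           cv_folds = cv_folds,
                                           stride = stride, seed = seed)
      ifs[[tn]] <- res
      feats <- res$optimal_features
    }
    Xs <- X[, feats, drop = FALSE]
    tiers[[tn]] <- if (grid_search) {
      grid_search_train(Xs, y, c_grid = c_grid, width_grid = width_grid,
                        cv_folds = cv_folds, seed = seed,
                        encoder = sp$encoder, positive = sp$positive,
                        label_set = sort(unique(y)))
    } else {
      fixed_train(Xs, y, encoder = sp$encoder, positive = sp$positive,
                  label_set = sort(unique(y)))
    }
  }
  structure(list(tier1 = tiers$tier1, tier2 = tiers$tier2, ifs = ifs,
                 selection = selection, seed = seed,
                 call = match.call()),
            class = "apofam")
}

#' Two-tier prediction for protein records
#'
#' Each record is first encoded with tier 1's encoder and classified as
#' apolipoprotein or not; only tier-1 positives are passed to tier 2 for
#' subfamily assignment. A record that cannot be encoded (e.g. non-standard
#' residues, too short) yields an error entry; the remaining records are
#' still processed.
#'
#' @param object A fitted [apofam] model.
#' @param newdata An [apo_dataset] or character vector of sequences.
#' @param ... Unused.
#' @return A data.frame with one row per record: `id`, `tier1_label`,
#'   `tier1_score` (signed decision value, positive = apolipoprotein),
#'   `subfamily` (`NA` for tier-1 negatives), and `error` (`NA` unless the
#'   record failed). The tier-2 vote matrix for the positives is attached as
#'   attribute `"subfamily_scores"`.
#' @export
predict.apofam <- function(object, newdata, ...) {
  if (is.character(newdata)) {
    newdata <- apo_dataset(sprintf("query_%d", seq_along(newdata)), newdata)
  }
  stopifnot(inherits(newdata, "apo_dataset"))
  n <- length(newdata)
  out <- data.frame(id = newdata$ids,
                    tier1_label = rep(NA_character_, n),
                    tier1_score = rep(NA_real_, n),
                    subfamily = rep(NA_character_, n),
                    error = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (!n) {
    attr(out, "subfamily_scores") <-
      matrix(0, 0L, length(object$tier2$label_set),
             dimnames = list(NULL, object$tier2$label_set))
    return(out)
  }
  enc1 <- lapply(seq_len(n), function(i) {
    tryCatch(.encode_one(newdata$sequences[i], object$tier1$encoder),
             error = function(e) conditionMessage(e))
  })
  ok <- !vapply(enc1, is.character, logical(1))
  out$error[!ok] <- unlist(enc1[!ok])
  votes <- matrix(0, 0L, length(object$tier2$label_set),
                  dimnames = list(NULL, object$tier2$label_set))
  if (any(ok)) {
    X1 <- do.call(rbind, enc1[ok])
    rownames(X1) <- newdata$ids[ok]
    p1 <- predict(object$tier1, X1)
    out$tier1_label[ok] <- p1$labels
    out$tier1_score[ok] <- p1$scores
    pos <- which(ok)[p1$labels == object$tier1$positive]
    if (length(pos)) {
      pos_ok <- logical(length(pos))
      enc2 <- lapply(pos, function(i) {
        tryCatch(.encode_one(newdata$sequences[i], object$tier2$encoder),
                 error = function(e) conditionMessage(e))
      })
      pos_ok <- !vapply(enc2, is.character, logical(1))
      out$error[pos[!pos_ok]] <- unlist(enc2[!pos_ok])
      if (any(pos_ok)) {
        X2 <- do.call(rbind, enc2[pos_ok])
        rownames(X2) <- newdata$ids[pos[pos_ok]]
        p2 <- predict(object$tier2, X2)
        out$subfamily[pos[pos_ok]] <- p2$labels
        votes <- p2$scores
      }
    }
  }
  attr(out, "subfamily_scores") <- votes
  out
}

#' @export
print.apofam <- function(x, ...) {
  cat("Two-tier apolipoprotein classifier (apofam)\n")
  cat("-- tier 1 (identification) --\n"); print(x$tier1)
  cat("-- tier 2 (subfamily) --\n"); print(x$tier2)
  invisible(x)
}

#' @export
#' @method summary apofam
summary.apofam <- function(object, ...) {
  cat("Two-tier apolipoprotein classifier\n")
  cat("selection:", object$selection, "| seed:", object$seed, "\n\n")
  for (tn in c("tier1", "tier2")) {
    t <- object[[tn]]
    cat(tn, ": ", t$encoder$encoder, " encoder, ",
        length(t$selected_features), " features, cost ", format(t$cost),
        ", kernel width ", format(t$kernel_width), sep = "")
    if (!is.na(t$cv_accuracy)) {
      cat(", grid-search CV accuracy ", sprintf("%.4f", t$cv_accuracy),
          sep = "")
    }
    cat("\n")
    if (!is.null(object$ifs[[tn]])) {
      cat("  IFS optimum: ", object$ifs[[tn]]$optimal_size,
          " features at CV accuracy ",
          sprintf("%.4f", object$ifs[[tn]]$optimal_accuracy), "\n", sep = "")
    }
  }
  invisible(object)
}

#' Serialize / restore a fitted model
#'
#' Writes a JSON envelope (`<path>.json`: encoder config, selected features,
#' hyperparameters, scaling, provenance — sufficient to retrain
#' bit-compatibly from the same data and seed) plus an opaque fitted payload
#' (`<path>.rds`).
#'
#' @param object An `apofam` or `apofam_tier` model.
#' @param path Output path stem.
#' @return `write_model` returns `path` invisibly; `read_model` the restored
#'   model.
#' @export
write_model <- function(object, path) {
  envelope <- function(t) {
    list(encoder = unclass(t$encoder), selected_features = t$selected_features,
         cost = t$cost, kernel_width = t$kernel_width,
         label_set = t$label_set, positive = t$positive,
         scaling = t$fit$scaling, provenance = t$provenance)
  }
  env <- if (inherits(object, "apofam_tier")) {
    list(class = "apofam_tier", tier = envelope(object))
  } else {
    list(class = "apofam", tier1 = envelope(object$tier1),
         tier2 = envelope(object$tier2), selection = object$selection,
         seed = object$seed)
  }
  jsonlite::write_json(env, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  saveRDS(object, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  readRDS(paste0(path, ".rds"))
}
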