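test_that("confusion-count metrics match the defining formulas", {
  perfect <- binary_metrics(50, 50, 0, 0)
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  degenerate <- binary_metrics(0, 50, 0, 50)
  expect_equal(unname(degenerate), c(0, 1, 0.5, 0))
  withr::local_seed(51)
  for (rep in 1:100) {
    cnt <- rpois(4, lambda = 20)
    tp <- cnt[1]; tn <- cnt[2]; fp <- cnt[3]; fn <- cnt[4]
    if (sum(cnt) == 0) next
    m <- binary_metrics(tp, tn, fp, fn)
    if (tp + fn > 0) expect_equal(unname(m["sn"]), tp / (tp + fn))
    if (tn + fp > 0) expect_equal(unname(m["sp"]), tn / (tn + fp))
    expect_equal(unname(m["acc"]), (tp + tn) / sum(cnt))
    den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
    mcc_direct <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
    expect_equal(unname(m["mcc"]), mcc_direct, tolerance = 1e-12)
    expect_gte(m["mcc"], -1); expect_lte(m["mcc"], 1)
  }
  expect_error(binary_metrics(0, 0, 0, 0), "zero")
})

test_that("ROC endpoints, degenerate cases and the rank-statistic oracle", {
  truth <- rep(c(TRUE, FALSE), each = 5)
  sep <- roc_auc(10:1, truth)
  expect_equal(sep$auc, 1)
  expect_equal(sep$roc_points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(sep$roc_points[nrow(sep$roc_points), ]),
               c(fpr = 1, tpr = 1))
  flat <- roc_auc(rep(2, 10), truth)
  expect_equal(flat$auc, 0.5)
  withr::local_seed(52)
  for (rep in 1:100) {
    n <- sample(20:60, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth) || all(truth)) next
    scores <- sample(rnorm(10), n, replace = TRUE)  # heavy ties
    r <- roc_auc(scores, truth)
    expect_equal(r$auc, rank_auc(scores, truth), tolerance = 1e-12)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("cross-validation pools counts exactly and is seed-reproducible", {
  sets <- generate_two_tier(
    synthetic_spec(n_classes = 2, n_per_class = 15, label_prefix = "pos",
                   seed = 61),
    synthetic_spec(n_classes = 1, n_per_class = 30, label_prefix = "neg",
                   seed = 62),
    subfamily_labels = c("ApoA", "ApoB"))
  pipe <- svm_pipeline(encoder_config("PseAAC", gamma = 5), select_top = 30)
  ev <- kfold_cv(sets$binary, pipe, folds = 5, seed = 7)
  expect_identical(sum(ev$confusion), length(sets$binary))
  expect_gte(ev$acc, 0.9)  # strongly separated synthetic classes
  ev2 <- kfold_cv(sets$binary, pipe, folds = 5, seed = 7)
  expect_identical(ev$predictions, ev2$predictions)
  expect_equal(ev$auc, ev2$auc)
  expect_error(kfold_cv(sets$binary, pipe, folds = 200), "smaller")
})

test_that("multiclass accuracy equals the weighted mean of sensitivities", {
  g <- generate(synthetic_spec(n_classes = 3, n_per_class = 12, seed = 63))
  pipe <- svm_pipeline(encoder_config("CKSAAP", k_max = 1), select_top = 50)
  ev <- kfold_cv(g$dataset, pipe, folds = 4, seed = 2)
  expect_identical(sum(ev$confusion), length(g$dataset))
  counts <- rowSums(ev$confusion)
  expect_equal(ev$acc,
               sum(ev$per_class_sensitivity * counts) / sum(counts),
               tolerance = 1e-12)
  expect_true(all(ev$per_class_sensitivity >= 0 &
                    ev$per_class_sensitivity <= 1))
})

test_that("label-permuted data scores at chance level", {
  withr::local_seed(53)
  g <- generate(synthetic_spec(n_classes = 2, n_per_class = 20,
                               pair_signal_strength = 0,
                               composition_concentration = 1e6, seed = 64))
  d <- g$dataset
  permuted <- apo_dataset(d$ids, d$sequences, labels = sample(d$labels),
                          label_set = d$label_set)
  pipe <- svm_pipeline(encoder_config("DPC"), select_top = 30)
  ev <- kfold_cv(permuted, pipe, folds = 4, seed = 3)
  # within ~3 binomial SE of 0.5 at n = 40
  expect_lt(abs(ev$acc - 0.5), 3 * sqrt(0.25 / length(permuted)) + 0.05)
})

test_that("fold-internal selection differs from leak-prone full-data
           selection on pure noise", {
  withr::local_seed(54)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 1000), ncol = 1000,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:1000)))
  folds <- rep(1:4, length.out = n)
  acc <- function(select_on_fold) {
    correct <- 0
    for (f in 1:4) {
      tr <- folds != f
      ranked <- if (select_on_fold) anova_rank(X[tr, ], y[tr])
                else anova_rank(X, y)
      feats <- ranked$feature_names[1:10]
      m <- apofam:::fixed_train(X[tr, feats], y[tr])
      correct <- correct + sum(predict(m, X[!tr, feats])$labels == y[!tr])
    }
    correct / n
  }
  leaky <- acc(FALSE)
  clean <- acc(TRUE)
  # the leak-prone oracle is optimistic on noise; the correct procedure
  # stays near chance
  expect_gt(leaky, clean)
  expect_lt(clean, 0.7)
  expect_gt(leaky, 0.75)
})

test_that("evaluation reports serialize with ROC sidecar", {
  withr::local_seed(55)
  scores <- c(rnorm(20, 1), rnorm(20))
  truth <- rep(c("apo", "non-apo"), each = 20)
  r <- roc_auc(scores, truth)
  ev <- structure(list(folds = 2L, seed = 1L,
                       confusion = table(truth, truth),
                       sn = 0.9, sp = 0.8, acc = 0.85, mcc = 0.7,
                       auc = r$auc, roc_points = r$roc_points),
                  class = "apo_eval")
  js <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_eval(ev, js, roc_tsv = tsv)
  got <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(got$auc, r$auc)
  roc_tab <- read.delim(tsv)
  expect_identical(names(roc_tab), c("fpr", "tpr"))
})
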