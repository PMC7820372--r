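# Two-class blobs with controllable separation, as plain feature matrices.
make_blobs <- function(n_per_class = 20, d = 5, sep = 4, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("a", "b"), each = n_per_class)
    X <- matrix(rnorm(2 * n_per_class * d), ncol = d)
    X[y == "b", 1:2] <- X[y == "b", 1:2] + sep
    colnames(X) <- paste0("f", seq_len(d))
    rownames(X) <- sprintf("s%02d", seq_along(y))
    list(X = X, y = y)
  })
}

test_that("grid search solves separable data and respects its grids", {
  b <- make_blobs(sep = 6)
  m <- grid_search_train(b$X, b$y, c_grid = c(1, 8), width_grid = c(0.05, 0.5),
                         cv_folds = 4, seed = 1)
  expect_s3_class(m, "apofam_tier")
  expect_equal(m$cv_accuracy, 1)
  expect_true(m$cost %in% c(1, 8))
  expect_true(m$kernel_width %in% c(0.05, 0.5))
  p <- predict(m, b$X)
  expect_identical(p$labels, b$y)
  # determinism: same seed and inputs pick the same hyperparameters
  m2 <- grid_search_train(b$X, b$y, c_grid = c(1, 8),
                          width_grid = c(0.05, 0.5), cv_folds = 4, seed = 1)
  expect_identical(m2$cost, m$cost)
  expect_identical(m2$kernel_width, m$kernel_width)
  expect_identical(predict(m2, b$X)$scores, p$scores)
  expect_error(grid_search_train(b$X, rep("a", nrow(b$X))), "2 classes")
  expect_error(grid_search_train(b$X, b$y, c_grid = c(-1, 1)), "positive")
})

test_that("conflicting labels on identical rows cap accuracy at the prior", {
  X <- matrix(1, nrow = 20, ncol = 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c("a", "b"), times = c(14, 6))
  m <- grid_search_train(X, y, c_grid = c(1), width_grid = c(0.1),
                         cv_folds = 4, seed = 1)
  expect_lte(m$cv_accuracy, 14 / 20)
})

test_that("prediction aligns features by name and permutes with samples", {
  b <- make_blobs(seed = 3)
  m <- grid_search_train(b$X, b$y, c_grid = 2, width_grid = 0.2,
                         cv_folds = 3, seed = 1)
  shuffled <- b$X[, c(3, 1, 5, 2, 4)]
  expect_identical(predict(m, shuffled)$labels, predict(m, b$X)$labels)
  perm <- withr::with_seed(4, sample(nrow(b$X)))
  expect_identical(predict(m, b$X[perm, ])$labels,
                   predict(m, b$X)$labels[perm])
  expect_error(predict(m, b$X[, 1:3]), "missing required feature")
})

test_that("binary decision scores are oriented towards the positive class", {
  b <- make_blobs(sep = 6, seed = 5)
  y <- ifelse(b$y == "a", "apo", "non-apo")
  m <- grid_search_train(b$X, y, c_grid = 2, width_grid = 0.2,
                         cv_folds = 3, seed = 1)
  p <- predict(m, b$X)
  expect_true(all(p$scores[p$labels == "apo"] > 0))
  expect_true(all(p$scores[p$labels == "non-apo"] < 0))
})

test_that("refitting with recorded hyperparameters reproduces predictions", {
  b <- make_blobs(seed = 6, sep = 3)
  m <- grid_search_train(b$X, b$y, c_grid = c(0.5, 2, 8),
                         width_grid = c(0.02, 0.2), cv_folds = 4, seed = 9)
  probe <- make_blobs(seed = 7, sep = 3)
  m2 <- grid_search_train(b$X, b$y, c_grid = m$cost,
                          width_grid = m$kernel_width,
                          cv_folds = m$provenance$cv_folds,
                          seed = m$provenance$seed)
  expect_identical(predict(m2, probe$X)$labels, predict(m, probe$X)$labels)
  expect_equal(predict(m2, probe$X)$scores, predict(m, probe$X)$scores)
})

test_that("the fitted two-tier model gates subfamily calls on tier 1", {
  sets <- generate_two_tier(
    synthetic_spec(n_classes = 3, n_per_class = 12, label_prefix = "pos",
                   seed = 31),
    synthetic_spec(n_classes = 1, n_per_class = 30, label_prefix = "neg",
                   seed = 32),
    subfamily_labels = c("ApoA", "ApoB", "ApoC"))
  fit <- apofam(sets$binary, sets$subfamily, selection = "topn",
                n_features = 40, grid_search = FALSE, cv_folds = 3)
  expect_s3_class(fit, "apofam")
  pred <- predict(fit, sets$binary)
  neg <- pred$tier1_label == "non-apo"
  expect_true(all(is.na(pred$subfamily[neg])))
  pos <- pred$tier1_label == "apo"
  expect_true(all(pred$subfamily[pos] %in% fit$tier2$label_set))
  # empty input gives an empty report with the full column set
  empty <- predict(fit, apo_dataset(character(0), character(0)))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("id", "tier1_label", "subfamily") %in% colnames(empty)))
  # per-record encoding failure is reported without aborting the rest
  mixed <- apo_dataset(c("good", "bad"),
                       c(sets$binary$sequences[1], strrep("A", 5)))
  res <- predict(fit, mixed)
  expect_true(is.na(res$error[1]))
  expect_false(is.na(res$error[2]))
  expect_false(is.na(res$tier1_label[1]))
  # character input is accepted
  res2 <- predict(fit, sets$binary$sequences[1:2])
  expect_identical(nrow(res2), 2L)
})

test_that("strongly separated synthetic positives are flagged and models
           round-trip through serialization", {
  sets <- generate_two_tier(
    synthetic_spec(n_classes = 3, n_per_class = 12, label_prefix = "pos",
                   seed = 33),
    synthetic_spec(n_classes = 1, n_per_class = 36, label_prefix = "neg",
                   seed = 34),
    subfamily_labels = c("ApoA", "ApoB", "ApoC"))
  fit <- apofam(sets$binary, sets$subfamily, selection = "topn",
                n_features = 40, grid_search = FALSE, cv_folds = 3)
  pred <- predict(fit, sets$subfamily)
  expect_gte(mean(pred$tier1_label == "apo"), 0.95)
  stem <- file.path(withr::local_tempdir(), "model")
  write_model(fit, stem)
  expect_true(file.exists(paste0(stem, ".json")))
  env <- jsonlite::read_json(paste0(stem, ".json"))
  expect_identical(env$class, "apofam")
  expect_identical(length(env$tier1$selected_features),
                   length(fit$tier1$selected_features))
  back <- read_model(stem)
  expect_identical(predict(back, sets$subfamily), pred)
})
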