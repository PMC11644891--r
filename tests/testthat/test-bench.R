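test_that("report arithmetic reproduces the published-style counts", {
  r <- class_report(c(18L, 10L, 28L), c(18L, 11L, 30L))
  expect_equal(round(r$rank_accuracy, 2), c(100.00, 90.91, 93.33))
  expect_equal(round(r$total_accuracy, 2), 94.92)
  # perfect predictor
  r <- class_report(c(18L, 11L, 30L), c(18L, 11L, 30L))
  expect_equal(r$rank_accuracy, c(100, 100, 100))
  expect_equal(r$total_accuracy, 100)
  # degenerate all-level-1 predictor on the same composition
  r <- class_report(c(18L, 0L, 0L), c(18L, 11L, 30L))
  expect_equal(round(r$total_accuracy, 2), 30.51)
  expect_error(class_report(c(5, 3), c(4, 3)), "correct <= total")
})

test_that("overall accuracy equals pooled per-level counts on random tables", {
  set.seed(77)
  for (i in 1:50) {
    total <- sample(1:40, 3, replace = TRUE)
    correct <- vapply(total, function(t) sample(0:t, 1), integer(1))
    r <- class_report(correct, total)
    expect_equal(r$total_accuracy, 100 * sum(correct) / sum(total))
    expect_equal(r$rank_accuracy, 100 * correct / total)
  }
})

test_that("the bench fits all eight learners and is deterministic", {
  co <- normalize_cohort(simulate_cohort(seed = 5))
  b1 <- stress_bench(co, seed = 5, gbdt_trees = 40L, rf_trees = 150L,
                     xgb_rounds = 30L)
  expect_length(b1$models, 8L)
  p1 <- predict(b1, co$features[co$test_idx, ])
  expect_true(all(p1 %in% 1:3))
  b2 <- stress_bench(co, seed = 5, gbdt_trees = 40L, rf_trees = 150L,
                     xgb_rounds = 30L)
  p2 <- predict(b2, co$features[co$test_idx, ])
  expect_identical(p1, p2)
  reps <- evaluate_bench(b1, co)
  expect_named(reps, c("GaussianNB", "PAC", "NC", "KNN", "RF", "SVC",
                       "GBDT", "XGB"))
  tab <- report_table(reps)
  expect_equal(nrow(tab), 24L)
})

test_that("single-level training data are rejected", {
  f <- matrix(runif(60 * 7), ncol = 7, dimnames = list(NULL, c(
    "HR", "MR", "SDNN", "RMSSD", "pNN50", "CV", "TO")))
  co <- labeled_cohort(f, rep(1:3, 20), 1:54, 55:60)
  co$labels[co$train_idx] <- 1L       # degrade after construction
  expect_error(stress_bench(co, algorithms = "NC"), "single stress level")
})

test_that("SVM grid search solves separable and ring geometries", {
  set.seed(21)
  # linearly separable 2-feature toy data
  x <- rbind(cbind(rnorm(30, 0, 0.3), rnorm(30, 0, 0.3)),
             cbind(rnorm(30, 3, 0.3), rnorm(30, 3, 0.3)),
             cbind(rnorm(30, 0, 0.3), rnorm(30, 6, 0.3)))
  y <- rep(1:3, each = 30)
  gs <- grid_search_svm(x, y, folds = 3)
  expect_equal(mean(predict(gs$model, x) == y), 1)
  # concentric rings: a radial kernel must win over linear
  th <- runif(200, 0, 2 * pi)
  r <- rep(c(0.5, 2.5), each = 100)
  xr <- cbind(r * cos(th), r * sin(th)) + matrix(rnorm(400, 0, 0.1), ncol = 2)
  yr <- rep(c(1, 2), each = 100)
  gs <- grid_search_svm(xr, yr, kernels = c("linear", "radial"), folds = 3)
  expect_equal(gs$kernel, "radial")
  # determinism of the selection
  gs2 <- grid_search_svm(xr, yr, kernels = c("linear", "radial"), folds = 3)
  expect_equal(gs$grid$cv_accuracy, gs2$grid$cv_accuracy)
  expect_equal(gs$kernel, gs2$kernel)
})

test_that("all learners solve the widely separated cohort", {
  co <- normalize_cohort(simulate_cohort(
    separated_model(counts = c(40L, 40L, 40L),
                    test_counts = c(12L, 12L, 12L)), seed = 9))
  b <- stress_bench(co, seed = 9, gbdt_trees = 60L, rf_trees = 200L,
                    xgb_rounds = 40L, svm_folds = 3L)
  reps <- evaluate_bench(b, co)
  for (a in names(reps))
    expect_gte(reps[[a]]$total_accuracy, 95)
})
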