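test_that("confusion counts follow the four definitions", {
  cc <- confusion(c("F", "F", "A", "A"), c("F", "A", "F", "A"), positive = "F")
  expect_equal(as.numeric(cc), c(1, 1, 1, 1))
  cc2 <- confusion(c("F", "A"), c("F", "A"), positive = "F")
  expect_equal(cc2$FP + cc2$FN, 0)
  expect_equal(rowSums(confusion(character(), character())), c(0),
               ignore_attr = TRUE)
  expect_error(confusion("F", c("F", "A")), "lengths differ")
})

test_that("binary metrics reproduce the worked example", {
  m <- binary_metrics(tibble::tibble(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 9 / 11, tolerance = 1e-12)
  expect_equal(m$f1, 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11), tolerance = 1e-12)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$maa, (0.9 + 0.8) / 2)

  perfect <- binary_metrics(tibble::tibble(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_true(all(perfect[c("accuracy", "sensitivity", "specificity",
                            "precision", "f1", "maa")] == 1))

  flagged <- binary_metrics(tibble::tibble(TP = 0, FN = 3, TN = 4, FP = 0))
  expect_equal(flagged$precision, 0)
  expect_equal(flagged$f1, 0)
  expect_match(flagged$undefined, "precision")
  expect_error(binary_metrics(tibble::tibble(TP = 0, FN = 0, TN = 0, FP = 0)),
               "no evaluated")
})

test_that("metric identities hold on enumerated counts", {
  grid <- expand.grid(TP = 0:3, TN = 0:3, FP = 0:3, FN = 0:3)
  grid <- grid[rowSums(grid) > 0, ]
  for (i in seq_len(nrow(grid))) {
    m <- binary_metrics(grid[i, ])
    total <- sum(grid[i, ])
    expect_equal(m$accuracy * total, grid$TP[i] + grid$TN[i], tolerance = 1e-12)
    expect_equal(m$maa, (m$sensitivity + m$specificity) / 2, tolerance = 1e-12)
    if (m$sensitivity + m$precision > 0) {
      expect_equal(m$f1, 2 / (1 / m$sensitivity + 1 / m$precision), tolerance = 1e-12)
    }
  }
})

test_that("macro-average accuracy equals the brute-force tally", {
  expect_equal(macro_average_accuracy(c("a", "b", "b", "c", "c", "c", "c"),
                                      c("a", "b", "x", "c", "c", "c", "x"),
                                      c("a", "b", "c")),
               mean(c(1, 0.5, 0.75)))
  withr::with_seed(15, {
    for (i in 1:20) {
      classes <- letters[1:4]
      y <- sample(classes, 60, replace = TRUE)
      while (length(unique(y)) < 4) y <- sample(classes, 60, replace = TRUE)
      p <- sample(classes, 60, replace = TRUE)
      expect_equal(macro_average_accuracy(y, p, classes), oracle_maa(y, p, classes),
                   tolerance = 1e-12)
    }
  })
  # binary identity with sensitivity/specificity
  y <- rep(c("FALL", "ADL"), c(10, 30))
  p <- withr::with_seed(3, sample(c("FALL", "ADL"), 40, replace = TRUE))
  m <- binary_metrics(confusion(y, p))
  expect_equal(macro_average_accuracy(y, p), m$maa, tolerance = 1e-12)
  expect_error(macro_average_accuracy("a", "a", c("a", "b")), "never occurs")
})

test_that("fold plans partition rows; loso folds isolate subjects", {
  ft <- small_event_features()
  p5 <- make_folds(ft, "kfold", k = 5, seed = 1)
  expect_equal(sort(unlist(p5$test)), seq_len(nrow(ft)))
  expect_true(max(lengths(p5$test)) - min(lengths(p5$test)) <= 1)
  expect_identical(make_folds(ft, "kfold", k = 5, seed = 1)$test, p5$test)
  expect_false(identical(make_folds(ft, "kfold", k = 5, seed = 2)$test, p5$test))

  pl <- make_folds(ft, "loso")
  expect_equal(nrow(pl), length(unique(ft$subject_id)))
  for (i in seq_len(nrow(pl))) {
    subj <- unique(ft$subject_id[pl$test[[i]]])
    expect_length(subj, 1)
    expect_false(subj %in% ft$subject_id[pl$train[[i]]])
  }
  expect_silent(audit_fold_plan(pl, ft))
  expect_error(make_folds(ft, "kfold", k = 1), "k")
})

test_that("audit catches leakage", {
  ft <- small_event_features()
  plan <- make_folds(ft, "kfold", k = 4, seed = 1)
  broken <- plan
  broken$test[[1]] <- broken$test[[1]][-1]
  expect_error(audit_fold_plan(broken, ft), "partition")
  ft2 <- ft
  ft2$subject_id[plan$test[[2]][1]] <- "synthetic"
  expect_error(audit_fold_plan(plan, ft2), "synthetic")
})

test_that("run_cv evaluates each fold with SMOTE confined to training", {
  ft <- small_event_features()
  plan <- make_folds(ft, "kfold", k = 4, seed = 2)
  cv <- run_cv(ft, plan, model_spec("knn"), seed = 2)
  expect_equal(nrow(cv$folds), 4)
  # balanced training: n_train = 2 * majority count within the training fold
  for (i in 1:4) {
    tr_lab <- ft$label[plan$train[[i]]]
    expect_equal(cv$folds$n_train[i], 2L * max(table(tr_lab)))
  }
  expect_equal(sum(cv$folds$n_test), nrow(ft))
  expect_equal(cv$pooled$TP + cv$pooled$FN, sum(ft$label == "FALL"))
  g <- glance(cv)
  expect_equal(g$n_folds, 4)
  t <- tidy(cv)
  expect_true(all(c("fold", "accuracy", "sensitivity") %in% names(t)))
})

test_that("the OR rule flags a sample iff any window is positive", {
  expect_equal(or_rule_sample_label(c("ADL", "ADL", "FALL")), "FALL")
  expect_equal(or_rule_sample_label(c("ADL", "ADL")), "ADL")
  expect_equal(or_rule_sample_label("FALL"), "FALL")
  expect_error(or_rule_sample_label(character()), ">= 1")
})
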