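#' Confusion counts for a binary task
#'
#' TP: predicted positive, truly positive. TN: predicted negative, truly
#' negative. FP: predicted positive, truly negative. FN: predicted
#' negative, truly positive.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive the positive (fall) class label.
#' @return a one-row tibble with columns `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred, positive = "FALL") {
  if (length(y_true) != length(y_pred)) abort_usage("y_true and y_pred lengths differ")
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tibble::tibble(TP = tp, TN = tn, FP = fp, FN = fn)
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Binary detection metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, F1 (harmonic mean of sensitivity
#' and precision) and macro-average accuracy (the unweighted mean of
#' per-class accuracies, which for a binary task is
#' `(sensitivity + specificity)/2`). A ratio with a zero denominator is
#' reported as 0 and flagged in the `undefined` column.
#'
#' @param counts a one-row tibble from [confusion()] (or anything with
#'   columns TP, TN, FP, FN).
#' @return a one-row tibble of metrics plus the counts and an `undefined`
#'   character column naming flagged ratios (empty string if none).
#' @export
binary_metrics <- function(counts) {
  tp <- counts$TP[1]; tn <- counts$TN[1]; fp <- counts$FP[1]; fn <- counts$FN[1]
  total <- tp + tn + fp + fn
  if (total == 0) abort_usage("no evaluated items (all counts zero)")
  undef <- character()
  if (tp + fn == 0) undef <- c(undef, "sensitivity")
  if (tn + fp == 0) undef <- c(undef, "specificity")
  if (tp + fp == 0) undef <- c(undef, "precision")
  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  prec <- safe_ratio(tp, tp + fp)
  f1 <- if (sens + prec == 0) {
    undef <- c(undef, "f1"); 0
  } else 2 * sens * prec / (sens + prec)
  tibble::tibble(
    accuracy = (tp + tn) / total, sensitivity = sens, specificity = spec,
    precision = prec, f1 = f1, maa = (sens + spec) / 2,
    TP = tp, TN = tn, FP = fp, FN = fn,
    undefined = paste(undef, collapse = ",")
  )
}

#' Macro-average accuracy over arbitrary classes
#'
#' The unweighted arithmetic mean of per-class accuracies
#' `TP_a / T_a`, where `T_a` counts true occurrences of class `a` and
#' `TP_a` the correct predictions among them. Every class in `classes`
#' must occur at least once in `y_true`.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes label set; defaults to the classes present in `y_true`.
#' @return a single fraction in `[0, 1]`.
#' @export
macro_average_accuracy <- function(y_true, y_pred, classes = sort(unique(y_true))) {
  if (length(y_true) != length(y_pred)) abort_usage("y_true and y_pred lengths differ")
  if (!all(y_true %in% classes)) abort_usage("y_true contains labels outside classes")
  acc <- vapply(classes, function(a) {
    ta <- sum(y_true == a)
    if (ta == 0) abort_usage(sprintf("class '%s' never occurs in y_true", a))
    sum(y_true == a & y_pred == a) / ta
  }, numeric(1))
  mean(acc)
}

#' Build a cross-validation fold plan
#'
#' `kfold` shuffles rows with the seed and splits them into `k` test folds
#' as evenly as possible; `loso` (leave-one-subject-out) makes one fold
#' per subject, whose rows never appear in that fold's training set —
#' measuring performance on unseen wearers.
#'
#' @param features a feature tibble (needs `subject_id` for loso).
#' @param mode `"kfold"` or `"loso"`.
#' @param k number of folds for kfold.
#' @param seed shuffle seed (kfold).
#' @return a `fold_plan`: a tibble with columns `fold`, `train`, `test`
#'   (list-columns of row indices), plus `subject` for loso.
#' @export
make_folds <- function(features, mode = c("kfold", "loso"), k = 5, seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(features)
  if (mode == "kfold") {
    if (k < 2 || k > n) abort_usage("kfold needs 2 <= k <= number of rows")
    perm <- withr::with_seed(seed, sample.int(n))
    # even split: fold sizes differ by at most one
    sizes <- diff(floor(seq(0, n, length.out = k + 1)))
    test_sets <- split(perm, rep(seq_len(k), times = sizes))
    plan <- tibble::tibble(
      fold = seq_len(k),
      test = unname(test_sets),
      train = lapply(test_sets, function(te) setdiff(seq_len(n), te))
    )
  } else {
    if (!"subject_id" %in% names(features)) abort_usage("loso needs a subject_id column")
    subjects <- sort(unique(as.character(features$subject_id)))
    if (length(subjects) < 2L) abort_usage("loso needs >= 2 subjects")
    plan <- tibble::tibble(
      fold = seq_along(subjects),
      subject = subjects,
      test = lapply(subjects, function(s) which(features$subject_id == s)),
      train = lapply(subjects, function(s) which(features$subject_id != s))
    )
  }
  structure(plan, mode = mode, seed = seed, n_rows = n,
            class = c("fold_plan", class(plan)))
}

#' Audit a fold plan against a feature table
#'
#' Checks that test folds partition the rows, that loso test folds are
#' single-subject and subject-disjoint from their training folds, and that
#' no synthetic (SMOTE) row is present in any test fold. Errors on the
#' first violation.
#'
#' @param plan a [make_folds()] plan.
#' @param features the feature tibble the plan indexes.
#' @return `TRUE`, invisibly.
#' @export
audit_fold_plan <- function(plan, features) {
  n <- attr(plan, "n_rows")
  test_all <- sort(unlist(plan$test))
  if (!identical(test_all, seq_len(n))) {
    abort_data("test folds do not partition the rows")
  }
  if ("subject_id" %in% names(features)) {
    for (i in seq_len(nrow(plan))) {
      te <- features$subject_id[plan$test[[i]]]
      if (any(te == "synthetic")) abort_data("synthetic row found in a test fold")
      if (identical(attr(plan, "mode"), "loso")) {
        if (length(unique(te)) != 1L) abort_data("loso test fold spans several subjects")
        if (any(features$subject_id[plan$train[[i]]] == unique(te))) {
          abort_data("loso test subject leaks into its training fold")
        }
      }
    }
  }
  invisible(TRUE)
}

#' Run a cross-validation experiment
#'
#' For each fold: optionally balance the *training* rows with SMOTE (the
#' test fold is never touched, so no synthetic sample can leak), fit the
#' detector, predict the test rows, and score them. Folds whose training
#' set collapses to a single class are skipped with a warning.
#'
#' @param features a feature tibble with `label` (and `subject_id`).
#' @param plan a [make_folds()] plan over `features`.
#' @param spec a [model_spec()].
#' @param smote apply SMOTE balancing inside training folds (default
#'   `TRUE`).
#' @param smote_k SMOTE neighbour count.
#' @param positive positive class label.
#' @param seed root seed for SMOTE and the fit.
#' @return a `cv_result` with per-fold metrics, a summary (mean and sd of
#'   each metric over folds), and the pooled confusion counts.
#' @export
run_cv <- function(features, plan, spec = model_spec(), smote = TRUE,
                   smote_k = 5, positive = "FALL", seed = 1) {
  audit_fold_plan(plan, features)
  fold_rows <- list(); pooled_true <- character(); pooled_pred <- character()
  skipped <- integer()
  for (i in seq_len(nrow(plan))) {
    tr <- features[plan$train[[i]], , drop = FALSE]
    te <- features[plan$test[[i]], , drop = FALSE]
    if (length(unique(tr$label)) < 2L) {
      warning(sprintf("fold %d skipped: single-class training set", plan$fold[i]))
      skipped <- c(skipped, plan$fold[i]); next
    }
    if (isTRUE(smote)) {
      tr <- balance_training_set(tr, k = smote_k, seed = derive_seed(seed, 100L + i))
    }
    model <- fit_detector(tr, spec, positive = positive, seed = derive_seed(seed, 200L + i))
    pred <- predict(model, te)
    m <- binary_metrics(confusion(te$label, pred, positive))
    m$fold <- plan$fold[i]
    m$n_test <- nrow(te)
    m$n_train <- nrow(tr)
    fold_rows[[length(fold_rows) + 1L]] <- m
    pooled_true <- c(pooled_true, te$label)
    pooled_pred <- c(pooled_pred, pred)
  }
  if (length(fold_rows) == 0L) abort_data("every fold was skipped")
  folds <- dplyr::bind_rows(fold_rows)
  metric_names <- c("accuracy", "sensitivity", "specificity", "precision", "f1", "maa")
  summary <- tidyr::pivot_longer(folds[metric_names], dplyr::everything(),
                                 names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(
    folds = folds, summary = summary,
    pooled = binary_metrics(confusion(pooled_true, pooled_pred, positive)),
    spec = spec, mode = attr(plan, "mode"), smote = isTRUE(smote),
    positive = positive, seed = seed, skipped = skipped
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s %s, %d fold(s)%s, SMOTE %s\n",
              x$spec$kind, x$mode, nrow(x$folds),
              if (length(x$skipped)) sprintf(" (%d skipped)", length(x$skipped)) else "",
              if (x$smote) "on" else "off"))
  print(x$summary)
  invisible(x)
}

#' OR-rule aggregation of window labels to a sample label
#'
#' A multi-window sample is labeled positive iff at least one of its
#' windows is — prioritising sensitivity: one detected window suffices to
#' flag the sample.
#'
#' @param window_labels non-empty label vector for one sample's windows.
#' @param positive positive class label.
#' @return `positive` or `"ADL"`.
#' @export
or_rule_sample_label <- function(window_labels, positive = "FALL") {
  if (length(window_labels) == 0L) abort_usage("OR rule needs >= 1 window label")
  if (any(window_labels == positive)) positive else "ADL"
}
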