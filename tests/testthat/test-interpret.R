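test_that("sampling Shapley recovers an additive model", {
  f <- function(rows) as.matrix(rows)[, 1] + as.matrix(rows)[, 2]
  # constant background: the estimator is exact for additive models
  bg <- matrix(c(0.5, -0.25), 20, 2, byrow = TRUE,
               dimnames = list(NULL, c("a", "b")))
  x <- c(a = 2, b = 3)
  att <- shapley_attributions(f, x, bg, n_perm = 50, seed = 1)
  expect_equal(att$phi$phi[1], 2 - 0.5, tolerance = 1e-12)
  expect_equal(att$phi$phi[2], 3 - (-0.25), tolerance = 1e-12)
  expect_true(all(att$phi$mc_error < 1e-9))
  g <- glance(att)
  expect_lt(g$efficiency_gap, 1e-9)
})

test_that("estimates agree with exact subset-enumeration Shapley", {
  withr::with_seed(2, {
    W <- rnorm(6)
    bg <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(NULL, letters[1:6]))
    x <- stats::setNames(rnorm(6), letters[1:6])
  })
  # non-additive toy model with interactions
  f <- function(rows) {
    M <- as.matrix(rows)
    as.numeric(M %*% W) + 0.5 * M[, 1] * M[, 2] + tanh(M[, 3])
  }
  exact <- oracle_exact_shapley(f, x, bg)
  att <- shapley_attributions(f, x, bg, n_perm = 4000, seed = 3)
  expect_equal(att$phi$phi, unname(exact), tolerance = 0.05)
  # and efficiency holds exactly for the exact values
  expect_equal(sum(exact), f(matrix(x, 1)) - mean(f(bg)), tolerance = 1e-9)
})

test_that("null players get exactly zero attribution", {
  f <- function(rows) as.matrix(rows)[, 1]^2
  bg <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("used", "ignored")))
  att <- shapley_attributions(f, c(used = 1, ignored = 5), bg, n_perm = 30, seed = 4)
  expect_identical(att$phi$phi[att$phi$feature == "ignored"], 0)
})

test_that("symmetric features receive equal attribution within error", {
  f <- function(rows) rowSums(as.matrix(rows))^2
  bg <- matrix(0, 10, 2, dimnames = list(NULL, c("p", "q")))
  att <- shapley_attributions(f, c(p = 1, q = 1), bg, n_perm = 400, seed = 5)
  expect_equal(att$phi$phi[1], att$phi$phi[2],
               tolerance = 4 * sum(att$phi$mc_error) + 1e-9)
})

test_that("efficiency holds within Monte-Carlo tolerance for real detectors", {
  ft <- small_event_features()
  bal <- balance_training_set(ft, seed = 1)
  for (kind in c("knn", "svm")) {
    m <- fit_detector(bal, model_spec(kind), seed = 1)
    fn <- score_function(m)
    fcols <- m$feature_names
    bg <- as.data.frame(ft[ft$label == "ADL", fcols])[1:40, ]
    inst <- ft[ft$label == "FALL", fcols][1, ]
    att <- shapley_attributions(fn, inst, bg, n_perm = 80, seed = 6)
    g <- glance(att)
    tol <- 4 * g$aggregate_mc_error + 4 * sd(fn(bg)) / sqrt(nrow(bg))
    expect_lte(g$efficiency_gap, tol + 1e-9)
  }
})

test_that("attribution is deterministic under a fixed seed", {
  f <- function(rows) rowSums(as.matrix(rows)^2)
  bg <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  x <- c(a = 1, b = -1, c = 0.5)
  a1 <- shapley_attributions(f, x, bg, n_perm = 25, seed = 9)
  a2 <- shapley_attributions(f, x, bg, n_perm = 25, seed = 9)
  expect_identical(a1$phi, a2$phi)
})

test_that("global importance ranks by mean absolute attribution", {
  mk <- function(phis) {
    structure(list(phi = tibble::tibble(feature = names(phis),
                                        value = 0, phi = unname(phis),
                                        mc_error = 0),
                   base_value = 0, fx = sum(phis), n_perm = 1, seed = 1),
              class = "attribution")
  }
  atts <- list(mk(c(SLOP2 = 0.5, m_x1 = 0, sd_z2 = 0)),
               mk(c(SLOP2 = -0.7, m_x1 = 0, sd_z2 = 0.1)))
  imp <- global_importance(atts)
  expect_equal(imp$feature[1], "SLOP2")
  expect_equal(nrow(imp), 3)
  expect_equal(imp$mean_abs_phi[1], 0.6)
  expect_error(global_importance(list()), "at least one")
})

test_that("explanations of synthetic falls are dominated by impact-phase features", {
  ft <- small_event_features()
  bal <- balance_training_set(ft, seed = 1)
  m <- fit_detector(bal, model_spec("knn"), seed = 1)
  falls <- ft[ft$label == "FALL", ][1:5, ]
  ex <- explain_detector(m, falls, ft, n_perm = 60, background_size = 60, seed = 2)
  top5 <- ex$importance$feature[1:5]
  # the fall signature lives in the second (impact) sub-window
  expect_gte(sum(grepl("2$", top5)), 3)
  expect_equal(nrow(ex$long), 5 * 44)
})
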