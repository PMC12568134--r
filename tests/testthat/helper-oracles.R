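# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive every quantity from its definition, not by
# calling the code paths they verify.

# literal transcription of the per-axis statistics
oracle_axis_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  s <- sort(x)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  sdev <- sqrt(sum((x - mu)^2) / n)
  skew <- if (sdev == 0) 0 else sum((x - mu)^3) / n / sdev^3
  kurt <- if (sdev == 0) 0 else sum((x - mu)^4) / n / sdev^4
  c(mean = mu, median = med, sd = sdev, skew = skew, kurt = kurt,
    max = max(x), min = min(x))
}

oracle_slope <- function(x, y, z) {
  sqrt((max(x) - min(x))^2 + (max(y) - min(y))^2 + (max(z) - min(z))^2)
}

# feature vector for the default 3 s / 2 sub-window / 50% scheme at 50 Hz,
# with the sub-window sample bounds hardcoded from their definition
# (two 2 s = 100-sample sub-windows, shifted by 1 s = 50 samples)
oracle_features_3s2sub_50hz <- function(mat) {
  stopifnot(nrow(mat) == 150, ncol(mat) == 3)
  bounds <- list(c(1, 100), c(51, 150))
  out <- numeric(0)
  for (b in bounds) {
    idx <- b[1]:b[2]
    for (stat in 1:7) {
      for (ax in 1:3) out <- c(out, oracle_axis_stats(mat[idx, ax])[stat])
    }
    out <- c(out, oracle_slope(mat[idx, 1], mat[idx, 2], mat[idx, 3]))
  }
  unname(out)
}

# brute-force sliding-window enumerator
oracle_slide_count <- function(n_samples, w_samp, h_samp) {
  count <- 0L
  start <- 0L
  while (start + w_samp <= n_samples) {
    count <- count + 1L
    start <- start + h_samp
  }
  count
}

# brute-force macro-average accuracy
oracle_maa <- function(y_true, y_pred, classes) {
  accs <- c()
  for (a in classes) {
    ta <- 0; hit <- 0
    for (i in seq_along(y_true)) {
      if (y_true[i] == a) {
        ta <- ta + 1
        if (y_pred[i] == a) hit <- hit + 1
      }
    }
    accs <- c(accs, hit / ta)
  }
  mean(accs)
}

# exact Shapley values by subset enumeration with background imputation:
# value(S) = mean over background rows of f(row with S set to x)
oracle_exact_shapley <- function(f, x, background) {
  B <- as.matrix(background)
  d <- length(x)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), d))
  val <- function(S) {
    Z <- B
    for (j in which(S)) Z[, j] <- x[j]
    colnames(Z) <- names(x)
    mean(f(Z))
  }
  vals <- apply(subsets, 1L, function(S) val(as.logical(S)))
  phi <- numeric(d)
  for (j in seq_len(d)) {
    for (r in seq_len(nrow(subsets))) {
      S <- as.logical(subsets[r, ])
      if (S[j]) next
      s <- sum(S)
      w <- factorial(s) * factorial(d - s - 1) / factorial(d)
      Sj <- S; Sj[j] <- TRUE
      key_with <- sum(Sj * 2^(seq_len(d) - 1)) + 1
      key_without <- sum(S * 2^(seq_len(d) - 1)) + 1
      phi[j] <- phi[j] + w * (vals[key_with] - vals[key_without])
    }
  }
  names(phi) <- names(x)
  phi
}

# random test trace: white noise within the sensor range
random_trace <- function(n = 150, rate = 50, seed = 1, scale = 0.8) {
  withr::with_seed(seed, {
    triaxial_trace(stats::rnorm(n, 0, scale) |> pmin(2) |> pmax(-2),
                   stats::rnorm(n, 0, scale) |> pmin(2) |> pmax(-2),
                   stats::rnorm(n, 0.3, scale) |> pmin(2) |> pmax(-2),
                   rate = rate, range_g = 2)
  })
}

# memoised small synthetic dataset shared across test files
.fixtures <- new.env(parent = emptyenv())
small_event_features <- function() {
  if (is.null(.fixtures$feats)) {
    cfg <- synthetic_config(n_subjects = 4, falls_per_subject = 8,
                            adls_per_subject = 24, seed = 11)
    ev <- gen_event_dataset(cfg)
    .fixtures$events <- ev
    .fixtures$feats <- extract_features(ev)
  }
  .fixtures$feats
}
small_event_dataset <- function() {
  invisible(small_event_features())
  .fixtures$events
}
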