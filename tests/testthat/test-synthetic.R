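test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_subjects = 2, falls_per_subject = 2,
                          adls_per_subject = 4, seed = 9)
  expect_identical(gen_fall_window(cfg, 1, 7), gen_fall_window(cfg, 1, 7))
  expect_identical(gen_adl_window(cfg, "walk", 2, 7), gen_adl_window(cfg, "walk", 2, 7))
  d1 <- gen_event_dataset(cfg); d2 <- gen_event_dataset(cfg)
  expect_identical(d1, d2)
  r1 <- gen_continuous_recording(cfg, 30, 1, seed = 3)
  r2 <- gen_continuous_recording(cfg, 30, 1, seed = 3)
  expect_identical(r1, r2)
  expect_false(identical(gen_fall_window(cfg, 1, 7), gen_fall_window(cfg, 1, 8)))
})

test_that("fall windows have the two-phase amplitude ordering", {
  cfg <- synthetic_config(seed = 5)
  for (s in 1:20) {
    tr <- gen_fall_window(cfg, subject = (s %% 5) + 1, seed = 200 + s)
    dyn <- sqrt(tr$x^2 + tr$y^2 + tr$z^2) - 1  # deviation from resting 1 g
    rms <- function(v) sqrt(mean(v^2))
    expect_gt(rms(dyn[76:150]), rms(dyn[1:75]))
    expect_lte(max(abs(c(tr$x, tr$y, tr$z))), cfg$range_g)
    expect_equal(nrow(tr), 150)
  }
})

test_that("ADL subtypes match their construction", {
  cfg <- synthetic_config(seed = 5)
  still <- gen_adl_window(cfg, "lie_still", 1, 31)
  expect_lte(max(sd(still$x), sd(still$y), sd(still$z)), 3 * cfg$noise_sd_g)

  # walking is periodic at ~2 Hz: periodogram argmax of the demeaned magnitude
  walk <- gen_adl_window(cfg, "walk", 1, 32)
  mag <- sqrt(walk$x^2 + walk$y^2 + walk$z^2)
  sp <- stats::spec.pgram(mag - mean(mag), plot = FALSE, taper = 0)
  f_peak <- sp$freq[which.max(sp$spec)] * 50
  expect_lt(abs(f_peak - 2), 0.5)

  # sit-down spike stays below the fall impact amplitude
  for (s in 1:10) {
    sit <- gen_adl_window(cfg, "sit_down", 1, 40 + s)
    mag_sit <- sqrt(sit$x^2 + sit$y^2 + sit$z^2)
    expect_lt(max(mag_sit), 1 + cfg$impact_amp_g)
  }
  expect_error(gen_adl_window(cfg, "swim", 1, 1), "subtype")
})

test_that("event datasets have the configured composition", {
  cfg <- synthetic_config(n_subjects = 3, falls_per_subject = 4,
                          adls_per_subject = 12, seed = 13)
  ds <- gen_event_dataset(cfg)
  expect_equal(nrow(ds), 3 * 16)
  expect_equal(sum(ds$label == "FALL"), 12)
  expect_equal(unname(table(ds$subject_id)), rep(16L, 3), ignore_attr = TRUE)
  expect_true(all(vapply(ds$trace, nrow, integer(1)) == 150))
  ft <- extract_features(ds)
  expect_equal(dim(ft), c(48, 46))  # 44 features + label + subject_id
})

test_that("continuous recordings carry valid annotations at the stated length", {
  cfg <- synthetic_config(seed = 13)
  rec <- gen_continuous_recording(cfg, duration_s = 90, n_falls = 2, seed = 6)
  expect_equal(nrow(rec), 90 * 50)
  ann <- trace_annotations(rec)
  expect_equal(nrow(ann), 2)
  expect_true(all(ann$start_s >= 0 & ann$end_s <= 90))
  expect_true(all(ann$end_s - ann$start_s == 3))
  r2 <- gen_continuous_recording(cfg, duration_s = 90, n_falls = 2, seed = 7)
  expect_false(identical(trace_annotations(r2)$start_s, ann$start_s))
  expect_error(gen_continuous_recording(cfg, duration_s = 20, n_falls = 5), "pack")
})

test_that("the recording magnitude peak lies inside a fall when spikes are off", {
  cfg <- synthetic_config(adl_mix = c(walk = 0.5, lie_still = 0.3, transition = 0.2),
                          seed = 17)
  for (s in 1:5) {
    rec <- gen_continuous_recording(cfg, duration_s = 60, n_falls = 1, seed = 50 + s)
    ann <- trace_annotations(rec)
    t_peak <- (which.max(sqrt(rec$x^2 + rec$y^2 + rec$z^2)) - 1) / 50
    expect_true(t_peak >= ann$start_s && t_peak <= ann$end_s)
  }
})

test_that("impact features separate falls from quiet ADLs by a wide margin", {
  cfg <- synthetic_config(seed = 19)
  n <- 60
  fall_max <- vapply(1:n, function(s) {
    f <- window_features(gen_fall_window(cfg, (s %% 5) + 1, 300 + s))
    max(f$max_x2, f$max_y2, f$max_z2)
  }, numeric(1))
  adl_max <- vapply(1:n, function(s) {
    f <- window_features(gen_adl_window(cfg, c("lie_still", "walk")[1 + s %% 2],
                                        (s %% 5) + 1, 600 + s))
    max(f$max_x2, f$max_y2, f$max_z2)
  }, numeric(1))
  expect_gt(mean(fall_max) - mean(adl_max), 5 * cfg$noise_sd_g)
})

test_that("rate and range overrides emulate sensor heterogeneity", {
  cfg <- synthetic_config(seed = 23)
  rec20 <- gen_continuous_recording(cfg, duration_s = 30, n_falls = 1, seed = 2,
                                    rate = 20)
  expect_equal(trace_rate(rec20), 20)
  expect_equal(nrow(rec20), 600)
  up <- resample_trace(rec20, 50, "linear")
  expect_equal(trace_rate(up), 50)
  expect_equal(trace_annotations(up), trace_annotations(rec20))
})
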