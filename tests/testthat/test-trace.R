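test_that("trace construction validates axes, range and annotations", {
  tr <- triaxial_trace(c(0, 0.1, 0.2, 0.1), c(0, 0, 0, 0), c(1, 1, 1, 1), rate = 50)
  expect_equal(nrow(tr), 4)
  expect_equal(trace_duration(tr), 0.08)
  expect_error(triaxial_trace(1:3, 1:3, 1:2, rate = 50), "identical length")
  expect_error(triaxial_trace(0, 0, 3, rate = 50, range_g = 2), "range")
  expect_error(
    triaxial_trace(rep(0, 50), rep(0, 50), rep(1, 50), rate = 50,
                   annotations = data.frame(start_s = 0.5, end_s = 0.2)),
    "start >= end")
})

test_that("write/read round-trips samples, rate and annotations", {
  dir <- withr::local_tempdir()
  tr <- gen_continuous_recording(synthetic_config(seed = 3), duration_s = 20,
                                 n_falls = 1, seed = 5)
  path <- file.path(dir, "trace.csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(trace_rate(back), trace_rate(tr))
  expect_equal(back$x, tr$x, tolerance = 1e-9)
  expect_equal(back$y, tr$y, tolerance = 1e-9)
  expect_equal(back$z, tr$z, tolerance = 1e-9)
  expect_equal(trace_annotations(back)$start_s, trace_annotations(tr)$start_s,
               tolerance = 1e-9)
  expect_error(write_trace(tr, file.path(dir, "no/such/dir/x.csv")))
})

test_that("time_xyz dialect infers the rate and rejects ragged grids", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.csv")
  writeLines(c("t,x,y,z", "0,0,0,1", "0.02,0.1,0,1", "0.04,0.2,0,1"), p)
  tr <- read_trace(p)
  expect_equal(trace_rate(tr), 50)
  writeLines(c("t,x,y,z", "0,0,0,1", "0.02,0.1,0,1", "0.05,0.2,0,1"), p)
  expect_error(read_trace(p), "uniform")
})

test_that("a non-numeric cell is reported with its line number", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.csv")
  writeLines(c("x,y,z", "0,0,1", "oops,0,1", "0,0,1"), p)
  expect_error(read_trace(p, rate_hint = 50), "line 3")
})

test_that("xyz dialect requires a rate", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "r.csv")
  writeLines(c("x,y,z", "0,0,1", "0,0,1"), p)
  expect_error(read_trace(p), "rate_hint")
  expect_equal(trace_rate(read_trace(p, rate_hint = 20)), 20)
})

test_that("decimation keeps every ratio-th sample from index 0", {
  tr <- triaxial_trace(1:10 / 10, rep(0, 10), rep(1, 10), rate = 100)
  out <- resample_trace(tr, 50, "decimate")
  expect_equal(trace_rate(out), 50)
  expect_equal(out$x, (1:10 / 10)[c(1, 3, 5, 7, 9)])
  expect_error(resample_trace(tr, 30, "decimate"), "linear")
  # duration shrinks by at most one source sample period
  expect_lte(abs(trace_duration(out) - trace_duration(tr)), 1 / 100 + 1e-12)
})

test_that("linear resampling is exact on affine signals", {
  tt <- (0:39) / 20
  tr <- triaxial_trace(tt, 2 * tt - 1, rep(0.5, 40), rate = 20, range_g = 6)
  out <- resample_trace(tr, 50, "linear")
  tnew <- (seq_len(nrow(out)) - 1) / 50
  expect_equal(out$x, tnew, tolerance = 1e-9)
  expect_equal(out$y, 2 * tnew - 1, tolerance = 1e-9)
  expect_equal(out$z, rep(0.5, nrow(out)), tolerance = 1e-9)
})

test_that("87 Hz -> 50 Hz linear resampling has the grid-derived length", {
  tr <- random_trace(870, rate = 87, seed = 7)
  out <- resample_trace(tr, 50, "linear")
  expect_equal(nrow(out), floor((869 / 87) * 50) + 1)
})

test_that("clip_range clamps, is idempotent, and tightens monotonically", {
  tr <- triaxial_trace(c(3.1, 0.4), c(-2.5, 0), c(0.4, 1), rate = 50, range_g = 6)
  c2 <- clip_range(tr, 2)
  expect_equal(c2$x, c(2, 0.4))
  expect_equal(c2$y, c(-2, 0))
  expect_equal(c2$z, c(0.4, 1))
  expect_equal(as.data.frame(clip_range(c2, 2)), as.data.frame(c2))
  # clip(6) then clip(2) == clip(2)
  expect_equal(as.data.frame(clip_range(clip_range(tr, 6), 2)), as.data.frame(c2))
  expect_equal(attr(c2, "range_g"), 2)
})
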