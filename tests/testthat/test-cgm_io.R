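test_that("glucose_series validates its invariants", {
  gs <- glucose_series(c(5.0, 5.2, 5.1), dt = 300)
  expect_s3_class(gs, "glucose_series")
  expect_length(gs, 3)
  expect_true(all(diff(gs$timestamps) == 300))
  expect_error(glucose_series(5.0), "insufficient")
  expect_error(glucose_series(c(5, -1, 4)), "finite and > 0")
  expect_error(glucose_series(c(5, 6), dt = 0), "dt")
  expect_error(glucose_series(c(5, 6), timestamps = c(10, 10)), "increasing")
})

test_that("read_cgm_csv parses, sorts and collapses duplicates", {
  t0 <- as.numeric(as.POSIXct("2017-06-20 12:00:00", tz = "UTC"))
  path <- tmp_csv(data.frame(timestamp = c(t0, t0 + 300),
                             glucose_mmol_per_L = c(5.0, 5.2)))
  gs <- read_cgm_csv(path)
  expect_length(gs, 2)
  expect_equal(gs$dt, 300)
  expect_equal(gs$values, c(5.0, 5.2))

  # out-of-order rows give the same series as sorted input
  path2 <- tmp_csv(data.frame(timestamp = c(t0 + 300, t0),
                              glucose_mmol_per_L = c(5.2, 5.0)))
  gs2 <- read_cgm_csv(path2, label = gs$label)
  expect_equal(gs2$values, gs$values)
  expect_equal(gs2$timestamps, gs$timestamps)

  # duplicate timestamps collapse by mean
  path3 <- tmp_csv(data.frame(timestamp = c(t0, t0, t0 + 300),
                              glucose_mmol_per_L = c(5.0, 6.0, 5.2)))
  expect_equal(read_cgm_csv(path3)$values, c(5.5, 5.2))

  # ISO-8601 timestamps parse too
  path4 <- tmp_csv(data.frame(timestamp = c("2017-06-20 12:00:00",
                                            "2017-06-20 12:05:00"),
                              glucose_mmol_per_L = c(5.0, 5.2)))
  expect_equal(read_cgm_csv(path4)$dt, 300)
})

test_that("read_cgm_csv rejects bad input", {
  path <- tmp_csv(data.frame(timestamp = 0, glucose_mmol_per_L = 5.0))
  expect_error(read_cgm_csv(path), "insufficient")
  path2 <- tmp_csv(data.frame(when = c(0, 300), value = c(5, 6)))
  expect_error(read_cgm_csv(path2), "format error")
  expect_error(read_cgm_csv(tempfile()), "not found")
})

test_that("write + read round-trips a series", {
  gs <- gen_cgm_trace(n = 100, seed = 7)
  path <- tempfile(fileext = ".csv")
  write_cgm_csv(gs, path)
  back <- read_cgm_csv(path, label = gs$label)
  expect_equal(back$values, gs$values, tolerance = 1e-8)
  expect_equal(back$timestamps, gs$timestamps)
})

test_that("regularize fills short gaps and refuses long ones", {
  gs <- gen_cgm_trace(n = 50, seed = 3)
  # already-uniform series returns identically
  expect_identical(regularize(gs), gs)
  # idempotence
  expect_identical(regularize(regularize(gs)), regularize(gs))

  # one missing interior point: filled by linear interpolation, length + 1
  keep <- setdiff(seq_len(50), 20)
  gapped <- glucose_series(gs$values[keep], dt = 300,
                           timestamps = gs$timestamps[keep])
  fixed <- regularize(gapped, max_gap = 2)
  expect_length(fixed, 50)
  expect_equal(fixed$values[20], mean(gs$values[c(19, 21)]))

  # a 2-hour hole (24 points at 300 s) is a contiguity error naming the gap
  keep2 <- setdiff(seq_len(50), 10:33)
  gapped2 <- glucose_series(gs$values[keep2], dt = 300,
                            timestamps = gs$timestamps[keep2])
  expect_error(regularize(gapped2, max_gap = 2), "contiguity error")
})
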