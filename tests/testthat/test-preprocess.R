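make_rec <- function(x, fs) {
  eeg_recording(tri_channel(x), fs, "s1", "control", "baseline")
}

test_that("config guards its cutoffs", {
  expect_error(preprocess_config(hp_cut = 0), "hp_cut")
  expect_error(preprocess_config(hp_cut = 60, lp_cut = 50), "hp_cut")
  expect_error(preprocess_config(lp_cut = 200, target_fs = 250), "hp_cut")
  expect_silent(preprocess_config())
})

test_that("filtering precedes an exact 1000 -> 250 Hz downsample", {
  set.seed(8)
  rec <- make_rec(rnorm(60 * 1000), fs = 1000)
  out <- bandlimit_resample(rec)
  expect_equal(out$fs, 250)
  expect_equal(ncol(out$data), 60 * 250)

  # a 0.1 Hz drift is crushed by the 1 Hz high-pass
  drift <- make_rec(sin(2 * pi * 0.1 * seq(0, 120, by = 1 / 250)[-1]), fs = 250)
  filt <- bandlimit_resample(drift)
  expect_lt(sqrt(mean(filt$data^2)), 0.05 * sqrt(mean(drift$data^2)))

  # already at target rate: sample count unchanged
  flat <- make_rec(rnorm(10 * 250), fs = 250)
  expect_equal(ncol(bandlimit_resample(flat)$data), 10 * 250)

  expect_error(
    bandlimit_resample(make_rec(rnorm(1000), fs = 80)),
    "Nyquist"
  )
})

test_that("band-limiting is linear", {
  set.seed(3)
  x <- rnorm(5 * 250)
  a <- bandlimit_resample(make_rec(x, 250))
  b <- bandlimit_resample(make_rec(3 * x, 250))
  expect_lt(max(abs(b$data - 3 * a$data)), 1e-6 * sqrt(mean(a$data^2)))
})

test_that("baseline correction subtracts the baseline channel means", {
  x <- make_rec(rnorm(3 * 250) + 3, 250)
  # self-correction leaves zero-mean channels
  self <- baseline_correct(x, x)
  expect_equal(unname(rowMeans(self$data)), rep(0, 3), tolerance = 1e-12)

  # constant arithmetic: 5 - mean(3) = 2
  base <- make_rec(rep(3, 250), 250)
  task <- make_rec(rep(5, 250), 250)
  expect_equal(unname(baseline_correct(task, base)$data[1, 1]), 2)

  # idempotence against a zero-mean baseline
  zero <- make_rec(sin(2 * pi * 10 * seq_len(250) / 250), 250)
  zero$data <- zero$data - rowMeans(zero$data)
  once <- baseline_correct(task, zero)
  expect_equal(baseline_correct(once, zero)$data, once$data)

  bad <- task
  rownames(bad$data) <- c("Fz", "Cz", "Oz")
  bad2 <- try(eeg_recording(bad$data, 250, "s", "control", "speech"), silent = TRUE)
  expect_s3_class(bad2, "try-error") # Pz is mandatory
  mism <- make_rec(rep(1, 250), 250)
  mism$data <- mism$data[c(2, 1, 3), ]
  expect_error(baseline_correct(task, mism), "identical channels")
})

test_that("windowing floors to whole windows and keeps order", {
  rec <- make_rec(seq_len(round(600.5 * 250)), 250)
  w <- window_recording(rec)
  expect_equal(n_windows(w), 600)
  expect_equal(dim(w$windows)[1:2], c(3, 250))
  # order-preserving, contiguous, non-overlapping
  expect_equal(w$windows["Fz", , 2], 251:500)

  expect_error(
    window_recording(make_rec(1:100, 250)),
    "shorter than one window"
  )
})

test_that("time-window partitions slice the documented ranges", {
  long <- as_windows(tri_channel(rep(seq_len(600), each = 250)), condition = "baseline")
  short <- as_windows(tri_channel(rep(seq_len(300), each = 250)), condition = "speech")

  p3 <- time_window_partition(3)
  sel <- select_time_window(long, p3)
  expect_equal(n_windows(sel), 200)
  expect_equal(sel$window_index, 400:599)

  p2 <- time_window_partition(2)
  s2 <- select_time_window(short, p2)
  expect_equal(s2$window_index, 100:299)
  s3 <- select_time_window(short, time_window_partition(3))
  expect_identical(s3$windows, s2$windows) # slices 2 and 3 coincide for speech

  # the three baseline slices are disjoint and exhaustive
  idx <- unlist(lapply(1:3, function(i) {
    select_time_window(long, time_window_partition(i))$window_index
  }))
  expect_equal(sort(idx), 0:599)
  expect_equal(anyDuplicated(idx), 0)

  # every slice has 200 windows for all four conditions
  for (cond in c("baseline", "preparation", "speech", "arithmetic")) {
    n_total <- if (cond %in% c("baseline", "preparation")) 600 else 300
    wrec <- as_windows(tri_channel(rnorm(n_total * 250)), condition = cond)
    for (i in 1:3) {
      expect_equal(n_windows(select_time_window(wrec, time_window_partition(i))), 200)
    }
  }

  too_short <- as_windows(tri_channel(rnorm(100 * 250)), condition = "speech")
  expect_error(select_time_window(too_short, p2), "speech")
  expect_error(time_window_partition(4), "1, 2 or 3")
})

test_that("amplitude rejection drops only offending windows", {
  x <- rnorm(10 * 250)
  x[3 * 250 + 5] <- 500
  w <- as_windows(tri_channel(x))
  kept <- reject_windows(w, threshold_uv = 100)
  expect_equal(n_windows(kept), 9)
  expect_false(3L %in% kept$window_index)
  expect_equal(n_windows(reject_windows(w)), 10) # Inf threshold is a no-op
})
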