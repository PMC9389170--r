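# R-peak detection, beat-series extraction, RR cleaning, window
# resampling and window assembly.

test_that("detector recovers generator beats on clean signal", {
  cfg <- tiny_sim_cfg(duration_s = 90, noise_sd = 0, seed = 11)
  truth <- generate_beats(cfg)
  expect_gte(length(truth$beat_times), 100)
  ecg <- synthesize_ecg(truth, cfg)
  peaks <- detect_r_peaks(ecg)
  det_t <- (peaks - 1) / ecg$fs
  matched <- vapply(truth$beat_times,
                    function(bt) any(abs(det_t - bt) <= 0.05), logical(1))
  d_matched <- vapply(det_t,
                      function(dt) any(abs(truth$beat_times - dt) <= 0.05),
                      logical(1))
  expect_gte(mean(matched), 0.99)     # sensitivity
  expect_gte(mean(d_matched), 0.99)   # positive predictivity
})

test_that("detector returns nothing on a flat signal", {
  expect_identical(detect_r_peaks(ecg_record("z", 100, rep(0, 6000))),
                   integer(0))
})

test_that("detector lands a single QRS on its argmax sample", {
  cfg <- tiny_sim_cfg(duration_s = 10, noise_sd = 0, seed = 2)
  truth <- structure(list(beat_times = 5.0, beat_amplitudes = 1.0,
                          minute_labels = minute_labels("tst", integer(0)),
                          cfg = cfg),
                     class = "ground_truth")
  ecg <- synthesize_ecg(truth, cfg)
  peaks <- detect_r_peaks(ecg)
  expect_length(peaks, 1)
  expect_identical(peaks, which.max(ecg$signal))
})

test_that("beat series extraction computes times, RR and amplitudes", {
  ecg <- ecg_record("b", 100, seq(0, 3.2, length.out = 320))
  # R sample index i corresponds to time (i - 1)/fs
  bs <- extract_beat_series(ecg, c(101L, 201L, 301L))
  expect_equal(bs$times, c(1, 2, 3))
  expect_equal(bs$rr, c(1, 1))
  expect_equal(bs$amp, ecg$signal[c(101, 201, 301)])

  one <- extract_beat_series(ecg, 50L)
  expect_length(one$rr, 0)
  expect_length(one$amp, 1)

  expect_error(extract_beat_series(ecg, c(30L, 20L)), "ascending")
  expect_error(extract_beat_series(ecg, c(1L, 10000L)), "bounds")
})

test_that("beat series RR equals pairwise time differences", {
  set.seed(8)
  ecg <- ecg_record("r", 100, rnorm(5000))
  peaks <- sort(sample(10:4990, 40))
  bs <- extract_beat_series(ecg, peaks)
  expect_equal(bs$rr, diff((peaks - 1) / 100))
})

test_that("RR cleaning leaves physiological series untouched", {
  set.seed(3)
  times <- cumsum(c(1, runif(60, 0.75, 0.95)))
  bs <- beat_series(times, rnorm(61, 1, 0.02))
  out <- clean_rr(bs)
  expect_equal(out$rr, bs$rr)
  expect_equal(out$amp, bs$amp)
})

test_that("RR outliers are replaced by the running median", {
  rr <- rep(0.8, 20)
  rr[10] <- 3.0
  times <- cumsum(c(1, rr))
  amp <- rep(1, 21)
  amp[11] <- 4              # amplitude at the beat carrying the bad RR
  bs <- beat_series(times, amp)
  out <- clean_rr(bs)
  med <- as.numeric(stats::runmed(rr, 5, endrule = "median"))
  expect_equal(out$rr[10], med[10])
  expect_equal(out$rr[-10], rr[-10])
  amed <- as.numeric(stats::runmed(amp, 5, endrule = "median"))
  expect_equal(out$amp[11], amed[11])
})

test_that("RR cleaning handles empty series and bad config", {
  bs <- beat_series(numeric(0), numeric(0))
  expect_length(clean_rr(bs)$rr, 0)
  bs2 <- beat_series(c(1, 2), c(1, 1))
  expect_error(clean_rr(bs2, lo_s = 2, hi_s = 1), "lo_s")
  expect_error(clean_rr(bs2, median_k = 4), "odd")
})

test_that("RR cleaning is idempotent on series with isolated outliers", {
  for (rep in 1:100) {
    bs <- random_beat_series(seed = rep)
    once <- clean_rr(bs)
    twice <- clean_rr(once)
    expect_equal(twice$rr, once$rr)
    expect_equal(twice$amp, once$amp)
  }
})

test_that("window resampling yields 900 points per channel", {
  cfg <- tiny_sim_cfg(duration_s = 360, seed = 5)
  truth <- generate_beats(cfg)
  bs <- beat_series(truth$beat_times, truth$beat_amplitudes)
  ch <- resample_window(bs, 0, 300)
  expect_length(ch$rr_channel, 900)
  expect_length(ch$amp_channel, 900)
})

test_that("resampling is exact on constant series", {
  times <- seq(0.5, 310, by = 1)      # rr exactly 1.0 throughout
  bs <- beat_series(times, rep(0.9, length(times)))
  ch <- resample_window(bs, 0, 300)
  expect_lt(max(abs(ch$rr_channel - 1)), 1e-9)
  expect_lt(max(abs(ch$amp_channel - 0.9)), 1e-9)
})

test_that("resampling reproduces affine RR series", {
  # construct beat times whose RR (attributed to the later beat) lies
  # exactly on rr = a + b * t
  a <- 0.7; b <- 3e-4
  times <- 1
  while (utils::tail(times, 1) < 320) {
    t_next <- (utils::tail(times, 1) + a) / (1 - b)
    times <- c(times, t_next)
  }
  bs <- beat_series(times, rep(1, length(times)))
  ch <- resample_window(bs, 0, 300)
  grid <- seq(0, 300, length.out = 900)
  kt <- times[times >= 0 & times <= 300][-1]
  inside <- grid >= min(kt) & grid <= max(kt)
  expect_gt(sum(inside), 800)
  expect_lt(max(abs(ch$rr_channel[inside] - (a + b * grid[inside]))),
            1e-6)
})

test_that("sparse windows are rejected with a typed condition", {
  bs <- beat_series(c(10, 100, 200), rep(1, 3))
  expect_error(resample_window(bs, 0, 300),
               class = "apnea_sparse_beats")
})

test_that("window assembly drops edge minutes and keeps center labels", {
  cfg <- tiny_sim_cfg(duration_s = 600, seed = 9)
  truth <- generate_beats(cfg)
  bs <- beat_series(truth$beat_times, truth$beat_amplitudes)

  set.seed(21)
  labs10 <- minute_labels("tst", sample(0:1, 10, replace = TRUE))
  w10 <- build_windows(bs, labs10)
  expect_length(w10, 6)
  expect_identical(vapply(w10, `[[`, integer(1), "center_minute"), 2:7)
  for (w in w10)
    expect_identical(w$label, labs10$labels[w$center_minute + 1L])

  labs5 <- minute_labels("tst", rep(0L, 5))
  w5 <- build_windows(bs, labs5)
  expect_length(w5, 1)
  expect_identical(w5[[1]]$center_minute, 2L)

  expect_length(build_windows(bs, minute_labels("tst", rep(0L, 4))), 0)
})

test_that("every emitted window has 900-point channels and binary label", {
  cfg <- tiny_sim_cfg(duration_s = 600,
                      apnea_intervals = list(c(100, 300)), seed = 13)
  truth <- generate_beats(cfg)
  bs <- beat_series(truth$beat_times, truth$beat_amplitudes)
  wins <- build_windows(bs, truth$minute_labels)
  expect_gt(length(wins), 0)
  for (w in wins) {
    expect_length(w$rr_channel, 900)
    expect_length(w$amp_channel, 900)
    expect_true(w$label %in% c(0L, 1L))
  }
})
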