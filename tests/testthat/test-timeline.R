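# Tag correction, pause-based epoch segmentation, duration parameters and
# covariate extraction.

test_that("tag correction widens enclosing units and is idempotent", {
  tags <- tiny_tags()
  # epoch tag lagging the word by 4 ms gets clamped to the word start
  tags$ss[1:2] <- 1.004
  fixed <- correct_tag_order(tags)
  expect_equal(fixed$ss[1], 1.0)
  with(fixed, {
    expect_true(all(ss <= cs & cs <= ws & ws < we & we <= ce & ce <= se))
  })
  # already-consistent tags are untouched; a second pass changes nothing
  expect_identical(correct_tag_order(fixed), fixed)

  # word end after epoch end: epoch end moves out
  tags2 <- tiny_tags()
  tags2$we[3] <- 3.503
  tags2$ce[3] <- 3.503
  fixed2 <- correct_tag_order(tags2)
  expect_equal(fixed2$se[3], 3.503)

  tags3 <- tiny_tags()
  tags3$we[1] <- tags3$ws[1]
  expect_error(correct_tag_order(tags3), "word end")
})

test_that("durations are non-negative after correction on random jitter", {
  set.seed(41)
  for (rep in 1:20) {
    tags <- tiny_tags()
    tags$ss <- tags$ss + runif(3, 0, 0.01)
    tags$cs <- tags$cs + runif(3, 0, 0.01)
    tags$se <- tags$se - runif(3, 0, 0.01)
    tags$ce <- tags$ce - runif(3, 0, 0.01)
    dur <- duration_parameters(correct_tag_order(tags))
    expect_true(all(as.matrix(dur) >= 0))
  }
})

test_that("speech epochs split at pauses of 200 ms or more, inclusively", {
  on <- c(0, 1, 2)
  # gaps of 150 ms: one epoch
  seg <- segment_speech_epochs(on, on + 0.85)
  expect_equal(seg$epoch_id, c(1, 1, 1))
  expect_equal(nrow(seg$epochs), 1)
  # middle gap of 250 ms: two epochs
  seg2 <- segment_speech_epochs(c(0, 1, 2), c(0.85, 1.75, 2.5))
  expect_equal(seg2$epoch_id, c(1, 1, 2))
  # exactly 200 ms is a pause (>= rule)
  seg3 <- segment_speech_epochs(c(0, 1), c(0.8, 1.5))
  expect_equal(seg3$epoch_id, c(1, 2))
  # just under 200 ms is not
  seg4 <- segment_speech_epochs(c(0, 1), c(0.801, 1.5))
  expect_equal(seg4$epoch_id, c(1, 1))
  expect_error(segment_speech_epochs(c(0, 0.5), c(0.6, 1)), "overlapping")
})

test_that("re-segmentation of a generated discourse is stable", {
  st <- tiny_study(13)
  d <- st$discourse
  seg <- segment_speech_epochs(d$ws, d$we)
  expect_equal(seg$epoch_id, d$epoch_id)
  # invariants: intra-epoch gaps < 0.2 s, inter-epoch gaps >= 0.2 s
  gaps <- d$ws[-1] - d$we[-nrow(d)]
  same <- diff(d$epoch_id) == 0
  expect_true(all(gaps[same] < 0.2))
  expect_true(all(gaps[!same] >= 0.2))
})

test_that("duration parameters are exact and translation-invariant", {
  tags <- data.frame(ws = 2.0, we = 2.5, cs = 1.5, ce = 3.0, ss = 1.0,
                     se = 4.0, clause_id = 1, epoch_id = 1)
  dur <- duration_parameters(tags)
  expect_equal(dur$ss_ws, 1000)
  expect_equal(dur$ws_we, 500)
  expect_equal(dur$we_se, 1500)
  expect_equal(dur$cs_ce, 1500)
  expect_equal(dur$ss_cs, 500)
  expect_equal(dur$ce_se, 1000)
  # epoch-initial word and clause == epoch
  tags2 <- data.frame(ws = 1, we = 1.5, cs = 1, ce = 2, ss = 1, se = 2,
                      clause_id = 1, epoch_id = 1)
  dur2 <- duration_parameters(tags2)
  expect_equal(dur2$ss_ws, 0)
  expect_equal(dur2$ss_cs, 0)
  expect_equal(dur2$ce_se, 0)
  # shifting every tag leaves all durations unchanged
  shifted <- tags
  for (cl in c("ws", "we", "cs", "ce", "ss", "se"))
    shifted[[cl]] <- shifted[[cl]] + 11.3
  expect_equal(duration_parameters(shifted), dur)
  # a token outside its epoch is an annotation error
  bad <- tags
  bad$ws <- 0.5
  expect_error(duration_parameters(bad), "outside")
})

test_that("mean intensity averages the trace over the word interval", {
  tr <- data.frame(time = seq(0, 1, by = 0.01), intensity_db = 60)
  expect_equal(mean_intensity(tr, c(0.2, 0.6)), 60)
  # linear ramp: symmetric mean
  tr2 <- data.frame(time = seq(0, 1, length.out = 101),
                    intensity_db = seq(50, 70, length.out = 101))
  expect_equal(mean_intensity(tr2, c(0, 1)), 60)
  expect_true(is.na(mean_intensity(tr, c(2, 3))))
})

test_that("intensity traces derive dB from framed mean square amplitude", {
  fs <- 1000
  audio <- rep(0.5, fs) # constant amplitude, -6.02 dB rel. full scale
  tr <- intensity_trace(audio, fs)
  expect_equal(unique(round(tr$intensity_db, 2)), round(10 * log10(0.25), 2))
})

test_that("EMG band power is measured relative to its own baseline", {
  fs <- 256
  cfg <- spectral_config(fs = fs, f_max = 128)
  # the baseline is one 200-ms window, so a single word carries ~0.2 of
  # baseline-estimation noise; average several independent words to test
  # the closed forms
  set.seed(7)
  v0 <- v2 <- numeric(6)
  for (k in 1:6) {
    emg <- rnorm(20 * fs)
    # stationary noise: word interval indistinguishable from baseline
    v0[k] <- emg_band_rsm(emg, fs, c(8, 8.5), band = c(60, 120), cfg = cfg)
    # doubling the amplitude around the word doubles the band magnitude
    # relative to baseline: log RSM of about log 2
    emg2 <- emg
    idx <- round(7.5 * fs):round(9.5 * fs)
    emg2[idx] <- emg2[idx] * 2
    v2[k] <- emg_band_rsm(emg2, fs, c(8.05, 8.95), band = c(60, 120),
                          cfg = cfg)
  }
  expect_lt(abs(mean(v0)), 0.15)
  expect_equal(mean(v2), log(2), tolerance = 0.15)
  # band above Nyquist is rejected; edge word is missing
  emg <- rnorm(20 * fs)
  expect_error(emg_band_rsm(emg, fs, c(8, 8.5), band = c(60, 200)),
               "Nyquist")
  expect_warning(v <- emg_band_rsm(emg, fs, c(0.5, 1), band = c(60, 120),
                                   cfg = cfg), "edge")
  expect_true(is.na(v))
})
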