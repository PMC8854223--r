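# Spectral pipeline: CAR, Slepian tapers, multitaper spectrograms, trial
# extraction, baseline normalization, and the RSM group test.

test_that("common average reference zeroes the cross-channel mean", {
  set.seed(1)
  x <- matrix(rnorm(4 * 1000), nrow = 4)
  rec <- recording(x, fs = 500)
  out <- common_average_reference(rec)
  expect_lt(max(abs(colMeans(out$samples))), 1e-12)

  # two channels x and -x: the average is zero, signals unchanged
  rec2 <- recording(rbind(x[1, ], -x[1, ]), fs = 500)
  out2 <- common_average_reference(rec2)
  expect_equal(out2$samples[1, ], x[1, ])

  # a common offset signal added to every channel is removed exactly
  offset <- sin(seq_len(1000) / 50)
  reco <- recording(sweep(x, 2, offset, "+"), fs = 500)
  expect_equal(common_average_reference(reco)$samples, out$samples)
})

test_that("bad and seizure-onset channels are excluded and dropped", {
  set.seed(2)
  ch <- data.frame(name = c("A1", "A2", "H5", "H6"),
                   label = "unassigned",
                   status = c("good", "good", "seizure-onset", "bad"))
  rec <- recording(matrix(rnorm(4 * 256), nrow = 4), fs = 256, channels = ch)
  out <- common_average_reference(rec)
  expect_setequal(out$channels$name, c("A1", "A2"))
  # the excluded channels influenced neither the average nor the output
  expect_equal(out$samples,
               sweep(rec$samples[1:2, ], 2, colMeans(rec$samples[1:2, ])))
  # fewer than two usable channels is an error
  ch$status <- c("good", "bad", "bad", "bad")
  rec3 <- recording(rec$samples, fs = 256, channels = ch)
  expect_error(common_average_reference(rec3), "at least 2")
})

test_that("Slepian tapers are orthonormal and spectrally concentrated", {
  h <- dpss_tapers(205, nw = 3, k = 5)
  expect_equal(crossprod(h), diag(5), tolerance = 1e-10)
  # concentration: in-band energy fraction near 1 for the leading taper
  n <- 205
  w <- 3 / n
  spec <- Mod(fft(c(h[, 1], rep(0, 4096 - n))))^2
  f <- (seq_len(4096) - 1) / 4096
  inband <- sum(spec[f <= w | f >= 1 - w]) / sum(spec)
  expect_gt(inband, 0.999)
})

test_that("multitaper spectrogram matches a direct per-taper FFT oracle", {
  fs <- 1024
  cfg <- fast_cfg(fs, f_max = 300)
  set.seed(4)
  x <- rnorm(2 * fs)
  sp <- multitaper_spectrogram(x, cfg)
  h <- dpss_tapers(cfg$n_win, cfg$nw, cfg$n_tapers)
  for (w in c(1, 7)) {
    seg <- x[(w - 1) * cfg$n_step + seq_len(cfg$n_win)]
    direct <- rowMeans(vapply(seq_len(5), function(j)
      Mod(fft(seg * h[, j]))[1 + seq_along(cfg$freq)],
      numeric(length(cfg$freq))))
    expect_equal(sp$asm[1, , w], direct, tolerance = 1e-12)
  }
  # nominal frequency resolution of about 5 Hz with 200-ms windows
  expect_equal(cfg$df, fs / 205)
  expect_equal(cfg$df, 5, tolerance = 0.1)
  # a pure 100-Hz tone peaks within one bin of the tone at every time step
  # (the taper average is flat-topped over its concentration band, so the
  # maximum may sit on either neighbor of the tone's off-grid frequency)
  tone <- sin(2 * pi * 100 * (0:(2 * fs - 1)) / fs)
  spt <- multitaper_spectrogram(tone, cfg)
  nearest <- cfg$freq[which.min(abs(cfg$freq - 100))]
  peaks <- cfg$freq[apply(spt$asm[1, , ], 2, which.max)]
  expect_true(all(abs(peaks - nearest) <= cfg$df + 1e-9))
  expect_error(multitaper_spectrogram(rnorm(100), cfg), "shorter")
})

test_that("taper averaging reduces spectral estimator variance", {
  fs <- 512
  cfg5 <- spectral_config(fs = fs, f_max = 200, n_tapers = 5)
  cfg1 <- spectral_config(fs = fs, f_max = 200, n_tapers = 1, nw = 3)
  set.seed(9)
  n_rep <- 100
  a5 <- a1 <- matrix(NA_real_, n_rep, length(cfg5$freq))
  for (i in seq_len(n_rep)) {
    x <- rnorm(cfg5$n_win)
    a5[i, ] <- multitaper_spectrogram(x, cfg5)$asm[1, , 1]
    a1[i, ] <- multitaper_spectrogram(x, cfg1)$asm[1, , 1]
  }
  expect_lt(mean(apply(a5, 2, var)), mean(apply(a1, 2, var)))
})

test_that("white-noise spectrum is flat within tolerance (Parseval sanity)", {
  fs <- 512
  cfg <- spectral_config(fs = fs, f_max = 250, power = TRUE)
  set.seed(10)
  n_rep <- 100
  acc <- 0
  for (i in seq_len(n_rep))
    acc <- acc + multitaper_spectrogram(rnorm(cfg$n_win), cfg)$asm[1, , 1]
  avg <- acc / n_rep
  # unit-variance white noise: flat expected power at every bin
  expect_lt(max(abs(avg / mean(avg) - 1)), 0.10 * 3)
  expect_lt(abs(mean(avg) / (cfg$n_win / length(cfg$freq) / 2) - 1), 0.35)
})

test_that("trial extraction drops edge onsets and keeps exact lengths", {
  fs <- 1024
  cfg <- fast_cfg(fs)
  set.seed(3)
  rec <- recording(matrix(rnorm(2 * 10 * fs), nrow = 2), fs = fs)
  # an onset 1 s into the recording lacks its 2 s of history
  expect_warning(ex <- extract_trials(rec, c(1.0, 3.0, 5.0), cfg), "dropped")
  expect_equal(dim(ex$trials), c(2, 2, round(5 * fs)))
  expect_equal(ex$onsets, c(3, 5))
  expect_error(extract_trials(rec, numeric(0), cfg) ,
               class = "ecoglex_empty")
  expect_error(extract_trials(rec, c(1.0), cfg), class = "ecoglex_empty")
})

test_that("baseline normalization has the exact unit-mean identity", {
  fs <- 1024
  cfg <- fast_cfg(fs)
  set.seed(6)
  rec <- recording(matrix(rnorm(2 * 12 * fs), nrow = 2), fs = fs)
  sp <- word_spectra(rec, onsets = c(3, 6.5), cfg = cfg, reference = FALSE)
  half <- (cfg$n_win - 1) / 2 / fs
  bl <- which(sp$time - half >= -2 - 1e-9 & sp$time + half <= -1.8 + 1e-9)
  expect_gte(length(bl), 1)
  rsm <- exp(sp$log_rsm)
  blmean <- apply(rsm[, , , bl, drop = FALSE], 1:3, mean)
  expect_lt(max(abs(blmean - 1)), 1e-12)

  # closed forms: constant ASM -> 0 everywhere; doubling -> log 2
  asm <- array(2, c(1, 3, 5))
  time <- seq(-1.9, -1.9 + 0.02 * 4, by = 0.02)
  lr <- baseline_correct(asm, time, cfg)
  expect_equal(lr, array(0, dim(asm)))
  asm2 <- asm
  asm2[, , 3:5] <- 4 # magnitude doubles after the baseline bin
  lr2 <- baseline_correct(asm2, time, cfg)
  expect_equal(lr2[1, 1, 4], log(2))
})

test_that("the word_spectra fast path equals the per-trial reference path", {
  fs <- 1024
  cfg <- fast_cfg(fs, f_max = 200)
  set.seed(12)
  rec <- recording(matrix(rnorm(3 * 14 * fs), nrow = 3), fs = fs)
  sp <- word_spectra(rec, onsets = c(3, 7, 10.5), cfg = cfg,
                     reference = FALSE)
  ex <- extract_trials(rec, c(3, 7, 10.5), cfg)
  for (tr in c(1, 3)) {
    mt <- multitaper_spectrogram(ex$trials[tr, , ], cfg, t0 = -2)
    lr <- baseline_correct(mt$asm, mt$time, cfg)
    expect_equal(sp$log_rsm[tr, , , ], lr, tolerance = 1e-12)
  }
})

test_that("the signed-rank bin test matches stats::wilcox.test", {
  set.seed(13)
  m <- cbind(rnorm(20), rnorm(20) + 1, c(rnorm(18), 0, 0),
             round(rnorm(20), 1)) # includes zeros and ties
  p <- ecoglex:::signed_rank_p(m)
  for (j in 1:4) {
    ref <- suppressWarnings(stats::wilcox.test(m[, j]))$p.value
    expect_equal(p[j], ref, tolerance = 1e-10)
  }
})

test_that("the RSM group test flags real changes and respects BH monotonicity", {
  fs <- 1024
  cfg <- fast_cfg(fs)
  set.seed(14)
  rec <- recording(matrix(rnorm(65 * fs), nrow = 1), fs = fs)
  onsets <- seq(3, 60, length.out = 20)
  sp <- word_spectra(rec, onsets = onsets, cfg = cfg, reference = FALSE,
                     time_range = c(-0.2, 0.4))
  # inject a gross artificial shift at one bin across all trials
  sp$log_rsm[, 1, 5, 8] <- sp$log_rsm[, 1, 5, 8] + 5
  res <- rsm_group_test(sp, q = 0.05)
  expect_true(res$mask[1, 5, 8])
  res01 <- rsm_group_test(sp, q = 0.01)
  expect_true(all(!res01$mask | res$mask)) # q=0.01 mask nested in q=0.05
  # the sign-test alternative runs and is better than chance on the spike
  res_sign <- rsm_group_test(sp, q = 0.05, method = "sign")
  expect_true(res_sign$p[1, 5, 8] < 0.01)
})
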