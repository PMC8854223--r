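# Spectral pipeline: common-average reference, word-aligned trial
# extraction, multitaper (Slepian) spectrograms, per-trial baseline
# normalization to log relative spectral magnitude (RSM), and the
# RSM-vs-baseline group test.

#' Multichannel recording container
#'
#' @param samples Numeric matrix, channels x time samples (microvolt-like
#'   units).
#' @param fs Sampling rate (Hz), default 1024.
#' @param channels Data frame with one row per channel: `name`, `label`
#'   (free-text anatomical label) and `status` (one of `"good"`, `"bad"`,
#'   `"seizure-onset"`).
#' @return Object of class `ecoglex_recording`.
#' @export
recording <- function(samples, fs = 1024, channels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(fs), fs > 0)
  n_ch <- nrow(samples)
  if (is.null(channels))
    channels <- data.frame(name = sprintf("ch%02d", seq_len(n_ch)),
                           label = "unassigned", status = "good",
                           stringsAsFactors = FALSE)
  stopifnot(nrow(channels) == n_ch,
            all(c("name", "label", "status") %in% names(channels)))
  if (!all(channels$status %in% c("good", "bad", "seizure-onset")))
    stop_invalid("channel status must be good, bad or seizure-onset")
  structure(list(samples = samples, fs = fs, channels = channels),
            class = "ecoglex_recording")
}

#' @export
print.ecoglex_recording <- function(x, ...) {
  cat("<ecoglex_recording> ", nrow(x$samples), " channels x ",
      ncol(x$samples), " samples @ ", x$fs, " Hz (",
      sprintf("%.1f", ncol(x$samples) / x$fs), " s); ",
      sum(x$channels$status == "good"), " good channels\n", sep = "")
  invisible(x)
}

#' Common average reference (CAR)
#'
#' Subtracts, at every sample, the mean over the included channels from each
#' included channel. Channels whose status is not `"good"` and any channels
#' named in `exclude` are left out of the average and dropped from the
#' output. The result is invariant to adding a common offset signal to every
#' included channel.
#'
#' @param rec An [recording()].
#' @param exclude Channel names or indices to exclude in addition to non-good
#'   channels.
#' @return A re-referenced `ecoglex_recording` containing only the included
#'   channels.
#' @export
common_average_reference <- function(rec, exclude = NULL) {
  stopifnot(inherits(rec, "ecoglex_recording"))
  drop <- rec$channels$status != "good"
  if (!is.null(exclude)) {
    if (is.character(exclude)) drop <- drop | rec$channels$name %in% exclude
    else drop[exclude] <- TRUE
  }
  keep <- which(!drop)
  if (length(keep) < 2)
    stop_invalid("common average reference needs at least 2 included channels")
  x <- rec$samples[keep, , drop = FALSE]
  x <- sweep(x, 2, colMeans(x))
  recording(x, fs = rec$fs, channels = rec$channels[keep, , drop = FALSE])
}

#' Spectral analysis configuration
#'
#' Defaults follow the standard analysis settings: 200-ms sliding windows
#' with 20-ms steps (nominal frequency resolution of about 5 Hz at 1024 Hz),
#' 5 Slepian tapers (time-bandwidth product NW = 3, the standard pairing for
#' K = 2NW - 1 tapers), trials of 2 s before to 3 s after word onset, and a
#' baseline of the first 200 ms of the trial window ([-2, -1.8] s). Spectra
#' are magnitudes; set `power = TRUE` for squared magnitudes. The alternative
#' 500-ms/50-ms windowing can be configured but is not the default.
#'
#' @param fs Sampling rate (Hz).
#' @param window Sliding-window length (s).
#' @param step Window step (s); must be smaller than `window`.
#' @param n_tapers Number of Slepian tapers.
#' @param nw Time-bandwidth product of the taper family.
#' @param f_max Highest analyzed frequency (Hz): 300 for the full analysis,
#'   150 for the focalized one.
#' @param trial_window Trial extent around word onset (s).
#' @param baseline_window Baseline extent (s), inside the trial window.
#' @param power Use squared magnitude instead of magnitude.
#' @return List of class `spectral_config` with derived fields `n_win`,
#'   `n_step`, `freq` (bin centers, Hz) and `df` (bin spacing, Hz).
#' @export
spectral_config <- function(fs = 1024, window = 0.2, step = 0.02,
                            n_tapers = 5, nw = 3, f_max = 300,
                            trial_window = c(-2, 3),
                            baseline_window = c(-2, -1.8),
                            power = FALSE) {
  if (!(window > step && step > 0)) stop_invalid("need window > step > 0")
  if (f_max > fs / 2) stop_invalid("f_max exceeds the Nyquist frequency")
  if (baseline_window[1] < trial_window[1] ||
      baseline_window[2] > trial_window[2])
    stop_invalid("baseline window must lie inside the trial window")
  n_win <- round(window * fs)
  df <- fs / n_win
  k <- seq_len(floor(f_max / df))
  structure(list(fs = fs, window = window, step = step, n_tapers = n_tapers,
                 nw = nw, f_max = f_max, trial_window = trial_window,
                 baseline_window = baseline_window, power = power,
                 n_win = n_win, n_step = max(1L, round(step * fs)),
                 freq = k * df, df = df),
            class = "spectral_config")
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the symmetric tridiagonal formulation of the spectral
#' concentration problem. Tapers are orthonormal; polarity follows the usual
#' convention (leading significant element positive).
#'
#' @param n Taper length (samples).
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (at most `2 * nw - 1` for good concentration).
#' @return `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  stopifnot(n > k, nw > 0, k >= 1)
  w <- nw / n
  t <- seq_len(n) - 1
  d <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  e <- t[-1] * (n - t[-1]) / 2
  m <- diag(d)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- e
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- e
  eg <- eigen(m, symmetric = TRUE)
  h <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    hj <- h[, j]
    lead <- which(abs(hj) > max(abs(hj)) * 1e-6)[1]
    if (hj[lead] < 0) h[, j] <- -hj
    h[, j] <- h[, j] / sqrt(sum(h[, j]^2))
  }
  h
}

# Real-valued DFT operator restricted to the analyzed bins, one block of
# cosine and sine rows per taper, pre-multiplied by the taper. One matrix
# product of this operator with a segment matrix yields all tapers at once.
mt_operator <- function(cfg) {
  n <- cfg$n_win
  tapers <- dpss_tapers(n, cfg$nw, cfg$n_tapers)
  t_idx <- seq_len(n) - 1
  k <- round(cfg$freq / cfg$df)
  ang <- 2 * pi * outer(k, t_idx) / n
  cosm <- cos(ang)
  sinm <- sin(ang)
  blocks <- lapply(seq_len(cfg$n_tapers), function(j) {
    h <- tapers[, j]
    rbind(cosm * rep(h, each = length(k)), sinm * rep(h, each = length(k)))
  })
  do.call(rbind, blocks)
}

# ASM from a segment matrix (n_win x n_segments): taper-averaged magnitude
# (or squared magnitude) of the DFT, returned as n_freq x n_segments.
mt_asm <- function(segments, op, cfg) {
  y <- op %*% segments
  nf <- length(cfg$freq)
  asm <- 0
  for (j in seq_len(cfg$n_tapers)) {
    re <- y[(2 * (j - 1)) * nf + seq_len(nf), , drop = FALSE]
    im <- y[(2 * (j - 1) + 1) * nf + seq_len(nf), , drop = FALSE]
    m2 <- re * re + im * im
    asm <- asm + if (cfg$power) m2 else sqrt(m2)
  }
  asm / cfg$n_tapers
}

# Sliding-window start offsets (0-based) and center times for a signal of
# `n` samples whose first sample is at time `t0`.
mt_windows <- function(n, cfg, t0 = 0) {
  if (n < cfg$n_win) stop_invalid("signal shorter than the analysis window")
  starts <- seq(0L, n - cfg$n_win, by = cfg$n_step)
  list(starts = starts,
       time = t0 + (starts + (cfg$n_win - 1) / 2) / cfg$fs)
}

#' Multitaper spectrogram (absolute spectral magnitudes)
#'
#' Taper-averaged magnitude of the windowed discrete Fourier transform over
#' the configured Slepian taper family, at every sliding-window position and
#' every frequency bin up to `f_max`. Time stamps are window centers.
#'
#' @param x Numeric vector (one channel) or channels x samples matrix.
#' @param cfg [spectral_config()].
#' @param t0 Time of the first sample (s).
#' @return List with `asm` (channels x frequency x time array), `freq` (Hz)
#'   and `time` (s).
#' @export
multitaper_spectrogram <- function(x, cfg = spectral_config(), t0 = 0) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  win <- mt_windows(ncol(x), cfg, t0)
  op <- mt_operator(cfg)
  idx <- outer(seq_len(cfg$n_win), win$starts, "+")
  nf <- length(cfg$freq)
  asm <- array(NA_real_, c(nrow(x), nf, length(win$starts)))
  for (ch in seq_len(nrow(x))) {
    seg <- matrix(x[ch, ][idx], nrow = cfg$n_win)
    asm[ch, , ] <- mt_asm(seg, op, cfg)
  }
  list(asm = asm, freq = cfg$freq, time = win$time)
}

#' Extract word-aligned trials
#'
#' Cuts one trial per onset, covering the configured trial window around
#' word onset. Onsets whose trial would extend beyond the recording are
#' dropped with a warning.
#'
#' @param rec An [recording()].
#' @param onsets Word-onset times (s), sorted.
#' @param cfg [spectral_config()].
#' @return List with `trials` (trials x channels x samples array), `onsets`
#'   (kept onsets) and `kept` (logical over the input onsets).
#' @export
extract_trials <- function(rec, onsets, cfg = spectral_config()) {
  stopifnot(inherits(rec, "ecoglex_recording"))
  if (is.unsorted(onsets)) stop_invalid("onsets must be sorted")
  n_samp <- round((cfg$trial_window[2] - cfg$trial_window[1]) * rec$fs)
  start <- round(onsets * rec$fs) + round(cfg$trial_window[1] * rec$fs) + 1
  ok <- start >= 1 & (start + n_samp - 1) <= ncol(rec$samples)
  if (!any(ok))
    stop(structure(class = c("ecoglex_empty", "error", "condition"),
                   list(message = "no onset admits a full trial window",
                        call = NULL)))
  if (any(!ok))
    warning(sum(!ok), " onset(s) too close to a recording edge were dropped")
  start <- start[ok]
  n_tr <- length(start)
  trials <- array(NA_real_, c(n_tr, nrow(rec$samples), n_samp))
  rel <- seq_len(n_samp) - 1
  for (i in seq_len(n_tr))
    trials[i, , ] <- rec$samples[, start[i] + rel, drop = FALSE]
  list(trials = trials, onsets = onsets[ok], kept = ok)
}

# indices of spectrogram bins whose window lies fully inside the baseline
baseline_bins <- function(time, cfg) {
  half <- (cfg$n_win - 1) / 2 / cfg$fs
  which(time - half >= cfg$baseline_window[1] - 1e-9 &
          time + half <= cfg$baseline_window[2] + 1e-9)
}

#' Baseline-normalize spectra to log relative spectral magnitude
#'
#' Per trial and frequency, divides the spectrogram by the mean magnitude
#' over the baseline bins at that frequency and takes the natural log. By
#' construction the pre-log relative magnitude averages to exactly 1 over
#' the baseline bins. Frequencies with zero baseline magnitude are flagged
#' missing with a warning.
#'
#' @param asm Array of absolute spectral magnitudes: channels x frequency x
#'   time, or trials x channels x frequency x time.
#' @param time Time stamps of the spectrogram bins (s, relative to word
#'   onset).
#' @param cfg [spectral_config()]; supplies the baseline window.
#' @return Array of log relative spectral magnitudes, same shape.
#' @export
baseline_correct <- function(asm, time, cfg = spectral_config()) {
  nd <- length(dim(asm))
  if (nd == 3) {
    asm <- array(asm, c(1, dim(asm)))
    out <- baseline_correct(asm, time, cfg)
    return(array(out, dim(out)[-1]))
  }
  stopifnot(nd == 4, dim(asm)[4] == length(time))
  bl <- baseline_bins(time, cfg)
  if (!length(bl))
    stop_invalid("baseline window contains no complete spectrogram bin")
  d <- dim(asm)
  base <- asm[, , , bl, drop = FALSE]
  dim(base) <- c(prod(d[1:3]), length(bl))
  base <- rowMeans(base)
  dim(base) <- d[1:3]
  if (any(base <= 0, na.rm = TRUE)) {
    warning("zero baseline magnitude at some bins; flagged missing")
    base[base <= 0] <- NA_real_
  }
  log(asm / as.vector(base)) # recycles base over the time dimension
}

#' Word-aligned trial spectra (log RSM)
#'
#' High-level routine: optionally applies the common average reference,
#' extracts one trial per onset, computes multitaper spectrograms and
#' baseline-normalizes them to natural-log relative spectral magnitudes.
#' Channels are processed with a single matrix product over all trials and
#' window positions.
#'
#' @param rec An [recording()].
#' @param onsets Word-onset times (s), sorted.
#' @param cfg [spectral_config()].
#' @param reference Apply [common_average_reference()] first.
#' @param exclude Channels to exclude from the reference (see
#'   [common_average_reference()]).
#' @param time_range Optional length-2 vector (s relative to onset): only
#'   spectrogram bins with centers inside this range (plus the baseline
#'   bins) are computed, which saves time for focalized analyses.
#' @return Object of class `trial_spectra`: `log_rsm` (trials x channels x
#'   frequency x time), `freq`, `time`, `onsets`, `channels`, `cfg`.
#' @export
word_spectra <- function(rec, onsets, cfg = spectral_config(),
                         reference = TRUE, exclude = NULL,
                         time_range = NULL) {
  stopifnot(inherits(rec, "ecoglex_recording"))
  if (reference) rec <- common_average_reference(rec, exclude)
  if (is.unsorted(onsets)) stop_invalid("onsets must be sorted")
  n_samp <- round((cfg$trial_window[2] - cfg$trial_window[1]) * rec$fs)
  start <- round(onsets * rec$fs) + round(cfg$trial_window[1] * rec$fs) + 1
  ok <- start >= 1 & (start + n_samp - 1) <= ncol(rec$samples)
  if (!any(ok))
    stop(structure(class = c("ecoglex_empty", "error", "condition"),
                   list(message = "no onset admits a full trial window",
                        call = NULL)))
  if (any(!ok))
    warning(sum(!ok), " onset(s) too close to a recording edge were dropped")
  start <- start[ok]
  win <- mt_windows(n_samp, cfg, t0 = cfg$trial_window[1])
  sel <- seq_along(win$starts)
  if (!is.null(time_range)) {
    keep <- (win$time >= time_range[1] & win$time <= time_range[2])
    keep[baseline_bins(win$time, cfg)] <- TRUE
    sel <- which(keep)
  }
  starts <- win$starts[sel]
  time <- win$time[sel]
  if (!length(baseline_bins(time, cfg)))
    stop_invalid("baseline window contains no complete spectrogram bin")
  op <- mt_operator(cfg)
  nf <- length(cfg$freq)
  asm <- cpp_trial_asm(t(rec$samples), start - 1L, starts, op,
                       nf, cfg$n_tapers, cfg$power)
  log_rsm <- baseline_correct(asm, time, cfg)
  structure(list(log_rsm = log_rsm, freq = cfg$freq, time = time,
                 onsets = onsets[ok], channels = rec$channels$name,
                 cfg = cfg),
            class = "trial_spectra")
}

#' @export
print.trial_spectra <- function(x, ...) {
  d <- dim(x$log_rsm)
  cat("<trial_spectra> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " freq bins (", min(x$freq), "-", round(max(x$freq)), " Hz) x ", d[4],
      " time bins (", sprintf("%.2f", min(x$time)), " to ",
      sprintf("%.2f", max(x$time)), " s)\n", sep = "")
  invisible(x)
}

#' Trial-averaged log RSM image for one channel
#'
#' @param x A `trial_spectra` object.
#' @param channel Channel index or name.
#' @param ... Passed to [graphics::image()].
#' @export
plot.trial_spectra <- function(x, channel = 1, ...) {
  if (is.character(channel)) channel <- match(channel, x$channels)
  m <- apply(x$log_rsm[, channel, , , drop = FALSE], c(3, 4), mean,
             na.rm = TRUE)
  graphics::image(x$time, x$freq, t(m), xlab = "time (s)",
                  ylab = "frequency (Hz)",
                  main = paste0("mean log RSM, channel ", x$channels[channel]),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(x)
}

# Vectorized one-sample Wilcoxon signed-rank test against 0, one test per
# column. Exact null distribution (psignrank) when n < 50 with no ties or
# zeros, else normal approximation with continuity and tie corrections —
# mirroring stats::wilcox.test defaults.
signed_rank_p <- function(m) {
  apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    zeros <- any(x == 0)
    x <- x[x != 0]
    n <- length(x)
    if (n < 1) return(1)
    r <- rank(abs(x))
    v <- sum(r[x > 0])
    ties <- any(duplicated(abs(x)))
    if (!ties && !zeros && n < 50) {
      p <- min(2 * min(stats::psignrank(v, n),
                       stats::psignrank(v - 1, n, lower.tail = FALSE)), 1)
      return(p)
    }
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) return(1)
    z <- v - mu
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)
    min(2 * stats::pnorm(-abs(z)), 1)
  })
}

sign_test_p <- function(m) {
  apply(m, 2, function(x) {
    x <- x[!is.na(x) & x != 0]
    n <- length(x)
    if (n < 1) return(1)
    b <- sum(x > 0)
    min(2 * min(stats::pbinom(b, n, 0.5),
                stats::pbinom(b - 1, n, 0.5, lower.tail = FALSE)), 1)
  })
}

#' Test log RSM against no change, with FDR control
#'
#' Per channel, frequency and time bin, a two-sided one-sample Wilcoxon test
#' of the log relative spectral magnitudes against 0 across trials
#' (equivalently, of RSM against 1), corrected jointly over all time bins,
#' frequency bins and channels by the Benjamini-Hochberg procedure at level
#' `q`. Degenerate bins (all values identical) get p = 1.
#'
#' @param spectra A [word_spectra()] result with at least 10 trials.
#' @param q FDR level.
#' @param method `"signed-rank"` (default) or `"sign"`.
#' @return List with `p`, `p_adj` (channels x freq x time arrays), `mask`
#'   (logical array of FDR-significant bins), `q` and `n_tests`.
#' @export
rsm_group_test <- function(spectra, q = 0.05,
                           method = c("signed-rank", "sign")) {
  method <- match.arg(method)
  d <- dim(spectra$log_rsm)
  if (d[1] < 10) stop_invalid("need at least 10 trials for the group test")
  m <- matrix(spectra$log_rsm, nrow = d[1])
  p <- if (method == "signed-rank") signed_rank_p(m) else sign_test_p(m)
  p_adj <- stats::p.adjust(p, method = "BH")
  shape <- d[-1]
  list(p = array(p, shape), p_adj = array(p_adj, shape),
       mask = array(p_adj < q, shape), q = q, n_tests = length(p),
       method = method)
}
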