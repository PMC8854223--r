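# Forward model for recovery testing: 1/f background noise per channel plus
# word-locked, band-limited bursts whose amplitude is monotone in a chosen
# linguistic parameter, calibrated so that the realized correlation between
# per-bin log RSM and the (log) parameter approximates a requested Pearson r.

#' Specify an injected neural effect
#'
#' Ground truth for recovery tests: a band-limited burst added around every
#' content-word onset on one channel, with amplitude coupled to a linguistic
#' parameter.
#'
#' @param channel Target channel index (1-based).
#' @param parameter One of `"NoS"`, `"CVR"`, `"EoA"`, `"FRQ"`, `"ss_ws"`,
#'   `"ws_we"`, `"we_se"`, `"intensity"`.
#' @param band Frequency band (Hz), within (0, 512).
#' @param window Burst interval relative to word onset (s), within [-2, 3].
#' @param r Target Pearson correlation between per-bin log RSM and the log
#'   parameter at the effect bins; |r| < 1.
#' @param sign Effect sign (+1 or -1); defaults to the sign of `r`.
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(channel, parameter, band, window = c(0, 0.4),
                        r = 0.5, sign = NULL) {
  if (is.null(sign)) sign <- if (r < 0) -1 else 1
  if (abs(r) >= 1) stop_invalid("|coupling r| must be below 1")
  if (band[1] <= 0 || band[2] >= 512 || band[2] <= band[1])
    stop_invalid("band must be an increasing interval within (0, 512) Hz")
  if (window[1] < -2 || window[2] > 3 || window[2] <= window[1])
    stop_invalid("window must be an increasing interval within [-2, 3] s")
  par_ok <- c("NoS", "CVR", "EoA", "FRQ", "ss_ws", "ws_we", "we_se",
              "intensity")
  if (!parameter %in% par_ok)
    stop_invalid("parameter must be one of: ", paste(par_ok, collapse = ", "))
  structure(list(channel = as.integer(channel), parameter = parameter,
                 band = band, window = window, r = abs(r) * sign,
                 sign = sign),
            class = "effect_spec")
}

# 1/f^a-shaped noise, unit variance per channel, via spectral shaping of
# white noise. Synthesis runs at the next 2-3-5-smooth length (fast FFT)
# and truncates; `channels` traces are shaped in one mvfft call.
one_over_f_noise <- function(n, fs, exponent = 1, channels = 1) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- matrix(stats::rnorm(m * channels), m, channels)
  xf <- stats::mvfft(x)
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f[f > fs / 2] <- fs - f[f > fs / 2] # fold to physical frequency
  shape <- c(0, 1 / f[-1]^(exponent / 2))
  y <- Re(stats::mvfft(xf * shape, inverse = TRUE))[seq_len(n), ,
                                                    drop = FALSE] / m
  y <- sweep(y, 2, apply(y, 2, stats::sd), "/")
  if (channels == 1) drop(y) else t(y)
}

# fraction of total signal power falling inside [band] for the 1/f shape
band_power_fraction <- function(band, fs, exponent, n = 8192) {
  f <- seq(0, fs / 2, length.out = n)[-1]
  s <- 1 / f^exponent
  sum(s[f >= band[1] & f <= band[2]]) / sum(s)
}

# band-limited unit-variance noise of length n (sharp FFT mask)
band_noise <- function(n, fs, band) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(m)
  xf <- stats::fft(x)
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  mask <- as.numeric(f >= band[1] & f <= band[2])
  y <- Re(stats::fft(xf * mask, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(y)
  if (s == 0) stop_invalid("empty frequency band for burst synthesis")
  y / s
}

tukey_window <- function(n, alpha = 0.3) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / edge - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + edge) / edge)))
  w
}

# Per-token target log relative magnitudes for slope `s` around a fixed
# baseline offset `c0`: floored just above zero, capped two slopes above
# the offset to keep extreme words physical. The offset is chosen once per
# effect (from the nominal slope, see below) and never fed back, so burst
# levels cannot ratchet up across calibration passes.
burst_levels <- function(s, zs, c0 = 0.7) {
  pmin(pmax(c0 + s * zs, 0.02), c0 + 2 * s)
}

# offset that keeps all but the lowest 2% of words off the floor at the
# nominal slope
burst_offset <- function(s_nominal, zs) {
  max(0.7, 0.05 - s_nominal * stats::quantile(zs, 0.02, names = FALSE))
}

# Parameter value per token for an effect spec (natural units, pre-log).
token_parameter <- function(discourse, parameter, covariates = NULL) {
  switch(parameter,
         NoS = discourse$nos,
         CVR = discourse$cvr,
         EoA = discourse$eoa,
         FRQ = discourse$frequency,
         ss_ws = (discourse$ws - discourse$ss) * 1000,
         ws_we = (discourse$we - discourse$ws) * 1000,
         we_se = (discourse$se - discourse$we) * 1000,
         intensity = {
           if (is.null(covariates))
             stop_invalid("intensity coupling needs the covariates argument")
           covariates$intensity$intensity_db[
             match(discourse$token_id, covariates$intensity$token_id)]
         },
         stop_invalid("unknown parameter ", parameter))
}

# Add band-limited, envelope-shaped bursts around each onset. `ci` is the
# per-onset target log relative magnitude: burst variance is chosen as
# p_bg * (exp(2 ci) - 1) so the expected log magnitude ratio at the effect
# bins is about ci.
inject_bursts <- function(x, fs, onsets, ci, effect, noise_exponent) {
  pfrac <- band_power_fraction(effect$band, fs, noise_exponent)
  len <- round((effect$window[2] - effect$window[1]) * fs)
  env <- tukey_window(len)
  env_scale <- sqrt(mean(env^2))
  n <- length(x)
  for (i in seq_along(onsets)) {
    v <- pfrac * expm1(2 * ci[i])
    at <- round((onsets[i] + effect$window[1]) * fs)
    j <- at + seq_len(len)
    ok <- j >= 1 & j <= n
    if (!any(ok)) next
    burst <- band_noise(len, fs, effect$band) * env / env_scale * sqrt(v)
    x[j[ok]] <- x[j[ok]] + burst[ok]
  }
  x
}

# Pilot simulation on a single synthetic channel carrying the full burst
# train of the discourse: measures the per-bin log-RSM noise SD at the
# effect bins through the same spectral pipeline the analysis uses,
# including the contamination of baselines and effect windows by
# neighboring words' bursts. Two passes: first with constant-amplitude
# bursts to get an initial slope, then at the operating amplitudes, where
# the own-word signal is regressed out so only noise is counted.
calibrate_effect_slope <- function(effect, fs, noise_exponent, cfg,
                                   onsets, zs, probe_pool = NULL,
                                   c0 = 0.7, n_pilot = 96) {
  k <- abs(effect$r) / sqrt(1 - effect$r^2)
  dur <- max(onsets) + cfg$trial_window[2] + 0.2
  n <- ceiling(dur * fs)
  pcfg <- spectral_config(fs = fs, window = cfg$window, step = cfg$step,
                          n_tapers = cfg$n_tapers, nw = cfg$nw,
                          f_max = min(effect$band[2] + cfg$df, fs / 2),
                          trial_window = cfg$trial_window,
                          baseline_window = cfg$baseline_window,
                          power = cfg$power)
  # probe the same word population the analysis will correlate over (the
  # deduplicated selection when available), not the raw token stream
  if (is.null(probe_pool)) probe_pool <- seq_along(onsets)
  usable <- probe_pool[onsets[probe_pool] + cfg$trial_window[1] > 0 &
                         onsets[probe_pool] + cfg$trial_window[2] < dur]
  probe <- usable[unique(round(seq(1, length(usable),
                                   length.out = min(n_pilot,
                                                    length(usable)))))]
  measure <- function(ci) {
    x <- one_over_f_noise(n, fs, noise_exponent)
    x <- inject_bursts(x, fs, onsets, ci, effect, noise_exponent)
    sp <- word_spectra(recording(matrix(x, nrow = 1), fs = fs),
                       onsets = onsets[probe], cfg = pcfg,
                       reference = FALSE,
                       time_range = effect$window + c(-0.1, 0.1))
    core <- effect_core_bins(sp$freq, sp$time, effect, cfg)
    vals <- sp$log_rsm[, 1, core$fsel, core$tsel, drop = FALSE]
    matrix(vals, nrow = dim(vals)[1])
  }
  zp <- zs[probe]
  zc <- zp - mean(zp)
  ssz <- sum(zc^2)
  sd_zp <- stats::sd(zp) # parameter spread of the analysis population
  # realized slope and residual (noise) SD of the per-bin log RSM on the
  # standardized parameter, at injected slope `s`
  probe_fit <- function(s) {
    ci <- burst_levels(s, zs, c0)
    y <- measure(ci)
    m <- nrow(y)
    beta <- colSums(zc * y) / ssz
    resvar <- vapply(seq_len(ncol(y)), function(b) {
      yb <- y[, b]
      yc <- yb - mean(yb)
      max((sum(yc^2) - sum(zc * yb)^2 / ssz) / (m - 2), 0)
    }, numeric(1))
    list(beta = mean(beta), sigma = sqrt(mean(resvar)))
  }
  # two calibration passes from a generic starting slope: overlapping
  # neighbor bursts attenuate the injected slope (log of summed band power
  # is compressive), so each pass measures the realized slope and residual
  # noise at the current operating point and rescales; growth is capped so
  # the fixed-point search cannot run away on dense discourse
  s0 <- k * 0.55 # typical per-bin log-RSM noise SD under these settings
  s <- s0
  for (pass in 1:2) {
    fit <- probe_fit(s)
    atten <- min(max(fit$beta / s, 0.4), 1.5)
    s <- min(k * fit$sigma / (atten * sd_zp), 3 * s0)
  }
  s
}

# frequency / time selections of the bins fully inside an effect's band and
# burst plateau (excluding the envelope ramps)
effect_core_bins <- function(freq, time, effect, cfg) {
  ramp <- 0.15 * (effect$window[2] - effect$window[1])
  half <- cfg$window / 2
  fsel <- freq >= effect$band[1] & freq <= effect$band[2]
  tsel <- time - half >= effect$window[1] + ramp &
    time + half <= effect$window[2] - ramp
  if (!any(tsel)) # short bursts: fall back to windows inside the burst
    tsel <- time - half >= effect$window[1] & time + half <= effect$window[2]
  list(fsel = fsel, tsel = tsel)
}

#' Synthesize a multichannel recording with injected effects
#'
#' Background activity is 1/f-shaped noise, independent across channels.
#' For every [effect_spec()], band-limited bursts are added around each
#' content-word onset with log-amplitude linear in the standardized log
#' parameter. The slope is calibrated from a seeded pilot simulation that
#' measures the per-bin log-RSM noise SD through the same spectral pipeline,
#' so that the realized per-bin correlation at the effect bins approximates
#' the requested r. Channels not named in any effect carry no word-locked
#' coupling.
#'
#' @param discourse An [generate_discourse()] result.
#' @param effects List of [effect_spec()] objects.
#' @param n_channels Number of channels.
#' @param fs Sampling rate (Hz); must exceed twice the highest effect-band
#'   frequency.
#' @param seed Optional integer seed (fixed seed gives bit-identical
#'   signals).
#' @param noise_exponent Spectral exponent of the background (1 = pink).
#' @param duration Recording length (s); defaults to cover the discourse
#'   plus the trial window margins.
#' @param covariates Optional [synthesize_covariates()] result (needed for
#'   intensity-coupled effects).
#' @param cfg [spectral_config()] used for calibration; defaults to the
#'   standard settings at `fs`.
#' @param channel_status Optional character vector of channel statuses.
#' @return An [recording()] with attribute `effects`.
#' @export
synthesize_recording <- function(discourse, effects = list(),
                                 n_channels = 16, fs = 1024, seed = NULL,
                                 noise_exponent = 1, duration = NULL,
                                 covariates = NULL, cfg = NULL,
                                 channel_status = NULL) {
  stopifnot(is.data.frame(discourse), nrow(discourse) > 0)
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  if (is.null(cfg))
    cfg <- spectral_config(fs = fs, f_max = min(300, fs / 2))
  for (ef in effects) {
    if (ef$band[2] >= fs / 2)
      stop_invalid("effect band reaches the Nyquist frequency")
    if (ef$channel > n_channels || ef$channel < 1)
      stop_invalid("effect channel outside 1..n_channels")
  }
  if (is.null(duration)) duration <- max(discourse$se) + cfg$trial_window[2] +
    0.2
  n <- ceiling(duration * fs)
  with_seed(seed, {
    x <- one_over_f_noise(n, fs, noise_exponent, channels = n_channels)
    if (n_channels == 1) x <- matrix(x, nrow = 1)
    content <- !is.na(content_category(discourse$pos)) &
      !is.na(discourse$frequency)
    for (ef in effects) {
      vals <- token_parameter(discourse, ef$parameter, covariates)
      use <- content & !is.na(vals)
      lv <- log_transform(pmax(vals[use], 0))
      # standardize over word types (first occurrence of each form), not
      # tokens: the downstream analysis runs on deduplicated words, so the
      # coupling must be scaled to the type-level spread
      types <- !duplicated(data.frame(discourse$orthography,
                                      discourse$pos)[use, ])
      mu <- mean(lv[types])
      sdv <- stats::sd(lv[types])
      if (is.na(sdv) || sdv == 0)
        stop_invalid("parameter ", ef$parameter,
                     " is constant; cannot couple an effect to it")
      zs <- ef$sign * (lv - mu) / sdv
      onsets <- discourse$ws[use]
      sel_ids <- select_content_words(discourse)$token_id
      probe_pool <- which(discourse$token_id[use] %in% sel_ids)
      c0 <- burst_offset(abs(ef$r) / sqrt(1 - ef$r^2) * 0.55, zs)
      s <- calibrate_effect_slope(ef, fs, noise_exponent, cfg, onsets, zs,
                                  probe_pool = probe_pool, c0 = c0)
      ci <- burst_levels(s, zs, c0)
      x[ef$channel, ] <- inject_bursts(x[ef$channel, ], fs, onsets, ci,
                                       ef, noise_exponent)
    }
    status <- if (is.null(channel_status)) rep("good", n_channels)
              else channel_status
    rec <- recording(x, fs = fs,
                     channels = data.frame(
                       name = sprintf("ch%02d", seq_len(n_channels)),
                       label = "unassigned", status = status,
                       stringsAsFactors = FALSE))
    attr(rec, "effects") <- effects
    rec
  })
}
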