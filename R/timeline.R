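# Tag model and timing parameters: post-hoc tag-order correction,
# pause-based speech-epoch segmentation, duration parameters (ms), mean
# acoustic intensity, and EMG band power relative to baseline.

#' Correct manual tag ordering
#'
#' Word tags are set as precisely as possible; manually placed clause and
#' epoch tags may lag or lead by a few milliseconds. The correction widens
#' each enclosing unit to contain its content: clause starts are clamped to
#' the earliest word start of the clause, clause ends to the latest word end;
#' epoch starts/ends likewise to their clauses and words. Word tags are never
#' moved. Idempotent.
#'
#' @param tags Data frame with one row per token and columns `ws`, `we`
#'   (word start/end, s), `cs`, `ce` (enclosing clause), `ss`, `se`
#'   (enclosing epoch), plus `clause_id` and `epoch_id` identifying the
#'   enclosing units.
#' @return The corrected data frame, satisfying
#'   `ss <= cs <= ws < we <= ce <= se` on every row.
#' @export
correct_tag_order <- function(tags) {
  stopifnot(is.data.frame(tags),
            all(c("ws", "we", "cs", "ce", "ss", "se",
                  "clause_id", "epoch_id") %in% names(tags)))
  if (any(tags$we <= tags$ws))
    stop_invalid("invalid annotation: word end at or before word start")
  tags$cs <- pmin(tags$cs, stats::ave(tags$ws, tags$clause_id, FUN = min))
  tags$ce <- pmax(tags$ce, stats::ave(tags$we, tags$clause_id, FUN = max))
  tags$ss <- pmin(tags$ss, stats::ave(tags$cs, tags$epoch_id, FUN = min),
                  stats::ave(tags$ws, tags$epoch_id, FUN = min))
  tags$se <- pmax(tags$se, stats::ave(tags$ce, tags$epoch_id, FUN = max),
                  stats::ave(tags$we, tags$epoch_id, FUN = max))
  tags
}

#' Segment tokens into speech-production epochs
#'
#' A speech-production epoch is a stretch of speech without pauses of 0.2 s
#' or longer: consecutive tokens separated by a gap strictly below the
#' threshold share an epoch; a gap at or above it (the ">= 200 ms" rule)
#' starts a new one.
#'
#' @param onsets,offsets Token onset/offset times (s), time-ordered.
#' @param pause_threshold Pause threshold (s), default 0.2.
#' @return List with `epoch_id` (integer per token) and `epochs` (data frame
#'   `epoch_id`, `ss`, `se`, `n_tokens`).
#' @export
segment_speech_epochs <- function(onsets, offsets, pause_threshold = 0.2) {
  stopifnot(length(onsets) == length(offsets))
  if (!length(onsets))
    return(list(epoch_id = integer(0),
                epochs = data.frame(epoch_id = integer(0), ss = numeric(0),
                                    se = numeric(0), n_tokens = integer(0))))
  if (is.unsorted(onsets)) stop_invalid("tokens must be time-ordered")
  if (any(offsets <= onsets))
    stop_invalid("invalid annotation: token offset at or before onset")
  gaps <- onsets[-1] - offsets[-length(offsets)]
  if (any(gaps < 0))
    stop_invalid("invalid annotation: overlapping tokens")
  epoch_id <- cumsum(c(1L, as.integer(gaps >= pause_threshold - 1e-9)))
  epochs <- data.frame(
    epoch_id = unique(epoch_id),
    ss = tapply(onsets, epoch_id, min)[as.character(unique(epoch_id))],
    se = tapply(offsets, epoch_id, max)[as.character(unique(epoch_id))],
    n_tokens = as.integer(table(epoch_id)[as.character(unique(epoch_id))]),
    row.names = NULL)
  list(epoch_id = epoch_id, epochs = epochs)
}

#' Duration parameters per token
#'
#' Computes the six duration parameters in milliseconds: distance from epoch
#' start to word start (`ss_ws`), word duration (`ws_we`), distance from word
#' end to epoch end (`we_se`), clause duration (`cs_ce`), and the distances
#' from epoch start to clause start (`ss_cs`) and clause end to epoch end
#' (`ce_se`). Tags must already be order-corrected; all values are
#' non-negative and invariant under a common time shift.
#'
#' @param tags Data frame with columns `ws`, `we`, `cs`, `ce`, `ss`, `se`
#'   (s).
#' @return Data frame with the six duration columns (ms).
#' @export
duration_parameters <- function(tags) {
  stopifnot(is.data.frame(tags),
            all(c("ws", "we", "cs", "ce", "ss", "se") %in% names(tags)))
  if (any(tags$ws < tags$ss | tags$we > tags$se))
    stop_invalid("invalid annotation: token outside its speech epoch; ",
                 "run correct_tag_order() first")
  data.frame(ss_ws = (tags$ws - tags$ss) * 1000,
             ws_we = (tags$we - tags$ws) * 1000,
             we_se = (tags$se - tags$we) * 1000,
             cs_ce = (tags$ce - tags$cs) * 1000,
             ss_cs = (tags$cs - tags$ss) * 1000,
             ce_se = (tags$se - tags$ce) * 1000)
}

#' Mean acoustic intensity over an interval
#'
#' Arithmetic mean of the dB samples of an intensity trace falling within
#' `[interval[1], interval[2]]`. Returns `NA` (missing) when the interval
#' does not overlap the trace support.
#'
#' @param trace Data frame with columns `time` (s) and `intensity_db`.
#' @param interval Numeric length-2 vector, word start/end (s).
#' @return Mean intensity in dB, or `NA_real_`.
#' @export
mean_intensity <- function(trace, interval) {
  stopifnot(is.data.frame(trace),
            all(c("time", "intensity_db") %in% names(trace)),
            length(interval) == 2L)
  sel <- trace$time >= interval[1] & trace$time <= interval[2]
  if (!any(sel)) return(NA_real_)
  mean(trace$intensity_db[sel])
}

#' Intensity trace from a raw audio waveform
#'
#' Frames the waveform (10-ms frames by default) and returns
#' `10 * log10` of the mean squared amplitude per frame relative to full
#' scale (amplitude 1).
#'
#' @param audio Numeric waveform.
#' @param fs Sampling rate (Hz).
#' @param frame Frame length (s).
#' @return Data frame `time` (frame centers, s), `intensity_db`.
#' @export
intensity_trace <- function(audio, fs, frame = 0.01) {
  n_frame <- max(1L, round(frame * fs))
  n <- floor(length(audio) / n_frame)
  if (n < 1) stop_invalid("audio shorter than one frame")
  m <- matrix(audio[seq_len(n * n_frame)], nrow = n_frame)
  p <- colMeans(m^2)
  data.frame(time = (seq_len(n) - 0.5) * n_frame / fs,
             intensity_db = 10 * log10(pmax(p, .Machine$double.xmin)))
}

#' Word-locked EMG band power relative to baseline
#'
#' Computes the same per-trial baseline-relative spectral magnitude as the
#' neural pipeline on a single EMG channel, then averages the natural-log
#' relative magnitude over the analysis band (60-200 Hz by default) and over
#' the word interval.
#'
#' @param emg Numeric EMG trace.
#' @param fs EMG sampling rate (Hz).
#' @param interval Word start/end times (s) within the trace.
#' @param band Frequency band (Hz), below the Nyquist frequency.
#' @param cfg [spectral_config()]; its `fs` is overridden by `fs`.
#' @return Scalar log relative band magnitude, or `NA_real_` when the word
#'   lies too close to a recording edge for the trial window.
#' @export
emg_band_rsm <- function(emg, fs, interval, band = c(60, 200),
                         cfg = spectral_config(fs = fs)) {
  stopifnot(length(interval) == 2L, interval[2] > interval[1])
  if (band[2] > fs / 2) stop_invalid("EMG band exceeds the Nyquist frequency")
  cfg <- spectral_config(fs = fs, window = cfg$window, step = cfg$step,
                         n_tapers = cfg$n_tapers, nw = cfg$nw,
                         f_max = min(band[2] + 20, fs / 2),
                         trial_window = cfg$trial_window,
                         baseline_window = cfg$baseline_window)
  rec <- recording(matrix(emg, nrow = 1), fs = fs,
                   channels = data.frame(name = "EMG", label = "emg",
                                         status = "good"))
  sp <- tryCatch(word_spectra(rec, onsets = interval[1], cfg = cfg,
                              reference = FALSE),
                 ecoglex_empty = function(e) NULL)
  if (is.null(sp)) {
    warning("word too close to the recording edge for the trial window; ",
            "EMG value set to missing")
    return(NA_real_)
  }
  fsel <- sp$freq >= band[1] & sp$freq <= band[2]
  tsel <- sp$time >= 0 & sp$time <= (interval[2] - interval[1])
  if (!any(fsel) || !any(tsel)) return(NA_real_)
  mean(sp$log_rsm[1, 1, fsel, tsel])
}
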