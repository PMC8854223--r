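# Synthetic discourse: timed word tokens grouped into clauses and
# pause-delimited speech-production epochs, with the position-in-epoch biases
# seen in spontaneous speech (longer and rarer words occur later in an
# epoch).

FUNCTION_WORDS <- data.frame(
  orthography = c("der", "die", "das", "und", "in", "er", "sie", "zu"),
  pos = c("ART", "ART", "ART", "KON", "APPR", "PPER", "PPER", "APPR"),
  stringsAsFactors = FALSE)

#' Discourse generator configuration
#'
#' Token counts default to mid-range per-subject counts for the three content
#' categories (adverb group, full verbs, normal nouns). Word durations follow
#' `duration_base + duration_slope * NoS + noise`, which induces the strong
#' positive correlation between syllable count and word duration. Pauses of
#' at least 0.2 s delimit speech-production epochs; within-epoch gaps stay
#' strictly below that threshold.
#'
#' @param n_tokens Named integer vector of content-token counts per category
#'   (`ADV`, `FV`, `NN`).
#' @param filler_rate Function-word tokens inserted per content token.
#' @param duration_base,duration_slope,duration_sd Word-duration model (s).
#' @param gap_range Within-epoch inter-word gap range (s), both ends < 0.2.
#' @param pause_rate Mean additional pause duration beyond 0.2 s (s) for the
#'   exponential pause model.
#' @param epoch_size_mean Mean number of tokens per speech epoch.
#' @param position_noise_sd Noise on the syllable-count key used to order
#'   words within an epoch (larger = weaker position bias).
#' @param start_time Onset of the first word (s); leaves room for the
#'   pre-onset trial window.
#' @param seed Optional integer seed.
#' @return List of class `discourse_config`.
#' @export
discourse_config <- function(n_tokens = c(ADV = 110L, FV = 189L, NN = 118L),
                             filler_rate = 0.3,
                             duration_base = 0.12, duration_slope = 0.09,
                             duration_sd = 0.04,
                             gap_range = c(0.03, 0.18),
                             pause_rate = 0.3,
                             epoch_size_mean = 6,
                             position_noise_sd = 1.2,
                             start_time = 2.5,
                             seed = NULL) {
  if (any(n_tokens <= 0)) stop_invalid("token counts must be positive")
  if (gap_range[1] < 0 || gap_range[2] >= 0.2)
    stop_invalid("within-epoch gaps must lie in [0, 0.2) s")
  structure(list(n_tokens = n_tokens, filler_rate = filler_rate,
                 duration_base = duration_base,
                 duration_slope = duration_slope, duration_sd = duration_sd,
                 gap_range = gap_range, pause_rate = pause_rate,
                 epoch_size_mean = epoch_size_mean,
                 position_noise_sd = position_noise_sd,
                 start_time = start_time, seed = seed),
            class = "discourse_config")
}

#' Generate an annotated synthetic discourse
#'
#' Samples content tokens from the lexicon with frequency-proportional
#' probability (so word forms repeat, as in real speech), interleaves
#' function-word fillers, groups tokens into pause-delimited speech epochs
#' and clauses, and assigns onset/offset times. Within an epoch, tokens are
#' ordered by a noisy syllable-count key, which reproduces the tendency of
#' longer, rarer words to occur later in the epoch.
#'
#' @param lexicon An [generate_lexicon()] result.
#' @param config A [discourse_config()].
#' @return A data frame of class `ecoglex_discourse`: one row per token with
#'   columns `token_id`, `orthography`, `lemma`, `pos`, `template`,
#'   `stress_index`, `gesture_count`, `frequency`, `nos`, `cvr`, `eoa`,
#'   `ws`, `we` (word start/end, s), `epoch_id`, `clause_id`, `ss`, `se`,
#'   `cs`, `ce` (enclosing epoch and clause bounds, s).
#' @export
generate_discourse <- function(lexicon, config = discourse_config()) {
  if (!is.data.frame(lexicon) || !nrow(lexicon))
    stop_invalid("lexicon must be a non-empty lexicon data frame")
  stopifnot(inherits(config, "discourse_config"))
  with_seed(config$seed, {
    lex <- as.data.frame(lexicon)
    lex$.category <- content_category(lex$pos)
    rows <- integer(0)
    for (cat in names(config$n_tokens)) {
      pool <- which(lex$.category == cat)
      if (!length(pool))
        stop_invalid("lexicon has no entries of category ", cat)
      rows <- c(rows, sample(pool, config$n_tokens[[cat]], replace = TRUE,
                             prob = lex$frequency[pool]))
    }
    tok <- lex[rows, setdiff(names(lex), c("rank", ".category")),
               drop = FALSE]
    n_fill <- round(config$filler_rate * nrow(tok))
    if (n_fill > 0) {
      fi <- sample(nrow(FUNCTION_WORDS), n_fill, replace = TRUE)
      fill <- data.frame(orthography = FUNCTION_WORDS$orthography[fi],
                         lemma = FUNCTION_WORDS$orthography[fi],
                         pos = FUNCTION_WORDS$pos[fi],
                         template = "CV", stress_index = 0L,
                         gesture_count = 3, frequency = NA_real_,
                         nos = 1, cvr = 1, eoa = NA_real_,
                         stringsAsFactors = FALSE)
      tok <- rbind(tok, fill[, names(tok)])
    }
    tok <- tok[sample(nrow(tok)), , drop = FALSE]
    n <- nrow(tok)

    # epoch memberships
    sizes <- integer(0)
    while (sum(sizes) < n)
      sizes <- c(sizes, 2L + stats::rpois(1, config$epoch_size_mean - 2))
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
    sizes <- sizes[sizes > 0]
    epoch_id <- rep(seq_along(sizes), sizes)

    # within each epoch, order tokens by noisy syllable count: longer and
    # rarer words drift towards the epoch end
    ord <- unlist(lapply(split(seq_len(n), epoch_id), function(idx) {
      key <- tok$nos[idx] + stats::rnorm(length(idx), 0,
                                         config$position_noise_sd)
      idx[order(key)]
    }), use.names = FALSE)
    tok <- tok[ord, , drop = FALSE]

    dur <- pmax(0.06, config$duration_base +
                  config$duration_slope * tok$nos +
                  stats::rnorm(n, 0, config$duration_sd))
    gap <- stats::runif(n, config$gap_range[1], config$gap_range[2])
    new_epoch <- c(FALSE, diff(epoch_id) != 0)
    gap[new_epoch] <- 0.2 + stats::rexp(sum(new_epoch), 1 / config$pause_rate)
    gap[1] <- 0
    ws <- config$start_time + cumsum(gap) + cumsum(c(0, dur[-n]))
    we <- ws + dur

    # clauses: contiguous runs within an epoch
    clause_id <- integer(n)
    cid <- 0L
    for (e in unique(epoch_id)) {
      idx <- which(epoch_id == e)
      left <- length(idx)
      pos <- 1L
      while (left > 0) {
        csize <- min(left, 1L + stats::rpois(1, 2))
        cid <- cid + 1L
        clause_id[idx[pos:(pos + csize - 1L)]] <- cid
        pos <- pos + csize
        left <- left - csize
      }
    }

    tok$token_id <- seq_len(n)
    tok$ws <- ws
    tok$we <- we
    tok$epoch_id <- epoch_id
    tok$clause_id <- clause_id
    tok$ss <- stats::ave(ws, epoch_id, FUN = min)
    tok$se <- stats::ave(we, epoch_id, FUN = max)
    tok$cs <- stats::ave(ws, clause_id, FUN = min)
    tok$ce <- stats::ave(we, clause_id, FUN = max)
    rownames(tok) <- NULL
    first <- c("token_id", "orthography", "lemma", "pos", "ws", "we",
               "epoch_id", "clause_id", "ss", "se", "cs", "ce")
    tok <- tok[, c(first, setdiff(names(tok), first))]
    structure(tok, class = c("ecoglex_discourse", "data.frame"),
              config = config)
  })
}

#' @export
print.ecoglex_discourse <- function(x, ...) {
  cat("<ecoglex_discourse> ", nrow(x), " tokens, ",
      length(unique(x$epoch_id)), " speech epochs, ",
      length(unique(x$clause_id)), " clauses, span ",
      sprintf("%.1f", max(x$se) - min(x$ss)), " s\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)[
    , c("token_id", "orthography", "pos", "ws", "we", "epoch_id",
        "clause_id")], 6))
  invisible(x)
}

#' Synthesize per-token covariates (acoustic intensity, EMG)
#'
#' Mean acoustic intensity per word is generated in dB with the empirically
#' observed negative correlation with the word's distance from speech start.
#' An EMG trace is returned as broadband noise, optionally with word-locked
#' bursts of configurable gain.
#'
#' @param discourse An [generate_discourse()] result.
#' @param seed Optional integer seed.
#' @param base_db,slope_db_per_s,noise_db Intensity model: `base_db +
#'   slope_db_per_s * (ws - ss) + noise` (slope negative by default).
#' @param emg_fs EMG sampling rate (Hz).
#' @param emg_burst_gain Amplitude gain of word-locked EMG bursts (0 =
#'   none).
#' @return List with `intensity` (data frame `token_id`, `intensity_db`),
#'   `emg` (numeric trace) and `emg_fs`.
#' @export
synthesize_covariates <- function(discourse, seed = NULL,
                                  base_db = 66, slope_db_per_s = -2.5,
                                  noise_db = 2, emg_fs = 1024,
                                  emg_burst_gain = 0) {
  if (!is.data.frame(discourse) || !nrow(discourse))
    stop_invalid("discourse must be a non-empty token table")
  with_seed(seed, {
    ss_ws <- discourse$ws - discourse$ss
    intensity <- base_db + slope_db_per_s * ss_ws +
      stats::rnorm(nrow(discourse), 0, noise_db)
    n_samp <- ceiling((max(discourse$se) + 1) * emg_fs)
    emg <- stats::rnorm(n_samp)
    if (emg_burst_gain > 0) {
      for (i in seq_len(nrow(discourse))) {
        i0 <- max(1L, round(discourse$ws[i] * emg_fs))
        i1 <- min(n_samp, round(discourse$we[i] * emg_fs))
        emg[i0:i1] <- emg[i0:i1] * (1 + emg_burst_gain)
      }
    }
    list(intensity = data.frame(token_id = discourse$token_id,
                                intensity_db = intensity),
         emg = emg, emg_fs = emg_fs)
  })
}
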