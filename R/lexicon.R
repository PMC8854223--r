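# Synthetic lexicon generation: Zipfian lemma frequencies plus abstract
# C*V+C* syllable templates whose structure induces the collinearity pattern
# observed in spontaneous-speech word material (frequent words shorter and
# easier to articulate; polysyllabic words with proportionally fewer
# consonants).

CONSONANTS <- c("b","d","f","g","k","l","m","n","p","r","s","t","v","z")
VOWELS <- c("a","e","i","o","u")

# Vectorized complexity features from template columns. `df` needs columns
# template, stress_index, gesture_count.
word_features <- function(df, weights = eoa_weights()) {
  tpl <- df$template
  nos <- vapply(strsplit(tpl, ".", fixed = TRUE), length, integer(1))
  cons <- nchar(gsub("[^C]", "", tpl))
  vows <- nchar(gsub("[^V]", "", tpl))
  clus <- vapply(strsplit(tpl, ".", fixed = TRUE), function(parts) {
    sum(vapply(parts, function(p) {
      runs <- regmatches(p, gregexpr("C{2,}", p))[[1]]
      length(runs)
    }, numeric(1)))
  }, numeric(1))
  eoa <- weights$intercept -
    weights$w_metric * as.numeric(df$stress_index > 0) -
    weights$w_cluster * clus -
    weights$w_gesture * df$gesture_count
  data.frame(nos = nos, cvr = cons / vows, eoa = eoa)
}

sample_template <- function(nos, rarity = 0) {
  # consonant load per syllable decreases with syllable count, which makes
  # the consonant-to-vowel ratio anticorrelated with syllable count
  key <- as.character(nos)
  onset_p <- switch(key,
                    `1` = c(0.10, 0.50, 0.40),
                    `2` = c(0.25, 0.55, 0.20),
                    `3` = c(0.40, 0.52, 0.08))
  coda_p <- switch(key,
                   `1` = c(0.15, 0.50, 0.35),
                   `2` = c(0.55, 0.35, 0.10),
                   `3` = c(0.75, 0.22, 0.03))
  # rarer words carry heavier consonant structure: probability mass moves
  # from the cluster-free to the cluster outcome
  shift <- 0.35 * rarity
  onset_p <- onset_p + c(-min(shift, onset_p[1]), 0, min(shift, onset_p[1]))
  coda_p <- coda_p + c(-min(shift, coda_p[1]), 0, min(shift, coda_p[1]))
  syl <- character(nos)
  onsets <- integer(nos)
  codas <- integer(nos)
  for (i in seq_len(nos)) {
    onsets[i] <- sample(0:2, 1, prob = onset_p)
    # only the final syllable may carry a coda cluster; medial codas stay light
    codas[i] <- if (i == nos) sample(0:2, 1, prob = coda_p)
                else sample(0:1, 1, prob = c(0.7, 0.3))
  }
  # content words virtually never lack consonants entirely; force one onset
  # so the consonant-to-vowel ratio never hits exactly zero
  if (sum(onsets) + sum(codas) == 0) onsets[1] <- 1L
  for (i in seq_len(nos)) {
    nuc <- sample(1:2, 1, prob = c(0.9, 0.1)) # occasional diphthong
    syl[i] <- paste0(strrep("C", onsets[i]), strrep("V", nuc),
                     strrep("C", codas[i]))
  }
  paste(syl, collapse = ".")
}

orthography_from_template <- function(template, rank) {
  chars <- strsplit(gsub(".", "", template, fixed = TRUE), "")[[1]]
  letters <- vapply(chars, function(ch)
    if (ch == "C") sample(CONSONANTS, 1) else sample(VOWELS, 1), character(1))
  paste0(paste(letters, collapse = ""), rank)
}

#' Generate a synthetic lexicon
#'
#' Lemma frequencies follow a Zipf law, `f(rank) = rank^-zipf_exponent` up to
#' normalization (frequencies sum to 1). Syllable structures are sampled so
#' that rarer words tend to have more syllables and heavier consonant
#' structure; this induces the empirically observed sign pattern among the
#' complexity parameters (ease-of-articulation positively correlated with
#' frequency, both negatively with syllable count, consonant-to-vowel ratio
#' negatively with syllable count).
#'
#' @param n_words Number of entries (>= 1).
#' @param zipf_exponent Zipf exponent (> 0).
#' @param seed Optional integer seed; fixed seed gives identical lexicons.
#' @param weights [eoa_weights()] used for the `eoa` column.
#' @param nos_rank_gradient How strongly the expected syllable count grows
#'   with log frequency rank (0 = no frequency-length relation). The
#'   default reproduces the usual strong inverse frequency-length law;
#'   smaller values decouple syllable count from frequency, which is useful
#'   for constructing controlled collinearity scenarios.
#' @return A data frame of class `ecoglex_lexicon` with columns `rank`,
#'   `orthography`, `lemma`, `pos`, `template`, `stress_index`,
#'   `gesture_count`, `frequency`, `nos`, `cvr`, `eoa`.
#' @examples
#' lex <- generate_lexicon(50, seed = 1)
#' head(lex)
#' @export
generate_lexicon <- function(n_words, zipf_exponent = 1, seed = NULL,
                             weights = eoa_weights(),
                             nos_rank_gradient = 0.6) {
  if (!is.numeric(n_words) || n_words < 1)
    stop_invalid("n_words must be a positive count")
  if (!is.numeric(zipf_exponent) || zipf_exponent <= 0)
    stop_invalid("zipf_exponent must be positive")
  n_words <- as.integer(n_words)
  with_seed(seed, {
    rank <- seq_len(n_words)
    freq <- rank^(-zipf_exponent)
    freq <- freq / sum(freq)
    # rarer words get more syllables (log-rank-driven), so that log frequency
    # and syllable count are negatively correlated
    q <- if (n_words > 1) (log(rank) - log(1)) / (log(n_words) - log(1)) else 0
    p3 <- pmin(0.9, pmax(0.05, 0.12 + nos_rank_gradient * q))
    nos <- 1L + stats::rbinom(n_words, 2L, p3)
    template <- vapply(seq_len(n_words), function(i)
      sample_template(nos[i], rarity = q[i]), character(1))
    # rarer words more often carry non-initial stress
    raw_stress <- sample(1:2, n_words, replace = TRUE)
    stress_index <- ifelse(nos > 1L & stats::runif(n_words) < 0.15 + 0.35 * q,
                           pmin(raw_stress, nos - 1L), 0L)
    pos <- sample(c("FV", "NN", "ADV", "ADJD", "PWAV", "PAV"), n_words,
                  replace = TRUE,
                  prob = c(0.40, 0.33, 0.15, 0.06, 0.03, 0.03))
    orthography <- vapply(seq_len(n_words), function(i)
      orthography_from_template(template[i], rank[i]), character(1))
    df <- data.frame(rank = rank, orthography = orthography,
                     lemma = orthography, pos = pos, template = template,
                     stress_index = stress_index, gesture_count = NA_real_,
                     frequency = freq, stringsAsFactors = FALSE)
    cons <- nchar(gsub("[^C]", "", template))
    df$gesture_count <- cons + nos + 1
    df <- cbind(df, word_features(df, weights))
    structure(df, class = c("ecoglex_lexicon", "data.frame"),
              zipf_exponent = zipf_exponent, seed = seed)
  })
}

#' @export
print.ecoglex_lexicon <- function(x, ...) {
  cat("<ecoglex_lexicon> ", nrow(x), " entries, zipf exponent ",
      attr(x, "zipf_exponent"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

#' Frequency lexicon view of a synthetic lexicon
#'
#' Returns the (lemma, pos, frequency) table consumed by
#' [lookup_frequency()].
#'
#' @param lexicon An `ecoglex_lexicon`.
#' @return Data frame with columns `lemma`, `pos`, `frequency`.
#' @export
frequency_lexicon <- function(lexicon) {
  data.frame(lemma = lexicon$lemma, pos = lexicon$pos,
             frequency = lexicon$frequency, stringsAsFactors = FALSE)
}
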