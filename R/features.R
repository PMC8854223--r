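# Word-complexity parameters: NoS, CVR, EoA, FRQ, plus content-word
# selection and the log transform applied before every correlation analysis.

#' Construct a word type
#'
#' A `word_type` is a lexical entry carrying the phonological decomposition
#' needed by the complexity measures: an ordered list of syllables (onset /
#' nucleus / coda segment counts), the position of the stressed syllable, and
#' an articulatory gesture count.
#'
#' @param orthography Word form (character scalar).
#' @param lemma Lemma (defaults to the orthography).
#' @param pos Part-of-speech tag. Content categories are `"FV"` (full verb),
#'   `"NN"` (normal noun) and the adverb group `"ADV"`, `"ADJD"`, `"PWAV"`,
#'   `"PAV"`; other tags are permitted but dropped by
#'   [select_content_words()].
#' @param syllables Either a template string such as `"CV.CCVC"` (syllables
#'   separated by `"."`, `C` = consonant, `V` = vowel) or a list of lists with
#'   elements `onset`, `nucleus`, `coda` (non-negative counts,
#'   `nucleus >= 1`).
#' @param stress_index 0-based index of the stressed syllable.
#' @param gesture_count Number of articulatory gestures. If `NULL`, derived
#'   as one gesture per consonant plus one per syllable nucleus plus one
#'   word-level (glottal/velic) gesture.
#' @return An object of class `word_type`.
#' @examples
#' w <- word_type("banane", pos = "NN", syllables = "CV.CV.CV", stress_index = 1)
#' count_syllables(w)
#' consonant_vowel_ratio(w)
#' @export
word_type <- function(orthography, lemma = orthography, pos = "NN",
                      syllables = "CV", stress_index = 0L,
                      gesture_count = NULL) {
  syl <- if (is.character(syllables)) parse_syllables(syllables) else syllables
  if (length(syl) < 1L) stop_invalid("a word must have at least one syllable")
  for (s in syl) {
    if (is.null(s$nucleus) || s$nucleus < 1L)
      stop_invalid("every syllable needs a vocalic nucleus (nucleus >= 1)")
    if (s$onset < 0L || s$coda < 0L)
      stop_invalid("negative segment counts are not allowed")
  }
  if (stress_index < 0L || stress_index >= length(syl))
    stop_invalid("stress_index must name an existing syllable (0-based)")
  if (is.null(gesture_count))
    gesture_count <- sum(vapply(syl, function(s) s$onset + s$coda, numeric(1))) +
      length(syl) + 1L
  if (gesture_count < length(syl))
    stop_invalid("gesture_count cannot be smaller than the syllable count")
  structure(list(orthography = orthography, lemma = lemma, pos = pos,
                 syllables = syl, stress_index = as.integer(stress_index),
                 gesture_count = gesture_count),
            class = "word_type")
}

#' Parse a syllable template string
#'
#' Template syntax: syllables separated by `"."`, each syllable a string of
#' `C` (consonant) and `V` (vowel) in onset-nucleus-coda order, e.g.
#' `"CCVC.CV"`. The nucleus is the maximal central run of `V`s; a `"VV"`
#' nucleus counts two vowel segments.
#'
#' @param template Template string.
#' @return List of syllables, each `list(onset, nucleus, coda)`.
#' @export
parse_syllables <- function(template) {
  stopifnot(is.character(template), length(template) == 1L)
  parts <- strsplit(template, ".", fixed = TRUE)[[1]]
  if (!length(parts)) stop_invalid("empty syllable template")
  lapply(parts, function(p) {
    if (!grepl("^C*V+C*$", p))
      stop_invalid("syllable '", p, "' is not of the form C*V+C*")
    chars <- strsplit(p, "")[[1]]
    v <- which(chars == "V")
    list(onset = v[1] - 1L, nucleus = length(v),
         coda = length(chars) - v[length(v)])
  })
}

#' Number of spoken syllables (NoS)
#'
#' @param word A [word_type()].
#' @return Integer syllable count.
#' @export
count_syllables <- function(word) {
  stopifnot(inherits(word, "word_type"))
  if (!length(word$syllables)) stop_invalid("word has no syllables")
  length(word$syllables)
}

#' Consonant-to-vowel ratio (CVR)
#'
#' The number of consonant segments divided by the number of vowel segments
#' of the spoken word (phonological, not orthographic, counts).
#'
#' @param word A [word_type()].
#' @return Dimensionless ratio (0 for vowel-only words).
#' @export
consonant_vowel_ratio <- function(word) {
  stopifnot(inherits(word, "word_type"))
  cons <- sum(vapply(word$syllables, function(s) s$onset + s$coda, numeric(1)))
  vows <- sum(vapply(word$syllables, function(s) s$nucleus, numeric(1)))
  cons / vows
}

#' Ease-of-articulation weights
#'
#' Penalty weights for the ease-of-articulation score: a linear model over
#' the three factor families known to predict articulation errors — the
#' metrical (stress) pattern, complex constrictions (consonant clusters of
#' size >= 2), and the number of articulatory gestures. The defaults produce
#' the expected sign structure among the complexity parameters; they are not
#' fitted coefficients and can be replaced wholesale (see
#' [read_eoa_weights()]).
#'
#' @param intercept Baseline score for a maximally easy word.
#' @param w_metric Penalty applied when stress is not word-initial.
#' @param w_cluster Penalty per consonant cluster of size >= 2.
#' @param w_gesture Penalty per articulatory gesture.
#' @return An object of class `eoa_weights`.
#' @export
eoa_weights <- function(intercept = 10, w_metric = 1, w_cluster = 1,
                        w_gesture = 0.25) {
  w <- list(intercept = intercept, w_metric = w_metric,
            w_cluster = w_cluster, w_gesture = w_gesture)
  if (!all(vapply(w, function(x) is.numeric(x) && is.finite(x), logical(1))))
    stop_invalid("all ease-of-articulation weights must be finite numbers")
  structure(w, class = "eoa_weights")
}

# number of consonant clusters (onset or coda runs of size >= 2)
cluster_count <- function(word) {
  sum(vapply(word$syllables,
             function(s) (s$onset >= 2) + (s$coda >= 2), numeric(1)))
}

#' Ease-of-articulation score (EoA)
#'
#' A high score reflects greater ease of articulation; each penalty term
#' (non-initial stress, consonant clusters, articulatory gestures) lowers it.
#' The score is defined for words of at most three syllables.
#'
#' @param word A [word_type()].
#' @param weights An [eoa_weights()] object.
#' @return Numeric score.
#' @export
ease_of_articulation <- function(word, weights = eoa_weights()) {
  stopifnot(inherits(word, "word_type"), inherits(weights, "eoa_weights"))
  nos <- count_syllables(word)
  if (nos > 3L)
    stop_invalid("the ease-of-articulation model is undefined for words of ",
                 "more than three syllables (got ", nos, ")")
  weights$intercept -
    weights$w_metric * as.numeric(word$stress_index > 0L) -
    weights$w_cluster * cluster_count(word) -
    weights$w_gesture * word$gesture_count
}

#' Look up a PoS-disambiguated lemma frequency
#'
#' Frequencies are keyed by (lemma, PoS class) so that homographs of a
#' different category do not contaminate the value; e.g. for the German lemma
#' "sein" the verb reading and the possessive-pronoun reading are kept apart,
#' and a verb lookup sums only the verbal (finite + non-finite)
#' sub-entries. A missing (lemma, class) pair yields `NA` — the token is then
#' excluded from downstream correlation analyses rather than imputed as zero.
#'
#' @param lemma Lemma string.
#' @param pos PoS tag of the token (mapped to a coarse class, see
#'   [pos_class()]).
#' @param lexicon A frequency lexicon: data frame with columns `lemma`,
#'   `pos` (tag or class) and `frequency`; see [read_frequency_lexicon()].
#' @return Numeric frequency, or `NA_real_` when the pair is absent.
#' @export
lookup_frequency <- function(lemma, pos, lexicon) {
  stopifnot(is.data.frame(lexicon),
            all(c("lemma", "pos", "frequency") %in% names(lexicon)))
  if (any(lexicon$frequency < 0, na.rm = TRUE))
    stop_invalid("frequency lexicon contains negative frequencies")
  cls <- pos_class(pos)
  hit <- lexicon$lemma == lemma & pos_class(lexicon$pos) == cls
  if (!any(hit)) return(NA_real_)
  sum(lexicon$frequency[hit])
}

#' Map a PoS tag to its coarse class
#'
#' Verbal tags map to `"verb"`, nominal tags to `"noun"`, the adverb group
#' (`ADV`, `ADJD`, `PWAV`, `PAV`) to `"adverb"`, pronouns to `"pronoun"`;
#' anything else maps to itself (lower-cased).
#'
#' @param pos Character vector of tags.
#' @return Character vector of classes.
#' @export
pos_class <- function(pos) {
  map <- c(FV = "verb", VVFIN = "verb", VVINF = "verb", VAFIN = "verb",
           verb = "verb",
           NN = "noun", NE = "noun", noun = "noun",
           ADV = "adverb", ADJD = "adverb", PWAV = "adverb", PAV = "adverb",
           adverb = "adverb",
           PPOSAT = "pronoun", PPER = "pronoun", pronoun = "pronoun")
  out <- unname(map[pos])
  out[is.na(out)] <- tolower(pos[is.na(out)])
  out
}

# content-word category of a tag: "FV", "NN", "ADV" (the adverb group), or NA
content_category <- function(pos) {
  out <- rep(NA_character_, length(pos))
  out[pos == "FV"] <- "FV"
  out[pos == "NN"] <- "NN"
  out[pos %in% c("ADV", "ADJD", "PWAV", "PAV")] <- "ADV"
  out
}

#' Select and deduplicate content words
#'
#' Keeps only tokens of the content categories (full verbs, normal nouns and
#' the adverb group), drops words longer than three syllables (outside the
#' domain of the ease-of-articulation model), and keeps only the
#' chronologically first occurrence of each word form within its category.
#' Chronological order within each category is preserved.
#'
#' @param tokens Data frame of timed word tokens with at least columns
#'   `orthography`, `pos` and `ws` (word start, s). A `nos` column (syllable
#'   count) is used for the three-syllable cap when present.
#' @return The filtered token data frame, rows ordered by category then time.
#' @export
select_content_words <- function(tokens) {
  stopifnot(is.data.frame(tokens),
            all(c("orthography", "pos", "ws") %in% names(tokens)))
  tokens$.category <- content_category(tokens$pos)
  tokens <- tokens[!is.na(tokens$.category), , drop = FALSE]
  if (!nrow(tokens)) {
    tokens$.category <- NULL
    return(tokens)
  }
  # chronological order within category is a contract of the input
  for (cat in unique(tokens$.category)) {
    ws <- tokens$ws[tokens$.category == cat]
    if (is.unsorted(ws)) stop_invalid("tokens of category ", cat,
                                      " are not in chronological order")
  }
  if (!is.null(tokens$nos)) tokens <- tokens[tokens$nos <= 3L, , drop = FALSE]
  keep <- !duplicated(tokens[, c(".category", "orthography")])
  tokens <- tokens[keep, , drop = FALSE]
  tokens <- tokens[order(match(tokens$.category, c("ADV", "FV", "NN")),
                         tokens$ws), , drop = FALSE]
  tokens$.category <- NULL
  rownames(tokens) <- NULL
  tokens
}

#' Natural-log transform with a small offset
#'
#' Every parameter entering a correlation analysis is rendered on a natural
#' logarithmic scale; an offset (default 0.001) is added first so that zeros
#' map to a finite value instead of minus infinity.
#'
#' @param values Non-negative numeric vector (`NA` passed through).
#' @param offset Offset added before taking the log.
#' @return `log(values + offset)`.
#' @export
log_transform <- function(values, offset = 0.001) {
  stopifnot(is.numeric(values))
  if (any(values < 0, na.rm = TRUE))
    stop_invalid("log_transform expects non-negative values")
  log(values + offset)
}

#' @export
print.word_type <- function(x, ...) {
  tpl <- vapply(x$syllables, function(s)
    paste0(strrep("C", s$onset), strrep("V", s$nucleus), strrep("C", s$coda)),
    character(1))
  cat("<word_type> ", x$orthography, " [", x$pos, "] ",
      paste(tpl, collapse = "."),
      " stress=", x$stress_index, " gestures=", x$gesture_count, "\n", sep = "")
  invisible(x)
}
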