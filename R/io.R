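# Interchange formats: tabular TSV for annotations/lexicons/effects,
# Praat-style TextGrid interval tiers for annotations, JSON for effect
# specifications and pipeline configuration, and R's native serialization
# for recordings and spectra.

#' Write / read token annotations
#'
#' Two dialects are supported. `"tsv"`: a tab-separated table with columns
#' `token_id`, `orthography`, `pos`, `onset_s`, `offset_s`, `epoch_id`,
#' `clause_id` (columns named `onset_ms` / `offset_ms` are accepted on read
#' and converted to seconds). `"textgrid"`: a Praat TextGrid (long text
#' format) with interval tiers `words` (label `orthography|pos`), `clauses`
#' and `epochs`. Reading a written discourse reproduces the token timing,
#' grouping and labels; overlapping word intervals are a parse error.
#'
#' @param discourse Token table (e.g. from [generate_discourse()]).
#' @param path Output file.
#' @param dialect `"tsv"` or `"textgrid"`.
#' @return `write_annotations` the path, invisibly; `read_annotations` a
#'   token data frame with columns `token_id`, `orthography`, `pos`, `ws`,
#'   `we`, `epoch_id`, `clause_id`, `ss`, `se`, `cs`, `ce`.
#' @export
write_annotations <- function(discourse, path, dialect = c("tsv", "textgrid")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- data.frame(token_id = discourse$token_id,
                      orthography = discourse$orthography,
                      pos = discourse$pos,
                      onset_s = discourse$ws, offset_s = discourse$we,
                      epoch_id = discourse$epoch_id,
                      clause_id = discourse$clause_id)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  xmax <- max(discourse$se) + 1
  tier <- function(name, starts, ends, labels) {
    c(sprintf("    item []:"),
      sprintf("        class = \"IntervalTier\""),
      sprintf("        name = \"%s\"", name),
      sprintf("        xmin = 0"),
      sprintf("        xmax = %.6f", xmax),
      sprintf("        intervals: size = %d", length(starts)),
      unlist(lapply(seq_along(starts), function(i)
        c(sprintf("        intervals [%d]:", i),
          sprintf("            xmin = %.6f", starts[i]),
          sprintf("            xmax = %.6f", ends[i]),
          sprintf("            text = \"%s\"", labels[i])))))
  }
  cl <- discourse[!duplicated(discourse$clause_id), ]
  ep <- discourse[!duplicated(discourse$epoch_id), ]
  lines <- c("File type = \"ooTextFile\"", "Object class = \"TextGrid\"", "",
             "xmin = 0", sprintf("xmax = %.6f", xmax),
             "tiers? <exists>", "size = 3", "item []:",
             tier("words", discourse$ws, discourse$we,
                  paste(discourse$orthography, discourse$pos, sep = "|")),
             tier("clauses", cl$cs, cl$ce, paste0("c", cl$clause_id)),
             tier("epochs", ep$ss, ep$se, paste0("e", ep$epoch_id)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, dialect = c("tsv", "textgrid")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    if ("onset_ms" %in% names(tab)) tab$onset_s <- tab$onset_ms / 1000
    if ("offset_ms" %in% names(tab)) tab$offset_s <- tab$offset_ms / 1000
    need <- c("orthography", "pos", "onset_s", "offset_s")
    if (!all(need %in% names(tab)))
      stop_invalid("annotation TSV must provide columns ",
                   paste(need, collapse = ", "))
    ord <- order(tab$onset_s)
    tab <- tab[ord, , drop = FALSE]
    if (any(tab$onset_s[-1] < tab$offset_s[-nrow(tab)] - 1e-9))
      stop_invalid("parse error: overlapping word intervals in ", path)
    seg <- segment_speech_epochs(tab$onset_s, tab$offset_s)
    out <- data.frame(token_id = if ("token_id" %in% names(tab)) tab$token_id
                                 else seq_len(nrow(tab)),
                      orthography = tab$orthography, pos = tab$pos,
                      ws = tab$onset_s, we = tab$offset_s,
                      epoch_id = if ("epoch_id" %in% names(tab)) tab$epoch_id
                                 else seg$epoch_id,
                      clause_id = if ("clause_id" %in% names(tab))
                                    tab$clause_id else seg$epoch_id,
                      stringsAsFactors = FALSE)
  } else {
    out <- read_textgrid_tokens(path)
  }
  out$ss <- stats::ave(out$ws, out$epoch_id, FUN = min)
  out$se <- stats::ave(out$we, out$epoch_id, FUN = max)
  out$cs <- stats::ave(out$ws, out$clause_id, FUN = min)
  out$ce <- stats::ave(out$we, out$clause_id, FUN = max)
  rownames(out) <- NULL
  out
}

# minimal long-format TextGrid interval-tier parser
read_textgrid_tiers <- function(path) {
  lines <- readLines(path)
  num <- function(l) as.numeric(sub(".*= *", "", l))
  str <- function(l) gsub("\"", "", sub(".*= *", "", l))
  tiers <- list()
  i <- 1
  cur <- NULL
  while (i <= length(lines)) {
    l <- trimws(lines[i])
    if (grepl("^class = \"IntervalTier\"", l)) {
      if (!is.null(cur)) tiers[[cur$name]] <- cur
      cur <- list(name = NULL, xmin = numeric(0), xmax = numeric(0),
                  text = character(0))
    } else if (!is.null(cur) && grepl("^name =", l)) {
      cur$name <- str(l)
    } else if (!is.null(cur) && grepl("^intervals \\[", l)) {
      if (i + 3 > length(lines))
        stop_invalid("parse error: truncated interval near line ", i,
                     " of ", path)
      cur$xmin <- c(cur$xmin, num(trimws(lines[i + 1])))
      cur$xmax <- c(cur$xmax, num(trimws(lines[i + 2])))
      cur$text <- c(cur$text, str(trimws(lines[i + 3])))
      i <- i + 3
    }
    i <- i + 1
  }
  if (!is.null(cur)) tiers[[cur$name]] <- cur
  tiers
}

read_textgrid_tokens <- function(path) {
  tiers <- read_textgrid_tiers(path)
  if (!all(c("words", "clauses", "epochs") %in% names(tiers)))
    stop_invalid("parse error: TextGrid must contain tiers 'words', ",
                 "'clauses', 'epochs' (", path, ")")
  w <- tiers$words
  ord <- order(w$xmin)
  w$xmin <- w$xmin[ord]; w$xmax <- w$xmax[ord]; w$text <- w$text[ord]
  if (any(w$xmin[-1] < w$xmax[-length(w$xmax)] - 1e-9))
    stop_invalid("parse error: overlapping word intervals in tier 'words'")
  parts <- strsplit(w$text, "|", fixed = TRUE)
  mids <- (w$xmin + w$xmax) / 2
  locate <- function(tier) {
    id <- integer(length(mids))
    for (k in seq_along(tier$xmin))
      id[mids >= tier$xmin[k] & mids <= tier$xmax[k]] <- k
    if (any(id == 0))
      stop_invalid("parse error: word interval outside every '",
                   tier$name %||% "", "' interval")
    id
  }
  data.frame(token_id = seq_along(mids),
             orthography = vapply(parts, `[`, character(1), 1),
             pos = vapply(parts, function(p)
               if (length(p) > 1) p[2] else NA_character_, character(1)),
             ws = w$xmin, we = w$xmax,
             epoch_id = locate(tiers$epochs),
             clause_id = locate(tiers$clauses),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a lexicon as TSV
#'
#' @param lexicon A lexicon data frame ([generate_lexicon()]).
#' @param path File path.
#' @return The path (write) or a lexicon data frame (read), invisibly for
#'   write.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(as.data.frame(lexicon), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(df, class = c("ecoglex_lexicon", "data.frame"))
}

#' Read a lemma-frequency lexicon from TSV
#'
#' Expects columns `lemma`, `pos`, `frequency`; sub-entries (several rows
#' per lemma/PoS-class pair) are allowed and summed by
#' [lookup_frequency()].
#'
#' @param path File path.
#' @return Data frame with the three columns.
#' @export
read_frequency_lexicon <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("lemma", "pos", "frequency") %in% names(df)))
    stop_invalid("frequency lexicon needs columns lemma, pos, frequency")
  df
}

#' Read ease-of-articulation weights from a JSON config
#'
#' @param path JSON file with fields `intercept`, `w_metric`, `w_cluster`,
#'   `w_gesture`.
#' @return An [eoa_weights()] object.
#' @export
read_eoa_weights <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  eoa_weights(intercept = x$intercept, w_metric = x$w_metric,
              w_cluster = x$w_cluster, w_gesture = x$w_gesture)
}

#' Write / read effect specifications as JSON
#'
#' @param effects List of [effect_spec()] objects.
#' @param path JSON file path.
#' @return The path (write) or a list of `effect_spec` objects (read).
#' @export
write_effect_specs <- function(effects, path) {
  jsonlite::write_json(lapply(effects, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_effect_specs
#' @export
read_effect_specs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i)
    effect_spec(channel = raw$channel[i], parameter = raw$parameter[i],
                band = unlist(raw$band[i]), window = unlist(raw$window[i]),
                r = raw$r[i], sign = raw$sign[i]))
}

#' Write an effect table as TSV
#'
#' The machine-readable per-effect summary: subject, parameter, channel,
#' time and frequency extents, sign, band, reported threshold and (when
#' present) the pre/post-residualization match flag.
#'
#' @param effects An `effect_table`.
#' @param path File path.
#' @param subject Subject identifier recorded in the first column.
#' @return The path, invisibly.
#' @export
write_effects <- function(effects, path, subject = "S1") {
  df <- as.data.frame(effects)
  df <- cbind(subject = rep(subject, nrow(df)), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a recording
#'
#' Recordings (and any other pipeline object) are persisted with R's native
#' serialization.
#'
#' @param rec An [recording()].
#' @param path File path.
#' @return The path (save) or the recording (load).
#' @export
save_recording <- function(rec, path) {
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname save_recording
#' @export
load_recording <- function(path) readRDS(path)
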