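# End-to-end orchestration: synthetic study -> features -> spectra ->
# neurocorrelation (pre) -> residualization -> neurocorrelation (post) ->
# effect extraction and pre/post matching.

#' Pipeline configuration
#'
#' Bundles every stage's settings with their standard defaults: 200-ms/20-ms
#' multitaper windows with 5 tapers, trials of [-2, 3] s around word onset
#' with a [-2, -1.8] s baseline, FDR and Bonferroni levels q = 0.05, the
#' 0.001 log offset, the 0.2-s pause rule, the 0.4 strong-correlation cut,
#' the 5e-6 ladder cap, the 40-ms/20-Hz effect-overlap criteria and the
#' alpha (5-10 Hz) / beta (15-30 Hz) / gamma (> 35 Hz) bands.
#'
#' @param n_words Synthetic lexicon size.
#' @param zipf_exponent Zipf exponent of the lemma-frequency distribution.
#' @param discourse A [discourse_config()].
#' @param effects List of [effect_spec()] objects to inject.
#' @param n_channels,fs Recording geometry.
#' @param n_trials Number of selected content-word trials analyzed (`NULL` =
#'   all available).
#' @param parameters Parameters to neurocorrelate.
#' @param cfg [spectral_config()] for the spectral stage.
#' @param focal_f_max,focal_margin Focalized analysis window: frequency cap
#'   (Hz) and margin (s) around the mean speech epoch.
#' @param q Bonferroni level for the correlation maps.
#' @param alpha Pairwise-significance level for collinearity/predictor
#'   selection.
#' @param ladder A [threshold_ladder()].
#' @param seed Integer master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_words = 400, zipf_exponent = 1,
                            discourse = discourse_config(),
                            effects = list(), n_channels = 16, fs = 1024,
                            n_trials = NULL,
                            parameters = c("FRQ", "EoA", "CVR", "NoS"),
                            cfg = NULL, focal_f_max = 150,
                            focal_margin = 0.5, q = 0.05, alpha = 0.05,
                            ladder = threshold_ladder(), seed = 1) {
  if (is.null(cfg)) cfg <- spectral_config(fs = fs, f_max = min(300, fs / 2))
  structure(list(n_words = n_words, zipf_exponent = zipf_exponent,
                 discourse = discourse, effects = effects,
                 n_channels = n_channels, fs = fs, n_trials = n_trials,
                 parameters = parameters, cfg = cfg,
                 focal_f_max = focal_f_max, focal_margin = focal_margin,
                 q = q, alpha = alpha, ladder = ladder, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Generates a lexicon, discourse and recording (with any configured
#' injected effects), selects and deduplicates content words, assembles the
#' log-scale parameter table, computes word-aligned log-RSM spectra
#' (common-average referenced), restricts them to the focalized window,
#' computes pre-residualization neurocorrelation maps, residualizes every
#' parameter on its significant correlates, re-correlates, extracts
#' Bonferroni-significant effect clusters from both passes and matches them.
#' Deterministic for a fixed config (including its seed).
#'
#' @param config A [pipeline_config()].
#' @return Object of class `ecoglex_results`: lexicon, tokens, parameter
#'   table, correlation matrix, pre/post maps and effect tables, matches,
#'   config and a provenance hash.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(
        class = c("ecoglex_stage_error", "error", "condition"),
        list(message = paste0("pipeline stage '", name, "' failed: ",
                              conditionMessage(e)),
             call = NULL, stage = name)))
    })
  }
  dc <- config$discourse
  dc$seed <- dc$seed %||% derive_seed(config$seed, 2)
  lexicon <- stage("synthetic_data",
                   generate_lexicon(config$n_words, config$zipf_exponent,
                                    seed = derive_seed(config$seed, 1)))
  discourse <- stage("synthetic_data", generate_discourse(lexicon, dc))
  covariates <- stage("synthetic_data",
                      synthesize_covariates(discourse,
                                            seed = derive_seed(config$seed,
                                                               3)))
  rec <- stage("synthetic_data",
               synthesize_recording(discourse, effects = config$effects,
                                    n_channels = config$n_channels,
                                    fs = config$fs,
                                    seed = derive_seed(config$seed, 4),
                                    covariates = covariates,
                                    cfg = config$cfg))
  tokens <- stage("features", select_content_words(discourse))
  if (!is.null(config$n_trials) && nrow(tokens) > config$n_trials)
    tokens <- tokens[seq_len(config$n_trials), , drop = FALSE]
  tokens <- tokens[order(tokens$ws), , drop = FALSE] # onsets must be sorted
  ptab <- stage("features", parameter_table(tokens, covariates = covariates))
  cor_matrix <- stage("neurocorr",
                      parameter_correlation_matrix(ptab,
                                                   alpha = config$alpha))

  ss_rel <- tokens$ss - tokens$ws
  se_rel <- tokens$se - tokens$ws
  lo <- max(mean(ss_rel) - config$focal_margin, config$cfg$trial_window[1])
  hi <- min(mean(se_rel) + config$focal_margin, config$cfg$trial_window[2])
  cfg_focal <- spectral_config(fs = config$fs, window = config$cfg$window,
                               step = config$cfg$step,
                               n_tapers = config$cfg$n_tapers,
                               nw = config$cfg$nw,
                               f_max = config$focal_f_max,
                               trial_window = config$cfg$trial_window,
                               baseline_window = config$cfg$baseline_window,
                               power = config$cfg$power)
  spectra <- stage("spectral",
                   word_spectra(rec, onsets = tokens$ws, cfg = cfg_focal,
                                time_range = c(lo, hi)))
  spectra <- stage("spectral",
                   restrict_window(spectra, ss = ss_rel, se = se_rel,
                                   margin = config$focal_margin,
                                   f_max = config$focal_f_max))

  run_maps <- function(tab) {
    maps <- list()
    for (par in config$parameters)
      maps[[par]] <- neurocorrelate(spectra, tab[[par]], name = par)
    maps
  }
  maps_pre <- stage("neurocorr", run_maps(ptab))
  rtab <- stage("neurocorr", residualize_table(ptab, alpha = config$alpha))
  maps_post <- stage("neurocorr", run_maps(rtab))

  collect_effects <- function(maps) {
    out <- list()
    for (par in names(maps)) {
      mask <- bonferroni_test(maps[[par]], q = config$q)
      lt <- ladder_test(maps[[par]], config$ladder)
      out[[par]] <- extract_effects(maps[[par]], mask,
                                    threshold = lt$threshold)
    }
    out
  }
  eff_pre <- stage("effects", collect_effects(maps_pre))
  eff_post <- stage("effects", collect_effects(maps_post))
  matches <- stage("effects", {
    m <- lapply(config$parameters, function(par)
      match_pre_post(eff_pre[[par]], eff_post[[par]]))
    names(m) <- config$parameters
    m
  })

  structure(list(lexicon = lexicon, discourse = discourse, tokens = tokens,
                 parameter_table = ptab, residual_table = rtab,
                 cor_matrix = cor_matrix, spectra_dim = dim(spectra$log_rsm),
                 maps_pre = maps_pre, maps_post = maps_post,
                 effects_pre = eff_pre, effects_post = eff_post,
                 matches = matches, config = config,
                 seed = config$seed, hash = config_hash(unclass(config))),
            class = "ecoglex_results")
}

#' @export
print.ecoglex_results <- function(x, ...) {
  cat("<ecoglex_results> config ", x$hash, ", seed ", x$seed, "\n",
      "  trials: ", nrow(x$tokens), "; spectra ",
      paste(x$spectra_dim, collapse = " x "), "\n", sep = "")
  for (par in names(x$effects_pre))
    cat("  ", par, ": ", nrow(x$effects_pre[[par]]), " pre / ",
        nrow(x$effects_post[[par]]), " post effect cluster(s)\n", sep = "")
  invisible(x)
}

#' Human-readable analysis report
#'
#' Summarizes a results bundle: the parameter correlation matrix with
#' strong/weak labels, per-parameter effect counts by channel, band and
#' sign, and the pre/post-residualization match summary. Regenerating the
#' report from the same bundle yields identical text.
#'
#' @param bundle An [run_pipeline()] result.
#' @param path Optional output file.
#' @return Character vector of report lines, invisibly.
#' @export
report <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "ecoglex_results"))
  fmt <- function(...) sprintf(...)
  lines <- c(fmt("ecoglex analysis report (config %s, seed %d)",
                 bundle$hash, bundle$seed),
             fmt("trials analyzed: %d", nrow(bundle$tokens)), "",
             "parameter correlations (upper triangle: |r|, S = strong > 0.4, * = p < alpha):")
  cm <- bundle$cor_matrix
  cols <- colnames(cm$r)
  for (i in seq_along(cols)) {
    entries <- vapply(seq_along(cols), function(j) {
      if (j <= i) return("      .")
      if (is.na(cm$r[i, j])) return("     NA")
      sprintf("%6.2f%s", cm$r[i, j],
              if (isTRUE(cm$strong[i, j])) "S"
              else if (isTRUE(cm$significant[i, j])) "*" else " ")
    }, character(1))
    lines <- c(lines, fmt("  %-9s %s", cols[i], paste(entries, collapse = "")))
  }
  lines <- c(lines, "", "effects (Bonferroni q, per parameter):")
  total <- 0
  for (par in names(bundle$effects_pre)) {
    pre <- bundle$effects_pre[[par]]
    post <- bundle$effects_post[[par]]
    mt <- bundle$matches[[par]]
    total <- total + nrow(pre) + nrow(post)
    lines <- c(lines, fmt("  %s: %d pre, %d post, %d matched pre/post",
                          par, nrow(pre), nrow(post),
                          if (nrow(mt)) sum(mt$matched) else 0L))
    if (nrow(pre))
      for (k in seq_len(nrow(pre)))
        lines <- c(lines, fmt(
          "    pre  ch%02d %s %s [%.0f-%.0f Hz] [%.2f-%.2f s] thr %s",
          pre$channel[k], if (pre$sign[k] > 0) "+" else "-",
          pre$band[k], pre$f_low[k], pre$f_high[k], pre$t_start[k],
          pre$t_end[k], format(pre$threshold[k])))
    if (nrow(post))
      for (k in seq_len(nrow(post)))
        lines <- c(lines, fmt(
          "    post ch%02d %s %s [%.0f-%.0f Hz] [%.2f-%.2f s]%s",
          post$channel[k], if (post$sign[k] > 0) "+" else "-",
          post$band[k], post$f_low[k], post$f_high[k], post$t_start[k],
          post$t_end[k],
          if (isTRUE(bundle$matches[[par]]$matched[k])) " (matched pre)"
          else ""))
  }
  if (total == 0)
    lines <- c(lines, "  zero significant effects in either pass")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
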