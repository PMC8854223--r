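# Neurocorrelation: per-bin Pearson correlation of log RSM with linguistic
# parameters, Bonferroni and threshold-ladder testing, parameter
# collinearity, and residualization.

#' Build the per-trial parameter table
#'
#' Assembles, for the selected tokens (in the same order as the trials of
#' the spectral analysis), the nine analysis parameters: lemma frequency
#' (`FRQ`), ease of articulation (`EoA`), consonant-to-vowel ratio (`CVR`),
#' syllable count (`NoS`), the three duration parameters in ms (`ss_ws`,
#' `ws_we`, `we_se`), mean acoustic intensity (`intensity`) and word-locked
#' EMG band power (`emg_rsm`). All columns are natural-log transformed (with
#' the 0.001 offset) when `log = TRUE`; `emg_rsm` is already a log quantity
#' and is never re-transformed.
#'
#' @param tokens Selected token table (rows = trials, chronological within
#'   category), e.g. from [select_content_words()] on a
#'   [generate_discourse()] result.
#' @param covariates Optional [synthesize_covariates()] result or a data
#'   frame with `token_id` and `intensity_db`.
#' @param emg_rsm Optional numeric vector of per-token log relative EMG band
#'   power (see [emg_band_rsm()]).
#' @param log Apply [log_transform()] to all parameters.
#' @return Data frame of class `parameter_table`.
#' @export
parameter_table <- function(tokens, covariates = NULL, emg_rsm = NULL,
                            log = TRUE) {
  stopifnot(is.data.frame(tokens))
  dur <- duration_parameters(tokens)
  tab <- data.frame(FRQ = tokens$frequency, EoA = tokens$eoa,
                    CVR = tokens$cvr, NoS = tokens$nos,
                    ss_ws = dur$ss_ws, ws_we = dur$ws_we,
                    we_se = dur$we_se)
  if (!is.null(covariates)) {
    intensity <- if (is.data.frame(covariates)) covariates
                 else covariates$intensity
    tab$intensity <- intensity$intensity_db[
      match(tokens$token_id, intensity$token_id)]
  }
  if (log) tab[] <- lapply(tab, function(col) log_transform(pmax(col, 0)))
  if (!is.null(emg_rsm)) tab$emg_rsm <- emg_rsm
  structure(tab, class = c("parameter_table", "data.frame"))
}

#' Pairwise Pearson correlations between linguistic parameters
#'
#' Pearson correlation over pairwise-complete cases, with two-sided p-values
#' (uncorrected) and the strong/weak classification at |r| > 0.4. Constant
#' columns yield `NA` for their pairs with a warning.
#'
#' @param table Numeric data frame (e.g. [parameter_table()]), columns
#'   already log-transformed.
#' @param alpha Significance level for the uncorrected pairwise test.
#' @return Object of class `param_cor` with matrices `r`, `p`, `n`,
#'   `significant` and `strong`.
#' @export
parameter_correlation_matrix <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table))
  cols <- names(table)
  k <- length(cols)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  constant <- vapply(table, function(x)
    stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x)), logical(1))
  if (any(constant))
    warning("constant column(s): ", paste(cols[constant], collapse = ", "),
            "; correlations flagged NA")
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j < i) next
      x <- table[[i]]
      y <- table[[j]]
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
        next
      }
      if (n < 3 || constant[i] || constant[j]) next
      rv <- stats::cor(x[ok], y[ok])
      r[i, j] <- r[j, i] <- rv
      tt <- rv * sqrt((n - 2) / max(1 - rv^2, .Machine$double.eps))
      pv <- 2 * stats::pt(-abs(tt), df = n - 2)
      p[i, j] <- p[j, i] <- pv
    }
  }
  structure(list(r = r, p = p, n = nmat, significant = p < alpha,
                 strong = abs(r) > 0.4, alpha = alpha),
            class = "param_cor")
}

#' @export
print.param_cor <- function(x, digits = 2, ...) {
  cat("<param_cor> pairwise Pearson correlations (",
      "* p < ", x$alpha, ", bold |r| > 0.4 marked 'S')\n", sep = "")
  k <- ncol(x$r)
  disp <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (is.na(x$r[i, j])) { disp[i, j] <- "NA"; next }
    disp[i, j] <- paste0(formatC(x$r[i, j], digits = digits, format = "f"),
                         if (isTRUE(x$significant[i, j]) && i != j) "*" else "",
                         if (isTRUE(x$strong[i, j]) && i != j) "S" else "")
  }
  print(disp, quote = FALSE)
  invisible(x)
}

#' Correlate log RSM with a linguistic parameter ("neurocorrelation")
#'
#' Per channel, frequency and time bin, the Pearson correlation across
#' trials between the log relative spectral magnitudes and a per-trial
#' parameter (on its natural-log scale), with two-sided p-values. Bins with
#' zero variance are flagged `NA`. Invariant under affine rescaling of the
#' parameter.
#'
#' @param spectra A [word_spectra()] result.
#' @param x Per-trial parameter values (length = number of trials), already
#'   log-transformed.
#' @param name Parameter name stored in the map.
#' @return Object of class `neurocorr_map` with arrays `r` and `p`
#'   (channels x freq x time), coordinates and `n` (complete trials).
#' @export
neurocorrelate <- function(spectra, x, name = deparse(substitute(x))) {
  stopifnot(inherits(spectra, "trial_spectra"))
  d <- dim(spectra$log_rsm)
  if (length(x) != d[1])
    stop_invalid("parameter length (", length(x),
                 ") does not match the trial count (", d[1], ")")
  ok <- !is.na(x)
  m <- matrix(spectra$log_rsm[ok, , , , drop = FALSE], nrow = sum(ok))
  xs <- x[ok]
  n <- length(xs)
  if (n < 3) stop_invalid("need at least 3 complete trials")
  xc <- xs - mean(xs)
  cm <- colMeans(m)
  num <- drop(crossprod(xc, m))
  den_m <- sqrt(colSums(m^2) - n * cm^2)
  den_x <- sqrt(sum(xc^2))
  r <- num / (den_x * den_m)
  r[den_m <= den_x * 1e-14] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  shape <- d[-1]
  structure(list(r = array(r, shape), p = array(p, shape),
                 freq = spectra$freq, time = spectra$time,
                 channels = spectra$channels, parameter = name, n = n),
            class = "neurocorr_map")
}

#' @export
print.neurocorr_map <- function(x, ...) {
  cat("<neurocorr_map> parameter ", x$parameter, ", ", x$n, " trials, ",
      paste(dim(x$r), collapse = " x "),
      " (channels x freq x time); |r| max = ",
      sprintf("%.3f", max(abs(x$r), na.rm = TRUE)), ", min p = ",
      format(min(x$p, na.rm = TRUE), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Correlation-map image for one channel
#'
#' @param x A `neurocorr_map`.
#' @param channel Channel index or name.
#' @param ... Passed to [graphics::image()].
#' @export
plot.neurocorr_map <- function(x, channel = 1, ...) {
  if (is.character(channel)) channel <- match(channel, x$channels)
  m <- x$r[channel, , ]
  graphics::image(x$time, x$freq, t(m),
                  zlim = c(-1, 1) * max(abs(m), na.rm = TRUE),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = paste0("r(", x$parameter, "), channel ",
                                x$channels[channel]),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(x)
}

#' Bonferroni-corrected significance mask
#'
#' @param map A [neurocorrelate()] result.
#' @param q Family-wise level.
#' @param m Number of tests; defaults to the number of map bins (channels x
#'   frequency bins x time bins).
#' @return Logical array: `p < q / m`.
#' @export
bonferroni_test <- function(map, q = 0.05, m = NULL) {
  if (is.null(m)) m <- length(map$p)
  mask <- map$p < q / m
  mask[is.na(mask)] <- FALSE
  mask
}

#' Threshold ladder
#'
#' An ordered scale of increasingly conservative uncorrected significance
#' thresholds. No uncorrected p-value above the cap (5e-6) is ever called
#' significant; the default rungs descend geometrically from the cap.
#'
#' @param thresholds Strictly decreasing thresholds, all at or below 5e-6.
#' @return Numeric vector of class `threshold_ladder`.
#' @export
threshold_ladder <- function(thresholds = 5e-6 * 10^(-(0:8))) {
  if (any(thresholds > 5e-6 + 1e-18))
    stop_invalid("all ladder thresholds must be at or below the 5e-6 cap")
  if (any(diff(thresholds) >= 0))
    stop_invalid("ladder thresholds must be strictly decreasing")
  structure(thresholds, class = "threshold_ladder")
}

#' Most conservative significant threshold on a ladder
#'
#' Walks the ladder from the least to the most conservative rung and returns
#' the last (smallest) threshold at which at least one bin satisfies
#' `p <= threshold`, together with the mask at that threshold. When no bin
#' passes even the 5e-6 cap, no effect is reported.
#'
#' @param map A [neurocorrelate()] result.
#' @param ladder A [threshold_ladder()].
#' @return List with `threshold` (`NA` when no effect), `mask` and `n_sig`.
#' @export
ladder_test <- function(map, ladder = threshold_ladder()) {
  stopifnot(inherits(ladder, "threshold_ladder"))
  pmin_val <- suppressWarnings(min(map$p, na.rm = TRUE))
  passing <- ladder[pmin_val <= ladder]
  if (!length(passing)) {
    mask <- array(FALSE, dim(map$p))
    return(list(threshold = NA_real_, mask = mask, n_sig = 0L))
  }
  thr <- min(passing)
  mask <- map$p <= thr
  mask[is.na(mask)] <- FALSE
  list(threshold = thr, mask = mask, n_sig = sum(mask))
}

#' Residualize a parameter on its significant correlates
#'
#' Regresses the target column (ordinary least squares, with intercept) on
#' every other column it is significantly correlated with (uncorrected
#' pairwise p below `alpha`), and returns the residuals — orthogonal to all
#' predictors. With no significant correlate the residual is the
#' mean-centered target. Collinear predictors are dropped in column order
#' with a message. Rows with missing values yield `NA` residuals.
#'
#' @param table A [parameter_table()].
#' @param target Column name to residualize.
#' @param alpha Predictor-selection level.
#' @param cor_matrix Optional precomputed [parameter_correlation_matrix()].
#' @return Numeric residual vector, one entry per row of `table`, with
#'   attribute `predictors`.
#' @export
residualize <- function(table, target, alpha = 0.05, cor_matrix = NULL) {
  stopifnot(is.data.frame(table), target %in% names(table))
  if (is.null(cor_matrix))
    cor_matrix <- parameter_correlation_matrix(table, alpha = alpha)
  sig <- cor_matrix$p[target, ] < alpha
  sig[is.na(sig)] <- FALSE
  predictors <- setdiff(names(table)[sig], target)
  y <- table[[target]]
  out <- rep(NA_real_, length(y))
  if (!length(predictors)) {
    out <- y - mean(y, na.rm = TRUE)
    attr(out, "predictors") <- character(0)
    return(out)
  }
  dat <- table[, c(target, predictors), drop = FALSE]
  names(dat)[1] <- ".y"
  ok <- stats::complete.cases(dat)
  if (sum(ok) < length(predictors) + 2)
    stop_invalid("not enough complete rows to residualize ", target)
  fit <- stats::lm(.y ~ ., data = dat[ok, , drop = FALSE])
  dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(dropped))
    message("residualize(", target, "): dropped collinear predictor(s) ",
            paste(dropped, collapse = ", "))
  out[ok] <- stats::residuals(fit)
  attr(out, "predictors") <- predictors
  out
}

#' Residualize every parameter of a table
#'
#' Applies [residualize()] column by column, always predicting from the
#' original (non-residualized) columns, and returns a new table for
#' re-correlation with the neural data.
#'
#' @inheritParams residualize
#' @return A `parameter_table` of residual columns.
#' @export
residualize_table <- function(table, alpha = 0.05) {
  cm <- parameter_correlation_matrix(table, alpha = alpha)
  out <- table
  for (nm in names(table))
    out[[nm]] <- as.numeric(residualize(table, nm, alpha = alpha,
                                        cor_matrix = cm))
  out
}

#' Restrict trial spectra to the focalized analysis window
#'
#' Drops frequency bins above `f_max` and time bins outside
#' `[mean(ss) - margin, mean(se) + margin]` (times relative to word onset,
#' clipped to the trial window) — the shortened analysis window running from
#' a margin before the mean speech start to a margin after the mean speech
#' end.
#'
#' @param spectra A [word_spectra()] result.
#' @param ss,se Per-trial speech-epoch start/end relative to word onset (s);
#'   scalars are used directly as window edges.
#' @param margin Margin (s) added on both sides.
#' @param f_max Highest retained frequency (Hz).
#' @return A restricted `trial_spectra` object.
#' @export
restrict_window <- function(spectra, ss, se, margin = 0.5, f_max = 150) {
  stopifnot(inherits(spectra, "trial_spectra"), margin >= 0)
  lo <- max(mean(ss) - margin, min(spectra$time))
  hi <- min(mean(se) + margin, max(spectra$time))
  fsel <- spectra$freq <= f_max
  tsel <- spectra$time >= lo & spectra$time <= hi
  if (!any(fsel) || !any(tsel))
    stop_invalid("window restriction leaves no bins")
  spectra$log_rsm <- spectra$log_rsm[, , fsel, tsel, drop = FALSE]
  spectra$freq <- spectra$freq[fsel]
  spectra$time <- spectra$time[tsel]
  spectra
}
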