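# Effect clusters: connected significant time-frequency regions per
# electrode, band labeling, the interval-based overlap criteria, and
# matching of effects before vs. after residualization.

band_label <- function(f) {
  if (f > 35) "gamma"
  else if (f >= 15 && f <= 30) "beta"
  else if (f >= 5 && f <= 10) "alpha"
  else "other"
}

# 4-connected component labels of a logical matrix (freq x time)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      cell <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      ci <- cell[1]; cj <- cell[2]
      if (ci < 1 || cj < 1 || ci > nrow(mask) || cj > ncol(mask)) next
      if (!mask[ci, cj] || lab[ci, cj] != 0L) next
      lab[ci, cj] <- cur
      stack <- c(stack, list(c(ci - 1, cj), c(ci + 1, cj),
                             c(ci, cj - 1), c(ci, cj + 1)))
    }
  }
  lab
}

#' Extract effect clusters from a significance mask
#'
#' Connected components (4-connectivity in the time x frequency plane, per
#' channel) of significant bins. Each component becomes one effect cluster
#' with its bounding time and frequency extents, the sign of its mean r, and
#' a band label (alpha 5-10 Hz, beta 15-30 Hz, gamma > 35 Hz) taken at the
#' midpoint of the frequency extent; clusters straddling a band boundary are
#' labeled by the midpoint band with a warning.
#'
#' @param map A [neurocorrelate()] result.
#' @param mask Logical array with the map's dimensions (e.g. from
#'   [bonferroni_test()] or [ladder_test()]).
#' @param min_bins Minimum component size.
#' @param threshold Reported threshold to record on each cluster (optional).
#' @return Data frame of class `effect_table`: `channel`, `t_start`,
#'   `t_end`, `f_low`, `f_high` (bin-center extents), `sign`, `band`,
#'   `n_bins`, `r_mean`, `parameter`, `threshold`.
#' @export
extract_effects <- function(map, mask, min_bins = 1, threshold = NA_real_) {
  stopifnot(all(dim(mask) == dim(map$r)))
  out <- list()
  for (ch in seq_len(dim(mask)[1])) {
    m2 <- matrix(mask[ch, , , drop = FALSE], nrow = dim(mask)[2])
    r2 <- matrix(map$r[ch, , , drop = FALSE], nrow = dim(mask)[2])
    if (!any(m2)) next
    lab <- label_components(m2)
    for (comp in seq_len(max(lab))) {
      cells <- which(lab == comp, arr.ind = TRUE)
      if (nrow(cells) < min_bins) next
      f_ext <- range(map$freq[cells[, 1]])
      t_ext <- range(map$time[cells[, 2]])
      rvals <- r2[cells]
      mid_band <- band_label(mean(f_ext))
      bands_present <- unique(vapply(map$freq[cells[, 1]], band_label,
                                     character(1)))
      if (length(bands_present) > 1)
        warning("cluster at channel ", ch,
                " straddles a band boundary; labeled by its midpoint (",
                mid_band, ")")
      out[[length(out) + 1]] <- data.frame(
        channel = ch, t_start = t_ext[1], t_end = t_ext[2],
        f_low = f_ext[1], f_high = f_ext[2],
        sign = if (mean(rvals, na.rm = TRUE) < 0) -1 else 1,
        band = mid_band, n_bins = nrow(cells),
        r_mean = mean(rvals, na.rm = TRUE),
        parameter = if (is.null(map$parameter)) NA_character_
                    else map$parameter,
        threshold = threshold, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(channel = integer(0), t_start = numeric(0),
                         t_end = numeric(0), f_low = numeric(0),
                         f_high = numeric(0), sign = numeric(0),
                         band = character(0), n_bins = integer(0),
                         r_mean = numeric(0), parameter = character(0),
                         threshold = numeric(0), stringsAsFactors = FALSE)
  res <- res[order(res$channel, res$t_start, res$f_low), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("effect_table", "data.frame"))
}

#' @export
print.effect_table <- function(x, ...) {
  cat("<effect_table> ", nrow(x), " effect cluster(s)\n", sep = "")
  if (nrow(x)) print.data.frame(as.data.frame(x), digits = 3)
  invisible(x)
}

interval_gap <- function(a, b) max(0, max(a[1], b[1]) - min(a[2], b[2]))

#' Do two effect clusters describe the same time-frequency component?
#'
#' True when the clusters sit on the same channel, their time extents are
#' within 40 ms of each other (interval-to-interval distance, 0 when
#' overlapping, bounds inclusive), and their frequency extents are either
#' both in the gamma range (> 35 Hz) within 20 Hz of each other, or both in
#' the same alpha/beta band. Symmetric in its arguments.
#'
#' @param a,b One-row data frames (rows of an `effect_table`).
#' @param max_dt Maximum temporal distance (s).
#' @param max_df Maximum frequency distance within gamma (Hz).
#' @return Logical flag.
#' @export
detect_overlap <- function(a, b, max_dt = 0.04, max_df = 20) {
  if (a$channel != b$channel) return(FALSE)
  dt <- interval_gap(c(a$t_start, a$t_end), c(b$t_start, b$t_end))
  if (dt > max_dt + 1e-12) return(FALSE)
  if (a$band == "gamma" && b$band == "gamma") {
    df <- interval_gap(c(a$f_low, a$f_high), c(b$f_low, b$f_high))
    return(df <= max_df + 1e-9)
  }
  a$band == b$band && a$band %in% c("alpha", "beta")
}

#' Match effects before vs. after residualization
#'
#' Each post-residualization effect is matched to at most one
#' pre-residualization effect on the same electrode, in the same
#' time-frequency range (per [detect_overlap()]) and with the same sign.
#' Both lists are first put into canonical (channel, time, frequency) order,
#' so the result is stable under reordering of the inputs.
#'
#' @param pre,post `effect_table`s of the same parameter and subject.
#' @return The `post` table with added columns `matched` (logical) and
#'   `pre_index` (row of `pre`, or `NA`), sorted by channel; the indices of
#'   unmatched pre-effects are in attribute `unmatched_pre`.
#' @export
match_pre_post <- function(pre, post) {
  ord_pre <- order(pre$channel, pre$t_start, pre$f_low)
  pre <- pre[ord_pre, , drop = FALSE]
  post <- post[order(post$channel, post$t_start, post$f_low), , drop = FALSE]
  used <- rep(FALSE, nrow(pre))
  matched <- rep(FALSE, nrow(post))
  pre_index <- rep(NA_integer_, nrow(post))
  for (i in seq_len(nrow(post))) {
    for (j in seq_len(nrow(pre))) {
      if (used[j]) next
      if (detect_overlap(post[i, ], pre[j, ]) &&
          post$sign[i] == pre$sign[j]) {
        used[j] <- TRUE
        matched[i] <- TRUE
        pre_index[i] <- j
        break
      }
    }
  }
  post$matched <- matched
  post$pre_index <- pre_index
  rownames(post) <- NULL
  attr(post, "unmatched_pre") <- which(!used)
  post
}
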