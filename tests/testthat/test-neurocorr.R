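# Parameter collinearity, neurocorrelation maps, Bonferroni / ladder
# testing, residualization and window restriction.

make_spectra <- function(n_tr = 40, n_ch = 2, nf = 6, nt = 8, seed = 1) {
  set.seed(seed)
  structure(list(log_rsm = array(rnorm(n_tr * n_ch * nf * nt),
                                 c(n_tr, n_ch, nf, nt)),
                 freq = seq(5, by = 5, length.out = nf),
                 time = seq(-0.5, by = 0.02, length.out = nt),
                 onsets = seq_len(n_tr), channels = sprintf("ch%02d",
                                                            seq_len(n_ch)),
                 cfg = fast_cfg()),
            class = "trial_spectra")
}

test_that("pairwise parameter correlations behave like cor.test", {
  set.seed(21)
  tab <- data.frame(a = rnorm(60), b = rnorm(60))
  tab$c <- tab$a * 0.8 + rnorm(60, 0, 0.3)
  tab$dup <- tab$a
  cm <- parameter_correlation_matrix(tab)
  expect_equal(cm$r["a", "dup"], 1)
  expect_true(cm$significant["a", "dup"])
  ref <- cor.test(tab$a, tab$c)
  expect_equal(cm$r["a", "c"], unname(ref$estimate))
  expect_equal(cm$p["a", "c"], ref$p.value, tolerance = 1e-12)
  expect_true(cm$strong["a", "c"])
  # constant columns are flagged, not fatal
  tab$k <- 1
  expect_warning(cmk <- parameter_correlation_matrix(tab), "constant")
  expect_true(is.na(cmk$r["k", "a"]))
})

test_that("independent columns rarely show spurious |r| > 0.1 at n = 1000", {
  hits <- 0L
  for (s in 1:200) {
    set.seed(300 + s)
    x <- rnorm(1000)
    y <- rnorm(1000)
    hits <- hits + (abs(cor(x, y)) < 0.1)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("neurocorrelation is exact at a self-coupled bin and affine-invariant", {
  sp <- make_spectra()
  x <- sp$log_rsm[, 1, 3, 4]
  map <- neurocorrelate(sp, x, "self")
  expect_equal(map$r[1, 3, 4], 1)
  # affine rescaling leaves r untouched and preserves the sign
  map2 <- neurocorrelate(sp, 3.7 * x + 11, "affine")
  expect_equal(map2$r, map$r, tolerance = 1e-12)
  # oracle: direct cor() on a handful of bins
  set.seed(22)
  z <- rnorm(dim(sp$log_rsm)[1])
  mz <- neurocorrelate(sp, z, "z")
  for (b in list(c(1, 1, 1), c(2, 5, 7), c(1, 6, 2))) {
    expect_equal(mz$r[b[1], b[2], b[3]],
                 cor(z, sp$log_rsm[, b[1], b[2], b[3]]), tolerance = 1e-12)
    expect_equal(mz$p[b[1], b[2], b[3]],
                 cor.test(z, sp$log_rsm[, b[1], b[2], b[3]])$p.value,
                 tolerance = 1e-10)
  }
  expect_error(neurocorrelate(sp, z[-1]), "trial count")
})

test_that("permuted parameters yield uncorrected significance near alpha", {
  sp <- make_spectra(n_tr = 60, n_ch = 1, nf = 8, nt = 10, seed = 23)
  x <- rnorm(60)
  alpha <- 0.05
  set.seed(24)
  fracs <- vapply(1:100, function(i) {
    m <- neurocorrelate(sp, sample(x), "perm")
    mean(m$p < alpha)
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - alpha), 2 * se + 0.01)
})

test_that("Bonferroni masks use q/m and nest inside the ladder cap", {
  sp <- make_spectra(seed = 25)
  x <- rnorm(dim(sp$log_rsm)[1])
  map <- neurocorrelate(sp, x, "x")
  # arithmetic: m = 10,000 at q = 0.05 -> threshold 5e-6
  map$p[1, 1, 1] <- 1e-6
  map$p[1, 1, 2] <- 1e-5
  mask <- bonferroni_test(map, q = 0.05, m = 10000)
  expect_true(mask[1, 1, 1])
  expect_false(mask[1, 1, 2])
  # on random p-maps: Bonferroni at q/m <= 5e-6 is within the cap mask
  set.seed(26)
  for (i in 1:20) {
    map$p <- array(10^runif(length(map$p), -9, 0), dim(map$p))
    m <- length(map$p) * 2000 # ensures q/m <= 5e-6
    bmask <- bonferroni_test(map, q = 0.05, m = m)
    cap <- map$p <= 5e-6
    expect_true(all(!bmask | cap))
  }
})

test_that("the threshold ladder reports the most conservative passing rung", {
  ladder <- threshold_ladder(c(5e-6, 5e-7, 5e-8))
  sp <- make_spectra(seed = 27)
  map <- neurocorrelate(sp, rnorm(dim(sp$log_rsm)[1]), "x")
  map$p[] <- 0.5
  map$p[1, 2, 3] <- 1e-7
  res <- ladder_test(map, ladder)
  expect_equal(res$threshold, 5e-7)
  expect_true(res$mask[1, 2, 3])
  expect_equal(res$n_sig, 1)
  # nothing at or below the cap: no effect
  map$p[1, 2, 3] <- 1e-5
  res2 <- ladder_test(map, ladder)
  expect_true(is.na(res2$threshold))
  expect_equal(res2$n_sig, 0)
  # boundary: exactly 5e-6 reports at 5e-6 (inclusive)
  map$p[1, 2, 3] <- 5e-6
  res3 <- ladder_test(map, ladder)
  expect_equal(res3$threshold, 5e-6)
  # a smaller p can only keep or lower the reported threshold
  map$p[2, 1, 1] <- 1e-9
  res4 <- ladder_test(map, ladder)
  expect_lte(res4$threshold, res3$threshold)
  # ladder validation
  expect_error(threshold_ladder(c(1e-5, 5e-6)), "cap")
  expect_error(threshold_ladder(c(5e-6, 5e-6)), "decreasing")
})

test_that("residualization is orthogonal to its predictors", {
  set.seed(28)
  n <- 200
  tab <- data.frame(a = rnorm(n))
  tab$b <- -0.7 * tab$a + rnorm(n, 0, 0.5)
  tab$c <- 0.5 * tab$a + 0.3 * tab$b + rnorm(n, 0, 0.7)
  # exactly orthogonal to the other columns in-sample
  tab$d <- residuals(lm(rnorm(n) ~ tab$a + tab$b + tab$c))
  res <- residualize(tab, "a")
  for (p in attr(res, "predictors"))
    expect_lt(abs(cor(res, tab[[p]])), 1e-10)
  expect_true(all(c("b", "c") %in% attr(res, "predictors")))
  # an isolated column is just mean-centered
  resd <- residualize(tab, "d")
  expect_equal(as.numeric(resd), tab$d - mean(tab$d), tolerance = 1e-12)
  expect_length(attr(resd, "predictors"), 0)
  # collinear predictors are dropped with a message, not an error
  tab$b2 <- tab$b
  expect_message(res2 <- residualize(tab, "a"), "collinear")
  for (p in c("b", "c")) expect_lt(abs(cor(res2, tab[[p]])), 1e-10)
  # full-table residualization keeps orthogonality column by column
  rt <- residualize_table(tab[, 1:4])
  cm <- parameter_correlation_matrix(tab[, 1:4])
  for (target in names(rt)) {
    preds <- setdiff(names(rt)[cm$p[target, ] < 0.05], target)
    for (p in preds) expect_lt(abs(cor(rt[[target]], tab[[p]])), 1e-10)
  }
})

test_that("residualizing an orthogonal parameter leaves its map unchanged", {
  sp <- make_spectra(n_tr = 120, seed = 29)
  set.seed(30)
  tab <- data.frame(x = rnorm(120), y = rnorm(120))
  map_raw <- neurocorrelate(sp, tab$x, "x")
  res <- residualize(tab, "x")
  map_res <- neurocorrelate(sp, as.numeric(res), "x")
  # mean-centering leaves Pearson r bit-unchanged
  expect_equal(map_res$r, map_raw$r, tolerance = 1e-10)
})

test_that("window restriction clips frequency and time as configured", {
  sp <- make_spectra(nf = 40, nt = 60)
  sp$freq <- seq(5, by = 5, length.out = 40)
  sp$time <- seq(-1.5, by = 0.05, length.out = 60)
  out <- restrict_window(sp, ss = rep(-0.8, 40), se = rep(0.9, 40),
                         margin = 0.5, f_max = 150)
  expect_true(all(out$freq <= 150))
  expect_true(all(out$time >= -1.3 - 1e-9 & out$time <= 1.4 + 1e-9))
  # margin 0 with ss = onset: window starts at the onset
  out2 <- restrict_window(sp, ss = rep(0, 40), se = rep(0.9, 40),
                          margin = 0, f_max = 200)
  expect_gte(min(out2$time), 0)
  # identity configuration reproduces the full analysis
  out3 <- restrict_window(sp, ss = -Inf, se = Inf, margin = 0, f_max = 300)
  expect_equal(dim(out3$log_rsm), dim(sp$log_rsm))
})
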