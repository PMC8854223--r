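# Synthetic lexicon / discourse / covariate generators: Zipf frequencies,
# collinearity sign structure, pause-rule timing, determinism.

test_that("lexicon frequencies follow the Zipf law", {
  lex1 <- generate_lexicon(1)
  expect_equal(nrow(lex1), 1)
  expect_equal(lex1$frequency, 1) # normalization constant for n = 1
  lex <- generate_lexicon(1000, zipf_exponent = 1, seed = 7)
  expect_equal(lex$frequency[1] / lex$frequency[2], 2.0)
  expect_equal(sum(lex$frequency), 1)
  expect_true(all(lex$frequency > 0))
  expect_false(any(duplicated(lex[, c("lemma", "pos")])))
  expect_true(all(lex$nos >= 1))
  expect_error(generate_lexicon(0), "positive")
  expect_error(generate_lexicon(10, zipf_exponent = -1), "positive")
})

test_that("rarer words have more syllables (log FRQ vs NoS negative)", {
  lex <- generate_lexicon(500, seed = 11)
  r <- cor(log(lex$frequency), lex$nos)
  expect_lt(r, 0)
  expect_gt(abs(r), 0.3)
})

test_that("generators are deterministic under a fixed seed", {
  a <- generate_lexicon(80, seed = 5)
  b <- generate_lexicon(80, seed = 5)
  expect_identical(a, b)
  da <- generate_discourse(a, discourse_config(n_tokens = c(ADV = 10L,
                                                            FV = 15L,
                                                            NN = 10L),
                                               seed = 6))
  db <- generate_discourse(b, discourse_config(n_tokens = c(ADV = 10L,
                                                            FV = 15L,
                                                            NN = 10L),
                                               seed = 6))
  expect_identical(da, db)
  # serialized byte-for-byte
  expect_identical(serialize(da, NULL), serialize(db, NULL))
  # and the generator does not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(generate_lexicon(10, seed = 4)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("generated discourse respects the pause rule and position biases", {
  st <- tiny_study(3, n_words = 300,
                   n_tokens = c(ADV = 60L, FV = 100L, NN = 70L))
  d <- st$discourse
  expect_true(all(d$we > d$ws))
  # position in epoch: later words are longer / rarer
  expect_gt(cor(d$ws - d$ss, d$nos), 0)
  expect_lt(cor(d$ws - d$ss, log(d$frequency + 0.001), use = "complete.obs"),
            0.15) # rarer words not earlier
  # epoch bounds enclose their tokens exactly
  expect_true(all(d$ws >= d$ss & d$we <= d$se))
  expect_true(all(d$ws >= d$cs & d$we <= d$ce))
  expect_error(generate_discourse(d[0, ], discourse_config()), "non-empty")
})

test_that("sign structure of the parameter pairs reproduces across seeds", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    lex <- generate_lexicon(400, seed = 100 + s)
    disc <- generate_discourse(lex, discourse_config(
      n_tokens = c(ADV = 60L, FV = 100L, NN = 70L), seed = 200 + s))
    tok <- select_content_words(disc)
    tab <- parameter_table(tok)
    ok <- cor(tab$EoA, tab$FRQ) > 0 &&
      cor(tab$EoA, tab$NoS) < 0 &&
      cor(tab$FRQ, tab$NoS) < 0 &&
      cor(tab$CVR, tab$NoS) < 0 &&
      cor(tab$NoS, tab$ws_we) > 0
    hits <- hits + ok
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("covariates carry the intensity-position bias", {
  st <- tiny_study(5)
  cov <- synthesize_covariates(st$discourse, seed = 5)
  expect_equal(nrow(cov$intensity), nrow(st$discourse))
  expect_true(all(is.finite(cov$intensity$intensity_db)))
  expect_lt(cor(cov$intensity$intensity_db,
                st$discourse$ws - st$discourse$ss), 0)
  one <- st$discourse[1, ]
  cov1 <- synthesize_covariates(one, seed = 1)
  expect_equal(nrow(cov1$intensity), 1)
})

test_that("effect specifications validate their domains", {
  expect_error(effect_spec(1, "CVR", band = c(70, 110), r = 1.2), "below 1")
  expect_error(effect_spec(1, "CVR", band = c(0, 110)), "within")
  expect_error(effect_spec(1, "CVR", band = c(70, 110),
                           window = c(-3, 0.4)), "within")
  expect_error(effect_spec(1, "XYZ", band = c(70, 110)), "parameter")
  ef <- effect_spec(3, "NoS", band = c(40, 80), r = -0.4)
  expect_equal(ef$sign, -1)
})

test_that("recordings are deterministic and reject impossible effects", {
  st <- tiny_study(9, n_words = 150,
                   n_tokens = c(ADV = 12L, FV = 18L, NN = 12L))
  r1 <- synthesize_recording(st$discourse, n_channels = 2, fs = 256,
                             seed = 31)
  r2 <- synthesize_recording(st$discourse, n_channels = 2, fs = 256,
                             seed = 31)
  expect_identical(r1$samples, r2$samples)
  expect_error(
    synthesize_recording(st$discourse,
                         effects = effect_spec(1, "CVR", band = c(100, 140)),
                         n_channels = 2, fs = 256),
    "Nyquist")
  expect_error(
    synthesize_recording(st$discourse,
                         effects = effect_spec(9, "CVR", band = c(70, 110)),
                         n_channels = 2, fs = 1024),
    "channel")
})

test_that("background noise is 1/f-shaped with unit variance", {
  set.seed(8)
  x <- ecoglex:::one_over_f_noise(2^15, 1024, 1)
  expect_equal(sd(x), 1, tolerance = 1e-9)
  # spectral slope of average periodogram approximately -1
  p <- Mod(fft(x))^2
  f <- (seq_along(p) - 1) * 1024 / length(p)
  sel <- f > 2 & f < 400
  slope <- coef(lm(log(p[sel]) ~ log(f[sel])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.25)
})
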