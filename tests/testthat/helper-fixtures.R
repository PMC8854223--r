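# Shared fixtures: small, fast synthetic objects built in code.

fast_cfg <- function(fs = 1024, f_max = 150, ...) {
  spectral_config(fs = fs, f_max = f_max, ...)
}

# a small discourse with known structure for timeline tests
tiny_tags <- function() {
  data.frame(ws = c(1.0, 1.6, 3.0), we = c(1.4, 2.0, 3.5),
             cs = c(1.0, 1.6, 3.0), ce = c(1.4, 2.0, 3.5),
             ss = c(1.0, 1.0, 3.0), se = c(2.0, 2.0, 3.5),
             clause_id = c(1, 2, 3), epoch_id = c(1, 1, 2))
}

# deterministic small lexicon + discourse pair
tiny_study <- function(seed = 7, n_words = 120,
                       n_tokens = c(ADV = 25L, FV = 40L, NN = 30L)) {
  lex <- generate_lexicon(n_words, seed = seed)
  disc <- generate_discourse(lex, discourse_config(n_tokens = n_tokens,
                                                   seed = seed + 1))
  list(lexicon = lex, discourse = disc)
}

# brute-force connected components oracle (4-connectivity) for effect
# clustering: grows components by repeated neighbor expansion
oracle_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  repeat {
    todo <- which(mask & lab == 0L, arr.ind = TRUE)
    if (!nrow(todo)) break
    nxt <- nxt + 1L
    lab[todo[1, 1], todo[1, 2]] <- nxt
    repeat {
      grew <- FALSE
      cur <- which(lab == nxt, arr.ind = TRUE)
      for (k in seq_len(nrow(cur))) {
        i <- cur[k, 1]; j <- cur[k, 2]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ii <- i + d[1]; jj <- j + d[2]
          if (ii >= 1 && jj >= 1 && ii <= nrow(mask) && jj <= ncol(mask) &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- nxt
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
  }
  lab
}

# wrap a freq x time logical matrix as a one-channel map-like object
as_map <- function(r2, freq, time, parameter = "test") {
  structure(list(r = array(r2, c(1, dim(r2))),
                 p = array(0.5, c(1, dim(r2))),
                 freq = freq, time = time, channels = "ch01",
                 parameter = parameter, n = 100),
            class = "neurocorr_map")
}
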