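# Independent oracles, deliberately written from the textbook formulas and
# kept separate from the package's code paths.

# Woolf odds-ratio interval
oracle_woolf <- function(a, b, c, d) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, low = or * exp(-1.96 * se), high = or * exp(1.96 * se))
}

# uncorrected Pearson chi-square via stats::chisq.test
oracle_chi2 <- function(a, b, c, d) {
  suppressWarnings(
    unname(chisq.test(matrix(c(a, c, b, d), 2, 2), correct = FALSE)$statistic))
}

# second literal transcription of the closed-form BCPNN information
# component (log2 throughout, terms written in a different order)
oracle_ic <- function(a, b, c, d) {
  N <- a + b + c + d
  gamma_ <- (N + 2)^2 / ((a + b + 1) * (a + c + 1))
  eic <- log2(a + 1) + log2((N + 2)^2) -
    log2((N + gamma_) * (a + b + 1) * (a + c + 1))
  vic <- (1 / log(2))^2 * (
    (N - a + gamma_ - 1) / ((a + 1) * (1 + N + gamma_)) +
      (N - (a + b) + 1) / (((a + b) + 1) * (N + 3)) +
      (N - (a + c) + 1) / (((a + c) + 1) * (N + 3)))
  list(eic = eic, ic025 = eic - 2 * sqrt(vic))
}

# brute-force cell probabilities of the synthetic generative model,
# looped over drugs/events rather than vectorized
oracle_expected_ror <- function(config, lab, pt) {
  shares <- config$drugs$share / sum(config$drugs$share)
  base <- config$events$rate / sum(config$events$rate)
  j <- which(config$events$pt == pt)
  pa <- pb <- pc <- pd <- 0
  for (i in seq_len(nrow(config$drugs))) {
    li <- config$drugs$label[i]
    w <- base
    if (nrow(config$planted)) {
      for (r in seq_len(nrow(config$planted))) {
        if (config$planted$drug_label[r] == li) {
          k <- which(config$events$pt == config$planted$pt[r])
          w[k] <- w[k] * config$planted$lambda[r]
        }
      }
    }
    w <- w / sum(w)
    if (li == lab) {
      pa <- pa + shares[i] * w[j]
      pb <- pb + shares[i] * (1 - w[j])
    } else {
      pc <- pc + shares[i] * w[j]
      pd <- pd + shares[i] * (1 - w[j])
    }
  }
  (pa * pd) / (pb * pc)
}

random_tables <- function(n, max_cell = 1e4, min_cell = 0, seed = 42) {
  set.seed(seed)
  data.frame(a = sample(min_cell:max_cell, n, TRUE),
             b = sample(min_cell:max_cell, n, TRUE),
             c = sample(min_cell:max_cell, n, TRUE),
             d = sample(min_cell:max_cell, n, TRUE))
}
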