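# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and vectorised base shortcuts where feasible) so that
# agreement is evidence, not tautology.

bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# full edge chain: Pearson -> ((r+1)/2)^beta -> arctanh -> degree centrality
bf_degree_chain <- function(data, beta = 6) {
  R <- ncol(data)
  dc <- numeric(R)
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      if (i == j) next
      r <- bf_pearson(data[, i], data[, j])
      w <- ((r + 1) / 2)^beta
      dc[i] <- dc[i] + atanh(min(w, 1 - 1e-7))
    }
  }
  dc
}

# Benjamini-Hochberg step-up, written out long-hand
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, m * p[o[k]] / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# Type III F statistics via explicit model refits (lm machinery, not the
# package's closed-form route)
bf_type3_anova <- function(y, cells) {
  a <- factor(ifelse(cells %in% c("lw-no", "lw-o"), "low", "high"),
              levels = c("low", "high"))
  b <- factor(ifelse(cells %in% c("lw-no", "hw-no"), "no", "o"),
              levels = c("no", "o"))
  X <- model.matrix(~ a * b,
                    contrasts.arg = list(a = contr.sum, b = contr.sum))
  full <- lm.fit(X, y)
  rss_full <- sum(full$residuals^2)
  df2 <- length(y) - ncol(X)
  mse <- rss_full / df2
  Fs <- sapply(2:4, function(j) {
    red <- lm.fit(X[, -j, drop = FALSE], y)
    (sum(red$residuals^2) - rss_full) / mse
  })
  names(Fs) <- c("wmh", "obesity", "interaction")
  Fs
}

bf_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# small deterministic time-series fixture
make_ts_fixture <- function(T = 50, R = 5, seed = 11) {
  set.seed(seed)
  region_ts("fix01", matrix(rnorm(T * R), T, R))
}

# tiny spec used across tests
tiny_spec <- function(...) {
  cohort_spec(n_subjects = 8, n_regions = 5, n_timepoints = 50, seed = 1,
              ...)
}
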