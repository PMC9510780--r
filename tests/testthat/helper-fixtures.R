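# Shared fixtures, built once per test run. Cohorts use a 3-minute
# scaled version of the 7-segment protocol (discard and transition
# time constant scaled by the same 3/15 factor) so the suite stays
# fast while keeping the block structure proportional.

.fixtures <- new.env(parent = emptyenv())

scaled_protocol <- function(segment_minutes = 3) {
  make_protocol(c(1.5, 2.3, 1.0, 1.5, 1.0, 2.3, 1.5), segment_minutes)
}

scaled_config <- function(...) {
  generator_config(transition_tau_s = 12, ...)
}

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 3-animal cohort with all modulations on, plus its feature table.
fix_cohort <- function() fixture("cohort", function() {
  simulate_cohort(3, scaled_protocol(), scaled_config(), seed = 11)
})

fix_features <- function() fixture("features", function() {
  extract_cohort_features(fix_cohort(), discard_minutes = 1)
})

# Brute-force oracles -------------------------------------------------

# Direct double-loop sample-entropy counts from the definition.
brute_sampen_counts <- function(x, m, lag, r) {
  N <- length(x) - m * lag
  A <- 0; B <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      d <- max(abs(x[i + (0:(m - 1)) * lag] - x[j + (0:(m - 1)) * lag]))
      if (d <= r) {
        B <- B + 1
        if (abs(x[i + m * lag] - x[j + m * lag]) <= r) A <- A + 1
      }
    }
  }
  c(B = B, A = A)
}

# Exhaustive-history LZ76 parser: grow the current word until it is no
# longer a substring of everything before its last symbol, then start a
# new word. Terminal incomplete word counts as one.
brute_lz76 <- function(s) {
  s <- paste(s, collapse = "")
  n <- nchar(s)
  if (n <= 1) return(n)
  c_words <- 0
  l <- 1
  while (l <= n) {
    k <- 1
    while (l + k - 1 <= n) {
      word <- substr(s, l, l + k - 1)
      history <- substr(s, 1, l + k - 2)
      if (!grepl(word, history, fixed = TRUE)) break
      k <- k + 1
    }
    c_words <- c_words + 1
    l <- l + k
  }
  c_words
}

# Exact two-sided Mann-Whitney p by full enumeration of group
# assignments (no ties assumed).
brute_mwu_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_stat <- function(xi) {
    r <- rank(pooled)
    sum(r[xi]) - nx * (nx + 1) / 2
  }
  u_obs <- u_stat(seq_len(nx))
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, u_stat)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# BH step-up by trying every threshold.
brute_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(k) > 0) reject[ord[seq_len(max(k))]] <- TRUE
  reject
}

# ~20-line reference stagewise booster on rpart trees (squared loss).
reference_booster <- function(X, y, steps, max_depth, lr) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  pred <- rep(mean(y), length(y))
  trees <- list()
  for (m in seq_len(steps)) {
    df$resid <- y - pred
    fit <- rpart::rpart(resid ~ ., data = df,
                        control = rpart::rpart.control(
                          maxdepth = max_depth, cp = 0, minsplit = 2,
                          minbucket = 1, xval = 0))
    pred <- pred + lr * predict(fit, df)
    trees[[m]] <- fit
  }
  list(pred = pred, base = mean(y), trees = trees)
}
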