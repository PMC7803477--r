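# Independent brute-force oracles used to validate the processing and
# rank-test implementations. These deliberately use naive per-element
# scans and full enumeration, not the package's algorithms.

# maximal runs of zeros with length >= min_len, by walking the vector
# one minute at a time; returns 0-based half-open [start, end)
oracle_zero_runs <- function(steps, min_len) {
  starts <- integer(); ends <- integer()
  run_start <- NA_integer_
  for (i in seq_along(steps)) {
    z <- !is.na(steps[i]) && steps[i] == 0
    if (z && is.na(run_start)) run_start <- i
    if (!z && !is.na(run_start)) {
      if (i - run_start >= min_len) {
        starts <- c(starts, run_start - 1L); ends <- c(ends, i - 1L)
      }
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start) && length(steps) + 1 - run_start >= min_len) {
    starts <- c(starts, run_start - 1L); ends <- c(ends, length(steps))
  }
  data.frame(start = starts, end = ends)
}

# per-minute class lookup after masking the oracle's nonwear intervals
oracle_classify <- function(steps, min_len = 120) {
  iv <- oracle_zero_runs(steps, min_len)
  nonwear <- rep(FALSE, length(steps))
  for (k in seq_len(nrow(iv))) nonwear[(iv$start[k] + 1):iv$end[k]] <- TRUE
  out <- character(length(steps))
  for (i in seq_along(steps)) {
    s <- steps[i]
    out[i] <-
      if (nonwear[i]) "nonwear"
      else if (is.na(s)) "missing"
      else if (s <= 9) "sedentary"
      else if (s <= 100) "walking"
      else if (s <= 130) "moderate"
      else "vigorous"
  }
  out
}

# random minute series with nonwear-like zero stretches, activity and
# missing/artifact minutes; n_days whole days
random_series <- function(n_days = 3, p_zero_block = 0.3) {
  n <- n_days * 1440L
  steps <- sample(0:220, n, replace = TRUE,
                  prob = c(0.5, rep(0.5 / 220, 220)))
  # implant a few long zero stretches of varying length around the
  # nonwear threshold
  for (k in seq_len(rpois(1, 2))) {
    len <- sample(100:300, 1)
    at <- sample(n - len, 1)
    steps[at:(at + len - 1)] <- 0L
  }
  steps[runif(n) < 0.01] <- NA_integer_
  steps
}

as_series_tibble <- function(steps, id = "S1",
                             start = as.Date("2016-03-07")) {
  n_days <- length(steps) / 1440L
  tibble::tibble(
    participant_id = id,
    date = rep(start + seq_len(n_days) - 1, each = 1440L),
    minute = rep(0:1439, times = n_days),
    steps = as.integer(steps)
  )
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# permutation p for the trend statistic, permuting group labels
oracle_trend_permutation <- function(values, group, n_perm = 2000) {
  z_obs <- glance(trend_test(values, group))$statistic
  z_perm <- replicate(n_perm, {
    glance(trend_test(values, sample(group)))$statistic
  })
  mean(abs(z_perm) >= abs(z_obs) - 1e-12)
}

# hand-rolled cluster-robust sandwich with the G/(G-1)*(N-1)/(N-K)
# small-sample factor, from first principles
oracle_cluster_vcov <- function(fit, cluster) {
  x <- model.matrix(fit)
  u <- residuals(fit)
  bread <- solve(crossprod(x))
  meat <- matrix(0, ncol(x), ncol(x))
  for (g in unique(cluster)) {
    idx <- cluster == g
    sg <- colSums(x[idx, , drop = FALSE] * u[idx])
    meat <- meat + tcrossprod(sg)
  }
  n <- nrow(x); k <- ncol(x); gn <- length(unique(cluster))
  corr <- gn / (gn - 1) * (n - 1) / (n - k)
  corr * bread %*% meat %*% bread
}
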