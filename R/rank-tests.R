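#' Spearman rank correlation with large-sample p-value
#'
#' Rank correlation on untransformed data with average (mid) ranks for
#' ties; the p-value uses the large-sample t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return One-row tibble: `estimate` (r_s), `statistic` (t), `p.value`,
#'   `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    abort("correlation undefined for constant input")
  }
  r <- cor(rank(x), rank(y))
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  tibble(estimate = r, statistic = t, p.value = p, n = n)
}

# exact null distribution of the doubled positive-rank sum via the
# shift algorithm: f(x) = prod_i (1 + x^(2 r_i)); counts over 2^n signings
signed_rank_counts <- function(doubled_ranks) {
  counts <- c(1, numeric(sum(doubled_ranks)))
  for (dr in doubled_ranks) {
    shifted <- c(numeric(dr), counts[seq_len(length(counts) - dr)])
    counts <- counts + shifted
  }
  counts  # counts[k + 1] = number of signings with doubled sum k
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped; ties among absolute differences get
#' midranks. For up to `exact_max` nonzero differences (default 25) the
#' p-value is exact, computed over all `2^n` sign assignments (midranks
#' included); beyond that, the normal approximation with tie-corrected
#' variance is used. Two-sided throughout.
#'
#' @param x,y Paired numeric vectors (the test is on `x - y`), or give
#'   differences directly in `x` with `y = NULL`.
#' @param exact_max Largest n for the exact path.
#' @return One-row tibble: `statistic` (positive-rank sum V),
#'   `p.value`, `n` (nonzero differences), `method`. When every
#'   difference is zero the result is degenerate: `statistic = 0`,
#'   `p.value = NA`, `method = "degenerate"`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(tibble(statistic = 0, p.value = NA_real_, n = 0L,
                  method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    counts <- signed_rank_counts(as.integer(round(2 * r)))
    total <- 2^n
    k <- as.integer(round(2 * v))
    p_le <- sum(counts[seq_len(k + 1)]) / total
    p_ge <- sum(counts[(k + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation, tie-corrected"
  }
  tibble(statistic = v, p.value = p, n = n, method = method)
}

#' Nonparametric test for trend across ordered groups
#'
#' Cuzick-type rank trend test with equally spaced group scores
#' (1, 2, ..., k) and midranks for ties; the variance carries the usual
#' tie correction. With two groups the statistic reduces exactly to the
#' Wilcoxon rank-sum z (tie-corrected, no continuity correction).
#'
#' @param values Numeric outcome (e.g. BMI).
#' @param group Ordered grouping (factor level order = trend order);
#'   incomplete pairs dropped.
#' @return Object of class `trend_test`: use [tidy()] for the per-group
#'   summary and [glance()] for the z statistic and two-sided p-value.
#' @export
trend_test <- function(values, group) {
  if (!is.factor(group)) group <- factor(group)
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  k <- nlevels(group)
  if (k < 2) abort("need at least 2 nonempty ordered groups")
  n <- length(values)
  scores <- seq_len(k)
  l <- scores[as.integer(group)]
  rk <- rank(values)
  big_t <- sum(l * rk)
  nj <- tabulate(as.integer(group), k)
  sum_l <- sum(scores * nj)
  e_t <- (n + 1) / 2 * sum_l
  ties <- table(rk)
  tie_factor <- 1 - sum(ties^3 - ties) / (n^3 - n)
  var_t <- (n + 1) / 12 * (n * sum(scores^2 * nj) - sum_l^2) * tie_factor
  if (var_t <= 0) abort("degenerate trend test (zero variance)")
  z <- (big_t - e_t) / sqrt(var_t)
  g_mean <- as.numeric(tapply(values, group, mean))
  g_sd <- as.numeric(tapply(values, group, sd))
  groups <- tibble(
    group = levels(group),
    score = scores,
    n = as.integer(nj),
    mean = g_mean,
    sd = g_sd
  )
  structure(
    list(groups = groups, statistic = z, p.value = 2 * pnorm(-abs(z)),
         n = n),
    class = "trend_test"
  )
}

#' @export
print.trend_test <- function(x, ...) {
  cat("Nonparametric test for trend across", nrow(x$groups),
      "ordered groups\n")
  print(x$groups)
  cat(sprintf("z = %.3f, two-sided p = %.4g (n = %d)\n",
              x$statistic, x$p.value, x$n))
  invisible(x)
}

#' @rdname trend_test
#' @param x A `trend_test` object.
#' @param ... Unused.
#' @method tidy trend_test
#' @export
tidy.trend_test <- function(x, ...) x$groups

#' @rdname trend_test
#' @method glance trend_test
#' @export
glance.trend_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, n = x$n,
         n_groups = nrow(x$groups))
}
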