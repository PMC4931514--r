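# Exact small-sample rank tests used for all between-sex comparisons, with
# the reporting conventions of the movement-ecology literature: U is the
# larger of U1/U2 and the two-sided p doubles the smaller tail of the exact
# null distribution.

#' Exact Mann-Whitney U test
#'
#' Two-sample rank test with the exact null distribution of U obtained by
#' the counting recursion over all rank configurations (ties: enumeration of
#' all group assignments of the observed midranks, when feasible). The
#' reported statistic is `max(U1, U2)`, so complete separation of n1 = 3 vs
#' n2 = 5 gives U = 15 with p = 2/56 = 0.036. The two-sided p doubles the
#' smaller exact tail (capped at 1); `p_convention = "tail_sum"` instead
#' sums both tails at least as extreme (identical under a symmetric null).
#'
#' @param x,y numeric samples.
#' @param p_convention `"double"` (default) or `"tail_sum"`.
#' @param exact_limit exact enumeration is used while `n1 * n2` (and, under
#'   ties, `choose(n1 + n2, n1)`) stays at or below this bound (default
#'   1e6); beyond it a normal approximation with tie correction is used and
#'   flagged.
#' @return object of class `exact_test` with fields `test`, `statistic`
#'   (U), `u1`, `u2`, `n1`, `n2`, `p_two_sided`, `method`
#'   (`"exact"`/`"normal_approx"`), `tie_note`.
#' @export
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6, 7, 8))  # U = 15, p = 0.036
mann_whitney_exact <- function(x, y, p_convention = c("double", "tail_sum"),
                               exact_limit = 1e6) {
  p_convention <- match.arg(p_convention)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks under ties
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- any(duplicated(pooled))
  tie_note <- if (ties) "ties present; midranks used" else NA_character_
  if (!ties && n1 * n2 <= exact_limit) {
    dist <- mw_null_distribution(n1, n2)           # P(U1 = 0..n1*n2)
    p <- mw_p_from_dist(dist, 0:(n1 * n2), u1, p_convention)
    method <- "exact"
  } else if (ties && choose(n1 + n2, n1) <= exact_limit) {
    sp <- utils::combn(n1 + n2, n1)
    us <- apply(sp, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    vals <- sort(unique(us))
    dist <- as.numeric(table(factor(us, levels = vals))) / ncol(sp)
    p <- mw_p_from_dist(dist, vals, u1, p_convention)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sig <- sqrt(n1 * n2 / 12 *
                  ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) /
                     ((n1 + n2) * (n1 + n2 - 1))))
    p <- min(1, 2 * stats::pnorm(-abs(u1 - mu) / sig))
    method <- "normal_approx"
  }
  structure(list(test = "mann_whitney", statistic = max(u1, u2),
                 u1 = u1, u2 = u2, n1 = n1, n2 = n2,
                 p_two_sided = p, method = method, tie_note = tie_note),
            class = "exact_test")
}

# exact null pmf of U1 for untied samples. The count generating function is
# the Gaussian binomial coefficient prod_{m=1}^{n1} (1 - q^(n2+m))/(1 - q^m),
# built up one factor at a time (polynomial multiply, then synthetic
# division by (1 - q^m) as stride-m cumulative sums).
mw_null_distribution <- function(n1, n2) {
  maxu <- n1 * n2
  p <- c(1, numeric(maxu))
  for (m in seq_len(n1)) {
    k <- n2 + m
    if (k <= maxu)
      p[(k + 1):(maxu + 1)] <- p[(k + 1):(maxu + 1)] - p[1:(maxu + 1 - k)]
    for (r0 in seq_len(min(m, maxu + 1))) {
      idx <- seq.int(r0, maxu + 1, by = m)
      p[idx] <- cumsum(p[idx])
    }
  }
  stopifnot(abs(sum(p) - choose(n1 + n2, n1)) < 1e-6)
  p / choose(n1 + n2, n1)
}

mw_p_from_dist <- function(pmf, vals, u_obs, p_convention) {
  lo <- sum(pmf[vals <= u_obs + 1e-9])
  hi <- sum(pmf[vals >= u_obs - 1e-9])
  if (p_convention == "double") return(min(1, 2 * min(lo, hi)))
  mu <- sum(vals * pmf)
  min(1, sum(pmf[abs(vals - mu) >= abs(u_obs - mu) - 1e-9]))
}

#' Exact Wilcoxon signed-rank test for paired values
#'
#' Differences are `before - after`; zero differences are dropped (count
#' noted). W is the sum of the ranks (midranks under tied magnitudes) of the
#' positive differences; the exact two-sided p doubles the smaller tail of
#' the null distribution over all 2^n sign patterns, computed by a
#' subset-sum convolution.
#'
#' @param before,after equal-length numeric vectors.
#' @param exact_limit exact computation while the number of non-zero pairs
#'   is at most this (default 25); beyond it, normal approximation.
#' @return `exact_test` object: `statistic` (W), `n_pairs` (non-zero),
#'   `n_zero_dropped`, `p_two_sided`, `method`, `tie_note`.
#' @export
wilcoxon_signed_rank_exact <- function(before, after, exact_limit = 25) {
  stopifnot(length(before) == length(after))
  d <- as.numeric(before) - as.numeric(after)
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (!length(d)) stop("degenerate test: all differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  tie_note <- if (ties) "tied magnitudes; midranks used" else NA_character_
  if (n <= exact_limit) {
    # doubled midranks are integers; pmf of 2W by subset-sum convolution
    w2 <- round(2 * r)
    pmf <- c(1, numeric(sum(w2)))
    for (wi in w2) {
      shifted <- c(numeric(wi), pmf[seq_len(length(pmf) - wi)])
      pmf <- pmf + shifted
    }
    pmf <- pmf / 2^n
    vals <- (seq_along(pmf) - 1) / 2
    lo <- sum(pmf[vals <= w + 1e-9]); hi <- sum(pmf[vals >= w - 1e-9])
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    p <- min(1, 2 * stats::pnorm(-abs(w - mu) / sig))
    method <- "normal_approx"
  }
  structure(list(test = "wilcoxon_signed_rank", statistic = w, n_pairs = n,
                 n_zero_dropped = n_zero, p_two_sided = p, method = method,
                 tie_note = tie_note),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Paper-style rendering of a test result
#'
#' `"U = 15, p = 0.036, n = 8"` for Mann-Whitney (n = n1 + n2),
#' `"W = 18, p = 0.14, n = 7"` for the signed-rank test.
#' @param x an `exact_test`.
#' @param ... unused.
#' @export
format.exact_test <- function(x, ...) {
  if (x$test == "mann_whitney")
    sprintf("U = %s, p = %s, n = %d", format(x$statistic),
            format(signif(x$p_two_sided, 2)), x$n1 + x$n2)
  else
    sprintf("W = %s, p = %s, n = %d", format(x$statistic),
            format(signif(x$p_two_sided, 2)), x$n_pairs)
}

#' Mean, sample standard deviation and n
#'
#' Descriptives in the "mean +/- SD" form; SD uses the n-1 denominator and
#' is reported absent (`NA`) for a single value.
#'
#' @param values numeric vector (length >= 1).
#' @return list of class `summary_msd`: `mean`, `sd`, `n`.
#' @export
summarize_msd <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty input")
  structure(list(mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else NA_real_,
                 n = length(values)),
            class = "summary_msd")
}

#' @export
print.summary_msd <- function(x, digits = 1, ...) {
  cat(sprintf("%.*f ± %s (n = %d)\n", digits, x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.*f", digits, x$sd), x$n))
  invisible(x)
}
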