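# Exact small-sample nonparametric tests and multiplicity correction.
#
# Exact p-values are computed by dynamic programming over the (doubled) midrank
# scores, which is equivalent to full enumeration of rank assignments / sign
# patterns but polynomial in n. Tests fall back to tie-corrected normal
# approximations above a configurable enumeration threshold.

#' Construct a test report
#'
#' Light container for a two-tailed hypothesis test result; all test functions
#' in the package return one. Supports [tidy()] and [glance()].
#'
#' @param test Test name.
#' @param statistic Test statistic.
#' @param p_value Two-tailed p-value in \[0, 1\] (NA only for degenerate input).
#' @param method One of `"exact"`, `"normal_approx"`, `"t"`, `"chi_square"`.
#' @param n Named integer vector of group sizes.
#' @param note Optional character note (degeneracies, dropped observations).
#' @return An object of class `surveil_test`.
#' @keywords internal
new_surveil_test <- function(test, statistic, p_value, method, n, note = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(
    list(
      test = test, statistic = unname(statistic), p_value = unname(p_value),
      method = method, n = n, tails = "two", note = note
    ),
    class = "surveil_test"
  )
}

#' @export
print.surveil_test <- function(x, ...) {
  cat(sprintf(
    "<%s> statistic = %.6g, two-tailed p = %.6g (%s; n = %s)\n",
    x$test, x$statistic, x$p_value, x$method,
    paste(x$n, collapse = ", ")
  ))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @rdname new_surveil_test
#' @param x A `surveil_test` object.
#' @param ... Unused.
#' @export
tidy.surveil_test <- function(x, ...) {
  tibble(
    test = x$test,
    statistic = x$statistic,
    p_value = x$p_value,
    method = x$method,
    n = sum(x$n),
    note = x$note %||% NA_character_
  )
}

#' @rdname new_surveil_test
#' @export
glance.surveil_test <- function(x, ...) tidy(x)

# distribution of the sum of `k` scores chosen from `scores` (integer vector),
# as a numeric vector of counts indexed by sum 0..sum(scores)
subset_sum_counts <- function(scores, k) {
  total <- sum(scores)
  # f[kk + 1, s + 1] = number of k-subsets summing to s
  f <- matrix(0, nrow = k + 1, ncol = total + 1)
  f[1, 1] <- 1
  for (r in scores) {
    upper <- min(k, nrow(f) - 1)
    for (kk in seq(upper, 1)) {
      idx <- seq_len(total + 1 - r)
      f[kk + 1, idx + r] <- f[kk + 1, idx + r] + f[kk, idx]
    }
  }
  f[k + 1, ]
}

two_tail_p <- function(counts, observed_index) {
  total <- sum(counts)
  lower <- sum(counts[seq_len(observed_index)]) / total
  upper <- sum(counts[seq(observed_index, length(counts))]) / total
  min(1, 2 * min(lower, upper))
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact p by full enumeration of rank assignments (via a subset-sum dynamic
#' program over doubled midranks, tie-safe) when `n + m <= exact_limit`;
#' otherwise a tie-corrected normal approximation with continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest combined sample size for which the exact null
#'   distribution is enumerated (default 12).
#' @return A [surveil_test][new_surveil_test] object with the U statistic of `x`.
#' @examples
#' mann_whitney(c(1, 2, 3, 4), c(5, 6, 7, 8))$p_value # 2/70
#' @export
mann_whitney <- function(x, y, exact_limit = 12) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  u_stat <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (N <= exact_limit) {
    scores <- as.integer(round(2 * r))
    counts <- subset_sum_counts(scores, n)
    w_obs <- as.integer(round(2 * sum(r[seq_len(n)])))
    p <- two_tail_p(counts, w_obs + 1)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- (n * m / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_stat - n * m / 2)
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  new_surveil_test("mann_whitney", u_stat, p, method, c(n = n, m = m))
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Exact p by enumeration of the `2^n` sign patterns (generating-function
#' dynamic program over doubled midranks) when the number of nonzero
#' differences is at most `exact_limit`; normal approximation otherwise.
#' Zero differences are dropped and counted in the report note.
#'
#' @param x Differences, or first member of each pair when `y` is given.
#' @param y Optional second member of each pair.
#' @inheritParams mann_whitney
#' @return A [surveil_test][new_surveil_test] with the W+ statistic.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 12) {
  d <- if (is.null(y)) as.numeric(x) else {
    stopifnot(length(x) == length(y))
    as.numeric(x) - as.numeric(y)
  }
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  note <- if (n_zero > 0) sprintf("%d zero differences dropped", n_zero)
  if (n == 0) {
    return(new_surveil_test(
      "wilcoxon_signed_rank", 0, 1, "exact", c(n = 0L),
      note = paste(c(note, "degenerate: all differences zero"), collapse = "; ")
    ))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  if (n <= exact_limit) {
    scores <- as.integer(round(2 * r))
    # counts over W+ on the doubled scale: product of (1 + z^score)
    counts <- numeric(sum(scores) + 1)
    counts[1] <- 1
    for (s in scores) {
      shifted <- c(numeric(s), counts[seq_len(length(counts) - s)])
      counts <- counts + shifted
    }
    p <- two_tail_p(counts, as.integer(round(2 * w_plus)) + 1)
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- w_plus - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  new_surveil_test("wilcoxon_signed_rank", w_plus, p, method, c(n = n), note = note)
}

#' Paired t tests
#'
#' `paired_t()` is the two-tailed t test on within-pair differences;
#' `ratio_paired_t()` applies it to log-transformed values (a test on ratios),
#' requiring strictly positive input.
#'
#' @param x,y Equal-length paired samples.
#' @return A [surveil_test][new_surveil_test].
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- as.numeric(x) - as.numeric(y)
  n <- length(d)
  if (n < 2) abort("need at least 2 pairs")
  s <- sd(d)
  # treat numerically constant differences as zero-variance
  if (s <= 1e-12 * max(abs(mean(d)), 1e-12)) {
    if (all(d == 0)) {
      return(new_surveil_test("paired_t", 0, 1, "t", c(n = n),
                              note = "degenerate: all differences zero"))
    }
    return(new_surveil_test("paired_t", NA_real_, NA_real_, "t", c(n = n),
                            note = "degenerate: zero-variance nonzero differences"))
  }
  tstat <- mean(d) / (s / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  new_surveil_test("paired_t", tstat, p, "t", c(n = n))
}

#' @rdname paired_t
#' @export
ratio_paired_t <- function(x, y) {
  if (any(x <= 0) || any(y <= 0)) abort("ratio-paired t requires strictly positive values")
  out <- paired_t(log(x), log(y))
  out$test <- "ratio_paired_t"
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-tailed p by the point-probability method: the sum of hypergeometric
#' probabilities (fixed margins) of all tables no more probable than the one
#' observed. A zero margin yields p = 1 with a note.
#'
#' @param table_2x2 Nonnegative integer 2x2 matrix.
#' @return A [surveil_test][new_surveil_test]; statistic is the sample odds ratio.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value # 2/252
#' @export
fisher_exact <- function(table_2x2) {
  tab <- as.matrix(table_2x2)
  if (!all(dim(tab) == c(2, 2))) abort("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) abort("table entries must be nonnegative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  odds <- (a * d) / (b * cc)
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) {
    return(new_surveil_test("fisher_exact", odds, 1, "exact",
                            c(n = sum(tab)), note = "degenerate: zero margin"))
  }
  k <- seq(max(0, c1 - r2), min(r1, c1))
  probs <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  new_surveil_test("fisher_exact", odds, p, "exact", c(n = sum(tab)))
}

#' Kruskal-Wallis rank-sum test
#'
#' Omnibus H statistic with tie correction and a chi-square p-value.
#'
#' @param groups List of numeric vectors (>= 2 groups).
#' @return A [surveil_test][new_surveil_test].
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes == 0)) abort("all groups must be nonempty")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * rbar^2) - 3 * (N + 1)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_corr > 0) H <- H / tie_corr else H <- 0
  p <- pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  new_surveil_test("kruskal_wallis", H, p, "chi_square",
                   setNames(as.integer(sizes), paste0("n", seq_along(sizes))))
}

#' Dunn's pairwise post hoc comparisons
#'
#' Pairwise z tests on mean ranks following [kruskal_wallis()], with
#' multiplicity adjustment (Benjamini-Hochberg default, Holm available).
#'
#' @inheritParams kruskal_wallis
#' @param p_adjust `"BH"` or `"holm"`.
#' @return Tibble with one row per group pair: `z`, `p_value`, `p_adjusted`.
#' @export
dunn_pairwise <- function(groups, p_adjust = c("BH", "holm")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.list(groups), length(groups) >= 2)
  nms <- names(groups) %||% paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  ties <- table(r)
  var_term <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(var_term * (1 / sizes[i] + 1 / sizes[j]))
    z <- (rbar[i] - rbar[j]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  out <- tibble(
    group1 = nms[pairs[1, ]],
    group2 = nms[pairs[2, ]],
    z = res[1, ],
    p_value = pmin(1, res[2, ])
  )
  out$p_adjusted <- if (p_adjust == "BH") bh_fdr(out$p_value) else stats::p.adjust(out$p_value, "holm")
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH with monotonicity enforcement; the returned vector is aligned
#' with the input positions.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) abort("p-values must be in [0, 1] and non-missing")
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}
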