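# Exact and classical categorical statistics used by the pipeline.

#' Clopper–Pearson exact binomial confidence interval
#'
#' Two-sided exact interval from Beta-distribution quantiles:
#' lower = Beta(x, n - x + 1) quantile at alpha/2 (0 when x = 0),
#' upper = Beta(x + 1, n - x) quantile at 1 - alpha/2 (1 when x = n).
#' Coverage is conservative (at least nominal).
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (n >= 1).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(33, 125)
#' clopper_pearson(0, 8)  # upper = 1 - 0.025^(1/8)
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n) {
    stop("require 0 <= x <= n and n >= 1", call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Construct a 2xK contingency table of successes by stratum
#'
#' @param successes Integer vector of successes (informative trials) per
#'   stratum.
#' @param totals Integer vector of stratum sizes.
#' @param labels Optional stratum labels.
#' @return A `contingency_2xk` object.
#' @export
contingency_2xk <- function(successes, totals, labels = NULL) {
  successes <- as.integer(successes)
  totals <- as.integer(totals)
  if (length(successes) != length(totals) || length(totals) < 2) {
    stop("need K >= 2 strata with matching successes/totals", call. = FALSE)
  }
  if (any(is.na(successes)) || any(is.na(totals)) ||
      any(successes < 0) || any(successes > totals)) {
    stop("require 0 <= successes[k] <= totals[k]", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("stratum_", seq_along(totals))
  structure(list(successes = successes, totals = totals,
                 labels = as.character(labels)),
            class = "contingency_2xk")
}

#' @export
print.contingency_2xk <- function(x, ...) {
  m <- rbind(success = x$successes, failure = x$totals - x$successes)
  colnames(m) <- x$labels
  print(m)
  invisible(x)
}

ti_test_result <- function(method, statistic, df, p_value) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value), class = "ti_test")
}

#' @export
print.ti_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic)) {
    cat(sprintf("  statistic = %.4f, df = %d\n", x$statistic, x$df))
  }
  # two significant figures in scientific notation below 1e-3, else two
  # decimals
  p <- x$p_value
  cat("  p =", if (p < 1e-3) formatC(p, format = "e", digits = 1)
      else formatC(p, format = "f", digits = 2), "\n")
  invisible(x)
}

#' Pearson chi-square test on a 2xK table
#'
#' Computes the chi-square statistic `sum((|O - E| - c)^2 / E)` with expected
#' counts from the product of margins. The continuity correction `c = 0.5`
#' is applied to 2x2 tables only (the convention of standard statistical
#' environments), with `c = 0` for K > 2; `correct` can override this.
#'
#' @param table A [contingency_2xk()] object.
#' @param correct `"auto"` (Yates for 2x2 only, the default), `TRUE` (always),
#'   or `FALSE` (never).
#' @return A `ti_test` result with `method`, `statistic`, `df = K - 1`, and
#'   upper-tail `p_value`.
#' @export
pearson_chi_square <- function(table, correct = "auto") {
  stopifnot(inherits(table, "contingency_2xk"))
  if (any(table$totals == 0)) stop("zero stratum total", call. = FALSE)
  K <- length(table$totals)
  obs <- rbind(table$successes, table$totals - table$successes)
  if (any(rowSums(obs) == 0)) stop("zero table margin", call. = FALSE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  use_yates <- if (identical(correct, "auto")) K == 2 else isTRUE(correct)
  cc <- if (use_yates) 0.5 else 0
  stat <- sum(pmax(abs(obs - expd) - cc, 0)^2 / expd)
  df <- K - 1L
  ti_test_result(if (use_yates) "chi_square_yates" else "chi_square",
                 stat, df, stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Two-sided Fisher exact test on a 2xK table by enumeration
#'
#' Enumerates every 2xK table with the observed margins; the p-value is the
#' total multivariate-hypergeometric probability of tables no more probable
#' than the observed one. A relative tolerance of 1e-7 on the probability
#' comparison absorbs floating-point ties. For 2x2 tables this reduces to the
#' classical two-sided hypergeometric Fisher test.
#'
#' @param table A [contingency_2xk()] object.
#' @param max_tables Enumeration guard: error when the candidate table count
#'   bound exceeds this (default 1e7).
#' @return A `ti_test` result (no statistic or df; exact `p_value`).
#' @export
fisher_exact_2xk <- function(table, max_tables = 1e7) {
  stopifnot(inherits(table, "contingency_2xk"))
  t_k <- table$totals
  K <- length(t_k)
  N <- sum(t_k)
  M <- sum(table$successes)
  bound <- prod(pmin(t_k, M) + 1)
  if (!is.finite(bound) || bound > max_tables) {
    stop("enumeration guard exceeded (", format(bound, big.mark = ","),
         " candidate tables > ", format(max_tables, big.mark = ","),
         "); a Monte-Carlo approximation would be required and is not",
         " provided", call. = FALSE)
  }
  lden <- lchoose(N, M)
  p_obs <- exp(sum(lchoose(t_k, table$successes)) - lden)
  tail_sums <- rev(cumsum(rev(t_k)))  # tail_sums[k] = sum(t_k[k:K])
  cutoff <- p_obs * (1 + 1e-7)
  p_total <- 0
  rec <- function(k, rem, lp) {
    if (k == K) {
      p <- exp(lp + lchoose(t_k[K], rem) - lden)
      if (p <= cutoff) p_total <<- p_total + p
      return(invisible())
    }
    lo <- max(0L, rem - tail_sums[k + 1])
    hi <- min(t_k[k], rem)
    for (sk in lo:hi) rec(k + 1L, rem - sk, lp + lchoose(t_k[k], sk))
  }
  rec(1L, M, 0)
  ti_test_result("fisher_exact", NA_real_, NA_integer_, min(p_total, 1))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between two raters'
#' categorical judgments over the same items, with chance agreement computed
#' from the rater marginals. When chance agreement is exactly 1 (both raters
#' degenerate on one category), kappa is defined as 1 under perfect agreement
#' and is otherwise undefined.
#'
#' @param rater1,rater2 Vectors of categorical ratings, equal length.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(rater1, rater2) {
  if (length(rater1) != length(rater2) || length(rater1) < 1) {
    stop("ratings must be non-empty vectors of equal length", call. = FALSE)
  }
  lev <- sort(unique(c(as.character(rater1), as.character(rater2))))
  r1 <- factor(as.character(rater1), levels = lev)
  r2 <- factor(as.character(rater2), levels = lev)
  n <- length(r1)
  tab <- table(r1, r2)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < .Machine$double.eps) {
    if (p_o == 1) return(1)
    stop("kappa undefined: chance agreement is 1 with observed disagreement",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}
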