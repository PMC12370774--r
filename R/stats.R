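#' D'Agostino-Pearson omnibus normality test
#'
#' Combines D'Agostino's skewness Z and the Anscombe-Glynn kurtosis Z
#' into the K-squared statistic, referred to a chi-squared distribution
#' with 2 degrees of freedom. Requires n >= 8.
#'
#' @param x Numeric sample.
#' @return `htest`-like list with `statistic` (K2) and `p.value`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) {
    tm_error("tm_invalid_params", "D'Agostino-Pearson requires n >= 8")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    tm_error("tm_constant_sample", "zero-variance sample")
  }
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3

  # skewness: D'Agostino (1970) transformation to normality
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  a <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / a + sqrt((Y / a)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  Eg2 <- -6 / (n + 1)
  Vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eg2) / sqrt(Vg2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  inner <- (1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4)))
  Z2 <- ((1 - 2 / (9 * A)) - sign(inner) * abs(inner)^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Z1^2 + Z2^2
  list(statistic = c(K2 = K2),
       p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       method = "D'Agostino-Pearson omnibus test")
}

#' Four-test normality battery
#'
#' Runs the D'Agostino-Pearson omnibus, Anderson-Darling, Shapiro-Wilk
#' and (Lilliefors-corrected) Kolmogorov-Smirnov normality tests and
#' combines them into a parametric/non-parametric verdict: parametric
#' when at least 3 of the 4 tests fail to reject at `alpha`
#' (`rule = "majority"`, the default), or when all 4 do
#' (`rule = "all"`). Samples with fewer than 8 values, or with zero
#' variance, are declared non-parametric with a warning rather than
#' crashing.
#'
#' @param x Numeric sample.
#' @param alpha Per-test significance level (default 0.05).
#' @param rule `"majority"` (>= 3 of 4) or `"all"` (4 of 4).
#' @return An object of class `NormalityReport`: per-test statistic
#'   and p-value, `n`, `passes` (0-4), `verdict` (`TRUE` =
#'   parametric), `rule`, `alpha`.
#' @export
normality_battery <- function(x, alpha = 0.05,
                              rule = c("majority", "all")) {
  rule <- match.arg(rule)
  x <- x[is.finite(x)]
  n <- length(x)
  tests <- list(dagostino_pearson = NULL, anderson_darling = NULL,
                shapiro_wilk = NULL, kolmogorov_smirnov = NULL)
  degenerate <- NULL
  if (n < 8L) {
    degenerate <- sprintf("n = %d < 8: all four tests need n >= 8", n)
  } else if (stats::var(x) == 0) {
    degenerate <- "zero-variance sample"
  }
  if (!is.null(degenerate)) {
    tm_warn("tm_nonparametric_fallback",
            paste0(degenerate, "; verdict set to non-parametric"))
    return(structure(
      list(tests = tests, n = n, passes = 0L, verdict = FALSE,
           rule = rule, alpha = alpha, note = degenerate),
      class = "NormalityReport"))
  }
  xs <- if (n > 5000L) sort(x)[round(seq(1L, n, length.out = 5000L))] else x
  res <- list(
    dagostino_pearson = dagostino_pearson_test(x),
    anderson_darling = nortest::ad.test(x),
    shapiro_wilk = stats::shapiro.test(xs),
    kolmogorov_smirnov = nortest::lillie.test(x))
  tests <- lapply(res, function(t) {
    list(statistic = unname(t$statistic), p.value = t$p.value)
  })
  passes <- sum(vapply(tests, function(t) t$p.value > alpha, TRUE))
  verdict <- if (rule == "majority") passes >= 3L else passes == 4L
  structure(
    list(tests = tests, n = n, passes = passes, verdict = verdict,
         rule = rule, alpha = alpha, note = NULL),
    class = "NormalityReport")
}

#' @export
print.NormalityReport <- function(x, ...) {
  cat(sprintf("NormalityReport (n = %d): %d/4 tests pass at alpha = %g -> %s\n",
              x$n, x$passes, x$alpha,
              if (x$verdict) "parametric" else "non-parametric"))
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    if (!is.null(t)) {
      cat(sprintf("  %-20s stat = %8.4f  p = %.4g\n", nm, t$statistic,
                  t$p.value))
    }
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value when the combined sample size does not exceed
#' `exact_max_n` (default 20): the full permutation distribution of U
#' is enumerated over all group assignments, which handles ties
#' exactly; the two-sided p is `2 * min(P(U <= u), P(U >= u))` capped
#' at 1. Larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b Numeric samples.
#' @param exact_max_n Largest combined n for the exact path.
#' @return List with `statistic` (U of the first sample), `p.value`,
#'   `exact` flag.
#' @export
mann_whitney_test <- function(a, b, exact_max_n = 20L) {
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) {
    tm_error("tm_empty_group", "both groups must be non-empty")
  }
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  if (n <= exact_max_n) {
    sets <- utils::combn(n, n1)
    rsums <- colSums(matrix(r[sets], nrow = n1))
    Us <- rsums - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9))
    p <- min(p, 1)
    list(statistic = c(U = U), p.value = p, exact = TRUE)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    list(statistic = c(U = U),
         p.value = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
  }
}

significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Two-group comparison through the normality-gated pathway
#'
#' Runs the [normality_battery()] on each group; when both verdicts
#' are parametric the groups are compared with a two-sided unpaired
#' Student's t-test (pooled variance; Welch by flag), otherwise with a
#' two-sided Mann-Whitney test. Either path can be forced via `test`.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param alpha Significance level used both in the battery and for
#'   the star annotation.
#' @param test `"auto"` (battery-gated), `"student"`,
#'   or `"mann_whitney"`.
#' @param welch Use the Welch unequal-variance t-test on the
#'   parametric path.
#' @param rule Battery combination rule, see [normality_battery()].
#' @param exact_max_n Exact Mann-Whitney cutoff, see
#'   [mann_whitney_test()].
#' @return An object of class `ComparisonResult`: `test_name`
#'   (`"unpaired_t"` or `"mann_whitney"`), `statistic`, `p_value`,
#'   `stars`, group sizes, means and medians, and the two
#'   `NormalityReport`s (`NULL` when forced).
#' @export
compare_groups <- function(a, b, alpha = 0.05,
                           test = c("auto", "student", "mann_whitney"),
                           welch = FALSE, rule = c("majority", "all"),
                           exact_max_n = 20L) {
  test <- match.arg(test)
  rule <- match.arg(rule)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    tm_error("tm_empty_group", "each group needs at least 2 finite values")
  }
  norm_a <- norm_b <- NULL
  if (test == "auto") {
    norm_a <- normality_battery(a, alpha, rule)
    norm_b <- normality_battery(b, alpha, rule)
    test <- if (norm_a$verdict && norm_b$verdict) "student" else "mann_whitney"
  }
  if (test == "student") {
    tt <- stats::t.test(a, b, var.equal = !welch)
    statistic <- unname(tt$statistic)
    p <- tt$p.value
    name <- "unpaired_t"
  } else {
    mw <- mann_whitney_test(a, b, exact_max_n)
    statistic <- unname(mw$statistic)
    p <- mw$p.value
    name <- "mann_whitney"
  }
  structure(
    list(test_name = name, statistic = statistic, p_value = p,
         stars = significance_stars(p),
         n = c(a = length(a), b = length(b)),
         mean = c(a = mean(a), b = mean(b)),
         median = c(a = stats::median(a), b = stats::median(b)),
         normality = list(a = norm_a, b = norm_b),
         alpha = alpha),
    class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("ComparisonResult: %s, statistic = %.4f, p = %.4g %s\n",
              x$test_name, x$statistic, x$p_value, x$stars))
  cat(sprintf("  n = (%d, %d), means = (%.4g, %.4g), medians = (%.4g, %.4g)\n",
              x$n[1L], x$n[2L], x$mean[1L], x$mean[2L],
              x$median[1L], x$median[2L]))
  invisible(x)
}
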