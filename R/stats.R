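#' @title Group-comparison statistics
#' @description One-way ANOVA and pairwise two-sample t tests computable
#'   either from raw per-animal values or exactly from published summary
#'   statistics (mean, sample SD, n per group), plus the strict p < alpha
#'   significance criterion.
#' @name groupstats
NULL

#' Summarise one group
#'
#' @param values Numeric vector, n >= 2.
#' @param label Group label.
#' @return A `group_summary`: `label`, `n`, `mean`, `sd` (sample SD,
#'   n - 1 denominator).
#' @export
group_summary <- function(values, label = "group") {
  if (length(values) < 2) stop("need n >= 2 values")
  structure(list(label = label, n = length(values),
                 mean = mean(values), sd = stats::sd(values)),
            class = "group_summary")
}

.as_summary <- function(x, label = "group") {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x)) return(group_summary(x, label))
  stopifnot(all(c("n", "mean", "sd") %in% names(x)))
  if (x$n < 2) stop("need n >= 2")
  if (x$sd < 0) stop("sd must be >= 0")
  structure(list(label = x$label %||% label, n = x$n, mean = x$mean,
                 sd = x$sd), class = "group_summary")
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance (default) or Welch t test computed exactly from
#' (mean, SD, n) pairs; two-sided p value. Degenerate cases with both SDs
#' zero return p = 1 (equal means) or p = 0 (different means) by
#' convention.
#'
#' @param a,b `group_summary` objects (or lists with `n`, `mean`, `sd`).
#' @param method `"pooled"` or `"welch"`.
#' @return A `test_result`: `statistic`, `df`, `p_value`, `comparison`.
#' @export
pooled_t_summary <- function(a, b, method = c("pooled", "welch")) {
  method <- match.arg(method)
  a <- .as_summary(a, "a"); b <- .as_summary(b, "b")
  comp <- paste(a$label, "vs", b$label)
  if (a$sd == 0 && b$sd == 0) {
    p <- if (a$mean == b$mean) 1 else 0
    return(structure(list(statistic = if (p == 1) 0 else Inf,
                          df = a$n + b$n - 2, p_value = p,
                          comparison = comp, method = method),
                     class = "test_result"))
  }
  if (method == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(statistic = t, df = df, p_value = p, comparison = comp,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, df = %s, p = %.4g\n", x$comparison,
              if (identical(x$method, "anova")) "F" else "t",
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' One-way ANOVA from raw values or summaries
#'
#' For summaries the between-group sum of squares is reconstructed from the
#' group means and the within-group sum of squares from the SDs; this is
#' exact, identical to the raw-data ANOVA.
#'
#' @param groups Either a list of numeric vectors (raw mode) or a data
#'   frame with columns `n`, `mean`, `sd` (summary mode).
#' @return A `test_result` with the F `statistic`, `df = c(k - 1, N - k)`
#'   and `p_value`.
#' @export
anova_oneway <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("n", "mean", "sd") %in% names(groups)))
    n <- groups$n; m <- groups$mean; s <- groups$sd
  } else {
    if (length(groups) < 2) stop("need >= 2 groups")
    n <- vapply(groups, length, 1L)
    m <- vapply(groups, mean, 1)
    s <- vapply(groups, stats::sd, 1)
  }
  k <- length(n)
  if (k < 2) stop("need >= 2 groups")
  if (any(n < 2)) stop("each group needs n >= 2")
  N <- sum(n)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0) {
    p <- if (ssb == 0) 1 else 0
    return(structure(list(statistic = if (p == 1) 0 else Inf,
                          df = c(df1, df2), p_value = p,
                          comparison = "one-way ANOVA", method = "anova"),
                     class = "test_result"))
  }
  f <- (ssb / df1) / (ssw / df2)
  structure(list(statistic = f, df = c(df1, df2),
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 comparison = "one-way ANOVA", method = "anova"),
            class = "test_result")
}

#' All pairwise comparisons from a summary table
#'
#' @param summaries Data frame with columns `label`, `n`, `mean`, `sd`.
#' @param method `"pooled"`, `"welch"`, or `"tukey"` (Tukey HSD using the
#'   pooled within-group mean square from all groups).
#' @return Tidy data frame: `group_a`, `group_b`, `statistic`, `df`, `p`.
#' @export
pairwise_tests <- function(summaries, method = c("pooled", "welch", "tukey")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(summaries),
            all(c("label", "n", "mean", "sd") %in% names(summaries)))
  k <- nrow(summaries)
  out <- NULL
  if (method == "tukey") {
    N <- sum(summaries$n)
    msw <- sum((summaries$n - 1) * summaries$sd^2) / (N - k)
    dfw <- N - k
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- as.list(summaries[i, ]); b <- as.list(summaries[j, ])
    if (method %in% c("pooled", "welch")) {
      r <- pooled_t_summary(a, b, method = method)
      row <- data.frame(group_a = a$label, group_b = b$label,
                        statistic = r$statistic, df = r$df[1],
                        p = r$p_value)
    } else {
      se <- sqrt(msw / 2 * (1 / a$n + 1 / b$n))
      q <- abs(a$mean - b$mean) / se
      row <- data.frame(group_a = a$label, group_b = b$label,
                        statistic = q, df = dfw,
                        p = stats::ptukey(q, k, dfw, lower.tail = FALSE))
    }
    out <- rbind(out, row)
  }
  out
}

#' Mark significant comparisons
#'
#' Applies the strict criterion p < alpha; p equal to alpha is not
#' significant.
#'
#' @param results Data frame with a `p` column (e.g. [pairwise_tests()]).
#' @param alpha Significance level.
#' @return The input with a logical `significant` column appended.
#' @export
significance_pattern <- function(results, alpha = 0.05) {
  if (is.null(results) || nrow(results) == 0) {
    return(data.frame(p = numeric(0), significant = logical(0)))
  }
  results$significant <- results$p < alpha
  results
}
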