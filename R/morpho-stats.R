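# Feeding-experiment statistics: two-sample t-tests from raw data or
# published summary statistics (mean, SD, n), one-way ANOVA, Tukey HSD,
# and relative effect sizes.

#' Group summary statistics for a trait
#'
#' The unit of summary-statistics testing: mean, SD and n for one group
#' and trait, in the trait's units (g, mm, mm^2).
#'
#' @param group,trait labels.
#' @param mean,sd,n summary statistics (`sd >= 0`, `n >= 2`).
#' @return a `morpho_summary` row (data frame).
#' @export
morpho_summary <- function(group, trait, mean, sd, n) {
  stopifnot(all(sd >= 0), all(n >= 2))
  out <- data.frame(group = group, trait = trait, mean = mean, sd = sd,
                    n = as.integer(n), stringsAsFactors = FALSE)
  class(out) <- c("morpho_summary", "data.frame")
  out
}

#' Summarize a per-individual measurement table
#'
#' @param measurements data frame with `group` and one numeric column
#'   per trait (non-numeric id columns are ignored).
#' @return a `morpho_summary` data frame (group x trait long format).
#' @export
summarize_morpho <- function(measurements) {
  stopifnot("group" %in% names(measurements))
  traits <- names(measurements)[vapply(measurements, is.numeric,
                                       logical(1))]
  rows <- list()
  for (g in unique(measurements$group)) {
    sub <- measurements[measurements$group == g, , drop = FALSE]
    for (tr in traits)
      rows[[length(rows) + 1L]] <-
        morpho_summary(g, tr, mean(sub[[tr]]), sd(sub[[tr]]), nrow(sub))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("morpho_summary", "data.frame")
  out
}

#' Two-sample t-test from summary statistics
#'
#' Student's pooled-variance test (default) or Welch's test computed
#' directly from `(mean, sd, n)` pairs, so published summary tables can
#' be re-tested without raw data. Degenerate case: zero pooled variance
#' gives p = 1 for equal means and p = 0 (reported below 1e-12)
#' otherwise.
#'
#' @param g1,g2 single-row [morpho_summary()] objects (or lists with
#'   `mean`, `sd`, `n`).
#' @param pooled use the pooled-variance (Student) form; `FALSE` for
#'   Welch.
#' @return a `test_result` list: `statistic, df, p, estimate` (mean
#'   difference g1 - g2).
#' @export
ttest_from_summary <- function(g1, g2, pooled = TRUE) {
  m1 <- g1$mean; s1 <- g1$sd; n1 <- g1$n
  m2 <- g2$mean; s2 <- g2$sd; n2 <- g2$n
  stopifnot(n1 >= 2, n2 >= 2)
  est <- m1 - m2
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    p <- if (est == 0) 1 else 0
    tstat <- if (est == 0) 0 else sign(est) * Inf
  } else {
    tstat <- est / se
    p <- 2 * pt(-abs(tstat), df)
  }
  structure(list(statistic = tstat, df = df, p = p, estimate = est,
                 method = if (pooled) "pooled t" else "welch t"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic,
              paste(signif(x$df, 6), collapse = ", "), x$p))
  invisible(x)
}

#' Two-sample t-test from raw values
#'
#' Raw-data twin of [ttest_from_summary()]: identical to applying the
#' summary-statistics test to the samples' own mean/sd/n.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param pooled as in [ttest_from_summary()].
#' @return a `test_result`.
#' @export
ttest_from_raw <- function(x, y, pooled = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations")
  ttest_from_summary(list(mean = mean(x), sd = sd(x), n = length(x)),
                     list(mean = mean(y), sd = sd(y), n = length(y)),
                     pooled = pooled)
}

#' One-way ANOVA on a list of samples
#'
#' Classical F = MSB/MSW with df (k - 1, N - k). Zero within-group
#' variance with equal means gives F = 0, p = 1; with unequal means the
#' p-value is reported as 0 (below 1e-12).
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return a `test_result` with `statistic` = F and `df = c(df1, df2)`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0)
      return(structure(list(statistic = 0, df = c(df1, df2), p = 1,
                            estimate = 0, method = "one-way ANOVA"),
                       class = "test_result"))
    return(structure(list(statistic = Inf, df = c(df1, df2), p = 0,
                          estimate = ssb, method = "one-way ANOVA"),
                     class = "test_result"))
  }
  f <- (ssb / df1) / (ssw / df2)
  structure(list(statistic = f, df = c(df1, df2),
                 p = pf(f, df1, df2, lower.tail = FALSE),
                 estimate = ssb / df1, method = "one-way ANOVA",
                 msw = ssw / df2, ns = ns, means = means),
            class = "test_result")
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' All-pairs post-hoc comparison after one-way ANOVA. For groups i, j:
#' \deqn{q = |m_i - m_j| / \sqrt{(MSW/2)(1/n_i + 1/n_j)}}
#' with the p-value from the studentized-range distribution with
#' parameters (k, N - k) (Tukey-Kramer for unequal n).
#'
#' @param groups list of numeric samples, named or not.
#' @return data frame `group_a, group_b, estimate, q, p`.
#' @export
tukey_hsd <- function(groups) {
  fit <- anova_oneway(groups)
  k <- length(groups)
  if (is.null(names(groups)))
    names(groups) <- sprintf("group_%d", seq_len(k))
  msw <- if (is.null(fit$msw)) 0 else fit$msw
  df2 <- fit$df[2]
  pairs <- combn(names(groups), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- mean(groups[[a]]) - mean(groups[[b]])
    se <- sqrt(msw / 2 * (1 / length(groups[[a]]) +
                            1 / length(groups[[b]])))
    if (se == 0) {
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0
    } else {
      q <- abs(diff) / se
      p <- ptukey(q, k, df2, lower.tail = FALSE)
    }
    data.frame(group_a = a, group_b = b, estimate = diff, q = q, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative treated-versus-control effect
#'
#' `(control mean - treated mean) / control mean`: positive values mean
#' the treated group is smaller (e.g. 0.08 for "8 percent lighter").
#'
#' @param treated,control [morpho_summary()] rows or lists with `mean`.
#' @return the relative difference.
#' @export
percent_effect <- function(treated, control) {
  if (control$mean == 0) stop("control mean must be non-zero")
  (control$mean - treated$mean) / control$mean
}
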