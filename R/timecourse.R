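# Time-course analysis: LOWESS normalization of two-channel
# intensities, scaling to the day-4 royal-jelly reference, paired
# day-pair tests, and trend-shape classification.

DAY_PAIRS <- list(c(4L, 5L), c(5L, 6L), c(4L, 6L))

#' LOWESS (MA) normalization of two-channel intensities
#'
#' Background-subtracted channel intensities are floored at `floor`,
#' converted to M = log2(ch1/ch2) and A = mean log2 intensity, and the
#' locally weighted linear fit of M on A (tri-cube weights, `span`,
#' `iterations` robustness passes) is subtracted from M, removing
#' intensity-dependent dye bias.
#'
#' @param ch1,ch2 positive intensity vectors (same length, >= 10 probes).
#' @param span LOWESS smoother span (fraction of probes).
#' @param iterations robustness (bisquare) iterations.
#' @param floor clamp for non-positive intensities.
#' @return data frame `A, M, M_normalized, fit`.
#' @export
lowess_normalize <- function(ch1, ch2, span = 0.4, iterations = 2L,
                             floor = 1) {
  stopifnot(length(ch1) == length(ch2))
  if (length(ch1) < 10L)
    stop("need at least 10 probes for the LOWESS fit")
  ch1 <- pmax(ch1, floor)
  ch2 <- pmax(ch2, floor)
  M <- log2(ch1) - log2(ch2)
  A <- (log2(ch1) + log2(ch2)) / 2
  fit <- lowess(A, M, f = span, iter = iterations)
  fitted <- approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
  data.frame(A = A, M = M, M_normalized = M - fitted, fit = fitted)
}

#' Scale a time course to the day-4 royal-jelly reference
#'
#' Divides every value of a miRNA (both jellies, all days) by that
#' miRNA's mean royal-jelly day-4 value, so relative concentrations are
#' 1 on day 4 in royal jelly. miRNAs with a non-positive reference are
#' flagged and excluded.
#'
#' @param tc long data frame `mirna, jelly, day, replicate, value`.
#' @return the data frame on the relative scale, with attribute
#'   `excluded` (miRNAs dropped for a zero reference) and
#'   `scale = "relative"`.
#' @export
scale_to_reference <- function(tc) {
  stopifnot(all(c("mirna", "jelly", "day", "value") %in% names(tc)))
  ref <- tapply(tc$value[tc$jelly == "RJ" & tc$day == 4L],
                tc$mirna[tc$jelly == "RJ" & tc$day == 4L], mean)
  bad <- names(ref)[!is.finite(ref) | ref <= 0]
  missing_ref <- setdiff(unique(tc$mirna), names(ref))
  excluded <- union(bad, missing_ref)
  out <- tc[!tc$mirna %in% excluded, , drop = FALSE]
  out$value <- out$value / as.vector(ref[out$mirna])
  attr(out, "excluded") <- excluded
  attr(out, "scale") <- "relative"
  out
}

# paired two-sided t on log-free values; constant nonzero difference
# with zero spread is reported as p = 0 (i.e. < 1e-12)
paired_t_p <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  sdd <- sd(d)
  if (sdd == 0) return(if (mean(d) == 0) 1 else 0)
  tstat <- mean(d) / (sdd / sqrt(length(d)))
  2 * pt(-abs(tstat), length(d) - 1L)
}

#' Paired day-pair tests per miRNA and jelly
#'
#' Two-sided paired t-tests (pairing by replicate index) for the day
#' pairs 4-5, 5-6 and 4-6.
#'
#' @param tc long data frame `mirna, jelly, day, replicate, value` with
#'   equal replicate counts per cell.
#' @return data frame `mirna, jelly, day_a, day_b, mean_a, mean_b, p`.
#' @export
daypair_tests <- function(tc) {
  stopifnot(all(c("mirna", "jelly", "day", "replicate", "value") %in%
                  names(tc)))
  rows <- list()
  for (m in unique(tc$mirna)) for (j in unique(tc$jelly)) {
    cell <- tc[tc$mirna == m & tc$jelly == j, , drop = FALSE]
    if (!nrow(cell)) next
    series <- lapply(c(4L, 5L, 6L), function(d) {
      s <- cell[cell$day == d, , drop = FALSE]
      s$value[order(s$replicate)]
    })
    ns <- lengths(series)
    if (length(unique(ns)) != 1L)
      stop("paired tests need equal replicate counts per day")
    for (dp in DAY_PAIRS) {
      a <- series[[dp[1] - 3L]]
      b <- series[[dp[2] - 3L]]
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = m, jelly = j, day_a = dp[1], day_b = dp[2],
        mean_a = mean(a), mean_b = mean(b), p = paired_t_p(a, b),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify the shape of a 3-day concentration trend
#'
#' Rule table on the relative day means d4, d5, d6 and the day-pair
#' p-values, applied in the order: transient_increase (significant rise
#' then significant fall), dip (significant fall then significant
#' rise), drop_then_stable (significant fall, then no significant
#' change), persistent_increase (monotone rise, day4-day6 significant),
#' persistent_fall (monotone fall, day4-day6 significant), else none.
#' drop_then_stable precedes persistent_fall because a strong drop with
#' a stable tail also satisfies the monotone-fall conditions whenever
#' the tail drifts down by noise.
#'
#' @param means numeric `c(d4, d5, d6)` relative means.
#' @param p named numeric day-pair p-values
#'   `c(p45 = , p56 = , p46 = )`.
#' @param alpha significance level (0.05 for small qRT-PCR style panels;
#'   0.01 for replicate microarray style panels).
#' @return the trend class as a character scalar.
#' @export
classify_trend <- function(means, p, alpha = 0.05) {
  stopifnot(length(means) == 3L,
            all(c("p45", "p56", "p46") %in% names(p)))
  d4 <- means[1]; d5 <- means[2]; d6 <- means[3]
  s45 <- p[["p45"]] < alpha
  s56 <- p[["p56"]] < alpha
  s46 <- p[["p46"]] < alpha
  if (d5 > d4 && s45 && d6 < d5 && s56) return("transient_increase")
  if (d5 < d4 && s45 && d6 > d5 && s56) return("dip")
  if (d5 < d4 && s45 && !s56) return("drop_then_stable")
  if (d5 > d4 && d6 >= d5 && s46) return("persistent_increase")
  if (d5 < d4 && d6 <= d5 && s46) return("persistent_fall")
  "none"
}

#' Trend calls for every miRNA and jelly of a time course
#'
#' Convenience wrapper: scales to the royal-jelly day-4 reference (if
#' not already relative), runs [daypair_tests()] and applies
#' [classify_trend()].
#'
#' @param tc long time-course data frame.
#' @param alpha significance level for the day-pair tests.
#' @return data frame `mirna, jelly, class, d4, d5, d6, p45, p56, p46`.
#' @export
classify_trends <- function(tc, alpha = 0.05) {
  if (!identical(attr(tc, "scale"), "relative"))
    tc <- scale_to_reference(tc)
  tests <- daypair_tests(tc)
  key <- unique(tests[, c("mirna", "jelly")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sub <- tests[tests$mirna == key$mirna[i] &
                   tests$jelly == key$jelly[i], , drop = FALSE]
    get <- function(a, b) sub[sub$day_a == a & sub$day_b == b, ,
                              drop = FALSE]
    means <- c(get(4L, 5L)$mean_a, get(4L, 5L)$mean_b,
               get(5L, 6L)$mean_b)
    p <- c(p45 = get(4L, 5L)$p, p56 = get(5L, 6L)$p, p46 = get(4L, 6L)$p)
    data.frame(mirna = key$mirna[i], jelly = key$jelly[i],
               class = classify_trend(means, p, alpha),
               d4 = means[1], d5 = means[2], d6 = means[3],
               p45 = p[["p45"]], p56 = p[["p56"]], p46 = p[["p46"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
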