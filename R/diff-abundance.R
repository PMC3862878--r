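# Count-based differential abundance between two sequencing libraries:
# the Audic-Claverie posterior-predictive test, library-size-normalized
# fold changes, BH correction, the ratio/p DE rule, and target-overlap
# accounting.

#' Audic-Claverie two-library count test
#'
#' Exact test for equality of a feature's concentration in two libraries
#' of sizes N1 and N2, based on the Poisson posterior predictive
#' distribution of the second count given the first:
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}
#' The two-sided p-value doubles the smaller of the lower and upper tail
#' sums at the observed `y`, capped at 1. All mass terms are evaluated in
#' log space via log-gamma; the upper tail is `1 -` the strict lower tail
#' with a non-negativity clamp.
#'
#' @param x,y counts in library 1 and 2 (vectorized).
#' @param n1,n2 library sizes (> 0).
#' @return two-sided p-values in `[0, 1]`.
#' @export
ac_pvalue <- function(x, y, n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library sizes must be > 0")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  r <- rep_len(n2 / n1, n)
  vapply(seq_len(n), function(i) {
    lo <- ac_tail(x[i], y[i], r[i])           # P(Y <= y)
    hi <- 1 - ac_tail(x[i], y[i] - 1, r[i])   # P(Y >= y), clamped
    hi <- max(hi, 0)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
}

# P(Y <= y | x) under the posterior predictive; log-space summation
ac_tail <- function(x, y, r) {
  if (y < 0) return(0)
  k <- 0:y
  lp <- k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(r)
  min(1, exp(logsumexp(lp)))
}

#' Normalized fold change between two library counts
#'
#' `((x + pc) / N1) / ((y + pc) / N2)` with pseudocount `pc` so features
#' absent from one library still get a finite concentration ratio.
#'
#' @param x,y counts; `n1,n2` library sizes; `pseudocount` default 0.5.
#' @return positive fold changes (library 1 relative to library 2).
#' @export
fold_change <- function(x, y, n1, n2, pseudocount = 0.5) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library sizes must be > 0")
  ((x + pseudocount) / n1) / ((y + pseudocount) / n2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  stop_if_not_prob(p, "p-values")
  p.adjust(p, method = "BH")
}

#' Differential abundance table for paired library counts
#'
#' Computes fold change, Audic-Claverie p, BH q and direction for every
#' feature of a two-library count table.
#'
#' @param counts data frame with columns `feature, x, y` (counts in
#'   libraries 1 and 2).
#' @param n1,n2 library sizes; default to `sum(x)` / `sum(y)`.
#' @param pseudocount passed to [fold_change()].
#' @return a `diff_result` data frame:
#'   `feature, x, y, fold_change, p, q, direction`.
#' @export
diff_abundance <- function(counts, n1 = sum(counts$x), n2 = sum(counts$y),
                           pseudocount = 0.5) {
  stopifnot(all(c("feature", "x", "y") %in% names(counts)))
  fc <- fold_change(counts$x, counts$y, n1, n2, pseudocount)
  p <- ac_pvalue(counts$x, counts$y, n1, n2)
  out <- data.frame(feature = counts$feature, x = counts$x, y = counts$y,
                    n1 = n1, n2 = n2, fold_change = fc, p = p,
                    q = bh_adjust(p),
                    direction = ifelse(fc > 1, "up_in_1",
                                       ifelse(fc < 1, "up_in_2", "none")),
                    stringsAsFactors = FALSE)
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Differentially expressed feature rule (ratio and p thresholds)
#'
#' Flags features with normalized fold change above `ratio_thresh` in
#' either direction and Audic-Claverie p below `p_thresh` (the
#' "ratio > 2 and p < 0.01" rule), and partitions them by direction.
#'
#' @param diff a `diff_result` from [diff_abundance()].
#' @param ratio_thresh fold-change threshold (either direction).
#' @param p_thresh p-value threshold.
#' @param use_q use BH-adjusted q instead of raw p.
#' @return list with `de` (flagged subset of the table), `up` and `down`
#'   feature vectors (up/down in library 1) and `n_de`.
#' @export
de_genes <- function(diff, ratio_thresh = 2, p_thresh = 0.01,
                     use_q = FALSE) {
  stopifnot(inherits(diff, "diff_result"))
  pv <- if (use_q) diff$q else diff$p
  big <- pmax(diff$fold_change, 1 / diff$fold_change) > ratio_thresh
  flag <- big & pv < p_thresh
  de <- diff[flag, , drop = FALSE]
  list(de = de,
       up = de$feature[de$fold_change > 1],
       down = de$feature[de$fold_change < 1],
       n_de = sum(flag))
}

#' Target-overlap accounting for a differential table
#'
#' Given predicted targets of one miRNA, reports how many are in the
#' expressed universe, how many of those move up or down at `p_thresh`,
#' and the strongly repressed subset (down more than `strong_fold`-fold).
#'
#' @param diff a `diff_result` (x = treated, y = control).
#' @param target_set character vector of predicted target genes.
#' @param expressed_set character vector of expressed genes (defaults to
#'   all features in `diff`).
#' @param p_thresh significance threshold for up/down calls.
#' @param strong_fold fold threshold defining the strong-repression set.
#' @return list of counts and the underlying gene sets.
#' @export
target_overlap <- function(diff, target_set, expressed_set = diff$feature,
                           p_thresh = 0.05, strong_fold = 2) {
  stopifnot(inherits(diff, "diff_result"))
  expressed_targets <- intersect(target_set, expressed_set)
  sub <- diff[diff$feature %in% expressed_targets, , drop = FALSE]
  up <- sub$feature[sub$p < p_thresh & sub$fold_change > 1]
  down <- sub$feature[sub$p < p_thresh & sub$fold_change < 1]
  strong_down <- sub$feature[sub$p < p_thresh &
                               sub$fold_change < 1 / strong_fold]
  list(n_targets = length(unique(target_set)),
       n_expressed = length(expressed_targets),
       n_up = length(up), n_down = length(down),
       n_strong_down = length(strong_down),
       up = up, down = down, strong_down = strong_down)
}
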