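# Shared fixture builders; everything is generated in code under fixed
# seeds, no stored data.

make_tags <- function(...) {
  df <- data.frame(...)
  names(df) <- c("sequence", "count")
  df
}

small_catalog <- function() {
  data.frame(
    sequence = c("ACGTACGTACGTACGTACGTA",   # mir-001 isoform 1
                 "ACGTACGTACGTACGTACGT",    # mir-001 isoform 2
                 "TTTTCCCCGGGGAAAATTTTCC",  # mir-002
                 "GGGGAAAACCCCTTTTGGGGAA",  # trna-001
                 "CCCCTTTTAAAAGGGGCCCCTT"), # ncrna-001
    gene = c("mir-001", "mir-001", "mir-002", "trna-001", "ncrna-001"),
    isoform = c("mir-001.1", "mir-001.2", "mir-002.1", "trna-001.1",
                "ncrna-001.1"),
    category = c("known_miRNA", "known_miRNA", "known_miRNA", "tRNA",
                 "other_ncRNA"),
    stringsAsFactors = FALSE) -> cat
  class(cat) <- c("rna_catalog", "data.frame")
  cat
}

# independent naive AC posterior-predictive tail: direct linear-space
# summation of the mass terms via their ratio recurrence
# t_{k+1}/t_k = r (x+k+1) / ((k+1)(1+r)), t_0 = (1+r)^-(x+1)
ac_oracle <- function(x, y, n1, n2) {
  r <- n2 / n1
  term <- (1 + r)^-(x + 1)
  lower <- 0
  upper <- 0
  k <- 0
  repeat {
    if (k <= y) lower <- lower + term
    if (k >= y) upper <- upper + term
    if (k > y && k > x * r && term < 1e-30) break
    term <- term * r * (x + k + 1) / ((k + 1) * (1 + r))
    k <- k + 1
  }
  min(1, 2 * min(lower, upper))
}

# enumerate all subsets for the Poisson-binomial tail
poisbinom_enum <- function(p, k) {
  m <- length(p)
  total <- 0
  for (mask in 0:(2^m - 1)) {
    bits <- as.integer(intToBits(mask))[1:m]
    if (sum(bits) >= k)
      total <- total + prod(ifelse(bits == 1, p, 1 - p))
  }
  total
}

# random small diff_result-like table for rule tests
random_diff <- function(features, fc, p) {
  out <- data.frame(feature = features, x = 0L, y = 0L, n1 = 1, n2 = 1,
                    fold_change = fc, p = p, q = p,
                    direction = ifelse(fc > 1, "up_in_1",
                                       ifelse(fc < 1, "up_in_2", "none")),
                    stringsAsFactors = FALSE)
  class(out) <- c("diff_result", "data.frame")
  out
}
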