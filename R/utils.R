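# Internal helpers shared across modules.

#' Derive a reproducible sub-seed for one generator stream
#'
#' A single user-facing seed drives one explicit RNG stream per synthetic
#' operation, so that regenerating one artifact never perturbs another.
#' The tag is hashed with a small polynomial rolling hash; all arithmetic
#' stays below 2^53 so the result is exact, and the seed fits in a 32-bit
#' integer.
#'
#' @param seed integer master seed.
#' @param tag character scalar naming the stream (e.g. "annotation").
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% m
  as.integer((abs(seed) %% m + h * 1009) %% m)
}

#' Run code under a local RNG stream
#' @keywords internal
with_stream <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, tag))
  expr
}

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Generate n distinct random DNA sequences
#' @keywords internal
random_dna <- function(n, min_len = 18L, max_len = 30L, avoid = character()) {
  if (n == 0L) return(character())
  # unique 18-mer space is 4^18; explicit guard for pathological requests
  if (n > 4^min_len / 2)
    stop("requested sequence count exceeds the available unique k-mer space")
  seen <- new.env(parent = emptyenv())
  for (s in avoid) assign(s, TRUE, envir = seen)
  out <- character(n)
  i <- 0L
  while (i < n) {
    len <- sample.int(max_len - min_len + 1L, 1L) + min_len - 1L
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (is.null(seen[[s]])) {
      assign(s, TRUE, envir = seen)
      i <- i + 1L
      out[i] <- s
    }
  }
  out
}

# reverse complement over ACGT (U converted to T first)
revcomp <- function(x) {
  x <- chartr("Uu", "Tt", x)
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

stop_if_not_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("%s must lie in [0, 1]", what))
  invisible(x)
}
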