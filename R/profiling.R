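# Small-RNA tag library filtering, classification and quantification.

#' Collapsed small-RNA tag library
#'
#' The unit of sequencing input: unique tag sequences with read counts.
#'
#' @param library_id character label.
#' @param tags data frame with columns `sequence` (ACGT strings; U is
#'   converted to T) and `count` (non-negative integers). Duplicate
#'   sequences are collapsed by summing counts.
#' @return a `tag_library`: list with `library_id`, `tags`, `total_reads`.
#' @export
tag_library <- function(library_id, tags) {
  stopifnot(is.character(library_id), length(library_id) == 1L)
  if (nrow(tags) == 0L) {
    tags <- data.frame(sequence = character(), count = integer(),
                       stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("sequence", "count") %in% names(tags)))
    if (any(tags$count < 0)) stop("tag counts must be non-negative")
    tags$sequence <- chartr("Uu", "TT", toupper(tags$sequence))
    if (!all(grepl("^[ACGT]+$", tags$sequence)))
      stop("tag sequences must be over the ACGT alphabet")
    if (anyDuplicated(tags$sequence)) {
      agg <- tapply(tags$count, tags$sequence, sum)
      tags <- data.frame(sequence = names(agg),
                         count = as.vector(agg), stringsAsFactors = FALSE)
    }
    tags <- tags[order(tags$sequence, method = "radix"), , drop = FALSE]
    rownames(tags) <- NULL
  }
  structure(list(library_id = library_id, tags = tags,
                 total_reads = sum(tags$count)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag_library '%s': %d unique tags, %s reads\n",
              x$library_id, nrow(x$tags),
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Length-filter a tag library
#'
#' Retains tags whose sequence length lies in `[min_len, max_len]`
#' (defaults 18-30 nt, the gel-excised small-RNA fraction); counts are
#' preserved unchanged.
#'
#' @param lib a [tag_library()].
#' @param min_len,max_len inclusive length bounds.
#' @return a filtered `tag_library`.
#' @export
filter_tags <- function(lib, min_len = 18L, max_len = 30L) {
  stopifnot(inherits(lib, "tag_library"))
  if (min_len > max_len) stop("'min_len' must be <= 'max_len'")
  len <- nchar(lib$tags$sequence)
  keep <- len >= min_len & len <= max_len
  tag_library(lib$library_id, lib$tags[keep, , drop = FALSE])
}

#' Classify tags against an annotation catalog
#'
#' Exact, full-length, sense-strand sequence lookup. A tag matching
#' several categories is assigned by `precedence` (known miRNAs first by
#' default, matching the miRNA-centric accounting of jelly libraries);
#' tags matching nothing are `unannotated`. Within a category the
#' reported feature is the lexicographically first matching feature id;
#' [quantify_mirnas()] re-resolves multi-gene miRNA tags to every gene.
#'
#' @param lib a [tag_library()].
#' @param catalog an `rna_catalog` data frame
#'   (`sequence, gene, isoform, category`).
#' @param precedence category order used to break multi-category matches.
#' @return a `classified_library`: the tag table with `category` and
#'   `feature` columns plus library metadata.
#' @export
classify_tags <- function(lib, catalog,
                          precedence = c("known_miRNA", "tRNA",
                                         "other_ncRNA", "genic_mRNA")) {
  stopifnot(inherits(lib, "tag_library"))
  stopifnot(all(precedence %in% SMALLRNA_CATEGORIES))
  tags <- lib$tags
  category <- rep("unannotated", nrow(tags))
  feature <- rep(NA_character_, nrow(tags))
  cat_df <- as.data.frame(catalog)
  for (cl in precedence) {
    sub <- cat_df[cat_df$category == cl, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$gene, method = "radix"), , drop = FALSE]
    idx <- match(tags$sequence, sub$sequence)
    hit <- !is.na(idx) & category == "unannotated"
    category[hit] <- cl
    feature[hit] <- sub$gene[idx[hit]]
  }
  out <- data.frame(sequence = tags$sequence, count = tags$count,
                    category = category, feature = feature,
                    stringsAsFactors = FALSE)
  structure(list(library_id = lib$library_id, tags = out,
                 total_reads = lib$total_reads),
            class = "classified_library")
}

#' Read-fraction composition by annotation category
#'
#' Fractions are computed over reads (counts), not unique tags, matching
#' how library composition percentages are reported for sequencing runs.
#'
#' @param classified a `classified_library` from [classify_tags()].
#' @return named numeric vector over all five categories, summing to 1.
#' @export
composition <- function(classified) {
  stopifnot(inherits(classified, "classified_library"))
  if (classified$total_reads == 0)
    stop("cannot compute composition of an empty library")
  counts <- tapply(classified$tags$count, classified$tags$category, sum)
  out <- setNames(numeric(length(SMALLRNA_CATEGORIES)),
                  SMALLRNA_CATEGORIES)
  out[names(counts)] <- counts
  out / classified$total_reads
}

#' Digital miRNA expression profile
#'
#' Per-gene count = sum of the read counts of tags assigned to any of the
#' gene's isoforms (a tag whose sequence is an isoform of several genes
#' contributes to each, a documented double-counting rule). CPM
#' normalizes by the classified library's total reads.
#'
#' @param classified a `classified_library`.
#' @param catalog the `rna_catalog` used for classification.
#' @return a `mirna_profile` data frame (`gene, count, cpm`) with
#'   `library_id` and `library_size` attributes; all catalog miRNA genes
#'   are reported, zeros included.
#' @export
quantify_mirnas <- function(classified, catalog) {
  stopifnot(inherits(classified, "classified_library"))
  cat_df <- as.data.frame(catalog)
  mir <- cat_df[cat_df$category == "known_miRNA", , drop = FALSE]
  genes <- sort(unique(mir$gene), method = "radix")
  counts <- setNames(numeric(length(genes)), genes)
  tags <- classified$tags[classified$tags$category == "known_miRNA", ,
                          drop = FALSE]
  if (nrow(tags) && nrow(mir)) {
    # expand to every (tag, gene) pair sharing a sequence
    hit <- merge(tags[, c("sequence", "count")],
                 unique(mir[, c("sequence", "gene")]), by = "sequence")
    if (nrow(hit)) {
      agg <- tapply(hit$count, hit$gene, sum)
      counts[names(agg)] <- agg
    }
  }
  size <- classified$total_reads
  out <- data.frame(gene = genes, count = as.vector(counts),
                    cpm = if (size > 0) as.vector(counts) * 1e6 / size
                          else 0, stringsAsFactors = FALSE)
  attr(out, "library_id") <- classified$library_id
  attr(out, "library_size") <- size
  class(out) <- c("mirna_profile", "data.frame")
  out
}

#' Detection summary across miRNA profiles
#'
#' Presence = count >= `detection_min` (default 1 read). Reports
#' per-library detected counts, the union and intersection of detected
#' gene sets, and the low-count set with fewer than `low_count` reads in
#' every library, for which concentration differences are considered
#' meaningless.
#'
#' @param ... two or more `mirna_profile` objects (or a single list).
#' @param detection_min minimal count to call a gene present.
#' @param low_count threshold defining the low-count set.
#' @return list with `detected` (named list of gene vectors),
#'   `n_detected`, `union`, `intersection`, `low_count_set`.
#' @export
detection_summary <- function(..., detection_min = 1, low_count = 10) {
  profiles <- list(...)
  if (length(profiles) == 1L && !inherits(profiles[[1]], "mirna_profile"))
    profiles <- profiles[[1]]
  stopifnot(length(profiles) >= 1L)
  ids <- vapply(seq_along(profiles), function(i) {
    id <- attr(profiles[[i]], "library_id")
    if (is.null(id)) sprintf("library_%d", i) else id
  }, character(1))
  detected <- lapply(profiles, function(p)
    p$gene[p$count >= detection_min])
  names(detected) <- ids
  genes <- sort(unique(unlist(lapply(profiles, `[[`, "gene"))),
                method = "radix")
  maxc <- rep(0, length(genes))
  for (p in profiles) {
    m <- match(p$gene, genes)
    maxc[m] <- pmax(maxc[m], p$count)
  }
  list(detected = detected,
       n_detected = vapply(detected, length, integer(1)),
       union = sort(unique(unlist(detected)), method = "radix"),
       intersection = sort(Reduce(intersect, detected), method = "radix"),
       low_count_set = genes[maxc < low_count])
}
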