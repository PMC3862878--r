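# Readers and writers for the plain-text interchange formats:
# tag TSV (sequence<TAB>count), catalog FASTA (header gene|isoform|category),
# target-map TSV (mirna<TAB>mrna), GMT term sets, count and result TSVs.

#' Write / read a collapsed tag TSV (`sequence<TAB>count`)
#' @param lib a [tag_library()].
#' @param path file path.
#' @return `read_tag_tsv` returns a `tag_library`.
#' @export
write_tag_tsv <- function(lib, path) {
  stopifnot(inherits(lib, "tag_library"))
  write.table(lib$tags, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_tag_tsv
#' @param library_id label for the loaded library (file stem by default).
#' @export
read_tag_tsv <- function(path, library_id = NULL) {
  if (is.null(library_id))
    library_id <- sub("\\.[^.]*$", "", basename(path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  tag_library(library_id, df)
}

#' Write / read an annotation catalog as FASTA
#'
#' One record per isoform with header `gene|isoform|category`.
#' @param catalog an `rna_catalog`.
#' @param path file path.
#' @export
write_catalog_fasta <- function(catalog, path) {
  seqs <- Biostrings::DNAStringSet(catalog$sequence)
  names(seqs) <- paste(catalog$gene, catalog$isoform, catalog$category,
                       sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' @rdname write_catalog_fasta
#' @export
read_catalog_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("catalog FASTA headers must be 'gene|isoform|category'")
  cat <- data.frame(sequence = as.character(seqs),
                    gene = vapply(parts, `[`, "", 1L),
                    isoform = vapply(parts, `[`, "", 2L),
                    category = vapply(parts, `[`, "", 3L),
                    stringsAsFactors = FALSE)
  rownames(cat) <- NULL
  class(cat) <- c("rna_catalog", "data.frame")
  cat
}

#' Read tags from FASTA or FASTQ
#'
#' FASTA records may carry a `count=N` token in the header (collapsed
#' reads); otherwise each record counts once. FASTQ reads are collapsed
#' by identical sequence; an optional mean-quality floor discards reads
#' whose mean Phred score is below it, qualities are otherwise ignored.
#'
#' @param path input file.
#' @param library_id label (file stem by default).
#' @param min_mean_quality optional mean Phred floor (FASTQ only).
#' @return a [tag_library()].
#' @export
read_tags_fasta <- function(path, library_id = NULL) {
  if (is.null(library_id))
    library_id <- sub("\\.[^.]*$", "", basename(path))
  seqs <- Biostrings::readDNAStringSet(path)
  m <- regmatches(names(seqs), regexpr("count=[0-9]+", names(seqs)))
  counts <- rep(1L, length(seqs))
  has <- grepl("count=[0-9]+", names(seqs))
  counts[has] <- as.integer(sub("count=", "", m))
  tag_library(library_id, data.frame(sequence = as.character(seqs),
                                     count = counts,
                                     stringsAsFactors = FALSE))
}

#' @rdname read_tags_fasta
#' @export
read_tags_fastq <- function(path, library_id = NULL,
                            min_mean_quality = NULL) {
  if (is.null(library_id))
    library_id <- sub("\\.[^.]*$", "", basename(path))
  # readQualityScaledDNAStringSet warns that fastq metadata columns are
  # dropped; we only need sequence and quality
  reads <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path))
  if (!is.null(min_mean_quality)) {
    q <- methods::as(Biostrings::quality(reads), "IntegerList")
    keep <- vapply(q, function(v) mean(v) >= min_mean_quality, logical(1))
    reads <- reads[keep]
  }
  tag_library(library_id,
              data.frame(sequence = as.character(reads), count = 1L,
                         stringsAsFactors = FALSE))
}

#' Write / read a target map TSV (`mirna<TAB>mrna` edge list)
#'
#' The declared universe is stored in comment header lines
#' (`# universe: <id>`), so a map with unexpressed universe genes
#' round-trips losslessly.
#' @param tmap a [target_map()].
#' @param path file path.
#' @export
write_target_map <- function(tmap, path) {
  stopifnot(inherits(tmap, "target_map"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# universe: %s", tmap$universe), con)
  writeLines("mirna\tmrna", con)
  for (m in names(tmap$targets))
    if (length(tmap$targets[[m]]))
      writeLines(paste(m, tmap$targets[[m]], sep = "\t"), con)
  invisible(path)
}

#' @rdname write_target_map
#' @param universe optional explicit universe; otherwise taken from the
#'   `# universe:` header lines, falling back to the observed mRNA ids.
#' @export
read_target_map <- function(path, universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  uni_lines <- grep("^# universe: ", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(body)]
  if (length(body) && body[1] == "mirna\tmrna") body <- body[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  df <- data.frame(mirna = vapply(parts, `[`, "", 1L),
                   mrna = vapply(parts, `[`, "", 2L),
                   stringsAsFactors = FALSE)
  if (is.null(universe)) {
    universe <- if (length(uni_lines))
      sub("^# universe: ", "", uni_lines) else unique(df$mrna)
  }
  target_map(split(df$mrna, df$mirna), universe)
}

#' Read / write GMT term-set files
#'
#' Tab-separated: term id, description, then member genes.
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors with a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("GMT lines need term, description and >=1 gene")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "description") <- setNames(vapply(parts, `[`, "", 2L),
                                        names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene vectors; an optional `description`
#'   attribute supplies the second column.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
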