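test_that("length filter keeps exactly the in-range tags with counts intact", {
  lib <- tag_library("t", make_tags(
    c(strrep("ACGT", 5), "ACGTACGTACGTACG"), c(7L, 3L)))
  f <- filter_tags(lib)
  expect_equal(nrow(f$tags), 1)
  expect_equal(f$tags$sequence, strrep("ACGT", 5))
  expect_equal(f$total_reads, 7)
  expect_error(filter_tags(lib, min_len = 25, max_len = 20), "min_len")
  empty <- filter_tags(tag_library("e", data.frame()))
  expect_equal(empty$total_reads, 0)
})

test_that("a tight length window matches a brute-force scan", {
  set.seed(42)
  seqs <- unique(replicate(60, paste(
    sample(c("A", "C", "G", "T"), sample(15:35, 1), replace = TRUE),
    collapse = "")))
  lib <- tag_library("mix", make_tags(seqs, seq_along(seqs)))
  f <- filter_tags(lib, 21, 21)
  brute <- lib$tags[nchar(lib$tags$sequence) == 21, ]
  expect_setequal(f$tags$sequence, brute$sequence)
  expect_equal(f$total_reads, sum(brute$count))
})

test_that("classification is exact-match with miRNA-first precedence", {
  cat <- small_catalog()
  lib <- tag_library("t", make_tags(
    c(cat$sequence[1],            # miRNA isoform
      cat$sequence[4],            # tRNA
      strrep("ATGC", 5)),         # nothing
    c(10L, 5L, 2L)))
  cl <- classify_tags(lib, cat)
  got <- setNames(cl$tags$category, cl$tags$sequence)
  expect_equal(got[[cat$sequence[1]]], "known_miRNA")
  expect_equal(got[[cat$sequence[4]]], "tRNA")
  expect_equal(got[[strrep("ATGC", 5)]], "unannotated")
  expect_equal(cl$tags$feature[cl$tags$sequence == cat$sequence[1]],
               "mir-001")
  expect_true(is.na(cl$tags$feature[cl$tags$category == "unannotated"]))
})

test_that("a sequence present in two catalog classes follows precedence", {
  cat <- small_catalog()
  dup <- rbind(cat, data.frame(sequence = cat$sequence[1],
                               gene = "trna-099", isoform = "trna-099.1",
                               category = "tRNA"))
  class(dup) <- c("rna_catalog", "data.frame")
  lib <- tag_library("t", make_tags(cat$sequence[1], 4L))
  expect_equal(classify_tags(lib, dup)$tags$category, "known_miRNA")
  flipped <- classify_tags(lib, dup,
                           precedence = c("tRNA", "known_miRNA"))
  expect_equal(flipped$tags$category, "tRNA")
})

test_that("classification does not depend on tag input order", {
  cat <- small_catalog()
  seqs <- c(cat$sequence, strrep("TTTA", 5))
  lib1 <- tag_library("a", make_tags(seqs, 1:6))
  lib2 <- tag_library("b", make_tags(rev(seqs), 6:1))
  c1 <- classify_tags(lib1, cat)$tags
  c2 <- classify_tags(lib2, cat)$tags
  expect_equal(c1[order(c1$sequence), c("sequence", "category", "feature")],
               c2[order(c2$sequence), c("sequence", "category", "feature")])
})

test_that("composition is read-weighted and sums to one", {
  cat <- small_catalog()
  lib <- tag_library("t", make_tags(
    c(cat$sequence[1], cat$sequence[4], cat$sequence[5], strrep("ATGC", 5)),
    c(51L, 17L, 6L, 26L)))
  comp <- composition(classify_tags(lib, cat))
  expect_equal(comp[["known_miRNA"]], 0.51)
  expect_equal(comp[["tRNA"]], 0.17)
  expect_equal(comp[["other_ncRNA"]], 0.06)
  expect_equal(comp[["unannotated"]], 0.26)
  expect_equal(sum(comp), 1)
  only <- tag_library("o", make_tags(cat$sequence[4], 9L))
  expect_equal(composition(classify_tags(only, cat))[["tRNA"]], 1)
  expect_error(composition(classify_tags(tag_library("e", data.frame()),
                                         cat)), "empty")
})

test_that("miRNA quantification sums isoforms and conserves reads", {
  cat <- small_catalog()
  lib <- tag_library("t", make_tags(
    c(cat$sequence[1], cat$sequence[2], cat$sequence[3]),
    c(30L, 12L, 5L)))
  prof <- quantify_mirnas(classify_tags(lib, cat), cat)
  expect_equal(prof$count[prof$gene == "mir-001"], 42)
  expect_equal(prof$count[prof$gene == "mir-002"], 5)
  expect_equal(prof$cpm, prof$count * 1e6 / lib$total_reads)
  # conservation: per-gene counts sum to the miRNA-category read count
  cl <- classify_tags(lib, cat)
  expect_equal(sum(prof$count),
               sum(cl$tags$count[cl$tags$category == "known_miRNA"]))
  # no miRNA tags -> all-zero profile over all catalog genes
  none <- tag_library("n", make_tags(cat$sequence[4], 3L))
  p0 <- quantify_mirnas(classify_tags(none, cat), cat)
  expect_true(all(p0$count == 0))
  expect_setequal(p0$gene, c("mir-001", "mir-002"))
})

test_that("detection summary reports presence, overlap and low-count sets", {
  mk <- function(id, genes, counts) {
    p <- data.frame(gene = genes, count = counts,
                    cpm = counts, stringsAsFactors = FALSE)
    attr(p, "library_id") <- id
    class(p) <- c("mirna_profile", "data.frame")
    p
  }
  a <- mk("A", c("m1", "m2"), c(5, 0))
  b <- mk("B", c("m1", "m2"), c(0, 3))
  det <- detection_summary(a, b)
  expect_equal(unname(det$n_detected), c(1L, 1L))
  expect_length(det$union, 2)
  expect_length(det$intersection, 0)
  expect_setequal(det$low_count_set, c("m1", "m2"))
  big <- detection_summary(mk("A", "m1", 100), mk("B", "m1", 50))
  expect_length(big$low_count_set, 0)
  # random fixture against naive set arithmetic
  set.seed(9)
  genes <- sprintf("g%02d", 1:30)
  pa <- mk("A", genes, rpois(30, 4))
  pb <- mk("B", genes, rpois(30, 4))
  det2 <- detection_summary(pa, pb)
  expect_setequal(det2$union,
                  union(genes[pa$count >= 1], genes[pb$count >= 1]))
  expect_setequal(det2$intersection,
                  intersect(genes[pa$count >= 1], genes[pb$count >= 1]))
  expect_setequal(det2$low_count_set,
                  genes[pmax(pa$count, pb$count) < 10])
})

test_that("synthetic library composition matches the generator within 3 binomial SDs", {
  cfg <- sim_config(seed = 21, library_size_wj = 1e5, library_size_rj = 1e5)
  catalog <- gen_annotation(cfg)
  libs <- gen_jelly_libraries(cfg, catalog)
  comp <- composition(classify_tags(filter_tags(libs$wj), catalog))
  for (categ in names(cfg$composition_wj)) {
    p <- cfg$composition_wj[[categ]]
    sd3 <- 3 * sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(comp[[categ]] - p), sd3 + 1e-12)
  }
})

test_that("tag TSV, catalog FASTA and FASTQ readers round-trip", {
  cfg <- sim_config(seed = 31, n_mirna_genes = 5, n_trna = 3,
                    n_other_nc = 2, n_genic = 2,
                    timecourse_trends = c(dip = 2))
  catalog <- gen_annotation(cfg)
  fa <- tempfile(fileext = ".fa")
  write_catalog_fasta(catalog, fa)
  back <- read_catalog_fasta(fa)
  expect_equal(as.data.frame(back), as.data.frame(catalog))
  lib <- tag_library("x", make_tags(catalog$sequence[1:3], c(4L, 2L, 9L)))
  tsv <- tempfile(fileext = ".tsv")
  write_tag_tsv(lib, tsv)
  expect_equal(read_tag_tsv(tsv, "x"), lib)
  # FASTQ collapses identical sequences; a mean-quality floor drops reads
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGTACGTACGTACGT", "+", strrep("I", 20),
               "@r2", "ACGTACGTACGTACGTACGT", "+", strrep("I", 20),
               "@r3", "TTTTACGTACGTACGTACGT", "+", strrep("#", 20)), fq)
  got <- read_tags_fastq(fq, "q")
  expect_equal(sum(got$tags$count), 3)
  expect_equal(got$tags$count[got$tags$sequence ==
                                "ACGTACGTACGTACGTACGT"], 2)
  hq <- read_tags_fastq(fq, "q", min_mean_quality = 20)
  expect_equal(sum(hq$tags$count), 2)
})
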