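test_that("sim_config validates compositions, depletion and fold range", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  bad <- c(known_miRNA = 0.5, tRNA = 0.2, other_ncRNA = 0.1,
           genic_mRNA = 0.1, unannotated = 0.2)
  expect_error(sim_config(composition_wj = bad), "sum to 1")
  expect_error(sim_config(depletion_factor = 0.5), "depletion_factor")
  expect_error(sim_config(fold_range = c(10, 2)), "fold_range")
  expect_error(sim_config(timecourse_trends = c(dip = 100)),
               "n_mirna_genes")
})

test_that("annotation catalogs are deterministic, seed-sensitive and unique", {
  cfg <- sim_config(seed = 1)
  a <- gen_annotation(cfg)
  b <- gen_annotation(cfg)
  expect_identical(a, b)
  c2 <- gen_annotation(sim_config(seed = 2))
  expect_false(identical(a$sequence, c2$sequence))
  expect_false(anyDuplicated(a$sequence) > 0)
  expect_true(all(nchar(a$sequence) >= 18 & nchar(a$sequence) <= 30))
  # every miRNA gene has at least one isoform
  mir <- a[a$category == "known_miRNA", ]
  expect_setequal(unique(mir$gene), sprintf("mir-%03d", 1:58))
})

test_that("an empty miRNA class leaves other classes populated", {
  cfg <- sim_config(seed = 3, n_mirna_genes = 0,
                    timecourse_trends = c(dip = 0))
  cat0 <- gen_annotation(cfg)
  expect_equal(sum(cat0$category == "known_miRNA"), 0)
  expect_equal(sum(cat0$category == "tRNA"), cfg$n_trna)
  expect_equal(sum(cat0$category == "other_ncRNA"), cfg$n_other_nc)
})

test_that("jelly libraries hit the configured composition and record truth", {
  cfg <- sim_config(seed = 11)
  catalog <- gen_annotation(cfg)
  libs <- gen_jelly_libraries(cfg, catalog)
  expect_equal(libs$wj$total_reads, cfg$library_size_wj)
  expect_equal(sum(libs$wj$tags$count), libs$wj$total_reads)
  # observed WJ miRNA fraction within 0.51 +- 0.02 (binomial SD ~ 0.0011)
  cl <- classify_tags(libs$wj, catalog)
  comp <- composition(cl)
  expect_lt(abs(comp[["known_miRNA"]] - 0.51), 0.02)
  expect_lt(abs(comp[["tRNA"]] - 0.17), 0.02)
  expect_equal(sum(comp), 1)
  # truth: one fold per gene, geometric mean equal to the global factor
  mf <- libs$truth$mirna_fold
  expect_equal(nrow(mf), 58)
  expect_equal(exp(mean(log(mf$true_fold))), cfg$depletion_factor,
               tolerance = 1e-10)
})

test_that("null configuration gives unit true ratios and identical sampling", {
  comp <- c(known_miRNA = 0.4, tRNA = 0.3, other_ncRNA = 0.1,
            genic_mRNA = 0.05, unannotated = 0.15)
  cfg <- sim_config(seed = 5, depletion_factor = 1, fold_range = c(1, 1),
                    composition_wj = comp, composition_rj = comp)
  libs <- gen_jelly_libraries(cfg, gen_annotation(cfg))
  expect_true(all(libs$truth$mirna_fold$true_fold == 1))
  expect_equal(libs$truth$p_wj, libs$truth$p_rj, tolerance = 1e-12)
})

test_that("library generation is byte-identical across runs (TSV)", {
  cfg <- sim_config(seed = 7, library_size_wj = 2e4, library_size_rj = 2e4)
  catalog <- gen_annotation(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_tag_tsv(gen_jelly_libraries(cfg, catalog)$wj, f1)
  write_tag_tsv(gen_jelly_libraries(cfg, catalog)$wj, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("tag category frequencies follow the composition vector (chi-square GOF)", {
  cfg <- sim_config(seed = 13, library_size_wj = 1e5, library_size_rj = 1e5)
  catalog <- gen_annotation(cfg)
  libs <- gen_jelly_libraries(cfg, catalog)
  cl <- classify_tags(libs$wj, catalog)
  obs <- sapply(split(cl$tags$count, cl$tags$category), sum)
  expected <- cfg$composition_wj[cfg$composition_wj > 0]
  obs <- obs[names(expected)]
  gof <- suppressWarnings(chisq.test(obs, p = expected))
  expect_gt(gof$p.value, 0.001)
})

test_that("timecourse generator realizes planted shapes exactly at zero noise", {
  cfg <- sim_config(seed = 2, timecourse_noise_sd = 0,
                    timecourse_trends = c(persistent_fall = 3))
  tc <- gen_timecourse(cfg)
  wj <- tc$data[tc$data$jelly == "WJ", ]
  for (m in unique(wj$mirna)) {
    mm <- tapply(wj$value[wj$mirna == m], wj$day[wj$mirna == m], mean)
    expect_true(mm[["4"]] > mm[["5"]] && mm[["5"]] > mm[["6"]])
  }
  # royal jelly: first panel miRNA pinned at the 2.6-fold day4/day5 drop
  rj <- tc$data[tc$data$jelly == "RJ" & tc$data$mirna == tc$truth$mirna[1], ]
  mm <- tapply(rj$value, rj$day, mean)
  expect_equal(mm[["4"]] / mm[["5"]], 2.6, tolerance = 1e-12)
  expect_identical(gen_timecourse(cfg)$data, tc$data)
})

test_that("larval expression plants the configured repression on targets", {
  cfg <- sim_config(seed = 4, n_mrna = 400, repression_factor = 0.5)
  # a bare map without a top-miRNA annotation represses every target
  genes <- sprintf("mRNA-%04d", 1:400)
  tmap <- target_map(list(`mir-001` = genes[1:6], `mir-002` = genes[5:10],
                          `mir-003` = genes[200:205]), genes)
  expr <- gen_larval_expression(cfg, tmap)
  targets <- unique(unlist(tmap$targets))
  expect_true(all(expr$true_ratio$true_ratio[
    expr$true_ratio$gene %in% targets] == 0.5))
  expect_true(all(expr$true_ratio$true_ratio[
    !expr$true_ratio$gene %in% targets] == 1))
  # neutral repression: every true ratio is 1
  cfg1 <- sim_config(seed = 4, n_mrna = 400, repression_factor = 1)
  expr1 <- gen_larval_expression(cfg1, tmap)
  expect_true(all(expr1$true_ratio$true_ratio == 1))
  expect_identical(gen_larval_expression(cfg, tmap)$counts, expr$counts)
  # with jelly truth, only targets of the top WJ-high panel move
  cfg2 <- sim_config(seed = 4, top_mirnas = 2, module_mirnas = 2)
  tmap2 <- gen_target_map(cfg2)
  truth <- list(mirna_fold = data.frame(
    gene = names(tmap2$targets),
    true_fold = 20,
    wj_share = rev(seq_along(tmap2$targets)),
    stringsAsFactors = FALSE))
  expr2 <- gen_larval_expression(cfg2, tmap2, truth)
  panel <- names(tmap2$targets)[1:2]  # highest shares by construction
  rep_genes <- unique(unlist(tmap2$targets[panel]))
  expect_setequal(expr2$true_ratio$gene[expr2$true_ratio$repressed],
                  rep_genes)
})

test_that("target map plants complete co-targeting modules inside the universe", {
  cfg <- sim_config(seed = 6)
  tmap <- gen_target_map(cfg)
  planted <- attr(tmap, "planted_modules")
  expect_length(planted, cfg$n_planted_modules)
  for (mod in planted) {
    expect_true(all(mod$mrnas %in% tmap$universe))
    for (m in mod$mirnas)
      expect_true(all(mod$mrnas %in% tmap$targets[[m]]))
  }
})

test_that("morphometric generator matches its own summary and CLT bounds", {
  cfg <- sim_config(seed = 8)
  mor <- gen_morpho(cfg)
  # summary of the generated table equals the returned summary
  re <- summarize_morpho(mor$measurements)
  expect_equal(re, mor$summary)
  # zero effects: all true group means equal
  cfg0 <- sim_config(seed = 8, morpho_effects = c(birth_weight_g = 0))
  m0 <- gen_morpho(cfg0)
  expect_true(all(apply(m0$true_means, 2, function(v) length(unique(v))) == 1))
  # large-sample treated mean lands within 4 standard errors of the target
  cfgN <- sim_config(seed = 9,
                     group_ns = c(untreated = 10, control = 10,
                                  treated = 10000),
                     morpho_effects = c(birth_weight_g = -0.08))
  mN <- gen_morpho(cfgN)
  treated <- mN$measurements$birth_weight_g[
    mN$measurements$group == "treated"]
  se <- 0.02 / sqrt(10000)
  expect_lt(abs(mean(treated) - 0.2355 * 0.92), 4 * se)
})
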