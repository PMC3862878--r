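# Synthetic-data generators with planted ground truth.
#
# Every input the pipeline consumes can be generated here: an annotation
# catalog, the two jelly tag libraries, a miRNA->mRNA target map with
# planted co-targeted modules, a larval mRNA count table with planted
# anti-correlation, a 3-day concentration time course, term sets, and a
# per-bee morphometric table. One master seed drives an explicit RNG
# stream per operation so artifacts can be regenerated independently.

SMALLRNA_CATEGORIES <- c("known_miRNA", "tRNA", "other_ncRNA",
                         "genic_mRNA", "unannotated")

TREND_CLASSES <- c("persistent_increase", "transient_increase", "dip",
                   "persistent_fall", "drop_then_stable", "none")

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generators.
#' Defaults reproduce the statistical structure of the worker-jelly (WJ)
#' versus royal-jelly (RJ) small-RNA study design: a category composition
#' strongly skewed between conditions (miRNA read fraction 0.51 vs ~0.02,
#' tRNA 0.17 vs 0.48), a global per-miRNA depletion in royal jelly with
#' log-uniform per-gene jitter spanning the reported 7-215 fold range,
#' 3-day concentration trends, a bipartite target structure with planted
#' co-targeted modules, and group-structured morphometric measurements
#' with small relative effects.
#'
#' @param seed master integer seed; each generator derives its own stream.
#' @param n_mirna_genes,n_trna,n_other_nc,n_genic numbers of annotated
#'   features per small-RNA category (58 known bee miRNA genes by default).
#' @param n_unannotated size of the unannotated tag pool.
#' @param n_mrna size of the mRNA universe used by the target map and the
#'   larval expression table.
#' @param library_size_wj,library_size_rj sequencing depth (tag counts).
#' @param composition_wj,composition_rj category read-fraction vectors over
#'   `known_miRNA, tRNA, other_ncRNA, genic_mRNA, unannotated`; must sum
#'   to 1. For royal jelly the miRNA entry is implied by the depletion
#'   model (the WJ miRNA fractions divided by the per-gene folds); the
#'   remaining mass is split among the other categories in the proportions
#'   given here.
#' @param depletion_factor global WJ/RJ miRNA concentration ratio (>= 1).
#' @param fold_range `c(lo, hi)` of the per-miRNA fold jitter. Jitter is
#'   drawn log-uniformly on this range and rescaled to geometric mean 1,
#'   so the global (geometric-mean) fold equals `depletion_factor`
#'   exactly; `c(1, 1)` disables jitter.
#' @param timecourse_trends named counts of planted worker-jelly trend
#'   classes; their sum is the size of the tested panel and must not
#'   exceed `n_mirna_genes`. Royal-jelly series in the panel all follow
#'   the drop-then-stable shape.
#' @param timecourse_replicates replicates per (miRNA, jelly, day) cell.
#' @param timecourse_noise_sd lognormal replicate noise (SD of log values).
#' @param rj_drop_range day4/day5 drop-factor range for royal jelly; the
#'   first panel miRNA is pinned to the lower edge (2.6 by default).
#' @param repression_factor worker/queen expression ratio planted on
#'   targets of WJ-high miRNAs in the larval mRNA table.
#' @param mrna_depth expected larval mRNA library size per condition.
#' @param target_density `c(lo, hi)` per-miRNA targeting probability range.
#' @param n_planted_modules,module_mirnas,module_mrnas,top_mirnas planted
#'   co-targeting structure: each module adds a complete bipartite clique
#'   between `module_mirnas` of the `top_mirnas` most abundant WJ miRNAs
#'   and `module_mrnas` dedicated mRNAs.
#' @param n_random_terms random term sets written next to the planted
#'   module terms by [gen_term_sets()].
#' @param morpho_baseline data frame (trait, mean, sd) of control-group
#'   trait distributions; defaults follow the published control summaries
#'   for birth weight, body length and wing area, with realistic values
#'   for the remaining wing and proboscis traits.
#' @param morpho_effects named relative treated-vs-control effects per
#'   trait (e.g. -0.08 for an 8 percent reduction).
#' @param group_ns named group sizes (untreated, control, treated).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(
    seed = 1L,
    n_mirna_genes = 58L, n_trna = 40L, n_other_nc = 30L, n_genic = 25L,
    n_unannotated = 1500L, n_mrna = 3000L,
    library_size_wj = 2e5, library_size_rj = 2e5,
    composition_wj = c(known_miRNA = 0.51, tRNA = 0.17, other_ncRNA = 0.06,
                       genic_mRNA = 0.00, unannotated = 0.26),
    composition_rj = c(known_miRNA = 0.02, tRNA = 0.48, other_ncRNA = 0.09,
                       genic_mRNA = 0.00, unannotated = 0.41),
    depletion_factor = 25, fold_range = c(7, 215),
    timecourse_trends = c(persistent_increase = 5, transient_increase = 5,
                          dip = 4, persistent_fall = 4,
                          drop_then_stable = 4),
    timecourse_replicates = 4L, timecourse_noise_sd = 0.05,
    rj_drop_range = c(2.6, 64),
    repression_factor = 0.35, mrna_depth = 2e6,
    target_density = c(0.005, 0.02),
    n_planted_modules = 4L, module_mirnas = 6L, module_mrnas = 5L,
    top_mirnas = 10L, n_random_terms = 40L,
    morpho_baseline = data.frame(
      trait = c("birth_weight_g", "body_length_mm", "proboscis_length_mm",
                "wing_length_mm", "wing_width_mm", "wing_area_mm2"),
      mean = c(0.2355, 18.0737, 6.59, 9.39, 3.28, 20.4017),
      sd   = c(0.02, 1.038, 0.33, 0.32, 0.12, 1.0491)),
    morpho_effects = c(birth_weight_g = -0.08, body_length_mm = -0.05,
                       proboscis_length_mm = 0.03, wing_length_mm = -0.03,
                       wing_width_mm = -0.05, wing_area_mm2 = -0.07),
    group_ns = c(untreated = 22L, control = 57L, treated = 64L)) {
  cfg <- list(seed = as.integer(seed),
              n_mirna_genes = as.integer(n_mirna_genes),
              n_trna = as.integer(n_trna),
              n_other_nc = as.integer(n_other_nc),
              n_genic = as.integer(n_genic),
              n_unannotated = as.integer(n_unannotated),
              n_mrna = as.integer(n_mrna),
              library_size_wj = library_size_wj,
              library_size_rj = library_size_rj,
              composition_wj = composition_wj,
              composition_rj = composition_rj,
              depletion_factor = depletion_factor,
              fold_range = fold_range,
              timecourse_trends = timecourse_trends,
              timecourse_replicates = as.integer(timecourse_replicates),
              timecourse_noise_sd = timecourse_noise_sd,
              rj_drop_range = rj_drop_range,
              repression_factor = repression_factor,
              mrna_depth = mrna_depth,
              target_density = target_density,
              n_planted_modules = as.integer(n_planted_modules),
              module_mirnas = as.integer(module_mirnas),
              module_mrnas = as.integer(module_mrnas),
              top_mirnas = as.integer(top_mirnas),
              n_random_terms = as.integer(n_random_terms),
              morpho_baseline = morpho_baseline,
              morpho_effects = morpho_effects,
              group_ns = group_ns)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_mirna_genes", "n_trna", "n_other_nc", "n_genic",
              "n_unannotated", "n_mrna")
  for (f in counts)
    if (cfg[[f]] < 0L) stop(sprintf("'%s' must be >= 0", f))
  for (comp in c("composition_wj", "composition_rj")) {
    v <- cfg[[comp]]
    if (!identical(names(v), SMALLRNA_CATEGORIES))
      stop(sprintf("'%s' must be named over: %s", comp,
                   paste(SMALLRNA_CATEGORIES, collapse = ", ")))
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9)
      stop(sprintf("'%s' must be non-negative and sum to 1 (+-1e-9)", comp))
  }
  if (cfg$depletion_factor < 1) stop("'depletion_factor' must be >= 1")
  if (length(cfg$fold_range) != 2L || any(cfg$fold_range <= 0) ||
      cfg$fold_range[1] > cfg$fold_range[2])
    stop("'fold_range' must be positive with lo <= hi")
  if (any(cfg$library_size_wj < 0, cfg$library_size_rj < 0))
    stop("library sizes must be >= 0")
  tr <- cfg$timecourse_trends
  if (!all(names(tr) %in% setdiff(TREND_CLASSES, "none")))
    stop("unknown trend class in 'timecourse_trends'")
  if (sum(tr) > cfg$n_mirna_genes)
    stop("'timecourse_trends' counts must sum to <= n_mirna_genes")
  if (cfg$timecourse_replicates < 2L)
    stop("'timecourse_replicates' must be >= 2")
  if (cfg$repression_factor <= 0) stop("'repression_factor' must be > 0")
  if (cfg$module_mirnas > cfg$top_mirnas)
    stop("'module_mirnas' cannot exceed 'top_mirnas'")
  if (any(cfg$group_ns < 2L)) stop("'group_ns' must all be >= 2")
  bl <- cfg$morpho_baseline
  if (!all(c("trait", "mean", "sd") %in% names(bl)) || any(bl$sd < 0))
    stop("'morpho_baseline' needs trait/mean/sd columns with sd >= 0")
  if (!all(names(cfg$morpho_effects) %in% bl$trait))
    stop("'morpho_effects' names must be morpho_baseline traits")
  invisible(cfg)
}

mirna_gene_ids <- function(n) sprintf("mir-%03d", seq_len(n))
mrna_ids       <- function(n) sprintf("mRNA-%04d", seq_len(n))

#' Generate a small-RNA annotation catalog
#'
#' Produces unique DNA sequences (18-30 nt, U already converted to T) for
#' each annotation category. Each miRNA gene carries 1-3 isoforms (the
#' full mature sequence plus end-trimmed variants), mirroring the isoform
#' grouping of public miRNA catalogs.
#'
#' @param cfg a [sim_config()].
#' @return an `rna_catalog` data frame with columns
#'   `sequence, gene, isoform, category`.
#' @export
gen_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stream(cfg$seed, "annotation", {
    seen <- character()
    rows <- list()
    add_simple <- function(n, prefix, category) {
      if (n == 0L) return()
      seqs <- random_dna(n, avoid = seen)
      seen <<- c(seen, seqs)
      rows[[length(rows) + 1L]] <<- data.frame(
        sequence = seqs, gene = sprintf("%s-%03d", prefix, seq_len(n)),
        isoform = sprintf("%s-%03d.1", prefix, seq_len(n)),
        category = category, stringsAsFactors = FALSE)
    }
    # miRNA genes first: mature sequence 20-24 nt plus trimmed isoforms
    if (cfg$n_mirna_genes > 0L) {
      genes <- mirna_gene_ids(cfg$n_mirna_genes)
      n_iso <- sample(1:3, cfg$n_mirna_genes, replace = TRUE)
      for (i in seq_len(cfg$n_mirna_genes)) {
        base <- random_dna(1L, min_len = 20L, max_len = 24L, avoid = seen)
        iso <- base
        if (n_iso[i] >= 2L) iso <- c(iso, substr(base, 1L, nchar(base) - 1L))
        if (n_iso[i] >= 3L) iso <- c(iso, substr(base, 2L, nchar(base)))
        iso <- setdiff(unique(iso), seen)
        seen <- c(seen, iso)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = iso, gene = genes[i],
          isoform = sprintf("%s.%d", genes[i], seq_along(iso)),
          category = "known_miRNA", stringsAsFactors = FALSE)
      }
    }
    add_simple(cfg$n_trna, "trna", "tRNA")
    add_simple(cfg$n_other_nc, "ncrna", "other_ncRNA")
    add_simple(cfg$n_genic, "genic", "genic_mRNA")
    cat <- do.call(rbind, rows)
    if (is.null(cat))
      cat <- data.frame(sequence = character(), gene = character(),
                        isoform = character(), category = character(),
                        stringsAsFactors = FALSE)
    rownames(cat) <- NULL
    stopifnot(!anyDuplicated(cat$sequence))
    class(cat) <- c("rna_catalog", "data.frame")
    cat
  })
}

# feature-level sampling weights shared by both jelly libraries
jelly_feature_table <- function(cfg, catalog) {
  iso <- as.data.frame(catalog)
  parts <- split(iso, iso$category)
  out <- list()
  for (category in SMALLRNA_CATEGORIES[1:4]) {
    p <- parts[[category]]
    if (is.null(p) || nrow(p) == 0L) next
    if (category == "known_miRNA") {
      genes <- sort(unique(p$gene), method = "radix")
      gshare <- rlnorm(length(genes), 0, 2)
      gshare <- gshare / sum(gshare)
      names(gshare) <- genes
      iw <- rexp(nrow(p)) + 0.2
      within <- unsplit(lapply(split(iw, p$gene), function(w) w / sum(w)),
                        p$gene)
      p$share <- gshare[p$gene] * within
    } else {
      w <- rlnorm(nrow(p), 0, 1)
      p$share <- w / sum(w)
    }
    out[[category]] <- p[, c("sequence", "gene", "category", "share")]
  }
  if (cfg$n_unannotated > 0L) {
    seqs <- random_dna(cfg$n_unannotated, avoid = iso$sequence)
    w <- rlnorm(cfg$n_unannotated, 0, 1.5)
    out[["unannotated"]] <- data.frame(
      sequence = seqs, gene = NA_character_, category = "unannotated",
      share = w / sum(w), stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, out)
  rownames(feats) <- NULL
  feats
}

#' Generate worker- and royal-jelly tag libraries with planted depletion
#'
#' Worker-jelly tags are drawn multinomially: category by
#' `composition_wj`, then feature within category (lognormal abundance
#' shares; miRNA shares defined at the gene level and split across
#' isoforms). Royal-jelly miRNA concentrations equal the worker-jelly
#' concentrations divided by per-gene folds
#' `depletion_factor x jitter` (jitter log-uniform on `fold_range`,
#' rescaled to geometric mean 1); the remaining royal-jelly probability
#' mass is distributed over the non-miRNA categories in the
#' `composition_rj` proportions, so the planted WJ/RJ concentration
#' ratios are exact by construction.
#'
#' @param cfg a [sim_config()].
#' @param catalog an `rna_catalog` from [gen_annotation()].
#' @return a list with `wj` and `rj` ([tag_library()] objects) and
#'   `truth`: per-gene true folds and shares (`mirna_fold`), the per-tag
#'   category/feature table (`tag_table`), and the WJ-high miRNA set.
#' @export
gen_jelly_libraries <- function(cfg, catalog) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!nrow(catalog) && cfg$n_unannotated == 0L)
    stop("catalog is empty and no unannotated pool requested")
  with_stream(cfg$seed, "jelly_libraries", {
    feats <- jelly_feature_table(cfg, catalog)
    comp_wj <- cfg$composition_wj
    p_wj <- comp_wj[feats$category] * feats$share
    present <- tapply(feats$share, feats$category, sum)
    # renormalize if some categories are absent from the catalog
    p_wj <- p_wj / sum(p_wj)

    genes <- sort(unique(feats$gene[feats$category == "known_miRNA"]),
                  method = "radix")
    jit <- exp(runif(length(genes), log(cfg$fold_range[1]),
                     log(cfg$fold_range[2])))
    if (length(jit)) jit <- jit / exp(mean(log(jit)))
    fold <- cfg$depletion_factor * jit
    names(fold) <- genes

    is_mir <- feats$category == "known_miRNA"
    p_rj <- numeric(nrow(feats))
    p_rj[is_mir] <- p_wj[is_mir] / fold[feats$gene[is_mir]]
    mir_mass <- sum(p_rj[is_mir])
    if (mir_mass >= 1)
      stop("royal-jelly miRNA mass >= 1; increase depletion_factor")
    w <- cfg$composition_rj[SMALLRNA_CATEGORIES[-1]]
    w <- w * as.numeric(!is.na(present[SMALLRNA_CATEGORIES[-1]]))
    w[is.na(w)] <- 0
    if (sum(w) > 0) {
      cat_mass <- (1 - mir_mass) * w / sum(w)
      for (category in names(cat_mass)) {
        idx <- feats$category == category
        if (any(idx))
          p_rj[idx] <- cat_mass[category] * feats$share[idx] /
            sum(feats$share[idx])
      }
    }
    p_rj <- p_rj / sum(p_rj)

    draw <- function(p, size, id) {
      counts <- if (size > 0)
        as.vector(rmultinom(1L, size, p)) else integer(nrow(feats))
      keep <- counts > 0L
      tag_library(id, data.frame(sequence = feats$sequence[keep],
                                 count = counts[keep],
                                 stringsAsFactors = FALSE))
    }
    wj <- draw(p_wj, cfg$library_size_wj, "WJ")
    rj <- draw(p_rj, cfg$library_size_rj, "RJ")

    gene_share <- tapply(feats$share[is_mir], feats$gene[is_mir], sum)
    truth <- list(
      mirna_fold = data.frame(gene = genes,
                              true_fold = unname(fold[genes]),
                              wj_share = unname(gene_share[genes]),
                              stringsAsFactors = FALSE),
      tag_table = feats[, c("sequence", "gene", "category")],
      wj_high = genes[fold[genes] >= 2],
      p_wj = unname(p_wj), p_rj = unname(p_rj))
    list(wj = wj, rj = rj, truth = truth)
  })
}

#' Generate a miRNA to mRNA target map with planted co-targeted modules
#'
#' Background edges are independent per miRNA with a targeting probability
#' drawn from `target_density`. On top, `n_planted_modules` complete
#' bipartite cliques are planted between subsets of the most abundant
#' worker-jelly miRNAs and dedicated mRNAs, emulating co-targeting of
#' specific transcripts by the top jelly miRNAs.
#'
#' @param cfg a [sim_config()].
#' @param truth optional `truth` from [gen_jelly_libraries()]; if given,
#'   the top miRNAs are the highest WJ-share genes, otherwise the first
#'   genes in id order.
#' @return a [target_map()] whose `planted_modules` attribute lists the
#'   miRNA and mRNA memberships of each planted module.
#' @export
gen_target_map <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stream(cfg$seed, "target_map", {
    mirnas <- mirna_gene_ids(cfg$n_mirna_genes)
    universe <- mrna_ids(cfg$n_mrna)
    dens <- runif(length(mirnas), cfg$target_density[1],
                  cfg$target_density[2])
    targets <- lapply(seq_along(mirnas), function(i) {
      universe[runif(length(universe)) < dens[i]]
    })
    names(targets) <- mirnas
    top <- if (!is.null(truth)) {
      mf <- truth$mirna_fold
      mf$gene[order(-mf$wj_share, mf$gene, method = "radix")][
        seq_len(min(cfg$top_mirnas, nrow(mf)))]
    } else head(mirnas, cfg$top_mirnas)
    planted <- list()
    if (cfg$n_planted_modules > 0L && length(top) >= cfg$module_mirnas) {
      pool <- universe
      for (j in seq_len(cfg$n_planted_modules)) {
        mm <- sort(sample(top, cfg$module_mirnas), method = "radix")
        gg <- sort(sample(pool, cfg$module_mrnas), method = "radix")
        pool <- setdiff(pool, gg)
        for (m in mm) targets[[m]] <- union(targets[[m]], gg)
        planted[[j]] <- list(mirnas = mm, mrnas = gg)
      }
    }
    targets <- lapply(targets, function(x) sort(x, method = "radix"))
    tm <- target_map(targets, universe)
    attr(tm, "planted_modules") <- planted
    attr(tm, "top_mirnas") <- top
    tm
  })
}

#' Generate a larval mRNA count table with planted anti-correlation
#'
#' Baseline expression is lognormal; in the "worker larvae" condition the
#' targets of the top-abundance WJ-high miRNAs (the co-targeting panel)
#' are down-scaled by `repression_factor` before Poisson sampling,
#' emulating repression of the predicted targets of the miRNAs most
#' abundant in worker jelly. Restricting repression to the top panel
#' keeps the repressed fraction of the transcriptome small, so
#' library-size normalization does not absorb the planted signal
#' compositionally.
#'
#' @param cfg a [sim_config()].
#' @param tmap a [target_map()] over the configured mRNA universe.
#' @param truth `truth` from [gen_jelly_libraries()] (ranks miRNAs by
#'   worker-jelly abundance and defines the WJ-high set); if `NULL`, the
#'   map's `top_mirnas` attribute or, failing that, all map miRNAs are
#'   used.
#' @return list with `counts` (gene, worker, queen) and `true_ratio`
#'   (gene, true worker/queen concentration ratio before depth
#'   renormalization, repressed flag).
#' @export
gen_larval_expression <- function(cfg, tmap, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(tmap, "target_map"))
  with_stream(cfg$seed, "larval_expression", {
    universe <- tmap$universe
    wj_high <- if (!is.null(truth)) {
      mf <- truth$mirna_fold
      high <- mf[mf$true_fold >= 2, , drop = FALSE]
      high$gene[order(-high$wj_share, high$gene,
                      method = "radix")][
        seq_len(min(cfg$top_mirnas, nrow(high)))]
    } else if (!is.null(attr(tmap, "top_mirnas"))) {
      attr(tmap, "top_mirnas")
    } else names(tmap$targets)
    repressed <- unique(unlist(tmap$targets[
      intersect(names(tmap$targets), wj_high)], use.names = FALSE))
    base <- rlnorm(length(universe), meanlog = log(100), sdlog = 1)
    ratio <- ifelse(universe %in% repressed, cfg$repression_factor, 1)
    lam_q <- base / sum(base) * cfg$mrna_depth
    lam_w <- lam_q * ratio
    counts <- data.frame(gene = universe,
                         worker = rpois(length(universe), lam_w),
                         queen = rpois(length(universe), lam_q),
                         stringsAsFactors = FALSE)
    list(counts = counts,
         true_ratio = data.frame(gene = universe, true_ratio = ratio,
                                 repressed = universe %in% repressed,
                                 stringsAsFactors = FALSE))
  })
}

trend_day_factors <- function(class, rj_drop = NULL) {
  switch(class,
    persistent_increase = {
      total <- runif(1, 1.5, 1.7); f1 <- runif(1, 1.25, 1.35)
      c(f1, total / f1)
    },
    transient_increase = c(runif(1, 1.4, 4.5), 1 / runif(1, 1.7, 2.1)),
    dip = c(1 / runif(1, 1.8, 2.5), runif(1, 1.8, 2.5)),
    persistent_fall = c(1 / runif(1, 1.4, 1.6), 1 / runif(1, 1.4, 1.6)),
    drop_then_stable = c(1 / (if (is.null(rj_drop))
      runif(1, 2, 4) else rj_drop), runif(1, 0.97, 1.03)),
    none = c(1, 1),
    stop("unknown trend class: ", class))
}

#' Generate a 3-day jelly miRNA concentration time course
#'
#' A panel of miRNAs (one per planted trend in `timecourse_trends`) is
#' measured on days 4, 5 and 6 in both jellies with replicate lognormal
#' noise. Worker-jelly series realize the planted classes as
#' multiplicative day effects drawn from the reported ranges (transient:
#' 1.4-4.5 fold up then 1.7-2.1 fold down; persistent: 1.5-1.7 fold total
#' rise). Every royal-jelly series follows the drop-then-stable shape
#' with a day4/day5 factor from `rj_drop_range`; the first panel miRNA is
#' pinned to the lower edge of that range.
#'
#' @param cfg a [sim_config()].
#' @return list with `data` (long data frame: mirna, jelly, day,
#'   replicate, value) and `truth` (mirna, jelly, class, day factors).
#' @export
gen_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tr <- cfg$timecourse_trends
  with_stream(cfg$seed, "timecourse", {
    panel <- mirna_gene_ids(cfg$n_mirna_genes)[seq_len(sum(tr))]
    classes <- sample(rep(names(tr), tr))
    nrep <- cfg$timecourse_replicates
    rows <- list(); truths <- list()
    rj_drops <- exp(runif(length(panel), log(cfg$rj_drop_range[1]),
                          log(cfg$rj_drop_range[2])))
    rj_drops[1] <- cfg$rj_drop_range[1]
    for (i in seq_along(panel)) {
      base_rj <- rlnorm(1, 0, 0.5)
      base_wj <- base_rj * exp(runif(1, log(cfg$fold_range[1]),
                                     log(cfg$fold_range[2])))
      for (jelly in c("RJ", "WJ")) {
        class <- if (jelly == "RJ") "drop_then_stable" else classes[i]
        f <- trend_day_factors(class,
                               rj_drop = if (jelly == "RJ") rj_drops[i])
        base <- if (jelly == "RJ") base_rj else base_wj
        means <- base * cumprod(c(1, f))
        vals <- rep(means, each = nrep) *
          exp(rnorm(3L * nrep, 0, cfg$timecourse_noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = panel[i], jelly = jelly,
          day = rep(c(4L, 5L, 6L), each = nrep),
          replicate = rep(seq_len(nrep), 3L),
          value = vals, stringsAsFactors = FALSE)
        truths[[length(truths) + 1L]] <- data.frame(
          mirna = panel[i], jelly = jelly, class = class,
          f45 = f[1], f56 = f[2], stringsAsFactors = FALSE)
      }
    }
    list(data = do.call(rbind, rows), truth = do.call(rbind, truths))
  })
}

#' Generate GMT-style term sets over the mRNA universe
#'
#' One term per planted co-targeted module (its mRNAs plus a few random
#' padding genes) and `n_random_terms` random terms of size 10-50, so
#' hypergeometric enrichment of detected modules has planted signal
#' against a realistic background.
#'
#' @param cfg a [sim_config()].
#' @param tmap a [target_map()] from [gen_target_map()].
#' @return named list of character vectors (term -> member genes), with a
#'   `description` attribute.
#' @export
gen_term_sets <- function(cfg, tmap) {
  stopifnot(inherits(cfg, "sim_config"), inherits(tmap, "target_map"))
  with_stream(cfg$seed, "term_sets", {
    universe <- tmap$universe
    planted <- attr(tmap, "planted_modules")
    sets <- list()
    for (j in seq_along(planted)) {
      pad <- sample(setdiff(universe, planted[[j]]$mrnas), 5L)
      sets[[sprintf("PLANTED_MODULE_%d", j)]] <-
        sort(c(planted[[j]]$mrnas, pad), method = "radix")
    }
    for (j in seq_len(cfg$n_random_terms)) {
      sz <- sample(10:50, 1L)
      sets[[sprintf("RANDOM_TERM_%02d", j)]] <-
        sort(sample(universe, sz), method = "radix")
    }
    attr(sets, "description") <- setNames(
      c(rep("planted co-targeted module", length(planted)),
        rep("random background term", cfg$n_random_terms)), names(sets))
    sets
  })
}

#' Generate a per-bee morphometric table for the feeding experiment
#'
#' Normal traits per group: untreated and control share the baseline
#' means; treated means are shifted multiplicatively by `morpho_effects`.
#'
#' @param cfg a [sim_config()].
#' @return list with `measurements` (bee_id, group, one column per
#'   trait), `summary` (a [morpho_summary()] of the generated table) and
#'   `true_means` (group x trait matrix of population means).
#' @export
gen_morpho <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stream(cfg$seed, "morpho", {
    bl <- cfg$morpho_baseline
    groups <- names(cfg$group_ns)
    eff <- cfg$morpho_effects
    true_means <- sapply(bl$trait, function(tr) {
      e <- if (tr %in% names(eff)) eff[[tr]] else 0
      setNames(bl$mean[bl$trait == tr] *
                 ifelse(groups == "treated", 1 + e, 1), groups)
    })
    meas <- do.call(rbind, lapply(groups, function(g) {
      n <- cfg$group_ns[[g]]
      df <- data.frame(bee_id = sprintf("%s-%03d", g, seq_len(n)),
                       group = g, stringsAsFactors = FALSE)
      for (tr in bl$trait)
        df[[tr]] <- rnorm(n, true_means[g, tr], bl$sd[bl$trait == tr])
      df
    }))
    rownames(meas) <- NULL
    list(measurements = meas,
         summary = summarize_morpho(meas),
         true_means = true_means)
  })
}
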