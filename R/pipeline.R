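# End-to-end replay of the study's analysis stages on synthetic data:
# simulate -> profile -> diff -> network -> modules -> enrich ->
# timecourse -> morpho, with a provenance-complete machine-readable
# report.

PIPELINE_STAGES <- c("simulate", "profile", "diff", "network", "modules",
                     "enrich", "timecourse", "morpho")

#' Pipeline configuration
#'
#' Validates thresholds and stage toggles for [run_pipeline()]. Unknown
#' arguments are rejected.
#'
#' @param seed master RNG seed (drives the simulation config too).
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param fold_thresh,p_thresh fold/p rule for DE calls and concordant
#'   pair selection.
#' @param detection_min minimal count for presence calls.
#' @param low_count threshold for the meaningless-difference class.
#' @param vwp MCODE vertex weight percentage.
#' @param trend_alpha significance level for time-course trend calls
#'   (0.01, the replicate-panel threshold).
#' @param cotarget_k co-targeting hit threshold.
#' @param seed_span miRNA seed positions for the built-in matcher.
#' @param stages named logical vector toggling pipeline stages.
#' @param report_path optional path for the JSON run report.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            fold_thresh = 2, p_thresh = 0.01,
                            detection_min = 1, low_count = 10,
                            vwp = 0.2, trend_alpha = 0.01,
                            cotarget_k = 6L, seed_span = c(2L, 8L),
                            stages = setNames(
                              rep(TRUE, length(PIPELINE_STAGES)),
                              PIPELINE_STAGES),
                            report_path = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  if (!is.numeric(fold_thresh) || fold_thresh <= 0)
    stop("'fold_thresh' must be a positive number")
  if (p_thresh <= 0 || p_thresh > 1)
    stop("'p_thresh' must lie in (0, 1]")
  if (trend_alpha <= 0 || trend_alpha > 1)
    stop("'trend_alpha' must lie in (0, 1]")
  if (detection_min < 0) stop("'detection_min' must be >= 0")
  if (vwp < 0 || vwp >= 1) stop("'vwp' must lie in [0, 1)")
  if (length(seed_span) != 2L || seed_span[1] < 1 ||
      seed_span[1] >= seed_span[2])
    stop("'seed_span' must be increasing 1-based positions")
  if (!all(names(stages) %in% PIPELINE_STAGES))
    stop("unknown stage name in 'stages'")
  st <- setNames(rep(FALSE, length(PIPELINE_STAGES)), PIPELINE_STAGES)
  st[names(stages)] <- stages
  structure(list(seed = as.integer(seed), sim = sim,
                 fold_thresh = fold_thresh, p_thresh = p_thresh,
                 detection_min = detection_min, low_count = low_count,
                 vwp = vwp, trend_alpha = trend_alpha,
                 cotarget_k = as.integer(cotarget_k),
                 seed_span = seed_span, stages = st,
                 report_path = report_path),
            class = "pipeline_config")
}

config_as_report <- function(cfg) {
  sim <- unclass(cfg$sim)
  sim$morpho_baseline <- as.list(sim$morpho_baseline)
  out <- unclass(cfg)
  out$sim <- sim
  out
}

#' Run the full synthetic-study pipeline
#'
#' Executes the enabled stages in study order and collects a run report:
#' per-library composition, detected/DE counts, network node and edge
#' counts, module scores, enrichment hits, trend-class counts and the
#' feeding-experiment statistics. The report embeds the fully resolved
#' configuration and seed. A stage failure aborts with an error naming
#' the stage; results of completed stages are retained on the returned
#' condition.
#'
#' @param cfg a [pipeline_config()].
#' @return the run report (list); also written as JSON when
#'   `cfg$report_path` is set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  report <- list(config = config_as_report(cfg), seed = cfg$seed,
                 stages = list())
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    if (!cfg$stages[[name]]) return()
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      cond <- simpleError(sprintf("pipeline stage '%s' failed: %s",
                                  name, conditionMessage(e)))
      cond$partial_report <- report
      stop(cond)
    })
    message(sprintf("[jellynet] stage %-10s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    report$stages[[name]] <<- res
  }

  run_stage("simulate", function() {
    state$catalog <- gen_annotation(cfg$sim)
    state$libs <- gen_jelly_libraries(cfg$sim, state$catalog)
    state$tmap <- gen_target_map(cfg$sim, state$libs$truth)
    state$expr <- gen_larval_expression(cfg$sim, state$tmap,
                                        state$libs$truth)
    state$terms <- gen_term_sets(cfg$sim, state$tmap)
    state$tc <- gen_timecourse(cfg$sim)
    state$morpho <- gen_morpho(cfg$sim)
    list(n_catalog_sequences = nrow(state$catalog),
         wj_reads = state$libs$wj$total_reads,
         rj_reads = state$libs$rj$total_reads,
         n_mrna = length(state$tmap$universe))
  })

  run_stage("profile", function() {
    prof <- lapply(list(WJ = state$libs$wj, RJ = state$libs$rj),
                   function(lib) {
      cl <- classify_tags(filter_tags(lib), state$catalog)
      list(classified = cl, composition = composition(cl),
           profile = quantify_mirnas(cl, state$catalog))
    })
    state$profiles <- prof
    det <- detection_summary(prof$WJ$profile, prof$RJ$profile,
                             detection_min = cfg$detection_min,
                             low_count = cfg$low_count)
    state$detection <- det
    list(composition = lapply(prof, function(p) as.list(p$composition)),
         n_detected = as.list(det$n_detected),
         n_union = length(det$union),
         n_intersection = length(det$intersection),
         n_low_count = length(det$low_count_set))
  })

  run_stage("diff", function() {
    pw <- state$profiles$WJ$profile
    pr <- state$profiles$RJ$profile
    counts <- data.frame(feature = pw$gene, x = pw$count,
                         y = pr$count[match(pw$gene, pr$gene)],
                         stringsAsFactors = FALSE)
    counts$y[is.na(counts$y)] <- 0L
    state$mirna_diff <- diff_abundance(
      counts, n1 = attr(pw, "library_size"),
      n2 = attr(pr, "library_size"))
    mir_de <- de_genes(state$mirna_diff, cfg$fold_thresh, cfg$p_thresh)
    ec <- state$expr$counts
    state$mrna_diff <- diff_abundance(
      data.frame(feature = ec$gene, x = ec$worker, y = ec$queen,
                 stringsAsFactors = FALSE))
    mrna_de <- de_genes(state$mrna_diff, cfg$fold_thresh, cfg$p_thresh)
    state$expressed <- ec$gene[ec$worker + ec$queen > 0]
    list(n_mirna_de = mir_de$n_de,
         n_mirna_up_wj = length(mir_de$up),
         n_mrna_de = mrna_de$n_de,
         n_mrna_down_worker = length(mrna_de$down))
  })

  run_stage("network", function() {
    edges <- select_concordant_pairs(state$mirna_diff, state$mrna_diff,
                                     state$tmap, cfg$fold_thresh,
                                     cfg$p_thresh)
    state$network <- build_network(edges)
    top <- attr(state$tmap, "top_mirnas")
    cases <- cotargeted_mrnas(state$tmap, top, cfg$cotarget_k)
    state$cotarget <- cotarget_stat(state$tmap, top, cfg$cotarget_k,
                                    length(cases))
    list(node_count = state$network$node_count,
         edge_count = state$network$edge_count,
         cotarget = list(p_single = state$cotarget$p_single,
                         expected_cases = state$cotarget$expected_cases,
                         observed_cases = state$cotarget$observed_cases,
                         p_multi = state$cotarget$p_multi))
  })

  run_stage("modules", function() {
    state$modules <- mcode_modules(state$network, vwp = cfg$vwp)
    list(n_modules = length(state$modules),
         scores = vapply(state$modules, `[[`, numeric(1), "score"),
         sizes = vapply(state$modules, `[[`, numeric(1), "size"))
  })

  run_stage("enrich", function() {
    universe <- state$expressed
    res <- lapply(state$modules, function(mod) {
      genes <- intersect(mod$vertices, universe)
      if (length(genes) < 1L) return(NULL)
      enrich(genes, state$terms, universe)
    })
    state$enrichment <- res
    list(n_modules_tested = sum(!vapply(res, is.null, logical(1))),
         top_terms = lapply(res, function(r)
           if (is.null(r) || !nrow(r)) NULL else
             list(term = r$term[1], p = r$p[1], q = r$q[1])))
  })

  run_stage("timecourse", function() {
    calls <- classify_trends(state$tc$data, alpha = cfg$trend_alpha)
    truth <- state$tc$truth
    m <- merge(calls, truth, by = c("mirna", "jelly"))
    state$trend_calls <- calls
    list(class_counts = as.list(table(calls$class)),
         accuracy = mean(m$class.x == m$class.y))
  })

  run_stage("morpho", function() {
    meas <- state$morpho$measurements
    traits <- setdiff(names(meas)[vapply(meas, is.numeric, logical(1))],
                      character())
    res <- lapply(traits, function(tr) {
      groups <- split(meas[[tr]], meas$group)
      fit <- anova_oneway(groups)
      tk <- tukey_hsd(groups)
      smry <- state$morpho$summary
      tt <- ttest_from_summary(
        smry[smry$group == "treated" & smry$trait == tr, ],
        smry[smry$group == "control" & smry$trait == tr, ])
      list(anova_f = fit$statistic, anova_p = fit$p,
           tukey_treated_control = tk$p[
             (tk$group_a == "treated" & tk$group_b == "control") |
             (tk$group_a == "control" & tk$group_b == "treated")],
           ttest_p = tt$p,
           percent_effect = percent_effect(
             smry[smry$group == "treated" & smry$trait == tr, ],
             smry[smry$group == "control" & smry$trait == tr, ]))
    })
    names(res) <- traits
    res
  })

  if (!is.null(cfg$report_path)) {
    jsonlite::write_json(report, cfg$report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE,
                         null = "null")
  }
  report
}
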