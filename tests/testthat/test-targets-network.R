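test_that("seed matching equals a brute-force substring scan", {
  mir <- c(mA = "TTAGGTACCTGATCGATCGAT", mB = "TGGGGGGGGATCGATCGATCG")
  utr <- c(u1 = paste0("AAAA", jellynet:::revcomp(substr(mir[["mA"]], 2, 8)), "TTTT"),
           u2 = strrep("A", 40))
  tm <- seed_match_targets(mir, utr)
  expect_equal(tm$targets$mA, "u1")
  expect_length(tm$targets$mB, 0)
  # brute force over every position of every UTR
  for (m in names(mir)) {
    seed <- jellynet:::revcomp(substr(mir[[m]], 2, 8))
    hits <- names(utr)[vapply(utr, function(u) {
      any(vapply(seq_len(max(0, nchar(u) - 6)), function(i)
        substr(u, i, i + 6) == seed, logical(1)))
    }, logical(1))]
    expect_setequal(tm$targets[[m]], hits)
  }
  expect_error(seed_match_targets(c(s = "ACGTA"), utr), "seed span")
  empty <- seed_match_targets(mir, setNames(character(), character()))
  expect_length(unlist(empty$targets), 0)
})

test_that("U-containing sequences are handled as DNA", {
  mir <- c(m = "UUAGGUACCUGAUCGAUCGAU")
  utr <- c(u1 = paste0("CCC", jellynet:::revcomp("TAGGTAC"), "CCC"))
  expect_equal(seed_match_targets(mir, utr)$targets$m, "u1")
})

test_that("concordant pair selection applies the anti-correlation rule", {
  mir <- random_diff(c("mUp", "mDown", "mFlat"),
                     fc = c(10, 0.1, 1.1), p = c(1e-4, 1e-4, 0.5))
  gene <- random_diff(c("gDown", "gUp", "gFlat"),
                      fc = c(0.4, 5, 1), p = c(1e-3, 1e-3, 0.9))
  tmap <- target_map(list(mUp = c("gDown", "gUp", "gFlat"),
                          mDown = c("gUp", "gDown"),
                          mFlat = c("gDown")),
                     c("gDown", "gUp", "gFlat"))
  edges <- select_concordant_pairs(mir, gene, tmap)
  expect_equal(edges$mirna, c("mDown", "mUp"))
  expect_equal(edges$mrna, c("gUp", "gDown"))
  expect_equal(edges$sign, c("rj_high", "wj_high"))
  # reversing both differential directions flips signs, keeps the edges
  mir2 <- mir; mir2$fold_change <- 1 / mir$fold_change
  gene2 <- gene; gene2$fold_change <- 1 / gene$fold_change
  edges2 <- select_concordant_pairs(mir2, gene2, tmap)
  expect_equal(edges2[, c("mirna", "mrna")], edges[, c("mirna", "mrna")])
  expect_equal(edges2$sign, c("wj_high", "rj_high"))
})

test_that("a random rule fixture agrees with an independent evaluation", {
  set.seed(77)
  mirnas <- sprintf("m%02d", 1:10)
  genes <- sprintf("g%02d", 1:20)
  mir <- random_diff(mirnas, fc = exp(rnorm(10, 0, 2)), p = runif(10, 0, 0.02))
  gd <- random_diff(genes, fc = exp(rnorm(20, 0, 2)), p = runif(20, 0, 0.02))
  targets <- lapply(mirnas, function(m) sample(genes, 6))
  names(targets) <- mirnas
  tmap <- target_map(targets, genes)
  got <- select_concordant_pairs(mir, gd, tmap, fold_thresh = 2,
                                 p_thresh = 0.01)
  naive <- list()
  for (m in mirnas) for (g in targets[[m]]) {
    fm <- mir$fold_change[mir$feature == m]; pm <- mir$p[mir$feature == m]
    fg <- gd$fold_change[gd$feature == g]; pg <- gd$p[gd$feature == g]
    keep <- (fm >= 2 && pm < 0.01 && fg <= 0.5 && pg < 0.01) ||
      (fm <= 0.5 && pm < 0.01 && fg >= 2 && pg < 0.01)
    if (keep) naive[[length(naive) + 1L]] <- paste(m, g)
  }
  expect_identical(sort(paste(got$mirna, got$mrna)),
                   sort(as.character(unlist(naive))))
  expect_gt(nrow(got), 0)  # the fixture exercises both rule branches
})

test_that("network construction deduplicates and counts correctly", {
  edges <- data.frame(mirna = c("m1", "m1", "m1", "m1"),
                      mrna = c("g1", "g2", "g3", "g1"))
  net <- build_network(edges)
  expect_equal(net$node_count, 4)
  expect_equal(net$edge_count, 3)
  expect_error(build_network(data.frame(mirna = c("a", "x"),
                                        mrna = c("x", "b"))),
               "bipartition")
  # random bipartite fixture vs naive counting
  set.seed(5)
  e <- unique(data.frame(mirna = sample(sprintf("m%d", 1:6), 40, TRUE),
                         mrna = sample(sprintf("g%d", 1:15), 40, TRUE)))
  net2 <- build_network(e)
  expect_equal(net2$edge_count, nrow(e))
  expect_equal(net2$node_count,
               length(unique(e$mirna)) + length(unique(e$mrna)))
})

test_that("MCODE weights and modules behave on canonical graphs", {
  # edgeless graph: no modules
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b", "c")
  expect_length(mcode_modules(g0), 0)
  # isolated K4: all weights 3 (3-core of density 1), one module of 4
  k4 <- igraph::make_full_graph(4, directed = FALSE)
  igraph::V(k4)$name <- c("a", "b", "c", "d")
  w <- mcode_vertex_weights(k4)
  expect_equal(unname(w), rep(3, 4))
  mods <- mcode_modules(k4)
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$vertices, c("a", "b", "c", "d"))
  expect_equal(mods[[1]]$density, 1)
  expect_equal(mods[[1]]$score, 4)
})

test_that("MCODE recovers a planted dense bipartite module", {
  set.seed(2024)
  mirnas <- sprintf("m%02d", 1:50)
  genes <- sprintf("g%02d", 1:50)
  edges <- expand.grid(mirna = mirnas, mrna = genes,
                       stringsAsFactors = FALSE)
  edges <- edges[runif(nrow(edges)) < 0.02, ]
  planted <- expand.grid(mirna = mirnas[1:5], mrna = genes[1:5],
                         stringsAsFactors = FALSE)
  net <- build_network(rbind(edges, planted))
  # on bipartite graphs every closed neighborhood is a star, so vertex
  # weights scale like 2/(degree+1); a wider inclusion window (vwp 0.4)
  # keeps planted vertices that carry extra random edges
  mods <- mcode_modules(net, vwp = 0.4)
  expect_gte(length(mods), 1)
  top <- mods[[1]]$vertices
  expect_gte(length(intersect(top, c(mirnas[1:5], genes[1:5]))), 9)
})

test_that("MCODE weights are bounded and their core order is edge-monotone", {
  # weight = k_max x density(k_max-core of the closed neighborhood):
  # bounded by the vertex degree, and the k_max component can never
  # grow when an edge is removed (core numbers are edge-monotone; the
  # density factor is not, since a pruned core can be denser)
  nbhd_kmax <- function(g, v) {
    nb <- unique(c(v, as.integer(igraph::neighbors(g, v))))
    if (length(nb) < 2L) return(0L)
    as.integer(max(igraph::coreness(igraph::induced_subgraph(g, nb))))
  }
  set.seed(11)
  g <- igraph::sample_gnp(25, 0.2)
  igraph::V(g)$name <- sprintf("v%02d", 1:25)
  w0 <- mcode_vertex_weights(g)
  expect_true(all(w0 >= 0))
  expect_true(all(w0 <= igraph::degree(g) + 1e-12))
  k0 <- vapply(seq_len(25), function(v) nbhd_kmax(g, v), integer(1))
  for (eid in sample(igraph::ecount(g), 10)) {
    g1 <- igraph::delete_edges(g, eid)
    k1 <- vapply(seq_len(25), function(v) nbhd_kmax(g1, v), integer(1))
    expect_true(all(k1 <= k0))
  }
})

test_that("Poisson-binomial tail matches enumeration and closed forms", {
  expect_equal(poisbinom_tail(c(0.2, 0.7), 0), 1)
  expect_equal(poisbinom_tail(c(0.5, 0.5), 2), 0.25)
  # binomial closed form
  expect_equal(poisbinom_tail(rep(0.1, 10), 6),
               sum(dbinom(6:10, 10, 0.1)), tolerance = 1e-12)
  # exhaustive enumeration for heterogeneous p, m up to 12
  set.seed(3)
  for (m in c(5, 9, 12)) {
    p <- runif(m)
    for (k in c(0, 1, ceiling(m / 2), m))
      expect_equal(poisbinom_tail(p, k), poisbinom_enum(p, k),
                   tolerance = 1e-12)
  }
})

test_that("the co-targeting statistic composes the DP and Poisson tails", {
  tmap <- target_map(list(mA = c("g1", "g2"), mB = c("g3", "g4")),
                     sprintf("g%d", 1:4))
  st <- cotarget_stat(tmap, c("mA", "mB"), k = 2, observed_cases = 1)
  expect_equal(st$p_single, 0.25)
  expect_equal(st$expected_cases, 1)
  expect_equal(st$p_multi, 1 - exp(-1), tolerance = 1e-12)
  expect_equal(cotarget_stat(tmap, c("mA", "mB"), 0, 0)$p_single, 1)
  expect_error(cotarget_stat(tmap, c("mA", "mB"), 3, 1), "exceed")
  expect_setequal(cotargeted_mrnas(tmap, c("mA", "mB"), 1),
                  sprintf("g%d", 1:4))
})
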