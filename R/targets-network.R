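# Target-map ingestion and seed matching, the anti-correlation
# miRNA-mRNA regulatory network, MCODE-style module detection, and the
# Poisson-binomial co-targeting statistic.

#' Bipartite miRNA to mRNA target map
#'
#' @param targets named list: miRNA id -> character vector of target
#'   mRNA ids (deduplicated; must lie inside `universe`).
#' @param universe character vector of all mRNA ids (size N).
#' @return a `target_map` list with `targets`, `universe`, `n_targets`.
#' @export
target_map <- function(targets, universe) {
  universe <- unique(universe)
  targets <- lapply(targets, function(x) sort(unique(x), method = "radix"))
  bad <- vapply(targets, function(x) any(!x %in% universe), logical(1))
  if (any(bad))
    stop("targets outside the declared universe for: ",
         paste(names(targets)[bad], collapse = ", "))
  structure(list(targets = targets, universe = universe,
                 n_targets = vapply(targets, length, integer(1))),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("target_map: %d miRNAs, universe %d mRNAs, %d edges\n",
              length(x$targets), length(x$universe), sum(x$n_targets)))
  invisible(x)
}

#' Seed-match target prediction
#'
#' Deterministic stand-in for alignment-based target predictors: an edge
#' is called iff the reverse complement of miRNA positions `seed_span`
#' (2-8, the canonical seed) occurs as a substring of the mRNA 3'UTR.
#' All sequences are DNA alphabet (U converted to T).
#'
#' @param mirna_seqs named character vector of mature miRNA sequences.
#' @param utr_seqs named character vector of 3'UTR sequences; names are
#'   the mRNA universe.
#' @param seed_span `c(first, last)` 1-based miRNA positions.
#' @return a [target_map()] over `names(utr_seqs)`.
#' @export
seed_match_targets <- function(mirna_seqs, utr_seqs,
                               seed_span = c(2L, 8L)) {
  mirna_seqs <- chartr("Uu", "Tt", toupper(mirna_seqs))
  utr_seqs <- chartr("Uu", "Tt", toupper(utr_seqs))
  if (any(nchar(mirna_seqs) < seed_span[2]))
    stop("miRNA sequence shorter than the seed span")
  seeds <- revcomp(substr(mirna_seqs, seed_span[1], seed_span[2]))
  targets <- lapply(seeds, function(s) {
    if (length(utr_seqs) == 0L) return(character())
    names(utr_seqs)[grepl(s, utr_seqs, fixed = TRUE)]
  })
  names(targets) <- names(mirna_seqs)
  target_map(targets, names(utr_seqs) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select concordant miRNA-mRNA pairs
#'
#' Implements the anti-correlation rule: keep a predicted edge iff the
#' miRNA is significantly more concentrated in worker jelly and its
#' target is significantly down-regulated in worker larvae, or the
#' mirror image. `mirna_diff` is oriented WJ vs RJ and `mrna_diff`
#' worker vs queen larvae (fold > 1 = higher in worker).
#'
#' @param mirna_diff,mrna_diff `diff_result` tables from
#'   [diff_abundance()].
#' @param tmap a [target_map()]; its universe must cover `mrna_diff`.
#' @param fold_thresh,p_thresh thresholds defining "high" and
#'   "significant" (defaults 2 and 0.01, the study's stated DE rule).
#' @return data frame of kept edges `(mirna, mrna, sign)`; sign
#'   `"wj_high"` for miRNA-up/target-down, `"rj_high"` for the mirror.
#' @export
select_concordant_pairs <- function(mirna_diff, mrna_diff, tmap,
                                    fold_thresh = 2, p_thresh = 0.01) {
  stopifnot(inherits(mirna_diff, "diff_result"),
            inherits(mrna_diff, "diff_result"),
            inherits(tmap, "target_map"))
  mir_up <- mirna_diff$feature[mirna_diff$fold_change >= fold_thresh &
                                 mirna_diff$p < p_thresh]
  mir_dn <- mirna_diff$feature[mirna_diff$fold_change <= 1 / fold_thresh &
                                 mirna_diff$p < p_thresh]
  gene_dn <- mrna_diff$feature[mrna_diff$fold_change <= 1 / fold_thresh &
                                 mrna_diff$p < p_thresh]
  gene_up <- mrna_diff$feature[mrna_diff$fold_change >= fold_thresh &
                                 mrna_diff$p < p_thresh]
  edges <- list()
  for (m in names(tmap$targets)) {
    tg <- tmap$targets[[m]]
    if (m %in% mir_up) {
      keep <- intersect(tg, gene_dn)
      if (length(keep))
        edges[[length(edges) + 1L]] <- data.frame(
          mirna = m, mrna = keep, sign = "wj_high",
          stringsAsFactors = FALSE)
    } else if (m %in% mir_dn) {
      keep <- intersect(tg, gene_up)
      if (length(keep))
        edges[[length(edges) + 1L]] <- data.frame(
          mirna = m, mrna = keep, sign = "rj_high",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(edges))
    return(data.frame(mirna = character(), mrna = character(),
                      sign = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, edges)
  out[order(out$mirna, out$mrna, method = "radix"), , drop = FALSE]
}

#' Build the bipartite regulatory network
#'
#' Deduplicates edges and counts nodes with at least one edge. A node id
#' appearing on both sides of the bipartition is an error.
#'
#' @param edges data frame with columns `mirna, mrna` and optionally
#'   `sign`.
#' @return a `regulatory_network`: edge table, `node_count`,
#'   `edge_count`, and the underlying [igraph::graph] (miRNA vertices
#'   have `type = FALSE`, mRNA `TRUE`).
#' @export
build_network <- function(edges) {
  stopifnot(all(c("mirna", "mrna") %in% names(edges)))
  if (!"sign" %in% names(edges)) edges$sign <- NA_character_
  key <- paste(edges$mirna, edges$mrna, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  both <- intersect(unique(edges$mirna), unique(edges$mrna))
  if (length(both))
    stop("node(s) on both sides of the bipartition: ",
         paste(both, collapse = ", "))
  mirnas <- sort(unique(edges$mirna), method = "radix")
  mrnas <- sort(unique(edges$mrna), method = "radix")
  g <- igraph::graph_from_data_frame(
    edges[, c("mirna", "mrna")], directed = FALSE,
    vertices = data.frame(name = c(mirnas, mrnas),
                          type = c(rep(FALSE, length(mirnas)),
                                   rep(TRUE, length(mrnas)))))
  structure(list(edges = edges, node_count = length(mirnas) +
                   length(mrnas), edge_count = nrow(edges), graph = g),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d nodes, %d edges\n",
              x$node_count, x$edge_count))
  invisible(x)
}

#' MCODE vertex weights
#'
#' For each vertex: take the subgraph induced by its closed neighborhood,
#' find the highest k-core of that subgraph, and set
#' weight = k_max x density(k-core subgraph). Isolated vertices weigh 0.
#'
#' @param g an [igraph::graph] (simple, undirected).
#' @return named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(g) {
  stopifnot(igraph::is_igraph(g))
  nms <- igraph::V(g)$name
  w <- setNames(numeric(igraph::vcount(g)), nms)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (i in seq_along(w)) {
    nb <- unique(c(i, as.integer(adj[[i]])))
    if (length(nb) < 2L) next
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0L) next
    kc <- igraph::induced_subgraph(sub, which(core >= kmax))
    w[i] <- kmax * igraph::edge_density(kc)
  }
  w
}

#' MCODE-style module detection
#'
#' Molecular-complex detection on a simple undirected graph: vertices
#' are weighted by the density of the highest k-core of their closed
#' neighborhood ([mcode_vertex_weights()]); complexes grow greedily from
#' the highest-weight unused seed, recursively including neighbors whose
#' weight is at least `seed_weight x (1 - vwp)`. Optional haircut
#' removes singly connected vertices (the module's 2-core); optional
#' fluff adds boundary neighbors whose closed-neighborhood density
#' exceeds `fluff_thresh`. Each vertex belongs to at most one module
#' (first seed wins); ties are broken by lexicographic vertex id, so the
#' decomposition is deterministic.
#'
#' @param net a `regulatory_network` or an [igraph::graph].
#' @param vwp vertex weight percentage (0-1): tolerance below the seed
#'   weight for inclusion.
#' @param haircut,fluff post-processing toggles.
#' @param fluff_thresh neighborhood-density threshold for fluff.
#' @param min_size discard modules smaller than this after post-processing.
#' @return list of modules, ranked by score = density x size; each has
#'   `vertices`, `seed`, `score`, `density`, `size` and the per-vertex
#'   `weights`.
#' @export
mcode_modules <- function(net, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                          fluff_thresh = 0.2, min_size = 2L) {
  g <- if (inherits(net, "regulatory_network")) net$graph else net
  stopifnot(igraph::is_igraph(g))
  if (igraph::ecount(g) == 0L) return(list())
  w <- mcode_vertex_weights(g)
  nms <- igraph::V(g)$name
  order_idx <- order(-w, nms, method = "radix")
  used <- setNames(rep(FALSE, length(w)), nms)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  names(adj) <- nms
  modules <- list()
  for (si in order_idx) {
    seed <- nms[si]
    if (used[seed] || w[seed] <= 0) next
    thresh <- w[seed] * (1 - vwp)
    members <- seed
    used[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nxt <- character()
      for (v in frontier) {
        for (u in nms[as.integer(adj[[v]])]) {
          if (!used[u] && w[u] >= thresh) {
            used[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    if (haircut && length(members) > 1L) {
      sub <- igraph::induced_subgraph(g, members)
      core <- igraph::coreness(sub)
      dropped <- igraph::V(sub)$name[core < 2L]
      kept <- igraph::V(sub)$name[core >= 2L]
      # haircut casualties belong to no module; release them so a later
      # seed can still claim them (exclusivity is over final modules).
      # A complex that loses its own seed is spurious: discard it whole.
      if (!seed %in% kept) {
        used[members] <- FALSE
        next
      }
      used[dropped] <- FALSE
      members <- kept
    }
    if (fluff && length(members)) {
      boundary <- setdiff(unique(unlist(lapply(members, function(v)
        nms[as.integer(adj[[v]])]))), members)
      for (u in boundary) {
        nb <- unique(c(u, nms[as.integer(adj[[u]])]))
        dsub <- igraph::edge_density(igraph::induced_subgraph(g, nb))
        if (!is.nan(dsub) && dsub > fluff_thresh)
          members <- c(members, u)
      }
      members <- unique(members)
    }
    if (length(members) < min_size) next
    sub <- igraph::induced_subgraph(g, members)
    dens <- igraph::edge_density(sub)
    modules[[length(modules) + 1L]] <- list(
      vertices = sort(members, method = "radix"), seed = seed,
      size = length(members), density = dens,
      score = dens * length(members),
      weights = w[sort(members, method = "radix")])
  }
  if (!length(modules)) return(modules)
  scores <- vapply(modules, `[[`, numeric(1), "score")
  seeds <- vapply(modules, `[[`, character(1), "seed")
  modules[order(-scores, seeds, method = "radix")]
}

#' Poisson-binomial upper tail by dynamic programming
#'
#' Exact `P(S >= k)` for `S` the sum of independent Bernoulli(p_i),
#' computed by convolving the success-count distribution one variable at
#' a time.
#'
#' @param p vector of success probabilities.
#' @param k integer threshold.
#' @return the tail probability.
#' @export
poisbinom_tail <- function(p, k) {
  stop_if_not_prob(p, "probabilities")
  if (k <= 0) return(1)
  if (k > length(p)) return(0)
  dist <- c(1, numeric(length(p)))  # P(S = 0..m)
  for (pi in p)
    dist <- c(dist[1] * (1 - pi),
              dist[-1] * (1 - pi) + dist[-length(dist)] * pi)
  sum(dist[(k + 1):length(dist)])
}

#' Co-targeting probability statistic
#'
#' Null model for multiple top miRNAs sharing single target mRNAs:
#' each of the `m` miRNAs targets any given mRNA independently with
#' probability `p_i = |T_i| / N`. `p_single` is the Poisson-binomial
#' tail probability that one mRNA is hit by at least `k` of the m
#' miRNAs; the number of such mRNAs among the universe is approximated
#' as Poisson with mean `N x p_single`, and `p_multi` is its upper tail
#' at the observed number of cases `c`.
#'
#' @param tmap a [target_map()].
#' @param top_mirnas character vector of the m miRNAs considered.
#' @param k hit threshold (an mRNA "case" is targeted by >= k of them).
#' @param observed_cases observed number of such mRNAs.
#' @return a `cotarget_stat` list: `m, k, p_i, p_single, expected_cases,
#'   observed_cases, p_multi`.
#' @export
cotarget_stat <- function(tmap, top_mirnas, k, observed_cases) {
  stopifnot(inherits(tmap, "target_map"))
  if (!all(top_mirnas %in% names(tmap$targets)))
    stop("'top_mirnas' must all be in the target map")
  m <- length(top_mirnas)
  if (k > m) stop("'k' cannot exceed the number of top miRNAs")
  N <- length(tmap$universe)
  p_i <- tmap$n_targets[top_mirnas] / N
  p_single <- poisbinom_tail(unname(p_i), k)
  mu <- N * p_single
  p_multi <- if (observed_cases <= 0) 1 else
    ppois(observed_cases - 1, mu, lower.tail = FALSE)
  structure(list(m = m, k = k, p_i = p_i, p_single = p_single,
                 expected_cases = mu, observed_cases = observed_cases,
                 p_multi = p_multi),
            class = "cotarget_stat")
}

#' Count mRNAs targeted by at least k of a miRNA set
#' @param tmap a [target_map()].
#' @param top_mirnas miRNA ids; `k` hit threshold.
#' @return character vector of co-targeted mRNA ids.
#' @export
cotargeted_mrnas <- function(tmap, top_mirnas, k) {
  stopifnot(inherits(tmap, "target_map"))
  hits <- table(unlist(tmap$targets[top_mirnas], use.names = FALSE))
  sort(names(hits)[hits >= k], method = "radix")
}
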