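#' Sample a typed subnetwork from a general network
#'
#' Draws the requested number of nodes uniformly without replacement within
#' each of four categories — TFs with targets, TFs without targets, miRNAs,
#' mRNAs — and returns the induced subnetwork.  This mirrors deriving a
#' condition-specific network of fixed composition from the general
#' network by chance.
#'
#' @param general_network a [grn].
#' @param counts named numeric vector with entries `tf_with_targets`,
#'   `tf_without_targets`, `mirna`, `mrna`.
#' @param rng_seed integer seed (or `NULL` to use the current RNG stream).
#' @return A [grn] induced on the sampled nodes.
#' @export
sample_typed_subnetwork <- function(general_network, counts,
                                    rng_seed = NULL) {
  stopifnot(inherits(general_network, "grn"))
  cats <- node_categories(general_network)
  need <- c("tf_with_targets", "tf_without_targets", "mirna", "mrna")
  missing <- setdiff(need, names(counts))
  if (length(missing))
    stop("configuration error: counts lacks ", paste(missing, collapse = ", "))
  for (cat in need)
    if (counts[[cat]] > length(cats[[cat]]))
      stop("configuration error: requested ", counts[[cat]], " ", cat,
           " but only ", length(cats[[cat]]), " available")
  with_seed(rng_seed, {
    picked <- unlist(lapply(need, function(cat) {
      pool <- cats[[cat]]
      k <- counts[[cat]]
      if (k == 0) character(0)
      else if (length(pool) == 1 && k == 1) pool
      else sample(pool, k)
    }), use.names = FALSE)
    induced_subnetwork(general_network, picked)
  })
}

# Node ids per sampling category.
node_categories <- function(network) {
  nd <- grn_nodes(network)
  outdeg <- igraph::degree(network$graph, mode = "out")
  tf <- nd$id[nd$type == "TF"]
  list(tf_with_targets = tf[outdeg[tf] > 0],
       tf_without_targets = tf[outdeg[tf] == 0],
       mirna = nd$id[nd$type == "miRNA"],
       mrna = nd$id[nd$type == "mRNA"])
}

# Category counts of a network, in sample_typed_subnetwork() layout.
category_node_counts <- function(network) {
  vapply(node_categories(network), length, 1L)
}

#' Rank-stability randomization test (node-sampling null)
#'
#' Tests whether a ranking strategy's output for an observed
#' condition-specific network could have been obtained by chance from the
#' general network: regulators are ranked in many randomly sampled typed
#' subnetworks of identical composition, each regulator's rank is averaged
#' over the samples in which it appears, and the squared Pearson
#' correlation between observed and mean random ranks is reported.  A high
#' R-squared means the strategy ranks by a global property of the node
#' rather than by condition-specific structure.
#'
#' @param general_network the general [grn] to sample from.
#' @param observed_network the condition-specific [grn] whose composition
#'   and observed ranking are used.
#' @param strategy one of `"outdeg"`, `"indeg"`, `"closeness"`,
#'   `"betweenness"`, `"pagerank"`, `"kcore"`.
#' @param n_samples number of sampled subnetworks (the full-scale analysis
#'   uses 10,000; desk-scale runs use a few hundred).
#' @param rng_seed integer seed.
#' @return List of class `null_sample_result`: `strategy`, `r_squared`,
#'   `n_samples`, `per_regulator` (data.frame with `observed_rank`,
#'   `mean_random_rank`, `n_appearances`), and for `"kcore"` also
#'   `r_squared_core` computed on raw core numbers.
#' @export
rank_stability_r2 <- function(general_network, observed_network, strategy,
                              n_samples = 200L, rng_seed = 1L) {
  strategies <- c("outdeg", "indeg", "closeness", "betweenness",
                  "pagerank", "kcore")
  strategy <- match.arg(strategy, strategies)
  counts <- category_node_counts(observed_network)
  obs_rank <- strategy_ranks(observed_network, strategy)
  obs_core <- if (strategy == "kcore")
    kcore_decompose(observed_network)$core_number else NULL

  rank_sum <- core_sum <- n_app <- stats::setNames(
    numeric(length(obs_rank)), names(obs_rank))
  with_seed(rng_seed, {
    for (s in seq_len(n_samples)) {
      sub <- sample_typed_subnetwork(general_network, counts, rng_seed = NULL)
      rk <- strategy_ranks(sub, strategy)
      shared <- intersect(names(rk), names(obs_rank))
      if (!length(shared)) next
      rank_sum[shared] <- rank_sum[shared] + rk[shared]
      n_app[shared] <- n_app[shared] + 1
      if (!is.null(obs_core)) {
        cn <- kcore_decompose(sub)$core_number
        core_sum[shared] <- core_sum[shared] + cn[shared]
      }
    }
  })
  seen <- names(n_app)[n_app >= 1]
  if (length(seen) < 3)
    stop("undefined R^2: fewer than 3 regulators shared with the samples")
  mean_rank <- rank_sum[seen] / n_app[seen]
  r2 <- stats::cor(obs_rank[seen], mean_rank)^2
  res <- list(strategy = strategy, r_squared = unname(r2),
              n_samples = n_samples,
              per_regulator = data.frame(
                regulator = seen,
                observed_rank = unname(obs_rank[seen]),
                mean_random_rank = unname(mean_rank),
                n_appearances = unname(n_app[seen]),
                stringsAsFactors = FALSE, row.names = NULL))
  if (!is.null(obs_core)) {
    mean_core <- core_sum[seen] / n_app[seen]
    res$r_squared_core <- unname(stats::cor(obs_core[seen], mean_core)^2)
  }
  class(res) <- "null_sample_result"
  res
}

# 1-based ranks of the eligible regulators of a network under one strategy.
strategy_ranks <- function(network, strategy) {
  regs <- regulators(network)
  if (length(regs) < 1) return(stats::setNames(numeric(0), character(0)))
  rl <- switch(strategy,
    outdeg = rank_by_degree(network, "out", regs),
    indeg = rank_by_degree(network, "in", regs),
    closeness = rank_by_centrality(network, "closeness", regs),
    betweenness = rank_by_centrality(network, "betweenness", regs),
    pagerank = rank_by_centrality(network, "pagerank", regs),
    kcore = rank_by_core(kcore_decompose(network), regs))
  stats::setNames(rl$rank, rl$regulator)
}

#' Degree-preserving edge randomization (directed configuration model)
#'
#' Rewires the network by the directed configuration model on its exact
#' in- and out-degree sequences, then collapses the resulting multigraph
#' to a simple digraph with self-loops removed (the binary edge encoding
#' downstream cannot represent parallel edges).  Node names and types are
#' preserved; the small edge loss from collapsing is recorded.
#'
#' @param network a [grn].
#' @param rng_seed integer seed.
#' @return A [grn] with attribute `edge_loss` — the number of edges removed
#'   by collapsing (pre-collapse degree sequences match the input exactly).
#' @export
randomize_edges <- function(network, rng_seed = NULL) {
  stopifnot(inherits(network, "grn"))
  g <- network$graph
  outdeg <- igraph::degree(g, mode = "out")
  indeg <- igraph::degree(g, mode = "in")
  with_seed(rng_seed, {
    rg <- igraph::sample_degseq(out.deg = outdeg, in.deg = indeg,
                                method = "configuration")
    igraph::V(rg)$name <- igraph::V(g)$name
    igraph::V(rg)$type <- igraph::V(g)$type
    pre <- igraph::ecount(rg)
    rg <- igraph::simplify(rg, remove.multiple = TRUE, remove.loops = TRUE)
    out <- as_grn(rg)
    attr(out, "edge_loss") <- pre - igraph::ecount(rg)
    out
  })
}
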