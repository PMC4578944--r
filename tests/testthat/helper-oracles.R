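# Brute-force oracles and fixture builders shared across the suite.
# The oracles deliberately use naive algorithms (matrix Floyd-Warshall,
# subset search, power iteration, pairwise counting) independent of the
# implementations they check.

# Quick grn builder: edges as a two-column data.frame or matrix.
mk_grn <- function(edges, tf = character(0), mirna = character(0),
                   mrna = character(0)) {
  nodes <- data.frame(id = c(tf, mirna, mrna),
                      type = rep(c("TF", "miRNA", "mRNA"),
                                 c(length(tf), length(mirna), length(mrna))),
                      stringsAsFactors = FALSE)
  if (is.matrix(edges)) edges <- as.data.frame(edges,
                                               stringsAsFactors = FALSE)
  if (!nrow(edges)) edges <- data.frame(from = character(0),
                                        to = character(0))
  names(edges) <- c("from", "to")
  grn(nodes, edges)
}

# Random all-TF digraph wrapped as a grn (every edge is permitted TF->TF).
random_tf_grn <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n) < p, n, n)
  ids <- sprintf("T%02d", seq_len(n))
  idx <- which(A, arr.ind = TRUE)
  mk_grn(data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                    stringsAsFactors = FALSE), tf = ids)
}

grn_adjacency <- function(network) {
  ids <- grn_nodes(network)$id
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  el <- grn_edges(network)
  if (nrow(el)) A[cbind(match(el$from, ids), match(el$to, ids))] <- 1L
  A
}

# ---- K-core oracles ---------------------------------------------------

# Exhaustive subset-search definition: core number of v = largest k such
# that some subgraph containing v has minimum total degree >= k.
bf_core_subsets <- function(A) {
  diag(A) <- 0L
  n <- nrow(A)
  best <- integer(n)
  U <- A + t(A)  # total-degree adjacency (counts both directions)
  for (mask in seq_len(2^n) - 1L) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(S) == 0) next
    mindeg <- min(rowSums(U[S, S, drop = FALSE]))
    best[S] <- pmax(best[S], mindeg)
  }
  best
}

# Independent peeling oracle on the adjacency matrix.
bf_core_peel <- function(A) {
  diag(A) <- 0L
  n <- nrow(A)
  U <- A + t(A)
  alive <- rep(TRUE, n)
  core <- integer(n)
  k <- -1L   # pass k = 0 first: initially isolated nodes have coreness 0
  while (any(alive)) {
    k <- k + 1L
    repeat {
      deg <- rowSums(U[, alive, drop = FALSE])[alive]
      victims <- which(alive)[deg <= k]
      if (!length(victims)) break
      core[victims] <- k
      alive[victims] <- FALSE
    }
  }
  core
}

# ---- shortest-path centralities ---------------------------------------

bf_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Count shortest paths s -> t by dynamic programming over the distance
# matrix.
bf_path_counts <- function(A, d) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  ord <- order(as.vector(d))
  for (idx in ord) {
    t <- ((idx - 1) %/% n) + 1
    s <- ((idx - 1) %% n) + 1
    if (s == t || !is.finite(d[s, t])) next
    preds <- which(A[, t] > 0 & d[s, ] + 1 == d[s, t])
    sigma[s, t] <- sum(sigma[s, preds])
  }
  sigma
}

bf_betweenness <- function(A) {
  diag(A) <- 0L
  n <- nrow(A)
  d <- bf_distances(A)
  sigma <- bf_path_counts(A, d)
  bw <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || s == v || t == v) next
    if (!is.finite(d[s, t]) || sigma[s, t] == 0) next
    if (d[s, v] + d[v, t] == d[s, t])
      bw[v] <- bw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  }
  bw
}

bf_closeness_in <- function(A) {
  diag(A) <- 0L
  n <- nrow(A)
  d <- bf_distances(A)
  vapply(seq_len(n), function(i) {
    din <- d[-i, i]
    din <- din[is.finite(din)]
    r <- length(din)
    if (r == 0 || sum(din) == 0) return(0)
    (r / (n - 1)) * (r / sum(din))
  }, numeric(1))
}

bf_pagerank <- function(A, damping = 0.85, tol = 1e-13) {
  n <- nrow(A)
  outdeg <- rowSums(A)
  x <- rep(1 / n, n)
  for (iter in 1:10000) {
    xn <- numeric(n)
    for (j in seq_len(n)) {
      if (outdeg[j] > 0) xn <- xn + x[j] * A[j, ] / outdeg[j]
      else xn <- xn + x[j] / n
    }
    xn <- damping * xn + (1 - damping) / n
    if (max(abs(xn - x)) < tol) break
    x <- xn
  }
  xn
}

# ---- classification oracles -------------------------------------------

bf_auroc_pairs <- function(scores, y) {
  sp <- scores[y > 0]
  sn <- scores[y < 0]
  comp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(comp)
}

# Planted-signal dataset straight from the generator, as most model tests
# consume it.
planted_dataset <- function(seed, n_mrna = 500, noise_sd = NA, ...) {
  cfg <- synthetic_config(seed = seed, n_mrna = n_mrna, ...)
  gen <- generate_network(cfg)
  deg <- generate_labels(gen$network, gen$truth, noise_sd = noise_sd,
                         seed = seed + 5000L)
  labels <- stats::setNames(deg$direction, deg$gene_id)
  list(network = gen$network, truth = gen$truth, deg = deg,
       labels = labels)
}

network_interactions_df <- function(network) {
  el <- grn_edges(network)
  ty <- stats::setNames(grn_nodes(network)$type, grn_nodes(network)$id)
  data.frame(source_id = el$from, source_type = unname(ty[el$from]),
             target_id = el$to, target_type = unname(ty[el$to]),
             evidence = "synthetic", stringsAsFactors = FALSE)
}

grn_nodes_as_annotation <- function(network) {
  nd <- grn_nodes(network)
  data.frame(gene_id = nd$id, type = nd$type, stringsAsFactors = FALSE)
}

# Per-category node counts in sample_typed_subnetwork() layout.
category_counts_of <- function(network) {
  nd <- grn_nodes(network)
  outdeg <- igraph::degree(network$graph, mode = "out")
  tf <- nd$id[nd$type == "TF"]
  c(tf_with_targets = sum(outdeg[tf] > 0),
    tf_without_targets = sum(outdeg[tf] == 0),
    mirna = sum(nd$type == "miRNA"),
    mrna = sum(nd$type == "mRNA"))
}

# A condition-specific observed network: a typed subsample of the general
# network plus a dense mutual core among `n_core` of its active TFs --
# core structure specific to the observed network, absent from the
# general one.
condition_specific_observed <- function(general, counts, n_core = 8,
                                        density = 0.8, rng_seed = 1) {
  obs <- sample_typed_subnetwork(general, counts, rng_seed = rng_seed)
  nd <- grn_nodes(obs)
  outdeg <- igraph::degree(obs$graph, mode = "out")
  tf <- nd$id[nd$type == "TF" & outdeg[nd$id] > 0]
  set.seed(rng_seed + 1L)
  core <- sample(tf, min(n_core, length(tf)))
  pairs <- expand.grid(from = core, to = core, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to & stats::runif(nrow(pairs)) < density, ]
  el <- unique(rbind(grn_edges(obs), pairs))
  list(network = grn(nd, el), core = core)
}
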