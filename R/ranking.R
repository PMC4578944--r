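#' @importFrom igraph betweenness page_rank distances coreness
NULL

# Assemble a RankedList data.frame with the package-wide tie rule:
# score descending, then total degree descending, then id ascending.
ranked_list <- function(strategy, ids, scores, tiebreak_degree = NULL) {
  if (is.null(tiebreak_degree)) tiebreak_degree <- numeric(length(ids))
  ord <- order(-scores, -tiebreak_degree, ids)
  data.frame(strategy = strategy,
             rank = seq_along(ids),
             regulator = ids[ord],
             score = unname(scores[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank regulators by absolute differential expression
#'
#' "Most differentially expressed" means the largest `|log2fc|`; regulators
#' missing from the table score 0.  Ties fall back to lexicographic id.
#'
#' @param deg_table DEG data.frame (`gene_id`, `log2fc`, ...).
#' @param regulators character vector of regulator ids to rank.
#' @return RankedList data.frame (`strategy`, `rank`, `regulator`, `score`).
#' @export
rank_by_differential_expression <- function(deg_table, regulators) {
  lfc <- stats::setNames(rep(0, length(regulators)), regulators)
  hit <- intersect(regulators, deg_table$gene_id)
  lfc[hit] <- abs(deg_table$log2fc[match(hit, deg_table$gene_id)])
  ranked_list("de", regulators, lfc[regulators])
}

#' Rank regulators by degree
#'
#' @param network a [grn].
#' @param direction `"out"` (number of targets) or `"in"` (number of
#'   regulators).
#' @param regulator_ids regulators to rank; defaults to [regulators()].
#' @return RankedList data.frame.
#' @export
rank_by_degree <- function(network, direction = c("out", "in"),
                           regulator_ids = NULL) {
  direction <- match.arg(direction)
  if (is.null(regulator_ids)) regulator_ids <- regulators(network)
  d <- igraph::degree(network$graph, mode = direction)[regulator_ids]
  td <- total_degree_noloops(network$graph)[regulator_ids]
  ranked_list(paste0(direction, "deg"), regulator_ids, d, td)
}

#' Rank regulators by fold enrichment of differentially expressed targets
#'
#' Score of a regulator = ((# targets that are DE) / (# DE genes)) /
#' ((# targets) / (# all genes)), with targets counted in the universe
#' network.  Regulators with no targets are excluded.  The null
#' expectation under random DE assignment is 1.
#'
#' @param network_universe a [grn] in which targets are counted.
#' @param deg_set character vector of DE gene ids (subset of `all_genes`).
#' @param all_genes character vector of all assayable gene ids.
#' @param regulator_ids regulators to score.
#' @return RankedList data.frame (zero-target regulators omitted).
#' @export
rank_by_fold_enrichment <- function(network_universe, deg_set, all_genes,
                                    regulator_ids = NULL) {
  if (!length(deg_set) || !length(all_genes))
    stop("undefined fold enrichment: empty DE set or gene universe")
  if (length(setdiff(deg_set, all_genes)))
    stop("deg_set must be a subset of all_genes")
  if (is.null(regulator_ids)) regulator_ids <- regulators(network_universe)
  el <- grn_edges(network_universe)
  el <- el[el$from %in% regulator_ids, , drop = FALSE]
  targets <- split(el$to, el$from)
  keep <- regulator_ids[regulator_ids %in% names(targets)]
  if (!length(keep))
    return(ranked_list("enrich", character(0), numeric(0)))
  n_de <- length(deg_set)
  n_all <- length(all_genes)
  score <- vapply(keep, function(r) {
    tg <- unique(targets[[r]])
    (sum(tg %in% deg_set) / n_de) / (length(tg) / n_all)
  }, numeric(1))
  td <- total_degree_noloops(network_universe$graph)[keep]
  ranked_list("enrich", keep, score, td)
}

#' Rank regulators by a centrality measure
#'
#' Standard directed-graph definitions: closeness uses the
#' reachable-component scaling `C(u) = ((r-1)/(n-1)) * ((r-1)/sum d)` where
#' `r` is the number of nodes connected to `u` in the chosen direction
#' (`mode = "in"`, the default, measures how quickly `u` is reached);
#' betweenness counts directed shortest paths; pagerank uses damping 0.85.
#'
#' @param network a [grn].
#' @param measure one of `"closeness"`, `"betweenness"`, `"pagerank"`.
#' @param regulator_ids regulators to rank; defaults to [regulators()].
#' @param mode distance orientation for closeness.
#' @param damping pagerank damping factor.
#' @return RankedList data.frame.
#' @export
rank_by_centrality <- function(network,
                               measure = c("closeness", "betweenness",
                                           "pagerank"),
                               regulator_ids = NULL, mode = c("in", "out"),
                               damping = 0.85) {
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  if (is.null(regulator_ids)) regulator_ids <- regulators(network)
  g <- network$graph
  score <- switch(measure,
    closeness = closeness_scaled(g, mode = mode),
    betweenness = igraph::betweenness(g, directed = TRUE),
    pagerank = igraph::page_rank(g, damping = damping,
                                 directed = TRUE)$vector)
  td <- total_degree_noloops(g)[regulator_ids]
  ranked_list(measure, regulator_ids, score[regulator_ids], td)
}

# Closeness with reachable-set scaling on a possibly disconnected digraph.
closeness_scaled <- function(g, mode = "in") {
  n <- igraph::vcount(g)
  if (n <= 1)
    return(stats::setNames(rep(0, n), igraph::V(g)$name))
  dm <- igraph::distances(g, mode = mode)
  vapply(seq_len(n), function(i) {
    d <- dm[i, -i]
    d <- d[is.finite(d)]
    r <- length(d)
    if (r == 0 || sum(d) == 0) return(0)
    (r / (n - 1)) * (r / sum(d))
  }, numeric(1)) -> cc
  stats::setNames(cc, igraph::V(g)$name)
}

#' K-core (K-shell) decomposition
#'
#' Assigns every node the iteration of the iterative leaf-removal process
#' in which it is removed: nodes of total degree at most 1 go in the first
#' iteration, at most 2 in the second, and so on, each removal cascading
#' until no node of the current degree bound remains.  Degree is total
#' (in + out) on the directed graph; self-loops are ignored.
#'
#' @param network a [grn] or igraph graph.
#' @return List of class `core_assignment`: `core_number` (named integer),
#'   `n_shells` (max core number), `total_degree` (used for tie-breaks).
#' @export
kcore_decompose <- function(network) {
  g <- if (inherits(network, "grn")) network$graph else network
  g2 <- igraph::delete_edges(g, igraph::E(g)[igraph::which_loop(g)])
  cn <- igraph::coreness(g2, mode = "all")
  structure(list(core_number = cn,
                 n_shells = if (length(cn)) max(cn) else 0L,
                 total_degree = igraph::degree(g2, mode = "all")),
            class = "core_assignment")
}

#' Rank regulators by K-core depth
#'
#' The innermost shell (largest core number) receives rank 1; within a
#' shell ties are broken by total degree, then id.
#'
#' @param core a `core_assignment` from [kcore_decompose()].
#' @param regulator_ids regulators to rank.
#' @return RankedList data.frame with the core number as score.
#' @export
rank_by_core <- function(core, regulator_ids) {
  stopifnot(inherits(core, "core_assignment"))
  missing <- setdiff(regulator_ids, names(core$core_number))
  if (length(missing))
    stop("regulators absent from core assignment: ",
         paste(utils::head(missing, 3), collapse = ", "))
  ranked_list("kcore", regulator_ids,
              core$core_number[regulator_ids],
              core$total_degree[regulator_ids])
}

#' Run all eight ranking strategies
#'
#' Executes differential expression, out-degree, in-degree, fold
#' enrichment, closeness, betweenness, pagerank and K-core rankings over a
#' shared regulator set, and returns the full lists plus a top-k report.
#'
#' @param network the condition-specific [grn] to analyze.
#' @param deg_table DEG data.frame for the expression-based strategies.
#' @param universe the general [grn] used for fold enrichment (defaults to
#'   `network`).
#' @param deg_set DE gene ids (defaults to the nodes of `network`).
#' @param all_genes gene universe (defaults to the nodes of `universe`).
#' @param top_k rows per strategy in the report.
#' @return List with `rankings` (named list of RankedList data.frames) and
#'   `top_table` (long data.frame of the top `top_k` per strategy).
#' @export
run_all_strategies <- function(network, deg_table, universe = network,
                               deg_set = NULL, all_genes = NULL,
                               top_k = 20L) {
  regs <- regulators(network)
  if (!length(regs)) stop("network has no eligible regulators")
  if (is.null(deg_set)) deg_set <- grn_nodes(network)$id
  if (is.null(all_genes)) all_genes <- grn_nodes(universe)$id
  deg_set <- intersect(deg_set, all_genes)
  core <- kcore_decompose(network)
  rankings <- list(
    de = rank_by_differential_expression(deg_table, regs),
    outdeg = rank_by_degree(network, "out", regs),
    indeg = rank_by_degree(network, "in", regs),
    enrich = rank_by_fold_enrichment(universe, deg_set, all_genes, regs),
    closeness = rank_by_centrality(network, "closeness", regs),
    betweenness = rank_by_centrality(network, "betweenness", regs),
    pagerank = rank_by_centrality(network, "pagerank", regs),
    kcore = rank_by_core(core, regs))
  top_table <- do.call(rbind, lapply(rankings, function(r)
    utils::head(r, top_k)))
  rownames(top_table) <- NULL
  list(rankings = rankings, top_table = top_table)
}
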