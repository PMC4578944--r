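#' @importFrom igraph V E graph_from_data_frame vcount ecount degree
#'   induced_subgraph as_data_frame delete_edges which_loop is_igraph
NULL

# Edge categories a regulatory network may contain.  mRNAs never regulate,
# and miRNA->miRNA regulation is not part of the model.
GRN_CATEGORIES <- c("TF->TF", "TF->mRNA", "TF->miRNA", "miRNA->TF", "miRNA->mRNA")

NODE_TYPES <- c("TF", "miRNA", "mRNA")

#' Construct a typed regulatory network
#'
#' A `grn` wraps a directed [igraph] graph whose vertices carry a `type`
#' attribute (`"TF"`, `"miRNA"` or `"mRNA"`) together with per-category edge
#' counts.  Edges always point from a regulator (TF or miRNA) to its target;
#' self-loops are permitted only as TF auto-regulation.
#'
#' @param nodes data.frame with columns `id`, `type`.
#' @param edges data.frame with columns `from`, `to` (node ids); may have
#'   zero rows.  Duplicate edges are collapsed.
#' @return An object of class `grn` with elements `graph` (igraph) and
#'   `category_counts` (named integer vector over the five edge categories).
#' @export
grn <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), all(c("id", "type") %in% names(nodes)))
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids in annotation")
  bad <- setdiff(unique(nodes$type), NODE_TYPES)
  if (length(bad))
    stop("unknown node type(s): ", paste(bad, collapse = ", "))
  if (nrow(edges)) {
    edges <- unique(edges[, c("from", "to")])
    type_of <- stats::setNames(nodes$type, nodes$id)
    st <- type_of[edges$from]
    tt <- type_of[edges$to]
    if (anyNA(st) || anyNA(tt))
      stop("edge endpoint missing from node table")
    if (any(st == "mRNA"))
      stop("mRNA nodes cannot be edge sources")
    loop <- edges$from == edges$to
    if (any(loop & st != "TF"))
      stop("self-loops are only permitted for TFs")
    if (any(st == "miRNA" & tt == "miRNA"))
      stop("miRNA->miRNA edges are not permitted")
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  out <- structure(list(graph = g, category_counts = count_categories(g)),
                   class = "grn")
  out
}

# Recompute the per-category edge tally from the graph.
count_categories <- function(g) {
  counts <- stats::setNames(integer(length(GRN_CATEGORIES)), GRN_CATEGORIES)
  if (igraph::ecount(g) == 0) return(counts)
  el <- igraph::as_data_frame(g, what = "edges")
  ty <- stats::setNames(igraph::V(g)$type, igraph::V(g)$name)
  key <- paste0(ty[el$from], "->", ty[el$to])
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  counts
}

as_grn <- function(g) {
  structure(list(graph = g, category_counts = count_categories(g)),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("Regulatory network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  tt <- table(factor(igraph::V(x$graph)$type, levels = NODE_TYPES))
  cat("  nodes:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  cc <- x$category_counts
  cc <- cc[cc > 0]
  if (length(cc))
    cat("  edges:", paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n")
  invisible(x)
}

#' Node and edge accessors
#'
#' `grn_nodes()` returns the typed node table, `grn_edges()` the directed
#' edge list.
#'
#' @param network a `grn` object.
#' @return A data.frame: `id`/`type` for nodes, `from`/`to` for edges.
#' @export
grn_nodes <- function(network) {
  stopifnot(inherits(network, "grn"))
  data.frame(id = igraph::V(network$graph)$name,
             type = igraph::V(network$graph)$type,
             stringsAsFactors = FALSE)
}

#' @rdname grn_nodes
#' @export
grn_edges <- function(network) {
  stopifnot(inherits(network, "grn"))
  el <- igraph::as_data_frame(network$graph, what = "edges")
  el[, c("from", "to"), drop = FALSE]
}

#' Eligible regulator nodes of a network
#'
#' TFs qualify only when they have at least one outgoing edge in the network
#' under analysis; miRNAs are always eligible.
#'
#' @param network a `grn` object.
#' @return Character vector of regulator node ids.
#' @export
regulators <- function(network) {
  stopifnot(inherits(network, "grn"))
  g <- network$graph
  ty <- igraph::V(g)$type
  nm <- igraph::V(g)$name
  outdeg <- igraph::degree(g, mode = "out")
  sort(c(nm[ty == "TF" & outdeg > 0], nm[ty == "miRNA"]))
}

# Total degree with self-loops dropped (the convention used for K-core and
# tie-breaking throughout).
total_degree_noloops <- function(g) {
  g2 <- igraph::delete_edges(g, igraph::E(g)[igraph::which_loop(g)])
  igraph::degree(g2, mode = "all")
}

# Run expr with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# Deterministically derive a sub-seed from a master seed (kept below 2^31).
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 1000L + (k %% 1000L)
}
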