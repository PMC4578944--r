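#' Assign ChIP peaks to target genes by TSS proximity
#'
#' A gene is a direct target of a TF when its TSS lies within `window_bp`
#' of a binding peak of that TF, measured from the peak interval (not a
#' summit) and inclusive at exactly `window_bp`.  Peaks are 0-based
#' half-open on disk; internally the peak `[start, end)` becomes the
#' 1-based closed interval `[start + 1, end]`, expanded by the window on
#' both sides.  Strand is ignored.
#'
#' @param peaks data.frame with columns `chrom`, `start` (0-based),
#'   `end` (exclusive), `tf_id`.
#' @param annotation data.frame with columns `gene_id`, `type`, `chrom`,
#'   `tss` (1-based), and optionally `strand`.
#' @param window_bp window half-width in bp (default 1000).
#' @return Deduplicated interaction data.frame with columns `source_id`,
#'   `source_type`, `target_id`, `target_type`, `evidence`.
#' @export
assign_peak_targets <- function(peaks, annotation, window_bp = 1000L) {
  stopifnot(window_bp > 0)
  if (anyDuplicated(annotation$gene_id))
    stop("annotation gene_ids must be unique")
  if (!nrow(peaks))
    return(empty_interactions())
  if (any(peaks$start < 0) || any(peaks$start >= peaks$end))
    stop("parse error: malformed peak coordinates (need 0 <= start < end)")
  tf_ids <- annotation$gene_id[annotation$type == "TF"]
  unknown <- setdiff(unique(peaks$tf_id), tf_ids)
  if (length(unknown))
    warning(length(unknown), " peak TF id(s) absent from the annotation's ",
            "TF set; their edges are still emitted")
  chroms <- union(unique(peaks$chrom), unique(annotation$chrom))
  pk <- GenomicRanges::GRanges(
    seqnames = factor(peaks$chrom, levels = chroms),
    ranges = IRanges::IRanges(start = pmax(1L, peaks$start + 1L - window_bp),
                              end = peaks$end + window_bp))
  ts <- GenomicRanges::GRanges(
    seqnames = factor(annotation$chrom, levels = chroms),
    ranges = IRanges::IRanges(start = annotation$tss, width = 1L))
  hits <- GenomicRanges::findOverlaps(pk, ts, ignore.strand = TRUE)
  if (!length(hits))
    return(empty_interactions())
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  res <- data.frame(
    source_id = peaks$tf_id[qh],
    source_type = "TF",
    target_id = annotation$gene_id[sh],
    target_type = annotation$type[sh],
    evidence = "peak",
    stringsAsFactors = FALSE)
  res <- res[res$source_id != res$target_id |
               res$target_type == "TF", , drop = FALSE]
  unique(res)
}

empty_interactions <- function() {
  data.frame(source_id = character(0), source_type = character(0),
             target_id = character(0), target_type = character(0),
             evidence = character(0), stringsAsFactors = FALSE)
}

#' Consensus miRNA-target interactions across prediction databases
#'
#' Keeps a miRNA-target pair when it is predicted by at least `min_support`
#' distinct databases; the evidence field records the supporting databases.
#'
#' @param per_db named list of interaction data.frames (one per database),
#'   each with columns `source_id`, `target_id` and optionally the type
#'   columns.
#' @param min_support minimum number of supporting databases (default 2).
#' @return Interaction data.frame in the standard five-column layout.
#' @export
consensus_mirna_targets <- function(per_db, min_support = 2L) {
  stopifnot(min_support >= 1)
  if (length(per_db) < min_support)
    stop("configuration error: fewer databases (", length(per_db),
         ") than min_support (", min_support, ")")
  if (is.null(names(per_db)) || any(names(per_db) == ""))
    names(per_db) <- paste0("db", seq_along(per_db))
  rows <- do.call(rbind, lapply(names(per_db), function(db) {
    x <- per_db[[db]]
    if (!nrow(x)) return(NULL)
    unique(data.frame(source_id = x$source_id, target_id = x$target_id,
                      db = db, stringsAsFactors = FALSE))
  }))
  if (is.null(rows)) return(empty_interactions())
  key <- paste(rows$source_id, rows$target_id, sep = "\r")
  support <- tapply(rows$db, key, function(d) sort(unique(d)))
  keep <- names(support)[vapply(support, length, 1L) >= min_support]
  if (!length(keep)) return(empty_interactions())
  parts <- strsplit(keep, "\r", fixed = TRUE)
  data.frame(
    source_id = vapply(parts, `[`, "", 1L),
    source_type = "miRNA",
    target_id = vapply(parts, `[`, "", 2L),
    target_type = "mRNA",
    evidence = vapply(support[keep], paste, "", collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a typed regulatory network from interaction evidence
#'
#' All annotated genes and miRNAs become nodes (isolated nodes included).
#' Interactions with an unannotated endpoint are dropped with a message;
#' records whose source is annotated as mRNA are rejected.  The target type
#' recorded in the interaction table is ignored in favour of the annotation.
#'
#' @param interactions data.frame with columns `source_id`, `target_id`
#'   (the standard five-column layout is accepted).
#' @param annotation data.frame with columns `gene_id`, `type` (one of
#'   TF/miRNA/mRNA).
#' @return A [grn].
#' @export
build_network <- function(interactions, annotation) {
  if (anyDuplicated(annotation$gene_id))
    stop("annotation gene_ids must be unique")
  nodes <- data.frame(id = annotation$gene_id, type = annotation$type,
                      stringsAsFactors = FALSE)
  type_of <- stats::setNames(nodes$type, nodes$id)
  el <- interactions
  if (nrow(el)) {
    known <- el$source_id %in% nodes$id & el$target_id %in% nodes$id
    if (any(!known))
      message(sum(!known), " interaction(s) dropped: unannotated endpoint")
    el <- el[known, , drop = FALSE]
    bad_src <- type_of[el$source_id] == "mRNA"
    if (any(bad_src))
      message(sum(bad_src), " interaction(s) rejected: mRNA source")
    el <- el[!bad_src, , drop = FALSE]
  }
  grn(nodes, data.frame(from = el$source_id, to = el$target_id,
                        stringsAsFactors = FALSE))
}

#' Induced subnetwork on a node set
#'
#' Keeps the intersection of `node_ids` with the network's nodes and
#' exactly the edges with both endpoints retained.  Node types are
#' preserved; an empty intersection yields a valid empty network.
#'
#' @param network a [grn].
#' @param node_ids character vector of node ids.
#' @return A [grn].
#' @export
induced_subnetwork <- function(network, node_ids) {
  stopifnot(inherits(network, "grn"))
  keep <- intersect(igraph::V(network$graph)$name, node_ids)
  as_grn(igraph::induced_subgraph(network$graph, keep))
}

#' Select differentially expressed genes across tables
#'
#' Genes passing `fdr < fdr_threshold` in each table are combined by union
#' or intersection.  Genes whose direction of change disagrees between
#' tables (among those passing in at least two tables) are counted and
#' reported as an attribute.
#'
#' @param tables list of DEG data.frames (`gene_id`, `log2fc`, `fdr`, and
#'   optionally `direction`).
#' @param fdr_threshold FDR cutoff in (0, 1].
#' @param combine `"union"` or `"intersection"`.
#' @return Character vector of gene ids with attribute
#'   `direction_conflicts` (count of sign disagreements).
#' @export
select_degs <- function(tables, fdr_threshold = 0.001,
                        combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1)
    stop("configuration error: fdr_threshold must lie in (0, 1]")
  if (is.data.frame(tables)) tables <- list(tables)
  passing <- lapply(tables, function(tb) tb[tb$fdr < fdr_threshold, ,
                                            drop = FALSE])
  sets <- lapply(passing, `[[`, "gene_id")
  ids <- if (combine == "union") Reduce(union, sets, character(0))
         else Reduce(intersect, sets)
  if (is.null(ids)) ids <- character(0)
  dirs <- do.call(rbind, lapply(passing, function(tb)
    data.frame(gene_id = tb$gene_id, dir = sign(tb$log2fc),
               stringsAsFactors = FALSE)))
  conflicts <- 0L
  if (!is.null(dirs) && nrow(dirs)) {
    rng <- tapply(dirs$dir, dirs$gene_id, function(d) length(unique(d)))
    conflicts <- sum(rng > 1)
  }
  structure(ids, direction_conflicts = conflicts)
}

#' Degree statistics per interaction category
#'
#' For each of the five edge categories, summarizes the out-degree of the
#' sources and the in-degree of the targets (ten rows in all), computed
#' over nodes with at least one edge of that kind — so every minimum is at
#' least 1 by construction.  Categories with no edges are absent from the
#' result.
#'
#' @param network a [grn].
#' @return data.frame with columns `category`, `side` (`"out"` for the
#'   regulator, `"in"` for the target), `n_nodes`, `min`, `max`, `mean`,
#'   `median`.
#' @export
degree_stats <- function(network) {
  stopifnot(inherits(network, "grn"))
  el <- grn_edges(network)
  ty <- stats::setNames(grn_nodes(network)$type, grn_nodes(network)$id)
  out <- NULL
  for (cat in GRN_CATEGORIES) {
    parts <- strsplit(cat, "->", fixed = TRUE)[[1]]
    sub <- el[ty[el$from] == parts[1] & ty[el$to] == parts[2], , drop = FALSE]
    if (!nrow(sub)) next
    for (side in c("out", "in")) {
      d <- if (side == "out") table(sub$from) else table(sub$to)
      d <- as.numeric(d)
      out <- rbind(out, data.frame(
        category = cat, side = side, n_nodes = length(d),
        min = min(d), max = max(d), mean = mean(d),
        median = stats::median(d), stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(category = character(0), side = character(0),
                      n_nodes = integer(0), min = numeric(0), max = numeric(0),
                      mean = numeric(0), median = numeric(0))
  out
}

#' Log-linear exponential fit to a degree distribution
#'
#' Bins the empirical degree histogram (equal-width bins, zero-count bins
#' excluded) and fits log-frequency against the bin centre by ordinary
#' least squares.  An exponential (geometric) law is log-linear, so the
#' coefficient of determination of this fit measures how exponential the
#' distribution looks; the decay rate is the negative slope.
#'
#' @param degree_values vector of positive integer degrees.
#' @param n_bins number of equal-width histogram bins (degree ranges
#'   narrower than `n_bins` fall back to unit bins).
#' @return List with `rate`, `r_squared`, and the fitted `lm` object.
#' @export
fit_exponential <- function(degree_values, n_bins = 10L) {
  degree_values <- degree_values[is.finite(degree_values)]
  if (length(unique(degree_values)) < 3)
    stop("fit error: need at least 3 distinct degree values")
  rng <- range(degree_values)
  n_bins <- min(n_bins, diff(rng) + 1L)
  breaks <- seq(rng[1] - 0.5, rng[2] + 0.5, length.out = n_bins + 1)
  h <- graphics::hist(degree_values, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0
  if (sum(keep) < 3)
    stop("fit error: fewer than 3 occupied bins")
  fit <- stats::lm(log(h$counts[keep]) ~ h$mids[keep])
  ## summary.lm warns on numerically perfect fits; those are legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(rate = -unname(stats::coef(fit)[2]),
       r_squared = r2,
       fit = fit)
}

#' Cumulative network growth over experiment batches and linear extrapolation
#'
#' Counts unique edges accumulated after each batch of interactions, fits
#' an ordinary least-squares line to edges-vs-batch-index, and returns a
#' function extrapolating the line to any batch count.
#'
#' @param experiment_batches ordered list of interaction data.frames.
#' @return List with `series` (data.frame `batch`, `cum_edges`), `slope`,
#'   `intercept`, and `extrapolate(at_n)`.
#' @export
growth_curve <- function(experiment_batches) {
  stopifnot(length(experiment_batches) >= 1)
  seen <- character(0)
  cum <- integer(length(experiment_batches))
  for (i in seq_along(experiment_batches)) {
    b <- experiment_batches[[i]]
    if (nrow(b))
      seen <- union(seen, paste(b$source_id, b$target_id, sep = "\r"))
    cum[i] <- length(seen)
  }
  series <- data.frame(batch = seq_along(cum), cum_edges = cum)
  if (nrow(series) >= 2) {
    fit <- stats::lm(cum_edges ~ batch, data = series)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  } else {
    slope <- NA_real_
    intercept <- cum[1]
  }
  list(series = series, slope = slope, intercept = intercept,
       extrapolate = function(at_n) intercept + slope * at_n)
}
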