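#' Read and write the package's tab-separated file dialects
#'
#' All files are headered TSV except peaks, which are BED3+name (0-based
#' half-open, no header).  Column layouts:
#' * interactions: `source_id`, `source_type`, `target_id`, `target_type`,
#'   `evidence`
#' * annotation: `gene_id`, `type`, `chrom`, `tss` (1-based), `strand`
#' * DEG table: `gene_id`, `log2fc`, `fdr` (a `direction` column is
#'   recomputed as `sign(log2fc)` on read)
#' * expression matrix: first column `gene_id`, remaining columns tissues
#'
#' @param path file path.
#' @name grn_io
NULL

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  df
}

#' @rdname grn_io
#' @export
read_interactions <- function(path) {
  read_tsv_checked(path, c("source_id", "source_type", "target_id",
                           "target_type", "evidence"))
}

#' @rdname grn_io
#' @export
read_annotation <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "type"))
  bad <- setdiff(unique(df$type), NODE_TYPES)
  if (length(bad))
    stop("file ", path, " has unknown node type(s): ",
         paste(bad, collapse = ", "))
  df
}

#' @rdname grn_io
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED file ", path, " needs 4 columns (BED3+name)")
  names(df)[1:4] <- c("chrom", "start", "end", "tf_id")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("parse error in ", path, ": start >= end at row ", bad[1])
  df[, 1:4]
}

#' @rdname grn_io
#' @export
read_deg_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "log2fc", "fdr"))
  if (any(df$fdr < 0 | df$fdr > 1))
    stop("file ", path, ": fdr outside [0, 1]")
  df$direction <- sign(df$log2fc)
  df
}

#' @rdname grn_io
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_checked(path, "gene_id")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' @rdname grn_io
#' @param x object to write (see individual writers).
#' @export
write_interactions <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grn_io
#' @param network a [grn]; written as an edge-list TSV with a `.nodes.tsv`
#'   sidecar of node types.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "grn"))
  utils::write.table(grn_edges(network), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- sub("\\.tsv$", "", path)
  utils::write.table(grn_nodes(network), paste0(sidecar, ".nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grn_io
#' @export
write_peaks <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end", "tf_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Interactions table from a grn edge list (used by the pipeline writers).
network_interactions <- function(network) {
  el <- grn_edges(network)
  ty <- stats::setNames(grn_nodes(network)$type, grn_nodes(network)$id)
  data.frame(source_id = el$from, source_type = unname(ty[el$from]),
             target_id = el$to, target_type = unname(ty[el$to]),
             evidence = "synthetic", stringsAsFactors = FALSE)
}
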