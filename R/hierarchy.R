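#' Parse a core-band predicate
#'
#' Bands are written against the depth-relabelled core number K, where the
#' innermost (last-surviving) core is K = 1 and K increases outward —
#' matching the convention of reporting the innermost regulators as
#' "K <= 2".  Supported forms: `"K<=2"`, `"K<2"`, `"K==3"` (or `"K=3"`),
#' `"K>=8"`, `"K>7"`, and double bounds such as `"3<K<=7"` or
#' `"4<=K<=7"`.
#'
#' @param band predicate string.
#' @return A function mapping integer depth K to logical.
#' @export
parse_core_band <- function(band) {
  s <- gsub(" ", "", band)
  m <- regmatches(s, regexec("^([0-9]+)(<=?)K(<=?)([0-9]+)$", s))[[1]]
  if (length(m)) {
    lo <- as.numeric(m[2]); hi <- as.numeric(m[5])
    lo_inc <- m[3] == "<="; hi_inc <- m[4] == "<="
    return(function(K) (if (lo_inc) K >= lo else K > lo) &
             (if (hi_inc) K <= hi else K < hi))
  }
  m <- regmatches(s, regexec("^K(<=|>=|==|=|<|>)([0-9]+)$", s))[[1]]
  if (length(m)) {
    v <- as.numeric(m[3])
    return(switch(m[2],
                  "<=" = function(K) K <= v,
                  ">=" = function(K) K >= v,
                  "<" = function(K) K < v,
                  ">" = function(K) K > v,
                  function(K) K == v))
  }
  stop("cannot parse core band: ", band)
}

# Depth-relabelled core number: innermost shell is 1.
core_depth <- function(core) {
  stopifnot(inherits(core, "core_assignment"))
  core$n_shells - core$core_number + 1L
}

#' K-core layered hierarchy of regulators
#'
#' Groups the regulators by K-core shell, innermost (largest core number)
#' first, annotating each with its type and expression direction.  Shells
#' may optionally be clubbed together for display via a named list mapping
#' a layer label to the raw core numbers it absorbs.
#'
#' @param core a [kcore_decompose()] result.
#' @param network the [grn] the decomposition came from.
#' @param labels named +1/-1 expression direction vector (optional).
#' @param clubbing optional named list: layer label -> core numbers.
#' @return List of class `hierarchy_layout`: `layers` (named list of
#'   regulator id vectors, core number descending) and `annotation`
#'   (data.frame: `id`, `type`, `direction`, `core_number`, `depth`).
#' @export
build_hierarchy <- function(core, network, labels = NULL, clubbing = NULL) {
  regs <- regulators(network)
  cn <- core$core_number[regs]
  depth <- core$n_shells - cn + 1L
  ty <- stats::setNames(grn_nodes(network)$type, grn_nodes(network)$id)
  ann <- data.frame(id = regs, type = unname(ty[regs]),
                    direction = if (is.null(labels)) NA_real_
                                else unname(labels[regs]),
                    core_number = unname(cn), depth = unname(depth),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (is.null(clubbing)) {
    shells <- sort(unique(cn), decreasing = TRUE)
    layers <- lapply(shells, function(k) regs[cn == k])
    names(layers) <- paste0("core_", shells)
  } else {
    layers <- lapply(clubbing, function(ks) regs[cn %in% ks])
    covered <- unlist(clubbing)
    rest <- sort(setdiff(unique(cn), covered), decreasing = TRUE)
    for (k in rest) layers[[paste0("core_", k)]] <- regs[cn == k]
    ord <- order(-vapply(layers, function(ids)
      if (length(ids)) max(cn[ids]) else -Inf, numeric(1)))
    layers <- layers[ord]
  }
  structure(list(layers = layers, annotation = ann),
            class = "hierarchy_layout")
}

#' Classification sweep over K-core selection bands
#'
#' For each band predicate, the regulators whose depth K matches become
#' the feature set and every other labelled node becomes a target; each
#' requested model is then cross-validated.  This measures how much of
#' gene expression each layer of the hierarchy explains.
#'
#' @param network a [grn].
#' @param labels named +1/-1 labels covering regulators and targets.
#' @param selections character vector of band predicates
#'   (see [parse_core_band()]).
#' @param models subset of `"LR"`, `"PCA"`, `"SVR"`, `"SVC"`.
#' @param k_folds cross-validation folds.
#' @param rng_seed seed (fold partitions derive from it per row).
#' @param exclude_mirna drop miRNAs from every feature set.
#' @return data.frame with one row per selection: `selection`,
#'   `n_regulators`, `n_targets`, `empty`, and one metric column per model.
#' @export
core_cutoff_sweep <- function(network, labels, selections,
                              models = c("LR", "PCA"), k_folds = 5L,
                              rng_seed = 1L, exclude_mirna = FALSE) {
  core <- kcore_decompose(network)
  regs <- regulators(network)
  depth <- stats::setNames(core_depth(core)[regs], regs)
  ty <- stats::setNames(grn_nodes(network)$type, grn_nodes(network)$id)
  labelled <- names(labels)
  rows <- NULL
  for (i in seq_along(selections)) {
    pred <- parse_core_band(selections[i])
    sel <- regs[pred(depth[regs])]
    if (exclude_mirna) sel <- sel[ty[sel] != "miRNA"]
    row <- data.frame(selection = selections[i],
                      n_regulators = length(sel),
                      n_targets = length(setdiff(labelled, sel)),
                      empty = length(sel) == 0,
                      stringsAsFactors = FALSE)
    for (m in models) {
      val <- NA_real_
      if (length(sel)) {
        fm <- build_feature_matrix(network, sel, labels)
        val <- cross_validate(fm, m, k = k_folds,
                              rng_seed = derive_seed(rng_seed, i))$mean
      }
      row[[m]] <- val
    }
    rows <- rbind(rows, row)
  }
  rownames(rows) <- NULL
  rows
}

#' miRNA-ablation classification sweep
#'
#' Runs [core_cutoff_sweep()] twice — once as given and once with miRNAs
#' excluded from every feature set — to measure the regulatory
#' contribution of miRNAs.
#'
#' @inheritParams core_cutoff_sweep
#' @return List with data.frames `with_mirna` and `without_mirna`, rows
#'   keyed by selection.
#' @export
mirna_ablation <- function(network, labels, selections,
                           models = c("LR", "PCA"), k_folds = 5L,
                           rng_seed = 1L) {
  list(with_mirna = core_cutoff_sweep(network, labels, selections, models,
                                      k_folds, rng_seed,
                                      exclude_mirna = FALSE),
       without_mirna = core_cutoff_sweep(network, labels, selections, models,
                                         k_folds, rng_seed,
                                         exclude_mirna = TRUE))
}

# Citation ranks: 1 = most cited; missing regulators count 0 citations.
citation_ranks <- function(regulator_ids, citation_counts) {
  cnt <- stats::setNames(rep(0, length(regulator_ids)), regulator_ids)
  hit <- intersect(regulator_ids, names(citation_counts))
  if (length(hit) < length(regulator_ids))
    message(length(regulator_ids) - length(hit),
            " regulator(s) missing from the citation table; counted as 0")
  cnt[hit] <- citation_counts[hit]
  ord <- order(-cnt, names(cnt))
  stats::setNames(seq_along(ord), names(cnt)[ord])[regulator_ids]
}

#' Literature validation score of a ranking strategy
#'
#' Regulators are ranked by citation count (rank 1 = most cited, ties by
#' id); the strategy's score is the sum of the citation ranks of its top
#' `top_k` regulators — lower is better, with minimum `k(k+1)/2` when the
#' strategy's top k are exactly the k most-cited.  A random baseline
#' (mean and sd of the score over uniform draws of `top_k` regulators)
#' calibrates the scale; its analytic mean is `k(n+1)/2`.
#'
#' @param ranked a RankedList data.frame.
#' @param citation_counts named numeric vector of citation counts.
#' @param top_k regulators scored (default 20, capped at the list length).
#' @param n_random baseline draws.
#' @param rng_seed seed for the baseline.
#' @return List: `score`, `random_mean`, `random_sd`, `top_k`,
#'   `n_regulators`.
#' @export
literature_score <- function(ranked, citation_counts, top_k = 20L,
                             n_random = 1000L, rng_seed = 1L) {
  regs <- ranked$regulator
  top_k <- min(top_k, length(regs))
  cr <- citation_ranks(regs, citation_counts)
  top <- ranked$regulator[order(ranked$rank)][seq_len(top_k)]
  score <- sum(cr[top])
  draws <- with_seed(rng_seed, replicate(n_random, sum(cr[sample(regs, top_k)])))
  list(score = unname(score), random_mean = mean(draws),
       random_sd = stats::sd(draws), top_k = top_k,
       n_regulators = length(regs))
}

#' Average citation rank per K-core band
#'
#' @param core a [kcore_decompose()] result.
#' @param citation_counts named numeric vector.
#' @param core_bands band predicates, ordered inner to outer.
#' @param regulator_ids regulators to consider.
#' @return data.frame: `band`, `n_regulators`, `average_rank`.
#' @export
per_core_literature_rank <- function(core, citation_counts, core_bands,
                                     regulator_ids) {
  depth <- stats::setNames(core_depth(core)[regulator_ids], regulator_ids)
  cr <- citation_ranks(regulator_ids, citation_counts)
  out <- NULL
  for (band in core_bands) {
    pred <- parse_core_band(band)
    members <- regulator_ids[pred(depth)]
    out <- rbind(out, data.frame(
      band = band, n_regulators = length(members),
      average_rank = if (length(members)) mean(cr[members]) else NA_real_,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Three-layer TF hierarchy baseline
#'
#' Classifies TFs over the TF-TF subgraph (self-loops ignored): top = TFs
#' regulating other TFs but regulated by none, bottom = regulated but
#' regulating none, middle = both.  TFs isolated in the TF-TF subgraph fit
#' none of the three definitions and are reported as unclassifiable —
#' in densely cross-regulated networks the top layer is typically empty,
#' which is why the K-core hierarchy is used instead.
#'
#' @param network a [grn].
#' @return List of id vectors: `top`, `middle`, `bottom`, `unclassifiable`.
#' @export
three_layer_classification <- function(network) {
  nd <- grn_nodes(network)
  tfs <- nd$id[nd$type == "TF"]
  el <- grn_edges(network)
  el <- el[el$from %in% tfs & el$to %in% tfs & el$from != el$to, ,
           drop = FALSE]
  has_out <- tfs %in% el$from
  has_in <- tfs %in% el$to
  list(top = tfs[has_out & !has_in],
       middle = tfs[has_out & has_in],
       bottom = tfs[!has_out & has_in],
       unclassifiable = tfs[!has_out & !has_in])
}
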