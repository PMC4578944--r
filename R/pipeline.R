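#' Pipeline run configuration
#'
#' Collects every stage parameter in one validated object so that no stage
#' carries hard-coded analysis settings; a serialized copy is written into
#' the output directory by [run_pipeline()].
#'
#' @param output_dir directory for stage outputs and the manifest.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param window_bp peak-to-TSS assignment window.
#' @param min_support miRNA-target database consensus threshold.
#' @param fdr_threshold,combine DEG selection parameters.
#' @param strategies ranking strategies for the classification stage
#'   (subset of the eight strategy names, or `"all"`).
#' @param n_samples node-sampling null draws (0 skips the stage).
#' @param n_trials edge-randomization null trials (0 skips).
#' @param models classification models for the sweep stage.
#' @param k_folds cross-validation folds.
#' @param bands core-band predicates for the hierarchy sweep.
#' @param top_k regulators kept per ranking strategy.
#' @param synthetic a [synthetic_config()] used when no input files are
#'   given.
#' @return List of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1L, window_bp = 1000L,
                       min_support = 2L, fdr_threshold = 0.001,
                       combine = "union", strategies = "all",
                       n_samples = 0L, n_trials = 0L,
                       models = c("LR", "PCA"), k_folds = 5L,
                       bands = c("K<=2", "K==3", "K>=4"), top_k = 20L,
                       synthetic = synthetic_config(seed = seed)) {
  cfg <- list(output_dir = output_dir, seed = as.integer(seed),
              window_bp = window_bp, min_support = min_support,
              fdr_threshold = fdr_threshold, combine = combine,
              strategies = strategies, n_samples = n_samples,
              n_trials = n_trials, models = models, k_folds = k_folds,
              bands = bands, top_k = top_k, synthetic = synthetic)
  structure(cfg, class = "run_config")
}

#' Validate pipeline input files
#'
#' Schema-checks every supplied file (TSV/BED dialects of [grn_io]),
#' verifies referential integrity (each interaction endpoint annotated),
#' and flags duplicate records.  Schema violations are fatal; referential
#' and duplicate issues are reported with counts.
#'
#' @param paths named list with any of `interactions`, `annotation`,
#'   `deg` (vector of paths), `peaks`, `expression`.
#' @return List: `ok` (no fatal issue) and `issues` (data.frame with
#'   `severity`, `file`, `message`).
#' @export
validate_inputs <- function(paths) {
  issues <- data.frame(severity = character(0), file = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  note <- function(sev, f, msg) {
    issues <<- rbind(issues, data.frame(severity = sev, file = f,
                                        message = msg,
                                        stringsAsFactors = FALSE))
  }
  ann <- NULL
  if (!is.null(paths$annotation)) {
    ann <- tryCatch(read_annotation(paths$annotation),
                    error = function(e) {
                      note("error", paths$annotation, conditionMessage(e))
                      NULL
                    })
    if (!is.null(ann) && anyDuplicated(ann$gene_id))
      note("error", paths$annotation, "duplicate gene_id entries")
  }
  if (!is.null(paths$interactions)) {
    ia <- tryCatch(read_interactions(paths$interactions),
                   error = function(e) {
                     note("error", paths$interactions, conditionMessage(e))
                     NULL
                   })
    if (!is.null(ia)) {
      dup <- sum(duplicated(ia[, c("source_id", "target_id")]))
      if (dup) note("warning", paths$interactions,
                    paste(dup, "duplicate interaction(s)"))
      if (!is.null(ann)) {
        un <- sum(!(ia$source_id %in% ann$gene_id) |
                    !(ia$target_id %in% ann$gene_id))
        if (un) note("warning", paths$interactions,
                     paste(un, "interaction(s) with unannotated endpoint"))
      }
    }
  }
  for (p in paths$deg) {
    tryCatch(read_deg_table(p),
             error = function(e) note("error", p, conditionMessage(e)))
  }
  if (!is.null(paths$peaks)) {
    tryCatch(read_peaks(paths$peaks),
             error = function(e) note("error", paths$peaks,
                                      conditionMessage(e)))
  }
  if (!is.null(paths$expression)) {
    tryCatch(read_expression_matrix(paths$expression),
             error = function(e) note("error", paths$expression,
                                      conditionMessage(e)))
  }
  list(ok = !any(issues$severity == "error"), issues = issues)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (when no inputs are given),
#' validate, build, subnetwork, rank, nulls (optional), classify,
#' hierarchy — writing per-stage outputs and a JSON manifest (input
#' hashes, seed, versions, stage timings) into the configured output
#' directory.  Reruns with the same configuration and inputs reproduce
#' identical deterministic outputs.
#'
#' @param config a [run_config()].
#' @param inputs optional named list of input paths (see
#'   [validate_inputs()]); when `NULL` a synthetic dataset is generated
#'   from `config$synthetic`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("coreGRN")),
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }
  out_path <- function(f) file.path(config$output_dir, f)

  truth <- NULL
  if (is.null(inputs)) {
    sim <- t_stage("simulate", {
      cfgs <- config$synthetic
      gen <- generate_network(cfgs)
      deg <- generate_labels(gen$network, gen$truth,
                             noise_sd = cfgs$noise_sd,
                             seed = derive_seed(config$seed, 2L),
                             fdr_threshold = config$fdr_threshold)
      write_interactions(network_interactions(gen$network),
                         out_path("interactions.tsv"))
      nd <- grn_nodes(gen$network)
      utils::write.table(
        data.frame(gene_id = nd$id, type = nd$type, chrom = "chrS",
                   tss = 10000L * seq_len(nrow(nd)), strand = "+"),
        out_path("annotation.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(deg[, c("gene_id", "log2fc", "fdr")],
                         out_path("deg.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      gen
    })
    truth <- sim$truth
    inputs <- list(interactions = out_path("interactions.tsv"),
                   annotation = out_path("annotation.tsv"),
                   deg = out_path("deg.tsv"))
  }

  val <- t_stage("validate", validate_inputs(inputs))
  if (!val$ok)
    stop("stage 'validate' failed: ",
         paste(val$issues$message[val$issues$severity == "error"],
               collapse = "; "))

  net <- t_stage("build", {
    ia <- read_interactions(inputs$interactions)
    ann <- read_annotation(inputs$annotation)
    n <- build_network(ia, ann)
    write_network(n, out_path("network.tsv"))
    n
  })

  deg_tables <- lapply(inputs$deg, read_deg_table)
  sub <- t_stage("subnetwork", {
    ids <- select_degs(deg_tables, config$fdr_threshold, config$combine)
    s <- induced_subnetwork(net, ids)
    write_network(s, out_path("subnetwork.tsv"))
    s
  })

  deg_all <- do.call(rbind, deg_tables)
  ranks <- t_stage("rank", {
    r <- run_all_strategies(sub, deg_all, universe = net,
                            top_k = config$top_k)
    wanted <- if (identical(config$strategies, "all")) names(r$rankings)
              else intersect(config$strategies, names(r$rankings))
    r$rankings <- r$rankings[wanted]
    r$top_table <- r$top_table[r$top_table$strategy %in% wanted, ]
    utils::write.table(r$top_table, out_path("rankings.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    r
  })

  if (config$n_samples > 0) {
    t_stage("null_nodes", {
      ns <- rank_stability_r2(net, sub, "outdeg",
                              n_samples = config$n_samples,
                              rng_seed = derive_seed(config$seed, 3L))
      utils::write.table(ns$per_regulator, out_path("null_nodes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ns
    })
  }

  labels <- stats::setNames(deg_all$direction, deg_all$gene_id)
  labels <- labels[names(labels) %in% grn_nodes(sub)$id]
  cls <- t_stage("classify", {
    res <- list()
    for (st in names(ranks$rankings)) {
      top <- utils::head(ranks$rankings[[st]], config$top_k)$regulator
      if (!length(top)) next
      fm <- build_feature_matrix(sub, top, labels)
      res[[st]] <- lapply(stats::setNames(config$models, config$models),
                          function(m)
        cross_validate(fm, m, k = config$k_folds,
                       rng_seed = derive_seed(config$seed, 4L))$mean)
    }
    jsonlite::write_json(res, out_path("classification.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })

  hier <- t_stage("hierarchy", {
    core <- kcore_decompose(sub)
    h <- build_hierarchy(core, sub, labels)
    jsonlite::write_json(
      list(layers = h$layers, annotation = h$annotation),
      out_path("hierarchy.json"), auto_unbox = TRUE, digits = NA)
    sweep <- core_cutoff_sweep(sub, labels, config$bands,
                               models = config$models,
                               k_folds = config$k_folds,
                               rng_seed = derive_seed(config$seed, 5L))
    utils::write.table(sweep, out_path("core_sweep.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    h
  })

  in_files <- unlist(inputs, use.names = FALSE)
  manifest$inputs <- data.frame(
    path = in_files, md5 = unname(tools::md5sum(in_files)),
    stringsAsFactors = FALSE)
  manifest$outputs <- list.files(config$output_dir)
  jsonlite::write_json(
    c(manifest, list(config = config[setdiff(names(config),
                                             "output_dir")])),
    out_path("manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(manifest)
}
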