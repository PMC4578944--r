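#' Configuration for the synthetic network generator
#'
#' Defines the study conditions for benchmark networks: node-type counts,
#' the size and internal density of the planted core-regulator set, the
#' in/out degree laws, and the label-noise level.  Counts default to a
#' desk-scale analogue of a condition-specific differential-expression
#' network (a few hundred targets, tens of regulators).
#'
#' The degree model has two parts.  Each mRNA draws a total in-degree from a
#' shifted geometric law (discrete exponential, minimum 1) with mean
#' `mean_in_degree_mrna`.  Each in-edge slot attaches to a planted core
#' regulator with probability `core_attachment` (at most one edge per core
#' regulator per target); remaining slots attach to background regulators
#' sampled proportionally to a two-component geometric quota mixture whose
#' mean is `mean_out_degree_tf` — a small fraction (`hub_frac`) of background
#' regulators are hubs carrying most background edges, mimicking the flat,
#' heavy-tailed out-degree of TFs.
#'
#' Expression structure: each target belongs to an up (+1) or down (-1)
#' program (probability `frac_up` of up).  Core regulators carry signed
#' weights `w` (log-normal magnitude, `weight_sdlog`) and activities `a`;
#' core edges attach preferentially (probability `program_alignment`) to
#' core regulators whose effect sign `sign(w*a)` matches the target's
#' program, so that planted labels are coherent transcriptional programs.
#'
#' @param n_tf total number of TF nodes.
#' @param n_tf_with_targets number of TFs with at least one outgoing edge.
#' @param n_mirna number of miRNA nodes.
#' @param n_mrna number of mRNA nodes.
#' @param n_core number of planted core regulators (first TFs, then miRNAs
#'   if `n_core > n_tf_with_targets`).
#' @param mean_out_degree_tf mean of the background out-degree quota mixture.
#' @param mean_in_degree_mrna mean total in-degree of mRNAs (>= 1).
#' @param core_density probability of each permitted ordered edge between
#'   two distinct planted core regulators.
#' @param noise_sd standard deviation of the Gaussian label noise; `NA`
#'   (default) means 0.25 * sum(|w|) over the planted weights.
#' @param frac_up probability that a target's program is up (+1).
#' @param seed integer seed making the generator deterministic.
#' @param core_attachment,program_alignment,hub_frac,weight_sdlog shape
#'   parameters of the degree/label model described above.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_tf = 50L, n_tf_with_targets = 20L,
                             n_mirna = 10L, n_mrna = 500L, n_core = 8L,
                             mean_out_degree_tf = 20, mean_in_degree_mrna = 4,
                             core_density = 0.8, noise_sd = NA_real_,
                             frac_up = 0.5, seed = 1L,
                             core_attachment = 0.9, program_alignment = 0.95,
                             hub_frac = 0.15, weight_sdlog = 1) {
  cfg <- list(n_tf = as.integer(n_tf),
              n_tf_with_targets = as.integer(n_tf_with_targets),
              n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              n_core = as.integer(n_core),
              mean_out_degree_tf = mean_out_degree_tf,
              mean_in_degree_mrna = mean_in_degree_mrna,
              core_density = core_density, noise_sd = noise_sd,
              frac_up = frac_up, seed = as.integer(seed),
              core_attachment = core_attachment,
              program_alignment = program_alignment,
              hub_frac = hub_frac, weight_sdlog = weight_sdlog)
  counts <- c("n_tf", "n_tf_with_targets", "n_mirna", "n_mrna", "n_core")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop("configuration error: ", f, " must be a non-negative count")
  for (f in c("core_density", "frac_up", "core_attachment",
              "program_alignment", "hub_frac"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: ", f, " must lie in [0, 1]")
  if (!is.na(cfg$noise_sd) && cfg$noise_sd < 0)
    stop("configuration error: noise_sd must be non-negative")
  if (cfg$n_tf_with_targets > cfg$n_tf)
    stop("configuration error: n_tf_with_targets exceeds n_tf")
  if (cfg$n_core > cfg$n_tf_with_targets + cfg$n_mirna)
    stop("configuration error: n_core exceeds the number of regulators")
  if (cfg$mean_in_degree_mrna < 1)
    stop("configuration error: mean_in_degree_mrna must be >= 1")
  if (cfg$mean_out_degree_tf <= 0)
    stop("configuration error: mean_out_degree_tf must be positive")
  structure(cfg, class = "synthetic_config")
}

# Node id helpers shared by the generator and tests.
synth_node_ids <- function(cfg) {
  list(tf = sprintf("TF%03d", seq_len(cfg$n_tf)),
       mirna = sprintf("miR%03d", seq_len(cfg$n_mirna)),
       mrna = sprintf("G%05d", seq_len(cfg$n_mrna)))
}

#' Generate a synthetic regulatory network with planted core regulators
#'
#' Draws a typed TF/miRNA/mRNA network under the degree and program model of
#' [synthetic_config()].  The planted core regulators are densely
#' interconnected (each permitted ordered pair with probability
#' `core_density`; miRNA-to-miRNA edges are never drawn) and attach to a
#' large share of targets, so that their mutual connectivity and reach
#' exceed those of background regulators.
#'
#' @param config a [synthetic_config()] object.
#' @return A list with elements `network` (a [grn]) and `truth`, the planted
#'   ground truth: `core_ids`, signed `weights`, `activities` (all named by
#'   regulator), and `labels` — the noiseless +1/-1 labels implied by the
#'   sign rule `sign(sum_j w_j a_j x_ij)` with zero sums resolved by a
#'   seeded fair coin.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    ids <- synth_node_ids(cfg)
    act <- ids$tf[seq_len(cfg$n_tf_with_targets)]
    reg_pool <- c(act, ids$mirna)
    core <- if (cfg$n_core > 0) reg_pool[seq_len(cfg$n_core)] else character(0)
    bg <- setdiff(reg_pool, core)
    type_of <- c(stats::setNames(rep("TF", cfg$n_tf), ids$tf),
                 stats::setNames(rep("miRNA", cfg$n_mirna), ids$mirna),
                 stats::setNames(rep("mRNA", cfg$n_mrna), ids$mrna))

    ## planted weights/activities and per-target programs
    w <- a <- numeric(0)
    if (cfg$n_core > 0) {
      w <- stats::rlnorm(cfg$n_core, 0, cfg$weight_sdlog) *
        sample(c(-1, 1), cfg$n_core, replace = TRUE)
      a <- sample(c(-1, 1), cfg$n_core, replace = TRUE)
      names(w) <- names(a) <- core
    }
    eff_sign <- sign(w * a)
    program <- sample(c(-1, 1), cfg$n_mrna, replace = TRUE,
                      prob = c(1 - cfg$frac_up, cfg$frac_up))

    ## background quota mixture: a deterministic count of hubs
    quota <- numeric(length(bg))
    if (length(bg)) {
      n_hub <- max(1L, round(cfg$hub_frac * length(bg)))
      n_hub <- min(n_hub, length(bg))
      hubs <- sample(length(bg), n_hub)
      m_lo <- 1.5
      m_hi <- max(m_lo, (length(bg) * cfg$mean_out_degree_tf -
                           (length(bg) - n_hub) * m_lo) / n_hub)
      quota <- 1 + stats::rgeom(length(bg), 1 / (m_lo - 0.5))
      quota[hubs] <- 1 + stats::rgeom(n_hub, 1 / m_hi)
    }

    from <- character(0); to <- character(0)

    ## mRNA in-edges: shifted-geometric total, core slots first
    d <- 1 + stats::rgeom(cfg$n_mrna, 1 / cfg$mean_in_degree_mrna)
    for (i in seq_len(cfg$n_mrna)) {
      n_c <- if (cfg$n_core > 0)
        stats::rbinom(1, min(d[i], cfg$n_core), cfg$core_attachment) else 0L
      if (n_c > 0) {
        matched <- which(eff_sign == program[i])
        wmag <- abs(w)
        pick <- integer(0)
        for (s in seq_len(n_c)) {
          if (stats::runif(1) < cfg$program_alignment) {
            ## a matched-program slot; if the matched set is exhausted the
            ## slot falls through to the background (never to the opposing
            ## program, which would couple labels to in-degree)
            pool <- setdiff(matched, pick)
          } else {
            pool <- setdiff(seq_len(cfg$n_core), pick)
          }
          if (!length(pool)) next
          ## influential regulators attract proportionally more targets
          pick <- c(pick, if (length(pool) == 1) pool
                          else sample(pool, 1, prob = wmag[pool]))
        }
        from <- c(from, core[pick])
        to <- c(to, rep(ids$mrna[i], length(pick)))
        n_c <- length(pick)
      }
      n_b <- d[i] - n_c
      if (n_b > 0 && length(bg)) {
        src <- sample(bg, n_b, replace = TRUE, prob = quota)
        from <- c(from, src)
        to <- c(to, rep(ids$mrna[i], n_b))
      }
    }

    ## mutual edges among the planted core (permitted categories only)
    if (cfg$n_core > 1 && cfg$core_density > 0) {
      pairs <- expand.grid(i = seq_len(cfg$n_core), j = seq_len(cfg$n_core))
      pairs <- pairs[pairs$i != pairs$j, ]
      ok <- !(type_of[core[pairs$i]] == "miRNA" &
                type_of[core[pairs$j]] == "miRNA")
      pairs <- pairs[ok & stats::runif(nrow(pairs)) < cfg$core_density, ]
      from <- c(from, core[pairs$i])
      to <- c(to, core[pairs$j])
    }

    ## light regulator-on-regulator background (TF->TF, TF->miRNA, miRNA->TF)
    if (length(reg_pool)) {
      tf_in <- stats::rpois(cfg$n_tf, 1)
      for (i in seq_len(cfg$n_tf)) {
        if (tf_in[i] == 0) next
        src <- sample(reg_pool, tf_in[i], replace = TRUE)
        src <- src[src != ids$tf[i]]
        from <- c(from, src); to <- c(to, rep(ids$tf[i], length(src)))
      }
      act_tf <- act
      if (length(act_tf) && cfg$n_mirna > 0) {
        mir_in <- stats::rpois(cfg$n_mirna, 0.5)
        for (i in seq_len(cfg$n_mirna)) {
          if (mir_in[i] == 0) next
          src <- sample(act_tf, mir_in[i], replace = TRUE)
          from <- c(from, src); to <- c(to, rep(ids$mirna[i], length(src)))
        }
      }
    }

    ## every active TF keeps at least one outgoing edge
    miss <- setdiff(act, unique(from))
    if (length(miss)) {
      from <- c(from, miss)
      to <- c(to, sample(ids$mrna, length(miss), replace = TRUE))
    }

    edges <- unique(data.frame(from = from, to = to,
                               stringsAsFactors = FALSE))
    ## inactive TFs must not regulate anything
    edges <- edges[!(edges$from %in% setdiff(ids$tf, act)), ]
    nodes <- data.frame(id = names(type_of), type = unname(type_of),
                        stringsAsFactors = FALSE)
    net <- grn(nodes, edges)

    truth <- list(core_ids = core, weights = w, activities = a,
                  labels = noiseless_labels(net, core, w, a,
                                            coin_seed = derive_seed(cfg$seed, 1L)))
    list(network = net, truth = truth)
  })
}

# Deterministic labels from the sign rule; zero sums resolved by a seeded
# fair coin.  Labelled nodes are all mRNAs plus all eligible regulators.
noiseless_labels <- function(network, core, w, a, coin_seed) {
  nodes <- grn_nodes(network)
  labelled <- c(nodes$id[nodes$type == "mRNA"], regulators(network))
  labelled <- unique(labelled)
  s <- core_score(network, core, w, a, labelled)
  lab <- sign(s)
  zero <- lab == 0
  if (any(zero)) {
    lab[zero] <- with_seed(coin_seed,
                           sample(c(-1, 1), sum(zero), replace = TRUE))
  }
  stats::setNames(lab, labelled)
}

# Sum of w_j * a_j over core regulators with a direct edge onto each target.
core_score <- function(network, core, w, a, targets) {
  s <- stats::setNames(numeric(length(targets)), targets)
  if (!length(core)) return(s)
  el <- grn_edges(network)
  el <- el[el$from %in% core & el$to %in% targets, , drop = FALSE]
  if (nrow(el)) {
    contrib <- w[el$from] * a[el$from]
    agg <- tapply(contrib, el$to, sum)
    s[names(agg)] <- as.numeric(agg)
  }
  s
}

#' Generate noisy expression labels and a differential-expression table
#'
#' Applies the planted linear sign rule `y_i = sign(sum_j w_j a_j x_ij +
#' eps_i)` with Gaussian noise `eps ~ N(0, noise_sd^2)` to every labelled
#' node (all mRNAs plus eligible regulators).  Targets with no core-regulator
#' edge have zero signal; with `noise_sd = 0` their label is a seeded fair
#' coin.  Log fold change magnitudes are drawn from an exponential law with
#' sign matching the label; FDR values are uniform on `[0, fdr_threshold/2]`
#' (every synthetic gene is a true DEG).
#'
#' @param network a [grn] from [generate_network()].
#' @param truth the planted truth from [generate_network()].
#' @param noise_sd label noise standard deviation; `NA` means
#'   `0.25 * sum(abs(weights))`.
#' @param seed integer seed.
#' @param fdr_threshold FDR level the synthetic table is generated under.
#' @return A data.frame (DEG table) with columns `gene_id`, `log2fc`,
#'   `fdr`, `direction`.
#' @export
generate_labels <- function(network, truth, noise_sd = NA_real_, seed = 1L,
                            fdr_threshold = 0.001) {
  stopifnot(inherits(network, "grn"))
  if (!all(truth$core_ids %in% grn_nodes(network)$id))
    stop("consistency error: truth regulators absent from network")
  if (is.na(noise_sd))
    noise_sd <- if (length(truth$weights)) 0.25 * sum(abs(truth$weights)) else 0
  with_seed(seed, {
    nodes <- grn_nodes(network)
    labelled <- unique(c(nodes$id[nodes$type == "mRNA"], regulators(network)))
    s <- core_score(network, truth$core_ids, truth$weights, truth$activities,
                    labelled)
    eps <- if (noise_sd > 0) stats::rnorm(length(s), 0, noise_sd) else 0
    lab <- sign(s + eps)
    zero <- lab == 0
    if (any(zero))
      lab[zero] <- sample(c(-1, 1), sum(zero), replace = TRUE)
    lfc <- stats::rexp(length(lab), rate = 1) * lab
    data.frame(gene_id = labelled,
               log2fc = lfc,
               fdr = stats::runif(length(lab), 0, fdr_threshold / 2),
               direction = lab,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Emit a ChIP-peak / TSS-annotation fixture that round-trips a network
#'
#' Writes BED-style peak records and a TSS annotation such that applying
#' [assign_peak_targets()] with the same window reconstructs exactly the
#' TF-sourced edges of the input network.  Genes are spaced far apart so no
#' peak can reach a foreign TSS.  Placement cycles through: TSS inside the
#' peak, TSS exactly `window_bp` downstream of the peak end (the inclusive
#' boundary), exactly `window_bp` upstream, and a random in-window offset.
#' One decoy peak per TF is placed at `window_bp + 1` from a non-target TSS
#' as a negative control.
#'
#' @param network a [grn].
#' @param window_bp positive window size in bp.
#' @param seed integer seed.
#' @return List with `peaks` (data.frame: `chrom`, `start` 0-based,
#'   `end` exclusive, `tf_id`) and `annotation` (data.frame: `gene_id`,
#'   `type`, `chrom`, `tss` 1-based, `strand`).
#' @export
generate_peak_fixture <- function(network, window_bp = 1000L, seed = 1L) {
  stopifnot(inherits(network, "grn"), window_bp > 0)
  window_bp <- as.integer(window_bp)
  with_seed(seed, {
    nodes <- grn_nodes(network)
    spacing <- 10L * window_bp + 2000L
    tss <- stats::setNames(spacing * seq_len(nrow(nodes)), nodes$id)
    annotation <- data.frame(gene_id = nodes$id, type = nodes$type,
                             chrom = "chrS", tss = unname(tss),
                             strand = rep(c("+", "-"),
                                          length.out = nrow(nodes)),
                             stringsAsFactors = FALSE)
    el <- grn_edges(network)
    ty <- stats::setNames(nodes$type, nodes$id)
    el <- el[ty[el$from] == "TF", , drop = FALSE]
    width <- 200L
    peaks <- NULL
    if (nrow(el)) {
      mode <- (seq_len(nrow(el)) - 1L) %% 4L
      t0 <- tss[el$to]
      start1 <- integer(nrow(el))
      ## 1-based peak start for each placement mode
      start1[mode == 0L] <- t0[mode == 0L] - width %/% 2L     # TSS inside peak
      start1[mode == 1L] <- t0[mode == 1L] - window_bp - width + 1L # TSS = end + window
      start1[mode == 2L] <- t0[mode == 2L] + window_bp         # TSS = start - window
      if (any(mode == 3L)) {
        off <- sample(seq_len(window_bp), sum(mode == 3L), replace = TRUE)
        start1[mode == 3L] <- t0[mode == 3L] - off - width %/% 2L
      }
      peaks <- data.frame(chrom = "chrS", start = start1 - 1L,
                          end = start1 - 1L + width, tf_id = el$from,
                          stringsAsFactors = FALSE)
    }
    ## negative controls at window_bp + 1
    tfs <- unique(nodes$id[nodes$type == "TF"])
    decoys <- NULL
    for (tf in tfs) {
      non_targets <- setdiff(nodes$id, c(tf, el$to[el$from == tf]))
      if (!length(non_targets)) next
      gid <- sample(non_targets, 1)
      start1 <- tss[[gid]] + window_bp + 1L
      decoys <- rbind(decoys,
                      data.frame(chrom = "chrS", start = start1 - 1L,
                                 end = start1 - 1L + width, tf_id = tf,
                                 stringsAsFactors = FALSE))
    }
    peaks <- rbind(peaks, decoys)
    rownames(peaks) <- NULL
    list(peaks = peaks, annotation = annotation)
  })
}

#' Generate a synthetic tissue expression matrix
#'
#' Tissue-specific genes have one dominant tissue whose expression outweighs
#' all others combined (SPM > 0.5 in exactly that tissue); the remaining
#' genes are near-uniform across tissues.  The near-uniform guarantee
#' `SPM <= 0.5` everywhere requires at least 5 tissues.
#'
#' @param n_genes,n_tissues matrix dimensions (`n_tissues >= 2`).
#' @param frac_specific per-gene probability of being tissue-specific.
#' @param seed integer seed.
#' @return A numeric matrix (genes x tissues) with a logical attribute
#'   `specific` marking the planted tissue-specific genes.
#' @export
generate_tissue_profiles <- function(n_genes, n_tissues = 12L,
                                     frac_specific = 0.3, seed = 1L) {
  if (n_tissues < 2)
    stop("configuration error: n_tissues must be at least 2")
  if (n_tissues < 5)
    warning("with fewer than 5 tissues near-uniform genes can exceed SPM 0.5")
  with_seed(seed, {
    specific <- stats::runif(n_genes) < frac_specific
    m <- matrix(1 + stats::runif(n_genes * n_tissues, -0.05, 0.05),
                n_genes, n_tissues)
    if (any(specific)) {
      idx <- which(specific)
      dom <- sample.int(n_tissues, length(idx), replace = TRUE)
      for (k in seq_along(idx)) {
        u <- stats::runif(n_tissues, 0.5, 1)
        u[dom[k]] <- 1.5 * sqrt(sum(u[-dom[k]]^2))
        m[idx[k], ] <- u
      }
    }
    dimnames(m) <- list(sprintf("gene%05d", seq_len(n_genes)),
                        sprintf("tissue%02d", seq_len(n_tissues)))
    attr(m, "specific") <- specific
    m
  })
}
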