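# Peak-to-TSS assignment ------------------------------------------------

ann3 <- data.frame(gene_id = c("T1", "gA", "gB"),
                   type = c("TF", "mRNA", "mRNA"),
                   chrom = c("chr1", "chr1", "chr1"),
                   tss = c(100000L, 5000L, 50000L),
                   strand = "+", stringsAsFactors = FALSE)

test_that("peak window arithmetic is inclusive and 1-based internally", {
  ## 0-based [3999, 4200) covers 1-based 4000..4200; TSS 5000 is 800 away
  pk <- data.frame(chrom = "chr1", start = 3999L, end = 4200L, tf_id = "T1")
  hit <- assign_peak_targets(pk, ann3, window_bp = 1000)
  expect_equal(hit$target_id, "gA")
  ## 1-based end 3000; gap to TSS 5000 is 2000 > 1000
  pk2 <- data.frame(chrom = "chr1", start = 2000L, end = 3000L, tf_id = "T1")
  expect_equal(nrow(assign_peak_targets(pk2, ann3, window_bp = 1000)), 0)
  ## exactly window_bp away is in; window_bp + 1 is out
  pk3 <- data.frame(chrom = "chr1", start = 3000L, end = 4000L, tf_id = "T1")
  expect_equal(assign_peak_targets(pk3, ann3, 1000)$target_id, "gA")
  pk4 <- data.frame(chrom = "chr1", start = 2999L, end = 3999L, tf_id = "T1")
  expect_equal(nrow(assign_peak_targets(pk4, ann3, 1000)), 0)
  ## different chromosome never matches
  pk5 <- data.frame(chrom = "chr2", start = 4500L, end = 5500L, tf_id = "T1")
  expect_equal(nrow(assign_peak_targets(pk5, ann3, 1000)), 0)
})

test_that("peak assignment matches a brute-force distance check", {
  set.seed(31)
  genes <- sprintf("g%02d", 1:50)
  ann <- data.frame(gene_id = c("TF1", "TF2", genes),
                    type = c("TF", "TF", rep("mRNA", 50)),
                    chrom = sample(c("chr1", "chr2"), 52, replace = TRUE),
                    tss = sample.int(100000, 52),
                    strand = "+", stringsAsFactors = FALSE)
  st <- sample.int(100000, 200)
  pk <- data.frame(chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
                   start = st, end = st + sample.int(500, 200),
                   tf_id = sample(c("TF1", "TF2"), 200, replace = TRUE))
  w <- 750
  got <- assign_peak_targets(pk, ann, w)
  ## O(peaks x genes) oracle on 1-based closed intervals
  want <- character(0)
  for (i in seq_len(nrow(pk))) for (j in seq_len(nrow(ann))) {
    if (pk$chrom[i] != ann$chrom[j]) next
    lo <- pk$start[i] + 1 - w
    hi <- pk$end[i] + w
    if (ann$tss[j] >= lo && ann$tss[j] <= hi)
      want <- c(want, paste(pk$tf_id[i], ann$gene_id[j]))
  }
  want <- setdiff(unique(want), c("TF1 TF1", "TF2 TF2")[FALSE])
  expect_setequal(paste(got$source_id, got$target_id), want)
})

test_that("widening the window never removes an edge", {
  gen <- generate_network(synthetic_config(seed = 8, n_mrna = 40, n_tf = 8,
                                           n_tf_with_targets = 5,
                                           n_mirna = 2, n_core = 3))
  fx <- generate_peak_fixture(gen$network, window_bp = 500, seed = 1)
  prev <- -1L
  for (w in c(250, 500, 1000, 2000)) {
    n <- nrow(assign_peak_targets(fx$peaks, fx$annotation, w))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("peak assignment flags unknown TFs and bad coordinates", {
  pk <- data.frame(chrom = "chr1", start = 4500L, end = 5500L,
                   tf_id = "NOTATF")
  expect_warning(res <- assign_peak_targets(pk, ann3, 1000), "absent")
  expect_equal(res$source_id, "NOTATF")
  bad <- data.frame(chrom = "chr1", start = 500L, end = 400L, tf_id = "T1")
  expect_error(assign_peak_targets(bad, ann3, 1000), "parse error")
})

# miRNA consensus --------------------------------------------------------

mk_db <- function(pairs) {
  data.frame(source_id = vapply(pairs, `[`, "", 1),
             target_id = vapply(pairs, `[`, "", 2),
             stringsAsFactors = FALSE)
}

test_that("consensus keeps pairs supported by enough databases", {
  dbs <- list(
    A = mk_db(list(c("m1", "g1"), c("m1", "g2"), c("m2", "g1"))),
    B = mk_db(list(c("m1", "g1"), c("m2", "g1"))),
    C = mk_db(list(c("m1", "g1"), c("m1", "g3"))),
    D = mk_db(list(c("m1", "g1"))))
  two <- consensus_mirna_targets(dbs, min_support = 2)
  expect_setequal(paste(two$source_id, two$target_id),
                  c("m1 g1", "m2 g1"))
  ## evidence records the supporting databases
  ev <- two$evidence[two$source_id == "m1"]
  expect_equal(ev, "A,B,C,D")
  ## support counts are set algebra: 4-way (m1 g1) only at min_support 3
  three <- consensus_mirna_targets(dbs, min_support = 3)
  expect_equal(paste(three$source_id, three$target_id), "m1 g1")
  ## raising min_support never adds an interaction
  for (ms in 1:4) {
    lo <- consensus_mirna_targets(dbs, ms)
    if (ms < 4) {
      hi <- consensus_mirna_targets(dbs, ms + 1)
      expect_true(all(paste(hi$source_id, hi$target_id) %in%
                        paste(lo$source_id, lo$target_id)))
    }
  }
  expect_error(consensus_mirna_targets(dbs[1], min_support = 2),
               "configuration error")
})

# Network construction ---------------------------------------------------

test_that("build_network counts categories and keeps isolated nodes", {
  ann <- data.frame(gene_id = c("T1", "T2", "g1", "m1", "iso"),
                    type = c("TF", "TF", "mRNA", "miRNA", "mRNA"),
                    stringsAsFactors = FALSE)
  ia <- data.frame(source_id = c("T1", "T2", "T1", "m1"),
                   target_id = c("g1", "g1", "T1", "g1"),
                   stringsAsFactors = FALSE)
  net <- build_network(ia, ann)
  expect_equal(unname(net$category_counts[c("TF->TF", "TF->mRNA",
                                            "miRNA->mRNA")]),
               c(1L, 2L, 1L))
  expect_equal(nrow(grn_nodes(net)), 5)          # isolated node retained
  ## empty interactions: isolated typed nodes, zero counts
  empty <- build_network(ia[0, ], ann)
  expect_equal(sum(empty$category_counts), 0L)
  expect_equal(nrow(grn_nodes(empty)), 5)
  ## mRNA source rejected, unannotated endpoint dropped
  bad <- data.frame(source_id = c("g1", "T1", "T9"),
                    target_id = c("T1", "g1", "g1"),
                    stringsAsFactors = FALSE)
  expect_message(net2 <- build_network(bad, ann), "rejected")
  expect_equal(sum(net2$category_counts), 1L)
})

test_that("synthetic generator bookkeeping matches build_network", {
  gen <- generate_network(synthetic_config(seed = 4, n_mrna = 150))
  rebuilt <- build_network(network_interactions_df(gen$network),
                           grn_nodes_as_annotation(gen$network))
  expect_identical(rebuilt$category_counts, gen$network$category_counts)
})

test_that("induced subnetworks are exact and idempotent", {
  gen <- generate_network(synthetic_config(seed = 6, n_mrna = 120))
  net <- gen$network
  ids <- grn_nodes(net)$id
  ## identity
  full <- induced_subnetwork(net, ids)
  expect_equal(sort(paste(grn_edges(full)$from, grn_edges(full)$to)),
               sort(paste(grn_edges(net)$from, grn_edges(net)$to)))
  ## brute-force filter on a 50% sample
  set.seed(9)
  keep <- sample(ids, length(ids) %/% 2)
  sub <- induced_subnetwork(net, keep)
  el <- grn_edges(net)
  want <- el[el$from %in% keep & el$to %in% keep, ]
  expect_setequal(paste(grn_edges(sub)$from, grn_edges(sub)$to),
                  paste(want$from, want$to))
  ## category counts stay consistent after subsetting
  expect_equal(sum(sub$category_counts), nrow(grn_edges(sub)))
  ## idempotence
  sub2 <- induced_subnetwork(sub, keep)
  expect_identical(grn_edges(sub2), grn_edges(sub))
  ## single node keeps only self-loops; empty intersection is valid
  one <- induced_subnetwork(net, grn_nodes(net)$id[1])
  expect_true(all(grn_edges(one)$from == grn_edges(one)$to))
  none <- induced_subnetwork(net, "nope")
  expect_equal(nrow(grn_nodes(none)), 0)
})

# DEG selection ----------------------------------------------------------

test_that("DEG selection combines tables and reports conflicts", {
  t1 <- data.frame(gene_id = paste0("g", 1:5), log2fc = c(1, -2, 3, 1, 2),
                   fdr = c(rep(1e-4, 5)), stringsAsFactors = FALSE)
  t2 <- data.frame(gene_id = paste0("g", 3:7),
                   log2fc = c(-3, 1, 2, 1, 1),
                   fdr = rep(1e-4, 5), stringsAsFactors = FALSE)
  u <- select_degs(list(t1, t2), 0.001, "union")
  expect_setequal(as.character(u), paste0("g", 1:7))
  expect_equal(attr(u, "direction_conflicts"), 1L)   # g3 flips sign
  i <- select_degs(list(t1, t2), 0.001, "intersection")
  expect_setequal(as.character(i), paste0("g", 3:5))
  ## disjoint passing sets intersect to nothing
  t3 <- data.frame(gene_id = "g9", log2fc = 1, fdr = 1e-4)
  expect_length(select_degs(list(t1, t3), 0.001, "intersection"), 0)
  expect_error(select_degs(list(t1), 0), "configuration error")
  expect_error(select_degs(list(t1), 1.5), "configuration error")
})

# Degree statistics ------------------------------------------------------

test_that("degree stats summarize each category over active nodes", {
  star <- mk_grn(data.frame(from = rep("T1", 10), to = paste0("g", 1:10)),
                 tf = "T1", mrna = paste0("g", 1:10))
  st <- degree_stats(star)
  out_row <- st[st$category == "TF->mRNA" & st$side == "out", ]
  expect_equal(c(out_row$min, out_row$max, out_row$mean, out_row$median),
               rep(10, 4))
  in_row <- st[st$category == "TF->mRNA" & st$side == "in", ]
  expect_equal(c(in_row$min, in_row$max, in_row$mean, in_row$median),
               rep(1, 4))
  ## empty network: no rows
  empty <- mk_grn(data.frame(from = character(0), to = character(0)),
                  tf = "T1", mrna = "g1")
  expect_equal(nrow(degree_stats(empty)), 0)
})

test_that("degree stats equal a brute-force recount on synthetic data", {
  gen <- generate_network(synthetic_config(seed = 13, n_mrna = 150))
  st <- degree_stats(gen$network)
  el <- grn_edges(gen$network)
  ty <- stats::setNames(grn_nodes(gen$network)$type,
                        grn_nodes(gen$network)$id)
  key <- paste0(ty[el$from], "->", ty[el$to])
  for (r in seq_len(nrow(st))) {
    sub <- el[key == st$category[r], ]
    d <- if (st$side[r] == "out") table(sub$from) else table(sub$to)
    expect_equal(st$min[r], min(d))
    expect_equal(st$max[r], max(d))
    expect_equal(st$mean[r], mean(d))
    expect_equal(st$median[r], stats::median(as.numeric(d)))
    expect_gte(st$min[r], 1)
  }
})

# Exponential fits -------------------------------------------------------

test_that("exponential fit is exact on geometric counts and flat on uniform", {
  ## frequencies c * q^k are log-linear by construction
  degs <- rep(1:8, times = round(1024 * 0.5^(1:8)))
  fit <- fit_exponential(degs)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$rate, log(2), tolerance = 1e-6)
  ## uniform counts: slope about zero
  flat <- rep(1:10, each = 20)
  expect_lt(abs(fit_exponential(flat)$rate), 1e-8)
  ## geometric sample at n = 10000 fits well
  set.seed(5)
  smp <- stats::rgeom(10000, 0.2) + 1
  expect_gt(fit_exponential(smp)$r_squared, 0.9)
  expect_error(fit_exponential(c(1, 1, 2)), "fit error")
})

# Growth curves ----------------------------------------------------------

test_that("growth curves accumulate unique edges and extrapolate", {
  mkb <- function(lo, hi) data.frame(
    source_id = "T1", target_id = paste0("g", lo:hi),
    stringsAsFactors = FALSE)
  ## each batch adds exactly 100 new edges
  batches <- lapply(0:4, function(i) mkb(i * 100 + 1, (i + 1) * 100))
  gc <- growth_curve(batches)
  expect_equal(gc$series$cum_edges, seq(100, 500, by = 100))
  expect_equal(gc$slope, 100)
  expect_equal(gc$extrapolate(50), gc$intercept + 5000)
  ## fully overlapping batches saturate
  same <- replicate(5, mkb(1, 100), simplify = FALSE)
  gs <- growth_curve(same)
  expect_equal(unique(gs$series$cum_edges), 100)
  expect_equal(gs$slope, 0)
})

test_that("growth-curve OLS recovers a planted slope under noise", {
  set.seed(77)
  s <- 40
  pool <- sprintf("e%05d", 1:100000)
  batches <- lapply(1:50, function(i) {
    k <- max(1, round(s + stats::rnorm(1, 0, 4)))
    data.frame(source_id = "T1",
               target_id = pool[((i - 1) * s + 1):((i - 1) * s + k)],
               stringsAsFactors = FALSE)
  })
  fit <- growth_curve(batches)
  expect_lt(abs(fit$slope - s) / s, 0.05)
})

# SPM and tissue merging -------------------------------------------------

test_that("SPM is the cosine against each tissue axis", {
  one <- c(0, 0, 5, 0)
  expect_equal(compute_spm(one), c(0, 0, 1, 0))
  unif <- rep(2, 9)
  expect_equal(compute_spm(unif), rep(1 / 3, 9))
  ## normalization invariant over random profiles
  set.seed(2)
  for (i in 1:20) {
    x <- stats::runif(sample(2:15, 1))
    expect_equal(sum(compute_spm(x)^2), 1, tolerance = 1e-12)
    expect_true(all(compute_spm(x) >= 0 & compute_spm(x) <= 1))
  }
  expect_error(compute_spm(c(0, 0, 0)), "all-zero")
})

test_that("tissue merging averages member tissues", {
  m <- matrix(stats::runif(40), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("t", 1:8)))
  ident <- stats::setNames(paste0("t", 1:8), paste0("t", 1:8))
  expect_equal(unname(merge_tissues(m, ident)), unname(m))
  ## two identical tissues merge to either
  m2 <- m; m2[, 2] <- m2[, 1]
  grp <- stats::setNames(c("a", "a", paste0("t", 3:8)), paste0("t", 1:8))
  merged <- merge_tissues(m2, grp)
  expect_equal(merged[, "a"], m2[, 1])
  ## 84 -> 12 grouping: dimensions and per-group means
  big <- matrix(stats::runif(84 * 10), 10, 84,
                dimnames = list(paste0("g", 1:10), paste0("t", 1:84)))
  grouping <- stats::setNames(paste0("it", rep(1:12, each = 7)),
                              paste0("t", 1:84))
  got <- merge_tissues(big, grouping)
  expect_equal(dim(got), c(10, 12))
  expect_equal(got[, "it3"], rowMeans(big[, paste0("t", 15:21)]))
  spm12 <- compute_spm(got)
  expect_equal(unname(rowSums(spm12^2)), rep(1, 10))
})
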