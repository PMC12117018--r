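# Single-cell layer: barcode resolution, metacell graph, distances,
# modules, signatures, pseudobulk DE and breadth.

test_that("resolve_multibarcode_cells applies the doublet and multi-integration rules", {
  df <- data.frame(
    cell_id = c("c1", "c2", "c2", paste0("m", rep(1:5, each = 2))),
    barcode = c("AAA", "AAA", "BBB", rep(c("AAA", "CCC"), 5)),
    reads = c(10, 5, 4, rep(c(50, 8), 5)),
    stringsAsFactors = FALSE)
  res <- resolve_multibarcode_cells(df)
  a <- res$assignments
  # unique >= 2-barcode pattern in one cell: doublet, blacklisted
  expect_identical(a$status[a$cell_id == "c2"], "doublet_blacklisted")
  expect_true(is.na(a$resolved_barcode[a$cell_id == "c2"]))
  # the same pattern in 5 cells: multiple integration, one representative
  mi <- a[grepl("^m", a$cell_id), ]
  expect_true(all(mi$status == "multi_integration_resolved"))
  expect_true(all(mi$resolved_barcode == "AAA"))  # highest aggregate reads
  # single-barcode cells unchanged
  expect_identical(a$status[a$cell_id == "c1"], "single")
  expect_identical(a$resolved_barcode[a$cell_id == "c1"], "AAA")
  expect_equal(res$multibarcode_rate, 6 / 7)

  # lexicographic tie-break on equal read totals
  df2 <- data.frame(cell_id = rep(c("x1", "x2"), each = 2),
                    barcode = rep(c("TTT", "GGG"), 2),
                    reads = rep(5, 4), stringsAsFactors = FALSE)
  res2 <- resolve_multibarcode_cells(df2)
  expect_true(all(res2$assignments$resolved_barcode == "GGG"))
})

test_that("planted rates are recovered by the resolver on fixtures", {
  clones <- data.frame(barcode = replicate(15, paste(sample(c("A", "C", "G",
                                                              "T"), 27, TRUE),
                                                     collapse = "")),
                       fate = c("propagating", rep("transient", 10),
                                rep("emerging", 4)),
                       stringsAsFactors = FALSE)
  fx <- simulate_single_cell_fixture(clones, n_cells = 1500,
                                     doublet_rate = 0.06,
                                     multi_integration_rate = 0.3,
                                     n_metacells = 15, n_genes = 100,
                                     seed = 22)
  res <- resolve_multibarcode_cells(fx$cell_barcodes)
  a <- res$assignments
  # every planted doublet that is not also in a multi-integration clone
  # pattern is blacklisted
  mi_clones <- fx$truth$multi_integration_clones
  pure_doublets <- setdiff(fx$truth$doublet_cells,
                           fx$cells$cell_id[fx$cells$clone %in% mi_clones])
  expect_true(all(a$status[a$cell_id %in% pure_doublets] ==
                    "doublet_blacklisted"))
  # multi-integration carriers resolve to a single barcode per clone
  for (cl in mi_clones) {
    carriers <- setdiff(fx$cells$cell_id[fx$cells$clone == cl],
                        fx$truth$doublet_cells)
    resolved <- unique(a$resolved_barcode[a$cell_id %in% carriers])
    expect_length(resolved, 1L)
  }
  # observed multibarcode rate matches the planted construction
  planted <- length(union(fx$truth$doublet_cells,
                          fx$cells$cell_id[fx$cells$clone %in% mi_clones]))
  expect_equal(res$multibarcode_rate, planted / 1500)
})

test_that("k-NN graph construction is complete at small n, recovers chains, and is deterministic", {
  s4 <- random_similarity(4)
  g4 <- metacell_graph(s4, k = 3)
  expect_identical(nrow(g4$edges), 6L)  # complete graph on 4 nodes

  # chain-structured similarity recovered at k = 1 (nearest neighbor only)
  n <- 8
  d <- abs(outer(1:n, 1:n, "-"))
  s <- exp(-d)
  dimnames(s) <- list(paste0("mc", 1:n), paste0("mc", 1:n))
  g <- metacell_graph(s, k = 1)
  chain <- cbind(paste0("mc", 1:(n - 1)), paste0("mc", 2:n))
  chain <- t(apply(chain, 1, sort))
  got <- g$edges[order(g$edges[, 1], g$edges[, 2]), ]
  want <- chain[order(chain[, 1], chain[, 2]), ]
  expect_identical(got, want)

  set.seed(23)
  s2 <- random_similarity(12)
  expect_identical(metacell_graph(s2, k = 3)$edges,
                   metacell_graph(s2, k = 3)$edges)
  expect_error(metacell_graph(matrix(1, 1, 1)), "at least 2")
  expect_error(metacell_graph(matrix(runif(16), 4, 4)), "symmetric")
})

test_that("find_roots requires at least 3 primary cells per metacell", {
  n <- 20
  d <- abs(outer(1:n, 1:n, "-"))
  s <- exp(-d / 2)
  dimnames(s) <- list(paste0("mc", 1:n), paste0("mc", 1:n))
  # clone X: 3 primary cells in mc1..mc8, 2 in mc9
  mem <- data.frame(
    cell_id = sprintf("c%03d", 1:26),
    clone = "X",
    passage = "P",
    metacell = paste0("mc", c(rep(1:8, each = 3), 9, 9)),
    stringsAsFactors = FALSE)
  g <- metacell_graph(s, k = 3, membership = mem)
  roots <- find_roots(g, "X")
  expect_setequal(roots, paste0("mc", 1:8))  # exactly the 8 planted roots
  expect_false("mc9" %in% roots)
  expect_warning(find_roots(g, "Y"), "no root")
})

test_that("assign_distances is breadth-first distance from the nearest root", {
  s <- exp(-abs(outer(1:3, 1:3, "-")))
  dimnames(s) <- list(c("A", "B", "C"), c("A", "B", "C"))
  g <- metacell_graph(s, k = 1)
  d <- assign_distances(g, "A")
  expect_identical(unname(d[c("A", "B", "C")]), c(0L, 1L, 2L))
  # all nodes roots: all distances zero
  expect_true(all(assign_distances(g, c("A", "B", "C")) == 0L))
  expect_error(assign_distances(g, character(0)), "nonempty")

  # random graphs agree with brute-force shortest paths minimized over roots
  set.seed(24)
  for (r in 1:20) {
    n <- sample(6:15, 1)
    g2 <- metacell_graph(random_similarity(n), k = sample(2:3, 1))
    roots <- sample(g2$nodes, sample(1:3, 1))
    got <- assign_distances(g2, roots)
    sp <- oracle_shortest_paths(graph_adjacency(g2))
    want <- apply(sp[match(roots, g2$nodes), , drop = FALSE], 2, min)
    want <- ifelse(is.finite(want), as.integer(want), NA_integer_)
    expect_identical(as.integer(got), want)
  }
})

test_that("gene modules recover planted anticorrelated blocks", {
  set.seed(25)
  n_mc <- 30
  base <- runif(n_mc)
  expr <- rbind(
    t(replicate(10, 5 * base + rnorm(n_mc, 0, 0.05))),
    t(replicate(10, 5 * (1 - base) + rnorm(n_mc, 0, 0.05))))
  rownames(expr) <- sprintf("g%02d", 1:20)
  colnames(expr) <- paste0("mc", 1:n_mc)
  mods <- cluster_gene_modules(expr, 2, min_mean = 0, var_quantile = 0,
                               seed = 26)
  groups <- split(names(mods$assignment), mods$assignment)
  expect_setequal(vapply(groups, length, integer(1)), c(10L, 10L))
  expect_true(all(sprintf("g%02d", 1:10) %in% groups[[mods$assignment["g01"]]]))

  # same seed, same partition
  mods2 <- cluster_gene_modules(expr, 2, min_mean = 0, var_quantile = 0,
                                seed = 26)
  expect_identical(mods$assignment, mods2$assignment)

  # one module per gene when n_modules equals the gene count
  singletons <- cluster_gene_modules(expr, 20, min_mean = 0,
                                     var_quantile = 0, seed = 27)
  expect_true(all(lengths(singletons$modules) == 1L))

  expect_error(cluster_gene_modules(expr, 1), "at least 2")
})

test_that("module enrichment over distance is flat for uniform expression and tracks planted gradients", {
  n_mc <- 12
  dist <- stats::setNames(0:(n_mc - 1), paste0("mc", 1:n_mc))
  uni <- matrix(3, 6, n_mc,
                dimnames = list(paste0("u", 1:6), paste0("mc", 1:n_mc)))
  enr <- module_enrichment_by_distance(uni, list(M = paste0("u", 1:6)), dist)
  expect_true(all(abs(enr$log2_enrichment) < 1e-9))

  grad <- matrix(rep(1 + 0:(n_mc - 1), each = 4), 4, n_mc, byrow = FALSE,
                 dimnames = list(paste0("g", 1:4), paste0("mc", 1:n_mc)))
  enr2 <- module_enrichment_by_distance(grad, list(up = paste0("g", 1:4)),
                                        dist)
  expect_true(all(diff(enr2$log2_enrichment[order(enr2$distance)]) > 0))
})

test_that("the planted epithelial-mesenchymal gradient is recovered through roots and distances", {
  clones <- data.frame(barcode = replicate(10, paste(sample(c("A", "C", "G",
                                                              "T"), 27, TRUE),
                                                     collapse = "")),
                       fate = c("propagating", rep("transient", 7),
                                rep("emerging", 2)),
                       stringsAsFactors = FALSE)
  fx <- simulate_single_cell_fixture(clones, n_cells = 1200,
                                     doublet_rate = 0,
                                     multi_integration_rate = 0,
                                     n_metacells = 24, n_genes = 150,
                                     n_roots = 3, seed = 28)
  g <- metacell_graph(fx$similarity, k = 3, membership = fx$cells,
                      expression = fx$expression)
  roots <- find_roots(g, fx$truth$dominant_clone)
  expect_setequal(roots, paste0("mc", 1:3))
  dist <- assign_distances(g, roots)
  expect_false(anyNA(dist))
  mods <- list(epithelial = fx$truth$epithelial_genes,
               mesenchymal = fx$truth$mesenchymal_genes)
  enr <- module_enrichment_by_distance(g, mods, dist)
  epi <- enr[enr$module == "epithelial", ]
  mes <- enr[enr$module == "mesenchymal", ]
  epi <- epi[order(epi$distance), ]
  mes <- mes[order(mes$distance), ]
  # epithelial enrichment decreases and mesenchymal increases overall
  expect_lt(stats::cor(epi$distance, epi$log2_enrichment), -0.8)
  expect_gt(stats::cor(mes$distance, mes$log2_enrichment), 0.8)
  # the two modules cross: epithelial starts above, ends below mesenchymal
  expect_gt(epi$log2_enrichment[1], mes$log2_enrichment[1])
  expect_lt(epi$log2_enrichment[nrow(epi)],
            mes$log2_enrichment[nrow(mes)])
})

test_that("signature_ternary returns proportions over signature UMIs only", {
  sigs <- list(basal = paste0("b", 1:3), lp = paste0("l", 1:3),
               ml = paste0("m", 1:4))
  umis <- stats::setNames(c(10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 99),
                          c(sigs$basal, sigs$lp, sigs$ml, "other"))
  expect_equal(unname(signature_ternary(umis, sigs)), c(0.3, 0.3, 0.4))
  # all UMIs in ML genes
  ml_only <- stats::setNames(c(0, 0, 0, 5, 7, 0, 0, 0, 0, 0),
                             c(sigs$basal, sigs$ml, sigs$lp))
  expect_equal(unname(signature_ternary(ml_only, sigs)), c(0, 0, 1))
  # invariant to uniform UMI scaling
  expect_equal(signature_ternary(umis * 17, sigs),
               signature_ternary(umis, sigs))
  expect_error(signature_ternary(stats::setNames(0, "b1"), sigs),
               "undefined")
})

test_that("pseudobulk DE applies the 50%-cells and 0.1-UMI filters and finds planted genes", {
  set.seed(29)
  ng <- 50
  ncell <- 40
  genes <- sprintf("g%02d", 1:ng)
  lam <- runif(ng, 2, 6)
  a <- matrix(rpois(ng * ncell, lam), ng, ncell, dimnames = list(genes, NULL))
  b <- matrix(rpois(ng * ncell, lam), ng, ncell, dimnames = list(genes, NULL))
  # g01 strongly up in A; g02 expressed in under half of A's cells;
  # g03 present but at mean UMI below 0.1 in both groups
  a["g01", ] <- rpois(ncell, 30)
  a["g02", ] <- 0
  a["g02", 1:15] <- rpois(15, 8)
  b["g02", ] <- 0
  a["g03", ] <- rbinom(ncell, 1, 0.04)
  b["g03", ] <- 0
  de <- pseudobulk_de(a, b, umi_floor = 0, seed = 30)
  expect_false("g02" %in% de$gene)  # below 50% of enriched-group cells
  expect_false("g03" %in% de$gene)  # below 0.1 mean UMI
  expect_true("g01" %in% de$gene)
  expect_lt(de$q[de$gene == "g01"], 0.05)
  expect_identical(de$enriched_group[de$gene == "g01"], "A")
  expect_gt(de$log2_enrichment[de$gene == "g01"], 0)
  expect_error(pseudobulk_de(a[, 1, drop = FALSE], b, umi_floor = 0),
               "at least 2 cells")
})

test_that("bimodal_threshold finds the valley between two modes and shifts with translation", {
  set.seed(31)
  x <- c(rnorm(1000, 0, 0.05), rnorm(1000, 0.3, 0.05))
  thr <- bimodal_threshold(x)
  expect_lt(abs(as.numeric(thr) - 0.15), 0.02)
  # translation equivariance
  thr2 <- bimodal_threshold(x + 1)
  expect_lt(abs(as.numeric(thr2) - as.numeric(thr) - 1), 0.01)
  expect_error(bimodal_threshold(rnorm(1000)), "unimodal")
  expect_error(bimodal_threshold(rnorm(50)), "at least 100")
})

test_that("replicate_state_correlation is 1 for identical fractions and near 0 for independent ones", {
  set.seed(32)
  f <- prop.table(runif(50))
  expect_equal(replicate_state_correlation(f, f), 1, tolerance = 1e-9)
  noisy <- prop.table(pmax(0, f + rnorm(50, 0, 0.1 * sd(f))))
  expect_gt(replicate_state_correlation(f, noisy), 0.9)
  r0 <- replicate_state_correlation(prop.table(runif(200)),
                                    prop.table(runif(200)))
  expect_lt(abs(r0), 0.05)
  expect_warning(replicate_state_correlation(rep(0.2, 5), f[1:5]),
                 "zero-variance")
})

test_that("clone_state_breadth spans and entropy separate dominant from transient clones", {
  clones <- data.frame(barcode = replicate(8, paste(sample(c("A", "C", "G",
                                                             "T"), 27, TRUE),
                                                    collapse = "")),
                       fate = c("propagating", rep("transient", 7)),
                       stringsAsFactors = FALSE)
  fx <- simulate_single_cell_fixture(clones, n_cells = 1000,
                                     doublet_rate = 0,
                                     multi_integration_rate = 0,
                                     n_metacells = 16, n_genes = 100,
                                     seed = 33)
  g <- metacell_graph(fx$similarity, k = 3, membership = fx$cells,
                      expression = fx$expression)
  dom <- fx$truth$dominant_clone
  bd <- clone_state_breadth(g, dom)
  expect_equal(bd$fraction, 1)  # spans 100% of metacells
  for (tr in clones$barcode[clones$fate == "transient"]) {
    bt <- clone_state_breadth(g, tr)
    expect_lt(bt$entropy, bd$entropy)
  }
  # absent clone has zero breadth; single-metacell clone has zero entropy
  expect_equal(clone_state_breadth(g, "absent")$n_metacells, 0L)
  g1 <- metacell_graph(fx$similarity, k = 3,
                       membership = data.frame(cell_id = "c", clone = "z",
                                               passage = "P",
                                               metacell = "mc1"))
  expect_equal(clone_state_breadth(g1, "z")$entropy, 0)
})
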