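# Single-cell layer: barcode-cell assignment resolution, the metacell
# similarity graph, transcriptional distances from clone roots, gene
# modules and their enrichment over distance, signature projections,
# pseudobulk differential expression and clone state breadth.

#' Resolve cells carrying multiple barcodes
#'
#' A pattern of >= 2 barcodes seen in exactly one cell is most likely a
#' cell doublet from the droplet workflow: the cell is blacklisted. The
#' same >= 2-barcode pattern recurring in multiple cells indicates
#' multiple lentiviral integrations in one clone of origin: all carriers
#' are kept and resolved to a single representative barcode (highest
#' aggregate read count across the dataset, ties broken lexicographically)
#' so the clone is not counted more than once.
#'
#' @param assignments data.frame with columns `cell_id`, `barcode` and
#'   optionally `reads` (one row per cell-barcode link).
#' @return A list with `assignments` (one row per cell: `cell_id`,
#'   `barcodes` (the `+`-joined pattern), `status` in
#'   single/doublet_blacklisted/multi_integration_resolved,
#'   `resolved_barcode`) and `multibarcode_rate` (fraction of cells with
#'   >= 2 barcodes).
#' @export
resolve_multibarcode_cells <- function(assignments) {
  stopifnot(all(c("cell_id", "barcode") %in% names(assignments)))
  reads <- if ("reads" %in% names(assignments)) assignments$reads
           else rep(1, nrow(assignments))
  bc_reads <- tapply(reads, assignments$barcode, sum)
  pat <- vapply(split(assignments$barcode, assignments$cell_id),
                function(b) paste(sort(unique(b)), collapse = "+"),
                character(1))
  cell_ids <- names(pat)
  multi <- grepl("+", pat, fixed = TRUE)
  pat_cells <- table(pat[multi])
  status <- rep("single", length(pat))
  resolved <- ifelse(multi, NA_character_, pat)
  for (p in names(pat_cells)) {
    carriers <- which(pat == p)
    if (pat_cells[[p]] == 1L) {
      status[carriers] <- "doublet_blacklisted"
    } else {
      status[carriers] <- "multi_integration_resolved"
      bcs <- strsplit(p, "+", fixed = TRUE)[[1]]
      tot <- bc_reads[bcs]
      tot[is.na(tot)] <- 0
      rep_bc <- bcs[order(-tot, bcs)][1]
      resolved[carriers] <- rep_bc
    }
  }
  list(assignments = data.frame(cell_id = cell_ids, barcodes = unname(pat),
                                status = status,
                                resolved_barcode = unname(resolved),
                                row.names = NULL, stringsAsFactors = FALSE),
       multibarcode_rate = mean(multi))
}

#' Build the metacell k-nearest-neighbor similarity graph
#'
#' Each metacell is connected to its `k` most transcriptionally similar
#' metacells (undirected union of the directed top-k lists; ties broken by
#' node id so construction is deterministic). The diagonal of the
#' similarity matrix is ignored. When fewer than `k` other nodes exist,
#' all of them are connected.
#'
#' @param similarity square symmetric similarity matrix with metacell ids
#'   as dimnames (integer ids are assigned when absent).
#' @param k neighbors per node (default 3).
#' @param membership optional data.frame of cells with columns `cell_id`,
#'   `clone`, `passage`, `metacell`.
#' @param expression optional genes-by-metacells matrix of mean UMI.
#' @return An object of class `MetacellGraph` with `graph` (igraph),
#'   `nodes`, `edges` (two-column character matrix), `k`, `membership`,
#'   `expression`.
#' @export
metacell_graph <- function(similarity, k = 3, membership = NULL,
                           expression = NULL) {
  stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity))
  n <- nrow(similarity)
  if (n < 2L) {
    stop("need at least 2 metacells")
  }
  if (!isSymmetric(unname(similarity), tol = 1e-8)) {
    stop("similarity matrix must be symmetric")
  }
  ids <- rownames(similarity) %||% as.character(seq_len(n))
  kk <- min(k, n - 1L)
  edges <- matrix(character(0), ncol = 2)
  for (i in seq_len(n)) {
    s <- similarity[i, ]
    s[i] <- -Inf
    nb <- order(-s, seq_len(n))[seq_len(kk)]
    edges <- rbind(edges, cbind(ids[i], ids[nb]))
  }
  und <- unique(t(apply(edges, 1, sort)))
  g <- igraph::graph_from_edgelist(und, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(ids, igraph::V(g)$name)),
                            name = setdiff(ids, igraph::V(g)$name))
  structure(list(graph = g, nodes = ids, edges = und, k = k,
                 membership = membership, expression = expression),
            class = "MetacellGraph")
}

#' @export
print.MetacellGraph <- function(x, ...) {
  cat(sprintf("MetacellGraph: %d metacells, %d edges (k = %d)%s%s\n",
              length(x$nodes), nrow(x$edges), x$k,
              if (!is.null(x$membership)) sprintf(", %d cells",
                                                  nrow(x$membership)) else "",
              if (!is.null(x$expression)) sprintf(", %d genes",
                                                  nrow(x$expression)) else ""))
  invisible(x)
}

#' Find the root metacells of a clone
#'
#' Roots (transcriptional distance 0) are the metacells containing at
#' least `min_primary_cells` of the clone's primary-xenograft cells - the
#' cell states representing the clone's early transcriptional profile.
#'
#' @param graph a `MetacellGraph` with cell membership.
#' @param clone clone (barcode) identifier.
#' @param min_primary_cells minimum primary cells per root metacell.
#' @param primary_passages passage label(s) counted as primary.
#' @return Character vector of root metacell ids; empty (with a warning)
#'   when the clone has no root, in which case distance analysis is
#'   skipped for that clone.
#' @export
find_roots <- function(graph, clone, min_primary_cells = 3,
                       primary_passages = "P") {
  stopifnot(inherits(graph, "MetacellGraph"))
  mem <- graph$membership
  if (is.null(mem)) {
    stop("graph has no cell membership")
  }
  sel <- mem$clone == clone & mem$passage %in% primary_passages
  counts <- table(factor(as.character(mem$metacell[sel]),
                         levels = graph$nodes))
  roots <- names(counts)[counts >= min_primary_cells]
  if (!length(roots)) {
    warning(sprintf("clone %s has no root metacell; distance analysis skipped",
                    clone))
  }
  roots
}

#' Assign transcriptional distances from the nearest root
#'
#' Breadth-first graph distance from each metacell to the nearest root on
#' the k-NN similarity graph. Roots have distance 0; metacells unreachable
#' from any root get NA and are listed in the `unreachable` attribute.
#'
#' @param graph a `MetacellGraph`.
#' @param roots character vector of root metacell ids (nonempty).
#' @return Named integer vector of distances over all metacells.
#' @export
assign_distances <- function(graph, roots) {
  stopifnot(inherits(graph, "MetacellGraph"))
  if (!length(roots)) {
    stop("roots must be nonempty")
  }
  roots <- as.character(roots)
  stopifnot(all(roots %in% graph$nodes))
  dmat <- igraph::distances(graph$graph, v = roots, to = graph$nodes)
  d <- apply(dmat, 2, min)
  d <- d[graph$nodes]
  out <- ifelse(is.finite(d), as.integer(d), NA_integer_)
  names(out) <- graph$nodes
  attr(out, "unreachable") <- graph$nodes[is.na(out)]
  out
}

#' Cluster genes into modules
#'
#' Selects strong (mean expression above `min_mean`) and highly variable
#' (log-expression variance in the top `1 - var_quantile` among strong
#' genes) genes, computes the gene-gene correlation matrix of
#' log-expression across metacells, and partitions the correlation
#' profiles with k-means (seeded, multiple starts) into disjoint modules.
#'
#' @param expression genes-by-metacells matrix of mean UMI.
#' @param n_modules number of modules (>= 2).
#' @param min_mean strong-gene threshold on mean expression.
#' @param var_quantile keep genes with log-variance above this quantile of
#'   the strong genes (0 keeps all strong genes).
#' @param seed integer seed for the k-means starts.
#' @return A `GeneModuleSet`: `modules` (named list of gene vectors),
#'   `assignment` (named integer vector), `genes_used`.
#' @export
cluster_gene_modules <- function(expression, n_modules, min_mean = 0.1,
                                 var_quantile = 0.5, seed = NULL) {
  if (n_modules < 2L) {
    stop("n_modules must be at least 2")
  }
  lg <- log2(1 + expression)
  strong <- rowMeans(expression) >= min_mean
  v <- apply(lg, 1, stats::var)
  thr <- stats::quantile(v[strong], var_quantile, names = FALSE)
  keep <- strong & v >= thr & v > 0
  genes <- rownames(expression)[keep]
  if (length(genes) < n_modules) {
    stop("fewer filtered genes than requested modules")
  }
  cors <- suppressWarnings(stats::cor(t(lg[keep, , drop = FALSE])))
  cors[is.na(cors)] <- 0
  if (n_modules == length(genes)) {
    assignment <- stats::setNames(seq_along(genes), genes)
  } else {
    cl <- with_seed(seed,
                    stats::kmeans(cors, centers = n_modules, nstart = 10,
                                  iter.max = 100))
    assignment <- stats::setNames(cl$cluster, genes)
  }
  modules <- split(genes, paste0("GM", assignment))
  structure(list(modules = modules, assignment = assignment,
                 genes_used = genes),
            class = "GeneModuleSet")
}

#' @export
print.GeneModuleSet <- function(x, ...) {
  cat(sprintf("GeneModuleSet: %d modules over %d genes\n",
              length(x$modules), length(x$genes_used)))
  invisible(x)
}

#' Gene-module enrichment over transcriptional distance
#'
#' For each module and distance, the fold enrichment is the mean module
#' expression over metacells at that distance relative to the mean over
#' all metacells, reported as log2. The point estimate is the log2 ratio
#' of means; the standard error comes from the per-metacell log2 ratios at
#' that distance. Distances with no metacell are omitted.
#'
#' @param graph a `MetacellGraph` with expression, or a genes-by-metacells
#'   matrix.
#' @param modules a `GeneModuleSet` or named list of gene vectors.
#' @param distances named distance vector from [assign_distances()].
#' @param baseline `"arithmetic"` (default) or `"geometric"` mean over all
#'   metacells as the enrichment denominator.
#' @return data.frame with `module`, `distance`, `log2_enrichment`, `se`,
#'   `n_metacells`.
#' @export
module_enrichment_by_distance <- function(graph, modules, distances,
                                          baseline = c("arithmetic",
                                                       "geometric")) {
  baseline <- match.arg(baseline)
  expr <- if (inherits(graph, "MetacellGraph")) graph$expression else graph
  if (is.null(expr)) {
    stop("no expression available")
  }
  if (inherits(modules, "GeneModuleSet")) {
    modules <- modules$modules
  }
  dd <- distances[colnames(expr)]
  eps <- 1e-12
  out <- list()
  for (m in names(modules)) {
    genes <- intersect(modules[[m]], rownames(expr))
    score <- colMeans(expr[genes, , drop = FALSE])
    ref <- if (baseline == "arithmetic") mean(score)
           else exp(mean(log(score + eps)))
    for (d in sort(unique(dd[!is.na(dd)]))) {
      at <- which(!is.na(dd) & dd == d)
      est <- log2((mean(score[at]) + eps) / (ref + eps))
      percell <- log2((score[at] + eps) / (ref + eps))
      out[[length(out) + 1L]] <- data.frame(
        module = m, distance = d, log2_enrichment = est,
        se = if (length(at) > 1L) stats::sd(percell) / sqrt(length(at))
             else NA_real_,
        n_metacells = length(at), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Ternary projection of a clone onto epithelial signatures
#'
#' The proportion of a clone's signature-gene UMIs falling in each of the
#' basal, luminal-progenitor (LP) and mature-luminal (ML) normal mammary
#' epithelial gene lists. Proportions are over signature-gene UMIs only
#' and sum to one; they are invariant to uniform UMI scaling.
#'
#' @param clone_umis named numeric vector of per-gene total UMIs for the
#'   clone.
#' @param sigs list with nonempty gene vectors `basal`, `lp`, `ml`
#'   (overlapping genes should already have been removed).
#' @return Named numeric vector `c(basal, lp, ml)` summing to 1.
#' @export
signature_ternary <- function(clone_umis, sigs) {
  stopifnot(all(c("basal", "lp", "ml") %in% names(sigs)),
            all(lengths(sigs[c("basal", "lp", "ml")]) > 0))
  tot <- vapply(c("basal", "lp", "ml"), function(s) {
    sum(clone_umis[intersect(sigs[[s]], names(clone_umis))])
  }, numeric(1))
  if (sum(tot) <= 0) {
    stop("undefined projection: clone has no signature-gene UMIs")
  }
  tot / sum(tot)
}

# Multivariate-hypergeometric downsampling of one cell's counts to a
# target total.
downsample_counts <- function(v, target) {
  tot <- sum(v)
  if (tot <= target) {
    return(v)
  }
  idx <- sample.int(tot, target)
  cum <- cumsum(v)
  gene <- findInterval(idx - 0.5, c(0, cum))
  tabulate(gene, nbins = length(v))
}

#' Pseudobulk differential expression between two cell groups
#'
#' Cells are first downsampled to a common per-cell UMI total (the minimum
#' across both groups, after excluding cells below `umi_floor` UMIs), the
#' groups are pooled into pseudobulk profiles normalized to equal totals,
#' and genes are kept when, in the group where they are enriched, they are
#' expressed in at least `min_frac_cells` of cells and average at least
#' `min_mean_umi` UMI per cell. Per-gene p-values come from the
#' Mann-Whitney rank-sum test on the per-cell downsampled counts and are
#' corrected by the Benjamini-Hochberg FDR method.
#'
#' @param cells_a,cells_b genes-by-cells UMI count matrices with matching
#'   rownames.
#' @param min_frac_cells expressed-cell fraction filter in the enriched
#'   group.
#' @param min_mean_umi mean-UMI filter in the enriched group.
#' @param umi_floor cells with fewer total UMIs are excluded before
#'   downsampling.
#' @param seed integer seed for the downsampling.
#' @return data.frame with one row per tested gene: `gene`,
#'   `log2_enrichment` (A over B), `enriched_group`, `p`, `q`,
#'   `frac_cells_enriched`, `mean_umi_enriched`. The common UMI target is
#'   in attribute `umi_target`.
#' @export
pseudobulk_de <- function(cells_a, cells_b, min_frac_cells = 0.5,
                          min_mean_umi = 0.1, umi_floor = 500, seed = NULL) {
  stopifnot(is.matrix(cells_a) || inherits(cells_a, "Matrix"),
            identical(rownames(cells_a), rownames(cells_b)))
  cells_a <- as.matrix(cells_a)
  cells_b <- as.matrix(cells_b)
  cells_a <- cells_a[, colSums(cells_a) >= umi_floor, drop = FALSE]
  cells_b <- cells_b[, colSums(cells_b) >= umi_floor, drop = FALSE]
  if (ncol(cells_a) < 2L || ncol(cells_b) < 2L) {
    stop("need at least 2 cells per group above the UMI floor")
  }
  target <- min(c(colSums(cells_a), colSums(cells_b)))
  with_seed(seed, {
    dsa <- apply(cells_a, 2, downsample_counts, target = target)
    dsb <- apply(cells_b, 2, downsample_counts, target = target)
    pba <- rowSums(dsa)
    pbb <- rowSums(dsb)
    # normalize pseudobulk profiles to equal totals
    tt <- (sum(pba) + sum(pbb)) / 2
    na <- pba / sum(pba) * tt
    nb <- pbb / sum(pbb) * tt
    enr_a <- na >= nb
    frac <- ifelse(enr_a, rowMeans(dsa > 0), rowMeans(dsb > 0))
    meanumi <- ifelse(enr_a, rowMeans(dsa), rowMeans(dsb))
    keep <- frac >= min_frac_cells & meanumi >= min_mean_umi
    genes <- rownames(cells_a)[keep]
    if (!length(genes)) {
      out <- data.frame(gene = character(0), log2_enrichment = numeric(0),
                        enriched_group = character(0), p = numeric(0),
                        q = numeric(0), frac_cells_enriched = numeric(0),
                        mean_umi_enriched = numeric(0))
      attr(out, "umi_target") <- target
      return(out)
    }
    p <- vapply(which(keep), function(g) {
      suppressWarnings(stats::wilcox.test(dsa[g, ], dsb[g, ],
                                          exact = FALSE)$p.value)
    }, numeric(1))
    p[is.na(p)] <- 1
    out <- data.frame(gene = genes,
                      log2_enrichment = log2((na[keep] + 1) / (nb[keep] + 1)),
                      enriched_group = ifelse(enr_a[keep], "A", "B"),
                      p = p, q = stats::p.adjust(p, method = "BH"),
                      frac_cells_enriched = frac[keep],
                      mean_umi_enriched = meanumi[keep],
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "umi_target") <- target
    out
  })
}

#' Threshold between the two modes of a bimodal score distribution
#'
#' Kernel-density estimate of per-cell signature scores; the threshold is
#' the density minimum between the two largest modes (the inflection point
#' separating the two cell fractions). Unimodal distributions raise an
#' error.
#'
#' @param scores per-cell signature scores (>= 100 values).
#' @param bw,adjust bandwidth rule and multiplier for [stats::density()].
#' @return The threshold score; the two mode locations are in attribute
#'   `modes`.
#' @export
bimodal_threshold <- function(scores, bw = "nrd0", adjust = 1) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 100L) {
    stop("need at least 100 scores")
  }
  den <- stats::density(scores, bw = bw, adjust = adjust)
  y <- den$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n],
              FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2L) {
    stop("no threshold: score density is unimodal")
  }
  top2 <- sort(peaks[order(-y[peaks])][1:2])
  valley <- seq(top2[1], top2[2])
  thr <- den$x[valley[which.min(y[valley])]]
  attr(thr, "modes") <- den$x[top2]
  thr
}

#' Reproducibility of a clone's cell-state proportions across replicates
#'
#' Adjusted R-squared of the ordinary least-squares fit of one secondary
#' replicate's per-metacell cell-state fractions on another's, for the
#' same clone.
#'
#' @param frac_rep1,frac_rep2 per-metacell cell-state fractions over the
#'   same metacell index (>= 3 states).
#' @return Adjusted R-squared; NA with a warning for zero-variance input.
#' @export
replicate_state_correlation <- function(frac_rep1, frac_rep2) {
  stopifnot(length(frac_rep1) == length(frac_rep2))
  if (length(frac_rep1) < 3L) {
    stop("need at least 3 cell states")
  }
  if (stats::var(frac_rep1) == 0 || stats::var(frac_rep2) == 0) {
    warning("zero-variance state fractions; correlation undefined")
    return(NA_real_)
  }
  suppressWarnings(
    summary(stats::lm(frac_rep2 ~ frac_rep1)))$adj.r.squared
}

#' Differentiation breadth of a clone across cell states
#'
#' The number and fraction of metacells containing at least one cell of
#' the clone, and the Shannon entropy (bits) of the clone's cell
#' distribution over metacells. Dominant propagating clones span all
#' model-specific cell states and show the highest entropy.
#'
#' @param graph a `MetacellGraph` with cell membership.
#' @param clone clone (barcode) identifier.
#' @param passages restrict to these passages (default: all).
#' @return A list with `n_metacells`, `fraction`, `entropy` (NA when the
#'   clone is absent).
#' @export
clone_state_breadth <- function(graph, clone, passages = NULL) {
  stopifnot(inherits(graph, "MetacellGraph"))
  mem <- graph$membership
  if (is.null(mem)) {
    stop("graph has no cell membership")
  }
  sel <- mem$clone == clone
  if (!is.null(passages)) {
    sel <- sel & mem$passage %in% passages
  }
  if (!any(sel)) {
    return(list(n_metacells = 0L, fraction = 0, entropy = NA_real_))
  }
  counts <- table(as.character(mem$metacell[sel]))
  list(n_metacells = length(counts),
       fraction = length(counts) / length(graph$nodes),
       entropy = shannon_entropy(as.numeric(counts), base = 2,
                                 normalize = TRUE))
}
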