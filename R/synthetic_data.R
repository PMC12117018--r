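# Synthetic-data module: generates every input the pipeline consumes -
# barcode libraries, ground-truth clone populations across passages,
# spike-in manifests, paired amplicon FASTQ, and single-cell fixtures -
# together with the ground truth needed for recovery tests.

#' Generate a barcode library
#'
#' Draws `n` unique barcodes uniformly at random over `{A,C,G,T}^length`.
#' The published libraries use a semi-random 27-bp design whose template is
#' not public; uniform barcodes have collision properties at least as
#' adverse as any design with constrained positions, so diversity checks
#' on them are conservative.
#'
#' @param n number of unique barcodes (at most `4^length`).
#' @param length barcode length in bases (default 27).
#' @param library_id 4-base library tag carried by the library's inserts.
#' @param seed integer seed; the same seed regenerates the identical set.
#' @return An object of class `BarcodeLibrary` with fields `library_id`,
#'   `barcodes`, `length`, `seed`.
#' @export
generate_barcode_library <- function(n, length = 27, library_id = "ACGT",
                                     seed = NULL) {
  capacity <- 4^length
  if (n > capacity) {
    stop(sprintf("capacity error: n = %s exceeds 4^%d", format(n), length))
  }
  stopifnot(n >= 0, grepl("^[ACGT]+$", library_id))
  barcodes <- with_seed(seed, {
    bcs <- character(0)
    while (base::length(bcs) < n) {
      need <- n - base::length(bcs)
      draw <- random_dna(max(need + ceiling(0.05 * need), 10L), length)
      bcs <- unique(c(bcs, draw))
    }
    bcs[seq_len(n)]
  })
  structure(list(library_id = library_id, barcodes = barcodes,
                 length = length, seed = seed),
            class = "BarcodeLibrary")
}

#' @export
print.BarcodeLibrary <- function(x, ...) {
  cat(sprintf("BarcodeLibrary '%s': %d unique %d-bp barcodes\n",
              x$library_id, length(x$barcodes), x$length))
  invisible(x)
}

#' Default synthetic-experiment configuration
#'
#' Two xenograft models (one basal-like, one luminal-like) with a primary
#' and two secondary passages each, three growth-rate subpopulations with
#' the proportions observed across clone speed classes (19% fast, 62%
#' medium, 19% slow), rare propagating clones among the primary founders,
#' and a spike-in ladder spanning 10 to 12,500 cells.
#'
#' @return A nested list understood by [simulate_experiment()].
#' @export
default_experiment_config <- function() {
  subpops <- data.frame(label = c("fast", "medium", "slow"),
                        mu = c(5, 15, 40), weight = c(0.19, 0.62, 0.19),
                        stringsAsFactors = FALSE)
  model <- function(name, library, subtype) {
    list(name = name, library = library, subtype = subtype,
         cells_implanted = 1e5, transduction_efficiency = 0.25,
         pct_tumor_sampled = 10, tumor_cells = 2e6,
         days = c(P = 60, S1 = 120, S2 = 120),
         n_clones = 250, prop_propagating = 0.05, n_emerging = 40,
         subpopulations = subpops)
  }
  list(models = list(model("XB1", "BC1", "basal"),
                     model("XL1", "BC2", "luminalB")),
       spikein = list(levels = c(10, 50, 125, 500, 1250, 5000, 12500),
                      replicates = 24, library = "BC3"),
       barcode_length = 27,
       library_tags = c(BC1 = "ACGT", BC2 = "CATG", BC3 = "GTCA"))
}

#' Read an experiment configuration from YAML
#'
#' Values in the YAML file override the defaults of
#' [default_experiment_config()] at the top level; `models` and `spikein`
#' replace the defaults wholesale when present.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_experiment_config <- function(path) {
  cfg <- default_experiment_config()
  user <- yaml::read_yaml(path)
  for (nm in names(user)) {
    cfg[[nm]] <- user[[nm]]
  }
  if (!is.null(user$models)) {
    cfg$models <- lapply(user$models, function(m) {
      if (!is.null(m$subpopulations) && !is.data.frame(m$subpopulations)) {
        m$subpopulations <- as.data.frame(m$subpopulations,
                                          stringsAsFactors = FALSE)
      }
      m
    })
  }
  if (!is.null(user$library_tags)) {
    cfg$library_tags <- unlist(user$library_tags)
  }
  cfg
}

#' Simulate a barcoded-xenograft experiment
#'
#' Draws ground-truth clone populations for every model and passage.
#' Primary founders are assigned a growth subpopulation by weight and a
#' fate: propagating clones are present in the primary and every
#' secondary passage, transient clones in the primary only, and emerging
#' clones (absent when a model has no secondary passages) appear in
#' secondaries only. Clone sizes come from the stochastic growth model,
#' capped so the summed cells per xenograft never exceed the configured
#' tumor size. A spike-in manifest and a xenograft metadata table are
#' generated alongside.
#'
#' @param config configuration list, see [default_experiment_config()].
#' @param seed integer seed.
#' @return An object of class `ClonalExperiment`: `clones` (barcode,
#'   model, subpopulation, mu, fate), `clone_cells` (model, passage,
#'   sample_id, barcode, cells), `spikeins` (barcode, known_cells,
#'   replicate), `metadata` (one row per xenograft sample), `config`.
#' @export
simulate_experiment <- function(config = default_experiment_config(),
                                seed = NULL) {
  for (m in config$models) {
    if (abs(sum(m$subpopulations$weight) - 1) > 1e-8) {
      stop(sprintf("config error: subpopulation weights of model %s do not sum to 1",
                   m$name))
    }
  }
  with_seed(seed, {
    clones_list <- list()
    cells_list <- list()
    meta_list <- list()
    for (m in config$models) {
      passages <- names(m$days)
      secondaries <- setdiff(passages, "P")
      n_emerging <- if (length(secondaries)) m$n_emerging %||% 0L else 0L
      n_total <- m$n_clones + n_emerging
      lib <- generate_barcode_library(n_total,
                                      length = config$barcode_length,
                                      library_id = config$library_tags[[m$library]])
      bcs <- lib$barcodes
      founder_bcs <- bcs[seq_len(m$n_clones)]
      emerging_bcs <- if (n_emerging) bcs[m$n_clones + seq_len(n_emerging)]
                      else character(0)

      sp <- m$subpopulations
      comp <- sample.int(nrow(sp), n_total, replace = TRUE,
                         prob = sp$weight)
      fate <- c(ifelse(stats::runif(m$n_clones) < (m$prop_propagating %||% 0) &
                         length(secondaries) > 0,
                       "propagating", "transient"),
                rep("emerging", n_emerging))
      clones <- data.frame(model = m$name, barcode = bcs,
                           subpopulation = sp$label[comp], mu = sp$mu[comp],
                           fate = fate, stringsAsFactors = FALSE)
      clones_list[[m$name]] <- clones

      for (pas in passages) {
        present <- switch(pas, P = clones$fate != "emerging",
                          clones$fate != "transient")
        idx <- which(present)
        if (!length(idx)) next
        # grow the clones present in this xenograft; one fixed mean
        # doubling time per clone keeps the truth labels attached
        grown <- simulate_population_fixed(mu = clones$mu[idx],
                                           limits = sim_limits(m$tumor_cells,
                                                               m$days[[pas]]),
                                           overshoot = "truncate")
        cells_list[[paste(m$name, pas, sep = "_")]] <-
          data.frame(model = m$name, passage = pas,
                     sample_id = paste(m$name, pas, sep = "_"),
                     barcode = clones$barcode[idx],
                     cells = pmax(1, round(grown$cells)),
                     stringsAsFactors = FALSE)
        meta_list[[paste(m$name, pas, sep = "_")]] <-
          data.frame(model = m$name, sample_id = paste(m$name, pas, sep = "_"),
                     passage = pas, days_in_vivo = m$days[[pas]],
                     cells_implanted = m$cells_implanted,
                     transduction_efficiency = m$transduction_efficiency,
                     pct_tumor_sampled = m$pct_tumor_sampled,
                     library = m$library, stringsAsFactors = FALSE)
      }
    }
    spl <- config$spikein
    n_sp <- length(spl$levels) * spl$replicates
    sp_lib <- generate_barcode_library(n_sp, length = config$barcode_length,
                                       library_id = config$library_tags[[spl$library]])
    spikeins <- data.frame(barcode = sp_lib$barcodes,
                           known_cells = rep(spl$levels,
                                             each = spl$replicates),
                           replicate = rep(seq_len(spl$replicates),
                                           times = length(spl$levels)),
                           stringsAsFactors = FALSE)
    structure(list(clones = do.call(rbind, clones_list),
                   clone_cells = do.call(rbind, cells_list),
                   spikeins = spikeins,
                   metadata = do.call(rbind, meta_list),
                   config = config, seed = seed),
              class = "ClonalExperiment")
  })
}

# Growth of a fixed set of clones with known per-clone mean doubling times,
# truncated at a shared tumor capacity (uses the caller's RNG stream).
simulate_population_fixed <- function(mu, limits,
                                      overshoot = c("truncate", "include")) {
  overshoot <- match.arg(overshoot)
  n <- length(mu)
  lambda <- mu  # per-day convention: mean 1/mu doublings per day
  cum <- numeric(n)
  t <- 0L
  log2_cap <- log2(limits$max_cells)
  while (t < limits$max_days) {
    newcum <- cum + stats::rexp(n, lambda)
    t <- t + 1L
    if (sum(2^newcum) >= limits$max_cells) {
      if (overshoot == "include") cum <- newcum
      break
    }
    cum <- newcum
  }
  list(cells = 2^cum, days = t)
}

#' @export
print.ClonalExperiment <- function(x, ...) {
  cat(sprintf("ClonalExperiment: %d models, %d clones, %d spike-ins, %d samples\n",
              length(unique(x$clones$model)), nrow(x$clones),
              nrow(x$spikeins), nrow(x$metadata)))
  print(table(x$clones$model, x$clones$fate))
  invisible(x)
}

#' Write an experiment's ground truth as TSV files
#'
#' @param experiment a `ClonalExperiment`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "ClonalExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("clones", "clone_cells", "spikeins", "metadata")) {
    utils::write.table(experiment[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read-simulation configuration
#'
#' @param depth reads per sample.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param flanks flank pairs emitted round-robin, see [amplicon_flanks()].
#' @param q_high Phred score of ordinary bases (default 37).
#' @param low_q_rate per-base probability of a low-quality base.
#' @param q_low Phred score assigned to corrupted bases (default 20).
#' @param seed integer seed.
#' @return A list of class `ReadSimConfig`.
#' @export
read_sim_config <- function(depth, error_rate = 0, flanks = amplicon_flanks(),
                            q_high = 37, low_q_rate = 0, q_low = 20,
                            seed = NULL) {
  stopifnot(depth >= 0, error_rate >= 0, error_rate < 1,
            low_q_rate >= 0, low_q_rate < 1)
  structure(list(depth = as.integer(depth), error_rate = error_rate,
                 flanks = flanks, q_high = q_high, low_q_rate = low_q_rate,
                 q_low = q_low, seed = seed),
            class = "ReadSimConfig")
}

# Substitute random different bases at `rate` per base, in place on a
# character vector of equal-length reads.
mutate_reads <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) {
    return(reads)
  }
  L <- nchar(reads[1])
  total <- length(reads) * L
  n_mut <- stats::rbinom(1L, total, rate)
  if (n_mut == 0L) {
    return(reads)
  }
  pos <- sample.int(total, n_mut)
  ri <- (pos - 1L) %/% L + 1L
  pj <- (pos - 1L) %% L + 1L
  by_read <- split(pj, ri)
  idxs <- as.integer(names(by_read))
  reads[idxs] <- vapply(seq_along(idxs), function(k) {
    s <- strsplit(reads[idxs[k]], "", fixed = TRUE)[[1]]
    for (j in by_read[[k]]) {
      s[j] <- sample(setdiff(DNA_BASES, s[j]), 1L)
    }
    paste(s, collapse = "")
  }, character(1))
  reads
}

#' Simulate paired amplicon FASTQ reads
#'
#' Reads are drawn from the pooled cell population (clones plus spike-in
#' controls) with probability proportional to cell number, so per-barcode
#' read fractions converge to cell fractions with depth. Each read 1 is
#' `flank5 + 31-bp insert + flank3` with the three staggered flank pairs
#' emitted round-robin; the insert is the 27-bp barcode followed by the
#' 4-bp library ID. Substitution errors are applied at `error_rate` per
#' base; read 2 is the reverse complement. Qualities are constant
#' `q_high` with a configurable fraction of low-quality bases.
#'
#' @param clones data.frame with `barcode`, `cells` and `library` (tag
#'   sequence or name resolvable via `library_tags`).
#' @param spikeins data.frame with `barcode` and `known_cells`.
#' @param cfg a [read_sim_config()].
#' @param library_tags named tag map used to resolve `library` names and
#'   to tag spike-ins (name taken from `spikein_library`).
#' @param spikein_library library name of the spike-in stream.
#' @param paths optional character(2): write read 1 / read 2 FASTQ files.
#' @return Invisibly when written to `paths`; otherwise a list with
#'   `read1` and `read2` ([Biostrings::QualityScaledDNAStringSet]) and the
#'   per-read source index in attribute `truth`.
#' @export
simulate_amplicon_fastq <- function(clones, spikeins, cfg,
                                    library_tags = default_experiment_config()$library_tags,
                                    spikein_library = "BC3", paths = NULL) {
  stopifnot(inherits(cfg, "ReadSimConfig"))
  if (cfg$depth > 0L && (is.null(clones) || nrow(clones) == 0L) &&
      (is.null(spikeins) || nrow(spikeins) == 0L)) {
    stop("no clones or spike-ins to sequence")
  }
  src <- rbind(
    if (!is.null(clones) && nrow(clones)) {
      tag <- ifelse(clones$library %in% names(library_tags),
                    library_tags[clones$library], clones$library)
      data.frame(barcode = clones$barcode, tag = tag, cells = clones$cells,
                 stringsAsFactors = FALSE)
    },
    if (!is.null(spikeins) && nrow(spikeins)) {
      data.frame(barcode = spikeins$barcode,
                 tag = library_tags[[spikein_library]],
                 cells = spikeins$known_cells, stringsAsFactors = FALSE)
    })
  out <- with_seed(cfg$seed, {
    if (cfg$depth == 0L) {
      empty <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(character(0)),
        Biostrings::PhredQuality(character(0)))
      list(read1 = empty, read2 = empty,
           idx = integer(0), pair = integer(0))
    } else {
      idx <- sample.int(nrow(src), cfg$depth, replace = TRUE,
                        prob = src$cells)
      pair <- rep_len(seq_len(nrow(cfg$flanks)), cfg$depth)
      insert <- paste0(src$barcode[idx], src$tag[idx])
      r1 <- paste0(cfg$flanks$flank5[pair], insert, cfg$flanks$flank3[pair])
      r1 <- mutate_reads(r1, cfg$error_rate)
      r2 <- revcomp(r1)
      L <- nchar(r1[1])
      qconst <- strrep(intToUtf8(cfg$q_high + 33), L)
      q1 <- rep(qconst, cfg$depth)
      if (cfg$low_q_rate > 0) {
        n_low <- stats::rbinom(1L, cfg$depth * L, cfg$low_q_rate)
        if (n_low > 0L) {
          pos <- sample.int(cfg$depth * L, n_low)
          ri <- (pos - 1L) %/% L + 1L
          pj <- (pos - 1L) %% L + 1L
          for (k in seq_len(n_low)) {
            substr(q1[ri[k]], pj[k], pj[k]) <- intToUtf8(cfg$q_low + 33)
          }
        }
      }
      ids <- sprintf("read%07d", seq_len(cfg$depth))
      make_qs <- function(s, q) {
        x <- Biostrings::QualityScaledDNAStringSet(
          Biostrings::DNAStringSet(s), Biostrings::PhredQuality(q))
        names(x) <- ids
        x
      }
      list(read1 = make_qs(r1, q1),
           read2 = make_qs(r2, vapply(q1, function(z)
             paste(rev(strsplit(z, "")[[1]]), collapse = ""), character(1),
             USE.NAMES = FALSE)),
           idx = idx, pair = pair)
    }
  })
  res <- list(read1 = out$read1, read2 = out$read2)
  attr(res, "truth") <- data.frame(source = out$idx, flank_pair = out$pair)
  attr(res, "sources") <- src
  if (!is.null(paths)) {
    stopifnot(length(paths) == 2L)
    # writeQualityScaledXStringSet warns about dropped metadata columns
    suppressWarnings({
      Biostrings::writeQualityScaledXStringSet(out$read1, paths[1])
      Biostrings::writeQualityScaledXStringSet(out$read2, paths[2])
    })
    return(invisible(res))
  }
  res
}

#' Simulate the FASTQ for one xenograft sample of an experiment
#'
#' Convenience wrapper: pools the sample's clone cells (scaled by the
#' fraction of the tumor taken for amplification) with the spike-in
#' controls and simulates reads.
#'
#' @param experiment a `ClonalExperiment`.
#' @param sample_id row of `experiment$metadata` to sequence.
#' @param depth reads to simulate.
#' @param error_rate per-base substitution rate.
#' @param seed integer seed.
#' @param ... further arguments to [read_sim_config()].
#' @inheritParams simulate_amplicon_fastq
#' @return As [simulate_amplicon_fastq()].
#' @export
simulate_sample_fastq <- function(experiment, sample_id, depth,
                                  error_rate = 0, seed = NULL, paths = NULL,
                                  ...) {
  stopifnot(inherits(experiment, "ClonalExperiment"))
  meta <- experiment$metadata[experiment$metadata$sample_id == sample_id, ]
  if (nrow(meta) != 1L) {
    stop("unknown sample_id")
  }
  cells <- experiment$clone_cells[
    experiment$clone_cells$sample_id == sample_id, ]
  clones <- data.frame(barcode = cells$barcode,
                       cells = cells$cells * meta$pct_tumor_sampled / 100,
                       library = meta$library, stringsAsFactors = FALSE)
  cfg <- read_sim_config(depth, error_rate = error_rate, seed = seed, ...)
  simulate_amplicon_fastq(clones, experiment$spikeins, cfg,
                          library_tags = experiment$config$library_tags,
                          spikein_library = experiment$config$spikein$library,
                          paths = paths)
}

#' Simulate a single-cell fixture with planted structure
#'
#' Emulates the inputs of the single-cell layer: a cell-to-barcode table,
#' a metacell partition with passage labels, a symmetric metacell
#' similarity matrix, and per-metacell mean expression. Metacells lie on a
#' chain (similarity decays with chain distance) carrying a planted
#' epithelial-to-mesenchymal gradient: epithelial module genes decrease
#' and mesenchymal module genes increase along the chain. The first clone
#' marked propagating becomes the dominant clone spanning every metacell,
#' with its primary-passage cells confined to the first `n_roots`
#' metacells; transient clones occupy small primary-only neighborhoods and
#' emerging clones small secondary-only neighborhoods. A configurable
#' fraction of cells are doublets (a cell-unique pair of barcodes) and a
#' fraction of clones carry multiple integrations (the same barcode pair
#' in all their cells).
#'
#' @param clones data.frame with `barcode` and `fate`
#'   (propagating/transient/emerging).
#' @param n_cells total cells (>= `n_metacells`).
#' @param doublet_rate fraction of cells made doublets, in `[0, 1)`.
#' @param multi_integration_rate fraction of clones given a second
#'   integrated barcode, in `[0, 1]`.
#' @param n_metacells number of metacells (chain length).
#' @param n_genes number of genes (>= 40).
#' @param n_roots metacells holding the dominant clone's primary cells.
#' @param seed integer seed.
#' @return A list with `cell_barcodes` (cell_id, barcode, reads),
#'   `cells` (cell_id, clone, passage, metacell), `similarity`,
#'   `expression` (genes x metacells), and `truth` (dominant clone,
#'   doublet cells, multi-integration clones, module gene ids).
#' @export
simulate_single_cell_fixture <- function(clones, n_cells = 2000,
                                         doublet_rate = 0.02,
                                         multi_integration_rate = 0.02,
                                         n_metacells = 30, n_genes = 200,
                                         n_roots = 3, seed = NULL) {
  stopifnot(doublet_rate >= 0, doublet_rate < 1,
            multi_integration_rate >= 0, multi_integration_rate <= 1,
            n_genes >= 40, n_roots >= 1, n_roots <= n_metacells)
  if (n_metacells > n_cells) {
    stop("config error: n_metacells exceeds n_cells")
  }
  fates <- as.character(clones$fate)
  dom <- clones$barcode[match("propagating", fates)]
  if (is.na(dom)) {
    stop("need at least one propagating clone for the dominant-clone layout")
  }
  with_seed(seed, {
    mc <- seq_len(n_metacells)
    # clone -> metacell neighborhoods
    home <- lapply(seq_len(nrow(clones)), function(i) {
      if (clones$barcode[i] == dom) {
        return(mc)
      }
      w <- sample.int(max(1L, n_metacells %/% 8L), 1L) + 1L
      s <- sample.int(n_metacells, 1L)
      sort(unique(pmin(n_metacells, s + 0:(w - 1L))))
    })
    # passage availability per fate
    passage_of <- function(fate) {
      switch(fate, propagating = c("P", "S1"), transient = "P",
             emerging = "S1")
    }
    # dominant clone gets half the cells; the rest shared by the others
    n_dom <- ceiling(n_cells / 2)
    owner <- c(rep(match(dom, clones$barcode), n_dom),
               sample(seq_len(nrow(clones)), n_cells - n_dom,
                      replace = TRUE))
    cell_id <- sprintf("cell%05d", seq_len(n_cells))
    passage <- vapply(owner, function(i) {
      p <- passage_of(fates[i])
      p[sample.int(length(p), 1L)]
    }, character(1))
    metacell <- integer(n_cells)
    for (i in seq_len(n_cells)) {
      o <- owner[i]
      if (clones$barcode[o] == dom && passage[i] == "P") {
        metacell[i] <- sample.int(n_roots, 1L)
      } else {
        hh <- home[[o]]
        metacell[i] <- hh[sample.int(length(hh), 1L)]
      }
    }
    # guarantee every metacell is populated (dominant clone, secondary)
    missing <- setdiff(mc, unique(metacell))
    if (length(missing)) {
      take <- which(owner == match(dom, clones$barcode) & passage == "S1")
      take <- take[seq_along(missing)]
      metacell[take] <- missing
    }
    cells <- data.frame(cell_id = cell_id, clone = clones$barcode[owner],
                        passage = passage, metacell = paste0("mc", metacell),
                        stringsAsFactors = FALSE)

    # cell -> barcode table with doublets and multiple integrations
    mi_clones <- clones$barcode[stats::runif(nrow(clones)) <
                                  multi_integration_rate]
    ghost <- stats::setNames(random_dna(length(mi_clones), 27L), mi_clones)
    rows <- data.frame(cell_id = cell_id, barcode = clones$barcode[owner],
                       reads = stats::rpois(n_cells, 20) + 1L,
                       stringsAsFactors = FALSE)
    if (length(mi_clones)) {
      extra <- rows[rows$barcode %in% mi_clones, ]
      extra$barcode <- unname(ghost[extra$barcode])
      rows <- rbind(rows, extra)
    }
    doublet_cells <- cell_id[stats::runif(n_cells) < doublet_rate]
    if (length(doublet_cells)) {
      rows <- rbind(rows,
                    data.frame(cell_id = doublet_cells,
                               barcode = random_dna(length(doublet_cells),
                                                    27L),
                               reads = stats::rpois(length(doublet_cells),
                                                    5) + 1L,
                               stringsAsFactors = FALSE))
    }

    # chain similarity with decaying kernel
    d <- abs(outer(mc, mc, "-"))
    similarity <- exp(-d / 2)
    dimnames(similarity) <- list(paste0("mc", mc), paste0("mc", mc))

    # expression: epithelial module decreasing, mesenchymal increasing
    n_mod <- max(10L, n_genes %/% 10L)
    epi <- seq_len(n_mod)
    mes <- n_mod + seq_len(n_mod)
    base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.3)
    pos <- (mc - 1) / (n_metacells - 1)
    expr <- matrix(0, n_genes, n_metacells,
                   dimnames = list(sprintf("gene%04d", seq_len(n_genes)),
                                   paste0("mc", mc)))
    for (g in seq_len(n_genes)) {
      prof <- rep(base[g], n_metacells)
      if (g %in% epi) prof <- base[g] * (1.5 - pos)
      if (g %in% mes) prof <- base[g] * (0.5 + pos)
      expr[g, ] <- pmax(0, prof * exp(stats::rnorm(n_metacells, 0, 0.05)))
    }

    list(cell_barcodes = rows[order(rows$cell_id), ], cells = cells,
         similarity = similarity, expression = expr,
         truth = list(dominant_clone = dom, doublet_cells = doublet_cells,
                      multi_integration_clones = mi_clones,
                      ghost_barcodes = ghost,
                      epithelial_genes = rownames(expr)[epi],
                      mesenchymal_genes = rownames(expr)[mes],
                      n_roots = n_roots))
  })
}

#' Write a single-cell fixture to plain-text files
#'
#' Expression goes to MatrixMarket format with separate row/column name
#' files; tables to TSV.
#'
#' @param fixture output of [simulate_single_cell_fixture()].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_sc_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(fixture$expression,
                                             sparse = TRUE), "CsparseMatrix"),
                  file.path(dir, "expression.mtx"))
  writeLines(rownames(fixture$expression), file.path(dir, "genes.txt"))
  writeLines(colnames(fixture$expression), file.path(dir, "metacells.txt"))
  utils::write.table(fixture$cell_barcodes,
                     file.path(dir, "cell_barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(fixture$similarity),
                     file.path(dir, "similarity.tsv"), sep = "\t",
                     quote = FALSE)
  invisible(dir)
}
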