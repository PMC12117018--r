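# Generators: barcode libraries, ground-truth experiments, amplicon reads
# and single-cell fixtures.

test_that("generate_barcode_library fills capacity, is deterministic and validates", {
  lib <- generate_barcode_library(16, length = 2, seed = 1)
  expect_setequal(lib$barcodes,
                  as.vector(outer(c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"), paste0)))

  a <- generate_barcode_library(1000, seed = 7)
  b <- generate_barcode_library(1000, seed = 7)
  expect_identical(a$barcodes, b$barcodes)
  expect_false(identical(a$barcodes,
                         generate_barcode_library(1000, seed = 8)$barcodes))

  expect_identical(anyDuplicated(a$barcodes), 0L)
  expect_true(all(nchar(a$barcodes) == 27L))
  expect_true(all(grepl("^[ACGT]+$", a$barcodes)))

  expect_error(generate_barcode_library(17, length = 2), "capacity")
})

test_that("simulate_experiment respects fate definitions, capacity and subpopulation weights", {
  ex <- simulate_experiment(seed = 5)
  cc <- ex$clone_cells
  for (m in unique(ex$clones$model)) {
    cl <- ex$clones[ex$clones$model == m, ]
    cm <- cc[cc$model == m, ]
    in_p <- cl$barcode %in% cm$barcode[cm$passage == "P"]
    in_s <- cl$barcode %in% cm$barcode[cm$passage != "P"]
    expect_true(all((in_p & in_s) == (cl$fate == "propagating")))
    expect_true(all((in_p & !in_s) == (cl$fate == "transient")))
    expect_true(all((!in_p & in_s) == (cl$fate == "emerging")))
  }
  # xenograft cell totals never exceed the configured tumor size
  cfg_cap <- vapply(ex$config$models, `[[`, numeric(1), "tumor_cells")
  names(cfg_cap) <- vapply(ex$config$models, `[[`, character(1), "name")
  totals <- tapply(cc$cells, cc$sample_id, sum)
  expect_true(all(totals <= cfg_cap[sub("_.*", "", names(totals))]))
  expect_true(all(cc$cells >= 1))

  # subpopulation counts of primary founders fall inside a binomial CI
  cl <- ex$clones[ex$clones$fate != "emerging", ]
  sp <- ex$config$models[[1]]$subpopulations
  n <- nrow(cl)
  for (k in seq_len(nrow(sp))) {
    obs <- sum(cl$subpopulation == sp$label[k])
    p <- sp$weight[k]
    expect_lt(abs(obs - n * p), 4 * sqrt(n * p * (1 - p)) + 1)
  }
})

test_that("experiment config edge cases: single-fate and no-secondary designs", {
  cfg <- default_experiment_config()
  cfg$models <- cfg$models[1]
  cfg$models[[1]]$prop_propagating <- 1
  cfg$models[[1]]$n_emerging <- 0
  ex <- simulate_experiment(cfg, seed = 9)
  expect_true(all(ex$clones$fate == "propagating"))

  cfg2 <- default_experiment_config()
  cfg2$models <- cfg2$models[1]
  cfg2$models[[1]]$days <- c(P = 60)  # zero secondary passages
  ex2 <- simulate_experiment(cfg2, seed = 10)
  expect_false(any(ex2$clones$fate == "emerging"))
  expect_false(any(ex2$clones$fate == "propagating"))

  cfg3 <- default_experiment_config()
  cfg3$models[[1]]$subpopulations$weight <- c(0.5, 0.2, 0.2)
  expect_error(simulate_experiment(cfg3), "sum to 1")
})

test_that("simulated amplicon reads mirror cell fractions and honor depth and error settings", {
  clones <- data.frame(barcode = c(strrep("A", 27), strrep("C", 27)),
                       cells = c(100, 900), library = "BC1",
                       stringsAsFactors = FALSE)
  spikes <- data.frame(barcode = strrep("G", 27), known_cells = 0)

  # depth 0 gives an empty FASTQ
  fq0 <- simulate_amplicon_fastq(clones, NULL, read_sim_config(0))
  expect_length(fq0$read1, 0L)

  # error-free reads: every extracted insert matches a truth insert
  fq <- simulate_amplicon_fastq(clones, NULL,
                                read_sim_config(2000, seed = 12))
  cb <- count_barcodes(fq$read1)
  tags <- default_experiment_config()$library_tags
  expect_setequal(names(cb$counts), paste0(clones$barcode, tags["BC1"]))
  expect_identical(sum(cb$counts), 2000L)

  # a clone holding 10% of cells gets a 10% +/- 1% read share at depth 1e5
  fq2 <- simulate_amplicon_fastq(clones, NULL,
                                 read_sim_config(1e5, seed = 13))
  cb2 <- count_barcodes(fq2$read1)
  share <- cb2$counts[paste0(strrep("A", 27), tags["BC1"])] / 1e5
  expect_lt(abs(share - 0.1), 0.01)

  # read 2 is the mate: reverse complement of read 1
  expect_identical(
    unname(as.character(Biostrings::reverseComplement(fq$read2[1]))),
    unname(as.character(fq$read1[1])))
})

test_that("single-cell fixture plants doublets, multiple integrations and a populated chain", {
  clones <- data.frame(barcode = replicate(12, paste(sample(c("A", "C", "G",
                                                              "T"), 27, TRUE),
                                                     collapse = "")),
                       fate = c("propagating", rep("transient", 8),
                                rep("emerging", 3)),
                       stringsAsFactors = FALSE)

  fx <- simulate_single_cell_fixture(clones, n_cells = 600,
                                     doublet_rate = 0,
                                     multi_integration_rate = 0,
                                     n_metacells = 20, n_genes = 100,
                                     seed = 14)
  per_cell <- table(fx$cell_barcodes$cell_id)
  expect_true(all(per_cell == 1L))
  expect_true(isSymmetric(unname(fx$similarity)))
  expect_true(all(diag(fx$similarity) == 1))
  expect_true(all(fx$expression >= 0))
  expect_setequal(unique(fx$cells$metacell), paste0("mc", 1:20))
  # the dominant clone spans every metacell
  dom <- fx$truth$dominant_clone
  expect_setequal(unique(fx$cells$metacell[fx$cells$clone == dom]),
                  paste0("mc", 1:20))

  # forced multiple integration: one repeated barcode pair across all cells
  fx2 <- simulate_single_cell_fixture(clones, n_cells = 400,
                                      doublet_rate = 0,
                                      multi_integration_rate = 1,
                                      n_metacells = 10, n_genes = 100,
                                      seed = 15)
  expect_setequal(fx2$truth$multi_integration_clones, clones$barcode)
  one <- clones$barcode[1]
  carriers <- fx2$cell_barcodes[fx2$cell_barcodes$cell_id %in%
    fx2$cells$cell_id[fx2$cells$clone == one], ]
  pats <- tapply(carriers$barcode, carriers$cell_id,
                 function(b) paste(sort(b), collapse = "+"))
  expect_length(unique(pats), 1L)
  expect_identical(unname(lengths(strsplit(unique(pats), "+", fixed = TRUE))),
                   2L)

  expect_error(simulate_single_cell_fixture(clones, n_cells = 5,
                                            n_metacells = 10),
               "config error")
})
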