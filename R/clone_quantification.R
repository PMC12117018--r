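# Clone quantification: fractional read values, spike-in calibration,
# absolute clone sizes, detection thresholds and the limit of detection.
#
# Spike-in controls are barcoded cells of known number added to each
# sequencing sample. The fractional read value (FRV) of a clone is its
# read count divided by the summed reads of all spike-in controls; the
# calibration regression of log10(cells) on log10(FRV) converts FRV into
# absolute cell numbers, correcting amplification bias.

#' Fractional read value
#'
#' `FRV = clone reads / sum of reads from all spike-in controls` in the
#' same sample.
#'
#' @param clone_reads read count(s) for the clone(s) of interest.
#' @param spikein_total_reads summed reads over all spike-in barcodes.
#' @return Numeric vector of FRVs (>= 0).
#' @examples
#' compute_frv(500, 10000)  # 0.05
#' @export
compute_frv <- function(clone_reads, spikein_total_reads) {
  stopifnot(length(spikein_total_reads) == 1L)
  if (is.na(spikein_total_reads) || spikein_total_reads <= 0) {
    stop("calibration impossible: zero spike-in reads")
  }
  if (any(clone_reads < 0)) {
    stop("negative read counts")
  }
  clone_reads / spikein_total_reads
}

#' Fit the spike-in calibration model
#'
#' Ordinary least-squares fit of `log10(known_cells)` on `log10(FRV)` over
#' the spike-in ladder. The regression direction is the inversion needed
#' for estimation (cells from FRV). Spike-ins with zero reads cannot enter
#' the log-log fit; they are excluded and reported.
#'
#' @param spikeins data.frame with columns `barcode`, `known_cells` and
#'   `reads` (one row per spike-in technical replicate).
#' @return A `CalibrationModel` with elements `slope`, `intercept` (log10
#'   cells at FRV = 1), `residual_sd`, `n_points` and `n_excluded`.
#' @export
fit_calibration <- function(spikeins) {
  stopifnot(is.data.frame(spikeins),
            all(c("known_cells", "reads") %in% names(spikeins)))
  if (any(spikeins$known_cells <= 0)) {
    stop("known_cells must be positive")
  }
  total <- sum(spikeins$reads)
  if (total <= 0) {
    stop("calibration impossible: zero spike-in reads")
  }
  use <- spikeins$reads > 0
  n_excluded <- sum(!use)
  pts <- spikeins[use, , drop = FALSE]
  if (length(unique(pts$known_cells)) < 2L) {
    stop("need at least 2 distinct spike-in cell levels with nonzero reads")
  }
  frv <- compute_frv(pts$reads, total)
  fit <- stats::lm(log10(pts$known_cells) ~ log10(frv))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = suppressWarnings(summary(fit)$sigma),
                 n_points = nrow(pts),
                 n_excluded = n_excluded,
                 spikein_total_reads = total),
            class = "CalibrationModel")
}

#' @export
print.CalibrationModel <- function(x, ...) {
  cat(sprintf(
    "CalibrationModel: log10(cells) = %.4f + %.4f * log10(FRV)\n",
    x$intercept, x$slope))
  cat(sprintf("  %d spike-in points (%d zero-read excluded), residual sd %.4f\n",
              x$n_points, x$n_excluded, x$residual_sd))
  invisible(x)
}

#' Estimate absolute clone size from FRV
#'
#' Applies the calibration model: `cells = 10^(intercept + slope *
#' log10(frv))`. Monotone increasing in FRV for positive slope.
#'
#' @param frv fractional read value(s), strictly positive.
#' @param model a `CalibrationModel` from [fit_calibration()].
#' @return Estimated clone size(s) in cells.
#' @export
estimate_absolute_size <- function(frv, model) {
  stopifnot(inherits(model, "CalibrationModel"))
  if (any(frv <= 0)) {
    stop("undefined size: FRV must be strictly positive")
  }
  10^(model$intercept + model$slope * log10(frv))
}

#' Remove low-read barcodes from a count table
#'
#' Applies the read threshold used to remove possibly aberrant reads.
#' Filtering happens after error collapsing (never before), so that true
#' reads absorbed into their centroid are not lost.
#'
#' @param table a `BarcodeCountTable`.
#' @param min_reads barcodes with fewer reads are removed.
#' @return The filtered `BarcodeCountTable`; removed reads are added to a
#'   `below_min_reads` rejected bucket and the number of removed barcodes
#'   is stored in attribute `n_filtered`.
#' @export
apply_detection_filters <- function(table, min_reads) {
  stopifnot(inherits(table, "BarcodeCountTable"), min_reads >= 0)
  drop <- table$counts < min_reads
  removed_reads <- sum(table$counts[drop])
  table$counts <- table$counts[!drop]
  table$rejected <- c(table$rejected,
                      below_min_reads = as.integer(removed_reads))
  attr(table, "n_filtered") <- sum(drop)
  table
}

#' Limit of detection for a sampled tumor
#'
#' The assay detects clones of 20 cells with 95% sensitivity when the whole
#' tumor is sampled; sampling a fraction of the tumor scales the smallest
#' detectable clone accordingly: `LOD = 20 * (100 / percent sampled)`.
#'
#' @param percent_tumor_sampled percentage of the tumor taken for
#'   amplification, in (0, 100].
#' @return Limit of detection in cells.
#' @examples
#' limit_of_detection(100)  # 20 cells
#' limit_of_detection(10)   # 200 cells
#' @export
limit_of_detection <- function(percent_tumor_sampled) {
  if (any(percent_tumor_sampled <= 0) || any(percent_tumor_sampled > 100)) {
    stop("percent_tumor_sampled must be in (0, 100]")
  }
  20 * (100 / percent_tumor_sampled)
}

#' Default read threshold implied by the calibration
#'
#' The read-count threshold is chosen so that the implied size estimate of
#' a kept barcode is at least one cell under the fitted calibration.
#'
#' @param model a `CalibrationModel`.
#' @return Minimum read count (integer).
#' @export
min_reads_for_one_cell <- function(model) {
  stopifnot(inherits(model, "CalibrationModel"))
  frv_star <- 10^(-model$intercept / model$slope)
  max(1L, as.integer(ceiling(frv_star * model$spikein_total_reads)))
}

#' Quantify clones in a sample
#'
#' Joins a clone count table with the sample's spike-in stream and
#' manifest, fits the calibration, and reports FRV, absolute size and
#' limit-of-detection status per clone.
#'
#' @param clone_table `BarcodeCountTable` of clone barcodes (BC1/BC2).
#' @param spikein_table `BarcodeCountTable` of the spike-in stream (BC3).
#' @param manifest data.frame with `barcode` and `known_cells` for every
#'   spike-in control; controls missing from the reads get zero counts.
#' @param percent_tumor_sampled percentage of the tumor sampled, used for
#'   the limit of detection.
#' @param min_reads read threshold applied to the clone table before
#'   quantification; `NULL` uses [min_reads_for_one_cell()].
#' @return A data.frame with columns `sample`, `library`, `barcode`,
#'   `reads`, `frv`, `est_cells`, `pass_lod`, plus the fitted model in
#'   attribute `calibration`. Because the spike-in controls are added to
#'   the sampled aliquot, the calibrated estimate measures cells in the
#'   sample; `est_cells` is scaled by `100 / percent_tumor_sampled` to the
#'   whole-tumor clone size, the scale on which the limit of detection is
#'   defined.
#' @export
quantify_clones <- function(clone_table, spikein_table, manifest,
                            percent_tumor_sampled = 100, min_reads = NULL) {
  stopifnot(inherits(clone_table, "BarcodeCountTable"),
            inherits(spikein_table, "BarcodeCountTable"))
  reads <- spikein_table$counts[manifest$barcode]
  reads[is.na(reads)] <- 0L
  sp <- data.frame(barcode = manifest$barcode,
                   known_cells = manifest$known_cells,
                   reads = as.integer(reads), stringsAsFactors = FALSE)
  model <- fit_calibration(sp)
  if (is.null(min_reads)) {
    min_reads <- min_reads_for_one_cell(model)
  }
  tab <- apply_detection_filters(clone_table, min_reads)
  lod <- limit_of_detection(percent_tumor_sampled)
  if (length(tab$counts)) {
    frv <- compute_frv(as.integer(tab$counts), model$spikein_total_reads)
    est <- estimate_absolute_size(frv, model) * 100 / percent_tumor_sampled
  } else {
    frv <- numeric(0)
    est <- numeric(0)
  }
  out <- data.frame(sample = tab$sample_id, library = tab$library_id,
                    barcode = names(tab$counts) %||% character(0),
                    reads = as.integer(tab$counts), frv = frv,
                    est_cells = est, pass_lod = est >= lod,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "calibration") <- model
  attr(out, "limit_of_detection") <- lod
  out
}
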