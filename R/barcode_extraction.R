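# Barcode extraction: raw amplicon reads -> collapsed per-library barcode
# count tables, plus the library collision-safety simulation.
#
# Amplicon layout: each read carries a 31-bp insert (27-bp barcode followed
# by a 4-bp library ID) between constant flanks. Three staggered primer
# pairs were used to increase library complexity, so extraction accepts any
# of the three flank pairs.

#' Constant flank pairs of the staggered amplicon primers
#'
#' The three target-specific flank pairs surrounding the 31-bp barcode
#' insert. `flank5` is the constant sequence immediately 5' of the insert
#' on read 1; `flank3` is the reverse complement of the reverse primer's
#' target-specific sequence, i.e. the constant sequence immediately 3' of
#' the insert.
#'
#' @return A data.frame with columns `pair`, `flank5`, `flank3`.
#' @export
amplicon_flanks <- function() {
  fwd <- c("TAGAAGGCACAGGTCGACAG",
           "GCAACTAGAAGGCACAGGTC",
           "CAACTAGAAGGCACAGGTCG")
  rev3 <- c("GTCTAGACTCACTGGCCGTC",
            "GACTCACTGGCCGTCGTTTT",
            "AGACTCACTGGCCGTCGTTT")
  data.frame(pair = 1:3, flank5 = fwd, flank3 = revcomp(rev3),
             stringsAsFactors = FALSE)
}

REJECTION_REASONS <- c("no_flank", "length", "pattern", "quality")

#' Extract the barcode insert from amplicon reads
#'
#' Locates a known flank pair in each read, takes the sequence between the
#' flanks as the candidate insert, and applies (in order) a length filter
#' (the insert must be exactly `insert_length` bases), an alphabet/pattern
#' filter (A/C/G/T only, plus an optional regular-expression hook), and a
#' base-quality filter (minimum insert Phred score must be >=
#' `min_phred`). Reads failing any step receive a typed rejection reason.
#'
#' @param seqs character vector of read sequences.
#' @param quals character vector of Phred+33 quality strings (same lengths
#'   as `seqs`), or NULL to skip the quality filter.
#' @param flanks data.frame of flank pairs as returned by
#'   [amplicon_flanks()]; any of the pairs is accepted.
#' @param min_phred minimum acceptable Phred score of any insert base.
#' @param insert_length required insert length in bases (27-bp barcode +
#'   4-bp library ID).
#' @param pattern optional regular expression the insert must match, a hook
#'   for constrained (semi-random) barcode designs; NULL disables it.
#' @return A data.frame with columns `insert` (NA when rejected) and
#'   `reason` (NA when accepted; otherwise one of `no_flank`, `length`,
#'   `pattern`, `quality`).
#' @export
extract_barcodes <- function(seqs, quals = NULL, flanks = amplicon_flanks(),
                             min_phred = 30, insert_length = 31,
                             pattern = NULL) {
  seqs <- as.character(seqs)
  n <- length(seqs)
  if (!is.null(quals)) {
    quals <- as.character(quals)
    stopifnot(length(quals) == n)
    if (any(nchar(quals) != nchar(seqs))) {
      stop("malformed record: sequence and quality lengths differ")
    }
  }
  if (any(nchar(seqs) == 0L)) {
    stop("malformed record: empty read sequence")
  }

  start <- rep(NA_integer_, n)   # insert start
  end <- rep(NA_integer_, n)     # insert end (base before flank3)
  found5 <- logical(n)
  for (p in seq_len(nrow(flanks))) {
    f5 <- flanks$flank5[p]
    f3 <- flanks$flank3[p]
    p5 <- regexpr(f5, seqs, fixed = TRUE)
    hit5 <- p5 > 0L
    found5 <- found5 | hit5
    p3 <- regexpr(f3, seqs, fixed = TRUE)
    ok <- is.na(start) & hit5 & p3 > 0L & p3 > p5 + nchar(f5) - 1L
    start[ok] <- p5[ok] + nchar(f5)
    end[ok] <- p3[ok] - 1L
  }

  reason <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  reason[is.na(start)] <- ifelse(found5[is.na(start)], "length", "no_flank")
  # both flanks found: check exact insert length
  has <- !is.na(start)
  len_ok <- has & (end - start + 1L) == insert_length
  reason[has & !len_ok] <- "length"
  insert[len_ok] <- substr(seqs[len_ok], start[len_ok], end[len_ok])

  pat_ok <- len_ok
  if (any(len_ok)) {
    bad <- len_ok & grepl("[^ACGT]", insert)
    if (!is.null(pattern)) {
      bad <- bad | (len_ok & !grepl(pattern, insert))
    }
    reason[bad] <- "pattern"
    insert[bad] <- NA_character_
    pat_ok <- len_ok & !bad
  }

  if (!is.null(quals) && any(pat_ok)) {
    idx <- which(pat_ok)
    qsub <- substr(quals[idx], start[idx], end[idx])
    minq <- vapply(qsub, function(z) min(utf8ToInt(z)), numeric(1),
                   USE.NAMES = FALSE) - 33
    fail <- minq < min_phred
    reason[idx[fail]] <- "quality"
    insert[idx[fail]] <- NA_character_
  }

  data.frame(insert = insert, reason = reason, stringsAsFactors = FALSE)
}

#' Extract the barcode insert from a single read
#'
#' Scalar convenience wrapper around [extract_barcodes()].
#'
#' @inheritParams extract_barcodes
#' @param seq read sequence.
#' @param qual Phred+33 quality string or NULL.
#' @return A list with `barcode` (the insert, or NA) and `reason` (NA when
#'   accepted).
#' @export
extract_barcode <- function(seq, qual = NULL, flanks = amplicon_flanks(),
                            min_phred = 30, insert_length = 31,
                            pattern = NULL) {
  res <- extract_barcodes(seq, qual, flanks = flanks, min_phred = min_phred,
                          insert_length = insert_length, pattern = pattern)
  list(barcode = res$insert[1], reason = res$reason[1])
}

#' Count barcode inserts in a FASTQ file
#'
#' Reads amplicon reads (read 1 of the pair), extracts the 31-bp insert
#' from each, and tallies reads per unique insert. Rejected reads are
#' counted by reason so that reads are conserved:
#' `sum(counts) + sum(rejected) == n_reads`.
#'
#' @param fastq path to a FASTQ file, or a
#'   [Biostrings::QualityScaledDNAStringSet].
#' @inheritParams extract_barcodes
#' @return A list with `counts` (named integer vector of reads per insert,
#'   descending), `rejected` (named integer vector of reads per rejection
#'   reason) and `n_reads`.
#' @export
count_barcodes <- function(fastq, flanks = amplicon_flanks(), min_phred = 30,
                           insert_length = 31, pattern = NULL) {
  if (is.character(fastq)) {
    # the reader warns about dropped metadata columns on plain FASTQ
    fastq <- suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(fastq))
  }
  seqs <- as.character(fastq)
  quals <- as.character(Biostrings::quality(fastq))
  ext <- extract_barcodes(seqs, quals, flanks = flanks, min_phred = min_phred,
                          insert_length = insert_length, pattern = pattern)
  kept <- ext$insert[!is.na(ext$insert)]
  counts <- sort(table(kept), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  rej <- table(factor(ext$reason, levels = REJECTION_REASONS))
  list(counts = counts,
       rejected = stats::setNames(as.integer(rej), names(rej)),
       n_reads = length(seqs))
}

#' Collapse barcode counts by edit distance
#'
#' Greedy directional collapse of sequencing-error variants: barcodes are
#' visited in descending read count (ties broken lexicographically); each
#' unabsorbed barcode becomes a centroid and absorbs the reads of all
#' remaining barcodes within `max_dist` mismatches of it. Fixed-length
#' inserts make Hamming and edit distance coincide here. Total reads are
#' conserved and the result is idempotent (surviving centroids are pairwise
#' more than `max_dist` apart).
#'
#' @param counts named integer vector of reads per barcode (equal-length
#'   barcodes).
#' @param max_dist maximum Hamming distance absorbed into a centroid.
#' @return Named integer vector of collapsed counts, descending, with
#'   attribute `centroids` mapping each input barcode to its centroid.
#' @export
collapse_by_edit_distance <- function(counts, max_dist = 1) {
  if (length(counts) == 0L) {
    out <- integer(0)
    attr(out, "centroids") <- character(0)
    return(out)
  }
  stopifnot(!is.null(names(counts)), all(counts >= 1))
  ord <- order(-as.numeric(counts), names(counts))
  bcs <- names(counts)[ord]
  cts <- as.numeric(counts)[ord]
  n <- length(bcs)
  mat <- seq_to_int_matrix(bcs)
  assigned <- integer(n)  # index of centroid for each barcode, 0 = free
  out_counts <- numeric(0)
  out_names <- character(0)
  for (i in seq_len(n)) {
    if (assigned[i] > 0L) next
    assigned[i] <- i
    total <- cts[i]
    free <- which(assigned == 0L)
    if (length(free)) {
      # distance of all free barcodes to this centroid, vectorized by column
      d <- colSums(t(mat[free, , drop = FALSE]) != mat[i, ])
      absorb <- free[d <= max_dist]
      if (length(absorb)) {
        assigned[absorb] <- i
        total <- total + sum(cts[absorb])
      }
    }
    out_names <- c(out_names, bcs[i])
    out_counts <- c(out_counts, total)
  }
  ord2 <- order(-out_counts, out_names)
  out <- stats::setNames(as.integer(out_counts[ord2]), out_names[ord2])
  attr(out, "centroids") <- stats::setNames(bcs[assigned], bcs)
  out
}

#' Barcode count table for one sample and library
#'
#' Container for collapsed per-library barcode counts. Constructed by
#' [split_by_library()].
#'
#' @param sample_id sample label.
#' @param library_id library tag name (e.g. "BC1").
#' @param counts named integer vector of reads per 27-bp barcode.
#' @param spikein logical; TRUE when this library is the spike-in stream.
#' @param rejected named integer vector of rejected reads by reason.
#' @return An object of class `BarcodeCountTable`.
#' @export
barcode_count_table <- function(sample_id, library_id, counts,
                                spikein = FALSE, rejected = integer(0)) {
  structure(list(sample_id = sample_id, library_id = library_id,
                 counts = counts, spikein = spikein, rejected = rejected),
            class = "BarcodeCountTable")
}

#' @export
print.BarcodeCountTable <- function(x, ...) {
  cat(sprintf("BarcodeCountTable: sample %s, library %s%s\n", x$sample_id,
              x$library_id, if (x$spikein) " (spike-in stream)" else ""))
  cat(sprintf("  %d barcodes, %d reads (%d rejected)\n", length(x$counts),
              sum(x$counts), sum(x$rejected)))
  invisible(x)
}

#' @export
as.data.frame.BarcodeCountTable <- function(x, ...) {
  n <- length(x$counts)
  data.frame(sample = rep(x$sample_id, n), library = rep(x$library_id, n),
             barcode = names(x$counts) %||% character(0),
             reads = as.integer(x$counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split insert counts by library ID
#'
#' Each 31-bp insert carries a 4-bp library ID; inserts are routed to their
#' library by exact match of that tag. The spike-in library (by default
#' `BC3`) is flagged so downstream calibration can find it. Inserts with an
#' unknown tag are counted as rejected.
#'
#' @param counts named integer vector of reads per 31-bp insert (typically
#'   the output of [collapse_by_edit_distance()]).
#' @param library_tags named character vector mapping library names to
#'   4-base tags, e.g. `c(BC1 = "ACGT", BC2 = "CATG", BC3 = "GTCA")`.
#' @param sample_id sample label stored in each table.
#' @param tag_position where the library ID sits in the insert: `"suffix"`
#'   (final 4 bases, the default) or `"prefix"`.
#' @param spikein_tag name of the spike-in library.
#' @return Named list of [barcode_count_table()] objects, one per library
#'   tag, each with 27-bp barcodes and an `unknown_tag` rejected bucket.
#' @export
split_by_library <- function(counts, library_tags, sample_id = "sample",
                             tag_position = c("suffix", "prefix"),
                             spikein_tag = "BC3") {
  tag_position <- match.arg(tag_position)
  if (anyDuplicated(library_tags)) {
    stop("duplicate library tags")
  }
  tag_len <- unique(nchar(library_tags))
  stopifnot(length(tag_len) == 1L)
  inserts <- names(counts)
  ilen <- unique(nchar(inserts))
  if (length(inserts) && length(ilen) != 1L) {
    stop("all inserts must have equal length")
  }
  if (tag_position == "suffix") {
    tags <- substr(inserts, ilen - tag_len + 1L, ilen)
    bcs <- substr(inserts, 1L, ilen - tag_len)
  } else {
    tags <- substr(inserts, 1L, tag_len)
    bcs <- substr(inserts, tag_len + 1L, ilen)
  }
  hit <- match(tags, library_tags)
  unknown_reads <- sum(counts[is.na(hit)])
  out <- lapply(seq_along(library_tags), function(k) {
    sel <- which(!is.na(hit) & hit == k)
    cc <- stats::setNames(as.integer(counts[sel]), bcs[sel])
    cc <- cc[order(-cc, names(cc))]
    barcode_count_table(sample_id, names(library_tags)[k], cc,
                        spikein = identical(names(library_tags)[k], spikein_tag),
                        rejected = c(unknown_tag = as.integer(unknown_reads)))
  })
  stats::setNames(out, names(library_tags))
}

#' Simulate the barcode-library collision rate
#'
#' Estimates how often a random draw of `sample_size` barcodes from a
#' library (or pooled libraries) contains at least one pair within
#' `max_hamming` mismatches. Each replicate samples without replacement and
#' tests all pairs. A sufficiently diverse library keeps this fraction
#' below 1% at 1,000-barcode draws and Hamming <= 4, guaranteeing that
#' observed barcodes represent unique clones even after error collapsing.
#'
#' @param library a `BarcodeLibrary`, a character vector of barcodes, or a
#'   list of either (pooled).
#' @param sample_size barcodes drawn per replicate (>= 2).
#' @param max_hamming collision threshold in mismatches.
#' @param n_reps number of replicate draws.
#' @param seed integer seed.
#' @return Fraction of replicates containing a colliding pair, with
#'   attribute `collided` (logical per replicate).
#' @export
simulate_collision_rate <- function(library, sample_size = 1000,
                                    max_hamming = 4, n_reps = 100,
                                    seed = NULL) {
  pool <- pool_barcodes(library)
  if (sample_size < 2L) {
    stop("sample_size must be at least 2")
  }
  if (sample_size > length(pool)) {
    stop("sample_size exceeds library size")
  }
  collided <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      draw <- pool[sample.int(length(pool), sample_size)]
      min_pairwise_hamming(seq_to_int_matrix(draw)) <= max_hamming
    }, logical(1))
  })
  out <- mean(collided)
  attr(out, "collided") <- collided
  out
}

# Flatten libraries / character vectors into one barcode pool.
pool_barcodes <- function(library) {
  if (inherits(library, "BarcodeLibrary")) {
    return(library$barcodes)
  }
  if (is.character(library)) {
    return(library)
  }
  if (is.list(library)) {
    return(unlist(lapply(library, pool_barcodes), use.names = FALSE))
  }
  stop("unsupported library object")
}
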