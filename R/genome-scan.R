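# Genome-wide actual-vs-shuffled cyclizability differences.
#
# Sign convention: D = C_actual - C_randomized, so D > 0 means the genomic
# sequence is more flexible than its locally shuffled version and D < 0
# means it is stiffer than expected for its base composition.

#' Genome-wide shuffle-difference scan
#'
#' Tiles the genome into 50-bp windows (step 50, ambiguous windows
#' discarded), scores each window, then shuffles every window at the
#' single-base level `n_shuffles` times (mode configurable) and records
#' `D = C_actual - C_randomized` per window and shuffle.
#'
#' @param genome a [genome_store()].
#' @param p a predictor.
#' @param n_shuffles shuffles per window (default 5).
#' @param mode shuffle mode, "mono" (default, base-composition preserving)
#'   or "dinuc" (dinucleotide-count preserving).
#' @param window,step tiling parameters.
#' @return object of class `shuffle_diff_result`: list with `windows`
#'   (data.frame chrom, start, end), `c_actual`, `c_shuffled` (n x k
#'   matrix), `diffs` (n x k matrix, `c_actual - c_shuffled`), `summary`
#'   (mean, sd, n of the pooled diffs), and `per_window_mean`.
#' @export
genome_shuffle_diff <- function(genome, p, n_shuffles = 5L,
                                mode = c("mono", "dinuc"),
                                window = 50L, step = 50L) {
  mode <- match.arg(mode)
  tiles <- tile_genome(genome, window, step)
  if (nrow(tiles) == 0L) stop("no retained windows after tiling")
  shuf <- if (mode == "mono") shuffle_mono else shuffle_dinuc
  c_actual <- predict_c0(p, tiles$seq)
  k <- as.integer(n_shuffles)
  c_shuffled <- matrix(NA_real_, nrow(tiles), k)
  for (j in seq_len(k)) {
    shuffled <- vapply(tiles$seq, shuf, character(1L), USE.NAMES = FALSE)
    c_shuffled[, j] <- predict_c0(p, shuffled)
  }
  diffs <- c_actual - c_shuffled
  structure(list(
    windows = tiles[, c("chrom", "start", "end")],
    c_actual = c_actual, c_shuffled = c_shuffled, diffs = diffs,
    summary = list(mean = mean(diffs), sd = stats::sd(as.vector(diffs)),
                   n = length(diffs)),
    per_window_mean = rowMeans(diffs),
    n_shuffles = k, mode = mode
  ), class = "shuffle_diff_result")
}

#' @export
print.shuffle_diff_result <- function(x, ...) {
  cat(sprintf("<shuffle_diff_result> %d windows x %d %s-shuffles\n",
              nrow(x$windows), x$n_shuffles, x$mode))
  cat(sprintf("  pooled D = C_a - C_r: mean %.4g, sd %.4g, n %d\n",
              x$summary$mean, x$summary$sd, x$summary$n))
  invisible(x)
}

#' Label windows by containment in a set of intervals
#'
#' Windows fully contained in the (merged) intervals are `inside`, windows
#' with zero overlap are `outside`, partially overlapping windows are
#' `straddling` (excluded from inside/outside comparisons, e.g. the
#' exon/non-exon stratification of a shuffle scan).
#'
#' @param windows data.frame with columns chrom, start, end (0-based
#'   half-open).
#' @param intervals data.frame with columns chrom, start, end (0-based
#'   half-open, e.g. from [read_bed()]); may be empty.
#' @return character vector of labels, one per window.
#' @export
label_windows_by_intervals <- function(windows, intervals) {
  labels <- rep("outside", nrow(windows))
  if (is.null(intervals) || nrow(intervals) == 0L) return(labels)
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0L) next
    w_ir <- IRanges::IRanges(start = windows$start[wi] + 1L,
                             end = windows$end[wi])
    iv_ir <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L,
                                              end = iv$end))
    hits <- IRanges::findOverlaps(w_ir, iv_ir)
    if (length(hits) == 0L) next
    inter <- IRanges::pintersect(w_ir[S4Vectors::queryHits(hits)],
                                 iv_ir[S4Vectors::subjectHits(hits)])
    cov <- tapply(IRanges::width(inter), S4Vectors::queryHits(hits), sum)
    q <- as.integer(names(cov))
    full <- cov == IRanges::width(w_ir)[q]
    labels[wi[q[full]]] <- "inside"
    labels[wi[q[!full]]] <- "straddling"
  }
  labels
}
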