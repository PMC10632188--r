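# Anchor-centered metaprofiles of predicted cyclizability and composition.
#
# Offset convention: a profile value at offset o is the mean over anchors of
# the rc-averaged prediction for the 50-bp window whose 25th base (1-based
# within the window) sits at offset o; the window therefore spans offsets
# o-24 .. o+25. The profile domain is every offset whose full window fits
# inside the extracted -flank..+flank region: o in [24-flank, flank-25].

WINDOW_BP <- 50L
ANCHOR_OFFSET <- 24L   # 0-based position of the "25th base" within a window

profile_offsets <- function(flank) seq.int(24L - flank, flank - 25L)

new_positional_profile <- function(offsets, mean, sd, n, meta = list()) {
  structure(data.frame(offset = offsets, mean = mean, sd = sd, n = n),
            class = c("positional_profile", "data.frame"), meta = meta)
}

#' @export
print.positional_profile <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<positional_profile> offsets %d..%d, %d anchors%s\n",
              min(x$offset), max(x$offset), max(x$n),
              if (!is.null(meta$mode)) paste0(", mode ", meta$mode) else ""))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

# windows of a region string for all profile offsets
.region_windows <- function(region, flank) {
  o <- profile_offsets(flank)
  starts <- o - ANCHOR_OFFSET + flank + 1L    # 1-based index into region
  substring(region, starts, starts + WINDOW_BP - 1L)
}

.profile_from_score_matrix <- function(scores, offsets, meta) {
  # scores: n_offsets x n_regions, NA for dropped windows
  n <- rowSums(!is.na(scores))
  if (all(n == 0L)) stop("zero usable anchors")
  mu <- rowMeans(scores, na.rm = TRUE)
  sdv <- apply(scores, 1L, stats::sd, na.rm = TRUE)
  new_positional_profile(offsets, mu, sdv, n, meta)
}

.score_regions <- function(regions, p, flank, transform = identity) {
  offsets <- profile_offsets(flank)
  n_off <- length(offsets)
  scores <- matrix(NA_real_, n_off, length(regions))
  # chunk anchors to bound peak memory of the window vector
  chunk <- max(1L, 100000L %/% n_off)
  for (s in seq.int(1L, length(regions), by = chunk)) {
    e <- min(s + chunk - 1L, length(regions))
    wins <- unlist(lapply(regions[s:e], .region_windows, flank = flank),
                   use.names = FALSE)
    wins <- transform(wins)
    scores[, s:e] <- matrix(predict_c0(p, wins, na_ambiguous = TRUE), n_off)
  }
  list(scores = scores, offsets = offsets)
}

#' Anchor-centered mean cyclizability profile
#'
#' For each anchor (e.g. a TSS) the region covering offsets -flank..+flank
#' is extracted in transcription orientation and every 50-bp window inside
#' it is scored with reverse-complement averaging; the profile reports the
#' per-offset mean, SD and count across anchors. Anchors too close to a
#' chromosome edge are skipped with a warning; windows containing ambiguous
#' letters are dropped from the per-offset counts.
#'
#' @param genome a [genome_store()].
#' @param anchors data.frame with columns chrom, pos, strand (e.g. from
#'   [read_tss_from_gff()], or interval midpoints).
#' @param p a predictor.
#' @param flank flank size in bp (>= 25; 525 reproduces a TSS metaprofile
#'   over roughly -500..+500).
#' @return a `positional_profile` data.frame (offset, mean, sd, n).
#' @export
anchored_mean_profile <- function(genome, anchors, p, flank = 525L) {
  regions <- extract_anchored_regions(genome, anchors, flank)
  regions <- regions[!is.na(regions)]
  if (length(regions) == 0L) stop("zero usable anchors")
  sc <- .score_regions(regions, p, flank)
  .profile_from_score_matrix(sc$scores, sc$offsets,
                             list(mode = "actual", flank = flank))
}

#' Randomized anchor-centered profiles
#'
#' Rebuilds the anchored profile under one of the sequence null models:
#' \describe{
#'   \item{mono_h / dinuc_h}{"horizontal": every 50-bp window is
#'     independently shuffled (mononucleotide or exact
#'     dinucleotide-preserving) before prediction.}
#'   \item{mono_v / dinuc_v}{"vertical": whole regions are resampled from a
#'     position-specific base model fit to all anchor regions (marginal or
#'     conditional first-order), then profiled.}
#'   \item{matched_pair}{per window, one dinucleotide shuffle and one
#'     distance-matched mononucleotide shuffle with the same number of
#'     matches to the parent window; returns both profiles and the paired
#'     per-window score differences.}
#' }
#'
#' @inheritParams anchored_mean_profile
#' @param mode one of "mono_h", "dinuc_h", "mono_v", "dinuc_v",
#'   "matched_pair".
#' @param n_reps independent randomization replicates pooled into the
#'   profile.
#' @return a `positional_profile`; for `matched_pair` a list with elements
#'   `dinuc` and `mono_matched` (profiles) and `diffs` (data.frame of paired
#'   per-window differences randomized - actual).
#' @export
randomized_profile <- function(genome, anchors, p, flank = 525L,
                               mode = c("mono_h", "dinuc_h", "mono_v",
                                        "dinuc_v", "matched_pair"),
                               n_reps = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_reps >= 1L)
  regions <- extract_anchored_regions(genome, anchors, flank)
  regions <- regions[!is.na(regions)]
  if (length(regions) == 0L) stop("zero usable anchors")

  if (mode %in% c("mono_v", "dinuc_v")) {
    usable <- regions[!grepl("[^ACGT]", regions)]
    model <- fit_positional_model(regions)
    synth <- sample_vertical(model, if (mode == "mono_v") "mono" else "dinuc",
                             n = length(usable) * n_reps)
    sc <- .score_regions(synth, p, flank)
    return(.profile_from_score_matrix(sc$scores, sc$offsets,
                                      list(mode = mode, flank = flank,
                                           n_reps = n_reps)))
  }

  if (mode %in% c("mono_h", "dinuc_h")) {
    shuf <- if (mode == "mono_h") shuffle_mono else shuffle_dinuc
    transform <- function(wins) {
      ok <- !grepl("[^ACGT]", wins)
      wins[ok] <- vapply(wins[ok], shuf, character(1L), USE.NAMES = FALSE)
      wins
    }
    reps <- lapply(seq_len(n_reps), function(r) {
      .score_regions(regions, p, flank, transform = transform)
    })
    scores <- do.call(cbind, lapply(reps, `[[`, "scores"))
    return(.profile_from_score_matrix(scores, reps[[1L]]$offsets,
                                      list(mode = mode, flank = flank,
                                           n_reps = n_reps)))
  }

  # matched_pair: paired dinucleotide and distance-matched mono shuffles
  offsets <- profile_offsets(flank)
  n_off <- length(offsets)
  nreg <- length(regions)
  sc_d <- matrix(NA_real_, n_off, nreg)
  sc_m <- matrix(NA_real_, n_off, nreg)
  diffs <- vector("list", nreg)
  actual <- .score_regions(regions, p, flank)$scores
  for (ri in seq_len(nreg)) {
    wins <- .region_windows(regions[ri], flank)
    dw <- rep(NA_character_, n_off)
    mw <- rep(NA_character_, n_off)
    for (wi in seq_len(n_off)) {
      w <- wins[wi]
      if (grepl("[^ACGT]", w)) next
      for (attempt in 1:3) {
        d <- shuffle_dinuc(w)
        m <- tryCatch(matched_distance_shuffle(w, count_matches(w, d)),
                      dnaflex_shuffle_error = function(e) NULL)
        if (!is.null(m)) { dw[wi] <- d; mw[wi] <- m; break }
      }
    }
    sc_d[, ri] <- predict_c0(p, dw, na_ambiguous = TRUE)
    sc_m[, ri] <- predict_c0(p, mw, na_ambiguous = TRUE)
    diffs[[ri]] <- data.frame(offset = offsets,
                              diff_dinuc = sc_d[, ri] - actual[, ri],
                              diff_mono = sc_m[, ri] - actual[, ri])
  }
  list(dinuc = .profile_from_score_matrix(sc_d, offsets,
                                          list(mode = "matched_dinuc", flank = flank)),
       mono_matched = .profile_from_score_matrix(sc_m, offsets,
                                                 list(mode = "matched_mono", flank = flank)),
       diffs = do.call(rbind, diffs))
}

#' Position-wise dinucleotide log-ratio profile
#'
#' For aligned equal-length sequences, the natural log of the ratio between
#' the observed frequency of each dinucleotide at each offset and its
#' expected frequency. The default expected model is the product of the
#' position-pooled mononucleotide frequencies; alternatives are the pooled
#' dinucleotide frequencies or a user-supplied 16-vector. Cells with zero
#' observed count, or an expected frequency of zero, are flagged undefined
#' (NA), never infinite.
#'
#' @param aligned_seqs character vector of equal-length sequences.
#' @param expected "mono_product", "pooled_dinuc", or a numeric 16-vector of
#'   expected frequencies in AA..TT order.
#' @param start_offset offset label of the first sequence position (e.g.
#'   `-flank` for TSS-centered regions); offsets label the first base of
#'   each dinucleotide step.
#' @return object of class `dinuc_logratio_profile`: list with labels,
#'   offsets, values (16 x n_offsets matrix of ln(obs/exp)), undefined
#'   (logical matrix), expected (the 16 expected frequencies).
#' @export
dinuc_logratio_profile <- function(aligned_seqs,
                                   expected = "mono_product",
                                   start_offset = 0L) {
  if (length(aligned_seqs) < 1L) stop("need at least one sequence")
  m <- seqs_int_matrix(aligned_seqs)
  L <- nrow(m)
  if (L < 2L) stop("sequences must have length >= 2")
  idx <- 4L * m[-L, , drop = FALSE] + m[-1L, , drop = FALSE] + 1L
  obs <- matrix(0, 16L, L - 1L, dimnames = list(DINUCS, NULL))
  for (d in 1:16) obs[d, ] <- rowSums(idx == d, na.rm = TRUE)
  totals <- colSums(obs)
  freq <- sweep(obs, 2L, pmax(totals, 1L), "/")

  if (is.numeric(expected)) {
    if (length(expected) != 16L) stop("expected must have 16 entries")
    e <- expected / sum(expected)
  } else if (identical(expected, "mono_product")) {
    q <- tabulate(m + 1L, 4L)
    q <- q / sum(q)
    e <- as.vector(t(outer(q, q)))   # AA,AC,AG,AT,CA,... order
  } else if (identical(expected, "pooled_dinuc")) {
    e <- rowSums(obs) / sum(obs)
  } else {
    stop("unknown expected model")
  }
  names(e) <- DINUCS

  undef <- obs == 0 | matrix(e == 0, 16L, L - 1L)
  vals <- matrix(NA_real_, 16L, L - 1L, dimnames = list(DINUCS, NULL))
  ok <- !undef
  vals[ok] <- log(freq[ok] / matrix(e, 16L, L - 1L)[ok])
  structure(list(labels = DINUCS,
                 offsets = seq.int(start_offset, length.out = L - 1L),
                 values = vals, undefined = undef, expected = e),
            class = "dinuc_logratio_profile")
}

#' Per-position cyclizability track
#'
#' Scores every 50-bp window in `[start, end)` (step `step`) and assigns
#' each score to the window's 25th base. Positions whose full window does
#' not fit, or whose window contains ambiguous letters, are absent.
#'
#' @param genome a [genome_store()].
#' @param chrom chromosome id.
#' @param start,end 0-based half-open region, `end - start >= 50`.
#' @param p a predictor.
#' @param step step size in bp.
#' @return data.frame with columns chrom, pos (0-based), score.
#' @export
predict_track <- function(genome, chrom, start, end, p, step = 1L) {
  L <- chrom_length(genome, chrom)
  start <- max(0L, start); end <- min(end, L)
  if (end - start < WINDOW_BP) stop("region shorter than 50 bp")
  win_starts <- seq.int(start, end - WINDOW_BP, by = step)
  seqs <- substring(genome[[chrom]], win_starts + 1L, win_starts + WINDOW_BP)
  score <- predict_c0(p, seqs, na_ambiguous = TRUE)
  keep <- !is.na(score)
  data.frame(chrom = chrom, pos = win_starts[keep] + ANCHOR_OFFSET,
             score = score[keep])
}

#' Sample autocorrelation function
#'
#' Standard mean-removed, variance-normalized sample ACF computed by the
#' direct O(N * lag) definition: `acf[k] = sum((x_t - xbar)(x_{t+k} - xbar))
#' / sum((x_t - xbar)^2)`; `acf[0] = 1` always.
#'
#' @param values finite numeric vector, longer than `max_lag`.
#' @param max_lag maximum lag (>= 0).
#' @return numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
acf_signal <- function(values, max_lag) {
  if (any(!is.finite(values))) stop("values must be finite")
  N <- length(values)
  if (max_lag < 0L || N <= max_lag) stop("need length(values) > max_lag >= 0")
  xc <- values - mean(values)
  denom <- sum(xc^2)
  if (denom == 0) stop("zero variance: ACF undefined")
  out <- numeric(max_lag + 1L)
  out[1L] <- 1
  for (k in seq_len(max_lag)) {
    out[k + 1L] <- sum(xc[seq_len(N - k)] * xc[(k + 1L):N]) / denom
  }
  out
}

#' Write a positional profile as TSV
#' @param profile a `positional_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
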