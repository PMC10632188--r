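# Effect-size comparisons of predicted flexibility at genomic feature sets:
# variant-bearing windows, methylation-context windows, TF motif sites, and
# per-position signal tracks.
#
# "Window containing a position" means the 50-bp window whose 25th base is
# the position, consistent with the track convention.

#' Classify windows by overlapping variant types
#'
#' A variant hits a window when its reference span `[pos, pos + ref_span)`
#' overlaps the window `[start, end)`. Windows are labelled `none`,
#' `snp_only`, `indel_only` or `snp_and_indel`.
#'
#' @param windows data.frame with columns chrom, start, end.
#' @param variants data.frame with columns chrom, pos (0-based), vtype
#'   ("SNP", "INS" or "DEL"), ref_span (>= 1; 1 for SNPs and insertions).
#' @return character vector of labels, one per window.
#' @export
classify_variant_windows <- function(windows, variants) {
  has_snp <- logical(nrow(windows))
  has_indel <- logical(nrow(windows))
  if (nrow(variants) > 0L) {
    if (any(variants$ref_span < 1L)) stop("ref_span must be >= 1")
    if (any(variants$vtype == "SNP" & variants$ref_span != 1L)) {
      stop("SNP records must have ref_span 1")
    }
    for (ch in unique(windows$chrom)) {
      wi <- which(windows$chrom == ch)
      va <- variants[variants$chrom == ch, , drop = FALSE]
      if (nrow(va) == 0L) next
      w_ir <- IRanges::IRanges(start = windows$start[wi] + 1L,
                               end = windows$end[wi])
      v_ir <- IRanges::IRanges(start = va$pos + 1L,
                               end = va$pos + va$ref_span)
      hits <- IRanges::findOverlaps(w_ir, v_ir)
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      has_snp[wi] <- has_snp[wi] |
        tabulate(q[va$vtype[s] == "SNP"], length(wi)) > 0L
      has_indel[wi] <- has_indel[wi] |
        tabulate(q[va$vtype[s] %in% c("INS", "DEL")], length(wi)) > 0L
    }
  }
  ifelse(has_snp & has_indel, "snp_and_indel",
         ifelse(has_snp, "snp_only",
                ifelse(has_indel, "indel_only", "none")))
}

.window_seqs <- function(genome, windows) {
  if (!is.null(windows$seq)) return(windows$seq)
  vapply(seq_len(nrow(windows)), function(i) {
    substr(genome[[windows$chrom[i]]], windows$start[i] + 1L, windows$end[i])
  }, character(1L))
}

#' Compare predicted flexibility between two window sets
#'
#' Scores both sets with reverse-complement averaging and reports the
#' pooled-SD Cohen's d of set A versus set B (`d > 0` means A is more
#' flexible) together with a Welch t-test.
#'
#' @param genome a [genome_store()] (may be NULL when both window sets carry
#'   a `seq` column).
#' @param windows_A,windows_B data.frames with columns chrom, start, end
#'   (and optionally seq).
#' @param p a predictor.
#' @return an `effect_size_report` (see [cohens_d()]) with extra fields
#'   `welch` (the Welch test) and per-group scores in attributes.
#' @export
compare_feature_windows <- function(genome, windows_A, windows_B, p) {
  if (nrow(windows_A) < 2L || nrow(windows_B) < 2L) {
    stop("both window sets need at least 2 windows")
  }
  sa <- predict_c0(p, .window_seqs(genome, windows_A), na_ambiguous = TRUE)
  sb <- predict_c0(p, .window_seqs(genome, windows_B), na_ambiguous = TRUE)
  sa <- sa[!is.na(sa)]; sb <- sb[!is.na(sb)]
  if (length(sa) < 2L || length(sb) < 2L) {
    stop("fewer than 2 scorable windows in a set")
  }
  rep_ <- cohens_d(sa, sb)
  rep_$welch <- two_sample_t(sa, sb, "welch")
  attr(rep_, "scores_A") <- sa
  attr(rep_, "scores_B") <- sb
  rep_
}

#' Enumerate cytosine methylation contexts on a chromosome
#'
#' Finds every cytosine on either strand (a C on the plus strand, or a G on
#' the plus strand read as a C on the minus strand) with a full 3-base
#' downstream context on the C's strand, and classifies it by the plant
#' methylation-context rule: CG if the second base is G, CHG if the third
#' base is G (second in A/C/T), otherwise CHH. Cytosines within 2 bp of the
#' 3' edge, or with ambiguous context letters, are skipped.
#'
#' @param genome a [genome_store()].
#' @param chrom chromosome id.
#' @return data.frame with columns chrom, pos (0-based position of the C on
#'   the genome), strand, context3, context_class; the `methylated` flag is
#'   left unset (NA).
#' @export
find_cytosine_contexts <- function(genome, chrom) {
  s <- genome[[chrom]]
  if (is.null(s)) stop(sprintf("unknown chromosome '%s'", chrom))
  L <- nchar(s)
  if (L < 3L) stop("chromosome shorter than 3 bp")
  v <- utf8ToInt(s)
  Cp <- which(v == utf8ToInt("C"))
  Gp <- which(v == utf8ToInt("G"))
  out <- list()
  plus <- Cp[Cp <= L - 2L]
  if (length(plus) > 0L) {
    ctx <- substring(s, plus, plus + 2L)
    ok <- !grepl("[^ACGT]", ctx)
    out$plus <- data.frame(chrom = chrom, pos = plus[ok] - 1L, strand = "+",
                           context3 = ctx[ok], stringsAsFactors = FALSE)
  }
  minus <- Gp[Gp >= 3L]
  if (length(minus) > 0L) {
    raw <- substring(s, minus - 2L, minus)
    ok <- !grepl("[^ACGT]", raw)
    out$minus <- data.frame(chrom = chrom, pos = minus[ok] - 1L, strand = "-",
                            context3 = revcomp(raw[ok]),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context3 = character(),
                      context_class = character(),
                      methylated = logical()))
  }
  res <- res[order(res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res$context_class <- classify_context3(res$context3)
  res$methylated <- NA
  res
}

#' Classify a 3-base cytosine context
#' @param context3 character vector of 3-base strings starting with C.
#' @return "CG", "CHG" or "CHH" per string.
#' @export
classify_context3 <- function(context3) {
  if (any(substr(context3, 1L, 1L) != "C")) {
    stop("context3 must start with C")
  }
  b2 <- substr(context3, 2L, 2L)
  b3 <- substr(context3, 3L, 3L)
  ifelse(b2 == "G", "CG", ifelse(b3 == "G", "CHG", "CHH"))
}

.positions_in_intervals <- function(chrom, pos, intervals) {
  keep <- logical(length(pos))
  for (ch in unique(chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0L) next
    sel <- chrom == ch
    p_ir <- IRanges::IRanges(start = pos[sel] + 1L, width = 1L)
    iv_ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    keep[sel] <- IRanges::countOverlaps(p_ir, iv_ir) > 0L
  }
  keep
}

.site_windows <- function(sites) {
  data.frame(chrom = sites$chrom, start = sites$pos - 24L,
             end = sites$pos + 26L, stringsAsFactors = FALSE)
}

#' Compare flexibility at methylated vs unmethylated cytosines
#'
#' For each methylation context class (and optionally each specific
#' triplet), the 50-bp windows whose 25th base is a methylated cytosine
#' inside the promoter intervals are compared to windows around
#' unmethylated cytosines of the same context, also inside promoters.
#' Contexts with fewer than 2 sites in either group are skipped with a
#' warning.
#'
#' @param genome a [genome_store()].
#' @param sites data.frame as from [find_cytosine_contexts()] with the
#'   `methylated` flag set (see [simulate_methylation_set()]).
#' @param promoters data.frame of intervals (chrom, start, end), e.g. 300 bp
#'   upstream of each TSS (see [promoter_intervals()]).
#' @param p a predictor.
#' @param by_context3 also compare each specific 3-base context.
#' @return named list of `effect_size_report`s, one per context class (keys
#'   "CG", "CHG", "CHH"), plus one per triplet when `by_context3 = TRUE`.
#' @export
methylation_comparison <- function(genome, sites, promoters, p,
                                   by_context3 = FALSE) {
  if (is.null(promoters) || nrow(promoters) == 0L) stop("promoters required")
  if (all(is.na(sites$methylated))) stop("sites must carry methylated flags")
  inprom <- .positions_in_intervals(sites$chrom, sites$pos, promoters)
  sites <- sites[inprom, , drop = FALSE]
  groups <- split(seq_len(nrow(sites)), sites$context_class)
  if (by_context3) {
    groups <- c(groups, split(seq_len(nrow(sites)), sites$context3))
  }
  out <- list()
  for (g in names(groups)) {
    sub <- sites[groups[[g]], , drop = FALSE]
    a <- sub[sub$methylated %in% TRUE, , drop = FALSE]
    b <- sub[sub$methylated %in% FALSE, , drop = FALSE]
    if (nrow(a) < 2L || nrow(b) < 2L) {
      warning(sprintf("context %s skipped: fewer than 2 sites in a group", g))
      next
    }
    out[[g]] <- compare_feature_windows(genome, .site_windows(a),
                                        .site_windows(b), p)
  }
  out
}

#' Promoter intervals upstream of TSSs
#'
#' @param tss data.frame with chrom, pos, strand (see [read_tss_from_gff()]).
#' @param genome a [genome_store()] for bounds clipping.
#' @param upstream promoter length in bp (300 for the methylation/variant
#'   analyses, 1000 for TF-binding and break-site analyses).
#' @return data.frame of 0-based half-open intervals (chrom, start, end),
#'   clipped to chromosome bounds; empty intervals dropped.
#' @export
promoter_intervals <- function(tss, genome, upstream = 300L) {
  start <- ifelse(tss$strand == "+", tss$pos - upstream, tss$pos + 1L)
  end <- ifelse(tss$strand == "+", tss$pos, tss$pos + 1L + upstream)
  lens <- vapply(tss$chrom, function(ch) chrom_length(genome, ch), integer(1L))
  start <- pmax(start, 0L)
  end <- pmin(end, lens)
  keep <- end > start
  data.frame(chrom = tss$chrom[keep], start = start[keep], end = end[keep])
}

#' Site-centered profiles for bound vs all motif occurrences
#'
#' Anchors every motif interval at its midpoint (rounded down for even
#' lengths) and builds anchored mean profiles over -flank..+flank for the
#' bound subset and for all sites. Bound/unbound determination (motif scan +
#' in vitro binding overlap) is upstream input, consumed as intervals with a
#' logical `bound` column.
#'
#' @param genome a [genome_store()].
#' @param motif_sites data.frame with columns chrom, start, end, bound
#'   (logical), optionally strand.
#' @param p a predictor.
#' @param flank profile flank (default 200).
#' @param min_sites minimum sites per set before a low-coverage warning
#'   (default 100); profiles are still computed.
#' @return list with elements `bound` and `all`, both `positional_profile`s.
#' @export
tf_bound_vs_unbound <- function(genome, motif_sites, p, flank = 200L,
                                min_sites = 100L) {
  if (nrow(motif_sites) == 0L) stop("no motif sites")
  mid <- motif_sites$start + (motif_sites$end - motif_sites$start - 1L) %/% 2L
  strand <- if (!is.null(motif_sites$strand) &&
                all(motif_sites$strand %in% c("+", "-"))) {
    motif_sites$strand
  } else rep("+", nrow(motif_sites))
  anchors <- data.frame(chrom = motif_sites$chrom, pos = mid, strand = strand)
  bound <- which(motif_sites$bound)
  if (length(bound) < min_sites || nrow(motif_sites) < min_sites) {
    warning(sprintf("fewer than %d sites in a set; profiles computed anyway",
                    min_sites))
  }
  if (length(bound) == 0L) stop("no bound sites")
  list(bound = anchored_mean_profile(genome, anchors[bound, , drop = FALSE],
                                     p, flank),
       all = anchored_mean_profile(genome, anchors, p, flank))
}

#' Correlate a per-position track with predicted cyclizability
#'
#' For each non-zero track position outside the excluded intervals, the
#' 50-bp window whose 25th base is that position is scored, and the Pearson
#' correlation between track values and predictions is returned (e.g.
#' meiotic break-site signal vs flexibility, with the centromere excluded).
#'
#' @param track data.frame with columns chrom, pos (0-based), value (see
#'   [read_bedgraph()]).
#' @param genome a [genome_store()].
#' @param p a predictor.
#' @param exclude optional data.frame of intervals (chrom, start, end) to
#'   drop.
#' @param keep_zero keep zero-valued track positions (default FALSE).
#' @return list with elements r (Pearson correlation) and n (positions
#'   used). Fewer than 2 usable positions is an error.
#' @export
positionwise_correlation <- function(track, genome, p, exclude = NULL,
                                     keep_zero = FALSE) {
  use <- if (keep_zero) rep(TRUE, nrow(track)) else track$value != 0
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    use <- use & !.positions_in_intervals(track$chrom, track$pos, exclude)
  }
  track <- track[use, , drop = FALSE]
  if (nrow(track) > 0L) {
    lens <- vapply(track$chrom, function(ch) chrom_length(genome, ch),
                   integer(1L))
    fits <- track$pos - 24L >= 0L & track$pos + 26L <= lens
    track <- track[fits, , drop = FALSE]
  }
  if (nrow(track) < 2L) stop("fewer than 2 usable track positions")
  preds <- predict_c0(p, .window_seqs(genome, .site_windows(
    data.frame(chrom = track$chrom, pos = track$pos))), na_ambiguous = TRUE)
  ok <- !is.na(preds)
  if (sum(ok) < 2L) stop("fewer than 2 usable track positions")
  list(r = pearson_r(track$value[ok], preds[ok]), n = sum(ok))
}
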