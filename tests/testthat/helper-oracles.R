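# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: scoring walks the sequence character by character,
# profiles are assembled by explicit double loops, overlaps by all-pairs
# scans.

BASES4 <- c("A", "C", "G", "T")

brute_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# character-walk linear dinucleotide score
brute_linear_score <- function(model, s) {
  chars <- strsplit(s, "")[[1]]
  total <- model$b
  for (i in seq_len(length(chars) - 1L)) {
    total <- total + model$w[[paste0(chars[i], chars[i + 1L])]]
  }
  total
}

brute_rc_avg <- function(model, s) {
  (brute_linear_score(model, s) + brute_linear_score(model, brute_revcomp(s))) / 2
}

# anchors x offsets double loop; window for offset o spans o-24 .. o+25
brute_profile <- function(genome, anchors, model, flank) {
  offsets <- seq.int(24L - flank, flank - 25L)
  acc <- matrix(NA_real_, length(offsets), nrow(anchors))
  for (a in seq_len(nrow(anchors))) {
    chrom <- unclass(genome)[[anchors$chrom[a]]]
    pos <- anchors$pos[a]
    if (pos - flank < 0L || pos + flank >= nchar(chrom)) next
    region <- substr(chrom, pos - flank + 1L, pos + flank + 1L)
    if (anchors$strand[a] == "-") region <- brute_revcomp(region)
    for (oi in seq_along(offsets)) {
      o <- offsets[oi]
      st <- (o - 24L) + flank + 1L
      win <- substr(region, st, st + 49L)
      if (grepl("[^ACGT]", win)) next
      acc[oi, a] <- brute_rc_avg(model, win)
    }
  }
  data.frame(offset = offsets,
             mean = rowMeans(acc, na.rm = TRUE),
             n = rowSums(!is.na(acc)))
}

brute_count_dinucs <- function(s) {
  chars <- strsplit(s, "")[[1]]
  labs <- as.vector(t(outer(BASES4, BASES4, paste0)))
  counts <- setNames(integer(16), labs)
  for (i in seq_len(length(chars) - 1L)) {
    d <- paste0(chars[i], chars[i + 1L])
    counts[d] <- counts[d] + 1L
  }
  counts
}

brute_base_counts <- function(s) {
  table(factor(strsplit(s, "")[[1]], levels = BASES4))
}

# all-pairs window/interval overlap labels
brute_interval_labels <- function(windows, intervals) {
  vapply(seq_len(nrow(windows)), function(i) {
    ws <- windows$start[i]; we <- windows$end[i]
    cover <- rep(FALSE, we - ws)
    any_overlap <- FALSE
    for (j in seq_len(nrow(intervals))) {
      if (intervals$chrom[j] != windows$chrom[i]) next
      lo <- max(ws, intervals$start[j]); hi <- min(we, intervals$end[j])
      if (hi > lo) {
        any_overlap <- TRUE
        cover[(lo - ws + 1L):(hi - ws)] <- TRUE
      }
    }
    if (!any_overlap) "outside" else if (all(cover)) "inside" else "straddling"
  }, character(1L))
}

brute_variant_labels <- function(windows, variants) {
  vapply(seq_len(nrow(windows)), function(i) {
    snp <- FALSE; indel <- FALSE
    for (j in seq_len(nrow(variants))) {
      if (variants$chrom[j] != windows$chrom[i]) next
      vs <- variants$pos[j]; ve <- vs + variants$ref_span[j]
      if (vs < windows$end[i] && ve > windows$start[i]) {
        if (variants$vtype[j] == "SNP") snp <- TRUE else indel <- TRUE
      }
    }
    if (snp && indel) "snp_and_indel" else if (snp) "snp_only"
    else if (indel) "indel_only" else "none"
  }, character(1L))
}

# FFT-based ACF (independent route for the direct O(N*lag) implementation)
fft_acf <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  pad <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(xc, rep(0, pad - n)))
  acov <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:(max_lag + 1L)] / pad
  acov / acov[1L]
}

# deterministic toy genome with a sprinkle of Ns
toy_genome <- function(len = 600L, seed = 11L, n_positions = integer(0)) {
  withr::with_seed(seed, {
    s <- paste(sample(BASES4, len, replace = TRUE), collapse = "")
  })
  for (p in n_positions) substr(s, p, p) <- "N"
  genome_store(c(chr1 = s))
}

# predictor stub scoring listed sequences by lookup; reverse complements
# score identically so rc-averaging returns the mapped value
lookup_predictor <- function(map) {
  full <- c(map, setNames(map, vapply(names(map), brute_revcomp,
                                      character(1))))
  as_flex_predictor(function(seqs) unname(full[seqs]), kind = "lookup")
}

# mononucleotide-composition-only predictor (invariant to any mono shuffle)
mono_composition_predictor <- function(coef = c(A = 0.31, C = -0.2,
                                                G = 0.11, T = -0.07)) {
  as_flex_predictor(function(seqs) {
    vapply(seqs, function(s) {
      sum(coef * as.vector(brute_base_counts(s)))
    }, numeric(1L), USE.NAMES = FALSE)
  }, kind = "mono_composition")
}
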