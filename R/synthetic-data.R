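# Synthetic inputs with known ground truth: genomes with planted
# TSS-proximal positional dinucleotide structure, loop-seq-style score
# libraries, and variant/methylation annotations with planted or null
# associations. Every generator is a pure function of its seed.

#' Default linear dinucleotide ground-truth model
#'
#' Strand-symmetric (w[d] = w[revcomp(d)]) additive dinucleotide model used
#' as synthetic ground truth. Weights follow the field's qualitative
#' ordering of dinucleotide step flexibility: the pyrimidine-purine TA step
#' is the most flexible, A-tract steps (AA/TT) the most rigid, GA/TC
#' mildly rigid; the intercept centers scores slightly below zero. Over
#' random 50-mers the score SD is about 0.5, comparable to measured
#' intrinsic cyclizability scores.
#'
#' @param asymmetry optional additive perturbation breaking strand symmetry
#'   (added to w["TA"] only), used to exercise the rc-averaging contract.
#' @return a [linear_dinuc_model()].
#' @export
default_truth_model <- function(asymmetry = 0) {
  w <- c(AA = -0.15, AC = -0.02, AG = -0.05, AT = 0.12,
         CA = 0.08, CC = -0.03, CG = 0.06, CT = -0.05,
         GA = -0.09, GC = 0.04, GG = -0.03, GT = -0.02,
         TA = 0.20, TC = -0.09, TG = 0.08, TT = -0.15)
  w["TA"] <- w["TA"] + asymmetry
  linear_dinuc_model(w, b = -0.2)
}

#' Position-specific promoter Markov model with a planted flexibility band
#'
#' Builds a `positional_base_model` over offsets -flank..+flank whose
#' transition matrices inside `flex_band` are a doubly stochastic mixture
#' `theta * P_alt + (1-theta)/4 * J`, where `P_alt` maps A<->T and C<->G.
#' This enriches TA/AT (and CG/GC) alternation inside the band while keeping
#' the mononucleotide composition exactly uniform at every offset, so the
#' planted profile structure is purely dinucleotide-borne: mononucleotide
#' shuffling erases it, dinucleotide-preserving shuffling retains it.
#'
#' @param flank half-width of the modeled region.
#' @param flex_band integer c(lo, hi): anchor-relative offsets (inclusive)
#'   of dinucleotide steps receiving the alternation bias.
#' @param theta mixture weight of the alternation component (0..1).
#' @return a `positional_base_model` of length `2*flank + 1`.
#' @export
promoter_markov_model <- function(flank = 150L, flex_band = c(-60L, -10L),
                                  theta = 0.5) {
  stopifnot(theta >= 0, theta <= 1, flank >= 25L)
  L <- 2L * flank + 1L
  p0 <- matrix(0.25, L, 4L, dimnames = list(NULL, BASES))
  P_alt <- matrix(0, 4L, 4L, dimnames = list(BASES, BASES))
  P_alt["A", "T"] <- 1; P_alt["T", "A"] <- 1
  P_alt["C", "G"] <- 1; P_alt["G", "C"] <- 1
  uni <- matrix(0.25, 4L, 4L)
  trans <- array(0, c(L - 1L, 4L, 4L), dimnames = list(NULL, BASES, BASES))
  offs <- seq.int(-flank, flank - 1L)   # offset of each step's first base
  for (i in seq_len(L - 1L)) {
    inband <- offs[i] >= flex_band[1L] && offs[i] <= flex_band[2L]
    trans[i, , ] <- if (inband) theta * P_alt + (1 - theta) * uni else uni
  }
  structure(list(L = L, p0 = p0, trans = trans, pseudocount = 0,
                 uniform_fallback = matrix(FALSE, L - 1L, 4L)),
            class = "positional_base_model")
}

#' Closed-form expected cyclizability profile under a positional Markov model
#'
#' Analytic expectation of the rc-averaged linear dinucleotide score of
#' every profile window for sequences drawn from a `positional_base_model`
#' by conditional-dinucleotide ("vertical") sampling: marginals are
#' propagated through the chain, pair probabilities are
#' `q_i[a] * T_i[a, b]`, and the expected window score sums the
#' strand-symmetrized weights over the window's 49 steps. This is the
#' pipeline's master oracle: the simulate -> read -> profile round trip must
#' reproduce it within sampling error.
#'
#' @param model a `positional_base_model` over -flank..+flank.
#' @param truth a [linear_dinuc_model()].
#' @return data.frame with columns offset, mean (expected rc-averaged
#'   score).
#' @export
expected_profile_markov <- function(model, truth) {
  L <- model$L
  flank <- (L - 1L) %/% 2L
  w_sym <- (truth$w + truth$w[.dinuc_rc_index]) / 2
  # propagate marginals through the chain
  q <- matrix(0, L, 4L)
  q[1L, ] <- model$p0[1L, ]
  for (i in 2:L) q[i, ] <- drop(q[i - 1L, ] %*% model$trans[i - 1L, , ])
  # expected symmetrized step score at each of the L-1 steps
  W <- matrix(w_sym, 4L, 4L, byrow = TRUE)  # W[a, b] = w_sym[dinuc ab]
  step_e <- vapply(seq_len(L - 1L), function(i) {
    pair <- q[i, ] * model$trans[i, , ]     # 4 x 4 of P(a, b)
    sum(pair * W)
  }, numeric(1L))
  offsets <- profile_offsets(flank)
  means <- vapply(offsets, function(o) {
    first_step <- (o - ANCHOR_OFFSET) + flank + 1L   # region index of window start
    truth$b + sum(step_e[first_step:(first_step + WINDOW_BP - 2L)])
  }, numeric(1L))
  data.frame(offset = offsets, mean = means)
}

# first-order chain sampler; rows of `trans` sum to 1
.sample_markov_chain <- function(n, trans, init = rep(0.25, 4)) {
  if (max(abs(sweep(trans, 1L, trans[1L, ], "-"))) < 1e-12) {
    # all rows equal: i.i.d. fast path
    return(sample.int(4L, n, replace = TRUE, prob = trans[1L, ]) - 1L)
  }
  cum <- t(apply(trans, 1L, cumsum))
  u <- stats::runif(n)
  b <- integer(n)
  b[1L] <- sample.int(4L, 1L, prob = init)
  for (t in 2:n) {
    r <- u[t]; row <- b[t - 1L]
    b[t] <- if (r <= cum[row, 1L]) 1L else if (r <= cum[row, 2L]) 2L
            else if (r <= cum[row, 3L]) 3L else 4L
  }
  b - 1L
}

#' Specification for a synthetic genome with planted TSS architecture
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param background_trans 4x4 first-order background transition matrix
#'   (rows sum to 1); the default is i.i.d. with a mildly AT-rich
#'   composition (30/20/20/30), typical of plant genomes.
#' @param n_genes number of genes to plant.
#' @param promoter_model a `positional_base_model` (see
#'   [promoter_markov_model()]) written in transcription orientation around
#'   each TSS.
#' @param tata_fraction fraction of genes receiving a TATAWAWR-consistent
#'   insert at offsets -35..-28 (default 0.29, the reported TATA frequency
#'   in plant promoters).
#' @param min_gene_spacing minimum bp between planted regions.
#' @param utr_len annotated 5' UTR length.
#' @param seed RNG seed; generators are pure functions of their seed.
#' @return an object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(chrom_lengths = c(chr1 = 300000L),
                                  background_trans = NULL,
                                  n_genes = 100L,
                                  promoter_model = promoter_markov_model(),
                                  tata_fraction = 0.29,
                                  min_gene_spacing = 100L,
                                  utr_len = 50L,
                                  seed = 1L) {
  if (is.null(background_trans)) {
    background_trans <- matrix(rep(c(0.3, 0.2, 0.2, 0.3), each = 4L), 4L, 4L)
  }
  stopifnot(all(abs(rowSums(background_trans) - 1) < 1e-9),
            tata_fraction >= 0, tata_fraction <= 1,
            inherits(promoter_model, "positional_base_model"))
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  structure(list(chrom_lengths = chrom_lengths,
                 background_trans = background_trans,
                 n_genes = as.integer(n_genes),
                 promoter_model = promoter_model,
                 tata_fraction = tata_fraction,
                 min_gene_spacing = as.integer(min_gene_spacing),
                 utr_len = as.integer(utr_len),
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

.tata_insert <- function() {
  # TATAWAWR consensus: W in {A,T}, R in {A,G}
  paste0("TATA", sample(c("A", "T"), 1L), "A",
         sample(c("A", "T"), 1L), sample(c("A", "G"), 1L))
}

#' Simulate a genome with planted TSS-proximal dinucleotide structure
#'
#' Draws background sequence from the first-order background chain, plants
#' `n_genes` promoter regions (sampled from the promoter model by
#' conditional-dinucleotide sampling, written in transcription orientation,
#' roughly half on the minus strand), optionally inserts a TATAWAWR motif at
#' offsets -35..-28 in a `tata_fraction` subset, and emits a GFF3 annotation
#' whose `five_prime_UTR` features recover the planted TSSs exactly.
#'
#' @param spec a [synthetic_genome_spec()].
#' @return list with elements `genome` (a [genome_store()]), `gff`
#'   (data.frame writable by [write_gff3()]), `tss` (planted TSS records:
#'   gene_id, chrom, pos, strand), `manifest` (tss plus the `tata` flag and
#'   the spec seed).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  flank <- (spec$promoter_model$L - 1L) %/% 2L
  slot <- 2L * flank + 1L + spec$min_gene_spacing
  capacity <- pmax(0L, (spec$chrom_lengths - spec$min_gene_spacing) %/% slot)
  if (sum(capacity) < spec$n_genes) {
    stop(sprintf("genes do not fit: capacity %d < n_genes %d",
                 sum(capacity), spec$n_genes))
  }
  records <- stats::setNames(vector("character", length(spec$chrom_lengths)),
                             names(spec$chrom_lengths))
  for (ci in seq_along(spec$chrom_lengths)) {
    b <- .sample_markov_chain(spec$chrom_lengths[ci], spec$background_trans)
    records[ci] <- ints_seq(b)
  }

  # allocate genes to chromosomes in order, filling capacity
  alloc <- integer(0)
  remaining <- spec$n_genes
  for (ci in seq_along(capacity)) {
    take <- min(capacity[ci], remaining)
    alloc <- c(alloc, rep(ci, take))
    remaining <- remaining - take
  }

  n <- spec$n_genes
  if (n == 0L) {
    empty_gff <- data.frame(seqid = character(), source = character(),
                            type = character(), start = integer(),
                            end = integer(), score = character(),
                            strand = character(), phase = character(),
                            attributes = character())
    empty_tss <- data.frame(gene_id = character(), chrom = character(),
                            pos = integer(), strand = character())
    return(list(genome = genome_store(records), gff = empty_gff,
                tss = empty_tss,
                manifest = cbind(empty_tss, tata = logical(),
                                 seed = integer())))
  }
  gene_id <- sprintf("g%04d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tata <- seq_len(n) %in% sample.int(n, round(spec$tata_fraction * n))
  pos <- integer(n)
  chrom <- names(spec$chrom_lengths)[alloc]
  slot_index <- stats::ave(seq_len(n), alloc, FUN = seq_along)
  pos <- spec$min_gene_spacing + (slot_index - 1L) * slot + flank

  regions <- sample_vertical(spec$promoter_model, "dinuc", n = n)
  for (i in seq_len(n)) {
    r <- regions[i]
    if (tata[i]) {
      j <- -35L + flank + 1L          # region index of offset -35
      substr(r, j, j + 7L) <- .tata_insert()
    }
    insert <- if (strand[i] == "+") r else revcomp(r)
    s <- records[[chrom[i]]]
    substr(s, pos[i] - flank + 1L, pos[i] + flank + 1L) <- insert
    records[[chrom[i]]] <- s
    regions[i] <- r
  }

  body_len <- min(100L, flank - spec$utr_len)
  gff <- do.call(rbind, lapply(seq_len(n), function(i) {
    p1 <- pos[i] + 1L                  # 1-based TSS
    if (strand[i] == "+") {
      g_s <- p1; g_e <- min(p1 + spec$utr_len + body_len - 1L,
                            spec$chrom_lengths[[chrom[i]]])
      u_s <- p1; u_e <- p1 + spec$utr_len - 1L
    } else {
      g_e <- p1; g_s <- max(p1 - spec$utr_len - body_len + 1L, 1L)
      u_e <- p1; u_s <- p1 - spec$utr_len + 1L
    }
    iso <- paste0(gene_id[i], ".1")
    data.frame(
      seqid = chrom[i], source = "dnaflex",
      type = c("gene", "mRNA", "five_prime_UTR"),
      start = c(g_s, g_s, u_s), end = c(g_e, g_e, u_e),
      score = ".", strand = strand[i], phase = ".",
      attributes = c(sprintf("ID=%s", gene_id[i]),
                     sprintf("ID=%s;Parent=%s", iso, gene_id[i]),
                     sprintf("ID=%s.utr5;Parent=%s", iso, iso)),
      stringsAsFactors = FALSE)
  }))

  genome <- genome_store(records)
  tss <- data.frame(gene_id = gene_id, chrom = chrom, pos = pos,
                    strand = strand, stringsAsFactors = FALSE)
  manifest <- cbind(tss, tata = tata, seed = spec$seed)
  list(genome = genome, gff = gff, tss = tss, manifest = manifest)
}

#' Simulate a loop-seq style scored sequence library
#'
#' Probes are 50 i.i.d. uniform bases; the score is the linear
#' dinucleotide ground-truth score plus Gaussian noise; raw sequences carry
#' fixed 25-base adapters at either terminus.
#'
#' @param n library size.
#' @param truth a [linear_dinuc_model()] (default [default_truth_model()]).
#' @param noise_sd Gaussian noise SD on the score (default 0.2, roughly the
#'   median prediction error reported for loop-seq regressors).
#' @param adapter5,adapter3 fixed 25-base terminal adapters.
#' @param seed RNG seed.
#' @return data.frame with columns sequence (100 bp raw), probe (50 bp),
#'   c0, truth_score.
#' @export
simulate_loopseq_library <- function(n, truth = default_truth_model(),
                                     noise_sd = 0.2,
                                     adapter5 = "GTCTCTAGGCAGGCACGTGGTTAGC",
                                     adapter3 = "CATTCGGATCCTAGCCAGTGAACTC",
                                     seed = 1L) {
  stopifnot(n >= 1L, noise_sd >= 0, nchar(adapter5) == 25L,
            nchar(adapter3) == 25L)
  set.seed(seed)
  probes <- random_seqs(n, 50L)
  truth_score <- score_raw(truth, probes)
  c0 <- truth_score + stats::rnorm(n, sd = noise_sd)
  data.frame(sequence = paste0(adapter5, probes, adapter3),
             probe = probes, c0 = c0, truth_score = truth_score,
             stringsAsFactors = FALSE)
}

# draw case/control window sets at a given mechanism slope
.draw_case_control <- function(z, n_case, n_control, slope) {
  w <- stats::plogis(-slope * z)
  case <- sample.int(length(z), n_case, prob = w)
  rest <- setdiff(seq_along(z), case)
  control <- if (length(rest) <= n_control) rest else sample(rest, n_control)
  list(case = case, control = control)
}

#' Simulate a variant set with a planted flexibility association
#'
#' Tiles the genome into 50-bp windows, scores them with the ground-truth
#' model, and selects `n_case` "mutated" windows with probability decreasing
#' in the standardized score (planting mutations in rigid windows). The
#' mechanism slope is calibrated by redrawing until the realized Cohen's d
#' between control and case window scores is within `tol` of `target_d`.
#' SNP and/or indel records are then emitted inside the case windows.
#'
#' @param genome a [genome_store()].
#' @param truth a [linear_dinuc_model()] ground truth.
#' @param target_d planted effect size (control minus case; positive means
#'   mutated windows are more rigid). `0` plants a null.
#' @param n_case,n_control group sizes.
#' @param seed RNG seed.
#' @param tol calibration tolerance on the realized d (default 0.02).
#' @param max_rounds redraw budget before failing with the achieved d.
#' @param vtype_probs probabilities of emitting only a SNP, only an indel,
#'   or both per case window.
#' @return list with `variants` (data.frame chrom, pos, vtype, ref_span),
#'   `case_windows`, `control_windows` (window data.frames), `expected_d`
#'   (the realized calibrated d), `slope`, `seed`.
#' @export
simulate_variant_set <- function(genome, truth, target_d, n_case, n_control,
                                 seed = 1L, tol = 0.02, max_rounds = 60L,
                                 vtype_probs = c(snp = 0.5, indel = 0.3,
                                                 both = 0.2)) {
  stopifnot(n_case >= 2L, n_control >= 2L)
  set.seed(seed)
  tiles <- tile_genome(genome)
  if (nrow(tiles) < n_case + n_control) {
    stop("genome too small for the requested group sizes")
  }
  scores <- predict_c0(truth, tiles$seq)
  z <- (scores - mean(scores)) / stats::sd(scores)

  realized <- function(slope) {
    dr <- .draw_case_control(z, n_case, n_control, slope)
    list(d = cohens_d(scores[dr$control], scores[dr$case])$d, draw = dr)
  }

  if (target_d == 0) {
    slope <- 0
  } else {
    # initialize by bisection on the expected d of the weighted mechanism
    expected_d <- function(slope) {
      w <- stats::plogis(-slope * z)
      mu_w <- sum(w * scores) / sum(w)
      var_w <- sum(w * (scores - mu_w)^2) / sum(w)
      (mean(scores) - mu_w) / sqrt((stats::var(scores) + var_w) / 2)
    }
    lo <- 0; hi <- 1
    while (expected_d(hi) < target_d && hi < 512) hi <- hi * 2
    if (expected_d(hi) < target_d) {
      stop(sprintf("target_d %.3f unreachable (max expected d %.3f)",
                   target_d, expected_d(hi)))
    }
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (expected_d(mid) < target_d) lo <- mid else hi <- mid
    }
    slope <- (lo + hi) / 2
  }

  best <- NULL
  for (round in seq_len(max_rounds)) {
    r <- realized(slope)
    if (is.null(best) || abs(r$d - target_d) < abs(best$d - target_d)) best <- r
    if (abs(r$d - target_d) <= tol) { best <- r; break }
    if (target_d != 0) slope <- slope * (1 + 0.5 * (target_d - r$d) / max(abs(target_d), 0.05))
  }
  if (abs(best$d - target_d) > tol) {
    stop(sprintf("calibration failed: achieved d %.4f for target %.4f",
                 best$d, target_d))
  }

  case_w <- tiles[best$draw$case, , drop = FALSE]
  control_w <- tiles[best$draw$control, , drop = FALSE]
  kinds <- sample(names(vtype_probs), nrow(case_w), replace = TRUE,
                  prob = vtype_probs)
  emit_snp <- function(wd) {
    data.frame(chrom = wd$chrom, pos = wd$start + sample.int(50L, 1L) - 1L,
               vtype = "SNP", ref_span = 1L, stringsAsFactors = FALSE)
  }
  emit_indel <- function(wd) {
    if (stats::runif(1) < 0.5) {
      span <- sample(2:10, 1L)
      data.frame(chrom = wd$chrom,
                 pos = wd$start + sample.int(50L - span + 1L, 1L) - 1L,
                 vtype = "DEL", ref_span = span, stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = wd$chrom, pos = wd$start + sample.int(50L, 1L) - 1L,
                 vtype = "INS", ref_span = 1L, stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, lapply(seq_len(nrow(case_w)), function(i) {
    wd <- case_w[i, , drop = FALSE]
    switch(kinds[i],
           snp = emit_snp(wd),
           indel = emit_indel(wd),
           both = rbind(emit_snp(wd), emit_indel(wd)))
  }))
  rownames(variants) <- NULL
  list(variants = variants, case_windows = case_w,
       control_windows = control_w, expected_d = best$d, slope = slope,
       seed = seed)
}

#' Simulate methylation calls with a null or planted association
#'
#' Enumerates cytosine contexts inside the promoter intervals and assigns
#' methylation flags either independently of sequence (`association =
#' "null"`) or with probability increasing in the standardized ground-truth
#' score of the site's window, calibrated so the realized pooled Cohen's d
#' (methylated vs unmethylated windows) matches the planted target.
#'
#' @param genome a [genome_store()].
#' @param promoters intervals (chrom, start, end), e.g.
#'   [promoter_intervals()].
#' @param truth a [linear_dinuc_model()] (used only for planted
#'   associations).
#' @param association "null" or a numeric target Cohen's d (positive means
#'   methylated sites sit in more flexible windows).
#' @param rate overall methylation rate (default 0.3).
#' @param seed RNG seed.
#' @param tol calibration tolerance (planted mode).
#' @param max_rounds redraw budget (planted mode).
#' @return data.frame of sites as [find_cytosine_contexts()] with the
#'   `methylated` flag set; attribute `realized_d` in planted mode.
#' @export
simulate_methylation_set <- function(genome, promoters,
                                     truth = default_truth_model(),
                                     association = "null", rate = 0.3,
                                     seed = 1L, tol = 0.02,
                                     max_rounds = 60L) {
  set.seed(seed)
  sites <- do.call(rbind, lapply(names(genome), function(ch) {
    find_cytosine_contexts(genome, ch)
  }))
  keep <- .positions_in_intervals(sites$chrom, sites$pos, promoters)
  sites <- sites[keep, , drop = FALSE]
  lens <- vapply(sites$chrom, function(ch) chrom_length(genome, ch),
                 integer(1L))
  sites <- sites[sites$pos - 24L >= 0L & sites$pos + 26L <= lens, ,
                 drop = FALSE]
  if (nrow(sites) == 0L) stop("no cytosine sites in promoters")
  rownames(sites) <- NULL

  if (identical(association, "null")) {
    sites$methylated <- stats::runif(nrow(sites)) < rate
    return(sites)
  }

  target_d <- as.numeric(association)
  scores <- predict_c0(truth, .window_seqs(genome, .site_windows(sites)),
                       na_ambiguous = TRUE)
  ok <- !is.na(scores)
  sites <- sites[ok, , drop = FALSE]
  scores <- scores[ok]
  z <- (scores - mean(scores)) / stats::sd(scores)
  alpha <- stats::qlogis(rate)

  realized <- function(slope) {
    flags <- stats::runif(length(z)) < stats::plogis(alpha + slope * z)
    if (sum(flags) < 2L || sum(!flags) < 2L) {
      return(list(d = NA_real_, flags = flags))
    }
    list(d = cohens_d(scores[flags], scores[!flags])$d, flags = flags)
  }
  # expected-d initialization: E[z | meth] - E[z | unmeth] approx d
  slope <- target_d
  best <- NULL
  for (round in seq_len(max_rounds)) {
    r <- realized(slope)
    if (!is.na(r$d)) {
      if (is.null(best) || abs(r$d - target_d) < abs(best$d - target_d)) best <- r
      if (abs(r$d - target_d) <= tol) { best <- r; break }
      slope <- slope * (1 + 0.7 * (target_d - r$d) / max(abs(target_d), 0.05))
    } else {
      slope <- slope / 2
    }
  }
  if (is.null(best) || abs(best$d - target_d) > tol) {
    stop(sprintf("calibration failed: achieved d %s for target %.4f",
                 if (is.null(best)) "NA" else sprintf("%.4f", best$d),
                 target_d))
  }
  sites$methylated <- best$flags
  attr(sites, "realized_d") <- best$d
  sites
}
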