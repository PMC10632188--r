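test_that("anchored_mean_profile matches the brute-force double loop", {
  g <- toy_genome(900, seed = 41)
  anchors <- data.frame(chrom = "chr1", pos = c(200L, 650L),
                        strand = c("+", "-"))
  truth <- default_truth_model()
  prof <- anchored_mean_profile(g, anchors, truth, flank = 100L)
  oracle <- brute_profile(g, anchors, truth, flank = 100L)
  expect_identical(prof$offset, oracle$offset)
  expect_lt(max(abs(prof$mean - oracle$mean)), 1e-10)
  expect_identical(prof$n, oracle$n)
})

test_that("a constant predictor yields a flat profile with full counts", {
  g <- toy_genome(700, seed = 42)
  anchors <- data.frame(chrom = "chr1", pos = c(150L, 300L, 450L),
                        strand = "+")
  const <- as_flex_predictor(function(s) rep(0.37, length(s)))
  prof <- anchored_mean_profile(g, anchors, const, flank = 60L)
  expect_true(all(prof$mean == 0.37))
  expect_true(all(prof$sd == 0))
  expect_true(all(prof$n == 3L))
  expect_identical(prof$offset, seq.int(24L - 60L, 60L - 25L))
})

test_that("profile offset 0 scores the window spanning offsets -24..+25", {
  g <- toy_genome(600, seed = 43)
  truth <- default_truth_model()
  anchors <- data.frame(chrom = "chr1", pos = 300L, strand = "+")
  prof <- anchored_mean_profile(g, anchors, truth, flank = 50L)
  win <- substr(g[["chr1"]], 300 - 24 + 1, 300 + 25 + 1)
  expect_equal(prof$mean[prof$offset == 0], predict_c0(truth, win))
})

test_that("dinuc_h randomization cannot move a dinucleotide-additive score", {
  sim <- simulate_genome(synthetic_genome_spec(
    chrom_lengths = c(chr1 = 60000L), n_genes = 20L,
    promoter_model = promoter_markov_model(flank = 80L), seed = 44))
  truth <- default_truth_model()   # strand-symmetric weights
  actual <- anchored_mean_profile(sim$genome, sim$tss, truth, flank = 80L)
  withr::local_seed(45)
  rand <- randomized_profile(sim$genome, sim$tss, truth, flank = 80L,
                             mode = "dinuc_h")
  expect_lt(max(abs(rand$mean - actual$mean)), 1e-12)
})

test_that("mono_h randomization flattens planted dinucleotide structure", {
  sim <- simulate_genome(synthetic_genome_spec(
    chrom_lengths = c(chr1 = 90000L), n_genes = 40L,
    promoter_model = promoter_markov_model(flank = 80L, theta = 0.5),
    tata_fraction = 0, seed = 46))
  truth <- default_truth_model()
  actual <- anchored_mean_profile(sim$genome, sim$tss, truth, flank = 80L)
  withr::local_seed(47)
  rand <- randomized_profile(sim$genome, sim$tss, truth, flank = 80L,
                             mode = "mono_h")
  expect_lt(var(rand$mean) / var(actual$mean), 0.2)
})

test_that("vertical sampling modes return profiles on the same offsets", {
  sim <- simulate_genome(synthetic_genome_spec(
    chrom_lengths = c(chr1 = 40000L), n_genes = 12L,
    promoter_model = promoter_markov_model(flank = 60L), seed = 48))
  const <- as_flex_predictor(function(s) rep(-1.5, length(s)))
  withr::local_seed(49)
  for (mode in c("mono_v", "dinuc_v")) {
    prof <- randomized_profile(sim$genome, sim$tss, const, flank = 60L,
                               mode = mode)
    expect_identical(prof$offset, seq.int(24L - 60L, 60L - 25L))
    expect_true(all(prof$mean == -1.5))
  }
})

test_that("matched_pair mode pairs dinucleotide and distance-matched shuffles", {
  g <- toy_genome(400, seed = 50)
  anchors <- data.frame(chrom = "chr1", pos = 200L, strand = "+")
  truth <- default_truth_model()
  withr::local_seed(51)
  res <- randomized_profile(g, anchors, truth, flank = 40L,
                            mode = "matched_pair")
  expect_named(res, c("dinuc", "mono_matched", "diffs"))
  # symmetric linear model: dinucleotide-preserving shuffles change nothing
  expect_lt(max(abs(res$diffs$diff_dinuc), na.rm = TRUE), 1e-12)
  # matched mono shuffles generally do
  expect_gt(stats::sd(res$diffs$diff_mono, na.rm = TRUE), 0)
})

test_that("dinuc_logratio_profile computes ln(observed/expected)", {
  # observed equal expected everywhere -> all zeros
  prof <- dinuc_logratio_profile(dnaflex:::DINUCS, expected = "pooled_dinuc")
  expect_true(all(prof$values[!prof$undefined] == 0))
  expect_identical(dim(prof$values), c(16L, 1L))

  # alternating AT: only AT at odd steps, only TA at even steps
  prof2 <- dinuc_logratio_profile(rep("ATATAT", 4),
                                  expected = rep(1 / 16, 16),
                                  start_offset = -3L)
  expect_identical(prof2$offsets, -3:1)
  expect_equal(unname(prof2$values["AT", c(1, 3, 5)]), rep(log(16), 3))
  expect_equal(unname(prof2$values["TA", c(2, 4)]), rep(log(16), 2))
  expect_true(all(prof2$undefined[setdiff(rownames(prof2$values), c("AT", "TA")), ]))

  # i.i.d. uniform set: values near 0 under the mono-product expectation
  withr::local_seed(52)
  seqs <- dnaflex:::random_seqs(4000, 30)
  prof3 <- dinuc_logratio_profile(seqs)
  # log-ratio sd is about sqrt((1-p)/(n p)) per cell; allow for the maximum
  # over 16 x 29 cells
  expect_lt(max(abs(prof3$values), na.rm = TRUE),
            4.5 * sqrt((1 - 1 / 16) / (4000 / 16)))
})

test_that("predict_track assigns scores to the 25th base", {
  g <- toy_genome(300, seed = 53)
  truth <- default_truth_model()
  tr1 <- predict_track(g, "chr1", 0L, 50L, truth)
  expect_identical(nrow(tr1), 1L)
  expect_identical(tr1$pos, 24L)

  tr2 <- predict_track(g, "chr1", 100L, 160L, truth)
  expect_identical(tr2$pos, seq.int(124L, 134L))
  win <- substr(g[["chr1"]], 101, 150)
  expect_equal(tr2$score[1], predict_c0(truth, win))

  const <- as_flex_predictor(function(s) rep(2, length(s)))
  expect_true(all(predict_track(g, "chr1", 0L, 300L, const)$score == 2))
  expect_error(predict_track(g, "chr1", 10L, 55L, truth), "shorter than 50")
})

test_that("acf_signal matches closed forms and the FFT route", {
  withr::local_seed(54)
  x <- rnorm(2000)
  a <- acf_signal(x, 40L)
  expect_identical(a[1], 1)
  expect_equal(a, fft_acf(x, 40L), tolerance = 1e-8)
  expect_equal(a[-1], unname(stats::acf(x, lag.max = 40, plot = FALSE,
                                        demean = TRUE)$acf[-1, 1, 1]),
               tolerance = 1e-10)

  alt <- rep(c(1, -1), 500)
  expect_lt(abs(acf_signal(alt, 1L)[2] + 1), 2 / 1000 + 1e-9)

  wn <- rnorm(10000)
  expect_true(all(abs(acf_signal(wn, 50L)[-1]) < 3 / sqrt(10000)))

  expect_error(acf_signal(rep(1, 10), 2L), "zero variance")
  expect_error(acf_signal(c(1, 2), 5L), "max_lag")
})
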