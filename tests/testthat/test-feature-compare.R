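test_that("classify_variant_windows implements the four-class overlap rule", {
  w <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L), end = c(50L, 150L, 250L))
  v <- data.frame(chrom = "chr1",
                  pos = c(120L, 130L, 95L),
                  vtype = c("SNP", "DEL", "DEL"),
                  ref_span = c(1L, 5L, 10L))
  labels <- classify_variant_windows(w, v)
  expect_identical(labels[1], "none")
  expect_identical(labels[2], "snp_and_indel")
  # DEL spanning [95, 105) starts 5 bp before window 2's start -> hits it
  expect_identical(classify_variant_windows(w[2, , drop = FALSE],
                                            v[3, , drop = FALSE]),
                   "indel_only")

  withr::local_seed(71)
  for (rep in 1:5) {
    windows <- data.frame(chrom = "chr1", start = sample(0:300, 30) * 3L)
    windows$end <- windows$start + 50L
    variants <- data.frame(chrom = "chr1", pos = sample(0:950, 25),
                           vtype = sample(c("SNP", "INS", "DEL"), 25, TRUE))
    variants$ref_span <- ifelse(variants$vtype == "DEL",
                                sample(2:12, 25, TRUE), 1L)
    expect_identical(classify_variant_windows(windows, variants),
                     brute_variant_labels(windows, variants))
  }
})

test_that("compare_feature_windows reports Cohen's d of A vs B", {
  withr::local_seed(72)
  seqs <- dnaflex:::random_seqs(4, 50)
  stub <- lookup_predictor(setNames(c(2, 4, 0, 2), seqs))
  wA <- data.frame(chrom = "c", start = 0L, end = 50L, seq = seqs[1:2])
  wB <- data.frame(chrom = "c", start = 0L, end = 50L, seq = seqs[3:4])
  rep_ <- compare_feature_windows(NULL, wA, wB, stub)
  expect_equal(rep_$d, sqrt(2))
  expect_equal(rep_$s, sqrt(2))
  expect_equal(rep_$t, sqrt(2))   # pooled identity d * sqrt(n1 n2/(n1+n2))

  same <- compare_feature_windows(NULL, wA, wA, stub)
  expect_equal(same$d, 0)
  expect_error(compare_feature_windows(NULL, wA[1, ], wB, stub), "at least 2")
})

test_that("find_cytosine_contexts enumerates both strands with the plant rule", {
  g <- genome_store(c(c1 = "ACGTT"))
  sites <- find_cytosine_contexts(g, "c1")
  plus <- sites[sites$strand == "+", ]
  expect_identical(plus$pos, 1L)
  expect_identical(plus$context3, "CGT")
  expect_identical(plus$context_class, "CG")
  minus <- sites[sites$strand == "-", ]
  expect_identical(minus$pos, 2L)       # the G read as C on the minus strand
  expect_identical(minus$context3, "CGT")

  expect_identical(classify_context3(c("CAG", "CCT", "CGA", "CTT")),
                   c("CHG", "CHH", "CG", "CHH"))
  expect_identical(nrow(find_cytosine_contexts(
    genome_store(c(c1 = "ATATAT")), "c1")), 0L)

  # totality: every 3-mer starting with C maps to exactly one class
  all3 <- apply(expand.grid("C", BASES4, BASES4), 1, paste, collapse = "")
  cls <- classify_context3(all3)
  expect_true(all(cls %in% c("CG", "CHG", "CHH")))
  expect_identical(sum(cls == "CG"), 4L)     # C G N
  expect_identical(sum(cls == "CHG"), 3L)    # C H G
  expect_identical(sum(cls == "CHH"), 9L)
})

test_that("methylation_comparison compares per-context site windows", {
  sim <- simulate_genome(synthetic_genome_spec(
    chrom_lengths = c(chr1 = 150000L), n_genes = 60L,
    promoter_model = promoter_markov_model(flank = 80L), seed = 73))
  prom <- promoter_intervals(sim$tss, sim$genome, upstream = 300L)
  sites <- simulate_methylation_set(sim$genome, prom, association = "null",
                                    rate = 0.4, seed = 74)
  truth <- default_truth_model()
  reps <- methylation_comparison(sim$genome, sites, prom, truth)
  expect_true(all(c("CG", "CHG", "CHH") %in% names(reps)))
  for (r in reps) expect_true(abs(r$d) < 0.15)  # loose null sanity at this n

  # identical sequences in both groups -> d = 0 by convention
  g2 <- genome_store(c(c1 = strrep("AC", 200)))
  s2 <- find_cytosine_contexts(g2, "c1")
  s2 <- s2[s2$pos >= 24 & s2$pos <= 374, ]
  s2$methylated <- seq_len(nrow(s2)) %% 2 == 0
  p2 <- data.frame(chrom = "c1", start = 0L, end = 400L)
  reps2 <- methylation_comparison(g2, s2, p2, truth)
  expect_equal(reps2[["CHH"]]$d, 0)
})

test_that("tf_bound_vs_unbound centers profiles on motif midpoints", {
  g <- toy_genome(3000, seed = 75)
  sites <- data.frame(chrom = "chr1",
                      start = seq(300L, 2500L, by = 200L))
  sites$end <- sites$start + 10L
  sites$bound <- TRUE
  truth <- default_truth_model()
  expect_warning(prof <- tf_bound_vs_unbound(g, sites, truth, flank = 50L),
                 "fewer than")
  expect_equal(prof$bound$mean, prof$all$mean)   # bound set = all sites

  # planted rigid bound sites sit below the all-sites profile at the center
  flex <- strrep("TA", 60)
  rigid <- paste0(strrep("A", 60), strrep("T", 60))
  s <- paste0(strrep("G", 100), rigid, strrep("G", 80), flex, strrep("G", 100))
  g2 <- genome_store(c(c1 = s))
  sites2 <- data.frame(chrom = "c1", start = c(155L, 355L), end = c(165L, 365L),
                       bound = c(TRUE, FALSE))
  suppressWarnings(prof2 <- tf_bound_vs_unbound(g2, sites2, truth, flank = 40L))
  center <- prof2$bound$offset %in% -5:5
  expect_true(all(prof2$bound$mean[center] < prof2$all$mean[center]))
})

test_that("positionwise_correlation scores windows centered on track positions", {
  g <- toy_genome(4000, seed = 76)
  truth <- default_truth_model()
  tr <- predict_track(g, "chr1", 0L, 2000L, truth, step = 7L)
  track <- data.frame(chrom = tr$chrom, pos = tr$pos, value = tr$score)
  track$value[track$value == 0] <- 1e-9
  expect_equal(positionwise_correlation(track, g, truth)$r, 1)
  track_neg <- transform(track, value = -value)
  expect_equal(positionwise_correlation(track_neg, g, truth)$r, -1)

  # excluded intervals are dropped
  res <- positionwise_correlation(track, g, truth,
                                  exclude = data.frame(chrom = "chr1",
                                                       start = 0L, end = 1000L))
  expect_identical(res$n, sum(track$pos >= 1000))

  withr::local_seed(77)
  noise <- transform(track, value = rnorm(nrow(track)))
  res2 <- positionwise_correlation(noise, g, truth)
  expect_lt(abs(res2$r), 3 / sqrt(res2$n))
  expect_error(positionwise_correlation(track[1, ], g, truth), "fewer than 2")
})
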