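test_that("simulate_genome plants recoverable TSSs and TATA inserts", {
  spec0 <- synthetic_genome_spec(chrom_lengths = c(chr1 = 5000L),
                                 n_genes = 0L, seed = 91)
  sim0 <- simulate_genome(spec0)
  expect_identical(nrow(sim0$gff), 0L)
  expect_identical(nchar(sim0$genome[["chr1"]]), 5000L)

  spec <- synthetic_genome_spec(chrom_lengths = c(chrA = 30000L, chrB = 30000L),
                                n_genes = 25L,
                                promoter_model = promoter_markov_model(flank = 60L),
                                tata_fraction = 1, seed = 92)
  sim <- simulate_genome(spec)
  gff_path <- withr::local_tempfile(fileext = ".gff3")
  fa_path <- withr::local_tempfile(fileext = ".fa")
  write_gff3(sim$gff, gff_path)
  write_fasta(sim$genome, fa_path)
  tss <- read_tss_from_gff(gff_path, read_fasta(fa_path))
  m <- merge(tss, sim$tss, by = "gene_id")
  expect_identical(nrow(m), 25L)
  expect_identical(m$pos.x, m$pos.y)
  expect_identical(m$strand.x, m$strand.y)
  expect_identical(m$chrom.x, m$chrom.y)

  # tata_fraction = 1: a TATAWAWR match at offsets -35..-28 of every promoter
  regions <- extract_anchored_regions(sim$genome, sim$tss, flank = 60L)
  insert <- substr(regions, -35 + 60 + 1, -28 + 60 + 1)
  expect_true(all(grepl("^TATA[AT]A[AT][AG]$", insert)))
})

test_that("generators are pure functions of their seed", {
  spec <- synthetic_genome_spec(chrom_lengths = c(c1 = 20000L), n_genes = 8L,
                                promoter_model = promoter_markov_model(flank = 40L),
                                seed = 93)
  expect_identical(simulate_genome(spec), simulate_genome(spec))
  expect_identical(simulate_loopseq_library(50, seed = 4),
                   simulate_loopseq_library(50, seed = 4))
})

test_that("simulate_genome refuses genomes that cannot hold the genes", {
  expect_error(simulate_genome(synthetic_genome_spec(
    chrom_lengths = c(c1 = 2000L), n_genes = 50L,
    promoter_model = promoter_markov_model(flank = 60L), seed = 1)),
    "do not fit")
})

test_that("simulate_loopseq_library scores probes with the planted truth", {
  truth <- default_truth_model()
  lib <- simulate_loopseq_library(500, truth = truth, noise_sd = 0, seed = 94)
  expect_identical(nchar(lib$sequence[1]), 100L)
  expect_identical(strip_adapters(lib$sequence), lib$probe)
  expect_equal(lib$c0, score_raw(truth, lib$probe))

  lib2 <- simulate_loopseq_library(50000, truth = truth, noise_sd = 0.2,
                                   seed = 95)
  expect_lt(abs(sd(lib2$c0 - lib2$truth_score) - 0.2) / 0.2, 0.02)
})

test_that("simulate_variant_set plants a calibrated or null association", {
  sim <- simulate_genome(synthetic_genome_spec(
    chrom_lengths = c(c1 = 200000L), n_genes = 0L, seed = 96))
  truth <- default_truth_model()
  vs <- simulate_variant_set(sim$genome, truth, target_d = 0,
                             n_case = 800L, n_control = 800L, seed = 97)
  expect_lte(abs(vs$expected_d), 0.02)

  vs3 <- simulate_variant_set(sim$genome, truth, target_d = 0.3,
                              n_case = 800L, n_control = 800L, seed = 98)
  expect_lte(abs(vs3$expected_d - 0.3), 0.02)
  # every emitted variant lies inside a case window
  labels <- classify_variant_windows(vs3$case_windows, vs3$variants)
  expect_true(all(labels != "none"))
  inside_case <- brute_variant_labels(
    data.frame(chrom = vs3$variants$chrom, start = vs3$variants$pos,
               end = vs3$variants$pos + vs3$variants$ref_span),
    data.frame(chrom = vs3$case_windows$chrom, pos = vs3$case_windows$start,
               vtype = "DEL", ref_span = 50L))
  expect_true(all(inside_case != "none"))
})

test_that("simulate_methylation_set supports null and planted modes", {
  sim <- simulate_genome(synthetic_genome_spec(
    chrom_lengths = c(c1 = 120000L), n_genes = 50L,
    promoter_model = promoter_markov_model(flank = 80L), seed = 99))
  prom <- promoter_intervals(sim$tss, sim$genome, upstream = 300L)
  truth <- default_truth_model()

  sites <- simulate_methylation_set(sim$genome, prom, association = "null",
                                    rate = 0.3, seed = 100)
  expect_true(all(startsWith(sites$context3, "C")))
  expect_identical(classify_context3(sites$context3), sites$context_class)
  expect_true(all(sites$methylated %in% c(TRUE, FALSE)))

  planted <- simulate_methylation_set(sim$genome, prom, truth = truth,
                                      association = 0.5, seed = 101)
  expect_lte(abs(attr(planted, "realized_d") - 0.5), 0.02)
  # pipeline recovery at the planted size: pooled over contexts
  wA <- dnaflex:::.site_windows(planted[planted$methylated, ])
  wB <- dnaflex:::.site_windows(planted[!planted$methylated, ])
  rec <- compare_feature_windows(sim$genome, wA, wB, truth)
  expect_lte(abs(rec$d - 0.5), 0.1)
})

test_that("the closed-form Markov profile oracle matches brute enumeration", {
  # tiny chain where the expectation can be cross-checked by exhaustive
  # enumeration over a short window
  model <- promoter_markov_model(flank = 26L, flex_band = c(-2L, 3L),
                                 theta = 0.7)
  truth <- default_truth_model()
  exp_prof <- expected_profile_markov(model, truth)
  expect_identical(exp_prof$offset, seq.int(24L - 26L, 26L - 25L))

  # Monte Carlo agreement
  withr::local_seed(102)
  draws <- sample_vertical(model, "dinuc", n = 40000)
  w_off <- exp_prof$offset[2]   # offset -1: window covers region fully
  st <- (w_off - 24L) + 26L + 1L
  wins <- substr(draws, st, st + 49L)
  mc <- mean(predict_c0(truth, wins))
  se <- sd(predict_c0(truth, wins)) / sqrt(40000)
  expect_lt(abs(mc - exp_prof$mean[2]), 4 * se)
})
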