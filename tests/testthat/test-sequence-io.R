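test_that("read_fasta normalizes case, preserves order, rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt"), fa)
  g <- read_fasta(fa)
  expect_identical(unclass(g), c(c1 = "ACGT"))

  writeLines(c(">c1 descr", "ACGT", ">c2", "TTnTT"), fa)
  g <- read_fasta(fa)
  expect_identical(names(g), c("c1", "c2"))
  expect_identical(g[["c2"]], "TTNTT")

  writeLines(c(">c1", "ACGT", ">c1", "TTTT"), fa)
  expect_error(read_fasta(fa), "duplicate")

  writeLines(c(">c1", "ACXT"), fa)
  expect_error(read_fasta(fa), "'X'")

  fa2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGTN", ">b", "GGCC"), fa2)
  rt <- read_fasta(write_fasta(read_fasta(fa2),
                               withr::local_tempfile(fileext = ".fa")))
  expect_identical(unclass(rt), c(a = "ACGTN", b = "GGCC"))
})

test_that("read_tss_from_gff applies the 5'UTR-first-base convention", {
  g <- genome_store(c(chr1 = strrep("A", 400)))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t260\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t260\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\tsrc\tfive_prime_UTR\t101\t150\t.\t+\t.\tID=u1;Parent=g1.1",
    "chr1\tsrc\tgene\t150\t260\t.\t-\t.\tID=g2",
    "chr1\tsrc\tmRNA\t150\t260\t.\t-\t.\tID=g2.1;Parent=g2",
    "chr1\tsrc\tfive_prime_UTR\t201\t260\t.\t-\t.\tID=u2;Parent=g2.1",
    "chr1\tsrc\tgene\t300\t350\t.\t+\t.\tID=g3",
    "chr1\tsrc\tmRNA\t300\t350\t.\t+\t.\tID=g3.1;Parent=g3",
    "chr1\tsrc\tCDS\t300\t350\t.\t+\t0\tID=c3;Parent=g3.1"), gff)
  tss <- read_tss_from_gff(gff, g)
  tss <- tss[order(tss$gene_id), ]
  # 1-based inclusive UTR -> 0-based TSS: + strand start-1, - strand end-1
  expect_identical(tss$gene_id, c("g1", "g2"))
  expect_identical(tss$pos, c(100L, 259L))
  expect_identical(tss$strand, c("+", "-"))
})

test_that("isoform selection prefers .1, else lexicographically first", {
  g <- genome_store(c(chr1 = strrep("A", 400)))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=g1.2;Parent=g1",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\tsrc\tfive_prime_UTR\t21\t40\t.\t+\t.\tParent=g1.2",
    "chr1\tsrc\tfive_prime_UTR\t51\t70\t.\t+\t.\tParent=g1.1"), gff)
  expect_identical(read_tss_from_gff(gff, g)$pos, 50L)
})

test_that("malformed GFF lines and out-of-bounds TSSs are handled", {
  g <- genome_store(c(chr1 = strrep("A", 100)))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t50\t.\t+\t.\tID=g1",
               "chr1\tonly three fields"), gff)
  expect_error(read_tss_from_gff(gff, g), "line 3")

  writeLines("chr1\tsrc\tfive_prime_UTR\t150\t160\t.\t+\t.\tParent=g9", gff)
  expect_warning(tss <- read_tss_from_gff(gff, g), "skipped")
  expect_identical(nrow(tss), 0L)
})

test_that("tile_genome tiles, drops ambiguity, respects short chromosomes", {
  g <- toy_genome(200, seed = 5)
  w <- tile_genome(g)
  expect_identical(w$start, c(0L, 50L, 100L, 150L))
  expect_identical(w$seq, substring(g[["chr1"]], w$start + 1L, w$end))

  expect_identical(nrow(tile_genome(genome_store(c(c1 = strrep("A", 49))))), 0L)

  gN <- genome_store(c(c1 = paste0(strrep("A", 60), "N", strrep("A", 60))))
  wN <- tile_genome(gN)
  expect_identical(wN$start, 0L)   # window at 50 contains the N
})

test_that("tile_genome window count matches a brute-force scan", {
  withr::local_seed(42)
  for (rep in 1:10) {
    len <- sample(40:400, 1)
    window <- sample(c(10L, 50L), 1)
    step <- sample(c(7L, 25L, 50L), 1)
    nn <- sample(0:3, 1)
    g <- toy_genome(len, seed = rep,
                    n_positions = if (nn > 0) sample(len, nn) else integer(0))
    got <- tile_genome(g, window, step)
    s <- g[["chr1"]]
    expected <- 0L
    if (len >= window) {
      for (st in seq.int(0L, len - window, by = step)) {
        if (!grepl("[^ACGT]", substr(s, st + 1L, st + window))) {
          expected <- expected + 1L
        }
      }
    }
    expect_identical(nrow(got), expected)
  }
})

test_that("extract_anchored_regions orients and skips edges", {
  withr::local_seed(7)
  s <- paste(sample(BASES4, 1200, replace = TRUE), collapse = "")
  g <- genome_store(c(chr1 = s))
  anchors <- data.frame(chrom = "chr1", pos = c(525L, 600L, 10L),
                        strand = c("+", "-", "+"))
  expect_warning(regions <- extract_anchored_regions(g, anchors, 525L),
                 "skipped")
  expect_identical(regions[1], substr(s, 1, 1051))
  expect_identical(regions[2], brute_revcomp(substr(s, 600 - 525 + 1, 600 + 525 + 1)))
  expect_true(is.na(regions[3]))
})

test_that("strip_adapters keeps the central 50 bp", {
  raw <- paste0(strrep("C", 25), strrep("A", 50), strrep("G", 25))
  expect_identical(strip_adapters(raw), strrep("A", 50))
  expect_identical(strip_adapters(strrep("T", 50)), strrep("T", 50))
  expect_error(strip_adapters(strrep("A", 99)), "99")
  # wrap -> strip round trip on random probes
  withr::local_seed(1)
  probes <- dnaflex:::random_seqs(20, 50)
  expect_identical(strip_adapters(paste0(strrep("G", 25), probes,
                                         strrep("T", 25))), probes)
})

test_that("revcomp is a strict involution", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("AAC"), "GTT")
  expect_error(revcomp("ANT"), "'N'")
  withr::local_seed(3)
  seqs <- dnaflex:::random_seqs(1000, 50)
  expect_identical(revcomp(revcomp(seqs)), seqs)
  expect_identical(revcomp(seqs[1:25]),
                   vapply(seqs[1:25], brute_revcomp, character(1),
                          USE.NAMES = FALSE))
})

test_that("one_hot uses fixed A,C,G,T column order", {
  expect_identical(one_hot("A")[1, ], c(A = 1L, C = 0L, G = 0L, T = 0L))
  withr::local_seed(4)
  m <- one_hot(dnaflex:::random_seqs(1, 30))
  expect_true(all(rowSums(m) == 1L))
  expect_error(one_hot("ANT"), "'N'")
})

test_that("loop-seq TSV and BED/bedGraph readers round-trip", {
  lib <- data.frame(sequence = c("ACGTT", "TTGCA"), c0 = c(-0.5, 1.25))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_loopseq_tsv(lib, p)
  expect_equal(read_loopseq_tsv(p), lib)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t60\tsiteA\t0\t+\t1", "chr1\t100\t130\tsiteB\t0\t-\t0"),
             bed)
  b <- read_bed(bed)
  expect_identical(b$start, c(10L, 100L))
  expect_identical(b$V7, c(1L, 0L))

  bg <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t5\t7\t0.5", "chr1\t9\t10\t-1"), bg)
  tr <- read_bedgraph(bg)
  expect_identical(tr$pos, c(5L, 6L, 9L))
  expect_identical(tr$value, c(0.5, 0.5, -1))
})
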