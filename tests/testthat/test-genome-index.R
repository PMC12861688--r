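test_that("CG dinucleotides are found case-insensitively, ambiguity excluded", {
  idx <- tiny_index()
  expect_equal(idx$total_cpgs, 2L)
  expect_equal(idx$cpg_positions$chr1, c(2L, 5L))

  idx2 <- make_index(c(chr1 = "CGCG"))
  expect_equal(idx2$cpg_positions$chr1, c(1L, 3L))

  soft <- make_index(c(chr1 = "acgtcgg"))
  expect_equal(soft$cpg_positions$chr1, c(2L, 5L))

  amb <- make_index(c(chr1 = "ACNGTCGN"))
  expect_equal(amb$cpg_positions$chr1, 6L)
})

test_that("bad FASTA input is rejected", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr1", "TTTT"), fa)
  expect_error(build_index(fa), "duplicate")
  writeLines(character(0), fa)
  expect_error(build_index(fa))
})

test_that("locus_to_cpg is exact-match and cpg_to_locus inverts it", {
  idx <- tiny_index()
  expect_equal(locus_to_cpg(idx, "chr1", 5), 2L)
  expect_equal(locus_to_cpg(idx, "chr1", 2), 1L)
  expect_error(locus_to_cpg(idx, "chr1", 3), "not a CpG")
  expect_error(locus_to_cpg(idx, "chrX", 3), )

  expect_equal(cpg_to_locus(idx, 2), list(chrom = "chr1", pos = 5L))
  expect_error(cpg_to_locus(idx, 3), "out of range")
})

test_that("round trip holds for every CpG of a multi-chromosome genome", {
  idx <- make_index(c(a = "CGCGTTACG", b = "TTTT", c = "ACGACGT"))
  expect_equal(idx$total_cpgs, 5L)
  for (i in seq_len(idx$total_cpgs)) {
    loc <- cpg_to_locus(idx, i)
    expect_identical(locus_to_cpg(idx, loc$chrom, loc$pos), i)
  }
})

test_that("region_to_cpg_range uses 0-based half-open genomic intervals", {
  idx <- tiny_index()
  expect_equal(region_to_cpg_range(idx, "chr1", 0, 7),
               list(start_cpg = 1L, end_cpg = 3L))
  expect_equal(region_to_cpg_range(idx, "chr1", 3, 4),
               list(start_cpg = 2L, end_cpg = 2L))
  expect_error(region_to_cpg_range(idx, "nope", 0, 7), "unknown chromosome")

  # linear-scan oracle over random intervals
  g <- simulate_genome(40, spacing = 5, seed = 11)
  fa <- tempfile(fileext = ".fa"); write_sim_fasta(g, fa)
  gi <- build_index(fa)
  with_seed(42, {
    for (k in 1:50) {
      s <- sample(0:(g$length - 1), 1); e <- sample(s:g$length, 1)
      inside <- which(g$positions > s & g$positions <= e)
      r <- region_to_cpg_range(gi, g$chrom, s, e)
      expect_equal(r$end_cpg - r$start_cpg, length(inside))
      if (length(inside)) expect_equal(r$start_cpg, min(inside))
    }
  })
})

test_that("whole-chromosome region returns the chromosome's CpG count", {
  idx <- make_index(c(a = "CGCGTTACG", b = "ACGACGT"))
  r <- region_to_cpg_range(idx, "a", 0, idx$chrom_sizes[["a"]])
  expect_equal(r$end_cpg - r$start_cpg, length(idx$cpg_positions$a))
  r <- region_to_cpg_range(idx, "b", 0, idx$chrom_sizes[["b"]])
  expect_equal(r$end_cpg - r$start_cpg, length(idx$cpg_positions$b))
})

test_that("reverse-complemented genome has the same CpG count", {
  g <- simulate_genome(25, spacing = 6, seed = 3)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$seq)))
  expect_equal(make_index(c(chr1 = g$seq))$total_cpgs,
               make_index(c(chr1 = rc))$total_cpgs)
})

test_that("convert_bed appends CpG ranges and preserves rows", {
  idx <- tiny_index()
  one <- convert_bed(idx, data.frame(V1 = "chr1", V2 = 0, V3 = 7))
  expect_equal(one$startCpG, 1L)
  expect_equal(one$endCpG, 3L)

  empty <- convert_bed(idx, data.frame(V1 = character(0), V2 = integer(0),
                                       V3 = integer(0)))
  expect_equal(nrow(empty), 0L)

  g <- simulate_genome(30, spacing = 8, seed = 5)
  fa <- tempfile(fileext = ".fa"); write_sim_fasta(g, fa)
  gi <- build_index(fa)
  bed <- data.frame(V1 = g$chrom, V2 = c(0, 40, 100),
                    V3 = c(60, 41, 200), name = c("x", "y", "z"))
  out <- convert_bed(gi, bed)
  expect_equal(out$name, bed$name)
  for (i in 1:3) {
    r <- region_to_cpg_range(gi, g$chrom, bed$V2[i], bed$V3[i])
    expect_equal(out$startCpG[i], r$start_cpg)
    expect_equal(out$endCpG[i], r$end_cpg)
  }
})

test_that("convert_bed flags bad rows by line, strict mode aborts", {
  idx <- tiny_index()
  bed <- data.frame(V1 = c("chr1", "chrZ"), V2 = c(0, 0), V3 = c(7, 5))
  expect_warning(out <- convert_bed(idx, bed), "line")
  expect_equal(nrow(out), 1L)
  expect_error(convert_bed(idx, bed, strict = TRUE), "line")
})

test_that("index file round trip preserves everything", {
  idx <- make_index(c(a = "CGCGTTACG", b = "TTTT", c = "ACGACGT"))
  f <- tempfile()
  write_index(idx, f)
  idx2 <- read_index(f)
  expect_equal(idx2$chrom_order, idx$chrom_order)
  expect_equal(idx2$cpg_positions, idx$cpg_positions)
  expect_equal(idx2$chrom_offsets, idx$chrom_offsets)
  expect_equal(idx2$total_cpgs, idx$total_cpgs)
})

test_that("build_index recovers planted CpGs of simulated genomes", {
  with_seed(99, {
    for (k in 1:10) {
      n <- sample(1:60, 1)
      g <- simulate_genome(n, spacing = sample(2:12, 1))
      fa <- tempfile(fileext = ".fa"); write_sim_fasta(g, fa)
      gi <- build_index(fa)
      expect_equal(gi$total_cpgs, n)
      expect_equal(gi$cpg_positions[[g$chrom]], g$positions)
    }
  })
})
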