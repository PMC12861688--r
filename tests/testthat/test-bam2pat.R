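# hand-built reference with four CpGs at known positions
ref4 <- function() {
  g <- simulate_genome(4, spacing = 6, pad = 10, seed = 2)
  fa <- tempfile(fileext = ".fa"); write_sim_fasta(g, fa)
  list(g = g, idx = build_index(fa))
}

write_sam <- function(g, rows, path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", g$chrom, g$length), rows), path)
  path
}

# a read copied from the reference with chosen base at each CpG C position
read_with <- function(g, from, to, at, bases, flag = 0L, mapq = 60L,
                      qname = "r1") {
  chars <- strsplit(g$seq, "", fixed = TRUE)[[1]][from:to]
  chars[at - from + 1L] <- bases
  paste(qname, flag, g$chrom, from, mapq, paste0(to - from + 1L, "M"),
        "*", 0L, 0L, paste(chars, collapse = ""), "*", sep = "\t")
}

test_that("top-strand reads call C->methylated, T->unmethylated", {
  r <- ref4()
  span <- c(r$g$positions[1] - 2L, r$g$positions[4] + 3L)
  sam <- write_sam(r$g, read_with(r$g, span[1], span[2], r$g$positions,
                                  c("C", "C", "C", "T")))
  out <- bam_to_pat(sam, r$idx)
  expect_equal(out$pattern, "CCCT")
  expect_equal(out$start_cpg, 1L)
  # non-C/T base at a CpG is unknown
  sam2 <- write_sam(r$g, read_with(r$g, span[1], span[2], r$g$positions,
                                   c("C", "G", "C", "T")))
  expect_equal(bam_to_pat(sam2, r$idx)$pattern, "C.CT")
})

test_that("bottom-strand reads call at the G: G->methylated, A->unmethylated", {
  r <- ref4()
  gpos <- r$g$positions + 1L
  sam <- write_sam(r$g, read_with(r$g, gpos[1] - 1L, gpos[1] + 2L, gpos[1],
                                  "G", flag = 16L))
  expect_equal(bam_to_pat(sam, r$idx)$pattern, "C")
  sam2 <- write_sam(r$g, read_with(r$g, gpos[1] - 1L, gpos[1] + 2L, gpos[1],
                                   "A", flag = 16L))
  expect_equal(bam_to_pat(sam2, r$idx)$pattern, "T")
})

test_that("reads overlapping no CpG are discarded", {
  r <- ref4()
  # squeeze between CpG 1's G and CpG 2's C
  from <- r$g$positions[1] + 2L; to <- r$g$positions[2] - 1L
  sam <- write_sam(r$g, read_with(r$g, from, to, integer(0), character(0)))
  expect_equal(nrow(bam_to_pat(sam, r$idx)), 0L)
})

test_that("flag and mapq filters follow the defaults", {
  r <- ref4()
  span <- c(r$g$positions[1] - 2L, r$g$positions[2] + 2L)
  low_q <- read_with(r$g, span[1], span[2], r$g$positions[1:2], c("C", "C"),
                     mapq = 5L)
  dup <- read_with(r$g, span[1], span[2], r$g$positions[1:2], c("C", "C"),
                   flag = 1024L)
  good <- read_with(r$g, span[1], span[2], r$g$positions[1:2], c("C", "C"))
  out <- bam_to_pat(write_sam(r$g, c(low_q, dup, good)), r$idx)
  expect_equal(sum(out$count), 1L)
})

test_that("mates merge with gap filling and conflict masking", {
  expect_equal(merge_mates(list(start_cpg = 1L, pattern = "C"),
                           list(start_cpg = 4L, pattern = "T")),
               list(start_cpg = 1L, pattern = "C..T"))
  expect_equal(merge_mates(list(start_cpg = 1L, pattern = "CC"),
                           list(start_cpg = 2L, pattern = "CT"))$pattern,
               "CCT")
  expect_equal(merge_mates(list(start_cpg = 1L, pattern = "CC"),
                           list(start_cpg = 2L, pattern = "TT"))$pattern,
               "C.T")
})

test_that("pattern count equals fragments passing filters with >=1 CpG", {
  g <- simulate_genome(25, spacing = 9, seed = 31)
  fa <- tempfile(fileext = ".fa"); write_sim_fasta(g, fa)
  idx <- build_index(fa)
  sim <- simulate_reads(g, theta = 0.5, depth = 12, read_len = 40,
                        paired = TRUE, insert_len = 100, seed = 32)
  out <- bam_to_pat(sim$sam, idx)
  expect_equal(sum(out$count), sum(sim$truth$count))
  expect_identical(out, sim$truth)
})

test_that("a fully unmethylated library yields no methylated calls", {
  g <- simulate_genome(20, spacing = 7, seed = 41)
  fa <- tempfile(fileext = ".fa"); write_sim_fasta(g, fa)
  idx <- build_index(fa)
  sim <- simulate_reads(g, theta = 0, depth = 10, read_len = 35, seed = 42)
  out <- bam_to_pat(sim$sam, idx)
  expect_false(any(grepl("C", out$pattern)))
  sim2 <- simulate_reads(g, theta = 1, depth = 10, read_len = 35, seed = 43)
  expect_false(any(grepl("T", bam_to_pat(sim2$sam, idx)$pattern)))
})

test_that("calling is order-independent after collapse", {
  g <- simulate_genome(15, spacing = 8, seed = 51)
  fa <- tempfile(fileext = ".fa"); write_sim_fasta(g, fa)
  idx <- build_index(fa)
  sim <- simulate_reads(g, theta = 0.5, depth = 8, read_len = 40, seed = 52)
  lines <- readLines(sim$sam)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  shuf <- tempfile(fileext = ".sam")
  writeLines(c(hdr, with_seed(1, sample(body))), shuf)
  expect_identical(bam_to_pat(shuf, idx), bam_to_pat(sim$sam, idx))
})

test_that("strand symmetry: complementary reads give identical patterns", {
  r <- ref4()
  p <- r$g$positions
  span <- c(p[1] - 2L, p[4] + 3L)
  top <- read_with(r$g, span[1], span[2], p, c("C", "T", "C", "T"))
  # bottom-strand counterpart: same methylation encoded at the G positions
  bot <- read_with(r$g, span[1], span[2], p + 1L, c("G", "A", "G", "A"),
                   flag = 16L, qname = "r2")
  out <- bam_to_pat(write_sam(r$g, c(top, bot)), r$idx)
  expect_equal(out$pattern, "CTCT")
  expect_equal(out$count, 2L)
})

test_that("long reads call from MM/ML tags with 0.5 threshold tie -> C", {
  r <- ref4()
  p <- r$g$positions
  seq <- substr(r$g$seq, p[1] - 2L, p[2] + 3L)
  cl <- call_longread(r$g$chrom, p[1] - 2L, paste0(nchar(seq), "M"), seq,
                      flag = 0L, mm = "C+m?,0,0;", ml = c(230L, 20L),
                      index = r$idx)
  expect_equal(cl$pattern, "CT")
  # ML 128 decodes to (128 + 0.5)/256 >= 0.5: boundary calls methylated
  cl2 <- call_longread(r$g$chrom, p[1] - 2L, paste0(nchar(seq), "M"), seq,
                       flag = 0L, mm = "C+m?,0,0;", ml = c(128L, 127L),
                       index = r$idx)
  expect_equal(cl2$pattern, "CT")
})

test_that("a 120-CpG long read round-trips as one record", {
  g <- simulate_genome(120, spacing = 4, pad = 5, seed = 61)
  fa <- tempfile(fileext = ".fa"); write_sim_fasta(g, fa)
  idx <- build_index(fa)
  sim <- simulate_reads(g, theta = 0.5, depth = 1, read_len = g$length,
                        long_read = TRUE, seed = 62)
  out <- bam_to_pat(sim$sam, idx, conversion_params(long_read = TRUE))
  expect_identical(out, sim$truth)
  expect_true(any(nchar(out$pattern) == 120L))
})

test_that("cigar projection handles indels and clips", {
  r <- ref4()
  p <- r$g$positions
  # read starts 3 bases left of CpG1, 2-base insertion before the CpG,
  # then matches across it
  chars <- strsplit(r$g$seq, "", fixed = TRUE)[[1]]
  seq <- paste(c(chars[(p[1] - 3L):(p[1] - 1L)], "A", "A",
                 chars[p[1]:(p[1] + 4L)]), collapse = "")
  row <- paste("r1", 0L, r$g$chrom, p[1] - 3L, 60L, "3M2I5M", "*", 0, 0,
               seq, "*", sep = "\t")
  out <- bam_to_pat(write_sam(r$g, row), r$idx)
  expect_equal(out$pattern, "C")   # reference C read as C through the cigar
  # deletion spanning CpG1 gives an unknown call there; CpG2 still called
  seq2 <- paste(chars[c((p[1] - 3L):(p[1] - 1L), (p[1] + 3L):(p[1] + 7L))],
                collapse = "")
  row2 <- paste("r1", 0L, r$g$chrom, p[1] - 3L, 60L, "3M3D5M", "*", 0, 0,
                seq2, "*", sep = "\t")
  out2 <- bam_to_pat(write_sam(r$g, row2), r$idx)
  expect_equal(out2$pattern, "C")
  expect_equal(out2$start_cpg, 2L)
})
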