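test_that("identical patterns collapse with summed counts", {
  rec <- pat_records("chr1", c(5, 5), c("CTTT", "CTTT"))
  out <- collapse_pat(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$count, 2L)
  expect_equal(out$pattern, "CTTT")
})

test_that("distinct patterns stay separate and sort in C locale", {
  out <- collapse_pat(pat_records("chr1", c(5, 5), c("CTTT", "CTTC")))
  expect_equal(out$pattern, c("CTTC", "CTTT"))
  # '.' sorts before 'C' before 'T'
  out2 <- collapse_pat(pat_records("chr1", c(2, 2, 2),
                                   c("T.T", "C.C", "CTC")))
  expect_equal(out2$pattern, c("C.C", "CTC", "T.T"))
})

test_that("collapse conserves counts, is idempotent, keeps the multiset", {
  rec <- random_pat(100, seed = 7)
  out <- collapse_pat(rec)
  expect_equal(sum(out$count), sum(rec$count))
  expect_identical(collapse_pat(out), out)
  key <- function(df) sort(rep(paste(df$chrom, df$start_cpg, df$pattern),
                               df$count))
  expect_identical(key(out), key(rec))
  expect_identical(collapse_pat(rec[0, ]), rec[0, ])
})

test_that("clipping trims patterns to CpG boundaries", {
  out <- clip_pat(pat_records("chr1", 3, "CCCT"), 4, 6)
  expect_equal(out$start_cpg, 4L)
  expect_equal(out$pattern, "CC")
  # clipping away all observed sites drops the record
  expect_equal(nrow(clip_pat(pat_records("chr1", 3, "C..T"), 4, 6)), 0L)
})

test_that("query filters by observed-site overlap, min_sites, subsampling", {
  rec <- pat_records("chr1", c(3, 10), c("C..T", "CCT"))
  # record 1 has observed sites {3, 6}: a window over its '.' gap misses it
  hit <- query_pat(rec, start_cpg = 4, end_cpg = 6)
  expect_equal(nrow(hit), 0L)
  hit <- query_pat(rec, start_cpg = 6, end_cpg = 7)
  expect_equal(hit$pattern, "C..T")

  expect_equal(nrow(query_pat(rec, min_sites = 3)), 1L)  # "C..T" observes 2
  expect_equal(query_pat(rec, min_sites = 3)$pattern, "CCT")

  expect_identical(query_pat(rec, subsample_rate = 1), rec)
  expect_equal(nrow(query_pat(rec, subsample_rate = 0)), 0L)
  a <- query_pat(rec, subsample_rate = 0.5, seed = 9)
  b <- query_pat(rec, subsample_rate = 0.5, seed = 9)
  expect_identical(a, b)
})

test_that("min_sites counts observed sites after clipping", {
  rec <- pat_records("chr1", 1, "CCCCC")
  out <- query_pat(rec, clip_to = c(2, 4), min_sites = 3)
  expect_equal(nrow(out), 0L)
  out <- query_pat(rec, clip_to = c(2, 5), min_sites = 3)
  expect_equal(out$pattern, "CCC")
})

test_that("masking blanks CpGs, drops empty records, re-collapses", {
  mk <- function(s, e) data.frame(chrom = rep("chr1", length(s)),
                                  start_cpg = s, end_cpg = e)
  out <- mask_pat(pat_records("chr1", 10, "CCT"), mk(11, 12))
  expect_equal(out$pattern, "C.T")
  expect_equal(nrow(mask_pat(pat_records("chr1", 10, "CC"), mk(10, 12))), 0L)
  rec <- random_pat(50, seed = 3)
  expect_identical(mask_pat(rec, mk(integer(0), integer(0))),
                   collapse_pat(rec))
  # masked sites lose all coverage downstream
  masked <- mask_pat(pat_records("chr1", c(1, 2), c("CCC", "TTT")), mk(2, 3))
  b <- pat_to_beta(masked, 5)
  expect_equal(b$total[2], 0L)
})

test_that("mixing thins each source at its rate and is reproducible", {
  a <- pat_records("chr1", 1:5, rep("CC", 5), 10L)
  b <- pat_records("chr1", 6:8, rep("TT", 3), 10L)
  expect_identical(mix_pat(list(a, b), c(1, 0)), collapse_pat(a))
  expect_error(mix_pat(list(a, b), 1), "one rate per")

  big <- pat_records("chr1", 1, "CT", 10000L)
  got <- sum(mix_pat(list(big), 0.5, seed = 5)$count)
  expect_lt(abs(got - 5000), 4 * sqrt(10000 * 0.25))

  expect_identical(mix_pat(list(a, b), c(0.5, 0.5), seed = 77),
                   mix_pat(list(a, b), c(0.5, 0.5), seed = 77))
})

test_that("PAT file round trip preserves the record multiset exactly", {
  rec <- collapse_pat(random_pat(80, seed = 21))
  gz <- write_pat(rec, tempfile(fileext = ".pat"))
  expect_true(file.exists(paste0(gz, ".tbi")))
  back <- read_pat(gz)
  expect_identical(back, rec)

  plain <- write_pat(rec, tempfile(fileext = ".pat"), index = FALSE)
  expect_identical(read_pat(plain), rec)
})

test_that("tabix-indexed regional query matches in-memory filtering", {
  rec <- collapse_pat(random_pat(120, seed = 8))
  gz <- write_pat(rec, tempfile(fileext = ".pat"))
  for (win in list(c(1, 10), c(10, 25), c(30, 51))) {
    expect_identical(
      query_pat(gz, chrom = "chr1", start_cpg = win[1], end_cpg = win[2]),
      query_pat(rec, chrom = "chr1", start_cpg = win[1], end_cpg = win[2]))
  }
  # whole-range query returns everything
  expect_identical(query_pat(gz, chrom = "chr1"), rec)
})

test_that("invalid records are rejected", {
  expect_error(pat_records("chr1", 1, "CXT"), "only contain")
  expect_error(pat_records("chr1", 1, "..."), "at least one observed")
  expect_error(pat_records("chr1", 1, "CT", 0), "count")
  expect_error(pat_records("chr1", 0, "CT"), "positive CpG index")
})
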