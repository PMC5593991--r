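test_that("support profile: identical and disjoint samples", {
  iv <- data.frame(contig = "chrT", start = 100, end = 200)
  prof <- support_profile(list(iv, iv, iv))
  expect_equal(prof, data.frame(contig = "chrT", start = 100, end = 200,
                                support = 3L))
  disj <- lapply(c(0, 300, 600), function(s)
    data.frame(contig = "chrT", start = s, end = s + 100))
  expect_true(all(support_profile(disj)$support == 1))
})

test_that("sweep-line support equals the naive per-base oracle on random instances", {
  set.seed(42)
  for (i in 1:120) {
    colls <- random_collections(sample(2:6, 1), contig_len = 10000)
    prof <- support_profile(colls)
    expect_identical(profile_to_bases(prof, 10000),
                     per_base_support(colls, 10000))
  }
})

test_that("the 14-of-18 rule and input exclusion behave as specified", {
  locus <- data.frame(contig = "chrT", start = 1000, end = 1500)
  other <- data.frame(contig = "chrT", start = 5000, end = 5500)
  mk <- function(n_locus, n_other = 18) {
    lapply(seq_len(18), function(i) {
      rbind(if (i <= n_locus) locus, if (i <= n_other) other)
    })
  }
  # covered by exactly 14 of 18 -> consensus
  cs <- call_consensus(mk(14), m = 14)
  expect_true(any(cs$regions$start == 1000 & cs$regions$end == 1500))
  # 13 of 18 -> not called
  cs13 <- call_consensus(mk(13), m = 14)
  expect_false(any(cs13$regions$start == 1000))
  # 18 of 18 but overlapping an input peak -> excluded, not consensus
  input <- data.frame(contig = "chrT", start = 1490, end = 1600)
  cse <- call_consensus(mk(18), input = input, m = 14)
  expect_false(any(cse$regions$start == 1000))
  expect_true(any(cse$excluded$start == 1000))
  # the non-overlapping locus stays consensus with full support
  expect_true(any(cse$regions$start == 5000 & cse$regions$support_min == 18))
  expect_error(call_consensus(list(), m = 1))
})

test_that("consensus is monotone in m and reduces to merged union minus input at m = 1", {
  set.seed(7)
  colls <- random_collections(6, contig_len = 10000)
  input <- data.frame(contig = "chrT", start = c(40, 7000), end = c(90, 7050))
  base_cov <- function(cs) {
    sum(cs$regions$end - cs$regions$start)
  }
  prev <- Inf
  for (m in 1:6) {
    cs <- call_consensus(colls, input = input, m = m)
    expect_lte(base_cov(cs), prev)
    prev <- base_cov(cs)
  }
  cs1 <- call_consensus(colls, input = input, m = 1)
  merged <- support_profile(colls)
  keep <- !overlaps_any_regions(merged, input)
  # m = 1: union of all calls (merged runs), minus regions touching input
  union_runs <- call_consensus(colls, input = empty_peaks(), m = 1)$regions
  expect_equal(cs1$regions[c("contig", "start", "end")],
               union_runs[!overlaps_any_regions(union_runs, input),
                          c("contig", "start", "end")],
               ignore_attr = TRUE)
})

test_that("call_consensus is idempotent on its own output", {
  set.seed(9)
  colls <- random_collections(5, contig_len = 8000)
  input <- data.frame(contig = "chrT", start = 100, end = 160)
  cs <- call_consensus(colls, input = input, m = 3)
  again <- call_consensus(list(cs$regions[c("contig", "start", "end")]),
                          input = input, m = 1)
  expect_equal(again$regions[c("contig", "start", "end")],
               cs$regions[c("contig", "start", "end")], ignore_attr = TRUE)
})

test_that("sweep consensus equals the per-base oracle, including exclusions", {
  set.seed(11)
  for (i in 1:100) {
    colls <- random_collections(sample(3:8, 1), contig_len = 10000)
    input <- if (i %% 3 == 0) random_collections(1, 10000)[[1]] else empty_peaks()
    m <- sample(seq_along(colls), 1)
    cs <- call_consensus(colls, input = input, m = m)
    orc <- oracle_consensus(colls, normalize_peaks(input), m, 10000)
    got <- rbind(cs$regions[c("start", "end")], cs$excluded[c("start", "end")])
    got <- got[order(got$start), ]
    expect_equal(got$start, orc$start)
    expect_equal(got$end, orc$end)
    expect_equal(cs$excluded$start, orc$start[orc$excluded])
  }
})

test_that("gene annotation reflects consensus but not excluded regions", {
  locus <- data.frame(contig = "chrT", start = 1000, end = 1500)
  excl <- data.frame(contig = "chrT", start = 5000, end = 5500)
  colls <- lapply(1:3, function(i) rbind(locus, excl))
  input <- data.frame(contig = "chrT", start = 5400, end = 5600)
  cs <- call_consensus(colls, input = input, m = 3)
  genes <- data.frame(contig = "chrT", start = c(900, 4900, 8000),
                      end = c(2000, 5600, 8100),
                      name = c("Npy", "Npy2r", "Npy5r"))
  ann <- annotate_genes(cs, genes)
  expect_equal(ann$has_consensus_peak, c(TRUE, FALSE, FALSE))
})

test_that("synthetic truth loci are recovered exactly at full presence", {
  loci <- data.frame(contig = "chrT", start = c(2000, 6000), end = c(2400, 6300))
  pk <- simulate_peaksets(18, loci, presence_prob = 1, jitter_sd = 0,
                          noise_rate = 0, seed = 3)
  cs <- call_consensus(pk$samples, pk$input, m = 14)
  genes <- data.frame(contig = "chrT", start = loci$start - 100,
                      end = loci$end + 100, name = c("g1", "g2"))
  expect_true(all(annotate_genes(cs, genes)$has_consensus_peak))
})

test_that("BED round-trip preserves 0-based half-open coordinates", {
  p <- data.frame(contig = c("chrT", "chrT"), start = c(0, 500), end = c(100, 700))
  f <- tempfile(fileext = ".bed")
  write_peaks_bed(p, f)
  expect_equal(read_peaks_bed(f), p)
  raw <- read.table(f, sep = "\t")
  expect_equal(raw$V2, c(0, 500))  # BED stores 0-based starts
})

test_that("interval normalization merges overlaps and validates bounds", {
  p <- data.frame(contig = "chrT", start = c(10, 50, 200), end = c(60, 100, 300))
  n <- normalize_peaks(p)
  expect_equal(n$start, c(10, 200))
  expect_equal(n$end, c(100, 300))
  expect_error(normalize_peaks(data.frame(contig = "c", start = 5, end = 5)))
})
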