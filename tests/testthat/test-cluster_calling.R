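mk_reads <- function(pos, strand = "+", chrom = "chr1") {
  tibble::tibble(chrom = chrom, strand = strand, polya_pos = as.integer(pos),
                 mate_pos = as.integer(pos) - 100L,
                 sample = "S01", replicate = "R1")
}

test_that("gap clustering splits only on gaps above the threshold", {
  gg <- group_by_gap(mk_reads(c(100, 110, 126, 150)))
  expect_equal(gg$raw_cluster, c(1L, 1L, 2L, 3L))
  # a gap of exactly 15 bp stays in one cluster
  expect_equal(group_by_gap(mk_reads(c(100, 115)))$raw_cluster, c(1L, 1L))
  expect_equal(group_by_gap(mk_reads(42))$raw_cluster, 1L)
  expect_error(group_by_gap(mk_reads(c(5, 3))), "sorted")
})

test_that("gap clustering separates chromosome strands", {
  rd <- dplyr::bind_rows(mk_reads(c(100, 105)), mk_reads(c(100, 105), "-"))
  expect_equal(group_by_gap(rd)$raw_cluster, c(1L, 1L, 2L, 2L))
})

test_that("peak splitting resolves two spikes and discards in-between noise", {
  pos <- rep(c(0L, 10L, 20L, 30L, 40L, 50L), c(100, 1, 1, 1, 1, 100))
  parts <- split_by_peaks(pos)
  expect_length(parts, 2)
  expect_equal(parts[[1]], rep(0L, 100))
  expect_equal(parts[[2]], rep(50L, 100))
})

test_that("narrow clusters pass through the peak finder unchanged", {
  pos <- rep(c(5L, 45L), c(3, 7)) # span exactly 40
  expect_equal(split_by_peaks(pos), list(sort(pos)))
})

test_that("equal spikes 30 bp apart give one joint and one single cluster", {
  # the 5'-most argmax anchors a window retaining the first two spikes as
  # the middle candidate; the third is recovered by recursion on the right
  pos <- rep(c(0L, 30L, 60L), each = 100)
  parts <- split_by_peaks(pos)
  expect_length(parts, 2)
  expect_equal(sort(unique(parts[[1]])), c(0L, 30L))
  expect_equal(unique(parts[[2]]), 60L)
})

test_that("peak splitting matches the independently coded recursion", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(2:300, 1)
    span <- sample(10:200, 1)
    pos <- sort(sample(0:span, n, replace = TRUE,
                       prob = runif(span + 1)^3))
    strand <- sample(c("+", "-"), 1)
    got <- split_by_peaks(pos, strand = strand)
    want <- oracle_peak_split(pos, strand = strand)
    expect_identical(got, want)
  }
})

test_that("retained reads partition exactly into the returned clusters", {
  set.seed(7)
  for (i in 1:20) {
    pos <- sort(sample(0:150, 200, replace = TRUE, prob = runif(151)^4))
    parts <- split_by_peaks(pos)
    kept <- sort(unlist(parts))
    # leaves are disjoint in position and each retained read appears once
    expect_true(all(table(kept) <= table(pos)[names(table(kept))]))
    if (length(parts) > 1) {
      for (k in seq_len(length(parts) - 1)) {
        expect_true(max(parts[[k]]) < min(parts[[k + 1]]))
      }
    }
  }
})

test_that("cluster position is the (lower-middle) median member", {
  expect_equal(cluster_position(c(100, 100, 100)), 100)
  expect_equal(cluster_position(c(104, 100, 102)), 102)
  expect_equal(cluster_position(c(100, 101, 103, 104)), 101)
})

test_that("precision is the concentration index over read positions", {
  expect_equal(precision(rep(7, 500)), 1.0)
  expect_equal(precision(rep(c(1, 9), each = 5)), 0.5)
  expect_equal(precision(1:10), 0.1)
  expect_error(precision(integer(0)), "empty")
})

test_that("duplication filter compares polyA and mate precision strictly", {
  expect_true(filter_duplication(rep(5, 10), 1:10 * 50))
  expect_false(filter_duplication(1:10, rep(1, 10)))
  expect_false(filter_duplication(c(1, 1, 2, 2), c(5, 5, 9, 9))) # tie
})

test_that("internal-priming filter counts downstream A's in transcript sense", {
  g <- str_genome(paste0(strrep("C", 20), "AAAAAAAAAACGTACGTACG",
                         "AACGGACGAACGGACGAACG"))
  cl <- dplyr::bind_rows(
    fake_cluster(polya_pos = 20L), # downstream = 10 A's then CGT...
    fake_cluster(polya_pos = 40L) # downstream = 8 A's
  )
  expect_equal(filter_internal_priming(cl, g), c(TRUE, FALSE))
})

test_that("minus-strand mispriming reads the plus-strand T run", {
  g <- str_genome(paste0(strrep("C", 10), strrep("T", 10), strrep("G", 20)))
  cl <- fake_cluster(strand = "-", polya_pos = 21L) # upstream genomic [1,20]
  expect_true(filter_internal_priming(cl, g))
  cl2 <- fake_cluster(strand = "+", polya_pos = 21L)
  expect_false(filter_internal_priming(cl2, g))
})

test_that("abundance filter applies count and grey-zone correlation rules", {
  m <- function(r1, r2) cbind(r1, r2)
  expect_equal(filter_abundance(m(c(24, 0, 0, 0, 0, 0), c(25, 0, 0, 0, 0, 0))),
               "low_count") # total 49
  # total 75 inside the grey zone with perfectly correlated replicates
  expect_equal(filter_abundance(m(c(20, 15, 10, 10, 10, 10) / 2,
                                  c(20, 15, 10, 10, 10, 10) / 2)), "keep")
  r1 <- c(20, 0, 0, 0, 0, 10)
  r2 <- c(0, 10, 0, 20, 0, 0)
  expect_lt(abs(cor(r1, r2)), 0.5)
  expect_equal(filter_abundance(m(r1, r2)), "low_replicate_corr")
  expect_equal(filter_abundance(m(rep(8, 6), rep(8, 6))),
               "low_replicate_corr") # total 96, zero variance, R undefined
  expect_equal(filter_abundance(m(rep(30, 6), rep(30, 6))), "keep") # total 360
})

test_that("raising the count threshold never adds retained clusters", {
  set.seed(31)
  rd <- tibble::tibble(
    chrom = "chr1", strand = "+",
    polya_pos = sort(sample(seq(100, 2000, by = 60), 400, replace = TRUE)),
    mate_pos = 0L, sample = sample(sprintf("S%02d", 1:6), 400, TRUE),
    replicate = sample(c("R1", "R2"), 400, TRUE)
  )
  rd$mate_pos <- rd$polya_pos - sample(80:250, 400, TRUE)
  kept <- sapply(c(10, 30, 50, 80), function(mc) {
    sum(call_clusters(rd, params = peak_params(min_count = mc,
                                               grey_zone = c(mc, mc)))$retained)
  })
  expect_true(all(diff(kept) <= 0))
})
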