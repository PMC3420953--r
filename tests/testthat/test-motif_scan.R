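test_that("ARE scanner enforces the exact central pentamer", {
  expect_equal(scan_are("TTTTATTTATTTT", merge = FALSE)$mismatches, 0L)
  expect_equal(scan_are("GTTTATTTATTTT", merge = FALSE)$mismatches, 1L)
  expect_equal(nrow(scan_are("TTTTATTGATTTT")), 0L) # pentamer violated
  expect_equal(nrow(scan_are("GGTTATTTATTTT")), 0L) # two flank mismatches
})

test_that("GRE scanner allows Hamming distance one anywhere", {
  expect_equal(nrow(scan_gre("TGTTTGTTTGT")), 1L)
  expect_equal(nrow(scan_gre("TGTTTGTTTGA")), 1L)
  expect_equal(nrow(scan_gre("TGTTAGTTAGT")), 0L)
})

test_that("PUF scanner matches TGTANATA exactly", {
  expect_equal(nrow(scan_puf("TGTACATA")), 1L)
  expect_equal(nrow(scan_puf("TGTAAATA")), 1L)
  expect_equal(nrow(scan_puf("TGTACATG")), 0L)
})

test_that("scanners agree with the brute-force window oracle", {
  set.seed(99)
  for (i in 1:150) {
    s <- random_dna(60, probs = c(0.35, 0.15, 0.15, 0.35))
    o_are <- oracle_scan(s, "WWWTATTTATTTW", 1, fixed = 5:9)
    g_are <- scan_are(s, merge = FALSE)
    expect_equal(g_are$start, o_are$start)
    o_gre <- oracle_scan(s, "TGTTTGTTTGT", 1)
    expect_equal(scan_gre(s, merge = FALSE)$start, o_gre$start)
    o_puf <- oracle_scan(s, "TGTANATA", 0)
    expect_equal(scan_puf(s)$start, o_puf$start)
  }
})

test_that("merging is idempotent and yields disjoint maximal intervals", {
  set.seed(17)
  for (i in 1:30) {
    h <- tibble::tibble(start = sample(1:80, 15, TRUE))
    h$end <- h$start + sample(5:12, 15, TRUE)
    m1 <- merge_hits(h)
    expect_identical(merge_hits(m1), m1)
    if (nrow(m1) > 1) expect_true(all(diff(m1$start) > 0))
    for (k in seq_len(nrow(m1) - 1)) {
      expect_true(m1$start[k + 1] > m1$end[k])
    }
  }
  # overlapping ARE matches combine into one maximal interval
  s <- paste0("TTTTATTTATTTTATTTATTTT", strrep("G", 10))
  expect_equal(nrow(scan_are(s)), 1L)
})

test_that("external sites are score-filtered and clipped to 3' UTRs", {
  utr <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                        start = 100L, end = 400L)
  mir <- data.frame(chrom = "chr1", start = c(120L, 150L),
                    end = c(127L, 157L), context_score = c(-0.5, -0.3))
  hits <- ingest_external_sites(mir, "miRNA", utr_regions = utr)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 120L)
  alu <- data.frame(chrom = "chr1", start = 380L, end = 500L)
  ah <- ingest_external_sites(alu, "Alu", utr_regions = utr)
  expect_equal(c(ah$start, ah$end), c(380L, 400L)) # clipped overlap
  expect_error(ingest_external_sites(data.frame(chrom = "chr1", start = 5,
                                                end = 2),
                                     "Alu", utr_regions = utr), "line 1")
})

test_that("hits are labelled by region with straddles going differential", {
  apa <- tibble::tibble(
    gene_id = c("gI", "gII"), apa_class = c("I", "II"), chrom = "chr1",
    strand = "+", utr3_start = c(0L, 0L), utr3_end = c(200L, 300L),
    shared_start = c(NA, 0L), shared_end = c(NA, 100L),
    diff_start = c(NA, 101L), diff_end = c(NA, 300L)
  )
  hits <- tibble::tibble(
    gene_id = c("gI", "gII", "gII", "gII"),
    motif_type = "ARE",
    start = c(50L, 20L, 150L, 95L), end = c(60L, 30L, 160L, 110L)
  )
  lab <- label_regions(hits, apa)
  expect_equal(lab$region_label,
               c("class_I_utr", "shared", "differential", "differential"))
})

test_that("SNP density counts SNPs on merged match bases", {
  hits <- tibble::tibble(chrom = "chr1", start = c(1L, 251L), end = c(250L, 500L))
  snps <- tibble::tibble(chrom = "chr1", pos = c(100L, 400L, 900L))
  d <- snp_density(hits, snps)
  expect_equal(d$snp_per_kb, 4.0)
  expect_equal(d$total_len, 500L)
  # boundary base counts (closed intervals)
  d2 <- snp_density(tibble::tibble(chrom = "chr1", start = 10L, end = 20L),
                    tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 21L)))
  expect_equal(d2$n_snps, 2L)
  expect_equal(snp_density(hits, snps[0, ])$snp_per_kb, 0)
})

test_that("background model reproduces per-base SNP rates", {
  set.seed(4)
  g <- str_genome(random_dna(4000))
  utr <- tibble::tibble(chrom = "chr1", strand = "+", start = 1L, end = 4000L)
  snps <- tibble::tibble(chrom = "chr1", pos = sample(1:4000, 200))
  rates <- snp_base_rates(utr, g, snps)
  ch <- strsplit(as.character(g[[1]]), "")[[1]]
  for (b in c("A", "C", "G", "T")) {
    expect_equal(rates[[b]], sum(ch[snps$pos] == b) / sum(ch == b))
  }
})

test_that("expected density averages per-base rates over the hit sequence", {
  g <- str_genome(paste0("AAAA", "AACC", strrep("G", 20)))
  rates <- c(A = 0.01, C = 0.02, G = 0.03, T = 0.04)
  hits <- tibble::tibble(motif_type = c("PUF", "PUF"), chrom = "chr1",
                         strand = "+", start = c(1L, 5L), end = c(4L, 8L))
  ex <- expected_snp_density(hits, g, rates)
  expect_equal(ex$expected_lower, 0.01) # "AAAA"
  expect_equal(ex$expected_upper, 0.015) # "AACC"
  # uniform per-base rate: bounds collapse to that rate
  exu <- expected_snp_density(hits, g, c(A = 0.02, C = 0.02, G = 0.02, T = 0.02))
  expect_equal(exu$expected_lower, 0.02)
  expect_equal(exu$expected_upper, 0.02)
})

test_that("miRNA expectations use only the 7-mer seed", {
  g <- str_genome(paste0(strrep("A", 10), strrep("C", 7), strrep("G", 10)))
  rates <- c(A = 0.01, C = 0.05, G = 0.01, T = 0.01)
  hits <- tibble::tibble(motif_type = "miRNA", chrom = "chr1", strand = "+",
                         start = 1L, end = 17L)
  # plus strand: the 3'-most 7 bases are the C run
  expect_equal(expected_snp_density(hits, g, rates)$expected_lower, 0.05)
})

test_that("region enrichment builds the 2x2 table and Fisher p", {
  apa <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                        apa_class = "II")
  # genes 1..20 have a shared-region hit, genes 21..40 a differential hit
  hits <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40), motif_type = "ARE",
    region_label = rep(c("shared", "differential"), each = 20)
  )
  res <- region_enrichment(apa, hits)
  want <- fisher.test(matrix(c(20, 20, 20, 20), 2, byrow = TRUE))$p.value
  expect_equal(res$p_value, want)
  # all-differential, none-shared split is strongly non-random
  res2 <- region_enrichment(apa, hits[hits$region_label == "differential", ])
  expect_lt(res2$p_value, 0.001)
  expect_error(region_enrichment(apa[0, ], hits), "class II")
})
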