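test_that("consensus base emits ambiguity codes above the minor-base cutoff", {
  expect_equal(consensus_base(c(C = 7, T = 3), "G"),
               list(base = "Y", source = "read_consensus"))
  expect_equal(consensus_base(c(C = 9, T = 1), "G"),
               list(base = "C", source = "read_consensus"))
  expect_equal(consensus_base(c(C = 3, T = 1), "G"),
               list(base = "G", source = "reference_fallback"))
  expect_equal(consensus_base(c(A = 6, G = 4), "C")$base, "R")
})

test_that("build_consensus blends read consensus with reference fallback", {
  g <- str_genome("ACGTACGTAC")
  pu <- tibble::tibble(chrom = "chr1", pos = c(3L, 4L),
                       A = c(6L, 2L), C = c(0L, 1L), G = c(1L, 0L),
                       T = c(0L, 1L))
  tr <- build_consensus(pu, g)
  expect_equal(tr$base, c("A", "T")) # pos 4 (coverage 4) falls back to ref T
  expect_equal(tr$source, c("read_consensus", "reference_fallback"))
})

test_that("pileup counts both mates and splits alleles by genotype dosage", {
  g <- str_genome(strrep("ACGT", 100))
  rd <- tibble::tibble(
    chrom = "chr1", strand = "+",
    polya_pos = rep(200L, 10), mate_pos = rep(120L, 10),
    n_T = rep(10L, 10),
    sample = rep(c("S01", "S02"), each = 5), replicate = "R1"
  )
  pu <- reads_pileup(rd, g, "chr1", 180L, 200L)
  # tail-anchored body covers [171, 200]: coverage 10 across the window
  expect_true(all(pu$A + pu$C + pu$G + pu$T == 10L))
  v <- tibble::tibble(snp_id = "s1", chrom = "chr1", pos = 190L,
                      ref = "C", alt = "T")
  gt <- tibble::tibble(snp_id = "s1", sample = c("S01", "S02"),
                       dosage_ref = c(2L, 0L))
  pu2 <- reads_pileup(rd, g, "chr1", 180L, 200L, variants = v, genotypes = gt)
  i <- match(190L, pu2$pos)
  expect_equal(pu2$C[i], 5L) # S01 homozygous reference
  expect_equal(pu2$T[i], 5L) # S02 homozygous alternate
})

test_that("signal priority follows hexamer rank, then proximity", {
  w <- function(...) {
    s <- strrep("C", 40)
    for (p in list(...)) substr(s, p[[2]], p[[2]] + nchar(p[[1]]) - 1) <- p[[1]]
    s
  }
  # canonical at -30 (idx 5..10) beats a closer variant at -10 (idx 25..30)
  res <- find_pas(w(list("AATAAA", 5), list("AGTAAA", 25)))
  expect_equal(res$motif, "AATAAA")
  expect_equal(res$category, "canonical")
  # two instances of the same hexamer: the one closest to the cleavage wins
  res2 <- find_pas(w(list("AATAAA", 5), list("AATAAA", 25)))
  expect_equal(res2$start, 25L)
  expect_equal(res2$offset, 40L - 30L)
  # ambiguity codes match by set containment: AATARA contains AATAAA
  res3 <- find_pas(w(list("AATARA", 15)))
  expect_equal(res3$category, "canonical")
  expect_equal(res3$motif, "AATAAA")
  # no hexamer, no A-rich stretch
  expect_equal(find_pas(strrep("CGTG", 10))$category, "unknown")
  expect_equal(find_pas("CGT")$category, "unknown") # window too short
})

test_that("A-rich search keeps the best 9-mer and adjusts boundaries", {
  # candidate CCGAAAAAA -> trimmed/extended to the plain A run
  w <- paste0("CCG", "AAAAAA", "GTCC", strrep("G", 27))
  res <- find_arich(w)
  expect_equal(substr(w, res[1], res[2]), "AAAAAA")
  # an all-A 9-mer inside a longer run extends through the full run
  w2 <- paste0(strrep("C", 10), strrep("A", 14), strrep("G", 16))
  res2 <- find_arich(w2)
  expect_equal(res2, c(11L, 24L))
  # at most 5 A's per 9-mer: nothing
  expect_null(find_arich(strrep("AACCG", 8)))
})

test_that("USE calling needs six T's with a TTT run", {
  bg <- strrep("G", 10)
  expect_equal(find_use(paste0(bg, "TTTTTTCTT", strrep("G", 11))),
               c(11L, 19L))
  expect_null(find_use(paste0(bg, "TCTTCTTCT", strrep("G", 11)))) # no TTT
  expect_null(find_use(paste0(bg, "TTGGTTGTC", strrep("G", 11)))) # 5 T's
})

test_that("USE/DSE boundary adjustment trims and extends greedily", {
  # candidate window ends on non-T: trimmed back to the last T
  w <- paste0(strrep("G", 5), "TTTTTTTCC", strrep("G", 16))
  res <- find_use(w)
  expect_equal(substr(w, res[1], res[2]), "TTTTTTT")
  # a T two bases past the boundary is absorbed while the proportion holds
  w2 <- paste0(strrep("G", 5), "TTTTTTTTT", "CT", strrep("G", 14))
  res2 <- find_use(w2)
  expect_equal(substr(w2, res2[1], res2[2]), "TTTTTTTTTCT")
})

test_that("DSE calling needs five T's and a U/G-rich string", {
  bg <- strrep("C", 10)
  res <- find_dse(paste0(bg, "TGTGTTTGT", strrep("C", 21)))
  expect_equal(res, c(11L, 19L))
  expect_null(find_dse(paste0(bg, "TATATATAT", strrep("C", 21)))) # no string
  expect_null(find_dse(paste0(bg, "TTGGGGGTC", strrep("C", 21)))) # 4 T's
})

test_that("signal categories partition calls", {
  expect_equal(classify_pas_category("AATAAA"), "canonical")
  expect_equal(classify_pas_category("ATTAAA"), "canonical")
  expect_equal(classify_pas_category("AGTAAA"), "variant")
  expect_equal(classify_pas_category("CCCCCC"), "unknown")
  expect_equal(classify_pas_category(NA_character_, is_arich = TRUE), "a_rich")
})

test_that("planted signals are recovered per cluster with genomic intervals", {
  set.seed(5)
  sim <- simulate_apa_study(sim_config(n_genes = 4, seed = 21))
  pr <- prep_reads(sim$reads, genome = sim$genome)
  cl <- call_clusters(pr, sim$genome)
  el <- call_elements(cl, sim$genome, reads = pr)
  truth <- sim$truth$sites
  joined <- dplyr::inner_join(
    el, cl[, c("cluster_id", "polya_pos", "strand")], by = "cluster_id"
  )
  for (i in seq_len(nrow(joined))) {
    site <- truth[abs(truth$pos - joined$polya_pos[i]) <= 2 &
                    truth$strand == joined$strand[i], ]
    if (nrow(site) == 1) {
      want <- ifelse(site$pas_category == "none", "unknown", site$pas_category)
      expect_equal(joined$category[i], want)
      if (want %in% c("canonical", "variant")) {
        expect_equal(joined$motif[i], site$pas_motif)
      }
    }
  }
})
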