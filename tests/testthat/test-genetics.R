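test_that("expression normalisation divides by library totals and sums", {
  counts <- tibble::tibble(
    cluster_id = c("c1", "c2", "c1", "c2"),
    sample = "S01", replicate = c("R1", "R1", "R2", "R2"),
    count = c(100, 300, 400, 600)
  )
  libs <- tibble::tibble(sample = "S01", replicate = c("R1", "R2"),
                         library_size = c(1e6, 1e6))
  ex <- normalize_expression(counts, libs,
                             cluster_genes = tibble::tibble(
                               cluster_id = c("c1", "c2"), gene_id = "g1"))
  expect_equal(ex$cluster$value[1], 1e-4)
  g <- ex$gene[ex$gene$replicate == "R1", ]
  expect_equal(g$value, 4e-4) # 1e-4 + 3e-4
  expect_equal(ex$gene_assoc$value, 4e-4 + 1e-3)
  expect_error(normalize_expression(counts, libs |>
                                      dplyr::mutate(library_size = 0)),
               "zero library")
})

test_that("intraclass heritability handles the degenerate extremes", {
  # identical replicates, differing samples: perfect repeatability
  y <- matrix(c(1, 1, 2, 2, 3, 3), nrow = 3, byrow = TRUE)
  h <- heritability(y)
  expect_equal(h$MS_e, 0)
  expect_equal(h$H2, 1)
  # no variance at all
  expect_equal(heritability(matrix(5, 6, 2))$H2, 0)
  expect_error(heritability(matrix(c(1, NA, 2, 2), 2)), "missing|I >= 3")
})

test_that("heritability estimator recovers intraclass correlation", {
  # independent Monte-Carlo oracle: median of the clamped estimator tracks
  # the true ICC closely at I=6, J=2; the mean is biased low (ratio
  # estimator), so medians carry the recovery check
  set.seed(123)
  for (rho in c(0, 0.5, 0.9)) {
    est <- replicate(400, {
      g <- rnorm(6, 0, sqrt(rho))
      e <- matrix(rnorm(12, 0, sqrt(1 - rho)), 6, 2)
      heritability(g + e)$H2
    })
    expect_lt(abs(median(est) - rho), 0.07)
  }
})

test_that("polyA-position trait picks the per-library dominant cluster", {
  m1 <- matrix(0, 2, 2, dimnames = list(c("S01", "S02"), c("R1", "R2")))
  m2 <- m1
  m1["S01", "R1"] <- 50; m2["S01", "R1"] <- 10 # S01/R1 dominated by c1
  m1["S01", "R2"] <- 30; m2["S01", "R2"] <- 30 # tie -> proximal (5'-most)
  # S02 has no reads at all -> missing
  cl <- tibble::tibble(
    cluster_id = c("c1", "c2"), gene_id = "g1", chrom = "chr1", strand = "+",
    polya_pos = c(100L, 300L), counts = list(m1, m2), retained = TRUE
  )
  tr <- polya_position_trait(cl)
  expect_equal(tr$value[tr$sample == "S01" & tr$replicate == "R1"], 100)
  expect_equal(tr$value[tr$sample == "S01" & tr$replicate == "R2"], 100)
  expect_true(all(is.na(tr$value[tr$sample == "S02"])))
})

test_that("dosage association is a started-log Pearson correlation", {
  d <- c(2, 2, 1, 1, 0, 0)
  a <- associate(d, 10^d) # expression log-linear in dosage
  expect_equal(a$signed_R, 1, tolerance = 1e-3) # started-log c = 0.5 here
  expect_null(associate(rep(2, 6), runif(6))) # monomorphic
  expect_null(associate(d, rep(3, 6))) # zero-variance expression
  # permuted expression: mean |R| matches the n=6 null expectation
  set.seed(77)
  null_r <- replicate(600, associate(d, sample(10^d))$abs_R)
  oracle <- replicate(600, abs(cor(rnorm(6), rnorm(6))))
  expect_lt(abs(mean(null_r) - mean(oracle)), 0.06)
})

test_that("signal strength scores are 1 / 0.5 / 0", {
  expect_equal(pas_strength("AATAAA"), 1)
  expect_equal(pas_strength("ATTAAA"), 1)
  expect_equal(pas_strength("AATACA"), 0.5)
  expect_equal(pas_strength("AATCCA"), 0)
  expect_error(pas_strength("AATAA"), "6-mer")
})

test_that("allelic strength differences subtract minor from major", {
  # AATAAA (major) vs AATACA (minor, variant): 1 - 0.5
  sc <- score_difference("AATAAA", 5L, "A", "C")
  expect_equal(sc$score_diff, 0.5)
  # AATAAA vs AATCAA (no signal): 1 - 0
  sc2 <- score_difference("AATAAA", 4L, "A", "C")
  expect_equal(sc2$score_diff, 1)
  # weak major: negative difference
  sc3 <- score_difference("AATAAA", 5L, "C", "A")
  expect_equal(sc3$score_diff, -0.5)
})

test_that("enrichment tests wrap Wilcoxon, Fisher and the regression", {
  set.seed(9)
  x <- runif(50)
  same <- enrichment_tests(x, x)
  expect_gt(same$wilcoxon$p_value, 0.3)
  shifted <- enrichment_tests(x + 0.3, x)
  expect_lt(shifted$wilcoxon$p_value, 0.01)
  tab <- matrix(c(4, 196, 12, 3988), 2, byrow = TRUE)
  et <- enrichment_tests(x, x, count_table = tab,
                         signed_r = c(-0.9, -0.1, 0.5, 0.8),
                         score_diff = c(-1, -0.5, 0.5, 1))
  expect_equal(et$fisher$p_value, fisher.test(tab)$p.value)
  expect_gt(et$regression$slope, 0)
  expect_error(enrichment_tests(numeric(0), x), "empty")
  expect_equal(nrow(tidy(et)), 3L)
  expect_equal(ncol(glance(et)), 3L)
})

test_that("UTR SNP association codes major-allele dosage with PAS scoring", {
  set.seed(55)
  sim <- simulate_apa_study(sim_config(n_genes = 20, seed = 41,
                                       frac_pas_snp = 1))
  pr <- prep_reads(sim$reads, genome = sim$genome)
  cl <- call_clusters(pr, sim$genome)
  el <- call_elements(cl, sim$genome, reads = pr)
  apa <- classify_apa(cl, sim$annotation)
  assign_tbl <- match_annotation(cl[cl$retained, ], sim$annotation)
  ex <- normalize_expression(cluster_counts(cl[cl$retained, ]),
                             attr(cl, "libraries"),
                             cluster_genes = assign_tbl[, c("cluster_id", "gene_id")])
  assoc <- associate_utr_snps(sim$truth$variants, sim$truth$genotypes,
                              ex$gene_assoc, apa, elements = el, clusters = cl)
  expect_true(all(abs(assoc$signed_R) <= 1 + 1e-12))
  expect_true(all(assoc$abs_R == abs(assoc$signed_R)))
  # PAS-flagged SNPs carry scores; others carry none
  expect_true(all(!is.na(assoc$score_diff[assoc$in_pas])))
  expect_true(all(is.na(assoc$score_diff[!assoc$in_pas])))
  # planted weak alleles break AATAAA to AATCAA (strength 0) or AATACA
  # (variant, 0.5); when the strong allele is major the difference is
  # 1 - strength(weak hexamer)
  truth_pas <- sim$truth$variants[sim$truth$variants$effect == "pas_weak", ]
  pas_rows <- assoc[assoc$snp_id %in% truth_pas$snp_id & assoc$in_pas, ]
  gt <- sim$truth$genotypes
  el_pas <- el[!is.na(el$pas_start), ]
  for (i in seq_len(nrow(pas_rows))) {
    v <- truth_pas[truth_pas$snp_id == pas_rows$snp_id[i], ]
    d <- gt$dosage_ref[gt$snp_id == v$snp_id]
    if (sum(d) < length(d)) next # weak allele ended up major: sign flips
    hit <- el_pas[el_pas$pas_start <= v$pos & el_pas$pas_end >= v$pos, ][1, ]
    g <- sim$truth$genes[sim$truth$genes$gene_id == v$gene_id, ]
    off <- if (g$strand == "+") v$pos - hit$pas_start + 1L else hit$pas_end - v$pos + 1L
    weak_hex <- hit$motif
    substr(weak_hex, off, off) <- "C"
    expect_equal(pas_rows$score_diff[i], 1 - pas_strength(weak_hex))
  }
})
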