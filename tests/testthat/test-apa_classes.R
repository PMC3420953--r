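mk_annotation <- function() {
  tibble::tibble(
    transcript_id = c("tA", "tB", "tC"),
    gene_id = c("g1", "g1", "g2"),
    chrom = "chr1", strand = c("+", "+", "-"),
    tx_start = c(100L, 100L, 2000L), tx_end = c(1000L, 1500L, 3000L),
    cds_start = c(100L, 100L, 2600L), cds_end = c(500L, 500L, 3000L),
    utr3_start = c(501L, 501L, 2000L), utr3_end = c(1000L, 1500L, 2599L),
    end3 = c(1000L, 1500L, 2000L)
  )
}

mk_cluster <- function(id, pos, strand = "+", total = 100, chrom = "chr1") {
  m <- matrix(total / 12, 6, 2, dimnames = list(sprintf("S%02d", 1:6),
                                                c("R1", "R2")))
  tibble::tibble(
    cluster_id = id, chrom = chrom, strand = strand,
    span_start = pos - 2L, span_end = pos + 2L, polya_pos = pos,
    n_reads = total, counts = list(m), positions = list(rep(pos, 3)),
    mate_positions = list(rep(pos - 100L, 3)), retained = TRUE
  )
}

test_that("annotation matching minimises 3'-end distance with exon tie-break", {
  ann <- mk_annotation()
  hit <- match_annotation(mk_cluster("c1", 995L), ann)
  expect_equal(hit$transcript_id, "tA") # distances 5 vs 505
  # equal distances (5 bp each side): greater exon overlap wins
  ann2 <- ann[1:2, ]
  ann2$end3 <- c(990L, 1000L)
  ann2$tx_start <- c(890L, 500L)
  ann2$tx_end <- c(994L, 1500L)
  hit2 <- match_annotation(mk_cluster("c1", 995L), ann2) # overlaps 2 vs 5 bp
  expect_equal(hit2$transcript_id, "tB")
  # no overlapping transcript: intergenic
  expect_equal(nrow(match_annotation(mk_cluster("c1", 5000L), ann)), 0L)
})

test_that("APA classes follow cluster count and 3' UTR membership", {
  ann <- mk_annotation()
  # one cluster in the 3' UTR: class I
  apa1 <- classify_apa(mk_cluster("c1", 800L), ann)
  expect_equal(apa1$apa_class, "I")
  # two clusters in the same transcript 3' UTR: class II
  cl2 <- dplyr::bind_rows(mk_cluster("c1", 700L), mk_cluster("c2", 990L))
  apa2 <- classify_apa(cl2, ann)
  expect_equal(apa2$apa_class, "II")
  expect_equal(apa2$proximal_pos, 700L)
  expect_equal(apa2$distal_pos, 990L)
  # single cluster in coding sequence: class III_S
  apa3 <- classify_apa(mk_cluster("c1", 300L), ann)
  expect_equal(apa3$apa_class, "III_S")
  # clusters matched to different transcript 3' ends: class III
  cl4 <- dplyr::bind_rows(mk_cluster("c1", 990L), mk_cluster("c2", 1490L))
  expect_equal(classify_apa(cl4, ann)$apa_class, "III")
})

test_that("only the two most expressed clusters drive classification", {
  ann <- mk_annotation()
  cl <- dplyr::bind_rows(
    mk_cluster("c1", 700L, total = 500),
    mk_cluster("c2", 990L, total = 300),
    mk_cluster("c3", 300L, total = 10) # CDS cluster, too weak to matter
  )
  apa <- classify_apa(cl, ann)
  expect_equal(apa$apa_class, "II")
  expect_setequal(c(apa$proximal_cluster, apa$distal_cluster), c("c1", "c2"))
})

test_that("shared and differential regions split the 3' UTR at the sites", {
  sd1 <- shared_differential(0L, 200L, 80L, 180L, "+")
  expect_equal(sd1$shared, c(0L, 80L))
  expect_equal(sd1$differential, c(81L, 180L))
  expect_true(shared_differential(0L, 200L, 80L, 80L, "+")$degenerate)
  # minus strand: transcript orientation runs from high to low coordinates
  sd2 <- shared_differential(1000L, 1200L, 1120L, 1020L, "-")
  expect_equal(sd2$shared, c(1120L, 1200L))
  expect_equal(sd2$differential, c(1020L, 1119L))
})

test_that("minus-strand class II genes round-trip genomic regions", {
  ann <- mk_annotation()[3, ]
  cl <- dplyr::bind_rows(mk_cluster("c1", 2400L, "-"),
                         mk_cluster("c2", 2100L, "-"))
  apa <- classify_apa(cl, ann)
  expect_equal(apa$apa_class, "II")
  expect_equal(apa$proximal_pos, 2400L) # proximal = closest to CDS on "-"
  expect_equal(apa$distal_pos, 2100L)
  expect_equal(c(apa$shared_start, apa$shared_end), c(2400L, 2599L))
  expect_equal(c(apa$diff_start, apa$diff_end), c(2100L, 2399L))
  # shared and differential stay inside the annotated 3' UTR
  expect_gte(apa$diff_start, ann$utr3_start)
  expect_lte(apa$shared_end, ann$utr3_end)
})

test_that("external polyA-site support uses inclusive span containment", {
  cl <- dplyr::bind_rows(mk_cluster("c1", 800L), mk_cluster("c2", 990L))
  sites <- tibble::tibble(chrom = "chr1", pos = c(802L, 993L + 1L))
  expect_equal(match_external_sites(cl, sites), c(TRUE, FALSE))
  expect_equal(match_external_sites(cl, sites[0, ]), c(FALSE, FALSE))
})

test_that("dominant form follows mean expression with ties to the long form", {
  ann <- mk_annotation()
  cl <- dplyr::bind_rows(mk_cluster("c1", 700L), mk_cluster("c2", 990L))
  apa <- classify_apa(cl, ann)
  ex <- function(short, long) {
    tibble::tibble(cluster_id = rep(c("c1", "c2"), each = 6),
                   sample = rep(sprintf("S%02d", 1:6), 2),
                   value = rep(c(short, long), each = 6))
  }
  expect_equal(dominant_form(apa, ex(10, 30))$dominant_form, "long")
  expect_equal(dominant_form(apa, ex(30, 10))$dominant_form, "short")
  expect_equal(dominant_form(apa, ex(20, 20))$dominant_form, "long")
})

test_that("simulated gene classes are recovered when clusters survive", {
  sim <- simulate_apa_study(sim_config(n_genes = 12, seed = 33))
  pr <- prep_reads(sim$reads, genome = sim$genome)
  cl <- call_clusters(pr, sim$genome)
  apa <- classify_apa(cl, sim$annotation)
  truth <- sim$truth$genes
  both <- dplyr::inner_join(apa, truth, by = "gene_id")
  # genes whose expected cluster count survived must match the planted class
  retained_cl <- dplyr::filter(cl, .data$retained)
  n_retained <- match_annotation(retained_cl, sim$annotation) |>
    dplyr::count(.data$gene_id)
  full <- dplyr::inner_join(both, n_retained, by = "gene_id")
  expected_n <- ifelse(full$apa_class.y == "I", 1L, 2L)
  ok <- full$n == expected_n
  expect_true(all(full$apa_class.x[ok] == full$apa_class.y[ok]))
  expect_gt(sum(ok), 0)
})
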