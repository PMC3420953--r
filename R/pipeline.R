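resolve_genome <- function(x) if (is.character(x)) read_genome_fasta(x) else x

resolve_reads <- function(x, read_len) {
  if (!is.character(x)) return(as_tibble(x))
  if (grepl("\\.(sam|bam)$", x)) read_reads_sam(x, read_len) else read_reads_tsv(x)
}

resolve_annotation <- function(x) {
  if (!is.character(x)) return(as_tibble(x))
  read_annotation_gtf(x)
}

#' Run the full APA analysis pipeline
#'
#' Executes the stages in order -- read preparation, tag-cluster calling,
#' polyadenylation-signal/element calling, APA classification, 3' UTR motif
#' scanning with SNP-density conservation, and genetics (expression
#' normalisation, heritability, dosage association) -- writing every
#' intermediate as TSV/BED plus a `MANIFEST.json` with checksums and the
#' serialised configuration. Per-stage record counts and per-reason filter
#' tallies are logged and written to `filter_log.tsv`. A stage failure
#' aborts with the stage name; previously written outputs are retained and
#' the MANIFEST notes incompleteness.
#'
#' @param out_dir output directory.
#' @param genome genome FASTA path or [Biostrings::DNAStringSet].
#' @param annotation GTF path or transcript tibble.
#' @param reads TSV/SAM path or read tibble.
#' @param variants,genotypes VCF path (for `variants`) or tibbles; `NULL`
#'   skips the association stage (heritability still runs).
#' @param external_sites optional named list of external motif-site inputs,
#'   e.g. `list(miRNA = "sites.tsv", Alu = "alu.bed")`.
#' @param peak [peak_params()].
#' @param elements [element_params()].
#' @param hexamers [pas_hexamers()].
#' @param mirna_context context-score threshold for miRNA site ingestion
#'   (default -0.4).
#' @param h2_cutoff heritability threshold used to report heritable
#'   polyA-position genes (default 0.6).
#' @param expr_h2_cutoff expression-heritability threshold (default 0.5).
#' @param started_log_c started-logarithm constant; `NULL` derives it from
#'   the expression matrix.
#' @param read_len sequenced read length.
#' @param log_level `"info"` or `"quiet"`.
#' @return (invisibly) a list with the main result tables and `out_dir`.
#' @export
run_pipeline <- function(out_dir, genome, annotation, reads,
                         variants = NULL, genotypes = NULL,
                         external_sites = NULL,
                         peak = peak_params(), elements = element_params(),
                         hexamers = pas_hexamers(), mirna_context = -0.4,
                         h2_cutoff = 0.6, expr_h2_cutoff = 0.5,
                         started_log_c = NULL, read_len = 40L,
                         log_level = "info") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(complete = FALSE, files = list())
  say <- function(stage, ...) {
    if (log_level != "quiet") message(sprintf("[%s] ", stage), ...)
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_file(df, path)
    manifest$files[[name]] <<- unname(tools::md5sum(path))
    path
  }
  finish_manifest <- function(complete) {
    manifest$complete <- complete
    jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  stage <- function(name, expr) {
    say(name, "starting")
    tryCatch(expr, error = function(e) {
      finish_manifest(FALSE)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  logs <- new_filter_log()

  genome <- stage("inputs", resolve_genome(genome))
  annotation <- stage("inputs", resolve_annotation(annotation))
  reads <- stage("inputs", resolve_reads(reads, read_len))
  if (is.character(variants)) {
    vcf <- stage("genetics", {
      if (!file.exists(variants)) stop("VCF not found: ", variants)
      read_variants_vcf(variants)
    })
    variants <- vcf$variants
    genotypes <- vcf$genotypes
  }

  prepped <- stage("read_prep", prep_reads(reads, genome = genome))
  logs <- bind_rows(logs, filter_log(prepped))
  say("read_prep", nrow(reads), " reads in, ", nrow(prepped), " kept")
  emit(prepped, "prepared_reads.tsv")

  clusters <- stage("cluster_calling", call_clusters(prepped, genome, peak))
  logs <- bind_rows(logs, filter_log(clusters))
  say("cluster_calling", nrow(clusters), " clusters (",
      sum(clusters$retained), " retained)")
  write_clusters(clusters, file.path(out_dir, "clusters.bed"),
                 file.path(out_dir, "clusters.tsv"))
  manifest$files[["clusters.tsv"]] <-
    unname(tools::md5sum(file.path(out_dir, "clusters.tsv")))
  manifest$files[["clusters.bed"]] <-
    unname(tools::md5sum(file.path(out_dir, "clusters.bed")))

  element_calls <- stage("consensus_elements", {
    call_elements(clusters, genome, reads = prepped, variants = variants,
                  genotypes = genotypes, hexamers = hexamers,
                  params = elements, read_len = read_len)
  })
  emit(element_calls, "elements.tsv")

  apa <- stage("apa_classes", classify_apa(clusters, annotation))
  libraries <- attr(clusters, "libraries")
  assign_tbl <- match_annotation(clusters[clusters$retained, , drop = FALSE],
                                 annotation)
  expr <- stage("genetics", {
    normalize_expression(cluster_counts(clusters[clusters$retained, , drop = FALSE]),
                         libraries,
                         cluster_genes = assign_tbl[, c("cluster_id", "gene_id")])
  })
  apa <- stage("apa_classes", dominant_form(apa, expr$cluster))
  emit(apa, "apa_genes.tsv")
  say("apa_classes", nrow(apa), " genes classified")

  hits <- stage("motif_scan", {
    h <- scan_utr_motifs(apa, genome)
    if (!is.null(external_sites)) {
      utr_regions <- apa |>
        filter(!is.na(.data$utr3_start)) |>
        select("gene_id", "chrom", "strand",
               start = "utr3_start", end = "utr3_end")
      for (mt in names(external_sites)) {
        h <- bind_rows(h, ingest_external_sites(
          external_sites[[mt]], mt, score_threshold = mirna_context,
          utr_regions = utr_regions
        ))
      }
    }
    label_regions(h, apa)
  })
  emit(hits, "motif_hits.tsv")

  conservation <- NULL
  enrich_regions <- NULL
  if (!is.null(variants) && nrow(hits) > 0) {
    conservation <- stage("motif_scan", {
      utr_regions <- apa |>
        filter(!is.na(.data$utr3_start)) |>
        select("chrom", "strand", start = "utr3_start", end = "utr3_end")
      conservation_stats(hits, variants[, c("chrom", "pos")], genome,
                         utr_regions)
    })
    emit(conservation, "conservation.tsv")
    if (any(apa$apa_class == "II")) {
      enrich_regions <- stage("motif_scan", region_enrichment(apa, hits))
      emit(enrich_regions, "region_enrichment.tsv")
    }
  }

  herit <- stage("genetics", {
    ptrait <- clusters[clusters$retained, , drop = FALSE] |>
      dplyr::inner_join(assign_tbl, by = "cluster_id") |>
      polya_position_trait()
    bind_rows(
      heritability_by_gene(ptrait, trait = "polya_position"),
      heritability_by_gene(expr$gene, trait = "expression")
    )
  })
  emit(herit, "heritability.tsv")
  say("genetics", sum(herit$trait == "polya_position" & herit$H2 > h2_cutoff),
      " genes with polyA-position H2 > ", h2_cutoff)

  assoc <- NULL
  tests <- NULL
  if (!is.null(variants) && nrow(variants) > 0) {
    assoc <- stage("genetics", {
      associate_utr_snps(variants, genotypes, expr$gene_assoc, apa,
                         elements = element_calls, clusters = clusters,
                         c = started_log_c, hexamers = hexamers)
    })
    emit(assoc, "association.tsv")
    if (any(assoc$in_pas) && any(!assoc$in_pas)) {
      tests <- stage("genetics", {
        enrichment_tests(
          assoc$abs_R[assoc$in_pas], assoc$abs_R[!assoc$in_pas],
          signed_r = assoc$signed_R[assoc$in_pas],
          score_diff = assoc$score_diff[assoc$in_pas]
        )
      })
      emit(tidy(tests), "enrichment_tests.tsv")
    }
  }

  emit(logs, "filter_log.tsv")
  finish_manifest(TRUE)
  say("done", "outputs in ", out_dir)
  invisible(list(
    out_dir = out_dir, reads = prepped, clusters = clusters,
    elements = element_calls, apa_genes = apa, hits = hits,
    conservation = conservation, region_enrichment = enrich_regions,
    expression = expr, heritability = herit, association = assoc,
    tests = tests, filter_log = logs
  ))
}
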