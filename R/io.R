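#' Write / read the genome FASTA
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

annotation_to_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$tx_start, annotation$tx_end),
    strand = annotation$strand,
    transcript_id = annotation$transcript_id,
    gene_id = annotation$gene_id
  )
}

#' Write the transcript annotation as GTF
#'
#' Emits `transcript`, `exon`, `CDS` and `three_prime_utr` features carrying
#' `gene_id` and `transcript_id` attributes.
#'
#' @param annotation transcript tibble (see [generate_genome_annotation()]).
#' @param path output file.
#' @export
write_annotation_gtf <- function(annotation, path) {
  feat <- function(type, s, e) {
    keep <- !is.na(s) & !is.na(e)
    a <- annotation[keep, , drop = FALSE]
    GenomicRanges::GRanges(
      seqnames = a$chrom, ranges = IRanges::IRanges(s[keep], e[keep]),
      strand = a$strand, type = type,
      gene_id = a$gene_id, transcript_id = a$transcript_id,
      phase = if (type == "CDS") 0L else NA_integer_
    )
  }
  gr <- c(
    feat("transcript", annotation$tx_start, annotation$tx_end),
    feat("exon", annotation$tx_start, annotation$tx_end),
    feat("CDS", annotation$cds_start, annotation$cds_end),
    feat("three_prime_utr", annotation$utr3_start, annotation$utr3_end)
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a GTF annotation into the transcript tibble
#'
#' Requires `transcript`/`exon` features with `gene_id` and `transcript_id`
#' attributes; `CDS` and `three_prime_utr` features populate the CDS and
#' 3' UTR intervals; the annotated 3' end is the transcript-strand end of
#' the transcript.
#'
#' @param path a GTF file.
#' @return transcript tibble as used by [match_annotation()].
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  tx <- df |> filter(.data$type == "transcript")
  get_iv <- function(ttype, id) {
    d <- df[df$type == ttype & df$transcript_id == id, , drop = FALSE]
    if (nrow(d) == 0L) c(NA_integer_, NA_integer_) else c(min(d$start), max(d$end))
  }
  purrr::pmap(
    list(tx$transcript_id, tx$gene_id, as.character(tx$seqnames),
         as.character(tx$strand), tx$start, tx$end),
    function(tid, gid, chrom, strand, s, e) {
      cds <- get_iv("CDS", tid)
      u3 <- get_iv("three_prime_utr", tid)
      ex <- df[df$type == "exon" & df$transcript_id == tid, , drop = FALSE]
      tibble(
        transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
        tx_start = s, tx_end = e, cds_start = cds[1], cds_end = cds[2],
        utr3_start = u3[1], utr3_end = u3[2],
        end3 = if (strand == "+") e else s,
        exons = list(cbind(ex$start, ex$end))
      )
    }
  ) |> list_rbind()
}

#' Write the annotation as BED12
#'
#' @param annotation transcript tibble.
#' @param path output file.
#' @export
write_annotation_bed12 <- function(annotation, path) {
  exons <- GenomicRanges::GRangesList(lapply(seq_len(nrow(annotation)), function(i) {
    GenomicRanges::GRanges(
      seqnames = annotation$chrom[[i]],
      ranges = IRanges::IRanges(annotation$tx_start[[i]], annotation$tx_end[[i]]),
      strand = annotation$strand[[i]]
    )
  }))
  names(exons) <- annotation$transcript_id
  bed <- rtracklayer::asBED(exons)
  rtracklayer::export(bed, path, format = "bed")
  invisible(path)
}

#' Write / read reads in the pipeline TSV dialect
#'
#' Tab-separated with a header; missing values are `.`. Columns: `read_id`,
#' `chrom`, `strand`, `polya_pos`, `mate_pos`, `n_T`, `tail_mismatches`,
#' `sample`, `replicate` (simulated data adds `truth_label`, `true_site`,
#' `gene_id`).
#'
#' @param reads read tibble.
#' @param path file path (gzip transparently supported by extension).
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(as.data.frame(reads), gzfile_maybe(path), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

gzfile_maybe <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              na.strings = ".", stringsAsFactors = FALSE))
}

#' Write reads as SAM
#'
#' One alignment line per read pair: the poly-T (tail) mate, paired flags
#' set, with the trimmed-portion alignment as CIGAR, the opposite mate's
#' position in PNEXT, and tags `ZT` (trimmed tail length), `ZM` (tail
#' mismatches) and `RG` (`sample.replicate`). The reverse bit (0x10) is set
#' for plus-strand transcripts: the poly-T read is antisense to the mRNA.
#'
#' @param reads read tibble.
#' @param genome named [Biostrings::DNAStringSet] (for `@SQ` headers).
#' @param path output SAM file.
#' @param read_len sequenced read length.
#' @export
write_reads_sam <- function(reads, genome, path, read_len = 40L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(genome)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, length(genome[[nm]])), con)
  }
  for (rg in sort(unique(paste(reads$sample, reads$replicate, sep = ".")))) {
    writeLines(sprintf("@RG\tID:%s", rg), con)
  }
  body <- read_len - reads$n_T
  pos <- if_else(reads$strand == "+", reads$polya_pos - body + 1L, reads$polya_pos)
  pnext_ <- if_else(reads$strand == "+", reads$mate_pos,
                    reads$mate_pos - read_len + 1L)
  flag <- 1L + 2L + 64L + if_else(reads$strand == "+", 16L + 0L, 32L)
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t0\t*\t*\tZT:i:%d\tZM:i:%d\tRG:Z:%s.%s",
    reads$read_id, flag, reads$chrom, pos, body, pnext_,
    reads$n_T, reads$tail_mismatches, reads$sample, reads$replicate
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read a SAM/BAM file of 3'-end reads
#'
#' Accepts SAM written by [write_reads_sam()] (or equivalent BAM): tags `ZT`
#' and `ZM` carry the trimming metadata; `RG` is parsed as
#' `sample.replicate`.
#'
#' @param path SAM or BAM file.
#' @param read_len sequenced read length.
#' @return read tibble in the pipeline dialect.
#' @export
read_reads_sam <- function(path, read_len = 40L) {
  if (grepl("\\.sam$", path)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mpos", "cigar"),
    tag = c("ZT", "ZM", "RG")
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  body <- as.integer(sub("M$", "", b$cigar))
  strand <- if_else(bitwAnd(b$flag, 16L) > 0L, "+", "-")
  rg <- strsplit(b$tag$RG, ".", fixed = TRUE)
  tibble(
    read_id = b$qname,
    chrom = as.character(b$rname),
    strand = strand,
    polya_pos = if_else(strand == "+", b$pos + body - 1L, b$pos),
    mate_pos = if_else(strand == "+", b$mpos, b$mpos + read_len - 1L),
    n_T = b$tag$ZT,
    tail_mismatches = b$tag$ZM,
    sample = purrr::map_chr(rg, 1),
    replicate = purrr::map_chr(rg, 2)
  )
}

#' Write simulated SNPs and genotypes as VCF 4.2
#'
#' @param variants tibble `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param genotypes tibble `snp_id`, `sample`, `dosage_ref`.
#' @param genome named [Biostrings::DNAStringSet] (contig headers).
#' @param path output `.vcf` path (plain text).
#' @export
write_variants_vcf <- function(variants, genotypes, genome, path) {
  samples <- sort(unique(genotypes$sample))
  gt_code <- function(d) c("1/1", "0/1", "0/0")[d + 1L]
  gt <- matrix("0/0", nrow(variants), length(samples),
               dimnames = list(variants$snp_id, samples))
  for (i in seq_len(nrow(genotypes))) {
    gt[genotypes$snp_id[[i]], genotypes$sample[[i]]] <-
      gt_code(genotypes$dosage_ref[[i]])
  }
  vr <- VariantAnnotation::VCF(
    rowRanges = GenomicRanges::GRanges(
      seqnames = variants$chrom,
      ranges = IRanges::IRanges(variants$pos, variants$pos, names = variants$snp_id)
    ),
    colData = S4Vectors::DataFrame(Samples = seq_along(samples),
                                   row.names = samples),
    exptData = list(header = VariantAnnotation::VCFHeader(
      samples = samples,
      header = IRanges::DataFrameList(
        fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                          row.names = "fileformat"),
        FORMAT = S4Vectors::DataFrame(
          Number = "1", Type = "String", Description = "Genotype",
          row.names = "GT"
        )
      )
    )),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(variants$ref),
      ALT = methods::as(as.list(variants$alt), "CharacterList"),
      QUAL = rep(100, nrow(variants)),
      FILTER = rep("PASS", nrow(variants))
    ),
    geno = S4Vectors::SimpleList(GT = gt)
  )
  VariantAnnotation::writeVcf(vr, path)
  invisible(path)
}

#' Read a VCF of biallelic SNVs into variant and genotype tibbles
#'
#' Multiallelic or non-SNV records are skipped with a warning.
#'
#' @param path a VCF file.
#' @return list of tibbles `variants` (`snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`) and `genotypes` (`snp_id`, `sample`, `dosage_ref`, `dosage_alt`).
#' @export
read_variants_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- VariantAnnotation::alt(v)
  ref <- as.character(VariantAnnotation::ref(v))
  is_snv <- lengths(alt) == 1L & nchar(ref) == 1L &
    nchar(as.character(unlist(alt))) == 1L
  if (any(!is_snv)) {
    warning(sum(!is_snv), " non-biallelic-SNV record(s) skipped")
  }
  v <- v[is_snv, ]
  rr <- rr[is_snv, ]
  ids <- names(rr) %||% sprintf("snp%04d", seq_along(rr))
  variants <- tibble(
    snp_id = ids,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = as.character(unlist(VariantAnnotation::alt(v)))
  )
  gt <- VariantAnnotation::geno(v)$GT
  genotypes <- purrr::map(colnames(gt), function(s) {
    d_ref <- vapply(gt[, s], function(g) {
      a <- strsplit(g, "[/|]")[[1]]
      sum(a == "0")
    }, integer(1))
    tibble(snp_id = ids, sample = s, dosage_ref = unname(d_ref),
           dosage_alt = 2L - unname(d_ref))
  }) |> list_rbind()
  list(variants = variants, genotypes = genotypes)
}

#' Write a tag-cluster table as BED6(+) and TSV
#'
#' The BED6 carries `chrom`, 0-based `span_start`, `span_end`, cluster id,
#' pooled count and strand; the TSV adds positions, precision values and
#' filter flags.
#'
#' @param clusters result of [call_clusters()].
#' @param bed_path,tsv_path output files (`NULL` skips one).
#' @export
write_clusters <- function(clusters, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(
      chrom = clusters$chrom,
      start = clusters$span_start - 1L, # 1-based closed -> BED half-open
      end = clusters$span_end,
      name = clusters$cluster_id,
      score = clusters$n_reads,
      strand = clusters$strand
    )
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       col.names = FALSE, row.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    flat <- clusters |>
      select(-dplyr::any_of(c("counts", "positions", "mate_positions")))
    utils::write.table(as.data.frame(flat), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = ".")
  }
  invisible(NULL)
}

write_tsv_file <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Write all simulator outputs to a directory
#'
#' Emits the genome FASTA, GTF and BED12 annotation, reads as TSV and SAM,
#' SNPs as VCF 4.2, and the ground-truth tables as TSV.
#'
#' @param sim result of [simulate_apa_study()].
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_annotation_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  write_annotation_bed12(sim$annotation, file.path(dir, "annotation.bed"))
  write_reads_tsv(sim$reads, file.path(dir, "reads.tsv"))
  write_reads_sam(sim$reads, sim$genome, file.path(dir, "reads.sam"),
                  read_len = sim$config$read_len)
  if (nrow(sim$truth$variants) > 0) {
    write_variants_vcf(sim$truth$variants, sim$truth$genotypes, sim$genome,
                       file.path(dir, "snps.vcf"))
  }
  for (nm in c("genes", "sites", "misprime_loci", "dup_loci", "variants",
               "genotypes", "elements")) {
    write_tsv_file(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")))
  }
  invisible(dir)
}
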