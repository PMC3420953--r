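#' Match tag clusters to annotated transcripts
#'
#' Among transcripts on the same chromosome and strand whose span overlaps
#' the cluster interval, the transcript minimising the distance between its
#' annotated 3' end and the cluster polyA position is chosen; ties are broken
#' by the greatest overlap between the cluster interval and annotated exons.
#'
#' @param clusters a data frame of clusters (`cluster_id`, `chrom`, `strand`,
#'   `span_start`, `span_end`, `polya_pos`).
#' @param annotation transcript models: `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `utr3_start`, `utr3_end`, `end3`, and
#'   optionally an `exons` list-column of `(start, end)` matrices.
#' @return tibble `cluster_id`, `transcript_id`, `gene_id`, `distance`
#'   (clusters matching nothing are absent: they are intergenic).
#' @export
match_annotation <- function(clusters, annotation) {
  annotation <- as_tibble(annotation)
  res <- purrr::pmap(
    list(clusters$cluster_id, clusters$chrom, clusters$strand,
         clusters$span_start, clusters$span_end, clusters$polya_pos),
    function(id, chrom, strand, s, e, pos) {
      cand <- annotation[annotation$chrom == chrom & annotation$strand == strand &
                           annotation$tx_start <= e & annotation$tx_end >= s, ,
                         drop = FALSE]
      if (nrow(cand) == 0L) return(NULL)
      dist <- abs(cand$end3 - pos)
      cand <- cand[dist == min(dist), , drop = FALSE]
      if (nrow(cand) > 1L) {
        ov <- vapply(seq_len(nrow(cand)), function(k) {
          ex <- if ("exons" %in% names(cand)) cand$exons[[k]] else {
            cbind(cand$tx_start[[k]], cand$tx_end[[k]])
          }
          sum(pmax(0L, pmin(ex[, 2], e) - pmax(ex[, 1], s) + 1L))
        }, numeric(1))
        cand <- cand[which.max(ov), , drop = FALSE]
      }
      tibble(cluster_id = id, transcript_id = cand$transcript_id[[1]],
             gene_id = cand$gene_id[[1]], distance = abs(cand$end3[[1]] - pos))
    }
  )
  list_rbind(res[!vapply(res, is.null, logical(1))])
}

in_utr3 <- function(pos, utr3_start, utr3_end) {
  !is.na(utr3_start) & pos >= utr3_start & pos <= utr3_end
}

#' Shared and differential 3' UTR regions of a class II gene
#'
#' The shared region runs from the 3' UTR start (CDS end) to the proximal
#' cleavage site inclusive; the differential region from just past the
#' proximal site to the distal site inclusive, in transcript orientation.
#'
#' @param utr3_start,utr3_end genomic 3' UTR interval (sorted).
#' @param proximal,distal genomic polyA positions of the two clusters
#'   (proximal = closer to the CDS on the transcript strand).
#' @param strand `"+"` or `"-"`.
#' @return list with genomic intervals `shared = c(start, end)` and
#'   `differential = c(start, end)`; `NULL` components when degenerate.
#' @export
shared_differential <- function(utr3_start, utr3_end, proximal, distal, strand) {
  if (proximal == distal) {
    return(list(shared = NULL, differential = NULL, degenerate = TRUE))
  }
  if (strand == "+") {
    list(shared = c(utr3_start, proximal),
         differential = c(proximal + 1L, distal), degenerate = FALSE)
  } else {
    list(shared = c(proximal, utr3_end),
         differential = c(distal, proximal - 1L), degenerate = FALSE)
  }
}

#' Classify alternative polyadenylation per gene
#'
#' Clusters are assigned to genes through [match_annotation()]; per gene only
#' the two clusters with the highest pooled expression are used. A single
#' cluster inside the annotated 3' UTR gives class I; two clusters in the
#' same transcript's 3' UTR give class II (with shared/differential regions);
#' a cluster in coding sequence/intron or two clusters in 3' UTRs of
#' different transcripts give class III; a single cluster outside any
#' annotated 3' UTR gives class III_S.
#'
#' @param clusters result of [call_clusters()] (retained clusters are used).
#' @param annotation transcript models (see [match_annotation()]).
#' @return tibble: `gene_id`, `apa_class`, `proximal_cluster`,
#'   `distal_cluster`, `proximal_pos`, `distal_pos`, `chrom`, `strand`,
#'   `shared_start`, `shared_end`, `diff_start`, `diff_end`,
#'   `utr3_start`, `utr3_end`.
#' @export
classify_apa <- function(clusters, annotation) {
  cl <- clusters[clusters$retained, , drop = FALSE]
  hits <- match_annotation(cl, annotation)
  cl <- cl |>
    dplyr::inner_join(hits, by = "cluster_id") |>
    mutate(total = purrr::map_dbl(.data$counts, sum))
  genes <- split(cl, cl$gene_id)
  res <- purrr::map(genes, function(g) {
    strand <- g$strand[[1]]
    # top-2 by pooled count; equal counts resolved 5'-most first
    tx_ord <- if (strand == "+") g$polya_pos else -g$polya_pos
    g <- g[order(-g$total, tx_ord), , drop = FALSE]
    g <- utils::head(g, 2L)
    ann <- annotation[match(g$transcript_id, annotation$transcript_id), , drop = FALSE]
    inutr <- in_utr3(g$polya_pos, ann$utr3_start, ann$utr3_end)
    base <- tibble(
      gene_id = g$gene_id[[1]], chrom = g$chrom[[1]], strand = strand,
      proximal_cluster = NA_character_, distal_cluster = NA_character_,
      proximal_pos = NA_integer_, distal_pos = NA_integer_,
      shared_start = NA_integer_, shared_end = NA_integer_,
      diff_start = NA_integer_, diff_end = NA_integer_,
      utr3_start = NA_integer_, utr3_end = NA_integer_
    )
    if (nrow(g) == 1L) {
      base$apa_class <- if (inutr[[1]]) "I" else "III_S"
      base$proximal_cluster <- g$cluster_id[[1]]
      base$proximal_pos <- g$polya_pos[[1]]
      base$utr3_start <- ann$utr3_start[[1]]
      base$utr3_end <- ann$utr3_end[[1]]
      return(base)
    }
    # order proximal -> distal on the transcript strand
    ord <- order(if (strand == "+") g$polya_pos else -g$polya_pos)
    g <- g[ord, , drop = FALSE]
    ann <- ann[ord, , drop = FALSE]
    inutr <- inutr[ord]
    base$proximal_cluster <- g$cluster_id[[1]]
    base$distal_cluster <- g$cluster_id[[2]]
    base$proximal_pos <- g$polya_pos[[1]]
    base$distal_pos <- g$polya_pos[[2]]
    if (all(inutr) && g$transcript_id[[1]] == g$transcript_id[[2]]) {
      base$apa_class <- "II"
      base$utr3_start <- ann$utr3_start[[1]]
      base$utr3_end <- ann$utr3_end[[1]]
      sd_ <- shared_differential(ann$utr3_start[[1]], ann$utr3_end[[1]],
                                 g$polya_pos[[1]], g$polya_pos[[2]], strand)
      if (!sd_$degenerate) {
        base$shared_start <- sd_$shared[1]
        base$shared_end <- sd_$shared[2]
        base$diff_start <- sd_$differential[1]
        base$diff_end <- sd_$differential[2]
      }
    } else {
      base$apa_class <- "III"
    }
    base
  })
  list_rbind(res) |>
    select("gene_id", "apa_class", dplyr::everything()) |>
    arrange(.data$gene_id)
}

#' Flag clusters supported by external polyA-site evidence
#'
#' A cluster is supported when an external site coordinate (EST cleavage
#' position) lies within its span, inclusive.
#'
#' @param clusters cluster tibble.
#' @param sites tibble with `chrom` and `pos` (one row per external site);
#'   a BED-style `start`/`end` pair is accepted, using `end` as the 1-based
#'   site coordinate.
#' @return logical vector along `clusters`.
#' @export
match_external_sites <- function(clusters, sites) {
  if (is.null(sites) || nrow(sites) == 0L) {
    return(rep(FALSE, nrow(clusters)))
  }
  sites <- as_tibble(sites)
  if (is.null(sites$pos)) sites$pos <- sites$end
  vapply(seq_len(nrow(clusters)), function(i) {
    any(sites$chrom == clusters$chrom[[i]] &
          sites$pos >= clusters$span_start[[i]] &
          sites$pos <= clusters$span_end[[i]])
  }, logical(1))
}

#' Dominant 3' length form of class II genes
#'
#' The form (short = proximal, long = distal) with the greater mean
#' normalised expression across cell lines; exact ties go to the long form
#' (distal forms dominate genome-wide).
#'
#' @param apa_genes result of [classify_apa()].
#' @param expression cluster-level normalised expression (tibble
#'   `cluster_id`, `sample`, `value`; see [normalize_expression()]).
#' @return `apa_genes` with a `dominant_form` column
#'   (`"short"`/`"long"`/`NA`).
#' @export
dominant_form <- function(apa_genes, expression) {
  mean_expr <- expression |>
    group_by(.data$cluster_id) |>
    summarise(m = mean(.data$value), .groups = "drop")
  get_m <- function(id) {
    v <- mean_expr$m[match(id, mean_expr$cluster_id)]
    if_else(is.na(v), 0, v)
  }
  apa_genes |>
    mutate(dominant_form = dplyr::case_when(
      .data$apa_class != "II" ~ NA_character_,
      get_m(.data$proximal_cluster) > get_m(.data$distal_cluster) ~ "short",
      TRUE ~ "long"
    ))
}
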