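# generic positional scanner: pattern positions may be IUPAC codes (W, N);
# `fixed` marks positions where no mismatch is tolerated.
scan_pattern <- function(sequence, pattern, max_mm = 0L, fixed = integer(0)) {
  k <- nchar(pattern)
  L <- nchar(sequence)
  if (L < k) {
    return(tibble(start = integer(0), end = integer(0),
                  match = character(0), mismatches = integer(0)))
  }
  ch <- s_chars(sequence)
  pat <- s_chars(pattern)
  n_win <- L - k + 1L
  mm_free <- integer(n_win)
  mm_fixed <- integer(n_win)
  for (p in seq_len(k)) {
    allowed <- IUPAC_SETS[[pat[p]]]
    bad <- !(ch[p:(p + n_win - 1L)] %in% allowed)
    if (p %in% fixed) mm_fixed <- mm_fixed + bad else mm_free <- mm_free + bad
  }
  hit <- mm_fixed == 0L & mm_free <= max_mm
  starts <- which(hit)
  matches <- if (length(starts)) {
    substring(sequence, starts, starts + k - 1L)
  } else {
    character(0)
  }
  tibble::new_tibble(
    list(start = starts, end = starts + k - 1L, match = matches,
         mismatches = mm_free[hit]),
    nrow = length(starts)
  )
}

#' Merge overlapping motif hits into maximal intervals
#'
#' @param hits tibble with `start`, `end` (1-based closed intervals on one
#'   sequence or chromosome strand).
#' @return tibble of disjoint merged intervals, sorted.
#' @export
merge_hits <- function(hits) {
  if (nrow(hits) == 0L) return(tibble(start = integer(0), end = integer(0)))
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  out_s <- hits$start[[1]]
  out_e <- hits$end[[1]]
  for (i in seq_len(nrow(hits))[-1]) {
    if (hits$start[[i]] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], hits$end[[i]])
    } else {
      out_s <- c(out_s, hits$start[[i]])
      out_e <- c(out_e, hits$end[[i]])
    }
  }
  tibble(start = out_s, end = out_e)
}

#' Scan for AU-rich destabilising elements (ARE)
#'
#' Matches the class II ARE motif `WWWTATTTATTTW` (W = A/T) allowing up to
#' one mismatch outside the central pentamer `ATTTA`, which must be exact.
#' Overlapping matches are merged into maximal intervals by default.
#'
#' @param sequence transcript-strand DNA string.
#' @param merge merge overlapping hits (default `TRUE`).
#' @return tibble `start`, `end` (+ `match`, `mismatches` when unmerged).
#' @export
#' @examples
#' scan_are("GGTTTTATTTATTTTGG")
scan_are <- function(sequence, merge = TRUE) {
  hits <- scan_pattern(sequence, "WWWTATTTATTTW", max_mm = 1L, fixed = 5:9)
  if (merge) merge_hits(hits) else hits
}

#' Scan for GU-rich destabilising elements (GRE)
#'
#' Matches `TGTTTGTTTGT` within Hamming distance 1.
#'
#' @inheritParams scan_are
#' @return tibble of hits.
#' @export
scan_gre <- function(sequence, merge = TRUE) {
  hits <- scan_pattern(sequence, "TGTTTGTTTGT", max_mm = 1L)
  if (merge) merge_hits(hits) else hits
}

#' Scan for Pumilio binding elements (PUF)
#'
#' Exact matches of `TGTANATA` (N = any base).
#'
#' @param sequence transcript-strand DNA string.
#' @return tibble of hits.
#' @export
scan_puf <- function(sequence) {
  scan_pattern(sequence, "TGTANATA", max_mm = 0L)
}

#' Scan annotated 3' UTRs for destabilising motifs
#'
#' Runs the ARE/GRE/PUF scanners over the reference-genome 3' UTR sequence
#' of each gene (transcript strand) and maps hits back to genomic
#' coordinates.
#'
#' @param apa_genes result of [classify_apa()] (genes with a defined
#'   `utr3_start`/`utr3_end` are scanned).
#' @param genome named [Biostrings::DNAStringSet].
#' @param motifs subset of `c("ARE", "GRE", "PUF")`.
#' @return tibble `gene_id`, `motif_type`, `chrom`, `strand`, `start`,
#'   `end` (genomic, sorted).
#' @export
scan_utr_motifs <- function(apa_genes, genome, motifs = c("ARE", "GRE", "PUF")) {
  gs <- apa_genes[!is.na(apa_genes$utr3_start), , drop = FALSE]
  res <- purrr::pmap(
    list(gs$gene_id, gs$chrom, gs$strand, gs$utr3_start, gs$utr3_end),
    function(gene_id, chrom, strand, u3s, u3e) {
      seqs <- seq_window(genome, chrom, u3s, u3e, strand)
      L <- nchar(seqs)
      to_genomic <- function(h) {
        if (nrow(h) == 0L) return(h)
        if (strand == "+") {
          h$gstart <- u3s + h$start - 1L
          h$gend <- u3s + h$end - 1L
        } else {
          h$gstart <- u3e - h$end + 1L
          h$gend <- u3e - h$start + 1L
        }
        h
      }
      per_motif <- list(
        ARE = if ("ARE" %in% motifs) scan_are(seqs) else NULL,
        GRE = if ("GRE" %in% motifs) scan_gre(seqs) else NULL,
        PUF = if ("PUF" %in% motifs) scan_puf(seqs)[, c("start", "end")] else NULL
      )
      purrr::imap(per_motif, function(h, nm) {
        if (is.null(h) || nrow(h) == 0L) return(NULL)
        h <- to_genomic(h)
        tibble(gene_id = gene_id, motif_type = nm, chrom = chrom,
               strand = strand, start = h$gstart, end = h$gend)
      }) |> list_rbind()
    }
  )
  list_rbind(res)
}

#' Ingest external motif-site files (miRNA target sites, Alu repeats)
#'
#' TargetScan-style TSV sites are retained when their context score is below
#' the threshold; BED-style repeat intervals are passed through. All
#' intervals are intersected with the supplied 3' UTR regions and the
#' overlapping parts recorded as hits.
#'
#' @param x a file path or data frame. TSV/data frame needs columns `chrom`,
#'   `start`, `end` (1-based closed; BED files, recognised by a `.bed`
#'   extension, are converted from 0-based half-open) and, for miRNA sites,
#'   `context_score`; optional `gene_id`, `strand`.
#' @param motif_type `"miRNA"` or `"Alu"`.
#' @param score_threshold retain miRNA sites with context score strictly
#'   below this (default -0.4).
#' @param utr_regions tibble `gene_id`, `chrom`, `strand`, `start`, `end` of
#'   3' UTRs to intersect with.
#' @return hits tibble `gene_id`, `motif_type`, `chrom`, `strand`, `start`,
#'   `end`.
#' @export
ingest_external_sites <- function(x, motif_type = c("miRNA", "Alu"),
                                  score_threshold = -0.4, utr_regions) {
  motif_type <- match.arg(motif_type)
  if (is.character(x)) {
    is_bed <- grepl("\\.bed$", x)
    df <- tryCatch(
      utils::read.table(x, header = !is_bed, sep = "\t",
                        stringsAsFactors = FALSE),
      error = function(e) stop("failed to parse ", x, ": ", conditionMessage(e))
    )
    if (is_bed) {
      names(df)[1:3] <- c("chrom", "start", "end")
      df$start <- df$start + 1L # BED is 0-based half-open
    }
  } else {
    df <- as.data.frame(x)
  }
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("external site input lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad_rows <- which(!is.finite(df$start) | !is.finite(df$end) | df$end < df$start)
  if (length(bad_rows) > 0) {
    stop("malformed external site record at line ", bad_rows[1])
  }
  if (motif_type == "miRNA") {
    if (is.null(df$context_score)) stop("miRNA sites need a context_score column")
    df <- df[df$context_score < score_threshold, , drop = FALSE]
  }
  out <- purrr::pmap(
    list(utr_regions$gene_id, utr_regions$chrom, utr_regions$strand,
         utr_regions$start, utr_regions$end),
    function(gene_id, chrom, strand, us, ue) {
      ov <- df[df$chrom == chrom & df$start <= ue & df$end >= us, , drop = FALSE]
      if (nrow(ov) == 0L) return(NULL)
      tibble(gene_id = gene_id, motif_type = motif_type, chrom = chrom,
             strand = strand,
             start = pmax(ov$start, us), end = pmin(ov$end, ue))
    }
  )
  list_rbind(out)
}

#' Label motif hits by 3' UTR region
#'
#' Hits in class I gene UTRs get `class_I_utr`; in class II genes, hits
#' overlapping the differential region (including hits straddling the
#' proximal cleavage site, which are absent from the short form's mature
#' transcript) get `differential`, hits confined to the shared region get
#' `shared`.
#'
#' @param hits hits tibble with `gene_id`, `start`, `end`.
#' @param apa_genes result of [classify_apa()].
#' @return `hits` with a `region_label` column.
#' @export
label_regions <- function(hits, apa_genes) {
  g <- apa_genes[match(hits$gene_id, apa_genes$gene_id), , drop = FALSE]
  hits$region_label <- dplyr::case_when(
    g$apa_class == "I" ~ "class_I_utr",
    g$apa_class == "II" & !is.na(g$diff_start) &
      hits$end >= g$diff_start & hits$start <= g$diff_end ~ "differential",
    g$apa_class == "II" & !is.na(g$shared_start) &
      hits$end >= g$shared_start & hits$start <= g$shared_end ~ "shared",
    TRUE ~ NA_character_
  )
  hits
}

#' Observed SNP density over motif matches
#'
#' SNPs falling on any base of the merged hit intervals (closed) are counted
#' and divided by the total merged match length.
#'
#' @param hits hits tibble (`chrom`, `start`, `end`); merged per chromosome
#'   before counting so overlapping matches are not double-counted.
#' @param snps tibble `chrom`, `pos`.
#' @return list: `snp_per_kb`, `n_snps`, `total_len`.
#' @export
snp_density <- function(hits, snps) {
  if (nrow(hits) == 0L) {
    return(list(snp_per_kb = NA_real_, n_snps = 0L, total_len = 0L))
  }
  merged <- hits |>
    group_by(.data$chrom) |>
    dplyr::group_modify(~ merge_hits(.x)) |>
    ungroup()
  total_len <- sum(merged$end - merged$start + 1L)
  n <- sum(vapply(seq_len(nrow(snps)), function(i) {
    any(merged$chrom == snps$chrom[[i]] & merged$start <= snps$pos[[i]] &
          merged$end >= snps$pos[[i]])
  }, logical(1)))
  list(snp_per_kb = 1000 * n / total_len, n_snps = n, total_len = total_len)
}

#' Background model: per-base SNP rates over the 3' UTR universe
#'
#' Tabulates base frequencies P(base) and SNP rates P(SNP, base) across all
#' supplied 3' UTR sequence (transcript strand) and returns
#' P(SNP | base) = P(SNP, base) / P(base) per base.
#'
#' @param utr_regions tibble `chrom`, `strand`, `start`, `end`.
#' @param genome named [Biostrings::DNAStringSet].
#' @param snps tibble `chrom`, `pos`.
#' @return named numeric vector `c(A=, C=, G=, T=)` of per-base SNP
#'   probabilities.
#' @export
snp_base_rates <- function(utr_regions, genome, snps) {
  base_n <- c(A = 0, C = 0, G = 0, T = 0)
  snp_n <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_len(nrow(utr_regions))) {
    ch <- s_chars(seq_window(genome, utr_regions$chrom[[i]],
                             utr_regions$start[[i]], utr_regions$end[[i]],
                             utr_regions$strand[[i]]))
    tb <- table(factor(ch, levels = c("A", "C", "G", "T")))
    base_n <- base_n + as.numeric(tb)
    inreg <- snps$chrom == utr_regions$chrom[[i]] &
      snps$pos >= utr_regions$start[[i]] & snps$pos <= utr_regions$end[[i]]
    if (any(inreg)) {
      # transcript-strand base at each SNP position
      for (p in snps$pos[inreg]) {
        b <- seq_window(genome, utr_regions$chrom[[i]], p, p,
                        utr_regions$strand[[i]])
        if (b %in% names(snp_n)) snp_n[[b]] <- snp_n[[b]] + 1
      }
    }
  }
  if (any(base_n == 0)) {
    stop("base(s) absent from the 3' UTR universe: ",
         paste(names(base_n)[base_n == 0], collapse = ", "))
  }
  snp_n / base_n
}

#' Expected SNP-density bounds for motif hits
#'
#' For each hit sequence s of length N the expectation is
#' P(SNP | s) = (1/N) * sum_i P(SNP | s_i); the bounds are the minimum and
#' maximum of this value over all hits of the motif. For miRNA hits only the
#' 7-mer seed (the 3'-most 7 bases of the site) is used.
#'
#' @param hits hits tibble (`motif_type`, `chrom`, `strand`, `start`, `end`).
#' @param genome named [Biostrings::DNAStringSet].
#' @param rates per-base SNP probabilities from [snp_base_rates()].
#' @return tibble `motif_type`, `expected_lower`, `expected_upper` (per-base
#'   probabilities), `expected_lower_per_kb`, `expected_upper_per_kb`.
#' @export
expected_snp_density <- function(hits, genome, rates) {
  per_hit <- vapply(seq_len(nrow(hits)), function(i) {
    s <- hits$start[[i]]
    e <- hits$end[[i]]
    if (hits$motif_type[[i]] == "miRNA" && e - s + 1L > 7L) {
      if (hits$strand[[i]] == "+") s <- e - 6L else e <- s + 6L
    }
    ch <- s_chars(seq_window(genome, hits$chrom[[i]], s, e, hits$strand[[i]]))
    ch <- ch[ch %in% names(rates)]
    if (length(ch) == 0L) return(NA_real_)
    mean(rates[ch])
  }, numeric(1))
  tibble(motif_type = hits$motif_type, p = per_hit) |>
    filter(!is.na(.data$p)) |>
    group_by(.data$motif_type) |>
    summarise(expected_lower = min(.data$p), expected_upper = max(.data$p),
              .groups = "drop") |>
    mutate(expected_lower_per_kb = 1000 * .data$expected_lower,
           expected_upper_per_kb = 1000 * .data$expected_upper)
}

#' Motif conservation statistics (observed vs expected SNP density)
#'
#' @param hits labelled hits tibble.
#' @param snps tibble `chrom`, `pos`.
#' @param genome named [Biostrings::DNAStringSet].
#' @param utr_regions 3' UTR universe for the background model.
#' @return tibble per motif type: observed `snp_per_kb`, `n_snps`,
#'   `total_len`, `expected_lower_per_kb`, `expected_upper_per_kb`.
#' @export
conservation_stats <- function(hits, snps, genome, utr_regions) {
  rates <- snp_base_rates(utr_regions, genome, snps)
  obs <- hits |>
    group_by(.data$motif_type) |>
    dplyr::group_modify(function(h, key) {
      d <- snp_density(h, snps)
      tibble(snp_per_kb = d$snp_per_kb, n_snps = d$n_snps,
             total_len = d$total_len)
    }) |>
    ungroup()
  exp <- expected_snp_density(hits, genome, rates)
  left_join(obs, exp, by = "motif_type")
}

#' Shared vs differential region enrichment (Fisher's exact test)
#'
#' For each motif type, class II genes are cross-classified by region
#' (shared / differential) and motif presence (at least one hit / none), and
#' a two-sided Fisher's exact test is applied to the 2x2 table.
#'
#' @param apa_genes result of [classify_apa()].
#' @param hits labelled hits (see [label_regions()]).
#' @return tibble `motif_type`, counts, `odds_ratio`, `p_value`.
#' @export
region_enrichment <- function(apa_genes, hits) {
  cls2 <- apa_genes$gene_id[apa_genes$apa_class == "II"]
  if (length(cls2) == 0L) stop("no class II genes: enrichment undefined")
  purrr::map(unique(hits$motif_type), function(mt) {
    h <- hits[hits$motif_type == mt, , drop = FALSE]
    sh <- cls2 %in% h$gene_id[h$region_label == "shared"]
    df_ <- cls2 %in% h$gene_id[h$region_label == "differential"]
    tab <- matrix(c(sum(sh), sum(!sh), sum(df_), sum(!df_)), nrow = 2,
                  byrow = TRUE,
                  dimnames = list(c("shared", "differential"),
                                  c("hit", "no_hit")))
    ft <- fisher.test(tab, alternative = "two.sided")
    tibble(motif_type = mt,
           shared_hit = tab[1, 1], shared_none = tab[1, 2],
           diff_hit = tab[2, 1], diff_none = tab[2, 2],
           odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  }) |> list_rbind()
}
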