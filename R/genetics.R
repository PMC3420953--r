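#' Normalise cluster expression by library size
#'
#' The expression of a tag cluster in a library is its read count divided by
#' the total mapped reads in that library. Gene-level expression is the sum
#' over the gene's clusters; the association-ready value sums the two
#' replicates of each sample after normalisation.
#'
#' @param counts long tibble `cluster_id`, `sample`, `replicate`, `count`
#'   (see [cluster_counts()]).
#' @param libraries tibble `sample`, `replicate`, `library_size` (total
#'   mapped reads per library).
#' @param cluster_genes optional tibble `cluster_id`, `gene_id` for
#'   gene-level aggregation.
#' @return a list of tibbles: `cluster` (`cluster_id`, `sample`,
#'   `replicate`, `value`), and when `cluster_genes` is given `gene`
#'   (per-replicate gene values) and `gene_assoc` (per-sample values summed
#'   over replicates).
#' @export
normalize_expression <- function(counts, libraries, cluster_genes = NULL) {
  if (any(libraries$library_size <= 0)) stop("zero library total")
  x <- counts |>
    left_join(libraries, by = c("sample", "replicate")) |>
    mutate(value = .data$count / .data$library_size) |>
    select("cluster_id", "sample", "replicate", "value")
  out <- list(cluster = x)
  if (!is.null(cluster_genes)) {
    g <- x |>
      dplyr::inner_join(cluster_genes, by = "cluster_id") |>
      group_by(.data$gene_id, .data$sample, .data$replicate) |>
      summarise(value = sum(.data$value), .groups = "drop")
    out$gene <- g
    out$gene_assoc <- g |>
      group_by(.data$gene_id, .data$sample) |>
      summarise(value = sum(.data$value), .groups = "drop")
  }
  out
}

#' Broad-sense heritability from intraclass correlation
#'
#' One-way ANOVA over I samples with J replicates each:
#' MS_b = J * sum_i (ybar_i - ybar)^2 / (I - 1),
#' MS_e = sum_ij (y_ij - ybar_i)^2 / (I (J - 1)),
#' H2 = (MS_b - MS_e) / (MS_b + (J - 1) MS_e), clamped to `[0, 1]` (the raw
#' estimate is kept in `H2_raw` for diagnostics). A trait with zero total
#' variance has H2 = 0.
#'
#' @param y numeric matrix, samples x replicates (no missing cells), or a
#'   long data frame with columns `sample`, `replicate`, `value`.
#' @return one-row tibble `H2`, `H2_raw`, `MS_b`, `MS_e`, `I`, `J`.
#' @export
#' @examples
#' heritability(matrix(c(1, 1, 2, 2, 3, 3), nrow = 3, byrow = TRUE))
heritability <- function(y) {
  if (is.data.frame(y)) {
    wide <- tidyr::pivot_wider(y[, c("sample", "replicate", "value")],
                               names_from = "replicate", values_from = "value")
    y <- as.matrix(wide[, -1, drop = FALSE])
  }
  if (anyNA(y)) stop("missing cells: heritability requires complete replicates")
  I <- nrow(y)
  J <- ncol(y)
  stopifnot(I >= 3, J >= 2)
  mi <- rowMeans(y)
  m <- mean(y)
  if (all(y == y[[1]])) {
    return(tibble(H2 = 0, H2_raw = 0, MS_b = 0, MS_e = 0, I = I, J = J))
  }
  MS_b <- J * sum((mi - m)^2) / (I - 1)
  MS_e <- sum((y - mi)^2) / (I * (J - 1))
  raw <- (MS_b - MS_e) / (MS_b + (J - 1) * MS_e)
  tibble(H2 = min(1, max(0, raw)), H2_raw = raw, MS_b = MS_b, MS_e = MS_e,
         I = I, J = J)
}

#' Heritability of a trait across genes
#'
#' @param traits long tibble `gene_id`, `sample`, `replicate`, `value`;
#'   genes with missing cells are skipped.
#' @param trait label stored in the result (e.g. `"polya_position"`,
#'   `"expression"`).
#' @return an `apa_heritability` tibble: `gene_id`, `trait`, `H2`, `H2_raw`,
#'   `MS_b`, `MS_e`, `I`, `J`.
#' @export
heritability_by_gene <- function(traits, trait = "expression") {
  res <- traits |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "value") |>
    tidyr::drop_na() |>
    group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      heritability(as.matrix(d[, -1, drop = FALSE]))
    }) |>
    ungroup() |>
    mutate(trait = trait, .after = "gene_id")
  class(res) <- c("apa_heritability", class(res))
  res
}

#' PolyA-position trait per sample and replicate
#'
#' For each gene and library, the trait is the pooled polyA position of the
#' cluster with the highest read count in that library (ties resolved to the
#' 5'-most cluster on the transcript strand); libraries with no reads in any
#' of the gene's clusters yield a missing value.
#'
#' @param clusters retained cluster tibble with a `gene_id` column (e.g.
#'   after joining [match_annotation()]).
#' @return long tibble `gene_id`, `sample`, `replicate`, `value` (genomic
#'   polyA position; `NA` when unobserved).
#' @export
polya_position_trait <- function(clusters) {
  stopifnot(!is.null(clusters$gene_id))
  counts <- cluster_counts(clusters) |>
    left_join(clusters |>
                select("cluster_id", "gene_id", "strand", "polya_pos"),
              by = "cluster_id")
  counts |>
    group_by(.data$gene_id, .data$sample, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      if (all(d$count == 0)) return(tibble(value = NA_real_))
      top <- d[d$count == max(d$count), , drop = FALSE]
      if (nrow(top) > 1L) { # tie: 5'-most on the transcript strand
        top <- if (top$strand[[1]] == "+") {
          top[which.min(top$polya_pos), ]
        } else {
          top[which.max(top$polya_pos), ]
        }
      }
      tibble(value = as.numeric(top$polya_pos[[1]]))
    }) |>
    ungroup()
}

#' Default started-logarithm constant
#'
#' Half the smallest nonzero expression value: scale-free and admits zeros.
#' @param values numeric expression values.
#' @return a positive constant.
#' @export
started_log_constant <- function(values) {
  nz <- values[values > 0]
  if (length(nz) == 0L) return(1e-9)
  min(nz) / 2
}

#' Dosage-expression association for one SNP
#'
#' Pearson correlation between the major-allele dosage (0-2 per sample) and
#' the started logarithm log10(expression + c) of gene expression. Positive
#' values mean the major allele is associated with higher expression.
#'
#' @param dosage integer vector of major-allele counts per sample.
#' @param expression numeric vector of per-sample expression (same order).
#' @param c started-log constant; default [started_log_constant()] of
#'   `expression`.
#' @return list `signed_R`, `abs_R`, `n`; `NULL` when undefined (monomorphic
#'   dosage or zero-variance expression).
#' @export
associate <- function(dosage, expression, c = NULL) {
  keep <- complete.cases(dosage, expression)
  dosage <- dosage[keep]
  expression <- expression[keep]
  if (length(dosage) < 3L || length(unique(dosage)) < 2L) return(NULL)
  c <- c %||% started_log_constant(expression)
  y <- log10(expression + c)
  if (sd(y) == 0) return(NULL)
  r <- cor(dosage, y)
  list(signed_R = r, abs_R = abs(r), n = length(dosage))
}

#' Polyadenylation-signal strength score of a hexamer
#'
#' 1 for the canonical AATAAA/ATTAAA, 0.5 for a variant-table hexamer,
#' 0 otherwise.
#'
#' @param hexamer a 6-mer.
#' @param hexamers a [pas_hexamers()] table.
#' @return 1, 0.5 or 0.
#' @export
pas_strength <- function(hexamer, hexamers = pas_hexamers()) {
  if (is.na(hexamer) || nchar(hexamer) != 6L) stop("pas_strength needs a 6-mer")
  cat <- classify_pas_category(hexamer, FALSE, hexamers)
  switch(cat, canonical = 1, variant = 0.5, 0)
}

#' Allelic strength difference for a SNP inside a polyadenylation signal
#'
#' Both allelic hexamers are built by substituting the SNP base into the
#' signal sequence; the difference is strength(major) - strength(minor).
#'
#' @param pas_seq reference hexamer (transcript strand).
#' @param offset_in_pas 1-based position of the SNP within the hexamer.
#' @param major,minor transcript-strand alleles.
#' @param hexamers a [pas_hexamers()] table.
#' @return list `score_major`, `score_minor`, `score_diff`.
#' @export
score_difference <- function(pas_seq, offset_in_pas, major, minor,
                             hexamers = pas_hexamers()) {
  stopifnot(nchar(pas_seq) == 6L, offset_in_pas >= 1L, offset_in_pas <= 6L)
  sub1 <- pas_seq
  substr(sub1, offset_in_pas, offset_in_pas) <- major
  sub2 <- pas_seq
  substr(sub2, offset_in_pas, offset_in_pas) <- minor
  s1 <- pas_strength(sub1, hexamers)
  s2 <- pas_strength(sub2, hexamers)
  list(score_major = s1, score_minor = s2, score_diff = s1 - s2)
}

#' Association tests between 3' UTR SNPs and gene expression
#'
#' For every biallelic SNP located in a gene's 3' UTR, dosages are coded as
#' major-allele counts across the samples (major allele determined across
#' the analysed samples, ties to the reference allele) and correlated with
#' the started-log gene expression. SNPs falling inside an inferred
#' polyadenylation signal additionally receive allele strength scores.
#'
#' @param variants tibble `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param genotypes tibble `snp_id`, `sample`, `dosage_ref` (0-2 copies of
#'   the reference allele).
#' @param expression per-sample gene expression (`gene_id`, `sample`,
#'   `value`; replicate-summed, see [normalize_expression()]).
#' @param apa_genes result of [classify_apa()] supplying per-gene 3' UTR
#'   intervals and strand.
#' @param elements optional result of [call_elements()] with genomic PAS
#'   intervals, joined to clusters for PAS-SNP scoring.
#' @param clusters optional cluster tibble (to map elements to genes).
#' @param c started-log constant; default derived from the expression
#'   matrix.
#' @param hexamers a [pas_hexamers()] table.
#' @return an `apa_association` tibble: `snp_id`, `gene_id`, `signed_R`,
#'   `abs_R`, `n`, `in_pas`, `pas_score_major`, `pas_score_minor`,
#'   `score_diff`, `region_label`.
#' @export
associate_utr_snps <- function(variants, genotypes, expression, apa_genes,
                               elements = NULL, clusters = NULL, c = NULL,
                               hexamers = pas_hexamers()) {
  c <- c %||% started_log_constant(expression$value)
  samples <- sort(unique(expression$sample))
  pas_tbl <- NULL
  if (!is.null(elements) && !is.null(clusters)) {
    pas_tbl <- elements |>
      filter(!is.na(.data$pas_start), .data$category %in% c("canonical", "variant")) |>
      left_join(clusters |> select("cluster_id", "chrom", "strand"),
                by = "cluster_id")
  }
  rows <- purrr::map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    g <- apa_genes[apa_genes$chrom == v$chrom &
                     !is.na(apa_genes$utr3_start) &
                     v$pos >= apa_genes$utr3_start &
                     v$pos <= apa_genes$utr3_end, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    g <- g[1, ]
    gt <- genotypes[genotypes$snp_id == v$snp_id, , drop = FALSE]
    d_ref <- gt$dosage_ref[match(samples, gt$sample)]
    if (anyNA(d_ref)) return(NULL)
    # major allele across the analysed samples; ties to the reference allele
    major_is_ref <- sum(d_ref) >= length(samples)
    dosage <- if (major_is_ref) d_ref else 2L - d_ref
    ev <- expression[expression$gene_id == g$gene_id, , drop = FALSE]
    ex <- ev$value[match(samples, ev$sample)]
    a <- associate(dosage, ex, c = c)
    if (is.null(a)) return(NULL)
    region <- dplyr::case_when(
      g$apa_class == "I" ~ "class_I_utr",
      g$apa_class == "II" & !is.na(g$diff_start) &
        v$pos >= g$diff_start & v$pos <= g$diff_end ~ "differential",
      g$apa_class == "II" & !is.na(g$shared_start) &
        v$pos >= g$shared_start & v$pos <= g$shared_end ~ "shared",
      TRUE ~ NA_character_
    )
    out <- tibble(
      snp_id = v$snp_id, gene_id = g$gene_id,
      signed_R = a$signed_R, abs_R = a$abs_R, n = a$n,
      in_pas = FALSE, pas_score_major = NA_real_, pas_score_minor = NA_real_,
      score_diff = NA_real_, region_label = region
    )
    if (!is.null(pas_tbl)) {
      hit <- pas_tbl[pas_tbl$chrom == v$chrom & pas_tbl$pas_start <= v$pos &
                       pas_tbl$pas_end >= v$pos, , drop = FALSE]
      if (nrow(hit) > 0L) {
        hit <- hit[1, ]
        strand <- hit$strand
        # transcript-strand position of the SNP within the hexamer
        off <- if (strand == "+") {
          v$pos - hit$pas_start + 1L
        } else {
          hit$pas_end - v$pos + 1L
        }
        maj_g <- if (major_is_ref) v$ref else v$alt
        min_g <- if (major_is_ref) v$alt else v$ref
        if (strand == "-") {
          maj_g <- rc(maj_g)
          min_g <- rc(min_g)
        }
        sc <- score_difference(hit$motif, off, maj_g, min_g, hexamers)
        out$in_pas <- TRUE
        out$pas_score_major <- sc$score_major
        out$pas_score_minor <- sc$score_minor
        out$score_diff <- sc$score_diff
      }
    }
    out
  })
  res <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  class(res) <- c("apa_association", class(res))
  res
}

#' Distribution and count enrichment tests for association statistics
#'
#' One-sided Wilcoxon rank-sum test of whether the |R| values of a focal SNP
#' set (e.g. polyadenylation-signal SNPs) are stochastically larger than a
#' background set; two-sided Fisher's exact test on a 2x2 count table (e.g.
#' PAS-SNP presence in heritable vs all genes); and the linear regression of
#' signed R on the allelic strength difference.
#'
#' @param abs_r_focal,abs_r_background numeric |R| sets.
#' @param count_table optional 2x2 matrix for Fisher's exact test.
#' @param signed_r,score_diff optional paired vectors for the regression.
#' @return an `apa_enrichment` list with `wilcoxon`, `fisher`, `regression`
#'   components (tibbles; `NULL` where inputs were not supplied).
#' @export
enrichment_tests <- function(abs_r_focal, abs_r_background,
                             count_table = NULL, signed_r = NULL,
                             score_diff = NULL) {
  if (length(abs_r_focal) == 0L || length(abs_r_background) == 0L) {
    stop("empty |R| set: enrichment undefined")
  }
  wt <- wilcox.test(abs_r_focal, abs_r_background, alternative = "greater",
                    exact = FALSE)
  out <- list(
    wilcoxon = tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                      n_focal = length(abs_r_focal),
                      n_background = length(abs_r_background)),
    fisher = NULL, regression = NULL
  )
  if (!is.null(count_table)) {
    ft <- fisher.test(count_table, alternative = "two.sided")
    out$fisher <- tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  }
  if (!is.null(signed_r) && !is.null(score_diff)) {
    keep <- complete.cases(signed_r, score_diff)
    if (sum(keep) >= 3L && sd(score_diff[keep]) > 0) {
      fit <- lm(signed_r[keep] ~ score_diff[keep])
      sm <- summary(fit)
      out$regression <- tibble(
        slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
        r_squared = sm$r.squared, n = sum(keep)
      )
    }
  }
  class(out) <- "apa_enrichment"
  out
}
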