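#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a heritability result
#'
#' @param x an `apa_heritability` tibble.
#' @param ... unused.
#' @return the per-gene tibble.
#' @method tidy apa_heritability
#' @export
tidy.apa_heritability <- function(x, ...) {
  as_tibble(unclass(x))
}

#' One-row heritability summary
#'
#' @param x an `apa_heritability` tibble.
#' @param h2_cutoff threshold defining "heritable" (default 0.6).
#' @param ... unused.
#' @return tibble with one row per trait: gene count, mean/median H2 and the
#'   count of heritable genes.
#' @method glance apa_heritability
#' @export
glance.apa_heritability <- function(x, h2_cutoff = 0.6, ...) {
  as_tibble(unclass(x)) |>
    group_by(.data$trait) |>
    summarise(
      n_genes = dplyr::n(),
      mean_H2 = mean(.data$H2),
      median_H2 = median(.data$H2),
      n_heritable = sum(.data$H2 > h2_cutoff),
      .groups = "drop"
    )
}

#' Histogram of per-gene heritability estimates
#'
#' @param object an `apa_heritability` tibble.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot apa_heritability
#' @export
autoplot.apa_heritability <- function(object, bins = 20, ...) {
  df <- as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$H2)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = expression(H^2 ~ "(intraclass correlation)"),
                  y = "genes") +
    ggplot2::theme_minimal()
}

#' Tidy an association result
#'
#' @param x an `apa_association` tibble.
#' @param ... unused.
#' @return the per-SNP tibble.
#' @method tidy apa_association
#' @export
tidy.apa_association <- function(x, ...) {
  as_tibble(unclass(x))
}

#' One-row association summary
#'
#' @param x an `apa_association` tibble.
#' @param ... unused.
#' @return tibble: SNP counts, mean |R| inside/outside polyadenylation
#'   signals, and the one-sided Wilcoxon p value comparing them (when both
#'   sets are nonempty).
#' @method glance apa_association
#' @export
glance.apa_association <- function(x, ...) {
  df <- as_tibble(unclass(x))
  p <- NA_real_
  if (any(df$in_pas) && any(!df$in_pas)) {
    p <- wilcox.test(df$abs_R[df$in_pas], df$abs_R[!df$in_pas],
                     alternative = "greater", exact = FALSE)$p.value
  }
  tibble(
    n_snps = nrow(df),
    n_pas = sum(df$in_pas),
    mean_abs_R_pas = if (any(df$in_pas)) mean(df$abs_R[df$in_pas]) else NA_real_,
    mean_abs_R_other = if (any(!df$in_pas)) mean(df$abs_R[!df$in_pas]) else NA_real_,
    wilcoxon_p = p
  )
}

#' Signed association versus allelic signal-strength difference
#'
#' Scatter of signed R against the polyadenylation-signal strength
#' difference (major minus minor allele) with the least-squares line; SNPs
#' outside signals are shown as an |R| histogram when no PAS SNPs exist.
#'
#' @param object an `apa_association` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot apa_association
#' @export
autoplot.apa_association <- function(object, ...) {
  df <- as_tibble(unclass(object))
  pas <- df[df$in_pas & !is.na(df$score_diff), , drop = FALSE]
  if (nrow(pas) >= 3) {
    return(
      ggplot2::ggplot(pas, ggplot2::aes(x = .data$score_diff, y = .data$signed_R)) +
        ggplot2::geom_point(alpha = 0.6) +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                             colour = "firebrick") +
        ggplot2::labs(x = "PAS strength difference (major - minor)",
                      y = "signed R") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_R, fill = .data$in_pas)) +
    ggplot2::geom_histogram(bins = 20, position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "|R|", y = "SNPs") +
    ggplot2::theme_minimal()
}

#' Tidy enrichment test results
#'
#' @param x an `apa_enrichment` object (see [enrichment_tests()]).
#' @param ... unused.
#' @return long tibble with one row per component test.
#' @method tidy apa_enrichment
#' @export
tidy.apa_enrichment <- function(x, ...) {
  rows <- list()
  rows$wilcoxon <- x$wilcoxon |>
    mutate(test = "wilcoxon_one_sided", .before = 1) |>
    select("test", "statistic", "p_value")
  if (!is.null(x$fisher)) {
    rows$fisher <- x$fisher |>
      mutate(test = "fisher_two_sided", statistic = .data$odds_ratio,
             .before = 1) |>
      select("test", "statistic", "p_value")
  }
  if (!is.null(x$regression)) {
    rows$regression <- x$regression |>
      mutate(test = "lm_signedR_on_score_diff", statistic = .data$slope,
             p_value = NA_real_, .before = 1) |>
      select("test", "statistic", "p_value")
  }
  list_rbind(rows)
}

#' One-row enrichment summary
#'
#' @param x an `apa_enrichment` object.
#' @param ... unused.
#' @return one-row tibble: Wilcoxon p, Fisher p and regression slope (where
#'   computed).
#' @method glance apa_enrichment
#' @export
glance.apa_enrichment <- function(x, ...) {
  tibble(
    wilcoxon_p = x$wilcoxon$p_value,
    fisher_p = if (!is.null(x$fisher)) x$fisher$p_value else NA_real_,
    slope = if (!is.null(x$regression)) x$regression$slope else NA_real_
  )
}

#' Bar chart of APA class membership
#'
#' @param apa_genes result of [classify_apa()].
#' @return a ggplot object.
#' @export
plot_apa_classes <- function(apa_genes) {
  ggplot2::ggplot(apa_genes, ggplot2::aes(x = .data$apa_class)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "APA class", y = "genes") +
    ggplot2::theme_minimal()
}

#' Bar chart of cluster filter outcomes
#'
#' @param clusters result of [call_clusters()].
#' @return a ggplot object.
#' @export
plot_cluster_filters <- function(clusters) {
  df <- tibble(
    outcome = c("retained", "misprimed", "low_precision", "low_count",
                "low_replicate_corr"),
    n = c(sum(clusters$retained), sum(clusters$flag_misprimed),
          sum(clusters$flag_low_precision), sum(clusters$flag_low_count),
          sum(clusters$flag_low_replicate_corr))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$outcome, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "clusters") +
    ggplot2::theme_minimal()
}
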