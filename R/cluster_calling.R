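#' Group sorted polyA positions into raw tag clusters
#'
#' Reads are pooled over samples and replicates, sorted by polyA position
#' within each chromosome strand, and grouped: consecutive positions at most
#' `max_gap` bp apart share a cluster; a larger gap starts a new one.
#'
#' @param reads a data frame with `chrom`, `strand`, `polya_pos`, sorted by
#'   `(chrom, strand, polya_pos)`; unsorted input is an error.
#' @param params a [peak_params()] list.
#' @return the input tibble with an integer `raw_cluster` column.
#' @export
group_by_gap <- function(reads, params = peak_params()) {
  reads <- as_tibble(reads)
  key <- paste(reads$chrom, reads$strand)
  unsorted <- unlist(tapply(reads$polya_pos, factor(key, levels = unique(key)),
                            function(p) is.unsorted(p)), use.names = FALSE)
  if (any(unsorted)) stop("reads must be sorted by polya_pos within chrom/strand")
  pos <- as.numeric(reads$polya_pos)
  new_group <- key != dplyr::lag(key, default = "\r") |
    (pos - dplyr::lag(pos, default = -Inf)) > params$max_gap
  reads$raw_cluster <- cumsum(new_group)
  reads
}

peak_recurse <- function(pos, params, strand) {
  tab <- table(pos)
  coords <- as.integer(names(tab))
  cnt <- as.integer(tab)
  maxh <- max(cnt)
  at_max <- coords[cnt == maxh]
  # argmax tie: 5'-most coordinate on the transcript strand
  posM <- if (strand == "-") max(at_max) else min(at_max)
  inwin <- abs(coords - posM) <= params$window
  retained <- coords[inwin & cnt > params$height_frac * maxh]
  posL <- min(retained)
  posR <- max(retained)
  left <- pos[pos < posL]
  middle <- pos[pos >= posL & pos <= posR]
  right <- pos[pos > posR]
  out <- list()
  if (posR - posL <= params$window) out <- c(out, list(sort(middle)))
  for (side in list(left, right)) {
    if (length(side) == 0L) next
    stab <- table(side)
    if (all(as.integer(stab) < params$height_frac * maxh)) next # eliminated
    out <- c(out, peak_recurse(side, params, strand))
  }
  out
}

#' Split a wide tag cluster with the recursive peak finder
#'
#' Clusters spanning at most `span_trigger` bp are returned unchanged.
#' Otherwise the per-coordinate read counts are peak-split: the coordinate
#' with the greatest count (`posM`, ties to the 5'-most on the transcript
#' strand) anchors a window of `window` bp either side; coordinates in the
#' window with counts above `height_frac` of the peak height delimit
#' `posL`/`posR`; reads split into left (`< posL`), middle
#' (`[posL, posR]`, kept unless wider than `window`), and right (`> posR`)
#' candidates; a side candidate whose coordinates all fall below
#' `height_frac` of the peak height is discarded, otherwise the procedure
#' recurses on it from the argmax step.
#'
#' @param positions integer vector of member polyA positions (multiset).
#' @param params a [peak_params()] list.
#' @param strand `"+"` or `"-"` (argmax tie-break orientation).
#' @return a list of sorted integer vectors, one per surviving cluster, in
#'   genomic order. Positions absent from every element were discarded.
#' @export
#' @examples
#' split_by_peaks(rep(c(0L, 50L), c(100, 100)))
split_by_peaks <- function(positions, params = peak_params(), strand = "+") {
  if (length(positions) == 0L) return(list())
  positions <- as.integer(positions)
  if (max(positions) - min(positions) <= params$span_trigger) {
    return(list(sort(positions)))
  }
  out <- peak_recurse(positions, params, strand)
  out[order(vapply(out, min, integer(1)))]
}

#' Cluster polyA position: the median member position
#'
#' For an even member count the lower middle value is taken, so the reported
#' position is always an observed cleavage coordinate.
#'
#' @param positions integer vector of member polyA positions.
#' @return a single coordinate.
#' @export
cluster_position <- function(positions) {
  stopifnot(length(positions) > 0)
  p <- sort(positions)
  p[[ceiling(length(p) / 2)]]
}

#' Precision (concentration) of a set of read positions
#'
#' The concentration index \eqn{\sum_i (n_i/N)^2}, where \eqn{n_i} is the
#' number of reads at the i-th distinct position and N the total. Equals 1
#' iff all reads share one position; small values indicate scattered
#' positions.
#'
#' @param positions nonempty vector of coordinates (multiset).
#' @return a value in (0, 1].
#' @export
#' @examples
#' precision(c(1, 1, 2, 2)) # 0.5
precision <- function(positions) {
  if (length(positions) == 0L) stop("precision of an empty position set is undefined")
  p <- as.vector(table(positions)) / length(positions)
  sum(p^2)
}

#' PCR-duplicate / false-mapping filter
#'
#' Biological 3' ends give polyA positions that are *less* heterogeneous than
#' the opposite mate positions (which arise from random fragmentation). The
#' cluster is kept iff `precision(polyA positions) > precision(mate
#' positions)`; ties fail (strict inequality).
#'
#' @param polya_positions,mate_positions member coordinate multisets.
#' @return `TRUE` (keep) or `FALSE` (flag as likely PCR duplication).
#' @export
filter_duplication <- function(polya_positions, mate_positions) {
  precision(polya_positions) > precision(mate_positions)
}

#' Internal-priming (mispriming) filter
#'
#' Flags a cluster when the `a_window` genomic bases immediately downstream
#' (transcript strand) of its polyA position contain at least `a_run` A's in
#' the transcript-strand sense -- the signature of oligo-dT priming on a
#' genomic A-rich stretch rather than on a real poly(A) tail. A window
#' truncated by the chromosome end is counted over the available bases.
#'
#' @param clusters data frame with `chrom`, `strand`, `polya_pos`.
#' @param genome named [Biostrings::DNAStringSet].
#' @param params [peak_params()].
#' @return logical vector, `TRUE` = flagged as misprimed.
#' @export
filter_internal_priming <- function(clusters, genome, params = peak_params()) {
  purrr::pmap_lgl(
    list(clusters$chrom, clusters$strand, clusters$polya_pos),
    function(chrom, strand, pos) {
      win <- if (strand == "+") {
        seq_window(genome, chrom, pos + 1L, pos + params$a_window, "+")
      } else {
        seq_window(genome, chrom, pos - params$a_window, pos - 1L, "-")
      }
      ch <- s_chars(gsub("N", "", win, fixed = TRUE))
      if (params$a_run_consecutive) {
        r <- rle(ch == "A")
        any(r$values & r$lengths >= params$a_run)
      } else {
        sum(ch == "A") >= params$a_run
      }
    }
  )
}

#' Abundance and replicate-reproducibility filter
#'
#' Pooled count below `min_count` flags `low_count`. Counts inside the grey
#' zone require the Pearson correlation between the two replicate count
#' vectors across samples to reach `min_repl_R` in absolute value, else
#' `low_replicate_corr` (an undefined correlation from a zero-variance
#' vector also flags). Larger counts pass outright.
#'
#' @param counts numeric matrix, samples x replicates (>= 2 replicates).
#' @param params [peak_params()].
#' @return `"keep"`, `"low_count"` or `"low_replicate_corr"`.
#' @export
filter_abundance <- function(counts, params = peak_params()) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  total <- sum(counts)
  if (total < params$min_count) return("low_count")
  if (total >= params$grey_zone[1] && total <= params$grey_zone[2]) {
    r1 <- counts[, 1]
    r2 <- counts[, 2]
    if (sd(r1) == 0 || sd(r2) == 0) return("low_replicate_corr")
    if (abs(cor(r1, r2)) < params$min_repl_R) return("low_replicate_corr")
  }
  "keep"
}

#' Call, split and filter tag clusters from prepared reads
#'
#' Pools reads over samples and replicates, gap-clusters polyA positions per
#' chromosome strand, splits wide clusters with the recursive peak finder,
#' computes per-cluster positions, counts and precision statistics, and
#' applies the internal-priming, PCR-duplication and abundance filters. All
#' filter flags are evaluated independently; `retained` is true when no flag
#' is set.
#'
#' @param reads prepared reads (see [prep_reads()]): `chrom`, `strand`,
#'   `polya_pos`, `mate_pos`, `sample`, `replicate`.
#' @param genome named [Biostrings::DNAStringSet] (for the mispriming
#'   filter); `NULL` skips that filter.
#' @param params [peak_params()].
#' @return a tibble of clusters: `cluster_id`, `chrom`, `strand`,
#'   `span_start`, `span_end`, `polya_pos`, `n_reads`, `precision_polya`,
#'   `precision_mate`, flag columns, `retained`, plus list-columns `counts`
#'   (sample x replicate matrix), `positions`, `mate_positions`. Attributes:
#'   `filter_log` (elimination tallies) and `libraries` (per-library read
#'   totals used later for normalisation).
#' @export
call_clusters <- function(reads, genome = NULL, params = peak_params()) {
  reads <- as_tibble(reads) |> arrange(.data$chrom, .data$strand, .data$polya_pos)
  samples <- sort(unique(reads$sample))
  replicates <- sort(unique(reads$replicate))
  libraries <- reads |>
    count(.data$sample, .data$replicate, name = "library_size")

  gg <- group_by_gap(reads, params)
  log <- new_filter_log()

  pieces <- gg |>
    group_by(.data$raw_cluster) |>
    dplyr::group_split()
  n_discarded <- 0L
  leaves <- list()
  for (piece in pieces) {
    strand <- piece$strand[[1]]
    parts <- split_by_peaks(piece$polya_pos, params, strand)
    kept_pos <- unlist(parts)
    # assign each read to the leaf whose position range contains it
    for (part in parts) {
      lo <- min(part)
      hi <- max(part)
      idx <- piece$polya_pos >= lo & piece$polya_pos <= hi
      leaves[[length(leaves) + 1L]] <- piece[idx, , drop = FALSE]
    }
    n_discarded <- n_discarded + (nrow(piece) - length(kept_pos))
  }
  log <- add_log(log, "split_by_peaks", "peak_discarded_reads", n_discarded)

  count_matrix <- function(df) {
    m <- matrix(0L, length(samples), length(replicates),
                dimnames = list(samples, replicates))
    tb <- df |> count(.data$sample, .data$replicate)
    m[cbind(match(tb$sample, samples), match(tb$replicate, replicates))] <- tb$n
    m
  }

  cl <- purrr::map(leaves, function(df) {
    tibble(
      chrom = df$chrom[[1]],
      strand = df$strand[[1]],
      span_start = min(df$polya_pos),
      span_end = max(df$polya_pos),
      polya_pos = cluster_position(df$polya_pos),
      n_reads = nrow(df),
      precision_polya = precision(df$polya_pos),
      precision_mate = precision(df$mate_pos),
      counts = list(count_matrix(df)),
      positions = list(df$polya_pos),
      mate_positions = list(df$mate_pos)
    )
  }) |> list_rbind()
  if (nrow(cl) == 0L) {
    stop("no clusters could be formed from the supplied reads")
  }
  cl <- cl |>
    arrange(.data$chrom, .data$strand, .data$span_start) |>
    mutate(cluster_id = sprintf("TC%05d", row_number()), .before = 1)

  cl$flag_low_precision <- !purrr::map2_lgl(cl$positions, cl$mate_positions,
                                            filter_duplication)
  ab <- purrr::map_chr(cl$counts, filter_abundance, params = params)
  cl$flag_low_count <- ab == "low_count"
  cl$flag_low_replicate_corr <- ab == "low_replicate_corr"
  cl$flag_misprimed <- if (is.null(genome)) FALSE else {
    filter_internal_priming(cl, genome, params)
  }
  cl$retained <- !(cl$flag_misprimed | cl$flag_low_precision |
                     cl$flag_low_count | cl$flag_low_replicate_corr)

  log <- add_log(log, "cluster_filters", "misprimed", sum(cl$flag_misprimed))
  log <- add_log(log, "cluster_filters", "low_precision", sum(cl$flag_low_precision))
  log <- add_log(log, "cluster_filters", "low_count", sum(cl$flag_low_count))
  log <- add_log(log, "cluster_filters", "low_replicate_corr",
                 sum(cl$flag_low_replicate_corr))
  attr(cl, "filter_log") <- log
  attr(cl, "libraries") <- libraries
  cl
}

#' Long-format per-library cluster counts
#'
#' @param clusters result of [call_clusters()].
#' @return tibble `cluster_id`, `sample`, `replicate`, `count`.
#' @export
cluster_counts <- function(clusters) {
  purrr::map2(clusters$cluster_id, clusters$counts, function(id, m) {
    tibble(
      cluster_id = id,
      sample = rep(rownames(m), times = ncol(m)),
      replicate = rep(colnames(m), each = nrow(m)),
      count = as.vector(m)
    )
  }) |> list_rbind()
}
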