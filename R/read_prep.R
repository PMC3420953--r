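#' Trim leading poly-T tracts and classify read pairs
#'
#' 3'-end RNA-seq reads begin with the reverse-complemented poly(A) tail, a
#' run of T's. The run is trimmed from whichever mate carries it and its
#' length recorded as `n_T`. A pair is rejected when the run exceeds
#' `max_t` nt on either mate (likely oligo-dT artefact) or when neither mate
#' has a leading T stretch of at least `min_t` nt (no tail evidence).
#'
#' @param pairs a data frame with character columns `mate1` and `mate2`
#'   (sequences over A/C/G/T/N).
#' @param max_t maximum tail length retained (default 20).
#' @param min_t minimum leading-T run that counts as a tail stretch
#'   (default 1, i.e. any leading T).
#' @return a tibble: input columns plus `n_T` (tail length), `tail_mate`
#'   (1 or 2), `mate1_trimmed`, `mate2_trimmed`, `status`
#'   (`"kept"`/`"rejected"`) and `reject_reason`. A per-reason tally is
#'   attached as the `filter_log` attribute.
#' @export
#' @examples
#' trim_and_classify(data.frame(mate1 = "TTTTTACGACG", mate2 = "GATTACA"))
trim_and_classify <- function(pairs, max_t = 20L, min_t = 1L) {
  pairs <- as_tibble(pairs)
  if (!all(c("mate1", "mate2") %in% names(pairs))) {
    stop("`pairs` must have columns mate1 and mate2")
  }
  if (any(!nzchar(pairs$mate1) | !nzchar(pairs$mate2) |
            is.na(pairs$mate1) | is.na(pairs$mate2))) {
    stop("malformed input: empty sequence in read pair")
  }
  lead_t <- function(s) {
    m <- regmatches(s, regexpr("^T*", s))
    nchar(m)
  }
  t1 <- lead_t(pairs$mate1)
  t2 <- lead_t(pairs$mate2)
  # the tail mate is the one with the longer leading-T run
  tail_mate <- if_else(t1 >= t2, 1L, 2L)
  n_T <- pmax(t1, t2)
  too_long <- t1 > max_t | t2 > max_t
  no_tail <- n_T < min_t
  status <- if_else(too_long | no_tail, "rejected", "kept")
  reason <- dplyr::case_when(
    too_long ~ "tail_longer_than_max",
    no_tail ~ "no_t_stretch",
    TRUE ~ NA_character_
  )
  out <- pairs |>
    mutate(
      n_T = as.integer(n_T),
      tail_mate = tail_mate,
      mate1_trimmed = if_else(tail_mate == 1L, substring(.data$mate1, n_T + 1L), .data$mate1),
      mate2_trimmed = if_else(tail_mate == 2L, substring(.data$mate2, n_T + 1L), .data$mate2),
      status = status,
      reject_reason = reason
    )
  log <- out |>
    filter(.data$status == "rejected") |>
    count(.data$reject_reason, name = "n") |>
    rename(reason = "reject_reason") |>
    mutate(stage = "trim_and_classify", .before = 1)
  attr(out, "filter_log") <- log
  out
}

#' Count tail mismatches against the genome
#'
#' The trimmed poly-T tract claims that the `n_T` bases immediately
#' downstream (transcript strand) of `polya_pos` are a non-genomic poly(A)
#' tail. Each of those genomic bases is compared with `A`; disagreements
#' (including `N` and positions beyond the chromosome end) count as
#' mismatches.
#'
#' @param reads a data frame with `chrom`, `strand`, `polya_pos`, `n_T`.
#' @param genome named [Biostrings::DNAStringSet].
#' @return integer vector of mismatch counts, one per read.
#' @export
tail_mismatches <- function(reads, genome) {
  out <- integer(nrow(reads))
  count_char <- function(s, ch) nchar(s) - nchar(gsub(ch, "", s, fixed = TRUE))
  for (chrom in unique(reads$chrom)) {
    len <- length(genome[[chrom]])
    for (strand in c("+", "-")) {
      i <- which(reads$chrom == chrom & reads$strand == strand)
      if (length(i) == 0L) next
      nT <- reads$n_T[i]
      lo <- if (strand == "+") reads$polya_pos[i] + 1L else reads$polya_pos[i] - nT
      hi <- if (strand == "+") reads$polya_pos[i] + nT else reads$polya_pos[i] - 1L
      clo <- pmax(1L, lo)
      chi <- pmin(len, hi)
      seqs <- as.character(Biostrings::extractAt(
        genome[[chrom]], IRanges::IRanges(clo, pmax(clo - 1L, chi))
      ))
      # on the transcript strand the tail reads as A; on the genomic plus
      # strand that is A (+) or T (-); out-of-bounds bases never match
      matches <- count_char(seqs, if (strand == "+") "A" else "T")
      out[i] <- nT - matches
    }
  }
  out
}

#' Keep reads whose tail is not genomically templated
#'
#' A tail matching the genome (2 or fewer mismatches over the tract) is the
#' signature of internal priming on an A-rich genomic stretch; such reads are
#' rejected. Reads are kept iff `tail_mismatches > max_match`.
#'
#' @param reads a data frame of mapped 3'-end reads (`chrom`, `strand`,
#'   `polya_pos`, `n_T`, and `tail_mismatches` unless `genome` is supplied).
#' @param genome optional genome; when given, mismatches are recomputed from
#'   sequence rather than taken from the `tail_mismatches` column.
#' @param max_match maximum tail-genome agreement tolerated (default 2
#'   mismatches or fewer rejects).
#' @return the kept subset as a tibble, with a `filter_log` attribute.
#' @export
validate_tail <- function(reads, genome = NULL, max_match = 2L) {
  reads <- as_tibble(reads)
  if (!is.null(genome)) {
    reads$tail_mismatches <- tail_mismatches(reads, genome)
  }
  if (is.null(reads$tail_mismatches)) {
    stop("need a tail_mismatches column or a genome to compute it")
  }
  keep <- reads$tail_mismatches > max_match
  out <- reads[keep, , drop = FALSE]
  attr(out, "filter_log") <- add_log(
    new_filter_log(), "validate_tail", "genomic_tail", sum(!keep)
  )
  out
}

#' Infer transcript strand from tail and mate coordinates
#'
#' The mapped poly-T tract marks the transcript 3' end. If its coordinate is
#' lower than the other mate's the read comes from the minus strand; if
#' higher, from the plus strand. Equal coordinates leave the strand undefined
#' and the read is rejected.
#'
#' @param tail_pos,mate_pos genomic coordinates of the poly-T tract and of
#'   the other mate.
#' @return character vector over `"+"`, `"-"`, `NA` (ambiguous).
#' @export
#' @examples
#' infer_strand(c(1000, 2300), c(1150, 2100))
infer_strand <- function(tail_pos, mate_pos) {
  dplyr::case_when(
    tail_pos < mate_pos ~ "-",
    tail_pos > mate_pos ~ "+",
    TRUE ~ NA_character_
  )
}

#' Prepare mapped 3'-end reads for clustering
#'
#' Applies strand inference (when a `strand` column is absent) and tail
#' validation, accumulating per-reason elimination tallies.
#'
#' @param reads mapped reads: `chrom`, `polya_pos`, `mate_pos`, `n_T`,
#'   `sample`, `replicate`, and either `strand` or raw coordinates from which
#'   it is inferred; `tail_mismatches` optional when `genome` given.
#' @param genome optional genome for tail re-validation.
#' @param max_match see [validate_tail()].
#' @return tibble of surviving reads with a `filter_log` attribute.
#' @export
prep_reads <- function(reads, genome = NULL, max_match = 2L) {
  reads <- as_tibble(reads)
  log <- new_filter_log()
  if (!"strand" %in% names(reads)) {
    reads$strand <- infer_strand(reads$polya_pos, reads$mate_pos)
    amb <- is.na(reads$strand)
    log <- add_log(log, "infer_strand", "ambiguous_strand", sum(amb))
    reads <- reads[!amb, , drop = FALSE]
  }
  out <- validate_tail(reads, genome = genome, max_match = max_match)
  log <- bind_rows(log, filter_log(out))
  attr(out, "filter_log") <- log
  out
}
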