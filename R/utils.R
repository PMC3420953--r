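#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n row_number across all_of if_else rename count
#' @importFrom purrr map map_dbl map_chr map_int map2 pmap imap list_rbind
#' @importFrom stats median cor fisher.test wilcox.test lm coef rnorm rpois
#'   runif rbinom setNames complete.cases sd
NULL

# IUPAC one- and two-base codes used throughout (consensus and motif matching)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T")
)

# two-base set -> ambiguity code, keyed by sorted base pair
IUPAC_CODE2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @keywords internal
rc <- function(x) {
  out <- character(length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    out[ok] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok])))
  }
  out[!ok] <- x[!ok]
  out
}

s_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Extract a genomic window on the transcript strand
#'
#' Coordinates are 1-based closed. Bases outside the chromosome are returned
#' as `N` so that downstream mismatch counting treats them as mismatches.
#'
#' @param genome a named [Biostrings::DNAStringSet] (or named character vector).
#' @param chrom chromosome name.
#' @param start,end 1-based closed genomic interval (start <= end).
#' @param strand `"+"` or `"-"`; for `"-"` the reverse complement is returned
#'   so the string reads 5' to 3' on the transcript strand.
#' @return a character scalar.
#' @export
seq_window <- function(genome, chrom, start, end, strand = "+") {
  stopifnot(length(chrom) == 1, start <= end)
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(unlist(genome))
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  lo <- max(1L, start)
  hi <- min(len, end)
  core <- if (lo > hi) "" else as.character(Biostrings::subseq(genome[[chrom]], lo, hi))
  pre <- strrep("N", max(0L, lo - start))
  post <- strrep("N", max(0L, end - hi))
  s <- paste0(pre, core, post)
  if (strand == "-") rc(s) else s
}

#' Does an IUPAC code match a concrete base?
#'
#' Set-containment semantics: the code matches iff its base set contains the
#' base.
#' @keywords internal
iupac_matches <- function(code, base) {
  set <- IUPAC_SETS[[code]]
  !is.null(set) && base %in% set
}

# vectorised: codes, bases character vectors of equal length
iupac_match_vec <- function(codes, bases) {
  mapply(function(cd, b) {
    set <- IUPAC_SETS[[cd]]
    !is.null(set) && b %in% set
  }, codes, bases, USE.NAMES = FALSE)
}

new_filter_log <- function() tibble(stage = character(), reason = character(), n = integer())

add_log <- function(log, stage, reason, n) {
  bind_rows(log, tibble(stage = stage, reason = reason, n = as.integer(n)))
}

#' Retrieve the filter log attached to a pipeline result
#'
#' Most stage functions attach a tally of records eliminated per reason as an
#' attribute; this accessor returns it as a tibble.
#'
#' @param x a stage result.
#' @return a tibble with columns `stage`, `reason`, `n`.
#' @export
filter_log <- function(x) attr(x, "filter_log") %||% new_filter_log()
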