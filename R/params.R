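#' Polyadenylation-signal hexamer table
#'
#' The canonical signals AATAAA and ATTAAA followed by the ten variant
#' hexamers, in decreasing order of their abundance in the human genome
#' (Tian et al. 2005). The rank order drives signal priority: when several
#' hexamers occur in the 40-nt window upstream of a cleavage site, the
#' highest-ranked (most abundant) one wins regardless of proximity.
#'
#' @param variants optional replacement character vector for the ten variant
#'   hexamers (ranked).
#' @return a tibble with columns `hexamer`, `rank`, `category`
#'   (`"canonical"` or `"variant"`).
#' @export
#' @examples
#' pas_hexamers()
pas_hexamers <- function(variants = NULL) {
  canon <- c("AATAAA", "ATTAAA")
  vars <- variants %||% c(
    "AGTAAA", "TATAAA", "CATAAA", "GATAAA", "AATATA",
    "AATACA", "AATAGA", "AAAAAG", "ACTAAA", "AATGAA"
  )
  stopifnot(all(nchar(vars) == 6L))
  tibble(
    hexamer = c(canon, vars),
    rank = seq_len(length(canon) + length(vars)),
    category = c(rep("canonical", 2L), rep("variant", length(vars)))
  )
}

#' Tag-cluster calling parameters
#'
#' Defaults reproduce the study design: clusters are seeded by gap clustering
#' (new cluster when the next polyA position is more than `max_gap` bp away),
#' clusters spanning more than `span_trigger` bp are split by the recursive
#' peak finder (window `window` bp either side of the peak, retention at
#' `height_frac` of the peak height), clusters with fewer than `min_count`
#' pooled reads are dropped, clusters inside `grey_zone` need between-replicate
#' Pearson |R| of at least `min_repl_R`, and a cluster is flagged as internal
#' priming when the `a_window` bases immediately downstream of its polyA
#' position contain at least `a_run` A's (transcript strand).
#'
#' @param max_gap maximum gap (bp) joining consecutive polyA positions.
#' @param span_trigger span (max - min position, bp) above which peak
#'   splitting is applied.
#' @param window half-window (bp) around the peak coordinate.
#' @param height_frac fraction of the peak height for coordinate retention.
#' @param min_count minimum pooled read count.
#' @param grey_zone count interval (inclusive) in which replicate correlation
#'   is additionally required.
#' @param min_repl_R minimum |Pearson R| between replicate count vectors.
#' @param a_run minimum number of A's flagging internal priming.
#' @param a_window downstream window length (bp) scanned for A's.
#' @param a_run_consecutive if `TRUE`, require a consecutive run of `a_run`
#'   A's instead of a total count (alternative reading; default total count).
#' @return a `peak_params` list.
#' @export
peak_params <- function(max_gap = 15L, span_trigger = 40L, window = 40L,
                        height_frac = 0.10, min_count = 50L,
                        grey_zone = c(50L, 100L), min_repl_R = 0.5,
                        a_run = 10L, a_window = 20L,
                        a_run_consecutive = FALSE) {
  stopifnot(
    max_gap > 0, span_trigger > 0, window > 0,
    height_frac > 0, height_frac < 1,
    min_count > 0, length(grey_zone) == 2, grey_zone[1] <= grey_zone[2]
  )
  structure(
    list(
      max_gap = as.integer(max_gap), span_trigger = as.integer(span_trigger),
      window = as.integer(window), height_frac = height_frac,
      min_count = as.integer(min_count), grey_zone = as.integer(grey_zone),
      min_repl_R = min_repl_R, a_run = as.integer(a_run),
      a_window = as.integer(a_window), a_run_consecutive = a_run_consecutive
    ),
    class = "peak_params"
  )
}

#' Element-calling parameters
#'
#' @param pas_window length (nt) of the window upstream of the cleavage site
#'   scanned for polyadenylation signals.
#' @param use_window length (nt) of the window upstream of the signal scanned
#'   for the U-rich upstream element.
#' @param dse_window length (nt) of the window downstream of the cleavage
#'   site scanned for the U/G-rich downstream element.
#' @param min_coverage read coverage below which the consensus falls back to
#'   the reference base.
#' @param ambig_frac minor-base fraction above which an ambiguity code is
#'   emitted.
#' @param use_t_frac T proportion to maintain while extending the USE.
#' @param dse_t_frac T proportion to maintain while extending the DSE.
#' @param optimistic_t if `TRUE`, ambiguity codes containing T (W/Y/K) count
#'   as T in T-count rules; default strict (only literal T counts).
#' @return an `element_params` list.
#' @export
element_params <- function(pas_window = 40L, use_window = 30L, dse_window = 40L,
                           min_coverage = 5L, ambig_frac = 0.20,
                           use_t_frac = 0.65, dse_t_frac = 0.50,
                           optimistic_t = FALSE) {
  structure(
    list(
      pas_window = as.integer(pas_window), use_window = as.integer(use_window),
      dse_window = as.integer(dse_window), min_coverage = as.integer(min_coverage),
      ambig_frac = ambig_frac, use_t_frac = use_t_frac, dse_t_frac = dse_t_frac,
      optimistic_t = optimistic_t
    ),
    class = "element_params"
  )
}
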