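#' Consensus base at one coordinate
#'
#' With read coverage of at least `min_coverage` the consensus is the
#' most frequent base; when the second most frequent base exceeds
#' `ambig_frac` of the coverage the two-base IUPAC ambiguity code is emitted
#' (M/R/W/S/Y/K). Below the coverage threshold the reference base is used and
#' flagged as fallback.
#'
#' @param counts named numeric vector of read base counts (names among
#'   A/C/G/T).
#' @param ref_base reference base at the coordinate.
#' @param min_coverage,ambig_frac thresholds (see [element_params()]).
#' @return list with `base` and `source`
#'   (`"read_consensus"`/`"reference_fallback"`).
#' @export
#' @examples
#' consensus_base(c(C = 7, T = 3), "G") # Y
consensus_base <- function(counts, ref_base, min_coverage = 5L, ambig_frac = 0.20) {
  full <- c(A = 0, C = 0, G = 0, T = 0)
  full[names(counts)] <- counts
  cov <- sum(full)
  if (cov < min_coverage) {
    return(list(base = ref_base, source = "reference_fallback"))
  }
  ord <- order(-full, names(full)) # count desc, base alphabetical for ties
  top <- names(full)[ord[1]]
  second <- names(full)[ord[2]]
  if (full[[second]] > ambig_frac * cov) {
    pair <- paste(sort(c(top, second)), collapse = "")
    list(base = unname(IUPAC_CODE2[[pair]]), source = "read_consensus")
  } else {
    list(base = top, source = "read_consensus")
  }
}

#' Build a consensus track from a pileup
#'
#' @param pileup tibble with `chrom`, `pos` and base-count columns
#'   `A`, `C`, `G`, `T`.
#' @param genome named [Biostrings::DNAStringSet] supplying reference
#'   fallback bases.
#' @param params [element_params()].
#' @return tibble `chrom`, `pos`, `base`, `coverage`, `source`.
#' @export
build_consensus <- function(pileup, genome, params = element_params()) {
  pileup <- as_tibble(pileup)
  refs <- character(nrow(pileup))
  for (chrom in unique(pileup$chrom)) {
    i <- which(pileup$chrom == chrom)
    refs[i] <- as.character(Biostrings::extractAt(
      genome[[chrom]], IRanges::IRanges(pileup$pos[i], pileup$pos[i])
    ))
  }
  res <- purrr::pmap(
    list(pileup$pos, refs, pileup$A, pileup$C, pileup$G, pileup$T),
    function(pos, ref, a, c, g, t) {
      cb <- consensus_base(c(A = a, C = c, G = g, T = t), ref,
                           params$min_coverage, params$ambig_frac)
      tibble(pos = pos, base = cb$base, coverage = a + c + g + t,
             source = cb$source)
    }
  )
  list_rbind(res) |>
    mutate(chrom = pileup$chrom, .before = 1)
}

#' Pileup of 3'-end read coverage over a region
#'
#' Coverage comes from both mates of each pair: the tail-anchored portion
#' (ending at `polya_pos`, length `read_len - n_T`) and the opposite mate
#' (length `read_len` starting at `mate_pos` on the transcript strand). Base
#' counts equal reference-base coverage except at supplied SNP positions,
#' where each sample's coverage is split between alleles according to its
#' diploid dosage.
#'
#' @param reads prepared read tibble.
#' @param genome named [Biostrings::DNAStringSet].
#' @param chrom,start,end region (1-based closed).
#' @param read_len sequenced read length (default 40).
#' @param variants optional tibble `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param genotypes optional tibble `snp_id`, `sample`, `dosage_ref`
#'   (reference-allele count, 0-2).
#' @return pileup tibble `chrom`, `pos`, `A`, `C`, `G`, `T`.
#' @export
reads_pileup <- function(reads, genome, chrom, start, end, read_len = 40L,
                         variants = NULL, genotypes = NULL) {
  rd <- reads[reads$chrom == chrom &
                reads$polya_pos >= start - 400L &
                reads$polya_pos <= end + 400L, , drop = FALSE]
  body_len <- pmax(read_len - rd$n_T, 0L)
  s1 <- if_else(rd$strand == "+", rd$polya_pos - body_len + 1L, rd$polya_pos)
  e1 <- if_else(rd$strand == "+", rd$polya_pos, rd$polya_pos + body_len - 1L)
  s2 <- if_else(rd$strand == "+", rd$mate_pos, rd$mate_pos - read_len + 1L)
  e2 <- if_else(rd$strand == "+", rd$mate_pos + read_len - 1L, rd$mate_pos)
  ir <- IRanges::IRanges(start = c(s1, s2), end = c(e1, e2))
  ir <- ir[IRanges::width(ir) > 0]
  pos <- start:end
  covv <- IRanges::countOverlaps(IRanges::IRanges(pos, pos), ir)
  refs <- s_chars(seq_window(genome, chrom, start, end, "+"))
  out <- tibble(chrom = chrom, pos = pos, A = 0L, C = 0L, G = 0L, T = 0L)
  for (b in c("A", "C", "G", "T")) out[[b]] <- if_else(refs == b, covv, 0L)
  # SNP-aware allele split by per-sample coverage
  if (!is.null(variants) && !is.null(genotypes) && nrow(variants) > 0) {
    vv <- variants[variants$chrom == chrom & variants$pos >= start &
                     variants$pos <= end, , drop = FALSE]
    for (k in seq_len(nrow(vv))) {
      p <- vv$pos[[k]]
      covers <- (s1 <= p & e1 >= p) | (s2 <= p & e2 >= p)
      if (!any(covers)) next
      per_sample <- table(rd$sample[covers])
      gt <- genotypes[genotypes$snp_id == vv$snp_id[[k]], , drop = FALSE]
      nref <- 0
      nalt <- 0
      for (s in names(per_sample)) {
        d <- gt$dosage_ref[match(s, gt$sample)]
        if (is.na(d)) d <- 2L
        nref <- nref + per_sample[[s]] * d / 2
        nalt <- nalt + per_sample[[s]] * (2 - d) / 2
      }
      i <- match(p, out$pos)
      for (b in c("A", "C", "G", "T")) out[[b]][i] <- 0L
      out[[vv$ref[[k]]]][i] <- as.integer(round(nref))
      out[[vv$alt[[k]]]][i] <- as.integer(round(nalt))
    }
  }
  out
}

# count of (optionally optimistic) T's in a character vector of IUPAC codes
t_count <- function(ch, optimistic = FALSE) {
  if (optimistic) sum(ch %in% c("T", "W", "Y", "K")) else sum(ch == "T")
}

#' Scan a 40-nt upstream consensus window for a polyadenylation signal
#'
#' Hexamers are tried in priority (genome-abundance rank) order: the first
#' rank with a match wins, and among several instances of the winning
#' hexamer the one closest to the cleavage site is reported. Ambiguity codes
#' in the consensus match a hexamer base iff the code's base set contains
#' it. With no hexamer match an A-rich stretch is sought
#' ([find_arich()]); failing that the category is `unknown`.
#'
#' @param window transcript-strand consensus string; its last character is
#'   the base immediately 5' of the cleavage site.
#' @param hexamers a [pas_hexamers()] table.
#' @param params [element_params()].
#' @return list: `category` (`canonical`/`variant`/`a_rich`/`unknown`),
#'   `motif`, `offset` (bases between motif 3' end and cleavage site),
#'   `start`, `end` (1-based indices into `window`, `NA` if none).
#' @export
find_pas <- function(window, hexamers = pas_hexamers(), params = element_params()) {
  L <- nchar(window)
  none <- list(category = "unknown", motif = NA_character_,
               offset = NA_integer_, start = NA_integer_, end = NA_integer_)
  if (L < 6L) return(none)
  ch <- s_chars(window)
  for (r in seq_len(nrow(hexamers))) {
    hx <- s_chars(hexamers$hexamer[[r]])
    starts <- integer(0)
    for (i in seq_len(L - 5L)) {
      codes <- ch[i:(i + 5L)]
      if (all(mapply(function(cd, b) {
        set <- IUPAC_SETS[[cd]]
        !is.null(set) && b %in% set
      }, codes, hx))) {
        starts <- c(starts, i)
      }
    }
    if (length(starts) > 0) {
      i <- max(starts) # closest to the cleavage site
      return(list(category = hexamers$category[[r]],
                  motif = hexamers$hexamer[[r]],
                  offset = L - (i + 5L), start = i, end = i + 5L))
    }
  }
  ar <- find_arich(window, params)
  if (!is.null(ar)) {
    return(list(category = "a_rich",
                motif = substr(window, ar[1], ar[2]),
                offset = L - ar[2], start = ar[1], end = ar[2]))
  }
  none
}

#' Find an A-rich surrogate polyadenylation signal
#'
#' Candidate: any 9-bp region of the window containing at least 6 A's; with
#' several candidates the one with the most A's wins (ties to the 5'-most).
#' Boundaries are adjusted: an A at a boundary extends through all
#' consecutive A's; a non-A boundary base is trimmed until the boundary is
#' an A.
#'
#' @param window transcript-strand consensus string.
#' @param params [element_params()].
#' @return integer `c(start, end)` (1-based, inclusive) or `NULL`.
#' @export
find_arich <- function(window, params = element_params()) {
  L <- nchar(window)
  if (L < 9L) return(NULL)
  ch <- s_chars(window)
  a_counts <- vapply(seq_len(L - 8L), function(i) sum(ch[i:(i + 8L)] == "A"), integer(1))
  if (max(a_counts) < 6L) return(NULL)
  i <- which.max(a_counts) # ties: 5'-most
  s <- i
  e <- i + 8L
  # left boundary
  if (ch[s] == "A") {
    while (s > 1L && ch[s - 1L] == "A") s <- s - 1L
  } else {
    while (s <= e && ch[s] != "A") s <- s + 1L
  }
  # right boundary
  if (ch[e] == "A") {
    while (e < L && ch[e + 1L] == "A") e <- e + 1L
  } else {
    while (e >= s && ch[e] != "A") e <- e - 1L
  }
  if (e < s) return(NULL)
  c(s, e)
}

# shared USE/DSE machinery: best 9-mer by T count, then boundary adjustment.
# A boundary starting on a T is greedily extended: if a T lies within the
# adjacent 2 bp, the window grows to the nearest such T (plus intervening
# bases) provided the T proportion stays above `t_frac`; a non-T boundary is
# trimmed inward until it is a T.
adjust_t_window <- function(ch, s, e, t_frac, optimistic) {
  L <- length(ch)
  is_t <- function(i) t_count(ch[i], optimistic) == 1L
  prop <- function(a, b) t_count(ch[a:b], optimistic) / (b - a + 1L)
  if (!is_t(s)) {
    while (s <= e && !is_t(s)) s <- s + 1L
  } else {
    repeat {
      cand <- (s - 1L):(s - 2L)
      cand <- cand[cand >= 1L]
      hit <- cand[vapply(cand, is_t, logical(1))]
      if (length(hit) == 0L) break
      s2 <- max(hit) # nearest T
      if (prop(s2, e) > t_frac) s <- s2 else break
    }
  }
  if (!is_t(e)) {
    while (e >= s && !is_t(e)) e <- e - 1L
  } else {
    repeat {
      cand <- (e + 1L):(e + 2L)
      cand <- cand[cand <= L]
      hit <- cand[vapply(cand, is_t, logical(1))]
      if (length(hit) == 0L) break
      e2 <- min(hit)
      if (prop(s, e2) > t_frac) e <- e2 else break
    }
  }
  if (e < s) NULL else c(s, e)
}

best_t_window <- function(ch, width = 9L, optimistic = FALSE) {
  L <- length(ch)
  if (L < width) return(NULL)
  tc <- vapply(seq_len(L - width + 1L), function(i) {
    t_count(ch[i:(i + width - 1L)], optimistic)
  }, integer(1))
  i <- which.max(tc) # ties: 5'-most
  list(start = i, end = i + width - 1L, t = tc[[i]])
}

#' Find the upstream U-rich element (USE)
#'
#' The candidate is the 9-bp window with the most T's within the 30 nt
#' upstream of the polyadenylation signal; it must hold at least 6 T's
#' including a run of 3 consecutive T's. Boundaries are then adjusted with a
#' T-proportion threshold of 0.65.
#'
#' @param window transcript-strand consensus of the 30 nt upstream of the
#'   signal.
#' @param params [element_params()].
#' @return integer `c(start, end)` into `window`, or `NULL`.
#' @export
find_use <- function(window, params = element_params()) {
  ch <- s_chars(window)
  bw <- best_t_window(ch, 9L, params$optimistic_t)
  if (is.null(bw) || bw$t < 6L) return(NULL)
  run <- rle(vapply(ch[bw$start:bw$end], t_count, integer(1),
                    optimistic = params$optimistic_t) == 1L)
  if (!any(run$values & run$lengths >= 3L)) return(NULL)
  out <- adjust_t_window(ch, bw$start, bw$end, params$use_t_frac, params$optimistic_t)
  if (is.null(out)) return(NULL)
  # re-check thresholds on the adjusted window
  seg <- ch[out[1]:out[2]]
  run2 <- rle(vapply(seg, t_count, integer(1), optimistic = params$optimistic_t) == 1L)
  if (t_count(seg, params$optimistic_t) < 6L ||
        !any(run2$values & run2$lengths >= 3L)) {
    return(NULL)
  }
  out
}

DSE_STRINGS <- c("TTT", "TGTG", "GTGT", "GTCT", "CTGT", "TCTG", "TGTC")

#' Find the downstream U/G-rich element (DSE)
#'
#' The candidate is the 9-bp window with the most T's within the 40 nt
#' downstream of the cleavage site; it must hold at least 5 T's and contain
#' one of TTT, TGTG, GTGT, GTCT, CTGT, TCTG or TGTC. Boundary adjustment as
#' for the USE with a T-proportion threshold of 0.50.
#'
#' @param window transcript-strand consensus of the 40 nt downstream of the
#'   cleavage site.
#' @param params [element_params()].
#' @return integer `c(start, end)` into `window`, or `NULL`.
#' @export
find_dse <- function(window, params = element_params()) {
  ch <- s_chars(window)
  bw <- best_t_window(ch, 9L, params$optimistic_t)
  if (is.null(bw) || bw$t < 5L) return(NULL)
  seg0 <- paste(ch[bw$start:bw$end], collapse = "")
  if (!any(vapply(DSE_STRINGS, function(p) grepl(p, seg0, fixed = TRUE), logical(1)))) {
    return(NULL)
  }
  out <- adjust_t_window(ch, bw$start, bw$end, params$dse_t_frac, params$optimistic_t)
  if (is.null(out)) return(NULL)
  seg <- paste(ch[out[1]:out[2]], collapse = "")
  if (t_count(s_chars(seg), params$optimistic_t) < 5L ||
        !any(vapply(DSE_STRINGS, function(p) grepl(p, seg, fixed = TRUE), logical(1)))) {
    return(NULL)
  }
  out
}

#' Categorise a polyadenylation-signal call
#'
#' @param motif the matched hexamer (or `NA`).
#' @param is_arich whether the call is an A-rich interval.
#' @param hexamers a [pas_hexamers()] table.
#' @return one of `"canonical"`, `"variant"`, `"a_rich"`, `"unknown"`.
#' @export
classify_pas_category <- function(motif, is_arich = FALSE, hexamers = pas_hexamers()) {
  if (isTRUE(is_arich)) return("a_rich")
  if (is.na(motif)) return("unknown")
  i <- match(motif, hexamers$hexamer)
  if (is.na(i)) "unknown" else hexamers$category[[i]]
}

#' Call polyadenylation signals and auxiliary elements for tag clusters
#'
#' For every retained cluster the 40-nt upstream consensus window is scanned
#' for a polyadenylation signal; given a signal, the 30 nt upstream of it are
#' scanned for a USE, and the 40 nt downstream of the cleavage site for a
#' DSE. When `reads` are supplied the windows use the read-backed consensus
#' (reference fallback below 5x coverage); otherwise the reference sequence.
#'
#' @param clusters result of [call_clusters()].
#' @param genome named [Biostrings::DNAStringSet].
#' @param reads optional prepared reads for consensus building.
#' @param variants,genotypes optional SNP table and dosages (see
#'   [reads_pileup()]).
#' @param hexamers a [pas_hexamers()] table.
#' @param params [element_params()].
#' @param read_len read length used for pileup intervals.
#' @return tibble: `cluster_id`, `category`, `motif`, `offset`, genomic
#'   `pas_start`/`pas_end`, `use_start`/`use_end`, `dse_start`/`dse_end`.
#' @export
call_elements <- function(clusters, genome, reads = NULL, variants = NULL,
                          genotypes = NULL, hexamers = pas_hexamers(),
                          params = element_params(), read_len = 40L) {
  cl <- clusters[clusters$retained, , drop = FALSE]
  res <- purrr::pmap(
    list(cl$cluster_id, cl$chrom, cl$strand, cl$polya_pos),
    function(id, chrom, strand, pos) {
      up_ext <- params$pas_window + params$use_window
      lo <- if (strand == "+") pos - up_ext else pos - params$dse_window
      hi <- if (strand == "+") pos + params$dse_window else pos + up_ext
      track <- NULL
      if (!is.null(reads)) {
        pu <- reads_pileup(reads, genome, chrom, max(1L, lo), hi,
                           read_len = read_len, variants = variants,
                           genotypes = genotypes)
        track <- build_consensus(pu, genome, params)
      }
      fetch <- function(a, b) { # transcript-strand consensus of genomic [a,b]
        if (is.null(track)) return(seq_window(genome, chrom, a, b, strand))
        idx <- match(a:b, track$pos)
        bases <- ifelse(is.na(idx), NA, track$base[idx])
        bases[is.na(bases)] <- s_chars(seq_window(genome, chrom, a, b, "+"))[is.na(bases)]
        s <- paste(bases, collapse = "")
        if (strand == "-") rc(s) else s
      }
      # window index (1-based, 5'->3' transcript strand) -> genomic coordinate
      gpos <- function(win_hi_genomic, L, i) {
        if (strand == "+") win_hi_genomic - L + i else win_hi_genomic + L - i
      }
      if (strand == "+") {
        up <- fetch(pos - params$pas_window, pos - 1L)
        up_hi <- pos - 1L
      } else {
        up <- fetch(pos + 1L, pos + params$pas_window)
        up_hi <- pos + 1L
      }
      pas <- find_pas(up, hexamers, params)
      L <- nchar(up)
      pas_g <- c(NA_integer_, NA_integer_)
      use_g <- c(NA_integer_, NA_integer_)
      dse_g <- c(NA_integer_, NA_integer_)
      if (!is.na(pas$start)) {
        pas_g <- sort(c(gpos(up_hi, L, pas$start), gpos(up_hi, L, pas$end)))
        # USE: 30 nt upstream of the signal start (transcript strand)
        pas_start_g <- if (strand == "+") pas_g[1] else pas_g[2]
        if (strand == "+") {
          uw <- fetch(pas_start_g - params$use_window, pas_start_g - 1L)
          uw_hi <- pas_start_g - 1L
        } else {
          uw <- fetch(pas_start_g + 1L, pas_start_g + params$use_window)
          uw_hi <- pas_start_g + 1L
        }
        u <- find_use(uw, params)
        if (!is.null(u)) {
          use_g <- sort(c(gpos(uw_hi, nchar(uw), u[1]), gpos(uw_hi, nchar(uw), u[2])))
        }
      }
      # DSE: 40 nt downstream of the cleavage site (independent of the PAS)
      if (strand == "+") {
        dw <- fetch(pos + 1L, pos + params$dse_window)
        dmap <- function(i) pos + i
      } else {
        dw <- fetch(pos - params$dse_window, pos - 1L)
        dmap <- function(i) pos - i
      }
      d <- find_dse(dw, params)
      if (!is.null(d)) dse_g <- sort(c(dmap(d[1]), dmap(d[2])))
      tibble(
        cluster_id = id, category = pas$category, motif = pas$motif,
        offset = pas$offset,
        pas_start = pas_g[1], pas_end = pas_g[2],
        use_start = use_g[1], use_end = use_g[2],
        dse_start = dse_g[1], dse_end = dse_g[2]
      )
    }
  )
  list_rbind(res)
}
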