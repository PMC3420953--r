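# Independent oracles, coded separately from the package implementations.

# Literal transcription of the peak-finding recursion, written as an explicit
# worklist over per-coordinate count tables (no code shared with
# split_by_peaks). Entry: clusters spanning more than `trigger` bp are
# processed; inside the recursion the span is never re-checked.
oracle_peak_split <- function(positions, trigger = 40, half_window = 40,
                              frac = 0.10, strand = "+") {
  if (length(positions) == 0) {
    return(list())
  }
  positions <- sort(as.integer(positions))
  if ((max(positions) - min(positions)) <= trigger) {
    return(list(positions))
  }
  leaves <- list()
  work <- list(positions)
  while (length(work) > 0) {
    pos <- work[[1]]
    work <- work[-1]
    counts <- integer(0)
    for (p in pos) {
      key <- as.character(p)
      counts[key] <- if (is.na(counts[key])) 1L else counts[key] + 1L
    }
    coords <- as.integer(names(counts))
    max_h <- max(counts)
    best <- coords[counts == max_h]
    pos_m <- if (strand == "+") min(best) else max(best)
    keep <- c()
    for (i in seq_along(coords)) {
      if (coords[i] >= pos_m - half_window && coords[i] <= pos_m + half_window &&
            counts[i] > frac * max_h) {
        keep <- c(keep, coords[i])
      }
    }
    pos_l <- min(keep)
    pos_r <- max(keep)
    left <- pos[pos < pos_l]
    mid <- pos[pos >= pos_l & pos <= pos_r]
    right <- pos[pos > pos_r]
    if ((pos_r - pos_l) <= half_window) {
      leaves[[length(leaves) + 1]] <- mid
    }
    for (cand in list(left, right)) {
      if (length(cand) == 0) next
      cand_counts <- integer(0)
      for (p in cand) {
        key <- as.character(p)
        cand_counts[key] <- if (is.na(cand_counts[key])) 1L else cand_counts[key] + 1L
      }
      # eliminated only when ALL coordinates fall below the threshold
      if (any(cand_counts >= frac * max_h)) {
        work[[length(work) + 1]] <- cand
      }
    }
  }
  leaves[order(sapply(leaves, min))]
}

# Brute-force windowed pattern matcher: per window, per position, checks the
# base against the pattern letter (W = A or T, N = anything); `fixed`
# positions tolerate no mismatch.
oracle_scan <- function(sequence, pattern, max_mm = 0, fixed = integer(0)) {
  k <- nchar(pattern)
  sq <- strsplit(sequence, "")[[1]]
  pt <- strsplit(pattern, "")[[1]]
  hits <- data.frame(start = integer(0), end = integer(0))
  if (length(sq) < k) return(hits)
  for (i in 1:(length(sq) - k + 1)) {
    mm <- 0
    bad_fixed <- FALSE
    for (j in 1:k) {
      base <- sq[i + j - 1]
      ok <- switch(pt[j],
                   W = base %in% c("A", "T"),
                   N = base %in% c("A", "C", "G", "T"),
                   base == pt[j])
      if (!ok) {
        if (j %in% fixed) bad_fixed <- TRUE else mm <- mm + 1
      }
    }
    if (!bad_fixed && mm <= max_mm) {
      hits <- rbind(hits, data.frame(start = i, end = i + k - 1))
    }
  }
  hits
}

random_dna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# single-chromosome genome from a literal string
str_genome <- function(s, name = "chr1") {
  g <- Biostrings::DNAStringSet(s)
  names(g) <- name
  g
}

# minimal cluster tibble row for filter-level tests
fake_cluster <- function(chrom = "chr1", strand = "+", polya_pos,
                         positions = polya_pos, mate_positions = polya_pos - 100L,
                         counts = NULL) {
  tibble::tibble(
    cluster_id = "TC00001", chrom = chrom, strand = strand,
    span_start = min(positions), span_end = max(positions),
    polya_pos = polya_pos, n_reads = length(positions),
    precision_polya = precision(positions),
    precision_mate = precision(mate_positions),
    counts = list(counts), positions = list(positions),
    mate_positions = list(mate_positions), retained = TRUE
  )
}

# bulk brute-force scanner: per sequence, builds the explicit window matrix
# and counts positionwise disagreements row by row (used where many
# sequences are checked; oracle_scan above stays the literal per-window
# loop)
oracle_scan_bulk <- function(sequence, pattern, max_mm = 0, fixed = integer(0)) {
  k <- nchar(pattern)
  sq <- strsplit(sequence, "")[[1]]
  pt <- strsplit(pattern, "")[[1]]
  n <- length(sq) - k + 1
  if (n < 1) return(integer(0))
  W <- matrix(sq[outer(seq_len(n) - 1, seq_len(k), "+")], n, k)
  bad <- matrix(FALSE, n, k)
  for (j in seq_len(k)) {
    allowed <- switch(pt[j], W = c("A", "T"), N = c("A", "C", "G", "T"), pt[j])
    bad[, j] <- !(W[, j] %in% allowed)
  }
  free <- setdiff(seq_len(k), fixed)
  hit <- rowSums(bad[, free, drop = FALSE]) <= max_mm &
    rowSums(bad[, fixed, drop = FALSE]) == 0
  which(hit)
}

# the hand-built 12-read fixture exercising every filter (3 samples x 2
# replicates; plus-strand coordinates throughout)
filter_fixture <- function() {
  chars <- rep("C", 700)
  chars[301:312] <- "A" # internal-priming A-run behind cluster B
  chars[651:662] <- "A" # genomic tail trap for the rejected read
  genome <- str_genome(paste(chars, collapse = ""))
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:12),
    chrom = "chr1",
    polya_pos = c(90L, 650L, 100L, 101L, 101L, 300L, 300L, 400L, 410L,
                  600L, 600L, 600L),
    mate_pos = c(90L, 550L, 20L, 30L, 40L, 200L, 210L, 250L, 250L,
                 450L, 460L, 470L),
    n_T = c(10L, 10L, 10L, 10L, 10L, 16L, 16L, 10L, 10L, 10L, 10L, 10L),
    sample = c("S01", "S01", "S01", "S01", "S02", "S01", "S02", "S01", "S03",
               "S01", "S01", "S02"),
    replicate = c("R1", "R1", "R1", "R2", "R1", "R1", "R2", "R1", "R2",
                  "R1", "R1", "R1")
  )
  list(genome = genome, reads = reads,
       params = peak_params(min_count = 3, grey_zone = c(3, 4)))
}
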