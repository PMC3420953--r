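#' Configuration for the synthetic 3'-end RNA-seq study
#'
#' The defaults emulate the study design: six diploid individuals with two
#' biological replicates each, ~300 pooled reads per gene, cleavage jitter
#' of 3 bp (keeping ~99% of reads within +/-8 bp of the true site, matching
#' tag clusters that mostly span under 24 bp), a minor-allele frequency of
#' 0.25 so six samples usually segregate, and 40-bp paired-end reads.
#'
#' @param n_genes number of genes.
#' @param genome_len optional genome length (bp); default sized to fit the
#'   gene cassettes; too small a value is an error.
#' @param n_samples number of individuals (>= 3).
#' @param n_replicates replicates per individual (>= 2).
#' @param class_mix named proportions over APA classes `I`, `II`, `III`
#'   (must sum to 1).
#' @param reads_per_gene_mean mean pooled genuine read count per gene.
#' @param cleavage_jitter_sd SD (bp) of the rounded-Normal cleavage jitter.
#' @param frac_misprimed fraction of genes carrying an internal-priming
#'   locus (a genomic A-run) emitting misprimed reads.
#' @param frac_pcr_dup_clusters fraction of genes carrying a planted
#'   PCR-duplicate read cluster (heterogeneous polyA positions, one shared
#'   mate position).
#' @param h2_grid target intraclass correlations cycled over genes.
#' @param pas_variant_effect multiplicative expression effect of the weak
#'   polyadenylation-signal allele (homozygous weak = this factor times the
#'   strong homozygote).
#' @param maf minor-allele frequency for simulated genotypes.
#' @param read_len sequenced read length (bp).
#' @param pas_mix proportions of planted signal categories over
#'   `canonical`, `variant`, `a_rich`, `none`.
#' @param frac_pas_snp fraction of canonical-signal genes carrying a
#'   signal-disrupting SNP with `pas_variant_effect`.
#' @param n_neutral_snps neutral 3' UTR SNPs planted per gene.
#' @param plant_are,plant_gre,plant_puf per-slot probabilities of planting
#'   ARE/GRE/PUF destabilising motifs in the 3' UTR (class II genes have
#'   separate shared-region and differential-region slots).
#' @param seed integer seed; fully determines all outputs.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 50L, genome_len = NULL, n_samples = 6L,
                       n_replicates = 2L,
                       class_mix = c(I = 0.4, II = 0.4, III = 0.2),
                       reads_per_gene_mean = 300, cleavage_jitter_sd = 3,
                       frac_misprimed = 0.1, frac_pcr_dup_clusters = 0.1,
                       h2_grid = c(0, 0.3, 0.6, 0.9),
                       pas_variant_effect = 0.5, maf = 0.25, read_len = 40L,
                       pas_mix = c(canonical = 0.7, variant = 0.15,
                                   a_rich = 0.1, none = 0.05),
                       frac_pas_snp = 0.3, n_neutral_snps = 2L,
                       plant_are = 0.6, plant_gre = 0.4, plant_puf = 0.4,
                       seed = 1L) {
  stopifnot(
    n_genes >= 1, n_samples >= 3, n_replicates >= 2,
    all(class_mix >= 0), all(class_mix <= 1),
    abs(sum(class_mix) - 1) < 1e-8,
    all(names(class_mix) %in% c("I", "II", "III")),
    frac_misprimed >= 0, frac_misprimed <= 1,
    frac_pcr_dup_clusters >= 0, frac_pcr_dup_clusters <= 1,
    pas_variant_effect > 0, maf > 0, maf < 1,
    abs(sum(pas_mix) - 1) < 1e-8,
    is.numeric(seed), seed == round(seed)
  )
  structure(
    list(
      n_genes = as.integer(n_genes), genome_len = genome_len,
      n_samples = as.integer(n_samples),
      n_replicates = as.integer(n_replicates),
      class_mix = class_mix, reads_per_gene_mean = reads_per_gene_mean,
      cleavage_jitter_sd = cleavage_jitter_sd,
      frac_misprimed = frac_misprimed,
      frac_pcr_dup_clusters = frac_pcr_dup_clusters,
      h2_grid = h2_grid, pas_variant_effect = pas_variant_effect,
      maf = maf, read_len = as.integer(read_len), pas_mix = pas_mix,
      frac_pas_snp = frac_pas_snp, n_neutral_snps = as.integer(n_neutral_snps),
      plant_are = plant_are, plant_gre = plant_gre, plant_puf = plant_puf,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# cassette geometry (transcript-strand coordinates within one gene block)
CASSETTE <- list(
  block = 1300L, pad = 100L, tx_len = 1100L,
  tx_start = 51L, cds_start = 51L, cds_end = 450L, utr3_start = 451L,
  site_I = 750L, site_II = c(650L, 850L), site_III = c(580L, 860L),
  utr3_end_III_A = 600L,
  mis_anchor = 480L, mis_run_len = 12L, dup_center = 530L, dup_half = 8L
)

rand_dna <- function(n, probs = c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# plant the PAS (and USE for hexamer categories) upstream of a site in the
# cassette character vector; returns the modified vector plus truth fields.
plant_site_elements <- function(cas, site, category, hexamers,
                                force_motif = NULL) {
  win_lo <- site - 40L
  hex_start <- site - 26L # hexamer occupies site-26 .. site-21 (offset 20)
  for (try in 1:200) {
    cas[win_lo:(site - 1L)] <- rand_dna(40L)
    motif <- NA_character_
    if (category %in% c("canonical", "variant")) {
      pool <- hexamers$hexamer[hexamers$category == category]
      motif <- force_motif %||% sample(pool, 1L)
      cas[hex_start:(hex_start + 5L)] <- s_chars(motif)
      # USE 12-20 bp upstream of the signal
      cas[(hex_start - 20L):(hex_start - 12L)] <- s_chars("TTTTTTCTT")
    } else if (category == "a_rich") {
      cas[(site - 27L):(site - 21L)] <- "A"
      cas[site - 28L] <- sample(c("C", "T"), 1L)
      cas[site - 20L] <- sample(c("C", "T"), 1L)
      motif <- strrep("A", 7L)
    }
    win <- paste(cas[win_lo:(site - 1L)], collapse = "")
    call <- find_pas(win, hexamers)
    ok <- switch(category,
      canonical = , variant = identical(call$category, category) &&
        identical(call$motif, motif) && call$offset == 20L,
      a_rich = identical(call$category, "a_rich"),
      none = identical(call$category, "unknown")
    )
    if (ok) {
      return(list(cas = cas, motif = motif))
    }
  }
  stop("failed to sanitise a PAS window (should not happen)")
}

#' Generate the synthetic genome, annotation and ground truth
#'
#' Lays one gene cassette per gene along a single chromosome (alternating
#' strands), plants cleavage sites according to the APA class mix (class II:
#' two sites 200 bp apart in one 3' UTR; class III: sites in the 3' UTRs of
#' two transcript isoforms), polyadenylation signals 21 bp upstream of each
#' site (sanitised windows so the planted category is unambiguous), USE/DSE
#' auxiliary elements, internal-priming A-runs, PCR-duplicate loci, and
#' 3' UTR SNPs (signal-disrupting and neutral) with diploid genotypes.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [Biostrings::DNAStringSet]), `annotation`
#'   (transcript tibble) and `truth` (list of tibbles: `genes`, `sites`,
#'   `misprime_loci`, `dup_loci`, `variants`, `genotypes`, `elements`).
#' @export
generate_genome_annotation <- function(config = sim_config()) {
  set.seed(config$seed)
  K <- CASSETTE
  n <- config$n_genes
  need_len <- n * K$block + 200L
  if (!is.null(config$genome_len) && config$genome_len < need_len) {
    stop("genome too short to place ", n, " genes: need at least ", need_len, " bp")
  }
  glen <- max(config$genome_len %||% need_len, need_len)
  hex <- pas_hexamers()

  # largest-remainder class allocation, then shuffled over genes
  mix <- config$class_mix[c("I", "II", "III")]
  mix[is.na(mix)] <- 0
  names(mix) <- c("I", "II", "III")
  cnt <- floor(mix * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(-(mix * n - cnt))
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  classes <- sample(rep(names(cnt), cnt))
  strands <- rep(c("+", "-"), length.out = n)
  h2s <- rep(config$h2_grid, length.out = n)
  samples <- sprintf("S%02d", seq_len(config$n_samples))

  chrom_chars <- rand_dna(glen)
  genes <- list(); sites <- list(); mis <- list(); dup <- list()
  ann <- list(); variants <- list(); genos <- list(); elements <- list()
  snp_k <- 0L

  for (k in seq_len(n)) {
    gene_id <- sprintf("G%03d", k)
    cls <- classes[[k]]
    strand <- strands[[k]]
    offset <- (k - 1L) * K$block
    t2g <- function(t) {
      if (strand == "+") offset + K$pad + t else offset + K$pad + (K$tx_len + 1L - t)
    }
    cas <- rand_dna(K$tx_len)

    site_t <- switch(cls, I = K$site_I, II = K$site_II, III = K$site_III)
    cats <- sample(names(config$pas_mix), length(site_t), replace = TRUE,
                   prob = config$pas_mix)
    usage <- switch(cls, I = 1, II = c(0.4, 0.6), III = c(0.5, 0.5))
    # a signal-disrupting SNP needs an AATAAA site so the weak allele is the
    # AATACA variant; decide before planting
    wants_pas_snp <- runif(1) < config$frac_pas_snp
    pas_snp_site <- if (wants_pas_snp && any(cats == "canonical")) {
      which(cats == "canonical")[[1]]
    } else {
      0L
    }
    motifs <- character(length(site_t))
    for (si in seq_along(site_t)) {
      pl <- plant_site_elements(cas, site_t[[si]], cats[[si]], hex,
                                force_motif = if (si == pas_snp_site) "AATAAA")
      cas <- pl$cas
      motifs[[si]] <- pl$motif
      # DSE downstream of the site
      cas[(site_t[[si]] + 5L):(site_t[[si]] + 13L)] <- s_chars("TGTGTTTGT")
      # keep the 20 bp downstream A-poor so genuine sites never look misprimed
      down <- (site_t[[si]] + 1L):(site_t[[si]] + 4L)
      cas[down][cas[down] == "A"] <- "C"
      dd <- (site_t[[si]] + 14L):(site_t[[si]] + 22L)
      cas[dd][cas[dd] == "A"] <- "G"
    }

    # destabilising-motif slots, chosen clear of signal/USE/DSE windows and
    # of the mispriming and duplicate loci
    motif_slots <- switch(cls,
      I = list(c("ARE", 560L, "utr"), c("GRE", 595L, "utr"),
               c("PUF", 620L, "utr")),
      II = list(c("ARE", 560L, "shared"), c("GRE", 590L, "shared"),
                c("PUF", 541L, "shared"), c("ARE", 745L, "differential"),
                c("GRE", 770L, "differential"),
                c("PUF", 725L, "differential")),
      III = list(c("ARE", 640L, "utr"), c("GRE", 670L, "utr"),
                 c("PUF", 700L, "utr"))
    )
    motif_seq <- c(ARE = "TTTTATTTATTTT", GRE = "TGTTTGTTTGT",
                   PUF = "TGTAAATA")
    motif_occupied <- integer(0)
    for (slot in motif_slots) {
      pr_plant <- switch(slot[[1]], ARE = config$plant_are,
                         GRE = config$plant_gre, PUF = config$plant_puf)
      if (runif(1) >= pr_plant) next
      seq_ <- motif_seq[[slot[[1]]]]
      at <- as.integer(slot[[2]])
      cas[at:(at + nchar(seq_) - 1L)] <- s_chars(seq_)
      motif_occupied <- c(motif_occupied, at:(at + nchar(seq_) - 1L))
      giv <- sort(c(t2g(at), t2g(at + nchar(seq_) - 1L)))
      elements[[length(elements) + 1L]] <- tibble(
        gene_id = gene_id, motif_type = slot[[1]], chrom = "chr1",
        strand = strand, start = giv[1], end = giv[2], region = slot[[3]]
      )
    }

    has_mis <- runif(1) < config$frac_misprimed
    if (has_mis) {
      run <- (K$mis_anchor + 1L):(K$mis_anchor + K$mis_run_len)
      cas[run] <- "A"
      cas[K$mis_anchor] <- sample(c("C", "G", "T"), 1L)
      cas[max(run) + 1L] <- sample(c("C", "G", "T"), 1L)
      mis[[length(mis) + 1L]] <- tibble(
        gene_id = gene_id, chrom = "chr1", strand = strand,
        anchor_pos = t2g(K$mis_anchor),
        run_start = t2g(run[1]), run_end = t2g(run[length(run)]),
        run_len = K$mis_run_len
      )
    }
    has_dup <- runif(1) < config$frac_pcr_dup_clusters
    if (has_dup) {
      dup[[length(dup) + 1L]] <- tibble(
        gene_id = gene_id, chrom = "chr1", strand = strand,
        center_pos = t2g(K$dup_center), half_spread = K$dup_half
      )
    }

    # transcripts and annotation
    # annotated 3' UTRs extend 5 bp past the planted end so that cleavage
    # heterogeneity around the site stays inside the annotation
    if (cls == "III") {
      tx <- tibble(
        transcript_id = paste0(gene_id, c(".A", ".B")), gene_id = gene_id,
        utr3_end_t = c(K$utr3_end_III_A, site_t[[2]] + 5L),
        end3_t = c(site_t[[1]], site_t[[2]])
      )
    } else {
      tx <- tibble(
        transcript_id = paste0(gene_id, ".A"), gene_id = gene_id,
        utr3_end_t = site_t[[length(site_t)]] + 5L,
        end3_t = site_t[[length(site_t)]]
      )
    }
    for (j in seq_len(nrow(tx))) {
      gcoords <- sort(c(t2g(K$tx_start), t2g(tx$utr3_end_t[[j]])))
      u3 <- sort(c(t2g(K$utr3_start), t2g(tx$utr3_end_t[[j]])))
      cds <- sort(c(t2g(K$cds_start), t2g(K$cds_end)))
      ann[[length(ann) + 1L]] <- tibble(
        transcript_id = tx$transcript_id[[j]], gene_id = gene_id,
        chrom = "chr1", strand = strand,
        tx_start = gcoords[1], tx_end = gcoords[2],
        cds_start = cds[1], cds_end = cds[2],
        utr3_start = u3[1], utr3_end = u3[2],
        end3 = t2g(tx$end3_t[[j]])
      )
    }

    # SNPs: one signal-disrupting SNP on canonical sites (some genes), plus
    # neutral UTR SNPs away from planted elements
    gene_has_pas_snp <- FALSE
    if (pas_snp_site > 0L) {
      si <- pas_snp_site
      hex_start <- site_t[[si]] - 26L
      # weak allele hits the 4th or 5th hexamer base: AATAAA -> AATCAA (no
      # signal, strength 0) or AATACA (variant, strength 0.5), spreading the
      # allelic strength differences
      pos_t <- hex_start + sample(c(3L, 4L), 1L)
      weak_t <- "C"
      ref_t <- cas[pos_t]
      snp_k <- snp_k + 1L
      gpos <- t2g(pos_t)
      ref_g <- if (strand == "+") ref_t else rc(ref_t)
      alt_g <- if (strand == "+") weak_t else rc(weak_t)
      variants[[length(variants) + 1L]] <- tibble(
        snp_id = sprintf("snp%04d", snp_k), gene_id = gene_id, chrom = "chr1",
        pos = gpos, ref = ref_g, alt = alt_g, effect = "pas_weak",
        effect_size = config$pas_variant_effect
      )
      gene_has_pas_snp <- TRUE
    }
    occupied <- unique(c(unlist(lapply(site_t, function(s) (s - 60L):(s + 25L))),
                         motif_occupied))
    utr_span <- (K$utr3_start):(max(site_t))
    free <- setdiff(utr_span, c(occupied,
                                if (has_mis) (K$mis_anchor - 2L):(K$mis_anchor + K$mis_run_len + 2L),
                                if (has_dup) (K$dup_center - 12L):(K$dup_center + 12L)))
    if (config$n_neutral_snps > 0 && length(free) >= config$n_neutral_snps) {
      for (pos_t in sample(free, config$n_neutral_snps)) {
        snp_k <- snp_k + 1L
        ref_t <- cas[pos_t]
        alt_t <- sample(setdiff(c("A", "C", "G", "T"), ref_t), 1L)
        variants[[length(variants) + 1L]] <- tibble(
          snp_id = sprintf("snp%04d", snp_k), gene_id = gene_id, chrom = "chr1",
          pos = t2g(pos_t),
          ref = if (strand == "+") ref_t else rc(ref_t),
          alt = if (strand == "+") alt_t else rc(alt_t),
          effect = "neutral", effect_size = 1
        )
      }
    }

    genes[[length(genes) + 1L]] <- tibble(
      gene_id = gene_id, chrom = "chr1", strand = strand, apa_class = cls,
      h2_target = h2s[[k]], has_misprime = has_mis, has_dup = has_dup,
      has_pas_snp = gene_has_pas_snp, offset = offset
    )
    for (si in seq_along(site_t)) {
      sites[[length(sites) + 1L]] <- tibble(
        gene_id = gene_id, site_id = paste0(gene_id, ".s", si),
        chrom = "chr1", strand = strand, pos = t2g(site_t[[si]]),
        apa_class = cls, pas_category = cats[[si]], pas_motif = motifs[[si]],
        usage = usage[[si]],
        rank = si # proximal -> distal
      )
    }

    # write cassette into the chromosome (transcript strand -> genomic)
    gidx <- vapply(seq_len(K$tx_len), t2g, integer(1))
    gchars <- if (strand == "+") cas else s_chars(rc(paste(cas, collapse = "")))
    chrom_chars[sort(gidx)] <- gchars # rc() already reads in ascending genomic order
  }

  variants <- if (length(variants)) list_rbind(variants) else
    tibble(snp_id = character(), gene_id = character(), chrom = character(),
           pos = integer(), ref = character(), alt = character(),
           effect = character(), effect_size = numeric())
  # diploid genotypes at minor-allele frequency maf (alt = minor by intent)
  if (nrow(variants) > 0) {
    genos <- tidyr::expand_grid(snp_id = variants$snp_id, sample = samples) |>
      mutate(
        dosage_alt = rbinom(dplyr::n(), 2L, config$maf),
        dosage_ref = 2L - .data$dosage_alt
      )
  } else {
    genos <- tibble(snp_id = character(), sample = character(),
                    dosage_alt = integer(), dosage_ref = integer())
  }

  genome <- Biostrings::DNAStringSet(paste(chrom_chars, collapse = ""))
  names(genome) <- "chr1"
  list(
    genome = genome,
    annotation = list_rbind(ann),
    truth = list(
      genes = list_rbind(genes),
      sites = list_rbind(sites),
      misprime_loci = if (length(mis)) list_rbind(mis) else
        tibble(gene_id = character(), chrom = character(), strand = character(),
               anchor_pos = integer(), run_start = integer(),
               run_end = integer(), run_len = integer()),
      dup_loci = if (length(dup)) list_rbind(dup) else
        tibble(gene_id = character(), chrom = character(), strand = character(),
               center_pos = integer(), half_spread = integer()),
      variants = variants,
      genotypes = genos,
      elements = if (length(elements)) list_rbind(elements) else
        tibble(gene_id = character(), motif_type = character(),
               chrom = character(), strand = character(), start = integer(),
               end = integer(), region = character())
    ),
    config = config
  )
}

#' Simulate 3'-end read sets with per-read truth labels
#'
#' Genuine reads jitter around the planted cleavage sites (rounded Normal),
#' with mate positions 80-250 bp upstream on the transcript strand; per-gene
#' per-library counts are Poisson with lognormal genotype/replicate effects
#' delivering the target intraclass correlations, and the weak
#' polyadenylation-signal allele scales expression by
#' `pas_variant_effect^(dosage/2)`. Misprimed reads anchor immediately 5' of
#' planted genomic A-runs; PCR-duplicate clusters emit heterogeneous polyA
#' positions sharing a single mate position. Tail lengths are drawn 8-20 nt
#' and tail mismatches computed honestly against the genome.
#'
#' @param sim result of [generate_genome_annotation()].
#' @param config a [sim_config()]; defaults to the one stored in `sim`.
#' @return tibble of reads: `read_id`, `chrom`, `strand`, `polya_pos`,
#'   `mate_pos`, `n_T`, `tail_mismatches`, `sample`, `replicate`,
#'   `truth_label` (`genuine`/`misprimed`/`pcr_dup`), `true_site`,
#'   `gene_id`.
#' @export
simulate_reads <- function(sim, config = sim$config) {
  set.seed(config$seed + 1L)
  truth <- sim$truth
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  reps <- sprintf("R%d", seq_len(config$n_replicates))
  n_lib <- length(samples) * length(reps)
  sigma2 <- 0.09 # total log-scale variance of expression effects

  out <- list()
  for (k in seq_len(nrow(truth$genes))) {
    g <- truth$genes[k, ]
    gsites <- truth$sites[truth$sites$gene_id == g$gene_id, , drop = FALSE]
    strand <- g$strand
    h2 <- g$h2_target
    gi <- rnorm(length(samples), 0, sqrt(h2 * sigma2))
    # weak-allele multiplier per sample
    mult <- rep(1, length(samples))
    if (g$has_pas_snp) {
      v <- truth$variants[truth$variants$gene_id == g$gene_id &
                            truth$variants$effect == "pas_weak", ][1, ]
      gt <- truth$genotypes[truth$genotypes$snp_id == v$snp_id, ]
      w <- gt$dosage_alt[match(samples, gt$sample)]
      mult <- config$pas_variant_effect^(w / 2)
    }
    base <- config$reads_per_gene_mean / n_lib
    for (s in seq_along(samples)) {
      for (r in seq_along(reps)) {
        eij <- rnorm(1, 0, sqrt((1 - h2) * sigma2))
        lam <- base * mult[[s]] * exp(gi[[s]] + eij)
        n_gene <- rpois(1, lam)
        if (n_gene > 0) {
          si <- sample(seq_len(nrow(gsites)), n_gene, replace = TRUE,
                       prob = gsites$usage)
          jit <- as.integer(round(rnorm(n_gene, 0, config$cleavage_jitter_sd)))
          pos <- gsites$pos[si] + if (strand == "+") jit else -jit
          d <- as.integer(floor(runif(n_gene, 80, 251)))
          mate <- if (strand == "+") pos - d else pos + d
          out[[length(out) + 1L]] <- tibble(
            chrom = g$chrom, strand = strand, polya_pos = pos,
            mate_pos = mate,
            n_T = sample(8:20, n_gene, replace = TRUE),
            sample = samples[[s]], replicate = reps[[r]],
            truth_label = "genuine", true_site = gsites$site_id[si],
            gene_id = g$gene_id
          )
        }
        if (g$has_misprime) {
          ml <- truth$misprime_loci[truth$misprime_loci$gene_id == g$gene_id, ][1, ]
          n_mis <- rpois(1, 0.3 * base)
          if (n_mis > 0) {
            d <- as.integer(floor(runif(n_mis, 80, 251)))
            mmate <- if (strand == "+") ml$anchor_pos - d else ml$anchor_pos + d
            out[[length(out) + 1L]] <- tibble(
              chrom = g$chrom, strand = strand,
              polya_pos = rep(ml$anchor_pos, n_mis),
              mate_pos = mmate,
              n_T = sample(8:20, n_mis, replace = TRUE),
              sample = samples[[s]], replicate = reps[[r]],
              truth_label = "misprimed", true_site = NA_character_,
              gene_id = g$gene_id
            )
          }
        }
        if (g$has_dup) {
          dl <- truth$dup_loci[truth$dup_loci$gene_id == g$gene_id, ][1, ]
          n_dup <- rpois(1, 0.25 * base)
          if (n_dup > 0) {
            spread <- sample(-dl$half_spread:dl$half_spread, n_dup, replace = TRUE)
            dmate <- dl$center_pos + if (strand == "+") -150L else 150L
            out[[length(out) + 1L]] <- tibble(
              chrom = g$chrom, strand = strand,
              polya_pos = dl$center_pos + spread,
              mate_pos = rep(dmate, n_dup),
              n_T = sample(8:20, n_dup, replace = TRUE),
              sample = samples[[s]], replicate = reps[[r]],
              truth_label = "pcr_dup", true_site = NA_character_,
              gene_id = g$gene_id
            )
          }
        }
      }
    }
  }
  reads <- list_rbind(out) |>
    mutate(read_id = sprintf("read%06d", row_number()), .before = 1)
  reads$tail_mismatches <- tail_mismatches(reads, sim$genome)
  reads
}

#' Run the full synthetic study generator
#'
#' @param config a [sim_config()].
#' @return the [generate_genome_annotation()] result with a `reads` element
#'   appended.
#' @export
simulate_apa_study <- function(config = sim_config()) {
  sim <- generate_genome_annotation(config)
  sim$reads <- simulate_reads(sim, config)
  sim
}
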