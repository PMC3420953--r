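---
title: "Methods: tag clusters, 3' processing elements, and the genetics of polyA-site usage"
author: "apatag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag clusters, 3' processing elements, and the genetics of polyA-site usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apatag)
```

apatag analyses 3'-end RNA-seq: a protocol in which poly(A)-selected RNA
fragments are reverse-transcribed from an anchored oligo-dT primer, so that
one mate of each read pair begins with the reverse-complemented poly(A)
tail. After trimming, the genomic base adjacent to the tail marks the
position at which the nascent transcript was cleaved and polyadenylated.
Collections of such positions define *tag clusters* — candidate transcript
3' ends — and comparing cluster usage and expression across replicated
individuals lets one ask how heritable 3'-end choice is and which 3' UTR
sequence variants move expression. This vignette describes the models and
rules the package implements, the choices made where the procedure was
genuinely open, and what the synthetic-data tests do and do not establish.

## From raw read pairs to cleavage positions

`trim_and_classify()` removes consecutive leading T's from whichever mate
carries them and records the run length `n_T`. Pairs whose run exceeds 20 nt
(likely oligo-dT artefacts) or where neither mate has a leading T stretch
are rejected. The minimum run that counts as "a stretch" is 1 nt by default
and configurable, since shorter anchors carry less evidence but the
protocol itself does not dictate a cutoff.

Because oligo-dT can also prime internally on genomically encoded A-rich
stretches, the trimmed tail must be checked against the genome:
`validate_tail()` compares the `n_T` claimed-tail bases with the genomic
sequence immediately downstream (transcript strand) of the cleavage
position and keeps the read only if more than 2 bases disagree. A tail that
matches the genome is genomically templated, not evidence of
polyadenylation. `N` bases and positions beyond the chromosome end count as
mismatches: both reduce evidence that the tail is templated, which errs
toward keeping reads and letting the cluster-level filters decide.

Transcript strand follows from coordinate order (`infer_strand()`): a
poly-T tract mapping 5' of its mate means the read came from the minus
strand, and vice versa. Equal coordinates (a zero-length insert) leave the
rule undefined and the pair is rejected.

## Tag clusters

Reads from all samples and replicates are pooled before clustering — the
cluster definition should not depend on which library a read came from.
Sorted cleavage positions are grouped greedily (`group_by_gap()`): a
position more than `max_gap = 15` bp beyond the previous one starts a new
cluster.

Gap clustering chains overlapping peaks, so clusters whose positions span
more than `span_trigger = 40` bp are re-examined by a recursive peak finder
(`split_by_peaks()`): find the coordinate with the greatest read count
(`posM`; ties go to the 5'-most coordinate on the transcript strand, a
deterministic and configurable choice), keep coordinates within 40 bp of it
whose counts exceed 10% of the peak height, and use the extreme kept
coordinates `posL`/`posR` to split reads into left, middle and right
candidates. The middle is a finished cluster unless it is wider than 40 bp
(then it is discarded as dispersed, no-peak structure); a side candidate
whose coordinates all fall below 10% of the *parent's* peak height is
discarded, otherwise the procedure recurses on it starting from the argmax
step. Two readings deserve a note. First, the elimination threshold must
refer to the parent's peak height: a candidate's own maximum always exceeds
10% of itself, so the self-referential reading could never trigger.
Second, the span trigger guards only the initial entry; recursive calls
re-enter at the argmax step, otherwise a 40-bp-wide side candidate
containing only noise positions could never shed them. The package carries
an independently coded transcription of the same recursion in its test
suite and verifies identity on thousands of random read sets.

A cluster's reported polyA position is the median member position, with the
lower middle member taken for even counts so the position is always an
observed cleavage coordinate.

### Cluster-level filters

Three filters flag artefact clusters; all are evaluated independently, and
a cluster is *retained* only when no flag is set. The per-reason tallies
are logged so record counts reconcile at every stage.

* **Internal priming** (`filter_internal_priming()`): flag when the
  `a_window = 20` genomic bases immediately downstream of the polyA
  position contain at least `a_run = 10` A's in the transcript-strand
  sense. The count is of total A's in the window; an alternative reading
  (a consecutive run of 10) is available as `a_run_consecutive = TRUE`.
* **PCR duplication / false mapping** (`filter_duplication()`): genuine 3'
  ends give cleavage positions *less* heterogeneous than the opposite mate
  positions, which arise from random fragmentation. The comparison uses the
  concentration index `precision(x) = sum_i (n_i/N)^2` over positions —
  1 when all reads agree, small when scattered — and keeps the cluster only
  if the polyA precision strictly exceeds the mate precision. The exact
  functional form of this statistic was an open choice; the concentration
  (Simpson) index was selected because it is bounded in (0, 1], increases
  with tightness, and needs no tuning. Ties fail the strict inequality.
* **Abundance** (`filter_abundance()`): clusters with fewer than
  `min_count = 50` pooled reads are flagged; clusters with 50–100 reads
  must additionally show a between-replicate Pearson correlation of at
  least 0.5 in absolute value across the samples (an undefined correlation
  from a zero-variance replicate vector also flags — a cluster whose
  reproducibility cannot be assessed is not kept on count alone).

## Consensus sequences and 3' processing elements

Motif calls near cleavage sites use a read-backed consensus
(`build_consensus()`): at coverage ≥ 5 the most frequent read base wins,
and a second base exceeding 20% of coverage turns the call into the
two-base IUPAC code; below 5x the reference base is used and flagged. The
blended track (consensus where covered, reference elsewhere) is also what
the A-rich search runs on, with the fallback recorded per position.

`find_pas()` scans the 40-nt window upstream of the cleavage position
(positions −40…−1 on the transcript strand; the hexamer must lie wholly
inside) against a ranked hexamer table: AATAAA and ATTAAA (canonical), then
ten variants ranked by genome abundance (`pas_hexamers()`; the table ships
as data and is replaceable). Rank beats proximity — the first rank with any
match wins — and among instances of the winning hexamer the one closest to
the cleavage site is reported. Ambiguity codes match a hexamer base when
the code's base set contains it. With no hexamer, `find_arich()` looks for
a 9-bp region with at least 6 A's (most A's wins, ties 5'-most), extending
boundary A's through their full run and trimming non-A boundaries; failing
that the cluster has no identifiable signal (`unknown`).

The auxiliary elements follow the same shape: `find_use()` takes the 9-bp
window with the most T's within 30 nt upstream of the signal and requires
≥ 6 T's including a TTT run; `find_dse()` takes the best 9-bp window within
40 nt downstream of the cleavage site and requires ≥ 5 T's plus one of
TTT/TGTG/GTGT/GTCT/CTGT/TCTG/TGTC. Both adjust boundaries: a non-T boundary
is trimmed inward; a T boundary is extended greedily — if another T lies
within 2 bp, the window grows to the nearest such T (plus intervening
bases) as long as the T proportion stays above 0.65 (USE) or 0.50 (DSE).
The prose rule "extended if there was a T in the adjacent 2 bp" is
iterative but does not pin down termination; the greedy loop with a
proportion re-check after each step is this package's reading, and the
adjusted window is re-validated against the original thresholds. In
T-counting, ambiguity codes containing T (W/Y/K) are by default *not*
counted as T; `optimistic_t = TRUE` switches to the permissive reading.
Ties between equal-T-count windows go to the 5'-most window.

## APA classes and 3' UTR regions

Clusters are assigned to transcripts by `match_annotation()`: among
same-strand transcripts whose span overlaps the cluster, the one whose
annotated 3' end is nearest the cluster's polyA position wins, with ties
broken by exon overlap. Per gene, only the two most expressed clusters
(pooled counts; ties resolved toward the 5'-most) enter classification:

* **class I** — one cluster, inside the annotated 3' UTR;
* **class II** — two clusters in the same transcript's 3' UTR
  (alternative polyadenylation within one UTR);
* **class III** — a cluster in coding sequence or intron, or two clusters
  belonging to different transcript isoforms;
* **class III-S** — a single cluster outside any annotated 3' UTR.

For class II genes the 3' UTR splits at the proximal cleavage site into the
*shared* region (present in both transcript forms) and the *differential*
region (present only in the long form), computed in transcript orientation
and reported in genomic coordinates. The degenerate case (proximal equals
distal) is flagged rather than silently producing an empty region, since
such clusters should have been merged upstream. For class III genes with a
coding-region cluster these regions are undefined and left missing. The
dominant form of a class II gene is the one with greater mean normalised
expression across cell lines; exact ties go to the long form, consistent
with the genome-wide dominance of distal sites.

## Destabilising motifs and population conservation

ARE (`WWWTATTTATTTW`, one mismatch allowed outside the exact ATTTA core),
GRE (`TGTTTGTTTGT`, Hamming distance ≤ 1) and PUF (`TGTANATA`, exact)
scanners run on the reference-genome 3' UTR sequence — annotation sequence,
not read consensus, which is reserved for the processing elements.
Overlapping ARE and GRE matches are merged into maximal intervals (merging
is stated for ARE; it is extended to GRE for consistency, and both the
merged and raw hit sets are available). miRNA target sites and Alu
intervals are ingested from files (TargetScan-style TSV filtered at
context score < −0.4; BED), never predicted in-package. Hits are labelled
by region; a hit straddling the proximal cleavage site counts as
differential, because the motif is absent from the short form's mature
transcript (configurable).

Conservation asks whether motif matches carry fewer SNPs than expected.
The observed density is SNPs per kb of *merged* match length (merging
avoids double-counting the denominator; the same choice applies to the
numerator's containment test). The background model tabulates, over the 3'
UTR universe, base frequencies P(base) and per-base SNP rates
P(SNP, base), giving P(SNP | base); a match of sequence s has expectation
mean_i P(SNP | s_i), and the reported bounds are the minimum and maximum of
this value over all matches of the motif (for miRNA sites only the 7-mer
seed is used). Under a uniform per-base rate p the bounds collapse to p
exactly — a property the acceptance suite exploits. Region enrichment per
motif is a two-sided Fisher's exact test on class II genes cross-classified
by region and motif presence.

## Heritability and association

Cluster expression is normalised per library (count divided by total mapped
reads), summed within genes, and — for association — summed over the two
replicates of each sample after normalisation.

Broad-sense heritability of a trait measured on I individuals with J
replicates is the one-way ANOVA intraclass correlation:
MS_b = J·Σ_i(ȳ_i − ȳ)²/(I−1), MS_e = Σ_ij(y_ij − ȳ_i)²/(I(J−1)),
H² = (MS_b − MS_e)/(MS_b + (J−1)·MS_e), clamped to [0, 1] with the raw
value kept in a diagnostic column. A zero-variance trait has H² = 0. The
polyA-position trait of a gene in a library is the pooled polyA position of
whichever cluster dominates that library (ties to the 5'-most cluster);
libraries with no reads leave the gene out of the position analysis. At
I = 6, J = 2 this estimator is noisy and, being a ratio estimator, its
*mean* over genes sits below the true intraclass correlation at
intermediate values (Monte Carlo: clamped means ≈ 0.31/0.54/0.86 at true
0.3/0.6/0.9) while the *median* tracks truth to within about 0.01; the
tests assert both behaviours rather than pretending the bias away.

Association codes each 3' UTR SNP as the count of major alleles per sample
(the major allele is determined across the analysed samples, ties toward
the reference allele) and correlates dosage with the started logarithm
log10(expression + c) of gene expression. The constant c defaults to half
the smallest nonzero expression value — scale-free, admits zeros, and
configurable since no specific constant is canonical. Positive signed R
means the major allele raises expression. SNPs falling inside an inferred
polyadenylation signal get allele strengths (1 canonical / 0.5 variant /
0 otherwise) for both allelic hexamers and their difference
(major − minor); the regression of signed R on this difference, a one-sided
Wilcoxon rank-sum test of |R| for signal SNPs versus all 3' UTR SNPs, and
Fisher's exact test on count tables summarise the genetic structure.
Monomorphic dosages and zero-variance expression vectors are skipped with a
recorded reason rather than silently dropped.

## The synthetic study generator

`sim_config()`/`simulate_apa_study()` generate the study the tests run on:
a single chromosome of gene cassettes (alternating strands), each with a
CDS, a 3' UTR, and planted cleavage sites per APA class — one site
(class I), two sites 200 bp apart in one UTR (class II), or sites in two
transcript isoforms (class III). Each site gets a polyadenylation signal
planted 21 bp upstream with a sanitised surrounding window (redrawn until
the planted category is the unambiguous call), a USE and a DSE;
destabilising motifs are planted into shared/differential regions; a
fraction of genes carry a genomic A-run with misprimed reads anchored at
it, a PCR-duplicate locus (scattered polyA positions sharing one mate
position), a signal-disrupting SNP (weak allele at the 4th or 5th AATAAA
base, giving allele strength differences of 1.0 or 0.5), and neutral UTR
SNPs placed away from planted elements.

Defaults are the study conditions: 6 individuals × 2 replicates, ~300
pooled reads per gene, cleavage jitter sd 3 bp (≈99% of reads within
±8 bp, so clusters span well under the 24 bp typical width), minor-allele
frequency 0.25 (six diploid samples usually segregate), 40-bp paired-end
reads, mate positions 80–250 bp upstream, weak-allele expression effect
0.5. Tail lengths are drawn 8–20 nt and tail mismatches computed honestly
against the genome, so misprimed reads with tails shorter than the planted
12-A run are caught by tail validation while longer-tailed ones survive to
exercise the cluster-level A-run filter — the split emerges from geometry,
not from a tuned knob. Expression heritability is delivered through
lognormal genotype and replicate effects (total log-scale variance 0.09) on
Poisson counts; Poisson shot noise adds to the within-replicate variance,
so the intraclass correlation realised from counts runs somewhat below
high targets — the estimator-recovery tests therefore simulate the
Gaussian trait directly, and the generator's own calibration checks target
the weak-allele effect (recovered within 10%) and the zero-heritability
boundary.

What passing tests on this generator do *not* show: the simulator has no
sequencing errors or quality scores, no splice junctions, single-exon gene
models, no fragment-length distribution, no population structure, and
planted elements at fixed offsets. Recovery rates on real libraries —
mapping artefacts, overlapping genes, annotation errors — will be lower,
and the filters' false-positive behaviour on dispersed no-peak regions is
deliberately out of scope.

## Problem sizes and determinism

The shipped test suite and acceptance script use 1,000 random read sets for
the peak-finder/oracle identity, 10,000 random 60-mers for the
scanner/oracle identity, a 50-gene default study for site recovery,
artefact flagging, signal-category accuracy and the background SNP model, a
200-gene study for the association structure, 1,000 genes per target for
heritability recovery, and a 20–50-gene study run twice for byte-identical
determinism — sizes chosen so each property is measured with comfortable
statistical margin on a desk machine. Every random draw flows from a single
integer seed; the pipeline itself contains no randomness, and rerunning any
stage with the same inputs reproduces identical files (the Wilcoxon test
uses the Normal approximation for exactly this reason).

## Known limitations

Cluster assignment gives each cluster to exactly one transcript, so genes
sharing UTR sequence compete; intronic APA is not sub-classified; the
two-form model ignores minor isoforms beyond the top two clusters; the
heritability estimator is reported per gene without shrinkage or
multiple-testing machinery (the analyses report distribution shifts, not
per-gene discoveries); and association is restricted to same-gene 3' UTR
variants with no population-structure correction — all consistent with the
package's scope of desk-scale reanalysis and simulation-backed validation.
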