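---
title: "Gene-targeted assembly of shotgun metagenomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-targeted assembly of shotgun metagenomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genetarget)
```

## The problem

Ammonia monooxygenase (AMO) catalyses the first step of nitrification.
Its subunit genes (*amoA*, *amoB*, *amoC*, plus the accessory *amoX*,
*amoD*, *amoE*) are carried by ammonia-oxidizing bacteria (AOB) and
archaea (AOA) and are close paralogs of the particulate methane
monooxygenase genes (*pmoABC*). Recovering full-length *amo* genes and
intact operons from shotgun metagenomes through whole-metagenome
assembly is expensive and biased toward abundant community members.
`genetarget` implements the alternative route: recruit only the reads
with translated homology to a labelled reference protein panel, assemble
just those reads across several k-mer sizes, re-annotate the resulting
genes at a stringent threshold, screen them for assembly chimeras and
complete operons, and compute the community statistics (contiguity,
Bray–Curtis similarity, distance–decay and taxa–area slopes,
nearest-reference clades, neighbour-joining trees) that an ecological
study of the gene family needs.

Every stage is testable against planted ground truth: the package ships
a seeded synthetic-metagenome generator producing the panel, genomes
with planted operons, a nested ring sampling design, a spatial community
with calibrated scaling slopes, and error-bearing reads.

## The processing route

`run_targeted()` chains the stages; each is exported on its own.

1. **Recruitment** (`recruit_reads`). Each read is translated in six
   frames (table 11; codons containing N become `X`, which never
   matches) and aligned to every panel protein that shares an exact
   5-residue seed with it. Alignment is affine-gap Smith–Waterman
   (BLOSUM62, gap existence 11, extension 1); because the extension is a
   full dynamic program over the seeded pair, every reported score
   equals unrestricted Smith–Waterman — seeding only decides *whether* a
   pair is examined, never degrades a reported alignment. Bit scores and
   e-values follow Karlin–Altschul statistics with the standard gapped
   BLOSUM62 constants ($\lambda = 0.267$, $K = 0.041$), with the search
   space $m \times n$ taken as query length times total panel residues.
   A read is recruited iff its single best hit (highest bit score; ties
   by identity, then subject id) passes the mode's e-value cutoff —
   *relaxed* ($e \le 1$) before assembly, *stringent* ($e \le 10^{-5}$)
   for re-annotation — with identity $\ge 0.3$, and belongs to a target
   family. The relaxed threshold is deliberately leaky: under the
   Karlin–Altschul model a random 150-bp read against a $10^4$-residue
   panel reaches $e \approx 1$ routinely, which is precisely why the
   route ends with a stringent second filter rather than trusting
   recruitment alone.

2. **Assembly** (`assemble_multi_k`). A de Bruijn graph over canonical
   k-mers (lexicographic minimum of k-mer and reverse complement; k odd)
   is built at each k in an ascending list, with the previous k's long
   contigs fed in alongside the reads. *No abundance cutoff is applied*:
   every observed k-mer enters the graph with count ≥ 1, so
   low-coverage gene variants are never discarded wholesale. Unitigs are
   maximal non-branching paths; bubbles are *not* popped, so allelic
   variants survive as separate contigs. All per-k contigs are pooled
   and merged into a consensus set: exact duplicates and contigs
   contained in a longer contig at ≥ 0.99 identity over their full
   length (reverse-complement aware) are removed, then contigs shorter
   than 200 bp are dropped.

3. **Gene calling and stringent re-annotation** (`call_orfs`,
   `annotate_stringent`, `dereplicate`). Contigs reaching this stage are
   near-complete genes, so a six-frame stop-to-stop ORF scan with
   start-codon preference (ATG/GTG/TTG) replaces an HMM gene finder. A
   stop-free interval without any start codon is reported only when a
   stop codon anchors it on at least one side (a truncated gene at a
   contig edge); frames with neither signal are not credible coding
   regions. Calls are re-searched against the panel at the stringent
   threshold; only *amo*/*pmo* calls are kept, then dereplicated by
   CD-HIT-style greedy clustering (length-sorted, join the first
   representative matched at ≥ 0.95 identity over ≥ 0.9 of the shorter
   sequence).

4. **Chimera screening** (`detect_ref`, `detect_denovo`). One
   crossover-maximisation score serves both modes. For a query and
   candidate parents A, B the model match count at crossover $x$ is the
   matches to A on query columns $< x$ plus matches to B on columns
   $\ge x$ (columns from pairwise global alignments projected onto the
   query); `d_score` is the best model count minus the best single
   parent's matches. Verdicts: *chimeric* if `d_score` ≥ 3 and both
   segments cover ≥ 20% of columns at ≥ 0.8 identity; *unclassified* if
   the gain is positive but below that band; *non-chimeric* otherwise.
   Reference mode draws parents from the panel's nucleotide CDS; de
   novo mode draws them from the other queries carrying at least twice
   the query's coverage, the abundance-skew logic of de novo bimera
   detectors. The *unclassified* band is an analog of the "unknown"
   category such detectors report, not a replica of any of them.

5. **Operon detection** (`detect_operons`). On each contig, *amo* calls
   separated by ≤ 500 bp cluster into one operon call. Completeness is
   by co-occurrence on a single contig — `complete_CAB` (amoC+A+B),
   `complete_ABCX` (plus amoX), `extended_DE` (plus amoD/amoE) —
   because *amo* subunits scatter across the genome in some lineages;
   canonical C–A–B order and same-strand arrangement are reported as
   flags, and the summary gives both lenient and strict counts.
   Competing calls at one locus (multi-frame shadows) resolve toward
   the higher bit score, but overlaps of ≤ 30% of the shorter call are
   tolerated: a start-codon scan may legitimately extend a call a few
   codons into its neighbour.

6. **Diversity statistics** (`assembly_stats`, `map_reads`,
   `bray_curtis`, `fit_ddr`, `fit_tar`, `assign_clade`, `nj_tree`).
   N50/N90 are the contig length at which the descending cumulative
   length first reaches 50%/90% of the total; L50/L90 count the contigs
   needed. Reads map to the dereplicated gene representative sharing the
   most canonical 31-mers (ties dropped as ambiguous). The
   distance–decay relationship (DDR) regresses similarity
   ($1 -$ Bray–Curtis on relative abundances) on $\log_{10}$ distance,
   excluding zero-distance pairs; the taxa–area relationship (TAR)
   regresses $\log_{10}$ pooled richness within each ring radius on
   $\log_{10}(\pi r^2)$, pooling cumulatively and counting a variant as
   present at abundance > 0 (no rarefaction; an option exposes it).
   Clade assignment is nearest-reference by global-alignment identity
   against the clade-labelled panel members (threshold 0.5, ties to the
   lexicographically smallest label, flagged). Trees use
   Poisson-corrected p-distances ($d = -\ln(1-p)$, $p$ capped at 0.95)
   and Saitou–Nei neighbour joining with negative branches clamped to
   zero — a deliberate, documented substitution for maximum-likelihood
   phylogenetics, which is out of scope.

## The synthetic-data model

`synth_config()` fixes every study condition; identical configurations
(including the seed) give byte-identical outputs.

**Reference panel.** Family ancestors are uniform-residue proteins
(A subunits 250 ± 30 aa, others 200 ± 30, always starting with M);
amo/pmo paralog pairs share a superfamily ancestor so their members sit
at 40–50% identity, within-family members at well above 60%, and
archaeal *amoA* members carry clade labels (NP-γ, NP-ζ, NP-η, NT-α,
NT-γ) arranged as clade subtrees. Every record also gets a
reverse-translated CDS with uniform synonymous codons — codon bias is
deliberately not modelled — which doubles as the nucleotide reference
for chimera screening and as the planted gene itself.

**Genomes and reads.** Each genome is i.i.d. uniform background DNA
with one operon inserted (layouts cycle through amoCAB, amoCAB+X and
amoCAB+DE; gaps 20–120 bp; random strand) and, by default, a non-amo
decoy gene downstream to exercise neighbour annotation. Reads are
uniformly positioned 150-bp fragments on a random strand with
substitution errors only (indels are off by design: the assembler
contract is defined for substitution noise) plus i.i.d. background
reads. Per-read origins and coordinates are recorded, so recruiter
recall and precision have exact denominators.

**Sampling design.** One central sample plus four samples on each of
six rings (default radii 5–200 m), 25 samples in all, emulating a
nested survey around a central point; four samples per ring plus a
centre is the natural 25-sample filling of such a design, and the
largest default radius keeps a 200 m spatial extent typical of
intertidal surveys. The radii are configurable.

**Calibrated spatial community.** Distance-decay and taxa-area slopes
are planted *by construction*, not tuned by simulation. Target
similarities $s_0 + d\,\log_{10}(\mathrm{dist})$ are projected onto the
samples' average-linkage dendrogram (giving the closest ultrametric
approximation, enforced monotone); each internal node of the dendrogram
becomes a "block" variant shared equally by its member samples. With
equal per-sample totals, the Bray–Curtis similarity of two samples is
then *exactly* the block value of their lowest common ancestor, and the
internal slope is root-found so that the fitted DDR slope on the
noise-free truth equals the planted $d$ to machine precision. Cumulative
ring richness is topped up to $\mathrm{round}(R_0\,\mathrm{area}^z)$
with singleton variants assigned to ring samples, planting the TAR
exponent; a private filler variant per sample normalises totals to 1.
A multinomial observation layer (`sample_counts`) adds realistic
sampling noise on top of the noise-free truth. This community is
two-tier with respect to the read simulation: slope statistics need
hundreds of variants, far more than desk-scale read simulation can
support, so the genome-backed variants that emit reads form a small
subset with their own spatial weights (Gaussian kernels around
genome-specific epicentres). Passing the slope-recovery tests therefore
demonstrates correct *fitting and calibration machinery*, not that a
desk-scale assembled community reproduces field-scale biogeography.

What the generator does **not** emulate: real mudflat community
complexity (hundreds of strains at log-normal abundances), quality-score
structure, PCR and GC bias, indel errors, and paired-end insert-size
variation. Conclusions about those failure modes cannot be drawn from
these tests.

## Numerical choices and degenerate inputs

* Alignment scoring: BLOSUM62 with gap existence 11 / extension 1 (a
  gap of length $g$ costs $11 + g$); nucleotide scoring 2/−3 with gap
  5/2. `N` and `X` never count as matches. These are community-standard
  parameters; the emulated workflow specifies only its thresholds, so
  standard scoring is what makes those thresholds meaningful.
* Best-hit ties break by identity then lexicographic subject id;
  contigs are emitted in canonical orientation and sorted by length
  then sequence; every output is therefore byte-stable under a fixed
  seed (the pipeline manifest records md5 sums and a manifest hash to
  prove it).
* Graph cleaning. The only cleaning is clipping of weakly supported
  side paths: an attached unitig is removed when all its k-mer counts
  are 1, or when a parallel branch carries at least four times its
  support; tips may be as long as the read length (read-end errors) and
  bridges as long as read length + k (multi-error reads). Balanced
  bubbles — genuine variants with comparable support on both arms — are
  never clipped. Contigs from the previous k are fed forward only when
  comfortably longer than this artifact scale, so residual error k-mers
  are not reinforced into unclippable count-2 branches.
* Degenerate inputs: empty read sets flow through every stage and give
  empty outputs; empty FASTA files warn; k values exceeding all read
  lengths are skipped with a warning; queries shorter than 15 bases are
  unclassified in chimera screening; DDR needs ≥ 3 positive-distance
  pairs and TAR ≥ 3 rings with positive richness, otherwise they error
  with a clear message.

## Problem sizes used by the tests

The suite and the acceptance script run at desk scale, chosen so the
full battery completes in minutes on one CPU: panels of ~36 proteins,
genomes of 3–6 kb, per-fixture read sets of a few hundred reads at
10–20× coverage (clean fixtures tile reads so the stated coverage
precondition holds at every base), 20-fixture batteries for
reconstruction, operon recovery and chimera characteristics, 20
community replicates for slope recovery, and end-to-end runs of ~800
reads across 7 samples. The k-mer list defaults to 21, 33, 55, 77 at
this scale; the full-scale analogue of the route spans k = 29–141.

## Known limitations

* The recruiter is a sensitive but not exhaustive search: a pair
  sharing no exact 5-residue seed is never aligned. The sensitivity
  contract is explicit and tested (disabling seeds can only add
  recruited reads).
* The assembler targets recruited-read scale (at most a few hundred
  thousand reads), not whole metagenomes; memory-efficient graph
  representations are out of scope.
* Chimera verdicts reproduce a three-way vocabulary with tested
  operating characteristics but are not score-compatible with any
  specific published detector.
* Clade assignment is nearest-reference, not phylogenetic placement;
  it inherits the panel's labelling.
* A count-1 variant running parallel to an abundant allele is
  indistinguishable from a sequencing error and is clipped; variants at
  coverage ≥ 2 survive.
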