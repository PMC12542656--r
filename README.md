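# genetarget

Gene-targeted metagenome assembly and diversity analysis in R.

## What it is for

Whole-metagenome assembly is a blunt instrument when the question is
about one functional gene family: it costs hundreds of gigabytes of RAM
and days of runtime, and it is biased toward the abundant fraction of
the community. `genetarget` implements the targeted alternative for
microbial ecologists studying a gene family such as ammonia
monooxygenase (*amo*) and its paralogs (*pmo*):

1. **Recruit** the reads with translated homology to a labelled
   reference protein panel — six-frame translation, seeded
   Smith–Waterman (BLOSUM62, gap 11/1), Karlin–Altschul e-values
   (λ = 0.267, K = 0.041), best-hit rule at a relaxed cutoff
   (e ≤ 1, identity ≥ 0.3).
2. **Assemble** only the recruited reads with a multi-k de Bruijn
   assembler (canonical k-mers, no abundance cutoff, bubbles kept so
   allelic variants survive), merging per-k contigs into a consensus
   set by containment at ≥ 0.99 identity.
3. **Call and re-annotate genes** (six-frame ORF scan, stringent
   re-search at e ≤ 1e-5, identity ≥ 0.3) and remove redundancy by
   greedy clustering at 0.95 nucleotide identity.
4. **Screen for chimeras** in reference and de novo (coverage-skew)
   modes with a crossover-maximisation score and a three-way verdict
   (chimeric / non-chimeric / unclassified).
5. **Detect operons**: amoCAB co-occurrence on one contig, amoABCX and
   amoD/E extensions, gene order and strand as flags, neighbouring
   genes annotated against the panel.
6. **Quantify diversity**: N50/L50/N90/L90 contiguity, read-to-gene
   abundance matrices by canonical 31-mer assignment, Bray–Curtis
   community similarity, distance–decay slope *d* (similarity vs
   log10 distance), taxa–area exponent *z* (log richness vs log area),
   nearest-reference clade assignment (NP-*/NT-* lineages of archaeal
   *amoA*), and neighbour-joining trees from Poisson-corrected
   distances.

A fully seeded synthetic-metagenome generator (`simulate_metagenome`)
plants a reference panel, operon-bearing genomes, a 25-sample nested
ring design, a spatial community whose DDR/TAR slopes are calibrated by
construction, error-bearing reads and chimeric splices — so every stage
is validated against exact ground truth.

## Worked example

```r
library(genetarget)

cfg <- synth_config(seed = 42, n_genomes = 3, coverage_per_sample = 1,
                    background_fraction = 0.2, radii = c(5, 20, 100),
                    n_per_ring = 2)
sim <- simulate_metagenome(cfg)
run <- run_targeted(pipeline_config(sim$reads, sim$panel,
                                    design = sim$design,
                                    out_dir = "readme_run", seed = 1))
print(run)
#> targeted-assembly run: readme_run
#>   451 reads recruited, 7 contigs, 13 targeted genes (13 reps), 6 operon calls

run$operons[, c("contig_id", "completeness_class", "subunits",
                "canonical_order")]
#>   contig_id completeness_class            subunits canonical_order
#> 1  ctg00001       complete_CAB      amoB,amoA,amoC            TRUE
#> 2  ctg00002       partial:ABDE amoA,amoB,amoD,amoE           FALSE
#> 3  ctg00003         partial:AC           amoC,amoA           FALSE
#> ...

run$diversity$assembly_stats
#> 7 contigs, 9111 bp | N50=1659 L50=3 | N90=707 L90=5

evaluate_against_truth(run, sim)[c("recruit_recall", "recruit_precision")]
#> recruiter recall 1.000, precision 0.996
```

At 1× per-sample coverage one of the three planted operons assembles
completely (`complete_CAB` on `ctg00001`, in canonical C–A–B order once
the strand is accounted for); the others are recovered as partial
clusters. Recall 1.0 means every error-free read lying inside a planted
*amo*/*pmo* CDS was recruited; precision 0.996 is the fraction of
recruited reads that truly originate from a planted genome (the relaxed
e ≤ 1 cutoff is deliberately permissive — the stringent re-annotation
stage is what guarantees specificity of the final gene set).

The spatial statistics recover their planted values on the noise-free
community truth:

```r
des <- ring_design()
com <- simulate_community(des, synth_config(seed = 42))
fit_ddr(com$matrix, des)
#> slope = -0.045 (intercept 0.545), r2 = 0.943, P = 1.89e-187, n = 300
fit_tar(com$matrix, des)
#> slope = 0.01633 (intercept 2.235), r2 = 0.999, P = 5.51e-07, n = 6
```

The DDR slope is exactly the planted −0.045 (the generator root-finds
its internal parameter so the fitted slope matches by construction);
the TAR exponent lands within rounding of the planted 0.016.

## Command line

A thin wrapper over the same functions ships in `inst/cli/genetarget.R`:

```sh
Rscript inst/cli/genetarget.R simulate --seed 4 --out sim/
Rscript inst/cli/genetarget.R run --reads "sim/reads/*.fastq" \
    --panel sim/panel.faa --design sim/design.tsv --out run/ --seed 1
```

Subcommands `recruit`, `assemble`, `annotate`, `chimera`, `operon` and
`diversity` expose the individual stages.

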