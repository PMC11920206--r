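---
title: "Resolving the fibromelanosis structural allele from collapsed-reference population data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving the fibromelanosis structural allele from collapsed-reference population data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmscan)
```

## The problem

Fibromelanosis (FM) is a dominant hyperpigmentation phenotype of chicken
caused by a complex structural variant on chromosome 20: two large
duplications — DUP1 (chr20:10,766,772–10,894,151; 127.4 kb) and DUP2
(chr20:11,306,686–11,477,501) — separated by a non-duplicated intervening
region (INT, 412.54 kb boundary to boundary), with an inversion whose exact
placement distinguishes three candidate internal arrangements, FM-1, FM-2 and
FM-3. Short reads from the extra copies of DUP1/DUP2 map onto the single
reference copy ("collapsed mapping"), so depth sums over copies and allele
fractions average across paralogs, which is exactly why the arrangement is
hard to resolve by assembly but leaves a rich population-genomic footprint.

`fmscan` implements that footprint as a testable pipeline. Its core logic:

* **Relative depth** distinguishes N/N, FM/N and FM/FM carriers
  (expected region/background ratios 1.0, 1.5, 2.0 in the duplications).
* **Recombination suppression** over a duplicated span freezes the two
  copies of the founding FM haplotype. Where the two donor copies differ,
  every FM homozygote is called heterozygous — *fixed heterozygosity*,
  reference-allele frequency pinned at 0.5. Where they agree, the cohort is
  fixed at 0 or 1. The resulting frequency profile — sites clustered at 0,
  0.5, 1 — is the "bubble".
* Each configuration predicts where the bubble must appear, because a region
  shows a bubble exactly when *all* of its copies lie inside the suppressed
  span: WT (0,0,0), FM-1 (1,1,1), FM-2 (1,0,0), FM-3 (0,0,1) over
  (DUP1, INT, DUP2). Matching the observed triple against these templates by
  Hamming distance is the configuration call; an exact match is `confident`.

The frequency signature is corroborated by windowed
F~ST~ between FM/FM and N/N cohorts, by nucleotide diversity (reduced in the
frozen span only), by LD retention against the genome background, and by
neighbor-joining trees of the two duplications (FM samples coalesce on short
terminal branches only where frozen).

## The generator

Real data of this design (hundreds of resequenced chickens) cannot ship with
a package, so `fmscan` includes a first-class synthetic generator that
emulates the statistical structure of the system, not its sequences:

1. **Founders** (`simulate_founders`): segregating sites placed by a Poisson
   process; each site gets a founder reference-allele frequency drawn
   Beta(α, α) (default α = 0.3, a U-shaped frequency spectrum typical of
   SNP panels); pool haplotypes sample alleles independently per site.
   There is deliberately *no background LD* — the FM allele's identity by
   descent is the only source of elevated LD, so every LD signal the scan
   finds is attributable to the rearrangement.
2. **Birth of the FM allele** (`construct_fm_allele`): an inter-chromosomal
   event between two donor haplotypes A and B. Duplicated regions carry
   copy 1 from A and copy 2 from B; with probability `donor_divergence` a
   site is promoted to a guaranteed A≠B fixed difference.
3. **Erosion** (`erode_population`): each non-suppressed segment of each FM
   chromosome is replaced by random wild-type content with probability
   `erosion_p` (default 0.9), a memoryless stand-in for
   1 − exp(−rg) recombination over the allele's age. Frozen segments are
   never touched.
4. **Observation** (`observe`): per site and sample, reads are
   Poisson(depth·c/2) over the total copy number c, reference reads
   Binomial with the paralog-averaged reference fraction (plus sequencing
   error, default 0.001), and a diploid genotype is called from the
   reference-read fraction with a symmetric het band (default 0.2–0.8).
   This band is a surrogate for a full variant-calling pipeline, chosen as
   the simplest rule that reproduces het calls at paralog fractions 1/4,
   1/2 and 3/4; a `deterministic` mode replaces sampling by expectations
   for exact unit tests.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `scale` | 100 (analyses), 1 (coordinates) | divisor on all map coordinates |
| `site_density` | 1/200 per scale-1 bp | expected segregating sites |
| `sfs_alpha` | 0.3 | founder frequency spectrum shape |
| `donor_divergence` | 0.1 | forced A≠B rate in duplications |
| `erosion_p` | 0.9 | per-segment replacement probability |
| `depth` | 30 | mean per-site coverage at c = 2 |
| `het_band` | (0.2, 0.8) | reference-fraction band called het |
| `maf`, `max_missing` | 0.05, 0.9 | site filters |
| `eps`, `min_called` | 0.05, 20 | site-class tolerance / support |
| `tau` | 0.5 | bubble fixed-fraction threshold |
| window, step | 20 kb/scale, 10 kb/scale | scan grid |
| CNV thresholds | 1.25, 1.75 | midpoints between ratios 1.0/1.5/2.0 |

`site_density` is defined per base of *unscaled* sequence and multiplied by
the map scale, so expected per-region site counts are scale-invariant
(DUP1 carries ~640 sites whether the map is full-size or desk-scale); this
keeps every per-region analysis adequately powered at scale 100, where the
whole 1.1 Mb scan region shrinks to ~11 kb and a complete
simulate–observe–infer replicate runs in well under a second.

`donor_divergence = 0.1` deserves a note. At a segregating site two random
donor haplotypes already differ with probability 2p(1−p); the parameter adds
divergence on top. Fixed-heterozygous sites contribute ≈ 0.5 each to
windowed π in the FM cohort, while eroded regions contribute the ordinary
heterozygosity E[2pq]. Pushing forced divergence much above ~0.25 therefore
*inverts* the diversity-reduction signal (π in the frozen DUP1 would exceed
π in INT), contradicting the biology the scan is meant to detect; 0.1 keeps
fixed heterozygosity clearly visible (roughly a quarter of filtered DUP1
sites) while preserving the π reduction.

### Breakpoint injections

Two controlled perturbations support the finer-scale analyses:

* `identical_interval` forces the donors equal over a sub-interval, removing
  fixed heterozygosity there while the span stays frozen — a pure
  donor-identity break.
* `free_interval` lifts suppression over a sub-interval, so both copies
  erode — the recombination reading of a sharp fixed-heterozygosity
  disruption. Only this injection also breaks the LD structure: with donors
  merely identical, every frozen site still co-segregates with FM carrier
  status and the pairwise r² matrix stays effectively rank one, which no
  split criterion can partition. The concordance experiment (fixed-het
  breakpoint vs LD block boundary, below) therefore uses `free_interval`
  with full donor divergence, making the truth breakpoint a clean step.

## Numerical and design choices

* **Interval lengths** use the end − start convention, under which the
  printed 127.4 kb follows from DUP1's coordinates; the intervening span is
  measured boundary to boundary (dup2.start − dup1.end = 412,535 bp
  = 412.54 kb). The published DUP2 size (170.5 kb) differs from its
  coordinate arithmetic (170.8 kb); both are kept, and the published value
  enters only the ancestral tandem-unit sum 127.4 + 412.5 + 170.5 =
  710.4 kb, the span duplicated by unequal crossing over in the birth model
  (tandem duplication, then an inversion that deleted one copy of the
  intervening region).
* **F~ST~** is the Weir–Cockerham (1984) two-population estimator,
  aggregated per window as a ratio of sums; sites monomorphic across both
  cohorts carry no information and are excluded from both sums. A
  formula-literal second implementation serves as the oracle in tests
  (agreement to 1e-12).
* **Z tests** standardize window values against the background-region
  windows and use one-sided upper-tail p-values (the scan asks whether the
  locus is *higher* than background); BH-FDR is applied across the whole
  tested window set.
* **Site classes** use tolerance `eps = 0.05` around 0, 0.5 and 1 (exact
  fixation is an infinite-sample idealization) and require 20 called
  alleles; `eps` ≥ 0.25 is rejected because the classes would overlap.
* **Change-point detection** is an exhaustive two-segment Bernoulli
  likelihood scan (the region holds at most a few thousand sites, so the
  O(N) scan is both the oracle and the implementation), reported above an
  LRT threshold of 10. The indicator series defaults to membership in
  FIXED_HET — the signal whose disruption marks the breakpoint; an
  all-fixed-classes indicator would be constant over a frozen span and
  blind to it.
* **LD block boundary** maximizes the contrast (mean within-block r² −
  mean cross-block r²) over all splits, reported only above a contrast of
  0.2 to suppress boundary calls on homogeneous blocks. Minimizing the
  cross term alone degenerates whenever LD is mediated by a latent carrier
  factor (the cross mean then factorizes and is smallest at an extreme
  split), which is precisely the structure collapsed duplication data
  produce.
* **Neighbor joining** is implemented directly (Saitou–Nei, Q-criterion)
  with deterministic lexicographic tie-breaking and negative branch lengths
  clamped to zero with the deficit logged; on additive matrices it is exact
  (verified against path distances and `ape::nj` topologies). Distances
  are allele-sharing means of |dosage differences|/2, the simplest distance
  computable from unphased genotypes.
* **Degenerate inputs**: zero sites in a named region aborts the simulation
  with advice to raise density; an empty FM/FM cohort (the wild-type
  situation) yields all-clear bubble flags and a confident WT call rather
  than an error; windows with undefined statistics are reported with site
  counts and `NA` values.

## Problem sizes

All shipped analyses run at scale 100 (scan region ≈ 11 kb, ≈ 8,000 sites,
100 individuals, pool of ~120 haplotypes), chosen so that every region keeps
hundreds of classified sites and a full replicate — simulate, observe,
genotype, scan, call — completes in under a second; configuration-recovery
experiments use 20 seeded replicates per architecture, and the
breakpoint-concordance experiment 20 replicates.

## What passing tests do and do not show

The generator reproduces the *statistical geometry* of the system: depth
ratios, paralog-averaged allele fractions, fixed heterozygosity, erosion
outside the suppressed span, and LD created by identity by descent. It does
not model background LD or haplotype blocks among wild-type chromosomes,
demography, selection, GC/mappability bias, genotyping artifacts beyond a
symmetric allele-fraction band, or sequence-level effects (indels,
multi-mapping beyond copy pooling). Recovery of the generating architecture
here therefore demonstrates that the inference logic is correct and
well-calibrated for the signal it targets — not that any particular
real-data depth or divergence threshold transfers verbatim. The study's
real-data effect sizes (for example the reported mean F~ST~ Z-scores) depend
on an 817-sample panel and are intentionally not reproduced; the pipeline
reports the same statistics on any input.

## A worked run

```{r example, eval = FALSE}
map <- build_region_map(scale = 100)
pop <- simulate_population(map, fm_sim_params(config = "FM-2", seed = 7))
obs <- observe(pop, depth = 30, seed = 7)
fit <- infer_fm_configuration(obs)
summary(fit)
plot(fit)   # the bubble: FM/FM frequencies pinned at 0, 0.5, 1 over DUP1
```

The same stages run from files (`read_vcf`, `read_depth_tsv`, `read_bed`),
so any third-party VCF plus depth table can replace the simulator;
`run_fm_pipeline()` chains everything and writes each product in its
documented format.
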