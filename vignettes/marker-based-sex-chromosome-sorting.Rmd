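---
title: "Marker-based sorting of sex-limited chromosome reads: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based sorting of sex-limited chromosome reads: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mskit)
```

## The problem and the method

A sex-limited chromosome (Y in XY systems, W in ZW) is carried by one sex
only, never recombines over most of its length, and is typically the last
and worst-assembled part of a genome. `mskit` enriches its long reads
before assembly using a purely k-mer-based signal that needs no reference:

1. k-mers are counted per individual in short-read data from $n$ males and
   $n$ females (canonical form: the lexicographic minimum of a k-mer and
   its reverse complement, so both strands agree);
2. a k-mer is *present* in an individual only if observed at least twice —
   an isolated sequencing error produces a singleton k-mer, which this rule
   removes almost entirely;
3. a k-mer is a male-specific k-mer (MSK) when present in at least
   $m = 2n/3$ males and in no female;
4. long reads are kept when their MSK density reaches a threshold $M$
   (markers per kilobase).

In an XY system only Y sequence can systematically generate such k-mers;
the same machinery applied with groups swapped yields W-specific markers.

## Poisson presence model and the error rates

Each single-copy k-mer is observed in one individual's reads a
Poisson-distributed number of times with rate
$\lambda = d(1-r)^k(l-k+1)/l$: depth $d$ times the chance a k-mer is read
error-free, times the fraction of read positions that begin a complete
window. Absence (count $<2$) has probability $q_o = (1+\lambda)e^{-\lambda}$.

Four closed forms follow (all exported):

* `fp_coverage()` — probability an autosome/X k-mer passes by coverage
  fluctuations alone: $f_1 = q_o^n\sum_{i=m}^n \binom{n}{i}p_o^i q_o^{n-i}$.
  At $n=5$, $d=5\times$, $l=150$, $r=0.01$, $k=21$ this is
  $4.4\times10^{-5}$, and $1.9\times10^{-9}$ at $n=10$.
* `fp_heterozygosity()` — the same mechanism for the two allele k-mers of a
  polymorphic autosomal site with population frequencies $p_{h1}, p_{h2}$,
  each observed at rate $p_{hj}\lambda$.
* `fp_total()` — the $kh$-weighted combination, integrating $p_{h1}$ over a
  built-in empirical 5-point distribution (0.05–0.45 with probabilities
  92.77%…1.36%), overridable via `het_allele_distribution()`.
* `tpr_msk()` and `read_sort_prob()` — the binomial tails for marker
  recovery and read sorting; `msk_precision()` combines TPR/FPR with the
  genome k-mer census.

Two approximations are quantified rather than modelled: a k-mer holding
more than one heterozygous site (`het_multi_site_prob(21, 0.001)` ≈
$2.1\times10^{-4}$) and an error converting one k-mer into a specific
edit-distance-1 neighbour (`misid_prob(21, 0.01)` ≈ 0.3%); both are
neglected in $f_2$.

### The threshold rule for m

The male-presence threshold is $m$ = nearest integer to $2n/3$ by default.
The alternative ceiling reading gives a different $f_1$ at $n = 5$
($\approx 3.9\times10^{-5}$ instead of $4.4\times10^{-5}$): only the
nearest-integer rule reproduces the model's reference values at both
$n = 5$ and $n = 10$, which is why it is the default; `ceil` and `floor`
remain available everywhere the rule appears
(`male_presence_threshold()`, `theory_params()`, `select_male_specific()`).

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `k` | k-mer length (bases) | 21 | odd, 3–63; 51 useful for repeat-rich targets |
| `min_count` | per-individual presence threshold | 2 | "seen more than once" |
| `rule` | rounding of $2n/3$ | `round` | see above |
| `threshold_per_kb` | read-sorting density $M$ | 7 | human-Y average; recompute with `estimate_density_threshold()` given a reference ≥ 10 kb |
| `min_hits` | minimum marker positions per read | 1 | guards a zero threshold |
| `d`, `l`, `r` | short-read depth/length/error | 5×, 150 bp, 0.009 | substitution-dominated Illumina regime |
| `depth_band` | pooled-count window | off | optional half-depth filter |

Two decisions in the sorter are fixed and documented: density uses the full
read length as denominator (hits × 1000 / length — indistinguishable from
$l-k+1$ for long reads), and a read exactly at the threshold is **kept**
(only *lower* density is excluded). Hits count marker *positions*;
`distinct = TRUE` switches to distinct markers. The default 7/kb exists
because the "average density over the whole Y" cannot be computed before a
Y assembly exists; when any Y-like reference is available,
`estimate_density_threshold()` replaces the constant.

The depth-band filter (`depth_band_filter()`) — keeping k-mers whose pooled
male count sits near the haploid expectation $nd/2$ — is exposed but off by
default: the operational selection rule is presence/absence only, and the
band is an optional sharpening for high-depth cohorts.

## The synthetic data generator

`generate_genome()` builds an autosome, an X, and a Y composed of a PAR
(copied verbatim from the X, so zero specific k-mers by construction), an
X-derived segment substituted at `xy_divergence` per site, and a fraction
(`y_novel_frac`, default 0.2) of novel sequence. Defaults are the
desk-scale stand-in used throughout: 5 Mb autosome, 2 Mb X, 0.5 Mb Y,
20 kb PAR, 1% divergence. All sequence is i.i.d. uniform ACGT.

Individuals (`derive_individual()`) carry the diploid dosage of their sex
(male: A×2, X, Y; female: A×2, X×2). Heterozygosity comes in two models:

* **shared polymorphism** (default in population sweeps): a panel of
  autosomal SNPs whose minor-allele frequency is drawn from the same
  5-point distribution the theory uses; site density is set so the realised
  per-individual heterozygosity equals `h`. This is the model under which
  population heterogeneity can create false markers — an allele observed in
  many males and, by coverage chance, in no female — and therefore the
  model the heterozygosity false-positive rate describes.
* **private mutations**: each site heterozygous with probability `h`
  independently per individual. Useful for dosage/rate checks, but private
  alleles can never reach $m$ males, so this model cannot reproduce the
  heterogeneity effect.

Short reads are substitution-only at `r = 0.009` (the per-mille indel rates
of Illumina-like data are negligible for presence/absence k-mer analysis);
depth is per haploid copy, so a male's X and Y see half the autosomal
depth, as the models assume. `systematic = TRUE` tiles reads
deterministically (stride $l-k+1$, each read emitted twice) so every
k-window is covered at least twice — the noise-free regime in which marker
recovery is provably exact; random placement cannot guarantee that premise
at any finite depth. Long reads (`simulate_long_reads()`) use technology
presets (HiFi 1% total error, 12 kb ± 1 kb; CLR 10%, 7.5 kb ± 3 kb; ONT
9%, 15 kb ± 8 kb) with substitution/insertion/deletion errors and carry
their origin coordinates in the read id.

What the generator does **not** emulate: repeat families and segmental
duplications (real Y chromosomes are heterochromatin-rich, which depresses
usable marker density), GC bias, quality-score structure, chimeric reads,
and X-chromosome polymorphism. Passing tests therefore demonstrate the
correctness of the algorithms under their stated model, not performance on
repeat-dense real genomes.

## Evaluation design

`eval_marker_set()` scores predicted against exact truth k-mers;
`eval_read_partition()` scores the read partition per read (not per base)
against origin labels. A Y read is labelled `Y` only if at least half of
its template lies outside the PAR: PAR reads are marker-free by
construction and are deliberately not counted against recall. Reads
straddling the PAR boundary are genuinely ambiguous (a read 40% inside
the diverged Y is rejected by any consistent labelling yet carries marker
density); exact-recovery checks exclude them, stochastic sweeps keep them.

`degrade_marker_precision()` emulates imperfect marker identification by
spiking decoys sampled from real autosome+X k-mers. At large genome scale
an identified marker set is a *subset* of all true specific k-mers plus
false positives whose genomic density is far below the sorting threshold
(~1/kb against 7/kb); at desk scale, keeping every true marker while
adding enough decoys for 70% precision would push decoy density above the
threshold itself — a scale artefact, not a property of the method. The
`decoy_density_per_kb` option therefore fixes the physically meaningful
quantity (decoy density on non-target sequence) and subsamples the true
markers so the requested precision still holds exactly. The remaining true
markers (~16k over the 0.5 Mb Y, ~34/kb) keep Y reads far above the
threshold, as in the large-genome regime.

### Problem sizes

Chosen once as the package's desk-scale study conditions:

* exact-recovery checks: the default 5 Mb + 2 Mb + 0.5 Mb genome, 5
  males + 5 females, tiled error-free reads (~1.5 min);
* population sweeps: a 400 kb + 150 kb + 60 kb genome, depth 5×,
  `r = 0.009`, 5 replicates per condition — large enough that marker F1
  trends (rising with $n$, falling with `h`) are far outside replicate
  noise;
* precision sweep: the full default genome, HiFi reads at 25× Y / 50×
  elsewhere, 5 replicates.

## Numerical choices

Binomial tails go through `stats::pbinom` (regularized incomplete beta),
accurate to relative error far below $10^{-10}$ for the cohort sizes
involved; nothing sums raw binomial terms. k-mers with $k \le 31$ live in
2-bit-packed 64-bit integers whose numeric order equals lexicographic
order, so sorted integer tables and sorted text dumps agree; $33 \le k
\le 63$ falls back to a string path with identical semantics. Windows
containing any non-ACGT symbol are skipped entirely (never coerced).
Selection over many individuals streams sorted per-individual tables
through a k-way merge, so memory does not grow with cohort size; the
in-memory route produces identical results and both are tested against a
brute-force double loop. Table files are KMC-dump-compatible TSV, gzip
optional, with strict parse validation that reports the offending line.
All generators draw from R's RNG under explicitly passed seeds
(per-individual seeds derived from a master seed by counter), making every
simulation bit-reproducible; file outputs are written via
temp-file-and-rename.

## Known limitations

* Random genomes lack repeats: real marker density is far less uniform,
  and the constant 7/kb threshold interacts with that non-uniformity
  (heterochromatic stretches fall below any fixed threshold).
* The theory treats allele observation rates as $p_{hj}\lambda$ — a
  population-frequency approximation of individual dosage; the simulator
  draws true genotypes, so small systematic gaps between theory and
  simulation at high `h` are expected.
* Sequence similarity between the Y and other chromosomes beyond the
  modelled X-Y homology (e.g. recent transpositions) is outside the error
  model.
* Assembly of the sorted reads, and alignment-based validation, are out of
  scope by design; the package stops at sorted read sets, contig
  partitions, and their evaluation against synthetic truth.
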