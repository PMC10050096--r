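---
title: "Methods: inferring mutations and copy-neutral LOH in clonal lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring mutations and copy-neutral LOH in clonal lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalloh)
```

## The inference problem and its assumptions

`clonalloh` analyzes multi-sample genotype data from an obligately clonal
diploid in which a focal sub-lineage (for instance a discrete mutant morph)
must be distinguished from its wild-type clonemates by exhaustive genotype
comparison rather than by crosses. Three assumptions carry the whole
method:

1. **Clonality.** All focal samples descend mitotically (or by automixis
   with central fusion) from one founding individual, so they share every
   lineage-defining variant. A site where focal samples disagree is
   therefore never lineage-defining and is excluded by construction.
2. **Completeness of the reference panel.** A distinguishing site requires
   that *no* reference sample carries the focal genotype. The more
   reference genomes, the fewer coincidental matches survive; with few
   references the site list inflates.
3. **Biallelic SNPs.** Genotypes are collapsed to three classes (hom-ref,
   het, hom-alt). Multi-allelic records and indels are excluded at read
   time and counted in the read log.

Under central-fusion automixis, heterozygosity is preserved near
centromeres and lost distal to crossovers: one meiotic crossover on a
chromosome makes all loci distal to it homozygous in the offspring with
probability 1/2. This is the mechanism that turns a single recombination
event into a contiguous, megabase-scale, *copy-neutral* loss of
heterozygosity — the central object this package detects.

## From sites to events

`find_distinguishing_sites()` applies the definition literally (shared
focal class, absent from every reference; references may vary among
themselves). `classify_events()` then reads zygosity:

- focal-**het** sites are gains of heterozygosity — de novo point
  mutations, one event per site;
- focal-**hom** sites are losses of heterozygosity, merged into events when
  consecutive sites lie within `merge_gap` (default 1000 bp, the
  sub-kilobase scale of gene-conversion tracts). A run is broken by an
  intervening gain-of-het site, which keeps events on a chromosome
  disjoint. Merged runs spanning at most `segmental_span` (default
  10,000 bp) are gene conversions; larger runs are segmental. The 10 kbp
  default sits between the two biological regimes — conversion tracts are
  sub-kilobase while crossover LOH is chromosome-scale — so the split is
  insensitive to its exact value over orders of magnitude.

`run_pipeline()` deliberately does **not** rely on gap-merging to find
segmental events: at realistic heterozygous-site densities (~1 site/kbp)
the gaps between informative sites routinely exceed 1 kbp and a megabase
tract would fragment. Instead, each chromosome is scanned for its maximal
run of consecutive sister-informative sites at which all focal samples are
homozygous (`locate_loh_boundaries()`). If that run spans more than
`segmental_span` with at least `loh_min_sites` (default 10) supporting
sites, the chromosome carries a segmental event: the run's ends are the
*inner* bounds, the flanking heterozygous informative sites the *outer*
bounds, and the true breakpoints provably lie between them. Only the
remaining chromosomes' sites go through the short-event classifier. This
mirrors analyzing a chromosome-scale LOH separately from the scattered
small mutations elsewhere in the genome.

Copy-number status comes from `check_copy_neutral()`: the mean focal
normalized depth over SNPs inside the interval divided by the mean
reference normalized depth. The default bands — 0.85–1.15 copy-neutral,
0.35–0.65 deletion-like — separate the two regimes at ~35× coverage with
hundreds of supporting SNPs; anything between is flagged `untested` rather
than forced into a class.

## Filters and depth normalization

`hard_filter()` removes every site with a missing call and every site where
any sample's depth is **greater than or equal to** twice the global median
depth (`depth_multiplier = 2`), the cutoff computed once on the unfiltered
matrix. Excess depth marks collapsed duplicates whose "heterozygosity" is
an artifact of mis-mapped reads — exactly the false signal that would
survive inside an LOH. The threshold uses one global median (a single
printed cutoff for the cohort); per-sample medians are used only for
normalization, where between-library loading differences are the explicit
motivation: `normalize_depth()` divides each sample's depths by that
sample's median over retained SNPs, so every sample's median normalized
depth is 1.

Numerical note: medians of integer depths are (half-)integers, so the
normalized depth ratio carries a granularity of roughly 1/median — at 35×,
about 3%. A focal/reference ratio of 1.03 inside a copy-neutral region is
expected jitter, which is why the neutral band is ±15% and not tighter.

## The generation clock

With mutation rate μ per site per haploid genome per generation and haploid
genome size G, the de novo count per generation is Poisson with mean
2μG — at the defaults μ = 3.5×10⁻⁹ and G = 224 Mbp, 1.568 (≈1.6) SNPs per
generation. `estimate_generations()` divides the observed gain-of-het count
by 2μG and attaches a 95% Poisson likelihood-ratio interval (profile of the
Poisson log-likelihood in the generation number, solved by `uniroot`; a
zero count gives the one-sided interval [0, upper]). The estimate assumes
all gain-of-het events are genuine de novo mutations on the focal branch
and that μ, borrowed from related taxa, applies — both are stated
assumptions, not checked by the data.

## What the simulator emulates, and what it does not

`sim_config()` / `simulate_cohort()` generate: a diploid founder with
Poisson-distributed heterozygous sites at density `founder_het_density`
(default 10⁻³/bp, a dense clonal-line background); per-generation de novo
mutations at rate 2μG placed at previously non-segregating positions;
gene-conversion tracts with geometric lengths (mean 300 bp, kept
sub-kilobase); per-chromosome Poisson crossovers, each triggering distal
LOH with probability 1/2 (centromeres fixed at position 0 — the simulator
reproduces the *geometry* of central fusion, not a full meiosis model);
hemizygous deletions that halve expected depth; and negative-binomial
depths with mean `mean_depth` (35) and dispersion `depth_dispersion`
(0.02, giving the ~20% coefficient of variation of real short-read
coverage; 0 degenerates to constant depth for exact tests). Genotypes are
unphased: when a tract loses heterozygosity the surviving allele is drawn
per site, which is observationally equivalent for genotype-class analyses
but means the simulator cannot test haplotype-identity claims.

Not emulated: read-level errors and genotype-calling noise, mapping
artifacts from collapsed duplicates (the very thing the depth filter
guards against in real data), indels, selection, and sexual reproduction.
Passing tests therefore demonstrate that the inference recovers planted
events from clean genotype matrices at realistic density and coverage —
they do not certify robustness to caller-specific artifacts.

`simulate_validation_cohort()` freezes the package's reference scenario:
20 Mbp over five chromosomes, 2 focal + 15 reference + 1 outgroup samples,
9 planted de novo SNPs, 19 conversion tracts (500 bp, each anchored on a
founder heterozygous site so it leaves a genotypic footprint; a conversion
that converts no heterozygous site is biologically invisible), one 2.25 Mbp
copy-neutral segmental LOH, and one 400 kbp half-depth deletion control on
a separate chromosome. Events are placed at least 20 kbp apart so each maps
to exactly one call. These sizes keep the full suite under a minute on one
CPU while leaving every rate and density at the values above.

## Windowed scans and chromosome profiles

`relative_heterozygosity()` uses 250 kbp windows by default. "Heterozygous
in the sister clade" means heterozygous in **all** sister samples (strict
intersection; configurable to "any"): the denominator is then the clade's
shared ancestral heterozygosity, which is the quantity an LOH erodes.
Windows with no informative sites are reported as `NA` — such windows are
homozygous in the references, and zero-filling would fake LOH where there
is no information. The trailing partial window is kept and flagged.

`feature_proportions()` applies *element-level* overlap exclusion: a TE
overlapping any exon is dropped entirely, and vice versa, before each set
is merged and divided by ungapped length. Element-level (rather than
base-level) exclusion discards ambiguous annotations wholesale instead of
trimming them; a base-level mode is available behind `mode = "base"`.
Structural variants shorter than 50 bp are dropped before merging.

## Morphometrics and behavior

Traits are rescaled to [0, 1] per species (`normalize_traits()`), making
shape comparable across species with different absolute sizes; a trait
constant within a species becomes 0 with a warning. `size_match()`
iteratively removes one extreme at a time — from the group whose mean
deviates more from the pooled mean, its maximum if it sits above the pooled
mean, its minimum otherwise, alternating on exact ties starting with the
larger-mean group — re-testing with a Welch two-sample t-test (the
procedure targets *means*; a Wilcoxon alternative sits behind
`test = "wilcoxon"`) until p ≥ α = 0.05. The removal schedule and test are
design choices the data cannot pin down; both are exposed as arguments.
`pca_project()` runs covariance-based PCA on the normalized traits (no
re-standardization — the 0–1 scaling already equalizes ranges).
`raid_summary()` divides per-genotype raid totals by the colony count and
reports participant fractions.

## Degenerate inputs and tie-breaks

- Empty VCF body → empty matrix, no error; all-sites-filtered → warning
  plus empty matrix.
- `hard_filter()` computes its threshold before removal; on depth
  distributions whose median is stable under tail removal (the simulator's
  regime and any realistic coverage profile) a second application removes
  nothing.
- A chromosome with no sister-informative sites is an error for boundary
  localization; no focal-homozygous run returns `NULL` rather than a
  zero-width interval.
- `pairwise_divergence()` scores shared alleles fractionally (het vs
  matching hom = 0.5) and is a sanity companion for externally inferred
  trees, not a substitute for model-based phylogenetics.

## Known limitations

- A single spurious residual heterozygous call inside a genuine LOH (e.g.
  from collapsed duplicates) splits the maximal run and shortens the
  reported inner span; the depth filter removes most such sites, but no
  smoothing is applied — raw values are reported.
- The distinguishing-site definition requires complete genotype calls;
  sites missing in any sample are lost with the default filter, which
  under-counts events in sparse data.
- The generation clock inherits μ and G from external sources; its
  interval reflects Poisson counting error only.
- Boundary localization reports inner bounds as the headline span; the
  true breakpoint is only known to lie between inner and outer bounds
  (at ~1 site/kbp the two differ by a few kilobases).
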