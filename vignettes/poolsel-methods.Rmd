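---
title: "Methods: divergence islands and selection coefficients from pool-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence islands and selection coefficients from pool-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsel)
```

`poolsel` analyses pooled whole-genome sequencing of marine and freshwater
population samples: it estimates allele frequencies from read counts, finds
marine–freshwater marker SNPs, clusters them into divergence islands (DIs),
contrasts diversity and coding effects inside and outside the islands, and
estimates selection coefficients from allele-frequency change in populations
of known age. This vignette records the models, the parameters that matter,
the numerical conventions, and the choices we made where the design was
genuinely open.

## From counts to frequencies

Input is a tab-separated table, one row per site: `chrom`, `pos` (1-based),
`ref`, then one `A:C:G:T` field per pool (six-field `A:C:G:T:N:del` variants
are accepted; N and deletion counts are discarded because only SNPs are
analysed). A field of `"."` marks a pool-site that failed the upstream
base-quality screen. That screen is represented as a resolved boolean rather
than recomputed: a per-population base-quality cutoff applied during pileup
cannot be reconstructed from counts alone, so the contract is simply that
quality-failed pool-sites carry no usable counts.

At each site the two most frequent nucleotides, summed across pools, define
the biallelic site (ties broken alphabetically, for determinism). The
per-pool frequency of the tracked (overall-major) allele is the raw ratio
`major/(major+minor)` — no pool-size shrinkage, because everything downstream
thresholds raw frequencies at 0.5/0.8. A pool-site is *usable* when its
quality flag is set and its total depth strictly exceeds the pool's
`min_depth` (the cutoffs are read literally as "> 10" / "> 5", so depth equal
to the cutoff fails). Sites where reads of a third allele exceed 5% of the
total are rejected outright: the marker criteria assume biallelic sites, and
a triallelic rule is not something the frequency estimator should silently
paper over. Rejection is a recorded outcome, not an error. Monomorphic
covered sites are kept (frequency 1) so that diversity denominators can count
them.

## Marker SNPs

A site is a *strong* marker when some allele exceeds frequency 0.8 in every
marine pool while the other allele exceeds 0.8 in every freshwater pool; a
*weak* marker relaxes only the freshwater threshold to 0.5. Two conventions
are worth making explicit:

* the marine-side threshold stays at 0.8 under both criteria — the weak
  criterion describes freshwater populations that have not yet carried the
  freshwater allele far, not noisier marine pools;
* all thresholds are strict, so a frequency of exactly 0.80 does not qualify.

Every strong marker is also a weak marker, so the weak-criterion marker set
is `status %in% c("strong", "weak")`. Sites unusable in any criteria-defining
pool are skipped, never imputed; by default only the four defining pools must
be usable, not all pools in the study.

## Divergence islands

Chromosomes are tiled with consecutive, non-overlapping 10-kb windows
anchored at position 1 (frames, not a sliding window). Windows holding at
least `min_strong = 10` strong (or `min_weak = 20` weak) markers are flagged;
maximal runs of adjacent flagged windows form seed regions; each region is
trimmed to the outermost markers it contains; and regions whose gap
(`next start − previous end − 1`) is strictly below 40 kb are merged. Over
the timescales involved, recombination between regions that close is
unlikely, which is the rationale for merging. We merge *after* trimming —
published island boundaries are not 10-kb multiples, which indicates
trimming to markers, and measuring gaps between trimmed boundaries keeps the
merge rule a statement about marker-to-marker distance rather than about
window arithmetic. Merging is idempotent, and disabling it
(`merging_enabled = FALSE`) can only increase the island count; both
properties are asserted in the tests.

The strong- and weak-criterion island sets are then overlaid: overlapping
intervals merge into one DI spanning their union, recording which criteria
supported it. Ids follow the chromosome-ordinal convention (`IV-2` = second
DI on chromosome IV). Internally all coordinates are 1-based inclusive, so
`length = end − start + 1`; BED output converts to 0-based half-open.

## Nucleotide diversity

π for a pool over a region is the mean over usable sites of
`2·p̂·(1−p̂)·n_c/(n_c−1)`, where `n_c` is the number of pooled chromosomes;
monomorphic covered sites contribute zero but count in the denominator. The
estimator is deliberately simple; the `n_c/(n_c−1)` factor corrects for
sampling individuals into the pool. Read sampling adds a further downward
bias of exactly `1/depth` to `2p̂(1−p̂)`, so an optional
`depth_correction = TRUE` mode multiplies each site by `depth/(depth−1)`,
making the estimator unbiased for the population heterozygosity under
binomial pooling and error-free reads. The raw mode is the default (it is
what frequency-threshold analyses implicitly use); the corrected mode is what
the calibration tests use when comparing π against a simulation's generating
heterozygosity, because at 50× the 2% depth bias exceeds the Monte-Carlo
noise of 10^5 sites.

## Coding effects and contingency

SNPs are mapped into CDS coordinates of every transcript covering them
(GFF3 + FASTA, strand-aware, honouring the phase of the first coding
segment), codons are rebuilt and translated with the standard genetic code.
A site in several transcripts is called nonsynonymous if it is nonsynonymous
in any of them — conservative toward detecting selection — with per-transcript
detail retained. Sites in a trailing partial codon of a flagged-incomplete
transcript are not classified. When genes overlap, SNPs are counted once per
genomic site. NS/S ratios are reported to two decimals per stratum (inside
vs outside DIs); a zero synonymous count yields an infinite ratio with a
flag. The two-tailed Fisher exact test uses point-probability summation (the
sum over all tables with the observed margins whose probability does not
exceed the observed table's); a zero margin returns P = 1 by convention. The
tests cross-check the implementation against a full enumeration oracle.

## Selection coefficients

For a DI with mean freshwater-allele frequency `p_t` in a population of known
age, `s` solves the deterministic diploid recursion (see
`?forward_trajectory`) after `G` generations, with intermediate dominance
h = 0.5 and a two-year generation time, so `G = age/2` rounded to nearest.
Assumed founding frequencies: 0.1 in natural lakes (the marine standing
frequency) and the founder ratio in quarry populations (0.5 for equal
seeding). Two fitness parameterizations are exposed — `advantage`
(`1+s, 1+hs, 1`), the default, and `gillespie` (`1, 1−hs, 1−s`) — because the
classical treatment writes selection against the disfavoured allele; they
differ at order `s²`, which matters at the `s ≈ 0.2` values seen here, so
the choice is surfaced in the configuration rather than hidden.

The inversion is a bisection on `s` over `[0, 10]` (advantage; just below 1
for gillespie, keeping all fitnesses positive) when `p_t > p_0`, and
`[−0.99, 0]` with a `negative` flag when `p_t < p_0`, valid because the final
frequency is strictly increasing in `s` (asserted numerically over a grid).
Convergence tolerance is `|p_G − p_t| ≤ 1e-8` with the bracket narrowed below
1e-10; the round trip `estimate_s(forward_trajectory(...))` recovers `s` to
better than 1e-6 across the tested grid. Degenerate observations: `p_t`
exactly 0 or 1 is unreachable in finite time from an interior `p_0` and
yields `NA`; `p_t ≥ 0.995` is flagged `near_fixation_unreliable` (the
estimate is still reported). The 0.995 cutoff is an artifact choice — near
fixation the trajectory saturates and the inversion loses all precision —
and it is deliberately conservative.

Cross-population summaries exclude estimates flagged negative or
near-fixation (and missing values): a "mean s" should describe the islands
where directional selection was actually measurable, and this exclusion rule
is also the one under which the bundled catalogue reproduces its printed
means. Spearman's rho uses average ranks for ties and a two-sided P from the
t approximation with n−2 degrees of freedom; population pairs with fewer
than three shared usable islands are omitted with a notice.

## Chronology

Two linear clocks: lake age = elevation × 1000 / 3.8 mm·yr⁻¹ (optionally
rounded, e.g. to the nearest half-century), and haplotype divergence time
`T = d/μ` generations at μ = 1e-8 per site per generation. The one-way form
of the divergence clock is the default — it is the convention under which a
1% haplotype divergence dates to 10⁶ generations — with the textbook pairwise
`T = d/(2μ)` available as a flag.

## The simulator: what it emulates, and what it does not

`simulate_metapopulation()` generates the data structure the analysis
assumes. Per island, two ancient haplotypes differ at
`Binomial(length, marker_density)` sites (default density 0.009, the scale
observed in real islands); the marine population carries the freshwater
haplotype at standing frequency 0.1. Freshwater populations are founded
binomially from marine frequencies (lakes) or with exact founder counts
(quarries), then evolve by Wright–Fisher binomial resampling of the island
haplotype frequency around the deterministic selection recursion — complete
linkage within an island, islands independent. Background SNPs drift
neutrally from Beta(0.3, 0.3) marine frequencies. Pooled sequencing draws
*one* haplotype sample per island per pool (the same individuals underlie
all of an island's sites), Poisson depth per site, binomial reads, and
uniform base errors at rate `error_rate`, satisfying
`E[alt/depth] = f(1−ε) + (1−f)ε/3`. Planted genes with known codon structure
provide synonymous/nonsynonymous ground truth.

Defaults are the study conditions: eight pools with coverages 17–63× and
pool sizes 8–20, per-pool depth cutoffs of 10 or 5, ages 34–700 years,
quarry seedings of 20+20 and 1+1 founders, 19 islands, h = 0.5. Values no
study states were fixed once at field-realistic levels: Nₑ = 500 for lakes
and the large quarry and Nₑ = 50 for the tiny one (its carrying capacity is
~100 fish); founder counts of 100 individuals for natural lake
colonisations; per-island s uniform on 0.05–0.25 (bracketing the published
0.02–0.27 range while keeping islands detectable in the old lakes);
sequencing error 10⁻³ (post-quality-filter); a Beta(0.3, 0.3) background
frequency spectrum (U-shaped, as for neutral variation).

What the simulator does **not** model — and therefore what passing tests do
not establish about real data: within-island recombination (a two-haplotype
frequency stands in for the hitch-hiking structure of real islands, which is
defensible precisely because real DIs sit in low-recombination regions and
inversions); hitch-hiking of background sites outside islands; migration
between freshwater populations; fluctuating or habitat-reversed selection;
mapping artefacts, strand bias, indels and reference bias in the counts; and
linked variation in base quality. Detection recall and estimator bias
measured on the simulator are statements about sampling noise, drift and the
method's own conventions, not about alignment-level error modes.

Problem sizes in the tests and the acceptance script were chosen to exercise
the statistics at meaningful precision while staying desk-scale: a 4-Mb
genome with 50 replicate islands for parameter recovery (s = 0.15, Nₑ = 500,
depth 50, 17 generations), the default 19-island genome at depth 50 for
detection recall, ~10⁵ usable null sites for the marker false-positive rate,
and ~10⁵ sites for π calibration against the generating heterozygosity.

## Pipeline and reproducibility

`run_pipeline()` executes the stages in order, writes TSV/BED/JSON outputs
plus a manifest naming every method constant and per-stage row counts, and
is a pure function of (inputs, configuration): reruns are byte-identical.
The manifest's configuration checksum excludes the output directory, which
is not part of the analysis identity. A failing stage aborts with its name
and leaves a `FAILED` marker beside any partial outputs. The stage functions
are all exported, so any subset (simulate, frequencies, markers, islands,
diversity, coding, selection, report) can be driven directly from R.

## Known limitations

* Frequencies are raw read ratios; no genotype likelihoods or posteriors, so
  very low-coverage pools are handled only through the depth cutoff.
* The selection estimator is deterministic: drift is not part of the
  inversion, so individual-island estimates inherit drift variance (visible
  in the simulator's small-Nₑ quarry) and near-fixation estimates are
  unreliable by construction. No confidence intervals are attached.
* π has no PoPoolation-style depth-spectrum correction beyond the
  `depth/(depth−1)` factor; Watterson's θ and Tajima's D are out of scope.
* The DI definition is the windowed-count rule described above; HMM/SOM or
  composite-score scans are deliberately not implemented.
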