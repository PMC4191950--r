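# poolsel

Divergence islands and selection coefficients from pooled whole-genome
sequencing of marine and freshwater fish populations.

## The problem

Marine threespine stickleback repeatedly colonise newly formed freshwater
lakes, and the alleles that adapt them to freshwater pre-exist at low
frequency (~0.1) in the sea ("transporter hypothesis"). Comparing pooled
whole-genome sequencing (pool-seq) of marine and freshwater population
samples reveals short genomic regions — *divergence islands* (DIs) — packed
with SNPs whose allele frequencies differ sharply between the habitats. In
freshwater populations of *known age* (lakes dated by post-glacial land
uplift, or quarry populations seeded at a known date with known founder
mixes), the rise of freshwater alleles from a known starting frequency
measures the strength of selection directly.

`poolsel` implements this analysis end to end for people working with pooled
count data (mpileup- or sync-style tables):

* **Allele frequencies** from per-pool nucleotide read counts, with per-pool
  depth cutoffs (strict `>`), base-quality flags, and rejection of sites with
  more than 5% third-allele reads.
* **Marker SNPs**: biallelic sites where every marine pool has one allele at
  frequency > 0.8 and every freshwater pool has the other allele at > 0.8
  ("strong") or > 0.5 ("weak").
* **Divergence islands**: 10-kb windows holding at least 10 strong (20 weak)
  markers, runs of such windows trimmed to their outermost markers, regions
  closer than 40 kb merged, and the strong and weak sets overlaid into the
  final DI catalogue.
* **Nucleotide diversity** (π) per pool, genome-wide and inside/outside DIs:
  mean per-site heterozygosity `2p(1-p) · n_c/(n_c-1)` over covered sites,
  with an optional `depth/(depth-1)` unbiasing mode.
* **Coding effects**: synonymous/nonsynonymous classification of SNPs against
  GFF3 gene models and a FASTA genome, NS/S ratios inside/outside DIs, and a
  two-tailed Fisher exact test.
* **Selection coefficients**: with freshwater-allele frequency `p` and
  fitnesses `w_FF = 1+s`, `w_FM = 1+hs`, `w_MM = 1` (or the equivalent
  `1, 1-hs, 1-s` form), the deterministic recursion

      p' = p (p·w_FF + q·w_FM) / (p²·w_FF + 2pq·w_FM + q²·w_MM)

  is iterated over `G = age/2` generations and inverted by bisection to find
  the `s` that carries the assumed founding frequency (0.1 in natural lakes,
  founder ratio in quarries) to the observed DI-mean frequency, assuming
  intermediate dominance (h = 0.5). Estimates are summarised per population
  and correlated across populations (Spearman).
* **Chronology**: lake age from elevation at 3.8 mm/yr uplift; haplotype
  divergence time `T = d/μ` at μ = 1e-8.
* **A Wright–Fisher metapopulation simulator** producing pooled count tables,
  FASTA, GFF3 and ground truth, so the whole pipeline is testable without any
  external download.

The package also bundles the published White Sea summary tables
(`whitesea_islands()`, `whitesea_pools()`, `whitesea_ns_s()`) used as
reference inputs for the bookkeeping arithmetic.

## Worked example

Simulate the default metapopulation (19 planted islands, eight pools with
realistic coverages 17–63×) and run the full pipeline:

```r
library(poolsel)

sim <- simulate_metapopulation(sim_config(seed = 7))
res <- run_pipeline(run_config(counts = sim$paths$counts, pools = sim$pools,
                               gff = sim$paths$gff, fasta = sim$paths$fasta,
                               out_dir = tempfile()))
#> read 57945 sites x 8 pools
#> frequencies: 57945 sites kept
#> markers: 6640 strong, 6648 weak-criterion
#> islands: 19 DIs, 1,179,888 nt total
#> selection: 114 estimates, mean s: ershovskoye_residential=0.110, ...

head(res$island_summary$per_di[c("id", "chrom", "start", "end", "length")])
#>      id  chrom  start    end length
#> 1   I-1   chrI 200184 216160  15977
#> 2   I-2   chrI 360695 398852  38158
#> 3 III-1 chrIII  10320  88549  78230
#> ...

truth_report(sim, res$islands)[c("recall", "precision")]
#> $recall    [1] 1
#> $precision [1] 1
```

All 19 planted islands are recovered exactly; 99.1% of strong markers fall
inside the detected DIs; and the per-population mean selection coefficients
(`res$selection_summary`) land near the simulated values, with the old lakes
flagged `near_fixation_unreliable` because their freshwater alleles have had
~300 generations to fix. The report bundle written to `out_dir` contains
`markers.tsv`, `islands.tsv`/`islands.bed`, `diversity.tsv`, `effects.tsv`,
`contingency.json`, `selection.tsv`, `summary.json` and a `manifest.json`
with all method constants; a rerun with the same inputs is byte-identical.

On the published catalogue, the same summary functions reproduce the printed
numbers:

```r
s <- summarize_selection(whitesea_selection_scan())
round(s$mean_s, 2)                 # 0.16 (Ershovskoye), 0.13 (Goluboy)
round(s$correlations$rho, 2)       # 0.30 over the 16 doubly-usable DIs
fisher_exact_two_tailed(matrix(c(17, 139, 4, 146), 2))  # 0.0056
```

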