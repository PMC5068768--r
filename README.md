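# dmrbump

Bump-hunting detection of differentially methylated regions (DMRs) from
Illumina 450K-style methylation arrays, with multi-cohort consensus.

## What it does, and for whom

Case-control methylation studies of heterogeneous disorders rarely replicate
at the single-CpG level. `dmrbump` is for analysts who have *processed*
beta-value matrices (probes × samples) from two or more independent cohorts
and want the regions — runs of neighbouring CpGs — that are consistently
differentially methylated in all of them, each with resampling-based
uncertainty attached.

The pipeline:

1. **Filter probes**: detection P > 0.05 in any sample; annotated SNP at the
   single-base extension (offset 0) or CpG site (offsets 1–2); X/Y
   chromosomes; optional exclusion lists (e.g. cell-type-specific marker
   probes).
2. **Estimate effects**: per probe, OLS of M-values
   `M = log2(beta/(1-beta))` on case/control status adjusted for sex, age
   and post-mortem interval when available; Δ*M* is the group coefficient.
3. **Smooth**: running medians (window 5) within probe clusters (neighbours
   ≤ `maxgap` = 500 bp apart).
4. **Bootstrap null**: refit with the group column removed, resample
   residual columns with replacement, re-fit and re-smooth `n_boot` times.
   The effect cut-off is the 95% quantile of the pooled absolute smoothed
   null statistics.
5. **Call and score regions**: maximal within-cluster runs beyond ±cut-off;
   per region, an area statistic Σ|smoothed Δ*M*|, a pooled-null P-value, a
   Benjamini–Hochberg FDR and a bootstrap-max FWER.
6. **Consensus**: direction-stratified intersection of significant regions
   across cohorts (common overlap ≥ 2 bp), plus nearest-gene annotation.

A synthetic three-cohort study generator with planted DMRs
(`simulate_study()`) makes the whole pipeline testable end to end without
any downloads.

## Worked example

```r
library(dmrbump)

study <- simulate_study(sim_config(), seed = 11)   # 3 cohorts, ~2000 probes,
                                                   # 5 shared hyper + 2 shared hypo DMRs
coh <- study$cohorts$cohort1
man <- study$manifest[match(rownames(coh$beta), study$manifest$probe_id), ]
filt <- run_filter_stack(coh$beta, coh$detp, man,
          filter_config(exclusion_lists = list(celltype = study$truth$celltype_probes)))
fit <- bumphunt(filt$matrix, filt$manifest, coh$samples, n_boot = 100, seed = 42)
fit
#> Bump-hunting DMR analysis
#>   probes: 1891 in 266 clusters (maxgap 500 bp); samples: 24 cases, 24 controls
#>   covariates: sex, age, pmi
#>   bootstrap: 100 samples, seed 42, cut-off quantile 0.95
#>   82 candidate DMR (cut-off M-value 0.184); 10 with P<0.05; 9 with FWER<0.1
```

82 runs of probes exceeded the empirical cut-off of 0.184 M units; 10 have a
region-level P below 0.05 (the planted DMRs plus a few borderline runs), and
9 survive at FWER < 0.1. Repeating for the other two cohorts and
intersecting the significant regions:

```r
fits <- lapply(1:3, function(i) { ... as above per cohort ... })
sig <- lapply(fits, function(f) select_significant(f$regions, 0.05))
names(sig) <- names(study$cohorts)
cons <- consensus_overlap(sig, min_overlap = 2)
cons[, 1:5]
#>   chrom intersect_start intersect_end width direction
#> 1 chr15           22952         25045  2094     hyper
#> 2 chr17           29545         30023   479      hypo
#> 3 chr21           51243         51984   742     hyper
#> 4  chr4           28754         30114  1361     hyper
#> 5  chr5           27095         28024   930     hyper
#> 6  chr7           23065         23807   743     hyper
#> 7  chr8           29000         29834   835      hypo
```

Exactly the 5 hyper- and 2 hypo-methylated loci planted in all three cohorts
are recovered; the per-cohort private DMRs correctly fail consensus. Each row
also carries per-cohort coordinates and average Δ*M* columns, and
`annotate_nearest_gene(cons, read_gene_models(path))` adds the nearest gene
and its distance.

For real data, start at step 1 with your own `read_methyl_matrix()`,
`read_probe_manifest()` and `read_sample_sheet()` files; a thin command-line
dispatcher over the same functions is in `inst/cli/dmrbump.R`
(`simulate`, `bumphunt`, `consensus` subcommands).

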